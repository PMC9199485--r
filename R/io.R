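#' Write a connectivity matrix as a tab-delimited square table
#'
#' The table carries node ids as both the header row and the first column,
#' so matrices round-trip with their node labelling.
#'
#' @param matrix A `connectivity_matrix`.
#' @param path Output path.
#' @export
write_matrix <- function(matrix, path) {
  m <- unclass(matrix)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  d <- data.frame(node_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_matrix()]
#'
#' @param path File path.
#' @param subject_id,visit Optional labels stored as attributes.
#' @param tol Symmetry tolerance passed to [connectivity_matrix()].
#' @return A `connectivity_matrix`.
#' @export
read_matrix <- function(path, subject_id = NULL, visit = NULL, tol = 1e-10) {
  d <- read.delim(path, header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!identical(colnames(m), ids))
    stop("matrix header and node-id column disagree in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  connectivity_matrix(m, subject_id = subject_id, visit = visit, tol = tol)
}

#' Write a long-format behaviour table as CSV
#'
#' Columns: subject_id, group, visit, domain, score, then any covariates.
#'
#' @param behavior Data frame in long format.
#' @param path Output path.
#' @export
write_behavior <- function(behavior, path) {
  req <- c("subject_id", "group", "visit", "domain", "score")
  if (!all(req %in% names(behavior)))
    stop("behavior table must have columns ", paste(req, collapse = ", "))
  write.csv(behavior, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format behaviour table
#'
#' @param path CSV path.
#' @param invert_domains Domains whose scores are multiplied by -1 at load
#'   so that higher always means better (e.g. reaction-time composites where
#'   raw high scores mean poor performance).
#' @return Data frame with `subject_id`, `group`, `visit`, `domain`,
#'   `score` and any covariate columns.
#' @export
read_behavior <- function(path, invert_domains = character()) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "visit", "domain", "score")
  if (!all(req %in% names(d)))
    stop("behavior table must have columns ", paste(req, collapse = ", "))
  if (length(invert_domains)) {
    flip <- d$domain %in% invert_domains
    d$score[flip] <- -d$score[flip]
  }
  d
}
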