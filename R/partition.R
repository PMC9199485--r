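#' Canonical seven-network cortical labels
#'
#' The seven large-scale functional networks commonly used to partition the
#' cerebral cortex: visual, somatomotor, dorsal attention, ventral attention,
#' limbic, frontoparietal and default mode.
#'
#' @return Character vector of the seven network labels, in canonical order.
#' @export
yeo7_labels <- function() {
  c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
    "limbic", "frontoparietal", "default_mode")
}

#' Construct a node-to-network partition
#'
#' A partition assigns every node of a connectivity matrix to exactly one
#' large-scale network. It is represented as a factor named by node id whose
#' levels are the declared (ordered) label set; the level order fixes the
#' order of all per-network output.
#'
#' @param node_ids Character vector of node identifiers (unique).
#' @param labels Character vector, one network label per node.
#' @param levels Declared label set; defaults to the labels present, in
#'   order of first appearance. Every label must belong to this set.
#' @return A named factor of class `network_partition`.
#' @export
network_partition <- function(node_ids, labels, levels = unique(labels)) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("duplicate node ids in partition")
  if (length(labels) != length(node_ids))
    stop("labels and node_ids must have equal length")
  if (!all(labels %in% levels))
    stop("partition labels outside the declared label set: ",
         paste(setdiff(labels, levels), collapse = ", "))
  p <- factor(labels, levels = levels)
  names(p) <- node_ids
  class(p) <- c("network_partition", class(p))
  p
}

# align a partition to the node set of a matrix; errors on mismatch
align_partition <- function(partition, node_ids) {
  node_ids <- as.character(node_ids)
  if (is.null(names(partition)))
    stop("partition must be named by node id")
  missing <- setdiff(node_ids, names(partition))
  if (length(missing))
    stop("partition does not cover nodes: ",
         paste(head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  p <- partition[node_ids]
  names(p) <- node_ids
  p
}

#' Read a partition from a two-column TSV (node_id, network_label)
#'
#' @param path File path.
#' @param levels Optional declared label set (defaults to order of first
#'   appearance in the file).
#' @return A `network_partition`.
#' @export
read_partition <- function(path, levels = NULL) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (ncol(d) < 2L) stop("partition file needs columns node_id, network_label")
  if (is.null(levels)) levels <- unique(d[[2L]])
  network_partition(d[[1L]], d[[2L]], levels = levels)
}

#' Write a partition as a two-column TSV
#'
#' @param partition A `network_partition`.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  d <- data.frame(node_id = names(partition),
                  network_label = as.character(partition))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
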