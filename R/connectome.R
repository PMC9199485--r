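#' Construct a time-series panel
#'
#' Holds per-node signal vectors (columns of `series`) and optional nuisance
#' regressors of the same length (columns of `confounds`): motion parameters,
#' tissue signals, global signal. All analyses of real resting-state data
#' start from such a panel; band-pass filtering and spatial preprocessing are
#' assumed to have happened upstream.
#'
#' @param series Numeric matrix, rows = timepoints (T >= 3), columns = nodes;
#'   column names are node ids (generated if absent).
#' @param confounds Optional numeric matrix of same-length regressors.
#' @return List of class `time_series_panel` with elements `series`,
#'   `confounds`.
#' @export
time_series_panel <- function(series, confounds = NULL) {
  series <- as.matrix(series)
  if (nrow(series) < 3L) stop("time series must have length T >= 3")
  if (anyNA(series)) stop("time series contain missing samples")
  if (is.null(colnames(series)))
    colnames(series) <- sprintf("n%04d", seq_len(ncol(series)))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nrow(series))
      stop("confounds and series must have the same number of timepoints")
    if (anyNA(confounds)) stop("confounds contain missing samples")
    if (is.null(colnames(confounds)))
      colnames(confounds) <- sprintf("c%02d", seq_len(ncol(confounds)))
  }
  structure(list(series = series, confounds = confounds),
            class = "time_series_panel")
}

#' Regress nuisance confounds out of nodal time series
#'
#' Replaces every node series by its least-squares residual on an intercept
#' plus the panel's confound columns, producing partial time series whose
#' correlations are controlled for the confounds. With no confounds the
#' series are mean-centred.
#'
#' @param panel A [time_series_panel()].
#' @return A `time_series_panel` of residual series (confounds dropped).
#' @export
regress_confounds <- function(panel) {
  stopifnot(inherits(panel, "time_series_panel"))
  Y <- panel$series
  X <- cbind(`(intercept)` = rep(1, nrow(Y)), panel$confounds)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    # pivoted QR puts dependent columns last
    bad <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop("confound matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  R <- qr.resid(qr_x, Y)
  colnames(R) <- colnames(Y)
  time_series_panel(R, confounds = NULL)
}

#' Compute a functional connectivity matrix from a panel
#'
#' Entry (i, j) is the Pearson correlation of node i's and node j's series;
#' the diagonal is forced to zero (self-correlation carries no information
#' and is excluded from every downstream metric). Run [regress_confounds()]
#' first to obtain partial correlations controlled for nuisance signals.
#'
#' @param panel A [time_series_panel()] (typically residual series).
#' @param subject_id,visit Optional labels stored as attributes.
#' @return Symmetric numeric matrix with node-id dimnames, zero diagonal,
#'   class `connectivity_matrix`.
#' @export
compute_fc <- function(panel, subject_id = NULL, visit = NULL) {
  stopifnot(inherits(panel, "time_series_panel"))
  Y <- panel$series
  sds <- apply(Y, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance series for nodes: ",
         paste(colnames(Y)[sds == 0], collapse = ", "))
  M <- cor(Y)
  diag(M) <- 0
  connectivity_matrix(M, subject_id = subject_id, visit = visit,
                      check_symmetry = FALSE)
}

#' Construct / validate a connectivity matrix
#'
#' @param m Square numeric matrix of edge weights on the correlation scale.
#'   Symmetry is enforced by averaging `(m + t(m)) / 2`; a deviation above
#'   `tol` raises a warning. The diagonal is set to zero.
#' @param node_ids Node identifiers (defaults to existing dimnames).
#' @param subject_id,visit Optional labels stored as attributes.
#' @param tol Symmetry tolerance (default 1e-10).
#' @param check_symmetry Warn when asymmetry exceeds `tol`.
#' @return Matrix of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(m, node_ids = NULL, subject_id = NULL,
                                visit = NULL, tol = 1e-10,
                                check_symmetry = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("connectivity matrix must be square")
  if (is.null(node_ids))
    node_ids <- if (!is.null(rownames(m))) rownames(m) else
      sprintf("n%04d", seq_len(nrow(m)))
  asym <- max(abs(m - t(m)))
  if (check_symmetry && asym > tol)
    warning(sprintf("matrix asymmetry %.3g above tolerance; symmetrising", asym))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(node_ids, node_ids)
  attr(m, "subject_id") <- subject_id
  attr(m, "visit") <- visit
  class(m) <- c("connectivity_matrix", class(m))
  m
}

#' Zero out negative functional connectivity
#'
#' Negative FC edges have no agreed interpretation; all graph metrics here
#' are computed on the rectified matrix in which negative weights are set to
#' zero and nonnegative weights are unchanged.
#'
#' @param matrix A `connectivity_matrix`.
#' @return The rectified matrix (attributes preserved).
#' @export
rectify <- function(matrix) {
  out <- pmax(matrix, 0)
  attributes(out) <- attributes(matrix)
  attr(out, "rectified") <- TRUE
  out
}

#' Positive-edge density, globally and per network block
#'
#' Density is the fraction of possible undirected edges with strictly
#' positive weight: globally over all N(N-1)/2 node pairs and per network
#' block (diagonal blocks = within-network, off-diagonal = between-network
#' pairs). Exact zeros - e.g. produced by rectification - count as absent
#' edges, so density is invariant to rectification.
#'
#' @param matrix A `connectivity_matrix`.
#' @param partition A `network_partition` covering all nodes.
#' @return List of class `density_report`: `global` (fraction), `blocks`
#'   (K x K matrix of block densities), `n_edges_pos`, `n_edges_max`.
#' @export
fc_density <- function(matrix, partition) {
  p <- align_partition(partition, rownames(matrix))
  N <- nrow(matrix)
  up <- upper.tri(matrix)
  pos <- matrix > 0 & up
  labs <- levels(p)
  K <- length(labs)
  idx <- as.integer(p)
  # block membership of each upper-triangle pair, as an ordered label pair
  row_net <- matrix(idx, N, N)
  col_net <- matrix(idx, N, N, byrow = TRUE)
  a <- pmin(row_net, col_net)[up]
  b <- pmax(row_net, col_net)[up]
  pos_up <- (matrix > 0)[up]
  key <- (a - 1L) * K + b
  pos_counts <- tapply(pos_up, key, sum)
  tot_counts <- tapply(rep(1L, length(key)), key, sum)
  blocks <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  for (nm in names(tot_counts)) {
    k <- as.integer(nm)
    i <- (k - 1L) %/% K + 1L
    j <- (k - 1L) %% K + 1L
    d <- as.numeric(pos_counts[nm]) / as.numeric(tot_counts[nm])
    blocks[i, j] <- d
    blocks[j, i] <- d
  }
  structure(list(global = sum(pos_up) / (N * (N - 1) / 2),
                 blocks = blocks,
                 n_edges_pos = sum(pos_up),
                 n_edges_max = N * (N - 1) / 2),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("FC density: global %.3f (%d / %d positive edges)\n",
              x$global, x$n_edges_pos, x$n_edges_max))
  print(round(x$blocks, 3))
  invisible(x)
}
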