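#' Weighted nodal participation coefficient
#'
#' For node i with total strength \eqn{k_i} (sum of its nonnegative edge
#' weights) and per-network strengths \eqn{k_{i,m}} to each of the M declared
#' networks,
#' \deqn{PC_i = 1 - \sum_{m=1}^{M} (k_{i,m} / k_i)^2.}
#' A node whose edges all stay inside its own network has PC 0; a node whose
#' strength is spread evenly over all M networks attains the maximum
#' 1 - 1/M. PC is computed on weighted (not binarised) edges; run
#' [rectify()] first, negative weights are refused.
#'
#' Isolated nodes (\eqn{k_i = 0}) are assigned PC 0 and flagged in the
#' `isolated` column rather than propagating NaN, so network means stay
#' defined; the flagged count is reported via a message.
#'
#' @param matrix Nonnegative symmetric `connectivity_matrix`, zero diagonal.
#' @param partition A `network_partition` covering the matrix's nodes.
#' @return Data frame of class `nodal_metrics`: `node_id`, `network`,
#'   `strength`, `pc`, `isolated`; per-network strengths in attribute
#'   `k_by_network`.
#' @export
participation_coefficient <- function(matrix, partition) {
  if (any(matrix < 0))
    stop("matrix has negative entries; apply rectify() before computing PC")
  p <- align_partition(partition, rownames(matrix))
  k <- rowSums(matrix)
  # k_{i,m}: column-group sums per node
  kim <- t(rowsum(t(unclass(matrix)), group = p, reorder = FALSE))
  # rowsum orders groups by factor level when reorder = TRUE; keep level order
  kim <- kim[, levels(p), drop = FALSE]
  iso <- k == 0
  pc <- numeric(length(k))
  if (any(!iso)) {
    ratio <- kim[!iso, , drop = FALSE] / k[!iso]
    pc[!iso] <- 1 - rowSums(ratio^2)
  }
  if (any(iso))
    message(sum(iso), " isolated node(s) assigned PC 0")
  out <- data.frame(node_id = rownames(matrix),
                    network = as.character(p),
                    strength = unname(k),
                    pc = unname(pc),
                    isolated = unname(iso),
                    stringsAsFactors = FALSE)
  attr(out, "k_by_network") <- kim
  attr(out, "networks") <- levels(p)
  class(out) <- c("nodal_metrics", class(out))
  out
}

#' Network-level and global mean participation coefficient
#'
#' Arithmetic mean PC over the nodes of each network (the extent to which
#' that network connects to others) and over all nodes (global integration).
#' The global mean is identically the node-count-weighted mean of the
#' network means. An empty network yields `NA` with a warning.
#'
#' @param nodal A `nodal_metrics` table from [participation_coefficient()].
#' @param partition Optional `network_partition`; defaults to the partition
#'   recorded in `nodal`.
#' @return Data frame of class `pc_summary`: `network`, `mean_pc`,
#'   `n_nodes`, with the all-nodes mean as a final row labelled `"global"`.
#' @export
summarize_pc <- function(nodal, partition = NULL) {
  networks <- if (is.null(partition)) attr(nodal, "networks") else
    levels(partition)
  if (is.null(networks)) networks <- unique(nodal$network)
  f <- factor(nodal$network, levels = networks)
  n <- as.integer(table(f))
  m <- as.numeric(tapply(nodal$pc, f, mean))
  if (any(n == 0L))
    warning("empty network(s): ", paste(networks[n == 0L], collapse = ", "),
            "; mean PC reported as NA")
  out <- data.frame(network = c(networks, "global"),
                    mean_pc = c(m, mean(nodal$pc)),
                    n_nodes = c(n, nrow(nodal)),
                    stringsAsFactors = FALSE)
  class(out) <- c("pc_summary", class(out))
  out
}

#' Select the high-PC ("diverse club") node set
#'
#' Takes the `floor(fraction * N)` nodes with highest PC (default top 20
#' percent), breaking ties deterministically by node id, and reports the
#' percentage composition of the selection across networks.
#'
#' @param nodal A `nodal_metrics` table.
#' @param fraction Top fraction in (0, 1); default 0.20.
#' @return List of class `high_pc_report`: `nodes` (character vector),
#'   `composition` (named percentages summing to 100), `fraction`,
#'   `n_selected`.
#' @export
high_pc_nodes <- function(nodal, fraction = 0.20) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_sel <- floor(fraction * nrow(nodal))
  if (n_sel < 1L) stop("fraction * N < 1: no nodes selectable")
  ord <- order(-nodal$pc, nodal$node_id)
  sel <- nodal[ord[seq_len(n_sel)], , drop = FALSE]
  structure(list(nodes = sel$node_id,
                 composition = network_composition(
                   sel$node_id,
                   setNames(factor(nodal$network,
                                   levels = attr(nodal, "networks") %||%
                                     unique(nodal$network)),
                            nodal$node_id)),
                 fraction = fraction,
                 n_selected = n_sel),
            class = "high_pc_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage of a node set covered by a boolean mask
#'
#' E.g. the percentage of high-PC nodes that are significantly active under
#' a task-activation mask supplied as input.
#'
#' @param node_set Character vector of node ids (nonempty).
#' @param mask Logical vector named by node id, covering the set.
#' @return Overlap as a percentage in `[0, 100]`.
#' @export
set_overlap <- function(node_set, mask) {
  if (length(node_set) == 0L) stop("empty node set")
  missing <- setdiff(node_set, names(mask))
  if (length(missing))
    stop("mask does not cover nodes: ", paste(head(missing, 5L), collapse = ", "))
  100 * mean(mask[node_set])
}

#' Per-network composition of a node set
#'
#' @param node_set Character vector of node ids (nonempty).
#' @param partition A `network_partition` (or named factor) covering the set.
#' @return Named numeric vector of percentages over the declared networks,
#'   summing to 100.
#' @export
network_composition <- function(node_set, partition) {
  if (length(node_set) == 0L) stop("empty node set")
  p <- align_partition(partition, node_set)
  pct <- 100 * as.numeric(table(p)) / length(node_set)
  setNames(pct, levels(p))
}
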