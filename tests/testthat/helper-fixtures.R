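# in-code fixtures and independent oracles shared across test files

# small symmetric nonnegative weighted graph with a given partition
toy_two_network <- function() {
  # nodes a1 a2 a3 in net A, b1 b2 b3 in net B
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  m <- matrix(0, 6, 6, dimnames = list(ids, ids))
  m["a1", "a2"] <- 1; m["a1", "a3"] <- 1          # a1: within only
  m["a2", "b1"] <- 2; m["a2", "a3"] <- 1
  m["b1", "b2"] <- 0.5; m["b2", "b3"] <- 0.5
  m <- m + t(m)
  part <- network_partition(ids, rep(c("A", "B"), each = 3))
  list(matrix = connectivity_matrix(m), partition = part)
}

random_connectivity <- function(n, signed = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n, n)
  up <- upper.tri(m)
  m[up] <- if (signed) runif(sum(up), -1, 1) else runif(sum(up))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  connectivity_matrix(m, node_ids = sprintf("n%03d", seq_len(n)),
                      check_symmetry = FALSE)
}

random_partition <- function(node_ids, n_networks, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- sprintf("net%d", seq_len(n_networks))
  # guarantee every network nonempty
  assign <- c(labs, sample(labs, length(node_ids) - n_networks,
                           replace = TRUE))
  network_partition(node_ids, sample(assign), levels = labs)
}

# independent per-node loop oracle for the participation coefficient
brute_force_pc <- function(matrix, partition) {
  labs <- levels(partition)
  p <- as.character(partition[rownames(matrix)])
  vapply(seq_len(nrow(matrix)), function(i) {
    k_i <- 0
    k_im <- setNames(numeric(length(labs)), labs)
    for (j in seq_len(ncol(matrix))) {
      if (j == i) next
      w <- matrix[i, j]
      k_i <- k_i + w
      k_im[p[j]] <- k_im[p[j]] + w
    }
    if (k_i == 0) return(0)
    s <- 0
    for (lab in labs) s <- s + (k_im[[lab]] / k_i)^2
    1 - s
  }, numeric(1))
}

# step-up BH definition evaluated literally: min over j >= rank of m p_(j) / j
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * sorted[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# tiny default-like config for fast cohort tests
tiny_config <- function(...) {
  args <- list(...)
  base <- list(n_intervention = 10L, n_control = 5L,
               nodes_per_network = rep(8L, 7), seed = 42L)
  do.call(synthetic_config, utils::modifyList(base, args))
}
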