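#' Configuration for the synthetic cohort generator
#'
#' Describes the generative world the analysis assumes: a two-arm (2:1
#' allocation), two-visit cohort of modular connectomes with a planted,
#' intervention-specific shift in between-network coupling at the post
#' visit, plus behavioural domains coupled to the resulting change in
#' participation coefficient.
#'
#' Edge-weight defaults are calibrated so that at `edge_sd = 0.30` the
#' positive-edge density of generated baseline matrices falls inside the
#' empirical bands reported for dense cortical FC: roughly 63-80 percent
#' within-network and 42-62 percent between-network.
#'
#' @param n_intervention,n_control Group sizes (default 56 and 28, the 2:1
#'   allocation of the emulated design).
#' @param n_networks Number of networks M (default 7).
#' @param nodes_per_network Integer vector of length `n_networks`.
#' @param within_mean,between_mean Mean edge weight inside diagonal blocks
#'   and off-diagonal blocks (correlation scale); must satisfy
#'   `within_mean > between_mean`.
#' @param edge_sd Gaussian edge-noise SD; 0 gives exact block means.
#' @param integration_shift_mean,integration_shift_sd Mean and SD of the
#'   subject-specific additive shift applied to between-network block means
#'   of intervention subjects at the post visit. The subject-level draw
#'   gives the change in PC between-subject variance, without which no
#'   interaction is detectable.
#' @param trained_domain,transfer_domain,null_domain Domain names.
#' @param behavior_baseline_mean,behavior_baseline_sd Named numeric vectors
#'   (per domain) of baseline score distributions.
#' @param behavior_noise_sd Residual SD of post-visit scores in the trained
#'   and transfer domains.
#' @param trained_gain Intervention-only mean gain in the trained domain.
#' @param transfer_coupling Slope of transfer-domain gain on the change in
#'   global PC, intervention group only.
#' @param null_domain_sd Residual SD of the null domain (no planted effect
#'   in either group).
#' @param mediation_paths Named numeric vector `c(a, b, c_prime)` of
#'   standardized paths for mediation scenario simulation
#'   (see [simulate_mediation_data()]).
#' @param seed Integer root seed; identical configs generate bit-identical
#'   cohorts.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_intervention = 56L,
                             n_control = 28L,
                             n_networks = 7L,
                             nodes_per_network = rep(20L, n_networks),
                             within_mean = 0.17,
                             between_mean = 0.01,
                             edge_sd = 0.30,
                             integration_shift_mean = 0.01,
                             integration_shift_sd = 0.01,
                             trained_domain = "ufov",
                             transfer_domain = "working_memory",
                             null_domain = "episodic_memory",
                             behavior_baseline_mean = c(ufov = 0,
                                                        working_memory = 0,
                                                        episodic_memory = 0),
                             behavior_baseline_sd = c(ufov = 1,
                                                      working_memory = 1,
                                                      episodic_memory = 1),
                             behavior_noise_sd = 0.5,
                             trained_gain = 0.5,
                             transfer_coupling = 20,
                             null_domain_sd = 0.5,
                             mediation_paths = c(a = 0.4, b = 0.4,
                                                 c_prime = 0.2),
                             seed = 1L) {
  if (n_intervention < 1 || n_control < 1 || n_networks < 1)
    stop("counts must be positive")
  if (length(nodes_per_network) != n_networks)
    stop("nodes_per_network must have length n_networks (configuration error)")
  if (any(nodes_per_network < 1)) stop("nodes_per_network must be positive")
  if (!(within_mean > between_mean))
    stop("modular structure requires within_mean > between_mean")
  if (edge_sd < 0) stop("edge_sd must be nonnegative")
  domains <- c(trained_domain, transfer_domain, null_domain)
  for (v in list(behavior_baseline_mean, behavior_baseline_sd))
    if (!all(domains %in% names(v)))
      stop("behavior baseline parameters must be named for every domain")
  structure(list(
    n_intervention = as.integer(n_intervention),
    n_control = as.integer(n_control),
    n_networks = as.integer(n_networks),
    nodes_per_network = as.integer(nodes_per_network),
    within_mean = within_mean, between_mean = between_mean,
    edge_sd = edge_sd,
    integration_shift_mean = integration_shift_mean,
    integration_shift_sd = integration_shift_sd,
    trained_domain = trained_domain, transfer_domain = transfer_domain,
    null_domain = null_domain,
    behavior_baseline_mean = behavior_baseline_mean,
    behavior_baseline_sd = behavior_baseline_sd,
    behavior_noise_sd = behavior_noise_sd,
    trained_gain = trained_gain,
    transfer_coupling = transfer_coupling,
    null_domain_sd = null_domain_sd,
    mediation_paths = mediation_paths,
    seed = as.integer(seed)), class = "synthetic_config")
}

# network labels for a config: canonical seven names, generic beyond
config_networks <- function(config) {
  if (config$n_networks == 7L) yeo7_labels()
  else sprintf("net%02d", seq_len(config$n_networks))
}

# the a-priori partition implied by a config
config_partition <- function(config) {
  labs <- config_networks(config)
  node_labels <- rep(labs, times = config$nodes_per_network)
  n <- sum(config$nodes_per_network)
  network_partition(sprintf("n%04d", seq_len(n)), node_labels, levels = labs)
}

#' Analytic participation coefficient of the noise-free block model
#'
#' In the noise-free generator every node of network m has within-strength
#' \eqn{(n_m - 1) \cdot within\_mean} and strength
#' \eqn{n_{m'} \cdot between\_mean} to each other network; the PC formula
#' applied to these strengths gives the expected per-network PC exactly.
#' Serves as the closed-form oracle for recovery tests.
#'
#' @param config A [synthetic_config()].
#' @param between_shift Additive shift on the between-network mean (e.g.
#'   the planted post-visit integration shift); default 0.
#' @return Named numeric vector of per-network expected PC, with the
#'   node-count-weighted global mean in attribute `"global"`.
#' @export
expected_pc <- function(config, between_shift = 0) {
  b <- config$between_mean + between_shift
  w <- config$within_mean
  if (w < 0 || b < 0)
    stop("expected PC undefined for negative block means")
  n <- config$nodes_per_network
  labs <- config_networks(config)
  pc <- numeric(length(n))
  for (m in seq_along(n)) {
    k_within <- (n[m] - 1) * w
    k_between <- n[-m] * b
    k <- k_within + sum(k_between)
    if (k <= 0) stop("expected nodal strength <= 0; PC undefined")
    pc[m] <- 1 - sum((c(k_within, k_between) / k)^2)
  }
  names(pc) <- labs
  attr(pc, "global") <- sum(pc * n) / sum(n)
  pc
}
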