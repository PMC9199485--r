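# one noisy block-model matrix; between-block means may be shifted
block_model_matrix <- function(config, partition, between_shift = 0,
                               subject_id = NULL, visit = NULL) {
  idx <- as.integer(partition)
  N <- length(idx)
  same <- outer(idx, idx, "==")
  M <- matrix(config$between_mean + between_shift, N, N)
  M[same] <- config$within_mean
  if (config$edge_sd > 0) {
    up <- upper.tri(M)
    noise <- rnorm(sum(up), 0, config$edge_sd)
    M[up] <- M[up] + noise
    M[lower.tri(M)] <- t(M)[lower.tri(M)]   # mirror upper triangle
  }
  M <- pmin(pmax(M, -1), 1)
  diag(M) <- 0
  dimnames(M) <- list(names(partition), names(partition))
  connectivity_matrix(M, subject_id = subject_id, visit = visit,
                      check_symmetry = FALSE)
}

#' Generate the connectome arm of a synthetic cohort
#'
#' Every subject gets one symmetric signed matrix per visit. Diagonal
#' (within-network) blocks have mean `within_mean`; off-diagonal blocks have
#' mean `between_mean`, except at the post visit of intervention subjects,
#' where each subject's own integration shift (drawn once per subject from
#' Normal(`integration_shift_mean`, `integration_shift_sd`)) is added,
#' planting a subject-varying increase in between-network coupling and hence
#' in PC. Edges get i.i.d. Gaussian noise per undirected pair, are mirrored,
#' clamped to \eqn{[-1, 1]}, and the diagonal is zero.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_cohort`: `matrices` (named
#'   `"<subject>.<visit>"`), `subjects` (subject_id, group), `partition`,
#'   `truth` (planted parameters: per-subject shifts, analytic expected PC
#'   per group-visit), `config`.
#' @export
generate_connectomes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "connectomes"))
  partition <- config_partition(config)
  n_tot <- config$n_intervention + config$n_control
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_tot)),
    group = rep(c("intervention", "control"),
                c(config$n_intervention, config$n_control)),
    stringsAsFactors = FALSE)
  shifts <- ifelse(subjects$group == "intervention",
                   rnorm(n_tot, config$integration_shift_mean,
                         config$integration_shift_sd),
                   0)
  matrices <- list()
  for (i in seq_len(n_tot)) {
    sid <- subjects$subject_id[i]
    matrices[[paste(sid, "baseline", sep = ".")]] <-
      block_model_matrix(config, partition, 0, sid, "baseline")
    matrices[[paste(sid, "post", sep = ".")]] <-
      block_model_matrix(config, partition, shifts[i], sid, "post")
  }
  truth <- list(
    shifts = setNames(shifts, subjects$subject_id),
    expected_pc_baseline = expected_pc(config),
    expected_pc_post_intervention =
      expected_pc(config, config$integration_shift_mean),
    transfer_coupling = config$transfer_coupling,
    trained_gain = config$trained_gain)
  structure(list(matrices = matrices, subjects = subjects,
                 partition = partition, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Participation-coefficient table for a cohort's matrices
#'
#' Rectifies each matrix and computes the global and per-network mean PC,
#' returning one row per subject-visit-scale.
#'
#' @param cohort A `synthetic_cohort`, or a named list of
#'   `connectivity_matrix` objects (names `"<subject>.<visit>"`) plus an
#'   explicit `partition` and `subjects` table.
#' @param partition,subjects Overrides when `cohort` is a bare list.
#' @return Data frame: `subject_id`, `group`, `visit`, `scale`, `pc`.
#' @export
cohort_pc_table <- function(cohort, partition = NULL, subjects = NULL) {
  if (inherits(cohort, "synthetic_cohort")) {
    matrices <- cohort$matrices
    partition <- cohort$partition
    subjects <- cohort$subjects
  } else matrices <- cohort
  keys <- strsplit(names(matrices), ".", fixed = TRUE)
  labs <- c(levels(partition), "global")
  vals <- matrix(NA_real_, length(matrices), length(labs))
  for (i in seq_along(matrices)) {
    nod <- participation_coefficient(rectify(matrices[[i]]), partition)
    vals[i, ] <- c(as.numeric(tapply(nod$pc, factor(nod$network,
                                                    levels = levels(partition)),
                                     mean)),
                   mean(nod$pc))
  }
  out <- data.frame(
    subject_id = rep(vapply(keys, `[`, "", 1L), each = length(labs)),
    visit = rep(vapply(keys, `[`, "", 2L), each = length(labs)),
    scale = rep(labs, times = length(matrices)),
    pc = as.numeric(t(vals)),
    stringsAsFactors = FALSE)
  out$group <- subjects$group[match(out$subject_id, subjects$subject_id)]
  out[, c("subject_id", "group", "visit", "scale", "pc")]
}

#' Generate behavioural outcomes coupled to connectome change
#'
#' Baseline scores are Gaussian per domain. Post-visit scores follow the
#' planted model: trained domain gains `trained_gain` in the intervention
#' group only; transfer domain gains `transfer_coupling` times the
#' subject's realised change in global PC, intervention group only; the
#' null domain changes by noise alone in both groups. Six motion-parameter
#' covariates (per visit), ADSCT and age are generated as inert covariates.
#'
#' @param cohort A `synthetic_cohort` from [generate_connectomes()].
#' @param config Defaults to `cohort$config`.
#' @return Long-format data frame (`subject_id`, `group`, `visit`,
#'   `domain`, `score`, covariates), with the subject-visit PC table in
#'   attribute `"pc"`.
#' @export
generate_behavior <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  subjects <- cohort$subjects
  expect_keys <- as.vector(outer(subjects$subject_id, c("baseline", "post"),
                                 paste, sep = "."))
  missing <- setdiff(expect_keys, names(cohort$matrices))
  if (length(missing))
    stop("missing matrix for subject-visit: ",
         paste(head(missing, 5L), collapse = ", "))
  pc <- cohort_pc_table(cohort)
  set.seed(derive_seed(config$seed, "behavior"))
  n <- nrow(subjects)
  gpc <- pc[pc$scale == "global", ]
  delta_pc <- gpc$pc[gpc$visit == "post"][match(subjects$subject_id,
                                                gpc$subject_id[gpc$visit == "post"])] -
    gpc$pc[gpc$visit == "baseline"][match(subjects$subject_id,
                                          gpc$subject_id[gpc$visit == "baseline"])]
  is_int <- subjects$group == "intervention"
  domains <- c(config$trained_domain, config$transfer_domain,
               config$null_domain)
  adsct <- rnorm(n, 2.77, 0.16)
  age <- round(rnorm(n, 74.7, 7.3))
  rows <- list()
  for (d in domains) {
    base <- rnorm(n, config$behavior_baseline_mean[[d]],
                  config$behavior_baseline_sd[[d]])
    post <- base +
      if (d == config$trained_domain) {
        config$trained_gain * is_int + rnorm(n, 0, config$behavior_noise_sd)
      } else if (d == config$transfer_domain) {
        config$transfer_coupling * delta_pc * is_int +
          rnorm(n, 0, config$behavior_noise_sd)
      } else {
        rnorm(n, 0, config$null_domain_sd)
      }
    rows[[paste(d, "baseline")]] <-
      data.frame(subject_id = subjects$subject_id, group = subjects$group,
                 visit = "baseline", domain = d, score = base,
                 stringsAsFactors = FALSE)
    rows[[paste(d, "post")]] <-
      data.frame(subject_id = subjects$subject_id, group = subjects$group,
                 visit = "post", domain = d, score = post,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # motion parameters vary by visit, demographics by subject
  sv <- unique(out[, c("subject_id", "visit")])
  motion <- matrix(rnorm(nrow(sv) * 6L, 0, 0.05), ncol = 6L,
                   dimnames = list(NULL, sprintf("motion%d", 1:6)))
  sv <- cbind(sv, motion)
  out <- merge(out, sv, by = c("subject_id", "visit"), sort = FALSE)
  out$adsct <- adsct[match(out$subject_id, subjects$subject_id)]
  out$age <- age[match(out$subject_id, subjects$subject_id)]
  out <- out[order(out$subject_id, out$domain, out$visit),
             c("subject_id", "group", "visit", "domain", "score",
               sprintf("motion%d", 1:6), "adsct", "age")]
  rownames(out) <- NULL
  attr(out, "pc") <- pc
  attr(out, "delta_pc_global") <- setNames(delta_pc, subjects$subject_id)
  out
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [generate_connectomes()] then [generate_behavior()].
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort` with `behavior` and `pc` elements filled in.
#' @export
generate_cohort <- function(config) {
  cohort <- generate_connectomes(config)
  cohort$behavior <- generate_behavior(cohort, config)
  cohort$pc <- attr(cohort$behavior, "pc")
  cohort
}

#' Simulate nodal time series with the cohort's block correlation structure
#'
#' Factor model: each node loads on its network's latent factor and on one
#' global factor, so population correlations are approximately
#' `within_mean` inside networks and `between_mean` across networks. Used to
#' exercise the FC-construction path end to end.
#'
#' @param config A [synthetic_config()] with nonnegative block means.
#' @param n_timepoints Series length T (default 200).
#' @param n_confounds Number of inert Gaussian confound regressors bundled
#'   with the panel (default 6, mimicking motion parameters).
#' @param seed Seed (defaults to the config seed).
#' @return A [time_series_panel()].
#' @export
generate_timeseries <- function(config, n_timepoints = 200L,
                                n_confounds = 6L, seed = config$seed) {
  if (config$between_mean < 0 || config$within_mean <= config$between_mean)
    stop("time-series mode needs within_mean > between_mean >= 0")
  if (config$within_mean >= 1) stop("within_mean must be < 1")
  set.seed(derive_seed(seed, "timeseries"))
  partition <- config_partition(config)
  N <- length(partition)
  lg <- sqrt(config$between_mean)
  ln <- sqrt(config$within_mean - config$between_mean)
  noise_sd <- sqrt(1 - config$within_mean)
  f_global <- rnorm(n_timepoints)
  f_net <- matrix(rnorm(n_timepoints * config$n_networks), n_timepoints)
  Y <- lg * f_global +
    f_net[, as.integer(partition), drop = FALSE] * ln +
    matrix(rnorm(n_timepoints * N, 0, noise_sd), n_timepoints)
  colnames(Y) <- names(partition)
  conf <- if (n_confounds > 0)
    matrix(rnorm(n_timepoints * n_confounds), n_timepoints,
           dimnames = list(NULL, sprintf("motion%d", seq_len(n_confounds))))
  time_series_panel(Y, conf)
}

#' Simulate data for a mediation scenario with known standardized paths
#'
#' Generates x, mediator m and outcome y with planted standardized paths:
#' `m = a x + e_m`, `y = c_prime x + b m + e_y`, residual variances chosen
#' so m and y have unit variance when the paths permit, making the planted
#' `a`, `b`, `c_prime` the true standardized coefficients and `a * b` the
#' true indirect effect.
#'
#' @param n Sample size.
#' @param paths Named vector `c(a, b, c_prime)`.
#' @param seed Optional seed.
#' @return Data frame with columns `x`, `m`, `y`.
#' @export
simulate_mediation_data <- function(n, paths = c(a = 0.4, b = 0.4,
                                                 c_prime = 0.2),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- paths[["a"]]; b <- paths[["b"]]; cp <- paths[["c_prime"]]
  if (a^2 >= 1) stop("path a must satisfy a^2 < 1 for unit-variance m")
  x <- rnorm(n)
  m <- a * x + rnorm(n, 0, sqrt(1 - a^2))
  vy <- cp^2 + b^2 + 2 * a * b * cp
  sd_ey <- if (vy < 1) sqrt(1 - vy) else 1
  y <- cp * x + b * m + rnorm(n, 0, sd_ey)
  data.frame(x = x, m = m, y = y)
}
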