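test_that("config validation catches malformed worlds", {
  expect_error(synthetic_config(nodes_per_network = rep(10L, 5)),
               "configuration error")
  expect_error(synthetic_config(n_intervention = 0), "positive")
  expect_error(synthetic_config(within_mean = 0.1, between_mean = 0.2),
               "within_mean > between_mean")
  expect_error(synthetic_config(edge_sd = -1), "edge_sd")
})

test_that("noise-free generator reproduces block means exactly", {
  cfg <- tiny_config(edge_sd = 0, integration_shift_mean = 0,
                     integration_shift_sd = 0, n_intervention = 2L,
                     n_control = 2L)
  coh <- generate_connectomes(cfg)
  m <- coh$matrices[[1L]]
  idx <- as.integer(coh$partition)
  same <- outer(idx, idx, "==")
  off <- !diag(nrow(m))
  expect_true(all(m[same & off] == cfg$within_mean))
  expect_true(all(m[!same] == cfg$between_mean))
  expect_true(all(diag(m) == 0))
  expect_equal(unname(unclass(m)), unname(t(unclass(m))))
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- tiny_config(seed = 77L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a$matrices, unclass), lapply(b$matrices, unclass))
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$pc, b$pc)
  c3 <- generate_cohort(tiny_config(seed = 78L))
  expect_false(identical(unclass(a$matrices[[1]]), unclass(c3$matrices[[1]])))
})

test_that("analytic expected PC: isolated modules, uniform limit, oracle", {
  cfg <- synthetic_config(between_mean = 0, within_mean = 0.5,
                          nodes_per_network = rep(10L, 7))
  expect_equal(as.numeric(expected_pc(cfg)), rep(0, 7))

  # within == between (via shift), equal sizes, M = 7, large n -> 1 - 1/7
  cfg_u <- synthetic_config(within_mean = 0.3, between_mean = 0.1,
                            nodes_per_network = rep(500L, 7))
  pc_u <- expected_pc(cfg_u, between_shift = 0.2)   # b becomes 0.3 = w
  expect_equal(as.numeric(pc_u), rep(1 - 1 / 7, 7), tolerance = 1e-3)

  # 3 networks of 10, within 0.5, between 0.2: brute force on the
  # noise-free matrix
  cfg3 <- synthetic_config(n_intervention = 1L, n_control = 1L,
                           n_networks = 3L, nodes_per_network = rep(10L, 3),
                           within_mean = 0.5, between_mean = 0.2,
                           edge_sd = 0, integration_shift_mean = 0,
                           integration_shift_sd = 0)
  coh3 <- generate_connectomes(cfg3)
  pc_emp <- brute_force_pc(coh3$matrices[[1L]], coh3$partition)
  per_net <- tapply(pc_emp, as.character(coh3$partition), unique)
  expect_equal(as.numeric(per_net[levels(coh3$partition)]),
               as.numeric(expected_pc(cfg3)), tolerance = 1e-10)

  # degenerate strengths are refused
  cfg_bad <- synthetic_config(n_networks = 3L,
                              nodes_per_network = rep(1L, 3),
                              within_mean = 0.5, between_mean = 0)
  expect_error(expected_pc(cfg_bad), "strength")
})

test_that("empirical network PC on noise-free matrices equals expected_pc", {
  cfg <- tiny_config(edge_sd = 0, integration_shift_mean = 0,
                     integration_shift_sd = 0, n_intervention = 2L,
                     n_control = 2L)
  coh <- generate_connectomes(cfg)
  nod <- participation_coefficient(rectify(coh$matrices[[1L]]),
                                   coh$partition)
  s <- summarize_pc(nod, coh$partition)
  ep <- expected_pc(cfg)
  expect_equal(s$mean_pc[match(names(ep), s$network)], as.numeric(ep),
               tolerance = 1e-6)
  expect_equal(s$mean_pc[s$network == "global"], attr(ep, "global"),
               tolerance = 1e-6)
})

test_that("integration shift monotonically raises intervention delta PC", {
  mean_dpc <- vapply(c(0, 0.01, 0.03), function(sh) {
    cfg <- tiny_config(edge_sd = 0, integration_shift_mean = sh,
                       integration_shift_sd = 0, n_intervention = 3L,
                       n_control = 2L)
    coh <- generate_connectomes(cfg)
    pc <- cohort_pc_table(coh)
    g <- pc[pc$scale == "global" & pc$group == "intervention", ]
    mean(g$pc[g$visit == "post"]) - mean(g$pc[g$visit == "baseline"])
  }, numeric(1))
  expect_equal(mean_dpc[1], 0, tolerance = 1e-12)
  expect_true(all(diff(mean_dpc) > 0))
})

test_that("behavioural coupling is planted in the intervention group only", {
  # noise-free behaviour: transfer change is exactly coupling * delta PC
  # for intervention subjects and exactly 0 for controls
  cfg <- tiny_config(behavior_noise_sd = 0, null_domain_sd = 0,
                     transfer_coupling = 5, trained_gain = 0.7)
  coh <- generate_cohort(cfg)
  d <- change_scores(coh$behavior)
  dpc <- attr(coh$behavior, "delta_pc_global")[d$subject_id]
  int <- d$group == "intervention"
  expect_equal(d$delta_working_memory[int], 5 * unname(dpc[int]),
               tolerance = 1e-10)
  expect_equal(d$delta_working_memory[!int], rep(0, sum(!int)),
               tolerance = 1e-10)
  expect_equal(d$delta_ufov[int], rep(0.7, sum(int)), tolerance = 1e-10)
  expect_equal(d$delta_episodic_memory, rep(0, nrow(d)), tolerance = 1e-10)
})

test_that("null transfer coupling leaves delta PC and transfer uncorrelated", {
  cfg <- tiny_config(transfer_coupling = 0, n_intervention = 60L,
                     n_control = 30L, nodes_per_network = rep(6L, 7),
                     seed = 9L)
  coh <- generate_cohort(cfg)
  d <- change_scores(coh$behavior)
  dpc <- attr(coh$behavior, "delta_pc_global")[d$subject_id]
  int <- d$group == "intervention"
  r <- cor(dpc[int], d$delta_working_memory[int])
  expect_lt(abs(r), 0.35)   # ~ N(0, 1/sqrt(58)) under the null
})

test_that("generate_behavior refuses a cohort with a missing matrix", {
  cfg <- tiny_config(n_intervention = 2L, n_control = 2L)
  coh <- generate_connectomes(cfg)
  coh$matrices[["S001.post"]] <- NULL
  expect_error(generate_behavior(coh), "missing matrix")
})

test_that("factor-model time series reproduce the block correlation structure", {
  cfg <- synthetic_config(n_networks = 3L, nodes_per_network = rep(15L, 3),
                          within_mean = 0.4, between_mean = 0.1,
                          seed = 21L)
  panel <- generate_timeseries(cfg, n_timepoints = 3000L)
  fc <- compute_fc(regress_confounds(panel))
  part <- netpc:::config_partition(cfg)
  idx <- as.integer(part)
  same <- outer(idx, idx, "==") & !diag(nrow(fc))
  expect_lt(abs(mean(fc[same]) - 0.4), 0.03)
  expect_lt(abs(mean(fc[!same & !diag(nrow(fc))]) - 0.1), 0.03)
})
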