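make_long <- function(n_i = 8, n_c = 4, effect = 0, seed = 1) {
  set.seed(seed)
  n <- n_i + n_c
  ids <- sprintf("S%02d", seq_len(n))
  group <- rep(c("intervention", "control"), c(n_i, n_c))
  base <- rnorm(n)
  post <- base + effect * (group == "intervention") + rnorm(n, 0, 0.5)
  data.frame(subject_id = rep(ids, 2), group = rep(group, 2),
             visit = rep(c("baseline", "post"), each = n),
             domain = "wm", score = c(base, post),
             stringsAsFactors = FALSE)
}

test_that("change_scores computes deltas and applies the complete-case rule", {
  d <- make_long()
  cs <- change_scores(d)
  # hand-computed delta for one subject
  s1 <- d[d$subject_id == "S01", ]
  expect_equal(cs$delta_wm[cs$subject_id == "S01"],
               s1$score[s1$visit == "post"] - s1$score[s1$visit == "baseline"])

  # post == baseline gives exactly zero
  d0 <- d; d0$score[d0$visit == "post"] <- d0$score[d0$visit == "baseline"]
  expect_true(all(change_scores(d0)$delta_wm == 0))

  # missing post drops the subject with a message
  d_miss <- d[!(d$subject_id == "S02" & d$visit == "post"), ]
  expect_message(cs_m <- change_scores(d_miss), "dropped")
  expect_false("S02" %in% cs_m$subject_id)
  expect_equal(nrow(cs_m), 11)

  expect_error(change_scores(rbind(d, d[1, ])), "duplicate")
})

test_that("interaction GLM: Wald identity, group coding, planted recovery", {
  set.seed(10)
  n <- 120
  group <- rep(c("intervention", "control"), c(80, 40))
  dpc <- rnorm(n, 0, 0.05)
  dy <- 2 + 1.5 * (group == "intervention") +
    10 * dpc * (group == "intervention") + rnorm(n, 0, 0.4)
  f <- fit_interaction_glm(dy, group, dpc, scale_label = "global")
  expect_identical(f$scale, "global")
  # Wald chi-square is (B/SE)^2 for every coefficient
  expect_equal(f$coefficients$wald_chi2,
               (f$coefficients$estimate / f$coefficients$se)^2,
               tolerance = 1e-8)
  # planted slope difference recovered within 3 SEs (99.7% band, so the
  # frozen-seed check is robust)
  B <- f$interaction$estimate; SE <- f$interaction$se
  expect_lt(abs(B - 10), 3 * SE)
  # control is the reference level: its simple slope is beta[delta_pc]
  ctrl_slope <- coef(lm(dy[group == "control"] ~ dpc[group == "control"]))[2]
  expect_equal(f$coefficients$estimate[f$coefficients$term == "delta_pc"],
               unname(ctrl_slope), tolerance = 1e-8)
})

test_that("without the PC term the GLM reduces to the pooled-variance t", {
  set.seed(11)
  group <- rep(c("intervention", "control"), c(30, 20))
  dy <- rnorm(50) + 0.8 * (group == "intervention")
  f <- fit_interaction_glm(dy, group)
  tt <- two_sample_t(x = dy[group == "intervention"],
                     y = dy[group == "control"])
  grp <- f$coefficients[f$coefficients$term == "group", ]
  expect_equal(grp$estimate,
               mean(dy[group == "intervention"]) -
                 mean(dy[group == "control"]), tolerance = 1e-10)
  expect_equal(grp$estimate / grp$se, tt$statistic, tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly, naming aliased columns", {
  set.seed(12)
  group <- rep(c("intervention", "control"), each = 10)
  dpc <- rnorm(20)
  cov <- data.frame(dup = dpc)   # perfectly collinear with delta_pc
  expect_error(fit_interaction_glm(rnorm(20), group, dpc, covariates = cov),
               "rank deficient")
})

test_that("pure-noise covariates barely move the interaction estimate", {
  set.seed(13)
  n <- 400
  group <- rep(c("intervention", "control"), c(267, 133))
  dpc <- rnorm(n, 0, 0.05)
  dy <- 5 * dpc * (group == "intervention") + rnorm(n, 0, 0.3)
  noise_cov <- as.data.frame(matrix(rnorm(n * 6), n,
                                    dimnames = list(NULL,
                                                    paste0("m", 1:6))))
  plain <- fit_interaction_glm(dy, group, dpc)
  with_cov <- fit_interaction_glm(dy, group, dpc, covariates = noise_cov)
  expect_lt(abs(plain$interaction$estimate - with_cov$interaction$estimate),
            0.5)   # o(1) shift relative to B = 5
})

test_that("BH adjustment reproduces printed pairs and the step-up oracle", {
  # seven-network family with the printed raw p-values among fillers
  fam_a <- c(0.002, 0.017, 0.023, 0.028, 0.3, 0.4, 0.5)
  adj_a <- bh_adjust(fam_a)
  expect_equal(adj_a[1], 0.014, tolerance = 1e-12)
  expect_equal(adj_a[4], 0.049, tolerance = 1e-12)
  fam_b <- c(0.001, 0.003, 0.016, 0.3, 0.4, 0.5, 0.6)
  expect_equal(bh_adjust(fam_b)[1], 0.007, tolerance = 1e-12)

  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.4)), "\\[0, 1\\]")

  set.seed(14)
  for (i in 1:200) {
    p <- runif(sample(3:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_force_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
    # also agrees with the reference implementation
    expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("per-group correlations: direction, tails and sign symmetry", {
  set.seed(15)
  group <- rep(c("intervention", "control"), each = 20)
  dpc <- rnorm(40)
  dy <- dpc                       # perfectly collinear, positive
  res <- group_correlations(dpc, dy, group)
  expect_equal(res$r, c(1, 1), tolerance = 1e-10)
  expect_true(all(res$p < 1e-10))

  dy2 <- dpc + rnorm(40, 0, 1)
  p_pos <- group_correlations(dpc, dy2, group)$p
  p_neg <- group_correlations(dpc, -dy2, group)$p
  expect_equal(p_pos + p_neg, c(1, 1), tolerance = 1e-10)

  expect_error(group_correlations(dpc, rep(1, 40), group), "zero variance")
  expect_error(group_correlations(dpc[1:5], dy[1:5],
                                  c("intervention", "intervention",
                                    "intervention", "control", "control")),
               ">= 3")
})

test_that("interaction_scan adjusts across the network family only", {
  cfg <- tiny_config(seed = 30L)
  coh <- generate_cohort(cfg)
  d_beh <- change_scores(coh$behavior)
  d_pc <- change_scores(coh$pc, var_col = "scale", value_col = "pc")
  names(d_pc) <- sub("^delta_", "delta_pc_", names(d_pc))
  deltas <- merge(d_beh, d_pc[, c("subject_id",
                                  grep("^delta_pc_", names(d_pc),
                                       value = TRUE))], by = "subject_id")
  scales <- c("global", yeo7_labels())
  scan <- interaction_scan(deltas, "working_memory", scales)
  expect_equal(nrow(scan), 8)
  expect_true(is.na(scan$p_fdr[scan$scale == "global"]))
  net <- scan[scan$scale != "global", ]
  expect_equal(net$p_fdr, bh_adjust(net$p_raw), tolerance = 1e-12)
  expect_true(all(net$p_fdr >= net$p_raw - 1e-12))
})

test_that("GEE: AR(1) equals exchangeable on two visits and matches OLS", {
  cfg <- tiny_config(seed = 31L, n_intervention = 12L, n_control = 6L)
  coh <- generate_cohort(cfg)
  pc <- coh$pc[coh$pc$scale == "global", ]
  g_ar <- fit_gee(pc, corstr = "ar1")
  g_ex <- fit_gee(pc, corstr = "exchangeable")
  expect_equal(g_ar$coefficients$estimate, g_ex$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(g_ar$coefficients$robust_se, g_ex$coefficients$robust_se,
               tolerance = 1e-6)

  # balanced two-visit data: GEE point estimates equal OLS cell-mean fits
  ols <- lm(pc ~ I(visit == "post") * I(group == "intervention"), data = pc)
  expect_equal(g_ar$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("GEE recovers a planted visit-by-group PC shift", {
  set.seed(32)
  n_i <- 60; n_c <- 30; delta <- 0.05
  ids <- sprintf("S%03d", seq_len(n_i + n_c))
  group <- rep(c("intervention", "control"), c(n_i, n_c))
  subj_int <- rnorm(n_i + n_c, 0.5, 0.03)   # subject-level random intercept
  long <- do.call(rbind, lapply(c("baseline", "post"), function(v)
    data.frame(subject_id = ids, group = group, visit = v,
               pc = subj_int + delta * (v == "post") *
                 (group == "intervention") + rnorm(n_i + n_c, 0, 0.01),
               stringsAsFactors = FALSE)))
  g <- fit_gee(long)
  inter <- g$coefficients[g$coefficients$term == "visit:group", ]
  expect_lt(abs(inter$estimate - delta), 1.96 * inter$robust_se)
  expect_gt(g$alpha, 0.5)   # strong within-subject correlation detected
  expect_error(fit_gee(long[long$visit == "baseline", ]), "2 visits")
})
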