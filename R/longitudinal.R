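#' Per-subject change scores from a long two-visit table
#'
#' Computes post minus baseline per subject for every variable in a long
#' table. Subjects missing either visit for a variable are dropped for that
#' variable (complete-case rule) and the exclusion count is reported via a
#' message and recorded as an attribute.
#'
#' @param records Long data frame with columns `subject_id`, `group`,
#'   `visit` (`"baseline"` / `"post"`) and the variable/value columns named
#'   by `var_col` / `value_col`.
#' @param var_col,value_col Names of the variable and value columns
#'   (defaults `"domain"` / `"score"`; use `"scale"` / `"pc"` for PC
#'   tables).
#' @return Wide data frame: `subject_id`, `group`, one `delta_<variable>`
#'   column per variable; attribute `n_dropped` (per variable).
#' @export
change_scores <- function(records, var_col = "domain", value_col = "score") {
  req <- c("subject_id", "group", "visit", var_col, value_col)
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(records[, c("subject_id", "visit", var_col)]))
    stop("duplicate subject-visit records")
  vars <- unique(records[[var_col]])
  subj <- unique(records[, c("subject_id", "group")])
  if (anyDuplicated(subj$subject_id))
    stop("group must be constant within subject")
  out <- subj
  dropped <- integer(0)
  for (v in vars) {
    r <- records[records[[var_col]] == v, ]
    base <- r[[value_col]][r$visit == "baseline"][
      match(subj$subject_id, r$subject_id[r$visit == "baseline"])]
    post <- r[[value_col]][r$visit == "post"][
      match(subj$subject_id, r$subject_id[r$visit == "post"])]
    out[[paste0("delta_", v)]] <- post - base
    dropped[v] <- sum(is.na(post - base))
  }
  keep <- complete.cases(out)
  if (any(!keep))
    message(sum(!keep), " subject(s) dropped for missing visits")
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Change-score interaction model for one scale
#'
#' Fits the Gaussian identity-link least-squares model
#' `delta_cognition ~ group + delta_pc + delta_pc:group (+ covariates)`,
#' with the control group as reference (group coded 0/1), so the
#' interaction coefficient B measures how much more strongly cognitive
#' change tracks PC change under the intervention. Each coefficient gets a
#' 1-df Wald chi-square `(B/SE)^2` with its asymptotic p-value. Per-group
#' Pearson correlations between `delta_pc` and `delta_cognition` (one-tailed
#' for positive association by default) accompany the fit.
#'
#' @param delta_cognition Numeric change scores.
#' @param group `"intervention"` / `"control"` per subject.
#' @param delta_pc Numeric PC change scores; `NULL` drops the PC and
#'   interaction terms, reducing the model to a group comparison of change
#'   scores (the group coefficient then matches the pooled-variance t
#'   estimate).
#' @param covariates Optional data frame / matrix of additional regressors.
#' @param scale_label Label for the PC scale (e.g. `"global"`).
#' @param alternative Direction for the per-group correlation tests.
#' @return List of class `interaction_result`: `scale`, `coefficients`
#'   (term, estimate, se, wald_chi2, p), `interaction` (the `delta_pc:group`
#'   row), `correlations` (per-group r and one-tailed p), `n`.
#' @export
fit_interaction_glm <- function(delta_cognition, group, delta_pc = NULL,
                                covariates = NULL, scale_label = "global",
                                alternative = "greater") {
  g <- as.integer(factor(group, levels = c("control", "intervention"))) - 1L
  if (anyNA(g)) stop("group must be 'intervention' or 'control'")
  if (min(table(g)) < 2L) stop("need >= 2 subjects per group")
  X <- data.frame(delta_cognition = delta_cognition, group = g)
  terms <- "group"
  if (!is.null(delta_pc)) {
    X$delta_pc <- delta_pc
    terms <- c(terms, "delta_pc", "group:delta_pc")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    X <- cbind(X, covariates)
    terms <- c(terms, names(covariates))
  }
  form <- stats::reformulate(terms, response = "delta_cognition")
  fit <- lm(form, data = X)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  wald <- (sm[, "Estimate"] / sm[, "Std. Error"])^2
  tab <- data.frame(term = rownames(sm),
                    estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"],
                    wald_chi2 = wald,
                    p = pchisq(wald, df = 1L, lower.tail = FALSE),
                    row.names = NULL, stringsAsFactors = FALSE)
  inter <- tab[tab$term == "group:delta_pc", ]
  cors <- if (!is.null(delta_pc))
    group_correlations(delta_pc, delta_cognition, group,
                       alternative = alternative)
  structure(list(scale = scale_label, coefficients = tab,
                 interaction = inter, correlations = cors,
                 n = length(delta_cognition), fit = fit),
            class = "interaction_result")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted values are `min over j >= i of m * p_(j) / j` after sorting,
#' capped at 1 and returned in the original order — the step-up procedure
#' controlling the false discovery rate across the test family (here,
#' typically the seven network-level tests for one cognitive domain).
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and length.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  ranked <- pvals[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))       # enforce step-up monotonicity
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Per-group Pearson correlations with directional tests
#'
#' @param delta_pc,delta_cognition Paired change scores.
#' @param group `"intervention"` / `"control"` per subject.
#' @param alternative `"greater"` (one-tailed, positive association;
#'   default), `"less"`, or `"two.sided"`.
#' @return Data frame: `group`, `r`, `p`, `n`.
#' @export
group_correlations <- function(delta_pc, delta_cognition, group,
                               alternative = "greater") {
  out <- lapply(c("intervention", "control"), function(gr) {
    i <- group == gr
    if (sum(i) < 3L) stop("need >= 3 subjects per group for correlation")
    if (sd(delta_pc[i]) == 0 || sd(delta_cognition[i]) == 0)
      stop("zero variance in group ", gr)
    ct <- cor.test(delta_pc[i], delta_cognition[i],
                   alternative = alternative)
    data.frame(group = gr, r = unname(ct$estimate), p = ct$p.value,
               n = sum(i), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Interaction models across all PC scales for one cognitive domain
#'
#' Fits [fit_interaction_glm()] for the global scale and each network
#' scale, then BH-adjusts the interaction p-values across the network
#' family only (the global test is reported unadjusted, mirroring the
#' convention of reporting global results outside the 7-network family).
#'
#' @param deltas Wide change-score table from [change_scores()] containing
#'   `delta_<domain>` and `delta_pc_<scale>` columns plus `group`.
#' @param domain Cognitive domain name.
#' @param scales Character vector of PC scale names; must include
#'   `"global"`.
#' @param covariates Optional covariate column names in `deltas`.
#' @param alternative Direction for per-group correlations.
#' @return Data frame of class `interaction_scan`: one row per scale with
#'   `scale`, `estimate`, `se`, `wald_chi2`, `p_raw`, `p_fdr` (NA for
#'   global), plus the per-fit results in attribute `"fits"`.
#' @export
interaction_scan <- function(deltas, domain, scales, covariates = NULL,
                             alternative = "greater") {
  ycol <- paste0("delta_", domain)
  if (!ycol %in% names(deltas)) stop("no change scores for domain ", domain)
  fits <- lapply(scales, function(s) {
    pcol <- paste0("delta_pc_", s)
    if (!pcol %in% names(deltas)) stop("no PC change scores for scale ", s)
    cv <- if (!is.null(covariates)) deltas[, covariates, drop = FALSE]
    fit_interaction_glm(deltas[[ycol]], deltas$group, deltas[[pcol]],
                        covariates = cv, scale_label = s,
                        alternative = alternative)
  })
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(scale = f$scale, estimate = f$interaction$estimate,
               se = f$interaction$se, wald_chi2 = f$interaction$wald_chi2,
               p_raw = f$interaction$p, stringsAsFactors = FALSE)))
  tab$p_fdr <- NA_real_
  net <- tab$scale != "global"
  tab$p_fdr[net] <- bh_adjust(tab$p_raw[net])
  attr(tab, "fits") <- fits
  attr(tab, "domain") <- domain
  class(tab) <- c("interaction_scan", class(tab))
  tab
}
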