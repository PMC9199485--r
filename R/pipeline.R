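#' Assemble a pipeline run configuration
#'
#' Merges defaults, an optional YAML config file, and explicit overrides
#' (overrides win). Two input modes exist: `"simulate"` (the synthetic
#' cohort generator supplies matrices and behaviour) and `"from-files"`
#' (matrices, partition and behaviour are read from disk).
#'
#' @param path Optional YAML file with any subset of the fields.
#' @param ... Named overrides: `mode`, `seed`, `out_dir`, and the nested
#'   lists `synthetic` (arguments to [synthetic_config()]), `paths`
#'   (`matrices_dir`, `partition`, `behavior`), `analysis` (`sem_mode`,
#'   `reliability`, `covariate_bundle` in `"none"`, `"motion6"`, `"adsct"`,
#'   `tails`, `n_boot`, `mediation_scale`, `mediation_group`,
#'   `high_pc_fraction`, `invert_domains`).
#' @return List of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    mode = "simulate",
    seed = 1L,
    out_dir = NULL,
    synthetic = list(),
    paths = list(matrices_dir = NULL, partition = NULL, behavior = NULL),
    analysis = list(sem_mode = "mean", reliability = NULL,
                    covariate_bundle = "none", tails = "greater",
                    n_boot = 5000L, mediation_scale = "global",
                    mediation_group = "intervention",
                    high_pc_fraction = 0.20,
                    invert_domains = character()))
  cfg <- defaults
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg <- merge_config(cfg, list(...))
  if (!cfg$mode %in% c("simulate", "from-files"))
    stop("mode must be 'simulate' or 'from-files'")
  if (cfg$mode == "from-files") {
    for (p in c("matrices_dir", "partition", "behavior")) {
      if (is.null(cfg$paths[[p]]) || !file.exists(cfg$paths[[p]]))
        stop("from-files mode requires existing path for ", p)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

# load matrices/partition/behavior in from-files mode
load_inputs <- function(cfg) {
  partition <- read_partition(cfg$paths$partition)
  files <- sort(list.files(cfg$paths$matrices_dir, pattern = "\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("no .tsv matrices in ", cfg$paths$matrices_dir)
  keys <- sub("\\.tsv$", "", basename(files))
  matrices <- setNames(lapply(seq_along(files), function(i) {
    key <- strsplit(keys[i], ".", fixed = TRUE)[[1L]]
    read_matrix(files[i], subject_id = key[1L], visit = key[2L])
  }), keys)
  behavior <- read_behavior(cfg$paths$behavior,
                            invert_domains = cfg$analysis$invert_domains)
  subjects <- unique(behavior[, c("subject_id", "group")])
  list(matrices = matrices, partition = partition, behavior = behavior,
       subjects = subjects)
}

run_stage <- function(name, expr, log) {
  log(sprintf("stage %s: start", name))
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: cohort input (simulate or load), baseline
#' density profiling, PC computation and summarisation, high-PC node
#' report, reliable-improvement outcomes, change-score interaction models
#' with BH adjustment across networks, visit-by-group GEE per scale, and
#' mediation of the transfer effect through PC change. All stages derive
#' their randomness from the root seed, so identical configs give
#' identical reports; artifacts (CSV/JSON per stage plus a combined
#' report and a log) are written under `out_dir` when set.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_report` with elements `density`, `pc`,
#'   `high_pc`, `outcomes`, `models`, `gee`, `mediation`, `log`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  log(sprintf("mode=%s seed=%d", config$mode, config$seed))

  inputs <- run_stage("input", {
    if (config$mode == "simulate") {
      syn <- do.call(synthetic_config,
                     c(config$synthetic, list(seed = config$seed)))
      cohort <- generate_cohort(syn)
      log(sprintf("simulated cohort: %d intervention + %d control subjects",
                  syn$n_intervention, syn$n_control))
      list(matrices = cohort$matrices, partition = cohort$partition,
           behavior = cohort$behavior, subjects = cohort$subjects,
           pc = cohort$pc, truth = cohort$truth)
    } else {
      log("loading matrices, partition and behavior from files")
      load_inputs(config)
    }
  }, log)

  density <- run_stage("density", {
    base_keys <- grep("\\.baseline$", names(inputs$matrices), value = TRUE)
    reports <- lapply(inputs$matrices[base_keys], fc_density,
                      partition = inputs$partition)
    blocks <- Reduce(`+`, lapply(reports, `[[`, "blocks")) / length(reports)
    list(global = mean(vapply(reports, `[[`, numeric(1), "global")),
         blocks = blocks)
  }, log)
  log(sprintf("mean baseline density: global %.3f", density$global))

  pc <- run_stage("pc", {
    if (!is.null(inputs$pc)) inputs$pc
    else cohort_pc_table(inputs$matrices, inputs$partition, inputs$subjects)
  }, log)

  high_pc <- run_stage("high_pc", {
    base_keys <- grep("\\.baseline$", names(inputs$matrices), value = TRUE)
    # group-mean baseline matrix, as in baseline hub characterisation
    mean_mat <- Reduce(`+`, inputs$matrices[base_keys]) / length(base_keys)
    mean_mat <- connectivity_matrix(mean_mat,
                                    node_ids = rownames(inputs$matrices[[1L]]),
                                    check_symmetry = FALSE)
    nod <- participation_coefficient(rectify(mean_mat), inputs$partition)
    high_pc_nodes(nod, fraction = config$analysis$high_pc_fraction)
  }, log)

  domains <- setdiff(unique(inputs$behavior$domain), NA)
  scales <- unique(pc$scale)
  scales <- c("global", setdiff(scales, "global"))

  outcomes <- run_stage("outcomes", {
    res <- lapply(domains, function(d) {
      b <- inputs$behavior[inputs$behavior$domain == d, ]
      wide <- change_scores(b)
      base <- b$score[b$visit == "baseline"][
        match(wide$subject_id, b$subject_id[b$visit == "baseline"])]
      post <- base + wide[[paste0("delta_", d)]]
      compare_reliable_improvement(base, post, wide$group,
                                   sem_mode = config$analysis$sem_mode,
                                   reliability = config$analysis$reliability)
    })
    names(res) <- domains
    res
  }, log)

  deltas <- run_stage("deltas", {
    d_beh <- change_scores(inputs$behavior)
    d_pc <- change_scores(pc, var_col = "scale", value_col = "pc")
    names(d_pc) <- sub("^delta_", "delta_pc_", names(d_pc))
    d <- merge(d_beh, d_pc[, c("subject_id",
                               grep("^delta_pc_", names(d_pc), value = TRUE))],
               by = "subject_id")
    if (config$analysis$covariate_bundle == "motion6") {
      mv <- unique(inputs$behavior[, c("subject_id", "visit",
                                       sprintf("motion%d", 1:6))])
      long_m <- stats::reshape(mv, direction = "long",
                               varying = sprintf("motion%d", 1:6),
                               v.names = "value", timevar = "param",
                               times = sprintf("motion%d", 1:6))
      long_m$group <- "x"; long_m$subject_id <- long_m$subject_id
      dm <- change_scores(
        data.frame(subject_id = long_m$subject_id, group = "x",
                   visit = long_m$visit, domain = long_m$param,
                   score = long_m$value, stringsAsFactors = FALSE))
      d <- merge(d, dm[, c("subject_id",
                           grep("^delta_motion", names(dm), value = TRUE))],
                 by = "subject_id")
    } else if (config$analysis$covariate_bundle == "adsct") {
      ad <- unique(inputs$behavior[, c("subject_id", "adsct")])
      d <- merge(d, ad, by = "subject_id")
    }
    d
  }, log)

  covars <- switch(config$analysis$covariate_bundle,
                   motion6 = grep("^delta_motion", names(deltas), value = TRUE),
                   adsct = "adsct",
                   NULL)

  models <- run_stage("models", {
    res <- lapply(domains, function(d)
      interaction_scan(deltas, d, scales, covariates = covars,
                       alternative = config$analysis$tails))
    names(res) <- domains
    res
  }, log)

  gee <- run_stage("gee", {
    res <- lapply(scales, function(s)
      fit_gee(pc[pc$scale == s, ], corstr = "ar1"))
    names(res) <- scales
    res
  }, log)

  mediation <- run_stage("mediation", {
    trained <- domains[1L]; transfer <- domains[2L]
    syn_defaults <- if (config$mode == "simulate")
      do.call(synthetic_config, c(config$synthetic, list(seed = config$seed)))
    if (!is.null(syn_defaults)) {
      trained <- syn_defaults$trained_domain
      transfer <- syn_defaults$transfer_domain
    }
    d <- deltas
    if (config$analysis$mediation_group == "intervention")
      d <- d[d$group == "intervention", ]
    fit_mediation(d[[paste0("delta_", trained)]],
                  d[[paste0("delta_pc_", config$analysis$mediation_scale)]],
                  d[[paste0("delta_", transfer)]],
                  n_boot = config$analysis$n_boot,
                  seed = derive_seed(config$seed, "mediation"))
  }, log)

  log("pipeline complete")
  report <- structure(list(density = density, pc = pc, high_pc = high_pc,
                           outcomes = outcomes, models = models, gee = gee,
                           mediation = mediation, log = log_lines,
                           config = config),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# serialise per-stage artifacts and the combined JSON report
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$pc, file.path(out_dir, "pc.csv"), row.names = FALSE)
  models_tab <- do.call(rbind, lapply(names(report$models), function(d) {
    t <- as.data.frame(report$models[[d]])
    cbind(domain = d, t)
  }))
  write.csv(models_tab, file.path(out_dir, "models.csv"), row.names = FALSE)
  gee_tab <- do.call(rbind, lapply(names(report$gee), function(s)
    cbind(scale = s, report$gee[[s]]$coefficients)))
  write.csv(gee_tab, file.path(out_dir, "gee.csv"), row.names = FALSE)
  json <- report_json(report)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(report$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

# reduced machine-readable form of the report
report_json <- function(report) {
  list(
    density = list(global = report$density$global,
                   blocks = report$density$blocks),
    high_pc = list(n_selected = report$high_pc$n_selected,
                   composition = as.list(report$high_pc$composition)),
    outcomes = lapply(report$outcomes, function(o)
      list(proportions = as.list(o$proportions),
           chi_square = o$chi_square$statistic,
           p = o$chi_square$p.value, hedges_g = o$hedges_g,
           sem_mode = o$sem_mode)),
    models = lapply(report$models, function(t)
      as.data.frame(t[, c("scale", "estimate", "se", "wald_chi2",
                          "p_raw", "p_fdr")])),
    gee = lapply(report$gee, function(g) g$coefficients),
    mediation = report$mediation[c("a", "b", "c", "c_prime", "indirect",
                                   "ci_lower", "ci_upper", "significant",
                                   "n_boot", "n", "method")],
    seed = report$config$seed)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("netpc pipeline report\n")
  cat(sprintf("  baseline density (global): %.3f\n", x$density$global))
  cat(sprintf("  scales: %s\n",
              paste(unique(x$pc$scale), collapse = ", ")))
  for (d in names(x$models)) {
    t <- x$models[[d]]
    best <- t[which.min(t$p_raw), ]
    cat(sprintf("  %s: strongest interaction at %s (B = %.3f, raw p = %.4f)\n",
                d, best$scale, best$estimate, best$p_raw))
  }
  cat(sprintf("  mediation indirect effect %.4f, %d%% CI [%.4f, %.4f]\n",
              x$mediation$indirect, round(100 * x$mediation$ci),
              x$mediation$ci_lower, x$mediation$ci_upper))
  invisible(x)
}
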