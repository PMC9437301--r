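#' Default pipeline configuration
#'
#' A complete, valid configuration for the simulate-mode pipeline: the
#' synthetic cohort parameters, every stage parameter with its default, a
#' global seed that fans out to fixed per-stage seeds, and the output
#' directory.
#'
#' @param outdir Output directory for the run artifacts.
#' @param seed Global non-negative integer seed.
#' @param ... Overrides for [sim_config()] fields.
#' @return A named list of class `"pipeline_config"`.
#' @export
default_pipeline_config <- function(outdir = tempfile("cuproscore_run_"),
                                    seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = unclass(sim_config(seed = as.integer(seed), ...)),
    inputs = NULL,                 # list(expression=, clinical=, genesets=) when simulate off
    cluster = list(kmax = 3L, reps = 50L, subsample = 0.8, policy = "min_pac",
                   fixed_k = 2L),
    deg = list(lfc_thresh = 1.0, p_thresh = 0.05, use_adjusted = FALSE),
    cutpoint = list(minprop = 0.1),
    boruta = list(alpha = 0.01, max_iter = 50L, keep_tentative = TRUE),
    ridge = list(lambda_grid = 10^(-2:4), folds = 5L),
    stages = list(correct = TRUE, cluster1 = TRUE, enrich = TRUE,
                  deg = TRUE, cox_screen = TRUE, cluster2 = TRUE,
                  score = TRUE, survival = TRUE, drugresp = TRUE)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks without executing anything. Accepts a
#' config list or the path of a YAML file with the same structure.
#'
#' @param config A `"pipeline_config"`, a plain list, or a YAML file path.
#' @return `list(valid, errors)` of class `"config_report"`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("unreadable config file: ", config)
    config <- yaml::read_yaml(config)
  }
  errors <- character(0L)
  err <- function(msg) errors <<- c(errors, msg)
  if (is.null(config$seed) || is.na(config$seed) || config$seed < 0 ||
      config$seed != round(config$seed)) {
    err("seed must be a non-negative integer")
  }
  cl <- config$cluster
  if (!is.null(cl)) {
    if (!is.null(cl$subsample) && (cl$subsample <= 0 || cl$subsample > 1)) {
      err("cluster$subsample must be in (0, 1] (consensus stage bound)")
    }
    if (!is.null(cl$reps) && cl$reps < 1) err("cluster$reps must be >= 1")
    if (!is.null(cl$kmax) && cl$kmax < 2) err("cluster$kmax must be >= 2")
    if (!is.null(cl$policy) && !cl$policy %in% c("min_pac", "fixed")) {
      err("cluster$policy must be 'min_pac' or 'fixed'")
    }
  }
  dg <- config$deg
  if (!is.null(dg)) {
    if (!is.null(dg$lfc_thresh) && dg$lfc_thresh <= 0) err("deg$lfc_thresh must be > 0")
    if (!is.null(dg$p_thresh) && (dg$p_thresh <= 0 || dg$p_thresh >= 1)) {
      err("deg$p_thresh must be in (0, 1)")
    }
  }
  if (!is.null(config$cutpoint$minprop) &&
      (config$cutpoint$minprop <= 0 || config$cutpoint$minprop >= 0.5)) {
    err("cutpoint$minprop must be in (0, 0.5)")
  }
  if (!is.null(config$boruta$max_iter) && config$boruta$max_iter < 10) {
    err("boruta$max_iter must be >= 10")
  }
  if (is.null(config$simulate)) {
    ins <- config$inputs
    need <- c("expression", "clinical", "genesets")
    missing_f <- need[!vapply(need, function(k) {
      !is.null(ins[[k]]) && file.exists(ins[[k]])
    }, logical(1L))]
    if (length(missing_f)) {
      err(paste0("simulate is off and input path(s) missing: ",
                 paste(missing_f, collapse = ", ")))
    } else {
      cl_tab <- utils::read.delim(ins$clinical, nrows = 1L)
      surv_on <- isTRUE(config$stages$survival) || isTRUE(config$stages$cox_screen)
      miss_col <- setdiff(c("sample", if (surv_on) c("time", "event")),
                          names(cl_tab))
      if (length(miss_col)) {
        err(paste0("clinical table missing column(s): ",
                   paste(miss_col, collapse = ", ")))
      }
    }
  }
  out <- list(valid = !length(errors), errors = errors)
  class(out) <- "config_report"
  out
}

#' @export
print.config_report <- function(x, ...) {
  if (x$valid) cat("configuration valid\n") else {
    cat("configuration INVALID:\n")
    for (e in x$errors) cat("  -", e, "\n")
  }
  invisible(x)
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 0L, correct = 101L, cluster1 = 202L, enrich = 303L,
               deg = 404L, cox_screen = 505L, cluster2 = 606L, score = 707L,
               survival = 808L, drugresp = 909L)
  config$seed + unname(offsets[stage])
}

pipeline_write <- function(obj, path) {
  if (is.matrix(obj)) {
    utils::write.table(data.frame(id = rownames(obj), obj, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  path
}

#' Run the full subtype-and-score pipeline
#'
#' Executes the enabled stages in order: simulate (or load inputs), batch
#' correction, first consensus clustering on the program genes, immune
#' landscape scoring, differential expression between the program subtypes,
#' prognostic Cox screening of the DEGs, secondary consensus clustering on
#' the screened genes, signature sign-split + Boruta + PC1 scoring into the
#' per-sample CUS with a survival-optimal cutoff, survival and immune
#' comparisons of the high/low groups, and ridge drug-sensitivity
#' imputation from the reference panel. Every intermediate artifact is
#' written under `config$outdir` and listed, with MD5 checksums and
#' per-stage wall-clock, in `manifest.json`.
#'
#' @param config A configuration from [default_pipeline_config()] (or a
#'   YAML path / compatible list).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  report <- validate_config(config)
  if (!report$valid) {
    stop("invalid configuration:\n  ", paste(report$errors, collapse = "\n  "))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0L)
  timings <- list()
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  keep <- function(path) { artifacts <<- c(artifacts, path); path }

  ## --- inputs ---------------------------------------------------------
  sim_mode <- !is.null(config$simulate)
  if (sim_mode) {
    scfg <- do.call(sim_config, config$simulate)
    sim <- run_stage("simulate", function() simulate_cohort(scfg))
    expr <- sim$expr
    clinical <- sim$clinical
    program_genes <- sim$truth$program_genes
    immune_sets <- sim_immune_gmt(sim$truth)
    truth <- sim$truth
  } else {
    expr <- read_expression(config$inputs$expression)
    clinical <- utils::read.delim(config$inputs$clinical,
                                  stringsAsFactors = FALSE)
    gs <- read_gmt(config$inputs$genesets)
    if (!"program" %in% names(gs)) stop("genesets GMT must contain a 'program' set")
    program_genes <- intersect(gs$program, rownames(expr))
    immune_sets <- gs[grep("^immune", names(gs))]
    truth <- NULL
  }
  keep(pipeline_write(clinical, file.path(config$outdir, "clinical.tsv")))

  ## --- batch correction ----------------------------------------------
  if (isTRUE(config$stages$correct) && length(unique(clinical$batch)) > 1L) {
    adj <- run_stage("correct", function() {
      combat_adjust(expr[, clinical$sample, drop = FALSE], clinical$batch)
    })
    expr <- adj$corrected
    sev <- batch_severity(expr, clinical$batch)
    jsonlite::write_json(unclass(sev),
                         keep(file.path(config$outdir, "batch_severity.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  keep(write_expression(expr, file.path(config$outdir, "expression_corrected.tsv")))

  ## --- first clustering (program genes) -------------------------------
  cons1 <- run_stage("cluster1", function() {
    consensus_cluster(expr, genes = program_genes,
                      kmax = config$cluster$kmax, reps = config$cluster$reps,
                      subsample = config$cluster$subsample,
                      seed = stage_seed(config, "cluster1"))
  })
  k1 <- if (config$cluster$policy == "fixed") {
    choose_k(cons1, "fixed", k = config$cluster$fixed_k)
  } else cons1$chosen_k
  cl1 <- consensus_assignment(cons1, k1)
  # orient labels: cluster "B" = lower program-gene mean (suppressed program)
  if (k1 == 2L) {
    pm <- colMeans(expr[program_genes, , drop = FALSE])
    means <- tapply(pm[names(cl1)], cl1, mean)
    b_id <- as.integer(names(means)[which.min(means)])
    subtype1 <- ifelse(cl1 == b_id, "B", "A")
  } else {
    subtype1 <- paste0("C", cl1)
  }
  names(subtype1) <- names(cl1)
  keep(pipeline_write(data.frame(sample = names(subtype1), cluster = subtype1),
                      file.path(config$outdir, "cluster1_assignments.tsv")))

  ## --- immune landscape -----------------------------------------------
  if (isTRUE(config$stages$enrich) && length(immune_sets)) {
    es <- run_stage("enrich", function() ssgsea_scores(expr, immune_sets))
    keep(pipeline_write(es, file.path(config$outdir, "ssgsea_scores.tsv")))
  } else es <- NULL

  ## --- DEG screen between the two program subtypes ---------------------
  labels <- factor(subtype1, levels = sort(unique(subtype1)))  # A then B
  deg_tab <- run_stage("deg", function() moderated_t_table(expr, labels))
  degs <- filter_degs(deg_tab, config$deg$lfc_thresh, config$deg$p_thresh,
                      config$deg$use_adjusted)
  keep(pipeline_write(deg_tab, file.path(config$outdir, "deg_table.tsv")))

  ## --- prognostic screen -> CSRGs --------------------------------------
  screen <- run_stage("cox_screen", function() {
    screen_prognostic(expr, clinical, rule = "csrg", genes = degs)
  })
  csrgs <- screen$kept
  keep(pipeline_write(screen$table, file.path(config$outdir, "cox_screen.tsv")))
  if (length(csrgs) < 2L) stop("stage 'cox_screen': fewer than 2 prognostic genes")

  ## --- secondary clustering on CSRGs -----------------------------------
  cons2 <- run_stage("cluster2", function() {
    consensus_cluster(expr, genes = csrgs,
                      kmax = config$cluster$kmax, reps = config$cluster$reps,
                      subsample = config$cluster$subsample,
                      seed = stage_seed(config, "cluster2"))
  })
  k2 <- if (config$cluster$policy == "fixed") {
    choose_k(cons2, "fixed", k = config$cluster$fixed_k)
  } else cons2$chosen_k
  cl2 <- consensus_assignment(cons2, k2)
  keep(pipeline_write(data.frame(sample = names(cl2), genecluster = cl2),
                      file.path(config$outdir, "cluster2_assignments.tsv")))

  ## --- CUS --------------------------------------------------------------
  score_res <- run_stage("score", function() {
    # reference cluster = the worse-prognosis gene cluster, so sigC1 holds the
    # genes up under cuproptosis suppression and high CUS means poor prognosis
    cox2 <- cox_fit_univariate(clinical$time, clinical$event,
                               as.numeric(cl2[clinical$sample] ==
                                            sort(unique(cl2))[1L]),
                               name = "genecluster1")
    ref <- if (cox2$beta > 0) sort(unique(cl2))[1L] else sort(unique(cl2))[2L]
    split <- split_signature(expr, csrgs, cl2, reference_cluster = ref)
    bor <- boruta_select(t(expr[csrgs, , drop = FALSE]),
                         factor(cl2[colnames(expr)]),
                         alpha = config$boruta$alpha,
                         max_iter = config$boruta$max_iter,
                         seed = stage_seed(config, "score"))
    cus <- compute_cus(expr, split, boruta = bor,
                       keep_tentative = config$boruta$keep_tentative)
    cp <- optimal_cutpoint(cus$CUS, clinical$time[match(cus$sample, clinical$sample)],
                           clinical$event[match(cus$sample, clinical$sample)],
                           minprop = config$cutpoint$minprop)
    cus$group <- assign_cus_groups(cus$CUS, cp$cutoff)
    list(split = split, boruta = bor, cus = cus, cutpoint = cp)
  })
  cus <- score_res$cus
  keep(pipeline_write(cus, file.path(config$outdir, "cus_scores.tsv")))
  jsonlite::write_json(list(status = as.list(score_res$boruta$status),
                            iterations = score_res$boruta$iterations),
                       keep(file.path(config$outdir, "boruta_report.json")),
                       auto_unbox = TRUE, digits = NA)

  ## --- survival + immune comparison ------------------------------------
  surv_summary <- NULL
  if (isTRUE(config$stages$survival)) {
    surv_summary <- run_stage("survival", function() {
      idx <- match(cus$sample, clinical$sample)
      lr <- logrank_test(clinical$time[idx], clinical$event[idx], cus$group)
      cox <- cox_fit_univariate(clinical$time[idx], clinical$event[idx],
                                as.numeric(cus$group == "high"),
                                name = "cus_high")
      imm <- if (!is.null(es)) {
        correlate_scores(stats::setNames(cus$CUS, cus$sample), es)
      } else NULL
      if (!is.null(imm)) {
        keep(pipeline_write(imm, file.path(config$outdir,
                                           "cus_immune_correlation.tsv")))
      }
      list(cutoff = score_res$cutpoint$cutoff, logrank = lr, cox = cox)
    })
    jsonlite::write_json(list(cutoff = surv_summary$cutoff,
                              logrank_chisq = surv_summary$logrank$chisq,
                              logrank_p = surv_summary$logrank$p,
                              hr_high_vs_low = surv_summary$cox$hr,
                              hr_ci = c(surv_summary$cox$ci_low,
                                        surv_summary$cox$ci_high)),
                         keep(file.path(config$outdir, "survival_summary.json")),
                         auto_unbox = TRUE, digits = NA)
  }

  ## --- drug response ----------------------------------------------------
  if (isTRUE(config$stages$drugresp) && sim_mode) {
    drug <- run_stage("drugresp", function() {
      panel <- simulate_reference_panel(scfg)
      hom <- homogenize(panel$expr, expr)
      model <- train_ridge(hom$combined[, hom$reference_samples, drop = FALSE],
                           panel$response,
                           lambda_grid = config$ridge$lambda_grid,
                           folds = config$ridge$folds,
                           seed = stage_seed(config, "drugresp"))
      pred <- predict_ic50(model, hom$combined[, hom$cohort_samples, drop = FALSE])
      grp <- cus$group[match(rownames(pred), cus$sample)]
      comp <- do.call(rbind, lapply(colnames(pred), function(d) {
        rs <- rank_sum_test(pred[grp == "high", d], pred[grp == "low", d])
        data.frame(drug = d, U = rs$U, p = rs$p,
                   mean_high = mean(pred[grp == "high", d]),
                   mean_low = mean(pred[grp == "low", d]))
      }))
      list(pred = pred, comparison = comp)
    })
    keep(pipeline_write(drug$pred, file.path(config$outdir, "predicted_ic50.tsv")))
    keep(pipeline_write(drug$comparison,
                        file.path(config$outdir, "ic50_group_comparison.tsv")))
  }

  ## --- manifest ---------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("cuproscore")),
    seed = config$seed,
    chosen_k = list(cluster1 = k1, cluster2 = k2),
    n_degs = length(degs),
    n_csrgs = length(csrgs),
    stage_seconds = timings,
    files = lapply(stats::setNames(nm = basename(artifacts)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(file.path(config$outdir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
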