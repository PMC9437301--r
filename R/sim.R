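#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set describing the simulated study:
#' two expression batches with additive per-gene shifts, a small
#' copper-death-promoting ("program") gene module defining two latent
#' subtypes, a block of downstream signature genes split into positively and
#' negatively associated subsets, immune marker sets with subtype-dependent
#' infiltration, proportional-hazards survival driven by the latent program,
#' and a cell-line-like reference panel with gene-linear log-IC50.
#'
#' @param n_samples_per_batch Integer vector, samples per batch (default
#'   `c(200, 200)`, i.e. two batches).
#' @param n_genes Total gene count.
#' @param n_program_genes Size of the subtype-defining program module.
#' @param n_signature_genes Downstream signature size.
#' @param n_signature_pos How many signature genes are positively associated
#'   with the good-prognosis subtype; the rest are negatively associated.
#' @param subtype_effect Log2 shift applied per program/signature gene
#'   between subtypes.
#' @param batch_shift SD of the additive per-gene, per-batch location shift.
#' @param batch_scale_sd SD (log scale) of an optional multiplicative
#'   per-gene, per-batch noise-scale effect; 0 disables it.
#' @param noise_sd Residual SD on the log2 scale.
#' @param hazard_coef Log-hazard per unit latent activity.
#' @param censor_rate Target censoring fraction in `[0, 1)`.
#' @param n_immune_sets,immune_set_size Immune marker gene sets.
#' @param immune_shift Up-shift of immune markers in the poor-prognosis
#'   subtype.
#' @param n_ref_samples Reference (cell-line-like) panel size.
#' @param n_drugs Number of simulated drugs.
#' @param n_drug_predictors Genes per drug carrying a nonzero IC50
#'   coefficient.
#' @param drug_noise_sd Residual SD of the simulated log-IC50.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples_per_batch = c(200L, 200L),
                       n_genes = 1000L,
                       n_program_genes = 7L,
                       n_signature_genes = 31L,
                       n_signature_pos = 16L,
                       subtype_effect = 2.0,
                       batch_shift = 0.5,
                       batch_scale_sd = 0,
                       noise_sd = 1.0,
                       hazard_coef = 0.8,
                       censor_rate = 0.4,
                       n_immune_sets = 5L,
                       immune_set_size = 10L,
                       immune_shift = 1.0,
                       n_ref_samples = 120L,
                       n_drugs = 1L,
                       n_drug_predictors = 10L,
                       drug_noise_sd = 1.0,
                       seed = 1L) {
  cfg <- list(n_samples_per_batch = as.integer(n_samples_per_batch),
              n_genes = as.integer(n_genes),
              n_program_genes = as.integer(n_program_genes),
              n_signature_genes = as.integer(n_signature_genes),
              n_signature_pos = as.integer(n_signature_pos),
              subtype_effect = subtype_effect,
              batch_shift = batch_shift,
              batch_scale_sd = batch_scale_sd,
              noise_sd = noise_sd,
              hazard_coef = hazard_coef,
              censor_rate = censor_rate,
              n_immune_sets = as.integer(n_immune_sets),
              immune_set_size = as.integer(immune_set_size),
              immune_shift = immune_shift,
              n_ref_samples = as.integer(n_ref_samples),
              n_drugs = as.integer(n_drugs),
              n_drug_predictors = as.integer(n_drug_predictors),
              drug_noise_sd = drug_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_samples_per_batch", "n_genes", "n_program_genes",
              "n_signature_genes", "n_immune_sets", "immune_set_size",
              "n_ref_samples")
  for (f in counts) {
    if (any(is.na(cfg[[f]])) || any(cfg[[f]] <= 0L)) stop(f, " must be positive")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (cfg$n_signature_pos < 1L || cfg$n_signature_pos >= cfg$n_signature_genes) {
    stop("n_signature_pos must leave both signature subsets non-empty")
  }
  reserved <- cfg$n_program_genes + cfg$n_signature_genes +
    cfg$n_immune_sets * cfg$immune_set_size
  # disjointness of program / signature / immune / noise index blocks
  if (reserved >= cfg$n_genes) {
    stop("n_genes too small for disjoint program, signature and immune sets")
  }
  if (cfg$noise_sd < 0 || cfg$batch_shift < 0 || cfg$batch_scale_sd < 0 ||
      cfg$drug_noise_sd < 0) stop("standard deviations must be non-negative")
  invisible(cfg)
}

sim_gene_ids <- function(cfg) sprintf("G%05d", seq_len(cfg$n_genes))

sim_gene_index <- function(cfg) {
  ids <- sim_gene_ids(cfg)
  program <- ids[seq_len(cfg$n_program_genes)]
  sig <- ids[cfg$n_program_genes + seq_len(cfg$n_signature_genes)]
  sig_pos <- sig[seq_len(cfg$n_signature_pos)]
  sig_neg <- setdiff(sig, sig_pos)
  off <- cfg$n_program_genes + cfg$n_signature_genes
  immune <- lapply(seq_len(cfg$n_immune_sets), function(i) {
    ids[off + (i - 1L) * cfg$immune_set_size + seq_len(cfg$immune_set_size)]
  })
  names(immune) <- sprintf("immune_set_%02d", seq_len(cfg$n_immune_sets))
  list(ids = ids, program = program, sig_pos = sig_pos, sig_neg = sig_neg,
       immune = immune)
}

# censoring rate theta such that E[ theta / (theta + lambda_i) ] = target,
# solved by bisection (exponential event and censoring times)
censor_rate_bisect <- function(lambda, target, tol = 1e-10) {
  if (target <= 0) return(0)
  f <- function(theta) mean(theta / (theta + lambda)) - target
  lo <- 1e-12; hi <- max(lambda) * 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)   # log-scale bisection, theta spans orders of magnitude
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi / lo - 1 < tol) break
  }
  sqrt(lo * hi)
}

#' Simulate an expression cohort with known ground truth
#'
#' Generates a log2-scale gene-by-sample matrix with two latent subtypes:
#' subtype 2 has the program genes shifted *down* by `subtype_effect`
#' (emulating low expression of the copper-death program in the
#' poor-prognosis cluster), positively associated signature genes up in
#' subtype 1, negatively associated ones up in subtype 2, and immune markers
#' up in subtype 2. Batches receive additive per-gene shifts. Survival times
#' are exponential proportional-hazards with linear predictor
#' `hazard_coef * activity`, where the recorded latent activity is the
#' centered program-suppression axis (high activity = low program
#' expression = poor prognosis), so a Cox fit on the recorded activity
#' recovers `+hazard_coef`. Censoring is independent exponential with rate
#' tuned by bisection to the target fraction.
#'
#' @param config A [sim_config()].
#' @return `list(expr, clinical, truth)`; `truth` records the subtype,
#'   latent activity, batch, gene memberships with association signs, and the
#'   generator configuration.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  idx <- sim_gene_index(config)
  n_batches <- length(config$n_samples_per_batch)
  n <- sum(config$n_samples_per_batch)
  batch <- rep(seq_len(n_batches), config$n_samples_per_batch)
  samples <- sprintf("S%04d", seq_len(n))

  baseline <- stats::runif(config$n_genes, 4, 10)
  names(baseline) <- idx$ids
  subtype <- sample(1:2, n, replace = TRUE)

  mu <- matrix(baseline, nrow = config$n_genes, ncol = n,
               dimnames = list(idx$ids, samples))
  is2 <- subtype == 2L
  mu[idx$program, is2] <- mu[idx$program, is2] - config$subtype_effect
  mu[idx$sig_pos, !is2] <- mu[idx$sig_pos, !is2] + config$subtype_effect
  mu[idx$sig_neg, is2] <- mu[idx$sig_neg, is2] + config$subtype_effect
  imm_genes <- unlist(idx$immune, use.names = FALSE)
  mu[imm_genes, is2] <- mu[imm_genes, is2] + config$immune_shift

  # latent activity: program-suppression axis (centered, sign-flipped program mean)
  prog_mean <- colMeans(mu[idx$program, , drop = FALSE])
  activity <- -(prog_mean - mean(prog_mean))

  noise <- matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
                  nrow = config$n_genes)
  shift <- matrix(stats::rnorm(config$n_genes * n_batches, 0, config$batch_shift),
                  nrow = config$n_genes)
  if (config$batch_scale_sd > 0) {
    scl <- matrix(exp(stats::rnorm(config$n_genes * n_batches, 0,
                                   config$batch_scale_sd)),
                  nrow = config$n_genes)
    noise <- noise * scl[, batch, drop = FALSE]
  }
  expr <- mu + noise + shift[, batch, drop = FALSE]
  attr(expr, "unit") <- "log2TPM1"

  base_rate <- log(2) / 1095   # median baseline survival ~3 years (days)
  lambda <- base_rate * exp(config$hazard_coef * activity)
  t_event <- stats::rexp(n, lambda)
  theta <- censor_rate_bisect(lambda, config$censor_rate)
  t_cens <- if (theta > 0) stats::rexp(n, theta) else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  grade_probs <- rbind(c(0.15, 0.45, 0.30, 0.10),   # subtype 1: lower grade
                       c(0.05, 0.25, 0.40, 0.30))
  grade <- vapply(subtype, function(z) {
    sample(paste0("G", 1:4), 1L, prob = grade_probs[z, ])
  }, character(1L))
  stage_probs <- rbind(c(0.55, 0.15, 0.20, 0.10),
                       c(0.30, 0.10, 0.30, 0.30))
  stage <- vapply(subtype, function(z) {
    sample(c("I", "II", "III", "IV"), 1L, prob = stage_probs[z, ])
  }, character(1L))

  clinical <- data.frame(sample = samples, time = time, event = event,
                         grade = grade, stage = stage, batch = batch,
                         stringsAsFactors = FALSE)
  sig_genes <- c(idx$sig_pos, idx$sig_neg)
  truth <- list(subtype = stats::setNames(subtype, samples),
                activity = stats::setNames(activity, samples),
                batch = stats::setNames(batch, samples),
                program_genes = idx$program,
                signature_genes = sig_genes,
                signature_sign = stats::setNames(
                  c(rep(1L, length(idx$sig_pos)), rep(-1L, length(idx$sig_neg))),
                  sig_genes),
                immune_sets = idx$immune,
                censor_theta = theta,
                config = config)
  list(expr = expr, clinical = clinical, truth = truth)
}

#' Immune-marker gene sets of a simulated cohort
#'
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @return A GMT-style named list of marker gene sets.
#' @export
sim_immune_gmt <- function(truth) {
  sets <- truth$immune_sets
  attr(sets, "description") <- stats::setNames(
    rep("synthetic immune marker set", length(sets)), names(sets))
  sets
}

#' Simulate a reference drug-response panel
#'
#' The panel shares the cohort's gene universe. Each line carries a latent
#' program-propensity factor (its position along the cuproptosis axis) that
#' loads on the program and signature genes with the same sign pattern the
#' cohort subtypes follow, emulating the correlated expression modules that
#' make expression-based response transfer work on real cell-line panels.
#' Each drug's true log-IC50 is a linear combination of a recorded
#' predictor-gene subset (drawn from the program and signature blocks, with
#' coefficient signs aligned to the axis so sensitivity tracks the program)
#' plus Gaussian noise; the cohort subtypes therefore differ in true
#' sensitivity.
#'
#' @param config A [sim_config()] with `n_drugs >= 1`.
#' @return `list(expr, response, truth)`: panel expression (genes x lines),
#'   line-by-drug log-IC50 matrix, and the coefficient / loading ground
#'   truth.
#' @export
simulate_reference_panel <- function(config) {
  validate_sim_config(config)
  if (config$n_drugs < 1L) stop("at least 1 simulated drug is required")
  set.seed(config$seed + 777L)
  idx <- sim_gene_index(config)
  nl <- config$n_ref_samples
  lines <- sprintf("CL%04d", seq_len(nl))
  baseline <- stats::runif(config$n_genes, 4, 10)

  # gene loadings on the latent program-suppression axis: same sign pattern
  # as the cohort subtype contrast, at half the between-subtype amplitude
  loading <- stats::setNames(numeric(config$n_genes), idx$ids)
  loading[idx$program] <- -config$subtype_effect / 2
  loading[idx$sig_pos] <- -config$subtype_effect / 2
  loading[idx$sig_neg] <- config$subtype_effect / 2
  loading[unlist(idx$immune, use.names = FALSE)] <- config$immune_shift / 2
  factor_line <- stats::rnorm(nl)

  expr <- matrix(baseline, nrow = config$n_genes, ncol = nl,
                 dimnames = list(idx$ids, lines)) +
    outer(loading, factor_line) +
    matrix(stats::rnorm(config$n_genes * nl, 0, 1), nrow = config$n_genes)
  attr(expr, "unit") <- "log2TPM1"

  drug_names <- sprintf("drug%02d", seq_len(config$n_drugs))
  pool <- c(idx$program, idx$sig_pos, idx$sig_neg)
  coef <- matrix(0, nrow = config$n_genes, ncol = config$n_drugs,
                 dimnames = list(idx$ids, drug_names))
  intercept <- stats::rnorm(config$n_drugs, 2, 1)
  names(intercept) <- drug_names
  for (d in seq_len(config$n_drugs)) {
    pred <- sample(pool, min(config$n_drug_predictors, length(pool)))
    coef[pred, d] <- sign(loading[pred]) * abs(stats::rnorm(length(pred)))
    if (all(coef[, d] == 0) && config$drug_noise_sd == 0) {
      stop("degenerate constant response for ", drug_names[d])
    }
  }
  response <- t(expr) %*% coef +
    matrix(intercept, nrow = nl, ncol = config$n_drugs, byrow = TRUE) +
    matrix(stats::rnorm(nl * config$n_drugs, 0, config$drug_noise_sd), nrow = nl)
  truth <- list(coef = coef, intercept = intercept, loading = loading,
                line_factor = stats::setNames(factor_line, lines),
                noise_sd = config$drug_noise_sd, config = config)
  list(expr = expr, response = response, truth = truth)
}

#' True log-IC50 implied by the panel ground truth for any expression matrix
#'
#' @param truth Panel ground truth from [simulate_reference_panel()].
#' @param expr Gene-by-sample matrix over (at least) the panel's gene
#'   universe.
#' @return Sample-by-drug matrix of noiseless log-IC50.
#' @export
sim_true_ic50 <- function(truth, expr) {
  t(expr[rownames(truth$coef), , drop = FALSE]) %*% truth$coef +
    matrix(truth$intercept, nrow = ncol(expr), ncol = ncol(truth$coef),
           byrow = TRUE)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Writes the cohort expression and clinical tables, a GMT holding the
#' program, signature and immune sets, the reference panel files, a
#' sample-level ground-truth table, and a JSON manifest recording the
#' configuration, seed and per-file MD5 checksums.
#'
#' @param dir_path Writable directory (created if needed).
#' @param config A [sim_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_fixture_bundle <- function(dir_path, config) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir_path)) stop("cannot create directory ", dir_path)
  sim <- simulate_cohort(config)
  panel <- simulate_reference_panel(config)

  files <- c(expression = "expression.tsv", clinical = "clinical.tsv",
             genesets = "genesets.gmt", panel_expression = "panel_expression.tsv",
             panel_ic50 = "panel_ic50.tsv", ground_truth = "ground_truth.tsv")
  paths <- file.path(dir_path, files)
  names(paths) <- names(files)

  write_expression(sim$expr, paths["expression"])
  utils::write.table(sim$clinical, paths["clinical"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sets <- c(list(program = sim$truth$program_genes,
                 signature_pos = names(sim$truth$signature_sign)[sim$truth$signature_sign > 0],
                 signature_neg = names(sim$truth$signature_sign)[sim$truth$signature_sign < 0]),
            sim$truth$immune_sets)
  write_gmt(sets, paths["genesets"])
  write_expression(panel$expr, paths["panel_expression"])
  utils::write.table(data.frame(sample = rownames(panel$response),
                                panel$response, check.names = FALSE),
                     paths["panel_ic50"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gt <- data.frame(sample = names(sim$truth$subtype),
                   subtype = sim$truth$subtype,
                   activity = sim$truth$activity,
                   batch = sim$truth$batch, stringsAsFactors = FALSE)
  utils::write.table(gt, paths["ground_truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(config = unclass(config), seed = config$seed,
                   files = lapply(stats::setNames(nm = names(paths)), function(k) {
                     list(path = unname(files[k]),
                          md5 = unname(tools::md5sum(paths[k])))
                   }))
  jsonlite::write_json(manifest, file.path(dir_path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
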