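#' Homogenize a reference panel with a study cohort
#'
#' Intersects the gene universes, treats reference and cohort as two
#' batches, and applies the parametric empirical-Bayes batch correction so
#' the ridge models trained on the panel transfer to the cohort scale.
#'
#' @param reference Gene-by-line reference expression matrix.
#' @param cohort Gene-by-sample cohort matrix.
#' @param min_overlap Minimum shared gene count (default 100).
#' @return `list(combined, reference_samples, cohort_samples, model)`.
#' @export
homogenize <- function(reference, cohort, min_overlap = 100L) {
  genes <- intersect(rownames(reference), rownames(cohort))
  if (length(genes) < min_overlap) {
    stop("gene overlap ", length(genes), " below minimum ", min_overlap)
  }
  dup <- intersect(colnames(reference), colnames(cohort))
  if (length(dup)) stop("sample id collision: ", paste(dup, collapse = ", "))
  combined <- cbind(reference[genes, , drop = FALSE],
                    cohort[genes, , drop = FALSE])
  batch <- c(rep("reference", ncol(reference)), rep("cohort", ncol(cohort)))
  adj <- combat_adjust(combined, batch)
  list(combined = adj$corrected,
       reference_samples = colnames(reference),
       cohort_samples = colnames(cohort),
       model = adj$model)
}

ridge_solve <- function(x, y, lambda) {
  # closed-form ridge on centered y via SVD: beta = V diag(d/(d^2+lambda)) U'y
  sv <- svd(x)
  keep <- sv$d > max(sv$d) * 1e-12
  shrink <- sv$d[keep] / (sv$d[keep]^2 + lambda)
  as.vector(sv$v[, keep, drop = FALSE] %*%
              (shrink * crossprod(sv$u[, keep, drop = FALSE], y)))
}

#' Train ridge-regression drug-response models on a reference panel
#'
#' Predictors are gene-standardized (reference means and SDs, stored for
#' prediction); per drug the closed-form ridge solution is computed and the
#' penalty is chosen by k-fold cross-validated mean squared error over
#' `lambda_grid`, ties going to the larger (more regularized) penalty.
#'
#' @param reference Gene-by-line expression matrix.
#' @param response Line-by-drug log-IC50 matrix (no missing values).
#' @param lambda_grid Candidate penalties (default `10^(-2:4)`).
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return Object of class `"ridge_model"`: per-drug coefficients over the
#'   gene space, intercepts, chosen lambdas, CV error curves, and the gene
#'   standardization used.
#' @export
train_ridge <- function(reference, response, lambda_grid = 10^(-2:4),
                        folds = 10L, seed = 1L) {
  check_expression(reference)
  response <- as.matrix(response)
  if (is.null(colnames(response))) {
    colnames(response) <- paste0("drug", seq_len(ncol(response)))
  }
  if (anyDuplicated(colnames(response))) stop("drug names must be unique")
  if (!length(lambda_grid)) stop("empty lambda grid")
  n <- ncol(reference)
  if (nrow(response) != n) stop("response rows must match reference samples")
  if (anyNA(response)) stop("missing drug response values")
  if (n < folds) stop("fewer samples than folds")

  centers <- rowMeans(reference)
  sds <- apply(reference, 1L, stats::sd)
  usable <- sds > 0
  if (!all(usable)) {
    message(sum(!usable), " constant gene(s) dropped from the predictor space")
  }
  x <- t((reference[usable, , drop = FALSE] - centers[usable]) / sds[usable])

  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  lambda_grid <- sort(lambda_grid)

  drugs <- colnames(response)
  models <- lapply(drugs, function(d) {
    y <- response[, d]
    cv_mse <- vapply(lambda_grid, function(lam) {
      errs <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        beta <- ridge_solve(x[tr, , drop = FALSE], y[tr] - mean(y[tr]), lam)
        pred <- mean(y[tr]) + x[!tr, , drop = FALSE] %*% beta
        mean((y[!tr] - pred)^2)
      }, numeric(1L))
      mean(errs)
    }, numeric(1L))
    best <- max(which(cv_mse == min(cv_mse)))   # ties -> larger lambda
    lam <- lambda_grid[best]
    beta <- ridge_solve(x, y - mean(y), lam)
    list(coef = stats::setNames(beta, colnames(x)), intercept = mean(y),
         lambda = lam, cv = data.frame(lambda = lambda_grid, mse = cv_mse))
  })
  names(models) <- drugs
  out <- list(models = models, genes = colnames(x),
              centers = centers[usable], sds = sds[usable],
              folds = folds, seed = seed)
  class(out) <- "ridge_model"
  out
}

#' Predict cohort drug sensitivity from a trained ridge model
#'
#' Applies the model's reference standardization to the cohort expression
#' and evaluates the linear predictor per drug. Run [homogenize()] first so
#' the cohort shares the reference scale.
#'
#' @param model A [train_ridge()] model.
#' @param cohort Gene-by-sample cohort matrix containing every model gene.
#' @return Sample-by-drug matrix of predicted log-IC50.
#' @export
predict_ic50 <- function(model, cohort) {
  missing <- setdiff(model$genes, rownames(cohort))
  if (length(missing)) {
    stop("model gene(s) missing from cohort: ", paste(missing, collapse = ", "))
  }
  x <- t((cohort[model$genes, , drop = FALSE] - model$centers) / model$sds)
  pred <- vapply(model$models, function(m) {
    as.vector(m$intercept + x %*% m$coef)
  }, numeric(nrow(x)))
  rownames(pred) <- colnames(cohort)
  pred
}

#' Gene-drug correlation mining
#'
#' Pearson correlation (with the two-sided t-test p-value) between each
#' selected gene's expression and each drug's response, BH-adjusted across
#' all pairs and sorted by absolute correlation. Constant vectors give an
#' `NA` row flagged in `degenerate`.
#'
#' @param expression Gene-by-sample matrix of the genes of interest.
#' @param responses Sample-by-drug response matrix (>= 3 shared samples).
#' @return data.frame `gene`, `drug`, `r`, `p`, `fdr`, `degenerate`.
#' @export
gene_drug_correlation <- function(expression, responses) {
  common <- intersect(colnames(expression), rownames(responses))
  if (length(common) < 3L) stop("need >= 3 shared samples")
  expression <- expression[, common, drop = FALSE]
  responses <- responses[common, , drop = FALSE]
  grid <- expand.grid(gene = rownames(expression), drug = colnames(responses),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- expression[grid$gene[i], ]
    y <- responses[, grid$drug[i]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(gene = grid$gene[i], drug = grid$drug[i],
                        r = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    ct <- stats::cor.test(x, y)
    data.frame(gene = grid$gene[i], drug = grid$drug[i],
               r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$fdr <- bh_adjust(out$p)
  out[order(-abs(out$r), na.last = TRUE), c("gene", "drug", "r", "p", "fdr",
                                            "degenerate")]
}
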