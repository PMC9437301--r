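#' Parametric empirical-Bayes batch correction
#'
#' Location-and-scale batch adjustment for log-scale expression: per gene,
#' the data are standardized against the batch-size-weighted grand mean and
#' pooled variance, per-batch location (gamma) and scale (delta^2) effects
#' are estimated, shrunk towards batch-level priors (normal prior on gamma,
#' inverse-gamma on delta^2, method-of-moments hyperparameters, fixed-point
#' updates to convergence), and the standardized data are adjusted and
#' back-transformed. Genes with zero pooled variance pass through unchanged.
#' After adjustment each gene is re-anchored at its original batch-weighted
#' pooled mean, so correction never moves the cohort-level location.
#'
#' @param matrix Gene-by-sample log-scale matrix.
#' @param batch Batch label per sample (length `ncol(matrix)`).
#' @param tol Convergence tolerance of the fixed-point EB updates.
#' @param max_iter Maximum fixed-point iterations per batch.
#' @param preserve_pooled_mean Re-center each gene at its pre-correction
#'   batch-weighted mean (default `TRUE`).
#' @return `list(corrected, model)`; `model` (class `"batch_model"`) holds
#'   the grand means, pooled variances, raw and shrunken batch effects and
#'   the prior hyperparameters.
#' @export
combat_adjust <- function(matrix, batch, tol = 1e-4, max_iter = 100L,
                          preserve_pooled_mean = TRUE) {
  check_expression(matrix)
  batch <- as.factor(batch)
  if (length(batch) != ncol(matrix)) stop("batch labels must match sample count")
  if (nlevels(batch) < 2L) {
    warning("single batch: nothing to correct, returning input unchanged")
    return(list(corrected = matrix, model = NULL))
  }
  nb <- table(batch)
  if (any(nb < 2L)) {
    stop("batch(es) with <2 samples: ",
         paste(names(nb)[nb < 2L], collapse = ", "))
  }
  n <- ncol(matrix)
  levs <- levels(batch)

  batch_means <- vapply(levs, function(b) {
    rowMeans(matrix[, batch == b, drop = FALSE])
  }, numeric(nrow(matrix)))
  grand_mean <- as.vector(batch_means %*% (as.numeric(nb) / n))
  resid <- matrix - batch_means[, as.integer(batch), drop = FALSE]
  pooled_var <- rowMeans(resid^2)

  keep <- pooled_var > 0
  if (!all(keep)) {
    message(sum(!keep), " zero-variance gene(s) passed through unchanged")
  }
  Z <- matrix
  Z[keep, ] <- (matrix[keep, , drop = FALSE] - grand_mean[keep]) /
    sqrt(pooled_var[keep])
  Z[!keep, ] <- 0

  g <- sum(keep)
  gamma_hat <- vapply(levs, function(b) {
    rowMeans(Z[keep, batch == b, drop = FALSE])
  }, numeric(g))
  delta_hat <- vapply(levs, function(b) {
    apply(Z[keep, batch == b, drop = FALSE], 1L, stats::var)
  }, numeric(g))

  # method-of-moments hyperparameters per batch
  gamma_bar <- colMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 2L, stats::var)
  a_prior <- vapply(seq_along(levs), function(j) {
    m <- mean(delta_hat[, j]); s2 <- stats::var(delta_hat[, j])
    (2 * s2 + m^2) / s2
  }, numeric(1L))
  b_prior <- vapply(seq_along(levs), function(j) {
    m <- mean(delta_hat[, j]); s2 <- stats::var(delta_hat[, j])
    (m * s2 + m^3) / s2
  }, numeric(1L))

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (j in seq_along(levs)) {
    sel <- batch == levs[j]
    nj <- sum(sel)
    zj <- Z[keep, sel, drop = FALSE]
    g_old <- gamma_hat[, j]
    d_old <- delta_hat[, j]
    for (it in seq_len(max_iter)) {
      g_new <- (nj * tau2[j] * gamma_hat[, j] + d_old * gamma_bar[j]) /
        (nj * tau2[j] + d_old)
      sse <- rowSums((zj - g_new)^2)
      d_new <- (b_prior[j] + 0.5 * sse) / (nj / 2 + a_prior[j] - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      if (change < tol) break
    }
    gamma_star[, j] <- g_old
    delta_star[, j] <- d_old
  }

  adj <- Z[keep, , drop = FALSE]
  jb <- as.integer(batch)
  adj <- (adj - gamma_star[, jb, drop = FALSE]) /
    sqrt(delta_star[, jb, drop = FALSE])
  corrected <- matrix
  corrected[keep, ] <- adj * sqrt(pooled_var[keep]) + grand_mean[keep]
  if (preserve_pooled_mean) {
    w_mean <- vapply(levs, function(b) {
      rowMeans(corrected[keep, batch == b, drop = FALSE])
    }, numeric(g)) %*% (as.numeric(nb) / n)
    corrected[keep, ] <- corrected[keep, , drop = FALSE] -
      as.vector(w_mean) + grand_mean[keep]
  }
  attr(corrected, "unit") <- attr(matrix, "unit")

  model <- list(grand_mean = grand_mean, pooled_var = pooled_var,
                gamma_hat = gamma_hat, delta_hat = delta_hat,
                gamma_star = gamma_star, delta_star = delta_star,
                hyper = list(gamma_bar = gamma_bar, tau2 = tau2,
                             a_prior = a_prior, b_prior = b_prior),
                batch_levels = levs, genes_adjusted = rownames(matrix)[keep])
  class(model) <- "batch_model"
  list(corrected = corrected, model = model)
}

#' Batch-severity diagnostics
#'
#' Quantifies how strongly batch structures an expression matrix:
#' (a) the mean per-gene one-way F statistic across batches and (b) the
#' silhouette width of the batch labels in the space of the top two
#' principal components of the samples.
#'
#' @param matrix Gene-by-sample matrix.
#' @param batch Batch label per sample.
#' @return `list(mean_f, pc_silhouette, n_batches)` of class
#'   `"batch_severity"`.
#' @export
batch_severity <- function(matrix, batch) {
  check_expression(matrix)
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) stop("batch_severity needs >= 2 batches")
  n <- ncol(matrix)
  k <- nlevels(batch)
  nb <- as.numeric(table(batch))

  bm <- vapply(levels(batch), function(b) {
    rowMeans(matrix[, batch == b, drop = FALSE])
  }, numeric(nrow(matrix)))
  gm <- rowMeans(matrix)
  ssb <- as.vector((bm - gm)^2 %*% nb)
  ssw <- rowSums((matrix - bm[, as.integer(batch), drop = FALSE])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f <- f[is.finite(f)]

  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  xy <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  sil <- cluster::silhouette(as.integer(batch), stats::dist(xy))
  out <- list(mean_f = mean(f),
              pc_silhouette = mean(sil[, "sil_width"]),
              n_batches = k)
  class(out) <- "batch_severity"
  out
}

#' @export
print.batch_severity <- function(x, ...) {
  cat("Batch severity:", x$n_batches, "batches\n")
  cat("  mean per-gene F:", format(x$mean_f, digits = 4), "\n")
  cat("  PC1-2 batch silhouette:", format(x$pc_silhouette, digits = 4), "\n")
  invisible(x)
}
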