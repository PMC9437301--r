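#' Split a prognostic signature by association sign with a reference cluster
#'
#' Each screened gene is correlated (point-biserial) with the indicator of
#' the reference gene-cluster; positively correlated genes form `sigC1`,
#' negatively correlated ones `sigC2`. Genes with exactly zero correlation
#' are excluded with a warning.
#'
#' @param matrix Gene-by-sample expression matrix.
#' @param csrg_genes Screened prognostic gene ids (all present in the
#'   matrix, none with zero variance).
#' @param cluster_labels Two-cluster assignment named by sample.
#' @param reference_cluster The cluster whose indicator defines the
#'   positive direction.
#' @return `list(sigC1, sigC2, stat)` of class `"signature_split"`; `stat`
#'   holds the per-gene correlations.
#' @export
split_signature <- function(matrix, csrg_genes, cluster_labels,
                            reference_cluster) {
  missing <- setdiff(csrg_genes, rownames(matrix))
  if (length(missing)) stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  labs <- cluster_labels[colnames(matrix)]
  if (anyNA(labs)) stop("cluster labels missing for some samples")
  if (length(unique(labs)) != 2L) stop("exactly 2 clusters required")
  if (!reference_cluster %in% labs) stop("reference_cluster not among labels")
  ind <- as.numeric(labs == reference_cluster)
  stat <- vapply(csrg_genes, function(g) {
    x <- matrix[g, ]
    if (stats::sd(x) == 0) stop("zero-variance gene: ", g)
    stats::cor(x, ind)
  }, numeric(1L))
  zero <- names(stat)[stat == 0]
  if (length(zero)) {
    warning("gene(s) with zero association excluded: ", paste(zero, collapse = ", "))
  }
  out <- list(sigC1 = names(stat)[stat > 0], sigC2 = names(stat)[stat < 0],
              stat = stat, reference_cluster = reference_cluster)
  class(out) <- "signature_split"
  out
}

#' Shadow-feature (Boruta-style) all-relevant feature selection
#'
#' Each iteration appends a shuffled "shadow" copy of every undecided
#' feature, computes importances, and scores a hit for features beating the
#' maximum shadow importance. After each iteration a two-sided binomial
#' test (hit probability 1/2) at level `alpha` confirms clear winners and
#' rejects clear losers; rejected features leave the pool, confirmed ones
#' stay to keep the importance context stable. Decision p-values are
#' Bonferroni-adjusted across the features under test (`mc_adjust`), which
#' keeps features that correlate with the target only by sampling accident
#' from being confirmed. The loop ends when no feature is tentative or
#' `max_iter` is reached.
#'
#' The default importance is the (out-of-bag) permutation importance of a
#' single-threaded, seeded `ranger` random forest — its per-iteration
#' variance is what keeps fixed chance-correlated features from
#' persistently beating the re-drawn shadow maximum; any function
#' `f(x, y)` returning one importance per column can be substituted.
#'
#' @param x Sample-by-feature numeric matrix (>= 20 samples, >= 2
#'   features).
#' @param y Target factor with >= 2 classes (non-constant).
#' @param importance_fn Optional importance function.
#' @param alpha Binomial test level (default 0.01).
#' @param max_iter Maximum iterations (>= 10).
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param num_trees Trees per forest for the default importance.
#' @param mc_adjust Bonferroni-adjust the decision tests across features
#'   (default `TRUE`).
#' @return Object of class `"boruta_report"`: per-feature `status`
#'   (confirmed / rejected / tentative), `hits`, `iterations`, importance
#'   history, `alpha`, `seed`.
#' @export
boruta_select <- function(x, y, importance_fn = NULL, alpha = 0.01,
                          max_iter = 100L, seed = 1L, num_trees = 100L,
                          mc_adjust = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 20L) stop("need >= 20 samples")
  if (ncol(x) < 2L) stop("need >= 2 features")
  y <- as.factor(y)
  if (nlevels(y) < 2L) stop("constant target")
  if (max_iter < 10L) stop("max_iter must be >= 10")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  feat <- colnames(x)

  if (is.null(importance_fn)) {
    importance_fn <- function(xx, yy, it_seed) {
      df <- data.frame(xx, check.names = FALSE)
      df$.target <- yy
      fit <- ranger::ranger(dependent.variable.name = ".target", data = df,
                            num.trees = num_trees, importance = "permutation",
                            seed = it_seed, num.threads = 1L,
                            verbose = FALSE)
      pmax(fit$variable.importance, 0)
    }
  } else {
    user_fn <- importance_fn
    importance_fn <- function(xx, yy, it_seed) pmax(user_fn(xx, yy), 0)
  }

  set.seed(seed)
  status <- stats::setNames(rep("tentative", length(feat)), feat)
  hits <- stats::setNames(integer(length(feat)), feat)
  tested <- stats::setNames(integer(length(feat)), feat)
  history <- list()
  it <- 0L
  while (any(status == "tentative") && it < max_iter) {
    it <- it + 1L
    pool <- feat[status != "rejected"]
    xr <- x[, pool, drop = FALSE]
    xs <- apply(xr, 2L, sample)
    colnames(xs) <- paste0(".shadow.", pool)
    imp <- importance_fn(cbind(xr, xs), y, seed + it)
    real_imp <- imp[seq_along(pool)]
    shadow_max <- max(imp[-seq_along(pool)])
    hit <- real_imp > shadow_max
    hits[pool] <- hits[pool] + as.integer(hit)
    tested[pool] <- tested[pool] + 1L
    history[[it]] <- stats::setNames(real_imp, pool)

    tent <- feat[status == "tentative"]
    p_hi <- stats::pbinom(hits[tent] - 1L, tested[tent], 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hits[tent], tested[tent], 0.5)
    thresh <- alpha / 2 / if (mc_adjust) length(feat) else 1L
    status[tent[p_hi < thresh]] <- "confirmed"
    status[tent[p_lo < thresh]] <- "rejected"
  }
  out <- list(status = status, hits = hits, tested = tested, iterations = it,
              importance_history = history, alpha = alpha, seed = seed)
  class(out) <- "boruta_report"
  out
}

#' @export
print.boruta_report <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("confirmed", "tentative", "rejected")))
  cat("Boruta-style selection:", x$iterations, "iterations, alpha", x$alpha, "\n")
  cat(sprintf("  confirmed %d, tentative %d, rejected %d\n",
              tab["confirmed"], tab["tentative"], tab["rejected"]))
  invisible(x)
}

#' First-principal-component score of a gene signature
#'
#' Genes are centered and unit-scaled, the sample projections on the first
#' right singular direction are computed by SVD, and the sign is fixed so
#' the score correlates non-negatively with the mean scaled signature
#' expression (PC signs are otherwise arbitrary). A single-gene signature
#' returns that gene's scaled values with a note.
#'
#' @param matrix Gene-by-sample expression matrix.
#' @param genes Gene subset defining the signature (>= 1 gene; zero
#'   variance is an error).
#' @return Named numeric per-sample score with attribute `var_explained`.
#' @export
pc1_scores <- function(matrix, genes = NULL) {
  if (is.null(genes)) genes <- rownames(matrix)
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing)) stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  m <- matrix[genes, , drop = FALSE]
  if (ncol(m) < 3L) stop("need >= 3 samples")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s) in signature: ",
         paste(genes[sds == 0], collapse = ", "))
  }
  z <- (m - rowMeans(m)) / sds
  if (length(genes) == 1L) {
    score <- stats::setNames(as.numeric(z), colnames(m))
    attr(score, "var_explained") <- 1
    attr(score, "note") <- "single-gene signature: scaled expression used"
    return(score)
  }
  x <- t(z)                       # samples x genes, columns centered & scaled
  sv <- svd(x)
  score <- sv$u[, 1L] * sv$d[1L]
  ref <- rowMeans(x)
  cc <- stats::cor(score, ref)
  if (!is.na(cc) && cc < 0) score <- -score
  score <- stats::setNames(score, colnames(m))
  attr(score, "var_explained") <- sv$d[1L]^2 / sum(sv$d^2)
  score
}

#' Per-sample cuproptosis score (CUS)
#'
#' `CUS = PsigC1 - PsigC2`, where `PsigC1`/`PsigC2` are the first
#' principal-component scores of the positively / negatively associated
#' signature subsets. When a Boruta report is supplied, each subset is
#' intersected with the confirmed (and, by default, tentative) features
#' first; a subset emptied by filtering is an error naming the set.
#'
#' @param matrix Gene-by-sample expression matrix.
#' @param split A [split_signature()] result.
#' @param boruta Optional [boruta_select()] report used to filter genes.
#' @param keep_tentative Keep tentative features when filtering (default
#'   `TRUE`, so small signatures survive an undecided run).
#' @return data.frame `sample`, `PsigC1`, `PsigC2`, `CUS` of class
#'   `"cus_result"`, with per-signature variance explained as attributes.
#' @export
compute_cus <- function(matrix, split, boruta = NULL, keep_tentative = TRUE) {
  sig1 <- split$sigC1
  sig2 <- split$sigC2
  if (!is.null(boruta)) {
    keep_status <- c("confirmed", if (keep_tentative) "tentative")
    kept <- names(boruta$status)[boruta$status %in% keep_status]
    f1 <- intersect(sig1, kept)
    f2 <- intersect(sig2, kept)
    if (length(sig1) && !length(f1)) stop("sigC1 emptied by Boruta filtering")
    if (length(sig2) && !length(f2)) stop("sigC2 emptied by Boruta filtering")
    sig1 <- f1; sig2 <- f2
  }
  if (!length(sig1) && !length(sig2)) stop("both signature sets are empty")
  p1 <- if (length(sig1)) pc1_scores(matrix, sig1) else
    stats::setNames(rep(0, ncol(matrix)), colnames(matrix))
  p2 <- if (length(sig2)) pc1_scores(matrix, sig2) else
    stats::setNames(rep(0, ncol(matrix)), colnames(matrix))
  out <- data.frame(sample = colnames(matrix), PsigC1 = as.vector(p1),
                    PsigC2 = as.vector(p2), CUS = as.vector(p1) - as.vector(p2),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "var_explained_sigC1") <- attr(p1, "var_explained")
  attr(out, "var_explained_sigC2") <- attr(p2, "var_explained")
  class(out) <- c("cus_result", "data.frame")
  out
}

#' Dichotomize a score at a cutoff
#'
#' Scores strictly above the cutoff are `"high"`; scores at or below it are
#' `"low"` (ties go low).
#'
#' @param cus Numeric score vector.
#' @param cutoff Finite cutoff.
#' @return Factor with levels `low`, `high`.
#' @export
assign_cus_groups <- function(cus, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  factor(ifelse(cus > cutoff, "high", "low"), levels = c("low", "high"))
}
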