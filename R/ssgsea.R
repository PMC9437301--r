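#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression in decreasing order (ties
#' broken by ascending gene id so the output is deterministic across
#' platforms) and assigned rank weights `r^alpha`, where `r` is the rank
#' value (largest for the most highly expressed gene). Walking down the
#' ranked list, the enrichment score of a set is the sum over positions of
#' the difference between the cumulative weighted in-set fraction and the
#' cumulative uniform out-of-set fraction. With `normalize = TRUE` all
#' scores are divided by the range (max - min) of the whole score matrix.
#'
#' @param matrix Gene-by-sample expression matrix.
#' @param sets Named list of gene sets; sets with no gene in the matrix are
#'   an error (listed by name).
#' @param alpha Rank weighting exponent (>= 0), default 0.25.
#' @param normalize Rescale by the global score range.
#' @return Sample-by-set matrix of enrichment scores with attributes
#'   `alpha` and `normalized`.
#' @export
ssgsea_scores <- function(matrix, sets, alpha = 0.25, normalize = TRUE) {
  check_expression(matrix)
  if (!length(sets)) stop("empty gene set collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names")
  }
  if (alpha < 0) stop("alpha must be >= 0")
  genes <- rownames(matrix)
  overlap <- lapply(sets, intersect, genes)
  empty <- names(sets)[vapply(overlap, length, integer(1L)) == 0L]
  if (length(empty)) {
    stop("gene set(s) with no gene in the matrix: ", paste(empty, collapse = ", "))
  }
  n <- length(genes)
  es <- matrix(NA_real_, nrow = ncol(matrix), ncol = length(sets),
               dimnames = list(colnames(matrix), names(sets)))
  in_set <- vapply(overlap, function(s) genes %in% s, logical(n))
  for (j in seq_len(ncol(matrix))) {
    ord <- order(-matrix[, j], genes)           # desc expression, id tie-break
    rank_w <- (n:1)^alpha                       # weight of ordered position i
    for (s in seq_along(sets)) {
      inset <- in_set[ord, s]
      w <- rank_w * inset
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!inset) / (n - sum(inset))
      es[j, s] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  attr(es, "alpha") <- alpha
  attr(es, "normalized") <- normalize
  es
}

#' Stromal / immune / combined microenvironment scores
#'
#' Unnormalized ssGSEA enrichment of a stromal and an immune marker set;
#' the combined score is exactly their sum and tracks tumor purity
#' inversely.
#'
#' @param matrix Gene-by-sample expression matrix.
#' @param stromal_set,immune_set Character vectors of marker genes.
#' @param alpha Rank weighting exponent passed to [ssgsea_scores()].
#' @return data.frame with `sample`, `StromalScore`, `ImmuneScore`,
#'   `ESTIMATEScore`.
#' @export
estimate_scores <- function(matrix, stromal_set, immune_set, alpha = 0.25) {
  es <- ssgsea_scores(matrix,
                      list(stromal = stromal_set, immune = immune_set),
                      alpha = alpha, normalize = FALSE)
  data.frame(sample = rownames(es),
             StromalScore = es[, "stromal"],
             ImmuneScore = es[, "immune"],
             ESTIMATEScore = es[, "stromal"] + es[, "immune"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate a per-sample score with enrichment scores
#'
#' Pearson (or Spearman) correlation of one score vector against every
#' column of an enrichment-score matrix, with the two-sided t-distribution
#' p-value (df n - 2). Zero-variance inputs yield an `NA` row flagged in
#' `degenerate` rather than an error.
#'
#' @param x Named numeric per-sample score (e.g. the CUS).
#' @param scores Sample-by-set score matrix (rownames = samples).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame `geneset`, `r`, `p`, `significant`, `degenerate`.
#' @export
correlate_scores <- function(x, scores, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- intersect(names(x), rownames(scores))
  if (length(common) < 3L) stop("need >= 3 shared samples")
  x <- x[common]
  scores <- scores[common, , drop = FALSE]
  if (!all(is.finite(x)) || !all(is.finite(scores))) stop("non-finite values")
  res <- lapply(colnames(scores), function(s) {
    y <- scores[, s]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(geneset = s, r = NA_real_, p = NA_real_,
                        significant = NA, degenerate = TRUE))
    }
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    data.frame(geneset = s, r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < 0.05, degenerate = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
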