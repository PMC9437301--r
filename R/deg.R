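#' Moderated two-group differential expression
#'
#' Per gene: `logFC` is the mean of the second group minus the first, the
#' residual variance is pooled across both groups (df `d = nA + nB - 2`),
#' and an empirical-Bayes prior `(d0, s0^2)` on the variances is fitted by
#' method of moments on the log residual variances (trigamma inversion).
#' The posterior variance `(d0*s0^2 + d*s^2) / (d0 + d)` yields the
#' moderated t statistic with `d0 + d` degrees of freedom. Setting
#' `prior_df = 0` disables moderation (ordinary pooled t); `prior_df = Inf`
#' shrinks every gene fully to the common variance.
#'
#' @param matrix Gene-by-sample log-scale matrix.
#' @param labels Two-group factor over the samples (first level = reference;
#'   `logFC` = second level minus first).
#' @param prior_df Optional override of the estimated prior df `d0`.
#' @return data.frame `gene`, `logFC`, `t`, `p`, `adj_p`, `mean_A`,
#'   `mean_B`, sorted in input gene order, with attributes `prior_df` and
#'   `prior_var`.
#' @export
moderated_t_table <- function(matrix, labels, prior_df = NULL) {
  check_expression(matrix)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 groups")
  if (length(labels) != ncol(matrix)) stop("labels must match sample count")
  nA <- sum(labels == levels(labels)[1L])
  nB <- sum(labels == levels(labels)[2L])
  if (nA < 2L || nB < 2L) stop("each group needs >= 2 samples")

  a <- matrix[, labels == levels(labels)[1L], drop = FALSE]
  b <- matrix[, labels == levels(labels)[2L], drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  lfc <- mean_b - mean_a
  d <- nA + nB - 2L
  s2 <- (rowSums((a - mean_a)^2) + rowSums((b - mean_b)^2)) / d

  pos <- s2 > 0
  if (!any(pos)) stop("all genes have zero residual variance")
  e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
  e_var <- stats::var(e)
  tri_diff <- e_var - trigamma(d / 2)
  if (is.null(prior_df)) {
    d0 <- if (is.finite(tri_diff) && tri_diff > 0) 2 * trigamma_inverse(tri_diff) else Inf
  } else {
    d0 <- prior_df
  }
  s02 <- if (is.finite(d0) && d0 > 0) {
    exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    exp(mean(e))
  }

  s2_post <- if (d0 == 0) s2 else if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  tstat <- ifelse(se > 0, lfc / se, 0)
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[se == 0] <- 1   # zero variance everywhere and equal means

  out <- data.frame(gene = rownames(matrix), logFC = lfc, t = tstat, p = p,
                    adj_p = stats::p.adjust(p, method = "BH"),
                    mean_A = mean_a, mean_B = mean_b,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

# Newton solve of trigamma(x) = y (y > 0), as used for the variance prior
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Filter a differential-expression table to the screening rule
#'
#' Keeps genes with `|logFC| > lfc_thresh` AND `p < p_thresh` (strict
#' inequalities), ordered by ascending p-value. By default the raw p-value
#' column is used; `use_adjusted = TRUE` switches to the BH column.
#'
#' @param records Output of [moderated_t_table()].
#' @param lfc_thresh,p_thresh Thresholds (defaults 1.0 and 0.05).
#' @param use_adjusted Filter on `adj_p` instead of `p`.
#' @return Character vector of gene ids, ascending p order.
#' @export
filter_degs <- function(records, lfc_thresh = 1.0, p_thresh = 0.05,
                        use_adjusted = FALSE) {
  if (lfc_thresh <= 0) stop("lfc_thresh must be > 0")
  if (p_thresh <= 0 || p_thresh >= 1) stop("p_thresh must be in (0, 1)")
  if (!nrow(records)) return(character(0L))
  pv <- if (use_adjusted) records$adj_p else records$p
  keep <- abs(records$logFC) > lfc_thresh & pv < p_thresh
  records$gene[keep][order(pv[keep])]
}

#' Over-representation analysis (hypergeometric test)
#'
#' For each set, the upper hypergeometric tail `P(X >= k)` of the overlap
#' between the gene list and the set within the declared universe, with BH
#' adjustment across sets. The universe is the gene space the analysis can
#' observe (typically the expression matrix rows).
#'
#' @param genes Gene list (must be a subset of `universe`).
#' @param universe Background gene universe.
#' @param sets Named list of gene sets (intersected with the universe).
#' @return data.frame `set`, `k`, `K`, `n`, `N`, `p`, `adj_p`,
#'   `significant` sorted by adjusted p.
#' @export
ora_enrich <- function(genes, universe, sets) {
  outside <- setdiff(genes, universe)
  if (length(outside)) stop("gene(s) not in universe: ", paste(outside, collapse = ", "))
  if (!length(sets)) stop("empty gene set collection")
  N <- length(unique(universe))
  n <- length(unique(genes))
  res <- lapply(names(sets), function(nm) {
    set_u <- intersect(sets[[nm]], universe)
    K <- length(set_u)
    k <- length(intersect(set_u, genes))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$adj_p < 0.05
  out[order(out$adj_p, out$p), , drop = FALSE]
}

#' Two-sample rank-sum (Wilcoxon / Mann-Whitney) test
#'
#' Exact enumeration when the combined size is at most 12 and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return `list(U, p)` where `U` is the Mann-Whitney statistic for `x`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  exact <- (length(x) + length(y) <= 12L) && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Kruskal-Wallis test across two or more groups
#'
#' @param groups List of numeric vectors (each non-empty).
#' @return `list(H, df, p)`; all-identical values give `H = 0`, `p = 1`.
#' @export
kruskal_wallis_test <- function(groups) {
  if (length(groups) < 2L || any(!lengths(groups))) {
    stop("need >= 2 non-empty groups")
  }
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(vals, factor(rep(seq_along(groups), lengths(groups))))
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-[(Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl)]`.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Finite
#'   cycle-threshold values.
#' @return Fold change relative to the control condition.
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(vals))) stop("non-finite Ct value")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
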