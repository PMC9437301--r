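#' k-medoids (PAM) clustering
#'
#' Thin deterministic front end to the BUILD + SWAP k-medoids algorithm of
#' `cluster::pam()`, accepting either an observation matrix (Euclidean
#' distances) or a precomputed dissimilarity. The total cost (sum of
#' distances to the assigned medoid) is recomputed directly from the
#' returned medoids.
#'
#' @param x Numeric matrix (observations in rows) or a `dist` object.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Unused (PAM is deterministic); kept so callers can treat all
#'   clusterers uniformly.
#' @return `list(assignment, medoids, cost)`.
#' @export
pam_cluster <- function(x, k, seed = NULL) {
  d <- if (inherits(x, "dist")) x else stats::dist(x)
  if (any(is.na(d))) stop("NaN/NA distance")
  n <- attr(d, "Size")
  if (k > n) stop("k > number of observations")
  if (k == n) {
    dm <- as.matrix(d)
    return(list(assignment = seq_len(n), medoids = seq_len(n), cost = 0))
  }
  fit <- cluster::pam(d, k = k, diss = TRUE, cluster.only = FALSE,
                      keep.diss = FALSE, keep.data = FALSE)
  dm <- as.matrix(d)
  med <- as.integer(fit$id.med)
  assign <- apply(dm[, med, drop = FALSE], 1L, which.min)
  cost <- sum(dm[cbind(seq_len(n), med[assign])])
  list(assignment = as.integer(assign), medoids = med, cost = cost)
}

#' Resampled (Monti-style) consensus clustering
#'
#' For each of `reps` repetitions, a fraction `subsample` of the samples is
#' drawn without replacement, genes are z-scored on the subsample, and PAM
#' with Euclidean distances is run for every `k` in `2:kmax`. The consensus
#' matrix entry (i, j) is the co-clustering count divided by the
#' co-sampling count; pairs never co-sampled get consensus 0 (with a
#' warning when they exceed 1\% of pairs). The final assignment at each k is
#' an average-linkage agglomerative cut of `1 - consensus`. The proportion
#' of ambiguous clustering (PAC; consensus entries strictly inside
#' (0.1, 0.9)), the consensus CDF and the delta-area statistic are reported
#' per k.
#'
#' @param matrix Gene-by-sample expression matrix.
#' @param genes Optional gene subset to cluster on (e.g. the program genes).
#' @param kmax Largest number of clusters to evaluate (>= 2).
#' @param reps Number of resampling repetitions.
#' @param subsample Subsampling fraction in (0, 1].
#' @param seed Integer seed.
#' @param pac_bounds Lower/upper consensus bounds defining ambiguity.
#' @return An object of class `"consensus_result"`: per-k consensus
#'   matrices, assignments, PAC, CDF and delta-area, plus the chosen k under
#'   the min-PAC policy.
#' @export
consensus_cluster <- function(matrix, genes = NULL, kmax = 4L, reps = 50L,
                              subsample = 0.8, seed = 1L,
                              pac_bounds = c(0.1, 0.9)) {
  check_expression(matrix)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(matrix))
    if (length(missing)) stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
    matrix <- matrix[genes, , drop = FALSE]
  }
  if (nrow(matrix) < 2L) stop("need >= 2 genes to cluster on")
  n <- ncol(matrix)
  if (n < max(10L, kmax)) stop("need >= max(10, kmax) samples")
  if (subsample <= 0 || subsample > 1) stop("subsample must be in (0, 1]")
  if (reps < 1L) stop("reps must be >= 1")
  ks <- 2:kmax

  set.seed(seed)
  m_sub <- ceiling(subsample * n)
  together <- array(0, dim = c(n, n, length(ks)))
  sampled <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    idx <- sort(sample.int(n, m_sub))
    sampled[idx, idx] <- sampled[idx, idx] + 1
    sub <- matrix[, idx, drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    z <- (sub - rowMeans(sub)) / ifelse(sds > 0, sds, 1)
    d <- stats::dist(t(z))
    for (ki in seq_along(ks)) {
      cl <- pam_cluster(d, ks[ki])$assignment
      for (g in unique(cl)) {
        members <- idx[cl == g]
        together[members, members, ki] <- together[members, members, ki] + 1
      }
    }
  }
  never <- sampled == 0 & upper.tri(sampled)
  if (mean(never) > 0.01) {
    warning(sprintf("%.1f%% of sample pairs were never co-sampled (consensus 0)",
                    100 * mean(never)))
  }

  grid <- seq(0, 1, by = 0.01)
  per_k <- list()
  areas <- numeric(length(ks))
  for (ki in seq_along(ks)) {
    cons <- together[, , ki] / ifelse(sampled > 0, sampled, 1)
    cons[sampled == 0] <- 0
    diag(cons) <- 1
    cons <- (cons + t(cons)) / 2
    dimnames(cons) <- list(colnames(matrix), colnames(matrix))
    up <- cons[upper.tri(cons)]
    cdf <- vapply(grid, function(c0) mean(up <= c0), numeric(1L))
    areas[ki] <- sum(diff(grid) * cdf[-1L])
    pac <- mean(up > pac_bounds[1L] & up < pac_bounds[2L])
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    assign <- stats::cutree(hc, k = ks[ki])
    per_k[[ki]] <- list(k = ks[ki], consensus = cons, assignment = assign,
                        pac = pac, cdf = cdf, cdf_grid = grid)
  }
  delta <- c(areas[1L],
             if (length(areas) > 1L) diff(areas) / areas[-length(areas)])
  for (ki in seq_along(ks)) per_k[[ki]]$delta_area <- delta[ki]
  names(per_k) <- paste0("k", ks)

  res <- list(per_k = per_k, ks = ks, reps = reps, subsample = subsample,
              seed = seed, never_cosampled_frac = mean(never))
  class(res) <- "consensus_result"
  res$chosen_k <- choose_k(res)
  res
}

#' Select the number of clusters from a consensus result
#'
#' @param result A `"consensus_result"`.
#' @param policy `"min_pac"` (default): k with the smallest proportion of
#'   ambiguous consensus entries, ties to the smallest k. `"fixed"`: return
#'   `k` unchanged.
#' @param k Required when `policy = "fixed"`.
#' @return The selected integer k.
#' @export
choose_k <- function(result, policy = c("min_pac", "fixed"), k = NULL) {
  policy <- match.arg(policy)
  if (!inherits(result, "consensus_result") || !length(result$per_k)) {
    stop("empty consensus result")
  }
  if (policy == "fixed") {
    if (is.null(k)) stop("policy 'fixed' requires k")
    return(as.integer(k))
  }
  pac <- vapply(result$per_k, `[[`, numeric(1L), "pac")
  result$ks[which.min(pac)]   # which.min takes the first (smallest k) on ties
}

#' Final assignment at a given k
#'
#' @param result A `"consensus_result"`.
#' @param k Number of clusters; defaults to the chosen k.
#' @return Named integer vector of cluster labels.
#' @export
consensus_assignment <- function(result, k = result$chosen_k) {
  key <- paste0("k", k)
  if (!key %in% names(result$per_k)) stop("k = ", k, " not in the evaluated range")
  result$per_k[[key]]$assignment
}

#' @export
print.consensus_result <- function(x, ...) {
  pac <- vapply(x$per_k, `[[`, numeric(1L), "pac")
  cat("Consensus clustering:", x$reps, "reps, subsample", x$subsample, "\n")
  cat("  PAC by k:", paste(sprintf("k=%d: %.3f", x$ks, pac), collapse = ", "), "\n")
  cat("  chosen k (min-PAC):", x$chosen_k, "\n")
  invisible(x)
}
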