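# Independent oracles used across the suite. These deliberately re-derive
# every quantity with naive loops / enumeration, never through the package's
# own code paths.

# exhaustive k-medoids: best medoid subset by total distance
brute_force_pam <- function(dm, k) {
  n <- nrow(dm)
  combos <- utils::combn(n, k)
  best <- NULL
  best_cost <- Inf
  for (j in seq_len(ncol(combos))) {
    med <- combos[, j]
    cost <- sum(apply(dm[, med, drop = FALSE], 1L, min))
    if (cost < best_cost) {
      best_cost <- cost
      best <- med
    }
  }
  list(medoids = best, cost = best_cost)
}

# step-by-step ssGSEA running sum for one sample
hand_running_sum <- function(expr, set, alpha) {
  genes <- names(expr)
  ord <- order(-expr, genes)
  genes <- genes[ord]
  n <- length(genes)
  rank_val <- n:1
  inset <- genes %in% set
  w_in <- 0; w_out <- 0; es <- 0
  total_in <- sum(rank_val[inset]^alpha)
  total_out <- sum(!inset)
  for (i in seq_len(n)) {
    if (inset[i]) w_in <- w_in + rank_val[i]^alpha else w_out <- w_out + 1
    es <- es + (w_in / total_in - w_out / total_out)
  }
  es
}

# untied Cox partial log-likelihood for one covariate
cox_partial_loglik <- function(beta, time, event, x) {
  lp <- beta * x
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + lp[i] - log(sum(exp(lp[at_risk])))
  }
  ll
}

# two-group log-rank chi-square from first principles (O - E with
# hypergeometric variance at each distinct event time)
hand_logrank_chisq <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t0 in times) {
    at_risk <- time >= t0
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & group == 1L)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# naive loop implementation of the parametric EB batch-effect equations
naive_combat_eb <- function(mat, batch, tol = 1e-4, max_iter = 100) {
  batch <- as.factor(batch)
  n <- ncol(mat)
  levs <- levels(batch)
  nb <- sapply(levs, function(b) sum(batch == b))
  bm <- sapply(levs, function(b) rowMeans(mat[, batch == b, drop = FALSE]))
  grand <- as.vector(bm %*% (nb / n))
  v <- numeric(nrow(mat))
  for (g in seq_len(nrow(mat))) {
    r <- mat[g, ] - bm[g, as.integer(batch)]
    v[g] <- mean(r^2)
  }
  z <- (mat - grand) / sqrt(v)
  gam_hat <- sapply(levs, function(b) rowMeans(z[, batch == b, drop = FALSE]))
  del_hat <- sapply(levs, function(b) apply(z[, batch == b, drop = FALSE], 1, var))
  gam_star <- gam_hat; del_star <- del_hat
  for (j in seq_along(levs)) {
    gbar <- mean(gam_hat[, j]); t2 <- var(gam_hat[, j])
    m <- mean(del_hat[, j]); s2 <- var(del_hat[, j])
    a <- (2 * s2 + m^2) / s2
    b <- (m * s2 + m^3) / s2
    zj <- z[, batch == levs[j], drop = FALSE]
    g_old <- gam_hat[, j]; d_old <- del_hat[, j]
    for (it in seq_len(max_iter)) {
      g_new <- (nb[j] * t2 * gam_hat[, j] + d_old * gbar) / (nb[j] * t2 + d_old)
      d_new <- numeric(length(g_new))
      for (g in seq_along(g_new)) {
        d_new[g] <- (b + 0.5 * sum((zj[g, ] - g_new[g])^2)) /
          (nb[j] / 2 + a - 1)
      }
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (change < tol) break
    }
    gam_star[, j] <- g_old; del_star[, j] <- d_old
  }
  list(gamma_star = gam_star, delta_star = del_star)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# small, fast cohort configuration used where defaults would be overkill
small_config <- function(seed = 1, n_samples_per_batch = c(30L, 30L), ...) {
  sim_config(n_samples_per_batch = n_samples_per_batch, n_genes = 150L,
             n_immune_sets = 2L, immune_set_size = 5L,
             n_ref_samples = 60L, seed = seed, ...)
}

# two-batch, location-only batch-effect fixture: per-gene shifts ~ N(0, sd^2)
shifted_batches <- function(ng = 1000, nb = 500, shift_sd = 3, seed = 5) {
  set.seed(seed)
  m <- matrix(rnorm(ng * 2 * nb, 6, 1), nrow = ng,
              dimnames = list(sprintf("g%04d", seq_len(ng)),
                              sprintf("s%04d", seq_len(2 * nb))))
  batch <- rep(1:2, each = nb)
  m[, batch == 2] <- m[, batch == 2] + rnorm(ng, 0, shift_sd)
  list(m = m, batch = batch)
}

rand_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 6, 1), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}
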