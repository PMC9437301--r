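test_that("prior df 0 reduces the moderated t to the ordinary pooled t", {
  m <- rand_expr(50, 12, seed = 1)
  lab <- factor(rep(c("A", "B"), each = 6))
  tab <- moderated_t_table(m, lab, prior_df = 0)
  for (g in sample(rownames(m), 10)) {
    tt <- t.test(m[g, lab == "B"], m[g, lab == "A"], var.equal = TRUE)
    expect_equal(tab$t[tab$gene == g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab$p[tab$gene == g], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated statistics agree with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(8)
  m <- rand_expr(300, 10, seed = 8)
  lab <- factor(rep(c("A", "B"), each = 5))
  tab <- moderated_t_table(m, lab)
  design <- model.matrix(~lab)
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(tab, "prior_df"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(tab, "prior_var"), fit$s2.prior, tolerance = 1e-4)
  expect_equal(tab$t, fit$t[, 2], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(tab$p, fit$p.value[, 2], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("method of moments recovers a known variance prior", {
  set.seed(15)
  ng <- 5000; d0 <- 4; s02 <- 1
  sigma2 <- d0 * s02 / rchisq(ng, d0)
  n_per <- 4
  m <- matrix(rnorm(ng * 2 * n_per, 0, sqrt(rep(sigma2, 2 * n_per))),
              nrow = ng,
              dimnames = list(sprintf("g%05d", 1:ng),
                              sprintf("s%d", 1:(2 * n_per))))
  lab <- factor(rep(c("A", "B"), each = n_per))
  tab <- moderated_t_table(m, lab)
  expect_lt(abs(attr(tab, "prior_df") - d0), 1)
  expect_lt(abs(attr(tab, "prior_var") - s02) / s02, 0.1)
})

test_that("zero residual variance stays finite through moderation", {
  m <- rand_expr(100, 8, seed = 3)
  lab <- factor(rep(c("A", "B"), each = 4))
  m[1, ] <- rep(c(1, 2), each = 4)   # zero within-group variance, unequal means
  tab <- moderated_t_table(m, lab)
  expect_true(is.finite(tab$t[1]))
  expect_gt(abs(tab$t[1]), 0)
})

test_that("DEG filter applies strict thresholds in ascending p order", {
  rec <- data.frame(gene = paste0("g", 1:5),
                    logFC = c(2, 1.0, -1.5, 0.2, -3),
                    t = 0, p = c(0.01, 0.001, 0.04, 0.0001, 0.05),
                    adj_p = c(0.02, 0.002, 0.08, 0.0002, 0.1))
  # g2 fails |logFC| > 1 (not strict), g4 fails logFC, g5 fails p < 0.05
  expect_equal(filter_degs(rec), c("g1", "g3"))
  expect_equal(filter_degs(rec, use_adjusted = TRUE), "g1")
  expect_equal(filter_degs(rec[0, ]), character(0))
  expect_error(filter_degs(rec, lfc_thresh = 0), "lfc")
  expect_error(filter_degs(rec, p_thresh = 1), "p_thresh")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- paste0("u", 1:20)
  set5 <- universe[1:5]
  genes <- c(universe[1:4], universe[6])   # k = 4 of K = 5, n = 5
  out <- ora_enrich(genes, universe, list(s = set5))
  manual <- (choose(5, 4) * choose(15, 1) + choose(5, 5) * choose(15, 0)) /
    choose(20, 5)
  expect_equal(out$p, manual)          # 76 / 15504
  expect_equal(out$p, 76 / 15504)

  sat <- ora_enrich(universe, universe, list(s = set5))
  expect_equal(sat$k, sat$K)
  expect_equal(sat$p, 1)
  expect_error(ora_enrich(c("u1", "zz"), universe, list(s = set5)), "zz")
})

test_that("enrichment significance is flagged on the BH-adjusted column", {
  set.seed(2)
  universe <- paste0("u", 1:200)
  sets <- c(list(hot = universe[1:20]),
            lapply(1:10, function(i) sample(universe, 20)))
  names(sets)[-1] <- paste0("rand", 1:10)
  genes <- universe[1:15]
  out <- ora_enrich(genes, universe, sets)
  expect_identical(out$significant, out$adj_p < 0.05)
  expect_true(out$set[1] == "hot")
})

test_that("rank-sum exact and approximate p-values behave as enumeration says", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p, 2 / 6, tolerance = 1e-12)
  expect_equal(rank_sum_test(c(5, 1, 3), c(3, 1, 5))$p, 1)
  # approximation error on an untied 4 vs 4
  x <- c(1.2, 3.4, 2.2, 0.1); y <- c(4.5, 2.8, 6.1, 5.0)
  exact <- wilcox.test(x, y, exact = TRUE)$p.value
  x8 <- rep(x, 2) + 1e-9 * seq_len(8)   # untied 8 vs 8: approximate regime
  y8 <- rep(y, 2) + 2e-9 * seq_len(8)
  expect_lt(abs(rank_sum_test(x8, y8)$p -
                  wilcox.test(x8, y8, exact = TRUE)$p.value), 0.03)
  expect_lt(abs(rank_sum_test(x, y)$p - exact), 1e-12)  # still in exact regime
  expect_error(rank_sum_test(numeric(0), 1), "empty")
})

test_that("Kruskal-Wallis equals the squared rank-sum z for two groups", {
  set.seed(5)
  x <- rnorm(8); y <- rnorm(9)
  kw <- kruskal_wallis_test(list(x, y))
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  u <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(kw$H, z^2, tolerance = 1e-8)
  expect_equal(kruskal_wallis_test(list(c(1, 1), c(1, 1, 1)))$H, 0)
})

test_that("Kruskal-Wallis matches the hand rank formula for three groups", {
  g <- list(c(2.1, 3.3, 1.0), c(4.4, 5.5), c(0.5, 6.6, 7.7, 8.8))
  kw <- kruskal_wallis_test(g)
  r <- rank(unlist(g))
  N <- length(r)
  idx <- split(seq_len(N), rep(seq_along(g), lengths(g)))
  h <- 12 / (N * (N + 1)) *
    sum(vapply(idx, function(i) sum(r[i])^2 / length(i), numeric(1))) -
    3 * (N + 1)
  expect_equal(kw$H, h, tolerance = 1e-10)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(3)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.2, 1.4)), "outside")
})

test_that("ddCt fold changes follow the exponent identity", {
  expect_equal(ddct_fold_change(20, 18, 22, 20), 1.0)
  expect_equal(ddct_fold_change(19, 18, 22, 20), 2.0)
  expect_equal(ddct_fold_change(21, 18, 22, 20), 0.5)
  expect_error(ddct_fold_change(NA, 1, 1, 1), "finite")
})

test_that("signature genes dominate the DEG list on the synthetic cohort", {
  counts <- vapply(1:3, function(s) {
    sim <- simulate_cohort(sim_config(seed = s))
    lab <- factor(ifelse(sim$truth$subtype == 2, "B", "A"))
    tab <- moderated_t_table(sim$expr, lab)
    degs <- filter_degs(tab)
    length(intersect(degs, sim$truth$signature_genes))
  }, numeric(1))
  expect_gte(mean(counts), 27)
})
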