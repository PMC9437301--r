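test_that("signature split follows the association sign rule and is antisymmetric", {
  set.seed(1)
  n <- 60
  lab <- setNames(rep(c(1, 2), each = n / 2), paste0("s", 1:n))
  m <- rand_expr(10, n, seed = 1)
  colnames(m) <- names(lab)
  m["g001", lab == 1] <- m["g001", lab == 1] + 2   # up in reference cluster
  split <- split_signature(m, c("g001", "g002"), lab, reference_cluster = 1)
  expect_true("g001" %in% split$sigC1)

  m2 <- m
  m2["g001", ] <- -m2["g001", ]
  split2 <- split_signature(m2, c("g001", "g002"), lab, reference_cluster = 1)
  expect_true("g001" %in% split2$sigC2)

  mz <- m; mz["g002", ] <- 5
  expect_error(split_signature(mz, c("g001", "g002"), lab, 1), "zero-variance")
  expect_error(split_signature(m, "g001", setNames(rep(1, n), names(lab)), 1),
               "2 clusters")
})

test_that("split recovers the generator's association signs", {
  hits <- vapply(1:3, function(s) {
    sim <- simulate_cohort(sim_config(seed = s))
    truth <- sim$truth
    lab <- setNames(truth$subtype, names(truth$subtype))
    split <- split_signature(sim$expr, truth$signature_genes, lab,
                             reference_cluster = 2)  # suppressed-program subtype
    got <- sign(split$stat[truth$signature_genes])
    want <- ifelse(truth$signature_sign > 0, -1, 1)  # pos genes are DOWN in subtype 2
    sum(got == want)
  }, numeric(1))
  expect_gte(mean(hits), 29)
})

test_that("a perfect predictor is confirmed and obvious noise rejected", {
  set.seed(2)
  n <- 100
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- cbind(perfect = as.numeric(y) + rnorm(n, 0, 0.01),
             junk1 = rnorm(n), junk2 = rnorm(n), junk3 = rnorm(n))
  rep <- boruta_select(x, y, max_iter = 30, seed = 2)
  expect_equal(unname(rep$status["perfect"]), "confirmed")
  expect_true(all(rep$status[c("junk1", "junk2", "junk3")] != "confirmed"))
  expect_error(boruta_select(x, factor(rep("a", n)), seed = 1), "constant")
  expect_error(boruta_select(x, y, max_iter = 5), "max_iter")
})

test_that("informative features are confirmed alongside noise at cohort scale", {
  res <- lapply(1:2, function(s) {
    set.seed(s)
    n <- 200
    y <- factor(rep(c("a", "b"), each = n / 2))
    inf <- sapply(1:5, function(i) 2 * (as.numeric(y) - 1.5) + rnorm(n))
    noise <- matrix(rnorm(n * 50), n)
    x <- cbind(inf, noise)
    colnames(x) <- c(paste0("inf", 1:5), paste0("noise", 1:50))
    boruta_select(x, y, max_iter = 100, seed = s)
  })
  conf_inf <- vapply(res, function(r) sum(r$status[1:5] == "confirmed"),
                     numeric(1))
  rej_noise <- vapply(res, function(r) mean(r$status[6:55] == "rejected"),
                      numeric(1))
  expect_true(all(conf_inf == 5))
  expect_gte(mean(rej_noise), 0.9)
})

test_that("pure-noise panels are rejected at the calibrated rate", {
  # the far tail of fixed chance correlations is indistinguishable from weak
  # signal by any shadow comparison, so a small residue of confirmations is
  # expected; the bulk must be rejected
  res <- lapply(1:2, function(s) {
    set.seed(s + 100)
    x <- matrix(rnorm(200 * 50), 200, dimnames = list(NULL, paste0("n", 1:50)))
    y <- factor(rep(c("a", "b"), each = 100))
    boruta_select(x, y, max_iter = 100, seed = s)
  })
  rej <- vapply(res, function(r) mean(r$status == "rejected"), numeric(1))
  conf <- vapply(res, function(r) mean(r$status == "confirmed"), numeric(1))
  expect_gte(mean(rej), 0.85)
  expect_lte(mean(conf), 0.02)
})

test_that("Boruta runs are reproducible under a fixed seed", {
  set.seed(3)
  n <- 60
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  r1 <- boruta_select(x, y, max_iter = 15, seed = 7)
  r2 <- boruta_select(x, y, max_iter = 15, seed = 7)
  expect_identical(r1$status, r2$status)
  expect_identical(r1$hits, r2$hits)
})

test_that("PC1 scores reproduce an independent eigen-decomposition", {
  set.seed(4)
  m <- rand_expr(5, 10, seed = 4)
  score <- pc1_scores(m)
  z <- t(scale(t(m)))
  ev <- eigen(cov(t(z)))
  proj <- as.vector(t(z) %*% ev$vectors[, 1])
  # align sign, then compare; cov() uses n-1, svd-based scores are the same space
  if (cor(proj, score) < 0) proj <- -proj
  expect_equal(unname(score), proj, tolerance = 1e-8, ignore_attr = TRUE)
  expect_gte(cor(score, colMeans(z)), 0)
  expect_equal(attr(score, "var_explained"),
               ev$values[1] / sum(ev$values), tolerance = 1e-8)
})

test_that("rank-1 input gives 100% explained variance and proportional scores", {
  u <- c(1, -2, 0.5)
  v <- rnorm(12)
  m <- outer(u, v) + 5
  dimnames(m) <- list(paste0("g", 1:3), paste0("s", 1:12))
  score <- pc1_scores(m)
  expect_equal(attr(score, "var_explained"), 1, tolerance = 1e-10)
  expect_gt(abs(cor(score, v)), 1 - 1e-10)
  single <- pc1_scores(m, "g1")
  expect_equal(unname(single), as.vector(scale(m["g1", ])), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("CUS obeys its defining identity and degenerate form", {
  sim <- simulate_cohort(small_config(seed = 5))
  genes <- sim$truth$signature_genes
  lab <- sim$truth$subtype
  split <- split_signature(sim$expr, genes, lab, reference_cluster = 2)
  cus <- compute_cus(sim$expr, split)
  expect_equal(cus$CUS, cus$PsigC1 - cus$PsigC2, tolerance = 1e-12)

  only1 <- split; only1$sigC2 <- character(0)
  cus1 <- compute_cus(sim$expr, only1)
  expect_equal(cus1$CUS, cus1$PsigC1)

  swapped <- split
  swapped$sigC1 <- split$sigC2; swapped$sigC2 <- split$sigC1
  cus_sw <- compute_cus(sim$expr, swapped)
  expect_equal(cus_sw$CUS, -cus$CUS, tolerance = 1e-10)
})

test_that("CUS is invariant to gene-wise affine rescaling", {
  sim <- simulate_cohort(small_config(seed = 6))
  split <- split_signature(sim$expr, sim$truth$signature_genes,
                           sim$truth$subtype, reference_cluster = 2)
  cus <- compute_cus(sim$expr, split)
  m2 <- sim$expr * rep(runif(nrow(sim$expr), 0.5, 3), ncol(sim$expr)) +
    rep(rnorm(nrow(sim$expr)), ncol(sim$expr))
  cus2 <- compute_cus(m2, split)
  expect_equal(cus2$CUS, cus$CUS, tolerance = 1e-8)
})

test_that("Boruta filtering respects tentative handling and empty-set errors", {
  sim <- simulate_cohort(small_config(seed = 7))
  split <- split_signature(sim$expr, sim$truth$signature_genes,
                           sim$truth$subtype, reference_cluster = 2)
  fake <- list(status = setNames(rep("rejected", 31),
                                 sim$truth$signature_genes))
  class(fake) <- "boruta_report"
  expect_error(compute_cus(sim$expr, split, boruta = fake), "sigC1")
  fake$status[split$sigC1] <- "confirmed"
  fake$status[split$sigC2] <- "tentative"
  cus_keep <- compute_cus(sim$expr, split, boruta = fake, keep_tentative = TRUE)
  expect_false(all(cus_keep$PsigC2 == 0))
  expect_error(compute_cus(sim$expr, split, boruta = fake,
                           keep_tentative = FALSE), "sigC2")
})

test_that("group assignment sends exact ties to the low group", {
  g <- assign_cus_groups(c(-1, 0, 0.5), cutoff = 0)
  expect_equal(as.character(g), c("low", "low", "high"))
  expect_true(all(assign_cus_groups(c(1, 2), 0) == "high"))
  expect_error(assign_cus_groups(1:3, NA), "finite")
})
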