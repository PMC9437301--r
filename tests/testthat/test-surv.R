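test_that("mirrored groups give a null Cox coefficient", {
  time <- rep(c(3, 6, 9, 12, 15), 2)
  event <- rep(c(1, 0, 1, 1, 0), 2)
  x <- rep(c(0, 1), each = 5)
  fit <- cox_fit_univariate(time, event, x)
  expect_equal(fit$beta, 0, tolerance = 1e-8)
  expect_equal(fit$hr, 1, tolerance = 1e-8)
  expect_error(cox_fit_univariate(time, event, rep(1, 10)), "constant")
})

test_that("Cox beta maximizes the explicit partial likelihood (n = 8, untied)", {
  set.seed(4)
  for (rep in 1:3) {
    time <- sort(rexp(8)) * 100
    event <- rep(1, 8)
    x <- rnorm(8)
    fit <- cox_fit_univariate(time, event, x)
    oracle <- optimize(function(b) cox_partial_loglik(b, time, event, x),
                       interval = c(-10, 10), maximum = TRUE, tol = 1e-8)
    expect_equal(fit$beta, oracle$maximum, tolerance = 1e-4)
  }
})

test_that("Cox coefficient is scale-equivariant", {
  set.seed(6)
  time <- rexp(40, 0.01); event <- rbinom(40, 1, 0.7); x <- rnorm(40)
  b1 <- cox_fit_univariate(time, event, x)$beta
  b5 <- cox_fit_univariate(time, event, 5 * x)$beta
  expect_equal(b5, b1 / 5, tolerance = 1e-8)
})

test_that("perfect separation is capped and flagged, not fatal", {
  time <- c(1, 2, 3, 4, 50, 60, 70, 80, 90, 100)
  event <- rep(1, 10)
  x <- c(rep(1, 4), rep(0, 6))
  expect_warning(fit <- cox_fit_univariate(time, event, x), "monotone")
  expect_equal(abs(fit$beta), 15)
  expect_true(fit$monotone)
})

test_that("prognostic screens apply their rules, including the protective-gene rule", {
  set.seed(9)
  n <- 200
  prot <- rnorm(n)                  # strong protective covariate
  null_g <- rnorm(n)
  rate <- 0.01 * exp(-1.2 * prot)
  time <- rexp(n, rate)
  event <- as.integer(time < quantile(time, 0.8))
  time <- pmin(time, quantile(time, 0.8))
  m <- rbind(prot = prot, null = null_g)
  colnames(m) <- paste0("s", 1:n)
  cl <- data.frame(sample = colnames(m), time = time, event = event)
  out <- screen_prognostic(m, cl, rule = "potential_cpg")
  expect_true("prot" %in% out$kept)
  expect_false("null" %in% out$kept)
  expect_true(all(out$table$hr > 0))
  empty <- screen_prognostic(m, cl, genes = character(0))
  expect_length(empty$kept, 0)
  expect_error(screen_prognostic(m, cl, rule = "nope"))
})

test_that("Kaplan-Meier estimates follow the product-limit by hand", {
  none <- km_curve(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(none$surv == 1))
  all_ev <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(all_ev$surv, c(2 / 3, 1 / 3, 0))
  mixed <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(mixed$surv[mixed$time == 1], 2 / 3)
  expect_equal(mixed$surv[mixed$time == 3], 0)
  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
})

test_that("pooled KM curve lies within the groupwise envelope", {
  set.seed(11)
  t1 <- rexp(30, 0.02); t2 <- rexp(30, 0.08)
  e1 <- rbinom(30, 1, 0.8); e2 <- rbinom(30, 1, 0.8)
  pool <- km_curve(c(t1, t2), c(e1, e2))
  k1 <- km_curve(t1, e1); k2 <- km_curve(t2, e2)
  step_at <- function(km, t0) {
    s <- c(1, km$surv)[findInterval(t0, km$time) + 1]
    s
  }
  for (t0 in pool$time) {
    lo <- min(step_at(k1, t0), step_at(k2, t0))
    hi <- max(step_at(k1, t0), step_at(k2, t0))
    expect_gte(step_at(pool, t0), lo - 1e-12)
    expect_lte(step_at(pool, t0), hi + 1e-12)
  }
})

test_that("log-rank chi-square matches the O-E/V evaluation by hand", {
  expect_equal(logrank_test(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2),
                            rep(c("a", "b"), each = 3))$chisq, 0,
               tolerance = 1e-12)
  time <- c(1, 2, 3, 4); event <- rep(1, 4); grp <- c("a", "a", "b", "b")
  lt <- logrank_test(time, event, grp)
  expect_equal(lt$chisq, hand_logrank_chisq(time, event, grp),
               tolerance = 1e-10)
  set.seed(13)
  t2 <- rexp(40); e2 <- rbinom(40, 1, 0.7); g2 <- rep(c("x", "y"), 20)
  expect_equal(logrank_test(t2, e2, g2)$chisq,
               hand_logrank_chisq(t2, e2, g2), tolerance = 1e-8)
  expect_error(logrank_test(t2, e2, rep("x", 40)), "2 groups")
})

test_that("cutpoint search equals an exhaustive scan with an independent log-rank", {
  set.seed(17)
  for (rep in 1:3) {
    score <- rnorm(20)
    time <- rexp(20, 0.05)
    event <- rbinom(20, 1, 0.8)
    if (sum(event) < 3) event[1:3] <- 1
    cp <- optimal_cutpoint(score, time, event, minprop = 0.1)
    u <- sort(unique(score))
    mids <- (u[-1] + u[-length(u)]) / 2
    feas <- sapply(mids, function(c0) min(sum(score <= c0), sum(score > c0)) >= 2)
    stats <- sapply(mids[feas], function(c0) {
      sqrt(hand_logrank_chisq(time, event, score > c0))
    })
    expect_equal(cp$cutoff, mids[feas][which.max(stats)], tolerance = 1e-12)
    expect_equal(cp$statistic, max(stats), tolerance = 1e-8)
  }
})

test_that("cutpoint recovers a separating gap to within boundary samples", {
  # with two separated hazard regimes the argmax split can sit one or two
  # boundary samples off the gap (the variance term rewards mild imbalance),
  # so the recovered partition is asserted up to 2 samples
  for (s in 1:5) {
    set.seed(s)
    n <- 60
    score <- c(runif(n / 2, 0, 1), runif(n / 2, 3, 4))
    time <- c(rexp(n / 2, 0.01), rexp(n / 2, 0.6))
    cens <- rexp(n, 0.002)
    event <- as.integer(time <= cens)
    time <- pmin(time, cens)
    cp <- optimal_cutpoint(score, time, event)
    gap_partition <- score > 2
    got_partition <- score > cp$cutoff
    expect_lte(sum(gap_partition != got_partition), 2)

    cp2 <- optimal_cutpoint(exp(score), time, event)
    expect_equal(sum(score > cp$cutoff), sum(exp(score) > cp2$cutoff))
    expect_equal(cp2$statistic, cp$statistic, tolerance = 1e-10)
  }
  expect_error(optimal_cutpoint(rep(1, 60), rexp(60), rbinom(60, 1, 0.5)),
               "constant")
})

test_that("maximally selected statistics are anticonservative under the null", {
  set.seed(23)
  n <- 20
  crit <- qchisq(0.95, 1)
  exceed <- vapply(1:2000, function(i) {
    score <- rnorm(n)
    time <- rexp(n, 0.05)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 2) event[1:2] <- 1
    cp <- try(optimal_cutpoint(score, time, event), silent = TRUE)
    if (inherits(cp, "try-error")) return(NA)
    cp$statistic^2 > crit
  }, logical(1))
  expect_gte(mean(exceed, na.rm = TRUE), 0.15)
})

test_that("contingency chi-square follows the 2x2 closed form", {
  tab <- rbind(c(20, 30), c(30, 20))
  out <- chi_square_2xk(tab)
  n <- sum(tab)
  closed <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  expect_equal(out$chisq, closed)
  expect_equal(out$chisq, 4.0)
  expect_equal(chi_square_2xk(rbind(c(10, 20), c(20, 40)))$chisq, 0,
               tolerance = 1e-12)
  expect_error(chi_square_2xk(rbind(c(1, 0), c(2, 0))), "margin")
})
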