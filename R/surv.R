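#' Univariate Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the partial likelihood (via
#' `survival::coxph`) with Efron handling of tied event times by default.
#' Monotone partial likelihood (perfect separation) is detected by a runaway
#' coefficient; the coefficient is capped at |beta| = 15 and flagged rather
#' than failing, so genome-wide screens complete.
#'
#' @param time,event Survival time (> 0) and 0/1 event flag.
#' @param covariate Numeric covariate (non-constant).
#' @param name Covariate name carried into the output.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return One-row data.frame: `name`, `beta`, `hr`, `ci_low`, `ci_high`,
#'   `z`, `p`, `n`, `events`, `monotone`.
#' @export
cox_fit_univariate <- function(time, event, covariate, name = "covariate",
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(unique(covariate)) < 2L) stop("constant covariate")
  if (sum(event) < 1L) stop("no events")
  # coxph warns about possibly-infinite coefficients itself; monotone
  # likelihood is detected and flagged below instead
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ covariate, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50L)))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  monotone <- !is.finite(beta) || abs(beta) > 15
  if (monotone) {
    warning("monotone partial likelihood for '", name, "': beta capped at 15")
    beta <- sign(beta) * 15
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(name = name, beta = beta, hr = exp(beta),
             ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
             z = z, p = p, n = length(time), events = sum(event),
             monotone = monotone, row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen genes for prognostic significance by univariate Cox regression
#'
#' Fits one Cox model per gene on its expression. Rule `"csrg"` keeps genes
#' with p < 0.05 (the subtype-related-gene screen); rule `"potential_cpg"`
#' keeps protective genes with p < 0.001 and 1 - HR > 0.4 (i.e. HR < 0.6).
#'
#' @param matrix Gene-by-sample expression matrix.
#' @param clinical Clinical table with `sample`, `time`, `event`.
#' @param rule `"csrg"` or `"potential_cpg"`.
#' @param genes Optional gene subset to screen.
#' @return `list(kept, table)`: the gene ids passing the rule and the full
#'   per-gene Cox table.
#' @export
screen_prognostic <- function(matrix, clinical, rule = c("csrg", "potential_cpg"),
                              genes = NULL) {
  rule <- match.arg(rule)
  if (is.null(genes)) genes <- rownames(matrix)
  if (!length(genes)) {
    return(list(kept = character(0L),
                table = data.frame(name = character(0L))))
  }
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing)) stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  common <- intersect(colnames(matrix), clinical$sample)
  cl <- clinical[match(common, clinical$sample), , drop = FALSE]
  rows <- lapply(genes, function(g) {
    cox_fit_univariate(cl$time, cl$event, matrix[g, common], name = g)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  kept <- switch(rule,
                 csrg = tab$name[tab$p < 0.05],
                 potential_cpg = tab$name[tab$p < 0.001 & (1 - tab$hr) > 0.4])
  list(kept = kept, table = tab)
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate with Greenwood standard errors via
#' `survival::survfit`; at tied times events precede censorings.
#'
#' @param time,event Survival data (times > 0).
#' @return data.frame `time`, `n_risk`, `n_event`, `surv`, `std_err` of
#'   class `"km_curve"`.
#' @export
km_curve <- function(time, event) {
  if (any(time < 0)) stop("negative survival time")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    surv = sf$surv, std_err = sf$surv * sf$std.err)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test across groups
#'
#' Observed-minus-expected events with hypergeometric variance at each
#' distinct event time (`survival::survdiff`), chi-square with g - 1 df.
#'
#' @param time,event Survival data.
#' @param groups Group label per subject (>= 2 non-empty groups).
#' @return `list(chisq, df, p)`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) == 0L)) stop("group with zero subjects")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Survival-optimal cutpoint by maximally selected log-rank statistic
#'
#' Scans every midpoint between consecutive sorted unique score values
#' whose induced split leaves both groups with at least
#' `ceiling(minprop * n)` samples and returns the cutoff maximizing the
#' standardized log-rank statistic (ties broken towards the lower cutoff).
#' Because the statistic is maximized over many candidate splits, the
#' implied log-rank p-value is selection-inflated and is reported as
#' descriptive only.
#'
#' @param score Non-constant numeric score.
#' @param time,event Survival data.
#' @param minprop Minimum group fraction (default 0.1).
#' @return `list(cutoff, statistic, candidates, minprop)` of class
#'   `"cutpoint_result"`; `statistic` is the standardized (square-root
#'   chi-square) log-rank statistic at the cutoff.
#' @export
optimal_cutpoint <- function(score, time, event, minprop = 0.1) {
  n <- length(score)
  if (length(unique(score)) < 2L) stop("constant score")
  if (ceiling(minprop * n) < 1L) stop("minprop too small")
  u <- sort(unique(score))
  mids <- (u[-1L] + u[-length(u)]) / 2
  min_n <- ceiling(minprop * n)
  feasible <- vapply(mids, function(c0) {
    nlow <- sum(score <= c0)
    nlow >= min_n && (n - nlow) >= min_n
  }, logical(1L))
  mids <- mids[feasible]
  if (!length(mids)) stop("no feasible split under minprop")
  stat <- vapply(mids, function(c0) {
    grp <- score > c0
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    sqrt(unname(sd$chisq))
  }, numeric(1L))
  best <- which.max(stat)   # first (lowest cutoff) on exact ties
  out <- list(cutoff = mids[best], statistic = stat[best],
              candidates = data.frame(cutoff = mids, statistic = stat),
              minprop = minprop)
  class(out) <- "cutpoint_result"
  out
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("Optimal survival cutpoint:", format(x$cutoff, digits = 7), "\n")
  cat("  standardized log-rank statistic:", format(x$statistic, digits = 4),
      "(descriptive; maximally selected)\n")
  cat("  candidates scanned:", nrow(x$candidates), " minprop:", x$minprop, "\n")
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' @param counts Matrix of non-negative integer counts without an all-zero
#'   row or column.
#' @param correct Apply the Yates continuity correction (2x2 only);
#'   default off.
#' @return `list(chisq, df, p)`.
#' @export
chi_square_2xk <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all-zero row or column margin")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}
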