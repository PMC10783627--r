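#' Signal-to-noise ratio in dB
#'
#' SNR of a delivered-power or reflectance trace defined as
#' `mean^2 / SD^2`, reported as `10 * log10(mean^2 / SD^2)` dB (equivalently
#' `20 * log10(mean / SD)`). The SD uses the n - 1 denominator.
#'
#' @param values Numeric vector (n >= 2), or a [signal_trace()].
#' @return SNR in dB; `-Inf` (with a warning) when the mean is zero.
#' @examples
#' snr_db(c(2, 2.2, 1.8))   # mean 2, sd 0.2 -> 20 dB
#' @export
snr_db <- function(values) {
  if (inherits(values, "signal_trace")) values <- values$values
  if (length(values) < 2L) stop("need at least two samples")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance")
  m <- mean(values)
  if (m == 0) {
    warning("zero mean; SNR is -Inf")
    return(-Inf)
  }
  10 * log10(m^2 / s^2)
}

#' Coefficient of variation
#'
#' `SD / mean` with the n - 1 SD denominator; scale invariant for positive
#' scalings.
#'
#' @param values Numeric vector (n >= 2) with nonzero mean.
#' @return CV as a fraction.
#' @examples
#' coefficient_of_variation(c(9, 10, 11))  # 0.1
#' @export
coefficient_of_variation <- function(values) {
  if (inherits(values, "signal_trace")) values <- values$values
  if (length(values) < 2L) stop("need at least two samples")
  m <- mean(values)
  if (m == 0) stop("zero mean")
  stats::sd(values) / m
}

#' Bland-Altman method-agreement analysis
#'
#' For paired latency measurements by two methods, plots (conceptually)
#' the per-trial difference `method1 - method2` against the per-trial
#' average. Fixed bias is assessed by a one-sample t test of the mean
#' difference against zero; proportional bias by the least-squares
#' regression of difference on average (with a t test of the slope against
#' zero) and its 95 % prediction band. The regression line can be evaluated
#' at query averages to express the practical size of a proportional bias.
#'
#' @param m1,m2 Paired measurements (same length, n >= 3), method 1 and 2.
#' @param query_avgs Optional averages (ms) at which to evaluate the fitted
#'   difference.
#' @param conf Confidence level for tests and the prediction band
#'   (default 0.95).
#' @return An object of class `agreement_report`: per-pair `differences`
#'   and `averages`; `mean_diff` with `fixed_bias` test (t, df, p);
#'   `slope`, `intercept` and `slope_test`; `band` (data.frame with the
#'   fit and prediction interval over the observed averages); `query`
#'   (data.frame of predicted differences at `query_avgs`); `degenerate`
#'   flag when all averages coincide (slope undefined).
#' @export
bland_altman <- function(m1, m2, query_avgs = NULL, conf = 0.95) {
  if (length(m1) != length(m2)) stop("m1 and m2 must be paired")
  if (length(m1) < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(m1)) || !all(is.finite(m2))) stop("values must be finite")
  d <- m1 - m2
  a <- (m1 + m2) / 2
  tt <- if (stats::sd(d) > 0) stats::t.test(d, mu = 0, conf.level = conf) else NULL
  fixed_bias <- list(
    t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    df = length(d) - 1,
    p = if (is.null(tt)) if (mean(d) == 0) 1 else 0 else tt$p.value)
  degenerate <- isTRUE(all.equal(stats::var(a), 0)) || stats::var(a) == 0
  if (degenerate) {
    fit <- NULL
    slope <- NA_real_
    intercept <- mean(d)
    slope_test <- list(t = NA_real_, df = NA_real_, p = NA_real_)
    band <- NULL
    query <- NULL
  } else {
    fit <- stats::lm(d ~ a)
    cf <- stats::coef(fit)
    intercept <- unname(cf[1])
    slope <- unname(cf[2])
    sm <- suppressWarnings(stats::summary.lm(fit))$coefficients
    slope_test <- list(t = sm[2, "t value"], df = fit$df.residual,
                       p = sm[2, "Pr(>|t|)"])
    grid <- data.frame(a = seq(min(a), max(a), length.out = 100))
    pb <- stats::predict(fit, newdata = grid, interval = "prediction",
                         level = conf)
    band <- cbind(average = grid$a, as.data.frame(pb))
    names(band) <- c("average", "fit", "lower", "upper")
    query <- if (!is.null(query_avgs)) {
      data.frame(average = query_avgs,
                 predicted_diff = unname(
                   stats::predict(fit, newdata = data.frame(a = query_avgs))))
    } else NULL
  }
  structure(list(differences = d, averages = a, mean_diff = mean(d),
                 fixed_bias = fixed_bias, slope = slope,
                 intercept = intercept, slope_test = slope_test,
                 band = band, query = query, degenerate = degenerate,
                 conf = conf, fit = fit),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d pairs\n", length(x$differences)))
  cat(sprintf("  mean difference %.3f ms (fixed-bias t = %.3f, p = %.3g)\n",
              x$mean_diff, x$fixed_bias$t, x$fixed_bias$p))
  if (!x$degenerate) {
    cat(sprintf("  difference ~ average: slope %.4g (t = %.3f, p = %.3g)\n",
                x$slope, x$slope_test$t, x$slope_test$p))
  } else {
    cat("  slope undefined: all averages identical\n")
  }
  if (!is.null(x$query)) {
    for (i in seq_len(nrow(x$query))) {
      cat(sprintf("  predicted difference at %g ms: %.3f ms\n",
                  x$query$average[i], x$query$predicted_diff[i]))
    }
  }
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x An `agreement_report`.
#' @param ... Passed to [plot()].
#' @export
plot.agreement_report <- function(x, ...) {
  plot(x$averages, x$differences, xlab = "average of methods (ms)",
       ylab = "difference between methods (ms)", pch = 16, ...)
  graphics::abline(h = 0, lty = 3)
  if (!x$degenerate) {
    graphics::lines(x$band$average, x$band$fit, col = "darkgreen")
    graphics::lines(x$band$average, x$band$lower, col = "darkgreen", lty = 2)
    graphics::lines(x$band$average, x$band$upper, col = "darkgreen", lty = 2)
  }
  invisible(x)
}

#' Classify withdrawal latencies as fast or slow
#'
#' Bimodal pulse-evoked latencies split at the `cutoff` (default 75 ms):
#' fast responses are strictly below the cutoff, slow responses at or above
#' it (an exactly-75 ms latency is classed slow). With a grouping factor,
#' also returns the per-group contingency counts suitable for a chi-square
#' test of proportions.
#'
#' @param latencies Positive latencies in ms.
#' @param cutoff Class boundary in ms (default 75).
#' @param group Optional per-trial grouping (e.g. stimulus intensity).
#' @return A list: `labels` (factor `fast`/`slow`), `counts` (2-column
#'   matrix of per-group counts, or overall counts when `group` is NULL),
#'   and `degenerate` (TRUE when one class is empty).
#' @export
classify_fast_slow <- function(latencies, cutoff = 75, group = NULL) {
  if (any(latencies <= 0)) stop("latencies must be positive")
  labels <- factor(ifelse(latencies < cutoff, "fast", "slow"),
                   levels = c("fast", "slow"))
  counts <- if (is.null(group)) {
    t(as.matrix(table(labels)))
  } else {
    as.matrix(table(group, labels))
  }
  list(labels = labels, counts = counts,
       degenerate = any(colSums(counts) == 0))
}

#' Pearson chi-square test of proportions
#'
#' Pearson chi-square on a contingency table, without continuity
#' correction, df = (r - 1)(c - 1).
#'
#' @param counts Matrix of non-negative integer counts, >= 2 rows and
#'   columns.
#' @return A list with `statistic`, `df` and `p`.
#' @export
chi2_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("need at least a 2 x 2 table")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) stop("expected count of zero; drop empty rows/columns")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Power-law stimulus-response fit
#'
#' Fits `y = a * x^b` by ordinary least squares of `log10(y)` on
#' `log10(x)` (a linear regression on log axes), so `a = 10^intercept` and
#' `b` is the slope.
#'
#' @param x,y Strictly positive vectors, n >= 3.
#' @return An object of class `power_law_fit` with `a`, `b`, `fit` (the
#'   underlying `lm`), `domain` (range of x) and `r_squared`.
#' @export
fit_power_law <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (any(x <= 0) || any(y <= 0)) stop("x and y must be strictly positive")
  lx <- log10(x); ly <- log10(y)
  fit <- stats::lm(ly ~ lx)
  cf <- stats::coef(fit)
  structure(list(a = unname(10^cf[1]), b = unname(cf[2]), fit = fit,
                 domain = range(x),
                 r_squared = suppressWarnings(stats::summary.lm(fit))$r.squared),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4g (R^2 = %.4f)\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  object$a * newdata^object$b
}

#' Psychometric function fit and 50 % withdrawal threshold
#'
#' Fits a logistic sigmoid in log intensity to binary withdrawal outcomes
#' by maximum likelihood and reports the threshold: the intensity at which
#' the fitted probability of withdrawal is 50 %.
#'
#' @param intensities Stimulus intensities (> 0), one per trial.
#' @param outcomes Binary withdrawal outcomes (0/1 or logical).
#' @return An object of class `psychometric_fit`: `threshold` (intensity at
#'   p = 0.5; `NA` with `flag = "undefined"` when all outcomes are equal),
#'   `coef` (intercept and slope on log intensity), `fit`, `extrapolated`
#'   (TRUE when the threshold lies outside the tested range), `separation`
#'   (TRUE when the data were completely separated), and the input summary
#'   `table` (per-intensity response probabilities).
#' @export
fit_psychometric <- function(intensities, outcomes) {
  if (length(intensities) != length(outcomes)) {
    stop("intensities and outcomes must be the same length")
  }
  if (any(intensities <= 0)) stop("intensities must be > 0")
  outcomes <- as.numeric(outcomes)
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary")
  if (length(unique(intensities)) < 2L) {
    stop("need at least 2 distinct intensities")
  }
  tab <- stats::aggregate(list(p = outcomes),
                          by = list(intensity = intensities), FUN = mean)
  tab$n <- as.vector(table(intensities)[as.character(tab$intensity)])
  if (all(outcomes == 0) || all(outcomes == 1)) {
    return(structure(list(threshold = NA_real_, coef = c(NA_real_, NA_real_),
                          fit = NULL, extrapolated = NA, separation = FALSE,
                          flag = "undefined", table = tab),
                     class = "psychometric_fit"))
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcomes ~ log(intensities), family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("did not converge", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  threshold <- if (cf[2] > 0) unname(exp(-cf[1] / cf[2])) else NA_real_
  extrapolated <- !is.na(threshold) &&
    (threshold < min(intensities) || threshold > max(intensities))
  structure(list(threshold = threshold, coef = unname(cf), fit = fit,
                 extrapolated = extrapolated, separation = separation,
                 flag = if (is.na(threshold)) "non-increasing" else "ok",
                 table = tab),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat(sprintf("<psychometric_fit> threshold undefined (%s)\n", x$flag))
  } else {
    cat(sprintf("<psychometric_fit> threshold %.4g (p = 0.5)%s%s\n",
                x$threshold,
                if (x$extrapolated) ", extrapolated" else "",
                if (x$separation) ", complete separation" else ""))
  }
  invisible(x)
}

#' Compare latency distributions between two groups
#'
#' Pooled-trial empirical distributions are compared with a two-sample
#' Kolmogorov-Smirnov test; within-animal variability is summarized by the
#' intra-unit coefficient of variation (SD/mean per unit) and compared
#' between groups with a two-sample t test.
#'
#' @param groupA,groupB Data frames with columns `unit` and `latency`.
#' @return A list: `ks` (`D`, `p`), `cv_A`, `cv_B` (named per-unit CVs),
#'   `cv_test` (`t`, `df`, `p`), and `excluded` (units dropped for having
#'   fewer than 2 trials, with a warning).
#' @export
compare_latency_distributions <- function(groupA, groupB) {
  check_group <- function(g, nm) {
    if (!all(c("unit", "latency") %in% names(g))) {
      stop(nm, " must have columns 'unit' and 'latency'")
    }
    g
  }
  groupA <- check_group(groupA, "groupA")
  groupB <- check_group(groupB, "groupB")
  per_unit <- function(g) {
    counts <- table(g$unit)
    bad <- names(counts)[counts < 2]
    if (length(bad) > 0) {
      warning("excluding units with < 2 trials: ",
              paste(bad, collapse = ", "))
      g <- g[!(g$unit %in% bad), , drop = FALSE]
    }
    cvs <- vapply(split(g$latency, g$unit), coefficient_of_variation,
                  numeric(1))
    list(g = g, cvs = cvs, excluded = bad)
  }
  ua <- per_unit(groupA)
  ub <- per_unit(groupB)
  if (length(ua$cvs) < 2L || length(ub$cvs) < 2L) {
    stop("each group needs at least 2 units with >= 2 trials")
  }
  ks <- suppressWarnings(stats::ks.test(ua$g$latency, ub$g$latency))
  tt <- stats::t.test(ua$cvs, ub$cvs)
  list(ks = list(D = unname(ks$statistic), p = ks$p.value),
       cv_A = ua$cvs, cv_B = ub$cvs,
       cv_test = list(t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value),
       excluded = c(ua$excluded, ub$excluded))
}

#' Association between post-stimulus behavior and withdrawal latency
#'
#' Tests whether a non-reflexive behavior (licking, guarding, flinching)
#' relates to the latency of the preceding withdrawal: logistic regression
#' of an occurrence flag on latency, or linear regression of a behavior
#' duration on latency. The slope's confidence interval comes from a
#' seeded case-resampling bootstrap.
#'
#' @param latency Withdrawal latencies (ms or s; units only affect the
#'   slope's scale).
#' @param response Behavior flag (logical/0-1) for `mode = "logistic"`, or
#'   duration (s) for `mode = "linear"`.
#' @param mode `"logistic"` or `"linear"`.
#' @param boot_reps Bootstrap replicates (default 2000; 0 skips the CI).
#' @param seed Bootstrap seed.
#' @param conf Confidence level (default 0.95).
#' @return A list: `slope`, `p` (model-based test of the slope; for
#'   completely separated logistic fits this is flagged unreliable),
#'   `ci` (bootstrap percentile interval, or NULL), `separation`, `fit`.
#' @export
behavior_latency_association <- function(latency, response,
                                         mode = c("logistic", "linear"),
                                         boot_reps = 2000, seed = 1,
                                         conf = 0.95) {
  mode <- match.arg(mode)
  if (length(latency) != length(response)) {
    stop("latency and response must be the same length")
  }
  if (length(latency) < 10L) stop("need at least 10 trials")
  separation <- FALSE
  fit_one <- function(lat, resp) {
    if (mode == "logistic") {
      f <- withCallingHandlers(
        stats::glm(resp ~ lat, family = stats::binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1",
                    conditionMessage(w))) {
            separation <<- TRUE
            invokeRestart("muffleWarning")
          }
        })
    } else {
      f <- stats::lm(resp ~ lat)
    }
    f
  }
  if (mode == "logistic") {
    response <- as.numeric(response)
    if (!all(response %in% c(0, 1))) stop("flags must be binary")
    if (length(unique(response)) < 2L) {
      stop("logistic mode needs both outcome classes present")
    }
  }
  fit <- fit_one(latency, response)
  sm <- stats::coef(suppressWarnings(summary(fit)))
  slope <- sm[2, 1]
  p <- sm[2, 4]
  ci <- NULL
  if (boot_reps > 0) {
    n <- length(latency)
    slopes <- with_seed(seed, {
      vapply(seq_len(boot_reps), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        if (mode == "logistic" && length(unique(response[idx])) < 2L) {
          return(NA_real_)
        }
        f <- suppressWarnings(fit_one(latency[idx], response[idx]))
        stats::coef(f)[2]
      }, numeric(1))
    })
    slopes <- slopes[!is.na(slopes)]
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(slopes, c(alpha, 1 - alpha)))
  }
  list(slope = slope, p = if (separation) NA_real_ else p, ci = ci,
       separation = separation, fit = fit, mode = mode)
}
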