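#' Confusion-matrix performance metrics with Agresti-Coull intervals
#'
#' Computes sensitivity, specificity, balanced accuracy, positive and
#' negative predictive value, and the Matthews correlation coefficient
#' from the four confusion counts, together with Agresti-Coull 95%
#' confidence intervals for the proportion metrics.
#'
#' The interval for each proportion p is computed by feeding `p * n_interval`
#' pseudo-successes to [agresti_coull_interval()]. `n_interval` defaults to
#' the total number of subjects, which is the denominator that reproduces
#' published neonatal-cohort intervals computed on imbalanced confusion
#' matrices; it can be set to the class-specific count instead.
#'
#' Conventions for degenerate margins: PPV is `NA` when no subject is
#' predicted positive (TP + FP = 0), NPV is `NA` when none is predicted
#' negative, and MCC is 0 when any margin of the confusion matrix is zero.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts. True positives are
#'   laser-treated infants predicted positive.
#' @param conf Confidence level for the intervals (default 0.95).
#' @param n_interval Denominator used for the interval half-width; defaults
#'   to `tp + fp + fn + tn`.
#' @return An object of class `evaluation_result`: a list with the counts,
#'   each metric, and a `intervals` data.frame (metric, lower, upper).
#' @examples
#' m <- confusion_metrics(11, 10, 4, 75)
#' round(m$balanced_accuracy, 2)
#' @export
confusion_metrics <- function(tp, fp, fn, tn, conf = 0.95,
                              n_interval = NULL) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("confusion counts must be non-negative integers")
  if (tp + fn < 1 || tn + fp < 1)
    stop("both classes must be represented (positives >= 1, negatives >= 1)")
  if (is.null(n_interval)) n_interval <- tp + fp + fn + tn

  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ba   <- (sens + spec) / 2
  ppv  <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv  <- if (tn + fn > 0) tn / (tn + fn) else NA_real_

  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)

  props <- c(sensitivity = sens, specificity = spec, balanced_accuracy = ba)
  ints <- do.call(rbind, lapply(names(props), function(nm) {
    ci <- agresti_coull_interval(props[[nm]] * n_interval, n_interval, conf)
    data.frame(metric = nm, lower = ci[[1]], upper = ci[[2]])
  }))

  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = sens, specificity = spec, balanced_accuracy = ba,
         ppv = ppv, npv = npv, mcc = mcc,
         intervals = ints, n_interval = n_interval, conf = conf),
    class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("Evaluation (TP", x$tp, "FP", x$fp, "FN", x$fn, "TN", x$tn, ")\n")
  fmt <- function(v) formatC(round_away(v, 2), format = "f", digits = 2)
  for (nm in c("balanced_accuracy", "sensitivity", "specificity")) {
    i <- x$intervals[x$intervals$metric == nm, ]
    cat(sprintf("  %-18s %s (%s-%s)\n", nm, fmt(x[[nm]]),
                fmt(i$lower), fmt(i$upper)))
  }
  cat(sprintf("  %-18s %s\n", "mcc", fmt(x$mcc)))
  if (!is.na(x$ppv)) cat(sprintf("  %-18s %s\n", "ppv", fmt(x$ppv)))
  if (!is.na(x$npv)) cat(sprintf("  %-18s %s\n", "npv", fmt(x$npv)))
  invisible(x)
}

#' Agresti-Coull confidence interval for a binomial proportion
#'
#' The add-z^2 pseudo-count interval: with \eqn{\tilde n = n + z^2} and
#' \eqn{\tilde p = (x + z^2/2)/\tilde n}, the interval is
#' \eqn{\tilde p \pm z \sqrt{\tilde p (1-\tilde p)/\tilde n}}, clipped to
#' \[0, 1\]. Non-integer `successes` are accepted so that an interval can be
#' attached to a derived proportion (e.g. balanced accuracy) at a chosen
#' denominator.
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' agresti_coull_interval(73, 100) # approx (0.64, 0.81)
#' @export
agresti_coull_interval <- function(successes, n, conf = 0.95) {
  if (n < 1 || successes < 0 || successes > n)
    stop("require 0 <= successes <= n and n >= 1")
  z <- qnorm(1 - (1 - conf) / 2)
  nt <- n + z^2
  pt <- (successes + z^2 / 2) / nt
  hw <- z * sqrt(pt * (1 - pt) / nt)
  c(lower = max(0, pt - hw), upper = min(1, pt + hw))
}

#' Two-sided mid-p McNemar test
#'
#' Exact binomial McNemar test on the discordant-pair counts, with the
#' mid-p correction: half the probability of the observed count is removed
#' from the tail. With `n = b + c`, `k = max(b, c)` and
#' `X ~ Binomial(n, 1/2)`, the p-value is `2 P(X >= k) - P(X = k)`,
#' capped at 1; `b = c = 0` returns 1 by convention.
#'
#' @param b,c Non-negative discordant-pair counts (subjects classified
#'   correctly by one model only, each direction).
#' @return The two-sided mid-p value.
#' @examples
#' mcnemar_midp(5, 1) # 0.125
#' @export
mcnemar_midp <- function(b, c) {
  if (b < 0 || c < 0 || b != floor(b) || c != floor(c))
    stop("discordant counts must be non-negative integers")
  n <- b + c
  if (n == 0) return(1)
  k <- max(b, c)
  p <- 2 * (1 - pbinom(k - 1, n, 0.5)) - dbinom(k, n, 0.5)
  min(1, p)
}

#' ROC points from a set of out-of-fold predictions
#'
#' One (1 - specificity, sensitivity) point per distinct predicted
#' probability, anchored at (0, 0) and (1, 1); at each threshold a subject
#' is predicted positive when its probability is >= the threshold.
#'
#' @param predictions A `prediction_set` data.frame with columns `truth`
#'   (0/1) and `prob`.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, ordered by
#'   increasing `fpr` then `tpr` (a staircase from (0,0) to (1,1)).
#' @export
roc_points <- function(predictions) {
  stopifnot(all(c("truth", "prob") %in% names(predictions)))
  truth <- predictions$truth
  prob <- predictions$prob
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0) stop("both classes required for a ROC curve")
  thr <- sort(unique(prob), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(prob >= t & truth == 1) / npos, 0)
  fpr <- vapply(thr, function(t) sum(prob >= t & truth == 0) / nneg, 0)
  out <- data.frame(threshold = c(Inf, thr, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  out[order(out$fpr, out$tpr), , drop = FALSE]
}

#' Area under the ROC staircase
#'
#' Trapezoidal area under [roc_points()], equal to the Mann-Whitney
#' concordance probability with ties counted 1/2.
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(predictions) {
  pts <- roc_points(predictions)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}

#' Baseline characteristics table with group comparison tests
#'
#' Summarises each cohort variable by outcome group as median (IQR) for
#' continuous variables or n (%) for binary/categorical ones, with a
#' p-value from the Wilcoxon rank-sum test (continuous) or the chi-squared /
#' Fisher exact test (categorical; the exact test is used whenever any
#' expected cell count is below 5).
#'
#' @param cohort A cohort data.frame with an `outcome` column (0/1) plus
#'   the variables to summarise.
#' @param variables Character vector of columns to include; defaults to all
#'   columns except `infant_id` and `outcome`.
#' @return data.frame with columns `variable`, `type`, `summary_all`,
#'   `summary_neg`, `summary_pos`, `test`, `p_value`.
#' @export
baseline_table <- function(cohort, variables = NULL) {
  if (!"outcome" %in% names(cohort)) stop("cohort must have an outcome column")
  g <- cohort$outcome
  if (length(unique(g)) < 2) stop("both outcome groups must be present")
  if (is.null(variables))
    variables <- setdiff(names(cohort), c("infant_id", "outcome"))

  summ_cont <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
  }
  summ_bin <- function(x) {
    sprintf("%d (%.0f%%)", sum(x == 1, na.rm = TRUE),
            100 * mean(x == 1, na.rm = TRUE))
  }

  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    is_bin <- is.logical(x) || is.factor(x) || is.character(x) ||
      length(unique(x[!is.na(x)])) <= 2
    if (is_bin) {
      xb <- if (is.logical(x)) as.integer(x)
            else if (is.numeric(x)) x
            else as.integer(x == sort(unique(as.character(x)))[2])
      tab <- table(factor(xb, levels = 0:1), factor(g, levels = 0:1))
      exp_ct <- suppressWarnings(chisq.test(tab, correct = TRUE)$expected)
      if (any(exp_ct < 5)) {
        test <- "fisher"; p <- fisher.test(tab)$p.value
      } else {
        test <- "chisq"
        p <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
      }
      data.frame(variable = v, type = "binary",
                 summary_all = summ_bin(xb),
                 summary_neg = summ_bin(xb[g == 0]),
                 summary_pos = summ_bin(xb[g == 1]),
                 test = test, p_value = p)
    } else {
      p <- suppressWarnings(
        wilcox.test(x[g == 1], x[g == 0], exact = FALSE)$p.value)
      data.frame(variable = v, type = "continuous",
                 summary_all = summ_cont(x),
                 summary_neg = summ_cont(x[g == 0]),
                 summary_pos = summ_cont(x[g == 1]),
                 test = "wilcoxon", p_value = p)
    }
  })
  do.call(rbind, rows)
}
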