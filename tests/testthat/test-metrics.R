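test_that("confusion metrics follow their defining formulas", {
  m <- confusion_metrics(11, 10, 4, 75)
  expect_equal(m$sensitivity, 11 / 15)
  expect_equal(m$specificity, 75 / 85)
  expect_equal(m$balanced_accuracy, (11 / 15 + 75 / 85) / 2)
  expect_equal(m$ppv, 11 / 21)
  expect_equal(m$npv, 75 / 79)
  expect_equal(m$mcc, (11 * 75 - 10 * 4) / sqrt(21 * 79 * 15 * 85))

  perfect <- confusion_metrics(15, 0, 0, 85)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$mcc, 1)

  expect_error(confusion_metrics(-1, 0, 1, 1), "non-negative")
  expect_error(confusion_metrics(0, 5, 0, 5), "classes")
})

test_that("degenerate-margin conventions: PPV missing, MCC zero", {
  m <- confusion_metrics(0, 0, 5, 10) # nothing predicted positive
  expect_true(is.na(m$ppv))
  expect_equal(m$mcc, 0)
})

test_that("MCC is +/-1 exactly for diagonal and antidiagonal matrices", {
  expect_equal(confusion_metrics(7, 0, 0, 13)$mcc, 1)
  expect_equal(confusion_metrics(0, 13, 7, 0)$mcc, -1)
})

test_that("MCC is near zero for label-independent predictions", {
  set.seed(7)
  mccs <- replicate(200, {
    truth <- rbinom(60, 1, 0.3)
    pred <- rbinom(60, 1, 0.5)
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
    if (tp + fn == 0 || tn + fp == 0) NA
    else confusion_metrics(tp, fp, fn, tn)$mcc
  })
  expect_lt(abs(mean(mccs, na.rm = TRUE)),
            3 * sd(mccs, na.rm = TRUE) / sqrt(sum(!is.na(mccs))))
})

test_that("Agresti-Coull interval matches its closed form and clips", {
  z <- qnorm(0.975)
  nt <- 100 + z^2
  pt <- (73 + z^2 / 2) / nt
  hw <- z * sqrt(pt * (1 - pt) / nt)
  ci <- agresti_coull_interval(73, 100)
  expect_equal(unname(ci), c(pt - hw, pt + hw))

  lo <- agresti_coull_interval(0, 10)
  expect_equal(unname(lo[1]), 0) # clipped at 0
  expect_gte(lo[2], 0)
  expect_lte(lo[2], 1)
  expect_error(agresti_coull_interval(11, 10), "successes")
})

test_that("Agresti-Coull interval contains the point estimate", {
  set.seed(1)
  for (rep in 1:50) {
    n <- sample(5:200, 1)
    x <- sample(0:n, 1)
    ci <- agresti_coull_interval(x, n)
    expect_gte(x / n + 1e-12, ci[1])
    expect_lte(x / n - 1e-12, ci[2])
  }
})

test_that("mid-p McNemar matches exact enumeration and is symmetric", {
  # oracle: enumerate Binomial(n, 1/2); full weight strictly beyond k,
  # half weight at k and at its mirror n - k
  midp_oracle <- function(b, c) {
    n <- b + c
    if (n == 0) return(1)
    k <- max(b, c)
    if (k == n - k) return(1)
    pr <- dbinom(0:n, n, 0.5)
    j <- 0:n
    min(1, sum(pr[j > k | j < n - k]) + 0.5 * sum(pr[j == k | j == n - k]))
  }
  for (b in 0:12) for (c in 0:(12 - b))
    expect_equal(mcnemar_midp(b, c), midp_oracle(b, c),
                 info = sprintf("b=%d c=%d", b, c))
  expect_equal(mcnemar_midp(5, 1), 0.125)
  expect_equal(mcnemar_midp(1, 1), 1)
  expect_equal(mcnemar_midp(0, 0), 1)
  expect_equal(mcnemar_midp(3, 8), mcnemar_midp(8, 3))
})

test_that("mid-p value never exceeds the exact binomial two-sided p", {
  for (b in 0:10) for (c in 0:(10 - b)) {
    n <- b + c
    if (n == 0) next
    k <- max(b, c)
    p_exact <- min(1, 2 * (1 - pbinom(k - 1, n, 0.5)))
    expect_lte(mcnemar_midp(b, c), p_exact + 1e-12)
  }
})

test_that("ROC staircase is anchored, monotone, and AUC matches concordance", {
  set.seed(3)
  prob <- round(runif(20), 2)
  truth <- rbinom(20, 1, 0.4)
  if (sum(truth) == 0) truth[1] <- 1
  if (sum(truth) == length(truth)) truth[2] <- 0
  preds <- make_predictions(prob, truth)
  pts <- roc_points(preds)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_true(all(pts$fpr >= 0 & pts$fpr <= 1 & pts$tpr >= 0 & pts$tpr <= 1))

  # brute-force pairwise concordance (Mann-Whitney with 1/2 for ties)
  pos <- prob[truth == 1]; neg <- prob[truth == 0]
  conc <- mean(outer(pos, neg, function(p, q)
    (p > q) + 0.5 * (p == q)))
  expect_equal(roc_auc(preds), conc)
})

test_that("perfect and constant scores give the expected ROC shapes", {
  perf <- make_predictions(c(rep(0.9, 5), rep(0.1, 10)),
                           c(rep(1, 5), rep(0, 10)))
  pts <- roc_points(perf)
  expect_true(any(pts$fpr == 0 & pts$tpr == 1)) # passes through (0, 1)

  const <- make_predictions(rep(0.5, 12), rep(c(1, 0), 6))
  pts2 <- roc_points(const)
  expect_true(all(abs(pts2$fpr - pts2$tpr) < 1e-12)) # chance diagonal
  expect_equal(roc_auc(const), 0.5)
})

test_that("baseline table: summaries, test choice, and identical groups", {
  # identical data in the two groups, balanced sizes -> exact p = 1
  base <- data.frame(
    infant_id = sprintf("I%02d", 1:20),
    outcome = rep(c(0, 1), each = 10),
    exposed = rep(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 2))
  tab <- baseline_table(base)
  expect_equal(tab$test, "fisher") # expected cells < 5
  expect_equal(tab$p_value, 1)

  # strongly different exposure -> small exact p
  coh <- data.frame(
    infant_id = sprintf("I%03d", 1:100),
    outcome = rep(c(0, 1), c(85, 15)),
    dexamethasone = c(rep(1, 22), rep(0, 63), rep(1, 12), rep(0, 3)))
  tab2 <- baseline_table(coh)
  expect_lt(tab2$p_value, 0.01)

  # continuous variable: medians/IQR equal hand-sorted order statistics
  set.seed(9)
  x <- round(rnorm(10, 26, 2), 1)
  coh3 <- data.frame(infant_id = sprintf("I%02d", 1:10),
                     outcome = rep(c(0, 1), each = 5),
                     gestational_age = x)
  tab3 <- baseline_table(coh3)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(tab3$summary_all,
               sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3]))
  expect_equal(tab3$test, "wilcoxon")
  expect_error(baseline_table(data.frame(outcome = rep(1, 5), x = 1:5)),
               "both outcome groups")
})
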