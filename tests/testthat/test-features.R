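test_that("validity filtering keeps exactly the flagged samples", {
  tr <- make_trace(rep(95, 1000), valid = rep(c(1L, 0L), 500))
  expect_equal(nrow(filter_valid(tr)), 500)
  expect_identical(filter_valid(make_trace(rep(95, 10)))$spo2, rep(95, 10))
  expect_equal(nrow(filter_valid(make_trace(rep(95, 10),
                                            valid = rep(0L, 10)))), 0)
})

test_that("availability is valid time over nominal window time", {
  n14 <- 14 * 1440 # 14 days of 1-min samples
  full <- make_trace(rep(95, n14))
  expect_equal(availability(full, 1, 14)$availability, 1)

  # valid samples only on days 1-7 of a 14-day window -> 0.5
  half <- make_trace(rep(95, n14),
                     valid = rep(c(1L, 0L), c(7 * 1440, 7 * 1440)))
  expect_equal(availability(half, 1, 14)$availability, 0.5)

  # 79% valid falls below the 80% inclusion bound
  n_ok <- round(0.79 * n14)
  part <- make_trace(rep(95, n14),
                     valid = rep(c(1L, 0L), c(n_ok, n14 - n_ok)))
  av <- availability(part, 1, 14)$availability
  expect_equal(av, n_ok / n14)
  expect_lt(av, 0.80)
  expect_error(availability(full, 5, 4), "day_start <= day_end")
})

test_that("daily means, including the per-sample SpO2/FiO2 ratio", {
  tr <- make_trace(rep(95, 1440), fio2 = rep(0.21, 1440))
  expect_equal(daily_mean(tr, "sf_ratio", 1), 95 / 0.21)
  expect_equal(daily_mean(tr, "spo2", 1), 95)

  halves <- make_trace(c(rep(90, 720), rep(100, 720)))
  expect_equal(daily_mean(halves, "spo2", 1), 95)

  # ratio of per-sample ratios, not ratio of means
  tr2 <- make_trace(c(90, 100), fio2 = c(0.3, 0.5), interval = 43200)
  expect_equal(daily_mean(tr2, "sf_ratio", 1), (90 / 0.3 + 100 / 0.5) / 2)

  none <- make_trace(rep(95, 10), valid = rep(0L, 10))
  expect_true(is.na(daily_mean(none, "spo2", 1)))
})

test_that("daily skewness uses the b1 moment form and its guards", {
  tr <- make_trace(c(1, 2, 3, 4, 5) + 90, interval = 60)
  expect_equal(daily_skewness(tr, "spo2", 1), 0)

  tr2 <- make_trace(c(1, 2, 9), interval = 60)
  expect_equal(daily_skewness(tr2, "spo2", 1), skew_oracle(c(1, 2, 9)))
  # hand value: m2 = 38/3, m3 = 30, times (2/3)^(3/2)
  expect_equal(daily_skewness(tr2, "spo2", 1),
               30 / (38 / 3)^1.5 * (2 / 3)^1.5)

  # negation flips the sign
  tr3 <- make_trace(-c(1, 2, 9), interval = 60)
  expect_equal(daily_skewness(tr3, "spo2", 1),
               -daily_skewness(tr2, "spo2", 1))

  expect_true(is.na(daily_skewness(make_trace(c(5, 5, 5)), "spo2", 1)))
  expect_true(is.na(daily_skewness(make_trace(c(1, 2)), "spo2", 1)))
})

test_that("threshold areas follow the rectangle rule in %*min", {
  const85 <- make_trace(rep(85, 1440))
  expect_equal(auc_threshold(const85, "spo2", 1, 80, "below"), 0)

  # 70% for 10 min of 1-min samples below an 80% threshold
  dip <- make_trace(c(rep(70, 10), rep(85, 1430)))
  expect_equal(auc_threshold(dip, "spo2", 1, 80, "below"), 100)

  # 98% for 30 min above a 95% threshold
  high <- make_trace(c(rep(98, 30), rep(93, 1410)))
  expect_equal(auc_threshold(high, "spo2", 1, 95, "above"), 90)
  expect_error(auc_threshold(high, "spo2", 1, 95, "sideways"))
})

test_that("time percentages use <= below and strictly > above", {
  all97 <- make_trace(rep(97, 100))
  expect_equal(pct_time(all97, "spo2", 1, 95, "above"), 100)

  at95 <- make_trace(rep(95, 100))
  expect_equal(pct_time(at95, "spo2", 1, 95, "above"), 0)

  # 3 of 12 valid samples at or below 80
  mix <- make_trace(c(rep(80, 3), rep(90, 9)), interval = 7200)
  expect_equal(pct_time(mix, "spo2", 1, 80, "below"), 25)
})

test_that("event counting honours duration, merging, and onset day", {
  rule <- event_rule("spo2", "below", 80, min_duration = 10, merge_gap = 10)
  expect_equal(count_events(make_trace(rep(95, 1440)), rule, day = 1), 0)

  # one 60-s dip (1-s samples)
  sec <- function(v) make_trace(v, interval = 1)
  dip <- sec(c(rep(95, 100), rep(70, 60), rep(95, 100)))
  expect_equal(count_events(dip, rule, day = 1), 1)

  # two 30-s dips separated by 5 s merge; separated by 60 s they do not
  two5 <- sec(c(rep(95, 50), rep(70, 30), rep(95, 5), rep(70, 30),
                rep(95, 50)))
  expect_equal(count_events(two5, rule, day = 1), 1)
  two60 <- sec(c(rep(95, 50), rep(70, 30), rep(95, 60), rep(70, 30),
                 rep(95, 50)))
  expect_equal(count_events(two60, rule, day = 1), 2)

  # sub-minimum-duration runs are discarded
  blip <- sec(c(rep(95, 50), rep(70, 5), rep(95, 50)))
  expect_equal(count_events(blip, rule, day = 1), 0)

  # an event straddling midnight counts on its onset day
  late <- make_trace(rep(c(95, 70), c(1435, 10)), interval = 60)
  expect_equal(count_events(late, rule, day = 1), 1)
  expect_equal(count_events(late, rule, day = 2), 0)
})

test_that("event counts are monotone in window length and min_duration", {
  set.seed(21)
  x <- ifelse(runif(2000) < 0.1, 70, 95)
  tr <- make_trace(x, interval = 30)
  base_rule <- function(md) event_rule("spo2", "below", 80,
                                       min_duration = md, merge_gap = 0)
  counts <- vapply(c(0, 30, 60, 120), function(md)
    sum(count_events(tr, base_rule(md))$count), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("the feature matrix matches per-feature oracles on a crafted day", {
  n <- 1440
  spo2 <- rep(93, n)
  spo2[101:110] <- 70   # 10-min deep desaturation
  spo2[151] <- 75       # 1-min brief desaturation
  spo2[201:230] <- 97   # 30-min hyperoxia plateau
  hr <- rep(160, n)
  hr[301:305] <- 210    # tachycardia burst
  hr[401:403] <- 90     # bradycardia dip
  fio2 <- rep(c(0.30, 0.40), each = n / 2)
  tr <- make_trace(spo2, hr, fio2)

  fm <- build_feature_matrix(tr, days = 1)
  val <- function(f) fm$value[fm$feature == f]
  expect_equal(val("mean_spo2"), mean(spo2))
  expect_equal(val("mean_hr"), mean(hr))
  expect_equal(val("mean_fio2"), 0.35)
  expect_equal(val("mean_sf_ratio"), mean(spo2 / fio2))
  expect_equal(val("skew_spo2"), skew_oracle(spo2))
  expect_equal(val("skew_hr"), skew_oracle(hr))
  expect_equal(val("auc_below_80"), (80 - 70) * 10 + (80 - 75) * 1)
  expect_equal(val("auc_above_95"), (97 - 95) * 30)
  expect_equal(val("pct_time_le_80"), 11 / n * 100)
  expect_equal(val("pct_time_gt_95"), 30 / n * 100)
  expect_equal(val("n_desaturations"), 2)
  expect_equal(val("n_bradycardia"), 1)
  expect_equal(val("n_tachycardia"), 1)
})

test_that("within-day sample permutation leaves day-level statistics fixed", {
  set.seed(5)
  spo2 <- 90 + round(rnorm(1440), 1)
  tr <- make_trace(spo2)
  fm1 <- build_feature_matrix(tr, days = 1)
  perm <- sample(1440)
  fm2 <- build_feature_matrix(make_trace(spo2[perm]), days = 1)
  stable <- c("mean_spo2", "skew_spo2", "auc_below_80", "auc_above_95",
              "pct_time_le_80", "pct_time_gt_95")
  for (f in stable)
    expect_equal(fm1$value[fm1$feature == f], fm2$value[fm2$feature == f],
                 info = f)
})

test_that("doubling the sample rate of a piecewise-constant trace changes nothing", {
  spo2 <- rep(c(93, 70, 97, 93), c(600, 120, 240, 480)) # minutes
  hr <- rep(c(160, 90, 160), c(700, 40, 700))
  tr1 <- make_trace(spo2, hr, interval = 60)
  tr2 <- make_trace(rep(spo2, each = 2), rep(hr, each = 2), interval = 30)
  fm1 <- build_feature_matrix(tr1, days = 1)
  fm2 <- build_feature_matrix(tr2, days = 1)
  # skewness carries a ((n-1)/n)^(3/2) finite-sample factor, hence the
  # small tolerance; every other family is exactly invariant
  expect_equal(fm1$value, fm2$value, tolerance = 1e-3)
})

test_that("hypoxia percentage and area vanish together; percentages bounded", {
  sim <- small_sim(n = 8, npos = 2, seed = 13)
  fm <- build_feature_matrix(sim$traces)
  wide <- data.frame(
    le80 = fm$value[fm$feature == "pct_time_le_80"],
    gt95 = fm$value[fm$feature == "pct_time_gt_95"],
    auc80 = fm$value[fm$feature == "auc_below_80"])
  expect_true(all(wide$le80 + wide$gt95 <= 100 + 1e-9, na.rm = TRUE))
  expect_true(all(wide$le80 >= 0 & wide$le80 <= 100, na.rm = TRUE))
  # auc below 80 uses excursions below the threshold; it is zero iff no
  # valid sample sits strictly below 80, which implies pct(<=80) counts
  # only exact-80 samples
  expect_true(all((wide$auc80 == 0) >= (wide$le80 == 0), na.rm = TRUE))
})

test_that("days without valid samples yield missing cells, not zeros", {
  n <- 2880 # two days
  valid <- rep(c(1L, 0L), each = 1440)
  tr <- make_trace(rep(93, n), valid = valid)
  fm <- build_feature_matrix(tr, days = 2)
  expect_true(all(fm$day == 1))
  m <- feature_day_matrix(fm, "mean_spo2", days = 2)
  expect_equal(unname(m[1, ]), c(93, NA))
})

test_that("feature matrix round-trips through delimited text", {
  sim <- small_sim(n = 4, npos = 1, seed = 3)
  fm <- build_feature_matrix(sim$traces)
  path <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  fm2 <- read_feature_matrix(path)
  expect_equal(fm2$value, fm$value, tolerance = 1e-9)
  expect_equal(attr(fm2, "days"), 30)
})
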