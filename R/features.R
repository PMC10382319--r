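#' The 13 daily physiological feature families
#'
#' Per infant and postnatal day the pipeline derives: mean SpO2 (%), mean
#' heart rate (bpm), mean FiO2 (fraction), mean SpO2/FiO2 ratio
#' (%/fraction, per-sample ratio averaged), skewness of SpO2 and of heart
#' rate (unitless), area under the 80% SpO2 curve and above the 95% SpO2
#' curve (%*min/day), percentage of time at SpO2 <= 80% and > 95%, and
#' daily counts of desaturation, bradycardia and tachycardia events.
#'
#' @return Character vector of the 13 family names.
#' @export
feature_families <- function() {
  c("mean_spo2", "mean_hr", "mean_fio2", "mean_sf_ratio",
    "skew_spo2", "skew_hr", "auc_below_80", "auc_above_95",
    "pct_time_le_80", "pct_time_gt_95",
    "n_desaturations", "n_bradycardia", "n_tachycardia")
}

#' Define an episodic event rule
#'
#' An event is a maximal run of samples beyond a threshold; runs separated
#' by less than `merge_gap` seconds are merged first, then runs shorter
#' than `min_duration` are discarded. `below` means strictly less than the
#' threshold, `above` strictly greater.
#'
#' @param signal One of `"spo2"`, `"hr"`, `"fio2"`.
#' @param comparator `"below"` or `"above"`.
#' @param threshold Threshold in the signal's units.
#' @param min_duration Minimum event duration in seconds.
#' @param merge_gap Runs separated by less than this many seconds are
#'   merged.
#' @return An `event_rule` list.
#' @export
event_rule <- function(signal, comparator = c("below", "above"), threshold,
                       min_duration = 10, merge_gap = 10) {
  stopifnot(signal %in% c("spo2", "hr", "fio2"),
            min_duration >= 0, merge_gap >= 0)
  structure(list(signal = signal, comparator = match.arg(comparator),
                 threshold = threshold, min_duration = min_duration,
                 merge_gap = merge_gap),
            class = "event_rule")
}

#' Default neonatal event definitions
#'
#' Desaturation: SpO2 below 80% for at least 10 s; bradycardia: heart rate
#' below 100 bpm for at least 10 s; tachycardia: heart rate above 200 bpm
#' for at least 10 s; runs closer than 10 s are merged. These are the
#' package's defaults, chosen to match common neonatal monitoring
#' definitions and the 80%/95% oxygenation-burden thresholds used
#' elsewhere in the pipeline; all are configurable.
#'
#' @return Named list of [event_rule()]s (`desaturation`, `bradycardia`,
#'   `tachycardia`).
#' @export
default_event_rules <- function() {
  list(desaturation = event_rule("spo2", "below", 80),
       bradycardia = event_rule("hr", "below", 100),
       tachycardia = event_rule("hr", "above", 200))
}

# sampling interval (seconds) from timestamps of one infant
infer_interval <- function(t_seconds) {
  if (length(t_seconds) < 2) return(NA_real_)
  median(diff(sort(t_seconds)))
}

#' Drop samples flagged invalid
#'
#' @param trace Long trace table (one or more infants).
#' @return The valid-flagged rows only.
#' @export
filter_valid <- function(trace) {
  tr <- data.table::as.data.table(trace)
  tr[valid == 1L][]
}

#' Fraction of a day window covered by valid samples
#'
#' Valid-sample time divided by the nominal window time, per infant; used
#' for the cohort inclusion rule (at least 80% availability over the first
#' two postnatal weeks).
#'
#' @param traces Long trace table.
#' @param day_start,day_end Postnatal day window (1-based, inclusive).
#' @param interval Sampling interval in seconds; inferred from the
#'   timestamps when `NULL`.
#' @return data.frame with columns `infant_id`, `availability`; infants
#'   absent from `traces` are absent here (availability 0 by convention of
#'   the caller).
#' @export
availability <- function(traces, day_start = 1, day_end = 14,
                         interval = NULL) {
  stopifnot(day_start <= day_end, day_start >= 1)
  tr <- data.table::as.data.table(traces)
  window_s <- (day_end - day_start + 1) * 86400
  if (window_s <= 0) stop("zero-length window")
  lo <- (day_start - 1) * 86400
  hi <- day_end * 86400
  out <- tr[, {
    dt <- if (is.null(interval)) infer_interval(t_seconds) else interval
    inw <- t_seconds >= lo & t_seconds < hi
    .(availability = sum(valid[inw] == 1L) * dt / window_s)
  }, by = infant_id]
  as.data.frame(out)
}

# helper: one infant's valid samples for one day
day_slice <- function(trace, day) {
  tr <- filter_valid(trace)
  tr[t_seconds >= (day - 1) * 86400 & t_seconds < day * 86400]
}

#' Daily mean of a signal over valid samples
#'
#' For `signal = "sf_ratio"` the per-sample ratio SpO2\[%\]/FiO2\[fraction\]
#' is averaged.
#'
#' @param trace One infant's trace.
#' @param signal `"spo2"`, `"hr"`, `"fio2"` or `"sf_ratio"`.
#' @param day Postnatal day (1-based).
#' @return The mean, or `NA` when the day has no valid samples.
#' @export
daily_mean <- function(trace, signal, day) {
  sl <- day_slice(trace, day)
  if (nrow(sl) == 0) return(NA_real_)
  x <- if (signal == "sf_ratio") sl$spo2 / sl$fio2 else sl[[signal]]
  mean(x)
}

#' Daily sample skewness of a signal
#'
#' Sample skewness \eqn{b_1 = (m_3 / m_2^{3/2})\,((n-1)/n)^{3/2}} with
#' biased central moments \eqn{m_k} (`e1071::skewness` type 3, the
#' convention of the analysis this mirrors); 0 indicates a symmetric
#' distribution. Requires at least 3 valid samples with nonzero variance,
#' else `NA`.
#'
#' @inheritParams daily_mean
#' @return The skewness, or `NA`.
#' @export
daily_skewness <- function(trace, signal, day) {
  sl <- day_slice(trace, day)
  skew_vec(sl[[signal]])
}

skew_vec <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || var(x) == 0) return(NA_real_)
  e1071::skewness(x, type = 3)
}

#' Daily area beyond an SpO2 threshold
#'
#' Rectangle-rule sum over valid samples of the excursion beyond the
#' threshold times the sample duration, in %*min per day: `side = "below"`
#' accumulates `(threshold - x)+`, `side = "above"` accumulates
#' `(x - threshold)+`.
#'
#' @inheritParams daily_mean
#' @param threshold Threshold in signal units.
#' @param side `"below"` or `"above"`.
#' @param interval Sampling interval in seconds (inferred when `NULL`).
#' @return Area in %*min, or `NA` when the day has no valid samples.
#' @export
auc_threshold <- function(trace, signal, day, threshold,
                          side = c("below", "above"), interval = NULL) {
  side <- match.arg(side)
  sl <- day_slice(trace, day)
  if (nrow(sl) == 0) return(NA_real_)
  if (is.null(interval)) interval <- infer_interval(trace$t_seconds)
  x <- sl[[signal]]
  exc <- if (side == "below") pmax(threshold - x, 0) else pmax(x - threshold, 0)
  sum(exc) * interval / 60
}

#' Daily percentage of valid time beyond a threshold
#'
#' `side = "below"` counts samples with value <= threshold, `side =
#' "above"` counts samples strictly > threshold (the hypoxia burden uses
#' SpO2 <= 80%, the hyperoxia burden SpO2 > 95%).
#'
#' @inheritParams auc_threshold
#' @return Percentage of valid time in \[0, 100\], or `NA`.
#' @export
pct_time <- function(trace, signal, day, threshold,
                     side = c("below", "above")) {
  side <- match.arg(side)
  sl <- day_slice(trace, day)
  if (nrow(sl) == 0) return(NA_real_)
  x <- sl[[signal]]
  100 * mean(if (side == "below") x <= threshold else x > threshold)
}

# Event onsets on plain vectors (t sorted ascending, valid samples only).
# Returns integer vector of onset days (one element per event).
onset_days_vec <- function(t, x, rule, interval) {
  hit <- if (rule$comparator == "below") x < rule$threshold
         else x > rule$threshold
  if (!any(hit)) return(integer(0))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rs <- starts[r$values]; re <- ends[r$values]
  t_start <- t[rs]
  t_end <- t[re] + interval
  # merge runs separated (in valid time) by less than merge_gap
  grp <- if (length(rs) > 1)
    cumsum(c(1, t_start[-1] - t_end[-length(rs)] >= rule$merge_gap))
  else 1
  # onset = first run start per merged group (runs are in time order);
  # duration = covered valid time within the merged run
  on_t <- t_start[!duplicated(grp)]
  dur <- rowsum((re - rs + 1) * interval, grp, reorder = TRUE)[, 1]
  keep <- dur >= rule$min_duration
  as.integer(on_t[keep] %/% 86400 + 1L)
}

# Event onsets from one infant's (possibly unfiltered) trace under a rule.
event_onset_days <- function(trace, rule, interval = NULL) {
  tr <- filter_valid(trace)
  if (nrow(tr) == 0) return(integer(0))
  data.table::setorder(tr, t_seconds)
  if (is.null(interval)) interval <- infer_interval(tr$t_seconds)
  onset_days_vec(tr$t_seconds, tr[[rule$signal]], rule, interval)
}

#' Count threshold events on a day
#'
#' Number of maximal suprathreshold runs satisfying the rule's minimum
#' duration, after merging runs separated by less than the merge gap; an
#' event is assigned to the day containing its onset.
#'
#' @param trace One infant's trace.
#' @param rule An [event_rule()].
#' @param day Postnatal day; when `NULL` a per-day count table for the
#'   whole trace is returned.
#' @param interval Sampling interval in seconds (inferred when `NULL`).
#' @return A count, or a data.frame (`day`, `count`) when `day` is `NULL`.
#' @export
count_events <- function(trace, rule, day = NULL, interval = NULL) {
  stopifnot(inherits(rule, "event_rule"))
  onsets <- event_onset_days(trace, rule, interval)
  if (!is.null(day)) return(sum(onsets == day))
  if (length(onsets) == 0)
    return(data.frame(day = integer(0), count = integer(0)))
  tab <- table(onsets)
  data.frame(day = as.integer(names(tab)), count = as.integer(tab))
}

#' Build the per-infant daily feature matrix
#'
#' Converts filtered traces into the 13-family daily feature matrix in
#' long form. Cells for days without valid samples are missing (absent),
#' never zero-filled; infants with no valid data at all are dropped with a
#' message.
#'
#' @param traces Long trace table (all infants).
#' @param rules Event rules, as from [default_event_rules()].
#' @param days Number of postnatal days covered (default 30).
#' @return data.frame `infant_id`, `day`, `feature`, `value` with
#'   attribute `days`.
#' @export
build_feature_matrix <- function(traces, rules = default_event_rules(),
                                 days = 30) {
  tr <- filter_valid(traces)
  all_ids <- unique(data.table::as.data.table(traces)$infant_id)
  dropped <- setdiff(all_ids, unique(tr$infant_id))
  if (length(dropped))
    message("dropping ", length(dropped), " infant(s) with no valid data: ",
            paste(dropped, collapse = ", "))
  if (nrow(tr) == 0) stop("no valid samples in any trace")
  tr[, day := as.integer(t_seconds %/% 86400) + 1L]
  tr <- tr[day >= 1 & day <= days]

  ivl <- tr[, .(interval = infer_interval(t_seconds)), by = infant_id]
  tr <- merge(tr, ivl, by = "infant_id")

  daily <- tr[, {
    n <- .N
    list(
      mean_spo2 = mean(spo2),
      mean_hr = mean(hr),
      mean_fio2 = mean(fio2),
      mean_sf_ratio = mean(spo2 / fio2),
      skew_spo2 = skew_vec(spo2),
      skew_hr = skew_vec(hr),
      auc_below_80 = sum(pmax(80 - spo2, 0)) * interval[1] / 60,
      auc_above_95 = sum(pmax(spo2 - 95, 0)) * interval[1] / 60,
      pct_time_le_80 = 100 * mean(spo2 <= 80),
      pct_time_gt_95 = 100 * mean(spo2 > 95)
    )
  }, by = .(infant_id, day)]

  # event counts: 0 on days with valid data, missing otherwise
  data.table::setorder(tr, infant_id, t_seconds)
  rule_map <- c(n_desaturations = "desaturation",
                n_bradycardia = "bradycardia",
                n_tachycardia = "tachycardia")
  ev_wide <- tr[, {
    counts <- lapply(rule_map, function(rn) {
      rule <- rules[[rn]]
      od <- onset_days_vec(t_seconds, .SD[[rule$signal]], rule, interval[1])
      as.numeric(tabulate(od, nbins = days))
    })
    c(list(day = 1:days), counts)
  }, by = infant_id]

  out <- merge(daily, ev_wide, by = c("infant_id", "day"), all.x = TRUE)
  long <- data.table::melt(out, id.vars = c("infant_id", "day"),
                           variable.name = "feature", value.name = "value")
  long[, feature := as.character(feature)]
  long <- as.data.frame(long[order(infant_id, day, feature)])
  attr(long, "days") <- as.integer(days)
  long
}

#' Infant-by-day matrix for one feature family
#'
#' @param fm Long feature matrix from [build_feature_matrix()].
#' @param family One of [feature_families()].
#' @param days Number of day columns (defaults to the matrix attribute).
#' @param ids Row order; defaults to the infants present.
#' @return Numeric matrix (infants x days) with `NA` for missing cells.
#' @export
feature_day_matrix <- function(fm, family, days = NULL, ids = NULL) {
  if (is.null(days)) days <- attr(fm, "days") %||% max(fm$day)
  sub <- fm[fm$feature == family, , drop = FALSE]
  if (is.null(ids)) ids <- sort(unique(fm$infant_id))
  sub <- sub[sub$infant_id %in% ids, , drop = FALSE]
  m <- matrix(NA_real_, length(ids), days,
              dimnames = list(ids, paste0("d", seq_len(days))))
  m[cbind(match(sub$infant_id, ids), sub$day)] <- sub$value
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname build_feature_matrix
#' @param fm Long feature matrix.
#' @param path File path (tab-separated text).
#' @export
write_feature_matrix <- function(fm, path) {
  data.table::fwrite(fm, path, sep = "\t")
  invisible(path)
}

#' @rdname build_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  fm <- as.data.frame(data.table::fread(path, sep = "\t"))
  attr(fm, "days") <- max(fm$day)
  fm
}
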