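#' Configuration for the synthetic neonatal cohort generator
#'
#' Bundles and validates all knobs of the generator: cohort size, outcome
#' prevalence, trace resolution and length, signed group effects, sample
#' missingness, and the seed. The defaults describe a level-III NICU
#' population in which roughly 15% of very preterm infants later require
#' laser treatment for retinopathy of prematurity, with the laser group
#' showing (during the vulnerable early-postnatal window) a higher oxygen
#' requirement, more frequent brief desaturations, more time in hyperoxia,
#' but less deep-hypoxia burden and a lower heart-rate skewness.
#'
#' @param n_infants Number of infants to generate.
#' @param prevalence Probability that an infant is in the laser group
#'   (ignored when `n_positive` is given).
#' @param n_positive Optional exact number of laser-group infants.
#' @param sampling_interval Seconds between monitor samples; must divide
#'   86400.
#' @param days Trace length in postnatal days.
#' @param effect_windows data.frame with columns `family`, `day_start`,
#'   `day_end`, `effect`: signed effect sizes (in approximate within-group
#'   SD units of the daily feature) applied to the laser group's latent
#'   generators inside the day window. Supported families:
#'   `"mean_fio2"`, `"n_desaturations"`, `"hypoxia_burden"`,
#'   `"hyperoxia_time"`, `"skew_hr"`. Use
#'   `null_effect_windows()` for a no-difference cohort.
#' @param missingness_rate Per-sample probability of an invalid flag.
#' @param on_degenerate What to do when a binomial outcome draw leaves a
#'   class empty for `n_infants >= 20`: `"resample"` (default, with a
#'   warning) or `"fail"`.
#' @param seed Integer seed; identical configurations give identical
#'   cohorts.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_infants,
                             prevalence = 0.15,
                             n_positive = NULL,
                             sampling_interval = 60,
                             days = 30,
                             effect_windows = default_effect_windows(),
                             missingness_rate = 0.02,
                             on_degenerate = c("resample", "fail"),
                             seed = 1L) {
  stopifnot(n_infants >= 2, prevalence > 0, prevalence < 1,
            sampling_interval > 0, 86400 %% sampling_interval == 0,
            days >= 1, missingness_rate >= 0, missingness_rate <= 1)
  if (!is.null(n_positive))
    stopifnot(n_positive >= 1, n_positive < n_infants)
  if (!is.null(effect_windows) && nrow(effect_windows) > 0) {
    stopifnot(all(c("family", "day_start", "day_end", "effect") %in%
                    names(effect_windows)),
              all(effect_windows$day_start <= effect_windows$day_end),
              all(effect_windows$day_end <= days),
              all(effect_windows$day_start >= 1))
    unknown <- setdiff(effect_windows$family, names(.effect_families))
    if (length(unknown))
      stop("unsupported effect families: ", paste(unknown, collapse = ", "))
  }
  structure(list(n_infants = as.integer(n_infants), prevalence = prevalence,
                 n_positive = if (is.null(n_positive)) NULL
                              else as.integer(n_positive),
                 sampling_interval = as.integer(sampling_interval),
                 days = as.integer(days), effect_windows = effect_windows,
                 missingness_rate = missingness_rate,
                 on_degenerate = match.arg(on_degenerate),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default signed group effects of the generated cohort
#'
#' The laser group receives a higher FiO2 setpoint from day 3 onwards, and
#' during days 5-15 more brief desaturations and hyperoxia time but fewer
#' deep hypoxic episodes and a lower heart-rate skewness. The SpO2/FiO2
#' ratio difference emerges from the FiO2 shift (lower ratio under higher
#' oxygen requirement) and is not injected separately.
#'
#' @return data.frame of effect windows (see [generator_config()]).
#' @export
default_effect_windows <- function() {
  data.frame(
    family   = c("mean_fio2", "n_desaturations", "hypoxia_burden",
                 "hyperoxia_time", "skew_hr"),
    day_start = c(3, 5, 5, 5, 5),
    day_end   = c(30, 15, 15, 15, 15),
    effect    = c(1.0, 0.8, -0.8, 0.8, -0.8))
}

#' @rdname default_effect_windows
#' @export
null_effect_windows <- function() {
  default_effect_windows()[0, , drop = FALSE]
}

# latent-dial mapping for each supported effect family
.effect_families <- c(mean_fio2 = "fio2_shift",
                      n_desaturations = "desat_rate",
                      hypoxia_burden = "deep_rate",
                      hyperoxia_time = "hyper_rate",
                      skew_hr = "spike_rate")

# baseline latent parameters of the signal model
.gen_par <- list(
  spo2_setpoint_mean = 93, spo2_setpoint_sd = 1.2,
  spo2_sd = 1.5, spo2_tau = 600,
  hr_setpoint_mean = 160, hr_setpoint_sd = 8, hr_sd = 7, hr_tau = 300,
  hr_spike_rate = 24, hr_spike_amp = 18, hr_spike_dur = c(30, 180),
  hr_dip_rate = 4, hr_dip_cv = 0.5, hr_dip_depth = c(70, 95),
  hr_dip_dur = c(10, 60),
  fio2_base_mean_excess = 0.04, fio2_base_cap = 0.8,
  fio2_step_rate = 4, fio2_step_sd = 0.02, fio2_setpoint_sd = 0.04,
  desat_rate = 8, desat_cv = 0.4, desat_depth = c(65, 78),
  desat_dur = c(15, 60), desat_rate_sd = 4,
  deep_rate = 1.5, deep_cv = 0.5, deep_depth = c(55, 70),
  deep_dur = c(120, 360),
  hyper_rate = 3, hyper_cv = 0.5, hyper_level = c(96.5, 99.5),
  hyper_dur = c(600, 2400))

#' Generate a synthetic cohort with 30-day physiological traces
#'
#' Draws a demographics/clinical table whose group-conditional
#' distributions mirror a very-preterm NICU population (laser-group infants
#' have lower gestational age and birth weight and higher rates of
#' inotrope/dexamethasone exposure), and per-infant monitor traces: SpO2 as
#' a bounded AR(1) process around a per-infant setpoint with desaturation,
#' deep-hypoxia and hyperoxia event overlays; heart rate as AR(1) with
#' positive-skew spike events; FiO2 as a slowly varying step function
#' bounded below by room air (0.21). Group effects configured in
#' `config$effect_windows` are injected on these latent generators, not on
#' extracted features.
#'
#' @param config A [generator_config()].
#' @return list with elements `cohort` (data.frame, one row per infant) and
#'   `traces` (data.table: `infant_id`, `t_seconds`, `spo2`, `hr`, `fio2`,
#'   `valid`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_infants
    if (!is.null(config$n_positive)) {
      outcome <- integer(n)
      outcome[sample.int(n, config$n_positive)] <- 1L
    } else {
      outcome <- rbinom(n, 1, config$prevalence)
      tries <- 0
      while (n >= 20 && length(unique(outcome)) < 2 && tries < 100) {
        if (config$on_degenerate == "fail")
          stop("degenerate outcome draw: one class is empty")
        if (tries == 0)
          warning("outcome draw left a class empty; resampling")
        outcome <- rbinom(n, 1, config$prevalence)
        tries <- tries + 1
      }
    }
    cohort <- generate_demographics(outcome)
    traces <- generate_traces(cohort, config)
    if (config$missingness_rate > 0)
      traces <- apply_missingness(traces, config$missingness_rate,
                                  seed = derive_seed(config$seed, "missing"))
    list(cohort = cohort, traces = traces)
  })
}

# Demographics/clinical covariates conditional on outcome; rates and
# location shifts follow the typical contrast between infants who do and
# do not go on to need laser treatment (younger, lighter, more oxygen and
# steroid exposure in the laser group).
generate_demographics <- function(outcome) {
  n <- length(outcome)
  pos <- outcome == 1
  ga <- ifelse(pos, rnorm(n, 25.0, 0.9), rnorm(n, 26.8, 1.5))
  ga <- pmin(pmax(ga, 23), 31.9)
  bw <- ifelse(pos, 660 + 150 * (ga - 25.0) + rnorm(n, 0, 120),
                    855 + 170 * (ga - 26.6) + rnorm(n, 0, 180))
  bw <- pmax(bw, 350)
  rb <- function(p_neg, p_pos) rbinom(n, 1, ifelse(pos, p_pos, p_neg))
  data.frame(
    infant_id = sprintf("P%04d", seq_len(n)),
    outcome = as.integer(outcome),
    gestational_age = round(ga, 1),
    birth_weight = round(bw),
    sex = rb(0.73, 0.47),
    multiple_birth = rb(0.26, 0.13),
    prenatal_steroid_doses = rbinom(n, 3, ifelse(pos, 0.55, 0.62)),
    delivery_route = rb(0.59, 0.73),
    apgar_1min = pmin(pmax(round(rnorm(n, ifelse(pos, 5.8, 5.2), 2)), 0), 10),
    apgar_5min = pmin(pmax(round(rnorm(n, 7.7, 1.2)), 0), 10),
    surfactant = rb(0.76, 0.93),
    inotropes = rb(0.29, 0.67),
    doxapram = rb(0.48, 0.53),
    dexamethasone = rb(0.26, 0.80),
    rbc_transfusion = rb(0.81, 0.97),
    ino_therapy = rb(0.12, 0.33),
    nec = rb(0.13, 0.13),
    sepsis = rb(0.65, 0.87),
    ivh = rb(0.19, 0.20),
    pda = rb(0.45, 0.53),
    stringsAsFactors = FALSE)
}

# effect value per day (length `days`) for one family, 0 when unconfigured
effect_by_day <- function(windows, family, days) {
  e <- numeric(days)
  if (is.null(windows) || nrow(windows) == 0) return(e)
  w <- windows[windows$family == family, , drop = FALSE]
  for (k in seq_len(nrow(w)))
    e[w$day_start[k]:w$day_end[k]] <- e[w$day_start[k]:w$day_end[k]] +
      w$effect[k]
  e
}

# stationary AR(1) with correlation time tau (seconds)
ar1_series <- function(n, sd_st, tau, dt) {
  phi <- exp(-dt / tau)
  innov <- rnorm(n, 0, sd_st * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, 0, sd_st)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# Poisson events with per-day rates; onset uniform within the day.
draw_events <- function(rate_by_day, dur_range) {
  counts <- rpois(length(rate_by_day), pmax(rate_by_day, 0))
  total <- sum(counts)
  if (total == 0)
    return(data.frame(start_s = numeric(0), dur_s = numeric(0)))
  d <- rep(seq_along(rate_by_day), counts)
  data.frame(start_s = (d - 1) * 86400 + runif(total) * 86400,
             dur_s = runif(total, dur_range[1], dur_range[2]))
}

# indices of samples covered by events (sample k covers [(k-1)dt, k dt))
event_sample_idx <- function(ev, dt, n_samp) {
  if (nrow(ev) == 0) return(list(idx = integer(0), ev_id = integer(0)))
  first <- pmax(1L, as.integer(ev$start_s %/% dt) + 1L)
  last <- pmin(n_samp, as.integer((ev$start_s + ev$dur_s) %/% dt) + 1L)
  len <- pmax(0L, last - first + 1L)
  keep <- len > 0L
  list(idx = sequence(len[keep], from = first[keep]),
       ev_id = rep(which(keep), len[keep]))
}

generate_traces <- function(cohort, config) {
  p <- .gen_par
  dt <- config$sampling_interval
  days <- config$days
  n_samp <- as.integer(days * 86400 / dt)
  t_s <- (seq_len(n_samp) - 1) * dt
  day_of_sample <- as.integer(t_s %/% 86400) + 1L
  ew <- config$effect_windows

  eff <- lapply(names(.effect_families), function(f)
    effect_by_day(ew, f, days))
  names(eff) <- names(.effect_families)

  per_infant <- lapply(seq_len(nrow(cohort)), function(i) {
    laser <- cohort$outcome[i] == 1
    e <- if (laser) eff else
      lapply(eff, function(x) numeric(days))

    # --- FiO2: step function >= 0.21, laser setpoint shifted in window
    base_fio2 <- 0.21 + min(rexp(1, 1 / p$fio2_base_mean_excess),
                            p$fio2_base_cap - 0.21)
    n_steps <- rpois(1, p$fio2_step_rate * days) + 1L
    step_t <- sort(c(0, runif(n_steps - 1, 0, days * 86400)))
    step_v <- pmax(0.21, base_fio2 + rnorm(n_steps, 0, p$fio2_step_sd))
    fio2 <- step_v[findInterval(t_s, step_t)]
    fio2 <- pmin(1, pmax(0.21, fio2 +
      e$mean_fio2[day_of_sample] * p$fio2_setpoint_sd))

    # --- SpO2: AR(1) + event overlays
    sp_set <- rnorm(1, p$spo2_setpoint_mean, p$spo2_setpoint_sd)
    spo2 <- sp_set + ar1_series(n_samp, p$spo2_sd, p$spo2_tau, dt)

    hyper_rate <- rgamma_rate(p$hyper_rate, p$hyper_cv) *
      pmax(0.02, 1 + 0.5 * e$hyperoxia_time)
    hyper <- draw_events(hyper_rate, p$hyper_dur)
    hx <- event_sample_idx(hyper, dt, n_samp)
    if (length(hx$idx)) {
      lev <- runif(nrow(hyper), p$hyper_level[1], p$hyper_level[2])
      spo2[hx$idx] <- pmax(spo2[hx$idx], lev[hx$ev_id])
    }

    desat_rate <- pmax(0.2, rgamma_rate(p$desat_rate, p$desat_cv) +
                              e$n_desaturations * p$desat_rate_sd)
    desat <- draw_events(desat_rate, p$desat_dur)
    deep_rate <- rgamma_rate(p$deep_rate, p$deep_cv) *
      pmax(0.02, 1 + 0.6 * e$hypoxia_burden)
    deep <- draw_events(deep_rate, p$deep_dur)
    dips <- rbind(desat, deep)
    depth <- c(runif(nrow(desat), p$desat_depth[1], p$desat_depth[2]),
               runif(nrow(deep), p$deep_depth[1], p$deep_depth[2]))
    dx <- event_sample_idx(dips, dt, n_samp)
    if (length(dx$idx))
      spo2[dx$idx] <- pmin(spo2[dx$idx],
                           depth[dx$ev_id] + rnorm(length(dx$idx), 0, 1))
    spo2 <- pmin(100, pmax(40, spo2))

    # --- HR: AR(1) + positive spikes; spike rate sets daily skewness
    hr_set <- rnorm(1, p$hr_setpoint_mean, p$hr_setpoint_sd)
    hr <- hr_set + ar1_series(n_samp, p$hr_sd, p$hr_tau, dt)
    spike_rate <- rgamma_rate(p$hr_spike_rate, 0.3) *
      pmax(0.02, 1 + 0.6 * e$skew_hr)
    spikes <- draw_events(spike_rate, p$hr_spike_dur)
    sx <- event_sample_idx(spikes, dt, n_samp)
    if (length(sx$idx)) {
      amp <- rexp(nrow(spikes), 1 / p$hr_spike_amp)
      hr <- hr + `[<-`(numeric(n_samp), sx$idx, amp[sx$ev_id])
    }
    # apnea-associated bradycardia dips
    dip_rate <- rgamma_rate(p$hr_dip_rate, p$hr_dip_cv)
    hrdips <- draw_events(rep(dip_rate, days), p$hr_dip_dur)
    bx <- event_sample_idx(hrdips, dt, n_samp)
    if (length(bx$idx)) {
      dep <- runif(nrow(hrdips), p$hr_dip_depth[1], p$hr_dip_depth[2])
      hr[bx$idx] <- pmin(hr[bx$idx],
                         dep[bx$ev_id] + rnorm(length(bx$idx), 0, 2))
    }
    hr <- pmax(50, hr)

    data.table(infant_id = cohort$infant_id[i], t_seconds = t_s,
               spo2 = spo2, hr = hr, fio2 = fio2, valid = 1L)
  })
  rbindlist(per_infant)
}

# per-infant mean rate heterogeneity: gamma with given mean and CV, per day
rgamma_rate <- function(mean_rate, cv) {
  shape <- 1 / cv^2
  rep(stats::rgamma(1, shape = shape, rate = shape / mean_rate), 1)
}

#' Flag a random fraction of samples invalid
#'
#' Marks each sample invalid independently with the given probability,
#' emulating monitor artifacts/disconnections. Timestamps and signal values
#' are unchanged; invalid samples carry a flag, never sentinel values.
#'
#' @param traces Long trace table (see [generate_cohort()]).
#' @param rate Per-sample probability of invalidation, in \[0, 1\].
#' @param seed Integer seed.
#' @return The trace table with an updated `valid` column.
#' @export
apply_missingness <- function(traces, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  out <- data.table::as.data.table(traces)
  with_seed(seed, {
    drop <- runif(nrow(out)) < rate
    out[, valid := as.integer(valid == 1L & !drop)]
  })
  out[]
}

#' Read or write trace and cohort tables as delimited text
#'
#' Traces are long-format tab-separated text, one row per sample with
#' columns `infant_id`, `t_seconds`, `spo2`, `hr`, `fio2`, `valid`; the
#' cohort table is tab-separated with a header row.
#'
#' @param traces,cohort Tables as produced by [generate_cohort()].
#' @param path File path.
#' @return The read functions return a data.table / data.frame.
#' @export
write_traces <- function(traces, path) {
  data.table::fwrite(traces, path, sep = "\t")
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  tr <- data.table::fread(path, sep = "\t")
  need <- c("infant_id", "t_seconds", "spo2", "hr", "fio2", "valid")
  if (!all(need %in% names(tr)))
    stop("trace file must have columns: ", paste(need, collapse = ", "))
  tr
}

#' @rdname write_traces
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(cohort, path, sep = "\t")
  invisible(path)
}

#' @rdname write_traces
#' @export
read_cohort <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
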