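#' Welch two-sample t statistic
#'
#' Unequal-variance (Welch) t statistic, robust to the strong group-size
#' imbalance of this cohort (about 15 laser vs 85 non-laser infants).
#' Missing values are dropped. Also returns the Welch-Satterthwaite
#' degrees of freedom used for the cluster-forming threshold.
#'
#' @param a,b Numeric vectors (group A and group B).
#' @return list with `t` (positive when mean(a) > mean(b)) and `df`; both
#'   `NA` when either group has fewer than 2 non-missing values.
#' @export
pointwise_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) return(list(t = NA_real_, df = NA_real_))
  va <- var(a) / na; vb <- var(b) / nb
  se2 <- va + vb
  if (se2 == 0) return(list(t = 0, df = na + nb - 2))
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = (mean(a) - mean(b)) / sqrt(se2), df = df)
}

#' Form candidate clusters from a daily t-statistic series
#'
#' Maximal runs of consecutive days whose |t| exceeds the two-sided
#' critical value at `alpha_cluster` (per-day Welch df), split by sign; a
#' missing day breaks contiguity. The cluster mass is the sum of t over
#' the run.
#'
#' @param t_series Per-day t statistics (NA allowed).
#' @param df_series Per-day degrees of freedom for the critical value.
#' @param alpha_cluster Two-sided cluster-forming alpha (default 0.05).
#' @return data.frame `day_start`, `day_end`, `sign`, `mass` (possibly
#'   zero rows).
#' @export
form_clusters <- function(t_series, df_series, alpha_cluster = 0.05) {
  crit <- qt(1 - alpha_cluster / 2, df_series)
  supra <- !is.na(t_series) & abs(t_series) > crit
  sgn <- ifelse(supra, sign(t_series), 0)
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0 & !is.na(r$values)
  if (!any(keep))
    return(data.frame(day_start = integer(0), day_end = integer(0),
                      sign = integer(0), mass = numeric(0)))
  ds <- starts[keep]; de <- ends[keep]
  mass <- vapply(seq_along(ds),
                 function(k) sum(t_series[ds[k]:de[k]]), 0)
  data.frame(day_start = ds, day_end = de,
             sign = as.integer(r$values[keep]), mass = mass)
}

# Vectorised Welch t for all permutations at once.
# X: n x d matrix (may contain NA); P: n x n_col 0/1 group-A membership.
# Returns list of d x n_col matrices t and df.
welch_t_perm <- function(X, P) {
  V <- !is.na(X)
  X0 <- ifelse(V, X, 0)
  Vn <- V * 1
  nA <- crossprod(Vn, P)              # d x n_col
  sA <- crossprod(X0, P)
  qA <- crossprod(X0^2, P)
  nT <- colSums(Vn); sT <- colSums(X0); qT <- colSums(X0^2)
  nB <- nT - nA; sB <- sT - sA; qB <- qT - qA
  ok <- nA >= 2 & nB >= 2
  nA[!ok] <- NA
  mA <- sA / nA; mB <- sB / nB
  vA <- (qA - nA * mA^2) / (nA - 1)
  vB <- (qB - nB * mB^2) / (nB - 1)
  vA <- pmax(vA, 0); vB <- pmax(vB, 0)
  ra <- vA / nA; rb <- vB / nB
  se2 <- ra + rb
  tst <- (mA - mB) / sqrt(se2)
  df <- se2^2 / (ra^2 / (nA - 1) + rb^2 / (nB - 1))
  zerose <- !is.na(se2) & se2 == 0
  tst[zerose] <- 0
  df[zerose] <- (nA + nB - 2)[zerose]
  tst[!ok] <- NA
  list(t = tst, df = df)
}

# lean scorer for the permutation loop: max |cluster mass| of one series,
# given precomputed critical values (same clustering rule as form_clusters)
max_cluster_mass <- function(t_col, crit_col) {
  supra <- !is.na(t_col) & abs(t_col) > crit_col
  if (!any(supra)) return(0)
  sgn <- numeric(length(t_col))
  sgn[supra] <- sign(t_col[supra])
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- 0
  for (k in which(r$values != 0)) {
    m <- abs(sum(t_col[starts[k]:ends[k]]))
    if (m > best) best <- m
  }
  best
}

#' Cluster-based permutation test for one feature family
#'
#' Identifies day windows where a daily feature differs between the laser
#' and non-laser groups, with family-wise error control over days by the
#' cluster-mass permutation method: per-day Welch t statistics are
#' thresholded at the two-sided `alpha_cluster` critical value, contiguous
#' suprathreshold runs form clusters scored by their summed t, and each
#' observed cluster mass is referred to the permutation distribution of
#' the maximum absolute cluster mass under random relabelling (group sizes
#' preserved). Monte-Carlo p = (1 + #\{null >= |mass|\}) / (1 + n_perm).
#'
#' @param X Numeric matrix, infants x days (NA for missing cells).
#' @param labels 0/1 outcome per row of `X` (1 = laser); the t statistic
#'   is positive when the laser group mean is higher.
#' @param n_perm Number of label permutations (>= 99; default 5000).
#' @param seed Integer seed for the permutation draw.
#' @param alpha_cluster Cluster-forming alpha (default 0.05).
#' @param alpha Cluster-level significance level (default 0.05).
#' @return list of class `cluster_result`: `clusters` (data.frame with
#'   `day_start`, `day_end`, `sign`, `mass`, `p_value`, `significant`),
#'   `pointwise_t`, `pointwise_df`, `n_perm`, `seed`.
#' @export
permutation_test <- function(X, labels, n_perm = 5000, seed = 1L,
                             alpha_cluster = 0.05, alpha = 0.05) {
  stopifnot(is.matrix(X), nrow(X) == length(labels), n_perm >= 99)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both groups must be non-empty")
  n <- nrow(X)
  nA <- sum(labels == 1)

  obs <- welch_t_perm(X, matrix(as.numeric(labels == 1), ncol = 1))
  t_obs <- unname(drop(obs$t)); df_obs <- unname(drop(obs$df))
  clusters <- form_clusters(t_obs, df_obs, alpha_cluster)

  null_max <- with_seed(seed, {
    P <- matrix(0, n, n_perm)
    for (j in seq_len(n_perm)) P[sample.int(n, nA), j] <- 1
    w <- welch_t_perm(X, P)
    crit <- qt(1 - alpha_cluster / 2, w$df)
    vapply(seq_len(n_perm), function(j)
      max_cluster_mass(w$t[, j], crit[, j]), 0)
  })

  if (nrow(clusters) > 0) {
    clusters$p_value <- vapply(clusters$mass, function(m)
      (1 + sum(null_max >= abs(m))) / (1 + n_perm), 0)
    clusters$significant <- clusters$p_value < alpha
  } else {
    clusters$p_value <- numeric(0)
    clusters$significant <- logical(0)
  }
  structure(list(clusters = clusters, pointwise_t = t_obs,
                 pointwise_df = df_obs, n_perm = n_perm, seed = seed,
                 alpha_cluster = alpha_cluster, alpha = alpha),
            class = "cluster_result")
}

#' Cluster scan over all feature families
#'
#' Runs [permutation_test()] for each feature family of a daily feature
#' matrix and collects per-family cluster tables.
#'
#' @param fm Long feature matrix from [build_feature_matrix()].
#' @param cohort Cohort table supplying `infant_id` and `outcome`.
#' @param families Families to scan (default all 13).
#' @param n_perm,seed,alpha_cluster,alpha Passed to [permutation_test()];
#'   each family gets an independent sub-seed derived from `seed`.
#' @return list of class `cluster_scan`: named list `results` of
#'   `cluster_result`, plus `summary` data.frame (one row per cluster).
#' @export
cluster_scan <- function(fm, cohort, families = feature_families(),
                         n_perm = 5000, seed = 1L,
                         alpha_cluster = 0.05, alpha = 0.05) {
  ids <- cohort$infant_id
  labels <- cohort$outcome
  results <- lapply(families, function(f) {
    X <- feature_day_matrix(fm, f, ids = ids)
    permutation_test(X, labels, n_perm = n_perm,
                     seed = derive_seed(seed, f),
                     alpha_cluster = alpha_cluster, alpha = alpha)
  })
  names(results) <- families
  summary <- do.call(rbind, lapply(families, function(f) {
    cl <- results[[f]]$clusters
    if (nrow(cl) == 0) return(NULL)
    cbind(feature = f, cl)
  }))
  if (is.null(summary))
    summary <- data.frame(feature = character(0), day_start = integer(0),
                          day_end = integer(0), sign = integer(0),
                          mass = numeric(0), p_value = numeric(0),
                          significant = logical(0))
  structure(list(results = results, summary = summary,
                 n_perm = n_perm, seed = seed),
            class = "cluster_scan")
}

#' Feature families with at least one significant cluster
#'
#' Optionally restricted to clusters overlapping a day window, for the
#' classifier's feature-window selection.
#'
#' @param scan A `cluster_scan`.
#' @param day_window Optional `c(start, end)`; only clusters overlapping
#'   it count.
#' @return Character vector of family names.
#' @export
significant_families <- function(scan, day_window = NULL) {
  s <- scan$summary
  s <- s[s$significant, , drop = FALSE]
  if (!is.null(day_window))
    s <- s[s$day_start <= day_window[2] & s$day_end >= day_window[1], ,
           drop = FALSE]
  unique(s$feature)
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat("Cluster scan:", length(x$results), "families,",
      x$n_perm, "permutations\n")
  s <- x$summary[x$summary$significant, , drop = FALSE]
  if (nrow(s) == 0) cat("  no significant clusters\n")
  else for (k in seq_len(nrow(s)))
    cat(sprintf("  %-16s days %2d-%2d  sign %+d  mass %8.2f  p = %.4f\n",
                s$feature[k], s$day_start[k], s$day_end[k], s$sign[k],
                s$mass[k], s$p_value[k]))
  invisible(x)
}
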