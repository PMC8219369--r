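#' Kolmogorov-Smirnov comparison of seizure-duration distributions
#'
#' Two-sample two-sided KS test on the empirical distributions of stimulated
#' (light on) versus unstimulated (light off) seizure durations within one
#' animal.
#'
#' @param on,off duration vectors, seconds (each of length >= 3).
#' @return list with `D` and `p`.
#' @export
ks_durations <- function(on, off) {
  if (length(on) < 3 || length(off) < 3) {
    stop("both duration lists must hold at least 3 values", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(on, off, alternative = "two.sided"))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Paired Wilcoxon signed-rank test on per-animal medians
#'
#' Two-sided signed-rank test on the paired differences of per-animal median
#' seizure durations (or interseizure intervals) between conditions. Exact
#' distribution for up to 25 pairs, normal approximation with continuity
#' correction above. All-zero differences are a degenerate case reported as
#' `p = 1`.
#'
#' @param median_on,median_off per-animal medians, paired.
#' @return list with `W`, `p`, `n`, and `degenerate`.
#' @export
group_wilcoxon_medians <- function(median_on, median_off) {
  if (length(median_on) != length(median_off)) {
    stop("paired medians must have equal length", call. = FALSE)
  }
  d <- median_on - median_off
  if (all(d == 0)) {
    return(list(W = 0, p = 1, n = length(d), degenerate = TRUE))
  }
  n_nz <- sum(d != 0)
  res <- suppressWarnings(
    stats::wilcox.test(median_on, median_off, paired = TRUE,
                       exact = n_nz <= 25, correct = TRUE,
                       alternative = "two.sided")
  )
  list(W = unname(res$statistic), p = res$p.value, n = length(d),
       degenerate = FALSE)
}

#' Normalized change in median seizure duration
#'
#' `(median_on - median_off) / median_off` per animal: the per-mouse
#' normalized change between light off and light on conditions.
#'
#' @param median_on,median_off per-animal medians (median_off > 0).
#' @return numeric vector of normalized changes.
#' @export
normalized_change <- function(median_on, median_off) {
  if (any(median_off <= 0)) {
    stop("`median_off` must be positive to normalize", call. = FALSE)
  }
  (median_on - median_off) / median_off
}

#' Two-sample t test on normalized median-duration changes
#'
#' Compares per-animal normalized changes between the opsin-expressing group
#' and opsin-free controls. Welch's unequal-variance form by default (safer
#' at 7 vs 4 animals); the classic pooled form is available via
#' `var_equal = TRUE`.
#'
#' @param chr2_changes,control_changes per-animal normalized changes (each
#'   length >= 2).
#' @param var_equal assume equal variances (default FALSE: Welch).
#' @return list with `T`, `df`, and `p`.
#' @export
normalized_change_test <- function(chr2_changes, control_changes,
                                   var_equal = FALSE) {
  if (length(chr2_changes) < 2 || length(control_changes) < 2) {
    stop("both groups must hold at least 2 animals", call. = FALSE)
  }
  if (stats::var(chr2_changes) == 0 && stats::var(control_changes) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  res <- stats::t.test(chr2_changes, control_changes, var.equal = var_equal,
                       alternative = "two.sided")
  list(T = unname(res$statistic), df = unname(res$parameter), p = res$p.value)
}

#' Interseizure-interval analysis
#'
#' The interval following each seizure (next onset minus this offset) is
#' assigned to that seizure's stimulation condition; per-animal median
#' intervals are compared across conditions with a paired Wilcoxon
#' signed-rank test. The last event's trailing interval is undefined and
#' excluded; animals lacking both conditions are excluded.
#'
#' @param events_by_animal list of per-animal event data frames with columns
#'   `onset`, `offset`, `stimulated`.
#' @return list with `per_animal` (data frame: animal, median_on, median_off),
#'   `W`, `p`, and `n_excluded`.
#' @export
interseizure_analysis <- function(events_by_animal) {
  rows <- lapply(seq_along(events_by_animal), function(a) {
    ev <- events_by_animal[[a]]
    if (is.null(ev) || nrow(ev) < 2) return(NULL)
    ev <- ev[order(ev$onset), , drop = FALSE]
    gap <- ev$onset[-1] - ev$offset[-nrow(ev)]
    cond <- ev$stimulated[-nrow(ev)]
    if (!any(cond) || all(cond)) return(NULL)
    data.frame(animal = a,
               median_on = stats::median(gap[cond]),
               median_off = stats::median(gap[!cond]))
  })
  keep <- !vapply(rows, is.null, logical(1))
  per_animal <- do.call(rbind, rows[keep])
  if (is.null(per_animal) || nrow(per_animal) < 2) {
    stop("fewer than 2 animals with both conditions", call. = FALSE)
  }
  w <- group_wilcoxon_medians(per_animal$median_on, per_animal$median_off)
  list(per_animal = per_animal, W = w$W, p = w$p,
       n_excluded = sum(!keep))
}

#' Paired t test on median behavioural seizure severity
#'
#' Two-sided paired t test on per-animal median Racine scores between
#' stimulated and unstimulated seizures. Scores must lie on the modified
#' six-point Racine scale (1-6). Identical paired medians are a degenerate
#' case reported as `T = 0, p = 1`.
#'
#' @param severity_on,severity_off per-animal median Racine scores, paired.
#' @return list with `T`, `df`, `p`, and `degenerate`.
#' @export
severity_paired_test <- function(severity_on, severity_off) {
  if (length(severity_on) != length(severity_off) || length(severity_on) < 2) {
    stop("need >= 2 paired per-animal severity medians", call. = FALSE)
  }
  sev <- c(severity_on, severity_off)
  if (any(sev < 1 | sev > 6)) {
    stop("Racine scores must lie in [1, 6]", call. = FALSE)
  }
  d <- severity_on - severity_off
  if (all(d == 0)) {
    return(list(T = 0, df = length(d) - 1, p = 1, degenerate = TRUE))
  }
  res <- stats::t.test(severity_on, severity_off, paired = TRUE,
                       alternative = "two.sided")
  list(T = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, degenerate = FALSE)
}

#' Summarize one animal's detected seizures
#'
#' Builds the per-animal endpoint summary from an event table: duration
#' medians by condition, the KS comparison, the normalized median change,
#' and (if present) severity medians.
#'
#' @param events data frame with `onset`, `offset`, `duration`, `stimulated`,
#'   and optionally `severity`.
#' @param animal_id identifier stored with the result.
#' @return an object of class `szl_animal` (list of summaries).
#' @export
animal_result <- function(events, animal_id = NA) {
  on <- events$duration[events$stimulated]
  off <- events$duration[!events$stimulated]
  ks <- if (length(on) >= 3 && length(off) >= 3) ks_durations(on, off) else
    list(D = NA_real_, p = NA_real_)
  med_on <- stats::median(on); med_off <- stats::median(off)
  sev_on <- sev_off <- NA_real_
  if (!is.null(events$severity)) {
    sev_on <- stats::median(events$severity[events$stimulated])
    sev_off <- stats::median(events$severity[!events$stimulated])
  }
  structure(
    list(animal_id = animal_id, events = events,
         durations_on = on, durations_off = off,
         median_on = med_on, median_off = med_off,
         ks_statistic = ks$D, ks_p = ks$p,
         normalized_change = if (is.finite(med_off) && med_off > 0)
           (med_on - med_off) / med_off else NA_real_,
         severity_on = sev_on, severity_off = sev_off),
    class = "szl_animal"
  )
}

#' Group-level endpoint statistics for a two-cohort experiment
#'
#' Assembles the endpoint tests from per-animal results: paired Wilcoxon on
#' median durations within the opsin cohort, the two-sample t test on
#' normalized changes between cohorts, the interseizure-interval Wilcoxon,
#' and (when severity is present) the paired severity t test.
#'
#' @param chr2 list of `szl_animal` results for the opsin-expressing cohort.
#' @param control list of `szl_animal` results for the control cohort (may be
#'   `NULL` to skip the between-cohort test).
#' @return an object of class `szl_group` (list of test results and the
#'   per-animal table).
#' @export
group_result <- function(chr2, control = NULL) {
  med_on <- vapply(chr2, function(a) a$median_on, numeric(1))
  med_off <- vapply(chr2, function(a) a$median_off, numeric(1))
  wil <- group_wilcoxon_medians(med_on, med_off)
  nc_chr2 <- vapply(chr2, function(a) a$normalized_change, numeric(1))
  tt <- NULL
  if (!is.null(control)) {
    nc_ctrl <- vapply(control, function(a) a$normalized_change, numeric(1))
    tt <- normalized_change_test(nc_chr2, nc_ctrl)
  }
  isz <- interseizure_analysis(lapply(chr2, function(a) a$events))
  sev <- NULL
  sev_on <- vapply(chr2, function(a) a$severity_on, numeric(1))
  sev_off <- vapply(chr2, function(a) a$severity_off, numeric(1))
  if (all(is.finite(sev_on)) && all(is.finite(sev_off))) {
    sev <- severity_paired_test(sev_on, sev_off)
  }
  per_animal <- data.frame(
    animal = vapply(chr2, function(a) as.character(a$animal_id), character(1)),
    median_on = med_on, median_off = med_off,
    ks_p = vapply(chr2, function(a) a$ks_p, numeric(1)),
    normalized_change = nc_chr2
  )
  structure(
    list(per_animal = per_animal, wilcoxon = wil,
         normalized_change_t = tt, interseizure = isz, severity = sev),
    class = "szl_group"
  )
}
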