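#' Sigmoidal bounding of raw feature values
#'
#' Maps each raw feature through a logistic
#' `x -> 1 / (1 + exp(-(x - centre) / scale))`, producing values strictly in
#' (0, 1) and strictly increasing in the raw feature. Outputs are clipped to
#' `[1e-12, 1 - 1e-12]` so extreme features cannot saturate to the exact
#' bounds in floating point.
#'
#' @param features numeric vector (or matrix, intervals in rows) of raw
#'   feature values ordered as `coastline, intermittency, spikiness,
#'   coherence`.
#' @param calibration list with numeric vectors `centre` and `scale` (one
#'   entry per feature) as produced by [calibrate_sigmoid()].
#' @return bounded values with the same shape as `features`.
#' @export
sigmoid_bound <- function(features, calibration) {
  if (any(calibration$scale <= 0)) {
    stop("sigmoid `scale` must be positive for every feature", call. = FALSE)
  }
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (is.matrix(features)) {
    out <- sapply(seq_len(ncol(features)), function(j) {
      clamp(stats::plogis((features[, j] - calibration$centre[j]) /
                            calibration$scale[j]))
    })
    out <- matrix(out, ncol = ncol(features))
    colnames(out) <- colnames(features)
    out
  } else {
    clamp(stats::plogis((features - calibration$centre) / calibration$scale))
  }
}

#' Calibrate the sigmoid bounding from labelled intervals
#'
#' Per feature, the logistic centre is the midpoint of the baseline and
#' seizure medians and the scale is half the mean of the two interquartile
#' ranges, so baseline intervals map mostly below 0.5 and seizure intervals
#' mostly above.
#'
#' @param baseline_features matrix/data frame of raw feature rows from
#'   non-seizure intervals (columns `coastline, intermittency, spikiness,
#'   coherence`).
#' @param seizure_features same, for within-seizure intervals.
#' @return list with `centre` and `scale` numeric vectors (length 4).
#' @export
calibrate_sigmoid <- function(baseline_features, seizure_features) {
  b <- as.matrix(as.data.frame(baseline_features)[, szl_feature_names])
  s <- as.matrix(as.data.frame(seizure_features)[, szl_feature_names])
  if (nrow(b) == 0 || nrow(s) == 0) {
    stop("both baseline and seizure feature sets must be non-empty",
         call. = FALSE)
  }
  med_b <- apply(b, 2, stats::median)
  med_s <- apply(s, 2, stats::median)
  iqr_b <- apply(b, 2, stats::IQR)
  iqr_s <- apply(s, 2, stats::IQR)
  centre <- (med_b + med_s) / 2
  scale <- (iqr_b + iqr_s) / 4
  if (any(scale <= 0)) {
    stop("degenerate zero-spread feature; cannot calibrate sigmoid",
         call. = FALSE)
  }
  flat <- med_b == med_s
  if (any(flat)) {
    warning(sprintf("non-separable feature(s): %s",
                    paste(szl_feature_names[flat], collapse = ", ")))
  }
  list(centre = centre, scale = scale)
}

#' Classify one interval against the seizure library
#'
#' An interval is seizure-positive if some library entry matches it to within
#' the similarity threshold on every metric simultaneously (per-metric
#' Chebyshev rule, boundary inclusive).
#'
#' @param sigmoid_vec bounded 4-feature vector of the interval.
#' @param library a [build_seizure_library()] object, or a numeric matrix of
#'   bounded library entries (entries in rows).
#' @param threshold per-metric similarity threshold (default 0.1).
#' @return list with `is_seizure` (logical) and `best_distance` (minimum over
#'   entries of the max-over-features absolute difference).
#' @export
classify_interval <- function(sigmoid_vec, library, threshold = 0.1) {
  entries <- if (inherits(library, "szl_library")) library$entries else library
  if (is.null(entries) || nrow(entries) == 0) {
    stop("seizure library is empty", call. = FALSE)
  }
  d <- abs(sweep(entries, 2, as.numeric(sigmoid_vec)))
  best <- min(apply(d, 1, max))
  list(is_seizure = best <= threshold, best_distance = best)
}

# Vectorized Chebyshev-match of many intervals (rows of `sig`) against the
# library; returns the per-interval best distance.
chebyshev_best_distance <- function(sig, entries) {
  best <- rep(Inf, nrow(sig))
  for (k in seq_len(nrow(entries))) {
    d <- abs(sig[, 1] - entries[k, 1])
    for (j in 2:ncol(sig)) {
      d <- pmax(d, abs(sig[, j] - entries[k, j]))
    }
    best <- pmin(best, d)
  }
  best
}

#' Assemble seizure events from per-interval classifications
#'
#' Implements the online timestamp rule and the offline event extension: a
#' timestamp is emitted at the Nth consecutive positive interval
#' (`consecutive_required`, default 3), the event onset is the start of the
#' first interval of that run, and the offline offset is the end of the last
#' positive interval before a run of more than `gap_tolerance_intervals`
#' negatives.
#'
#' @param flags logical vector of per-interval classifications, time-ordered
#'   and contiguous.
#' @param config a [detector_config()].
#' @return data frame with `onset`, `offset`, `duration` (seconds) and
#'   `timestamp_interval` (1-based index of the interval whose end produced
#'   the timestamp).
#' @export
assemble_events <- function(flags, config = detector_config()) {
  len <- config$interval_length
  need <- config$consecutive_required
  gap_tol <- config$gap_tolerance_intervals
  onset <- numeric(0); offset <- numeric(0); ts_int <- integer(0)
  streak <- 0L; gap <- 0L
  in_event <- FALSE
  run_start <- NA_integer_; last_pos <- NA_integer_
  for (i in seq_along(flags)) {
    if (flags[i]) {
      if (!in_event) {
        if (streak == 0L) run_start <- i
        streak <- streak + 1L
        if (streak >= need) {
          in_event <- TRUE
          onset <- c(onset, (run_start - 1L) * len)
          ts_int <- c(ts_int, i)
          last_pos <- i
          gap <- 0L
        }
      } else {
        last_pos <- i
        gap <- 0L
      }
    } else {
      if (in_event) {
        gap <- gap + 1L
        if (gap > gap_tol) {
          offset <- c(offset, last_pos * len)
          in_event <- FALSE
          streak <- 0L; gap <- 0L
        }
      } else {
        streak <- 0L
      }
    }
  }
  if (in_event) offset <- c(offset, last_pos * len)
  data.frame(onset = onset, offset = offset, duration = offset - onset,
             timestamp_interval = ts_int)
}

#' Build a seizure library from a recording with ground truth
#'
#' Collects the sigmoid-bounded 4-feature vectors of all analysis intervals
#' lying fully inside true seizure intervals, calibrating the sigmoid from the
#' within-seizure intervals against intervals fully outside any seizure (with
#' a 2-s guard margin). The calibration is persisted with the library.
#'
#' @param rec a single- or multi-channel [recording()] (the `"lfp"` channel is
#'   used).
#' @param truth ground-truth list with a `seizure_intervals` data frame
#'   (`onset`, `offset` in seconds).
#' @param config a [detector_config()].
#' @return an object of class `szl_library` with `entries` (matrix of bounded
#'   vectors), `calibration`, and `provenance`.
#' @export
build_seizure_library <- function(rec, truth, config = detector_config()) {
  iv <- truth$seizure_intervals
  if (is.null(iv) || nrow(iv) == 0) {
    stop("ground truth holds no seizures; cannot build a library",
         call. = FALSE)
  }
  x <- channel(rec, "lfp")
  feats <- interval_features(x, rec$fs, config)
  len <- config$interval_length
  starts <- feats$interval_start
  ends <- starts + len
  inside <- vapply(seq_along(starts), function(i) {
    any(iv$onset <= starts[i] & ends[i] <= iv$offset)
  }, logical(1))
  margin <- 2
  outside <- vapply(seq_along(starts), function(i) {
    !any(iv$onset - margin < ends[i] & starts[i] < iv$offset + margin)
  }, logical(1))
  if (!any(inside)) {
    stop("no analysis interval lies fully inside a true seizure", call. = FALSE)
  }
  raw <- as.matrix(feats[, szl_feature_names])
  calibration <- calibrate_sigmoid(raw[outside, , drop = FALSE],
                                   raw[inside, , drop = FALSE])
  entries <- sigmoid_bound(raw[inside, , drop = FALSE], calibration)
  colnames(entries) <- szl_feature_names
  structure(
    list(entries = entries, calibration = calibration,
         provenance = list(fs = rec$fs, n_intervals = sum(inside),
                           interval_ids = which(inside))),
    class = "szl_library"
  )
}

#' @export
print.szl_library <- function(x, ...) {
  cat(sprintf("<szl_library> %d entries, calibrated on 4 features\n",
              nrow(x$entries)))
  invisible(x)
}

#' Offline seizure detection on a full recording
#'
#' Runs the complete detector offline: per-interval features, sigmoid
#' bounding with the library's calibration, library matching, and event
#' assembly.
#'
#' @param rec a [recording()] with an `"lfp"` channel.
#' @param library a [build_seizure_library()] object.
#' @param config a [detector_config()].
#' @return list with `events` (data frame from [assemble_events()]), `flags`
#'   (per-interval logical), and `features` (per-interval table with bounded
#'   values appended as `sig_*` columns).
#' @export
detect_seizures <- function(rec, library, config = detector_config()) {
  x <- channel(rec, "lfp")
  feats <- interval_features(x, rec$fs, config)
  sig <- sigmoid_bound(as.matrix(feats[, szl_feature_names]),
                       library$calibration)
  best <- chebyshev_best_distance(sig, library$entries)
  flags <- best <= config$similarity_threshold
  events <- assemble_events(flags, config)
  colnames(sig) <- paste0("sig_", szl_feature_names)
  list(events = events, flags = flags,
       features = cbind(feats, as.data.frame(sig), best_distance = best))
}
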