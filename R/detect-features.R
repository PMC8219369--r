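#' Detector configuration
#'
#' Parameters of the online electrographic seizure detector: non-overlapping
#' 1-s analysis intervals, four interval features, sigmoidal bounding, and
#' library matching with a per-metric similarity threshold. Three consecutive
#' seizure-positive intervals produce a seizure timestamp.
#'
#' @param interval_length analysis interval, seconds.
#' @param spikiness_bin_width bin width for the spikiness feature, seconds
#'   (19.6 ms: 10 samples at 512 Hz).
#' @param intermittency_top_fraction fraction of largest steps whose summed
#'   coastline defines intermittency.
#' @param coherence_n_pairs number of largest peak-trough pairs used by the
#'   coherence feature.
#' @param similarity_threshold per-metric similarity threshold against the
#'   seizure library (inclusive).
#' @param consecutive_required consecutive positive intervals required for a
#'   seizure timestamp.
#' @param gap_tolerance_intervals offline event assembly bridges runs of up to
#'   this many negative intervals when extending an event to its offset.
#' @return an object of class `szl_detector_config`.
#' @export
detector_config <- function(interval_length = 1.0,
                            spikiness_bin_width = 0.0196,
                            intermittency_top_fraction = 0.10,
                            coherence_n_pairs = 10L,
                            similarity_threshold = 0.1,
                            consecutive_required = 3L,
                            gap_tolerance_intervals = 2L) {
  if (intermittency_top_fraction <= 0 || intermittency_top_fraction >= 1) {
    stop("`intermittency_top_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (consecutive_required < 1) {
    stop("`consecutive_required` must be >= 1", call. = FALSE)
  }
  if (similarity_threshold <= 0) {
    stop("`similarity_threshold` must be > 0", call. = FALSE)
  }
  structure(
    list(interval_length = interval_length,
         spikiness_bin_width = spikiness_bin_width,
         intermittency_top_fraction = intermittency_top_fraction,
         coherence_n_pairs = as.integer(coherence_n_pairs),
         similarity_threshold = similarity_threshold,
         consecutive_required = as.integer(consecutive_required),
         gap_tolerance_intervals = as.integer(gap_tolerance_intervals)),
    class = "szl_detector_config"
  )
}

szl_feature_names <- c("coastline", "intermittency", "spikiness", "coherence")

#' Coastline (line length) of an interval
#'
#' Sum of absolute sample-to-sample voltage changes; scale-equivariant and
#' elevated during rhythmic seizure discharges.
#'
#' @param x numeric voltage vector (length >= 2), microvolts.
#' @return coastline in microvolts.
#' @export
coastline <- function(x) {
  if (length(x) < 2) stop("interval must hold at least 2 samples", call. = FALSE)
  sum(abs(diff(x)))
}

#' Intermittency of an interval
#'
#' Fraction of the coastline generated by the largest steps: with
#' `m = ceiling(top_fraction * n_steps)`, the summed `m` largest absolute
#' steps divided by the total coastline. A flat interval (zero coastline)
#' returns 0 with a degenerate attribute.
#'
#' @param x numeric voltage vector (length >= 2).
#' @param top_fraction fraction of steps counted as "largest" (default 0.10).
#' @return fraction in `[top_fraction, 1]` (0 if degenerate).
#' @export
intermittency <- function(x, top_fraction = 0.10) {
  if (length(x) < 2) stop("interval must hold at least 2 samples", call. = FALSE)
  steps <- abs(diff(x))
  total <- sum(steps)
  if (total == 0) {
    return(structure(0, degenerate = TRUE))
  }
  m <- ceiling(top_fraction * length(steps))
  sum(sort(steps, decreasing = TRUE)[seq_len(m)]) / total
}

#' Spikiness of an interval
#'
#' Ratio of the maximum voltage range across fixed-width bins to the median
#' bin range. Bins are `floor(bin_width * fs)` samples (19.6 ms: 10 samples at
#' 512 Hz); a trailing partial bin is dropped. A constant interval (median
#' range 0) returns 1 with a degenerate attribute.
#'
#' @param x numeric voltage vector spanning at least two full bins.
#' @param fs sampling rate, Hz.
#' @param bin_width bin width, seconds.
#' @return ratio >= 1 (or degenerate 1).
#' @export
spikiness <- function(x, fs, bin_width = 0.0196) {
  bw <- floor(bin_width * fs)
  if (bw < 1) stop("bin unrepresentable at this sampling rate", call. = FALSE)
  nb <- floor(length(x) / bw)
  if (nb < 2) stop("interval must span at least two full bins", call. = FALSE)
  m <- matrix(x[seq_len(nb * bw)], nrow = bw)
  ranges <- apply(m, 2, function(v) max(v) - min(v))
  med <- stats::median(ranges)
  if (med == 0) return(structure(1, degenerate = TRUE))
  max(ranges) / med
}

#' Coherence of an interval
#'
#' Fraction of the voltage area under the curve (sum of absolute
#' mean-referenced voltages) occupied by the largest peak-trough pairs. The
#' mean-centred interval is segmented at its local extrema (endpoints
#' included); adjacent extrema are grouped into disjoint peak-trough pairs,
#' each pair owning the samples up to the next pair's first extremum (one full
#' deflection cycle), and pairs are ranked by the absolute voltage difference
#' between their two extrema. The summed area of the top `n_pairs` pairs is
#' divided by the total area. A flat interval returns 0 with a degenerate
#' attribute.
#'
#' @param x numeric voltage vector (length >= 3).
#' @param n_pairs number of pairs counted (default 10).
#' @return fraction in `[0, 1]`.
#' @export
coherence_metric <- function(x, n_pairs = 10L) {
  if (length(x) < 3) stop("interval must hold at least 3 samples", call. = FALSE)
  v <- x - mean(x)
  a <- abs(v)
  total <- sum(a)
  if (total == 0) return(structure(0, degenerate = TRUE))
  ext <- local_extrema(v)
  if (length(ext) < 2) return(structure(0, degenerate = TRUE))
  n_pr <- floor(length(ext) / 2)
  first <- ext[2 * seq_len(n_pr) - 1]
  second <- ext[2 * seq_len(n_pr)]
  span_end <- c(first[-1] - 1L, length(v))
  amp <- abs(v[first] - v[second])
  cs <- c(0, cumsum(a))
  area <- cs[span_end + 1L] - cs[first]
  top <- order(amp, decreasing = TRUE)[seq_len(min(n_pairs, n_pr))]
  min(1, sum(area[top]) / total)
}

# Indices of local extrema of v, endpoints included; plateaus collapse to the
# first sample of the plateau.
local_extrema <- function(v) {
  n <- length(v)
  d <- diff(v)
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  # carry last non-zero sign through plateaus
  idx <- cumsum(nz)
  filled <- s[nz][pmax(idx, 1L)]
  turns <- which(diff(filled) != 0) + 1L
  unique(c(1L, turns, n))
}

#' Per-interval feature table for a whole trace
#'
#' Splits a voltage trace into consecutive non-overlapping intervals aligned
#' to the trace start and computes the four raw detector features for each.
#'
#' @param x numeric voltage vector, microvolts.
#' @param fs sampling rate, Hz.
#' @param config a [detector_config()].
#' @return data frame with `interval_start` (seconds) and one column per
#'   feature (`coastline`, `intermittency`, `spikiness`, `coherence`).
#' @export
interval_features <- function(x, fs, config = detector_config()) {
  len <- round(config$interval_length * fs)
  n_int <- floor(length(x) / len)
  if (n_int < 1) stop("trace shorter than one analysis interval", call. = FALSE)
  m <- matrix(x[seq_len(n_int * len)], nrow = len)

  d <- abs(m[-1, , drop = FALSE] - m[-len, , drop = FALSE])
  cl <- colSums(d)
  n_top <- ceiling(config$intermittency_top_fraction * (len - 1))
  inter <- vapply(seq_len(n_int), function(j) {
    if (cl[j] == 0) return(0)
    sum(sort(d[, j], decreasing = TRUE)[seq_len(n_top)]) / cl[j]
  }, numeric(1))

  bw <- floor(config$spikiness_bin_width * fs)
  nb <- floor(len / bw)
  mb <- matrix(m[seq_len(nb * bw), , drop = FALSE], nrow = bw)
  rows <- asplit(mb, 1)
  rng <- matrix(do.call(pmax, rows) - do.call(pmin, rows), nrow = nb)
  spk <- vapply(seq_len(n_int), function(j) {
    med <- stats::median(rng[, j])
    if (med == 0) 1 else max(rng[, j]) / med
  }, numeric(1))

  coh <- vapply(seq_len(n_int), function(j) {
    as.numeric(coherence_metric(m[, j], config$coherence_n_pairs))
  }, numeric(1))

  data.frame(interval_start = (seq_len(n_int) - 1) * config$interval_length,
             coastline = cl, intermittency = inter, spikiness = spk,
             coherence = coh)
}
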