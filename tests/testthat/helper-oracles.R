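# Independent brute-force implementations of the four interval features,
# written as naive loops straight from their definitions. These exist only to
# cross-check the package implementations and share no code with them.

bf_coastline <- function(x) {
  total <- 0
  for (k in seq_len(length(x) - 1)) {
    total <- total + abs(x[k + 1] - x[k])
  }
  total
}

bf_intermittency <- function(x, top_fraction = 0.10) {
  steps <- numeric(length(x) - 1)
  for (k in seq_len(length(x) - 1)) {
    steps[k] <- abs(x[k + 1] - x[k])
  }
  total <- sum(steps)
  if (total == 0) return(0)
  m <- ceiling(top_fraction * length(steps))
  sorted <- sort(steps, decreasing = TRUE)
  top_sum <- 0
  for (k in seq_len(m)) top_sum <- top_sum + sorted[k]
  top_sum / total
}

bf_spikiness <- function(x, fs, bin_width = 0.0196) {
  bw <- floor(bin_width * fs)
  nb <- floor(length(x) / bw)
  ranges <- numeric(nb)
  for (b in seq_len(nb)) {
    lo <- Inf; hi <- -Inf
    for (k in ((b - 1) * bw + 1):(b * bw)) {
      if (x[k] < lo) lo <- x[k]
      if (x[k] > hi) hi <- x[k]
    }
    ranges[b] <- hi - lo
  }
  med <- stats::median(ranges)
  if (med == 0) return(1)
  max(ranges) / med
}

bf_coherence <- function(x, n_pairs = 10) {
  v <- x - mean(x)
  total <- sum(abs(v))
  if (total == 0) return(0)
  n <- length(v)
  # local extrema by scanning the sign of consecutive differences, carrying
  # the previous non-zero slope through plateaus; endpoints included
  slopes <- numeric(n - 1)
  last <- 0
  for (k in seq_len(n - 1)) {
    s <- sign(v[k + 1] - v[k])
    if (s == 0) s <- last
    slopes[k] <- s
    last <- s
  }
  first_nz <- slopes[slopes != 0]
  if (length(first_nz) == 0) return(0)
  slopes[slopes == 0] <- first_nz[1]   # leading plateau
  ext <- c(1)
  for (k in seq_len(n - 2)) {
    if (slopes[k + 1] != slopes[k]) ext <- c(ext, k + 1)
  }
  ext <- unique(c(ext, n))
  if (length(ext) < 2) return(0)
  n_pr <- floor(length(ext) / 2)
  amp <- area <- numeric(n_pr)
  for (p in seq_len(n_pr)) {
    e1 <- ext[2 * p - 1]; e2 <- ext[2 * p]
    amp[p] <- abs(v[e1] - v[e2])
    span_end <- if (p < n_pr) ext[2 * p + 1] - 1 else n
    a <- 0
    for (k in e1:span_end) a <- a + abs(v[k])
    area[p] <- a
  }
  keep <- order(amp, decreasing = TRUE)[seq_len(min(n_pairs, n_pr))]
  min(1, sum(area[keep]) / total)
}

# A miniature library + calibration built from hand-made feature rows, for
# classification tests that should not depend on a full simulation.
toy_library <- function(entries) {
  structure(
    list(entries = entries,
         calibration = list(centre = rep(0, 4), scale = rep(1, 4)),
         provenance = list()),
    class = "szl_library"
  )
}

# Shared small-scale simulated recording used across detector tests; cached
# per test run to keep the suite fast.
cached_detector_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lib_sim <- generate_epileptic_recording(1200, 512, seed = 421)
      lib <- build_seizure_library(lib_sim$recording, lib_sim$truth)
      test_sim <- generate_epileptic_recording(1800, 512, seed = 422)
      cache <<- list(lib_sim = lib_sim, library = lib, test_sim = test_sim)
    }
    cache
  }
})
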