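#' Entrainment analysis configuration
#'
#' Band definitions for the entrainment power ratio: cumulative spectral power
#' within `stim_freq +/- narrow_halfwidth` divided by cumulative power in the
#' `[band_low, band_high]` theta band, endpoints inclusive, bins assigned by
#' bin-centre frequency.
#'
#' @param stim_freq optical stimulation frequency, Hz.
#' @param narrow_halfwidth half-width of the narrow band around `stim_freq`,
#'   Hz.
#' @param band_low,band_high wide-band limits, Hz.
#' @return an object of class `szl_entrain_config`.
#' @export
entrain_config <- function(stim_freq = 10, narrow_halfwidth = 1,
                           band_low = 3, band_high = 13) {
  if (stim_freq - narrow_halfwidth < band_low ||
      stim_freq + narrow_halfwidth > band_high) {
    stop("narrow band must lie inside the wide band", call. = FALSE)
  }
  structure(
    list(stim_freq = stim_freq, narrow_halfwidth = narrow_halfwidth,
         band_low = band_low, band_high = band_high),
    class = "szl_entrain_config"
  )
}

#' Instantaneous phase via the analytic signal
#'
#' Removes the mean, builds the analytic signal with the FFT construction of
#' the Hilbert transform, and returns its angle in `(-pi, pi]`.
#'
#' @param x numeric voltage vector (length >= 2, not all-constant).
#' @return phase series, radians.
#' @export
extract_phase <- function(x) {
  if (length(x) < 2) stop("signal too short for phase extraction", call. = FALSE)
  x <- x - mean(x)
  if (all(x == 0)) {
    stop("phase undefined for an all-constant signal", call. = FALSE)
  }
  ph <- Arg(analytic_signal(x))
  ph[ph <= -pi] <- pi          # half-open convention (-pi, pi]
  ph
}

# Analytic signal z = x + i * H(x) via one-sided spectrum doubling.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Slice a session into baseline and stimulation epoch sets
#'
#' Instantaneous phase is computed once on the whole continuous LFP and LED
#' traces (avoiding transform edge artefacts inside short windows) and then
#' sliced into trials. Each stimulation epoch `[onset, onset + epoch_duration)`
#' is paired with the equal-length baseline immediately preceding it. Trials
#' whose stimulation epoch or baseline falls outside the recording are dropped
#' with a warning, and a warning is logged if the LED channel is silent during
#' a claimed stimulation epoch.
#'
#' @param rec a [recording()] with `"lfp"` and `"led"` channels.
#' @param epoch_onsets stimulation epoch onset times, seconds.
#' @param epoch_duration epoch length, seconds.
#' @param baseline_offset gap between the end of the baseline window and the
#'   stimulation onset, seconds (default 0: the window immediately before).
#' @return list of two epoch sets (`baseline`, `stimulation`), each a list
#'   with matrices `phase_led`, `phase_lfp`, `voltage_lfp` (trials x
#'   timepoints), `fs`, and `condition`.
#' @export
epoch_session <- function(rec, epoch_onsets, epoch_duration,
                          baseline_offset = 0) {
  fs <- rec$fs
  lfp <- channel(rec, "lfp")
  led <- channel(rec, "led")
  ph_lfp <- extract_phase(lfp)
  ph_led <- extract_phase(led)
  n <- length(lfp)
  n_t <- round(epoch_duration * fs)

  stim_start <- round(epoch_onsets * fs)            # 0-based sample index
  base_start <- round((epoch_onsets - baseline_offset - epoch_duration) * fs)
  ok <- base_start >= 0 & (stim_start + n_t) <= n
  if (any(!ok)) {
    warning(sprintf("%d epoch(s) outside the recording were dropped",
                    sum(!ok)))
  }
  stim_start <- stim_start[ok]; base_start <- base_start[ok]
  if (length(stim_start) == 0) stop("no usable epochs", call. = FALSE)

  slice <- function(v, starts) {
    t(vapply(starts, function(s) v[(s + 1):(s + n_t)], numeric(n_t)))
  }
  silent <- vapply(stim_start, function(s) all(led[(s + 1):(s + n_t)] == 0),
                   logical(1))
  if (any(silent)) {
    warning(sprintf("LED silent during %d claimed stimulation epoch(s)",
                    sum(silent)))
  }
  make_set <- function(starts, condition) {
    list(phase_led = slice(ph_led, starts),
         phase_lfp = slice(ph_lfp, starts),
         voltage_lfp = slice(lfp, starts),
         fs = fs, condition = condition)
  }
  list(baseline = make_set(base_start, "baseline"),
       stimulation = make_set(stim_start, "stimulation"))
}

#' Per-timepoint phase locking value across trials
#'
#' `PLV(tau) = | mean over trials of exp(i (phase_led - phase_lfp)) |`:
#' the modulus of the trial-averaged unit phasor of the LED-LFP phase
#' difference, evaluated at every timepoint. 1 means identical lag on every
#' trial; for independent phases the expectation is the Rayleigh mean
#' `sqrt(pi) / (2 sqrt(n_trials))`.
#'
#' @param phase_led,phase_lfp trials x timepoints phase matrices (radians), or
#'   an epoch set from [epoch_session()] as the first argument.
#' @return numeric vector of PLV values in `[0, 1]`, one per timepoint.
#' @export
plv_timecourse <- function(phase_led, phase_lfp = NULL) {
  if (is.list(phase_led) && is.null(phase_lfp)) {
    phase_lfp <- phase_led$phase_lfp
    phase_led <- phase_led$phase_led
  }
  if (!identical(dim(phase_led), dim(phase_lfp))) {
    stop("phase matrices must have identical shape", call. = FALSE)
  }
  if (nrow(phase_led) < 2) {
    stop("PLV requires at least 2 trials (degenerate at 1)", call. = FALSE)
  }
  Mod(colMeans(exp(1i * (phase_led - phase_lfp))))
}

#' Baseline-subtracted mean phase locking value
#'
#' Computes the PLV timecourse of the stimulation and baseline epoch sets,
#' averages each over timepoints, and subtracts the baseline mean from the
#' stimulation mean.
#'
#' @param stim,base epoch sets from [epoch_session()].
#' @return an object of class `szl_plv` with `plv_timecourse` (stimulation),
#'   `mean_plv`, `baseline_mean_plv`, and `baseline_subtracted_mean`.
#' @export
baseline_subtracted_plv <- function(stim, base) {
  if (!identical(dim(stim$phase_led), dim(base$phase_led))) {
    stop("stimulation and baseline epoch sets must have identical shape",
         call. = FALSE)
  }
  tc_stim <- plv_timecourse(stim)
  tc_base <- plv_timecourse(base)
  structure(
    list(plv_timecourse = tc_stim,
         mean_plv = mean(tc_stim),
         baseline_mean_plv = mean(tc_base),
         baseline_subtracted_mean = mean(tc_stim) - mean(tc_base)),
    class = "szl_plv"
  )
}

#' One-sided periodogram
#'
#' Rectangular-window periodogram of a mean-removed segment with power
#' spectral density scaling: the integral of the density over frequency
#' equals the signal variance (Parseval). Frequency resolution is
#' `fs / length(segment)`.
#'
#' @param x numeric voltage segment, at least 1 s long (`length >= fs`).
#' @param fs sampling rate, Hz.
#' @return list with `freq` (Hz) and `power` (density, per Hz).
#' @export
psd_periodogram <- function(x, fs) {
  n <- length(x)
  if (n < fs) stop("segment must be at least 1 s long", call. = FALSE)
  x <- x - mean(x)
  X <- stats::fft(x)
  n_freq <- floor(n / 2) + 1L
  p <- (Mod(X[seq_len(n_freq)])^2) / (fs * n)
  if (n %% 2 == 0) {
    if (n_freq > 2) p[2:(n_freq - 1)] <- 2 * p[2:(n_freq - 1)]
  } else {
    if (n_freq > 1) p[2:n_freq] <- 2 * p[2:n_freq]
  }
  list(freq = (seq_len(n_freq) - 1) * fs / n, power = p)
}

#' Entrainment power ratio of one spectrum
#'
#' Cumulative spectral power within `stim_freq +/- narrow_halfwidth` divided
#' by cumulative power in `[band_low, band_high]`, endpoints inclusive. A
#' zero wide-band spectrum yields 0 with a warning.
#'
#' @param psd list with `freq` and `power` from [psd_periodogram()].
#' @param config an [entrain_config()].
#' @return ratio in `[0, 1]`.
#' @export
entrainment_ratio <- function(psd, config = entrain_config()) {
  if (max(psd$freq) < config$band_high) {
    stop("frequency grid does not cover the wide band", call. = FALSE)
  }
  narrow <- psd$freq >= config$stim_freq - config$narrow_halfwidth &
    psd$freq <= config$stim_freq + config$narrow_halfwidth
  wide <- psd$freq >= config$band_low & psd$freq <= config$band_high
  den <- sum(psd$power[wide])
  if (den == 0) {
    warning("zero wide-band power; ratio defined as 0")
    return(0)
  }
  sum(psd$power[narrow]) / den
}

#' Entrainment efficiency from paired per-epoch ratios
#'
#' Median over epochs of (stimulation ratio - baseline ratio); per-epoch
#' pairs are preserved for distributional comparisons.
#'
#' @param stim_ratios,base_ratios equal-length per-epoch ratio vectors.
#' @return an object of class `szl_entrainment` with `ratio_stim`,
#'   `ratio_base`, and `efficiency`.
#' @export
entrainment_efficiency <- function(stim_ratios, base_ratios) {
  if (length(stim_ratios) != length(base_ratios)) {
    stop("stimulation and baseline ratio lists must have equal length",
         call. = FALSE)
  }
  structure(
    list(ratio_stim = stim_ratios, ratio_base = base_ratios,
         efficiency = stats::median(stim_ratios - base_ratios)),
    class = "szl_entrainment"
  )
}

#' Full entrainment analysis of one session
#'
#' Epochs the session, computes the baseline-subtracted mean PLV, and the
#' per-epoch entrainment power ratios with their median stimulation-baseline
#' difference.
#'
#' @param rec a [recording()] with `"lfp"` and `"led"` channels.
#' @param epoch_onsets stimulation onsets, seconds.
#' @param epoch_duration epoch length, seconds.
#' @param config an [entrain_config()].
#' @return list with `plv` (class `szl_plv`), `entrainment` (class
#'   `szl_entrainment`), and `per_epoch` (data frame: epoch, condition,
#'   ratio).
#' @export
entrain_session <- function(rec, epoch_onsets, epoch_duration = 30,
                            config = entrain_config()) {
  sets <- epoch_session(rec, epoch_onsets, epoch_duration)
  plv <- baseline_subtracted_plv(sets$stimulation, sets$baseline)
  ratio_of <- function(v) {
    entrainment_ratio(psd_periodogram(v, rec$fs), config)
  }
  r_stim <- apply(sets$stimulation$voltage_lfp, 1, ratio_of)
  r_base <- apply(sets$baseline$voltage_lfp, 1, ratio_of)
  eff <- entrainment_efficiency(r_stim, r_base)
  per_epoch <- data.frame(
    epoch = rep(seq_along(r_stim), 2),
    condition = rep(c("baseline", "stimulation"), each = length(r_stim)),
    ratio = c(r_base, r_stim)
  )
  list(plv = plv, entrainment = eff, per_epoch = per_epoch)
}
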