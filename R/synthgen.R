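#' Stimulation protocol description
#'
#' The optical stimulation protocol: trains of short square pulses delivered
#' in fixed-length epochs separated by stimulation-free intervals. Defaults
#' follow the standard entrainment session used throughout: 120 epochs of
#' 10-ms pulses at 10 Hz, 30 s per epoch, 90 s between epochs.
#'
#' @param pulse_rate pulse rate within an epoch, Hz.
#' @param pulse_width pulse duration, seconds.
#' @param epoch_duration stimulation epoch length, seconds.
#' @param inter_epoch_interval stimulation-free gap between epochs, seconds.
#' @param n_epochs number of epochs in a session.
#' @return an object of class `szl_protocol`.
#' @export
stim_protocol <- function(pulse_rate = 10, pulse_width = 0.010,
                          epoch_duration = 30, inter_epoch_interval = 90,
                          n_epochs = 120) {
  stop_if_not_positive(pulse_rate, "pulse_rate")
  stop_if_not_positive(pulse_width, "pulse_width")
  stop_if_not_positive(epoch_duration, "epoch_duration")
  stop_if_not_positive(inter_epoch_interval, "inter_epoch_interval")
  if (n_epochs < 1) stop("`n_epochs` must be >= 1", call. = FALSE)
  if (pulse_width >= 1 / pulse_rate) {
    stop("`pulse_width` must be shorter than the pulse period", call. = FALSE)
  }
  if (epoch_duration < 1 / pulse_rate) {
    stop("`epoch_duration` must hold at least one pulse", call. = FALSE)
  }
  structure(
    list(pulse_rate = pulse_rate, pulse_width = pulse_width,
         epoch_duration = epoch_duration,
         inter_epoch_interval = inter_epoch_interval,
         n_epochs = as.integer(n_epochs)),
    class = "szl_protocol"
  )
}

#' Background LFP model
#'
#' Parameters of the ongoing (non-seizure) hippocampal local field potential:
#' broadband noise with a power-law spectrum, a theta-band oscillation, and an
#' optional stimulation-phase-locked component whose locking strength is the
#' concentration `kappa` of a von Mises law on the per-epoch phase lag to the
#' LED fundamental. `kappa = 0` means the LFP phase is independent of the LED;
#' large `kappa` means a nearly deterministic lag. The locked component's
#' amplitude scales with the mean resultant length r(kappa) = I1(kappa)/I0(kappa),
#' so an unlocked session (`kappa = 0`) contains no stimulation-frequency drive
#' at all and locking strength moves phase stability and entrained power
#' together, as an increasing opsin-mediated drive would.
#'
#' @param noise_exponent spectral slope of the broadband noise (power ~
#'   1/f^noise_exponent); 2 approximates the steep high-frequency roll-off of
#'   hippocampal LFP.
#' @param theta_freq theta oscillation frequency, Hz.
#' @param theta_power fraction of background variance carried by theta, in
#'   `[0, 1]`.
#' @param theta_linewidth spectral width of the theta peak, Hz: the theta
#'   phase diffuses as a Wiener process, so theta is coherent only over
#'   ~`1/linewidth` seconds, as in real LFP (0 = a pure sinusoid).
#' @param locking_strength von Mises concentration `kappa >= 0` of the
#'   stimulation-locked component's phase lag.
#' @param sd total background standard deviation, microvolts.
#' @param locked_rel_amp peak amplitude of a fully locked (`kappa -> Inf`)
#'   stimulation component, as a multiple of `sd`.
#' @return an object of class `szl_background`.
#' @export
background_model <- function(noise_exponent = 2, theta_freq = 7,
                             theta_power = 0.3, theta_linewidth = 0.5,
                             locking_strength = 0,
                             sd = 100, locked_rel_amp = 2) {
  if (theta_power < 0 || theta_power > 1) {
    stop("`theta_power` must be in [0, 1]", call. = FALSE)
  }
  if (locking_strength < 0) stop("`locking_strength` must be >= 0", call. = FALSE)
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  stop_if_not_positive(theta_freq, "theta_freq")
  structure(
    list(noise_exponent = noise_exponent, theta_freq = theta_freq,
         theta_power = theta_power, theta_linewidth = theta_linewidth,
         locking_strength = locking_strength,
         sd = sd, locked_rel_amp = locked_rel_amp),
    class = "szl_background"
  )
}

#' Electrographic seizure model
#'
#' Spontaneous electrographic seizures are rendered as trains of alternating
#' biphasic sharp transients (raised-cosine kernels) superimposed on the
#' background, with heavy-tailed (log-normal) durations and Poisson event
#' times. Defaults emulate the frequent short electrographic discharges of
#' chronic intrahippocampal-kainate epilepsy.
#'
#' @param event_rate seizure rate, events per hour.
#' @param duration_median median seizure duration, seconds (must exceed 3 s so
#'   events span at least three detector intervals).
#' @param duration_sigma log-scale standard deviation of the log-normal
#'   duration law.
#' @param spike_rate rhythmic discharge rate within a seizure, Hz.
#' @param spike_amplitude peak spike amplitude, as a multiple of the
#'   background standard deviation.
#' @param onset_ramp duration of the linear amplitude ramp at seizure onset
#'   and offset, seconds.
#' @return an object of class `szl_seizures`.
#' @export
seizure_model <- function(event_rate = 20, duration_median = 30,
                          duration_sigma = 0.4, spike_rate = 8,
                          spike_amplitude = 5, onset_ramp = 1) {
  if (event_rate < 0) stop("`event_rate` must be >= 0", call. = FALSE)
  stop_if_not_positive(duration_median, "duration_median")
  stop_if_not_positive(spike_rate, "spike_rate")
  if (spike_amplitude < 0) stop("`spike_amplitude` must be >= 0", call. = FALSE)
  if (duration_median <= 3) {
    stop("`duration_median` must exceed 3 s (three detector intervals)",
         call. = FALSE)
  }
  structure(
    list(event_rate = event_rate, duration_median = duration_median,
         duration_sigma = duration_sigma, spike_rate = spike_rate,
         spike_amplitude = spike_amplitude, onset_ramp = onset_ramp),
    class = "szl_seizures"
  )
}

#' Sample from a von Mises distribution centred at zero
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the circular uniform.
#'
#' @param n number of draws.
#' @param kappa concentration parameter (>= 0).
#' @return angles in `(-pi, pi]`.
#' @keywords internal
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  out
}

#' Mean resultant length of the von Mises law
#'
#' r(kappa) = I1(kappa) / I0(kappa): 0 at kappa = 0, -> 1 as kappa -> Inf.
#'
#' @param kappa concentration (>= 0).
#' @return mean resultant length in `[0, 1)`.
#' @keywords internal
mean_resultant_length <- function(kappa) {
  if (kappa == 0) return(0)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Generate background LFP
#'
#' Spectrally shaped Gaussian noise (power ~ 1/f^noise_exponent) plus a
#' theta-band sinusoid with random phase, scaled so the trace has standard
#' deviation `model$sd` with the variance split `theta_power` /
#' `1 - theta_power` between theta and broadband noise. Deterministic in
#' (parameters, seed).
#'
#' @param duration trace length, seconds.
#' @param fs sampling rate, Hz.
#' @param model a [background_model()].
#' @param seed integer seed.
#' @return a single-channel [recording()] with role `"lfp"`.
#' @export
generate_background <- function(duration, fs, model = background_model(),
                                seed = 1) {
  stop_if_not_positive(duration, "duration")
  stop_if_not_positive(fs, "fs")
  if (fs <= 2 * model$theta_freq) {
    stop("`fs` must exceed twice the theta frequency", call. = FALSE)
  }
  n <- round(duration * fs)
  x <- with_seed(seed, {
    noise <- colored_noise(n, fs, model$noise_exponent)
    phase <- stats::runif(1, 0, 2 * pi)
    lw <- model$theta_linewidth %||% 0
    if (lw > 0) {
      # Wiener phase diffusion with Lorentzian linewidth `lw` Hz
      phase <- phase +
        cumsum(stats::rnorm(n, 0, sqrt(2 * pi * lw / fs)))
    }
    tt <- (seq_len(n) - 1) / fs
    theta <- sqrt(2) * sin(2 * pi * model$theta_freq * tt + phase)
    model$sd * (sqrt(1 - model$theta_power) * noise +
                  sqrt(model$theta_power) * theta)
  })
  recording(x, fs, channel_roles = "lfp")
}

# Unit-variance Gaussian noise with power-law spectrum 1/f^alpha, built by
# frequency-domain shaping of white noise (Hermitian-symmetric filter, so the
# inverse transform is real up to roundoff).
colored_noise <- function(n, fs, alpha) {
  white <- stats::rnorm(n)
  if (alpha == 0) return((white - mean(white)) / stats::sd(white))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n            # |frequency| per FFT bin
  amp <- c(0, f[-1]^(-alpha / 2))         # kill DC
  shaped <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / n
  s <- stats::sd(shaped)
  if (s == 0) return(shaped)
  (shaped - mean(shaped)) / s
}

#' Generate the LED stimulation channel
#'
#' Builds the binary LED trace for a whole session: each cycle is a
#' stimulation-free interval followed by a pulse-train epoch, so every epoch
#' has a full-length pre-stimulation baseline before it. Pulses are high for
#' `round(pulse_width * fs)` samples at `pulse_rate`.
#'
#' @param protocol a [stim_protocol()].
#' @param fs sampling rate, Hz.
#' @return a list with `recording` (single `"led"` channel) and `onsets`
#'   (epoch onset times, seconds).
#' @export
generate_led_channel <- function(protocol = stim_protocol(), fs = 512) {
  stopifnot(inherits(protocol, "szl_protocol"))
  pw_samples <- round(protocol$pulse_width * fs)
  if (pw_samples < 1) {
    stop("pulse unrepresentable: `pulse_width * fs` < 1 sample", call. = FALSE)
  }
  if (fs < 2 / protocol$pulse_width) {
    warning("`fs` below 2 / pulse_width; pulse edges will be coarse")
  }
  cycle <- protocol$inter_epoch_interval + protocol$epoch_duration
  onsets <- protocol$inter_epoch_interval +
    (seq_len(protocol$n_epochs) - 1) * cycle
  n <- round(protocol$n_epochs * cycle * fs)
  led <- numeric(n)
  n_pulses <- floor(protocol$epoch_duration * protocol$pulse_rate)
  for (on in onsets) {
    starts <- round((on + (0:(n_pulses - 1)) / protocol$pulse_rate) * fs)
    for (s in starts) {
      idx <- (s + 1):min(s + pw_samples, n)
      led[idx] <- 1
    }
  }
  list(recording = recording(led, fs, channel_roles = "led"), onsets = onsets)
}

#' Generate a full entrainment session with a phase-locked component
#'
#' Background LFP plus, during each stimulation epoch, a sinusoid at the pulse
#' rate whose phase lag to the LED fundamental is drawn once per epoch from a
#' von Mises law with concentration `kappa = model$locking_strength` (constant
#' within the epoch). The component's amplitude is
#' `locked_rel_amp * sd * r(kappa)`, so `kappa = 0` adds nothing and the
#' session is a true null for both phase locking and entrained power.
#'
#' @param protocol a [stim_protocol()].
#' @param background a [background_model()] (its `locking_strength` is used).
#' @param fs sampling rate, Hz.
#' @param seed integer master seed.
#' @return a list with `recording` (channels `"lfp"`, `"led"`), `truth`
#'   (ground-truth list with `locking_strength` and `seed`) and `onsets`.
#' @export
generate_locked_session <- function(protocol = stim_protocol(),
                                    background = background_model(),
                                    fs = 512, seed = 1) {
  led <- generate_led_channel(protocol, fs)
  n <- n_samples(led$recording)
  duration <- n / fs
  bg <- generate_background(duration, fs, background, derive_seed(seed, 1))
  kappa <- background$locking_strength
  lags <- with_seed(derive_seed(seed, 2),
                    rvonmises(protocol$n_epochs, kappa))
  amp <- background$locked_rel_amp * background$sd * mean_resultant_length(kappa)
  lfp <- channel(bg, "lfp")
  if (amp > 0) {
    n_ep <- round(protocol$epoch_duration * fs)
    for (i in seq_along(led$onsets)) {
      i0 <- round(led$onsets[i] * fs)
      idx <- (i0 + 1):min(i0 + n_ep, n)
      tt <- (idx - 1 - i0) / fs
      lfp[idx] <- lfp[idx] +
        amp * cos(2 * pi * protocol$pulse_rate * tt - lags[i])
    }
  }
  rec <- recording(cbind(lfp, channel(led$recording, "led")), fs,
                   channel_roles = c("lfp", "led"))
  truth <- list(seizure_intervals = empty_intervals(),
                locking_strength = kappa, seed = seed)
  list(recording = rec, truth = truth, onsets = led$onsets)
}

empty_intervals <- function() {
  data.frame(onset = numeric(0), offset = numeric(0))
}

#' Generate an epileptic recording with ground truth
#'
#' Superimposes electrographic seizures on background LFP. Event onsets form a
#' Poisson process at `seizures$event_rate` per hour; durations are log-normal
#' with the configured median and log-sd; overlapping draws are merged. Each
#' seizure is a train of alternating-sign biphasic raised-cosine spikes at
#' `spike_rate`, peak amplitude `spike_amplitude` times the background SD,
#' with linear on/off amplitude ramps.
#'
#' @param duration recording length, seconds.
#' @param fs sampling rate, Hz.
#' @param background a [background_model()].
#' @param seizures a [seizure_model()].
#' @param seed integer master seed.
#' @return a list with `recording` (single `"lfp"` channel) and `truth`
#'   (list with `seizure_intervals` data frame, `seed`).
#' @export
generate_epileptic_recording <- function(duration, fs = 512,
                                         background = background_model(),
                                         seizures = seizure_model(),
                                         seed = 1) {
  stop_if_not_positive(duration, "duration")
  bg <- generate_background(duration, fs, background, derive_seed(seed, 1))
  ev <- with_seed(derive_seed(seed, 2), {
    n_ev <- stats::rpois(1, seizures$event_rate * duration / 3600)
    if (n_ev == 0) {
      empty_intervals()
    } else {
      onset <- sort(stats::runif(n_ev, 0, duration))
      dur <- stats::rlnorm(n_ev, meanlog = log(seizures$duration_median),
                           sdlog = seizures$duration_sigma)
      data.frame(onset = onset, offset = pmin(onset + dur, duration))
    }
  })
  ev <- merge_intervals(ev)
  if (nrow(ev) > 0 && sum(ev$offset - ev$onset) > 0.5 * duration) {
    warning("seizures cover more than half the recording after merging")
  }
  x <- channel(bg, "lfp")
  if (nrow(ev) > 0 && seizures$spike_amplitude > 0) {
    x <- x + render_seizures(ev, length(x), fs, seizures,
                             background$sd, derive_seed(seed, 3))
  }
  rec <- recording(x, fs, channel_roles = "lfp")
  list(recording = rec, truth = list(seizure_intervals = ev, seed = seed))
}

# Merge overlapping/touching intervals; input data.frame(onset, offset).
merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv$onset), , drop = FALSE]
  on <- iv$onset[1]; off <- iv$offset[1]
  res_on <- numeric(0); res_off <- numeric(0)
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$onset[i] <= off) {
      off <- max(off, iv$offset[i])
    } else {
      res_on <- c(res_on, on); res_off <- c(res_off, off)
      on <- iv$onset[i]; off <- iv$offset[i]
    }
  }
  data.frame(onset = c(res_on, on), offset = c(res_off, off))
}

# Additive seizure trace: alternating biphasic raised-cosine spikes.
render_seizures <- function(intervals, n, fs, seizures, bg_sd, seed) {
  lobe <- max(4L, round(0.025 * fs))     # samples per kernel lobe
  up <- 0.5 * (1 - cos(2 * pi * seq_len(lobe) / (lobe + 1)))
  kernel <- c(up, -0.7 * up)
  klen <- length(kernel)
  amp0 <- seizures$spike_amplitude * bg_sd
  out <- numeric(n)
  with_seed(seed, {
    for (e in seq_len(nrow(intervals))) {
      on <- intervals$onset[e]; off <- intervals$offset[e]
      times <- seq(on, off - klen / fs, by = 1 / seizures$spike_rate)
      if (length(times) == 0) next
      jitter <- stats::runif(length(times), -0.1, 0.1) / seizures$spike_rate
      times <- pmin(pmax(times + jitter, on), off - klen / fs)
      ramp <- pmin(1, (times - on) / max(seizures$onset_ramp, 1e-9),
                   (off - times) / max(seizures$onset_ramp, 1e-9))
      sgn <- (-1)^(seq_along(times) - 1)
      for (j in seq_along(times)) {
        i0 <- round(times[j] * fs)
        idx <- (i0 + 1):min(i0 + klen, n)
        out[idx] <- out[idx] + amp0 * ramp[j] * sgn[j] * kernel[seq_along(idx)]
      }
    }
  })
  out
}
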