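test_that("analytic-signal phase matches closed-form identities", {
  fs <- 512
  tt <- (0:(10 * fs - 1)) / fs
  ph_cos <- extract_phase(cos(2 * pi * 10 * tt))
  # interior unwrapped slope = 2*pi*10 rad/s
  core <- 100:(length(ph_cos) - 100)
  d <- diff(ph_cos[core])
  d <- d[d > -pi]                       # remove wrap jumps
  expect_lt(abs(median(d) * fs - 2 * pi * 10), 0.01)

  ph_sin <- extract_phase(sin(2 * pi * 10 * tt))
  lag <- Arg(exp(1i * (ph_sin[core] - ph_cos[core])))
  expect_lt(max(abs(lag + pi / 2)), 0.01)

  # chirp: instantaneous frequency rises monotonically
  f0 <- 5; f1 <- 15
  chirp <- cos(2 * pi * (f0 * tt + (f1 - f0) * tt^2 / 20))
  ph <- extract_phase(chirp)
  unwrapped <- cumsum(c(ph[1], Arg(exp(1i * diff(ph)))))
  inst <- diff(unwrapped) * fs / (2 * pi)
  sm <- stats::filter(inst, rep(1 / fs, fs))
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm[seq(1, length(sm), by = fs)]) > 0))

  expect_error(extract_phase(rep(2, 100)), "constant")
  expect_error(extract_phase(1), "short")
  expect_true(all(ph_cos > -pi & ph_cos <= pi))
})

test_that("PLV is 1 for identical or constantly lagged phases and bounded", {
  ph <- matrix(runif(5 * 100, -pi, pi), nrow = 5)
  expect_equal(plv_timecourse(ph, ph), rep(1, 100))
  expect_equal(plv_timecourse(ph, ph - pi / 2), rep(1, 100), tolerance = 1e-12)
  expect_error(plv_timecourse(ph[1, , drop = FALSE], ph[1, , drop = FALSE]),
               "2 trials")
  expect_error(plv_timecourse(ph, ph[, 1:50]), "identical shape")
  v <- plv_timecourse(ph, matrix(runif(500, -pi, pi), nrow = 5))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("PLV of independent phases matches the Rayleigh expectation", {
  set.seed(12)
  n_trials <- 120
  vals <- replicate(300, Mod(mean(exp(1i * runif(n_trials, -pi, pi)))))
  expected <- sqrt(pi) / (2 * sqrt(n_trials))
  expect_lt(abs(mean(vals) - expected), 0.008)

  # constant-offset invariance of the timecourse
  led <- matrix(runif(10 * 50, -pi, pi), nrow = 10)
  lfp <- matrix(runif(10 * 50, -pi, pi), nrow = 10)
  p1 <- plv_timecourse(led, lfp)
  p2 <- plv_timecourse(led + 1.3, lfp)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("epoching slices whole-trace phase into matched trials", {
  proto <- stim_protocol(n_epochs = 4, epoch_duration = 5,
                         inter_epoch_interval = 10)
  ses <- generate_locked_session(proto, background_model(locking_strength = 2),
                                 fs = 256, seed = 4)
  sets <- epoch_session(ses$recording, ses$onsets, 5)
  expect_equal(dim(sets$stimulation$phase_led), c(4, 5 * 256))
  expect_equal(dim(sets$baseline$phase_lfp), c(4, 5 * 256))

  # an onset too early for its baseline is dropped with a warning
  expect_warning(
    sets2 <- epoch_session(ses$recording, c(2, ses$onsets), 5),
    "dropped")
  expect_equal(nrow(sets2$stimulation$phase_led), 4)

  # claimed epoch where the LED never lights -> warning
  expect_warning(epoch_session(ses$recording, 7, 2), "LED silent")

  res <- baseline_subtracted_plv(sets$stimulation, sets$baseline)
  expect_equal(res$baseline_subtracted_mean, res$mean_plv - res$baseline_mean_plv)
  expect_error(baseline_subtracted_plv(sets$stimulation,
                                       list(phase_led = matrix(0, 2, 2))),
               "identical shape")
  # identical inputs -> zero difference
  same <- baseline_subtracted_plv(sets$stimulation, sets$stimulation)
  expect_equal(same$baseline_subtracted_mean, 0)
})

test_that("periodogram satisfies Parseval and localizes tones", {
  fs <- 512
  tt <- (0:(30 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * tt)
  p <- psd_periodogram(x, fs)
  expect_equal(p$freq[which.max(p$power)], 10)
  expect_equal(sum(p$power) * fs / length(x),
               mean((x - mean(x))^2), tolerance = 1e-9)

  set.seed(5)
  w <- rnorm(10 * fs)
  pw <- psd_periodogram(w, fs)
  expect_equal(sum(pw$power) * fs / length(w), mean((w - mean(w))^2),
               tolerance = 1e-9)

  # DC-only input is rejected as constant-free: all power at 0 Hz after
  # mean removal means zero everywhere
  pc <- psd_periodogram(rep(3, fs), fs)
  expect_true(all(pc$power == 0))
  expect_error(psd_periodogram(rnorm(100), 512), "1 s")
})

test_that("white-noise spectrum is flat over 1-100 Hz", {
  set.seed(6)
  fs <- 512
  pw <- 0
  for (r in 1:50) {
    p <- psd_periodogram(rnorm(10 * fs), fs)
    pw <- pw + p$power / 50
  }
  band <- p$freq >= 1 & p$freq <= 100
  fit <- lm(log(pw[band]) ~ log(p$freq[band]))
  expect_lt(abs(unname(coef(fit)[2])), 0.05)
})

test_that("entrainment ratio isolates narrow-band power", {
  fs <- 512
  tt <- (0:(30 * fs - 1)) / fs
  cfg <- entrain_config()
  p10 <- psd_periodogram(sin(2 * pi * 10 * tt), fs)
  expect_gt(entrainment_ratio(p10, cfg), 0.99)
  p5 <- psd_periodogram(sin(2 * pi * 5 * tt), fs)
  expect_lt(entrainment_ratio(p5, cfg), 0.01)
  expect_warning(
    r0 <- entrainment_ratio(list(freq = c(0, 5, 10, 15), power = rep(0, 4)),
                            cfg),
    "zero wide-band")
  expect_equal(r0, 0)
  expect_error(entrainment_ratio(list(freq = 0:5, power = rep(1, 6)), cfg),
               "cover")
  expect_error(entrain_config(stim_freq = 2), "inside")
})

test_that("entrainment efficiency is the median paired ratio difference", {
  r <- runif(20)
  expect_equal(entrainment_efficiency(r, r)$efficiency, 0)
  expect_equal(entrainment_efficiency(r + 0.3, r)$efficiency, 0.3)
  expect_error(entrainment_efficiency(r, r[1:5]), "equal length")
})

test_that("an unlocked session is a null for PLV and efficiency", {
  proto <- stim_protocol(n_epochs = 20)
  d_plv <- eff <- numeric(4)
  for (r in 1:4) {
    ses <- generate_locked_session(proto,
                                   background_model(locking_strength = 0),
                                   fs = 512, seed = 800 + r)
    ea <- entrain_session(ses$recording, ses$onsets, 30)
    d_plv[r] <- ea$plv$baseline_subtracted_mean
    eff[r] <- ea$entrainment$efficiency
  }
  expect_lt(abs(mean(d_plv)), 3 * sd(d_plv) / sqrt(4) + 0.02)
  expect_lt(abs(mean(eff)), 0.02)
})
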