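test_that("background generator is deterministic and respects degenerate limits", {
  m <- background_model()
  a <- generate_background(10, 512, m, seed = 7)
  b <- generate_background(10, 512, m, seed = 7)
  expect_identical(a$samples, b$samples)
  c <- generate_background(10, 512, m, seed = 8)
  expect_false(identical(a$samples, c$samples))

  zero <- generate_background(5, 512, background_model(theta_power = 0, sd = 0),
                              seed = 3)
  expect_true(all(channel(zero, "lfp") == 0))

  expect_error(generate_background(-1, 512), "positive")
  expect_error(generate_background(10, -512), "positive")
  expect_true(is.finite(var(channel(a, "lfp"))))
})

test_that("background spectrum peaks at the theta frequency", {
  m <- background_model(theta_power = 0.5, theta_freq = 7)
  pw <- 0
  for (s in 1:5) {
    bg <- generate_background(60, 512, m, seed = s)
    p <- psd_periodogram(channel(bg, "lfp"), 512)
    pw <- pw + p$power
  }
  band <- p$freq >= 1 & p$freq <= 100
  peak <- p$freq[band][which.max(pw[band])]
  expect_lt(abs(peak - 7), 0.5)
})

test_that("background spectral slope tracks the noise exponent", {
  # log-log regression over 1-100 Hz on a replicate-averaged periodogram
  for (alpha in c(1, 2)) {
    m <- background_model(noise_exponent = alpha, theta_power = 0)
    pw <- 0
    for (s in 1:30) {
      bg <- generate_background(30, 512, m, seed = 100 + s)
      p <- psd_periodogram(channel(bg, "lfp"), 512)
      pw <- pw + p$power / 30
    }
    band <- p$freq >= 1 & p$freq <= 100
    fit <- lm(log(pw[band]) ~ log(p$freq[band]))
    expect_lt(abs(unname(coef(fit)[2]) + alpha), 0.15)
  }
})

test_that("LED channel realizes the pulse protocol exactly", {
  proto <- stim_protocol(n_epochs = 2)
  led <- generate_led_channel(proto, 512)
  v <- channel(led$recording, "led")
  expect_equal(rec_duration(led$recording), 2 * (30 + 90))
  expect_equal(led$onsets, c(90, 210))
  # 300 pulses per epoch, 5 high samples per pulse at 512 Hz
  rises <- sum(diff(v) == 1)
  expect_equal(rises, 2 * 300)
  expect_equal(sum(v), 2 * 300 * round(0.010 * 512))
  expect_true(all(v[1:(90 * 512)] == 0))

  expect_error(generate_led_channel(stim_protocol(pulse_width = 0.0005), 512),
               "unrepresentable")
  expect_error(stim_protocol(pulse_width = 0.2), "period")
  expect_error(stim_protocol(n_epochs = 0), ">= 1")
})

test_that("locked session adds nothing at kappa = 0 and clusters lags with kappa", {
  proto <- stim_protocol(n_epochs = 3)
  ses <- generate_locked_session(proto, background_model(locking_strength = 0),
                                 fs = 512, seed = 11)
  bg <- generate_background(rec_duration(ses$recording), 512,
                            background_model(locking_strength = 0),
                            seed = szloop:::derive_seed(11, 1))
  expect_equal(channel(ses$recording, "lfp"), channel(bg, "lfp"))
  expect_equal(nrow(ses$truth$seizure_intervals), 0)

  # circular variance of von Mises lags decreases monotonically in kappa
  cv <- sapply(c(0, 0.5, 2, 10), function(k) {
    th <- szloop:::with_seed(5, szloop:::rvonmises(3000, k))
    1 - Mod(mean(exp(1i * th)))
  })
  expect_true(all(diff(cv) < 0))
  expect_true(all(szloop:::with_seed(1, szloop:::rvonmises(100, 4)) > -pi))
})

test_that("epileptic generator honours rate, amplitude, and Poisson counts", {
  bg <- background_model()
  none <- generate_epileptic_recording(600, 512, bg,
                                       seizure_model(event_rate = 0), seed = 2)
  expect_equal(nrow(none$truth$seizure_intervals), 0)

  flat <- generate_epileptic_recording(600, 512, bg,
                                       seizure_model(spike_amplitude = 0),
                                       seed = 2)
  pure <- generate_background(600, 512, bg, szloop:::derive_seed(2, 1))
  expect_equal(channel(flat$recording, "lfp"), channel(pure, "lfp"))

  sim <- generate_epileptic_recording(7200, 512, bg,
                                      seizure_model(event_rate = 6), seed = 1)
  n_ev <- nrow(sim$truth$seizure_intervals)
  expect_gte(n_ev, qpois(0.005, 12))
  expect_lte(n_ev, qpois(0.995, 12))
  iv <- sim$truth$seizure_intervals
  expect_true(all(diff(iv$onset) > 0))
  expect_true(all(iv$offset > iv$onset))
  # merged: no overlaps
  if (n_ev > 1) expect_true(all(iv$onset[-1] >= iv$offset[-n_ev]))
})

test_that("overlapping seizure draws are merged", {
  iv <- data.frame(onset = c(10, 12, 30), offset = c(15, 20, 40))
  m <- szloop:::merge_intervals(iv)
  expect_equal(m$onset, c(10, 30))
  expect_equal(m$offset, c(20, 40))
})

test_that("within-seizure coastline exceeds background for amplitude >= 3", {
  sim <- generate_epileptic_recording(1800, 512, background_model(),
                                      seizure_model(spike_amplitude = 3),
                                      seed = 31)
  feats <- interval_features(channel(sim$recording, "lfp"), 512)
  iv <- sim$truth$seizure_intervals
  starts <- feats$interval_start
  inside <- sapply(starts, function(s) any(iv$onset <= s & s + 1 <= iv$offset))
  outside <- sapply(starts, function(s) !any(iv$onset - 2 < s + 1 & s < iv$offset + 2))
  bg_med <- median(feats$coastline[outside])
  expect_gte(mean(feats$coastline[inside] > bg_med), 0.95)
})

test_that("library collects sigmoid vectors of within-seizure intervals", {
  # one crafted 10-s seizure aligned to interval boundaries -> 10 entries
  bg <- generate_background(60, 512, background_model(), seed = 5)
  truth <- list(seizure_intervals = data.frame(onset = 20, offset = 30))
  x <- channel(bg, "lfp") +
    szloop:::render_seizures(truth$seizure_intervals, 60 * 512, 512,
                             seizure_model(), 100, seed = 6)
  rec <- recording(x, 512, "lfp")
  lib <- build_seizure_library(rec, truth)
  expect_equal(nrow(lib$entries), 10)
  expect_true(all(lib$entries > 0 & lib$entries < 1))
  lib2 <- build_seizure_library(rec, truth)
  expect_identical(lib$entries, lib2$entries)

  # misaligned seizure clips a boundary interval
  truth2 <- list(seizure_intervals = data.frame(onset = 20.3, offset = 30.3))
  lib3 <- build_seizure_library(rec, truth2)
  expect_equal(nrow(lib3$entries), 9)

  expect_error(build_seizure_library(rec, list(seizure_intervals = NULL)),
               "no seizures")
})
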