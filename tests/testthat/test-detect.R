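test_that("sigmoid bounding is a strictly increasing logistic map", {
  cal <- list(centre = c(20, 0.3, 5, 0.5), scale = c(4, 0.05, 1, 0.1))
  expect_equal(as.numeric(sigmoid_bound(cal$centre, cal)), rep(0.5, 4))
  hi <- sigmoid_bound(cal$centre + 1e6 * cal$scale, cal)
  lo <- sigmoid_bound(cal$centre - 1e6 * cal$scale, cal)
  expect_equal(as.numeric(hi), rep(1, 4), tolerance = 1e-9)
  expect_true(all(hi < 1) && all(lo > 0))
  expect_equal(as.numeric(lo), rep(0, 4), tolerance = 1e-9)
  xs <- sort(runif(20, -50, 50))
  ys <- plogis((xs - 20) / 4)
  expect_true(all(diff(sapply(xs, function(x)
    sigmoid_bound(c(x, 0, 0, 0), cal)[1])) > 0))
  expect_equal(sapply(xs, function(x) sigmoid_bound(c(x, 0, 0, 0), cal)[1]),
               ys)
  expect_error(sigmoid_bound(1:4, list(centre = rep(0, 4), scale = c(1, 1, 0, 1))),
               "positive")
})

test_that("sigmoid calibration centres between baseline and seizure medians", {
  set.seed(1)
  base <- matrix(rnorm(400, 10, 1), ncol = 4,
                 dimnames = list(NULL, szloop:::szl_feature_names))
  seiz <- matrix(rnorm(400, 30, 2), ncol = 4,
                 dimnames = list(NULL, szloop:::szl_feature_names))
  cal <- calibrate_sigmoid(base, seiz)
  expect_equal(unname(cal$centre),
               unname((apply(base, 2, median) + apply(seiz, 2, median)) / 2))
  expect_true(all(cal$scale > 0))
  # baseline maps mostly below 0.5, seizure mostly above
  sb <- sigmoid_bound(base, cal)
  ss <- sigmoid_bound(seiz, cal)
  expect_gt(mean(sb < 0.5), 0.95)
  expect_gt(mean(ss > 0.5), 0.95)

  flat <- matrix(1, 10, 4, dimnames = list(NULL, szloop:::szl_feature_names))
  expect_error(calibrate_sigmoid(flat, flat), "zero-spread")
  expect_error(calibrate_sigmoid(base[0, ], seiz), "non-empty")
})

test_that("library matching uses an inclusive per-metric Chebyshev rule", {
  entries <- rbind(c(0.8, 0.7, 0.9, 0.6), c(0.5, 0.5, 0.5, 0.5))
  lib <- toy_library(entries)
  hit <- classify_interval(c(0.8, 0.7, 0.9, 0.6), lib)
  expect_true(hit$is_seizure)
  expect_equal(hit$best_distance, 0)

  miss <- classify_interval(entries[2, ] + 0.2, lib, threshold = 0.1)
  expect_false(miss$is_seizure)
  expect_equal(miss$best_distance, 0.2, tolerance = 1e-12)

  edge <- classify_interval(entries[2, ] + 0.1, lib, threshold = 0.1)
  expect_true(edge$is_seizure)   # boundary inclusive

  expect_error(classify_interval(rep(0.5, 4), toy_library(entries[0, , drop = FALSE])),
               "empty")
  # vectorized distance agrees with the scalar rule
  set.seed(3)
  sig <- matrix(runif(40), ncol = 4)
  best <- szloop:::chebyshev_best_distance(sig, entries)
  for (i in 1:10) {
    expect_equal(best[i], classify_interval(sig[i, ], lib)$best_distance)
  }
})

test_that("event assembly follows the consecutive-interval and gap rules", {
  cfg <- detector_config()
  ev <- assemble_events(c(FALSE, TRUE, TRUE, TRUE, FALSE), cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 1)
  expect_equal(ev$duration, 3)
  expect_equal(ev$timestamp_interval, 4)

  expect_equal(nrow(assemble_events(c(TRUE, TRUE, FALSE, TRUE, TRUE), cfg)), 0)

  cfg1 <- detector_config(gap_tolerance_intervals = 1)
  ev2 <- assemble_events(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                         cfg1)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$onset, 0)
  expect_equal(ev2$duration, 5)

  # event open at end of stream is closed at the last positive interval
  ev3 <- assemble_events(c(FALSE, TRUE, TRUE, TRUE), cfg)
  expect_equal(ev3$offset, 4)

  # gap longer than tolerance splits events
  ev4 <- assemble_events(c(rep(TRUE, 3), rep(FALSE, 3), rep(TRUE, 3)), cfg1)
  expect_equal(nrow(ev4), 2)
})

test_that("calibrated sigmoid features separate true seizure intervals", {
  fx <- cached_detector_fixture()
  sim <- fx$test_sim
  feats <- interval_features(channel(sim$recording, "lfp"), 512)
  sig <- sigmoid_bound(as.matrix(feats[, szloop:::szl_feature_names]),
                       fx$library$calibration)
  iv <- sim$truth$seizure_intervals
  inside <- sapply(feats$interval_start,
                   function(s) any(iv$onset <= s & s + 1 <= iv$offset))
  frac_high <- rowMeans(sig[inside, ] > 0.5)
  expect_gte(mean(frac_high >= 3 / 4), 0.9)
})

test_that("detector recovers ground-truth seizures with faithful durations", {
  fx <- cached_detector_fixture()
  det <- detect_seizures(fx$test_sim$recording, fx$library)
  iv <- fx$test_sim$truth$seizure_intervals
  ts <- det$events$timestamp_interval
  hit <- sapply(seq_len(nrow(iv)), function(j)
    any(iv$onset[j] <= ts & ts <= iv$offset[j]))
  long <- iv$offset - iv$onset >= 10
  expect_gte(mean(hit[long]), 0.9)

  # false timestamps outside any true seizure (2 s guard): < 1 per hour
  fp <- sapply(ts, function(t) !any(iv$onset - 2 <= t & t <= iv$offset + 2))
  expect_lt(sum(fp) / (rec_duration(fx$test_sim$recording) / 3600), 1)

  # offline duration fidelity: rank correlation with ground truth > 0.9
  match_idx <- sapply(seq_len(nrow(det$events)), function(e)
    which(iv$onset <= det$events$timestamp_interval[e] &
            det$events$timestamp_interval[e] <= iv$offset)[1])
  ok <- !is.na(match_idx)
  est <- det$events$duration[ok]
  tru <- (iv$offset - iv$onset)[match_idx[ok]]
  expect_gt(cor(est, tru, method = "spearman"), 0.9)
})
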