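#' Closed-loop controller configuration
#'
#' On every seizure timestamp the controller draws from a pre-seeded Bernoulli
#' stream; a positive draw triggers one stimulation train (default 30 s of
#' 10-ms pulses at 10 Hz). Trains never overlap: a new train is only emitted
#' once the refractory period since the last train start has elapsed (the
#' draw is consumed either way, keeping the stream aligned with detection
#' order).
#'
#' @param stim_probability probability a timestamp triggers stimulation.
#' @param train_duration stimulation train length, seconds.
#' @param refractory minimum spacing between train starts, seconds (default =
#'   train length, so trains cannot overlap).
#' @param seed integer seed for the Bernoulli stream.
#' @return an object of class `szl_controller_config`.
#' @export
controller_config <- function(stim_probability = 0.5, train_duration = 30,
                              refractory = train_duration, seed = 1) {
  if (stim_probability < 0 || stim_probability > 1) {
    stop("`stim_probability` must be in [0, 1]", call. = FALSE)
  }
  stop_if_not_positive(train_duration, "train_duration")
  structure(
    list(stim_probability = stim_probability,
         train_duration = train_duration,
         refractory = refractory, seed = as.integer(seed)),
    class = "szl_controller_config"
  )
}

# Sequential stimulation decisions for a series of detection timestamps.
# One Bernoulli draw per timestamp, consumed in detection order; a train is
# emitted iff the draw is positive and the refractory period has elapsed.
decide_stimulation <- function(timestamps, config) {
  n <- length(timestamps)
  draws <- with_seed(config$seed,
                     stats::runif(n) < config$stim_probability)
  stimulated <- logical(n)
  last_start <- -Inf
  for (k in seq_len(n)) {
    if (draws[k] && timestamps[k] - last_start >= config$refractory) {
      stimulated[k] <- TRUE
      last_start <- timestamps[k]
    }
  }
  list(stimulated = stimulated, draws = draws)
}

#' Run the simulated closed-loop controller on a recording
#'
#' Streams the recording in 1-s analysis intervals through the online
#' detector (features, sigmoid bounding, library match, consecutive-interval
#' rule); every timestamp triggers a Bernoulli draw and, if positive and out
#' of refractory, a stimulation train. The online decision at interval `i`
#' uses only samples up to the end of interval `i` (each feature depends
#' solely on its own interval), so processing is strictly causal. One
#' timestamp is emitted per contiguous positive run.
#'
#' @param rec a [recording()] with an `"lfp"` channel.
#' @param library a [build_seizure_library()] object.
#' @param config a [controller_config()].
#' @param det_config a [detector_config()].
#' @return an object of class `szl_event_log`: list with `detections` (data
#'   frame: timestamp, stimulated, draw), `stim_trains` (data frame: start,
#'   end), `events` (offline-assembled events with a `stimulated` flag), and
#'   `flags`.
#' @export
run_controller <- function(rec, library, config = controller_config(),
                           det_config = detector_config()) {
  n_int_avail <- floor(n_samples(rec) / (det_config$interval_length * rec$fs))
  if (n_int_avail < det_config$consecutive_required) {
    return(empty_event_log())
  }
  det <- detect_seizures(rec, library, det_config)
  n_int <- length(det$flags)
  if (n_int < det_config$consecutive_required) {
    return(empty_event_log())
  }
  timestamps <- det$events$timestamp_interval * det_config$interval_length
  dec <- decide_stimulation(timestamps, config)
  trains <- data.frame(start = timestamps[dec$stimulated],
                       end = timestamps[dec$stimulated] + config$train_duration)
  events <- det$events
  events$stimulated <- dec$stimulated
  structure(
    list(detections = data.frame(timestamp = timestamps,
                                 stimulated = dec$stimulated,
                                 draw = dec$draws),
         stim_trains = trains, events = events, flags = det$flags),
    class = "szl_event_log"
  )
}

empty_event_log <- function() {
  structure(
    list(detections = data.frame(timestamp = numeric(0),
                                 stimulated = logical(0), draw = logical(0)),
         stim_trains = data.frame(start = numeric(0), end = numeric(0)),
         events = data.frame(onset = numeric(0), offset = numeric(0),
                             duration = numeric(0),
                             timestamp_interval = integer(0),
                             stimulated = logical(0)),
         flags = logical(0)),
    class = "szl_event_log"
  )
}

#' Replay pre-computed detection timestamps through the controller
#'
#' Applies the controller's randomized stimulation logic (the same code path
#' used by [run_controller()]) to an externally supplied series of detection
#' timestamps, e.g. for calibration of the randomization contract.
#'
#' @param timestamps detection times, seconds, increasing.
#' @param config a [controller_config()].
#' @return an `szl_event_log` (without interval flags).
#' @export
replay_detections <- function(timestamps, config = controller_config()) {
  dec <- decide_stimulation(timestamps, config)
  structure(
    list(detections = data.frame(timestamp = timestamps,
                                 stimulated = dec$stimulated,
                                 draw = dec$draws),
         stim_trains = data.frame(start = timestamps[dec$stimulated],
                                  end = timestamps[dec$stimulated] +
                                    config$train_duration),
         events = NULL, flags = NULL),
    class = "szl_event_log"
  )
}

#' Detection latency against ground truth
#'
#' Matches each detection timestamp to the ground-truth seizure containing it
#' and reports `timestamp - true onset`. Unmatched detections are excluded
#' and counted.
#'
#' @param event_log an `szl_event_log` from [run_controller()].
#' @param truth ground-truth list with `seizure_intervals`.
#' @param slack seconds a timestamp may trail the true offset and still match
#'   (default 0).
#' @return list with `latency` data frame (timestamp, true_onset, latency,
#'   stimulated) and `n_unmatched`.
#' @export
detection_latency <- function(event_log, truth, slack = 0) {
  iv <- truth$seizure_intervals
  ts <- event_log$detections$timestamp
  match_idx <- vapply(ts, function(t) {
    j <- which(iv$onset <= t & t <= iv$offset + slack)
    if (length(j) == 0) NA_integer_ else j[1]
  }, integer(1))
  ok <- !is.na(match_idx)
  list(
    latency = data.frame(
      timestamp = ts[ok],
      true_onset = iv$onset[match_idx[ok]],
      latency = ts[ok] - iv$onset[match_idx[ok]],
      stimulated = event_log$detections$stimulated[ok]
    ),
    n_unmatched = sum(!ok)
  )
}

#' Apply the stimulation effect to ground-truth seizures
#'
#' For every stimulation train that starts inside a true seizure, the
#' seizure's remaining duration after the train onset is multiplied by
#' `multiplier` (truncation model of a stimulation-induced shortening);
#' unstimulated seizures are untouched. `multiplier = 1` is an exact null.
#'
#' @param truth ground-truth list with `seizure_intervals`.
#' @param event_log an `szl_event_log` with `stim_trains`.
#' @param multiplier duration multiplier in `(0, 1]` for the post-train part
#'   of stimulated seizures.
#' @return modified ground-truth list; `seizure_intervals` gains a
#'   `stimulated` flag column.
#' @export
apply_stim_effect <- function(truth, event_log, multiplier) {
  if (multiplier <= 0 || multiplier > 1) {
    stop("`multiplier` must be in (0, 1]", call. = FALSE)
  }
  iv <- truth$seizure_intervals
  iv$stimulated <- FALSE
  for (s in event_log$stim_trains$start) {
    j <- which(iv$onset <= s & s <= iv$offset)
    if (length(j) == 0) next
    j <- j[1]
    iv$offset[j] <- s + multiplier * (iv$offset[j] - s)
    iv$stimulated[j] <- TRUE
  }
  truth$seizure_intervals <- iv
  truth
}
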