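#' Recording container
#'
#' A multi-channel voltage time series with sampling rate and per-channel
#' roles. Voltage is stored as a numeric matrix with one column per channel
#' (time runs down the rows), in microvolts; a light-emitting-diode (LED)
#' stimulation channel is dimensionless 0/1.
#'
#' @param samples numeric matrix (time x channels) or a vector for a single
#'   channel, in microvolts (LED channel: 0/1).
#' @param fs sampling rate in Hz.
#' @param channel_roles character vector of roles, one per channel; use
#'   `"led"` for the stimulation channel and any other label (e.g. `"lfp"`)
#'   for recording sites.
#' @param start_time recording start in seconds (default 0).
#' @return an object of class `szl_recording`.
#' @export
recording <- function(samples, fs, channel_roles = NULL, start_time = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (time x channels)", call. = FALSE)
  }
  stop_if_not_positive(fs, "fs")
  if (is.null(channel_roles)) {
    channel_roles <- if (ncol(samples) == 1L) "lfp" else
      c("lfp", rep("led", ncol(samples) - 1L))
  }
  if (length(channel_roles) != ncol(samples)) {
    stop("`channel_roles` must name every channel", call. = FALSE)
  }
  led <- which(channel_roles == "led")
  for (j in led) {
    v <- samples[, j]
    if (!all(v %in% c(0, 1))) {
      stop("LED channel must be binary 0/1", call. = FALSE)
    }
  }
  colnames(samples) <- channel_roles
  structure(
    list(samples = samples, fs = fs, channel_roles = channel_roles,
         start_time = start_time),
    class = "szl_recording"
  )
}

#' @export
print.szl_recording <- function(x, ...) {
  cat(sprintf("<szl_recording> %d channel(s) [%s], %.1f s at %g Hz\n",
              ncol(x$samples), paste(x$channel_roles, collapse = ", "),
              nrow(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Extract one channel of a recording by role
#'
#' @param rec a [recording()].
#' @param role channel role to extract (first match).
#' @return numeric vector of samples.
#' @export
channel <- function(rec, role) {
  stopifnot(inherits(rec, "szl_recording"))
  j <- match(role, rec$channel_roles)
  if (is.na(j)) stop(sprintf("no channel with role '%s'", role), call. = FALSE)
  rec$samples[, j]
}

#' Number of samples in a recording
#' @param rec a [recording()].
#' @return integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' Duration of a recording in seconds
#' @param rec a [recording()].
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) nrow(rec$samples) / rec$fs
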