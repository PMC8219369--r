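#' Write a recording to delimited text
#'
#' CSV with a `time` column (seconds) and one column per channel named by its
#' role; the sampling rate is stored on a leading `# fs=` comment line.
#' Paths ending in `.gz` are gzip-compressed.
#'
#' @param rec a [recording()].
#' @param path output path (`.csv` or `.csv.gz`).
#' @return the path, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g start_time=%.10g", rec$fs, rec$start_time),
             con)
  df <- data.frame(time = rec$start_time +
                     (seq_len(nrow(rec$samples)) - 1) / rec$fs)
  for (j in seq_len(ncol(rec$samples))) {
    df[[rec$channel_roles[j]]] <- rec$samples[, j]
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Inverse of [write_recording()]: channel roles are taken from the column
#' names; the sampling rate comes from the `# fs=` header (or, failing that,
#' from the median time step).
#'
#' @param path input path (`.csv` or `.csv.gz`).
#' @return a [recording()].
#' @export
read_recording <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  fs <- NA_real_; start_time <- 0
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("fs=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) fs <- as.numeric(m[2])
    m <- regmatches(first, regexec("start_time=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) start_time <- as.numeric(m[2])
    df <- utils::read.csv(con)
  } else {
    pushBack(first, con)
    df <- utils::read.csv(con)
  }
  if (!"time" %in% names(df)) stop("missing `time` column", call. = FALSE)
  if (is.na(fs)) fs <- 1 / stats::median(diff(df$time))
  roles <- setdiff(names(df), "time")
  if (length(roles) == 0) stop("no channel columns", call. = FALSE)
  recording(as.matrix(df[, roles, drop = FALSE]), fs,
            channel_roles = roles, start_time = start_time)
}

#' Write ground truth to JSON
#' @param truth ground-truth list (`seizure_intervals`, optional
#'   `locking_strength`, `seed`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read ground truth from JSON
#' @param path input path.
#' @return ground-truth list with a `seizure_intervals` data frame.
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv <- truth$seizure_intervals
  truth$seizure_intervals <- if (is.null(iv) || length(iv) == 0)
    empty_intervals() else as.data.frame(iv)
  truth
}

#' Serialize a seizure library (entries + calibration + provenance) to JSON
#' @param library an `szl_library`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_library <- function(library, path) {
  obj <- list(entries = unclass(as.data.frame(library$entries)),
              calibration = library$calibration,
              provenance = library$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a seizure library from JSON
#' @param path input path.
#' @return an `szl_library`.
#' @export
read_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- as.matrix(as.data.frame(obj$entries))
  colnames(entries) <- szl_feature_names
  structure(
    list(entries = entries,
         calibration = list(centre = as.numeric(obj$calibration$centre),
                            scale = as.numeric(obj$calibration$scale)),
         provenance = obj$provenance),
    class = "szl_library"
  )
}

#' Write an event table to CSV
#'
#' Deterministic column order `onset, offset, duration, stimulated,
#' severity` (severity omitted when absent); an empty table writes a valid
#' header-only CSV.
#'
#' @param events event data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_events <- function(events, path) {
  cols <- intersect(c("onset", "offset", "duration", "stimulated", "severity"),
                    names(events))
  utils::write.csv(events[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#' @param path input path.
#' @return event data frame.
#' @export
read_events <- function(path) {
  utils::read.csv(path)
}

#' Write a resolved pipeline configuration to YAML
#' @param config named list of configuration values.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(strip_classes(config), path)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}

#' Read a pipeline configuration from YAML
#' @param path input path.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
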