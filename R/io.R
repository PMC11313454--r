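# Readers and writers for the pipeline's on-disk formats: BIDS-iEEG-style
# channels/events TSVs (tab-separated, header row, UTF-8, "n/a" for missing)
# and a flat float64 binary + JSON sidecar container for continuous
# recordings.

CHANNEL_COLS <- c("name", "subject", "montage_type", "shaft", "contact_index",
                  "anatomical_label", "roi", "status", "exclusion_reason")
EVENT_COLS <- c("subject", "session", "onset_s", "condition", "target")

write_tsv <- function(df, path) {
  df[] <- lapply(df, function(col) { col[is.na(col)] <- "n/a"; col })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "n/a",
                          fileEncoding = "UTF-8")
  df
}

schema_error <- function(what, rows, msg) {
  stop(sprintf("%s schema violation (%s) in row(s): %s", what, msg,
               paste(utils::head(rows, 10), collapse = ", ")), call. = FALSE)
}

#' Validate a channel table
#'
#' Checks column presence, name uniqueness within subject, montage values,
#' and the consistency rule that a contact is excluded if and only if its
#' exclusion reason is not `"none"`.
#' @param channels data.frame
#' @return the validated table, invisibly usable
#' @export
validate_channels <- function(channels) {
  miss <- setdiff(CHANNEL_COLS, names(channels))
  if (length(miss))
    stop(sprintf("channel table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  dup <- which(duplicated(channels[c("subject", "name")]))
  if (length(dup)) schema_error("channels", dup, "duplicate name within subject")
  bad <- which(!channels$montage_type %in% c("depth", "grid"))
  if (length(bad)) schema_error("channels", bad, "montage_type must be depth/grid")
  bad <- which(!channels$status %in% c("good", "excluded"))
  if (length(bad)) schema_error("channels", bad, "status must be good/excluded")
  bad <- which(!channels$exclusion_reason %in%
                 c("seizure", "saturation", "noise", "none"))
  if (length(bad))
    schema_error("channels", bad, "exclusion_reason must be seizure/saturation/noise/none")
  bad <- which((channels$status == "excluded") != (channels$exclusion_reason != "none"))
  if (length(bad))
    schema_error("channels", bad, "excluded status must match a non-none reason")
  channels
}

#' Validate an event table
#'
#' Onsets must be strictly increasing within each session with same-session
#' inter-onset intervals of at least 1.9 s; conditions must be tms/sham and
#' targets dlpfc/parietal.
#' @param events data.frame
#' @return the validated table
#' @export
validate_events <- function(events) {
  miss <- setdiff(EVENT_COLS, names(events))
  if (length(miss))
    stop(sprintf("event table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  bad <- which(!events$condition %in% c("tms", "sham"))
  if (length(bad)) schema_error("events", bad, "condition must be tms/sham")
  bad <- which(!events$target %in% c("dlpfc", "parietal"))
  if (length(bad)) schema_error("events", bad, "target must be dlpfc/parietal")
  key <- paste(events$subject, events$session)
  for (k in unique(key)) {
    o <- events$onset_s[key == k]
    d <- diff(o)
    if (any(d <= 0))
      schema_error("events", which(key == k)[which(d <= 0) + 1L],
                   "onsets must be strictly increasing within session")
    if (any(d < 1.9 - 1e-9))
      schema_error("events", which(key == k)[which(d < 1.9 - 1e-9) + 1L],
                   "inter-onset interval below 1.9 s")
  }
  events
}

#' Read / write a channel table (TSV)
#' @param path TSV file path
#' @return validated channel table data.frame
#' @export
read_channels <- function(path) {
  if (!file.exists(path)) stop(sprintf("channels file not found: %s", path))
  validate_channels(read_tsv(path))
}

#' @rdname read_channels
#' @param channels channel table to write
#' @export
write_channels <- function(channels, path) write_tsv(validate_channels(channels), path)

#' Read / write an event table (TSV)
#' @param path TSV file path
#' @return validated event table data.frame
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("events file not found: %s", path))
  validate_events(read_tsv(path))
}

#' @rdname read_events
#' @param events event table to write
#' @export
write_events <- function(events, path) write_tsv(validate_events(events), path)

#' Read / write a continuous recording (float64 binary + JSON sidecar)
#'
#' The container is a headerless little-endian float64 file in channel-major
#' order with a JSON sidecar (`<prefix>.json`) holding the sampling rate,
#' dimensions, channel names and start time.
#'
#' @param prefix path prefix; `<prefix>.bin` and `<prefix>.json` are used
#' @param channels optional channel table; when given, the recording's
#'   channel names and sampling rate are validated against it
#' @return a [continuous_recording()]
#' @export
read_recording <- function(prefix, channels = NULL) {
  bin <- paste0(prefix, ".bin"); sidecar <- paste0(prefix, ".json")
  if (!file.exists(bin) || !file.exists(sidecar))
    stop(sprintf("recording container not found: %s(.bin/.json)", prefix))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(bin, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(x) != n) stop("recording binary is truncated")
  rec <- continuous_recording(matrix(x, meta$n_channels, meta$n_samples),
                              as.numeric(meta$fs), meta$channel_names,
                              as.numeric(meta$start_time %||% 0))
  if (!is.null(channels)) {
    missing_ch <- setdiff(rec$channel_names, channels$name)
    if (length(missing_ch))
      stop(sprintf("recording channel(s) absent from the channel table: %s",
                   paste(missing_ch, collapse = ", ")))
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_recording
#' @param recording a [continuous_recording()] to write
#' @export
write_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "continuous_recording"))
  con <- file(paste0(prefix, ".bin"), "wb")
  writeBin(as.vector(recording$data), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(list(fs = recording$fs,
                            n_channels = nrow(recording$data),
                            n_samples = ncol(recording$data),
                            channel_names = recording$channel_names,
                            start_time = recording$start_time),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Summarize contact exclusions
#'
#' Per-reason counts and percentages (half-up, 1 decimal) over the total
#' contact count, plus the included remainder.
#' @param channels validated channel table
#' @return list with `total`, `included`, and `reasons` (data.frame with
#'   `reason`, `count`, `percent`)
#' @export
summarize_exclusions <- function(channels) {
  if (!nrow(channels)) stop("channel table is empty")
  validate_channels(channels)
  total <- nrow(channels)
  reasons <- c("seizure", "saturation", "noise")
  counts <- vapply(reasons, function(r)
    sum(channels$exclusion_reason == r), integer(1))
  list(total = total,
       included = total - sum(counts),
       reasons = data.frame(reason = reasons, count = counts,
                            percent = round_half_up(100 * counts / total, 1),
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Write pipeline result tables to a directory
#' @param tables named list of data.frames
#' @param dir output directory (created if needed)
#' @return invisibly, the written paths
#' @export
write_results <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
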