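# sleep_io: recordings, hypnograms, event tables, NREM masks.
#
# Conventions used throughout the package: time in seconds from recording
# start, 0-based; sample indices 1-based inside R; event intervals are
# half-open [onset_s, offset_s) so duration_s = offset_s - onset_s.

#' Construct a two-channel (or multi-channel) recording
#'
#' @param signals numeric matrix, samples x channels, in uV.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of channel labels.
#' @param roles named character vector mapping labels to roles
#'   (`"NC"`, `"HIPP"` or `"other"`).
#' @param start_time optional POSIXct start time.
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(signals, fs, channel_names = colnames(signals),
                          roles = NULL, start_time = NULL) {
  signals <- as.matrix(signals)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(signals)))
  stopifnot(fs > 0, length(channel_names) == ncol(signals))
  colnames(signals) <- channel_names
  if (is.null(roles)) {
    roles <- rep("other", length(channel_names))
    names(roles) <- channel_names
    roles[grepl("hipp", channel_names, ignore.case = TRUE)] <- "HIPP"
    roles[grepl("^(nc|cz|c3|c4)", channel_names, ignore.case = TRUE)] <- "NC"
  }
  structure(list(signals = signals, fs = fs, channel_names = channel_names,
                 roles = roles, start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f min)\n",
              ncol(x$signals), nrow(x$signals), x$fs,
              nrow(x$signals) / x$fs / 60))
  cat("  channels:", paste(sprintf("%s[%s]", x$channel_names,
                                   x$roles[x$channel_names]), collapse = ", "), "\n")
  invisible(x)
}

# Pick the signal for a role; errors name the missing role.
channel_by_role <- function(recording, role) {
  idx <- which(recording$roles == role)
  if (length(idx) == 0)
    stop(sprintf("recording has no channel with role '%s'", role))
  recording$signals[, names(recording$roles)[idx[1]]]
}

n_samples <- function(recording) nrow(recording$signals)

# ---- EDF (European Data Format, 16-bit) ------------------------------------

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to disk
#'
#' `format = "edf"` writes a standard EDF file (16-bit samples, physical
#' units uV, 1 s data records; the signal is zero-padded to a whole number
#' of records). `format = "raw"` writes little-endian float64 samples in
#' channel blocks next to a JSON header (`<path>.json`) holding the sampling
#' rate, channel labels and roles.
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @param format `"edf"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("edf", "raw")) {
  format <- match.arg(format)
  if (format == "raw") return(write_recording_raw(recording, path))
  sig <- recording$signals
  fs <- recording$fs
  ns <- ncol(sig)
  spr <- as.integer(round(fs))          # samples per 1 s record
  n_rec <- as.integer(ceiling(nrow(sig) / spr))
  total <- n_rec * spr
  if (total > nrow(sig))
    sig <- rbind(sig, matrix(0, total - nrow(sig), ns))
  phys_max <- pmax(apply(abs(sig), 2, max), 1)
  phys_max <- ceiling(phys_max)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr(paste("Startdate 01-JAN-2000", "X", "X", "X"), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(as.character(256L + ns * 256L), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  for (lab in recording$channel_names) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(as.character(-phys_max[i]), 8)
  for (i in seq_len(ns)) wr(as.character(phys_max[i]), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(spr), 8)
  for (i in seq_len(ns)) wr("", 32)
  # match the EDF decoding convention exactly: dig = (phys - phys_min) *
  # (dig_max - dig_min)/(phys_max - phys_min) + dig_min
  scale <- 65535 / (2 * phys_max)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(pmax(-32768, pmin(32767,
        round((sig[rows, ch] + phys_max[ch]) * scale[ch]) - 32768L)))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  # JSON sidecar keeps the channel-role map, which EDF cannot carry
  jsonlite::write_json(as.list(recording$roles), paste0(path, ".roles.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  fs <- spr / rec_dur
  if (length(unique(fs)) != 1)
    stop("EDF files with per-channel sampling rates are not supported")
  out <- matrix(0, n_rec * spr[1], ns)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offs <- phys_min - gain * dig_min
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little", signed = TRUE)
      out[((r - 1L) * spr[ch] + 1L):(r * spr[ch]), ch] <- dig * gain[ch] + offs[ch]
    }
  }
  colnames(out) <- labels
  roles <- NULL
  sidecar <- paste0(path, ".roles.json")
  if (file.exists(sidecar))
    roles <- unlist(jsonlite::read_json(sidecar))
  new_recording(out, fs[1], labels, roles)
}

write_recording_raw <- function(recording, path) {
  hdr <- list(fs = recording$fs,
              n_samples = n_samples(recording),
              channels = recording$channel_names,
              roles = as.list(recording$roles),
              dtype = "float64le")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  for (ch in seq_len(ncol(recording$signals)))
    writeBin(as.numeric(recording$signals[, ch]), con, size = 8L,
             endian = "little")
  invisible(path)
}

read_recording_raw <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  nch <- length(hdr$channels)
  out <- matrix(0, hdr$n_samples, nch)
  for (ch in seq_len(nch))
    out[, ch] <- readBin(con, "numeric", n = hdr$n_samples, size = 8L,
                         endian = "little")
  colnames(out) <- hdr$channels
  new_recording(out, hdr$fs, hdr$channels, unlist(hdr$roles))
}

#' Read a recording from disk
#'
#' @param path path written by [write_recording()].
#' @param format `"edf"` or `"raw"`.
#' @param require_roles character vector of roles that must be resolvable;
#'   an error names any missing role.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, format = c("edf", "raw"),
                           require_roles = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- switch(format, edf = read_edf(path), raw = read_recording_raw(path))
  for (role in require_roles) {
    if (!any(rec$roles == role))
      stop(sprintf("channel with role '%s' missing from %s", role, path))
  }
  rec
}

# ---- hypnogram -------------------------------------------------------------

STAGE_LEVELS <- c("W", "S1", "S2", "SWS", "REM", "unscored")

#' Construct a hypnogram
#'
#' @param stages character vector of stage labels, one per scoring epoch,
#'   from `W, S1, S2, SWS, REM, unscored`.
#' @param epoch_len_s scoring epoch length in seconds (20 by convention).
#' @return an object of class `hypnogram`.
#' @export
new_hypnogram <- function(stages, epoch_len_s = 20) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad))
    stop("unknown sleep stages: ", paste(bad, collapse = ", "))
  structure(list(stages = stages, epoch_len_s = epoch_len_s),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGE_LEVELS))
  cat(sprintf("<hypnogram> %d epochs x %g s\n", length(x$stages), x$epoch_len_s))
  print(tab)
  invisible(x)
}

#' @rdname new_hypnogram
#' @param path text file with one stage label per line.
#' @export
read_hypnogram <- function(path, epoch_len_s = 20) {
  new_hypnogram(trimws(readLines(path)), epoch_len_s)
}

#' @rdname new_hypnogram
#' @param hypnogram a `hypnogram` object to write.
#' @export
write_hypnogram <- function(hypnogram, path) {
  writeLines(hypnogram$stages, path)
  invisible(path)
}

# Per-sample stage labels, truncated/extended to n_total samples.
stage_per_sample <- function(hypnogram, fs, n_total) {
  per <- rep(hypnogram$stages, each = round(hypnogram$epoch_len_s * fs))
  if (length(per) >= n_total) return(per[seq_len(n_total)])
  c(per, rep("unscored", n_total - length(per)))
}

#' Per-sample NREM mask from a hypnogram
#'
#' Marks samples that fall in NREM scoring epochs. NREM is defined as
#' stages S2 and SWS; S1 can be included with `include_s1 = TRUE`.
#'
#' @param hypnogram a `hypnogram`.
#' @param fs sampling rate of the recording in Hz.
#' @param n_total number of samples in the recording.
#' @param include_s1 include stage S1 in the mask.
#' @return logical vector of length `n_total`.
#' @export
nrem_mask <- function(hypnogram, fs, n_total, include_s1 = FALSE) {
  covered <- length(hypnogram$stages) * hypnogram$epoch_len_s * fs
  if (abs(covered - n_total) > hypnogram$epoch_len_s * fs)
    stop(sprintf(
      "hypnogram covers %d samples but recording has %d (off by > 1 epoch)",
      as.integer(covered), as.integer(n_total)))
  stages <- c("S2", "SWS", if (include_s1) "S1")
  stage_per_sample(hypnogram, fs, n_total) %in% stages
}

# ---- event tables ----------------------------------------------------------

EVENT_COLS <- c("id", "channel", "kind", "onset_s", "offset_s", "peak_s",
                "duration_s", "peak_amp_uv")

#' Create an empty event table
#' @return zero-row data.frame with the canonical event columns.
#' @export
empty_events <- function() {
  data.frame(id = integer(), channel = character(), kind = character(),
             onset_s = numeric(), offset_s = numeric(), peak_s = numeric(),
             duration_s = numeric(), peak_amp_uv = numeric(),
             stringsAsFactors = FALSE)
}

validate_events <- function(events) {
  stopifnot(all(EVENT_COLS %in% names(events)))
  if (nrow(events)) {
    stopifnot(all(events$onset_s < events$peak_s | events$duration_s == 0),
              all(events$peak_s <= events$offset_s),
              all(abs(events$duration_s - (events$offset_s - events$onset_s)) < 1e-9))
  }
  events
}

#' Read or write an event table as TSV
#'
#' @param events event data.frame (see [empty_events()] for the columns).
#' @param path TSV file path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_events(ev)
}
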