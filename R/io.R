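# File I/O: CSV time series, a minimal EDF reader/writer, and JSON metadata
# sidecars. EDF is the interchange format for multi-hour EEG; CSV is the
# bit-exact, tool-friendly format for shorter LFP and fluorescence traces.
#
# The EDF code implements the plain EDF specification (fixed-width ASCII
# header, 16-bit little-endian samples, per-signal physical/digital scaling).
# No EDF+ annotations are written.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = width, flag = "-")
  if (nchar(s) > width) s <- substr(s, 1, width)
  s
}

edf_num <- function(x, width) edf_field(format(x, trim = TRUE, scientific = FALSE, digits = 8), width)

#' Write a recording to an EDF file
#'
#' Samples are scaled to 16-bit integers using per-channel physical ranges,
#' so a round trip preserves samples to within the 16-bit quantization step.
#' Channels may have different sampling rates; `fs * record_duration` must
#' be a whole number for every channel. The final partial record, if any,
#' is padded by repeating the last sample.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @param record_duration data record length in seconds (default 1).
#' @export
write_edf <- function(rec, path, record_duration = 1) {
  chans <- rec$channels
  ns <- length(chans)
  spr <- vapply(chans, function(ch) ch$fs * record_duration, numeric(1))
  if (any(abs(spr - round(spr)) > 1e-9))
    stopf("fs * record_duration must be integer for every channel")
  spr <- as.integer(round(spr))
  n_rec <- max(ceiling(vapply(chans, ts_duration, numeric(1)) / record_duration))

  pmin_ <- pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- chans[[i]]$samples
    need <- n_rec * spr[i]
    if (length(x) < need) x <- c(x, rep(x[length(x)], need - length(x)))
    r <- range(x)
    if (diff(r) == 0) r <- r + c(-1, 1)
    # widen slightly so extreme samples are not clipped by rounding
    r <- r + c(-1, 1) * diff(r) * 1e-4
    pmin_[i] <- r[1]; pmax_[i] <- r[2]
    dig[[i]] <- as.integer(round((x - r[1]) / (r[2] - r[1]) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(rec$animal_id, 80),
    edf_field(paste("Startdate 01-JAN-2000", rec$group), 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_num(256 * (ns + 1), 8),
    edf_field("", 44),
    edf_num(n_rec, 8),
    edf_num(record_duration, 8),
    edf_num(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(chans, function(ch) edf_field(ch$label, 16), ""), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(vapply(chans, function(ch) edf_field(ch$units, 8), ""), collapse = ""),
    paste(vapply(pmin_, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax_, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_num(-32768, 8), ns), collapse = ""),
    paste(rep(edf_num(32767, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(vapply(spr, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Channels are returned at their native per-channel sampling rates; no
#' resampling is performed.
#'
#' @param path EDF file path.
#' @param animal_id,group metadata overrides; defaults come from the header
#'   and a JSON sidecar when present (see [load_recording()]).
#' @export
read_edf <- function(path, animal_id = NULL, group = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stopf("not an EDF file (bad version field '%s')", version)
  patient <- rd(80); rec_id <- rd(80); rd(8); rd(8)
  hdr_bytes <- as.numeric(rd(8))
  rd(44)
  n_rec <- as.numeric(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stopf("EDF header: bad signal count field")
  if (is.na(n_rec) || is.na(dur) || dur <= 0)
    stopf("EDF header: bad record count/duration fields")
  labs <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                     # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)                     # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr)))
    stopf("EDF header: unparsable numeric signal fields")

  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- integer(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little",
                   signed = TRUE)
      raw[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- v
    }
  }
  chans <- stats::setNames(vector("list", ns), labs)
  for (i in seq_len(ns)) {
    phys <- pmin_[i] + (raw[[i]] - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    chans[[i]] <- time_series(phys, fs = spr[i] / dur, label = labs[i],
                              units = units[i])
  }
  recording(chans, animal_id = animal_id %||% patient,
            group = group %||% "control")
}

#' Load a recording from CSV or EDF
#'
#' CSV dialect: header row required, comma separated, '.' decimal, first
#' column `t` (seconds, uniformly sampled) and one column per channel.
#' A JSON sidecar `<path minus extension>.json` with fields `animal_id`,
#' `group`, `hemisphere_map` and optionally `units` populates metadata
#' when present.
#'
#' @param path input file.
#' @param format `"csv"` or `"edf"`; inferred from the extension by default.
#' @return a [recording()].
#' @export
load_recording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  side <- sub("\\.[A-Za-z]+$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()

  if (format == "edf") {
    rec <- read_edf(path, animal_id = meta$animal_id, group = meta$group)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df) || names(df)[1L] != "t")
      stopf("CSV format error: first column must be 't' (time in seconds)")
    if (anyNA(df))
      stopf("CSV structural error: missing values (mismatched channel lengths?)")
    dt <- diff(df$t)
    if (any(abs(dt - dt[1L]) > 1e-6 * dt[1L]))
      stopf("CSV format error: column 't' is not uniformly sampled")
    fs <- 1 / dt[1L]
    units <- meta$units %||% "mV"
    chans <- lapply(names(df)[-1L], function(nm) {
      u <- if (length(units) > 1L) units[[nm]] %||% "mV" else units
      time_series(df[[nm]], fs = fs, t0 = df$t[1L], label = nm, units = u)
    })
    names(chans) <- names(df)[-1L]
    rec <- recording(chans, animal_id = meta$animal_id %||% "animal",
                     group = meta$group %||% "control")
  }
  if (!is.null(meta$hemisphere_map))
    rec$hemisphere_map <- unlist(meta$hemisphere_map)
  if (!is.null(meta$animal_id)) rec$animal_id <- meta$animal_id
  if (!is.null(meta$group)) rec$group <- meta$group
  rec
}

#' Write a recording (equal-rate channels) to CSV, with JSON sidecar
#' @param rec a [recording()].
#' @param path output CSV path.
#' @export
write_recording_csv <- function(rec, path) {
  fs <- vapply(rec$channels, function(ch) ch$fs, numeric(1))
  if (length(unique(fs)) != 1L)
    stopf("CSV export requires equal sampling rates across channels")
  n <- min(vapply(rec$channels, function(ch) length(ch$samples), numeric(1)))
  df <- data.frame(t = rec$channels[[1L]]$t0 + (seq_len(n) - 1) / fs[1L])
  for (nm in names(rec$channels)) df[[nm]] <- rec$channels[[nm]]$samples[seq_len(n)]
  utils::write.csv(df, path, row.names = FALSE)
  side <- sub("\\.[A-Za-z]+$", ".json", path)
  jsonlite::write_json(
    list(animal_id = rec$animal_id, group = rec$group,
         hemisphere_map = as.list(rec$hemisphere_map)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
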