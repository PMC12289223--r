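#' Construct a multichannel record
#'
#' @param channels named list of numeric sample vectors.
#' @param fs sampling rate(s) in Hz: a single value recycled to all
#'   channels, or a named vector.
#' @param units per-channel unit strings (single value recycled, or named).
#' @param roles per-channel roles; if missing, inferred from channel names
#'   (names containing ecg/ppg/abp|art/vcp|fin map to the matching role,
#'   anything else to \code{"other"}).
#' @param t0 record start time, seconds.
#' @return a [MultiChannelRecord-class].
#' @examples
#' rec <- multiChannelRecord(list(ECG = sin(1:100), PPG = cos(1:100)), fs = 100)
#' channelRoles(rec)
#' @export
multiChannelRecord <- function(channels, fs, units = "au", roles = NULL,
                               t0 = 0) {
  nm <- names(channels)
  expand <- function(v, default = NULL) {
    if (is.null(v)) v <- default
    if (is.null(names(v))) v <- stats::setNames(rep(v, length.out = length(nm)), nm)
    v[nm]
  }
  fs <- expand(fs)
  units <- expand(units)
  if (is.null(roles)) roles <- inferRoles(nm)
  roles <- expand(roles)
  new("MultiChannelRecord", channels = channels, fs = fs, units = units,
      roles = roles, t0 = t0)
}

#' Infer channel roles from channel names
#'
#' @param nm character vector of channel names.
#' @return character vector of roles, named by \code{nm}.
#' @export
inferRoles <- function(nm) {
  role1 <- function(x) {
    lx <- tolower(x)
    if (grepl("ecg|ekg", lx)) "ECG"
    else if (grepl("ppg|pleth", lx)) "PPG"
    else if (grepl("abp|art|aline", lx)) "ABP"
    else if (grepl("vcp|finap|clamp", lx)) "VCP"
    else "other"
  }
  stats::setNames(vapply(nm, role1, character(1)), nm)
}

#' Construct an event list
#'
#' @param kind,label,start,end vectors (recycled) describing the events;
#'   times in seconds from record start. Rows are sorted by \code{start}.
#' @return an [EventList-class].
#' @export
eventList <- function(kind = character(), label = "", start = numeric(),
                      end = start) {
  n <- length(start)
  ev <- data.frame(kind = rep_len(as.character(kind), n),
                   label = rep_len(as.character(label), n),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  new("EventList", events = ev)
}

#' Read a multichannel recording
#'
#' Supported formats: the package's documented CSV dialect, EDF (16-bit
#' European Data Format) and WFDB (format-16 signal file with a text
#' header). The format is taken from \code{format}, or guessed from the
#' file extension (.csv, .edf, .hea).
#'
#' The CSV dialect is: leading \code{#}-comment header lines carrying
#' metadata (\code{# fs <channel> <Hz>}, \code{# units <channel> <unit>},
#' \code{# role <channel> <role>}, \code{# t0 <s>}), then a header row of
#' channel names, then one column per channel. Channels with different
#' sampling rates are right-padded with empty cells; trailing empties are
#' stripped on read.
#'
#' @param path file path (for WFDB, the \code{.hea} header file).
#' @param format one of \code{"csv"}, \code{"edf"}, \code{"wfdb"}, or
#'   \code{NULL} to guess from the extension.
#' @param fs fallback sampling rate(s) if the file carries none (CSV only).
#' @param roles optional named role overrides.
#' @return a [MultiChannelRecord-class]; channels with unrecognized names
#'   get role \code{"other"}.
#' @seealso [writeRecord()]
#' @export
readRecord <- function(path, format = NULL, fs = NULL, roles = NULL) {
  if (!file.exists(path))
    stop("cannot read record: no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("cannot read record: empty file: ", path, call. = FALSE)
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               csv = "csv", edf = "edf", hea = "wfdb",
                               stop("cannot guess format of ", path,
                                    call. = FALSE))
  rec <- switch(match.arg(format, c("csv", "edf", "wfdb")),
                csv = .readCSVRecord(path, fs),
                edf = .readEDF(path),
                wfdb = .readWFDB(path))
  if (!is.null(roles)) rec@roles[names(roles)] <- roles
  validObject(rec)
  rec
}

#' Write a multichannel recording
#'
#' Writes the formats read by [readRecord()]. CSV is lossless at full
#' double precision; EDF and WFDB store 16-bit integers, so round trips are
#' exact only to the per-channel quantization step
#' \code{(max - min) / 65535}. EDF pads the final partial 1-second data
#' record by repeating the last sample; WFDB requires all channels to share
#' one sampling rate.
#'
#' @param record a [MultiChannelRecord-class].
#' @param path output path (for WFDB, the \code{.hea} path; the \code{.dat}
#'   is written alongside).
#' @param format \code{"csv"}, \code{"edf"}, \code{"wfdb"}, or \code{NULL}
#'   to guess from the extension.
#' @return \code{path}, invisibly.
#' @export
writeRecord <- function(record, path, format = NULL) {
  stopifnot(is(record, "MultiChannelRecord"))
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               csv = "csv", edf = "edf", hea = "wfdb",
                               stop("cannot guess format of ", path,
                                    call. = FALSE))
  switch(match.arg(format, c("csv", "edf", "wfdb")),
         csv = .writeCSVRecord(record, path),
         edf = .writeEDF(record, path),
         wfdb = .writeWFDB(record, path))
  invisible(path)
}

.readCSVRecord <- function(path, fs = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list(fs = c(), units = c(), role = c(), t0 = 0)
  for (l in lines[hdr]) {
    tok <- strsplit(trimws(sub("^#\\s*", "", l)), "\\s+")[[1]]
    if (length(tok) == 2L && tok[1] == "t0") meta$t0 <- as.numeric(tok[2])
    if (length(tok) == 3L && tok[1] %in% c("fs", "units", "role")) {
      v <- if (tok[1] == "fs") as.numeric(tok[3]) else tok[3]
      meta[[tok[1]]][tok[2]] <- v
    }
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop("cannot read record: no data rows in ", path, call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE)
  channels <- lapply(df, function(col) {
    col <- as.numeric(col)
    keep <- which(!is.na(col))
    if (!length(keep)) numeric() else col[seq_len(max(keep))]
  })
  fsv <- meta$fs
  if (is.null(fsv) || !length(fsv)) {
    if (is.null(fs))
      stop("sampling rate missing: CSV carries no '# fs' lines and no ",
           "'fs' argument was given", call. = FALSE)
    fsv <- fs
  }
  multiChannelRecord(channels, fs = fsv,
                     units = if (length(meta$units)) meta$units else "au",
                     roles = if (length(meta$role)) {
                       r <- inferRoles(names(channels))
                       r[names(meta$role)] <- meta$role
                       r
                     } else NULL,
                     t0 = meta$t0)
}

.writeCSVRecord <- function(record, path) {
  nm <- names(record@channels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ambubrs-record v1",
               sprintf("# t0 %.10g", record@t0),
               sprintf("# fs %s %.10g", nm, record@fs[nm]),
               sprintf("# units %s %s", nm, record@units[nm]),
               sprintf("# role %s %s", nm, record@roles[nm])), con)
  n <- max(vapply(record@channels, length, integer(1)))
  df <- as.data.frame(lapply(record@channels, function(x) {
    length(x) <- n
    x
  }), check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, na = "")
}

# --- EDF (16-bit European Data Format), minimal dialect -------------------
# Fixed 256-byte main header + 256 bytes per signal, then 1-second data
# records of little-endian int16. t0 is stashed in the reserved field.

.padAscii <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

.writeEDF <- function(record, path) {
  nm <- names(record@channels)
  ns <- length(nm)
  fs <- record@fs[nm]
  if (any(abs(fs - round(fs)) > 1e-9))
    stop("EDF writer requires integer sampling rates", call. = FALSE)
  spr <- stats::setNames(as.integer(round(fs)), nm)
  nrec <- max(ceiling(vapply(nm, function(x)
    length(record@channels[[x]]) / spr[[x]], numeric(1))))
  rng <- lapply(record@channels, function(x) {
    r <- range(x)
    if (diff(r) == 0) r <- r + c(-1, 1)
    r
  })
  con <- file(path, "wb")
  on.exit(close(con))
  wa <- function(x, w) writeChar(.padAscii(x, w), con, nchars = w, eos = NULL)
  wa("0", 8); wa("X", 80); wa("X", 80)
  wa("01.01.00", 8); wa("00.00.00", 8)
  wa(256L * (1L + ns), 8)
  wa(sprintf("t0=%.10g", record@t0), 44)
  wa(nrec, 8); wa("1", 8); wa(ns, 4)
  for (i in seq_len(ns)) wa(nm[i], 16)
  for (i in seq_len(ns)) wa(record@roles[[nm[i]]], 80)
  for (i in seq_len(ns)) wa(record@units[[nm[i]]], 8)
  for (i in seq_len(ns)) wa(sprintf("%.8g", rng[[i]][1]), 8)
  for (i in seq_len(ns)) wa(sprintf("%.8g", rng[[i]][2]), 8)
  for (i in seq_len(ns)) wa("-32768", 8)
  for (i in seq_len(ns)) wa("32767", 8)
  for (i in seq_len(ns)) wa("", 80)
  for (i in seq_len(ns)) wa(spr[[i]], 8)
  for (i in seq_len(ns)) wa("", 32)
  dig <- lapply(seq_len(ns), function(i) {
    x <- record@channels[[i]]
    need <- nrec * spr[[i]]
    if (length(x) < need) x <- c(x, rep(x[length(x)], need - length(x)))
    r <- rng[[i]]
    as.integer(round((x - r[1]) / (r[2] - r[1]) * 65535 - 32768))
  })
  for (k in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      idx <- ((k - 1L) * spr[[i]] + 1L):(k * spr[[i]])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
}

.readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ra <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ra(8); ra(80); ra(80); ra(8); ra(8)
  hbytes <- as.integer(ra(8))
  reserved <- ra(44)
  nrec <- as.integer(ra(8))
  recdur <- as.numeric(ra(8))
  ns <- as.integer(ra(4))
  if (!isTRUE(ns > 0) || !isTRUE(nrec >= 0) || !isTRUE(hbytes == 256L * (1L + ns)))
    stop("garbled EDF header in ", path, call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) ra(16), character(1))
  transd <- vapply(seq_len(ns), function(i) ra(80), character(1))
  units <- vapply(seq_len(ns), function(i) ra(8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) ra(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) ra(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) ra(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) ra(8), character(1)))
  for (i in seq_len(ns)) ra(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) ra(8), character(1)))
  for (i in seq_len(ns)) ra(32)
  raw <- lapply(seq_len(ns), function(i) vector("list", nrec))
  for (k in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      raw[[i]][[k]] <- readBin(con, integer(), n = spr[[i]], size = 2L,
                               signed = TRUE, endian = "little")
    }
  }
  channels <- lapply(seq_len(ns), function(i) {
    d <- unlist(raw[[i]])
    pmin[i] + (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
  })
  names(channels) <- make.unique(labels)
  t0 <- 0
  if (grepl("^t0=", reserved)) t0 <- as.numeric(sub("^t0=", "", reserved))
  multiChannelRecord(channels, fs = stats::setNames(spr / recdur, names(channels)),
                     units = stats::setNames(units, names(channels)),
                     roles = stats::setNames(
                       ifelse(transd %in% c("ECG", "PPG", "ABP", "VCP"),
                              transd, inferRoles(names(channels))),
                       names(channels)),
                     t0 = t0)
}

# --- WFDB format 16 -------------------------------------------------------
# <rec>.hea text header + <rec>.dat interleaved little-endian int16.
# value = (adc - baseline) / gain. All channels must share one fs.

.writeWFDB <- function(record, path) {
  nm <- names(record@channels)
  fs <- unique(unname(record@fs[nm]))
  if (length(fs) != 1L)
    stop("WFDB writer requires a single sampling rate across channels",
         call. = FALSE)
  n <- unique(vapply(record@channels, length, integer(1)))
  if (length(n) != 1L)
    stop("WFDB writer requires equal-length channels", call. = FALSE)
  base <- sub("\\.hea$", "", basename(path))
  gains <- vapply(record@channels, function(x) {
    m <- max(abs(x), 1e-12)
    32000 / m
  }, numeric(1))
  hea <- c(sprintf("%s %d %.10g %d", base, length(nm), fs, n),
           sprintf("%s.dat 16 %.10g(0)/%s 16 0 0 0 0 %s",
                   base, gains, record@units[nm], nm),
           sprintf("# t0 %.10g", record@t0),
           sprintf("# role %s %s", nm, record@roles[nm]))
  writeLines(hea, path)
  adc <- mapply(function(x, g) as.integer(round(x * g)),
                record@channels, gains, SIMPLIFY = FALSE)
  inter <- as.integer(t(do.call(cbind, adc)))
  con <- file(file.path(dirname(path), paste0(base, ".dat")), "wb")
  on.exit(close(con))
  writeBin(inter, con, size = 2L, endian = "little")
}

.readWFDB <- function(path) {
  lines <- readLines(path)
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 4L) stop("garbled WFDB header in ", path, call. = FALSE)
  nsig <- as.integer(rec[2]); fs <- as.numeric(rec[3]); n <- as.integer(rec[4])
  sig <- lines[2:(1 + nsig)]
  meta <- lapply(sig, function(l) strsplit(trimws(l), "\\s+")[[1]])
  datfile <- meta[[1]][1]
  if (any(vapply(meta, function(m) m[2], character(1)) != "16"))
    stop("only WFDB format 16 is supported", call. = FALSE)
  gspec <- vapply(meta, function(m) m[3], character(1))
  gains <- as.numeric(sub("\\(.*$", "", gspec))
  basel <- as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gspec))
  unitv <- sub("^[^/]*/", "", gspec)
  nm <- vapply(meta, function(m) m[length(m)], character(1))
  t0 <- 0; roles <- inferRoles(nm)
  for (l in grep("^#", lines, value = TRUE)) {
    tok <- strsplit(trimws(sub("^#\\s*", "", l)), "\\s+")[[1]]
    if (length(tok) == 2L && tok[1] == "t0") t0 <- as.numeric(tok[2])
    if (length(tok) == 3L && tok[1] == "role") roles[tok[2]] <- tok[3]
  }
  con <- file(file.path(dirname(path), datfile), "rb")
  on.exit(close(con))
  adc <- readBin(con, integer(), n = n * nsig, size = 2L, signed = TRUE,
                 endian = "little")
  channels <- lapply(seq_len(nsig), function(i) {
    (adc[seq(i, length(adc), by = nsig)] - basel[i]) / gains[i]
  })
  names(channels) <- nm
  multiChannelRecord(channels, fs = fs,
                     units = stats::setNames(unitv, nm),
                     roles = roles[nm], t0 = t0)
}

#' Read event annotations
#'
#' Reads a CSV with columns \code{kind,label,start,end} (header optional;
#' times in seconds). Rows are validated and sorted by start time;
#' overlapping intervals are preserved.
#'
#' @param path file path.
#' @return an [EventList-class].
#' @export
readEvents <- function(path) {
  if (!file.exists(path))
    stop("cannot read events: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) && grepl("^.?kind", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) return(eventList())
  df <- utils::read.csv(text = paste(lines, collapse = "\n"), header = FALSE,
                        col.names = c("kind", "label", "start", "end"),
                        colClasses = c("character", "character",
                                       "numeric", "numeric"))
  bad <- which(df$end < df$start)
  if (length(bad))
    stop("event end < start at row ", bad[1], " of ", path, call. = FALSE)
  eventList(df$kind, df$label, df$start, df$end)
}

#' Write event annotations
#'
#' @param ev an [EventList-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeEvents <- function(ev, path) {
  stopifnot(is(ev, "EventList"))
  utils::write.csv(ev@events, path, row.names = FALSE)
  invisible(path)
}

#' Export / import a beat table as CSV
#'
#' One row per beat with the feature columns, the qualification flag and
#' semicolon-joined reason codes.
#'
#' @param bt a [BeatTable-class].
#' @param path CSV path.
#' @return \code{path} (write) or a [BeatTable-class] (read).
#' @export
writeBeatTable <- function(bt, path) {
  stopifnot(is(bt, "BeatTable"))
  df <- beats(bt)
  attr(df, "modality") <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# modality %s", bt@modality), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBeatTable
#' @export
readBeatTable <- function(path) {
  lines <- readLines(path)
  modality <- ""
  ml <- grep("^# modality", lines, value = TRUE)
  if (length(ml)) modality <- trimws(sub("^# modality", "", ml[1]))
  lines <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(lines, collapse = "\n"))
  reasons <- strsplit(ifelse(is.na(df$reasons), "", as.character(df$reasons)),
                      ";", fixed = TRUE)
  reasons <- lapply(reasons, function(r) r[nzchar(r)])
  df$qualified <- NULL
  df$reasons <- NULL
  new("BeatTable", beats = df, modality = modality,
      qualified = lengths(reasons) == 0L, reasons = reasons)
}
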