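#' Read an SpO2 trace from a CSV file
#'
#' Expects one saturation value per row in a column named `spo2` (an optional
#' `time_s` column is ignored for sample values). A single header row is
#' auto-detected: if the first row is non-numeric it is treated as a header.
#' Values are read verbatim; validity is assigned later by [mark_invalid()].
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz.
#' @param phase `"preop"` or `"postop"`.
#' @param subject_id Subject identifier attached to the record.
#' @return An [spo2_record()] with an all-`TRUE` validity mask.
#' @export
read_spo2_csv <- function(path, fs = 3, phase = c("preop", "postop"),
                          subject_id = NULL) {
  phase <- match.arg(phase)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty SpO2 file: ", path)

  first <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(trimws(first)))))
  col <- 1L
  if (has_header) {
    header <- tolower(trimws(first))
    hit <- which(header == "spo2")
    if (length(hit)) col <- hit[1L]
    lines <- lines[-1L]
    if (length(lines) == 0L) stop("no data rows in SpO2 file: ", path)
  }

  fields <- vapply(strsplit(lines, ",", fixed = TRUE),
                   function(f) trimws(f[min(col, length(f))]), character(1))
  values <- suppressWarnings(as.numeric(fields))
  bad <- which(is.na(values))
  if (length(bad)) {
    row <- bad[1L] + if (has_header) 1L else 0L
    stop(sprintf("non-numeric SpO2 value at row %d of %s: '%s'",
                 row, path, fields[bad[1L]]))
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  spo2_record(values, fs = fs, subject_id = subject_id, phase = phase)
}

#' Write an SpO2 record to CSV
#'
#' Writes a `spo2` column (and a `time_s` column) in the dialect
#' [read_spo2_csv()] reads. Invalid samples are written as recorded.
#'
#' @param record An [spo2_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spo2_csv <- function(record, path) {
  assert_record(record)
  dt <- data.table::data.table(
    time_s = (seq_along(record$samples) - 1) / record$fs,
    spo2 = record$samples
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# EDF (European Data Format, 16-bit) support. The format is a fixed-width
# ASCII header (256 bytes + 256 per signal) followed by data records of
# little-endian 16-bit integers. Only continuous single-segment EDF is
# handled, which covers oximeter exports.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write an SpO2 record as an EDF file
#'
#' Stores the trace as one EDF signal with a 1-second record duration and an
#' identity digital-to-physical mapping over 0--100%, so integer-quantized
#' saturations round-trip exactly. If the sample count does not fill a whole
#' number of records the tail is padded with 0 (which [mark_invalid()] flags).
#'
#' @param record An [spo2_record()].
#' @param path Output path.
#' @param channel_name EDF signal label (default `"SpO2"`).
#' @return `path`, invisibly.
#' @export
write_spo2_edf <- function(record, path, channel_name = "SpO2") {
  assert_record(record)
  fs <- record$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- as.integer(round(record$samples))
  n_rec <- ceiling(length(x) / fs)
  x <- c(x, integer(n_rec * fs - length(x)))  # zero-pad final record
  x[x < 0L] <- 0L; x[x > 100L] <- 100L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(record$subject_id, 80),
    edf_pad(paste("Startdate X spo2burden", record$phase), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L + 256L, 8),          # header bytes: 1 signal
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),                    # record duration, seconds
    edf_pad(1L, 4)
  )
  sig <- paste0(
    edf_pad(channel_name, 16), edf_pad("pulse oximeter", 80),
    edf_pad("%", 8),
    edf_pad(0, 8), edf_pad(100, 8),   # physical min/max
    edf_pad(0, 8), edf_pad(100, 8),   # digital min/max (identity mapping)
    edf_pad("", 80), edf_pad(fs, 8), edf_pad("", 32)
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  writeBin(x, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8)); patient <- trimws(rd(80)); recording <- trimws(rd(80))
  startdate <- rd(8); starttime <- rd(8)
  header_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_records <- as.integer(rd(8)); record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  field <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), character(1))
  labels <- field(16); transducer <- field(80); dim <- field(8)
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  prefilter <- field(80); spr <- as.integer(field(8)); field(32)
  list(version = version, patient = patient, recording = recording,
       header_bytes = header_bytes, n_records = n_records,
       record_dur = record_dur, ns = ns, labels = labels,
       phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, samples_per_record = spr)
}

#' Read an SpO2 channel from an EDF file
#'
#' The sampling rate is taken from the EDF header (samples per record divided
#' by record duration). Physical values are rounded to integer percent to
#' honor the 1% resolution of the source devices.
#'
#' @param path Path to the EDF file.
#' @param channel_name Label of the signal to read.
#' @param phase `"preop"` or `"postop"`.
#' @param subject_id Subject identifier; defaults to the EDF patient field.
#' @return An [spo2_record()] with an all-`TRUE` validity mask.
#' @export
read_spo2_edf <- function(path, channel_name = "SpO2",
                          phase = c("preop", "postop"), subject_id = NULL) {
  phase <- match.arg(phase)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  ch <- which(h$labels == channel_name)
  if (length(ch) == 0L)
    stop(sprintf("channel '%s' not found; available channels: %s",
                 channel_name, paste(sprintf("'%s'", h$labels), collapse = ", ")))
  ch <- ch[1L]
  rec_len <- sum(h$samples_per_record)
  raw <- readBin(con, integer(), n = rec_len * h$n_records, size = 2L,
                 endian = "little", signed = TRUE)
  offsets <- cumsum(c(0L, h$samples_per_record))
  spr <- h$samples_per_record[ch]
  idx <- as.vector(outer(seq_len(spr) + offsets[ch],
                         (seq_len(h$n_records) - 1L) * rec_len, `+`))
  dig <- raw[idx]
  gain <- (h$phys_max[ch] - h$phys_min[ch]) / (h$dig_max[ch] - h$dig_min[ch])
  phys <- h$phys_min[ch] + (dig - h$dig_min[ch]) * gain
  fs <- spr / h$record_dur
  if (is.null(subject_id)) {
    subject_id <- strsplit(h$patient, " ")[[1]][1]
    if (is.na(subject_id) || !nzchar(subject_id)) subject_id <- "anonymous"
  }
  spo2_record(round(phys), fs = fs, subject_id = subject_id, phase = phase)
}

# ---------------------------------------------------------------------------

#' Read a cohort covariate table
#'
#' Reads a delimited table with one row per subject. Mandatory columns:
#' `subject_id`, `sex` (F/M), `bmi`, `comorbidity` (0/1 cardiorespiratory
#' comorbidity flag). Optional: `age`, `ahi`, `total_arousal_index`,
#' `resp_arousal_index`, `rd_label`. Missing optional columns stay absent;
#' blank optional cells become `NA`.
#'
#' @param path Path to the CSV/TSV file.
#' @return A `data.table` with one row per subject.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  mandatory <- c("subject_id", "sex", "bmi", "comorbidity")
  miss <- setdiff(mandatory, names(dt))
  if (length(miss))
    stop("missing column: ", paste(miss, collapse = ", "))
  dt[, subject_id := as.character(subject_id)]
  dt[, sex := toupper(as.character(sex))]
  if (!all(dt$sex %in% c("F", "M")))
    stop("sex column must contain only F/M")
  dt[, bmi := as.numeric(bmi)]
  dt[, comorbidity := as.integer(comorbidity)]
  for (opt in c("age", "ahi", "total_arousal_index", "resp_arousal_index"))
    if (opt %in% names(dt)) dt[, (opt) := as.numeric(get(opt))]
  if ("rd_label" %in% names(dt)) dt[, rd_label := as.integer(rd_label)]
  dt[]
}

#' Export detected episodes as a table or BED-like intervals
#'
#' `episodes_to_table()` writes one row per episode with onset, nadir and end
#' times in seconds plus depth, baseline and burden columns.
#' `episodes_to_bed()` writes 0-based half-open intervals over sample time for
#' use with genome-browser-style interval tools.
#'
#' @param episodes Episode table from [detect_episodes()].
#' @param path Output path.
#' @param record The [spo2_record()] the episodes were detected on (BED export
#'   uses its subject id as the sequence name).
#' @return `path`, invisibly.
#' @export
episodes_to_table <- function(episodes, path) {
  cols <- c("onset_s", "nadir_s", "end_s", "drop_magnitude", "baseline_level",
            "duration_s", "burden", "normalized_burden", "recovered_fully")
  data.table::fwrite(as.data.table(episodes)[, cols, with = FALSE], path)
  invisible(path)
}

#' @rdname episodes_to_table
#' @export
episodes_to_bed <- function(episodes, record, path) {
  assert_record(record)
  ep <- as.data.table(episodes)
  bed <- data.table::data.table(
    chrom = record$subject_id,
    start = ep$drop_onset_idx - 1L,            # 0-based, inclusive
    end = ep$recovery_end_idx,                 # half-open
    name = sprintf("desat_%d", seq_len(nrow(ep))),
    score = round(pmin(1000, ep$burden))
  )
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

as.data.table <- data.table::as.data.table
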