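#' Write / read a recording as delimited text
#'
#' One row per channel (first column the channel label), tab-separated, with
#' a `# fs=<Hz>` header line; markers go to a `<path>.markers.tsv` sidecar
#' with columns `sample`, `condition`, `event`.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_text <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", recording$fs), con)
  df <- data.frame(channel = recording$channel_labels,
                   recording$data, check.names = FALSE)
  write.table(df, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  if (nrow(recording$markers))
    write.table(recording$markers, paste0(path, ".markers.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_text
#' @export
read_recording_text <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# fs=", first)) stop("missing '# fs=' header line")
  fs <- as.numeric(sub("^# fs=", "", first))
  df <- read.table(path, sep = "\t", skip = 1, header = FALSE,
                   stringsAsFactors = FALSE)
  labels <- df[[1]]
  data <- as.matrix(df[, -1, drop = FALSE])
  dimnames(data) <- NULL
  mpath <- paste0(path, ".markers.tsv")
  markers <- NULL
  if (file.exists(mpath))
    markers <- read.table(mpath, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  eeg_recording(data, fs, labels, markers)
}

# Fixed-width ASCII field of an EDF header.
edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording to European Data Format (EDF)
#'
#' Minimal continuous EDF: 16-bit samples, one data record per second (the
#' recording is zero-padded to a whole number of seconds), physical range
#' taken from the data and stored in the header. Markers are exported to the
#' same `<path>.markers.tsv` sidecar as [write_recording_text()].
#'
#' @param recording an [eeg_recording()]; `fs` must be a whole number.
#' @param path output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  ns <- nrow(data)
  n_rec <- as.integer(ceiling(ncol(data) / fs))
  if (ncol(data) < n_rec * fs)
    data <- cbind(data, matrix(0, ns, n_rec * fs - ncol(data)))
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  pmax_[pmax_ <= pmin_] <- pmin_[pmax_ <= pmin_] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),                  # patient id
    edf_field("Startdate X X X X", 80),        # recording id
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 + ns * 256, 8),
    edf_field("", 44),
    edf_field(n_rec, 8), edf_field("1", 8),    # record duration 1 s
    edf_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_field, "", width = width),
                     collapse = ""), con, eos = NULL)
  per_sig(recording$channel_labels, 16)
  per_sig(rep("EEG", ns), 80)                  # transducer
  per_sig(rep("uV", ns), 8)
  per_sig(sprintf("%.8g", pmin_), 8)
  per_sig(sprintf("%.8g", pmax_), 8)
  per_sig(rep(dmin, ns), 8)
  per_sig(rep(dmax, ns), 8)
  per_sig(rep("", ns), 80)                     # prefiltering
  per_sig(rep(fs, ns), 8)
  per_sig(rep("", ns), 32)                     # reserved
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, cols] - pmin_[ch]) * gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  if (nrow(recording$markers))
    write.table(recording$markers, paste0(path, ".markers.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports continuous 16-bit EDF with a common sampling rate across
#' signals. A `<path>.markers.tsv` sidecar, if present, is loaded as the
#' marker table.
#'
#' @param path EDF file path.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))                   # samples per record
  rdv(32)
  if (length(unique(spr)) != 1) stop("signals with differing rates unsupported")
  fs <- spr[1] / dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little",
                     signed = TRUE)
      data[ch, cols] <- pmin_[ch] +
        (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
    }
  }
  mpath <- paste0(path, ".markers.tsv")
  markers <- NULL
  if (file.exists(mpath))
    markers <- read.table(mpath, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  eeg_recording(data, fs, labels, markers)
}

#' Write / read a connectivity matrix as delimited text
#'
#' Square tab-separated matrix preceded by a one-line header recording kind,
#' band, normalization state and channel labels.
#'
#' @param matrix a `connectivity_matrix`.
#' @param path file path.
#' @return `path` (writer) or a `connectivity_matrix` (reader).
#' @export
write_connectivity <- function(matrix, path) {
  labels <- matrix$channel_labels
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(matrix$values)))
  hdr <- sprintf("# kind=%s band=%s normalized=%d labels=%s",
                 matrix$kind,
                 if (is.null(matrix$band)) "NA" else matrix$band,
                 as.integer(matrix$normalized),
                 paste(labels, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(matrix$values, con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  hdr <- readLines(path, n = 1)
  get <- function(key) sub(sprintf(".*%s=(\\S+).*", key), "\\1", hdr)
  vals <- as.matrix(read.table(path, sep = "\t", skip = 1, header = FALSE))
  dimnames(vals) <- NULL
  band <- get("band")
  connectivity_matrix(vals, kind = get("kind"),
                      normalized = get("normalized") == "1",
                      channel_labels = strsplit(get("labels"), ",")[[1]],
                      band = if (band == "NA") NULL else band)
}

#' Write a barcode as delimited text
#'
#' Rows `dimension`, `birth`, `death` with `inf` marking essential bars.
#'
#' @param barcode a `barcode_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_barcode <- function(barcode, path) {
  df <- as.data.frame(barcode)
  df$death <- ifelse(is.infinite(df$death), "inf", format(df$death))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an Euler curve as delimited text (`epsilon`, `chi`, `entropy`)
#' @param curve an `euler_curve`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_euler_curve <- function(curve, path) {
  write.table(as.data.frame(curve), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a feature or summary table as tab-separated text
#' @param table a data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
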