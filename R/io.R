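#' Read an EEG recording from disk
#'
#' Two on-disk forms are supported: European Data Format (`.edf`,
#' 16-bit integer encoding) and a delimited matrix (`.tsv`, samples in
#' rows, one column per channel) with a JSON sidecar (`<stem>.json`)
#' carrying `fs`, `labels` and `reference`. `format = "auto"` dispatches on
#' the file extension.
#'
#' @param path file path (`.edf` or `.tsv`).
#' @param format `"auto"`, `"edf"` or `"matrix"`.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("file not found:", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  rec <- switch(format, edf = read_edf(path), matrix = read_recording_matrix(path))
  if (rec$fs < 64 || rec$fs > 1024) {
    warn(sprintf("unusual sampling rate %g Hz (expected 64-1024 Hz)", rec$fs))
  }
  rec
}

#' @rdname read_recording
#' @param rec an `eeg_recording` to write.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  switch(format, edf = write_edf(rec, path), matrix = write_recording_matrix(rec, path))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

write_recording_matrix <- function(rec, path) {
  utils::write.table(t(rec$data), path, sep = "\t", row.names = FALSE,
                     col.names = rec$labels, quote = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, labels = rec$labels, reference = rec$reference,
         n_samples = ncol(rec$data), unit = "uV"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
}

read_recording_matrix <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) abort(paste("missing JSON sidecar:", sc_path))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (field in c("fs", "labels")) {
    if (is.null(sc[[field]])) abort(sprintf("sidecar %s lacks required field '%s'", sc_path, field))
  }
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE))
  if (ncol(m) != length(sc$labels)) {
    abort(sprintf("matrix has %d columns but sidecar lists %d labels", ncol(m), length(sc$labels)))
  }
  ref <- sc$reference %||% "other"
  if (!ref %in% c("linked-earlobe", "common-average", "other")) ref <- "other"
  new_recording(t(m), sc$fs, sc$labels, reference = ref)
}

# --- Minimal European Data Format writer/reader -----------------------------
# One-second data records, 16-bit little-endian samples, per-channel
# symmetric physical range. Covers the subset of the format this package
# writes; reading arbitrary third-party EDF files with annotations or mixed
# per-signal rates is out of scope.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = -width, flag = " ")
}

write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) abort("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) abort("recording shorter than one 1-s EDF data record")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  phys_max <- pmax(apply(abs(data), 1L, max) * 1.0001, 1)
  # encode with the same affine map used on decode, so the round-trip error
  # is at most half a quantization step
  dig <- matrix(0L, ns, ncol(data))
  for (i in seq_len(ns)) {
    dig[i, ] <- as.integer(round((data[i, ] + phys_max[i]) / (2 * phys_max[i]) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field(paste("Startdate 01-JAN-2000", rec$reference), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256L * (ns + 1L), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1L, 8), pad_field(ns, 4)
  ), con, eos = NULL)
  fields <- list(
    list(rec$labels, 16L), list(rep("simulated", ns), 80L),
    list(rep("uV", ns), 8L),
    list(formatC(-phys_max, format = "g", digits = 6), 8L),
    list(formatC(phys_max, format = "g", digits = 6), 8L),
    list(rep("-32768", ns), 8L), list(rep("32767", ns), 8L),
    list(rep("", ns), 80L), list(rep(fs, ns), 8L), list(rep("", ns), 32L)
  )
  for (f in fields) writeChar(paste0(vapply(f[[1]], pad_field, "", f[[2]]), collapse = ""),
                              con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx])), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(n) {
    x <- suppressWarnings(as.numeric(trimws(rd(n))))
    if (is.na(x)) abort("ill-formed EDF header: non-numeric field")
    x
  }
  rd(8)  # version
  rd(80); recording_field <- rd(80)
  rd(8); rd(8)
  num(8)  # header bytes
  rd(44)
  n_rec <- num(8)
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  if (ns < 1) abort("ill-formed EDF header: ns < 1")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")  # transducer
  vapply(seq_len(ns), function(i) rd(8), "")   # phys dim
  phys_min <- vapply(seq_len(ns), function(i) num(8), 0)
  phys_max <- vapply(seq_len(ns), function(i) num(8), 0)
  dig_min <- vapply(seq_len(ns), function(i) num(8), 0)
  dig_max <- vapply(seq_len(ns), function(i) num(8), 0)
  vapply(seq_len(ns), function(i) rd(80), "")  # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(num(8)), 0L)
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1L) abort("EDF reader supports a single common sampling rate only")
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2L, signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, idx] <- t(block)
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (i in seq_len(ns)) data[i, ] <- phys_min[i] + (data[i, ] - dig_min[i]) * scale[i]
  ref <- if (grepl("common-average", recording_field)) "common-average" else "other"
  new_recording(data, fs, labels, reference = ref)
}

# --- Leadfield and cohort IO ------------------------------------------------

#' Read and write leadfields
#'
#' The gain matrix is stored as a delimited numeric matrix (channels in
#' rows) and the voxel table as JSON.
#'
#' @param lf an `eeg_leadfield`.
#' @param gain_path path for the gain matrix (TSV).
#' @param voxel_path path for the voxel table (JSON).
#' @export
write_leadfield <- function(lf, gain_path, voxel_path) {
  validate_leadfield(lf)
  utils::write.table(lf$gain, gain_path, sep = "\t", row.names = lf$channels,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(lf$voxels, voxel_path, auto_unbox = FALSE, digits = NA)
  invisible(gain_path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(gain_path, voxel_path) {
  g <- utils::read.table(gain_path, sep = "\t", row.names = 1L, header = FALSE)
  vox <- tibble::as_tibble(jsonlite::read_json(voxel_path, simplifyVector = TRUE))
  lf <- structure(
    list(gain = as.matrix(g), channels = rownames(g), voxels = vox, seed = NA_integer_),
    class = "eeg_leadfield"
  )
  colnames(lf$gain) <- NULL
  validate_leadfield(lf)
}

#' Write / read a simulated cohort
#'
#' One recording file per subject (matrix + JSON sidecar, or EDF) plus a
#' tab-delimited `manifest.tsv` listing subject metadata and file names.
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created if needed).
#' @param format `"matrix"` or `"edf"` per-subject recording format.
#' @export
write_cohort <- function(cohort, dir, format = c("matrix", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "edf") ".edf" else ".tsv"
  man <- cohort_manifest(cohort)
  man$file <- paste0(man$subject, ext)
  for (s in cohort) {
    write_recording(s$recording, file.path(dir, paste0(s$id, ext)), format)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) abort(paste("missing manifest:", man_path))
  man <- tibble::as_tibble(utils::read.table(man_path, header = TRUE, sep = "\t"))
  records <- purrr::map(seq_len(nrow(man)), function(i) {
    rec <- read_recording(file.path(dir, man$file[i]))
    structure(
      c(as.list(man[i, setdiff(names(man), "file")]),
        list(id = man$subject[i], recording = rec)),
      class = "subject_record"
    )
  })
  structure(records, class = "eeg_cohort")
}
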