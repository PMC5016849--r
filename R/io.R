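# Minimal RIFF/WAVE 16-bit PCM reader and writer, enough for the
# two-channel (PCG + ECG) recordings this package exchanges.

#' Write a recording as a two-channel 16-bit PCM WAV file
#'
#' Channel 1 is the PCG, channel 2 the ECG. Each channel is scaled by a
#' common factor so the louder channel peaks at 0.9 full scale; the scale
#' is not stored, so amplitudes are relative (which is all the pipeline
#' uses).
#'
#' @param recording A `pcg_recording`, or a numeric matrix with one column
#'   per channel (then `sampling_rate` is required).
#' @param path Output path.
#' @param sampling_rate Required for matrix input.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path, sampling_rate = NULL) {
  if (inherits(recording, "pcg_recording")) {
    data <- cbind(recording$pcg, recording$ecg)
    fs <- recording$sampling_rate
  } else {
    data <- as.matrix(recording)
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for matrix input")
  }
  peak <- max(abs(data), 1e-12)
  pcm <- as.integer(round(t(data) / peak * 0.9 * 32767))
  n_ch <- ncol(data)
  byte_rate <- fs * n_ch * 2L
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file
#'
#' @param path WAV file path (16-bit PCM).
#' @return List with `data` (samples x channels matrix, scaled to [-1, 1])
#'   and `sampling_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fs <- NULL; n_ch <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      n_ch <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16L)
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt")
      if (bits != 16L) stop("only 16-bit PCM supported")
      data <- readBin(con, integer(), n = size %/% 2L, size = 2,
                      signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(data)) stop("no data chunk in ", path)
  list(data = matrix(data / 32767, ncol = n_ch, byrow = TRUE),
       sampling_rate = fs)
}

#' Write a cohort to disk
#'
#' Writes one two-channel WAV per subject (PCG + ECG), a cohort CSV
#' (subject_id, mpap, label, seed, path) and a JSON annotations sidecar per
#' subject carrying the ground-truth cycle annotations.
#'
#' @param cohort A `pcg_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The cohort CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pcg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- cohort$metadata
  meta$path <- file.path(dir, paste0(meta$subject_id, ".wav"))
  for (i in seq_len(nrow(meta))) {
    rec <- cohort$recordings[[meta$subject_id[i]]]
    write_wav(rec, meta$path[i])
    jsonlite::write_json(
      list(subject_id = rec$subject_id, sampling_rate = rec$sampling_rate,
           mpap = rec$mpap, label = rec$label,
           annotations = rec$annotations),
      file.path(dir, paste0(meta$subject_id[i], ".annotations.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(meta, csv, row.names = FALSE)
  invisible(csv)
}

#' Read a cohort directory back into recordings
#'
#' @param dir Directory written by [write_cohort()] (or containing a
#'   compatible `cohort.csv` with subject_id, label and path columns).
#' @return A `pcg_cohort` whose recordings carry annotations when sidecar
#'   JSONs are present.
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "cohort.csv")
  if (!file.exists(csv)) stop("no cohort.csv in ", dir)
  meta <- utils::read.csv(csv, stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    p <- meta$path[i]
    if (!file.exists(p)) p <- file.path(dir, basename(p))
    wav <- read_wav(p)
    if (ncol(wav$data) < 2)
      stop("recording ", meta$subject_id[i], " has no ECG channel; ",
           "this pipeline requires a simultaneous ECG for S2 localization")
    ann_path <- file.path(dir, paste0(meta$subject_id[i],
                                      ".annotations.json"))
    ann <- NULL
    if (file.exists(ann_path)) {
      j <- jsonlite::read_json(ann_path, simplifyVector = TRUE)
      ann <- as.data.frame(j$annotations)
    }
    structure(list(subject_id = meta$subject_id[i],
                   pcg = wav$data[, 1], ecg = wav$data[, 2],
                   sampling_rate = wav$sampling_rate,
                   duration = nrow(wav$data) / wav$sampling_rate,
                   mpap = if ("mpap" %in% names(meta)) meta$mpap[i] else NULL,
                   label = meta$label[i], annotations = ann),
              class = "pcg_recording")
  })
  names(recs) <- meta$subject_id
  structure(list(recordings = recs, metadata = meta, config = NULL),
            class = "pcg_cohort")
}
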