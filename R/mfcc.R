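#' MFCC extraction configuration
#'
#' Framing and filterbank settings for mel-frequency cepstral coefficient
#' extraction. Defaults: 20 ms frames with a 10 ms hop (successive frames
#' overlap by 50 percent of the frame length), pre-emphasis 0.97, 26
#' triangular mel filters, and the first 13 coefficients (indices 0--12,
#' including the energy-like 0th).
#'
#' @param frame_length Frame length in seconds (default 0.020).
#' @param frame_hop Hop between frame starts in seconds (default 0.010;
#'   must not exceed `frame_length`).
#' @param pre_emphasis First-difference pre-emphasis coefficient in [0, 1)
#'   (y[n] = x[n] - a x[n-1]; default 0.97).
#' @param n_mel_filters Number of triangular mel filters (default 26).
#' @param n_coefficients Number of cepstral coefficients D kept after the
#'   DCT (default 13; must not exceed `n_mel_filters`).
#' @param fft_length FFT size in samples; default the next power of two at
#'   or above the frame length in samples.
#' @param mel_range Frequency interval in Hz spanned by the filterbank;
#'   default 0 to Nyquist.
#' @return An object of class `mfcc_config`.
#' @export
mfcc_config <- function(frame_length = 0.020, frame_hop = 0.010,
                        pre_emphasis = 0.97, n_mel_filters = 26L,
                        n_coefficients = 13L, fft_length = NULL,
                        mel_range = NULL) {
  stopifnot(frame_length > 0, frame_hop > 0,
            pre_emphasis >= 0, pre_emphasis < 1,
            n_mel_filters >= 1, n_coefficients >= 1)
  if (frame_hop > frame_length + 1e-12)
    stop("frame_hop must not exceed frame_length")
  if (n_coefficients > n_mel_filters)
    stop("n_coefficients must not exceed n_mel_filters")
  structure(list(frame_length = frame_length, frame_hop = frame_hop,
                 pre_emphasis = pre_emphasis,
                 n_mel_filters = as.integer(n_mel_filters),
                 n_coefficients = as.integer(n_coefficients),
                 fft_length = fft_length, mel_range = mel_range),
            class = "mfcc_config")
}

#' Hz to mel and back
#'
#' The perceptual mel frequency warp, `mel(f) = 2595 log10(1 + f/700)`.
#'
#' @param f Frequency in Hz.
#' @param m Frequency in mel.
#' @return Frequency in mel (`hz_to_mel`) or Hz (`mel_to_hz`).
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# effective FFT length for a config at a given rate
fft_length_for <- function(config, sampling_rate) {
  L <- round(config$frame_length * sampling_rate)
  config$fft_length %||% 2^ceiling(log2(L))
}

#' Slice a signal into pre-emphasized, Hamming-windowed frames
#'
#' Applies pre-emphasis (`y[1] = x[1]`, `y[n] = x[n] - a x[n-1]`), slices
#' frames of `frame_length` every `frame_hop` (the last partial frame is
#' dropped), and multiplies each frame by a Hamming window.
#'
#' @param x Numeric sample vector (at least one frame long).
#' @param sampling_rate Sampling rate in Hz.
#' @param config An [mfcc_config()].
#' @return Matrix with one row per frame.
#' @export
frame_signal <- function(x, sampling_rate, config = mfcc_config()) {
  L <- round(config$frame_length * sampling_rate)
  hop <- round(config$frame_hop * sampling_rate)
  if (length(x) < L)
    stop(sprintf("segment of %d samples shorter than one frame (%d samples)",
                 length(x), L))
  y <- x - config$pre_emphasis * c(0, x[-length(x)])
  y[1] <- x[1]
  n_frames <- (length(x) - L) %/% hop + 1L
  idx <- outer(seq_len(n_frames) - 1L, seq_len(L) - 1L,
               function(f, s) f * hop + s + 1L)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  frames <- matrix(y[idx], nrow = n_frames)
  sweep(frames, 2L, w, `*`)
}

#' Triangular mel filterbank matrix
#'
#' Filter centers are equally spaced on the mel scale over `mel_range`;
#' adjacent triangles overlap at half height (each filter rises from the
#' previous center to its own and falls to the next).
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param config An [mfcc_config()].
#' @return Matrix of size `n_mel_filters` x `fft_length/2 + 1` with
#'   non-negative weights; attribute `"fft_length"` records the FFT size.
#' @export
mel_filterbank <- function(sampling_rate, config = mfcc_config()) {
  nfft <- fft_length_for(config, sampling_rate)
  nbins <- nfft %/% 2L + 1L
  rng <- config$mel_range %||% c(0, sampling_rate / 2)
  if (rng[1] < 0 || rng[2] > sampling_rate / 2 + 1e-9)
    stop("mel_range must lie within [0, sampling_rate/2]")
  M <- config$n_mel_filters
  if (M > nbins - 2L)
    stop(sprintf("%d mel filters need more than the %d FFT bins available",
                 M, nbins))
  pts <- mel_to_hz(seq(hz_to_mel(rng[1]), hz_to_mel(rng[2]),
                       length.out = M + 2L))
  binf <- (seq_len(nbins) - 1L) * sampling_rate / nfft
  fb <- matrix(0, M, nbins)
  for (m in seq_len(M)) {
    lo <- pts[m]; c0 <- pts[m + 1L]; hi <- pts[m + 2L]
    up <- (binf - lo) / (c0 - lo)
    down <- (hi - binf) / (hi - c0)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  structure(fb, fft_length = nfft, sampling_rate = sampling_rate)
}

# orthonormal DCT-II matrix, D x M (first D rows)
dct_matrix <- function(D, M) {
  k <- seq_len(D) - 1L
  m <- seq_len(M) - 1L
  C <- sqrt(2 / M) * cos(outer(k, 2 * m + 1) * pi / (2 * M))
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

#' MFCCs of windowed frames
#'
#' For each already-windowed frame: one-sided magnitude-squared spectrum by
#' FFT (zero-padded to the configured FFT length), mel filterbank energies,
#' natural log with a floor at `1e-12` times the frame's largest filter
#' energy (absolute floor `1e-30` for silent frames), then an orthonormal
#' type-II DCT over the log energies, keeping the first D coefficients.
#'
#' `mfcc_frame()` transforms a single frame vector; `mfcc_frames()` a
#' matrix with one frame per row.
#'
#' @param frame A single windowed frame (numeric vector).
#' @param frames Matrix of windowed frames (one per row), as produced by
#'   [frame_signal()].
#' @param filterbank Matrix from [mel_filterbank()].
#' @param config An [mfcc_config()].
#' @return `mfcc_frame()`: numeric vector of length D. `mfcc_frames()`:
#'   N x D matrix.
#' @export
mfcc_frame <- function(frame, filterbank, config = mfcc_config()) {
  drop(mfcc_frames(matrix(frame, nrow = 1L), filterbank, config))
}

#' @rdname mfcc_frame
#' @export
mfcc_frames <- function(frames, filterbank, config = mfcc_config()) {
  nfft <- attr(filterbank, "fft_length")
  nbins <- nfft %/% 2L + 1L
  padded <- matrix(0, nrow(frames), nfft)
  padded[, seq_len(ncol(frames))] <- frames
  spec <- Mod(stats::mvfft(t(padded)))^2          # nfft x N
  power <- spec[seq_len(nbins), , drop = FALSE]   # one-sided
  energies <- filterbank %*% power                # M x N
  floors <- pmax(1e-12 * apply(energies, 2L, max), 1e-30)
  logE <- log(pmax(energies, rep(floors, each = nrow(energies))))
  C <- dct_matrix(config$n_coefficients, config$n_mel_filters)
  t(C %*% logE)                                   # N x D
}

#' Build a subject's MFCC feature matrix from S2 segments
#'
#' Frames every S2 segment, extracts MFCCs, and stacks them into the N x D
#' feature matrix used for training and scoring (N frames over all
#' segments, in temporal order), with per-row provenance.
#'
#' @param segments An `s2_segments` object from [extract_s2_segments()].
#' @param config An [mfcc_config()].
#' @return An object of class `mfcc_matrix`: list with `values` (N x D
#'   matrix), `info` (data.frame: subject_id, segment, frame), `config`,
#'   and `fingerprint` (hash of the configuration, embedded in all derived
#'   artifacts so differently-configured features cannot be mixed).
#' @export
subject_features <- function(segments, config = mfcc_config()) {
  stopifnot(inherits(segments, "s2_segments"))
  fs <- segments$sampling_rate
  fb <- mel_filterbank(fs, config)
  per_seg <- lapply(seq_len(ncol(segments$segments)), function(j) {
    fr <- frame_signal(segments$segments[, j], fs, config)
    cbind(segment = j, frame = seq_len(nrow(fr)),
          mfcc_frames(fr, fb, config))
  })
  all <- do.call(rbind, per_seg)
  values <- all[, -(1:2), drop = FALSE]
  colnames(values) <- paste0("c", seq_len(ncol(values)) - 1L)
  if (any(!is.finite(values))) stop("non-finite MFCC values")
  structure(list(
    values = values,
    info = data.frame(subject_id = segments$subject_id,
                      segment = all[, 1L], frame = all[, 2L]),
    config = config,
    fingerprint = mfcc_fingerprint(config, fs)),
    class = "mfcc_matrix")
}

mfcc_fingerprint <- function(config, sampling_rate) {
  settings_fingerprint(c(unclass(config),
                         list(sampling_rate = sampling_rate)))
}

#' Row-bind feature matrices into a class training matrix
#'
#' @param ... `mfcc_matrix` objects (or a single list of them).
#' @return An `mfcc_matrix` with rows concatenated in argument order.
#' @export
bind_features <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "mfcc_matrix")) xs <- xs[[1L]]
  stopifnot(all(vapply(xs, inherits, TRUE, "mfcc_matrix")))
  fps <- unique(vapply(xs, `[[`, "", "fingerprint"))
  if (length(fps) > 1L)
    stop("cannot mix feature matrices with different MFCC configurations")
  structure(list(values = do.call(rbind, lapply(xs, `[[`, "values")),
                 info = do.call(rbind, lapply(xs, `[[`, "info")),
                 config = xs[[1L]]$config,
                 fingerprint = fps),
            class = "mfcc_matrix")
}

#' @export
print.mfcc_matrix <- function(x, ...) {
  cat(sprintf("<mfcc_matrix> %d frames x %d coefficients (%d subject(s), config %s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$info$subject_id)), x$fingerprint))
  invisible(x)
}

#' Round-trip feature matrices to TSV
#'
#' Writes subject_id, segment, frame and c0..c(D-1) columns, with the
#' configuration fingerprint in a header comment so mismatched features are
#' refused on read.
#'
#' @param x An `mfcc_matrix`.
#' @param path File path.
#' @param config The [mfcc_config()] expected on read (fingerprint check
#'   uses the stored hash).
#' @return `write_features()`: `path` invisibly; `read_features()`: an
#'   `mfcc_matrix`.
#' @export
write_features <- function(x, path) {
  stopifnot(inherits(x, "mfcc_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# phonoPH mfcc fingerprint=%s", x$fingerprint), con)
  df <- cbind(x$info, as.data.frame(x$values))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path, config = mfcc_config()) {
  header <- readLines(path, n = 1L)
  fp <- sub(".*fingerprint=", "", header)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  values <- as.matrix(df[, grep("^c[0-9]+$", names(df)), drop = FALSE])
  structure(list(values = values,
                 info = df[, c("subject_id", "segment", "frame")],
                 config = config, fingerprint = fp),
            class = "mfcc_matrix")
}
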