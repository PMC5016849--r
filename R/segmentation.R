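#' Detect R waves on a single-lead ECG
#'
#' A Pan-Tompkins-style detector: band-pass 5--25 Hz, differentiate, square,
#' integrate over a 150 ms moving window, threshold at a configurable
#' multiple of the running median of the integrated signal, then refine each
#' detection to the local energy peak of the band-passed ECG. Consecutive
#' detections are forced at least `refractory` seconds apart.
#'
#' @param ecg Numeric ECG sample vector.
#' @param sampling_rate Sampling rate in Hz (>= 200).
#' @param threshold_mult Threshold as a multiple of the running median of
#'   the integrated detection function (default 4).
#' @param refractory Minimum spacing between detections in seconds
#'   (default 0.2).
#' @return Strictly increasing numeric vector of R times in seconds from
#'   the start of the recording.
#' @export
detect_r_waves <- function(ecg, sampling_rate, threshold_mult = 4,
                           refractory = 0.2) {
  fs <- sampling_rate
  stopifnot(fs >= 200)
  if (length(ecg) < 2 * fs) stop("recording must be at least 2 s long")
  bp <- signal::filtfilt(signal::butter(2, c(5, 25) / (fs / 2), "pass"), ecg)
  det <- moving_average(c(diff(bp), 0)^2, round(0.150 * fs))
  # running median of the detection function over a 2.5 s window, computed
  # on a 10x-decimated copy (det is already smooth at that scale)
  dec <- det[seq(1L, length(det), by = 10L)]
  k <- min(length(dec), round(0.25 * fs))
  if (k %% 2 == 0) k <- k - 1L
  rmed <- rep(stats::runmed(dec, k), each = 10L)[seq_along(det)]
  thr <- threshold_mult * rmed + 1e-4 * max(det)
  above <- det > thr
  if (!any(above)) stop("insufficient cycles: no R waves detected")
  # contiguous above-threshold regions -> candidate peaks
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L); ends <- which(d == -1L) - 1L
  cand <- mapply(function(s, e) s + which.max(det[s:e]) - 1L, starts, ends)
  amp <- det[cand]
  # amplitude gate: candidate peaks far below the typical QRS peak are
  # low-frequency leakage (e.g. T waves); the upper quantile tracks the QRS
  # amplitude even when leaked peaks outnumber true ones
  gate <- amp >= 0.2 * stats::quantile(amp, 0.8)
  cand <- cand[gate]; amp <- amp[gate]
  # enforce refractory period, keeping the stronger of clashing candidates
  keep <- logical(length(cand))
  for (i in order(amp, decreasing = TRUE)) {
    if (!any(abs(cand[keep] - cand[i]) < refractory * fs))
      keep[i] <- TRUE
  }
  cand <- sort(cand[keep])
  # refine: peak of 50 ms-smoothed band-passed energy within +/- 100 ms
  # (the window spans both lobes of the biphasic QRS, so the smoothed
  # energy peaks at the deflection center)
  env <- moving_average(bp^2, round(0.050 * fs))
  half <- round(0.100 * fs)
  refined <- vapply(cand, function(i) {
    lo <- max(1, i - half); hi <- min(length(env), i + half)
    lo + which.max(env[lo:hi]) - 1
  }, 0)
  r <- sort(unique(refined))
  r <- r[c(TRUE, diff(r) >= refractory * fs)]
  if (length(r) < 2) stop("insufficient cycles: fewer than 2 R waves")
  (r - 1) / fs
}

#' Detect T waves given R times
#'
#' For each complete RR interval the ECG is low-passed at 10 Hz and the T
#' time is the maximum of the filtered signal in the physiological search
#' window (r + 0.12 s, r + 0.55 * RR), which avoids the QRS complex and the
#' next cycle. Exactly one T is emitted per complete RR interval; the
#' incomplete cycle after the final R gets none.
#'
#' @param ecg Numeric ECG sample vector.
#' @param r_times R times in seconds, from [detect_r_waves()].
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric vector of T times (length `length(r_times) - 1`).
#' @export
detect_t_waves <- function(ecg, r_times, sampling_rate) {
  fs <- sampling_rate
  if (length(r_times) < 2) stop("need at least 2 R times")
  lp <- signal::filtfilt(signal::butter(2, 10 / (fs / 2), "low"), ecg)
  vapply(seq_len(length(r_times) - 1L), function(i) {
    rr <- r_times[i + 1L] - r_times[i]
    lo <- max(1L, round((r_times[i] + 0.12) * fs) + 1L)
    hi <- min(length(lp), round((r_times[i] + 0.55 * rr) * fs) + 1L)
    (lo + which.max(lp[lo:hi]) - 2L) / fs
  }, 0)
}

#' Extract fixed-length S2 segments from a PCG
#'
#' For every complete cardiac cycle, an S2 search window covering
#' `window_frac` (default 30 percent) of the cycle is centered on the T
#' wave. The S2 center is located as the maximum of the PCG's short-time
#' energy (20 ms moving average of the squared 25--150 Hz band-passed
#' signal) inside that window, and a snippet of `s2_segment_duration`
#' seconds centered on it is extracted. Cycles whose snippet would overrun
#' the recording are dropped and counted.
#'
#' @param recording A `pcg_recording`, or a numeric PCG vector (then
#'   `sampling_rate` must be given).
#' @param r_times,t_times Detected R and T times in seconds; when `NULL`
#'   they are detected from `recording$ecg`.
#' @param s2_segment_duration Length of each emitted snippet in seconds
#'   (default 0.100, giving 9 analysis frames at 20 ms / 10 ms framing).
#' @param window_frac Fraction of the cycle covered by the S2 search window
#'   (default 0.30; at 72 bpm this is the classic 0.25 s window).
#' @param sampling_rate Required when `recording` is a bare numeric vector.
#' @return An object of class `s2_segments`: list with `segments` (matrix,
#'   one column per retained cycle), `annotations` (per-cycle data.frame
#'   with r_time, t_time, cycle_length, win_start, win_end, s2_center),
#'   `sampling_rate`, `subject_id`, and `n_dropped`.
#' @export
extract_s2_segments <- function(recording, r_times = NULL, t_times = NULL,
                                s2_segment_duration = 0.100,
                                window_frac = 0.30, sampling_rate = NULL) {
  if (inherits(recording, "pcg_recording")) {
    pcg <- recording$pcg
    fs <- recording$sampling_rate
    sid <- recording$subject_id
    if (is.null(r_times)) r_times <- detect_r_waves(recording$ecg, fs)
    if (is.null(t_times)) t_times <- detect_t_waves(recording$ecg, r_times, fs)
  } else {
    pcg <- recording
    fs <- sampling_rate
    sid <- NA_character_
    if (is.null(fs)) stop("sampling_rate required for a bare signal")
    if (is.null(r_times) || is.null(t_times))
      stop("r_times and t_times required for a bare signal")
  }
  if (length(t_times) < 1) stop("no S2 segments: no complete cycle with a T")
  energy <- s2_energy(pcg, fs)
  n <- length(pcg)
  seg_len <- round(s2_segment_duration * fs)
  half <- seg_len %/% 2L
  rows <- list(); segs <- list(); dropped <- 0L
  for (i in seq_along(t_times)) {
    rr <- r_times[i + 1L] - r_times[i]
    w0 <- max(0, t_times[i] - window_frac / 2 * rr)
    w1 <- min(n / fs, t_times[i] + window_frac / 2 * rr)
    lo <- round(w0 * fs) + 1L; hi <- min(n, round(w1 * fs))
    center_idx <- lo + which.max(energy[lo:hi]) - 1L
    s0 <- center_idx - half; s1 <- s0 + seg_len - 1L
    if (s0 < 1L || s1 > n) { dropped <- dropped + 1L; next }
    segs[[length(segs) + 1L]] <- pcg[s0:s1]
    rows[[length(rows) + 1L]] <- data.frame(
      r_time = r_times[i], t_time = t_times[i], cycle_length = rr,
      win_start = w0, win_end = w1, s2_center = (center_idx - 1L) / fs)
  }
  if (dropped > 0)
    message(sprintf("dropped %d cycle(s) whose S2 snippet overran the recording",
                    dropped))
  if (length(segs) == 0) stop("no S2 segments: all cycles dropped")
  structure(list(subject_id = sid,
                 segments = do.call(cbind, segs),
                 annotations = do.call(rbind, rows),
                 sampling_rate = fs,
                 segment_duration = s2_segment_duration,
                 n_dropped = dropped),
            class = "s2_segments")
}

# short-time energy: 20 ms moving average of squared 25-150 Hz band-passed PCG
s2_energy <- function(pcg, fs) {
  hi <- min(150, 0.45 * fs)
  bp <- signal::filtfilt(signal::butter(2, c(25, hi) / (fs / 2), "pass"), pcg)
  moving_average(bp^2, round(0.020 * fs))
}

#' @export
print.s2_segments <- function(x, ...) {
  cat(sprintf("<s2_segments> subject %s: %d segments of %.0f ms @ %g Hz (%d dropped)\n",
              x$subject_id, ncol(x$segments), 1000 * x$segment_duration,
              x$sampling_rate, x$n_dropped))
  invisible(x)
}

#' Write S2 windows as a BED-like TSV for inspection
#'
#' @param x An `s2_segments` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_s2_intervals <- function(x, path) {
  stopifnot(inherits(x, "s2_segments"))
  df <- data.frame(subject_id = x$subject_id,
                   start_s = x$annotations$win_start,
                   end_s = x$annotations$win_end,
                   s2_center_s = x$annotations$s2_center)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
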