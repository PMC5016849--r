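#' Configuration for a synthetic PCG+ECG cohort
#'
#' Defines the study conditions emulated by the simulator: cohort sizes, the
#' virtual mean pulmonary artery pressure (mPAp) ranges of the two diagnostic
#' classes, and the monotone acoustic maps that translate mPAp into the two
#' features that distinguish pulmonary hypertension (PH) on auscultation --
#' a widened interval between the aortic (A2) and pulmonary (P2) components
#' of the second heart sound, and a louder P2 relative to A2.
#'
#' PH is defined as mPAp >= 25 mmHg, so `mpap_range_ph` must lie at or above
#' 25 and `mpap_range_normal` strictly below it. Both acoustic maps must be
#' non-decreasing in mPAp (checked on a grid at construction).
#'
#' @param n_subjects_ph,n_subjects_normal Number of subjects per class.
#' @param sampling_rate Sampling rate in Hz. Heart sounds live below a few
#'   hundred Hz, so the default 2000 Hz is generous.
#' @param duration Recording length in seconds (default 20, the length of the
#'   clinical recordings the pipeline targets).
#' @param heart_rate_mean,heart_rate_sd Across-subject heart-rate
#'   distribution, beats per minute.
#' @param cycle_jitter_sd Within-subject lognormal standard deviation of
#'   multiplicative cycle-length jitter (0.03 = 3 percent).
#' @param mpap_range_ph,mpap_range_normal mPAp sampling intervals (mmHg) for
#'   the two classes; subject pressures are drawn uniformly.
#' @param split_map Function mPAp (mmHg) -> A2--P2 splitting interval in
#'   milliseconds; must be non-decreasing.
#' @param p2_gain_map Function mPAp (mmHg) -> P2/A2 amplitude ratio; must be
#'   non-decreasing.
#' @param noise_sd Additive Gaussian noise standard deviation, relative to
#'   the peak absolute amplitude of each clean channel.
#' @param seed Integer master seed; per-subject child seeds are derived from
#'   it so cohorts are reproducible and subjects independent.
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_subject()], [generate_cohort()]
#' @export
#' @examples
#' cfg <- synth_config(n_subjects_ph = 2, n_subjects_normal = 2, seed = 7)
#' cfg$split_map(41) > cfg$split_map(17)
synth_config <- function(n_subjects_ph = 10L,
                         n_subjects_normal = 10L,
                         sampling_rate = 2000,
                         duration = 20,
                         heart_rate_mean = 70,
                         heart_rate_sd = 10,
                         cycle_jitter_sd = 0.03,
                         mpap_range_ph = c(28, 54),
                         mpap_range_normal = c(10, 24),
                         split_map = default_split_map,
                         p2_gain_map = default_p2_gain_map,
                         noise_sd = 0.02,
                         seed = 1L) {
  stopifnot(n_subjects_ph >= 0, n_subjects_normal >= 0,
            sampling_rate > 0, duration > 0,
            heart_rate_mean > 0, heart_rate_sd >= 0, cycle_jitter_sd >= 0,
            noise_sd >= 0, length(mpap_range_ph) == 2,
            length(mpap_range_normal) == 2)
  if (mpap_range_ph[1] < 25)
    stop("mpap_range_ph must have lower bound >= 25 mmHg (PH definition)")
  if (mpap_range_normal[2] >= 25)
    stop("mpap_range_normal must have upper bound < 25 mmHg")
  grid <- seq(5, 80, by = 2.5)
  if (any(diff(vapply(grid, split_map, 0)) < 0))
    stop("split_map must be non-decreasing in mPAp")
  if (any(diff(vapply(grid, p2_gain_map, 0)) < 0))
    stop("p2_gain_map must be non-decreasing in mPAp")
  structure(list(
    n_subjects_ph = as.integer(n_subjects_ph),
    n_subjects_normal = as.integer(n_subjects_normal),
    sampling_rate = sampling_rate, duration = duration,
    heart_rate_mean = heart_rate_mean, heart_rate_sd = heart_rate_sd,
    cycle_jitter_sd = cycle_jitter_sd,
    mpap_range_ph = mpap_range_ph, mpap_range_normal = mpap_range_normal,
    split_map = split_map, p2_gain_map = p2_gain_map,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Default mPAp to A2--P2 split map
#'
#' Linear from 20 ms at 15 mmHg to 60 ms at 60 mmHg, clamped outside that
#' range. Only monotonicity matters for the pipeline; the slope is a
#' plausible rendering of the splitting that widens with pulmonary pressure.
#'
#' @param mpap Mean pulmonary artery pressure in mmHg.
#' @return Splitting interval in milliseconds.
#' @export
default_split_map <- function(mpap) {
  20 + 40 * pmin(1, pmax(0, (mpap - 15) / 45))
}

#' Default mPAp to P2/A2 amplitude-ratio map
#'
#' Linear from 0.4 at 15 mmHg to 1.5 at 60 mmHg, clamped: P2 is softer than
#' A2 at normal pressures and overtakes it as pressure rises.
#'
#' @param mpap Mean pulmonary artery pressure in mmHg.
#' @return P2/A2 amplitude ratio (dimensionless).
#' @export
default_p2_gain_map <- function(mpap) {
  0.4 + 1.1 * pmin(1, pmax(0, (mpap - 15) / 45))
}

# Gaussian-enveloped sinusoid (a damped transient) centered at tc.
gauss_tone <- function(t, tc, sigma, freq, amp) {
  amp * exp(-(t - tc)^2 / (2 * sigma^2)) * sin(2 * pi * freq * (t - tc))
}

# Fixed morphology constants of the simulator (seconds / Hz / relative amp).
.synth_shape <- list(
  r_sigma = 0.010,            # half-width of the biphasic R deflection
  t_sigma = 0.040, t_amp = 0.35, t_frac = 0.32,  # T hump at 32% of RR
  s1_delay = 0.055, s1_sigma = 0.010, s1_freq = 65, s1_amp = 0.7,
  a2_sigma = 0.008, a2_freq = 50, a2_amp = 1.0,
  p2_sigma = 0.008, p2_freq = 45,
  tail_frac = 0.45            # cycle sound events fit within r + tail_frac*RR
)

#' Generate one synthetic subject recording
#'
#' Builds a quasi-periodic phonocardiogram and time-locked single-lead ECG
#' for one subject. Every cardiac cycle contains: a sharp biphasic R
#' deflection and a smooth T hump on the ECG; an S1 burst shortly after R on
#' the PCG; and an S2 composed of two Gaussian-enveloped damped sinusoids
#' (A2 then P2) whose separation is `config$split_map(mpap)` and whose
#' amplitude ratio is `config$p2_gain_map(mpap)`. Gaussian noise is added at
#' `config$noise_sd` relative to each clean channel's peak amplitude.
#'
#' Ground-truth annotations (R time, T time, S1 onset, S2 center, cycle
#' length) are recorded per cycle; the S2 center is the time of maximum
#' 20 ms short-time energy of the clean PCG inside the S2 region, i.e.
#' exactly the quantity the segmentation stage estimates.
#'
#' @param config A [synth_config()].
#' @param mpap Virtual mean pulmonary artery pressure in mmHg (> 0).
#' @param subject_id Subject identifier string.
#' @param rng_state Integer seed; the same seed reproduces the recording
#'   bit for bit.
#' @return An object of class `pcg_recording`: list with `pcg`, `ecg`
#'   (equal-length numeric vectors), `sampling_rate`, `duration`, `mpap`,
#'   `label` ("PH" iff mpap >= 25), and `annotations` (one row per cycle).
#' @export
#' @examples
#' cfg <- synth_config(heart_rate_sd = 0, cycle_jitter_sd = 0, noise_sd = 0,
#'                     heart_rate_mean = 60)
#' rec <- generate_subject(cfg, mpap = 41, subject_id = "demo", rng_state = 1)
#' nrow(rec$annotations)  # 20 cycles in 20 s at 60 bpm
generate_subject <- function(config, mpap, subject_id, rng_state = 1L) {
  stopifnot(inherits(config, "synth_config"), mpap > 0)
  sh <- .synth_shape
  fs <- config$sampling_rate
  dur <- config$duration
  with_seed(rng_state, {
    hr <- min(140, max(40, stats::rnorm(1, config$heart_rate_mean,
                                        config$heart_rate_sd)))
    rr0 <- 60 / hr
    # minimum duration: one full cycle's sounds starting at 0.25*RR
    min_dur <- (0.25 + sh$tail_frac) * rr0
    if (dur < min_dur)
      stop(sprintf(
        "duration %.2f s too short for one cardiac cycle at %.0f bpm; minimum %.2f s",
        dur, hr, min_dur))
    # cycle grid with multiplicative lognormal jitter
    r_times <- numeric(0); rr_list <- numeric(0)
    r <- 0.25 * rr0
    repeat {
      rr <- rr0 * exp(stats::rnorm(1, 0, config$cycle_jitter_sd))
      if (r + sh$tail_frac * rr > dur + 1e-9) break
      r_times <- c(r_times, r); rr_list <- c(rr_list, rr)
      r <- r + rr
    }
    if (length(r_times) == 0)
      stop(sprintf("duration %.2f s too short for one cardiac cycle; minimum %.2f s",
                   dur, min_dur))
    n <- round(dur * fs)
    t <- (seq_len(n) - 1) / fs
    ecg <- numeric(n); pcg <- numeric(n)
    split_s <- config$split_map(mpap) / 1000
    p2_amp <- sh$a2_amp * config$p2_gain_map(mpap)
    ann <- data.frame(r_time = r_times, cycle_length = rr_list,
                      t_time = NA_real_, s1_onset = NA_real_,
                      s2_center = NA_real_)
    for (i in seq_along(r_times)) {
      r_i <- r_times[i]; rr <- rr_list[i]
      # ECG: biphasic R (derivative-of-Gaussian, unit peak), Gaussian T hump
      u <- (t - r_i) / sh$r_sigma
      ecg <- ecg + u * exp(0.5 - u^2 / 2)
      t_i <- r_i + sh$t_frac * rr
      ecg <- ecg + sh$t_amp * exp(-(t - t_i)^2 / (2 * sh$t_sigma^2))
      # PCG: S1 then A2 + P2
      s1_c <- r_i + sh$s1_delay
      pcg <- pcg + gauss_tone(t, s1_c, sh$s1_sigma, sh$s1_freq, sh$s1_amp)
      a2_c <- t_i
      p2_c <- a2_c + split_s
      pcg <- pcg + gauss_tone(t, a2_c, sh$a2_sigma, sh$a2_freq, sh$a2_amp) +
        gauss_tone(t, p2_c, sh$p2_sigma, sh$p2_freq, p2_amp)
      ann$t_time[i] <- t_i
      ann$s1_onset[i] <- s1_c - 2 * sh$s1_sigma
      ann$s2_center[i] <- c(a2_c, p2_c)[which.max(c(sh$a2_amp, p2_amp))]
    }
    # refine the S2-center annotation to the clean-signal short-time energy
    # peak inside the S2 region, using the same energy operator the
    # segmentation stage applies, so truth is the noise-free value of the
    # quantity that stage estimates
    energy <- s2_energy(pcg, fs)
    for (i in seq_along(r_times)) {
      lo <- max(1L, round((ann$t_time[i] - 0.05) * fs) + 1L)
      hi <- min(n, round((ann$t_time[i] + split_s + 0.05) * fs) + 1L)
      ann$s2_center[i] <- (lo + which.max(energy[lo:hi]) - 2L) / fs
    }
    if (config$noise_sd > 0) {
      pcg <- pcg + stats::rnorm(n, 0, config$noise_sd * max(abs(pcg)))
      ecg <- ecg + stats::rnorm(n, 0, config$noise_sd * max(abs(ecg)))
    }
    structure(list(subject_id = subject_id, pcg = pcg, ecg = ecg,
                   sampling_rate = fs, duration = dur, mpap = mpap,
                   label = if (mpap >= 25) "PH" else "non-PH",
                   heart_rate = hr, annotations = ann),
              class = "pcg_recording")
  })
}

#' Generate a full synthetic cohort
#'
#' Draws each subject's mPAp uniformly from its class interval, assigns the
#' PH label by the 25 mmHg rule, derives an independent child seed per
#' subject from `config$seed`, and generates all recordings.
#'
#' @param config A [synth_config()] with `n_subjects_ph + n_subjects_normal
#'   >= 1`.
#' @return A list of class `pcg_cohort` with `recordings` (list of
#'   [generate_subject()] outputs) and `metadata` (data.frame with
#'   subject_id, mpap, label, seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_ph <- config$n_subjects_ph; n_np <- config$n_subjects_normal
  if (n_ph + n_np < 1) stop("cohort must contain at least one subject")
  meta <- with_seed(config$seed, {
    ids <- c(sprintf("PH%03d", seq_len(n_ph)),
             sprintf("NP%03d", seq_len(n_np)))
    mpap <- c(stats::runif(n_ph, config$mpap_range_ph[1],
                           config$mpap_range_ph[2]),
              stats::runif(n_np, config$mpap_range_normal[1],
                           config$mpap_range_normal[2]))
    data.frame(subject_id = ids, mpap = mpap,
               label = ifelse(mpap >= 25, "PH", "non-PH"),
               seed = sample.int(.Machine$integer.max - 1L, n_ph + n_np),
               stringsAsFactors = FALSE)
  })
  recs <- lapply(seq_len(nrow(meta)), function(i)
    generate_subject(config, meta$mpap[i], meta$subject_id[i], meta$seed[i]))
  names(recs) <- meta$subject_id
  structure(list(recordings = recs, metadata = meta, config = config),
            class = "pcg_cohort")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> subject %s: %.1f s @ %g Hz, %d cycles\n",
              x$subject_id, x$duration, x$sampling_rate,
              nrow(x$annotations)))
  if (!is.null(x$mpap))
    cat(sprintf("  mPAp %.1f mmHg -> label %s\n", x$mpap, x$label))
  invisible(x)
}

#' @export
print.pcg_cohort <- function(x, ...) {
  tab <- table(x$metadata$label)
  cat(sprintf("<pcg_cohort> %d subjects (%s)\n", nrow(x$metadata),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Plot a recording's PCG and ECG with annotations
#'
#' @param x A `pcg_recording`.
#' @param xlim Time range in seconds (default first 5 s).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pcg_recording <- function(x, xlim = c(0, min(5, x$duration)), ...) {
  t <- (seq_along(x$pcg) - 1) / x$sampling_rate
  op <- graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(t, x$pcg, type = "l", xlim = xlim, xlab = "time (s)",
                 ylab = "PCG", main = x$subject_id, ...)
  graphics::abline(v = x$annotations$s2_center, col = "red", lty = 3)
  graphics::plot(t, x$ecg, type = "l", xlim = xlim, xlab = "time (s)",
                 ylab = "ECG", ...)
  graphics::points(x$annotations$r_time,
                   rep(max(x$ecg), nrow(x$annotations)), pch = 1, col = "blue")
  graphics::points(x$annotations$t_time,
                   rep(max(x$ecg), nrow(x$annotations)), pch = 4, col = "red")
  invisible(x)
}
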