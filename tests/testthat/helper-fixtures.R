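# Shared small fixtures, built once per test run.

# A clean, metronome-regular subject: 60 bpm, no jitter, no noise.
clean_config <- function(...) {
  args <- utils::modifyList(list(heart_rate_mean = 60, heart_rate_sd = 0,
                                 cycle_jitter_sd = 0, noise_sd = 0),
                            list(...))
  do.call(synth_config, args)
}

clean_subject <- function(mpap = 41, seed = 1, ...) {
  generate_subject(clean_config(...), mpap = mpap,
                   subject_id = sprintf("clean%02d", seed), rng_state = seed)
}

# Small realistic cohort reused by evaluation and IO tests.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_subjects_ph = 6, n_subjects_normal = 6,
                          seed = 42)
      co <- generate_cohort(cfg)
      cache <<- list(cohort = co,
                     features = lapply(co$recordings, subject_pipeline),
                     labels = co$metadata$label,
                     mpap = co$metadata$mpap)
    }
    cache
  }
})

# Estimate the A2-P2 split (s) and P2/A2 envelope ratio from a clean
# waveform: the dominant local maximum of the 10 ms-smoothed squared PCG in
# each annotated S2 region, plus the strongest peak at least 12 ms away
# (10 ms smoothing removes the 2f carrier ripple of the squared tones).
measure_s2_components <- function(rec) {
  fs <- rec$sampling_rate
  env <- phonoPH:::moving_average(rec$pcg^2, round(0.010 * fs))
  out <- t(vapply(seq_len(nrow(rec$annotations)), function(i) {
    tt <- rec$annotations$t_time[i]
    lo <- round((tt - 0.03) * fs); hi <- min(length(env), round((tt + 0.12) * fs))
    e <- env[lo:hi]
    pk <- which(diff(sign(diff(e))) == -2) + 1
    if (length(pk) < 2) return(c(NA, NA))
    p1 <- pk[which.max(e[pk])]
    rest <- pk[abs(pk - p1) >= 0.012 * fs]
    if (length(rest) < 1) return(c(NA, NA))
    p2 <- rest[which.max(e[rest])]
    early <- min(p1, p2); late <- max(p1, p2)
    c(split = (late - early) / fs, ratio = sqrt(e[late] / e[early]))
  }, c(0, 0)))
  colMeans(out, na.rm = TRUE)
}
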