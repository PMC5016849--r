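test_that("R waves are recovered exactly on a clean regular ECG", {
  rec <- clean_subject(mpap = 30, seed = 1)
  r <- detect_r_waves(rec$ecg, rec$sampling_rate)
  expect_length(r, 20)
  expect_true(all(diff(r) >= 0.2))
  err <- vapply(rec$annotations$r_time, function(t) min(abs(r - t)), 0)
  expect_lt(max(err), 0.010)
})

test_that("a flat ECG yields the insufficient-cycles error", {
  expect_error(detect_r_waves(rep(0, 8000), 2000), "insufficient cycles")
})

test_that("R detection survives 10% additive noise (Monte Carlo)", {
  cfg <- synth_config(noise_sd = 0.10)
  hits <- 0; total <- 0
  for (s in 1:20) {
    rec <- generate_subject(cfg, mpap = 20 + 2 * s, subject_id = "n",
                            rng_state = 1000 + s)
    r <- detect_r_waves(rec$ecg, rec$sampling_rate)
    err <- vapply(rec$annotations$r_time, function(t) min(abs(r - t)), 0)
    hits <- hits + sum(err <= 0.020)
    total <- total + length(err)
  }
  expect_gte(hits / total, 0.95)
})

test_that("T waves land on the annotated T peak, one per complete cycle", {
  rec <- clean_subject(mpap = 35, seed = 2)
  r <- detect_r_waves(rec$ecg, rec$sampling_rate)
  tt <- detect_t_waves(rec$ecg, r, rec$sampling_rate)
  expect_length(tt, length(r) - 1)  # no T for the incomplete final cycle
  err <- abs(tt - rec$annotations$t_time[seq_along(tt)])
  expect_lt(max(err), 0.015)
  expect_true(all(tt > r[-length(r)] & tt < r[-1]))

  # a recording trimmed to a single complete cycle yields exactly one T
  fs <- rec$sampling_rate
  two <- rec$ecg[1:round(2.2 * fs)]
  r2 <- r[r < 2.0][1:2]
  expect_length(detect_t_waves(two, r2, fs), 1)
})

test_that("the S2 window covers 30% of the cycle around the T wave", {
  rec <- clean_subject(mpap = 30, seed = 3)
  segs <- extract_s2_segments(rec)
  ann <- segs$annotations
  expect_equal(ann$win_end - ann$win_start, 0.30 * ann$cycle_length,
               tolerance = 1 / rec$sampling_rate)
  expect_true(all(ann$t_time >= ann$win_start & ann$t_time < ann$win_end))
  expect_true(all(ann$s2_center >= ann$win_start &
                    ann$s2_center < ann$win_end))
})

test_that("at 72 bpm the S2 window is the classic quarter second", {
  cfg <- clean_config(heart_rate_mean = 72)
  rec <- generate_subject(cfg, 30, "b72", 4)
  segs <- extract_s2_segments(rec)
  expect_equal(mean(segs$annotations$win_end - segs$annotations$win_start),
               0.25, tolerance = 0.005)
})

test_that("clean S2 centers match the ground truth annotations", {
  for (mpap in c(17, 41)) {
    rec <- clean_subject(mpap = mpap, seed = 5)
    segs <- extract_s2_segments(rec)
    err <- vapply(segs$annotations$s2_center,
                  function(t) min(abs(rec$annotations$s2_center - t)), 0)
    expect_lt(max(err), 0.020)
  }
})

test_that("an impulse train at the true S2 centers is localized exactly", {
  rec <- clean_subject(mpap = 30, seed = 6)
  fs <- rec$sampling_rate
  impulse <- numeric(length(rec$pcg))
  impulse[round(rec$annotations$s2_center * fs) + 1] <- 1
  segs <- extract_s2_segments(impulse,
                              r_times = rec$annotations$r_time,
                              t_times = rec$annotations$t_time[-nrow(rec$annotations)],
                              sampling_rate = fs)
  err <- vapply(segs$annotations$s2_center,
                function(t) min(abs(rec$annotations$s2_center - t)), 0)
  # band-pass + 20 ms energy smoothing keeps the peak on the impulse sample
  expect_lt(max(err), 1.5 / fs)
})

test_that("segments all share the configured length and exclude S1", {
  rec <- clean_subject(mpap = 45, seed = 7)
  segs <- extract_s2_segments(rec)
  expect_equal(nrow(segs$segments), round(0.1 * rec$sampling_rate))
  expect_lte(ncol(segs$segments), nrow(rec$annotations) - 1)
  # S1 bursts (shortly after R) lie outside every S2 window
  s1 <- rec$annotations$s1_onset
  for (i in seq_len(nrow(segs$annotations)))
    expect_false(any(s1 >= segs$annotations$win_start[i] &
                       s1 < segs$annotations$win_end[i]))
})

test_that("delaying both channels shifts all detected times equally", {
  rec <- clean_subject(mpap = 30, seed = 8, duration = 12)
  fs <- rec$sampling_rate
  delay <- 0.25
  pad <- numeric(round(delay * fs))
  ecg2 <- c(pad, rec$ecg)
  r1 <- detect_r_waves(rec$ecg, fs)
  r2 <- detect_r_waves(ecg2, fs)
  expect_length(r2, length(r1))
  expect_equal(r2, r1 + delay, tolerance = 1.01 / fs)
  t1 <- detect_t_waves(rec$ecg, r1, fs)
  t2 <- detect_t_waves(ecg2, r2, fs)
  expect_equal(t2, t1 + delay, tolerance = 1.01 / fs)
})

test_that("dropped overrunning snippets are counted and reported", {
  rec <- clean_subject(mpap = 30, seed = 9)
  fs <- rec$sampling_rate
  ann <- rec$annotations
  n_t <- nrow(ann) - 1
  # truncate the PCG just after the last complete cycle's S2 center, so its
  # snippet overruns the recording end
  pcg <- rec$pcg[1:round((ann$s2_center[n_t] + 0.02) * fs)]
  expect_message(
    segs <- extract_s2_segments(pcg, r_times = ann$r_time,
                                t_times = ann$t_time[seq_len(n_t)],
                                sampling_rate = fs),
    "dropped")
  expect_gte(segs$n_dropped, 1)
})
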