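test_that("beat segmentation recovers the generator's ground-truth timings", {
  h <- fix_state()
  wf <- generate_beat_waveforms(h, rate = 1000, n_beats = 8)
  w <- segment_beats(wf$rv_pressure)
  expect_length(w, 8)
  t_es <- vapply(w, `[[`, numeric(1), "t_es")
  t_start <- vapply(w, `[[`, numeric(1), "t_start")
  T_true <- wf$truth$t_es - wf$truth$t_start
  # each ejection period within one sample of the generator's truth
  expect_lt(max(abs((t_es - t_start) - T_true)), 1 / 1000 + 1e-12)
  expect_lt(max(abs(t_es - wf$truth$t_es)), 2 / 1000)
  for (bw in w) {
    expect_true(bw$t_start < bw$t_es && bw$t_es < bw$t_ed)
  }
})

test_that("segmentation is invariant to a constant pressure offset", {
  wf <- generate_beat_waveforms(fix_state(), rate = 1000, n_beats = 8)
  w0 <- segment_beats(wf$rv_pressure)
  shifted <- pressure_trace(wf$rv_pressure$samples + 25, 1000, "RV_pressure")
  w1 <- segment_beats(shifted)
  expect_equal(
    vapply(w0, `[[`, numeric(1), "t_es"),
    vapply(w1, `[[`, numeric(1), "t_es"))
})

test_that("segmentation is rate-invariant within one coarse sample", {
  h <- fix_state()
  wf_hi <- generate_beat_waveforms(h, rate = 1000, n_beats = 8)
  wf_lo <- generate_beat_waveforms(h, rate = 250, n_beats = 8)
  es_hi <- vapply(segment_beats(wf_hi$rv_pressure), `[[`, numeric(1), "t_es")
  es_lo <- vapply(segment_beats(wf_lo$rv_pressure), `[[`, numeric(1), "t_es")
  expect_lt(max(abs(es_hi - es_lo)), 1 / 250 + 1e-12)
})

test_that("degenerate traces are rejected", {
  expect_error(segment_beats(pressure_trace(rep(40, 2000), 1000, "RV_pressure")),
               "insufficient data")
  expect_error(pressure_trace(c(1, NA, 3), 1000), "non-finite")
  wf <- generate_beat_waveforms(fix_state(), rate = 1000, n_beats = 3)
  expect_error(segment_beats(wf$rv_pressure), "insufficient data")
  expect_error(segment_beats(wf$pa_pressure), "RV_pressure")
})

test_that("ensemble averaging is exact for identical beats and mean-correct", {
  wf <- generate_beat_waveforms(fix_state(), rate = 1000, n_beats = 8)
  w <- segment_beats(wf$rv_pressure)
  avg <- ensemble_average(wf$rv_pressure, w, n_beats = 5)
  one <- ensemble_average(wf$rv_pressure, w, n_beats = 1)
  expect_equal(avg$samples, one$samples, tolerance = 1e-10)
  # alternating offsets b, b+2 average to b+1
  tr <- wf$rv_pressure
  offs <- rep(c(0, 2), length.out = length(w))
  tt <- trace_times(tr)
  bumped <- tr$samples
  for (k in seq_along(w)) {
    idx <- tt >= w[[k]]$t_start & tt < w[[k]]$t_ed
    bumped[idx] <- bumped[idx] + offs[k]
  }
  avg2 <- ensemble_average(pressure_trace(bumped, tr$rate, tr$channel), w,
                           n_beats = 6)
  expect_equal(avg2$samples, one$samples + 1, tolerance = 1e-8)
  expect_error(ensemble_average(tr, w, n_beats = 0), "n_beats")
})

test_that("averaging five noisy beats shrinks noise like 1/sqrt(5)", {
  wf <- generate_beat_waveforms(fix_state(), rate = 1000, n_beats = 8)
  w <- lapply(seq_len(nrow(wf$truth)), function(k)
    beat_window(wf$truth$t_start[k], wf$truth$t_es[k], wf$truth$t_ed[k]))
  clean <- ensemble_average(wf$rv_pressure, w, n_beats = 5)
  set.seed(11)
  rms <- replicate(200, {
    noisy <- pressure_trace(
      wf$rv_pressure$samples + rnorm(length(wf$rv_pressure$samples), 0, 1),
      1000, "RV_pressure")
    avg <- ensemble_average(noisy, w, n_beats = 5)
    sqrt(mean((avg$samples - clean$samples)^2))
  })
  expect_lt(mean(rms), 1 / sqrt(5) * 1.5)
})

test_that("mean ejection pressure matches analytic values", {
  w <- beat_window(0.1, 0.4, 0.8)
  const <- pressure_trace(rep(40, 1000), 1000, "RV_pressure")
  expect_equal(mean_ejection_pressure(const, w), 40)
  tt <- (0:999) / 1000
  ramp <- pressure_trace(ifelse(tt >= 0.1 & tt <= 0.4,
                                20 + (tt - 0.1) / 0.3 * 40, 20),
                         1000, "RV_pressure")
  expect_equal(mean_ejection_pressure(ramp, w), 40, tolerance = 1e-6)
  # raised-cosine beat: closed-form mean over the ejection window is
  # RV_EDP + amplitude * (1 + 2/pi) / 2, which the generator inverts to
  # hit mRV_EP exactly
  h <- fix_state()
  wf <- generate_beat_waveforms(h, rate = 1000, n_beats = 8)
  seg <- segment_beats(wf$rv_pressure)
  expect_equal(mean_ejection_pressure(wf$rv_pressure, seg[[1]]), h$mrv_ep,
               tolerance = 0.005)
  expect_error(mean_ejection_pressure(const, beat_window(2, 3, 4)),
               "outside")
})

test_that("mean ejection pressure is sampling-rate invariant within 1%", {
  h <- fix_state()
  m <- vapply(c(250, 1000), function(r) {
    wf <- generate_beat_waveforms(h, rate = r, n_beats = 8)
    mean_ejection_pressure(wf$rv_pressure, segment_beats(wf$rv_pressure)[[1]])
  }, numeric(1))
  expect_lt(abs(m[1] - m[2]) / m[2], 0.01)
})
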