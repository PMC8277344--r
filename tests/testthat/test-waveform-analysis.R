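sinusoid <- function(f, fps, n, phase = 0) {
  (1 + sin(2 * pi * f * (0:(n - 1)) / fps + phase)) / 2
}

test_that("estimate_f0 recovers tones through padding and interpolation", {
  # the clinical operating point: 224 Hz at 939.44 fps, 0.4 s
  s <- sinusoid(224, 939.44, 375, -pi / 2)
  expect_equal(estimate_f0(s, 939.44)$f0, 224, tolerance = 0.5)
  # on-bin tone without padding is exact
  s2 <- sin(2 * pi * 100 * (0:199) / 1000)  # bin 20 of 200 samples
  expect_equal(estimate_f0(s2, 1000, pad_factor = 1)$f0, 100)
  # low-frequency drift is rejected by the f_min guard
  t <- (0:599) / 1000
  s3 <- 3 * sin(2 * pi * 5 * t) + sin(2 * pi * 150 * t)
  expect_equal(estimate_f0(s3, 1000, f_min = 70)$f0, 150, tolerance = 0.5)
  # invariants and error cases
  sr <- estimate_f0(s, 939.44)
  expect_gte(sr$f0, sr$f_min_used)
  expect_equal(diff(sr$freq_grid[1:2]), 939.44 / (16 * 375))
  expect_error(estimate_f0(rep(1, 100), 1000), "constant")
  expect_error(estimate_f0(s[1:8], 939.44), "16 samples")
  expect_error(estimate_f0(s, 939.44, f_min = 500), "Nyquist")
})

test_that("f0 recovery is within 1 Hz across the phonation band", {
  for (f0 in seq(100, 260, by = 40)) {
    w <- simulate_gaw(glottis_sim_params(f0 = f0, fps = 939.44,
                                         duration = 0.4))
    expect_equal(estimate_f0(w$total_area, 939.44)$f0, f0, tolerance = 1)
  }
})

test_that("asymmetry index implements (A_L - A_R)/(A_L + A_R)", {
  s <- sinusoid(200, 939.44, 200)
  expect_equal(asymmetry_index(s, s), 0)
  # constant left (paralysis): A_L = 0 so AI = -1
  expect_equal(asymmetry_index(rep(0, 200), s), -1)
  # A_L = 2 A_R gives 1/3
  expect_equal(asymmetry_index(2 * s, s), 1 / 3)
  # swapping the inputs negates the index exactly
  expect_equal(asymmetry_index(0.3 * s, s), -asymmetry_index(s, 0.3 * s))
  # both flat: undefined, flagged
  ai <- asymmetry_index(rep(1, 10), rep(1, 10))
  expect_true(is.na(ai))
  expect_match(attr(ai, "flag"), "undefined")
  expect_error(asymmetry_index(s, s[-1]), "equal length")
})

test_that("closure deficit measures the mean per-cycle minimum", {
  fps <- 939.44; f0 <- 224
  # complete closure: deficit stays near zero
  s <- sinusoid(f0, fps, 375, -pi / 2); s <- s / max(s)
  expect_lte(closure_deficit(s, f0, fps), 0.05)
  # 0.2 residual gap: deficit recovers the construction
  s2 <- 0.2 + 0.8 * sinusoid(f0, fps, 375, -pi / 2); s2 <- s2 / max(s2)
  expect_lt(abs(closure_deficit(s2, f0, fps) - 0.2), 0.02)
  # constant series at 1: every window minimum is 1
  expect_equal(closure_deficit(rep(1, 100), f0, fps), 1)
  # raw (unrefined) mode never reports less than the sampled minimum
  expect_gte(closure_deficit(s2, f0, fps, refine = FALSE),
             min(s2))
  expect_error(closure_deficit(s[1:5], f0, fps), "2 complete cycles")
})

test_that("closure deficit is invariant to whole-cycle time shifts", {
  fps <- 1000; f0 <- 125  # exactly 8 frames per cycle
  s <- sinusoid(f0, fps, 400); s <- s / max(s)
  base <- closure_deficit(s[1:320], f0, fps)
  for (k in c(1, 3)) {
    shifted <- s[(k * 8 + 1):(k * 8 + 320)]
    expect_equal(closure_deficit(shifted, f0, fps), base, tolerance = 1e-9)
  }
})

test_that("lateral phase lag recovers constructed shifts", {
  fps <- 939.44
  left <- 100 + 40 * sinusoid(150, fps, 400)
  expect_equal(lateral_phase_lag(left, left), 0)
  # right delayed by 5 frames: positive lag of 5
  n <- length(left)
  right <- c(left[1:5], left[1:(n - 5)])
  expect_equal(lateral_phase_lag(left[6:n], right[6:n]), 5,
               tolerance = 0.5)
  # swap negates the lag
  expect_equal(lateral_phase_lag(right[6:n], left[6:n]), -5,
               tolerance = 0.5)
  # antiphase sinusoids with period ~12.5 frames: lag -P/2 by convention
  l2 <- sinusoid(80, 1000, 300); r2 <- sinusoid(80, 1000, 300, pi)
  expect_equal(lateral_phase_lag(l2, r2), -1000 / 80 / 2, tolerance = 0.5)
  # constant series: undefined, flagged
  pl <- lateral_phase_lag(rep(2, 50), sinusoid(80, 1000, 50))
  expect_true(is.na(pl))
  expect_match(attr(pl, "flag"), "undefined")
})

test_that("frames_per_cycle reproduces both printed capture regimes", {
  expect_identical(frames_per_cycle(940, 115), 8L)
  expect_identical(frames_per_cycle(4000, 260), 15L)
  expect_identical(frames_per_cycle(1000, 250), 4L)
  f0s <- seq(115, 260, by = 0.5)
  expect_identical(sort(unique(frames_per_cycle(940, f0s))), 3:8)
  expect_identical(sort(unique(frames_per_cycle(4000, f0s))), 15:34)
  expect_error(frames_per_cycle(940, 0), "positive")
})

test_that("build_report separates the synthetic phenotypes", {
  rep_h <- build_report(simulate_gaw(glottis_preset("healthy")))
  expect_equal(rep_h$f0_hz, 224, tolerance = 1)
  expect_lte(abs(rep_h$asymmetry_index), 0.05)
  expect_lte(rep_h$closure_deficit, 0.05)
  expect_identical(rep_h$frames_per_cycle, 4L)

  rep_p <- build_report(simulate_gaw(glottis_preset("paralysis-left")))
  expect_lte(rep_p$asymmetry_index, -0.8)
  expect_true(any(grepl("paralysis-like \\(image-left", rep_p$flags)))

  rep_l <- build_report(simulate_gaw(glottis_preset("laryngitis")))
  expect_gte(rep_l$closure_deficit, 0.1)
  expect_true(any(grepl("incomplete-closure", rep_l$flags)))
})

test_that("build_report reports a phase lag set by the generator phases", {
  # right side lags left by a quarter period = fps/(4*f0) frames
  p <- glottis_sim_params(phase_left = 0, phase_right = -pi / 2)
  rep <- build_report(simulate_gaw(p))
  expect_equal(rep$phase_lag_frames, 939.44 / (4 * 224), tolerance = 0.3)
  expect_equal(rep$phase_lag_frames,
               simulate_glottis_stack(
                 glottis_sim_params(phase_left = 0, phase_right = -pi / 2,
                                    duration = 0.01, noise_sigma = 0)
               )$truth$phase_lag_frames, tolerance = 0.3)
})

test_that("diagnostic reports serialize to the documented JSON schema", {
  rep <- build_report(simulate_gaw(glottis_preset("healthy")))
  js <- jsonlite::fromJSON(report_json(rep))
  expect_setequal(names(js),
                  c("f0_hz", "asymmetry_index", "closure_deficit",
                    "phase_lag_frames", "frames_per_cycle", "fps",
                    "settings", "flags"))
  expect_equal(js$f0_hz, rep$f0_hz)
})
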