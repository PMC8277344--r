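test_that("degenerate generator parameters are rejected", {
  expect_error(glottis_sim_params(glottis_span = c(100, 20)), "degenerate")
  expect_error(glottis_sim_params(image_height = 0), "zero-size")
  expect_error(glottis_sim_params(amp_left = -1), "amplitudes")
  expect_error(glottis_sim_params(glottis_level = 200,
                                  background_level = 100), "glottis_level")
  expect_error(glottis_sim_params(duration = 0.0005), "at least 2 frames")
})

test_that("a fully closed glottis renders zero area in every frame", {
  sim <- simulate_glottis_stack(glottis_sim_params(
    amp_left = 0, amp_right = 0, closure_left = 0, closure_right = 0,
    duration = 0.02, noise_sigma = 0))
  expect_true(all(sim$truth$areas$total_area_px == 0))
  expect_true(all(vapply(sim$stack$frames,
                         function(f) sum(f == 40), numeric(1)) == 0))
})

test_that("phase -pi/2 with zero closure starts fully closed at t = 0", {
  sim <- simulate_glottis_stack(glottis_sim_params(
    closure_left = 0, closure_right = 0, phase_left = -pi / 2,
    phase_right = -pi / 2, duration = 0.02, noise_sigma = 0))
  expect_identical(sim$truth$areas$total_area_px[1], 0L)
})

test_that("noise-free rendered dark area equals ground truth and the
           independent rasterization oracle", {
  p <- glottis_sim_params(duration = 0.01, amp_left = 11.3, amp_right = 17.8,
                          closure_left = 1.2, closure_right = 0,
                          phase_right = 0.4, noise_sigma = 0)
  sim <- simulate_glottis_stack(p)
  for (k in c(0, 3, 7)) {
    dark <- sum(sim$stack$frames[[k + 1]] == p$glottis_level)
    oracle <- glottis_area_oracle(p, k)
    expect_identical(dark, as.integer(sim$truth$areas$total_area_px[k + 1]))
    expect_identical(as.integer(oracle["left"]),
                     as.integer(sim$truth$areas$left_area_px[k + 1]))
    expect_identical(as.integer(oracle["right"]),
                     as.integer(sim$truth$areas$right_area_px[k + 1]))
  }
})

test_that("left + right equals total exactly on every frame", {
  sim <- simulate_glottis_stack(glottis_preset("polyp-right",
                                               duration = 0.05))
  a <- sim$truth$areas
  expect_identical(a$left_area_px + a$right_area_px, a$total_area_px)
})

test_that("horizontal mirror with swapped side parameters reproduces the
           stack pixel for pixel", {
  W <- 160
  p1 <- glottis_sim_params(amp_left = 5, amp_right = 15, closure_left = 2,
                           closure_right = 0, phase_left = -pi / 2,
                           phase_right = 0.7, duration = 0.02,
                           noise_sigma = 0, image_width = W,
                           polyp = list(side = "right",
                                        center = c(60, 86), radius = 5))
  p2 <- glottis_sim_params(amp_left = 15, amp_right = 5, closure_left = 0,
                           closure_right = 2, phase_left = 0.7,
                           phase_right = -pi / 2, duration = 0.02,
                           noise_sigma = 0, image_width = W,
                           midline_col = W - 80,
                           polyp = list(side = "left",
                                        center = c(60, W - 1 - 86),
                                        radius = 5))
  s1 <- simulate_glottis_stack(p1)$stack
  s2 <- simulate_glottis_stack(p2)$stack
  for (k in seq_len(n_frames(s1)))
    expect_identical(s1$frames[[k]][, W:1], s2$frames[[k]])
})

test_that("identical rng_seed gives bit-identical stacks", {
  a <- simulate_glottis_stack(glottis_preset("healthy", duration = 0.02,
                                             rng_seed = 42))
  b <- simulate_glottis_stack(glottis_preset("healthy", duration = 0.02,
                                             rng_seed = 42))
  expect_identical(a$stack$frames, b$stack$frames)
  c <- simulate_glottis_stack(glottis_preset("healthy", duration = 0.02,
                                             rng_seed = 43))
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("polyp occlusion removes area from the named side only", {
  base <- glottis_sim_params(duration = 0.02, noise_sigma = 0)
  # disc wholly on the image-right side of the midline (cols 81-89)
  occl <- glottis_sim_params(duration = 0.02, noise_sigma = 0,
                             polyp = list(side = "right",
                                          center = c(60, 85), radius = 4))
  a0 <- simulate_glottis_stack(base)$truth$areas
  a1 <- simulate_glottis_stack(occl)$truth$areas
  expect_identical(a0$left_area_px, a1$left_area_px)
  expect_true(any(a1$right_area_px < a0$right_area_px))
})

test_that("chopper stack parameters enforce Nyquist and quadrant rules", {
  expect_error(chopper_sim_params(fps = 939.44, blocked_quadrants = 3),
               "blocked_quadrants")
  expect_error(chopper_sim_params(fps = 35, chopper_hz = 10,
                                  blocked_quadrants = 2), "Nyquist")
  expect_error(chopper_sim_params(fps = 100, chopper_hz = -1), "chopper_hz")
})

test_that("chopper frame-mean trace is periodic with the design period", {
  # 1000 fps / (2 quadrants * 10 Hz) = 50 frames per modulation cycle
  st <- simulate_chopper_stack(chopper_sim_params(fps = 1000,
                                                  chopper_hz = 10,
                                                  blocked_quadrants = 2,
                                                  duration = 0.3))
  v <- intensity_trace(st)$values
  expect_equal(v[1:250], v[51:300], tolerance = 1e-12)
  # one blocked quadrant: one cycle per rotation, fps/chopper_hz frames
  st1 <- simulate_chopper_stack(chopper_sim_params(fps = 800,
                                                   chopper_hz = 10,
                                                   blocked_quadrants = 1,
                                                   duration = 0.3))
  v1 <- intensity_trace(st1)$values
  expect_equal(v1[1:160], v1[81:240], tolerance = 1e-12)
})

test_that("simulate_gaw matches the sampled analytic model", {
  # symmetric parameters: left equals right exactly
  w <- simulate_gaw(glottis_sim_params(duration = 0.05))
  expect_identical(w$left_area, w$right_area)
  expect_equal(w$total_area, w$left_area + w$right_area)
  # paralysis phenotype: silent left side is identically zero
  wp <- simulate_gaw(glottis_sim_params(amp_left = 0, closure_left = 0,
                                        duration = 0.05))
  expect_true(all(wp$left_area == 0))
  # sample count and spectral peak at the clinical operating point
  wf <- simulate_gaw(glottis_sim_params(f0 = 224, fps = 939.44,
                                        duration = 0.4))
  expect_length(wf$total_area, 375L)
  expect_equal(estimate_f0(wf$total_area, 939.44)$f0, 224, tolerance = 0.51)
})
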