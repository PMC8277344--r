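#' Parameters for the synthetic glottis video generator
#'
#' Describes a spindle-shaped glottal gap between two bright vocal folds
#' oscillating sinusoidally. At frame time `t`, the half-width of side `s`
#' at image row `y` is
#' `w_s(y, t) = m(y) * (closure_s + amp_s * (1 + sin(2*pi*f0*t + phase_s)) / 2)`
#' with the spindle profile
#' `m(y) = sin(pi * (y - row_top) / (row_bottom - row_top))` inside
#' `glottis_span` and 0 outside. The anatomical midline lies on the boundary
#' between columns `midline_col - 1` and `midline_col` (continuous column
#' coordinate `midline_col - 0.5`); a pixel is glottal (dark) iff its center
#' column lies strictly inside `(c - w_L, c + w_R)` at its row and outside
#' any polyp disc. Zero half-widths therefore give a fully closed (empty)
#' gap, and mirroring the image horizontally while swapping the left/right
#' parameters reproduces the stack pixel for pixel.
#'
#' @param image_height,image_width frame size in pixels.
#' @param fps frames per second.
#' @param duration clip length in seconds; `floor(duration*fps)` frames are
#'   rendered, frame `k` at time `k/fps`.
#' @param f0 fundamental vibration frequency, Hz.
#' @param amp_left,amp_right peak half-width amplitude per side, pixels.
#' @param closure_left,closure_right residual half-width at maximal closure,
#'   pixels (0 = complete closure).
#' @param phase_left,phase_right oscillation phases, radians. The default
#'   `-pi/2` starts each side fully closed at `t = 0`.
#' @param glottis_span `(row_top, row_bottom)`, 0-based rows bounding the
#'   glottal spindle.
#' @param midline_col 0-based column index; the midline sits on the boundary
#'   just left of this column, so columns `< midline_col` are image-left.
#' @param polyp optional polyp occlusion: a list with elements `side`
#'   ("left" or "right"), `center` (0-based `(row, col)`), and `radius`
#'   (pixels). Glottal pixels inside the disc are rendered as tissue; the
#'   lost area is attributed to the named side in the ground truth.
#' @param background_level,glottis_level 8-bit intensities of the fold
#'   tissue and of the dark glottal gap; `glottis_level < background_level`.
#' @param noise_sigma additive Gaussian sensor noise (intensity units),
#'   applied last and clipped to 0-255.
#' @param rng_seed integer seed making the rendering deterministic.
#' @return A validated list of class `glottis_sim_params`.
#' @seealso [glottis_preset()] for ready-made healthy/pathology settings,
#'   [simulate_glottis_stack()] for rendering.
#' @export
glottis_sim_params <- function(image_height = 120, image_width = 160,
                               fps = 939.44, duration = 0.4, f0 = 224,
                               amp_left = 18, amp_right = 18,
                               closure_left = 0, closure_right = 0,
                               phase_left = -pi / 2, phase_right = -pi / 2,
                               glottis_span = c(20, 100), midline_col = 80,
                               polyp = NULL,
                               background_level = 180, glottis_level = 40,
                               noise_sigma = 0, rng_seed = 1L) {
  p <- list(image_height = as.integer(image_height),
            image_width = as.integer(image_width),
            fps = fps, duration = duration, f0 = f0,
            amp_left = amp_left, amp_right = amp_right,
            closure_left = closure_left, closure_right = closure_right,
            phase_left = phase_left, phase_right = phase_right,
            glottis_span = as.numeric(glottis_span),
            midline_col = midline_col, polyp = polyp,
            background_level = background_level,
            glottis_level = glottis_level,
            noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed))
  if (p$image_height < 1L || p$image_width < 1L)
    stop("invalid parameter: zero-size image")
  if (!is.finite(p$fps) || p$fps <= 0) stop("invalid parameter: fps must be > 0")
  if (p$amp_left < 0 || p$amp_right < 0)
    stop("invalid parameter: amplitudes must be >= 0")
  if (p$closure_left < 0 || p$closure_right < 0)
    stop("invalid parameter: closure offsets must be >= 0")
  if (p$glottis_level >= p$background_level)
    stop("invalid parameter: glottis_level must be below background_level")
  if (length(p$glottis_span) != 2L || p$glottis_span[1L] >= p$glottis_span[2L])
    stop("invalid parameter: degenerate glottis_span (row_top >= row_bottom)")
  if (p$glottis_span[1L] < 0 || p$glottis_span[2L] > p$image_height - 1L)
    stop("invalid parameter: glottis_span outside image bounds")
  if (p$midline_col < 0 || p$midline_col > p$image_width - 1L)
    stop("invalid parameter: midline_col outside image bounds")
  if (floor(p$duration * p$fps) < 2)
    stop("invalid parameter: duration*fps must give at least 2 frames")
  if (p$noise_sigma < 0) stop("invalid parameter: noise_sigma must be >= 0")
  if (!is.null(polyp)) {
    if (!is.list(polyp) || is.null(polyp$side) || is.null(polyp$center) ||
        is.null(polyp$radius) || !polyp$side %in% c("left", "right") ||
        length(polyp$center) != 2L || polyp$radius <= 0)
      stop("invalid parameter: polyp must be list(side=, center=c(row,col), radius=)")
  }
  class(p) <- "glottis_sim_params"
  p
}

#' Preset synthetic subjects
#'
#' Parameter sets emulating the four clinical phenotypes the pipeline is
#' designed to separate: a healthy subject (symmetric oscillation with
#' complete closure), left vocal-fold paralysis (near-zero left amplitude),
#' chronic laryngitis (incomplete closure on both sides), and a right
#' vocal-fold polyp (reduced right amplitude plus a disc occlusion and
#' incomplete closure). The healthy preset vibrates at 224 Hz, a typical
#' young-adult female fundamental frequency.
#'
#' @param name one of `"healthy"`, `"paralysis-left"`, `"laryngitis"`,
#'   `"polyp-right"`.
#' @param ... overrides passed on to [glottis_sim_params()].
#' @return A `glottis_sim_params` object.
#' @examples
#' p <- glottis_preset("paralysis-left", duration = 0.1)
#' p$amp_left
#' @export
glottis_preset <- function(name = c("healthy", "paralysis-left",
                                    "laryngitis", "polyp-right"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "healthy" = list(),
    "paralysis-left" = list(amp_left = 1),
    "laryngitis" = list(closure_left = 4, closure_right = 4,
                        amp_left = 14, amp_right = 14),
    "polyp-right" = list(amp_right = 8, closure_left = 3, closure_right = 3,
                         polyp = list(side = "right", center = c(60, 86),
                                      radius = 5)))
  base$noise_sigma <- 2
  over <- list(...)
  base[names(over)] <- over
  do.call(glottis_sim_params, base)
}

# Per-side oscillation factors at a vector of times.
glottis_osc <- function(p, t) {
  list(left = p$closure_left +
         p$amp_left * (1 + sin(2 * pi * p$f0 * t + p$phase_left)) / 2,
       right = p$closure_right +
         p$amp_right * (1 + sin(2 * pi * p$f0 * t + p$phase_right)) / 2)
}

# Spindle profile m(y) over all image rows (0 outside the span).
glottis_profile <- function(p) {
  y <- 0:(p$image_height - 1L)
  top <- p$glottis_span[1L]; bot <- p$glottis_span[2L]
  m <- numeric(p$image_height)
  inside <- y >= top & y <= bot
  m[inside] <- sin(pi * (y[inside] - top) / (bot - top))
  m
}

#' Render a synthetic high-speed glottis stack with ground truth
#'
#' Rasterizes the kinematic model of [glottis_sim_params()] into a
#' [frame_stack] and, from the same half-width profiles, counts the true
#' per-frame total/left/right open areas *before* noise is added, so the
#' returned ground truth is exact for the rendered pixels.
#'
#' @param params a [glottis_sim_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{stack}{[frame_stack] of `floor(duration*fps)` rendered frames.}
#'     \item{truth}{class `glottis_ground_truth`: `areas` (data frame with
#'       `frame`, `time_s`, `total_area_px`, `left_area_px`,
#'       `right_area_px`), `half_width_left`/`half_width_right`
#'       (`image_height x n_frames` matrices of continuous half-widths),
#'       `f0`, `phase_lag_frames` (positive = right lags left),
#'       `closure_min_px2`, and `params`.}
#'   }
#' @examples
#' sim <- simulate_glottis_stack(glottis_preset("healthy", duration = 0.05))
#' head(sim$truth$areas)
#' @export
simulate_glottis_stack <- function(params) {
  p <- if (inherits(params, "glottis_sim_params")) params else
    do.call(glottis_sim_params, params)
  nf <- floor(p$duration * p$fps + 1e-9)
  H <- p$image_height; W <- p$image_width
  xs <- 0:(W - 1L)
  m <- glottis_profile(p)
  cmid <- p$midline_col - 0.5
  left_cols <- matrix(xs < cmid, H, W, byrow = TRUE)
  right_cols <- matrix(xs > cmid, H, W, byrow = TRUE)
  keep <- NULL
  if (!is.null(p$polyp)) {
    ys <- 0:(H - 1L)
    disc <- outer((ys - p$polyp$center[1L])^2, (xs - p$polyp$center[2L])^2,
                  "+") <= p$polyp$radius^2
    keep <- !disc
  }
  t <- (0:(nf - 1L)) / p$fps
  osc <- glottis_osc(p, t)
  wl <- outer(m, osc$left)    # H x nf continuous half-widths
  wr <- outer(m, osc$right)

  set.seed(p$rng_seed)
  frames <- vector("list", nf)
  areas_l <- areas_r <- integer(nf)
  for (k in seq_len(nf)) {
    dl <- outer(cmid - wl[, k], xs, "<") & left_cols
    dr <- outer(cmid + wr[, k], xs, ">") & right_cols
    if (!is.null(keep)) { dl <- dl & keep; dr <- dr & keep }
    areas_l[k] <- sum(dl); areas_r[k] <- sum(dr)
    img <- matrix(p$background_level, H, W)
    img[dl | dr] <- p$glottis_level
    if (p$noise_sigma > 0) {
      img <- img + matrix(rnorm(H * W, 0, p$noise_sigma), H, W)
      img <- round(pmin(pmax(img, 0), 255))
    }
    frames[[k]] <- img
  }
  total <- areas_l + areas_r
  truth <- structure(list(
    areas = data.frame(frame = 0:(nf - 1L), time_s = t,
                       total_area_px = total, left_area_px = areas_l,
                       right_area_px = areas_r),
    half_width_left = wl, half_width_right = wr,
    f0 = p$f0,
    phase_lag_frames = (p$phase_left - p$phase_right) * p$fps /
      (2 * pi * p$f0),
    closure_min_px2 = min(total),
    params = p), class = "glottis_ground_truth")
  list(stack = frame_stack(frames, p$fps, source = "synthetic-glottis"),
       truth = truth)
}

#' Analytic glottal waveforms without rasterization
#'
#' Samples the continuous-area version of the kinematic model at the frame
#' rate: each side's area is `sum_y m(y) * osc_s(t)` over the image rows
#' (continuous across columns, so no pixel quantization). Edge-length series
#' are the analytic approximation `2*h*(osc_s > 0) + 2*osc_s` of the
#' unit-edge perimeter, which carries the side's oscillation phase. Useful
#' for testing the waveform analysis without rendering and segmenting
#' images. Polyps are ignored here (rasterization-level detail).
#'
#' @param params a [glottis_sim_params()] object.
#' @return A [glottal_waveforms] object with `floor(duration*fps)` samples.
#' @export
simulate_gaw <- function(params) {
  p <- if (inherits(params, "glottis_sim_params")) params else
    do.call(glottis_sim_params, params)
  nf <- floor(p$duration * p$fps + 1e-9)
  t <- (0:(nf - 1L)) / p$fps
  K <- sum(glottis_profile(p))
  h <- p$glottis_span[2L] - p$glottis_span[1L]
  osc <- glottis_osc(p, t)
  left <- K * osc$left
  right <- K * osc$right
  glottal_waveforms(fps = p$fps,
                    total_area = left + right,
                    left_area = left, right_area = right,
                    left_edge = 2 * h * (osc$left > 0) + 2 * osc$left,
                    right_edge = 2 * h * (osc$right > 0) + 2 * osc$right)
}

#' Parameters for the synthetic chopper-wheel calibration stack
#'
#' A rotating sector mask with `blocked_quadrants` of its 4 quadrants
#' opaque modulates the light reaching the sensor; the frame-mean intensity
#' then oscillates with period `1/(blocked_quadrants*chopper_hz)` seconds,
#' i.e. `fps/(blocked_quadrants*chopper_hz)` frames. With 2 opposite
#' quadrants blocked (the standard arrangement) the modulation period is
#' half the rotation period.
#'
#' @param fps frames per second of the simulated camera.
#' @param chopper_hz wheel rotation rate, rotations/second.
#' @param blocked_quadrants 1 or 2 opaque quadrants.
#' @param duration clip length, seconds.
#' @param bright_level,dark_level 8-bit intensities at full transmission and
#'   full blockage.
#' @param noise_sigma additive Gaussian noise, intensity units.
#' @param rng_seed integer seed.
#' @param image_height,image_width frame size (the trace only uses the
#'   frame mean, so small frames suffice).
#' @return A validated list of class `chopper_sim_params`.
#' @export
chopper_sim_params <- function(fps, chopper_hz = 10, blocked_quadrants = 2,
                               duration = 0.4, bright_level = 200,
                               dark_level = 20, noise_sigma = 0,
                               rng_seed = 1L,
                               image_height = 8, image_width = 8) {
  p <- list(fps = fps, chopper_hz = chopper_hz,
            blocked_quadrants = as.integer(blocked_quadrants),
            duration = duration, bright_level = bright_level,
            dark_level = dark_level, noise_sigma = noise_sigma,
            rng_seed = as.integer(rng_seed),
            image_height = as.integer(image_height),
            image_width = as.integer(image_width))
  if (!p$blocked_quadrants %in% c(1L, 2L))
    stop("invalid parameter: blocked_quadrants must be 1 or 2")
  if (p$chopper_hz <= 0) stop("invalid parameter: chopper_hz must be > 0")
  if (p$fps <= 2 * p$blocked_quadrants * p$chopper_hz)
    stop("invalid parameter: fps at or below the Nyquist rate for the modulation")
  if (p$duration * p$fps < 2) stop("invalid parameter: fewer than 2 frames")
  if (p$dark_level >= p$bright_level)
    stop("invalid parameter: dark_level must be below bright_level")
  class(p) <- "chopper_sim_params"
  p
}

#' Render a synthetic chopper-wheel stack
#'
#' Frame-mean intensity follows the transparent-sector fraction visible at
#' each frame time, modeled as a raised cosine
#' `dark + (bright-dark)*(1 + cos(2*pi*blocked_quadrants*chopper_hz*t))/2`,
#' so the noise-free trace is periodic with period
#' `fps/(blocked_quadrants*chopper_hz)` frames and peaks at whole rotations
#' of the blocked sectors past the aperture.
#'
#' @param params a [chopper_sim_params()] object.
#' @return A [frame_stack] of constant-intensity frames (plus noise).
#' @seealso [intensity_trace()], [detect_peaks()], [estimate_frame_rate()]
#' @export
simulate_chopper_stack <- function(params) {
  p <- if (inherits(params, "chopper_sim_params")) params else
    do.call(chopper_sim_params, params)
  nf <- floor(p$duration * p$fps + 1e-9)
  t <- (0:(nf - 1L)) / p$fps
  level <- p$dark_level + (p$bright_level - p$dark_level) *
    (1 + cos(2 * pi * p$blocked_quadrants * p$chopper_hz * t)) / 2
  set.seed(p$rng_seed)
  frames <- lapply(seq_len(nf), function(k) {
    img <- matrix(level[k], p$image_height, p$image_width)
    if (p$noise_sigma > 0) {
      img <- img + matrix(rnorm(length(img), 0, p$noise_sigma), nrow(img))
      img <- pmin(pmax(img, 0), 255)
    }
    img
  })
  frame_stack(frames, p$fps, source = "synthetic-chopper")
}
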