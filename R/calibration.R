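#' Frame-mean intensity trace
#'
#' Arithmetic mean of all pixel intensities in each frame; the signal the
#' chopper-wheel calibration is run on.
#'
#' @param stack a [frame_stack] with at least 2 frames.
#' @return An object of class `intensity_trace`: `values` (one mean per
#'   frame) and `fps_nominal` (the stack's advisory frame rate).
#' @export
intensity_trace <- function(stack) {
  if (n_frames(stack) < 2L) stop("need at least 2 frames")
  structure(list(values = vapply(stack$frames, mean, numeric(1)),
                 fps_nominal = stack$fps), class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %d frames, range %.4g - %.4g\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Detect modulation peaks in an intensity trace
#'
#' Local maxima above the trace midrange `(min+max)/2`, separated by at
#' least `min_separation` frames, each refined to a fractional frame
#' position by 3-point parabolic interpolation. The first and last frames
#' are never reported as peaks (no neighbor to refine against, and a clip
#' boundary is not evidence of a maximum).
#'
#' @param trace an [intensity_trace] or a plain numeric vector.
#' @param min_separation minimum peak spacing in frames (>= 2).
#' @return Increasing fractional 0-based frame positions.
#' @export
detect_peaks <- function(trace, min_separation = 2) {
  v <- if (inherits(trace, "intensity_trace")) trace$values else trace
  if (min_separation < 2) stop("min_separation must be >= 2")
  n <- length(v)
  if (n < 3L) stop("trace too short for peak detection")
  mid <- (min(v) + max(v)) / 2
  cand <- which(v[2:(n - 1L)] > v[1:(n - 2L)] &
                  v[2:(n - 1L)] >= v[3:n] &
                  v[2:(n - 1L)] > mid) + 1L
  peaks <- numeric(0)
  last_kept <- -Inf
  for (i in cand) {
    if (i - last_kept < min_separation) next
    last_kept <- i
    a <- v[i - 1L]; b <- v[i]; c <- v[i + 1L]
    den <- a - 2 * b + c
    delta <- if (den < 0) 0.5 * (a - c) / den else 0
    peaks <- c(peaks, (i - 1L) + delta)  # 0-based
  }
  if (length(peaks) < 2L)
    stop("no modulation detected: fewer than 2 peaks ",
         "(trace too short or unmodulated)")
  peaks
}

#' Frame rate from chopper-wheel peak positions
#'
#' With `blocked_quadrants` opaque quadrants on a wheel rotating at
#' `chopper_hz`, the intensity modulation period is
#' `1/(blocked_quadrants*chopper_hz)` seconds (half the rotation period in
#' the standard 2-blocked-quadrant arrangement). The measured mean
#' peak-to-peak interval in frames therefore converts to
#' `fps = mean_interval * blocked_quadrants * chopper_hz`. The mean is taken
#' over all consecutive peak pairs.
#'
#' @param peaks increasing fractional frame positions from [detect_peaks()].
#' @param chopper_hz wheel rotation rate, rotations/second.
#' @param blocked_quadrants 1 or 2.
#' @return An object of class `calibration_result`: `peak_positions`,
#'   `mean_interval` (frames), `fps_estimate`, `chopper_hz`,
#'   `blocked_quadrants`.
#' @examples
#' estimate_frame_rate(c(0, 46.972), chopper_hz = 10,
#'                     blocked_quadrants = 2)$fps_estimate  # 939.44
#' @export
estimate_frame_rate <- function(peaks, chopper_hz = 10,
                                blocked_quadrants = 2) {
  if (length(peaks) < 2L) stop("need at least 2 peaks")
  if (any(diff(peaks) <= 0)) stop("peak positions must be strictly increasing")
  if (chopper_hz <= 0) stop("chopper_hz must be positive")
  if (!blocked_quadrants %in% c(1, 2))
    stop("blocked_quadrants must be 1 or 2")
  mean_interval <- mean(diff(peaks))
  structure(list(peak_positions = peaks, mean_interval = mean_interval,
                 fps_estimate = mean_interval * blocked_quadrants *
                   chopper_hz,
                 chopper_hz = chopper_hz,
                 blocked_quadrants = as.integer(blocked_quadrants)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> %d peaks, mean interval %.3f frames\n",
    length(x$peak_positions), x$mean_interval))
  cat(sprintf(
    "  chopper %.4g Hz, %d blocked quadrant(s) => %.2f fps\n",
    x$chopper_hz, x$blocked_quadrants, x$fps_estimate))
  invisible(x)
}

#' Spatial resolution: line pairs per millimeter to micrometers
#'
#' Width of one resolved line pair: `1000 / lp_per_mm` micrometers,
#' reported to 3 decimals (23 lp/mm resolves 43.478 um features).
#'
#' @param lp_per_mm resolved line pairs per millimeter (> 0).
#' @return Line-pair width in micrometers.
#' @export
lp_mm_to_um <- function(lp_per_mm) {
  if (any(lp_per_mm <= 0)) stop("lp_per_mm must be positive")
  round(1000 / lp_per_mm, 3)
}

#' Frames captured in a clip
#'
#' `floor(duration * fps)`, with a small epsilon so that exact products are
#' not lost to floating-point representation (0.4 s at 940 fps is exactly
#' 376 frames).
#'
#' @param duration clip length, seconds (> 0).
#' @param fps frames per second (> 0).
#' @return Integer frame count.
#' @export
capture_frame_count <- function(duration, fps) {
  if (any(duration <= 0) || any(fps <= 0))
    stop("duration and fps must be positive")
  as.integer(floor(duration * fps + 1e-9))
}
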