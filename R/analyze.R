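#' Analyze a high-speed glottis clip end to end
#'
#' Runs the full pipeline on a frame stack: grayscale conversion, global
#' percentile contrast stretch, seeded-region-growing segmentation of the
#' glottal gap, midline fit (or a supplied manual midline), left/right area
#' and edge-length waveform extraction, and the diagnostic parameters
#' (fundamental frequency, amplitude asymmetry, closure deficit, lateral
#' phase lag, frames per cycle).
#'
#' @param stack a [frame_stack] (RGB or grayscale).
#' @param grayscale_weights channel weights for [to_grayscale()].
#' @param contrast `c(low_pct, high_pct)` for [adjust_contrast()], or `NULL`
#'   to skip the stretch.
#' @param seed0 a [seed_spec()] for the first frame.
#' @param grow a [grow_config()].
#' @param midline a [midline_model()], or `NULL` to fit one from the
#'   segmentation union.
#' @param f_min,pad_factor,robust_amplitude,refine_closure passed to
#'   [build_report()].
#' @return An object of class `glottal_analysis`: list with `report`
#'   (a `diagnostic_report`), `waveforms` (a [glottal_waveforms]),
#'   `segmentation` (a `glottal_segmentation`), `midline`, `fps`, and
#'   `settings`. Methods: `print`, `summary`, `coef` (named vector of the
#'   diagnostic parameters), `plot` (normalized waveforms).
#' @examples
#' sim <- simulate_glottis_stack(glottis_preset("healthy", duration = 0.1,
#'                                              noise_sigma = 0))
#' fit <- analyze_glottis(sim$stack)
#' coef(fit)
#' @export
analyze_glottis <- function(stack,
                            grayscale_weights = c(0.299, 0.587, 0.114),
                            contrast = c(1, 99),
                            seed0 = seed_spec("darkest-in-roi"),
                            grow = grow_config(),
                            midline = NULL,
                            f_min = 70, pad_factor = 16,
                            robust_amplitude = FALSE,
                            refine_closure = TRUE) {
  if (n_frames(stack) < 16L)
    stop("too few frames for spectral analysis (need >= 16)")
  gs <- to_grayscale(stack, grayscale_weights)
  pre <- if (is.null(contrast)) gs else
    adjust_contrast(gs, contrast[1L], contrast[2L])
  seg <- segment_stack(pre, seed0 = seed0, config = grow)
  ml <- if (is.null(midline)) fit_midline(seg) else midline
  waves <- compute_waveforms(seg, ml, stack$fps)
  rep <- build_report(waves, f_min = f_min, pad_factor = pad_factor,
                      robust_amplitude = robust_amplitude,
                      refine_closure = refine_closure)
  structure(list(report = rep, waveforms = waves, segmentation = seg,
                 midline = ml, fps = stack$fps,
                 settings = list(grayscale_weights = grayscale_weights,
                                 contrast = contrast,
                                 seed0 = seed0, grow = seg$config,
                                 f_min = f_min, pad_factor = pad_factor,
                                 robust_amplitude = robust_amplitude,
                                 refine_closure = refine_closure,
                                 source = stack$source)),
            class = "glottal_analysis")
}

#' @export
print.glottal_analysis <- function(x, ...) {
  cat(sprintf("<glottal_analysis> %d frames @ %.6g fps [%s]\n",
              length(x$waveforms$total_area), x$fps, x$settings$source))
  print(x$report)
  invisible(x)
}

#' @export
summary.glottal_analysis <- function(object, ...) {
  x <- object
  print(x)
  areas <- vapply(x$segmentation$masks, sum, numeric(1))
  cat(sprintf("  segmentation: %s, %d-connectivity, %d closed frame(s)\n",
              x$segmentation$config$criterion,
              x$segmentation$config$connectivity,
              length(x$segmentation$empty_frames)))
  cat(sprintf("  glottal area: %d - %d px^2 (median %g)\n",
              as.integer(min(areas)), as.integer(max(areas)),
              median(areas)))
  print(x$midline)
  invisible(x)
}

#' @export
coef.glottal_analysis <- function(object, ...) {
  r <- object$report
  c(f0_hz = r$f0_hz, asymmetry_index = r$asymmetry_index,
    closure_deficit = r$closure_deficit,
    phase_lag_frames = r$phase_lag_frames,
    frames_per_cycle = as.numeric(r$frames_per_cycle))
}

#' @export
plot.glottal_analysis <- function(x, which = c("total", "sides"), ...) {
  which <- match.arg(which)
  w <- x$waveforms
  t <- (seq_along(w$total_area) - 1L) / w$fps
  mx <- max(w$total_area)
  if (mx == 0) stop("all-zero waveforms: nothing to plot")
  if (which == "total") {
    graphics::plot(t, w$total_area / mx, type = "l",
                   xlab = "time (s)", ylab = "normalized glottal area",
                   main = sprintf("total glottal area (f0 = %.1f Hz)",
                                  x$report$f0_hz), ...)
  } else {
    graphics::plot(t, w$left_area / mx, type = "l", col = "firebrick",
                   ylim = c(0, 1), xlab = "time (s)",
                   ylab = "normalized glottal area",
                   main = "left/right glottal areas", ...)
    graphics::lines(t, w$right_area / mx, col = "navy")
    graphics::legend("topright", legend = c("image-left", "image-right"),
                     col = c("firebrick", "navy"), lty = 1, bty = "n")
  }
  invisible(x)
}
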