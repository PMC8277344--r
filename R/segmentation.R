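#' Seed specification for region growing
#'
#' @param mode `"manual"` (use `pixel`), `"darkest-in-roi"` (argmin
#'   intensity within `roi`), or `"propagate"` (darkest pixel within the
#'   previous nonempty mask's bounding box, falling back to
#'   `darkest-in-roi`).
#' @param pixel 0-based `(row, col)`, required for `"manual"`.
#' @param roi 0-based half-open rectangle `(row0, col0, row1, col1)` for the
#'   automatic modes; `NULL` means the whole frame.
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(mode = c("darkest-in-roi", "manual", "propagate"),
                      pixel = NULL, roi = NULL) {
  mode <- match.arg(mode)
  if (mode == "manual" && (is.null(pixel) || length(pixel) != 2L))
    stop("manual seeding needs pixel = c(row, col)")
  if (!is.null(roi) && length(roi) != 4L)
    stop("roi must be c(row0, col0, row1, col1), half-open, 0-based")
  structure(list(mode = mode, pixel = pixel, roi = roi), class = "seed_spec")
}

#' Region growing configuration
#'
#' Two growth criteria are available. `"region-mean"` follows the classic
#' seeded-region-growing scheme: the boundary pixel whose intensity is
#' closest to the current region mean is admitted while that difference
#' stays within `tau` (ties by insertion order). `"fixed-threshold"` takes
#' the connected component of pixels with intensity `<= threshold` that
#' contains the seed; it is exactly a flood fill and therefore trivially
#' oracle-testable. With `tau = NULL` / `threshold = NULL` the values are
#' derived per clip from Otsu's threshold on the first seeded frame (see
#' [segment_stack()]).
#'
#' @param criterion `"region-mean"` (default) or `"fixed-threshold"`.
#' @param tau intensity tolerance for region-mean mode (`>= 0`).
#' @param threshold intensity cutoff for fixed-threshold mode.
#' @param connectivity 4 (default) or 8.
#' @param max_area_frac abort threshold: a region exceeding this fraction of
#'   the frame area raises a leakage error rather than silently truncating.
#' @return An object of class `grow_config`.
#' @export
grow_config <- function(criterion = c("region-mean", "fixed-threshold"),
                        tau = NULL, threshold = NULL, connectivity = 4,
                        max_area_frac = 0.25) {
  criterion <- match.arg(criterion)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (!is.null(tau) && tau < 0) stop("tau must be >= 0")
  if (max_area_frac <= 0 || max_area_frac > 1)
    stop("max_area_frac must be in (0, 1]")
  structure(list(criterion = criterion, tau = tau, threshold = threshold,
                 connectivity = as.integer(connectivity),
                 max_area_frac = max_area_frac), class = "grow_config")
}

# Darkest pixel in a 0-based half-open roi; ties to smallest row, then col.
darkest_pixel <- function(frame, roi) {
  r0 <- roi[1L] + 1L; c0 <- roi[2L] + 1L; r1 <- roi[3L]; c1 <- roi[4L]
  sub <- frame[r0:r1, c0:c1, drop = FALSE]
  hits <- which(sub == min(sub), arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  unname(c(hits[1L, 1L] + r0 - 2L, hits[1L, 2L] + c0 - 2L))  # back to 0-based
}

#' Resolve a seed pixel for one frame
#'
#' Applies the seeding rule and then a closed-glottis guard: if the
#' candidate pixel is not convincingly darker than the frame background
#' (for region-mean, intensity above `median(frame) - tau`; for
#' fixed-threshold, above `threshold`), the glottis is taken to be fully
#' closed in this frame and `NULL` is returned, which yields an empty mask.
#'
#' @param frame intensity matrix.
#' @param spec a [seed_spec()].
#' @param prev_mask previous frame's mask for `"propagate"` mode (may be
#'   `NULL` or empty, triggering the fallback).
#' @param config a [grow_config()] supplying the guard levels; `tau` /
#'   `threshold` must be concrete here.
#' @return 0-based `c(row, col)`, or `NULL` for a closed frame.
#' @export
resolve_seed <- function(frame, spec, prev_mask = NULL,
                         config = grow_config(tau = 0)) {
  H <- nrow(frame); W <- ncol(frame)
  full <- c(0L, 0L, H, W)
  in_bounds <- function(px) px[1L] >= 0 && px[1L] < H && px[2L] >= 0 &&
    px[2L] < W
  px <- switch(spec$mode,
    manual = {
      if (!in_bounds(spec$pixel))
        stop("manual seed pixel outside image bounds")
      as.integer(spec$pixel)
    },
    `darkest-in-roi` = darkest_pixel(frame, if (is.null(spec$roi)) full
                                            else spec$roi),
    propagate = {
      if (!is.null(prev_mask) && any(prev_mask)) {
        hits <- which(prev_mask, arr.ind = TRUE)
        bbox <- c(min(hits[, 1L]) - 1L, min(hits[, 2L]) - 1L,
                  max(hits[, 1L]), max(hits[, 2L]))
        darkest_pixel(frame, bbox)
      } else {
        darkest_pixel(frame, if (is.null(spec$roi)) full else spec$roi)
      }
    })
  val <- frame[px[1L] + 1L, px[2L] + 1L]
  closed <- if (config$criterion == "fixed-threshold") {
    if (is.null(config$threshold)) stop("config$threshold must be set")
    val > config$threshold
  } else {
    if (is.null(config$tau)) stop("config$tau must be set")
    val > median(frame) - config$tau
  }
  if (closed) NULL else px
}

#' Grow a glottal region from a seed
#'
#' @param frame intensity matrix.
#' @param seed 0-based `c(row, col)`, or `NULL` for a closed frame (returns
#'   an all-`FALSE` mask).
#' @param config a [grow_config()] with concrete `tau`/`threshold`.
#' @return Logical mask, same shape as `frame`; a nonempty mask is a single
#'   connected component containing the seed.
#' @examples
#' fr <- matrix(c(10, 10, 200, 10, 200, 200, 200, 200, 200), 3, byrow = TRUE)
#' cfg <- grow_config("fixed-threshold", threshold = 100, max_area_frac = 1)
#' sum(region_grow(fr, c(0, 0), cfg))  # the three dark pixels
#' @export
region_grow <- function(frame, seed, config = grow_config(tau = 0)) {
  if (is.null(seed))
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  if (seed[1L] < 0 || seed[1L] >= nrow(frame) ||
      seed[2L] < 0 || seed[2L] >= ncol(frame))
    stop("seed outside image bounds")
  max_px <- max(1L, floor(config$max_area_frac * length(frame)))
  res <- if (config$criterion == "fixed-threshold") {
    if (is.null(config$threshold)) stop("config$threshold must be set")
    rg_fixed_cpp(frame, seed[1L], seed[2L], config$threshold,
                 config$connectivity, max_px)
  } else {
    if (is.null(config$tau)) stop("config$tau must be set")
    rg_mean_cpp(frame, seed[1L], seed[2L], config$tau,
                config$connectivity, max_px)
  }
  if (res$leaked)
    stop("region leakage: grown area exceeded max_area_frac = ",
         config$max_area_frac,
         " of the frame; adjust tau/threshold or max_area_frac")
  res$mask
}

# Fill in tau/threshold from Otsu's threshold on one frame.
auto_grow_config <- function(config, frame) {
  thr <- EBImage::otsu(frame, range = c(0, 255), levels = 256L)
  if (config$criterion == "fixed-threshold" && is.null(config$threshold))
    config$threshold <- thr
  if (config$criterion == "region-mean" && is.null(config$tau))
    config$tau <- max(1, thr - min(frame))
  config
}

#' Segment the glottal gap in every frame of a clip
#'
#' Frame 0 is seeded by `seed0`; each subsequent frame is seeded by
#' propagation (darkest pixel within the previous nonempty mask's bounding
#' box, falling back to `seed0`'s ROI). Frames whose resolved seed fails the
#' closed-glottis guard get empty masks and are listed in `empty_frames`.
#' Unset `tau`/`threshold` values are derived once, from Otsu's threshold on
#' the first frame with an accepted seed, and reused for the whole clip so
#' that area waveforms are comparable across frames.
#'
#' @param stack preprocessed single-channel [frame_stack].
#' @param seed0 a [seed_spec()] for the first frame.
#' @param config a [grow_config()].
#' @return An object of class `glottal_segmentation`: list with `masks`
#'   (one logical matrix per frame), `seeds_used` (0-based `(row, col)` or
#'   `NULL` per frame), `config` (with resolved `tau`/`threshold`), and
#'   `empty_frames` (0-based indices).
#' @export
segment_stack <- function(stack, seed0 = seed_spec("darkest-in-roi"),
                          config = grow_config()) {
  if (is_rgb_stack(stack))
    stop("segment_stack expects a single-channel stack")
  nf <- n_frames(stack)
  needs_auto <- (config$criterion == "fixed-threshold" &&
                   is.null(config$threshold)) ||
    (config$criterion == "region-mean" && is.null(config$tau))
  if (needs_auto) {
    # calibrate on the frame with the widest intensity spread (most likely
    # to show an open glottis against the fold tissue)
    spread <- vapply(stack$frames, function(f) diff(range(f)), numeric(1))
    config <- auto_grow_config(config, stack$frames[[which.max(spread)]])
  }
  masks <- vector("list", nf)
  seeds <- vector("list", nf)
  empty <- integer(0)
  prev <- NULL
  for (k in seq_len(nf)) {
    frame <- stack$frames[[k]]
    spec <- if (k == 1L) seed0 else
      seed_spec("propagate", roi = seed0$roi)
    seed <- resolve_seed(frame, spec, prev_mask = prev, config = config)
    mask <- tryCatch(region_grow(frame, seed, config),
                     error = function(e)
                       stop("frame ", k - 1L, ": ", conditionMessage(e),
                            call. = FALSE))
    masks[[k]] <- mask
    seeds[[k]] <- seed
    if (!any(mask)) empty <- c(empty, k - 1L) else prev <- mask
  }
  structure(list(masks = masks, seeds_used = seeds, config = config,
                 empty_frames = empty),
            class = "glottal_segmentation")
}

#' @export
print.glottal_segmentation <- function(x, ...) {
  areas <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("<glottal_segmentation> %d frames (%s, %d-connectivity)\n",
              length(x$masks), x$config$criterion, x$config$connectivity))
  cat(sprintf("  area px: min %d / median %g / max %d; %d closed frame(s)\n",
              as.integer(min(areas)), median(areas),
              as.integer(max(areas)), length(x$empty_frames)))
  invisible(x)
}
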