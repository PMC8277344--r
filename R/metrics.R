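#' Anatomical midline model
#'
#' An oriented 2D line through `point` along the unit vector `direction`,
#' in 0-based continuous `(row, col)` coordinates. In the clinic the midline
#' is drawn by hand; [fit_midline()] produces one automatically from the
#' segmentation.
#'
#' @param point `(row, col)`, any point on the line.
#' @param direction `(d_row, d_col)`; normalized to unit length.
#' @param source `"manual"` or `"fitted"`.
#' @return An object of class `midline_model`.
#' @export
midline_model <- function(point, direction, source = "manual") {
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) stop("direction must be nonzero")
  structure(list(point = as.numeric(point),
                 direction = as.numeric(direction) / nrm,
                 source = source), class = "midline_model")
}

#' @export
print.midline_model <- function(x, ...) {
  cat(sprintf(
    "<midline_model> point (%.2f, %.2f), direction (%.4f, %.4f) [%s]\n",
    x$point[1L], x$point[2L], x$direction[1L], x$direction[2L], x$source))
  invisible(x)
}

#' Fit the midline from a segmentation
#'
#' Principal axis of the union of all nonempty masks: the largest-variance
#' eigenvector of the covariance of the union's 0-based pixel coordinates,
#' anchored at the union centroid. One line is fitted per clip, mirroring
#' the single drawn midline of clinical practice. The direction sign is
#' fixed to `d_row >= 0` (ties: `d_col >= 0`) so the fit is deterministic
#' even for a degenerate (circular) union.
#'
#' The fit assumes the glottal gap is roughly symmetric about the true
#' anatomical midline. Strongly one-sided pathology (paralysis, large
#' polyp) pulls the union centroid toward the mobile side, biasing the
#' fitted line; for such clips supply a manually drawn [midline_model()]
#' instead, as is done in clinical practice.
#'
#' @param seg a [segment_stack()] result.
#' @return A `midline_model` with `source = "fitted"`.
#' @export
fit_midline <- function(seg) {
  pts <- NULL
  union <- Reduce(`|`, seg$masks)
  if (!any(union))
    stop("all masks are empty: supply a manual midline_model instead")
  hits <- which(union, arr.ind = TRUE) - 1  # 0-based (row, col)
  ctr <- colMeans(hits)
  cv <- stats::cov(hits)
  eg <- eigen(cv, symmetric = TRUE)
  d <- eg$vectors[, 1L]
  if (d[1L] < 0 || (d[1L] == 0 && d[2L] < 0)) d <- -d
  midline_model(point = ctr, direction = d, source = "fitted")
}

#' Split a mask into image-left and image-right parts
#'
#' A pixel center `p` is assigned by the sign of the 2D cross product
#' `direction x (p - point)`: negative goes image-left, zero or positive
#' image-right (pixels exactly on the line go right, keeping the split
#' deterministic and area-conserving). For the conventional top-to-bottom
#' midline (`direction = (1, 0)`) this puts smaller columns on the left.
#'
#' @param mask logical matrix.
#' @param midline a [midline_model()].
#' @return `list(left = , right = )` logical matrices with
#'   `left | right == mask` and `left & right` empty.
#' @export
split_mask <- function(mask, midline) {
  d <- midline$direction; p0 <- midline$point
  H <- nrow(mask); W <- ncol(mask)
  rows <- matrix(0:(H - 1L), H, W)
  cols <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  cross <- d[1L] * (cols - p0[2L]) - d[2L] * (rows - p0[1L])
  list(left = mask & cross < 0, right = mask & cross >= 0)
}

#' Perimeter of a binary mask as a unit-edge count
#'
#' Counts the unit edges between a `TRUE` pixel and a `FALSE` (or
#' out-of-image) 4-neighbor. An exact integer, additive over disconnected
#' components: a single pixel scores 4, a 2x2 square 8.
#'
#' @param mask logical matrix.
#' @return Non-negative integer perimeter in pixel units.
#' @export
edge_length <- function(mask) {
  if (!any(mask)) return(0L)
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  up    <- pad[1:H, 2:(W + 1L)]
  down  <- pad[3:(H + 2L), 2:(W + 1L)]
  left  <- pad[2:(H + 1L), 1:W]
  right <- pad[2:(H + 1L), 3:(W + 2L)]
  as.integer(sum(core & !up) + sum(core & !down) +
               sum(core & !left) + sum(core & !right))
}

#' Glottal waveform container
#'
#' Per-frame total/left/right glottal areas (pixels^2) and per-side
#' edge lengths (pixels), with the frame rate. The total-area series is the
#' clinical "base cord" signal (total glottal area change over the clip);
#' the edge-length series feed the lateral phase difference.
#'
#' @param fps frames per second.
#' @param total_area,left_area,right_area area series;
#'   `left + right == total` must hold exactly on every frame.
#' @param left_edge,right_edge edge-length series.
#' @param normalized logical flag, `TRUE` after [normalize_waveform()]-style
#'   scaling has been applied to the stored series.
#' @return An object of class `glottal_waveforms`.
#' @export
glottal_waveforms <- function(fps, total_area, left_area, right_area,
                              left_edge, right_edge, normalized = FALSE) {
  n <- length(total_area)
  if (length(left_area) != n || length(right_area) != n ||
      length(left_edge) != n || length(right_edge) != n)
    stop("all waveform series must have the same length")
  if (!isTRUE(all(left_area + right_area == total_area)))
    stop("left_area + right_area must equal total_area on every frame")
  structure(list(fps = fps, total_area = total_area, left_area = left_area,
                 right_area = right_area, left_edge = left_edge,
                 right_edge = right_edge, normalized = normalized),
            class = "glottal_waveforms")
}

#' @export
print.glottal_waveforms <- function(x, ...) {
  cat(sprintf(
    "<glottal_waveforms> %d frames @ %.6g fps (%.4g s)%s\n",
    length(x$total_area), x$fps, length(x$total_area) / x$fps,
    if (x$normalized) ", normalized" else ""))
  cat(sprintf("  total area: %.4g - %.4g; left/right max %.4g / %.4g\n",
              min(x$total_area), max(x$total_area),
              max(x$left_area), max(x$right_area)))
  invisible(x)
}

#' Compute area and edge-length waveforms from a segmentation
#'
#' Splits each mask at the midline and counts pixels per side; edge lengths
#' are the unit-edge perimeters of each side mask. Series are returned
#' unnormalized.
#'
#' @param seg a [segment_stack()] result.
#' @param midline a [midline_model()].
#' @param fps frames per second.
#' @return A [glottal_waveforms] object.
#' @export
compute_waveforms <- function(seg, midline, fps) {
  nf <- length(seg$masks)
  la <- ra <- le <- re <- numeric(nf)
  for (k in seq_len(nf)) {
    sides <- split_mask(seg$masks[[k]], midline)
    la[k] <- sum(sides$left); ra[k] <- sum(sides$right)
    le[k] <- edge_length(sides$left); re[k] <- edge_length(sides$right)
  }
  glottal_waveforms(fps = fps, total_area = la + ra, left_area = la,
                    right_area = ra, left_edge = le, right_edge = re)
}

#' Normalize a waveform by its maximum
#'
#' @param series non-negative per-frame values.
#' @return `series / max(series)`; an all-zero series is returned unchanged
#'   with attribute `degenerate = TRUE`.
#' @export
normalize_waveform <- function(series) {
  if (any(series < 0))
    stop("areas and edge lengths cannot be negative")
  mx <- max(series)
  if (mx == 0) {
    attr(series, "degenerate") <- TRUE
    return(series)
  }
  series / mx
}

#' Write / read waveform CSV
#'
#' Columns `frame` (0-based), `time_s`, `total_area_px`, `left_area_px`,
#' `right_area_px`, `left_edge_px`, `right_edge_px`; header row, UTF-8,
#' `.` decimal separator.
#'
#' @param waves a [glottal_waveforms] object.
#' @param path output CSV path.
#' @return `path` invisibly (writer); a [glottal_waveforms] (reader).
#' @export
write_waveform_csv <- function(waves, path) {
  n <- length(waves$total_area)
  df <- data.frame(frame = 0:(n - 1L), time_s = (0:(n - 1L)) / waves$fps,
                   total_area_px = waves$total_area,
                   left_area_px = waves$left_area,
                   right_area_px = waves$right_area,
                   left_edge_px = waves$left_edge,
                   right_edge_px = waves$right_edge)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param fps frame rate override for the reader; by default recovered from
#'   the `time_s` column.
#' @export
read_waveform_csv <- function(path, fps = NULL) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  if (is.null(fps))
    fps <- if (nrow(df) > 1L) 1 / (df$time_s[2L] - df$time_s[1L]) else 1
  if (any(abs(df$total_area_px - (df$left_area_px + df$right_area_px)) >
            1e-6 * pmax(1, df$total_area_px)))
    stop("waveform CSV violates left + right = total")
  # re-derive the total so the exact conservation invariant survives the
  # decimal round trip
  df$total_area_px <- df$left_area_px + df$right_area_px
  glottal_waveforms(fps = fps, total_area = df$total_area_px,
                    left_area = df$left_area_px,
                    right_area = df$right_area_px,
                    left_edge = df$left_edge_px,
                    right_edge = df$right_edge_px)
}
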