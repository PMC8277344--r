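#' Read a frame stack from disk
#'
#' Accepts a directory of PNG/TIFF frames (ordered by lexicographic
#' filename) or a multi-page TIFF file. The frame rate is always supplied by
#' the caller: capture containers routinely store only a nominal playback
#' rate, so any embedded value is advisory and ignored. MP4/AVI containers
#' are not supported; decode such clips to an image sequence first.
#'
#' @param path image-sequence directory or multi-page TIFF file.
#' @param fps frames per second of the recording.
#' @return A [frame_stack]. 8-bit intensities in 0-255; RGB frames are kept
#'   as 3-channel arrays (see [to_grayscale()]).
#' @export
read_frame_stack <- function(path, fps) {
  if (!file.exists(path)) stop("input not found: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0L)
      stop("format error: no PNG/TIFF frames found in ", path)
    frames <- lapply(files, read_one_frame)
    st <- frame_stack(frames, fps, source = path)
    return(st)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, normalize_pixels)
    return(frame_stack(frames, fps, source = path))
  }
  if (ext %in% c("mp4", "avi", "mov"))
    stop("format error: video containers are not supported; ",
         "decode '", path, "' to a PNG/TIFF sequence first")
  stop("format error: cannot read '", path,
       "' (expected a frame directory or multi-page TIFF)")
}

read_one_frame <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- tryCatch(
    if (ext == "png") png::readPNG(f) else tiff::readTIFF(f),
    error = function(e) stop("format error reading frame '", f, "': ",
                             conditionMessage(e)))
  normalize_pixels(img)
}

# png/tiff readers return values in [0,1]; rescale to 8-bit 0-255 and drop
# an alpha channel if present.
normalize_pixels <- function(img) {
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L)
    img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) == 3L && dim(img)[3L] == 1L)
    img <- img[, , 1L]
  round(img * 255)
}

#' Write a frame stack to disk
#'
#' Writes either a zero-padded PNG sequence (`frame_000000.png`, ...) into a
#' directory or a single multi-page TIFF. Intensities are quantized to
#' 8 bits, so a write/read round trip of 8-bit data is lossless.
#'
#' @param stack a [frame_stack].
#' @param path output directory (`format = "png"`) or `.tiff` file path.
#' @param format `"png"` (default) or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  to01 <- function(fr) pmin(pmax(round(fr) / 255, 0), 1)
  if (format == "png") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(stack$frames))
      png::writePNG(to01(stack$frames[[k]]),
                    file.path(path, sprintf("frame_%06d.png", k - 1L)))
  } else {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tiff::writeTIFF(lapply(stack$frames, to01), path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Convert an RGB stack to grayscale
#'
#' Weighted channel sum, rounded to integer intensities. Single-channel
#' stacks pass through unchanged. Default weights are the Rec.601 luma
#' coefficients.
#'
#' @param stack a [frame_stack].
#' @param weights `(w_R, w_G, w_B)` summing to 1 (tolerance 1e-6).
#' @return A single-channel [frame_stack].
#' @examples
#' fr <- array(0, c(2, 2, 3)); fr[, , 1] <- 255  # pure red
#' gs <- to_grayscale(frame_stack(list(fr), fps = 100))
#' gs$frames[[1]][1, 1]  # 76 = round(0.299*255)
#' @export
to_grayscale <- function(stack, weights = c(0.299, 0.587, 0.114)) {
  if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-6)
    stop("invalid parameter: grayscale weights must sum to 1")
  if (!is_rgb_stack(stack)) return(stack)
  frames <- lapply(stack$frames, function(fr)
    round(weights[1L] * fr[, , 1L] + weights[2L] * fr[, , 2L] +
          weights[3L] * fr[, , 3L]))
  frame_stack(frames, stack$fps, stack$source)
}

#' Global percentile contrast stretch
#'
#' Linearly maps the intensity at/below the low percentile to
#' `out_range[1]` and at/above the high percentile to `out_range[2]`, with
#' linear interpolation between. The percentiles are computed over the
#' *whole stack*, giving one mapping for every frame: per-frame stretching
#' would make equal glottal intensities map to different values in
#' different frames and put flicker into the area waveforms.
#'
#' The map is monotone, so within-frame intensity ordering is preserved. A
#' constant stack is returned unchanged with attribute
#' `contrast_degenerate = TRUE` and a warning.
#'
#' @param stack a single-channel [frame_stack].
#' @param low_pct,high_pct percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @param out_range output intensity range, default `c(0, 255)`.
#' @return The stretched [frame_stack] (integer intensities).
#' @export
adjust_contrast <- function(stack, low_pct = 1, high_pct = 99,
                            out_range = c(0, 255)) {
  if (is_rgb_stack(stack))
    stop("adjust_contrast expects a single-channel stack; run to_grayscale first")
  if (low_pct < 0 || high_pct > 100 || low_pct >= high_pct)
    stop("invalid parameter: need 0 <= low_pct < high_pct <= 100")
  all_px <- unlist(stack$frames, use.names = FALSE)
  q <- quantile(all_px, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[1L] == q[2L]) {
    warning("constant stack: contrast left unchanged")
    attr(stack, "contrast_degenerate") <- TRUE
    return(stack)
  }
  lo <- q[1L]; hi <- q[2L]
  frames <- lapply(stack$frames, function(fr) {
    v <- (fr - lo) / (hi - lo) * (out_range[2L] - out_range[1L]) +
      out_range[1L]
    round(pmin(pmax(v, out_range[1L]), out_range[2L]))
  })
  out <- frame_stack(frames, stack$fps, stack$source)
  out
}
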