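#' Frame stack container
#'
#' An ordered sequence of frames with a frame rate. Each frame is either a
#' single-channel intensity matrix (values 0-255) or an
#' `height x width x 3` RGB array. All frames in a stack share the same
#' dimensions and channel count. Frame `k` (0-based) is at time `k/fps`
#' seconds.
#'
#' @param frames list of numeric matrices (grayscale) or 3-d arrays (RGB).
#' @param fps frames per second; must be positive.
#' @param source provenance string (file path, "synthetic", ...).
#' @return An object of class `frame_stack`: a list with elements `frames`,
#'   `fps` and `source`.
#' @examples
#' fs <- frame_stack(list(matrix(0, 4, 4), matrix(255, 4, 4)), fps = 100)
#' n_frames(fs)
#' @export
frame_stack <- function(frames, fps, source = "memory") {
  if (!is.list(frames) || length(frames) < 1L)
    stop("'frames' must be a non-empty list of frames")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("'fps' must be a single positive number")
  d0 <- dim(frames[[1L]])
  if (is.null(d0) || !(length(d0) == 2L || (length(d0) == 3L && d0[3L] == 3L)))
    stop("frames must be matrices or height x width x 3 arrays")
  for (i in seq_along(frames)) {
    d <- dim(frames[[i]])
    if (!identical(as.integer(d), as.integer(d0)))
      stop(sprintf("frame %d has dimensions %s; expected %s",
                   i - 1L, paste(d, collapse = "x"),
                   paste(d0, collapse = "x")))
  }
  structure(list(frames = frames, fps = fps, source = as.character(source)),
            class = "frame_stack")
}

#' Number of frames in a stack
#' @param stack a [frame_stack].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Frame dimensions
#' @param stack a [frame_stack].
#' @return Integer vector `(height, width)`.
#' @export
frame_dim <- function(stack) dim(stack$frames[[1L]])[1:2]

is_rgb_stack <- function(stack) length(dim(stack$frames[[1L]])) == 3L

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  chan <- if (length(d) == 3L) "RGB" else "grayscale"
  cat(sprintf("<frame_stack> %d frames, %dx%d px (%s), %.6g fps [%s]\n",
              length(x$frames), d[1L], d[2L], chan, x$fps, x$source))
  cat(sprintf("  duration %.4g s; frame k is at time k/fps\n",
              length(x$frames) / x$fps))
  invisible(x)
}
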