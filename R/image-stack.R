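#' Time-lapse image stack
#'
#' Container for a grayscale brightfield time-lapse: a list of numeric
#' matrices with intensities in \[0, 1\] and strictly increasing acquisition
#' times in minutes.  Pixel coordinates are 0-based and row-major when
#' exchanged with files; in R the frames are ordinary matrices.
#'
#' @param frames list of numeric matrices, all the same dimension, values
#'   in \[0, 1\].
#' @param times numeric vector of acquisition times in minutes, one per
#'   frame, strictly increasing.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, times = seq(0, by = 10, length.out = length(frames))) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("all frames must share the same dimensions", call. = FALSE)
  if (length(times) != length(frames))
    stop("`times` must have one entry per frame", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  rng <- range(vapply(frames, range, numeric(2)))
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    stop("frame intensities must be finite and within [0, 1]", call. = FALSE)
  structure(list(frames = frames, times = as.numeric(times)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frame(s) of %d x %d px, t = %s min\n",
              length(x$frames), d[1], d[2],
              paste(x$times, collapse = ",")))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)
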