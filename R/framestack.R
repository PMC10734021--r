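#' Frame stacks
#'
#' A `frame_stack` is a rows x cols x frames numeric array of non-negative
#' post-beamformed envelope intensities, with the acquisition frame rate,
#' pixel pitch and the mm coordinates of the first pixel attached as
#' attributes. Rows index depth (z), columns lateral position (x).
#'
#' @param data A rows x cols x frames array (a matrix is treated as a single
#'   frame).
#' @param frame_rate Frames per second (Hz).
#' @param pixel_size_mm Pixel pitch, mm.
#' @param origin Length-2 numeric: mm coordinates (x, z) of the centre of
#'   pixel (1, 1).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(data, frame_rate, pixel_size_mm, origin = c(0, 0)) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  stopifnot(is.array(data), length(dim(data)) == 3, dim(data)[3] >= 1)
  if (!is.finite(frame_rate) || frame_rate <= 0) {
    stop("frame_stack: frame_rate must be positive", call. = FALSE)
  }
  if (!is.finite(pixel_size_mm) || pixel_size_mm <= 0) {
    stop("frame_stack: pixel_size_mm must be positive", call. = FALSE)
  }
  structure(data, frame_rate = frame_rate, pixel_size_mm = pixel_size_mm,
            origin = as.numeric(origin), class = "frame_stack")
}

#' @rdname frame_stack
#' @param x A `frame_stack`.
#' @export
n_frames <- function(x) dim(x)[3]

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_stack> %d x %d px, %d frames @ %g Hz, pixel %g mm\n",
              d[1], d[2], d[3], attr(x, "frame_rate"),
              attr(x, "pixel_size_mm")))
  invisible(x)
}

stack_like <- function(template, data) {
  frame_stack(data, attr(template, "frame_rate"),
              attr(template, "pixel_size_mm"), attr(template, "origin"))
}

#' Write / read a frame stack as multi-page TIFF plus metadata sidecar
#'
#' Frames are stored one per TIFF page as 32-bit float, scaled to [0, 1];
#' the scale factor, frame rate, pixel size and origin go to a `<path>.yaml`
#' sidecar so the stack round-trips exactly up to float32 precision.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path (the sidecar is written next to it).
#' @return `read_frame_stack()` returns a [frame_stack()];
#'   `write_frame_stack()` returns `path` invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  scale <- max(stack, 1e-300)
  pages <- lapply(seq_len(n_frames(stack)), function(f) stack[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(
    frame_rate = attr(stack, "frame_rate"),
    pixel_size_mm = attr(stack, "pixel_size_mm"),
    origin = as.numeric(attr(stack, "origin")),
    intensity_scale = scale
  ), paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * meta$intensity_scale
  frame_stack(arr, meta$frame_rate, meta$pixel_size_mm,
              as.numeric(meta$origin))
}
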