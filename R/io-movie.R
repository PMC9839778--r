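#' Time-lapse movie container
#'
#' A `movie_stack` holds a single-plane time-lapse movie as a T x Y x X
#' intensity array together with the physical metadata every downstream
#' measurement needs: the frame interval (as a frame rate in frames/s) and
#' the pixel width in micrometres.
#'
#' @param pixels numeric T x Y x X array, T >= 2 frames.
#' @param frame_rate frames per second, > 0.
#' @param pixel_width micrometres per pixel, > 0.
#' @param origin_label free-text provenance label.
#'
#' @return An object of class `movie_stack` with elements `pixels`,
#'   `frame_rate`, `pixel_width`, `origin_label`.
#' @examples
#' m <- movie_stack(array(0, c(2, 4, 4)), frame_rate = 240, pixel_width = 1.92)
#' dim(m$pixels)
#' @export
movie_stack <- function(pixels, frame_rate, pixel_width, origin_label = "") {
  pixels <- unname(as.array(pixels))
  if (length(dim(pixels)) != 3L) stop("pixels must be a T x Y x X array")
  if (dim(pixels)[1] < 2L) stop("a movie needs at least 2 frames")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("frame_rate must be a single positive number")
  }
  if (!is.numeric(pixel_width) || length(pixel_width) != 1L || pixel_width <= 0) {
    stop("pixel_width must be a single positive number")
  }
  structure(
    list(pixels = pixels, frame_rate = frame_rate,
         pixel_width = pixel_width, origin_label = as.character(origin_label)),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<movie_stack> %d frames, %d x %d px, %g fps, %g um/px\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_width))
  invisible(x)
}

#' Z-stack container
#'
#' A static z-stack: a Z x Y x X array with the axial step and pixel width.
#'
#' @param pixels numeric Z x Y x X array, Z >= 1.
#' @param z_step micrometres between planes, > 0.
#' @param pixel_width micrometres per pixel, > 0.
#' @return An object of class `z_stack`.
#' @export
z_stack <- function(pixels, z_step, pixel_width) {
  pixels <- unname(as.array(pixels))
  if (length(dim(pixels)) == 2L) pixels <- array(pixels, c(1L, dim(pixels)))
  if (length(dim(pixels)) != 3L) stop("pixels must be a Z x Y x X array")
  if (!is.numeric(z_step) || length(z_step) != 1L || z_step <= 0) {
    stop("z_step must be a single positive number")
  }
  if (!is.numeric(pixel_width) || length(pixel_width) != 1L || pixel_width <= 0) {
    stop("pixel_width must be a single positive number")
  }
  structure(list(pixels = pixels, z_step = z_step, pixel_width = pixel_width),
            class = "z_stack")
}

#' @export
print.z_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<z_stack> %d planes, %d x %d px, %g um z-step, %g um/px\n",
              d[1], d[2], d[3], x$z_step, x$pixel_width))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

# encode a page stack (list of Y x X matrices) to TIFF plus scaling metadata
write_pages <- function(pages, path) {
  flat <- unlist(lapply(pages, as.vector))
  integral <- all(flat == round(flat)) && min(flat) >= 0 && max(flat) <= 65535
  if (integral) {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L, reduce = FALSE)
    list(dtype = "uint16", offset = 0, scale = 65535)
  } else {
    offset <- min(flat)
    scale <- max(flat) - offset
    if (scale <= 0) scale <- 1
    tiff::writeTIFF(lapply(pages, function(p) (p - offset) / scale), path,
                    bits.per.sample = 32L, reduce = FALSE)
    list(dtype = "float_scaled", offset = offset, scale = scale)
  }
}

read_pages <- function(path, enc) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = identical(enc$dtype, "uint16")),
    error = function(e) stop("format error reading TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("format error: TIFF pages have non-uniform shapes", call. = FALSE)
  }
  if (identical(enc$dtype, "uint16")) {
    pages
  } else {
    lapply(pages, function(p) p * enc$scale + enc$offset)
  }
}

#' Write / read a movie as multi-page TIFF with a JSON sidecar
#'
#' `write_movie()` stores the frames as a multi-page TIFF (losslessly as
#' 16-bit when the pixel values are integers in 0..65535, otherwise rescaled
#' 32-bit) and the metadata in `<path>.json`. `read_movie()` reverses it;
#' when the sidecar is absent, `frame_rate` and `pixel_width` must be given.
#'
#' @param stack a [movie_stack].
#' @param path TIFF file path.
#' @param frame_rate,pixel_width metadata overrides used when no sidecar
#'   exists; ignored otherwise.
#' @return `read_movie()` returns a [movie_stack]; `write_movie()` returns
#'   `path` invisibly.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$pixels)
  pages <- lapply(seq_len(d[1]), function(t) stack$pixels[t, , ])
  enc <- write_pages(pages, path)
  meta <- c(list(kind = "movie", frame_rate = stack$frame_rate,
                 pixel_width = stack$pixel_width,
                 origin_label = stack$origin_label), enc)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path, frame_rate = NULL, pixel_width = NULL) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  } else {
    meta <- list(dtype = "uint16", origin_label = "")
  }
  if (!is.null(frame_rate)) meta$frame_rate <- frame_rate
  if (!is.null(pixel_width)) meta$pixel_width <- pixel_width
  if (is.null(meta$frame_rate) || is.null(meta$pixel_width)) {
    stop("metadata error: no sidecar for '", path,
         "' and frame_rate/pixel_width not supplied", call. = FALSE)
  }
  pages <- read_pages(path, meta)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  movie_stack(arr, meta$frame_rate, meta$pixel_width,
              origin_label = meta$origin_label %||% "")
}

#' Write / read a z-stack as multi-page TIFF with a JSON sidecar
#'
#' @param stack a [z_stack].
#' @param path TIFF file path.
#' @param z_step,pixel_width metadata overrides used when no sidecar exists.
#' @return `read_zstack()` returns a [z_stack].
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "z_stack"))
  d <- dim(stack$pixels)
  pages <- lapply(seq_len(d[1]), function(z) stack$pixels[z, , ])
  enc <- write_pages(pages, path)
  meta <- c(list(kind = "zstack", z_step = stack$z_step,
                 pixel_width = stack$pixel_width), enc)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zstack
#' @export
read_zstack <- function(path, z_step = NULL, pixel_width = NULL) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  } else {
    meta <- list(dtype = "uint16")
  }
  if (!is.null(z_step)) meta$z_step <- z_step
  if (!is.null(pixel_width)) meta$pixel_width <- pixel_width
  if (is.null(meta$z_step) || is.null(meta$pixel_width)) {
    stop("metadata error: no sidecar for '", path,
         "' and z_step/pixel_width not supplied", call. = FALSE)
  }
  pages <- read_pages(path, meta)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  z_stack(arr, meta$z_step, meta$pixel_width)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
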