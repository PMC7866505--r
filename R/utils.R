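# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

vec_norm <- function(x) sqrt(sum(x^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Spatial and temporal capture resolution
#'
#' Resolution of a video capture: the physical length covered along one image
#' axis divided by the pixel count of that axis, and the frame period.
#'
#' @param length_m physical length covered along the image axis, metres.
#' @param pixels number of pixels along that axis.
#' @param fps frame rate, frames per second.
#' @return `spatial_resolution_mm()`: millimetres per pixel.
#'   `temporal_resolution_ms()`: milliseconds per frame.
#'   `interframe_displacement_cm()`: centimetres travelled between consecutive
#'   frames at velocity `v_mps`.
#' @examples
#' spatial_resolution_mm(4, 1920)     # ~2.1 mm/px
#' temporal_resolution_ms(240)        # ~4.2 ms
#' interframe_displacement_cm(1.4, 240)
#' @export
spatial_resolution_mm <- function(length_m, pixels) {
  stopifnot(length_m > 0, pixels > 0)
  1000 * length_m / pixels
}

#' @rdname spatial_resolution_mm
#' @export
temporal_resolution_ms <- function(fps) {
  stopifnot(fps > 0)
  1000 / fps
}

#' @rdname spatial_resolution_mm
#' @param v_mps barbell velocity in metres per second.
#' @export
interframe_displacement_cm <- function(v_mps, fps) {
  stopifnot(fps > 0)
  100 * v_mps / fps
}
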