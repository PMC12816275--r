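#' Screen and viewing geometry
#'
#' Describes the physical display and viewing distance used to convert
#' on-screen pixel displacements into visual angle. Pixels are assumed
#' square; the physical width and height are derived from the diagonal and
#' the pixel aspect ratio.
#'
#' Defaults correspond to a 23.8-inch 1920x1080 monitor viewed at 70 cm,
#' a common configuration for screen-based consumer eye trackers.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param diagonal_mm Physical diagonal of the display in millimetres.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#'
#' @return An object of class `screen_geometry` with fields `width_px`,
#'   `height_px`, `diagonal_mm`, `viewing_distance_mm` and the derived
#'   `mm_per_px` pixel pitch.
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(100, 0, geom)
#' @export
screen_geometry <- function(width_px = 1920L, height_px = 1080L,
                            diagonal_mm = 23.8 * 25.4,
                            viewing_distance_mm = 700) {
  vals <- c(width_px, height_px, diagonal_mm, viewing_distance_mm)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be finite and > 0", call. = FALSE)
  }
  diag_px <- sqrt(width_px^2 + height_px^2)
  structure(
    list(
      width_px = as.integer(round(width_px)),
      height_px = as.integer(round(height_px)),
      diagonal_mm = diagonal_mm,
      viewing_distance_mm = viewing_distance_mm,
      mm_per_px = diagonal_mm / diag_px
    ),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %d x %d px, diagonal %.0f mm, viewing distance %.0f mm\n",
    x$width_px, x$height_px, x$diagonal_mm, x$viewing_distance_mm
  ))
  cat(sprintf("  pixel pitch %.4f mm/px; 1 deg ~ %.2f px at screen centre\n",
              x$mm_per_px, deg_to_px(1, x)))
  invisible(x)
}

is_screen_geometry <- function(x) inherits(x, "screen_geometry")

#' Convert a pixel displacement to visual angle
#'
#' Returns the visual angle (degrees) subtended by the Euclidean on-screen
#' displacement `(dx, dy)` at the configured viewing distance, via the
#' arctangent of physical displacement over distance. Vectorised over
#' `dx`/`dy`.
#'
#' @param dx,dy Displacement components in pixels.
#' @param geom A [screen_geometry()].
#' @return Visual angle in degrees (numeric, same length as the inputs).
#' @export
px_to_deg <- function(dx, dy = 0, geom = screen_geometry()) {
  stopifnot(is_screen_geometry(geom))
  if (!all(is.finite(dx)) || !all(is.finite(dy))) {
    stop("px_to_deg: non-finite displacement", call. = FALSE)
  }
  disp_mm <- sqrt(dx^2 + dy^2) * geom$mm_per_px
  atan2(disp_mm, geom$viewing_distance_mm) * 180 / pi
}

# Inverse of px_to_deg for small angles along one axis (used for config
# values expressed in degrees, e.g. ROI linkage radius).
deg_to_px <- function(deg, geom = screen_geometry()) {
  stopifnot(is_screen_geometry(geom))
  tan(deg * pi / 180) * geom$viewing_distance_mm / geom$mm_per_px
}
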