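#' Scatterer geometry
#'
#' Shape and dimensions of a single scatterer resting on a substrate. A
#' \emph{dome} is a hemisphere flat-face-down (the model of a
#' substrate-deformed cell); a \emph{semi-capsule} is a dome elongated by a
#' half-cylindrical mid-section of length \code{L} between two
#' quarter-sphere end caps, so its projected footprint is a stadium (disk
#' of radius \code{R} plus a \code{2R x L} rectangle). Illumination is
#' normal to the flat face throughout.
#'
#' @param shape one of \code{"sphere"}, \code{"dome"},
#'   \code{"semi-cylinder"}, \code{"semi-capsule"}
#' @param R end-cap/base radius in micrometers, > 0
#' @param L elongation in micrometers (semi-capsule only; >= 0; \code{L = 0}
#'   degenerates to a dome). Ignored, with a warning, for other shapes.
#' @return an object of class \code{scatterer_geometry}
#' @export
scatterer_geometry <- function(shape = c("sphere", "dome", "semi-cylinder",
                                         "semi-capsule"),
                               R, L = 0) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R))
  if (R <= 0) stop("radius R must be positive (micrometers)")
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L))
  if (shape == "semi-capsule") {
    if (L < 0) stop("elongation L must be non-negative (micrometers)")
  } else if (L != 0) {
    warning("elongation L is ignored for shape '", shape, "'")
    L <- 0
  }
  structure(list(shape = shape, R = R, L = L), class = "scatterer_geometry")
}

#' @export
print.scatterer_geometry <- function(x, ...) {
  cat(sprintf("scatterer_geometry: %s, R = %g um%s\n", x$shape, x$R,
              if (x$shape == "semi-capsule") sprintf(", L = %g um", x$L) else ""))
  invisible(x)
}

# Projected-thickness (chord) profile, projected area and integration region
# of a geometry, in micrometers; used to drive the numerical ADA oracle.
# Region types: "radial" (chord a function of radius r over a disk),
# "strip" (function of the transverse coordinate y, per unit length), and
# "xy" (general 2-D region with half-width(x), chord(x, y)).
#' Chord profile of a scatterer geometry
#'
#' Returns the straight-ray thickness profile, projected area, and
#' integration region of a \code{\link{scatterer_geometry}}, in the form
#' consumed by \code{\link{qext_ada_numeric}}. All lengths in micrometers.
#'
#' @param geom a \code{\link{scatterer_geometry}}
#' @return list with elements \code{chord} (a function), \code{area}
#'   (projected area, um^2, or um per unit length for the semi-cylinder)
#'   and \code{region} (a list describing the integration domain)
#' @export
geometry_chord <- function(geom) {
  stopifnot(inherits(geom, "scatterer_geometry"))
  R <- geom$R
  L <- geom$L
  switch(geom$shape,
    "sphere" = list(
      chord = function(r) 2 * sqrt(pmax(R^2 - r^2, 0)),
      area = pi * R^2,
      region = list(type = "radial", rmax = R)),
    "dome" = list(
      chord = function(r) sqrt(pmax(R^2 - r^2, 0)),
      area = pi * R^2,
      region = list(type = "radial", rmax = R)),
    "semi-cylinder" = list(
      chord = function(y) sqrt(pmax(R^2 - y^2, 0)),
      area = 2 * R,
      region = list(type = "strip", halfwidth = R)),
    "semi-capsule" = list(
      chord = function(x, y) {
        dx <- pmax(abs(x) - L / 2, 0)
        sqrt(pmax(R^2 - dx^2 - y^2, 0))
      },
      area = pi * R^2 + 2 * R * L,
      region = list(
        type = "xy",
        xlim = c(-(L / 2 + R), L / 2 + R),
        halfwidth = function(x) {
          dx <- pmax(abs(x) - L / 2, 0)
          sqrt(pmax(R^2 - dx^2, 0))
        })))
}
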