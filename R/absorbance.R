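#' Aperture geometry of a transmission measurement
#'
#' Geometric cross sections of the sample (\code{g}) and of the detector
#' aperture (\code{G}) that set the fraction of the beam intercepted by the
#' scatterer in a transmission measurement; the absorbance model assumes
#' \code{G >> g}.
#'
#' @param g sample geometric cross section (um^2), 0 < g < G
#' @param G detector/aperture geometric cross section (um^2)
#' @return an object of class \code{aperture_geometry}
#' @export
aperture_geometry <- function(g, G) {
  stopifnot(is.numeric(g), is.numeric(G), length(g) == 1L, length(G) == 1L)
  if (!(g > 0 && g < G)) stop("aperture geometry requires 0 < g < G")
  structure(list(g = g, G = G), class = "aperture_geometry")
}

#' Apparent absorbance from an extinction efficiency
#'
#' Maps \eqn{Q_{ext}} to the apparent absorbance recorded in transmission,
#' \deqn{Z = -\log_{10}\!\left(1 - \frac{g}{G} Q_{ext}\right)
#'   \approx \frac{1}{\ln 10}\frac{g}{G} Q_{ext},}
#' where the linearized form holds for \eqn{(g/G) Q_{ext} \ll 1}. Both
#' forms are returned; \code{z} holds the one selected by
#' \code{linearized}.
#'
#' @param q an \code{\link{extinction_spectrum}}
#' @param ap an \code{\link{aperture_geometry}}
#' @param linearized if \code{TRUE}, \code{z} holds the linearized form
#' @return an object of class \code{absorbance_spectrum} with fields
#'   \code{grid}, \code{z}, \code{z_exact}, \code{z_linear},
#'   \code{linearized}
#' @export
#' @examples
#' q <- qext_vdh_sphere(1.5, R = 10, grid = default_grid())
#' z <- absorbance_from_qext(q, aperture_geometry(1, 100))
#' range(z$z)
absorbance_from_qext <- function(q, ap, linearized = FALSE) {
  stopifnot(inherits(q, "extinction_spectrum"),
            inherits(ap, "aperture_geometry"))
  frac <- ap$g / ap$G * q$qext
  if (any(frac >= 1))
    stop("(g/G) * Q_ext >= 1: total extinction exceeds the aperture model")
  z_exact <- -log10(1 - frac)
  z_linear <- frac / log(10)
  structure(list(grid = q$grid,
                 z = if (linearized) z_linear else z_exact,
                 z_exact = z_exact, z_linear = z_linear,
                 linearized = linearized),
            class = "absorbance_spectrum")
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("absorbance_spectrum (%s form): %d points, Z in [%.4g, %.4g]\n",
              if (x$linearized) "linearized" else "exact",
              length(x$grid), min(x$z), max(x$z)))
  invisible(x)
}
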