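#' Numerical anomalous-diffraction extinction efficiency (quadrature oracle)
#'
#' Evaluates the ADA extinction integral
#' \deqn{Q_{ext}(\nu) = \frac{2}{A} \iint
#'   \mathrm{Re}\{1 - e^{i\,2\pi\nu(m(\nu)-1)\,t(x,y)}\}\, dA}
#' by adaptive quadrature for an arbitrary chord (thickness) profile over a
#' projected region. This is the brute-force arbiter against which every
#' closed-form model in the package is checked; it shares no code with the
#' closed forms.
#'
#' Three region types are supported: \code{"radial"} (chord a function of
#' the radius over a disk, reduced to a 1-D radial integral),
#' \code{"strip"} (chord a function of the transverse coordinate of an
#' infinitely long scatterer, per unit length), and \code{"xy"} (general
#' 2-D region \eqn{|y| \le} \code{halfwidth(x)}, nested quadrature).
#'
#' @param m a \code{\link{refindex_spectrum}} or single (complex) number
#' @param chord chord function (micrometers): of \code{r} for
#'   \code{"radial"}, of \code{y} for \code{"strip"}, of \code{(x, y)} for
#'   \code{"xy"}; must be vectorized in its (last) argument
#' @param area projected area in um^2 (um for \code{"strip"}, per unit
#'   length)
#' @param region list describing the domain: \code{list(type = "radial",
#'   rmax =)}, \code{list(type = "strip", halfwidth =)} or
#'   \code{list(type = "xy", xlim =, halfwidth = function(x))}
#' @param grid wavenumbers (cm^-1); defaults to the grid of \code{m}
#' @param geometry optional \code{\link{scatterer_geometry}} recorded as
#'   provenance
#' @param rel.tol requested relative quadrature tolerance
#' @return an \code{\link{extinction_spectrum}} with method
#'   \code{"ada-numeric"}
#' @seealso \code{\link{geometry_chord}} for ready-made chord/area/region
#'   triples of the package geometries
#' @export
#' @examples
#' gc <- geometry_chord(scatterer_geometry("dome", R = 10))
#' q <- qext_ada_numeric(1.5, gc$chord, gc$area, gc$region,
#'                       grid = c(1000, 2000, 3000))
#' q$qext
qext_ada_numeric <- function(m, chord, area, region, grid = NULL,
                             geometry = NULL, rel.tol = 1e-9) {
  ri <- resolve_index(m, grid)
  stopifnot(is.function(chord), is.numeric(area), length(area) == 1L)
  if (area <= 0) stop("projected area must be positive")
  type <- match.arg(region$type, c("radial", "strip", "xy"))
  phase <- 2 * pi * UM_PER_CM * ri$grid * (ri$mc - 1)   # per micrometer
  q <- vapply(seq_along(ri$grid), function(i) {
    ph <- phase[i]
    integrand1 <- switch(type,
      radial = function(r) 2 * pi * r * Re(1 - exp(1i * ph * chord(r))),
      strip  = function(y) Re(1 - exp(1i * ph * chord(y))),
      xy     = NULL)
    val <- if (type == "radial") {
      safe_integrate(integrand1, 0, region$rmax, rel.tol)
    } else if (type == "strip") {
      safe_integrate(integrand1, -region$halfwidth, region$halfwidth, rel.tol)
    } else {
      outer_f <- function(xv) {
        vapply(xv, function(x) {
          hw <- region$halfwidth(x)
          if (hw <= 0) return(0)
          safe_integrate(function(y) Re(1 - exp(1i * ph * chord(x, y))),
                         -hw, hw, rel.tol)
        }, numeric(1))
      }
      safe_integrate(outer_f, region$xlim[1], region$xlim[2], rel.tol)
    }
    2 / area * val
  }, numeric(1))
  if (is.null(geometry)) geometry <- scatterer_geometry("sphere", R = 1)
  extinction_spectrum(ri$grid, q, geometry, "ada-numeric")
}

safe_integrate <- function(f, lower, upper, rel.tol) {
  res <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = rel.tol,
                     abs.tol = rel.tol, subdivisions = 400L,
                     stop.on.error = FALSE),
    error = function(e) stop("quadrature failed: ", conditionMessage(e)))
  if (!res$message %in% c("OK", "maximum number of subdivisions reached") &&
      !grepl("probably divergent", res$message))
    stop("quadrature did not converge (", res$message,
         "); achieved estimate ", format(res$value))
  res$value
}

#' Numerical ADA extinction for a named geometry
#'
#' Convenience wrapper combining \code{\link{geometry_chord}} and
#' \code{\link{qext_ada_numeric}}.
#'
#' @param m a \code{\link{refindex_spectrum}} or single (complex) number
#' @param geom a \code{\link{scatterer_geometry}}
#' @inheritParams qext_ada_numeric
#' @return an \code{\link{extinction_spectrum}}
#' @export
qext_ada_geometry <- function(m, geom, grid = NULL, rel.tol = 1e-9) {
  gc <- geometry_chord(geom)
  qext_ada_numeric(m, gc$chord, gc$area, gc$region, grid = grid,
                   geometry = geom, rel.tol = rel.tol)
}
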