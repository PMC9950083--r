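# Closed-form anomalous-diffraction (van de Hulst) extinction efficiencies.
#
# In the anomalous diffraction approximation a ray traverses the scatterer
# undeflected, acquiring the phase factor exp(i k0 (m-1) t) over the local
# chord t; interference of this field with the unscattered field gives
# Q_ext = (2/A) Int Re{1 - exp(i k0 (m-1) t(x,y))} dA over the projected
# area A. With m = n + ik (k >= 0) the exponent decays under absorption.
# Units: wavenumbers nu in cm^-1, lengths in micrometers; k0 = 2 pi nu and
# the um -> cm conversion factor 1e-4 enter together as 2e-4 * pi * nu.

UM_PER_CM <- 1e-4

#' Extinction-efficiency spectrum
#'
#' Container for \eqn{Q_{ext}(\nu)} with geometry and method provenance.
#' The size parameter \eqn{x = 2\pi\nu R} and complex phase parameter
#' \eqn{\rho = 2x(m-1)} are stored per grid point.
#'
#' @param grid wavenumbers (cm^-1)
#' @param qext extinction efficiency per grid point (>= 0 up to roundoff)
#' @param geometry a \code{\link{scatterer_geometry}}
#' @param method one of \code{"vdh-closed-form"}, \code{"ada-numeric"},
#'   \code{"mie-exact"}
#' @param x size parameter per grid point (optional)
#' @param rho complex phase parameter per grid point (optional)
#' @return an object of class \code{extinction_spectrum}
#' @export
extinction_spectrum <- function(grid, qext, geometry, method, x = NULL,
                                rho = NULL) {
  check_grid(grid)
  stopifnot(length(qext) == length(grid), is.numeric(qext))
  if (any(!is.finite(qext))) stop("Q_ext must be finite")
  if (any(qext < -1e-9)) stop("Q_ext must be non-negative")
  method <- match.arg(method, c("vdh-closed-form", "ada-numeric", "mie-exact"))
  structure(list(grid = grid, qext = pmax(qext, 0), geometry = geometry,
                 method = method, x = x, rho = rho),
            class = "extinction_spectrum")
}

#' @export
print.extinction_spectrum <- function(x, ...) {
  cat(sprintf("extinction_spectrum [%s, %s]: %d points, Q_ext in [%.4g, %.4g]\n",
              x$geometry$shape, x$method, length(x$grid),
              min(x$qext), max(x$qext)))
  invisible(x)
}

# Resolve the refractive index argument: a refindex_spectrum (grid taken
# from it, or checked against an explicit grid), or a single (possibly
# complex) number used uniformly on an explicit grid.
resolve_index <- function(m, grid) {
  if (inherits(m, "refindex_spectrum")) {
    if (!is.null(grid)) {
      if (length(grid) != length(m$grid) || any(grid != m$grid))
        stop("explicit grid does not match the refractive-index grid")
    }
    list(grid = m$grid, mc = complex(real = m$n, imaginary = m$k))
  } else if (is.numeric(m) || is.complex(m)) {
    if (length(m) != 1L) stop("non-spectral m must be a single number")
    if (is.null(grid)) stop("a wavenumber grid is required with scalar m")
    check_grid(grid)
    mc <- as.complex(m)
    if (Im(mc) < 0) stop("imaginary index must be non-negative")
    list(grid = grid, mc = rep(mc, length(grid)))
  } else {
    stop("m must be a refindex_spectrum or a single (complex) number")
  }
}

# van de Hulst kernel: Q = 4 Re K(w), K(w) = 1/2 + e^-w/w + (e^-w - 1)/w^2,
# w = -i rho with rho = 2 x (m - 1). Power series near w = 0 avoids the
# catastrophic cancellation of the direct form.
vdh_kernel <- function(w) {
  out <- complex(length(w))
  small <- Mod(w) < 1e-2
  if (any(small)) {
    ws <- w[small]
    s <- 0 + 0i
    term <- rep(1 + 0i, length(ws))
    # K(w) = sum_{p>=1} (-1)^(p+1) (p+1)/(p+2)! w^p
    for (p in 1:10) {
      term <- term * ws
      s <- s + (-1)^(p + 1) * (p + 1) / factorial(p + 2) * term
    }
    out[small] <- s
  }
  if (any(!small)) {
    wl <- w[!small]
    out[!small] <- 0.5 + exp(-wl) / wl + (exp(-wl) - 1) / wl^2
  }
  out
}

#' Van de Hulst extinction efficiency of a sphere
#'
#' Anomalous-diffraction \eqn{Q_{ext}} for a homogeneous (possibly
#' absorbing) sphere:
#' \deqn{Q = 4\,\mathrm{Re}\{ \tfrac12 + e^{-w}/w + (e^{-w}-1)/w^2 \},
#'   \qquad w = -i\rho,\ \rho = 2x(m-1),\ x = 2\pi\nu R.}
#' For real \eqn{m} this reduces to the familiar
#' \eqn{Q = 2 - (4/\rho)\sin\rho + (4/\rho^2)(1-\cos\rho)}.
#'
#' @param m a \code{\link{refindex_spectrum}}, or a single (complex) number
#' @param R sphere radius in micrometers
#' @param grid wavenumbers (cm^-1); defaults to the grid of \code{m}
#' @return an \code{\link{extinction_spectrum}}
#' @export
#' @examples
#' q <- qext_vdh_sphere(1.5, R = 10, grid = default_grid())
#' max(q$qext)
qext_vdh_sphere <- function(m, R, grid = NULL) {
  ri <- resolve_index(m, grid)
  geom <- scatterer_geometry("sphere", R = R)
  if (any(Re(ri$mc) < 1))
    warning("refractive index with n < 1 encountered; formula still defined")
  x <- 2 * pi * ri$grid * R * UM_PER_CM
  rho <- 2 * x * (ri$mc - 1)
  q <- 4 * Re(vdh_kernel(-1i * rho))
  extinction_spectrum(ri$grid, q, geom, "vdh-closed-form", x = x, rho = rho)
}

#' Extinction efficiency of a dome (hemisphere on its flat face)
#'
#' The chord through a dome illuminated along its axis is half the sphere
#' chord, \eqn{t(r) = \sqrt{R^2-r^2}}, so the dome \eqn{Q_{ext}} is the
#' sphere solution evaluated at half the phase parameter (the factor-2
#' reduced path length of rays traversing a dome relative to a sphere).
#'
#' @inheritParams qext_vdh_sphere
#' @return an \code{\link{extinction_spectrum}}
#' @export
qext_dome <- function(m, R, grid = NULL) {
  ri <- resolve_index(m, grid)
  geom <- scatterer_geometry("dome", R = R)
  x <- 2 * pi * ri$grid * R * UM_PER_CM
  rho <- 2 * x * (ri$mc - 1)
  q <- 4 * Re(vdh_kernel(-1i * rho / 2))
  extinction_spectrum(ri$grid, q, geom, "vdh-closed-form", x = x, rho = rho)
}

#' Extinction efficiency of an infinitely long semi-cylinder
#'
#' Anomalous-diffraction \eqn{Q_{ext}} per unit length for a half-cylinder
#' lying flat-face-down under normal incidence, normalized by the projected
#' width \eqn{2R}. Writing \eqn{c = x(m-1)}, integrating the chord
#' \eqn{t(y)=\sqrt{R^2-y^2}} gives the closed form
#' \deqn{Q = \pi\,\mathrm{Re}\{ \mathbf{H}_1(c) - i J_1(c) \},}
#' with \eqn{\mathbf{H}_1} the Struve function and \eqn{J_1} the Bessel
#' function, both of complex argument for absorbing media.
#'
#' @inheritParams qext_vdh_sphere
#' @return an \code{\link{extinction_spectrum}}
#' @export
qext_semicylinder <- function(m, R, grid = NULL) {
  ri <- resolve_index(m, grid)
  geom <- scatterer_geometry("semi-cylinder", R = R)
  x <- 2 * pi * ri$grid * R * UM_PER_CM
  cc <- x * (ri$mc - 1)
  q <- pi * Re(cstruve_h1(cc) - 1i * cbessel_j1(cc))
  extinction_spectrum(ri$grid, q, geom, "vdh-closed-form", x = x,
                      rho = 2 * cc)
}

#' Extinction efficiency of a semi-capsule (elongated dome)
#'
#' The projected footprint of a semi-capsule is a stadium: a disk of radius
#' \code{R} (the two end caps) plus a \code{2R x L} rectangle (the
#' half-cylindrical mid-section). Because the ADA integral is additive over
#' disjoint projection regions, \eqn{Q_{ext}} is the projected-area-weighted
#' combination
#' \deqn{Q = \frac{\pi R^2\,Q_{dome} + 2RL\,Q_{semicyl}}{\pi R^2 + 2RL}.}
#' \code{L = 0} reduces identically to the dome; as \eqn{L} grows, \eqn{Q}
#' approaches the semi-cylinder solution.
#'
#' @inheritParams qext_vdh_sphere
#' @param L elongation in micrometers, >= 0
#' @return an \code{\link{extinction_spectrum}}
#' @export
qext_semicapsule <- function(m, R, L, grid = NULL) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L < 0)
    stop("elongation L must be a single non-negative number (micrometers)")
  ri <- resolve_index(m, grid)
  geom <- scatterer_geometry("semi-capsule", R = R, L = L)
  qd <- qext_dome(m, R, grid)
  qc <- qext_semicylinder(m, R, grid)
  fd <- pi * R^2 / (pi * R^2 + 2 * R * L)
  fc <- 2 * R * L / (pi * R^2 + 2 * R * L)
  q <- fd * qd$qext + fc * qc$qext
  extinction_spectrum(ri$grid, q, geom, "vdh-closed-form", x = qd$x,
                      rho = qd$rho)
}

#' Locate the first wiggle maximum of an extinction spectrum
#'
#' Finds the wavenumber of the first interior local maximum of
#' \eqn{Q_{ext}(\nu)}, with optional boxcar smoothing to suppress sharp
#' ripple resonances (present in exact Mie curves but not in ADA curves)
#' before locating the broad wiggle. The grid position is refined by a
#' parabolic fit through the three points around the maximum.
#'
#' @param es an \code{\link{extinction_spectrum}}
#' @param smooth_window half-width of the boxcar smoother in grid points
#'   (0 = no smoothing)
#' @return wavenumber of the first wiggle maximum (cm^-1), or \code{NA} if
#'   no interior maximum exists on the grid
#' @export
first_wiggle_maximum <- function(es, smooth_window = 0L) {
  stopifnot(inherits(es, "extinction_spectrum"))
  q <- es$qext
  v <- es$grid
  if (smooth_window > 0L) {
    w <- 2L * as.integer(smooth_window) + 1L
    q <- as.numeric(stats::filter(q, rep(1 / w, w), sides = 2))
    keep <- !is.na(q)
    q <- q[keep]
    v <- v[keep]
  }
  n <- length(q)
  if (n < 3L) return(NA_real_)
  i <- which(q[2:(n - 1)] > q[1:(n - 2)] & q[2:(n - 1)] >= q[3:n])
  if (length(i) == 0L) return(NA_real_)
  i <- i[1] + 1L
  # parabolic refinement on (v, q) around the grid maximum
  d1 <- (q[i + 1L] - q[i - 1L]) / 2
  d2 <- q[i + 1L] - 2 * q[i] + q[i - 1L]
  if (d2 >= 0) return(v[i])
  h <- v[i + 1L] - v[i]
  v[i] - d1 / d2 * h
}
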