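#' Exact Mie extinction efficiency of a homogeneous sphere
#'
#' Full Mie-series \eqn{Q_{ext}} for a homogeneous sphere of (possibly
#' complex) refractive index, the exact electromagnetic reference against
#' which the anomalous-diffraction approximations are compared. The series
#' is truncated at the Wiscombe order \eqn{n_{max} = \lceil x + 4x^{1/3} +
#' 2\rceil}; the logarithmic derivative \eqn{D_n(mx)} is generated by
#' downward recurrence started 15 orders above \eqn{n_{max}}, and the
#' Riccati-Bessel functions \eqn{\psi_n(x)}, \eqn{\chi_n(x)} by upward
#' recurrence.
#'
#' Unlike the ADA curves, exact Mie curves carry sharp ripple resonances
#' superimposed on the broad wiggles; use the smoothing option of
#' \code{\link{first_wiggle_maximum}} when locating wiggles.
#'
#' @inheritParams qext_vdh_sphere
#' @param max_x guard against overflow: size parameters above this bound
#'   raise an error with a diagnostic
#' @return an \code{\link{extinction_spectrum}} with method
#'   \code{"mie-exact"}
#' @export
#' @examples
#' q <- qext_mie_exact(1.5, R = 1, grid = c(1000, 2000))
#' q$qext
qext_mie_exact <- function(m, R, grid = NULL, max_x = 2000) {
  ri <- resolve_index(m, grid)
  geom <- scatterer_geometry("sphere", R = R)
  x <- 2 * pi * ri$grid * R * UM_PER_CM
  if (any(x > max_x))
    stop(sprintf("size parameter x = %.3g exceeds the overflow guard (%g)",
                 max(x), max_x))
  q <- vapply(seq_along(x), function(i) mie_qext_one(x[i], ri$mc[i]),
              numeric(1))
  extinction_spectrum(ri$grid, q, geom, "mie-exact", x = x,
                      rho = 2 * x * (ri$mc - 1))
}

# Single-size-parameter Mie Q_ext (BHMIE scheme).
mie_qext_one <- function(x, mc) {
  if (x <= 0) stop("size parameter must be positive")
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  nmx <- nmax + 15L
  mx <- mc * x
  # downward recurrence for D_n(mx) = psi_n'(mx)/psi_n(mx), D_nmx ~ 0
  d <- complex(nmx)                      # d[n] holds D_n
  for (n in nmx:2) {
    rn <- n / mx
    d[n - 1L] <- rn - 1 / (d[n] + rn)
  }
  psi0 <- cos(x); psi1 <- sin(x)         # psi_{-1}, psi_0
  chi0 <- -sin(x); chi1 <- cos(x)        # chi_{-1}, chi_0
  xi0 <- complex(real = psi0, imaginary = -chi0)
  xi1 <- complex(real = psi1, imaginary = -chi1)
  s <- 0
  for (n in 1:nmax) {
    psi2 <- (2 * n - 1) / x * psi1 - psi0
    chi2 <- (2 * n - 1) / x * chi1 - chi0
    xi2 <- complex(real = psi2, imaginary = -chi2)
    dn <- d[n]
    ta <- dn / mc + n / x
    tb <- dn * mc + n / x
    an <- (ta * psi2 - psi1) / (ta * xi2 - xi1)
    bn <- (tb * psi2 - psi1) / (tb * xi2 - xi1)
    if (!is.finite(Re(an)) || !is.finite(Re(bn)))
      stop(sprintf("Mie series overflow at order %d (x = %.3g)", n, x))
    s <- s + (2 * n + 1) * Re(an + bn)
    psi0 <- psi1; psi1 <- psi2
    chi0 <- chi1; chi1 <- chi2
    xi1 <- xi2
  }
  2 / x^2 * s
}

#' Rayleigh small-particle extinction efficiency
#'
#' Closed-form small-particle (\eqn{x \ll 1}) limit
#' \eqn{Q = (8/3) x^4 |(m^2-1)/(m^2+2)|^2} for a non-absorbing sphere,
#' used as an independent check of the exact Mie series.
#'
#' @param x size parameter
#' @param m refractive index (single number)
#' @return Rayleigh \eqn{Q_{ext}}
#' @export
qext_rayleigh <- function(x, m) {
  mc <- as.complex(m)
  8 / 3 * x^4 * Mod((mc^2 - 1) / (mc^2 + 2))^2
}
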