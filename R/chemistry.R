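#' Lorentzian absorption band
#'
#' A single Lorentzian line in the imaginary part of the refractive index,
#' parameterized by its center wavenumber, full width at half maximum, and
#' peak amplitude. The band profile is
#' \deqn{k(\nu) = a \, \frac{(w/2)^2}{(\nu - c)^2 + (w/2)^2},}
#' so \code{amplitude} is the value of \eqn{k} attained exactly at
#' \code{center}, and \eqn{k} drops to half that value at
#' \code{center +/- width/2}.
#'
#' @param center band center (cm^-1), must be positive
#' @param width full width at half maximum (cm^-1), must be positive
#' @param amplitude peak imaginary index (dimensionless), must be >= 0
#' @return an object of class \code{lorentz_band}
#' @export
#' @examples
#' lorentz_band(1500, 60, 0.1)
lorentz_band <- function(center, width, amplitude) {
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(width), length(width) == 1L, is.finite(width),
            is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude))
  if (center <= 0) stop("band center must be positive (cm^-1)")
  if (width <= 0) stop("band width must be positive (cm^-1)")
  if (amplitude < 0) stop("band amplitude must be non-negative")
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "lorentz_band")
}

#' Chemistry model: Lorentz bands plus a constant real-index offset
#'
#' The generative description of a material's "chemistry": an ordered set of
#' Lorentzian absorption bands defining the imaginary index \eqn{k(\nu)},
#' plus a constant offset for the real part \eqn{n(\nu)} about which the
#' Kramers-Kronig dispersion fluctuates.
#'
#' @param bands a list of \code{\link{lorentz_band}} objects; band centers
#'   must be distinct (they are sorted into increasing order)
#' @param n_offset constant real-index offset, must exceed 1 (default 1.5,
#'   typical of hydrated organic material in the mid-infrared)
#' @return an object of class \code{chemistry_model}
#' @seealso \code{\link{default_chemistry}}, \code{\link{shift_bands}},
#'   \code{\link{synth_refractive_index}}
#' @export
chemistry_model <- function(bands = list(), n_offset = 1.5) {
  stopifnot(is.list(bands))
  for (b in bands) {
    if (!inherits(b, "lorentz_band")) stop("all bands must be lorentz_band objects")
  }
  if (!is.numeric(n_offset) || length(n_offset) != 1L || !is.finite(n_offset))
    stop("n_offset must be a single finite number")
  if (n_offset <= 1) stop("n_offset must exceed 1")
  centers <- vapply(bands, `[[`, numeric(1), "center")
  if (anyDuplicated(centers)) stop("band centers must be distinct")
  bands <- bands[order(centers)]
  structure(list(bands = bands, n_offset = n_offset), class = "chemistry_model")
}

#' @export
print.chemistry_model <- function(x, ...) {
  cat("chemistry_model:", length(x$bands), "Lorentz band(s), n_offset =",
      x$n_offset, "\n")
  for (b in x$bands) {
    cat(sprintf("  center %8.1f cm^-1  FWHM %6.1f cm^-1  amplitude %.4g\n",
                b$center, b$width, b$amplitude))
  }
  invisible(x)
}

#' Default four-band chemistry
#'
#' Bands at 1500, 2010, 3000 and 5400 cm^-1 with a real-index offset of 1.5.
#' Widths (60 cm^-1 FWHM) and amplitudes (0.1) are common magnitudes for
#' mid-infrared absorption bands of organic material and are small compared
#' to the offset.
#'
#' @param width full width at half maximum applied to every band (cm^-1)
#' @param amplitude peak imaginary index applied to every band
#' @param n_offset constant real-index offset
#' @return a \code{\link{chemistry_model}}
#' @export
default_chemistry <- function(width = 60, amplitude = 0.1, n_offset = 1.5) {
  centers <- c(1500, 2010, 3000, 5400)
  chemistry_model(lapply(centers, lorentz_band, width = width,
                         amplitude = amplitude),
                  n_offset = n_offset)
}

#' Default wavenumber grid
#'
#' A uniform grid from 1000 to 6000 cm^-1 in steps of 2 cm^-1, covering all
#' bands of \code{\link{default_chemistry}} with margin on both sides.
#'
#' @param start,stop,step grid limits and spacing (cm^-1)
#' @return a numeric vector of wavenumbers
#' @export
default_grid <- function(start = 1000, stop = 6000, step = 2) {
  if (start <= 0 || stop <= start || step <= 0) stop("invalid grid specification")
  seq(start, stop, by = step)
}

check_grid <- function(grid) {
  if (length(grid) == 0L) stop("wavenumber grid is empty")
  if (!is.numeric(grid) || anyNA(grid)) stop("grid must be numeric without NA")
  if (any(grid <= 0)) stop("wavenumbers must be positive")
  if (length(grid) > 1L && any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  invisible(grid)
}

#' Imaginary refractive index from a chemistry model
#'
#' Sums the Lorentzian profiles of all bands on the given wavenumber grid.
#' A band whose center lies outside the grid still contributes its tails
#' (with a warning), matching the convention that the chemistry is defined
#' on the whole axis and merely sampled on the grid.
#'
#' @param chem a \code{\link{chemistry_model}}
#' @param grid strictly increasing, positive wavenumbers (cm^-1)
#' @return numeric vector of \eqn{k(\nu)} (>= 0) along \code{grid}
#' @export
synth_imag_index <- function(chem, grid) {
  stopifnot(inherits(chem, "chemistry_model"))
  check_grid(grid)
  k <- numeric(length(grid))
  for (b in chem$bands) {
    if (b$center < grid[1] || b$center > grid[length(grid)])
      warning(sprintf("band at %.6g cm^-1 lies outside the grid; tails still evaluated",
                      b$center))
    g <- b$width / 2
    k <- k + b$amplitude * g^2 / ((grid - b$center)^2 + g^2)
  }
  k
}

#' Closed-form complex Lorentzian refractive index
#'
#' The analytic complex index whose imaginary part is exactly the Lorentzian
#' band sum of \code{\link{synth_imag_index}} and whose real part is its
#' exact Hilbert transform (single-pole Lorentz oscillator):
#' \deqn{m(\nu) = n_{off} + \sum_b a_b\, \gamma_b\,
#'   \frac{(c_b-\nu) + i\gamma_b}{(\nu-c_b)^2 + \gamma_b^2},
#'   \qquad \gamma_b = w_b/2.}
#' The dispersive real part lies above \code{n_offset} on the low-wavenumber
#' side of each isolated band (anomalous dispersion). This closed form
#' serves as the independent oracle for the numerical Kramers-Kronig
#' transform in \code{\link{kk_real_index}}.
#'
#' @inheritParams synth_imag_index
#' @return a \code{\link{refindex_spectrum}}
#' @export
lorentz_complex_analytic <- function(chem, grid) {
  stopifnot(inherits(chem, "chemistry_model"))
  check_grid(grid)
  n <- rep(chem$n_offset, length(grid))
  k <- numeric(length(grid))
  for (b in chem$bands) {
    g <- b$width / 2
    den <- (grid - b$center)^2 + g^2
    n <- n + b$amplitude * g * (b$center - grid) / den
    k <- k + b$amplitude * g^2 / den
  }
  refindex_spectrum(grid, n, k)
}

#' Shift band centers of a chemistry model
#'
#' Moves the listed band centers to new positions, preserving widths and
#' amplitudes; bands are re-sorted by center. Used for the peak-shift
#' negative control, where extinction curves from a perturbed chemistry are
#' reconstructed with a subspace trained on the original chemistry.
#'
#' @param chem a \code{\link{chemistry_model}}
#' @param mapping named numeric vector: names are existing centers (matched
#'   exactly after numeric conversion), values are the new centers. E.g.
#'   \code{c("1500" = 1520, "2010" = 1950, "3000" = 3500, "5400" = 5350)}.
#' @return a new \code{\link{chemistry_model}}
#' @export
shift_bands <- function(chem, mapping) {
  stopifnot(inherits(chem, "chemistry_model"))
  if (length(mapping) == 0L) return(chem)
  stopifnot(is.numeric(mapping), !is.null(names(mapping)))
  old <- as.numeric(names(mapping))
  if (anyNA(old)) stop("mapping names must be numeric band centers")
  centers <- vapply(chem$bands, `[[`, numeric(1), "center")
  bands <- chem$bands
  for (i in seq_along(old)) {
    j <- which(centers == old[i])
    if (length(j) != 1L)
      stop(sprintf("no band with center %.6g cm^-1 in chemistry model", old[i]))
    bands[[j]] <- lorentz_band(unname(mapping[i]), bands[[j]]$width,
                               bands[[j]]$amplitude)
  }
  chemistry_model(bands, n_offset = chem$n_offset)
}

#' Band centers of a chemistry model
#' @param chem a \code{\link{chemistry_model}}
#' @return numeric vector of centers (cm^-1), increasing
#' @export
band_centers <- function(chem) {
  stopifnot(inherits(chem, "chemistry_model"))
  vapply(chem$bands, `[[`, numeric(1), "center")
}
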