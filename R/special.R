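# Complex-argument Bessel J1, Y1 and Struve H1.
#
# Needed for the closed-form semi-cylinder extinction efficiency, where the
# argument x(m-1) is complex for absorbing media. Base R's besselJ/besselY
# are real-only. Power series are used for |z| <= 20 (worst-case
# cancellation there amplifies roundoff to ~1e-9 absolute); Hankel
# asymptotic expansions, and the Struve-minus-Y asymptotic series, beyond.
# Valid for |arg z| < pi/2 + eps, ample for refractive indices with n > 1.
# Accuracy is pinned in tests against quadrature of the defining integrals
# and base R's real-argument Bessel functions.

SPECIAL_SERIES_CUTOFF <- 20

# J1 power series: sum_k (-1)^k (z/2)^(2k+1) / (k! (k+1)!)
cbessel_j1_series <- function(z) {
  s <- term <- z / 2
  zz <- -(z / 2)^2
  for (k in 0:70) {
    term <- term * zz / ((k + 1) * (k + 2))
    s <- s + term
  }
  s
}

# Struve H1 power series: (2/pi) sum_{j>=1} (-1)^(j-1) z^(2j)/((2j-1)!!(2j+1)!!)
cstruve_h1_series <- function(z) {
  term <- z^2 / 3
  s <- term
  zz <- -z^2
  for (j in 1:90) {
    term <- term * zz / ((2 * j + 1) * (2 * j + 3))
    s <- s + term
  }
  2 / pi * s
}

# Hankel asymptotic expansions for J1 and Y1, order-1 coefficients
# a_k = prod_{j=1..k} (4 - (2j-1)^2) / (k 8), |z| > 20
cbessel_asym <- function(z, nterm = 14L) {
  ak <- numeric(nterm + 1L)
  ak[1L] <- 1
  for (k in 1:nterm) ak[k + 1L] <- ak[k] * (4 - (2 * k - 1)^2) / (k * 8)
  P <- 0 + 0i
  Q <- 0 + 0i
  for (k in 0:(nterm %/% 2L)) P <- P + (-1)^k * ak[2L * k + 1L] / z^(2 * k)
  for (k in 0:((nterm - 1L) %/% 2L)) Q <- Q + (-1)^k * ak[2L * k + 2L] / z^(2 * k + 1)
  chi <- z - 3 * pi / 4
  pref <- sqrt(2 / (pi * z))
  list(J = pref * (cos(chi) * P - sin(chi) * Q),
       Y = pref * (sin(chi) * P + cos(chi) * Q))
}

# H1(z) = Y1(z) + (1/pi) sum_k Gamma(k+1/2)/Gamma(3/2-k) (z/2)^(-2k)
cstruve_h1_asym <- function(z, nterm = 10L) {
  y1 <- cbessel_asym(z)$Y
  s <- 0 + 0i
  coef <- 2           # k = 0: Gamma(1/2)/Gamma(3/2) = 2
  zz <- rep(1 + 0i, length(z))
  for (k in 0:nterm) {
    s <- s + coef * zz
    coef <- coef * (k + 0.5) * (0.5 - k)
    zz <- zz / (z / 2)^2
  }
  y1 + s / pi
}

# vectorized complex J1 / H1 dispatching on |z|
cbessel_j1 <- function(z) {
  z <- as.complex(z)
  out <- complex(length(z))
  small <- Mod(z) <= SPECIAL_SERIES_CUTOFF
  if (any(small)) out[small] <- cbessel_j1_series(z[small])
  if (any(!small)) out[!small] <- cbessel_asym(z[!small])$J
  out
}

cstruve_h1 <- function(z) {
  z <- as.complex(z)
  out <- complex(length(z))
  small <- Mod(z) <= SPECIAL_SERIES_CUTOFF
  if (any(small)) out[small] <- cstruve_h1_series(z[small])
  if (any(!small)) out[!small] <- cstruve_h1_asym(z[!small])
  out
}
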