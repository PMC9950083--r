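# Sphere-subspace (ME-EMSC meta-model core): a PCA basis of van de Hulst
# sphere extinction curves, and projections of non-spherical extinction
# curves onto it.

#' Training grid for the sphere-subspace model
#'
#' The set of (real-index offset, radius) pairs for which van de Hulst
#' sphere extinction curves are generated. Defaults: 10 offsets regularly
#' spaced over [1.3, 1.7] crossed with 10 radii over [5, 10] um, giving
#' 100 curves.
#'
#' @param offsets real-index offsets (dimensionless)
#' @param radii sphere radii (micrometers)
#' @return an object of class \code{training_grid}
#' @export
training_grid <- function(offsets = seq(1.3, 1.7, length.out = 10),
                          radii = seq(5, 10, length.out = 10)) {
  stopifnot(is.numeric(offsets), is.numeric(radii),
            length(offsets) >= 1L, length(radii) >= 1L)
  if (any(offsets <= 1)) stop("offsets must exceed 1")
  if (any(radii <= 0)) stop("radii must be positive")
  structure(list(offsets = offsets, radii = radii,
                 n_curves = length(offsets) * length(radii)),
            class = "training_grid")
}

#' Build the sphere extinction training set
#'
#' Generates one van de Hulst sphere extinction curve per (offset, radius)
#' pair of the training grid. All curves share the imaginary index
#' \eqn{k(\nu)} and the Kramers-Kronig dispersion of the chemistry model;
#' only the constant real-index offset is substituted, then the radius
#' varied. Ordering is offset-major (all radii for the first offset, then
#' the next offset).
#'
#' @param chem a \code{\link{chemistry_model}} (its own \code{n_offset} is
#'   replaced by each training offset in turn)
#' @param tg a \code{\link{training_grid}}
#' @param grid uniform wavenumber grid (cm^-1)
#' @return list of \code{\link{extinction_spectrum}} objects of length
#'   \code{tg$n_curves}
#' @export
build_training_set <- function(chem, tg, grid = default_grid()) {
  stopifnot(inherits(chem, "chemistry_model"), inherits(tg, "training_grid"))
  check_grid(grid)
  k <- synth_imag_index(chem, grid)
  dn <- kk_real_index(k, grid, n_offset = 0)   # dispersion about the offset
  curves <- vector("list", tg$n_curves)
  i <- 0L
  for (off in tg$offsets) {
    m <- refindex_spectrum(grid, off + dn, k)
    for (R in tg$radii) {
      i <- i + 1L
      curves[[i]] <- qext_vdh_sphere(m, R = R)
    }
  }
  curves
}

#' Fit the PCA subspace of a set of extinction curves
#'
#' Compresses training curves into an orthonormal principal-component
#' basis via singular-value decomposition, the subspace used by the
#' ME-EMSC meta-model. Curves are mean-centered by default (set
#' \code{center = FALSE} for uncentered PCA). Component signs follow a
#' deterministic convention: the largest-magnitude element of each
#' component is positive.
#'
#' @param curves list of \code{\link{extinction_spectrum}} objects on a
#'   common grid, or a numeric matrix with one curve per row
#' @param max_comp number of components to retain (default: full rank);
#'   requests beyond the numerical rank are truncated with a warning
#' @param center mean-center the curves before decomposition
#' @return an object of class \code{subspace_basis} with fields
#'   \code{grid}, \code{mean_curve}, \code{components} (n_points x n_comp
#'   matrix of orthonormal columns), \code{explained_variance},
#'   \code{centered}
#' @export
fit_subspace <- function(curves, max_comp = NULL, center = TRUE) {
  if (is.list(curves)) {
    stopifnot(length(curves) >= 2L)
    grid <- curves[[1]]$grid
    for (cv in curves) {
      stopifnot(inherits(cv, "extinction_spectrum"))
      if (length(cv$grid) != length(grid) || any(cv$grid != grid))
        stop("all curves must share one wavenumber grid")
    }
    X <- do.call(rbind, lapply(curves, `[[`, "qext"))
  } else {
    stopifnot(is.matrix(curves), nrow(curves) >= 2L)
    X <- curves
    grid <- attr(curves, "grid")
    if (is.null(grid)) grid <- seq_len(ncol(X))
  }
  if (is.null(max_comp)) max_comp <- nrow(X)
  if (max_comp > nrow(X)) stop("max_comp exceeds the number of curves")
  mean_curve <- if (center) colMeans(X) else numeric(ncol(X))
  Xc <- sweep(X, 2L, mean_curve)
  sv <- svd(Xc)
  ev <- sv$d^2 / max(1L, nrow(X) - 1L)
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  if (max_comp > rank) {
    warning(sprintf("requested %d components but rank is %d; truncating",
                    max_comp, rank))
    max_comp <- rank
  }
  comp <- sv$v[, seq_len(max_comp), drop = FALSE]
  # deterministic sign: largest-magnitude element of each component positive
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(grid = grid, mean_curve = mean_curve, components = comp,
                 explained_variance = ev[seq_len(max_comp)],
                 centered = center),
            class = "subspace_basis")
}

#' @export
print.subspace_basis <- function(x, ...) {
  cat(sprintf("subspace_basis: %d components on %d grid points (%scentered)\n",
              ncol(x$components), length(x$grid),
              if (x$centered) "" else "un"))
  invisible(x)
}

#' Project an extinction curve onto the sphere subspace
#'
#' Reconstructs a target extinction curve from the leading \code{n_comp}
#' principal components:
#' \deqn{\hat q = \bar q + \sum_{i \le n_{comp}}
#'   \langle q - \bar q,\, p_i\rangle\, p_i.}
#'
#' @param target an \code{\link{extinction_spectrum}} on the basis grid
#' @param basis a \code{\link{subspace_basis}}
#' @param n_comp number of components used, between 1 and the number
#'   available
#' @param chem optional \code{\link{chemistry_model}}: when given, residual
#'   energy (sum of squared residuals) is reported within each band window
#'   (center +/- 2 FWHM)
#' @return an object of class \code{reconstruction_report} with fields
#'   \code{n_comp}, \code{reconstructed}, \code{residual}, \code{rel_rmse}
#'   (l2 residual norm / l2 target norm) and optionally
#'   \code{band_residuals}
#' @export
reconstruct <- function(target, basis, n_comp, chem = NULL) {
  stopifnot(inherits(target, "extinction_spectrum"),
            inherits(basis, "subspace_basis"))
  if (length(target$grid) != length(basis$grid) ||
      any(target$grid != basis$grid))
    stop("target grid does not match the basis grid")
  navail <- ncol(basis$components)
  if (n_comp < 1L || n_comp > navail)
    stop(sprintf("n_comp must be between 1 and %d", navail))
  P <- basis$components[, seq_len(n_comp), drop = FALSE]
  centered <- target$qext - basis$mean_curve
  scores <- drop(crossprod(P, centered))
  rec <- basis$mean_curve + drop(P %*% scores)
  residual <- target$qext - rec
  rel_rmse <- sqrt(sum(residual^2)) / sqrt(sum(target$qext^2))
  band_res <- NULL
  if (!is.null(chem)) {
    wins <- band_windows(chem)
    band_res <- vapply(wins, function(w) {
      sel <- target$grid >= w[1] & target$grid <= w[2]
      sum(residual[sel]^2)
    }, numeric(1))
  }
  structure(list(n_comp = n_comp, reconstructed = rec, residual = residual,
                 rel_rmse = rel_rmse, band_residuals = band_res,
                 grid = target$grid),
            class = "reconstruction_report")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf("reconstruction_report: n_comp = %d, rel_rmse = %.4g\n",
              x$n_comp, x$rel_rmse))
  invisible(x)
}

#' Band windows of a chemistry model
#'
#' Wavenumber windows of width +/- \code{half_widths} FWHM around each band
#' center, used to localize reconstruction residuals at absorption bands.
#'
#' @param chem a \code{\link{chemistry_model}}
#' @param half_widths half-window size in units of the band FWHM
#' @return named list of \code{c(lo, hi)} windows (cm^-1)
#' @export
band_windows <- function(chem, half_widths = 2) {
  stopifnot(inherits(chem, "chemistry_model"))
  wins <- lapply(chem$bands, function(b)
    c(b$center - half_widths * b$width, b$center + half_widths * b$width))
  names(wins) <- vapply(chem$bands, function(b) format(b$center), character(1))
  wins
}

#' Sweep the number of principal components
#'
#' Runs \code{\link{reconstruct}} for each entry of \code{n_comp_list};
#' for a sorted list the rel_rmse sequence is non-increasing (nested
#' projections onto one basis).
#'
#' @inheritParams reconstruct
#' @param n_comp_list integer vector of component counts
#' @return list of \code{reconstruction_report}, one per entry
#' @export
sweep_ncomp <- function(target, basis, n_comp_list, chem = NULL) {
  lapply(n_comp_list, function(nc) reconstruct(target, basis, nc, chem = chem))
}

#' Peak-shift negative control
#'
#' Demonstrates that the sphere subspace is specific to the chemistry it
#' was trained on: extinction curves of a target geometry are computed for
#' the original chemistry and for a band-shifted chemistry, both are
#' reconstructed with the \emph{original-chemistry} basis, and residual
#' energy is compared inside windows (+/- 2 FWHM) around the shifted
#' bands' new positions. A successful control shows the shifted-chemistry
#' residual energy exceeding the original's in those windows.
#'
#' @param chem the original \code{\link{chemistry_model}} (the one the
#'   basis was trained on)
#' @param mapping band-shift mapping as in \code{\link{shift_bands}}
#' @param basis a \code{\link{subspace_basis}} trained on \code{chem}
#' @param geometry a \code{\link{scatterer_geometry}} for the target curve
#' @param n_comp number of components used for both reconstructions
#' @param grid wavenumber grid (must match the basis grid)
#' @return list with elements \code{original}, \code{shifted} (the two
#'   \code{reconstruction_report}s), \code{windows}, per-window energies
#'   \code{energy_original}, \code{energy_shifted}, \code{ratio}
#'   (shifted/original per window), \code{exceeds} (logical per window),
#'   and the pooled \code{total_ratio}
#' @export
peak_shift_experiment <- function(chem, mapping, basis, geometry, n_comp,
                                  grid = default_grid()) {
  stopifnot(inherits(chem, "chemistry_model"),
            inherits(basis, "subspace_basis"),
            inherits(geometry, "scatterer_geometry"))
  chem2 <- shift_bands(chem, mapping)
  tgt1 <- qext_for_geometry(chem, geometry, grid)
  tgt2 <- qext_for_geometry(chem2, geometry, grid)
  rep1 <- reconstruct(tgt1, basis, n_comp)
  rep2 <- reconstruct(tgt2, basis, n_comp)
  if (length(mapping) > 0L) {
    # windows around the *new* centers of the shifted bands
    shifted_bands <- chem2$bands[match(as.numeric(unname(mapping)),
                                       band_centers(chem2))]
    wins <- lapply(shifted_bands, function(b)
      c(b$center - 2 * b$width, b$center + 2 * b$width))
    names(wins) <- vapply(shifted_bands, function(b) format(b$center),
                          character(1))
  } else {
    wins <- band_windows(chem)
  }
  energy <- function(rep) vapply(wins, function(w) {
    sel <- grid >= w[1] & grid <= w[2]
    sum(rep$residual[sel]^2)
  }, numeric(1))
  e1 <- energy(rep1)
  e2 <- energy(rep2)
  list(original = rep1, shifted = rep2, windows = wins,
       energy_original = e1, energy_shifted = e2,
       ratio = e2 / e1, exceeds = e2 > e1,
       total_ratio = sum(e2) / sum(e1))
}

#' Extinction curve of a geometry under a chemistry model
#'
#' Production route: Lorentz band sum plus numerical Kramers-Kronig index,
#' then the closed-form ADA extinction model of the geometry.
#'
#' @param chem a \code{\link{chemistry_model}}
#' @param geometry a \code{\link{scatterer_geometry}}
#' @param grid uniform wavenumber grid (cm^-1)
#' @return an \code{\link{extinction_spectrum}}
#' @export
qext_for_geometry <- function(chem, geometry, grid) {
  m <- synth_refractive_index(chem, grid)
  switch(geometry$shape,
         "sphere" = qext_vdh_sphere(m, geometry$R),
         "dome" = qext_dome(m, geometry$R),
         "semi-cylinder" = qext_semicylinder(m, geometry$R),
         "semi-capsule" = qext_semicapsule(m, geometry$R, geometry$L))
}
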