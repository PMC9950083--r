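test_that("training grid defaults give 100 curves and validate inputs", {
  tg <- training_grid()
  expect_equal(tg$n_curves, 100)
  expect_equal(range(tg$offsets), c(1.3, 1.7))
  expect_equal(range(tg$radii), c(5, 10))
  expect_error(training_grid(offsets = c(0.9, 1.5)), "exceed 1")
  expect_error(training_grid(radii = c(-5, 10)), "positive")
})

test_that("a singleton training grid reproduces the plain sphere curve", {
  grid <- default_grid(step = 10)
  chem <- default_chemistry()
  curves <- build_training_set(chem, training_grid(offsets = 1.5, radii = 10),
                               grid)
  expect_length(curves, 1L)
  want <- qext_vdh_sphere(synth_refractive_index(chem, grid), R = 10)
  expect_equal(curves[[1]]$qext, want$qext, tolerance = 1e-12)
})

test_that("the default training set is 100 non-negative, pairwise distinct curves", {
  curves <- fix_training_curves()
  expect_length(curves, 100L)
  X <- do.call(rbind, lapply(curves, `[[`, "qext"))
  expect_true(all(X >= 0))
  # pairwise sup-norm separation
  mins <- vapply(1:99, function(i) {
    min(vapply((i + 1):100, function(j) max(abs(X[i, ] - X[j, ])), numeric(1)))
  }, numeric(1))
  expect_true(all(mins > 0))
  # offset-major ordering: first block shares the offset, radii increasing,
  # so the small-particle limit (first grid point) increases down the block
  expect_equal(curves[[1]]$geometry$R, 5)
  expect_equal(curves[[10]]$geometry$R, 10)
})

test_that("PCA basis is orthonormal with non-increasing explained variance", {
  basis <- fix_basis()
  G <- crossprod(basis$components)
  expect_lt(max(abs(G - diag(ncol(basis$components)))), 1e-10)
  expect_true(all(diff(basis$explained_variance) <= 1e-12))
  cum <- cumsum(basis$explained_variance) / sum(basis$explained_variance)
  expect_true(all(diff(cum) > 0))
  expect_gt(cum[12], 0.99)
  # deterministic sign convention: largest-magnitude element positive
  for (j in seq_len(ncol(basis$components))) {
    col <- basis$components[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("degenerate curve sets produce degenerate bases", {
  grid <- default_grid(step = 50)
  chem <- default_chemistry()
  m <- synth_refractive_index(chem, grid)
  q <- qext_vdh_sphere(m, 10)
  # identical curves: rank 0 after centering
  expect_warning(b0 <- fit_subspace(list(q, q), max_comp = 2), "rank")
  expect_equal(ncol(b0$components), 0L)
  # mean + one direction: rank 1, direction recovered up to sign
  base <- q$qext
  dir <- sin(seq_along(base) / 20)
  dir <- dir / sqrt(sum(dir^2))
  X <- rbind(base + 0.5 * dir, base + 1.5 * dir, base + 2.5 * dir)
  expect_warning(b1 <- fit_subspace(X, max_comp = 3), "rank")
  expect_equal(ncol(b1$components), 1L)
  expect_lt(min(sum((b1$components[, 1] - dir)^2),
                sum((b1$components[, 1] + dir)^2)), 1e-16)
})

test_that("projection is exact for in-span targets and idempotent", {
  expect_warning(basis <- fit_subspace(fix_training_curves(),
                                       max_comp = 100), "rank")
  curves <- fix_training_curves()
  full <- ncol(basis$components)
  r <- reconstruct(curves[[37]], basis, full)
  expect_lt(r$rel_rmse, 1e-8)
  # mean curve reconstructs with zero scores at any n_comp
  mean_target <- extinction_spectrum(basis$grid, basis$mean_curve,
                                     scatterer_geometry("sphere", 10),
                                     "vdh-closed-form")
  expect_lt(reconstruct(mean_target, basis, 3)$rel_rmse, 1e-12)
  # idempotence: projecting a projection changes nothing
  tgt <- fix_semicapsule_target()
  r8 <- reconstruct(tgt, basis, 8)
  again <- extinction_spectrum(basis$grid, r8$reconstructed,
                               tgt$geometry, "vdh-closed-form")
  r8b <- reconstruct(again, basis, 8)
  expect_lt(max(abs(r8b$reconstructed - r8$reconstructed)), 1e-10)
  # grid mismatch is an error
  small <- qext_vdh_sphere(1.5, 10, grid = default_grid(step = 10))
  expect_error(reconstruct(small, basis, 5), "grid")
})

test_that("rel_rmse is non-increasing in n_comp and the dome is easiest", {
  basis <- fix_basis()
  tgt <- fix_semicapsule_target()
  reports <- sweep_ncomp(tgt, basis, 5:12)
  rr <- vapply(reports, `[[`, numeric(1), "rel_rmse")
  expect_true(all(diff(rr) <= 1e-12))
  # singleton sweep equals reconstruct
  expect_equal(sweep_ncomp(tgt, basis, 7)[[1]]$rel_rmse,
               reconstruct(tgt, basis, 7)$rel_rmse)
  # a dome (in the sphere span up to path-length scaling) reconstructs at
  # least as well as the semi-capsule at every n_comp
  dome <- qext_for_geometry(fix_chem(),
                            scatterer_geometry("dome", R = 10), fix_grid())
  rr_dome <- vapply(sweep_ncomp(dome, basis, 5:12), `[[`, numeric(1),
                    "rel_rmse")
  expect_true(all(rr_dome <= rr))
})

test_that("qualitative subspace conclusions hold without mean-centering", {
  basis_u <- fit_subspace(fix_training_curves(), max_comp = 20,
                          center = FALSE)
  expect_equal(basis_u$mean_curve, numeric(length(basis_u$grid)))
  tgt <- fix_semicapsule_target()
  rr <- vapply(sweep_ncomp(tgt, basis_u, c(5, 8, 12, 20)), `[[`, numeric(1),
               "rel_rmse")
  expect_true(all(diff(rr) <= 0))
  expect_lt(rr[4], rr[1] / 10)
})

test_that("the subspace is insensitive to the training sampling scheme", {
  set.seed(42)
  tg_rand <- training_grid(offsets = sort(stats::runif(10, 1.3, 1.7)),
                           radii = sort(stats::runif(10, 5, 10)))
  curves_rand <- build_training_set(fix_chem(), tg_rand, fix_grid())
  basis_rand <- fit_subspace(curves_rand, max_comp = 12)
  tgt <- fix_semicapsule_target()
  r_grid <- reconstruct(tgt, fix_basis(), 12)$rel_rmse
  r_rand <- reconstruct(tgt, basis_rand, 12)$rel_rmse
  expect_lt(max(r_grid, r_rand) / min(r_grid, r_rand), 3)
})

test_that("the peak-shift control localizes failure at the shifted bands", {
  chem <- fix_chem()
  grid <- fix_grid()
  basis <- fix_basis()
  geom <- scatterer_geometry("semi-capsule", R = 10, L = 10)
  mapping <- c("1500" = 1520, "2010" = 1950, "3000" = 3500, "5400" = 5350)
  ps <- peak_shift_experiment(chem, mapping, basis, geom, n_comp = 12,
                              grid = grid)
  expect_named(ps$ratio, c("1520", "1950", "3500", "5350"))
  expect_true(all(ps$exceeds))
  expect_gt(ps$total_ratio, 5)
  # failure is concentrated at the shifted bands: per-point residual
  # energy density inside the shifted windows exceeds the density outside
  sel <- rep(FALSE, length(grid))
  for (w in ps$windows) sel <- sel | (grid >= w[1] & grid <= w[2])
  dens_in <- sum(ps$shifted$residual[sel]^2) / sum(sel)
  dens_out <- sum(ps$shifted$residual[!sel]^2) / sum(!sel)
  expect_gt(dens_in, dens_out)
  # empty mapping: the two runs coincide
  ps0 <- peak_shift_experiment(chem, numeric(0), basis, geom, 12, grid)
  expect_equal(ps0$original$rel_rmse, ps0$shifted$rel_rmse)
  expect_equal(ps0$total_ratio, 1)
})
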