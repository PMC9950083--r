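# Closed-form ADA extinction models against the quadrature oracle and
# their analytic limits. Oracle comparisons use coarse subgrids; the
# full-resolution sweeps live in the acceptance tests.

test_that("sphere Q_ext vanishes as the phase parameter goes to zero", {
  q <- qext_vdh_sphere(1.5, R = 0.01, grid = c(100, 200))  # x ~ 1e-3
  expect_true(all(q$qext >= 0))
  expect_true(all(q$qext < 1e-4))
})

test_that("non-absorbing sphere matches the classic closed form and its wiggle", {
  grid <- seq(200, 2000, by = 2)
  n0 <- 1.5
  R <- 10
  q <- qext_vdh_sphere(n0, R, grid = grid)
  rho <- 2 * (2 * pi * grid * R * 1e-4) * (n0 - 1)
  want <- 2 - 4 * sin(rho) / rho + 4 * (1 - cos(rho)) / rho^2
  expect_rel_equal(q$qext, want, 1e-12)
  # first wiggle maximum: root-find oracle on the closed form in rho
  f <- function(r) 2 - 4 * sin(r) / r + 4 * (1 - cos(r)) / r^2
  rho_star <- stats::optimize(f, c(2, 6), maximum = TRUE)$maximum
  nu_star <- rho_star / (2 * 2 * pi * R * 1e-4 * (n0 - 1))
  expect_equal(first_wiggle_maximum(q), nu_star, tolerance = 1e-3)
  # height agrees too
  expect_equal(max(q$qext), f(rho_star), tolerance = 1e-4)
})

test_that("sphere closed form equals the radial quadrature oracle", {
  m <- fix_index_sub(by = 125)
  q <- qext_vdh_sphere(m, R = 10)
  qo <- qext_ada_geometry(m, scatterer_geometry("sphere", 10), rel.tol = 1e-9)
  expect_lt(max_rel_err(q, qo), 1e-6)
})

test_that("dome equals the sphere at half phase and its own quadrature oracle", {
  m <- fix_index()
  # halving the radius halves x and hence the phase parameter exactly
  qd <- qext_dome(m, R = 10)
  qs_half <- qext_vdh_sphere(m, R = 5)
  expect_rel_equal(qd$qext, qs_half$qext, 1e-12)
  msub <- fix_index_sub(by = 125)
  qo <- qext_ada_geometry(msub, scatterer_geometry("dome", 10), rel.tol = 1e-9)
  expect_lt(max_rel_err(qext_dome(msub, R = 10), qo), 1e-6)
})

test_that("semi-cylinder matches its 1-D quadrature oracle for absorbing media", {
  msub <- fix_index_sub(by = 125)
  q <- qext_semicylinder(msub, R = 10)
  qo <- qext_ada_geometry(msub, scatterer_geometry("semi-cylinder", 10),
                          rel.tol = 1e-9)
  expect_lt(max_rel_err(q, qo), 1e-6)
})

test_that("non-absorbing semi-cylinder approaches the extinction paradox limit", {
  # rho = 200 corresponds to x(m-1) = 100 for n = 1.5
  R <- 10
  n0 <- 1.5
  nu_of_rho <- function(rho) rho / (2 * 2 * pi * R * 1e-4 * (n0 - 1))
  # the oscillation averages out around the extinction-paradox value 2
  g200 <- nu_of_rho(seq(190, 210, length.out = 400))
  expect_lt(abs(mean(qext_semicylinder(n0, R, grid = g200)$qext) - 2), 0.02)
  # oscillation decays: envelope at rho ~ 200 tighter than at rho ~ 20
  dev <- function(rho_lo, rho_hi) {
    g <- nu_of_rho(seq(rho_lo, rho_hi, length.out = 200))
    max(abs(qext_semicylinder(n0, R, grid = g)$qext - 2))
  }
  expect_lt(dev(190, 210), dev(15, 35) / 3)
})

test_that("semi-capsule composition, degeneracy and 2-D oracle agree", {
  m <- fix_index()
  # L = 0 degenerates to the dome exactly
  q0 <- qext_semicapsule(m, R = 10, L = 0)
  expect_rel_equal(q0$qext, qext_dome(m, R = 10)$qext, 1e-12)
  # area-weighted composition identity
  L <- 7.3
  R <- 10
  qsc <- qext_semicapsule(m, R, L)
  mix <- (pi * R^2 * qext_dome(m, R)$qext +
            2 * R * L * qext_semicylinder(m, R)$qext) / (pi * R^2 + 2 * R * L)
  expect_rel_equal(qsc$qext, mix, 1e-10)
  expect_error(qext_semicapsule(m, R, L = -1), "non-negative")
  # 2-D stadium quadrature oracle on a very coarse subgrid
  msub <- fix_index_sub(by = 500)
  qo <- qext_ada_geometry(msub, scatterer_geometry("semi-capsule", 10, L = 10),
                          rel.tol = 1e-8)
  expect_lt(max_rel_err(qext_semicapsule(msub, 10, 10), qo), 1e-6)
})

test_that("generic ADA oracle handles degenerate and film chords analytically", {
  grid <- c(1000, 3000, 5000)
  # zero chord: no scatterer, Q = 0
  q0 <- qext_ada_numeric(1.5, chord = function(r) 0 * r, area = pi,
                         region = list(type = "radial", rmax = 1),
                         grid = grid)
  expect_equal(q0$qext, numeric(3))
  # constant chord t0 over a disk (a film): Q = 2 Re{1 - e^{i phi t0}}
  t0 <- 4.2
  mc <- 1.4 + 0.03i
  qf <- qext_ada_numeric(mc, chord = function(r) rep(t0, length(r)),
                         area = pi, region = list(type = "radial", rmax = 1),
                         grid = grid)
  want <- 2 * Re(1 - exp(1i * 2 * pi * 1e-4 * grid * (mc - 1) * t0))
  expect_rel_equal(qf$qext, want, 1e-9)
})

test_that("extinction efficiencies stay within physical bounds", {
  m <- fix_index()
  for (q in list(qext_vdh_sphere(m, 10), qext_dome(m, 10),
                 qext_semicylinder(m, 10), qext_semicapsule(m, 10, 10))) {
    expect_true(all(q$qext >= 0))
    expect_true(all(q$qext <= 5))
  }
})

test_that("geometry constructor enforces shape-specific rules", {
  expect_error(scatterer_geometry("sphere", R = -1), "positive")
  expect_error(scatterer_geometry("semi-capsule", R = 10, L = -2),
               "non-negative")
  expect_warning(g <- scatterer_geometry("dome", R = 10, L = 5), "ignored")
  expect_equal(g$L, 0)
})
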