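# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fix_grid <- function() default_grid()

fix_chem <- function() default_chemistry()

fix_index <- function() {
  memo("index", synth_refractive_index(fix_chem(), fix_grid()))
}

# refractive index restricted to every by-th grid point (for quadrature
# oracles, which are slow on the full grid)
fix_index_sub <- function(by = 50) {
  memo(paste0("index_sub_", by), {
    m <- fix_index()
    sel <- seq(1L, length(m$grid), by = by)
    refindex_spectrum(m$grid[sel], m$n[sel], m$k[sel])
  })
}

fix_training_curves <- function() {
  memo("training_curves",
       build_training_set(fix_chem(), training_grid(), fix_grid()))
}

fix_basis <- function() {
  memo("basis", fit_subspace(fix_training_curves(), max_comp = 20))
}

fix_semicapsule_target <- function(L = 10) {
  memo(paste0("target_L", L),
       qext_for_geometry(fix_chem(),
                         scatterer_geometry("semi-capsule", R = 10, L = L),
                         fix_grid()))
}

# max relative deviation between a closed-form curve and its quadrature
# oracle on the oracle's grid
max_rel_err <- function(q_closed, q_oracle) {
  scale <- pmax(abs(q_oracle$qext), 1e-8)
  max(abs(q_closed$qext - q_oracle$qext) / scale)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
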