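# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form assembly and Thomas paths: dense linear algebra via
# base solve(), integrals via stats::integrate on the hat functions.

# derivative of hat i (0-based) at x, for a uniform mesh
hat_deriv <- function(mesh, i, x) {
  xi <- mesh$nodes[i + 1L]
  h <- mesh$h
  ifelse(x > xi - h & x < xi, 1 / h,
         ifelse(x > xi & x < xi + h, -1 / h, 0))
}

# entry (i, j) of the weighted stiffness integral D(phi_h) e_i' e_j' by blind
# adaptive quadrature over each element (i, j are 0-based node indices)
quad_stiffness_entry <- function(mesh, i, j, weight_fn) {
  tot <- 0
  for (e in seq_len(mesh$M + 1L)) {
    a <- mesh$nodes[e]; b <- mesh$nodes[e + 1L]
    f <- function(x) weight_fn(x) * hat_deriv(mesh, i, x) * hat_deriv(mesh, j, x)
    tot <- tot + stats::integrate(f, a, b, rel.tol = 1e-13, abs.tol = 1e-15)$value
  }
  tot
}

quad_mass_entry <- function(mesh, i, j) {
  f <- function(x) hat_value(mesh, i, x) * hat_value(mesh, j, x)
  stats::integrate(f, -mesh$L, mesh$L, rel.tol = 1e-13, abs.tol = 1e-15,
                   subdivisions = 400L)$value
}

# piecewise-linear interpolant of nodal values at x
field_eval <- function(mesh, values, x) {
  stats::approx(mesh$nodes, values, xout = x)$y
}

dense_tridiag <- function(tri) as.matrix(tri)

# full (M+2)-state with given interior and boundary values
full_state <- function(mesh, interior, bc) c(bc, interior, bc)

expect_spd <- function(m) {
  expect_true(isSymmetric(m, tol = 1e-12))
  expect_error(chol(m), NA)
}
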