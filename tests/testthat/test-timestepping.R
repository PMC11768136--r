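test_that("Thomas solver matches dense solves", {
  idty <- tridiag(rep(0, 4), rep(1, 5))
  rhs <- c(3, -1, 2, 0.5, 4)
  expect_equal(thomas_solve(idty, rhs), rhs)

  lap <- tridiag(rep(-1, 7), rep(2, 8))
  e1 <- c(1, rep(0, 7))
  expect_equal(thomas_solve(lap, e1), solve(dense_tridiag(lap), e1),
               tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:5) {
    n <- sample(3:40, 1)
    sub <- stats::runif(n - 1, -1, 1)
    dg <- c(abs(sub), 0) + c(0, abs(sub)) + stats::runif(n, 0.5, 2)  # diag dominant
    mat <- tridiag(sub, dg)
    rhs <- stats::rnorm(n)
    x <- thomas_solve(mat, rhs)
    xd <- solve(dense_tridiag(mat), rhs)
    expect_equal(x, xd, tolerance = 1e-11)
    # residual check in the infinity norm
    resid <- max(abs(dense_tridiag(mat) %*% x - rhs))
    expect_lt(resid, 1e-10 * (max(abs(dg)) * max(abs(x)) + max(abs(rhs))))
  }
  singular <- tridiag(numeric(0), 0)
  expect_error(thomas_solve(singular, 1), "singular")
})

test_that("ellipticity bound is the endpoint minimum of the diffusion law", {
  expect_equal(check_ellipticity(diffusion_law(17.413, 0.3, 2)), 17.413)
  expect_equal(check_ellipticity(diffusion_law(1, -0.5, 1)), 0.5)
  suppressWarnings({
    law <- diffusion_law(1, -1, 2)
    expect_warning(dstar <- check_ellipticity(law), "degenerate")
  })
  expect_equal(dstar, 0)
})

test_that("equilibrium states are exact fixed points of the step", {
  mesh <- build_mesh(L = 1.8, M = 12)
  state <- nodal_field(mesh, rep(0.42, 14))
  out <- step_constant(mesh, D = 3, dt = 0.2, state, phiInf = 0.42)
  expect_equal(out$values, rep(0.42, 14), tolerance = 1e-13)
  out2 <- step_nonlinear(mesh, diffusion_law(3, 0.6, 2), 0.2, state, 0.42)
  expect_equal(out2$values, rep(0.42, 14), tolerance = 1e-13)
})

test_that("the nonlinear path with delta = 0 equals the constant path exactly", {
  mesh <- build_mesh(L = 1, M = 15)
  state <- l2_project_initial(mesh, 1)
  s_const <- step_constant(mesh, D = 2.5, dt = 0.01, state, phiInf = 0)
  s_nl1 <- step_nonlinear(mesh, diffusion_law(2.5, 0, 1), 0.01, state, 0)
  s_nl2 <- step_nonlinear(mesh, diffusion_law(2.5, 0, 2), 0.01, state, 0)
  expect_identical(s_const$values, s_nl1$values)
  expect_identical(s_const$values, s_nl2$values)
})

test_that("a single lagged step converges at first order to the iterated fine solution", {
  mesh <- build_mesh(L = 1, M = 31)
  law <- diffusion_law(1, 0.3, 2)
  state <- l2_project_initial(mesh, 1)
  ref <- state
  dt <- 0.02
  for (i in 1:64)  # dt/64 substeps, Picard iterated to tolerance
    ref <- step_nonlinear(mesh, law, dt / 64, ref, 0, picard_iters = 50L)
  errs <- vapply(c(1, 2, 4), function(nsub) {
    s <- state
    for (i in seq_len(nsub)) s <- step_nonlinear(mesh, law, dt / nsub, s, 0)
    max(abs(s$values - ref$values))
  }, numeric(1))
  # halving dt should roughly halve the error (first-order scheme)
  rates <- log2(errs[-3] / errs[-1])
  expect_true(all(rates > 0.6 & rates < 1.4))
})

test_that("simulation preserves the trivial solution and spatial symmetry", {
  mesh <- build_mesh(L = 2, M = 14)
  tt <- seq(0, 2, by = 0.25)
  hist <- simulate_concentration(mesh, diffusion_law(4, 0.5, 2), tt,
                                 boundary_spec(0.8, 0.8))
  expect_equal(max(abs(hist$states - 0.8)), 0, tolerance = 1e-13)

  hist2 <- simulate_concentration(mesh, diffusion_law(4, 0.7, 2), tt,
                                  boundary_spec(1, 0))
  flipped <- hist2$states[rev(seq_len(nrow(hist2$states))), ]
  expect_equal(hist2$states, flipped, tolerance = 1e-12)
  # boundary rows carry phiInf at every post-initial level
  expect_equal(unname(hist2$states[1, -1]), rep(0, length(tt) - 1))
})

test_that("restarting from an intermediate state reproduces the one-shot run", {
  mesh <- build_mesh(L = 1, M = 10)
  law <- diffusion_law(2, 0.4, 1)
  tt <- seq(0, 1, by = 0.1)
  full <- simulate_concentration(mesh, law, tt, boundary_spec(1, 0))
  # stage 1: first 5 steps; stage 2: restart stepping manually
  mid <- nodal_field(mesh, full$states[, 6])
  state <- mid
  for (n in 7:11)
    state <- step_nonlinear(mesh, law, tt[n] - tt[n - 1], state, 0)
  expect_identical(state$values, full$states[, 11])
})

test_that("post-initial states stay in physical bounds and lose mass monotonically", {
  set.seed(301)
  for (rep in 1:5) {
    d <- stats::runif(1, 0, 1)
    k <- sample(1:2, 1)
    L <- stats::runif(1, 1, 4)
    D0 <- stats::runif(1, 5, 80)
    mesh <- build_mesh(L, 31)
    tt <- seq(0, 3 * L^2 / D0, length.out = 61)
    hist <- simulate_concentration(mesh, diffusion_law(D0, d, k), tt,
                                   boundary_spec(1, 0))
    post <- hist$states[, -1]
    expect_gt(min(post), -1e-8)
    expect_lt(max(post), 1 + 1e-8)
    mass <- apply(hist$states, 2, function(v)
      integrate_field(nodal_field(mesh, v)))
    expect_true(all(diff(mass) < 0))
  }
})

test_that("implicit system matrices stay SPD along nonlinear trajectories", {
  mesh <- build_mesh(L = 1.5, M = 12)
  law <- diffusion_law(6, 0.9, 2)
  tt <- seq(0, 1, by = 0.1)
  hist <- simulate_concentration(mesh, law, tt, boundary_spec(1, 0))
  B <- as.matrix(assemble_mass(mesh))
  for (n in seq_len(length(tt) - 1)) {
    A <- assemble_stiffness_nonlinear(mesh, law, hist$states[, n])
    expect_spd(B + (tt[n + 1] - tt[n]) * dense_tridiag(A))
  }
})

test_that("time-dependent surface concentrations are interpolated and applied", {
  mesh <- build_mesh(L = 1, M = 9)
  series <- data.frame(time = c(0, 1, 2), value = c(1, 0.5, 0.2))
  bnd <- boundary_spec(1, series)
  expect_equal(phi_inf_at(bnd, 0.5), 0.75)  # linear midpoint
  expect_equal(phi_inf_at(bnd, 5), 0.2)     # constant extrapolation
  hist <- simulate_concentration(mesh, diffusion_law(1, 0.2, 2),
                                 seq(0, 2, by = 0.25), bnd)
  expect_equal(unname(hist$states[1, ]),
               phi_inf_at(bnd, seq(0, 2, by = 0.25)))
})

test_that("lifted-boundary mode runs and enforces the boundary values", {
  mesh <- build_mesh(L = 1, M = 9)
  law <- diffusion_law(1, 0.3, 2)
  hist <- simulate_concentration(mesh, law, seq(0, 1, by = 0.1),
                                 boundary_spec(1, 0), mode = "lifted")
  expect_equal(unname(hist$states[1, -1]), rep(0, 10))
  expect_true(all(is.finite(hist$states)))
  # with zero surface concentration the lifting vanishes and both modes agree
  hist_c <- simulate_concentration(mesh, law, seq(0, 1, by = 0.1),
                                   boundary_spec(1, 0))
  expect_equal(hist$states, hist_c$states, tolerance = 1e-13)
})

test_that("grid validation and refinement behave as documented", {
  expect_error(time_grid(c(0.1, 0.2)), "start at t = 0")
  expect_error(time_grid(c(0, 0.2, 0.2)), "strictly increasing")
  ref <- refine_grid(c(0, 1, 4), max_dt = 0.5)
  expect_true(all(diff(ref) <= 0.5 + 1e-12))
  expect_true(all(c(0, 1, 4) %in% ref))
})
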