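test_that("mass matrix has the closed-form entries and quadrature pedigree", {
  mesh <- build_mesh(L = 1, M = 3)   # h = 0.5
  B <- assemble_mass(mesh)
  expect_equal(B$diag, rep(1 / 3, 3))
  expect_equal(B$sub, rep(1 / 12, 2))
  expect_equal(B$sub, B$sup)
  # interior row sum 2h/3 + 2*(h/6) = h
  expect_equal(B$diag[2] + 2 * B$sub[1], mesh$h)
  # blind quadrature of e_i e_j
  for (i in 1:3) for (j in 1:3) {
    expected <- if (abs(i - j) > 1) 0 else if (i == j) B$diag[i] else B$sub[min(i, j)]
    expect_equal(quad_mass_entry(mesh, i, j), expected, tolerance = 1e-13)
  }
  expect_equal(B$bc_left, mesh$h / 6)
})

test_that("constant stiffness matrix matches formula and quadrature", {
  mesh <- build_mesh(L = 1, M = 3)
  A <- assemble_stiffness_constant(mesh, D = 1)
  expect_equal(A$diag, rep(4, 3))
  expect_equal(A$sub, rep(-2, 2))
  for (i in 1:3) for (j in 1:3) {
    expected <- if (abs(i - j) > 1) 0 else if (i == j) A$diag[i] else A$sub[1]
    expect_equal(quad_stiffness_entry(mesh, i, j, function(x) rep(1, length(x))),
                 expected, tolerance = 1e-13)
  }
  # gradients annihilate constants up to the boundary columns
  full_row_sum <- A$diag[2] + 2 * A$sub[1]
  expect_equal(full_row_sum, 0)
  expect_equal(A$bc_left, -1 / mesh$h)
  expect_error(assemble_stiffness_constant(mesh, 0), "positive")
})

test_that("element diffusivity integral has exact closed forms", {
  h <- 0.31
  law1 <- diffusion_law(2.5, 0.4, 1)
  law2 <- diffusion_law(2.5, 0.4, 2)
  # delta = 0 collapses to h*D0 for any k
  for (k in 1:4)
    expect_equal(element_diffusivity_integral(diffusion_law(3, 0, k), 0.2, 0.9, h),
                 3 * h)
  # k = 2 with zero state: all bracket terms equal 1
  expect_equal(element_diffusivity_integral(law2, 0, 0, h), 2.5 * h)

  # random states against blind adaptive quadrature
  set.seed(11)
  for (rep in 1:6) {
    aL <- stats::runif(1); aR <- stats::runif(1); d <- stats::runif(1, -0.9, 1)
    for (k in c(1L, 2L, 3L, 5L)) {
      law <- diffusion_law(1.7, d, k)
      oracle <- stats::integrate(function(s) 1.7 * (1 + d * (aL + (aR - aL) * s))^k,
                                 0, 1, rel.tol = 1e-13)$value * h
      expect_equal(element_diffusivity_integral(law, aL, aR, h), oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("nonlinear stiffness reduces to the constant matrix when delta = 0", {
  mesh <- build_mesh(L = 2, M = 8)
  state <- nodal_field(mesh, stats::runif(10))
  A0 <- assemble_stiffness_nonlinear(mesh, diffusion_law(3.7, 0, 2), state)
  Ac <- assemble_stiffness_constant(mesh, 3.7)
  expect_identical(A0$diag, Ac$diag)
  expect_identical(A0$sub, Ac$sub)
  expect_identical(A0$bc_left, Ac$bc_left)
})

test_that("nonlinear stiffness entries match the transcribed q_i / r_i bands", {
  # closed-form bands, transcribed independently of the element-sum assembly
  bands_k1 <- function(D0, d, h, a) {           # a: full nodal vector, 0-based
    M <- length(a) - 2L
    i <- 1:M
    q <- -1 - (d / 2) * (a[i + 1] + a[i + 2])   # a_i, a_{i+1} (0-based)
    r <- 2 + (d / 2) * (a[i] + 2 * a[i + 1] + a[i + 2])
    list(q = (D0 / h) * q[1:(M - 1)], r = (D0 / h) * r)
  }
  bands_k2 <- function(D0, d, h, a) {
    M <- length(a) - 2L
    g <- 1 + d * a
    i <- 1:M
    q <- -(1 / 3) * (g[i + 1]^2 + g[i + 1] * g[i + 2] + g[i + 2]^2)
    r <- (1 / 3) * g[i]^2 + (2 / 3) * g[i + 1]^2 + (1 / 3) * g[i + 2]^2 +
      (1 / 3) * g[i + 1] * (2 + d * a[i] + d * a[i + 2])
    list(q = (D0 / h) * q[1:(M - 1)], r = (D0 / h) * r)
  }
  set.seed(23)
  for (rep in 1:5) {
    mesh <- build_mesh(L = stats::runif(1, 0.5, 4), M = sample(4:12, 1))
    a <- stats::runif(mesh$M + 2)
    d <- stats::runif(1, -0.9, 1)
    D0 <- stats::runif(1, 0.5, 50)
    for (k in 1:2) {
      A <- assemble_stiffness_nonlinear(mesh, diffusion_law(D0, d, k),
                                        nodal_field(mesh, a))
      ref <- if (k == 1) bands_k1(D0, d, mesh$h, a) else bands_k2(D0, d, mesh$h, a)
      expect_equal(A$diag, ref$r, tolerance = 1e-12)
      expect_equal(A$sub, ref$q, tolerance = 1e-12)
      expect_equal(A$sub, A$sup)
    }
  }
})

test_that("nonlinear stiffness entries match blind numerical quadrature", {
  set.seed(31)
  mesh <- build_mesh(L = 1.7, M = 6)
  a <- stats::runif(8)
  for (params in list(c(0.6, 1), c(-0.4, 2), c(0.9, 2))) {
    d <- params[1]; k <- params[2]
    law <- diffusion_law(2.2, d, k)
    A <- assemble_stiffness_nonlinear(mesh, law, nodal_field(mesh, a))
    weight <- function(x) 2.2 * (1 + d * field_eval(mesh, a, x))^k
    for (i in 1:6) {
      expect_equal(A$diag[i], quad_stiffness_entry(mesh, i, i, weight),
                   tolerance = 1e-11)
      if (i < 6)
        expect_equal(A$sub[i], quad_stiffness_entry(mesh, i, i + 1, weight),
                     tolerance = 1e-11)
    }
    expect_equal(A$bc_left, quad_stiffness_entry(mesh, 0, 1, weight),
                 tolerance = 1e-11)
    expect_equal(A$bc_right, quad_stiffness_entry(mesh, 7, 6, weight),
                 tolerance = 1e-11)
  }
})

test_that("uniform state scales the k = 1 stiffness by 1 + delta * c", {
  mesh <- build_mesh(L = 2.2, M = 9)
  c0 <- 0.55; d <- 0.7
  A <- assemble_stiffness_nonlinear(mesh, diffusion_law(4, d, 1),
                                    nodal_field(mesh, rep(c0, 11)))
  Ac <- assemble_stiffness_constant(mesh, 4)
  expect_equal(A$diag, (1 + d * c0) * Ac$diag, tolerance = 1e-14)
  expect_equal(A$sub, (1 + d * c0) * Ac$sub, tolerance = 1e-14)
})

test_that("mass and implicit-Euler system matrices are SPD", {
  set.seed(47)
  for (rep in 1:5) {
    mesh <- build_mesh(L = stats::runif(1, 0.5, 5), M = sample(3:20, 1))
    expect_spd(dense_tridiag(assemble_mass(mesh)))
    d <- stats::runif(1, -0.99, 1)
    law <- diffusion_law(stats::runif(1, 0.1, 80), d, sample(1:2, 1))
    state <- nodal_field(mesh, stats::runif(mesh$M + 2))
    A <- assemble_stiffness_nonlinear(mesh, law, state)
    dt <- stats::runif(1, 1e-4, 10)
    sys <- as.matrix(assemble_mass(mesh))
    sys <- sys + dt * dense_tridiag(A)
    expect_spd(sys)
  }
})

test_that("diffusion law guards its admissible range", {
  expect_error(diffusion_law(1, -1.2, 1), "inadmissible")
  expect_warning(diffusion_law(1, -1, 2), "degenerate")
  expect_error(diffusion_law(-1, 0, 1), "positive")
  law <- diffusion_law(17.413, 0.3, 2)
  expect_equal(diffusivity(law, 0), 17.413)
  expect_equal(diffusivity(law, 1), 17.413 * 1.69)
})
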