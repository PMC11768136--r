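#' Symmetric tridiagonal matrix with optional boundary couplings
#'
#' Storage for the interior finite-element matrices. `sub`, `diag`, `sup` hold
#' the three bands of the `M x M` interior block (basis `e_1 ... e_M`).
#' `bc_left` / `bc_right` hold the single non-zero interaction of the first /
#' last interior row with the boundary half-tents `e_0` / `e_{M+1}`; they are
#' needed to impose non-homogeneous surface concentrations consistently and
#' are carried alongside the interior block.
#'
#' @param sub,sup Sub/super-diagonal, length `M - 1` (equal here: all matrices
#'   assembled in this package are symmetric).
#' @param diag Main diagonal, length `M`.
#' @param bc_left,bc_right Coupling coefficients with the boundary nodes
#'   (default `NA`, meaning not applicable).
#' @return An object of class `tridiag`.
#' @export
tridiag <- function(sub, diag, sup = sub, bc_left = NA_real_, bc_right = NA_real_) {
  sub <- as.numeric(sub); diag <- as.numeric(diag); sup <- as.numeric(sup)
  if (length(sub) != length(diag) - 1L || length(sup) != length(diag) - 1L)
    stop("band lengths inconsistent: need length(sub) = length(sup) = length(diag) - 1")
  structure(list(sub = sub, diag = diag, sup = sup,
                 bc_left = bc_left, bc_right = bc_right),
            class = "tridiag")
}

#' @export
print.tridiag <- function(x, ...) {
  cat(sprintf("<tridiag> %d x %d, symmetric: %s\n", length(x$diag), length(x$diag),
              isTRUE(all.equal(x$sub, x$sup))))
  invisible(x)
}

#' @export
as.matrix.tridiag <- function(x, ...) {
  n <- length(x$diag)
  m <- diag(x$diag, n, n)
  if (n > 1L) {
    m[cbind(2:n, 1:(n - 1L))] <- x$sub
    m[cbind(1:(n - 1L), 2:n)] <- x$sup
  }
  m
}

#' @export
dim.tridiag <- function(x) rep(length(x$diag), 2L)

# y = T x for the interior tridiagonal block
tridiag_mult <- function(mat, x) {
  n <- length(mat$diag)
  if (length(x) != n) stop("dimension mismatch in tridiag_mult")
  y <- mat$diag * x
  if (n > 1L) {
    y[1:(n - 1L)] <- y[1:(n - 1L)] + mat$sup * x[2:n]
    y[2:n] <- y[2:n] + mat$sub * x[1:(n - 1L)]
  }
  y
}

# A + c*B on the bands; boundary couplings combined the same way when present
tridiag_add <- function(a, b, scale = 1) {
  tridiag(a$sub + scale * b$sub, a$diag + scale * b$diag, a$sup + scale * b$sup,
          bc_left = if (is.na(a$bc_left) || is.na(b$bc_left)) NA_real_
                    else a$bc_left + scale * b$bc_left,
          bc_right = if (is.na(a$bc_right) || is.na(b$bc_right)) NA_real_
                     else a$bc_right + scale * b$bc_right)
}

#' Concentration-dependent diffusion law
#'
#' Defines `D(phi) = D0 * (1 + delta * phi)^k`, the power-law dependence of
#' the diffusion coefficient on the local (normalized) drug concentration.
#' `delta = 0` recovers a constant coefficient `D0`; `delta > -1` keeps
#' `D > 0` on the physical range `phi` in `[0, 1]`. The degenerate edge
#' `delta = -1` (where `D(1) = 0`) is admitted with a warning because the
#' delta grid scan evaluates it.
#'
#' @param D0 Dilute-limit diffusion coefficient `D(0)` (micrometre^2/hour), positive.
#' @param delta Dimensionless concentration-dependence parameter, `>= -1`.
#' @param k Integer exponent (1 or 2 in the closed-form assembly; larger
#'   values fall back to exact Gauss-Legendre quadrature).
#' @return An object of class `diffusion_law`.
#' @examples
#' law <- diffusion_law(D0 = 17.413, delta = 0.3, k = 2)
#' diffusivity(law, c(0, 0.5, 1))
#' @export
diffusion_law <- function(D0, delta = 0, k = 1L) {
  if (!is.numeric(D0) || length(D0) != 1L || !is.finite(D0) || D0 <= 0)
    stop("`D0` must be a single positive number (micrometre^2/hour)")
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta))
    stop("`delta` must be a single finite number")
  if (delta < -1)
    stop("inadmissible diffusion law: `delta` < -1 makes D(phi) negative on [0, 1]")
  if (delta == -1)
    warning("degenerate diffusion law: delta = -1 gives D(1) = 0 (no ellipticity margin)")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a positive integer exponent")
  structure(list(D0 = D0, delta = delta, k = as.integer(k)), class = "diffusion_law")
}

#' @export
print.diffusion_law <- function(x, ...) {
  cat(sprintf("<diffusion_law> D(phi) = %g * (1 + %g * phi)^%d  [um^2/h]\n",
              x$D0, x$delta, x$k))
  invisible(x)
}

#' Evaluate a diffusion law
#' @param law A [diffusion_law()].
#' @param phi Concentration value(s).
#' @return `D0 * (1 + delta * phi)^k`, vectorized over `phi`.
#' @export
diffusivity <- function(law, phi) {
  stopifnot(inherits(law, "diffusion_law"))
  law$D0 * (1 + law$delta * phi)^law$k
}

#' Assemble the interior mass matrix
#'
#' P1 mass matrix on a uniform mesh: diagonal `2h/3`, off-diagonal `h/6`.
#' The boundary couplings (first/last interior hat against the boundary
#' half-tents) are `h/6` as well.
#'
#' @param mesh An [build_mesh()] mesh.
#' @return A [tridiag()] of size `M x M` with `bc_left = bc_right = h/6`.
#' @export
assemble_mass <- function(mesh) {
  stopifnot(inherits(mesh, "fe_mesh"))
  h <- mesh$h; M <- mesh$M
  tridiag(rep(h / 6, M - 1L), rep(2 * h / 3, M),
          bc_left = h / 6, bc_right = h / 6)
}

#' Assemble the constant-coefficient stiffness matrix
#'
#' P1 stiffness matrix for a constant diffusion coefficient `D`: diagonal
#' `2D/h`, off-diagonal `-D/h`; boundary couplings `-D/h`.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param D Constant diffusion coefficient (micrometre^2/hour), positive.
#' @return A [tridiag()] of size `M x M`.
#' @export
assemble_stiffness_constant <- function(mesh, D) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("`D` must be a single positive number")
  h <- mesh$h; M <- mesh$M
  tridiag(rep(-D / h, M - 1L), rep(2 * D / h, M),
          bc_left = -D / h, bc_right = -D / h)
}

#' Exact element integral of the diffusion coefficient
#'
#' Integral of `D(phi_h)` over one element of width `h`, where `phi_h` varies
#' linearly from `aL` to `aR` across the element. Closed forms for the
#' exponents used in practice:
#' * `k = 1`: `h * D0 * (1 + delta * (aL + aR) / 2)`
#' * `k = 2`: `(h * D0 / 3) * ((1+d*aL)^2 + (1+d*aL)(1+d*aR) + (1+d*aR)^2)`
#' * `k >= 3`: Gauss-Legendre with `ceiling((k+1)/2)` points (exact for the
#'   degree-`k` polynomial integrand).
#'
#' Dividing by `h^2` and attaching signs gives the element stiffness
#' contributions, since the P1 gradients are `+-1/h` on the element.
#'
#' @param law A [diffusion_law()].
#' @param aL,aR Nodal concentrations at the element ends (vectorized).
#' @param h Element width (micrometres), positive.
#' @return Element integral(s) of `D(phi_h)`.
#' @export
element_diffusivity_integral <- function(law, aL, aR, h) {
  stopifnot(inherits(law, "diffusion_law"))
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("`h` must be positive")
  d <- law$delta
  if (law$k == 1L) {
    h * law$D0 * (1 + d * (aL + aR) / 2)
  } else if (law$k == 2L) {
    gL <- 1 + d * aL; gR <- 1 + d * aR
    (h * law$D0 / 3) * (gL^2 + gL * gR + gR^2)
  } else {
    ng <- ceiling((law$k + 1) / 2)
    gl <- pracma::gaussLegendre(ng, 0, 1)
    out <- numeric(length(aL))
    for (j in seq_len(ng))
      out <- out + gl$w[j] * (1 + d * (aL + (aR - aL) * gl$x[j]))^law$k
    h * law$D0 * out
  }
}

#' Assemble the concentration-dependent stiffness matrix
#'
#' Stiffness matrix for `D(phi) = D0 (1 + delta phi)^k` evaluated at a frozen
#' (lagged) nodal state, as used by the Picard-linearized implicit Euler
#' scheme. Entries are built by summing [element_diffusivity_integral()] over
#' the one or two elements adjacent to each node pair, with the P1 gradient
#' factors `+-1/h^2`; for `k = 1, 2` this reproduces the closed-form band
#' entries exactly. The state must include its boundary values, which enter
#' the elements next to the surfaces.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param law A [diffusion_law()].
#' @param state A [nodal_field()] on `mesh` (or a numeric vector of length
#'   `M + 2`), the concentration at which `D` is frozen.
#' @return A [tridiag()] of size `M x M` with boundary couplings filled in.
#' @export
assemble_stiffness_nonlinear <- function(mesh, law, state) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(law, "diffusion_law"))
  v <- if (inherits(state, "nodal_field")) {
    if (!identical(state$mesh$nodes, mesh$nodes))
      stop("`state` is defined on a different mesh")
    state$values
  } else as.numeric(state)
  M <- mesh$M; h <- mesh$h
  if (length(v) != M + 2L)
    stop(sprintf("`state` must have length M + 2 = %d", M + 2L))
  # delta = 0 collapses the law to the constant coefficient D0; take the
  # closed-form constant assembly so the reduction is exact entry-by-entry
  if (law$delta == 0)
    return(assemble_stiffness_constant(mesh, law$D0))
  # S[j] = integral of D(phi_h) over element j (between nodes j-1 and j, 0-based)
  S <- element_diffusivity_integral(law, v[1:(M + 1L)], v[2:(M + 2L)], h)
  dg <- (S[1:M] + S[2:(M + 1L)]) / h^2
  off <- if (M > 1L) -S[2:M] / h^2 else numeric(0)
  tridiag(off, dg, bc_left = -S[1] / h^2, bc_right = -S[M + 1L] / h^2)
}
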