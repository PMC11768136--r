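#' Uniform one-dimensional finite-element mesh
#'
#' Builds a uniform partition of the film cross-section `[-L, L]` with `M`
#' interior nodes, i.e. `M + 2` equally spaced nodes `x_0 = -L, ..., x_{M+1} = L`
#' and spacing `h = 2L/(M+1)`. The two boundary nodes are always stored so that
#' prescribed surface concentrations are a plain assignment into the nodal
#' vector rather than a separate object.
#'
#' @param L Half-thickness of the film (micrometres), `L > 0`.
#' @param M Number of interior nodes, integer `>= 1`.
#'
#' @return An object of class `fe_mesh`: a list with elements `L`, `M`,
#'   `h` and `nodes` (length `M + 2`, strictly increasing, from `-L` to `L`).
#'
#' @examples
#' m <- build_mesh(L = 1, M = 3)
#' m$h          # 0.5
#' m$nodes      # -1 -0.5 0 0.5 1
#' @export
build_mesh <- function(L, M) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("`L` must be a single positive number (half-thickness in micrometres)")
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M < 1 || M != round(M))
    stop("`M` must be a single integer >= 1 (interior node count)")
  M <- as.integer(M)
  h <- 2 * L / (M + 1)
  nodes <- -L + h * (0:(M + 1))
  nodes[M + 2] <- L  # guard the right endpoint against accumulated rounding
  structure(list(L = L, M = M, h = h, nodes = nodes), class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> [-L, L] = [%g, %g] um, M = %d interior nodes, h = %g um\n",
              -x$L, x$L, x$M, x$h))
  invisible(x)
}

#' Nodal concentration field on a mesh
#'
#' A piecewise-linear field identified by one value per node, boundary nodes
#' included (length `M + 2`). The interior slice `values[2:(M+1)]` carries the
#' finite-element coefficients; the first and last entries carry the
#' prescribed surface concentration (the Dirichlet lifting).
#'
#' @param mesh An [build_mesh()] mesh.
#' @param values Numeric vector of length `mesh$M + 2`.
#' @return An object of class `nodal_field` with elements `mesh` and `values`.
#' @export
nodal_field <- function(mesh, values) {
  stopifnot(inherits(mesh, "fe_mesh"))
  values <- as.numeric(values)
  if (length(values) != mesh$M + 2L)
    stop(sprintf("`values` must have length M + 2 = %d, got %d",
                 mesh$M + 2L, length(values)))
  structure(list(mesh = mesh, values = values), class = "nodal_field")
}

#' @export
print.nodal_field <- function(x, ...) {
  cat(sprintf("<nodal_field> %d nodes on [%g, %g], range [%g, %g]\n",
              length(x$values), -x$mesh$L, x$mesh$L,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Evaluate a hat (tent) basis function
#'
#' Piecewise-linear basis function centred at node `i` (0-based, so `i = 0`
#' and `i = M + 1` are the boundary half-tents), equal to 1 at `x_i`, 0 at all
#' other nodes, supported on `[x_{i-1}, x_{i+1}]`.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param i Node index, 0-based, in `0:(M+1)`.
#' @param x Coordinates (micrometres), all within `[-L, L]`; vectorized.
#' @return Basis values at `x`.
#' @export
hat_value <- function(mesh, i, x) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (length(i) != 1L || i < 0 || i > mesh$M + 1 || i != round(i))
    stop("`i` must be a single node index in 0:(M+1)")
  tol <- 1e-12 * max(1, mesh$L)
  if (any(x < -mesh$L - tol | x > mesh$L + tol))
    stop("`x` outside the domain [-L, L]")
  xi <- mesh$nodes[i + 1L]
  pmax(0, 1 - abs(x - xi) / mesh$h)
}

# f_i = integral of phi0 * e_i over the support of interior hat i, for all
# interior i at once. phi0: scalar, function, or nodal values (length M+2).
.project_rhs <- function(mesh, phi0) {
  M <- mesh$M
  h <- mesh$h
  if (is.numeric(phi0) && length(phi0) == 1L) {
    return(rep(phi0 * h, M))
  }
  if (is.numeric(phi0) && length(phi0) == M + 2L) {
    # phi0 already piecewise linear on this mesh: exact mass-matrix product
    v <- phi0
    i <- 2:(M + 1L)
    return((h / 6) * v[i - 1L] + (2 * h / 3) * v[i] + (h / 6) * v[i + 1L])
  }
  if (!is.function(phi0))
    stop("`phi0` must be a scalar, a function of x, or a nodal vector of length M + 2")
  # composite Simpson per element, doubled until successive results agree
  simpson_rhs <- function(nsub) {
    f <- numeric(M)
    for (e in 1:(M + 1L)) {          # element e spans nodes e-1, e (0-based)
      a <- mesh$nodes[e]; b <- mesh$nodes[e + 1L]
      xs <- seq(a, b, length.out = nsub + 1L)
      w <- c(1, rep(c(4, 2), length.out = nsub - 1L), 1)
      w[length(w)] <- 1
      base <- ((b - a) / (3 * nsub)) * w * phi0(xs)
      # left hat of the element is node e-1, right hat is node e (0-based)
      up <- (xs - a) / h              # right-hat values on the element
      if (e >= 2L)      f[e - 1L] <- f[e - 1L] + sum(base * (1 - up))
      if (e <= M)       f[e]      <- f[e]      + sum(base * up)
    }
    f
  }
  nsub <- 8L
  f <- simpson_rhs(nsub)
  repeat {
    nsub <- nsub * 2L
    f2 <- simpson_rhs(nsub)
    if (max(abs(f2 - f)) <= 1e-10 * max(1, max(abs(f2)))) return(f2)
    if (nsub > 2^14) stop("quadrature for `phi0` did not converge")
    f <- f2
  }
}

#' L2-projection of initial data onto the finite-element space
#'
#' Computes the best piecewise-linear, zero-trace approximation of the initial
#' concentration `phi0` in the mean-square sense: the interior coefficients
#' solve the mass-matrix system `B alpha = f` with `f_i = integral(phi0 e_i)`.
#' The right-hand side is exact for constant or piecewise-linear `phi0` and
#' uses adaptive composite Simpson quadrature otherwise.
#'
#' Because the projection space has zero boundary trace, the projected field
#' of a uniform `phi0 = 1` oscillates near the surfaces: that initial boundary
#' layer is the physically meaningful incompatibility between a loaded film
#' and its surface condition. The stored boundary entries are set to
#' `boundary_value` (the ambient surface concentration at the initial instant
#' by default); pass `boundary_value = phi0` for diagnostics of the projected
#' interior alone.
#'
#' The interior unknown of the lifted formulation is `phi0` minus the
#' boundary lifting `boundary_value * (e_0 + e_{M+1})`, so the lifting's mass
#' coupling is subtracted from the right-hand side before solving. With
#' `boundary_value = 0` this is the plain projection of `phi0`; with
#' `boundary_value = phi0` (a film in equilibrium with its surroundings) the
#' projected field is exactly the constant `phi0`, as stationarity requires.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param phi0 Initial concentration: scalar, function of `x`, or nodal vector.
#' @param boundary_value Value stored at the two boundary nodes (default 0).
#' @return A [nodal_field()].
#' @export
l2_project_initial <- function(mesh, phi0, boundary_value = 0) {
  f <- .project_rhs(mesh, phi0)
  f[1] <- f[1] - (mesh$h / 6) * boundary_value
  f[mesh$M] <- f[mesh$M] - (mesh$h / 6) * boundary_value
  B <- assemble_mass(mesh)
  alpha <- thomas_solve(B, f)
  nodal_field(mesh, c(boundary_value, alpha, boundary_value))
}

#' Exact integral of a piecewise-linear nodal field
#'
#' Trapezoidal rule on the mesh nodes, which is exact for the piecewise-linear
#' interpolant: `h * (v_0/2 + v_1 + ... + v_M + v_{M+1}/2)`.
#'
#' @param field A [nodal_field()].
#' @return The integral over `[-L, L]` (micrometre x concentration).
#' @export
integrate_field <- function(field) {
  stopifnot(inherits(field, "nodal_field"))
  v <- field$values
  n <- length(v)
  field$mesh$h * (v[1] / 2 + sum(v[2:(n - 1L)]) + v[n] / 2)
}
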