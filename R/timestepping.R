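#' Thomas algorithm for tridiagonal systems
#'
#' O(M) forward elimination / back substitution for `mat %*% x = rhs`.
#' Intended for the symmetric positive-definite systems produced by the
#' implicit Euler scheme (`B + dt * A`), for which no pivoting is needed.
#' A vanishing pivot signals an inadmissible matrix and raises an error.
#'
#' @param mat A [tridiag()] (boundary couplings, if any, are ignored: the
#'   system is the interior block).
#' @param rhs Right-hand-side vector, length `M`.
#' @return Solution vector `x`.
#' @export
thomas_solve <- function(mat, rhs) {
  stopifnot(inherits(mat, "tridiag"))
  n <- length(mat$diag)
  if (length(rhs) != n) stop("dimension mismatch between matrix and rhs")
  cp <- numeric(n); dp <- numeric(n)
  piv <- mat$diag[1]
  if (piv == 0 || !is.finite(piv)) stop("zero pivot in Thomas algorithm: matrix is singular")
  if (n == 1L) return(rhs / piv)
  cp[1] <- mat$sup[1] / piv
  dp[1] <- rhs[1] / piv
  for (i in 2:n) {
    piv <- mat$diag[i] - mat$sub[i - 1L] * cp[i - 1L]
    if (piv == 0 || !is.finite(piv)) stop("zero pivot in Thomas algorithm: matrix is singular")
    if (i < n) cp[i] <- mat$sup[i] / piv
    dp[i] <- (rhs[i] - mat$sub[i - 1L] * dp[i - 1L]) / piv
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

#' Ellipticity lower bound of a diffusion law
#'
#' Smallest value of `D(phi) = D0 (1 + delta phi)^k` over the physical range
#' `phi` in `[0, 1]`. Since `D` is monotone in `phi` for `delta >= -1`, the
#' minimum sits at an endpoint: `D0` for `delta >= 0`, `D0 (1 + delta)^k`
#' otherwise. A positive bound guarantees unique solvability of every linear
#' system in the scheme; `delta = -1` returns 0 with a warning.
#'
#' @param law A [diffusion_law()].
#' @return The lower bound `D*` (micrometre^2/hour).
#' @export
check_ellipticity <- function(law) {
  stopifnot(inherits(law, "diffusion_law"))
  dstar <- min(diffusivity(law, 0), diffusivity(law, 1))
  if (dstar <= 0)
    warning("diffusion law is degenerate on [0, 1]: D* = 0, ellipticity is lost")
  dstar
}

#' Boundary and initial conditions for a simulation
#'
#' @param phi0 Uniform initial concentration inside the film (scalar), or a
#'   function of `x` for non-uniform loading. Default 1 (fully loaded film,
#'   normalized).
#' @param phiInf Surface concentration: either a constant (default 0, perfect
#'   sink) or a two-column `data.frame`/list with components `time` and
#'   `value`, linearly interpolated to solver times and extrapolated as
#'   constant beyond its range.
#' @return An object of class `boundary_spec`.
#' @export
boundary_spec <- function(phi0 = 1, phiInf = 0) {
  if (!(is.function(phi0) || (is.numeric(phi0) && length(phi0) == 1L && is.finite(phi0))))
    stop("`phi0` must be a finite scalar or a function of x")
  if (is.numeric(phiInf) && length(phiInf) == 1L) {
    if (!is.finite(phiInf)) stop("`phiInf` must be finite")
  } else {
    phiInf <- as.data.frame(phiInf)
    if (!all(c("time", "value") %in% names(phiInf)))
      stop("a time-dependent `phiInf` needs columns `time` and `value`")
    if (nrow(phiInf) < 1L || any(!is.finite(phiInf$time)) || any(!is.finite(phiInf$value)))
      stop("`phiInf` series must be finite")
    if (is.unsorted(phiInf$time, strictly = TRUE))
      stop("`phiInf` series times must be strictly increasing")
  }
  structure(list(phi0 = phi0, phiInf = phiInf), class = "boundary_spec")
}

#' Surface concentration at given times
#' @param boundary A [boundary_spec()].
#' @param t Time(s) (hours).
#' @return `phiInf` evaluated at `t` (constant, or linearly interpolated with
#'   constant extrapolation).
#' @export
phi_inf_at <- function(boundary, t) {
  stopifnot(inherits(boundary, "boundary_spec"))
  if (is.numeric(boundary$phiInf)) return(rep_len(boundary$phiInf, length(t)))
  s <- boundary$phiInf
  if (nrow(s) == 1L) return(rep_len(s$value, length(t)))
  stats::approx(s$time, s$value, xout = t, rule = 2)$y
}

#' Validate a simulation time grid
#'
#' @param times Strictly increasing times (hours) starting at `t = 0`;
#'   non-uniform spacing is allowed.
#' @return The times, as a plain numeric vector (invisibly classed `time_grid`).
#' @export
time_grid <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2L || any(!is.finite(times)))
    stop("`times` must contain at least two finite values")
  if (abs(times[1]) > 0) stop("`times` must start at t = 0")
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing")
  structure(times, class = c("time_grid", "numeric"))
}

#' Refine a time grid to a maximum step
#'
#' Subdivides each interval uniformly so that no step exceeds `max_dt`,
#' keeping every original time as a grid point (so sampled experimental times
#' can serve directly as reporting points of a refined solver grid).
#'
#' @param times Strictly increasing times including `t = 0`.
#' @param max_dt Maximum allowed step (hours).
#' @return Refined, strictly increasing time vector.
#' @export
refine_grid <- function(times, max_dt) {
  times <- as.numeric(times)
  stopifnot(max_dt > 0, length(times) >= 2L)
  out <- times[1]
  for (i in seq_len(length(times) - 1L)) {
    nseg <- max(1L, ceiling((times[i + 1L] - times[i]) / max_dt - 1e-12))
    out <- c(out, times[i] + (times[i + 1L] - times[i]) * (1:nseg) / nseg)
  }
  out[length(out)] <- times[length(times)]
  out
}

# One implicit Euler step: shared core.
# state: full nodal vector (length M+2) at t_n, including its boundary values.
# Returns the full nodal vector at t_{n+1}, boundary entries = phi_next.
.advance <- function(mesh, law, dt, state_values, phi_next,
                     mode = c("consistent", "lifted"), picard_iters = 1L,
                     picard_tol = 1e-10) {
  mode <- match.arg(mode)
  M <- mesh$M; h <- mesh$h
  B <- assemble_mass(mesh)
  alpha_n <- state_values[2:(M + 1L)]
  lag <- state_values
  iter_prev <- NULL
  for (it in seq_len(max(1L, picard_iters))) {
    Ahat <- assemble_stiffness_nonlinear(mesh, law, lag)
    sys <- tridiag_add(B, Ahat, scale = dt)
    if (mode == "consistent") {
      # Full-node mass and stiffness, Dirichlet rows eliminated exactly:
      # old boundary values enter through the mass coupling, the new one
      # through both mass and (lagged) stiffness couplings.
      rhs <- tridiag_mult(B, alpha_n)
      rhs[1] <- rhs[1] + (h / 6) * state_values[1] -
        ((h / 6) + dt * Ahat$bc_left) * phi_next
      rhs[M] <- rhs[M] + (h / 6) * state_values[M + 2L] -
        ((h / 6) + dt * Ahat$bc_right) * phi_next
    } else {
      # compact lifted form: rhs = B alpha_n - (B + dt Ahat) mu, with mu
      # carrying phiInf in its first and last interior entries
      mu <- numeric(M); mu[1] <- phi_next; mu[M] <- phi_next
      rhs <- tridiag_mult(B, alpha_n) - tridiag_mult(sys, mu)
    }
    alpha <- thomas_solve(sys, rhs)
    if (any(!is.finite(alpha)))
      stop("numerical blow-up: non-finite state produced by the time step")
    new_full <- c(phi_next, alpha, phi_next)
    if (!is.null(iter_prev) && max(abs(new_full - iter_prev)) < picard_tol) {
      lag <- new_full
      break
    }
    iter_prev <- new_full
    lag <- new_full
  }
  lag
}

#' One implicit Euler step with constant diffusivity
#'
#' Advances the nodal concentration by `dt` with constant coefficient `D` and
#' constant surface concentration `phiInf`, using the consistent boundary
#' treatment (exact mass and stiffness couplings with the boundary nodes).
#'
#' @param mesh An [build_mesh()] mesh.
#' @param D Constant diffusion coefficient (micrometre^2/hour).
#' @param dt Time step (hours), positive.
#' @param state A [nodal_field()] at the current time (boundary values included).
#' @param phiInf Surface concentration at the new time level.
#' @return A [nodal_field()] at the new time level.
#' @export
step_constant <- function(mesh, D, dt, state, phiInf = 0) {
  stopifnot(inherits(state, "nodal_field"), dt > 0)
  law <- diffusion_law(D0 = D, delta = 0, k = 1L)
  nodal_field(mesh, .advance(mesh, law, dt, state$values, phiInf,
                             mode = "consistent", picard_iters = 1L))
}

#' One implicit Euler step with concentration-dependent diffusivity
#'
#' Advances the nodal concentration by `dt` with `D(phi)` frozen at the
#' previous state (lagged-coefficient / Picard linearization): each sweep
#' assembles the stiffness matrix from the latest available state and solves
#' one tridiagonal system. With `picard_iters = 1` (default) this is the
#' plain lagged scheme; more sweeps iterate the linearization to tolerance
#' `1e-10` in the max norm.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param law A [diffusion_law()].
#' @param dt Time step (hours), positive.
#' @param state A [nodal_field()] at the current time.
#' @param phiInf_next Surface concentration at the new time level.
#' @param mode `"consistent"` (default; exact boundary couplings, reduces to
#'   the constant-coefficient scheme when `delta = 0` and `phiInf` is
#'   constant) or `"lifted"` (compact lifted right-hand side, kept for
#'   comparison runs).
#' @param picard_iters Maximum Picard sweeps per step (default 1).
#' @return A [nodal_field()] at the new time level.
#' @export
step_nonlinear <- function(mesh, law, dt, state, phiInf_next,
                           mode = c("consistent", "lifted"), picard_iters = 1L) {
  stopifnot(inherits(state, "nodal_field"), dt > 0)
  nodal_field(mesh, .advance(mesh, law, dt, state$values, phiInf_next,
                             mode = match.arg(mode), picard_iters = picard_iters))
}

#' Simulate the concentration history
#'
#' Full forward solve: the initial state is the L2-projection of `phi0`
#' (boundary entries set to the surface concentration at the initial
#' instant), then one lagged-coefficient implicit Euler step per interval of
#' `times`. Surface concentrations are taken from `boundary` at each new time
#' level (constant, or interpolated from an empirical series).
#'
#' @param mesh An [build_mesh()] mesh.
#' @param law A [diffusion_law()].
#' @param times Solver times (hours), strictly increasing from 0 (see
#'   [time_grid()], [refine_grid()]).
#' @param boundary A [boundary_spec()].
#' @param mode Boundary treatment, `"consistent"` (default) or `"lifted"`.
#' @param picard_iters Maximum Picard sweeps per step (default 1).
#' @param initial_boundary `"ambient"` (default: boundary entries of the
#'   initial state carry `phiInf(0)`, the surface condition the film meets at
#'   `t = 0+`) or `"initial"` (carry `phi0`; diagnostic only, requires scalar
#'   `phi0`).
#' @return An object of class `concentration_history`: list with `mesh`,
#'   `times`, `states` (matrix, one column per time level, one row per node)
#'   and `boundary`.
#' @examples
#' mesh <- build_mesh(L = 3.25, M = 31)
#' law <- diffusion_law(D0 = 28.648, delta = 0.3, k = 2)
#' hist <- simulate_concentration(mesh, law, times = seq(0, 1, by = 0.01),
#'                                boundary = boundary_spec(1, 0))
#' release_from_history(hist)[1:3, ]
#' @export
simulate_concentration <- function(mesh, law, times, boundary = boundary_spec(),
                                   mode = c("consistent", "lifted"),
                                   picard_iters = 1L,
                                   initial_boundary = c("ambient", "initial")) {
  mode <- match.arg(mode)
  initial_boundary <- match.arg(initial_boundary)
  stopifnot(inherits(mesh, "fe_mesh"), inherits(law, "diffusion_law"),
            inherits(boundary, "boundary_spec"))
  times <- time_grid(times)
  nlev <- length(times)
  bvals <- phi_inf_at(boundary, times)
  b0 <- if (initial_boundary == "ambient") bvals[1] else {
    if (!is.numeric(boundary$phi0)) stop("`initial_boundary = \"initial\"` needs a scalar phi0")
    boundary$phi0
  }
  states <- matrix(NA_real_, nrow = mesh$M + 2L, ncol = nlev)
  state <- l2_project_initial(mesh, boundary$phi0, boundary_value = b0)
  states[, 1] <- state$values
  for (n in 2:nlev) {
    dt <- times[n] - times[n - 1L]
    vals <- tryCatch(
      .advance(mesh, law, dt, states[, n - 1L], bvals[n],
               mode = mode, picard_iters = picard_iters),
      error = function(e) stop(sprintf("time step %d (t = %g h) failed: %s",
                                       n - 1L, times[n], conditionMessage(e)),
                               call. = FALSE))
    states[, n] <- vals
  }
  structure(list(mesh = mesh, times = as.numeric(times), states = states,
                 boundary = boundary),
            class = "concentration_history")
}

#' @export
print.concentration_history <- function(x, ...) {
  cat(sprintf("<concentration_history> %d nodes x %d time levels, t in [%g, %g] h\n",
              nrow(x$states), ncol(x$states), x$times[1], x$times[length(x$times)]))
  invisible(x)
}
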