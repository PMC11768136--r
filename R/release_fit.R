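#' Release profile container
#'
#' A cumulative release curve: strictly increasing times (hours) and the
#' released fraction `Mt/Minf` at each time. Experimental fractions may
#' slightly exceed `[0, 1]`; they are kept as measured.
#'
#' @param time Times (hours), strictly increasing, first entry `>= 0`.
#' @param fraction Cumulative release fractions, finite.
#' @param label Optional sample name.
#' @param replicate Optional replicate index.
#' @return A `data.frame` with class `release_profile`.
#' @export
release_profile <- function(time, fraction, label = NULL, replicate = NULL) {
  time <- as.numeric(time); fraction <- as.numeric(fraction)
  if (length(time) != length(fraction))
    stop("`time` and `fraction` must have equal length")
  if (length(time) < 1L || any(!is.finite(time)) || any(!is.finite(fraction)))
    stop("times and fractions must be finite")
  if (time[1] < 0) stop("times must be >= 0")
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing")
  out <- data.frame(time = time, fraction = fraction)
  attr(out, "label") <- label
  attr(out, "replicate") <- replicate
  class(out) <- c("release_profile", "data.frame")
  out
}

#' Release profile from a simulated concentration history
#'
#' Converts a concentration history into a cumulative release curve via the
#' mass-balance functional
#' `Mt/Minf(t_n) = integral(phi_h^n - phi0) / (2L (phiInf(t_n) - phi0))`,
#' with the numerator integrated exactly over the piecewise-linear field.
#' The fraction is defined from the first post-initial level `t_1` on (the
#' initial level carries the projected loading, not a release value).
#'
#' @param history A [simulate_concentration()] result.
#' @param boundary Boundary spec (defaults to the one stored in `history`);
#'   its `phi0` must be a scalar.
#' @return A [release_profile()] at times `t_1 ... t_{N+1}`.
#' @export
release_from_history <- function(history, boundary = history$boundary) {
  stopifnot(inherits(history, "concentration_history"),
            inherits(boundary, "boundary_spec"))
  phi0 <- boundary$phi0
  if (!is.numeric(phi0))
    stop("release requires a scalar initial concentration `phi0`")
  L <- history$mesh$L
  tt <- history$times[-1]
  binf <- phi_inf_at(boundary, tt)
  bad <- which(binf == phi0)
  if (length(bad))
    stop(sprintf("phiInf equals phi0 at t = %g h: release fraction undefined",
                 tt[bad[1]]))
  num <- apply(history$states[, -1, drop = FALSE], 2L,
               function(v) integrate_field(nodal_field(history$mesh, v))) -
    2 * L * phi0
  release_profile(tt, num / (2 * L * (binf - phi0)))
}

#' Sum-of-squares error against the analytic release model
#'
#' `e_ana = sum_n (u_n - w_n(D0))^2`, where `u_n` are the profile's fractions
#' and `w_n(D0)` is the closed-form constant-coefficient release evaluated at
#' the profile's own times.
#'
#' @param profile A [release_profile()] (the experimental curve `u_n`).
#' @param D0 Diffusion coefficient (micrometre^2/hour).
#' @param L Half-thickness (micrometres).
#' @param p Series truncation index (default 100).
#' @return The residual sum of squares.
#' @export
error_analytic <- function(profile, D0, L, p = 100L) {
  stopifnot(inherits(profile, "release_profile"))
  w <- analytic_release(profile$time, D = D0, L = L, p = p)
  sum((profile$fraction - w)^2)
}

#' Fit the dilute-limit diffusion coefficient to a release profile
#'
#' Stage one of the calibration: minimizes [error_analytic()] over `D0 > 0`
#' with the Nelder-Mead simplex, searching in `log10(D0)` so positivity is
#' structural. Several starting values guard against the objective's flat
#' large-`D0` tail; the best converged start is returned.
#'
#' @param profile A [release_profile()] with at least 2 distinct fractions.
#' @param L Half-thickness (micrometres).
#' @param p Series truncation index (default 100).
#' @param starts Starting values for `D0` (micrometre^2/hour).
#' @param maxit Maximum objective evaluations per start.
#' @return An object of class `fit_result`: list with `parameter` (named
#'   `D0`), `objective`, `evaluations`, `converged` and `trace` (per-start
#'   table).
#' @examples
#' prof <- release_profile(time = c(0.25, 0.5, 1, 2, 4),
#'                         fraction = analytic_release(c(0.25, 0.5, 1, 2, 4),
#'                                                     D = 28.648, L = 3.25))
#' fit_d0(prof, L = 3.25)$parameter
#' @export
fit_d0 <- function(profile, L, p = 100L, starts = c(1, 10, 100), maxit = 2000L) {
  stopifnot(inherits(profile, "release_profile"), L > 0)
  if (nrow(profile) < 2L || length(unique(profile$fraction)) < 2L)
    stop("`profile` needs at least two samples with distinct fractions")
  obj <- function(ld0) error_analytic(profile, 10^ld0, L, p = p)
  rows <- lapply(starts, function(s) {
    fit <- suppressWarnings(stats::optim(
      par = log10(s), fn = obj, method = "Nelder-Mead",
      control = list(maxit = maxit, reltol = 1e-10, abstol = 1e-10)))
    data.frame(start = s, D0 = 10^fit$par, objective = fit$value,
               evaluations = fit$counts[["function"]],
               converged = fit$convergence == 0)
  })
  trace <- do.call(rbind, rows)
  ok <- trace[trace$converged, , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("fit_d0: no Nelder-Mead start converged; trace:\n",
         paste(utils::capture.output(print(trace)), collapse = "\n"))
  best <- ok[which.min(ok$objective), ]
  structure(list(parameter = c(D0 = best$D0), objective = best$objective,
                 evaluations = sum(trace$evaluations),
                 converged = TRUE, trace = trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n  parameter:",
      paste(sprintf("%s = %g", names(x$parameter), x$parameter), collapse = ", "),
      sprintf("\n  objective: %g (%d evaluations, converged: %s)\n",
              x$objective, x$evaluations, x$converged))
  invisible(x)
}

#' Sum-of-squares error of the finite-element release model
#'
#' `e_num = sum_n (u_n - v_n)^2`: runs the lagged-coefficient finite-element
#' solver with the given diffusion law, forms the simulated release curve,
#' and compares it with the profile at the profile's own times. The solver
#' grid is the profile's times (with `t = 0` prepended) refined so that no
#' step exceeds the time span divided by `refine`.
#'
#' @param profile A [release_profile()].
#' @param law A [diffusion_law()].
#' @param mesh An [build_mesh()] mesh (its `L` fixes the half-thickness).
#' @param boundary A [boundary_spec()] (default: loaded film in a perfect
#'   sink, `phi0 = 1`, `phiInf = 0`).
#' @param mode Boundary treatment passed to [simulate_concentration()].
#' @param picard_iters Picard sweeps per step.
#' @param refine Time-grid refinement denominator (default 200; set to
#'   `NULL`/`Inf` to solve on the sample times only).
#' @return The residual sum of squares.
#' @export
error_numeric <- function(profile, law, mesh, boundary = boundary_spec(1, 0),
                          mode = c("consistent", "lifted"), picard_iters = 1L,
                          refine = 200) {
  stopifnot(inherits(profile, "release_profile"))
  tt <- profile$time
  base <- if (tt[1] > 0) c(0, tt) else tt
  grid <- if (is.null(refine) || !is.finite(refine)) base
          else refine_grid(base, max_dt = (max(base) - base[1]) / refine)
  hist <- simulate_concentration(mesh, law, grid, boundary,
                                 mode = match.arg(mode),
                                 picard_iters = picard_iters)
  sim <- release_from_history(hist, boundary)
  idx <- match(round(tt, 12), round(sim$time, 12))
  if (any(is.na(idx))) stop("internal error: sample times missing from solver grid")
  sum((profile$fraction - sim$fraction[idx])^2)
}

#' Grid search for the concentration-dependence parameter
#'
#' Stage two of the calibration: with `D0` and `k` fixed, evaluates
#' [error_numeric()] for each candidate `delta` in the grid and returns the
#' minimizer. Ties are broken toward the smallest `|delta|` (preferring the
#' simpler, closer-to-constant law).
#'
#' @param profile A [release_profile()].
#' @param D0 Diffusion coefficient from stage one (micrometre^2/hour).
#' @param k Exponent of the diffusion law (1 or 2).
#' @param delta_grid Candidate values in `[-1, 1]` (default the seven-point
#'   grid `-1, -0.3, -0.2, 0, 0.2, 0.3, 1`).
#' @param mesh An [build_mesh()] mesh (default `M = 31` on the half-thickness
#'   `L`; pass either `mesh` or `L`).
#' @param L Half-thickness, used only when `mesh` is missing.
#' @param boundary,mode,picard_iters,refine Passed to [error_numeric()].
#' @return A `fit_result` whose `parameter` is `c(delta = ...)` and whose
#'   `trace` is the full `(delta, e_num)` table.
#' @export
grid_search_delta <- function(profile, D0, k = 2L,
                              delta_grid = c(-1, -0.3, -0.2, 0, 0.2, 0.3, 1),
                              mesh = NULL, L = NULL,
                              boundary = boundary_spec(1, 0),
                              mode = "consistent", picard_iters = 1L,
                              refine = 200) {
  stopifnot(inherits(profile, "release_profile"), length(delta_grid) >= 1L)
  if (any(delta_grid < -1))
    stop("inadmissible `delta` in grid: values below -1 make D(phi) negative")
  if (is.null(mesh)) {
    if (is.null(L)) stop("provide either `mesh` or `L`")
    mesh <- build_mesh(L = L, M = 31L)
  }
  errs <- vapply(delta_grid, function(d) {
    law <- withCallingHandlers(
      diffusion_law(D0 = D0, delta = d, k = k),
      warning = function(w) invokeRestart("muffleWarning"))
    error_numeric(profile, law, mesh, boundary = boundary, mode = mode,
                  picard_iters = picard_iters, refine = refine)
  }, numeric(1))
  trace <- data.frame(delta = delta_grid, e_num = errs)
  # minimizer; ties (to within double rounding) toward smallest |delta|
  cand <- which(errs <= min(errs) * (1 + 1e-12))
  best <- cand[order(abs(delta_grid[cand]), delta_grid[cand])][1]
  structure(list(parameter = c(delta = delta_grid[best], k = k),
                 objective = errs[best],
                 evaluations = length(delta_grid), converged = TRUE,
                 trace = trace),
            class = "fit_result")
}

#' Relative improvement between two model errors
#'
#' `100 * (e_ref - e_new) / e_new`: how much more accurate the model with
#' error `e_new` is than the reference with error `e_ref`, in percent.
#'
#' @param e_ref Reference (larger, usually) residual sum of squares.
#' @param e_new Competing residual sum of squares, `> 0`.
#' @return Improvement in percent (negative when the reference is better).
#' @examples
#' improvement_percent(0.176, 0.146)  # ~20.55
#' @export
improvement_percent <- function(e_ref, e_new) {
  stopifnot(is.numeric(e_ref), is.numeric(e_new))
  if (any(e_new <= 0))
    stop("improvement undefined: `e_new` must be positive")
  100 * (e_ref - e_new) / e_new
}
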