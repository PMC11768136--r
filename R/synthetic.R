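#' Sampling-time designs for synthetic release experiments
#'
#' @param T_h Time horizon (hours), positive.
#' @param n Number of samples, `>= 2`.
#' @param scheme `"uniform"`: equally spaced on `(0, T_h]`; `"early-dense"`:
#'   geometric spacing (ratio `ratio`) concentrating samples at small times,
#'   where release curves rise fastest. Both end exactly at `T_h`.
#' @param ratio Geometric ratio for `"early-dense"` (default 0.7).
#' @return Strictly increasing times (hours).
#' @examples
#' default_times(4, 4)                  # 1 2 3 4
#' default_times(4, 6, "early-dense")
#' @export
default_times <- function(T_h, n, scheme = c("uniform", "early-dense"),
                          ratio = 0.7) {
  scheme <- match.arg(scheme)
  stopifnot(T_h > 0, n >= 2, ratio > 0, ratio < 1)
  if (scheme == "uniform") {
    seq(T_h / n, T_h, length.out = n)
  } else {
    T_h * ratio^((n - 1):0)
  }
}

#' Generate synthetic release profiles
#'
#' Emulates triplicate release experiments: the noiseless forward model (the
#' closed-form series for constant `D`, or the finite-element solver for a
#' concentration-dependent law) sampled at `times`, plus independent additive
#' Gaussian noise per replicate, optionally clipped to `[0, 1]`. The mean
#' profile across replicates is returned alongside the replicates, and the
#' whole draw is reproducible from `seed`.
#'
#' @param times Sampling times (hours), strictly increasing, positive.
#' @param L Half-thickness (micrometres).
#' @param law A [diffusion_law()], or a single number interpreted as a
#'   constant diffusion coefficient.
#' @param model `"analytic"` (constant-coefficient series; requires
#'   `delta = 0`) or `"fe"` (finite-element forward solve).
#' @param sigma Noise standard deviation on the fraction scale (default 0).
#' @param replicates Number of replicates (default 3).
#' @param seed Integer seed (default `NULL`: leave the RNG stream alone).
#' @param clip Clip noisy fractions to `[0, 1]` (default `TRUE`).
#' @param M Interior mesh nodes for the `"fe"` model (default 31).
#' @param p Series truncation for the `"analytic"` model (default 100).
#' @param label Optional sample name attached to the profiles.
#' @param mode,picard_iters,refine Solver options for the `"fe"` model, as in
#'   [error_numeric()].
#' @return A list with `mean` (a [release_profile()]), `replicates` (list of
#'   profiles) and `noiseless` (the forward-model profile).
#' @export
generate_profile <- function(times, L, law, model = c("analytic", "fe"),
                             sigma = 0, replicates = 3L, seed = NULL,
                             clip = TRUE, M = 31L, p = 100L, label = NULL,
                             mode = "consistent", picard_iters = 1L,
                             refine = 200) {
  model <- match.arg(model)
  stopifnot(sigma >= 0, replicates >= 1)
  times <- as.numeric(times)
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing and positive")
  if (is.numeric(law)) law <- diffusion_law(D0 = law, delta = 0, k = 1L)
  stopifnot(inherits(law, "diffusion_law"))
  forward <- if (model == "analytic") {
    if (law$delta != 0)
      stop("the analytic forward model requires a constant coefficient (delta = 0)")
    analytic_release(times, D = law$D0, L = L, p = p)
  } else {
    mesh <- build_mesh(L, M)
    prof <- release_profile(times, rep(0, length(times)))
    grid <- refine_grid(c(0, times), max_dt = max(times) / refine)
    hist <- simulate_concentration(mesh, law, grid, boundary_spec(1, 0),
                                   mode = mode, picard_iters = picard_iters)
    sim <- release_from_history(hist)
    sim$fraction[match(round(times, 12), round(sim$time, 12))]
  }
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(replicates), function(r) {
    y <- forward + stats::rnorm(length(times), sd = sigma)
    if (clip) y <- pmin(1, pmax(0, y))
    release_profile(times, y, label = label, replicate = r)
  })
  mean_frac <- Reduce(`+`, lapply(reps, `[[`, "fraction")) / replicates
  list(mean = release_profile(times, mean_frac, label = label),
       replicates = reps,
       noiseless = release_profile(times, forward, label = label))
}

#' Empirical surface-concentration series from a release profile
#'
#' In a finite, imperfectly stirred dissolution volume the ambient
#' concentration seen by the film surface is not zero: it is approximated
#' pointwise by `phiInf(t) = 1 - Mt/Minf`. Returns the series ready for
#' [boundary_spec()], with `(0, 1)` prepended when the profile does not start
#' at `t = 0`.
#'
#' @param profile A [release_profile()].
#' @return A `data.frame` with columns `time` and `value`.
#' @export
empirical_boundary <- function(profile) {
  stopifnot(inherits(profile, "release_profile"))
  tt <- profile$time; vv <- 1 - profile$fraction
  if (tt[1] > 0) { tt <- c(0, tt); vv <- c(1, vv) }
  data.frame(time = tt, value = vv)
}

#' Reference film samples
#'
#' The four nanocellulose/nanoporous-silicon composite films studied
#' experimentally: name, nPSi mass percentage, film thickness `2L`
#' (micrometres) and the constant-coefficient diffusivity `D0`
#' (micrometre^2/hour) fitted to each film's measured release curve.
#'
#' @return A `data.frame` with columns `name`, `npsi_percent`,
#'   `thickness_um`, `L_um` and `D0`.
#' @examples
#' reference_samples()
#' @export
reference_samples <- function() {
  s <- data.frame(
    name = c("NC", "NC/nPSi-0.1%", "NC/nPSi-0.5%", "NC/nPSi-1.0%"),
    npsi_percent = c(0, 0.1, 0.5, 1.0),
    thickness_um = c(6.5, 10.5, 12.7, 29.5),
    D0 = c(28.648, 107.640, 17.413, 51.523))
  s$L_um <- s$thickness_um / 2
  s[, c("name", "npsi_percent", "thickness_um", "L_um", "D0")]
}
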