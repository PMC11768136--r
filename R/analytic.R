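#' Closed-form concentration for constant diffusivity
#'
#' Fourier series solution of the slab diffusion problem with uniform initial
#' concentration `phi0`, constant surface concentration `phiInf` at
#' `x = +-L`, and constant diffusion coefficient `D`:
#' \deqn{\frac{\phi(x,t)-\phi_0}{\phi_\infty-\phi_0} = 1
#'   - \frac{4}{\pi}\sum_{n=0}^{p} \frac{(-1)^n}{2n+1}
#'     \cos\frac{(2n+1)\pi x}{2L}
#'     \exp\left(-\frac{D(2n+1)^2\pi^2 t}{4L^2}\right).}
#' Terms are accumulated in descending `n` so the small high-order terms are
#' summed first; terms below 1e-300 underflow harmlessly and are skipped.
#'
#' @param x Position(s) in `[-L, L]` (micrometres).
#' @param t Time(s) (hours), `>= 0`. `x` and `t` follow usual recycling rules.
#' @param D Diffusion coefficient (micrometre^2/hour), positive.
#' @param L Half-thickness (micrometres), positive.
#' @param phi0 Uniform initial concentration.
#' @param phiInf Surface concentration.
#' @param p Series truncation index: terms `n = 0 ... p` are retained
#'   (default 100).
#' @return Concentration value(s).
#' @export
analytic_concentration <- function(x, t, D, L, phi0 = 1, phiInf = 0, p = 100L) {
  stopifnot(D > 0, L > 0, p >= 0, all(t >= 0))
  tol <- 1e-12 * max(1, L)
  if (any(abs(x) > L + tol)) stop("`x` outside the domain [-L, L]")
  n <- max(length(x), length(t))
  x <- rep_len(x, n); t <- rep_len(t, n)
  s <- numeric(n)
  for (k in p:0) {
    m <- 2 * k + 1
    ex <- exp(-D * m^2 * pi^2 * t / (4 * L^2))
    if (all(ex < 1e-300)) next
    s <- s + ((-1)^k / m) * cos(m * pi * x / (2 * L)) * ex
  }
  phi0 + (phiInf - phi0) * (1 - (4 / pi) * s)
}

#' Closed-form cumulative release for constant diffusivity
#'
#' Fraction of drug released from the slab by time `t`, for the desorption
#' configuration (uniform load, zero surface concentration), constant `D`:
#' \deqn{\frac{M_t}{M_\infty} = 1 - \frac{8}{\pi^2}\sum_{n=0}^{p}
#'   \frac{1}{(2n+1)^2}\exp\left(-\frac{D(2n+1)^2\pi^2 t}{4L^2}\right).}
#' Depends on `(t, D, L)` only through the dimensionless group `D t / L^2`.
#'
#' @param t Time(s) (hours), `>= 0`; vectorized.
#' @param D Diffusion coefficient (micrometre^2/hour), positive.
#' @param L Half-thickness (micrometres), positive.
#' @param p Series truncation index (default 100).
#' @return Cumulative release fraction(s) in `[0, 1)`.
#' @examples
#' analytic_release(c(0.5, 1, 2), D = 28.648, L = 3.25)
#' @export
analytic_release <- function(t, D, L, p = 100L) {
  stopifnot(D > 0, L > 0, p >= 0, all(t >= 0))
  s <- numeric(length(t))
  for (k in p:0) {
    m <- 2 * k + 1
    ex <- exp(-D * m^2 * pi^2 * t / (4 * L^2))
    if (all(ex < 1e-300)) next
    s <- s + ex / m^2
  }
  1 - (8 / pi^2) * s
}
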