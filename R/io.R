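#' Read release profiles from a delimited text file
#'
#' Expects comma-separated text with a header containing at least the columns
#' `time_h` and `release_fraction`; optional `sample` and `replicate` columns
#' split the file into separate profiles. Rows are sorted by time and
#' validated (finite values, strictly increasing times within each profile).
#'
#' @param path Path to a CSV file.
#' @return A single [release_profile()], or a named list of them when the
#'   file holds several samples/replicates.
#' @export
read_release_profile <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "release_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  for (col in need) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite value in column `%s`, data row %d",
                   col, bad[1]))
    df[[col]] <- vals
  }
  key <- interaction(
    if ("sample" %in% names(df)) df$sample else "profile",
    if ("replicate" %in% names(df)) df$replicate else "",
    drop = TRUE, sep = "#")
  make_one <- function(rows) {
    rows <- rows[order(rows$time_h), , drop = FALSE]
    dup <- which(diff(rows$time_h) == 0)
    if (length(dup))
      stop(sprintf("duplicated time %g h (rows %d and %d after sorting)",
                   rows$time_h[dup[1]], dup[1], dup[1] + 1L))
    release_profile(rows$time_h, rows$release_fraction,
                    label = if ("sample" %in% names(rows)) rows$sample[1] else NULL,
                    replicate = if ("replicate" %in% names(rows)) rows$replicate[1] else NULL)
  }
  out <- lapply(split(df, key), make_one)
  if (length(out) == 1L) out[[1]] else out
}

#' Write a release profile to a delimited text file
#'
#' Comma-separated, period decimal, header `time_h,release_fraction` (plus
#' `sample`/`replicate` when present), values at 17 significant digits so a
#' write-then-read round trip is lossless.
#'
#' @param profile A [release_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_release_profile <- function(profile, path) {
  stopifnot(inherits(profile, "release_profile"))
  df <- data.frame(time_h = sprintf("%.17g", profile$time),
                   release_fraction = sprintf("%.17g", profile$fraction))
  lbl <- attr(profile, "label"); rep_ <- attr(profile, "replicate")
  if (!is.null(lbl)) df$sample <- lbl
  if (!is.null(rep_)) df$replicate <- rep_
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# L2(I) norm of (phi_h - analytic) at one time, 4-point Gauss per element
.l2_error_vs_series <- function(values, mesh, t, D, L, phi0, phiInf, p = 2000L) {
  gp <- c(-0.8611363115940526, -0.3399810435848563,
          0.3399810435848563, 0.8611363115940526)
  gw <- c(0.3478548451374538, 0.6521451548625461,
          0.6521451548625461, 0.3478548451374538)
  h <- mesh$h
  tot <- 0
  for (e in seq_len(mesh$M + 1L)) {
    a <- mesh$nodes[e]; b <- mesh$nodes[e + 1L]
    xs <- (a + b) / 2 + (h / 2) * gp
    fh <- values[e] + (values[e + 1L] - values[e]) * (xs - a) / h
    fx <- analytic_concentration(xs, t, D = D, L = L, phi0 = phi0,
                                 phiInf = phiInf, p = p)
    tot <- tot + (h / 2) * sum(gw * (fh - fx)^2)
  }
  sqrt(tot)
}

#' Convergence study against the closed-form solution
#'
#' Verification harness for the constant-coefficient limit: solves the
#' desorption problem on nested meshes and time grids, measures the spatial
#' L2 error at the final time against the Fourier series, and estimates
#' observed orders from successive error ratios. The spatial sweep couples
#' `dt` to `h^2` so the first-order time error does not mask the
#' second-order spatial rate; the temporal sweep fixes a fine mesh.
#'
#' @param L Half-thickness (micrometres), default 1.
#' @param D Constant diffusion coefficient, default 1.
#' @param T_h Final time (hours), default `0.25 * L^2 / D`.
#' @param phi0,phiInf Initial and surface concentrations (default 1, 0).
#' @param spatial_levels Number of mesh-halving levels (default 4, coarsest
#'   `M = 7`).
#' @param temporal_levels Number of step-halving levels (default 4, coarsest
#'   8 steps, mesh `M = 511`).
#' @param p Series truncation for the reference solution (default 2000).
#' @return A list with data frames `spatial` (`M`, `h`, `steps`, `error`,
#'   `order`) and `temporal` (`steps`, `dt`, `error`, `order`); `order` is
#'   the base-2 log ratio of successive errors (`NA` in the first row).
#' @export
run_convergence_study <- function(L = 1, D = 1, T_h = 0.25 * L^2 / D,
                                  phi0 = 1, phiInf = 0,
                                  spatial_levels = 4L, temporal_levels = 4L,
                                  p = 2000L) {
  solve_final <- function(M, N) {
    mesh <- build_mesh(L, M)
    hist <- simulate_concentration(mesh, diffusion_law(D, 0, 1L),
                                   seq(0, T_h, length.out = N + 1L),
                                   boundary_spec(phi0, phiInf))
    .l2_error_vs_series(hist$states[, N + 1L], mesh, T_h, D, L, phi0, phiInf, p)
  }
  sp <- data.frame(M = integer(), h = numeric(), steps = integer(),
                   error = numeric())
  for (lev in seq_len(spatial_levels) - 1L) {
    M <- 8L * 2L^lev - 1L
    N <- 16L * 4L^lev           # dt ~ h^2
    sp <- rbind(sp, data.frame(M = M, h = 2 * L / (M + 1), steps = N,
                               error = solve_final(M, N)))
  }
  sp$order <- c(NA, log2(sp$error[-nrow(sp)] / sp$error[-1]))
  tm <- data.frame(steps = integer(), dt = numeric(), error = numeric())
  for (lev in seq_len(temporal_levels) - 1L) {
    N <- 8L * 2L^lev
    tm <- rbind(tm, data.frame(steps = N, dt = T_h / N,
                               error = solve_final(511L, N)))
  }
  tm$order <- c(NA, log2(tm$error[-nrow(tm)] / tm$error[-1]))
  list(spatial = sp, temporal = tm)
}
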