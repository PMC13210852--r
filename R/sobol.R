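#' Sobol sampling design
#'
#' Saltelli paired-matrix design: two independent Latin-hypercube base
#' matrices of `n_base` rows on the unit hypercube, mapped to the
#' parameter ranges either linearly or in log10 space.  The full
#' design costs `(d + 2) * n_base` model evaluations.
#'
#' @param n_base base sample count (a power of 2 is recommended).
#' @param lower,upper named numeric vectors of parameter ranges.
#' @param scale `"log10"` (default: uniform in log10 between the
#'   bounds) or `"linear"`.
#' @param seed RNG seed.
#' @return An object of class `sobol_design`.
#' @export
sobol_design <- function(n_base, lower, upper, scale = c("log10", "linear"),
                         seed = 1L) {
  scale <- match.arg(scale)
  if (length(lower) != length(upper) || any(lower >= upper))
    stop("need lower < upper elementwise", call. = FALSE)
  if (scale == "log10" && any(lower <= 0))
    stop("log10 scale requires positive lower bounds", call. = FALSE)
  structure(list(n_base = as.integer(n_base), lower = lower, upper = upper,
                 d = length(lower), scale = scale, seed = as.integer(seed),
                 names = names(lower)),
            class = "sobol_design")
}

# map unit-hypercube rows to parameter space
map_design <- function(u, design) {
  lo <- design$lower; hi <- design$upper
  if (design$scale == "log10") {
    llo <- log10(lo); lhi <- log10(hi)
    out <- 10^sweep(sweep(u, 2, lhi - llo, `*`), 2, llo, `+`)
  } else {
    out <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  }
  colnames(out) <- design$names
  out
}

#' First- and total-order Sobol indices
#'
#' Saltelli paired-matrix estimation: first-order indices use the
#' Saltelli (2010) estimator `S_i = mean(f_B (f_ABi - f_A)) / V`,
#' total-order indices the Jansen estimator
#' `ST_i = mean((f_A - f_ABi)^2) / (2 V)`.  The model function may be
#' vector-valued (one column per output/time point); indices are
#' computed per column.  Rows on which any evaluation failed (`NA`)
#' are excluded pairwise and counted.
#'
#' @param f function taking a parameter matrix (rows = evaluations,
#'   columns = parameters in design order) and returning a numeric
#'   vector (one output) or matrix (rows matching input rows, one
#'   column per output).
#' @param design a [sobol_design()].
#' @return An object of class `sobol_result`: `S1` and `ST`
#'   (output x parameter matrices), `variance`, `mean` (per output),
#'   `n_base`, `n_failed`, `undefined` (logical per output: zero
#'   output variance, indices meaningless there).
#' @export
#' @examples
#' d <- sobol_design(256, c(x1 = 0, x2 = 0), c(x1 = 1, x2 = 1),
#'                   scale = "linear", seed = 1)
#' r <- sobol_indices(function(X) 3 * X[, 1] + X[, 2], d)
#' r$S1  # ~ (0.9, 0.1): variance shares 9/10 and 1/10
sobol_indices <- function(f, design) {
  n <- design$n_base; d <- design$d
  set.seed(design$seed)
  A <- map_design(lhs::randomLHS(n, d), design)
  B <- map_design(lhs::randomLHS(n, d), design)
  as_mat <- function(y) {
    y <- as.matrix(y)
    if (nrow(y) != n) stop("f must return one row per input row",
                           call. = FALSE)
    y
  }
  fA <- as_mat(f(A)); fB <- as_mat(f(B))
  n_out <- ncol(fA)
  S1 <- ST <- matrix(NA_real_, n_out, d,
                     dimnames = list(NULL, design$names))
  fAB <- vector("list", d)
  for (i in seq_len(d)) {
    ABi <- A; ABi[, i] <- B[, i]
    fAB[[i]] <- as_mat(f(ABi))
  }
  ok_rows <- stats::complete.cases(cbind(fA, fB,
                                         do.call(cbind, fAB)))
  n_failed <- sum(!ok_rows)
  variance <- numeric(n_out); f0 <- numeric(n_out)
  undefined <- logical(n_out)
  for (j in seq_len(n_out)) {
    a <- fA[ok_rows, j]; b <- fB[ok_rows, j]
    all_j <- c(a, b)
    f0[j] <- mean(all_j)
    variance[j] <- mean(all_j^2) - f0[j]^2
    if (variance[j] <= .Machine$double.eps * max(1, f0[j]^2)) {
      undefined[j] <- TRUE
      next
    }
    for (i in seq_len(d)) {
      ab <- fAB[[i]][ok_rows, j]
      S1[j, i] <- mean(b * (ab - a)) / variance[j]
      ST[j, i] <- mean((a - ab)^2) / (2 * variance[j])
    }
  }
  structure(list(S1 = S1, ST = ST, variance = variance, mean = f0,
                 n_base = n, n_failed = n_failed, undefined = undefined,
                 design = design),
            class = "sobol_result")
}

#' Default sensitivity-analysis ranges around a calibrated point
#'
#' The reference ranges for the global analysis: each parameter varies
#' over `[factor_low x, factor_high x]` its calibrated value, sampled
#' uniformly in log10 space.  Pass a [feasible_box()] instead to
#' explore the full calibration box.
#'
#' @param theta named length-8 calibrated vector (default: case-study
#'   values).
#' @param factor_low,factor_high multiplicative range limits.
#' @return List with `lower` and `upper` named vectors.
#' @export
sa_ranges <- function(theta = NULL, factor_low = 0.5, factor_high = 2) {
  if (is.null(theta)) {
    cs <- case_study_parameters()
    theta <- c(kin_to_vector(cs$kinetics), De0 = cs$transport$De0)
  }
  list(lower = theta * factor_low, upper = theta * factor_high)
}

#' Time-dependent Sobol indices of the mass-loss output
#'
#' Runs the forward model once per design row and applies
#' [sobol_indices()] to the weight loss at each evaluation time,
#' giving first- and total-order index trajectories `S_i(t)`,
#' `S_Ti(t)` for the eight parameters at a given film half-thickness.
#'
#' @param L film half-thickness (mm).
#' @param times evaluation times (h); `t = 0` is excluded
#'   automatically (zero output variance there).
#' @param n_base base sample count.
#' @param ranges list with `lower`/`upper` named length-8 vectors
#'   ([sa_ranges()] by default).
#' @param sa_nodes grid nodes used for the sensitivity runs (coarser
#'   than the reference grid; thousands of forward solves).
#' @param initial an [initial_composition()].
#' @param alpha_e,residual forwarded to the model.
#' @param seed RNG seed.
#' @return A `sobol_result` with an extra element `times`.
#' @export
time_dependent_sobol <- function(L, times = c(4, 8, 16, 20, 24, 40, 64),
                                 n_base = 256, ranges = sa_ranges(),
                                 sa_nodes = 41,
                                 initial = initial_composition(0.302),
                                 alpha_e = 1,
                                 residual = "bound_complexes", seed = 1L) {
  times <- times[times > 0]
  geometry <- film_geometry(L, N = sa_nodes)
  settings <- solver_settings(t_end = max(times), output_times = times)
  f <- function(X) {
    out <- matrix(NA_real_, nrow(X), length(times))
    for (r in seq_len(nrow(X))) {
      p <- theta_to_parameters(X[r, ], alpha_e = alpha_e)
      traj <- tryCatch(
        simulate_degradation(p$kinetics, p$transport, geometry, initial,
                             settings),
        error = function(e) NULL)
      if (!is.null(traj))
        out[r, ] <- vapply(traj$states, weight_loss_percent, numeric(1),
                           geometry = geometry, residual = residual)
    }
    out
  }
  design <- sobol_design(n_base, ranges$lower, ranges$upper,
                         scale = "log10", seed = seed)
  res <- sobol_indices(f, design)
  res$times <- times
  res
}

#' Tidy data frame of a Sobol result
#'
#' @param x a `sobol_result`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return Long-format data frame with columns `output` (time if
#'   available), `parameter`, `S1`, `ST`.
#' @export
as.data.frame.sobol_result <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  out_id <- if (!is.null(x$times)) x$times else seq_along(x$variance)
  d <- ncol(x$S1)
  data.frame(
    output = rep(out_id, d),
    parameter = rep(colnames(x$S1), each = length(out_id)),
    S1 = as.vector(x$S1),
    ST = as.vector(x$ST))
}
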