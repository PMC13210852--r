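#' Feasible parameter box
#'
#' Bound constraints for the eight-parameter vector
#' `theta = (k1, k_m1, k3, k_m3, k_conv, k_deg_C, k_deg_A, De0)`:
#' by default every rate constant lies in `[1e-6, 50]` 1/h and the
#' baseline diffusivity in `[1e-12, 50]` mm^2/h.  Lower bounds must be
#' strictly positive so the log-uniform prior over the box is proper.
#'
#' @param rate_min,rate_max bounds shared by the seven rate constants.
#' @param De0_min,De0_max bounds for the baseline diffusivity.
#' @return An object of class `feasible_box`: list with named numeric
#'   vectors `min` and `max`.
#' @export
feasible_box <- function(rate_min = 1e-6, rate_max = 50,
                         De0_min = 1e-12, De0_max = 50) {
  lo <- c(rep(rate_min, 7), De0_min)
  hi <- c(rep(rate_max, 7), De0_max)
  names(lo) <- names(hi) <- THETA_NAMES
  if (any(lo <= 0) || any(lo >= hi))
    stop("box must satisfy 0 < min < max per parameter", call. = FALSE)
  structure(list(min = lo, max = hi), class = "feasible_box")
}

in_box <- function(theta, box) {
  all(theta >= box$min) && all(theta <= box$max)
}

# Model-predicted observables at the dataset's observation times.
# Returns list(wl, chi) or NULL on integration failure.
predict_at_data_times <- function(theta, dataset, geometry, initial,
                                  alpha_e = 1, residual = "bound_complexes",
                                  solver_args = list()) {
  p <- tryCatch(theta_to_parameters(theta, alpha_e = alpha_e),
                error = function(e) NULL)
  if (is.null(p)) return(NULL)
  t_wl <- dataset$time_h[dataset$observable == "weight_loss"]
  t_chi <- dataset$time_h[dataset$observable == "crystallinity"]
  all_t <- sort(unique(c(t_wl, t_chi)))
  settings <- do.call(solver_settings,
                      c(list(t_end = max(all_t), output_times = all_t),
                        solver_args))
  # failures (integration breakdown, or a parameter draw so extreme the
  # film fully degrades and crystallinity is undefined) yield NULL
  tryCatch({
    traj <- simulate_degradation(p$kinetics, p$transport, geometry, initial,
                                 settings)
    obs <- observable_series(traj, residual = residual)
    list(wl = obs$weight_loss_pct[match(t_wl, obs$time_h)],
         chi = obs$crystallinity_pct[match(t_chi, obs$time_h)])
  }, error = function(e) NULL)
}

#' Joint weighted least-squares objective
#'
#' The calibration loss: each residual between model prediction and
#' observation is divided by that observation's measurement standard
#' deviation, squared, and summed over both series,
#' `L(theta) = sum_i ((yhat_WL(t_i) - y_WL,i)/sigma_WL,i)^2
#'           + sum_j ((yhat_chi(t_j) - y_chi,j)/sigma_chi,j)^2`.
#' Sigma-scaling places weight loss and crystallinity on a common
#' dimensionless scale so both datasets contribute comparably.
#'
#' @param theta length-8 parameter vector in the canonical order
#'   (`k1, k_m1, k3, k_m3, k_conv, k_deg_C, k_deg_A, De0`).
#' @param dataset a `degradation_dataset`.
#' @param geometry a [film_geometry()].
#' @param initial an [initial_composition()].
#' @param alpha_e porosity-diffusivity coupling (fixed, not fitted).
#' @param residual weight-loss convention, see [weight_loss_percent()].
#' @param penalty loss returned when the simulation fails at `theta`
#'   (a large finite value rather than `Inf`, so bounded optimisers
#'   can still compare failed points).
#' @return Scalar loss (dimensionless).
#' @export
wls_objective <- function(theta, dataset, geometry, initial, alpha_e = 1,
                          residual = "bound_complexes", penalty = 1e12) {
  pred <- predict_at_data_times(theta, dataset, geometry, initial,
                                alpha_e = alpha_e, residual = residual)
  if (is.null(pred)) return(penalty)
  wl <- dataset[dataset$observable == "weight_loss", ]
  chi <- dataset[dataset$observable == "crystallinity", ]
  loss <- sum(((pred$wl - wl$value_pct) / wl$sd_pct)^2)
  if (nrow(chi) > 0)
    loss <- loss + sum(((pred$chi - chi$value_pct) / chi$sd_pct)^2)
  loss
}

#' Fit the model to a degradation dataset
#'
#' Bound-constrained minimisation of [wls_objective()] over the
#' feasible box.  Parameters are searched in log10 space (the box
#' spans many orders of magnitude): a Latin-hypercube pre-search with
#' a fixed seed screens the box globally, then the best candidates
#' (and `start`, if given) are refined with `L-BFGS-B`.
#'
#' @param dataset a `degradation_dataset` (weight loss required;
#'   crystallinity recommended for joint identifiability).
#' @param geometry a [film_geometry()].
#' @param initial an [initial_composition()].
#' @param box a [feasible_box()].
#' @param start optional length-8 starting vector (natural scale).
#' @param n_presearch Latin-hypercube screening points.
#' @param n_local how many screened candidates are refined locally.
#' @param seed RNG seed for the pre-search (recorded in the result).
#' @param alpha_e,residual forwarded to the objective.
#' @return An object of class `fit_result`: `theta` (named, natural
#'   scale), `objective`, `r_squared` (per observable, computed on the
#'   raw unweighted values), `residuals` (data frame), `convergence`,
#'   `seed`, `n_local`.
#' @export
fit_parameters <- function(dataset, geometry, initial,
                           box = feasible_box(), start = NULL,
                           n_presearch = 40, n_local = 3, seed = 1L,
                           alpha_e = 1, residual = "bound_complexes") {
  lo <- log10(box$min); hi <- log10(box$max)
  d <- length(lo)
  obj_log <- function(lt) {
    wls_objective(10^lt, dataset, geometry, initial,
                  alpha_e = alpha_e, residual = residual)
  }

  set.seed(seed)
  cand <- list()
  if (!is.null(start)) {
    if (length(start) != d || !in_box(start, box))
      stop("start must be a length-8 vector inside the box", call. = FALSE)
    cand <- c(cand, list(log10(start)))
  }
  if (n_presearch > 0) {
    u <- lhs::randomLHS(n_presearch, d)
    pts <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
    losses <- apply(pts, 1, obj_log)
    keep <- order(losses)[seq_len(min(n_local, n_presearch))]
    cand <- c(cand, lapply(keep, function(i) pts[i, ]))
  }
  if (length(cand) == 0)
    stop("no starting points: give start or n_presearch > 0", call. = FALSE)

  obj_boxed <- function(lt) {
    if (any(lt < lo) || any(lt > hi)) return(1e12)
    obj_log(lt)
  }
  fits <- lapply(cand, function(p0) {
    fit <- tryCatch(
      stats::optim(p0, obj_log, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 1e5,
                                  ndeps = rep(1e-5, d))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    # derivative-free polish: the finite-difference gradient stalls in
    # the flat valley around the optimum
    polish <- stats::optim(fit$par, obj_boxed, method = "Nelder-Mead",
                           control = list(maxit = 1000, reltol = 1e-10))
    if (polish$value < fit$value) polish else fit
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    stop("all local fits failed", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta_hat <- 10^best$par
  names(theta_hat) <- THETA_NAMES

  pred <- predict_at_data_times(theta_hat, dataset, geometry, initial,
                                alpha_e = alpha_e, residual = residual)
  wl <- dataset[dataset$observable == "weight_loss", ]
  chi <- dataset[dataset$observable == "crystallinity", ]
  r2 <- function(y, yhat) {
    if (length(y) < 2) return(NA_real_)
    1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }
  resid_df <- rbind(
    data.frame(observable = "weight_loss", time_h = wl$time_h,
               observed = wl$value_pct, predicted = pred$wl,
               sd_pct = wl$sd_pct),
    if (nrow(chi) > 0)
      data.frame(observable = "crystallinity", time_h = chi$time_h,
                 observed = chi$value_pct, predicted = pred$chi,
                 sd_pct = chi$sd_pct))
  resid_df$residual <- resid_df$observed - resid_df$predicted

  structure(list(
    theta = theta_hat,
    objective = best$value,
    r_squared = c(weight_loss = r2(wl$value_pct, pred$wl),
                  crystallinity = if (nrow(chi) > 0)
                    r2(chi$value_pct, pred$chi) else NA_real_),
    residuals = resid_df,
    convergence = best$convergence,
    seed = seed,
    n_local = length(fits),
    box = box),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Weighted least-squares fit, objective =",
      format(x$objective, digits = 4), "\n")
  print(signif(x$theta, 3))
  cat("R^2 (unweighted): weight loss", round(x$r_squared[1], 3),
      "| crystallinity", round(x$r_squared[2], 3), "\n")
  invisible(x)
}
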