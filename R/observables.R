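# Trapezoidal quadrature on the uniform grid; second order, matching
# the spatial finite-difference scheme.
trapz_uniform <- function(y, dx) {
  n <- length(y)
  dx * (sum(y) - (y[1] + y[n]) / 2)
}

#' Bulk crystallinity of the remaining polymer
#'
#' The crystalline fraction of what is still polymer:
#' `chi_c = integral(C) / integral(C + A)` over the half-thickness.
#' Complexes and product are excluded because washing and drying before
#' calorimetry removes enzyme and solubles.
#'
#' @param state a `state_field`.
#' @param geometry a [film_geometry()].
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
#' @examples
#' s <- state_field(E = 0, C = rep(0.302, 5), A = rep(0.698, 5),
#'                  EC = numeric(5), EA = numeric(5), P = numeric(5))
#' bulk_crystallinity(s, film_geometry(0.25, 5))  # 0.302
bulk_crystallinity <- function(state, geometry) {
  num <- trapz_uniform(state$C, geometry$dx)
  den <- trapz_uniform(state$C + state$A, geometry$dx)
  if (den <= 1e-12 * geometry$L)
    stop("film fully degraded: no remaining polymer to take a crystalline ",
         "fraction of", call. = FALSE)
  num / den
}

#' Local crystallinity profile
#'
#' Crystalline fraction of the remaining polymer at each node,
#' `chi_i = C_i / (C_i + A_i)`.  Nodes where the polymer is fully
#' degraded (`C + A` below `tol`) are undefined and reported as `NA`,
#' never silently zeroed.
#'
#' @param state a `state_field`.
#' @param tol threshold below which a node counts as fully degraded.
#' @return Numeric vector (with `NA` at degraded nodes).
#' @export
local_crystallinity <- function(state, tol = 1e-10) {
  tot <- state$C + state$A
  chi <- ifelse(tot > tol, state$C / tot, NA_real_)
  chi
}

#' Percent weight loss
#'
#' Mass fraction of the initial polymer converted to soluble product
#' and removed to the bath.  By pointwise conservation
#' `C + A + EC + EA + P = 1`, so the default convention
#' `WL = 100 * integral(P) / L` equals
#' `100 * (1 - integral(C + A + EC + EA) / L)`: polymer still bound in
#' enzyme complexes has not left the film and is counted as residual
#' mass.  The alternative convention `residual = "free_polymer"`
#' counts only unbound polymer `C + A` as residual (complexed polymer
#' treated as lost with the wash).
#'
#' @param state a `state_field`.
#' @param geometry a [film_geometry()].
#' @param residual `"bound_complexes"` (default) or `"free_polymer"`.
#' @return Percentage in `[0, 100]`.
#' @export
weight_loss_percent <- function(state, geometry,
                                residual = c("bound_complexes",
                                             "free_polymer")) {
  residual <- match.arg(residual)
  if (residual == "bound_complexes")
    100 * trapz_uniform(state$P, geometry$dx) / geometry$L
  else
    100 * (1 - trapz_uniform(state$C + state$A, geometry$dx) / geometry$L)
}

#' Observable series of a trajectory
#'
#' @param trajectory a `deg_trajectory`.
#' @param residual weight-loss convention, see [weight_loss_percent()].
#' @return Data frame with columns `time_h`, `weight_loss_pct`,
#'   `crystallinity_pct`.
#' @export
observable_series <- function(trajectory, residual = "bound_complexes") {
  g <- trajectory$geometry
  data.frame(
    time_h = trajectory$times,
    weight_loss_pct = vapply(trajectory$states, weight_loss_percent,
                             numeric(1), geometry = g, residual = residual),
    crystallinity_pct = vapply(trajectory$states, function(s)
      100 * bulk_crystallinity(s, g), numeric(1))
  )
}

#' Local crystallinity profiles on the dimensionless position xi = x/L
#'
#' @param trajectory a `deg_trajectory`.
#' @param times subset of the trajectory's output times (default all).
#' @return Data frame with columns `time_h`, `xi`, `chi_local_pct`
#'   (`NA` where the node is fully degraded).
#' @export
spatial_profiles <- function(trajectory, times = trajectory$times) {
  idx <- match(times, trajectory$times)
  if (anyNA(idx))
    stop("requested times not in the trajectory output times", call. = FALSE)
  g <- trajectory$geometry
  do.call(rbind, lapply(idx, function(i) {
    data.frame(time_h = trajectory$times[i], xi = g$x / g$L,
               chi_local_pct = 100 * local_crystallinity(trajectory$states[[i]]))
  }))
}

#' Damkohler numbers and diffusion timescale
#'
#' Regime metrics comparing catalysis with enzyme transport:
#' `Da_A = k_deg_A * L^2 / De0`, `Da_C = k_deg_C * L^2 / De0`, and the
#' diffusion timescale `tau_diff = L^2 / De0` (h).  Small Damkohler
#' numbers indicate reaction-limited behaviour; values approaching
#' unity indicate transport influence.
#'
#' @param kinetics a [kinetic_parameters()].
#' @param transport a [transport_parameters()].
#' @param L half-thickness (mm).
#' @return An object of class `regime_metrics` with `Da_A`, `Da_C`,
#'   `tau_diff`.
#' @export
#' @examples
#' cs <- case_study_parameters()
#' damkohler(cs$kinetics, cs$transport, L = 4)$tau_diff  # ~9.64 h
damkohler <- function(kinetics, transport, L) {
  tau <- L^2 / transport$De0
  structure(list(Da_A = kinetics$k_deg_A * tau,
                 Da_C = kinetics$k_deg_C * tau,
                 tau_diff = tau, L = L),
            class = "regime_metrics")
}
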