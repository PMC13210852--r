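#' Kinetic rate constants of the two-state degradation scheme
#'
#' Bundles the seven first-order rate constants of the enzyme-polymer
#' reaction network: reversible binding of free enzyme to crystalline
#' (`k1`, `k_m1`) and amorphous (`k3`, `k_m3`) polymer, amorphisation of
#' bound crystalline material (`k_conv`), and catalytic enzymolysis of
#' the crystalline and amorphous complexes (`k_deg_C`, `k_deg_A`).
#'
#' All concentrations in the model are dimensionless (polymer volume
#' fractions, enzyme normalised by the bath concentration), so every
#' rate constant carries units of 1/h.
#'
#' @param k1,k_m1 forward/backward rate of enzyme binding to the
#'   crystalline phase (1/h).
#' @param k3,k_m3 forward/backward rate of enzyme binding to the
#'   amorphous phase (1/h).
#' @param k_conv rate of conversion of bound crystalline material to
#'   amorphous material (1/h).
#' @param k_deg_C,k_deg_A catalytic enzymolysis rates of the crystalline
#'   and amorphous complexes (1/h).
#' @return An object of class `kinetic_parameters` (a named list).
#' @export
#' @examples
#' kinetic_parameters(k1 = 0.65, k_m1 = 0.47, k3 = 0.30, k_m3 = 0.03,
#'                    k_conv = 0.58, k_deg_C = 0.0012, k_deg_A = 0.005)
kinetic_parameters <- function(k1, k_m1, k3, k_m3, k_conv, k_deg_C, k_deg_A) {
  p <- list(k1 = k1, k_m1 = k_m1, k3 = k3, k_m3 = k_m3,
            k_conv = k_conv, k_deg_C = k_deg_C, k_deg_A = k_deg_A)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("kinetic parameter '", nm, "' must be a finite non-negative scalar",
           call. = FALSE)
  }
  structure(p, class = "kinetic_parameters")
}

#' Enzyme transport parameters
#'
#' @param De0 baseline enzyme diffusivity in the dense polymer
#'   (mm^2/h).  Must be positive.
#' @param alpha_e dimensionless porosity-diffusivity coupling constant;
#'   the effective diffusivity is `De0 * (1 + alpha_e * phi)`.
#' @return An object of class `transport_parameters`.
#' @export
transport_parameters <- function(De0, alpha_e = 1) {
  if (!is.numeric(De0) || length(De0) != 1L || !is.finite(De0) || De0 <= 0)
    stop("De0 must be a finite positive scalar", call. = FALSE)
  if (!is.numeric(alpha_e) || length(alpha_e) != 1L || !is.finite(alpha_e) ||
      alpha_e < 0)
    stop("alpha_e must be a finite non-negative scalar", call. = FALSE)
  structure(list(De0 = De0, alpha_e = alpha_e), class = "transport_parameters")
}

#' Half-thickness film geometry and uniform grid
#'
#' The film is modelled on the symmetric half-thickness domain
#' `[0, L]`: `x = 0` is the exposed surface (in contact with the
#' well-mixed enzyme bath) and `x = L` the mid-plane of a film of full
#' thickness `2L`.  The grid is uniform with `N` nodes and spacing
#' `dx = L / (N - 1)`.
#'
#' @param L half-thickness of the film (mm).
#' @param N number of grid nodes (integer, at least 3).  The default
#'   keeps the spacing at or below 0.0104 mm (25 nodes for
#'   `L = 0.25` mm) so thick films are resolved at the same `dx` as the
#'   reference geometry.
#' @return An object of class `film_geometry` with elements `L`, `N`,
#'   `dx` and the node coordinates `x`.
#' @export
#' @examples
#' g <- film_geometry(L = 0.25)
#' g$N   # 25
#' g$dx  # ~0.0104 mm
film_geometry <- function(L, N = default_grid_nodes(L)) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("L must be a finite positive scalar (mm)", call. = FALSE)
  N <- as.integer(N)
  if (is.na(N) || N < 3L)
    stop("N must be an integer >= 3", call. = FALSE)
  dx <- L / (N - 1L)
  structure(list(L = L, N = N, dx = dx, x = seq(0, L, length.out = N)),
            class = "film_geometry")
}

#' Default node count for a given half-thickness
#'
#' Scales the grid so `dx <= 0.0104 mm`, the spacing of the 25-node
#' reference grid at `L = 0.25` mm; never fewer than 25 nodes.
#'
#' @param L half-thickness (mm).
#' @param dx_max largest admissible spacing (mm).
#' @return Integer node count.
#' @export
default_grid_nodes <- function(L, dx_max = 0.25 / 24) {
  max(25L, as.integer(ceiling(L / dx_max)) + 1L)
}

#' Initial film composition
#'
#' Initial crystalline (`C0`) and amorphous (`A0`) volume fractions,
#' normalised by the initial total polymer volume so `C0 + A0 = 1`.
#'
#' @param C0 initial crystalline volume fraction.
#' @param A0 initial amorphous volume fraction (default `1 - C0`).
#' @return An object of class `initial_composition`.
#' @export
initial_composition <- function(C0, A0 = 1 - C0) {
  if (!is.numeric(C0) || C0 < 0 || !is.numeric(A0) || A0 < 0)
    stop("C0 and A0 must be non-negative", call. = FALSE)
  if (abs(C0 + A0 - 1) > 1e-10)
    stop("C0 + A0 must equal 1 (fractions of the initial polymer volume)",
         call. = FALSE)
  structure(list(C0 = C0, A0 = A0), class = "initial_composition")
}

#' Stiff-integrator settings
#'
#' @param t_end end of the integration window (h).
#' @param output_times times (h) at which the state is reported; must
#'   lie in `[0, t_end]`.  Defaults to an hourly grid.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param max_step largest internal step (h).
#' @param method stiff integrator identifier passed to
#'   [deSolve::ode()]; any BDF-family implicit multistep method is
#'   conformant.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(t_end = 72, output_times = seq(0, t_end, by = 1),
                            rtol = 1e-6, atol = 1e-9, max_step = 0.5,
                            method = "bdf") {
  if (any(output_times < 0) || any(output_times > t_end + 1e-12))
    stop("output_times must lie in [0, t_end]", call. = FALSE)
  if (rtol <= 0 || atol <= 0 || max_step <= 0)
    stop("rtol, atol and max_step must be positive", call. = FALSE)
  structure(list(t_end = t_end, output_times = sort(unique(output_times)),
                 rtol = rtol, atol = atol, max_step = max_step,
                 method = method),
            class = "solver_settings")
}

#' Calibrated case-study parameters (PCL degraded by fungal lipase)
#'
#' The rate constants and baseline diffusivity calibrated jointly to
#' in-vitro weight-loss and crystallinity measurements of a 0.5 mm PCL
#' film degraded by Candida antarctica lipase, together with the
#' corresponding geometry (half-thickness 0.25 mm) and initial
#' crystallinity 0.302.
#'
#' Note on units: the baseline diffusivity is used throughout as
#' De0 = 1.66 mm^2/h, the only unit for which Fick's law and the
#' diffusion timescale L^2/De0 are dimensionally consistent.
#'
#' @return A list with elements `kinetics`, `transport`, `geometry`,
#'   `initial` and `solver`, directly usable by [simulate_degradation()].
#' @export
#' @examples
#' cs <- case_study_parameters()
#' cs$kinetics$k_deg_A  # 0.005 1/h
case_study_parameters <- function() {
  list(
    kinetics = kinetic_parameters(k1 = 0.65, k_m1 = 0.47, k3 = 0.30,
                                  k_m3 = 0.03, k_conv = 0.58,
                                  k_deg_C = 0.0012, k_deg_A = 0.005),
    transport = transport_parameters(De0 = 1.66, alpha_e = 1),
    geometry = film_geometry(L = 0.25, N = 25L),
    initial = initial_composition(C0 = 0.302),
    solver = solver_settings(t_end = 72)
  )
}

# Internal: kinetic_parameters -> named numeric vector in the canonical
# theta order (seven rates, then De0 appended by callers that need it).
kin_to_vector <- function(kin) {
  unlist(kin[c("k1", "k_m1", "k3", "k_m3", "k_conv", "k_deg_C", "k_deg_A")])
}

# Canonical parameter-vector names used by calibration/inference/SA.
THETA_NAMES <- c("k1", "k_m1", "k3", "k_m3", "k_conv", "k_deg_C", "k_deg_A",
                 "De0")

# Internal: theta (length-8 named or unnamed vector in canonical order)
# -> list(kinetics, transport)
theta_to_parameters <- function(theta, alpha_e = 1) {
  theta <- as.numeric(theta)
  if (length(theta) != 8L)
    stop("theta must have 8 elements (7 rates + De0)", call. = FALSE)
  list(
    kinetics = kinetic_parameters(theta[1], theta[2], theta[3], theta[4],
                                  theta[5], theta[6], theta[7]),
    transport = transport_parameters(De0 = theta[8], alpha_e = alpha_e)
  )
}
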