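#' Species concentration fields at one time
#'
#' A `state_field` holds the six dimensionless concentration fields of
#' the model on the spatial grid: free enzyme `E` (normalised by the
#' bath concentration), crystalline `C` and amorphous `A` polymer,
#' enzyme-crystalline `EC` and enzyme-amorphous `EA` complexes, and
#' soluble degradation product `P` (all polymer species normalised by
#' the initial total polymer volume).
#'
#' @param E,C,A,EC,EA,P numeric vectors of equal length (one value per
#'   grid node).
#' @return An object of class `state_field`.
#' @export
state_field <- function(E, C, A, EC, EA, P) {
  n <- length(E)
  fields <- list(E = E, C = C, A = A, EC = EC, EA = EA, P = P)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.numeric(v) || length(v) != n)
      stop("field '", nm, "' must be numeric of length ", n, call. = FALSE)
    if (!all(is.finite(v)))
      stop("field '", nm, "' contains non-finite values", call. = FALSE)
  }
  structure(fields, class = "state_field")
}

#' Initial state of an undegraded film
#'
#' Implements the initial and surface conditions: no enzyme or product
#' inside the film, polymer split `C0`/`A0`, and the surface node held
#' at the bath enzyme concentration (`E = 1` at `x = 0` for `t > 0`;
#' the jump from the enzyme-free initial film is absorbed by the stiff
#' integrator's first step).
#'
#' @param geometry a [film_geometry()].
#' @param initial an [initial_composition()].
#' @return A `state_field`.
#' @export
initial_state <- function(geometry, initial) {
  N <- geometry$N
  E <- numeric(N)
  E[1] <- 1
  state_field(E = E,
              C = rep(initial$C0, N), A = rep(initial$A0, N),
              EC = numeric(N), EA = numeric(N), P = numeric(N))
}

# pack/unpack between a state_field and the 6N solver vector
# (block order E | C | A | EC | EA | P)
pack_state <- function(state) {
  c(state$E, state$C, state$A, state$EC, state$EA, state$P)
}

unpack_state <- function(y, N) {
  y <- unname(y)
  structure(list(E = y[seq_len(N)],
                 C = y[N + seq_len(N)],
                 A = y[2 * N + seq_len(N)],
                 EC = y[3 * N + seq_len(N)],
                 EA = y[4 * N + seq_len(N)],
                 P = y[5 * N + seq_len(N)]),
            class = "state_field")
}

#' Local porosity
#'
#' Porosity is the volume fraction not occupied by solid polymer,
#' `phi = 1 - (C + A)`.  Bound complexes and product do not count as
#' solid.  Values are clipped to `[0, 1]` before use in the
#' diffusivity; the state itself is never clipped.
#'
#' @param state a `state_field`.
#' @param clip clip to the physical range `[0, 1]` (default `TRUE`).
#' @return Numeric vector of per-node porosities.
#' @export
#' @examples
#' s <- state_field(E = 0, C = 0.302, A = 0.698, EC = 0, EA = 0, P = 0)
#' porosity(s)  # 0: dense undegraded polymer
porosity <- function(state, clip = TRUE) {
  phi <- 1 - (state$C + state$A)
  if (clip) phi <- pmin(pmax(phi, 0), 1)
  phi
}

#' Porosity-dependent effective enzyme diffusivity
#'
#' `De(phi) = De0 * (1 + alpha_e * phi)`: equal to the baseline `De0`
#' in the dense polymer and increasing linearly as degradation opens
#' pores.
#'
#' @param phi porosity vector in `[0, 1]`.
#' @param transport a [transport_parameters()].
#' @return Numeric vector of diffusivities (mm^2/h).
#' @export
effective_diffusivity <- function(phi, transport) {
  transport$De0 * (1 + transport$alpha_e * phi)
}

#' Mass-action reaction rates
#'
#' Evaluates the reaction part of the model at every node: reversible
#' binding of enzyme to both polymer phases, amorphisation of the bound
#' crystalline phase, and catalytic enzymolysis of both complexes.
#' Diffusion is excluded (see [assemble_rhs()]).
#'
#' The scheme conserves polymer pointwise
#' (`d(C+A+EC+EA+P)/dt = 0`) and, in its reaction part, enzyme
#' (`d(E+EC+EA)/dt = 0`): enzyme is released intact on amorphisation
#' and on product formation.
#'
#' @param state a `state_field`.
#' @param kinetics a [kinetic_parameters()].
#' @return A list of six per-node rate vectors `E`, `C`, `A`, `EC`,
#'   `EA`, `P` (1/h).
#' @export
reaction_rates <- function(state, kinetics) {
  k <- kinetics
  bC <- k$k1 * state$E * state$C
  bA <- k$k3 * state$E * state$A
  rC <- k$k_m1 * state$EC
  rA <- k$k_m3 * state$EA
  cv <- k$k_conv * state$EC
  gC <- k$k_deg_C * state$EC
  gA <- k$k_deg_A * state$EA
  list(E  = -bC + rC - bA + rA + cv + gC + gA,
       C  = -bC + rC,
       A  = -bA + rA + cv,
       EC = bC - rC - cv - gC,
       EA = bA - rA - gA,
       P  = gC + gA)
}

#' Full method-of-lines right-hand side
#'
#' Adds the discrete enzyme-diffusion operator to [reaction_rates()]:
#' a second-order finite difference with arithmetic-mean interface
#' diffusivities `D_{i+1/2} = (De(phi_i) + De(phi_{i+1})) / 2`.  The
#' surface node is held at the bath concentration (`dE/dt = 0`); the
#' symmetry node carries the zero-flux half-control-volume correction.
#' Only free enzyme diffuses.
#'
#' This is the reference R implementation; [simulate_degradation()]
#' integrates an equivalent compiled version by default.
#'
#' @param state a `state_field`.
#' @param kinetics a [kinetic_parameters()].
#' @param transport a [transport_parameters()].
#' @param geometry a [film_geometry()].
#' @return Time derivative of the packed 6N state vector.
#' @export
assemble_rhs <- function(state, kinetics, transport, geometry) {
  if (!all(vapply(state, function(v) all(is.finite(v)), logical(1))))
    stop("non-finite state passed to assemble_rhs", call. = FALSE)
  N <- geometry$N
  r <- reaction_rates(state, kinetics)
  De <- effective_diffusivity(porosity(state), transport)
  E <- state$E
  dE <- r$E
  dx2 <- geometry$dx^2
  if (N > 2) {
    i <- 2:(N - 1)
    Dp <- (De[i] + De[i + 1]) / 2
    Dm <- (De[i - 1] + De[i]) / 2
    dE[i] <- dE[i] + (Dp * (E[i + 1] - E[i]) - Dm * (E[i] - E[i - 1])) / dx2
  }
  Dm_last <- (De[N - 1] + De[N]) / 2
  dE[N] <- dE[N] + 2 * Dm_last * (E[N - 1] - E[N]) / dx2
  dE[1] <- 0
  c(dE, r$C, r$A, r$EC, r$EA, r$P)
}

# R-level func for deSolve (fallback / cross-check path)
rhs_desolve_r <- function(t, y, parms) {
  state <- unpack_state(y, parms$geometry$N)
  list(assemble_rhs(state, parms$kinetics, parms$transport, parms$geometry))
}

#' Integrate the degradation model
#'
#' Solves the semi-discretised reaction-diffusion system by the method
#' of lines with a stiff implicit multistep (BDF) integrator at the
#' configured tolerances.  The model for `L = 0.25` mm with 25 nodes is
#' a 150-equation stiff ODE system.
#'
#' @param kinetics a [kinetic_parameters()].
#' @param transport a [transport_parameters()].
#' @param geometry a [film_geometry()].
#' @param initial an [initial_composition()].
#' @param settings a [solver_settings()].
#' @param compiled integrate the compiled right-hand side (default);
#'   set `FALSE` to use the reference R implementation
#'   ([assemble_rhs()]), e.g. for debugging.
#' @return An object of class `deg_trajectory`: list with `times`,
#'   `states` (one `state_field` per output time), the `geometry`, and
#'   `provenance` (all inputs).
#' @export
#' @examples
#' cs <- case_study_parameters()
#' traj <- simulate_degradation(cs$kinetics, cs$transport, cs$geometry,
#'                              cs$initial, solver_settings(t_end = 8))
#' weight_loss_percent(traj$states[[length(traj$states)]], traj$geometry)
simulate_degradation <- function(kinetics, transport, geometry, initial,
                                 settings = solver_settings(),
                                 compiled = TRUE) {
  stopifnot(inherits(kinetics, "kinetic_parameters"),
            inherits(transport, "transport_parameters"),
            inherits(geometry, "film_geometry"),
            inherits(initial, "initial_composition"))
  y0 <- pack_state(initial_state(geometry, initial))
  times <- settings$output_times
  t0_included <- length(times) == 0L || times[1] > 0
  solve_times <- if (t0_included) c(0, times) else times

  if (compiled) {
    parms <- c(kinetics$k1, kinetics$k_m1, kinetics$k3, kinetics$k_m3,
               kinetics$k_conv, kinetics$k_deg_C, kinetics$k_deg_A,
               transport$De0, transport$alpha_e,
               as.numeric(geometry$N), geometry$dx)
    out <- deSolve::ode(y = y0, times = solve_times, func = "filmdeg_derivs",
                        parms = parms, dllname = "filmdeg",
                        initfunc = "filmdeg_initmod",
                        method = settings$method,
                        rtol = settings$rtol, atol = settings$atol,
                        hmax = settings$max_step)
  } else {
    parms <- list(kinetics = kinetics, transport = transport,
                  geometry = geometry)
    out <- deSolve::ode(y = y0, times = solve_times, func = rhs_desolve_r,
                        parms = parms, method = settings$method,
                        rtol = settings$rtol, atol = settings$atol,
                        hmax = settings$max_step)
  }

  if (nrow(out) < length(solve_times)) {
    stop("integration failed at t = ", max(out[, 1]), " h (of ",
         settings$t_end, " h requested)", call. = FALSE)
  }
  if (t0_included) out <- out[-1, , drop = FALSE]

  states <- lapply(seq_len(nrow(out)), function(i)
    unpack_state(out[i, -1], geometry$N))
  structure(list(times = times, states = states, geometry = geometry,
                 provenance = list(kinetics = kinetics, transport = transport,
                                   geometry = geometry, initial = initial,
                                   settings = settings,
                                   compiled = compiled)),
            class = "deg_trajectory")
}

#' @export
print.deg_trajectory <- function(x, ...) {
  cat("Degradation trajectory:", length(x$times), "output times over [",
      min(x$times), ",", max(x$times), "] h;",
      x$geometry$N, "nodes, L =", x$geometry$L, "mm\n")
  invisible(x)
}

#' Tidy data frame of a trajectory
#'
#' @param x a `deg_trajectory`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return Long-format data frame with columns `time_h`, `x_mm` and the
#'   six species.
#' @export
as.data.frame.deg_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  N <- x$geometry$N
  do.call(rbind, lapply(seq_along(x$times), function(i) {
    s <- x$states[[i]]
    data.frame(time_h = x$times[i], x_mm = x$geometry$x,
               E = s$E, C = s$C, A = s$A, EC = s$EC, EA = s$EA, P = s$P)
  }))
}
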