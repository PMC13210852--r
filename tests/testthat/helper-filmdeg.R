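# Shared fixtures and independent oracles for the test suite.

# Calibrated case-study parameter vector in canonical order (matches case_study_parameters()).
calibrated_theta <- function() {
  c(k1 = 0.65, k_m1 = 0.47, k3 = 0.30, k_m3 = 0.03, k_conv = 0.58,
    k_deg_C = 0.0012, k_deg_A = 0.005, De0 = 1.66)
}

# A random physically plausible state on an N-node grid (seeded by caller).
random_state <- function(N) {
  C <- runif(N, 0, 0.3)
  A <- runif(N, 0, 0.5)
  EC <- runif(N, 0, 0.1)
  EA <- runif(N, 0, 0.1)
  P <- pmax(1 - C - A - EC - EA - runif(N, 0, 0.2), 0)
  state_field(E = runif(N), C = C, A = A, EC = EC, EA = EA, P = P)
}

# Independent explicit-Euler method-of-lines integrator, with the
# right-hand side re-derived directly from the governing equations
# (not shared with the package implementation).  Fine time step, same
# spatial grid; used as a time-integration oracle on small instances.
euler_oracle <- function(theta, L, N, C0, t_out, dt, alpha_e = 1) {
  dx <- L / (N - 1)
  E <- numeric(N); E[1] <- 1
  C <- rep(C0, N); A <- rep(1 - C0, N)
  EC <- EA <- P <- numeric(N)
  k1 <- theta[["k1"]]; km1 <- theta[["k_m1"]]; k3 <- theta[["k3"]]
  km3 <- theta[["k_m3"]]; kc <- theta[["k_conv"]]
  kdC <- theta[["k_deg_C"]]; kdA <- theta[["k_deg_A"]]
  De0 <- theta[["De0"]]
  t <- 0
  out <- vector("list", length(t_out))
  next_out <- 1L
  n_steps <- round(max(t_out) / dt)
  for (step in seq_len(n_steps + 1L)) {
    while (next_out <= length(t_out) && t >= t_out[next_out] - dt / 2) {
      out[[next_out]] <- list(E = E, C = C, A = A, EC = EC, EA = EA, P = P)
      next_out <- next_out + 1L
    }
    if (next_out > length(t_out)) break
    phi <- pmin(pmax(1 - C - A, 0), 1)
    De <- De0 * (1 + alpha_e * phi)
    # interface fluxes F_{i+1/2} = D_{i+1/2} (E_{i+1} - E_i) / dx
    Fi <- (De[-N] + De[-1]) / 2 * (E[-1] - E[-N]) / dx
    diff_term <- numeric(N)
    if (N > 2) diff_term[2:(N - 1)] <- (Fi[-1] - Fi[-(N - 1)]) / dx
    diff_term[N] <- -2 * Fi[N - 1] / dx
    dE <- diff_term - k1 * E * C + km1 * EC - k3 * E * A + km3 * EA +
      kc * EC + kdC * EC + kdA * EA
    dC <- -k1 * E * C + km1 * EC
    dA <- -k3 * E * A + km3 * EA + kc * EC
    dEC <- k1 * E * C - km1 * EC - kc * EC - kdC * EC
    dEA <- k3 * E * A - km3 * EA - kdA * EA
    dP <- kdC * EC + kdA * EA
    dE[1] <- 0
    E <- E + dt * dE; C <- C + dt * dC; A <- A + dt * dA
    EC <- EC + dt * dEC; EA <- EA + dt * dEA; P <- P + dt * dP
    t <- t + dt
  }
  out
}

# Well-mixed (E identically 1) linear-system solution by matrix
# exponential: independent closed-form oracle for the fast-diffusion
# limit.  Returns the (C, A, EC, EA, P) vector at time t.
well_mixed_expm <- function(theta, C0, t) {
  k1 <- theta[["k1"]]; km1 <- theta[["k_m1"]]; k3 <- theta[["k3"]]
  km3 <- theta[["k_m3"]]; kc <- theta[["k_conv"]]
  kdC <- theta[["k_deg_C"]]; kdA <- theta[["k_deg_A"]]
  M <- rbind(
    c(-k1, 0, km1, 0, 0),
    c(0, -k3, kc, km3, 0),
    c(k1, 0, -(km1 + kc + kdC), 0, 0),
    c(0, k3, 0, -(km3 + kdA), 0),
    c(0, 0, kdC, kdA, 0))
  y0 <- c(C0, 1 - C0, 0, 0, 0)
  as.numeric(Matrix::expm(M * t) %*% y0)
}

# Small synthetic dataset + matching geometry for calibration and
# inference tests (coarse grid keeps many-simulation studies fast).
quick_setup <- function(seed = 1L, N = 13L, sd = 2,
                        times = c(0, 4, 8, 16, 20, 24, 40, 64)) {
  th <- calibrated_theta()
  kin <- kinetic_parameters(th[1], th[2], th[3], th[4], th[5], th[6], th[7])
  tr <- transport_parameters(De0 = th[["De0"]])
  geom <- film_geometry(0.25, N = N)
  init <- initial_composition(0.302)
  spec <- synthetic_spec(kin, tr, geom, init, times_wl = times,
                         times_chi = times, sd_wl = sd, sd_chi = sd,
                         seed = seed)
  list(theta = th, kinetics = kin, transport = tr, geometry = geom,
       initial = init, spec = spec)
}
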