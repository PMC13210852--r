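test_that("porosity is the non-polymer volume fraction, clipped for transport", {
  N <- 5
  dense <- state_field(E = numeric(N), C = rep(0.302, N), A = rep(0.698, N),
                       EC = numeric(N), EA = numeric(N), P = numeric(N))
  expect_equal(porosity(dense), rep(0, N))
  empty <- state_field(E = rep(1, N), C = numeric(N), A = numeric(N),
                       EC = numeric(N), EA = numeric(N), P = rep(1, N))
  expect_equal(porosity(empty), rep(1, N))
  half <- state_field(E = numeric(N), C = rep(0.1, N), A = rep(0.4, N),
                      EC = numeric(N), EA = numeric(N), P = rep(0.5, N))
  expect_equal(porosity(half), rep(0.5, N))
  # solver slack can push C + A slightly above 1; transport sees [0, 1]
  over <- state_field(E = numeric(1), C = 0.6, A = 0.5, EC = 0, EA = 0, P = 0)
  expect_equal(porosity(over), 0)
  expect_lt(porosity(over, clip = FALSE), 0)
})

test_that("effective diffusivity is linear in porosity and equals De0 when dense", {
  tr <- transport_parameters(De0 = 1.66, alpha_e = 1)
  expect_equal(effective_diffusivity(0, tr), 1.66)
  expect_equal(effective_diffusivity(1, tr), 2 * 1.66)
  expect_equal(effective_diffusivity(0.5, tr), 2.49)
  phi <- seq(0, 1, by = 0.1)
  expect_true(all(diff(effective_diffusivity(phi, tr)) >= 0))
})

test_that("reaction rates conserve polymer and enzyme pointwise", {
  set.seed(42)
  th <- calibrated_theta()
  kin <- kinetic_parameters(th[1], th[2], th[3], th[4], th[5], th[6], th[7])
  for (rep in 1:5) {
    s <- random_state(11)
    r <- reaction_rates(s, kin)
    expect_equal(r$C + r$A + r$EC + r$EA + r$P, rep(0, 11),
                 tolerance = 1e-14)
    expect_equal(r$E + r$EC + r$EA, rep(0, 11), tolerance = 1e-14)
  }
  # no enzyme (free or bound) means no reaction at all
  s0 <- state_field(E = numeric(4), C = rep(0.3, 4), A = rep(0.7, 4),
                    EC = numeric(4), EA = numeric(4), P = numeric(4))
  r0 <- reaction_rates(s0, kin)
  expect_true(all(vapply(r0, function(v) all(v == 0), logical(1))))
})

test_that("full RHS differs from reaction rates only in the enzyme block", {
  set.seed(7)
  th <- calibrated_theta()
  kin <- kinetic_parameters(th[1], th[2], th[3], th[4], th[5], th[6], th[7])
  tr <- transport_parameters(De0 = th[["De0"]])
  geom <- film_geometry(0.25, N = 9)
  s <- random_state(9)
  full <- assemble_rhs(s, kin, tr, geom)
  r <- reaction_rates(s, kin)
  expect_equal(full[10:54], c(r$C, r$A, r$EC, r$EA, r$P))
  # uniform E and phi: zero diffusive contribution at interior nodes
  su <- state_field(E = rep(0.4, 9), C = rep(0.2, 9), A = rep(0.3, 9),
                    EC = rep(0.1, 9), EA = rep(0.1, 9), P = rep(0.3, 9))
  fu <- assemble_rhs(su, kin, tr, geom)
  ru <- reaction_rates(su, kin)
  expect_equal(fu[2:9], ru$E[2:9])
  # surface node is clamped
  expect_identical(fu[1], 0)
  # Fickian inflow: enzyme spike at the surface flows into node 2
  sp <- state_field(E = c(1, numeric(8)), C = rep(0.3, 9), A = rep(0.7, 9),
                    EC = numeric(9), EA = numeric(9), P = numeric(9))
  fp <- assemble_rhs(sp, kin, tr, geom)
  expect_gt(fp[2], 0)
  expect_error(assemble_rhs(
    structure(list(E = NaN, C = 1, A = 1, EC = 0, EA = 0, P = 0),
              class = "state_field"), kin, tr, geom),
    "non-finite")
})

test_that("compiled RHS agrees with the R reference implementation", {
  set.seed(3)
  th <- calibrated_theta()
  kin <- kinetic_parameters(th[1], th[2], th[3], th[4], th[5], th[6], th[7])
  tr <- transport_parameters(De0 = th[["De0"]], alpha_e = 1.7)
  geom <- film_geometry(0.3, N = 12)
  init <- initial_composition(0.302)
  settings <- solver_settings(t_end = 24, output_times = c(6, 12, 24))
  tc <- simulate_degradation(kin, tr, geom, init, settings, compiled = TRUE)
  tr_ <- simulate_degradation(kin, tr, geom, init, settings, compiled = FALSE)
  for (i in seq_along(tc$states))
    expect_equal(unclass(tc$states[[i]]), unclass(tr_$states[[i]]),
                 tolerance = 1e-6)
})

test_that("inert film: with all rate constants zero, enzyme relaxes to 1", {
  kin <- kinetic_parameters(0, 0, 0, 0, 0, 0, 0)
  tr <- transport_parameters(De0 = 1.66)
  geom <- film_geometry(0.25, N = 15)
  init <- initial_composition(0.302)
  traj <- simulate_degradation(kin, tr, geom, init,
                               solver_settings(t_end = 5,
                                               output_times = c(1, 5)))
  final <- traj$states[[2]]
  expect_equal(final$E, rep(1, 15), tolerance = 1e-4)
  expect_equal(final$C, rep(0.302, 15), tolerance = 1e-8)
  expect_equal(final$A, rep(0.698, 15), tolerance = 1e-8)
  expect_equal(final$P, rep(0, 15), tolerance = 1e-8)
})

test_that("case-study trajectory keeps state invariants at every output time", {
  cs <- case_study_parameters()
  traj <- simulate_degradation(cs$kinetics, cs$transport, cs$geometry,
                               cs$initial, cs$solver)
  atol <- cs$solver$atol
  for (s in traj$states) {
    total <- s$C + s$A + s$EC + s$EA + s$P
    expect_lt(max(abs(total - 1)), 10 * atol)
    # E may transiently exceed the bath value by a whisker where
    # complexes release enzyme faster than diffusion relaxes it
    expect_true(all(s$E <= 1 + 1e-4))
    expect_true(all(vapply(s, function(v) all(v >= -10 * atol), logical(1))))
  }
  expect_true(all(diff(traj$times) > 0))
  # t = 0 state matches the initial conditions
  s0 <- traj$states[[1]]
  expect_equal(s0$C, rep(0.302, 25))
  expect_equal(s0$E[-1], rep(0, 24))
})

test_that("geometry bookkeeping: grid spacing and equation count", {
  g <- film_geometry(0.25, N = 25)
  expect_equal(g$dx * (g$N - 1), g$L)
  expect_equal(g$dx, 0.25 / 24)
  expect_equal(length(pack_state <- filmdeg:::pack_state(
    initial_state(g, initial_composition(0.302)))), 150)
  expect_equal(default_grid_nodes(0.25), 25)
  # thick films keep dx at or below the reference spacing
  g4 <- film_geometry(4)
  expect_lte(g4$dx, 0.25 / 24 + 1e-12)
})

test_that("constructors reject non-physical inputs", {
  expect_error(kinetic_parameters(-1, 0, 0, 0, 0, 0, 0), "non-negative")
  expect_error(transport_parameters(De0 = 0), "positive")
  expect_error(initial_composition(0.4, 0.4), "equal 1")
  expect_error(film_geometry(0.25, N = 2), ">= 3")
  expect_error(solver_settings(t_end = 10, output_times = c(0, 20)),
               "output_times")
})
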