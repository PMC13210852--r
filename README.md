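# filmdeg

Reaction–diffusion modelling of enzymatic degradation of thin
semicrystalline polymer films.

Bioresorbable polyester films (the motivating system is
poly(ε-caprolactone) degraded in vitro by *Candida antarctica* lipase)
lose mass and change microstructure at the same time: the enzyme attacks
amorphous and crystalline material at different rates and disrupts
crystalline order before cleaving it. Models that treat the polymer as one
homogeneous substrate cannot capture that, so `filmdeg` implements a
one-dimensional two-state reaction–diffusion model in which crystalline
(C) and amorphous (A) polymer are distinct reactive species:

```
E + C  <=[k1 / k-1]=>  EC  --k_conv-->  E + A      (amorphisation)
E + A  <=[k3 / k-3]=>  EA
EC --k_deg_C--> E + P,    EA --k_deg_A--> E + P    (enzymolysis)
```

Free enzyme E diffuses through the film with a porosity-dependent
effective diffusivity `De(φ) = De0 (1 + αe φ)`, `φ = 1 − (C + A)`; the
film is solved on the symmetric half-thickness domain `[0, L]` with the
surface held at the bath concentration. The package provides:

* stiff method-of-lines integration of the six-species system
  (compiled right-hand side, BDF integrator via `deSolve`);
* the measurable observables — percent weight loss, bulk crystallinity
  `χc = ∫C dx / ∫(C+A) dx`, local crystallinity profiles — and
  Damköhler-number regime metrics;
* joint weighted least-squares calibration of the eight parameters
  `(k1, k-1, k3, k-3, k_conv, k_deg_C, k_deg_A, De0)` against
  weight-loss + crystallinity datasets with per-point standard
  deviations;
* Bayesian uncertainty quantification by differential-evolution MCMC
  with snooker updates (DE-MCz), credible intervals and posterior
  predictive bands;
* time-dependent first- and total-order Sobol sensitivity indices of
  the mass-loss output (Saltelli/Jansen estimators);
* predictive film-thickness sweeps with regime classification
  (reaction-limited vs transport-influenced);
* a synthetic-dataset generator mirroring the reference experiment, and
  a command-line interface (`inst/cli/filmdeg.R`) with subcommands
  `simulate`, `synth`, `fit`, `sample`, `sobol`, `thickness`.

## Worked example

```r
library(filmdeg)

cs <- case_study_parameters()   # calibrated PCL–lipase parameters,
                                # L = 0.25 mm (0.5 mm film), C0 = 0.302
traj <- simulate_degradation(cs$kinetics, cs$transport, cs$geometry,
                             cs$initial, cs$solver)
obs <- observable_series(traj)
obs[obs$time_h %in% c(0, 8, 24, 72), ]
#>    time_h weight_loss_pct crystallinity_pct
#> 1       0           0.000            30.200
#> 9       8           1.961            11.455
#> 25     24           8.557             0.430
#> 73     72          26.455             0.000
```

The film loses about a quarter of its mass over 72 h while the
crystalline fraction of the remaining polymer collapses from 30.2% to
essentially zero — the signature of an enzyme that amorphises crystalline
material rather than sparing it.

```r
damkohler(cs$kinetics, cs$transport, L = 4)$tau_diff   # 9.639 h
classify_regime(damkohler(cs$kinetics, cs$transport, 4))
#> "transport-influenced"
classify_regime(damkohler(cs$kinetics, cs$transport, 0.1))
#> "reaction-limited"
```

A 0.2 mm film equilibrates with enzyme in ~0.006 h and degrades at the
reaction-limited rate; an 8 mm film needs ~9.7 h of diffusion and
degrades measurably more slowly, retaining crystallinity in its interior
at early times (`run_thickness_sweep()`, `spatial_profiles()`).

To calibrate against data, supply a CSV with columns
`observable,time_h,value_pct,sd_pct` (observables `weight_loss` and
`crystallinity`); see `generate_synthetic()` /
`inst/extdata/synthetic_case_study_dataset.csv` for the format, and
`fit_parameters()` / `sample_posterior()` for estimation.

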