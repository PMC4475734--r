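# stspdyn

Short-term synaptic plasticity (STSP) of GABAergic inputs onto striatal
projection neurons (SPNs), for synaptic physiologists and modellers.
Trains of inhibitory postsynaptic currents (IPSCs) evoked at 20 Hz fall
into three classes — depressing (STD), facilitating (STF) and biphasic
(STB, facilitation then depression) — and these classes respond
differently to dopamine depletion (the 6-OHDA model of Parkinsonism).
`stspdyn` implements the full quantitative toolchain for this problem:

* **Presynaptic release model.** Two state variables — readily
  releasable pool occupancy *x* and release probability *p* — driven by
  alpha-shaped pulse forcing φ:

  dx/dt = x(x∞ − x)/τ_Rec − p·x·Σφ(t − t_k)
  dp/dt = p(p∞ − p)/τ_Dep + (1 − p)·q(h)·Σφ(t − t_k)

  Released transmitter is x(t)·p(t); per-pulse release is sampled at
  each spike arrival and normalized by x(0)p(0). Fixed-step RK4
  integration, bounded Levenberg–Marquardt refitting
  (`simulate_release()`, `fit_model_to_curve()`).
* **Descriptive fits.** Normalized trains are summarised by a product of
  recovery and depletion exponentials
  (A − e^(−x/τ_Rec))(e^(−x/τ_Dep) + B) + C (`fit_eq1()`), and
  intensity–amplitude data by the sigmoid A_max/(1 + e^(−k(I − I_h)))
  with recruitment index RI = k/I_h (`fit_eq2()`,
  `recruitment_index()`); RI ≥ 1 marks depressing inputs, RI < 1
  facilitating and biphasic ones.
* **Quantal analysis.** Per-pulse variance–mean points are fitted by the
  binomial parabola σ² = Qμ − μ²/N, yielding quantal size Q, release
  site count N and the weighted release probability P_w = μ₁/(NQ)
  (`variance_mean()`, `weighted_release_probability()`,
  `failure_rate()`).
* **Classification and synthesis.** Curve-shape classification into
  STD/STF/STB (`classify_stsp()`), and a seeded binomial quantal
  generator with failures, gamma quantal variability and baseline noise
  (`gen_quantal_sweeps()`, `schedule_from_model()`) that lets every
  stage be validated end-to-end.

Reference parameter sets for all six condition × class regimes (control
and 6-OHDA; STD/STF/STB) ship with the package: `stsp_model_params()`,
`stsp_eq1_params()`, `stsp_ia_params()`.

## Worked example

Simulate the control biphasic regime, classify it, refit its initial
release probability from a perturbed start, and run quantal analysis on
synthetic sweeps generated from the same regime:

```r
library(stspdyn)

params <- stsp_model_params("control", "STB")
traj <- simulate_release(params)
traj
#> <release_trajectory> 10 pulses, dt = 0.05 ms, readout = onset
#>   normalized per-pulse release:
#>   1 1.7429 1.5782 1.3457 1.1855 1.0861 1.0249 0.9868 0.9627 0.9473

curve <- as_normalized_curve(traj)
classify_stsp(curve)
#> <stsp_label> STB (peak at pulse 2, v_peak = 1.74, v_last = 0.947)

fit_model_to_curve(curve, update_p0(params, 0.5), "p0")
#> <release_model_fit> (converged)
#>   parameter estimate std_error
#> 1        p0     0.29         0
#>   residual norm: 0 after 7 iterations

sched <- schedule_from_model(params)
qp <- quantal_params(n_sites = 10, quantal_size_pa = 15,
                     p_schedule = sched, baseline_sd_pa = 2,
                     cv_quantal = 0.3)
sweeps <- gen_quantal_sweeps(qp, n_sweeps = 200, seed = 1)
variance_mean(sweeps)
#> <variance_mean_result>
#>   quantal size Q = 16.9 pA, release sites N = 9.62, Pw = 0.261
failure_rate(sweeps, 1)
#> [1] 0.035
```

Reading the numbers: the release trace rises to 1.74× the first pulse at
pulse 2 and then sags below 1 — the biphasic signature — and the
classifier reports exactly that shape. The refit recovers the generating
p(0) = 0.29 from a perturbed start of 0.5 with zero residual. On the
synthetic sweeps, the variance–mean parabola returns the generating
quantal parameters (N = 10 sites, Q = 15 pA) to within sampling error
and a first-pulse weighted release probability near the generating 0.29;
3.5 % of first pulses are failures, as expected for a low-p₀ input.

The full pipeline (synthesis → normalization → both fits → variance–mean
→ classification, with a JSON manifest) runs from one config:

```r
cfg <- yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                                   package = "stspdyn"))
cfg$out_dir <- tempfile("stspdyn-demo")
manifest <- run_pipeline(cfg)
```

A thin command-line wrapper with subcommands `simulate`, `synth`,
`fit-train`, `fit-ia`, `vmean`, `classify` and `pipeline` is installed
at `system.file("cli", "stspdyn.R", package = "stspdyn")`.

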