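---
title: "Modelling short-term plasticity of striatal GABAergic inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling short-term plasticity of striatal GABAergic inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stspdyn)
```

## The scientific problem

Inhibitory GABAergic inputs onto striatal projection neurons (SPNs) are
heterogeneous. When driven with short trains of field stimuli (10 pulses at
20 Hz, one train every 10 s), their inhibitory postsynaptic currents
(IPSCs) display three qualitatively different classes of short-term
synaptic plasticity (STSP): depression (STD, amplitudes fall along the
train), facilitation (STF, amplitudes grow), and biphasic dynamics (STB,
initial facilitation followed by depression). These classes behave
differently again after dopamine depletion (the 6-OHDA rodent model of
Parkinsonism): depressing inputs barely change, while facilitating and
biphasic inputs lose failures and increase their release.

`stspdyn` packages the quantitative machinery needed to study this:
a mechanistic presynaptic release model, two descriptive curve fits,
variance–mean quantal analysis, a taxonomy of train dynamics, and a
seeded synthetic-data generator that closes the loop for validation.

## The release model

Two state variables describe a presynaptic terminal: the occupancy of the
readily releasable pool $x(t)$ and the release probability $p(t)$:

$$
\frac{dx}{dt} = \frac{x(x_\infty - x)}{\tau_{Rec}} - p\,x \sum_k \phi(t-t_k),
\qquad
\frac{dp}{dt} = \frac{p(p_\infty - p)}{\tau_{Dep}} + (1-p)\,q(h) \sum_k \phi(t-t_k),
$$

with each stimulus at time $t_k$ entering through the alpha-shaped forcing
$\phi(t) = A\,(t/\tau_\phi)\,e^{1-t/\tau_\phi}$ (defaults
$A = \tau_\phi = 1$). A pulse consumes pool occupancy in proportion to
$p\,x$ and increments the release probability with gain $q(h)$, saturating
at $p = 1$ through the $(1-p)$ factor. Released transmitter corresponds to
the product $x(t)\,p(t)$.

Parameters, units and defaults:

| parameter | meaning | units | typical values |
|---|---|---|---|
| `tau_rec_ms` | pool recovery time constant | ms | 9.5–33 |
| `tau_dep_ms` | probability relaxation time constant | ms | 5–1000 |
| `p0` | initial release probability | – | 0.2–0.54 |
| `x0` | initial pool occupancy | – | 0.7–4 |
| `h` | facilitation parameter | – | 0.05–0.3 |
| `q_bar` | maximum probability increment | – | 1 |

The six bundled regimes (control and 6-OHDA, each for STD/STF/STB) are
available through `stsp_model_params()`. Intuition: STD has fast
depletion relative to recovery and a high `p0`; STF has slow probability
relaxation, fast pool recovery and a low `p0`; STB combines a strong
facilitation gain with slow probability decay, so `p` climbs while `x`
drains — facilitation first, depression later.

### Design choices in the equations

Four aspects of the model were genuinely open and are resolved as
explicit, documented choices:

* **Relaxation form.** The recovery terms are implemented state-multiplied
  ("logistic", `x(x_\infty - x)/\tau_{Rec}`) by default, with
  `relaxation = "linear"` switching to `(x_\infty - x)/\tau_{Rec}`. The
  logistic form is the default because it is the form the system of
  equations writes; the linear form is the more common convention in
  depletion models, so both are first-class.
* **Facilitation gain.** `q_form = "constant"` (default) reads the gain
  as $q(h) = \bar q\,h$ with $\bar q = 1$, so tabulated `h` values act
  directly as gains; `q_form = "exponential"` implements
  $\bar q\,h\,e^{1-h/\tau_{Dep}}$. Round trips are convention-invariant
  as long as generation and fitting share one reading.
* **Steady states.** $x_\infty$ and $p_\infty$ default to the initial
  conditions and stay tied to them: at 0.1 Hz train repetition every
  time constant has long relaxed between trains, so the resting state
  *is* the steady state. Ties are preserved through fitting (freeing
  `p0` moves `p_inf` with it) and can be broken by passing explicit
  values.
* **Per-pulse readout.** The per-pulse "maximal release" is the product
  $x\,p$ sampled at pulse onset — the amplitude the arriving spike sees,
  and the local maximum of the release trace attached to that pulse.
  Under depression this coincides (to within the ~1 ms forcing rise
  time) with the maximum of $x\,p$ over the interstimulus window; under
  facilitation the product keeps rising *between* pulses, so a windowed
  maximum would effectively report the state just before the *next*
  pulse and the first pulse would no longer normalize to 1. Onset
  sampling keeps `normalized_release[1] = 1` exactly and reproduces the
  depressing/facilitating/biphasic shapes; `readout = "window_max"` is
  retained for comparison.

### Numerics

Integration is a fixed-step fourth-order Runge–Kutta scheme at
`dt_ms = 0.05` (step at most $\tau_\phi/10$ enforced), with the summed
forcing evaluated analytically on the full- and half-step grid. Pulses
enter only through the continuous forcing — no discrete state jumps — so
the trajectory is smooth and the integrator's classical order applies.
Halving the step changes per-pulse release by well under 0.1 % on all six
bundled regimes (tested), and the trajectory agrees with an independent
adaptive-step integration (deSolve's `lsoda` at `rtol = 1e-9`) to better
than $10^{-4}$ relative. Non-finite states abort with the offending time.

Refitting (`fit_model_to_curve()`) is bounded Levenberg–Marquardt on the
per-pulse residuals with bounds $\tau \in [0.1, 10^4]$ ms,
$p_0 \in [0,1]$, $x_0 \in (0, 10]$, $h \in [0, 10]$; it is deterministic
given its start, and noiseless single-parameter round trips recover each
parameter to $10^{-3}$ relative or better on every bundled regime.

## Descriptive fits

Two descriptive (non-mechanistic) fits summarise recordings:

**Normalized train shape.** `fit_eq1()` fits
$\mathrm{IPSC}_n/\mathrm{IPSC}_1 = (A - e^{-x/\tau_{Rec}})(e^{-x/\tau_{Dep}} + B) + C$
by Levenberg–Marquardt, weighting by $1/\mathrm{SEM}^2$ when the curve
carries dispersion. The abscissa $x$ is the time of the $n$th stimulus
from train onset in ms ($x_n = 50(n-1)$ at 20 Hz): the bundled
descriptive time constants are tens to hundreds of ms, which only makes
sense on a time abscissa. The starting offset $C$ is always rebalanced so
the initial curve passes through 1 at $x = 0$; the converged fit is
unconstrained. Without a user start, a small deterministic grid of
starting points is tried and the best fit kept — reproducible, and robust
to the strong $A$–$B$–$C$ trade-offs this functional form allows. These
descriptive time constants are deliberately housed apart from the
mechanistic `tau_rec_ms`/`tau_dep_ms` of `release_params()`; the package
never converts between the two families.

**Input–output curves.** `fit_eq2()` fits the three-parameter sigmoid
$A(I) = A_{max}/(1 + e^{-k(I - I_h)})$ to amplitude versus stimulus
intensity in threshold units (Tu). The slope factor `k` is taken as
carrying Tu$^{-1}$ so the exponent is dimensionless. The recruitment
index $RI = k/I_h$ separates classes: depressing inputs have $RI > 1$
(they recruit release sites quickly and saturate early), facilitating
and biphasic inputs $RI < 1$. RI is invariant to amplitude scaling.

## Variance–mean quantal analysis

With $N$ release sites of quantal size $Q$ and per-pulse probability
$P_n$, per-pulse moments obey $\mu_n = N P_n Q$ and
$\sigma^2_n = N P_n (1-P_n) Q^2$, hence the parabola
$\sigma^2 = Q\mu - \mu^2/N$. Because successive pulses in a train sample
different release probabilities, the per-pulse (mean, variance) points of
one condition trace this parabola. `variance_mean()` subtracts the known
baseline variance, fits the parabola through the origin by least squares,
and reports $\hat Q$, $\hat N$ and the weighted release probability
$P_w = \mu_1/(\hat N \hat Q)$, clipped to $[0,1]$ with a flag. A convex
fit (no concavity, $N \le 0$) is flagged rather than inverted. The
estimator is exact on noiseless binomial moments; on finite data its
scatter is dominated by the sampling noise of the per-pulse variances
($\mathrm{sd}(s^2) \approx \sigma^2\sqrt{2/(S-1)}$ at $S$ sweeps), which
is why the bundled protocols use hundreds of sweeps.

## Synthetic data: what it emulates, and what it does not

`gen_quantal_sweeps()` draws sweeps from the same binomial quantal model
the analysis assumes: per pulse, a $\mathrm{Binomial}(N, P_n)$ number of
sites release, quanta are gamma-distributed around $Q$ with coefficient
of variation `cv_quantal` (default 0.3, giving the realistic spread of
individual traces; the sum of $k$ quanta is drawn exactly as a gamma
with shape $k/\mathrm{cv}^2$), and Gaussian baseline noise of SD 2 pA is
added. `schedule_from_model()` links the generator to the mechanistic
model by scaling the simulated normalized release into a per-site
probability schedule (first pulse at `p0` by default), clipped at 1 with
a saturation flag — a proportionality convenience, not a mechanistic
identity. Defaults mirror the recording protocol: 10 pulses at 20 Hz,
25-sweep demo sets, 200–500 sweep analysis sets, $N = 10$, $Q = 15$ pA.

Randomness uses one root seed stretched into operation-specific
substreams, recorded in the outputs, and never perturbs the caller's RNG
state.

Because generator and estimator share the binomial assumption, passing
tests demonstrate *internal consistency* — the estimators recover what
the generator put in — not that real synapses satisfy uniform quantal
size across sites, site independence, or stationarity across sweeps.
Real recordings also contain asynchronous release, electrode drift and
amplitude run-down that the generator deliberately omits; it synthesises
per-pulse amplitudes only, never raw current waveforms.

## Classification

`classify_stsp()` labels a normalized curve from its shape, with
tolerance `delta = 0.1` (10 % of the first-pulse amplitude — small
enough to separate the bundled exemplar curves cleanly, large enough to
ignore quantal jitter at a few hundred sweeps): STD when the curve ends
below $1-\delta$ without an interior peak; STF when it ends above
$1+\delta$ and has not fallen more than $\delta$ from its peak; STB when
an interior peak above $1+\delta$ is followed by a fall of at least
$\delta$. Anything else receives the nearest label plus a low-confidence
flag rather than an error, so pipelines never stall on borderline cells.

## Problem sizes and reproducibility

The bundled validation suite exercises: noiseless descriptive-fit round
trips on all six parameter columns (recovery to $10^{-4}$ relative);
single-parameter model round trips on all six regimes ($10^{-3}$);
$P_w$ recovery within $\pm 0.05$ from 200-sweep generated sets; and
full-pipeline closure (model → schedule → 500 generated sweeps →
normalization → classification returns the generating class) for the
three control regimes. All randomness is seeded; `run_pipeline()` writes
a manifest with the package version, config hash and seed, and its
numeric outputs are byte-identical across repeated runs of one config.

## Known limitations

* The mapping from modeled release $x\,p$ to per-site probability is
  proportional by construction; saturation in strongly facilitating
  dopamine-depleted regimes is clipped and flagged.
* The variance–mean estimator assumes uniform $P$ across sites at each
  pulse; heterogeneous-probability corrections are not implemented.
* $x_\infty$/$p_\infty$ defaults encode the resting-state-equals-steady-
  state convention; regimes with overfilled pools (e.g. `x0 = 4`) are
  represented by raising the steady state with the initial condition,
  which is one of several readings of that regime.
* The descriptive and mechanistic time-constant families are homonyms
  with different values; no conversion between them is meaningful.
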