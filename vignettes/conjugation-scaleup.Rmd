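---
title: "Modelling fed-batch ADC conjugation and vessel mixing at process scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fed-batch ADC conjugation and vessel mixing at process scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjmix)
```

## The problem

In antibody-drug conjugate (ADC) manufacturing, a cytotoxic linker-drug
("payload") is added to a stirred solution of functionalized antibody.
The conjugation chemistry is fast (characteristic times of seconds to
minutes), so when a process is scaled from a reaction tube to a
multi-litre vessel, the question arises whether vessel mixing is fast
enough for the reaction to behave as if ideally mixed — or whether local
payload accumulation around the feed point distorts the reaction course.
`conjmix` answers this question *in silico* for a site-specific DAR-2
conjugation: a kinetic model is run both in an ideal-mixed fed-batch
reactor (the "0D model") and spatially resolved over a
compartment-network surrogate of the vessel, and the two predictions are
compared through the drug-to-antibody ratio (DAR).

## The kinetic model

Six antibody species and two drug pools are tracked. Antibody carries
two engineered cysteines; after functionalization a fraction $p_2$ of
molecules has both sites reactive, $p_1$ one, and $p_0$ none (the
*activation distribution*). The reactions are two consecutive
bimolecular conjugation steps and a parallel first-order payload sink
(e.g. hydrolysis of the maleimide):

$$\mathrm{A_2} + \mathrm{D} \xrightarrow{k_1} \mathrm{M_{1a}}, \qquad
  \mathrm{A_1} + \mathrm{D} \xrightarrow{k_1} \mathrm{M_{1b}}, \qquad
  \mathrm{M_{1a}} + \mathrm{D} \xrightarrow{k_2} \mathrm{M_2}, \qquad
  \mathrm{D} \xrightarrow{k_3} \varnothing$$

with mass-action rates, zero backward rates, isothermal and
constant-volume conditions. The default constants
($k_1 = 0.797$, $k_2 = 1.476\ \mathrm{mM^{-1}s^{-1}}$,
$k_3 = 0.00155\ \mathrm{s^{-1}}$) are calibrated values for the
site-specific cysteine conjugation system this model family was
developed on. The printed unit of $k_1, k_2$ is read as per-mM-per-s,
the only dimensionally consistent choice for a bimolecular rate. The
singly-activated species is assigned the same constant $k_1$ as the
doubly-activated one — the payload–cysteine chemistry is identical and
no separate constant is reported; this is a model choice, exposed
through `kinetic_params()`. Cysteines pre-inactivated on $A_1/A_0$
molecules are assumed not to consume drug.

The DAR follows as
$\mathrm{DAR}(t) = (c_{M1a} + c_{M1b} + 2 c_{M2})/c_{mAb,0} \in [0, 2]$.
At full conversion under the distribution
$(p_2, p_1, p_0) = (0.8859, 0.0860, 0.0281)$ the endpoint is
$2 p_2 + p_1 = 1.8578$, which is why measured final DARs of this
chemistry fall short of the theoretical 2. With $p_2 = 1$ the model
reduces exactly to the 3-reaction scheme; the distribution only
re-partitions the initial pool, so both variants share one
implementation.

Antibody molar mass defaults to 150 kDa (typical IgG; it also reproduces
the 1.67 % (v/v) payload volume fraction of the standard condition from
a 10 mM stock). Concentrations are in mM throughout, which conveniently
equals mol/m$^3$ in the network model.

### Fed-batch operation and integration

`feed_schedule()` describes payload addition: *batch* (all at $t=0$) or
*constant-rate* over a duration. The added volume (under 2 % of the
vessel) is neglected. `simulate_0d()` integrates with `deSolve::lsoda`
at relative tolerance $10^{-8}$ and absolute tolerance $10^{-10}$,
piecewise over the feed and post-feed phases so the source-term
discontinuity never sits inside a solver step. States are clipped to
zero only within $-10^{-8}$ mM (about 100$\times$ the absolute
tolerance — `lsoda` transiently undershoots zero by more than the
tolerance itself on long horizons); anything more negative raises an
error. Two balances are enforced by construction and checked in the
tests to $10^{-6}$ relative: antibody conservation and the drug balance
(free + inactivated + conjugated-equivalents = cumulatively fed).

## The compartment-network reactor

A full CFD treatment of the vessels is out of scope at desk scale;
instead the vessel is discretized into `levels × rings` well-mixed zones
(default 4 × 3 = 12, valid from 8 to 48) exchanging material through
constant ("frozen") volumetric flows — a classical network-of-zones
surrogate. Three vessel templates encode the flow structures of the
study vessels qualitatively:

* **GST-1** (0.3 L lab glass tank, anchor stirrer): uniform strong
  exchange everywhere.
* **GST-2** (22 L glass tank, pitched-blade stirrer): strong in-level
  exchange, axial exchange weakened 12-fold, with an additional
  bottleneck below the impeller level — the bulk above the impeller
  rotates with little axial transport.
* **SUM** (25 L single-use mixer, eccentric bottom-mounted impeller): a
  directed bottom-to-top circulation loop along one side superimposed on
  weak background exchange.

The topology is a heuristic emulation, not a CFD result. Quantitative
fidelity comes from one scalar: `calibrate_exchange()` scales all flows
by a single factor so the simulated global 95 % mixing time matches the
vessel's published value (9.4 s, 32.2 s, 17.6 s for GST-1, GST-2, SUM).
For linear frozen-flow transport the mixing time is exactly inversely
proportional to a uniform flow scaling, so the calibration is a
closed-form inversion verified by one re-simulation (within 2 %,
limited only by output-grid interpolation). CFD-derived flow maps can
be supplied instead through the JSON flow-map format.

Payload feeding goes entirely to the feed zone (top level, outer ring —
sub-surface addition near the liquid surface); the probe zone (bottom,
inner) mimics a local sensor. Stirrer speed is emulated by scaling all
exchange flows proportionally to speed (mixing time $\propto 1/N$ for
frozen-flow transport) — an emulation, not a turbulence claim.
Inter-compartment diffusion is neglected; at this granularity convective
exchange dominates a molecular diffusivity of $10^{-9}$ m$^2$/s by many
orders of magnitude.

Two structural limits pin the surrogate to the exact models on either
side: a two-zone network has closed-form tracer dynamics (relaxation
rate $2q/V$) used as an analytic oracle in the tests, and scaling all
flows by $10^6$ must reproduce the 0D model's DAR within 0.1 %.

## Mixing metrics

The global homogenization index is the volume-weighted squared-deviation
form
$$M_{\mathrm{global}}(t) = 1 - \frac{1}{V}\sum_i V_i
  \left(\frac{c_i(t)}{c_\infty} - 1\right)^2,$$
implemented exactly as printed (no square root), so it is strongly
negative immediately after a concentrated injection; only the approach
to 1 matters. The mixing time is the *last* crossing of the criterion
(default 95 %), linearly interpolated — robust to transient
re-crossings. For experimental conductivity traces,
`mixing_time_probe()` subtracts the tubing dead time and applies a
two-sided band: "95 % criterion" means the signal stays within
$\pm 5$ % of its final value (sidedness is a convention choice; the
sources do not state it).

## Scale-up metrics and time scales

`power_per_volume()` ($P/V = 2\pi N M/V$ from the stationary impeller
torque) and `reynolds_impeller()` ($Re = \rho N D^2/\mu$, with water +
10 % DMSO defaults $\rho = 1010.5$ kg/m$^3$, $\mu = 0.00106$ Pa s) are
the classical scale-up parameters; both are strictly linear in their
driving variable, so published values at one stirrer speed anchor any
other speed (`reynolds_at_speed()`). The characteristic bimolecular
reaction time $\tau_R = 1/(k_1(\tilde c_1 + \tilde c_2))$ is compared
against the mixing time by `classify_regime()`: a reaction slower than
mixing by more than the margin (default 1 — the sources do not quantify
"significantly larger", and the boundary case is conservatively called
mixing-sensitive) counts as ideal-mixed. At the standard condition
($\tau_R \approx 6.3$ s against a 32.2 s mixing time) the conjugation is
mixing-sensitive during the addition phase, which is exactly where the
models deviate.

The deviation itself is quantified by
$\Delta\mathrm{DAR}(t) = |\mathrm{DAR}_{0D}(t) - \mathrm{DAR}_{net}(t)|$
(described as an absolute difference, and implemented with the absolute
value even though one printed form omits the bars). `delta_dar()`
reports the maximum, its time, and the first time after feed end at
which the deviation stays below 0.005 (≈0.25 % of the target DAR 2;
configurable). Because the chemistry is consecutive and selective, all
operating conditions share one reaction endpoint: mixing only shifts
*when* conversion happens, never *where it ends*. The one-factor
parameter study (`run_parameter_study()`: 60/80/120 rpm equivalents,
batch/60 s/300 s feeding, 5/10 mg/mL) checks endpoint invariance to
$10^{-3}$ and reproduces the expected trends — batch feeding worst,
slow feeding best, higher concentration worse, faster stirring better.

A caveat stated once and relied on throughout: the published maximum
$\Delta$DAR values (0.0035 for GST-1, 0.08 for GST-2) are CFD results.
The surrogate reproduces their *ordering* (GST-2 > SUM > GST-1, matching
the mixing-time ordering) and qualitative shape, not the CFD magnitudes.

## Calibration from time-course data

`fit_rate_constants()` estimates $(k_1, k_2, k_3)$ by
Levenberg–Marquardt least squares (`minpack.lm`) between the 0D model
and a quenched-sample time course. Parameters are fitted on the log
scale (positivity for free), from five log-spaced starts around the
guess, deterministically. Each species is weighted by the inverse of its
observed maximum, floored at 5 % of the overall observation scale — the
floor prevents a species that stays near zero (bi-conjugate when
$k_2 \approx 0$) from acquiring unbounded weight and destabilizing the
fit; such a generating process instead drives the estimate to the lower
bound, which is flagged. Confidence intervals use a sandwich covariance
with model-based point variances when the dataset declares its relative
noise SD (squared residuals otherwise): under multiplicative noise the
plain residual covariance is overconfident. $k_3$ is structurally weak
without free-drug observations at saturating excess; such requests are
reported with a warning rather than silently fitted.
`fit_activation_distribution()` maps the final unconjugated/mono/bi
fractions directly onto $(p_0, p_1, p_2)$ — the dead-end species make
the end state a direct readout of the distribution.

## Synthetic data

`generate_kinetic_dataset()` emulates the quenched RP-UHPLC assay:
exact 0D trajectories sampled at 20 points over one hour (denser during
the rise phase), multiplicative Gaussian noise (default SD 2 %,
mimicking peak-area variability) truncated at zero, quenching treated as
perfect sampling at the nominal time. `generate_tracer_trace()` emulates
the external conductivity loop of a salt-spike experiment: the probe
zone's tracer curve, shifted by a dead time, with additive noise. Both
are seeded and deterministic. What the generators do *not* emulate —
chromatographic peak overlap, quench kinetics, sensor dynamics beyond a
pure delay, drift — bounds what passing recovery tests show about real
assays: they establish self-consistency of the estimator under the
stated noise model, not robustness to assay artefacts.

## Numerical choices and problem sizes

Tolerances $10^{-8}/10^{-10}$ (ODE), mixing-time interpolation on a
0.1 s output grid, completion times interpolated linearly at the 1 %
residual crossing. The test and example workloads use 12-zone networks
(8 and 48 in the size-sweep), 300–900 s reaction horizons, and
10-seed recovery studies — sizes chosen so the full analysis reruns in
about a minute on a laptop while leaving all conclusions
grid-independent (halving any grid changes no reported digit).

## Worked example

```{r, eval = FALSE}
library(conjmix)

c_mab <- molar_from_mass(5, 150000)          # 0.0333 mM
feed  <- feed_schedule(c_mab * 5, duration = 60)
tr0   <- simulate_0d(species_state(c_mab), kinetic_params(), feed, 300)
completion_time(tr0, 0.01)                   # ~86 s: well inside 300 s

net <- calibrated_vessel(vessel_template("GST-2"))
tr3 <- volume_average(simulate_reaction_network(net, kinetic_params(),
                                                c_mab, feed))
dd <- delta_dar(tr0, tr3)
attr(dd, "max_delta")                        # ~0.12, during feeding
attr(dd, "convergence_time")                 # ~117 s

classify_regime(reaction_timescale(0.797, c_mab, c_mab * 5), 32.2)
```

## Known limitations

No flow–reaction feedback (frozen flows), no turbulence or shear
modelling, no aggregation or fragmentation, no DAR-8 stochastic
conjugation chemistry (no kinetic model exists for it), no temperature
dependence, and compartment topologies that are plausible emulations
rather than derived decompositions. The package is therefore a
screening and reasoning tool for mixing sensitivity, not a replacement
for flow simulation where local fields matter.
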