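# conjmix

Fed-batch conjugation kinetics and mixing scale-up analysis for
antibody-drug conjugates (ADCs).

## What problem this solves

When an ADC conjugation is scaled from a reaction tube to a multi-litre
stirred vessel, the payload (linker-drug) is fed into a solution of
functionalized antibody and the conjugation chemistry competes with
vessel homogenization. Process developers need to know whether the
reaction can be treated as ideally mixed at a given scale — and if not,
how large the transient deviation is and which handles (stirrer speed,
feed duration, concentration) control it. `conjmix` answers this at
desk scale for a site-specific DAR-2 conjugation, without a CFD
licence: a mechanistic kinetic model is run both in an ideal-mixed
fed-batch reactor ("0D model") and over a compartment-network
(network-of-zones) surrogate of the vessel, and the two are compared
through the drug-to-antibody ratio (DAR).

## The model in brief

Species: antibody with two/one/zero activated cysteines
(A<sub>2</sub>, A<sub>1</sub>, A<sub>0</sub>), mono-conjugates
(M<sub>1a</sub> with one remaining reactive site, terminal
M<sub>1b</sub>), the bi-conjugate M<sub>2</sub>, free drug D, and
inactivated drug. Mass-action kinetics:

    A2 + D  --k1-->  M1a        M1a + D  --k2-->  M2
    A1 + D  --k1-->  M1b        D        --k3-->  (inactivated)

with defaults k1 = 0.797, k2 = 1.476 mM⁻¹s⁻¹, k3 = 0.00155 s⁻¹ and an
activation distribution (p2, p1, p0) = (0.8859, 0.0860, 0.0281), so the
attainable endpoint is DAR = 2·p2 + p1 = 1.8578 (or 2 with p2 = 1).

DAR(t) = (c<sub>M1a</sub> + c<sub>M1b</sub> + 2 c<sub>M2</sub>) / c<sub>mAb,0</sub>.

The vessel surrogate discretizes the tank into levels × rings well-mixed
zones with frozen convective exchange flows, laid out per vessel
(uniform for the 0.3 L GST-1; rotationally dominated with an axial
bottleneck for the 22 L GST-2; a one-sided circulation loop for the
25 L single-use mixer) and calibrated by a single flow-scaling factor to
the vessel's published 95 % global mixing time (9.4 / 32.2 / 17.6 s).
Mixing metrics (variance-based global index, probe traces with dead-time
correction), classical scale-up numbers (impeller Reynolds number, P/V),
a reaction/mixing time-scale classifier, ΔDAR deviation analysis, and a
least-squares calibrator for the rate constants complete the pipeline.
Seeded synthetic-data generators stand in for the quenched-sample
chromatography assay and conductivity traces, so everything runs without
external data.

## Worked example

```r
library(conjmix)

c_mab <- molar_from_mass(5, 150000)            # 5 mg/mL IgG -> 0.0333 mM
feed  <- feed_schedule(c_mab * 5, duration = 60)  # 5x excess over 60 s

tr0 <- simulate_0d(species_state(c_mab), kinetic_params(), feed, t_end = 300)
tr0
#> <conj_trajectory> 3001 points, t in [0, 300] s, final DAR 2
completion_time(tr0, 0.01)
#> [1] 86.22783

net <- calibrated_vessel(vessel_template("GST-2"))
tr3 <- volume_average(simulate_reaction_network(net, kinetic_params(),
                                                c_mab, feed))
dd <- delta_dar(tr0, tr3)
attr(dd, "max_delta"); attr(dd, "convergence_time")
#> [1] 0.1214922
#> [1] 117.2

classify_regime(reaction_timescale(0.797, c_mab, c_mab * 5), 32.2)
#> <timescale_pair> tau_R = 6.274 s, tau_mix = 32.2 s, ratio 0.195 -> mixing-sensitive

reynolds_at_speed(22141, 60, 120)              # GST-2 at 120 rpm
#> [1] 44282
```

Reading: at the standard large-scale condition the activated antibody
pool is ≥99 % conjugated after ~86 s (comfortably inside the 300 s
process window); the 22 L vessel's slow mixing makes the network model
lag the ideal-mixed model by up to ≈0.12 DAR units *during feeding*,
with the deviation gone ~117 s in — mixing shifts when conversion
happens, never the endpoint. The reaction time (6.3 s) being shorter
than the mixing time (32.2 s) classifies the addition phase as
mixing-sensitive, which is precisely where the deviation lives.

A YAML-driven interface (`read_run_config()`, `cmd_simulate()`,
`cmd_compare()`, `cmd_metrics()`, `cmd_fit()`, `cmd_generate()`, plus a
thin `inst/exec/conjmix` script) ties the stages together; a standard
configuration ships in `inst/extdata/gst2_standard.yaml`.

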