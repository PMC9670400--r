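---
title: "Methods: T-type channel variant gating and thalamic excitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T-type channel variant gating and thalamic excitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavgate)
```

`cavgate` analyses the biophysics of Cav3.2 (T-type) calcium-channel
missense variants characterised by whole-cell voltage clamp, and
projects the fitted gating changes onto the excitability of a model
reticular thalamic (nRT) neuron. This vignette records the models, the
tunable parameters and the design decisions, so results can be read
with the right caveats.

## Gating models

Whole-cell T-currents are summarised by three fitted objects:

* **Activation** — the peak current--voltage relationship is a Boltzmann
  activation term times a linear driving force,
  $I(V) = G_{max}\,(V - V_{rev})\,/\,(1 + e^{(V_{1/2}-V)/k})$, with
  $G_{max}$ in nS/pF (normalized to cell capacitance), and the
  conductance curve $G(V) = G_{max}/(1 + e^{(V_{1/2}-V)/k})$.
* **Steady-state inactivation (SSI)** — channel availability after 1 s
  conditioning, $I(V) = I_{max}/(1 + e^{(V-V_{1/2})/k})$. The slope
  factor is stored positive with the decreasing form; report writers
  re-emit the conventional negative sign. This removes a sign ambiguity
  from fitting bounds.
* **Recovery from inactivation** — a single exponential
  $I/I_{max} = A\,(1 - e^{-t/\tau})$ at $-110$ mV.

The bundled table (`cav32_variants()`) carries the published mean ± SEM
values for wild type and 13 variants, together with the per-condition
cell counts. `i_max` and `A` are allowed up to 1.05 so that noisy
normalized fits near 1 are representable.

A `t_gating_model` is the two-gate Hodgkin–Huxley representation: open
fraction $m(V,t)^p\,h(V,t)$ with gate exponent $p = 2$ (the convention
of the reference nRT T-current), voltage-dependent steady states and
time constants, and either linear or constant-field (GHK) driving.

### Two constructions, two purposes

The voltage-clamp data determine steady states and one kinetic quantity
(the recovery $\tau$); they do not determine $\tau_m(V)$ and
$\tau_h(V)$. The package therefore builds two different models from the
same fitted parameters:

* `build_gating_model()` — used for the **neuron simulation**. Steady
  states are the normalized fitted curves; the time-constant curves are
  those of the reference nRT T-current (Destexhe et al. 1996,
  *J Neurophysiol* 76:2049), voltage-shifted per gate by the variant's
  half-voltage shift. The hyperpolarized (recovery) limb of $\tau_h$ is
  scaled so that $\tau_h(-110\,\mathrm{mV})$ equals the variant's fitted
  recovery $\tau$; the scale blends into the unscaled depolarized limb
  through a sigmoid centred on the inactivation midpoint (5 mV width).
  Anchoring to the fitted value (rather than scaling by a WT ratio
  alone) makes every built model honor its own measured recovery time
  constant, and the ratio of two built models' recovery limbs still
  equals the ratio of their fitted taus.
* `recording_model()` — used for **synthesizing voltage-clamp sweeps**.
  Activation is fast ($\tau_m = 0.25$ ms, voltage-independent; the gate
  is the $1/p$-th root of the fitted curve so the macroscopic
  conductance equals the Boltzmann exactly), and $\tau_h(V)$ runs from
  the fitted recovery $\tau$ below $-100$ mV to 150 ms at depolarized
  potentials through a sigmoid placed at $-95$ mV. These constants
  separate the protocol timescales: activation equilibrates within the
  first millisecond of a test step (peak loss < 2%), SSI conditioning
  reaches steady state within its 1 s prepulse
  ($e^{-1000/150} < 10^{-2}$), and the recovery protocol reads out the
  fitted $\tau$ at $-110$ mV. With the neuron-model kinetics instead,
  the transient peak under-reads the steady-state conductance by a
  voltage-dependent 15–35%, and no fitting procedure can recover the
  generating parameters from the peaks; the idealized instrument
  kinetics are what make the generator a valid test bed for the fitting
  pipeline. Verified round-trip fidelity across all 14 parameter sets
  (noiseless): half-voltages within 0.03 mV, $G_{max}$ within 1.6%,
  $\tau$ within 0.6%.

## Synthetic recordings

`simulate_sweeps()` emulates the three standard protocols (constructors
`make_*_protocol()`): activation (140 ms steps, $-80$ to $+20$ mV in
5 mV increments, 200 ms prepulse at $-110$ mV from $-100$ mV holding),
SSI (1 s conditioning from $-110$ to $-15$ mV, 50 ms test at $-30$ mV)
and recovery (2 s inactivating pulse at $-20$ mV, $-110$ mV interpulse
of 1 ms–8 s, 150 ms test pulse). Within each constant-voltage segment
the gates follow the exact exponential update, so no ODE tolerance
enters the synthesis. Traces are digitized at 10 kHz, low-pass filtered
at 2 kHz with a 4-pole Bessel stage (built from the analog prototype
poles and the bilinear transform; the filter state is initialized at
the holding level so no start-up transient is introduced), and carry
ohmic leak plus i.i.d. Gaussian noise (defaults: 15 pF, 2 nS, 5 pA SD —
plausible whole-cell values, configurable). `p4_subtract()` removes the
leak the way an amplifier's P/4 protocol does, including the noise cost
of the four quarter-amplitude subsweeps.

What the generator does *not* emulate: series-resistance and
capacitance-transient artifacts, seal instability, rundown, or any
kinetic feature beyond the two-gate model. Passing round-trip tests
therefore validate the analysis pipeline, not the biological adequacy
of the two-gate description.

Cohort synthesis (`cohort_fits()`) fits each virtual cell separately
and summarises over cells (mean ± SEM), matching how patch-clamp
cohorts are reported. Optional per-cell parameter jitter draws from
Gaussians with SD = SEM·√n reconstructed from the published dispersion;
it is a stand-in for unavailable per-cell data, not a claim about the
real cohort, and it is off in the parameter-recovery checks (those
isolate recording noise).

## Peak measurement and fitting

`measure_peaks()` takes the extremal inward current of the filtered
trace within the test segment (inward negative), normalized by
capacitance. Baseline: the classical pre-step mean for the activation
protocol (its prepulse carries no T current), but the initial
holding-segment mean for SSI/recovery — at depolarized conditioning
voltages a steady window current flows immediately before the test
step, and subtracting it would bias the fitted inactivation midpoint by
up to ~1 mV.

Fits are bounded Levenberg–Marquardt with deterministic, data-driven
starts ($V_{1/2}$ from the half-maximal crossing, slope from a
two-point logit, $V_{rev}$ at +40 mV) and physiological bounds
($k \in [0.5, 30]$ mV, $V_{1/2} \in [-90, 0]$ mV,
$V_{rev} \in [10, 80]$ mV) that prevent limb-swapping degeneracy.
Non-convergence is an error; estimates at a bound are reported
distinctly. Degenerate inputs (all-zero peaks, availability increasing
with voltage, single-point recovery) are refused rather than
mis-fitted. A junction-potential helper applies the $-2.6$ mV
correction uniformly when emulating the published workflow; the
synthetic round-trip tests run without it (it cancels identically).

## Window current

`window_curve()` samples the normalized activation and availability
curves on a $\le 0.05$ mV grid over $[-110, 20]$ mV and takes their
pointwise **minimum** by default; the peak then sits at the closed-form
crossing $(k_i V_{1/2,act} + k_a V_{1/2,inact})/(k_a + k_i)$, which
reproduces the published per-variant peak voltages to within ~1 mV.
The pointwise **product** (an occupancy-style definition) is available
but is not the default because its argmax does not land on the
published peaks. The area is the trapezoidal integral of the overlap
(normalized amplitude × mV) and is reported both absolutely and as a
variant/WT ratio: the published absolute areas are in arbitrary units
that cannot be reconstructed from printed mean parameters (they were
evidently integrated from mean data curves), so the package reports its
own internally consistent measure instead of matching those numbers.

## Variant comparison and statistics

`summarize_variant()` computes variant-minus-WT shifts, the recovery
fold (WT $\tau$ / variant $\tau$; > 1 means faster recovery) and the
relative $G_{max}$ change. Report tables round at the source precision
— values are snapped to the 2-decimal grid of the published parameters
and then rounded half away from zero (`report_round()`), the behaviour
of the original analysis software; IEEE `round()` applied to doubles
would turn $-14.95$ into $-14.9$.

The functional classification (GoF / LoF / neutral) is explicit package
policy with configurable thresholds (activation shift $\le -5$ mV or
recovery fold $\ge 2$, significant, for GoF; $G_{max}$ drop $\ge 40\%$
or an inactivation-only shift $\le -10$ mV for LoF), because the
published labels are narrative, not algorithmic.

`kruskal_dunn()` implements the tie-corrected Kruskal–Wallis H and
Dunn's z versus the control group with a Bonferroni-style adjustment
across the control comparisons (the convention of the named software;
Holm/BH/none available). For small groups an exact permutation mode
enumerates all assignments; unit tests pin both modes against an
independent brute-force oracle, and the asymptotic test's type-I error
is verified to sit in [0.03, 0.07] at $\alpha = 0.05$ under the null.
Cells are treated as independent between protocols because pairing
across the published tables is unknowable.

## The nRT neuron model

The simulator is a three-compartment conductance-based cell in the
style of the reduced reticular-thalamic neuron of Destexhe et al.
(1996): a soma (L 38.4 µm × d 26 µm) carrying Traub-style fast Na⁺ and
delayed-rectifier K⁺ currents, two dendritic sections, passive leak and
axial coupling throughout, and T-type current as a constant-field
(GHK) flux with gate exponent 2, concentrated in the dendrites. T-gate
kinetics use the published reference curves with Q10 factors 5 (m) and
3 (h) referenced to 24 °C; the cell is simulated at 36 °C, inheriting
the reference model's temperature handling unchanged. Internal calcium
is held at 240 nM (no pool dynamics — the overlap with the driving
force is negligible at these fluxes, and the published model's pool
mainly serves its own calcium-dependent mechanisms, which this cell
does not include).

The original model's densities and geometry are not printed in the
source for this analysis, so the package pins its own parameter file
(`inst/extdata/nrt_reference_model.json`) and treats it as *the*
reference cell. The constants were calibrated once, against qualitative
targets only — a stable $-70$ mV rest under a solved bias current, a
terminating rebound burst with a clear rheobase under 200 ms
hyperpolarizing pulses, sustained tonic firing during 200 ms
depolarizing pulses at 0.2 nA, and tonic behaviour nearly independent
of the variant carried — and then frozen. Absolute rheobase and
frequency values are calibration-dependent and are not comparable
across different reference parameterizations; the package's claims are
the *relative* variant-versus-WT effects.

Variant substitution follows the heterozygosity argument: roughly 40%
of the native nRT T conductance is Cav3.2 and half of that carries the
variant, so `build_nrt_model(..., f = 0.2)` splits every compartment's
T permeability into 80% reference kinetics and 20% variant kinetics
with independent gate states, preserving total density. Substitution is
uniform across compartments (the source does not state otherwise).
`f = 0` reproduces the reference cell bit for bit, which is the tested
identity anchoring all comparisons.

Numerical choices:

* fixed-step RK4 at 12.5 µs, states recorded every 0.1 ms; the fixed
  step keeps runs bit-reproducible (an adaptive controller would break
  the `f = 0` identity), and halving the step is the accuracy
  cross-check (spike counts and times agree). 25 µs is marginally
  unstable during full Na⁺ activation at the calibrated density, hence
  the finer default.
* somatic gate rates are capped at 40/ms; the cap only binds at
  unphysiological voltages (below $\approx -150$ mV) reached during
  deep bisection probes, where the gates are saturated anyway.
* holding at $-70$ mV is implemented as a solved constant somatic bias
  current (a current-clamp holding, not a voltage clamp), found by
  secant iteration on 3 s relaxations and cached per model.
* spikes are upward 0 mV crossings with a 2 ms refractory; the rebound
  window runs from pulse offset to 400 ms after offset (near threshold
  the burst ignites with a delay of up to ~200 ms); frequencies use the
  200 ms convention (3 rebound spikes ⇒ 15 Hz).
* rheobase is found by bisection on the pulse magnitude to a stated
  resolution (defaults 1 pA rebound / 0.1 pA tonic; the ordering
  analyses use 0.02 pA because variant effects at 20% substitution are
  a few percent of the rheobase).

## Known limitations

* The S187L rebound rheobase ties WT in this model instead of being
  slightly smaller: the S187L and WT activation curves cross at
  $-67.7$ mV, which is the burst-ignition voltage at the $-70$ mV
  holding, so S187L's steeper-but-left-shifted activation confers no
  ignition advantage while its hyperpolarized inactivation midpoint
  ($-70.2$ mV) reduces resting availability. Its rebound *frequency* is
  elevated as expected. A reference cell operating deeper in the
  recovery regime separates S187L but loses the near-equality of tonic
  firing across variants; with one pinned reference cell both cannot
  hold at once.
* Tonic-frequency differences across variants are dominated by the
  variants' window current at inter-spike voltages and are inherently a
  few percent (P1120L, the variant with the largest window, is the
  extreme case) — consistent with the few-percent spread the source
  reports for depolarizing injections.
* Problem sizes used in the shipped checks — 10-cell cohorts, 10-point
  recovery grids, 0.05 mV window grids, seven simulated variants — are
  the package's defaults chosen to characterise the methods precisely
  at interactive runtimes; all are configurable upward.

## A minimal session

```{r}
tab <- cav32_variants()
variant_summary_table(tab)[c(1, 12, 13), ]

wt <- variant_params("WT")
w <- window_curve(wt$act, wt$inact)
w$peak_v
```

```{r, eval = FALSE}
# synthesize, leak-subtract, fit one virtual WT cell
mod <- recording_model(wt$act, wt$inact, wt$rec, label = "WT")
sw <- p4_subtract(simulate_sweeps(mod, make_activation_protocol(),
                                  noise_sd = 5, seed = 1))
fit_iv(measure_peaks(sw))

# neuron-level consequence of one variant
p <- variant_params("P2280H")
m <- build_nrt_model(build_gating_model(p$act, p$inact, p$rec,
                                        label = "P2280H"))
find_rheobase(m, "rebound", rebound_ms = 400)
```
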