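---
title: "Modelling asymmetric electrical coupling between TRN neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling asymmetric electrical coupling between TRN neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapasym)
```

## The model

Neurons of the thalamic reticular nucleus (TRN) are coupled by gap
junctions (electrical synapses), often at dendro-dendritic contacts far
from either soma. `gapasym` models a coupled pair as a small network of
isopotential Hodgkin–Huxley compartments. Each compartment `i` obeys

$$C_m \frac{dV_i}{dt} = G_{leak}(E_{leak} - V_i)
  + \sum_{ion} G_{ion}(t)\,(E_{ion} - V_i)
  + \sum_{syn} G_{syn}(t)\,(E_{syn} - V_i)
  + I_{inj}(t)
  + \sum_{j} G^{elec}_{ji}(V_j - V_i)
  + \sum_{j} G^{int}_{ji}(V_j - V_i)$$

with six voltage-gated currents: fast transient Na⁺ (NaT), delayed
rectifier K⁺ (Kd), transient A-type K⁺ (Kt), slowly inactivating K⁺ (K2),
the anomalous rectifier (AR, hyperpolarization-activated), and the
low-threshold transient Ca²⁺ current (CaT) that underlies burst firing.
Reversal potentials are 50 mV (Na), −100 mV (K), 125 mV (Ca, held fixed —
no calcium-pool or GHK dynamics), −40 mV (AR) and −75 mV (leak).

Two cell geometries are provided. `make_single_compartment_trn()` is a
soma-only cell (capacitance 1 µF/cm², leak 0.1 mS/cm²; NaT 60.5, Kd 60,
Kt 5, K2 0.5, AR 0.025, CaT 0.75 mS/cm²). `make_three_compartment_trn()`
adds a middle and a distal dendritic compartment (capacitance 1.2 µF/cm²,
dendritic leak 0.035 mS/cm²) joined by fixed internal conductances of
0.4 mS/cm² (middle–soma) and 0.35 mS/cm² (distal–middle). Soma maxima are
NaT 60.5, Kd 90, Kt 5, K2 0.5, AR 0.005, CaT 0.5 mS/cm²; dendrites carry
no sodium current (TRN dendrites do not spike) and a reduced CaT of
0.15 mS/cm². We read the remaining dendritic conductances (Kd, Kt, K2,
AR) as inherited from the per-model table, since only the sodium removal
and the CaT reduction are singled out as dendrite-specific.

All compartments are treated as unit-area membrane patches: conductance
and current *densities* (mS/cm², µA/cm²) serve directly as absolute
quantities, because the parameter set specifies densities and no
geometric areas.

### Gating kinetics

The maximal conductances above fix how much of each current is available,
but the rate equations behind the gating variables come from the
Traub-lineage thalamic reticular formulations that this family of TRN
models is built on; `trn_kinetics_table()` prints the Boltzmann constants
and time-constant formulas per gate, and `steady_state_and_tau()`
evaluates exactly what the compiled integrator uses. One constant was
calibrated rather than copied: the NaT half-activation/-inactivation pair
is shifted 1 mV leftward (to −39/−63.9 mV), the smallest adjustment in
this lineage's own shift-parameter style for which the single-compartment
cell fires *regular tonic* spikes at its published operating drives
(0.575 and 0.6 µA/cm² give 62 and 66 Hz with negligible ISI variance)
instead of sitting just below rheobase. Subthreshold results do not
depend on this choice — they are dominated by the printed passive
parameters and are verified against an exact linear solution (below) —
while spike-dependent results should be read as reproducing trends and
approximate values, which is why their tests carry wider tolerances.
Temperature factors are folded into the rate constants and not exposed.

### Electrical synapses and asymmetry

An `electrical_synapse()` carries two independent conductances: `g_ab`
drives current `g_ab (V_a − V_b)` into endpoint b, and `g_ba` the
reverse. Equal values give a symmetric junction that conserves charge
exactly; unequal values leave a per-step imbalance
`(g_ab − g_ba)(V_a − V_b)` — the model's representation of junctional
rectification. The conductance ratio `g_12/g_21` follows the convention
that `g_12` governs transmission *from cell 1 into cell 2*.

AMPAergic inputs are difference-of-exponentials events (rise 5 ms, fall
35 ms, reversal 0 mV), peak-normalized so an event's amplitude *is* its
peak. Because the drive is specified as EPSC *currents* in µA/cm², the
default injects the waveform as a current; `mode = "conductance"`
switches to a conductance-based variant with explicit driving force, for
users who prefer that reading.

## Numerics

The coupled system is integrated by a fixed-step midpoint (second-order
Runge–Kutta) scheme in C++, at `dt = 0.01` ms by default. "Second-order
Runge–Kutta" is ambiguous between midpoint and Heun variants; the
difference is far below the step-halving stability requirement we impose:
on subthreshold two-cell protocols, halving `dt` moves final voltages by
less than 10⁻³ mV (measured: ~10⁻¹² mV), and every reported quantity is
`dt`-stable. Gating variables are clamped to [0, 1] after each step
(binding only at numerical round-off), and any |V| > 200 mV aborts with
a diagnostic naming the first offending compartment and time. Every
simulation is settled for `settle_time` (default 500 ms) with stimuli
silenced, so t = 0 starts at the model's rest; runs are deterministic and
bit-identical across repeats, and mirror-symmetric configurations produce
exactly exchanged traces.

Spike detection uses upward crossings of 0 mV with a 2-ms refractory
window. Model action potentials overshoot 0 mV robustly, so counts are
unchanged across thresholds from −20 to +10 mV (asserted in tests).

## Measurement protocols

**Coupling coefficients.** `measure_coupling()` injects a 500-ms
hyperpolarizing square pulse (default −0.5 µA/cm²) into one soma and
reads both cells at the stated site; the steady-state deflection is the
mean over the last 200 ms of the pulse minus a 200-ms pre-pulse baseline
(the baseline window length mirrors the steady-state window, making the
estimator symmetric), and `cc = ΔV_other/ΔV_injected`; both directions
are measured in separate runs, and `cc_ratio = cc_12/cc_21`. Two
implementation details matter. First, the deflection is computed on the
*difference* between the stimulated run and an unstimulated control run:
the full model relaxes toward rest on multi-second time scales (slow K2
inactivation), and control subtraction removes that drift exactly, making
the measured cc amplitude-independent to better than 0.1% (the
subthreshold-linearity assertion in the tests). Second, the pulse must
stay subthreshold; spike contamination raises an error rather than a
silently corrupted value.

**Input resistance.** `measure_input_resistance()` applies the same
protocol to a single cell. Input-resistance changes are realized by leak
scaling (`scale_leak`, all compartments by default, with a soma-only
switch for sensitivity checks, since the source description does not
restrict the scaling). The published bracket — factors 0.75–1.45 mapping
to roughly ±25% input resistance — is visibly asymmetric, so the map from
target percentage to factor is not assumed linear:
`calibrate_rin_change()` bisects against the measured (or, for passive
models, analytic) input resistance to within 0.01 percentage points.

**Latency modulation.** `measure_latency()` delivers the standard burst
(13 EPSCs, 1 µA/cm², 5-ms inter-event interval) to both distal dendrites
with a 0.5 µA/cm² somatic holding current, and measures each cell's time
from its own first EPSC to its first somatic spike. The reported
modulation is `(Δlat₁ − Δlat₂)`, each `Δlat` relative to the latency of
an uncoupled cell under the identical stimulus — the sign convention
being "change of cell 1's latency minus change of cell 2's", exposed
explicitly in the output. Cells that fail to spike are flagged `NA` and
excluded from sweep summaries. Bursts begin 250 ms after the holding
current switches on so its onset transient has decayed.

**Synchrony phase.** `measure_synchrony()` drives two single-compartment
cells tonically (0.575 / 0.6 µA/cm²), takes a 500-ms window of stable
firing from the end of a 2500-ms run (extending the run and shifting the
window later if the mean ISI drifts more than 5% between window halves),
binarizes both somatic spike trains on the integration grid, filters them
with a 5-ms Hanning window, and cross-correlates. The lag of the
correlogram peak nearest zero — ties broken toward the non-negative lag,
so perfect anti-phase reports +180° — is converted to a phase by
`t_max_lag/ISI × 360`, mapped to [−180°, 180°]; positive phase means
cell 2 fires after cell 1. The ISI in the formula is cell 1's mean ISI;
at the locked states where phase is meaningful the two ISIs agree to
<1% (reported as `rate_converged`). Correlogram normalization (raw vs
Pearson) is exposed but cannot move the peak lag, hence never the phase
(asserted). Phase locking in this model stabilizes well within the
default run length — measured phases are unchanged from 2.5-s to 40-s
horizons.

## The analytic oracle

With every channel conductance zeroed (`zero_channels()`), the membrane
equation's steady state is a linear nodal system `G ΔV = I` over
compartments, with leaks on the diagonal and (possibly asymmetric)
junction terms off it. `solve_steady_state()` solves it directly;
`analytic_cc()`/`analytic_cc_ratio()` derive coupling coefficients from
two solves. This closed form — linearized at the leak reversal, by
construction, so it is compared only against simulations whose channels
are likewise zeroed — is the package's independent correctness gate:
`oracle_check()` rebuilds 42 passive configurations spanning the
location, input-resistance, geometry and directional-conductance grids
and verifies that the time-domain integrator matches the linear solution;
the test suite requires < 0.5% everywhere (measured: ~10⁻⁶ relative).
With active channels restored, simulated cc deviates smoothly from the
passive value at rest (resting AR/CaT/K2/Kt conductances add membrane
load, most of it dendritic, which also deepens location-sourced
asymmetry); this is documented behaviour, not a tested tolerance.

## Sweep runners and problem sizes

Each `run_*` function regenerates one parameter map as a tidy data frame
with every axis echoed per row, deterministic and bit-identical on
re-run. Default grids are chosen to bracket the published anchor values
while keeping a desk-scale footprint:

- junction conductance axis: 0.05–0.25 mS/cm² (anchors 0.005–0.2,
  reference 0.15);
- input-resistance axis: ±25% in calibrated steps;
- directional-conductance ratios: 0.3–3, the experimentally observed
  range, around a fixed `g_21 = 0.15 mS/cm²`;
- burst-onset differences: −30 to +30 ms in 2-ms steps (spanning the
  60-ms burst);
- synchrony base strengths: 0.005, 0.0125, 0.025 mS/cm².

`run_masking_isoclines()` reproduces six configurations in which
distinct mechanisms produce the same soma-measured asymmetry (cc ratio
≈ 1.2 or ≈ 0.8): a directional junction plus an input-resistance change
(G_c ratio 1.8 with −20%, or 0.667 with +6%), a mismatched location plus
an input-resistance change (M-D with +25%, M-S with −12%), and a
mismatched location plus altered cell-2 dendritic geometry (S-M with
internal factors 0.867/0.8, D-S with 1.2/1.2). For the two
directional-junction cases the junction is soma-somatic, matching the
protocol of the directional-conductance sweep, as the configuration
descriptions leave the location implicit.

## What the stimulus generator does and does not emulate

The stimulus module *is* the package's synthetic-data generator: square
steps, EPSC bursts and tonic drives are exact, noise-free parametric
waveforms, reproducible from their parameter tuples. Real TRN input is
noisy, afferent bursts jitter, and real pairs are never perfectly
identical; passing tests therefore demonstrate the mechanisms —
location-, resistance-, geometry- and conductance-sourced asymmetry and
its spike-timing consequences — under clean conditions, not robustness
of those mechanisms to biological variability. Networks larger than two
cells, noisy or naturalistic stimuli, synaptic plasticity, gap-junction
voltage gating and cable-resolution dendrites are out of scope.

## A worked example

```{r example, eval = FALSE}
# how much asymmetry does a mismatched synapse location produce?
pair <- coupled_pair(c("M", "D"), g_12 = 0.15)
measure_coupling(pair)
#> <coupling: cc_12 = 0.2308, cc_21 = 0.1860, ratio = 1.2406 (site S)>

# and the passive linear prediction for the same topology:
analytic_cc_ratio(coupled_pair(c("M", "D"), 0.15,
                               cell1 = zero_channels(make_three_compartment_trn())))
#> [1] 1.047567
```

The active model shows more location asymmetry than its passive
skeleton: the resting dendritic conductances (Kt, K2, AR, CaT window)
add membrane load exactly where the location mismatch acts. The passive
value is what the oracle certifies; the active value is the measurement
the protocols report.

## Known limitations

- Gating kinetics are adopted from the model lineage, not printed with
  the parameter tables; spike-dependent quantities (latencies, phases,
  firing rates) are faithful in trend and approximate in value.
- The analytic oracle covers only the passive limit; there is no
  impedance (frequency-domain) analysis.
- The latency sweep reports `NA` for conditions where a cell never
  spikes; with the default grids this does not occur, but more extreme
  user grids (very strong junctions, large onset offsets) can suppress
  firing in one cell.
- Phase is reported from a single locked window; for parameter values
  close to a locking boundary the reported value depends on window
  placement, flagged by `rate_converged = FALSE`.
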