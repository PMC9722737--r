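---
title: "Methods: windkessel boundary conditions for craniospinal CSF dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windkessel boundary conditions for craniospinal CSF dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfsim)
```

## The model

`csfsim` treats the craniospinal cerebrospinal-fluid (CSF) space as a
hydraulic circuit. Three ingredients define the physics:

1. **Inlet sources.** CSF production is a constant volumetric source
   (default 6.67e-3 ml/s, i.e. 0.4 ml/min, at the ventricles). Vascular
   volume changes are idealized as zero-mean sinusoids: a small 1 Hz
   cardiac source at the ventricles (0.11 ml/s, the stroke flow seen in the
   cerebral aqueduct), a large 1 Hz cardiac source in the basilar region
   (5.05 ml/s, large-artery volume change), and a 0.2 Hz respiratory venous
   source at the cranial subarachnoid space (SAS) (1.01 ml/s). Because the
   skull is rigid, these volume sources must be displaced or stored — this
   is what drives pulsatile CSF flow.

2. **Windkessel outlets.** Absorption into the venous and lymphatic systems
   is lumped into four outlets — interstitial (`int`), spinal (`sp`),
   lymphatic (`lym`) and arachnoid villi (`av`) — each a 2-element
   windkessel: resistance $R_i$ and compliance $C_i$ in parallel against an
   external pressure $P_{out} = 0$,
   $$ Q = \frac{P - P_{out}}{R} + C\,\frac{d(P - P_{out})}{dt}. $$
   All storage in the model lives in these outlet compliances; the
   compartments themselves are rigid.

3. **A rigid compartment network.** Four compartments — ventricles, basilar
   region, cranial SAS, spinal SAS — are joined by three laminar conduits
   (cerebral aqueduct, tentorial passage, foramen magnum). Node mass
   balance plus linear conduit laws yield one small linear system per time
   step.

The same windkessel recurrence also powers a 0D model (one node, the
combined inflow, one windkessel with $R_{tot}$, $C_{tot}$) used to fit the
total compliance before running the network.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `ICP_avg` | 10 | mmHg | target mean intracranial pressure (normal range 7–15) |
| `Q_production` | 6.67e-3 | ml/s | constant CSF formation |
| `R_tot` | 1500 | mmHg·s/ml | `ICP_avg / Q_production`: sets mean ICP |
| `q` | 20/20/30/30 % | — | outflow fractions int/sp/lym/av; `R_i = R_tot / q_i` |
| `c` | case-dependent | — | compliance fractions; `C_i = c_i C_tot` |
| `C_tot` | 0.17–1.01 | ml/mmHg | total craniospinal compliance (in vivo ~0.4–1.2) |
| `dt` | 0.05 | s | time step, fixed, all solvers |
| `target_amplitude` | 5 | mmHg | ICP pulsation amplitude the tuning aims for |

Outflow fractions express that absorption routes beyond the arachnoid villi
(lymphatic, interstitial, spinal) carry a substantial share of CSF uptake;
their exact split is uncertain in vivo, and `outlet_allocation()` accepts
any fractions that sum to one. Because the resistances sit in parallel,
`allocate_resistances()` recovers `R_tot` exactly under parallel
recombination — an invariant the test suite asserts.

The default spinal compliance fraction (0.67) reflects the supine in vivo
estimate that the spinal compartment provides roughly two thirds of
craniospinal buffering. The respiratory source default of 1.01 ml/s is
taken from the same parameter table as the cardiac amplitudes so that the
case definitions form one consistent set (about 20 % of the combined
cardiac amplitude of 5.16 ml/s).

## Time discretization

The windkessel ODE is discretized with a backward difference and solved for
the current pressure:
$$ P_n = \frac{Q_n R + P_{n-1}\,C R/\Delta t}{1 + C R/\Delta t}, $$
(`wk_update()`). This is implicit — unconditionally stable for any
$\Delta t$ — and reduces exactly to the resistor law $P = QR$ when $C = 0$.
Its frequency response is the backward-difference filter gain
$$ \left| \frac{R}{1 + CR\,(1 - e^{-i\omega\Delta t})/\Delta t} \right|, $$
which the test suite verifies against simulated steady cycles to 0.5 % and
which converges to the continuous-time windkessel gain
$R/\sqrt{1+(\omega R C)^2}$ as $\Delta t \to 0$. At $\Delta t = 0.05$ s and
1 Hz the discrete gain sits about 1 % above the continuous one; all
default analyses use $\Delta t = 0.05$ s consistently, so fitted
compliances and simulated amplitudes are mutually consistent at that step.

With constant inflow the recurrence contracts toward $Q R + P_{out}$ by the
exact factor $a/(1+a)$ per step, $a = CR/\Delta t$; the outlet time
constants $R_{tot} C_{tot}$ are 255–1515 s, so mean-pressure transients are
minutes long while pulsations equilibrate within a few cycles.

## Compliance tuning protocol

`tune_total_compliance()` implements the fit of $C_{tot}$:

* simulate the 0D model for $t \in [0, 5]$ s (five cardiac cycles) from
  $P_0 = 0$ at $\Delta t = 0.05$ s;
* measure the pulsation amplitude as **half** the peak-to-peak pressure
  excursion over the whole window (start-up drift included);
* scan 1000 compliance values on $(0, 1.2]$ ml/mmHg — the in vivo range —
  excluding $C = 0$ (a pure resistor has no finite-compliance amplitude
  limit);
* amplitude is strictly decreasing in compliance (a property test), so the
  crossing with the target is unique; it is located by linear interpolation
  between the bracketing grid points, since the raw grid spacing
  (0.0012 ml/mmHg) would otherwise limit precision.

Half peak-to-peak is the package's amplitude convention throughout
(`pulsation_amplitude()`): a pure sinusoid of amplitude $a$ reports $a$.
Under this protocol the cardiac-only fit at a 5 mmHg target lands at
0.164 ml/mmHg (the acceptance suite checks 0.17 ± 0.01). An unreachable
target fails loudly, naming the achieved amplitude range rather than
returning an endpoint.

## Network solvers

**Monolithic** (`step_monolithic()`): one linear solve per step in the
compartment pressures, with outlet admittances $1/R_i + C_i/\Delta t$ on
the diagonal and the windkessel history as a source term. A
single-compartment network reproduces the 0D recurrence exactly (same
linear relation), which the tests assert to 1e-13.

**Partitioned** (`step_partitioned()`): mirrors how windkessels are coupled
to a black-box flow solver that only accepts pressure boundary values. Per
step it (1) runs the flow solve with the outlet pressures frozen,
(2) probes each outlet pressure with a 1e-3 mmHg perturbation to build the
outlet-flow/outlet-pressure sensitivity matrix, (3) solves the linearized
coupled problem, and (4) iterates until the interface imbalance drops below
1e-9 mmHg (at most 50 iterations; non-convergence is an error that reports
the residual). The implicit coupling matters because spatial pressure
differences (order 0.01 mmHg) are tiny against temporal swings (order
10 mmHg): `tol = Inf` exposes the single-pass explicit scheme for
comparison. On a linear network the linearization is exact, so the scheme
converges in two iterations and matches the monolithic solution to solver
precision (asserted at 1e-6 mmHg on all fixtures).

Outlets that share a compartment (int, lym, av on the cranial SAS) share
one interface pressure — the compartment collapses what would be distinct
outlet surfaces in a spatially resolved model to a point — and their
individual flows are recovered from their own windkessel relations.

## Network geometry

Conduit resistances follow laminar first principles on water (density
998.2 kg/m³, viscosity 1.003e-3 kg/(m·s)). The aqueduct is a circular tube
(length 15 mm, area 10 mm²; `poiseuille_resistance()`, $8\mu L/\pi r^4$).
The tentorial and foramen-magnum passages are thin annular gaps around the
midbrain and spinal cord, for which a circular-tube law badly
underestimates resistance; they use the plane-slit law
$12\mu L/(\ell h^3)$ (`slit_resistance()`) with gap 3 mm/circumference
50 mm and gap 1.5 mm/circumference 100 mm respectively (both area
150 mm²). These dimensions were chosen once, on anatomical plausibility,
so that spatial pressure differences land in the sub-0.1 mmHg range and
peak aqueduct velocity at the default area is ~1.2 cm/s; peak Reynolds
numbers stay of order 10–100 (`reynolds_number()`), consistent with the
laminar assumption.

## Initialization and metrics windows

Initial pressures default to the 10 mmHg target mean for steady-cycle
metrics: since the mean transient is minutes long, a 25 s run initialized
at 0 would report means far from equilibrium. For transient studies
(e.g. the long 0D runs) $P_0 = 0$ is used and stated. Even
mean-initialized runs keep a slow residual drift (the oscillatory
particular solution displaces the mean), so 25 s means sit ~1–4 mmHg above
the asymptotic value — the 0D long-run check (2005 s) confirms the mean
settles at the targeted 10 mmHg within 0.05.

Report metrics (`compute_metrics()`) are evaluated over the last 5 s of a
25 s run: the last five cardiac cycles when only 1 Hz sources are active
(case A) and the last full respiratory cycle otherwise — windows covering
whole periods of every active source, so sinusoid means cancel exactly on
the sampling grid. The "ventricle to upper spinal SAS" pressure difference
is the pointwise difference of the two node pressures; the surrogate has
no spatial axis inside a compartment.

## Reference cases

`build_case()`/`run_case()` encode five configurations: **A** cardiac only,
compliance on int/sp (33/67 %), $C_{tot} = 0.17$; **B** respiration added,
$C_{tot} = 0.51$; **C** compliance over all four outlets (11/67/11/11);
**D** int/sp swapped (67/33); **E** as B with $C_{tot} = 1.01$. For B–E
the total compliance is a configuration input, not re-fitted. These
fixtures are the study conditions the tests run: they emulate the
idealized physiology (pure sinusoids, fixed fractions, rigid walls), not
any individual's anatomy or measured waveforms. Passing tests therefore
demonstrate the circuit physics — flow splits proportional to compliance
fractions, pressure amplitude inversely proportional to total compliance,
production conserved — and say nothing about patient-specific geometry,
non-sinusoidal waveforms, or posture.

## Degenerate inputs and failure modes

Zero outflow fractions are rejected (omit the outlet instead); fraction
sums are validated to 1e-9; networks without an outlet, with dangling
references, self-loops or disconnected compartments are rejected at
construction; an empty metrics window and windows outside the simulated
span are errors. $C = 0$ outlets are exact resistors, not a numerical
limit. All computations are deterministic; repeated runs are bit-for-bit
identical, and the time-series writer emits byte-identical CSV.

## Problem sizes

Default analyses are deliberately small: 0D tuning is 1000 × 100 steps,
the long 0D run 40,100 steps, and each network case 500 steps of a 4×4
linear system — a few seconds in total, so the full case grid can be
re-run interactively.

## Limitations

* No spatial resolution within compartments: velocities exist only as
  conduit mean velocities; wall shear, jet structure and local gradients
  are out of scope.
* Rigid compartments: all compliance is lumped at the outlets. A
  fluid–structure treatment of dural/parenchymal deformation would
  distribute storage continuously.
* Inlet waveforms are single sinusoids; measured waveform playback is not
  implemented.
* Gravity, posture and autoregulation are neglected; parameters represent
  a supine adult.
* The windkessel is the 2-element form; inertance (3-element) and
  nonlinear (exponential) pressure–volume behavior are not modeled, so
  very large pressure excursions are outside the model's validity.
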