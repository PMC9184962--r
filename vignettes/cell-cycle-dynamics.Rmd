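---
title: "Models and methods: CDK oscillations, bistable switches and size control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: CDK oscillations, bistable switches and size control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdkclock)
```

# The biological system and the models

Entry into and exit from mitosis is driven by M-phase promoting factor
(MPF), the CycB:Cdk1 dimer.  `cdkclock` implements a nested family of four
ODE models of this control system, each adding one experimentally motivated
regulatory layer, together with the dynamical-systems machinery needed to
characterise them.  Throughout, time is in minutes and concentrations are
dimensionless activity units; the reference parameter sets are shipped as
plain-text fixtures (`inst/extdata/parameters/`) and loaded with
`table1_parameters()`.

**Model 1 — delayed negative feedback.**  Cyclin B is synthesised at a
constant rate; MPF activates an intermediary kinase, which activates the
APC/C ubiquitin ligase, which degrades cyclin B.  Kinase and phosphatase
steps follow Michaelis–Menten kinetics, making the responses ultrasensitive
and the loop oscillatory (a relaxation-free, ~46-minute limit cycle).
States: `MPF`, `KinP`, `APCP`.

**Model 2 — the Gwl/ENSA/B55 feed-forward loop.**  MPF activates APC/C both
directly (phosphorylation) and indirectly: MPF activates Greatwall kinase,
Greatwall phosphorylates ENSA, and phospho-ENSA sequesters the counteracting
phosphatase PP2A:B55.  Two algebraic closures carry the biochemistry:

* `tqssa_complex()` — the ENSA-P:B55 complex from the total quasi-steady-state
  approximation, the smaller root of \(C^2 - BC + E_T B_T = 0\) with
  \(B = E_T + B_T + K_m\), evaluated in the cancellation-free form
  \(2 E_T B_T / (B + \sqrt{B^2 - 4 E_T B_T})\).
* `ub_fraction()` — the fraction of cyclin B carrying a full ubiquitin chain
  under an ordered-distributive mechanism with chain depth four (states
  Ub0–Ub4; the depth is a structural constant of the mechanism, not a tunable).
  With activity ratio \(r\), the geometric occupancies give
  \(f = r^4/(1 + r + r^2 + r^3 + r^4)\).

**Model 3** differs from Model 2 by one term: PP2A:B55 also dephosphorylates
Greatwall.  This closes a double-negative feedback loop
(Gwl ⊣ B55 ⊣ Gwl) that makes B55 — and hence APC/C — a *bistable* function
of MPF.

**Model 4 — the dual-bistable engine.**  Adds the inhibitory tyrosine
phosphorylation of Cdk1 by Wee1, reversed by Cdc25, with both enzymes
multisite substrates of MPF.  The eight-site ordered-distributive chains
give the closed forms in `wee1_active_fraction()` and
`cdc25_active_fraction()` (nine geometric states; the first five Wee1
states and last four Cdc25 states are the active ones; the two fractions
sum to one identically).  States add total cyclin `CycBT`, with the hard
constraint `MPF <= CycBT`.

**Checkpoints** are parameter changes to Model 4 (`apply_checkpoint()`):
G2 arrest by Cdc25 sequestration (`Cdc25_tot = 0.4`), spindle-assembly
arrest by Cdc20 sequestration (`Cdc20_tot = 0.1`, with `0.2` as a
documented milder alternative — both arrest), and G1 arrest by
APC/C:Cdh1-mediated degradation, an extra term
\(k_{de3}(APC_{tot} - APC_P)\) in the cyclin degradation factor.  We apply
the Cdh1 term to both the `CycBT` and `MPF` equations: the term models
degradation of the cyclin moiety, which removes active and
tyrosine-phosphorylated dimers alike; applying it to total cyclin only
would let `MPF` exceed `CycBT`.  With `kde3_cycb = 0` the variant is
bit-identical to plain Model 4.

**Size control** (`simulate_size_control()`) couples Model 4 to cell
growth: total Cdc25 equals cell size \(V\), \(dV/dt = \mu V\), and \(V\) is
halved at division.  Division fires on the downward crossing of MPF
through an exit threshold (0.2), armed once MPF has exceeded an entry
threshold since the last division.  The entry threshold is not a published
number; we use 0.5, comfortably above the interphase MPF plateau and below
the mitotic peak, and division statistics are insensitive to it because
arming is a level condition.  Only \(V\) is discontinuous at division —
protein concentrations are intensive quantities and stay continuous.

# Numerical methods

**Integration.**  `cc_integrate()` wraps `deSolve::lsoda` (stiff-capable,
adaptive) with defaults `rtol = 1e-8`, `atol = 1e-10`; the bistable models
produce relaxation oscillations with near-discontinuous jumps, which is
why the defaults are tight.  Division events use `deSolve::lsodar`
root-finding, so event times are located to integrator precision, far
below the output step.

**Removable singularities.**  The rational forms of the ubiquitination and
phosphorylation fractions are 0/0 at ratio one.  All three closures are
evaluated as ratios of geometric sums (normalised by the largest term),
which are singularity-free for any non-negative ratio including infinity;
no guard interval is needed.

**Limit cycles.**  `find_limit_cycle()` measures the period as the mean
spacing of successive MPF maxima (quadratically interpolated below the
output grid), after discarding a transient of three putative periods or
500 min, whichever is larger.  Convergence requires at least five maxima
with a coefficient of variation of spacings below `1e-3`.  Non-oscillation
is a reported outcome, not an error.  On a test oscillator with known
period the estimator is accurate to 0.1%.

**Steady states and stability.**  `find_steady_states()` runs damped
Newton iteration from a deterministic factorial grid over the admissible
state box and filters converged roots against the physical invariants.
The filter matters: the mass-action APC/C:Cdc20 binding equation has
spurious roots with more complex than either partner, which are genuine
zeros of the algebra but not states of the system.  Stability comes from
eigenvalues of central-difference Jacobians (relative step `1e-6`).

**Continuation.**  `continue_branch()` is a native pseudo-arclength
continuation (secant predictor, Newton corrector on the
arclength-augmented system) — no external bifurcation tool is required.
Folds are flagged where the parameter direction reverses along the branch
and refined by a local role swap: the fastest-changing state component
becomes the continuation variable and the parameter's interior extremum is
located by Brent search (the saddle-node normal form is recovered to
better than `1e-6`).  Hopf points are flagged where the real part of a
complex-conjugate eigenvalue pair changes sign and refined by bisection on
the parameter.

**Hysteresis folds of pseudo-nullclines.**  `pseudo_nullcline()` removes
one state's ODE, treats that state as a parameter, and continues the
reduced system's steady states.  For reduced systems of dimension four and
above the curve can fold more than twice: the nested Gwl/ENSA/B55 switch
puts extra folds on interior stretches (the clamped-CycBT system of
Model 4 has up to seven coexisting states at intermediate clamp values).
The activation/inactivation thresholds reported are therefore the extreme
folds adjacent to *stable* segments — the boundaries of the observable
bistable window; interior folds remain in the curve data.  The shape
classification (`monotone`, `S-shaped`, `Z-shaped`, `complex`) follows the
count and orientation of those stability-adjacent folds.

**SNIC classification.**  A fold is declared a saddle-node on an invariant
circle when stable large-amplitude oscillations exist just beyond it, the
measured period grows monotonically as the fold is approached, and the
period closest to the fold exceeds five times the far-field period.  The
factor five is our operational criterion; probe offsets reach `1e-4` of
the parameter because the period divergence is slow on the scale of the
outermost probes.

**Two modelling subtleties worth knowing.**  First, `APCPC20 <= APCP` is
an admissibility condition for input states and steady states but not an
invariant of the flow: the B55-driven dephosphorylation term acts on all
of APC-P including the complexed fraction, so during rapid mitotic exit
the complex can transiently exceed the free phospho-pool.  Second, the
"minimal futile cycling" property of the dual-bistable engine is measured
here as an amplitude-normalised phase-overlap index,
\(\langle MPF \cdot B55 \rangle / (\langle MPF\rangle\langle B55\rangle)\):
1.11 for the feed-forward model, 0.67 for the dual-bistable model — the
kinase and its counteracting phosphatase are strictly out of phase only
when both switches are present.  The raw product average is not
comparable across models because their amplitudes differ severalfold.

# Parameter provenance and a transcription caveat

The fixtures transcribe the published reference table plus the
figure-level constants (`Km_tqssa`, `deUb`, `CAP`, the Michaelis constants
of Model 1).  The plain-text rendering of the table concatenates columns;
the transcription used here is the unique split consistent with every
model having values for exactly the parameters its equations use, and it
reproduces the published dynamical anchors directly: the 46-min period of
Model 1, oscillation of Models 2–4, the hysteresis thresholds near
CycBT = 1.2 and 0.5, and all three checkpoint arrests.

One family of published numbers does **not** reproduce under this
parameter set: in the size-clamped one-parameter diagram we find the SNIC
fold at \(V \approx 0.54\) and the Hopf at \(V \approx 0.010\) (published:
0.85 and 0.05), and the hybrid simulation consequently divides at
\(V \approx 0.64\) rather than 1.0.  The discrepancy is structural, not
numerical: the clamped-CycBT folds pin every Model-4 parameter except the
cyclin synthesis/degradation rates, and those force the interphase cyclin
plateau to \(k_{sy}/k_{de1} = 2.0\); with mitotic entry where
\(V \cdot CycB_T \approx 1.2\), the SNIC cannot sit near 0.85 unless the
plateau is ~1.4, which the published rates exclude.  The package reports
what the stated equations and parameters actually produce.  The
growth-law predictions that do not depend on this scale — interdivision
time equal to the mass doubling time \(\ln 2/\mu\) (~139 min at
\(\mu = 0.005\,\mathrm{min}^{-1}\)), size homeostasis from any starting
size, and SNIC-type period divergence at the fold — all reproduce.

# Problem sizes and defaults used in the shipped analyses

Limit-cycle runs integrate 4000 min at 0.1-min output resolution; arrest
classification uses a 6000-min horizon with a trailing-window derivative
test (`|rhs| < 1e-8`, drift `< 1e-6`).  Branch continuations use initial
arclength step 0.004 (cap 0.01; 0.006 for the size-clamped diagram).  The
hybrid lineage runs 10–12 divisions and discards the first five cycles for
asymptotic statistics.  These sizes give converged results — halving
tolerances or doubling horizons moves the headline numbers by far less
than their comparison bands.

# What the tests do and do not show

The suite checks the algebraic closures against independent oracles
(explicit chain steady states via dense linear algebra, polynomial root
finding), the right-hand sides against independent transcriptions at
random valid states, structural reductions (Model 3 → Model 2 when
`kdp2_gwl = 0`), conservation and invariants along trajectories,
cross-integrator agreement, normal-form bifurcation locations, and the
figure-level scenarios end-to-end.  All of this validates the
*implementation of the stated models*; none of it validates the models
against new experimental data, and the checkpoint variants deliberately
compress complex surveillance biochemistry into single parameter changes,
as the source models do.

# Known limitations

Unstable limit cycles (the subcritical branch emanating from the Hopf
point of the size-clamped diagram) are not traced: detection by forward
integration is impossible and collocation-based cycle continuation is out
of scope.  Two-parameter bifurcation diagrams, stochastic or delay
formulations, and the tristable interlinked-switch extension are likewise
out of scope.  The SAC is modelled purely as a reduction of available
Cdc20; mitotic checkpoint complex assembly kinetics are not represented.
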