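---
title: "Designing spatial bacterial logic: models and methods"
author: "macchiato"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing spatial bacterial logic: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macchiato)
```

## The computing paradigm

A spatial bacterial computer encodes a digital function in the geometry of a
plate. Each input is a source of one diffusible molecule (an inducer droplet
or a biosensing sender colony); each output is a receiver colony that converts
the local signal concentration into fluorescence through a threshold response
— highpass (ON above a threshold), lowpass (ON below), bandpass (ON between
two thresholds) or bandstop (its inverse). Because every input produces the
same molecule, overlapping gradients add, so the concentration a receiver
sees in input state $s$ is the subset sum

$$u(s) \;=\; \sum_{i\,:\,s_i = 1} c_i,$$

where $c_i \ge 0$ is the contribution of input $i$, set by its distance to
the receiver. Changing positions changes the order of the $2^n$ state
concentrations along a one-dimensional axis; the activation function cuts
that axis into ON and OFF intervals, and the cut pattern *is* the logic gate.

This package implements the whole design pipeline: truth tables and their
gate codes, exact enumeration of single-receiver-realizable functions,
minimal multi-receiver decomposition (the Macchiato algorithm), a
reaction-diffusion device simulator, and evolutionary placement optimization.

## Gate codes

A DC-free $n$-input table is identified by a hex code in which bit $p$ holds
the output of state $2^n-1-p$: the binary string of outputs is written with
state $00\ldots0$ first (most significant bit) down to $11\ldots1$. Under
this convention a bandpass receiver computing "A AND NOT C" is `0x0A`,
"B AND C" is `0x11`, and their OR — the 2-to-1 multiplexer with C as
selector — is `0x1B`:

```{r}
tt_or(list(tt_from_hex(0x0A, 3), tt_from_hex(0x11, 3)))
```

The convention is fixed by those worked gates. Beware that it is the
*reverse* of the Wolfram cellular-automaton rule numbering, in which the
all-ones neighborhood is the most significant bit; elementary CA rules must
be bit-reversed before use (Rule 30 is gate `0x78`, Rule 110 is `0x76`). We
flag this prominently because both conventions are common and silently
incompatible.

## Admissible orderings and realizability

Not every ordering of the $2^n$ subset sums is geometrically meaningful:
additivity forces $u(s) \le u(t)$ whenever $s \subseteq t$, and further
non-lattice constraints follow from the shared contribution values (for
example $a < b$ forces $a + c < b + c$). We characterize admissible strict
orderings by linear feasibility: an ordering is admissible iff some $c \ge 0$
separates consecutive sums by a unit gap. The system is homogeneous in $c$,
so "unit gap" is equivalent to strict feasibility at any scale, and the
verdict is independent of the margin used (scale freedom). Feasibility is
decided by a small quadratic program (the minimum-norm point of the
constraint polyhedron), which doubles as a witness generator: its solution is
a concrete contribution vector realizing the ordering. The search enumerates
linear extensions of the subset lattice with feasibility pruning; there are
2 admissible orderings for two inputs, 12 for three and 336 for four.

Given an ordering, each activation kind can realize exactly the output
patterns compatible with its shape and with strictly positive thresholds:
highpass ON-sets are proper suffixes, lowpass ON-sets non-empty prefixes
(zero concentration is always ON), bandpass ON-sets contiguous runs
excluding the minimum, bandstop their complements. Ties between state
concentrations are allowed in witnesses (symmetric placements) but never
needed: any table realizable with ties survives a generic perturbation, so
enumeration restricts to strict orders. Enumerating patterns over orderings
gives the exact realizable sets: all 16 two-input gates with
bandpass + bandstop, and 152 of the 256 three-input gates with the full kind
set. Because the activation set behind a reported
single-receiver count is not always stated, `realizable_kind_counts()` reports the count
for all 15 non-empty kind subsets; only the full set yields 152. A
`min_blocks()` view expresses the same theory in block language: a table is
single-receiver realizable with the full kind set iff it can be rearranged
to at most three blocks, with DC states free to join any block.

Degenerate placements are rejected rather than rounded: a receiver whose
state concentration falls within `margin` of a threshold (default $10^{-6}$
after normalizing the largest subset sum to 1) raises an error naming the
state, since its digital behavior would be undefined in practice.

## The Macchiato algorithm

Functions beyond the single-receiver set are built from several receivers
under an implicit OR: the device reads ON iff any receiver colony is ON,
which needs no second signaling molecule. A valid design must keep every
receiver OFF in every function-OFF state and cover each function-ON state
with at least one receiver; DC states are unconstrained. Minimization is a
set cover over the realizable candidate catalog restricted to candidates OFF
wherever the target is OFF. The exact solver is an iterative-deepening
depth-first search branching on the lowest uncovered state; the greedy
alternative picks maximal new coverage. Both use a deterministic candidate
order — fewer thresholds first (single-threshold hardware is simpler), then
smaller gate code — so results are reproducible; the exact solver returns
the first minimal cover in that lexicographic order rather than globally
minimizing a secondary threshold-count objective, which would require
enumerating all minimal covers. An `explicit_or_layer()` helper emits the
alternative two-level architecture (a highpass OR node reading a dedicated
channel produced by all first-layer receivers), purely structurally.

With the full kind set every three-input function needs at most two
receivers; dropping bandstop preserves feasibility, and dropping bandpass as
well leaves under half of the three-input functions buildable. For any
function OFF in the all-zero state, highpass + bandpass covers exist with at
most $n-1$ receivers at $n = 3,4$.

Two demonstrated builds deserve a note. Rule 30 and Rule 110 were demonstrated
with two colonies, yet with free thresholds both admit a single-bandpass
witness (for Rule 30, ON-set $\{001,010,011,100\}$: $c = (3, 1.5, 1)$, band
$(0.5, 3.5)$), so `macchiato_minimize()` reports 1. The gap is physical: a
real strain's thresholds are fixed, and the witness can demand band ratios
or off-lattice distances the hardware cannot deliver. The catalog therefore
records both numbers (`receivers_min`, `receivers_reported`), and
device-level validation uses the demonstrated decomposition where one is
recorded (`design_from_codes()`); under this package's stand-in strains the
Rule 30 witness happens to be buildable and validates in simulation, while
the Rule 110 witness does not — its two-colony build (`0x70` + `0x66`, the
latter being B XOR C) is used instead. The same reasoning applies to the
sender-input NAND, whose ON-set is a prefix and hence a single lowpass in
the abstract model, but which was demonstrated — and is validated here — as
two NOT colonies.

## Reaction-diffusion device model

The simulator solves $\partial_t u = D\nabla^2 u - \lambda u$ on a uniform
2-D grid with an explicit (FTCS) scheme, guarded by the stability bound
$\Delta t \le \Delta x^2/(4D)$ (80% of the bound by default). Droplets are
instantaneous Gaussian deposits of one-grid-cell width; senders inject at a
constant rate while induced. No-flux boundaries conserve mass to solver
tolerance; the linear PDE superposes exactly, which the implementation
exploits by simulating each input once and summing per state. Against the
free-space kernel $u(r,t) = Q\,e^{-r^2/4Dt}/4\pi D t$ the solver's RMSE is
well under 1% of the peak at the verification settings.

Colony biology is deliberately minimal, and its functional forms are
reconstructed stand-ins (no fitted equations for a real strain are bundled): logistic biomass growth after a lag, and
fluorescence accumulating proportionally to biomass times a Hill-type dose
response — activating Hill for highpass, repressing for lowpass, a product
of activating and repressing Hills for bandpass (an activator plus
high-threshold repressor circuit), and its inverse for bandstop. Receivers
*commit*: the experimental ring position is temporally static, so by default
a colony reads its local concentration once at `commit_time` (6 h) and holds
that expression state; a continuous-integration mode is available
(`colony_dynamics(mode = "integrate")`). Under commitment the 20 h fold
change reduces to the response ratio at the committed concentration, since
the biomass integral cancels.

Default physics follows the standard working conditions of such devices: a
35 × 35 mm domain (one 6-well well), 0.25 mm grid (0.5 mm for device-level
validation), $D = 1.4$ mm²/h (literature-order small-molecule mobility in
agar), droplets of 7.5 amount units (1 µL of 7.5 mM inducer), read-out at
20 h, placement on the 4.5 mm 384-well lattice. Dose-response parameters
were chosen by desk calculation so the response knees straddle the
concentrations reached at one-to-two lattice pitches around commit time
(e.g. highpass $K_{\mathrm{act}} = 0.015$, Hill 4; bandpass
$K_{\mathrm{act}} = 0.005$, $K_{\mathrm{rep}} = 0.04$, repression Hill 12).
They are stand-ins, not fits to any measured curve; all live in
`sim_defaults()`.

A receiver's digital verdict is ON when its expression exceeds
`decision_ratio` (1.5) times its basal level. For highpass and bandpass
strains this is exactly the fold-change rule (their no-input output is
basal); for lowpass and bandstop strains — maximally bright in the all-OFF
configuration, so fold change never exceeds 1 — the basal-normalized form is
the natural generalization. Gate scores stay in the conventional fold-change
currency: each output colony is scored against its own induced sub-function
(least fluorescent ON state over most fluorescent OFF state), and a
multi-colony device reports the worst colony score — one score per output
colony is the natural read-out of an implicit-OR device.

## Placement optimization

The physical step — turning a design's abstract contribution vectors into
droplet and colony coordinates — is a discrete search on the plate lattice,
run by a generational evolutionary algorithm: tournament selection (size 3),
uniform crossover over node positions, per-node 8-neighborhood lattice-step
mutation with an occasional node reset, elitism of 1, and
repair-by-rejection of moves violating bounds or minimum separation.
Droplets may sit on top of colonies (as in the robot protocol), so the
default minimum separation is 0. The outermost lattice ring is excluded by
default: fitness uses free-space kernels, which underestimate concentrations
near the no-flux wall.

Fitness evaluates the analytic kernels at commit time (droplet Gaussian; for
senders the time-integrated kernel $\frac{q}{4\pi D}E_1(r^2/4Dt)$), making
each evaluation microseconds instead of a full grid solve; the optimized
layout is then validated with the finite-difference model via
`predict_gate()`. The objective is the ON/OFF separation — smallest
function-ON output minus largest function-OFF output, in basal-normalized
expression units — plus three shaping terms chosen here (there is no canonical
choice): a per-colony sub-function separation bonus so
partially working multi-receiver layouts outrank dead ones, a soft penalty
for expression in function-OFF states with a 20% margin below the decision
ratio (keeping optima clear of the verdict boundary, where kernel and grid
models can disagree), and a dominant penalty per wrong verdict state so a
correct layout always outranks an incorrect one. A layout whose receivers
see no signal scores at most 0. Multi-receiver landscapes are needle-like;
`optimize_layout(restarts = k)` runs up to $k$ searches with
deterministically derived seeds and stops at the first correct, scoring
layout, keeping everything reproducible. `geometric_feasibility_report()`
afterwards compares each receiver's achieved contribution vector with its
axis-model witness and flags receivers whose digital behavior was
compromised by the shared-geometry constraint (moving an input relative to
one receiver moves it relative to all).

## Synthetic characterization and fitting

`generate_characterization()` emulates a dose-response characterization:
mean-preserving multiplicative log-normal noise around a chosen curve, with
replicates and an explicit seed. It reproduces measurement-scale scatter
only — no plate effects, no growth-fluorescence coupling, no spatial
artifacts — so passing recovery tests demonstrate estimator correctness, not
robustness to real assay pathologies. `fit_dose_response()` fits the curve
by Levenberg-Marquardt least squares on log-fluorescence with positivity
enforced by log-scale parameters, and reports a sign-runs diagnostic on
concentration-ordered mean residuals (residuals within half the residual
standard error are dropped as shape-free) that flags the systematic arc left
by fitting the wrong response kind. With the default noise (CV 0.1, three
replicates, eight concentrations) the activation midpoint is recovered
within 20% in well over 90% of seeded trials.

## Validation scale and limitations

The shipped tests enumerate exhaustively at up to three inputs (the regime
of the headline capability counts), sample 1000 random four-input tables for the
$n-1$ cover bound, validate the full demonstrated-gate catalog end to end on
a 0.5 mm grid with an 80 × 150 EA budget, and cross-check the enumeration
against a $10^5$-sample random-witness oracle. Known limitations: the axis
model ignores fixed strain thresholds (see the Rule 110 discussion above);
the simulator is 2-D, with no nutrient depletion, no colony expansion and no
signal degradation by default; sender induction is binary; and the EA is
single-objective with reconstructed hyperparameters. The decomposition
theory is exact; everything downstream of the stand-in biology is
qualitative by design.
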