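---
title: "Methods: cell-based tissue electrophysiology with sknm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-based tissue electrophysiology with sknm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`sknm` simulates small 2D collections of ventricular cardiomyocytes in which
every cell is resolved individually and coupled to its axial neighbours
through gap junctions — the simplified Kirchhoff network model (SKNM). The
purpose is the study of cellular heterogeneity: electrotonic homogenization
of action potentials, wavefront roughening under reduced coupling, and the
emergence of early afterdepolarizations (EADs) when heterogeneity meets weak
coupling.

For cell $k$ with neighbours $N_k$:

$$C_m \frac{dv_k}{dt} = \frac{\lambda}{(1+\lambda) A_m}
  \sum_{j \in N_k} G_{j,k}\,(v_j - v_k) \; - \; I_{ion}^k(v_k, s_k), \qquad
  \frac{ds_k}{dt} = F^k(s_k, v_k).$$

$I_{ion}$ is the total transmembrane current density in A/F (outward
positive); the stimulus is a negative (depolarizing) current added to it.
The coupling current $G_{j,k}(v_j - v_k)$ (mS·mV = µA) is divided by the
total cell capacitance $C_m A_m$ to appear in A/F alongside $I_{ion}$ —
this is the only unit-consistent reading of the model equation and the one
implemented.

## Geometry and electrical constants

Cells are cylinders, length $l = 100\,\mu m$, diameter $d = 20\,\mu m$,
packed in $l \times d \times d$ boxes (4-connectivity, no diagonals;
boundary cells simply have fewer neighbours, giving no-flux boundaries by
construction). Constants: $C_m = 1\,\mu F/cm^2$; membrane area
$A_m = 2\pi l d$ (the factor 2 accounts for membrane folding);
intracellular volume fraction $\delta_i = \pi/4$ (the cylinder volume over
its bounding box); conductivities $\sigma_i = 4$, $\sigma_e = 20$ mS/cm.
Per connection, the intercellular conductance is the series combination

$$G_{j,k} = \left( \frac{L_{j,k}}{\delta_i A_{j,k} \sigma_i} +
  \frac{1}{G_g^{j,k}} \right)^{-1},$$

with $L = l$, $A = d^2$ in the x-direction and $L = d$, $A = l\,d$ in the
y-direction (the box-packing consistent with $\delta_i$; the y-direction
areas are a design choice — only the x-direction values are fixed by the
definition of $\lambda$). A closed junction ($G_g = 0$) disconnects the
pair. Extracellular space enters only through the scalar
$\lambda = G_{e,x} / G_{i,x}(G_g^*)$ computed **once** per simulation from
the average coupling $G_g^*$ and x-direction geometry,
$G_{e,x} = (1-\delta_i)\,d^2 \sigma_e / l$. Note that $\lambda$ *decreases*
as $G_g^*$ grows (the gap junctions, not the extracellular path, are the
bottleneck at weak coupling) and approaches
$(1-\delta_i)\sigma_e/(\delta_i \sigma_i) \approx 1.37$ for perfectly open
junctions; at 600 nS, $\lambda = 4.23$ and the coupling prefactor
$\lambda/(1+\lambda) = 0.81$.

## The hybrid membrane model

The ionic model is the endocardial O'Hara–Rudy formulation with the fast
sodium current replaced by the ten Tusscher INa ($m^3 h j$ gating), whose
maximal conductance is **doubled**; the late sodium current and the rest of
the O'Hara–Rudy machinery (CaMK phosphorylation pathways, two-compartment
calcium handling, buffers) are retained unchanged. Design readings where
the sources leave room:

- the swap replaces only fast INa and its three gates (the CaMK-
  phosphorylated fast-INa gates disappear with it); INaL keeps the original
  activation time constant;
- the endocardial subtype is the default and the only one built in
  (`build_ord_hybrid(subtype = "endo")` reserves the argument);
- the 20 scalable parameters are `gNa, gNaL, pNaK, pNab, gKr, gKs, gto,
  gK1, gKb, pCaL, gNaCa, gpCa, pbCa, Jrel, Jup, BmaxSL, BmaxSR, BmaxCMDN,
  BmaxCSQN, BmaxTRPN`. `Jup` is the SERCA base rate (0.004375 mM/ms);
  `Jrel` is a unitless multiplier (default 1) on the SR-release amplitude,
  because the source model has no single published maximal release-rate
  constant — scaling the amplitude rather than the release time constant is
  the reading that varies "maximum flux" without altering kinetics.
- parameter modifications compose multiplicatively on the defaults in the
  order: cell-type perturbation → pharmacological block → random scaling.
  `make_perturbed_type()` is deliberately not idempotent.
- the stimulus is $-80$ A/F for 1 ms (the source model's own amplitude),
  booked on potassium to avoid slow ionic drift over hundreds of beats. A
  $-53$ A/F, 1 ms stimulus — a common single-cell convention — *fails* to
  excite a stimulated column against the electrotonic load at 600 nS, which
  is why the stronger default was chosen. It is configurable and recorded
  in every trace's metadata.
- the constant perturbation currents of variation case 6 enter the membrane
  equation only; they are abstract currents not attributed to any ion.

# Numerics

The coupled system (38 states × cells) is integrated monolithically by an
adaptive-step Rush–Larsen / forward-Euler scheme implemented in C++:
all 28 relaxation-form states are updated exactly against their momentary
steady state and time constant, $x \leftarrow x_\infty + (x - x_\infty)
e^{-\Delta t/\tau}$; the membrane potential, concentrations and CaMK trap
advance by forward Euler. The global step is chosen each iteration from

- the fastest membrane-potential motion (default $|\Delta v| \le 0.2$ mV),
- the relative motion of the fast calcium compartments (subspace and
  junctional SR, $\le 5\%$),
- the explicit stability bound of the coupling operator
  ($\Delta t \le 0.8 / \max_k \sum_j w_{j,k}$),
- bounds $[10^{-3}, 0.5]$ ms, and alignment to stimulus edges and sample
  times (0.5 ms recording default; all biomarker crossings are linearly
  interpolated, so finer sampling is unnecessary).

An implicit multistep (ode15s-class) integrator would be the conventional
alternative; none is available as a dependency here, and the scheme above
is the standard in large tissue electrophysiology codes. Correctness is
covered by (i) a *dual implementation*: the entire ionic model exists twice,
as readable R and as compiled C++, and the test suite asserts agreement of
all derivatives to ~1e-15 at randomized states; (ii) *step-refinement
convergence*: halving all step controls changes single-cell APD50 by
< 0.5 ms and leaves the conduction velocity unchanged to three significant
digits; (iii) *structural equivalences*: a 1×1 collection equals the
single-cell path bitwise, closed junctions reproduce independent cells, and
checkpointed runs match direct runs.

Pre-pacing: the study protocol conditions collections with 200 beats before
recording. Tissue runs at desk scale use the `prepace_mode = "isolated"`
shortcut — every cell is conditioned *uncoupled* (one compiled call, all
cells stimulated), then a few coupled beats precede recording. This is
accurate for biomarkers that converge quickly, but **the single-cell EAD
block threshold is a near-limit-cycle property**: with 40-beat conditioning
the apparent threshold is 61% IKr block, with the full 200 beats it
converges to 59%. The acceptance suite therefore uses full conditioning for
the threshold scan (cheap for a single cell) and reduced conditioning
elsewhere, as permitted.

# Synthetic heterogeneity (the generator's stated world)

All draws are uniform on closed intervals, the conventional reading of
"drawn randomly from the interval". A master seed derives fixed substreams
for parameter scalings, perturbation currents, gap variation and layout, so
enabling one map never shifts another's draws (controlled ablations across
the six variation cases). Defaults fixed by the stated world: two-type
random mixing fraction 0.5; gap variation half-widths {0, 0.25, 0.5};
cell-variation degrees r up to 0.5 ("50% variation"); conductance menus
{600, 60, 6, 4, 2} nS; grids 15×5, 15×20, 25×25. Variation maps are drawn
once per experiment bundle and held fixed across a conductance sweep, so
coupling is the only changing factor (the alternative — redrawing per
conductance — is not what a controlled comparison wants). Maps serialize to
JSON alongside results for exact replay.

What the generator does *not* emulate: spatially correlated heterogeneity
fields, fibrosis geometry, non-uniform distributions, 3D stacks,
fibroblasts. A green test therefore establishes behaviour under idealized,
independently-drawn heterogeneity on small rectangular sheets — not under
realistic pathological architecture.

# Biomarkers and the EAD criterion

- **APD50**: from the time of maximum upstroke velocity (finite differences
  on the recorded grid, earliest sample within float noise of the maximal
  slope) to the **final** interpolated downward crossing of
  $(v_{max}+v_{min})/2$ after the AP peak, both taken within the beat
  window delimited by stimulus times. Cells with max $dv/dt$ below the
  excitation floor (5 mV/ms) or without a crossing are flagged `NA`, never
  silently zero.
- **ToA**: first upward (depolarization) or last downward (repolarization)
  interpolated crossing of −30 mV within the beat; the last-crossing rule
  makes the repolarization arrival of EAD-bearing cells the *final*
  repolarization, matching wave-arrival semantics.
- **CV**: column distance × cell length over the mean ToA difference,
  default columns at 25% and 75% of the x-extent (clear of stimulus and
  boundary artifacts).
- **CaA**: max − min cytosolic calcium within the beat (a max − diastolic
  variant is available by flag).
- **EADs**: the sources give no formal criterion, so the detector is this
  package's definition: after the AP peak, an upturn of $dv/dt$ from
  non-positive to positive at a potential inside (−60, 0) mV followed by a
  rise of ≥ 2 mV before the next downturn counts as one EAD. The rebound
  threshold is configurable; the test suite documents sensitivity over
  1–5 mV, and the acceptance results (absence at ≤ 58% block, presence at
  59%) are insensitive in that range because the observed EADs rebound by
  tens of millivolts.

# Reproduction results and known limitations

Computed by the acceptance suite and `scripts/acceptance.R` (never stated
beyond what those compute):

- **Minimal propagating coupling** — a 15×5 homogeneous sheet under the EAD
  protocol (53% IKr block, 4× pCaL, 0.25 Hz) carries a first-column wave to
  every cell at 600, 60, 6, 4 and 2 nS and fails at 1 nS: the published
  threshold of 2 nS reproduces exactly.
- **EAD block threshold** — scanning IKr block upward in 1% steps at
  0.25 Hz with 4× pCaL and full conditioning: no EADs through 58%, EADs
  from 59% on; the published 59% reproduces exactly.
- **Homogenization** — in a random two-type mix at 600 nS the within-column
  APD50 range is < 1 ms (cells of opposite type at the same wavefront
  position are indistinguishable), while disconnected cells revert to their
  isolated dynamics; dispersion of both wavefronts at 4 nS strictly exceeds
  that at 600 nS under parameter and combined variation; homogeneous sheets
  never show EADs at any considered coupling, and heterogeneous (r = 0.5)
  sheets at 2 nS do.
- **Conduction velocity (known limitation)** — the calibration target for
  the hybrid model is ≈50 cm/s at 600 nS. The printed network constants and
  equations, implemented literally, give a converged 37.5 cm/s (insensitive
  to step refinement, stimulus strength and conditioning length; raising
  gNa further saturates near 44 cm/s, so the coupling operator — fully
  determined by the stated constants — is the limit). Doubling the coupling
  weight (equivalent to normalizing by the geometric area $\pi l d$ instead
  of the folded area $2\pi l d$) would land at ~53 cm/s but destroys the
  2 nS propagation-threshold agreement above, which pins the coupling
  operator as implemented. We therefore report the honest value and flag
  the CV target as not attainable from the stated equations alone.
- The perturbed two-type phenotype (no IKr, 75% reduced gK1, doubled gCaL)
  does **not** repolarize as an isolated hybrid cell — it settles near
  −19 mV. The two-cell-type experiments were designed around a different
  (base) ventricular model that is out of scope here and only reachable
  through the external-model adapter; with the hybrid model the
  homogenization result still holds (coupled mixes produce a common,
  intermediate action potential), but isolated-cell APD comparisons for
  the perturbed type are degenerate and are asserted as such.
- The external-model adapter (`register_external_model()`) accepts any
  model satisfying the contract (state template with `v`, finite rates at
  the initial state); such models integrate through a generic R-level path,
  orders of magnitude slower than the built-in compiled model — adequate
  for toy models and validation, not for 25×25 sweeps.
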