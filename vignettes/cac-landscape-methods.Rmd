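---
title: "Quasi-potential landscapes and transition paths for the cancer-adipose conversion circuit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAC landscape methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(caclandscape)
```

## The model

Each gene or microRNA $X$ in the circuit follows a single-layer kinetic
equation

$$\frac{dX}{dt} = g_X\,G - k_X\,K\,X,$$

where $g_X$ and $k_X$ are basal synthesis and degradation rates and $G$,
$K$ are products of *shifted Hill* factors over the regulations entering
the synthesis or the degradation side of $X$:

$$H_s(Y; S, \lambda, n) = 1 + (\lambda-1)\frac{Y^n}{S^n + Y^n}.$$

The factor is 1 with no regulator and saturates at the fold change
$\lambda$; $\lambda > 1$ is activation, $\lambda < 1$ inhibition, and $n$
sets the steepness.  Drugs (TGF-β, a MEK inhibitor, rosiglitazone) are
clamped input nodes: they regulate their targets but have zero dynamics,
so dose scans are parameter sweeps.  All regulations in the packaged
network act on the synthesis side except MDM2's promotion of P53
degradation, which enters $K$.

Concentrations and time are dimensionless, with basal levels of order 1
(`g/k` ≈ 0.3–1.5) and degradation rates of 1; the TGF-β axis spans 0–10
so that the interesting fold structure sits at levels 3–8.

## The packaged CAC network

`cac_network()` loads the cancer–adipose conversion circuit: the
p53/MDM2 hub with the p53-induced microRNAs (miR-34, miR-145, miR-200),
the EMT transcription factors SNAIL1 and ZEB1 with their mutual
microRNA antagonism and ZEB1 self-activation, the metastasis module
(LIN28/let-7, BACH1, RKIP), the MAPK cascade (MEK/ERK, with ERK
self-activation and self-inhibition at different thresholds), and the
adipogenic switch (PPARγ/C/EBPα positive feedback, opened by
rosiglitazone and gated by the EMT state).  The wiring follows the
published circuit; the kinetic parameters are a **synthetic
reconstruction**: the original per-edge values are not restated in the
main text, so the packaged values were calibrated (see
`inst/extdata/cac_network.yml`, and the `meta` block therein) so that
the reported attractor structure reproduces:

* no drugs → monostable epithelial (E) state;
* moderate TGF-β → E/M bistability; high TGF-β → monostable M;
* TGF-β + MEKi → three states (E, M and the partial-EMT state P1);
* TGF-β + MEKi + rosiglitazone → five states (E, M, P1, P2, A)
  separated by unstable saddles;
* 500× ZEB1-activation + rosiglitazone from the no-drug baseline →
  monostable adipose (A) state, while the same dose of
  SNAIL1-activation + rosiglitazone yields monostable M with no A state
  (SNAIL1 represses RKIP and so keeps MEK/ERK active, which blocks
  PPARγ).

The mechanism behind the five-state structure in this parameterization:
the ZEB1/miR-200/miR-145 axis is tristable under MEK inhibition (the
mid-ZEB1 branch is held by miR-145, whose brake releases only at high
ZEB1), and the PPARγ/C/EBPα loop is bistable wherever its C/EBPα gate is
open — ZEB1 above ≈0.5 opens it, miR-200 (high in E) and SNAIL1 (high in
M at high TGF-β) close it.  A is the partial-EMT state with the loop on;
P2 is the mesenchymal-context state with the loop on at a lower PPARγ
level.  Two calibration caveats are documented honestly rather than
hidden: the interior TGF-β thresholds at which P2/A/P1 appear differ by
up to ≈0.9 from the reported values (the terminal thresholds ≈3.2 and
≈7.3–7.5 reproduce closely, as does the 1→2→3→4→5→4→3→2→1 fold
cascade), and MDM2 activation alone does not trigger EMT in this
reconstruction, so the MDM2-based drug combination is not reproduced.

Phenotype labels are assigned by fixed marker thresholds
(`cac_marker_rules()`), in priority order: A (PPARγ above 2.5), P2
(PPARγ above 1.7, the adipogenic program engaged), M (ZEB1 above 2.5),
P1 (ZEB1 above 0.35), E (P53 above 0.55).  Absolute thresholds — fixed
once at calibration — are used instead of z-scores across the attractor
set because monostable sets (the point of the drug interventions) leave
nothing to z-score against.

## Attractor search and bifurcation scans

`find_attractors()` draws Latin-hypercube starts over
$[0, 2\,g_X/k_X \cdot \min(\prod \lambda^+, 10)]$ per coordinate,
integrates each forward (batched fixed-step RK4 — only the basin
endpoint matters, so a moderate step plus Newton polishing is accurate
and cheap), polishes with a damped Newton iteration using the analytic
Jacobian, and merges duplicates at a relative $L_\infty$ tolerance of
$10^{-3}$ (the point with the smaller residual is kept).  Stability is
read off the eigenvalues of the Jacobian restricted to the dynamic
coordinates.  Saddles are additionally sought from midpoints between
stable states.  `bifurcation_scan()` continues branches across a
parameter grid by warm-starting each grid point with the previous
attractors plus fresh Latin-hypercube starts; folds are reported as
midpoints of the grid cells where the stable count changes, so a step of
0.05 brackets thresholds quoted to one decimal place.

## Mean-field landscape

With isotropic noise of diffusion coefficient $D$, the stationary
density near a stable attractor is approximated by a Gaussian whose mean
is the attractor and whose variance solves the moment equation
$\dot\sigma = \sigma A^T + A\sigma + 2D$ with $A$ the Jacobian.  Under
the mean-field (product) truncation only the diagonal is retained, so
$\sigma_i = -D/A_{ii}$, solved algebraically; for a linear system
$F = -kx$ this is the exact Ornstein–Uhlenbeck variance $D/k$.  The
truncation requires $A_{ii} < 0$, true at every attractor of the
packaged networks (degradation dominates the diagonal), and ignores
cross-correlations — on the toggle switch the diagonal variances agree
with Langevin marginals to within ~10% at $D = 0.01$ because each
node's regulator sits in a saturated (flat) region of its Hill curve at
an attractor.

The steady-state probability is the weighted mixture over attractors of
the product-form Gaussians, and $U = -\ln P_{ss}$.  Mixture weights are
a modelling choice the formalism leaves open; the package defaults to
equal weights and offers long-run basin occupancy estimated by the
Langevin simulator (`weights = "occupancy"`), which makes
occupancy-based statements self-consistent.  $D$ defaults to 0.01
relative to the order-1 expression scale — small enough that basins are
well separated, large enough that Langevin ensembles equilibrate within
affordable horizons; it is exposed everywhere as a parameter.
Projections onto a gene pair are exact 2-D marginals of the mixture
(the product form makes marginals analytic); principal-component
projections sample the mixture, project onto the fitted (or supplied)
basis, and smooth with a 2-D kernel density estimate.  On a 200×200
grid the quadrature of $e^{-U}$ is unity to within 1%.

## Langevin oracle

`simulate_langevin()` integrates $dx = F(x)\,dt + \sqrt{2D\,dt}\,\eta$
by Euler–Maruyama with reflection at zero for concentration variables
(toy potentials on the whole line are not reflected).  Defaults: step
0.01 (halving it changes summary statistics by well under 2%), the first
20% of the horizon discarded as burn-in, every 10th step stored.
Occupancies assign post-burn-in samples to the nearest attractor in
z-scored coordinates, with an optional transient cutoff.  All
randomness derives from a single integer seed; identical seeds give
bit-identical ensembles.

## Transition paths

The most probable noise-driven route between attractors minimizes the
Freidlin–Wentzell action
$S_T[\varphi] = \tfrac12\int_0^T |\dot\varphi - F(\varphi)|^2\,dt$.
The path is discretized at $N$ uniform segments with the velocity as a
forward difference and the drift at segment midpoints; the action
gradient with respect to interior points is analytic (it needs only the
Jacobian at the midpoints), and the endpoint-pinned path is optimized by
L-BFGS-B from a straight-line initialization (optionally routed through
an intermediate attractor).  Because transitions prefer long traversal
times while the functional fixes $T$, a geometric sweep
$T \in \{5, 10, 20, 40, 80\}$ is run warm-started, stopping when the
action stops improving by more than $10^{-4}$ relative; the minimizing
horizon is kept and reported.  On 1-D gradient systems the minimized
action reproduces the identity $S = 2\,\Delta V$ to within 2% at
$N = 200$, and doubling $N$ changes the action by under 0.5%.

## Landscape control

The control objective sums forward-minus-reverse transition actions
toward the adipose state over the tumor-associated source states
(E, M, P1, P2); minimizing it deepens the A basin.  A source state that
disappears during optimization contributes zero — losing tumor states is
the desired outcome and must not penalize the objective — while a
vanishing target state invalidates the iterate (a large penalty keeps
the search away).  The search space over a network is every kinetic
parameter (synthesis and degradation rates, thresholds, fold changes,
Hill exponents, drug doses; 189 for the packaged CAC network), bounded
multiplicatively at 10× by default, Hill exponents rounded to integers
in 1–6 and flagged non-druggable along with fold changes.  The
optimizer is quasi-Newton with box constraints (Brent line search for a
single parameter), restarted seven times from perturbed initial values;
per-parameter sensitivities $(p_{opt}-p_{base})/p_{base}$ are averaged
across restarts and ranked by magnitude.  Exact per-iterate
recomputation of the actions is used — no surrogate — which is why the
shipped problem sizes keep the per-iterate action meshes modest
($N = 40$–80, horizons to 40).

## Synthetic expression data

`generate_expression()` emulates cluster-structured bulk expression
over the model's cell states: each sample is a state's attractor mean
under multiplicative log-normal noise (`exp(log(mean) + N(0, sd²))`),
the bulk-RNA-seq-like dispersion model.  Zero noise embeds the states
exactly; all generators are seed-deterministic.  Model–data comparison
z-scores both sides per gene (the normalization choice is a documented
convention, not derivable from the comparison figures it emulates) and
reports per-gene absolute differences and state-to-centroid Pearson
correlations, with an explicit gene-name map bridging model node names
and data symbols.  What passing these checks shows is internal
consistency of the pipeline on data generated under its own noise
model; real bulk RNA-seq adds library-size effects, gene-length bias
and non-log-normal dispersion that the generator deliberately omits.
One consequence worth knowing: clustering samples generated from the
five CAC attractors themselves is *not* guaranteed to recover labels
perfectly at moderate noise, because some state pairs (M vs P2 in
particular) differ in only the two adipogenic markers out of fifteen
genes; the clustering guarantees in the tests therefore use
fully-separable synthetic states, and the CAC-state version is checked
qualitatively.

## Problem sizes and numerical defaults

The shipped tests and the acceptance script use: 100–150 multi-starts
per attractor search (the five-state census is stable from ~60 starts
on), bifurcation scans at step 0.05 with 25 fresh starts per grid point
and branch continuation, Langevin ensembles of 100–500 trajectories at
dt = 0.005–0.01, action meshes of 80–200 points, and 7 control
restarts with a budget of 25 iterations each.  These sizes were chosen
so the full census of a condition completes in tens of seconds on a
single core while leaving the reported quantities stable to well within
the tolerances asserted in the tests.

## Known limitations

* The kinetic parameters are a calibrated reconstruction, not the
  original table; quantities tied to exact parameter values (interior
  bifurcation thresholds, the MDM2 intervention, control sensitivity
  rankings on the full network) should be read qualitatively.
* The mean-field landscape ignores covariance between genes and assumes
  small, constant, isotropic noise.
* Transition actions are used as relative propensities; no rate
  prefactors are computed.
* The optional TGF-β autoregulation variant is exposed as a config flag
  (`cac_network(tgfb_autoregulation = TRUE)`) and modeled as a
  SNAIL1-mediated amplification because drug nodes are clamped; it is
  off by default and untested against reported behavior.
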