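# caclandscape

Quasi-potential landscapes, minimum-action transition paths and
landscape control for the **cancer–adipose conversion (CAC)** gene
regulatory network.

Tumor cells can be coaxed into becoming post-mitotic adipocytes by
driving them through a partial epithelial–mesenchymal transition (EMT)
and then engaging the adipogenic program — a therapy concept that
trades killing cancer cells for converting them. This package models
that conversion as noise-driven transitions between attractors of a
regulatory circuit, and asks which drug combinations reshape the
landscape so that the adipose state wins.

## The model

Every gene or microRNA `X` follows

    dX/dt = g_X · G − k_X · K · X

with `G`, `K` products of shifted Hill factors
`H_s(Y; S, λ, n) = 1 + (λ−1) Yⁿ/(Sⁿ + Yⁿ)` over the incoming
regulations (λ>1 activation, λ<1 inhibition). Three drugs — TGF-β, a
MEK inhibitor (MEKi), rosiglitazone (Rosi) — are clamped input nodes.
On top of the deterministic circuit the package provides:

* **Attractors & bifurcations** — multi-start fixed-point census with
  analytic Jacobians, stability spectra, phenotype labels
  (E / M / A / P1 / P2), and one-parameter fold continuation.
* **Mean-field landscapes** — self-consistent Gaussian moments per
  attractor (diagonal variance `σ_i = −D/A_ii`), mixture steady-state
  density, quasi-potential `U = −ln P_ss`, exact 2-D marginals and
  PCA projections.
* **Transition paths** — Freidlin–Wentzell action
  `S_T = ½∫|φ̇ − F(φ)|² dt` minimized over endpoint-pinned discretized
  paths (analytic gradient, L-BFGS-B, traversal-time sweep).
* **Landscape control** — minimize
  `ΔS_A = Σ_s (S_{s→A} − S_{A→s})` over the 189 kinetic parameters to
  find drug targets that maximize adipose-state occupancy, with
  multi-restart sensitivity ranking.
* **Langevin oracle** — Euler–Maruyama simulation with reflecting
  boundaries, basin occupancy estimates, and every stochastic method
  cross-checked against it in the tests.
* **Synthetic data** — cluster-structured expression matrices generated
  from model attractors under log-normal noise, plus model-vs-data
  comparison utilities.

The packaged CAC circuit (`inst/extdata/cac_network.yml`) is a
**synthetic reconstruction**: the wiring follows the published diagram
(p53/MDM2, miR-34/145/200, SNAIL1/ZEB1, LIN28/let-7/BACH1/RKIP,
MEK/ERK, PPARγ/C-EBPα, three drug inputs) and the kinetic parameters
were calibrated to reproduce the reported attractor structure; see the
methods vignette (`vignettes/cac-landscape-methods.Rmd`) for what does
and does not reproduce.

## Worked example

```r
library(caclandscape)

## the five-state condition: TGF-beta 4.3, MEKi 0.02, Rosi 1.5
as <- cac_attractors("full", n_starts = 150, seed = 1)
print(as)
#> <attractor_set> 9 fixed points (5 stable)
#>   ...  SNAIL1   ZEB1    ERK  PPARG  CEBPA stable label
#> 1      2.012   3.769  0.702  0.454  0.555   TRUE     M
#> 2      2.008   3.759  0.702  2.116  1.765   TRUE    P2
#> 3      1.557   0.750  0.684  0.825  0.505   TRUE    P1
#> 4      1.498   0.683  0.682  4.572  1.917   TRUE     A
#> 5      1.080   0.067  0.666  1.075  0.112   TRUE     E
#> ... (plus the unstable saddles between them)
```

Five stable cell states coexist — epithelial (E), mesenchymal (M), two
partial-EMT intermediates (P1, P2) and the adipose state (A, by far the
highest PPARγ/C-EBPα) — separated by unstable saddles, matching the
reported five-attractor landscape. From here:

```r
net <- set_drugs(cac_network(), 4.3, 0.02, 1.5)

## quasi-potential projected on the (miR145, PPARG) plane
ls <- build_landscape(net, as, D = 0.01)
proj <- project_landscape(ls, c("miR145", "PPARG"))
nrow(local_minima(proj))          # one basin per stable state

## most probable E -> A route and its pseudotime profiles
map <- minimize_action(net, attractor_by_label(as, "E"),
                       attractor_by_label(as, "A"), N = 100)
head(pseudotime_profiles(map, c("ZEB1", "miR145", "PPARG")))

## predicted drug combination: 500x ZEB1 activation + rosiglitazone
zeb <- apply_intervention(cac_network(), c("g:ZEB1" = 500, "input:ROSI" = 500))
cac <- classify_phenotype(find_attractors(zeb, n_starts = 100, seed = 1),
                          cac_rules())
cac$labels[cac$stable]
#> [1] "A"        # monostable adipose state: conversion complete
```

The same 500× dose of a SNAIL1 activator plus rosiglitazone instead
drives every cell to the mesenchymal state (`"M"`), with no adipose
attractor — SNAIL1 represses RKIP, keeping MEK/ERK active, which blocks
PPARγ.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/caclandscape.R", package="caclandscape"))')" \
  --stages attractors,landscape --tgfb 4.3 --meki 0.02 --rosi 1.5 --out results/
```

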