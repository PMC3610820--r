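# dynppi — dynamic circadian protein–protein interaction networks

Most regulatory protein–protein interactions (PPIs) are transient, and for
clock-controlled genes the window of opportunity recurs daily. `dynppi`
predicts *when* the interactions in a static PPI network are formed across
the circadian day, using circadian expression profiles as a proxy for
protein abundance, and analyzes the temporal organization of the resulting
dynamic network. It is aimed at chronobiologists and systems biologists
with (i) a gene × timepoint expression matrix sampled over ≥ 2 circadian
cycles, (ii) an interaction edge list (PSI-MI TAB 2.5, TSV, or SIF), and
optionally (iii) a gene→category annotation and (iv) plate-reader
bioluminescence traces from perturbation screens.

## The statistics at the core

**Rhythmicity.** A standardized profile $x$ (mean 0, sd 1) is scored at
period $T = 24$ h by the Fourier score

$$F = \sqrt{\Big(\sum_i x_i \cos\tfrac{2\pi t_i}{T}\Big)^2 +
            \Big(\sum_i x_i \sin\tfrac{2\pi t_i}{T}\Big)^2},$$

the magnitude of the 24-h frequency component. Significance comes from
permuted time series, $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(B+1)$, with a
background pooled across genes so empirical FDR thresholds down to
$10^{-5}$ are attainable; peak phase is the shift of a 24-h cosine
maximizing overlap with the profile.

**Dynamic interactions.** The abundance of the complex formed by $P_1$ and
$P_2$ is approximated by the product of their raw expression profiles,
$A_C(t) = E_{P_1}(t)\,E_{P_2}(t)$; the product is standardized and scored
exactly like a gene. Edges passing the FDR threshold are *dynamic* and
carry an interaction phase (for baseline-matched partners, the circular
midpoint of the two peak phases).

**Network analyses.** Topology (shortest paths, clustering, topological
coefficients, power-law fit) against degree-preserving double-edge-swap
null models; Pearson co-expression enrichment of interacting pairs
(PCC > 0.5) versus random pairs; party/date hub classification against
random partner sets; and a category-pair "process network" judged against
label-permutation null networks (10-of-1000 display rule).

**Phenotyping.** Reporter traces are detrended (24-h running mean) and fit
with $A e^{-\lambda t}\cos(2\pi(t-\varphi)/\tau)$; traces with fit
correlation $r < 0.8$ are arrhythmic. Period deviations and flags combine
into an ordinal phenotypic score per gene, compared between proteins with
many (≥ 5) versus few dynamic interactions.

Simulators for all four input classes (`simulate_expression`,
`simulate_network`, `simulate_reporter`, `simulate_annotation`) make every
stage testable end-to-end with known ground truth.

## Worked example

```r
library(dynppi)

sim  <- simulate_expression(n_genes = 300, frac_rhythmic = 0.3, seed = 11)
net  <- simulate_network(sim$truth, n_nodes = 200, attachment_edges = 3,
                         planted_dynamic_edges = 25, seed = 12)

scan <- detect_rhythms(sim$expr, B = 200, seed = 13)
scan
#> Rhythmicity scan (period 24 h, B = 200, pooled background)
#>   profiles:  300 (0 untestable)
#>   rhythmic:  94 at q < 0.05
```

94 of 300 genes are called rhythmic at q < 0.05 — the 90 planted rhythmic
genes plus a few borderline noise genes, consistent with the nominal FDR.

```r
dyn <- call_dynamic_edges(net$edges, sim$expr, fdr_threshold = 0.05,
                          B = 200, seed = 14)
dyn
#> Dynamic interaction calls (FDR < 0.05, B = 200)
#>              input duplicates_dropped             tested           unmapped
#>                619                  0                619                  0
#>       non_testable            dynamic
#>                  0                345

head(dyn$edges[dyn$edges$dynamic, c("idA", "idB", "score", "q", "phase")], 3)
#>     idA   idB    score q phase
#> 1 g0247 g0174 31.21547 0   6.5
#> 3 g0247 g0034 30.62876 0  10.3
#> 4 g0247 g0136 30.53830 0   6.7
```

345 of 619 edges are predicted to form rhythmically (any edge touching a
rhythmic gene has a rhythmic product profile, so this exceeds the 25
planted edges by design); each carries the circadian phase (h) at which
the complex is predicted to peak.

```r
head(sort(dynamic_degree(dyn), decreasing = TRUE), 5)
#> g0136 g0034 g0174 g0091 g0204
#>    33    32    26    22    14

topology_summary(net$graph)
#> Network topology: 200 nodes, 619 edges (1 component(s))
#>   mean shortest path : 2.87 links (largest component, 200 nodes)
#>   mean degree        : 6.19 partners/node
#>   clustering coeff.  : 0.098 (mean local)
#>   power-law slope    : -1.75 (log count vs log degree)
```

A small-world, scale-free graph: any two proteins are ~3 links apart and
the degree-frequency slope is steeper than −1. Finally, a perturbation
trace:

```r
tr  <- simulate_reporter(period_h = 25.2, amplitude = 800,
                         damping_rate = 0.012, noise_sd = 80, seed = 15)
fit <- fit_damped_cosine(detrend(tr$counts, tr$time_h), tr$time_h)
fit
#> Damped cosine fit
#>   period    : 25.00 h (window 18-32)
#>   amplitude : 794.8 counts
#>   damping   : 0.0130 / h
#>   phase     : 0.21 h
#>   fit r     : 0.958 -> rhythmic (threshold 0.80)
```

The fitted period is ~0.2 h short of the simulated 25.2 h: the 24-h
detrending window slightly attenuates and shifts oscillations whose period
differs from 24 h — visible here because the truth is known.

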