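---
title: "Predicting time-of-day specific protein interactions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting time-of-day specific protein interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynppi)
```

## The problem

Most regulatory protein–protein interactions (PPIs) are transient: they
happen when both partners are present, which for clock-controlled genes
means at particular times of day. Given (i) a static PPI network and (ii)
circadian expression profiles (hourly sampling over 48 h, i.e. two full
cycles), `dynppi` predicts **which** interactions are rhythmically formed
and **when**, then asks what that temporal structure implies for network
organization: are interacting proteins co-expressed in time, which hubs
meet all their partners at once ("party hubs") versus one at a time ("date
hubs"), and which cellular processes are coupled through rhythmic
interactions. A separate branch quantifies circadian phenotypes of genetic
perturbations from bioluminescence reporter traces.

Transcript profiles stand in for protein abundance throughout. That proxy
is the method's central assumption and its main limitation: spatial
restriction, posttranslational control, stoichiometry, and binding kinetics
are all invisible to it, so every "dynamic" call is a prediction, not an
observation.

## Rhythmicity: Fourier score with a permutation null

A profile $x$ (length $N \ge 8$) is standardized to mean 0 and sd 1
(population convention, divide by $N$) and scored at test period $T$
(24 h):

$$F = \sqrt{\Big(\sum_i x_i \cos \tfrac{2\pi t_i}{T}\Big)^2 +
            \Big(\sum_i x_i \sin \tfrac{2\pi t_i}{T}\Big)^2}$$

i.e. the magnitude of the $T$-periodic frequency component. We use the
unnormalized sum; any fixed $1/N$ convention cancels in the permutation
test because observed and permuted profiles share it. Significance comes
from randomly permuting the time order: $p = (1 + \#\{F_{perm} \ge
F_{obs}\}) / (B + 1)$.

**Pooled background.** By default the permuted scores of *all* profiles in
a batch are pooled into one background. Standardized profiles are
exchangeable under the null, and pooling raises the background size from
$B$ to $B \cdot G$, which is what makes empirical FDR thresholds as small
as $10^{-5}$ attainable with a desk-scale number of permutations. A
per-gene mode is available (`pooled = FALSE`). Whether the original
analysis pooled is not something the score itself records; both modes give
calibrated p-values (the test suite checks calibration on 1000 white-noise
genes).

**Empirical FDR.** At score threshold $s$,
$q(s) = \frac{\#\{\text{background} \ge s\}/B}{\#\{\text{observed} \ge s\}}$,
clipped to $[0,1]$ and monotonized step-up (as in Benjamini–Hochberg) so
$q$ never increases with the score. When no background score reaches $s$,
$q(s) = 0$: with a pooled background this is the only way a $q < 10^{-5}$
call can exist at practical $B$, and it is the intended behavior, not an
underflow.

**Phase.** A 24-h cosine is slid along the time axis; the shift maximizing
$\sum_i x_i \cos(2\pi(t_i - \alpha)/T)$ is the peak phase $\alpha \in
[0, 24)$ h. The default grid step is 0.1 h; ties break toward the smallest
shift. The grid search agrees with the closed-form
$\alpha = \tfrac{T}{2\pi}\,\mathrm{atan2}(S, C)$ within half a grid step
(property-tested), but the grid formulation is kept because it mirrors the
operational definition and handles degenerate profiles uniformly.

Profiles with missing timepoints are excluded and reported, never imputed;
constant profiles are flagged non-testable, which is a data property, not
an error.

## Complex abundance: the product of profiles

The abundance of the complex $C$ formed by proteins $P_1, P_2$ is
approximated by the pointwise product $A_C(t) = E_{P_1}(t) \cdot
E_{P_2}(t)$ of the **raw**, strictly positive profiles; only the product is
standardized before scoring. Multiplying per-gene *standardized* profiles
would be wrong for this purpose: the product of two zero-mean sinusoids
contains only DC and 12-h terms, so every 24-h signature would vanish. On
raw profiles, writing each partner as $b(1 + a\cos\theta)$, the 24-h
component of the product is $a b^2 (\cos\theta_1 + \cos\theta_2)$ — the sum
of the two phase vectors. Consequences we rely on and test:

* a rhythmic partner with a flat partner gives the rhythmic partner's
  phase;
* two baseline-matched cosines with phases $\varphi_1, \varphi_2$ (offset
  < 12 h) give the circular midpoint;
* as the offset grows toward antiphase the 24-h score of the product
  decays monotonically to zero.

The alternative (multiplying standardized profiles) is deliberately **not**
offered behind a flag: it answers a different question (shared 12-h
structure) and would silently change the meaning of every downstream phase.

An edge is **dynamic** when its product profile passes the periodicity FDR
threshold (default $10^{-5}$, the genome-scale setting; small synthetic
studies use 0.05 because a 1500-edge run cannot calibrate $10^{-5}$
empirically). Each dynamic edge carries its product phase. Input edge lists
are made undirected: self-loops and A–B/B–A duplicates are dropped with
counts; edges with an endpoint missing from the matrix are counted as
untested rather than failing the run.

## Network topology and null models

Topology statistics follow the conventions standard for interactome
analysis: mean shortest path over unordered reachable pairs **within the
largest connected component** (configurable to score disconnected graphs
as infinite instead — the averaging convention is not universal, so it is
explicit); local clustering $C_n = 2e_n/(k_n(k_n-1))$ with degree-<2 nodes
contributing 0 to the global mean but excluded from the degree-averaged
curve; the topological coefficient $T_n = \mathrm{mean}_m
|\mathrm{shared}(n,m)|/k_n$ over nodes $m$ sharing at least one neighbor
with $n$; and a power-law exponent from least squares on log count vs log
degree. The topology null model is the double edge swap: repeated swaps of
two independent edges, rejecting self-loops and multi-edges, preserving
every degree exactly. Default ensemble: 100 replicates of $10\,|E|$ swaps.
Graphs with no legal swap (e.g. a triangle) are returned unchanged with a
warning rather than looping forever.

## Co-expression and hub classification

Temporal co-expression of a pair is the Pearson correlation of the two
profiles; a pair is "co-expressed" when PCC strictly exceeds 0.5 (the
boundary counts as not co-expressed). Enrichment among interacting pairs
is a 2×2 chi-squared against pairs drawn uniformly from profiled genes,
excluding the interacting pairs themselves.

A hub's label compares its mean PCC with its true partners against
`n_background` random partner sets of equal size: party if the empirical
FDR for "higher than chance" is below 0.01, date if "lower than chance"
is, else unclassified. The background FDRs use the add-one estimator, so
the minimal attainable value is $1/(n_{background}+1)$ — choose
`n_background` ≥ 200 for a 0.01 threshold. A "partial" background
(retain a uniformly chosen half of the true partners, resample the rest)
is provided for sensitivity analysis; its exact recipe is this package's
construction, stated here because no standard one exists.

## Process coupling

Each network protein may carry one or more functional categories (a
reduced GO-style annotation, consumed as input — reducing GO is out of
scope). An edge links category pair $(A, B)$ if one endpoint carries $A$
and the other $B$; multi-annotated endpoints contribute to every
qualifying pair, each edge once per pair (so an $x\!-\!y$ edge with both
genes annotated $\{A, B\}$ counts for $(A,A)$, $(A,B)$, $(B,B)$). The null
model redistributes the dynamic label uniformly over all edges, keeping
the global dynamic count fixed — the graph and the annotation never
change. We do not additionally preserve per-node dynamic degree; that
stricter null is a possible refinement, and the label-permutation choice
is recorded here as the package's reading of "randomized versions of the
dynamic interactome". A pair is displayed when at most 10 of 1000 random
networks beat its dynamic count ($p_{perm} \le 0.01$; both numbers
configurable). With single-annotated genes and two categories this
permutation p matches a hypergeometric closed form (property-tested).
Per-category enrichment of dynamically interacting genes is an ordinary
hypergeometric test with BH correction, background = all annotated genes.

## Reporter phenotyping

Traces (default: 30-min sampling over 6 days) are detrended by subtracting
a centered 24-h running mean. Points exactly on the window boundary get
half weight (a trapezoidal window): on a uniform grid the window then
spans exactly one period, so a pure 24-h cosine passes through unchanged
and a linear ramp is removed exactly; without the half weights a
boundary point is double-counted and ~2% of the oscillation leaks into
the trend. Edges use a shrinking window, so the outermost half-window of
the trace is distorted — fits weight all points equally and tolerate this.

The oscillation model is $A e^{-\lambda t} \cos(2\pi(t-\varphi)/\tau)$.
For fixed $(\tau, \lambda)$ the model is linear in
$(a, b) = A(\cos, \sin)$ components, so fitting is a grid multi-start over
$\tau \in [18, 32]$ h (step 0.25) × a small damping grid with an exact
linear solve at each node, followed by `nlminb` refinement of
$(\tau, \lambda)$ with the linear solve nested inside. Fits are
canonicalized to $A > 0$, $\varphi \in [0, \tau)$. Rhythmicity is judged
by the Pearson correlation $r$ between fit and data: rhythmic iff $r \ge
0.8$. Both the model and the cutoff are this package's explicit choices
(the original screening software's internals are not published); both are
arguments, and they are stamped into the returned object. The optimizer's
convergence code is kept as a diagnostic but does not veto the call —
"false convergence" reports at a usable optimum are common for this
profile surface.

**Phenotypic score.** Per construct: 0 if $|\Delta\tau| < 0.5$ h and no
flags; 1 if $0.5 \le |\Delta\tau| < 2$ h or an amplitude/damping flag; 2
if $|\Delta\tau| \ge 2$ h; 3 if arrhythmic. Within a perturbation
direction the score is the **minimum** over replicate constructs — a
phenotype must reproduce across constructs to count, and the minimum (i)
implements "the score supported by the weaker construct" uniformly and
(ii) keeps the score monotone: worsening any single input can never lower
the gene score (property-tested). The gene score is the sum over measured
directions (0–6 with both). These rules are a configurable default, not a
reconstruction of any unpublished rule set. Scores are compared between
proteins with ≥ 5 versus < 5 dynamic interactions by two-sided t and
Mann–Whitney tests.

## What the simulators emulate — and what they do not

`simulate_expression` draws $x_g(t) = b_g(1 + a_g \cos(2\pi(t -
\varphi_g)/24)) + \varepsilon$ with log-normal baselines (log-mean
$\log 100$, log-sd 0.5), relative amplitudes uniform on $[0.2, 0.6]$,
phases uniform on $[0, 24)$, Gaussian noise with sd `noise_sd`$\cdot b_g$
(default 0.1, i.e. SNR ≈ 10 relative to baseline), truncated below at
$0.01\,b_g$ so products are well-defined. Defaults: 48 hourly timepoints,
30% rhythmic genes — chosen once as a realistic tissue-level rhythmic
fraction for a clock-enriched gene set, midway between genome-wide
(2–10%) and clock-network (~50%) figures. `simulate_network` grows a
preferential-attachment graph (scale-free, connected, simple) over the
simulated genes and plants co-phase edges (offset ≤ 2 h) between rhythmic
genes as recoverable ground truth. `simulate_reporter` produces damped
cosines with polynomial trend and Gaussian noise; `simulate_annotation`
draws overlapping category memberships.

Not emulated: probe-level measurement error structure, tissue
specificity, transcript–protein delay and half-life, amplitude–baseline
correlation, and hub-dependent co-expression. Passing tests therefore
demonstrate statistical correctness and calibration of the machinery
under the stated generative model, not biological validity on real liver
data.

All generators take one integer seed; `run_pipeline` derives per-stage
child seeds deterministically from a single global seed, so any synthetic
study is reproducible byte-for-byte.

## Numerical choices and degenerate inputs

* Population sd in standardization (divide by $N$); permutation inference
  is invariant to the choice.
* Scores, p, q, phases are `NA` (with a status string) for unmapped,
  missing-value, or constant profiles — never silently 0.
* `empirical_fdr` tolerates ties via a $10^{-12}$ guard when counting
  "$\ge s$".
* Phase ties (exactly antipodal optima) break toward the smallest shift.
* `rewire_preserving_degrees` counts attempted, not successful, swaps; the
  default $10\,|E|$ attempts is the conventional mixing heuristic.
* Seeds below $2^{31}$ throughout; the RNG state of the caller is saved
  and restored around every seeded call.

## Problem sizes

The shipped test-and-verification studies use: 1000 genes × 48 timepoints
with $B = 100$–200 permutations; a 500-node / ~1540-edge network with 50
planted dynamic edges; 1000 label-permutation networks over 465 category
pairs; and 100 simulated reporter traces (289 points each) for period
recovery. These sizes give stable Monte-Carlo estimates (binomial CIs of
a few percent) while a full run of the verification script completes in
well under a minute; all counts scale linearly through the same function
arguments.

## Known limitations

* Transcript-as-proxy: everything downstream inherits it.
* Only the 24-h component is scored; harmonics and non-sinusoidal shapes
  are invisible except through their 24-h projection. Multi-period scans
  and nonparametric tests (JTK-style) are out of scope.
* The product statistic treats partners symmetrically; competition,
  saturation, and stoichiometry are not modeled.
* Empirical FDR at $10^{-5}$ relies on the pooled-exchangeability
  assumption; strongly heteroskedastic profile sets would weaken it.
* The process-network null preserves the global dynamic count only, not
  per-node dynamic degrees.
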