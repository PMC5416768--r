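---
title: "Methods: simulating and analysing transcriptional rewiring screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing transcriptional rewiring screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewirescreen)
```

## The problem

Genetic rewiring fuses the promoter of one endogenous gene to the coding
sequence (CDS) of a transcriptional regulator, adding a synthetic edge to the
host's regulatory network. A combinatorial library over a promoter set and a
regulator-CDS set — every ordered promoter::CDS pair — is screened in
microtiter plates for clones with enhanced heterologous protein expression
(GFP fluorescence per OD600) or metabolite titre (lycopene A484 per A660).
This package implements the quantitative side of such a screen end to end:
simulation with known ground truth, hit calling, validation statistics, and
topological characterisation of the regulators that keep turning up among
hits.

## The screen model

A library of `n_promoters * n_cds` constructs is sampled uniformly with
replacement (colony picking) at a chosen coverage — the expected number of
clones per construct — and arrayed into plates. Each well's signal is
generated as

$$\text{signal} = B \cdot f_c \cdot g \cdot \pi_p \cdot \varepsilon$$

where $B$ is the baseline growth-normalised signal, $f_c$ the construct's
true fold effect ($f_c = 1$ for non-enhancers), $g$ the culture density
(lognormal around `growth_mean`), $\pi_p$ a per-plate batch factor
(lognormal, SD `plate_sd` on the log scale) and $\varepsilon$ a mean-one
multiplicative well noise with coefficient of variation `well_cv`. The model
is deliberately the structure the analysis pipeline is designed to remove:
growth normalisation divides out $g$ exactly, and per-plate standardisation
removes $\pi_p$ and $B$.

Noise defaults, chosen once as values a screener would call realistic and
not estimated from any published screen (none reports them): `well_cv = 0.2`
for single-well plate readings, `plate_sd = 0.1` (≈10% plate-to-plate),
`growth_mean = 0.5` OD with `growth_cv = 0.2`. Two noise families are
provided: `"lognormal"` (strictly positive, right-skewed, the default) with
factor $\exp(sZ - s^2/2)$, $s^2 = \log(1+\text{cv}^2)$; and `"normal"`
($1 + \text{cv}\,Z$), which makes per-plate z-scores exactly Gaussian under
the null and is what the type-I calibration checks use. At cv = 0.2 the
normal family's negative-value probability is negligible (~$3\times10^{-7}$,
clamped at zero).

### Hit calling

Per round: wells below the growth floor (default 0.05 OD — a culture that
thin is a failed well, and dividing by it would blow up) are excluded with a
message; signals are divided by growth; each plate is standardised by
subtracting its mean and dividing by its *sample* SD (n−1 — plates hold at
most 96 wells, so the finite-sample convention matters and makes
`plate_standardize(c(1,2,3))` exactly `c(-1,0,1)`); clones whose z-score
strictly exceeds the round's threshold on the high side are selected.
Defaults follow the two-threshold protocol: 2 SD in the primary screen,
1 SD in the repeat assay, and a clone must clear every round (survivor sets
are intersected). Selection is one-sided because the screen seeks *enhanced*
expressors; a `two_sided` flag exists for sensitivity analysis.

Numerical corner cases, fixed by convention: a plate whose normalised
signals are constant cannot be standardised — its wells score z = 0 (never
selected) and a warning counts such plates; this is what makes the
noise-free limit well defined, where plates without a planted enhancer are
exactly constant. A prior survivor missing from a later round is a failed
re-screen (warned, dropped), since only consistent outliers count.
Standardisation always uses everything measured on the plate in that round,
whether the round re-arrays only survivors or re-reads the whole library.

### Validation statistics

The re-cloned validation assay compares `n = 44` independent rewired clones
against 44 controls, paired by plate-well position so plate effects cancel.
`fold_change` is the ratio of group means with a delta-method standard
error, $\mathrm{SE} = \hat f\sqrt{(\mathrm{SE}_r/\bar r)^2 +
(\mathrm{SE}_c/\bar c)^2}$; ratio-of-means is used rather than
mean-of-ratios because control clones are not biologically paired to
specific rewired clones. `paired_t_test` works on positionally paired
differences; identical vectors return t = 0, p = 1 (no evidence), while
zero-variance differences with nonzero mean are a degenerate error.
Lycopene assays go through `lycopene_signal` (A484 scaled by the 1:5
dilution, divided by A660) and `percent_enhancement`, i.e.
$100(\hat f - 1)$. The simulated lycopene validation uses triplicate
cultures with `well_cv = 0.05`: flask-scale triplicate absorbance assays
are far tighter than single-well library screening, and 5% is a
conventional figure for such measurements.

## Network topology

Metrics are computed from scratch on the directed regulation graph
(self-loops stored but excluded everywhere, to keep autoregulation from
inflating degree and triangle counts):

* **out-degree** — distinct targets per regulator;
* **betweenness centrality** — Brandes' algorithm (single-source BFS plus
  dependency back-propagation), directed shortest paths, unnormalised pair
  counts; unreachable pairs contribute nothing. An undirected mode exists
  for sensitivity analysis, but regulation is directional and directed is
  the default;
* **clustering coefficient** — on the undirected projection (the natural
  reading of "how connected are a node's neighbours"), $2L/k(k-1)$, zero by
  convention below two neighbours; a directed-triangle variant sits behind a
  flag;
* **eccentricity** — max BFS distance to *reachable* nodes; sinks get 0.
  Finite values are required downstream (a t-test cannot average
  infinities), hence the finite-reachable-set convention;
* **hierarchy levels** — on the TF–TF subnetwork, strongly connected
  components are condensed first (Kosaraju), guaranteeing termination, then
  the longest-path rule: a TF regulating no other TF is level 1, otherwise
  1 + max level of its TF targets. This is an explicit, testable stand-in
  for curated hierarchy annotations; externally determined levels can be
  supplied and are validated instead.

Every metric is tested for exact equality against a brute-force oracle
built on a different algorithm family (dense matrix powers count
minimal-length walks, which are shortest paths), and against igraph.

The synthetic network generator draws per-TF out-degrees from a scaled
Pareto(α = 2) tail and attaches targets preferentially by current in-degree,
reproducing the hub structure of ChIP-derived regulatory networks without
claiming to model any particular database. The reference network this
emulates has 6407 nodes and 48086 edges (≈7.5 edges per node), so the
reduced study condition used throughout the enrichment simulations is 200
nodes, 40 TFs, mean out-degree 37.5 — the same edge density at 1/32 the
node count. At much sparser settings (≤2 edges per node) a
preferential-attachment generator leaves a substantial fraction of genes
untargeted and the giant weak component claim no longer holds; connectivity
is therefore asserted at the matched density, where the largest weak
component covers >90% of nodes.

## Enrichment testing

Hit regulators are compared with the remaining TFs (the genome background)
one metric at a time with a one-tailed Welch test: unequal variances,
Satterthwaite degrees of freedom, direction fixed per metric as
configuration, not inference — higher out-degree, higher betweenness, lower
clustering, higher hierarchy, lower eccentricity by default, each printed
with the result. TFs where clustering is undefined (fewer than two
neighbours) keep the 0-by-convention value so the background is not
asymmetrically thinned; a flag drops them instead. Raw one-tailed p-values
are reported per metric (no correction across the five metrics, matching
how such screens are usually quoted), with a Bonferroni column for
transparency.

Two statistical caveats the simulations make explicit. First, under random
(bias-0) hit sets the Welch p-values are only approximately uniform: for
small hit sets (k ≈ 10) drawn from heavy-tailed discrete metric values, the
t approximation visibly deviates (KS D up to ~0.17 at 500 replicates); the
uniformity checks therefore use balanced splits (k = 20 of 40 TFs), where
the approximation is sound. Second, power at small k is limited by the
variance of the top-ranked group itself — with the top 5 of 40 TFs by
out-degree planted as hits, detection at p < 0.05 succeeds in ≥90% of
seeded replicates at the matched density, but drops noticeably on much
sparser networks.

## Calibration of the null selection rate

Because each plate is standardised by its own estimated mean and SD
(n = 96), the null probability that a well scores z > 2 is not the
asymptotic normal tail 0.02275 but the exact studentised value
$P\!\left(t_{n-2} > c\sqrt{\tfrac{n}{n-1}}\sqrt{\tfrac{n-2}{\,n-1-c^2\frac{n}{n-1}}}\right) = 0.021883$
for c = 2 — about 0.0009 lower. At the scale of the calibration test
(48 000 wells) that difference is three binomial standard errors, so the
test compares against the exact finite-plate value and separately asserts
it lies within 0.002 of the normal tail. Practically: a 96-well plate
screen at 2 SD selects ~2.2% of null wells either way.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest
scale, chosen as the smallest sizes at which each property is
statistically meaningful: oracle equivalence on 50 graphs of ≤30 nodes,
validation assays at the published n = 44 (protein) and n = 3 (lycopene)
over 20 seeds, null calibration on 50 × 960 wells, enrichment simulations
on 200-node networks with 50–500 replicates, and a full demo pipeline
(2×-coverage screen of a 12 × 15 library against a 200-node network) that
completes in seconds.

## What the simulations do and do not show

Passing recovery tests shows the pipeline correctly inverts its own
generative model — multiplicative growth, plate and well effects around
planted fold changes — and that the statistics behave as designed under
that model. Real screens add structure the generator does not emulate:
spatial plate gradients (edge effects), growth–expression coupling beyond
simple normalisation, construct-specific growth penalties, library
abundance biases from assembly, and measurement saturation. Results on real
data therefore depend on those effects being small or separately corrected;
the package's claims are about the correctness and calibration of the
procedures, not about any particular organism's biology.

## Known limitations

* Betweenness is exact but pure R; networks beyond ~10⁴ edges will be slow.
* The hierarchy rule is a structural stand-in; when curated levels exist,
  supply them via `external_levels`.
* Ortholog mapping is a strict one-to-one table; many-to-many ortholog
  families must be resolved upstream.
* The fold-change SE uses the delta method, which is anti-conservative for
  very small control groups (n < 5) with large CV.
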