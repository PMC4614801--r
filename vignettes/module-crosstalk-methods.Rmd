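---
title: "Methods: module crosstalk between two disease contexts"
author: "ModuleCrosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: module crosstalk between two disease contexts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ModuleCrosstalk)
```

# Overview

ModuleCrosstalk asks whether dense functional modules detected in two
disease contexts — canonically chronic inflammation and cancer of the
same tissue — are connected in the protein–protein interaction (PPI)
network by more interactions than a degree-preserving random-network
null allows. The pipeline runs five stages: per-dataset differential
expression, cross-dataset integration, module detection on the DEG-mapped
interactome, crosstalk permutation testing, and pivot-regulator
identification, with generic gene-set enrichment for annotation. This
vignette documents the model behind each stage, every tunable parameter,
the numerical conventions, and the properties and limits of the synthetic
test bed.

# Differential expression

## Statistic

For gene $i$ with disease samples $x$ and normal samples $y$,

$$d_i = \frac{\bar{x}_i - \bar{y}_i}{s_i + s_0}, \qquad
s_i = \sqrt{\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)
\frac{\sum (x - \bar x_i)^2 + \sum (y - \bar y_i)^2}{n_1 + n_2 - 2}}$$

The fudge constant $s_0 \ge 0$ damps the statistic for genes whose
variance is accidentally tiny. The reference method tunes $s_0$ by
minimizing the coefficient of variation of $d$ across quantiles of $s_i$;
we default to the simpler and well-behaved **median of the gene-wise
$s_i$**, with `s0` exposed for stricter variants. Both groups need at
least two samples; with `s0 = 0` a zero pooled standard error is an
error by default (`zeroSe = "infinite"` returns signed infinities
instead).

## Permutation FDR and threshold choice

Group labels are permuted (`nPermutations`, default 100, minimum 50; all
distinct assignments are enumerated when there are fewer of them) and the
statistic is recomputed with the *same* $s_0$. For each candidate
symmetric threshold $t$ (the observed $|d|$ values), the estimated FDR is
the median over permutations of $\#\{|d^*| \ge t\}$ divided by
$\#\{|d| \ge t\}$. Per-gene q-values take the smallest estimated FDR
among thresholds that call the gene (a running minimum from the top),
and genes with $q \le$ `fdrTarget` (default 0.01, the reference
protocol's 1% FDR) are called with the sign of $d$ as direction. When no
threshold achieves the target the call set is empty and a message is
logged — not an error, since null datasets are expected to produce this.

## Integration

A gene enters the integrated set of a context iff (1) it is called in at
least `minSupport` datasets (default 2) and (2) every call has the same
direction. Direction conflicts exclude a gene outright. For a
direct two-condition comparison backed by a single dataset pair,
`minSupport = 1` applies the same machinery.

# Interactome handling

Interaction tables are 3-column TSVs (geneA, geneB, score). Scores above
1 anywhere in a file are interpreted as the 0–999 integer dialect and
divided by 1000. The score cutoff (default 0.9) is **inclusive**: a
boundary score survives, which makes reported edge counts reproducible
against the convention stated here. Self-loops are dropped (count
logged); duplicate pairs collapse to their maximum score. Gene
identifiers are opaque case-sensitive symbols — identifier mapping is
upstream curation and out of scope. DEG mapping takes the exact induced
subgraph; the maximal connected component breaks size ties in favor of
the component containing the lexicographically smallest gene id.

# Module detection

The detector reimplements the classic seeded-growth complex algorithm.
Vertex weight is $k \cdot \mathrm{density}$ of the highest $k$-core of
the vertex's closed neighborhood (density $= 2E/(n(n-1))$; isolated
vertices weigh 0). Weights are computed once on the input graph, not
recomputed during growth. Complexes grow breadth-first from the
highest-weight unvisited seed (ties broken by lexicographic gene id, so
output is independent of input ordering); a neighbor is admitted when its
weight **strictly exceeds** $(1 - \texttt{nodeScoreCutoff}) \times$ the
seed weight, and each vertex belongs to at most one complex. Defaults
mirror the algorithm's published defaults: node score cutoff 0.2, haircut
on (iterative removal to the 2-core of the complex), fluff off (when on:
unvisited neighbors whose closed-neighborhood density exceeds
`fluffDensityCutoff` are appended, before the haircut), growth depth
limit 100, and complexes must contain a non-empty 2-core. The complex
score is density × size. If the haircut prunes the seed itself, the
highest-weight surviving member is reported as seed. No module-size floor
is imposed beyond the 2-core rule; three-gene complexes are legitimate
output.

Two behaviors of this algorithm are worth knowing when interpreting
results, both measured on the synthetic test bed:

* **Threshold dropout.** Within a module of internal density about 0.8,
  vertex weights spread by more than 20%, so members whose weight falls
  more than `nodeScoreCutoff` below the seed's are not admitted and the
  reported complex is a dense core of the module rather than the whole
  module.
* **Bridge merging.** Two dense modules whose vertex weights lie within
  20% of each other merge into a single complex as soon as one edge
  bridges them, because members on the far side pass the seed-relative
  threshold.

Consequently the planted-recovery benchmark in the test suite plants
cliques (density 1.0) with well-separated sizes, where neither effect
operates and recovery is essentially exact; at density 0.8 partial
recovery is expected *behavior*, not a defect.

# Crosstalk testing

## Counting convention

The observed statistic for a module pair is the number of network edges
with one endpoint among members exclusive to the first module and the
other among members exclusive to the second. Edges incident to shared
genes are **excluded** from the crosstalk count and reported separately
(`sharedElements()`: the member intersection and the edges internal to
it), because interactions inside the common part of two modules describe
shared structure, not communication between the module-specific parts;
counting them would double-count internal edges. The alternative
convention is available via `includeSharedEndpoints = TRUE`.

## Null model and p-value

`nRandom` degree-preserving randomizations (default 1000, minimum 100)
are generated by double-edge swaps — proposals creating self-loops or
parallel edges are rejected — with `swapsPerEdge` (default 10) swap
trials per edge. One shared ensemble serves every module pair: the
protocol randomizes the *network*, not each pair, and this is also
hundreds of times cheaper. The p-value is

$$p = \frac{1}{N}\sum_{i=1}^{N} S_i, \qquad
S_i = \mathbf{1}\{c^*_i > c\}$$

with strict exceedance, exactly as in the reference protocol. A
conservative variant $(\#\{c^* \ge c\} + 1)/(N + 1)$ sits behind
`conservative = TRUE` (default off, fidelity first). Significance is
declared at $p <$ `alpha` (default 0.05) **and** $c > 0$: with the strict
formula, a pair whose observed and null counts are all zero would get
$p = 0$, and flagging "significant crosstalk" with zero observed
interactions would be meaningless. No multiple-testing correction is
applied across pairs by default, matching the reference protocol; BH is
available via `adjust = TRUE`. Stored null-count matrices make every
p-value re-derivable by exact integer arithmetic.

## Calibration design

Permutation p-values are calibrated *against their own null*: the
guarantee is uniformity when the observed network is a draw from the
fixed-degree-sequence ensemble. A preferential-attachment graph is not
such a draw (its local structure differs from the configuration model,
and we measure a modest excess of small p-values when treating it as
observed). The calibration study in the test suite therefore randomizes
the background graph once — making the null true by construction — and
tests random disjoint gene sets as module pairs; the significant fraction
then falls within the 99% binomial band around the nominal 0.05. The
residual upward push comes from the strict-exceedance convention, which
resolves ties in favor of small p-values.

# Pivot regulators

For every regulator and every significant module pair, the in-module
target counts and two upper-tail hypergeometric p-values are computed
(population = background universe, successes = module members, draws =
the regulator's targets restricted to the background). The pivot verdict
requires **more than 2** targets in each module (literally $> 2$, i.e.
$\ge 3$; `minTargets` allows stricter or looser variants) and both
p-values below `alpha` (default 0.05). The background universe defaults
to the node set of the full filtered interactome: the modules live in
that graph, so it is the natural sampling frame; the genome or the MCC
are alternatives a user can pass explicitly. TFs and miRNAs run through
identical logic, distinguished only by the type label. No
multiple-testing correction across regulators by default (`adjust`
enables BH per pair and module side).

# Enrichment

Annotation sets are read from GMT. Per queried gene set, every term is
restricted to the background, tested with the upper-tail hypergeometric,
and adjusted with Benjamini–Hochberg **within that run** (per module, not
pooled across modules — labels are per-module in the intended use).
Zero-overlap terms are reported with $p = 1$ rather than skipped, keeping
the term universe stable across queries. Significance is $q <$ 0.05 by
default.

# The synthetic test bed

`syntheticConfig()` defaults encode the study conditions the pipeline is
validated under:

| parameter | default | rationale |
|---|---|---|
| `nGenes` | 1000 | desk-scale stand-in for a genome-wide interactome |
| `backgroundAttachment` | 3 | preferential attachment; right-skewed degrees (max > 3× median) so the degree-preserving null is non-trivial |
| `plantedModules` | 8 modules, sizes 8–12, density 0.8 | complex-like scale for detection and crosstalk |
| `plantedCrosstalk` | 2 pairs × 12 extra inter-edges | effect size for the power analysis |
| `nDatasetsPerContext` | 3 | matches the reference design (3 studies per comparison) |
| `samplesPerGroup` | 20 | typical of the reference microarray cohorts |
| `degEffectSize`, `noiseSd` | 5, 1 | strong, clearly-recoverable planted effect |
| `backgroundDegFraction` | 0.3 | most real DEGs sit outside dense modules; without them the DEG-induced subgraph shatters and its MCC holds a single module |
| `nRegulators`, `decoyTargets` | 100, 10 | decoy pool for specificity estimates |
| `plantedPivots` | 4 (2 TF + 2 miRNA), 4 targets/module | recoverable dual-module regulators |

Planted modules are overlaid on the background by *adding* edges only, so
configured densities are lower bounds and the background degree spread is
preserved; modules are forced connected. Planted crosstalk adds exactly
the configured number of new edges between non-adjacent, non-shared
member pairs; the truth object records the resulting total inter-edge
count so audits by enumeration are exact. Expression is Gaussian per gene
with a shared noise SD — adequate because the DEG statistic is
location-scale based — with planted genes shifted by
`degEffectSize × noiseSd` in a per-gene direction fixed across all
datasets of a context. Identical configurations (including the seed)
produce byte-identical files.

What the generator does **not** emulate: probe-level/microarray artifacts,
batch effects, normalization residue, correlated expression within
modules, heavy-tailed noise, scale-free regulator out-degree, and
biological overlap between contexts beyond random leakage. Passing tests
demonstrate the machinery is correct and calibrated under these
idealized conditions; they do not certify performance on real cohorts.

# Numerical conventions and problem sizes

* Seeds: every stochastic function takes an explicit integer seed;
  the pipeline derives per-stage streams from one global seed by fixed
  small offsets.
* Tie-breaks: seed selection by lexicographic gene id; MCC ties by
  smallest member id; enrichment rows ordered by (q, p, term).
* Degenerate inputs: empty graphs, empty DEG sets, empty module lists
  and empty queries return empty results with logged messages; malformed
  input lines error with their line number.
* The test suite and acceptance script run at deliberate desk scale:
  1000-gene interactomes (about 3300 edges), ensembles of 100–200
  randomizations, 100 permutations, and 5–25 generator seeds per
  property — sizes chosen so the full suite completes in a few minutes
  while keeping every estimate's sampling error well inside the asserted
  margins. The reference protocol's 1000-network ensemble remains the
  package default for real analyses.

# Known limitations

* The permutation p-value has resolution $1/N$ and is exactly 0 when no
  null count exceeds the observed one; for publication-grade bounds use
  the conservative variant.
* Module detection inherits the reference algorithm's order-dependence
  and the merging/dropout behavior documented above.
* The SAM-style $s_0$ is a fixed median, not the coefficient-of-variation
  search of the original; on data with strong mean-variance structure the
  two can differ.
* Crosstalk and pivot tests are unadjusted across pairs/regulators by
  default, by protocol fidelity; enable the BH flags for conservative
  reporting.
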