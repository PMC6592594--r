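---
title: "Methods: permutation-null differential expression for matched-pair embryo transcriptomes"
author: "permde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-null differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permde)
```

## The design this package targets

`permde` implements the computational analysis of a two-condition,
matched-pair bulk RNA-seq study with very few biological replicates: embryos
conceived with fresh (FRSH) versus frozen-thawed (CRYO) sperm from the same
stallion-mare pairing, collected on days 8, 10 and 12 after ovulation, two
embryos per condition per day.  Each day is analysed as its own 2-vs-2
contrast.  With two replicates per group no parametric per-gene test has
usable power, which is why the pipeline's core statistic is a permutation
null pooled across the genome, crossed with a fold-change filter.

The stages are: quantification (TPM/RPKM) with an expression floor,
permutation differential expression with volcano construction, gene-set
over-representation (EASE score, Benjamini-Hochberg control), confidence-
thresholded interaction-network analysis with a permutation PPI-enrichment
test, and intersection of down-regulated candidates with ortholog-phenotype
annotations.  A negative-binomial simulator with planted condition effects
generates counts, annotations, networks and phenotype tables with the
statistical structure the analysis assumes, so every stage is testable
without external data.

## Quantification and the expression floor

Counts are converted per sample to length-normalised rates
$r_g = c_g / (\ell_g / 10^3)$ and rescaled to TPM,
$\mathrm{TPM}_g = 10^6 \, r_g / \sum_h r_h$, so every sample with any
signal sums to exactly one million.  RPKM is
$10^9 c_g / (\ell_g \, L)$ with $L$ the sample's total count.  Both are
monotone rescalings of $c_g/\ell_g$ within a sample, so they rank genes
identically; TPM is used for testing, RPKM for the floor.

A gene is considered expressed when its RPKM strictly exceeds 0.4.  The
floor's scope is configurable because "considered expressed" can reasonably
be read per sample, per condition, or across the whole contrast.  The
default retains a gene expressed (> 0.4) in *at least one* of the four
samples of the day under analysis: this keeps any gene detectably present
anywhere in the contrast (maximising power, since a gene silenced in one
condition is exactly the kind of candidate the analysis seeks) while
removing globally silent genes whose TPM differences are pure noise.
`filter_expressed()` also offers `"all"` and `"condition_mean"` scopes.

Effective length is the annotated transcript length as supplied; no
fragment-length correction is attempted because nothing upstream estimates
fragment distributions.

## The permutation test

For a day's contrast the statistic is the observed difference
$d_g = \bar{x}_{g,\mathrm{CRYO}} - \bar{x}_{g,\mathrm{FRSH}}$ of mean TPM.
The null is built by permutation, in one of two explicit modes, because
"permuting the TPM scores" genuinely admits two readings:

* **`label_within_gene`** (default).  Each permutation reassigns every
  gene's four TPM values to pseudo-groups uniformly at random and records
  the pseudo-difference; the null is the *pooled genome-wide* collection of
  these values.  A single gene admits only $\binom{4}{2} = 6$ label splits
  (three up to sign), so per-gene permutation alone cannot go below
  $P = 1/3$; pooling across genes is the only route to a fine-grained null
  at this replication level, and each pseudo-difference is still computed
  from that gene's own values, so each gene contributes noise on its own
  scale.
* **`global_score_shuffle`**.  TPM values are shuffled across genes within
  each sample before differencing.  This destroys per-gene scale and is
  retained as the alternative reading rather than the default.

P values are two-sided exceedances with the add-one correction,
$P_g = \bigl(1 + \#\{|z| \ge |d_g|\}\bigr) / (N_{\mathrm{null}} + 1)$,
so $P \in [1/(N+1), 1]$ and ties count as exceedances (conservative).  A
gene whose difference is "more extreme than 99% of the random cases" is
exactly a gene with $P < 0.01$.

**Calibration of the pooled null.**  Under the null, a gene's observed
difference is itself one random label assignment, i.e. a draw from the same
pooled mixture the null estimates.  The aggregate fraction of null genes
with $P < \alpha$ is therefore $\alpha$ by construction, even though genes
with unusually large (or small) expression are not *individually*
calibrated against their own scale: an abundant gene is compared against a
mixture dominated by quieter genes.  The test suite verifies aggregate
type-I control on an all-null simulation at $\alpha = 0.05$ and $0.01$; the
per-gene caveat is a property of the method, and the reason the candidate
criterion also demands a fold change.

**Numerical tie handling.**  The identity assignment puts $\pm d_g$ into
the null for gene $g$, and these algebraic ties must count as exceedances.
Because the null path computes pseudo-differences by a matrix product and
the observed path by row means, the two can differ by an ulp; the
exceedance comparison therefore carries a $10^{-9}$ relative tolerance.
For the same reason the sampled null canonicalises each gene's assignment
order by absolute difference, which makes candidate lists exactly
equivariant under swapping the condition labels (only signs depend on the
labeling, and P values use absolute values).

**Candidate selection.**  A candidate satisfies $P$ below the threshold
*and* $|\log_2 \mathrm{FC}| \ge 1$ (fold change $\ge 2$), where the fold
change is $\log_2$ of the CRYO over FRSH mean TPM with a pseudocount of
0.5 TPM added to both means so condition-absent genes stay finite; the
pseudocount is configurable.  The default P threshold is 0.01, with 0.05 as
the permissive alternative and 0.001 as a rescue threshold for days whose
candidate lists are too large to interpret (`per_day` overrides in
`run_pipeline()`, or `select_candidates(p_threshold = ...)`, which
re-flags without re-running the test).  Tightening either threshold can
only shrink the lists.  The fold-change filter exists to avoid expression
bias: with a pooled absolute-difference null, abundant genes reach small P
values on proportionally small shifts, and the fold criterion removes
exactly those.

**Volcano conventions.**  x is $\log_2$ FC (CRYO/FRSH), y is $-\log_{10} P$
capped at the attainable floor $-\log_{10} (1/(N+1))$; guide lines sit at
$x = \pm 1$ and $y = 1.30$ ($P = 0.05$); candidates render red.

## Gene-set over-representation

The enrichment stage is a local, explicit replacement for web-service
annotation charts.  Each set is scored with the EASE score: the one-sided
hypergeometric upper-tail probability of the $2\times2$ overlap table with
the overlap decremented by one (floored at zero).  The decrement is the
conservative feature: overlaps of 0 or 1 gene give $P = 1$ exactly, so no
single gene can carry a term.  Fold enrichment is $(k/n)/(K/N)$.  Sets
with fewer than two members are pruned (they can never be significant).

Benjamini-Hochberg control is applied within each annotation category
(mirroring per-category charts), and terms with FDR < 0.05 are flagged.
The universe is the *expressed genes of the contrast*, not a whole-genome
background: an enrichment ratio is only meaningful relative to the pool
from which candidates could actually have been drawn.  A human-genome
background, as annotation services default to, is not reproducible locally
and conflates annotation depth with biology; an explicit universe is the
honest analogue, and `enrich()` takes it as a parameter.

## Network analysis

The interaction network is a STRING-like weighted undirected graph with
combined confidence scores in $[0,1]$ (the 0-1000 integer scale is
auto-detected on read).  Edges at or above 0.700 are retained -- inclusive,
matching the "high confidence $\ge$ 0.700" convention.  PPI enrichment of a
query list is the permutation analogue of the service statistic (whose
analytic model is proprietary in detail): observed internal edges are
scored against `n_draws` equally sized node sets drawn uniformly from the
network, with the same add-one P as the expression test, so reports are
explicitly labelled as seeded permutation results.  Degree-binned draws are
not implemented: the simulator's planted modules are near-uniform in
degree, and a uniform null is the conservative default on such fixtures.
Clustering defaults to connected components of the query-induced subgraph
(no specific community algorithm is canonical for this step); greedy
modularity is available behind a flag.

## Phenotype intersection

Candidate down-regulated genes are intersected with a gene →
(ortholog, phenotype terms) table emulating a mouse-knockout database
export, optionally restricted to a term filter (e.g. embryonic-lethality
vocabulary).  One-to-many orthology yields one row per ortholog.  The
packaged generator produces a synthetic map; a real MGI/HomoloGene export
with the same three-column schema drops in unchanged.

## The simulator and its defaults

Counts are negative binomial in the mean-dispersion parameterisation
($\mathrm{Var} = \mu + \phi\mu^2$), the standard overdispersed model for
RNA-seq counts.  Expected counts scale a log-normal per-gene baseline by
transcript length (log-uniform in 300-15000 bp) and a log-normal library
size; planted genes have their CRYO expected value multiplied by exactly
$2^{\mathrm{effect}}$, so generating-mean ratios recover planted effects
exactly.  Defaults and the reasons for them:

* `n_genes = 29196` -- the scale of the expressed transcriptome per embryo
  in the motivating design (tests and the acceptance script use 2000 or
  fewer for speed; the statistical properties checked do not depend on
  genome size).
* `nb_dispersion = 0.2` -- a typical biological coefficient of variation
  (~45%) for outbred bulk samples; recovery scenarios use 0.05, the
  low-dispersion regime in which a 2-vs-2 design has power at all.
* `mean_library_size = 5e6`, CV 0.2 -- single-embryo library depth on a
  bench-top sequencer; the CV makes TPM normalisation non-trivial and is
  exposed (`library_size_cv`) so the count law is testable at CV 0.
* `baseline_log_mean_sd = 0.25` ($\log_2$ units) -- a deliberately narrow
  baseline spread.  This is the operating regime of a pooled
  absolute-difference null: detection of a *down*-regulated gene requires
  $0.75\,b_g$ (its absolute drop) to clear the pooled 95th percentile,
  which is set by the most abundant genes.  As the spread grows the method
  progressively loses the quiet half of the transcriptome: in design-phase
  simulations, recovery of four-fold planted effects falls from ~94% at an
  sd of 0.25 to ~86% at 0.5 and ~70% at 1.0.  The narrow default makes the
  planted-recovery guarantees meaningful; see the limitations below for
  what this implies about real data.
* Planted effects in recovery scenarios are split 50 down / 50 up at
  $|\log_2 \mathrm{FC}| = 2$, mirroring the roughly balanced up/down
  candidate counts such contrasts produce.

The generator does not simulate read-level data, isoforms, batch effects
beyond library size, or correlated genes outside planted network modules.

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` run: exhaustive-vs-sampled
agreement on 5 genes x (2 vs 2) at $10^4$ permutations; type-I calibration
and planted recovery on 2000-gene studies at $10^4$ permutations;
the EASE identity on the full grid $k \le n \le K \le N \le 40$ against a
direct `choose()` tail summation; 100-seed enrichment and network recovery
runs on 300-gene truths; and an end-to-end 2000-gene, 3-day pipeline run.
These sizes were chosen so the whole suite completes in about a minute
while keeping every Monte-Carlo bound (3 binomial SDs) meaningful.

## Known limitations

* The pooled null is calibrated in aggregate, not per gene; together with
  the absolute-difference statistic it favours abundant genes.  On real
  transcriptomes spanning decades of expression the method preferentially
  detects changes in highly expressed genes, and passing recovery tests on
  the narrow-spread simulator must not be read as power on wide-spread
  data.
* Day-level contrasts are 2-vs-2; the permutation machinery generalises to
  more replicates (`assignment_weights()` enumerates any group sizes) but
  no pooled-across-day or paired test is provided.
* No multiple-testing correction is applied across genes at the expression
  stage (the fold filter plays that conservative role); FDR control enters
  at the enrichment stage.
* The PPI null draws nodes uniformly, not degree-matched; on hub-heavy
  real networks this overstates enrichment of high-degree query sets.
* Enrichment and network P values depend on the supplied annotation and
  edge tables; with live database snapshots they are not expected to match
  any specific published magnitude.
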