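---
title: "Integrative RNA-Seq/ChIP-Seq gene prioritization with Pareto fronts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative RNA-Seq/ChIP-Seq gene prioritization with Pareto fronts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markfront)
library(dplyr)
```

## The problem

Differential expression analysis of RNA-Seq alone ranks genes by how much
their transcript abundance changes between two conditions. But transcription
is regulated in large part through post-translational histone modifications,
and a gene whose expression change is accompanied by *consistent* changes in
its chromatin state — activating marks such as H3K4me3 or H3K27ac moving with
expression, repressive marks such as H3K27me3 moving against it — carries far
stronger evidence of genuine regulatory rewiring than a gene whose RNA signal
moves alone. `markfront` turns that intuition into a ranking: it matches
ChIP-Seq histone-modification signal to genes, combines each mark's change
with the expression change into a per-gene, per-mark Z score, and orders
genes into Pareto fronts over those scores, so the genes with strong,
concordant multi-layer changes surface first.

## Matching ChIP signal to genes

ChIP-Seq reads are evidence about genomic regions; expression is a property
of genes. The bridge is the promoter: for marks enriched near transcription
start sites we count reads in a fixed window with the TSS at its center
(default 5 kb, `promoter_size`), one window per distinct TSS. For marks that
blanket transcribed regions (H3K36me3) we count over the genomic span of the
gene instead. Coordinates are handled in 0-based half-open form internally
(GTF input is 1-based inclusive), so window lengths are exact and a read
must overlap a window by at least one base to be counted; a read ending
exactly where a window starts does not count. Reads are counted per window
independently — a read under two overlapping windows counts in both — and
unmapped, secondary and supplementary alignments are always excluded.
Mapping-quality and duplicate filters exist (`min_mapq`, default 0;
`exclude_duplicates`, default off) but are deliberately permissive by
default, since the appropriate stringency depends on the upstream pipeline.

A gene with several promoters needs one value per sample. Two strategies are
offered. `match_highest()` selects, per gene, the promoter with the largest
mean count across **all** samples, and copies that promoter's entire
per-sample row. Using one consistent promoter (rather than a per-sample
argmax) matters: a per-sample argmax would conflate promoter switching with
abundance change and corrupt the fold change computed downstream. Ties break
toward the smallest TSS coordinate, making the output deterministic.
`match_weighted_mean()` instead averages promoters with weights equal to
their across-sample mean counts; for a gene whose promoters are all zero the
value is zero. "Abundance" is read as the across-sample mean in both
strategies so that the chosen promoter (or weighting) is identical in the
two conditions being contrasted.

As a quality control, `correlation_matrix()` computes the Spearman rank
correlation between every pair of samples — RNA and matched ChIP alike —
over the genes shared by all layers, on `log2(x + 1)` values. Rank
correlation is invariant to strictly monotone transforms, so the transform
only affects the tie structure among low counts. In sound data, activating
marks correlate positively with expression across samples and repressive
marks negatively; a sample that breaks this pattern is suspect. Constant
columns produce `NA` (undefined) rather than a misleading zero.

## Integration: from counts to Z scores

Counts are normalized by median-of-ratios size factors: each gene's
geometric mean across samples is a pseudo-reference (genes with any zero are
excluded from the reference), and a sample's factor is the median of its
count-to-reference ratios. If no gene is positive everywhere,
`pseudo_reference = TRUE` builds the reference from each gene's positive
counts only.

For each layer (RNA, and each mark's matched signal) the per-gene log2 fold
change between conditions is

\[
\mathrm{logFC}_g = \log_2 \frac{\bar n_{g,B} + pc}{\bar n_{g,A} + pc},
\]

with normalized condition means and pseudocount \(pc = 0.5\) (the standard
half-count continuity correction, configurable). Its standard error can be
estimated two ways (`se_method`):

* **`"model"`** (default): a delta-method negative-binomial standard error,
  \(\mathrm{se}_g = \tfrac{1}{\ln 2}\sqrt{\sum_{c \in \{A,B\}}
  (1/(\bar n_{g,c}+pc) + \hat\alpha)/n_c}\), where \(\hat\alpha\) is a single
  dispersion pooled across genes (median of method-of-moments estimates,
  floored at 0). Because it depends on the data only through the condition
  means and one global dispersion, it is stable even at two replicates —
  the reason model-based Wald standard errors are the norm for count data.
* **`"welch"`**: the empirical form
  \(\sqrt{s^2_A/n_A + s^2_B/n_B}\) of the per-condition sample variances of
  \(\log_2(n+pc)\). At two replicates a per-gene sample variance has two
  degrees of freedom and is extremely noisy; that noise propagates
  multiplicatively into every Z score of the gene. The option is kept for
  designs with enough replicates and for users who want no distributional
  assumption.

Both are floored at `se_min` (default 0.05) so Z scores stay finite. With a
single replicate per condition the Welch form degrades to the uniform floor
(with a prominent message) and the model form falls back to Poisson
(\(\alpha = 0\)).

Fold changes are then optionally shrunk toward zero
(`shrink_logfc()`): with prior variance \(\tau^2\) estimated by method of
moments as \(\max(0, \mathrm{var}(\mathrm{logFC}) -
\overline{\mathrm{se}^2})\), each gene's fold change is multiplied by
\(\tau^2/(\tau^2 + \mathrm{se}_g^2)\). Precise estimates pass through nearly
unchanged; noisy ones are attenuated. Shrinkage never changes a sign and
never increases a magnitude, so the Pareto semantics below are unaffected in
direction. Both layers are shrunk before combination. This is deliberately a
simple empirical-Bayes normal shrinkage, not a full NB generalized linear
model with adaptive priors: the downstream ranking needs only (logFC, se)
pairs with the qualitative property that low-information estimates are
pulled toward zero, and the interface accepts externally computed
(logFC, se) tables from any differential-analysis tool for users who prefer
theirs.

The two layers combine into the per-gene, per-mark Z score

\[
Z_{g,h} \;=\; \frac{\mathrm{logFC}^{(\mathrm{RNA})}_g}{\mathrm{se}^{(\mathrm{RNA})}_g}
\cdot \frac{\mathrm{logFC}^{(\mathrm{ChIP})}_{g,h}}{\mathrm{se}^{(\mathrm{ChIP})}_{g,h}} .
\]

\(Z_{g,h}\) is large and positive when expression and the mark change
strongly in the **same** direction (both up or both down), and negative when
they oppose each other. The denominator is the per-gene standard error of
the fold-change estimate — not an across-gene constant, which would reduce Z
to a rescaled product of fold changes and could not reflect gene-specific
uncertainty. Note the symmetry: a concordantly *down*-regulated gene
(expression down, activating marks down, repressive marks up) produces the
same Z-score signature as a concordantly up-regulated one; the method
prioritizes consistency of change, not its direction.

## Prioritization: Pareto fronts

With \(n\) marks each gene has an objective vector
\((\alpha_1 Z_{g,1}, \dots, \alpha_n Z_{g,n})\), where \(\alpha_i = +1\) for
activating and \(-1\) for repressive marks, so that every component is
maximized — equivalently, Z scores of repressive marks are minimized. The
sign flip happens in exactly one place (`signed_objectives()`), and the
reported tables always show the raw Z scores.

Gene *a* dominates gene *b* if *a* is at least as good in every objective
and strictly better in at least one. Front 1 is the set of non-dominated
genes; front 2 the non-dominated set after front 1 is removed; and so on.
Genes with identical vectors are co-ranked. `assign_fronts()` implements
this as a dominance-count peeling sort (pairwise dominance established once
with vectorized comparisons, then fronts peeled by decrementing dominator
counts); `brute_force_fronts()` is an independent quadratic oracle that
re-derives each front literally from the definition and is used to
cross-check the fast path in the tests. Useful invariants, all tested:
fronts are invariant under strictly increasing per-objective transforms;
deleting front 1 and re-ranking shifts all remaining fronts down by one; and
with a single mark the fronts are simply the descending order of the signed
Z with ties co-ranked.

To compare prioritizations, `enrichment_score()` computes the plain fraction
\(f_i = |G \cap GO_i| / |G|\) of a gene list annotated with a term, and
`cumulative_front_scores()` traces that fraction as fronts are accumulated
from the top. This is a descriptive score, not a significance test — no
background model, ontology propagation, or multiple-testing machinery.

## The synthetic experiment generator

`sim_config()` / `simulate_experiment()` generate a fully self-contained
two-condition experiment so every stage is testable without downloads: a GTF
annotation on one synthetic chromosome, kallisto-style transcript abundance
tables per RNA sample, per-mark ChIP data (either region-count tables or SAM
alignment files whose reads are placed uniformly inside the target windows
and realize the simulated counts exactly), and a truth table. Defaults
describe a realistic replicated design: 500 genes with 1–3 promoters each,
2 replicates per condition, four marks (H3K4me3 and H3K27ac activating at
promoters, H3K27me3 repressive at promoters, H3K36me3 activating over gene
bodies), negative-binomial counts with size 10, lognormal baselines (RNA
mean counts around 200 with sdlog 1; promoter ChIP counts around 100 with
sdlog 0.7), and a planted effect of |log2FC| = 2. Baseline mark abundance is
correlated with baseline expression (coupling 0.5, sign per mark direction),
reproducing the cross-layer correlation structure the QC heatmap detects in
real data. Planted classes are disjoint: 10 concordant-up genes (RNA up,
activating marks up, repressive down), 10 concordant-down (all reversed),
10 discordant (RNA up, every mark moved the opposite way), the rest null.
Everything derives from one seed; the same configuration reproduces the
experiment byte for byte.

What the generator does *not* emulate: peak shape and fragment-size
structure (reads are uniform in windows), enhancer signal, input/IgG
background, realistic read sequences and qualities, batch effects, and
mark-mark dependence beyond the shared expression coupling. Tests passing on
this generator therefore validate the *computational* contracts — counting,
matching, normalization, Z-score and front algebra, end-to-end plumbing —
not robustness to the full messiness of real ChIP-Seq.

## Numerical choices and degenerate inputs

* Promoter windows are `[t - 1 - w/2, t - 1 + w/2)` for a 1-based TSS `t`,
  clipped at position 0; unclipped windows have width exactly `w`. Centering
  an even window on a single base is asymmetric by one position; the
  convention is applied identically on both strands.
* Gene counts from transcript abundances are summed then rounded half away
  from zero (R's `round()` rounds half to even, which would bias sums of
  `x.5` values downward).
* `match_highest` ties break by smallest TSS; identical objective vectors
  share a Pareto front; ranking output is ordered by front, then gene id.
* Genes all-zero in both conditions are excluded before fold-change
  estimation; genes missing from any layer are dropped (with a message)
  before Z-score combination; genes with non-finite Z are excluded (with a
  message) before ranking. Nothing is imputed: a missing objective would
  make dominance undefined.
* `se_min = 0.05` keeps Z finite when an estimated standard error
  degenerates to zero; \(\tau^2 = 0\) (no signal beyond noise) shrinks all
  fold changes to zero with a warning rather than silently.

## Problem sizes

The test suite and the reproduction script run the full workflow at the
default study conditions (500 genes, 4 marks, 20 replicate simulations for
the stochastic recovery property) and verify the front algebra against the
brute-force oracle on 200 random instances of up to 500 genes and 6
objectives; these sizes exercise every code path at full default scale while
keeping a complete run in the order of a minute.

## Known limitations

* Enhancer–gene assignment is out of scope; signal is attributed to genes
  only through promoter windows and gene bodies.
* The differential layer is intentionally lightweight: no per-gene
  dispersion estimation, no Wald/likelihood-ratio tests, no multiple-testing
  correction — the ranking is by Pareto fronts, not significance. Externally
  computed (logFC, se) tables can be supplied where a full NB model is
  preferred.
* With few replicates, genes whose evidence is strong in every layer still
  spread over several adjacent fronts (their objective vectors share the
  RNA t-statistic as a common factor and are therefore nearly ordered);
  front membership near the boundary should be read as approximately, not
  sharply, ranked.
* Paired-end fragments are not reconstructed: each mapped segment counts
  once.
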