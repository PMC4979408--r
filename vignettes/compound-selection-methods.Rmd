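---
title: "Methods: connectivity-based compound selection and target annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based compound selection and target annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmselect)
```

# The problem

Directing pluripotent stem cells toward a target tissue with small
molecules requires choosing, from thousands of candidate compounds, the few
whose transcriptional effect pushes cells in the desired direction.
`cmselect` treats this as a signature-matching problem: the desired
direction is the ranked differential expression profile of the starting
cell state versus the target tissue, and each compound is represented by
the genes it most up- and downregulates. Compounds whose signatures sit at
the correct extremes of the tissue profile are candidate
differentiation-promoting agents; compounds at the opposite extremes are
candidate reversers, which is the classic drug-repositioning reading of the
same statistic.

# Connectivity model

## The ranked tissue profile

The tissue contrast enters as a two-class expression matrix (GCT), a
phenotype file (CLS) and a probe-to-symbol map (CHIP). Probes are collapsed
to genes before ranking; the default collapse takes each gene's per-sample
maximum over its probes (`mode = "max"`), the convention of GSEA's
`max_probe`, because the largest-signal probe is the least likely to be a
failed hybridization. `mean` is available for platforms where probe effects
are homogeneous.

Two ranking metrics are provided. `signal2noise`,
$(\mu_A - \mu_B)/(\sigma_A + \sigma_B)$, is the default because it
penalizes within-class variance and is the conventional default for
two-class microarray contrasts; each class standard deviation is floored at
$0.2\,|\mu|$ (0.2 when $\mu = 0$), which prevents near-constant genes from
reaching absurd scores on small sample counts, and at least three samples
per class are required for the variance estimate to mean anything.
`log2_ratio_of_classes` is the alternative for very small designs; with
pre-logged data (`logged = TRUE`, the common case for GEO series matrices)
it reduces to a difference of class means. Orientation is always *first CLS
class minus second*, so the sign convention is fixed by the phenotype file
and echoed by the CLI log; a profile named "stem cells vs heart" therefore
has stem-cell-high genes on top.

Ties are broken by gene symbol, ascending, making every ranking
reproducible across runs and platforms. Genes whose class means are both
zero get metric 0 rather than an error; a linear-scale ratio against a
single zero mean is an error, because it indicates the data were already
logged.

## Compound signatures

A compound instance (one compound × dose × cell line experiment) is
represented by its $x$ most up- and $x$ most downregulated genes by log2
treatment-versus-vehicle ratio. The default $x = 50$ per side: large enough
that a handful of platform-specific symbol mismatches do not starve the
statistic, small enough that the signature stays specific to the
perturbation. Signatures load from GMT files under a paired-set convention
(`<instance>_UP` / `<instance>_DN`); incomplete pairs are excluded and
reported rather than silently scored one-sided.

## The enrichment score

For a ranked list of $N$ genes with metric values $m_i$ and a query set
with $N_h$ members present in the list, the running sum gains
$|m_i|^p / N_R$ at each hit ($N_R = \sum_{\text{hits}} |m_i|^p$) and loses
$1/(N - N_h)$ at each miss. The enrichment score is the signed value of the
running sum at its maximum absolute deviation — a single statistic in
$[-1, 1]$, $+1$ exactly when the query occupies the top of the list and
$-1$ when it occupies the bottom. The default weight exponent is $p = 1$
(the weighted Kolmogorov–Smirnov statistic); $p = 0$ recovers the
unweighted KS walk of the original Connectivity Map and is retained for
comparability.

The two per-signature scores combine as
$\text{score} = (\text{score}_{up} - \text{score}_{down})/2$, in all cases:
no zeroing is applied when the two scores share a sign. The formula has no
side condition, and discarding same-sign pairs silently would hide
ambiguous instances; instead the output flags `sign_agreement` so users can
filter if they want the stricter convention. Instances are ranked in both
directions (`rank_positive` for mimics, `rank_negative` for reversers),
with ties shared in `source_id` order consistently in both directions.
Ranking granularity is the instance; an optional per-compound aggregation
reports each compound's extreme combined score but is off by default, since
dose and cell line legitimately change a compound's signature.

Leading-edge genes — the query genes at or before the running-sum peak
(at or after it, for negative scores) — are reported per signature side, as
they are the genes that actually carry a match and the natural starting
point for mode-of-action reading.

## Numerical choices

* **Peak tie-break.** Among positions attaining the maximal
  $|$deviation$|$, the earliest is taken. The comparison uses an absolute
  tolerance of $10^{-9}$ so that the choice is invariant to floating-point
  accumulation order; the test-suite oracle (an $O(N^2)$ prefix-sum
  recomputation) applies the same rule and must agree to $10^{-12}$.
* **All-zero-metric hits.** If $p = 1$ and every hit has metric exactly 0,
  $N_R = 0$; hit weights then fall back to the uniform $p = 0$ form, so the
  score remains defined instead of dividing by zero. This arises only on
  degenerate (e.g. constant) profiles.
* **Missing query genes** are dropped and counted (`hits_missing`), with an
  error only on empty overlap — cross-platform symbol gaps are routine and
  should not abort a 6000-instance screen.
* **Null substrate.** The empirical null helper scores uniformly random
  gene sets on a fixed list. On a list whose metric values are a single
  asymmetric draw (e.g. sorted Gaussians), the null mean conditional on
  that list carries a small list-specific offset, because the top and
  bottom $|m|$ profiles are not exact mirror images — this is a property of
  the weighted statistic, not an implementation artifact. Where a null
  centred exactly on zero is wanted (as in the package's own reference
  computations), the list is built with strictly decreasing antisymmetric
  metric values ($m_i = -m_{N+1-i}$), under which the null is symmetric by
  construction.

# Target prediction model

## Training data and filtering

Bioactivity triples (compound, target, affinity, assay confidence) are
unit-normalized to nM at read time; all threshold logic then lives in one
unit. Training keeps a pair iff affinity $< 10\ \mu M$ (strict) and
confidence $\in \{9, 10\}$ — the conventional "active, directly assigned
target" cut for this kind of model. Activity is an existence criterion
across assays: one passing assay makes the pair active. Pairs are
deduplicated to unique compounds per target, so assay multiplicity never
inflates counts.

## Fingerprints and standardization

Structures are standardized before fingerprinting: aromatization, removal
of explicit hydrogens, reduction of salts/mixtures to the largest fragment
by heavy-atom count, neutralization of ±1 charges, canonicalization. The
operation is idempotent, which the suite checks over a curated list of real
drug structures. Fingerprints are ECFP4 (circular substructures of radius
≤ 2) computed through OpenBabel and represented as sparse sets of set-bit
identifiers in a 4096-bit folded space. Folding can in principle alias two
substructures onto one bit; at 4096 bits and drug-sized molecules
(typically 30–80 set bits) collisions are rare, and the naive Bayes layer
is agnostic to the feature source — the model-correctness tests run on
unfolded abstract integer features precisely so that fingerprint folding
and classifier behaviour are tested independently.

## The classifier

One model per target stores the unique-active count $n_t$ and per-feature
active counts $A_{tf}$; globally the training size $n$ and feature totals
$T_f$ are shared. With prior $P(t) = n_t/n$, a query fingerprint $F$ scores

$$ \mathrm{score}(t \mid F) \;=\; \sum_{f \in F}
   \log\frac{A_{tf} + 1}{T_f\,P(t) + 1}. $$

The Laplacian correction pulls each per-feature likelihood ratio toward 1,
so a feature never seen in training contributes exactly
$\log(1/1) = 0$ — unseen chemistry is neutral, not penalized. The score is
a sum of per-feature terms (checked exactly in the suite), unbounded, and
used only for ranking targets within a compound; it is not a calibrated
probability. The default report keeps the top 5 targets per compound — deep
enough to read a mechanism hypothesis, shallow enough to stay reviewable —
and compounds without a parseable structure receive all-zero scores with a
flag rather than being dropped.

Predictions matching a measured triple carry the minimum measured affinity
across assays as direct experimental support.

# Disease annotation and the integrated report

Predicted targets map to gene symbols via a gene–protein table and gain the
inference score of that gene for one user-chosen disease from a CTD-style
link table. The disease is a required parameter, not a constant: the method
is general across differentiation settings and diseases. Unmapped targets
are flagged and scored 0; an absent disease id degrades to all-zero scores
with a warning.

The final report joins, per instance: connectivity scores and both ranks,
the compound's approved-drug flag, and its predicted targets with support
and disease scores. Connectivity values pass through bit-identical — no
layer reweights another, and no meta-score is invented. Which evidence to
weight, and how, is left to the user, because any fixed fusion rule would
encode a preference the data do not determine.

# Synthetic fixtures: what they do and do not show

The generators produce every input with known ground truth,
deterministically per seed:

* **Expression**: log2-scale values, per-gene baseline means
  $\sim N(7, 2)$ (a log-normal expression distribution), additive Gaussian
  noise (sd 0.5), 5 samples per class, 1000 genes of which 100 are planted
  differential at log2 effect 2 (half up, half down), and 10% of genes
  measured by a second, slightly noisier probe. These sizes keep a full
  pipeline run in seconds while leaving the planted/background separation
  non-trivial.
* **Instances**: 100 signatures of 50+50 genes; planted mimics sample
  their up set from the tissue profile's top decile and their down set from
  the bottom decile, reversers the converse, background uniformly.
* **Bioactivities**: 20 targets × 3 private features, 200 compounds whose
  abstract fingerprints carry their true target's features plus 3 of 50
  shared noise features; 20% of rows are generated to violate the training
  filter so rejection paths are exercised.

What passing on these fixtures shows: the statistics, filters, joins and
rankings do exactly what their definitions say, and planted signal of
realistic strength is recovered through the whole pipeline. What it does
not show: robustness to real microarray probe-effect structure, batch
effects, platform symbol drift, or the topology of real chemical space —
fixtures are deliberately idealized, and claims about real CMap/GEO/ChEMBL
behaviour require real data through the same file interfaces.

# Known limitations

* The enrichment score comes with an empirical-null helper but no
  FDR/normalized-enrichment machinery; the method's output is a ranking,
  not a calibrated significance statement.
* Signal-to-noise with the variance floor is the only variance treatment;
  there is no moderated/shrunken differential statistic, and no multi-class
  contrasts.
* Naive Bayes scores are uncalibrated and comparable only within a
  compound; thresholding them across compounds is not supported.
* The standardization contract operates at SMILES level; conformer-level
  cleanup has no effect on 2D circular fingerprints and is not performed.
* Signature size, weight exponent and the 10 μM/confidence cut are
  parameters with conventional defaults, not fitted quantities.
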