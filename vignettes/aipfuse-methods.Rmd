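---
title: "Methods: fused random-forest prediction of anti-inflammatory peptides"
author: "aipfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused random-forest prediction of anti-inflammatory peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aipfuse)
```

## The problem

Anti-inflammatory peptides (AIPs) are short sequences — here 1 to 25
residues — that induce anti-inflammatory cytokines (IL-10, IL-4, IL-13 and
others) in T-cell assays, making them candidate therapeutics for autoimmune
and inflammatory disease. Assaying peptides is slow and expensive, so a
sequence-based classifier that ranks candidates before synthesis is
valuable. `aipfuse` implements such a classifier: several complementary
feature encodings of the same peptide, one random-forest scorer per
encoding, and a convex fusion of the per-encoder scores, with decision
cutoffs calibrated to target specificities so a user can ask for
high-confidence calls or high-recall calls explicitly.

## Sequence representation

Every peptide is validated against the 20 standard amino-acid letters,
truncated to its first 25 residues if longer, and left-aligned into a
25-symbol window padded with gaps (`-`). All encoders consume this padded
window, so every feature vector has a fixed dimension regardless of peptide
length. For the positional enrichment analysis a separate 15-symbol
N-terminal window is used in which "no residue" is coded `O` — N-terminal
positions carry most of the activity signal in short therapeutic peptides,
and the distinct symbol keeps "short peptide" from masquerading as any
amino acid.

## The five encoders

**KSAAP** (k-spaced amino-acid-pair composition). For each spacing
$k = 0, \dots, 4$ and each ordered residue pair $(a, b)$, the fraction of
gap-free position pairs $(i, i+k+1)$ forming $(a,b)$. Each of the 5 blocks
has $20 \times 20 = 400$ entries, giving 2000 dimensions. The denominator
counts only gap-free pairs, which makes the encoding invariant to padding
and each block a proper composition (sums to 1 whenever any valid pair
exists). Pair order is frozen — alphabetical, first residue major — so
models are portable.

**AAindex.** Position-major physicochemical profile: for each of the 25
window positions, the values of 8 amino-acid indices for the residue there
(gaps contribute 0), giving 200 dimensions. The 8 default indices are
classical, widely used scales (Kyte–Doolittle hydropathy, Hopp–Woods
hydrophilicity, residue mass, Zimmerman isoelectric point, Chou–Fasman
helix and sheet propensities, Grantham polarity and volume), min–max
scaled to $[0,1]$ per index. The selection is deliberately configurable
(`read_aaindex_table()`): any 8-or-more-row index table with one column
per amino acid can be substituted, because which indices serve best is an
empirical, dataset-dependent question.

**pKSAAP.** The KSAAP construction applied to a position-specific scoring
matrix (PSSM) instead of the literal sequence. Raw log-odds scores $x$ are
squashed to $M = 1/(1+e^{-x})$ and the feature for spacing $k$ and pair
$(a,b)$ is $\sum_i M_{i,a} M_{i+k+1,b} / (L-k-1)$ over the $L-k-1$ valid
positions. When the squashed profile is exactly one-hot this reduces
algebraically to the sequence KSAAP — a degeneracy the package exploits
both as a test oracle and as a fallback: peptides without a profile file
get a one-hot self-profile (built from $\pm 999$ scores, which squash to
exact 0/1 in double precision), so the pipeline runs end to end without a
profile search. Profile generation itself (iterative BLAST searching) is
out of scope; only the standard ASCII matrix files are read.

**SPIDER2 / PEP2D structural tables.** Per-residue structural descriptors
read from delimited files produced by external predictors: 8 channels
(accessible surface area, four backbone torsion angles, three
secondary-structure propensities) or 3 channels (helix/sheet/coil
probabilities, each row summing to 1). Encoded position-major over the
25-window with zero fill, angles rescaled to $[-1,1]$ by dividing by 180
so no channel dwarfs the others. These encoders activate only when tables
are supplied; the default model uses the three sequence-derived encoders,
which in practice carry the weight anyway.

## Scoring and fusion

Each active encoder's matrix trains its own random forest: 1000 unpruned
Gini-split trees by default, `mtry` $= \lfloor\sqrt{K}\rfloor$ of the $K$
features per split, and the peptide's score is the fraction of trees
voting positive — a probability-like value in $[0,1]$. The engine is
`ranger` with a fixed seed and one thread, so training and scoring are
bit-reproducible.

The fused score is the convex combination

$$\mathrm{combined} = w_1\,\mathrm{SPIDER2} + w_2\,\mathrm{PEP2D} +
  w_3\,\mathrm{KSAAP} + w_4\,\mathrm{AAindex} + w_5\,\mathrm{pKSAAP},
  \qquad w_i \ge 0,\ \textstyle\sum_i w_i = 1.$$

The weights are found by exhaustive search of the 0.05-step lattice on the
simplex — $\binom{24}{4} = 10{,}626$ candidates for five encoders — keeping
the vector that maximizes the AUC of the combined score. Two details
matter:

* **Out-of-fold scores only.** The search (and the threshold calibration
  below) consumes scores from stratified 10-fold cross-validation, where
  each peptide is scored by a forest that never saw it. Resubstitution
  scores would make the fused AUC optimistically biased and the calibrated
  cutoffs too aggressive. The search maximizes the AUC of the pooled
  out-of-fold scores (fold-wise averaging is the alternative; pooled is
  simpler and uses every pairwise comparison).
* **Deterministic ties.** Candidates are enumerated in lexicographic order
  of $(w_1, \dots, w_5)$, each coordinate ascending, and the first maximum
  is kept. With identical score columns every candidate ties and the
  result is exactly $(0,0,0,0,1)$ — reproducibility is preferred over an
  arbitrary choice. Encoders that were not run are constrained to weight 0.

## Specificity-anchored thresholds

Rather than a single 0.5 cutoff, the model calibrates three cutoffs so the
prediction rule `positive iff score >= cutoff` attains target
specificities of 0.9 (high), 0.8 (moderate) and 0.7 (low) on the
out-of-fold fused scores. For each target the smallest candidate cutoff
(the observed scores plus one value just above the maximum) whose achieved
specificity reaches the target is kept, and the achieved value is
reported. Because the above-maximum candidate always attains specificity
1, every target is formally attainable; if the cutoff degenerates there
the model warns that it is predicting everything negative. Cutoffs are
non-increasing in the target, so the three calls are nested: a peptide
called positive at high confidence is positive at all three levels.
Specificity on a fresh dataset will differ from the calibrated value —
the calibration transfers the operating point, not a guarantee.

## Evaluation toolkit

Threshold metrics are the standard four: sensitivity, specificity,
accuracy, and Matthews correlation coefficient with denominator
$\sqrt{(TN{+}FN)(TP{+}FP)(TN{+}FP)(TP{+}FN)}$. Any metric with a zero
denominator is reported as `NA`, never coerced to 0. AUC uses the rank
(Mann–Whitney) statistic with mid-ranks, which equals the trapezoid ROC
area for tie-free scores and remains well defined with ties; ROC points
are exported for plotting. Cross-validation folds are random but
stratified, keeping each fold's class ratio within one sample of the
global ratio — the variance-reduction standard even where a plain random
split is described.

For interpretation, features can be ranked by information gain:
$IG = H(\text{labels}) - H(\text{labels} \mid \text{feature})$ in bits,
with continuous features discretized into 10 equal-width bins over their
observed range (deterministic and simple; the bin count is configurable).
Ranking is reporting only — selection did not improve the classifier, so
trained forests always see full feature vectors, with spacing motifs
rendered in `LxL` style for the top pairs.

Positional class contrasts come in two forms. A Welch two-sample t-test on
per-peptide residue indicators, per position and residue of the 15-symbol
analysis window (the computation behind two-sample sequence logos), flags
enriched/depleted residues at $p < 0.05$. A Kruskal–Wallis rank test per
position compares any per-peptide positional value — the average PSSM
score per position, an AAindex channel, or a structural channel — between
classes, Bonferroni-corrected over the 15 positions. Degenerate inputs are
resolved conservatively: all-tied positions get $p = 1$, and constant
indicator pairs get $p = 1$ when the groups agree.

## The synthetic-data generator

Real AIP training corpora are assembled from immunology databases and
external servers; to keep every stage testable offline the package ships a
generator that emulates the structure the method assumes:

* lengths from a rounded normal, mean 15, s.d. 4.5, truncated to $[4, 25]$
  — matching the length profile of curated AIP sets;
* uniform background residue usage (a natural-frequency background is
  available), which makes the zero-effect null exactly exchangeable;
* class-specific planted motifs, by default leucine-dominated enrichment
  at N-terminal positions 2, 5, 7, 8, 10, 11 and 15 for positives and
  D/T/V enrichment for negatives — the pattern reported for real AIP
  versus non-AIP sets. At a planted position the residue comes from the
  class's set with its background probability boosted by `effect_size` on
  the log-odds scale; the default effect size of 3 lifts a single planted
  residue from 5% to ~51%, a deliberately strong, recoverable signal.
  Planting events within a peptide are driven by one shared latent
  uniform, so they co-occur as they do in motif-bearing peptide families
  while each position keeps exactly its marginal probability;
* matched per-peptide PSSM profiles whose rows peak at the true residue
  ($\pm$`concentration` plus unit Gaussian noise, rounded to integers as
  profile searches print them), written in the standard ASCII layout so
  the reader is exercised; and plausible structural tables (simplex rows
  for secondary-structure probabilities, angles in $[-180, 180]$, ASA
  $\ge 0$).

What the generator does **not** emulate: natural residue covariance,
shared evolutionary ancestry between peptides (profiles carry no
information beyond the observed sequence), realistic cytokine-assay label
noise, and homology between training and test peptides. Passing the
recovery tests therefore shows the pipeline's machinery is sound — it does
not certify performance on real data. One measurable consequence: because
the planted signal sits at fixed absolute positions, the position-major
AAindex encoder reads it slightly better (out-of-fold AUC ≈ 0.92–0.93)
than the position-agnostic pair encoders (KSAAP ≈ 0.90, pKSAAP ≈ 0.87),
and the fused weights typically concentrate on AAindex. On real AIP data
the reverse is reported — pair-composition features dominate — because
real enrichment is compositional and family-structured rather than pinned
to exact positions.

## Numerical and design choices

* Pair order, PSSM column order (stored alphabetically; files read in the
  standard search-tool order), and feature names are frozen and documented
  so serialized models remain valid.
* Logistic squashing of PSSM scores is computed by `plogis`;
  equal-width IG discretization uses the observed range, so a constant
  feature scores exactly 0.
* Non-standard letters (B, J, O, U, X, Z) are rejected with a diagnostic
  naming the symbol and position; lower-case input is upper-cased with a
  warning; over-long peptides are truncated to their first 25 residues
  with a warning (validation precedes truncation).
* Labels may come from a two-column TSV, per-class FASTA files, or a
  `label=` header token.
* All randomness — generator, folds, forests — is derived from explicit
  integer seeds; repeated runs are bit-identical.

## Problem sizes used in the shipped checks

The package's own test and verification runs use scaled study sizes chosen
to exercise the full pipeline on a single CPU: pipeline-recovery runs use
300+300 training and 150+150 held-out peptides with 200-tree forests and
5-fold cross-validation over 5 generator seeds (held-out AUC 0.91–0.94 at
the default effect size; 0.50 ± 0.03 under the null); enrichment
calibration uses 100 generator seeds of 100+100 peptides; oracle
equivalence checks (brute-force pair enumeration, pairwise AUC, direct
metric formulas) use 200, 200 and 100 random instances. Full-size settings
(1000 trees, 10-fold cross-validation) remain the defaults of
`aip_train()`.

## Known limitations

* The fused model is only as good as its calibration data; with a few
  hundred peptides the 0.05 weight lattice can overfit the out-of-fold
  AUC by small margins, and near-tied encoders make the selected weights
  unstable between seeds even when the fused score barely changes.
* Achieved specificity is calibrated on cross-validation scores and will
  drift on data from a different distribution.
* Equal-width IG discretization is sensitive to outliers in heavy-tailed
  features; rank-based binning is not implemented.
* The Welch indicator test inherits the discreteness of small samples and
  is mildly conservative (measured null flag rate ≈ 4.4% at the 5%
  level).
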