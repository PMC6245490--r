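---
title: "Sliding-window motif scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window motif scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swscan)
```

## The problem and the model

Calmodulin binds its targets through short linear motifs (SLiMs) in
largely disordered regions, so CaM-target prediction cannot rely on a
conserved domain. `swscan` instead quantifies, for every protein and
every motif in a set, how much motif-like signal the sequence carries,
and uses those quantities as classification features.

Given a motif of width $W$ and a protein $A$ of length $L$, every one of
the $L - W + 1$ overlapping windows $a$ is a potential site. Two window
scores are implemented.

**Probability-matrix scoring (SWS_PPM).** A motif is a $W \times 20$
position-specific probability matrix $X$ (rows sum to 1; columns in the
fixed order A, C, D, …, Y). The window score is the sum of the observed
residues' probabilities,
$$P(a \mid X) = \sum_{i=1}^{W} X[i, a_i] \in [0, W].$$
A window is a *true site* when $P(a \mid X) \ge \tau W$. The per-protein
features are the total over true sites, $S$, and the average
$T = S / N$ over the $N$ true sites.

**Regular-expression scoring (SWS_RE).** A motif is a per-position set of
admissible residues (single letter, bracket class, or the wildcard `x`).
A window either matches at every position or scores 0. A match scores
$\sum_i 1/|\text{set}_i|$ with wildcards contributing 1, so rarer
patterns score higher per site. Match alone defines a site — no
$\tau$ threshold is applied, and since every match of a given motif
carries the same score, $T$ equals that constant whenever $N \ge 1$.

The proteins × motifs matrix of $S$ (or $T$) values is the input to
feature selection and classification.

## Interpreting the threshold

The window score is a sum of $W$ probabilities, so its maximum is $W$,
not 1; a percentage criterion only makes sense relative to that maximum.
The retention rule is therefore implemented as
$P(a \mid X) \ge \tau W$ with $\tau = 0.6$ by default — the mean
per-position probability must reach 0.6 — and the comparison is
inclusive. $\tau$ is exposed in `scoring_config()`; lowering it can only
grow $S$ and $N$ (a monotonicity the test suite checks).

Two degenerate cases have fixed conventions: $N = 0$ gives $T = 0$
(the average is otherwise undefined, and features must stay total), and
$W > L$ gives zero windows, hence $S = N = T = 0$.

## Non-standard residues

Real proteomes contain ambiguity and non-standard codes (B, J, O, U, X,
Z, `*`). These are retained on read and flagged per record, but they
carry probability 0 in PSPM scoring and never match any pattern position,
including wildcards. This is the conservative choice: a window containing
an unknown residue can only lose score, and window counts are unaffected.

## Motif input and the canonical registry

PSPMs are read from MEME text/minimal format (`letter-probability
matrix` blocks). The declared alphabet is remapped to the package's
canonical column order on read, so files written with any column
convention score identically. Row sums within $1 \pm 10^{-3}$ are
renormalized; larger deviations abort with the motif and row named —
silent repair of a clearly broken matrix would corrupt every downstream
score. `write_meme_motifs()` inverts the reader to 6 decimal places.

The 14 canonical CaM-binding motif patterns (the 1-10/1-12/1-14/1-16
hydrophobic spacing classes, their basic variants, and the IQ family)
ship as a plain `name<TAB>pattern` table compiled at call time by
`canonical_motifs()`, so the registry can be audited and diffed as text.

Occupancy profiling (`occupancy_profile()`) counts motif positions where
one residue class exceeds a 50% share. The comparison is strict
(`> 0.5`), so a position split exactly 0.5/0.5 between two residues does
not count for either. The default classes are basic = {R, K} and
hydrophobic = {F, A, I, L, V, W, M, C, Y}; class membership is a
biochemical convention with fuzzy edges, so both are arguments, not
constants.

## Feature selection

*Chi-square ranking* discretizes each feature into 10 equal-frequency
bins and scores the bin × class contingency table (no continuity
correction). Bin edges are type-1 (inverse-ECDF) quantiles — actual data
values — so the ranking is invariant under any strictly monotone
transform of a feature, a property interpolated quantiles would break.
Constant features score 0; ties keep column order.

*Wrapper selection* is a greedy forward best-first search: each candidate
subset is scored by stratified cross-validated accuracy of a seeded
random forest, the best single-feature addition is taken at every step,
and the search stops after a configurable number of consecutive
non-improving expansions (default 5). The same fold assignment and
training seed are reused for every subset, so subset comparisons are
paired and the whole search is reproducible from one integer.

*Backward elimination* repeatedly removes the feature whose removal
yields the highest CV accuracy, accepting removals that leave accuracy
unchanged (this is what prunes a duplicated or redundant feature) and
stopping when every removal strictly hurts or one feature remains. Ties
among removals drop the highest-index column, keeping the earliest.

## Classifiers

The four classifiers mirror widely used defaults and are documented
rather than bit-matched to any external toolkit: k-NN with Euclidean
distance (k = 1 default; k = 3 is common for less noisy votes), an SVM
with the normalized polynomial kernel
$K'(x,y) = K(x,y)/\sqrt{K(x,x)K(y,y)}$, $K(x,y) = (x \cdot y + 1)^d$,
degree 2, cost 1, on min-max scaled features, a 100-tree random forest,
and Gaussian naive Bayes. Folds and holdout splits are stratified and
seeded; out-of-fold predictions are pooled into a single confusion table.
ROC-AUC uses each model's natural score (vote fractions, posterior, or
the SVM decision value oriented toward the positive class on the training
data). MCC returns 0 when any denominator factor vanishes, since the
coefficient is undefined there and 0 is the natural "no information"
value. The holdout series (default seeds 1–10, 90/10 split) is summarized
by the five-number box statistics.

## What the synthetic generator emulates

`generate_dataset()` builds the two-class design the pipeline assumes:
positives are background sequences with planted motif sites, negatives
are background only. Defaults, chosen once:

* **Sequence length** uniform on 150–400 residues — the scale of typical
  human proteins while keeping desk-scale runs fast.
* **Background composition** uniform (1/20 each). Uniformity keeps the
  chance-match probability of a pattern in closed form (the product of
  class sizes over $20^W$ per window), which the tests exploit; a natural
  composition can be supplied as a named frequency vector.
* **One exact site per positive, no leak, no mutation** — the cleanest
  detectable signal; all three are dials for harder regimes.

Sites are sampled from the motif itself (PSPM rows as categorical
distributions; uniform over admissible sets for patterns), optionally
mutated per residue, and embedded at non-overlapping random offsets
(re-drawn up to 100 times before erroring). Every planted
(protein, offset, motif) triple is returned, and with mutation rate 0
each annotated window is guaranteed to match the planted pattern — a
cross-module consistency the tests verify.

The end-to-end validation plants the IQ motif and scores against the
full canonical registry. IQ was chosen for its low chance-match
probability under uniform background (about $1.7 \times 10^{-6}$ per
window), so negatives stay clean and recovery failures indicate pipeline
defects rather than background collisions. The mutation-rate monotonicity
check plants three sites per positive: with one site, intermediate
mutation rates leave so few intact sites that adjacent accuracy means
drift within cross-validation noise; three sites keep each step of the
mutation grid measurably distinct.

What the generator does **not** emulate: real amino-acid composition
bias, intrinsic disorder context around true CaM-binding sites, domain
architecture, homology between sequences, and realistic protein length
distributions. Passing recovery tests therefore demonstrates that the
scoring → selection → classification chain is correct and sensitive, not
that any given accuracy will transfer to curated proteome data.

## Problem sizes and numerical choices

The validation suite runs at desk scale: oracle-equivalence checks use
1000+ random (sequence, motif) pairs with $L \le 50$, $W \le 6$ against
a literal brute-force scorer and the PCRE engine; recovery runs use
balanced $n = 200$ datasets, 3-fold CV, a 100-tree forest and ten seeds;
wrapper/elimination tests use 25-tree forests on $n \le 100$ matrices.
Scores are kept at full double precision internally; TSV export rounds
to 6 significant digits (the round-trip tolerance the tests assert).
All randomness — generation, folds, splits, forests — flows from integer
seeds, and identical configurations produce byte-identical output files.

## Known limitations

* PSPM scoring uses raw probabilities, not log-odds against a background
  model; scores of different motifs are on comparable scales only through
  the classifier, not individually calibrated (no p-values).
* Overlapping true sites are all counted; no merging is attempted, so a
  single biological site inside a low-complexity region can contribute
  several windows.
* The SVM decision-value orientation is heuristic (training-class means);
  on pathological data with inverted margins the ROC-AUC of the SVM could
  flip, though predicted classes are unaffected.
* Multi-class problems and probability calibration are out of scope; the
  pipeline is strictly binary.
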