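---
title: "Scoring miRNA-disease associations with similarity-based random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring miRNA-disease associations with similarity-based random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irfmda)
```

## The problem

Experimentally confirming that a microRNA regulates a disease is slow and
expensive, while curated catalogues such as HMDD already hold thousands of
confirmed disease–miRNA pairs. Treating the catalogue as a bipartite graph,
the task is link prediction: score every *unconfirmed* pair so that true
but not-yet-observed associations concentrate at the top of the ranking.
The guiding assumption is the standard one in this field: functionally
similar miRNAs tend to associate with phenotypically similar diseases, and
vice versa.

`irfmda()` implements a four-stage supervised pipeline: (1) balanced sample
selection, (2) similarity-based sample representation, (3) feature
selection by out-of-bag permutation variable importance, and (4) random
forest regression scoring.

## Similarity kernels

**Disease semantic similarity.** Each disease $D$ comes with a directed
acyclic graph $DAG(D)$ of its ontology ancestors (MeSH-style). Two
contribution models assign a weight to every vertex $d \in S(D)$:

- *Model 1 (decay):* $C_D(D) = 1$ and
  $C_D(d) = \Delta \cdot \max\{C_D(d') : d' \text{ child of } d \text{ in } DAG(D)\}$,
  with decay $\Delta = 0.5$ by default. Contributions fall geometrically
  with distance from $D$.
- *Model 2 (information content):* $C(d) = -\log(n_d / N)$ where $n_d$
  counts the DAGs containing $d$ and $N$ is the number of diseases in the
  collection. Ubiquitous ancestors contribute nothing; rare ones much.

Either model yields a semantic value $DV(D) = \sum_{d \in S(D)} C_D(d)$ and
the pairwise similarity

$$\mathrm{DSS}(i,j) =
\frac{\sum_{d \in S(i) \cap S(j)} \big(C_i(d) + C_j(d)\big)}{DV(i) + DV(j)},$$

which lies in $[0,1]$ with unit diagonal. Model 2's scores are invariant to
the logarithm base (it cancels in the ratio); we use the natural log. For
"the number of diseases" in model 2 we use the DAG collection's own size:
the alternative (all diseases in the study, with or without DAGs) only
rescales every contribution by a constant and therefore leaves the
similarity unchanged. If both diseases have zero semantic value (every
vertex common to all DAGs) the ratio is undefined; we define the pair's
similarity as 1 on the diagonal and 0 off it, preserving self-similarity
without inventing signal.

**Gaussian interaction profile kernel (GIPK).** Row $i$ of the binary
adjacency matrix is disease $i$'s interaction profile $IP(d_i)$ (and
column $j$ miRNA $j$'s). The kernel is

$$K(i,j) = \exp\big(-\alpha\,\lVert IP(i) - IP(j)\rVert^2\big),
\qquad
\alpha = \alpha' \Big/ \tfrac1n \sum_i \lVert IP(i)\rVert^2,$$

with raw bandwidth $\alpha' = 1$ on both axes. One routine serves both
sides (rows vs. columns). An individual all-zero profile is legal — the
novel-disease protocol creates one deliberately — and only a fully zero
profile set is an error, since the bandwidth is then undefined.

**Integration.** Where both diseases have DAGs, the integrated disease
similarity is the mean of the two semantic models; otherwise it falls back
to the kernel. For miRNAs, a precomputed functional similarity matrix is
used verbatim where it covers both entities, with the kernel as fallback.
Functional or semantic entries for entities outside the association
catalogue are ignored.

## Sample representation and selection

A pair $(d, m)$ is represented by concatenating miRNA $m$'s row of the
integrated miRNA similarity matrix ($n_m$ values) with disease $d$'s row of
the integrated disease similarity matrix ($n_d$ values) — for a 495-miRNA,
383-disease catalogue, an 878-dimensional vector. All known associations
are positives; an equal number of unconfirmed pairs is drawn uniformly
without replacement as negatives (the seed is mandatory, recorded in every
manifest). Each feature column is min–max normalised to $[0,1]$ over the
training samples; the per-column statistics are stored and re-applied
(with clipping) to prediction-time pairs. Constant columns map to 0. We
normalise the full feature matrix before selection; because the transform
is per-column, selecting first and normalising after would give identical
values on the kept columns.

## Permutation variable importance

The score of feature $j$ is the average, over the forest's trees, of the
drop in out-of-bag accuracy when $j$ is permuted:

$$S_j = \frac1B \sum_{b=1}^{B} \big(R^{oob}_b - R^{oob}_{bj}\big),$$

where tree $b$'s OOB accuracy $R^{oob}_b$ is computed by thresholding the
regression predictions at 0.5 against the 0/1 labels, and $R^{oob}_{bj}$
is the same after permuting column $j$ *within tree $b$'s OOB rows*. The
final score averages this over fold resplits (`folds`, default 10, each
forest seeing nine tenths of the data); features are ranked descending
with stable ties and the top $k$ (default 100) kept. The headline model
formulation speaks of classification accuracy while the final scorer is a
regressor; we follow the accuracy reading literally (thresholded
regression predictions) and offer an OOB-MSE-increase variant behind
`type = "mse"`.

Implementation notes: per-tree OOB membership is recovered exactly from the
recorded in-bag bootstrap counts; trees are extracted once and evaluated by
a vectorised traversal that the test suite verifies is bit-identical to the
forest's own `predict`. A tree that never splits on feature $j$ cannot
change its predictions under permutation of $j$, so its term is exactly
zero and is skipped; one permutation is drawn per (tree, feature). Trees
with empty OOB sets are skipped entirely.

## The scorer and its evaluation

The final model is a regression forest on the 0/1 labels (`ntree = 500`,
`mtry = floor(k/3)` — 33 for the 100-feature working set), scoring any pair
in $[0,1]$ after clipping. Ranking-based protocols evaluate it:

- **k-fold CV** (default $k=5$): positives are split evenly; each held-out
  positive is ranked by score against *all* unlabelled pairs of the full
  adjacency. AUC is reported both pooled over folds and per repeat.
- **Global / local LOOCV**: one positive held out at a time, ranked
  against all unlabelled pairs (global) or only those of its disease
  (local). `mode = "exact"` refits per positive; `mode = "grouped"` refits
  once per disease (all of its positives removed) — a desk-scale
  approximation, not the textbook protocol.
- **Novel-disease hold-out**: every association of one disease is removed
  before any similarity, feature or model construction; all of its
  candidate miRNAs are then scored and sorted.

Ties in ranks and in the ROC construction are handled by mean rank /
trapezoidal interpolation, so the AUC equals the Mann–Whitney probability
with ties counted one half (verified against the closed form in tests).

**Leakage policy.** Under the default `leakage = "strict"` policy the
kernel similarities, the training set, the importance ranking and the
forest are all rebuilt from the training-only adjacency in every fold or
hold-out, so no information about a test association can reach the scorer.
`leakage = "shared"` builds the similarities once from the full adjacency —
cheaper, and closer to how such pipelines are sometimes run, but mildly
optimistic; the two are exposed side by side because the choice materially
affects AUC.

## The synthetic benchmark

`make_planted_world()` generates the test substrate: diseases and miRNAs
are partitioned into latent groups; a pair associates with probability
`p_in` within a matched group and `p_out` across (defaults `nd = 40`,
`nm = 60`, `groups = 4`, `p_in = 0.35`, `p_out = 0.02` — chosen once to
give a desk-scale world with realistic sparsity, about a 10% overall
association density, that runs end-to-end in minutes on one CPU). Disease
DAGs share a per-group ancestor chain under a global root, so same-group
diseases have high model-1 similarity with hand-verifiable values; the
functional matrix is uniform noise plus a within-group boost. Everything is
reproducible byte-for-byte from the seed.

What the generator does *not* emulate: real MeSH topology (deep, tangled
DAGs), degree heterogeneity of curated catalogues (hub miRNAs), and
correlated annotation noise. Passing the synthetic benchmark therefore
shows the machinery is sound and the signal path intact — not that
catalogue-scale performance numbers transfer.

**An information ceiling worth knowing about.** Within a block, held-out
positives are exchangeable with unlabelled cells given the training data
(associations are i.i.d. Bernoulli), so no scorer can rank them above
within-block negatives better than chance. The Bayes-optimal scorer for
the default world — `p_in` on within-group cells, `p_out` elsewhere —
achieves a 5-fold CV AUC of only about 0.84–0.85 depending on the seed.
Observed pipeline AUCs around 0.80–0.81 should be read against that
ceiling, not against 1. Enlarging the world or sharpening `p_in`/`p_out`
raises the ceiling; we keep the stated defaults as the benchmark's working
point.

## Numerical and design choices

- Names are matched case-sensitively after trimming; silent case-folding
  hides curation errors.
- Similarity matrices are symmetrised by averaging after a strict asymmetry
  check (1e-8 on file input, 1e-12 on computed matrices) and written with
  10 significant digits for round-trip stability.
- Negative sampling is uniform over the zero cells, without replacement —
  equivalent in distribution to rejection sampling of random
  (disease, miRNA) combinations.
- `mtry` uses floor division; ties in feature ranking break by original
  column order (stable).
- Every stochastic step (negative draw, fold split, forest growth,
  permutations) flows from a single user-supplied seed; per-fold seeds are
  derived from it so folds are independent but reproducible.
- Desk-scale evaluation settings used by the test suite and the acceptance
  script — importance forests of 150–200 trees on a single split,
  40-feature working sets, 500-tree scorers — are the package's chosen
  problem sizes for the synthetic worlds; the catalogue-scale defaults
  (`ntree = 500`, `folds = 10`, `k = 100`) remain the documented working
  point for real snapshots.

## Known limitations

- Computing miRNA functional similarity from scratch is out of scope; the
  matrix is an input (as it is for the catalogue this method targets).
- Raw MeSH XML is not parsed; the DAG collection arrives as an edge list
  already keyed by the catalogue's disease names.
- Exact LOOCV at catalogue scale is thousands of refits; use the grouped
  approximation, or k-fold CV, for desk work.
- Scores are regression outputs clipped to $[0,1]$, not calibrated
  probabilities.
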