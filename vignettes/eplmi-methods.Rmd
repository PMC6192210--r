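---
title: "Methods: two-way diffusion scoring of lncRNA-miRNA networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-way diffusion scoring of lncRNA-miRNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eplmi)
```

## The model and its assumptions

The package treats known lncRNA–miRNA interactions as a bipartite graph
with adjacency `A` (`nl × nm`) and asks, for every unobserved pair, how
plausible an interaction is.  The working assumption is that an lncRNA
tends to interact with a *cluster* of miRNAs that share regulation
patterns, and vice versa, and that this clustering is visible in side
information: tissue/cell-line expression profiles (Pearson correlation),
shared target genes or predicted function labels (set overlap), or global
sequence alignment.  EPLMI injects the two similarity spaces into the
graph as weighted networks `A^l = LS·A` and `A^m = A·MS`, normalizes each
into forward resource shares (`C`: columns sum to 1; `R`: rows sum to 1),
and scores by one forward plus one backward diffusion hop that lands on
the observed adjacency:

$$SS_{lnc}(W) = (C R^\top) A, \qquad SS_{mir}(W) = A\,(C^\top R),$$
$$SS = \tfrac14\left[SS_{lnc}(A^l) + SS_{lnc}(A^m) + SS_{mir}(A^l) + SS_{mir}(A^m)\right].$$

No iteration beyond the single forward–backward pass is performed, and no
weights are learned; known pairs are scored alongside unknown ones (their
scores order the "competitiveness" of confirmed interactions).

### Why this exact diffusion form

The verbal description of the method — resource flows forward from one
side and backward to where it started, both weighted networks enter the
first step, the two sides are assembled into `nl × nm` matrices and
averaged — admits more than one matrix formulation, and the printed
resource-vector formulas are not dimension-consistent.  We fixed the
unique reading that preserves every stated structural fact *and* conserves
mass: because the columns of `C` and the rows of `R` each sum to one,
every term above has the same total as `A`, so `sum(SS)` equals the number
of known edges exactly.  The mirrored hop order (`R C^\top` on the lncRNA
side) is row-stochastic instead and does not conserve the total, which
would break the conservation property the package treats as an invariant.
The backward operator is factored out (`two_way_diffusion`) so alternative
readings remain swappable.  An independent path-enumeration oracle — a
scalar-loop implementation of all two-hop resource paths — pins the
implementation down on every small instance (`nl, nm ≤ 5`) to 1e-10.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 1e-11 | value replacing zeros of `A^l`, `A^m`; keeps the column/row normalizations defined after an edge is held out. Scores move by < 1e-6 as it varies over [1e-12, 1e-10] (tested). |
| FS normalization | `product` | set-overlap denominator. The printed form divides by the *product* of set sizes, so identical sets of size n score 1/n; a geometric (Ochiai) form that restores self-similarity 1 is available, suggesting a dropped square root in the source's typesetting. The default stays faithful to the printed formula. |
| alignment scores | 2 / −1 / −0.5 / −0.1 | match, mismatch, gap open, gap extend. The source states match 2, gap open −0.5 and an extension printed as "<0.1"; the mismatch is unstated. We use the canonical 2/−1/−0.5/−0.1 parameterization of the cited alignment library, all four configurable. A gap of length L costs open + (L−1)·extend. |
| sequence normalization | `self_geometric` | `S(a,b)/\sqrt{S(a,a)S(b,b)}` clipped to [0,1]; whether raw or normalized scores fed the original diffusion is unstated, so the choice is a config option rather than a guess presented as truth. |
| CF/SVD/LFM/Katz hyperparameters | rank 20, factors 20, reg 0.01, lr 0.01, 200 epochs, β 0.01, kmax 4 | unstated in the source; fixed here for reproducibility of our own comparisons, not as a claim about the original runs. |
| `min_degree`, `sd_multiplier` | 2 / 0.5 | coherence filters: focal entities need strictly more than `min_degree` links (the well-studied partner-side analysis uses 5); highlighting uses 0.5 × SD of the identified-group means. |

## Evaluation protocol

LOOCV removes each known edge in turn, rescores, and ranks the held-out
pair among **all** unidentified pairs of the full grid — the candidate set
has size `nl·nm − |edges|` in every iteration, matching the corpus-scale
arithmetic 780·275 − 5348 = 209 152.  Ties take the average rank.  The
global AUC uses the threshold-on-rank construction: with candidate count
`c` and rank `r_i`, `AUC = mean((c + 1 − r_i)/c)`, which coincides with
the tie-corrected Mann–Whitney statistic when a single fixed score matrix
is ranked.  Repeated k-fold CV partitions the *edges* (not the entities)
uniformly at random per repeat (RNG seeded `seed + repeat`), computes one
AUC per fold against all unidentified pairs, and reports per-fold AUCs
with mean and SD; whether to average per fold or pool per repeat was an
open choice, and per-fold averaging was adopted (one ROC per round).
Training positives are never counted as negatives.

The coherence analysis reads "average correlation of a partner group" as
the mean over all unordered within-group pairs — the group's internal
coherence.  The source's description swaps the focal and grouped sides at
one point, so the focal side and degree filter are exposed as parameters
and both analyses are runnable.  Coherence uses the raw similarity kernel
(negative correlations included); clipping applies only to diffusion
inputs, where shares must be nonnegative.  The unidentified group uses all
covered non-partners, not a sample.

## The synthetic generator

`generate_dataset()` states the world the tests measure: paired blocks of
lncRNAs and miRNAs (round-robin assignment, 4 blocks by default over 60
lncRNAs and 40 miRNAs), edges Bernoulli(0.5) within a paired block and
Bernoulli(0.03) between, and per-entity expression profiles equal to a
per-block Gaussian template plus N(0, 0.5²) noise, over 22 conditions for
lncRNAs and 172 for miRNAs (the condition counts of the real panels the
method was built for).  Block templates are paired by index so "similar
lncRNAs interact with similar miRNAs" is exactly the planted signal.
Defaults were chosen once as a realistic strength of that signal
(within-block profile correlation ≈ 0.8 in expectation, between-block
≈ 0) and are not adjusted to test outcomes.

What the generator does *not* emulate: the heavy degree skew of CLIP-seq
corpora, tissue-specific expression sparsity, shared miRNA-family sequence
structure, and any mismatch between expression similarity and interaction
propensity.  A green test on this world therefore establishes internal
correctness and sane relative behavior, not real-data AUCs; reproducing
the published corpus figures would require the external databases and is
out of scope.

## Numerical choices and degenerate inputs

- Constant expression profiles have undefined correlation; they get
  similarity 0 and a logged message, never an error.
- Negative correlations are clipped to zero before diffusion; the diagonal
  is overwritten with the kernel's self-similarity (1).
- Alignment scores from Biostrings are accumulated in single precision;
  oracle comparisons use 1e-6, everything else in the package is double
  precision with stated tolerances (symmetry 1e-9, oracle equivalence
  1e-10).
- Ranking ties, everywhere, use the average-rank convention; output files
  break score ties by lexicographic id so reruns are byte-identical.
- Removing an edge can leave an all-zero row or column; ε keeps EPLMI
  defined, CF logs a zero row/column, and the evaluation drivers proceed.
- All seeded helpers save and restore the caller's RNG state; the CLI
  derives every stream from `--seed` and provenance records omit
  timestamps, so identical commands produce identical bytes.

## Known limitations

- On the planted-block world, the acceptance suite measures (20 seeds,
  LOOCV) mean AUCs of 0.826 for the two-way diffusion against 0.841/0.843
  for the two CF variants, 0.845 for Katz, 0.704 for the LFM, 0.643 for
  SVD and 0.501 for random scores.  The diffusion clears its absolute bar
  (≥ 0.80, far above random) but does **not** beat three of the five
  baselines there, and the corresponding acceptance assertion is left
  failing rather than weakened.  The reason is structural: the generator
  hands every method the *true* block similarity, and one-hop
  neighborhood methods with the true kernel are close to optimal on such
  a world, while ε-smoothed two-hop diffusion spreads some mass across
  blocks.  The regime in which diffusion wins — noisy similarity, sparse
  uneven coverage — is precisely what the generator deliberately does not
  model.
- The method cannot score entities without the chosen feature (profile,
  annotation set, or sequence); `align_entities()` drops them before
  modelling rather than imputing.
- Sequence similarity uses global alignment of full-length transcripts;
  for lncRNAs spanning orders of magnitude in length this is a blunt
  instrument (miRNA binding involves short sites), which is why it is an
  alternative kernel, not the default.
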