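---
title: "Methods: network-based drug repositioning with drugSimNet"
author: "drugSimNet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based drug repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugSimNet)
```

# Overview

`drugSimNet` nominates repositioning candidates for a cancer by
propagating a seed set of known therapeutic drugs through a drug–drug
similarity network and filtering the stably top-ranked drugs by the
survival-essentiality of their targets. This vignette is the package's
account of the underlying model: the assumptions behind each stage, the
tunable parameters and their defaults, the numerical conventions, the
design decisions that were genuinely open, and what the synthetic
validation scenario does and does not establish.

# The similarity model

The method rests on two assumptions. First, drugs whose targets are
enriched in the same cancer-hallmark gene set act on the same
dysfunctional process, so shared enrichment is evidence of functional
similarity. Second, the WHO ATC classification encodes clinical
therapeutic practice, so drugs with overlapping ATC code prefixes are
clinically similar. Neither channel alone is sufficient — targets are
sparse and many drugs lack ATC annotation — so the network takes the
union of the two.

## Functional channel

For a drug with `q` targets inside the gene-set universe (`Q` genes
total) and overlap `F` with a set of `M` genes, the enrichment p-value
is the upper-tail hypergeometric probability `P(X >= F)`. It is
computed with the survival form `phyper(F - 1, M, Q - M, q, lower.tail
= FALSE)` rather than subtracting the lower cumulative sum from 1: the
subtraction loses all significant digits exactly where it matters, for
very small p-values. The test suite checks the implementation against
explicit summation of binomial-coefficient ratios on every
configuration with `Q <= 15`.

Profiles are binarised at a raw p-value of `alpha = 0.05`, with ties at
the boundary counting as enriched (the inequality is `<=`). No
multiple-testing correction is applied by default — the thresholding of
raw per-set p-values is part of the method's definition — but
`hallmarkEnrichment(..., correction = "BH")` adjusts within each drug
for users who want it. Two drugs are functionally similar when the
Jaccard index of their binary profiles is non-zero, i.e. they share at
least one enriched set; the value carried on the edge is the binary
indicator `A`, not the Jaccard value. A drug enriched in no set is
similar to nobody, itself included.

## Clinical channel

Level-5 ATC codes are 7 characters; their leading 3, 4 and 5 characters
are the level-2 (therapeutic subgroup), level-3 (pharmacological
subgroup) and level-4 (chemical subgroup) codes. For each level the
similarity is the Jaccard index of the two drugs' prefix sets, and the
overall clinical similarity is the mean of the three levels. Levels 1
and 5 are deliberately not part of the average: the anatomical main
group is too coarse and the chemical substance level is an identity
check, while levels 2–4 carry the therapeutic and pharmacological
content. Pairs in which either drug has no ATC code are skipped, never
zero-scored — absence of annotation is not evidence of dissimilarity.

The significance threshold is the 95th nearest-rank percentile of the
empirical distribution of pairwise similarities among all ATC-annotated
drugs. Zero-valued pairs are part of that distribution by default,
because the threshold is meant to flag the top of the full empirical
distribution, not the top of the nonzero tail; `excludeZeros = TRUE` is
available for sensitivity analysis. The nearest-rank convention (the
value at position `ceiling(p/100 * n)` of the sorted sample, no
interpolation) makes the threshold an observed similarity value and
keeps it reproducible.

## The union network

An edge joins two drugs when `A = 1` or the clinical similarity is
significant *and positive*. The positivity guard matters only in the
degenerate case where more than 5% of all pairs are identical in
similarity 0 — then the nearest-rank threshold is 0, and "similarity at
least the threshold" would declare every pair, including completely
dissimilar ones, clinically similar. A zero-similarity pair is not a
similar pair, so it never forms an edge.

Each edge stores both `A` and the clinical value `B` so that every
weighting pattern can be applied without recomputing similarities. `B`
is the raw similarity when the pair passed the threshold and 0
otherwise, including on edges that exist for functional reasons: a
sub-threshold clinical similarity never created an edge on its own, so
it should not contribute propagation weight either. Only drugs with at
least one annotated target are eligible as nodes, and isolated drugs
are dropped — the node set is exactly the set of edge endpoints, which
guarantees every column of the transition matrix is normalisable.

# Propagation and weighting

Scores follow Random Walk with Restart,
`S_{t+1} = (1 - r) W S_t + r S_0`, with the column-normalised
transition matrix `W`, restart probability `r = 0.7`, the seed drugs
sharing the restart mass equally, and convergence declared when the L1
change drops below `1e-10` (at most 10,000 iterations; non-convergence
is an error carrying the last residual). Because `W` is column
stochastic and `S_0` sums to 1, the iterate is a probability vector at
every step; the converged vector equals the direct linear solution
`(I - (1-r)W)^{-1} r S_0`, which the tests verify to `1e-8` on random
graphs.

Edge weights are 1 under the unweighted pattern (a distinct sentinel,
not the 1:1 ratio) and `alpha*A + beta*B` under a weighted pattern.
Column normalisation makes `(c*alpha, c*beta)` behave identically to
`(alpha, beta)`, so coefficient pairs are reduced to simplest ratios at
construction — the scale-invariance property is exact by
representation, not approximate. Enumerating coprime pairs with
coefficients in 1..9 yields 55 ratios; the canonical grid of 54
excludes the equal-weight 1:1 ratio, and `includeEqual = TRUE` restores
it. The package records both counts.

Candidate rankings cover non-seed drugs only: a seed rediscovered by
itself is not a repositioning candidate, and the leave-one-out recall
(below) only makes sense if a left-out seed competes as a non-seed.
The top fraction is `ceiling(0.05 * n_nonseed)` drugs, sorted by score
descending with ties broken by drug identifier ascending — a
deterministic, if arbitrary, tie rule that keeps reruns bit-identical.
The denominator (non-seed node count) is configurable via
`topFraction`.

# Stability screening

The seed set is itself an uncertain input: scores shift when seeds are
added or removed. Two procedures quantify this.

*Leave-one-out recall*: each seed in turn is removed and re-scored with
the rest; it counts as recalled when it lands in the top 5% of the
non-seed ranking. Seeds absent from the network count as misses.

*Delete-n-out*: for each n, every subset with n seeds removed is
re-scored and the top 5% recorded. When the subset space exceeds
`subsetCap` (default 10,000), that many distinct subsets are sampled
uniformly without replacement — duplicates would double-count
frequencies — under an explicit RNG seed; run n of the full screen uses
`rngSeed + n` so depths sample independently yet reproducibly, and the
exhaustive branch ignores the RNG entirely. The appearance frequencies
of all drugs seen in at least one top list form a distribution whose
95th nearest-rank percentile is the candidate threshold; drugs at or
above it (inclusively) are the delete-n-out candidates. Inclusivity is
forced by the structure of the screen: with k seeds, the delete-1-out
threshold typically equals k, the maximum attainable frequency, and a
strict inequality would select nothing. Drugs never listed are not
zero-padded into the distribution — the percentile is over observed
candidates, not over the whole network.

The screen starts at n = 1 and continues while the candidate set at
n+1 is contained in the candidate set at n; the first failing depth is
`stopN` and the candidate set there is the stable set. Whether the
stable set should instead be the last depth *before* failure is
genuinely ambiguous; the package follows the convention that the set at
the stopping depth is final, and exposes `stableAt = "stop-1"` for the
other reading. If containment never fails the screen stops at
n = seeds − 1 with a warning — a perfectly healthy outcome on networks
where the candidates are insensitive to the seed subset. The stopping
depth is determined once, on the unweighted network, and reused as a
fixed depth (`fixedNStability`) for all 54 weighted patterns.

# Repurposing filter

The initial predicted drugs are the intersection of the unweighted
stable candidates with the intersection over all weighted patterns'
stable candidates. Empty intersections are legal (with a warning): a
method that cannot find stable candidates should say so rather than
relax itself.

A gene is a druggable target for cancer I when its CRISPR gene-effect
score is at or below −0.5 in at least one cell line of that cancer.
Three conventions are deliberate:

- the boundary uses `<=` (a score of exactly −0.5 qualifies); a
  `strict` flag switches to `<` for users who read the cutoff
  exclusively;
- "at least one cell line" is the essentiality quantifier; `minLines`
  generalises it;
- missing gene-effect measurements are excluded from the comparison,
  never imputed or treated as 0, and a target gene absent from the
  matrix altogether simply never qualifies (it is counted as
  non-essential, with the number of supporting cell lines reported per
  gene so the user can audit the decision).

Final drugs are the initial predicted drugs with at least one druggable
target; each is annotated with its qualifying targets and reported with
its average rank over every (pattern, seed-subset) condition in which
it was scored as a non-seed.

# The synthetic validation scenario

Because the real inputs are licensed snapshots, the package validates
itself on generated data with planted structure
(`SyntheticScenario()`). The default scenario uses 150 drugs, 400 genes
in 20 disjoint gene sets, a 10-drug seed cluster, 4 planted positives,
6 planted essential genes, and 15 cell lines of which 10 carry the
scenario cancer label — sizes chosen so that every stage (including all
54 weighted patterns) runs in seconds while the top-5% cut still leaves
room for both planted positives and background churn.

The seed cluster is split into two sub-communities of 5, each sharing
one planted gene set and one level-4 ATC branch; the two branches sit
under different level-2 codes, so the sub-communities are clinically
dissimilar to each other. The planted positives bridge the
sub-communities: their targets overlap both planted gene sets (plus
their share of the planted essential genes, assigned round-robin so
every essential gene is covered), and they carry one ATC code in each
branch. This mirrors the structure of real seed sets — known
therapeutics for a cancer are only partially similar to one another —
and it is what makes the stability screen informative: a drug similar
to *every* seed faction outranks any removed seed under any retained
subset, while a drug attached to a single faction does not.

Background drugs draw 3–7 targets from a random "home" gene set (so
functional communities exist in the background too), plus
Poisson-distributed noise targets from the whole gene space, and a
random ATC leaf outside the two reserved level-3 branches, plus an
occasional second code anywhere (including, rarely, the seed branches).
The ATC tree uses branching factors (3, 2, 2, 3, 4) with the real
format's character classes; with these factors roughly 8% of random
pairs share a level-3 prefix, so the empirical 95th-percentile
threshold lands strictly above 1/3 — background drugs that share only a
level-2 prefix with the cluster never form edges to it, while
within-community seed pairs (similarity 1) always do.

Gene-effect scores are N(0, 0.13) background noise; planted essential
genes are shifted to `-0.55 - |N(0, 0.2)|` in 60% of the cancer's cell
lines. The background scale is chosen so that chance essential calls at
−0.5 (about 4 standard deviations) are rare but not impossible — the
essentiality filter is genuinely exercised rather than handed a clean
separation. One percent of non-planted entries are blanked to exercise
the missing-data path.

What passing the end-to-end test shows: the pipeline's stages compose
correctly, the stability screen keeps exactly the drugs planted to be
stable, and the essentiality filter admits exactly the drugs with
planted-essential targets (and nothing when no essential genes are
planted). What it does not show: performance on real data. The
generator does not reproduce DrugBank's degree distribution, ATC
multiplicity, overlapping hallmark sets, or the target-sparsity of real
drugs, and the planted signal is stronger than any real repositioning
signal. Real-data behaviour has to be judged on real snapshots.

# Numerical conventions and degenerate inputs

- All percentiles (clinical threshold, frequency threshold) use the
  nearest-rank rule; no interpolation anywhere.
- All set-valued outputs are returned sorted, and all rankings break
  ties by identifier, so identical inputs give bit-identical outputs.
- Every stochastic step (subset sampling, scenario generation) takes an
  explicit integer seed; RWR itself is deterministic. The scenario
  generator restores the caller's RNG state.
- Degenerate inputs fail loudly: empty gene-set files, drugs with no
  in-universe targets, seed sets that do not resolve, networks with no
  surviving edges, all-zero transition columns and non-convergent walks
  are errors, not silent zeros.
- Multi-value table cells use ";" with no quoting, and numeric output
  uses 17 significant digits, so file round trips are exact.

# Limitations

The binary functional similarity discards the magnitude of profile
overlap, and the unweighted network discards similarity strength
entirely; both are faithful to the method's definition but coarse. The
pairwise clinical similarity matrix is computed densely over
ATC-annotated drugs, which is fine up to a few thousand drugs but would
need blocking beyond that. The stability screen's stopping rule
compares only consecutive depths, so a non-monotone candidate set that
happens to re-enter later is not detected. Survival analysis of
targets, pathway enrichment of the final drugs, and literature
validation are interpretation layers outside the package's scope.
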