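---
title: "Methods: semantic network comparison of verbal fluency groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic network comparison of verbal fluency groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluenet)
```

This vignette documents the statistical model behind `fluenet`, the
choices that were genuinely open when it was built, and what its tests
do and do not establish.

## The estimation model

A participant's fluency list is an ordered sample from their semantic
lexicon. Group-level structure is estimated, not per-participant: all
cleaned lists of a group form a binary response matrix \(B\)
(participants × exemplars), and the association between exemplars
\(i, j\) is the cosine of their binary columns,

\[ a_{ij} = \frac{c_{ij}}{\sqrt{c_i\,c_j}} \in [0, 1], \]

with \(c_{ij}\) the number of participants producing both. Cosine (not
correlation) is used so that associations are non-negative: two
exemplars that never co-occur get 0, not a negative weight.

The dense similarity matrix is then filtered with the Triangulated
Maximally Filtered Graph. TMFG is greedy: the four nodes with the
largest off-diagonal row sums form a seed tetrahedron; each remaining
node is inserted into the triangular face \((x,y,z)\) maximizing
\(a_{vx}+a_{vy}+a_{vz}\), which replaces that face by three new ones.
The output is planar and connected with exactly \(3n-6\) edges, and all
subsequent coefficients treat it as **unweighted**: weights steer the
topology only. Fixing the edge count is the point — two equated groups
always have identical \(n\) and \(m\), so coefficient differences
cannot be artifacts of network size.

Three coefficients summarize each network: ASPL, the mean breadth-first
distance over all unordered pairs (global spread); CC, the mean local
Watts–Strogatz clustering coefficient (local interconnectivity); and
Q, the Newman modularity of a Louvain partition
(compartmentalization).

### Assumptions worth stating

* Co-occurrence across participants is a meaningful proxy for semantic
  proximity. With ~38 lists of ~13–18 items over a vocabulary of ~100+
  exemplars, each \(a_{ij}\) rests on few observations; the bootstrap
  exists precisely because this estimate is noisy.
* Finalizing (≥ 2 producers) removes idiosyncratic exemplars whose
  cosine values would be pure noise; equating makes the two group
  networks comparable at the cost of discarding group-exclusive
  vocabulary (which is reported separately by
  `fluency_count_summary()`).

## Cleaning rules

Cleaning is deliberately *not* an automatic spell-checker. A
user-supplied lexicon (`raw,canonical,status`) plus three built-in
deterministic rules — lower-casing, accent stripping, and trailing
plural-marker removal only when the de-pluralized form is a known key —
decide every token identically on every run. Unmapped tokens are
rejected as out-of-category rather than guessed. Homonyms and compound
responses are the lexicon author's responsibility. Participants whose
whole list is rejected stay in the matrix as an all-zero row so that
group sizes (and hence bootstrap resampling) keep the declared n.

## The bootstrap comparison

Each replicate resamples participants with replacement within group,
carrying their covariates, and re-runs finalize → equate → cosine →
TMFG → coefficients. Replicates whose equated node set would fall below
four (TMFG's minimum) are redrawn with the next seed; more than 5%
redraws aborts, since that signals groups with too little shared
vocabulary for the design to make sense.

Group tests treat the \(2 n_\text{boot}\) replicate values as
observations of a linear model
`coefficient ~ group + mean_n_cleaned + n_edges` (+ SES, + non-verbal
intelligence for the adjusted models). Two covariate notes:

* "Response count and edge count of each child" has no per-child
  meaning at the group-network level; they are operationalized as the
  replicate's mean cleaned-response count and the equated network's
  edge count.
* When a covariate is constant across replicates (edge count often is,
  at fixed equated n) it is dropped with a note; with no covariates
  left the test reduces to Welch's two-sample t.

**Caveat, by construction.** Treating bootstrap replicates as
independent observations is anticonservative for inference about the
*populations*: replicate means concentrate on the observed samples'
difference, and standard errors shrink with \(n_\text{boot}\). The
package reproduces this procedure faithfully because it is the
procedure under study, and quantifies the consequence instead of hiding
it: the calibration suite shows the test *is* calibrated under the
"identical records" null (both groups the same participants, so
replicate distributions coincide), while genuinely distinct samples
from one population will be flagged apart at high rate. The repeated
harness (20 × by default) with its proportion-significant report is the
study design's own mitigation, and directional consistency of the
replicate means is the more robust summary.

## The synthetic world

No child-level data are deposited, so the generator stands in as a
stated world:

| parameter | default | rationale |
|---|---|---|
| vocabulary `v`, categories `k` | 100, 5 | within the plausible 100–250 exemplar range; small enough that 38 short lists yield informative co-occurrences |
| `p_in`, `p_out` | 0.35, 0.03 | clearly modular latent lexicon (categories ≈ animal sub-domains) |
| lists per group | 38 | study group size |
| list length A / B | N(13.05, 3.48²) / N(17.92, 5.16²), truncated ≥ 1 | the reported group means/SDs of cleaned counts |
| `jump_prob` | 0.15 | censored random walk with occasional restarts, the standard generative account of fluency retrieval |
| noise | 3% intrusions, 5% perseverations, 5% misspellings | realistic child-transcript noise; every variant is covered by the emitted lexicon so cleaning is exact |
| SES, non-verbal intelligence | N(58.6, 25.1²)/N(59, 18.1²); N(51.8, 11.1²)/N(88.7, 9.82²), clamped to [0, 100] | the reported covariate scales |
| nvi–length correlation | 0.3 | stated nowhere; a modest positive coupling between ability and production |
| group effect | 30% within-category edge deletion (+ the length difference) | the "less interconnected lexicon" hypothesis, each knob independently zeroable |

What the generator emulates: group-size and list-length scales,
category-clustered retrieval runs, singletons, partial vocabulary
overlap, noisy surface forms, covariates on their real scales. What it
does not: word frequencies, age-of-acquisition, orthography of a real
language, or individual differences in walk dynamics. A green
end-to-end test therefore establishes that the *pipeline* recovers
structure it is pointed at — not that any particular empirical cohort
must show that structure.

Two generator-level facts found while validating, both documented here
because they shape the tests: (1) within-category deletion alone
transmits only weakly into the estimated TMFG coefficients — it is the
*combination* with shorter lists that produces the reported signature
(higher ASPL, lower CC, higher Q in the affected group); (2) bootstrap
replicate means are a steadier direction estimate than the single
original-sample network, because averaging over resamples integrates
out finalize/equate jitter. The power acceptance check accordingly
reads direction off the harness means.

The calibration null uses `generate_cohort(mirrored = TRUE)`: one group
is generated and literally copied under the other label. Only under
this null are the two groups' replicate coefficients draws from one
distribution, making "proportion significant ≈ α" the correct
expectation (see the caveat above for why two *independent* draws would
not be).

## Numerical and determinism choices

* **Tie-breaking.** TMFG seed selection is a stable sort on (−row sum,
  index); insertion scans candidates in ascending node index, then face
  creation order, accepting only strict improvements — reruns are
  bit-identical, including on fully tied matrices. Columns are ordered
  lexicographically (C collation) everywhere so node indexing never
  depends on locale or input order.
* **Louvain.** Hand-implemented multilevel optimization with a fixed
  sweep order (vertex order; a non-zero seed permutes it
  reproducibly), strict-gain moves with lowest-community-id
  tie-breaks, and aggregation until no move. Single run per replicate.
  `igraph`'s Louvain is RNG-dependent, which is why it serves as a
  cross-check in the tests rather than as the implementation. The
  returned Q is verified against an independent recomputation from the
  edge list and, on small graphs, against the exhaustive maximum over
  all partitions (within 0.05; Louvain is near- but not exactly
  optimal).
* **CC variant.** Mean local clustering (not global transitivity), with
  degree-<2 nodes contributing zero, keeping the denominator at n;
  the verbal definition ("two neighbours of a node…") is local, and the
  referenced toolbox convention matches.
* **Degenerate inputs.** `tmfg()` errors below 4 nodes in strict mode;
  in pipeline mode a ≤ 4-node matrix yields the complete graph so a
  degenerate resample cannot abort a 1000-replicate run. ASPL refuses
  disconnected graphs (TMFG guarantees connectivity); Q refuses
  edgeless ones.
* **Seeds.** Every stochastic stage consumes an explicit seed derived
  from one master seed via a fixed-width `sample.int` stream; results
  are byte-identical across reruns of the same configuration, which the
  determinism tests assert on serialized output.

## Known limitations

* The replicate-as-observation test is anticonservative for
  population-level claims (above); interpret "proportion significant"
  as a consistency measure, not a p-value.
* Cosine-TMFG estimates are sensitive to list length; the covariate
  adjustment absorbs much of a group length difference, which also
  absorbs genuine structural signal correlated with it.
* The generator's world is a stochastic block model; real semantic
  networks have hubs, degree heterogeneity and cross-category
  polysemy that it does not model.
* Louvain on ~80-node planar graphs can differ from the true modularity
  optimum by up to the audited 0.05.
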