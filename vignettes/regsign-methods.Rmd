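---
title: "Methods: tiered sign-consistency inference and enrichment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered sign-consistency inference and enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regsign)
```

This vignette records the model, the statistical conventions and the
numerical choices behind `regsign`, and states what the synthetic
generators do and do not emulate.

## 1. The sign-consistency model

The object of study is a signed, directed gene regulatory network: nodes
are genes, and an edge $u \to v$ with sign $s(u,v) \in \{+1, -1\}$ asserts
that $u$ activates ($+1$) or represses ($-1$) $v$. In a loss-of-function
mutant, each gene has a misregulation state
$\sigma \in \{+1\ (\text{up}), -1\ (\text{down}), 0\ (\text{undetermined})\}$
relative to wild type. An edge is *consistent* with a state assignment when

$$\sigma(v) = s(u,v)\,\cdot\,\sigma(u).$$

This is the whole model: no magnitudes, no kinetics, no time course. It is
deliberately coarse — the input evidence (curated regulatory interactions
plus observed up/down calls) supports nothing finer, and the coarseness is
what lets heterogeneous evidence types vote on equal terms.

## 2. The tiered weighting scheme

Observed states come in tiers of reliability, and the inference respects
that hierarchy explicitly rather than treating all evidence alike:

| tier             | meaning                                   | weight |
|------------------|-------------------------------------------|:------:|
| `qrt_confirmed`  | state confirmed by paired qRT-PCR          | 2 |
| `array_reported` | state reported by microarray only          | 2 |
| `predicted`      | state assigned by an earlier inference pass | 1 |
| `unanchored`     | no state information                       | 0 |

For a candidate node $x$ and hypothesis $h \in \{+1, -1\}$, every incident
edge whose other endpoint has a determined state casts a weighted vote:
a downstream target $t$ supports $h$ iff $\sigma(t) = s(x,t)\,h$, and an
upstream regulator $r$ supports $h$ iff $h = s(r,x)\,\sigma(r)$
(`scoreHypothesis()`). The hypothesis with the larger total wins; exact
ties leave the node undetermined — ties are never broken by chance,
because a coin-flip prediction would be indistinguishable from evidence
downstream.

The 2/1 weighting encodes a simple ordinal judgement: a measured state
should outvote an inferred one, but two concordant inferences should
outvote one discordant measurement's echo. Nothing in the algorithm
depends on the exact values beyond their order; the packaged worked
example (`fig4bNetwork()`) is the canonical check that the arithmetic is
wired correctly (down 4 vs up 3).

`predictStates()` iterates the vote synchronously. Round 1 admits known
tiers only, so first-generation predictions rest exclusively on
measurements; from round 2, predicted states vote with weight 1, letting
information propagate deeper into the network. Nodes that enter with tier
`predicted` are treated as fixed evidence, not re-decided — they encode
the output of an earlier pass, and silently revising them would let weak
evidence overwrite strong provenance. Synchronous updates make the result
independent of edge and node input order. Iteration stops at a fixed
point; if the joint state vector revisits a previous value (possible only
with cycles), the oscillating nodes are frozen as undetermined and
reported, which is the honest answer for a node the evidence cannot pin
down. After prediction, `pruneInconsistent()` removes every edge whose two
determined endpoints violate the consistency equation; undetermined
endpoints never condemn an edge.

## 3. Statistical conventions

**Relative expression.** Paired-littermate qRT-PCR uses the standard
$2^{-\Delta\Delta C_t}$ estimator against the reference gene (default
`Hprt`). A tissue-dissection QC gene (default `Jag1`) must satisfy
$|\text{ratio} - 1| \le 0.30$ per pair; violating pairs are excluded
before testing. The boundary is compared with square-root-machine-epsilon
slack so a ratio of exactly 0.70 passes despite binary floating point.

**Exact rank-sum test.** Group sizes here are tiny (3–6 pairs), and
normalised wild-type values produce heavy ties, so the large-sample
Wilcoxon approximation is inappropriate and the classical exact test is
undefined under ties. `wilcoxonExact()` computes the exact conditional
permutation distribution of the rank-sum over tied mid-ranks by a
subset-sum dynamic programme over doubled mid-ranks (doubling makes them
integers, so the distribution is exact rational arithmetic in double
precision). The two-sided p-value is $\min(1, 2\min(p_{\le}, p_{\ge}))$,
which is a valid (conservative) p-value because each tail is valid at
half level. Above 12 observations per group the tie-corrected normal
approximation takes over; at qPCR scale the exact branch always runs.

**Multiplicity.** Benjamini–Hochberg throughout, via `stats::p.adjust`
wrapped with input validation (`bhAdjust()`): the step-up procedure is
standard and reimplementing it would add risk without insight.

**Signed fold change.** Ratios $\ge 1$ map to themselves, ratios $< 1$ to
$-1/\text{ratio}$, so a halving reads as $-2$; the transform is an exact
involution pair with `foldChangeToRatio()`.

**Word landscapes.** For an expression-ranked list of $N$ 3′UTRs and a
heptamer $w$, each gene is marked present/absent (a gene with five sites
counts once — the urn model draws genes, not sites). At each leading-bin
cutoff $c$ (multiples of `binStep`, default $\max(1,\lfloor N/50\rfloor)$,
about 50 points), the hypergeometric tail of the observed present-count is
computed; the score is $-\log_{10} p$ of the upper tail when the bin holds
at least its expectation and $+\log_{10} p$ of the lower tail otherwise,
so positive peaks mean concentration among upregulated genes. All
$4^7 = 16384$ heptamers are scanned via
`Biostrings::oligonucleotideFrequency`; p-values are floored at the
smallest positive double before taking logs. Seed matches are the DNA
reverse complement of microRNA bases 2–8; all sequence coordinates are
0-based half-open, forward strand.

**Over-representation and centrality.** ORA is the upper hypergeometric
tail `phyper(k - 1, K, N - K, n, lower.tail = FALSE)` with BH adjustment
across sets. PPI centralities come from `igraph`; betweenness is
normalised by $(n-1)(n-2)/2$ and closeness is computed per connected
component as $(r-1)/\sum d$ scaled by the component fraction
$(r-1)/(n-1)$, so nodes central to small fragments do not outrank nodes
central to the whole network. The high-degree filter is strict
(degree $> 75$), matching the reporting convention it reproduces.

## 4. Synthetic generators: what they emulate, and what they do not

All generators take a seed and isolate their randomness (`withSeed()`):
identical specs give byte-identical output and the caller's RNG state is
untouched.

`generateRegnet()` plants a ground truth: a root microRNA node fixed
*down* with only outgoing repression edges (its direct targets are
therefore *up*), remaining truth states propagated over a spanning forest
with the requested repression fraction, and every non-forest edge's sign
forced to $\sigma(u)\sigma(v)$ so the planted network is perfectly
sign-consistent. Anchors report the truth at the requested tier mix, with
optional independent flips as observation noise. In acyclic mode edges run
forward along a random topological order with the per-pair probability
doubled (capped at 1) to preserve the expected edge count
$n(n-1)p$. What this does **not** emulate: biological noise in edge signs
themselves, correlated measurement error, hub-heavy degree distributions
(edges are i.i.d., so degrees are binomial, not scale-free), or genes
regulated by pathways outside the network. It is a correctness instrument
— if inference fails here, it cannot be trusted anywhere — not a
simulation of a transcriptome.

`generateRankedUtrs()` draws i.i.d. UTRs at a set GC content and writes
the planted word at one uniform position into the first
$\lceil \text{planted\_fraction} \times n_\text{leading} \rceil$ genes. It
does not model UTR length variation, dinucleotide composition, repeat
structure or conservation — all of which shape real word counts — so it
validates the landscape statistic, not genomic effect sizes.

`generateQpcrTable()` shifts the mutant target mean by $-\log_2$ of the
true ratio with Gaussian Ct noise; reference and QC wells are
deterministic, so exactly `round(qc_violation_fraction * n_pairs)` pairs
violate the QC rule at any noise level. Pipetting error on reference
wells, plate effects and amplification-efficiency differences are out of
scope.

## 5. Resolved modelling questions

Decisions that had more than one defensible answer, and why these were
taken:

- **Predicted-tier inputs are fixed, not re-decided.** They represent a
  completed earlier pass; re-deciding them inside `predictStates()` would
  let the current pass overwrite its own evidence base mid-iteration.
- **Ties stay undetermined at every level** (hypothesis scores, node
  decisions), propagating zero weight onward. Any tie-break rule would
  manufacture certainty.
- **Presence/absence, not site counts, in the landscape urn.** The
  hypergeometric urn draws genes; counting sites would need a different
  null (and long UTRs would dominate it).
- **Genes with UTRs shorter than the word are kept** in the ranked set and
  simply never carry a word: excluding them would silently change the
  universe $N$ between words.
- **Duplicate edges collapse with a warning; opposite-sign parallel edges
  are kept** (with a note): the latter are real in curated networks
  (context-dependent regulation) and each sign is scored on its own.
- **The array-evidence threshold (adjusted p < 0.1) is more lenient than
  the qRT-PCR one (< 0.05)** when compiling misregulated genes: the list
  feeds network construction, where coverage matters more than per-gene
  certainty, and confirmed values override array values wherever both
  exist. Sign conflicts between significant sources are kept but flagged.

## 6. Problem sizes and runtime

The package targets desk scale throughout: networks of a few hundred
nodes (the iterative predictor is $O(\text{rounds} \times |E|)$ with
vectorised scoring), UTR sets of $\sim$500 genes × 300 bases scanned
against all 16384 heptamers in seconds, qPCR panels of $\le 12$ pairs
(exact test DP is $O(m \cdot (\text{rank sum range})) \approx$
microseconds), and PPI tables up to a few thousand nodes via `igraph`.
The full test suite, including 20-seed recovery sweeps at 200 nodes and
the all-heptamer scans, runs in roughly a minute on one CPU.
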