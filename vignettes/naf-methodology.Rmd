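---
title: "Alignment-frequency ensembles for topology-only annotation transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-frequency ensembles for topology-only annotation transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nafalign)
```

## The problem and the model

Protein–protein interaction (PPI) networks are sparse, noisy and very
unevenly sampled across species.  A single topology-only pairwise global
network alignment — an injective map $a: V_1 \to V_2$ from every node of
the smaller network into the larger — therefore carries a weak and
unstable functional signal: many near-optimal alignments exist, and a
single optimizer run commits arbitrarily to one of them.

`nafalign` treats that degeneracy as the signal.  It draws an *ensemble*
of independently seeded simulated-annealing runs, each converging to a
different near-optimal alignment of the same objective.  For a node pair
$(p, q)$, the **network alignment frequency** (NAF)
$\phi_{pq} = \#\{\text{runs aligning } p \to q\} / N$
measures how repeatable that pairing is across the frontier of
near-optimal solutions.  Pairs embedded in genuinely similar network
regions re-align far more often than chance; pairs that were aligned
incidentally do not.  NAF is reported in percent so that ensembles of any
size $N$ are comparable (with the conventional $N = 100$ a count is a
percentage directly).

Two edge-level objectives are built in, both in $[0,1]$:

* **EC** (edge correctness): conserved edges over $m_1$, the smaller
  network's edge count;
* **S³** (symmetric substructure score): conserved edges over *all*
  edges among aligned nodes, $c / (m_1 + |E_2[\mathrm{image}]| - c)$,
  which penalizes aligning into dense regions; $S^3 \le EC$ always.

Two node-level objectives score an alignment as the mean pairwise node
similarity: **graphlet degree vectors** (counts of automorphism orbits of
connected induced subgraphs on ≤ 4 or ≤ 5 nodes around each node,
compared with the standard log-scaled, orbit-weighted distance) and
**importance** (a deterministic minimum-degree-elimination hub score;
see below).

## The sampler

Each run performs Metropolis sampling over injective mappings: a move
either *swaps* the images of two $V_1$ nodes or (when $n_1 < n_2$)
*remaps* one node to an unused $V_2$ node, chosen uniformly among the
legal move types.  Moves are scored incrementally from cached counters
(conserved edges, image-induced edges, pairwise-similarity sum); the
delta of every move equals a from-scratch recomputation to $10^{-12}$,
which the test suite audits explicitly, and every run re-verifies its
cached final score from scratch at tolerance $10^{-9}$.

The temperature decays geometrically between auto-tuned endpoints: a
short probe walk records move-delta magnitudes, then $T_{\mathrm{init}}$
is set so at least 99% of probe moves would be accepted
($T_{\mathrm{init}} = \max|\Delta| / (-\ln 0.99)$) and
$T_{\mathrm{final}}$ so a mean-magnitude move survives with probability
at most $10^{-6}$ ($T_{\mathrm{final}} = \overline{|\Delta|}/\ln 10^6$).
If a probe yields only zero deltas (already-converged or degenerate
instances) the documented constants $(1, 10^{-6})$ are used.  The run
budget is expressed in move proposals rather than wall-clock time so
that results are exactly reproducible on any hardware; run $r$ of an
ensemble uses seed $\texttt{base\_seed} + r - 1$, and all randomness
flows through a private 64-bit Mersenne-Twister stream, so an ensemble
is bit-reproducible for a given base seed.  There are no restarts within
a run — the ensemble *is* the restart mechanism.

## From NAF to trusted transfers

Thresholding the NAF table at $\phi$ yields a (possibly many-to-many)
pair set.  Its **common connected subgraph** (CCS) has one node per pair
and an edge wherever *both* projections are real edges; the CCS mean
degree measures how much actual common topology backs the thresholded
pairs.  Ensembles whose CCS mean degree falls below 3 (the *degree-3
criterion*) are treated as unreliable sources of transfers.  The
**alignment quality** product $(\phi/100) \times EC_\phi \times
\bar d_{CCS}$ summarizes a threshold in one number;
$EC_\phi$ is computed CCS-restricted (conserved edges over the $g_1$
edges induced on the thresholded pairs' $g_1$-side nodes), since the
appropriate denominator for a pair subset is the subset's own edges; a
whole-alignment EC can be substituted by passing a precomputed report.

Annotation transfer then accumulates evidence: for every surviving pair
$(p, q)$ with $\phi_{pq}$ at or above a floor (default 2%), every
`(term, evidence)` record of the source protein $p$ — strict-filtered
against sequence-based evidence codes and restricted to an evidence
whitelist — adds $\phi_{pq}$ to the candidate annotation
$(q, \mathrm{term}, \mathrm{evidence})$, skipping anything $q$ already
carried at the earlier date and any pair in the exclusion lists
(precomputed sequence-similar and ortholog pairs).  The default
whitelist `{IPI, EXP, IDA}` holds the experimentally grounded codes
with the strongest transfer record; the default NOSEQ set
`{IBA, IEA, ISM, ISA, ISO, IGC, RCA, ISS}` is deliberately draconian —
any code that sequence comparison could have influenced.

Evaluation is time-split: predictions made from data at date $t$ are
validated against the annotation release of a later date $t'$.  The
recall denominator is the later release's validated annotations
intersected with the *predictable-in-principle* set (target protein
present in the earlier target network, term carried by at least one
non-excluded source protein at $t$) — materialized only on that
intersection, since the full predictable set is combinatorially huge.
A later association carrying any sequence-based evidence is discarded
from numerator and denominator alike (the stricter reading; a
`seq_discard = "only"` flag relaxes this to associations with *only*
sequence evidence).  The precision–recall sweep over descending
cumulative scores uses right-continuous step summation for AUPR — the
standard convention for threshold sweeps — and $F^*$ is the best $F_1$
along the sweep.

## Semantic similarity

Resnik similarity (max variant) scores an aligned pair as the highest
information content among common ancestors of any term pair annotating
the two proteins.  Annotations are propagated up `is_a` links first
(`part_of` optionally, off by default — the smallest defensible
closure), after which the most informative common ancestor is simply
the highest-IC term shared by both propagated sets.
$IC(t) = -\ln(n_t / n_{\mathrm{root}})$ with counts of distinct
annotated proteins, per namespace, over the loaded corpus — by default
the union of both species' filtered, propagated annotations, matching
the common implementation default; natural log throughout.  Proteins
without usable terms yield *no score* and are excluded from curves
rather than scored zero.  Because IC magnitudes depend on corpus size,
only trends (curve shapes, correlations), not absolute Resnik values,
are meaningful on synthetic corpora.

The `(S, M)` well-annotation filter keeps a protein only if at least
$S$ distinct terms annotate it, each annotating at most $M$ proteins of
its species.  Counts use direct (unpropagated) annotations — the most
plausible reading of "annotates at most M proteins", since propagation
would inflate shallow terms past any small $M$.  The grid machinery
computes the NAF–Resnik correlation per cell and then second-level
("Pearson²") correlations of $\rho(S, M)$ against $S$, $M$ and $S/M$
over cells passing a significance cutoff (default $5\times10^{-6}$,
i.e. 0.01 Bonferroni-corrected over a 2000-cell grid; no further
multiple-testing correction is applied).  For significance the package
reports both the t-statistic $\rho\sqrt{(n-2)/(1-\rho^2)}$ — which is
what published "σ" columns reproduce to four decimals — and the Fisher
r-to-z p-value.

## The importance objective

No standard definition exists for the elimination-based "importance"
driver, so the package fixes one deterministically: node weights start
at 0 and edges at 1; the lexicographically smallest node with degree
≤ 2 is repeatedly removed, pushing its accumulated weight onto its
neighbour (degree 1) or onto the edge joining its two neighbours
(degree 2, created if absent).  A node's importance is its node weight
plus half its incident edge weight at removal (survivors at
termination).  This captures the same idea — weight flows toward hubs —
while being exactly reproducible and relabelling-invariant up to the
documented tie-break; it is documented as this package's own concrete
choice, not a re-implementation of any published aligner's scorer.

## Graphlet machinery

Orbit counting enumerates connected induced subgraphs once each
(Wernicke's ESU) and classifies the touched node by canonical form.
The default size is 4 (15 orbits), which keeps the node-similarity
matrix cheap at fixture scale; size 5 (73 orbits) is available behind a
flag.  Graphlets are ordered by (node count, edge count, descending
degree sequence, canonical adjacency bits) and orbits within a graphlet
by (degree, canonical position); on ≤ 4 nodes this reproduces the
standard 15-orbit indexing exactly (edge; path end/mid; triangle; …;
K4), and on 5 nodes it is a deterministic canonical enumeration.  Orbit
weights $w_i = 1 - \log o_i / \log 73$ use dependency counts $o_i$
derived at registry-build time as the transitive closure of the
single-node-removal relation between orbits (touched node retained,
connectivity preserved), which reproduces the canonical counts
(1, 2, 2, 2, 3, 4, …) on the ≤ 4-node orbits; the 73-orbit
normalization is kept even in 15-orbit mode so the two modes agree on
shared orbits.  The $+1$ inside and $+2$ under each logarithm keep the
distance finite without an epsilon.

## What the synthetic generators emulate — and what they do not

`random_graph` + `noisy_copy` produce a pair with known correspondence:
`g2` is a relabelled copy with edges deleted (and optionally added) at
fixed rates, `g1` the original induced on a retained node subset —
emulating two incomplete observations of a shared interactome.  The
benchmark conditions used throughout the tests are a 60-node
Erdős–Rényi graph at edge probability 0.1 with 15% edge deletion, full
node retention, and an ensemble of 20 EC-driven runs of $2\times10^6$
proposals: small enough to run in about a minute on one CPU, large
enough that truth pairs separate cleanly from random pairs in NAF.
`synth_go_world` surrounds such a pair with a toy single-namespace
ontology (a random tree, default 40 terms, depth ≤ 4) and three dated
annotation stores: each true pair shares a planted specific term
(probability 0.8 by default) that the source carries early and the
target acquires only in the later release with non-sequence evidence;
decoy annotations (rate 0.2 per protein) and a default evidence mix of
EXP 0.4 / IPI 0.3 / IDA 0.2 / IEA 0.1 exercise both the whitelist and
the sequence-filter paths.

These generators deliberately do **not** reproduce real PPI
degree-correlation structure beyond the ER/BA models, database growth
dynamics, annotation bias toward well-studied proteins, or realistic GO
DAG shape.  A passing recovery suite therefore demonstrates that the
machinery extracts a planted signal under controlled noise — not that
any particular pair of real interactomes contains such a signal.

## Numerical and degenerate-input conventions

* Graph cleaning: self-loops, duplicate edges and degree-zero nodes are
  dropped at ingestion; an input that cleans to nothing is an error,
  not an empty object.  Vertices are held in lexicographic order so
  seeded runs are independent of input row order.
* Zero predictions at a threshold leave precision *undefined* (`NA`),
  recall 0; a ledger with no rows or a ground-truth intersection of
  size 0 is an error for curve construction.
* Correlations on constant input raise an error rather than returning
  `NA`.
* NAF thresholds are percentages in $(0, 100]$; threshold sets are
  antitone by construction.
* All file formats are plain text (edge-list TSV, OBO 1.2, GAF 2.x,
  2-column pair lists, NAF/prediction TSVs with `#` config headers) and
  round-trip through their readers.

## Known limitations

The sampler's schedule and move set are this package's own design;
they aim for the same behaviour as published annealing aligners
(near-optimal scores with run-to-run variability) rather than exact
equivalence to any of them.  The 73-orbit indexing beyond 4 nodes is
canonical-deterministic rather than the literature's table order.
Full-scale interactome ensembles (hundreds of runs at $10^7$+ proposals
on $10^4$-node networks) are computationally out of desk scope; the
package's defaults target fixture-scale reproducibility, and the
ensemble loop is trivially parallelizable externally by splitting seed
ranges.
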