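---
title: "Methods: conserved C2H2 cores, disordered extensions, and how ovolution measures them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved C2H2 cores, disordered extensions, and how ovolution measures them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovolution)
```

## The model

`ovolution` treats a zinc-finger protein as three concatenated parts:

* an **N-terminal extension** (possibly empty),
* a **conserved core**: four C2H2 zinc-finger motifs — each a short span in
  which two cysteines and two histidines coordinate a zinc ion — joined by
  short linkers, taken as a single domain from motif I start to motif IV
  end,
* a **C-terminal extension** (possibly empty).

The extensions are intrinsically disordered (ID): compositionally biased,
indel-prone, non-homologous across lineages, and much faster-evolving than
the core. The package's job is to (i) find the core with a
pattern grammar, (ii) annotate the disordered and biased parts, (iii)
quantify the divergence contrast between the partitions, and (iv) classify
loci across genomes from their flanking-marker neighborhoods.

All coordinates are **1-based, fully closed** (a span 118–140 is 23
residues), matching how such features are conventionally printed;
converters at the I/O boundary handle everything else. Sequences admit the
20 standard residues plus `X` for unknown; `*` is rejected on ingest since
a stop codon inside a protein indicates an upstream parsing fault.

## Pattern grammar and scanning

The supported dialect is the subset actually used for C2H2 motifs: residue
letters, bracketed sets with lowercase "exceptional" members
(`[FWsgat]`), wildcards `x`, `x(n)`, `x(n,m)`, `-` separators. Prosite's
exclusion classes and anchors are rejected with a clear message rather
than silently misinterpreted.

Scanning decisions that matter:

* **Exceptional residues are allowed during matching** exactly like
  uppercase members; the case distinction only reports how often a
  residue was observed. They are printed members of the motif, not
  forbidden ones.
* **`X` matches wildcards only.** An unknown residue cannot certify
  membership in a residue set.
* **Variable repeats match shortest-first at each anchor**, and the
  default mode returns a greedy left-to-right non-overlapping cover. Zinc
  fingers never overlap, so this is the natural counting mode; an
  `"all"` mode returns every satisfying `(start, end)` for exhaustive
  analyses, and the test suite holds the scanner to an independent
  regex-enumeration oracle in that mode.
* `find_tetrad()` looks for four consecutive non-overlapping matches with
  inter-motif linkers of at most `max_linker = 20` residues — the
  observed linkers are 5, 5 and 15, so 20 gives headroom without
  admitting arbitrary gaps. Architecture assembly prefers the
  **C-terminal-most** valid tetrad because that is where this family's
  tetrad sits; `find_tetrad()` itself defaults to the first.

A known tension, and how we resolved it: the family-specific per-motif
patterns imply 21–22-residue matches, while the printed motif spans are
23–24 residues — only the generic C2H2 pattern
(`C-x(2,4)-C-x(3)-[LIVMFYWC]-x(8)-H-x(3,5)-H`, PS00028) is consistent with
those spans. Both pattern families ship in `ovol_patterns()`; the
synthetic reference stand-ins use the PS00028-compatible 23/24-aa
geometry, while the simulator's core template uses the overall-consensus
geometry (21/22 aa) because the generator explicitly guarantees its cores
match that consensus.

## Consensus derivation and logos

`derive_pattern()` classifies each alignment column of a motif-instance
set: residues at frequency ≥ `f_major` (default 0.2) are uppercase
majors, residues observed below that are lowercase exceptionals, and a
column whose top frequency falls below `f_wild` (default 0.5) becomes a
wildcard; consecutive wildcards consolidate to `x(n)` or `x(n,m)` when
instance gap patterns make covered lengths vary. The defaults reproduce
the published bracket shapes (e.g. a column with F at 0.8 and S, G, A, T
at 0.05 each renders `[Fsgat]`); no canonical thresholds exist, so both
are exposed. Two deliberate choices keep the derived pattern consistent
with its own instances: frequencies are computed over the **total
instance count** (so a residue present only via a single-instance
insertion column classifies as part of a variable-length wildcard region
rather than as a fixed element), and bracket members are ordered by
descending frequency with ties broken by first appearance.

`logo_matrix()` reports per-column residue frequencies (renormalised over
non-gap residues, with the gap fraction carried separately) and
information content $I_j = \log_2 20 - H_j - e_n$, with
$e_n = 19/(2\ln 2\, n)$ the small-sample correction, on by default to
mirror common logo practice, and information clamped at 0. An all-gap
column gets zero frequencies, zero information and an `all_gap` flag.

## Disorder and compositional bias

Disorder prediction itself is a trained classifier and is *consumed*, not
reimplemented: `read_disorder_track()` ingests per-residue tables
(position, residue, score and/or state). When only scores are present the
state threshold defaults to 0.5 — the published 5%-false-positive-rate
threshold is a calibration of the upstream predictor and cannot be
recomputed here. `call_disordered_regions()` returns maximal disordered
runs of at least `min_len` residues (default 5; shorter calls are
typically low-confidence).

`find_bias_patches()` slides a `window` (default 20) and, per residue
type, merges windows where that residue reaches `min_frac` (default 0.35)
into maximal patches, trimmed at both ends to occurrences of the dominant
residue, with minimum patch length equal to the window. Reported biased
patches in this family range from ~21 to ~322 aa, so the window bounds
the smallest patch we would call while the merge covers the largest;
overlapping patches of different residues are all reported (His-rich and
Asn-rich regions genuinely overlap in the fly protein).

## Divergence

`p_distance()` implements the proportion of differing sites among
comparable positions with **pairwise deletion**: a position counts only
when both rows carry one of the 20 standard residues. Gaps *and* `X` are
excluded — an unknown residue can be scored neither as match nor
mismatch. `distance_matrix()` reports per-pair comparable-site counts and
flags a pair undefined when none remain. `bootstrap_variance()` resamples
alignment columns (not distance values) with replacement, 1000 replicates
by default, seed mandatory; replicates in which the pair becomes
undefined are excluded and counted.

`partition_columns()` turns per-sequence disorder calls into alignment
partitions by a column vote: a column is disordered when more than
`rule_frac` (default 0.5) of its non-gap residues lie inside a disordered
annotation of their own row. How per-sequence calls should map onto
columns is genuinely underdetermined, so an alternative is provided
behind `compare_partitions(method = "per-row-mask")`, which instead
restricts each pair's comparable sites to positions where both rows agree
on being inside (or outside) their own annotations; on clean block
structure the two agree exactly.

`kruskal_wallis()` delegates the tie-corrected H statistic and chi-square
p-value (df = groups − 1) to `stats::kruskal.test()`, adding the tie
correction factor, group sizes, a seeded permutation p-value option for
small samples, and the convention that H = 0 when all values are
identical (the tie-corrected statistic is otherwise 0/0).
`compare_partitions()` applies it to the full-length, structured-only and
disordered-only pairwise distance collections and emits the five-number
box-plot summary per partition (quantile type 7). **Caveat:** pairwise
distances are not independent observations — each sequence contributes to
many pairs — so the test is a conventional summary of the partition
contrast, not a calibrated inference; we compute it as defined and say
so. An empty partition (no columns) is flagged and dropped, and the test
runs on the remaining groups when at least two survive.

`nj_tree()` is a deliberately lightweight clustering check, not a
substitute for model-based phylogenetics: neighbor joining (via
`ape::nj()`) exactly reconstructs additive matrices, so recovering the
generating topology from simulated distances is a meaningful pipeline
test. Negative branch lengths on non-additive input are clamped to zero
with a warning. Substitution-model selection, gamma/invariant-sites
estimation and Bayesian inference are out of scope.

## Micro-synteny

Loci are compared as `locus_card`s: a focal gene (possibly lost) plus
flanking markers with family ids, strands and rank distances. Defaults:
`min_ortho = 3` identical shared markers for orthology (a conserved
triad), `min_para = 2` shared marker *families* for a
fragmental-duplication call (two homologous flanking pairs, e.g.
BANF1/BANF2 and SNX32/SNX5, ground the call), `window = 8` ranks
(the conserved blocks are a 3-gene triad plus a 5-gene set).
`detect_duplication_loss()` requires both (i) the focal-less original
locus to share ≥ `min_ortho` markers with a reference genome's
focal-bearing locus and (ii) a paralogous marker-family pair (different
genes, one family, one per locus — the AKT2a/AKT2b configuration) tying
the original to the duplicated locus. Marker order and strand are
recorded but not scored: the classification argues from marker presence;
a colinearity statistic is an explicit non-goal. Absence claims ("this
genome lacks the locus") can only be made relative to a supplied
gene-order table.

## The simulator: what it emulates, and what it does not

`simulate_family()` emulates the statistical structure the analysis
assumes: an ancestral core of four consensus-matching motifs with linkers
5/5/15, flanked by ID segments whose lengths are drawn once from
`id_length` (default 100–1000 aa, the observed range), evolved along a
star tree (default 6 taxa) with per-branch, per-site substitution
probabilities `p_core = 0.02` and `p_id = 0.4`. Those defaults are the
study conditions under which the package's headline properties are
evaluated; they produce expected pairwise distances of about 0.04 at core
sites and 0.63 at ID sites between star-tree leaves
($1-[(1-p)^2 + p^2/19]$ per site pair), i.e. the strong contrast the
family exhibits. Design choices worth knowing:

* **Anchors are hard-invariant** (a `mutate_anchors` flag relaxes this),
  and substitutions at the pattern-constrained `[FWsgat]` position draw
  from the other members of that set. The generator thereby *guarantees*
  that every taxon's core matches the consensus pattern, so a detection
  failure indicates a pipeline bug, not simulation luck. Unconstrained
  substitution at that position would silently break ~5% of taxa at the
  default rates, turning the architecture-recovery property into a coin
  flip about the simulator rather than a test of the pipeline.
* **ID segments are ancestral and shared**, evolved at `p_id` with
  geometric indels (mean 3, insertion/deletion equiprobable at
  `indel_rate = 0.02` per site per branch, simulated directly in
  alignment space so the true alignment is exact). Fully independent
  per-lineage segments would leave *zero* comparable disordered sites
  under pairwise deletion and make the partition comparison undefined;
  at `p_id = 0.4` per branch the shared segments are near saturation and
  thus effectively lineage-specific, while per-lineage side
  configuration (`extension_side`, default `"N"`, the predominant side
  in this family) models outright gain/loss of whole extensions.
* **Replacements are uniform over the other 19 residues** — no empirical
  exchange matrix. The downstream statistics are distance-based, not
  model-based, so a realistic matrix would add parameters without
  changing what the tests can show. Compositional bias is modelled
  per-segment: with probability `bias_prob = 0.5` a segment is dominated
  by one residue at frequency `bias_strength = 0.5`, comfortably above
  the 0.35 patch-calling threshold.
* `emit_disorder_tracks()` converts truth ID regions into
  predictor-shaped tracks (score 0.9 inside, 0.1 outside, optional
  Gaussian noise, 0.5 threshold), so the disorder-ingestion path is
  exercised end-to-end.

What passing these simulations does **not** show: performance on real
predictor output (scores near the threshold, fragmented calls), on motifs
that have drifted outside the consensus, on alignment error (the
simulator emits the true alignment; real pipelines inherit aligner
artifacts), or under substitution processes with rate heterogeneity and
non-uniform exchange. The simulator validates the machinery, not the
biology.

A boundary case in the configuration: the validator enforces
`p_core < p_id` strictly (a disordered segment evolving no faster than
the core contradicts the model being simulated), so a fully frozen family
is expressed as `p_core = 0` with a vanishingly small `p_id`, not
`p_id = 0`.

## Problem sizes and determinism

The test suite and the acceptance script evaluate: 200 randomized
pattern/sequence cases against the scanning oracle; 100 random additive
trees (≤ 8 taxa) for neighbor joining; and 100 replicate families at the
study conditions (6-taxon star, seeds 1..100) for the partition-ordering,
Kruskal–Wallis-significance and architecture-recovery rates — sizes
chosen so the whole suite runs in well under a minute per property while
leaving the binomial margins of the ≥ 95% / ≥ 99% thresholds
interpretable. Every stochastic entry point takes an explicit seed, and
equal seed + config is guaranteed byte-identical output; `run_pipeline()`
logs the package version, a config hash and the seed alongside its
outputs.

## Known limitations

* The pattern engine is a motif grammar, not a profile method: no PSSM or
  HMM scoring, so diverged motifs outside the residue sets are invisible.
* The Kruskal–Wallis p-value inherits the non-independence caveat above.
* Column partitioning of disorder is threshold-based; genuinely ambiguous
  columns (half the rows disordered) land on the structured side at the
  default `rule_frac = 0.5`.
* Synteny verdicts depend on the completeness of the supplied gene-order
  tables; missing markers can demote orthologous to paralogous or
  unrelated.
* The bundled reference proteins are synthetic stand-ins built to the
  printed feature coordinates (their filler residues are not the real
  database sequences), so results on them validate geometry handling,
  not database retrieval.
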