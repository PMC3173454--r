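---
title: "HICF physical maps with bacmapr: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HICF physical maps with bacmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacmapr)
```

## The problem

Before a reference genome exists, a BAC-based physical map orders
large-insert clones (~100–150 kb) along chromosomes using only their
restriction *fingerprints*: each clone is digested with a cocktail of
enzymes, the fragment sizes are read on a capillary sequencer, and clones
with many shared fragment sizes are declared overlapping. Contigs of
overlapping clones are then anchored to a genetic map with hybridization
probes, concatenated into pseudomolecules, and mined for a minimum tile
path (MTP) of clones to end-sequence. bacmapr implements this pipeline
end-to-end, together with a seeded simulator so that every stage can be
validated against planted truth without any external data.

## The overlap model

Two fingerprints are compared by greedy ascending band matching: walking
both sorted integer band lists in parallel, two bands match when they
differ by at most a tolerance $t$ (in size-units), and each band is
consumed at most once. On this interval structure the greedy sweep attains
the maximum bipartite matching — the test suite certifies this against
exhaustive search on small instances rather than assuming it.

The evidence that an observed match count $m$ is not chance is the Sulston
score. With band counts $n_L \le n_H$ and a "gel" of $G$ distinguishable
size-units, the chance that any one band of the smaller clone finds a
partner is

$$p = 1 - \left(1 - \frac{2t+1}{G}\right)^{n_H},$$

and the score is the binomial upper tail

$$S = \sum_{j=m}^{n_L} \binom{n_L}{j} p^j (1-p)^{n_L - j},$$

evaluated in log space (`stats::pbinom(..., log.p = TRUE)`) so that
magnitudes like $10^{-100}$ survive; all cutoff comparisons are done on
$\log_{10} S$. Defaults follow classic HICF mapping practice:
$t = 3$, $G = 5650$ (sizes 35.0–600.0 bp at 0.1 bp per size-unit), build
cutoff $10^{-80}$, refinement cutoff $10^{-50}$, evidence merges down to
$10^{-25}$.

### What the score can and cannot certify

A useful consequence of the formula, derived here because it shapes the
whole pipeline: with ~100 in-window bands per clone, $p \approx 0.12$, so
even a *perfectly* matching pair scores only around $10^{-71}$ — the
$10^{-80}$ build cutoff is reachable only by band-rich, near-completely
overlapping clone pairs. A pair sharing 50% of its bands scores around
$10^{-15}$: decisive evidence, but far from the build cutoff. This is why
the classic procedure follows the stringent build with DQer and relaxed
end-merging at $10^{-50}$, and why small-insert clones (~30 bands, whose
best attainable score is ~$10^{-26}$) legitimately remain singletons at
every stage — a few percent of clones, as in real maps. The calibration
tests assert exactly these relationships: ≥50% physical overlap gives
$\log_{10} S \le -10$, and a band-rich clone refingerprinted with
independent sizing noise (the duplicated control-clone scenario) clears
$10^{-80}$ with probability ≥ 0.95.

## Assembly: build, layout, DQer, merges

`build_contigs()` forms single-linkage components of the graph of pairs
with $S$ at or below the build cutoff; singleton components become the
singleton list. Pairs are scored and cached down to $10^{-25}$ so that
later stages (layout, merges, DQer re-clustering) see longer-range
constraints than the build cutoff alone provides.

Layout replaces FPC's simulated-annealing consensus-band map with a
deterministic procedure adequate for the coordinate-level uses downstream
(MTP spacing, marker placement): the pairwise CB distance between clones
$i, j$ is $\tfrac{n_i + n_j}{2} - m_{ij}/\hat r$, where $\hat r$ is a
per-contig match-rate estimate (the 0.95 quantile of $m/\min(n_i,n_j)$
over contig edges, clamped to $[0.9, 1]$) correcting for the bands lost to
sizing noise; without this correction every distance is inflated by the
noise loss and layouts compress. Clones are placed in Prim order
(strongest edge to the placed set first), each at the candidate position —
either side of each placed neighbour — minimising the squared disagreement
between predicted ($\hat r \times$ CB overlap) and observed matched bands;
exact ties extend away from the placed mass. Like any fingerprint-only
layout, the result is defined up to reflection of the whole contig, so
order-accuracy checks use $|\rho|$.

A clone is *questionable* (Q) when more than half of its bands fail to
match the pooled bands of its contig-mates at tolerance $t$ (the rule is
left to FPC internals in the original software; this definition is the
package's own). `dqer()` re-clusters any contig whose Q fraction exceeds
10% at a cutoff tightened by $10^{-10}$ per step, at most three steps,
conserving clone counts. `relaxed_merge()` implements Ends-to-Ends,
Singles-to-Ends and evidence merges: end clones are members whose span
intersects the first or last `end_window_cb` of a contig (default: the
median clone span, roughly one clone deep); merges apply best-score-first
through a union-find, and evidence mode additionally requires both contigs
to carry markers of one linkage group within 10 cM.

### Accuracy metrics on simulated data

Precision is measured on the overlap *calls* — the fraction of clone pairs
scoring at or below the most permissive cutoff used ($10^{-50}$) that
truly overlap in the simulation. It is not measured on co-contig
membership: a correctly assembled, continuously covered chromosome puts
every clone in one contig, where most pairs are distant by construction,
so co-membership precision is bounded near 15% for *any* correct assembly.
Recall is co-membership of truly overlapping pairs in the final refined
map. On the default study simulation the suite requires precision ≥ 0.99
and recall ≥ 0.90, plus Spearman $|\rho| \ge 0.95$ between CB layout and
true coordinates in every large contig.

## Anchoring by 3-D pooled hybridization

125 probes occupy a $5{\times}5{\times}5$ cube; the 15 axis pools are
hybridized instead of 125 individual probes. Deconvolution is purely
combinatorial: a clone positive on exactly one pool per axis whose
coordinate holds a designed probe is a `unique` call; clones positive on
several pools per axis are `ambiguous`, with the candidate set
$A \times B \times C$ intersected with the design; an empty axis alongside
a non-empty one is an `inconsistent` artefact. Ambiguous clones are
reported, never auto-resolved, and only unique calls anchor contigs — the
classic workflow resolves ambiguity by manual hit-calling, so automation
here must be conservative. Probes hitting more than 8 locations are masked
as repetitive. A marker's CB position in a contig is the median midpoint
of its hit clones' spans (a rule FPC leaves unspecified); a contig
is anchored by any linkage-group-bearing marker, flagged as a conflict
when two groups disagree, and markers without linkage groups (COSII)
inherit their contig's group.

## Pseudomolecules, genome size, MTP

CB units convert to bp by `avg_insert_bp / avg_bands_per_clone`
(138 kb / 114.2 ≈ 1208 bp, reported as 1210 after rounding to 10 bp).
Anchored contigs are ordered by mean marker cM and oriented by the sign of
the Spearman correlation between marker CB and cM (two distinct markers
required; otherwise "unknown" and left as laid out). Consecutive contigs
are separated by a fixed 250 kb gap; gap padding never enters genome-size
statistics: the genome-size estimate is the plain sum of anchored plus
unanchored contig lengths (e.g. 307.2 + 67.4 = 374.6 Mbp at full scale); a
flag enables the gap-inclusive variant. CMAP exports carry the four
feature types (contig, gap, marker, STS) 1-based inclusive; AGP v2 uses
`W` component and `N` gap lines (250000, "contig", "no"). Internally all
coordinates are 0-based half-open.

MTP selection computes the CB spacing $n = \max(1,\mathrm{round}(m k /
i))$ — the dimensionally consistent form of the classic "n = mik" recipe,
and the one that reproduces $n = 7$ from $m = 120$ CB, $i = 138$ kb,
$k = 8$ kb. The selector walks targets
$0, n, 2n, \dots$ per contig, picking the unselected clone with the
nearest left end (ties to the smaller clone id), and skips targets within
$n/2$ CB of any existing end — prior BES clones' ends, previously selected
right ends (the "region" for that exclusion is taken as $\pm n/2$ of the
target), or previously selected left ends.
Because both ends of every selected clone are anchors and right ends
deliberately fill the grid between left ends, the achieved spacing is
measured as anchor-end density: summed contig CB span divided by
2 × selected clones, converted to bp. On the default study this lands
within 20% of the 8 kb target.

## Synteny

`chain_anchors()` is a deliberately simple, deterministic stand-in for
full dot-plot synteny software: within each (source unit, reference
chromosome) group, anchors in source order are segmented into maximal runs
with consistent reference direction and per-side gaps at most `max_gap_bp`
(default 500 kb; the demo pipeline scales it to 50 kb for its 500 kb
chromosomes); runs shorter than `min_anchors = 3` are dropped, anchors
placed at more than 8 reference locations are removed first (mirroring the
overgo repeat rule), and overlapping same-group blocks resolve in favour
of anchor count. Coverage and double-coverage are computed exactly with
`IRanges` run-length encodings. Unanchored contigs inherit a linkage group
when more than half their anchors — and strictly more than for any rival —
fall inside reference intervals of blocks from a single linkage group.
This chaining assumes locally monotone source coordinates; the demo
pipeline therefore anchors BES reads at their simulated positions rather
than CB-converted ones, whose local jitter at ~3 kb anchor spacing would
shred direction runs. `true_synteny_blocks()` derives the planted truth
from the rearrangement event log for end-to-end recovery tests.

## The simulator and what passing tests mean

`simulate_genome()` draws i.i.d. nucleotides (default GC 0.38); partial
digestion is modelled as uniform sampling of same-enzyme cut-site pairs
whose spacing fits the insert window — overlap structure without
biochemical kinetics. The default libraries mirror a three-library design:
HindIII 90–185 kb, EcoRI 40–160 kb, MboI 80–180 kb, each at 10× coverage.
Fingerprinting digests with HindIII/BamHI/XbaI/XhoI/HaeIII; in the
study-default protocol only the four sticky-cutters carry a fluorescent
label, so a fragment is observed when at least one boundary cut is
labelled (fill-in labels both flanking fragments), within a 35–600 bp
window at 0.1 bp per size-unit and Gaussian sizing noise of 1 size-unit
(0.1 bp, typical capillary repeatability). These defaults yield a median
of ~100–130 bands per clone, compatible with the 20–220 QC filter; the
per-enzyme fluorophore channels are collapsed into one band list because
FPC-style matching operates on a single digitized fingerprint per clone.

The demo study spans 2 Mbp as four 500 kb chromosomes (one linkage group
each) — separate chromosomes are what make linkage groups and contig
separability meaningful at desk scale; at 374 Mbp the corresponding design
is ten chromosomes. Simulated marker maps use a constant 10 kb/cM.
Problem sizes throughout the test suite (2 Mbp genome, ~500 clones, 10⁵
Monte-Carlo trials, 1 Mbp planted-rearrangement genome) keep the full
suite around a minute of compute while leaving every statistical assertion
with comfortable sample sizes.

Passing tests show that the algorithms recover planted truth under this
generative model. The simulator deliberately omits vector/insert
chimerism, cloning bias, repeat-driven spurious band sharing, partial-digest
band dropout correlated across clones, and real trace artefacts — so
passing says nothing about wet-lab failure modes, only about the
statistical and algorithmic core.

## Numerical choices and degenerate inputs

Scores are compared exclusively as $\log_{10}$; empty fingerprints score
exactly 1 (no evidence); QC removes them with reason "empty". Tie-breaks
are lexicographic by clone id everywhere (clustering order, MTP picks,
merge application). An effectively zero cutoff yields an all-singleton
map; an empty fingerprint set yields an empty map. Contig ids are
renumbered deterministically (size, then smallest member id) after every
refinement pass, and clone conservation (`clone_count()`) is asserted
across passes. Rearrangement events apply simultaneously to the original
genome: sources must be disjoint and destinations must fall outside every
source, which keeps the event log replayable and the planted truth
well-defined.

## Known limitations

* The layout is a spanning-tree approximation: good to a few CB locally,
  not a banded consensus map; FPC's CB maps are sharper within deep
  contigs.
* Sulston scoring inherits the formula's penalty for size-mismatched
  pairs (large $n_H$ inflates $p$), so containment of a small clone in a
  large one scores worse than equal-size overlap with the same shared
  fraction.
* Synteny chaining requires locally monotone source coordinates and has
  no rescue for noisy orders (no dot-plot filtering or block merging).
* The 3-D pool deconvolution is noise-flagging, not error-correcting:
  axis-inconsistent clones are reported, not decoded probabilistically.
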