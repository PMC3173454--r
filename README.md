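# bacmapr

Build and exploit BAC physical maps from high-information-content
fingerprints (HICF), in R.

Before a genome is sequenced, large-insert BAC clones (~100–150 kb) can be
ordered along chromosomes from their restriction fingerprints alone: clones
sharing many fragment sizes overlap, overlapping clones chain into contigs,
contigs are anchored to a genetic map with pooled hybridization probes, and
the anchored map yields chromosome-scale pseudomolecules plus a minimum
tile path (MTP) of clones for end-sequencing. bacmapr implements this
entire workflow — together with a seeded simulator of genomes, partial-digest
BAC libraries, multi-enzyme fingerprints, pooled marker hybridizations and
rearranged reference genomes, so every stage is testable against planted
truth with no external data.

## The statistical core

Two fingerprints (sorted integer band lists) are compared by greedy
tolerance matching (each band used once, match iff sizes differ by at most
*t* size-units; the greedy sweep attains the maximum bipartite matching).
The chance significance of *m* matched bands between clones with
*n<sub>L</sub> ≤ n<sub>H</sub>* bands on a gel of *G* distinct size-units
is the Sulston score — a binomial upper tail evaluated in log space:

    p = 1 − (1 − (2t+1)/G)^nH
    S = Σ_{j=m}^{nL} C(nL, j) p^j (1−p)^(nL−j)

Contigs are single-linkage components at a stringent cutoff (default
1e−80, tolerance 3, G = 5650), refined by Q-clone breakup (DQer) and
relaxed Ends-to-Ends / Singles-to-Ends merging at 1e−50, with
marker-evidence merges allowed down to 1e−25. MTP spacing uses
n = round(m·k/i) CB units (median CB per BAC × desired anchor distance /
average insert). Synteny blocks are maximal monotone anchor chains with
bounded gaps.

## Worked example

Simulate one 500 kb chromosome, three complementary BAC libraries at 10×
each (HindIII 90–185 kb, EcoRI 40–160 kb, MboI 80–180 kb), fingerprint,
QC, assemble, refine, and select a dense MTP:

```r
library(bacmapr)

genome <- simulate_genome(5e5, gc = 0.38, seed = 1)
libs   <- default_library_specs()
clones <- do.call(rbind, lapply(seq_along(libs), function(i)
  simulate_bac_library(genome, libs[[i]], seed = 10 + i)))
fps <- hicf_fingerprints(clones, genome, default_hicf_spec(), seed = 3)
fps
#> <fingerprint_set> 124 clones (TCCBa,TCCBb,TCCBc), bands/clone: median 109.5 [37-172]

qc  <- qc_filter(fps)                       # 20-220 band filter
map <- build_contigs(qc$kept, score_params(cutoff = 1e-80))
map <- dqer(map, qc$kept)
map <- relaxed_merge(map, qc$kept, 1e-50, "ends_to_ends")
map <- relaxed_merge(map, qc$kept, 1e-50, "singles_to_ends")
map
#> <physical_map> 1 contig(s) holding 113 clone(s), 11 singleton(s)
#>   largest contig: 113 clones, 425 CB
```

The chromosome assembles into a single contig; the 11 singletons are
small-insert clones whose ~40-band fingerprints cannot reach even the
relaxed cutoff (the same reason real maps retain a few percent of
singletons). Convert CB units to bp and pick an MTP aiming at an anchor
every 8 kb:

```r
model <- cb_to_bp_factor(mean(clones$insert_size), mean(band_counts(qc$kept)))
model$bp_per_cb_rounded
#> [1] 1070

n <- cb_spacing(m = median(band_counts(qc$kept)),
                i = mean(clones$insert_size), k = 8000)
mtp <- select_mtp(map, n)
mtp
#> <mtp_selection> 36 BACs (72 sequencing reactions) at n = 7 CB
mtp_mean_spacing_bp(mtp, map, model)
#> [1] 6307.48
```

Each selected BAC contributes both ends as sequence anchor points, so 72
anchors across ~454 kb of contig span ≈ one anchor every 6.3 kb.

`run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))` executes the
full study — 2 Mbp over four chromosomes, marker simulation, 5×5×5 pooled
overgo anchoring with deconvolution, pseudomolecule construction with
250 kb gaps, CMAP/AGP export, MTP selection, and synteny chaining of BES
anchors against a rearranged reference — writing every artifact table to
`run1/`. A thin command-line wrapper lives at `inst/scripts/bacmap.R`
(`Rscript bacmap.R demo --seed 1 --out run1`).

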