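test_that("genome simulation is seeded, validated, and hits its GC target", {
  g1 <- simulate_genome(1e5, 0.5, seed = 1)
  g2 <- simulate_genome(1e5, 0.5, seed = 1)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$site_index, g2$site_index)
  g3 <- simulate_genome(1e5, 0.5, seed = 2)
  expect_false(identical(g1$sequence, g3$sequence))

  expect_error(simulate_genome(1e5, 1.0), "gc")
  expect_error(simulate_genome(1e5, 0), "gc")
  expect_error(simulate_genome(-5, 0.5), "length")
  expect_error(simulate_genome(500, 0.5), "length")

  # binomial oracle: observed GC count within 3 SD of n*gc
  g <- simulate_genome(1e6, 0.38, seed = 7)
  gc_obs <- sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C"))
  sd <- sqrt(1e6 * 0.38 * 0.62)
  expect_lt(abs(gc_obs - 1e6 * 0.38), 3 * sd)

  # site index is sorted, strictly inside the sequence
  for (s in g1$site_index) {
    expect_false(is.unsorted(s, strictly = TRUE))
    if (length(s)) expect_true(all(s > 0 & s < g1$length))
  }
})

test_that("BAC library simulation respects cut sites, windows and coverage", {
  g <- simulate_genome(1e6, 0.38, seed = 3)
  spec <- library_spec("L1", "HindIII", 80e3, 120e3, clone_count = 100)
  cl <- simulate_bac_library(g, spec, seed = 4)
  expect_equal(nrow(cl), 100)
  sites <- g$site_index$HindIII
  expect_true(all(cl$true_start %in% sites))
  expect_true(all(cl$true_end %in% sites))
  expect_true(all(cl$insert_size >= 80e3 & cl$insert_size <= 120e3))
  expect_true(all(cl$true_end - cl$true_start == cl$insert_size))

  # nominal coverage = count x insert / length; empirical per-base mean
  # within 10% of it (Monte-Carlo coverage oracle via IRanges)
  nominal <- sum(cl$insert_size) / g$length
  cov <- IRanges::coverage(IRanges::IRanges(cl$true_start + 1, cl$true_end),
                           width = g$length)
  expect_lt(abs(mean(cov) - nominal) / nominal, 0.10)

  # determinism and infeasibility
  expect_identical(cl, simulate_bac_library(g, spec, seed = 4))
  tight <- library_spec("L2", "XhoI", 10, 12, clone_count = 5)
  expect_error(simulate_bac_library(g, tight, seed = 1), "infeasible")
})

test_that("HICF fingerprints match the brute-force digestion oracle", {
  # toy single-enzyme digest: GG^CC in the middle gives two 5 bp fragments
  g <- genome_from_sequence("TTTGGCCTTT")
  spec <- hicf_spec(enzymes = "HaeIII", size_min_bp = 1, size_max_bp = 600,
                    resolution_bp = 1, noise_sd = 0)
  clone <- list(true_start = 0L, true_end = 10L, clone_id = "toy")
  expect_equal(hicf_fingerprint(clone, g, spec), c(5L, 5L))

  # an insert with no recognition site yields one fragment, outside the
  # default window, hence an empty band list
  g2 <- genome_from_sequence(strrep("AT", 500))
  clone2 <- list(true_start = 0L, true_end = 1000L)
  expect_length(hicf_fingerprint(clone2, g2, default_hicf_spec()), 0)

  # noise-free multiset equality with exhaustive site enumeration on 10 kb
  g3 <- simulate_genome(2e4, 0.45, seed = 11)
  spec3 <- hicf_spec(size_min_bp = 1, size_max_bp = 1e4,
                     resolution_bp = 1, noise_sd = 0)
  clone3 <- list(true_start = 4000L, true_end = 14000L)
  got <- hicf_fingerprint(clone3, g3, spec3)
  want <- brute_force_digest(g3$sequence, 4000L, 14000L, spec3$enzymes)
  expect_identical(sort(got), sort(as.integer(want)))

  # clone outside the genome is rejected
  expect_error(hicf_fingerprint(list(true_start = -5L, true_end = 100L), g3, spec3),
               "outside")
})

test_that("marker truth is exact interval containment with sane coverage", {
  g <- simulate_genome(1e6, 0.38, seed = 13)
  clones <- data.frame(clone_id = c("a", "b"), library = "L", chrom = "chr1",
                       true_start = c(0, 200000), true_end = c(100000, 300000),
                       insert_size = 1e5, stringsAsFactors = FALSE)
  mk <- data.frame(marker_id = c("m1", "m2"), chrom = "chr1",
                   coord = c(50000, 150000), stringsAsFactors = FALSE)
  truth <- simulate_marker_truth(mk, clones, g)
  expect_identical(truth$m1, "a")
  expect_length(truth$m2, 0)
  bad <- data.frame(marker_id = "mx", chrom = "chr1", coord = 2e6)
  expect_error(simulate_marker_truth(bad, clones, g), "outside")

  # Poisson coverage oracle: mean hits per probe approximates coverage
  spec <- library_spec("L", "HindIII", 80e3, 120e3, target_coverage = 10)
  lib <- simulate_bac_library(g, spec, seed = 14)
  mk2 <- data.frame(marker_id = sprintf("p%02d", 1:40), chrom = "chr1",
                    coord = round(seq(1e5, 9e5, length.out = 40)))
  truth2 <- simulate_marker_truth(mk2, lib, g)
  hits <- lengths(truth2)
  nominal <- sum(lib$insert_size) / g$length
  expect_lt(abs(mean(hits) - nominal) / nominal, 0.20)
})

test_that("rearranged references replay their event log", {
  g <- genome_from_sequence(paste(rep(c("ACGTTGCAAC", "GGATCCTTAA"), 10),
                                  collapse = ""))
  # no events: identity
  ref0 <- simulate_rearranged_reference(g, list())
  expect_identical(ref0$sequence, g$sequence)

  # one inversion is an in-place reverse complement
  ref1 <- simulate_rearranged_reference(g, list(rearrangement_event("inversion", 50, 120)))
  want <- paste0(substr(g$sequence, 1, 50),
                 revcomp(substr(g$sequence, 51, 120)),
                 substr(g$sequence, 121, g$length))
  expect_identical(ref1$sequence, want)
  expect_equal(ref1$length, g$length)

  # coordinate mapping agrees with the segment log, flipping inside inversions
  hit <- map_genome_to_ref(ref1, c(10, 60))
  expect_equal(hit$ref_pos[hit$pos == 10], 10)
  expect_equal(hit$strand[hit$pos == 60], "-")
  expect_equal(hit$ref_pos[hit$pos == 60], 50 + (120 - 1 - 60))

  # duplications double the footprint; translocations move it
  ref2 <- simulate_rearranged_reference(g, list(rearrangement_event("duplication", 0, 30, dest_pos = 100)))
  expect_equal(ref2$length, g$length + 30)
  expect_equal(nrow(map_genome_to_ref(ref2, 5)), 2)

  # overlapping sources and in-source destinations are rejected
  expect_error(simulate_rearranged_reference(g, list(
    rearrangement_event("inversion", 10, 50),
    rearrangement_event("inversion", 40, 80))), "overlap")
  expect_error(simulate_rearranged_reference(g, list(
    rearrangement_event("translocation", 10, 50, dest_pos = 20))), "inside")
})

test_that("BES anchors land at clone ends with strand from the event log", {
  g <- simulate_genome(5e4, 0.4, seed = 21)
  clones <- data.frame(clone_id = c("c1", "c2"), library = "L", chrom = "chr1",
                       true_start = c(1000, 30000), true_end = c(11000, 40000),
                       insert_size = 10000, stringsAsFactors = FALSE)
  ref <- simulate_rearranged_reference(g, list())
  a <- simulate_bes_anchors(clones, ref, read_len = 500, seed = 1)
  expect_equal(a$ref_start[a$anchor_id == "c1_L"], 1000)
  expect_equal(a$ref_start[a$anchor_id == "c1_R"], 10500)
  expect_true(all(a$strand == "+"))
  expect_true(all(a$pct_identity >= 74 & a$pct_identity <= 100))

  # paired ends of one clone sit insert_size - read_len apart on an
  # identity reference
  d <- a$ref_start[a$anchor_id == "c2_R"] - a$ref_start[a$anchor_id == "c2_L"]
  expect_equal(d, 10000 - 500)

  # an end inside an inverted segment flips strand
  refi <- simulate_rearranged_reference(g, list(rearrangement_event("inversion", 25000, 45000)))
  ai <- simulate_bes_anchors(clones, refi, read_len = 500, seed = 1)
  expect_equal(ai$strand[ai$anchor_id == "c2_L"], "-")
  expect_equal(ai$strand[ai$anchor_id == "c1_L"], "+")

  expect_error(simulate_bes_anchors(clones, ref, read_len = 20000), "exceeds")
})
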