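test_that("3-D pool design partitions probes into axis slices", {
  probes <- sprintf("P%03d", 1:125)
  d <- design_3d_pools(probes, c(5, 5, 5))
  expect_length(d$pools, 15)
  expect_true(all(lengths(d$pools[sprintf("X%d", 1:5)]) == 25))
  # each probe sits in exactly three pools, one per axis
  membership <- table(unlist(d$pools))
  expect_true(all(membership == 3))
  # per-axis pool sizes sum to the probe count
  for (ax in c("X", "Y", "Z"))
    expect_equal(sum(lengths(d$pools[startsWith(names(d$pools), ax)])), 125)

  d1 <- design_3d_pools("solo", c(5, 5, 5))
  expect_equal(sum(vapply(d1$pools, function(p) "solo" %in% p, logical(1))), 3)
  expect_error(design_3d_pools(sprintf("q%d", 1:126), c(5, 5, 5)), "capacity")
})

test_that("deconvolution classifies negatives, uniques, ambiguities and artefacts", {
  probes <- sprintf("P%03d", 1:125)
  d <- design_3d_pools(probes, c(5, 5, 5))
  hits <- matrix(FALSE, 15, 4, dimnames = list(names(d$pools),
                                               c("neg", "uni", "amb", "bad")))
  hits[c("X2", "Y3", "Z1"), "uni"] <- TRUE
  # two true probes at (1,1,1) and (2,2,2)
  hits[c("X1", "X2", "Y1", "Y2", "Z1", "Z2"), "amb"] <- TRUE
  hits[c("X4"), "bad"] <- TRUE
  res <- deconvolve(d, hits)
  st <- setNames(res$clones$status, res$clones$clone_id)
  expect_equal(unname(st[c("neg", "uni", "amb", "bad")]),
               c("negative", "unique", "ambiguous", "inconsistent"))
  # the unique call is the probe at coordinate (2,3,1)
  co <- d$coords
  expect_equal(res$candidates$uni,
               co$probe_id[co$x == 2 & co$y == 3 & co$z == 1])
  expect_equal(res$probe_hits[[res$candidates$uni]], "uni")

  # brute-force enumeration oracle: a probe is a candidate iff its three
  # axis pools are all positive for the clone
  oracle <- co$probe_id[vapply(seq_len(nrow(co)), function(k)
    hits[paste0("X", co$x[k]), "amb"] &&
      hits[paste0("Y", co$y[k]), "amb"] &&
      hits[paste0("Z", co$z[k]), "amb"], logical(1))]
  expect_setequal(res$candidates$amb, oracle)
  expect_length(res$candidates$amb, 8)

  expect_error(deconvolve(d, matrix(FALSE, 2, 1, dimnames = list(c("X1", "QQ"), "c"))),
               "pool")
})

test_that("multi-probe ambiguity is bounded by k^3 and noise-free recovery is exact", {
  probes <- sprintf("P%03d", 1:125)
  d <- design_3d_pools(probes, c(5, 5, 5))
  # k true probes per clone, k = 1..3
  for (k in 1:3) {
    chosen <- probes[seq(1, by = 31, length.out = k)]
    pos <- unique(unlist(lapply(chosen, function(p) {
      co <- d$coords[d$coords$probe_id == p, ]
      c(paste0("X", co$x), paste0("Y", co$y), paste0("Z", co$z))
    })))
    hits <- matrix(FALSE, 15, 1, dimnames = list(names(d$pools), "c"))
    hits[pos, 1] <- TRUE
    res <- deconvolve(d, hits)
    expect_lte(res$clones$n_candidates, k^3)
    expect_true(all(chosen %in% res$candidates$c))
    if (k == 1) expect_equal(res$clones$status, "unique")
  }
})

test_that("repetitive probes are screened at the hit bound", {
  counts <- c(a = 0, b = 8, c = 9, d = 30)
  out <- screen_probes(counts, max_hits = 8)
  expect_setequal(out$kept, c("a", "b"))
  expect_setequal(out$masked$probe_id, c("c", "d"))
  expect_true(all(out$masked$reason == "repetitive"))
  expect_equal(length(out$kept) + nrow(out$masked), length(counts))
  expect_error(screen_probes(c(x = -1)), ">= 0")
})

test_that("framework anchoring assigns linkage groups and flags conflicts", {
  contigs <- list(
    ctg1 = data.frame(clone_id = c("a1", "a2", "a3"),
                      left_cb = c(0, 50, 100), right_cb = c(120, 170, 220),
                      stringsAsFactors = FALSE),
    ctg2 = data.frame(clone_id = c("b1", "b2"),
                      left_cb = c(0, 30), right_cb = c(100, 130),
                      stringsAsFactors = FALSE),
    ctg3 = data.frame(clone_id = "c1", left_cb = 0, right_cb = 90,
                      stringsAsFactors = FALSE))
  map <- mock_map(contigs)
  markers <- data.frame(
    marker_id = c("ssr1", "ssr2", "ssr3", "cos1", "lost"),
    class = c("SSR", "SSR", "SSR", "COSII", "SSR"),
    linkage_group = c("LG2", "LG1", "LG4", NA, "LG5"),
    cm = c(30, 10, 12, NA, 50), stringsAsFactors = FALSE)
  hits <- list(ssr1 = c("a1", "a2"),          # ctg1
               ssr2 = c("b1", "b2"),          # ctg2 ...
               ssr3 = "b2",                   # ... conflicting LG
               cos1 = c("a3", "c1"),          # COSII in two contigs
               lost = "nobody")
  out <- anchor_contigs(map, hits, markers)

  a <- out$anchored
  expect_equal(a$linkage_group[a$contig_id == "ctg1"], "LG2")
  expect_false(a$conflict[a$contig_id == "ctg1"])
  expect_true(a$conflict[a$contig_id == "ctg2"])
  expect_false("ctg3" %in% a$contig_id)     # COSII alone never anchors
  expect_true("ctg3" %in% out$unanchored)

  # marker CB position is the median hit-clone midpoint
  pl <- out$placements
  expect_equal(pl$cb[pl$marker_id == "ssr1" & pl$contig_id == "ctg1"],
               median(c(60, 110)))
  # COSII inherits its contig's linkage group where one exists
  expect_equal(pl$inferred_lg[pl$marker_id == "cos1" & pl$contig_id == "ctg1"], "LG2")
  expect_true(is.na(pl$inferred_lg[pl$marker_id == "cos1" & pl$contig_id == "ctg3"]))

  expect_setequal(out$report$multi_contig_markers, "cos1")
  expect_setequal(out$report$unplaced_markers, "lost")
  expect_equal(out$report$single_location_rate, 1 - 1 / 4)
})
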