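test_that("the CB-to-bp model reproduces the reporting arithmetic", {
  m <- cb_to_bp_factor(138000, 114.2)
  expect_equal(m$bp_per_cb, 1208.406, tolerance = 1e-3)
  expect_equal(m$bp_per_cb_rounded, 1210)
  expect_equal(cb_to_bp_factor(100000, 100)$bp_per_cb, 1000)
  # inverse identity
  expect_equal(m$bp_per_cb * 114.2, 138000)
  expect_error(cb_to_bp_factor(0, 100), "> 0")
})

ord_fixture <- function() {
  anchored <- data.frame(
    contig_id = c("ctgA", "ctgB", "ctgC", "ctgD"),
    linkage_group = c("LG1", "LG1", "LG1", "LG2"),
    mean_cm = c(10, 40, 25, 5), n_markers = c(2, 2, 1, 1),
    conflict = FALSE, stringsAsFactors = FALSE)
  placements <- data.frame(
    marker_id = c("m1", "m2", "m3", "m4", "m5", "m6"),
    contig_id = c("ctgA", "ctgA", "ctgB", "ctgB", "ctgC", "ctgD"),
    cb = c(100, 900, 100, 900, 500, 400),
    linkage_group = c("LG1", "LG1", "LG1", "LG1", "LG1", "LG2"),
    cm = c(8, 12, 50, 20, 25, 5),
    class = "SSR", stringsAsFactors = FALSE)
  list(anchored = anchored, placements = placements)
}

test_that("contigs are ordered by genetic position and oriented by rank trend", {
  fx <- ord_fixture()
  oo <- order_and_orient(fx$anchored, fx$placements)
  lg1 <- oo$ordered[oo$ordered$linkage_group == "LG1", ]
  expect_equal(lg1$contig_id, c("ctgA", "ctgC", "ctgB"))  # 10, 25, 40 cM
  expect_equal(lg1$orientation[lg1$contig_id == "ctgA"], "+")
  expect_equal(lg1$orientation[lg1$contig_id == "ctgB"], "-")  # cb up, cM down
  expect_equal(lg1$orientation[lg1$contig_id == "ctgC"], "unknown")

  # a contig with no cM-bearing marker is excluded and reported
  anch2 <- rbind(fx$anchored,
                 data.frame(contig_id = "ctgE", linkage_group = "LG2",
                            mean_cm = NaN, n_markers = 1, conflict = FALSE))
  pl2 <- rbind(fx$placements,
               data.frame(marker_id = "cosx", contig_id = "ctgE", cb = 10,
                          linkage_group = "LG2", cm = NA, class = "COSII"))
  oo2 <- order_and_orient(anch2, pl2)
  expect_setequal(oo2$excluded, "ctgE")
})

test_that("pseudomolecules insert fixed gaps and mirror minus-strand features", {
  lens_cb <- c(ctgA = 10e6, ctgC = 5e6, ctgB = 2e6, ctgD = 3e5)  # bp_per_cb = 1
  contigs <- lapply(lens_cb, function(L)
    data.frame(clone_id = "x", left_cb = 0, right_cb = L, stringsAsFactors = FALSE))
  map <- mock_map(contigs)
  fx <- ord_fixture()
  model <- cb_to_bp_factor(100, 100)  # 1 bp per CB
  pms <- build_pseudomolecules(oo <- order_and_orient(fx$anchored, fx$placements)$ordered,
                               map, model, fx$placements, gap_bp = 250000)
  lg1 <- pms$Pseudo_LG1
  expect_equal(lg1$length_bp, 17e6 + 2 * 250000)
  expect_equal(sum(lg1$features$type == "gap"), 2)
  expect_true(all(diff(lg1$features$start) >= 0))

  # single-contig linkage groups carry no gap
  expect_equal(sum(pms$Pseudo_LG2$features$type == "gap"), 0)

  # minus-strand mirroring is an involution around the contig span
  f <- lg1$features
  m3 <- f[f$name == "m3", ]            # ctgB is "-", cb 100 in a 2e6 contig
  ctgB <- f[f$name == "ctgB", ]
  expect_equal(m3$start - ctgB$start, 2e6 - 1 - 100)
  m1 <- f[f$name == "m1", ]            # ctgA is "+", cb 100 stays 100
  expect_equal(m1$start, 100)
})

test_that("genome size statistics exclude gap padding by default", {
  contigs <- list(
    anc = data.frame(clone_id = "a", left_cb = 0, right_cb = 307.2e6),
    una = data.frame(clone_id = "b", left_cb = 0, right_cb = 67.4e6))
  map <- mock_map(contigs)
  anchored <- data.frame(contig_id = "anc", linkage_group = "LG1",
                         stringsAsFactors = FALSE)
  model <- cb_to_bp_factor(100, 100)  # 1 bp per CB
  st <- genome_size_stats(map, anchored, model)
  expect_equal(st$anchored_mbp, 307.2)
  expect_equal(st$unanchored_mbp, 67.4)
  expect_equal(st$genome_mbp, 374.6)
  expect_equal(st$pct_anchored, 82.0)

  st2 <- genome_size_stats(mock_map(contigs["anc"]), anchored, model)
  expect_equal(st2$pct_anchored, 100.0)

  # the "(+ gaps)" accounting variant only pads between anchored contigs
  twoanc <- mock_map(list(a1 = contigs$anc, a2 = contigs$anc))
  anch2 <- data.frame(contig_id = c("a1", "a2"), linkage_group = "LG1")
  with_gap <- genome_size_stats(twoanc, anch2, model, include_gaps = TRUE)
  expect_equal(with_gap$anchored_mbp, round(2 * 307.2 + 0.25, 1))
})

test_that("CMAP and AGP exports round-trip exactly", {
  fx <- ord_fixture()
  lens <- c(ctgA = 1e6, ctgC = 4e5, ctgB = 2e5, ctgD = 3e5)
  contigs <- lapply(lens, function(L)
    data.frame(clone_id = "x", left_cb = 0, right_cb = L, stringsAsFactors = FALSE))
  map <- mock_map(contigs)
  model <- cb_to_bp_factor(100, 100)
  oo <- order_and_orient(fx$anchored, fx$placements)
  pms <- build_pseudomolecules(oo$ordered, map, model, fx$placements)

  fc <- tempfile(fileext = ".cmap")
  export_cmap(pms, fc)
  back <- read_cmap(fc)
  expect_setequal(names(back), names(pms))
  for (nm in names(pms)) {
    expect_equal(back[[nm]]$features, pms[[nm]]$features)
    expect_equal(back[[nm]]$length_bp, pms[[nm]]$length_bp)
  }

  fa <- tempfile(fileext = ".agp")
  export_agp(pms, fa)
  agp <- readLines(fa)
  lg1 <- grep("^Pseudo_LG1\t", agp, value = TRUE)
  expect_length(lg1, 5)                       # 3 contigs + 2 gaps
  expect_equal(sapply(strsplit(lg1, "\t"), `[`, 4), as.character(1:5))
  gap <- strsplit(grep("\tN\t", lg1, value = TRUE)[1], "\t")[[1]]
  expect_equal(gap[6], "250000")
  expect_equal(gap[7:8], c("contig", "no"))
  # AGP round trip restores the spine coordinates exactly (gap names are
  # synthesised from part numbers; the format carries none)
  back2 <- read_agp(fa)
  spine <- pms$Pseudo_LG1$features
  spine <- spine[spine$type %in% c("contig", "gap"), ]
  rownames(spine) <- NULL
  expect_equal(back2$Pseudo_LG1$features[, c("type", "start", "end")],
               spine[, c("type", "start", "end")])
  expect_equal(back2$Pseudo_LG1$length_bp, pms$Pseudo_LG1$length_bp)

  # empty export writes headers only
  f0 <- tempfile()
  export_cmap(list(), f0)
  expect_equal(length(readLines(f0)), 1)
})
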