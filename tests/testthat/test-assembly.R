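# Deterministic fixtures built from well-separated band values (spacing 10,
# so tolerance 3 never cross-matches distinct values).

# chain A-B-C: adjacent pairs share exactly half their bands
chain_fps <- function() {
  A <- seq(10L, 400L, 10L)
  B <- sort(c(seq(210L, 400L, 10L), seq(1010L, 1200L, 10L)))
  C <- sort(c(seq(1010L, 1200L, 10L), seq(2010L, 2200L, 10L)))
  fingerprint_set(c("A", "B", "C"), "L", list(A, B, C))
}

# two 2-clone contigs whose end clones share 57/60 bands (S ~ 1e-60.8),
# a singleton sharing 54/60 (~1e-54), and a relative sharing 40/60 (~1e-30.8)
merge_fps <- function() {
  X <- seq(10L, 600L, 10L)
  Y <- sort(c(X[1:57], c(2005L, 2015L, 2025L)))
  Z <- sort(c(X[1:54], seq(3005L, 3055L, 10L)))
  W <- sort(c(X[1:40], seq(4005L, 4195L, 10L)))
  fingerprint_set(c("X1", "X2", "Y1", "Y2", "Z0", "W1", "W2"), "L",
                  list(X, X, Y, Y, Z, W, W))
}

test_that("single-linkage build separates families and degenerates cleanly", {
  fps <- merge_fps()
  map <- build_contigs(fps, score_params(cutoff = 1e-65))
  expect_equal(length(map$contigs), 3)  # {X1,X2}, {Y1,Y2}, {W1,W2}
  expect_setequal(map$singletons, "Z0")
  expect_equal(clone_count(map), 7)
  fam <- function(ids) unique(substr(ids, 1, 1))
  for (m in map$contigs) expect_length(fam(m$clone_id), 1)

  # an (effectively) zero cutoff leaves every clone a singleton
  map0 <- build_contigs(fps, score_params(cutoff = 1e-300))
  expect_length(map0$contigs, 0)
  expect_length(map0$singletons, 7)

  # empty input gives an empty map; rebuilds are bit-identical
  expect_length(build_contigs(fps[integer(0)])$contigs, 0)
  expect_identical(map, build_contigs(fps, score_params(cutoff = 1e-65)))
})

test_that("CB layout places identical clones together and chains additively", {
  fps <- chain_fps()
  params <- score_params(cutoff = 1e-10)
  map <- build_contigs(fps, params)
  expect_length(map$contigs, 1)
  mem <- map$contigs[[1]]
  # half-overlap chain: C starts about one clone length from A
  xa <- mem$left_cb[mem$clone_id == "A"]
  xc <- mem$left_cb[mem$clone_id == "C"]
  xb <- mem$left_cb[mem$clone_id == "B"]
  expect_true(xb > min(xa, xc) && xb < max(xa, xc))
  expect_lt(abs(abs(xc - xa) - 40), 6)
  expect_true(all(mem$right_cb - mem$left_cb == 40))
  expect_equal(min(mem$left_cb), 0)

  # identical fingerprints overlay exactly
  twin <- fingerprint_set(c("t1", "t2"), "L", list(seq(10L, 300L, 10L), seq(10L, 300L, 10L)))
  lay <- layout_contig(c("t1", "t2"), twin, score_params(cutoff = 1e-20))
  expect_equal(lay$left_cb, c(0, 0))
  expect_equal(lay$right_cb, c(30, 30))

  # members without connecting scores cannot be laid out
  expect_error(layout_contig(c("A", "C"), fps, params), "not connected")
})

test_that("DQer breaks a planted chimera and respects its thresholds", {
  A <- bands_block(30)                      # 10..300
  B <- bands_block(30, offset = 1000)       # 1010..1300
  bridge <- sort(c(A[1:7], B[1:7], bands_block(16, offset = 2000)))
  fps <- fingerprint_set(c(sprintf("a%d", 1:4), sprintf("b%d", 1:4), "qq"), "L",
                         c(rep(list(A), 4), rep(list(B), 4), list(bridge)))
  params <- score_params(cutoff = 1e-4)
  map <- build_contigs(fps, params)
  expect_length(map$contigs, 1)             # one chimeric contig via the bridge
  expect_equal(sum(map$contigs[[1]]$q_flag), 1)
  expect_equal(map$contigs[[1]]$clone_id[map$contigs[[1]]$q_flag], "qq")

  split <- dqer(map, fps, q_threshold = 0.10)
  expect_length(split$contigs, 2)           # the two true regions
  expect_setequal(split$singletons, "qq")
  expect_equal(clone_count(split), 9)

  # q_threshold = 1 never breaks anything; a Q-free contig is untouched
  expect_identical(dqer(map, fps, q_threshold = 1)$contigs, map$contigs)
  clean <- build_contigs(fps[1:8], params)
  expect_identical(dqer(clean, fps[1:8])$contigs, clean$contigs)
})

test_that("relaxed end merges honour cutoffs, evidence and singletons", {
  fps <- merge_fps()
  params <- score_params(cutoff = 1e-65)
  map <- build_contigs(fps, params)

  # X/Y end pair scores ~1e-60.8: merged at 1e-50, never at 1e-80
  m80 <- relaxed_merge(map, fps, 1e-80, "ends_to_ends")
  expect_length(m80$contigs, 3)
  m50 <- relaxed_merge(map, fps, 1e-50, "ends_to_ends")
  expect_length(m50$contigs, 2)
  xy <- m50$contigs[[which.max(vapply(m50$contigs, nrow, integer(1)))]]
  expect_setequal(xy$clone_id, c("X1", "X2", "Y1", "Y2"))
  expect_equal(clone_count(m50), 7)

  # the singleton (~1e-54) attaches in singles_to_ends at 1e-50
  s50 <- relaxed_merge(m50, fps, 1e-50, "singles_to_ends")
  expect_length(s50$singletons, 0)
  expect_equal(clone_count(s50), 7)

  # W joins X only with same-linkage-group evidence at a relaxed cutoff
  mk <- function(map) data.frame(
    contig_id = names(map$contigs),
    linkage_group = "LG1",
    cm = c(10, 12)[seq_along(map$contigs)], stringsAsFactors = FALSE)
  ev <- relaxed_merge(m50, fps, 1e-28, "evidence", markers = mk(m50))
  expect_length(ev$contigs, 1)
  plain <- relaxed_merge(m50, fps, 1e-50, "ends_to_ends")
  expect_length(plain$contigs, 2)

  # genetic window and floor are enforced
  far <- data.frame(contig_id = names(m50$contigs), linkage_group = "LG1",
                    cm = c(10, 200), stringsAsFactors = FALSE)
  expect_length(relaxed_merge(m50, fps, 1e-28, "evidence", markers = far)$contigs, 2)
  expect_error(relaxed_merge(m50, fps, 1e-28, "evidence"), "marker")
  expect_error(relaxed_merge(m50, fps, 1e-20, "evidence", markers = mk(m50)),
               "floor")
})

test_that("contig summaries bin sizes and conserve clone counts", {
  empty <- mock_map(list())
  es <- contig_summary(empty)
  expect_equal(nrow(es$contigs), 0)
  expect_equal(es$total_clones, 0)

  sizes <- c(2, 10, 150)
  contigs <- lapply(seq_along(sizes), function(k) {
    n <- sizes[k]
    data.frame(clone_id = sprintf("c%d_%03d", k, seq_len(n)),
               left_cb = 0, right_cb = 100, stringsAsFactors = FALSE)
  })
  names(contigs) <- sprintf("ctg%d", 1:3)
  map <- mock_map(contigs, singletons = c("s1", "s2"))
  cs <- contig_summary(map, breaks = c(5, 15, 100))
  expect_equal(unname(as.vector(cs$histogram)), c(1, 1, 0, 1))
  expect_equal(cs$total_clones, sum(sizes) + 2)
  expect_equal(cs$n_singletons, 2)
})

test_that("the FPC subset dialect round-trips placements", {
  fps <- merge_fps()
  map <- build_contigs(fps, score_params(cutoff = 1e-65))
  f <- tempfile(fileext = ".fpc")
  write_fpc(map, fps, f)
  back <- read_fpc(f)
  expect_setequal(back$singletons, map$singletons)
  for (cn in names(map$contigs)) {
    mem <- map$contigs[[cn]]
    got <- back$placements[back$placements$contig_id == cn, ]
    expect_setequal(got$clone_id, mem$clone_id)
    expect_equal(got$left_cb[match(mem$clone_id, got$clone_id)], mem$left_cb,
                 tolerance = 1e-3)
  }
  writeLines(c('BAC : "x"', "Map broken"), f)
  expect_error(read_fpc(f), "malformed")
})
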