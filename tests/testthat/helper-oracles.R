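# Independent oracles and shared fixtures for the test suite.

# Exhaustive maximum bipartite matching between two band lists under a
# tolerance: recursion over the first list, trying every compatible partner.
brute_force_match <- function(a, b, tol) {
  if (length(a) == 0 || length(b) == 0) return(0L)
  best <- brute_force_match(a[-1], b, tol)
  for (j in seq_along(b)) {
    if (abs(a[1] - b[j]) <= tol)
      best <- max(best, 1L + brute_force_match(a[-1], b[-j], tol))
  }
  best
}

# Direct (non-log) binomial tail of the Sulston score, valid where the terms
# are representable in double precision.
sulston_direct <- function(m, n1, n2, tol, gellen) {
  nL <- min(n1, n2); nH <- max(n1, n2)
  if (nL == 0 || m <= 0) return(1)
  p <- 1 - (1 - (2 * tol + 1) / gellen)^nH
  j <- m:nL
  sum(choose(nL, j) * p^j * (1 - p)^(nL - j))
}

# Brute-force digestion oracle: every recognition-site occurrence found by
# plain string scanning (independent of Biostrings), fragment widths between
# consecutive cuts inside [from, to).
brute_force_digest <- function(sequence, from, to, enzymes) {
  tab <- restriction_enzymes()
  cuts <- integer(0)
  for (e in enzymes) {
    row <- tab[tab$enzyme == e, ]
    hits <- gregexpr(row$site, sequence, fixed = TRUE)[[1]]
    if (hits[1] != -1) cuts <- c(cuts, hits - 1L + row$cut_offset)
  }
  cuts <- sort(unique(cuts[cuts > from & cuts < to]))
  diff(c(from, cuts, to))
}

# Manual reverse complement, independent of Biostrings.
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Hand-built physical map from a named list of member data frames
# (clone_id, left_cb, right_cb); enough structure for anchoring/scaffold/MTP.
mock_map <- function(contigs, singletons = character(0),
                     params = score_params()) {
  contigs <- lapply(contigs, function(m) {
    if (is.null(m$library)) m$library <- "LIB"
    if (is.null(m$q_flag)) m$q_flag <- FALSE
    m
  })
  structure(list(contigs = contigs, singletons = singletons, params = params,
                 edges = data.frame(clone_i = character(0), clone_j = character(0),
                                    m = integer(0), log10S = numeric(0)),
                 log = character(0)),
            class = "physical_map")
}

# Deterministic fingerprint fixtures: `n` well-separated band values so that
# no accidental tolerance matches occur (spacing 10 > 2*3 + 1).
bands_block <- function(n, offset = 0) as.integer(seq(10, by = 10, length.out = n) + offset)

# The 2 Mbp / 3 libraries x 10x study simulation, run once per test session.
study_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(pipeline_config(seed = 1))
    cache
  }
})

# Truth lookup for the study run: per kept clone, chromosome and interval.
study_truth <- function(res) {
  ix <- match(res$qc$kept$clone_id, res$clones$clone_id)
  data.frame(clone_id = res$qc$kept$clone_id,
             chrom = res$clones$chrom[ix],
             start = res$clones$true_start[ix],
             end = res$clones$true_end[ix],
             insert = res$clones$insert_size[ix],
             stringsAsFactors = FALSE)
}

# Planted-rearrangement fixture shared by synteny tests: a 1 Mbp genome with
# one 200 kb inversion and one 100 kb translocation, plus dense noise-free
# BES anchors from 2 kb clones tiled every 2 kb.
planted_rearrangement <- function() {
  g <- simulate_genome(1e6, 0.4, seed = 9, name = "srcA")
  events <- list(
    rearrangement_event("inversion", 2e5, 4e5),
    rearrangement_event("translocation", 6e5, 7e5, dest_pos = 1e5)
  )
  ref <- simulate_rearranged_reference(g, events, name = "refA")
  starts <- seq(0, g$length - 2000, by = 2000)
  clones <- data.frame(clone_id = sprintf("tile_%04d", seq_along(starts)),
                       library = "TILE", chrom = g$name,
                       true_start = starts, true_end = starts + 2000,
                       insert_size = 2000, stringsAsFactors = FALSE)
  anchors <- simulate_bes_anchors(clones, ref, read_len = 500, seed = 5)
  list(genome = g, ref = ref, anchors = anchors)
}
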