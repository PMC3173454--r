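#' Chain sequence anchors into synteny blocks
#'
#' Within each (source unit, reference chromosome) group, anchors are taken
#' in source order and segmented into maximal runs whose reference positions
#' move monotonically in one direction (forward or inverted) with consecutive
#' gaps of at most `max_gap_bp` on both the source and reference sides. Runs
#' shorter than `min_anchors` are discarded. This is a deliberately simple,
#' deterministic stand-in for full dot-plot synteny computation. Repetitive
#' anchors (same sequence id placed at more than `max_hits` reference
#' locations) are dropped first.
#'
#' @param anchors data frame: `anchor_id`, `source_id`, `source_pos` (bp),
#'   `ref_chrom`, `ref_start`, `ref_end`, `strand` (ignored; orientation is
#'   inferred from collinearity), plus optional columns.
#' @param max_gap_bp maximum per-side gap between chained anchors.
#' @param min_anchors minimum anchors per block.
#' @param max_hits repeat filter: anchors whose `anchor_id` occurs at more
#'   than this many reference locations are removed.
#' @return Data frame of blocks: `source_id`, `ref_chrom`, `source_start`,
#'   `source_end`, `ref_start`, `ref_end`, `n_anchors`, `orientation`
#'   (forward/inverted), `length_bp` (reference side).
#' @export
chain_anchors <- function(anchors, max_gap_bp = 5e5, min_anchors = 3L,
                          max_hits = 8L) {
  empty <- data.frame(source_id = character(0), ref_chrom = character(0),
                      source_start = numeric(0), source_end = numeric(0),
                      ref_start = numeric(0), ref_end = numeric(0),
                      n_anchors = integer(0), orientation = character(0),
                      length_bp = numeric(0))
  if (nrow(anchors) == 0) return(empty)
  reps <- table(anchors$anchor_id)
  anchors <- anchors[anchors$anchor_id %in% names(reps)[reps <= max_hits], , drop = FALSE]
  blocks <- list()
  for (key in unique(paste(anchors$source_id, anchors$ref_chrom, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    a <- anchors[anchors$source_id == parts[1] & anchors$ref_chrom == parts[2], , drop = FALSE]
    a <- a[order(a$source_pos, a$ref_start), , drop = FALSE]
    mid <- (a$ref_start + a$ref_end) / 2
    if (nrow(a) == 1) { runs <- list(1L) } else {
      dirs <- sign(diff(mid))
      gap_ok <- diff(a$source_pos) <= max_gap_bp & abs(diff(mid)) <= max_gap_bp
      # segment at oversized gaps and at direction changes
      dir_change <- c(FALSE, dirs[-1] != dirs[-length(dirs)])
      breaks <- c(FALSE, !gap_ok | dir_change)
      runs <- split(seq_len(nrow(a)), cumsum(breaks))
    }
    for (idx in runs) {
      if (length(idx) < min_anchors) next
      sub <- a[idx, , drop = FALSE]
      submid <- mid[idx]
      orient <- if (length(idx) >= 2 && submid[length(submid)] < submid[1])
        "inverted" else "forward"
      blocks[[length(blocks) + 1]] <- data.frame(
        source_id = parts[1], ref_chrom = parts[2],
        source_start = min(sub$source_pos), source_end = max(sub$source_pos),
        ref_start = min(sub$ref_start), ref_end = max(sub$ref_end),
        n_anchors = length(idx), orientation = orient,
        length_bp = max(sub$ref_end) - min(sub$ref_start),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks) %||% empty
  # within a group, keep at most one block over any reference interval
  # (anchor-rich blocks win)
  keep <- rep(TRUE, nrow(out))
  for (gi in unique(paste(out$source_id, out$ref_chrom))) {
    sel <- which(paste(out$source_id, out$ref_chrom) == gi)
    taken <- IRanges::IRanges()
    for (r in sel[order(-out$n_anchors[sel], out$ref_start[sel])]) {
      ir <- IRanges::IRanges(start = out$ref_start[r] + 1, end = out$ref_end[r])
      if (sum(IRanges::countOverlaps(ir, taken)) > 0) keep[r] <- FALSE
      else taken <- c(taken, ir)
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$source_id, out$ref_chrom, out$source_start), , drop = FALSE]
}

#' Synteny block statistics
#'
#' Block-size bins (edges at 1 and 3 Mbp, lower edge inclusive), reference
#' coverage by at least one block, double-coverage by at least two blocks,
#' and the longest block.
#'
#' @param blocks data frame from [chain_anchors()].
#' @param ref_sizes named numeric vector of reference chromosome lengths, bp.
#' @return List: `bins` (named counts `<1Mbp`, `1-3Mbp`, `>3Mbp`),
#'   `coverage`, `double_coverage` (fractions of total reference bp),
#'   `longest_block_bp`.
#' @export
block_stats <- function(blocks, ref_sizes) {
  if (any(ref_sizes <= 0) || length(ref_sizes) == 0)
    stopf("reference sizes must be positive")
  bins <- c("<1Mbp" = sum(blocks$length_bp < 1e6),
            "1-3Mbp" = sum(blocks$length_bp >= 1e6 & blocks$length_bp < 3e6),
            ">3Mbp" = sum(blocks$length_bp >= 3e6))
  total <- sum(ref_sizes)
  cov1 <- 0; cov2 <- 0
  for (chr in names(ref_sizes)) {
    b <- blocks[blocks$ref_chrom == chr, , drop = FALSE]
    if (nrow(b) == 0) next
    ir <- IRanges::IRanges(start = pmax(1, b$ref_start + 1),
                           end = pmin(ref_sizes[[chr]], b$ref_end))
    cov <- IRanges::coverage(ir, width = ref_sizes[[chr]])
    cov1 <- cov1 + sum(S4Vectors::runLength(cov)[S4Vectors::runValue(cov) >= 1])
    cov2 <- cov2 + sum(S4Vectors::runLength(cov)[S4Vectors::runValue(cov) >= 2])
  }
  list(bins = bins, coverage = cov1 / total, double_coverage = cov2 / total,
       longest_block_bp = if (nrow(blocks)) max(blocks$length_bp) else 0)
}

#' Predict linkage groups for unanchored contigs by collinearity
#'
#' An unanchored contig inherits a linkage group when more than half of its
#' chained anchors — and strictly more than for any rival linkage group —
#' fall inside reference intervals occupied by synteny blocks of anchored
#' contigs from a single linkage group.
#'
#' @param anchors anchors of unanchored contigs (`source_id`, `ref_chrom`,
#'   `ref_start`, `ref_end`).
#' @param anchored_blocks blocks of anchored contigs (from [chain_anchors()])
#'   with an added `linkage_group` column.
#' @return Data frame: `source_id`, `linkage_group` (NA when "ambiguous" or
#'   "none"), `status` (assigned/ambiguous/none), `support` (anchor fraction
#'   behind the winning linkage group).
#' @export
predict_linkage_groups <- function(anchors, anchored_blocks) {
  out <- list()
  for (cid in unique(anchors$source_id)) {
    a <- anchors[anchors$source_id == cid, , drop = FALSE]
    mids <- (a$ref_start + a$ref_end) / 2
    votes <- character(0)
    for (k in seq_len(nrow(a))) {
      inside <- anchored_blocks$ref_chrom == a$ref_chrom[k] &
        anchored_blocks$ref_start <= mids[k] & mids[k] < anchored_blocks$ref_end
      votes <- c(votes, unique(anchored_blocks$linkage_group[inside]))
    }
    n_anchor <- nrow(a)
    if (length(votes) == 0) {
      out[[length(out) + 1]] <- data.frame(source_id = cid, linkage_group = NA_character_,
                                           status = "none", support = 0,
                                           stringsAsFactors = FALSE)
      next
    }
    tab <- sort(table(votes), decreasing = TRUE)
    frac <- tab[1] / n_anchor
    rival <- if (length(tab) > 1) tab[2] else 0
    if (frac > 0.5 && tab[1] > rival) {
      out[[length(out) + 1]] <- data.frame(source_id = cid,
                                           linkage_group = names(tab)[1],
                                           status = "assigned", support = unname(frac),
                                           stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1]] <- data.frame(source_id = cid, linkage_group = NA_character_,
                                           status = "ambiguous", support = unname(frac),
                                           stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out) %||%
    data.frame(source_id = character(0), linkage_group = character(0),
               status = character(0), support = numeric(0))
}
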