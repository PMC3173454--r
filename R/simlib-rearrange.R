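#' Describe a structural rearrangement event
#'
#' Events are interpreted simultaneously against the original genome:
#' source intervals must be pairwise disjoint and destination positions must
#' fall outside every source interval.
#'
#' @param kind one of "inversion", "translocation", "duplication".
#' @param src_start,src_end source interval, 0-based half-open bp.
#' @param dest_pos destination position (bp, original coordinates) for
#'   translocation/duplication; ignored for inversion.
#' @return A `rearrangement_event` object.
#' @export
rearrangement_event <- function(kind = c("inversion", "translocation", "duplication"),
                                src_start, src_end, dest_pos = NA) {
  kind <- match.arg(kind)
  if (src_start < 0 || src_end <= src_start) stopf("invalid source interval")
  if (kind != "inversion" && (is.na(dest_pos) || dest_pos < 0))
    stopf("%s requires a destination position", kind)
  structure(list(kind = kind, src_start = as.numeric(src_start),
                 src_end = as.numeric(src_end), dest_pos = as.numeric(dest_pos)),
            class = "rearrangement_event")
}

# Partition [0, len) at the given breakpoints; returns data.frame(g_start, g_end)
partition_at <- function(len, breaks) {
  b <- sort(unique(c(0, breaks[breaks > 0 & breaks < len], len)))
  data.frame(g_start = b[-length(b)], g_end = b[-1])
}

#' Build a rearranged reference genome
#'
#' Applies inversion/translocation/duplication events to a simulated genome
#' and returns the rearranged sequence together with a replayable segment map
#' (the event log) from which true synteny blocks can be derived.
#'
#' @param genome a [simulate_genome()] result.
#' @param events list of [rearrangement_event()] objects (may be empty).
#' @param name reference sequence name.
#' @return A `rearranged_reference`: list with `sequence`, `length`, `name`,
#'   `events`, and `segments` — a data frame (`g_start`, `g_end`, `strand`,
#'   `ref_start`, `ref_end`) mapping original-genome intervals to reference
#'   intervals in reference order.
#' @export
simulate_rearranged_reference <- function(genome, events = list(), name = "ref1") {
  if (inherits(events, "rearrangement_event")) events <- list(events)
  if (length(events)) {
    src <- do.call(rbind, lapply(events, function(e) c(e$src_start, e$src_end)))
    o <- order(src[, 1])
    if (any(src[o, 1][-1] < src[o, 2][-nrow(src)]))
      stopf("rearrangement source intervals overlap")
    if (any(src[, 2] > genome$length)) stopf("event interval outside genome bounds")
    for (e in events) {
      if (e$kind != "inversion") {
        if (e$dest_pos > genome$length) stopf("destination outside genome bounds")
        inside <- any(e$dest_pos > src[, 1] & e$dest_pos < src[, 2])
        if (inside) stopf("destination position falls inside a source interval")
      }
    }
  }
  breaks <- unlist(lapply(events, function(e)
    c(e$src_start, e$src_end, if (!is.na(e$dest_pos)) e$dest_pos)))
  base <- partition_at(genome$length, breaks %||% numeric(0))
  base$strand <- "+"
  base$slot <- "base"

  seg_key <- function(s, e) paste(s, e, sep = ":")
  moved <- character(0)     # base segments that leave their original place
  inserts <- list()         # dest_pos -> list of segment dfs to insert
  for (e in events) {
    sel <- base$g_start >= e$src_start & base$g_end <= e$src_end
    seg <- base[sel, , drop = FALSE]
    if (e$kind == "inversion") {
      seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
      seg$strand <- "-"
      key <- as.character(e$src_start)
      moved <- c(moved, seg_key(base$g_start[sel], base$g_end[sel]))
      inserts[[key]] <- rbind(inserts[[key]], seg)
    } else if (e$kind == "translocation") {
      moved <- c(moved, seg_key(base$g_start[sel], base$g_end[sel]))
      key <- as.character(e$dest_pos)
      inserts[[key]] <- rbind(inserts[[key]], seg)
    } else { # duplication: original stays, a copy lands at dest
      key <- as.character(e$dest_pos)
      inserts[[key]] <- rbind(inserts[[key]], seg)
    }
  }

  out <- list()
  emit_inserts_at <- function(pos) {
    key <- as.character(pos)
    if (!is.null(inserts[[key]])) {
      out[[length(out) + 1]] <<- inserts[[key]]
      inserts[[key]] <<- NULL
    }
  }
  for (k in seq_len(nrow(base))) {
    emit_inserts_at(base$g_start[k])
    if (!(seg_key(base$g_start[k], base$g_end[k]) %in% moved))
      out[[length(out) + 1]] <- base[k, , drop = FALSE]
  }
  emit_inserts_at(genome$length)
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  widths <- segs$g_end - segs$g_start
  segs$ref_start <- cumsum(c(0, widths[-length(widths)]))
  segs$ref_end <- segs$ref_start + widths
  segs$slot <- NULL

  dna <- Biostrings::DNAString(genome$sequence)
  pieces <- vapply(seq_len(nrow(segs)), function(k) {
    sub <- Biostrings::subseq(dna, start = segs$g_start[k] + 1, end = segs$g_end[k])
    if (segs$strand[k] == "-") sub <- Biostrings::reverseComplement(sub)
    as.character(sub)
  }, character(1))
  structure(list(sequence = paste(pieces, collapse = ""),
                 length = sum(widths), name = name,
                 genome_name = genome$name, events = events, segments = segs),
            class = "rearranged_reference")
}

#' Map original-genome positions onto a rearranged reference
#'
#' @param ref a [simulate_rearranged_reference()] result.
#' @param pos numeric vector of 0-based positions on the original genome.
#' @return Data frame with one row per (position, matching segment):
#'   `pos`, `ref_pos`, `strand`, `segment`. Positions inside duplicated
#'   intervals yield several rows.
#' @export
map_genome_to_ref <- function(ref, pos) {
  segs <- ref$segments
  out <- lapply(pos, function(x) {
    k <- which(segs$g_start <= x & x < segs$g_end)
    if (length(k) == 0) return(NULL)
    data.frame(pos = x,
               ref_pos = ifelse(segs$strand[k] == "+",
                                segs$ref_start[k] + (x - segs$g_start[k]),
                                segs$ref_start[k] + (segs$g_end[k] - 1 - x)),
               strand = segs$strand[k], segment = k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out) %||% data.frame(pos = numeric(0), ref_pos = numeric(0),
                                      strand = character(0), segment = integer(0))
}

#' True synteny blocks implied by the event log
#'
#' Consecutive reference segments that are also adjacent and equally oriented
#' on the source genome (within `max_gap_bp` on both sides) are merged into a
#' single collinear block, matching what anchor chaining can recover.
#'
#' @param ref a [simulate_rearranged_reference()] result.
#' @param max_gap_bp merge window in bp.
#' @return Data frame: `g_start`, `g_end`, `ref_start`, `ref_end`, `strand`.
#' @export
true_synteny_blocks <- function(ref, max_gap_bp = 5e5) {
  segs <- ref$segments
  if (nrow(segs) == 0) return(segs)
  blocks <- segs[1, c("g_start", "g_end", "ref_start", "ref_end", "strand")]
  for (k in seq_len(nrow(segs))[-1]) {
    cur <- blocks[nrow(blocks), ]
    s <- segs[k, ]
    joinable <- s$strand == cur$strand &&
      ((s$strand == "+" && abs(s$g_start - cur$g_end) <= max_gap_bp) ||
       (s$strand == "-" && abs(cur$g_start - s$g_end) <= max_gap_bp)) &&
      s$ref_start - cur$ref_end <= max_gap_bp
    if (joinable) {
      blocks$g_start[nrow(blocks)] <- min(cur$g_start, s$g_start)
      blocks$g_end[nrow(blocks)] <- max(cur$g_end, s$g_end)
      blocks$ref_end[nrow(blocks)] <- s$ref_end
    } else {
      blocks <- rbind(blocks, s[, c("g_start", "g_end", "ref_start", "ref_end", "strand")])
    }
  }
  rownames(blocks) <- NULL
  blocks
}

#' Simulate BAC-end sequence anchors against a reference
#'
#' Takes a read of `read_len` bp from each end of each clone and places it on
#' the rearranged reference via the event log. Reads spanning a rearrangement
#' breakpoint are dropped (unalignable ends). Percent identity is drawn
#' uniformly from [74, 100].
#'
#' @param clones clone table (rows of [simulate_bac_library()] output).
#' @param ref a [simulate_rearranged_reference()] result.
#' @param read_len read length in bp; must not exceed any insert size.
#' @param seed integer RNG seed.
#' @param source_id optional vector (parallel to `clones`) naming the source
#'   unit of each clone (e.g. its contig); defaults to the clone's chromosome.
#' @return Data frame of anchors: `anchor_id`, `clone_id`, `end` (L/R),
#'   `source_id`, `source_pos` (bp on source genome), `ref_chrom`,
#'   `ref_start`, `ref_end`, `strand`, `pct_identity`.
#' @export
simulate_bes_anchors <- function(clones, ref, read_len = 500, seed = 1L,
                                 source_id = NULL) {
  if (any(read_len > clones$insert_size))
    stopf("read_len %d exceeds the smallest insert (%d bp)",
          read_len, min(clones$insert_size))
  source_id <- source_id %||% clones$chrom
  segs <- ref$segments
  place <- function(a, b) { # read interval [a, b) -> segment wholly containing it
    k <- which(segs$g_start <= a & b <= segs$g_end)
    if (length(k) == 0) return(NULL)
    data.frame(segment = k,
               ref_start = ifelse(segs$strand[k] == "+",
                                  segs$ref_start[k] + (a - segs$g_start[k]),
                                  segs$ref_start[k] + (segs$g_end[k] - b)),
               strand = segs$strand[k], stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(clones))) {
    for (side in c("L", "R")) {
      a <- if (side == "L") clones$true_start[i] else clones$true_end[i] - read_len
      b <- a + read_len
      hit <- place(a, b)
      if (is.null(hit)) next
      rows[[length(rows) + 1]] <- data.frame(
        anchor_id = paste0(clones$clone_id[i], "_", side),
        clone_id = clones$clone_id[i], end = side,
        source_id = source_id[i], source_pos = a,
        ref_chrom = ref$name, ref_start = hit$ref_start,
        ref_end = hit$ref_start + read_len, strand = hit$strand,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no end read could be placed on the reference")
  out$pct_identity <- with_seed(seed, runif(nrow(out), 74, 100))
  rownames(out) <- NULL
  out
}
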