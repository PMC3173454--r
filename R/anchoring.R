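#' Design a three-dimensional overgo pool set
#'
#' Probes are assigned row-major to the coordinates of a `dx x dy x dz` cube;
#' the pools are the axis slices, so each probe sits in exactly three pools
#' (one X, one Y, one Z) and a 5x5x5 cube of 125 probes needs only 15
#' hybridizations.
#'
#' @param probe_ids character vector, at most `prod(dims)` probes.
#' @param dims integer vector of three pool dimensions.
#' @return A `pool_design`: list with `dims`, `coords` (data frame
#'   `probe_id`, `x`, `y`, `z`, 1-based) and `pools` (named list pool id ->
#'   probe ids; ids are `X1..`, `Y1..`, `Z1..`).
#' @export
design_3d_pools <- function(probe_ids, dims = c(5, 5, 5)) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) stopf("dims must be three positive integers")
  cap <- prod(dims)
  if (length(probe_ids) > cap)
    stopf("%d probes exceed the %dx%dx%d capacity of %d",
          length(probe_ids), dims[1], dims[2], dims[3], cap)
  if (anyDuplicated(probe_ids)) stopf("duplicate probe ids")
  k <- seq_along(probe_ids) - 1L
  coords <- data.frame(probe_id = probe_ids,
                       x = k %% dims[1] + 1L,
                       y = (k %/% dims[1]) %% dims[2] + 1L,
                       z = k %/% (dims[1] * dims[2]) + 1L,
                       stringsAsFactors = FALSE)
  pools <- c(
    setNames(lapply(seq_len(dims[1]), function(i) coords$probe_id[coords$x == i]),
             sprintf("X%d", seq_len(dims[1]))),
    setNames(lapply(seq_len(dims[2]), function(i) coords$probe_id[coords$y == i]),
             sprintf("Y%d", seq_len(dims[2]))),
    setNames(lapply(seq_len(dims[3]), function(i) coords$probe_id[coords$z == i]),
             sprintf("Z%d", seq_len(dims[3])))
  )
  structure(list(dims = dims, coords = coords, pools = pools), class = "pool_design")
}

#' Deconvolve a pooled-hybridization hit matrix
#'
#' For each clone, let A/B/C be its positive pools on the X/Y/Z axes. The
#' clone is `negative` when all three are empty, `unique` when each axis has
#' exactly one positive pool and the implied coordinate holds a designed
#' probe, `inconsistent` when some axis is empty while another is not (a
#' hybridization artefact), and `ambiguous` otherwise, with candidate set
#' `(A x B x C)` intersected with the designed probes. Ambiguous clones are
#' reported, never auto-resolved.
#'
#' @param design a [design_3d_pools()] result.
#' @param hits logical matrix pools x clones (dimnames required; pool names
#'   must match the design).
#' @return A `deconvolution_result`: list with `clones` (data frame
#'   `clone_id`, `status`, `n_candidates`), `candidates` (list clone ->
#'   candidate probes), and `probe_hits` (list probe -> clones with a unique
#'   call).
#' @export
deconvolve <- function(design, hits) {
  if (is.null(rownames(hits)) || is.null(colnames(hits)))
    stopf("hit matrix must carry pool and clone dimnames")
  unknown <- setdiff(rownames(hits), names(design$pools))
  if (length(unknown)) stopf("unknown pool id(s): %s", paste(unknown, collapse = ", "))
  missing <- setdiff(names(design$pools), rownames(hits))
  if (length(missing)) stopf("hit matrix lacks pool(s): %s", paste(missing, collapse = ", "))
  co <- design$coords
  key <- paste(co$x, co$y, co$z)
  axis_of <- substr(rownames(hits), 1, 1)
  idx_of <- as.integer(substring(rownames(hits), 2))
  clones <- colnames(hits)
  status <- character(length(clones))
  cand <- vector("list", length(clones))
  names(cand) <- clones
  for (ci in seq_along(clones)) {
    pos <- hits[, ci]
    A <- idx_of[pos & axis_of == "X"]
    B <- idx_of[pos & axis_of == "Y"]
    C <- idx_of[pos & axis_of == "Z"]
    na <- length(A); nb <- length(B); nc <- length(C)
    if (na + nb + nc == 0) {
      status[ci] <- "negative"; cand[[ci]] <- character(0)
    } else if (na == 0 || nb == 0 || nc == 0) {
      status[ci] <- "inconsistent"; cand[[ci]] <- character(0)
    } else {
      grid <- expand.grid(x = A, y = B, z = C)
      probes <- co$probe_id[match(paste(grid$x, grid$y, grid$z), key)]
      probes <- sort(probes[!is.na(probes)])
      cand[[ci]] <- probes
      status[ci] <-
        if (na == 1 && nb == 1 && nc == 1 && length(probes) == 1) "unique"
        else if (length(probes) == 0) "inconsistent"
        else "ambiguous"
    }
  }
  uniq <- status == "unique"
  probe_hits <- split(clones[uniq], unlist(cand[uniq], use.names = FALSE) %||% character(0))
  structure(list(
    clones = data.frame(clone_id = clones, status = status,
                        n_candidates = lengths(cand), stringsAsFactors = FALSE),
    candidates = cand,
    probe_hits = lapply(probe_hits, sort)
  ), class = "deconvolution_result")
}

#' Screen out repetitive probes
#'
#' Probes hitting more than `max_hits` locations are masked as repetitive and
#' excluded from anchoring.
#'
#' @param hit_counts named non-negative integer vector, probe -> hit count.
#' @param max_hits inclusive retention bound.
#' @return List: `kept` (probe names), `masked` (data frame `probe_id`,
#'   `hits`, `reason`).
#' @export
screen_probes <- function(hit_counts, max_hits = 8L) {
  if (any(hit_counts < 0)) stopf("hit counts must be >= 0")
  bad <- hit_counts > max_hits
  list(kept = names(hit_counts)[!bad],
       masked = data.frame(probe_id = names(hit_counts)[bad],
                           hits = unname(hit_counts[bad]),
                           reason = rep("repetitive", sum(bad)),
                           stringsAsFactors = FALSE))
}

#' Anchor contigs to linkage groups through marker hybridizations
#'
#' Each marker's CB position inside a contig is the median midpoint of the
#' spans of its hit clones there. A contig is anchored when it carries at
#' least one marker with a linkage-group assignment; contigs carrying
#' markers from more than one linkage group are flagged as conflicts.
#' Markers without a linkage group (e.g. COSII) are placed and inherit the
#' linkage group of their contig, but never anchor one.
#'
#' @param map a `physical_map`.
#' @param probe_hits named list marker_id -> clone ids (e.g. the
#'   `probe_hits` of [deconvolve()], or a simulated truth map).
#' @param markers marker table: `marker_id`, `class`, `linkage_group`
#'   (NA allowed), `cm` (NA allowed).
#' @return List: `anchored` (data frame `contig_id`, `linkage_group`,
#'   `mean_cm`, `n_markers`, `conflict`), `placements` (data frame
#'   `marker_id`, `contig_id`, `cb`, `linkage_group`, `cm`, `class`,
#'   `inferred_lg`), `unanchored` (contig ids), `report` (list:
#'   `multi_contig_markers`, `unplaced_markers`,
#'   `single_location_rate`).
#' @export
anchor_contigs <- function(map, probe_hits, markers) {
  placements <- list()
  multi <- character(0); unplaced <- character(0)
  for (mk in markers$marker_id) {
    hit_clones <- probe_hits[[mk]] %||% character(0)
    found <- 0L
    for (cn in names(map$contigs)) {
      mem <- map$contigs[[cn]]
      sel <- mem$clone_id %in% hit_clones
      if (!any(sel)) next
      found <- found + 1L
      mid <- (mem$left_cb[sel] + mem$right_cb[sel]) / 2
      row <- markers[markers$marker_id == mk, , drop = FALSE]
      placements[[length(placements) + 1]] <- data.frame(
        marker_id = mk, contig_id = cn, cb = median(mid),
        linkage_group = row$linkage_group, cm = row$cm, class = row$class,
        stringsAsFactors = FALSE)
    }
    if (found == 0) unplaced <- c(unplaced, mk)
    if (found > 1) multi <- c(multi, mk)
  }
  placements <- do.call(rbind, placements) %||%
    data.frame(marker_id = character(0), contig_id = character(0), cb = numeric(0),
               linkage_group = character(0), cm = numeric(0), class = character(0))
  anchored <- list()
  for (cn in names(map$contigs)) {
    pl <- placements[placements$contig_id == cn, , drop = FALSE]
    lgs <- unique(pl$linkage_group[!is.na(pl$linkage_group)])
    if (length(lgs) == 0) next
    anchored[[length(anchored) + 1]] <- data.frame(
      contig_id = cn,
      linkage_group = lgs[which.max(tabulate(match(pl$linkage_group, lgs)))],
      mean_cm = mean(pl$cm[!is.na(pl$cm)]),
      n_markers = nrow(pl),
      conflict = length(lgs) > 1,
      stringsAsFactors = FALSE)
  }
  anchored <- do.call(rbind, anchored) %||%
    data.frame(contig_id = character(0), linkage_group = character(0),
               mean_cm = numeric(0), n_markers = integer(0), conflict = logical(0))
  # unmapped markers inherit their contig's linkage group
  placements$inferred_lg <- placements$linkage_group
  na_lg <- is.na(placements$inferred_lg)
  placements$inferred_lg[na_lg] <-
    anchored$linkage_group[match(placements$contig_id[na_lg], anchored$contig_id)]
  placed <- setdiff(markers$marker_id, unplaced)
  list(anchored = anchored,
       placements = placements,
       unanchored = setdiff(names(map$contigs), anchored$contig_id),
       report = list(
         multi_contig_markers = multi,
         unplaced_markers = unplaced,
         single_location_rate = if (length(placed)) 1 - length(multi) / length(placed) else NA_real_))
}

#' Write/read anchoring tables
#'
#' Tab-separated marker tables and anchoring reports; columns as documented
#' in [anchor_contigs()]. Units: CB for physical, cM for genetic positions.
#'
#' @param x data frame to write.
#' @param file path.
#' @export
write_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
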