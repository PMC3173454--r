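#' Consensus-band to base-pair conversion model
#'
#' One CB unit corresponds on average to `avg_insert_bp / avg_bands_per_clone`
#' base pairs (insert length spread over its bands). The reporting helper
#' rounds the factor to the nearest 10 bp.
#'
#' @param avg_insert_bp average BAC insert size in bp.
#' @param avg_bands_per_clone average fingerprint band count.
#' @return A `cb_bp_model`: list with `avg_insert_bp`, `avg_bands_per_clone`,
#'   `bp_per_cb`, `bp_per_cb_rounded` (nearest 10 bp).
#' @export
cb_to_bp_factor <- function(avg_insert_bp, avg_bands_per_clone) {
  if (avg_insert_bp <= 0 || avg_bands_per_clone <= 0)
    stopf("insert size and band count must both be > 0")
  f <- avg_insert_bp / avg_bands_per_clone
  structure(list(avg_insert_bp = avg_insert_bp,
                 avg_bands_per_clone = avg_bands_per_clone,
                 bp_per_cb = f,
                 bp_per_cb_rounded = round(f / 10) * 10),
            class = "cb_bp_model")
}

#' Order and orient anchored contigs along their linkage groups
#'
#' Contigs are sorted by the mean genetic position (cM) of their markers
#' (ties broken by contig id). Orientation is the sign of the Spearman
#' correlation between marker CB position and cM when a contig carries at
#' least two markers at distinct positions; otherwise it is "unknown" and the
#' contig is kept as laid out. Contigs without any cM-bearing marker are
#' excluded and reported.
#'
#' @param anchored the `anchored` data frame of [anchor_contigs()].
#' @param placements the `placements` data frame of [anchor_contigs()].
#' @return List: `ordered` (data frame `linkage_group`, `order`, `contig_id`,
#'   `mean_cm`, `orientation`), `excluded` (contig ids without genetic
#'   position).
#' @export
order_and_orient <- function(anchored, placements) {
  has_cm <- vapply(anchored$contig_id, function(cn) {
    any(!is.na(placements$cm[placements$contig_id == cn]))
  }, logical(1))
  excluded <- anchored$contig_id[!has_cm]
  keep <- anchored[has_cm, , drop = FALSE]
  out <- list()
  for (lg in sort(unique(keep$linkage_group))) {
    sub <- keep[keep$linkage_group == lg, , drop = FALSE]
    sub <- sub[order(sub$mean_cm, sub$contig_id), , drop = FALSE]
    ori <- vapply(sub$contig_id, function(cn) {
      pl <- placements[placements$contig_id == cn & !is.na(placements$cm), , drop = FALSE]
      if (nrow(pl) < 2 || length(unique(pl$cb)) < 2 || length(unique(pl$cm)) < 2)
        return("unknown")
      rho <- cor(pl$cb, pl$cm, method = "spearman")
      if (is.na(rho) || rho == 0) "unknown" else if (rho > 0) "+" else "-"
    }, character(1))
    out[[length(out) + 1]] <- data.frame(
      linkage_group = lg, order = seq_len(nrow(sub)), contig_id = sub$contig_id,
      mean_cm = sub$mean_cm, orientation = unname(ori), stringsAsFactors = FALSE)
  }
  list(ordered = do.call(rbind, out) %||%
         data.frame(linkage_group = character(0), order = integer(0),
                    contig_id = character(0), mean_cm = numeric(0),
                    orientation = character(0)),
       excluded = excluded)
}

#' Build pseudomolecules from ordered contigs
#'
#' Converts contig CB spans to bp, concatenates the contigs of each linkage
#' group in order with a fixed gap between consecutive contigs, and places
#' markers (and optional STS features) at converted CB positions — mirrored
#' within contigs oriented "-". Coordinates are 0-based half-open internally.
#'
#' @param ordered the `ordered` data frame of [order_and_orient()].
#' @param map the `physical_map` providing contig CB spans.
#' @param model a [cb_to_bp_factor()] model.
#' @param placements marker placements (for marker features); may be NULL.
#' @param sts optional data frame `contig_id`, `cb`, `name` of sequence
#'   tagged sites (e.g. selected BAC ends).
#' @param gap_bp inter-contig gap in bp.
#' @return Named list of `pseudomolecule` objects: each a list with
#'   `linkage_group`, `length_bp`, and `features` (data frame `type` in
#'   contig/gap/marker/STS, `name`, `start`, `end`).
#' @export
build_pseudomolecules <- function(ordered, map, model, placements = NULL,
                                  sts = NULL, gap_bp = 250000) {
  contig_len_cb <- vapply(map$contigs, function(m) max(m$right_cb) - min(m$left_cb),
                          numeric(1))
  out <- list()
  for (lg in unique(ordered$linkage_group)) {
    sub <- ordered[ordered$linkage_group == lg, , drop = FALSE]
    sub <- sub[order(sub$order), , drop = FALSE]
    if (nrow(sub) == 0) next
    feats <- list()
    cursor <- 0
    for (r in seq_len(nrow(sub))) {
      cn <- sub$contig_id[r]
      len_bp <- round(contig_len_cb[[cn]] * model$bp_per_cb)
      if (r > 1) {
        feats[[length(feats) + 1]] <- data.frame(
          type = "gap", name = sprintf("gap_%s_%d", lg, r - 1),
          start = cursor, end = cursor + gap_bp, stringsAsFactors = FALSE)
        cursor <- cursor + gap_bp
      }
      feats[[length(feats) + 1]] <- data.frame(
        type = "contig", name = cn, start = cursor, end = cursor + len_bp,
        stringsAsFactors = FALSE)
      place_inside <- function(cb, nm, type) {
        pos <- round(cb * model$bp_per_cb)
        pos <- pmin(pmax(pos, 0), len_bp - 1)
        if (sub$orientation[r] == "-") pos <- len_bp - 1 - pos
        data.frame(type = type, name = nm, start = cursor + pos,
                   end = cursor + pos + 1, stringsAsFactors = FALSE)
      }
      if (!is.null(placements)) {
        pl <- placements[placements$contig_id == cn, , drop = FALSE]
        if (nrow(pl))
          feats[[length(feats) + 1]] <- place_inside(pl$cb, pl$marker_id, "marker")
      }
      if (!is.null(sts)) {
        st <- sts[sts$contig_id == cn, , drop = FALSE]
        if (nrow(st))
          feats[[length(feats) + 1]] <- place_inside(st$cb, st$name, "STS")
      }
      cursor <- cursor + len_bp
    }
    feats <- do.call(rbind, feats)
    feats <- feats[order(feats$start, feats$end, feats$type), , drop = FALSE]
    rownames(feats) <- NULL
    out[[paste0("Pseudo_", lg)]] <- structure(
      list(linkage_group = lg, length_bp = cursor, features = feats),
      class = "pseudomolecule")
  }
  out
}

#' @export
print.pseudomolecule <- function(x, ...) {
  tab <- table(x$features$type)
  cat(sprintf("<pseudomolecule> %s: %s bp; %s\n", x$linkage_group,
              format(x$length_bp, big.mark = ","),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Physical-map genome size statistics
#'
#' The genome size estimate is the summed bp length of anchored plus
#' unanchored contigs; inter-contig gap padding never enters these
#' statistics unless `include_gaps = TRUE` (which adds `gap_bp` per internal
#' adjacency of each anchored linkage group).
#'
#' @param map a `physical_map`.
#' @param anchored the `anchored` data frame of [anchor_contigs()] (or any
#'   data frame with `contig_id`, `linkage_group`).
#' @param model a [cb_to_bp_factor()] model.
#' @param include_gaps add gap padding to the anchored total.
#' @param gap_bp gap size used when `include_gaps = TRUE`.
#' @return List: `anchored_mbp`, `unanchored_mbp`, `genome_mbp`,
#'   `pct_anchored` (one decimal each).
#' @export
genome_size_stats <- function(map, anchored, model, include_gaps = FALSE,
                              gap_bp = 250000) {
  len_cb <- vapply(map$contigs, function(m) max(m$right_cb) - min(m$left_cb), numeric(1))
  len_mbp <- len_cb * model$bp_per_cb / 1e6
  is_anchored <- names(map$contigs) %in% anchored$contig_id
  a <- sum(len_mbp[is_anchored])
  if (include_gaps) {
    n_per_lg <- table(anchored$linkage_group[anchored$contig_id %in% names(map$contigs)])
    a <- a + sum(pmax(0, n_per_lg - 1)) * gap_bp / 1e6
  }
  u <- sum(len_mbp[!is_anchored])
  list(anchored_mbp = round(a, 1), unanchored_mbp = round(u, 1),
       genome_mbp = round(a, 1) + round(u, 1),
       pct_anchored = round(100 * round(a, 1) / (round(a, 1) + round(u, 1)), 1))
}

#' Export pseudomolecules as a CMAP-style tab file
#'
#' Columns: `map_name`, `feature_name`, `feature_type` (contig, gap, marker,
#' STS), `feature_start`, `feature_stop`; coordinates 1-based inclusive.
#' [read_cmap()] restores the internal 0-based half-open representation
#' exactly.
#'
#' @param pms list of pseudomolecules from [build_pseudomolecules()].
#' @param file output path.
#' @export
export_cmap <- function(pms, file) {
  rows <- list()
  for (nm in names(pms)) {
    f <- pms[[nm]]$features
    check_non_overlap(f, nm)
    if (nrow(f))
      rows[[length(rows) + 1]] <- data.frame(
        map_name = nm, feature_name = f$name, feature_type = f$type,
        feature_start = f$start + 1, feature_stop = f$end,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(map_name = character(0), feature_name = character(0),
               feature_type = character(0), feature_start = numeric(0),
               feature_stop = numeric(0))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

check_non_overlap <- function(f, nm) {
  spine <- f[f$type %in% c("contig", "gap"), , drop = FALSE]
  if (nrow(spine) > 1 && any(spine$start[-1] < head(spine$end, -1)))
    stopf("overlapping features in %s", nm)
  invisible(TRUE)
}

#' Read a CMAP-style tab file
#'
#' @param file path written by [export_cmap()].
#' @return Named list of `pseudomolecule` objects (marker/STS features
#'   included; lengths recomputed from the contig/gap spine).
#' @export
read_cmap <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  out <- list()
  for (nm in unique(df$map_name)) {
    sub <- df[df$map_name == nm, , drop = FALSE]
    feats <- data.frame(type = sub$feature_type, name = sub$feature_name,
                        start = sub$feature_start - 1, end = sub$feature_stop,
                        stringsAsFactors = FALSE)
    feats <- feats[order(feats$start, feats$end, feats$type), , drop = FALSE]
    rownames(feats) <- NULL
    spine <- feats[feats$type %in% c("contig", "gap"), , drop = FALSE]
    out[[nm]] <- structure(
      list(linkage_group = sub("^Pseudo_", "", nm),
           length_bp = if (nrow(spine)) max(spine$end) else 0, features = feats),
      class = "pseudomolecule")
  }
  out
}

#' Export pseudomolecules as AGP v2
#'
#' Contigs become `W` component lines; inter-contig gaps become `N` gap lines
#' (`gap_type` "contig", `linkage` "no"). Coordinates are 1-based inclusive.
#'
#' @param pms list of pseudomolecules from [build_pseudomolecules()].
#' @param file output path.
#' @export
export_agp <- function(pms, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  for (nm in names(pms)) {
    f <- pms[[nm]]$features
    check_non_overlap(f, nm)
    spine <- f[f$type %in% c("contig", "gap"), , drop = FALSE]
    for (r in seq_len(nrow(spine))) {
      common <- sprintf("%s\t%d\t%d\t%d", nm, spine$start[r] + 1, spine$end[r], r)
      if (spine$type[r] == "contig") {
        writeLines(sprintf("%s\tW\t%s\t1\t%d\t+", common, spine$name[r],
                           spine$end[r] - spine$start[r]), con)
      } else {
        writeLines(sprintf("%s\tN\t%d\tcontig\tno\tna", common,
                           spine$end[r] - spine$start[r]), con)
      }
    }
  }
  invisible(file)
}

#' Read an AGP v2 file
#'
#' @param file path written by [export_agp()].
#' @return Named list of `pseudomolecule` objects (contig/gap spine only).
#' @export
read_agp <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    p <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(p) < 6) stopf("malformed AGP line %d", i)
    nm <- p[1]
    type <- if (p[5] == "W") "contig" else "gap"
    name <- if (type == "contig") p[6] else sprintf("gap_%s_%s", nm, p[4])
    row <- data.frame(type = type, name = name,
                      start = as.numeric(p[2]) - 1, end = as.numeric(p[3]),
                      stringsAsFactors = FALSE)
    out[[nm]] <- rbind(out[[nm]], row)
  }
  Map(function(feats, nm) {
    structure(list(linkage_group = sub("^Pseudo_", "", nm),
                   length_bp = max(feats$end), features = feats),
              class = "pseudomolecule")
  }, out, names(out))
}
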