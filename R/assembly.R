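#' FPC-style physical map assembly
#'
#' Single-linkage clustering of fingerprints: clone pairs scoring at or below
#' the Sulston cutoff are connected; connected components of two or more
#' clones become contigs (laid out in consensus-band coordinates), components
#' of one clone become singletons.
#'
#' @param fps a QC-filtered [fingerprint_set()].
#' @param params a [score_params()]; `params$cutoff` is the build cutoff.
#' @return A `physical_map`: list with `contigs` (named list of member data
#'   frames: `clone_id`, `library`, `left_cb`, `right_cb`, `q_flag`),
#'   `singletons`, `params`, `edges` (scored pairs retained at the build
#'   cutoff) and `log`.
#' @export
build_contigs <- function(fps, params = score_params()) {
  # pairs are scored and cached down to a permissive floor so that contig
  # layout and later relaxed merges see longer-range constraints than the
  # stringent build cutoff provides; clustering itself uses params$cutoff
  layout_floor <- max(params$cutoff, 1e-25)
  scoring <- score_params(params$tolerance, params$gellen, layout_floor)
  edges <- score_pairs(fps, scoring)
  map <- structure(list(contigs = list(), singletons = character(0),
                        params = params, edges = edges,
                        log = sprintf("build: %d clones, cutoff %.0e, tolerance %d",
                                      length(fps), params$cutoff, params$tolerance)),
                   class = "physical_map")
  if (length(fps) == 0) return(map)
  comp <- cluster_members(fps$clone_id,
                          edges[edges$log10S <= log10(params$cutoff), , drop = FALSE])
  contigs <- list()
  for (members in comp$groups) {
    contigs[[length(contigs) + 1]] <- layout_members(members, fps, params, edges)
  }
  map$contigs <- contigs
  map$singletons <- comp$singles
  map <- flag_q_clones(map, fps)
  renumber_contigs(map)
}

# Connected components under the given edge set, restricted to `ids`.
# Returns list(groups = list of character vectors, singles = character).
cluster_members <- function(ids, edges) {
  keep <- edges$clone_i %in% ids & edges$clone_j %in% ids
  e <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("clone_i", "clone_j")],
                                     directed = FALSE,
                                     vertices = data.frame(name = sort(ids)))
  cm <- igraph::components(g)$membership
  groups <- split(names(cm), cm)
  sizes <- lengths(groups)
  list(groups = unname(groups[sizes > 1]),
       singles = sort(unname(unlist(groups[sizes == 1], use.names = FALSE)) %||% character(0)))
}

#' Lay out a contig in consensus-band (CB) coordinates
#'
#' Offsets are propagated over the maximum-weight spanning tree of the
#' overlap graph (weight = matched band count). The offset magnitude between
#' a clone pair is the mean of `n_i - m_ij` and `n_j - m_ij` CB units; the
#' left/right sign of each placement is chosen to minimise the squared
#' disagreement between predicted and observed band sharing against clones
#' already placed. Coordinates are normalised so the leftmost clone sits at
#' CB 0; a clone's span equals its band count. Layouts are deterministic for
#' a fixed input, and — like any fingerprint-only layout — defined up to
#' reflection of the whole contig.
#'
#' @param members character vector of clone ids (must be connected at the
#'   build cutoff).
#' @param fps the [fingerprint_set()] holding the members.
#' @param params a [score_params()].
#' @param edges scored pairs (from [score_pairs()]); defaults to re-scoring.
#' @return Member data frame: `clone_id`, `library`, `left_cb`, `right_cb`,
#'   `q_flag` (FALSE; see [flag_q_clones()]).
#' @export
layout_contig <- function(members, fps, params = score_params(), edges = NULL) {
  if (is.null(edges)) edges <- score_pairs(fps[members], params)
  layout_members(members, fps, params, edges)
}

layout_members <- function(members, fps, params, edges) {
  members <- sort(members)
  nb <- band_counts(fps)[members]
  if (length(members) == 1) {
    return(data.frame(clone_id = members,
                      library = fps$library[match(members, fps$clone_id)],
                      left_cb = 0, right_cb = unname(nb), q_flag = FALSE,
                      stringsAsFactors = FALSE))
  }
  e <- edges[edges$clone_i %in% members & edges$clone_j %in% members, , drop = FALSE]
  e <- e[order(-e$m, e$clone_i, e$clone_j), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$clone_i, to = e$clone_j, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = members))
  if (igraph::components(g)$no != 1)
    stopf("contig members are not connected at the build cutoff")

  # sizing noise loses a fraction of true band matches; estimate the match
  # rate from the best-overlapping pairs so distances are not inflated
  # clamped to [0.9, 1]: deep maps always contain near-duplicate pairs that
  # expose the noise loss, while sparse fixtures without such pairs carry no
  # evidence of loss and should not have distances shrunk
  nL <- pmin(nb[e$clone_i], nb[e$clone_j])
  rate <- min(1, max(0.9, unname(stats::quantile(e$m / nL, 0.95))))

  # adjacency over the scored edge set
  und <- rbind(data.frame(b = e$clone_j, m = e$m, stringsAsFactors = FALSE),
               data.frame(b = e$clone_i, m = e$m, stringsAsFactors = FALSE))
  adj <- split(und, c(e$clone_i, e$clone_j))
  overlap_cb <- function(x1, n1, x2, n2) pmax(0, pmin(x1 + n1, x2 + n2) - pmax(x1, x2))

  # Prim-order placement: always place next the clone with the strongest
  # match to an already-placed clone, at the candidate offset (either side of
  # each placed neighbour) minimising the squared disagreement between
  # predicted (rate x CB overlap) and observed matched bands
  strength <- vapply(adj, function(df) sum(df$m), numeric(1))[members]
  root <- members[order(-strength, members)][1]
  pos <- setNames(rep(NA_real_, length(members)), members)
  pos[root] <- 0
  best_link <- setNames(rep(0, length(members)), members)
  for (q in adj[[root]]$b) best_link[q] <- max(best_link[q], adj[[root]]$m[adj[[root]]$b == q])
  repeat {
    open <- names(pos)[is.na(pos)]
    if (length(open) == 0) break
    v <- open[order(-best_link[open], open)][1]
    nbr <- adj[[v]]
    nbr <- nbr[!is.na(pos[nbr$b]), , drop = FALSE]
    nbr <- nbr[!duplicated(nbr$b), , drop = FALSE]
    d_vq <- pmax(0, (nb[[v]] + nb[nbr$b]) / 2 - nbr$m / rate)
    cand <- unique(c(pos[nbr$b] + d_vq, pos[nbr$b] - d_vq))
    err <- vapply(cand, function(x) {
      sum((rate * overlap_cb(x, nb[[v]], pos[nbr$b], nb[nbr$b]) - nbr$m)^2)
    }, numeric(1))
    best <- cand[err == min(err)]
    # ties (symmetric, noise-free cases): extend away from the placed mass
    centroid <- mean(pos, na.rm = TRUE)
    best <- best[abs(best - centroid) == max(abs(best - centroid))]
    pos[[v]] <- max(best)
    for (k in seq_len(nrow(adj[[v]])))
      best_link[adj[[v]]$b[k]] <- max(best_link[adj[[v]]$b[k]], adj[[v]]$m[k])
  }
  left <- pos - min(pos)
  data.frame(clone_id = members,
             library = fps$library[match(members, fps$clone_id)],
             left_cb = unname(left[members]),
             right_cb = unname(left[members] + nb[members]),
             q_flag = FALSE, stringsAsFactors = FALSE)
}

# Multiset difference of two sorted integer vectors (each element of b
# removes one equal element of a).
multiset_diff <- function(a, b) {
  i <- 1L; j <- 1L; keep <- logical(length(a))
  while (i <= length(a)) {
    if (j <= length(b) && a[i] == b[j]) { i <- i + 1L; j <- j + 1L }
    else if (j <= length(b) && b[j] < a[i]) j <- j + 1L
    else { keep[i] <- TRUE; i <- i + 1L }
  }
  a[keep]
}

#' Flag questionable (Q) clones
#'
#' A clone is questionable when more than half of its bands fail to match the
#' pooled band consensus of the other members of its contig at the scoring
#' tolerance — the signature of a chimeric or misassigned fingerprint.
#'
#' @param map a `physical_map`.
#' @param fps the [fingerprint_set()] the map was built from.
#' @return The map with member `q_flag` columns updated.
#' @export
flag_q_clones <- function(map, fps) {
  for (k in seq_along(map$contigs)) {
    mem <- map$contigs[[k]]
    if (nrow(mem) < 2) { map$contigs[[k]]$q_flag <- FALSE; next }
    pooled <- sort(unlist(fps$bands[mem$clone_id], use.names = FALSE))
    q <- vapply(mem$clone_id, function(cl) {
      own <- fps$bands[[cl]]
      if (length(own) == 0) return(TRUE)
      rest <- multiset_diff(pooled, own)
      m <- .band_match_one(own, rest, map$params$tolerance)
      (m / length(own)) < 0.5
    }, logical(1))
    map$contigs[[k]]$q_flag <- unname(q)
  }
  map
}

q_fractions <- function(map) {
  vapply(map$contigs, function(mem) mean(mem$q_flag), numeric(1))
}

#' Break up contigs dominated by questionable clones (DQer)
#'
#' Contigs whose fraction of Q clones exceeds `q_threshold` are re-clustered
#' at a stepwise-stricter cutoff (multiplied by `step_factor` per step, at
#' most `max_steps` steps); fragments are re-laid out, lone clones fall back
#' to singletons, and the clone count is conserved.
#'
#' @param map a `physical_map`.
#' @param fps the [fingerprint_set()] the map was built from.
#' @param q_threshold maximum tolerated Q-clone fraction.
#' @param max_steps maximum stringency steps.
#' @param step_factor cutoff multiplier per step (< 1 tightens).
#' @return The refined `physical_map`.
#' @export
dqer <- function(map, fps, q_threshold = 0.10, max_steps = 3L, step_factor = 1e-10) {
  for (step in seq_len(max_steps)) {
    qf <- q_fractions(map)
    offending <- which(qf > q_threshold & vapply(map$contigs, nrow, integer(1)) > 1)
    if (length(offending) == 0) break
    cutoff <- map$params$cutoff * step_factor^step
    keep <- map$contigs[-offending]
    for (k in offending) {
      members <- map$contigs[[k]]$clone_id
      sub <- map$edges[map$edges$log10S <= log10(cutoff), , drop = FALSE]
      comp <- cluster_members(members, sub)
      for (grp in comp$groups)
        keep[[length(keep) + 1]] <- layout_members(grp, fps, map$params, map$edges)
      map$singletons <- sort(c(map$singletons, comp$singles))
    }
    map$contigs <- keep
    map <- flag_q_clones(map, fps)
    map$log <- c(map$log, sprintf("dqer step %d: cutoff %.0e, %d contig(s) re-clustered",
                                  step, cutoff, length(offending)))
  }
  renumber_contigs(map)
}

end_clone_ids <- function(mem, window_cb) {
  span_max <- max(mem$right_cb)
  mem$clone_id[mem$left_cb < window_cb | mem$right_cb > span_max - window_cb]
}

#' Relaxed merging of contig ends and singletons
#'
#' After the stringent build, contigs are extended at a relaxed cutoff:
#' `ends_to_ends` joins two contigs when a pair of their end clones scores at
#' or below `cutoff`; `singles_to_ends` attaches singletons to contig ends;
#' `evidence` behaves like `ends_to_ends` but additionally requires both
#' contigs to carry genetic markers from the same linkage group within
#' `cm_window` centimorgans, and may relax the cutoff down to `floor`.
#' Merges are applied best-score-first; each contig group merges through a
#' union-find, so no conflicting join is ever applied.
#'
#' @param map a `physical_map`.
#' @param fps the [fingerprint_set()] the map was built from.
#' @param cutoff merge cutoff (probability), e.g. 1e-50.
#' @param mode one of "ends_to_ends", "singles_to_ends", "evidence".
#' @param end_window_cb how deep a contig end reaches, in CB units; default
#'   the median clone span across the map (roughly one clone).
#' @param markers for `evidence` mode: data frame `contig_id`,
#'   `linkage_group`, `cm` of anchored marker placements.
#' @param cm_window evidence-mode genetic window in centimorgans.
#' @param floor lowest admissible evidence-mode cutoff.
#' @return The merged `physical_map`.
#' @export
relaxed_merge <- function(map, fps, cutoff,
                          mode = c("ends_to_ends", "singles_to_ends", "evidence"),
                          end_window_cb = NULL, markers = NULL, cm_window = 10,
                          floor = 1e-25) {
  mode <- match.arg(mode)
  if (mode == "evidence" && is.null(markers))
    stopf("evidence mode requires a marker placement table")
  if (mode == "evidence" && cutoff > floor)
    stopf("evidence cutoff %.0e is more permissive than the floor %.0e",
          cutoff, floor)
  if (length(map$contigs) == 0) return(map)
  end_window_cb <- end_window_cb %||%
    median(unlist(lapply(map$contigs, function(m) m$right_cb - m$left_cb)))
  ends <- lapply(map$contigs, end_clone_ids, window_cb = end_window_cb)

  score_cross <- function(ids_a, ids_b) {
    pairs <- expand.grid(a = match(ids_a, fps$clone_id), b = match(ids_b, fps$clone_id))
    m <- .band_match_counts(fps$bands, pairs$a, pairs$b, map$params$tolerance)
    nb <- band_counts(fps)
    lg <- sulston_log10(m, nb[pairs$a], nb[pairs$b], map$params$tolerance, map$params$gellen)
    data.frame(clone_i = fps$clone_id[pairs$a], clone_j = fps$clone_id[pairs$b],
               m = m, log10S = lg, stringsAsFactors = FALSE)
  }

  new_edges <- list()
  if (mode == "singles_to_ends") {
    if (length(map$singletons) == 0) return(map)
    cand <- list()
    for (k in seq_along(map$contigs)) {
      sc <- score_cross(map$singletons, ends[[k]])
      sc <- sc[sc$log10S <= log10(cutoff), , drop = FALSE]
      if (nrow(sc)) { sc$contig <- k; cand[[length(cand) + 1]] <- sc }
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand) || nrow(cand) == 0) return(map)
    cand <- cand[order(cand$log10S, cand$clone_i, cand$clone_j), , drop = FALSE]
    attached <- character(0)
    for (r in seq_len(nrow(cand))) {
      s <- cand$clone_i[r]
      if (s %in% attached) next
      attached <- c(attached, s)
      k <- cand$contig[r]
      map$contigs[[k]] <- rbind(map$contigs[[k]],
                                data.frame(clone_id = s,
                                           library = fps$library[match(s, fps$clone_id)],
                                           left_cb = 0, right_cb = 0, q_flag = FALSE,
                                           stringsAsFactors = FALSE))
      new_edges[[length(new_edges) + 1]] <- cand[r, c("clone_i", "clone_j", "m", "log10S")]
    }
    map$singletons <- setdiff(map$singletons, attached)
    map$edges <- rbind(map$edges, do.call(rbind, new_edges))
    touched <- unique(cand$contig[cand$clone_i %in% attached])
    for (k in touched)
      map$contigs[[k]] <- layout_members(map$contigs[[k]]$clone_id, fps, map$params, map$edges)
    map$log <- c(map$log, sprintf("singles_to_ends at %.0e: %d singleton(s) attached",
                                  cutoff, length(attached)))
    map <- flag_q_clones(map, fps)
    return(renumber_contigs(map))
  }

  # ends_to_ends / evidence: candidate contig pairs
  nc <- length(map$contigs)
  if (nc < 2) return(map)
  cand <- list()
  for (a in seq_len(nc - 1)) for (b in seq((a + 1), nc)) {
    if (mode == "evidence" && !evidence_compatible(a, b, markers, cm_window)) next
    sc <- score_cross(ends[[a]], ends[[b]])
    sc <- sc[sc$log10S <= log10(cutoff), , drop = FALSE]
    if (nrow(sc) == 0) next
    best <- sc[which.min(sc$log10S), , drop = FALSE]
    best$ca <- a; best$cb <- b
    cand[[length(cand) + 1]] <- best
    new_edges[[length(new_edges) + 1]] <- sc[, c("clone_i", "clone_j", "m", "log10S")]
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) return(map)
  cand <- cand[order(cand$log10S, cand$clone_i, cand$clone_j), , drop = FALSE]
  parent <- seq_len(nc)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  merged <- 0L
  for (r in seq_len(nrow(cand))) {
    ra <- find(cand$ca[r]); rb <- find(cand$cb[r])
    if (ra != rb) { parent[rb] <- ra; merged <- merged + 1L }
  }
  map$edges <- rbind(map$edges, do.call(rbind, new_edges))
  roots <- vapply(seq_len(nc), find, integer(1))
  contigs <- list()
  for (root in unique(roots)) {
    grp <- which(roots == root)
    members <- unlist(lapply(map$contigs[grp], `[[`, "clone_id"), use.names = FALSE)
    contigs[[length(contigs) + 1]] <-
      if (length(grp) == 1) map$contigs[[grp]]
      else layout_members(members, fps, map$params, map$edges)
  }
  map$contigs <- contigs
  map$log <- c(map$log, sprintf("%s at %.0e: %d merge(s)", mode, cutoff, merged))
  map <- flag_q_clones(map, fps)
  renumber_contigs(map)
}

contig_labels <- function(k) c(k, sprintf("ctg%d", k))

evidence_compatible <- function(a, b, markers, cm_window) {
  ma <- markers[markers$contig_id %in% contig_labels(a), , drop = FALSE]
  mb <- markers[markers$contig_id %in% contig_labels(b), , drop = FALSE]
  if (nrow(ma) == 0 || nrow(mb) == 0) return(FALSE)
  for (lg in intersect(ma$linkage_group, mb$linkage_group)) {
    da <- ma$cm[ma$linkage_group == lg]
    db <- mb$cm[mb$linkage_group == lg]
    if (min(abs(outer(da, db, "-"))) <= cm_window) return(TRUE)
  }
  FALSE
}

renumber_contigs <- function(map) {
  if (length(map$contigs) == 0) { names(map$contigs) <- character(0); return(map) }
  sizes <- vapply(map$contigs, nrow, integer(1))
  first <- vapply(map$contigs, function(m) min(m$clone_id), character(1))
  o <- order(-sizes, first)
  map$contigs <- map$contigs[o]
  names(map$contigs) <- sprintf("ctg%d", seq_along(map$contigs))
  map
}

#' @export
print.physical_map <- function(x, ...) {
  sizes <- vapply(x$contigs, nrow, integer(1))
  cat(sprintf("<physical_map> %d contig(s) holding %d clone(s), %d singleton(s)\n",
              length(x$contigs), sum(sizes), length(x$singletons)))
  if (length(sizes))
    cat(sprintf("  largest contig: %d clones, %.0f CB\n", max(sizes),
                max(vapply(x$contigs, function(m) max(m$right_cb), numeric(1)))))
  invisible(x)
}

#' Map-level clone accounting
#' @param map a `physical_map`.
#' @return Integer: contig members plus singletons.
#' @export
clone_count <- function(map) {
  sum(vapply(map$contigs, nrow, integer(1))) + length(map$singletons)
}

#' Summarise contigs of a physical map
#'
#' @param map a `physical_map`.
#' @param breaks upper clone-count bin edges for the histogram (a final
#'   open-ended bin is appended), e.g. `c(5, 15, 100)` gives bins <=5, 6-15,
#'   16-100, >100.
#' @return List: `contigs` (data frame `contig_id`, `n_clones`, `length_cb`,
#'   `q_fraction`), `histogram` (named bin counts), `n_singletons`,
#'   `total_clones`.
#' @export
contig_summary <- function(map, breaks = c(5, 15, 100)) {
  n <- vapply(map$contigs, nrow, integer(1))
  df <- data.frame(
    contig_id = names(map$contigs) %||% character(0),
    n_clones = as.integer(n),
    length_cb = vapply(map$contigs, function(m) if (nrow(m)) max(m$right_cb) - min(m$left_cb) else 0, numeric(1)),
    q_fraction = vapply(map$contigs, function(m) mean(m$q_flag), numeric(1)),
    stringsAsFactors = FALSE
  )
  edges <- c(0, breaks, Inf)
  labels <- c(paste0("<=", breaks[1]),
              if (length(breaks) > 1)
                sprintf("%d-%d", head(breaks, -1) + 1, breaks[-1]),
              paste0(">", breaks[length(breaks)]))
  hist <- table(cut(df$n_clones, edges, labels = labels, right = TRUE))
  list(contigs = df, histogram = hist,
       n_singletons = length(map$singletons), total_clones = clone_count(map))
}

#' Write a minimal FPC-dialect project file
#'
#' A documented subset of the FPC text format: one `BAC : "<id>"` record per
#' clone with its contig assignment and CB span (`Map "<ctg>" Ends Left L
#' Right R`); singletons carry contig `ctg0`. Round-trips through
#' [read_fpc()].
#'
#' @param map a `physical_map`.
#' @param fps the backing [fingerprint_set()] (for library provenance).
#' @param file output path.
#' @export
write_fpc <- function(map, fps, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("// bacmapr FPC subset v1", con)
  for (cn in names(map$contigs)) {
    mem <- map$contigs[[cn]]
    for (r in seq_len(nrow(mem))) {
      writeLines(sprintf('BAC : "%s"', mem$clone_id[r]), con)
      writeLines(sprintf('Map "%s" Ends Left %.3f Right %.3f', cn,
                         mem$left_cb[r], mem$right_cb[r]), con)
    }
  }
  for (s in map$singletons) {
    writeLines(sprintf('BAC : "%s"', s), con)
    writeLines('Map "ctg0" Ends Left 0.000 Right 0.000', con)
  }
  invisible(file)
}

#' Read a minimal FPC-dialect project file
#'
#' @param file path written by [write_fpc()].
#' @return List: `placements` data frame (`clone_id`, `contig_id`, `left_cb`,
#'   `right_cb`) and `singletons`.
#' @export
read_fpc <- function(file) {
  lines <- readLines(file)
  ids <- character(0); ctg <- character(0); l <- numeric(0); r <- numeric(0)
  cur <- NA_character_
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (startsWith(line, "BAC")) {
      cur <- sub('^BAC : "([^"]+)"$', "\\1", line)
    } else if (startsWith(line, "Map")) {
      m <- regmatches(line, regexec('^Map "([^"]+)" Ends Left ([-0-9.]+) Right ([-0-9.]+)$', line))[[1]]
      if (length(m) != 4 || is.na(cur)) stopf("malformed FPC line %d: '%s'", i, line)
      ids <- c(ids, cur); ctg <- c(ctg, m[2])
      l <- c(l, as.numeric(m[3])); r <- c(r, as.numeric(m[4]))
      cur <- NA_character_
    }
  }
  sing <- ids[ctg == "ctg0"]
  keep <- ctg != "ctg0"
  list(placements = data.frame(clone_id = ids[keep], contig_id = ctg[keep],
                               left_cb = l[keep], right_cb = r[keep],
                               stringsAsFactors = FALSE),
       singletons = sing)
}
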