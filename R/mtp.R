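#' CB spacing target for dense minimum-tile-path selection
#'
#' Converts a desired physical distance between sequence anchor points into a
#' consensus-band spacing: `n = max(1, round(m * k / i))`, where `m` is the
#' median CB span per BAC, `i` the average insert size in bp and `k` the
#' desired anchor distance in bp. With the map-wide medians m = 120 CB,
#' i = 138 kb and k = 8 kb this gives n = 7 CB.
#'
#' @param m median CB units per BAC.
#' @param i average BAC insert size, bp.
#' @param k desired distance between anchor points, bp.
#' @return Integer CB spacing n >= 1.
#' @export
cb_spacing <- function(m, i, k) {
  if (m <= 0 || i <= 0 || k <= 0) stopf("m, i and k must all be > 0")
  max(1L, as.integer(round(m * k / i)))
}

#' Select a dense minimum tile path
#'
#' Walks targets 0, n, 2n, ... across each contig's CB span and, at each
#' target, picks the not-yet-selected clone whose left end is nearest the
#' target (ties to the smaller clone id). A target is skipped when an end of
#' a clone with pre-existing BAC-end sequence, or the right end of a
#' previously selected clone, or the left end of a previously selected
#' clone, lies within n/2 CB of it — no new BAC is picked where ends already
#' exist. Both ends of every selected clone are sequenced, so reactions =
#' 2 x clones.
#'
#' @param map a laid-out `physical_map`.
#' @param n CB spacing from [cb_spacing()].
#' @param existing_bes clone ids that already carry end sequences.
#' @return An `mtp_selection`: list with `selection` (data frame
#'   `contig_id`, `clone_id`, `left_cb`, `target_cb`), `n_clones`,
#'   `n_reactions`, `n` (the spacing used).
#' @export
select_mtp <- function(map, n, existing_bes = character(0)) {
  if (n < 1) stopf("spacing n must be >= 1")
  rows <- list()
  for (cn in names(map$contigs)) {
    mem <- map$contigs[[cn]]
    if (any(is.na(mem$left_cb))) stopf("contig %s has no layout", cn)
    mem <- mem[order(mem$clone_id), , drop = FALSE]
    bes_ends <- c(mem$left_cb[mem$clone_id %in% existing_bes],
                  mem$right_cb[mem$clone_id %in% existing_bes])
    sel_left <- numeric(0)
    sel_right <- numeric(0)
    selected <- character(0)
    for (target in seq(0, max(mem$right_cb), by = n)) {
      blocked <- c(bes_ends, sel_right, sel_left)
      if (length(blocked) && min(abs(blocked - target)) < n / 2) next
      avail <- !(mem$clone_id %in% selected)
      if (length(sel_left))
        avail <- avail & vapply(mem$left_cb, function(x) min(abs(sel_left - x)) >= n / 2,
                                logical(1))
      if (!any(avail)) next
      cand <- mem[avail, , drop = FALSE]
      d <- abs(cand$left_cb - target)
      pick <- cand[d == min(d), , drop = FALSE][1, ]  # rows are clone_id-sorted
      selected <- c(selected, pick$clone_id)
      sel_left <- c(sel_left, pick$left_cb)
      sel_right <- c(sel_right, pick$right_cb)
      rows[[length(rows) + 1]] <- data.frame(
        contig_id = cn, clone_id = pick$clone_id, left_cb = pick$left_cb,
        target_cb = target, stringsAsFactors = FALSE)
    }
  }
  sel <- do.call(rbind, rows) %||%
    data.frame(contig_id = character(0), clone_id = character(0),
               left_cb = numeric(0), target_cb = numeric(0))
  structure(list(selection = sel, n_clones = nrow(sel),
                 n_reactions = 2L * nrow(sel), n = as.integer(n)),
            class = "mtp_selection")
}

#' @export
print.mtp_selection <- function(x, ...) {
  cat(sprintf("<mtp_selection> %d BACs (%d sequencing reactions) at n = %d CB\n",
              x$n_clones, x$n_reactions, x$n))
  invisible(x)
}

#' Mean physical spacing between MTP sequence anchor points
#'
#' Every selected BAC contributes two end anchors, so the achieved anchor
#' density is the summed CB span of the contigs that received selections
#' divided by twice the number of selected clones; the CB-to-bp model
#' converts it to a mean distance between anchor points in bp.
#'
#' @param mtp an [select_mtp()] result.
#' @param map the `physical_map` the selection was made on.
#' @param model a [cb_to_bp_factor()] model.
#' @return Mean anchor spacing in bp (NA for an empty selection).
#' @export
mtp_mean_spacing_bp <- function(mtp, map, model) {
  if (mtp$n_clones == 0) return(NA_real_)
  used <- unique(mtp$selection$contig_id)
  span_cb <- sum(vapply(map$contigs[used],
                        function(m) max(m$right_cb) - min(m$left_cb), numeric(1)))
  span_cb * model$bp_per_cb / mtp$n_reactions
}
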