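#' Simulate a genetic-marker table
#'
#' Places markers uniformly along each simulated chromosome. Each chromosome
#' is one linkage group; genetic positions assume a constant recombination
#' density (`bp_per_cm`). A fraction of markers are emitted as COSII markers
#' without a linkage-group assignment (to be inferred later from contig
#' placement); the rest are mapped SSRs.
#'
#' @param genomes a `genome_sim` or named list of them (one per chromosome).
#' @param n_per_chrom markers per chromosome.
#' @param cosii_fraction fraction emitted as unmapped COSII markers.
#' @param bp_per_cm physical-to-genetic scaling, bp per centimorgan.
#' @param seed integer RNG seed.
#' @return Data frame: `marker_id`, `class` (SSR/COSII), `linkage_group`
#'   (NA for unmapped COSII), `cm` (NA for unmapped), `chrom`, `coord` (bp,
#'   simulation truth).
#' @export
simulate_marker_table <- function(genomes, n_per_chrom = 15, cosii_fraction = 0.2,
                                  bp_per_cm = 1e4, seed = 1L) {
  if (inherits(genomes, "genome_sim")) genomes <- setNames(list(genomes), genomes$name)
  with_seed(seed, {
    out <- lapply(seq_along(genomes), function(gi) {
      g <- genomes[[gi]]
      coord <- sort(sample.int(g$length, n_per_chrom))
      cosii <- runif(n_per_chrom) < cosii_fraction
      data.frame(
        marker_id = sprintf("%s_%s%02d", ifelse(cosii, "COS", "SSR"), g$name, seq_len(n_per_chrom)),
        class = ifelse(cosii, "COSII", "SSR"),
        linkage_group = ifelse(cosii, NA_character_, sprintf("LG%d", gi)),
        cm = ifelse(cosii, NA_real_, coord / bp_per_cm),
        chrom = g$name,
        coord = coord,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}

#' True probe-to-clone hybridization map
#'
#' A probe hits exactly the clones whose insert interval contains its genomic
#' coordinate (on the same chromosome).
#'
#' @param markers data frame with `marker_id`, `chrom`, `coord`.
#' @param clones clone table from [simulate_bac_library()].
#' @param genomes genome(s) used to validate coordinates.
#' @return Named list: marker_id -> character vector of clone ids.
#' @export
simulate_marker_truth <- function(markers, clones, genomes) {
  if (inherits(genomes, "genome_sim")) genomes <- setNames(list(genomes), genomes$name)
  lens <- vapply(genomes, `[[`, integer(1), "length")
  bad <- markers$coord < 0 | markers$coord >= lens[markers$chrom]
  if (any(bad, na.rm = TRUE) || anyNA(lens[markers$chrom]))
    stopf("marker coordinate outside genome: %s",
          paste(markers$marker_id[bad | is.na(lens[markers$chrom])], collapse = ", "))
  setNames(lapply(seq_len(nrow(markers)), function(k) {
    hit <- clones$chrom == markers$chrom[k] &
      clones$true_start <= markers$coord[k] &
      clones$true_end > markers$coord[k]
    clones$clone_id[hit]
  }), markers$marker_id)
}

#' Simulate a pooled-hybridization hit matrix
#'
#' Builds the pools-by-clones boolean readout implied by a 3-D pool design and
#' a probe-to-clone truth map, with optional per-cell false-positive and
#' false-negative rates.
#'
#' @param design a [design_3d_pools()] result.
#' @param truth named list marker_id -> clone ids (see [simulate_marker_truth()]).
#' @param clone_ids clones screened on the filters.
#' @param fp_rate,fn_rate per-cell error rates.
#' @param seed integer RNG seed.
#' @return Logical matrix, pools x clones, dimnames set.
#' @export
simulate_hit_matrix <- function(design, truth, clone_ids, fp_rate = 0, fn_rate = 0,
                                seed = 1L) {
  pools <- names(design$pools)
  hits <- matrix(FALSE, nrow = length(pools), ncol = length(clone_ids),
                 dimnames = list(pools, clone_ids))
  for (p in pools) {
    probes <- intersect(design$pools[[p]], names(truth))
    cl <- unique(unlist(truth[probes], use.names = FALSE))
    hits[p, intersect(cl, clone_ids)] <- TRUE
  }
  if (fp_rate > 0 || fn_rate > 0) {
    hits <- with_seed(seed, {
      flip <- matrix(runif(length(hits)), nrow = nrow(hits))
      (hits & flip >= fn_rate) | (!hits & flip < fp_rate)
    })
    dimnames(hits) <- list(pools, clone_ids)
  }
  hits
}
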