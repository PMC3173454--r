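#' Configuration for the end-to-end demonstration pipeline
#'
#' Defaults describe the desk-scale study: a 2 Mbp genome split over four
#' 500 kb chromosomes (one linkage group each), three complementary BAC
#' libraries at 10-fold coverage apiece (30x combined), the five-enzyme HICF
#' protocol, a stringent 1e-80 build relaxed to 1e-50 end merges, 5x5x5
#' pooled overgo anchoring, 250 kb pseudomolecule gaps, an 8 kb MTP anchor
#' target, and one planted inversion per chromosome for the synteny stage.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir where to write artifacts (`NULL` = nothing written).
#' @param n_chrom,chrom_length,gc genome shape.
#' @param libraries list of [library_spec()]s.
#' @param hicf an [hicf_spec()].
#' @param score a [score_params()].
#' @param merge_cutoff relaxed merge cutoff.
#' @param pool_dims 3-D pool dimensions.
#' @param markers_per_chrom markers simulated per chromosome.
#' @param gap_bp pseudomolecule gap size.
#' @param mtp_k desired MTP anchor spacing, bp.
#' @param synteny_max_gap_bp,synteny_min_anchors chaining parameters (the
#'   gap default is scaled to the 500 kb demo chromosomes; [chain_anchors()]
#'   itself defaults to 500 kb for full-size genomes).
#' @param bes_read_len BES read length, bp.
#' @param rearrange plant one inversion per chromosome in the reference.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            n_chrom = 4L, chrom_length = 5e5, gc = 0.38,
                            libraries = default_library_specs(),
                            hicf = default_hicf_spec(),
                            score = score_params(),
                            merge_cutoff = 1e-50,
                            pool_dims = c(5, 5, 5),
                            markers_per_chrom = 15L,
                            gap_bp = 250000,
                            mtp_k = 8000,
                            synteny_max_gap_bp = 5e4,
                            synteny_min_anchors = 3L,
                            bes_read_len = 500L,
                            rearrange = TRUE) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) stopf("seed must be one integer")
  if (cfg$n_chrom < 1) stopf("need at least one chromosome")
  if (cfg$chrom_length < 1e4) stopf("chromosomes must be at least 10 kb")
  if (!length(cfg$libraries)) stopf("at least one library spec is required")
  if (!all(vapply(cfg$libraries, inherits, logical(1), "library_spec")))
    stopf("libraries must be library_spec objects")
  if (!inherits(cfg$hicf, "hicf_spec")) stopf("hicf must be an hicf_spec")
  if (!inherits(cfg$score, "score_params")) stopf("score must be score_params")
  if (cfg$markers_per_chrom < 1)
    stopf("anchoring is enabled: markers_per_chrom must be >= 1")
  if (prod(cfg$pool_dims) < 1) stopf("pool_dims must be positive")
  invisible(cfg)
}

#' Run the full physical-mapping pipeline on simulated data
#'
#' simulate -> fingerprint -> QC -> assemble (build, DQer, end merges) ->
#' anchor (3-D pools, deconvolution, framework) -> scaffold (pseudomolecules,
#' CMAP/AGP) -> MTP selection -> synteny (BES anchors vs a rearranged
#' reference). Identical configurations produce identical results; when
#' `out_dir` is set, all artifact tables, FASTA and the provenance log are
#' written there.
#'
#' @param config a [pipeline_config()].
#' @return List with every intermediate and final object: `genomes`,
#'   `clones`, `fingerprints`, `qc`, `map`, `markers`, `truth`,
#'   `deconvolution`, `anchoring`, `model`, `ordered`, `pseudomolecules`,
#'   `stats`, `mtp`, `references`, `bes_anchors`, `blocks`, `block_stats`,
#'   `lg_predictions`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  log <- c(sprintf("bacmapr pipeline, seed %d", config$seed),
           sprintf("genome: %d x %s bp, GC %.2f", config$n_chrom,
                   format(config$chrom_length, big.mark = ","), config$gc))
  seed0 <- as.integer(config$seed)

  # --- simulate genomes, libraries, fingerprints -------------------------
  genomes <- lapply(seq_len(config$n_chrom), function(k)
    simulate_genome(config$chrom_length, config$gc, seed = seed0 * 1000L + k,
                    name = sprintf("chr%d", k)))
  names(genomes) <- vapply(genomes, `[[`, character(1), "name")
  clones <- do.call(rbind, unlist(lapply(seq_along(genomes), function(gi) {
    lapply(seq_along(config$libraries), function(li) {
      spec <- config$libraries[[li]]
      simulate_bac_library(genomes[[gi]], spec,
                           seed = seed0 * 1000L + gi * 10L + li,
                           prefix = sprintf("%s_c%d", spec$name, gi))
    })
  }), recursive = FALSE))
  fps <- hicf_fingerprints(clones, genomes, config$hicf, seed = seed0 + 77L)
  qc <- qc_filter(fps, config$hicf$min_bands, config$hicf$max_bands)
  log <- c(log, sprintf("clones: %d simulated, %d passed QC (%d removed)",
                        nrow(clones), length(qc$kept), nrow(qc$removed)))

  # --- assemble ----------------------------------------------------------
  map <- build_contigs(qc$kept, config$score)
  map <- dqer(map, qc$kept)
  map <- relaxed_merge(map, qc$kept, config$merge_cutoff, "ends_to_ends")
  map <- relaxed_merge(map, qc$kept, config$merge_cutoff, "singles_to_ends")
  log <- c(log, sprintf("map: %d contigs, %d singletons",
                        length(map$contigs), length(map$singletons)))

  # --- anchor ------------------------------------------------------------
  markers <- simulate_marker_table(genomes, config$markers_per_chrom,
                                   seed = seed0 + 101L)
  truth <- simulate_marker_truth(markers, clones, genomes)
  cap <- prod(config$pool_dims)
  cubes <- split(markers$marker_id,
                 (seq_len(nrow(markers)) - 1L) %/% cap)
  probe_hits <- list()
  decon <- list()
  for (ci in seq_along(cubes)) {
    design <- design_3d_pools(cubes[[ci]], config$pool_dims)
    hits <- simulate_hit_matrix(design, truth, qc$kept$clone_id)
    res <- deconvolve(design, hits)
    decon[[ci]] <- res
    # only unique calls anchor; ambiguous clones are reported, never resolved
    for (p in cubes[[ci]]) probe_hits[[p]] <- res$probe_hits[[p]] %||% character(0)
  }
  loci <- vapply(markers$marker_id, function(mk)
    length(unique(markers$chrom[markers$marker_id == mk])), integer(1))
  screened <- screen_probes(setNames(loci, markers$marker_id))
  probe_hits <- probe_hits[names(probe_hits) %in% screened$kept]
  anch <- anchor_contigs(map, probe_hits, markers)
  log <- c(log, sprintf("anchoring: %d contigs anchored, %d unanchored, %.0f%% single-location",
                        nrow(anch$anchored), length(anch$unanchored),
                        100 * anch$report$single_location_rate))

  # --- scaffold ----------------------------------------------------------
  kept_clones <- clones[clones$clone_id %in% qc$kept$clone_id, , drop = FALSE]
  model <- cb_to_bp_factor(mean(kept_clones$insert_size),
                           mean(band_counts(qc$kept)))
  oo <- order_and_orient(anch$anchored, anch$placements)
  pms <- build_pseudomolecules(oo$ordered, map, model, anch$placements,
                               gap_bp = config$gap_bp)
  stats <- genome_size_stats(map, anch$anchored, model)
  log <- c(log, sprintf("scaffold: %d pseudomolecules, genome %.1f Mbp (%.1f%% anchored)",
                        length(pms), stats$genome_mbp, stats$pct_anchored))

  # --- MTP ---------------------------------------------------------------
  spans <- unlist(lapply(map$contigs, function(m) m$right_cb - m$left_cb))
  n_cb <- cb_spacing(median(spans), mean(kept_clones$insert_size), config$mtp_k)
  mtp <- select_mtp(map, n_cb)
  log <- c(log, sprintf("mtp: n = %d CB, %d BACs, %d reactions",
                        n_cb, mtp$n_clones, mtp$n_reactions))

  # --- synteny -----------------------------------------------------------
  contig_of <- setNames(rep(names(map$contigs), vapply(map$contigs, nrow, integer(1))),
                        unlist(lapply(map$contigs, `[[`, "clone_id")))
  refs <- list(); bes <- list()
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    events <- if (config$rearrange)
      list(rearrangement_event("inversion", round(g$length * 0.4), round(g$length * 0.6)))
    else list()
    refs[[g$name]] <- simulate_rearranged_reference(g, events,
                                                    name = paste0("ref_", g$name))
    sel <- mtp$selection$clone_id
    cl <- kept_clones[kept_clones$chrom == g$name & kept_clones$clone_id %in% sel, , drop = FALSE]
    cl <- cl[cl$insert_size >= config$bes_read_len, , drop = FALSE]
    if (nrow(cl) == 0) next
    bes[[g$name]] <- simulate_bes_anchors(cl, refs[[g$name]], config$bes_read_len,
                                          seed = seed0 + 300L + gi,
                                          source_id = unname(contig_of[cl$clone_id]))
  }
  bes <- do.call(rbind, bes)
  rownames(bes) <- NULL
  blocks <- chain_anchors(bes, config$synteny_max_gap_bp, config$synteny_min_anchors)
  lg_of_contig <- setNames(anch$anchored$linkage_group, anch$anchored$contig_id)
  blocks$linkage_group <- unname(lg_of_contig[blocks$source_id])
  ref_sizes <- vapply(refs, `[[`, numeric(1), "length")
  names(ref_sizes) <- vapply(refs, `[[`, character(1), "name")
  bstats <- block_stats(blocks, ref_sizes)
  un_anchors <- bes[bes$source_id %in% anch$unanchored, , drop = FALSE]
  lg_pred <- predict_linkage_groups(un_anchors,
                                    blocks[!is.na(blocks$linkage_group), , drop = FALSE])
  log <- c(log, sprintf("synteny: %d blocks, coverage %.2f, double-coverage %.2f",
                        nrow(blocks), bstats$coverage, bstats$double_coverage))

  result <- list(config = config, genomes = genomes, clones = clones,
                 fingerprints = fps, qc = qc, map = map, markers = markers,
                 truth = truth, deconvolution = decon, anchoring = anch,
                 model = model, ordered = oo, pseudomolecules = pms,
                 stats = stats, mtp = mtp, references = refs,
                 bes_anchors = bes, blocks = blocks, block_stats = bstats,
                 lg_predictions = lg_pred, log = c(log, map$log))
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config$out_dir)
  result
}

write_pipeline_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  for (g in res$genomes) write_fasta(g, p(paste0(g$name, ".fasta")))
  for (r in res$references) write_fasta(r, p(paste0(r$name, ".fasta")))
  write_tsv(res$clones, p("clones.tsv"))
  write_bands(res$qc$kept, p("fingerprints.sizes"))
  write_tsv(res$qc$removed, p("qc_removed.tsv"))
  write_fpc(res$map, res$qc$kept, p("map.fpc"))
  cs <- contig_summary(res$map)
  write_tsv(cs$contigs, p("contigs.tsv"))
  write_tsv(res$markers, p("markers.tsv"))
  write_tsv(res$anchoring$anchored, p("anchored_contigs.tsv"))
  write_tsv(res$anchoring$placements, p("marker_placements.tsv"))
  export_cmap(res$pseudomolecules, p("pseudomolecules.cmap"))
  export_agp(res$pseudomolecules, p("pseudomolecules.agp"))
  write_tsv(res$mtp$selection, p("mtp_selection.tsv"))
  write_tsv(res$blocks, p("synteny_blocks.tsv"))
  write_tsv(res$lg_predictions, p("lg_predictions.tsv"))
  stats <- data.frame(
    category = c("No. BACs fingerprinted", "No. BACs in map", "Contigs", "Singletons",
                 "Contigs, Anchored", "Contigs, Unanchored",
                 "Contig Len, Anchored (Mbp)", "Contig Len, Unanchored (Mbp)",
                 "FPC Genome Size (Mbp)", "% Genome Anchored (bp)",
                 "MTP BACs", "MTP reactions"),
    value = c(length(res$fingerprints), clone_count(res$map),
              length(res$map$contigs), length(res$map$singletons),
              nrow(res$anchoring$anchored), length(res$anchoring$unanchored),
              res$stats$anchored_mbp, res$stats$unanchored_mbp,
              res$stats$genome_mbp, res$stats$pct_anchored,
              res$mtp$n_clones, res$mtp$n_reactions))
  write_tsv(stats, p("map_statistics.tsv"))
  cfg <- res$config
  cfg$libraries <- lapply(cfg$libraries, unclass)
  cfg$hicf <- unclass(cfg$hicf)
  cfg$score <- unclass(cfg$score)
  jsonlite::write_json(list(config = unclass(cfg), log = res$log),
                       p("run_log.json"), auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
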