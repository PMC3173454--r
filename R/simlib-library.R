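#' Describe a BAC library
#'
#' @param name library name (used as clone-id prefix).
#' @param enzyme partial-digestion enzyme, see [restriction_enzymes()].
#' @param insert_min,insert_max insert-size window in bp.
#' @param clone_count number of clones; `NULL` derives it from
#'   `target_coverage` and the genome length at simulation time.
#' @param target_coverage nominal fold coverage used when `clone_count` is NULL.
#' @return A `library_spec` object.
#' @export
library_spec <- function(name, enzyme, insert_min, insert_max,
                         clone_count = NULL, target_coverage = 10) {
  if (insert_min >= insert_max) stopf("insert_min must be < insert_max")
  if (!is.null(clone_count) && clone_count < 1) stopf("clone_count must be >= 1")
  enzyme_info(enzyme)  # validates
  structure(list(name = name, enzyme = enzyme,
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 clone_count = if (is.null(clone_count)) NULL else as.integer(clone_count),
                 target_coverage = target_coverage),
            class = "library_spec")
}

#' Default trio of BAC libraries
#'
#' Three complementary libraries (HindIII 90-185 kb, EcoRI 40-160 kb,
#' MboI 80-180 kb), each at 10-fold nominal coverage, mirroring a typical
#' three-library physical-mapping design.
#'
#' @return List of three [library_spec()] objects.
#' @export
default_library_specs <- function() {
  list(
    library_spec("TCCBa", "HindIII", 90e3, 185e3, target_coverage = 10),
    library_spec("TCCBb", "EcoRI",   40e3, 160e3, target_coverage = 10),
    library_spec("TCCBc", "MboI",    80e3, 180e3, target_coverage = 10)
  )
}

#' Simulate a BAC library by partial digestion
#'
#' Clone ends are drawn uniformly from the pairs of cut sites of the library
#' enzyme whose spacing falls inside the insert-size window (a kinetics-free
#' model of partial digestion). Deterministic for a fixed seed.
#'
#' @param genome a [simulate_genome()] result.
#' @param spec a [library_spec()].
#' @param seed integer RNG seed.
#' @param prefix clone-id prefix; defaults to the library name.
#' @return Data frame of clone records: `clone_id`, `library`, `chrom`,
#'   `true_start`, `true_end` (0-based half-open bp), `insert_size`, `plate`,
#'   `well`.
#' @export
simulate_bac_library <- function(genome, spec, seed = 1L, prefix = spec$name) {
  sites <- genome$site_index[[spec$enzyme]]
  if (length(sites) < 2)
    stopf("infeasible library: enzyme %s has fewer than 2 cut sites", spec$enzyme)
  # feasible partner range per start site
  jlo <- findInterval(sites + spec$insert_min - 0.5, sites) + 1L
  jhi <- findInterval(sites + spec$insert_max + 0.5, sites)
  count <- pmax(0L, jhi - jlo + 1L)
  feasible <- which(count > 0L)
  if (length(feasible) == 0)
    stopf("infeasible library: no %s site pair spaced within [%d, %d] bp",
          spec$enzyme, spec$insert_min, spec$insert_max)
  n <- spec$clone_count %||%
    as.integer(round(spec$target_coverage * genome$length /
                     mean(c(spec$insert_min, spec$insert_max))))
  with_seed(seed, {
    i <- sample(feasible, n, replace = TRUE, prob = count[feasible])
    j <- jlo[i] + floor(runif(n) * count[i])
    start <- sites[i]
    end <- sites[j]
    idx <- seq_len(n)
    data.frame(
      clone_id = sprintf("%s_%05d", prefix, idx),
      library = spec$name,
      chrom = genome$name,
      true_start = start,
      true_end = end,
      insert_size = end - start,
      plate = (idx - 1L) %/% 384L + 1L,
      well = sprintf("%s%02d", LETTERS[(idx - 1L) %% 16L + 1L],
                     ((idx - 1L) %/% 16L) %% 24L + 1L),
      stringsAsFactors = FALSE
    )
  })
}

#' Describe an HICF fingerprinting protocol
#'
#' A multi-enzyme digest sized on a capillary sequencer. Fragment sizes are
#' converted to integer size-units at `resolution_bp` per unit with Gaussian
#' sizing noise, and only fragments inside the sizing window are observed.
#' `label_enzymes` restricts detection to fragments with at least one boundary
#' cut by a labelling enzyme (fluorescent fill-in at sticky ends); by default
#' every enzyme labels, so every in-window fragment is seen.
#'
#' @param enzymes character vector of digestion enzymes.
#' @param label_enzymes subset of `enzymes` whose cuts are labelled.
#' @param size_min_bp,size_max_bp sizing window in bp.
#' @param resolution_bp bp per integer size-unit.
#' @param noise_sd Gaussian sizing noise, in size-units.
#' @param min_bands,max_bands QC band-count bounds (see [qc_filter()]).
#' @return An `hicf_spec` object.
#' @export
hicf_spec <- function(enzymes = c("HindIII", "BamHI", "XbaI", "XhoI", "HaeIII"),
                      label_enzymes = enzymes,
                      size_min_bp = 35, size_max_bp = 600,
                      resolution_bp = 0.1, noise_sd = 1,
                      min_bands = 20L, max_bands = 220L) {
  if (size_min_bp >= size_max_bp) stopf("size_min_bp must be < size_max_bp")
  if (resolution_bp <= 0) stopf("resolution_bp must be > 0")
  enzyme_info(enzymes)
  if (!all(label_enzymes %in% enzymes))
    stopf("label_enzymes must be a subset of enzymes")
  structure(list(enzymes = enzymes, label_enzymes = label_enzymes,
                 size_min_bp = size_min_bp, size_max_bp = size_max_bp,
                 resolution_bp = resolution_bp, noise_sd = noise_sd,
                 min_bands = as.integer(min_bands),
                 max_bands = as.integer(max_bands)),
            class = "hicf_spec")
}

#' Study-default HICF protocol
#'
#' Five-enzyme digest (HindIII, BamHI, XbaI, XhoI, HaeIII) in which only the
#' four sticky-cutters carry a fluorescent label: a fragment bounded on both
#' sides by blunt HaeIII cuts (or insert ends) is invisible. Sizing window
#' 35-600 bp at 0.1 bp per size-unit, sizing noise 1 size-unit (0.1 bp),
#' QC band filter 20-220.
#'
#' @return An [hicf_spec()] object.
#' @export
default_hicf_spec <- function() {
  hicf_spec(label_enzymes = c("HindIII", "BamHI", "XbaI", "XhoI"))
}

# Digest one insert; returns integer band vector (size-units, ascending).
digest_insert <- function(start, end, genome, spec) {
  cuts <- integer(0)
  labelled <- logical(0)
  for (e in spec$enzymes) {
    s <- genome$site_index[[e]]
    s <- s[s > start & s < end]
    cuts <- c(cuts, s)
    labelled <- c(labelled, rep(e %in% spec$label_enzymes, length(s)))
  }
  o <- order(cuts)
  cuts <- cuts[o]
  labelled <- labelled[o]
  bounds <- c(start, cuts, end)
  lab <- c(FALSE, labelled, FALSE)  # insert ends carry no label
  widths <- diff(bounds)
  keep <- lab[-length(lab)] | lab[-1]
  widths[keep]
}

#' Simulate the HICF fingerprint of one clone
#'
#' Fragments of the multi-enzyme digest inside the insert are detected when a
#' boundary cut is labelled, sized with Gaussian noise, converted to integer
#' size-units and filtered to the sizing window. A clone with no in-window
#' fragment yields an empty band list (removed later by QC).
#'
#' @param clone one row of a [simulate_bac_library()] data frame (or any list
#'   with `true_start`, `true_end`).
#' @param genome the [simulate_genome()] object the clone derives from.
#' @param spec an [hicf_spec()].
#' @param seed integer RNG seed.
#' @return Sorted integer vector of band sizes in size-units.
#' @export
hicf_fingerprint <- function(clone, genome, spec = default_hicf_spec(), seed = 1L) {
  if (clone$true_start < 0 || clone$true_end > genome$length)
    stopf("clone interval [%d, %d) outside genome", clone$true_start, clone$true_end)
  widths <- digest_insert(clone$true_start, clone$true_end, genome, spec)
  with_seed(seed, size_bands(widths, spec))
}

size_bands <- function(widths_bp, spec) {
  if (length(widths_bp) == 0) return(integer(0))
  u <- round(widths_bp / spec$resolution_bp + rnorm(length(widths_bp), 0, spec$noise_sd))
  lo <- round(spec$size_min_bp / spec$resolution_bp)
  hi <- round(spec$size_max_bp / spec$resolution_bp)
  sort(as.integer(u[u >= lo & u <= hi]))
}

#' Fingerprint a whole clone table
#'
#' @param clones data frame from [simulate_bac_library()] (possibly several
#'   libraries/chromosomes row-bound; `chrom` selects the genome).
#' @param genomes a single `genome_sim` or a named list keyed by chromosome.
#' @param spec an [hicf_spec()].
#' @param seed integer RNG seed.
#' @return A [fingerprint_set()].
#' @export
hicf_fingerprints <- function(clones, genomes, spec = default_hicf_spec(), seed = 1L) {
  if (inherits(genomes, "genome_sim")) genomes <- setNames(list(genomes), genomes$name)
  bands <- with_seed(seed, {
    lapply(seq_len(nrow(clones)), function(k) {
      g <- genomes[[clones$chrom[k]]]
      widths <- digest_insert(clones$true_start[k], clones$true_end[k], g, spec)
      size_bands(widths, spec)
    })
  })
  fingerprint_set(clones$clone_id, clones$library, bands)
}
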