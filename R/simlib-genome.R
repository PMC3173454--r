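#' Restriction enzymes known to the simulator
#'
#' Recognition sequences and cut offsets for the enzymes used in BAC library
#' construction (HindIII, EcoRI, MboI) and HICF fingerprinting (HindIII,
#' BamHI, XbaI, XhoI, HaeIII). The cut offset is the number of bases between
#' the start of the recognition site and the cut position on the top strand.
#'
#' @return A data frame with columns `enzyme`, `site` and `cut_offset`.
#' @export
restriction_enzymes <- function() {
  data.frame(
    enzyme     = c("HindIII", "EcoRI",  "BamHI",  "XbaI",   "XhoI",   "HaeIII", "MboI"),
    site       = c("AAGCTT",  "GAATTC", "GGATCC", "TCTAGA", "CTCGAG", "GGCC",   "GATC"),
    cut_offset = c(1L,        1L,       1L,       1L,       1L,       2L,       0L),
    stringsAsFactors = FALSE
  )
}

enzyme_info <- function(enzyme) {
  tab <- restriction_enzymes()
  idx <- match(enzyme, tab$enzyme)
  if (anyNA(idx)) stopf("unknown enzyme(s): %s", paste(enzyme[is.na(idx)], collapse = ", "))
  tab[idx, , drop = FALSE]
}

#' Find cut positions of a restriction enzyme in a DNA sequence
#'
#' @param sequence character scalar (A/C/G/T) or a [Biostrings::DNAString].
#' @param enzyme enzyme name, see [restriction_enzymes()].
#' @return Sorted integer vector of 0-based cut positions.
#' @export
find_cut_sites <- function(sequence, enzyme) {
  info <- enzyme_info(enzyme)
  subj <- if (inherits(sequence, "DNAString")) sequence else Biostrings::DNAString(sequence)
  hits <- Biostrings::matchPattern(info$site, subj)
  sort(BiocGenerics::start(hits) - 1L + info$cut_offset)
}

#' Simulate a random genome with a restriction-site index
#'
#' Generates an i.i.d. nucleotide sequence at the requested GC content and
#' indexes the cut positions of every enzyme in [restriction_enzymes()].
#' Deterministic for a fixed seed.
#'
#' @param length genome length in bp (>= 10000).
#' @param gc GC fraction, strictly between 0 and 1.
#' @param seed integer RNG seed.
#' @param name sequence name used in FASTA export.
#' @return A `genome_sim` object: list with `sequence` (character), `length`,
#'   `gc`, `seed`, `name` and `site_index` (named list of sorted 0-based cut
#'   positions per enzyme).
#' @export
simulate_genome <- function(length, gc = 0.38, seed = 1L, name = "chr1") {
  if (!is.numeric(length) || length(length) != 1 || length < 10000)
    stopf("genome length must be a single number >= 10000, got %s", format(length))
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    stopf("gc must lie strictly between 0 and 1")
  length <- as.integer(length)
  seq <- with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
  dna <- Biostrings::DNAString(seq)
  enzymes <- restriction_enzymes()$enzyme
  site_index <- lapply(setNames(enzymes, enzymes), function(e) {
    s <- find_cut_sites(dna, e)
    s[s > 0 & s < length]
  })
  structure(
    list(sequence = seq, length = length, gc = gc, seed = seed,
         name = name, site_index = site_index),
    class = "genome_sim"
  )
}

#' Wrap an explicit DNA sequence as a simulated genome
#'
#' Builds the same `genome_sim` structure as [simulate_genome()] around a
#' given sequence (useful for worked examples and digestion fixtures).
#'
#' @param sequence character scalar over A/C/G/T.
#' @param name sequence name.
#' @return A `genome_sim` object (no length restriction).
#' @export
genome_from_sequence <- function(sequence, name = "chr1") {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stopf("sequence must contain only A/C/G/T")
  len <- nchar(sequence)
  dna <- Biostrings::DNAString(sequence)
  enzymes <- restriction_enzymes()$enzyme
  site_index <- lapply(setNames(enzymes, enzymes), function(e) {
    s <- find_cut_sites(dna, e)
    s[s > 0 & s < len]
  })
  gc <- sum(strsplit(sequence, "")[[1]] %in% c("G", "C")) / len
  structure(list(sequence = sequence, length = len, gc = gc, seed = NA_integer_,
                 name = name, site_index = site_index),
            class = "genome_sim")
}

#' @export
print.genome_sim <- function(x, ...) {
  cat(sprintf("<genome_sim> %s: %s bp, GC %.2f, seed %d\n",
              x$name, format(x$length, big.mark = ","), x$gc, x$seed))
  n <- vapply(x$site_index, length, integer(1))
  cat("  cut sites:", paste(sprintf("%s=%d", names(n), n), collapse = ", "), "\n")
  invisible(x)
}

#' Write simulated sequences to FASTA
#'
#' @param x a `genome_sim`, `rearranged_reference`, or named character vector.
#' @param file output path.
#' @export
write_fasta <- function(x, file) {
  if (inherits(x, "genome_sim")) x <- setNames(x$sequence, x$name)
  if (inherits(x, "rearranged_reference")) x <- setNames(x$sequence, x$name)
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}
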