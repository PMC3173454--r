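#' A set of clone fingerprints
#'
#' The unit of FPC-style clustering: per clone, a sorted list of integer band
#' sizes (in size-units) plus library provenance.
#'
#' @param clone_id character vector of clone names (unique).
#' @param library character vector (recycled) of library names.
#' @param bands list of sorted non-negative integer vectors.
#' @return A `fingerprint_set` object.
#' @export
fingerprint_set <- function(clone_id, library, bands) {
  if (length(bands) != length(clone_id)) stopf("bands and clone_id lengths differ")
  if (anyDuplicated(clone_id)) stopf("duplicate clone ids")
  library <- rep_len(as.character(library), length(clone_id))
  bands <- lapply(bands, function(b) {
    b <- as.integer(b)
    if (is.unsorted(b)) stopf("band lists must be sorted ascending")
    if (length(b) && b[1] < 1) stopf("band sizes must be positive")
    b
  })
  names(bands) <- clone_id
  structure(list(clone_id = as.character(clone_id), library = library, bands = bands),
            class = "fingerprint_set")
}

#' @export
length.fingerprint_set <- function(x) length(x$clone_id)

#' @export
`[.fingerprint_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$clone_id)
  fingerprint_set(x$clone_id[i], x$library[i], x$bands[i])
}

#' @export
print.fingerprint_set <- function(x, ...) {
  n <- band_counts(x)
  cat(sprintf("<fingerprint_set> %d clones (%s), bands/clone: median %s [%s-%s]\n",
              length(x), paste(unique(x$library), collapse = ","),
              if (length(n)) median(n) else NA,
              if (length(n)) min(n) else NA, if (length(n)) max(n) else NA))
  invisible(x)
}

#' Number of bands per clone
#' @param fps a [fingerprint_set()].
#' @return Named integer vector.
#' @export
band_counts <- function(fps) {
  vapply(fps$bands, length, integer(1))
}

#' Count matching bands between two fingerprints
#'
#' Greedy ascending matching: walking both sorted lists in parallel, two bands
#' match when they differ by at most `tolerance` size-units and each band is
#' used at most once. On this interval structure the greedy sweep attains the
#' maximum bipartite matching, and the count is symmetric in its arguments.
#'
#' @param f1,f2 sorted integer band vectors.
#' @param tolerance non-negative integer tolerance, in size-units.
#' @return Integer match count `m <= min(length(f1), length(f2))`.
#' @export
match_bands <- function(f1, f2, tolerance = 3L) {
  if (is.unsorted(f1) || is.unsorted(f2)) stopf("band lists must be sorted ascending")
  if (tolerance < 0) stopf("tolerance must be >= 0")
  .band_match_one(as.integer(f1), as.integer(f2), as.integer(tolerance))
}

#' Scoring parameters for the Sulston overlap test
#'
#' @param tolerance band-match tolerance in size-units.
#' @param gellen number of distinct size-units a band can take ("gel length").
#'   Default 5650: sizes 35.0-600.0 bp at 0.1 bp resolution.
#' @param cutoff Sulston-score build threshold (probability).
#' @return A `score_params` object.
#' @export
score_params <- function(tolerance = 3L, gellen = 5650L, cutoff = 1e-80) {
  if (tolerance < 0) stopf("tolerance must be >= 0")
  if (gellen <= 2 * tolerance + 1) stopf("gellen must exceed 2*tolerance + 1")
  if (cutoff <= 0 || cutoff > 1) stopf("cutoff must lie in (0, 1]")
  structure(list(tolerance = as.integer(tolerance), gellen = as.integer(gellen),
                 cutoff = cutoff),
            class = "score_params")
}

# Vectorised log10 Sulston score from match counts and band counts.
# p = 1 - (1 - (2t+1)/G)^nH is the chance that one band of the lower-count
# clone matches somewhere in the higher-count clone; the score is the
# binomial probability of observing >= m matches by chance, evaluated in
# log space to survive 1e-80 magnitudes.
sulston_log10 <- function(m, n1, n2, tolerance, gellen) {
  nL <- pmin(n1, n2)
  nH <- pmax(n1, n2)
  p <- 1 - (1 - (2 * tolerance + 1) / gellen)^nH
  out <- numeric(length(m))
  live <- nL > 0 & m > 0
  out[live] <- pbinom(m[live] - 1, nL[live], p[live],
                      lower.tail = FALSE, log.p = TRUE) / log(10)
  out
}

#' Sulston overlap score of two fingerprints
#'
#' Probability that two unrelated clones share at least the observed number of
#' matching bands by chance; small values are strong overlap evidence. An
#' empty fingerprint carries no evidence and scores exactly 1.
#'
#' @param f1,f2 sorted integer band vectors.
#' @param params a [score_params()].
#' @return List: `score` (probability; 0 when below double precision),
#'   `log10` (log10 of the score), `m` (matched bands), `n1`, `n2`.
#' @export
sulston_score <- function(f1, f2, params = score_params()) {
  m <- match_bands(f1, f2, params$tolerance)
  lg <- sulston_log10(m, length(f1), length(f2), params$tolerance, params$gellen)
  list(score = 10^lg, log10 = lg, m = m, n1 = length(f1), n2 = length(f2))
}

#' Score all clone pairs of a fingerprint set
#'
#' @param fps a [fingerprint_set()].
#' @param params a [score_params()]; only pairs scoring at or below
#'   `params$cutoff` are returned.
#' @return Data frame: `clone_i`, `clone_j`, `m`, `log10S`, sorted by score.
#' @export
score_pairs <- function(fps, params = score_params()) {
  n <- length(fps)
  empty <- data.frame(clone_i = character(0), clone_j = character(0),
                      m = integer(0), log10S = numeric(0))
  if (n < 2) return(empty)
  idx <- utils::combn(n, 2)
  m <- .band_match_counts(fps$bands, idx[1, ], idx[2, ], params$tolerance)
  nb <- band_counts(fps)
  lg <- sulston_log10(m, nb[idx[1, ]], nb[idx[2, ]], params$tolerance, params$gellen)
  keep <- lg <= log10(params$cutoff)
  out <- data.frame(clone_i = fps$clone_id[idx[1, keep]],
                    clone_j = fps$clone_id[idx[2, keep]],
                    m = m[keep], log10S = lg[keep], stringsAsFactors = FALSE)
  out[order(out$log10S, out$clone_i, out$clone_j), , drop = FALSE]
}

#' Band-count quality filter
#'
#' Removes clones whose fingerprints carry too few or too many bands (partial
#' digests, empty vectors, uncut wells) before assembly.
#'
#' @param fps a [fingerprint_set()].
#' @param min_bands,max_bands inclusive band-count bounds.
#' @return List: `kept` (a filtered [fingerprint_set()]) and `removed` (data
#'   frame `clone_id`, `n_bands`, `reason` in empty/too-few/too-many).
#' @export
qc_filter <- function(fps, min_bands = 20L, max_bands = 220L) {
  n <- band_counts(fps)
  reason <- rep(NA_character_, length(n))
  reason[n == 0] <- "empty"
  reason[n > 0 & n < min_bands] <- "too-few"
  reason[n > max_bands] <- "too-many"
  drop <- !is.na(reason)
  list(kept = fps[!drop],
       removed = data.frame(clone_id = fps$clone_id[drop], n_bands = unname(n[drop]),
                            reason = reason[drop], stringsAsFactors = FALSE))
}

#' Write fingerprints as an FPC-style band file
#'
#' Dialect: per clone a header line `clone_id band_count`, then one band size
#' per line (integer size-units, ascending).
#'
#' @param fps a [fingerprint_set()].
#' @param file output path.
#' @export
write_bands <- function(fps, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(fps$clone_id)) {
    writeLines(paste(fps$clone_id[i], length(fps$bands[[i]])), con)
    if (length(fps$bands[[i]])) writeLines(format(fps$bands[[i]]), con)
  }
  invisible(file)
}

#' Read an FPC-style band file
#'
#' @param file path written by [write_bands()].
#' @param library library label to attach (single value or per-clone vector).
#' @return A [fingerprint_set()].
#' @export
read_bands <- function(file, library = "unknown") {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  ids <- character(0); bands <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (length(hdr) != 2 || is.na(suppressWarnings(as.integer(hdr[2]))))
      stopf("malformed band-file header at line %d: '%s'", i, lines[i])
    k <- as.integer(hdr[2])
    if (i + k > length(lines)) stopf("truncated band list for clone %s", hdr[1])
    vals <- suppressWarnings(as.integer(lines[seq_len(k) + i]))
    if (anyNA(vals) && k > 0) stopf("non-integer band size under clone %s", hdr[1])
    ids <- c(ids, hdr[1])
    bands[[length(bands) + 1]] <- sort(vals)
    i <- i + k + 1L
  }
  fingerprint_set(ids, library, bands)
}
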