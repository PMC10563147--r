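#' Read a genome from a FASTA file
#'
#' Reads a (possibly multi-record, wrapped or unwrapped) FASTA file into a
#' [Biostrings::DNAStringSet], normalizing lower-case letters to upper case.
#' Only the characters `A`, `C`, `G`, `T`, `N` are accepted; anything else is
#' rejected with the offending record id and position so that malformed
#' references fail loudly rather than silently dropping labels.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per FASTA record, order preserved.
#' @seealso [generate_random_genome()], [bin_genome()]
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT", ">chr2", "ttaagg"), fa)
#' g <- read_genome_fasta(fa)
#' genome_length(g)  # 14
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA file contains no records: ", path)
  chars <- toupper(as.character(raw))
  bad <- regexpr("[^ACGTN]", chars)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 substr(chars[i], bad[i], bad[i]), names(raw)[i], bad[i]))
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- names(raw)
  out
}

#' Generate a random genome of i.i.d. uniform nucleotides
#'
#' Produces a single-record genome whose letters are drawn independently and
#' uniformly from `{A, C, G, T}`. Such sequences are the ideal regime of the
#' random-codebook channel model: every k-mer has density \eqn{4^{-k}} per
#' position and bin counts are asymptotically Poisson. Identical
#' `(length_bp, seed)` pairs yield identical sequences.
#'
#' @param length_bp Genome length in base pairs (>= 1). Lengths up to 1e8 bp
#'   are supported; generation is chunked to bound peak memory.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param name Record name for the resulting sequence.
#' @return A `DNAStringSet` with one record of width `length_bp`.
#' @examples
#' g <- generate_random_genome(1e4, seed = 1)
#' Biostrings::letterFrequency(g[[1]], "ACGT", OR = 0) / 1e4
#' @export
generate_random_genome <- function(length_bp, seed, name = "random") {
  if (length(length_bp) != 1L || is.na(length_bp) || length_bp < 1)
    stop("length_bp must be a positive integer")
  length_bp <- as.numeric(length_bp)
  bases <- c("A", "C", "G", "T")
  chunk <- 1e7
  seqs <- with_seed(seed, {
    n_chunks <- ceiling(length_bp / chunk)
    vapply(seq_len(n_chunks), function(i) {
      m <- min(chunk, length_bp - (i - 1) * chunk)
      paste(bases[sample.int(4L, m, replace = TRUE)], collapse = "")
    }, character(1))
  })
  out <- Biostrings::DNAStringSet(paste(seqs, collapse = ""))
  names(out) <- name
  out
}

#' Total genome length in base pairs
#'
#' @param genomes A `DNAStringSet` (or anything coercible by
#'   [Biostrings::DNAStringSet()]).
#' @return Total length G, the sum of all record widths.
#' @export
genome_length <- function(genomes) {
  genomes <- as_genome(genomes)
  sum(as.numeric(Biostrings::width(genomes)))
}

as_genome <- function(genomes) {
  if (methods::is(genomes, "DNAStringSet")) return(genomes)
  if (methods::is(genomes, "DNAString"))
    return(Biostrings::DNAStringSet(genomes))
  if (is.character(genomes)) {
    out <- Biostrings::DNAStringSet(toupper(genomes))
    if (is.null(names(out)))
      names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  stop("cannot interpret object of class '", class(genomes)[1], "' as a genome")
}

#' Locate all occurrences of a labeling pattern in a sequence
#'
#' Finds every exact, possibly overlapping match of any member of a
#' reverse-complement-closed pattern set, and returns the union of 0-based
#' start positions. Windows containing `N` never match.
#'
#' @param seq A single sequence: `DNAString`, one-element `DNAStringSet`, or
#'   character string.
#' @param patterns A [pattern_set()] (or a character label passed through
#'   `pattern_set()`).
#' @return Sorted integer vector of 0-based start positions, duplicates
#'   removed.
#' @examples
#' find_occurrences("GCATTCGAATGC", pattern_set("GCATTC"))  # 0, 6
#' @export
find_occurrences <- function(seq, patterns) {
  patterns <- as_pattern_set(patterns)
  if (length(patterns$concrete) == 0L) stop("empty pattern set")
  if (methods::is(seq, "DNAStringSet")) {
    if (length(seq) != 1L) stop("find_occurrences expects a single sequence")
    seq <- seq[[1L]]
  } else if (!methods::is(seq, "DNAString")) {
    seq <- Biostrings::DNAString(toupper(seq))
  }
  k <- nchar(patterns$concrete[1L])
  if (k > length(seq)) stop("pattern length exceeds sequence length")
  if (length(patterns$concrete) == 1L) {
    m <- Biostrings::matchPattern(patterns$concrete, seq)
    pos <- Biostrings::start(m)
  } else {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns$concrete))
    m <- Biostrings::matchPDict(pd, seq)
    pos <- unlist(Biostrings::startIndex(m), use.names = FALSE)
    if (is.null(pos)) pos <- integer(0)
  }
  sort(unique(as.integer(pos))) - 1L
}

#' Per-bin capped occurrence counts
#'
#' Segments a sequence of length `seq_length_bp` into non-overlapping bins of
#' `bin_size` bp and counts, per bin, the occurrence positions falling in it
#' (assignment by 0-based start coordinate), capping each count at `cap`.
#' The trailing partial bin — and any position starting in it — is dropped,
#' so all bins have exactly `bin_size` bp.
#'
#' @param positions Sorted 0-based start positions (as from
#'   [find_occurrences()]).
#' @param seq_length_bp Length of the sequence the positions refer to.
#' @param bin_size Bin size B in bp.
#' @param cap Maximum reported count per bin (counts above it saturate).
#' @return Integer vector of length `floor(seq_length_bp / bin_size)` with
#'   entries in `[0, cap]`.
#' @examples
#' bin_counts(c(0L, 999L, 1000L), 2000, bin_size = 1000)  # c(2, 1)
#' @export
bin_counts <- function(positions, seq_length_bp, bin_size = 1000, cap = 2) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (cap < 1) stop("cap must be >= 1")
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = FALSE)) stop("positions must be sorted")
  if (length(positions) &&
      (positions[1L] < 0L || positions[length(positions)] >= seq_length_bp))
    stop("positions must lie in [0, seq_length_bp)")
  n_bins <- floor(seq_length_bp / bin_size)
  if (n_bins < 1L) return(integer(0))
  idx <- positions %/% as.integer(bin_size) + 1L
  idx <- idx[idx <= n_bins]  # drop trailing partial bin
  pmin(tabulate(idx, nbins = n_bins), as.integer(cap))
}

#' Bin a genome's pattern occurrences
#'
#' Scans every record of a genome for a labeling pattern and reduces it to
#' per-record vectors of capped per-bin occurrence counts — the codebook
#' symbols x of the channel model.
#'
#' @inheritParams find_occurrences
#' @inheritParams bin_counts
#' @param genomes A `DNAStringSet` (or coercible).
#' @return An object of class `binned_genome`: a list with `counts` (list of
#'   integer vectors, one per record), `bin_size`, `cap`, `record_ids`,
#'   `record_lengths_bp`, `genome_length_bp`, `n_occurrences` (raw, uncapped
#'   total), and `pattern` (the pattern label).
#' @examples
#' g <- generate_random_genome(5e4, seed = 3)
#' b <- bin_genome(g, pattern_set("CTTAAG"))
#' table(b$counts[[1]])
#' @export
bin_genome <- function(genomes, patterns, bin_size = 1000, cap = 2) {
  genomes <- as_genome(genomes)
  patterns <- as_pattern_set(patterns)
  if (length(genomes) == 0L) stop("empty genome")
  occ <- lapply(seq_along(genomes), function(i)
    find_occurrences(genomes[[i]], patterns))
  binned_from_positions(occ, Biostrings::width(genomes), names(genomes),
                        bin_size, cap, patterns$label)
}

# Shared constructor used by bin_genome() and scan_patterns() (which reuses
# already-computed positions to avoid scanning twice).
binned_from_positions <- function(occ, widths, ids, bin_size, cap, label) {
  counts <- lapply(seq_along(occ), function(i)
    bin_counts(occ[[i]], widths[i], bin_size, cap))
  structure(list(
    counts = counts,
    bin_size = as.integer(bin_size),
    cap = as.integer(cap),
    record_ids = if (is.null(ids)) paste0("seq", seq_along(occ)) else ids,
    record_lengths_bp = as.numeric(widths),
    genome_length_bp = sum(as.numeric(widths)),
    n_occurrences = sum(lengths(occ)),
    pattern = label
  ), class = "binned_genome")
}

#' @export
print.binned_genome <- function(x, ...) {
  cat(sprintf(
    "binned_genome: %d record(s), %.3g bp, pattern %s, B = %d bp, cap = %d\n",
    length(x$counts), x$genome_length_bp, x$pattern, x$bin_size, x$cap))
  cat(sprintf("  %d bins, %d occurrences (uncapped)\n",
              sum(lengths(x$counts)), x$n_occurrences))
  invisible(x)
}

#' Write pattern occurrences as BED3
#'
#' Debugging aid: writes the 0-based half-open intervals of all pattern
#' occurrences across a genome as a three-column BED file.
#'
#' @inheritParams bin_genome
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occurrences_bed <- function(genomes, patterns, path) {
  genomes <- as_genome(genomes)
  patterns <- as_pattern_set(patterns)
  k <- nchar(patterns$concrete[1L])
  rows <- lapply(seq_along(genomes), function(i) {
    pos <- find_occurrences(genomes[[i]], patterns)
    if (length(pos) == 0L) return(NULL)
    data.frame(chrom = names(genomes)[i], start = pos, end = pos + k)
  })
  bed <- do.call(rbind, rows)
  if (is.null(bed)) bed <- data.frame(chrom = character(), start = integer(),
                                      end = integer())
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
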