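#' Reverse complement of DNA sequences
#'
#' Standard Watson-Crick reversal; `N` maps to `N`. Vectorized over a
#' character vector.
#'
#' @param seq Character vector of sequences over `{A, C, G, T, N}` (case
#'   insensitive).
#' @return Character vector of reverse complements, upper case.
#' @examples
#' reverse_complement("GCTCTTC")  # "GAAGAGC"
#' reverse_complement("CTTAAG")   # palindromic: unchanged
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) seq <- as.character(seq)
  up <- toupper(seq)
  if (any(grepl("[^ACGTN]", up))) stop("illegal character in sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
}

#' Is a pattern its own reverse complement?
#'
#' A labeling pattern and its reverse complement are always labeled jointly,
#' so palindromic patterns (in the reverse-complement sense) have a singleton
#' pattern set and half the union density of non-palindromic ones.
#'
#' @param seq Character vector of patterns.
#' @return Logical vector.
#' @export
is_palindrome <- function(seq) {
  toupper(seq) == reverse_complement(seq)
}

#' Construct a reverse-complement-closed labeling pattern set
#'
#' Expands an (optionally IUPAC-coded) recognition sequence into the set of
#' concrete `{A,C,G,T}` patterns it matches, then closes the set under
#' reverse complement — in OGM both strands are labeled, so occurrences are
#' always the union of a pattern's positions and its reverse complement's.
#'
#' @param label A recognition sequence over the 15-letter IUPAC nucleotide
#'   alphabet (e.g. `"CTTAAG"` for DLE-1, `"GCTCTTC"` for Nt.BspQI,
#'   `"GCNGC"`).
#' @return An object of class `pattern_set`: list with `label` (the input)
#'   and `concrete` (character vector of same-length patterns, closed under
#'   reverse complement, sorted).
#' @examples
#' pattern_set("CTTAAG")$concrete   # palindrome: a singleton
#' pattern_set("GCTCTTC")$concrete  # "GAAGAGC" "GCTCTTC"
#' length(pattern_set("GCNGC")$concrete)
#' @export
pattern_set <- function(label) {
  if (length(label) != 1L || !is.character(label) || nchar(label) == 0L)
    stop("label must be a single non-empty string")
  label <- toupper(label)
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(label, "")[[1L]]
  if (!all(chars %in% names(map)))
    stop("illegal IUPAC character(s): ",
         paste(unique(chars[!chars %in% names(map)]), collapse = ", "))
  expansions <- Reduce(function(acc, ch) {
    letters <- strsplit(map[[ch]], "")[[1L]]
    as.vector(t(outer(acc, letters, paste0)))
  }, chars, accumulate = FALSE, init = "")
  concrete <- sort(unique(c(expansions, reverse_complement(expansions))))
  structure(list(label = label, concrete = concrete), class = "pattern_set")
}

as_pattern_set <- function(x) {
  if (inherits(x, "pattern_set")) return(x)
  if (is.character(x) && length(x) == 1L) return(pattern_set(x))
  stop("expected a pattern_set or a single pattern string")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set '%s': %d concrete pattern(s) of length %d\n",
              x$label, length(x$concrete), nchar(x$concrete[1L])))
  invisible(x)
}

#' Enumerate all DNA patterns of a given length
#'
#' Generates all `4^k` strings over `{A, C, G, T}` in lexicographic order —
#' the candidate space scanned when designing an optimal labeling pattern.
#'
#' @param k Pattern length, 1 to 12.
#' @return Character vector of `4^k` patterns.
#' @examples
#' enumerate_patterns(1)           # "A" "C" "G" "T"
#' sum(is_palindrome(enumerate_patterns(4)))  # 16 = 4^2
#' @export
enumerate_patterns <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k > 12)
    stop("k must be an integer in [1, 12]")
  bases <- c("A", "C", "G", "T")
  Reduce(function(acc, i) as.vector(t(outer(acc, bases, paste0))),
         seq_len(as.integer(k)), init = "")
}
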