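# Fixtures are generated in code and cached for the duration of the run;
# large random genomes are expensive to regenerate per test.
.fixtures <- new.env(parent = emptyenv())

fixture_genome <- function(length_bp, seed) {
  key <- sprintf("genome_%g_%d", length_bp, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_random_genome(length_bp, seed = seed)
  .fixtures[[key]]
}

# A strictly positive random channel (rows drawn uniformly, renormalized).
random_channel <- function(cap = 2) {
  px <- runif(cap + 1) + 0.05
  P <- matrix(runif((cap + 1)^2) + 0.05, cap + 1)
  channel_model(px / sum(px), P / rowSums(P), cap = cap)
}

# Independent reference scorer for the ML decoder: scores every candidate by
# direct matrix indexing and applies the same lexicographic tie-break with
# the same tolerance. Shares no code with the package's C++ kernel.
oracle_decode <- function(y, counts_list, logL, tol = 1e-9) {
  n <- length(y)
  best <- -Inf
  res <- NULL
  for (k in seq_along(counts_list)) {
    x <- counts_list[[k]]
    nb <- length(x)
    if (nb < n) next
    for (ori in c("forward", "reverse")) {
      xx <- if (ori == "forward") x else rev(x)
      for (i in 0:(nb - n)) {
        s <- sum(logL[cbind(xx[(i + 1):(i + n)] + 1L, y + 1L)])
        if (is.null(res) || s > best + tol) {
          best <- s
          res <- list(record = k, start_bin = i, orientation = ori, score = s)
        }
      }
    }
  }
  res
}

# Naive sliding-window occurrence scan (string comparison, no Biostrings).
oracle_occurrences <- function(seq_chr, concrete) {
  k <- nchar(concrete[1])
  L <- nchar(seq_chr)
  if (L < k) return(integer(0))
  windows <- substring(seq_chr, 1:(L - k + 1), k:L)
  which(windows %in% concrete) - 1L
}
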