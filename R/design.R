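#' Average genome density of a labeling pattern
#'
#' Total number of union occurrences (pattern and reverse complement, all
#' records) divided by the total genome length G, in occurrences per bp.
#' On an i.i.d. random genome a length-k pattern has expected density
#' `2 * 4^-k` (or `4^-k` if palindromic, since its pattern set is a
#' singleton).
#'
#' @inheritParams bin_genome
#' @return Density in occurrences per bp.
#' @examples
#' pattern_density("CTTAAGCTTAAG", pattern_set("CTTAAG"))  # 2/12
#' @export
pattern_density <- function(genomes, patterns) {
  genomes <- as_genome(genomes)
  patterns <- as_pattern_set(patterns)
  if (length(genomes) == 0L || genome_length(genomes) == 0) stop("empty genome")
  total <- sum(vapply(seq_along(genomes), function(i)
    length(find_occurrences(genomes[[i]], patterns)), numeric(1)))
  total / genome_length(genomes)
}

#' Rank candidate labeling patterns on a target genome set
#'
#' For each candidate pattern: expand it ([pattern_set()]), locate and bin
#' its occurrences, re-estimate the pattern-density distribution `p_x` from
#' the target genome, and compute the closed-form error probability at the
#' given fragment length. The label-detection likelihood `p_y_given_x` of
#' `model` is held fixed across patterns — the likelihood is a property of
#' the labeling chemistry and imaging system, assumed comparable across
#' recognition sequences of similar length — while `p_x` is what each
#' pattern actually changes. Optionally a subset of patterns is also
#' validated by Monte-Carlo simulation.
#'
#' Patterns with no genome occurrences carry no information (`I = 0`); they
#' are reported with `p_err = 1` and `degenerate = TRUE`, the operational
#' meaning of mapping at chance. A pattern and its reverse complement yield
#' identical rows by construction; candidates are deliberately not
#' deduplicated so a full length-k scan has exactly `4^k` rows.
#'
#' @inheritParams bin_genome
#' @param model A [channel_model()] supplying the shared likelihood (and the
#'   fallback `p_x` when `reestimate_px = FALSE`).
#' @param L_bp Fragment length in bp.
#' @param candidates Character vector of pattern labels (IUPAC allowed),
#'   e.g. [enumerate_patterns()] output.
#' @param reestimate_px Re-estimate `p_x` per pattern from the genome
#'   (default) or reuse `model$p_x` for every pattern.
#' @param simulate_subset Number of candidates (sampled without replacement)
#'   to validate by simulation, or an integer vector of row indices into
#'   `candidates`; `NULL` to skip simulation.
#' @param trials,margin_bins,seed Passed to [simulate_error_rate()]; `seed`
#'   also fixes the subset sampling.
#' @return A data frame of class `pattern_scan`, sorted by `p_err`
#'   ascending, with columns `pattern`, `density`, `p_err`, `degenerate`,
#'   and — for simulated rows — `sim_rate`, `sim_ci_lo`, `sim_ci_hi`,
#'   `sim_trials`. The scan configuration is stored in
#'   `attr(, "config")`.
#' @examples
#' g <- generate_random_genome(2e5, seed = 1)
#' scan_patterns(g, dle1_channel(), L_bp = 3e4,
#'               candidates = c("CTTAAG", "GCATTC"))
#' @export
scan_patterns <- function(genomes, model, L_bp, candidates, bin_size = 1000,
                          reestimate_px = TRUE, simulate_subset = NULL,
                          trials = 512, margin_bins = 0, seed = NULL) {
  genomes <- as_genome(genomes)
  stopifnot(inherits(model, "channel_model"))
  if (length(candidates) == 0L) stop("no candidate patterns")
  if (anyDuplicated(candidates)) stop("candidate patterns must be unique")
  widths <- as.numeric(Biostrings::width(genomes))
  G <- sum(widths)

  rows <- vector("list", length(candidates))
  binned_cache <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    ps <- pattern_set(candidates[i])
    occ <- lapply(seq_along(genomes), function(j)
      find_occurrences(genomes[[j]], ps))
    binned <- binned_from_positions(occ, widths, names(genomes), bin_size,
                                    model$cap, ps$label)
    binned_cache[[i]] <- binned
    px <- if (reestimate_px) estimate_px(binned) else model$p_x
    m_i <- channel_model(px, model$p_y_given_x, cap = model$cap)
    tr <- withCallingHandlers(
      error_probability(m_i, genomes = binned, L_bp = L_bp,
                        bin_size = bin_size),
      warning = function(w) invokeRestart("muffleWarning"))
    rows[[i]] <- data.frame(pattern = candidates[i],
                            density = sum(lengths(occ)) / G,
                            p_err = tr$epsilon,
                            degenerate = tr$degenerate)
  }
  out <- do.call(rbind, rows)

  if (!is.null(simulate_subset)) {
    idx <- if (length(simulate_subset) == 1L && is.null(names(simulate_subset)))
      with_seed(seed, sample.int(length(candidates),
                                 min(simulate_subset, length(candidates))))
    else as.integer(simulate_subset)
    out$sim_rate <- NA_real_; out$sim_ci_lo <- NA_real_
    out$sim_ci_hi <- NA_real_; out$sim_trials <- NA_integer_
    for (i in idx) {
      px <- if (reestimate_px) estimate_px(binned_cache[[i]]) else model$p_x
      m_i <- channel_model(px, model$p_y_given_x, cap = model$cap)
      est <- simulate_error_rate(binned_cache[[i]], m_i, L_bp = L_bp,
                                 trials = trials, margin_bins = margin_bins,
                                 seed = if (is.null(seed)) NULL else seed + i)
      out$sim_rate[i] <- est$rate
      out$sim_ci_lo[i] <- est$ci95["lo"]
      out$sim_ci_hi[i] <- est$ci95["hi"]
      out$sim_trials[i] <- est$trials
    }
  }

  out <- out[order(out$p_err, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- list(genome_label = paste(names(genomes),
                                                   collapse = ","),
                              G = G, L_bp = L_bp, bin_size = bin_size,
                              cap = model$cap,
                              channel = model$label,
                              reestimate_px = reestimate_px)
  class(out) <- c("pattern_scan", "data.frame")
  out
}

#' Write / read a pattern scan as CSV
#'
#' Writes one row per pattern with header `pattern,density,p_err`
#' (simulation columns appended when present) at full double precision, so
#' that reading the file back reproduces the values bit-exactly.
#'
#' @param table A [scan_patterns()] result (or compatible data frame).
#' @param path Output (input) CSV path.
#' @return `write_scan_csv()`: `path`, invisibly. `read_scan_csv()`: a data
#'   frame.
#' @export
write_scan_csv <- function(table, path) {
  if (nrow(table) == 0L) stop("empty scan table")
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
read_scan_csv <- function(path) {
  if (!file.exists(path)) stop("scan CSV not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
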