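#' Sample a fragment from a binned genome
#'
#' Draws a bin-aligned fragment of `n` bins: the record is chosen with
#' probability proportional to its number of valid start offsets
#' (`n_bins - n + 1`), the start bin uniformly among them. With
#' `orientation = "reverse"` the fragment's count vector is the reversed
#' window, emulating a molecule imaged in the opposite direction.
#'
#' Uses the current RNG state; seed control belongs to the caller (see
#' [simulate_error_rate()]).
#'
#' @param binned A [bin_genome()] result.
#' @param n Fragment length in bins.
#' @param orientation `"forward"`, `"reverse"`, or `"random"` (fair coin).
#' @return List with `record_id`, `record` (index), `start_bin` (0-based,
#'   in forward coordinates), `n`, `orientation`, and `x_vec`.
#' @export
sample_fragment <- function(binned, n, orientation = c("forward", "reverse",
                                                       "random")) {
  stopifnot(inherits(binned, "binned_genome"))
  orientation <- match.arg(orientation)
  n <- as.integer(n)
  valid <- pmax(0L, lengths(binned$counts) - n + 1L)
  if (sum(valid) == 0L)
    stop("no record has >= n bins; fragment too long for this genome")
  k <- if (length(valid) == 1L) 1L else
    sample.int(length(valid), 1L, prob = valid)
  start <- sample.int(valid[k], 1L) - 1L
  if (orientation == "random")
    orientation <- if (runif(1) < 0.5) "forward" else "reverse"
  x <- binned$counts[[k]][(start + 1L):(start + n)]
  if (orientation == "reverse") x <- rev(x)
  list(record_id = binned$record_ids[k], record = k, start_bin = start,
       n = n, orientation = orientation, x_vec = x)
}

#' Pass genome bin counts through the detection channel
#'
#' Draws each detected-label count `y_j` independently from row `x_j` of the
#' label-detection likelihood — the memoryless channel acting on one
#' fragment.
#'
#' @param x_vec Integer vector of capped genome bin counts.
#' @param model A [channel_model()].
#' @return Integer vector of simulated label counts, same length as `x_vec`.
#' @export
emit_labels <- function(x_vec, model) {
  stopifnot(inherits(model, "channel_model"))
  x_vec <- as.integer(x_vec)
  if (any(x_vec < 0L | x_vec > model$cap))
    stop("x_vec entries must lie in [0, cap]")
  y <- integer(length(x_vec))
  for (v in 0:model$cap) {
    idx <- which(x_vec == v)
    if (length(idx))
      y[idx] <- sample.int(model$cap + 1L, length(idx), replace = TRUE,
                           prob = model$p_y_given_x[v + 1L, ]) - 1L
  }
  y
}

#' Maximum-likelihood decoding of a fragment
#'
#' Exhaustively scores every valid offset of every genome record, in forward
#' and reverse orientation, by the summed log-likelihood
#' \eqn{\sum_j \log p_{y|x}(y_j \mid x_{i+j})}, and returns the maximizer.
#' Reverse orientation scores the fragment against the reversed bin-count
#' vector of each record (the pattern set is reverse-complement-closed, so
#' strand reversal permutes bin counts up to a sub-bin boundary effect).
#' Ties are broken deterministically: first record in input order, forward
#' before reverse, smallest start bin.
#'
#' @param y_vec Integer vector of observed label counts.
#' @param binned A [bin_genome()] result.
#' @param model A [channel_model()].
#' @param likelihood_floor Lower bound applied to likelihood entries before
#'   taking logs (default 0, i.e. none). Zero entries then score `-Inf`; a
#'   small floor such as `1e-12` is only needed for likelihoods estimated
#'   from sparse data with empty cells.
#' @return List with `record_id`, `record`, `start_bin` (0-based, forward
#'   coordinates of the record), `orientation`, and `score`.
#' @export
ml_decode <- function(y_vec, binned, model, likelihood_floor = 0) {
  stopifnot(inherits(binned, "binned_genome"), inherits(model, "channel_model"))
  y_vec <- as.integer(y_vec)
  if (any(y_vec < 0L | y_vec > model$cap))
    stop("y_vec entries must lie in [0, cap]")
  P <- model$p_y_given_x
  if (likelihood_floor > 0) P <- pmax(P, likelihood_floor)
  logL <- log(P)
  res <- decode_ml_cpp(binned$counts, y_vec, logL)
  if (!is.finite(res$score) && res$score == -Inf)
    stop("all candidate offsets have zero likelihood; ",
         "set likelihood_floor > 0 for channels with empty cells")
  list(record_id = binned$record_ids[res$record], record = res$record,
       start_bin = res$start_bin,
       orientation = if (res$reverse) "reverse" else "forward",
       score = res$score)
}

#' Wilson 95% score interval for a binomial proportion
#'
#' @param errors Number of errors observed.
#' @param trials Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(lo, hi)`, clipped to `[0, 1]`.
#' @examples
#' wilson_interval(256, 512)
#' @export
wilson_interval <- function(errors, trials, conf = 0.95) {
  if (trials < 1) stop("trials must be >= 1")
  if (errors < 0 || errors > trials) stop("errors must lie in [0, trials]")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- errors / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' Monte-Carlo estimate of the mapping error rate
#'
#' Repeats: sample a fragment ([sample_fragment()]), pass its bin counts
#' through the channel ([emit_labels()]), decode by exhaustive maximum
#' likelihood ([ml_decode()]). A trial succeeds when the decoded record and
#' orientation match the truth and the decoded start bin is within
#' `margin_bins` of the true one (`margin_bins = 0`: exact position). The
#' returned rate carries a Wilson 95% confidence interval.
#'
#' A single integer seed makes the whole experiment reproducible: per-trial
#' seeds are drawn once up front, so trial t is identical across runs with
#' the same `(seed, configuration)`.
#'
#' @inheritParams sample_fragment
#' @inheritParams ml_decode
#' @param L_bp Fragment length in bp; `n = floor(L_bp / bin_size)` bins.
#' @param trials Number of fragments to simulate.
#' @param margin_bins Allowed start-position error in bins.
#' @param seed Integer seed, or `NULL` to consume the current RNG stream.
#' @param orientation Orientation of the simulated fragments (decoding
#'   always considers both).
#' @return An object of class `error_rate_estimate`: list with `errors`,
#'   `trials`, `rate`, `ci95`, `L_bp`, `n`, `margin_bins`.
#' @export
simulate_error_rate <- function(binned, model, L_bp, trials = 512,
                                margin_bins = 0, seed = NULL,
                                orientation = "forward",
                                likelihood_floor = 0) {
  stopifnot(inherits(binned, "binned_genome"), inherits(model, "channel_model"))
  if (trials < 1) stop("trials must be >= 1")
  n <- floor(L_bp / binned$bin_size)
  if (n < 1) stop("fragment shorter than one bin")
  trial_seeds <- with_seed(seed, sample.int(.Machine$integer.max, trials))
  errors <- 0L
  for (t in seq_len(trials)) {
    ok <- with_seed(trial_seeds[t], {
      fr <- sample_fragment(binned, n, orientation = orientation)
      y <- emit_labels(fr$x_vec, model)
      dec <- ml_decode(y, binned, model, likelihood_floor = likelihood_floor)
      expected_start <- if (fr$orientation == "forward") fr$start_bin else
        length(binned$counts[[fr$record]]) - n - fr$start_bin
      dec$record == fr$record &&
        dec$orientation == fr$orientation &&
        abs(dec$start_bin - expected_start) <= margin_bins
    })
    if (!ok) errors <- errors + 1L
  }
  ci <- wilson_interval(errors, trials)
  structure(list(errors = errors, trials = as.integer(trials),
                 rate = errors / trials, ci95 = ci, L_bp = L_bp, n = n,
                 margin_bins = margin_bins),
            class = "error_rate_estimate")
}

#' @export
print.error_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "error_rate_estimate: %d / %d errors (rate %.4g, 95%% CI [%.4g, %.4g])\n",
    x$errors, x$trials, x$rate, x$ci95["lo"], x$ci95["hi"]))
  cat(sprintf("  L = %.3g bp (n = %d bins), margin = %d bin(s)\n",
              x$L_bp, x$n, x$margin_bins))
  invisible(x)
}
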