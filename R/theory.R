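#' Log-likelihood-ratio table of a channel
#'
#' For each `(x, y)` cell, the log ratio
#' \eqn{r(x,y) = \log \frac{p_{xy}(x,y)}{p_x(x)\,p_y(y)}} of the joint
#' distribution \eqn{p_{xy} = p_{y|x} p_x} to the product of marginals.
#' Cells with zero joint probability carry `r = 0` by the standard
#' \eqn{0 \log 0 = 0} convention; they contribute nothing to moments.
#'
#' @param model A [channel_model()].
#' @param base Logarithm base (natural log by default; the error probability
#'   is invariant to the base when used consistently).
#' @return An object of class `log_ratio_table`: list with matrices `r` and
#'   `joint`, both `(cap + 1) x (cap + 1)`.
#' @export
log_ratio_table <- function(model, base = exp(1)) {
  stopifnot(inherits(model, "channel_model"))
  joint <- model$p_x * model$p_y_given_x  # row x scaled by p_x(x)
  py <- marginal_py(model)
  prod_marg <- outer(model$p_x, py)
  r <- matrix(0, model$cap + 1L, model$cap + 1L,
              dimnames = dimnames(model$p_y_given_x))
  pos <- joint > 0
  r[pos] <- log(joint[pos] / prod_marg[pos], base = base)
  structure(list(r = r, joint = joint), class = "log_ratio_table")
}

#' Per-bin mutual information and log-likelihood-ratio variance
#'
#' The mean \eqn{I = E[r]} and variance \eqn{V = Var[r]} of the log ratio
#' under the joint distribution of `(x, y)` — the channel's per-bin
#' information content and its dispersion, the two quantities entering the
#' normal-approximation error bound.
#'
#' @inheritParams log_ratio_table
#' @return List with `I` (nats per bin, or `base`-units) and `V` (squared
#'   units per bin).
#' @examples
#' information_stats(dle1_channel())
#' @export
information_stats <- function(model, base = exp(1)) {
  tab <- log_ratio_table(model, base = base)
  I <- sum(tab$joint * tab$r)
  V <- sum(tab$joint * (tab$r - I)^2)
  list(I = I, V = V)
}

#' Codebook size of a binned genome
#'
#' The number of candidate messages a fragment can decode to: every bin
#' offset in every record, in both orientations, i.e. `M = 2G/B` up to
#' partial-bin truncation. With `exact_offsets = TRUE` (and a fragment
#' length of `n` bins) only valid start offsets are counted:
#' `M = 2 * sum_k max(0, n_bins_k - n + 1)`. The error probability depends
#' on M only logarithmically, so the two agree closely for genomes much
#' longer than the fragment.
#'
#' @param genomes A `DNAStringSet`, a [bin_genome()] result, or a plain
#'   number interpreted as total genome length G in bp.
#' @param bin_size Bin size B in bp (ignored when `genomes` is already
#'   binned).
#' @param n Fragment length in bins; required for `exact_offsets`.
#' @param exact_offsets Count exact valid offsets instead of whole bins.
#' @return Codebook size M (a positive real number).
#' @examples
#' codebook_size(1e8, bin_size = 1000)  # 2e5
#' @export
codebook_size <- function(genomes, bin_size = 1000, n = NULL,
                          exact_offsets = FALSE) {
  if (inherits(genomes, "binned_genome")) {
    nb <- lengths(genomes$counts)
  } else if (is.numeric(genomes)) {
    nb <- floor(as.numeric(genomes) / bin_size)
  } else {
    nb <- floor(as.numeric(Biostrings::width(as_genome(genomes))) / bin_size)
  }
  if (sum(nb) < 1) stop("genome shorter than one bin (G < B)")
  if (exact_offsets) {
    if (is.null(n)) stop("exact_offsets requires the fragment length n")
    M <- 2 * sum(pmax(0, nb - n + 1))
    if (M < 1) stop("no valid fragment offsets: every record shorter than n bins")
  } else {
    M <- 2 * sum(nb)
  }
  M
}

#' Closed-form mapping error probability
#'
#' The normal-approximation finite-blocklength estimate of the probability
#' that a maximum-likelihood decoder maps a fragment of `n = floor(L/B)`
#' bins to the wrong genome position:
#' \deqn{\varepsilon = \Phi\!\left(\frac{\log M - nI - \tfrac12\log n}{\sqrt{nV}}\right),}
#' where \eqn{\Phi} is the standard normal CDF, M the codebook size, and
#' I, V the channel's per-bin information statistics. All logarithms use
#' `base`; \eqn{\varepsilon} is provably invariant to that choice.
#'
#' Degenerate cases: with `V = 0` the estimate is a step function (0 when
#' `n I + log(n)/2 > log M`, else 1); with `I = 0` (uninformative channel,
#' e.g. a pattern absent from the genome) decoding is at chance and the
#' result is flagged degenerate with `epsilon = 1`.
#'
#' @inheritParams log_ratio_table
#' @param genomes Genome (see [codebook_size()]) used for M; ignored when
#'   `M` is given directly.
#' @param L_bp Fragment length in bp.
#' @param bin_size Bin size B in bp.
#' @param M Codebook size, overriding `genomes`.
#' @param exact_offsets Passed to [codebook_size()].
#' @return An object of class `theory_result`: list with `I`, `V` (in `base`
#'   units), `n`, `M`, `epsilon`, `log_epsilon` (natural-log tail, finite
#'   even when `epsilon` underflows), and `degenerate`.
#' @examples
#' error_probability(dle1_channel(), genomes = 1e8, L_bp = 1e5)
#' @export
error_probability <- function(model, genomes = NULL, L_bp, bin_size = 1000,
                              M = NULL, exact_offsets = FALSE,
                              base = exp(1)) {
  stopifnot(inherits(model, "channel_model"))
  n <- floor(L_bp / bin_size)
  if (n < 1) stop("fragment shorter than one bin (L_bp < bin_size)")
  if (is.null(M)) {
    if (is.null(genomes)) stop("supply either genomes or M")
    M <- codebook_size(genomes, bin_size, n = n, exact_offsets = exact_offsets)
  }
  st <- information_stats(model, base = base)
  I <- st$I; V <- st$V
  degenerate <- FALSE
  # channels whose information is numerically indistinguishable from zero
  # (independent channels accumulate ~1e-16 rounding in r) map at chance
  if (I <= 1e-12) {
    warning("channel carries no information (I = 0): mapping at chance, epsilon = 1")
    epsilon <- 1; log_epsilon <- 0; degenerate <- TRUE
  } else if (V == 0) {
    epsilon <- if (n * I + 0.5 * log(n, base = base) > log(M, base = base)) 0 else 1
    log_epsilon <- if (epsilon == 0) -Inf else 0
  } else {
    z <- (log(M, base = base) - n * I - 0.5 * log(n, base = base)) /
      sqrt(n * V)
    epsilon <- pnorm(z)
    log_epsilon <- pnorm(z, log.p = TRUE)
  }
  structure(list(I = st$I, V = st$V, n = n, M = M, epsilon = epsilon,
                 log_epsilon = log_epsilon, degenerate = degenerate,
                 L_bp = L_bp, bin_size = bin_size),
            class = "theory_result")
}

#' @export
print.theory_result <- function(x, ...) {
  cat(sprintf(
    "theory_result: n = %d bins (L = %.3g bp, B = %d bp), M = %.6g\n",
    x$n, x$L_bp, x$bin_size, x$M))
  cat(sprintf("  I = %.6g, V = %.6g per bin\n", x$I, x$V))
  cat(sprintf("  epsilon = %.6g%s\n", x$epsilon,
              if (x$degenerate) " (degenerate: uninformative channel)" else ""))
  invisible(x)
}

#' Error probability over a grid of fragment lengths
#'
#' @inheritParams error_probability
#' @param lengths_bp Numeric vector of fragment lengths in bp.
#' @return Data frame with columns `L_bp`, `n`, `I`, `V`, `M`, `epsilon`.
#' @examples
#' theory_curve(dle1_channel(), genomes = 1e8,
#'              lengths_bp = seq(2e4, 1e5, by = 2e4))
#' @export
theory_curve <- function(model, genomes = NULL, lengths_bp, bin_size = 1000,
                         M = NULL, exact_offsets = FALSE, base = exp(1)) {
  rows <- lapply(lengths_bp, function(L) {
    tr <- error_probability(model, genomes = genomes, L_bp = L,
                            bin_size = bin_size, M = M,
                            exact_offsets = exact_offsets, base = base)
    data.frame(L_bp = L, n = tr$n, I = tr$I, V = tr$V, M = tr$M,
               epsilon = tr$epsilon)
  })
  do.call(rbind, rows)
}

#' Fragment length achieving a target error probability
#'
#' Inverts the closed-form bound: finds the (real-valued) number of bins n
#' at which the predicted error equals `epsilon`, and returns the
#' corresponding fragment length rounded up to whole bins. Useful for
#' choosing simulation grids or minimum useful fragment lengths.
#'
#' @inheritParams error_probability
#' @param epsilon Target error probability in (0, 1); vectorized.
#' @param n_max Upper bound of the search range in bins.
#' @return Numeric vector of fragment lengths in bp (multiples of
#'   `bin_size`); `NA` where the target is not reachable within `n_max` bins.
#' @export
fragment_length_for_error <- function(model, genomes = NULL, epsilon,
                                      bin_size = 1000, M = NULL,
                                      n_max = 10000) {
  stopifnot(inherits(model, "channel_model"))
  if (is.null(M)) {
    if (is.null(genomes)) stop("supply either genomes or M")
    M <- codebook_size(genomes, bin_size)
  }
  st <- information_stats(model)
  if (st$I <= 0 || st$V <= 0)
    stop("channel must have I > 0 and V > 0 to invert the bound")
  f <- function(n, z) (log(M) - n * st$I - 0.5 * log(n)) / sqrt(n * st$V) - z
  vapply(epsilon, function(e) {
    stopifnot(e > 0, e < 1)
    z <- qnorm(e)
    if (f(1, z) < 0 || f(n_max, z) > 0) return(NA_real_)
    n <- stats::uniroot(f, c(1, n_max), z = z, tol = 1e-9)$root
    ceiling(n) * bin_size
  }, numeric(1))
}
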