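#' Construct a discrete memoryless channel model for OGM
#'
#' The channel has input x (capped per-bin pattern-occurrence count in the
#' reference genome) and output y (capped per-bin detected-label count in a
#' fragment image). Its two free parameters are the pattern-density
#' distribution `p_x` over `x in 0..cap` and the label-detection likelihood
#' `p_y_given_x`, a row-stochastic matrix with rows indexed by x and columns
#' by y. The likelihood absorbs labeling efficiency, off-target labeling, and
#' imaging noise.
#'
#' @param p_x Numeric probability vector of length `cap + 1`.
#' @param p_y_given_x Numeric `(cap + 1) x (cap + 1)` matrix, each row a
#'   probability vector.
#' @param cap Count cap (defaults to `length(p_x) - 1`).
#' @param label Optional free-text description.
#' @return An object of class `channel_model`.
#' @seealso [dle1_channel()], [estimate_px()], [estimate_pyx()]
#' @export
channel_model <- function(p_x, p_y_given_x, cap = length(p_x) - 1L,
                          label = NULL) {
  p_x <- as.numeric(p_x)
  p_y_given_x <- as.matrix(p_y_given_x)
  cap <- as.integer(cap)
  if (length(p_x) != cap + 1L)
    stop("p_x must have length cap + 1")
  if (!all(dim(p_y_given_x) == cap + 1L))
    stop("p_y_given_x must be a (cap + 1) x (cap + 1) matrix")
  # accept probabilities rounded for printing (published tables sum to
  # 1 +/- 1e-4), then renormalize exactly below
  if (any(p_x < 0) || abs(sum(p_x) - 1) > 1e-4)
    stop("p_x must be non-negative and sum to 1 (tolerance 1e-4)")
  rs <- rowSums(p_y_given_x)
  if (any(p_y_given_x < 0) || any(abs(rs - 1) > 1e-4))
    stop("every row of p_y_given_x must be non-negative and sum to 1")
  dimnames(p_y_given_x) <- list(x = 0:cap, y = 0:cap)
  names(p_x) <- 0:cap
  structure(list(cap = cap, p_x = p_x / sum(p_x),
                 p_y_given_x = p_y_given_x / rs,
                 label = label),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("channel_model (cap = %d)%s\n", x$cap,
              if (is.null(x$label)) "" else paste0(": ", x$label)))
  cat("p_x:\n"); print(round(x$p_x, 5))
  cat("p_y_given_x:\n"); print(round(x$p_y_given_x, 5))
  invisible(x)
}

#' Default channel parameters from DLE-1-labeled human DNA
#'
#' The package's built-in channel: the pattern-density distribution of the
#' DLE-1 recognition site CTTAAG on the human genome (hg38, 1-kb bins,
#' counts capped at 2) and the label-detection likelihood estimated from
#' Saphyr images of DLE-1-labeled human DNA fragments aligned to hg38.
#' These are the published estimates for that labeling chemistry and
#' instrument; the likelihood is commonly reused across candidate patterns
#' under the assumption that other six-letter recognition chemistries have
#' similar labeling error characteristics.
#'
#' @return A [channel_model()] with `cap = 2`.
#' @examples
#' m <- dle1_channel()
#' rowSums(m$p_y_given_x)
#' @export
dle1_channel <- function() {
  channel_model(
    p_x = c(0.81555, 0.16278, 0.02168),
    p_y_given_x = rbind(c(0.95961, 0.03847, 0.00192),
                        c(0.18716, 0.67492, 0.13792),
                        c(0.13109, 0.35978, 0.50913)),
    cap = 2L,
    label = "DLE-1 (CTTAAG), human genome, 1 kb bins")
}

#' Estimate the pattern-density distribution p_x from binned counts
#'
#' The empirical frequency of each capped per-bin count over all bins of all
#' records — the histogram of x.
#'
#' @param binned A [bin_genome()] result, or an integer vector (or list of
#'   vectors) of capped counts.
#' @param cap Count cap; taken from the `binned_genome` when available.
#' @return Named probability vector over `0..cap`.
#' @examples
#' estimate_px(c(0L, 0L, 1L, 2L), cap = 2)  # 0.50 0.25 0.25
#' @export
estimate_px <- function(binned, cap = NULL) {
  if (inherits(binned, "binned_genome")) {
    if (is.null(cap)) cap <- binned$cap
    counts <- unlist(binned$counts, use.names = FALSE)
  } else {
    counts <- as.integer(unlist(binned, use.names = FALSE))
    if (is.null(cap)) cap <- max(counts, 1L)
  }
  if (length(counts) == 0L) stop("no bins to estimate p_x from")
  if (any(counts < 0L | counts > cap)) stop("counts must lie in [0, cap]")
  p <- tabulate(counts + 1L, nbins = cap + 1L) / length(counts)
  names(p) <- 0:cap
  p
}

#' Estimate the label-detection likelihood p(y | x) from aligned bin pairs
#'
#' Row-normalizes the 2D histogram of aligned `(x, y)` bin-count pairs, as
#' obtained from high-confidence alignments of imaged fragments to a
#' reference. Rows of x never observed are returned as `NA` and flagged in
#' the `"missing_rows"` attribute (or rejected when `strict = TRUE`) rather
#' than silently imputed, since an invented likelihood row would corrupt the
#' information statistics invisibly.
#'
#' @param pairs A two-column data frame or matrix of capped counts with
#'   columns `x` and `y` (see [read_xy_pairs()]).
#' @param cap Count cap (default 2).
#' @param strict Error on missing x rows instead of flagging.
#' @param pseudocount Added to every cell before normalization (default 0,
#'   i.e. the raw histogram; a small value guards downstream decoding against
#'   log(0) when estimation data are sparse).
#' @return `(cap + 1) x (cap + 1)` matrix, rows summing to 1 (or `NA` rows
#'   for unobserved x), with attribute `missing_rows` (integer x values).
#' @examples
#' estimate_pyx(data.frame(x = rep(0, 10), y = c(rep(0, 9), 1)))[1, ]
#' @export
estimate_pyx <- function(pairs, cap = 2, strict = FALSE, pseudocount = 0) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) stop("no (x, y) pairs supplied")
  if (!all(c("x", "y") %in% names(pairs))) names(pairs)[1:2] <- c("x", "y")
  x <- as.integer(pairs$x); y <- as.integer(pairs$y)
  cap <- as.integer(cap)
  if (any(x < 0L | x > cap) || any(y < 0L | y > cap))
    stop("x and y must already be capped to [0, cap]")
  h <- matrix(pseudocount, cap + 1L, cap + 1L,
              dimnames = list(x = 0:cap, y = 0:cap))
  tab <- table(factor(x, levels = 0:cap), factor(y, levels = 0:cap))
  h <- h + as.matrix(tab)
  rs <- rowSums(h)
  missing <- which(rs == 0) - 1L
  if (length(missing) && strict)
    stop("no observations for x = ", paste(missing, collapse = ", "))
  out <- h / ifelse(rs > 0, rs, NA_real_)
  attr(out, "missing_rows") <- as.integer(missing)
  out
}

#' Marginal distribution of detected-label counts
#'
#' \eqn{p_y(y) = \sum_x p_x(x)\, p_{y|x}(y \mid x)}, the output distribution
#' of the channel.
#'
#' @param model A [channel_model()].
#' @return Named probability vector over `0..cap`.
#' @export
marginal_py <- function(model) {
  stopifnot(inherits(model, "channel_model"))
  p <- as.vector(model$p_x %*% model$p_y_given_x)
  names(p) <- 0:model$cap
  p
}

#' Read aligned (x, y) bin-count pairs from a TSV file
#'
#' Expects a header line `x<TAB>y` and one aligned bin per row; counts must
#' already be capped.
#'
#' @param path Path to the TSV file.
#' @return Data frame with integer columns `x` and `y`.
#' @export
read_xy_pairs <- function(path) {
  if (!file.exists(path)) stop("pairs file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("x", "y") %in% names(df)))
    stop("expected a TSV with header columns 'x' and 'y'")
  data.frame(x = as.integer(df$x), y = as.integer(df$y))
}

#' Serialize / deserialize a channel model as JSON
#'
#' Writes `cap`, `p_x` and `p_y_given_x` (as a list of rows) at full double
#' precision, so that a read-back round trip reproduces the model exactly.
#'
#' @param model A [channel_model()].
#' @param path Output (input) file path.
#' @return `write_channel_json()`: `path`, invisibly. `read_channel_json()`:
#'   a `channel_model`.
#' @export
write_channel_json <- function(model, path) {
  stopifnot(inherits(model, "channel_model"))
  obj <- list(cap = model$cap,
              p_x = unname(model$p_x),
              p_y_given_x = lapply(seq_len(nrow(model$p_y_given_x)),
                                   function(i) unname(model$p_y_given_x[i, ])),
              label = model$label)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_channel_json
#' @export
read_channel_json <- function(path) {
  if (!file.exists(path)) stop("channel file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- obj$p_y_given_x
  if (is.list(P)) P <- do.call(rbind, P)
  channel_model(p_x = obj$p_x, p_y_given_x = P, cap = obj$cap,
                label = if (is.null(obj$label)) NULL else obj$label)
}
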