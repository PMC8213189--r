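# Intensity vectors are length 256 throughout; index i corresponds to the
# 8-bit grayscale level g = i - 1 (0 = black, 255 = white).
N_LEVELS <- 256L

intensity_levels <- function() 0:255

#' Construct a probability histogram over 8-bit intensities
#'
#' A probability histogram assigns a probability `p_g` to every intensity
#' level `g = 0, ..., 255`. Its support is the set of strictly positive bins.
#'
#' @param probs Numeric vector of length 256 of non-negative probabilities
#'   summing to 1 (tolerance `1e-9`).
#' @return An object of class `prob_histogram`: the probability vector with a
#'   `support` attribute holding the 0-based intensity levels with positive
#'   mass.
#' @export
prob_histogram <- function(probs) {
  probs <- as.numeric(probs)
  if (length(probs) != N_LEVELS)
    stop("'probs' must have length 256, got ", length(probs))
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("'probs' must be finite and non-negative")
  if (abs(sum(probs) - 1) > 1e-9)
    stop("'probs' must sum to 1 (tolerance 1e-9); sum is ", sum(probs))
  structure(probs, support = which(probs > 0) - 1L, class = "prob_histogram")
}

#' @export
print.prob_histogram <- function(x, ...) {
  s <- attr(x, "support")
  cat(sprintf("<prob_histogram> %d support bins in [%d, %d]\n",
              length(s), min(s), max(s)))
  invisible(x)
}

is_prob_histogram <- function(x) inherits(x, "prob_histogram")

assert_prob_histogram <- function(x, arg = deparse(substitute(x))) {
  if (!is_prob_histogram(x))
    stop("'", arg, "' must be a prob_histogram (see ?prob_histogram)")
  invisible(x)
}

#' Tally of pixel intensities for one channel of one image
#'
#' @param counts Integer vector of length 256; `counts[g + 1]` is the number
#'   of pixels with intensity `g`.
#' @param channel One of `"gray"`, `"red"`, `"green"`, `"blue"`.
#' @param source_id Opaque identifier of the originating image.
#' @return An object of class `channel_counts` with fields `counts`,
#'   `n_pixels`, `channel`, `source_id`.
#' @export
channel_counts <- function(counts, channel = "gray", source_id = NA_character_) {
  counts <- as.integer(counts)
  if (length(counts) != N_LEVELS)
    stop("'counts' must have length 256, got ", length(counts))
  if (any(is.na(counts)) || any(counts < 0))
    stop("'counts' must be non-negative integers")
  channel <- match_channel(channel)
  n <- sum(counts)
  if (n == 0L) stop("empty tally: no pixels counted")
  structure(list(counts = counts, n_pixels = n, channel = channel,
                 source_id = source_id),
            class = "channel_counts")
}

#' @export
print.channel_counts <- function(x, ...) {
  cat(sprintf("<channel_counts> %s channel, %d pixels (%s)\n",
              x$channel, x$n_pixels, x$source_id))
  invisible(x)
}

match_channel <- function(channel) {
  match.arg(channel, c("gray", "red", "green", "blue"))
}

#' Convert a tally of intensities to a probability histogram
#'
#' @param counts A [channel_counts] object.
#' @return A [prob_histogram]: relative frequencies `counts / n_pixels`.
#' @export
to_probability <- function(counts) {
  if (!inherits(counts, "channel_counts"))
    stop("'counts' must be a channel_counts object")
  prob_histogram(counts$counts / counts$n_pixels)
}

#' Cumulative distribution of an intensity histogram
#'
#' Computes `F_g = sum_{h < g} p_h` (strict inequality, so `F_0 = 0`). With
#' this convention `F_g` is the probability of a pixel strictly darker than
#' `g`, and `F_255 + p_255 = 1`.
#'
#' @param hist A [prob_histogram].
#' @return Object of class `cumulative_distribution`: numeric vector of
#'   length 256 with `values[g + 1] = F_g`.
#' @export
cumulative <- function(hist) {
  assert_prob_histogram(hist)
  f <- cumsum(c(0, as.numeric(hist)[-N_LEVELS]))
  structure(f, class = "cumulative_distribution")
}

#' Mean and median intensity of a histogram
#'
#' The median is the smallest intensity `g` with `F_g + p_g >= 1/2`, i.e.
#' the level at which the cumulative curve crosses one half; ties break to
#' the smallest qualifying intensity.
#'
#' @param hist A [prob_histogram].
#' @return A list with components `mean` (real) and `median` (integer
#'   intensity).
#' @export
summarize_histogram <- function(hist) {
  assert_prob_histogram(hist)
  p <- as.numeric(hist)
  g <- intensity_levels()
  fplus <- cumsum(p)  # F_g + p_g = P(X <= g)
  list(mean = sum(g * p),
       median = g[which(fplus >= 0.5)[1]])
}

#' Darkness ordering of two cumulative intensity distributions
#'
#' A distribution whose cumulative curve lies everywhere above the other
#' concentrates its mass at lower (darker, 0 = black) intensities. Verdict is
#' `"first_darker"` when `F_g >= G_g` for all `g` with strict inequality
#' somewhere, symmetrically `"second_darker"`, and `"incomparable"` when the
#' curves cross (or coincide).
#'
#' @param f,g Objects of class `cumulative_distribution` (see [cumulative]).
#' @param tol Numerical slack for the pointwise comparisons.
#' @return One of `"first_darker"`, `"second_darker"`, `"incomparable"`.
#' @export
darker_than <- function(f, g, tol = 1e-12) {
  stopifnot(inherits(f, "cumulative_distribution"),
            inherits(g, "cumulative_distribution"))
  d <- as.numeric(f) - as.numeric(g)
  if (all(d >= -tol) && any(d > tol)) return("first_darker")
  if (all(d <= tol) && any(d < -tol)) return("second_darker")
  "incomparable"
}


# Full-precision TSV writer: doubles are rendered with %.17g so values
# round-trip bit-for-bit through read.delim.
write_tsv_precise <- function(df, path) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- sprintf("%.17g", df[[col]])
      v[is.na(df[[col]])] <- "NA"
      df[[col]] <- v
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-image histogram as TSV
#'
#' Columns `g`, `count`, `prob`.
#'
#' @param counts A [channel_counts] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(counts, path) {
  if (!inherits(counts, "channel_counts"))
    stop("'counts' must be a channel_counts object")
  df <- data.frame(g = intensity_levels(), count = counts$counts,
                   prob = counts$counts / counts$n_pixels)
  write_tsv_precise(df, path)
}

#' Write a cumulative distribution as TSV
#'
#' Columns `g`, `F_g`.
#'
#' @param f A `cumulative_distribution`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cumulative_tsv <- function(f, path) {
  stopifnot(inherits(f, "cumulative_distribution"))
  df <- data.frame(g = intensity_levels(), F_g = as.numeric(f))
  write_tsv_precise(df, path)
}

#' Read a tabulated histogram from TSV
#'
#' Accepts the format written by [write_histogram_tsv] (columns `g` plus
#' `count` and/or `prob`); used by the histogram-level comparison entry
#' point.
#'
#' @param path TSV file with a `g` column covering 0..255 and a `count` or
#'   `prob` column.
#' @return A [prob_histogram].
#' @export
read_histogram_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"g" %in% names(df))
    stop("histogram TSV must have a 'g' column: ", path)
  col <- if ("prob" %in% names(df)) "prob" else if ("count" %in% names(df))
    "count" else stop("histogram TSV needs a 'prob' or 'count' column: ", path)
  p <- numeric(N_LEVELS)
  idx <- as.integer(df$g) + 1L
  if (any(idx < 1L | idx > N_LEVELS))
    stop("intensities out of range 0..255 in ", path)
  p[idx] <- as.numeric(df[[col]])
  prob_histogram(p / sum(p))
}
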