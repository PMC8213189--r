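# Fixed-shift model: pooling an ensemble of per-image channel tallies and
# the maximum-likelihood estimate of the shared group histogram.
#
# The model assumes every image's log-odds histogram (relative to the
# reference intensity g = 0) differs from a common profile only by an
# image-specific additive constant b_i, which absorbs staining-intensity
# variation between samples. Under that assumption the pooled counts d_g
# and total pixel number N_T are sufficient, and the MLE of the log-odds is
#   rho_g = ln( d_g / (N_T - d_0) ),   g >= 1, d_g > 0.

#' Pool an ensemble of per-image channel tallies
#'
#' @param ensemble Non-empty list of [channel_counts], all for the same
#'   channel.
#' @return Object of class `pooled_counts` with fields `d` (length-256
#'   pooled counts), `N_T` (total pixels), `n_images`, `channel`.
#' @export
pool_counts <- function(ensemble) {
  if (!is.list(ensemble) || length(ensemble) == 0L)
    stop("'ensemble' must be a non-empty list of channel_counts")
  if (!all(vapply(ensemble, inherits, logical(1), "channel_counts")))
    stop("every element of 'ensemble' must be a channel_counts object")
  channels <- unique(vapply(ensemble, function(x) x$channel, character(1)))
  if (length(channels) != 1L)
    stop("cannot pool mixed channels: ", paste(channels, collapse = ", "))
  d <- Reduce(`+`, lapply(ensemble, function(x) x$counts))
  structure(list(d = as.integer(d), N_T = sum(d),
                 n_images = length(ensemble), channel = channels),
            class = "pooled_counts")
}

#' @export
print.pooled_counts <- function(x, ...) {
  cat(sprintf("<pooled_counts> %s channel, %d images, N_T = %d\n",
              x$channel, x$n_images, x$N_T))
  invisible(x)
}

new_log_odds <- function(values, levels) {
  structure(stats::setNames(values, levels), reference_bin = 0L,
            class = "log_odds")
}

#' @export
print.log_odds <- function(x, ...) {
  cat(sprintf("<log_odds> %d bins relative to g = 0\n", length(x)))
  invisible(x)
}

#' Logit transform of a probability histogram
#'
#' Computes the log-odds `rho_g = ln p_g - ln p_0` against the reference
#' bin `g = 0` for every non-zero bin `g >= 1`; zero-probability bins are
#' omitted.
#'
#' @param hist A [prob_histogram] with `p_0 > 0`.
#' @return A `log_odds` object: named vector of `rho_g` over the support
#'   (names are intensity levels).
#' @export
logit_transform <- function(hist) {
  assert_prob_histogram(hist)
  p <- as.numeric(hist)
  if (p[1] <= 0)
    stop("reference bin g = 0 has zero probability; log-odds undefined")
  keep <- which(p > 0)
  keep <- keep[keep > 1L]
  new_log_odds(log(p[keep]) - log(p[1]), keep - 1L)
}

#' Fixed-shift MLE of the group log-odds
#'
#' `rho_g = ln( d_g / (N_T - d_0) )` for every `g >= 1` with `d_g > 0`.
#' A direct consequence of the formula is `sum_g exp(rho_g) = 1` over the
#' estimated bins.
#'
#' @param pooled A [pool_counts] result.
#' @return A `log_odds` object over the pooled support (bins `g >= 1` with
#'   `d_g > 0`).
#' @export
mle_log_odds <- function(pooled) {
  if (!inherits(pooled, "pooled_counts"))
    stop("'pooled' must be a pooled_counts object")
  d0 <- pooled$d[1]
  if (pooled$N_T == d0)
    stop("degenerate ensemble: every pixel has intensity 0 (N_T = d_0)")
  keep <- which(pooled$d > 0L)
  keep <- keep[keep > 1L]
  new_log_odds(log(pooled$d[keep]) - log(pooled$N_T - d0), keep - 1L)
}

#' Fixed-shift MLE of the group histogram
#'
#' Reconstructs probabilities from the estimated log-odds with
#' `p_0 = d_0 / N_T` and `p_g = (1 - p_0) * exp(rho_g)` for `g >= 1`. This
#' is the unique reconstruction consistent with the log-odds estimate that
#' sums to one; it coincides with the pooled relative frequencies
#' `d_g / N_T`.
#'
#' @param pooled A [pool_counts] result.
#' @return A [prob_histogram].
#' @export
mle_histogram <- function(pooled) {
  rho <- mle_log_odds(pooled)
  p0 <- pooled$d[1] / pooled$N_T
  if (pooled$d[1] == 0L)
    warning("reference bin g = 0 absent from the ensemble; ",
            "estimated histogram has no mass at 0")
  p <- numeric(N_LEVELS)
  p[1] <- p0
  p[as.integer(names(rho)) + 1L] <- (1 - p0) * exp(as.numeric(rho))
  prob_histogram(p)
}

#' Write the fixed-shift MLE as TSV
#'
#' Columns `g`, `d_g`, `rho_g` (NA outside the estimated support), `p_g`.
#'
#' @param pooled A [pool_counts] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mle_tsv <- function(pooled, path) {
  rho <- mle_log_odds(pooled)
  hist <- mle_histogram(pooled)
  rho_col <- rep(NA_real_, N_LEVELS)
  rho_col[as.integer(names(rho)) + 1L] <- as.numeric(rho)
  df <- data.frame(g = intensity_levels(), d_g = pooled$d,
                   rho_g = rho_col, p_g = as.numeric(hist))
  write_tsv_precise(df, path)
}
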