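# Group comparison: two-sample Kolmogorov-Smirnov test on estimated
# histograms, escort families, and beta-scans of Hellinger distance and
# Shannon-entropy difference.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Two-sample Kolmogorov-Smirnov comparison of two histograms
#'
#' The statistic is `D = max_g |F_p(g) - F_q(g)|` over all 256 intensity
#' levels. The p-value comes from the asymptotic two-sample Kolmogorov
#' distribution evaluated at `sqrt(n) * D` with
#' `n = n_eff_1 * n_eff_2 / (n_eff_1 + n_eff_2)`. The effective sample
#' sizes are supplied by the caller: pixel counts treat pixels as
#' independent draws (anti-conservative for textured images), image counts
#' are the conservative choice.
#'
#' @param p,q [prob_histogram] objects.
#' @param n_eff_1,n_eff_2 Positive effective sample sizes behind `p` and `q`.
#' @return Object of class `ks_result`: list with `statistic`, `p_value`,
#'   `n_eff_1`, `n_eff_2`.
#' @export
ks_compare <- function(p, q, n_eff_1, n_eff_2) {
  assert_prob_histogram(p); assert_prob_histogram(q)
  if (!is.numeric(n_eff_1) || !is.numeric(n_eff_2) ||
      n_eff_1 <= 0 || n_eff_2 <= 0)
    stop("effective sample sizes must be positive")
  d <- max(abs(as.numeric(cumulative(p)) - as.numeric(cumulative(q))))
  n <- n_eff_1 * n_eff_2 / (n_eff_1 + n_eff_2)
  structure(list(statistic = d, p_value = ks_asymptotic_pvalue(sqrt(n) * d),
                 n_eff_1 = n_eff_1, n_eff_2 = n_eff_2),
            class = "ks_result")
}

# Survival function of the Kolmogorov distribution,
# Q(lambda) = 2 * sum_{k>=1} (-1)^{k-1} exp(-2 k^2 lambda^2).
ks_asymptotic_pvalue <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.5f, p = %.4g (n_eff = %g, %g)\n",
              x$statistic, x$p_value, x$n_eff_1, x$n_eff_2))
  invisible(x)
}

#' Escort distribution of a histogram
#'
#' The escort family `P_g(beta) = p_g^beta / sum_h p_h^beta`, with the sum
#' restricted to the support (`p_h > 0`). `beta > 1` accentuates
#' high-probability bins, `beta < 1` (including negative beta) accentuates
#' rare bins; `beta = 0` is uniform on the support and `beta = 1` returns
#' the histogram itself. Computed in the log domain
#' (`beta * ln p - logsumexp(beta * ln p)`) so large and negative beta are
#' stable.
#'
#' @param hist A [prob_histogram].
#' @param beta Real escort parameter.
#' @return A [prob_histogram] on the same support.
#' @export
escort <- function(hist, beta) {
  assert_prob_histogram(hist)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("'beta' must be a single finite number")
  if (beta == 1) return(hist)
  p <- as.numeric(hist)
  sup <- which(p > 0)
  out <- numeric(N_LEVELS)
  if (beta == 0) {
    out[sup] <- 1 / length(sup)
    return(prob_histogram(out))
  }
  z <- beta * log(p[sup])
  if (any(!is.finite(z)))
    stop("escort exponent overflow at beta = ", beta)
  out[sup] <- exp(z - logsumexp(z))
  prob_histogram(out / sum(out))
}

#' Hellinger distance between two histograms
#'
#' `H` with `H^2 = (1/2) * sum_g (sqrt(p_g) - sqrt(q_g))^2`, evaluated over
#' the union of supports (missing bins contribute as 0); `H` lies in
#' `[0, 1]`, 0 for identical histograms and 1 for disjoint supports.
#' `method = "squared_diff"` replaces the square-root differences with raw
#' probability differences (`H^2 = (1/2) * sum (p - q)^2`), provided for
#' sensitivity checks only; it is not a [0, 1]-normalized metric on
#' histograms.
#'
#' @param p,q [prob_histogram] objects.
#' @param method `"sqrt"` (Hellinger proper, default) or `"squared_diff"`.
#' @return Distance in `[0, 1]` (for `"sqrt"`).
#' @export
hellinger <- function(p, q, method = c("sqrt", "squared_diff")) {
  assert_prob_histogram(p); assert_prob_histogram(q)
  method <- match.arg(method)
  pv <- as.numeric(p); qv <- as.numeric(q)
  h2 <- if (method == "sqrt") 0.5 * sum((sqrt(pv) - sqrt(qv))^2)
        else 0.5 * sum((pv - qv)^2)
  min(1, sqrt(max(0, h2)))
}

#' Shannon entropy of a histogram (nats)
#'
#' `S = -sum p_g ln p_g` over the support; zero-probability bins contribute
#' nothing. Low entropy flags a few dominant intensities (uniform regions);
#' high entropy flags mass spread over many bins.
#'
#' @param hist A [prob_histogram].
#' @return Entropy in nats, in `[0, ln 256]`.
#' @export
shannon_entropy <- function(hist) {
  assert_prob_histogram(hist)
  p <- as.numeric(hist)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy difference of two escort histograms
#'
#' `dS(beta) = S(escort(cells, beta)) - S(escort(control, beta))`; positive
#' values mean the treated-group histogram carries more informational
#' content at that beta, the signature of cluster formation.
#'
#' @param cells,control [prob_histogram] objects (treated and control group
#'   estimates).
#' @param beta Escort parameter.
#' @return Real entropy difference in nats.
#' @export
entropy_difference <- function(cells, control, beta) {
  shannon_entropy(escort(cells, beta)) - shannon_entropy(escort(control, beta))
}

#' Build a beta grid for escort scans
#'
#' Evenly spaced points on `[beta_min, beta_max]` with the anchor values 0
#' and 1 inserted (deduplicated), since the scan's two reference points are
#' the uniform escort (`beta = 0`) and the original histograms
#' (`beta = 1`).
#'
#' @param beta_min,beta_max Range of the scan.
#' @param steps Number of evenly spaced points before anchor insertion.
#' @return Strictly increasing numeric vector containing 0 and 1.
#' @export
beta_grid <- function(beta_min = -5, beta_max = 5, steps = 101) {
  if (beta_min >= beta_max) stop("'beta_min' must be below 'beta_max'")
  g <- sort(unique(c(seq(beta_min, beta_max, length.out = steps), 0, 1)))
  validate_beta_grid(g)
}

validate_beta_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L || any(diff(grid) <= 0))
    stop("beta grid must be strictly increasing")
  if (!any(grid == 0) || !any(grid == 1))
    stop("beta grid must contain the anchor values 0 and 1")
  grid
}

#' Scan Hellinger distance and entropy difference over escort parameters
#'
#' For every beta on the grid, forms the escort distributions of the two
#' group histograms (each on its own support) and records the Hellinger
#' distance between them (over the union of supports) and their
#' Shannon-entropy difference.
#'
#' @param cells,control [prob_histogram] objects (treated and control).
#' @param grid Beta grid from [beta_grid] (must contain 0 and 1).
#' @param staining,channel Optional metadata labels carried in the result.
#' @return Object of class `beta_scan_result`: data frame with columns
#'   `beta`, `hellinger`, `delta_entropy` and attributes `staining`,
#'   `channel`.
#' @export
beta_scan <- function(cells, control, grid = beta_grid(),
                      staining = NA_character_, channel = NA_character_) {
  assert_prob_histogram(cells); assert_prob_histogram(control)
  grid <- validate_beta_grid(grid)
  h <- numeric(length(grid))
  ds <- numeric(length(grid))
  for (i in seq_along(grid)) {
    ec <- escort(cells, grid[i])
    ek <- escort(control, grid[i])
    h[i] <- hellinger(ec, ek)
    ds[i] <- shannon_entropy(ec) - shannon_entropy(ek)
  }
  structure(data.frame(beta = grid, hellinger = h, delta_entropy = ds),
            staining = staining, channel = channel,
            class = c("beta_scan_result", "data.frame"))
}

#' Classify the shape of a Hellinger beta-profile
#'
#' Three qualitative classes: `flat` (range below `tol_flat` of the
#' maximum), `monotonic_growth` (successive differences never fall below
#' `-tol_mono`), otherwise `non_monotonic` with the beta of the curve's
#' maximum reported.
#'
#' @param hellinger_values Hellinger distances along the grid (>= 3 points).
#' @param grid The beta values the curve was evaluated at.
#' @param tol_flat Relative range below which the curve is called flat.
#' @param tol_mono Slack allowed on downward steps of a monotonic curve.
#' @return Object of class `profile_class`: list with `class` (one of
#'   `"monotonic_growth"`, `"flat"`, `"non_monotonic"`) and `argmax_beta`
#'   (NA unless non-monotonic).
#' @export
classify_profile <- function(hellinger_values, grid,
                             tol_flat = 0.05, tol_mono = 1e-6) {
  h <- as.numeric(hellinger_values)
  if (length(h) < 3L) stop("profile classification needs at least 3 points")
  if (length(grid) != length(h))
    stop("'grid' and 'hellinger_values' must have equal length")
  hmax <- max(h)
  cls <- if (max(h) - min(h) < tol_flat * max(hmax, 1e-12)) "flat"
         else if (all(diff(h) >= -tol_mono)) "monotonic_growth"
         else "non_monotonic"
  structure(list(class = cls,
                 argmax_beta = if (cls == "non_monotonic")
                   grid[which.max(h)] else NA_real_),
            class = "profile_class")
}

#' @export
print.profile_class <- function(x, ...) {
  cat("<profile_class>", x$class,
      if (!is.na(x$argmax_beta)) sprintf("(argmax beta = %g)", x$argmax_beta),
      "\n")
  invisible(x)
}

#' Write a beta scan as TSV
#'
#' Columns `beta`, `hellinger`, `delta_entropy`.
#'
#' @param scan A [beta_scan] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beta_scan_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "beta_scan_result"))
  write_tsv_precise(as.data.frame(scan), path)
}
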