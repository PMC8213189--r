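# Shared fixture builders: histograms are built in code, image fixtures are
# written as temporary PNGs at test time.

# Sparse histogram from a named vector of probabilities, e.g.
# hist_from(c(`0` = 0.5, `1` = 0.25, `2` = 0.25)).
hist_from <- function(x) {
  p <- numeric(256)
  p[as.integer(names(x)) + 1L] <- as.numeric(x)
  prob_histogram(p)
}

point_mass <- function(g) hist_from(stats::setNames(1, g))

# Random histogram supported on n_bins uniformly chosen levels, Dirichlet-ish
# weights. Deterministic under the caller's RNG state.
random_histogram <- function(n_bins = 20) {
  bins <- sample(0:255, n_bins)
  w <- stats::rgamma(n_bins, shape = 1)
  hist_from(stats::setNames(w / sum(w), bins))
}

# Write an integer h x w x 3 pixel array (0..255) as a PNG fixture and
# return its path.
write_png_fixture <- function(px, path = tempfile(fileext = ".png")) {
  png::writePNG(px / 255, path)
  path
}

rgb_array <- function(r, g, b) {
  h <- nrow(r); w <- ncol(r)
  a <- array(0L, dim = c(h, w, 3L))
  a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
  a
}

counts_from_values <- function(values, channel = "gray", source_id = "x") {
  channel_counts(tabulate(as.integer(values) + 1L, nbins = 256),
                 channel = channel, source_id = source_id)
}
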