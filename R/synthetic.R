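# Synthetic two-arm stained-histology study generator. Emulates the
# statistical structure the analysis assumes: a shared reference intensity
# histogram per arm, an image-specific fixed logit shift b_i ~ N(0, sigma^2),
# i.i.d. pixel sampling, and -- in the treated arm -- localized disc-shaped
# "cluster" blobs whose intensity offset moves mass into otherwise sparse
# bins and raises histogram entropy. Ground truth (shifts, masks, reference
# histograms) is retained for parameter-recovery experiments.

#' Default synthetic reference histogram
#'
#' Mass `p0` at intensity 0 (dark stained nuclei / background specks) plus
#' `1 - p0` spread as a discretized truncated normal over the stated bin
#' range (midtone stained tissue). The reference bin g = 0 must carry
#' non-trivial mass for the fixed shift -- which re-weights bin 0 against
#' all other bins -- to be a visible source of image-to-image variation.
#'
#' @param mean,sd Location and scale of the midtone component.
#' @param range Integer bin range of the midtone support.
#' @param p0 Probability mass at intensity 0.
#' @return A [prob_histogram].
#' @export
reference_histogram <- function(mean = 120, sd = 30, range = c(30L, 210L),
                                p0 = 0.1) {
  if (p0 < 0 || p0 >= 1) stop("'p0' must be in [0, 1)")
  p <- numeric(N_LEVELS)
  bins <- range[1]:range[2]
  w <- stats::dnorm(bins, mean, sd)
  p[bins + 1L] <- (1 - p0) * w / sum(w)
  p[1L] <- p0
  prob_histogram(p / sum(p))
}

staining_tint <- function(staining) {
  switch(match.arg(staining, c("H", "S", "M")),
         H = c(0.85, 0.45, 0.80),   # magenta-purple dominant
         S = c(1.00, 0.55, 0.30),   # red-orange dominant
         M = c(0.45, 0.70, 0.95))   # blue-green dominant
}

#' Specification of a two-arm synthetic study
#'
#' @param staining Staining tag, one of `"H"`, `"S"`, `"M"`; selects the RGB
#'   tint applied to the sampled gray field (the tints only make channel
#'   dependence testable; no histological realism is claimed).
#' @param n_images_per_arm Images per arm (the study design this emulates
#'   used 8 per arm for S staining and 7 for M and H).
#' @param height,width Image dimensions in pixels (the emulated study used
#'   1024 x 1360; tests use small images such as 64 x 64).
#' @param reference Control-arm reference [prob_histogram] for the
#'   underlying gray field; must have positive mass at g = 0.
#' @param shift_sigma Standard deviation of the per-image fixed logit shift
#'   `b_i ~ Normal(0, shift_sigma^2)`.
#' @param n_clusters Number of disc blobs added to each treated-arm image
#'   (0 gives a pure fixed-shift null).
#' @param radius_px Disc radius in pixels.
#' @param intensity_offset Additive intensity offset inside the discs
#'   (clipped to 0..255).
#' @param seed Master seed; all randomness is derived from it.
#' @return Object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(staining = "S", n_images_per_arm = 8L,
                                 height = 64L, width = 64L,
                                 reference = reference_histogram(),
                                 shift_sigma = 0.5, n_clusters = 3L,
                                 radius_px = 5, intensity_offset = 64L,
                                 seed = 1L) {
  assert_prob_histogram(reference)
  if (as.numeric(reference)[1] <= 0)
    stop("'reference' must have positive mass at g = 0")
  if (n_images_per_arm < 1L || height < 1L || width < 1L)
    stop("dimensions and arm sizes must be positive")
  if (shift_sigma < 0) stop("'shift_sigma' must be non-negative")
  if (n_clusters < 0L) stop("'n_clusters' must be >= 0")
  structure(list(staining = match.arg(staining, c("H", "S", "M")),
                 n_images_per_arm = as.integer(n_images_per_arm),
                 height = as.integer(height), width = as.integer(width),
                 reference = reference, shift_sigma = shift_sigma,
                 n_clusters = as.integer(n_clusters), radius_px = radius_px,
                 intensity_offset = as.integer(intensity_offset),
                 seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

#' Apply a fixed logit shift to a histogram
#'
#' Shifting every log-odds value `rho_g = ln(p_g / p_0)` by a constant `b`
#' and renormalizing scales every non-reference bin by `e^b` relative to
#' bin 0: `p'_g = e^b p_g / (p_0 + e^b (1 - p_0))` for `g >= 1` and
#' `p'_0 = p_0 / (p_0 + e^b (1 - p_0))`.
#'
#' @param ref A [prob_histogram] with `p_0 > 0`.
#' @param b Real shift.
#' @return A [prob_histogram] on the same support.
#' @export
shifted_histogram <- function(ref, b) {
  assert_prob_histogram(ref)
  p <- as.numeric(ref)
  if (p[1] <= 0)
    stop("reference bin g = 0 has zero probability; shift undefined")
  w <- p
  w[-1] <- exp(b) * p[-1]
  prob_histogram(w / sum(w))
}

#' Sample an i.i.d. pixel grid from a histogram
#'
#' @param hist A [prob_histogram].
#' @param height,width Positive dimensions.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers can embed the draw in their own stream).
#' @return Integer matrix `height x width` of intensities.
#' @export
sample_image <- function(hist, height, width, seed = NULL) {
  assert_prob_histogram(hist)
  if (height < 1L || width < 1L) stop("dimensions must be positive")
  draw <- function() matrix(sample.int(N_LEVELS, height * width,
                                       replace = TRUE,
                                       prob = as.numeric(hist)) - 1L,
                            nrow = height)
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic per-stream sub-seed: a counter-based integer mix so adding
# images never perturbs the streams of earlier ones. Kept below 2^31.
derive_seed <- function(master, stream) {
  ((as.numeric(master) %% 2147483647) * 48271 +
     (as.numeric(stream) + 1) * 16807) %% 2147483629 + 1
}

#' Add disc-shaped cluster blobs to a pixel grid
#'
#' Places `n_clusters` discs at uniform-random centers (overlap allowed,
#' discs are clipped at the image boundary) and offsets the intensity of
#' every covered pixel by `intensity_offset`, clipping to 0..255.
#'
#' @param grid Integer matrix of intensities.
#' @param n_clusters Number of discs (>= 0).
#' @param radius_px Disc radius in pixels; the disc diameter must fit
#'   inside the image.
#' @param intensity_offset Additive offset applied inside the discs.
#' @param seed Optional integer seed (see [sample_image]).
#' @return List with `grid` (modified matrix) and `mask` (logical matrix of
#'   altered pixels).
#' @export
add_clusters <- function(grid, n_clusters = 3L, radius_px = 5,
                         intensity_offset = 64L, seed = NULL) {
  h <- nrow(grid); w <- ncol(grid)
  if (2 * radius_px + 1 > min(h, w))
    stop("cluster radius ", radius_px, " too large for a ", h, " x ", w,
         " image")
  run <- function() {
    mask <- matrix(FALSE, h, w)
    if (n_clusters > 0L) {
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      for (k in seq_len(n_clusters)) {
        cy <- sample.int(h, 1L)
        cx <- sample.int(w, 1L)
        mask <- mask | ((rows - cy)^2 + (cols - cx)^2 <= radius_px^2)
      }
    }
    out <- grid
    out[mask] <- pmin(pmax(out[mask] + as.integer(intensity_offset), 0L), 255L)
    list(grid = out, mask = mask)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

# Map a gray field to one tinted RGB channel: g -> round(tint * g).
tint_channel <- function(gray, tint) {
  out <- pmin(pmax(round(tint * gray), 0), 255)
  storage.mode(out) <- "integer"
  out
}

# Pushforward of a histogram through the deterministic tinting map,
# used to express the per-channel reference truths.
pushforward_histogram <- function(hist, map) {
  p <- as.numeric(hist)
  out <- numeric(N_LEVELS)
  tgt <- as.integer(map) + 1L
  for (i in seq_len(N_LEVELS)) out[tgt[i]] <- out[tgt[i]] + p[i]
  prob_histogram(out)
}

#' Per-channel reference histograms implied by a gray reference and tint
#'
#' The synthetic generator draws a gray field and maps it deterministically
#' to tinted R, G, B components (and back to a luma gray); each channel's
#' reference histogram is therefore the pushforward of the gray reference
#' through that map.
#'
#' @param reference Gray-field reference [prob_histogram].
#' @param staining Staining tag selecting the tint.
#' @param weights Luma weights used for the gray view, see [gray_weights].
#' @return Named list of [prob_histogram]s for `gray`, `red`, `green`,
#'   `blue`.
#' @export
channel_references <- function(reference, staining, weights = gray_weights()) {
  tint <- staining_tint(staining)
  g <- intensity_levels()
  maps <- list(red = pmin(pmax(round(tint[1] * g), 0), 255),
               green = pmin(pmax(round(tint[2] * g), 0), 255),
               blue = pmin(pmax(round(tint[3] * g), 0), 255))
  w <- gray_weights(weights)
  maps$gray <- pmin(pmax(round(w[1] * maps$red + w[2] * maps$green +
                                 w[3] * maps$blue), 0), 255)
  lapply(maps[c("gray", "red", "green", "blue")],
         function(m) pushforward_histogram(reference, m))
}

#' Generate a two-arm synthetic study
#'
#' For each arm and image: draw the fixed shift `b_i ~ N(0, shift_sigma^2)`,
#' shift the reference histogram, sample an i.i.d. gray field, add cluster
#' discs (treated arm only), and tint to RGB by the staining tag. All
#' randomness derives from `spec$seed` through counter-based per-image
#' sub-seeds, so identical specs give byte-identical studies and enlarging
#' an arm leaves earlier images unchanged.
#'
#' @param spec A [synthetic_study_spec].
#' @return Object of class `synthetic_study`: list with `treated` and
#'   `control` (lists of [image_array]) and `truth` (reference histograms
#'   per channel, realized shifts per image, cluster masks per treated
#'   image, and the spec).
#' @export
generate_study <- function(spec) {
  if (!inherits(spec, "synthetic_study_spec"))
    stop("'spec' must be a synthetic_study_spec")
  tint <- staining_tint(spec$staining)
  arms <- list(control = 0L, treated = 100000L)
  images <- list(control = vector("list", spec$n_images_per_arm),
                 treated = vector("list", spec$n_images_per_arm))
  shifts <- list(control = numeric(spec$n_images_per_arm),
                 treated = numeric(spec$n_images_per_arm))
  masks <- vector("list", spec$n_images_per_arm)
  for (arm in names(arms)) {
    for (i in seq_len(spec$n_images_per_arm)) {
      s <- derive_seed(spec$seed, arms[[arm]] + i)
      res <- with_local_seed(s, {
        b <- stats::rnorm(1, 0, spec$shift_sigma)
        gray <- sample_image(shifted_histogram(spec$reference, b),
                             spec$height, spec$width)
        mask <- NULL
        if (arm == "treated") {
          cl <- add_clusters(gray, spec$n_clusters, spec$radius_px,
                             spec$intensity_offset)
          gray <- cl$grid
          mask <- cl$mask
        }
        list(b = b, gray = gray, mask = mask)
      })
      px <- array(0L, dim = c(spec$height, spec$width, 3L))
      for (c in 1:3) px[, , c] <- tint_channel(res$gray, tint[c])
      images[[arm]][[i]] <- image_array(px,
        source_id = sprintf("%s_%02d", arm, i))
      shifts[[arm]][i] <- res$b
      if (arm == "treated") masks[[i]] <- res$mask
    }
  }
  structure(list(treated = images$treated, control = images$control,
                 truth = list(reference = spec$reference,
                              reference_by_channel =
                                channel_references(spec$reference,
                                                   spec$staining),
                              shifts = shifts, cluster_masks = masks,
                              spec = spec)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  sp <- x$truth$spec
  cat(sprintf("<synthetic_study> %s staining, %d + %d images of %d x %d\n",
              sp$staining, length(x$treated), length(x$control),
              sp$height, sp$width))
  invisible(x)
}

rle_encode <- function(mask) {
  r <- rle(as.vector(mask))
  list(lengths = r$lengths, values = as.logical(r$values),
       dim = dim(mask))
}

#' Write a synthetic study to disk as a two-directory image layout
#'
#' Creates `treated/` and `control/` sub-directories of PNG images plus a
#' `truth.json` manifest (realized shifts, run-length-encoded cluster
#' masks, reference histograms), so the analysis pipeline can consume the
#' study exactly like real data.
#'
#' @param study A [generate_study] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  for (arm in c("treated", "control")) {
    d <- file.path(dir, arm)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (img in study[[arm]]) {
      png::writePNG(unclass(img) / 255,
                    file.path(d, paste0(attr(img, "source_id"), ".png")))
    }
  }
  truth <- study$truth
  manifest <- list(
    staining = truth$spec$staining,
    shifts = truth$shifts,
    reference = as.numeric(truth$reference),
    reference_by_channel = lapply(truth$reference_by_channel, as.numeric),
    cluster_masks = lapply(truth$cluster_masks, rle_encode),
    spec = truth$spec[c("n_images_per_arm", "height", "width", "shift_sigma",
                        "n_clusters", "radius_px", "intensity_offset",
                        "seed")])
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
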