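test_that("logit shift of a histogram has its closed form", {
  ref <- hist_from(c(`0` = 0.5, `1` = 0.5))
  expect_equal(as.numeric(shifted_histogram(ref, 0)), as.numeric(ref))

  s <- shifted_histogram(ref, log(3))
  expect_equal(as.numeric(s)[1:2], c(0.25, 0.75), tolerance = 1e-12)

  # b -> +Inf limit: mass at bin 0 goes to zero
  far <- shifted_histogram(ref, 30)
  expect_lt(as.numeric(far)[1], 1e-12)

  # shifting acts additively on the log-odds (the model's definition)
  r2 <- reference_histogram()
  b <- 0.7
  rho0 <- logit_transform(r2)
  rho1 <- logit_transform(shifted_histogram(r2, b))
  expect_equal(as.numeric(rho1), as.numeric(rho0) + b, tolerance = 1e-10)

  expect_error(shifted_histogram(point_mass(5), 1), "g = 0")
})

test_that("pixel sampling is deterministic and distributionally correct", {
  pm <- point_mass(42)
  expect_true(all(sample_image(pm, 5, 7, seed = 1) == 42L))

  g1 <- sample_image(reference_histogram(), 16, 16, seed = 9)
  g2 <- sample_image(reference_histogram(), 16, 16, seed = 9)
  expect_identical(g1, g2)

  # binomial sampling bound on 1e5 pixels from a two-bin histogram
  h <- hist_from(c(`0` = 0.3, `128` = 0.7))
  grid <- sample_image(h, 250, 400, seed = 5)
  n <- length(grid)
  f0 <- mean(grid == 0L)
  expect_lt(abs(f0 - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  expect_true(all(grid %in% c(0L, 128L)))
})

test_that("cluster discs match a brute-force geometric oracle", {
  base <- matrix(100L, 40, 40)
  res <- add_clusters(base, n_clusters = 0)
  expect_identical(res$grid, base)
  expect_false(any(res$mask))

  res1 <- add_clusters(base, n_clusters = 1, radius_px = 3,
                       intensity_offset = 50L, seed = 17)
  expect_true(all(res1$grid[res1$mask] == 150L))
  expect_true(all(res1$grid[!res1$mask] == 100L))

  # brute-force distance check: the mask must be the (boundary-clipped)
  # disc of radius 3 around some pixel center; scan every candidate
  disc_at <- function(cy, cx)
    outer(1:40, 1:40, function(r, c) (r - cy)^2 + (c - cx)^2 <= 9)
  hits <- 0L
  for (cy in 1:40) for (cx in 1:40)
    if (identical(unname(res1$mask), unname(disc_at(cy, cx)))) hits <- hits + 1L
  expect_gte(hits, 1L)

  # entropy can only grow when a constant region maps into a new bin
  before <- shannon_entropy(to_probability(count_intensities(base)))
  after <- shannon_entropy(to_probability(count_intensities(res1$grid)))
  expect_gte(after, before)

  expect_error(add_clusters(matrix(0L, 5, 5), radius_px = 4), "too large")
})

test_that("study generation is deterministic and honors the null spec", {
  spec <- synthetic_study_spec(n_images_per_arm = 2, height = 12, width = 12,
                               seed = 99)
  s1 <- generate_study(spec)
  s2 <- generate_study(spec)
  expect_identical(s1, s2)
  expect_length(s1$treated, 2)
  expect_length(s1$control, 2)
  expect_true(all(is.finite(unlist(s1$truth$shifts))))

  # pure null: no shift, no clusters
  null_spec <- synthetic_study_spec(n_images_per_arm = 2, height = 12,
                                    width = 12, shift_sigma = 0,
                                    n_clusters = 0, seed = 4)
  ns <- generate_study(null_spec)
  expect_true(all(unlist(ns$truth$shifts) == 0))
  expect_true(all(vapply(ns$truth$cluster_masks,
                         function(m) !any(m), logical(1))))

  # enlarging an arm leaves earlier images untouched (counter-based seeds)
  bigger <- generate_study(synthetic_study_spec(n_images_per_arm = 4,
                                                height = 12, width = 12,
                                                seed = 99))
  expect_identical(unclass(bigger$treated[[1]]), unclass(s1$treated[[1]]))
  expect_identical(unclass(bigger$control[[2]]), unclass(s1$control[[2]]))
})

test_that("per-channel reference truths are the tint pushforwards", {
  ref <- reference_histogram()
  refs <- channel_references(ref, "S")
  expect_named(refs, c("gray", "red", "green", "blue"))
  # S tint leaves the red channel untinted (factor 1.0)
  expect_equal(as.numeric(refs$red), as.numeric(ref), tolerance = 1e-12)
  for (h in refs) expect_s3_class(h, "prob_histogram")

  # a generated arm's red-channel tallies follow the red reference
  spec <- synthetic_study_spec(staining = "S", n_images_per_arm = 6,
                               height = 48, width = 48, shift_sigma = 0,
                               n_clusters = 0, seed = 21)
  st <- generate_study(spec)
  pooled <- pool_counts(lapply(st$control, function(img)
    count_intensities(extract_channel(img, "red"), channel = "red")))
  expect_lt(hellinger(mle_histogram(pooled), refs$red), 0.1)
})

test_that("MLE recovery improves with ensemble size under fixed shifts", {
  # Hellinger(estimate, reference) for pooled arms of 2 vs 8 images
  mean_dist <- function(n_images) {
    ds <- vapply(1:8, function(s) {
      spec <- synthetic_study_spec(n_images_per_arm = n_images, height = 32,
                                   width = 32, shift_sigma = 0.5,
                                   n_clusters = 0, seed = 1000 + s)
      st <- generate_study(spec)
      pooled <- pool_counts(lapply(st$control, function(img)
        count_intensities(extract_channel(img, "red"), channel = "red")))
      hellinger(mle_histogram(pooled),
                st$truth$reference_by_channel$red)
    }, numeric(1))
    mean(ds)
  }
  expect_lt(mean_dist(8), mean_dist(2))
})

test_that("written studies round-trip through the image reader and manifest", {
  dir <- tempfile("study")
  st <- simulate_study(dir, staining = "M", n_images_per_arm = 2,
                       height = 16, width = 16, seed = 7)
  expect_length(list.files(file.path(dir, "treated"), pattern = "png$"), 2)
  expect_length(list.files(file.path(dir, "control"), pattern = "png$"), 2)

  back <- read_image(file.path(dir, "control", "control_01.png"))
  expect_equal(unclass(back), unclass(st$control[[1]]), ignore_attr = TRUE)

  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  expect_equal(truth$shifts$treated, st$truth$shifts$treated,
               tolerance = 1e-12)
  expect_equal(truth$reference, as.numeric(st$truth$reference),
               tolerance = 1e-12)
  m1 <- truth$cluster_masks[[1]]
  expect_equal(sum(m1$lengths[m1$values]), sum(st$truth$cluster_masks[[1]]))
})
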