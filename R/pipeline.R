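# End-to-end pipeline over directory-organized image ensembles:
# (i) staining selection (a label), (ii) image reading, (iii) color
# selection, (iv) intensity counting, (v) fixed-shift MLE, (vi) KS
# comparison, (vii) escort construction, (viii) Hellinger / entropy
# analysis. Outputs are numeric TSVs plus one JSON summary per channel.

#' Pipeline run configuration
#'
#' @param treated_dir,control_dir Directories of treated and control arm
#'   images (PNG/JPEG).
#' @param staining Staining label `"H"`, `"S"` or `"M"` (metadata only;
#'   never inferred from pixels).
#' @param channels Channels to analyse, subset of
#'   `c("gray", "red", "green", "blue")`.
#' @param out_dir Output directory.
#' @param beta_min,beta_max,beta_steps Escort-scan grid, see [beta_grid].
#' @param n_eff KS effective-sample-size policy: `"images"` (number of
#'   images per arm, conservative default), `"pixels"` (total pooled pixels
#'   per arm), or a single positive number used for both arms.
#' @param alpha Significance level for the KS decision.
#' @param weights Gray-conversion weights, see [gray_weights].
#' @param log_level `"info"` for per-step messages or `"quiet"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(treated_dir, control_dir, staining = "H",
                       channels = c("gray", "red", "green", "blue"),
                       out_dir = "escort-results",
                       beta_min = -5, beta_max = 5, beta_steps = 101,
                       n_eff = "images", alpha = 0.05,
                       weights = gray_weights(), log_level = "info") {
  if (identical(normalizePath(treated_dir, mustWork = FALSE),
                normalizePath(control_dir, mustWork = FALSE)))
    stop("treated and control directories must be distinct")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  channels <- vapply(channels, match_channel, character(1), USE.NAMES = FALSE)
  if (is.character(n_eff)) n_eff <- match.arg(n_eff, c("images", "pixels"))
  else if (!is.numeric(n_eff) || length(n_eff) != 1L || n_eff <= 0)
    stop("'n_eff' must be \"images\", \"pixels\" or a positive number")
  structure(list(treated_dir = treated_dir, control_dir = control_dir,
                 staining = match.arg(staining, c("H", "S", "M")),
                 channels = channels, out_dir = out_dir,
                 beta_min = beta_min, beta_max = beta_max,
                 beta_steps = beta_steps, n_eff = n_eff, alpha = alpha,
                 weights = gray_weights(weights), log_level = log_level),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Fields are the arguments of [run_config]; values passed through `...`
#' override the file.
#'
#' @param path YAML or JSON configuration file.
#' @param ... Overrides for individual [run_config] arguments.
#' @return A `run_config` object.
#' @export
load_config <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(run_config, cfg)
}

list_images <- function(dir, step) {
  if (!dir.exists(dir)) stop("[", step, "] directory does not exist: ", dir)
  paths <- sort(list.files(dir, pattern = "\\.(png|jpg|jpeg)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(paths) == 0L)
    stop("[", step, "] no PNG/JPEG images found in ", dir)
  paths
}

pipe_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) message(...)
  invisible(NULL)
}

#' Analyse a channel ensemble: counts, pooling, fixed-shift MLE
#'
#' @param images List of [image_array] objects.
#' @param channel Channel name.
#' @param weights Gray weights, see [gray_weights].
#' @return List with `counts` (per image), `pooled`, `mle` (histogram),
#'   `cumulative`.
#' @export
analyze_ensemble <- function(images, channel, weights = gray_weights()) {
  counts <- lapply(images, function(img)
    count_intensities(extract_channel(img, channel, weights),
                      channel = channel, source_id = attr(img, "source_id")))
  pooled <- pool_counts(counts)
  mle <- mle_histogram(pooled)
  list(counts = counts, pooled = pooled, mle = mle,
       cumulative = cumulative(mle))
}

resolve_n_eff <- function(n_eff, pooled) {
  if (is.numeric(n_eff)) n_eff
  else if (n_eff == "pixels") pooled$N_T
  else pooled$n_images
}

#' Run the eight-step comparison pipeline over two image directories
#'
#' For every selected channel this reads both ensembles, pools intensity
#' tallies, computes the fixed-shift MLE histograms, compares the arms with
#' the Kolmogorov-Smirnov test, scans the escort family for Hellinger
#' distance and entropy difference, classifies the Hellinger beta-profile,
#' and writes MLE/cumulative/beta-scan TSVs plus a JSON summary into
#' `config$out_dir`.
#'
#' @param config A [run_config] (or a list of its arguments).
#' @return Invisibly, a named list (one entry per channel) of results:
#'   `ks`, `scan`, `profile`, `darkness`, `summary_treated`,
#'   `summary_control`, and the output file paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  pipe_log(config, "[i] staining: ", config$staining)
  paths <- list(treated = list_images(config$treated_dir, "ii:read-images"),
                control = list_images(config$control_dir, "ii:read-images"))
  images <- lapply(paths, function(p) lapply(p, read_image))
  pipe_log(config, "[ii] read ", length(images$treated), " treated + ",
           length(images$control), " control images")

  grid <- beta_grid(config$beta_min, config$beta_max, config$beta_steps)
  results <- list()
  for (channel in config$channels) {
    pipe_log(config, "[iii] channel: ", channel)
    ens <- lapply(images, analyze_ensemble, channel = channel,
                  weights = config$weights)
    pipe_log(config, "[iv-v] pooled N_T = ", ens$treated$pooled$N_T,
             " (treated), ", ens$control$pooled$N_T, " (control)")

    ks <- ks_compare(ens$treated$mle, ens$control$mle,
                     resolve_n_eff(config$n_eff, ens$treated$pooled),
                     resolve_n_eff(config$n_eff, ens$control$pooled))
    pipe_log(config, "[vi] KS D = ", signif(ks$statistic, 5), ", p = ",
             signif(ks$p_value, 4))

    scan <- beta_scan(ens$treated$mle, ens$control$mle, grid,
                      staining = config$staining, channel = channel)
    profile <- classify_profile(scan$hellinger, scan$beta)
    darkness <- darker_than(ens$treated$cumulative, ens$control$cumulative)
    pipe_log(config, "[vii-viii] profile: ", profile$class,
             ", darkness: ", darkness)

    tag <- paste0(config$staining, "_", channel)
    files <- c(
      mle_treated = write_mle_tsv(ens$treated$pooled,
        file.path(config$out_dir, paste0("mle_treated_", tag, ".tsv"))),
      mle_control = write_mle_tsv(ens$control$pooled,
        file.path(config$out_dir, paste0("mle_control_", tag, ".tsv"))),
      cumulative_treated = write_cumulative_tsv(ens$treated$cumulative,
        file.path(config$out_dir, paste0("cumulative_treated_", tag, ".tsv"))),
      cumulative_control = write_cumulative_tsv(ens$control$cumulative,
        file.path(config$out_dir, paste0("cumulative_control_", tag, ".tsv"))),
      beta_scan = write_beta_scan_tsv(scan,
        file.path(config$out_dir, paste0("beta_scan_", tag, ".tsv"))))

    summary <- list(
      staining = config$staining, channel = channel,
      n_images = list(treated = length(images$treated),
                      control = length(images$control)),
      n_pixels = list(treated = ens$treated$pooled$N_T,
                      control = ens$control$pooled$N_T),
      ks = list(statistic = ks$statistic, p_value = ks$p_value,
                n_eff_1 = ks$n_eff_1, n_eff_2 = ks$n_eff_2,
                alpha = config$alpha,
                significant = ks$p_value <= config$alpha),
      profile = list(class = profile$class,
                     argmax_beta = profile$argmax_beta),
      darkness = darkness,
      treated = summarize_histogram(ens$treated$mle),
      control = summarize_histogram(ens$control$mle),
      hellinger_beta1 = scan$hellinger[scan$beta == 1],
      delta_entropy_beta1 = scan$delta_entropy[scan$beta == 1],
      config = config[c("beta_min", "beta_max", "beta_steps", "n_eff",
                        "alpha", "weights")])
    summary_path <- file.path(config$out_dir, paste0("summary_", tag, ".json"))
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    results[[channel]] <- list(ks = ks, scan = scan, profile = profile,
                               darkness = darkness, summary = summary,
                               files = c(files, summary = summary_path))
  }
  invisible(results)
}

#' Generate a synthetic study and write it to disk
#'
#' Thin wrapper composing [synthetic_study_spec], [generate_study] and
#' [write_study] for shell use.
#'
#' @param dir Output directory.
#' @param ... Arguments of [synthetic_study_spec].
#' @return Invisibly, the generated study.
#' @export
simulate_study <- function(dir, ...) {
  study <- generate_study(synthetic_study_spec(...))
  write_study(study, dir)
  invisible(study)
}

#' Compare two pre-tabulated histograms from TSV files
#'
#' Runs the comparison stage only (KS, beta scan, profile, darkness) on
#' histograms already tabulated as TSV (columns `g` and `count` or `prob`,
#' as written by [write_histogram_tsv]).
#'
#' @param treated_tsv,control_tsv Histogram TSV paths.
#' @param out_dir Optional output directory for the beta-scan TSV and JSON
#'   summary; if `NULL`, nothing is written.
#' @param n_eff_1,n_eff_2 Effective sample sizes for the KS test.
#' @param grid Beta grid, see [beta_grid].
#' @param alpha Significance level.
#' @return List with `ks`, `scan`, `profile`, `darkness`.
#' @export
compare_histogram_files <- function(treated_tsv, control_tsv, out_dir = NULL,
                                    n_eff_1, n_eff_2, grid = beta_grid(),
                                    alpha = 0.05) {
  p <- read_histogram_tsv(treated_tsv)
  q <- read_histogram_tsv(control_tsv)
  ks <- ks_compare(p, q, n_eff_1, n_eff_2)
  scan <- beta_scan(p, q, grid)
  profile <- classify_profile(scan$hellinger, scan$beta)
  darkness <- darker_than(cumulative(p), cumulative(q))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_beta_scan_tsv(scan, file.path(out_dir, "beta_scan.tsv"))
    jsonlite::write_json(
      list(ks = list(statistic = ks$statistic, p_value = ks$p_value,
                     n_eff_1 = ks$n_eff_1, n_eff_2 = ks$n_eff_2,
                     alpha = alpha, significant = ks$p_value <= alpha),
           profile = list(class = profile$class,
                          argmax_beta = profile$argmax_beta),
           darkness = darkness),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  list(ks = ks, scan = scan, profile = profile, darkness = darkness)
}
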