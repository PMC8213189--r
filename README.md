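# escortHist

Statistical comparison of two ensembles of stained-histology microscopy
images — a medically treated arm against a control arm — through their
intensity histograms. The package is aimed at image-analysis practitioners
who want a global, examiner-independent check on whether a treatment
changed the appearance of histological sections, and at which intensity
ranges the change lives.

## The method

Every 8-bit image channel (gray, R, G or B) yields a histogram `p_g`,
`g = 0, …, 255`. Staining intensity varies from section to section, so the
per-image histograms are modelled with a **fixed-shift model**: each
image's log-odds profile `ρ_g = ln p_g − ln p_0` equals a common group
profile plus an image-specific constant `b_i`. Under this model the pooled
ensemble counts `d_g` (total pixels `N_T`) are sufficient, and the maximum
likelihood estimate of the group profile is

    ρ̂_g = ln( d_g / (N_T − d_0) ),      g ≥ 1, d_g > 0,

which normalizes so that Σ exp(ρ̂_g) = 1; the reconstructed group histogram
is `p̂_0 = d_0/N_T`, `p̂_g = (1 − p̂_0)·exp(ρ̂_g)`.

The two arms' estimated histograms are compared three ways:

1. **Kolmogorov–Smirnov test** on the cumulative distributions
   `F_g = Σ_{h<g} p_h` (effective sample size is an explicit choice:
   images, pixels, or a number you supply).
2. **Escort scan of the Hellinger distance.** The escort family
   `P_g(β) ∝ p_g^β` re-weights the histogram — β > 1 accentuates common
   intensities, β < 1 rare ones. Scanning
   `H(β) = Hellinger(P(β), Q(β))` locates the intensity groups that drive
   the difference; `H(0) = 0` for equal supports and `H(1)` is the distance
   of the original estimates. Profiles are classified as monotone growth,
   flat, or non-monotone with a reported argmax β.
3. **Shannon-entropy difference** `ΔS(β) = S(treated) − S(control)` of the
   escort histograms; a positive ΔS flags intensity mass spreading into
   extra bins, the histogram signature of cell-cluster formation during
   cartilage repair.

A synthetic study generator (`simulate_study()`) emulates exactly this
structure — shared reference histogram, per-image logit shifts, treated-arm
cluster discs — with full ground truth, for calibration and
parameter-recovery experiments.

## Worked example

```r
library(escortHist)

dir <- file.path(tempdir(), "demo")
simulate_study(dir, staining = "S", n_images_per_arm = 8,
               height = 64, width = 64, seed = 1)

res <- run_pipeline(run_config(
  file.path(dir, "treated"), file.path(dir, "control"),
  staining = "S", channels = "gray",
  out_dir = file.path(dir, "out"), log_level = "quiet"))

res$gray$ks
#> <ks_result> D = 0.03922, p = 1 (n_eff = 8, 8)
res$gray$profile
#> <profile_class> non_monotonic (argmax beta = -5)
res$gray$summary$hellinger_beta1
#> [1] 0.09251...
res$gray$summary$delta_entropy_beta1
#> [1] 0.1188...
```

The KS statistic `D = 0.039` is the largest vertical gap between the two
arms' cumulative intensity distributions; at the conservative image-level
effective sample size (8 vs 8) it is far from significant. The Hellinger
distance of the estimated histograms is `H(1) = 0.093`, and the positive
entropy difference `ΔS(1) = 0.119` nats reflects the treated arm's cluster
discs pushing intensity mass into otherwise-empty bins. Per-channel TSVs
(MLE histograms, cumulative curves, β-scans) and a JSON summary land in
`out/`.

A command-line wrapper with `analyze`, `simulate` and
`compare-histograms` subcommands is installed at
`inst/scripts/escorthist.R`.

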