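#' Platform noise/analysis profiles
#'
#' Two profiles emulate the study's sequencing platforms. Profile A is
#' MiSeq/VeriSeq-like: 0.9 Mb bins, ~750k total reads with 75% passing
#' filter, Gaussian-PDF state calling, and a validated mosaicism
#' detection band of +/-0.15 copies around the euploid baseline (limit
#' of detection 20%). Profile B is Ion PGM/ReproSeq-like: 1.0 Mb bins,
#' ~600k total reads, chromosome-read-fraction calling against a
#' baseline of 11 normal samples, a wider band of +/-0.25 copies (limit
#' of detection 30%), and higher per-bin WGA jitter.
#'
#' The WGA jitter is the sigma of a per-bin lognormal amplification
#' factor at the 10-cell biopsy scale; it shrinks with sqrt(10 /
#' cell_count), so 100-cell reconstructions are quieter. The
#' `chrom_cn_sd_target` is the pooled per-chromosome copy-number SD the
#' generator is calibrated to produce on euploid replicates (the
#' multinomial counting floor on the smallest autosome dominates it);
#' `range_k` is the euploid-range multiplier applied to that pooled SD,
#' chosen so the band sits midway between the last undetectable and the
#' first detectable mixture level of the study design.
#'
#' @param name "profileA" (or "A") or "profileB" (or "B").
#' @return object of class `platform_profile`.
#' @export
platform_profile <- function(name = c("profileA", "profileB", "A", "B")) {
  name <- match.arg(name)
  name <- if (name %in% c("A", "profileA")) "profileA" else "profileB"
  p <- if (name == "profileA") {
    list(
      name = "profileA",
      total_reads = 750000L,
      pf_fraction = 0.75,
      bin_size_bp = 900000L,
      wga_jitter_sd = 0.05,
      gc_bias_amp = 0.15,
      chrom_cn_sd_target = 0.016,
      range_k = 9,
      y_zero_tol = 0.05,
      min_run = 4L,
      seg_range_k = 3,
      baseline_n = NA_integer_,
      caller = "gaussian"
    )
  } else {
    list(
      name = "profileB",
      total_reads = 600000L,
      pf_fraction = 0.75,
      bin_size_bp = 1000000L,
      wga_jitter_sd = 0.08,
      gc_bias_amp = 0.20,
      chrom_cn_sd_target = 0.023,
      range_k = 11,
      y_zero_tol = 0.05,
      min_run = 5L,
      seg_range_k = 3,
      baseline_n = 11L,
      caller = "baseline"
    )
  }
  structure(p, class = "platform_profile")
}

#' @export
print.platform_profile <- function(x, ...) {
  cat(sprintf(
    "<platform_profile %s> reads=%d (pf %.0f%%), bin=%.1f Mb, jitter sd=%.2f,\n  caller=%s, euploid band=+/-%.3f CN, min_run=%d\n",
    x$name, x$total_reads, 100 * x$pf_fraction, x$bin_size_bp / 1e6,
    x$wga_jitter_sd, x$caller, x$range_k * x$chrom_cn_sd_target, x$min_run
  ))
  invisible(x)
}

#' Multiplicative GC amplification bias
#'
#' Smooth unimodal function of the bin GC fraction with amplitude `amp`,
#' peaking at GC 0.45 (the middle of the synthetic GC range). It is the
#' bias the normalizer must remove; `amp = 0` disables it.
#'
#' @param gc numeric GC fractions.
#' @param amp amplitude of the bias (profile `gc_bias_amp`).
#' @return positive multiplicative factors.
#' @export
gc_bias_curve <- function(gc, amp) {
  1 + amp * exp(-((gc - 0.45) / 0.08)^2 / 2)
}

#' Mosaicism-run configuration
#'
#' Bundles everything one validation run needs: master seed, the two
#' platform profiles, design options and calibration sizes. Round-trips
#' through YAML via [write_config_yaml()] / [read_config_yaml()].
#'
#' @param master_seed integer master seed; all per-sample seeds derive
#'   from it via [derive_seed()].
#' @param profiles list of [platform_profile()] objects.
#' @param design_cell_count cells per reconstructed biopsy in the
#'   120-sample concordance design (10 in the study).
#' @param curve_cell_count cells per sample for the reference-curve set
#'   (100 in the study).
#' @param replicates_per_level mosaic replicates per mixture level and
#'   set (6, so that 9 levels x 6 = 54 mosaics per set).
#' @param calibration_n euploid samples used to calibrate the euploid
#'   range per profile.
#' @param alpha significance level of the limit-of-detection t-tests.
#' @return object of class `run_config`.
#' @export
run_config <- function(master_seed = 42L,
                       profiles = list(platform_profile("A"),
                                       platform_profile("B")),
                       design_cell_count = 10L,
                       curve_cell_count = 100L,
                       replicates_per_level = 6L,
                       calibration_n = 30L,
                       alpha = 0.05) {
  structure(
    list(
      master_seed = as.integer(master_seed),
      profiles = profiles,
      design_cell_count = as.integer(design_cell_count),
      curve_cell_count = as.integer(curve_cell_count),
      replicates_per_level = as.integer(replicates_per_level),
      calibration_n = as.integer(calibration_n),
      alpha = alpha
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  out <- unclass(config)
  out$profiles <- lapply(config$profiles, unclass)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  profiles <- lapply(raw$profiles, function(p) {
    structure(p, class = "platform_profile")
  })
  run_config(
    master_seed = raw$master_seed,
    profiles = profiles,
    design_cell_count = raw$design_cell_count,
    curve_cell_count = raw$curve_cell_count,
    replicates_per_level = raw$replicates_per_level,
    calibration_n = raw$calibration_n,
    alpha = raw$alpha
  )
}
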