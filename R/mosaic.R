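#' Calibrate a euploid range from replicate CN values
#'
#' The mean and SD of chromosome CN estimates across euploid replicates
#' define the euploidy range, mean +/- k * SD; any CN falling outside it
#' is scored mosaic. This is the single-chromosome primitive; whole-
#' platform calibration across all chromosomes is
#' [calibrate_platform()].
#'
#' @param values numeric CN estimates from euploid replicates (>= 5).
#' @param k range multiplier.
#' @return object of class `euploid_range`: `mean`, `sd`, `k`, `lower`,
#'   `upper`.
#' @export
calibrate_euploid_range <- function(values, k = 3) {
  if (length(values) < 5) {
    stop("euploid-range calibration needs at least 5 replicate values",
         call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("degenerate calibration: zero variance across replicates",
         call. = FALSE)
  }
  m <- mean(values)
  structure(
    list(mean = m, sd = s, k = k, lower = m - k * s, upper = m + k * s),
    class = "euploid_range"
  )
}

#' Platform-wide euploid calibration
#'
#' Runs the platform's CN estimation over a set of euploid samples and
#' summarizes, per chromosome, the replicate mean and SD, plus the
#' pooled autosomal SD. The mosaicism band is `range_k` x pooled SD
#' around each chromosome's own euploid mean (so per-chromosome
#' normalization or baseline bias is absorbed into the center while the
#' band width stays platform-wide, as a single validated cutoff). The
#' per-chromosome SDs are retained for diagnostics.
#'
#' @param euploid_samples list of euploid `bincounts` (>= 5).
#' @param profile the [platform_profile()].
#' @param bins the bin grid.
#' @param baseline `baseline_caller_config` for profile B.
#' @return object of class `platform_calibration`: `mean` and `sd`
#'   (named per-chromosome vectors), `pooled_sd`, `band`
#'   (= range_k * pooled_sd), `range_k`, `y_zero_tol`, `n`.
#' @export
calibrate_platform <- function(euploid_samples, profile, bins,
                               baseline = NULL) {
  if (length(euploid_samples) < 5) {
    stop("platform calibration needs at least 5 euploid samples",
         call. = FALSE)
  }
  cn <- vapply(euploid_samples, sample_chromosome_cn, numeric(24L),
               profile = profile, bins = bins, baseline = baseline)
  mu <- rowMeans(cn)
  sds <- apply(cn, 1, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate calibration: zero variance on some chromosome",
         call. = FALSE)
  }
  autosome <- !(chrom_names() %in% c("X", "Y"))
  pooled <- sqrt(mean(sds[autosome]^2))
  structure(
    list(mean = mu, sd = sds, pooled_sd = pooled,
         band = profile$range_k * pooled, range_k = profile$range_k,
         y_zero_tol = profile$y_zero_tol,
         n = length(euploid_samples)),
    class = "platform_calibration"
  )
}

#' Classify one chromosome call against a euploid range
#'
#' Inside the range: disomic. Outside on the gain side: mosaic-gain up
#' to half a copy above the expected baseline, full-gain beyond (2.5 for
#' an autosome); symmetric for losses (full-loss at or below 1.5 for an
#' autosome). `expected_cn` defaults to 2 (autosome); pass 1 for the
#' sex chromosomes of a male-referenced assay.
#'
#' @param call a `chromosome_call`, or a bare CN estimate.
#' @param range a [calibrate_euploid_range()] result, or any list with
#'   `lower`/`upper`.
#' @param expected_cn baseline copy number the categories are relative
#'   to (2 autosomes, 1 X/Y).
#' @return one of "disomic", "mosaic-gain", "mosaic-loss", "full-gain",
#'   "full-loss".
#' @export
classify_chromosome <- function(call, range, expected_cn = 2) {
  cn <- if (inherits(call, "chromosome_call")) call$cn_estimate else call
  if (is.na(cn)) {
    return(NA_character_)
  }
  full_margin <- 0.5 * expected_cn / 2
  if (cn >= range$lower && cn <= range$upper) {
    "disomic"
  } else if (cn > range$upper) {
    if (cn >= expected_cn + full_margin) "full-gain" else "mosaic-gain"
  } else {
    if (cn <= expected_cn - full_margin) "full-loss" else "mosaic-loss"
  }
}

#' Classify all 24 chromosomes of a sample
#'
#' Autosomes are scored against their calibrated euploid means with the
#' platform band. The sex chromosomes are scored jointly, because a
#' normal female complement must not be mistaken for aneuploidy against
#' the male-referenced baselines: the (X, Y) pair is disomic when it is
#' consistent with a normal male (both within the platform band of
#' their euploid means) or with a normal female - X within the band of
#' one copy above its euploid mean AND Y consistent with zero
#' (`y_zero_tol`, i.e. no Y material beyond background; an XY/XX
#' mixture retains a clear residual Y signal of 1 - f, which is what
#' separates 90% mosaicism from a pure XX line). Otherwise X and Y are
#' classified against their male-reference baselines with the platform
#' band, so sex-chromosome mosaicism (X between 1 and 2) is flagged.
#'
#' @param cn named CN vector from [sample_chromosome_cn()].
#' @param calib a [calibrate_platform()] result.
#' @return named character vector of categories over the 24 chromosomes.
#' @export
classify_chromosomes <- function(cn, calib) {
  stopifnot(inherits(calib, "platform_calibration"))
  out <- stats::setNames(character(24L), chrom_names())
  for (ch in setdiff(chrom_names(), c("X", "Y"))) {
    rng <- list(lower = calib$mean[[ch]] - calib$band,
                upper = calib$mean[[ch]] + calib$band)
    out[[ch]] <- classify_chromosome(cn[[ch]], rng, expected_cn = 2)
  }
  x <- cn[["X"]]; y <- cn[["Y"]]
  male_ok <- abs(x - calib$mean[["X"]]) <= calib$band &&
    abs(y - calib$mean[["Y"]]) <= calib$band
  female_ok <- abs(x - (calib$mean[["X"]] + 1)) <= calib$band &&
    y <= calib$y_zero_tol
  if (male_ok || female_ok) {
    out[c("X", "Y")] <- "disomic"
  } else {
    for (ch in c("X", "Y")) {
      rng <- list(lower = calib$mean[[ch]] - calib$band,
                  upper = calib$mean[[ch]] + calib$band)
      out[[ch]] <- classify_chromosome(cn[[ch]], rng, expected_cn = 1)
    }
  }
  out
}

#' Sample-level ploidy classification
#'
#' All chromosomes disomic: euploid. Any full gain/loss and no mosaic:
#' aneuploid. Any mosaic and no full: mosaic (the study's
#' diploid-aneuploid-mosaic category). Both: "mosaic-aneuploid".
#'
#' @param categories per-chromosome categories from
#'   [classify_chromosomes()] (24 values).
#' @return list with `category` and `offending` (non-disomic
#'   chromosomes).
#' @export
classify_sample <- function(categories) {
  if (length(categories) != 24L) {
    stop("expected 24 chromosome categories", call. = FALSE)
  }
  full <- grepl("^full", categories)
  mosaic <- grepl("^mosaic", categories)
  category <- if (!any(full) && !any(mosaic)) {
    "euploid"
  } else if (any(full) && !any(mosaic)) {
    "aneuploid"
  } else if (any(mosaic) && !any(full)) {
    "mosaic"
  } else {
    "mosaic-aneuploid"
  }
  list(category = category,
       offending = names(categories)[full | mosaic])
}

#' Reference curve: mean CN vs mosaic fraction
#'
#' Per mixture level, the mean +/- SD of the CN estimates of a
#' chromosome of interest across replicates.
#'
#' @param df data frame with columns `level` and `cn` (one row per
#'   replicate), e.g. assembled from design results.
#' @return data frame of class `reference_curve`: level, mean_cn, sd,
#'   n, ordered by level.
#' @export
build_reference_curve <- function(df) {
  stopifnot(all(c("level", "cn") %in% names(df)))
  agg <- do.call(rbind, lapply(split(df, df$level), function(g) {
    data.frame(level = g$level[1], mean_cn = mean(g$cn),
               sd = stats::sd(g$cn), n = nrow(g))
  }))
  agg <- agg[order(agg$level), ]
  rownames(agg) <- NULL
  if (any(agg$n < 2)) {
    stop("reference curve needs >= 2 replicates per level", call. = FALSE)
  }
  class(agg) <- c("reference_curve", "data.frame")
  agg
}

#' Limit-of-detection determination
#'
#' For each mixture level, the replicate CN estimates of the chromosome
#' of interest are compared with the euploid replicates by a two-sample
#' two-tailed Welch t-test (per-comparison alpha, no multiplicity
#' correction), and the level's mean CN is compared with the calibrated
#' euploid range. The default detection rule requires both: a level is
#' detected when its mean CN falls outside the euploidy range AND the
#' t-test is significant - the range carries the platform's validated
#' cutoff while the t-test guards against levels whose shift is not
#' statistically supported. The LOD is the smallest detected level such
#' that every larger level is also detected. `method = "ttest"` uses
#' significance alone; `method = "range"` the range alone.
#'
#' @param level_values named list: for each level (names "0.1"..."1"),
#'   the replicate CN estimates (>= 3 each).
#' @param euploid_values CN estimates of the euploid replicates (>= 3).
#' @param range a euploid range (anything with `lower`/`upper`) for the
#'   chromosome of interest.
#' @param alpha significance level (0.05).
#' @param method detection rule (see above).
#' @return object of class `lod_result`: data frame `levels` (level,
#'   mean_cn, p_value, outside_range, significant, detected) plus `lod`
#'   (numeric, NA when undefined) and `alpha`.
#' @export
determine_lod <- function(level_values, euploid_values, range,
                          alpha = 0.05,
                          method = c("range+ttest", "ttest", "range")) {
  method <- match.arg(method)
  if (length(euploid_values) < 3) {
    stop("LOD determination needs >= 3 euploid replicates", call. = FALSE)
  }
  if (any(vapply(level_values, length, 0L) < 3)) {
    stop("LOD determination needs >= 3 replicates per level", call. = FALSE)
  }
  levels <- as.numeric(names(level_values))
  ord <- order(levels)
  levels <- levels[ord]
  level_values <- level_values[ord]
  rows <- lapply(seq_along(levels), function(i) {
    vals <- level_values[[i]]
    p <- tryCatch(
      stats::t.test(vals, euploid_values, var.equal = FALSE)$p.value,
      error = function(e) NA_real_
    )
    m <- mean(vals)
    outside <- m < range$lower || m > range$upper
    sig <- !is.na(p) && p < alpha
    detected <- switch(method,
      "range+ttest" = outside && sig,
      "ttest" = sig,
      "range" = outside
    )
    data.frame(level = levels[i], mean_cn = m, p_value = p,
               outside_range = outside, significant = sig,
               detected = detected)
  })
  tab <- do.call(rbind, rows)
  lod <- NA_real_
  for (i in seq_len(nrow(tab))) {
    if (all(tab$detected[i:nrow(tab)])) {
      lod <- tab$level[i]
      break
    }
  }
  structure(list(levels = tab, lod = lod, alpha = alpha, method = method),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> method=%s alpha=%.2f lod=%s\n", x$method,
              x$alpha, format(x$lod)))
  print(x$levels, row.names = FALSE)
  invisible(x)
}
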