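#' Configuration of the Gaussian copy-number state caller
#'
#' The profile-A caller scores each bin's CN against the integer states
#' 0-4 with a Gaussian likelihood of fixed standard deviation 0.33,
#' averages the normalized per-bin state posteriors over a chromosome,
#' and takes the top state - unless the ambiguity rule routes the call
#' through the median fallback: the median of the per-bin most-likely
#' states, declared a gain when > 2.5 and a loss when < 1.5 (strict
#' inequalities, so a median of exactly 2.5 stays disomic).
#'
#' The printed fallback condition triggers when the distance between the
#' two top state scores EXCEEDS 0.011, i.e. on unambiguous chromosomes -
#' which reads backwards (a wide margin should not need a fallback) but
#' is implemented literally by default; `literal_fallback_rule = FALSE`
#' inverts it so the fallback handles the ambiguous calls instead. On
#' clean integer-state data the two modes give identical calls.
#'
#' @param states integer copy states scored (0..4).
#' @param sigma Gaussian likelihood SD (0.33).
#' @param ambiguity_distance score-difference threshold (0.011, on the
#'   normalized-posterior scale).
#' @param gain_median_threshold,loss_median_threshold fallback
#'   thresholds on the median state (2.5 / 1.5).
#' @param literal_fallback_rule use the condition exactly as printed
#'   (default TRUE).
#' @return object of class `gaussian_caller_config`.
#' @export
gaussian_caller_config <- function(states = 0:4, sigma = 0.33,
                                   ambiguity_distance = 0.011,
                                   gain_median_threshold = 2.5,
                                   loss_median_threshold = 1.5,
                                   literal_fallback_rule = TRUE) {
  stopifnot(sigma > 0, loss_median_threshold < gain_median_threshold)
  structure(
    list(states = states, sigma = sigma,
         ambiguity_distance = ambiguity_distance,
         gain_median_threshold = gain_median_threshold,
         loss_median_threshold = loss_median_threshold,
         literal_fallback_rule = literal_fallback_rule),
    class = "gaussian_caller_config"
  )
}

#' Gaussian-PDF chromosome call
#'
#' @param np a `norm_profile` from [gc_normalize()].
#' @param chrom chromosome to call.
#' @param cfg a [gaussian_caller_config()].
#' @param min_bins minimum unmasked bins required (no-call below it).
#' @return object of class `chromosome_call`: `chrom`, `cn_estimate`
#'   (mean bin CN, always reported for mosaic quantitation), `state`
#'   (integer 0-4), `label` ("gain"/"loss"/"disomic" relative to state
#'   2), `call_path` ("pdf" or "median-fallback"), `state_scores`.
#' @export
call_chromosome_gaussian <- function(np, chrom, cfg = gaussian_caller_config(),
                                     min_bins = 5L) {
  cn <- np$cn[np$chrom == chrom & !np$masked]
  if (length(cn) < min_bins) {
    return(structure(
      list(chrom = chrom, cn_estimate = NA_real_, state = NA_integer_,
           label = "no-call", call_path = "no-call", state_scores = NULL),
      class = "chromosome_call"
    ))
  }
  dens <- vapply(cfg$states, function(s) stats::dnorm(cn, s, cfg$sigma),
                 numeric(length(cn)))
  post <- dens / pmax(rowSums(dens), .Machine$double.xmin)
  scores <- colMeans(post)
  names(scores) <- as.character(cfg$states)
  ord <- order(scores, decreasing = TRUE)
  margin <- scores[ord[1]] - scores[ord[2]]
  fallback <- if (cfg$literal_fallback_rule) {
    margin > cfg$ambiguity_distance
  } else {
    margin <= cfg$ambiguity_distance
  }
  if (fallback) {
    med <- stats::median(cfg$states[max.col(post, ties.method = "first")])
    state <- as.integer(round(med))
    label <- if (med > cfg$gain_median_threshold) {
      "gain"
    } else if (med < cfg$loss_median_threshold) {
      "loss"
    } else {
      "disomic"
    }
    if (label == "disomic") state <- 2L
    path <- "median-fallback"
  } else {
    state <- as.integer(cfg$states[ord[1]])
    label <- if (state > 2) "gain" else if (state < 2) "loss" else "disomic"
    path <- "pdf"
  }
  structure(
    list(chrom = chrom, cn_estimate = mean(cn), state = state, label = label,
         call_path = path, state_scores = scores),
    class = "chromosome_call"
  )
}

#' Build the chromosome-fraction baseline
#'
#' The profile-B reference: per-chromosome mean fraction of mapped reads
#' across a series of euploid samples (11 normals in the study).
#'
#' @param reference_samples list of euploid `bincounts` (>= 2).
#' @param bins the bin grid.
#' @return object of class `baseline_caller_config` with `baseline`
#'   (fractions summing to 1), `n`, and the printed discrete thresholds
#'   `gain_threshold` (CN > 3) and `loss_threshold` (CN < 1).
#' @export
build_baseline <- function(reference_samples, bins) {
  if (length(reference_samples) < 2) {
    stop("baseline requires at least 2 euploid reference samples",
         call. = FALSE)
  }
  fracs <- vapply(reference_samples, function(b) {
    chromosome_read_fractions(b, bins)
  }, numeric(24L))
  baseline <- rowMeans(fracs)
  baseline <- baseline / sum(baseline)
  structure(
    list(baseline = baseline, n = length(reference_samples),
         gain_threshold = 3, loss_threshold = 1),
    class = "baseline_caller_config"
  )
}

#' Fraction of reads per chromosome
#'
#' @param b a `bincounts` object (or count vector).
#' @param bins the bin grid.
#' @return named fractions over the 24 chromosomes, summing to 1.
#' @export
chromosome_read_fractions <- function(b, bins) {
  counts <- if (inherits(b, "bincounts")) b$counts else as.numeric(b)
  tot <- tapply(counts, factor(bins$chrom, levels = chrom_names()), sum)
  stats::setNames(as.numeric(tot) / sum(counts), chrom_names())
}

#' Baseline-ratio chromosome call
#'
#' CN estimate is the reference copy state of the chromosome times the
#' ratio of its observed read fraction to the baseline fraction (the
#' paper's percent-reads-per-chromosome method; the reference-CN factor
#' is 2 on autosomes and 1 on X/Y for the male baseline). The discrete
#' whole-chromosome call uses the printed thresholds - gain when CN > 3,
#' loss when CN < 1 - while mosaic detection downstream relies on the
#' calibrated euploid range, never on these.
#'
#' @param b a `bincounts` object.
#' @param cfg a [baseline_caller_config()].
#' @param bins the bin grid.
#' @param chrom chromosome to call.
#' @return a `chromosome_call` with `call_path = "baseline-ratio"`.
#' @export
call_chromosome_baseline <- function(b, cfg, bins, chrom) {
  stopifnot(inherits(cfg, "baseline_caller_config"))
  if (!chrom %in% names(cfg$baseline)) {
    stop("chromosome absent from baseline: ", chrom, call. = FALSE)
  }
  fr <- chromosome_read_fractions(b, bins)
  cn <- unname(reference_cn()[chrom] * fr[chrom] / cfg$baseline[chrom])
  label <- if (cn > cfg$gain_threshold) {
    "gain"
  } else if (cn < cfg$loss_threshold) {
    "loss"
  } else {
    "disomic"
  }
  structure(
    list(chrom = chrom, cn_estimate = cn,
         state = as.integer(pmin(4, pmax(0, round(cn)))), label = label,
         call_path = "baseline-ratio", state_scores = NULL),
    class = "chromosome_call"
  )
}

#' Call all 24 chromosomes of one sample
#'
#' Dispatches on the profile's caller: profile A normalizes the bin
#' counts (GC + in-silico reference) and applies the Gaussian state
#' caller; profile B applies the baseline-ratio caller. Continuous CN
#' estimates are returned for every chromosome for mosaic quantitation.
#'
#' @param b a `bincounts` object.
#' @param profile the [platform_profile()].
#' @param bins the bin grid.
#' @param baseline a `baseline_caller_config` (required for profile B).
#' @param cfg optional [gaussian_caller_config()].
#' @return data frame: sample_id, chrom, cn_estimate, state, label,
#'   call_path.
#' @export
call_sample <- function(b, profile, bins, baseline = NULL,
                        cfg = gaussian_caller_config()) {
  if (profile$caller == "gaussian") {
    np <- gc_normalize(b, insilico_reference(bins, profile), bins)
    calls <- lapply(chrom_names(), function(ch) {
      call_chromosome_gaussian(np, ch, cfg)
    })
  } else {
    if (is.null(baseline)) {
      stop("profile B calling requires a baseline (build_baseline)",
           call. = FALSE)
    }
    calls <- lapply(chrom_names(), function(ch) {
      call_chromosome_baseline(b, baseline, bins, ch)
    })
  }
  data.frame(
    sample_id = b$sample_id,
    chrom = vapply(calls, `[[`, "", "chrom"),
    cn_estimate = vapply(calls, `[[`, numeric(1), "cn_estimate"),
    state = vapply(calls, `[[`, integer(1), "state"),
    label = vapply(calls, `[[`, "", "label"),
    call_path = vapply(calls, `[[`, "", "call_path"),
    stringsAsFactors = FALSE
  )
}

#' Continuous per-chromosome CN estimates for one sample
#'
#' The quantitation path shared by both platforms: mean unmasked bin CN
#' (profile A) or baseline-ratio CN (profile B), as a named vector.
#' The fraction-based estimates are ploidy-recentered so the median
#' autosomal CN is 2 - read fractions are relative, so a genuine copy
#' change on one chromosome compresses every other chromosome's
#' fraction by the genome-mass change (about 3% for a pure trisomic
#' female line against a male baseline); the per-bin path achieves the
#' same recentering through its genome-median scaling.
#'
#' @inheritParams call_sample
#' @return named numeric vector over the 24 chromosomes.
#' @export
sample_chromosome_cn <- function(b, profile, bins, baseline = NULL) {
  if (profile$caller == "gaussian") {
    np <- gc_normalize(b, insilico_reference(bins, profile), bins)
    chromosome_cn(np)
  } else {
    if (is.null(baseline)) {
      stop("profile B requires a baseline", call. = FALSE)
    }
    fr <- chromosome_read_fractions(b, bins)
    cn <- reference_cn() * fr / cfg_baseline(baseline)
    cn * 2 / stats::median(cn[as.character(1:22)])
  }
}

cfg_baseline <- function(baseline) {
  stopifnot(inherits(baseline, "baseline_caller_config"))
  baseline$baseline
}
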