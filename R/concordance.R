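#' Expected per-chromosome status of the 120-sample design
#'
#' The truth table behind the concordance analysis: every (sample,
#' chromosome) slot of the design manifest is expected aneuploid or
#' disomic. Mosaic samples contribute three expected-aneuploid
#' chromosomes (the trisomic autosome plus X and Y, whose copy numbers
#' shift concomitantly in the 46,XY / 47,XX mixtures); full-aneuploid
#' (100%) samples contribute one (the trisomic autosome - their X and Y
#' form a normal female complement); euploid samples none. The full
#' design yields 2880 comparisons: 330 expected aneuploid and 2550
#' expected disomic.
#'
#' @param manifest design manifest from [simulate_design()].
#' @return data frame: sample_id, chrom, expected ("aneuploid" /
#'   "disomic").
#' @export
chromosome_truth_table <- function(manifest) {
  needed <- c("sample_id", "set", "level")
  if (!all(needed %in% names(manifest))) {
    stop("malformed manifest: needs columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  tri <- c(tri21 = "21", tri18 = "18")
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    expected <- rep("disomic", 24L)
    names(expected) <- chrom_names()
    if (row$level > 0 && row$level < 1) {
      expected[c(tri[[row$set]], "X", "Y")] <- "aneuploid"
    } else if (row$level >= 1) {
      expected[tri[[row$set]]] <- "aneuploid"
    }
    data.frame(sample_id = row$sample_id, chrom = chrom_names(),
               expected = unname(expected), level = row$level,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Confusion counts from truth and calls
#'
#' Chromosome level: a positive call is any non-disomic category on that
#' chromosome; TP = expected-aneuploid called positive, TN =
#' expected-disomic called disomic, FN/FP their complements. Sample
#' level: truth positive = mosaic or full-aneuploid sample, call
#' positive = any sample classification other than euploid.
#'
#' @param truth for `level = "chromosome"`: the truth table from
#'   [chromosome_truth_table()]; for `level = "sample"`: data frame
#'   sample_id, expected ("aneuploid"/"euploid").
#' @param calls for `level = "chromosome"`: data frame sample_id, chrom,
#'   category; for `level = "sample"`: data frame sample_id, category.
#' @param level "chromosome" or "sample".
#' @return object of class `confusion_counts`: tp, tn, fp, fn, level,
#'   plus `fn_detail` (the truth rows that were missed).
#' @export
score_concordance <- function(truth, calls, level = c("chromosome", "sample")) {
  level <- match.arg(level)
  if (level == "chromosome") {
    key_t <- paste(truth$sample_id, truth$chrom)
    key_c <- paste(calls$sample_id, calls$chrom)
  } else {
    key_t <- truth$sample_id
    key_c <- calls$sample_id
  }
  idx <- match(key_t, key_c)
  if (anyNA(idx)) {
    stop("calls are missing entries present in the truth table",
         call. = FALSE)
  }
  positive_call <- if (level == "chromosome") {
    calls$category[idx] != "disomic"
  } else {
    calls$category[idx] != "euploid"
  }
  positive_truth <- truth$expected == "aneuploid"
  tp <- sum(positive_truth & positive_call)
  fn <- sum(positive_truth & !positive_call)
  fp <- sum(!positive_truth & positive_call)
  tn <- sum(!positive_truth & !positive_call)
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn, level = level,
         fn_detail = truth[positive_truth & !positive_call, , drop = FALSE]),
    class = "confusion_counts"
  )
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Closed-form beta-quantile bounds: lower = qbeta(alpha/2, x, n-x+1)
#' (0 when x = 0), upper = qbeta(1-alpha/2, x+1, n-x) (1 when x = n).
#' For x = n the lower bound reduces to (alpha/2)^(1/n).
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials (>= 1).
#' @param alpha two-sided error rate (default 0.05 for a 95% CI).
#' @return numeric c(lower, upper).
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  if (n < 1 || x < 0 || x > n) {
    stop("require 0 <= x <= n and n >= 1", call. = FALSE)
  }
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Sensitivity and specificity with exact 95% CIs
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP); exact
#' Clopper-Pearson intervals for both. A zero denominator leaves the
#' metric (and its CI) NA and is flagged.
#'
#' @param c a `confusion_counts`.
#' @param alpha two-sided CI error rate.
#' @return object of class `concordance_result` with `sensitivity`,
#'   `specificity`, `sens_ci`, `spec_ci`, `counts`, `undefined`.
#' @export
sensitivity_specificity <- function(c, alpha = 0.05) {
  stopifnot(inherits(c, "confusion_counts"))
  undefined <- character()
  if (c$tp + c$fn > 0) {
    sens <- c$tp / (c$tp + c$fn)
    sens_ci <- clopper_pearson(c$tp, c$tp + c$fn, alpha)
  } else {
    sens <- NA_real_
    sens_ci <- c(lower = NA_real_, upper = NA_real_)
    undefined <- c(undefined, "sensitivity")
  }
  if (c$tn + c$fp > 0) {
    spec <- c$tn / (c$tn + c$fp)
    spec_ci <- clopper_pearson(c$tn, c$tn + c$fp, alpha)
  } else {
    spec <- NA_real_
    spec_ci <- c(lower = NA_real_, upper = NA_real_)
    undefined <- c(undefined, "specificity")
  }
  structure(
    list(sensitivity = sens, specificity = spec,
         sens_ci = sens_ci, spec_ci = spec_ci, counts = c,
         undefined = undefined),
    class = "concordance_result"
  )
}

#' Concordance table in the published layout
#'
#' Assembles chromosome- and sample-level counts and performance into
#' the row layout of the study's concordance table, for one platform.
#'
#' @param chrom_counts chromosome-level `confusion_counts`.
#' @param sample_counts sample-level `confusion_counts`.
#' @return data frame with `row` and `value` columns.
#' @export
table1_report <- function(chrom_counts, sample_counts) {
  cr <- sensitivity_specificity(chrom_counts)
  sr <- sensitivity_specificity(sample_counts)
  pct <- function(x) sprintf("%.2f%%", 100 * x)
  ci <- function(ci) sprintf("(%.2f-%.2f%%)", 100 * ci[["lower"]],
                             100 * ci[["upper"]])
  data.frame(
    row = c(
      "Chromosome calling comparison",
      "Euploid chromosomes (true negatives)",
      "Aneuploid chromosomes (true positives)",
      "Missed chromosome calls (false negatives)",
      "Extra chromosome calls (false positives)",
      "Aneuploidy call sensitivity",
      "Aneuploidy call specificity",
      "Euploid sample (true negatives)",
      "Aneuploid embryo (true positives)",
      "Missed aneuploid embryo calls (false negatives)",
      "Extra aneuploid embryo calls (false positives)",
      "Aneuploid embryo call sensitivity",
      "Aneuploid embryo call specificity"
    ),
    value = c(
      chrom_counts$tp + chrom_counts$tn + chrom_counts$fp + chrom_counts$fn,
      chrom_counts$tn + chrom_counts$fp,
      chrom_counts$tp + chrom_counts$fn,
      chrom_counts$fn,
      chrom_counts$fp,
      paste(pct(cr$sensitivity), ci(cr$sens_ci)),
      paste(pct(cr$specificity), ci(cr$spec_ci)),
      sample_counts$tn + sample_counts$fp,
      sample_counts$tp + sample_counts$fn,
      sample_counts$fn,
      sample_counts$fp,
      paste(pct(sr$sensitivity), ci(sr$sens_ci)),
      paste(pct(sr$specificity), ci(sr$spec_ci))
    ),
    stringsAsFactors = FALSE
  )
}
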