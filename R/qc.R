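#' Derivative log-ratio spread (DLR)
#'
#' The sample-noise metric gating profile-A analysis: the median
#' absolute difference between consecutive bin log2 ratios, divided by
#' sqrt(2) so it estimates the per-bin log-ratio SD-like spread.
#' Differences across chromosome boundaries are excluded (real copy
#' steps at boundaries are not noise). A `method = "sd"` variant uses
#' the SD of the differences instead of the median absolute difference.
#'
#' @param log2_ratios numeric per-bin log2 ratios.
#' @param chrom chromosome name per bin (differences are taken within
#'   chromosomes only); a single chromosome is assumed if omitted.
#' @param method "mad" (median absolute successive difference, default)
#'   or "sd".
#' @return non-negative spread estimate.
#' @export
compute_dlr <- function(log2_ratios, chrom = NULL, method = c("mad", "sd")) {
  method <- match.arg(method)
  if (length(log2_ratios) < 2) {
    stop("DLR needs at least 2 bins", call. = FALSE)
  }
  if (is.null(chrom)) {
    chrom <- rep("chr", length(log2_ratios))
  }
  d <- diff(log2_ratios)
  same <- chrom[-1] == chrom[-length(chrom)]
  d <- d[same & is.finite(d)]
  if (!length(d)) {
    stop("DLR needs at least 2 bins on one chromosome", call. = FALSE)
  }
  if (method == "mad") {
    stats::median(abs(d)) / sqrt(2)
  } else {
    stats::sd(d) / sqrt(2)
  }
}

#' Sample QC metrics
#'
#' @param total_reads total reads for the sample.
#' @param reads_pf reads passing filter (must not exceed total).
#' @param dlr derivative log-ratio spread from [compute_dlr()].
#' @return object of class `qc_metrics`.
#' @export
qc_metrics <- function(total_reads, reads_pf, dlr) {
  if (reads_pf > total_reads) {
    stop("reads_pf cannot exceed total_reads", call. = FALSE)
  }
  if (dlr < 0) {
    stop("dlr must be non-negative", call. = FALSE)
  }
  structure(list(total_reads = total_reads, reads_pf = reads_pf, dlr = dlr),
            class = "qc_metrics")
}

#' QC acceptance thresholds
#'
#' Defaults are the profile-A acceptance criteria: total reads strictly
#' above 700,000, reads passing filter strictly above 500,000, and DLR
#' at or below 0.2.
#'
#' @param min_total_reads,min_reads_pf strict lower bounds on reads.
#' @param max_dlr inclusive upper bound on DLR.
#' @return object of class `qc_config`.
#' @export
qc_config <- function(min_total_reads = 700000, min_reads_pf = 500000,
                      max_dlr = 0.2) {
  stopifnot(min_total_reads > 0, min_reads_pf > 0, max_dlr > 0)
  structure(list(min_total_reads = min_total_reads,
                 min_reads_pf = min_reads_pf, max_dlr = max_dlr),
            class = "qc_config")
}

#' Apply the QC gate
#'
#' Pass requires total reads > min, pf reads > min (both strict, as the
#' thresholds are printed) and DLR <= max (inclusive).
#'
#' @param m a [qc_metrics()].
#' @param c a [qc_config()].
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty when passing).
#' @export
qc_gate <- function(m, c = qc_config()) {
  stopifnot(inherits(m, "qc_metrics"), inherits(c, "qc_config"))
  reasons <- character()
  if (!(m$total_reads > c$min_total_reads)) {
    reasons <- c(reasons, sprintf("total_reads not > %d", c$min_total_reads))
  }
  if (!(m$reads_pf > c$min_reads_pf)) {
    reasons <- c(reasons, sprintf("reads_pf not > %d", c$min_reads_pf))
  }
  if (!(m$dlr <= c$max_dlr)) {
    reasons <- c(reasons, sprintf("dlr not <= %.2f", c$max_dlr))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' QC report for a set of samples
#'
#' @param samples list of `bincounts`.
#' @param profiles list of matching `norm_profile` objects (for DLR).
#' @param config a [qc_config()].
#' @return data frame: sample_id, total_reads, reads_pf, dlr, gate,
#'   fail_reasons.
#' @export
qc_report <- function(samples, profiles, config = qc_config()) {
  rows <- lapply(seq_along(samples), function(i) {
    b <- samples[[i]]
    np <- profiles[[i]]
    ok <- !np$masked & np$ratio > 0
    dlr <- compute_dlr(log2(np$ratio[ok]), np$chrom[ok])
    g <- qc_gate(qc_metrics(b$qc$total_reads, b$qc$reads_pf, dlr), config)
    data.frame(
      sample_id = b$sample_id, total_reads = b$qc$total_reads,
      reads_pf = b$qc$reads_pf, dlr = dlr,
      gate = if (g$pass) "pass" else "fail",
      fail_reasons = paste(g$reasons, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
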