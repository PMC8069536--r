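#' In-silico reference: expected per-bin counts
#'
#' Expected counts under the declared reference karyotype (46,XY: CN 2
#' on autosomes, CN 1 on X/Y) with no GC model: bin weight times
#' reference copy state, scaled to the pass-filter read total. The GC
#' amplification bias is deliberately not part of the reference - the
#' normalizer removes it empirically from the sample itself, so the
#' reference never has to know the platform's bias shape.
#'
#' @param bins bin grid.
#' @param profile a [platform_profile()].
#' @return numeric expected count per bin.
#' @export
insilico_reference <- function(bins, profile) {
  ref_cn <- reference_cn()[bins$chrom]
  w <- bins$weight * ref_cn / 2
  w / sum(w) * round(profile$total_reads * profile$pf_fraction)
}

#' GC and reference normalization of bin counts
#'
#' Produces the normalized per-bin profile the callers operate on:
#' ratio = count / reference, corrected by a GC-stratified median factor
#' (quantile strata of the GC fraction, estimated on unmasked autosomal
#' bins and applied genome-wide), then rescaled so the autosomal median
#' ratio is exactly 1 (sex chromosomes are excluded from the scale
#' because their ploidy varies with the sample's sex and mosaic
#' fraction). Per-bin copy number is the reference copy state
#' times the ratio, so a disomic autosome sits at CN 2 and the
#' hemizygous X/Y of a male at CN 1. Bins with a reference expectation
#' below the 1st percentile are masked.
#'
#' @param b a `bincounts` object (or bare integer count vector).
#' @param reference per-bin expected counts from [insilico_reference()].
#' @param bins the bin grid.
#' @param gc_strata number of GC quantile strata (default 10, deciles).
#' @return data frame of class `norm_profile` with columns `chrom`,
#'   `start`, `end`, `gc`, `ratio`, `cn`, `masked`.
#' @export
gc_normalize <- function(b, reference, bins, gc_strata = 10L) {
  counts <- if (inherits(b, "bincounts")) b$counts else as.numeric(b)
  stopifnot(length(counts) == nrow(bins), length(reference) == nrow(bins))
  if (any(reference < 0)) {
    stop("reference expectations must be non-negative", call. = FALSE)
  }
  masked <- reference < stats::quantile(reference[reference > 0], 0.01) |
    reference == 0
  ratio <- rep(NA_real_, length(counts))
  ratio[!masked] <- counts[!masked] / reference[!masked]

  autosome <- !(bins$chrom %in% c("X", "Y"))
  est <- !masked & autosome
  # GC-stratified median correction, fit on autosomes, applied everywhere.
  br <- unique(stats::quantile(bins$gc[est], probs = seq(0, 1, length.out = gc_strata + 1)))
  if (length(br) > 2) {
    stratum <- cut(bins$gc, breaks = br, include.lowest = TRUE)
    fac <- tapply(ratio[est], stratum[est], stats::median)
    fac <- fac / stats::median(ratio[est])
    f <- fac[as.character(stratum)]
    f[is.na(f)] <- 1
    ratio <- ratio / as.numeric(f)
  }
  # scale on autosomes only: sex-chromosome ploidy varies by sample sex
  # (and with the mosaic fraction in XY/XX mixtures), so including X/Y
  # bins would drag the median with the very signal being measured
  ratio <- ratio / stats::median(ratio[est])
  ref_cn <- reference_cn()[bins$chrom]
  out <- data.frame(
    chrom = bins$chrom, start = bins$start, end = bins$end, gc = bins$gc,
    ratio = ratio, cn = unname(ref_cn) * ratio, masked = masked,
    stringsAsFactors = FALSE
  )
  class(out) <- c("norm_profile", "data.frame")
  out
}

#' Per-chromosome mean copy number of a normalized profile
#'
#' The continuous CN estimate used for mosaic quantitation on the
#' Gaussian-caller platform: the mean of unmasked bin CN values per
#' chromosome.
#'
#' @param np a `norm_profile`.
#' @return named numeric vector over the chromosomes present.
#' @export
chromosome_cn <- function(np) {
  ok <- !np$masked
  vapply(split(np$cn[ok], factor(np$chrom[ok], levels = chrom_names())),
         mean, numeric(1))
}

#' Write a normalized profile as BED-like TSV
#'
#' Columns: chrom, start, end, cn. For plotting / external inspection.
#' @param np a `norm_profile`.
#' @param path output file.
#' @param seed optional provenance seed.
#' @export
write_profile_tsv <- function(np, path, seed = NA) {
  df <- data.frame(chrom = np$chrom, start = np$start, end = np$end,
                   cn = round(np$cn, 4))
  write_tsv_stamped(df[!np$masked, ], path, seed = seed)
}
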