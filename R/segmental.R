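#' Segmental-detector configuration
#'
#' Run-length detection of sub-chromosomal events: a segment is called
#' when at least `min_run` consecutive bins lie outside the bin-level
#' euploid band (the band is `seg_range_k` x the robust per-bin CN SD,
#' itself estimated from the profile's successive bin differences so
#' true segments do not inflate it). Runs separated by a single
#' interrupting bin are merged. Defaults follow the platform profiles
#' (min_run 4 on the 0.9 Mb grid, 5 on the 1.0 Mb grid).
#'
#' @param min_run minimum consecutive outlier bins (>= 2).
#' @param seg_range_k band multiplier on the robust bin SD.
#' @return object of class `segmental_config`.
#' @export
segmental_config <- function(min_run = 4L, seg_range_k = 3) {
  if (min_run < 2) {
    stop("min_run must be at least 2", call. = FALSE)
  }
  structure(list(min_run = as.integer(min_run), seg_range_k = seg_range_k),
            class = "segmental_config")
}

#' @rdname segmental_config
#' @param profile a [platform_profile()]; takes min_run/seg_range_k from
#'   it.
#' @export
segmental_config_for <- function(profile) {
  segmental_config(profile$min_run, profile$seg_range_k)
}

# Robust per-bin CN noise SD from successive differences (within
# chromosomes): median|diff| of N(0, 2*sigma^2) is 0.6745*sqrt(2)*sigma.
robust_bin_sd <- function(np) {
  ok <- !np$masked
  d <- diff(np$cn[ok])
  same <- np$chrom[ok][-1] == np$chrom[ok][-sum(ok)]
  stats::median(abs(d[same])) / (0.6745 * sqrt(2))
}

#' Detect sub-chromosomal copy-number segments
#'
#' Scans each chromosome of a normalized profile for maximal runs of at
#' least `min_run` consecutive unmasked bins whose CN lies outside the
#' bin-level euploid band around the chromosome's reference copy state
#' (for X/Y the band is scaled by the reference CN). Runs interrupted by
#' a single in-band bin are merged; events spanning (almost) the whole
#' chromosome are excluded - those are whole-chromosome calls and belong
#' to the chromosome callers.
#'
#' @param np a `norm_profile` from [gc_normalize()].
#' @param cfg a [segmental_config()].
#' @param whole_chrom_fraction runs covering at least this fraction of a
#'   chromosome's bins are dropped (default 0.9).
#' @return data frame of segment calls: chrom, start, end, n_bins,
#'   mean_cn, direction ("gain"/"loss"). Zero rows when nothing is
#'   found.
#' @export
detect_segments <- function(np, cfg = segmental_config(),
                            whole_chrom_fraction = 0.9) {
  sd_bin <- robust_bin_sd(np)
  ref <- reference_cn()
  out <- list()
  for (ch in chrom_names()) {
    idx <- which(np$chrom == ch & !np$masked)
    if (length(idx) < cfg$min_run) next
    base <- ref[[ch]]
    band <- cfg$seg_range_k * sd_bin * base / 2
    cnv <- np$cn[idx]
    low <- cnv < base - band
    high <- cnv > base + band
    for (side in c("loss", "gain")) {
      flag <- if (side == "loss") low else high
      runs <- merged_runs(flag)
      for (r in runs) {
        span <- r[2] - r[1] + 1
        if (span < cfg$min_run) next
        if (span >= whole_chrom_fraction * length(idx)) next
        sel <- idx[r[1]:r[2]]
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = np$start[sel[1]], end = np$end[sel[length(sel)]],
          n_bins = span, mean_cn = mean(np$cn[sel]),
          direction = side, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_bins = integer(),
                      mean_cn = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(match(res$chrom, chrom_names()), res$start), , drop = FALSE]
}

# Maximal runs of TRUE, merging runs separated by exactly one FALSE.
merged_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  true_runs <- which(r$values)
  if (!length(true_runs)) {
    return(list())
  }
  merged <- list(c(starts[true_runs[1]], ends[true_runs[1]]))
  if (length(true_runs) > 1) {
    for (i in true_runs[-1]) {
      last <- merged[[length(merged)]]
      gap <- starts[i] - last[2] - 1
      if (gap <= 1) {
        merged[[length(merged)]] <- c(last[1], ends[i])
      } else {
        merged[[length(merged) + 1]] <- c(starts[i], ends[i])
      }
    }
  }
  merged
}

#' Minimum resolvable segment size of a platform
#'
#' `min_run` consecutive bins of `bin_size_bp`, in Mb: 3.6 Mb for the
#' profile-A grid (4 x 0.9 Mb) and 5.0 Mb for profile B (5 x 1.0 Mb).
#'
#' @param cfg a [segmental_config()].
#' @param profile the [platform_profile()] providing the bin size.
#' @return size in Mb.
#' @export
min_detectable_size <- function(cfg, profile) {
  cfg$min_run * profile$bin_size_bp / 1e6
}

#' Mean CN over a known segment
#'
#' Quantifies (possibly mosaic) segmental copy number: the mean CN of
#' unmasked bins whose midpoint lies inside the segment. Regions listed
#' in `exclude` are dropped - used when two cell lines carry
#' overlapping deletions (the shared region is deleted in both
#' components of a mixture and so carries no mosaicism signal; only the
#' private region tracks the mixture fraction).
#'
#' @param np a `norm_profile`.
#' @param s a [segment_spec()].
#' @param exclude optional list of [segment_spec()] regions to drop.
#' @return mean CN; errors if the segment overlaps fewer than 2 bins.
#' @export
quantify_segment_cn <- function(np, s, exclude = list()) {
  stopifnot(inherits(s, "segment_spec"))
  mid <- (np$start + np$end) / 2
  sel <- np$chrom == s$chrom & mid >= s$start0 & mid < s$end0 & !np$masked
  for (e in exclude) {
    sel <- sel & !(np$chrom == e$chrom & mid >= e$start0 & mid < e$end0)
  }
  if (sum(sel) < 2) {
    stop("segment overlaps fewer than 2 usable bins", call. = FALSE)
  }
  mean(np$cn[sel])
}

#' Does a segment call hit a known deletion?
#'
#' A call matches when it is on the deletion's chromosome, in the loss
#' direction, and overlaps the deletion's coordinates.
#'
#' @param segments data frame from [detect_segments()].
#' @param s the known deletion ([segment_spec()]).
#' @return logical.
#' @export
segment_detected <- function(segments, s) {
  if (!nrow(segments)) {
    return(FALSE)
  }
  hit <- segments$chrom == s$chrom & segments$direction == "loss" &
    segments$start < s$end0 & segments$end > s$start0
  any(hit)
}
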