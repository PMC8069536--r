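#' Reconstructed cell mixture
#'
#' A weighted combination of karyotyped cell lines; the mosaic fraction
#' f of the study's mixtures is the weight of the aneuploid component.
#' Fractions must be non-negative and sum to 1; the study's mixtures sit
#' on the 10% grid (10:0, 9:1, ..., 0:10).
#'
#' @param karyotypes list of [karyotype_spec()] objects.
#' @param fractions numeric weights, same length, summing to 1.
#' @param cell_count total cells in the reconstruction (10 or 100).
#' @return object of class `cell_mixture`.
#' @export
cell_mixture <- function(karyotypes, fractions, cell_count = 10L) {
  if (length(karyotypes) == 0) {
    stop("mixture must contain at least one component", call. = FALSE)
  }
  stopifnot(length(karyotypes) == length(fractions))
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (cell_count < 1) {
    stop("cell_count must be at least 1", call. = FALSE)
  }
  structure(
    list(karyotypes = karyotypes, fractions = fractions,
         cell_count = as.integer(cell_count)),
    class = "cell_mixture"
  )
}

# Mixture of one aneuploid line at fraction f against the euploid line.
mosaic_mixture <- function(aneuploid, f, cell_count = 10L,
                           registry = karyotype_registry()) {
  euploid <- registry[["46,XY"]]
  k2 <- if (is.character(aneuploid)) registry[[aneuploid]] else aneuploid
  if (f >= 1) {
    cell_mixture(list(k2), 1, cell_count)
  } else if (f <= 0) {
    cell_mixture(list(euploid), 1, cell_count)
  } else {
    cell_mixture(list(euploid, k2), c(1 - f, f), cell_count)
  }
}

#' Expected per-bin copy number of a mixture
#'
#' The linear mixture model: CN per bin is the fraction-weighted average
#' of the component copy tracks, so a trisomic chromosome at aneuploid
#' fraction f has expected CN 2 + f, X mirrors at 1 + f and Y at 1 - f
#' for the 46,XY / 47,XX mixtures.
#'
#' @param m a [cell_mixture()].
#' @param bins bin grid from [make_bins()].
#' @return numeric per-bin expected copy number.
#' @export
expected_cn <- function(m, bins) {
  stopifnot(inherits(m, "cell_mixture"))
  tracks <- vapply(m$karyotypes, karyotype_cn_track, numeric(nrow(bins)),
                   bins = bins)
  as.numeric(tracks %*% m$fractions)
}

#' Simulate one sample's per-bin read counts
#'
#' Per-bin sampling probabilities are proportional to bin weight x GC
#' amplification bias x (expected CN / 2) x a per-bin lognormal WGA
#' jitter (sigma scaled by sqrt(10 / cell_count)); counts are then one
#' multinomial draw totalling `round(total_reads * pf_fraction)` reads,
#' so counts are conserved exactly and E\[count\] tracks expected CN.
#'
#' @param m a [cell_mixture()].
#' @param profile a [platform_profile()].
#' @param bins bin grid (must match `profile$bin_size_bp`).
#' @param seed integer seed; identical (m, profile, bins, seed) give
#'   bit-identical counts.
#' @param sample_id optional label.
#' @return object of class `bincounts`: list with `counts`, `sample_id`,
#'   `profile`, `seed`, `qc` (total/pf read numbers) and `truth` (the
#'   mixture, carried for validation only and never read by callers).
#' @export
simulate_bincounts <- function(m, profile, bins, seed, sample_id = "sample") {
  stopifnot(inherits(profile, "platform_profile"))
  cn <- expected_cn(m, bins)
  jitter_sd <- profile$wga_jitter_sd * sqrt(10 / m$cell_count)
  n_pf <- round(profile$total_reads * profile$pf_fraction)
  counts <- with_seed(seed, {
    pr <- bins$weight * gc_bias_curve(bins$gc, profile$gc_bias_amp) *
      (cn / 2) * exp(stats::rnorm(nrow(bins), 0, jitter_sd))
    if (all(pr == 0)) {
      stop("all bin probabilities are zero", call. = FALSE)
    }
    as.integer(stats::rmultinom(1, n_pf, pr))
  })
  structure(
    list(
      sample_id = sample_id,
      profile = profile$name,
      seed = as.integer(seed),
      counts = counts,
      qc = list(total_reads = profile$total_reads, reads_pf = n_pf),
      truth = m
    ),
    class = "bincounts"
  )
}

#' Materialize the 120-sample concordance design
#'
#' Two sets of mixtures (the trisomy-21 and trisomy-18 lines against the
#' euploid male line): per set, 9 mosaic levels (10%..90%) with
#' `replicates_per_level` replicates each, plus 3 full-aneuploid (100%)
#' and 3 euploid (0%) samples - 120 samples in total with the study's
#' structure. Per-sample seeds derive deterministically from the master
#' seed.
#'
#' @param profile a [platform_profile()].
#' @param bins bin grid for that profile.
#' @param cell_count cells per reconstruction (10 or 100).
#' @param seed master seed.
#' @param replicates_per_level mosaic replicates per level (default 6).
#' @return list with `manifest` (data frame: sample_id, set, level,
#'   replicate, cell_count, seed) and `samples` (list of `bincounts`).
#' @export
simulate_design <- function(profile, bins, cell_count = 10L, seed = 42L,
                            replicates_per_level = 6L) {
  stopifnot(cell_count >= 1)
  registry <- karyotype_registry()
  sets <- c(tri21 = "47,XX,+21", tri18 = "47,XX,+18")
  rows <- list()
  for (set in names(sets)) {
    for (lev in seq(0.1, 0.9, by = 0.1)) {
      for (rep in seq_len(replicates_per_level)) {
        rows[[length(rows) + 1]] <- data.frame(
          set = set, level = lev, replicate = rep, stringsAsFactors = FALSE)
      }
    }
    for (rep in 1:3) {
      rows[[length(rows) + 1]] <- data.frame(
        set = set, level = 1.0, replicate = rep, stringsAsFactors = FALSE)
    }
    for (rep in 1:3) {
      rows[[length(rows) + 1]] <- data.frame(
        set = set, level = 0.0, replicate = rep, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$cell_count <- as.integer(cell_count)
  manifest$sample_id <- sprintf("%s_%s_f%02.0f_r%d", profile$name,
                                manifest$set, 100 * manifest$level,
                                manifest$replicate)
  manifest$seed <- vapply(manifest$sample_id, function(id) {
    derive_seed(seed, "design", id)
  }, integer(1))
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    m <- mosaic_mixture(sets[[row$set]], row$level, cell_count, registry)
    simulate_bincounts(m, profile, bins, row$seed, row$sample_id)
  })
  manifest <- manifest[, c("sample_id", "set", "level", "replicate",
                           "cell_count", "seed")]
  list(manifest = manifest, samples = samples)
}

#' Simulate the 16-sample segmental-deletion panel
#'
#' Eight cell lines with deletions spanning 4.5-17 Mb, each in
#' duplicate, as pure (f = 1) samples.
#'
#' @inheritParams simulate_design
#' @return list of 16 `bincounts`, with the line name in `sample_id`.
#' @export
simulate_segmental_panel <- function(profile, bins, seed = 7L,
                                     cell_count = 10L) {
  registry <- karyotype_registry()
  out <- list()
  for (nm in segmental_panel_names()) {
    for (dup in 1:2) {
      id <- sprintf("%s_%s_d%d", profile$name, nm, dup)
      m <- cell_mixture(list(registry[[nm]]), 1, cell_count)
      out[[id]] <- simulate_bincounts(
        m, profile, bins, derive_seed(seed, "panel", id), id)
    }
  }
  out
}

#' Simulate the mosaic segmental series
#'
#' Mixtures of the two Coriell microdeletion lines (GM06918 carrying the
#' 17 Mb chr21 deletion, GM08331 the 12 Mb chr13 deletion) at GM06918
#' fractions 1.0, 0.8, 0.6, 0.4, 0.2, 0.0, in duplicate, on profile A.
#'
#' @param bins profile-A bin grid.
#' @param seed master seed.
#' @param profile platform profile (profile A in the study).
#' @param cell_count cells per reconstruction.
#' @return list of 12 `bincounts`; names encode the GM06918 fraction.
#' @export
simulate_mosaic_segmental_series <- function(bins, seed = 11L,
                                             profile = platform_profile("A"),
                                             cell_count = 10L) {
  registry <- karyotype_registry()
  out <- list()
  for (f in c(1.0, 0.8, 0.6, 0.4, 0.2, 0.0)) {
    for (dup in 1:2) {
      id <- sprintf("%s_segmix_f%03.0f_d%d", profile$name, 100 * f, dup)
      m <- if (f >= 1) {
        cell_mixture(list(registry[["GM06918"]]), 1, cell_count)
      } else if (f <= 0) {
        cell_mixture(list(registry[["GM08331"]]), 1, cell_count)
      } else {
        cell_mixture(list(registry[["GM08331"]], registry[["GM06918"]]),
                     c(1 - f, f), cell_count)
      }
      out[[id]] <- simulate_bincounts(
        m, profile, bins, derive_seed(seed, "segmix", id), id)
    }
  }
  out
}

#' Simulate a euploid reference/calibration set
#'
#' n euploid (46,XY) samples used to build the chromosome-fraction
#' baseline (11 normals in the study) or to calibrate the euploid range.
#'
#' @inheritParams simulate_design
#' @param n number of euploid samples (at least 2).
#' @return list of n `bincounts`.
#' @export
simulate_reference_set <- function(profile, bins, n = 11L, seed = 5L,
                                   cell_count = 10L) {
  if (n < 2) {
    stop("a reference set needs at least 2 samples", call. = FALSE)
  }
  registry <- karyotype_registry()
  m <- cell_mixture(list(registry[["46,XY"]]), 1, cell_count)
  lapply(seq_len(n), function(i) {
    id <- sprintf("%s_ref_%02d", profile$name, i)
    simulate_bincounts(m, profile, bins, derive_seed(seed, "ref", id), id)
  })
}

#' Write simulated bin counts as a BED-like TSV
#'
#' Columns: chrom, start, end, gc, count. A provenance header records
#' the seed.
#'
#' @param b a `bincounts` object.
#' @param bins the matching bin grid.
#' @param path output file.
#' @export
write_bincounts_tsv <- function(b, bins, path) {
  df <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   gc = round(bins$gc, 4), count = b$counts)
  write_tsv_stamped(df, path, seed = b$seed,
                    config = list(profile = b$profile, id = b$sample_id))
}

#' Read a BED-like bin-count TSV
#'
#' Validates the schema (chrom, start, end, gc, count) and returns the
#' table; used to feed user-supplied counts into the callers.
#'
#' @param path TSV written by [write_bincounts_tsv()] or equivalent.
#' @return data frame with the five columns above.
#' @export
read_bincounts_tsv <- function(path) {
  df <- read_tsv_stamped(path)
  needed <- c("chrom", "start", "end", "gc", "count")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("bin-count table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$count < 0)) {
    stop("column 'count' must be non-negative", call. = FALSE)
  }
  df
}
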