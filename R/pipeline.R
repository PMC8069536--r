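#' Prepare a platform workspace
#'
#' Everything a platform needs before samples can be analyzed: the bin
#' grid, the chromosome-fraction baseline (profile B, built from the
#' profile's `baseline_n` euploid normals), and the euploid-range
#' calibration from a dedicated euploid calibration set.
#'
#' @param profile a [platform_profile()].
#' @param master_seed master seed; stage seeds derive from it.
#' @param calibration_n euploid samples for range calibration.
#' @param cell_count cells per calibration sample (the biopsy-scale 10).
#' @param genome optional [genome_build()]; defaults to full hg19 at the
#'   profile's bin size.
#' @return list with `profile`, `bins`, `baseline` (NULL for profile A),
#'   `calibration`.
#' @export
profile_workspace <- function(profile, master_seed = 42L,
                              calibration_n = 30L, cell_count = 10L,
                              genome = NULL) {
  if (is.null(genome)) {
    genome <- genome_build(bin_size_bp = profile$bin_size_bp)
  }
  bins <- make_bins(genome, seed = derive_seed(master_seed, "gc", profile$name))
  baseline <- NULL
  if (profile$caller == "baseline") {
    refs <- simulate_reference_set(profile, bins, n = profile$baseline_n,
                                   seed = derive_seed(master_seed, "baseline"),
                                   cell_count = cell_count)
    baseline <- build_baseline(refs, bins)
  }
  cal_samples <- simulate_reference_set(
    profile, bins, n = calibration_n,
    seed = derive_seed(master_seed, "calibration", profile$name),
    cell_count = cell_count
  )
  calibration <- calibrate_platform(cal_samples, profile, bins, baseline)
  list(profile = profile, bins = bins, baseline = baseline,
       calibration = calibration)
}

#' Analyze a simulated design end to end
#'
#' Estimates every sample's 24 chromosome CNs, classifies chromosomes
#' and samples against the workspace calibration, scores concordance at
#' both levels, and determines the limit of detection from the
#' replicate CN estimates of the trisomic chromosome of each set.
#'
#' @param design result of [simulate_design()].
#' @param ws a [profile_workspace()].
#' @param alpha LOD significance level.
#' @param lod_method detection rule passed to [determine_lod()].
#' @return list: `chrom_calls` (long data frame sample_id, chrom,
#'   cn_estimate, category), `sample_calls`, `chrom_counts`,
#'   `sample_counts`, `lod`, `fn_levels` (mixture levels of the
#'   chromosome-level false negatives).
#' @export
evaluate_design <- function(design, ws, alpha = 0.05,
                            lod_method = "range+ttest") {
  manifest <- design$manifest
  cn_mat <- vapply(design$samples, sample_chromosome_cn, numeric(24L),
                   profile = ws$profile, bins = ws$bins,
                   baseline = ws$baseline)
  colnames(cn_mat) <- manifest$sample_id

  cat_mat <- apply(cn_mat, 2, classify_chromosomes, calib = ws$calibration)
  chrom_calls <- data.frame(
    sample_id = rep(manifest$sample_id, each = 24L),
    chrom = rep(chrom_names(), times = nrow(manifest)),
    cn_estimate = as.numeric(cn_mat),
    category = as.character(cat_mat),
    stringsAsFactors = FALSE
  )
  sample_calls <- data.frame(
    sample_id = manifest$sample_id,
    category = apply(cat_mat, 2, function(x) classify_sample(x)$category),
    stringsAsFactors = FALSE
  )

  truth <- chromosome_truth_table(manifest)
  chrom_counts <- score_concordance(truth, chrom_calls, "chromosome")
  sample_truth <- data.frame(
    sample_id = manifest$sample_id,
    expected = ifelse(manifest$level > 0, "aneuploid", "euploid"),
    stringsAsFactors = FALSE
  )
  sample_counts <- score_concordance(sample_truth, sample_calls, "sample")

  lod <- design_lod(manifest, cn_mat, ws, alpha, lod_method)
  fn_levels <- chrom_counts$fn_detail$level

  list(chrom_calls = chrom_calls, sample_calls = sample_calls,
       chrom_counts = chrom_counts, sample_counts = sample_counts,
       lod = lod, fn_levels = fn_levels, cn_mat = cn_mat)
}

# LOD from a design: per level, pool the trisomic-chromosome CN
# deviations of both sets (chr21 in the tri21 set, chr18 in tri18)
# against the pooled euploid replicates, on the deviation scale so the
# two chromosomes share one euploid range centered at 0.
design_lod <- function(manifest, cn_mat, ws, alpha, method) {
  tri <- c(tri21 = "21", tri18 = "18")
  dev_of <- function(rows) {
    vapply(rows, function(i) {
      ch <- tri[[manifest$set[i]]]
      cn_mat[match(ch, chrom_names()), i] - ws$calibration$mean[[ch]]
    }, numeric(1))
  }
  levels <- sort(unique(manifest$level[manifest$level > 0]))
  level_values <- lapply(levels, function(lv) {
    dev_of(which(manifest$level == lv))
  })
  names(level_values) <- as.character(levels)
  euploid_values <- dev_of(which(manifest$level == 0))
  rng <- list(lower = -ws$calibration$band, upper = ws$calibration$band)
  determine_lod(level_values, euploid_values, rng, alpha = alpha,
                method = method)
}

#' Run the segmental-resolution panel on one platform
#'
#' Simulates the 16-sample panel (8 lines in duplicate), normalizes each
#' sample, runs the run-length segment detector with the platform's
#' configuration, and records whether each sample's primary deletion was
#' called (correct chromosome, loss direction, overlapping coordinates)
#' and whether any extra segment was called.
#'
#' @param ws a [profile_workspace()].
#' @param seed panel seed.
#' @param cell_count cells per sample.
#' @return data frame: sample_id, line, size_mb, detected, n_extra.
#' @export
run_segmental_panel <- function(ws, seed = 7L, cell_count = 10L) {
  panel <- simulate_segmental_panel(ws$profile, ws$bins, seed = seed,
                                    cell_count = cell_count)
  registry <- karyotype_registry()
  cfg <- segmental_config_for(ws$profile)
  ref <- insilico_reference(ws$bins, ws$profile)
  rows <- lapply(names(panel), function(id) {
    b <- panel[[id]]
    np <- gc_normalize(b, ref, ws$bins)
    segs <- detect_segments(np, cfg)
    line <- sub(sprintf("^%s_(.*)_d[12]$", ws$profile$name), "\\1", id)
    k <- registry[[line]]
    primary <- primary_deletion(k)
    known <- vapply(k$segments, function(s) {
      any(segs$chrom == s$chrom & segs$direction == "loss" &
            segs$start < s$end0 & segs$end > s$start0)
    }, logical(1))
    data.frame(
      sample_id = id, line = line,
      size_mb = segment_length_mb(primary),
      detected = segment_detected(segs, primary),
      n_extra = nrow(segs) - sum(vapply(seq_len(nrow(segs)), function(j) {
        any(vapply(k$segments, function(s) {
          segs$chrom[j] == s$chrom & segs$direction[j] == "loss" &
            segs$start[j] < s$end0 & segs$end[j] > s$start0
        }, logical(1)))
      }, logical(1))),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Quantify the mosaic segmental series
#'
#' Runs the GM08331 x GM06918 mixture series on profile A and returns
#' the mean CN of the 17 Mb chr21 and 12 Mb chr13 deletions at each
#' GM06918 fraction.
#'
#' @param ws a profile-A [profile_workspace()].
#' @param seed series seed.
#' @param cell_count cells per sample.
#' @return data frame: sample_id, f (GM06918 fraction), cn_chr21_17mb,
#'   cn_chr13_12mb.
#' @export
run_mosaic_segmental_series <- function(ws, seed = 11L, cell_count = 10L) {
  series <- simulate_mosaic_segmental_series(ws$bins, seed = seed,
                                             profile = ws$profile,
                                             cell_count = cell_count)
  registry <- karyotype_registry()
  seg21 <- primary_deletion(registry[["GM06918"]])
  seg13 <- primary_deletion(registry[["GM08331"]])
  # GM08331's small chr21 deletion lies inside GM06918's 17 Mb one; the
  # shared region is deleted in both lines, so the 17 Mb CN is read
  # from the private region only.
  shared21 <- registry[["GM08331"]]$segments[[which(vapply(
    registry[["GM08331"]]$segments, `[[`, "", "chrom") == "21")]]
  ref <- insilico_reference(ws$bins, ws$profile)
  rows <- lapply(names(series), function(id) {
    np <- gc_normalize(series[[id]], ref, ws$bins)
    f <- as.numeric(sub(".*_f(\\d+)_d\\d$", "\\1", id)) / 100
    data.frame(sample_id = id, f = f,
               cn_chr21_17mb = quantify_segment_cn(np, seg21,
                                                   exclude = list(shared21)),
               cn_chr13_12mb = quantify_segment_cn(np, seg13),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full validation study
#'
#' The three-step design: (1) reference curves from the 100-cell
#' mixture sets; (2) limit-of-detection determination and concordance
#' scoring on the 120-sample 10-cell design, per platform; (3) the
#' segmental-resolution panel per platform plus the mosaic segmental
#' series on profile A. Returns all result tables; when `outdir` is
#' given, writes them as stamped TSVs plus a summary JSON.
#'
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @return list with per-profile `workspaces`, `curves`, `design_eval`,
#'   `table1`, `segmental`, `segmental_series`, `qc`, `summary`.
#' @export
run_validation <- function(config = run_config(), outdir = NULL) {
  seed <- config$master_seed
  out <- list(workspaces = list(), curves = list(), design_eval = list(),
              table1 = list(), segmental = list(), qc = list())
  tri <- c(tri21 = "21", tri18 = "18")

  for (profile in config$profiles) {
    pname <- profile$name
    ws <- profile_workspace(profile, master_seed = seed,
                            calibration_n = config$calibration_n,
                            cell_count = config$design_cell_count)
    out$workspaces[[pname]] <- ws

    # Step 1: reference curves on the 100-cell sets.
    curve_design <- simulate_design(
      profile, ws$bins, cell_count = config$curve_cell_count,
      seed = derive_seed(seed, "curve", pname),
      replicates_per_level = config$replicates_per_level
    )
    cn_mat <- vapply(curve_design$samples, sample_chromosome_cn,
                     numeric(24L), profile = profile, bins = ws$bins,
                     baseline = ws$baseline)
    man <- curve_design$manifest
    out$curves[[pname]] <- lapply(c("tri21", "tri18"), function(set) {
      sel <- man$set == set
      ch <- tri[[set]]
      build_reference_curve(data.frame(
        level = man$level[sel],
        cn = cn_mat[match(ch, chrom_names()), sel]
      ))
    })
    names(out$curves[[pname]]) <- c("tri21", "tri18")

    # Step 2: 10-cell design, LOD + concordance.
    design <- simulate_design(
      profile, ws$bins, cell_count = config$design_cell_count,
      seed = derive_seed(seed, "design", pname),
      replicates_per_level = config$replicates_per_level
    )
    ev <- evaluate_design(design, ws, alpha = config$alpha)
    out$design_eval[[pname]] <- ev
    out$table1[[pname]] <- table1_report(ev$chrom_counts, ev$sample_counts)

    npro <- lapply(design$samples, function(b) {
      gc_normalize(b, insilico_reference(ws$bins, profile), ws$bins)
    })
    out$qc[[pname]] <- qc_report(design$samples, npro)

    # Step 3: segmental panel.
    out$segmental[[pname]] <- run_segmental_panel(
      ws, seed = derive_seed(seed, "panel", pname),
      cell_count = config$design_cell_count
    )
  }

  ws_a <- out$workspaces[["profileA"]]
  if (!is.null(ws_a)) {
    out$segmental_series <- run_mosaic_segmental_series(
      ws_a, seed = derive_seed(seed, "segmix"),
      cell_count = config$design_cell_count
    )
  }

  out$summary <- list(
    master_seed = seed,
    lod = lapply(out$design_eval, function(e) e$lod$lod),
    chrom_fn = lapply(out$design_eval, function(e) e$chrom_counts$fn),
    chrom_fp = lapply(out$design_eval, function(e) e$chrom_counts$fp),
    sample_fn = lapply(out$design_eval, function(e) e$sample_counts$fn),
    segmental_detected = lapply(out$segmental, function(s) sum(s$detected)),
    min_detectable_mb = lapply(out$workspaces, function(ws) {
      min_detectable_size(segmental_config_for(ws$profile), ws$profile)
    })
  )

  if (!is.null(outdir)) {
    write_validation_outputs(out, config, outdir)
  }
  out
}

write_validation_outputs <- function(out, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$master_seed
  for (pname in names(out$design_eval)) {
    ev <- out$design_eval[[pname]]
    write_tsv_stamped(ev$chrom_calls,
                      file.path(outdir, paste0(pname, "_chrom_calls.tsv")),
                      seed, config)
    write_tsv_stamped(ev$sample_calls,
                      file.path(outdir, paste0(pname, "_sample_calls.tsv")),
                      seed, config)
    write_tsv_stamped(ev$lod$levels,
                      file.path(outdir, paste0(pname, "_lod.tsv")),
                      seed, config)
    write_tsv_stamped(out$table1[[pname]],
                      file.path(outdir, paste0(pname, "_table1.tsv")),
                      seed, config)
    write_tsv_stamped(out$segmental[[pname]],
                      file.path(outdir, paste0(pname, "_segmental.tsv")),
                      seed, config)
    write_tsv_stamped(out$qc[[pname]],
                      file.path(outdir, paste0(pname, "_qc.tsv")),
                      seed, config)
    for (set in names(out$curves[[pname]])) {
      write_tsv_stamped(
        out$curves[[pname]][[set]],
        file.path(outdir, sprintf("%s_curve_%s.tsv", pname, set)),
        seed, config
      )
    }
  }
  if (!is.null(out$segmental_series)) {
    write_tsv_stamped(out$segmental_series,
                      file.path(outdir, "profileA_segmental_series.tsv"),
                      seed, config)
  }
  jsonlite::write_json(out$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Analyze one bin-count table from disk
#'
#' Standalone entry point for a user-supplied BED-like TSV of bin
#' counts: QC, 24 chromosome calls, and segment detection, using a
#' prepared workspace whose bin grid must match the table.
#'
#' @param path TSV with columns chrom, start, end, gc, count.
#' @param ws a [profile_workspace()].
#' @return list with `qc`, `calls`, `segments`.
#' @export
call_sample_file <- function(path, ws) {
  df <- read_bincounts_tsv(path)
  if (nrow(df) != nrow(ws$bins)) {
    stop("bin-count table does not match the workspace bin grid (",
         nrow(df), " vs ", nrow(ws$bins), " bins)", call. = FALSE)
  }
  b <- structure(
    list(sample_id = basename(path), profile = ws$profile$name,
         seed = NA_integer_, counts = df$count,
         qc = list(total_reads = sum(df$count) / ws$profile$pf_fraction,
                   reads_pf = sum(df$count)),
         truth = NULL),
    class = "bincounts"
  )
  np <- gc_normalize(b, insilico_reference(ws$bins, ws$profile), ws$bins)
  ok <- !np$masked
  dlr <- compute_dlr(log2(pmax(np$ratio[ok], 1e-6)), np$chrom[ok])
  gate <- qc_gate(qc_metrics(b$qc$total_reads, b$qc$reads_pf, dlr))
  calls <- call_sample(b, ws$profile, ws$bins, baseline = ws$baseline)
  cnv <- sample_chromosome_cn(b, ws$profile, ws$bins, ws$baseline)
  calls$category <- unname(classify_chromosomes(cnv, ws$calibration))
  segs <- detect_segments(np, segmental_config_for(ws$profile))
  list(qc = c(list(dlr = dlr), gate), calls = calls, segments = segs)
}
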