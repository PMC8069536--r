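#!/usr/bin/env Rscript
# Step 1 of the validation: reference curves for whole-chromosome
# mosaicism. Reconstructed 100-cell mixtures of a 46,XY euploid line
# with the 47,XX,+21 or 47,XX,+18 line, at aneuploid fractions 0,
# 0.1, ..., 1.0, are simulated on both platform profiles; the mean +/-
# SD copy number of the trisomic chromosome (and of X and Y) per level
# is the platform's reference curve.
#
# Writes results/curves/<profile>_curve_<set>.tsv and prints the key
# curve values.

suppressPackageStartupMessages(library(lpmosaic))

seed <- 42L
outdir <- "results/curves"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
tri <- c(tri21 = "21", tri18 = "18")

for (nm in c("A", "B")) {
  profile <- platform_profile(nm)
  ws <- profile_workspace(profile, master_seed = seed)
  design <- simulate_design(profile, ws$bins, cell_count = 100L,
                            seed = derive_seed(seed, "curve", profile$name))
  cn <- vapply(design$samples, sample_chromosome_cn, numeric(24L),
               profile = profile, bins = ws$bins, baseline = ws$baseline)
  man <- design$manifest
  for (set in names(tri)) {
    sel <- man$set == set
    curve <- build_reference_curve(data.frame(
      level = man$level[sel],
      cn = cn[match(tri[[set]], chrom_names()), sel]
    ))
    path <- file.path(outdir, sprintf("%s_curve_%s.tsv", profile$name, set))
    write_tsv_stamped(curve, path, seed = seed)
    cat(sprintf(
      "%s %s (chr%s): CN %.2f at 20%% -> %.2f at 80%%; %.2f at 100%%\n",
      profile$name, set, tri[[set]],
      curve$mean_cn[curve$level == 0.2],
      curve$mean_cn[curve$level == 0.8],
      curve$mean_cn[curve$level == 1.0]
    ))
  }
  # sex-chromosome mirror at full replacement
  full <- man$level == 1
  cat(sprintf("%s at 100%%: X CN %.2f, Y CN %.2f\n", profile$name,
              mean(cn[match("X", chrom_names()), full]),
              mean(cn[match("Y", chrom_names()), full])))
}
cat("Curves written to", outdir, "\n")
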