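test_that("expected CN follows mixture arithmetic", {
  bins <- tiny_bins()
  reg <- fixture_registry()
  m <- cell_mixture(list(reg[["46,XY"]], reg[["47,XX,+21"]]), c(0.8, 0.2))
  cn <- expected_cn(m, bins)
  expect_true(all(abs(cn[bins$chrom == "21"] - 2.2) < 1e-12))
  expect_true(all(abs(cn[bins$chrom == "X"] - 1.2) < 1e-12))
  expect_true(all(abs(cn[bins$chrom == "Y"] - 0.8) < 1e-12))
  expect_true(all(cn[bins$chrom == "1"] == 2))
  full <- cell_mixture(list(reg[["47,XX,+18"]]), 1)
  cnf <- expected_cn(full, bins)
  expect_true(all(cnf[bins$chrom == "18"] == 3))
  expect_true(all(cnf[bins$chrom == "Y"] == 0))
})

test_that("mixtures validate fractions and emptiness", {
  reg <- fixture_registry()
  expect_error(cell_mixture(list(), numeric(0)), "at least one")
  expect_error(cell_mixture(list(reg[["46,XY"]]), 0.9), "sum to 1")
  expect_error(
    cell_mixture(list(reg[["46,XY"]], reg[["47,XX,+21"]]), c(1.2, -0.2)),
    "non-negative"
  )
})

test_that("simulated counts are conserved exactly and reproducible", {
  ws <- fixture_workspace("A")
  m <- cell_mixture(list(fixture_registry()[["46,XY"]]), 1)
  b1 <- simulate_bincounts(m, ws$profile, ws$bins, seed = 33L)
  b2 <- simulate_bincounts(m, ws$profile, ws$bins, seed = 33L)
  b3 <- simulate_bincounts(m, ws$profile, ws$bins, seed = 34L)
  expect_identical(b1$counts, b2$counts)
  expect_false(identical(b1$counts, b3$counts))
  expect_equal(sum(b1$counts),
               round(ws$profile$total_reads * ws$profile$pf_fraction))
})

test_that("the generator is unbiased: euploid chromosomes average CN 2", {
  # with the GC bias switched off, raw counts relative to the flat
  # reference expectation measure the generator itself, before any
  # normalization
  ws <- fixture_workspace("A")
  p0 <- ws$profile
  p0$gc_bias_amp <- 0
  reg <- fixture_registry()
  m <- cell_mixture(list(reg[["46,XY"]]), 1, cell_count = 10L)
  exp_counts <- insilico_reference(ws$bins, p0)
  sel <- ws$bins$chrom == "21"
  cn21 <- vapply(1:60, function(r) {
    b <- simulate_bincounts(m, p0, ws$bins, derive_seed(51L, "unbias", r))
    2 * sum(b$counts[sel]) / sum(exp_counts[sel])
  }, numeric(1))
  expect_lt(abs(mean(cn21) - 2), 0.02)
})

test_that("mean CN response is linear in the mosaic fraction with unit slope", {
  ws <- fixture_workspace("A")
  reg <- fixture_registry()
  levels <- seq(0, 1, by = 0.1)
  reps <- 20L
  cn <- vapply(levels, function(f) {
    mean(vapply(seq_len(reps), function(r) {
      m <- if (f == 0) {
        cell_mixture(list(reg[["46,XY"]]), 1)
      } else if (f == 1) {
        cell_mixture(list(reg[["47,XX,+21"]]), 1)
      } else {
        cell_mixture(list(reg[["46,XY"]], reg[["47,XX,+21"]]), c(1 - f, f))
      }
      b <- simulate_bincounts(m, ws$profile, ws$bins,
                              derive_seed(77L, "lin", f, r))
      sample_chromosome_cn(b, ws$profile, ws$bins)[["21"]]
    }, numeric(1)))
  }, numeric(1))
  slope <- stats::coef(stats::lm(cn ~ levels))[2]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("X and Y mirror the mosaic fraction in expectation", {
  ws <- fixture_workspace("A")
  reg <- fixture_registry()
  f <- 0.4
  m <- cell_mixture(list(reg[["46,XY"]], reg[["47,XX,+18"]]), c(1 - f, f))
  cnxy <- rowMeans(vapply(1:25, function(r) {
    b <- simulate_bincounts(m, ws$profile, ws$bins, derive_seed(88L, "xy", r))
    sample_chromosome_cn(b, ws$profile, ws$bins)[c("X", "Y")]
  }, numeric(2)))
  expect_lt(abs(cnxy[["X"]] - (1 + f)), 0.03)
  expect_lt(abs(cnxy[["Y"]] - (1 - f)), 0.03)
})

test_that("the 120-sample design has the study structure", {
  ev <- fixture_design_eval("A")
  man <- ev$design$manifest
  expect_equal(nrow(man), 120L)
  expect_equal(sum(man$level > 0 & man$level < 1), 108L)
  expect_equal(sum(man$level == 1), 6L)
  expect_equal(sum(man$level == 0), 6L)
  per_set <- table(man$set)
  expect_equal(unname(per_set[c("tri18", "tri21")]), c(60L, 60L),
               ignore_attr = TRUE)
  # 9 mosaic levels x 6 replicates per set
  for (set in c("tri21", "tri18")) {
    lv <- table(man$level[man$set == set & man$level > 0 & man$level < 1])
    expect_equal(length(lv), 9L)
    expect_true(all(lv == 6L))
  }
  expect_equal(anyDuplicated(man$seed), 0L)
})

test_that("euploid replicates meet the calibrated noise target", {
  for (nm in c("A", "B")) {
    ws <- fixture_workspace(nm)
    target <- ws$profile$chrom_cn_sd_target
    expect_lt(abs(ws$calibration$pooled_sd - target) / target, 0.25)
  }
})

test_that("the segmental panel is 16 pure duplicates and the series spans the grid", {
  ws <- fixture_workspace("A")
  panel <- simulate_segmental_panel(ws$profile, ws$bins, seed = 2L)
  expect_length(panel, 16L)
  ids <- names(panel)
  lines <- sub("_d[12]$", "", ids)
  expect_equal(sort(unique(table(lines))), 2L, ignore_attr = TRUE)
  d1 <- panel[[grep("GM06918_d1", ids)]]
  d2 <- panel[[grep("GM06918_d2", ids)]]
  expect_false(d1$seed == d2$seed)
  expect_identical(d1$truth$karyotypes[[1]]$name,
                   d2$truth$karyotypes[[1]]$name)
})

test_that("reference sets are euploid and genome-proportional; n = 1 errors", {
  ws <- fixture_workspace("B")
  refs <- simulate_reference_set(ws$profile, ws$bins, n = 11L, seed = 9L)
  expect_length(refs, 11L)
  base <- build_baseline(refs, ws$bins)
  # genome-proportional shares under the reference karyotype
  lens <- hg19_chrom_lengths() * reference_cn()
  share <- lens / sum(lens)
  expect_lt(max(abs(base$baseline - share) / share), 0.02)
  expect_error(simulate_reference_set(ws$profile, ws$bins, n = 1L),
               "at least 2")
})

test_that("bin-count tables round-trip through TSV and reject bad schemas", {
  ws <- fixture_workspace("A")
  m <- cell_mixture(list(fixture_registry()[["46,XY"]]), 1)
  b <- simulate_bincounts(m, ws$profile, ws$bins, 5L, "roundtrip")
  path <- tempfile(fileext = ".tsv")
  write_bincounts_tsv(b, ws$bins, path)
  back <- read_bincounts_tsv(path)
  expect_equal(back$count, b$counts)
  expect_equal(nrow(back), nrow(ws$bins))
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(chrom = "1", start = 0, end = 10),
                     bad, sep = "\t", row.names = FALSE)
  expect_error(read_bincounts_tsv(bad), "count")
})
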