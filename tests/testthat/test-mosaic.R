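test_that("euploid-range arithmetic follows the stated rule", {
  vals <- c(2.0, 1.95, 2.05, 2.08, 1.92)
  r <- calibrate_euploid_range(vals, k = 3)
  expect_equal(r$lower, mean(vals) - 3 * stats::sd(vals))
  expect_equal(r$upper, mean(vals) + 3 * stats::sd(vals))
  synthetic <- c(1.95, 2.05, 2.0, 2.0, 2.0)
  r2 <- calibrate_euploid_range(synthetic, k = 3)
  expect_true(r2$lower < 2 && r2$upper > 2)
  expect_error(calibrate_euploid_range(rep(2, 10)), "zero variance")
  expect_error(calibrate_euploid_range(c(2, 2.1)), "at least 5")
})

test_that("the platform bands separate the paper's detectable levels", {
  # profile A: 2.1 inside the range, 2.2 outside; B: 2.2 inside, 2.3 out
  wsA <- fixture_workspace("A")
  expect_gt(wsA$calibration$band, 0.1)
  expect_lt(wsA$calibration$band, 0.2)
  wsB <- fixture_workspace("B")
  expect_gt(wsB$calibration$band, 0.2)
  expect_lt(wsB$calibration$band, 0.3)
})

test_that("chromosome categories split at the range and the half-copy rule", {
  rng <- list(lower = 1.85, upper = 2.15)
  expect_equal(classify_chromosome(2.0, rng), "disomic")
  expect_equal(classify_chromosome(2.3, rng), "mosaic-gain")
  expect_equal(classify_chromosome(3.0, rng), "full-gain")
  expect_equal(classify_chromosome(2.5, rng), "full-gain")
  expect_equal(classify_chromosome(1.7, rng), "mosaic-loss")
  expect_equal(classify_chromosome(1.5, rng), "full-loss")
})

test_that("sample classification follows the category rules and ignores order", {
  cats <- stats::setNames(rep("disomic", 24), chrom_names())
  expect_equal(classify_sample(cats)$category, "euploid")
  cats18 <- cats
  cats18[c("18", "X")] <- "mosaic-gain"
  cats18["Y"] <- "mosaic-loss"
  expect_equal(classify_sample(cats18)$category, "mosaic")
  expect_setequal(classify_sample(cats18)$offending, c("18", "X", "Y"))
  full <- cats
  full["21"] <- "full-gain"
  expect_equal(classify_sample(full)$category, "aneuploid")
  both <- cats18
  both["21"] <- "full-gain"
  expect_equal(classify_sample(both)$category, "mosaic-aneuploid")
  shuffled <- cats18[sample(names(cats18))]
  expect_equal(classify_sample(shuffled)$category,
               classify_sample(cats18)$category)
})

test_that("a pure XX line is disomic while sex mosaicism is flagged", {
  calib <- fixture_workspace("A")$calibration
  base <- calib$mean
  # normal male
  expect_true(all(classify_chromosomes(base, calib) == "disomic"))
  # pure 47,XX,+21-like: X = 2, Y = 0, chr21 = 3
  xx <- base
  xx[["X"]] <- 2.0; xx[["Y"]] <- 0.0; xx[["21"]] <- 3.0
  cats <- classify_chromosomes(xx, calib)
  expect_equal(unname(cats[c("X", "Y")]), c("disomic", "disomic"))
  expect_equal(unname(cats[["21"]]), "full-gain")
  # 90% mosaicism: X = 1.9, Y = 0.1 is NOT a normal complement
  mos <- base
  mos[["X"]] <- 1.9; mos[["Y"]] <- 0.1
  cats90 <- classify_chromosomes(mos, calib)
  expect_true(cats90[["X"]] != "disomic")
  expect_true(cats90[["Y"]] != "disomic")
  # 10% mosaicism stays inside the band on both sex chromosomes
  low <- base
  low[["X"]] <- 1.1; low[["Y"]] <- 0.9
  expect_true(all(classify_chromosomes(low, calib)[c("X", "Y")] == "disomic"))
})

test_that("reference curves summarize levels and stay monotone", {
  ev <- fixture_design_eval("A")
  man <- ev$design$manifest
  sel <- man$set == "tri21"
  df <- data.frame(level = man$level[sel],
                   cn = ev$eval$cn_mat[match("21", chrom_names()), sel])
  curve <- build_reference_curve(df)
  expect_equal(curve$level, seq(0, 1, by = 0.1))
  expect_equal(curve$n, c(3, rep(6, 9), 3))
  expect_lt(abs(curve$mean_cn[curve$level == 0] - 2), 0.05)
  expect_true(all(diff(curve$mean_cn) > 0))
  expect_equal(stats::cor(curve$mean_cn, curve$level, method = "spearman"), 1)
  expect_error(build_reference_curve(data.frame(level = 0.1, cn = 2)),
               ">= 2 replicates")
})

test_that("LOD logic: detection requires consistency across larger levels", {
  rng <- list(lower = -0.15, upper = 0.15)
  lv <- list("0.1" = c(0.09, 0.11, 0.10, 0.1, 0.09, 0.12),
             "0.2" = c(0.19, 0.21, 0.20, 0.2, 0.22, 0.18),
             "0.3" = c(0.29, 0.31, 0.30, 0.3, 0.28, 0.32))
  eu <- c(-0.01, 0.01, 0, 0.02, -0.02, 0)
  res <- determine_lod(lv, eu, rng)
  expect_equal(res$lod, 0.2)
  expect_false(res$levels$detected[1])
  expect_true(all(res$levels$detected[2:3]))
  # identical distributions at all levels: undefined
  null_lv <- list("0.1" = eu, "0.2" = eu + 1e-9, "0.3" = eu - 1e-9)
  expect_true(is.na(determine_lod(null_lv, eu, rng)$lod))
  expect_error(determine_lod(lv, eu[1:2], rng), ">= 3 euploid")
})

test_that("the pure t-test rule is available as a method", {
  rng <- list(lower = -0.5, upper = 0.5)
  lv <- list("0.1" = c(0.09, 0.11, 0.10, 0.1, 0.09, 0.12),
             "0.2" = c(0.19, 0.21, 0.20, 0.2, 0.22, 0.18))
  eu <- c(-0.01, 0.01, 0, 0.02, -0.02, 0)
  # range rule finds nothing (wide band); t-test finds 0.1
  expect_true(is.na(determine_lod(lv, eu, rng, method = "range")$lod))
  expect_equal(determine_lod(lv, eu, rng, method = "ttest")$lod, 0.1)
})

test_that("estimated mosaic fraction recovers truth at profile-A noise", {
  # scaled-down recovery check; the full 200-replicate sweep runs in the
  # acceptance suite
  ws <- fixture_workspace("A")
  reg <- fixture_registry()
  for (f in c(0.3, 0.7)) {
    fhat <- vapply(1:60, function(r) {
      m <- cell_mixture(list(reg[["46,XY"]], reg[["47,XX,+21"]]), c(1 - f, f))
      b <- simulate_bincounts(m, ws$profile, ws$bins,
                              derive_seed(15L, "rec", f, r))
      sample_chromosome_cn(b, ws$profile, ws$bins)[["21"]] - 2
    }, numeric(1))
    expect_lt(abs(mean(fhat) - f), 0.02)
    expect_lt(sqrt(mean((fhat - f)^2)), 0.06)
  }
})
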