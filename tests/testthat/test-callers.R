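make_profile_df <- function(cn_by_chrom) {
  # minimal norm_profile-shaped frame
  rows <- lapply(names(cn_by_chrom), function(ch) {
    cn <- cn_by_chrom[[ch]]
    nb <- length(cn)
    data.frame(chrom = ch, start = (seq_len(nb) - 1) * 1e6,
               end = seq_len(nb) * 1e6,
               gc = 0.45, ratio = cn / 2,
               cn = cn, masked = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("norm_profile", "data.frame")
  out
}

test_that("clean integer states are called exactly, on both fallback modes", {
  for (literal in c(TRUE, FALSE)) {
    cfg <- gaussian_caller_config(literal_fallback_rule = literal)
    np <- make_profile_df(list("1" = rep(2, 40), "21" = rep(3, 40),
                               "9" = rep(1, 40)))
    expect_equal(call_chromosome_gaussian(np, "1", cfg)$state, 2L)
    expect_equal(call_chromosome_gaussian(np, "1", cfg)$label, "disomic")
    expect_equal(call_chromosome_gaussian(np, "21", cfg)$state, 3L)
    expect_equal(call_chromosome_gaussian(np, "21", cfg)$label, "gain")
    expect_equal(call_chromosome_gaussian(np, "9", cfg)$label, "loss")
  }
})

test_that("the literal ambiguity rule routes clean calls through the median fallback", {
  np <- make_profile_df(list("1" = rep(2, 40)))
  call <- call_chromosome_gaussian(np, "1", gaussian_caller_config())
  expect_equal(call$call_path, "median-fallback")
  inv <- call_chromosome_gaussian(
    np, "1", gaussian_caller_config(literal_fallback_rule = FALSE))
  expect_equal(inv$call_path, "pdf")
  expect_equal(call$state, inv$state)
})

test_that("a median of exactly 2.5 is not a gain (strict threshold)", {
  # bins midway between states 2 and 3 tie the state scores exactly, so
  # the literal rule (margin > 0.011) keeps the pdf path and the
  # inverted rule exercises the median fallback; both stay disomic
  # because the gain threshold is strictly > 2.5
  np <- make_profile_df(list("5" = rep(2.5, 40)))
  lit <- call_chromosome_gaussian(np, "5", gaussian_caller_config())
  expect_equal(lit$call_path, "pdf")
  expect_equal(lit$label, "disomic")
  inv <- call_chromosome_gaussian(
    np, "5", gaussian_caller_config(literal_fallback_rule = FALSE))
  expect_equal(inv$call_path, "median-fallback")
  expect_equal(inv$label, "disomic")
  expect_equal(inv$state, 2L)
  expect_equal(inv$cn_estimate, 2.5)
})

test_that("the Gaussian caller matches brute-force state scoring", {
  # oracle: enumerate the 5 state densities bin by bin, average
  # normalized posteriors, argmax
  brute_force_call <- function(cn, sigma = 0.33) {
    scores <- sapply(0:4, function(s) {
      d <- sapply(cn, function(v) {
        dens <- stats::dnorm(v, 0:4, sigma)
        (dens / sum(dens))[s + 1]
      })
      mean(d)
    })
    which.max(scores) - 1L
  }
  set.seed(42)
  for (s in c(1, 2, 3)) {
    for (rep in 1:5) {
      cn <- stats::rnorm(30, s, 0.15)
      np <- make_profile_df(list("7" = cn))
      call <- call_chromosome_gaussian(
        np, "7", gaussian_caller_config(literal_fallback_rule = FALSE))
      expect_equal(call$state, brute_force_call(cn))
      expect_equal(call$state, s)
    }
  }
})

test_that("too few bins produce a no-call", {
  np <- make_profile_df(list("1" = rep(2, 40)))
  np <- np[1:3, ]
  class(np) <- c("norm_profile", "data.frame")
  call <- call_chromosome_gaussian(np, "1")
  expect_equal(call$call_path, "no-call")
  expect_true(is.na(call$state))
})

test_that("the baseline caller estimates CN from read fractions", {
  ws <- fixture_workspace("B")
  base <- ws$baseline
  expect_equal(sum(base$baseline), 1)
  reg <- fixture_registry()
  # euploid: all chromosomes about their reference CN, nothing flagged
  b <- simulate_bincounts(cell_mixture(list(reg[["46,XY"]]), 1),
                          ws$profile, ws$bins, 71L)
  calls <- call_sample(b, ws$profile, ws$bins, baseline = base)
  aut <- calls$chrom %in% as.character(1:22)
  expect_true(all(abs(calls$cn_estimate[aut] - 2) < 0.1))
  expect_true(all(calls$label == "disomic"))
  # pure trisomy 21: chr21 about 3, at the printed strict > 3 boundary
  b21 <- simulate_bincounts(cell_mixture(list(reg[["47,XX,+21"]]), 1),
                            ws$profile, ws$bins, 72L)
  c21 <- call_chromosome_baseline(b21, base, ws$bins, "21")
  expect_lt(abs(c21$cn_estimate - 3), 0.15)
  # 30% mosaic: quantified at about 2.3, never a full discrete gain
  b30 <- simulate_bincounts(
    cell_mixture(list(reg[["46,XY"]], reg[["47,XX,+21"]]), c(0.7, 0.3)),
    ws$profile, ws$bins, 73L)
  c30 <- call_chromosome_baseline(b30, base, ws$bins, "21")
  expect_lt(abs(c30$cn_estimate - 2.3), 0.12)
  expect_equal(c30$label, "disomic")
  expect_error(call_chromosome_baseline(b30, base, ws$bins, "MT"), "absent")
})

test_that("baselines require two samples and reproduce identical inputs", {
  ws <- fixture_workspace("B")
  m <- cell_mixture(list(fixture_registry()[["46,XY"]]), 1)
  b <- simulate_bincounts(m, ws$profile, ws$bins, 81L)
  expect_error(build_baseline(list(b), ws$bins), "at least 2")
  base2 <- build_baseline(list(b, b), ws$bins)
  expect_equal(base2$baseline, chromosome_read_fractions(b, ws$bins),
               tolerance = 1e-12)
})

test_that("monosomy mixtures mirror trisomy mixtures about CN 2", {
  # caller symmetry: expected CN 2 - f via a monosomy-21 karyotype
  ws <- fixture_workspace("A")
  reg <- fixture_registry()
  mono21 <- karyotype_spec("45,XY,-21", x_copies = 1L, y_copies = 1L)
  mono21$copies["21"] <- 1L
  f <- 0.4
  up <- cell_mixture(list(reg[["46,XY"]], reg[["47,XX,+21"]]), c(1 - f, f))
  dn <- cell_mixture(list(reg[["46,XY"]], mono21), c(1 - f, f))
  cn_up <- mean(vapply(1:10, function(r) {
    b <- simulate_bincounts(up, ws$profile, ws$bins, derive_seed(91L, "u", r))
    sample_chromosome_cn(b, ws$profile, ws$bins)[["21"]]
  }, numeric(1)))
  cn_dn <- mean(vapply(1:10, function(r) {
    b <- simulate_bincounts(dn, ws$profile, ws$bins, derive_seed(91L, "d", r))
    sample_chromosome_cn(b, ws$profile, ws$bins)[["21"]]
  }, numeric(1)))
  expect_lt(abs((cn_up - 2) + (cn_dn - 2)), 0.03)
})
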