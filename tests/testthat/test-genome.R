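test_that("bin grid partitions every chromosome exactly once", {
  g <- genome_build(bin_size_bp = 1000000L, scale = 0.1)
  bins <- make_bins(g, seed = 1L)
  lens <- tapply(bins$end - bins$start, bins$chrom, sum)
  expect_equal(as.numeric(lens[g$chrom_names]),
               as.numeric(g$chrom_lengths_bp))
  # contiguous, non-overlapping, half-open
  for (ch in c("1", "21")) {
    sub <- bins[bins$chrom == ch, ]
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])
    expect_true(all(sub$end > sub$start))
  }
  expect_equal(nrow(bins),
               sum(ceiling(g$chrom_lengths_bp / g$bin_size_bp)))
})

test_that("an exact-multiple chromosome gets exact bins, a remainder a short last bin", {
  # 10 Mb / 1 Mb and 10.5 Mb / 1 Mb equivalents via scaled lengths
  g <- genome_build(bin_size_bp = 1000000L, scale = 0.1)
  # chr20 is 63,025,520 bp -> scaled 6,302,552 -> 7 bins, last short
  b20 <- subset(make_bins(g, seed = 1L), chrom == "20")
  expect_equal(nrow(b20), 7L)
  expect_equal(b20$end[7] - b20$start[7], 302552)
  expect_lt(b20$weight[7], 1)
  expect_equal(b20$weight[1], 1)
})

test_that("the GC track is deterministic per seed and bounded", {
  g <- genome_build(bin_size_bp = 1000000L, scale = 0.1)
  b1 <- make_bins(g, seed = 7L)
  b2 <- make_bins(g, seed = 7L)
  b3 <- make_bins(g, seed = 8L)
  expect_identical(b1$gc, b2$gc)
  expect_false(identical(b1$gc, b3$gc))
  expect_true(all(b1$gc >= 0.30 & b1$gc <= 0.60))
})

test_that("bin size below the supported minimum is rejected", {
  g <- genome_build(bin_size_bp = 50000L, scale = 0.1)
  expect_error(make_bins(g, 1L), "100,000")
})

test_that("karyotype registry holds the study lines with correct copy states", {
  reg <- karyotype_registry()
  expect_true(all(c("46,XY", "47,XX,+21", "47,XX,+18", "GM08331",
                    "GM06918") %in% names(reg)))
  xy <- reg[["46,XY"]]$copies
  expect_true(all(xy[as.character(1:22)] == 2))
  expect_equal(unname(xy[c("X", "Y")]), c(1L, 1L))
  t21 <- reg[["47,XX,+21"]]$copies
  expect_equal(unname(t21[c("21", "X", "Y")]), c(3L, 2L, 0L))
  t18 <- reg[["47,XX,+18"]]$copies
  expect_equal(unname(t18[c("18", "X", "Y")]), c(3L, 2L, 0L))
  # panel: 8 lines, deletion sizes spanning 4.5-17 Mb
  sizes <- sort(vapply(segmental_panel_names(), function(nm) {
    segment_length_mb(primary_deletion(reg[[nm]]))
  }, numeric(1)))
  expect_length(sizes, 8L)
  expect_equal(min(sizes), 4.5)
  expect_equal(round(max(sizes)), 17)
})

test_that("segment lengths follow the printed coordinates and are bin-size free", {
  reg <- karyotype_registry()
  s13 <- primary_deletion(reg[["GM08331"]])
  s21 <- primary_deletion(reg[["GM06918"]])
  expect_equal(segment_length_mb(s13), 12.104601)
  expect_equal(segment_length_mb(s21), 17.31694)
  expect_equal(segment_length_mb(segment_spec("1", 100, 100 + 1)), 2e-6)
})

test_that("karyotype CN tracks map copies onto bins by midpoint", {
  bins <- tiny_bins()
  reg <- fixture_registry()
  cn <- karyotype_cn_track(reg[["46,XY"]], bins)
  expect_true(all(cn[!(bins$chrom %in% c("X", "Y"))] == 2))
  expect_true(all(cn[bins$chrom == "X"] == 1))
  expect_true(all(cn[bins$chrom == "Y"] == 1))
  cn21 <- karyotype_cn_track(reg[["47,XX,+21"]], bins)
  expect_true(all(cn21[bins$chrom == "21"] == 3))
  expect_true(all(cn21[bins$chrom == "Y"] == 0))
  # GM08331 on the full grid: a chr13 bin whose midpoint is at ~100 Mb
  ws <- fixture_workspace("A")
  cnG <- karyotype_cn_track(reg[["GM08331"]], ws$bins)
  mid <- (ws$bins$start + ws$bins$end) / 2
  hit <- ws$bins$chrom == "13" & abs(mid - 1.0e8) < 5e5
  expect_true(all(cnG[hit] == 1))
  out <- ws$bins$chrom == "13" & mid < 98e6
  expect_true(all(cnG[out] == 2))
})

test_that("segments outside chromosome bounds are rejected", {
  expect_error(
    karyotype_spec("bad", segments = list(segment_spec("21", 1, 9e7))),
    "outside"
  )
})

test_that("the registry round-trips through YAML", {
  reg <- karyotype_registry()
  path <- tempfile(fileext = ".yaml")
  write_registry_yaml(reg, path)
  back <- read_registry_yaml(path)
  expect_equal(names(back), names(reg))
  expect_equal(back[["47,XX,+18"]]$copies, reg[["47,XX,+18"]]$copies)
  expect_equal(back[["GM06918"]]$segments[[2]]$start0,
               reg[["GM06918"]]$segments[[2]]$start0)
})
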