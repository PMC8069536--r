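#' Reference genome grid
#'
#' A `genome_build` holds the chromosome names and lengths over which the
#' per-bin analysis grid is laid out. The default is the hg19 assembly
#' (chromosomes 1-22, X, Y with their standard lengths). A scaled-down
#' genome (`scale < 1`) is available for fast unit tests; all
#' fraction-based logic downstream is scale-free.
#'
#' @param bin_size_bp width of the analysis bins in bp (platform-specific).
#' @param scale multiplier applied to every chromosome length (default 1,
#'   i.e. full hg19 lengths). Must be in (0, 1].
#' @return an object of class `genome_build` with fields `chrom_names`,
#'   `chrom_lengths_bp`, `bin_size_bp`.
#' @export
genome_build <- function(bin_size_bp = 900000L, scale = 1) {
  stopifnot(is.numeric(bin_size_bp), length(bin_size_bp) == 1L)
  if (bin_size_bp <= 0) {
    stop("bin_size_bp must be positive", call. = FALSE)
  }
  if (scale <= 0 || scale > 1) {
    stop("scale must be in (0, 1]", call. = FALSE)
  }
  lengths <- round(hg19_chrom_lengths() * scale)
  structure(
    list(
      chrom_names = names(lengths),
      chrom_lengths_bp = lengths,
      bin_size_bp = as.integer(bin_size_bp)
    ),
    class = "genome_build"
  )
}

#' hg19 chromosome lengths (bp)
#'
#' Standard hg19/GRCh37 chromosome sizes for chromosomes 1-22, X, Y.
#' @return named numeric vector of 24 lengths.
#' @export
hg19_chrom_lengths <- function() {
  c(
    "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
    "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
    "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
    "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
    "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
    "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566
  )
}

#' Chromosome names in canonical order
#' @return character vector "1".."22", "X", "Y".
#' @export
chrom_names <- function() c(as.character(1:22), "X", "Y")

#' Lay out the analysis bin grid with a synthetic GC track
#'
#' Partitions each chromosome into contiguous, non-overlapping bins of
#' `bin_size_bp` (0-based half-open intervals; the terminal bin may be
#' shorter and is down-weighted by its length). The GC fraction per bin is
#' drawn from a seeded smooth spatial process (a low-pass-filtered random
#' walk squashed into \[0.30, 0.60\]) standing in for assembly GC content.
#'
#' @param genome a [genome_build()].
#' @param seed integer seed; the GC track is deterministic per
#'   (genome, seed).
#' @return data frame of class `lp_bins` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `gc`, `weight` (bin length / bin size).
#' @export
make_bins <- function(genome, seed = 1L) {
  stopifnot(inherits(genome, "genome_build"))
  if (genome$bin_size_bp < 1e5) {
    stop("bin_size_bp must be at least 100,000 bp", call. = FALSE)
  }
  bs <- genome$bin_size_bp
  pieces <- with_seed(seed, lapply(seq_along(genome$chrom_names), function(i) {
    len <- genome$chrom_lengths_bp[[i]]
    nb <- ceiling(len / bs)
    start <- (seq_len(nb) - 1) * bs
    end <- pmin(start + bs, len)
    data.frame(
      chrom = genome$chrom_names[[i]],
      start = start,
      end = end,
      gc = smooth_gc_track(nb),
      weight = (end - start) / bs,
      stringsAsFactors = FALSE
    )
  }))
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  class(bins) <- c("lp_bins", "data.frame")
  bins
}

# Low-pass-filtered random walk mapped smoothly into [0.30, 0.60].
smooth_gc_track <- function(nb, half_width = 0.15, center = 0.45) {
  if (nb == 1L) {
    return(center)
  }
  walk <- cumsum(stats::rnorm(nb))
  k <- min(9L, nb)
  kern <- rep(1 / k, k)
  padded <- c(rep(walk[1], k), walk, rep(walk[nb], k))
  sm <- stats::filter(padded, kern, sides = 2)
  sm <- as.numeric(sm)[(k + 1):(k + nb)]
  z <- (sm - mean(sm)) / max(stats::sd(sm), 1e-12)
  center + half_width * tanh(z / 2)
}

#' Segmental abnormality specification
#'
#' Coordinates are given 1-based inclusive, as printed in cytogenetic
#' reports (Coriell style), and are converted internally to 0-based
#' half-open; the segment length is therefore `end - start + 1` bp.
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @param copies integer copy number of the segment (1 for a heterozygous
#'   deletion).
#' @return object of class `segment_spec` with 0-based half-open
#'   `start0`/`end0` alongside the printed coordinates.
#' @export
segment_spec <- function(chrom, start, end, copies = 1L) {
  if (end <= start) {
    stop("segment end must exceed start", call. = FALSE)
  }
  if (!copies %in% 0:4) {
    stop("segment copies must be in 0..4", call. = FALSE)
  }
  structure(
    list(
      chrom = as.character(chrom),
      start = start, end = end,
      start0 = start - 1, end0 = end,
      copies = as.integer(copies)
    ),
    class = "segment_spec"
  )
}

#' Segment length in megabases
#'
#' `(end - start + 1) / 1e6` for the printed 1-based inclusive
#' coordinates; invariant to bin size.
#' @param s a [segment_spec()].
#' @return length in Mb.
#' @export
segment_length_mb <- function(s) {
  stopifnot(inherits(s, "segment_spec"))
  (s$end - s$start + 1) / 1e6
}

#' Cell-line karyotype
#'
#' The ground-truth genome of one cell line: an integer copy state per
#' autosome, X and Y copies, plus optional segmental abnormalities.
#'
#' @param name karyotype label, e.g. "46,XY".
#' @param autosome_copies default copy state of every autosome.
#' @param x_copies,y_copies sex-chromosome copies.
#' @param trisomy optional autosome name carried at `autosome_copies + 1`.
#' @param segments list of [segment_spec()].
#' @return object of class `karyotype_spec` with a `copies` vector over
#'   all 24 chromosomes.
#' @export
karyotype_spec <- function(name, autosome_copies = 2L, x_copies = 1L,
                           y_copies = 1L, trisomy = NULL, segments = list()) {
  copies <- stats::setNames(rep(as.integer(autosome_copies), 24L), chrom_names())
  copies["X"] <- as.integer(x_copies)
  copies["Y"] <- as.integer(y_copies)
  if (!is.null(trisomy)) {
    copies[as.character(trisomy)] <- copies[as.character(trisomy)] + 1L
  }
  if (any(copies < 0 | copies > 4)) {
    stop("chromosome copies must be in 0..4", call. = FALSE)
  }
  lens <- hg19_chrom_lengths()
  for (s in segments) {
    stopifnot(inherits(s, "segment_spec"))
    if (!s$chrom %in% chrom_names() || s$end > lens[[s$chrom]]) {
      stop("segment outside chromosome bounds: ", s$chrom, call. = FALSE)
    }
  }
  structure(
    list(name = name, copies = copies, segments = segments),
    class = "karyotype_spec"
  )
}

#' Registry of the study karyotypes
#'
#' The euploid male line, the two trisomic female lines used for the
#' whole-chromosome mosaicism mixtures, the two Coriell
#' segmental-deletion lines with their printed hg19 coordinates, and a
#' panel of eight cell lines whose deletion sizes span 4.5-17 Mb (six
#' sizes are fixed by the study; the remaining two panel members are
#' placed on chromosomes 4 and 2 at 6.5 and 14 Mb).
#'
#' @return named list of [karyotype_spec()] objects.
#' @export
karyotype_registry <- function() {
  reg <- list(
    "46,XY" = karyotype_spec("46,XY"),
    "47,XX,+21" = karyotype_spec("47,XX,+21", x_copies = 2L, y_copies = 0L,
                                 trisomy = "21"),
    "47,XX,+18" = karyotype_spec("47,XX,+18", x_copies = 2L, y_copies = 0L,
                                 trisomy = "18"),
    GM08331 = karyotype_spec("GM08331", segments = list(
      segment_spec("13", 98158969, 110263569, 1L),
      segment_spec("21", 27316123, 29519188, 1L)
    )),
    GM06918 = karyotype_spec("GM06918", segments = list(
      segment_spec("6", 162784828, 162990795, 1L),
      segment_spec("21", 15275679, 32592618, 1L)
    ))
  )
  # Segmental-resolution panel. Coordinates of the six non-Coriell lines
  # are synthetic (placed on 9 Mb multiples); sizes follow the study.
  panel <- list(
    SEG_4.5_CH1  = list(chrom = "1",  start0 = 45e6, size = 4.50e6),
    SEG_5.04_CH15 = list(chrom = "15", start0 = 54e6, size = 5.04e6),
    SEG_6.5_CH4  = list(chrom = "4",  start0 = 90e6, size = 6.50e6),
    SEG_7.9_CH6  = list(chrom = "6",  start0 = 99e6, size = 7.90e6),
    SEG_10_CH3   = list(chrom = "3",  start0 = 90e6, size = 10.0e6),
    SEG_14_CH2   = list(chrom = "2",  start0 = 90e6, size = 14.0e6)
  )
  for (nm in names(panel)) {
    p <- panel[[nm]]
    reg[[nm]] <- karyotype_spec(nm, segments = list(
      segment_spec(p$chrom, p$start0 + 1, p$start0 + p$size, 1L)
    ))
  }
  reg
}

#' Names of the eight segmental-panel cell lines
#'
#' Six synthetic lines plus the two Coriell lines (12 and 17 Mb).
#' @return character vector of length 8.
#' @export
segmental_panel_names <- function() {
  c("SEG_4.5_CH1", "SEG_5.04_CH15", "SEG_6.5_CH4", "SEG_7.9_CH6",
    "SEG_10_CH3", "SEG_14_CH2", "GM08331", "GM06918")
}

#' Primary (size-defining) deletion of a panel line
#'
#' For the Coriell lines this is the deletion whose size names the line
#' in the study (12 Mb on chr13 for GM08331; 17 Mb on chr21 for
#' GM06918); for the synthetic panel lines it is their single deletion.
#'
#' @param k a [karyotype_spec()] carrying at least one segment.
#' @return a [segment_spec()].
#' @export
primary_deletion <- function(k) {
  stopifnot(inherits(k, "karyotype_spec"), length(k$segments) > 0)
  sizes <- vapply(k$segments, segment_length_mb, numeric(1))
  if (k$name == "GM08331") {
    return(k$segments[[which(vapply(k$segments, `[[`, "", "chrom") == "13")]])
  }
  if (k$name == "GM06918") {
    return(k$segments[[which(vapply(k$segments, `[[`, "", "chrom") == "21")]])
  }
  k$segments[[which.max(sizes)]]
}

#' Per-bin integer copy state of a karyotype
#'
#' Autosomal bins receive the karyotype's autosome copies, X/Y bins its
#' sex-chromosome copies, and bins whose midpoint lies inside a segment
#' receive that segment's copies.
#'
#' @param k a [karyotype_spec()].
#' @param bins the bin grid from [make_bins()].
#' @return integer vector of per-bin copy states aligned to `bins`.
#' @export
karyotype_cn_track <- function(k, bins) {
  stopifnot(inherits(k, "karyotype_spec"))
  cn <- unname(k$copies[bins$chrom])
  mid <- (bins$start + bins$end) / 2
  for (s in k$segments) {
    hit <- bins$chrom == s$chrom & mid >= s$start0 & mid < s$end0
    cn[hit] <- s$copies
  }
  cn
}

#' Reference copy state per chromosome
#'
#' The declared reference karyotype of the assay (a 46,XY male): CN 2 on
#' autosomes and CN 1 on X and Y. Used to build the in-silico reference
#' and as the baseline each chromosome call is interpreted against.
#' @return named integer vector over the 24 chromosomes.
#' @export
reference_cn <- function() {
  stats::setNames(c(rep(2L, 22L), 1L, 1L), chrom_names())
}

#' Write a bin grid as BED
#'
#' BED columns: chrom, start, end, name, gc. Plain text, tab separated.
#' @param bins an `lp_bins` data frame.
#' @param path output file.
#' @export
write_bins_bed <- function(bins, path) {
  df <- data.frame(
    chrom = bins$chrom, start = bins$start, end = bins$end,
    name = sprintf("bin_%06d", seq_len(nrow(bins))), gc = round(bins$gc, 4)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize the karyotype registry to YAML
#'
#' @param registry list from [karyotype_registry()].
#' @param path output YAML file.
#' @export
write_registry_yaml <- function(registry, path) {
  out <- lapply(registry, function(k) {
    list(
      name = k$name,
      copies = as.list(k$copies),
      segments = lapply(k$segments, function(s) {
        list(chrom = s$chrom, start = s$start, end = s$end,
             copies = s$copies)
      })
    )
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Load a karyotype registry from YAML
#'
#' @param path YAML file written by [write_registry_yaml()].
#' @return named list of [karyotype_spec()] objects.
#' @export
read_registry_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(x) {
    copies <- unlist(x$copies)
    k <- karyotype_spec(
      x$name,
      autosome_copies = 2L,
      x_copies = copies[["X"]], y_copies = copies[["Y"]],
      segments = lapply(x$segments, function(s) {
        segment_spec(s$chrom, s$start, s$end, s$copies)
      })
    )
    k$copies <- stats::setNames(as.integer(copies[chrom_names()]), chrom_names())
    k
  })
  names(out) <- names(raw)
  out
}
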