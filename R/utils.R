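# Internal helpers: seeded evaluation, seed derivation, small file utilities.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Deterministic 31-bit hash (djb2 over the key string, modulo a prime
#' below 2^31) so that every sample/stage gets an independent,
#' reproducible stream from one master seed.
#'
#' @param master integer master seed.
#' @param ... key components (coerced to character).
#' @return integer in \[0, 2^31).
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(format(master), vapply(list(...), format, "")), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(key)) {
    h <- (h * 33 + ch) %% 2147483629
  }
  as.integer(h)
}

# Short content hash (polynomial rolling hash, 31-bit) used to stamp
# output files.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x)), collapse = "\n"))
  h <- 17
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483629
  }
  sprintf("%08x", as.integer(h))
}

#' Write a result table as TSV with a provenance header
#'
#' All pipeline outputs are plain TSV with one comment line recording
#' the seed and a short config hash, so a rerun with the same seed is
#' byte-identical and diffable.
#'
#' @param df data frame to write.
#' @param path output file.
#' @param seed seed recorded in the header.
#' @param config optional object whose hash is recorded.
#' @export
write_tsv_stamped <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lpmosaic seed=%s config=%s", format(seed),
                     if (is.null(config)) "NA" else config_hash(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_stamped <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
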