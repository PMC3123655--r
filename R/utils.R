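# Small shared helpers.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a bounded substream seed from a base seed
#' @keywords internal
substream_seed <- function(seed, k) {
  (as.numeric(seed) * 1009 + k * 9973) %% 2147483647
}

#' Write a TSV with a header row
#' @keywords internal
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
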