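`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child RNG seed from a root seed
#'
#' Each stochastic pipeline stage draws its own seed from the root seed so
#' that stages are reproducible independently of how many random numbers
#' earlier stages consumed. A multiplicative congruential step keeps the
#' result a valid 32-bit integer.
#'
#' @param seed Integer root seed.
#' @param stream Integer stream index (one per stage).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(stream %% 8 + 1)) {
    s <- (s * 48271) %% 2147483647
  }
  as.integer((s + 104729 * as.double(stream)) %% 2147483647)
}

# GRanges from a chrom/start/end data.frame (0-based half-open in, 1-based in
# the GRanges; converted back symmetrically on the way out).
df_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

assert_intervals <- function(df, what = "interval") {
  bad <- which(df$end <= df$start | df$start < 0)
  if (length(bad)) {
    stop(sprintf("%s %d: end <= start or negative start (%s:%d-%d)",
                 what, bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(df)
}
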