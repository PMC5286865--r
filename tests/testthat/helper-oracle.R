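# Brute-force longest-match oracle: for every start position, grow the
# substring until fixed-string search over the reference set fails. N
# matches nothing on either side (reference N masked, query N stops growth).
brute_profile <- function(refs, S) {
  refs <- gsub("N", "#", refs)
  n <- nchar(S)
  vapply(seq_len(n), function(i) {
    best <- 0L
    for (k in seq_len(n - i + 1L)) {
      sub <- substr(S, i, i + k - 1L)
      if (grepl("N", sub, fixed = TRUE)) break
      if (any(grepl(sub, refs, fixed = TRUE))) best <- k else break
    }
    best
  }, integer(1))
}

rand_dna <- function(n, alpha = c("A", "C", "G", "T")) {
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

# memoized synthetic genomes shared across test files
.synth_cache <- new.env(parent = emptyenv())
synth_genome <- function(nGenes = 30L, seed = 5L, ...) {
  key <- paste(nGenes, seed, ...)
  if (is.null(.synth_cache[[key]])) {
    .synth_cache[[key]] <-
      synthesizeGenome(syntheticSpec(nGenes = nGenes, seed = seed, ...))
  }
  .synth_cache[[key]]
}
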