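#' @include AllGenerics.R
NULL

# Normalize sequences for matching: uppercase; anything outside ACGT -> N.
norm_seq <- function(s) gsub("[^ACGT]", "N", toupper(as.character(s)))

index_ptr <- function(index) {
  # rebuild the compiled automaton if the external pointer did not survive
  # serialization
  p <- index@ptr
  if (!methods::is(p, "externalptr") || identical(.sam_node_count_safe(p), NA_integer_)) {
    p <- .sam_build(index@seqs)
  }
  p
}

.sam_node_count_safe <- function(p) {
  tryCatch(.sam_node_count(p), error = function(e) NA_integer_)
}

#' Build a substring-query index over a reference set
#'
#' Compiles the reference sequences into a suffix automaton supporting
#' exact longest-prefix-match queries in amortized constant time per query
#' position. Matches never span two reference sequences; N matches nothing
#' on either side. Answers are independent of the order in which references
#' are supplied.
#'
#' @param references named character vector (or [Biostrings::DNAStringSet])
#'   of reference sequences; names are the element identifiers.
#' @return an [ArsiIndex].
#' @export
#' @examples
#' idx <- buildIndex(c(a = "ACGTA"))
#' matchLengthProfile(idx, "ACGTACGT")
buildIndex <- function(references) {
  seqs <- norm_seq(references)
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) stop("empty reference")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("ref", seq_along(seqs))
  methods::new("ArsiIndex",
    ids = ids, seqs = unname(seqs),
    totalLength = sum(nchar(seqs)),
    ptr = .sam_build(unname(seqs)))
}

#' Per-position longest-match profile
#'
#' For each position i of `S`, the length L(i) of the longest substring of
#' `S` starting at i that occurs contiguously in at least one reference
#' sequence. Every profile satisfies 0 <= L(i) <= |S| - i + 1 and
#' L(i+1) >= L(i) - 1.
#'
#' @param index an [ArsiIndex].
#' @param S query sequence (character scalar).
#' @return integer vector of length `nchar(S)`.
#' @export
matchLengthProfile <- function(index, S) {
  stopifnot(methods::is(index, "ArsiIndex"))
  S <- norm_seq(S)
  if (length(S) != 1L || nchar(S) < 1L) stop("S must be one non-empty sequence")
  .sam_match_profile(index_ptr(index), S)
}

#' Longest match starting at one position
#'
#' @param index an [ArsiIndex].
#' @param S query sequence.
#' @param i 1-based position in `S`.
#' @return integer match length (0 if `S[i]` occurs nowhere).
#' @export
longestMatchAt <- function(index, S, i) {
  n <- nchar(S)
  if (i < 1L || i > n) stop("position out of range: ", i)
  matchLengthProfile(index, S)[i]
}

#' ARSI score of a sequence
#'
#' The mean of the per-position longest-match lengths: the Average
#' Repetitive Substring Index of `S` against the indexed reference set.
#'
#' @inheritParams matchLengthProfile
#' @return non-negative numeric scalar.
#' @export
#' @examples
#' arsiScore(buildIndex(c(a = "ACGTA")), "ACGTACGT")  # 3
arsiScore <- function(index, S) {
  mean(matchLengthProfile(index, S))
}

#' Leave-one-out ARSI scores for a set of elements
#'
#' Scores every element against an index over all the other elements. With
#' `exclude = "gene"` (default) all elements sharing a `gene_id` are
#' excluded together, so the duplicated transcripts of a multi-intron gene
#' can never match themselves; `exclude = "element"` excludes only the
#' element itself. Computed exactly in two linear passes (prefix and suffix
#' automata); results are independent of input order.
#'
#' @param elements `data.frame` with columns `element_id`, `gene_id`,
#'   `sequence`.
#' @param exclude `"gene"` or `"element"`.
#' @return the input `data.frame` (minus `sequence`) with columns
#'   `length_nt` and `arsi`, in the input row order.
#' @export
arsiLeaveOneOut <- function(elements, exclude = c("gene", "element")) {
  exclude <- match.arg(exclude)
  stopifnot(all(c("element_id", "gene_id", "sequence") %in% names(elements)))
  if (nrow(elements) < 2L) stop("leave-one-out needs >=2 elements")
  seqs <- norm_seq(elements$sequence)
  if (any(nchar(seqs) == 0L)) stop("empty element sequence")
  key <- if (exclude == "gene") elements$gene_id else elements$element_id
  ord <- order(match(key, unique(key)))
  grp <- match(key[ord], unique(key[ord]))
  prof <- .sam_loo_profiles(seqs[ord], as.integer(grp))
  arsi <- numeric(nrow(elements))
  arsi[ord] <- vapply(prof, mean, numeric(1))
  data.frame(
    element_id = elements$element_id,
    gene_id = elements$gene_id,
    length_nt = nchar(seqs),
    arsi = arsi,
    stringsAsFactors = FALSE
  )
}

#' Leave-one-out match-length profiles
#'
#' Like [arsiLeaveOneOut()] but returning the full per-position profiles,
#' the raw material for sliding-window scoring.
#'
#' @inheritParams arsiLeaveOneOut
#' @return a list of integer vectors named by `element_id`, input order.
#' @export
looMatchProfiles <- function(elements, exclude = c("gene", "element")) {
  exclude <- match.arg(exclude)
  if (nrow(elements) < 2L) stop("leave-one-out needs >=2 elements")
  seqs <- norm_seq(elements$sequence)
  key <- if (exclude == "gene") elements$gene_id else elements$element_id
  ord <- order(match(key, unique(key)))
  grp <- match(key[ord], unique(key[ord]))
  prof <- .sam_loo_profiles(seqs[ord], as.integer(grp))
  out <- vector("list", nrow(elements))
  out[ord] <- prof
  names(out) <- elements$element_id
  out
}

#' Introduce uniform substitution errors
#'
#' Each position is independently substituted, with probability
#' `errorRate`, by one of the three other bases (uniformly). Mimics a
#' uniform sequencing-error process for robustness analyses. N positions
#' are left untouched.
#'
#' @param sequences character vector of sequences.
#' @param errorRate per-nucleotide substitution probability in `[0, 1)`.
#' @param seed optional integer seed for reproducibility.
#' @return character vector of mutated sequences (names preserved).
#' @export
simulateReadErrors <- function(sequences, errorRate, seed = NULL) {
  if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0, 1)")
  sequences <- as.character(sequences)
  if (errorRate == 0) return(sequences)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    vapply(sequences, function(s) {
      n <- nchar(s)
      hit <- which(runif(n) < errorRate)
      if (!length(hit)) return(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      keep <- ch[hit] %in% bases
      hit <- hit[keep]
      for (i in hit) {
        ch[i] <- sample(setdiff(bases, ch[i]), 1L)
      }
      paste(ch, collapse = "")
    }, "", USE.NAMES = !is.null(names(sequences)))
  })
}
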