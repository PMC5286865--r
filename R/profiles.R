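#' @include arsi-core.R
NULL

#' Sliding-window ARSI from a match-length profile
#'
#' The windowed score at center i is the ARSI of the window subsequence
#' `[i - (WL-1)/2, i + (WL-1)/2]` taken as the query. It is computed from
#' the full-sequence profile as the window mean of
#' `min(L(p), window_end - p + 1)`: a match of the window substring is a
#' full-sequence match truncated at the window end, so the two computations
#' are identical. Only complete windows are returned.
#'
#' @param L integer match-length profile of the full sequence.
#' @param WL odd window length (nt).
#' @return numeric vector of windowed scores for centers
#'   `(WL+1)/2 .. length(L) - (WL-1)/2`, with attribute `firstCenter`; empty
#'   (with a warning) if the sequence is shorter than `WL`.
#' @export
windowArsi <- function(L, WL = 41L) {
  WL <- as.integer(WL)
  if (WL %% 2L == 0L || WL < 1L) stop("WL must be odd and positive")
  h <- (WL - 1L) %/% 2L
  n <- length(L)
  if (n < WL) {
    warning("sequence shorter than window (", n, " < ", WL, ")")
    out <- numeric(0)
    attr(out, "firstCenter") <- NA_integer_
    return(out)
  }
  centers <- (h + 1L):(n - h)
  acc <- numeric(length(centers))
  for (d in -h:h) {
    acc <- acc + pmin(L[centers + d], h - d + 1L)
  }
  out <- acc / WL
  attr(out, "firstCenter") <- h + 1L
  out
}

#' Windowed ARSI profiles of all pre-mRNA transcripts
#'
#' Builds the anchored transcripts of every gene (multi-intron genes
#' duplicated per retained intron), computes leave-one-out match profiles
#' of each pre-mRNA against all other genes' pre-mRNAs, and windows them.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param models list of [GeneModel] objects.
#' @param WL odd window length (default 41).
#' @return a list with one entry per transcript: `element_id`, `gene_id`,
#'   `anchors`, `values` (windowed profile) and `firstCenter`.
#' @export
windowProfiles <- function(genome, models, WL = 41L) {
  genome <- as_genome_chr(genome)
  transcripts <- unlist(lapply(models, buildAnchoredTranscripts,
                               genome = genome), recursive = FALSE)
  elements <- data.frame(
    element_id = vapply(transcripts, function(t) t@elementID, ""),
    gene_id = vapply(transcripts, function(t) t@geneID, ""),
    sequence = vapply(transcripts, function(t) t@premrna, ""),
    stringsAsFactors = FALSE
  )
  prof <- looMatchProfiles(elements, exclude = "gene")
  Map(function(tr, L) {
    w <- suppressWarnings(windowArsi(L, WL))
    list(element_id = tr@elementID, gene_id = tr@geneID,
         anchors = tr@anchors, values = w,
         firstCenter = attr(w, "firstCenter"))
  }, transcripts, prof)
}

#' Average windowed profiles around an anchor
#'
#' Aligns the per-transcript windowed profiles on the requested anchor and
#' averages per offset over all transcripts whose complete window at that
#' offset lies within the sequence. The offset range is
#' `+/- floor((n - 1/2) * WL)`; offset 0 is the anchor nucleotide itself.
#'
#' @param profiles list as returned by [windowProfiles()].
#' @param anchor one of `"orf_start"`, `"orf_end"`, `"five_ss"`,
#'   `"three_ss"`.
#' @param WL odd window length the profiles were computed with.
#' @param n window-count parameter setting the flank extent (default 4).
#' @return an [AlignedAnchorProfile].
#' @export
alignAndAverage <- function(profiles, anchor = c("orf_start", "orf_end",
                                                 "five_ss", "three_ss"),
                            WL = 41L, n = 4L) {
  anchor <- match.arg(anchor)
  WL <- as.integer(WL)
  Fext <- as.integer(floor((n - 0.5) * WL))
  offsets <- seq.int(-Fext, Fext)
  sums <- numeric(length(offsets))
  counts <- integer(length(offsets))
  used <- 0L
  for (p in profiles) {
    a <- p$anchors[anchor]
    if (is.na(a) || length(p$values) == 0L) next
    used <- used + 1L
    first_c <- p$firstCenter
    last_c <- first_c + length(p$values) - 1L
    # centers c contribute at offset o = c - a
    lo <- max(first_c - a, -Fext)
    hi <- min(last_c - a, Fext)
    if (lo > hi) next
    oi <- (lo + Fext + 1L):(hi + Fext + 1L)
    ci <- (a + lo - first_c + 1L):(a + hi - first_c + 1L)
    sums[oi] <- sums[oi] + p$values[ci]
    counts[oi] <- counts[oi] + 1L
  }
  if (used == 0L) stop("no profiles carry anchor '", anchor, "'")
  methods::new("AlignedAnchorProfile",
    anchor = anchor, offsets = as.integer(offsets),
    mean = ifelse(counts > 0L, sums / pmax(counts, 1L), NaN),
    counts = counts, WL = WL, n = as.integer(n))
}

#' Anchor-aligned mean ARSI profile of a genome
#'
#' One-call pipeline: [windowProfiles()] then [alignAndAverage()].
#'
#' @inheritParams windowProfiles
#' @inheritParams alignAndAverage
#' @return an [AlignedAnchorProfile].
#' @export
anchorProfile <- function(genome, models, anchor = "orf_start", WL = 41L,
                          n = 4L) {
  alignAndAverage(windowProfiles(genome, models, WL = WL), anchor = anchor,
                  WL = WL, n = n)
}
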