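#' @include arsiscan-package.R
NULL

#' Gene structure on a chromosome
#'
#' Exon, CDS and UTR intervals of one gene (first mRNA isoform), in genomic
#' coordinates (1-based, inclusive; ascending order). Introns are derived as
#' the gaps between consecutive exons.
#'
#' @slot geneID gene identifier.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons,cds,fiveUTR,threeUTR [IRanges::IRanges] of the respective
#'   feature intervals, ascending genomic order (possibly empty for UTRs).
#' @slot notes character vector of parse-time flags (e.g. CDS length not a
#'   multiple of three).
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    geneID = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    cds = "IRanges",
    fiveUTR = "IRanges",
    threeUTR = "IRanges",
    notes = "character"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L) msg <- c(msg, "gene needs at least one exon")
  if (length(ex) > 1L) {
    if (is.unsorted(IRanges::start(ex))) msg <- c(msg, "exons must be ascending")
    if (any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons overlap or touch")
  }
  if (length(msg)) msg else TRUE
})

#' Extracted region sequences of one gene
#'
#' Nucleotide sequences, in transcript orientation, for the kinds
#' `five_utr`, `orf`, `intron.k`, `three_utr`, `upstream_flank`,
#' `downstream_flank`. Zero-length regions are omitted.
#'
#' @slot geneID gene identifier.
#' @slot sequences named character vector of region sequences.
#' @slot flankLength requested flank length (nt); realized flanks may be
#'   shorter at chromosome edges.
#' @exportClass RegionSet
setClass("RegionSet",
  representation(
    geneID = "character",
    sequences = "character",
    flankLength = "integer"
  )
)

#' Anchored pre-mRNA transcript
#'
#' A pre-mRNA sequence with anchor coordinates (1-based positions in
#' `premrna`). A gene with m > 1 introns is represented by m duplicates,
#' each retaining a different intron with the others spliced out; `anchors`
#' then refers to the retained intron's splice sites.
#'
#' @slot geneID gene identifier.
#' @slot elementID unique identifier of this duplicate.
#' @slot premrna nucleotide string, transcript orientation.
#' @slot anchors named integer vector; names among `orf_start` (first start
#'   codon nt), `orf_end` (first stop codon nt), `five_ss` (first retained
#'   intron nt), `three_ss` (last retained intron nt).
#' @slot retainedIntron index (transcription order) of the retained intron,
#'   or `NA` for intronless genes.
#' @exportClass AnchoredTranscript
setClass("AnchoredTranscript",
  representation(
    geneID = "character",
    elementID = "character",
    premrna = "character",
    anchors = "integer",
    retainedIntron = "integer"
  )
)

#' Substring-query index over a reference set
#'
#' Supports exact longest-prefix-match queries against the set of all
#' substrings of the reference sequences; matches never span two reference
#' sequences, and ambiguous bases (N) never match. Query answers are
#' independent of insertion order. The compiled index is rebuilt lazily if
#' the object was serialized.
#'
#' @slot ids reference element identifiers.
#' @slot seqs reference sequences (uppercase).
#' @slot totalLength total reference length (nt).
#' @slot ptr external pointer to the compiled automaton.
#' @exportClass ArsiIndex
setClass("ArsiIndex",
  representation(
    ids = "character",
    seqs = "character",
    totalLength = "integer",
    ptr = "ANY"
  )
)

#' Anchor-aligned mean window profile
#'
#' Mean windowed ARSI per offset relative to an anchor, averaged over all
#' genes long enough to contribute a complete window at that offset.
#'
#' @slot anchor anchor kind (`orf_start`, `orf_end`, `five_ss`, `three_ss`).
#' @slot offsets integer offsets relative to the anchor nucleotide.
#' @slot mean mean windowed ARSI per offset (`NaN` where no gene reaches).
#' @slot counts number of contributing transcripts per offset.
#' @slot WL,n window length (odd, nt) and window-count parameter; the
#'   offset range is +/- floor((n - 1/2) * WL).
#' @exportClass AlignedAnchorProfile
setClass("AlignedAnchorProfile",
  representation(
    anchor = "character",
    offsets = "integer",
    mean = "numeric",
    counts = "integer",
    WL = "integer",
    n = "integer"
  )
)

setValidity("AlignedAnchorProfile", function(object) {
  if (length(object@offsets) != length(object@mean) ||
      length(object@offsets) != length(object@counts))
    return("offsets, mean and counts must be parallel")
  TRUE
})

#' Ensemble of randomized-genome replicate statistics
#'
#' Per-replicate statistics (scores or profiles) computed on independent
#' randomized genomes under a named scheme, for Z-scoring real signals.
#'
#' @slot scheme subset of `c("codons", "introns", "utrs")`.
#' @slot R replicate count.
#' @slot seed master seed the replicate seeds were derived from.
#' @slot stats list of length `R` with one statistic per replicate.
#' @exportClass NullEnsemble
setClass("NullEnsemble",
  representation(
    scheme = "character",
    R = "integer",
    seed = "integer",
    stats = "list"
  )
)

#' Z-score profile against a null ensemble
#'
#' Per-offset standardized deviation of the real anchor-aligned profile from
#' the randomized-genome ensemble: z = (real - null mean) / null sd (sample
#' sd, denominator R - 1). Offsets where the null sd is zero or a replicate
#' is undefined carry `NA` and are listed in `undefined`.
#'
#' @slot anchor anchor kind.
#' @slot offsets integer offsets relative to the anchor.
#' @slot real,nullMean,nullSD,z numeric vectors parallel to `offsets`.
#' @slot R replicate count behind the null moments.
#' @slot undefined integer offsets flagged undefined.
#' @exportClass ZProfile
setClass("ZProfile",
  representation(
    anchor = "character",
    offsets = "integer",
    real = "numeric",
    nullMean = "numeric",
    nullSD = "numeric",
    z = "numeric",
    R = "integer",
    undefined = "integer"
  )
)
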