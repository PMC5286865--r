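#' @include AllClasses.R
NULL

#' Accessors for arsiscan classes
#'
#' `geneID()` returns the gene identifier; `regionSeqs()` the named region
#' sequences of a [RegionSet]; `introns()` the derived intron intervals of a
#' [GeneModel]; `anchors()` the anchor positions of an [AnchoredTranscript];
#' `profileMeans()`, `profileCounts()` and `profileOffsets()` the components
#' of an [AlignedAnchorProfile] or [ZProfile].
#'
#' @param x an arsiscan object.
#' @return the corresponding slot value (see class documentation).
#' @name accessors
#' @aliases geneID regionSeqs introns anchors profileMeans profileCounts
#'   profileOffsets
NULL

#' @rdname accessors
#' @export
setGeneric("geneID", function(x) standardGeneric("geneID"))

#' @rdname accessors
#' @export
setGeneric("regionSeqs", function(x) standardGeneric("regionSeqs"))

#' @rdname accessors
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))

#' @rdname accessors
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname accessors
#' @export
setGeneric("profileMeans", function(x) standardGeneric("profileMeans"))

#' @rdname accessors
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname accessors
#' @export
setGeneric("profileOffsets", function(x) standardGeneric("profileOffsets"))

#' @rdname accessors
setMethod("geneID", "GeneModel", function(x) x@geneID)

#' @rdname accessors
setMethod("geneID", "RegionSet", function(x) x@geneID)

#' @rdname accessors
setMethod("geneID", "AnchoredTranscript", function(x) x@geneID)

#' @rdname accessors
setMethod("regionSeqs", "RegionSet", function(x) x@sequences)

#' @rdname accessors
setMethod("introns", "GeneModel", function(x) {
  ex <- x@exons
  if (length(ex) < 2L) return(IRanges::IRanges())
  IRanges::IRanges(
    start = IRanges::end(ex)[-length(ex)] + 1L,
    end = IRanges::start(ex)[-1L] - 1L
  )
})

#' @rdname accessors
setMethod("anchors", "AnchoredTranscript", function(x) x@anchors)

#' @rdname accessors
setMethod("profileMeans", "AlignedAnchorProfile", function(x) x@mean)

#' @rdname accessors
setMethod("profileCounts", "AlignedAnchorProfile", function(x) x@counts)

#' @rdname accessors
setMethod("profileOffsets", "AlignedAnchorProfile", function(x) x@offsets)

#' @rdname accessors
setMethod("profileOffsets", "ZProfile", function(x) x@offsets)

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneID, sprintf("(%s%s)", object@chrom, object@strand),
      "\n  exons:", length(object@exons),
      " introns:", max(0L, length(object@exons) - 1L),
      " CDS nt:", sum(IRanges::width(object@cds)),
      " 5'UTR nt:", sum(IRanges::width(object@fiveUTR)),
      " 3'UTR nt:", sum(IRanges::width(object@threeUTR)), "\n")
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet", object@geneID, "-", length(object@sequences), "regions:",
      paste(sprintf("%s(%d)", names(object@sequences), nchar(object@sequences)),
            collapse = " "), "\n")
})

setMethod("show", "AnchoredTranscript", function(object) {
  cat("AnchoredTranscript", object@elementID,
      sprintf("(%d nt)", nchar(object@premrna)), "\n  anchors:",
      paste(sprintf("%s=%d", names(object@anchors), object@anchors),
            collapse = " "),
      if (!is.na(object@retainedIntron))
        sprintf(" (retained intron %d)", object@retainedIntron) else "",
      "\n")
})

setMethod("show", "ArsiIndex", function(object) {
  cat("ArsiIndex:", length(object@ids), "reference elements,",
      object@totalLength, "nt total\n")
})

setMethod("show", "AlignedAnchorProfile", function(object) {
  cat("AlignedAnchorProfile anchor =", object@anchor,
      sprintf("WL = %d, n = %d, offsets %d..%d\n", object@WL, object@n,
              min(object@offsets), max(object@offsets)))
  cat("  max contributing transcripts:", max(object@counts),
      " peak mean ARSI:", sprintf("%.3f", max(object@mean, na.rm = TRUE)),
      "at offset", object@offsets[which.max(object@mean)], "\n")
})

setMethod("show", "NullEnsemble", function(object) {
  cat("NullEnsemble: scheme {", paste(object@scheme, collapse = ","),
      "}, R =", object@R, "replicates\n")
})

setMethod("show", "ZProfile", function(object) {
  ok <- !is.na(object@z)
  cat("ZProfile anchor =", object@anchor,
      sprintf("(R = %d, offsets %d..%d)\n", object@R,
              min(object@offsets), max(object@offsets)))
  if (any(ok))
    cat("  max |z| =", sprintf("%.2f", max(abs(object@z[ok]))),
        "at offset", object@offsets[ok][which.max(abs(object@z[ok]))],
        ";", length(object@undefined), "undefined offsets\n")
})

#' Tabulate a profile object
#'
#' @param x an [AlignedAnchorProfile] or [ZProfile].
#' @param ... ignored.
#' @return a `data.frame` with one row per offset.
#' @export
setGeneric("profileTable", function(x, ...) standardGeneric("profileTable"))

#' @rdname profileTable
setMethod("profileTable", "AlignedAnchorProfile", function(x, ...) {
  data.frame(anchor = x@anchor, offset = x@offsets, mean_arsi = x@mean,
             n_genes = x@counts)
})

#' @rdname profileTable
setMethod("profileTable", "ZProfile", function(x, ...) {
  data.frame(anchor = x@anchor, offset = x@offsets, real = x@real,
             null_mean = x@nullMean, null_sd = x@nullSD, z = x@z,
             n_replicates = x@R)
})
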