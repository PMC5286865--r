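#' @include AllGenerics.R
NULL

# reverse-complement a plain character sequence (A/C/G/T/N alphabet)
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", intToUtf8(rev(utf8ToInt(s))))
}

# normalize a genome to a named character vector (cheap no-op if already one)
as_genome_chr <- function(genome) {
  if (is.character(genome)) genome else as.character(genome)
}

# Concatenated sequence of ascending genomic intervals, flipped into
# transcript orientation for minus-strand genes. `chrom_seq` is a plain
# character scalar (or anything as.character-able).
region_seq <- function(chrom_seq, ir, strand) {
  if (length(ir) == 0L) return("")
  chrom_seq <- as.character(chrom_seq)
  s <- paste(substring(chrom_seq, IRanges::start(ir), IRanges::end(ir)),
             collapse = "")
  if (strand == "-") s <- revcomp(s)
  s
}

#' Read a genome FASTA
#'
#' Sequences are uppercased and any character outside A/C/G/T is mapped to
#' N (N never matches in downstream scoring).
#'
#' @param fastaPath path to a (multi-)FASTA file.
#' @return a named [Biostrings::DNAStringSet]; names are truncated at the
#'   first whitespace.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "acgtRacgt"), fa)
#' as.character(readGenome(fa))
readGenome <- function(fastaPath) {
  if (!file.exists(fastaPath)) stop("FASTA not found: ", fastaPath)
  dss <- tryCatch(
    Biostrings::readBStringSet(fastaPath),
    error = function(e) stop("malformed FASTA '", fastaPath, "': ",
                             conditionMessage(e))
  )
  seqs <- toupper(as.character(dss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(dss))
  Biostrings::DNAStringSet(seqs)
}

#' Read gene models from a GFF3 annotation
#'
#' Expects `gene`/`mRNA` (or `transcript`)/`exon`/`CDS` features and
#' optionally `five_prime_UTR`/`three_prime_UTR`; when UTR features are
#' absent they are inferred as the exonic sequence outside the CDS span.
#' Only the first mRNA of each gene is used. Genes whose exons overlap are
#' rejected with a message; a CDS length not divisible by three raises a
#' warning and flags the model. For annotations that attach CDS features
#' directly to the gene (common in prokaryotes) the CDS intervals double as
#' exons.
#'
#' @param gffPath path to a GFF3 file (1-based inclusive coordinates).
#' @return a named list of [GeneModel] objects. Intervals are stored in
#'   ascending genomic order; use [exonsByTranscription()] for
#'   transcription order.
#' @export
readAnnotation <- function(gffPath) {
  if (!file.exists(gffPath)) stop("GFF3 not found: ", gffPath)
  gr <- rtracklayer::import(gffPath, format = "gff3")
  type <- as.character(gr$type)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  if (is.null(gr$Parent)) stop("GFF3 has no Parent attributes")
  pidx <- rep(seq_along(gr), lengths(gr$Parent))
  pval <- unlist(gr$Parent, use.names = FALSE)

  children_of <- function(pid, what) {
    i <- pidx[pval == pid]
    i[type[i] == what]
  }
  gene_i <- which(type == "gene")
  models <- list()
  for (gi in gene_i) {
    gid <- ids[gi]
    if (is.na(gid)) next
    tx_i <- pidx[pval == gid]
    tx_i <- tx_i[type[tx_i] %in% c("mRNA", "transcript")]
    pid <- if (length(tx_i)) ids[tx_i[1L]] else gid
    ex_i <- children_of(pid, "exon")
    cds_i <- children_of(pid, "CDS")
    if (length(ex_i) == 0L) ex_i <- cds_i
    if (length(ex_i) == 0L) {
      message("gene ", gid, ": no exon or CDS features; skipped")
      next
    }
    as_ir <- function(i) {
      if (length(i) == 0L) return(IRanges::IRanges())
      r <- IRanges::ranges(gr[i])
      r[order(IRanges::start(r))]
    }
    exons <- as_ir(ex_i)
    if (length(exons) > 1L &&
        any(IRanges::start(exons)[-1L] <= IRanges::end(exons)[-length(exons)])) {
      message("gene ", gid, ": overlapping exons; rejected")
      next
    }
    cds <- as_ir(cds_i)
    notes <- character(0)
    if (length(cds) && sum(IRanges::width(cds)) %% 3L != 0L) {
      warning("gene ", gid, ": CDS length not divisible by 3")
      notes <- c(notes, "cds_not_triplet")
    }
    strand <- as.character(BiocGenerics::strand(gr[gi]))
    if (!strand %in% c("+", "-")) strand <- "+"
    utr5 <- as_ir(children_of(pid, "five_prime_UTR"))
    utr3 <- as_ir(children_of(pid, "three_prime_UTR"))
    if (length(utr5) == 0L && length(utr3) == 0L && length(cds)) {
      cds_span <- IRanges::IRanges(min(IRanges::start(cds)),
                                   max(IRanges::end(cds)))
      non_cds <- BiocGenerics::setdiff(exons, cds_span)
      left <- non_cds[IRanges::end(non_cds) < IRanges::start(cds_span)]
      right <- non_cds[IRanges::start(non_cds) > IRanges::end(cds_span)]
      if (strand == "+") { utr5 <- left; utr3 <- right }
      else { utr5 <- right; utr3 <- left }
    }
    models[[gid]] <- methods::new("GeneModel",
      geneID = gid,
      chrom = as.character(GenomicRanges::seqnames(gr[gi])),
      strand = strand, exons = exons, cds = cds,
      fiveUTR = utr5, threeUTR = utr3, notes = notes)
  }
  models
}

#' Exon intervals in transcription order
#'
#' @param model a [GeneModel].
#' @return an [IRanges::IRanges]: ascending genomic order for plus-strand
#'   genes, descending (5' to 3' of the transcript) for minus-strand genes.
#' @export
exonsByTranscription <- function(model) {
  ex <- model@exons
  if (model@strand == "-") rev(ex) else ex
}

#' Extract regional sequences of a gene
#'
#' Returns the 5'UTR, ORF (concatenated CDS), introns, 3'UTR and the
#' upstream/downstream flanking sequences, all in transcript orientation.
#' Flanks are truncated at chromosome edges; zero-length regions are
#' omitted. For genes lacking annotated UTRs, `utrFallback > 0` substitutes
#' that many nucleotides of flanking sequence for each missing UTR (with a
#' message), a pragmatic stand-in for unannotated UTRs.
#'
#' @param genome a [Biostrings::DNAStringSet] as from [readGenome()].
#' @param model a [GeneModel].
#' @param flankLength flank length in nt (default 250).
#' @param utrFallback fixed UTR length in nt used when UTR annotation is
#'   absent (default 0 = no fallback).
#' @return a [RegionSet].
#' @export
extractRegions <- function(genome, model, flankLength = 250L, utrFallback = 0L) {
  chrom <- model@chrom
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  cs <- as.character(genome[[chrom]])
  clen <- nchar(cs)
  strand <- model@strand
  out <- character(0)

  add <- function(out, kind, s) {
    if (nchar(s) > 0L) out[kind] <- s
    out
  }
  out <- add(out, "five_utr", region_seq(cs, model@fiveUTR, strand))
  out <- add(out, "orf", region_seq(cs, model@cds, strand))
  iv <- introns(model)
  if (length(iv)) {
    iseqs <- vapply(seq_along(iv),
                    function(k) region_seq(cs, iv[k], strand), "")
    if (strand == "-") iseqs <- rev(iseqs)
    for (k in seq_along(iseqs)) out <- add(out, paste0("intron.", k), iseqs[k])
  }
  out <- add(out, "three_utr", region_seq(cs, model@threeUTR, strand))

  tx_start <- min(IRanges::start(model@exons))
  tx_end <- max(IRanges::end(model@exons))
  flank_ir <- function(side) {
    # side "up"/"down" in transcript orientation
    genomic_left <- (side == "up") == (strand == "+")
    if (genomic_left) {
      s <- max(1L, tx_start - flankLength)
      if (tx_start - 1L < s) return(IRanges::IRanges())
      IRanges::IRanges(s, tx_start - 1L)
    } else {
      e <- min(clen, tx_end + flankLength)
      if (e < tx_end + 1L) return(IRanges::IRanges())
      IRanges::IRanges(tx_end + 1L, e)
    }
  }
  up <- region_seq(cs, flank_ir("up"), strand)
  dn <- region_seq(cs, flank_ir("down"), strand)
  out <- add(out, "upstream_flank", up)
  out <- add(out, "downstream_flank", dn)

  if (utrFallback > 0L) {
    if (!"five_utr" %in% names(out) && nchar(up) > 0L) {
      message("gene ", model@geneID, ": no 5'UTR annotation; using ",
              utrFallback, " nt upstream flank")
      out["five_utr"] <- substr(up, max(1L, nchar(up) - utrFallback + 1L), nchar(up))
    }
    if (!"three_utr" %in% names(out) && nchar(dn) > 0L) {
      message("gene ", model@geneID, ": no 3'UTR annotation; using ",
              utrFallback, " nt downstream flank")
      out["three_utr"] <- substr(dn, 1L, min(utrFallback, nchar(dn)))
    }
  }
  methods::new("RegionSet", geneID = model@geneID, sequences = out,
               flankLength = as.integer(flankLength))
}

#' Build anchored pre-mRNA transcripts
#'
#' A gene with m > 1 introns yields m transcripts; duplicate k retains
#' intron k spliced in while all other introns are removed, so every
#' transcript carries at most one intron and well-defined `five_ss` /
#' `three_ss` anchors. Genes with 0 or 1 intron yield a single transcript.
#' The `orf_end` anchor is the first nucleotide of the stop codon (the stop
#' codon is taken to be included in the annotated CDS).
#'
#' @param model a [GeneModel].
#' @param genome a [Biostrings::DNAStringSet].
#' @return a list of [AnchoredTranscript] objects.
#' @export
buildAnchoredTranscripts <- function(model, genome) {
  cs <- as.character(genome[[model@chrom]])
  strand <- model@strand
  exT <- vapply(seq_along(model@exons),
                function(k) region_seq(cs, model@exons[k], strand), "")
  if (strand == "-") exT <- rev(exT)
  iv <- introns(model)
  inT <- character(0)
  if (length(iv)) {
    inT <- vapply(seq_along(iv), function(k) region_seq(cs, iv[k], strand), "")
    if (strand == "-") inT <- rev(inT)
  }
  u5 <- sum(IRanges::width(model@fiveUTR))
  cds_len <- sum(IRanges::width(model@cds))
  base_anchors <- integer(0)
  if (cds_len >= 3L) {
    base_anchors <- c(orf_start = u5 + 1L, orf_end = u5 + cds_len - 2L)
  }
  m <- length(inT)
  if (m == 0L) {
    tr <- methods::new("AnchoredTranscript",
      geneID = model@geneID, elementID = model@geneID,
      premrna = paste(exT, collapse = ""),
      anchors = base_anchors, retainedIntron = NA_integer_)
    return(list(tr))
  }
  ex_cum <- cumsum(nchar(exT))
  lapply(seq_len(m), function(k) {
    A <- ex_cum[k]                      # last exonic nt before retained intron
    ilen <- nchar(inT[k])
    premrna <- paste0(paste(exT[seq_len(k)], collapse = ""), inT[k],
                      paste(exT[seq(k + 1L, length(exT))], collapse = ""))
    shift <- function(p) ifelse(p <= A, p, p + ilen)
    anch <- c(
      if (length(base_anchors))
        stats::setNames(as.integer(shift(base_anchors)), names(base_anchors)),
      five_ss = A + 1L, three_ss = A + ilen)
    methods::new("AnchoredTranscript",
      geneID = model@geneID,
      elementID = paste0(model@geneID, ".i", k),
      premrna = premrna, anchors = anch, retainedIntron = k)
  })
}

#' Write region sequences to FASTA
#'
#' Headers follow `gene_id|region_kind|index` (index 1 except for introns).
#'
#' @param regionSets a list of [RegionSet] objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeRegionsFasta <- function(regionSets, path) {
  seqs <- character(0)
  for (rs in regionSets) {
    s <- rs@sequences
    kinds <- sub("\\.\\d+$", "", names(s))
    idx <- ifelse(grepl("\\.\\d+$", names(s)),
                  sub("^.*\\.", "", names(s)), "1")
    names(s) <- paste(rs@geneID, kinds, idx, sep = "|")
    seqs <- c(seqs, s)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
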