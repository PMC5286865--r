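test_that("FASTA reading normalizes case and alphabet", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 descr", "acgtACGT", ">chr2", "ACGRTN"), fa)
  g <- readGenome(fa)
  expect_identical(names(g), c("chr1", "chr2"))
  expect_identical(as.character(g[["chr1"]]), "ACGTACGT")
  expect_identical(as.character(g[["chr2"]]), "ACGNTN")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("no header here"), bad)
  expect_error(readGenome(bad), "FASTA")
  expect_error(readGenome("/nonexistent/x.fa"), "not found")
})

make_gff <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("GFF3 parsing handles exon structure, UTR inference and strand", {
  # single-exon gene, CDS = exon: no UTRs, no introns
  f1 <- make_gff(c(
    "chr1\tx\tgene\t101\t160\t.\t+\t.\tID=gA",
    "chr1\tx\tmRNA\t101\t160\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tx\texon\t101\t160\t.\t+\t.\tID=gA.e1;Parent=gA.t1",
    "chr1\tx\tCDS\t101\t160\t.\t+\t0\tID=gA.c1;Parent=gA.t1"))
  m <- readAnnotation(f1)[["gA"]]
  expect_s4_class(m, "GeneModel")
  expect_length(m@fiveUTR, 0)
  expect_length(m@threeUTR, 0)
  expect_length(introns(m), 0)
  expect_equal(IRanges::start(m@exons), 101L)

  # two-exon plus-strand gene: one intron = the inter-exon gap; UTRs
  # inferred from exon minus CDS span
  f2 <- make_gff(c(
    "chr1\tx\tgene\t101\t260\t.\t+\t.\tID=gB",
    "chr1\tx\tmRNA\t101\t260\t.\t+\t.\tID=gB.t1;Parent=gB",
    "chr1\tx\texon\t101\t160\t.\t+\t.\tParent=gB.t1",
    "chr1\tx\texon\t201\t260\t.\t+\t.\tParent=gB.t1",
    "chr1\tx\tCDS\t121\t160\t.\t+\t0\tParent=gB.t1",
    "chr1\tx\tCDS\t201\t240\t.\t+\t2\tParent=gB.t1"))
  m2 <- suppressWarnings(readAnnotation(f2)[["gB"]])
  expect_equal(as.data.frame(introns(m2))[, c("start", "end")],
               data.frame(start = 161L, end = 200L))
  expect_equal(IRanges::start(m2@fiveUTR), 101L)
  expect_equal(IRanges::end(m2@fiveUTR), 120L)
  expect_equal(IRanges::start(m2@threeUTR), 241L)

  # minus-strand: first exon in transcription order is the 3'-most genomic
  f3 <- make_gff(c(
    "chr1\tx\tgene\t101\t260\t.\t-\t.\tID=gC",
    "chr1\tx\tmRNA\t101\t260\t.\t-\t.\tID=gC.t1;Parent=gC",
    "chr1\tx\texon\t101\t160\t.\t-\t.\tParent=gC.t1",
    "chr1\tx\texon\t201\t260\t.\t-\t.\tParent=gC.t1",
    "chr1\tx\tCDS\t101\t160\t.\t-\t0\tParent=gC.t1",
    "chr1\tx\tCDS\t201\t254\t.\t-\t0\tParent=gC.t1"))
  m3 <- suppressWarnings(readAnnotation(f3))[["gC"]]
  expect_equal(IRanges::start(exonsByTranscription(m3))[1], 201L)
  expect_equal(IRanges::start(m3@exons)[1], 101L)  # storage stays genomic

  # overlapping exons are rejected; non-triplet CDS warns and flags
  f4 <- make_gff(c(
    "chr1\tx\tgene\t101\t260\t.\t+\t.\tID=gD",
    "chr1\tx\tmRNA\t101\t260\t.\t+\t.\tID=gD.t1;Parent=gD",
    "chr1\tx\texon\t101\t180\t.\t+\t.\tParent=gD.t1",
    "chr1\tx\texon\t160\t260\t.\t+\t.\tParent=gD.t1",
    "chr1\tx\tCDS\t101\t180\t.\t+\t0\tParent=gD.t1"))
  expect_message(mods <- readAnnotation(f4), "rejected")
  expect_false("gD" %in% names(mods))
  f5 <- make_gff(c(
    "chr1\tx\tgene\t101\t150\t.\t+\t.\tID=gE",
    "chr1\tx\tmRNA\t101\t150\t.\t+\t.\tID=gE.t1;Parent=gE",
    "chr1\tx\texon\t101\t150\t.\t+\t.\tParent=gE.t1",
    "chr1\tx\tCDS\t101\t150\t.\t+\t0\tParent=gE.t1"))
  expect_warning(m5 <- readAnnotation(f5)[["gE"]], "divisible by 3")
  expect_true("cds_not_triplet" %in% m5@notes)
})

test_that("region extraction is strand-aware and truncates flanks", {
  # minus-strand gene whose genomic CDS ends ...CAT reads ATG in transcript
  chrom <- paste0(strrep("G", 20), "TTACCC", "CAT", strrep("C", 15))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  m <- methods::new("GeneModel", geneID = "g", chrom = "chr1", strand = "-",
                    exons = IRanges::IRanges(21, 29),
                    cds = IRanges::IRanges(21, 29),
                    fiveUTR = IRanges::IRanges(), threeUTR = IRanges::IRanges(),
                    notes = character(0))
  rs <- extractRegions(genome, m, flankLength = 250)
  expect_identical(substr(regionSeqs(rs)[["orf"]], 1, 3), "ATG")
  # chromosome is 44 nt; flanks truncate at the edges
  expect_identical(nchar(regionSeqs(rs)[["upstream_flank"]]), 15L)
  expect_identical(nchar(regionSeqs(rs)[["downstream_flank"]]), 20L)

  # UTR fallback substitutes flanking sequence when annotation lacks UTRs
  expect_message(rs2 <- extractRegions(genome, m, flankLength = 250,
                                       utrFallback = 10L), "no 5'UTR")
  expect_identical(nchar(regionSeqs(rs2)[["five_utr"]]), 10L)
})

test_that("extracted regions reassemble the mature transcript", {
  g <- synth_genome(nGenes = 30, seed = 5)
  for (gid in head(names(g$models), 10)) {
    m <- g$models[[gid]]
    rs <- regionSeqs(extractRegions(g$genome, m))
    mature <- paste0(rs[["five_utr"]], rs[["orf"]], rs[["three_utr"]])
    exonic <- paste(vapply(seq_along(exonsByTranscription(m)), function(k) {
      arsiscan:::region_seq(as.character(g$genome[[m@chrom]]),
                            exonsByTranscription(m)[k], m@strand)
    }, ""), collapse = "")
    expect_identical(mature, exonic)
  }
})

test_that("a mirrored gene on the opposite strand yields identical regions", {
  g <- synth_genome(nGenes = 30, seed = 5)
  m <- g$models[[2]]
  chrom <- as.character(g$genome[[m@chrom]])
  L <- nchar(chrom)
  mirror_ir <- function(ir) {
    IRanges::IRanges(start = L - IRanges::end(ir) + 1L,
                     end = L - IRanges::start(ir) + 1L)
  }
  flip <- function(ir) ir[order(IRanges::start(mirror_ir(ir)))]
  m2 <- methods::new("GeneModel", geneID = m@geneID, chrom = m@chrom,
                     strand = if (m@strand == "+") "-" else "+",
                     exons = mirror_ir(m@exons)[order(IRanges::start(mirror_ir(m@exons)))],
                     cds = mirror_ir(m@cds)[order(IRanges::start(mirror_ir(m@cds)))],
                     fiveUTR = mirror_ir(m@fiveUTR),
                     threeUTR = mirror_ir(m@threeUTR),
                     notes = character(0))
  g2 <- Biostrings::DNAStringSet(setNames(arsiscan:::revcomp(chrom), m@chrom))
  expect_identical(regionSeqs(extractRegions(g2, m2)),
                   regionSeqs(extractRegions(g$genome, m)))
})

test_that("anchored transcripts duplicate multi-intron genes correctly", {
  g <- synth_genome(nGenes = 60, seed = 21)
  n_int <- vapply(g$models, function(m) length(introns(m)), 0L)
  expect_true(any(n_int == 2))  # the generator produces multi-intron genes

  for (gid in names(g$models)) {
    m <- g$models[[gid]]
    trs <- buildAnchoredTranscripts(m, g$genome)
    k <- length(introns(m))
    expect_length(trs, max(1L, k))
    mature_len <- sum(IRanges::width(m@exons))
    ilens <- IRanges::width(introns(m))
    if (m@strand == "-") ilens <- rev(ilens)
    for (j in seq_along(trs)) {
      tr <- trs[[j]]
      a <- anchors(tr)
      p <- tr@premrna
      expect_identical(substr(p, a[["orf_start"]], a[["orf_start"]] + 2L),
                       "ATG")
      expect_true(substr(p, a[["orf_end"]], a[["orf_end"]] + 2L) %in%
                    c("TAA", "TAG", "TGA"))
      if (k == 0L) {
        expect_false("five_ss" %in% names(a))
        expect_identical(nchar(p), mature_len)
        expect_true(is.na(tr@retainedIntron))
      } else {
        # exactly one retained intron: length bookkeeping and GT..AG ends
        expect_identical(nchar(p), mature_len + ilens[j])
        expect_identical(substr(p, a[["five_ss"]], a[["five_ss"]] + 1L), "GT")
        expect_identical(substr(p, a[["three_ss"]] - 1L, a[["three_ss"]]),
                         "AG")
        expect_identical(tr@retainedIntron, j)
      }
    }
  }
})

test_that("region FASTA export uses gene|kind|index headers", {
  g <- synth_genome(nGenes = 30, seed = 5)
  rs <- lapply(g$models[1:3], function(m) extractRegions(g$genome, m))
  f <- withr::local_tempfile(fileext = ".fa")
  writeRegionsFasta(rs, f)
  out <- Biostrings::readDNAStringSet(f)
  expect_true(all(grepl("^g\\d+\\|[a-z_5']+\\|\\d+$", names(out))))
  expect_identical(unname(as.character(out[[paste0(names(g$models)[1],
                                                   "|orf|1")]])),
                   regionSeqs(rs[[1]])[["orf"]])
})
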