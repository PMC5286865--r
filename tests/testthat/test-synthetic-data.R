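test_that("motif libraries are seeded, distinct and composition-faithful", {
  spec <- syntheticSpec(motifCount = 40, seed = 17)
  m1 <- makeMotifLibrary(spec)
  m2 <- makeMotifLibrary(spec)
  expect_identical(m1, m2)
  expect_length(m1, 40L)
  expect_false(any(duplicated(m1)))
  lens <- nchar(m1)
  expect_true(all(lens >= spec$motifLenRange[1] &
                    lens <= spec$motifLenRange[2]))
  # pooled GC close to the background target (binomial noise)
  bases <- strsplit(paste(m1, collapse = ""), "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_lt(abs(gc - spec$backgroundGC),
            4 * sqrt(0.25 / length(bases)) + 0.02)
})

test_that("genome synthesis is byte-identical under a fixed spec", {
  spec <- syntheticSpec(nGenes = 20, seed = 23)
  a <- synthesizeGenome(spec)
  b <- synthesizeGenome(spec)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$expression, b$expression)
  expect_identical(a$truthPlacements, b$truthPlacements)
  c <- synthesizeGenome(syntheticSpec(nGenes = 20, seed = 24))
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("generated gene structures satisfy their construction rules", {
  g <- synth_genome(nGenes = 60, seed = 21)
  expect_length(g$models, 60L)
  gchr <- as.character(g$genome)
  for (m in g$models) {
    iv <- introns(m)
    for (k in seq_along(iv)) {
      s <- arsiscan:::region_seq(gchr[[m@chrom]], iv[k], m@strand)
      expect_identical(substr(s, 1, 2), "GT")
      expect_identical(substring(s, nchar(s) - 1L), "AG")
      expect_true(grepl("TACTAAC", s, fixed = TRUE))
    }
    orf <- arsiscan:::region_seq(gchr[[m@chrom]], m@cds, m@strand)
    expect_identical(substr(orf, 1, 3), "ATG")
    expect_true(substring(orf, nchar(orf) - 2L) %in% c("TAA", "TAG", "TGA"))
    expect_equal(nchar(orf) %% 3L, 0L)
  }
})

test_that("motif placements lie within transcripts and never overlap", {
  g <- synth_genome(nGenes = 60, seed = 21)
  tp <- g$truthPlacements
  expect_gt(nrow(tp), 100L)
  tx_len <- vapply(g$models, function(m)
    max(IRanges::end(m@exons)) - min(IRanges::start(m@exons)) + 1L, 0L)
  expect_true(all(tp$offset >= 1L))
  expect_true(all(tp$offset + tp$length_nt - 1L <= tx_len[tp$gene_id]))
  for (gid in unique(tp$gene_id)) {
    p <- tp[tp$gene_id == gid, ]
    p <- p[order(p$offset), ]
    if (nrow(p) > 1L)
      expect_true(all(p$offset[-1L] > (p$offset + p$length_nt - 1L)[-nrow(p)]))
  }
  # intact copies in high-class genes; mutations only in low-class genes
  cls <- setNames(g$truthGenes$class, g$truthGenes$gene_id)
  expect_true(all(tp$n_mutations[cls[tp$gene_id] == "high"] == 0L))
  expect_gt(sum(tp$n_mutations[cls[tp$gene_id] == "low"]), 0L)
  # and the intact placements really carry the motif sequence
  gchr <- as.character(g$genome)
  hi <- tp[cls[tp$gene_id] == "high", ][1:20, ]
  for (i in seq_len(nrow(hi))) {
    m <- g$models[[hi$gene_id[i]]]
    span <- IRanges::IRanges(min(IRanges::start(m@exons)),
                             max(IRanges::end(m@exons)))
    tx <- arsiscan:::region_seq(gchr[[m@chrom]], span, m@strand)
    expect_identical(substr(tx, hi$offset[i],
                            hi$offset[i] + hi$length_nt[i] - 1L),
                     g$motifs[[hi$motif_id[i]]])
  }
})

test_that("the truth tables round-trip losslessly through disk", {
  g <- synth_genome(nGenes = 20, seed = 23)
  d <- withr::local_tempdir()
  writeSyntheticGenome(g, d)
  tg <- read.delim(file.path(d, "truth_genes.tsv"))
  tp <- read.delim(file.path(d, "truth_placements.tsv"))
  expect_equal(tg, g$truthGenes, tolerance = 1e-12)
  expect_equal(tp, g$truthPlacements, tolerance = 1e-12)
  expr <- readExpression(file.path(d, "expression.tsv"))
  expect_equal(expr, g$expression, tolerance = 1e-12)
  # genome + annotation re-read to the same models
  g2 <- readGenome(file.path(d, "genome.fa"))
  expect_identical(as.character(g2), as.character(g$genome))
  mods <- readAnnotation(file.path(d, "annotation.gff3"))
  expect_identical(names(mods), names(g$models))
  for (gid in names(mods)) {
    expect_identical(as.data.frame(mods[[gid]]@exons),
                     as.data.frame(g$models[[gid]]@exons))
    expect_identical(as.data.frame(mods[[gid]]@cds),
                     as.data.frame(g$models[[gid]]@cds))
    expect_identical(mods[[gid]]@strand, g$models[[gid]]@strand)
  }
})

test_that("zero placement density erases the class signal (negative control)", {
  g0 <- synthesizeGenome(syntheticSpec(nGenes = 60, densityInBand = 0,
                                       densityBackground = 0, seed = 11))
  expect_equal(nrow(g0$truthPlacements), 0L)
  sc <- scoreRegions(g0$genome, g0$models, "orf")
  gs <- perGeneScores(sc)
  hl <- splitHighLow(g0$expression, "mrna")
  cg <- compareGroups(gs, hl$high, hl$low)
  expect_gt(cg$p.value, 0.01)
})

test_that("high-class genes outscore low-class genes at defaults", {
  g <- synth_genome(nGenes = 60, seed = 21)
  sc <- perGeneScores(scoreRegions(g$genome, g$models, "orf"))
  cls <- setNames(g$truthGenes$class, g$truthGenes$gene_id)
  hi <- sc$arsi[cls[sc$gene_id] == "high"]
  lo <- sc$arsi[cls[sc$gene_id] == "low"]
  expect_gt(median(hi), median(lo))
})

test_that("invalid specifications are rejected", {
  expect_error(syntheticSpec(fracHigh = 1.4), "probabilities")
  expect_error(syntheticSpec(exprMeanlogHigh = 1, exprMeanlogLow = 2),
               "exceed")
  expect_error(syntheticSpec(motifCount = 0), "motifCount")
})
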