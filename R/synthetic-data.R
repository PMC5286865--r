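#' @include null-models.R
NULL

#' Specification for a synthetic motif-bearing genome
#'
#' Describes a multi-gene genome whose transcripts carry motifs from a
#' shared library, placed densely near ORF boundaries and splice sites and
#' sparsely elsewhere. Motif copies are intact in "highly expressed" genes
#' and point-mutated in "lowly expressed" genes, over an i.i.d. background
#' of configurable GC content. Introns carry canonical GT..TACTAAC..AG
#' signals.
#'
#' @param nGenes number of genes.
#' @param fracHigh fraction of genes in the high-expression class.
#' @param motifCount motif library size.
#' @param motifLenRange motif length range (nt).
#' @param backgroundGC background GC fraction.
#' @param utr5Range,utr3Range UTR length ranges (nt, uniform).
#' @param orfCodonRange ORF length range in codons (uniform; includes start
#'   and stop).
#' @param intronLenRange intron length range (nt, uniform).
#' @param intronProb per-gene intron propensity; the intron count is
#'   Binomial(2, `intronProb`), so some genes carry two introns.
#' @param anchorBand half-width (nt) of the motif-enriched band around each
#'   anchor (ORF start/end, splice sites).
#' @param densityInBand,densityBackground expected motif placements per
#'   100 nt inside / outside the band.
#' @param mutationRateLow per-nt substitution probability applied to motif
#'   copies in low-expression genes.
#' @param exprMeanlogHigh,exprMeanlogLow,exprSdlog log-normal expression
#'   model per class (`exprMeanlogHigh > exprMeanlogLow`).
#' @param paNoiseSdlog log-normal noise linking protein abundance to mRNA.
#' @param genesPerChrom genes per chromosome.
#' @param spacer intergenic spacer length (nt).
#' @param seed integer seed; the whole genome is a deterministic function
#'   of the spec.
#' @return a validated list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nGenes = 200L, fracHigh = 0.5, motifCount = 30L,
                          motifLenRange = c(8L, 25L), backgroundGC = 0.40,
                          utr5Range = c(40L, 150L), utr3Range = c(60L, 200L),
                          orfCodonRange = c(100L, 500L),
                          intronLenRange = c(80L, 400L), intronProb = 0.3,
                          anchorBand = 50L, densityInBand = 3.0,
                          densityBackground = 0.3, mutationRateLow = 0.15,
                          exprMeanlogHigh = log(100),
                          exprMeanlogLow = log(10), exprSdlog = 0.5,
                          paNoiseSdlog = 0.4, genesPerChrom = 100L,
                          spacer = 300L, seed = 1L) {
  spec <- list(nGenes = as.integer(nGenes), fracHigh = fracHigh,
               motifCount = as.integer(motifCount),
               motifLenRange = as.integer(motifLenRange),
               backgroundGC = backgroundGC,
               utr5Range = as.integer(utr5Range),
               utr3Range = as.integer(utr3Range),
               orfCodonRange = as.integer(orfCodonRange),
               intronLenRange = as.integer(intronLenRange),
               intronProb = intronProb, anchorBand = as.integer(anchorBand),
               densityInBand = densityInBand,
               densityBackground = densityBackground,
               mutationRateLow = mutationRateLow,
               exprMeanlogHigh = exprMeanlogHigh,
               exprMeanlogLow = exprMeanlogLow, exprSdlog = exprSdlog,
               paNoiseSdlog = paNoiseSdlog,
               genesPerChrom = as.integer(genesPerChrom),
               spacer = as.integer(spacer), seed = as.integer(seed))
  probs <- c(spec$fracHigh, spec$intronProb, spec$mutationRateLow,
             spec$backgroundGC)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (spec$exprMeanlogHigh <= spec$exprMeanlogLow)
    stop("exprMeanlogHigh must exceed exprMeanlogLow")
  if (spec$motifCount < 1L) stop("motifCount must be >= 1")
  class(spec) <- "SyntheticSpec"
  spec
}

rand_bases <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

rand_seq <- function(n, gc) paste(rand_bases(n, gc), collapse = "")

#' Draw a motif library
#'
#' Pairwise-distinct i.i.d. motifs at the background GC content.
#'
#' @param spec a [syntheticSpec()].
#' @param seed integer seed (defaults to the spec's).
#' @return character vector of motif sequences, named `motif_1` ...
#' @export
makeMotifLibrary <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < spec$motifCount) {
      len <- sample(seq(spec$motifLenRange[1], spec$motifLenRange[2]), 1L)
      m <- rand_seq(len, spec$backgroundGC)
      if (!m %in% out) out <- c(out, m)
      else if ((tries <- tries + 1L) > 100L * spec$motifCount)
        stop("could not draw pairwise-distinct motifs")
    }
    stats::setNames(out, paste0("motif_", seq_along(out)))
  })
}

# sense-codon sampler weighted toward the background GC content
sense_codon_table <- function(gc) {
  gcode <- Biostrings::GENETIC_CODE
  codons <- names(gcode)[gcode != "*"]
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(strsplit(codons, ""), function(b) prod(p[b]), numeric(1))
  list(codons = codons, w = w / sum(w))
}

#' Synthesize a genome with known motif placements
#'
#' Generates `spec$nGenes` genes laid head-to-tail (random strand) with
#' intergenic spacers, one chromosome per `spec$genesPerChrom` genes. Each
#' gene has a 5'UTR, a stop-free ORF (start and stop codons in place), 0-2
#' canonical introns inside the CDS, and a 3'UTR. Motifs from a shared
#' library are placed by a distance-to-anchor density, never overlapping
#' each other, the splice consensus, or the start/stop codons; copies in
#' low-expression genes are point-mutated at `spec$mutationRateLow`.
#' Expression is assigned by class (log-normal), not by realized motif
#' integrity.
#'
#' @param spec a [syntheticSpec()].
#' @param dir optional output directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `expression.tsv`, `truth_genes.tsv`,
#'   `truth_placements.tsv` and `motifs.tsv`.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `models` (named
#'   list of [GeneModel]), `expression` (`gene_id`, `mrna`, `pa`),
#'   `truthGenes` (`gene_id`, `class`, `mrna`, `pa`), `truthPlacements`
#'   (`gene_id`, `motif_id`, `offset`, `length_nt`, `n_mutations`),
#'   `motifs`, and `spec`.
#' @export
synthesizeGenome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  motifs <- makeMotifLibrary(spec)
  with_seed(spec$seed + 1L, {
    sct <- sense_codon_table(spec$backgroundGC)
    n_high <- round(spec$nGenes * spec$fracHigh)
    classes <- sample(rep(c("high", "low"),
                          c(n_high, spec$nGenes - n_high)))
    n_chrom <- ceiling(spec$nGenes / spec$genesPerChrom)
    chrom_parts <- replicate(n_chrom, list(), simplify = FALSE)
    chrom_len <- integer(n_chrom)
    models <- list()
    gff <- list()
    truth_genes <- list()
    truth_place <- list()
    exprs <- list()

    for (i in seq_len(spec$nGenes)) {
      gid <- sprintf("g%04d", i)
      cls <- classes[i]
      u5 <- sample(seq(spec$utr5Range[1], spec$utr5Range[2]), 1L)
      u3 <- sample(seq(spec$utr3Range[1], spec$utr3Range[2]), 1L)
      n_codons <- sample(seq(spec$orfCodonRange[1], spec$orfCodonRange[2]), 1L)
      orf_len <- 3L * n_codons
      orf <- paste0("ATG",
                    paste(sample(sct$codons, n_codons - 2L, replace = TRUE,
                                 prob = sct$w), collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      m_introns <- rbinom(1L, 2L, spec$intronProb)
      intron_seqs <- character(0)
      bs_off <- integer(0)  # branch-site start within each intron
      if (m_introns > 0L) {
        for (k in seq_len(m_introns)) {
          ilen <- sample(seq(spec$intronLenRange[1], spec$intronLenRange[2]), 1L)
          gap <- sample(15:35, 1L)
          mid <- ilen - 6L - 7L - gap - 3L
          intron_seqs[k] <- paste0("GTATGT", rand_seq(mid, spec$backgroundGC),
                                   "TACTAAC", rand_seq(gap, spec$backgroundGC),
                                   sample(c("C", "T"), 1L), "AG")
          bs_off[k] <- 6L + mid + 1L
        }
        # insertion points: intron k sits after ORF position ins[k]
        repeat {
          ins <- sort(sample(seq(30L, orf_len - 30L), m_introns))
          if (m_introns == 1L || min(diff(ins)) >= 60L) break
        }
      }
      # assemble pre-mRNA
      utr5_seq <- rand_seq(u5, spec$backgroundGC)
      utr3_seq <- rand_seq(u3, spec$backgroundGC)
      if (m_introns > 0L) {
        cuts <- c(0L, ins, orf_len)
        orf_pieces <- substring(orf, head(cuts, -1L) + 1L, cuts[-1L])
        body <- orf_pieces[1L]
        intron_at <- integer(m_introns)  # premrna start of each intron
        for (k in seq_len(m_introns)) {
          intron_at[k] <- u5 + nchar(body) + 1L
          body <- paste0(body, intron_seqs[k], orf_pieces[k + 1L])
        }
        premrna <- paste0(utr5_seq, body, utr3_seq)
      } else {
        intron_at <- integer(0)
        premrna <- paste0(utr5_seq, orf, utr3_seq)
      }
      L <- nchar(premrna)
      tot_intron <- sum(nchar(intron_seqs))
      orf_start <- u5 + 1L
      orf_end <- u5 + tot_intron + orf_len - 2L  # first stop nt
      anchor_pos <- c(orf_start, orf_end)
      if (m_introns > 0L) {
        anchor_pos <- c(anchor_pos, intron_at,
                        intron_at + nchar(intron_seqs) - 1L)
      }
      # protected positions: start/stop codons and splice consensus
      occupied <- logical(L)
      occupied[orf_start:(orf_start + 2L)] <- TRUE
      occupied[orf_end:(orf_end + 2L)] <- TRUE
      for (k in seq_len(m_introns)) {
        a <- intron_at[k]
        ilen <- nchar(intron_seqs[k])
        occupied[a:(a + 5L)] <- TRUE
        occupied[(a + bs_off[k] - 1L):(a + bs_off[k] + 5L)] <- TRUE
        occupied[(a + ilen - 3L):(a + ilen - 1L)] <- TRUE
      }
      # distance-to-anchor placement density (motifs per nt)
      d <- Reduce(pmin, lapply(anchor_pos,
                               function(a) abs(seq_len(L) - a)))
      dens <- ifelse(d <= spec$anchorBand, spec$densityInBand,
                     spec$densityBackground) / 100
      n_place <- if (sum(dens) > 0) rpois(1L, sum(dens)) else 0L
      ch <- strsplit(premrna, "", fixed = TRUE)[[1L]]
      placed <- list()
      for (pp in seq_len(n_place)) {
        done <- FALSE
        for (try in seq_len(50L)) {
          mi <- sample(spec$motifCount, 1L)
          mseq <- motifs[[mi]]
          mlen <- nchar(mseq)
          s0 <- sample.int(L, 1L, prob = dens)
          if (s0 + mlen - 1L > L) next
          span <- s0:(s0 + mlen - 1L)
          if (any(occupied[span])) next
          mot <- strsplit(mseq, "", fixed = TRUE)[[1L]]
          nmut <- 0L
          if (cls == "low" && spec$mutationRateLow > 0) {
            hit <- which(runif(mlen) < spec$mutationRateLow)
            for (hh in hit) mot[hh] <- sample(setdiff(c("A", "C", "G", "T"),
                                                      mot[hh]), 1L)
            nmut <- length(hit)
          }
          ch[span] <- mot
          occupied[span] <- TRUE
          placed[[length(placed) + 1L]] <-
            data.frame(gene_id = gid, motif_id = names(motifs)[mi],
                       offset = s0, length_nt = mlen, n_mutations = nmut,
                       stringsAsFactors = FALSE)
          done <- TRUE
          break
        }
        if (!done) next
      }
      premrna <- paste(ch, collapse = "")

      # place on a chromosome
      ci <- ceiling(i / spec$genesPerChrom)
      strand <- sample(c("+", "-"), 1L)
      chrom_parts[[ci]][[length(chrom_parts[[ci]]) + 1L]] <-
        rand_seq(spec$spacer, spec$backgroundGC)
      block_start <- chrom_len[ci] + spec$spacer + 1L
      block <- if (strand == "-") revcomp(premrna) else premrna
      chrom_parts[[ci]][[length(chrom_parts[[ci]]) + 1L]] <- block
      chrom_len[ci] <- chrom_len[ci] + spec$spacer + L
      chrom <- paste0("chr", ci)

      # premrna intervals -> genomic
      to_gen <- function(a, b) {
        if (strand == "+") c(block_start + a - 1L, block_start + b - 1L)
        else c(block_start + L - b, block_start + L - a)
      }
      mk_ir <- function(ivs) {
        # ivs: list of c(a, b) premrna intervals
        g <- lapply(ivs, function(v) to_gen(v[1L], v[2L]))
        ir <- IRanges::IRanges(start = vapply(g, `[`, 0L, 1L),
                               end = vapply(g, `[`, 0L, 2L))
        ir[order(IRanges::start(ir))]
      }
      intron_ivs <- if (m_introns > 0L)
        Map(function(a, s) c(a, a + nchar(s) - 1L), intron_at, intron_seqs)
      else list()
      # exons = complement of introns in [1, L]
      exon_ivs <- list()
      pos <- 1L
      for (iv in intron_ivs) {
        exon_ivs[[length(exon_ivs) + 1L]] <- c(pos, iv[1L] - 1L)
        pos <- iv[2L] + 1L
      }
      exon_ivs[[length(exon_ivs) + 1L]] <- c(pos, L)
      # CDS premrna span minus introns
      cds_ivs <- list()
      cds_a <- u5 + 1L
      cds_b <- L - u3
      pos <- cds_a
      for (iv in intron_ivs) {
        if (iv[1L] > pos) cds_ivs[[length(cds_ivs) + 1L]] <- c(pos, iv[1L] - 1L)
        pos <- iv[2L] + 1L
      }
      if (pos <= cds_b) cds_ivs[[length(cds_ivs) + 1L]] <- c(pos, cds_b)

      model <- methods::new("GeneModel",
        geneID = gid, chrom = chrom, strand = strand,
        exons = mk_ir(exon_ivs), cds = mk_ir(cds_ivs),
        fiveUTR = mk_ir(list(c(1L, u5))),
        threeUTR = mk_ir(list(c(L - u3 + 1L, L))),
        notes = character(0))
      models[[gid]] <- model

      mrna <- rlnorm(1L, if (cls == "high") spec$exprMeanlogHigh
                         else spec$exprMeanlogLow, spec$exprSdlog)
      pa <- mrna * rlnorm(1L, 0, spec$paNoiseSdlog)
      exprs[[gid]] <- data.frame(gene_id = gid, mrna = mrna, pa = pa,
                                 stringsAsFactors = FALSE)
      truth_genes[[gid]] <- data.frame(gene_id = gid, class = cls,
                                       mrna = mrna, pa = pa,
                                       stringsAsFactors = FALSE)
      if (length(placed))
        truth_place[[gid]] <- do.call(rbind, placed)

      gff[[gid]] <- build_gff_rows(model)
    }

    genome <- Biostrings::DNAStringSet(vapply(seq_len(n_chrom), function(ci) {
      paste0(paste(unlist(chrom_parts[[ci]]), collapse = ""),
             rand_seq(spec$spacer, spec$backgroundGC))
    }, ""))
    names(genome) <- paste0("chr", seq_len(n_chrom))

    out <- list(
      genome = genome,
      models = models,
      expression = do.call(rbind, unname(exprs)),
      truthGenes = do.call(rbind, unname(truth_genes)),
      truthPlacements = if (length(truth_place))
        do.call(rbind, unname(truth_place))
      else data.frame(gene_id = character(0), motif_id = character(0),
                      offset = integer(0), length_nt = integer(0),
                      n_mutations = integer(0)),
      motifs = motifs,
      gff = do.call(rbind, unname(gff)),
      spec = spec
    )
    rownames(out$expression) <- rownames(out$truthGenes) <-
      rownames(out$truthPlacements) <- NULL
    if (!is.null(dir)) writeSyntheticGenome(out, dir)
    out
  })
}

# GFF3 feature rows (data.frame) for one gene model
build_gff_rows <- function(m) {
  gid <- m@geneID
  tid <- paste0(gid, ".t1")
  span <- c(min(IRanges::start(m@exons)), max(IRanges::end(m@exons)))
  row <- function(type, s, e, id, parent, phase = NA_integer_) {
    data.frame(chrom = m@chrom, type = type, start = s, end = e,
               strand = m@strand, ID = id, Parent = parent, phase = phase,
               stringsAsFactors = FALSE)
  }
  rows <- list(row("gene", span[1L], span[2L], gid, NA_character_),
               row("mRNA", span[1L], span[2L], tid, gid))
  # CDS phase per piece, transcription order
  w <- IRanges::width(m@cds)
  wT <- if (m@strand == "-") rev(w) else w
  phT <- (3L - c(0L, cumsum(wT)[-length(wT)]) %% 3L) %% 3L
  cds_phase <- if (m@strand == "-") rev(phT) else phT
  feat <- function(type, ir, tag, phase = rep(NA_integer_, length(ir))) {
    lapply(seq_along(ir), function(k)
      row(type, IRanges::start(ir)[k], IRanges::end(ir)[k],
          paste0(gid, ".", tag, k), tid, phase[k]))
  }
  do.call(rbind, c(rows, feat("exon", m@exons, "e"),
                   feat("CDS", m@cds, "c", cds_phase),
                   feat("five_prime_UTR", m@fiveUTR, "u5."),
                   feat("three_prime_UTR", m@threeUTR, "u3.")))
}

#' Write a synthetic genome bundle to disk
#'
#' @param x list as returned by [synthesizeGenome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticGenome <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(x$genome, file.path(dir, "genome.fa"))
  g <- x$gff
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand)
  gr$type <- g$type
  gr$ID <- g$ID
  gr$phase <- g$phase
  gr$Parent <- IRanges::CharacterList(
    lapply(g$Parent, function(p) if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, file.path(dir, "annotation.gff3"), format = "gff3")
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(x$expression, "expression.tsv")
  tsv(x$truthGenes, "truth_genes.tsv")
  tsv(x$truthPlacements, "truth_placements.tsv")
  tsv(data.frame(motif_id = names(x$motifs), sequence = unname(x$motifs)),
      "motifs.tsv")
  invisible(dir)
}
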