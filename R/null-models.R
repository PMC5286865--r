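#' @include sequence-io.R
NULL

# rotate-right: move the last r characters to the front
rotate_right <- function(s, r) {
  n <- nchar(s)
  r <- r %% n
  if (r == 0L) return(s)
  paste0(substr(s, n - r + 1L, n), substr(s, 1L, n - r))
}

# split a transcript-orientation sequence back onto ascending genomic
# intervals (reverse-complementing pieces for minus-strand genes)
split_back <- function(new_seq, ir, strand) {
  w <- IRanges::width(ir)
  wT <- if (strand == "-") rev(w) else w
  ends <- cumsum(wT)
  starts <- ends - wT + 1L
  piecesT <- substring(new_seq, starts, ends)
  if (strand == "-") {
    rev(vapply(piecesT, revcomp, "", USE.NAMES = FALSE))
  } else {
    piecesT
  }
}

#' Splice-consensus specification for intron randomization
#'
#' Defaults describe budding-yeast-like introns: a 6 nt donor (5'SS)
#' prefix, the TACTAAC branch-site motif searched within the last 60 nt,
#' and a 3 nt acceptor (3'SS) suffix.
#'
#' @param fiveSSLen donor prefix length held fixed (nt).
#' @param threeSSLen acceptor suffix length held fixed (nt).
#' @param branchMotif IUPAC branch-site motif held fixed at its best hit.
#' @param branchWindow search window for the branch motif, counted from the
#'   intron 3' end (nt).
#' @return a list with the four components.
#' @export
consensusSpec <- function(fiveSSLen = 6L, threeSSLen = 3L,
                          branchMotif = "TACTAAC", branchWindow = 60L) {
  list(fiveSSLen = as.integer(fiveSSLen), threeSSLen = as.integer(threeSSLen),
       branchMotif = branchMotif, branchWindow = as.integer(branchWindow))
}

#' Permute synonymous codons genome-wide
#'
#' Pools the codons of all ORFs by encoded amino acid (standard genetic
#' code; stop codons form their own family, as do codons containing N) and
#' permutes each family uniformly across the genome, writing the permuted
#' codons back in place. Every protein sequence and the genome-wide codon
#' multiset — hence codon-usage bias — are conserved exactly.
#'
#' @param orfs named character vector of ORF sequences (start through stop,
#'   transcript orientation).
#' @param seed optional integer seed.
#' @param perGene permute within genes instead of genome-wide.
#' @return named character vector of randomized ORFs. ORFs whose length is
#'   not a multiple of three are returned unchanged with a warning;
#'   internal stop codons are permuted within the stop family (one message).
#' @export
permuteSynonymousCodons <- function(orfs, seed = NULL, perGene = FALSE) {
  orfs <- stats::setNames(as.character(orfs), names(orfs))
  ok <- nchar(orfs) %% 3L == 0L & nchar(orfs) > 0L
  if (any(!ok)) {
    warning(sum(!ok), " ORF(s) with length not divisible by 3; left unchanged")
  }
  if (!any(ok)) return(orfs)
  with_seed(seed, {
    codons_by_gene <- lapply(orfs[ok], function(s) {
      n <- nchar(s)
      substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    })
    gene_of <- rep(seq_along(codons_by_gene), lengths(codons_by_gene))
    codons <- unlist(codons_by_gene, use.names = FALSE)
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"
    is_last <- seq_along(aa) %in% cumsum(lengths(codons_by_gene))
    if (any(aa == "*" & !is_last)) {
      message("internal stop codons present; permuted within the stop family")
    }
    key <- if (perGene) paste(gene_of, aa) else aa
    fam <- split(seq_along(codons), key)
    for (idx in fam) {
      codons[idx] <- codons[idx][sample.int(length(idx))]
    }
    out <- orfs
    out[ok] <- vapply(split(codons, gene_of), paste, "", collapse = "",
                      USE.NAMES = FALSE)
    out
  })
}

#' Randomize one intron preserving splice consensus and composition
#'
#' Positions of the donor prefix, the acceptor suffix and the best
#' (3'-most) IUPAC hit of the branch motif inside the search window are
#' held fixed; all remaining positions are uniformly permuted. The
#' nucleotide multiset — hence GC content — is conserved exactly.
#'
#' @param intron intron sequence (transcript orientation).
#' @param spec a [consensusSpec()].
#' @param seed optional integer seed.
#' @return randomized intron. Introns no longer than the fixed termini are
#'   returned unchanged with a warning; a missing branch hit fixes only the
#'   termini.
#' @export
permuteIntron <- function(intron, spec = consensusSpec(), seed = NULL) {
  n <- nchar(intron)
  if (n <= spec$fiveSSLen + spec$threeSSLen) {
    warning("intron too short to randomize (", n, " nt); returned unchanged")
    return(intron)
  }
  fixed <- c(seq_len(spec$fiveSSLen), seq.int(n - spec$threeSSLen + 1L, n))
  win_start <- max(1L, n - spec$branchWindow + 1L)
  win <- substr(intron, win_start, n)
  hits <- Biostrings::matchPattern(spec$branchMotif,
                                   Biostrings::DNAString(win), fixed = FALSE)
  if (length(hits)) {
    h <- hits[length(hits)]  # 3'-most hit
    bs <- win_start + BiocGenerics::start(h) - 1L
    fixed <- c(fixed, seq.int(bs, bs + nchar(spec$branchMotif) - 1L))
  }
  fixed <- sort(unique(fixed))
  free <- setdiff(seq_len(n), fixed)
  if (length(free) < 2L) return(intron)
  ch <- strsplit(intron, "", fixed = TRUE)[[1L]]
  with_seed(seed, {
    ch[free] <- ch[free][sample.int(length(free))]
    paste(ch, collapse = "")
  })
}

#' Cyclically shift a UTR preserving composition
#'
#' 3'UTRs are rotated whole by a uniform random offset; for 5'UTRs the
#' terminal `contextLen` nucleotides (the start-codon context, immediately
#' preceding the ATG) are held fixed and only the remaining prefix is
#' rotated. Rotation conserves length and nucleotide counts exactly.
#'
#' @param utr UTR sequence (transcript orientation).
#' @param kind `"five"` or `"three"`.
#' @param contextLen fixed 5' start-codon context length (nt, default 6).
#' @param seed optional integer seed.
#' @return randomized UTR; sequences too short to rotate are returned
#'   unchanged.
#' @export
cyclicShiftUtr <- function(utr, kind = c("five", "three"), contextLen = 6L,
                           seed = NULL) {
  kind <- match.arg(kind)
  n <- nchar(utr)
  if (n <= 1L) return(utr)
  with_seed(seed, {
    if (kind == "three") {
      rotate_right(utr, sample.int(n - 1L, 1L))
    } else {
      if (n <= contextLen + 1L) return(utr)
      m <- n - contextLen
      if (m <= 1L) return(utr)
      paste0(rotate_right(substr(utr, 1L, m), sample.int(m - 1L, 1L)),
             substr(utr, m + 1L, n))
    }
  })
}

#' Randomize a genome under composition-preserving schemes
#'
#' Applies any subset of the three randomization schemes and writes the
#' randomized sequences back into the chromosome coordinates of each gene
#' (strand-aware), so all downstream extraction and scoring runs unchanged
#' on the result:
#' \describe{
#'   \item{codons}{genome-wide synonymous-codon permutation
#'     ([permuteSynonymousCodons()]): proteins and codon-usage bias
#'     conserved exactly.}
#'   \item{introns}{per-intron permutation fixing splice consensus
#'     ([permuteIntron()]): per-intron composition conserved exactly.}
#'   \item{utrs}{per-UTR cyclic shift ([cyclicShiftUtr()]): per-UTR
#'     composition and the 5' start-codon context conserved exactly.}
#' }
#' Each scheme draws from its own seed stream derived from `seed`, so the
#' schemes commute: any subset or application order with the same `seed`
#' yields the same genome. Genes are processed independently; overlapping
#' genes are not resolved.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param models list of [GeneModel] objects.
#' @param scheme character subset of `c("codons", "introns", "utrs")`, or
#'   `"all"`.
#' @param spec a [consensusSpec()] for intron randomization.
#' @param utrContextLen fixed 5'UTR context length (nt).
#' @param seed optional integer seed.
#' @return randomized genome as a [Biostrings::DNAStringSet].
#' @export
randomizeGenome <- function(genome, models,
                            scheme = c("codons", "introns", "utrs"),
                            spec = consensusSpec(), utrContextLen = 6L,
                            seed = NULL) {
  if (identical(scheme, "all")) scheme <- c("codons", "introns", "utrs")
  scheme <- match.arg(scheme, c("codons", "introns", "utrs"),
                      several.ok = TRUE)
  sub_seeds <- if (is.null(seed)) {
    stats::setNames(sample.int(.Machine$integer.max - 1L, 3L),
                    c("codons", "introns", "utrs"))
  } else {
    stats::setNames(derive_seeds(seed, 3L), c("codons", "introns", "utrs"))
  }
  gchr <- as_genome_chr(genome)
  # accumulate in-place replacements per chromosome (flat lists; one
  # IRanges construction per chromosome at the end)
  acc <- new.env(parent = emptyenv())
  acc$start <- list()
  acc$end <- list()
  acc$piece <- list()
  acc$chrom <- list()
  push <- function(chrom, ir, pieces) {
    i <- length(acc$start) + 1L
    acc$start[[i]] <- IRanges::start(ir)
    acc$end[[i]] <- IRanges::end(ir)
    acc$piece[[i]] <- pieces
    acc$chrom[[i]] <- rep(chrom, length(ir))
  }

  if ("codons" %in% scheme) {
    has_cds <- vapply(models, function(m)
      sum(IRanges::width(m@cds)) >= 3L, logical(1))
    cds_models <- models[has_cds]
    orfs <- vapply(cds_models, function(m)
      region_seq(gchr[[m@chrom]], m@cds, m@strand), "")
    rnd <- permuteSynonymousCodons(orfs, seed = sub_seeds[["codons"]])
    for (i in seq_along(cds_models)) {
      m <- cds_models[[i]]
      push(m@chrom, m@cds, split_back(rnd[i], m@cds, m@strand))
    }
  }
  if ("introns" %in% scheme) {
    with_seed(sub_seeds[["introns"]], {
      for (m in models) {
        iv <- introns(m)
        for (k in seq_along(iv)) {
          s <- region_seq(gchr[[m@chrom]], iv[k], m@strand)
          r <- suppressWarnings(permuteIntron(s, spec = spec))
          push(m@chrom, iv[k], split_back(r, iv[k], m@strand))
        }
      }
    })
  }
  if ("utrs" %in% scheme) {
    with_seed(sub_seeds[["utrs"]], {
      for (m in models) {
        if (length(m@fiveUTR)) {
          s <- region_seq(gchr[[m@chrom]], m@fiveUTR, m@strand)
          r <- cyclicShiftUtr(s, "five", contextLen = utrContextLen)
          push(m@chrom, m@fiveUTR, split_back(r, m@fiveUTR, m@strand))
        }
        if (length(m@threeUTR)) {
          s <- region_seq(gchr[[m@chrom]], m@threeUTR, m@strand)
          r <- cyclicShiftUtr(s, "three")
          push(m@chrom, m@threeUTR, split_back(r, m@threeUTR, m@strand))
        }
      }
    })
  }
  out <- Biostrings::DNAStringSet(gchr)
  if (length(acc$start)) {
    starts <- unlist(acc$start, use.names = FALSE)
    ends <- unlist(acc$end, use.names = FALSE)
    pieces <- unlist(acc$piece, use.names = FALSE)
    chroms <- unlist(acc$chrom, use.names = FALSE)
    for (chrom in unique(chroms)) {
      sel <- chroms == chrom
      out[[chrom]] <- Biostrings::replaceAt(
        out[[chrom]], IRanges::IRanges(starts[sel], ends[sel]),
        Biostrings::DNAStringSet(pieces[sel]))
    }
  }
  out
}

#' Ensemble of statistics over randomized-genome replicates
#'
#' Generates `R` independent randomized genomes and evaluates `statFun`
#' (signature `function(genome, models)`) on each with parameters identical
#' to the real run. Replicate seeds are derived from `seed`, so the same
#' seed reproduces the same ensemble.
#'
#' @inheritParams randomizeGenome
#' @param statFun function of `(genome, models)` returning the per-replicate
#'   statistic (scores, a profile, ...).
#' @param R replicate count (>= 2; default 50).
#' @return a [NullEnsemble].
#' @export
nullEnsemble <- function(genome, models, statFun,
                         scheme = c("codons", "introns", "utrs"), R = 50L,
                         seed = NULL, spec = consensusSpec(),
                         utrContextLen = 6L) {
  if (R < 2L) stop("R must be >= 2 to estimate a standard deviation")
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, R)
           else derive_seeds(seed, R)
  stats_list <- lapply(seq_len(R), function(r) {
    statFun(randomizeGenome(genome, models, scheme = scheme, spec = spec,
                            utrContextLen = utrContextLen, seed = seeds[r]),
            models)
  })
  methods::new("NullEnsemble",
    scheme = scheme, R = as.integer(R),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    stats = stats_list)
}

#' Z-score of a real signal against a null ensemble
#'
#' z = (real - null mean) / null sd, with the sample standard deviation
#' (denominator R - 1) over replicates, per scalar or per profile offset.
#' Positions where the null sd is zero (or a replicate is undefined) are
#' returned as `NA` and flagged, never as infinities.
#'
#' @param real a numeric scalar/vector, or an [AlignedAnchorProfile].
#' @param ensemble a [NullEnsemble] whose statistics match `real` in shape.
#' @return for numeric `real`: a numeric vector with attribute `undefined`
#'   (indices with zero null sd). For a profile: a [ZProfile].
#' @export
zScore <- function(real, ensemble) {
  stopifnot(methods::is(ensemble, "NullEnsemble"))
  if (methods::is(real, "AlignedAnchorProfile")) {
    reps <- ensemble@stats
    stopifnot(all(vapply(reps, methods::is, logical(1),
                         "AlignedAnchorProfile")))
    mat <- do.call(rbind, lapply(reps, function(p) p@mean))
    if (ncol(mat) != length(real@offsets))
      stop("ensemble profiles do not match the real profile's offsets")
    mu <- colMeans(mat)
    sdv <- apply(mat, 2L, stats::sd)
    z <- (real@mean - mu) / sdv
    bad <- which(!is.finite(z))
    z[bad] <- NA_real_
    return(methods::new("ZProfile",
      anchor = real@anchor, offsets = real@offsets, real = real@mean,
      nullMean = mu, nullSD = sdv, z = z, R = ensemble@R,
      undefined = real@offsets[bad]))
  }
  mat <- do.call(rbind, lapply(ensemble@stats, as.numeric))
  if (ncol(mat) != length(real)) stop("ensemble statistics do not match real")
  mu <- colMeans(mat)
  sdv <- apply(mat, 2L, stats::sd)
  z <- (real - mu) / sdv
  bad <- which(!is.finite(z))
  z[bad] <- NA_real_
  attr(z, "undefined") <- bad
  z
}

#' Paired test of real vs. matched randomized scores
#'
#' Two-sided Wilcoxon signed-rank test of per-element real scores against
#' the scores of one matched randomized replicate.
#'
#' @param real,random equal-length paired numeric score vectors.
#' @return list with `statistic`, `p.value`, `median_real`,
#'   `median_random`, `method`. If every difference is zero the p-value is
#'   1 (with a message).
#' @export
pairedRealVsRandomTest <- function(real, random) {
  if (length(real) != length(random)) stop("paired vectors differ in length")
  if (all(real == random)) {
    message("all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, p.value = 1,
                median_real = stats::median(real),
                median_random = stats::median(random),
                method = "Wilcoxon signed rank test (degenerate)"))
  }
  ht <- stats::wilcox.test(real, random, paired = TRUE, exact = FALSE,
                           correct = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       median_real = stats::median(real),
       median_random = stats::median(random), method = ht$method)
}

#' Z-score profile pipeline
#'
#' Computes the real anchor-aligned profile, an ensemble of profiles on
#' randomized genomes under the given scheme, and their per-offset Z-scores.
#'
#' @inheritParams anchorProfile
#' @inheritParams nullEnsemble
#' @return a [ZProfile].
#' @export
zscoreProfile <- function(genome, models, anchor = "orf_start", WL = 41L,
                          n = 4L, scheme = c("codons", "introns", "utrs"),
                          R = 50L, seed = NULL, spec = consensusSpec()) {
  real <- anchorProfile(genome, models, anchor = anchor, WL = WL, n = n)
  ens <- nullEnsemble(genome, models,
                      statFun = function(g, m)
                        anchorProfile(g, m, anchor = anchor, WL = WL, n = n),
                      scheme = scheme, R = R, seed = seed, spec = spec)
  zScore(real, ens)
}
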