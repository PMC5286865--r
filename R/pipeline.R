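#' @include profiles.R null-models.R expression-stats.R
NULL

#' Leave-one-out ARSI scores for one region kind across a genome
#'
#' Extracts the requested region from every gene and scores each element
#' against all the other genes' elements of the same region kind
#' (region-matched reference, excluding the scored gene). `"premrna"`
#' scores the full pre-mRNA (all introns retained, one element per gene).
#'
#' @inheritParams extractRegions
#' @param models named list of [GeneModel] objects.
#' @param region one of `"five_utr"`, `"orf"`, `"intron"`, `"three_utr"`,
#'   `"premrna"`, `"upstream_flank"`, `"downstream_flank"`.
#' @param exclude leave-one-out policy, see [arsiLeaveOneOut()].
#' @return `data.frame` with `element_id`, `gene_id`, `region`,
#'   `length_nt`, `arsi`.
#' @export
scoreRegions <- function(genome, models,
                         region = c("premrna", "orf", "five_utr",
                                    "three_utr", "intron", "upstream_flank",
                                    "downstream_flank"),
                         flankLength = 250L, utrFallback = 0L,
                         exclude = c("gene", "element")) {
  region <- match.arg(region)
  exclude <- match.arg(exclude)
  genome <- as_genome_chr(genome)
  rows <- list()
  for (m in models) {
    if (region == "premrna") {
      span <- IRanges::IRanges(min(IRanges::start(m@exons)),
                               max(IRanges::end(m@exons)))
      s <- region_seq(genome[[m@chrom]], span, m@strand)
      if (nchar(s))
        rows[[length(rows) + 1L]] <- data.frame(
          element_id = paste0(m@geneID, "|premrna|1"), gene_id = m@geneID,
          sequence = s, stringsAsFactors = FALSE)
    } else {
      rs <- extractRegions(genome, m, flankLength = flankLength,
                           utrFallback = utrFallback)
      sq <- regionSeqs(rs)
      kinds <- sub("\\.\\d+$", "", names(sq))
      sel <- which(kinds == region)
      for (j in sel) {
        idx <- if (grepl("\\.\\d+$", names(sq)[j]))
          sub("^.*\\.", "", names(sq)[j]) else "1"
        rows[[length(rows) + 1L]] <- data.frame(
          element_id = paste(m@geneID, region, idx, sep = "|"),
          gene_id = m@geneID, sequence = sq[[j]], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) < 2L)
    stop("fewer than 2 elements of region '", region, "'")
  elements <- do.call(rbind, rows)
  res <- arsiLeaveOneOut(elements, exclude = exclude)
  data.frame(element_id = res$element_id, gene_id = res$gene_id,
             region = region, length_nt = res$length_nt, arsi = res$arsi,
             stringsAsFactors = FALSE)
}

#' Per-gene ARSI scores from element scores
#'
#' Averages element scores within genes (relevant for multi-intron genes),
#' giving one score per gene for expression analyses.
#'
#' @param scores output of [scoreRegions()].
#' @return `data.frame` with `gene_id` and `arsi`.
#' @export
perGeneScores <- function(scores) {
  agg <- tapply(scores$arsi, scores$gene_id, mean)
  data.frame(gene_id = names(agg), arsi = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Correlate region scores with expression
#'
#' Spearman correlation of per-gene ARSI with an expression field, plus the
#' partial Spearman correlation controlling for element length.
#'
#' @param scores output of [scoreRegions()].
#' @param expr expression table ([readExpression()]).
#' @param field `"mrna"` or `"pa"`.
#' @return `data.frame` with one row per analysis (`plain`,
#'   `partial_length`): `rho`, `p.value`, `n`.
#' @export
correlateWithExpression <- function(scores, expr, field = c("mrna", "pa")) {
  field <- match.arg(field)
  gs <- perGeneScores(scores)
  len <- tapply(scores$length_nt, scores$gene_id, mean)[gs$gene_id]
  plain <- spearmanCorr(gs, expr, field)
  i <- match(gs$gene_id, expr$gene_id)
  part <- partialSpearman(gs$arsi, expr[[field]][i],
                          controls = list(length = as.numeric(len)))
  data.frame(
    analysis = c("plain", "partial_length"),
    rho = c(plain$rho, part$rho),
    p.value = c(plain$p.value, part$p.value),
    n = c(plain$n, part$n),
    stringsAsFactors = FALSE
  )
}
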