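#' @include arsi-core.R
NULL

#' Read an expression table
#'
#' Tab-separated file with header `gene_id`, `mrna`, `pa`; empty fields are
#' missing values. Negative values are rejected.
#'
#' @param path TSV path.
#' @return `data.frame` with columns `gene_id`, `mrna`, `pa`.
#' @export
readExpression <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "mrna", "pa")
  if (!all(need %in% names(x)))
    stop("expression table must have header: ", paste(need, collapse = ", "))
  for (f in c("mrna", "pa")) {
    x[[f]] <- as.numeric(x[[f]])
    if (any(x[[f]] < 0, na.rm = TRUE)) stop("negative ", f, " values")
  }
  x[need]
}

match_pairs <- function(scores, expr, field) {
  stopifnot(field %in% c("mrna", "pa"))
  i <- match(scores$gene_id, expr$gene_id)
  x <- scores$arsi
  y <- expr[[field]][i]
  keep <- !is.na(x) & !is.na(y)
  list(x = x[keep], y = y[keep], n = sum(keep))
}

#' Spearman correlation of ARSI scores with expression
#'
#' Pairs are matched by `gene_id`; missing measurements are excluded
#' pairwise and the number of pairs used is reported. Ties are handled by
#' average ranks.
#'
#' @param scores `data.frame` with columns `gene_id` and `arsi` (as from
#'   [arsiLeaveOneOut()] plus a `gene_id`).
#' @param expr expression `data.frame` as from [readExpression()].
#' @param field `"mrna"` or `"pa"`.
#' @return list with `rho`, `p.value`, `n`, `controls` (empty).
#' @export
spearmanCorr <- function(scores, expr, field = c("mrna", "pa")) {
  field <- match.arg(field)
  mp <- match_pairs(scores, expr, field)
  if (mp$n < 3L) stop("need at least 3 complete pairs, have ", mp$n)
  ht <- suppressWarnings(
    stats::cor.test(mp$x, mp$y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p.value = ht$p.value, n = mp$n,
       controls = character(0))
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and every control covariate, regresses the
#' ranked `x` and ranked `y` on the ranked controls by least squares, and
#' correlates the residuals (Pearson). The p-value uses the t
#' approximation with `n - 2 - length(controls)` degrees of freedom. With
#' no controls this reduces exactly to the Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param controls list (or data.frame) of control covariate vectors, e.g.
#'   sequence length; may be empty.
#' @return list with `rho`, `p.value`, `n`, `controls` (names).
#' @export
partialSpearman <- function(x, y, controls = list()) {
  controls <- as.list(controls)
  keep <- !is.na(x) & !is.na(y)
  for (z in controls) keep <- keep & !is.na(z)
  x <- x[keep]; y <- y[keep]
  controls <- lapply(controls, function(z) z[keep])
  n <- length(x)
  k <- length(controls)
  if (n < 3L + k) stop("need at least ", 3L + k, " complete cases, have ", n)
  rx <- rank(x); ry <- rank(y)
  if (k == 0L) {
    rho <- stats::cor(rx, ry)
  } else {
    Z <- do.call(cbind, lapply(controls, rank))
    qrz <- qr(cbind(1, Z))
    if (qrz$rank < ncol(Z) + 1L)
      stop("collinear controls: ",
           paste(names(controls), collapse = ", "))
    rho <- stats::cor(stats::residuals(stats::lm.fit(cbind(1, Z), rx)),
                      stats::residuals(stats::lm.fit(cbind(1, Z), ry)))
  }
  df <- n - 2L - k
  tstat <- rho * sqrt(df / max(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(rho = rho, p.value = p, n = n,
       controls = if (k) names(controls) else character(0))
}

#' Split genes into high- and low-expression sets
#'
#' @param expr expression `data.frame`.
#' @param field `"mrna"` or `"pa"`.
#' @param policy `"median"` (default; ties go to the high set) or
#'   `"quartile"` (top vs. bottom quartile).
#' @return list with character vectors `high` and `low` of gene ids.
#' @export
splitHighLow <- function(expr, field = c("mrna", "pa"),
                         policy = c("median", "quartile")) {
  field <- match.arg(field)
  policy <- match.arg(policy)
  v <- expr[[field]]
  keep <- !is.na(v)
  v <- v[keep]
  g <- expr$gene_id[keep]
  if (length(v) < 4L) stop("need at least 4 genes with values")
  if (max(v) == min(v)) stop("constant expression; cannot split")
  if (policy == "median") {
    m <- stats::median(v)
    list(high = g[v >= m], low = g[v < m])
  } else {
    q <- stats::quantile(v, c(0.25, 0.75), type = 7)
    list(high = g[rank(-v, ties.method = "first") <= ceiling(length(v) / 4)],
         low = g[rank(v, ties.method = "first") <= ceiling(length(v) / 4)])
  }
}

#' Compare ARSI scores between gene groups
#'
#' Two-sided Wilcoxon rank-sum test of the scores of genes in `high`
#' against those in `low`.
#'
#' @param scores `data.frame` with `gene_id` and `arsi`.
#' @param high,low character vectors of gene ids.
#' @return list with `statistic`, `p.value`, `median_high`, `median_low`,
#'   `n_high`, `n_low`.
#' @export
compareGroups <- function(scores, high, low) {
  a <- scores$arsi[scores$gene_id %in% high]
  b <- scores$arsi[scores$gene_id %in% low]
  if (!length(a) || !length(b)) stop("empty group")
  if (length(a) == length(b) && all(sort(a) == sort(b))) {
    return(list(statistic = NA_real_, p.value = 1,
                median_high = stats::median(a), median_low = stats::median(b),
                n_high = length(a), n_low = length(b)))
  }
  ht <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       median_high = stats::median(a), median_low = stats::median(b),
       n_high = length(a), n_low = length(b))
}
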