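#' Preprocess an expression matrix to per-group gene summaries
#'
#' Applies the convention matching the dataset kind and collapses columns to
#' group means, returning a gene-by-group matrix:
#' \itemize{
#'   \item \code{single_cell}: within each group, every gene is divided by
#'     its within-group standard deviation (variance scaling; zero-SD genes
#'     stay 0), then averaged over the group's cells.
#'   \item \code{microarray_log}: values are log10 transformed (positive
#'     input assumed) and averaged per group.
#'   \item \code{rnaseq_counts}: each column is scaled to a total of 1e6
#'     (TPM-like), then divided by its own mean across genes, then
#'     log10(x + offset) transformed and averaged per group. A true
#'     quantile normalization across columns is available via
#'     \code{normalization = "quantile"}.
#' }
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param offset log10 offset for count data (default 1).
#' @param normalization for \code{rnaseq_counts}: \code{"mean"} (per-column
#'   mean scaling, the default) or \code{"quantile"} (average-quantile
#'   normalization across columns).
#' @return matrix genes x groups of summarized expression.
#' @export
preprocessExpression <- function(dataset, offset = 1,
                                 normalization = c("mean", "quantile")) {
  normalization <- match.arg(normalization)
  X <- exprMatrix(dataset)
  groups <- columnGroups(dataset)
  glev <- unique(groups)
  if (any(table(groups) == 0L) || length(glev) == 0L)
    stop("empty column group")
  kind <- dataset@kind
  out <- matrix(0, nrow(X), length(glev),
                dimnames = list(rownames(X), glev))
  if (kind == "single_cell") {
    for (g in glev) {
      sub <- X[, groups == g, drop = FALSE]
      sds <- apply(sub, 1, sd)
      scaled <- sub / ifelse(sds == 0, 1, sds)
      scaled[sds == 0, ] <- 0
      out[, g] <- rowMeans(scaled)
    }
  } else if (kind == "microarray_log") {
    if (any(X <= 0)) stop("microarray_log expects strictly positive values")
    L <- log10(X)
    for (g in glev) out[, g] <- rowMeans(L[, groups == g, drop = FALSE])
  } else {
    tpm <- sweep(X, 2, colSums(X), "/") * 1e6
    if (normalization == "quantile") {
      ## classic average-quantile normalization across columns
      rk <- apply(tpm, 2, rank, ties.method = "average")
      srt <- apply(tpm, 2, sort)
      ref <- rowMeans(srt)
      norm <- matrix(0, nrow(tpm), ncol(tpm))
      for (j in seq_len(ncol(tpm)))
        norm[, j] <- stats::approx(seq_len(nrow(tpm)), ref, xout = rk[, j],
                                   rule = 2)$y
    } else {
      norm <- sweep(tpm, 2, colMeans(tpm), "/")
    }
    L <- log10(norm + offset)
    for (g in glev) out[, g] <- rowMeans(L[, groups == g, drop = FALSE])
  }
  out
}

#' Fraction of columns with detectable expression per gene
#'
#' "No detectable expression" is a value of exactly zero; the detectable
#' fraction uses a strictly-greater-than-zero test per cell.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param genes gene ids to report (default all).
#' @param group restrict to one column group (default all columns).
#' @return named per-gene fractions in [0, 1].
#' @export
nonzeroProportion <- function(dataset, genes = NULL, group = NULL) {
  X <- exprMatrix(dataset)
  if (!is.null(group)) {
    if (!group %in% columnGroups(dataset)) stop("unknown group: ", group)
    X <- X[, columnGroups(dataset) == group, drop = FALSE]
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(X))
    if (length(missing)) stop("unknown genes: ",
                              paste(head(missing, 3), collapse = ", "))
    X <- X[genes, , drop = FALSE]
  }
  rowMeans(X > 0)
}

#' Median-expression permutation enrichment test for a gene set
#'
#' Compares the median per-gene summary (group-mean processed expression, or
#' the fraction of columns with nonzero expression) of the target genes with
#' the medians of \code{nPerm} random gene sets of the same size drawn from
#' the background (genes present in both the association analysis and the
#' expression dataset), one-sided for enrichment:
#' \deqn{p = (1 + \#\{null \ge observed\}) / (1 + nPerm).}
#'
#' @param targetGenes gene set to test (subset of \code{backgroundGenes}).
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param backgroundGenes sampling universe.
#' @param group column group to summarize.
#' @param nPerm number of random sets (default 10,000).
#' @param statistic \code{"median_expression"} or
#'   \code{"nonzero_proportion"}.
#' @param seed integer seed.
#' @param offset,normalization passed to \code{\link{preprocessExpression}}.
#' @return an \linkS4class{EnrichmentResult}.
#' @export
medianEnrichmentTest <- function(targetGenes, dataset, backgroundGenes,
                                 group = columnGroups(dataset)[1],
                                 nPerm = 10000L,
                                 statistic = c("median_expression",
                                               "nonzero_proportion"),
                                 seed = 1L, offset = 1,
                                 normalization = "mean") {
  statistic <- match.arg(statistic)
  if (length(targetGenes) == 0L) stop("empty target gene set")
  if (!all(targetGenes %in% backgroundGenes))
    stop("targetGenes must be a subset of backgroundGenes")
  if (!all(backgroundGenes %in% rownames(exprMatrix(dataset))))
    stop("backgroundGenes must all be present in the expression dataset")
  if (length(backgroundGenes) < length(targetGenes))
    stop("background smaller than target set")
  summaryVec <- if (statistic == "median_expression") {
    preprocessExpression(dataset, offset = offset,
                         normalization = normalization)[backgroundGenes,
                                                        group]
  } else {
    nonzeroProportion(dataset, genes = backgroundGenes, group = group)
  }
  observed <- median(summaryVec[targetGenes])
  set.seed(seed)
  k <- length(targetGenes)
  nullMedians <- vapply(seq_len(nPerm), function(i)
    median(summaryVec[sample.int(length(summaryVec), k)]), 0)
  p <- (1 + sum(nullMedians >= observed)) / (1 + nPerm)
  new("EnrichmentResult", observed = observed, nullMedians = nullMedians,
      p = p, statistic = statistic, group = group,
      nTarget = as.integer(k))
}
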