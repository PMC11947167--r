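#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname accessors
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname accessors
#' @export
setGeneric("tss", function(x) standardGeneric("tss"))

#' @rdname accessors
#' @export
setGeneric("ldMatrix", function(x) standardGeneric("ldMatrix"))

#' @rdname accessors
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' @rdname accessors
#' @export
setGeneric("stageTallies", function(x) standardGeneric("stageTallies"))

#' @rdname accessors
#' @export
setGeneric("lociReports", function(x) standardGeneric("lociReports"))

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname accessors
#' @export
setGeneric("columnGroups", function(x) standardGeneric("columnGroups"))

#' @rdname accessors
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

#' Accessors for twasprio classes
#'
#' Small accessor family: \code{geneId}, \code{panelName},
#' \code{modelWeights}, \code{tss} (gene start on the + strand, gene end on
#' the - strand), \code{ldMatrix}, \code{resultsTable}, \code{stageTallies},
#' \code{lociReports}, \code{exprMatrix}, \code{columnGroups},
#' \code{posteriors}.
#'
#' @param x an object of the documented class.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("geneId", "WeightModel", function(x) x@geneId)
#' @rdname accessors
setMethod("geneId", "HarmonizedLocus", function(x) x@geneId)
#' @rdname accessors
setMethod("panelName", "WeightModel", function(x) x@panel)
#' @rdname accessors
setMethod("modelWeights", "WeightModel", function(x) x@weights)
#' @rdname accessors
setMethod("tss", "WeightModel", function(x)
  if (identical(x@strand, "-")) x@geneEnd else x@geneStart)
#' @rdname accessors
setMethod("ldMatrix", "HarmonizedLocus", function(x) x@V)
#' @rdname accessors
setMethod("resultsTable", "TwasResults", function(x) x@table)
#' @rdname accessors
setMethod("stageTallies", "TwasResults", function(x) x@tallies)
#' @rdname accessors
setMethod("lociReports", "TwasResults", function(x) x@loci)
#' @rdname accessors
setMethod("exprMatrix", "ExpressionDataset", function(x) x@matrix)
#' @rdname accessors
setMethod("columnGroups", "ExpressionDataset", function(x) x@columnGroups)
#' @rdname accessors
setMethod("posteriors", "ColocResult", function(x) x@pp)

setMethod("show", "WeightModel", function(object) {
  nz <- sum(object@weights$weight != 0)
  cat("WeightModel", object@geneId, sprintf("[%s/%s]", object@panel,
      object@modelType), "\n")
  cat(sprintf("  %d cis-SNPs (%d nonzero), cv R2 = %.3f (p = %.2g), h2 = %.3f (p = %.2g)\n",
              nrow(object@weights), nz, object@cvR2, object@cvP,
              object@h2, object@h2P))
  cat(sprintf("  chr%s:%s-%s (%s)\n", object@chrom,
              format(object@geneStart, big.mark = ","),
              format(object@geneEnd, big.mark = ","), object@strand))
})

setMethod("show", "HarmonizedLocus", function(object) {
  cat("HarmonizedLocus", object@geneId, "with", length(object@snpIds),
      "allele-aligned SNPs\n")
})

setMethod("show", "TwasSimulation", function(object) {
  cat("TwasSimulation:", nrow(object@genes), "genes,",
      nrow(object@snps), "SNPs,", nrow(object@genotypes),
      "reference samples\n")
  cat("  causal genes:", length(object@truth$causalGenes),
      " | enriched set:", length(object@truth$enrichedGeneSet), "\n")
})

setMethod("show", "ExpressionDataset", function(object) {
  cat("ExpressionDataset [", object@kind, "]: ", nrow(object@matrix),
      " genes x ", ncol(object@matrix), " columns in ",
      length(unique(object@columnGroups)), " group(s)\n", sep = "")
})

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult over", object@nSnps, "SNPs\n")
  print(round(object@pp, 4))
  cat("  colocalized (pp4 > threshold):", object@colocalized, "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult [", object@statistic, "] group ", object@group,
      ": observed = ", signif(object@observed, 4), ", p = ",
      signif(object@p, 4), " (", length(object@nullMedians),
      " permutations)\n", sep = "")
})

setMethod("show", "TwasResults", function(object) {
  cat("TwasResults:", nrow(object@table), "tested genes\n")
  t <- object@tallies
  for (nm in names(t)) cat(sprintf("  %-22s %s\n", nm, t[[nm]]))
})
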