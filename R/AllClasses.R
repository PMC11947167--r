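#' @import methods
#' @importFrom stats pnorm qnorm rnorm runif rbinom rnbinom qbinom cor sd
#'   median quantile p.adjust ks.test setNames
#' @importFrom utils head tail
NULL

## cis-window convention: weighted SNPs must lie within +/- 500 kb of the
## gene boundary, matching how the expression prediction models are trained.
CIS_WINDOW_BP <- 500000L

#' SimulationConfig: parameters of the synthetic TWAS study
#'
#' Bundles every knob of the synthetic-data generator: reference-panel size,
#' number of genes, cis-window size in SNPs, LD block structure, allele
#' frequency range, weight sparsity, and the mediated causal-gene model
#' (fraction of causal genes and their TWAS-scale effect, i.e. the expected
#' |Z| of the TWAS statistic at a causal gene).
#'
#' @slot nRefSamples number of LD reference samples.
#' @slot nGenes number of genes (one weight model each).
#' @slot snpsPerGene number of cis-SNPs per gene window.
#' @slot ldBlockSize SNPs per LD block; blocks are mutually independent and
#'   within a block adjacent-SNP correlation decays as \code{ldRho^distance}.
#' @slot ldRho within-block adjacent-SNP latent correlation, in [0, 1).
#' @slot mafRange allele-frequency range (low, high), in (0, 0.5].
#' @slot weightSparsity fraction of cis-SNPs with nonzero weight, in (0, 1].
#' @slot causalGeneFraction fraction of genes with a mediated effect.
#' @slot causalEffect expected |Z_TWAS| at a causal gene (noncentrality).
#' @slot windowStep SNP-index step between consecutive gene windows; equal to
#'   \code{snpsPerGene} gives non-overlapping windows, smaller values overlap
#'   them (shared cis-SNPs, hence correlated predicted expression).
#' @slot snpSpacing base pairs between adjacent SNPs.
#' @slot geneGap base-pair gap inserted between non-overlapping gene windows;
#'   the default (200 kb) keeps single-gene loci distinct under the 100 kb
#'   locus-merging rule.
#' @slot nChromosomes genes are split evenly over this many chromosomes.
#' @slot seed integer seed; all generators derive child seeds from it.
#' @export
setClass("SimulationConfig", representation(
  nRefSamples = "integer", nGenes = "integer", snpsPerGene = "integer",
  ldBlockSize = "integer", ldRho = "numeric", mafRange = "numeric",
  weightSparsity = "numeric", causalGeneFraction = "numeric",
  causalEffect = "numeric", windowStep = "integer", snpSpacing = "integer",
  geneGap = "integer", nChromosomes = "integer", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  counts <- c(nRefSamples = object@nRefSamples, nGenes = object@nGenes,
              snpsPerGene = object@snpsPerGene,
              ldBlockSize = object@ldBlockSize,
              windowStep = object@windowStep, snpSpacing = object@snpSpacing,
              nChromosomes = object@nChromosomes)
  if (any(counts < 1L))
    msg <- c(msg, paste("counts must be >= 1:",
                        paste(names(counts)[counts < 1L], collapse = ", ")))
  if (object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "ldRho must be in [0, 1)")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[1] > object@mafRange[2] || object@mafRange[2] > 0.5)
    msg <- c(msg, "mafRange must satisfy 0 < low <= high <= 0.5")
  if (object@weightSparsity <= 0 || object@weightSparsity > 1)
    msg <- c(msg, "weightSparsity must be in (0, 1]")
  if (object@causalGeneFraction < 0 || object@causalGeneFraction > 1)
    msg <- c(msg, "causalGeneFraction must be in [0, 1]")
  if (object@windowStep > object@snpsPerGene)
    msg <- c(msg, "windowStep must not exceed snpsPerGene")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nRefSamples,nGenes,snpsPerGene,ldBlockSize,ldRho,mafRange,weightSparsity,causalGeneFraction,causalEffect,windowStep,snpSpacing,geneGap,nChromosomes,seed
#'   see the slot documentation of \linkS4class{SimulationConfig}.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 20, seed = 1)
#' @export
simulationConfig <- function(nRefSamples = 400L, nGenes = 100L,
                             snpsPerGene = 10L, ldBlockSize = 10L,
                             ldRho = 0.7, mafRange = c(0.05, 0.5),
                             weightSparsity = 0.4, causalGeneFraction = 0.05,
                             causalEffect = 7, windowStep = snpsPerGene,
                             snpSpacing = 1000L, geneGap = 200000L,
                             nChromosomes = 1L, seed = 1L) {
  new("SimulationConfig",
      nRefSamples = as.integer(nRefSamples), nGenes = as.integer(nGenes),
      snpsPerGene = as.integer(snpsPerGene),
      ldBlockSize = as.integer(ldBlockSize), ldRho = ldRho,
      mafRange = as.numeric(mafRange), weightSparsity = weightSparsity,
      causalGeneFraction = causalGeneFraction, causalEffect = causalEffect,
      windowStep = as.integer(windowStep), snpSpacing = as.integer(snpSpacing),
      geneGap = as.integer(geneGap), nChromosomes = as.integer(nChromosomes),
      seed = as.integer(seed))
}

#' WeightModel: one gene's cis-SNP expression prediction model
#'
#' The unit the TWAS statistic is computed on: a sparse vector of cis-SNP
#' weights together with the cross-validation performance and cis-heritability
#' metadata used to filter models, and the gene's genomic coordinates
#' (1-based inclusive).
#'
#' @slot geneId gene identifier.
#' @slot panel source panel, one of \code{"testis"}, \code{"tumor"},
#'   \code{"cross_tissue"}.
#' @slot modelType label of the fitting method (free text, e.g. "lasso").
#' @slot weights data.frame with columns \code{snp_id}, \code{a1}, \code{a2},
#'   \code{weight} and optionally \code{pos}.
#' @slot cvR2 cross-validation R-squared of the model.
#' @slot cvP p-value of the cross-validation performance.
#' @slot h2 cis-SNP heritability of expression.
#' @slot h2P p-value of the cis-heritability estimate.
#' @slot chrom,geneStart,geneEnd,strand gene coordinates.
#' @export
setClass("WeightModel", representation(
  geneId = "character", panel = "character", modelType = "character",
  weights = "data.frame", cvR2 = "numeric", cvP = "numeric",
  h2 = "numeric", h2P = "numeric", chrom = "character",
  geneStart = "numeric", geneEnd = "numeric", strand = "character"
))

setValidity("WeightModel", function(object) {
  msg <- character()
  w <- object@weights
  need <- c("snp_id", "a1", "a2", "weight")
  if (!all(need %in% names(w)))
    msg <- c(msg, paste("weights must have columns",
                        paste(need, collapse = ", ")))
  else if (!any(w$weight != 0))
    msg <- c(msg, "model must have at least one nonzero weight")
  if (object@cvR2 < 0 || object@cvR2 > 1)
    msg <- c(msg, "cvR2 must be in [0, 1]")
  if (object@geneStart > object@geneEnd)
    msg <- c(msg, "geneStart must be <= geneEnd")
  if (!object@panel %in% c("testis", "tumor", "cross_tissue"))
    msg <- c(msg, "panel must be one of testis, tumor, cross_tissue")
  if ("pos" %in% names(w) && nrow(w)) {
    lo <- object@geneStart - CIS_WINDOW_BP
    hi <- object@geneEnd + CIS_WINDOW_BP
    if (any(w$pos < lo | w$pos > hi))
      msg <- c(msg, "weighted SNPs must lie within the gene boundary +/- 500 kb")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WeightModel
#'
#' @param geneId gene identifier.
#' @param weights data.frame (snp_id, a1, a2, weight[, pos]).
#' @param panel,modelType,cvR2,cvP,h2,h2P,chrom,geneStart,geneEnd,strand
#'   metadata; defaults describe a model that passes the quality filters.
#' @return a \linkS4class{WeightModel}.
#' @export
weightModel <- function(geneId, weights, panel = "testis",
                        modelType = "lasso", cvR2 = 0.2, cvP = 1e-6,
                        h2 = 0.25, h2P = 1e-4, chrom = "1",
                        geneStart = 1, geneEnd = 2, strand = "+") {
  new("WeightModel", geneId = geneId, panel = panel, modelType = modelType,
      weights = as.data.frame(weights), cvR2 = cvR2, cvP = cvP, h2 = h2,
      h2P = h2P, chrom = as.character(chrom), geneStart = geneStart,
      geneEnd = geneEnd, strand = strand)
}

#' HarmonizedLocus: allele-aligned gene cis-window
#'
#' The intersection of a gene's weighted SNPs with the GWAS table and the LD
#' reference panel, with Z-scores sign-flipped onto the model's allele coding
#' and the LD correlation matrix estimated from the panel dosages.
#'
#' @slot geneId gene identifier.
#' @slot snpIds ordered SNP identifiers.
#' @slot z GWAS Z-scores aligned to the model's effect alleles.
#' @slot w model weights, same order as \code{snpIds}.
#' @slot V LD correlation matrix estimated from the reference panel.
#' @slot maf panel allele-1 frequencies.
#' @export
setClass("HarmonizedLocus", representation(
  geneId = "character", snpIds = "character", z = "numeric",
  w = "numeric", V = "matrix", maf = "numeric"
))

setValidity("HarmonizedLocus", function(object) {
  m <- length(object@snpIds)
  msg <- character()
  if (length(object@z) != m || length(object@w) != m ||
      nrow(object@V) != m || ncol(object@V) != m || length(object@maf) != m)
    msg <- c(msg, "snpIds, z, w, maf and V dimensions must agree")
  else if (m > 0) {
    if (max(abs(object@V - t(object@V))) > 1e-8)
      msg <- c(msg, "V must be symmetric")
    if (max(abs(diag(object@V) - 1)) > 1e-6)
      msg <- c(msg, "diag(V) must equal 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HarmonizedLocus
#' @param geneId,snpIds,z,w,V,maf see \linkS4class{HarmonizedLocus}.
#' @return a \linkS4class{HarmonizedLocus}.
#' @export
harmonizedLocus <- function(geneId, snpIds, z, w, V,
                            maf = rep(0.5, length(snpIds))) {
  V <- as.matrix(V)
  dimnames(V) <- NULL
  new("HarmonizedLocus", geneId = geneId, snpIds = as.character(snpIds),
      z = as.numeric(z), w = as.numeric(w), V = V, maf = as.numeric(maf))
}

#' TwasSimulation: a complete synthetic TWAS study
#'
#' Holds the generated LD reference panel, SNP and gene tables, weight
#' models, GWAS Z-scores, and the planted ground truth that recovery tests
#' score against.
#'
#' @slot genotypes samples x SNPs dosage matrix in {0, 1, 2}.
#' @slot snps SNP table (snp_id, chrom, pos, a1, a2, maf).
#' @slot genes gene table (gene_id, chrom, start, end, strand, firstSnp,
#'   lastSnp).
#' @slot models list of \linkS4class{WeightModel}.
#' @slot gwas GWAS table (snp_id, a1, a2, z).
#' @slot truth list: \code{causalGenes}, \code{effect} (named vector),
#'   \code{enrichedGeneSet}, \code{expressionShift}.
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @export
setClass("TwasSimulation", representation(
  genotypes = "matrix", snps = "data.frame", genes = "data.frame",
  models = "list", gwas = "data.frame", truth = "list",
  config = "SimulationConfig"
))

setValidity("TwasSimulation", function(object) {
  msg <- character()
  if (ncol(object@genotypes) != nrow(object@snps))
    msg <- c(msg, "genotype columns must match the SNP table")
  if (length(object@truth$causalGenes) &&
      !all(object@truth$causalGenes %in% object@genes$gene_id))
    msg <- c(msg, "causal genes must be simulated gene ids")
  if (length(msg)) msg else TRUE
})

#' ExpressionDataset: a gene-by-column expression matrix
#'
#' @slot matrix gene x column nonnegative matrix (counts or intensities).
#' @slot columnGroups character vector labelling each column with a cell-type
#'   or histology group.
#' @slot kind one of \code{"single_cell"}, \code{"microarray_log"},
#'   \code{"rnaseq_counts"}; decides the preprocessing convention.
#' @export
setClass("ExpressionDataset", representation(
  matrix = "matrix", columnGroups = "character", kind = "character"
))

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (length(object@columnGroups) != ncol(object@matrix))
    msg <- c(msg, "columnGroups must label every column")
  if (any(object@matrix < 0))
    msg <- c(msg, "expression values must be nonnegative")
  if (is.null(rownames(object@matrix)) ||
      anyDuplicated(rownames(object@matrix)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (!object@kind %in% c("single_cell", "microarray_log", "rnaseq_counts"))
    msg <- c(msg, "kind must be single_cell, microarray_log or rnaseq_counts")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#' @param matrix,columnGroups,kind see \linkS4class{ExpressionDataset}.
#' @return an \linkS4class{ExpressionDataset}.
#' @export
expressionDataset <- function(matrix, columnGroups, kind) {
  new("ExpressionDataset", matrix = matrix,
      columnGroups = as.character(columnGroups), kind = kind)
}

#' EnrichmentResult: outcome of the median permutation enrichment test
#'
#' @slot observed observed median of the per-gene summary over target genes.
#' @slot nullMedians null medians from random same-size gene sets.
#' @slot p one-sided permutation p-value (add-one corrected).
#' @slot statistic \code{"median_expression"} or \code{"nonzero_proportion"}.
#' @slot group the column group tested.
#' @slot nTarget target-set size.
#' @export
setClass("EnrichmentResult", representation(
  observed = "numeric", nullMedians = "numeric", p = "numeric",
  statistic = "character", group = "character", nTarget = "integer"
))

#' ColocResult: posterior probabilities of the five colocalization hypotheses
#'
#' @slot pp named numeric of length 5 (pp0..pp4); sums to 1.
#' @slot logAbfEqtl,logAbfGwas per-SNP log approximate Bayes factors.
#' @slot nSnps number of SNPs used.
#' @slot colocalized TRUE iff pp4 exceeds the decision threshold.
#' @export
setClass("ColocResult", representation(
  pp = "numeric", logAbfEqtl = "numeric", logAbfGwas = "numeric",
  nSnps = "integer", colocalized = "logical"
))

setValidity("ColocResult", function(object) {
  if (length(object@pp) != 5L) return("pp must have length 5")
  if (abs(sum(object@pp) - 1) > 1e-9) return("pp must sum to 1")
  if (any(object@pp < -1e-12 | object@pp > 1 + 1e-12))
    return("pp must lie in [0, 1]")
  TRUE
})

#' TwasResults: per-gene records accumulated across pipeline stages
#'
#' A thin container around the master results table (one row per tested
#' gene) plus per-stage tallies and per-locus reports.
#'
#' @slot table data.frame with one row per gene: marginal, permutation,
#'   joint-conditional and colocalization columns (see \code{\link{runPipeline}}).
#' @slot tallies named list of stage counts.
#' @slot loci per-locus reports (residual Z tables, proportion explained).
#' @slot log character vector of per-gene skip reasons and stage messages.
#' @export
setClass("TwasResults", representation(
  table = "data.frame", tallies = "list", loci = "list", log = "character"
))
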