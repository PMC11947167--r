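## ---- synthetic study layout -------------------------------------------------
## Genes are split evenly over chromosomes; within a chromosome each gene owns
## a window of snpsPerGene consecutive SNPs, windows advancing by windowStep
## indices (step == snpsPerGene gives disjoint windows separated by geneGap
## base pairs; smaller steps overlap windows so neighboring genes share
## cis-SNPs). LD blocks of ldBlockSize consecutive SNPs are generated
## independently of one another.
.studyLayout <- function(config) {
  nG <- config@nGenes
  perChrom <- split(seq_len(nG),
                    ceiling(seq_len(nG) / ceiling(nG / config@nChromosomes)))
  snps <- NULL
  genes <- NULL
  offset <- 0L
  for (ci in seq_along(perChrom)) {
    gs <- perChrom[[ci]]
    k <- length(gs)
    m <- (k - 1L) * config@windowStep + config@snpsPerGene
    startIdx <- (seq_len(k) - 1L) * config@windowStep + 1L
    endIdx <- startIdx + config@snpsPerGene - 1L
    ## base-pair positions: geneGap inserted only at disjoint window starts
    isBoundary <- rep(FALSE, m)
    if (config@windowStep == config@snpsPerGene && k > 1L)
      isBoundary[startIdx[-1]] <- TRUE
    pos <- seq_len(m) * config@snpSpacing + cumsum(isBoundary) * config@geneGap
    block <- (seq_len(m) - 1L) %/% config@ldBlockSize + 1L
    snps <- rbind(snps, data.frame(
      chrom = as.character(ci), pos = pos,
      block = paste0(ci, "_", block), stringsAsFactors = FALSE))
    genes <- rbind(genes, data.frame(
      gene_id = sprintf("gene%04d", gs), chrom = as.character(ci),
      start = pos[startIdx], end = pos[endIdx],
      strand = ifelse(gs %% 2L == 0L, "-", "+"),
      firstSnp = offset + startIdx, lastSnp = offset + endIdx,
      stringsAsFactors = FALSE))
    offset <- offset + m
  }
  snps$snp_id <- sprintf("rs%06d", seq_len(nrow(snps)))
  list(snps = snps, genes = genes)
}

#' Simulate an LD reference panel
#'
#' Generates a samples-by-SNPs dosage matrix in {0, 1, 2} with
#' block-structured LD: within each block a Gaussian copula with
#' autoregressive latent correlation \code{ldRho^distance} is thresholded to
#' genotype dosages by Hardy-Weinberg quantiles at a per-SNP allele frequency
#' drawn from \code{mafRange}; distinct blocks are independent. Monomorphic
#' draws are rejected and the block resampled, so every emitted SNP is
#' polymorphic.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{genotypes} (matrix, samples x SNPs), \code{snps}
#'   (snp_id, chrom, pos, a1, a2, maf with the empirical panel frequency of
#'   a1), and \code{genes} (the window layout the other generators use).
#' @examples
#' panel <- simulateLdPanel(simulationConfig(nGenes = 5, seed = 1))
#' dim(panel$genotypes)
#' @export
simulateLdPanel <- function(config) {
  validObject(config)
  if (config@nRefSamples < 30)
    warning("fewer than 30 reference samples: LD estimates will be unstable")
  set.seed(.childSeed(config@seed, 1L))
  layout <- .studyLayout(config)
  snps <- layout$snps
  m <- nrow(snps)
  n <- config@nRefSamples
  popMaf <- runif(m, config@mafRange[1], config@mafRange[2])
  bases <- c("A", "C", "G", "T")
  alle <- t(vapply(seq_len(m), function(i) sample(bases, 2L), character(2)))
  G <- matrix(0L, n, m)
  for (b in unique(snps$block)) {
    idx <- which(snps$block == b)
    B <- length(idx)
    ## latent Markov correlation calibrated so that adjacent *dosage*
    ## correlation approximates ldRho after HWE-quantile thresholding
    if (config@ldRho == 0 || B == 1L) {
      R <- diag(B)
    } else {
      radj <- vapply(seq_len(B - 1L), function(k)
        .latentCorr(config@ldRho, popMaf[idx[k]], popMaf[idx[k + 1L]]), 0)
      lcp <- cumsum(log(pmax(radj, 1e-12)))
      R <- diag(B)
      for (i in seq_len(B - 1L)) for (j in (i + 1L):B)
        R[i, j] <- R[j, i] <- exp(lcp[j - 1L] - if (i > 1L) lcp[i - 1L] else 0)
    }
    U <- chol(R)
    for (try in seq_len(100L)) {
      Z <- matrix(rnorm(n * B), n, B) %*% U
      g <- qbinom(pnorm(Z), 2L, rep(popMaf[idx], each = n))
      dim(g) <- c(n, B)
      if (all(apply(g, 2, function(x) length(unique(x))) > 1L)) break
      if (try == 100L) stop("could not draw a polymorphic block; ",
                            "increase nRefSamples or mafRange")
    }
    G[, idx] <- g
  }
  snps$a1 <- alle[, 1]
  snps$a2 <- alle[, 2]
  snps$maf <- colMeans(G) / 2
  colnames(G) <- snps$snp_id
  list(genotypes = G, snps = snps[, c("snp_id", "chrom", "pos", "a1", "a2",
                                      "maf", "block")],
       genes = layout$genes)
}

#' Simulate per-gene expression weight models
#'
#' Each gene receives a contiguous cis-window of \code{snpsPerGene} SNPs with
#' \code{ceiling(weightSparsity * snpsPerGene)} nonzero standard-normal
#' weights. Metadata (cross-validation R-squared and p, cis-heritability and
#' p) are drawn so the quality filters keep the model; \code{nFailing} models
#' can be emitted with deliberately failing performance for filter tests.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param panel output of \code{\link{simulateLdPanel}} for the same config.
#' @param nFailing number of leading genes given cv R-squared 0.001 (rejected
#'   by \code{\link{selectModel}}).
#' @param panelLabel source-panel label assigned to every model.
#' @return list of \linkS4class{WeightModel}, one per gene.
#' @export
simulateWeightModels <- function(config, panel, nFailing = 0L,
                                 panelLabel = "testis") {
  validObject(config)
  set.seed(.childSeed(config@seed, 2L))
  snps <- panel$snps
  genes <- panel$genes
  k <- max(1L, ceiling(config@weightSparsity * config@snpsPerGene))
  lapply(seq_len(nrow(genes)), function(g) {
    idx <- genes$firstSnp[g]:genes$lastSnp[g]
    nz <- sort(sample(seq_along(idx), k))
    w <- numeric(length(idx))
    w[nz] <- rnorm(k)
    if (all(w == 0)) w[nz[1]] <- 1  # degenerate-draw guard
    failing <- g <= nFailing
    weightModel(
      geneId = genes$gene_id[g],
      weights = data.frame(snp_id = snps$snp_id[idx], a1 = snps$a1[idx],
                           a2 = snps$a2[idx], weight = w, pos = snps$pos[idx],
                           stringsAsFactors = FALSE),
      panel = panelLabel, modelType = "lasso",
      cvR2 = if (failing) 0.001 else runif(1, 0.05, 0.5),
      cvP = runif(1, 1e-8, 0.01),
      h2 = runif(1, 0.1, 0.4), h2P = runif(1, 1e-8, 0.01),
      chrom = genes$chrom[g], geneStart = genes$start[g],
      geneEnd = genes$end[g], strand = genes$strand[g])
  })
}

#' Draw the planted ground truth of a synthetic study
#'
#' Picks \code{causalGeneFraction} of the genes as causal, each with TWAS
#' noncentrality \code{causalEffect}; the enriched gene set for the
#' expression stage defaults to the causal genes.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param geneIds gene identifiers of the study.
#' @param expressionShift log10-scale location shift planted in the enriched
#'   genes of simulated expression matrices.
#' @param enrichedGeneSet optional explicit enriched set (default: the causal
#'   genes).
#' @return list with \code{causalGenes}, \code{effect} (named vector),
#'   \code{enrichedGeneSet}, \code{expressionShift}.
#' @export
simulateTruth <- function(config, geneIds, expressionShift = 0,
                          enrichedGeneSet = NULL) {
  set.seed(.childSeed(config@seed, 4L))
  nCausal <- round(config@causalGeneFraction * length(geneIds))
  causal <- if (nCausal > 0) sort(sample(geneIds, nCausal)) else character()
  effect <- setNames(rep(config@causalEffect, length(causal)), causal)
  if (is.null(enrichedGeneSet)) enrichedGeneSet <- causal
  list(causalGenes = causal, effect = effect,
       enrichedGeneSet = enrichedGeneSet, expressionShift = expressionShift)
}

## block-diagonal LD over a SNP index window, assembled from per-block
## matrices (cross-block correlation treated as zero, matching the noise
## generator)
.windowV <- function(idx, snps, Vblocks) {
  m <- length(idx)
  V <- matrix(0, m, m)
  for (b in unique(snps$block[idx])) {
    sel <- which(snps$block[idx] == b)
    withinBlock <- match(idx[sel], which(snps$block == b))
    V[sel, sel] <- Vblocks[[b]][withinBlock, withinBlock]
  }
  V
}

#' Simulate GWAS Z-scores under a mediated causal-gene model
#'
#' For each causal gene with effect \eqn{\alpha} and weights \eqn{w}, the
#' cis-window mean of the SNP Z vector is \eqn{\alpha V w / \sqrt{w'Vw}}
#' (the unit-normalized predicted-expression direction), so the expected
#' TWAS Z at that gene is \eqn{\alpha}. Overlapping windows add their mean
#' contributions. Noise is multivariate normal with covariance V, drawn per
#' LD block. By default V is the LD estimated from the panel genotypes (the
#' same matrix downstream stages estimate), isolating the pipeline's
#' statistical logic from LD-estimation error; \code{usePopulationLd = TRUE}
#' uses the generating autoregressive matrix instead for robustness checks.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param panel output of \code{\link{simulateLdPanel}}.
#' @param models list of \linkS4class{WeightModel} from
#'   \code{\link{simulateWeightModels}}.
#' @param truth output of \code{\link{simulateTruth}}.
#' @param usePopulationLd draw noise from the population AR matrix instead of
#'   the panel estimate.
#' @return data.frame (snp_id, a1, a2, z).
#' @export
simulateGwasZ <- function(config, panel, models, truth,
                          usePopulationLd = FALSE) {
  validObject(config)
  stopifnot(all(truth$causalGenes %in% vapply(models, geneId, "")))
  set.seed(.childSeed(config@seed, 3L))
  snps <- panel$snps
  m <- nrow(snps)
  Vblocks <- list()
  z <- numeric(m)
  for (b in unique(snps$block)) {
    idx <- which(snps$block == b)
    if (usePopulationLd) {
      B <- length(idx)
      Vb <- config@ldRho ^ abs(outer(seq_len(B), seq_len(B), "-"))
    } else {
      Vb <- .panelCor(panel$genotypes[, idx, drop = FALSE])
    }
    Vblocks[[b]] <- Vb
    U <- chol(Vb + diag(1e-8, nrow(Vb)))
    z[idx] <- as.numeric(crossprod(U, rnorm(length(idx))))
  }
  modelIds <- vapply(models, geneId, "")
  for (g in truth$causalGenes) {
    mod <- models[[match(g, modelIds)]]
    idx <- match(mod@weights$snp_id, snps$snp_id)
    w <- mod@weights$weight
    Vwin <- .windowV(idx, snps, Vblocks)
    quad <- drop(crossprod(w, Vwin %*% w))
    z[idx] <- z[idx] + truth$effect[[g]] * drop(Vwin %*% w) / sqrt(quad)
  }
  data.frame(snp_id = snps$snp_id, a1 = snps$a1, a2 = snps$a2, z = z,
             stringsAsFactors = FALSE)
}

#' Simulate gene expression matrices with optional planted enrichment
#'
#' \code{single_cell} mode emits negative-binomial counts with Bernoulli
#' dropout (zero inflation); \code{bulk} mode emits positive continuous
#' intensities, log10-normal about a per-gene baseline. Genes in
#' \code{truth$enrichedGeneSet} have their location parameter shifted up by
#' \code{truth$expressionShift} log10 units.
#'
#' @param truth output of \code{\link{simulateTruth}} (or any list with
#'   \code{enrichedGeneSet} and \code{expressionShift}).
#' @param geneIds gene identifiers (matrix rows).
#' @param nColumns columns per group.
#' @param mode \code{"single_cell"} or \code{"bulk"}.
#' @param seed integer seed.
#' @param groups character vector of group labels; each gets
#'   \code{nColumns} columns.
#' @param dropout single-cell dropout probability.
#' @param nbSize single-cell negative-binomial size (inverse dispersion).
#' @return an \linkS4class{ExpressionDataset} (kind \code{"single_cell"} for
#'   counts, \code{"microarray_log"} for bulk intensities).
#' @export
simulateExpression <- function(truth, geneIds, nColumns = 100L,
                               mode = c("single_cell", "bulk"), seed = 1L,
                               groups = "all", dropout = 0.3, nbSize = 2) {
  mode <- match.arg(mode)
  set.seed(.childSeed(seed, 5L))
  nG <- length(geneIds)
  shift <- ifelse(geneIds %in% truth$enrichedGeneSet,
                  truth$expressionShift, 0)
  nCol <- nColumns * length(groups)
  baseLog10 <- rnorm(nG, 1, 0.4)
  if (mode == "bulk") {
    X <- matrix(10 ^ (rnorm(nG * nCol, mean = baseLog10 + shift, sd = 0.3)),
                nG, nCol)
    kind <- "microarray_log"
  } else {
    mu <- 10 ^ (rnorm(nG, 0.3, 0.4) + shift)
    X <- matrix(rnbinom(nG * nCol, mu = rep(mu, nCol), size = nbSize),
                nG, nCol)
    X <- X * matrix(rbinom(nG * nCol, 1L, 1 - dropout), nG, nCol)
    kind <- "single_cell"
  }
  rownames(X) <- geneIds
  colnames(X) <- sprintf("col%04d", seq_len(nCol))
  expressionDataset(X, rep(groups, each = nColumns), kind)
}

#' Simulate a complete synthetic TWAS study
#'
#' Convenience wrapper chaining \code{\link{simulateLdPanel}},
#' \code{\link{simulateWeightModels}}, \code{\link{simulateTruth}} and
#' \code{\link{simulateGwasZ}} into one \linkS4class{TwasSimulation}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param expressionShift planted log10 shift for the enrichment stage.
#' @param nFailing deliberately failing models (see
#'   \code{\link{simulateWeightModels}}).
#' @param usePopulationLd see \code{\link{simulateGwasZ}}.
#' @return a \linkS4class{TwasSimulation}.
#' @examples
#' sim <- simulateTwasStudy(simulationConfig(nGenes = 20, seed = 7))
#' sim
#' @export
simulateTwasStudy <- function(config, expressionShift = 0, nFailing = 0L,
                              usePopulationLd = FALSE) {
  panel <- simulateLdPanel(config)
  models <- simulateWeightModels(config, panel, nFailing = nFailing)
  truth <- simulateTruth(config, panel$genes$gene_id,
                         expressionShift = expressionShift)
  gwas <- simulateGwasZ(config, panel, models, truth,
                        usePopulationLd = usePopulationLd)
  new("TwasSimulation", genotypes = panel$genotypes, snps = panel$snps,
      genes = panel$genes, models = models, gwas = gwas, truth = truth,
      config = config)
}

#' Simulate loci with one causal gene and correlated passengers
#'
#' Builds stand-alone loci for fine-mapping validation: per locus, one causal
#' gene plus passengers whose predicted expression has exactly
#' \code{rhoGene} correlation with the causal gene's under the locus LD
#' (constructed by Gram-Schmidt in the V inner product). GWAS Z-scores are
#' drawn as \eqn{\alpha V x_1 + MVN(0, V)} with \eqn{x_1} the causal gene's
#' unit-V-norm weight direction, so passenger genes carry expected marginal
#' TWAS Z of \eqn{\alpha \rho} with no independent signal.
#'
#' @param nLoci number of loci.
#' @param genesPerLocus genes per locus (1 causal + passengers).
#' @param rhoGene predicted-expression correlation of each passenger with the
#'   causal gene.
#' @param alpha causal TWAS noncentrality.
#' @param snpsPerLocus SNPs per locus.
#' @param nRef LD reference samples per locus.
#' @param ldRho adjacent-SNP latent correlation of the locus panel.
#' @param seed integer seed.
#' @return list of loci; each has \code{members} (gene ids, causal first),
#'   \code{causal}, \code{V}, \code{weights} (SNPs x genes), \code{z}
#'   (SNP Z-scores), \code{zTwas} and \code{p} (marginal per-gene stats) and
#'   \code{Sigma} (gene-gene predicted-expression correlation).
#' @export
simulatePassengerLoci <- function(nLoci = 20L, genesPerLocus = 3L,
                                  rhoGene = 0.8, alpha = 7,
                                  snpsPerLocus = 20L, nRef = 300L,
                                  ldRho = 0.3, seed = 1L) {
  set.seed(.childSeed(seed, 6L))
  lapply(seq_len(nLoci), function(l) {
    R <- ldRho ^ abs(outer(seq_len(snpsPerLocus), seq_len(snpsPerLocus), "-"))
    U <- chol(R)
    G <- matrix(rnorm(nRef * snpsPerLocus), nRef, snpsPerLocus) %*% U
    G <- qbinom(pnorm(G), 2L, 0.3)
    dim(G) <- c(nRef, snpsPerLocus)
    while (any(apply(G, 2, sd) == 0)) {
      G <- matrix(rnorm(nRef * snpsPerLocus), nRef, snpsPerLocus) %*% U
      G <- qbinom(pnorm(G), 2L, 0.3)
      dim(G) <- c(nRef, snpsPerLocus)
    }
    V <- .panelCor(G)
    vnorm <- function(a) drop(sqrt(crossprod(a, V %*% a)))
    x1 <- rnorm(snpsPerLocus)
    x1 <- x1 / vnorm(x1)
    W <- matrix(0, snpsPerLocus, genesPerLocus)
    W[, 1] <- x1
    for (j in seq_len(genesPerLocus - 1L)) {
      y <- rnorm(snpsPerLocus)
      y <- y - drop(crossprod(x1, V %*% y)) * x1
      y <- y / vnorm(y)
      W[, j + 1L] <- rhoGene * x1 + sqrt(1 - rhoGene ^ 2) * y
    }
    z <- alpha * drop(V %*% x1) +
      drop(crossprod(chol(V + diag(1e-8, snpsPerLocus)),
                     rnorm(snpsPerLocus)))
    quads <- apply(W, 2, function(w) drop(crossprod(w, V %*% w)))
    zTwas <- drop(crossprod(W, z)) / sqrt(quads)
    Sigma <- crossprod(W, V %*% W) / sqrt(outer(quads, quads))
    members <- sprintf("locus%02d_gene%d", l, seq_len(genesPerLocus))
    dimnames(Sigma) <- list(members, members)
    list(members = members, causal = members[1], V = V, weights = W, z = z,
         zTwas = setNames(zTwas, members),
         p = setNames(.twoSidedP(zTwas), members), Sigma = Sigma)
  })
}
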