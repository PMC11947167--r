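#' Select the best prediction model for a gene
#'
#' Applies the model quality filters -- significant cis-heritability
#' (h2 p < 0.05) and predictive performance (cv p < 0.05 and cv R-squared
#' > 0.01) -- then resolves surviving candidates by source-panel priority
#' testis > tumor > cross-tissue (mutually exclusive, in that order); within
#' a panel the candidate with the highest cross-validation R-squared wins.
#'
#' @param candidates list of \linkS4class{WeightModel} sharing one gene id.
#' @return the selected \linkS4class{WeightModel}, or \code{NULL} if every
#'   candidate fails a filter (or the list is empty).
#' @export
selectModel <- function(candidates) {
  if (length(candidates) == 0L) return(NULL)
  ids <- unique(vapply(candidates, geneId, ""))
  if (length(ids) != 1L)
    stop("candidates must share one gene id, got: ",
         paste(ids, collapse = ", "))
  pass <- Filter(function(m) m@h2P < 0.05 && m@cvP < 0.05 && m@cvR2 > 0.01,
                 candidates)
  if (length(pass) == 0L) return(NULL)
  prio <- c(testis = 1L, tumor = 2L, cross_tissue = 3L)
  ranks <- prio[vapply(pass, panelName, "")]
  pass <- pass[ranks == min(ranks)]
  r2 <- vapply(pass, function(m) m@cvR2, 0)
  pass[[which.max(r2)]]
}

.AMBIGUOUS <- c("A_T", "T_A", "C_G", "G_C")

#' Harmonize GWAS Z-scores, model weights and the LD panel for one gene
#'
#' Intersects the model's weighted SNPs with the GWAS table and the
#' reference panel by SNP identifier. A GWAS row whose allele pair is the
#' swap of the model's has its Z sign flipped; panel dosages coded on the
#' swapped allele are complemented (2 - dosage). SNPs with irreconcilable
#' allele pairs, or absent from any source, are dropped. Strand-ambiguous
#' (A/T, C/G) SNPs are kept by default. The LD matrix is the sample
#' correlation of the surviving panel dosages.
#'
#' @param gwas data.frame (snp_id, a1, a2, z).
#' @param model a \linkS4class{WeightModel}.
#' @param panel list with \code{genotypes} and \code{snps} as produced by
#'   \code{\link{simulateLdPanel}} (or read from disk).
#' @param dropAmbiguous drop strand-ambiguous SNPs.
#' @return a \linkS4class{HarmonizedLocus}, or \code{NULL} (with a
#'   \code{message} stating the reason) when fewer than one weighted SNP
#'   survives.
#' @export
harmonize <- function(gwas, model, panel, dropAmbiguous = FALSE) {
  w <- modelWeights(model)
  gi <- match(w$snp_id, gwas$snp_id)
  pi <- match(w$snp_id, panel$snps$snp_id)
  keep <- !is.na(gi) & !is.na(pi)
  if (dropAmbiguous)
    keep <- keep & !(paste(w$a1, w$a2, sep = "_") %in% .AMBIGUOUS)
  ## allele orientation vs the GWAS table
  sameG <- gwas$a1[gi] == w$a1 & gwas$a2[gi] == w$a2
  swapG <- gwas$a1[gi] == w$a2 & gwas$a2[gi] == w$a1
  keep <- keep & !is.na(sameG) & (sameG | swapG)
  ## allele orientation vs the panel
  sameP <- panel$snps$a1[pi] == w$a1 & panel$snps$a2[pi] == w$a2
  swapP <- panel$snps$a1[pi] == w$a2 & panel$snps$a2[pi] == w$a1
  keep <- keep & !is.na(sameP) & (sameP | swapP)
  if (sum(keep) < 1L) {
    message(geneId(model), ": no weighted SNP survives harmonization")
    return(NULL)
  }
  w <- w[keep, , drop = FALSE]
  gi <- gi[keep]; pi <- pi[keep]
  z <- ifelse(swapG[keep], -gwas$z[gi], gwas$z[gi])
  G <- panel$genotypes[, pi, drop = FALSE]
  flip <- which(swapP[keep])
  if (length(flip)) G[, flip] <- 2 - G[, flip]
  maf <- colMeans(G) / 2
  harmonizedLocus(geneId(model), w$snp_id, z, w$weight, .panelCor(G), maf)
}

#' Summary-based TWAS association statistic
#'
#' The correlation test between genetically predicted gene expression and
#' polygenic predisposition computed from summary statistics:
#' \deqn{Z_{TWAS} = w'z / \sqrt{w' V_r w}, \quad V_r = (1-\lambda) V +
#' \lambda I,} with \eqn{w} the expression weights, \eqn{z} the GWAS
#' Z-scores and \eqn{V} the reference LD; \eqn{\lambda} is a small ridge
#' that guards against rank-deficient LD estimates. The p-value is the
#' two-sided standard-normal tail.
#'
#' @param locus a \linkS4class{HarmonizedLocus}.
#' @param ridge LD shrinkage weight \eqn{\lambda} (default 0.1; set 0 for
#'   exact arithmetic on well-conditioned inputs).
#' @return list with \code{z} (the TWAS Z), \code{p}, and \code{quad}
#'   (the variance term \eqn{w'V_r w}, reused downstream).
#' @examples
#' loc <- harmonizedLocus("g", c("rs1", "rs2"), z = c(2, 1),
#'                        w = c(0.5, -0.3),
#'                        V = matrix(c(1, 0.2, 0.2, 1), 2))
#' twasZ(loc, ridge = 0)$z  # 0.7 / sqrt(0.28)
#' @export
twasZ <- function(locus, ridge = 0.1) {
  w <- locus@w
  if (!any(w != 0)) stop("all aligned weights are zero")
  Vr <- .ridgeV(locus@V, ridge)
  quad <- drop(crossprod(w, Vr %*% w))
  if (quad <= 0)
    stop("non-positive weight variance under the LD matrix: broken LD input")
  z <- drop(crossprod(w, locus@z)) / sqrt(quad)
  list(z = z, p = .twoSidedP(z), quad = quad)
}

#' Benjamini-Hochberg q-values over the pooled set of tests
#'
#' Step-up BH adjustment over all genes from all panels jointly (one family
#' covering the total number of tests); genes are significant at q below the
#' chosen FDR (0.01 in the pipeline default).
#'
#' @param p p-values in [0, 1].
#' @return monotone q-values, same order as \code{p}.
#' @export
bhFdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Flag overlap with known GWAS risk loci
#'
#' TRUE iff the gene's transcription start site lies on the same chromosome
#' and within a closed +/- \code{window} interval around any known top GWAS
#' SNP.
#'
#' @param chrom gene chromosome.
#' @param tssPos transcription start site position.
#' @param knownLoci data.frame (chrom, pos) of published index SNPs.
#' @param window half-width in bp (default 1 Mb).
#' @return logical.
#' @export
flagGwasOverlap <- function(chrom, tssPos, knownLoci, window = 1000000L) {
  if (is.null(knownLoci) || nrow(knownLoci) == 0L) return(FALSE)
  any(knownLoci$chrom == as.character(chrom) &
        abs(knownLoci$pos - tssPos) <= window)
}
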