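#' Wakefield log approximate Bayes factor for one SNP
#'
#' Reconstructs the standard error of the SNP effect from sample size and
#' allele frequency under the assumption that it is inversely proportional
#' to the square root of the sample size:
#' \eqn{se^2 = 1/(2 n f (1-f))} for a quantitative trait and
#' \eqn{se^2 = 1/(2 n f (1-f) s (1-s))} for a case-control trait with case
#' fraction s. With shrinkage \eqn{r = W/(W + se^2)} (W the prior effect
#' variance), \deqn{\log ABF = \tfrac12 \log(1-r) + \tfrac12 z^2 r.}
#'
#' @param z SNP Z-score(s).
#' @param maf allele frequency f in (0, 1).
#' @param n sample size.
#' @param traitType \code{"quant"} or \code{"cc"}.
#' @param s case fraction (case-control only).
#' @param priorSd prior effect standard deviation (0.15 quantitative, 0.2
#'   case-control by convention).
#' @return log approximate Bayes factor(s).
#' @examples
#' logAbf(z = 5, maf = 0.3, n = 500, traitType = "quant", priorSd = 0.15)
#' @export
logAbf <- function(z, maf, n, traitType = c("quant", "cc"), s = NA,
                   priorSd = if (match.arg(traitType) == "quant") 0.15
                             else 0.2) {
  traitType <- match.arg(traitType)
  if (any(maf <= 0 | maf >= 1)) stop("monomorphic SNP: maf must be in (0, 1)")
  se2 <- 1 / (2 * n * maf * (1 - maf))
  if (traitType == "cc") {
    if (is.na(s) || s <= 0 || s >= 1)
      stop("case fraction s in (0, 1) required for case-control traits")
    se2 <- se2 / (s * (1 - s))
  }
  r <- priorSd ^ 2 / (priorSd ^ 2 + se2)
  0.5 * log(1 - r) + 0.5 * z ^ 2 * r
}

#' Posterior probabilities of the five colocalization hypotheses
#'
#' Bayes-factor colocalization of an eQTL signal (trait 1, quantitative)
#' and a GWAS signal (trait 2, case-control) over a shared, allele-aligned
#' SNP set. With per-SNP Bayes factors \eqn{B1_i, B2_i} from
#' \code{\link{logAbf}} and prior per-SNP causal probabilities p1, p2, p12,
#' the (unnormalized) hypothesis likelihoods are L0 = 1,
#' L1 = p1 sum(B1), L2 = p2 sum(B2),
#' L3 = p1 p2 (sum(B1) sum(B2) - sum(B1 B2)), L4 = p12 sum(B1 B2); the
#' posteriors PP0..PP4 normalize these. All accumulation is in log space
#' (log-sum-exp), so Z-scores of any magnitude are safe.
#'
#' @param zEqtl,zGwas aligned per-SNP Z-scores for expression and trait.
#' @param maf shared allele frequencies.
#' @param nEqtl,nGwas sample sizes.
#' @param s GWAS case fraction.
#' @param p1,p2,p12 per-SNP prior probabilities of eQTL-only, GWAS-only, and
#'   shared causality.
#' @param priorSdEqtl,priorSdGwas prior effect standard deviations.
#' @param pp4Threshold decision threshold for the colocalized flag.
#' @return a \linkS4class{ColocResult}.
#' @export
colocPP <- function(zEqtl, zGwas, maf, nEqtl, nGwas, s,
                    p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                    priorSdEqtl = 0.15, priorSdGwas = 0.2,
                    pp4Threshold = 0.5) {
  m <- length(zEqtl)
  stopifnot(length(zGwas) == m, length(maf) == m, m >= 1L,
            s > 0, s < 1)
  lb1 <- logAbf(zEqtl, maf, nEqtl, "quant", priorSd = priorSdEqtl)
  lb2 <- logAbf(zGwas, maf, nGwas, "cc", s = s, priorSd = priorSdGwas)
  pp <- colocPPFromLogBf(lb1, lb2, p1 = p1, p2 = p2, p12 = p12)
  new("ColocResult", pp = pp, logAbfEqtl = lb1, logAbfGwas = lb2,
      nSnps = as.integer(m),
      colocalized = unname(pp["pp4"] > pp4Threshold))
}

#' Combine per-SNP log Bayes factors into hypothesis posteriors
#'
#' The prior-weighted hypothesis sums of \code{\link{colocPP}}, exposed for
#' workflows that supply precomputed per-SNP log approximate Bayes factors.
#' Swapping the two traits (and p1 with p2) swaps pp1 and pp2 and leaves
#' pp0, pp3, pp4 unchanged.
#'
#' @param lb1,lb2 per-SNP log Bayes factors of the two traits.
#' @param p1,p2,p12 per-SNP prior causal probabilities.
#' @return named numeric pp0..pp4 summing to 1.
#' @export
colocPPFromLogBf <- function(lb1, lb2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(lb1)
  stopifnot(length(lb2) == m, m >= 1L)
  s1 <- .lse(lb1)
  s2 <- .lse(lb2)
  s12 <- .lse(lb1 + lb2)
  l0 <- 0
  l1 <- log(p1) + s1
  l2 <- log(p2) + s2
  ## sum over distinct causal SNP pairs: sum(B1)sum(B2) - sum(B1*B2);
  ## exactly zero (log -Inf) for a single SNP
  l3 <- if (m == 1L) -Inf else log(p1) + log(p2) + .logdiff(s1 + s2, s12)
  l4 <- log(p12) + s12
  ll <- c(l0, l1, l2, l3, l4)
  pp <- exp(ll - .lse(ll))
  pp <- pp / sum(pp)
  names(pp) <- paste0("pp", 0:4)
  pp
}

#' Synthetic per-SNP eQTL summary Z-scores from a weight model
#'
#' Derives LD-consistent single-SNP eQTL marginals for synthetic runs: the
#' correlation between SNP i and the (heritable part of) expression is
#' \eqn{\sqrt{h^2}(Vw)_i/\sqrt{w'Vw}}, and the marginal test statistic at
#' eQTL sample size n is \eqn{\sqrt{n}} times that correlation, optionally
#' plus standard-normal estimation noise.
#'
#' @param w model weights over the locus SNPs.
#' @param V LD matrix over the locus SNPs.
#' @param nEqtl eQTL study sample size.
#' @param h2 cis-heritability carried by the weights.
#' @param noise add N(0, V)-distributed sampling noise.
#' @param seed seed for the noise draw.
#' @return numeric vector of per-SNP Z-scores.
#' @export
syntheticEqtlZ <- function(w, V, nEqtl = 500L, h2 = 0.25, noise = TRUE,
                           seed = 1L) {
  quad <- drop(crossprod(w, V %*% w))
  r <- sqrt(h2) * drop(V %*% w) / sqrt(quad)
  r <- pmin(pmax(r, -0.99), 0.99)
  z <- sqrt(nEqtl) * r
  if (noise) {
    set.seed(seed)
    z <- z + drop(crossprod(chol(V + diag(1e-8, nrow(V))),
                            rnorm(length(w))))
  }
  z
}

#' Run the colocalization stage over selected genes
#'
#' For each gene, pairs its harmonized GWAS Z-scores with per-SNP eQTL
#' summary Z-scores -- supplied as a table (snp_id, z_eqtl[, maf, n]) or
#' derived from the weight model via \code{\link{syntheticEqtlZ}} -- and
#' computes PP0..PP4. Genes without usable eQTL summaries are flagged
#' \code{coloc_unavailable} rather than dropped.
#'
#' @param loci named list of \linkS4class{HarmonizedLocus} (selected genes).
#' @param eqtlZ optional named list of per-gene eQTL summary data.frames;
#'   when NULL, synthetic marginals are derived from the weights.
#' @param nEqtl,nGwas,s,p1,p2,p12,pp4Threshold see \code{\link{colocPP}}.
#' @param seed base seed for synthetic eQTL noise.
#' @return named list of \linkS4class{ColocResult} (entries may be the
#'   string \code{"coloc_unavailable"}).
#' @export
runColocStage <- function(loci, eqtlZ = NULL, nEqtl = 500L,
                          nGwas = 189839L, s = 10156 / 189839,
                          p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                          pp4Threshold = 0.5, seed = 1L) {
  out <- vector("list", length(loci))
  names(out) <- names(loci)
  for (i in seq_along(loci)) {
    loc <- loci[[i]]
    g <- geneId(loc)
    maf <- pmin(pmax(loc@maf, 0.01), 0.99)
    if (!is.null(eqtlZ)) {
      tab <- eqtlZ[[g]]
      if (is.null(tab) || !all(loc@snpIds %in% tab$snp_id)) {
        out[[i]] <- "coloc_unavailable"
        next
      }
      ze <- tab$z_eqtl[match(loc@snpIds, tab$snp_id)]
    } else {
      ze <- syntheticEqtlZ(loc@w, loc@V, nEqtl = nEqtl,
                           seed = .childSeed(seed, 100L + i))
    }
    out[[i]] <- colocPP(ze, loc@z, maf, nEqtl = nEqtl, nGwas = nGwas, s = s,
                        p1 = p1, p2 = p2, p12 = p12,
                        pp4Threshold = pp4Threshold)
  }
  out
}
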