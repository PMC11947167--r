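#' Weight-resampling permutation test conditional on GWAS effects
#'
#' Guards against TWAS inflation from strong SNP-trait signals in extensive
#' LD: the expression weights are resampled across SNP positions (sampling
#' with replacement by default; a without-replacement shuffle is available)
#' and the TWAS statistic recomputed against the fixed GWAS Z-scores and LD,
#' giving an empirical p-value conditional on the GWAS effects at the locus:
#' \deqn{p = (1 + \#\{|Z_{perm}| \ge |z_{obs}|\}) / (1 + n).}
#' Sampling stops early once 100 exceedances are seen, at which point the
#' estimate has at most about 10\% relative error; \code{maxPerm} draws
#' (default 100,000) bound the effective number of permutations.
#'
#' @param locus a \linkS4class{HarmonizedLocus}.
#' @param zObs the observed TWAS Z for this locus.
#' @param maxPerm maximum number of resampling draws (>= 100).
#' @param seed integer seed.
#' @param ridge LD shrinkage passed to the statistic.
#' @param mode \code{"bootstrap"} (with replacement, the default) or
#'   \code{"shuffle"} (permutation without replacement).
#' @param stopExceed early-stopping exceedance count.
#' @return the permutation p-value in (0, 1]. Single-SNP loci return 1 by
#'   convention (no resampling variability), with a message.
#' @export
permutationTest <- function(locus, zObs, maxPerm = 100000L, seed = 1L,
                            ridge = 0.1, mode = c("bootstrap", "shuffle"),
                            stopExceed = 100L) {
  mode <- match.arg(mode)
  if (maxPerm < 100L) stop("maxPerm must be at least 100")
  m <- length(locus@w)
  if (m < 2L) {
    message(geneId(locus), ": single-SNP model, permutation p set to 1")
    return(1)
  }
  set.seed(seed)
  Vr <- .ridgeV(locus@V, ridge)
  z <- locus@z
  w <- locus@w
  absObs <- abs(zObs) - 1e-12
  exceed <- 0L
  done <- 0L
  batch <- 1000L
  while (done < maxPerm) {
    B <- min(batch, maxPerm - done)
    W <- vapply(seq_len(B), function(i)
      if (mode == "bootstrap") sample(w, m, replace = TRUE) else sample(w),
      numeric(m))
    quad <- colSums(W * (Vr %*% W))
    num <- drop(crossprod(W, z))
    zp <- ifelse(quad > 0, num / sqrt(quad), 0)
    exceed <- exceed + sum(abs(zp) >= absObs)
    done <- done + B
    if (exceed >= stopExceed) break
  }
  (1 + exceed) / (1 + done)
}

#' Group significant neighboring genes into loci
#'
#' Genes are sorted by chromosome and start; genes whose boundary intervals
#' overlap or lie within \code{gap} base pairs of each other (inclusive at
#' exactly \code{gap}) merge into one locus, with transitive closure.
#'
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}.
#' @param gap maximal merged boundary gap in bp (default 100 kb).
#' @return data.frame \code{gene_id}, \code{locus_id} (dense integer ids in
#'   (chrom, start) order), \code{chrom}; one row per input gene.
#' @export
groupLoci <- function(genes, gap = 100000L) {
  if (nrow(genes) == 0L)
    return(data.frame(gene_id = character(), locus_id = integer(),
                      chrom = character(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end))
  ## IRanges gapwidth = start2 - end1 - 1; merging when the boundary gap
  ## start2 - end1 is <= gap means gapwidth <= gap - 1, i.e. min.gapwidth = gap
  merged <- GenomicRanges::reduce(gr, min.gapwidth = gap)
  merged <- GenomicRanges::sort(merged)
  hit <- GenomicRanges::findOverlaps(gr, merged, maxgap = 0L)
  locus <- integer(nrow(genes))
  locus[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  data.frame(gene_id = genes$gene_id, locus_id = locus,
             chrom = as.character(genes$chrom), stringsAsFactors = FALSE)
}

#' Predicted-expression correlation between two gene models
#'
#' Correlation of the two genes' genetically predicted expression implied by
#' the shared LD: \eqn{(w_i'V w_j)/\sqrt{(w_i'V w_i)(w_j'V w_j)}} with
#' ridge-regularized V over the union of their SNPs (absent SNPs carry
#' weight 0).
#'
#' @param wi,wj weight vectors on the shared SNP union.
#' @param V LD matrix over the union.
#' @param ridge LD shrinkage.
#' @return correlation in [-1, 1].
#' @export
geneCorrelation <- function(wi, wj, V, ridge = 0.1) {
  Vr <- .ridgeV(V, ridge)
  qi <- drop(crossprod(wi, Vr %*% wi))
  qj <- drop(crossprod(wj, Vr %*% wj))
  if (qi <= 0 || qj <= 0)
    stop("zero predicted-expression variance for a gene model")
  drop(crossprod(wi, Vr %*% wj)) / sqrt(qi * qj)
}

## deterministic ordering: smallest p, then largest |z|, then gene id
.stepOrder <- function(p, z, ids) order(p, -abs(z), ids)

#' Forward-stepwise joint-conditional gene selection at a locus
#'
#' Given the locus members' marginal TWAS Z-scores and their
#' predicted-expression correlation matrix \eqn{\Sigma}, performs forward
#' stepwise selection under the multivariate-normal dependence of the
#' Z-scores: the smallest-p gene seeds the model; each round computes, for
#' every unselected gene r, the conditional statistic
#' \deqn{z_{cond} = (z_r - \Sigma_{rS}\Sigma_{SS}^{-1} z_S) /
#' \sqrt{1 - \Sigma_{rS}\Sigma_{SS}^{-1}\Sigma_{Sr}}}
#' and admits the best gene while its conditional p stays below
#' \code{alpha / nSigOnChrom} (Bonferroni by the number of TWAS-significant
#' genes on the chromosome). Genes with \eqn{|\Sigma| \ge 0.99} against a
#' selected gene are excluded from selection for numerical stability; after
#' selection, unselected genes with \eqn{\Sigma^2 > corrFlagR2} against a
#' leading gene are labelled \code{"correlated"}, the rest
#' \code{"conditional"}. Joint statistics for the selected set are
#' \eqn{b = \Sigma_{SS}^{-1} z_S}, \eqn{z_j = b_j /
#' \sqrt{(\Sigma_{SS}^{-1})_{jj}}}.
#'
#' @param Sigma named gene-gene correlation matrix.
#' @param zMarg named marginal TWAS Z-scores, same genes.
#' @param nSigOnChrom Bonferroni divisor (>= 1).
#' @param alpha nominal level (default 0.05).
#' @param corrFlagR2 R-squared threshold for the "correlated" label.
#' @return data.frame (gene_id, status in {leading, conditional, correlated},
#'   joint_z, joint_p for leading genes, cond_z, cond_p for the others at
#'   termination).
#' @export
jointConditionalSelect <- function(Sigma, zMarg, nSigOnChrom, alpha = 0.05,
                                   corrFlagR2 = 0.9) {
  stopifnot(nSigOnChrom >= 1L)
  ids <- names(zMarg)
  stopifnot(!is.null(ids), identical(ids, rownames(Sigma)))
  k <- length(ids)
  pMarg <- .twoSidedP(zMarg)
  selected <- character()
  if (k == 1L) {
    return(data.frame(gene_id = ids, status = "leading", joint_z = zMarg,
                      joint_p = pMarg, cond_z = NA_real_, cond_p = NA_real_,
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  thresh <- alpha / nSigOnChrom
  selected <- ids[.stepOrder(pMarg, zMarg, ids)[1]]
  condZ <- setNames(rep(NA_real_, k), ids)
  repeat {
    rest <- setdiff(ids, selected)
    if (!length(rest)) break
    SigSS <- Sigma[selected, selected, drop = FALSE]
    inv <- tryCatch(solve(SigSS), error = function(e) NULL)
    while (is.null(inv) && length(selected) > 1L) {
      ## drop the later-entering collinear gene
      message("locus: dropping collinear gene ", tail(selected, 1))
      selected <- head(selected, -1L)
      SigSS <- Sigma[selected, selected, drop = FALSE]
      inv <- tryCatch(solve(SigSS), error = function(e) NULL)
    }
    zS <- zMarg[selected]
    for (r in rest) {
      sRS <- Sigma[r, selected, drop = FALSE]
      num <- zMarg[r] - drop(sRS %*% inv %*% zS)
      den2 <- 1 - drop(sRS %*% inv %*% t(sRS))
      den <- sqrt(max(den2, 0))
      condZ[r] <- if (den < 1e-6) {
        if (abs(num) < 1e-6) 0 else sign(num) * Inf
      } else num / den
    }
    ## collinearity guard: never select near-duplicates of selected genes
    guard <- vapply(rest, function(r)
      max(abs(Sigma[r, selected])) < 0.99, TRUE)
    cand <- rest[guard]
    if (!length(cand)) break
    condP <- .twoSidedP(condZ[cand])
    best <- cand[.stepOrder(condP, condZ[cand], cand)[1]]
    if (.twoSidedP(condZ[best]) < thresh) {
      selected <- c(selected, best)
    } else break
  }
  SigSS <- Sigma[selected, selected, drop = FALSE]
  inv <- solve(SigSS)
  b <- drop(inv %*% zMarg[selected])
  jointZ <- b / sqrt(diag(inv))
  status <- setNames(rep("conditional", k), ids)
  status[selected] <- "leading"
  others <- setdiff(ids, selected)
  if (length(others)) {
    r2max <- vapply(others, function(r)
      max(Sigma[r, selected] ^ 2), 0)
    status[others[r2max > corrFlagR2]] <- "correlated"
  }
  data.frame(
    gene_id = ids, status = status[ids],
    joint_z = ifelse(ids %in% selected, jointZ[match(ids, selected)],
                     NA_real_),
    joint_p = ifelse(ids %in% selected,
                     .twoSidedP(jointZ[match(ids, selected)]), NA_real_),
    cond_z = ifelse(ids %in% selected, NA_real_, condZ[ids]),
    cond_p = ifelse(ids %in% selected, NA_real_, .twoSidedP(condZ[ids])),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' SNP-level GWAS association conditional on TWAS effects
#'
#' Imputes each SNP's GWAS Z conditional on the joint TWAS Z-scores of the
#' selected genes and standardizes the residual. With
#' \eqn{c_{ig} = (Vw_g)_i / \sqrt{w_g'Vw_g}} the SNP-gene correlation matrix
#' C, \deqn{z^{res}_i = (z_i - C_i \Sigma_{SS}^{-1} z_S) /
#' \sqrt{1 - C_i \Sigma_{SS}^{-1} C_i'},}
#' with the denominator floored at \code{tol} (fully mediated SNPs are 0/0
#' by construction and return exactly 0). The proportion of the GWAS signal
#' explained is \eqn{1 - \chi^2_{res} / \chi^2_{marg}} at the locus lead SNP
#' (largest marginal chi-squared), clipped to [0, 1]; \code{method =
#' "mean_sig"} instead averages the chi-squared ratio over genome-wide
#' significant SNPs (falling back to the lead SNP when there are none).
#'
#' @param z marginal SNP Z-scores at the locus.
#' @param V LD matrix over the locus SNPs.
#' @param W SNPs x selected-genes weight matrix (zero rows for SNPs a gene
#'   does not weight); NULL or zero columns give the identity transform.
#' @param ridge LD shrinkage.
#' @param tol denominator floor.
#' @param method proportion-explained definition (see above).
#' @param sigThreshold genome-wide significance level for
#'   \code{method = "mean_sig"}.
#' @return list with \code{residual} (Z vector), \code{proportionExplained},
#'   \code{leadSnp} (index of the lead SNP).
#' @export
gwasConditional <- function(z, V, W, ridge = 0.1, tol = 1e-6,
                            method = c("lead_snp", "mean_sig"),
                            sigThreshold = 5e-8) {
  method <- match.arg(method)
  lead <- which.max(z ^ 2)
  if (is.null(W) || NCOL(W) == 0L)
    return(list(residual = z, proportionExplained = 0, leadSnp = lead))
  W <- as.matrix(W)
  Vr <- .ridgeV(V, ridge)
  quads <- apply(W, 2, function(w) drop(crossprod(w, Vr %*% w)))
  if (any(quads <= 0)) stop("zero predicted-expression variance at the locus")
  C <- sweep(Vr %*% W, 2, sqrt(quads), "/")
  Sigma <- crossprod(W, Vr %*% W) / sqrt(outer(quads, quads))
  zS <- drop(crossprod(W, z)) / sqrt(quads)
  inv <- solve(Sigma)
  num <- z - drop(C %*% (inv %*% zS))
  den2 <- 1 - rowSums((C %*% inv) * C)
  den <- sqrt(pmax(den2, 0))
  residual <- num / pmax(den, tol)
  residual[abs(num) < tol & den < tol] <- 0
  prop <- if (method == "lead_snp" || !any(.twoSidedP(z) < sigThreshold)) {
    1 - residual[lead] ^ 2 / z[lead] ^ 2
  } else {
    sig <- which(.twoSidedP(z) < sigThreshold)
    1 - mean(residual[sig] ^ 2) / mean(z[sig] ^ 2)
  }
  list(residual = residual, proportionExplained = min(max(prop, 0), 1),
       leadSnp = lead)
}
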