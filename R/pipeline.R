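#' Pipeline thresholds and options
#'
#' All tunable thresholds of the prioritization pipeline, with the study
#' defaults: FDR 0.01 pooled over all tests, permutation level 0.05 with an
#' effective maximum of 100,000 draws, joint-conditional nominal level 0.05
#' Bonferroni-adjusted per chromosome, PP4 threshold 0.5, correlated-gene
#' flag at predicted-expression R-squared 0.9, 100 kb locus merge gap, 1 Mb
#' GWAS-locus overlap window, LD ridge 0.1.
#'
#' @param fdrQ FDR threshold on BH q-values.
#' @param permAlpha permutation-test significance level.
#' @param permMax maximum (effective) number of permutations.
#' @param permMode \code{"bootstrap"} or \code{"shuffle"}.
#' @param jointAlpha nominal joint-conditional level (Bonferroni divided by
#'   the number of TWAS-significant genes on the chromosome).
#' @param colocPP4 colocalization decision threshold.
#' @param corrFlagR2 correlated-gene R-squared flag.
#' @param locusGap locus merge gap in bp.
#' @param gwasOverlapWindow half-width of the GWAS-locus window in bp.
#' @param ridge LD shrinkage used by every LD-aware statistic.
#' @param dropAmbiguous drop strand-ambiguous SNPs during harmonization.
#' @param nEqtl,nGwas,caseFraction colocalization sample-size inputs.
#' @param enrichPerm permutations for the expression enrichment test.
#' @param seed global seed; per-stage and per-gene child seeds are derived
#'   deterministically from it.
#' @return named list of options.
#' @export
pipelineOptions <- function(fdrQ = 0.01, permAlpha = 0.05,
                            permMax = 100000L, permMode = "bootstrap",
                            jointAlpha = 0.05, colocPP4 = 0.5,
                            corrFlagR2 = 0.9, locusGap = 100000L,
                            gwasOverlapWindow = 1000000L, ridge = 0.1,
                            dropAmbiguous = FALSE, nEqtl = 500L,
                            nGwas = 189839L, caseFraction = 10156 / 189839,
                            enrichPerm = 10000L, seed = 1L) {
  list(fdrQ = fdrQ, permAlpha = permAlpha, permMax = as.integer(permMax),
       permMode = permMode, jointAlpha = jointAlpha, colocPP4 = colocPP4,
       corrFlagR2 = corrFlagR2, locusGap = as.integer(locusGap),
       gwasOverlapWindow = as.integer(gwasOverlapWindow), ridge = ridge,
       dropAmbiguous = dropAmbiguous, nEqtl = as.integer(nEqtl),
       nGwas = as.integer(nGwas), caseFraction = caseFraction,
       enrichPerm = as.integer(enrichPerm), seed = as.integer(seed))
}

## shared locus frame: union of the member genes' harmonized SNPs with
## z, V and per-gene weights all aligned to the panel's allele coding
.locusFrame <- function(members, models, gwas, panel, harmonized) {
  snpUnion <- unique(unlist(lapply(harmonized[members],
                                   function(h) h@snpIds)))
  pi <- match(snpUnion, panel$snps$snp_id)
  gi <- match(snpUnion, gwas$snp_id)
  swapG <- gwas$a1[gi] == panel$snps$a2[pi] & gwas$a2[gi] == panel$snps$a1[pi]
  z <- ifelse(swapG, -gwas$z[gi], gwas$z[gi])
  V <- .panelCor(panel$genotypes[, pi, drop = FALSE])
  W <- matrix(0, length(snpUnion), length(members),
              dimnames = list(snpUnion, members))
  for (g in members) {
    wtab <- modelWeights(models[[g]])
    keep <- wtab$snp_id %in% snpUnion
    wtab <- wtab[keep, , drop = FALSE]
    wi <- match(wtab$snp_id, panel$snps$snp_id)
    flip <- ifelse(wtab$a1 == panel$snps$a2[wi] &
                     wtab$a2 == panel$snps$a1[wi], -1, 1)
    W[wtab$snp_id, g] <- wtab$weight * flip
  }
  list(snpIds = snpUnion, z = z, V = V, W = W)
}

#' Run the full TWAS prioritization pipeline
#'
#' Executes, in order: per-gene model selection, allele harmonization,
#' the summary-based TWAS statistic, pooled BH FDR, the GWAS-conditional
#' permutation test, locus assembly, forward-stepwise joint-conditional
#' selection, colocalization of the leading genes, SNP-level GWAS
#' conditioning per locus, and (optionally) expression enrichment. Per-gene
#' failures are logged and skipped; the run is reproducible from inputs plus
#' \code{options$seed}.
#'
#' @param x a \linkS4class{TwasSimulation}, or NULL when \code{gwas},
#'   \code{panel} and \code{models} are given explicitly.
#' @param gwas GWAS table (snp_id, a1, a2, z).
#' @param panel list with \code{genotypes} and \code{snps}.
#' @param models list of \linkS4class{WeightModel}; multiple candidates per
#'   gene are resolved by \code{\link{selectModel}}.
#' @param knownLoci optional data.frame (chrom, pos) of published GWAS index
#'   SNPs for the overlap flag.
#' @param expressionData optional named list of
#'   \linkS4class{ExpressionDataset} for the enrichment stage.
#' @param eqtlZ optional per-gene eQTL summary tables (see
#'   \code{\link{runColocStage}}).
#' @param options \code{\link{pipelineOptions}()}.
#' @return a \linkS4class{TwasResults}.
#' @examples
#' sim <- simulateTwasStudy(simulationConfig(nGenes = 30, seed = 3,
#'                                           causalGeneFraction = 0.1))
#' res <- runPipeline(sim, options = pipelineOptions(permMax = 1000))
#' stageTallies(res)
#' @export
runPipeline <- function(x = NULL, gwas = NULL, panel = NULL, models = NULL,
                        knownLoci = NULL, expressionData = NULL,
                        eqtlZ = NULL, options = pipelineOptions()) {
  if (is(x, "TwasSimulation")) {
    gwas <- x@gwas
    panel <- list(genotypes = x@genotypes, snps = x@snps)
    models <- x@models
  }
  stopifnot(!is.null(gwas), !is.null(panel), !is.null(models))
  logLines <- character()
  note <- function(...) logLines <<- c(logLines, paste0(...))

  ## stage 1: model selection (one model per gene, panel priority order)
  byGene <- split(models, vapply(models, geneId, ""))
  selected <- list()
  for (g in names(byGene)) {
    m <- selectModel(byGene[[g]])
    if (is.null(m)) note(g, ": all models fail the quality filters")
    else selected[[g]] <- m
  }
  ## deterministic gene order
  ord <- order(vapply(selected, function(m) m@chrom, ""),
               vapply(selected, function(m) m@geneStart, 0),
               names(selected))
  selected <- selected[ord]

  ## stage 2-3: harmonization and the marginal TWAS statistic
  harmonized <- list()
  rows <- list()
  for (g in names(selected)) {
    m <- selected[[g]]
    h <- tryCatch(
      withCallingHandlers(
        harmonize(gwas, m, panel, dropAmbiguous = options$dropAmbiguous),
        message = function(c) {
          note(trimws(conditionMessage(c)))
          invokeRestart("muffleMessage")
        }),
      error = function(e) {
        note(g, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(h)) next
    tw <- tryCatch(twasZ(h, ridge = options$ridge), error = function(e) NULL)
    if (is.null(tw)) {
      note(g, ": TWAS statistic failed")
      next
    }
    harmonized[[g]] <- h
    rows[[g]] <- data.frame(
      gene_id = g, panel = m@panel, model_type = m@modelType,
      chrom = m@chrom, start = m@geneStart, end = m@geneEnd,
      strand = m@strand, tss = tss(m), n_snps = length(h@snpIds),
      z_twas = tw$z, p = tw$p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no gene survived model selection and harmonization")
  tab <- do.call(rbind, rows)
  rownames(tab) <- tab$gene_id

  ## stage 4: pooled FDR and GWAS-locus overlap
  tab$q <- bhFdr(tab$p)
  tab$fdr_significant <- tab$q < options$fdrQ
  tab$gwas_overlap <- vapply(seq_len(nrow(tab)), function(i)
    flagGwasOverlap(tab$chrom[i], tab$tss[i], knownLoci,
                    window = options$gwasOverlapWindow), TRUE)

  ## stage 5: permutation test conditional on GWAS effects
  tab$perm_p <- NA_real_
  sigGenes <- tab$gene_id[tab$fdr_significant]
  for (g in sigGenes) {
    i <- match(g, tab$gene_id)
    tab$perm_p[i] <- permutationTest(
      harmonized[[g]], tab$z_twas[i], maxPerm = options$permMax,
      seed = .childSeed(options$seed, 10000L + i), ridge = options$ridge,
      mode = options$permMode)
  }
  tab$perm_pass <- !is.na(tab$perm_p) & tab$perm_p < options$permAlpha

  ## stage 6: locus assembly over permutation-passing genes
  tab$locus_id <- NA_integer_
  passing <- tab[tab$perm_pass, , drop = FALSE]
  lociReports <- list()
  tab$joint_status <- NA_character_
  tab$joint_z <- NA_real_
  tab$joint_p <- NA_real_
  tab$cond_z <- NA_real_
  tab$cond_p <- NA_real_
  if (nrow(passing)) {
    lmap <- groupLoci(passing[, c("gene_id", "chrom", "start", "end")],
                      gap = options$locusGap)
    tab$locus_id[match(lmap$gene_id, tab$gene_id)] <- lmap$locus_id
    nSigByChrom <- table(tab$chrom[tab$fdr_significant])

    ## stage 7: joint-conditional selection per locus
    for (l in sort(unique(lmap$locus_id))) {
      members <- lmap$gene_id[lmap$locus_id == l]
      chrom <- lmap$chrom[match(members[1], lmap$gene_id)]
      nSig <- max(1L, as.integer(nSigByChrom[chrom]))
      frame <- .locusFrame(members, selected, gwas, panel, harmonized)
      if (length(members) == 1L) {
        g <- members
        rep <- data.frame(gene_id = g, status = "leading",
                          joint_z = tab[g, "z_twas"],
                          joint_p = tab[g, "p"],
                          cond_z = NA_real_, cond_p = NA_real_,
                          stringsAsFactors = FALSE)
      } else {
        Vr <- frame$V
        quads <- apply(frame$W, 2, function(w)
          drop(crossprod(w, .ridgeV(Vr, options$ridge) %*% w)))
        Wn <- frame$W
        Sigma <- crossprod(Wn, .ridgeV(Vr, options$ridge) %*% Wn) /
          sqrt(outer(quads, quads))
        dimnames(Sigma) <- list(members, members)
        zM <- setNames(tab[members, "z_twas"], members)
        rep <- jointConditionalSelect(Sigma, zM, nSigOnChrom = nSig,
                                      alpha = options$jointAlpha,
                                      corrFlagR2 = options$corrFlagR2)
      }
      idx <- match(rep$gene_id, tab$gene_id)
      tab$joint_status[idx] <- rep$status
      tab$joint_z[idx] <- rep$joint_z
      tab$joint_p[idx] <- rep$joint_p
      tab$cond_z[idx] <- rep$cond_z
      tab$cond_p[idx] <- rep$cond_p

      ## stage 9 (per locus): SNP-level GWAS conditioning on leading genes
      leadGenes <- rep$gene_id[rep$status == "leading"]
      cond <- gwasConditional(frame$z, frame$V,
                              frame$W[, leadGenes, drop = FALSE],
                              ridge = options$ridge)
      lociReports[[as.character(l)]] <- list(
        locus_id = l, chrom = chrom, members = members,
        leading = leadGenes, report = rep,
        residual = data.frame(snp_id = frame$snpIds,
                              z_marginal = frame$z,
                              z_residual = cond$residual,
                              stringsAsFactors = FALSE),
        proportion_explained = cond$proportionExplained,
        lead_snp = frame$snpIds[cond$leadSnp])
    }
  }
  tab$leading <- !is.na(tab$joint_status) & tab$joint_status == "leading"

  ## stage 8: colocalization of leading genes
  for (pcol in paste0("pp", 0:4)) tab[[pcol]] <- NA_real_
  tab$colocalized <- NA
  leadIds <- tab$gene_id[tab$leading]
  if (length(leadIds)) {
    cres <- runColocStage(harmonized[leadIds], eqtlZ = eqtlZ,
                          nEqtl = options$nEqtl, nGwas = options$nGwas,
                          s = options$caseFraction,
                          pp4Threshold = options$colocPP4,
                          seed = options$seed)
    for (g in leadIds) {
      i <- match(g, tab$gene_id)
      r <- cres[[g]]
      if (is.character(r)) {
        note(g, ": coloc_unavailable")
        tab$colocalized[i] <- NA
      } else {
        tab[i, paste0("pp", 0:4)] <- as.list(posteriors(r))
        tab$colocalized[i] <- r@colocalized
      }
    }
  }

  ## stage 10 (optional): expression enrichment of the leading genes
  enrichment <- NULL
  if (!is.null(expressionData) && length(leadIds)) {
    enrRows <- list()
    di <- 0L
    for (dn in names(expressionData)) {
      ds <- expressionData[[dn]]
      di <- di + 1L
      bg <- intersect(tab$gene_id, rownames(exprMatrix(ds)))
      tg <- intersect(leadIds, bg)
      if (!length(tg)) next
      stats <- if (ds@kind == "single_cell")
        c("median_expression", "nonzero_proportion")
      else "median_expression"
      for (grp in unique(columnGroups(ds))) for (st in stats) {
        er <- medianEnrichmentTest(tg, ds, bg, group = grp,
                                   nPerm = options$enrichPerm, statistic = st,
                                   seed = .childSeed(options$seed,
                                                     20000L + di))
        enrRows[[length(enrRows) + 1L]] <- data.frame(
          dataset = dn, group = grp, statistic = st,
          observed = er@observed, p = er@p, n_target = er@nTarget,
          stringsAsFactors = FALSE)
      }
    }
    if (length(enrRows)) enrichment <- do.call(rbind, enrRows)
  }

  tab$prioritized <- tab$leading & !is.na(tab$colocalized) & tab$colocalized
  tallies <- list(
    n_tested = nrow(tab),
    n_fdr_significant = sum(tab$fdr_significant),
    n_perm_passing = sum(tab$perm_pass),
    n_loci = length(lociReports),
    n_leading = sum(tab$leading),
    n_colocalized = sum(tab$prioritized),
    n_prioritized_gwas = sum(tab$prioritized & tab$gwas_overlap),
    n_prioritized_novel = sum(tab$prioritized & !tab$gwas_overlap))
  rownames(tab) <- NULL
  res <- new("TwasResults", table = tab, tallies = tallies,
             loci = lociReports, log = logLines)
  attr(res, "enrichment") <- enrichment
  attr(res, "options") <- options
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Retrieve the enrichment table of a pipeline run
#' @param results a \linkS4class{TwasResults} from \code{\link{runPipeline}}.
#' @return data.frame of enrichment results, or NULL.
#' @export
enrichmentTable <- function(results) attr(results, "enrichment")
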