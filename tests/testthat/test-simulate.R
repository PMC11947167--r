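test_that("all generators are bit-identical under the same config and seed", {
  cfg <- simulationConfig(nGenes = 6, nRefSamples = 60, seed = 42)
  s1 <- simulateTwasStudy(cfg)
  s2 <- simulateTwasStudy(cfg)
  expect_identical(s1@genotypes, s2@genotypes)
  expect_identical(s1@gwas, s2@gwas)
  expect_identical(lapply(s1@models, modelWeights),
                   lapply(s2@models, modelWeights))
  expect_identical(s1@truth, s2@truth)
  e1 <- simulateExpression(s1@truth, s1@genes$gene_id, 20, "single_cell",
                           seed = 3)
  e2 <- simulateExpression(s1@truth, s1@genes$gene_id, 20, "single_cell",
                           seed = 3)
  expect_identical(exprMatrix(e1), exprMatrix(e2))
})

test_that("LD panel reproduces the requested block correlation structure", {
  ## independence case: off-diagonal sample LD within sampling error
  cfg0 <- simulationConfig(nRefSamples = 1000, nGenes = 10, snpsPerGene = 10,
                           ldBlockSize = 10, ldRho = 0, seed = 5)
  p0 <- simulateLdPanel(cfg0)
  C <- cor(p0$genotypes)
  off <- abs(C[upper.tri(C)])
  expect_gt(mean(off < 4 / sqrt(1000)), 0.95)

  ## strong-LD case with well-matched MAFs: mean adjacent dosage |r|
  ## within 0.1 of the target 0.9
  cfg9 <- simulationConfig(nRefSamples = 1000, nGenes = 10, snpsPerGene = 10,
                           ldBlockSize = 10, ldRho = 0.9,
                           mafRange = c(0.3, 0.5), seed = 11)
  p9 <- simulateLdPanel(cfg9)
  adj <- unlist(lapply(unique(p9$snps$block), function(b) {
    idx <- which(p9$snps$block == b)
    vapply(seq_len(length(idx) - 1), function(i)
      cor(p9$genotypes[, idx[i]], p9$genotypes[, idx[i + 1]]), 0)
  }))
  expect_lt(abs(mean(abs(adj)) - 0.9), 0.1)

  ## SNPs in distinct blocks are independent
  b1 <- which(p9$snps$block == unique(p9$snps$block)[1])
  b2 <- which(p9$snps$block == unique(p9$snps$block)[2])
  cross <- abs(cor(p9$genotypes[, b1], p9$genotypes[, b2]))
  expect_lt(mean(cross), 0.05)

  ## no monomorphic SNPs
  expect_true(all(apply(p9$genotypes, 2, function(x) length(unique(x))) > 1))
})

test_that("copula calibration matches a direct Monte-Carlo simulation", {
  ## oracle: simulate the thresholded Gaussian copula directly at large n
  set.seed(31)
  r <- 0.8; f1 <- 0.3; f2 <- 0.4
  Z <- mvnDraw(300000, matrix(c(1, r, r, 1), 2))
  g1 <- qbinom(pnorm(Z[, 1]), 2, f1)
  g2 <- qbinom(pnorm(Z[, 2]), 2, f2)
  expect_lt(abs(twasprio:::.dosageCorr(r, f1, f2) - cor(g1, g2)), 0.02)
})

test_that("panel generation warns on tiny panels and rejects bad MAF ranges", {
  expect_warning(simulateLdPanel(simulationConfig(nRefSamples = 20,
                                                  nGenes = 2, seed = 1)),
                 "unstable")
  expect_error(simulationConfig(mafRange = c(0.4, 0.2)), "mafRange")
  expect_error(simulationConfig(weightSparsity = 0), "weightSparsity")
})

test_that("weight models honor sparsity and emit requested failing models", {
  cfg <- simulationConfig(nGenes = 8, nRefSamples = 60, snpsPerGene = 6,
                          weightSparsity = 1, seed = 9)
  panel <- simulateLdPanel(cfg)
  models <- simulateWeightModels(cfg, panel, nFailing = 3L)
  expect_true(all(vapply(models, function(m)
    all(modelWeights(m)$weight != 0), TRUE)))
  rejected <- vapply(models, function(m) is.null(selectModel(list(m))), TRUE)
  expect_identical(sum(rejected), 3L)
})

test_that("GWAS Z-scores are marginally standard normal under the null", {
  cfg <- simulationConfig(nRefSamples = 300, nGenes = 625, snpsPerGene = 8,
                          ldBlockSize = 8, ldRho = 0.7,
                          causalGeneFraction = 0, seed = 77)
  sim <- simulateTwasStudy(cfg)
  expect_identical(nrow(sim@gwas), 5000L)
  expect_gt(suppressWarnings(
    ks.test(sim@gwas$z, "pnorm")$p.value), 0.01)
})

test_that("a causal gene shifts the Z mean by alpha along the weight direction", {
  ## identity LD, single nonzero weight: E[Z] at that SNP equals the effect
  hot <- numeric(0); cold <- numeric(0)
  for (s in 1:40) {
    cfg <- simulationConfig(nRefSamples = 100, nGenes = 2, snpsPerGene = 5,
                            ldBlockSize = 5, ldRho = 0,
                            weightSparsity = 0.01, causalGeneFraction = 0,
                            seed = s)
    panel <- simulateLdPanel(cfg)
    models <- simulateWeightModels(cfg, panel)
    truth <- list(causalGenes = "gene0001", effect = c(gene0001 = 6),
                  enrichedGeneSet = character(), expressionShift = 0)
    gz <- simulateGwasZ(cfg, panel, models, truth, usePopulationLd = TRUE)
    w <- modelWeights(models[[1]])
    hotSnp <- w$snp_id[w$weight != 0]
    expect_length(hotSnp, 1L)
    ## E[Z] at the weighted SNP is alpha along the weight direction, i.e.
    ## +6 after orienting by the weight's sign
    hot <- c(hot, sign(w$weight[w$weight != 0]) *
               gz$z[match(hotSnp, gz$snp_id)])
    cold <- c(cold, gz$z[match(setdiff(w$snp_id, hotSnp), gz$snp_id)])
  }
  expect_lt(abs(mean(hot) - 6), 0.5)
  expect_lt(abs(mean(cold)), 0.3)
})

test_that("expression matrices carry the planted location shift", {
  genes <- sprintf("g%03d", 1:300)
  target <- genes[1:30]
  ## null case: zeros present in single-cell mode, none in bulk
  t0 <- list(enrichedGeneSet = character(), expressionShift = 0)
  sc <- simulateExpression(t0, genes, 50, "single_cell", seed = 2)
  bk <- simulateExpression(t0, genes, 50, "bulk", seed = 2)
  expect_true(any(exprMatrix(sc) == 0))
  expect_true(all(exprMatrix(bk) > 0))
  ## planted 2-log10 shift: target median beats background in every seed
  t2 <- list(enrichedGeneSet = target, expressionShift = 2)
  wins <- vapply(1:20, function(s) {
    X <- exprMatrix(simulateExpression(t2, genes, 20, "bulk", seed = s))
    med <- apply(log10(X), 1, median)
    median(med[target]) > median(med[setdiff(genes, target)])
  }, TRUE)
  expect_true(all(wins))
})
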