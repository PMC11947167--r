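test_that("model selection filters on quality and resolves by panel priority", {
  ## passing testis model beats a better-performing cross-tissue model
  pick <- selectModel(list(mk1 <- mkModel("testis", cvR2 = 0.05),
                           mkModel("cross_tissue", cvR2 = 0.40)))
  expect_identical(panelName(pick), "testis")
  ## testis model failing the R2 filter falls through to the tumor model
  pick <- selectModel(list(mkModel("testis", cvR2 = 0.005),
                           mkModel("tumor", cvR2 = 0.1)))
  expect_identical(panelName(pick), "tumor")
  ## within cross-tissue, the best-performing feature wins
  pick <- selectModel(list(mkModel("cross_tissue", cvR2 = 0.10),
                           mkModel("cross_tissue", cvR2 = 0.30)))
  expect_identical(pick@cvR2, 0.30)
  ## each filter rejects on its own
  expect_null(selectModel(list(mkModel("testis", cvP = 0.2))))
  expect_null(selectModel(list(mkModel("testis", h2P = 0.5))))
  expect_null(selectModel(list(mkModel("testis", cvR2 = 0.005))))
  expect_null(selectModel(list()))
  expect_error(selectModel(list(mkModel(gene = "a"), mkModel(gene = "b"))),
               "share one gene id")
})

test_that("harmonization aligns alleles and drops unmatchable SNPs", {
  panel <- tinyPanel()
  model <- weightModel("g1", data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    a1 = c("A", "C", "A"), a2 = c("G", "T", "G"),
    weight = c(0.5, -0.3, 0.2), stringsAsFactors = FALSE))
  ## rs1 swapped in the GWAS -> sign flip; rs3 absent -> dropped
  gwas <- data.frame(snp_id = c("rs1", "rs2"),
                     a1 = c("G", "C"), a2 = c("A", "T"),
                     z = c(2.0, 1.5), stringsAsFactors = FALSE)
  h <- harmonize(gwas, model, panel)
  expect_identical(h@snpIds, c("rs1", "rs2"))
  expect_equal(h@z, c(-2.0, 1.5))
  expect_equal(h@w, c(0.5, -0.3))
  ## identity coding: z unchanged, intersection kept
  gwasId <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                       a1 = c("A", "C", "A"), a2 = c("G", "T", "G"),
                       z = c(2.0, 1.5, -1.0), stringsAsFactors = FALSE)
  hId <- harmonize(gwasId, model, panel)
  expect_identical(length(hId@snpIds), 3L)
  expect_equal(hId@z, c(2.0, 1.5, -1.0))
  ## irreconcilable alleles are dropped
  gwasBad <- data.frame(snp_id = "rs1", a1 = "C", a2 = "T", z = 2,
                        stringsAsFactors = FALSE)
  expect_null(suppressMessages(harmonize(gwasBad, model, panel)))
})

test_that("strand-ambiguous SNPs are kept by default and droppable by flag", {
  panel <- tinyPanel()
  model <- weightModel("g1", data.frame(
    snp_id = c("rs1", "rs4"), a1 = c("A", "T"), a2 = c("G", "A"),
    weight = c(0.5, 0.4), stringsAsFactors = FALSE))
  gwas <- data.frame(snp_id = c("rs1", "rs4"), a1 = c("A", "T"),
                     a2 = c("G", "A"), z = c(2, 1),
                     stringsAsFactors = FALSE)
  expect_identical(harmonize(gwas, model, panel)@snpIds, c("rs1", "rs4"))
  expect_identical(harmonize(gwas, model, panel,
                             dropAmbiguous = TRUE)@snpIds, "rs1")
})

test_that("TWAS statistic matches direct arithmetic and its invariances", {
  ## single-SNP identity
  l1 <- harmonizedLocus("g", "rs1", z = 3.2, w = 1, V = matrix(1))
  expect_equal(twasZ(l1, ridge = 0)$z, 3.2)
  expect_equal(twasZ(l1, ridge = 0.1)$z, 3.2)
  expect_equal(twasZ(l1, ridge = 0)$quad, 1)
  ## two-SNP hand-computed value
  V <- matrix(c(1, 0.2, 0.2, 1), 2)
  l2 <- harmonizedLocus("g", c("rs1", "rs2"), z = c(2, 1),
                        w = c(0.5, -0.3), V = V)
  expect_equal(twasZ(l2, ridge = 0)$z, 0.7 / sqrt(0.28), tolerance = 1e-12)
  ## positive rescaling of the weights changes nothing
  l2c <- harmonizedLocus("g", c("rs1", "rs2"), z = c(2, 1),
                         w = 13 * c(0.5, -0.3), V = V)
  expect_equal(twasZ(l2c, ridge = 0)$z, twasZ(l2, ridge = 0)$z)
  ## simultaneous SNP reordering changes nothing
  set.seed(4)
  V5 <- arCorr(5, 0.5)
  w5 <- rnorm(5); z5 <- rnorm(5)
  perm <- sample(5)
  la <- harmonizedLocus("g", paste0("s", 1:5), z5, w5, V5)
  lb <- harmonizedLocus("g", paste0("s", perm), z5[perm], w5[perm],
                        V5[perm, perm])
  expect_equal(twasZ(la, 0.1)$z, twasZ(lb, 0.1)$z)
  ## error paths
  l0 <- harmonizedLocus("g", "rs1", z = 1, w = 0, V = matrix(1))
  expect_error(twasZ(l0), "zero")
})

test_that("TWAS statistic agrees with an individual-level brute-force oracle", {
  set.seed(12)
  V <- arCorr(3, 0.5)
  w <- c(0.5, -0.3, 0.2)
  z <- c(2, 1, -0.5)
  loc <- harmonizedLocus("g", paste0("s", 1:3), z, w, V)
  expect_equal(bruteForceTwas(w, z, V), twasZ(loc, ridge = 0)$z,
               tolerance = 0.15)
})

test_that("allele-flip of the whole GWAS table leaves the statistic invariant", {
  panel <- tinyPanel()
  model <- weightModel("g1", data.frame(
    snp_id = c("rs1", "rs2", "rs3"), a1 = c("A", "C", "A"),
    a2 = c("G", "T", "G"), weight = c(0.5, -0.3, 0.2),
    stringsAsFactors = FALSE))
  gwas <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                     a1 = c("A", "C", "A"), a2 = c("G", "T", "G"),
                     z = c(2.0, 1.5, -1.0), stringsAsFactors = FALSE)
  flipped <- data.frame(snp_id = gwas$snp_id, a1 = gwas$a2, a2 = gwas$a1,
                        z = -gwas$z, stringsAsFactors = FALSE)
  z1 <- twasZ(harmonize(gwas, model, panel))$z
  z2 <- twasZ(harmonize(flipped, model, panel))$z
  expect_equal(z1, z2)
})

test_that("BH q-values follow the textbook step-up arithmetic", {
  expect_equal(bhFdr(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhFdr(0.013), 0.013)
  expect_error(bhFdr(c(0.1, 1.2)))
})

test_that("GWAS-locus overlap uses a closed 1 Mb window on the same chromosome", {
  known <- data.frame(chrom = "3", pos = 5000000L, stringsAsFactors = FALSE)
  expect_true(flagGwasOverlap("3", 4000000L, known))   # exactly 1 Mb away
  expect_true(flagGwasOverlap("3", 4000001L, known))
  expect_false(flagGwasOverlap("3", 3999999L, known))
  expect_false(flagGwasOverlap("4", 5000000L, known))
  expect_false(flagGwasOverlap("3", 5000000L, NULL))
})
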