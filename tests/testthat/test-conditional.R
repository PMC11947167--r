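test_that("permutation test handles degenerate and adversarial loci", {
  m <- 20
  V <- arCorr(m, 0.3)
  ## constant weights: every bootstrap draw reproduces the observed statistic
  lc <- harmonizedLocus("g", paste0("s", 1:m), z = rnorm(m),
                        w = rep(0.7, m), V = V)
  zt <- twasZ(lc, 0)$z
  expect_equal(permutationTest(lc, zt, maxPerm = 500, seed = 1, ridge = 0), 1)
  ## single-SNP models get p = 1 by convention
  l1 <- harmonizedLocus("g", "s1", z = 5, w = 1, V = matrix(1))
  expect_message(p1 <- permutationTest(l1, 5, seed = 1), "single-SNP")
  expect_equal(p1, 1)
  expect_error(permutationTest(lc, zt, maxPerm = 50), "at least 100")
  ## hot-SNP inflation: one huge GWAS Z, observed weight loading exactly on
  ## it; resampled weights rarely reconcentrate there
  mh <- 50
  zh <- c(30, rep(0, mh - 1))
  wh <- c(1, rep(0, mh - 1))
  lh <- harmonizedLocus("g", paste0("s", 1:mh), zh, wh, diag(mh))
  ph <- permutationTest(lh, twasZ(lh, 0)$z, maxPerm = 5000, seed = 3,
                        ridge = 0)
  expect_gt(ph, 0.005)
  expect_lt(ph, 0.5)
})

test_that("permutation test retains weight-specific signal", {
  ## z generated along the weight direction: the observed concentration is
  ## hard to reproduce by resampling, so the gene passes
  m <- 50
  V <- arCorr(m, 0.2)
  U <- chol(V)
  pass <- vapply(1:20, function(s) {
    set.seed(s)
    w <- rnorm(m)
    quad <- drop(crossprod(w, V %*% w))
    z <- 8 * drop(V %*% w) / sqrt(quad) + drop(crossprod(U, rnorm(m)))
    loc <- harmonizedLocus("g", paste0("s", 1:m), z, w, V)
    permutationTest(loc, twasZ(loc, 0)$z, maxPerm = 2000, seed = 100 + s,
                    ridge = 0) <= 0.05
  }, TRUE)
  expect_gte(mean(pass), 0.9)
  ## p is never exactly zero (add-one correction)
  set.seed(1)
  w <- rnorm(m)
  z <- 12 * drop(V %*% w) / sqrt(drop(crossprod(w, V %*% w)))
  loc <- harmonizedLocus("g", paste0("s", 1:m), z, w, V)
  expect_gt(permutationTest(loc, twasZ(loc, 0)$z, maxPerm = 1000, seed = 2),
            0)
})

test_that("locus grouping merges at the inclusive 100 kb boundary", {
  genes <- data.frame(
    gene_id = c("A", "B", "C"), chrom = "1",
    start = c(900000, 1100000, 5000000),
    end = c(1000000, 1200000, 5100000), stringsAsFactors = FALSE)
  ## A ends 1,000,000; B starts 1,100,000: gap exactly 100,000 -> merge
  g <- groupLoci(genes)
  expect_identical(g$locus_id[g$gene_id == "A"], g$locus_id[g$gene_id == "B"])
  expect_false(g$locus_id[g$gene_id == "C"] == g$locus_id[g$gene_id == "A"])
  ## one base further apart: separate loci
  genes$start[2] <- 1100001
  g2 <- groupLoci(genes)
  expect_false(g2$locus_id[g2$gene_id == "A"] == g2$locus_id[g2$gene_id == "B"])
  ## transitive chaining A-B and B-C merges all three
  chain <- data.frame(gene_id = c("A", "B", "C"), chrom = "2",
                      start = c(1e6, 1.15e6, 1.30e6),
                      end = c(1.1e6, 1.25e6, 1.40e6),
                      stringsAsFactors = FALSE)
  expect_identical(length(unique(groupLoci(chain)$locus_id)), 1L)
})

test_that("locus grouping partitions genes and ignores input order", {
  set.seed(8)
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:30),
    chrom = as.character(rep(1:3, each = 10)),
    start = rep(seq(1e6, by = 4e5, length.out = 10), 3),
    stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(c(5e4, 4e5), 30, replace = TRUE)
  g <- groupLoci(genes)
  expect_identical(sort(g$gene_id), sort(genes$gene_id))
  expect_true(all(table(g$gene_id) == 1))
  shuf <- genes[sample(nrow(genes)), ]
  g2 <- groupLoci(shuf)
  m <- merge(g, g2, by = "gene_id")
  ## same partition: co-membership is preserved
  same1 <- outer(m$locus_id.x, m$locus_id.x, "==")
  same2 <- outer(m$locus_id.y, m$locus_id.y, "==")
  expect_identical(same1, same2)
})

test_that("predicted-expression correlation follows the quadratic form", {
  V <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(geneCorrelation(c(1, 0), c(0, 1), V, ridge = 0), 0.5)
  expect_equal(geneCorrelation(c(0.3, -0.2), c(0.3, -0.2), arCorr(2, 0.4)), 1)
  expect_equal(geneCorrelation(c(1, 0), c(0, 1), diag(2), ridge = 0), 0)
  expect_error(geneCorrelation(c(0, 0), c(1, 0), diag(2)), "variance")
})

test_that("joint-conditional selection matches MVN conditioning arithmetic", {
  ## single-gene locus: leading with joint = marginal
  S1 <- matrix(1, dimnames = list("A", "A"))
  r1 <- jointConditionalSelect(S1, c(A = 4.2), nSigOnChrom = 1)
  expect_identical(r1$status, "leading")
  expect_equal(r1$joint_z, 4.2)
  ## orthogonal pair: both leading, joint equals marginal
  S2 <- diag(2); dimnames(S2) <- list(c("A", "B"), c("A", "B"))
  r2 <- jointConditionalSelect(S2, c(A = 5, B = 4.5), nSigOnChrom = 2)
  expect_identical(unname(r2$status), c("leading", "leading"))
  expect_equal(r2$joint_z, c(5, 4.5))
  ## causal + passenger at Sigma = 0.8: hand-computed conditional z is
  ## (6.4 - 0.8 * 8) / sqrt(1 - 0.64) = 0 -> passenger is "conditional"
  S3 <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  r3 <- jointConditionalSelect(S3, c(A = 8, B = 6.4), nSigOnChrom = 2)
  expect_identical(r3$status[r3$gene_id == "A"], "leading")
  expect_identical(r3$status[r3$gene_id == "B"], "conditional")
  expect_equal(r3$cond_z[r3$gene_id == "B"], 0, tolerance = 1e-12)
  ## three genes, hand-computed two-step conditioning
  S4 <- matrix(c(1, 0.5, 0.2,
                 0.5, 1, 0.1,
                 0.2, 0.1, 1), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  zm <- c(A = 9, B = 4, C = 6)
  r4 <- jointConditionalSelect(S4, zm, nSigOnChrom = 3)
  ## seed = A; cond z for C given A = (6 - 0.2*9)/sqrt(1-0.04)
  condC <- (6 - 0.2 * 9) / sqrt(1 - 0.04)
  expect_identical(r4$status[r4$gene_id == "C"], "leading")
  expect_identical(r4$status[r4$gene_id == "B"], "conditional")
  selected <- c("A", "C")
  inv <- solve(S4[selected, selected])
  b <- drop(inv %*% zm[selected])
  expect_equal(r4$joint_z[match(selected, r4$gene_id)],
               unname(b / sqrt(diag(inv))))
  ## the remaining gene's conditional p is above the Bonferroni threshold
  expect_gte(r4$cond_p[r4$gene_id == "B"], 0.05 / 3)
})

test_that("near-duplicate genes are flagged correlated, not selected", {
  S <- matrix(c(1, 0.995, 0.2,
                0.995, 1, 0.2,
                0.2, 0.2, 1), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  r <- jointConditionalSelect(S, c(A = 8, B = 7.9, C = 6), nSigOnChrom = 3)
  expect_identical(r$status[r$gene_id == "A"], "leading")
  expect_identical(r$status[r$gene_id == "B"], "correlated")
  expect_identical(r$status[r$gene_id == "C"], "leading")
})

test_that("causal genes lead their loci over correlated passengers", {
  acc <- vapply(1:10, function(s) {
    loci <- simulatePassengerLoci(nLoci = 10, rhoGene = 0.8, alpha = 7,
                                  seed = 200 + s)
    mean(vapply(loci, function(l) {
      rep <- jointConditionalSelect(l$Sigma, l$zTwas, nSigOnChrom = 3)
      rep$status[rep$gene_id == l$causal] == "leading"
    }, TRUE))
  }, 0)
  expect_gte(mean(acc), 0.85)
})

test_that("GWAS conditioning removes mediated signal and nothing else", {
  ## fully mediated: single gene, single weighted SNP, identity LD
  m <- 5
  z <- c(4, 0.5, -0.2, 0.1, 0)
  W <- matrix(0, m, 1); W[1, 1] <- 1
  res <- gwasConditional(z, diag(m), W, ridge = 0)
  expect_identical(res$residual[1], 0)
  expect_equal(res$residual[-1], z[-1])
  expect_equal(res$proportionExplained, 1)
  expect_identical(res$leadSnp, 1L)
  ## orthogonal selection: gene weight sits on a zero-Z SNP
  z2 <- c(3, 2, 0, 1, -1)
  W2 <- matrix(0, m, 1); W2[3, 1] <- 1
  res2 <- gwasConditional(z2, diag(m), W2, ridge = 0)
  expect_equal(res2$residual[-3], z2[-3])
  expect_equal(res2$proportionExplained, 0)
  ## empty selection is the identity
  res3 <- gwasConditional(z2, diag(m), NULL)
  expect_identical(res3$residual, z2)
  expect_identical(res3$proportionExplained, 0)
})

test_that("mediated simulations yield high proportion of signal explained", {
  props <- vapply(1:20, function(s) {
    set.seed(700 + s)
    m <- 30
    R <- arCorr(m, 0.4)
    w <- rnorm(m) * rbinom(m, 1, 0.4)
    if (all(w == 0)) w[5] <- 1
    cvec <- drop(R %*% w) / sqrt(drop(crossprod(w, R %*% w)))
    z <- 8 * cvec + drop(crossprod(chol(R), rnorm(m)))
    gwasConditional(z, R, matrix(w, ncol = 1), ridge = 0)$proportionExplained
  }, 0)
  expect_gte(median(props), 0.8)
})
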