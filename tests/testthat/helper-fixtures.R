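# shared fixtures and independent oracles used across test files

# draw n samples from MVN(0, V) via Cholesky
mvnDraw <- function(n, V) {
  matrix(rnorm(n * nrow(V)), n) %*% chol(V)
}

arCorr <- function(m, rho) rho ^ abs(outer(seq_len(m), seq_len(m), "-"))

# plain-arithmetic TWAS statistic (no classes, no ridge machinery)
directTwas <- function(w, z, V) {
  drop(t(w) %*% z) / sqrt(drop(t(w) %*% V %*% w))
}

# independent brute-force oracle for the TWAS correlation test: simulate
# individual-level data at large n from the same LD, build a trait whose
# marginal SNP z-statistics match z, and average the standardized
# correlation statistic between predicted expression and the trait over
# replicates (Monte-Carlo error ~ 1/sqrt(reps))
bruteForceTwas <- function(w, z, V, n = 2000L, reps = 400L) {
  a <- solve(V, z) / sqrt(n)
  veps <- 1 - drop(t(a) %*% V %*% a)
  stopifnot(veps > 0)
  mean(vapply(seq_len(reps), function(r) {
    X <- mvnDraw(n, V)
    y <- drop(X %*% a) + rnorm(n, sd = sqrt(veps))
    g <- drop(X %*% w)
    sqrt(n) * cor(g, y)
  }, 0))
}

# exhaustive-enumeration oracle for colocalization posteriors: every causal
# configuration (none/none, i/none, none/j, i/j distinct, i/i shared) is
# enumerated explicitly with plain sums of Bayes factors
colocEnumOracle <- function(lb1, lb2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(lb1)
  B1 <- exp(lb1)
  B2 <- exp(lb2)
  L0 <- 1
  L1 <- p1 * sum(B1)
  L2 <- p2 * sum(B2)
  L3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j) L3 <- L3 + p1 * p2 * B1[i] * B2[j]
  L4 <- p12 * sum(B1 * B2)
  pp <- c(L0, L1, L2, L3, L4) / (L0 + L1 + L2 + L3 + L4)
  names(pp) <- paste0("pp", 0:4)
  pp
}

# tiny reference panel with known allele codings for harmonization tests
tinyPanel <- function(n = 80L, seed = 7L) {
  set.seed(seed)
  f <- c(0.5, 0.3, 0.4, 0.3)
  G <- sapply(f, function(p) rbinom(n, 2L, p))
  while (any(apply(G, 2, sd) == 0))
    G <- sapply(f, function(p) rbinom(n, 2L, p))
  snps <- data.frame(
    snp_id = paste0("rs", 1:4), chrom = "1",
    pos = c(100L, 200L, 300L, 400L),
    a1 = c("A", "C", "A", "T"), a2 = c("G", "T", "G", "A"),
    maf = colMeans(G) / 2, stringsAsFactors = FALSE)
  colnames(G) <- snps$snp_id
  list(genotypes = G, snps = snps)
}

# a candidate model with controllable filter metadata
mkModel <- function(panel = "testis", cvR2 = 0.2, cvP = 1e-4, h2P = 1e-3,
                    gene = "g1", weight = 0.5) {
  weightModel(gene,
              data.frame(snp_id = "rs1", a1 = "A", a2 = "G",
                         weight = weight, stringsAsFactors = FALSE),
              panel = panel, cvR2 = cvR2, cvP = cvP, h2P = h2P)
}
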