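## numerically stable log-sum-exp
.lse <- function(x) {
  x <- x[!is.na(x)]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a >= b; -Inf when the difference underflows
.logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

## FUSION-style shrinkage of an LD correlation matrix
.ridgeV <- function(V, ridge) {
  if (ridge <= 0) return(V)
  (1 - ridge) * V + ridge * diag(nrow(V))
}

.twoSidedP <- function(z) 2 * pnorm(-abs(z))

## deterministic per-stage / per-gene child seeds from one global seed
## (Lehmer step keeps everything inside the 32-bit integer range)
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 997 + 12345) %%
               2147483587) + 1L
}

## Genotype-scale correlation implied by a Gaussian copula with latent
## correlation r thresholded to Hardy-Weinberg dosages at frequencies f1, f2.
## g = 1{z > qnorm((1-f)^2)} + 1{z > qnorm(1-f^2)} is Binomial(2, f), so
## E[g1 g2] is a sum of four bivariate-normal orthant probabilities, each
## reduced to a 1-D integral.
.dosageCorr <- function(r, f1, f2) {
  th <- function(f) qnorm(c((1 - f) ^ 2, 1 - f ^ 2))
  t1 <- th(f1)
  t2 <- th(f2)
  orthant <- function(s, t) {
    stats::integrate(function(u)
      stats::dnorm(u) * pnorm((t - r * u) / sqrt(1 - r ^ 2),
                              lower.tail = FALSE),
      s, Inf, rel.tol = 1e-9, abs.tol = 1e-12)$value
  }
  e12 <- sum(vapply(t1, function(s)
    vapply(t2, function(t) orthant(s, t), 0), numeric(2)))
  (e12 - 4 * f1 * f2) / sqrt(4 * f1 * (1 - f1) * f2 * (1 - f2))
}

## Latent copula correlation needed so the *dosage* correlation hits rho;
## thresholding attenuates correlation, so the latent value is inflated by
## numerical inversion (capped where rho is unattainable for the MAF pair).
## Memoized on a rounded MAF grid for speed.
.latentCache <- new.env(parent = emptyenv())
.latentCorr <- function(rho, f1, f2) {
  if (rho <= 0) return(0)
  f1 <- round(f1, 2)
  f2 <- round(f2, 2)
  key <- paste(rho, min(f1, f2), max(f1, f2))
  hit <- .latentCache[[key]]
  if (!is.null(hit)) return(hit)
  upper <- 0.9995
  val <- if (.dosageCorr(upper, f1, f2) <= rho) upper else
    stats::uniroot(function(r) .dosageCorr(r, f1, f2) - rho,
                   c(1e-4, upper), tol = 1e-4)$root
  .latentCache[[key]] <- val
  val
}

## sample correlation with a guard for zero-variance columns
.panelCor <- function(G) {
  sds <- apply(G, 2, sd)
  if (any(sds == 0))
    stop("monomorphic SNP in reference panel: cannot estimate LD")
  V <- cor(G)
  dimnames(V) <- NULL
  V
}
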