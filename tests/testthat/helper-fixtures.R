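# shared fixtures, built in code

smallCohort <- function(seed, nSamples = 60, nGenes = 100, ...) {
  simulateLPDCohort(lpdSimControl(nSamples = nSamples,
                                  nGenes = nGenes, seed = seed, ...))
}

# hand-built model without reference quantiles
makeModel <- function(mu, sigma2, alpha,
                      priorMode = "uniform") {
  G <- nrow(mu); K <- ncol(mu)
  new("LPDModel", K = as.integer(K),
      geneIds = sprintf("g%04d", seq_len(G)),
      mu = unname(mu), sigma2 = unname(sigma2), alpha = alpha,
      priorMode = priorMode, referenceQuantiles = matrix(0, 0, 0),
      signatureLabels = paste0("sig", seq_len(K)),
      fitMeta = list())
}

namedMatrix <- function(values, G, A) {
  matrix(values, G, A, dimnames = list(sprintf("g%04d", seq_len(G)),
                                       sprintf("s%04d", seq_len(A))))
}

# independent oracle: log evidence of a single sample under a K = 2
# model, by numerical integration over the 1-d mixing simplex
logEvidenceK2 <- function(e, mu, sigma2, alpha) {
  f <- function(t) vapply(t, function(tt) {
    stats::dbeta(tt, alpha[1], alpha[2]) *
      prod(tt * stats::dnorm(e, mu[, 1], sqrt(sigma2[, 1])) +
             (1 - tt) * stats::dnorm(e, mu[, 2], sqrt(sigma2[, 2])))
  }, numeric(1))
  log(stats::integrate(f, 0, 1, rel.tol = 1e-10)$value)
}

# align fitted signatures to the truth by mu-column correlation
alignToTruth <- function(fit, truth) {
  apply(cor(signatureMeans(fit), truth$mu), 2, which.max)
}
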