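#' Configuration of the synthetic cohort generator
#'
#' Defines the generative model the decomposition assumes: per-sample
#' Dirichlet mixing weights over K expression signatures, a per-gene
#' categorical signature draw followed by a Gaussian emission, survival
#' times whose log-hazard is linear in one planted risk signature's
#' proportion, and a binary genomic feature whose frequency depends on
#' the dominant signature.
#'
#' Defaults emulate a prostatectomy expression cohort: sparse Dirichlet
#' mixing (`alpha = 0.1` per signature) so that roughly half the cohort
#' carries a near-zero proportion of any given signature, matching the
#' skewed per-sample DESNT distributions seen in real decompositions;
#' 30\% of genes carry a 2-standard-deviation mean offset in one
#' signature; 30\% of subjects are censored.
#'
#' @param nSamples,nGenes,nSignatures cohort dimensions.
#' @param alpha Dirichlet concentration, K strictly positive reals.
#' @param effectGeneFraction fraction of genes whose mean differs
#'   between signatures, in (0, 1].
#' @param effectSize mean offset for effect genes, in units of the
#'   gene's emission standard deviation.
#' @param sigmaRange range from which per-gene emission standard
#'   deviations are drawn (variances uniform on `sigmaRange^2`).
#' @param riskSignature index of the planted poor-prognosis ("DESNT")
#'   signature.
#' @param baselineHazard exponential event rate per month at zero risk
#'   proportion.
#' @param logHazardRatio log hazard ratio per unit risk-signature
#'   proportion.
#' @param censoringRate target censored fraction in [0, 1).
#' @param labelFrequencies per-signature Bernoulli frequency of the
#'   binary genomic feature (e.g. ERG status).
#' @param seed integer seed; `NULL` uses the session RNG.
#' @return a list of class `lpdSimControl`.
#' @export
lpdSimControl <- function(nSamples = 150L, nGenes = 300L,
                          nSignatures = 4L,
                          alpha = rep(0.1, nSignatures),
                          effectGeneFraction = 0.3, effectSize = 2,
                          sigmaRange = c(0.5, 1.5),
                          riskSignature = 1L,
                          baselineHazard = 0.02,
                          logHazardRatio = log(2),
                          censoringRate = 0.3,
                          labelFrequencies = ifelse(
                            seq_len(nSignatures) == riskSignature,
                            0.7, 0.3),
                          seed = NULL) {
  stopifnot(nSamples >= 1, nGenes >= 1, nSignatures >= 1,
            length(alpha) == nSignatures, all(alpha > 0),
            effectGeneFraction >= 0, effectGeneFraction <= 1,
            effectSize >= 0,
            length(sigmaRange) == 2, all(sigmaRange > 0),
            sigmaRange[1] <= sigmaRange[2],
            riskSignature >= 1, riskSignature <= nSignatures,
            baselineHazard > 0,
            censoringRate >= 0,
            length(labelFrequencies) == nSignatures,
            all(labelFrequencies >= 0), all(labelFrequencies <= 1))
  if (censoringRate >= 1) stop("censoringRate must be < 1")
  if (effectGeneFraction == 0 && effectSize > 0)
    warning("effectGeneFraction = 0: effectSize > 0 has no genes to act on")
  structure(list(nSamples = as.integer(nSamples),
                 nGenes = as.integer(nGenes),
                 nSignatures = as.integer(nSignatures), alpha = alpha,
                 effectGeneFraction = effectGeneFraction,
                 effectSize = effectSize, sigmaRange = sigmaRange,
                 riskSignature = as.integer(riskSignature),
                 baselineHazard = baselineHazard,
                 logHazardRatio = logHazardRatio,
                 censoringRate = censoringRate,
                 labelFrequencies = labelFrequencies, seed = seed),
            class = "lpdSimControl")
}

.geneIds <- function(G) sprintf("g%04d", seq_len(G))
.sampleIds <- function(A) sprintf("s%04d", seq_len(A))

#' Draw per-gene, per-signature emission parameters
#'
#' Baseline gene means are drawn once (Normal(7, 1.5^2), a typical
#' log-intensity scale); a per-gene emission variance is drawn uniformly
#' on `sigmaRange^2` and shared across signatures. For each of the
#' `ceiling(effectGeneFraction * nGenes)` effect genes, one randomly
#' chosen signature's mean is offset by `effectSize * sigma_g`.
#'
#' @param control an [lpdSimControl()] object.
#' @param seed overrides `control$seed` when given.
#' @return list with G x K matrices `mu` and `sigma2`, and the index
#'   vector `effectGenes`.
#' @export
simulateSignatureParams <- function(control, seed = control$seed) {
  G <- control$nGenes; K <- control$nSignatures
  .withSeed(seed, {
    base <- rnorm(G, mean = 7, sd = 1.5)
    s2 <- runif(G, control$sigmaRange[1]^2, control$sigmaRange[2]^2)
    mu <- matrix(base, G, K)
    nEff <- ceiling(control$effectGeneFraction * G)
    eff <- integer(0)
    if (nEff > 0 && control$effectSize > 0) {
      eff <- sort(sample.int(G, nEff))
      kk <- sample.int(K, nEff, replace = TRUE)
      mu[cbind(eff, kk)] <- mu[cbind(eff, kk)] +
        control$effectSize * sqrt(s2[eff])
    }
    sigma2 <- matrix(s2, G, K)
    dimnames(mu) <- dimnames(sigma2) <-
      list(.geneIds(G), paste0("sig", seq_len(K)))
    list(mu = mu, sigma2 = sigma2, effectGenes = eff)
  })
}

#' Draw per-sample Dirichlet mixing proportions
#'
#' @param control an [lpdSimControl()] object.
#' @param seed overrides `control$seed` when given.
#' @return A x K matrix whose rows sum to 1.
#' @export
simulateMixingProportions <- function(control, seed = control$seed) {
  A <- control$nSamples; K <- control$nSignatures
  .withSeed(seed, {
    g <- matrix(rgamma(A * K, shape = rep(control$alpha, each = A)),
                A, K)
    theta <- g / rowSums(g)
    dimnames(theta) <- list(.sampleIds(A), paste0("sig", seq_len(K)))
    theta
  })
}

#' Draw an expression matrix from the mixed-membership model
#'
#' For each sample a and gene g, a signature `z[g, a]` is drawn from
#' Categorical(theta[a, ]) and the value from
#' Normal(mu[g, z], sigma2[g, z]).
#'
#' @param theta A x K mixing proportions (rows sum to 1).
#' @param mu,sigma2 G x K emission parameter matrices.
#' @param seed integer seed or `NULL`.
#' @return list with `expression` (G x A matrix, genes in rows) and the
#'   latent assignment matrix `z` (G x A, entries in 1..K).
#' @export
simulateExpression <- function(theta, mu, sigma2, seed = NULL) {
  stopifnot(ncol(theta) == ncol(mu), all(dim(mu) == dim(sigma2)))
  if (any(sigma2 <= 0)) stop("emission variances must be positive")
  G <- nrow(mu); A <- nrow(theta); K <- ncol(mu)
  .withSeed(seed, {
    z <- matrix(0L, G, A)
    x <- matrix(0, G, A)
    sdm <- sqrt(sigma2)
    for (a in seq_len(A)) {
      za <- sample.int(K, G, replace = TRUE, prob = theta[a, ])
      idx <- cbind(seq_len(G), za)
      x[, a] <- rnorm(G, mean = mu[idx], sd = sdm[idx])
      z[, a] <- za
    }
    gid <- rownames(mu); if (is.null(gid)) gid <- .geneIds(G)
    sid <- rownames(theta); if (is.null(sid)) sid <- .sampleIds(A)
    dimnames(x) <- dimnames(z) <- list(gid, sid)
    list(expression = x, z = z)
  })
}

# expected censored fraction with C ~ U(0, tmax), T ~ Exp(rate)
.censFraction <- function(tmax, rates) {
  mean((1 - exp(-rates * tmax)) / (rates * tmax))
}

#' Draw survival outcomes and clinical covariates
#'
#' Event times are exponential with rate
#' `baselineHazard * exp(logHazardRatio * theta[, riskSignature])`.
#' Censoring times are uniform on (0, Tmax), with Tmax solved
#' numerically so that the expected censored fraction matches
#' `censoringRate`. Gleason, PSA, stage and surgical-margin covariates
#' are drawn independently of theta unless `gleasonAssociation` is
#' non-zero, in which case the Gleason category distribution is tilted
#' by the risk proportion to stress-test confounding.
#'
#' @param theta A x K mixing proportions.
#' @param control an [lpdSimControl()] object.
#' @param gleasonAssociation ordinal log-odds shift toward higher
#'   Gleason per unit risk proportion (default 0 = independent).
#' @param seed overrides `control$seed` when given.
#' @return a clinical `data.frame` (sample_id, time in months, event,
#'   gleason, psa, stage, margins).
#' @export
simulateSurvival <- function(theta, control, gleasonAssociation = 0,
                             seed = control$seed) {
  if (control$censoringRate >= 1) stop("censoringRate must be < 1")
  A <- nrow(theta)
  risk <- theta[, control$riskSignature]
  rates <- control$baselineHazard * exp(control$logHazardRatio * risk)
  .withSeed(seed, {
    tEvent <- rexp(A, rate = rates)
    if (control$censoringRate == 0) {
      time <- tEvent; event <- rep(1L, A)
    } else {
      f <- function(tm) .censFraction(tm, rates) - control$censoringRate
      tmax <- uniroot(f, lower = 1e-8 / control$baselineHazard,
                      upper = 1e6 / control$baselineHazard,
                      tol = 1e-10)$root
      cens <- runif(A, 0, tmax)
      event <- as.integer(tEvent <= cens)
      time <- pmin(tEvent, cens)
    }
    glev <- c("lt7", "3+4", "4+3", "gt7")
    base <- c(0.35, 0.35, 0.18, 0.12)
    if (gleasonAssociation == 0) {
      gleason <- sample(glev, A, replace = TRUE, prob = base)
    } else {
      cuts <- qlogis(cumsum(base)[1:3])
      lp <- gleasonAssociation * risk
      u <- runif(A)
      gleason <- vapply(seq_len(A), function(i) {
        p <- plogis(cuts - lp[i])
        glev[findInterval(u[i], c(p, 1), rightmost.closed = TRUE) + 1L]
      }, character(1))
    }
    sid <- rownames(theta); if (is.null(sid)) sid <- .sampleIds(A)
    data.frame(sample_id = sid, time = time, event = event,
               gleason = factor(gleason, levels = glev),
               psa = rlnorm(A, meanlog = log(8), sdlog = 0.6),
               stage = factor(sample(c("T1-T2", "T3-T4"), A,
                                     replace = TRUE, prob = c(0.6, 0.4)),
                              levels = c("T1-T2", "T3-T4")),
               margins = rbinom(A, 1, 0.35),
               row.names = NULL)
  })
}

#' Draw a binary genomic feature from signature-dependent frequencies
#'
#' @param dominant per-sample dominant-signature index (argmax of the
#'   true mixing proportions).
#' @param labelFrequencies per-signature Bernoulli frequency.
#' @param seed integer seed or `NULL`.
#' @return integer 0/1 vector.
#' @export
simulateFeatureLabels <- function(dominant, labelFrequencies,
                                  seed = NULL) {
  stopifnot(all(dominant >= 1), all(dominant <= length(labelFrequencies)),
            all(labelFrequencies >= 0), all(labelFrequencies <= 1))
  .withSeed(seed, rbinom(length(dominant), 1, labelFrequencies[dominant]))
}

#' Generate a complete synthetic cohort with ground truth
#'
#' One call to the full generative model: emission parameters, mixing
#' proportions, expression, survival outcomes with clinical covariates,
#' and a binary genomic feature.
#'
#' @param control an [lpdSimControl()] object.
#' @return list with `expression` (G x A matrix), `clinical`
#'   (data.frame, including the binary `label` column) and `truth`
#'   (theta, z, mu, sigma2, effectGenes, plantedLogHR, control).
#' @examples
#' cohort <- simulateLPDCohort(lpdSimControl(nSamples = 40, nGenes = 60,
#'                                           seed = 1))
#' dim(cohort$expression)
#' head(cohort$clinical)
#' @export
simulateLPDCohort <- function(control = lpdSimControl()) {
  seeds <- if (is.null(control$seed)) rep(list(NULL), 4)
           else as.list(.deriveSeeds(control$seed, 4))
  par <- simulateSignatureParams(control, seed = seeds[[1]])
  theta <- simulateMixingProportions(control, seed = seeds[[2]])
  expr <- simulateExpression(theta, par$mu, par$sigma2, seed = seeds[[3]])
  dominant <- apply(theta, 1, which.max)
  .withSeed(seeds[[4]], {
    clinical <- simulateSurvival(theta, control, seed = NULL)
    clinical$label <- simulateFeatureLabels(dominant,
                                            control$labelFrequencies,
                                            seed = NULL)
    list(expression = expr$expression, clinical = clinical,
         truth = list(theta = theta, z = expr$z, mu = par$mu,
                      sigma2 = par$sigma2,
                      effectGenes = par$effectGenes,
                      plantedLogHR = control$logHazardRatio,
                      control = control))
  })
}
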