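test_that("E-step handles the single-signature and symmetric cases", {
  G <- 10; A <- 4
  x <- namedMatrix(rnorm(G * A), G, A)
  m1 <- makeModel(matrix(rowMeans(x), G, 1),
                  matrix(1, G, 1), alpha = 2)
  es <- lpdEStep(x, m1)
  expect_true(all(es$Q == 1))
  expect_equal(unname(es$gamma[, 1]), rep(2 + G, A), tolerance = 1e-12)

  # identical emission columns + symmetric start stay symmetric
  mu <- matrix(rowMeans(x), G, 2)
  m2 <- makeModel(mu, matrix(1, G, 2), alpha = c(1, 1))
  es2 <- lpdEStep(x, m2)
  expect_equal(max(abs(es2$Q - 0.5)), 0, tolerance = 1e-12)
  expect_equal(es2$gamma[, 1], es2$gamma[, 2], tolerance = 1e-12)
})

test_that("one E-step sweep matches the hand-evaluated update", {
  # G = 1, K = 2: Q proportional to N(e; mu, s2) exp(digamma(gamma0))
  e <- 0.4
  mu <- matrix(c(0, 1), 1, 2)
  s2 <- matrix(c(1, 0.25), 1, 2)
  alpha <- c(0.5, 1.5)
  g0 <- matrix(c(2, 3), 1, 2)
  m <- makeModel(mu, s2, alpha)
  x <- matrix(e, 1, 1, dimnames = list("g0001", "s1"))
  es <- lpdEStep(x, m, gammaInit = g0, maxInner = 1, tol = 0)
  w <- dnorm(e, mu[1, ], sqrt(s2[1, ])) * exp(digamma(g0[1, ]))
  qExp <- w / sum(w)
  expect_equal(as.numeric(es$Q[1, 1, ]), qExp, tolerance = 1e-12)
  expect_equal(as.numeric(es$gamma), alpha + qExp, tolerance = 1e-12)
})

test_that("E-step additive identity holds for every sample", {
  for (s in 1:3) {
    sim <- smallCohort(seed = s, nSignatures = 3)
    fit <- suppressWarnings(fitLPD(sim$expression, K = 3,
                                   control = lpdFitControl(seed = s)))
    g <- posteriorGamma(fit)
    expect_equal(unname(rowSums(g)),
                 rep(sum(dirichletAlpha(fit)) + nrow(sim$expression),
                     ncol(sim$expression)),
                 tolerance = 1e-8)
    th <- signatureProportions(fit)
    expect_equal(unname(rowSums(th)), rep(1, nrow(th)),
                 tolerance = 1e-9)
  }
})

test_that("M-step computes responsibility-weighted moments", {
  x <- matrix(c(1, 2, 3), 1, 3,
              dimnames = list("g0001", paste0("s", 1:3)))
  Q <- array(0, c(1, 3, 2))
  Q[1, , 1] <- c(0.2, 0.3, 0.5)
  Q[1, , 2] <- 1 - Q[1, , 1]
  ms <- lpdMStep(x, Q)
  expect_equal(unname(ms$mu[1, 1]), 2.3, tolerance = 1e-12)
  # weighted variance about the weighted mean
  expect_equal(unname(ms$sigma2[1, 1]),
               sum(c(0.2, 0.3, 0.5) * (c(1, 2, 3) - 2.3)^2),
               tolerance = 1e-12)

  # uniform single-signature responsibilities give plain moments
  Q1 <- array(1, c(1, 3, 1))
  ms1 <- lpdMStep(x, Q1)
  expect_equal(unname(ms1$mu[1, 1]), 2)
  expect_equal(unname(ms1$sigma2[1, 1]), 2 / 3)  # population variance

  # symmetric halves give the gene mean in both columns
  Qh <- array(0.5, c(1, 3, 2))
  msh <- lpdMStep(x, Qh)
  expect_equal(unname(msh$mu[1, ]), c(2, 2))
})

test_that("alpha estimation preserves symmetry and recovers truth", {
  # symmetric gamma rows leave alpha symmetric
  g <- matrix(5, 40, 2)
  a <- estimateDirichletAlpha(g, c(1, 1))
  expect_equal(a[1], a[2], tolerance = 1e-10)

  # moment consistency: gamma concentrated at theta ~ Dirichlet(2, 5)
  set.seed(8)
  A <- 5000
  th <- cbind(rgamma(A, 2), rgamma(A, 5))
  th <- th / rowSums(th)
  ahat <- estimateDirichletAlpha(1e4 * th, c(1, 1))
  expect_lt(max(abs(ahat / c(2, 5) - 1)), 0.10)
})

test_that("variational bound has the K = 1 closed form and symmetry", {
  G <- 6; A <- 5
  x <- namedMatrix(rnorm(G * A, 3), G, A)
  m <- makeModel(matrix(rowMeans(x), G, 1),
                 matrix(1.3, G, 1), alpha = 1)
  es <- lpdEStep(x, m)
  b <- variationalBound(x, m, es$Q, es$gamma)
  closed <- sum(dnorm(x, rowMeans(x), sqrt(1.3), log = TRUE))
  expect_equal(b, closed, tolerance = 1e-9)

  # label-permutation symmetry
  sim <- smallCohort(seed = 4, nSignatures = 3)
  fit <- suppressWarnings(fitLPD(sim$expression, K = 3,
                                 control = lpdFitControl(seed = 4)))
  m0 <- lpdModel(fit)
  perm <- c(3, 1, 2)
  mp <- makeModel(signatureMeans(m0)[, perm],
                  signatureVariances(m0)[, perm],
                  dirichletAlpha(m0)[perm])
  dec <- decomposition(fit)
  b1 <- variationalBound(sim$expression, m0, dec@Q, dec@gamma)
  b2 <- variationalBound(sim$expression, mp,
                         dec@Q[, , perm], dec@gamma[, perm])
  expect_equal(b1, b2, tolerance = 1e-8)
  expect_equal(holdoutLogLik(sim$expression, m0),
               holdoutLogLik(sim$expression, mp), tolerance = 1e-6)
})

test_that("bound and hold-out likelihood agree with the quadrature oracle", {
  # the bound never exceeds the log evidence, whatever the prior
  set.seed(17)
  for (rep in 1:10) {
    G <- sample(1:2, 1)
    mu <- matrix(rnorm(G * 2, 0, 2), G, 2)
    s2 <- matrix(runif(G * 2, 0.3, 2), G, 2)
    alpha <- runif(2, 0.4, 3)
    e <- rnorm(G, mean = rowMeans(mu), sd = 1)
    m <- makeModel(mu, s2, alpha)
    x <- matrix(e, G, 1, dimnames = list(sprintf("g%04d", seq_len(G)),
                                         "s1"))
    logZ <- logEvidenceK2(e, mu, s2, alpha)
    es <- lpdEStep(x, m, maxInner = 2000, tol = 1e-10)
    b <- variationalBound(x, m, es$Q, es$gamma)
    expect_lte(b, logZ + 1e-8)
  }

  # the plug-in predictive equals the marginal likelihood when the
  # mixing posterior is concentrated (see the vignette for why the two
  # differ by up to log K under a diffuse prior at G <= 2)
  set.seed(18)
  for (rep in 1:10) {
    G <- sample(1:2, 1)
    mu <- matrix(rnorm(G * 2, 0, 1.5), G, 2)
    s2 <- matrix(runif(G * 2, 0.5, 2), G, 2)
    alpha <- runif(2, 20, 50)
    t1 <- rbeta(1, alpha[1], alpha[2])
    z <- rbinom(G, 1, 1 - t1) + 1
    e <- rnorm(G, mu[cbind(seq_len(G), z)],
               sqrt(s2[cbind(seq_len(G), z)]))
    m <- makeModel(mu, s2, alpha)
    x <- matrix(e, G, 1, dimnames = list(sprintf("g%04d", seq_len(G)),
                                         "s1"))
    expect_lt(abs(holdoutLogLik(x, m) - logEvidenceK2(e, mu, s2,
                                                      alpha)), 0.1)
  }
})

test_that("fitting K = 1 returns gene moments and unit proportions", {
  sim <- smallCohort(seed = 6)
  x <- sim$expression
  fit <- fitLPD(x, K = 1, control = lpdFitControl(seed = 6))
  expect_equal(unname(signatureMeans(fit)[, 1]), unname(rowMeans(x)),
               tolerance = 1e-8)
  A <- ncol(x)
  popVar <- rowSums((x - rowMeans(x))^2) / A
  expect_equal(unname(signatureVariances(fit)[, 1]), unname(popVar),
               tolerance = 1e-8)
  expect_true(all(signatureProportions(fit) == 1))
})

test_that("hold-out log-likelihood behaves like a likelihood", {
  sim <- smallCohort(seed = 7)
  x <- sim$expression
  m1 <- lpdModel(fitLPD(x, K = 1, control = lpdFitControl(seed = 7)))
  closed <- mean(colSums(dnorm(x, signatureMeans(m1)[, 1],
                               sqrt(signatureVariances(m1)[, 1]),
                               log = TRUE)))
  expect_equal(holdoutLogLik(x, m1), closed, tolerance = 1e-9)

  fit <- suppressWarnings(fitLPD(x, K = 3, priorMode = "estimated",
                                 control = lpdFitControl(seed = 7)))
  m <- lpdModel(fit)
  # data drawn from the fitted model itself
  set.seed(71)
  thNew <- simulateMixingProportions(
    lpdSimControl(nSamples = 40, nGenes = nrow(x), nSignatures = 3,
                  alpha = pmax(dirichletAlpha(m), 0.05)), seed = 72)
  xNew <- simulateExpression(thNew, signatureMeans(m),
                             signatureVariances(m), seed = 73)$expression
  rownames(xNew) <- rownames(x)
  inflated <- makeModel(signatureMeans(m),
                        10 * signatureVariances(m), dirichletAlpha(m))
  inflated@geneIds <- m@geneIds
  expect_lt(holdoutLogLik(xNew, inflated), holdoutLogLik(xNew, m))
})

test_that("selectK handles a singleton range and bad folds", {
  sim <- smallCohort(seed = 8, nSamples = 30, nGenes = 60)
  sk <- selectK(sim$expression, kRange = 3, nFolds = 3,
                priorModes = "uniform",
                control = lpdFitControl(maxIterations = 30,
                                        tolerance = 1e-4, seed = 8))
  expect_identical(sk$K, 3L)
  expect_identical(nrow(sk$table), 1L)
  expect_error(selectK(sim$expression, 2:3, nFolds = 30,
                       control = lpdFitControl(seed = 1)),
               "fewer than 2")
})

test_that("restart ensembles are deterministic under the master seed", {
  sim <- smallCohort(seed = 9, nSamples = 30, nGenes = 50)
  ctl <- lpdFitControl(maxIterations = 60, tolerance = 1e-5)
  e1 <- fitLPDRestarts(sim$expression, K = 2, nRestarts = 3,
                       control = ctl, seed = 5)
  e2 <- fitLPDRestarts(sim$expression, K = 2, nRestarts = 3,
                       control = ctl, seed = 5)
  expect_identical(ensembleBounds(e1), ensembleBounds(e2))
  expect_identical(ensembleSeeds(e1), ensembleSeeds(e2))
  expect_identical(length(e1), 3L)

  single <- fitLPDRestarts(sim$expression, K = 2, nRestarts = 1,
                           control = ctl, seed = 5)
  direct <- suppressWarnings({
    ctl2 <- ctl; ctl2$seed <- ensembleSeeds(single)[1]
    fitLPD(sim$expression, K = 2, control = ctl2)
  })
  expect_equal(ensembleBounds(single)[1], direct@decomposition@bound)
})

test_that("model serialisation round-trips bit-exactly", {
  sim <- smallCohort(seed = 10, nSamples = 30, nGenes = 40)
  fit <- suppressWarnings(fitLPD(sim$expression, K = 2,
                                 priorMode = "estimated",
                                 control = lpdFitControl(seed = 10)))
  m <- lpdModel(fit)
  signatureLabels(m) <- c("DESNT", "sig2")
  path <- tempfile(fileext = ".json")
  saveLPDModel(m, path)
  m2 <- loadLPDModel(path)
  expect_identical(m2@mu, m@mu)
  expect_identical(m2@sigma2, m@sigma2)
  expect_identical(m2@alpha, m@alpha)
  expect_identical(m2@referenceQuantiles, m@referenceQuantiles)
  expect_identical(signatureLabels(m2), c("DESNT", "sig2"))

  # invariant enforcement and corruption errors
  bad <- sub('"K":2', '"K":0', readLines(path))
  badPath <- tempfile(fileext = ".json")
  writeLines(bad, badPath)
  expect_error(loadLPDModel(badPath), "invalid K|K must")
  writeLines("{not json", badPath)
  expect_error(loadLPDModel(badPath), "corrupted")
  writeLines('{"format":"other","version":1}', badPath)
  expect_error(loadLPDModel(badPath), "not an LPDstrat model")
})
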