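test_that("signature assignment is argmax with low-index tie-break", {
  th <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0))
  rownames(th) <- c("a", "b")
  expect_warning(a <- assignSignatures(th), "tie")
  expect_identical(unname(a), c(2L, 1L))

  # well-separated synthetic signatures recover the dominant truth
  sim <- smallCohort(seed = 41, nSamples = 100, nGenes = 200,
                     effectSize = 3)
  fit <- suppressWarnings(fitLPD(sim$expression, K = 4,
                                 priorMode = "estimated",
                                 control = lpdFitControl(seed = 41)))
  perm <- alignToTruth(fit, sim$truth)
  est <- apply(signatureProportions(fit)[, perm], 1, which.max)
  truth <- apply(sim$truth$theta, 1, which.max)
  expect_gte(mean(est == truth), 0.9)
})

test_that("DESNT banding follows the published thresholds", {
  expect_identical(desntBand(c(0.0005, 0.15, 0.45, 0.7)),
                   c(1L, 2L, 3L, 4L))
  expect_identical(desntBand(c(0.001, 0.3, 0.6, 1, 0)),
                   c(2L, 3L, 4L, 4L, 1L))
  expect_error(desntBand(1.2), "\\[0, 1\\]")
  expect_error(desntBand(-0.1), "\\[0, 1\\]")

  # banding partitions any cohort
  p <- runif(500)
  expect_identical(sum(table(desntBand(p))), 500L)
})

test_that("stratification table is consistent with the decomposition", {
  sim <- smallCohort(seed = 42, nSamples = 40, nGenes = 80)
  fit <- suppressWarnings(fitLPD(sim$expression, K = 3,
                                 control = lpdFitControl(seed = 42)))
  st <- stratifyCohort(fit, desntSignature = 2)
  th <- signatureProportions(fit)
  expect_identical(st$sample_id, colnames(sim$expression))
  expect_equal(st$desnt_proportion, unname(th[, 2]))
  expect_identical(st$desnt_band, desntBand(th[, 2]))
})

test_that("representative-run selection finds the p-value mode", {
  # build an ensemble of real fits over a tiny cohort
  sim <- smallCohort(seed = 43, nSamples = 50, nGenes = 80)
  ens <- fitLPDRestarts(sim$expression, K = 3, nRestarts = 4,
                        control = lpdFitControl(maxIterations = 40,
                                                tolerance = 1e-4),
                        seed = 43)
  sel <- selectRepresentativeRun(ens, sim$clinical, desntIndex = 1)
  expect_true(sel$index %in% seq_len(4))
  # reproducibility
  sel2 <- selectRepresentativeRun(ens, sim$clinical, desntIndex = 1)
  expect_identical(sel, sel2)

  # KDE-mode oracle on a constructed p-value set
  lp <- log10(c(0.010, 0.011, 0.012, 0.5))
  d <- density(lp, bw = "nrd0")
  mode <- d$x[which.max(d$y)]
  expect_identical(which.min(abs(lp - mode)) %in% 1:3, TRUE)
})

test_that("signature labelling matches reference profiles", {
  sim <- smallCohort(seed = 44, nSamples = 40, nGenes = 120)
  fit <- suppressWarnings(fitLPD(sim$expression, K = 3,
                                 control = lpdFitControl(seed = 44)))
  m <- lpdModel(fit)
  ref <- signatureMeans(m)
  rownames(ref) <- m@geneIds
  colnames(ref) <- c("DESNT", "lpd2", "lpd3")
  lab <- labelSignatures(m, ref)
  expect_identical(as.character(lab), c("DESNT", "lpd2", "lpd3"))
  expect_equal(unname(attr(lab, "correlations")), rep(1, 3))

  # permuted reference columns are inverted
  lab2 <- labelSignatures(m, ref[, c(3, 1, 2)])
  expect_identical(as.character(lab2), c("DESNT", "lpd2", "lpd3"))

  # noisy reference still labels correctly
  set.seed(45)
  noisy <- ref + matrix(rnorm(length(ref), sd = 0.1), nrow(ref))
  expect_identical(as.character(labelSignatures(m, noisy)),
                   c("DESNT", "lpd2", "lpd3"))

  # insufficient overlap is an error
  expect_error(labelSignatures(m, ref[1:10, ]), "50%")
})

test_that("cross-cohort signature profiles correlate as expected", {
  sim <- smallCohort(seed = 46, nSamples = 60, nGenes = 100,
                     effectSize = 3)
  fit <- suppressWarnings(fitLPD(sim$expression, K = 3,
                                 priorMode = "estimated",
                                 control = lpdFitControl(seed = 46)))
  dec <- decomposition(fit)
  r <- signatureProfileCorrelation(sim$expression, dec,
                                   sim$expression, dec)
  pops <- table(factor(assignSignatures(dec), levels = 1:3))
  expect_equal(unname(r[pops > 0]), rep(1, sum(pops > 0)),
               tolerance = 1e-12)

  # symmetry between the two datasets
  sim2 <- smallCohort(seed = 47, nSamples = 60, nGenes = 100,
                      effectSize = 3)
  proj2 <- projectSamples(sim2$expression, lpdModel(fit))
  r12 <- signatureProfileCorrelation(sim$expression, dec,
                                     sim2$expression, proj2)
  r21 <- signatureProfileCorrelation(sim2$expression, proj2,
                                     sim$expression, dec)
  expect_equal(unname(r12), unname(r21), tolerance = 1e-12)
})

test_that("chi-square over-representation matches the direct formula", {
  # perfectly independent table
  asg <- rep(c(1L, 2L), c(20, 40))
  feat <- c(rep(c(1, 0), c(10, 10)), rep(c(1, 0), c(20, 20)))
  r0 <- overrepresentationTest(asg, feat, signature = 1,
                               correct = FALSE)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p.value, 1, tolerance = 1e-12)

  # [[10,20],[30,40]]: direct sum((O-E)^2/E) oracle
  asg2 <- rep(c(1L, 2L), c(30, 70))
  feat2 <- c(rep(c(1, 0), c(10, 20)), rep(c(1, 0), c(30, 40)))
  O <- matrix(c(10, 30, 20, 40), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  oracle <- sum((O - E)^2 / E)
  oracleYates <- sum((abs(O - E) - 0.5)^2 / E)
  r1 <- overrepresentationTest(asg2, feat2, 1, correct = FALSE)
  r2 <- overrepresentationTest(asg2, feat2, 1, correct = TRUE)
  expect_equal(r1$statistic, oracle, tolerance = 1e-10)
  expect_equal(r2$statistic, oracleYates, tolerance = 1e-10)
  expect_equal(round(oracle, 4), 0.7937)
  expect_equal(round(oracleYates, 4), 0.4464)

  # invariance to swapping both margins
  asgSwap <- rep(c(2L, 1L), c(30, 70))
  featSwap <- 1 - feat2
  r3 <- overrepresentationTest(asgSwap, featSwap, 2, correct = TRUE)
  expect_equal(r3$statistic, r2$statistic, tolerance = 1e-12)

  expect_error(overrepresentationTest(rep(1L, 10), rep(1, 10), 1),
               "margin")
})

test_that("planted label associations are detected with high power", {
  hits <- vapply(1:40, function(s) {
    ctl <- lpdSimControl(nSamples = 400, nSignatures = 4,
                         labelFrequencies = c(0.8, 0.2, 0.2, 0.2),
                         seed = s)
    th <- simulateMixingProportions(ctl)
    dom <- apply(th, 1, which.max)
    lab <- simulateFeatureLabels(dom, ctl$labelFrequencies,
                                 seed = s + 1000)
    overrepresentationTest(dom, lab, 1)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pathway activation scores behave on degenerate sets", {
  set.seed(48)
  x <- namedMatrix(rnorm(200), 20, 10)
  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  sets <- list(single = rownames(x)[1],
               all = rownames(x),
               tiny = rownames(x)[2])
  expect_warning(sc <- pathwayActivationScores(x, sets, minGenes = 2),
                 "dropped")
  expect_identical(colnames(sc), "all")
  sc1 <- pathwayActivationScores(x, sets["single"], minGenes = 1)
  expect_equal(unname(sc1[, 1]), unname(z[1, ]), tolerance = 1e-12)
  expect_error(pathwayActivationScores(x, list()), "empty")

  # all-zero z-scores give a zero set score
  xz <- x; xz[, ] <- rep(rnorm(20), 10)  # constant genes
  expect_equal(max(abs(pathwayActivationScores(xz, sets["all"]))), 0)
})

test_that("set ranking puts an injected DESNT surrogate first", {
  set.seed(49)
  theta <- runif(30)
  scores <- cbind(matrix(rnorm(30 * 5), 30),
                  desnt_itself = theta,
                  flat = rep(1, 30))
  colnames(scores)[1:5] <- paste0("set", 1:5)
  expect_warning(rk <- rankSetsByCorrelation(scores, theta, topN = 3),
                 "constant")
  expect_identical(rk$set[1], "desnt_itself")
  expect_equal(rk$abs_r[1], 1, tolerance = 1e-12)
  expect_warning(rankSetsByCorrelation(scores[, 1:3], theta,
                                       topN = 20), "returning all")
})

test_that("differential expression recovers planted effects and is calibrated", {
  set.seed(50)
  G <- 200; n1 <- 60; n2 <- 60
  x <- namedMatrix(rnorm(G * (n1 + n2)), G, n1 + n2)
  eff <- 1:40
  x[eff, 1:n1] <- x[eff, 1:n1] + 2          # 2 sigma shift
  asg <- rep(c(1L, 2L), c(n1, n2))
  de <- differentialExpression(x, asg, 1)
  expect_gte(mean(de$significant[eff]), 0.9)

  # BH step-up oracle
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5), tolerance = 1e-12)

  # permuted labels give (almost) no calls
  nulls <- vapply(1:60, function(s) {
    set.seed(s + 500)
    sum(differentialExpression(namedMatrix(rnorm(G * 40), G, 40),
                               sample(rep(c(1L, 2L), 20)),
                               1)$significant)
  }, numeric(1))
  expect_gte(mean(nulls == 0), 0.95)

  expect_error(differentialExpression(x, rep(c(1L, 2L), c(2, 118)), 1),
               "at least 3")

  # consensus filter across runs
  d1 <- data.frame(gene = c("a", "b"), significant = c(TRUE, TRUE))
  d2 <- data.frame(gene = c("a", "b"), significant = c(TRUE, FALSE))
  expect_identical(consensusSignificantGenes(list(d1, d2), 0.5),
                   c("a", "b"))
  expect_identical(consensusSignificantGenes(list(d1, d2), 0.9), "a")
})

test_that("GMT files round-trip through the reader", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdescA\tg1\tg2\tg3",
               "setB\tdescB\tg2\tg4"), f)
  sets <- readGMT(f)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setB, c("g2", "g4"))
  writeLines("bad\tline", f)
  expect_error(readGMT(f), "malformed")
})
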