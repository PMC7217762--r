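#' Control parameters for variational EM fitting
#'
#' @param maxIterations maximum EM iterations (default 2000).
#' @param tolerance relative change of the variational bound below
#'   which the fit is declared converged (default 1e-6).
#' @param varianceFloor lower bound on emission variances.
#' @param innerIterations maximum (Q, gamma) sweeps inside one E-step.
#' @param innerTolerance absolute gamma change below which the E-step
#'   stops.
#' @param seed integer seed controlling initialisation; `NULL` uses the
#'   session RNG.
#' @param initStrategy `"kmeans"` seeds the emission means from a
#'   k-means clustering of the samples; `"random"` perturbs the gene
#'   means.
#' @return list of class `lpdFitControl`.
#' @export
lpdFitControl <- function(maxIterations = 2000L, tolerance = 1e-6,
                          varianceFloor = 1e-6,
                          innerIterations = 25L, innerTolerance = 1e-3,
                          seed = NULL,
                          initStrategy = c("kmeans", "random")) {
  stopifnot(maxIterations >= 1, tolerance > 0, varianceFloor > 0,
            innerIterations >= 1, innerTolerance > 0)
  structure(list(maxIterations = as.integer(maxIterations),
                 tolerance = tolerance, varianceFloor = varianceFloor,
                 innerIterations = as.integer(innerIterations),
                 innerTolerance = innerTolerance, seed = seed,
                 initStrategy = match.arg(initStrategy)),
            class = "lpdFitControl")
}

.alignToModel <- function(x, model) {
  x <- .asExprMatrix(x)
  missing <- setdiff(model@geneIds, rownames(x))
  if (length(missing))
    stop(length(missing), " model gene(s) absent from the data, e.g. ",
         missing[1])
  x[model@geneIds, , drop = FALSE]
}

#' Variational E-step
#'
#' With model parameters fixed, iterates the coupled updates
#' \deqn{Q_{kga} \propto N(e_{ga}; \mu_{gk}, \sigma^2_{gk})
#'   \exp\{\psi(\gamma_{ak})\}, \qquad
#'   \gamma_{ak} = \alpha_k + \sum_g Q_{kga}}
#' until the gamma change falls below `tol`. After any full sweep the
#' additive identity \eqn{\sum_k \gamma_{ak} = \sum_k \alpha_k + G}
#' holds for every sample.
#'
#' @param x genes x samples matrix aligned to `model@geneIds`.
#' @param model an [LPDModel-class].
#' @param gammaInit optional A x K starting point (default flat,
#'   `alpha + G/K`).
#' @param maxInner,tol sweep limit and absolute gamma tolerance.
#' @return list with `Q` (G x A x K responsibility array), `gamma`
#'   (A x K), `iterations` and `converged`.
#' @export
lpdEStep <- function(x, model, gammaInit = NULL, maxInner = 200L,
                     tol = 1e-6) {
  x <- .alignToModel(x, model)
  A <- ncol(x); K <- model@K; G <- nrow(x)
  if (is.null(gammaInit))
    gammaInit <- matrix(rep(model@alpha, each = A) + G / K, A, K)
  stopifnot(all(dim(gammaInit) == c(A, K)))
  logdens <- cpp_log_dens(x, model@mu, model@sigma2)
  es <- cpp_e_step(logdens, model@alpha, gammaInit,
                   as.integer(maxInner), tol)
  dimnames(es$Q) <- list(rownames(x), colnames(x), NULL)
  dimnames(es$gamma) <- list(colnames(x), NULL)
  es
}

#' Variational M-step
#'
#' Responsibility-weighted Gaussian updates
#' \eqn{\mu_{gk} = \sum_a Q_{kga} e_{ga} / \sum_a Q_{kga}} and the
#' matching weighted variance, floored at `varianceFloor`. Cells with
#' zero total responsibility are reset to the gene's global
#' mean/variance (counted in `resets`).
#'
#' @param x genes x samples matrix.
#' @param Q G x A x K responsibility array.
#' @param varianceFloor lower bound on variances.
#' @return list with `mu`, `sigma2` (G x K) and `resets`.
#' @export
lpdMStep <- function(x, Q, varianceFloor = 1e-6) {
  x <- .asExprMatrix(x, requireNames = FALSE)
  stopifnot(length(dim(Q)) == 3, dim(Q)[1] == nrow(x),
            dim(Q)[2] == ncol(x))
  ms <- cpp_m_step(x, Q, varianceFloor)
  rownames(ms$mu) <- rownames(ms$sigma2) <- rownames(x)
  ms
}

#' Estimate the Dirichlet concentration by damped Newton iteration
#'
#' Maximises the Dirichlet term of the variational bound given the
#' sufficient statistics \eqn{E[\log\theta_{ak}] = \psi(\gamma_{ak}) -
#' \psi(\sum_k \gamma_{ak})}, using Newton steps with the standard
#' rank-one Hessian inversion; steps are halved (up to 50 times) until
#' alpha stays positive and the objective does not decrease. If no
#' admissible step is found the previous alpha is kept with a warning.
#'
#' @param gamma A x K matrix of variational Dirichlet posteriors.
#' @param alpha current K-vector of concentrations.
#' @param maxIter Newton iteration limit.
#' @return updated strictly positive K-vector.
#' @export
estimateDirichletAlpha <- function(gamma, alpha, maxIter = 100L) {
  A <- nrow(gamma); K <- ncol(gamma)
  stopifnot(length(alpha) == K, all(alpha > 0))
  S <- colSums(digamma(gamma) - digamma(rowSums(gamma)))
  obj <- function(a)
    A * (lgamma(sum(a)) - sum(lgamma(a))) + sum((a - 1) * S)
  cur <- obj(alpha)
  for (it in seq_len(maxIter)) {
    a0 <- sum(alpha)
    g <- A * (digamma(a0) - digamma(alpha)) + S
    h <- -A * trigamma(alpha)
    z <- A * trigamma(a0)
    b <- sum(g / h) / (1 / z + sum(1 / h))
    step <- (g - b) / h
    ok <- FALSE
    for (half in 0:50) {
      cand <- alpha - step / 2^half
      if (all(cand > 0)) {
        v <- obj(cand)
        if (v >= cur - 1e-12 * abs(cur)) {
          ok <- TRUE
          moved <- max(abs(cand - alpha))
          alpha <- cand; cur <- v
          break
        }
      }
    }
    if (!ok) {
      warning("Dirichlet Newton update found no admissible step; ",
              "keeping previous alpha")
      break
    }
    if (moved < 1e-10) break
  }
  alpha
}

#' Evidence lower bound of a decomposition
#'
#' @param x genes x samples matrix aligned to the model.
#' @param model an [LPDModel-class].
#' @param Q G x A x K responsibility array.
#' @param gamma A x K variational Dirichlet posteriors.
#' @return the variational bound (a finite scalar).
#' @export
variationalBound <- function(x, model, Q, gamma) {
  x <- .alignToModel(x, model)
  logdens <- cpp_log_dens(x, model@mu, model@sigma2)
  b <- cpp_elbo(logdens, Q, gamma, model@alpha)
  if (!is.finite(b)) stop("variational bound is not finite")
  b
}

.initFit <- function(x, K, alpha, control) {
  G <- nrow(x); A <- ncol(x)
  gmean <- rowMeans(x)
  gvar <- pmax(.rowVars(x), control$varianceFloor)
  mu <- matrix(gmean, G, K)
  if (control$initStrategy == "kmeans" && K > 1) {
    km <- tryCatch(kmeans(t(x), centers = K, nstart = 3, iter.max = 25),
                   error = function(e) NULL)
    if (!is.null(km)) mu <- t(km$centers)
  } else if (control$initStrategy == "random" && K > 1) {
    mu <- mu + matrix(rnorm(G * K, sd = 0.1 * sqrt(gvar)), G, K)
  }
  sigma2 <- matrix(gvar, G, K)
  gamma <- matrix(rep(alpha, each = A) + G / K +
                    runif(A * K, 0, 0.1 * G / K), A, K)
  list(mu = mu, sigma2 = sigma2, gamma = gamma)
}

#' Fit the latent process decomposition by variational EM
#'
#' Alternates the E-step ([lpdEStep()]) and M-step ([lpdMStep()]) --
#' plus the Dirichlet concentration update in `"estimated"` prior mode
#' -- until the relative change of the variational bound falls below
#' `control$tolerance`. The bound is non-decreasing across iterations
#' by construction of the coordinate ascent.
#'
#' In `"uniform"` prior mode alpha is held fixed at (1, ..., 1)
#' (equivalent to maximum likelihood for the mixing weights); in
#' `"estimated"` mode alpha is re-estimated each iteration.
#'
#' @param x genes x samples matrix (or SummarizedExperiment) of
#'   continuous, log-scale expression values.
#' @param K number of signatures (>= 1, at most the number of samples).
#' @param priorMode `"uniform"` or `"estimated"`.
#' @param control an [lpdFitControl()] object.
#' @param storeQ keep the G x A x K responsibility array in the result.
#' @return an [LPDFit-class] holding the fitted [LPDModel-class]
#'   (including the training reference quantiles for projection-time
#'   normalisation) and the training-cohort [LPDDecomposition-class].
#' @examples
#' sim <- simulateLPDCohort(lpdSimControl(nSamples = 50, nGenes = 80,
#'                                        seed = 7))
#' fit <- fitLPD(sim$expression, K = 4,
#'               control = lpdFitControl(seed = 7, maxIterations = 200))
#' head(signatureProportions(fit))
#' @export
fitLPD <- function(x, K, priorMode = c("uniform", "estimated"),
                   control = lpdFitControl(), storeQ = TRUE) {
  priorMode <- match.arg(priorMode)
  x <- .asExprMatrix(x)
  K <- as.integer(K)
  G <- nrow(x); A <- ncol(x)
  stopifnot(K >= 1)
  if (A < K) stop("need at least K samples to fit K signatures")
  alpha <- rep(1, K)
  .withSeed(control$seed, {
    st <- .initFit(x, K, alpha, control)
    mu <- st$mu; sigma2 <- st$sigma2; gamma <- st$gamma
    logdens <- cpp_log_dens(x, mu, sigma2)
    trace <- numeric(0)
    converged <- FALSE
    reseeds <- 0L
    Q <- NULL
    for (iter in seq_len(control$maxIterations)) {
      es <- cpp_e_step(logdens, alpha, gamma,
                       control$innerIterations, control$innerTolerance)
      Q <- es$Q; gamma <- es$gamma
      # re-seed a signature that has lost essentially all gene mass
      mass <- colSums(gamma) - A * alpha
      empty <- which(mass < 1e-3 * G)
      if (length(empty) && reseeds < 5L && iter > 1L) {
        theta <- gamma / rowSums(gamma)
        pll <- cpp_predictive_loglik(logdens, theta)
        worst <- which.min(pll)
        for (k in empty) {
          mu[, k] <- x[, worst]
          sigma2[, k] <- pmax(.rowVars(x), control$varianceFloor)
        }
        reseeds <- reseeds + 1L
        message("re-seeded ", length(empty),
                " empty signature(s) at iteration ", iter)
        logdens <- cpp_log_dens(x, mu, sigma2)
        trace <- numeric(0)  # ascent restarts from the new state
        next
      }
      ms <- cpp_m_step(x, Q, control$varianceFloor)
      mu <- ms$mu; sigma2 <- ms$sigma2
      if (priorMode == "estimated")
        alpha <- estimateDirichletAlpha(gamma, alpha)
      logdens <- cpp_log_dens(x, mu, sigma2)
      bound <- cpp_elbo(logdens, Q, gamma, alpha)
      if (!is.finite(bound))
        stop("variational bound became non-finite at iteration ", iter)
      trace <- c(trace, bound)
      n <- length(trace)
      if (n > 1 &&
          abs(trace[n] - trace[n - 1]) <= control$tolerance *
            abs(trace[n])) {
        converged <- TRUE
        break
      }
    }
    if (!converged)
      warning("EM did not converge within ", control$maxIterations,
              " iterations; returning the best state reached")
    model <- new("LPDModel", K = K, geneIds = rownames(x),
                 mu = unname(mu), sigma2 = unname(sigma2),
                 alpha = alpha, priorMode = priorMode,
                 referenceQuantiles = unname(geneReferenceQuantiles(x)),
                 signatureLabels = paste0("sig", seq_len(K)),
                 fitMeta = list(seed = control$seed,
                                iterations = length(trace),
                                bound = trace[length(trace)],
                                tolerance = control$tolerance,
                                converged = converged,
                                reseeds = reseeds,
                                boundTrace = trace))
    rownames(model@referenceQuantiles) <- rownames(x)
    dec <- new("LPDDecomposition", sampleIds = colnames(x),
               gamma = unname(gamma),
               Q = if (storeQ) Q else array(0, c(0, 0, 0)),
               bound = trace[length(trace)], converged = converged,
               nIterations = length(trace))
    new("LPDFit", model = model, decomposition = dec)
  })
}

#' Mean hold-out predictive log-likelihood of withheld samples
#'
#' Each held-out sample is decomposed with the model parameters frozen
#' (the one-added-sample E-step); its predictive log-likelihood is
#' \eqn{\sum_g \log \sum_k \hat\theta_{ak} N(e_{ga}; \mu_{gk},
#' \sigma^2_{gk})}. Returns the mean over samples.
#'
#' @param x genes x samples matrix of held-out samples.
#' @param model a fitted [LPDModel-class].
#' @param maxIterations,tol projection controls.
#' @return mean per-sample predictive log-likelihood.
#' @export
holdoutLogLik <- function(x, model, maxIterations = 500L, tol = 1e-6) {
  x <- .alignToModel(x, model)
  if (!ncol(x)) stop("empty hold-out set")
  es <- lpdEStep(x, model, maxInner = maxIterations, tol = tol)
  theta <- es$gamma / rowSums(es$gamma)
  logdens <- cpp_log_dens(x, model@mu, model@sigma2)
  mean(cpp_predictive_loglik(logdens, theta))
}

#' Choose the number of signatures by cross-validated hold-out likelihood
#'
#' Sample-wise cross-validation: for each candidate K and each prior
#' mode, the model is fitted on the training folds and the mean
#' hold-out predictive log-likelihood of the withheld samples is
#' recorded. The chosen K maximises the estimated-prior curve; exact
#' ties are broken by the uniform-prior curve and then by the smaller
#' K.
#'
#' @param x genes x samples matrix.
#' @param kRange candidate numbers of signatures.
#' @param nFolds number of folds (>= 2).
#' @param priorModes prior modes to evaluate.
#' @param control an [lpdFitControl()] object used for every fold fit.
#' @param nStarts independent starts per fold fit; the best bound wins.
#' @param seed master seed for fold assignment and fold fits.
#' @return list with `table` (data.frame: K and one mean hold-out
#'   log-likelihood column per prior mode) and the chosen `K`.
#' @export
selectK <- function(x, kRange, nFolds = 5L,
                    priorModes = c("uniform", "estimated"),
                    control = lpdFitControl(), nStarts = 1L,
                    seed = control$seed) {
  x <- .asExprMatrix(x)
  kRange <- sort(unique(as.integer(kRange)))
  stopifnot(length(kRange) >= 1, nFolds >= 2)
  priorModes <- match.arg(priorModes, several.ok = TRUE)
  A <- ncol(x)
  folds <- .withSeed(seed, sample(rep(seq_len(nFolds), length.out = A)))
  if (min(table(folds)) < 2) stop("a fold has fewer than 2 samples")
  seeds <- .deriveSeeds(if (is.null(seed)) 0 else seed,
                        length(kRange) * nFolds * length(priorModes) *
                          nStarts)
  si <- 0L
  res <- matrix(NA_real_, length(kRange), length(priorModes),
                dimnames = list(NULL, priorModes))
  for (ki in seq_along(kRange)) {
    for (mi in seq_along(priorModes)) {
      ll <- numeric(nFolds); wt <- numeric(nFolds)
      for (f in seq_len(nFolds)) {
        train <- x[, folds != f, drop = FALSE]
        test <- x[, folds == f, drop = FALSE]
        best <- NULL
        for (s in seq_len(nStarts)) {
          si <- si + 1L
          ctl <- control; ctl$seed <- seeds[si]
          fit <- suppressWarnings(
            fitLPD(train, kRange[ki], priorMode = priorModes[mi],
                   control = ctl))
          if (is.null(best) ||
              fit@decomposition@bound > best@decomposition@bound)
            best <- fit
        }
        ll[f] <- holdoutLogLik(test, lpdModel(best))
        wt[f] <- ncol(test)
      }
      res[ki, mi] <- sum(ll * wt) / sum(wt)
    }
  }
  tab <- data.frame(K = kRange, res, check.names = FALSE)
  pick <- if ("estimated" %in% priorModes) res[, "estimated"]
          else res[, 1]
  tie <- if (ncol(res) > 1) res[, setdiff(colnames(res), "estimated")[1]]
         else rep(0, nrow(res))
  ord <- order(-pick, -tie, kRange)
  list(table = tab, K = kRange[ord[1]])
}

#' Run an ensemble of independently seeded fits
#'
#' The decomposition is repeated `nRestarts` times from seeds derived
#' deterministically from the master seed (100 restarts in the
#' reference workflow). Individual failures are recorded; the ensemble
#' is returned as long as at least one run succeeds. Results are
#' independent of execution order.
#'
#' @param x genes x samples matrix.
#' @param K number of signatures.
#' @param nRestarts number of runs (default 100).
#' @param priorMode prior mode passed to [fitLPD()].
#' @param control an [lpdFitControl()] template.
#' @param seed master seed from which per-run seeds are derived.
#' @param storeQ keep responsibility arrays (off by default to bound
#'   memory across many runs).
#' @return an [LPDRunEnsemble-class], ordered by run seed.
#' @export
fitLPDRestarts <- function(x, K, nRestarts = 100L,
                           priorMode = c("uniform", "estimated"),
                           control = lpdFitControl(), seed = 1L,
                           storeQ = FALSE) {
  priorMode <- match.arg(priorMode)
  stopifnot(nRestarts >= 1)
  seeds <- .deriveSeeds(seed, nRestarts)
  runs <- lapply(seeds, function(s) {
    ctl <- control; ctl$seed <- s
    fit <- tryCatch(suppressWarnings(
      fitLPD(x, K, priorMode = priorMode, control = ctl,
             storeQ = storeQ)),
      error = function(e) e)
    if (inherits(fit, "error"))
      list(seed = s, fit = NULL, bound = NA_real_, converged = FALSE,
           error = conditionMessage(fit))
    else
      list(seed = s, fit = fit, bound = fit@decomposition@bound,
           converged = fit@decomposition@converged, error = NULL)
  })
  if (all(vapply(runs, function(r) is.null(r$fit), logical(1))))
    stop("all restarts failed; first error: ", runs[[1]]$error)
  new("LPDRunEnsemble", runs = runs[order(seeds)])
}

.MODEL_FORMAT <- "LPDstrat-model"
.MODEL_VERSION <- 1L

#' Save a fitted model to JSON
#'
#' All numeric content is written at full precision, so that
#' `loadLPDModel(saveLPDModel(m))` reproduces every field bit-exactly.
#'
#' @param model an [LPDModel-class].
#' @param path file path.
#' @export
saveLPDModel <- function(model, path) {
  validObject(model)
  # doubles are stored as %.17g strings, which round-trip exactly
  enc <- function(x) sprintf("%.17g", as.numeric(x))
  encMat <- function(m) list(dim = dim(m), data = enc(m))
  fm <- model@fitMeta
  for (nm in intersect(c("bound", "tolerance", "boundTrace"),
                       names(fm)))
    fm[[nm]] <- enc(fm[[nm]])
  payload <- list(format = .MODEL_FORMAT, version = .MODEL_VERSION,
                  K = model@K, geneIds = model@geneIds,
                  mu = encMat(unname(model@mu)),
                  sigma2 = encMat(unname(model@sigma2)),
                  alpha = enc(model@alpha), priorMode = model@priorMode,
                  referenceQuantiles =
                    encMat(unname(model@referenceQuantiles)),
                  signatureLabels = model@signatureLabels,
                  fitMeta = fm)
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' @param path file path written by [saveLPDModel()].
#' @return an [LPDModel-class].
#' @export
loadLPDModel <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e)
                        stop("corrupted model file: ",
                             conditionMessage(e)))
  if (!identical(payload$format, .MODEL_FORMAT))
    stop("not an LPDstrat model file")
  if (!identical(as.integer(payload$version), .MODEL_VERSION))
    stop("unsupported model file version: ", payload$version)
  decMat <- function(m) {
    if (is.null(m$data) || !length(m$data))
      return(matrix(0, 0, 0))
    matrix(as.numeric(m$data), m$dim[1], m$dim[2])
  }
  K <- as.integer(payload$K)
  if (is.na(K) || K < 1) stop("model file has invalid K")
  rq <- decMat(payload$referenceQuantiles)
  if (nrow(rq)) rownames(rq) <- payload$geneIds
  fm <- payload$fitMeta
  if (is.null(fm)) fm <- list()
  fm <- as.list(fm)
  for (nm in intersect(c("iterations", "reseeds", "seed"), names(fm)))
    if (!is.null(fm[[nm]])) fm[[nm]] <- as.integer(fm[[nm]])
  for (nm in intersect(c("bound", "tolerance", "boundTrace"), names(fm)))
    fm[[nm]] <- as.numeric(fm[[nm]])
  if (!is.null(fm$converged)) fm$converged <- as.logical(fm$converged)
  model <- new("LPDModel", K = K, geneIds = payload$geneIds,
               mu = decMat(payload$mu),
               sigma2 = decMat(payload$sigma2),
               alpha = as.numeric(payload$alpha),
               priorMode = payload$priorMode,
               referenceQuantiles = rq,
               signatureLabels = as.character(payload$signatureLabels),
               fitMeta = as.list(fm))
  validObject(model)
  model
}
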