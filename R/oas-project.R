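#' Decompose one new sample against a fitted model (OAS-LPD)
#'
#' One-added-sample decomposition: the model parameters
#' \eqn{\mu_{gk}}, \eqn{\sigma^2_{gk}} and \eqn{\alpha} stay frozen and
#' only the variational quantities \eqn{Q_{kg}} and \eqn{\gamma_k} of
#' the new sample are updated, starting from the flat
#' \eqn{\gamma_k = \alpha_k + G/K}, until
#' \eqn{\max_k |\Delta\gamma_k| < } `tol` or `maxIterations` sweeps.
#' Repeated calls are bit-identical.
#'
#' Up to 10\% of the model genes may be missing (or NA) in the input;
#' those genes are dropped from the sums with a warning, and the
#' additive identity then reads \eqn{\sum_k \gamma_k = \sum_k \alpha_k
#' + G_{used}}. More than 10\% missing is an error.
#'
#' @param e named per-gene expression vector.
#' @param model a fitted [LPDModel-class].
#' @param tol,maxIterations convergence controls.
#' @param quantileMap map the incoming values onto the model's stored
#'   training quantiles before decomposition. Off by default for a
#'   single vector: a rank-based per-gene map degenerates to the
#'   training medians when only one sample is available, so a lone
#'   sample must arrive already normalised to the training scale (see
#'   the package vignette).
#' @return list with `gamma` (K-vector), `theta` (normalised
#'   proportions), `nIterations`, `converged` and `genesUsed`.
#' @export
projectSample <- function(e, model, tol = 1e-6, maxIterations = 500L,
                          quantileMap = FALSE) {
  stopifnot(is.numeric(e))
  if (is.null(names(e))) stop("the expression vector must be named")
  x <- matrix(e, ncol = 1, dimnames = list(names(e), "sample"))
  if (quantileMap && ncol(model@referenceQuantiles))
    x <- quantileMapToReference(x, model@referenceQuantiles)
  res <- .projectAligned(x, model, tol, maxIterations)
  list(gamma = res$gamma[1, ], theta = res$theta[1, ],
       nIterations = res$nIterations[1], converged = res$converged[1],
       genesUsed = res$genesUsed[1])
}

# per-sample projection on a genes x samples matrix; handles per-sample
# missing genes; model parameters are never modified
.projectAligned <- function(x, model, tol, maxIterations) {
  G <- length(model@geneIds); K <- model@K
  present <- intersect(model@geneIds, rownames(x))
  x <- x[present, , drop = FALSE]
  A <- ncol(x)
  gamma <- matrix(NA_real_, A, K)
  nIter <- integer(A); conv <- logical(A); used <- integer(A)
  miss <- colSums(is.na(x)) + (G - length(present))
  if (any(miss > 0.1 * G))
    stop(sum(miss > 0.1 * G), " sample(s) are missing more than 10% ",
         "of the model genes")
  if (any(miss > 0))
    warning("dropping missing genes for ", sum(miss > 0),
            " sample(s) (at most ",
            max(miss), " of ", G, " genes)")
  idx <- match(present, model@geneIds)
  complete <- which(colSums(is.na(x)) == 0)
  if (length(complete)) {
    Gu <- length(present)
    logdens <- cpp_log_dens(x[, complete, drop = FALSE],
                            model@mu[idx, , drop = FALSE],
                            model@sigma2[idx, , drop = FALSE])
    g0 <- matrix(rep(model@alpha, each = length(complete)) + Gu / K,
                 length(complete), K)
    es <- cpp_e_step(logdens, model@alpha, g0,
                     as.integer(maxIterations), tol)
    gamma[complete, ] <- es$gamma
    nIter[complete] <- es$iterations
    conv[complete] <- es$converged
    used[complete] <- Gu
  }
  for (a in setdiff(seq_len(A), complete)) {
    keep <- which(!is.na(x[, a]))
    Gu <- length(keep)
    logdens <- cpp_log_dens(x[keep, a, drop = FALSE],
                            model@mu[idx[keep], , drop = FALSE],
                            model@sigma2[idx[keep], , drop = FALSE])
    g0 <- matrix(model@alpha + Gu / K, 1, K)
    es <- cpp_e_step(logdens, model@alpha, g0,
                     as.integer(maxIterations), tol)
    gamma[a, ] <- es$gamma
    nIter[a] <- es$iterations
    conv[a] <- es$converged
    used[a] <- Gu
  }
  list(gamma = gamma, theta = gamma / rowSums(gamma),
       nIterations = nIter, converged = conv, genesUsed = used,
       sampleIds = colnames(x))
}

#' Project a dataset onto a fitted model, one sample at a time
#'
#' Applies the one-added-sample decomposition independently to every
#' column of `x` (results do not depend on sample order) and assembles
#' an [LPDDecomposition-class]. Samples whose projection fails are
#' listed in a warning and omitted; the model itself is never
#' modified.
#'
#' @param x genes x samples matrix (or SummarizedExperiment).
#' @param model a fitted [LPDModel-class].
#' @param tol,maxIterations convergence controls.
#' @param quantileMap map each gene of the incoming dataset onto the
#'   model's stored training quantiles by rank before decomposition
#'   (default TRUE when the model carries reference quantiles).
#' @return an [LPDDecomposition-class]; its `bound` slot holds the
#'   summed per-sample predictive log-likelihood.
#' @export
projectSamples <- function(x, model, tol = 1e-6, maxIterations = 500L,
                           quantileMap = TRUE) {
  x <- .asExprMatrix(x)
  present <- intersect(model@geneIds, rownames(x))
  if (!length(present)) stop("no model genes present in the data")
  if (quantileMap && ncol(model@referenceQuantiles)) {
    x <- x[present, , drop = FALSE]
    x <- quantileMapToReference(
      x, model@referenceQuantiles[present, , drop = FALSE])
  }
  res <- tryCatch(.projectAligned(x, model, tol, maxIterations),
                  error = function(e) e)
  if (inherits(res, "error")) {
    # fall back to per-sample projection so that failures are isolated
    ok <- list(); bad <- character(0)
    for (a in seq_len(ncol(x))) {
      r <- tryCatch(.projectAligned(x[, a, drop = FALSE], model, tol,
                                    maxIterations),
                    error = function(e) e)
      if (inherits(r, "error")) bad <- c(bad, colnames(x)[a])
      else ok[[colnames(x)[a]]] <- r
    }
    if (!length(ok))
      stop("projection failed for every sample; first error: ",
           conditionMessage(res))
    warning("projection failed for sample(s): ",
            paste(bad, collapse = ", "))
    gamma <- do.call(rbind, lapply(ok, function(r) r$gamma))
    nIter <- vapply(ok, function(r) r$nIterations[1], integer(1))
    conv <- vapply(ok, function(r) r$converged[1], logical(1))
    sampleIds <- names(ok)
  } else {
    gamma <- res$gamma
    nIter <- res$nIterations
    conv <- res$converged
    sampleIds <- res$sampleIds
  }
  theta <- gamma / rowSums(gamma)
  idx <- match(intersect(model@geneIds, rownames(x)), model@geneIds)
  xc <- x[model@geneIds[idx], sampleIds, drop = FALSE]
  pll <- if (anyNA(xc)) NA_real_ else
    sum(cpp_predictive_loglik(
      cpp_log_dens(xc, model@mu[idx, , drop = FALSE],
                   model@sigma2[idx, , drop = FALSE]), theta))
  new("LPDDecomposition", sampleIds = sampleIds,
      gamma = unname(gamma), Q = array(0, c(0, 0, 0)),
      bound = pll, converged = all(conv),
      nIterations = as.integer(max(nIter)))
}
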