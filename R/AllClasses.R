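#' @useDynLib LPDstrat, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new is validObject slot
#' @importFrom stats approx cor density dnorm integrate kmeans median
#'   p.adjust pchisq pt qnorm quantile rbinom rexp rgamma rlnorm rnorm
#'   runif sd setNames uniroot var chisq.test complete.cases plogis
#'   qlogis
#' @importFrom utils read.delim write.table head read.csv
#' @import survival
NULL

.VARIANCE_FLOOR <- 1e-6

#' Fitted latent process decomposition model
#'
#' Container for the parameters of a Dirichlet/Gaussian mixed-membership
#' model of expression: per-gene, per-signature Gaussian emissions
#' \eqn{(\mu_{gk}, \sigma^2_{gk})}, the Dirichlet concentration
#' \eqn{\alpha}, and the per-gene reference quantiles of the training
#' cohort used to normalise incoming samples at projection time.
#'
#' @slot K number of signatures.
#' @slot geneIds ordered gene identifiers (length G).
#' @slot mu,sigma2 G x K matrices of emission means and variances.
#' @slot alpha K-vector of Dirichlet concentrations.
#' @slot priorMode `"uniform"` (alpha held fixed) or `"estimated"`
#'   (alpha re-estimated each M-step).
#' @slot referenceQuantiles G x n matrix of per-gene sorted training
#'   values (zero columns when absent).
#' @slot signatureLabels K labels (e.g. `"DESNT"`).
#' @slot fitMeta list with seed, iterations, final bound, tolerance,
#'   convergence flag and bound trace.
#' @export
setClass("LPDModel",
  slots = c(K = "integer", geneIds = "character", mu = "matrix",
            sigma2 = "matrix", alpha = "numeric", priorMode = "character",
            referenceQuantiles = "matrix", signatureLabels = "character",
            fitMeta = "list"))

setValidity("LPDModel", function(object) {
  msg <- character()
  K <- object@K
  if (length(K) != 1L || is.na(K) || K < 1L)
    msg <- c(msg, "K must be a single integer >= 1")
  G <- length(object@geneIds)
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "gene identifiers must be unique")
  if (!all(dim(object@mu) == c(G, K)))
    msg <- c(msg, "mu must be |geneIds| x K")
  if (!all(dim(object@sigma2) == c(G, K)))
    msg <- c(msg, "sigma2 must be |geneIds| x K")
  if (any(object@sigma2 < 0.999 * .VARIANCE_FLOOR))
    msg <- c(msg, "sigma2 entries must respect the variance floor (1e-6)")
  if (length(object@alpha) != K || any(object@alpha <= 0))
    msg <- c(msg, "alpha must be K strictly positive reals")
  if (!object@priorMode %in% c("uniform", "estimated"))
    msg <- c(msg, "priorMode must be 'uniform' or 'estimated'")
  if (length(object@signatureLabels) != K)
    msg <- c(msg, "signatureLabels must have length K")
  if (nrow(object@referenceQuantiles) &&
      nrow(object@referenceQuantiles) != G)
    msg <- c(msg, "referenceQuantiles must have one row per gene")
  if (length(msg)) msg else TRUE
})

#' Variational decomposition of a cohort
#'
#' Per-sample variational Dirichlet posteriors \eqn{\gamma_{ak}}, the
#' normalised signature proportions \eqn{\hat\theta_{ak} =
#' \gamma_{ak} / \sum_k \gamma_{ak}}, optional gene-level
#' responsibilities \eqn{Q_{kga}}, and the final variational bound.
#'
#' @slot sampleIds ordered sample identifiers (length A).
#' @slot gamma A x K matrix of Dirichlet posterior parameters.
#' @slot Q optional G x A x K responsibility array (length zero when
#'   dropped).
#' @slot bound final variational bound (or summed predictive
#'   log-likelihood for projections).
#' @slot converged,nIterations fit diagnostics.
#' @export
setClass("LPDDecomposition",
  slots = c(sampleIds = "character", gamma = "matrix", Q = "array",
            bound = "numeric", converged = "logical",
            nIterations = "integer"))

setValidity("LPDDecomposition", function(object) {
  msg <- character()
  if (nrow(object@gamma) != length(object@sampleIds))
    msg <- c(msg, "gamma must have one row per sample")
  if (any(object@gamma <= 0))
    msg <- c(msg, "gamma entries must be strictly positive")
  if (length(object@Q)) {
    d <- dim(object@Q)
    if (length(d) != 3L || d[2] != length(object@sampleIds) ||
        d[3] != ncol(object@gamma))
      msg <- c(msg, "Q must be a G x A x K array")
    else {
      s <- apply(object@Q, c(1, 2), sum)
      if (max(abs(s - 1)) > 1e-9)
        msg <- c(msg, "responsibilities must sum to 1 over signatures")
    }
  }
  if (length(msg)) msg else TRUE
})

#' A fitted model together with the decomposition of its training cohort
#'
#' @slot model an [LPDModel-class].
#' @slot decomposition an [LPDDecomposition-class].
#' @export
setClass("LPDFit",
  slots = c(model = "LPDModel", decomposition = "LPDDecomposition"))

#' Ensemble of independently seeded LPD fits
#'
#' @slot runs list, one element per restart, each holding `seed`, `fit`
#'   (an [LPDFit-class] or `NULL` on failure), `bound`, `converged` and
#'   `error`.
#' @export
setClass("LPDRunEnsemble", slots = c(runs = "list"))

setValidity("LPDRunEnsemble", function(object) {
  if (!length(object@runs)) return("ensemble must contain at least one run")
  ok <- vapply(object@runs, function(r) is.null(r$fit) ||
                 is.finite(r$bound), logical(1))
  if (!all(ok)) return("successful runs must have finite bounds")
  TRUE
})
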