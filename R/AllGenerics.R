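#' @rdname LPDModel-class
#' @param object,x an object.
#' @export
setGeneric("nSignatures", function(object) standardGeneric("nSignatures"))

#' @rdname LPDModel-class
#' @export
setGeneric("signatureMeans", function(object)
  standardGeneric("signatureMeans"))

#' @rdname LPDModel-class
#' @export
setGeneric("signatureVariances", function(object)
  standardGeneric("signatureVariances"))

#' @rdname LPDModel-class
#' @export
setGeneric("dirichletAlpha", function(object)
  standardGeneric("dirichletAlpha"))

#' @rdname LPDModel-class
#' @export
setGeneric("signatureLabels", function(object)
  standardGeneric("signatureLabels"))

#' @rdname LPDModel-class
#' @param value replacement value.
#' @export
setGeneric("signatureLabels<-", function(object, value)
  standardGeneric("signatureLabels<-"))

#' @rdname LPDDecomposition-class
#' @param object an object.
#' @export
setGeneric("posteriorGamma", function(object)
  standardGeneric("posteriorGamma"))

#' @rdname LPDDecomposition-class
#' @export
setGeneric("signatureProportions", function(object)
  standardGeneric("signatureProportions"))

#' @rdname LPDFit-class
#' @param object an object.
#' @export
setGeneric("lpdModel", function(object) standardGeneric("lpdModel"))

#' @rdname LPDFit-class
#' @export
setGeneric("decomposition", function(object)
  standardGeneric("decomposition"))

#' @rdname LPDFit-class
#' @export
setGeneric("boundTrace", function(object) standardGeneric("boundTrace"))

setMethod("nSignatures", "LPDModel", function(object) object@K)
setMethod("signatureMeans", "LPDModel", function(object) object@mu)
setMethod("signatureVariances", "LPDModel", function(object) object@sigma2)
setMethod("dirichletAlpha", "LPDModel", function(object) object@alpha)
setMethod("signatureLabels", "LPDModel", function(object)
  object@signatureLabels)
setMethod("signatureLabels<-", "LPDModel", function(object, value) {
  stopifnot(length(value) == object@K)
  object@signatureLabels <- as.character(value)
  validObject(object)
  object
})

#' @rdname LPDModel-class
#' @export
setMethod("dim", "LPDModel", function(x)
  c(length(x@geneIds), x@K))

setMethod("posteriorGamma", "LPDDecomposition", function(object) {
  g <- object@gamma
  rownames(g) <- object@sampleIds
  g
})
setMethod("signatureProportions", "LPDDecomposition", function(object) {
  g <- posteriorGamma(object)
  g / rowSums(g)
})
setMethod("nSignatures", "LPDDecomposition", function(object)
  ncol(object@gamma))

setMethod("lpdModel", "LPDFit", function(object) object@model)
setMethod("decomposition", "LPDFit", function(object)
  object@decomposition)
setMethod("nSignatures", "LPDFit", function(object) object@model@K)
setMethod("posteriorGamma", "LPDFit", function(object)
  posteriorGamma(object@decomposition))
setMethod("signatureProportions", "LPDFit", function(object)
  signatureProportions(object@decomposition))
setMethod("boundTrace", "LPDFit", function(object)
  object@model@fitMeta$boundTrace)
setMethod("signatureMeans", "LPDFit", function(object) object@model@mu)
setMethod("signatureVariances", "LPDFit", function(object)
  object@model@sigma2)
setMethod("dirichletAlpha", "LPDFit", function(object)
  object@model@alpha)
setMethod("signatureLabels", "LPDFit", function(object)
  object@model@signatureLabels)

setMethod("show", "LPDModel", function(object) {
  cat("LPDModel:", length(object@geneIds), "genes,", object@K,
      "signatures\n")
  cat("  prior mode:", object@priorMode, " alpha:",
      paste(signif(object@alpha, 3), collapse = " "), "\n")
  cat("  labels:", paste(object@signatureLabels, collapse = ", "), "\n")
  if (ncol(object@referenceQuantiles))
    cat("  reference quantiles stored for", ncol(object@referenceQuantiles),
        "training samples\n")
})

setMethod("show", "LPDDecomposition", function(object) {
  cat("LPDDecomposition:", length(object@sampleIds), "samples,",
      ncol(object@gamma), "signatures\n")
  cat("  bound:", format(object@bound), " converged:", object@converged,
      "(", object@nIterations, "iterations )\n")
  th <- signatureProportions(object)
  cat("  mean proportions:", paste(signif(colMeans(th), 3),
                                   collapse = " "), "\n")
})

setMethod("show", "LPDFit", function(object) {
  cat("LPDFit\n")
  show(object@model)
  show(object@decomposition)
})

setMethod("show", "LPDRunEnsemble", function(object) {
  b <- vapply(object@runs, function(r)
    if (is.null(r$fit)) NA_real_ else r$bound, numeric(1))
  cat("LPDRunEnsemble:", length(object@runs), "runs,",
      sum(!is.na(b)), "successful\n")
  if (any(!is.na(b)))
    cat("  bound range:", paste(signif(range(b, na.rm = TRUE), 6),
                                collapse = " .. "), "\n")
})

#' @rdname LPDRunEnsemble-class
#' @param x an [LPDRunEnsemble-class].
#' @export
setMethod("length", "LPDRunEnsemble", function(x) length(x@runs))

#' @rdname LPDRunEnsemble-class
#' @param i run index.
#' @export
setMethod("[[", "LPDRunEnsemble", function(x, i) x@runs[[i]])

#' Seeds of the runs in an ensemble
#' @param ensemble an [LPDRunEnsemble-class].
#' @return integer vector of per-run seeds.
#' @export
ensembleSeeds <- function(ensemble) {
  vapply(ensemble@runs, function(r) as.integer(r$seed), integer(1))
}

#' Final bounds of the runs in an ensemble
#' @param ensemble an [LPDRunEnsemble-class].
#' @return numeric vector (NA for failed runs).
#' @export
ensembleBounds <- function(ensemble) {
  vapply(ensemble@runs, function(r)
    if (is.null(r$fit)) NA_real_ else r$bound, numeric(1))
}
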