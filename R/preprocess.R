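#' Restrict an expression matrix to its most variable genes
#'
#' Keeps the `n` genes with the largest unbiased sample variance, with
#' variance computed in a designated reference matrix (the cohort on
#' which the decomposition is anchored; default 500 genes). Rows of
#' the result are ordered by descending reference variance.
#'
#' @param x genes x samples matrix (or SummarizedExperiment).
#' @param n number of genes to keep (default 500).
#' @param reference matrix in which variances are computed; defaults to
#'   `x` itself.
#' @return the restricted matrix, rows in descending reference variance.
#' @export
selectTopVarianceGenes <- function(x, n = 500L, reference = x) {
  x <- .asExprMatrix(x)
  reference <- .asExprMatrix(reference)
  shared <- intersect(rownames(x), rownames(reference))
  if (n > length(shared))
    stop("n = ", n, " exceeds the ", length(shared),
         " genes shared with the reference")
  v <- .rowVars(reference[shared, , drop = FALSE])
  keep <- shared[order(v, decreasing = TRUE)][seq_len(n)]
  x[keep, , drop = FALSE]
}

#' Restrict several matrices to their common genes
#'
#' @param matrices list of >= 2 genes x samples matrices.
#' @return list of matrices restricted to the common gene set, rows in
#'   identical order.
#' @export
intersectGenes <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2)
  matrices <- lapply(matrices, .asExprMatrix)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(common)) stop("gene sets have an empty intersection")
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Keep one probe per gene, chosen uniformly at random
#'
#' @param x probes x samples matrix (row names are probe ids).
#' @param probeMap data.frame with columns `probe` and `gene`.
#' @param seed integer seed or `NULL`.
#' @return genes x samples matrix (one row per gene).
#' @export
selectRandomProbePerGene <- function(x, probeMap, seed = NULL) {
  x <- .asExprMatrix(x)
  if (missing(probeMap) || is.null(probeMap))
    stop("a probe-to-gene map is required")
  stopifnot(all(c("probe", "gene") %in% colnames(probeMap)))
  probeMap <- probeMap[probeMap$probe %in% rownames(x), , drop = FALSE]
  if (!nrow(probeMap)) stop("no probes of the map are present in x")
  genes <- unique(probeMap$gene)
  .withSeed(seed, {
    chosen <- vapply(genes, function(g) {
      p <- probeMap$probe[probeMap$gene == g]
      p[sample.int(length(p), 1L)]
    }, character(1))
    out <- x[chosen, , drop = FALSE]
    rownames(out) <- genes
    out
  })
}

#' Per-gene rank-based inverse normal transform
#'
#' Each gene row is replaced by \eqn{\Phi^{-1}((r - 0.5)/n)} of its
#' within-row ranks (average ranks for ties), mapping the cross-sample
#' distribution of every gene onto a standard normal.
#'
#' @param x genes x samples matrix with >= 2 samples.
#' @return transformed matrix; constant rows become all zeros (with a
#'   warning).
#' @export
inverseNormalTransform <- function(x) {
  x <- .asExprMatrix(x, requireNames = FALSE)
  n <- ncol(x)
  if (n < 2) stop("need at least 2 samples")
  const <- apply(x, 1, function(v) max(v) == min(v))
  if (any(const))
    warning(sum(const), " constant gene row(s) transformed to zeros")
  out <- t(apply(x, 1, function(v)
    qnorm((rank(v, ties.method = "average") - 0.5) / n)))
  dimnames(out) <- dimnames(x)
  out
}

#' Per-gene sorted reference values for quantile mapping
#'
#' @param x genes x samples matrix.
#' @return G x n matrix of row-wise sorted values.
#' @export
geneReferenceQuantiles <- function(x) {
  x <- .asExprMatrix(x)
  out <- t(apply(x, 1, sort))
  rownames(out) <- rownames(x)
  out
}

#' Map each gene's values onto a reference distribution by rank
#'
#' A light-weight stand-in for cohort-level batch correction that also
#' works at projection time: per gene, the value of rank r among n
#' samples is mapped to the reference quantile at plotting position
#' (r - 0.5)/n, with linear interpolation between reference order
#' statistics. A dataset identical to the reference maps onto itself; a
#' monotone per-gene shift of the reference is undone exactly.
#'
#' @param x genes x samples matrix.
#' @param referenceQuantiles per-gene sorted reference values, as
#'   produced by [geneReferenceQuantiles()].
#' @return mapped matrix with the distribution of each gene matching
#'   the reference.
#' @export
quantileMapToReference <- function(x, referenceQuantiles) {
  x <- .asExprMatrix(x)
  missing <- setdiff(rownames(x), rownames(referenceQuantiles))
  if (length(missing))
    stop(length(missing), " gene(s) absent from the reference, e.g. ",
         missing[1])
  n <- ncol(x)
  m <- ncol(referenceQuantiles)
  pp <- (seq_len(m) - 0.5) / m
  out <- x
  for (g in seq_len(nrow(x))) {
    ref <- referenceQuantiles[rownames(x)[g], ]
    p <- (rank(x[g, ], ties.method = "average") - 0.5) / n
    out[g, ] <- approx(pp, ref, xout = p, rule = 2)$y
  }
  out
}
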