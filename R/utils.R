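# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed uses (and advances) the session RNG.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# unbiased per-row variance without matrixStats
.rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns to compute row variances")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# accept a plain genes x samples matrix or a SummarizedExperiment
.asExprMatrix <- function(x, requireNames = TRUE) {
  if (!is.matrix(x) && methods::is(x, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("the SummarizedExperiment package is required for this input")
    x <- SummarizedExperiment::assay(x, 1L)
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric genes x samples matrix")
  if (requireNames) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("expression matrix must have gene row names and sample column names")
    if (anyDuplicated(rownames(x))) stop("gene identifiers must be unique")
    if (anyDuplicated(colnames(x))) stop("sample identifiers must be unique")
  }
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  x
}

# derive a stream of valid 32-bit seeds from a master seed
.deriveSeeds <- function(seed, n) {
  as.integer((as.numeric(seed) + 9973 * seq_len(n)) %% .Machine$integer.max)
}

.logSumExpRows <- function(m) {
  mx <- do.call(pmax, as.data.frame(m))
  mx + log(rowSums(exp(m - mx)))
}
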