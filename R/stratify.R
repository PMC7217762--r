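#' Hard signature assignment by largest gamma
#'
#' Each sample is assigned to the signature with the largest posterior
#' gamma (equivalently the largest normalised proportion). Exact ties
#' are broken toward the lowest signature index, with a warning.
#'
#' @param x an [LPDDecomposition-class], [LPDFit-class] or a numeric
#'   matrix of per-sample proportions/gammas.
#' @return named integer vector of signature indices.
#' @export
assignSignatures <- function(x) {
  if (is(x, "LPDFit")) x <- decomposition(x)
  m <- if (is(x, "LPDDecomposition")) posteriorGamma(x) else x
  stopifnot(is.matrix(m))
  idx <- apply(m, 1, which.max)
  ties <- apply(m, 1, function(v) sum(v == max(v)) > 1)
  if (any(ties))
    warning(sum(ties), " tie(s) broken toward the lowest signature index")
  setNames(as.integer(idx), rownames(m))
}

#' DESNT proportion bands
#'
#' The four-group banding of the DESNT proportion: band 1 below 0.001
#' (no DESNT), band 2 in [0.001, 0.3), band 3 in [0.3, 0.6), band 4 at
#' 0.6 and above.
#'
#' @param proportion numeric vector in [0, 1].
#' @return integer vector of bands 1..4.
#' @export
desntBand <- function(proportion) {
  if (anyNA(proportion) || any(proportion < 0) || any(proportion > 1))
    stop("proportions must lie in [0, 1]")
  as.integer(cut(proportion, c(-Inf, 0.001, 0.3, 0.6, Inf),
                 right = FALSE, labels = FALSE))
}

#' Stratify a cohort by its DESNT proportion
#'
#' @param decomposition an [LPDDecomposition-class] or [LPDFit-class].
#' @param desntSignature index of the DESNT signature in the
#'   decomposition.
#' @return data.frame with sample_id, assigned_signature,
#'   desnt_proportion and desnt_band.
#' @export
stratifyCohort <- function(decomposition, desntSignature) {
  if (is(decomposition, "LPDFit"))
    decomposition <- decomposition(decomposition)
  theta <- signatureProportions(decomposition)
  stopifnot(desntSignature >= 1, desntSignature <= ncol(theta))
  p <- theta[, desntSignature]
  data.frame(sample_id = decomposition@sampleIds,
             assigned_signature = unname(assignSignatures(decomposition)),
             desnt_proportion = unname(p),
             desnt_band = desntBand(p), row.names = NULL)
}

#' Pick the representative run of an ensemble by survival p-value mode
#'
#' For each run the cohort is split into DESNT-assigned samples versus
#' the rest and the log-rank p-value is computed. The mode of the
#' log10 p-values is estimated by a Gaussian kernel density (Silverman
#' bandwidth); the representative run minimises the distance of its
#' log10 p to that mode, ties going to the smaller seed.
#'
#' @param ensemble an [LPDRunEnsemble-class].
#' @param clinical data.frame with sample_id, time and event, covering
#'   the training samples.
#' @param desntIndex integer: the DESNT signature index in each run
#'   (recycled, or one value per run).
#' @return list with `index` (position in the ensemble), `seed`,
#'   `pValues` and `mode` (on log10 scale).
#' @export
selectRepresentativeRun <- function(ensemble, clinical, desntIndex) {
  if (is.null(clinical$time) || is.null(clinical$event))
    stop("clinical table with time and event is required")
  runs <- ensemble@runs
  desntIndex <- rep_len(as.integer(desntIndex), length(runs))
  p <- rep(NA_real_, length(runs))
  for (i in seq_along(runs)) {
    if (is.null(runs[[i]]$fit)) next
    dec <- decomposition(runs[[i]]$fit)
    cl <- clinical[match(dec@sampleIds, clinical$sample_id), ]
    if (anyNA(cl$time)) stop("clinical table does not cover the cohort")
    grp <- assignSignatures(dec) == desntIndex[i]
    if (all(grp) || !any(grp)) next  # p undefined for a one-group split
    p[i] <- logrankTest(cl$time, cl$event, grp)$p.value
  }
  usable <- which(is.finite(p) & p > 0)
  if (!length(usable)) stop("no run yielded a log-rank p-value")
  lp <- log10(p[usable])
  seeds <- vapply(runs, function(r) as.integer(r$seed),
                  integer(1))[usable]
  if (length(usable) == 1L || diff(range(lp)) < 1e-12) {
    pick <- usable[which.min(seeds)]
    mode <- lp[1]
  } else {
    d <- density(lp, bw = "nrd0")
    mode <- d$x[which.max(d$y)]
    dist <- abs(lp - mode)
    o <- order(dist, seeds)
    pick <- usable[o[1]]
  }
  list(index = pick, seed = as.integer(runs[[pick]]$seed), pValues = p,
       mode = mode)
}

#' Label model signatures by correlation with reference profiles
#'
#' Each signature's mean-expression column is matched to the
#' best-correlated column of a reference gene-by-label profile matrix,
#' greedily and one-to-one on descending correlation; signatures left
#' unmatched are labelled `"unlabelled_k"`. At least half of the model
#' genes must be present in the reference.
#'
#' @param model an [LPDModel-class].
#' @param referenceProfiles genes x labels numeric matrix with row and
#'   column names (e.g. a published DESNT mean profile).
#' @return character vector of K labels, with the correlation of each
#'   match in the `"correlations"` attribute.
#' @export
labelSignatures <- function(model, referenceProfiles) {
  stopifnot(is.matrix(referenceProfiles),
            !is.null(rownames(referenceProfiles)),
            !is.null(colnames(referenceProfiles)))
  shared <- intersect(model@geneIds, rownames(referenceProfiles))
  if (length(shared) < 0.5 * length(model@geneIds))
    stop("fewer than 50% of the model genes overlap the reference")
  mu <- model@mu[match(shared, model@geneIds), , drop = FALSE]
  ref <- referenceProfiles[shared, , drop = FALSE]
  cc <- cor(mu, ref)
  K <- model@K
  labels <- paste0("unlabelled_", seq_len(K))
  rs <- rep(NA_real_, K)
  for (step in seq_len(min(K, ncol(ref)))) {
    i <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1, ]
    labels[i[1]] <- colnames(ref)[i[2]]
    rs[i[1]] <- cc[i[1], i[2]]
    cc[i[1], ] <- -Inf
    cc[, i[2]] <- -Inf
  }
  attr(labels, "correlations") <- rs
  labels
}

#' Cross-dataset signature profile correlation
#'
#' Implements the four-step comparison of signature expression
#' profiles between two cohorts: (i) one probe per gene chosen at
#' random (when a probe map is supplied), (ii) per-gene inverse normal
#' transform across samples, (iii) per-signature mean profile over the
#' samples hard-assigned to that signature, (iv) Pearson correlation of
#' the two mean profiles, per signature.
#'
#' @param xa,xb genes (or probes) x samples matrices.
#' @param da,db matching decompositions ([LPDDecomposition-class])
#'   with signatures aligned between the cohorts.
#' @param probeMapA,probeMapB optional probe-to-gene maps.
#' @param seed seed for the random probe choice.
#' @return named numeric vector of per-signature Pearson correlations;
#'   signatures unpopulated in either cohort are NA (with a warning).
#' @export
signatureProfileCorrelation <- function(xa, da, xb, db,
                                        probeMapA = NULL,
                                        probeMapB = NULL, seed = NULL) {
  K <- nSignatures(da)
  stopifnot(K == nSignatures(db))
  seeds <- if (is.null(seed)) list(NULL, NULL)
           else as.list(.deriveSeeds(seed, 2))
  if (!is.null(probeMapA))
    xa <- selectRandomProbePerGene(xa, probeMapA, seed = seeds[[1]])
  if (!is.null(probeMapB))
    xb <- selectRandomProbePerGene(xb, probeMapB, seed = seeds[[2]])
  common <- intersect(rownames(xa), rownames(xb))
  if (!length(common)) stop("no common genes between the datasets")
  za <- inverseNormalTransform(xa[common, , drop = FALSE])
  zb <- inverseNormalTransform(xb[common, , drop = FALSE])
  aa <- assignSignatures(da)
  ab <- assignSignatures(db)
  r <- setNames(rep(NA_real_, K), paste0("sig", seq_len(K)))
  for (k in seq_len(K)) {
    ia <- which(aa == k); ib <- which(ab == k)
    if (!length(ia) || !length(ib)) next
    r[k] <- cor(rowMeans(za[, ia, drop = FALSE]),
                rowMeans(zb[, ib, drop = FALSE]))
  }
  if (anyNA(r))
    warning("signature(s) with no assigned samples in one cohort: ",
            paste(names(r)[is.na(r)], collapse = ", "))
  r
}

#' Chi-square test of feature over-representation in a signature
#'
#' Builds the 2x2 table of signature membership against a binary
#' feature and applies Pearson's chi-square independence test with
#' Yates continuity correction (the R default).
#'
#' @param assignments per-sample signature indices.
#' @param feature binary 0/1 vector.
#' @param signature the signature index tested for over-representation.
#' @param correct apply the Yates continuity correction.
#' @return list of class `lpdContingency` with the 2x2 `counts`,
#'   `statistic`, `df`, `p.value` and `corrected`.
#' @export
overrepresentationTest <- function(assignments, feature, signature,
                                   correct = TRUE) {
  stopifnot(length(assignments) == length(feature),
            all(feature %in% c(0, 1)))
  inK <- factor(assignments == signature, levels = c(TRUE, FALSE))
  f <- factor(feature, levels = c(1, 0))
  counts <- table(inK, f)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate 2x2 table: a margin is zero")
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  structure(list(counts = unclass(counts),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p.value = ct$p.value,
                 corrected = correct),
            class = "lpdContingency")
}

#' @export
print.lpdContingency <- function(x, ...) {
  cat("2x2 over-representation test (chi-square",
      if (x$corrected) "with Yates correction" else "uncorrected", ")\n")
  print(x$counts)
  cat("X-squared =", format(x$statistic), " df =", x$df,
      " p =", format(x$p.value), "\n")
  invisible(x)
}

#' Per-sample gene-set activation scores
#'
#' Genes are z-scored across samples; the activation score of a set in
#' a sample is the mean z-score of its member genes. Sets with fewer
#' than `minGenes` genes present are dropped with a warning.
#'
#' @param x genes x samples matrix.
#' @param geneSets named list of gene-id vectors (see [readGMT()]).
#' @param minGenes minimum overlapping genes per set (default 3).
#' @return samples x sets score matrix.
#' @export
pathwayActivationScores <- function(x, geneSets, minGenes = 3L) {
  x <- .asExprMatrix(x)
  if (!length(geneSets)) stop("empty gene-set collection")
  sdv <- sqrt(.rowVars(x))
  z <- (x - rowMeans(x)) / ifelse(sdv > 0, sdv, 1)
  sizes <- vapply(geneSets, function(g) sum(g %in% rownames(z)),
                  integer(1))
  keep <- sizes >= minGenes
  if (!any(keep)) stop("no gene set has >= ", minGenes,
                       " genes present in the matrix")
  if (any(!keep))
    warning(sum(!keep), " gene set(s) dropped (fewer than ", minGenes,
            " overlapping genes)")
  out <- vapply(geneSets[keep], function(g)
    colMeans(z[intersect(g, rownames(z)), , drop = FALSE]),
    numeric(ncol(x)))
  rownames(out) <- colnames(x)
  out
}

#' Rank gene sets by absolute correlation with a DESNT proportion
#'
#' @param scores samples x sets activation-score matrix.
#' @param theta per-sample DESNT proportion (or gamma), aligned with
#'   the score rows.
#' @param topN number of sets to return (default 20).
#' @return data.frame (set, r, abs_r) ordered by descending |r|, ties
#'   broken by set name; constant score columns are excluded with a
#'   warning.
#' @export
rankSetsByCorrelation <- function(scores, theta, topN = 20L) {
  stopifnot(nrow(scores) == length(theta))
  sds <- apply(scores, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant score column(s) excluded")
    scores <- scores[, sds > 0, drop = FALSE]
  }
  r <- as.numeric(cor(scores, theta))
  o <- order(-abs(r), colnames(scores))
  out <- data.frame(set = colnames(scores)[o], r = r[o],
                    abs_r = abs(r[o]), row.names = NULL)
  if (nrow(out) < topN)
    warning("only ", nrow(out), " sets available; returning all")
  head(out, topN)
}

#' Differential expression between a signature and the rest
#'
#' Per-gene Welch t-test of the samples assigned to the signature
#' against all other samples, with Benjamini-Hochberg adjustment;
#' genes with q < `fdr` are flagged significant.
#'
#' @param x genes x samples matrix.
#' @param assignments per-sample signature indices aligned with the
#'   columns of `x`.
#' @param signature index of the signature of interest.
#' @param fdr false-discovery-rate threshold (default 0.05).
#' @return data.frame (gene, effect = mean difference, t, df, p, q,
#'   significant).
#' @export
differentialExpression <- function(x, assignments, signature,
                                   fdr = 0.05) {
  x <- .asExprMatrix(x)
  stopifnot(length(assignments) == ncol(x))
  inK <- assignments == signature
  n1 <- sum(inK); n2 <- sum(!inK)
  if (n1 < 3 || n2 < 3)
    stop("need at least 3 samples on each side (got ", n1, " vs ", n2,
         ")")
  x1 <- x[, inK, drop = FALSE]; x2 <- x[, !inK, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- .rowVars(x1); v2 <- .rowVars(x2)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  q <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(x), effect = m1 - m2, t = t, df = df,
             p = p, q = q, significant = q < fdr, row.names = NULL)
}

#' Consensus of differential-expression calls across restarts
#'
#' Genes called significant in at least a given fraction of the
#' ensemble runs (the cross-restart analogue of requiring a gene to be
#' differentially expressed in at least 50 of 100 runs).
#'
#' @param deTables list of data.frames from [differentialExpression()],
#'   one per run.
#' @param threshold minimum fraction of runs (default 0.5).
#' @return character vector of consensus genes.
#' @export
consensusSignificantGenes <- function(deTables, threshold = 0.5) {
  stopifnot(length(deTables) >= 1, threshold > 0, threshold <= 1)
  calls <- unlist(lapply(deTables, function(d) d$gene[d$significant]))
  if (!length(calls)) return(character(0))
  tab <- table(calls)
  sort(names(tab)[tab >= threshold * length(deTables)])
}
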