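#' Read an expression matrix from tab-separated text
#'
#' Expected layout: first column gene identifiers, header row of sample
#' identifiers, tab-separated numeric values.
#'
#' @param path file path.
#' @param impute replace missing values by the gene median instead of
#'   failing (logged via message).
#' @return genes x samples numeric matrix.
#' @export
readExpressionMatrix <- function(path, impute = FALSE) {
  d <- read.delim(path, check.names = FALSE, row.names = 1)
  x <- as.matrix(d)
  if (anyNA(x)) {
    if (!impute)
      stop("expression file contains ", sum(is.na(x)),
           " missing values; use impute = TRUE for gene-median imputation")
    message("imputing ", sum(is.na(x)), " missing values by gene medians")
    for (g in which(rowSums(is.na(x)) > 0)) {
      x[g, is.na(x[g, ])] <- median(x[g, ], na.rm = TRUE)
    }
  }
  .asExprMatrix(x)
}

#' Write an expression matrix as tab-separated text
#'
#' @param x genes x samples matrix.
#' @param path file path.
#' @export
writeExpressionMatrix <- function(x, path) {
  x <- .asExprMatrix(x)
  d <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical annotation table from CSV
#'
#' Requires columns sample_id, time, event; recognised optional columns
#' (gleason, psa, stage, margins, label) are checked against the fixed
#' vocabularies.
#'
#' @param path file path.
#' @return a clinical `data.frame` with gleason/stage as factors.
#' @export
readClinicalTable <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(d)))
    stop("clinical table must contain columns: ",
         paste(need, collapse = ", "))
  if (any(d$time <= 0)) stop("survival times must be positive")
  if (!all(d$event %in% c(0, 1))) stop("event flags must be 0/1")
  if ("gleason" %in% colnames(d)) {
    lv <- c("lt7", "3+4", "4+3", "gt7")
    if (!all(d$gleason %in% lv))
      stop("gleason categories must be one of: ", paste(lv, collapse = ", "))
    d$gleason <- factor(d$gleason, levels = lv)
  }
  if ("stage" %in% colnames(d)) {
    lv <- c("T1-T2", "T3-T4")
    if (!all(d$stage %in% lv))
      stop("stage must be one of: ", paste(lv, collapse = ", "))
    d$stage <- factor(d$stage, levels = lv)
  }
  if ("margins" %in% colnames(d) && !all(d$margins %in% c(0, 1)))
    stop("margins must be 0/1")
  d
}

#' Write a decomposition as tab-separated text
#'
#' Columns: sample_id, theta_1..theta_K, assigned_signature. The file
#' is byte-stable: identical decompositions produce identical files.
#'
#' @param decomposition an [LPDDecomposition-class].
#' @param path file path.
#' @export
writeDecomposition <- function(decomposition, path) {
  th <- signatureProportions(decomposition)
  a <- assignSignatures(decomposition)
  d <- data.frame(sample_id = decomposition@sampleIds,
                  matrix(sprintf("%.12g", th), nrow(th), ncol(th)),
                  assigned_signature = a, check.names = FALSE)
  colnames(d)[1 + seq_len(ncol(th))] <- paste0("theta_", seq_len(ncol(th)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a stratification table as tab-separated text
#'
#' @param stratification data.frame from [stratifyCohort()].
#' @param path file path.
#' @export
writeStratification <- function(stratification, path) {
  write.table(stratification, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes,
#' tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions kept in the
#'   `"description"` attribute.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}
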