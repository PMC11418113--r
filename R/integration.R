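#' Merge expression cohorts on their common genes
#'
#' Restricts every cohort to the intersection of gene sets (ordered
#' lexicographically) and concatenates samples in input order. The cohort
#' annotation is taken from each input's `colData$cohort` when present,
#' otherwise from the list names or the input position.
#'
#' @param matrices list of at least two
#'   [SummarizedExperiment::SummarizedExperiment]s (or genes-by-samples
#'   matrices) with unique gene and sample identifiers.
#' @return a merged `SummarizedExperiment` on the common genes.
#' @export
mergeCohorts <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2)
    stop("need at least two cohorts to merge", call. = FALSE)
  mats <- lapply(matrices, exprsOf)
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) == 0)
    stop("empty gene intersection across cohorts", call. = FALSE)
  common <- sort(common)
  all_samples <- unlist(lapply(mats, colnames))
  dup <- unique(all_samples[duplicated(all_samples)])
  if (length(dup))
    stop("duplicated sample ids across cohorts: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  nm <- names(matrices)
  if (is.null(nm)) nm <- rep(NA_character_, length(matrices))
  cds <- vector("list", length(matrices))
  for (i in seq_along(matrices)) {
    x <- matrices[[i]]
    if (is(x, "SummarizedExperiment")) {
      cd <- as.data.frame(colData(x))
    } else {
      cd <- data.frame(row.names = colnames(mats[[i]]))
    }
    if (is.null(cd$cohort) || all(is.na(cd$cohort)))
      cd$cohort <- if (!is.na(nm[i]) && nzchar(nm[i])) nm[i] else
        sprintf("cohort%02d", i)
    cds[[i]] <- cd
  }
  all_cols <- unique(unlist(lapply(cds, colnames)))
  cds <- lapply(cds, function(cd) {
    for (cc in setdiff(all_cols, colnames(cd))) cd[[cc]] <- NA
    cd[, all_cols, drop = FALSE]
  })
  E <- do.call(cbind, lapply(mats, function(m) m[common, , drop = FALSE]))
  cd <- do.call(rbind, cds)
  rownames(cd) <- colnames(E)
  SummarizedExperiment(assays = list(exprs = E), colData = DataFrame(cd))
}

#' Adjust cohort batch effects by location/scale standardization
#'
#' Per gene, each cohort's values are standardized to the pooled gene mean
#' and pooled SD (maximum-likelihood denominators, so the transform is an
#' exact fixed point). This is a direct location/scale batch adjustment in
#' the spirit of ComBat but without its empirical-Bayes shrinkage; it
#' removes per-cohort additive offsets exactly. Genes with zero
#' within-cohort variance skip the scale step (shift only).
#'
#' @param se a `SummarizedExperiment` whose `colData$cohort` labels define
#'   batches; at least two cohorts with >= 3 samples each.
#' @param batch optional explicit batch vector overriding
#'   `colData$cohort`.
#' @return the adjusted `SummarizedExperiment` (same dimensions and
#'   annotations).
#' @export
adjustBatch <- function(se, batch = NULL) {
  E <- exprsOf(se)
  if (is.null(batch)) {
    if (!is(se, "SummarizedExperiment") || is.null(colData(se)$cohort))
      stop("no cohort annotation found; supply 'batch'", call. = FALSE)
    batch <- as.character(colData(se)$cohort)
  }
  tab <- table(batch)
  if (length(tab) < 2)
    stop("batch adjustment needs at least two cohorts", call. = FALSE)
  if (any(tab < 3))
    stop("cohorts with fewer than 3 samples: ",
         paste(names(tab)[tab < 3], collapse = ", "), call. = FALSE)
  m_pool <- rowMeans(E)
  s_pool <- sqrt(rowMeans((E - m_pool)^2))
  out <- E
  for (b in names(tab)) {
    j <- which(batch == b)
    Eb <- E[, j, drop = FALSE]
    m_b <- rowMeans(Eb)
    s_b <- sqrt(rowMeans((Eb - m_b)^2))
    centered <- Eb - m_b
    scale_ok <- s_b > 0 & s_pool > 0
    fac <- ifelse(scale_ok, s_pool / pmax(s_b, .Machine$double.eps), 1)
    out[, j] <- centered * fac + m_pool
  }
  if (is(se, "SummarizedExperiment")) {
    assay(se) <- out
    se
  } else out
}

#' Select the most variable genes by median absolute deviation
#'
#' Genes are ranked by unscaled MAD (median of absolute deviations from
#' the gene median, no consistency constant) in decreasing order, ties
#' broken lexicographically by gene name.
#'
#' @param se expression container or matrix.
#' @param n number of genes to return (default 1500).
#' @return character vector of the top `n` gene names, in rank order.
#' @export
selectVariableGenes <- function(se, n = 1500) {
  E <- exprsOf(se)
  if (n > nrow(E))
    stop("n (", n, ") exceeds the number of genes (", nrow(E), ")",
         call. = FALSE)
  mads <- apply(E, 1, function(x) median(abs(x - median(x))))
  ord <- order(-mads, rownames(E))
  rownames(E)[ord][seq_len(n)]
}
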