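# Single-cell subtype scoring: each malignant epithelial cell's SC score
# for a subtype is the mean expression of the subtype signature minus the
# mean expression of an expression-bin-matched control gene set;
# assignment is the argmax score, and cells with a too-strong second-best
# score are flagged as hybrids and removed.

#' Bin genes by mean expression
#'
#' Genes are sorted by mean expression over cells ascending (ties broken
#' lexicographically) and split into `n_bins` equal bins of
#' floor(G / n_bins) genes; any remainder is appended to the last bin.
#'
#' @param sce expression container or genes-by-cells matrix.
#' @param n_bins number of bins (default 30).
#' @return named integer vector mapping gene -> bin (1..n_bins).
#' @export
binGenes <- function(sce, n_bins = 30) {
  E <- exprsOf(sce)
  G <- nrow(E)
  if (G < n_bins)
    stop("fewer genes (", G, ") than bins (", n_bins, ")", call. = FALSE)
  mu <- rowMeans(E)
  ord <- order(mu, rownames(E))
  size <- G %/% n_bins
  bins <- rep(seq_len(n_bins), each = size)
  bins <- c(bins, rep(n_bins, G - length(bins)))  # remainder -> last bin
  setNames(bins[order(ord)], rownames(E))[rownames(E)]
}

#' Draw a bin-matched control gene set for a signature
#'
#' For every signature gene, draws `per_bin` genes uniformly from the
#' bin containing that gene, so the control multiset is the signature
#' scaled up by a factor of `per_bin` and mirrors the signature's
#' expression-bin distribution (including bin occupancy weights, which
#' keeps the null expectation of the score at zero). When a bin holds
#' fewer than `per_bin` genes the draw is with replacement (flagged).
#' Repeated genes count repeatedly in the control mean.
#'
#' @param signature character vector of signature genes (all must be in
#'   the bin map).
#' @param bins gene -> bin map from [binGenes()].
#' @param per_bin genes drawn per signature gene from its bin
#'   (default 100).
#' @param seed RNG seed.
#' @return character vector (multiset) of `per_bin * length(signature)`
#'   control genes, with attribute `replacement` TRUE if any bin was
#'   sampled with replacement.
#' @export
controlSet <- function(signature, bins, per_bin = 100, seed = 1L) {
  if (length(signature) == 0) stop("empty signature", call. = FALSE)
  missing <- setdiff(signature, names(bins))
  if (length(missing))
    stop("signature genes missing from bin map: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  withSeed(seed, {
    repl_any <- FALSE
    ctrl <- unlist(lapply(signature, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      repl <- length(pool) < per_bin
      if (repl) repl_any <<- TRUE
      sample(pool, per_bin, replace = repl)
    }), use.names = FALSE)
    structure(ctrl, replacement = repl_any)
  })
}

#' Subtype score per cell
#'
#' SC(j) = mean expression of the signature genes in cell j minus the
#' mean expression of the control genes (multiset mean) in cell j.
#'
#' @param sce expression container or genes-by-cells matrix.
#' @param signature signature gene set.
#' @param control control gene multiset from [controlSet()].
#' @return named numeric vector of per-cell scores.
#' @export
subtypeScore <- function(sce, signature, control) {
  E <- exprsOf(sce)
  sig <- intersect(signature, rownames(E))
  if (length(sig) == 0)
    stop("signature has no genes in the matrix", call. = FALSE)
  if (!all(control %in% rownames(E)))
    stop("control genes missing from the matrix", call. = FALSE)
  sig_mean <- colMeans(E[sig, , drop = FALSE])
  ctrl_mean <- colMeans(E[control, , drop = FALSE])
  sig_mean - ctrl_mean
}

#' Assign subtypes to cells and remove hybrids
#'
#' Scores every malignant epithelial cell against each subtype signature
#' (bin-matched controls drawn per signature), assigns the argmax subtype
#' (ties broken by lexicographic subtype order and flagged), and flags a
#' cell as a subtype hybrid when ALL of: the second-best score exceeds
#' `t1`; the gap between second and third scores exceeds `t2`; and the
#' second score exceeds `t3` times the top score. Hybrids are removed
#' from the assignment output. Non-malignant cells are not scored.
#'
#' @param sce a `SingleCellExperiment` with `colData` columns `cell_type`
#'   and `stage`, or a genes-by-cells matrix (then all cells are scored
#'   and stage/type default to NA).
#' @param signatures named list of subtype signatures (>= 2).
#' @param n_bins,per_bin binning parameters (defaults 30 and 100).
#' @param t1 absolute threshold on the second score (default 1).
#' @param t2 threshold on second - third (default 0.3).
#' @param t3 fraction of the top score (default 0.1).
#' @param seed RNG seed for the control draws.
#' @param malignant_label `cell_type` value marking cells to score.
#' @return a [CellScores-class] over the scored (malignant) cells.
#' @export
assignAndFilter <- function(sce, signatures, n_bins = 30, per_bin = 100,
                            t1 = 1, t2 = 0.3, t3 = 0.1, seed = 1L,
                            malignant_label = "malignant_epithelial") {
  if (length(signatures) < 2)
    stop("need at least two subtype signatures", call. = FALSE)
  if (is.null(names(signatures)))
    names(signatures) <- paste0("C", seq_along(signatures))
  cell_type <- stage <- NULL
  if (is(sce, "SummarizedExperiment")) {
    cd <- colData(sce)
    if (!is.null(cd$cell_type)) cell_type <- as.character(cd$cell_type)
    if (!is.null(cd$stage)) stage <- as.character(cd$stage)
  }
  E <- exprsOf(sce)
  if (is.null(cell_type)) cell_type <- rep(malignant_label, ncol(E))
  if (is.null(stage)) stage <- rep(NA_character_, ncol(E))
  mal <- which(cell_type == malignant_label)
  if (length(mal) == 0)
    stop("no '", malignant_label, "' cells to score", call. = FALSE)
  Em <- E[, mal, drop = FALSE]
  bins <- binGenes(Em, n_bins = n_bins)
  subtypes <- sort(names(signatures))
  scores <- matrix(NA_real_, length(mal), length(subtypes),
                   dimnames = list(colnames(Em), subtypes))
  for (i in seq_along(subtypes)) {
    s <- subtypes[i]
    ctrl <- controlSet(signatures[[s]], bins, per_bin = per_bin,
                       seed = stageSeed(seed, i))
    scores[, s] <- subtypeScore(Em, signatures[[s]], ctrl)
  }
  hf <- hybridFilter(scores, t1 = t1, t2 = t2, t3 = t3)
  res <- new("CellScores", scores = scores, assigned = hf$assigned,
             tie = hf$tie, hybrid = hf$hybrid,
             cellType = cell_type[mal], stage = stage[mal])
  validObject(res)
  res
}

#' Argmax assignment and hybrid flags from a score matrix
#'
#' The decision rule behind [assignAndFilter()], exposed for use on
#' precomputed score tables: assignment is the argmax score (ties broken
#' by lexicographic subtype order and flagged); a cell is a hybrid iff
#' ALL of: second score > `t1`, second - third > `t2`, and second >
#' `t3` * first.
#'
#' @param scores cells-by-subtypes numeric matrix.
#' @param t1,t2,t3 hybrid thresholds (defaults 1, 0.3, 0.1).
#' @return list with `assigned` (factor), `tie`, `hybrid` (logical).
#' @export
hybridFilter <- function(scores, t1 = 1, t2 = 0.3, t3 = 0.1) {
  subtypes <- colnames(scores)
  stopifnot(!is.null(subtypes), ncol(scores) >= 2)
  ord <- order(subtypes)
  scores <- scores[, ord, drop = FALSE]
  subtypes <- subtypes[ord]
  sorted <- t(apply(scores, 1, sort, decreasing = TRUE))
  first <- sorted[, 1]
  second <- sorted[, 2]
  third <- if (length(subtypes) >= 3) sorted[, 3] else
    rep(-Inf, nrow(sorted))
  # argmax; lexicographic subtype order breaks ties (columns are sorted)
  assigned <- subtypes[apply(scores, 1, function(x)
    order(-x, seq_along(x))[1])]
  tie <- apply(scores, 1, function(x) sum(x == max(x)) > 1)
  hybrid <- (second > t1) & ((second - third) > t2) &
    (second > t3 * first)
  list(assigned = factor(assigned, levels = subtypes), tie = tie,
       hybrid = unname(hybrid))
}

#' Subtype proportions per stage
#'
#' Per stage, the proportions of retained (non-hybrid) malignant cells
#' assigned to each subtype; rows sum to 1.
#'
#' @param scores a [CellScores-class].
#' @return stages-by-subtypes matrix of proportions.
#' @export
stageProportions <- function(scores) {
  stopifnot(is(scores, "CellScores"))
  keep <- !scores@hybrid
  st <- scores@stage[keep]
  asg <- scores@assigned[keep]
  tab <- table(stage = st, subtype = asg)
  prop <- sweep(tab, 1, rowSums(tab), "/")
  as.matrix(prop)
}

#' Genes commonly upregulated at relapse
#'
#' Intersection of the up-gene sets of relapse vs primary and relapse vs
#' metastasis comparisons, using the same moderated test and thresholds
#' as the bulk differential analysis.
#'
#' @param sce expression container or genes-by-cells matrix.
#' @param stage named stage labels; taken from `colData(sce)$stage` when
#'   omitted.
#' @param lfc,fdr thresholds passed to [differentialGenes()].
#' @return character vector of commonly upregulated genes.
#' @export
stageDE <- function(sce, stage = NULL, lfc = 1, fdr = 0.05) {
  if (is(sce, "SummarizedExperiment") && is.null(stage))
    stage <- setNames(as.character(colData(sce)$stage), colnames(sce))
  E <- exprsOf(sce)
  rel <- names(stage)[stage == "relapse"]
  pri <- names(stage)[stage == "primary"]
  met <- names(stage)[stage == "metastasis"]
  up1 <- differentialGenes(E, rel, pri, lfc = lfc, fdr = fdr)$up
  up2 <- differentialGenes(E, rel, met, lfc = lfc, fdr = fdr)$up
  intersect(up1, up2)
}
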