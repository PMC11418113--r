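# Subtype marker discovery: moderated two-group tests define TT (subtype
# vs other subtypes) and TN (subtype vs normal) up-gene sets; one-way
# ANOVA F-scores summarize per-gene subtype separation; the intersection
# of four gene sets defines each subtype's signature.

#' Moderated two-group differential expression
#'
#' Per gene, a two-sample comparison on log2 expression with variance
#' moderation: the pooled within-group variance is shrunk halfway toward
#' the genewise-median pooled variance before forming the t statistic
#' (a simple stabilizer in the spirit of SAM / limma). P-values use the
#' pooled-variance t reference with nA + nB - 2 degrees of freedom and are
#' BH-adjusted across genes.
#'
#' @param E expression container or genes-by-samples matrix (log2 scale).
#' @param groupA,groupB disjoint character vectors of sample names.
#' @param lfc log2-fold-change threshold for the up set (default 1).
#' @param fdr BH-adjusted p threshold for the up set (default 0.05).
#' @param shrink weight on the genewise-median variance (default 0.5).
#' @return list with `table` (data.frame: gene, logFC, t, p, fdr, ordered
#'   as the input genes) and `up` (genes with logFC > lfc and FDR < fdr).
#' @export
differentialGenes <- function(E, groupA, groupB, lfc = 1, fdr = 0.05,
                              shrink = 0.5) {
  E <- exprsOf(E)
  if (length(intersect(groupA, groupB)))
    stop("groups overlap", call. = FALSE)
  missing <- setdiff(c(groupA, groupB), colnames(E))
  if (length(missing))
    stop("unknown samples: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 3 || nB < 3)
    stop("both groups need at least 3 samples", call. = FALSE)
  A <- E[, groupA, drop = FALSE]; B <- E[, groupB, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2); vB <- rowSums((B - mB)^2)
  df <- nA + nB - 2
  s2 <- (vA + vB) / df
  s2_tilde <- (1 - shrink) * s2 + shrink * median(s2)
  se <- sqrt(s2_tilde * (1 / nA + 1 / nB))
  logFC <- mA - mB
  tstat <- ifelse(se > 0, logFC / se, ifelse(logFC == 0, 0,
                                             sign(logFC) * Inf))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  tab <- data.frame(gene = rownames(E), logFC = logFC, t = tstat, p = p,
                    fdr = q, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(table = tab, up = tab$gene[tab$logFC > lfc & tab$fdr < fdr])
}

#' TT and TN up-gene sets per subtype
#'
#' TT genes are upregulated in one subtype versus the union of the other
#' subtypes; TN genes are upregulated in the subtype versus normal
#' samples; both at `logFC > lfc` and `FDR < fdr`.
#'
#' @param E expression container or matrix.
#' @param assignments named factor/character of subtype labels over tumor
#'   samples.
#' @param normals character vector of normal sample names (required).
#' @param lfc,fdr thresholds passed to [differentialGenes()].
#' @return named list per subtype with elements `TT` and `TN`.
#' @export
ttTnSets <- function(E, assignments, normals, lfc = 1, fdr = 0.05) {
  E <- exprsOf(E)
  if (missing(normals) || length(normals) == 0)
    stop("TN sets need normal samples", call. = FALSE)
  assignments <- assignments[!is.na(assignments)]
  subtypes <- sort(unique(as.character(assignments)))
  out <- list()
  for (s in subtypes) {
    own <- names(assignments)[assignments == s]
    rest <- names(assignments)[assignments != s]
    out[[s]] <- list(
      TT = differentialGenes(E, own, rest, lfc = lfc, fdr = fdr)$up,
      TN = differentialGenes(E, own, normals, lfc = lfc, fdr = fdr)$up)
  }
  out
}

#' Per-gene one-way ANOVA F statistics across subtypes
#'
#' @param E expression container or matrix.
#' @param assignments named subtype labels over the scored samples; every
#'   group needs >= 2 samples.
#' @return named numeric vector of F statistics (0 for constant genes;
#'   `Inf` when the within-group variance is zero but the between-group
#'   variance is not, i.e. the largest possible rank).
#' @export
fScores <- function(E, assignments) {
  E <- exprsOf(E)
  assignments <- assignments[!is.na(assignments)]
  E <- E[, names(assignments), drop = FALSE]
  groups <- split(seq_len(ncol(E)), as.character(assignments))
  if (any(lengths(groups) < 2))
    stop("every subtype group needs at least 2 samples", call. = FALSE)
  k <- length(groups)
  N <- ncol(E)
  grand <- rowMeans(E)
  ssb <- rep(0, nrow(E)); ssw <- rep(0, nrow(E))
  for (idx in groups) {
    m <- rowMeans(E[, idx, drop = FALSE])
    ssb <- ssb + length(idx) * (m - grand)^2
    ssw <- ssw + rowSums((E[, idx, drop = FALSE] - m)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  names(f) <- rownames(E)
  f
}

#' Subtype signatures as the intersection of four gene sets
#'
#' Set 1 is the subtype's TT up set and set 2 its TN up set. Set 3 is the
#' `top_n` genes by cancer-compartment log2 fold change of the subtype
#' versus the mean of the other subtypes, set 4 the `top_n` genes by
#' cancer-compartment fold change versus the normal mean profile (both
#' one-sided, descending FC, ties lexicographic). The signature is the
#' intersection of all four.
#'
#' @param tt_tn output of [ttTnSets()].
#' @param profiles a [CompartmentProfiles-class] covering every subtype.
#' @param normal_profile named numeric mean expression of normal samples.
#' @param top_n genes taken for sets 3 and 4 (default 200); `"auto"` uses
#'   max(|set1|, |set2|) per subtype.
#' @return named list per subtype: `sets` (list of the four gene sets)
#'   and `signature` (their intersection).
#' @export
subtypeSignatures <- function(tt_tn, profiles, normal_profile,
                              top_n = 200) {
  stopifnot(is(profiles, "CompartmentProfiles"))
  subtypes <- names(tt_tn)
  if (!all(subtypes %in% profiles@subtypes))
    stop("compartment profiles missing for: ",
         paste(setdiff(subtypes, profiles@subtypes), collapse = ", "),
         call. = FALSE)
  cancer <- cancerProfile(profiles)
  genes <- rownames(cancer)
  normal_profile <- normal_profile[genes]
  out <- list()
  for (s in subtypes) {
    n_s <- if (identical(top_n, "auto"))
      max(length(tt_tn[[s]]$TT), length(tt_tn[[s]]$TN)) else top_n
    if (n_s > length(genes))
      stop("top_n exceeds the gene count", call. = FALSE)
    others <- setdiff(subtypes, s)
    fc3 <- cancer[, s] - rowMeans(cancer[, others, drop = FALSE])
    fc4 <- cancer[, s] - normal_profile
    set3 <- genes[order(-fc3, genes)][seq_len(n_s)]
    set4 <- genes[order(-fc4, genes)][seq_len(n_s)]
    sets <- list(set1 = tt_tn[[s]]$TT, set2 = tt_tn[[s]]$TN,
                 set3 = set3, set4 = set4)
    out[[s]] <- list(sets = sets,
                     signature = Reduce(intersect, sets))
  }
  out
}
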