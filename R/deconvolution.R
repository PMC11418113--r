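# Two-compartment deconvolution: bulk expression of gene g in tumor
# sample i is modeled as purity-weighted mixture
#   e_i = p_i * mean(cancer) + (1 - p_i) * mean(stroma),
# so an ordinary least-squares fit of e on p per gene gives the stromal
# mean as the intercept and the cancer mean as intercept + slope.

#' Infer cancer- and stroma-compartment mean expression per subtype
#'
#' Per subtype and per gene, regresses bulk log2 expression on tumor
#' purity by ordinary least squares. Negative estimates on the (shifted
#' nonnegative) scale are clipped to zero and flagged.
#'
#' @param E expression container or genes-by-samples matrix (log2 scale).
#' @param purity named numeric in \[0,1\] over the tumor samples; taken
#'   from `colData(E)$purity` when omitted.
#' @param assignments named subtype labels over the tumor samples; taken
#'   from `colData(E)$subtype` when omitted.
#' @param min_n minimum samples per subtype (default 10).
#' @param min_purity_sd minimum purity SD per subtype (default 0.05);
#'   identifiability requires purity spread.
#' @param clip floor for compartment estimates (default 0); set to `-Inf`
#'   to disable clipping.
#' @return a [CompartmentProfiles-class] object.
#' @examples
#' E <- matrix(c(10, 2), nrow = 1,
#'             dimnames = list("G1", c("s1", "s2")))
#' p <- c(s1 = 1, s2 = 0)
#' pr <- inferCompartments(E, p, c(s1 = "C1", s2 = "C1"), min_n = 2,
#'                         min_purity_sd = 0.05)
#' cancerProfile(pr)  # 10
#' stromaProfile(pr)  # 2
#' @export
inferCompartments <- function(E, purity = NULL, assignments = NULL,
                              min_n = 10, min_purity_sd = 0.05,
                              clip = 0) {
  if (is(E, "SummarizedExperiment")) {
    cd <- colData(E)
    if (is.null(purity) && !is.null(cd$purity))
      purity <- setNames(cd$purity, rownames(cd))
    if (is.null(assignments) && !is.null(cd$subtype))
      assignments <- setNames(as.character(cd$subtype), rownames(cd))
  }
  E <- exprsOf(E)
  if (is.null(purity) || is.null(assignments))
    stop("purity and subtype assignments are required", call. = FALSE)
  assignments <- assignments[!is.na(assignments)]
  samples <- intersect(names(assignments), names(purity)[!is.na(purity)])
  purity <- purity[samples]
  if (any(purity < 0 | purity > 1))
    stop("purity outside [0,1]", call. = FALSE)
  assignments <- assignments[samples]
  subtypes <- sort(unique(as.character(assignments)))
  G <- nrow(E)
  genes <- rownames(E)
  cancer <- stroma <- residSD <- matrix(
    NA_real_, G, length(subtypes), dimnames = list(genes, subtypes))
  nS <- setNames(integer(length(subtypes)), subtypes)
  for (s in subtypes) {
    own <- samples[assignments == s]
    nS[s] <- length(own)
    if (length(own) < min_n)
      stop("subtype ", s, " has ", length(own),
           " samples (minimum ", min_n, ")", call. = FALSE)
    p <- purity[own]
    if (sd(p) < min_purity_sd)
      stop("purity SD below ", min_purity_sd, " for subtype ", s,
           call. = FALSE)
    X <- E[, own, drop = FALSE]
    pc <- p - mean(p)
    slope <- as.vector((X %*% pc)) / sum(pc^2)
    intercept <- rowMeans(X) - slope * mean(p)
    fitted <- outer(slope, p) + intercept
    res <- X - fitted
    df <- max(length(own) - 2, 1)
    residSD[, s] <- sqrt(rowSums(res^2) / df)
    stroma[, s] <- intercept
    cancer[, s] <- intercept + slope
  }
  clippedC <- cancer < clip
  clippedS <- stroma < clip
  cancer[clippedC] <- clip
  stroma[clippedS] <- clip
  new("CompartmentProfiles", genes = genes, subtypes = subtypes,
      cancer = cancer, stroma = stroma, residSD = residSD,
      clippedCancer = clippedC, clippedStroma = clippedS,
      nSamples = nS)
}

#' Compartment specificity scores
#'
#' For each gene, compartment and subtype: the compartment expression in
#' that subtype minus the mean compartment expression over the other
#' subtypes (a one-vs-rest log2 difference). A gene is called specific to
#' a subtype's compartment when |score| exceeds `threshold`.
#'
#' @param profiles a [CompartmentProfiles-class].
#' @param genes gene subset to score (default: all profile genes;
#'   typically the ligand/receptor universe).
#' @param threshold specificity call threshold on |score| (default 1).
#' @return data.frame (gene, compartment, subtype, score, specific).
#' @export
specificityScores <- function(profiles, genes = NULL, threshold = 1) {
  stopifnot(is(profiles, "CompartmentProfiles"))
  if (is.null(genes)) genes <- profiles@genes
  genes <- intersect(genes, profiles@genes)
  out <- list()
  for (comp in c("cancer", "stroma")) {
    M <- slot(profiles, comp)[genes, , drop = FALSE]
    for (s in profiles@subtypes) {
      others <- setdiff(profiles@subtypes, s)
      sc <- M[, s] - rowMeans(M[, others, drop = FALSE])
      out[[paste(comp, s)]] <- data.frame(
        gene = genes, compartment = comp, subtype = s, score = sc,
        specific = abs(sc) > threshold, row.names = NULL,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
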