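# Relative crosstalk (RC) scores: for a ligand-receptor pair, the product
# of ligand and receptor expression estimates the LR complex activity in
# each of the four signalling directions between the cancer (C) and
# stromal (S) compartments; each direction's RC score is its share of the
# total product mass, e.g.
#   S_CC = eL,C * eR,C / (eL,C*eR,C + eL,C*eR,S + eL,S*eR,C + eL,S*eR,S).

RC_DIRECTIONS <- c("CC", "CS", "SC", "SS")

# log2 -> linear concentration scale (2^x - 1, floored at 0)
linearScale <- function(x) pmax(2^x - 1, 0)

rcFromExpressions <- function(eLC, eLS, eRC, eRS) {
  eLC <- unname(eLC); eLS <- unname(eLS)
  eRC <- unname(eRC); eRS <- unname(eRS)
  prods <- c(CC = eLC * eRC, CS = eLC * eRS,
             SC = eLS * eRC, SS = eLS * eRS)
  tot <- sum(prods)
  if (tot == 0) return(setNames(rep(NA_real_, 4), RC_DIRECTIONS))
  prods / tot
}

#' Directional relative-crosstalk scores per LR pair and subtype
#'
#' Compartment expressions are mapped from log2 to linear scale
#' (2^x - 1, floored at 0) before the products are formed; pairs whose
#' four products are all zero are emitted with NA scores and a `null`
#' flag; pairs with a gene missing from the profiles are skipped with a
#' warning.
#'
#' @param profiles a [CompartmentProfiles-class].
#' @param lr_table data.frame with columns `ligand`, `receptor`.
#' @param linearize map log2 values to linear scale first (default TRUE).
#' @return data.frame with one row per retained pair and subtype:
#'   ligand, receptor, subtype, the four compartment expressions, the
#'   four direction scores `S_CC`, `S_CS`, `S_SC`, `S_SS`, and `null`.
#' @export
rcScores <- function(profiles, lr_table, linearize = TRUE) {
  stopifnot(is(profiles, "CompartmentProfiles"))
  genes <- profiles@genes
  have <- lr_table$ligand %in% genes & lr_table$receptor %in% genes
  if (any(!have))
    warning(sum(!have), " LR pair(s) skipped: gene not in profiles")
  lr <- lr_table[have, , drop = FALSE]
  if (nrow(lr) == 0)
    return(data.frame(ligand = character(), receptor = character(),
                      subtype = character(), eL_C = numeric(),
                      eL_S = numeric(), eR_C = numeric(),
                      eR_S = numeric(), S_CC = numeric(),
                      S_CS = numeric(), S_SC = numeric(),
                      S_SS = numeric(), null = logical()))
  C <- cancerProfile(profiles); S <- stromaProfile(profiles)
  if (linearize) { C <- linearScale(C); S <- linearScale(S) }
  rows <- lapply(profiles@subtypes, function(s) {
    eLC <- C[lr$ligand, s]; eLS <- S[lr$ligand, s]
    eRC <- C[lr$receptor, s]; eRS <- S[lr$receptor, s]
    pCC <- eLC * eRC; pCS <- eLC * eRS
    pSC <- eLS * eRC; pSS <- eLS * eRS
    tot <- pCC + pCS + pSC + pSS
    denom <- ifelse(tot > 0, tot, NA_real_)
    data.frame(
      ligand = lr$ligand, receptor = lr$receptor, subtype = s,
      eL_C = eLC, eL_S = eLS, eR_C = eRC, eR_S = eRS,
      S_CC = pCC / denom, S_CS = pCS / denom,
      S_SC = pSC / denom, S_SS = pSS / denom,
      null = tot == 0,
      row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Comprehensive RC score across subtypes
#'
#' Per pair and direction, the arithmetic mean of the subtype scores over
#' subtypes where the score is defined, with the count of contributing
#' subtypes.
#'
#' @param scores output of [rcScores()].
#' @return data.frame (ligand, receptor, direction, comprehensive,
#'   n_subtypes).
#' @export
comprehensiveRC <- function(scores) {
  key <- paste(scores$ligand, scores$receptor, sep = ">")
  out <- list()
  for (d in RC_DIRECTIONS) {
    col <- paste0("S_", d)
    agg_mean <- tapply(scores[[col]], key, mean, na.rm = TRUE)
    agg_n <- tapply(scores[[col]], key, function(x) sum(!is.na(x)))
    keys <- names(agg_mean)
    parts <- strsplit(keys, ">", fixed = TRUE)
    out[[d]] <- data.frame(
      ligand = vapply(parts, `[`, "", 1),
      receptor = vapply(parts, `[`, "", 2),
      direction = d,
      comprehensive = ifelse(agg_n > 0, as.vector(agg_mean), NA_real_),
      n_subtypes = as.vector(agg_n),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Top-scoring LR pairs per subtype for one direction
#'
#' @param scores output of [rcScores()].
#' @param direction one of `"CC"`, `"CS"`, `"SC"`, `"SS"`.
#' @param n pairs per subtype (default 5).
#' @return data.frame of the top `n` pairs per subtype, sorted by score
#'   descending, ties by pair name.
#' @export
topPairs <- function(scores, direction = "CC", n = 5) {
  direction <- match.arg(direction, RC_DIRECTIONS)
  col <- paste0("S_", direction)
  out <- list()
  for (s in sort(unique(scores$subtype))) {
    sub <- scores[scores$subtype == s & !is.na(scores[[col]]), ,
                  drop = FALSE]
    pair <- paste(sub$ligand, sub$receptor, sep = ">")
    ord <- order(-sub[[col]], pair)
    take <- head(ord, n)
    if (length(take))
      out[[s]] <- data.frame(subtype = s, pair = pair[take],
                             score = sub[[col]][take],
                             rank = seq_along(take),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
  else data.frame(subtype = character(), pair = character(),
                  score = numeric(), rank = integer())
}

#' RC scores between two single-cell populations
#'
#' Reuses the compartment RC formula with the per-cell-type mean
#' expression (mapped to linear scale) in place of compartment profiles:
#' type A stands in for the cancer compartment and type B for the stroma,
#' so `S_CC` is the A-to-A direction, `S_CS` A-to-B, and so on.
#'
#' @param sce a `SingleCellExperiment` (or genes-by-cells matrix) of log2
#'   expression.
#' @param cell_types named cell-type labels; taken from
#'   `colData(sce)$cell_type` when omitted.
#' @param lr_table data.frame with `ligand`, `receptor` columns.
#' @param typeA,typeB the two populations (each needs >= 10 cells).
#' @return data.frame as [rcScores()] with `subtype` replaced by the
#'   `typeA>typeB` pairing label.
#' @export
celltypeRC <- function(sce, cell_types = NULL, lr_table, typeA, typeB) {
  if (is(sce, "SummarizedExperiment") && is.null(cell_types))
    cell_types <- setNames(as.character(colData(sce)$cell_type),
                           colnames(sce))
  E <- exprsOf(sce)
  for (ty in c(typeA, typeB))
    if (sum(cell_types == ty, na.rm = TRUE) < 10)
      stop("cell type '", ty, "' has fewer than 10 cells", call. = FALSE)
  mA <- rowMeans(linearScale(E[, which(cell_types == typeA),
                               drop = FALSE]))
  mB <- rowMeans(linearScale(E[, which(cell_types == typeB),
                               drop = FALSE]))
  genes <- rownames(E)
  have <- lr_table$ligand %in% genes & lr_table$receptor %in% genes
  if (any(!have))
    warning(sum(!have), " LR pair(s) skipped: gene not in matrix")
  lr <- lr_table[have, , drop = FALSE]
  if (nrow(lr) == 0)
    return(data.frame(ligand = character(), receptor = character(),
                      subtype = character(), eL_C = numeric(),
                      eL_S = numeric(), eR_C = numeric(),
                      eR_S = numeric(), S_CC = numeric(),
                      S_CS = numeric(), S_SC = numeric(),
                      S_SS = numeric(), null = logical()))
  rows <- lapply(seq_len(nrow(lr)), function(i) {
    sc <- rcFromExpressions(mA[lr$ligand[i]], mB[lr$ligand[i]],
                            mA[lr$receptor[i]], mB[lr$receptor[i]])
    data.frame(ligand = lr$ligand[i], receptor = lr$receptor[i],
               subtype = paste0(typeA, ">", typeB),
               eL_C = mA[lr$ligand[i]], eL_S = mB[lr$ligand[i]],
               eR_C = mA[lr$receptor[i]], eR_S = mB[lr$receptor[i]],
               S_CC = sc["CC"], S_CS = sc["CS"], S_SC = sc["SC"],
               S_SS = sc["SS"], null = all(is.na(sc)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Immune-checkpoint LR pairs reported in the package's summaries
#'
#' A named list of well-known checkpoint ligand-receptor pairs used only
#' to filter crosstalk reports.
#'
#' @return data.frame with columns `ligand`, `receptor`.
#' @export
checkpointPairs <- function() {
  data.frame(
    ligand = c("CD86", "ICOSLG", "CD70", "TNFSF9", "PDCD1LG2", "IFNG"),
    receptor = c("CTLA4", "ICOS", "CD27", "TNFRSF9", "PDCD1", "IFNGR2"),
    stringsAsFactors = FALSE)
}
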