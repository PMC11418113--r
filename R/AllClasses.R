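#' Consensus clustering result
#'
#' Holds, for each factorization rank k in the scanned range, the consensus
#' (co-assignment) matrix and its cophenetic coefficient, plus the chosen k,
#' the final hard assignments, per-sample silhouette widths on the consensus
#' distance, and the mask of samples retained after silhouette filtering.
#'
#' @slot kRange integer vector of scanned ranks.
#' @slot consensus named list of samples-by-samples consensus matrices
#'   (entries in \[0,1\], symmetric, unit diagonal), one per k.
#' @slot cophenetic named numeric, cophenetic coefficient per k.
#' @slot assignmentsByK named list of factors, dendrogram-cut assignments
#'   per k.
#' @slot k chosen rank (cophenetic maximum, ties to the smaller k).
#' @slot assignments factor of subtype labels (C1, C2, ...) at the chosen k,
#'   named by sample, covering all samples before filtering.
#' @slot silhouette named numeric, per-sample silhouette width in \[-1,1\].
#' @slot retained named logical, TRUE for samples kept by the silhouette
#'   filter.
#'
#' @seealso [consensusCluster()], [selectK()], [silhouetteFilter()]
#' @export
setClass("ConsensusResult",
  representation(
    kRange = "integer",
    consensus = "list",
    cophenetic = "numeric",
    assignmentsByK = "list",
    k = "integer",
    assignments = "factor",
    silhouette = "numeric",
    retained = "logical"
  )
)

setValidity("ConsensusResult", function(object) {
  msg <- character()
  for (nm in names(object@consensus)) {
    cm <- object@consensus[[nm]]
    if (!is.matrix(cm) || nrow(cm) != ncol(cm))
      msg <- c(msg, sprintf("consensus[[%s]] is not square", nm))
    else {
      if (any(cm < -1e-12 | cm > 1 + 1e-12))
        msg <- c(msg, sprintf("consensus[[%s]] entries outside [0,1]", nm))
      if (max(abs(cm - t(cm))) > 1e-12)
        msg <- c(msg, sprintf("consensus[[%s]] not symmetric", nm))
      if (max(abs(diag(cm) - 1)) > 1e-12)
        msg <- c(msg, sprintf("consensus[[%s]] diagonal not 1", nm))
    }
  }
  if (length(object@k) == 1L && !is.na(object@k) &&
      !(object@k %in% object@kRange))
    msg <- c(msg, "chosen k outside kRange")
  if (length(msg)) msg else TRUE
})

#' Cancer / stroma compartment expression profiles
#'
#' Per-subtype per-gene mean expression of the cancer and stromal
#' compartments inferred by least squares from bulk expression and tumor
#' purity, together with residual standard deviations, clipping flags for
#' estimates floored at zero, and the number of samples used per subtype.
#'
#' @slot genes character, gene identifiers (rows of the matrices).
#' @slot subtypes character, subtype labels (columns).
#' @slot cancer,stroma genes-by-subtypes matrices of compartment means
#'   (log2 scale, floored at 0 on the shifted nonnegative scale).
#' @slot residSD genes-by-subtypes matrix of residual SDs of the per-gene
#'   fits.
#' @slot clippedCancer,clippedStroma logical matrices flagging estimates
#'   clipped to zero.
#' @slot nSamples named integer, samples used per subtype.
#'
#' @seealso [inferCompartments()], [specificityScores()]
#' @export
setClass("CompartmentProfiles",
  representation(
    genes = "character",
    subtypes = "character",
    cancer = "matrix",
    stroma = "matrix",
    residSD = "matrix",
    clippedCancer = "matrix",
    clippedStroma = "matrix",
    nSamples = "integer"
  )
)

setValidity("CompartmentProfiles", function(object) {
  msg <- character()
  dims <- c(length(object@genes), length(object@subtypes))
  for (sl in c("cancer", "stroma", "residSD", "clippedCancer",
               "clippedStroma")) {
    m <- slot(object, sl)
    if (!all(dim(m) == dims))
      msg <- c(msg, sprintf("slot %s has wrong dimensions", sl))
  }
  if (anyNA(object@cancer) || anyNA(object@stroma))
    msg <- c(msg, "non-finite compartment estimates")
  if (length(msg)) msg else TRUE
})

#' Prognostic risk model
#'
#' A linear risk score over a small gene panel: the overall survival score
#' (OSS) of a sample is the sum of coefficient times expression over the
#' model genes. Carries the training cut-point used to stratify samples into
#' high- and low-risk groups and a provenance tag distinguishing a freshly
#' fitted model from the packaged published ten-gene model.
#'
#' @slot genes character, model gene names (unique).
#' @slot coefficients named numeric, one nonzero coefficient per gene.
#' @slot cutpoint numeric(1), training-median OSS (NA if never set).
#' @slot provenance "fitted" or "published".
#'
#' @seealso [publishedModel()], [fitLassoCox()], [ossScore()]
#' @export
setClass("RiskModel",
  representation(
    genes = "character",
    coefficients = "numeric",
    cutpoint = "numeric",
    provenance = "character"
  )
)

setValidity("RiskModel", function(object) {
  msg <- character()
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate gene names")
  if (length(object@coefficients) != length(object@genes))
    msg <- c(msg, "coefficients and genes differ in length")
  if (!identical(names(object@coefficients), object@genes))
    msg <- c(msg, "coefficient names do not match genes")
  if (any(object@coefficients == 0))
    msg <- c(msg, "zero coefficients must not be stored")
  if (!object@provenance %in% c("fitted", "published"))
    msg <- c(msg, "provenance must be 'fitted' or 'published'")
  if (length(msg)) msg else TRUE
})

#' Per-cell subtype score table
#'
#' Subtype scores (SC) for malignant epithelial cells, the argmax subtype
#' assignment, and the hybrid flag marking cells whose second-best score is
#' too strong to trust the assignment. Hybrid cells are excluded from
#' downstream proportion summaries.
#'
#' @slot scores cells-by-subtypes numeric matrix of SC scores.
#' @slot assigned factor, argmax subtype per cell (ties broken by
#'   lexicographic subtype order).
#' @slot tie logical, TRUE where the top score was tied.
#' @slot hybrid logical, TRUE for cells flagged as subtype hybrids.
#' @slot cellType,stage character annotations carried through from the
#'   input cells.
#'
#' @seealso [subtypeScore()], [assignAndFilter()], [stageProportions()]
#' @export
setClass("CellScores",
  representation(
    scores = "matrix",
    assigned = "factor",
    tie = "logical",
    hybrid = "logical",
    cellType = "character",
    stage = "character"
  )
)

setValidity("CellScores", function(object) {
  n <- nrow(object@scores)
  msg <- character()
  if (length(object@assigned) != n || length(object@hybrid) != n ||
      length(object@tie) != n)
    msg <- c(msg, "per-cell vectors must match score matrix rows")
  ok <- abs(object@scores[cbind(seq_len(n),
            match(as.character(object@assigned),
                  colnames(object@scores)))] -
            apply(object@scores, 1, max)) < 1e-9
  if (n > 0 && !all(ok))
    msg <- c(msg, "assigned subtype must carry the maximal score")
  if (length(msg)) msg else TRUE
})
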