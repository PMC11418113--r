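#' @rdname ConsensusResult-class
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x, k) {
  if (missing(k)) k <- x@k
  nm <- paste0("k", k)
  if (!nm %in% names(x@consensus))
    stop("no consensus matrix for k = ", k)
  x@consensus[[nm]]
})

#' @rdname ConsensusResult-class
#' @export
setMethod("copheneticCoefficients", "ConsensusResult",
          function(x) x@cophenetic)

#' @rdname ConsensusResult-class
#' @param ... for `assignments`: `k` to extract assignments at a
#'   non-chosen rank
#' @export
setMethod("assignments", "ConsensusResult", function(x, ...) {
  args <- list(...)
  if (is.null(args$k)) return(x@assignments)
  nm <- paste0("k", args$k)
  if (!nm %in% names(x@assignmentsByK))
    stop("no assignments for k = ", args$k)
  x@assignmentsByK[[nm]]
})

#' @rdname ConsensusResult-class
#' @export
setMethod("silhouetteWidths", "ConsensusResult", function(x) x@silhouette)

#' @rdname ConsensusResult-class
#' @export
setMethod("retainedSamples", "ConsensusResult",
          function(x) names(x@retained)[x@retained])

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult over k =", paste(object@kRange, collapse = ","),
      "\n")
  cat("  cophenetic:",
      paste(sprintf("%d:%.3f", object@kRange,
                    object@cophenetic[paste0("k", object@kRange)]),
            collapse = "  "), "\n")
  cat("  chosen k:", object@k, " (", length(object@assignments),
      "samples,", sum(object@retained), "retained )\n")
  print(table(object@assignments))
})

#' @rdname CompartmentProfiles-class
#' @export
setMethod("cancerProfile", "CompartmentProfiles", function(x) x@cancer)

#' @rdname CompartmentProfiles-class
#' @export
setMethod("stromaProfile", "CompartmentProfiles", function(x) x@stroma)

#' @rdname CompartmentProfiles-class
#' @export
setMethod("clippedFlags", "CompartmentProfiles",
          function(x) list(cancer = x@clippedCancer,
                           stroma = x@clippedStroma))

setMethod("show", "CompartmentProfiles", function(object) {
  cat("CompartmentProfiles:", length(object@genes), "genes x",
      length(object@subtypes), "subtypes\n")
  cat("  subtypes:", paste(sprintf("%s (n=%d)", object@subtypes,
                                   object@nSamples[object@subtypes]),
                           collapse = ", "), "\n")
  cat("  clipped estimates:", sum(object@clippedCancer), "cancer /",
      sum(object@clippedStroma), "stroma\n")
})

#' @rdname RiskModel-class
#' @export
setMethod("riskGenes", "RiskModel", function(x) x@genes)

#' @rdname RiskModel-class
#' @export
setMethod("riskCoefficients", "RiskModel", function(x) x@coefficients)

#' @rdname RiskModel-class
#' @export
setMethod("riskCutpoint", "RiskModel", function(x) x@cutpoint)

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel (", object@provenance, "), ",
      length(object@genes), " genes\n", sep = "")
  print(round(object@coefficients, 4))
  if (!is.na(object@cutpoint))
    cat("  stratification cut-point:", signif(object@cutpoint, 4), "\n")
})

#' @rdname CellScores-class
#' @export
setMethod("scoreMatrix", "CellScores", function(x) x@scores)

#' @rdname CellScores-class
#' @export
setMethod("assignments", "CellScores", function(x, ...) {
  x@assigned[!x@hybrid]
})

#' @rdname CellScores-class
#' @export
setMethod("hybridCells", "CellScores",
          function(x) rownames(x@scores)[x@hybrid])

setMethod("show", "CellScores", function(object) {
  cat("CellScores:", nrow(object@scores), "cells x",
      ncol(object@scores), "subtypes;",
      sum(object@hybrid), "hybrids flagged\n")
  print(table(assigned = object@assigned[!object@hybrid]))
})
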