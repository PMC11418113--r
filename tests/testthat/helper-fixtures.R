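suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(SingleCellExperiment)
})

# Small bulk study used by several module tests.
smallBulk <- function(seed = 1L, ...) {
  args <- list(n_cohorts = 2, samples_per_cohort = 20, n_genes = 120,
               n_signature_genes_per_subtype = 10, n_stromal_markers = 10,
               n_normals = 10, seed = seed)
  args[names(list(...))] <- list(...)
  simulateBulk(do.call(bulkSimConfig, args))
}

bulkTruth <- function(se) metadata(se)$truth

# Compartment profiles with prescribed linear-scale expressions: takes
# genes-by-subtypes matrices on the linear scale and stores log2(x + 1)
# so that rcScores' linearization recovers them exactly.
profilesFromLinear <- function(cancer_lin, stroma_lin) {
  genes <- rownames(cancer_lin)
  subtypes <- colnames(cancer_lin)
  z <- matrix(0, nrow(cancer_lin), ncol(cancer_lin),
              dimnames = dimnames(cancer_lin))
  new("CompartmentProfiles", genes = genes, subtypes = subtypes,
      cancer = log2(cancer_lin + 1), stroma = log2(stroma_lin + 1),
      residSD = z, clippedCancer = z > 1, clippedStroma = z > 1,
      nSamples = setNames(rep(10L, length(subtypes)), subtypes))
}
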