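#' Configuration for the bulk multi-cohort simulator
#'
#' Bundles and validates the parameters of [simulateBulk()]. The defaults
#' describe the simulated study conditions used throughout the package's
#' tests: four cohorts of log2-scale expression, four planted subtypes with
#' moderate signature effects, additive per-cohort batch shifts, tumor
#' purity spread over (0.55, 0.9), exponential survival with the first
#' subtype at elevated hazard and the second protective, and a block of
#' stroma-marker genes elevated in the stromal compartment.
#'
#' @param n_cohorts number of cohorts (batches).
#' @param samples_per_cohort tumor samples simulated per cohort.
#' @param n_genes size of the gene universe.
#' @param n_subtypes number of planted subtypes (>= 2).
#' @param n_signature_genes_per_subtype genes upregulated (cancer
#'   compartment) in each subtype.
#' @param n_stromal_markers genes elevated in the stromal compartment of
#'   every subtype.
#' @param effect_size log2-units shift of signature genes (> 0).
#' @param batch_sd SD of per-cohort per-gene additive offsets (log2 units).
#' @param noise_sd per-observation Gaussian noise SD (log2 units).
#' @param purity_range length-2 numeric, tumor purity bounds in (0,1).
#' @param hazard_multipliers per-subtype relative hazards; default puts the
#'   first subtype at hazard 2 and the second at 0.5 with the rest neutral.
#' @param censoring_rate target fraction of censored samples.
#' @param n_normals normal (non-tumor) samples appended after the cohorts.
#' @param seed integer RNG seed.
#' @return a validated `BulkSimConfig` list.
#' @export
bulkSimConfig <- function(n_cohorts = 4, samples_per_cohort = 50,
                          n_genes = 300, n_subtypes = 4,
                          n_signature_genes_per_subtype = 20,
                          n_stromal_markers = 20,
                          effect_size = 2, batch_sd = 0.5, noise_sd = 0.5,
                          purity_range = c(0.55, 0.9),
                          hazard_multipliers = NULL,
                          censoring_rate = 0.3, n_normals = 20,
                          seed = 1L) {
  checkScalar(n_cohorts, "n_cohorts", lower = 1, integer = TRUE)
  checkScalar(samples_per_cohort, "samples_per_cohort", lower = 1,
              integer = TRUE)
  checkScalar(n_genes, "n_genes", lower = 1, integer = TRUE)
  checkScalar(n_subtypes, "n_subtypes", lower = 2, integer = TRUE)
  checkScalar(n_signature_genes_per_subtype,
              "n_signature_genes_per_subtype", lower = 1, integer = TRUE)
  checkScalar(n_stromal_markers, "n_stromal_markers", lower = 0,
              integer = TRUE)
  if (length(effect_size) != 1L || !is.numeric(effect_size) ||
      effect_size < 0)
    stop("invalid config: 'effect_size' must be >= 0", call. = FALSE)
  checkScalar(batch_sd, "batch_sd", lower = 0)
  checkScalar(noise_sd, "noise_sd", lower = 0)
  if (length(purity_range) != 2L || !is.numeric(purity_range) ||
      purity_range[1] <= 0 || purity_range[2] >= 1 ||
      purity_range[1] >= purity_range[2])
    stop("invalid config: 'purity_range' must satisfy 0 < lo < hi < 1",
         call. = FALSE)
  if (is.null(hazard_multipliers)) {
    hazard_multipliers <- rep(1, n_subtypes)
    hazard_multipliers[1] <- 2
    hazard_multipliers[2] <- 0.5
  }
  if (length(hazard_multipliers) != n_subtypes ||
      any(hazard_multipliers <= 0))
    stop("invalid config: 'hazard_multipliers' must be ", n_subtypes,
         " positive values", call. = FALSE)
  checkScalar(censoring_rate, "censoring_rate", lower = 0, upper = 0.95)
  checkScalar(n_normals, "n_normals", lower = 0, integer = TRUE)
  checkScalar(seed, "seed", integer = TRUE)
  if (n_subtypes * n_signature_genes_per_subtype + n_stromal_markers >
      n_genes)
    stop("invalid config: 'n_genes' too small for the requested ",
         "signature and stromal marker blocks", call. = FALSE)
  structure(list(
    n_cohorts = as.integer(n_cohorts),
    samples_per_cohort = as.integer(samples_per_cohort),
    n_genes = as.integer(n_genes), n_subtypes = as.integer(n_subtypes),
    n_signature_genes_per_subtype =
      as.integer(n_signature_genes_per_subtype),
    n_stromal_markers = as.integer(n_stromal_markers),
    effect_size = effect_size, batch_sd = batch_sd, noise_sd = noise_sd,
    purity_range = purity_range, hazard_multipliers = hazard_multipliers,
    censoring_rate = censoring_rate, n_normals = as.integer(n_normals),
    seed = as.integer(seed)), class = "BulkSimConfig")
}

# Administrative censoring horizon c solving
# P(U(0,c) < Exp(lambda)) = target, i.e. (1 - exp(-lambda c))/(lambda c).
censorHorizon <- function(lambda, target) {
  if (target <= 0) return(Inf)
  f <- function(cc) (1 - exp(-lambda * cc)) / (lambda * cc) - target
  stats::uniroot(f, lower = 1e-8, upper = 1e6 / lambda, tol = 1e-10)$root
}

#' Simulate a multi-cohort bulk expression study with planted subtypes
#'
#' Each tumor sample is a purity-weighted mixture of its subtype's cancer
#' compartment mean profile and a shared stromal profile, plus an additive
#' per-cohort batch offset and Gaussian noise, all on log2 scale. Survival
#' times are exponential with per-subtype hazard multipliers and
#' uniform-administrative censoring. Normal samples are drawn from a
#' separate baseline profile. Every planted parameter is recorded in
#' `metadata(se)$truth`.
#'
#' @param config a [bulkSimConfig()] object.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs` (genes x samples) and colData columns `cohort`, `subtype`,
#'   `normal`, `purity`, `time`, `event`; planted truth in
#'   `metadata()$truth`.
#' @examples
#' se <- simulateBulk(bulkSimConfig(n_cohorts = 2, samples_per_cohort = 10,
#'                                  n_genes = 60, seed = 7))
#' dim(se)
#' @export
simulateBulk <- function(config) {
  if (!inherits(config, "BulkSimConfig"))
    config <- do.call(bulkSimConfig, as.list(config))
  withSeed(config$seed, {
    G <- config$n_genes
    K <- config$n_subtypes
    genes <- sprintf("G%04d", seq_len(G))
    subtypes <- paste0("C", seq_len(K))

    # compartment mean profiles
    baseline <- rnorm(G, mean = 7, sd = 1)
    names(baseline) <- genes
    stroma <- baseline
    sig <- vector("list", K)
    names(sig) <- subtypes
    idx <- 0L
    cancer <- matrix(baseline, nrow = G, ncol = K,
                     dimnames = list(genes, subtypes))
    for (s in seq_len(K)) {
      take <- idx + seq_len(config$n_signature_genes_per_subtype)
      sig[[s]] <- genes[take]
      cancer[take, s] <- cancer[take, s] + config$effect_size
      idx <- idx + config$n_signature_genes_per_subtype
    }
    stromal_markers <- genes[idx + seq_len(config$n_stromal_markers)]
    stroma[stromal_markers] <- stroma[stromal_markers] + config$effect_size
    normal_profile <- baseline

    n_tum <- config$n_cohorts * config$samples_per_cohort
    cohort <- rep(sprintf("cohort%02d", seq_len(config$n_cohorts)),
                  each = config$samples_per_cohort)
    subtype <- sample(subtypes, n_tum, replace = TRUE)
    purity <- runif(n_tum, config$purity_range[1], config$purity_range[2])

    E <- cancer[, subtype, drop = FALSE] %*% diag(purity, n_tum) +
      outer(stroma, 1 - purity)

    batch <- matrix(rnorm(G * config$n_cohorts, sd = config$batch_sd),
                    nrow = G,
                    dimnames = list(genes,
                                    sprintf("cohort%02d",
                                            seq_len(config$n_cohorts))))
    E <- E + batch[, cohort, drop = FALSE]
    E <- E + matrix(rnorm(G * n_tum, sd = config$noise_sd), nrow = G)

    # survival: exponential, hazard scaled per subtype
    base_hazard <- 0.2
    lam <- base_hazard *
      config$hazard_multipliers[match(subtype, subtypes)]
    t_event <- rexp(n_tum, rate = lam)
    horizon <- censorHorizon(mean(lam), config$censoring_rate)
    cens <- if (is.finite(horizon)) runif(n_tum, 0, horizon) else
      rep(Inf, n_tum)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)

    # normals: distributed round-robin across the cohorts (each cohort
    # contributes its own normals, as in multi-cohort studies), so they
    # carry cohort batch offsets like any other sample
    cohort_n <- character(0)
    if (config$n_normals > 0) {
      cohort_n <- rep(sprintf("cohort%02d", seq_len(config$n_cohorts)),
                      length.out = config$n_normals)
      N <- matrix(normal_profile, nrow = G, ncol = config$n_normals) +
        batch[, cohort_n, drop = FALSE] +
        matrix(rnorm(G * config$n_normals, sd = config$noise_sd), nrow = G)
      E <- cbind(E, N)
    }
    n_all <- n_tum + config$n_normals
    samples <- c(sprintf("S%04d", seq_len(n_tum)),
                 if (config$n_normals > 0)
                   sprintf("N%04d", seq_len(config$n_normals)))
    colnames(E) <- samples
    rownames(E) <- genes

    cd <- DataFrame(
      cohort = c(cohort, cohort_n),
      subtype = c(subtype, rep(NA_character_, config$n_normals)),
      normal = c(rep(FALSE, n_tum), rep(TRUE, config$n_normals)),
      purity = c(purity, rep(NA_real_, config$n_normals)),
      time = c(time, rep(NA_real_, config$n_normals)),
      event = c(event, rep(NA_integer_, config$n_normals)),
      row.names = samples)

    truth <- list(config = config, cancer_profiles = cancer,
                  stroma_profile = stroma,
                  normal_profile = normal_profile,
                  signatures = sig, stromal_markers = stromal_markers,
                  batch_offsets = batch, subtype = setNames(subtype,
                                                            samples[seq_len(n_tum)]),
                  purity = setNames(purity, samples[seq_len(n_tum)]),
                  base_hazard = base_hazard)
    se <- SummarizedExperiment(assays = list(exprs = E), colData = cd)
    metadata(se)$truth <- truth
    se
  })
}

#' Configuration for the single-cell simulator
#'
#' @param n_cells_per_type_stage cells simulated per (cell type, stage).
#' @param cell_types character labels; must include
#'   `"malignant_epithelial"`; default adds `"T_cell"`.
#' @param stages stage labels (default primary / relapse / metastasis).
#' @param subtype_mixture_by_stage stages-by-subtypes matrix of latent
#'   subtype proportions among malignant cells (rows sum to 1). Default: a
#'   drift from C2-dominated primary toward C3-dominated metastasis.
#' @param signature_shift log2-units upshift of a malignant cell's own
#'   subtype signature genes.
#' @param noise_sd per-observation Gaussian noise SD.
#' @param n_relapse_genes genes upshifted in all relapse-stage cells.
#' @param relapse_shift log2-units shift for those genes.
#' @param seed integer RNG seed.
#' @return a validated `SCSimConfig` list.
#' @export
scSimConfig <- function(n_cells_per_type_stage = 100,
                        cell_types = c("malignant_epithelial", "T_cell"),
                        stages = c("primary", "relapse", "metastasis"),
                        subtype_mixture_by_stage = NULL,
                        signature_shift = 1, noise_sd = 0.5,
                        n_relapse_genes = 5, relapse_shift = 2,
                        seed = 1L) {
  checkScalar(n_cells_per_type_stage, "n_cells_per_type_stage", lower = 1,
              integer = TRUE)
  if (!"malignant_epithelial" %in% cell_types)
    stop("invalid config: 'cell_types' must include 'malignant_epithelial'",
         call. = FALSE)
  if (is.null(subtype_mixture_by_stage)) {
    subtype_mixture_by_stage <- rbind(
      primary = c(0.2, 0.5, 0.2, 0.1),
      relapse = c(0.3, 0.3, 0.3, 0.1),
      metastasis = c(0.3, 0.1, 0.5, 0.1))
    colnames(subtype_mixture_by_stage) <- paste0("C", 1:4)
    subtype_mixture_by_stage <-
      subtype_mixture_by_stage[stages[stages %in%
                                        rownames(subtype_mixture_by_stage)],
                               , drop = FALSE]
    if (nrow(subtype_mixture_by_stage) != length(stages))
      stop("invalid config: supply 'subtype_mixture_by_stage' for ",
           "non-default stages", call. = FALSE)
  }
  if (!is.matrix(subtype_mixture_by_stage) ||
      nrow(subtype_mixture_by_stage) != length(stages) ||
      any(abs(rowSums(subtype_mixture_by_stage) - 1) > 1e-8) ||
      any(subtype_mixture_by_stage < 0))
    stop("invalid config: 'subtype_mixture_by_stage' rows must be ",
         "nonnegative proportions summing to 1", call. = FALSE)
  rownames(subtype_mixture_by_stage) <- stages
  checkScalar(signature_shift, "signature_shift", lower = 0)
  checkScalar(noise_sd, "noise_sd", lower = 0)
  checkScalar(n_relapse_genes, "n_relapse_genes", lower = 0,
              integer = TRUE)
  checkScalar(relapse_shift, "relapse_shift", lower = 0)
  checkScalar(seed, "seed", integer = TRUE)
  structure(list(
    n_cells_per_type_stage = as.integer(n_cells_per_type_stage),
    cell_types = cell_types, stages = stages,
    subtype_mixture_by_stage = subtype_mixture_by_stage,
    signature_shift = signature_shift, noise_sd = noise_sd,
    n_relapse_genes = as.integer(n_relapse_genes),
    relapse_shift = relapse_shift,
    seed = as.integer(seed)), class = "SCSimConfig")
}

#' Simulate single cells with latent subtype identities
#'
#' Malignant epithelial cells carry a latent subtype drawn from the
#' stage-specific mixture; their subtype's signature genes are shifted up
#' by `signature_shift`. Other cell types carry no shift. A small block of
#' genes is elevated in all relapse-stage cells so stage-differential
#' analyses have planted truth.
#'
#' @param config a [scSimConfig()] object.
#' @param signatures named list of subtype gene sets (one per mixture
#'   column); all genes must be in `genes`.
#' @param genes the simulated gene universe (default: the union of
#'   signature genes padded with background genes to 10x the signature
#'   total, minimum 300).
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   `logcounts` and colData `cell_type`, `stage`, `latent_subtype`;
#'   planted truth in `metadata()$truth`.
#' @export
simulateSingleCell <- function(config, signatures, genes = NULL) {
  if (!inherits(config, "SCSimConfig"))
    config <- do.call(scSimConfig, as.list(config))
  if (!is.list(signatures) || length(signatures) == 0 ||
      any(lengths(signatures) == 0))
    stop("signatures must be a non-empty list of non-empty gene sets",
         call. = FALSE)
  if (ncol(config$subtype_mixture_by_stage) != length(signatures))
    stop("signatures must match the mixture's subtype columns",
         call. = FALSE)
  sig_genes <- unique(unlist(signatures))
  if (is.null(genes)) {
    n_bg <- max(300L, 10L * length(sig_genes)) - length(sig_genes)
    genes <- c(sig_genes, sprintf("BG%04d", seq_len(n_bg)))
  }
  missing <- setdiff(sig_genes, genes)
  if (length(missing))
    stop("signature genes absent from gene universe: ",
         paste(missing, collapse = ", "), call. = FALSE)
  subtypes <- colnames(config$subtype_mixture_by_stage)
  if (is.null(subtypes)) subtypes <- paste0("C", seq_along(signatures))
  names(signatures) <- subtypes

  withSeed(config$seed, {
    G <- length(genes)
    mu <- pmax(rnorm(G, mean = 3, sd = 1.5), 0)
    names(mu) <- genes
    relapse_genes <- if (config$n_relapse_genes > 0)
      sample(setdiff(genes, sig_genes), config$n_relapse_genes) else
        character()

    cells <- list(); ann <- list()
    ci <- 0L
    for (ty in config$cell_types) for (st in config$stages) {
      n <- config$n_cells_per_type_stage
      lat <- rep(NA_character_, n)
      M <- matrix(mu, nrow = G, ncol = n) +
        matrix(rnorm(G * n, sd = config$noise_sd), nrow = G)
      rownames(M) <- genes
      if (ty == "malignant_epithelial") {
        lat <- sample(subtypes, n, replace = TRUE,
                      prob = config$subtype_mixture_by_stage[st, ])
        for (s in subtypes) {
          sel <- which(lat == s)
          if (length(sel))
            M[signatures[[s]], sel] <- M[signatures[[s]], sel] +
              config$signature_shift
        }
      }
      if (st == "relapse" && length(relapse_genes))
        M[relapse_genes, ] <- M[relapse_genes, ] + config$relapse_shift
      cells[[length(cells) + 1L]] <- M
      ann[[length(ann) + 1L]] <- data.frame(
        cell_type = ty, stage = st, latent_subtype = lat,
        stringsAsFactors = FALSE)
      ci <- ci + n
    }
    E <- do.call(cbind, cells)
    cd <- do.call(rbind, ann)
    barcodes <- sprintf("cell%05d", seq_len(ncol(E)))
    colnames(E) <- barcodes
    rownames(cd) <- barcodes
    sce <- SingleCellExperiment(assays = list(logcounts = E),
                                colData = DataFrame(cd))
    metadata(sce)$truth <- list(config = config, gene_means = mu,
                                signatures = signatures,
                                relapse_genes = relapse_genes)
    sce
  })
}

#' Draw a synthetic ligand-receptor pair table
#'
#' Distinct (ligand, receptor) gene pairs sampled uniformly from the gene
#' universe; a synthetic stand-in for curated ligand-receptor resources.
#'
#' @param n_pairs number of pairs (default 1400).
#' @param gene_universe character vector of gene names.
#' @param seed integer RNG seed.
#' @return data.frame with columns `ligand`, `receptor`; no duplicate rows.
#' @export
simulateLRTable <- function(n_pairs = 1400, gene_universe, seed = 1L) {
  checkScalar(n_pairs, "n_pairs", lower = 0, integer = TRUE)
  U <- length(unique(gene_universe))
  if (U < 1) stop("empty gene universe", call. = FALSE)
  if (n_pairs > U^2)
    stop("n_pairs exceeds the ", U^2, " possible distinct pairs",
         call. = FALSE)
  gene_universe <- sort(unique(gene_universe))
  withSeed(seed, {
    idx <- sample.int(U^2, n_pairs) - 1L
    data.frame(ligand = gene_universe[idx %/% U + 1L],
               receptor = gene_universe[idx %% U + 1L],
               stringsAsFactors = FALSE)
  })
}
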