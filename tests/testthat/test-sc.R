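test_that("binGenes forms equal bins with the remainder in the last", {
  mk <- function(G) {
    matrix(seq_len(G), nrow = G, ncol = 3,
           dimnames = list(sprintf("g%03d", seq_len(G)),
                           c("c1", "c2", "c3")))
  }
  b60 <- binGenes(mk(60))
  expect_equal(as.vector(table(b60)), rep(2L, 30))
  b61 <- binGenes(mk(61))
  expect_equal(as.vector(table(b61))[30], 3L)
  expect_equal(as.vector(table(b61))[1:29], rep(2L, 29))
  # ascending mean order: lowest-expression genes in bin 1
  expect_equal(unname(b60[c("g001", "g060")]), c(1L, 30L))
  expect_error(binGenes(mk(10)), "fewer genes")

  # constant expression: ties broken lexicographically
  Ec <- matrix(1, 60, 2, dimnames = list(sprintf("g%03d", 1:60),
                                         c("c1", "c2")))
  bc <- binGenes(Ec)
  expect_equal(unname(bc[sort(names(bc))]),
               rep(1:30, each = 2))
})

test_that("controlSet draws from the signature's bins, reproducibly", {
  bins <- setNames(rep(1:3, each = 50), sprintf("g%03d", 1:150))
  sig <- c("g001", "g002")  # both in bin 1
  ctrl <- controlSet(sig, bins, per_bin = 100, seed = 5)
  expect_true(all(ctrl %in% names(bins)[bins == 1]))
  expect_length(ctrl, 100 * length(sig))  # 100 per signature gene
  expect_true(attr(ctrl, "replacement"))  # bin of 50 < 100
  expect_identical(ctrl, controlSet(sig, bins, per_bin = 100, seed = 5))

  # per_bin = bin size: a permutation of the whole bin, no replacement
  ctrl2 <- controlSet("g001", bins, per_bin = 50, seed = 1)
  expect_setequal(ctrl2, names(bins)[bins == 1])
  expect_false(attr(ctrl2, "replacement"))

  expect_error(controlSet(character(), bins), "empty")
  expect_error(controlSet("zz", bins), "missing")
})

test_that("an exact bin-matched construction gives SC = 1", {
  # 120 constant genes, bins of 4; one bin holds two signature genes at
  # value 4 and two mates at 2, so the whole-bin control mean is 3.
  G <- 120
  genes <- sprintf("g%03d", 1:G)
  vals <- c(seq(0.01, 0.56, length.out = 56), 2, 2, 4, 4,
            seq(5, 20, length.out = 60))
  E <- matrix(rep(vals, 4), nrow = G,
              dimnames = list(genes, sprintf("c%d", 1:4)))
  bins <- binGenes(E, n_bins = 30)
  sig <- genes[59:60]  # the two value-4 genes
  expect_length(unique(bins[genes[57:60]]), 1)  # share one bin
  ctrl <- controlSet(sig, bins, per_bin = 4, seed = 9)
  expect_setequal(ctrl, genes[57:60])
  sc <- subtypeScore(E, sig, ctrl)
  expect_equal(unname(sc), rep(1, 4), tolerance = 1e-12)

  # SC is invariant to adding a constant to a cell
  E2 <- E; E2[, 1] <- E2[, 1] + 7
  sc2 <- subtypeScore(E2, sig, ctrl)
  expect_equal(unname(sc2[1]), 1, tolerance = 1e-12)

  # cell where signature equals the control mean scores zero
  E3 <- E; E3[sig, 2] <- 3; E3[genes[57:58], 2] <- 3
  expect_equal(unname(subtypeScore(E3, sig, ctrl)[2]), 0,
               tolerance = 1e-12)
  expect_error(subtypeScore(E, c("zz1", "zz2"), ctrl), "no genes")
})

test_that("hybridFilter applies the three removal criteria with AND", {
  sc <- rbind(c(3.0, 2.0, 0.5, 0.1),   # all criteria met -> hybrid
              c(3.0, 0.5, 0.4, 0.1),   # second <= 1 -> retained
              c(3.0, 2.0, 1.9, 0.1),   # gap 0.1 <= 0.3 -> retained
              c(1, 1, 1, 1))           # tie; second = 1 not > 1
  colnames(sc) <- paste0("C", 1:4)
  rownames(sc) <- sprintf("cell%d", 1:4)
  hf <- hybridFilter(sc)
  expect_equal(hf$hybrid, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(as.character(hf$assigned), c("C1", "C1", "C1", "C1"))
  expect_true(hf$tie[4])
  expect_false(any(hf$tie[1:3]))
})

test_that("null signature shift gives near-zero subtype scores", {
  sig <- list(C1 = sprintf("S%02d", 1:10), C2 = sprintf("S%02d", 11:20),
              C3 = sprintf("S%02d", 21:30), C4 = sprintf("S%02d", 31:40))
  mix <- matrix(0.25, 3, 4,
                dimnames = list(c("primary", "relapse", "metastasis"),
                                names(sig)))
  # droplet-style log-normalized data: unit-scale dispersion, and a
  # transcriptome-sized gene universe so bins are well populated
  cfg <- scSimConfig(n_cells_per_type_stage = 120,
                     subtype_mixture_by_stage = mix,
                     signature_shift = 0, noise_sd = 1, seed = 51)
  genes <- c(unlist(sig, use.names = FALSE), sprintf("BG%04d", 1:1960))
  sce <- simulateSingleCell(cfg, sig, genes = genes)
  cs <- assignAndFilter(sce, sig, seed = 7)
  cd <- as.data.frame(colData(sce))
  lat <- cd[rownames(scoreMatrix(cs)), "latent_subtype"]
  for (s in names(sig)) {
    x <- scoreMatrix(cs)[lat == s, s]
    se_mean <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x)), 3 * se_mean + 1e-8)
  }
})

test_that("cells with shifted signatures are assigned accurately", {
  sig <- list(C1 = sprintf("S%02d", 1:10), C2 = sprintf("S%02d", 11:20),
              C3 = sprintf("S%02d", 21:30), C4 = sprintf("S%02d", 31:40))
  mix <- matrix(0.25, 3, 4,
                dimnames = list(c("primary", "relapse", "metastasis"),
                                names(sig)))
  cfg <- scSimConfig(n_cells_per_type_stage = 340,
                     subtype_mixture_by_stage = mix,
                     signature_shift = 1, noise_sd = 0.5, seed = 53)
  sce <- simulateSingleCell(cfg, sig)
  cs <- assignAndFilter(sce, sig, seed = 11)
  cd <- as.data.frame(colData(sce))
  keep <- !cs@hybrid
  lat <- cd[rownames(scoreMatrix(cs))[keep], "latent_subtype"]
  acc <- mean(as.character(cs@assigned[keep]) == lat)
  expect_gte(acc, 0.9)
})

test_that("stage proportions are recovered within binomial error", {
  sig <- list(C1 = sprintf("S%02d", 1:10), C2 = sprintf("S%02d", 11:20),
              C3 = sprintf("S%02d", 21:30), C4 = sprintf("S%02d", 31:40))
  mix <- matrix(rep(c(0.2, 0.3, 0.4, 0.1), each = 3), 3, 4,
                dimnames = list(c("primary", "relapse", "metastasis"),
                                names(sig)))
  cfg <- scSimConfig(n_cells_per_type_stage = 700,
                     cell_types = "malignant_epithelial",
                     subtype_mixture_by_stage = mix,
                     signature_shift = 2, noise_sd = 0.3, seed = 55)
  sce <- simulateSingleCell(cfg, sig)
  cs <- assignAndFilter(sce, sig, seed = 13)
  prop <- stageProportions(cs)
  expect_equal(unname(rowSums(prop)), rep(1, nrow(prop)),
               tolerance = 1e-12)
  for (st in rownames(prop))
    expect_lt(max(abs(prop[st, names(sig)] - c(0.2, 0.3, 0.4, 0.1))),
              0.03)
})

test_that("stage proportions degenerate case: one stage, one subtype", {
  sc <- new("CellScores",
            scores = matrix(c(2, 2, 0, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("C1", "C2"))),
            assigned = factor(c("C1", "C1"), levels = c("C1", "C2")),
            tie = c(FALSE, FALSE), hybrid = c(FALSE, FALSE),
            cellType = rep("malignant_epithelial", 2),
            stage = rep("primary", 2))
  prop <- stageProportions(sc)
  expect_equal(unname(prop["primary", "C1"]), 1)
})

test_that("stageDE finds genes commonly upregulated at relapse", {
  sig <- list(C1 = sprintf("S%02d", 1:10), C2 = sprintf("S%02d", 11:20))
  mix <- matrix(0.5, 3, 2,
                dimnames = list(c("primary", "relapse", "metastasis"),
                                names(sig)))
  cfg <- scSimConfig(n_cells_per_type_stage = 40,
                     subtype_mixture_by_stage = mix,
                     n_relapse_genes = 4, relapse_shift = 2,
                     noise_sd = 0.4, seed = 57)
  sce <- simulateSingleCell(cfg, sig)
  up <- stageDE(sce)
  planted <- metadata(sce)$truth$relapse_genes
  expect_true(all(planted %in% up))
  expect_length(stageDE(sce, lfc = Inf), 0)

  # identical stages: nothing is differential
  E <- assay(sce)
  st <- setNames(rep(c("primary", "relapse", "metastasis"),
                     length.out = ncol(E)), colnames(E))
  grp <- split(names(st), st)
  n <- min(lengths(grp))
  Eid <- cbind(E[, grp$primary[1:n]], E[, grp$primary[1:n]],
               E[, grp$primary[1:n]])
  colnames(Eid) <- sprintf("x%03d", 1:(3 * n))
  st2 <- setNames(rep(c("primary", "relapse", "metastasis"), each = n),
                  colnames(Eid))
  expect_length(stageDE(Eid, st2), 0)
})
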