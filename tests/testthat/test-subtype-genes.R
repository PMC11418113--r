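test_that("differentialGenes handles null and degenerate cases", {
  E <- matrix(rnorm(50 * 12), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("s%d", 1:12)))
  A <- sprintf("s%d", 1:6); B <- sprintf("s%d", 7:12)
  # identical group values -> all logFC 0, empty up set
  E2 <- cbind(E[, A], E[, A]); colnames(E2) <- c(A, B)
  res <- differentialGenes(E2, A, B)
  expect_true(all(res$table$logFC == 0))
  expect_length(res$up, 0)

  expect_length(differentialGenes(E, A, B, lfc = Inf)$up, 0)
  expect_error(differentialGenes(E, A, c(A[1], B)), "overlap")
  expect_error(differentialGenes(E, A[1:2], B), "at least 3")
})

test_that("BH adjustment is a monotone step-up transform", {
  withr::with_seed(5, {
    E <- matrix(rnorm(200 * 10), nrow = 200,
                dimnames = list(sprintf("g%03d", 1:200),
                                sprintf("s%d", 1:10)))
    tab <- differentialGenes(E, sprintf("s%d", 1:5),
                             sprintf("s%d", 6:10))$table
    ord <- order(tab$p)
    expect_true(all(diff(tab$fdr[ord]) >= -1e-15))
    expect_true(all(tab$fdr >= tab$p - 1e-15))
    expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
    expect_equal(tab$fdr, p.adjust(tab$p, "BH"))
  })
})

test_that("a planted +2 log-unit gene is detected reliably", {
  hits <- 0
  for (r in 1:100) {
    E <- withr::with_seed(1000 + r,
      matrix(rnorm(50 * 40, sd = 0.3), nrow = 50,
             dimnames = list(sprintf("g%02d", 1:50),
                             sprintf("s%d", 1:40))))
    E["g01", 1:20] <- E["g01", 1:20] + 2
    up <- differentialGenes(E, sprintf("s%d", 1:20),
                            sprintf("s%d", 21:40))$up
    hits <- hits + ("g01" %in% up)
  }
  expect_gte(hits, 95)
})

test_that("fScores matches a brute-force ANOVA and handles degeneracies", {
  E <- withr::with_seed(3,
    matrix(rnorm(5 * 12), nrow = 5,
           dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:12))))
  E[1, ] <- 7  # constant gene
  groups <- setNames(rep(c("C1", "C2", "C3"), each = 4), colnames(E))
  f <- fScores(E, groups)
  expect_equal(unname(f[1]), 0)
  # brute-force two-loop one-way ANOVA oracle
  brute <- sapply(rownames(E), function(g) {
    x <- E[g, ]; gl <- split(x, groups)
    grand <- mean(x)
    ssb <- sum(sapply(gl, function(v) length(v) * (mean(v) - grand)^2))
    ssw <- sum(sapply(gl, function(v) sum((v - mean(v))^2)))
    msb <- ssb / (length(gl) - 1); msw <- ssw / (length(x) - length(gl))
    if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  })
  expect_equal(f, brute, tolerance = 1e-12)
  # and against stats::aov on one gene
  a <- anova(aov(E[3, ] ~ factor(groups)))
  expect_equal(unname(f[3]), a$`F value`[1], tolerance = 1e-10)

  # zero within-group variance -> Inf
  E2 <- rbind(z = rep(c(0, 1), each = 6))
  colnames(E2) <- colnames(E)
  expect_equal(unname(fScores(E2, setNames(rep(c("A", "B"), each = 6),
                                           colnames(E2)))["z"]), Inf)
  expect_error(fScores(E, setNames(c("A", rep("B", 11)), colnames(E))),
               "at least 2")
})

test_that("null F-scores have the F-distribution mean", {
  E <- withr::with_seed(11,
    matrix(rnorm(10000 * 12), nrow = 10000,
           dimnames = list(sprintf("g%05d", 1:10000),
                           sprintf("s%d", 1:12))))
  groups <- setNames(rep(paste0("C", 1:4), each = 3), colnames(E))
  f <- fScores(E, groups)
  expect_lt(abs(mean(f) - 8 / 6), 0.05)  # E[F(3,8)] = 8/6
})

test_that("ttTnSets recovers planted signatures and needs normals", {
  se <- smallBulk(seed = 13, noise_sd = 0.3, samples_per_cohort = 30)
  tr <- bulkTruth(se)
  adj <- adjustBatch(se)
  tum <- colnames(se)[!colData(se)$normal]
  normals <- colnames(se)[colData(se)$normal]
  sets <- ttTnSets(adj, tr$subtype[tum], normals)
  for (s in names(sets)) {
    expect_true(all(tr$signatures[[s]] %in% sets[[s]]$TT))
    expect_true(all(tr$signatures[[s]] %in% sets[[s]]$TN))
  }
  expect_error(ttTnSets(adj, tr$subtype[tum], character()), "normal")
})

test_that("genes shared by two identical subtypes never enter their TT
           sets", {
  genes <- sprintf("g%02d", 1:30)
  E <- withr::with_seed(2,
    matrix(rnorm(30 * 20, mean = 5, sd = 0.2), nrow = 30,
           dimnames = list(genes, sprintf("s%d", 1:20))))
  shared <- genes[1:5]
  E[shared, ] <- E[shared, ] + 3  # elevated in both groups equally
  asg <- setNames(rep(c("C1", "C2"), each = 10), colnames(E))
  d12 <- differentialGenes(E, names(asg)[asg == "C1"],
                           names(asg)[asg == "C2"])
  expect_false(any(shared %in% d12$up))
})

test_that("subtypeSignatures intersects its four defining sets", {
  genes <- sprintf("g%02d", 1:20)
  cancer <- matrix(5, 20, 2, dimnames = list(genes, c("C1", "C2")))
  cancer["g01", "C1"] <- 9  # top FC gene for C1 in both contrasts
  stroma <- matrix(4, 20, 2, dimnames = dimnames(cancer))
  z <- matrix(0, 20, 2, dimnames = dimnames(cancer))
  prof <- new("CompartmentProfiles", genes = genes,
              subtypes = c("C1", "C2"), cancer = cancer, stroma = stroma,
              residSD = z, clippedCancer = z > 1, clippedStroma = z > 1,
              nSamples = c(C1 = 10L, C2 = 10L))
  normal_profile <- setNames(rep(5, 20), genes)
  tt_tn <- list(C1 = list(TT = c("g01", "g02"), TN = c("g01", "g03")),
                C2 = list(TT = "g04", TN = "g04"))
  res <- subtypeSignatures(tt_tn, prof, normal_profile, top_n = 5)
  expect_true("g01" %in% res$C1$signature)
  expect_true(all(res$C1$signature %in% tt_tn$C1$TT))
  expect_true(all(vapply(res, function(r)
    all(r$signature %in% r$sets$set3), logical(1))))

  res0 <- subtypeSignatures(tt_tn, prof, normal_profile, top_n = 0)
  expect_length(res0$C1$signature, 0)
  expect_error(subtypeSignatures(tt_tn, prof, normal_profile,
                                 top_n = 100), "top_n")

  # signatures shrink (weakly) as top_n decreases
  r10 <- subtypeSignatures(tt_tn, prof, normal_profile, top_n = 10)
  r3 <- subtypeSignatures(tt_tn, prof, normal_profile, top_n = 3)
  expect_true(all(r3$C1$signature %in% r10$C1$signature))
})

test_that("planted signatures survive the full four-set intersection", {
  se <- smallBulk(seed = 17, noise_sd = 0.3, samples_per_cohort = 30)
  tr <- bulkTruth(se)
  adj <- adjustBatch(se)
  tum <- colnames(se)[!colData(se)$normal]
  normals <- colnames(se)[colData(se)$normal]
  asg <- tr$subtype[tum]
  tt_tn <- ttTnSets(adj, asg, normals)
  prof <- inferCompartments(assay(adj)[, tum],
                            tr$purity[tum], asg)
  normal_profile <- rowMeans(assay(adj)[, normals])
  res <- subtypeSignatures(tt_tn, prof, normal_profile, top_n = 40)
  for (s in names(res)) {
    jac <- length(intersect(res[[s]]$signature, tr$signatures[[s]])) /
      length(union(res[[s]]$signature, tr$signatures[[s]]))
    expect_gte(jac, 0.5)
  }
})
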