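test_that("the published ten-gene model is reproduced exactly", {
  m <- publishedModel()
  co <- riskCoefficients(m)
  expect_length(riskGenes(m), 10)
  expect_equal(sum(co > 0), 3)
  expect_equal(sum(co < 0), 7)
  expect_equal(unname(co["FBLN2"]), 0.1858)
  expect_equal(unname(co["MFAP4"]), 0.0166)
  # OSS of an all-ones expression vector is the coefficient sum
  ones <- matrix(1, 10, 1, dimnames = list(riskGenes(m), "s1"))
  expect_equal(unname(ossScore(m, ones)), -0.0661, tolerance = 1e-12)
})

test_that("ossScore is linear and strict about missing genes", {
  m <- publishedModel()
  E <- withr::with_seed(3, matrix(rnorm(10 * 5, mean = 5), 10,
                                  dimnames = list(riskGenes(m),
                                                  sprintf("s%d", 1:5))))
  s1 <- ossScore(m, E)
  expect_equal(ossScore(m, 2 * E), 2 * s1, tolerance = 1e-12)
  expect_equal(unname(ossScore(m, E * 0)), rep(0, 5))
  expect_error(ossScore(m, E[-1, , drop = FALSE]), "MFAP4")
})

test_that("stratify cuts at the threshold with sane degenerate
           behavior", {
  sc <- setNames(c(1, 2, 3, 4, 5), sprintf("s%d", 1:5))
  g <- stratify(sc, median(sc))
  expect_equal(sum(g == "high"), 2)  # odd n: (n-1)/2 above the median
  expect_equal(names(g), names(sc))
  expect_warning(stratify(sc, 10), "single")
  g2 <- stratify(sc, -Inf)
  expect_true(all(g2 == "high"))
})

test_that("log-rank matches a hand-enumerated six-subject oracle", {
  # brute-force risk-set tabulation of the log-rank statistic
  bruteLogrank <- function(time, event, grp) {
    ev_times <- sort(unique(time[event == 1]))
    O <- Ex <- V <- 0
    for (t in ev_times) {
      at_risk <- time >= t
      n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
      d <- sum(time == t & event == 1)
      d1 <- sum(time == t & event == 1 & grp == 1)
      O <- O + d1
      Ex <- Ex + d * n1 / n
      if (n > 1)
        V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - Ex)^2 / V
  }
  time <- c(2, 4, 5, 7, 9, 12)
  event <- c(1, 1, 0, 1, 1, 1)
  grp <- c(1, 1, 1, 0, 0, 0)
  surv <- data.frame(sample = sprintf("s%d", 1:6), time = time,
                     event = event)
  groups <- setNames(factor(ifelse(grp == 1, "A", "B")), surv$sample)
  res <- logrankTest(groups, surv)
  expect_equal(res$statistic, bruteLogrank(time, event, grp),
               tolerance = 1e-10)
  expect_equal(res$p, pchisq(res$statistic, 1, lower.tail = FALSE))

  # label-swap invariance
  swapped <- setNames(factor(ifelse(grp == 1, "B", "A")), surv$sample)
  expect_equal(logrankTest(swapped, surv)$statistic, res$statistic,
               tolerance = 1e-12)
})

test_that("identical survival in both groups gives statistic 0", {
  surv <- data.frame(sample = sprintf("s%d", 1:8),
                     time = rep(c(1, 2, 3, 4), 2),
                     event = rep(c(1, 1, 0, 1), 2))
  groups <- setNames(factor(rep(c("A", "B"), each = 4)), surv$sample)
  res <- logrankTest(groups, surv)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_error(logrankTest(setNames(factor(rep("A", 8)), surv$sample),
                           surv), "two nonempty")
})

test_that("a planted hazard ratio of 3 is detected reliably", {
  hits <- 0
  for (r in 1:100) {
    withr::with_seed(2000 + r, {
      n <- 200
      t1 <- rexp(n, rate = 0.3); t2 <- rexp(n, rate = 0.1)
      cens <- runif(2 * n, 0, quantile(c(t1, t2), 0.8))
      time <- pmin(c(t1, t2), cens)
      event <- as.integer(c(t1, t2) <= cens)
      surv <- data.frame(sample = sprintf("s%03d", 1:(2 * n)),
                         time = pmax(time, 1e-6), event = event)
      groups <- setNames(factor(rep(c("hi", "lo"), each = n)),
                         surv$sample)
      hits <- hits + (logrankTest(groups, surv)$p < 0.01)
    })
  }
  expect_gte(hits, 95)
})

test_that("LASSO-Cox selects a planted risk gene with the right sign", {
  sel <- 0
  for (r in 1:10) {
    withr::with_seed(3000 + r, {
      n <- 300
      genes <- sprintf("g%02d", 1:15)
      E <- matrix(rnorm(15 * n, mean = 5), 15,
                  dimnames = list(genes, sprintf("s%03d", 1:n)))
      lp <- log(3) * (E["g01", ] - 5)  # hazard ratio 3 per unit
      t_ev <- rexp(n, rate = 0.2 * exp(lp))
      cens <- runif(n, 0, quantile(t_ev, 0.9))
      surv <- data.frame(sample = colnames(E),
                         time = pmax(pmin(t_ev, cens), 1e-6),
                         event = as.integer(t_ev <= cens))
      m <- fitLassoCox(E, surv, genes, seed = r)
      sel <- sel + ("g01" %in% riskGenes(m) &&
                      riskCoefficients(m)["g01"] > 0)
    })
  }
  expect_gte(sel, 9)
})

test_that("LASSO-Cox guard rails and determinism", {
  withr::with_seed(71, {
    n <- 60
    genes <- sprintf("g%02d", 1:8)
    E <- matrix(rnorm(8 * n, mean = 5), 8,
                dimnames = list(genes, sprintf("s%03d", 1:n)))
    surv <- data.frame(sample = colnames(E),
                       time = rexp(n, 0.2) + 1e-6,
                       event = rbinom(n, 1, 0.7))
    # pure-noise genes with an overwhelming penalty: empty-model error
    expect_error(fitLassoCox(E, surv, genes, seed = 1, lambda = 50),
                 "zero")
    m1 <- fitLassoCox(E, surv, genes, seed = 5, lambda = "min")
    m2 <- fitLassoCox(E, surv, genes, seed = 5, lambda = "min")
    expect_identical(riskCoefficients(m1), riskCoefficients(m2))
    expect_identical(riskCutpoint(m1), riskCutpoint(m2))

    surv0 <- surv; surv0$event <- 0
    expect_error(fitLassoCox(E, surv0, genes, seed = 1), "events")
  })
})

test_that("subtype-hazard simulation yields risk and protective signs", {
  se <- simulateBulk(bulkSimConfig(
    n_cohorts = 3, samples_per_cohort = 100, n_genes = 120,
    n_signature_genes_per_subtype = 10, noise_sd = 0.4,
    censoring_rate = 0.2, n_normals = 10, seed = 77))
  tr <- bulkTruth(se)
  tum <- colnames(se)[!colData(se)$normal]
  cand <- c(tr$signatures$C1, tr$signatures$C2)
  surv <- data.frame(sample = tum,
                     time = colData(se)[tum, "time"],
                     event = colData(se)[tum, "event"])
  m <- fitLassoCox(assay(se)[, tum], surv, cand, seed = 3,
                   lambda = "min")
  co <- riskCoefficients(m)
  c1 <- co[names(co) %in% tr$signatures$C1]
  c2 <- co[names(co) %in% tr$signatures$C2]
  expect_gt(length(c1), 0)
  expect_gt(length(c2), 0)
  # C1 carries hazard 2 (risk), C2 hazard 0.5 (protective)
  expect_gt(mean(c1 > 0), 0.5)
  expect_gt(mean(c2 < 0), 0.5)

  # stratifying by the fitted model separates survival
  sc <- ossScore(m, assay(se)[, tum])
  g <- stratify(sc, m)
  expect_lt(logrankTest(g, surv)$p, 0.01)
})
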