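# Consensus NMF subtyping: repeated factorizations build a co-assignment
# (consensus) matrix per rank k; average-linkage clustering of the
# consensus distance yields hard assignments, the cophenetic coefficient
# scores rank stability, and silhouette widths filter weak samples.

# Shift each gene so its minimum is zero (nonnegativity for NMF on
# log-scale data).
makeNonnegative <- function(E) {
  E - apply(E, 1, min)
}

#' Single NMF factorization with multiplicative updates
#'
#' Factorizes a nonnegative genes-by-samples matrix as W H using
#' Lee-Seung multiplicative updates for the Frobenius objective.
#' Log-scale input is first shifted per gene so its floor is zero.
#' Iterations stop when the relative reconstruction-error improvement
#' falls below `tol` or at `max_iter` (a warning flag is set if the cap is
#' hit).
#'
#' @param E genes-by-samples matrix (or expression container).
#' @param k factorization rank (>= 2).
#' @param seed RNG seed for the uniform initialization.
#' @param max_iter iteration cap (default 500).
#' @param tol relative-improvement convergence tolerance (default 1e-5).
#' @param shift if TRUE (default) apply the per-gene nonnegativity shift.
#' @return list with `W` (genes x k), `H` (k x samples), `cluster`
#'   (argmax over each H column), `error`, `iterations`, `converged`.
#' @export
nmfFactorize <- function(E, k, seed = 1L, max_iter = 500, tol = 1e-5,
                         shift = TRUE) {
  E <- exprsOf(E)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (shift) E <- makeNonnegative(E)
  if (all(E == 0)) stop("all-zero matrix cannot be factorized",
                        call. = FALSE)
  sc <- sqrt(mean(E) / k)
  fit <- withSeed(seed, {
    W0 <- matrix(runif(nrow(E) * k), ncol = k) * sc
    H0 <- matrix(runif(k * ncol(E)), nrow = k) * sc
    .nmf_mu(E, W0, H0, as.integer(max_iter), tol)
  })
  if (!fit$converged)
    warning("NMF did not converge within ", max_iter, " iterations")
  cl <- apply(fit$H, 2, which.max)
  names(cl) <- colnames(E)
  list(W = fit$W, H = fit$H, cluster = cl, error = fit$error,
       iterations = fit$iterations, converged = fit$converged)
}

# Relabel a hard clustering so C1 is the largest cluster, C2 the next,
# ties broken by first occurrence (cluster labels are arbitrary).
relabelBySize <- function(cl) {
  tab <- table(cl)
  ord <- names(tab)[order(-tab, match(names(tab), names(tab)))]
  factor(paste0("C", match(as.character(cl), ord)),
         levels = paste0("C", seq_along(ord)))
}

#' Consensus NMF clustering across a range of ranks
#'
#' For each k in `k_range`, runs `n_runs` NMF factorizations from
#' different random initializations; the consensus matrix entry (i, j) is
#' the fraction of runs assigning samples i and j to the same factor. The
#' cophenetic coefficient is the Pearson correlation between the
#' consensus distances (1 - consensus) and the cophenetic distances of
#' their average-linkage dendrogram; final hard assignments come from
#' cutting that dendrogram into k clusters (labels C1.. ordered by
#' decreasing cluster size). The chosen k maximizes the cophenetic
#' coefficient and silhouette widths at that k define the retained-sample
#' mask (width > `threshold`).
#'
#' @param E genes-by-samples matrix (typically the MAD-selected genes).
#' @param k_range ranks to scan (default 2:6).
#' @param n_runs factorizations per rank (default 30, must be >= 2).
#' @param seed global seed; per-run seeds are derived from it.
#' @param threshold silhouette retention threshold (default 0).
#' @param max_iter,tol passed to [nmfFactorize()].
#' @return a [ConsensusResult-class] object.
#' @export
consensusCluster <- function(E, k_range = 2:6, n_runs = 30, seed = 1L,
                             threshold = 0, max_iter = 500, tol = 1e-5) {
  E <- exprsOf(E)
  if (n_runs < 2) stop("n_runs must be >= 2", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  n <- ncol(E)
  samples <- colnames(E)
  Enn <- makeNonnegative(E)
  consensus <- list(); coph <- numeric(); assignK <- list()
  for (k in k_range) {
    C <- matrix(0, n, n)
    for (r in seq_len(n_runs)) {
      run_seed <- stageSeed(seed, k * 1009L + r)
      cl <- nmfFactorize(Enn, k, seed = run_seed, max_iter = max_iter,
                         tol = tol, shift = FALSE)$cluster
      C <- C + outer(cl, cl, "==")
    }
    C <- C / n_runs
    diag(C) <- 1
    dimnames(C) <- list(samples, samples)
    d <- as.dist(1 - C)
    hc <- hclust(d, method = "average")
    cd <- cophenetic(hc)
    coph[paste0("k", k)] <- if (sd(d) == 0 || sd(cd) == 0) 0 else
      cor(d, cd)
    asg <- relabelBySize(cutree(hc, k = k))
    names(asg) <- samples
    consensus[[paste0("k", k)]] <- C
    assignK[[paste0("k", k)]] <- asg
  }
  k_best <- k_range[which.max(coph[paste0("k", k_range)])]
  asg <- assignK[[paste0("k", k_best)]]
  sil <- consensusSilhouette(consensus[[paste0("k", k_best)]], asg)
  res <- new("ConsensusResult", kRange = k_range, consensus = consensus,
             cophenetic = coph, assignmentsByK = assignK,
             k = as.integer(k_best), assignments = asg, silhouette = sil,
             retained = sil > threshold)
  validObject(res)
  res
}

# Silhouette widths on the consensus distance 1 - C. Samples in singleton
# clusters get width 0 (and thus fall at the default retention threshold).
consensusSilhouette <- function(C, assignments) {
  D <- 1 - C
  cl <- as.character(assignments)
  n <- nrow(D)
  w <- numeric(n)
  sizes <- table(cl)
  for (i in seq_len(n)) {
    own <- cl[i]
    if (sizes[own] == 1L) { w[i] <- 0; next }
    a <- mean(D[i, cl == own & seq_len(n) != i])
    b <- min(vapply(setdiff(names(sizes), own),
                    function(g) mean(D[i, cl == g]), numeric(1)))
    denom <- max(a, b)
    w[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  names(w) <- rownames(D)
  w
}

#' Choose the factorization rank by cophenetic maximum
#'
#' @param x a [ConsensusResult-class] or a numeric vector of cophenetic
#'   coefficients named `k2`, `k3`, ... (or by plain integers).
#' @return the k with maximal cophenetic coefficient; ties go to the
#'   smaller k.
#' @export
selectK <- function(x) {
  co <- if (is(x, "ConsensusResult")) x@cophenetic else x
  ks <- as.integer(sub("^k", "", names(co)))
  ord <- order(ks)
  co <- co[ord]; ks <- ks[ord]
  ks[which.max(co)]
}

#' Filter samples by silhouette width on the consensus distance
#'
#' @param result a [ConsensusResult-class].
#' @param threshold retain samples with width strictly above this value
#'   (default 0).
#' @return character vector of retained sample names.
#' @export
silhouetteFilter <- function(result, threshold = 0) {
  stopifnot(is(result, "ConsensusResult"))
  sil <- result@silhouette
  names(sil)[sil > threshold]
}
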