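# Subtype-specific module (ssModule) selection: coexpression modules are a
# pluggable input (any module -> gene-list table); the package scores each
# module's overlap with a subtype's TT and TN gene sets by the
# hypergeometric upper tail and, within hierarchy chains, keeps the most
# significant module.

#' Hypergeometric module overlap test
#'
#' Upper-tail probability P(X >= overlap) of drawing at least the observed
#' overlap when `|module|` genes are drawn without replacement from a
#' universe containing `|target|` successes.
#'
#' @param module,target,universe character gene vectors; module and target
#'   must lie inside the universe.
#' @return the upper-tail hypergeometric p-value.
#' @export
moduleOverlapTest <- function(module, target, universe) {
  module <- unique(module); target <- unique(target)
  universe <- unique(universe)
  if (length(module) == 0) stop("empty module", call. = FALSE)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (length(setdiff(module, universe)) ||
      length(setdiff(target, universe)))
    stop("module and target must be subsets of the universe",
         call. = FALSE)
  ov <- length(intersect(module, target))
  phyper(ov - 1, m = length(target),
         n = length(universe) - length(target),
         k = length(module), lower.tail = FALSE)
}

#' Select subtype-specific modules
#'
#' Keeps modules whose overlaps with both the TT and the TN gene set are
#' significant (p < alpha each); among modules linked by parent-child
#' hierarchy relationships only the most significant one is kept, scored
#' by the product p_TT * p_TN (`combine = "product"`, the default) or by
#' min(p_TT, p_TN) (`combine = "min"`); ties go to the smaller module.
#'
#' @param modules named list of module gene sets.
#' @param tt,tn TT and TN gene sets for one subtype.
#' @param universe background gene list.
#' @param hierarchy optional data.frame with columns `module`, `parent`
#'   describing topology relationships between modules.
#' @param alpha significance threshold (default 0.05).
#' @param combine how to combine p_TT and p_TN for chain resolution.
#' @return data.frame (module, size, p_TT, p_TN, selected) with one row
#'   per input module; `selected` marks the final ssModules.
#' @export
selectSSModules <- function(modules, tt, tn, universe, hierarchy = NULL,
                            alpha = 0.05,
                            combine = c("product", "min")) {
  combine <- match.arg(combine)
  if (length(modules) == 0)
    return(data.frame(module = character(), size = integer(),
                      p_TT = numeric(), p_TN = numeric(),
                      selected = logical()))
  p_tt <- vapply(modules, moduleOverlapTest, numeric(1), target = tt,
                 universe = universe)
  p_tn <- vapply(modules, moduleOverlapTest, numeric(1), target = tn,
                 universe = universe)
  sig <- p_tt < alpha & p_tn < alpha
  score <- if (combine == "product") p_tt * p_tn else pmin(p_tt, p_tn)
  selected <- sig
  if (!is.null(hierarchy) && nrow(hierarchy) > 0 && any(sig)) {
    # connected components (union-find) over hierarchy edges restricted
    # to significant modules
    nms <- names(modules)
    par <- seq_along(nms)
    find <- function(i) { while (par[i] != i) i <- par[i]; i }
    for (r in seq_len(nrow(hierarchy))) {
      a <- match(as.character(hierarchy$module[r]), nms)
      b <- match(as.character(hierarchy$parent[r]), nms)
      if (!is.na(a) && !is.na(b) && sig[a] && sig[b])
        par[find(a)] <- find(b)
    }
    roots <- vapply(seq_along(nms), find, numeric(1))
    for (rt in unique(roots[sig])) {
      members <- nms[roots == rt & sig]
      if (length(members) > 1) {
        best <- members[order(score[members],
                              lengths(modules)[members],
                              members)][1]
        selected[setdiff(members, best)] <- FALSE
      }
    }
  }
  data.frame(module = names(modules),
             size = lengths(modules),
             p_TT = p_tt, p_TN = p_tn, selected = selected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter coexpression-network inputs by node and edge weight
#'
#' Strict-inequality filter applied before module detection: nodes with
#' weight > `gene_weight_min` are kept, and edges with weight >
#' `edge_weight_min` between kept nodes survive.
#'
#' @param nodes data.frame with columns `gene`, `weight`.
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param gene_weight_min node threshold (default 5.5, strict).
#' @param edge_weight_min edge threshold (default 0.6, strict).
#' @return list with filtered `nodes` and `edges` data.frames.
#' @export
moduleFilterInputs <- function(nodes, edges, gene_weight_min = 5.5,
                               edge_weight_min = 0.6) {
  keep_nodes <- nodes[nodes$weight > gene_weight_min, , drop = FALSE]
  keep_edges <- edges[edges$weight > edge_weight_min &
                        edges$from %in% keep_nodes$gene &
                        edges$to %in% keep_nodes$gene, , drop = FALSE]
  list(nodes = keep_nodes, edges = keep_edges)
}
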