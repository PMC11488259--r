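# Regulator ranking and TF-centred regulatory modules.
#
# Modules are extracted by seeded spin-glass community detection on the
# symmetrized |weight| graph; significance comes from relabelling the
# network's gene identifiers at random (the topology and the weight
# multiset are preserved exactly) and recomputing the modularity of the
# original member set under each relabelling.

# Weight matrix (regulators x targets) of any supported network object.
network_weights <- function(grn) {
  if (inherits(grn, "weighted_grn")) grn$weights
  else if (inherits(grn, "lineage_grn")) grn$G
  else if (is.matrix(grn)) grn
  else stopf("unsupported network object of class %s", class(grn)[1])
}

#' Rank regulators by connectivity
#'
#' Connectivity summarizes a regulator's outgoing weights: the mean of
#' their absolute values (\code{mean_abs}, default — robust to sign and
#' out-degree) or their plain sum (\code{sum}).  Only nonzero (skeleton)
#' targets enter the mean.
#'
#' @param grn \code{weighted_grn}, \code{lineage_grn} or weight matrix.
#' @param mode \code{"mean_abs"} or \code{"sum"}.
#' @return data.frame (\code{regulator}, \code{connectivity}) in
#'   decreasing order, ties by gene name.
#' @export
regulator_connectivity <- function(grn, mode = c("mean_abs", "sum")) {
  mode <- match.arg(mode)
  W <- network_weights(grn)
  if (!nrow(W)) stopf("network has no regulators")
  score <- apply(W, 1, function(w) {
    nz <- w[w != 0]
    if (!length(nz)) return(0)
    if (mode == "mean_abs") mean(abs(nz)) else sum(nz)
  })
  df <- data.frame(regulator = rownames(W), connectivity = unname(score))
  df[order(-df$connectivity, df$regulator), , drop = FALSE]
}

# Symmetrized |weight| adjacency of the network.
module_adjacency <- function(W) {
  genes <- union(rownames(W), colnames(W))
  A <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  A[rownames(W), colnames(W)] <- abs(W)
  pmax(A, t(A))
}

# Mean |weight| over undirected edges with both endpoints inside the
# node set `idx` (each edge counted once).
modularity_score <- function(A, idx) {
  sub <- A[idx, idx, drop = FALSE]
  w <- sub[upper.tri(sub)]
  w <- w[w > 0]
  if (!length(w)) return(0)
  mean(w)
}

#' Extract the TF-centred module of a network
#'
#' Runs spin-glass (Potts-model) community detection on the symmetrized
#' absolute-weight graph (restricted to the connected component holding
#' the seed TF) and returns the community containing the seed, scored by
#' its modularity: the mean absolute weight of within-module edges.
#'
#' @param grn \code{weighted_grn}, \code{lineage_grn} or weight matrix.
#' @param seed_tf gene id of the seed transcription factor.
#' @param rng_seed integer seed for the spin-glass annealing.
#' @param spins maximum number of communities (default 25).
#' @return Object of class \code{module_result}: \code{seed_tf},
#'   \code{members}, \code{modularity}, and (after
#'   [module_permutation_test()]) \code{perm_scores}, \code{p_value}.
#' @export
extract_module <- function(grn, seed_tf, rng_seed = 1, spins = 25) {
  W <- network_weights(grn)
  A <- module_adjacency(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
  if (!seed_tf %in% igraph::V(g)$name) stopf("seed TF %s absent from the network", seed_tf)
  if (igraph::degree(g, seed_tf) == 0) stopf("seed TF %s is isolated", seed_tf)
  comp <- igraph::components(g)
  comp_id <- comp$membership[seed_tf]
  gc <- igraph::induced_subgraph(g, vids = names(which(comp$membership == comp_id)))
  cl <- with_seed(rng_seed,
    igraph::cluster_spinglass(gc, weights = igraph::E(gc)$weight,
                              spins = min(spins, igraph::vcount(gc))))
  members <- igraph::V(gc)$name[igraph::membership(cl) == igraph::membership(cl)[seed_tf]]
  structure(list(seed_tf = seed_tf, members = sort(members),
                 modularity = modularity_score(A, match(sort(members), rownames(A))),
                 adjacency = A),
            class = "module_result")
}

#' Permutation significance test of a module
#'
#' Relabels the network's genes by a uniformly random permutation
#' \code{n_perm} times (same topology, same weight multiset), recomputes
#' the modularity of the original member-gene set under each relabelling,
#' and reports the add-one permutation p-value
#' \code{(1 + #(perm >= observed)) / (1 + n_perm)}.
#'
#' @param module a \code{module_result} from [extract_module()].
#' @param n_perm number of permutations (default 1000).
#' @param rng_seed integer seed.
#' @return The module with \code{perm_scores} and \code{p_value} filled
#'   in.
#' @export
module_permutation_test <- function(module, n_perm = 1000, rng_seed = 1) {
  stopifnot(inherits(module, "module_result"))
  if (length(module$members) < 2) stopf("module must contain at least 2 genes")
  A <- module$adjacency
  genes <- rownames(A)
  member_idx <- match(module$members, genes)
  perm_scores <- with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(i) {
      relabel <- sample.int(length(genes))  # new identity of each node
      # genes in the member set under the permuted labelling are the
      # nodes whose new label lands in the member set
      nodes <- which(relabel %in% member_idx)
      modularity_score(A, nodes)
    }, numeric(1))
  })
  module$perm_scores <- perm_scores
  module$p_value <- (1 + sum(perm_scores >= module$modularity)) / (1 + n_perm)
  module
}

#' @export
print.module_result <- function(x, ...) {
  cat(sprintf("module around %s: %d genes, modularity %.4g%s\n",
              x$seed_tf, length(x$members), x$modularity,
              if (!is.null(x$p_value)) sprintf(", permutation p = %.4g", x$p_value) else ""))
  invisible(x)
}

#' Modules for the top-k connected regulators
#'
#' Convenience wrapper: ranks regulators with
#' [regulator_connectivity()], extracts one module per top regulator and
#' attaches permutation p-values.
#'
#' @inheritParams extract_module
#' @param top_k number of seed TFs (default 5).
#' @param n_perm permutations per module (default 1000).
#' @param mode connectivity mode passed to [regulator_connectivity()].
#' @return Named list of \code{module_result} objects.
#' @export
top_regulator_modules <- function(grn, top_k = 5, n_perm = 1000,
                                  mode = c("mean_abs", "sum"), rng_seed = 1) {
  conn <- regulator_connectivity(grn, mode = match.arg(mode))
  seeds <- utils::head(conn$regulator[conn$connectivity > 0], top_k)
  mods <- lapply(seq_along(seeds), function(i) {
    mod <- extract_module(grn, seeds[i], rng_seed = child_seed(rng_seed, i))
    module_permutation_test(mod, n_perm = n_perm,
                            rng_seed = child_seed(rng_seed, 1000 + i))
  })
  stats::setNames(mods, seeds)
}
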