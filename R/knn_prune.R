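# KNN graph construction and negative-binomial link-probability pruning.
#
# Each seed cell's neighborhood is tested for homogeneity: a local NB
# background distribution is fitted per gene over the neighborhood, every
# neighbor's counts are scored under it, and the link probability is the
# geometric mean of the three smallest per-gene tail probabilities.
# Improbable links (P < p_tr) are pruned before metacell construction.

#' Exact k-nearest-neighbour graph in PC space
#'
#' Euclidean KNN over the embedding coordinates.  Exact search (all-pairs
#' distances, computed in blocks); distance ties are broken by lower cell
#' index so the graph is deterministic.
#'
#' @param embedding an \code{sc_embedding} from [compute_pca()], or a
#'   cells x dims coordinate matrix.
#' @param K neighbours per cell (positive, less than the number of cells).
#' @return Object of class \code{knn_graph}: \code{nn} (cells x K integer
#'   matrix of neighbour indices, nearest first), \code{dist} (matching
#'   distances), \code{K}.
#' @export
build_knn <- function(embedding, K) {
  coords <- if (inherits(embedding, "sc_embedding")) embedding$coords else as.matrix(embedding)
  m <- nrow(coords)
  if (!is.numeric(K) || K <= 0) stopf("K must be a positive integer, got %s", format(K))
  K <- as.integer(K)
  if (K >= m) stopf("K = %d must be smaller than the number of cells (%d)", K, m)
  sq <- rowSums(coords^2)
  nn <- matrix(0L, m, K)
  nd <- matrix(0, m, K)
  block <- max(1L, as.integer(2e7 / m))
  for (start in seq(1L, m, by = block)) {
    idx <- start:min(m, start + block - 1L)
    # squared distances, clipped at 0 for numerical safety
    d2 <- pmax(outer(sq[idx], sq, "+") - 2 * tcrossprod(coords[idx, , drop = FALSE], coords), 0)
    for (r in seq_along(idx)) {
      i <- idx[r]
      di <- d2[r, ]
      di[i] <- Inf  # no self-loop
      ord <- order(di, seq_len(m))[seq_len(K)]
      nn[i, ] <- ord
      nd[i, ] <- sqrt(di[ord])
    }
  }
  structure(list(nn = nn, dist = nd, K = K), class = "knn_graph")
}

# Rescale the raw counts of a neighbourhood to its median library size and
# round to the nearest integer, preserving count integrality.
rescale_neighborhood <- function(mat) {
  lib <- colSums(mat)
  if (sum(lib) == 0) stopf("neighbourhood has zero total counts")
  med <- stats::median(lib[lib > 0])
  sf <- ifelse(lib > 0, med / lib, 1)
  round(sweep(mat, 2, sf, "*"))
}

#' Fit the local negative-binomial background model of one neighbourhood
#'
#' Takes the raw counts of a seed cell and its K nearest neighbours,
#' rescales every member to the neighbourhood's median library size, and
#' fits per-gene NB parameters: the mean is the neighbourhood average; the
#' variance is predicted from a second-order polynomial regression of log
#' variance on log mean across the neighbourhood's expressed genes, so
#' single-gene variance estimates borrow strength across genes.  The
#' dispersion is \code{size = mu^2 / (v - mu)} with \code{v} clipped to
#' \code{mu * (1 + 1e-6)} from below (keeps the model at or above Poisson
#' noise and the size parameter finite).
#'
#' @param counts a [count_matrix()].
#' @param graph a \code{knn_graph}.
#' @param cell seed cell index.
#' @return Object of class \code{local_nb_model}: \code{mu}, \code{size}
#'   per gene, \code{coef} (polynomial coefficients), \code{members},
#'   \code{median_lib}.
#' @export
fit_local_background <- function(counts, graph, cell) {
  stopifnot(inherits(counts, "count_matrix"), inherits(graph, "knn_graph"))
  if (graph$K < 3) stopf("need K >= 3 neighbours to fit a background model")
  members <- c(cell, graph$nn[cell, ])
  mat <- as.matrix(counts$values[, members, drop = FALSE])
  mat <- rescale_neighborhood(mat)
  mu <- rowMeans(mat)
  v_emp <- apply(mat, 1, stats::var)
  fit_genes <- mu > 0 & v_emp > 0
  if (sum(fit_genes) >= 3) {
    lx <- log(mu[fit_genes])
    ly <- log(v_emp[fit_genes])
    co <- stats::coef(stats::lm(ly ~ lx + I(lx^2)))
    v_fit <- ifelse(mu > 0, exp(co[1] + co[2] * log(pmax(mu, 1e-300)) +
                                  co[3] * log(pmax(mu, 1e-300))^2), 0)
  } else {
    # too few informative genes: fall back to near-Poisson background
    co <- c(0, 1, 0)
    v_fit <- mu
  }
  v_fit <- pmax(v_fit, mu * (1 + 1e-6))
  size <- ifelse(mu > 0, mu^2 / (v_fit - mu), Inf)
  structure(list(mu = mu, size = size, coef = unname(co),
                 members = members, median_lib = stats::median(colSums(mat))),
            class = "local_nb_model")
}

#' Two-sided NB tail probability of an observed count
#'
#' Probability that a count as extreme as \code{count} arises under the
#' local background model of a gene:
#' \code{min(1, 2 * min(F(x), 1 - F(x - 1)))} with \code{F} the NB
#' cumulative distribution (\code{F(-1) = 0}).  A gene with zero local
#' mean is a point mass at zero.
#'
#' @param model a \code{local_nb_model}.
#' @param gene gene index (or name).
#' @param count observed non-negative integer count.
#' @return Probability in \code{[0, 1]}.
#' @export
gene_count_probability <- function(model, gene, count) {
  stopifnot(inherits(model, "local_nb_model"))
  nb_tail_probability(count, model$mu[gene], model$size[gene])
}

# Vectorized two-sided tail probability under NB(mu, size).
nb_tail_probability <- function(x, mu, size) {
  n <- max(length(x), length(mu), length(size))
  x <- rep_len(x, n); mu <- rep_len(mu, n); size <- rep_len(size, n)
  p <- numeric(n)
  zero <- mu <= 0
  p[zero] <- ifelse(x[zero] == 0, 1, 0)
  if (any(!zero)) {
    pois <- !zero & !is.finite(size)
    if (any(pois)) {
      lo <- stats::ppois(x[pois], lambda = mu[pois])
      hi <- 1 - stats::ppois(x[pois] - 1, lambda = mu[pois])
      p[pois] <- pmin(1, 2 * pmin(lo, hi))
    }
    nb <- !zero & is.finite(size)
    if (any(nb)) {
      lo <- stats::pnbinom(x[nb], size = size[nb], mu = mu[nb])
      hi <- 1 - stats::pnbinom(x[nb] - 1, size = size[nb], mu = mu[nb])
      p[nb] <- pmin(1, 2 * pmin(lo, hi))
    }
  }
  p
}

#' Link probabilities of KNN edges
#'
#' For every requested seed cell, fits the local NB background of its
#' neighbourhood and scores each neighbour's rescaled counts under it.
#' The link probability is the geometric mean of the three smallest
#' per-gene tail probabilities (all genes if fewer than three, with a
#' warning).  Large values mean the neighbour is consistent with the
#' seed's local expression state.
#'
#' @param counts a [count_matrix()].
#' @param graph a \code{knn_graph}.
#' @param cells seed cells to evaluate (default: all cells).  Columns for
#'   unevaluated cells are \code{NA}.
#' @return Object of class \code{link_prob_matrix}: a K x cells matrix of
#'   probabilities with the evaluated cell set in
#'   \code{attr(, "evaluated")}.
#' @export
link_probabilities <- function(counts, graph, cells = NULL) {
  stopifnot(inherits(counts, "count_matrix"), inherits(graph, "knn_graph"))
  m <- ncol(counts$values)
  if (is.null(cells)) cells <- seq_len(m)
  n_genes <- nrow(counts$values)
  n_use <- min(3L, n_genes)
  if (n_genes < 3) warnf("fewer than 3 genes; using all %d for link probabilities", n_genes)
  probs <- matrix(NA_real_, graph$K, m)
  for (j in cells) {
    members <- c(j, graph$nn[j, ])
    mat <- rescale_neighborhood(as.matrix(counts$values[, members, drop = FALSE]))
    mu <- rowMeans(mat)
    v_emp <- apply(mat, 1, stats::var)
    fit_genes <- mu > 0 & v_emp > 0
    if (sum(fit_genes) >= 3) {
      lx <- log(mu[fit_genes]); ly <- log(v_emp[fit_genes])
      co <- stats::coef(stats::lm(ly ~ lx + I(lx^2)))
      lmu <- log(pmax(mu, 1e-300))
      v_fit <- ifelse(mu > 0, exp(co[1] + co[2] * lmu + co[3] * lmu^2), 0)
    } else {
      v_fit <- mu
    }
    v_fit <- pmax(v_fit, mu * (1 + 1e-6))
    size <- ifelse(mu > 0, mu^2 / (v_fit - mu), Inf)
    for (l in seq_len(graph$K)) {
      pg <- nb_tail_probability(mat[, l + 1L], mu, size)
      smallest <- sort(pg, partial = n_use)[seq_len(n_use)]
      probs[l, j] <- exp(mean(log(pmax(smallest, 1e-300))))
    }
  }
  structure(probs, class = "link_prob_matrix", evaluated = cells)
}

#' Prune improbable KNN links
#'
#' Removes every link whose probability falls below \code{p_tr}
#' (default 0.01).  Seeds whose links are all pruned are retained as
#' degree-0 nodes.
#'
#' @param probs a \code{link_prob_matrix}.
#' @param graph the matching \code{knn_graph}.
#' @param p_tr probability threshold in (0, 1); links with
#'   \code{P < p_tr} are pruned (\code{p_tr = 0} keeps everything).
#' @return Object of class \code{pruned_knn}: \code{edges} (data.frame
#'   \code{seed}, \code{neighbor}, \code{prob}), \code{p_tr},
#'   \code{n_cells}, \code{seeds} (cells whose neighbourhoods were
#'   evaluated).
#' @export
prune_graph <- function(probs, graph, p_tr = 0.01) {
  stopifnot(inherits(probs, "link_prob_matrix"), inherits(graph, "knn_graph"))
  if (!is.numeric(p_tr) || p_tr < 0 || p_tr >= 1) {
    stopf("p_tr must lie in [0, 1), got %s", format(p_tr))
  }
  if (nrow(probs) != graph$K || ncol(probs) != nrow(graph$nn)) {
    stopf("link probability matrix (%d x %d) does not match graph (K = %d, %d cells)",
          nrow(probs), ncol(probs), graph$K, nrow(graph$nn))
  }
  cells <- attr(probs, "evaluated")
  seed <- rep(cells, each = graph$K)
  neighbor <- as.vector(t(graph$nn[cells, , drop = FALSE]))
  prob <- as.vector(probs[, cells])
  keep <- !is.na(prob) & prob >= p_tr
  structure(list(
    edges = data.frame(seed = seed[keep], neighbor = neighbor[keep],
                       prob = prob[keep]),
    p_tr = p_tr, n_cells = nrow(graph$nn), seeds = cells
  ), class = "pruned_knn")
}

#' Write a pruned graph as a TSV edge list
#'
#' @param pruned a \code{pruned_knn}.
#' @param path output TSV (columns seed_cell, neighbor_cell, probability).
#' @export
write_pruned_graph <- function(pruned, path) {
  stopifnot(inherits(pruned, "pruned_knn"))
  df <- pruned$edges
  names(df) <- c("seed_cell", "neighbor_cell", "probability")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
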