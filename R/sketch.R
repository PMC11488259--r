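# Seed-cell sampling and sampling-quality metrics.
#
# Geometric sketching samples one cell per occupied hypercube of an
# equal-sided grid laid over the (rescaled) PC space, so rare
# transcriptional states are represented out of proportion to their
# abundance; random sampling is the baseline.  Coverage is quantified by
# the directed Hausdorff distance and the explained-expression-variance
# (EEV) metric, and the seed-number sweep scores the trade-off between
# sample size and effective metacell size.

new_seed_set <- function(idx, method, rng_seed) {
  structure(list(seed_indices = sort(unique(as.integer(idx))),
                 method = method, rng_seed = rng_seed),
            class = "seed_set")
}

#' Geometric sketch of the cell manifold
#'
#' Covering-box sketch in PC space: each axis is min-max rescaled to
#' \code{[0, 1]}, a grid side length is binary-searched so that the number
#' of occupied hypercubes approximates \code{S}, and one uniformly chosen
#' cell per occupied cube is returned (trimmed, or padded with additional
#' cells from random occupied cubes, to hit \code{S} exactly).
#' Deterministic for a fixed \code{rng_seed}.
#'
#' @param embedding \code{sc_embedding} or cells x dims matrix.
#' @param S number of seed cells.
#' @param rng_seed integer seed.
#' @return A \code{seed_set}: sorted unique \code{seed_indices},
#'   \code{method = "geosketch"}, \code{rng_seed}.
#' @export
geometric_sketch <- function(embedding, S, rng_seed = 1) {
  coords <- if (inherits(embedding, "sc_embedding")) embedding$coords else as.matrix(embedding)
  m <- nrow(coords)
  if (S < 1) stopf("S must be at least 1")
  if (S >= m) {
    if (S > m) warnf("S = %d exceeds the %d available cells; returning all cells", S, m)
    return(new_seed_set(seq_len(m), "geosketch", rng_seed))
  }
  rng <- apply(coords, 2, range)
  span <- rng[2, ] - rng[1, ]
  keep_dim <- span > 0
  if (!any(keep_dim)) {  # all cells identical: grid degenerates to one cube
    return(new_seed_set(with_seed(rng_seed, sample.int(m, S)), "geosketch", rng_seed))
  }
  unit <- sweep(sweep(coords[, keep_dim, drop = FALSE], 2, rng[1, keep_dim], "-"),
                2, span[keep_dim], "/")
  occupied_cubes <- function(h) {
    cube <- floor(pmin(unit, 1 - 1e-9) / h)  # boundary cells fall in the last cube
    apply(cube, 1, paste, collapse = ",")
  }
  lo <- 1e-4; hi <- 1  # h = 1 -> one cube; small h -> every cell its own cube
  for (iter in 1:30) {
    mid <- sqrt(lo * hi)
    n_occ <- length(unique(occupied_cubes(mid)))
    if (n_occ >= S) lo <- mid else hi <- mid
  }
  ids <- occupied_cubes(lo)
  with_seed(rng_seed, {
    groups <- split(seq_len(m), ids)
    picks <- vapply(groups, function(g) if (length(g) == 1L) g else sample(g, 1L), integer(1))
    picks <- unname(picks)
    if (length(picks) > S) {
      picks <- sample(picks, S)
    } else if (length(picks) < S) {
      extra_pool <- setdiff(seq_len(m), picks)
      pad <- sample(extra_pool, S - length(picks))
      picks <- c(picks, pad)
    }
    new_seed_set(picks, "geosketch", rng_seed)
  })
}

#' Uniform random seed sample
#'
#' @param cells total number of cells.
#' @param S sample size (capped at \code{cells} with a warning).
#' @param rng_seed integer seed.
#' @return A \code{seed_set} with \code{method = "random"}.
#' @export
random_sample <- function(cells, S, rng_seed = 1) {
  if (S < 1) stopf("S must be at least 1")
  if (S >= cells) {
    if (S > cells) warnf("S = %d exceeds the %d available cells; returning all cells", S, cells)
    return(new_seed_set(seq_len(cells), "random", rng_seed))
  }
  new_seed_set(with_seed(rng_seed, sample.int(cells, S)), "random", rng_seed)
}

#' Directed Hausdorff distance from all cells to the seed set
#'
#' Coverage semantics: the largest Euclidean distance, over all cells,
#' from a cell to its nearest seed in PC space.  Zero iff every cell is a
#' seed; small values mean no transcriptional state is far from a seed.
#'
#' @param embedding \code{sc_embedding} or coordinate matrix.
#' @param seeds a \code{seed_set} (or integer vector of seed indices).
#' @return Non-negative scalar.
#' @export
hausdorff_distance <- function(embedding, seeds) {
  coords <- if (inherits(embedding, "sc_embedding")) embedding$coords else as.matrix(embedding)
  idx <- if (inherits(seeds, "seed_set")) seeds$seed_indices else as.integer(seeds)
  if (!length(idx)) stopf("seed set is empty")
  sc <- coords[idx, , drop = FALSE]
  sq_all <- rowSums(coords^2)
  sq_seed <- rowSums(sc^2)
  d2 <- outer(sq_all, sq_seed, "+") - 2 * tcrossprod(coords, sc)
  sqrt(max(pmax(apply(d2, 1, min), 0)))
}

#' Explained expression variance of a seed set
#'
#' For each of the top \code{K_pcs} principal components, the component's
#' gene-loading vector (genes as observations) is regressed on the
#' normalized expression profiles of the seed cells (predictors, with
#' intercept); the EEV is the eigenvalue-weighted mean of the per-component
#' R-squared values.  EEV = 1 means the seeds span every major
#' transcriptional axis of the full dataset.
#'
#' @param normalized genes x cells matrix from [normalize_counts()].
#' @param embedding the matching \code{sc_embedding}.
#' @param seeds a \code{seed_set} or index vector.
#' @param K_pcs number of leading components to score (default 10).
#' @return Object of class \code{eev_result}: \code{r2} (per component),
#'   \code{weights} (eigenvalue shares, summing to 1), \code{eev}.
#' @export
explained_expression_variance <- function(normalized, embedding, seeds, K_pcs = 10) {
  stopifnot(inherits(embedding, "sc_embedding"))
  if (K_pcs > embedding$n_pcs) {
    stopf("K_pcs = %d exceeds the %d components of the embedding", K_pcs, embedding$n_pcs)
  }
  idx <- if (inherits(seeds, "seed_set")) seeds$seed_indices else as.integer(seeds)
  X <- normalized[, idx, drop = FALSE]
  if (length(idx) >= nrow(normalized)) {
    warnf("seed count (%d) >= gene count (%d): R-squared is degenerate", length(idx), nrow(normalized))
  }
  lam <- embedding$eigenvalues[seq_len(K_pcs)]
  w <- lam / sum(lam)
  r2 <- vapply(seq_len(K_pcs), function(i) {
    y <- embedding$rotation[, i]
    fit <- stats::lm.fit(cbind(1, X), y)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot <= 0) return(1)
    max(0, min(1, 1 - ss_res / ss_tot))
  }, numeric(1))
  structure(list(r2 = r2, weights = w, eev = sum(w * r2)), class = "eev_result")
}

#' Score a seed-number sweep and pick the optimal sample size
#'
#' Normalizes the candidate sample sizes \code{S} and the square-rooted
#' partner counts \code{sqrt(n_s - 1)} to \code{[0, 1]} and scores each
#' candidate by their product; the optimal size is the argmax (ties go to
#' the smaller, cheaper \code{S}).  This balances sampling more seeds
#' against the shrinking effective size of each metacell.
#'
#' @param sweep data.frame with columns \code{S} and \code{n_s} (average
#'   effective metacell size per candidate), or a list of \code{c(S, n_s)}
#'   pairs.
#' @return Object of class \code{seed_sweep}: the input plus columns
#'   \code{S_star}, \code{n_s_star}, \code{score}, and \code{optimal_S}.
#' @export
optimal_seed_number <- function(sweep) {
  if (!is.data.frame(sweep)) {
    sweep <- as.data.frame(do.call(rbind, lapply(sweep, function(p) {
      stats::setNames(as.numeric(p[1:2]), c("S", "n_s"))
    })))
  }
  if (nrow(sweep) < 3) stopf("need at least 3 candidate sample sizes, got %d", nrow(sweep))
  if (any(sweep$n_s < 1)) stopf("every n_s must be >= 1")
  if (max(sweep$S) == min(sweep$S)) stopf("constant S across candidates: normalization undefined")
  r <- sqrt(sweep$n_s - 1)
  if (max(r) == min(r)) stopf("constant n_s across candidates: normalization undefined")
  S_star <- (sweep$S - min(sweep$S)) / (max(sweep$S) - min(sweep$S))
  n_s_star <- (r - min(r)) / (max(r) - min(r))
  score <- S_star * n_s_star
  best <- order(-score, sweep$S)[1]
  out <- cbind(sweep, S_star = S_star, n_s_star = n_s_star, score = score)
  structure(list(table = out, optimal_S = sweep$S[best]), class = "seed_sweep")
}

#' @export
print.seed_sweep <- function(x, ...) {
  print(x$table)
  cat(sprintf("optimal S = %d\n", as.integer(x$optimal_S)))
  invisible(x)
}

#' Sweep candidate seed numbers through the metacell pipeline
#'
#' For each candidate \code{S}: sketch \code{S} seeds, evaluate link
#' probabilities on their neighbourhoods, prune, reassign shared partner
#' cells, and record \code{n_s}, the average number of partner cells per
#' seed.  Feed the result to [optimal_seed_number()].
#'
#' @param counts a [count_matrix()].
#' @param embedding the matching \code{sc_embedding}.
#' @param graph a prebuilt \code{knn_graph} (built once; reused across
#'   candidates).
#' @param candidates integer vector of sample sizes (at least 3).
#' @param p_tr link-probability threshold.
#' @param method \code{"geosketch"} or \code{"random"}.
#' @param rng_seed integer seed.
#' @return data.frame with columns \code{S}, \code{n_s}.
#' @export
sweep_seed_numbers <- function(counts, embedding, graph, candidates,
                               p_tr = 0.01, method = c("geosketch", "random"),
                               rng_seed = 1) {
  method <- match.arg(method)
  m <- ncol(counts$values)
  if (length(candidates) < 3) stopf("need at least 3 candidate sample sizes")
  if (any(candidates < 1 | candidates > m)) stopf("candidates must lie in [1, %d]", m)
  rows <- lapply(seq_along(candidates), function(i) {
    S <- candidates[i]
    seeds <- if (method == "geosketch") {
      geometric_sketch(embedding, S, child_seed(rng_seed, i))
    } else {
      random_sample(m, S, child_seed(rng_seed, i))
    }
    probs <- link_probabilities(counts, graph, cells = seeds$seed_indices)
    pruned <- prune_graph(probs, graph, p_tr)
    asg <- assign_partners(pruned, seeds)
    data.frame(S = S, n_s = mean(asg$partner_counts))
  })
  do.call(rbind, rows)
}
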