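# Lineage-specific GRN inference.
#
# Cell fate probabilities (from any fate-mapping tool, or the built-in
# absorbing-Markov fallback) are lifted to metacells, metacells are
# clustered into lineages (GMM + BIC with a fold-change dominance rule),
# ordered by fate probability into pseudo-time series, and a lagged
# ridge Granger regression on the skeleton scores directed
# regulator-target edges per lineage.  Edge weight = |sum of lag
# coefficients|; a per-regulator 1/rank^2 transform makes weights
# comparable across lineages.

#' Validate and renormalize a cell fate matrix
#'
#' @param probs cells x fates numeric matrix with fate labels as column
#'   names; entries in \code{[0, 1]}, rows renormalized to sum 1.
#' @return The renormalized matrix of class \code{fate_matrix}.
#' @export
fate_matrix <- function(probs) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) colnames(probs) <- paste0("fate", seq_len(ncol(probs)))
  if (any(probs < 0) || any(probs > 1)) stopf("fate probabilities must lie in [0, 1]")
  rs <- rowSums(probs)
  if (any(rs <= 0)) stopf("fate matrix row(s) sum to zero")
  if (any(abs(rs - 1) > 1e-6)) probs <- probs / rs
  class(probs) <- c("fate_matrix", class(probs))
  probs
}

#' Read / write a fate matrix as CSV
#'
#' CSV with a header of fate labels and one row per cell (optional first
#' column of cell identifiers).
#' @param path CSV path.
#' @return A [fate_matrix()].
#' @export
read_fates <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(df[[1]])) {
    rownames(df) <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  fate_matrix(as.matrix(df))
}

#' @rdname read_fates
#' @param fates a [fate_matrix()].
#' @export
write_fates <- function(fates, path) {
  utils::write.csv(as.data.frame(unclass(fates)), path,
                   row.names = !is.null(rownames(fates)))
  invisible(path)
}

#' Lift cell-level fate probabilities to metacells
#'
#' The fate row of a metacell is the mean of its member cells' rows,
#' renormalized.
#'
#' @param fates cell-level [fate_matrix()] (rows align with the cell
#'   indexing used by the assignment).
#' @param metacells a \code{metacell_matrix}.
#' @return Metacell-level [fate_matrix()] (rows named by metacell).
#' @export
metacell_fate_probabilities <- function(fates, metacells) {
  stopifnot(inherits(metacells, "metacell_matrix"))
  if (nrow(fates) < max(unlist(metacells$member_lists))) {
    stopf("fate matrix does not cover all member cells")
  }
  rows <- t(vapply(metacells$member_lists,
                   function(mem) colMeans(fates[mem, , drop = FALSE]),
                   numeric(ncol(fates))))
  rownames(rows) <- names(metacells$member_lists)
  colnames(rows) <- colnames(fates)
  fate_matrix(rows)
}

#' Cluster metacells into lineages from fate probabilities
#'
#' Fits Gaussian mixture models with full covariance and 1 to
#' \code{max_components} components on the fate-probability rows, selects
#' the component count by BIC, and assigns each cluster by a fold-change
#' dominance rule on its mean fate vector: a cluster belongs to fate f if
#' its mean probability toward f is at least \code{fold_k} times its mean
#' toward every other fate; a cluster dominating a strict subset of fates
#' (every subset member at least \code{fold_k} times every fate outside
#' the subset) belongs to each fate in that subset; clusters with no
#' dominance anywhere are uncertain states.  Each lineage is the union of
#' its assigned clusters and all uncertain clusters.
#'
#' @param fates metacell-level [fate_matrix()].
#' @param fold_k dominance fold change (default 2).
#' @param max_components maximum GMM components (default 10).
#' @param rng_seed integer seed for the GMM initialization.
#' @return Object of class \code{lineage_assignment}: \code{cluster_of},
#'   \code{cluster_means}, \code{lineage_members} (metacell indices per
#'   fate), \code{uncertain}, \code{fold_k}, \code{n_components},
#'   \code{bic_trace}.
#' @importFrom mclust mclustBIC
#' @export
cluster_fates <- function(fates, fold_k = 2, max_components = 10, rng_seed = 1) {
  X <- unclass(fates)
  n_fates <- ncol(X)
  if (n_fates < 2) stopf("need at least 2 fates")
  G_max <- min(max_components, nrow(X) - 1)
  # rows sum to 1, so the last fate column is redundant; fit the GMM on
  # the full-rank simplex representation to keep VVV covariances
  # non-singular
  X_fit <- X[, -n_fates, drop = FALSE]
  model <- if (ncol(X_fit) == 1) "V" else "VVV"
  # conjugate prior regularization keeps BIC defined when a cluster has
  # zero variance (all-pure fate rows at exactly 0 or 1)
  fit <- with_seed(rng_seed,
    mclust::Mclust(X_fit, G = 1:G_max, modelNames = model,
                   prior = mclust::priorControl(), verbose = FALSE))
  if (is.null(fit)) {
    fit <- with_seed(rng_seed,
      mclust::Mclust(X_fit, G = 1:G_max, prior = mclust::priorControl(),
                     verbose = FALSE))
  }
  if (is.null(fit)) stopf("Gaussian mixture fit failed")
  cl <- fit$classification
  k <- fit$G
  means <- t(vapply(seq_len(k), function(g) colMeans(X[cl == g, , drop = FALSE]),
                    numeric(n_fates)))
  colnames(means) <- colnames(X)
  assigned <- vector("list", k)
  uncertain_clusters <- integer(0)
  for (g in seq_len(k)) {
    mg <- means[g, ]
    ord <- order(-mg, seq_along(mg))
    ms <- mg[ord]
    j_ok <- NA_integer_
    for (j in seq_len(n_fates - 1)) {
      if (ms[j] >= fold_k * ms[j + 1]) { j_ok <- j; break }
    }
    if (is.na(j_ok)) {
      uncertain_clusters <- c(uncertain_clusters, g)
      assigned[[g]] <- integer(0)
    } else {
      assigned[[g]] <- ord[seq_len(j_ok)]
    }
  }
  uncertain_mc <- which(cl %in% uncertain_clusters)
  lineage_members <- lapply(seq_len(n_fates), function(f) {
    in_f <- which(cl %in% which(vapply(assigned, function(a) f %in% a, logical(1))))
    sort(union(in_f, uncertain_mc))
  })
  names(lineage_members) <- colnames(X)
  if (length(uncertain_clusters) == k) {
    warnf("no cluster shows %g-fold fate dominance; all metacells enter every lineage", fold_k)
  }
  structure(list(cluster_of = cl, cluster_means = means,
                 lineage_members = lineage_members,
                 uncertain = uncertain_mc, fold_k = fold_k,
                 n_components = k, bic_trace = fit$BIC),
            class = "lineage_assignment")
}

#' Order a lineage's metacells into a pseudo-time series
#'
#' Metacells of the lineage sorted by increasing fate probability toward
#' that lineage (fate probability is a proxy for travel time from root to
#' terminal state); ties by metacell index.
#'
#' @param metacells \code{metacell_matrix} (or genes x metacells
#'   expression matrix — pass normalized profiles for Granger fitting).
#' @param fates metacell-level [fate_matrix()].
#' @param assignment a \code{lineage_assignment}.
#' @param lineage fate label (column of \code{fates}).
#' @param expr optional genes x metacells matrix to order instead of the
#'   raw metacell values.
#' @return Object of class \code{lineage_series}: \code{expr} (genes x T,
#'   ordered), \code{metacell_ids}, \code{fate_prob}, \code{lineage}.
#' @export
order_lineage_metacells <- function(metacells, fates, assignment, lineage,
                                    expr = NULL) {
  stopifnot(inherits(assignment, "lineage_assignment"))
  if (!lineage %in% names(assignment$lineage_members)) {
    stopf("unknown lineage '%s'", lineage)
  }
  members <- assignment$lineage_members[[lineage]]
  if (!length(members)) stopf("lineage '%s' has no metacells", lineage)
  mat <- if (!is.null(expr)) expr
         else if (inherits(metacells, "metacell_matrix")) metacells$values
         else as.matrix(metacells)
  p <- unclass(fates)[members, lineage]
  ord <- members[order(p, members)]
  structure(list(expr = mat[, ord, drop = FALSE],
                 metacell_ids = ord,
                 fate_prob = unclass(fates)[ord, lineage],
                 lineage = lineage),
            class = "lineage_series")
}

# Build the lagged design matrix for one target: rows t = L+1..T,
# columns (regulator j, lag l) = x_j(t - l).
lagged_design <- function(series_mat, regulators, L) {
  T_len <- ncol(series_mat)
  rows <- (L + 1):T_len
  X <- matrix(0, length(rows), length(regulators) * L)
  cn <- character(ncol(X))
  col <- 0L
  for (j in seq_along(regulators)) {
    for (l in seq_len(L)) {
      col <- col + 1L
      X[, col] <- series_mat[regulators[j], rows - l]
      cn[col] <- sprintf("%s.lag%d", regulators[j], l)
    }
  }
  colnames(X) <- cn
  X
}

#' Lagged ridge Granger regression for one target gene
#'
#' Predicts the target's ordered expression from the lagged series of its
#' skeleton regulators: minimizes squared error plus
#' \code{lambda_reg} times the squared L2 norm of the lag coefficients
#' (closed-form ridge; unpenalized intercept).  Gene series are
#' standardized to zero mean / unit variance first so
#' \code{lambda_reg = 150} is comparable across genes.  For short
#' lineages (\code{T <= L + 5}) the lag is reduced to
#' \code{max(1, floor((T - 1) / 3))}.  \code{penalty = "group"} instead
#' minimizes the group-lasso form (an unsquared L2 norm per regulator's
#' lag block) by proximal gradient descent.
#'
#' @param series a \code{lineage_series}.
#' @param skeleton a \code{skeleton_network} (or character vector of
#'   regulator ids).
#' @param target target gene id.
#' @param L maximum lag (default 30).
#' @param lambda_reg regularization strength (default 150).
#' @param penalty \code{"ridge"} (default) or \code{"group"}.
#' @param standardize standardize gene series first (default TRUE).
#' @return Object of class \code{granger_coeffs}: \code{coef}
#'   (regulators x lags), \code{intercept}, \code{regulators},
#'   \code{target}, \code{L} (effective), \code{lambda_reg}.
#' @export
fit_granger <- function(series, skeleton, target, L = 30, lambda_reg = 150,
                        penalty = c("ridge", "group"), standardize = TRUE) {
  stopifnot(inherits(series, "lineage_series"))
  penalty <- match.arg(penalty)
  regulators <- if (inherits(skeleton, "skeleton_network")) {
    rownames(skeleton$adj)[skeleton$adj[, target]]
  } else as.character(skeleton)
  regulators <- setdiff(regulators, target)
  if (!length(regulators)) stopf("target %s has no skeleton regulators", target)
  mat <- series$expr
  T_len <- ncol(mat)
  L_eff <- if (T_len <= L + 5) max(1L, as.integer(floor((T_len - 1) / 3))) else as.integer(L)
  if (T_len <= L_eff + 5) {
    stopf("lineage '%s' has only %d metacells; too short for lag %d",
          series$lineage, T_len, L_eff)
  }
  use <- unique(c(regulators, target))
  sub <- mat[use, , drop = FALSE]
  if (standardize) {
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    sdv[sdv == 0] <- 1
    sub <- (sub - mu) / sdv
  }
  X <- lagged_design(sub, regulators, L_eff)
  y <- sub[target, (L_eff + 1):T_len]
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  if (penalty == "ridge") {
    p <- ncol(Xc)
    a <- solve(crossprod(Xc) + lambda_reg * diag(p), crossprod(Xc, yc))
  } else {
    a <- group_lasso_fit(Xc, yc, groups = rep(seq_along(regulators), each = L_eff),
                         lambda = lambda_reg)
  }
  coef_mat <- matrix(a, nrow = length(regulators), ncol = L_eff, byrow = TRUE,
                     dimnames = list(regulators, paste0("lag", seq_len(L_eff))))
  structure(list(coef = coef_mat, intercept = ym - sum(xm * a),
                 regulators = regulators, target = target,
                 L = L_eff, lambda_reg = lambda_reg, penalty = penalty),
            class = "granger_coeffs")
}

# Proximal gradient descent for 0.5*||y - X a||^2 (implicit 0.5 absorbed
# by doubling lambda appropriately is avoided: objective matches
# ||y - X a||^2 + lambda * sum_g ||a_g||_2).
group_lasso_fit <- function(X, y, groups, lambda, max_iter = 2000, tol = 1e-9) {
  p <- ncol(X)
  a <- numeric(p)
  step <- 1 / (2 * max(eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values) + 1e-12)
  gset <- split(seq_len(p), groups)
  for (it in seq_len(max_iter)) {
    grad <- 2 * crossprod(X, X %*% a - y)
    z <- a - step * as.numeric(grad)
    a_new <- numeric(p)
    for (g in gset) {
      ng <- sqrt(sum(z[g]^2))
      if (ng > step * lambda) a_new[g] <- (1 - step * lambda / ng) * z[g]
    }
    if (max(abs(a_new - a)) < tol) { a <- a_new; break }
    a <- a_new
  }
  a
}

#' Granger edge weights of one target
#'
#' Edge weight of regulator j on target i: absolute value of the sum of
#' j's lag coefficients (coefficients of opposite sign across lags can
#' cancel).
#'
#' @param coeffs a \code{granger_coeffs}.
#' @return Named numeric vector (one weight per regulator).
#' @export
granger_edge_weights <- function(coeffs) {
  stopifnot(inherits(coeffs, "granger_coeffs"))
  abs(rowSums(coeffs$coef))
}

#' Per-regulator 1/rank^2 transform of an edge-weight matrix
#'
#' Within each regulator row, the nonzero targets are ranked by
#' decreasing weight (ties toward the lower target index) and the weight
#' is replaced by \code{1 / rank^2}; non-interacting entries stay zero.
#' Makes lineage networks comparable regardless of coefficient scale.
#'
#' @param G non-negative regulators x targets matrix.
#' @return Matrix of the same shape with entries in \code{{0} U {1/i^2}}.
#' @export
rank_transform <- function(G) {
  if (any(G < 0)) stopf("edge weights must be non-negative")
  out <- G * 0
  for (r in seq_len(nrow(G))) {
    nz <- which(G[r, ] > 0)
    if (!length(nz)) next
    ord <- nz[order(-G[r, nz], nz)]
    out[r, ord] <- 1 / seq_along(ord)^2
  }
  out
}

#' Infer the lineage-specific GRN for one lineage
#'
#' Runs [fit_granger()] for every skeleton target with at least one
#' regulator, assembles the edge-weight matrix G (regulators x targets)
#' from [granger_edge_weights()], and adds its [rank_transform()].
#'
#' @param series a \code{lineage_series} (normalized profiles).
#' @param skeleton a \code{skeleton_network}.
#' @inheritParams fit_granger
#' @return Object of class \code{lineage_grn}: \code{G}, \code{G_tilde},
#'   \code{lineage}, \code{L}, \code{lambda_reg}.
#' @export
infer_lineage_grn <- function(series, skeleton, L = 30, lambda_reg = 150,
                              penalty = c("ridge", "group")) {
  stopifnot(inherits(skeleton, "skeleton_network"))
  penalty <- match.arg(penalty)
  adj <- skeleton$adj
  present <- rownames(series$expr)
  targets <- colnames(adj)[colSums(adj) > 0]
  targets <- intersect(targets, present)
  G <- matrix(0, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  L_used <- NA_integer_
  for (tg in targets) {
    regs <- rownames(adj)[adj[, tg]]
    regs <- intersect(regs, present)
    regs <- setdiff(regs, tg)
    if (!length(regs)) next
    co <- fit_granger(series, regs, tg, L = L, lambda_reg = lambda_reg,
                      penalty = penalty)
    L_used <- co$L
    G[co$regulators, tg] <- granger_edge_weights(co)
  }
  structure(list(G = G, G_tilde = rank_transform(G),
                 lineage = series$lineage, L = L_used,
                 lambda_reg = lambda_reg),
            class = "lineage_grn")
}

#' Write a lineage GRN edge list
#'
#' @param lgrn a \code{lineage_grn}.
#' @param path TSV output (regulator, target, granger_weight,
#'   rank_weight).
#' @export
write_lineage_grn <- function(lgrn, path) {
  stopifnot(inherits(lgrn, "lineage_grn"))
  idx <- which(lgrn$G > 0, arr.ind = TRUE)
  df <- data.frame(regulator = rownames(lgrn$G)[idx[, 1]],
                   target = colnames(lgrn$G)[idx[, 2]],
                   granger_weight = lgrn$G[idx],
                   rank_weight = lgrn$G_tilde[idx])
  df <- df[order(-df$granger_weight, df$regulator, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Absorbing-Markov-chain fate probabilities
#'
#' Plumbing fallback when no external fate-mapping output is available: a
#' random walk on the pruned KNN graph (undirected, link probabilities as
#' unnormalized transition weights) with each terminal cell absorbing for
#' its fate; a cell's fate row is its absorption probability vector.
#' Cells with no path to any terminal set get a uniform row with a
#' warning.
#'
#' @param pruned a \code{pruned_knn} evaluated on all cells.
#' @param terminal_cells named list of disjoint, non-empty cell index
#'   sets, one per fate.
#' @return A cell-level [fate_matrix()].
#' @export
markov_fate_probabilities <- function(pruned, terminal_cells) {
  stopifnot(inherits(pruned, "pruned_knn"))
  k <- length(terminal_cells)
  if (k < 2) stopf("need at least 2 terminal sets")
  if (is.null(names(terminal_cells))) names(terminal_cells) <- paste0("fate", seq_len(k))
  all_t <- unlist(terminal_cells)
  if (anyDuplicated(all_t)) stopf("terminal sets must be disjoint")
  if (any(lengths(terminal_cells) == 0)) stopf("terminal sets must be non-empty")
  m <- pruned$n_cells
  e <- pruned$edges
  A <- Matrix::sparseMatrix(i = e$seed, j = e$neighbor, x = e$prob, dims = c(m, m))
  W <- A + Matrix::t(A)  # undirected: reciprocal links accumulate
  fate_of <- rep(NA_integer_, m)
  for (f in seq_len(k)) fate_of[terminal_cells[[f]]] <- f
  trans <- which(is.na(fate_of))
  F_out <- matrix(0, m, k, dimnames = list(NULL, names(terminal_cells)))
  F_out[cbind(all_t, fate_of[all_t])] <- 1
  if (length(trans)) {
    deg <- Matrix::rowSums(W)[trans]
    isolated <- trans[deg == 0]
    reach <- trans[deg > 0]
    if (length(reach)) {
      Dinv <- Matrix::Diagonal(x = 1 / deg[deg > 0])
      Q <- Dinv %*% W[reach, reach, drop = FALSE]
      R <- Dinv %*% W[reach, all_t, drop = FALSE]
      Rf <- matrix(0, length(reach), k)
      for (f in seq_len(k)) {
        cols <- match(terminal_cells[[f]], all_t)
        Rf[, f] <- Matrix::rowSums(R[, cols, drop = FALSE])
      }
      B <- as.matrix(Matrix::solve(Matrix::Diagonal(length(reach)) - Q, Rf))
      bad <- rowSums(B) < 1e-9
      B[bad, ] <- 1 / k
      if (any(bad)) warnf("%d cell(s) cannot reach any terminal set; uniform fate rows assigned", sum(bad))
      F_out[reach, ] <- B / rowSums(B)
    }
    if (length(isolated)) {
      warnf("%d isolated cell(s); uniform fate rows assigned", length(isolated))
      F_out[isolated, ] <- 1 / k
    }
  }
  fate_matrix(F_out)
}
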