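# Global GRN inference on metacell profiles.
#
# GENIE3-style decomposition: one random-forest regression per target
# gene, predictors = all other regulators, edge weight = impurity
# importance normalized to sum one per target.  The weighted network is
# binarized into a skeleton (per-regulator weight threshold + top-n
# targets) that constrains the lineage-specific Granger stage.

#' Depth-normalize and log-transform metacell profiles
#'
#' Metacell library sizes scale with member count, so profiles are
#' rescaled to the median metacell library before \code{log1p}.
#'
#' @param metacells a \code{metacell_matrix} or genes x metacells matrix.
#' @return genes x metacells numeric matrix.
#' @export
normalize_metacells <- function(metacells) {
  mat <- if (inherits(metacells, "metacell_matrix")) metacells$values else as.matrix(metacells)
  lib <- colSums(mat)
  if (any(lib == 0)) stopf("metacell(s) with zero total counts")
  log1p(sweep(mat, 2, lib / stats::median(lib), "/"))
}

#' Infer the global weighted GRN
#'
#' Per target gene, fits a random-forest regression of its normalized
#' metacell profile on the profiles of all other regulators
#' (\code{mtry = floor(sqrt(P))}, impurity importance) and normalizes the
#' importance vector to sum one; a gene is never its own predictor.
#' Deterministic for a fixed \code{rng_seed}.
#'
#' @param metacells \code{metacell_matrix} or genes x samples matrix
#'   (raw aggregated counts; normalized internally unless
#'   \code{normalize = FALSE}).
#' @param regulators character vector of regulator gene ids (>= 2).
#' @param targets target gene ids (default: all genes).
#' @param n_trees trees per target (default 1000).
#' @param rng_seed integer seed.
#' @param normalize depth-normalize + log1p before fitting (default TRUE).
#' @return Object of class \code{weighted_grn}: \code{weights}
#'   (regulators x targets, zero diagonal where a gene is both),
#'   \code{regulator_ids}, \code{target_ids}.
#' @export
infer_global_grn <- function(metacells, regulators, targets = NULL,
                             n_trees = 1000, rng_seed = 1, normalize = TRUE) {
  mat <- if (inherits(metacells, "metacell_matrix")) metacells$values else as.matrix(metacells)
  if (ncol(mat) < 10) stopf("need at least 10 metacells, got %d", ncol(mat))
  regulators <- as.character(regulators)
  if (length(regulators) < 2) stopf("need at least 2 regulators")
  missing <- setdiff(regulators, rownames(mat))
  if (length(missing)) stopf("regulator(s) absent from the matrix: %s",
                             paste(utils::head(missing, 3), collapse = ", "))
  if (is.null(targets)) targets <- rownames(mat)
  targets <- as.character(targets)
  expr <- if (normalize) normalize_metacells(mat) else mat
  # canonical sample order (lexicographic by expression profile) so the
  # result cannot depend on how the metacell columns were arranged
  ord <- do.call(order, c(as.data.frame(t(expr)), list(method = "radix")))
  expr <- expr[, ord, drop = FALSE]
  reg_expr <- t(expr[regulators, , drop = FALSE])  # samples x regulators
  W <- matrix(0, length(regulators), length(targets),
              dimnames = list(regulators, targets))
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    preds <- setdiff(regulators, tg)
    if (length(preds) < 1) next
    y <- expr[tg, ]
    if (stats::sd(y) == 0) {
      warnf("target %s has a constant profile; its column is all zero", tg)
      next
    }
    df <- as.data.frame(reg_expr[, preds, drop = FALSE])
    names(df) <- paste0("g", seq_along(preds))  # syntactic-safe predictor names
    df$..y.. <- y
    fit <- ranger::ranger(
      dependent.variable.name = "..y..", data = df,
      num.trees = n_trees, mtry = max(1L, floor(sqrt(length(preds)))),
      importance = "impurity", num.threads = 1,
      seed = child_seed(rng_seed, ti))
    imp <- pmax(fit$variable.importance, 0)
    if (sum(imp) > 0) W[preds, ti] <- imp / sum(imp)
  }
  structure(list(weights = W, regulator_ids = regulators, target_ids = targets),
            class = "weighted_grn")
}

#' @export
print.weighted_grn <- function(x, ...) {
  cat(sprintf("weighted_grn: %d regulators x %d targets, %d nonzero weights\n",
              nrow(x$weights), ncol(x$weights), sum(x$weights > 0)))
  invisible(x)
}

#' Binarize a weighted GRN into a skeleton
#'
#' Per regulator: keep targets with weight at or above
#' \code{weight_threshold}, then truncate to the \code{top_n} largest
#' (boundary ties resolved toward the lower target index).
#'
#' @param grn a \code{weighted_grn}.
#' @param weight_threshold minimum weight (default 0.001, on the
#'   per-target-normalized scale).
#' @param top_n maximum targets per regulator (default 50).
#' @return Object of class \code{skeleton_network}: logical \code{adj}
#'   (regulators x targets), \code{provenance}, thresholds.
#' @export
binarize_skeleton <- function(grn, weight_threshold = 0.001, top_n = 50) {
  stopifnot(inherits(grn, "weighted_grn"))
  if (weight_threshold <= 0 || top_n <= 0) stopf("thresholds must be positive")
  W <- grn$weights
  adj <- matrix(FALSE, nrow(W), ncol(W), dimnames = dimnames(W))
  for (r in seq_len(nrow(W))) {
    ok <- which(W[r, ] >= weight_threshold)
    ok <- setdiff(ok, match(rownames(W)[r], colnames(W)))  # no self-edges
    if (length(ok) > top_n) {
      ok <- ok[order(-W[r, ok], ok)][seq_len(top_n)]
    }
    adj[r, ok] <- TRUE
  }
  structure(list(adj = adj, provenance = "genie3",
                 weight_threshold = weight_threshold, top_n = top_n),
            class = "skeleton_network")
}

#' Intersect the skeleton with a prior network
#'
#' Keeps an edge only if it is present in both the inferred skeleton and
#' a user-supplied prior (for example a chromatin-derived
#' regulator-target list).
#'
#' @param skeleton a \code{skeleton_network}.
#' @param prior data.frame with columns regulator, target (extra columns
#'   ignored), or a two-column matrix.
#' @return A \code{skeleton_network} with
#'   \code{provenance = "intersected"}.
#' @export
intersect_prior <- function(skeleton, prior) {
  stopifnot(inherits(skeleton, "skeleton_network"))
  prior <- as.data.frame(prior)
  adj <- skeleton$adj
  prior_adj <- matrix(FALSE, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  r <- match(as.character(prior[[1]]), rownames(adj))
  t <- match(as.character(prior[[2]]), colnames(adj))
  ok <- !is.na(r) & !is.na(t)
  prior_adj[cbind(r[ok], t[ok])] <- TRUE
  out <- adj & prior_adj
  if (!any(out)) warnf("intersection with the prior network is empty")
  structure(list(adj = out, provenance = "intersected",
                 weight_threshold = skeleton$weight_threshold,
                 top_n = skeleton$top_n),
            class = "skeleton_network")
}

#' Edge-list view of a network
#'
#' @param x a \code{weighted_grn}, \code{skeleton_network}, or
#'   \code{lineage_grn}.
#' @param ... unused.
#' @return data.frame with columns \code{regulator}, \code{target} and
#'   the available weight columns, sorted by decreasing weight.
#' @export
as_edge_list <- function(x, ...) UseMethod("as_edge_list")

#' @export
as_edge_list.weighted_grn <- function(x, ...) {
  idx <- which(x$weights > 0, arr.ind = TRUE)
  df <- data.frame(regulator = rownames(x$weights)[idx[, 1]],
                   target = colnames(x$weights)[idx[, 2]],
                   weight = x$weights[idx])
  df[order(-df$weight, df$regulator, df$target), , drop = FALSE]
}

#' @export
as_edge_list.skeleton_network <- function(x, ...) {
  idx <- which(x$adj, arr.ind = TRUE)
  df <- data.frame(regulator = rownames(x$adj)[idx[, 1]],
                   target = colnames(x$adj)[idx[, 2]])
  df[order(df$regulator, df$target), , drop = FALSE]
}

#' Read a prior network edge list
#'
#' @param path two- or three-column TSV (regulator, target[, weight]);
#'   a header line is detected and skipped.
#' @return data.frame with columns \code{regulator}, \code{target} and
#'   optionally \code{weight}.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- any(tolower(first) %in% c("regulator", "target", "tf", "source"))
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("regulator", "target")
  if (ncol(df) >= 3) names(df)[3] <- "weight"
  df
}
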