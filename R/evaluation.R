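# Benchmarking predicted networks against ground truth.
#
# The candidate-edge universe is regulators x (universe genes minus
# self).  EPR normalizes early precision by the truth's edge density, so
# random guessing scores 1 regardless of network size.

#' Ground-truth network
#'
#' @param edges data.frame (or 2-column matrix) of directed
#'   regulator -> target pairs; self-loops are rejected.
#' @param regulators candidate regulator set (default: regulators
#'   appearing in \code{edges}).
#' @param universe gene universe for evaluation (default: all genes in
#'   \code{edges} plus \code{regulators}).
#' @return Object of class \code{ground_truth}: \code{edges},
#'   \code{regulators}, \code{universe}, \code{density}.
#' @export
ground_truth <- function(edges, regulators = NULL, universe = NULL) {
  edges <- as.data.frame(edges)[1:2]
  names(edges) <- c("regulator", "target")
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (any(edges$regulator == edges$target)) stopf("ground truth contains self-loops")
  edges <- unique(edges)
  if (is.null(regulators)) regulators <- sort(unique(edges$regulator))
  if (is.null(universe)) universe <- sort(unique(c(edges$regulator, edges$target, regulators)))
  if (!all(edges$regulator %in% regulators)) stopf("edge regulator outside regulator set")
  if (!all(c(edges$regulator, edges$target) %in% universe)) stopf("edge gene outside universe")
  n_cand <- length(regulators) * (length(universe) - 1)
  if (nrow(edges) == 0) stopf("ground truth has no edges")
  structure(list(edges = edges, regulators = regulators, universe = universe,
                 density = nrow(edges) / n_cand),
            class = "ground_truth")
}

# Canonical edge key.
edge_key <- function(reg, tgt) paste(reg, tgt, sep = "\r")

# Coerce a prediction (weighted_grn, lineage_grn G/G_tilde, or a
# data.frame regulator/target/score) to a scored edge data.frame
# restricted to the truth's universe, sorted by decreasing score with
# deterministic ties (score, then lexicographic edge order).
ranked_edges <- function(pred, truth) {
  if (inherits(pred, "weighted_grn")) {
    df <- as_edge_list(pred)
    names(df)[3] <- "score"
  } else if (inherits(pred, "lineage_grn")) {
    idx <- which(pred$G_tilde > 0, arr.ind = TRUE)
    df <- data.frame(regulator = rownames(pred$G_tilde)[idx[, 1]],
                     target = colnames(pred$G_tilde)[idx[, 2]],
                     score = pred$G_tilde[idx])
  } else if (is.matrix(pred)) {
    idx <- which(pred != 0, arr.ind = TRUE)
    df <- data.frame(regulator = rownames(pred)[idx[, 1]],
                     target = colnames(pred)[idx[, 2]],
                     score = pred[idx])
  } else {
    df <- as.data.frame(pred)
    names(df)[1:3] <- c("regulator", "target", "score")
  }
  df <- df[df$regulator %in% truth$regulators &
             df$target %in% truth$universe &
             df$regulator != df$target, , drop = FALSE]
  df[order(-df$score, df$regulator, df$target), , drop = FALSE]
}

#' Early precision rate
#'
#' Fraction of true edges among the top-k predicted edges, divided by
#' the ground truth's edge density (the precision of a random
#' predictor); EPR = 1 is random performance.  By default k is the
#' number of true edges.
#'
#' @param pred prediction: \code{weighted_grn}, \code{lineage_grn},
#'   scored matrix, or data.frame (regulator, target, score).
#' @param truth a [ground_truth()].
#' @param k number of top edges (default \code{nrow(truth$edges)}).
#' @return List with \code{early_precision}, \code{epr}, \code{k}.
#' @export
early_precision_rate <- function(pred, truth, k = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(k)) k <- nrow(truth$edges)
  if (k < 1) stopf("k must be at least 1")
  df <- ranked_edges(pred, truth)
  top <- utils::head(df, k)
  true_keys <- edge_key(truth$edges$regulator, truth$edges$target)
  hits <- sum(edge_key(top$regulator, top$target) %in% true_keys)
  ep <- hits / k
  list(early_precision = ep, epr = ep / truth$density, k = k)
}

#' AUROC and AUPRC of a ranked prediction
#'
#' Computed over the full candidate universe (regulators x non-self
#' genes); candidate edges without a score are appended with score 0.
#' AUROC uses the rank-sum (Mann-Whitney) form with ties averaged; AUPRC
#' is the step-wise area of the precision-recall curve under the
#' deterministic tie order.
#'
#' @inheritParams early_precision_rate
#' @return List with \code{auroc}, \code{auprc}, \code{n_candidates},
#'   \code{n_true}.
#' @export
auroc_auprc <- function(pred, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  df <- ranked_edges(pred, truth)
  cand_reg <- rep(truth$regulators, each = length(truth$universe))
  cand_tgt <- rep(truth$universe, times = length(truth$regulators))
  keep <- cand_reg != cand_tgt
  cand_reg <- cand_reg[keep]; cand_tgt <- cand_tgt[keep]
  keys <- edge_key(cand_reg, cand_tgt)
  score <- stats::setNames(rep(0, length(keys)), keys)
  score[edge_key(df$regulator, df$target)] <- df$score
  label <- keys %in% edge_key(truth$edges$regulator, truth$edges$target)
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0) stopf("truth must contain both true and false candidate edges")
  r <- rank(score, ties.method = "average")
  auroc <- (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(-score, cand_reg, cand_tgt)
  lab_sorted <- label[ord]
  tp <- cumsum(lab_sorted)
  precision <- tp / seq_along(tp)
  auprc <- sum(precision[lab_sorted]) / n_pos
  list(auroc = auroc, auprc = auprc,
       n_candidates = length(keys), n_true = n_pos)
}

#' Differential-expression lineage baseline
#'
#' The baseline lineage network: per terminal state, genes significantly
#' up-regulated versus all other states (one-sided Wilcoxon rank-sum,
#' Benjamini-Hochberg adjusted p < \code{alpha}) induce a subnetwork of
#' the global GRN.
#'
#' @param expr genes x samples matrix (metacell or cell level,
#'   normalized), or a \code{metacell_matrix}/[count_matrix()]
#'   (normalized internally).
#' @param groups factor/character vector of terminal-state labels per
#'   sample (>= 2 levels with >= 3 members each).
#' @param grn \code{weighted_grn} whose induced subnetworks are returned.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return Named list (one element per state): \code{genes} kept and
#'   \code{edges} (data.frame regulator, target, weight) of the induced
#'   subnetwork.
#' @export
deg_lineage_baseline <- function(expr, groups, grn, alpha = 0.05) {
  if (inherits(expr, "metacell_matrix")) expr <- normalize_metacells(expr)
  if (inherits(expr, "count_matrix")) expr <- normalize_counts(expr)
  expr <- as.matrix(expr)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stopf("need at least 2 terminal-state groups")
  if (any(tab < 3)) stopf("every group needs at least 3 members")
  W <- grn$weights
  out <- lapply(names(tab), function(st) {
    in_g <- groups == st
    pvals <- apply(expr, 1, function(x) {
      if (stats::sd(x) == 0) return(1)
      suppressWarnings(stats::wilcox.test(x[in_g], x[!in_g],
                                          alternative = "greater", exact = FALSE)$p.value)
    })
    padj <- stats::p.adjust(pvals, method = "BH")
    kept <- rownames(expr)[!is.na(padj) & padj < alpha]
    regs <- intersect(kept, rownames(W))
    tgts <- intersect(kept, colnames(W))
    if (!length(regs) || !length(tgts)) {
      warnf("no significant subnetwork for state %s", st)
      return(list(genes = kept, edges = data.frame(regulator = character(),
                                                   target = character(),
                                                   weight = numeric())))
    }
    sub <- W[regs, tgts, drop = FALSE]
    idx <- which(sub > 0, arr.ind = TRUE)
    edges <- data.frame(regulator = rownames(sub)[idx[, 1]],
                        target = colnames(sub)[idx[, 2]],
                        weight = sub[idx])
    list(genes = kept, edges = edges[order(-edges$weight), , drop = FALSE])
  })
  stats::setNames(out, names(tab))
}
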