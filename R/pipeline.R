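# End-to-end orchestration: sample -> prune -> metacell -> global GRN ->
# (optional) lineage GRNs, with a validated, serializable configuration
# so any run can be replayed exactly.

#' Pipeline configuration
#'
#' Collects every tunable with its default.  Unknown names are rejected
#' so a config file cannot silently misspell a parameter.
#'
#' @param K KNN neighbours per cell (default 10).
#' @param p_tr link-probability pruning threshold (default 0.01).
#' @param n_seeds number of seed cells, or \code{"auto"} to sweep
#'   \code{seed_grid} and take the optimal size (default \code{"auto"}).
#' @param seed_grid candidate seed numbers for the auto sweep (default
#'   \code{seq(50, 1000, by = 50)}, truncated to the dataset size).
#' @param sketch_method \code{"geosketch"} or \code{"random"}.
#' @param min_partners minimum partners per retained seed (default 5).
#' @param n_hvg highly variable genes (default 3000).
#' @param n_trees random-forest trees per target (default 1000).
#' @param weight_threshold,top_n skeleton binarization (defaults 0.001, 50).
#' @param L,lambda_reg Granger lag and ridge strength (defaults 30, 150).
#' @param fold_k lineage dominance fold change (default 2).
#' @param n_perm module permutations (default 1000).
#' @param n_pcs principal components (default 50).
#' @param rng_seed master seed (default 1).
#' @return Object of class \code{run_config} (a named list).
#' @export
run_config <- function(K = 10, p_tr = 0.01, n_seeds = "auto",
                       seed_grid = seq(50, 1000, by = 50),
                       sketch_method = "geosketch", min_partners = 5,
                       n_hvg = 3000, n_trees = 1000,
                       weight_threshold = 0.001, top_n = 50,
                       L = 30, lambda_reg = 150, fold_k = 2,
                       n_perm = 1000, n_pcs = 50, rng_seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Load a configuration from JSON
#'
#' @param path JSON file of name/value pairs; unknown keys are an error.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config a [run_config()].
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full inference pipeline
#'
#' Stages: gene selection, normalization, PCA, seed sampling (optionally
#' with an automatic seed-number sweep), link-probability pruning,
#' partner reassignment, metacell aggregation, global GRN inference and
#' skeleton binarization, then — when a fate matrix is available —
#' metacell lineage assignment and one Granger lineage GRN per fate.
#' Fully deterministic for a fixed \code{rng_seed}.
#'
#' @param counts a [count_matrix()] (or path readable by
#'   [load_counts()]).
#' @param config a [run_config()].
#' @param fates optional cell-level [fate_matrix()] (or CSV path); when
#'   absent the lineage stage is skipped.
#' @param tf_list optional character vector (or path) of regulator
#'   symbols.
#' @param prior optional prior edge list (data.frame or TSV path) to
#'   intersect with the skeleton.
#' @param out_dir optional directory; when given, edge lists, metacells,
#'   and \code{config.json} are written there.
#' @param verbose log stage progress to stderr (default TRUE).
#' @return List with \code{seeds}, \code{pruned}, \code{assignment},
#'   \code{metacells}, \code{grn}, \code{skeleton}, \code{lineage_grns},
#'   \code{lineage_assignment}, \code{sweep}, \code{config}.
#' @export
run_pipeline <- function(counts, config = run_config(), fates = NULL,
                         tf_list = NULL, prior = NULL, out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                                    sprintf(...)))
  if (is.character(counts)) counts <- load_counts(counts)
  if (is.character(fates)) fates <- read_fates(fates)
  if (is.character(tf_list) && length(tf_list) == 1 && file.exists(tf_list)) {
    tf_list <- read_tf_list(tf_list)
  }
  if (is.character(prior)) prior <- read_edge_list(prior)
  cfg <- config
  m <- ncol(counts$values)

  say("selecting genes (%d HVGs) and normalizing %d cells", cfg$n_hvg, m)
  sel <- select_genes(counts, tf_list %||% character(), n_hvg = cfg$n_hvg)
  counts_sel <- count_matrix(counts$values[sel$genes, , drop = FALSE],
                             sel$genes, counts$cell_ids)
  norm <- normalize_counts(counts_sel)
  n_pcs <- min(cfg$n_pcs, min(dim(norm)) - 1)
  emb <- compute_pca(norm, n_pcs = n_pcs)

  say("building exact KNN graph (K = %d)", cfg$K)
  graph <- build_knn(emb, K = cfg$K)

  sweep_res <- NULL
  n_seeds <- cfg$n_seeds
  if (identical(n_seeds, "auto")) {
    grid <- unique(pmin(cfg$seed_grid, m - 1))
    grid <- grid[grid >= 2]
    say("sweeping %d candidate seed numbers", length(grid))
    sw <- sweep_seed_numbers(counts_sel, emb, graph, grid, p_tr = cfg$p_tr,
                             method = cfg$sketch_method,
                             rng_seed = child_seed(cfg$rng_seed, 11))
    sweep_res <- optimal_seed_number(sw)
    n_seeds <- sweep_res$optimal_S
    say("optimal seed number: %d", n_seeds)
  }

  say("sampling %d seed cells (%s)", n_seeds, cfg$sketch_method)
  seeds <- if (cfg$sketch_method == "geosketch") {
    geometric_sketch(emb, n_seeds, rng_seed = child_seed(cfg$rng_seed, 12))
  } else {
    random_sample(m, n_seeds, rng_seed = child_seed(cfg$rng_seed, 12))
  }

  say("scoring link probabilities for %d seed neighbourhoods", length(seeds$seed_indices))
  probs <- link_probabilities(counts_sel, graph, cells = seeds$seed_indices)
  pruned <- prune_graph(probs, graph, p_tr = cfg$p_tr)
  assignment <- assign_partners(pruned, seeds)
  metacells <- aggregate_metacells(counts_sel, assignment,
                                   min_partners = cfg$min_partners)
  say("retained %d metacells", ncol(metacells$values))

  say("inferring global GRN (%d regulators, %d trees)", length(sel$regulators), cfg$n_trees)
  grn <- infer_global_grn(metacells, sel$regulators, n_trees = cfg$n_trees,
                          rng_seed = child_seed(cfg$rng_seed, 13))
  skeleton <- binarize_skeleton(grn, weight_threshold = cfg$weight_threshold,
                                top_n = cfg$top_n)
  if (!is.null(prior)) {
    say("intersecting skeleton with prior (%d edges)", nrow(prior))
    skeleton <- intersect_prior(skeleton, prior)
  }

  lineage_grns <- NULL
  lin_assign <- NULL
  if (!is.null(fates)) {
    say("lineage stage: %d fates", ncol(fates))
    mc_fates <- metacell_fate_probabilities(fates, metacells)
    lin_assign <- cluster_fates(mc_fates, fold_k = cfg$fold_k,
                                rng_seed = child_seed(cfg$rng_seed, 14))
    expr <- normalize_metacells(metacells)
    lineage_grns <- lapply(colnames(mc_fates), function(lin) {
      series <- order_lineage_metacells(metacells, mc_fates, lin_assign, lin,
                                        expr = expr)
      say("  lineage %s: %d metacells", lin, ncol(series$expr))
      infer_lineage_grn(series, skeleton, L = cfg$L, lambda_reg = cfg$lambda_reg)
    })
    names(lineage_grns) <- colnames(mc_fates)
  } else {
    say("no fate matrix supplied; lineage stage skipped")
  }

  result <- list(seeds = seeds, pruned = pruned, assignment = assignment,
                 metacells = metacells, grn = grn, skeleton = skeleton,
                 lineage_grns = lineage_grns, lineage_assignment = lin_assign,
                 sweep = sweep_res, selection = sel, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as_edge_list(grn), file.path(out_dir, "grn_global.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as_edge_list(skeleton), file.path(out_dir, "skeleton.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_metacells(metacells, file.path(out_dir, "metacells"),
                    cell_ids = counts$cell_ids)
    if (!is.null(lineage_grns)) {
      for (lin in names(lineage_grns)) {
        write_lineage_grn(lineage_grns[[lin]],
                          file.path(out_dir, sprintf("grn_%s.tsv", lin)))
      }
    }
    if (!is.null(sweep_res)) {
      utils::write.table(sweep_res$table, file.path(out_dir, "seed_sweep.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_config(cfg, file.path(out_dir, "config.json"))
    say("outputs written to %s", out_dir)
  }
  invisible(result)
}
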