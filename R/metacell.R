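# Disjoint metacell construction from pruned seed neighbourhoods.
#
# A partner cell shared by several seeds is assigned to exactly one of
# them, so no cell contributes to two metacell profiles — the property
# that prevents the spurious gene-gene correlations induced by
# overlapping-neighbourhood imputation.

#' Assign partner cells to seeds
#'
#' Every non-seed cell linked to at least one seed in the pruned graph is
#' assigned to the seed with the largest link probability; exact
#' probability ties go to the tied seed with the fewest partners assigned
#' so far (better expression estimates for small metacells), remaining
#' ties to the lowest seed index.  Cells are processed in decreasing
#' order of their best link probability, which fixes the outcome of the
#' fewest-partners rule.  Seed cells always belong to their own metacell
#' and are never partners of another seed.
#'
#' @param pruned a \code{pruned_knn} whose evaluated cells include the
#'   seeds.
#' @param seeds a \code{seed_set} (or integer vector).
#' @return Object of class \code{metacell_assignment}: \code{partner_of}
#'   (integer vector over all cells; the owning seed index, the cell's own
#'   index for seeds, \code{NA} if unassigned) and \code{partner_counts}
#'   (named by seed; number of partners, seed excluded).
#' @export
assign_partners <- function(pruned, seeds) {
  stopifnot(inherits(pruned, "pruned_knn"))
  idx <- if (inherits(seeds, "seed_set")) seeds$seed_indices else sort(unique(as.integer(seeds)))
  if (!all(idx %in% pruned$seeds)) {
    stopf("%d seed(s) have no evaluated neighbourhood in the pruned graph",
          sum(!(idx %in% pruned$seeds)))
  }
  m <- pruned$n_cells
  is_seed <- logical(m); is_seed[idx] <- TRUE
  e <- pruned$edges
  e <- e[e$seed %in% idx & !is_seed[e$neighbor], , drop = FALSE]

  partner_of <- rep(NA_integer_, m)
  partner_of[idx] <- idx
  counts <- stats::setNames(integer(length(idx)), idx)
  if (nrow(e)) {
    best <- tapply(e$prob, e$neighbor, max)
    cells <- as.integer(names(best))
    ord <- order(-as.numeric(best), cells)  # decreasing best probability, then cell index
    links_by_cell <- split(e[c("seed", "prob")], e$neighbor)
    for (k in ord) {
      cell <- cells[k]
      li <- links_by_cell[[as.character(cell)]]
      cand <- li$seed[li$prob == max(li$prob)]
      if (length(cand) > 1L) {
        load <- counts[as.character(cand)]
        cand <- cand[load == min(load)]
        cand <- min(cand)  # lowest seed index as the final tie-break
      }
      partner_of[cell] <- cand
      counts[as.character(cand)] <- counts[as.character(cand)] + 1L
    }
  }
  structure(list(partner_of = partner_of, partner_counts = counts,
                 seeds = idx), class = "metacell_assignment")
}

#' Aggregate metacell expression profiles
#'
#' Sums the raw counts of each seed and its assigned partners into one
#' column per metacell, then drops seeds with fewer than
#' \code{min_partners} partner cells (the seed itself is not counted) —
#' small neighbourhoods give unreliable profiles.  Cells of dropped seeds
#' become unassigned and are excluded downstream.
#'
#' @param counts a [count_matrix()].
#' @param assignment a \code{metacell_assignment}.
#' @param min_partners minimum partner count (default 5).
#' @param normalized optional genes x cells matrix; when supplied,
#'   normalized values are aggregated instead of raw counts.
#' @return Object of class \code{metacell_matrix}: \code{values} (genes x
#'   metacells), \code{member_lists} (cell indices per metacell, named by
#'   seed), \code{seed_cells}, \code{min_partners}.
#' @export
aggregate_metacells <- function(counts, assignment, min_partners = 5,
                                normalized = NULL) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(assignment, "metacell_assignment"))
  keep <- assignment$seeds[assignment$partner_counts >= min_partners]
  if (!length(keep)) {
    stopf("no seed retains >= %d partner cells; sample fewer seeds or increase K",
          min_partners)
  }
  mat <- if (is.null(normalized)) counts$values else normalized
  member_lists <- lapply(keep, function(s) which(assignment$partner_of == s))
  values <- vapply(member_lists,
                   function(mem) as.numeric(Matrix::rowSums(mat[, mem, drop = FALSE])),
                   numeric(nrow(mat)))
  rownames(values) <- counts$gene_ids
  colnames(values) <- paste0("MC_", keep)
  names(member_lists) <- colnames(values)
  structure(list(values = values, member_lists = member_lists,
                 seed_cells = keep, min_partners = min_partners),
            class = "metacell_matrix")
}

#' @export
print.metacell_matrix <- function(x, ...) {
  sizes <- lengths(x$member_lists)
  cat(sprintf("metacell_matrix: %d genes x %d metacells (member cells: median %d, range %d-%d)\n",
              nrow(x$values), ncol(x$values), as.integer(stats::median(sizes)),
              min(sizes), max(sizes)))
  invisible(x)
}

#' Write metacell profiles and memberships
#'
#' @param metacells a \code{metacell_matrix}.
#' @param dir output directory; writes \code{metacells.mtx},
#'   \code{genes.tsv}, \code{barcodes.tsv} and \code{membership.tsv}
#'   (columns cell_index, metacell_id).
#' @param cell_ids optional cell identifiers for the membership table.
#' @export
write_metacells <- function(metacells, dir, cell_ids = NULL) {
  stopifnot(inherits(metacells, "metacell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(metacells$values, sparse = TRUE),
                  file.path(dir, "metacells.mtx"))
  writeLines(rownames(metacells$values), file.path(dir, "genes.tsv"))
  writeLines(colnames(metacells$values), file.path(dir, "barcodes.tsv"))
  mem <- do.call(rbind, lapply(names(metacells$member_lists), function(mc) {
    cells <- metacells$member_lists[[mc]]
    data.frame(cell = if (is.null(cell_ids)) cells else cell_ids[cells],
               metacell_id = mc)
  }))
  utils::write.table(mem, file.path(dir, "membership.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
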