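#' Construct a validated UMI count matrix
#'
#' Wraps a genes x cells matrix of raw unique-molecular-identifier (UMI)
#' counts together with its gene and cell identifiers.  All downstream
#' stages (background models, metacell aggregation) operate on these raw
#' integer counts; normalization is always an explicit, separate step.
#'
#' @param values genes x cells matrix (base or \code{Matrix}) of
#'   non-negative integer counts.
#' @param gene_ids,cell_ids character vectors of unique identifiers; taken
#'   from \code{dimnames(values)} when omitted.
#' @return An object of class \code{count_matrix} with elements
#'   \code{values} (a \code{dgCMatrix}), \code{gene_ids}, \code{cell_ids}.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values)) {
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("C", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    stopf("identifier lists (%d genes, %d cells) do not match matrix dimensions %d x %d",
          length(gene_ids), length(cell_ids), nrow(values), ncol(values))
  }
  if (anyDuplicated(gene_ids)) {
    stopf("duplicate gene identifiers: %s",
          paste(utils::head(gene_ids[duplicated(gene_ids)], 3), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    stopf("duplicate cell identifiers: %s",
          paste(utils::head(cell_ids[duplicated(cell_ids)], 3), collapse = ", "))
  }
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  x <- values@x
  if (length(x)) {
    bad <- which(x < 0 | x != round(x))
    if (length(bad)) {
      ij <- entry_coordinates(values, bad[1])
      stopf("count matrix entry at gene row %d, cell column %d is %g (must be a non-negative integer)",
            ij[1], ij[2], x[bad[1]])
    }
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "count_matrix")
}

# Row/column of the k-th stored entry of a CsparseMatrix.
entry_coordinates <- function(m, k) {
  col <- findInterval(k - 0.5, m@p)
  c(m@i[k] + 1L, col)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %.0f total UMIs\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Load a UMI count matrix from disk
#'
#' Reads either a dense CSV/TSV (gene rows, header of cell identifiers,
#' first column of gene identifiers) or a MatrixMarket coordinate triplet
#' (1-based indices) accompanied by \code{genes.tsv} and
#' \code{barcodes.tsv} files in the same directory.  All-zero genes are
#' retained; any filtering is explicit elsewhere.
#'
#' @param path file path (for \code{mtx}: the \code{.mtx} file; companions
#'   are looked up next to it).
#' @param format one of \code{"mtx"}, \code{"csv"}, \code{"tsv"}; guessed
#'   from the extension by default.
#' @return A [count_matrix()].
#' @export
load_counts <- function(path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stopf("cannot guess format from extension '.%s'; pass format=", ext))
  }
  if (format == "mtx") {
    dir <- dirname(path)
    gene_file <- file.path(dir, "genes.tsv")
    cell_file <- file.path(dir, "barcodes.tsv")
    if (!file.exists(gene_file) || !file.exists(cell_file)) {
      stopf("MTX input requires companion files %s and %s", gene_file, cell_file)
    }
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stopf("malformed MatrixMarket file %s: %s",
                                            path, conditionMessage(e)))
    genes <- utils::read.table(gene_file, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(cell_file, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    return(count_matrix(m, genes, cells))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stopf("malformed %s header in %s: %s", format, path,
                              conditionMessage(e)))
  m <- as.matrix(df)
  if (!is.numeric(m)) stopf("non-numeric entries in %s", path)
  count_matrix(m, rownames(df), colnames(df))
}

#' Write a count matrix to disk
#'
#' Inverse of [load_counts()]: \code{mtx} writes a MatrixMarket triplet
#' plus \code{genes.tsv}/\code{barcodes.tsv}; \code{csv}/\code{tsv} write a
#' dense table with gene rows and a cell-identifier header.
#'
#' @param counts a [count_matrix()].
#' @param path output path (\code{.mtx} file for MTX).
#' @param format \code{"mtx"}, \code{"csv"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts, path, format = c("mtx", "csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(counts, "count_matrix"))
  if (format == "mtx") {
    Matrix::writeMM(counts$values, path)
    dir <- dirname(path)
    writeLines(counts$gene_ids, file.path(dir, "genes.tsv"))
    writeLines(counts$cell_ids, file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- as.data.frame(as.matrix(counts$values))
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = TRUE, col.names = NA)
  }
  invisible(path)
}

#' Depth-normalize and log-transform counts
#'
#' Scales every cell to a common library size and applies
#' \code{log1p}.  This normalized matrix feeds PCA, sketching and the
#' tree-ensemble regression only; the negative-binomial background models
#' and metacell aggregation always use raw counts.
#'
#' @param counts a [count_matrix()].
#' @param target_size positive target library size, or \code{"median"}
#'   (default) for the median library size across non-empty cells.
#' @return A dense genes x cells numeric matrix.  All-zero cells are
#'   dropped with a warning.
#' @export
normalize_counts <- function(counts, target_size = "median") {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- Matrix::colSums(counts$values)
  if (all(lib == 0)) stopf("all cells have zero counts")
  keep <- lib > 0
  if (any(!keep)) {
    warnf("excluding %d all-zero cell(s): %s", sum(!keep),
          paste(utils::head(counts$cell_ids[!keep], 5), collapse = ", "))
  }
  if (identical(target_size, "median")) {
    target_size <- stats::median(lib[keep])
  }
  if (!is.numeric(target_size) || target_size <= 0) {
    stopf("target_size must be positive or \"median\"")
  }
  m <- as.matrix(counts$values[, keep, drop = FALSE])
  m <- sweep(m, 2, lib[keep] / target_size, "/")
  log1p(m)
}

#' Principal component embedding of cells
#'
#' PCA of the normalized expression matrix with cells as observations and
#' genes as (centred, unscaled) features.  The per-component eigenvalues
#' and gene loadings are kept alongside the scores: the eigenvalues weight
#' the explained-expression-variance metric and the loadings are its
#' regression responses.
#'
#' @param normalized genes x cells numeric matrix from
#'   [normalize_counts()].
#' @param n_pcs number of components (default 50, capped at
#'   \code{min(genes, cells) - 1}).
#' @return An object of class \code{sc_embedding}: \code{coords} (cells x
#'   n_pcs scores), \code{n_pcs}, \code{eigenvalues} (non-increasing),
#'   \code{rotation} (genes x n_pcs loadings), \code{cell_ids},
#'   \code{gene_ids}.
#' @export
compute_pca <- function(normalized, n_pcs = 50) {
  if (!is.matrix(normalized)) normalized <- as.matrix(normalized)
  max_pcs <- min(nrow(normalized), ncol(normalized)) - 1L
  if (n_pcs < 1 || n_pcs > max_pcs) {
    stopf("n_pcs = %d outside [1, %d] for a %d x %d matrix",
          n_pcs, max_pcs, nrow(normalized), ncol(normalized))
  }
  pc <- stats::prcomp(t(normalized), center = TRUE, scale. = FALSE, rank. = n_pcs)
  structure(list(
    coords = pc$x[, seq_len(n_pcs), drop = FALSE],
    n_pcs = as.integer(n_pcs),
    eigenvalues = pc$sdev[seq_len(n_pcs)]^2,
    rotation = pc$rotation[, seq_len(n_pcs), drop = FALSE],
    cell_ids = colnames(normalized),
    gene_ids = rownames(normalized)
  ), class = "sc_embedding")
}

#' Select highly variable genes and regulators
#'
#' Ranks genes by variance-to-mean dispersion of their normalized
#' expression, keeps the top \code{n_hvg}, and adds every transcription
#' factor from \code{tf_list} present in the matrix.  Regulators are the
#' intersection of the selection with \code{tf_list}; with an empty list
#' all selected genes are candidate regulators.
#'
#' @param counts a [count_matrix()].
#' @param tf_list character vector of transcription-factor symbols (may be
#'   empty).
#' @param n_hvg number of highly variable genes (default 3000).
#' @return List with \code{genes} (selected gene ids, original matrix
#'   order), \code{regulators}, and \code{dispersion} (named scores).
#' @export
select_genes <- function(counts, tf_list = character(), n_hvg = 3000) {
  stopifnot(inherits(counts, "count_matrix"))
  norm <- normalize_counts(counts)
  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  names(disp) <- rownames(norm)
  n_keep <- min(n_hvg, length(disp))
  ord <- order(-disp, seq_along(disp))  # ties by original gene order
  hvg <- names(disp)[ord[seq_len(n_keep)]]
  tf_present <- intersect(tf_list, counts$gene_ids)
  genes <- counts$gene_ids[counts$gene_ids %in% union(hvg, tf_present)]
  if (length(tf_list)) {
    regulators <- intersect(genes, tf_list)
    if (!length(regulators)) {
      warnf("no transcription factor from tf_list found; using all selected genes as regulators")
      regulators <- genes
    }
  } else {
    regulators <- genes
  }
  list(genes = genes, regulators = regulators, dispersion = disp)
}

#' Read a transcription-factor list
#'
#' @param path plain-text file, one gene symbol per line.
#' @return Character vector of unique symbols.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- unique(trimws(readLines(path, warn = FALSE)))
  x[nzchar(x)]
}
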