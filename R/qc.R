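# Quality control, normalization, embedding, and marker-based annotation.

#' Quality-control parameters
#'
#' Defaults follow the standard droplet scRNA-seq filters: discard cells
#' with fewer than 250 RNA UMIs, then genes with fewer than 3 UMIs across
#' all retained cells.
#'
#' @param min_cell_umis minimum UMIs per cell (cells below are removed).
#' @param min_gene_umis minimum total UMIs per gene over retained cells.
#' @return object of class `qc_params`.
#' @export
qc_params <- function(min_cell_umis = 250L, min_gene_umis = 3L) {
  stopifnot(min_cell_umis >= 1, min_gene_umis >= 1)
  structure(list(min_cell_umis = as.integer(min_cell_umis),
                 min_gene_umis = as.integer(min_gene_umis)),
            class = "qc_params")
}

#' Filter a count matrix by cell and gene UMI totals
#'
#' Cells are filtered first on their totals in the input matrix; genes are
#' then filtered on their totals over the retained cells. "Fewer than" is
#' strict: a cell with exactly `min_cell_umis` UMIs is kept.
#'
#' @param counts gene x cell count matrix.
#' @param params a [qc_params()].
#' @param exclude_cells optional character vector of cells to drop first
#'   (hook for external low-quality/doublet masks).
#' @return filtered matrix; attribute `qc_report` records cells and genes
#'   removed at each step.
#' @export
filter_counts <- function(counts, params = qc_params(), exclude_cells = NULL) {
  if (nrow(counts) == 0 || ncol(counts) == 0) abort("empty count matrix")
  if (!is.null(exclude_cells)) {
    counts <- counts[, !(colnames(counts) %in% exclude_cells), drop = FALSE]
  }
  cell_tot <- Matrix::colSums(counts)
  keep_cells <- cell_tot >= params$min_cell_umis
  out <- counts[, keep_cells, drop = FALSE]
  gene_tot <- Matrix::rowSums(out)
  keep_genes <- gene_tot >= params$min_gene_umis
  out <- out[keep_genes, , drop = FALSE]
  if (nrow(out) == 0 || ncol(out) == 0) {
    abort("no cells or genes survive filtering (min_cell_umis = %d, min_gene_umis = %d)",
          params$min_cell_umis, params$min_gene_umis)
  }
  attr(out, "qc_report") <- list(
    cells_removed = sum(!keep_cells),
    genes_removed = sum(!keep_genes),
    cells_retained = ncol(out),
    genes_retained = nrow(out)
  )
  out
}

#' Depth-normalize and log2-transform counts
#'
#' Scales each cell to the median library size, then applies log2(x + 1).
#' Zeros stay zero and proportional count vectors map to identical profiles.
#' Per-gene centering and scaling is deliberately deferred to embedding
#' input (see [scale_genes()]), keeping the expression matrix sparse.
#'
#' @param counts filtered gene x cell count matrix.
#' @return sparse matrix of normalized log2 expression.
#' @export
normalize_log <- function(counts) {
  counts <- as_count_matrix(counts)
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) abort("cells with zero totals; run filter_counts() first")
  f <- stats::median(tot) / tot
  scaled <- counts %*% Matrix::Diagonal(x = f)
  dimnames(scaled) <- dimnames(counts)
  out <- scaled
  out@x <- log2(out@x + 1)
  out
}

#' Center and scale genes for embedding input
#'
#' @param expr normalized gene x cell matrix.
#' @return dense cell x gene matrix with unit-variance genes (zero-variance
#'   genes left centered only).
#' @export
scale_genes <- function(expr) {
  x <- t(as.matrix(expr))
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

# indices of the `n` most variable genes of a normalized expression matrix
top_variable_genes <- function(expr, n = 100L) {
  v <- apply(as.matrix(expr), 1, stats::var)
  head(order(v, decreasing = TRUE), min(n, length(v)))
}

# PCA with deterministic sign convention (largest-magnitude loading positive)
pca_embed <- function(x, n_comp = 2L) {
  n_comp <- min(n_comp, ncol(x), nrow(x) - 1L)
  if (n_comp < 1) abort("too few cells for PCA")
  cov <- crossprod(x) / (nrow(x) - 1)
  ev <- eigen(cov, symmetric = TRUE)
  v <- ev$vectors[, seq_len(n_comp), drop = FALSE]
  for (j in seq_len(ncol(v))) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  x %*% v
}

#' Two-dimensional embedding of normalized expression
#'
#' Computes a 2-D embedding on top principal components of the most variable
#' genes. The built-in backend is PCA (the first two components), which is
#' fully deterministic; a neighborhood-preserving nonlinear backend (e.g. a
#' UMAP implementation) can be plugged in via `method`.
#'
#' @param expr normalized gene x cell matrix.
#' @param seed integer seed, forwarded to pluggable backends.
#' @param n_var number of top-variance genes used.
#' @param method `"pca"` or a function `(scaled cell x gene matrix, seed)`
#'   returning an n x 2 coordinate matrix.
#' @return n_cells x 2 coordinate matrix (rows named by cell).
#' @export
embed2d <- function(expr, seed = 1L, n_var = 100L, method = "pca") {
  if (ncol(expr) < 20) abort("need at least 20 cells to embed")
  idx <- top_variable_genes(expr, n_var)
  x <- scale_genes(expr[idx, , drop = FALSE])
  coords <- if (is.function(method)) {
    method(x, seed)
  } else {
    match.arg(method, "pca")
    pca_embed(x, 2L)
  }
  if (ncol(coords) != 2) abort("embedding backend must return 2 columns")
  rownames(coords) <- colnames(expr)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Marker rule set for cell-type and CD4-subtype annotation
#'
#' The default cell-type rules use one literature-standard marker per PBMC
#' population (IL7R for CD4 T, CD8A for CD8 T, SPON2 for NK, MS4A1 for B,
#' CD14 for classical and FCGR3A for non-classical monocytes, CLEC10A for
#' dendritic cells, PF4 for platelets). CD4 subtypes are defined by
#' high/low patterns of SELL, S100A4 and GPR183.
#'
#' @param celltype_markers named list: cell type -> character vector of
#'   marker genes.
#' @param cd4_subtypes named list: subtype -> named character vector of
#'   `"high"`/`"low"` over the dichotomization genes.
#' @return object of class `marker_rules`.
#' @export
marker_rules <- function(celltype_markers = as.list(CANONICAL_MARKERS),
                         cd4_subtypes = CD4_SUBTYPE_PATTERNS) {
  structure(list(celltype_markers = celltype_markers,
                 cd4_subtypes = cd4_subtypes),
            class = "marker_rules")
}

# restrict a rule set to genes present; error unless drop_missing
bind_rules <- function(rules, genes, drop_missing = FALSE) {
  have <- vapply(rules$celltype_markers, function(g) all(g %in% genes), logical(1))
  if (!all(have) && !drop_missing) {
    abort("marker genes absent from matrix for cell type(s): %s",
          paste(names(rules$celltype_markers)[!have], collapse = ", "))
  }
  rules$celltype_markers <- rules$celltype_markers[have]
  sub_ok <- vapply(rules$cd4_subtypes, function(p) all(names(p) %in% genes), logical(1))
  if (!all(sub_ok)) {
    if (!drop_missing) abort("CD4 subtype rule genes absent from matrix")
    rules$cd4_subtypes <- rules$cd4_subtypes[sub_ok]
  }
  if (length(rules$celltype_markers) == 0) abort("no usable cell type rules")
  rules
}

#' Cluster cells on top principal components
#'
#' @param expr normalized gene x cell matrix.
#' @param k number of clusters.
#' @param seed integer seed (k-means initialization).
#' @param n_pcs,n_var PCs and top-variance genes used.
#' @return integer cluster vector named by cell.
#' @export
cluster_cells <- function(expr, k, seed = 1L, n_pcs = 10L, n_var = 100L) {
  idx <- top_variable_genes(expr, n_var)
  x <- scale_genes(expr[idx, , drop = FALSE])
  pcs <- pca_embed(x, n_pcs)
  km <- withr::with_seed(seed, stats::kmeans(pcs, centers = k, nstart = 10L,
                                             iter.max = 50L))
  stats::setNames(km$cluster, colnames(expr))
}

#' Annotate cell types and CD4 subtypes by marker rules
#'
#' Clusters (supplied or computed) are assigned the cell type whose marker
#' genes have the highest cluster-mean z-score across clusters; clusters
#' expressing none of the marker genes are labelled `"unassigned"`. Cells of
#' clusters annotated `"CD4 T"` are sub-labelled by dichotomizing each CD4
#' subtype gene at its median over CD4 cells and matching the high/low
#' pattern with the fewest mismatches (alphabetical tie-break).
#'
#' @param expr normalized gene x cell matrix.
#' @param rules a [marker_rules()]; rules referencing absent genes raise an
#'   error unless `drop_missing_rules = TRUE`.
#' @param clusters optional named integer vector; computed with
#'   [cluster_cells()] (k = number of cell type rules) when absent.
#' @param seed integer seed for clustering.
#' @param drop_missing_rules drop rules whose genes are absent instead of
#'   erroring.
#' @return data frame (`cell`, `cluster`, `celltype`, `cd4_subtype`).
#' @export
annotate_cells <- function(expr, rules = marker_rules(), clusters = NULL,
                           seed = 1L, drop_missing_rules = FALSE) {
  rules <- bind_rules(rules, rownames(expr), drop_missing_rules)
  if (is.null(clusters)) {
    clusters <- cluster_cells(expr, k = length(rules$celltype_markers), seed = seed)
  }
  cl_ids <- sort(unique(clusters))
  marker_genes <- unique(unlist(rules$celltype_markers))
  cl_mean <- vapply(cl_ids, function(cl) {
    Matrix::rowMeans(expr[marker_genes, names(clusters)[clusters == cl], drop = FALSE])
  }, numeric(length(marker_genes)))
  cl_mean <- matrix(cl_mean, nrow = length(marker_genes),
                    dimnames = list(marker_genes, cl_ids))
  mu <- rowMeans(cl_mean)
  sdv <- apply(cl_mean, 1, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (cl_mean - mu) / sdv
  type_of_cluster <- vapply(seq_along(cl_ids), function(jc) {
    if (all(cl_mean[, jc] == 0)) return("unassigned")
    score <- vapply(rules$celltype_markers, function(g) mean(z[g, jc]), numeric(1))
    best <- names(score)[score == max(score)]
    if (length(best) > 1) {
      warning(sprintf("cluster %s: tie between %s; using alphabetical order",
                      cl_ids[jc], paste(best, collapse = ", ")), call. = FALSE)
      best <- sort(best)
    }
    best[1]
  }, character(1))
  ann <- data.frame(cell = names(clusters), cluster = unname(clusters),
                    celltype = type_of_cluster[match(clusters, cl_ids)],
                    cd4_subtype = NA_character_, stringsAsFactors = FALSE)
  cd4_cells <- ann$cell[ann$celltype == "CD4 T"]
  if (length(cd4_cells) > 1 && length(rules$cd4_subtypes) > 0) {
    sub_genes <- unique(unlist(lapply(rules$cd4_subtypes, names)))
    ex <- as.matrix(expr[sub_genes, cd4_cells, drop = FALSE])
    med <- apply(ex, 1, stats::median)
    high <- ex > med  # genes x cells
    pat <- vapply(rules$cd4_subtypes, function(p) p[sub_genes] == "high",
                  logical(length(sub_genes)))
    mism <- t(pat) %*% (!high) + t(!pat) %*% high  # subtypes x cells mismatches
    best <- apply(mism, 2, function(mm) sort(names(mm)[mm == min(mm)])[1])
    ann$cd4_subtype[match(cd4_cells, ann$cell)] <- best
  }
  ann
}
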