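# Cell-type and CD4-subtype composition shift testing across donor/lane
# groups, using pairwise two-proportion chi-square tests.

#' Group x cell-type composition table
#'
#' Complete cross-tabulation (including empty combinations) of cells per
#' group and cell type, with row-normalized frequencies.
#'
#' @param annotation data frame with `cell`, `group`, and the type column.
#' @param by type column to tabulate (default `"celltype"`, or
#'   `"cd4_subtype"` for subtype composition).
#' @return object of class `composition_table` with `counts` and `freq`
#'   matrices (rows = groups).
#' @export
composition <- function(annotation, by = "celltype") {
  if (!all(c("cell", "group", by) %in% names(annotation))) {
    abort("annotation must have columns `cell`, `group`, `%s`", by)
  }
  ann <- annotation[!is.na(annotation[[by]]), , drop = FALSE]
  counts <- unclass(table(ann$group, ann[[by]]))
  freq <- sweep(counts, 1, pmax(rowSums(counts), 1), "/")
  structure(list(counts = counts, freq = freq), class = "composition_table")
}

#' Pairwise tests for shifts of one cell type's proportion between groups
#'
#' For every pair of groups, tests equality of the cell type's proportion
#' (type vs rest) with the standard two-proportion chi-square test with
#' Yates continuity correction, adjusting p-values across pairs with the
#' Holm procedure — i.e. `stats::pairwise.prop.test()` with default
#' arguments. Groups with zero cells yield missing entries.
#'
#' @param tab a [composition()] table.
#' @param celltype column of `tab` to test.
#' @param groups optional subset/order of groups (default: all rows).
#' @param p.adjust.method adjustment across pairs (default `"holm"`).
#' @param correct apply Yates continuity correction.
#' @return symmetric matrix of adjusted p-values (diagonal `NA`).
#' @export
pairwise_prop_tests <- function(tab, celltype, groups = NULL,
                                p.adjust.method = "holm", correct = TRUE) {
  stopifnot(inherits(tab, "composition_table"))
  if (!(celltype %in% colnames(tab$counts))) {
    abort("cell type %s not in composition table", celltype)
  }
  groups <- groups %||% rownames(tab$counts)
  if (length(groups) < 2) abort("need at least 2 groups")
  x <- tab$counts[groups, celltype]
  n <- rowSums(tab$counts)[groups]
  k <- length(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  ok <- n > 0
  if (any(!ok)) {
    warning("group(s) with zero cells; their p-values are NA", call. = FALSE)
  }
  if (sum(ok) >= 2) {
    pt <- suppressWarnings(
      stats::pairwise.prop.test(x[ok], n[ok], p.adjust.method = p.adjust.method,
                                correct = correct))
    sub <- matrix(NA_real_, sum(ok), sum(ok))
    sub[lower.tri(sub)] <- pt$p.value[lower.tri(pt$p.value, diag = TRUE)]
    sub[upper.tri(sub)] <- t(sub)[upper.tri(sub)]
    p[ok, ok] <- sub
  }
  p
}

#' Mixing-status proportion screen for one donor
#'
#' Convenience wrapper reporting, per cell type, the adjusted p-values for
#' the donor's unmixed-lane vs mixed-lane group contrasts (e.g. A1 vs A2
#' and A1 vs A3) — the contrasts where a mixing-induced composition shift
#' would appear.
#'
#' @param annotation annotation data frame with `group`, `celltype`.
#' @param unmixed_group reference group label (default `"A1"`).
#' @param mixed_groups mixed group labels (default `c("A2", "A3")`).
#' @param extra_groups additional groups included in the test family
#'   (default `"A4"`, the technical replicate).
#' @param by type column to test.
#' @return data frame (`celltype`, `contrast`, `p_adj`).
#' @export
mixing_proportion_screen <- function(annotation, unmixed_group = "A1",
                                     mixed_groups = c("A2", "A3"),
                                     extra_groups = "A4", by = "celltype") {
  tab <- composition(annotation, by = by)
  groups <- intersect(c(unmixed_group, mixed_groups, extra_groups),
                      rownames(tab$counts))
  rows <- list()
  for (ty in colnames(tab$counts)) {
    p <- pairwise_prop_tests(tab, ty, groups = groups)
    for (mg in intersect(mixed_groups, groups)) {
      rows[[paste(ty, mg)]] <- data.frame(
        celltype = ty, contrast = paste(unmixed_group, "vs", mg),
        p_adj = p[unmixed_group, mg], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
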