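# Balanced-subsample / 2-D kernel density / Jensen-Shannon divergence
# comparison of group expression states, with a donor-label permutation null.
#
# The workflow per iteration: draw equal numbers of cells of one cell type
# from each donor/lane group, recompute a 2-D embedding on the subsample,
# estimate a group-wise kernel density on a shared grid, compute all
# pairwise JSDs, and min-max scale the off-diagonal entries to [0, 1].
# Summaries average the scaled JSD within named comparison sets (inter-donor,
# mixing status, technical replicate) across iterations.

#' Default group comparison sets
#'
#' Groups are (donor, lane) labels such as `"A1"`. The defaults compare
#' donor A lane 1 against donors B/C in mixed lanes (inter-donor), unmixed
#' donor A (lanes 1 and 4) against mixed donor A (lanes 2 and 3) for mixing
#' status, and lanes 1 vs 4 as the technical-replicate noise floor.
#'
#' @return named list of lists of group-label pairs.
#' @export
default_comparison_sets <- function() {
  list(
    inter_donor = list(c("A1", "B2"), c("A1", "B3"), c("A1", "C2"), c("A1", "C3")),
    mixing = list(c("A1", "A2"), c("A1", "A3"), c("A4", "A2"), c("A4", "A3")),
    technical = list(c("A1", "A4"))
  )
}

#' Parameters for the JSD mixing-effect analysis
#'
#' @param n_iterations balanced-subsample iterations.
#' @param n_permutations donor-label permutations for the null.
#' @param grid_size kernel density grid points per axis.
#' @param min_cells_per_group cell types with fewer cells than this in any
#'   compared group are excluded.
#' @param seed integer seed controlling subsampling and permutation.
#' @param comparison_sets named list of group-pair lists (see
#'   [default_comparison_sets()]); the `mixing` and `technical` sets drive
#'   the permutation verdict.
#' @param permute_donor donor whose lane labels are shuffled under the null.
#' @param n_var top-variance genes used for the per-iteration embedding.
#' @param embed embedding backend passed to [embed2d()] (`"pca"` or a
#'   function); the embedding is recomputed on every subsample.
#' @param celltypes optional subset of cell types to analyze.
#' @param stratify_celltype cell type whose subsampling is additionally
#'   stratified by CD4 subtype.
#' @return object of class `jsd_params`.
#' @export
jsd_params <- function(n_iterations = 100L,
                       n_permutations = NULL,
                       grid_size = 25L,
                       min_cells_per_group = 50L,
                       seed = 1L,
                       comparison_sets = default_comparison_sets(),
                       permute_donor = "A",
                       n_var = 60L,
                       embed = "pca",
                       celltypes = NULL,
                       stratify_celltype = "CD4 T") {
  stopifnot(n_iterations >= 1, grid_size >= 10, min_cells_per_group >= 1)
  if (!all(c("mixing", "technical") %in% names(comparison_sets))) {
    abort("comparison_sets must include `mixing` and `technical`")
  }
  structure(list(
    n_iterations = as.integer(n_iterations),
    n_permutations = as.integer(n_permutations %||% n_iterations),
    grid_size = as.integer(grid_size),
    min_cells_per_group = as.integer(min_cells_per_group),
    seed = as.integer(seed),
    comparison_sets = comparison_sets,
    permute_donor = permute_donor,
    n_var = as.integer(n_var),
    embed = embed,
    celltypes = celltypes,
    stratify_celltype = stratify_celltype
  ), class = "jsd_params")
}

comparison_groups <- function(comparison_sets) {
  sort(unique(unlist(comparison_sets)))
}

#' Balanced subsample of one cell type across groups
#'
#' Draws `m = min(group sizes)` cells of the given cell type from each
#' group, without replacement. When `stratify_by` is supplied (CD4 T cells
#' are stratified by CD4 subtype), equal numbers of each stratum are drawn
#' from each group instead.
#'
#' @param annotation data frame with columns `cell`, `celltype`, `group`,
#'   and the stratification column if used.
#' @param celltype cell type to subsample.
#' @param groups group labels to balance across.
#' @param min_cells_per_group eligibility threshold; any group below it
#'   raises an error (callers exclude the cell type instead).
#' @param stratify_by optional annotation column for stratified balancing.
#' @param seed integer seed.
#' @return character vector of selected cell ids.
#' @export
balanced_subsample <- function(annotation, celltype, groups,
                               min_cells_per_group = 50L, stratify_by = NULL,
                               seed = 1L) {
  ann <- annotation[annotation$celltype == celltype &
                      annotation$group %in% groups, , drop = FALSE]
  missing <- setdiff(groups, unique(ann$group))
  if (length(missing) > 0) {
    abort("no %s cells in group(s): %s", celltype, paste(missing, collapse = ", "))
  }
  sizes <- table(factor(ann$group, levels = groups))
  if (any(sizes < min_cells_per_group)) {
    abort("cell type %s has < %d cells in group(s): %s", celltype,
          min_cells_per_group,
          paste(names(sizes)[sizes < min_cells_per_group], collapse = ", "))
  }
  withr::with_seed(seed, {
    if (is.null(stratify_by)) {
      m <- min(sizes)
      cells <- unlist(lapply(groups, function(g) {
        pool <- ann$cell[ann$group == g]
        sample(pool, m)
      }), use.names = FALSE)
    } else {
      strata <- ann[[stratify_by]]
      strata[is.na(strata)] <- "<none>"
      tab <- table(factor(ann$group, levels = groups), strata)
      m_s <- apply(tab, 2, min)
      m_s <- m_s[m_s > 0]
      if (length(m_s) == 0) abort("no stratum is present in every group")
      cells <- unlist(lapply(groups, function(g) {
        unlist(lapply(names(m_s), function(s) {
          pool <- ann$cell[ann$group == g & strata == s]
          sample(pool, m_s[[s]])
        }), use.names = FALSE)
      }), use.names = FALSE)
    }
  })
  cells
}

#' Two-dimensional kernel density on a shared grid
#'
#' Axis-separable Gaussian kernel density (the classic bivariate
#' normal-reference estimator) evaluated on a `grid_size` x `grid_size`
#' lattice over a fixed window and normalized to sum to one. Bandwidths use
#' the normal-reference rule `4 * 1.06 * min(sd, IQR/1.34) * n^(-1/5)` per
#' axis; an axis with zero spread falls back to `1e-6` of the window width
#' with a warning.
#'
#' @param coords n x 2 coordinate matrix.
#' @param window list with numeric `x` and `y` ranges; defaults to the
#'   coordinate ranges expanded by one bandwidth per side.
#' @param grid_size grid points per axis.
#' @param h optional precomputed per-axis bandwidths (normal-reference rule
#'   applied otherwise).
#' @return object of class `density_grid`: probability matrix `z` plus grid
#'   axes, window, and bandwidths.
#' @export
kde2d_grid <- function(coords, window = NULL, grid_size = 25L, h = NULL) {
  if (nrow(coords) < 2) abort("need at least 2 points for a density estimate")
  if (any(!is.finite(coords))) abort("coordinates must be finite")
  h <- h %||% c(MASS::bandwidth.nrd(coords[, 1]), MASS::bandwidth.nrd(coords[, 2]))
  if (is.null(window)) {
    window <- list(x = range(coords[, 1]) + c(-1, 1) * max(h, 1e-6),
                   y = range(coords[, 2]) + c(-1, 1) * max(h, 1e-6))
  }
  widths <- c(diff(window$x), diff(window$y))
  if (any(h <= 0)) {
    warning("zero spread on an axis; applying bandwidth floor", call. = FALSE)
    h <- pmax(h, 1e-6 * widths)
  }
  kd <- MASS::kde2d(coords[, 1], coords[, 2], h = h, n = grid_size,
                    lims = c(window$x, window$y))
  z <- kd$z / sum(kd$z)
  structure(list(z = z, x = kd$x, y = kd$y, window = window, bandwidth = h),
            class = "density_grid")
}

# shared evaluation window: union of group ranges + 1 max bandwidth per side
shared_window <- function(coords_list) {
  all_pts <- do.call(rbind, coords_list)
  h <- vapply(coords_list, function(co) {
    c(MASS::bandwidth.nrd(co[, 1]), MASS::bandwidth.nrd(co[, 2]))
  }, numeric(2))
  hmax <- pmax(apply(h, 1, max), 1e-6)
  list(x = range(all_pts[, 1]) + c(-1, 1) * hmax[1],
       y = range(all_pts[, 2]) + c(-1, 1) * hmax[2])
}

#' Jensen-Shannon divergence between two density grids
#'
#' `JSD(P, Q) = KL(P || M)/2 + KL(Q || M)/2` with `M = (P + Q)/2`, base-2
#' logarithms and the convention `0 * log(0/x) = 0`; symmetric, zero iff
#' `P = Q`, and bounded by 1.
#'
#' @param p,q `density_grid` objects on the same window, or nonnegative
#'   numeric vectors summing to one.
#' @return divergence in `[0, 1]`.
#' @export
jsd <- function(p, q) {
  if (inherits(p, "density_grid") || inherits(q, "density_grid")) {
    if (!(inherits(p, "density_grid") && inherits(q, "density_grid"))) {
      abort("both arguments must be density grids")
    }
    if (!identical(dim(p$z), dim(q$z)) ||
        !isTRUE(all.equal(p$window, q$window))) {
      abort("density grids must share window and grid size")
    }
    p <- as.vector(p$z)
    q <- as.vector(q$z)
  }
  if (length(p) != length(q)) abort("distributions must have equal length")
  m <- (p + q) / 2
  kl <- function(a) {
    # m can round to zero when a is subnormal; that cell's true contribution
    # is below 1e-320 bits, so restricting to m > 0 is numerically exact
    i <- a > 0 & m > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  min(max((kl(p) + kl(q)) / 2, 0), 1)
}

# symmetric matrix of pairwise JSDs over a named list of grids
jsd_matrix <- function(grids) {
  k <- length(grids)
  m <- matrix(0, k, k, dimnames = list(names(grids), names(grids)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- jsd(grids[[i]], grids[[j]])
    }
  }
  m
}

# min-max scale off-diagonal entries to [0, 1] (diagonal stays 0)
scale01_offdiag <- function(m) {
  off <- row(m) != col(m)
  v <- m[off]
  if (max(v) > min(v)) m[off] <- (v - min(v)) / (max(v) - min(v))
  m
}

# mean scaled JSD over the pairs of one comparison set
comparison_means <- function(m, comparison_sets) {
  vapply(comparison_sets, function(pairs) {
    mean(vapply(pairs, function(pr) m[pr[1], pr[2]], numeric(1)))
  }, numeric(1))
}

# one subsample -> embed -> KDE -> scaled JSD round for one cell type.
# `x` is the dense (variable genes x cells) expression of this cell type.
jsd_iteration <- function(x, ann_type, groups, params, stratify_by, seed) {
  cells <- balanced_subsample(ann_type, ann_type$celltype[1], groups,
                              params$min_cells_per_group, stratify_by, seed)
  xs <- scale_genes_dense(x[, cells, drop = FALSE])
  coords <- if (is.function(params$embed)) {
    params$embed(xs, seed)
  } else {
    pca_embed(xs, 2L)
  }
  grp <- ann_type$group[match(cells, ann_type$cell)]
  idx_by_group <- split(seq_along(grp), factor(grp, levels = groups))
  coords_list <- lapply(idx_by_group, function(i) coords[i, , drop = FALSE])
  h_list <- lapply(coords_list, function(co) {
    c(MASS::bandwidth.nrd(co[, 1]), MASS::bandwidth.nrd(co[, 2]))
  })
  hmax <- pmax(Reduce(pmax, h_list), 1e-6)
  win <- list(x = range(coords[, 1]) + c(-1, 1) * hmax[1],
              y = range(coords[, 2]) + c(-1, 1) * hmax[2])
  grids <- mapply(kde2d_grid, coords_list, h = h_list,
                  MoreArgs = list(window = win, grid_size = params$grid_size),
                  SIMPLIFY = FALSE)
  scale01_offdiag(jsd_matrix(grids))
}

# center/scale columns of an already-dense genes x cells slab (cells x genes out)
scale_genes_dense <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  v <- (rowSums(x * x) - n * mu * mu) / (n - 1)
  s <- sqrt(pmax(v, 0))
  s[s == 0] <- 1
  t((x - mu) / s)
}

# cell types eligible under the minimum-group-size rule, with reasons
eligible_celltypes <- function(annotation, groups, params) {
  types <- params$celltypes %||%
    sort(setdiff(unique(annotation$celltype), c(NA, "unassigned")))
  excluded <- list()
  keep <- character(0)
  for (ty in types) {
    sizes <- table(factor(annotation$group[annotation$celltype == ty],
                          levels = groups))
    if (any(sizes < params$min_cells_per_group)) {
      excluded[[ty]] <- sprintf(
        "fewer than %d cells in group(s) %s (sizes: %s)",
        params$min_cells_per_group,
        paste(names(sizes)[sizes < params$min_cells_per_group], collapse = ", "),
        paste(sizes, collapse = "/"))
    } else {
      keep <- c(keep, ty)
    }
  }
  list(keep = keep, excluded = excluded)
}

# dense variable-gene slab per cell type (variance computed once per type)
celltype_slab <- function(expr, annotation, celltype, groups, n_var) {
  cells <- annotation$cell[annotation$celltype == celltype &
                             annotation$group %in% groups]
  x <- as.matrix(expr[, cells, drop = FALSE])
  v <- apply(x, 1, stats::var)
  x[head(order(v, decreasing = TRUE), min(n_var, nrow(x))), , drop = FALSE]
}

#' Iterated balanced-subsample JSD analysis
#'
#' Runs `n_iterations` rounds of balanced subsampling, per-subsample 2-D
#' embedding, group-wise kernel density estimation on a shared window, and
#' pairwise JSD with per-iteration min-max scaling, for every eligible cell
#' type. Cell types with fewer than `min_cells_per_group` cells in any
#' compared group are excluded with a logged reason.
#'
#' @param expr normalized gene x cell matrix (see [normalize_log()]).
#' @param annotation data frame with columns `cell`, `celltype`, `group`
#'   (donor/lane label such as `"A1"`), and `cd4_subtype` for stratified
#'   balancing.
#' @param params a [jsd_params()].
#' @return object of class `jsd_result`: `pairs` (long data frame of scaled
#'   pairwise JSDs per cell type and iteration), `summary` (mean and SD per
#'   comparison set), `excluded` (named reasons), `subsample_sizes`.
#' @export
run_jsd_iterations <- function(expr, annotation, params = jsd_params()) {
  groups <- comparison_groups(params$comparison_sets)
  elig <- eligible_celltypes(annotation, groups, params)
  seeds <- derive_seeds(params$seed, params$n_iterations)
  pairs_long <- list()
  summaries <- list()
  sizes <- list()
  for (ty in elig$keep) {
    stratify_by <- if (identical(ty, params$stratify_celltype)) "cd4_subtype" else NULL
    ann_type <- annotation[annotation$celltype == ty &
                             annotation$group %in% groups, , drop = FALSE]
    x <- celltype_slab(expr, annotation, ty, groups, params$n_var)
    comp <- matrix(NA_real_, params$n_iterations, length(params$comparison_sets),
                   dimnames = list(NULL, names(params$comparison_sets)))
    mats <- vector("list", params$n_iterations)
    for (i in seq_len(params$n_iterations)) {
      m <- jsd_iteration(x, ann_type, groups, params, stratify_by, seeds[i])
      comp[i, ] <- comparison_means(m, params$comparison_sets)
      mats[[i]] <- m
    }
    idx <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
    pairs_long[[ty]] <- data.frame(
      celltype = ty,
      iteration = rep(seq_len(params$n_iterations), each = nrow(idx)),
      group_i = rep(groups[idx[, 1]], params$n_iterations),
      group_j = rep(groups[idx[, 2]], params$n_iterations),
      jsd = unlist(lapply(mats, function(m) m[idx])),
      stringsAsFactors = FALSE
    )
    summaries[[ty]] <- data.frame(
      celltype = ty,
      comparison = colnames(comp),
      mean = colMeans(comp),
      sd = apply(comp, 2, stats::sd),
      n_iterations = params$n_iterations,
      stringsAsFactors = FALSE
    )
    n_sub <- length(balanced_subsample(ann_type, ty, groups,
                                       params$min_cells_per_group, stratify_by,
                                       seeds[1]))
    sizes[[ty]] <- n_sub
  }
  structure(list(
    pairs = do.call(rbind, c(pairs_long, list(make.row.names = FALSE))),
    summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
    excluded = elig$excluded,
    subsample_sizes = unlist(sizes),
    params = params
  ), class = "jsd_result")
}

#' @export
print.jsd_result <- function(x, ...) {
  cat("Balanced-subsample JSD analysis\n")
  cat(sprintf("  %d iterations, grid %d x %d\n", x$params$n_iterations,
              x$params$grid_size, x$params$grid_size))
  if (length(x$excluded) > 0) {
    cat("  excluded:", paste(names(x$excluded), collapse = ", "), "\n")
  }
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Donor-label permutation null and significance verdict
#'
#' Shuffles the lane labels of the permuted donor's cells (within each cell
#' type, preserving the number of cells per donor/lane group) and reruns one
#' balanced-subsample JSD round per permutation, recording the permuted
#' mixing-status and technical-replicate scores. The observed differential
#' (mean mixing JSD minus mean technical JSD) is called a significant mixing
#' effect only if it exceeds the mean plus one standard deviation of the
#' permuted mixing-status JSD scores; the full permuted distributions are
#' returned so other rules can be applied.
#'
#' @param expr normalized gene x cell matrix.
#' @param annotation annotation data frame (see [run_jsd_iterations()]);
#'   must carry `donor` and `lane` columns for the permuted donor.
#' @param params a [jsd_params()].
#' @param observed a `jsd_result` from [run_jsd_iterations()]; computed here
#'   when absent.
#' @return object of class `jsd_null`: `verdicts` data frame (one row per
#'   cell type) and `distributions` (per-permutation scores per cell type).
#' @export
permutation_null <- function(expr, annotation, params = jsd_params(),
                             observed = NULL) {
  if (is.null(observed)) observed <- run_jsd_iterations(expr, annotation, params)
  groups <- comparison_groups(params$comparison_sets)
  donor <- params$permute_donor
  donor_groups <- groups[startsWith(groups, donor)]
  if (length(donor_groups) < 2) {
    abort("permutation requires at least two groups for donor %s", donor)
  }
  types <- unique(observed$summary$celltype)
  seeds <- derive_seeds(params$seed + 1L, params$n_permutations)
  dist_list <- list()
  verdicts <- list()
  for (ty in types) {
    stratify_by <- if (identical(ty, params$stratify_celltype)) "cd4_subtype" else NULL
    ann_type <- annotation[annotation$celltype == ty &
                             annotation$group %in% groups, , drop = FALSE]
    x <- celltype_slab(expr, annotation, ty, groups, params$n_var)
    is_donor <- ann_type$donor == donor
    perm <- matrix(NA_real_, params$n_permutations, 2,
                   dimnames = list(NULL, c("mixing", "technical")))
    for (p in seq_len(params$n_permutations)) {
      ann_p <- ann_type
      ann_p$group[is_donor] <- withr::with_seed(seeds[p] + 1L,
                                                sample(ann_type$group[is_donor]))
      m <- jsd_iteration(x, ann_p, groups, params, stratify_by, seeds[p])
      cm <- comparison_means(m, params$comparison_sets[c("mixing", "technical")])
      perm[p, ] <- cm
    }
    obs <- observed$summary[observed$summary$celltype == ty, ]
    obs_mix <- obs$mean[obs$comparison == "mixing"]
    obs_tech <- obs$mean[obs$comparison == "technical"]
    diff_obs <- obs_mix - obs_tech
    thr <- mean(perm[, "mixing"]) + stats::sd(perm[, "mixing"])
    verdicts[[ty]] <- data.frame(
      celltype = ty,
      observed_mixing = obs_mix,
      observed_technical = obs_tech,
      observed_differential = diff_obs,
      permuted_mixing_mean = mean(perm[, "mixing"]),
      permuted_mixing_sd = stats::sd(perm[, "mixing"]),
      permuted_differential_mean = mean(perm[, "mixing"] - perm[, "technical"]),
      permuted_differential_sd = stats::sd(perm[, "mixing"] - perm[, "technical"]),
      significant = diff_obs > thr,
      stringsAsFactors = FALSE
    )
    dist_list[[ty]] <- data.frame(
      celltype = ty, permutation = seq_len(params$n_permutations),
      mixing = perm[, "mixing"], technical = perm[, "technical"],
      differential = perm[, "mixing"] - perm[, "technical"],
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    verdicts = do.call(rbind, c(verdicts, list(make.row.names = FALSE))),
    distributions = do.call(rbind, c(dist_list, list(make.row.names = FALSE))),
    params = params
  ), class = "jsd_null")
}

#' @export
print.jsd_null <- function(x, ...) {
  cat("Donor-label permutation null\n")
  print(x$verdicts[, c("celltype", "observed_differential",
                       "permuted_mixing_mean", "permuted_mixing_sd",
                       "significant")], row.names = FALSE)
  invisible(x)
}

#' Alloreactivity marker report for CD4 subtypes
#'
#' For each CD4 subtype and marker gene, summarizes expression in mixed vs
#' unmixed cells (mean normalized expression and detection fraction) and
#' tests for a shift with a Wilcoxon rank-sum test; p-values are
#' Benjamini-Hochberg adjusted across markers x subtypes. Markers absent
#' from the matrix are reported as missing rather than erroring.
#'
#' @param expr normalized gene x cell matrix.
#' @param annotation data frame with `cell`, `celltype`, `cd4_subtype`, and
#'   logical `mixed` columns.
#' @param markers marker genes; defaults to the canonical allogeneic
#'   response genes (IFNG, CD40LG up; DUSP1, FOS down).
#' @return data frame, one row per subtype x marker.
#' @export
allo_marker_report <- function(expr, annotation,
                               markers = c(DEFAULT_ALLO_UP, DEFAULT_ALLO_DOWN)) {
  ann <- annotation[annotation$celltype == "CD4 T" & !is.na(annotation$cd4_subtype), ]
  if (nrow(ann) == 0) abort("no CD4 T cells with subtype annotation")
  rows <- list()
  for (st in sort(unique(ann$cd4_subtype))) {
    cells_mixed <- ann$cell[ann$cd4_subtype == st & ann$mixed]
    cells_unmixed <- ann$cell[ann$cd4_subtype == st & !ann$mixed]
    for (g in markers) {
      if (!(g %in% rownames(expr))) {
        rows[[paste(st, g)]] <- data.frame(
          cd4_subtype = st, gene = g, missing = TRUE,
          mean_mixed = NA_real_, mean_unmixed = NA_real_,
          detection_mixed = NA_real_, detection_unmixed = NA_real_,
          p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      xm <- as.numeric(expr[g, cells_mixed])
      xu <- as.numeric(expr[g, cells_unmixed])
      p <- if (length(xm) == 0 || length(xu) == 0) {
        NA_real_
      } else if (stats::sd(c(xm, xu)) == 0) {
        1  # every observation tied: no evidence of a shift
      } else {
        stats::wilcox.test(xm, xu, exact = FALSE)$p.value
      }
      rows[[paste(st, g)]] <- data.frame(
        cd4_subtype = st, gene = g, missing = FALSE,
        mean_mixed = mean(xm), mean_unmixed = mean(xu),
        detection_mixed = mean(xm > 0), detection_unmixed = mean(xu > 0),
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
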