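# Synthetic multi-donor PBMC generator
#
# Emulates the statistical structure a donor-multiplexed PBMC experiment
# hands to the analysis: negative-binomial gene x cell UMI counts with
# cell-type marker structure, per-donor expression offsets, log-normal
# library sizes, per-cell sample-tag counts with cell-type-dependent capture
# efficiency, and per-cell ground truth. An optional alloreactivity effect
# up/down-regulates a configurable gene set in mixed-lane cells.

# canonical PBMC marker symbols, so annotation rules are testable verbatim
CANONICAL_MARKERS <- c(
  "CD4 T"     = "IL7R",
  "CD8 T"     = "CD8A",
  "NK"        = "SPON2",
  "B"         = "MS4A1",
  "CD14 Mono" = "CD14",
  "CD16 Mono" = "FCGR3A",
  "DC"        = "CLEC10A",
  "Platelet"  = "PF4"
)

CD4_SUBTYPE_GENES <- c("SELL", "S100A4", "GPR183")

# high/low pattern of the three dichotomization genes per CD4 subtype
CD4_SUBTYPE_PATTERNS <- list(
  activated = c(SELL = "high", S100A4 = "low",  GPR183 = "high"),
  memory    = c(SELL = "low",  S100A4 = "high", GPR183 = "high"),
  naive     = c(SELL = "high", S100A4 = "low",  GPR183 = "low")
)

DEFAULT_ALLO_UP   <- c("IFNG", "CD40LG")
DEFAULT_ALLO_DOWN <- c("DUSP1", "FOS")

#' Default sample-tag barcode whitelist
#'
#' 8-nt barcodes, one per donor, with pairwise Hamming distance >= 6 so that
#' single-substitution correction (radius 1, and up to radius 2) is always
#' unambiguous.
#'
#' @param donors character vector of donor labels (at most 8).
#' @return named character vector of barcode sequences.
#' @export
default_whitelist <- function(donors) {
  pool <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT",
            "AACCGGTT", "CCAATTGG", "GGTTAACC", "TTGGCCAA")
  if (length(donors) > length(pool)) {
    abort("default whitelist supports at most %d donors", length(pool))
  }
  stats::setNames(pool[seq_along(donors)], donors)
}

#' Sample-tag simulation parameters
#'
#' @param tag_whitelist named character vector (donor -> barcode) or NULL to
#'   use [default_whitelist()] for the configured donors.
#' @param reads_per_cell_mean expected tag reads per cell before capture
#'   scaling.
#' @param background_fraction fraction of a cell's tag read mass assigned
#'   uniformly to the wrong tags (ambient/bleed-through).
#' @param capture_efficiency_by_celltype named numeric in (0, 1]; multiplies
#'   a cell's total tag read mass. Cell types not listed default to 1.
#'   Depressing lymphocyte capture emulates the antibody-tag classification
#'   bias seen against T and NK cells.
#' @param sequencing_error_rate per-base substitution probability.
#' @return object of class `tag_params`.
#' @export
tag_params <- function(tag_whitelist = NULL,
                       reads_per_cell_mean = 300,
                       background_fraction = 0.02,
                       capture_efficiency_by_celltype = NULL,
                       sequencing_error_rate = 0.005) {
  stopifnot(reads_per_cell_mean > 0, is_prob(background_fraction),
            is_prob(sequencing_error_rate))
  if (!is.null(capture_efficiency_by_celltype)) {
    if (is.null(names(capture_efficiency_by_celltype)) ||
        any(capture_efficiency_by_celltype <= 0) ||
        any(capture_efficiency_by_celltype > 1)) {
      abort("capture_efficiency_by_celltype must be a named vector with values in (0, 1]")
    }
  }
  structure(list(
    tag_whitelist = tag_whitelist,
    reads_per_cell_mean = reads_per_cell_mean,
    background_fraction = background_fraction,
    capture_efficiency_by_celltype = capture_efficiency_by_celltype,
    sequencing_error_rate = sequencing_error_rate
  ), class = "tag_params")
}

#' Injected alloreactivity effect specification
#'
#' Defines a positive control: a set of genes up- or down-regulated in a
#' fraction of target cells restricted to mixed lanes, mimicking the
#' transcriptional signature CD4 T cells would show during an allogeneic
#' response (IFNG and CD40LG induced, DUSP1 and FOS repressed).
#'
#' @param up_genes,down_genes disjoint character vectors of gene ids.
#' @param fold_change_up,fold_change_down positive multipliers applied to
#'   expected counts (down genes are divided by `fold_change_down`).
#' @param affected_fraction fraction of target cells carrying the effect.
#' @param target_celltype cell type receiving the effect.
#' @param target_condition only `"mixed-lanes-only"` is supported: cells in
#'   single-donor lanes are never affected.
#' @return object of class `allo_effect_spec`.
#' @export
allo_effect_spec <- function(up_genes = DEFAULT_ALLO_UP,
                             down_genes = DEFAULT_ALLO_DOWN,
                             fold_change_up = 4,
                             fold_change_down = 4,
                             affected_fraction = 0.5,
                             target_celltype = "CD4 T",
                             target_condition = "mixed-lanes-only") {
  if (length(intersect(up_genes, down_genes)) > 0) {
    abort("up_genes and down_genes must be disjoint")
  }
  stopifnot(fold_change_up > 0, fold_change_down > 0, is_prob(affected_fraction))
  target_condition <- match.arg(target_condition, "mixed-lanes-only")
  structure(list(
    up_genes = up_genes, down_genes = down_genes,
    fold_change_up = fold_change_up, fold_change_down = fold_change_down,
    affected_fraction = affected_fraction,
    target_celltype = target_celltype,
    target_condition = target_condition
  ), class = "allo_effect_spec")
}

#' Generator configuration
#'
#' The default configuration mirrors the mixing design of the experiment the
#' analysis targets: four microfluidic lanes with lane 1 = unmixed donor A,
#' lane 2 = donors A-D, lane 3 = donors A-H, and lane 4 = an unmixed donor A
#' technical replicate that differs from lane 1 only by sampling noise.
#'
#' @param n_genes number of genes (must accommodate all named marker genes).
#' @param donors donor labels.
#' @param lane_design named list: lane id -> character vector of donors
#'   present in that lane.
#' @param cells_per_donor_per_lane cells simulated per donor per lane.
#' @param celltype_proportions named probability vector over cell types.
#' @param cd4_subtype_proportions named probability vector over CD4 T
#'   subtypes (activated/memory/naive).
#' @param n_marker_genes_per_type marker genes per cell type (the canonical
#'   symbol plus `TYPE.M2`, `TYPE.M3`, ...).
#' @param marker_fold_change fold elevation of a marker gene in its own cell
#'   type (also used for the CD4 subtype high/low genes).
#' @param donor_effect_sd std-dev of per-donor log-normal gene offsets.
#' @param donor_effect_gene_fraction fraction of non-structural genes given a
#'   donor offset.
#' @param dispersion negative-binomial size (inverse-dispersion); counts tend
#'   to Poisson as `dispersion` grows.
#' @param library_size_log_mean,library_size_log_sd log-normal library size
#'   parameters.
#' @param allo_effect optional [allo_effect_spec()].
#' @param tag_params [tag_params()] object.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_genes = 300,
                             donors = LETTERS[1:8],
                             lane_design = list(
                               "1" = "A",
                               "2" = c("A", "B", "C", "D"),
                               "3" = LETTERS[1:8],
                               "4" = "A"
                             ),
                             cells_per_donor_per_lane = 1000,
                             celltype_proportions = c(
                               "CD4 T" = 0.35, "CD8 T" = 0.15,
                               "CD14 Mono" = 0.25, "CD16 Mono" = 0.10,
                               "NK" = 0.15
                             ),
                             cd4_subtype_proportions = c(
                               activated = 0.15, memory = 0.50, naive = 0.35
                             ),
                             n_marker_genes_per_type = 5,
                             marker_fold_change = 4,
                             donor_effect_sd = 0.30,
                             donor_effect_gene_fraction = 0.25,
                             dispersion = 5,
                             library_size_log_mean = log(1500),
                             library_size_log_sd = 0.25,
                             allo_effect = NULL,
                             tag_params = allomix::tag_params(),
                             seed = 1L) {
  if (abs(sum(celltype_proportions) - 1) > 1e-9) {
    abort("celltype_proportions must sum to 1 (got %.12f)", sum(celltype_proportions))
  }
  if (is.null(names(celltype_proportions))) abort("celltype_proportions must be named")
  if (!is_count(n_genes) || !is_count(cells_per_donor_per_lane) ||
      !is_count(n_marker_genes_per_type)) {
    abort("n_genes, cells_per_donor_per_lane and n_marker_genes_per_type must be positive integers")
  }
  stopifnot(marker_fold_change > 0, donor_effect_sd >= 0,
            is_prob(donor_effect_gene_fraction), dispersion > 0)
  lane_donors <- unique(unlist(lane_design))
  if (!all(lane_donors %in% donors)) {
    abort("lane_design references donors not in `donors`: %s",
          paste(setdiff(lane_donors, donors), collapse = ", "))
  }
  if (any(lengths(lane_design) == 0)) abort("every lane must contain at least one donor")
  if ("CD4 T" %in% names(celltype_proportions)) {
    if (abs(sum(cd4_subtype_proportions) - 1) > 1e-9) {
      abort("cd4_subtype_proportions must sum to 1")
    }
  }
  if (!is.null(allo_effect) && !inherits(allo_effect, "allo_effect_spec")) {
    abort("allo_effect must be built with allo_effect_spec()")
  }
  if (!inherits(tag_params, "tag_params")) abort("tag_params must be built with tag_params()")
  cfg <- structure(list(
    n_genes = as.integer(n_genes), donors = donors, lane_design = lane_design,
    cells_per_donor_per_lane = as.integer(cells_per_donor_per_lane),
    celltype_proportions = celltype_proportions,
    cd4_subtype_proportions = cd4_subtype_proportions,
    n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
    marker_fold_change = marker_fold_change,
    donor_effect_sd = donor_effect_sd,
    donor_effect_gene_fraction = donor_effect_gene_fraction,
    dispersion = dispersion,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    allo_effect = allo_effect,
    tag_params = tag_params,
    seed = as.integer(seed)
  ), class = "generator_config")
  # fail early if the gene universe does not fit
  build_gene_universe(cfg)
  cfg
}

# Deterministic gene universe: canonical markers + extra per-type markers +
# CD4 subtype genes + alloreactivity genes + numbered filler genes.
build_gene_universe <- function(config) {
  types <- names(config$celltype_proportions)
  marker_of <- character(0)
  genes <- character(0)
  for (ty in types) {
    canon <- if (ty %in% names(CANONICAL_MARKERS)) CANONICAL_MARKERS[[ty]] else
      paste0(gsub(" ", ".", ty), ".M1")
    extra <- if (config$n_marker_genes_per_type > 1) {
      paste0(gsub(" ", ".", ty), ".M", seq(2, config$n_marker_genes_per_type))
    } else character(0)
    mk <- c(canon, extra)
    genes <- c(genes, mk)
    marker_of <- c(marker_of, stats::setNames(rep(ty, length(mk)), mk))
  }
  subtype_genes <- if ("CD4 T" %in% types) CD4_SUBTYPE_GENES else character(0)
  allo_up <- DEFAULT_ALLO_UP
  allo_down <- DEFAULT_ALLO_DOWN
  if (!is.null(config$allo_effect)) {
    allo_up <- union(allo_up, config$allo_effect$up_genes)
    allo_down <- union(allo_down, config$allo_effect$down_genes)
  }
  structural <- unique(c(genes, subtype_genes, allo_up, allo_down))
  if (length(structural) > config$n_genes) {
    abort("n_genes = %d too small for %d structural genes", config$n_genes,
          length(structural))
  }
  filler <- sprintf("G%04d", seq_len(config$n_genes - length(structural)))
  list(
    genes = c(structural, filler),
    marker_of = marker_of,
    subtype_genes = subtype_genes,
    allo_up = setdiff(allo_up, c(genes, subtype_genes)),
    allo_down = setdiff(allo_down, c(genes, subtype_genes)),
    filler = filler
  )
}

# Gene-level generative model: base weights, marker/donor/subtype multipliers.
# Expected count of gene g in cell c:
#   mu[g,c] = lib_c * w_g(c) / Z_c,  w_g(c) = base_w[g] * marker * donor * subtype
build_model <- function(config, seed) {
  uni <- build_gene_universe(config)
  genes <- uni$genes
  n <- length(genes)
  types <- names(config$celltype_proportions)
  withr::with_seed(seed, {
    base_w <- stats::rlnorm(n, 0, 1)
    names(base_w) <- genes
    # structural genes get stable, moderately high baseline abundance so the
    # marker/subtype/allo signal is not at the mercy of a tiny base weight
    base_w[names(uni$marker_of)] <- 1.5
    base_w[uni$subtype_genes] <- 2.0
    base_w[c(uni$allo_up, uni$allo_down)] <- 1.5
    # donor offsets on filler genes only, keeping annotation rules orthogonal
    donor_mult <- matrix(1, n, length(config$donors),
                         dimnames = list(genes, config$donors))
    n_affected <- round(config$donor_effect_gene_fraction * length(uni$filler))
    for (d in config$donors) {
      idx <- sample(uni$filler, n_affected)
      donor_mult[idx, d] <- exp(stats::rnorm(n_affected, 0, config$donor_effect_sd))
    }
  })
  marker_mult <- matrix(1, n, length(types), dimnames = list(genes, types))
  for (g in names(uni$marker_of)) marker_mult[g, uni$marker_of[[g]]] <- config$marker_fold_change
  subtypes <- names(CD4_SUBTYPE_PATTERNS)
  subtype_mult <- matrix(1, n, length(subtypes), dimnames = list(genes, subtypes))
  if (length(uni$subtype_genes) > 0) {
    for (st in subtypes) {
      pat <- CD4_SUBTYPE_PATTERNS[[st]]
      hi <- names(pat)[pat == "high"]
      subtype_mult[hi, st] <- config$marker_fold_change
    }
  }
  list(genes = genes, universe = uni, base_w = base_w, donor_mult = donor_mult,
       marker_mult = marker_mult, subtype_mult = subtype_mult,
       dispersion = config$dispersion)
}

# per-gene weights for one (celltype, subtype, donor) combination
combo_weights <- function(model, celltype, subtype, donor) {
  w <- model$base_w * model$marker_mult[, celltype] * model$donor_mult[, donor]
  if (!is.na(subtype) && subtype %in% colnames(model$subtype_mult)) {
    w <- w * model$subtype_mult[, subtype]
  }
  w
}

# expected means for selected genes across a set of cells (pre-allo)
cell_gene_means <- function(model, cells, genes) {
  key <- paste(cells$celltype, cells$cd4_subtype, cells$donor, sep = "\r")
  out <- matrix(0, length(genes), nrow(cells),
                dimnames = list(genes, cells$cell))
  for (k in unique(key)) {
    idx <- which(key == k)
    w <- combo_weights(model, cells$celltype[idx[1]], cells$cd4_subtype[idx[1]],
                       cells$donor[idx[1]])
    out[, idx] <- outer(w[genes] / sum(w), cells$lib[idx])
  }
  out
}

#' Generate synthetic counts, tag counts, and ground truth
#'
#' Draws gene x cell UMI counts from a negative binomial (Gamma-Poisson) law
#' with mean `lib_c * w_g(c) / Z_c`, where the gene weight `w_g(c)` combines a
#' log-normal base weight with cell-type marker, per-donor, CD4-subtype, and
#' (optionally) injected alloreactivity multipliers, and `Z_c` normalizes the
#' cell's expected total to its log-normal library size. Tag counts give the
#' cell's own donor tag `(1 - background_fraction)` of the capture-scaled read
#' mass, the remainder spread uniformly over the other tags; per-base
#' sequencing errors thin the retained mass as counted at correction radius 1.
#'
#' @param config a [generator_config()].
#' @return list of class `allomix_sim` with elements `counts` (sparse
#'   gene x cell matrix), `tags` (tag x cell matrix, rows named by donor), and
#'   `truth` (list with per-cell `cells` data frame, per-gene `genes` data
#'   frame, and the internal generative `model`).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  seeds <- derive_seeds(config$seed, 4L)
  model <- build_model(config, seeds[1])

  # ---- cells ----
  lanes <- names(config$lane_design)
  layout <- do.call(rbind, lapply(lanes, function(ln) {
    data.frame(lane = ln, donor = config$lane_design[[ln]],
               stringsAsFactors = FALSE)
  }))
  n_cells <- nrow(layout) * config$cells_per_donor_per_lane
  types <- names(config$celltype_proportions)
  withr::with_seed(seeds[2], {
    cells <- data.frame(
      cell = sprintf("cell%06d", seq_len(n_cells)),
      donor = rep(layout$donor, each = config$cells_per_donor_per_lane),
      lane = rep(layout$lane, each = config$cells_per_donor_per_lane),
      stringsAsFactors = FALSE
    )
    cells$group <- group_label(cells$donor, cells$lane)
    n_per_lane <- lengths(config$lane_design)
    cells$mixed <- n_per_lane[cells$lane] > 1
    cells$celltype <- sample(types, n_cells, replace = TRUE,
                             prob = config$celltype_proportions)
    cells$cd4_subtype <- NA_character_
    is_cd4 <- cells$celltype == "CD4 T"
    if (any(is_cd4)) {
      cells$cd4_subtype[is_cd4] <- sample(
        names(config$cd4_subtype_proportions), sum(is_cd4), replace = TRUE,
        prob = config$cd4_subtype_proportions)
    }
    cells$lib <- stats::rlnorm(n_cells, config$library_size_log_mean,
                               config$library_size_log_sd)
    cells$allo_affected <- FALSE
    if (!is.null(config$allo_effect)) {
      sp <- config$allo_effect
      target <- cells$celltype == sp$target_celltype & cells$mixed
      cells$allo_affected[target] <-
        stats::runif(sum(target)) < sp$affected_fraction
    }
  })
  if (any(table(cells$lane) == 0)) abort("a lane has zero cells")

  # ---- counts ----
  genes <- model$genes
  counts <- matrix(0L, length(genes), n_cells, dimnames = list(genes, cells$cell))
  key <- paste(cells$celltype, cells$cd4_subtype, cells$donor, sep = "\r")
  combos <- sort(unique(key))
  withr::with_seed(seeds[3], {
    for (k in combos) {
      idx <- which(key == k)
      first <- idx[1]
      w <- combo_weights(model, cells$celltype[first], cells$cd4_subtype[first],
                         cells$donor[first])
      mu <- outer(w / sum(w), cells$lib[idx])
      if (!is.null(config$allo_effect)) {
        aff <- cells$allo_affected[idx]
        if (any(aff)) {
          sp <- config$allo_effect
          mu[sp$up_genes, aff] <- mu[sp$up_genes, aff] * sp$fold_change_up
          mu[sp$down_genes, aff] <- mu[sp$down_genes, aff] / sp$fold_change_down
        }
      }
      if (any(!is.finite(mu)) || max(mu) > 2^30) {
        abort("expected counts overflow (max mu = %g)", max(mu))
      }
      counts[, idx] <- stats::rnbinom(length(mu), mu = mu,
                                      size = config$dispersion)
    }
  })

  # ---- tags ----
  tp <- config$tag_params
  wl <- tp$tag_whitelist %||% default_whitelist(config$donors)
  if (!all(config$donors %in% names(wl))) {
    abort("tag whitelist must name a barcode for every donor")
  }
  tags <- simulate_tag_counts(cells, tp, wl, seeds[4])

  truth <- list(
    cells = cells,
    genes = data.frame(
      gene = genes,
      base_weight = unname(model$base_w),
      marker_of = ifelse(genes %in% names(model$universe$marker_of),
                         model$universe$marker_of[genes], NA_character_),
      subtype_gene = genes %in% model$universe$subtype_genes,
      allo_role = ifelse(genes %in% model$universe$allo_up, "up",
                  ifelse(genes %in% model$universe$allo_down, "down",
                         NA_character_)),
      stringsAsFactors = FALSE
    ),
    model = model,
    whitelist = wl,
    config = config
  )
  structure(list(counts = as_count_matrix(counts), tags = tags, truth = truth),
            class = "allomix_sim")
}

# Poisson tag counts per tag x cell, thinned by the probability that a read
# survives radius-1 error correction (<= 1 substitution over the barcode).
simulate_tag_counts <- function(cells, tp, whitelist, seed) {
  donors_wl <- names(whitelist)
  K <- length(donors_wl)
  L <- nchar(whitelist[[1]])
  cap <- rep(1, nrow(cells))
  if (!is.null(tp$capture_efficiency_by_celltype)) {
    hit <- cells$celltype %in% names(tp$capture_efficiency_by_celltype)
    cap[hit] <- tp$capture_efficiency_by_celltype[cells$celltype[hit]]
  }
  p_keep <- stats::pbinom(1, L, tp$sequencing_error_rate)
  lam <- tp$reads_per_cell_mean * cap
  own <- lam * (1 - tp$background_fraction) * p_keep
  other <- if (K > 1) lam * tp$background_fraction / (K - 1) * p_keep else 0
  withr::with_seed(seed, {
    tags <- matrix(stats::rpois(K * nrow(cells), rep(other, each = K)),
                   K, nrow(cells), dimnames = list(donors_wl, cells$cell))
    own_idx <- cbind(match(cells$donor, donors_wl), seq_len(nrow(cells)))
    tags[own_idx] <- stats::rpois(nrow(cells), own)
  })
  tags
}

#' Inject an alloreactivity effect into existing counts
#'
#' Re-draws the counts of the effect's target genes in affected cells from
#' the generative law with expected counts multiplied by `fold_change_up`
#' (up genes) or divided by `fold_change_down` (down genes). Only cells of
#' the target cell type in mixed lanes can be affected; unaffected cells are
#' untouched.
#'
#' @param counts gene x cell count matrix from [generate_counts()].
#' @param truth matching ground-truth list (carries the generative model).
#' @param spec an [allo_effect_spec()].
#' @param seed integer seed for selecting affected cells and re-sampling.
#' @return list with updated `counts` and `truth` (`allo_affected` flags set).
#' @export
inject_allo_effect <- function(counts, truth, spec, seed = 1L) {
  stopifnot(inherits(spec, "allo_effect_spec"))
  target_genes <- c(spec$up_genes, spec$down_genes)
  missing <- setdiff(target_genes, rownames(counts))
  if (length(missing) > 0) {
    abort("unknown gene id(s) in allo effect spec: %s",
          paste(missing, collapse = ", "))
  }
  cells <- truth$cells
  cells$allo_affected <- FALSE
  if (spec$affected_fraction == 0) {
    truth$cells <- cells
    return(list(counts = counts, truth = truth))
  }
  target <- which(cells$celltype == spec$target_celltype & cells$mixed)
  seeds <- derive_seeds(seed, 2L)
  aff <- withr::with_seed(seeds[1],
                          target[stats::runif(length(target)) < spec$affected_fraction])
  if (length(aff) > 0) {
    mu <- cell_gene_means(truth$model, cells[aff, , drop = FALSE], target_genes)
    mu[spec$up_genes, ] <- mu[spec$up_genes, , drop = FALSE] * spec$fold_change_up
    mu[spec$down_genes, ] <- mu[spec$down_genes, , drop = FALSE] / spec$fold_change_down
    new_counts <- withr::with_seed(seeds[2],
      matrix(stats::rnbinom(length(mu), mu = mu, size = truth$model$dispersion),
             nrow(mu), ncol(mu)))
    counts[target_genes, cells$cell[aff]] <- new_counts
    cells$allo_affected[aff] <- TRUE
  }
  truth$cells <- cells
  list(counts = counts, truth = truth)
}

#' Simulate read-level tag sequences
#'
#' Emits one row per tag read (cell barcode, read sequence), with background
#' reads drawn uniformly from the wrong tags and per-base substitution
#' errors, for exercising read-level counting with [count_tag_reads()].
#'
#' @param cells ground-truth cell data frame (`cell`, `donor`, `celltype`).
#' @param tp a [tag_params()] object.
#' @param whitelist named character vector donor -> barcode.
#' @param seed integer seed.
#' @return data frame with columns `cell` and `read`.
#' @export
simulate_tag_reads <- function(cells, tp, whitelist, seed = 1L) {
  donors_wl <- names(whitelist)
  L <- nchar(whitelist[[1]])
  bases <- c("A", "C", "G", "T")
  cap <- rep(1, nrow(cells))
  if (!is.null(tp$capture_efficiency_by_celltype)) {
    hit <- cells$celltype %in% names(tp$capture_efficiency_by_celltype)
    cap[hit] <- tp$capture_efficiency_by_celltype[cells$celltype[hit]]
  }
  withr::with_seed(seed, {
    n_reads <- stats::rpois(nrow(cells), tp$reads_per_cell_mean * cap)
    cell <- rep(cells$cell, n_reads)
    donor <- rep(cells$donor, n_reads)
    total <- length(cell)
    is_bg <- stats::runif(total) < tp$background_fraction
    src <- donor
    if (any(is_bg) && length(donors_wl) > 1) {
      src[is_bg] <- vapply(donor[is_bg], function(d) {
        sample(setdiff(donors_wl, d), 1L)
      }, character(1))
    }
    seqmat <- matrix(unlist(strsplit(whitelist[src], "")), nrow = L)
    err <- matrix(stats::runif(L * total) < tp$sequencing_error_rate, nrow = L)
    if (any(err)) {
      # substitute with a uniformly random *different* base
      idx <- which(err)
      cur <- seqmat[idx]
      seqmat[idx] <- vapply(cur, function(b) sample(setdiff(bases, b), 1L),
                            character(1))
    }
    reads <- apply(seqmat, 2, paste0, collapse = "")
  })
  data.frame(cell = cell, read = reads, stringsAsFactors = FALSE)
}
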