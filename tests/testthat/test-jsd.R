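# JSD operator, kernel densities, balanced subsampling, iteration machinery

test_that("JSD operator satisfies its metric-like properties against an oracle", {
  withr::with_seed(19, {
    for (i in 1:200) {
      p <- random_simplex(25)
      q <- random_simplex(25)
      v <- jsd(p, q)
      expect_equal(v, jsd(q, p), tolerance = 1e-12)
      expect_gte(v, 0)
      expect_lte(v, 1)
      expect_equal(v, jsd_entropy_oracle(p, q), tolerance = 1e-9)
    }
  })
  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)  # disjoint supports, base-2 maximum
})

test_that("the worked two-cell JSD value is reproduced", {
  p <- c(1, 0)
  q <- c(0.5, 0.5)
  expect_equal(jsd(p, q), 0.3113, tolerance = 1e-4 / 0.3113)
  expect_equal(jsd(p, q), jsd_entropy_oracle(p, q), tolerance = 1e-12)
})

test_that("kernel density grids are proper and centered where the data are", {
  withr::with_seed(5, {
    tight <- cbind(stats::rnorm(200, 0, 0.02), stats::rnorm(200, 0, 0.02))
  })
  g <- kde2d_grid(tight, window = list(x = c(-1, 1), y = c(-1, 1)),
                  grid_size = 25)
  expect_equal(sum(g$z), 1)
  am <- which(g$z == max(g$z), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(13, 13))  # central lattice cell
  # identical point sets give identical grids
  g2 <- kde2d_grid(tight, window = list(x = c(-1, 1), y = c(-1, 1)),
                   grid_size = 25)
  expect_identical(g, g2)
})

test_that("grid marginals of standard-normal samples are near zero", {
  withr::with_seed(23, {
    pts <- cbind(stats::rnorm(1000), stats::rnorm(1000))
  })
  g <- kde2d_grid(pts, window = list(x = c(-4, 4), y = c(-4, 4)),
                  grid_size = 25)
  mean_x <- sum(rowSums(g$z) * g$x)
  mean_y <- sum(colSums(g$z) * g$y)
  expect_lt(abs(mean_x), 0.15)
  expect_lt(abs(mean_y), 0.15)
})

test_that("degenerate axes get a bandwidth floor and mismatched grids error", {
  pts <- cbind(rep(0.5, 30), seq(0, 1, length.out = 30))
  expect_warning(g <- kde2d_grid(pts, window = list(x = c(0, 1), y = c(0, 1))),
                 "floor")
  expect_equal(sum(g$z), 1)
  g1 <- kde2d_grid(matrix(stats::rnorm(40), 20), grid_size = 10)
  g2 <- kde2d_grid(matrix(stats::rnorm(40), 20), grid_size = 12)
  expect_error(jsd(g1, g2), "grid")
  expect_error(jsd(g1, c(0.5, 0.5)), "density grids")
})

test_that("balanced subsampling draws min-group-size cells per group", {
  mk_ann <- function(sizes) {
    do.call(rbind, lapply(names(sizes), function(g) {
      data.frame(cell = paste0(g, "_", seq_len(sizes[[g]])),
                 celltype = "CD8 T", group = g,
                 cd4_subtype = NA_character_, stringsAsFactors = FALSE)
    }))
  }
  groups <- paste0(rep(c("A", "B"), each = 4), 1:4)
  sizes <- stats::setNames(c(167, 200, 250, 300, 180, 190, 400, 500), groups)
  ann <- mk_ann(sizes)
  cells <- balanced_subsample(ann, "CD8 T", groups, seed = 1)
  expect_length(cells, 8 * 167)
  tab <- table(ann$group[match(cells, ann$cell)])
  expect_true(all(tab == 167))
  # all groups equal size s -> returns every cell
  ann_eq <- mk_ann(stats::setNames(rep(120, 8), groups))
  expect_length(balanced_subsample(ann_eq, "CD8 T", groups, seed = 1), 8 * 120)
  # deterministic under a fixed seed
  expect_identical(cells, balanced_subsample(ann, "CD8 T", groups, seed = 1))
  expect_false(identical(cells, balanced_subsample(ann, "CD8 T", groups,
                                                   seed = 2)))
  # below-threshold groups error (callers exclude the cell type)
  sizes_low <- sizes
  sizes_low[["B4"]] <- 20
  expect_error(balanced_subsample(mk_ann(sizes_low), "CD8 T", groups),
               "< 50")
})

test_that("CD4 subsampling balances subtypes within every group", {
  withr::with_seed(3, {
    ann <- do.call(rbind, lapply(c("A1", "A2"), function(g) {
      n <- c(activated = 30, memory = 80, naive = 60 + (g == "A2") * 40)
      data.frame(cell = paste0(g, "_", seq_len(sum(n))),
                 celltype = "CD4 T", group = g,
                 cd4_subtype = rep(names(n), n), stringsAsFactors = FALSE)
    }))
  })
  cells <- balanced_subsample(ann, "CD4 T", c("A1", "A2"),
                              min_cells_per_group = 50,
                              stratify_by = "cd4_subtype", seed = 1)
  sel <- ann[match(cells, ann$cell), ]
  tab <- table(sel$group, sel$cd4_subtype)
  expect_true(all(tab["A1", ] == tab["A2", ]))
  expect_equal(unname(tab["A1", c("activated", "memory", "naive")]),
               c(30, 80, 60))
})

test_that("iterated JSD is reproducible, scaled to [0,1], and excludes thin types", {
  sim <- small_sim(seed = 7, cells = 250)
  ann <- truth_annotation(sim, jsd_groups)
  expr <- normalize_log(sim$counts[, ann$cell])
  p <- jsd_params(n_iterations = 3, n_permutations = 2, seed = 9)
  r1 <- run_jsd_iterations(expr, ann, p)
  r2 <- run_jsd_iterations(expr, ann, p)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$summary, r2$summary)
  # CD16 Mono: ~15 cells/group at this scale -> excluded under the 50-cell rule
  expect_true("CD16 Mono" %in% names(r1$excluded))
  expect_false("CD16 Mono" %in% r1$summary$celltype)
  expect_true("CD4 T" %in% r1$summary$celltype)
  expect_match(r1$excluded[["CD16 Mono"]], "fewer than 50")
  # per-iteration min-max scaling: each (celltype, iteration) spans [0, 1]
  sp <- split(r1$pairs$jsd, paste(r1$pairs$celltype, r1$pairs$iteration))
  for (v in sp) {
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("permuting labels of exchangeable groups centers the differential at zero", {
  # all groups drawn from one distribution: the permuted mixing-technical
  # differential must be centred at zero within Monte-Carlo error
  withr::with_seed(31, {
    n <- 1200
    counts <- matrix(stats::rnbinom(40 * n, mu = 5, size = 2), nrow = 40,
                     dimnames = list(paste0("g", 1:40), paste0("c", 1:n)))
    ann <- data.frame(cell = colnames(counts), donor = "A",
                      lane = as.character(rep(1:4, length.out = n)),
                      celltype = "CD8 T", cd4_subtype = NA_character_,
                      stringsAsFactors = FALSE)
    ann$group <- paste0(ann$donor, ann$lane)
  })
  expr <- normalize_log(counts)
  p <- jsd_params(n_iterations = 5, n_permutations = 40, seed = 2,
                  min_cells_per_group = 50, n_var = 20,
                  comparison_sets = list(
                    mixing = list(c("A1", "A2"), c("A4", "A3")),
                    technical = list(c("A1", "A4"))))
  nul <- permutation_null(expr, ann, p)
  d <- nul$distributions$differential
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 4 * se + 1e-12)
  expect_false(any(nul$verdicts$significant))
})

test_that("marker report handles exact ties, missing genes, and BH adjustment", {
  withr::with_seed(12, {
    base <- matrix(stats::rpois(4 * 40, 3), nrow = 4,
                   dimnames = list(c("IFNG", "CD40LG", "DUSP1", "FOS"), NULL))
  })
  # mixed cells duplicate unmixed cells exactly -> every test is fully tied
  counts <- cbind(base, base)
  colnames(counts) <- paste0("c", 1:80)
  ann <- data.frame(cell = colnames(counts), celltype = "CD4 T",
                    cd4_subtype = rep(rep(c("naive", "memory"), each = 20), 2),
                    mixed = rep(c(FALSE, TRUE), each = 40),
                    stringsAsFactors = FALSE)
  rep1 <- allo_marker_report(normalize_log(counts), ann)
  expect_true(all(rep1$p == 1))
  expect_true(all(rep1$p_adj == 1))
  rep2 <- allo_marker_report(normalize_log(counts), ann,
                             markers = c("IFNG", "ABSENT"))
  expect_true(all(rep2$missing[rep2$gene == "ABSENT"]))
  expect_false(any(rep2$missing[rep2$gene == "IFNG"]))
  # BH never lowers a p-value
  expect_true(all(rep2$p_adj >= rep2$p | is.na(rep2$p)))
})
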