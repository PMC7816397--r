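# tag demultiplexing: Hamming counting, classification, concordance, bias

test_that("whitelist construction enforces the unambiguity guarantee", {
  expect_error(barcode_whitelist(c(A = "AAAA", B = "AAAT"), 1), "Hamming")
  expect_error(barcode_whitelist(c(A = "AAAAAAAA", B = "AAAATTTT"), 2), "Hamming")
  wl <- barcode_whitelist(c(A = "AAAAAAAA", B = "CCCCCCCC"), 1)
  expect_s3_class(wl, "barcode_whitelist")
  expect_error(barcode_whitelist(c(A = "AAAA", B = "CCCCC"), 1), "length")
  # default donor whitelist supports radius up to 2
  expect_silent(barcode_whitelist(default_whitelist(LETTERS[1:8]), 2))
})

test_that("reads are corrected to the unique entry within the radius", {
  wl <- barcode_whitelist(c(A = "AAAAAAAA", B = "CCCCCCCC"), 1)
  reads <- data.frame(cell = "c1",
                      read = c("AAAAAAAA", "AAAAAAAT", "AAAATTTT", "CCCCCCCC"))
  counts <- count_tag_reads(reads, wl)
  expect_equal(counts["A", "c1"], 2L)  # exact + distance 1
  expect_equal(counts["B", "c1"], 1L)
  expect_equal(attr(counts, "dropped_fraction"), 0.25)
  expect_error(count_tag_reads(data.frame(cell = "c1", read = "AAAA"), wl),
               "length")
})

test_that("long barcodes are counted at radius 5 and dropped at 6", {
  wl <- barcode_whitelist(
    c(A = strrep("A", 40), B = strrep("C", 40)), correction_radius = 5)
  withr::with_seed(1, {
    r5 <- mutate_barcode(strrep("A", 40), 5)
    r6 <- mutate_barcode(strrep("A", 40), 6)
  })
  counts <- count_tag_reads(data.frame(cell = "c1", read = c(r5, r6)), wl)
  expect_equal(counts["A", "c1"], 1L)
  expect_equal(sum(counts), 1L)
})

test_that("counting agrees with an exhaustive Hamming oracle on random reads", {
  wl_seqs <- c(A = "AACCGGTT", B = "TTGGCCAA")
  wl <- barcode_whitelist(wl_seqs, 1)
  withr::with_seed(42, {
    reads <- vapply(1:300, function(i) {
      mutate_barcode(sample(wl_seqs, 1), sample(0:3, 1))
    }, character(1))
  })
  counts <- count_tag_reads(data.frame(cell = paste0("c", seq_along(reads)),
                                       read = reads), wl)
  for (i in seq_along(reads)) {
    d <- vapply(wl_seqs, hamming_oracle, numeric(1), a = reads[i])
    hit <- names(d)[d <= 1]
    cell <- paste0("c", i)
    if (length(hit) == 1) {
      expect_equal(counts[hit, cell], 1L)
      expect_equal(sum(counts[, cell]), 1L)
    } else {
      expect_equal(sum(counts[, cell]), 0L)
    }
  }
})

test_that("read-level simulation and counting recover donor structure", {
  sim <- small_sim(seed = 7, cells = 100)
  cells <- sim$truth$cells[sample.int(nrow(sim$truth$cells), 80), ]
  tp <- tag_params(reads_per_cell_mean = 60)
  reads <- simulate_tag_reads(cells, tp, sim$truth$whitelist, seed = 5)
  wl <- barcode_whitelist(sim$truth$whitelist, 1)
  counts <- count_tag_reads(reads, wl, cells = cells$cell)
  argmax <- rownames(counts)[apply(counts, 2, which.max)]
  expect_gte(mean(argmax == cells$donor), 0.99)
})

test_that("cells with one dominant tag are called as that donor", {
  withr::with_seed(1, {
    tags <- rbind(A = c(rep(500, 25), rpois(25, 1)),
                  B = c(rpois(25, 1), rep(400, 25)))
  })
  colnames(tags) <- paste0("c", 1:50)
  cls <- classify_cells(tags)
  expect_identical(unname(cls$calls[1:25]), rep("A", 25))
  expect_identical(unname(cls$calls[26:50]), rep("B", 25))
  # deterministic: identical result on repeat
  expect_identical(cls, classify_cells(tags))
})

test_that("classification input contracts are enforced", {
  tags <- matrix(rpois(40, 5), 2, 20,
                 dimnames = list(c("A", "B"), paste0("c", 1:20)))
  expect_error(classify_cells(tags[1, , drop = FALSE]), "2 tags")
  expect_error(classify_cells(tags[, 1:5]), "10 cells")
  tags0 <- tags
  tags0["B", ] <- 0
  expect_error(classify_cells(tags0), "all-zero")
})

test_that("synthetic default-noise tags classify >= 99% correctly, <= 1% doublets", {
  sim <- small_sim(seed = 7, cells = 200)
  cls <- classify_cells(sim$tags)
  truth <- sim$truth$cells$donor
  expect_gte(mean(cls$calls == truth), 0.99)
  expect_lte(mean(cls$calls == "Doublet"), 0.01)
})

test_that("depressed tag capture biases Negatives toward the affected types", {
  # three-point efficiency grid: the Negative fraction of the depressed type
  # never decreases as capture efficiency falls
  neg_frac <- vapply(c(1, 0.3, 0.05), function(ce) {
    cfg <- generator_config(
      cells_per_donor_per_lane = 200, n_genes = 40,
      tag_params = tag_params(capture_efficiency_by_celltype = c("CD4 T" = ce)),
      seed = 44)
    s <- generate_counts(cfg)
    cls <- suppressWarnings(classify_cells(s$tags))
    ann <- data.frame(cell = s$truth$cells$cell,
                      celltype = s$truth$cells$celltype)
    bias_by_celltype(cls, ann)["CD4 T", "Negative"]
  }, numeric(1))
  expect_true(all(diff(neg_frac) >= 0))
})

test_that("bias table rows sum to one and report zero Negatives when all classify", {
  sim <- small_sim(seed = 7, cells = 200)
  cls <- classify_cells(sim$tags)
  ann <- data.frame(cell = sim$truth$cells$cell,
                    celltype = sim$truth$cells$celltype)
  b <- bias_by_celltype(cls, ann)
  expect_equal(unname(rowSums(b)), rep(1, nrow(b)))
  if (all(cls$calls != "Negative")) {
    expect_equal(unname(b[, "Negative"]), rep(0, nrow(b)))
  }
})

test_that("concordance matches direct enumeration", {
  ref <- stats::setNames(rep(c("A", "B"), each = 5), paste0("c", 1:10))
  # identity
  self <- concordance(ref, ref)
  expect_equal(self$pct_unclassified, 0)
  expect_equal(self$pct_donor_match, 100)
  # 3 of 10 Negative, rest matching
  test <- ref
  test[c(1, 2, 6)] <- "Negative"
  r <- concordance(test, ref)
  expect_equal(r$pct_unclassified, 30)
  expect_equal(r$pct_donor_match, 100)
  # 2 of 8 donor-called cells swapped between donors
  test2 <- ref
  test2[1] <- "B"
  test2[6] <- "A"
  test2[c(2, 7)] <- "Negative"
  r2 <- concordance(test2, ref)
  expect_equal(r2$pct_donor_match, 75)
})

test_that("concordance is invariant to cell order and consistent relabeling", {
  withr::with_seed(8, {
    ref <- stats::setNames(sample(c("A", "B", "C"), 60, replace = TRUE),
                           paste0("c", 1:60))
    test <- ref
    test[sample(60, 10)] <- "Negative"
  })
  r1 <- concordance(test, ref)
  perm <- sample(60)
  r2 <- concordance(test[perm], ref)
  expect_equal(r1$pct_unclassified, r2$pct_unclassified)
  expect_equal(r1$pct_donor_match, r2$pct_donor_match)
  relabel <- c(A = "X", B = "Y", C = "Z", Negative = "Negative")
  r3 <- concordance(stats::setNames(relabel[test], names(test)),
                    stats::setNames(relabel[ref], names(ref)))
  expect_equal(r1$pct_donor_match, r3$pct_donor_match)
  # reference doublets/unassigned are excluded from the denominator
  ref2 <- ref
  ref2[1:10] <- "Doublet"
  r4 <- concordance(test, ref2)
  expect_equal(r4$n_reference_donor, 50)
  expect_error(concordance(test[1:5], ref[6:10]), "shared")
})
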