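# shared fixtures and independent oracles

# Jensen-Shannon divergence via the entropy identity H(M) - (H(P) + H(Q))/2,
# an algebraically distinct route from the package's half-KL implementation
jsd_entropy_oracle <- function(p, q) {
  ent <- function(w) {
    w <- w[w > 0]
    -sum(w * log2(w))
  }
  m <- (p + q) / 2
  ent(m) - (ent(p) + ent(q)) / 2
}

# plain character-wise Hamming distance between two equal-length strings
hamming_oracle <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# substitute `k` distinct positions of a barcode with a different base
mutate_barcode <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (i in pos) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste0(chars, collapse = "")
}

random_simplex <- function(n) {
  x <- stats::runif(n)
  x / sum(x)
}

# default-shaped simulation, cached per (seed, cells) within the test run
small_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7, cells = 200) {
    key <- paste0("s", seed, "c", cells)
    if (is.null(cache[[key]])) {
      cfg <- generator_config(cells_per_donor_per_lane = cells, seed = seed)
      cache[[key]] <- generate_counts(cfg)
    }
    cache[[key]]
  }
})

# ground-truth annotation columns used by the downstream analyses
truth_annotation <- function(sim, groups = NULL) {
  ann <- sim$truth$cells[, c("cell", "donor", "lane", "group", "mixed",
                             "celltype", "cd4_subtype")]
  if (!is.null(groups)) ann <- ann[ann$group %in% groups, ]
  ann
}

jsd_groups <- c("A1", "A2", "A3", "A4", "B2", "B3", "C2", "C3")
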