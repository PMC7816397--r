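# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent sub-seeds from one master seed
#'
#' Each randomized stage of the pipeline draws its own seed from the master
#' seed so that changing the number of draws in one stage does not perturb
#' another. Values stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# stop() with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

# group label for a (donor, lane) pair, e.g. "A1"
group_label <- function(donor, lane) paste0(donor, lane)

# coerce a counts input (base or Matrix) to dgCMatrix with dimnames intact
as_count_matrix <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("count matrix must carry gene (row) and cell (column) names")
  }
  methods::as(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE), "dMatrix"),
                          "generalMatrix"), "CsparseMatrix")
}
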