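# StrandBaseCounts: the central tensor of the package. Per-barcode,
# per-position, strand-specific base counts are held as eight sparse
# matrices (4 bases x 2 strands), each genome_length x n_barcodes.
# Coverage is always derived, never stored independently.

#' Construct a strand-specific base-count tensor
#'
#' @param barcodes ordered character vector of droplet barcodes.
#' @param genome_length positive integer; mitochondrial genome length.
#' @param counts optional named list `counts[[base]][[strand]]` of
#'   `genome_length x length(barcodes)` sparse matrices with non-negative
#'   integer entries; missing slots are filled with zeros.
#' @return an object of class `strand_base_counts`.
#' @export
strand_base_counts <- function(barcodes, genome_length, counts = NULL) {
  assert_that(length(barcodes) == length(unique(barcodes)),
              "barcodes must be unique")
  genome_length <- as.integer(genome_length)
  assert_that(genome_length >= 1L, "genome_length must be positive")
  n <- length(barcodes)
  zero <- function() {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(genome_length, n))
  }
  full <- lapply(setNames(BASES, BASES), function(b) {
    lapply(setNames(STRANDS, STRANDS), function(s) {
      m <- counts[[b]][[s]]
      if (is.null(m)) return(zero())
      m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
      assert_that(all(dim(m) == c(genome_length, n)),
                  "count matrix for %s/%s has wrong dimensions", b, s)
      assert_that(all(m@x >= 0), "negative counts in %s/%s", b, s)
      m
    })
  })
  structure(list(barcodes = as.character(barcodes),
                 genome_length = genome_length,
                 counts = full,
                 cache = new.env(parent = emptyenv())),
            class = "strand_base_counts")
}

#' Build a tensor from count triplets
#'
#' @param df data.frame with columns `position`, `barcode` (identifier or
#'   1-based index into `barcodes`), `base`, `fwd`, `rev`.
#' @inheritParams strand_base_counts
#' @return a `strand_base_counts` object.
#' @export
strand_counts_from_triplets <- function(df, barcodes, genome_length) {
  j <- if (is.numeric(df$barcode)) as.integer(df$barcode)
       else match(as.character(df$barcode), barcodes)
  assert_that(!anyNA(j) && all(j >= 1L & j <= length(barcodes)),
              "unknown barcode in triplets")
  assert_that(all(df$position >= 1L & df$position <= genome_length),
              "position outside [1, genome_length]")
  assert_that(all(df$fwd >= 0) && all(df$rev >= 0),
              "negative counts in triplets")
  counts <- list()
  for (b in BASES) {
    sel <- df$base == b
    for (s in STRANDS) {
      x <- if (s == "fwd") df$fwd[sel] else df$rev[sel]
      keep <- x > 0
      counts[[b]][[s]] <- Matrix::sparseMatrix(
        i = as.integer(df$position[sel][keep]), j = j[sel][keep],
        x = as.numeric(x[keep]), dims = c(genome_length, length(barcodes)))
    }
  }
  strand_base_counts(barcodes, genome_length, counts)
}

#' Derived coverage matrix
#'
#' Coverage is the sum of the four base counts over both strands, per
#' (position, barcode).
#'
#' @param x a `strand_base_counts` object.
#' @return a sparse `genome_length x n_barcodes` matrix.
#' @export
coverage_matrix <- function(x) {
  stopifnot(inherits(x, "strand_base_counts"))
  # derived quantity; memoised because the tensor is immutable by
  # convention (every mutating operation builds a new object)
  if (!is.null(x$cache) && !is.null(x$cache$coverage)) {
    return(x$cache$coverage)
  }
  cov <- Reduce(`+`, lapply(x$counts, function(bs) bs$fwd + bs$rev))
  if (!is.null(x$cache)) x$cache$coverage <- cov
  cov
}

#' Per-base strand-summed count matrix
#' @param x a `strand_base_counts` object.
#' @param base one of "A", "C", "G", "T".
#' @return a sparse matrix of `fwd + rev` counts for that base.
#' @export
base_count_matrix <- function(x, base) {
  x$counts[[base]]$fwd + x$counts[[base]]$rev
}

#' Subset a tensor to a set of barcodes
#' @param x a `strand_base_counts` object.
#' @param barcodes barcodes to keep (order respected).
#' @return a `strand_base_counts` object over `barcodes`.
#' @export
subset_barcodes <- function(x, barcodes) {
  j <- match(barcodes, x$barcodes)
  assert_that(!anyNA(j), "barcode not present in tensor: %s",
              paste(head(barcodes[is.na(j)], 3), collapse = ", "))
  counts <- lapply(x$counts, function(bs) lapply(bs, function(m) {
    m[, j, drop = FALSE]
  }))
  strand_base_counts(barcodes, x$genome_length, counts)
}

#' Total read count in a tensor
#' @param x a `strand_base_counts` object.
#' @return total number of reads (sum of all entries).
#' @export
total_counts <- function(x) {
  sum(vapply(x$counts, function(bs) sum(bs$fwd) + sum(bs$rev), 0))
}

#' @exportS3Method base::print
print.strand_base_counts <- function(x, ...) {
  cat(sprintf(
    "strand_base_counts: %d barcodes, genome length %d, %.0f reads\n",
    length(x$barcodes), x$genome_length, total_counts(x)))
  invisible(x)
}

#' Convert a tensor to a triplet data.table
#'
#' Long form used by the writers: one row per (position, barcode, base)
#' with nonzero total count, ordered by position then barcode index.
#'
#' @param x a `strand_base_counts` object.
#' @return a `data.table` with columns `position`, `barcode_index`,
#'   `base`, `fwd`, `rev`.
#' @export
strand_counts_triplets <- function(x) {
  out <- data.table::rbindlist(lapply(BASES, function(b) {
    f <- methods::as(x$counts[[b]]$fwd, "TsparseMatrix")
    r <- methods::as(x$counts[[b]]$rev, "TsparseMatrix")
    dt <- merge(
      data.table::data.table(position = f@i + 1L, barcode_index = f@j + 1L,
                             fwd = f@x),
      data.table::data.table(position = r@i + 1L, barcode_index = r@j + 1L,
                             rev = r@x),
      by = c("position", "barcode_index"), all = TRUE)
    dt$fwd[is.na(dt$fwd)] <- 0
    dt$rev[is.na(dt$rev)] <- 0
    dt$base <- b
    dt
  }))
  data.table::setcolorder(out, c("position", "barcode_index", "base",
                                 "fwd", "rev"))
  data.table::setorderv(out, c("position", "barcode_index", "base"))
  out[]
}
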