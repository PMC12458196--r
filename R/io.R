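# Readers and writers for the mgatk-dialect table layout:
#   A.txt, C.txt, G.txt, T.txt : CSV, no header, (position, barcode_index,
#                                fwd_count, rev_count)
#   coverage.txt               : CSV, no header, (position, barcode_index,
#                                coverage)
#   barcodes.txt               : one barcode per line
# plus a legacy sparse-triplet export (matrix.mtx / features.tsv /
# barcodes.tsv) with four feature rows per variant.

base_table_names <- function() paste0(BASES, ".txt")

find_table <- function(dir, name) {
  for (cand in c(name, paste0(name, ".gz"))) {
    p <- file.path(dir, cand)
    if (file.exists(p)) return(p)
  }
  stop_cc("missing table '%s' in %s", name, dir, class = "cryoclone_io_error")
}

#' Read strand-specific base-count tables
#'
#' Reads the per-base count tables plus the independently supplied
#' coverage table and cross-checks them: the coverage derived from the
#' four base tables must equal the coverage file exactly, otherwise an
#' integrity error names the first offending (barcode, position).
#'
#' @param dir directory containing `A.txt`..`T.txt`, `coverage.txt` and
#'   `barcodes.txt` (optionally gzipped).
#' @param genome_length mitochondrial genome length.
#' @return a `strand_base_counts` object.
#' @export
read_strand_counts <- function(dir, genome_length = 16569) {
  barcodes <- readLines(find_table(dir, "barcodes.txt"))
  n <- length(barcodes)
  read_csv_cols <- function(f, cols) {
    if (file.size(f) == 0) {
      dt <- data.table::as.data.table(
        setNames(rep(list(numeric(0)), length(cols)), cols))
    } else {
      dt <- data.table::fread(f, header = FALSE, col.names = cols)
    }
    dt
  }
  trip <- data.table::rbindlist(lapply(BASES, function(b) {
    dt <- read_csv_cols(find_table(dir, paste0(b, ".txt")),
                        c("position", "barcode_index", "fwd", "rev"))
    dt$base <- b
    dt
  }))
  if (nrow(trip) > 0) {
    if (any(trip$fwd < 0 | trip$rev < 0)) {
      stop_cc("negative counts in base tables",
              class = "cryoclone_format_error")
    }
    if (any(trip$barcode_index < 1L | trip$barcode_index > n)) {
      stop_cc("barcode index outside barcode list",
              class = "cryoclone_format_error")
    }
  }
  tensor <- strand_counts_from_triplets(
    data.frame(position = trip$position, barcode = trip$barcode_index,
               base = trip$base, fwd = trip$fwd, rev = trip$rev),
    barcodes, genome_length)

  covf <- read_csv_cols(find_table(dir, "coverage.txt"),
                        c("position", "barcode_index", "coverage"))
  supplied <- Matrix::sparseMatrix(
    i = covf$position, j = covf$barcode_index,
    x = as.numeric(covf$coverage), dims = c(genome_length, n))
  derived <- coverage_matrix(tensor)
  diffm <- methods::as(derived - supplied, "TsparseMatrix")
  bad <- which(diffm@x != 0)
  if (length(bad) > 0) {
    k <- bad[order(diffm@j[bad], diffm@i[bad])][1L]
    stop_cc(
      "coverage mismatch: barcode '%s' position %d (derived %g, file %g)",
      barcodes[diffm@j[k] + 1L], diffm@i[k] + 1L,
      derived[diffm@i[k] + 1L, diffm@j[k] + 1L],
      supplied[diffm@i[k] + 1L, diffm@j[k] + 1L],
      class = "cryoclone_integrity_error")
  }
  tensor
}

#' Write strand-specific base-count tables
#'
#' Emits the same dialect [read_strand_counts()] consumes, with
#' deterministic ordering (position ascending, then barcode index
#' ascending) so repeated writes of the same tensor are byte-identical.
#'
#' @param x a `strand_base_counts` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_strand_counts <- function(x, dir) {
  stopifnot(inherits(x, "strand_base_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trip <- strand_counts_triplets(x)
  for (b in BASES) {
    sel <- trip[trip$base == b, c("position", "barcode_index", "fwd", "rev")]
    data.table::fwrite(sel, file.path(dir, paste0(b, ".txt")),
                       col.names = FALSE)
  }
  cov <- methods::as(coverage_matrix(x), "TsparseMatrix")
  covdt <- data.table::data.table(position = cov@i + 1L,
                                  barcode_index = cov@j + 1L,
                                  coverage = cov@x)
  data.table::setorderv(covdt, c("position", "barcode_index"))
  data.table::fwrite(covdt, file.path(dir, "coverage.txt"),
                     col.names = FALSE)
  writeLines(x$barcodes, file.path(dir, "barcodes.txt"))
  invisible(dir)
}

#' Export a reference/variant quad matrix
#'
#' For each variant four feature rows are emitted in fixed order
#' `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`; columns are barcodes.
#' Written as MatrixMarket `matrix.mtx` plus `features.tsv` and
#' `barcodes.tsv` (the legacy sparse triplet layout consumed by
#' droplet-decontamination tools).
#'
#' @param x a `strand_base_counts` object.
#' @param variants variant `data.frame`; duplicates are an error.
#' @param barcodes columns of the export; must all exist in `x`.
#' @param dir output directory.
#' @return invisibly, the dense-free sparse matrix that was written.
#' @export
export_variant_quad_matrix <- function(x, variants, barcodes = x$barcodes,
                                       dir) {
  assert_that(nrow(variants) > 0, "variants must be non-empty")
  assert_that(!anyDuplicated(variants$label), "duplicate variants: %s",
              variants$label[duplicated(variants$label)][1] %||% "")
  quad <- variant_quad_matrix(x, variants, barcodes)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(quad, file.path(dir, "matrix.mtx"))
  writeLines(rownames(quad), file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  invisible(quad)
}

#' Build the quad matrix in memory
#' @inheritParams export_variant_quad_matrix
#' @return sparse matrix with `4 * nrow(variants)` feature rows.
#' @export
variant_quad_matrix <- function(x, variants, barcodes = x$barcodes) {
  j <- match(barcodes, x$barcodes)
  assert_that(!anyNA(j), "barcode not in tensor: %s",
              paste(head(barcodes[is.na(j)], 3), collapse = ", "))
  assert_that(all(variants$position <= x$genome_length),
              "variant position out of range")
  rows <- vector("list", 4L * nrow(variants))
  feat <- character(4L * nrow(variants))
  slots <- expand.grid(strand = STRANDS, allele = c("ref", "alt"),
                       stringsAsFactors = FALSE)[, 2:1]
  for (v in seq_len(nrow(variants))) {
    for (s in seq_len(4L)) {
      base <- variants[[slots$allele[s]]][v]
      strand <- slots$strand[s]
      rows[[(v - 1L) * 4L + s]] <-
        x$counts[[base]][[strand]][variants$position[v], j]
      feat[(v - 1L) * 4L + s] <-
        sprintf("%s|%s_%s", variants$label[v], slots$allele[s], strand)
    }
  }
  m <- methods::as(do.call(rbind, rows), "CsparseMatrix")
  dimnames(m) <- list(feat, barcodes)
  m
}

#' Read a per-barcode QC summary table
#'
#' Two dialects are supported. `positional` follows the cellranger-atac
#' `singlecell.csv` column layout: at least 18 columns, with the
#' mitochondrial fragment count in column 7 and `peak_region_fragments`
#' in column 18 (1-based). `named` requires a header and recognises the
#' columns `barcode`, `mito_fragments` (or `mitochondrial`),
#' `peak_region_fragments`, `tss_enrichment` (or `TSS.enrichment`),
#' `nucleosome_signal`, `n_count_peaks` (or `nCount_peaks`), `frip`
#' (or `FRiP`), `is_cell` (or `is__cell_barcode`).
#'
#' @param file path to the table (CSV/TSV; delimiter sniffed).
#' @param dialect `"positional"` or `"named"`.
#' @return a `data.frame` of barcode records; optional fields absent from
#'   the file are `NA`, not zero.
#' @export
read_barcode_summary <- function(file, dialect = c("positional", "named")) {
  dialect <- match.arg(dialect)
  if (dialect == "positional") {
    dt <- data.table::fread(file, header = "auto")
    if (ncol(dt) < 18L) {
      stop_cc("positional dialect needs >= 18 columns, found %d in %s",
              ncol(dt), file, class = "cryoclone_format_error")
    }
    if (!is.numeric(dt[[7L]]) || !is.numeric(dt[[18L]])) {
      stop_cc("columns 7/18 are not numeric in %s (row 1: '%s')",
              file, paste(unlist(dt[1L, c(7L, 18L)]), collapse = ","),
              class = "cryoclone_format_error")
    }
    rec <- data.frame(barcode = as.character(dt[[1L]]),
                      mito_fragments = as.numeric(dt[[7L]]),
                      peak_region_fragments = as.numeric(dt[[18L]]),
                      tss_enrichment = NA_real_,
                      nucleosome_signal = NA_real_,
                      n_count_peaks = NA_real_,
                      frip = NA_real_,
                      is_cell = NA,
                      stringsAsFactors = FALSE)
  } else {
    dt <- data.table::fread(file, header = TRUE)
    pick <- function(...) {
      for (nm in c(...)) if (nm %in% names(dt)) return(dt[[nm]])
      rep(NA_real_, nrow(dt))
    }
    rec <- data.frame(
      barcode = as.character(pick("barcode")),
      mito_fragments = as.numeric(pick("mito_fragments", "mitochondrial")),
      peak_region_fragments = as.numeric(pick("peak_region_fragments")),
      tss_enrichment = as.numeric(pick("tss_enrichment", "TSS.enrichment")),
      nucleosome_signal = as.numeric(pick("nucleosome_signal",
                                          "NucleosomeSignal")),
      n_count_peaks = as.numeric(pick("n_count_peaks", "nCount_peaks")),
      frip = as.numeric(pick("frip", "FRiP")),
      is_cell = as.logical(pick("is_cell", "is__cell_barcode")),
      stringsAsFactors = FALSE)
  }
  bad <- which(!is.na(rec$frip) & (rec$frip < 0 | rec$frip > 1))
  assert_that(length(bad) == 0, "FRiP outside [0,1] at row %d",
              if (length(bad)) bad[1] else 0L)
  rec
}

#' Write a barcode-record table (named dialect)
#' @param records barcode-record `data.frame`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_barcode_summary <- function(records, file) {
  data.table::fwrite(records, file)
  invisible(file)
}
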