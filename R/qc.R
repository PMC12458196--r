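# Cell-level quality control: depth computation, threshold profiles,
# background-barcode ranking and the histology tissue score.

#' QC threshold profiles
#'
#' Named threshold profiles matching the published analyses:
#' \describe{
#'   \item{default}{mtDNA depth > 5, TSS enrichment > 1.5.}
#'   \item{als}{default plus an upper depth bound (strict < 100) and
#'     nuclear fragment count > 1,000.}
#'   \item{nb}{250 < nCount_peaks < 20,000, FRiP > 0.1,
#'     TSS enrichment > 1.5, nucleosome signal < 2, depth > 5.}
#'   \item{aorta}{>= 1,000 detected peaks, 2 < TSS < 10,
#'     nucleosome signal < 2, depth >= 5.}
#' }
#' All bounds are strict (`>`/`<`) unless noted; the aorta profile's
#' published exclusions ("TSS <= 2 or >= 10", "nucleosome signal >= 2",
#' "fewer than 1,000 peaks", "< 5x depth") translate into the strictness
#' encoded here.
#'
#' @param name profile name.
#' @return a list of bounds, class `qc_profile`.
#' @export
qc_profile <- function(name = c("default", "als", "nb", "aorta")) {
  name <- match.arg(name)
  prof <- switch(name,
    default = list(min_mtdna_depth = 5, min_tss = 1.5),
    als = list(min_mtdna_depth = 5, max_mtdna_depth = 100, min_tss = 1.5,
               min_fragments = 1000),
    nb = list(min_mtdna_depth = 5, min_tss = 1.5,
              min_n_count_peaks = 250, max_n_count_peaks = 20000,
              min_frip = 0.1, max_nucleosome_signal = 2),
    aorta = list(min_mtdna_depth = 5, depth_ge = TRUE,
                 min_n_count_peaks = 1000, n_count_peaks_ge = TRUE,
                 min_tss = 2, max_tss = 10, max_nucleosome_signal = 2))
  structure(c(prof, list(name = name)), class = "qc_profile")
}

#' Per-cell mean mitochondrial depth
#'
#' Mean coverage over the mitochondrial genome:
#' `depth(b) = sum_p coverage(b, p) / genome_length`.
#'
#' @param x a `strand_base_counts` object.
#' @return named numeric vector, one entry per barcode.
#' @export
per_cell_mtdna_depth <- function(x) {
  setNames(Matrix::colSums(coverage_matrix(x)) / x$genome_length,
           x$barcodes)
}

#' Filter cells against a QC threshold profile
#'
#' A barcode is kept iff it satisfies every bound present in the profile
#' with the profile's strictness; failure reasons enumerate every
#' violated bound. Bounds whose covariate is `NA` for a record fail that
#' record (missing evidence is not a pass).
#'
#' @param records barcode-record `data.frame` (see
#'   [read_barcode_summary()]).
#' @param depths named per-barcode depth vector
#'   (see [per_cell_mtdna_depth()]); must cover all records.
#' @param profile a [qc_profile()] or a compatible named list.
#' @return list with `kept` (character vector) and `reasons`
#'   (`data.frame` of barcode, reasons for every rejected barcode).
#' @export
filter_cells <- function(records, depths, profile = qc_profile("default")) {
  assert_that(all(records$barcode %in% names(depths)),
              "depths missing for some records")
  d <- depths[records$barcode]
  fails <- list()
  chk <- function(ok, reason) {
    ok[is.na(ok)] <- FALSE
    fails[[reason]] <<- !ok
  }
  depth_ge <- isTRUE(profile$depth_ge)
  if (!is.null(profile$min_mtdna_depth))
    chk(if (depth_ge) d >= profile$min_mtdna_depth
        else d > profile$min_mtdna_depth, "mtdna_depth_low")
  if (!is.null(profile$max_mtdna_depth))
    chk(d < profile$max_mtdna_depth, "mtdna_depth_high")
  if (!is.null(profile$min_tss))
    chk(records$tss_enrichment > profile$min_tss, "tss")
  if (!is.null(profile$max_tss))
    chk(records$tss_enrichment < profile$max_tss, "tss_high")
  if (!is.null(profile$min_fragments))
    chk(records$peak_region_fragments > profile$min_fragments, "fragments")
  if (!is.null(profile$max_nucleosome_signal))
    chk(records$nucleosome_signal < profile$max_nucleosome_signal,
        "nucleosome_signal")
  if (!is.null(profile$min_n_count_peaks))
    chk(if (isTRUE(profile$n_count_peaks_ge))
          records$n_count_peaks >= profile$min_n_count_peaks
        else records$n_count_peaks > profile$min_n_count_peaks,
        "n_count_peaks_low")
  if (!is.null(profile$max_n_count_peaks))
    chk(records$n_count_peaks < profile$max_n_count_peaks,
        "n_count_peaks_high")
  if (!is.null(profile$min_frip))
    chk(records$frip > profile$min_frip, "frip")
  failm <- do.call(cbind, fails)
  rejected <- if (is.null(failm)) rep(FALSE, nrow(records))
              else rowSums(failm) > 0
  reasons <- data.frame(
    barcode = records$barcode[rejected],
    reasons = if (!any(rejected)) character(0) else
      apply(failm[rejected, , drop = FALSE], 1, function(r) {
        paste(colnames(failm)[r], collapse = ";")
      }),
    stringsAsFactors = FALSE)
  list(kept = records$barcode[!rejected], reasons = reasons)
}

#' Rank barcodes for background genotyping
#'
#' Barcodes sorted by `peak_region_fragments` descending (ties broken by
#' barcode, lexicographically), truncated to `top_n`, then barcodes with
#' zero mitochondrial fragments removed (background genotyping is
#' impossible without mitochondrial reads). `keep_zero_mito = TRUE`
#' restores the literal upstream behaviour of keeping them.
#'
#' @param records barcode-record `data.frame`.
#' @param top_n number of top-ranked barcodes to retain before the
#'   zero-mito exclusion (default 20,000).
#' @param keep_zero_mito keep barcodes with `mito_fragments == 0`.
#' @return ordered character vector of barcodes.
#' @export
rank_background_barcodes <- function(records, top_n = 20000,
                                     keep_zero_mito = FALSE) {
  assert_that(top_n > 0, "top_n must be positive")
  ord <- order(-records$peak_region_fragments, records$barcode)
  top <- records[ord, ][seq_len(min(top_n, nrow(records))), ]
  if (!keep_zero_mito) {
    top <- top[!is.na(top$mito_fragments) & top$mito_fragments > 0, ]
    if (nrow(top) == 0) {
      warning("no ranked barcodes with nonzero mitochondrial fragments")
    }
  }
  top$barcode
}

#' Histological tissue score
#'
#' `TS = (I + (1 - N) + (1 - FA)) / 3` from the fractions of intact
#' nuclei (I), necrosis (N) and freezing artifacts (FA) estimated on
#' H&E-stained cryosections. Arguments may be given as fractions or as
#' percentages (values > 1 are interpreted as percent and divided by
#' 100).
#'
#' @param I fraction (or percent) of intact nuclei.
#' @param N fraction (or percent) of necrosis.
#' @param FA fraction (or percent) of freezing artifacts.
#' @return list with the normalised inputs and `TS` in [0, 1].
#' @examples
#' tissue_score(0.9, 0.2, 0.1)$TS  # 0.8666...
#' @export
tissue_score <- function(I, N, FA) {
  norm <- function(x, nm) {
    if (any(x > 1)) x <- x / 100
    assert_that(all(x >= 0 & x <= 1), "%s outside [0, 1] after scaling", nm)
    x
  }
  I <- norm(I, "I"); N <- norm(N, "N"); FA <- norm(FA, "FA")
  list(I = I, N = N, FA = FA, TS = (I + (1 - N) + (1 - FA)) / 3)
}

#' Correlate tissue scores with a QC metric
#'
#' Pearson correlation with the two-sided p-value from the usual
#' t transform.
#'
#' @param ts_values numeric vector of tissue scores.
#' @param qc_metric numeric vector of a per-sample QC metric.
#' @return list with `r`, `p`, and `n`.
#' @export
correlate_scores <- function(ts_values, qc_metric) {
  assert_that(length(ts_values) == length(qc_metric) &&
                length(ts_values) >= 3,
              "need equal-length vectors with n >= 3")
  assert_that(stats::sd(ts_values) > 0 && stats::sd(qc_metric) > 0,
              "correlation undefined: zero variance")
  ct <- cor.test(ts_values, qc_metric, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ts_values))
}
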