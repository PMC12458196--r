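# Ambient mtDNA background model. Conceptually mirrors the
# empty-droplet workflow of droplet decontamination tools: the ambient
# alternate-allele fraction of each variant is estimated by pooling
# empty droplets, each cell receives an ambient scale factor, and the
# expected ambient contribution is removed from the per-cell alternate
# counts. The model is closed-form and deterministic (no training).

#' Select empty droplets for background estimation
#'
#' The top `total_droplets` barcodes ranked by `peak_region_fragments`,
#' minus the called cells, keeping only barcodes with more than
#' `low_count_threshold` mitochondrial fragments.
#'
#' @param records barcode-record `data.frame`.
#' @param called_cells barcodes identified as cells upstream.
#' @param total_droplets ranking depth (default 20,000).
#' @param low_count_threshold strict lower bound on mitochondrial
#'   fragments (default 1).
#' @return character vector of empty-droplet barcodes.
#' @export
select_empty_droplets <- function(records, called_cells,
                                  total_droplets = 20000,
                                  low_count_threshold = 1) {
  ord <- order(-records$peak_region_fragments, records$barcode)
  top <- records[ord, ][seq_len(min(total_droplets, nrow(records))), ]
  empties <- top$barcode[!(top$barcode %in% called_cells) &
                           !is.na(top$mito_fragments) &
                           top$mito_fragments > low_count_threshold]
  if (length(empties) == 0) {
    stop_cc("no background droplets after exclusions",
            class = "cryoclone_ambient_error")
  }
  empties
}

#' Estimate the ambient allele profile from empty droplets
#'
#' Pooled posterior-mean estimate with a symmetric pseudocount:
#' `alpha(v) = (sum(alt) + pseudocount * 0.5) /
#'             (sum(coverage) + pseudocount)`
#' over the empty droplets. Variants with zero empty coverage get
#' `alpha = NA` and are flagged.
#'
#' @param x a `strand_base_counts` object.
#' @param variants variant `data.frame`.
#' @param empties empty-droplet barcodes.
#' @param pseudocount positive smoothing mass (default 1).
#' @return an `ambient_profile`: list with `variants`, `alpha`,
#'   `empty_droplets`, `total_ambient_reads`, `pseudocount`,
#'   `uncovered` (labels with zero empty coverage).
#' @export
estimate_ambient_profile <- function(x, variants, empties,
                                     pseudocount = 1) {
  assert_that(length(empties) > 0, "empties must be non-empty")
  assert_that(pseudocount > 0, "pseudocount must be positive")
  het <- compute_heteroplasmy(x, variants, cells = empties)
  altsum <- colSums(het$alt_fwd + het$alt_rev)
  covsum <- colSums(het$cov)
  alpha <- (altsum + pseudocount * 0.5) / (covsum + pseudocount)
  alpha[covsum == 0] <- NA_real_
  structure(list(variants = variants,
                 alpha = setNames(alpha, variants$label),
                 empty_coverage = setNames(covsum, variants$label),
                 empty_droplets = empties,
                 total_ambient_reads = sum(covsum),
                 pseudocount = pseudocount,
                 uncovered = variants$label[covsum == 0]),
            class = "ambient_profile")
}

#' @exportS3Method base::print
print.ambient_profile <- function(x, ...) {
  cat(sprintf(
    "ambient_profile: %d variants, %d empty droplets, %.0f pooled reads\n",
    nrow(x$variants), length(x$empty_droplets), x$total_ambient_reads))
  invisible(x)
}

#' Estimate the per-cell ambient fraction
#'
#' Marker variants are those with an appreciable ambient allele fraction
#' (`alpha >= marker_alpha_min`). For each cell, only markers at which
#' the cell itself looks negative (`af < negative_af_max`) contribute,
#' so that a cell's own variants never inflate its ambient estimate:
#' `rho(b) = sum(alt) / sum(cov * alpha)` over those markers, clipped to
#' [0, 1]. Cells with no usable marker receive the cohort median
#' (fallback counted in the result).
#'
#' @param x a `strand_base_counts` object.
#' @param cells called-cell barcodes.
#' @param profile an [estimate_ambient_profile()] result.
#' @param het optional precomputed `heteroplasmy_matrix` over `cells`
#'   and the profile's variants.
#' @param marker_alpha_min minimum ambient allele fraction for a marker.
#' @param negative_af_max per-cell allele-frequency ceiling under which
#'   the cell is presumed negative for the marker.
#' @return list with `rho` (named per-cell vector) and `n_fallback`.
#' @export
estimate_cell_ambient_fraction <- function(x, cells, profile, het = NULL,
                                           marker_alpha_min = 0.05,
                                           negative_af_max = 0.20) {
  markers <- which(!is.na(profile$alpha) &
                     profile$alpha >= marker_alpha_min)
  if (length(markers) == 0) {
    stop_cc(paste("no ambient marker variants (alpha >= %g); supply",
                  "multi-donor markers or an explicit variant list"),
            marker_alpha_min, class = "cryoclone_ambient_error")
  }
  if (is.null(het)) {
    het <- compute_heteroplasmy(x, profile$variants, cells = cells)
  }
  alt <- (het$alt_fwd + het$alt_rev)[, markers, drop = FALSE]
  cov <- het$cov[, markers, drop = FALSE]
  af <- het$af[, markers, drop = FALSE]
  alpha <- profile$alpha[markers]
  usable <- cov > 0 & af < negative_af_max
  num <- rowSums(alt * usable)
  den <- rowSums(t(t(cov * usable) * alpha))
  rho <- ifelse(den > 0, pmin(1, pmax(0, num / den)), NA_real_)
  n_fallback <- sum(is.na(rho))
  if (n_fallback > 0) {
    rho[is.na(rho)] <- median(rho, na.rm = TRUE)
  }
  list(rho = setNames(rho, het$cells), n_fallback = n_fallback)
}

#' Correct per-cell counts for ambient contamination
#'
#' For every cell b and variant v the expected ambient alternate count
#' is `e = rho(b) * cov(b, v) * alpha(v)`. The corrected alternate count
#' is `max(0, k - round(e))` with round-half-away-from-zero. When
#' `tail_prob` is set, entries whose observed count is consistent with
#' pure ambient origin (`k <= qbinom(1 - tail_prob, cov, rho * alpha)`)
#' are zeroed entirely first -- a per-entry one-sided test that removes
#' low counts indistinguishable from background, analogous to posterior
#' denoising in droplet decontamination tools; pure expectation
#' subtraction cannot remove sub-integer expected contamination and
#' leaves most of it in place at typical single-cell depths.
#'
#' Removed reads are split across strands proportionally to the observed
#' strand counts (remainder to the strand with more counts, ties to
#' forward). `"reassign"` mode adds removed reads to the reference
#' allele on the same strand, preserving coverage; `"drop"` mode deletes
#' them.
#'
#' @param x a `strand_base_counts` object.
#' @param cells cell barcodes to correct.
#' @param profile an `ambient_profile`.
#' @param rho named per-cell ambient fractions.
#' @param mode `"reassign"` (coverage-preserving, default) or `"drop"`.
#' @param tail_prob one-sided tail probability for the
#'   ambient-consistency test, or `NULL` (default) for pure expected-
#'   count subtraction.
#' @return list with `tensor` (corrected `strand_base_counts`),
#'   `removed` (cells x variants matrix of removed read counts) and
#'   `total_removed`.
#' @export
correct_counts <- function(x, cells, profile, rho,
                           mode = c("reassign", "drop"),
                           tail_prob = NULL) {
  mode <- match.arg(mode)
  assert_that(all(cells %in% names(rho)), "rho missing for some cells")
  variants <- profile$variants
  het <- compute_heteroplasmy(x, variants, cells = cells)
  alpha <- profile$alpha
  alpha[is.na(alpha)] <- 0
  rr <- rho[cells]
  e <- (het$cov * outer(rr, alpha)) # expected ambient alt reads
  k <- het$alt_fwd + het$alt_rev
  removal <- pmin(k, round_half_away(e))
  if (!is.null(tail_prob)) {
    p_amb <- outer(rr, alpha)
    thr <- qbinom(1 - tail_prob, size = het$cov, prob = pmin(1, p_amb))
    removal[k <= thr] <- k[k <= thr]
  }
  # split removal across strands proportional to observed strand counts;
  # remainder goes to the strand with more counts (ties to forward)
  frac_f <- ifelse(k > 0, het$alt_fwd / pmax(k, 1), 0)
  rm_f <- floor(removal * frac_f + 1e-9)
  rm_r <- floor(removal * (1 - frac_f) + 1e-9)
  rem <- removal - rm_f - rm_r
  to_f <- het$alt_fwd >= het$alt_rev
  rm_f <- rm_f + rem * to_f
  rm_r <- rm_r + rem * (!to_f)
  over_f <- pmax(0, rm_f - het$alt_fwd)   # guard against rounding overflow
  over_r <- pmax(0, rm_r - het$alt_rev)
  rm_f <- rm_f - over_f + over_r
  rm_r <- rm_r - over_r + over_f
  stopifnot(all(rm_f <= het$alt_fwd), all(rm_r <= het$alt_rev),
            all(rm_f >= 0), all(rm_r >= 0))

  counts <- lapply(x$counts, function(bs) lapply(bs, identity))
  j <- match(cells, x$barcodes)
  adjust <- function(m, pos_v, delta_mat) {
    # delta_mat: cells x variants(subset) additive adjustment
    nz <- which(delta_mat != 0, arr.ind = TRUE)
    if (nrow(nz) == 0) return(m)
    idx <- cbind(pos_v[nz[, 2]], j[nz[, 1]])
    m <- methods::as(m, "CsparseMatrix")
    m[idx] <- m[idx] + delta_mat[nz]
    m
  }
  for (b in BASES) {
    vs <- which(variants$alt == b)
    if (length(vs)) {
      counts[[b]]$fwd <- adjust(counts[[b]]$fwd, variants$position[vs],
                                -rm_f[, vs, drop = FALSE])
      counts[[b]]$rev <- adjust(counts[[b]]$rev, variants$position[vs],
                                -rm_r[, vs, drop = FALSE])
    }
    if (mode == "reassign") {
      vs <- which(variants$ref == b)
      if (length(vs)) {
        counts[[b]]$fwd <- adjust(counts[[b]]$fwd, variants$position[vs],
                                  rm_f[, vs, drop = FALSE])
        counts[[b]]$rev <- adjust(counts[[b]]$rev, variants$position[vs],
                                  rm_r[, vs, drop = FALSE])
      }
    }
  }
  tensor <- strand_base_counts(x$barcodes, x$genome_length, counts)
  list(tensor = tensor, removed = removal, rho = rr,
       total_removed = sum(removal))
}

#' Remove ambient mtDNA background (end-to-end)
#'
#' Orchestrates the background workflow on in-memory objects:
#' background-barcode ranking, empty-droplet selection, ambient-profile
#' estimation, per-cell ambient-fraction estimation and count
#' correction. When `variants` is `NULL`, candidate variants are called
#' against the majority-base consensus of all ranked barcodes and
#' filtered with the default high-confidence thresholds.
#'
#' By default the ambient-consistency test is enabled
#' (`tail_prob = 0.01`): entries statistically indistinguishable from
#' pure ambient background are zeroed; set `tail_prob = NULL` for pure
#' expected-count subtraction.
#'
#' @param x a `strand_base_counts` object.
#' @param records barcode-record `data.frame`.
#' @param called_cells cell barcodes.
#' @param variants optional explicit variant `data.frame`.
#' @param total_droplets,low_count_threshold see
#'   [select_empty_droplets()].
#' @param mode correction mode, see [correct_counts()].
#' @param tail_prob see [correct_counts()]; default `0.01`.
#' @param pseudocount see [estimate_ambient_profile()].
#' @return list with `tensor`, `profile`, `rho`, `removed`,
#'   `report` (per-stage summary list).
#' @export
remove_background <- function(x, records, called_cells, variants = NULL,
                              total_droplets = 20000,
                              low_count_threshold = 1,
                              mode = "reassign", tail_prob = 0.01,
                              pseudocount = 1) {
  ranked <- rank_background_barcodes(records, top_n = total_droplets)
  empties <- select_empty_droplets(records, called_cells,
                                   total_droplets = total_droplets,
                                   low_count_threshold = low_count_threshold)
  if (is.null(variants)) {
    consensus <- consensus_reference(x, ranked)
    cand <- call_candidate_variants(x, consensus, cells = called_cells)
    het0 <- compute_heteroplasmy(x, cand, cells = called_cells)
    variants <- filter_high_confidence(compute_variant_metrics(het0))
    variants <- variants[, c("position", "ref", "alt", "label")]
    assert_that(nrow(variants) > 0,
                "no variable positions found for background removal")
  }
  profile <- estimate_ambient_profile(x, variants, empties,
                                      pseudocount = pseudocount)
  het <- compute_heteroplasmy(x, variants, cells = called_cells)
  rho_est <- estimate_cell_ambient_fraction(x, called_cells, profile,
                                            het = het)
  corr <- correct_counts(x, called_cells, profile, rho_est$rho,
                         mode = mode, tail_prob = tail_prob)
  report <- list(
    n_ranked = length(ranked), n_empty = length(empties),
    n_cells = length(called_cells), n_variants = nrow(variants),
    rho_summary = unname(stats::quantile(rho_est$rho,
                                         c(0, 0.25, 0.5, 0.75, 1))),
    n_rho_fallback = rho_est$n_fallback,
    total_removed = corr$total_removed,
    alpha = profile$alpha)
  list(tensor = corr$tensor, profile = profile, rho = rho_est$rho,
       removed = corr$removed, report = report)
}

#' Majority-base consensus reference
#'
#' The base with the highest pooled count at each position (ties to the
#' alphabetically first base); positions with zero pooled coverage are
#' `N`.
#'
#' @param x a `strand_base_counts` object.
#' @param barcodes barcodes to pool.
#' @return character vector of length `genome_length`.
#' @export
consensus_reference <- function(x, barcodes = x$barcodes) {
  j <- match(barcodes, x$barcodes)
  assert_that(!anyNA(j), "unknown barcode in consensus pool")
  tot <- vapply(BASES, function(b) {
    Matrix::rowSums(base_count_matrix(x, b)[, j, drop = FALSE])
  }, numeric(x$genome_length))
  if (is.null(dim(tot))) tot <- matrix(tot, nrow = 1)
  ref <- BASES[max.col(tot, ties.method = "first")]
  ref[rowSums(tot) == 0] <- "N"
  ref
}

#' File-based background removal
#'
#' Reads mgatk-dialect tables and a barcode summary, runs
#' [remove_background()] and writes corrected tables plus a JSON report.
#'
#' @param counts_dir input table directory.
#' @param singlecell_file barcode summary (positional dialect).
#' @param cells_file text file of called-cell barcodes, one per line.
#' @param out_dir output directory.
#' @param variants_file optional text file of variant labels.
#' @param genome_length genome length.
#' @param ... passed to [remove_background()].
#' @return the [remove_background()] result, invisibly.
#' @export
remove_background_files <- function(counts_dir, singlecell_file, cells_file,
                                    out_dir, variants_file = NULL,
                                    genome_length = 16569, ...) {
  x <- read_strand_counts(counts_dir, genome_length = genome_length)
  records <- read_barcode_summary(singlecell_file, dialect = "positional")
  cells <- readLines(cells_file)
  variants <- if (!is.null(variants_file)) {
    parse_variant_label(readLines(variants_file),
                        genome_length = genome_length)
  }
  res <- remove_background(x, records, cells, variants = variants, ...)
  write_strand_counts(res$tensor, out_dir)
  rep <- res$report
  rep$alpha <- as.list(rep$alpha)
  jsonlite::write_json(rep, file.path(out_dir, "background_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
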