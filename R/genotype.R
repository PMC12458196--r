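# Per-cell heteroplasmy, variant-confidence metrics, pseudobulk
# summaries, substitution spectra and variant-set overlaps.

#' Per-cell heteroplasmy matrix
#'
#' Allele frequencies from strand-specific counts normalised by coverage:
#' `af(b, v) = (alt_fwd + alt_rev) / coverage` at the variant position.
#' Entries with zero coverage are missing: `af = 0` with the missing mask
#' set.
#'
#' @param x a `strand_base_counts` object.
#' @param variants variant `data.frame`.
#' @param cells barcodes to genotype (subset of the tensor's barcodes).
#' @return a `heteroplasmy_matrix`: list with `cells`, `variants`, dense
#'   `af` and `cov` matrices (cells x variants) and helper accessors.
#' @export
compute_heteroplasmy <- function(x, variants, cells = x$barcodes) {
  j <- match(cells, x$barcodes)
  assert_that(!anyNA(j), "cells must be a subset of tensor barcodes")
  pos <- variants$position
  covm <- coverage_matrix(x)
  cov <- t(as.matrix(covm[pos, j, drop = FALSE]))
  altf <- matrix(0, length(cells), nrow(variants))
  altr <- matrix(0, length(cells), nrow(variants))
  for (b in BASES) {
    vs <- which(variants$alt == b)
    if (length(vs) == 0) next
    altf[, vs] <- t(as.matrix(x$counts[[b]]$fwd[pos[vs], j, drop = FALSE]))
    altr[, vs] <- t(as.matrix(x$counts[[b]]$rev[pos[vs], j, drop = FALSE]))
  }
  alt <- altf + altr
  stopifnot(all(alt <= cov))                 # alt reads never exceed coverage
  af <- ifelse(cov > 0, alt / pmax(cov, 1), 0)
  dimnames(af) <- dimnames(cov) <- dimnames(altf) <- dimnames(altr) <-
    list(cells, variants$label)
  structure(list(cells = cells, variants = variants, af = af, cov = cov,
                 alt_fwd = altf, alt_rev = altr),
            class = "heteroplasmy_matrix")
}

#' @exportS3Method base::print
print.heteroplasmy_matrix <- function(x, ...) {
  cat(sprintf("heteroplasmy_matrix: %d cells x %d variants\n",
              length(x$cells), nrow(x$variants)))
  invisible(x)
}

#' Enumerate candidate variants
#'
#' Every (position, alt != ref) combination with at least one alternate
#' read in at least one of the given cells; positions whose reference
#' base is `N` are skipped.
#'
#' @param x a `strand_base_counts` object.
#' @param reference character vector of reference bases, length
#'   `genome_length`.
#' @param cells barcodes to scan.
#' @return a variant `data.frame`, ordered by position then alt base.
#' @export
call_candidate_variants <- function(x, reference, cells = x$barcodes) {
  assert_that(length(reference) == x$genome_length,
              "reference length %d != genome length %d",
              length(reference), x$genome_length)
  j <- match(cells, x$barcodes)
  assert_that(!anyNA(j), "cells must be a subset of tensor barcodes")
  reference <- toupper(reference)
  hits <- list()
  for (b in BASES) {
    tot <- Matrix::rowSums(base_count_matrix(x, b)[, j, drop = FALSE])
    p <- which(tot > 0 & reference != b & reference != "N")
    if (length(p)) {
      hits[[b]] <- data.frame(position = p, ref = reference[p], alt = b)
    }
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) {
    return(variant(integer(0), character(0), character(0),
                   genome_length = x$genome_length)[0, ])
  }
  hits <- hits[order(hits$position, hits$alt), ]
  variant(hits$position, hits$ref, hits$alt, genome_length = x$genome_length)
}

#' Variant-confidence metrics
#'
#' Per variant, over the cells of a heteroplasmy matrix:
#' \itemize{
#'   \item `n_cells_conf_detected`: cells with at least
#'     `conf_min_alt_per_strand` alternate reads on each strand and at
#'     least `conf_min_alt_total` in total;
#'   \item `strand_concordance`: Pearson correlation across cells of the
#'     per-cell forward vs reverse alternate read counts, computed over
#'     cells with nonzero coverage; `NA` when fewer than two cells carry
#'     alternate reads or either strand has zero variance;
#'   \item `mean_coverage`: mean per-cell coverage at the position;
#'   \item `log10_vmr`: log10 of the variance-to-mean ratio of the
#'     per-cell allele frequency over covered cells (population variance,
#'     `ddof = 0` by default); `NA` when the mean is zero;
#'   \item `pseudobulk_het_mean` / `pseudobulk_het_aggregate`: mean of
#'     per-cell allele frequencies over covered cells, and the pooled
#'     `sum(alt) / sum(coverage)` ratio;
#'   \item `n_cells_over_threshold`: cells with
#'     `af > positivity_threshold`.
#' }
#' Undefined metrics are reported as `NA`, never as 0.
#'
#' @param het a `heteroplasmy_matrix`.
#' @param conf_min_alt_per_strand,conf_min_alt_total confident-detection
#'   thresholds.
#' @param positivity_threshold strict positivity threshold on `af`.
#' @param ddof variance denominator offset for the VMR (0 = population
#'   variance).
#' @return a `data.frame`, one row per variant.
#' @export
compute_variant_metrics <- function(het, conf_min_alt_per_strand = 1,
                                    conf_min_alt_total = 2,
                                    positivity_threshold = 0.20,
                                    ddof = 0) {
  nv <- nrow(het$variants)
  out <- het$variants
  out$n_cells_conf_detected <- integer(nv)
  out$strand_concordance <- NA_real_
  out$mean_coverage <- NA_real_
  out$log10_vmr <- NA_real_
  out$pseudobulk_het_mean <- NA_real_
  out$pseudobulk_het_aggregate <- NA_real_
  out$n_cells_over_threshold <- integer(nv)
  for (v in seq_len(nv)) {
    fwd <- het$alt_fwd[, v]; rev <- het$alt_rev[, v]
    alt <- fwd + rev; cov <- het$cov[, v]; af <- het$af[, v]
    covered <- cov > 0
    out$n_cells_conf_detected[v] <- sum(
      fwd >= conf_min_alt_per_strand & rev >= conf_min_alt_per_strand &
        alt >= conf_min_alt_total)
    nz <- covered & alt > 0
    if (sum(nz) >= 2 && var(fwd[covered]) > 0 && var(rev[covered]) > 0) {
      out$strand_concordance[v] <- cor(fwd[covered], rev[covered])
    }
    out$mean_coverage[v] <- mean(cov)
    if (any(covered)) {
      m <- mean(af[covered])
      n <- sum(covered)
      if (m > 0 && n > ddof) {
        vpop <- sum((af[covered] - m)^2) / (n - ddof)
        out$log10_vmr[v] <- log10(vpop / m)
      }
      out$pseudobulk_het_mean[v] <- m
      out$pseudobulk_het_aggregate[v] <- sum(alt[covered]) / sum(cov[covered])
    }
    out$n_cells_over_threshold[v] <- sum(af > positivity_threshold)
  }
  out
}

#' High-confidence variant filter
#'
#' Keep iff `n_cells_conf_detected >= min_cells` AND
#' `strand_concordance > min_concordance` AND
#' `log10_vmr > min_log10_vmr` AND `mean_coverage >= min_mean_cov`.
#' Undefined (`NA`) metrics fail.
#'
#' @param metrics output of [compute_variant_metrics()].
#' @param min_cells,min_concordance,min_log10_vmr,min_mean_cov published
#'   empirical thresholds.
#' @return the retained rows of `metrics`.
#' @export
filter_high_confidence <- function(metrics, min_cells = 5,
                                   min_concordance = 0.65,
                                   min_log10_vmr = -2, min_mean_cov = 5) {
  keep <- !is.na(metrics$strand_concordance) & !is.na(metrics$log10_vmr) &
    !is.na(metrics$mean_coverage) &
    metrics$n_cells_conf_detected >= min_cells &
    metrics$strand_concordance > min_concordance &
    metrics$log10_vmr > min_log10_vmr &
    metrics$mean_coverage >= min_mean_cov
  metrics[keep, , drop = FALSE]
}

#' Pseudobulk heteroplasmy per group
#'
#' `mean` mode averages per-cell allele frequencies over covered cells of
#' each group; `aggregate` mode pools reads (`sum(alt) / sum(cov)`).
#' The two coincide exactly when all covered cells of a group share the
#' same coverage at the position. Groups with no covered cell are `NA`.
#'
#' @param het a `heteroplasmy_matrix`.
#' @param groups named character vector mapping every cell to a group.
#' @param mode `"mean"` (default) or `"aggregate"`.
#' @return matrix variants x groups of fractions.
#' @export
pseudobulk_heteroplasmy <- function(het, groups, mode = c("mean",
                                                          "aggregate")) {
  mode <- match.arg(mode)
  assert_that(all(het$cells %in% names(groups)), "every cell must be labeled")
  g <- factor(groups[het$cells])
  out <- matrix(NA_real_, nrow(het$variants), nlevels(g),
                dimnames = list(het$variants$label, levels(g)))
  for (lv in levels(g)) {
    rows <- which(g == lv)
    for (v in seq_len(nrow(het$variants))) {
      cov <- het$cov[rows, v]; covered <- cov > 0
      if (!any(covered)) next
      out[v, lv] <- if (mode == "mean") mean(het$af[rows, v][covered])
      else sum(het$af[rows, v][covered] * cov[covered]) / sum(cov[covered])
    }
  }
  out
}

#' Substitution spectrum
#'
#' Counts and proportions over the 12 substitution classes, plus the
#' conventional 6-class pyrimidine-context collapse (purine
#' substitutions mapped to their reverse complement, e.g. `G>A` counted
#' as `C>T`).
#'
#' @param variants variant `data.frame`.
#' @return list with `counts12`, `proportions12`, `counts6`,
#'   `proportions6`.
#' @export
substitution_spectrum <- function(variants) {
  classes12 <- as.vector(outer(BASES, BASES, function(r, a) {
    paste0(r, ">", a)
  }))
  classes12 <- classes12[substr(classes12, 1, 1) !=
                           substr(classes12, 3, 3)]
  classes12 <- sort(classes12)
  cls <- paste0(variants$ref, ">", variants$alt)
  counts12 <- setNames(tabulate(factor(cls, classes12), length(classes12)),
                       classes12)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pyr <- ifelse(substr(classes12, 1, 1) %in% c("C", "T"), classes12,
                paste0(comp[substr(classes12, 1, 1)], ">",
                       comp[substr(classes12, 3, 3)]))
  classes6 <- sort(unique(pyr))
  counts6 <- setNames(vapply(classes6, function(k) {
    sum(counts12[pyr == k])
  }, 0), classes6)
  tot <- sum(counts12)
  list(counts12 = counts12,
       proportions12 = if (tot > 0) counts12 / tot else counts12 * 0,
       counts6 = counts6,
       proportions6 = if (tot > 0) counts6 / tot else counts6 * 0)
}

#' Variant-set overlaps across groups
#'
#' Venn-style sharing: for each variant the exact subset of groups that
#' contain it, and the count per group combination. Combination counts
#' partition the union of all sets.
#'
#' @param sets named list mapping a group to a character vector of
#'   variant labels.
#' @return list with `membership` (data.frame: variant, groups) and
#'   `combination_counts` (named integer vector keyed by
#'   `group1+group2+...`).
#' @export
variant_set_overlap <- function(sets) {
  assert_that(length(sets) >= 1 && !is.null(names(sets)),
              "sets must be a named list with >= 1 group")
  union_v <- sort(unique(unlist(sets, use.names = FALSE)))
  combo <- vapply(union_v, function(v) {
    paste(names(sets)[vapply(sets, function(s) v %in% s, TRUE)],
          collapse = "+")
  }, "")
  membership <- data.frame(variant = union_v, groups = unname(combo),
                           stringsAsFactors = FALSE)
  counts <- table(combo)
  list(membership = membership,
       combination_counts = setNames(as.integer(counts), names(counts)))
}
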