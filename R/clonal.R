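# Clone definition and lineage-bias statistics: strict VAF binarization,
# top-variant selection, Jaccard/Ward clone clustering, tie-corrected
# Kruskal-Wallis tests with Benjamini-Hochberg correction.

#' Binarize clone presence
#'
#' `presence(b, v) = (af > threshold) AND (cov >= min_cov)`.
#' The comparator is strictly-greater by default ("VAF exceeded 20%");
#' `comparator = ">="` switches to the inclusive reading.
#'
#' @param het a `heteroplasmy_matrix`.
#' @param threshold positivity threshold on allele frequency.
#' @param min_cov minimum coverage for a callable entry.
#' @param comparator `">"` (default, strict) or `">="`.
#' @return a `clone_presence` object: logical cells x variants matrix
#'   plus `retained_cells` (cells with >= 1 positive variant) and the
#'   threshold used.
#' @export
binarize_presence <- function(het, threshold = 0.20, min_cov = 1,
                              comparator = c(">", ">=")) {
  comparator <- match.arg(comparator)
  pos <- if (comparator == ">") het$af > threshold else het$af >= threshold
  pos <- pos & het$cov >= min_cov
  structure(list(presence = pos, threshold = threshold,
                 comparator = comparator,
                 cells = het$cells, variants = het$variants,
                 retained_cells = het$cells[rowSums(pos) > 0]),
            class = "clone_presence")
}

#' Select top pseudobulk-heteroplasmy variants
#'
#' Sort by pseudobulk heteroplasmy descending (ties broken by position
#' ascending) and truncate to `n`.
#'
#' @param metrics output of [compute_variant_metrics()].
#' @param n number of variants to keep (default 50).
#' @param mode which pseudobulk column to rank on.
#' @return the top rows of `metrics`, in rank order.
#' @export
select_top_variants <- function(metrics, n = 50,
                                mode = c("mean", "aggregate")) {
  mode <- match.arg(mode)
  assert_that(n > 0, "n must be positive")
  col <- paste0("pseudobulk_het_", mode)
  ord <- order(-metrics[[col]], metrics$position)
  metrics[ord, , drop = FALSE][seq_len(min(n, nrow(metrics))), ,
                               drop = FALSE]
}

#' Cluster cells into clones
#'
#' Cells positive for at least one variant are clustered on their
#' positive-variant sets with Jaccard (binary) distance and Ward
#' linkage; clone labels come from cutting the tree at `k` clusters or
#' at `cut_height`. The default `k` is the number of variants with at
#' least one positive cell.
#'
#' @param presence a [binarize_presence()] result.
#' @param k number of clones (exclusive with `cut_height`).
#' @param cut_height dendrogram cut height (exclusive with `k`).
#' @return list with `labels` (named integer clone ids over retained
#'   cells), `tree` (`hclust` or `NULL` for a single cell), `k`.
#' @export
cluster_clones <- function(presence, k = NULL, cut_height = NULL) {
  stopifnot(inherits(presence, "clone_presence"))
  assert_that(is.null(k) || is.null(cut_height),
              "supply at most one of k / cut_height")
  keep <- presence$cells %in% presence$retained_cells
  mat <- presence$presence[keep, , drop = FALSE] * 1
  cells <- presence$cells[keep]
  if (length(cells) == 0) {
    return(list(labels = setNames(integer(0), character(0)), tree = NULL,
                k = 0L))
  }
  if (length(cells) == 1) {
    return(list(labels = setNames(1L, cells), tree = NULL, k = 1L))
  }
  d <- jaccard_distance(mat)
  tree <- hclust(as.dist(d), method = "ward.D")
  if (is.null(k) && is.null(cut_height)) {
    k <- min(sum(colSums(mat) > 0), length(cells))
  }
  labels <- if (!is.null(k)) cutree(tree, k = min(k, length(cells)))
            else cutree(tree, h = cut_height)
  list(labels = setNames(labels, cells), tree = tree,
       k = length(unique(labels)))
}

#' Pairwise Jaccard distance on binary rows
#'
#' `d(A, B) = 1 - |A intersect B| / |A union B|`; rows with identical
#' sets (including two empty sets) get distance 0.
#'
#' @param mat binary (0/1) matrix, observations in rows.
#' @return dense symmetric distance matrix.
#' @export
jaccard_distance <- function(mat) {
  mat <- as.matrix(mat) * 1
  inter <- mat %*% t(mat)
  sizes <- rowSums(mat)
  un <- outer(sizes, sizes, "+") - inter
  d <- ifelse(un > 0, 1 - inter / pmax(un, 1), 0)
  diag(d) <- 0
  d
}

#' Lineage-bias table
#'
#' Per variant, a tie-corrected Kruskal-Wallis test of the per-cell
#' allele frequencies across cell-type groups (chi-square
#' approximation, df = groups - 1), Benjamini-Hochberg adjustment over
#' all tested variants, and per-group mean heteroplasmy plus
#' positive-cell counts. Variants with fewer than two groups containing
#' a covered cell are skipped (reported in `skipped`). When all values
#' are identical across groups the convention `H = 0, p = 1` applies.
#'
#' @param het a `heteroplasmy_matrix`.
#' @param groups named character vector mapping cells to cell types.
#' @param variants optional variant subset (default: all).
#' @param positivity_threshold strict threshold for positive-cell
#'   counts.
#' @return list with `table` (data.frame: label, H, p, p_adj, per-group
#'   columns) and `skipped`.
#' @export
lineage_bias <- function(het, groups, variants = het$variants,
                         positivity_threshold = 0.20) {
  assert_that(all(het$cells %in% names(groups)), "every cell must be labeled")
  g <- factor(groups[het$cells])
  idx <- match(variants$label, het$variants$label)
  assert_that(!anyNA(idx), "variants missing from heteroplasmy matrix")
  rows <- list()
  skipped <- character(0)
  for (v in idx) {
    cov <- het$cov[, v]; af <- het$af[, v]
    covered <- cov > 0
    gv <- droplevels(g[covered])
    if (nlevels(gv) < 2) {
      skipped <- c(skipped, het$variants$label[v])
      next
    }
    x <- af[covered]
    if (length(unique(x)) == 1) {
      H <- 0; p <- 1
    } else {
      kt <- kruskal.test(x, gv)
      H <- unname(kt$statistic); p <- kt$p.value
    }
    means <- tapply(x, gv, mean)
    npos <- tapply(af > positivity_threshold & covered, g, sum)
    row <- data.frame(label = het$variants$label[v], H = H, p = p,
                      stringsAsFactors = FALSE)
    for (lv in levels(g)) {
      row[[paste0("mean_het.", lv)]] <-
        if (lv %in% names(means)) unname(means[lv]) else NA_real_
      row[[paste0("n_pos.", lv)]] <- unname(npos[lv])
    }
    rows[[length(rows) + 1L]] <- row
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), H = numeric(0), p = numeric(0))
  if (nrow(tab)) tab$p_adj <- p.adjust(tab$p, method = "BH")
  else tab$p_adj <- numeric(0)
  list(table = tab, skipped = skipped)
}

#' Filter lineage-biased variants for a target group
#'
#' Keep iff `p_adj <= max_p_adj` and the positive-cell count in the
#' target group is at least `min_cells`.
#'
#' @param bias a [lineage_bias()] result (or its `table`).
#' @param target_group group label.
#' @param max_p_adj adjusted-p ceiling (inclusive).
#' @param min_cells minimum positive cells in the target group
#'   (inclusive).
#' @return the retained table rows.
#' @export
filter_biased_variants <- function(bias, target_group, max_p_adj = 0.05,
                                   min_cells = 4) {
  tab <- bias$table %||% bias
  col <- paste0("n_pos.", target_group)
  assert_that(col %in% names(tab), "unknown group '%s'", target_group)
  tab[!is.na(tab$p_adj) & tab$p_adj <= max_p_adj &
        tab[[col]] >= min_cells, , drop = FALSE]
}

#' Positive cells of a variant, split by group
#'
#' @param presence a [binarize_presence()] result.
#' @param label a variant label present in the matrix.
#' @param groups named character vector mapping cells to groups.
#' @return named list of barcode vectors, one per group with >= 1
#'   positive cell; empty list (with a warning) if the variant is
#'   absent or has no positives.
#' @export
clone_cells_across_groups <- function(presence, label, groups) {
  v <- match(label, presence$variants$label)
  if (is.na(v)) {
    warning(sprintf("variant '%s' not in presence matrix", label))
    return(list())
  }
  cells <- presence$cells[presence$presence[, v]]
  if (length(cells) == 0) return(list())
  split(cells, factor(groups[cells]))
}
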