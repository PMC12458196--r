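presence_fixture <- function(af, cov = NULL, threshold = 0.20) {
  # af: cells x variants matrix; build a het-like object directly
  if (is.null(cov)) cov <- matrix(20, nrow(af), ncol(af))
  cells <- sprintf("c%d", seq_len(nrow(af)))
  vars <- variant(seq_len(ncol(af)) * 2, "A", "G", 1000)
  het <- structure(list(cells = cells, variants = vars,
                        af = af, cov = cov,
                        alt_fwd = af * cov / 2, alt_rev = af * cov / 2),
                   class = "heteroplasmy_matrix")
  binarize_presence(het, threshold = threshold)
}

test_that("binarization is strictly greater-than and monotone in the
           threshold", {
  af <- matrix(c(0.20, 0.21, 0, 0.5), 2, 2)
  pres <- presence_fixture(af)
  expect_equal(unname(pres$presence),
               matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  # coverage gate
  pres_cov <- presence_fixture(af, cov = matrix(c(20, 0, 20, 20), 2, 2))
  expect_false(pres_cov$presence[2, 1])
  # monotone: higher threshold never adds positives
  set.seed(31)
  af_r <- matrix(runif(200), 20, 10)
  p_lo <- presence_fixture(af_r, threshold = 0.2)
  p_hi <- presence_fixture(af_r, threshold = 0.4)
  expect_true(all(p_hi$presence <= p_lo$presence))
  # independent positive-count oracle
  expect_equal(colSums(p_lo$presence), colSums(af_r > 0.2))
})

test_that("top-variant selection sorts by pseudobulk with position
           tie-break", {
  m <- data.frame(position = c(30, 10, 20, 40),
                  ref = "A", alt = "G",
                  label = sprintf("mt.%dA>G", c(30, 10, 20, 40)),
                  pseudobulk_het_mean = c(0.1, 0.5, 0.5, 0.05))
  top <- select_top_variants(m, n = 3)
  expect_equal(top$position, c(10, 20, 30))  # ties: lower position first
  expect_equal(nrow(select_top_variants(m, n = 10)), 4L)
  expect_error(select_top_variants(m, n = 0), "positive")
})

test_that("Jaccard distances match the set formula and behave as a
           metric", {
  m <- rbind(c(1, 0), c(1, 0), c(0, 1), c(1, 1))
  d <- jaccard_distance(m)
  expect_equal(d[1, 2], 0)    # {v1} vs {v1}
  expect_equal(d[1, 3], 1)    # {v1} vs {v2}
  expect_equal(d[1, 4], 0.5)  # {v1} vs {v1,v2}
  # metric properties on random binary fixtures
  set.seed(32)
  for (rep in 1:5) {
    mm <- matrix(rbinom(60, 1, 0.4), 10, 6)
    mm[rowSums(mm) == 0, 1] <- 1     # non-empty sets
    dd <- jaccard_distance(mm)
    expect_equal(dd, t(dd))
    expect_true(all(diag(dd) == 0))
    for (i in 1:10) for (j in 1:10) for (k in 1:10) {
      expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
    }
  }
})

test_that("clone clustering separates disjoint single-variant profiles",
{
  # 3 variants, 4 cells per variant, disjoint profiles -> 3 clones
  af <- matrix(0, 12, 3)
  for (v in 1:3) af[(v - 1) * 4 + 1:4, v] <- 0.6
  pres <- presence_fixture(af)
  cl <- cluster_clones(pres)
  expect_equal(cl$k, 3L)
  truth <- rep(1:3, each = 4)
  expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  # identical sets cluster together at distance 0
  expect_equal(length(unique(cl$labels[1:4])), 1L)
  # single retained cell: one clone, no tree
  af1 <- matrix(c(0.9, 0, 0, 0), 4, 1)
  cl1 <- cluster_clones(presence_fixture(af1))
  expect_equal(cl1$k, 1L)
  expect_null(cl1$tree)
  expect_error(cluster_clones(pres, k = 2, cut_height = 0.5),
               "at most one")
})

test_that("lineage bias computes tie-corrected KW with BH adjustment", {
  # identical values across groups: H = 0, p = 1 by convention
  af <- matrix(0.3, 12, 1)
  pres_het <- presence_fixture(af)
  het <- structure(list(cells = sprintf("c%d", 1:12),
                        variants = variant(2, "A", "G", 1000),
                        af = af, cov = matrix(20, 12, 1),
                        alt_fwd = af * 10, alt_rev = af * 10),
                   class = "heteroplasmy_matrix")
  groups <- setNames(rep(c("g1", "g2", "g3"), each = 4),
                     sprintf("c%d", 1:12))
  res <- lineage_bias(het, groups)
  expect_equal(res$table$H, 0)
  expect_equal(res$table$p, 1)
  # strongly biased variant: af 0.5 in one group, 0 in three others
  af2 <- matrix(0, 120, 1)
  af2[1:30, 1] <- 0.5
  het2 <- structure(list(cells = sprintf("c%d", 1:120),
                         variants = variant(2, "A", "G", 1000),
                         af = af2, cov = matrix(20, 120, 1),
                         alt_fwd = af2 * 10, alt_rev = af2 * 10),
                    class = "heteroplasmy_matrix")
  groups2 <- setNames(rep(paste0("g", 1:4), each = 30),
                      sprintf("c%d", 1:120))
  res2 <- lineage_bias(het2, groups2)
  # exact-rank oracle: compare to R's reference implementation
  expect_equal(res2$table$H,
               unname(kruskal.test(af2[, 1], factor(groups2))$statistic),
               tolerance = 1e-12)
  expect_lt(res2$table$p_adj, 1e-10)
  expect_equal(res2$table$`mean_het.g1`, 0.5)
  expect_equal(res2$table$`n_pos.g1`, 30L)
  expect_equal(res2$table$`n_pos.g2`, 0L)
})

test_that("BH adjustment and bias filtering honor inclusive bounds", {
  # manual step-up: (0.01, 0.02, 0.2) -> (0.03, 0.03, 0.2)
  expect_equal(p.adjust(c(0.01, 0.02, 0.2), method = "BH"),
               c(0.03, 0.03, 0.2))
  tab <- data.frame(label = c("v1", "v2", "v3"),
                    p_adj = c(0.05, 0.051, 0.01),
                    n_pos.micro = c(4L, 10L, 3L))
  kept <- filter_biased_variants(list(table = tab), "micro")
  expect_equal(kept$label, "v1")   # p_adj = 0.05 and 4 cells pass
  expect_error(filter_biased_variants(list(table = tab), "astro"),
               "unknown group")
})

test_that("clone membership across groups partitions positive cells", {
  af <- matrix(0, 9, 2)
  af[c(1, 2, 3), 1] <- 0.9
  pres <- presence_fixture(af)
  groups <- setNames(rep(c("X", "Y", "Z"), each = 3), pres$cells)
  by_group <- clone_cells_across_groups(pres, pres$variants$label[1],
                                        groups)
  expect_equal(names(by_group), "X")
  expect_length(by_group$X, 3)
  # variant with zero positives
  expect_length(clone_cells_across_groups(pres, pres$variants$label[2],
                                          groups), 0)
  expect_warning(clone_cells_across_groups(pres, "mt.999A>G", groups),
                 "not in presence")
})
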