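ambient_fixture <- function(n_cells = 3, cov = 100, alt = 6,
                            genome_length = 20) {
  cells <- sprintf("c%d", seq_len(n_cells))
  trip <- rbind(
    data.frame(position = 5, barcode = cells, base = "G",
               fwd = (cov - alt) / 2, rev = (cov - alt) / 2),
    data.frame(position = 5, barcode = cells, base = "A",
               fwd = alt / 2, rev = alt / 2))
  x <- strand_counts_from_triplets(trip, cells, genome_length)
  list(x = x, cells = cells,
       variants = variant(5, "G", "A", genome_length))
}

test_that("empty-droplet selection applies ranking, set difference and
           the low-count bound", {
  rec <- data.frame(barcode = sprintf("b%02d", 1:10),
                    mito_fragments = c(0, 1, rep(10, 8)),
                    peak_region_fragments = 10:1)
  cells <- c("b03", "b04")
  emp <- select_empty_droplets(rec, cells, total_droplets = 8)
  # top 8 by peak fragments are b01..b08; minus cells; minus mito <= 1
  expect_setequal(emp, c("b05", "b06", "b07", "b08"))
  expect_error(select_empty_droplets(rec[1:2, ], character(0)),
               "no background droplets")
})

test_that("ambient profile is the pseudocount-smoothed pooled fraction", {
  fx <- ambient_fixture(n_cells = 4, cov = 100, alt = 0)
  prof0 <- estimate_ambient_profile(fx$x, fx$variants, fx$cells)
  expect_equal(unname(prof0$alpha[1]), 0.5 / 401)   # ~0 in the limit
  fx1 <- ambient_fixture(n_cells = 4, cov = 100, alt = 100)
  prof1 <- estimate_ambient_profile(fx1$x, fx1$variants, fx1$cells)
  expect_equal(unname(prof1$alpha[1]), 400.5 / 401) # ~1 in the limit
  # zero-coverage variant flagged undefined
  v2 <- rbind(fx$variants, variant(9, "C", "T", 20))
  prof2 <- estimate_ambient_profile(fx$x, v2, fx$cells)
  expect_true(is.na(prof2$alpha[2]))
  expect_equal(prof2$uncovered, "mt.9C>T")
})

test_that("per-cell ambient fraction follows the marker formula", {
  # markers with alpha ~ 1, marker coverage 200, observed alt 10
  cells <- c("c1", "c2")
  trip <- rbind(
    data.frame(position = c(3, 7), barcode = "c1", base = "T",
               fwd = c(3, 2), rev = c(3, 2)),
    data.frame(position = c(3, 7), barcode = "c1", base = "A",
               fwd = c(47, 48), rev = c(47, 48)),
    data.frame(position = c(3, 7), barcode = "c2", base = "A",
               fwd = 50, rev = 50))
  x <- strand_counts_from_triplets(trip, cells, 20)
  vars <- variant(c(3, 7), c("A", "A"), c("T", "T"), 20)
  profile <- structure(list(
    variants = vars, alpha = setNames(c(1, 1), vars$label),
    empty_droplets = "e", pseudocount = 1), class = "ambient_profile")
  rho <- estimate_cell_ambient_fraction(x, cells, profile)
  expect_equal(unname(rho$rho["c1"]), 10 / 200)
  expect_equal(unname(rho$rho["c2"]), 0)   # no alt at any marker
  # no markers above the threshold -> error
  profile$alpha[] <- 0.001
  expect_error(estimate_cell_ambient_fraction(x, cells, profile),
               "marker")
})

test_that("count correction follows expected-count subtraction with
           identity limits", {
  fx <- ambient_fixture(n_cells = 3, cov = 100, alt = 6)
  profile <- structure(list(
    variants = fx$variants,
    alpha = setNames(1, fx$variants$label)), class = "ambient_profile")
  # e = 0.05 * 100 * 1 = 5 -> corrected alt 1
  rho <- setNames(rep(0.05, 3), fx$cells)
  res <- correct_counts(fx$x, fx$cells, profile, rho)
  het <- compute_heteroplasmy(res$tensor, fx$variants, fx$cells)
  expect_equal(unname(het$af[, 1] * het$cov[, 1]), rep(1, 3))
  expect_equal(unname(res$removed[, 1]), rep(5, 3))
  # rho = 0 and alpha = 0 are identities
  for (variant_args in list(list(rho = setNames(rep(0, 3), fx$cells),
                                 alpha = 1),
                            list(rho = rho, alpha = 0))) {
    profile$alpha[] <- variant_args$alpha
    r0 <- correct_counts(fx$x, fx$cells, profile, variant_args$rho)
    expect_equal(as.matrix(coverage_matrix(r0$tensor)),
                 as.matrix(coverage_matrix(fx$x)))
    expect_equal(sum(r0$removed), 0)
    for (b in c("A", "C", "G", "T")) {
      expect_equal(as.matrix(base_count_matrix(r0$tensor, b)),
                   as.matrix(base_count_matrix(fx$x, b)))
    }
  }
})

test_that("reassign preserves coverage, drop reduces it by the removal,
           and removal is monotone in rho and alpha", {
  fx <- random_fixture(seed = 21, n_cells = 10, genome_length = 15)
  vars <- variant(c(2, 6, 9), c("A", "C", "G"), c("G", "T", "A"), 15)
  profile <- structure(list(
    variants = vars, alpha = setNames(c(0.5, 0.8, 0.3), vars$label)),
    class = "ambient_profile")
  rho1 <- setNames(runif(10, 0, 0.2), fx$barcodes)
  res_re <- correct_counts(fx$tensor, fx$barcodes, profile, rho1,
                           mode = "reassign")
  expect_equal(as.matrix(coverage_matrix(res_re$tensor)),
               as.matrix(coverage_matrix(fx$tensor)))
  res_dr <- correct_counts(fx$tensor, fx$barcodes, profile, rho1,
                           mode = "drop")
  expect_equal(sum(coverage_matrix(fx$tensor)) -
                 sum(coverage_matrix(res_dr$tensor)),
               sum(res_dr$removed))
  # monotonicity: doubling rho or alpha never decreases removal
  res_hi <- correct_counts(fx$tensor, fx$barcodes, profile,
                           pmin(rho1 * 2, 1))
  expect_true(all(res_hi$removed >= res_re$removed))
  profile_hi <- profile
  profile_hi$alpha <- pmin(profile$alpha * 2, 1)
  res_ahi <- correct_counts(fx$tensor, fx$barcodes, profile_hi, rho1)
  expect_true(all(res_ahi$removed >= res_re$removed))
  # corrected alt counts are non-negative and removal <= original alt
  het_orig <- compute_heteroplasmy(fx$tensor, vars, fx$barcodes)
  expect_true(all(res_re$removed <= het_orig$alt_fwd + het_orig$alt_rev))
})

test_that("the ambient-consistency test zeroes background-compatible
           entries but spares strong signal", {
  # cov 100, alt 6, rho 0.05, alpha 1: e = 5, within the 99% binomial
  # tail of Binomial(100, 0.05) -> zeroed entirely under the test
  fx <- ambient_fixture(n_cells = 2, cov = 100, alt = 6)
  profile <- structure(list(
    variants = fx$variants, alpha = setNames(1, fx$variants$label)),
    class = "ambient_profile")
  rho <- setNames(rep(0.05, 2), fx$cells)
  res <- correct_counts(fx$x, fx$cells, profile, rho, tail_prob = 0.01)
  expect_equal(unname(res$removed[, 1]), rep(6, 2))
  # a strong clone signal (alt 40/100) survives with only e subtracted
  fx2 <- ambient_fixture(n_cells = 2, cov = 100, alt = 40)
  res2 <- correct_counts(fx2$x, fx2$cells, profile, rho, tail_prob = 0.01)
  expect_equal(unname(res2$removed[, 1]), rep(5, 2))
})
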