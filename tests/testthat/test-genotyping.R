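test_that("heteroplasmy equals strand-summed alt over coverage", {
  trip <- data.frame(position = c(5, 5), barcode = "B1",
                     base = c("G", "A"), fwd = c(5, 5), rev = c(5, 5))
  x <- strand_counts_from_triplets(trip, "B1", 10)
  het <- compute_heteroplasmy(x, variant(5, "G", "A", 10), "B1")
  expect_equal(unname(het$af[1, 1]), 0.5)
  expect_equal(unname(het$cov[1, 1]), 20)
  # zero alt with positive coverage -> 0; zero coverage -> 0 and missing
  v2 <- variant(c(5, 7), c("G", "C"), c("T", "A"), 10)
  het2 <- compute_heteroplasmy(x, v2, "B1")
  expect_equal(unname(het2$af[1, ]), c(0, 0))
  expect_equal(unname(het2$cov[1, ]), c(20, 0))

  fx <- random_fixture(seed = 7)
  vars <- variant(c(3, 11, 19), c("A", "C", "G"), c("C", "T", "A"),
                  fx$genome_length)
  het3 <- compute_heteroplasmy(fx$tensor, vars, fx$barcodes)
  oracle <- oracle_heteroplasmy(fx$trip, fx$barcodes, vars)
  expect_equal(unname(het3$af), oracle$af, tolerance = 1e-12)
  expect_equal(unname(het3$cov), oracle$cov)
})

test_that("candidate calling recovers exactly the non-reference alleles",
{
  fx <- random_fixture(seed = 8, n_cells = 6, genome_length = 15)
  reference <- rep("A", 15)
  cand <- call_candidate_variants(fx$tensor, reference)
  # oracle: any position x base with base != A and a read somewhere
  manual <- unique(fx$trip[fx$trip$base != "A" &
                             (fx$trip$fwd + fx$trip$rev) > 0,
                           c("position", "base")])
  expect_equal(nrow(cand), nrow(manual))
  expect_setequal(cand$label,
                  sprintf("mt.%dA>%s", manual$position, manual$base))
  # N positions skipped; empty input -> empty list
  reference_n <- reference; reference_n[manual$position[1]] <- "N"
  cand_n <- call_candidate_variants(fx$tensor, reference_n)
  expect_false(any(cand_n$position == manual$position[1]))
  empty <- strand_base_counts("B1", 15)
  expect_equal(nrow(call_candidate_variants(empty, reference)), 0L)
  expect_error(call_candidate_variants(fx$tensor, rep("A", 14)),
               "length")
})

test_that("variant metrics match hand-computed values", {
  # three cells with proportional strand counts -> concordance 1
  trip <- rbind(
    data.frame(position = 4, barcode = c("c1", "c2", "c3"), base = "T",
               fwd = c(2, 4, 6), rev = c(1, 2, 3)),
    data.frame(position = 4, barcode = c("c1", "c2", "c3"), base = "C",
               fwd = c(7, 4, 1), rev = c(10, 10, 10)))
  x <- strand_counts_from_triplets(trip, c("c1", "c2", "c3"), 10)
  m <- compute_variant_metrics(
    compute_heteroplasmy(x, variant(4, "C", "T", 10), c("c1", "c2", "c3")))
  expect_equal(m$strand_concordance, 1)
  expect_equal(m$n_cells_conf_detected, 3L)

  # af pattern {0, 0, 1, 1}: population variance 0.25, VMR 0.5
  trip2 <- rbind(
    data.frame(position = 2, barcode = c("c1", "c2"), base = "G",
               fwd = 5, rev = 5),
    data.frame(position = 2, barcode = c("c3", "c4"), base = "A",
               fwd = 5, rev = 5))
  x2 <- strand_counts_from_triplets(trip2, paste0("c", 1:4), 10)
  m2 <- compute_variant_metrics(
    compute_heteroplasmy(x2, variant(2, "G", "A", 10), paste0("c", 1:4)))
  expect_equal(m2$pseudobulk_het_mean, 0.5)
  expect_equal(m2$log10_vmr, log10(0.25 / 0.5), tolerance = 1e-12)

  # all-zero alt: no confident cells, undefined VMR (NA, not 0)
  m3 <- compute_variant_metrics(
    compute_heteroplasmy(x2, variant(2, "G", "C", 10), paste0("c", 1:4)))
  expect_equal(m3$n_cells_conf_detected, 0L)
  expect_true(is.na(m3$log10_vmr))
  expect_true(is.na(m3$strand_concordance))
})

test_that("high-confidence filter honors boundary strictness", {
  base_row <- data.frame(position = 1, ref = "A", alt = "G",
                         label = "mt.1A>G")
  mk <- function(n, sc, vmr, cov) {
    cbind(base_row, n_cells_conf_detected = n, strand_concordance = sc,
          log10_vmr = vmr, mean_coverage = cov)
  }
  expect_equal(nrow(filter_high_confidence(mk(5, 0.66, -1.9, 5.0))), 1L)
  expect_equal(nrow(filter_high_confidence(mk(5, 0.65, -1.9, 5.0))), 0L)
  expect_equal(nrow(filter_high_confidence(mk(5, 0.9, -2.0, 5.0))), 0L)
  expect_equal(nrow(filter_high_confidence(mk(4, 0.9, 0, 50))), 0L)
  expect_equal(nrow(filter_high_confidence(mk(5, 0.9, 0, 4.99))), 0L)
  expect_equal(nrow(filter_high_confidence(mk(5, NA, 0, 50))), 0L)
})

test_that("pseudobulk modes agree under equal coverage and diverge
           otherwise", {
  # two cells af {0, 0.5} at equal coverage: both modes 0.25
  trip <- rbind(
    data.frame(position = 3, barcode = "c1", base = "C", fwd = 5, rev = 5),
    data.frame(position = 3, barcode = "c2", base = "C", fwd = 3, rev = 2),
    data.frame(position = 3, barcode = "c2", base = "T", fwd = 3, rev = 2))
  x <- strand_counts_from_triplets(trip, c("c1", "c2"), 10)
  het <- compute_heteroplasmy(x, variant(3, "C", "T", 10), c("c1", "c2"))
  g <- c(c1 = "g", c2 = "g")
  expect_equal(unname(pseudobulk_heteroplasmy(het, g, "mean")[1, 1]), 0.25)
  expect_equal(unname(pseudobulk_heteroplasmy(het, g, "aggregate")[1, 1]),
               0.25)

  # unequal coverage: af {0 @ cov 100, 0.5 @ cov 10}
  trip2 <- rbind(
    data.frame(position = 3, barcode = "d1", base = "C", fwd = 50,
               rev = 50),
    data.frame(position = 3, barcode = "d2", base = "C", fwd = 3, rev = 2),
    data.frame(position = 3, barcode = "d2", base = "T", fwd = 3, rev = 2))
  x2 <- strand_counts_from_triplets(trip2, c("d1", "d2"), 10)
  het2 <- compute_heteroplasmy(x2, variant(3, "C", "T", 10), c("d1", "d2"))
  g2 <- c(d1 = "g", d2 = "g")
  expect_equal(unname(pseudobulk_heteroplasmy(het2, g2, "mean")[1, 1]),
               0.25)
  expect_equal(unname(pseudobulk_heteroplasmy(het2, g2,
                                              "aggregate")[1, 1]),
               5 / 110, tolerance = 1e-12)
  # single cell: both modes return its af
  het1 <- compute_heteroplasmy(x2, variant(3, "C", "T", 10), "d2")
  g1 <- c(d2 = "g")
  expect_equal(unname(pseudobulk_heteroplasmy(het1, g1, "mean")[1, 1]),
               unname(pseudobulk_heteroplasmy(het1, g1,
                                              "aggregate")[1, 1]))
})

test_that("substitution spectrum tallies and sums to one", {
  v <- parse_variant_label(c("mt.100C>T", "mt.200C>T"))
  sp <- substitution_spectrum(v)
  expect_equal(unname(sp$proportions12["C>T"]), 1.0)
  expect_equal(sum(sp$counts12), 2)
  # empty input: all-zero counts
  sp0 <- substitution_spectrum(v[0, ])
  expect_true(all(sp0$counts12 == 0) && all(sp0$proportions12 == 0))
  # random 50-variant fixture vs independent tally; G>A collapses to C>T
  set.seed(12)
  refalt <- t(replicate(50, sample(c("A", "C", "G", "T"), 2)))
  vv <- variant(sample.int(16000, 50), refalt[, 1], refalt[, 2])
  sp50 <- substitution_spectrum(vv)
  tally <- table(paste0(vv$ref, ">", vv$alt))
  for (k in names(tally)) {
    expect_equal(unname(sp50$counts12[k]), unname(tally[k]))
  }
  expect_equal(sum(sp50$proportions12), 1)
  expect_equal(sum(sp50$proportions6), 1)
  expect_equal(unname(sp50$counts6["C>T"]),
               unname(sp50$counts12["C>T"] + sp50$counts12["G>A"]))
})

test_that("variant-set overlaps partition the union", {
  a <- c("v1", "v2", "v3"); b <- c("v2", "v3", "v4")
  ov <- variant_set_overlap(list(A = a, B = b))
  expect_equal(unname(ov$combination_counts["A+B"]), 2L)
  expect_equal(sum(ov$combination_counts), length(union(a, b)))
  # identical sets: everything in the joint cell
  ov2 <- variant_set_overlap(list(A = a, B = a))
  expect_equal(names(ov2$combination_counts), "A+B")
  # disjoint sets share nothing
  ov3 <- variant_set_overlap(list(A = "v1", B = "v9"))
  expect_false("A+B" %in% names(ov3$combination_counts))
  # 4-group random fixture: counts partition the union
  set.seed(13)
  sets <- lapply(1:4, function(i) sample(paste0("m", 1:30), 12))
  names(sets) <- paste0("G", 1:4)
  ov4 <- variant_set_overlap(sets)
  expect_equal(sum(ov4$combination_counts),
               length(unique(unlist(sets))))
})
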