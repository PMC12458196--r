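# Independent brute-force oracles. These deliberately avoid the package
# internals: they operate on a plain triplet data.frame
# (position, barcode, base, fwd, rev) with explicit loops and base-R
# arithmetic only, so they can serve as the reference implementation
# for the oracle-equivalence tests.

# random count fixture: returns the triplet table, barcode list and the
# package tensor built from it
random_fixture <- function(seed, n_cells = 20, genome_length = 30,
                           density = 0.4, max_count = 12) {
  set.seed(seed)
  barcodes <- sprintf("BC%03d", seq_len(n_cells))
  rows <- list()
  for (b in seq_len(n_cells)) {
    for (p in seq_len(genome_length)) {
      if (runif(1) > density) next
      for (base in c("A", "C", "G", "T")) {
        if (runif(1) < 0.5) next
        fwd <- sample(0:max_count, 1)
        rev <- sample(0:max_count, 1)
        if (fwd + rev == 0) next
        rows[[length(rows) + 1L]] <-
          data.frame(position = p, barcode = barcodes[b], base = base,
                     fwd = fwd, rev = rev, stringsAsFactors = FALSE)
      }
    }
  }
  trip <- do.call(rbind, rows)
  tensor <- strand_counts_from_triplets(trip, barcodes, genome_length)
  list(trip = trip, barcodes = barcodes, genome_length = genome_length,
       tensor = tensor)
}

oracle_coverage <- function(trip, barcode, position) {
  sel <- trip$barcode == barcode & trip$position == position
  sum(trip$fwd[sel]) + sum(trip$rev[sel])
}

oracle_alt_counts <- function(trip, barcode, position, alt) {
  sel <- trip$barcode == barcode & trip$position == position &
    trip$base == alt
  c(fwd = sum(trip$fwd[sel]), rev = sum(trip$rev[sel]))
}

# per-cell x variant af/cov by explicit summation
oracle_heteroplasmy <- function(trip, cells, variants) {
  af <- cov <- matrix(0, length(cells), nrow(variants))
  for (i in seq_along(cells)) {
    for (v in seq_len(nrow(variants))) {
      cv <- oracle_coverage(trip, cells[i], variants$position[v])
      a <- sum(oracle_alt_counts(trip, cells[i], variants$position[v],
                                 variants$alt[v]))
      cov[i, v] <- cv
      af[i, v] <- if (cv > 0) a / cv else 0
    }
  }
  list(af = af, cov = cov)
}

oracle_variant_metrics <- function(trip, cells, variants,
                                   min_per_strand = 1, min_total = 2,
                                   positivity = 0.20) {
  out <- data.frame(label = variants$label)
  out$n_cells_conf_detected <- NA_integer_
  out$strand_concordance <- NA_real_
  out$mean_coverage <- NA_real_
  out$log10_vmr <- NA_real_
  out$pseudobulk_het_mean <- NA_real_
  out$pseudobulk_het_aggregate <- NA_real_
  out$n_cells_over_threshold <- NA_integer_
  for (v in seq_len(nrow(variants))) {
    fwd <- rev <- cov <- numeric(length(cells))
    for (i in seq_along(cells)) {
      a <- oracle_alt_counts(trip, cells[i], variants$position[v],
                             variants$alt[v])
      fwd[i] <- a["fwd"]; rev[i] <- a["rev"]
      cov[i] <- oracle_coverage(trip, cells[i], variants$position[v])
    }
    alt <- fwd + rev
    af <- ifelse(cov > 0, alt / pmax(cov, 1), 0)
    out$n_cells_conf_detected[v] <-
      sum(fwd >= min_per_strand & rev >= min_per_strand & alt >= min_total)
    covered <- cov > 0
    if (sum(covered & alt > 0) >= 2 &&
        stats::var(fwd[covered]) > 0 && stats::var(rev[covered]) > 0) {
      out$strand_concordance[v] <- stats::cor(fwd[covered], rev[covered])
    }
    out$mean_coverage[v] <- mean(cov)
    if (any(covered)) {
      m <- mean(af[covered])
      if (m > 0) {
        vpop <- mean((af[covered] - m)^2)
        out$log10_vmr[v] <- log10(vpop / m)
      }
      out$pseudobulk_het_mean[v] <- m
      out$pseudobulk_het_aggregate[v] <- sum(alt[covered]) / sum(cov[covered])
    }
    out$n_cells_over_threshold[v] <- sum(af > positivity)
  }
  out
}

oracle_high_confidence <- function(metrics) {
  keep <- logical(nrow(metrics))
  for (v in seq_len(nrow(metrics))) {
    keep[v] <- !is.na(metrics$strand_concordance[v]) &&
      !is.na(metrics$log10_vmr[v]) &&
      metrics$n_cells_conf_detected[v] >= 5 &&
      metrics$strand_concordance[v] > 0.65 &&
      metrics$log10_vmr[v] > -2 &&
      metrics$mean_coverage[v] >= 5
  }
  keep
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# tiny deterministic tensor: one barcode, explicit counts
tiny_tensor <- function(entries, barcodes, genome_length = 50) {
  strand_counts_from_triplets(entries, barcodes, genome_length)
}
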