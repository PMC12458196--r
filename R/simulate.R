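# Synthetic droplet-experiment generator. Emulates a multi-donor pooled
# mtscATAC-seq style run: donors carry distinct homoplasmic germline
# haplotypes, within-donor clones carry somatic heteroplasmic variants,
# all droplets share an ambient mtDNA pool, empty droplets sample the
# pool alone, reads are strand-split and carry substitution errors, and
# per-barcode QC covariates accompany the counts. Ground truth labels
# are emitted for parameter-recovery tests.

#' Simulation configuration
#'
#' @param seed RNG seed governing the whole experiment.
#' @param genome_length mitochondrial genome length (default human,
#'   16,569; presets use a scaled-down genome for tractability).
#' @param n_donors number of donors in the pool.
#' @param cells_per_donor cells per donor.
#' @param germline_per_donor homoplasmic donor-distinct germline
#'   variants per donor.
#' @param shared_germline homoplasmic variants shared by all donors.
#' @param clones_per_donor somatic clones per donor; each clone carries
#'   one private somatic variant.
#' @param clone_cells cells per clone (non-clone cells carry only the
#'   donor haplotype).
#' @param clone_het true heteroplasmy of each clone's somatic variant,
#'   recycled across clones.
#' @param cell_types cell-type labels sampled uniformly per cell.
#' @param depth_mean,depth_size negative-binomial per-position coverage
#'   model for cells.
#' @param empty_depth_mean,empty_depth_size coverage model for empty
#'   droplets.
#' @param n_empty number of empty droplets.
#' @param strand_split probability a read is assigned to the forward
#'   strand.
#' @param seq_error_rate per-read substitution probability (symmetric,
#'   uniform over the three other bases).
#' @param rho per-cell ambient fraction: a scalar, a vector recycled
#'   over cells, or `c(shape1, shape2)` via `rho_beta` for
#'   Beta-distributed fractions.
#' @param rho_beta optional `c(shape1, shape2)`; overrides `rho`.
#' @param doublet_fraction fraction of emitted cell barcodes that are
#'   cross-donor doublets (two cells merged into one droplet).
#' @param artifact_variants inject one artifactual variant at a
#'   blocklist position (only if it fits in the genome).
#' @param qc_fail_fraction fraction of cells given failing TSS
#'   enrichment covariates.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 16569L, n_donors = 2L,
                       cells_per_donor = 500L, germline_per_donor = 10L,
                       shared_germline = 5L, clones_per_donor = 3L,
                       clone_cells = 50L, clone_het = c(0.3, 0.6, 0.9),
                       cell_types = c("Oligo", "Astro", "Micro", "Neuron"),
                       depth_mean = 20, depth_size = 10,
                       empty_depth_mean = 2, empty_depth_size = 0.5,
                       n_empty = 2000L, strand_split = 0.5,
                       seq_error_rate = 5e-4, rho = 0.05,
                       rho_beta = NULL, doublet_fraction = 0,
                       artifact_variants = FALSE,
                       qc_fail_fraction = 0.05) {
  cfg <- as.list(environment())
  n_var <- shared_germline + n_donors * germline_per_donor +
    n_donors * clones_per_donor + as.integer(artifact_variants)
  assert_that(n_var <= genome_length,
              "more variants (%d) than genome positions (%d)",
              n_var, genome_length)
  assert_that(all(clone_het > 0 & clone_het < 1),
              "clone heteroplasmy must lie in (0, 1)")
  assert_that(clones_per_donor * clone_cells <= cells_per_donor,
              "clones exceed cells_per_donor")
  structure(cfg, class = "sim_config")
}

#' Two-donor mixing preset
#'
#' A scaled-down two-donor mixing experiment: 2 donors x 1,000 cells,
#' 20 discriminating germline variants per donor, 10 shared, 3 clones
#' per donor at heteroplasmy 0.3 / 0.6 / 0.9 (50 cells each), ambient
#' fraction 0.05, 5,000 empty droplets, per-position depth mean 20.
#' The genome is scaled to 1,000 positions so the full tensor stays
#' desk-sized; all per-position statistics are unaffected.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
two_donor_svz_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, genome_length = 1000L, n_donors = 2L,
               cells_per_donor = 1000L, germline_per_donor = 20L,
               shared_germline = 10L, clones_per_donor = 3L,
               clone_cells = 50L, clone_het = c(0.3, 0.6, 0.9),
               depth_mean = 20, n_empty = 5000L, rho = 0.05)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

#' Simulate a droplet experiment
#'
#' Generative model: each cell carries its donor's germline haplotype
#' (heteroplasmy 1) plus its clone's somatic variant at the configured
#' heteroplasmy; the ambient pool allele fraction of each variant is the
#' coverage-weighted mean of all cells' true allele fractions; per cell
#' and position coverage is negative-binomial and alternate reads are
#' `Binomial(coverage, (1 - rho) * own_af + rho * ambient_af)`;
#' substitution errors re-assign each read to a random other base with
#' probability `seq_error_rate`; reads are strand-split binomially;
#' empty droplets draw purely from the ambient pool at low depth;
#' QC covariates are drawn so the configured fraction of cells fails the
#' TSS filter. Fully reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a `strand_base_counts` over cells then
#'   empties), `records` (barcode QC data.frame) and `truth`
#'   (per-barcode labels, variant table with true ambient fractions,
#'   reference sequence).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  L <- cfg$genome_length

  reference <- sample(BASES, L, replace = TRUE)
  n_var <- cfg$shared_germline + cfg$n_donors * cfg$germline_per_donor +
    cfg$n_donors * cfg$clones_per_donor
  positions <- sort(sample.int(L, n_var))
  alt_of <- function(ref) vapply(ref, function(r) {
    sample(setdiff(BASES, r), 1)
  }, "")
  vtab <- data.frame(position = positions, ref = reference[positions],
                     alt = alt_of(reference[positions]),
                     stringsAsFactors = FALSE)
  classes <- c(rep("shared_germline", cfg$shared_germline),
               rep("germline", cfg$n_donors * cfg$germline_per_donor),
               rep("somatic", cfg$n_donors * cfg$clones_per_donor))
  vtab <- vtab[sample.int(nrow(vtab)), ]   # decouple class from position
  vtab$class <- classes
  vtab$donor <- NA_integer_
  vtab$clone <- NA_integer_
  vtab$het <- 1
  g_rows <- which(vtab$class == "germline")
  vtab$donor[g_rows] <- rep(seq_len(cfg$n_donors),
                            each = cfg$germline_per_donor)
  s_rows <- which(vtab$class == "somatic")
  vtab$donor[s_rows] <- rep(seq_len(cfg$n_donors),
                            each = cfg$clones_per_donor)
  vtab$clone[s_rows] <- rep(seq_len(cfg$clones_per_donor), cfg$n_donors)
  vtab$het[s_rows] <- rep_len(cfg$clone_het, length(s_rows))
  if (cfg$artifact_variants) {
    art <- artifact_blocklist(genome_length = max(L, 16569))
    art <- art[art$position <= L & !(art$position %in% vtab$position), ]
    if (nrow(art) > 0) {
      a <- art[1, ]
      reference[a$position] <- a$ref
      vtab <- rbind(vtab, data.frame(position = a$position, ref = a$ref,
                                     alt = a$alt, class = "artifact",
                                     donor = NA, clone = NA, het = 0.3))
    }
  }
  vtab$label <- sprintf("mt.%d%s>%s", vtab$position, vtab$ref, vtab$alt)
  nv <- nrow(vtab)

  n_cells <- cfg$n_donors * cfg$cells_per_donor
  donor <- rep(seq_len(cfg$n_donors), each = cfg$cells_per_donor)
  clone <- rep(NA_integer_, n_cells)
  for (d in seq_len(cfg$n_donors)) {
    off <- (d - 1L) * cfg$cells_per_donor
    for (cl in seq_len(cfg$clones_per_donor)) {
      clone[off + (cl - 1L) * cfg$clone_cells + seq_len(cfg$clone_cells)] <-
        cl
    }
  }
  cell_type <- sample(cfg$cell_types, n_cells, replace = TRUE)
  rho <- if (!is.null(cfg$rho_beta)) {
    stats::rbeta(n_cells, cfg$rho_beta[1], cfg$rho_beta[2])
  } else rep_len(cfg$rho, n_cells)

  # true allele-fraction matrix, variants x cells
  af_true <- matrix(0, nv, n_cells)
  for (v in seq_len(nv)) {
    af_true[v, ] <- switch(vtab$class[v],
      shared_germline = 1,
      germline = as.numeric(donor == vtab$donor[v]),
      somatic = vtab$het[v] * (donor == vtab$donor[v] &
                                 !is.na(clone) & clone == vtab$clone[v]),
      artifact = vtab$het[v])
  }
  # ambient pool: coverage-weighted mean of cells' true allele fractions
  # (expected depth is identical across cells, so plain mean)
  alpha <- rowMeans(af_true)
  vtab$ambient_af <- alpha

  sim_block <- function(n, mu, size, p_alt_mat) {
    # p_alt_mat: nv x n per-droplet alt probabilities at variant rows
    cov <- matrix(rnbinom(L * n, mu = mu, size = size), L, n)
    vcov <- cov[vtab$position, , drop = FALSE]
    alt <- matrix(rbinom(nv * n, vcov, p_alt_mat), nv, n)
    refv <- vcov - alt
    covnv <- cov
    covnv[vtab$position, ] <- 0          # non-variant portion
    nzr <- which(covnv > 0, arr.ind = TRUE)
    dt <- data.table::data.table(
      position = c(nzr[, 1], rep(vtab$position, n), rep(vtab$position, n)),
      cell = c(nzr[, 2], rep(seq_len(n), each = nv),
               rep(seq_len(n), each = nv)),
      base = c(reference[nzr[, 1]], rep(vtab$ref, n), rep(vtab$alt, n)),
      count = c(covnv[nzr], as.vector(refv), as.vector(alt)))
    dt <- dt[dt$count > 0, ]
    # symmetric per-read substitution errors
    if (cfg$seq_error_rate > 0 && nrow(dt) > 0) {
      nerr <- rbinom(nrow(dt), dt$count, cfg$seq_error_rate)
      hit <- which(nerr > 0)
      if (length(hit) > 0) {
        e1 <- rbinom(length(hit), nerr[hit], 1 / 3)
        e2 <- rbinom(length(hit), nerr[hit] - e1, 1 / 2)
        e3 <- nerr[hit] - e1 - e2
        others <- t(vapply(dt$base[hit], function(b) setdiff(BASES, b),
                           character(3)))
        err_dt <- data.table::data.table(
          position = rep(dt$position[hit], 3),
          cell = rep(dt$cell[hit], 3),
          base = c(others[, 1], others[, 2], others[, 3]),
          count = c(e1, e2, e3))
        dt$count[hit] <- dt$count[hit] - nerr[hit]
        dt <- rbind(dt, err_dt[err_dt$count > 0, ])
      }
    }
    dt <- dt[, list(count = sum(count)),
             by = c("position", "cell", "base")]
    dt <- dt[dt$count > 0, ]
    dt$fwd <- rbinom(nrow(dt), dt$count, cfg$strand_split)
    dt$rev <- dt$count - dt$fwd
    dt
  }

  p_cells <- t(t(af_true) * (1 - rho)) + outer(alpha, rho)
  cells_dt <- sim_block(n_cells, cfg$depth_mean, cfg$depth_size, p_cells)

  # cross-donor doublets: merge pairs of cells into single droplets
  n_doublet <- floor(cfg$doublet_fraction * n_cells)
  merge_map <- seq_len(n_cells)
  is_doublet <- rep(FALSE, n_cells)
  dropped <- integer(0)
  if (n_doublet > 0 && cfg$n_donors >= 2) {
    free_a <- which(donor == 1L)
    free_b <- which(donor == 2L)
    a <- free_a[seq_len(n_doublet)]
    b <- free_b[seq_len(n_doublet)]
    merge_map[b] <- a
    is_doublet[a] <- TRUE
    dropped <- b
  }
  cells_dt$cell <- merge_map[cells_dt$cell]
  cells_dt <- cells_dt[, list(fwd = sum(fwd), rev = sum(rev),
                              count = sum(count)),
                       by = c("position", "cell", "base")]
  kept_cells <- setdiff(seq_len(n_cells), dropped)

  p_empty <- matrix(alpha, nv, cfg$n_empty)
  empty_dt <- sim_block(cfg$n_empty, cfg$empty_depth_mean,
                        cfg$empty_depth_size, p_empty)

  cell_barcodes <- sprintf("CELL%05d-1", kept_cells)
  names(cell_barcodes) <- as.character(kept_cells)
  empty_barcodes <- sprintf("EMPTY%05d-1", seq_len(cfg$n_empty))
  barcodes <- c(cell_barcodes, empty_barcodes)

  cells_dt$barcode_index <- match(as.character(cells_dt$cell),
                                  names(cell_barcodes))
  empty_dt$barcode_index <- length(cell_barcodes) + empty_dt$cell
  trip <- rbind(cells_dt[, c("position", "barcode_index", "base",
                             "fwd", "rev")],
                empty_dt[, c("position", "barcode_index", "base",
                             "fwd", "rev")])
  counts <- strand_counts_from_triplets(
    data.frame(position = trip$position, barcode = trip$barcode_index,
               base = trip$base, fwd = trip$fwd, rev = trip$rev),
    unname(barcodes), L)

  # QC covariates
  nk <- length(kept_cells); ne <- cfg$n_empty
  mito <- setNames(Matrix::colSums(coverage_matrix(counts)),
                   counts$barcodes)
  tss_cell <- pmax(rnorm(nk, 6, 1.5), 0.1)
  fail <- runif(nk) < cfg$qc_fail_fraction
  tss_cell[fail] <- runif(sum(fail), 0, 1.4)
  records <- data.frame(
    barcode = counts$barcodes,
    mito_fragments = as.numeric(mito),
    peak_region_fragments = c(rnbinom(nk, mu = 8000, size = 5) + 1001,
                              rnbinom(ne, mu = 50, size = 1)),
    tss_enrichment = c(tss_cell, runif(ne, 0, 1.2)),
    nucleosome_signal = c(runif(nk, 0.3, 1.5), runif(ne, 0.5, 3)),
    n_count_peaks = c(rnbinom(nk, mu = 5000, size = 5) + 300,
                      rnbinom(ne, mu = 20, size = 1)),
    frip = c(runif(nk, 0.3, 0.7), runif(ne, 0, 0.3)),
    is_cell = c(rep(TRUE, nk), rep(FALSE, ne)),
    stringsAsFactors = FALSE)

  truth_barcodes <- data.frame(
    barcode = counts$barcodes,
    is_cell = c(rep(TRUE, nk), rep(FALSE, ne)),
    donor = c(ifelse(is_doublet[kept_cells], NA, donor[kept_cells]),
              rep(NA, ne)),
    clone = c(ifelse(is_doublet[kept_cells], NA, clone[kept_cells]),
              rep(NA, ne)),
    cell_type = c(cell_type[kept_cells], rep(NA, ne)),
    rho = c(rho[kept_cells], rep(NA, ne)),
    is_doublet = c(is_doublet[kept_cells], rep(FALSE, ne)),
    stringsAsFactors = FALSE)

  list(counts = counts, records = records,
       truth = list(barcodes = truth_barcodes, variants = vtab,
                    reference = reference,
                    af_true = af_true, cell_index = kept_cells),
       config = cfg)
}

#' Simulate the two-donor mixing preset
#'
#' @param preset preset name (currently only `"two_donor_svz"`).
#' @param seed RNG seed.
#' @param ... configuration overrides.
#' @return a [simulate_experiment()] result.
#' @export
simulate_mixing <- function(preset = "two_donor_svz", seed = 1L, ...) {
  preset <- match.arg(preset)
  simulate_experiment(two_donor_svz_config(seed = seed, ...))
}

#' Write a simulated experiment to disk
#'
#' Emits the mgatk-dialect tables, a named-dialect barcode summary and
#' truth TSVs.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_strand_counts(sim$counts, file.path(dir, "counts"))
  write_barcode_summary(sim$records, file.path(dir, "singlecell.csv"))
  data.table::fwrite(sim$truth$barcodes,
                     file.path(dir, "truth_barcodes.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$variants,
                     file.path(dir, "truth_variants.tsv"), sep = "\t")
  writeLines(sim$truth$reference, file.path(dir, "reference.txt"))
  invisible(dir)
}
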