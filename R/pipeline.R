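# End-to-end pipeline: QC -> genotyping -> background removal -> donor
# demultiplexing -> clone clustering -> lineage bias, with a JSON run
# manifest recording per-stage parameters, counts and output digests.

default_pipeline_config <- function() {
  list(seed = 1L,
       genome_length = 16569L,
       input = list(preset = "two_donor_svz"),
       qc = list(profile = "default"),
       demux = list(k_donors = 2L, fixed_af = 0.8, absent_af = 0.2),
       background = list(total_droplets = 20000L, low_count_threshold = 1L,
                         mode = "reassign", tail_prob = 0.01),
       clones = list(top_n = 50L, threshold = 0.20),
       bias = list(positivity_threshold = 0.20))
}

load_pipeline_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- default_pipeline_config()
  for (nm in names(config)) {
    # `input` is replaced wholesale: a user-supplied file input must not
    # inherit the default preset
    if (nm != "input" && is.list(cfg[[nm]]) && is.list(config[[nm]])) {
      cfg[[nm]][names(config[[nm]])] <- config[[nm]]
    } else cfg[[nm]] <- config[[nm]]
  }
  cfg
}

digest_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order on either a simulated preset or on
#' on-disk tables, writing stage outputs and a JSON manifest under
#' `out_dir`. The manifest records, per stage, the parameters used,
#' cell/variant counts in and out, and MD5 digests of the files
#' written, so a re-run with the same configuration and seed yields
#' identical digests.
#'
#' @param config a configuration list or path to a JSON file; unset
#'   fields fall back to defaults. `input` is either
#'   `list(preset = "two_donor_svz")` or
#'   `list(counts_dir =, singlecell =, celltypes = )`.
#' @param out_dir output directory.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list())
  note <- function(stage, params, counts, files = character(0)) {
    manifest$stages[[stage]] <<- list(
      params = params, counts = counts, digests = digest_files(files))
  }

  # --- input -------------------------------------------------------------
  groups <- NULL
  if (!is.null(cfg$input$preset)) {
    sim <- simulate_mixing(cfg$input$preset, seed = cfg$seed)
    x <- sim$counts
    records <- sim$records
    gl <- sim$config$genome_length
    reference <- sim$truth$reference
    tb <- sim$truth$barcodes
    groups <- setNames(tb$cell_type, tb$barcode)
    note("input", list(preset = cfg$input$preset, seed = cfg$seed),
         list(barcodes = length(x$barcodes)))
  } else {
    gl <- cfg$genome_length
    x <- read_strand_counts(cfg$input$counts_dir, genome_length = gl)
    records <- read_barcode_summary(cfg$input$singlecell,
                                    dialect = cfg$input$dialect %||%
                                      "named")
    reference <- NULL
    if (!is.null(cfg$input$celltypes)) {
      ct <- data.table::fread(cfg$input$celltypes, header = TRUE)
      groups <- setNames(as.character(ct[[2]]), as.character(ct[[1]]))
    }
    note("input", cfg$input, list(barcodes = length(x$barcodes)))
  }

  # --- qc ----------------------------------------------------------------
  depths <- per_cell_mtdna_depth(x)
  qc <- filter_cells(records, depths,
                     qc_profile(cfg$qc$profile %||% "default"))
  kept_file <- file.path(out_dir, "kept_barcodes.tsv")
  writeLines(qc$kept, kept_file)
  reasons_file <- file.path(out_dir, "qc_failures.tsv")
  data.table::fwrite(qc$reasons, reasons_file, sep = "\t")
  note("qc", list(profile = cfg$qc$profile),
       list(cells_in = nrow(records), cells_out = length(qc$kept)),
       c(kept_file, reasons_file))
  assert_that(length(qc$kept) > 0, "no cells passed QC")

  # --- genotyping --------------------------------------------------------
  if (is.null(reference)) reference <- consensus_reference(x, qc$kept)
  cand <- call_candidate_variants(x, reference, cells = qc$kept)
  het_all <- compute_heteroplasmy(x, cand, cells = qc$kept)
  metrics <- compute_variant_metrics(het_all)
  hc <- filter_high_confidence(metrics)
  hc <- drop_artifact_variants(hc)
  metrics_file <- file.path(out_dir, "variant_metrics.tsv")
  data.table::fwrite(metrics, metrics_file, sep = "\t")
  note("genotyping", list(), list(cells_in = length(qc$kept),
                                  variants_called = nrow(cand),
                                  variants_high_confidence = nrow(hc)),
       metrics_file)

  # --- background removal ------------------------------------------------
  bg <- remove_background(
    x, records, qc$kept,
    variants = hc[, c("position", "ref", "alt", "label")],
    total_droplets = cfg$background$total_droplets,
    low_count_threshold = cfg$background$low_count_threshold,
    mode = cfg$background$mode, tail_prob = cfg$background$tail_prob)
  corrected_dir <- file.path(out_dir, "corrected_counts")
  write_strand_counts(bg$tensor, corrected_dir)
  note("background", cfg$background,
       list(cells_in = length(qc$kept), n_empty = bg$report$n_empty,
            variants = bg$report$n_variants,
            total_removed = bg$report$total_removed),
       file.path(corrected_dir,
                 c(paste0(BASES, ".txt"), "coverage.txt", "barcodes.txt")))

  # --- demultiplexing ----------------------------------------------------
  het_hc <- compute_heteroplasmy(bg$tensor,
                                 hc[, c("position", "ref", "alt", "label")],
                                 cells = qc$kept)
  homo <- identify_homoplasmic_variants(
    het_hc, fixed_af = cfg$demux$fixed_af, absent_af = cfg$demux$absent_af)
  demux_result <- NULL
  if (cfg$demux$k_donors >= 2 &&
      nrow(homo$discriminating_candidate) > 0) {
    profiles <- infer_donor_profiles(het_hc, homo$discriminating_candidate,
                                     k_donors = cfg$demux$k_donors)
    assignments <- assign_cells(het_hc, profiles)
    contam <- estimate_contamination(het_hc, assignments, profiles)
    assignments$contamination <- contam$per_cell[assignments$barcode]
    assign_file <- file.path(out_dir, "assignments.tsv")
    data.table::fwrite(assignments, assign_file, sep = "\t")
    demux_result <- list(assignments = assignments, profiles = profiles,
                         contamination = contam)
    note("demux", cfg$demux,
         list(cells_in = length(qc$kept),
              discriminating = nrow(profiles$profiles[[1]]$
                                      discriminating_variants),
              contamination_percent = contam$dataset_percent),
         assign_file)
  } else {
    note("demux", cfg$demux, list(cells_in = length(qc$kept),
                                  discriminating = 0L))
  }

  # --- clones ------------------------------------------------------------
  somatic <- hc[hc$pseudobulk_het_mean < cfg$demux$fixed_af, , drop = FALSE]
  top <- select_top_variants(somatic, n = cfg$clones$top_n)
  het_top <- compute_heteroplasmy(bg$tensor,
                                  top[, c("position", "ref", "alt",
                                          "label")],
                                  cells = qc$kept)
  presence <- binarize_presence(het_top,
                                threshold = cfg$clones$threshold)
  clones <- cluster_clones(presence)
  clones_file <- file.path(out_dir, "clones.tsv")
  data.table::fwrite(data.frame(barcode = names(clones$labels),
                                clone = unname(clones$labels)),
                     clones_file, sep = "\t")
  note("clones", cfg$clones,
       list(cells_in = length(qc$kept),
            cells_retained = length(presence$retained_cells),
            n_clones = clones$k),
       clones_file)

  # --- lineage bias ------------------------------------------------------
  if (!is.null(groups) && !all(is.na(groups[qc$kept]))) {
    bias <- lineage_bias(het_top, groups,
                         positivity_threshold =
                           cfg$bias$positivity_threshold)
    bias_file <- file.path(out_dir, "bias.tsv")
    data.table::fwrite(bias$table, bias_file, sep = "\t")
    note("bias", cfg$bias,
         list(variants_tested = nrow(bias$table),
              variants_skipped = length(bias$skipped)),
         bias_file)
  } else {
    note("bias", cfg$bias, list(variants_tested = 0L, skipped = "no groups"))
  }

  manifest$config <- cfg
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render a plain-text run report
#'
#' Summarises a pipeline run from its manifest and stage outputs:
#' per-stage counts, contamination, clone sizes and the head of the
#' lineage-bias table. Sections whose stage output is missing are
#' marked absent.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @param file report path (default `report.txt` in `out_dir`).
#' @return the report lines, invisibly.
#' @export
render_report <- function(out_dir, file = file.path(out_dir,
                                                    "report.txt")) {
  mf <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                            simplifyVector = TRUE)
  lines <- c("cryoclone run report", strrep("=", 21), "")
  for (nm in names(mf$stages)) {
    st <- mf$stages[[nm]]
    lines <- c(lines, sprintf("[%s]", nm),
               vapply(names(st$counts), function(k) {
                 sprintf("  %s: %s", k,
                         paste(format(st$counts[[k]]), collapse = " "))
               }, ""), "")
  }
  clone_path <- file.path(out_dir, "clones.tsv")
  if (file.exists(clone_path)) {
    cl <- data.table::fread(clone_path)
    if (nrow(cl) == 0) {
      lines <- c(lines, "[clone sizes]", "  no clones", "")
    } else {
      sizes <- sort(table(cl$clone), decreasing = TRUE)
      lines <- c(lines, "[clone sizes]",
                 sprintf("  clone %s: %d cells", names(sizes),
                         as.integer(sizes)), "")
    }
  } else {
    lines <- c(lines, "[clone sizes]", "  absent", "")
  }
  bias_path <- file.path(out_dir, "bias.tsv")
  if (file.exists(bias_path)) {
    bt <- data.table::fread(bias_path)
    lines <- c(lines, "[lineage bias (head)]",
               utils::capture.output(print(head(
                 as.data.frame(bt)[, intersect(c("label", "H", "p",
                                                 "p_adj"), names(bt))]))),
               "")
  } else {
    lines <- c(lines, "[lineage bias]", "  absent", "")
  }
  writeLines(lines, file)
  invisible(lines)
}
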