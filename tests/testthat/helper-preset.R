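# Shared simulations for the acceptance suite. The two-donor preset is
# expensive (~30 s), so it is generated once per test run and cached.
# Seeds are fixed a priori; the analysis-side demux thresholds
# (fixed_af = 0.8, absent_af = 0.2) reflect the preset's ~20x depth,
# where allele-frequency granularity is 1/coverage.

.sim_cache <- new.env(parent = emptyenv())

get_preset_sim <- function() {
  if (is.null(.sim_cache$preset)) {
    .sim_cache$preset <- simulate_mixing(seed = 101L)
  }
  .sim_cache$preset
}

get_doublet_sim <- function() {
  if (is.null(.sim_cache$doublet)) {
    .sim_cache$doublet <- simulate_mixing(seed = 202L,
                                          doublet_fraction = 0.02)
  }
  .sim_cache$doublet
}

sim_cells <- function(sim) {
  tb <- sim$truth$barcodes
  tb$barcode[tb$is_cell]
}

sim_variant_df <- function(sim) {
  sim$truth$variants[, c("position", "ref", "alt", "label")]
}

# demux chain used by several criteria: candidate identification at
# depth-appropriate bounds, profile inference, assignment
run_demux_chain <- function(sim, het = NULL) {
  cells <- sim_cells(sim)
  if (is.null(het)) {
    het <- compute_heteroplasmy(sim$counts, sim_variant_df(sim), cells)
  }
  homo <- identify_homoplasmic_variants(het, fixed_af = 0.8,
                                        absent_af = 0.2)
  profiles <- infer_donor_profiles(het, homo$discriminating_candidate,
                                   k_donors = 2)
  assignments <- assign_cells(het, profiles)
  list(het = het, homo = homo, profiles = profiles,
       assignments = assignments)
}
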