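# Donor demultiplexing from homoplasmic germline mtDNA variants.
# Homoplasmic variants show a bimodal per-cell allele-frequency
# distribution in a multi-donor pool (near-fixed in cells of carriers,
# near-absent elsewhere); cells are assigned to binary donor profiles by
# Hamming matching, cross-donor collisions are flagged by intermediate
# allele frequencies, and residual contamination is quantified from
# foreign-donor variants.

#' Identify homoplasmic and donor-discriminating candidate variants
#'
#' A variant is a bimodal (discriminating) candidate iff at least
#' `bimodal_min_frac` of its covered cells sit in the extreme modes
#' (`af > fixed_af` or `af < absent_af`) and both modes are non-empty;
#' it is shared-homoplasmic iff at least `bimodal_min_frac` of covered
#' cells sit in the fixed mode. Variants covered in fewer than
#' `min_covered_cells` cells are skipped.
#'
#' The published bounds (fixed > 0.99, absent < 0.01) describe deeply
#' sequenced data; at modest coverage the granularity of `af` is
#' `1/coverage`, so the bounds should be relaxed accordingly (e.g.
#' 0.8 / 0.2 at ~20x).
#'
#' @param het a `heteroplasmy_matrix` over QC-passing cells.
#' @param fixed_af lower bound of the fixed mode.
#' @param absent_af upper bound of the absent mode.
#' @param bimodal_min_frac minimum fraction of covered cells in the two
#'   modes.
#' @param min_covered_cells minimum covered cells per variant.
#' @return list with `shared_homoplasmic`, `discriminating_candidate`
#'   (variant data.frames) and `skipped` (labels).
#' @export
identify_homoplasmic_variants <- function(het, fixed_af = 0.99,
                                          absent_af = 0.01,
                                          bimodal_min_frac = 0.9,
                                          min_covered_cells = 20) {
  nv <- nrow(het$variants)
  is_shared <- is_cand <- logical(nv)
  skipped <- character(0)
  for (v in seq_len(nv)) {
    covered <- het$cov[, v] > 0
    if (sum(covered) < min_covered_cells) {
      skipped <- c(skipped, het$variants$label[v])
      next
    }
    af <- het$af[covered, v]
    hi <- af > fixed_af
    lo <- af < absent_af
    frac <- mean(hi | lo)
    is_shared[v] <- mean(hi) >= bimodal_min_frac
    is_cand[v] <- frac >= bimodal_min_frac && any(hi) && any(lo)
  }
  list(shared_homoplasmic = het$variants[is_shared, , drop = FALSE],
       discriminating_candidate = het$variants[is_cand, , drop = FALSE],
       skipped = skipped)
}

binarize_at_half <- function(het, variants) {
  idx <- match(variants$label, het$variants$label)
  assert_that(!anyNA(idx), "variants missing from heteroplasmy matrix")
  state <- (het$af[, idx, drop = FALSE] > 0.5) * 1
  state[het$cov[, idx, drop = FALSE] == 0] <- NA
  state
}

#' Infer donor genotype profiles
#'
#' Binary per-variant profiles from discriminating candidate variants:
#' per-cell allele frequencies are binarised at 0.5, profiles are
#' seeded from the pair of cells at maximal Hamming distance (for
#' `k_donors > 2`, farthest-point seeding), and assignment-by-minimum-
#' Hamming alternates with majority-profile updates until convergence
#' (at most `max_iter` iterations, deterministic order). The final
#' `discriminating_variants` of each profile are those whose state
#' differs between at least two donors.
#'
#' @param het a `heteroplasmy_matrix`.
#' @param discriminating variant `data.frame` of candidate variants.
#' @param k_donors number of donors (>= 1).
#' @param max_iter iteration cap.
#' @return list with `profiles` (list of donor profiles: `donor_id`,
#'   `genotype` named 0/1 vector, `discriminating_variants`), `labels`
#'   (named per-cell provisional donor), `n_iter`.
#' @export
infer_donor_profiles <- function(het, discriminating, k_donors,
                                 max_iter = 100) {
  assert_that(k_donors >= 1, "k_donors must be >= 1")
  if (k_donors >= 2) {
    assert_that(nrow(discriminating) > 0,
                "discriminating variants required for k_donors >= 2")
  }
  state <- binarize_at_half(het, discriminating)
  majority <- function(rows) {
    m <- colMeans(state[rows, , drop = FALSE], na.rm = TRUE)
    out <- ifelse(is.nan(m), 0, (m > 0.5) * 1)   # ties -> absent
    out
  }
  donor_ids <- paste0("donor", seq_len(k_donors))
  if (k_donors == 1) {
    prof <- matrix(majority(seq_along(het$cells)), nrow = 1)
    labels <- setNames(rep(donor_ids, length(het$cells)), het$cells)
    profiles <- list(list(donor_id = donor_ids,
                          genotype = setNames(prof[1, ],
                                              discriminating$label),
                          discriminating_variants = discriminating[0, ]))
    return(list(profiles = profiles, labels = labels, n_iter = 0L))
  }
  # mean Hamming mismatch over jointly covered variants
  hamming <- function(A, B) {
    obs_a <- !is.na(A); A0 <- ifelse(obs_a, A, 0)
    obs_b <- !is.na(B); B0 <- ifelse(obs_b, B, 0)
    joint <- obs_a %*% t(obs_b)
    mism <- A0 %*% t(obs_b) + obs_a %*% t(B0) - 2 * (A0 %*% t(B0))
    ifelse(joint > 0, mism / joint, 0)
  }
  D <- hamming(state, state)
  seed <- arrayInd(which.max(D), dim(D))
  centers <- c(seed[1, 1], seed[1, 2])
  while (length(centers) < k_donors) {
    dmin <- apply(D[, centers, drop = FALSE], 1, min)
    centers <- c(centers, which.max(dmin))
  }
  prof <- state[centers, , drop = FALSE]
  prof[is.na(prof)] <- 0
  assign_idx <- rep(0L, length(het$cells))
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    Dp <- hamming(state, prof)
    new_idx <- max.col(-Dp, ties.method = "first")
    if (identical(new_idx, assign_idx)) break
    assign_idx <- new_idx
    for (kk in seq_len(k_donors)) {
      rows <- which(assign_idx == kk)
      if (length(rows)) prof[kk, ] <- majority(rows)
    }
    if (it == max_iter) {
      stop_cc("donor profile inference did not converge in %d iterations",
              max_iter, class = "cryoclone_demux_error")
    }
  }
  if (any(duplicated(as.data.frame(prof)))) {
    stop_cc("donor profiles collapsed: cells are genotypically identical",
            class = "cryoclone_demux_error")
  }
  differing <- apply(prof, 2, function(col) length(unique(col)) > 1)
  profiles <- lapply(seq_len(k_donors), function(kk) {
    list(donor_id = donor_ids[kk],
         genotype = setNames(prof[kk, ], discriminating$label),
         discriminating_variants =
           discriminating[differing, , drop = FALSE])
  })
  labels <- setNames(donor_ids[assign_idx], het$cells)
  list(profiles = profiles, labels = labels, n_iter = n_iter)
}

#' Assign cells to donors
#'
#' Per cell, `match_fraction(d)` is the fraction of covered
#' discriminating variants whose binarised state equals donor d's
#' profile. The cell is called a collision if at least `collision_frac`
#' of its covered discriminating variants have allele frequencies
#' strictly inside `intermediate_band`; otherwise it is assigned to the
#' best-matching donor if that match is at least `match_min` and leads
#' the runner-up by at least `margin_min`; otherwise it is unassigned.
#'
#' @param het a `heteroplasmy_matrix`.
#' @param profiles output of [infer_donor_profiles()] (or a compatible
#'   list of donor profiles).
#' @param match_min minimum match fraction for a donor call.
#' @param margin_min minimum lead over the runner-up.
#' @param intermediate_band open allele-frequency interval flagging
#'   cross-donor mixtures.
#' @param collision_frac fraction of intermediate variants that flags a
#'   collision.
#' @return `data.frame`: barcode, call, per-donor match fractions,
#'   `n_covered`, `frac_intermediate`.
#' @export
assign_cells <- function(het, profiles, match_min = 0.9, margin_min = 0.3,
                         intermediate_band = c(0.1, 0.9),
                         collision_frac = 0.25) {
  plist <- profiles$profiles %||% profiles
  disc <- plist[[1]]$discriminating_variants
  assert_that(nrow(disc) > 0, "profiles carry no discriminating variants")
  idx <- match(disc$label, het$variants$label)
  assert_that(!anyNA(idx), "profile variants missing from matrix")
  af <- het$af[, idx, drop = FALSE]
  cov <- het$cov[, idx, drop = FALSE]
  state <- (af > 0.5) * 1
  covered <- cov > 0
  n_cov <- rowSums(covered)
  inter <- covered & af > intermediate_band[1] & af < intermediate_band[2]
  frac_inter <- ifelse(n_cov > 0, rowSums(inter) / pmax(n_cov, 1), 0)
  mf <- vapply(plist, function(p) {
    g <- p$genotype[disc$label]
    agree <- covered & (state == matrix(g, nrow(af), length(g),
                                        byrow = TRUE))
    ifelse(n_cov > 0, rowSums(agree) / pmax(n_cov, 1), 0)
  }, numeric(nrow(af)))
  if (is.null(dim(mf))) mf <- matrix(mf, nrow = 1)
  colnames(mf) <- vapply(plist, `[[`, "", "donor_id")
  best <- max.col(mf, ties.method = "first")
  bestv <- mf[cbind(seq_len(nrow(mf)), best)]
  runner <- if (ncol(mf) > 1) {
    apply(mf, 1, function(r) max(r[-which.max(r)]))
  } else rep(0, nrow(mf))
  call <- rep("unassigned", nrow(mf))
  call[bestv >= match_min & (bestv - runner) >= margin_min] <-
    colnames(mf)[best[bestv >= match_min & (bestv - runner) >= margin_min]]
  call[n_cov > 0 & frac_inter >= collision_frac] <- "collision"
  call[n_cov == 0] <- "unassigned"
  out <- data.frame(barcode = het$cells, call = call,
                    n_covered = n_cov, frac_intermediate = frac_inter,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mf))
}

#' Quantify residual cross-donor contamination
#'
#' For a cell called donor d, contamination is the mean allele frequency
#' over covered variants that are present in some other donor's profile
#' and absent from d's. Cells without any covered foreign variant are
#' excluded from the dataset mean (and counted).
#'
#' @param het a `heteroplasmy_matrix`.
#' @param assignments output of [assign_cells()].
#' @param profiles output of [infer_donor_profiles()].
#' @return list with `per_cell` (named vector, `NA` where undefined),
#'   `dataset_percent` (mean over assigned singlets x 100),
#'   `n_undefined`.
#' @export
estimate_contamination <- function(het, assignments, profiles) {
  plist <- profiles$profiles %||% profiles
  donor_ids <- vapply(plist, `[[`, "", "donor_id")
  geno <- do.call(rbind, lapply(plist, `[[`, "genotype"))
  labels <- intersect(colnames(geno), het$variants$label)
  idx <- match(labels, het$variants$label)
  af <- het$af[, idx, drop = FALSE]
  cov <- het$cov[, idx, drop = FALSE]
  gm <- geno[, labels, drop = FALSE]
  contam <- setNames(rep(NA_real_, length(het$cells)), het$cells)
  for (d in seq_along(donor_ids)) {
    cells_d <- which(assignments$call == donor_ids[d])
    if (length(cells_d) == 0) next
    foreign <- gm[d, ] == 0 & colSums(gm[-d, , drop = FALSE] == 1) > 0
    if (!any(foreign)) next
    afd <- af[cells_d, foreign, drop = FALSE]
    covd <- cov[cells_d, foreign, drop = FALSE] > 0
    ncov <- rowSums(covd)
    vals <- ifelse(ncov > 0, rowSums(afd * covd) / pmax(ncov, 1), NA_real_)
    contam[cells_d] <- vals
  }
  singlet <- assignments$call %in% donor_ids
  defined <- singlet & !is.na(contam)
  list(per_cell = contam,
       dataset_percent = if (any(defined)) 100 * mean(contam[defined])
                         else NA_real_,
       n_undefined = sum(singlet) - sum(defined))
}
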