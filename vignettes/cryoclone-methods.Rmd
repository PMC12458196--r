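---
title: "cryoclone: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cryoclone: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoclone)
```

This vignette documents the statistical models behind the package, the
parameters that matter (with defaults and rationale), what the
synthetic-data generator does and does not emulate, and the design
choices made where the problem was genuinely open. It states no
empirical result that the test suite does not itself compute.

## Data model

The central object is a strand-specific base-count tensor: for every
droplet barcode, mitochondrial position, base and strand, a
non-negative read count, held as eight sparse matrices
(`genome_length x n_barcodes`). Coverage is always *derived* — the sum
of the four base counts over both strands — never stored separately;
when an external coverage table is supplied alongside base tables, the
reader cross-checks the two and treats any discrepancy as a hard
integrity error. Tensors are immutable by convention: every operation
that changes counts builds a new object, which lets derived quantities
(coverage) be memoised safely.

Per-cell heteroplasmy at a variant `v` is

$$\mathrm{af}(b, v) = \frac{\text{alt}_{fwd} + \text{alt}_{rev}}
                           {\text{coverage}(b, \mathrm{pos}(v))},$$

with `af = 0` and a missing flag wherever coverage is zero. Because
mtDNA is multicopy, `af` is a genuine cell-level fraction, not a
diploid genotype.

## Variant confidence metrics

Per variant, over a set of QC-passing cells:

* **n_cells_conf_detected** — cells with at least 1 alternate read on
  *each* strand and at least 2 in total. The upstream tooling this
  mirrors does not publish an exact definition, so both thresholds are
  arguments; parity with any particular external version is not
  claimed.
* **strand concordance** — Pearson correlation, across covered cells,
  of forward vs reverse alternate *counts* (not frequencies). Counts
  follow the established lineage of this metric; the operand is
  configurable only by computing it yourself from the returned
  matrices. Undefined (fewer than two cells with alternate reads, or a
  zero-variance strand) is reported as `NA` and *fails* downstream
  filters — missing evidence is never treated as passing.
* **log10 VMR** — variance-to-mean ratio of per-cell `af` over covered
  cells, log10-transformed. The variance is the population variance
  (`ddof = 0`, configurable): the cells at hand are the population of
  interest, and the convention keeps the worked identity
  `af = {0, 0, 1, 1} => VMR = 0.25 / 0.5 = 0.5` exact.
* **pseudobulk heteroplasmy** — both summaries are computed and kept
  side by side: the *mean* of per-cell allele frequencies over covered
  cells (default everywhere a single number is needed, matching the
  "mean heteroplasmy" convention) and the *aggregate* pooled ratio
  `sum(alt) / sum(cov)`. They coincide exactly when all covered cells
  share the same coverage at the site and diverge otherwise; published
  per-variant numbers rarely say which was used, so both are exposed.

The high-confidence filter applies the printed inequalities with their
printed strictness: `n_cells >= 5`, `concordance > 0.65`,
`log10 VMR > -2`, `mean coverage >= 5`. A seven-variant artifact
blocklist (homopolymer-tract and D-loop positions 301, 302, 309, 310,
316, 3109, 189) is removed by default before clonal analysis.

## QC profiles

Threshold profiles ship as named configurations (`default`, `als`,
`nb`, `aorta`) and apply each bound with the strictness of its printed
inequality: mtDNA depth `> 5` excludes a cell at exactly 5; the upper
depth bound of the `als` profile (`< 100`) excludes exactly 100; the
`aorta` profile uses `>=` semantics where its source text says
"fewer than" / "or more". Failure reasons enumerate *every* violated
bound, so filtering is auditable and idempotent.

Background-barcode ranking sorts by `peak_region_fragments` descending
and truncates to the top 20,000. Ties are broken lexicographically by
barcode — the ranking must be a pure function of the record multiset,
and no tie rule is published. Barcodes with *zero* mitochondrial
fragments are then dropped: the upstream description reads "removing
barcodes with nonzero mitochondrial count", which would leave only
barcodes that cannot be genotyped at all; we treat this as a slip for
*zero* (background genotyping is impossible without mitochondrial
reads) and provide `keep_zero_mito = TRUE` to restore the literal
reading.

The histological tissue score is
`TS = (I + (1 - N) + (1 - FA)) / 3` from the fractions of intact
nuclei, necrosis and freezing artifacts; inputs above 1 are read as
percentages and divided by 100, since the source convention mixes
both. TS is monotone increasing in I, decreasing in N and FA, and
bounded in `[0, 1]`.

## Ambient background model

The original workflow delegates background removal to an external
variational model trained on empty droplets. This package substitutes
a closed-form empirical model that keeps the conceptual structure —
empty droplets define the ambient distribution; cell counts are
corrected toward it — while being deterministic and unit-testable:

1. **Ambient profile.** Over the selected empty droplets,
   `alpha(v) = (sum alt + 0.5 p) / (sum cov + p)` with pseudocount
   `p = 1` — the posterior mean under a symmetric Beta(0.5 p, 0.5 p)
   prior, which keeps `alpha` defined and in `(0, 1)` at thin coverage.
2. **Per-cell ambient fraction.** Markers are variants with
   `alpha >= 0.05` (ambient-prevalent); for each cell only markers at
   which the cell looks negative (`af < 0.20`) contribute, so a cell's
   own homoplasmic or clonal variants never inflate its estimate:
   `rho(b) = sum(alt) / sum(cov * alpha)` over usable markers, clipped
   to `[0, 1]`. Both thresholds are exposed; cells with no usable
   marker receive the cohort median (counted and reported).
3. **Correction.** Expected ambient alternate reads
   `e = rho(b) cov(b, v) alpha(v)` are subtracted:
   `k' = max(0, k - round(e))` with round-half-away-from-zero
   (fractional expectations are the norm at single-cell depth, and
   banker's rounding would make the correction depend on parity).
   Removed reads are split across strands proportionally to the
   observed strand counts, remainder to the larger strand, ties to
   forward. `reassign` mode (default) adds removed reads back to the
   reference allele so per-position coverage — and hence every
   downstream heteroplasmy denominator — is unchanged; `drop` mode
   deletes them. Whether the original workflow preserves coverage is
   not stated, so both are provided.

**Why subtraction alone is not enough.** At depth ~20 with a 5%
ambient fraction and a 50% ambient allele fraction, the expected
contamination per cell and variant is ~0.5 reads. A deterministic
`round(e)` removes one read from roughly half the entries and zero
from the other half, while the observed contamination `k` is a
binomial draw with the same sub-integer mean — so expectation
subtraction leaves most of the contamination in place (the residual
mean of `max(0, k - round(e))` is ~60% of the original). The
orchestrated `remove_background()` therefore also applies a per-entry
one-sided *ambient-consistency test*: entries with
`k <= qbinom(1 - tail_prob, cov, rho * alpha)` (default
`tail_prob = 0.01`) are attributed entirely to ambient material and
zeroed. This is the closed-form analogue of posterior denoising in
droplet decontamination tools: counts statistically indistinguishable
from background carry no usable endogenous signal. Genuine clonal
signal is spared because a positive cell's alternate count sits far
above the ambient tail (e.g. 40/100 reads against an ambient
expectation of 5). The low-level `correct_counts()` defaults to pure
subtraction (`tail_prob = NULL`) so the arithmetic contract
`cov 100, k 6, rho 0.05, alpha 1 -> k' = 1` holds exactly;
the test is opt-in there and on by default only in the orchestrator.

Both limits are identities: `rho -> 0` or `alpha -> 0` leaves the
tensor untouched, and removal is monotone non-decreasing in both.

## Donor demultiplexing

Homoplasmic germline variants are bimodal across a pooled run. The
published bounds — fixed above 99%, absent below 1% — describe deeply
sequenced data: at coverage `c` the granularity of `af` is `1/c`, so
at ~20x "af > 0.99" is the event *zero foreign reads* and fails for a
large fraction of genuinely homoplasmic cells (with 2.5% expected
foreign reads per site, only ~0.6 of cells show none). The bounds are
therefore arguments, and the end-to-end analyses at preset depth use
`fixed_af = 0.8`, `absent_af = 0.2` — chosen from the depth argument
above (3+ foreign reads out of 20 is already a 0.1% binomial tail),
not tuned. At the published bounds and deep coverage the defaults
apply unchanged.

A variant is a *discriminating candidate* when at least 90% of its
covered cells sit in the two extreme modes and both modes are
occupied. Rare high-heteroplasmy clone variants can slip through this
screen (most cells are negative, a few near-fixed); they are
neutralised at the next stage, because the final discriminating set is
the subset of variants whose *inferred profiles disagree* — a clone
variant ends up absent in all profiles and drops out. Shared
homoplasmic variants (e.g. recurrent D-loop variants present in both
donors) never enter the candidate set because their absent mode is
empty.

Profiles are binary genotypes inferred by binarising `af` at 0.5,
seeding from the pair of cells at maximal Hamming distance
(farthest-point seeding for more donors) and alternating
minimum-Hamming assignment with majority updates (ties to absent,
deterministic order, at most 100 iterations). Assignment of a cell
requires a match fraction of at least 0.9 and a lead of at least 0.3
over the runner-up; no quantitative collision rule is published for
mtDNA, so collisions are flagged when at least 25% of a cell's covered
discriminating variants have `af` strictly inside `(0.1, 0.9)` — a
cross-donor droplet sits near 0.5 at *every* discriminating site,
which is unreachable for a singlet at any realistic depth. All four
thresholds are arguments.

Contamination of a cell called donor `d` is the mean `af` over covered
variants present in another donor's profile and absent from `d`'s;
covered entries only, to avoid zero-inflation from missing data. In an
equal two-donor pool the model-implied value is
`rho x alpha = rho / 2`, i.e. a 5% ambient fraction manifests as
~2.5% measured cross-donor contamination.

## Clonal tracing and lineage bias

Positivity is *strictly greater than* 20% VAF. The two published
descriptions disagree (">20%" in one analysis, ">=20%" in another);
the strict form is the default and the comparator is an argument, with
the discrepancy noted here. A coverage gate (`min_cov`, default 1)
keeps uncovered entries negative.

Clone clustering retains cells positive for at least one of the top-n
(default 50) pseudobulk-heteroplasmy variants (ties broken by position
ascending), computes Jaccard distance on positive-variant sets —
identical sets at distance 0, disjoint sets at 1 — and applies Ward
linkage. The tree-cut default is `k = number of variants with at least
one positive cell`: the source never states how clone labels were cut,
and in the oligoclonal regime the package targets (most clones marked
by a single variant) this equals the number of latent clones.

Lineage bias uses the tie-corrected Kruskal–Wallis statistic with the
chi-square approximation (`df = groups - 1`), matching standard
practice; no exact small-sample mode is provided. When every covered
cell has the same value the convention `H = 0, p = 1` applies (the
statistic is 0/0 otherwise). Benjamini–Hochberg adjustment spans all
*tested* variants — whether the published analyses adjusted over all
or only candidate variants is unstated; all-tested is the conservative
default and the tested set is under caller control. The
microglia-style filter keeps variants with `p_adj <= 0.05` (inclusive)
and at least 4 positive cells in the target group (inclusive).

## The simulator: a stated world

`simulate_experiment()` draws, per cell and position, coverage from a
negative binomial (preset mean 20, size 10 — mild overdispersion of
per-position depth), then alternate reads from
`Binomial(cov, (1 - rho) af_own + rho alpha)`, applies symmetric
per-read substitution errors (default 5e-4, small against the
homoplasmy bounds), splits reads binomially across strands (0.5), and
draws empty droplets purely from the ambient pool (negative binomial,
preset mean 2 per position, size 0.5). The ambient allele fraction of
each variant is the coverage-weighted mean of all cells' true allele
fractions — with identical expected depth per cell this is the plain
mean, e.g. 0.5 for a variant homoplasmic in one of two equal donors.
Everything is reproducible from a single seed.

The two-donor mixing preset fixes the stated world of the end-to-end
tests: 2 donors x 1,000 cells, 20 discriminating germline variants per
donor plus 10 shared, 3 clones per donor (50 cells each) at
heteroplasmy 0.3 / 0.6 / 0.9, ambient fraction 0.05, 5,000 empty
droplets, depth mean 20. Clone size (50) reflects that clonal
expansions are minority populations; were every cell a clone member,
high-heteroplasmy clone variants would masquerade as bimodal germline
candidates. The preset genome is scaled to 1,000 positions so the full
tensor stays desk-sized; all per-position statistics (depth, allele
fractions, per-variant coverage) are unaffected by genome length, and
the QC depth metric remains consistent because it divides by the same
scaled length. Cross-donor doublets (optional fraction) are built by
merging the counts of one cell from each donor into a single barcode —
the physical event being modelled — and labelled in the truth.

What the generator does **not** emulate: position-dependent coverage
profiles along the genome, strand composition bias, NUMT
misalignment, PCR duplication structure, overdispersed per-variant
heteroplasmy noise (a Beta-binomial option exists for `rho` only via
`rho_beta`; read sampling stays binomial by default), doublets within
a donor, and any nuclear chromatin structure beyond scalar QC
covariates. A green end-to-end test therefore establishes that the
estimators recover the parameters of *this* generative model at
realistic depth and scale — not robustness to artifacts the model does
not contain.

## Numerical conventions

* Rounding of expected ambient counts: half away from zero.
* All orderings are deterministic: barcodes lexicographic on ties,
  variants by position ascending, first-index tie-breaks in clustering
  seeds and assignment.
* Undefined metrics propagate as `NA` and fail filters; they are never
  silently zero.
* Coordinates are 1-based inclusive everywhere a user sees them;
  positional `singlecell` columns (7, 18) are 1-based as printed.
* Variant labels accept both the `mt.` and legacy `X` prefixes on
  input; `mt.` is canonical on output.

## Known limitations

Indels and multi-allelic sites are out of scope (one ref/alt pair per
variant). The ambient model assumes a single well-mixed pool shared by
all droplets; droplet-specific ambient composition is not modelled.
Donor inference assumes the discriminating variants are genuinely
homoplasmic; low-level heteroplasmic germline variants would soften
the profiles. The Kruskal–Wallis chi-square approximation is anti-
conservative for very small groups; the positive-cell count filter is
the practical guard. mgatk-version parity for `n_cells_conf_detected`
and strand concordance is not claimed.
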