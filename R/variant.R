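# Variant model: a variant is a row in a data.frame with columns
# position (1-based mtDNA coordinate), ref, alt, label. Labels follow the
# "mt.<pos><REF>><ALT>" convention; the legacy "X<pos><REF>><ALT>" dialect
# is accepted on input and normalised to the "mt." form.

#' Construct a variant table
#'
#' @param position integer vector of 1-based mitochondrial coordinates.
#' @param ref,alt character vectors of bases in `A`, `C`, `G`, `T`.
#' @param genome_length mitochondrial genome length used for range checks
#'   (16,569 for human, 16,299 for mouse).
#' @return a `data.frame` with columns `position`, `ref`, `alt`, `label`.
#' @examples
#' variant(1206, "G", "A")
#' @export
variant <- function(position, ref, alt, genome_length = 16569) {
  position <- as.integer(position)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(position), length(ref), length(alt))
  position <- rep_len(position, n)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  assert_that(all(ref %in% BASES) && all(alt %in% BASES),
              "variant bases must be one of A, C, G, T")
  assert_that(all(position >= 1L & position <= genome_length),
              "variant position out of range [1, %d]", genome_length)
  assert_that(all(ref != alt), "variant ref and alt must differ")
  data.frame(position = position, ref = ref, alt = alt,
             label = sprintf("mt.%d%s>%s", position, ref, alt),
             stringsAsFactors = FALSE)
}

#' Parse a variant label
#'
#' Accepts both the canonical `mt.1206G>A` dialect and the legacy
#' `X301A>C` dialect; the returned variant always carries the canonical
#' `mt.` label.
#'
#' @param label character vector of variant labels.
#' @param genome_length genome length for the position range check.
#' @return a variant `data.frame` (see [variant()]).
#' @examples
#' parse_variant_label("mt.1206G>A")
#' parse_variant_label("X301A>C")
#' @export
parse_variant_label <- function(label, genome_length = 16569) {
  label <- as.character(label)
  m <- regmatches(label,
                  regexec("^(?:mt\\.|X)([0-9]+)([ACGT])>([ACGT])$", label))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop_cc("malformed variant label: '%s'", label[bad][1L],
            class = "cryoclone_parse_error")
  }
  pos <- as.integer(vapply(m, `[`, "", 2L))
  ref <- vapply(m, `[`, "", 3L)
  alt <- vapply(m, `[`, "", 4L)
  if (any(pos < 1L | pos > genome_length)) {
    off <- label[pos < 1L | pos > genome_length][1L]
    stop_cc("variant position out of range in '%s'", off,
            class = "cryoclone_parse_error")
  }
  if (any(ref == alt)) {
    stop_cc("ref equals alt in '%s'", label[ref == alt][1L],
            class = "cryoclone_parse_error")
  }
  variant(pos, ref, alt, genome_length = genome_length)
}

#' Default artifact-variant blocklist
#'
#' Known artifactual mtDNA variants (homopolymer-tract and D-loop
#' positions) removed by default before clonal analysis.
#'
#' @param genome_length genome length for validation.
#' @return a variant `data.frame`.
#' @export
artifact_blocklist <- function(genome_length = 16569) {
  parse_variant_label(
    c("X301A>C", "X302A>C", "X309C>T", "X310T>C",
      "X316G>C", "X3109T>C", "X189A>G"),
    genome_length = genome_length)
}

#' Remove blocklisted variants
#'
#' Set difference of a variant table against a blocklist (by label).
#'
#' @param variants variant `data.frame`.
#' @param blocklist variant `data.frame`; defaults to [artifact_blocklist()].
#' @return the subset of `variants` not present in `blocklist`.
#' @export
drop_artifact_variants <- function(variants, blocklist = artifact_blocklist()) {
  variants[!(variants$label %in% blocklist$label), , drop = FALSE]
}
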