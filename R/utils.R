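#' @importFrom stats median pbinom qbinom rnbinom rbinom rnorm runif
#'   setNames var cor cor.test kruskal.test p.adjust pchisq hclust cutree
#'   as.dist rmultinom
#' @importFrom utils head write.table read.table
NULL

.datatable.aware <- TRUE

BASES <- c("A", "C", "G", "T")
STRANDS <- c("fwd", "rev")

#' Round half away from zero
#'
#' Deterministic rounding used when converting fractional expected ambient
#' read counts to integers: 0.5 rounds to 1, -0.5 to -1 (unlike base
#' `round()`, which rounds half to even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cc <- function(fmt, ..., class = "cryoclone_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error")))
}

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_cc(fmt, ...)
}
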