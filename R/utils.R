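# Small shared helpers. Kept internal.

geomean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

#' Genotype levels used throughout the package
#'
#' The four-genotype factorial design: wild type, writer heterozygote
#' (`A_HET`), eraser knockout (`B_KO`), and the double mutant (`DM`).
#'
#' @return Character vector of the four genotype labels.
#' @export
genotype_levels <- function() c("WT", "A_HET", "B_KO", "DM")

# stop() with a consistent prefix-free message, no call
abort <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == round(x)

is_fraction <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1

# deterministic integer derived from a base seed, kept under 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647)
}
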