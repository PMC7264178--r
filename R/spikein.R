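#' Spike-in antibody specificity and QC
#'
#' From the barcode count table, computes per-IP fractions of spike reads by
#' modification group. The IP passes QC when the target modification's
#' fraction reaches `threshold` in every IP — the "target mark dominates,
#' other states negligible" criterion. An IP with zero spike reads fails
#' with an explicit reason.
#'
#' @param spike Long-format spike table (`barcode`, `modification`,
#'   `sample`, `count`), including the input sample.
#' @param target Target modification name (default `"H3K4me3"`).
#' @param threshold Minimum target fraction for QC pass (default 0.8).
#' @param input_sample Name of the input sample, excluded from the QC
#'   verdict (specificity is a property of the IPs).
#' @return List of class `spike_specificity`: `fractions` (samples x
#'   modifications matrix, rows summing to 1), `target_fraction` (per IP),
#'   `pass` (logical), `reasons` (character, per failing IP).
#' @export
spike_specificity <- function(spike, target = "H3K4me3", threshold = 0.8,
                              input_sample = "input_1") {
  if (!target %in% spike$modification)
    abort("target modification `", target, "` absent from the spike table")
  tab <- tapply(spike$count, list(spike$sample, spike$modification), sum)
  tab[is.na(tab)] <- 0
  totals <- rowSums(tab)
  frac <- tab / ifelse(totals > 0, totals, NA)
  ips <- setdiff(rownames(tab), input_sample)
  tf <- frac[ips, target]
  reasons <- character(0)
  zero <- totals[ips] == 0
  if (any(zero))
    reasons <- c(reasons, paste0(ips[zero], ": zero spike reads"))
  low <- !zero & (is.na(tf) | tf < threshold)
  if (any(low))
    reasons <- c(reasons, sprintf("%s: target fraction %.3f < %.2f",
                                  ips[low], tf[low], threshold))
  structure(list(fractions = frac, target_fraction = tf,
                 pass = length(reasons) == 0, reasons = reasons,
                 target = target, threshold = threshold),
            class = "spike_specificity")
}

#' @export
print.spike_specificity <- function(x, ...) {
  cat(sprintf("spike-in specificity (target %s): QC %s\n", x$target,
              if (x$pass) "PASS" else "FAIL"))
  if (!x$pass) cat(paste0("  ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}

#' Spike-in normalization coefficients and effective size factors
#'
#' For IP sample `i`, the spike enrichment is
#' `E_i = (spike_i / total_i) / (spike_input / total_input)`, the ratio of
#' spike read share in the IP to that in input. The normalization
#' coefficient anchors the enrichments at their geometric mean,
#' `c_i = E_i / geomean(E)`, and the effective size factor is
#' `s_eff_i = (total_i * c_i) / geomean(total * c)`; normalized signal is
#' `count / s_eff_i`. Because sequencing depth appears in both `total_i`
#' and `spike_i/total_i`, a uniform depth rescaling of an IP leaves `c_i`
#' unchanged, while a genome-wide signal gain (which dilutes the constant
#' spike) is preserved rather than normalized away.
#'
#' @param spike Long-format spike table including the input sample.
#' @param ip_totals Named vector of total mapped genomic reads (or relative
#'   depth factors) per IP sample.
#' @param input_totals Total mapped reads of the input sample(s); multiple
#'   inputs are pooled.
#' @param input_sample Input sample name(s) in the spike table.
#' @return List of class `spike_norm`: `enrichment` (`E_i`), `coefficient`
#'   (`c_i`), `size_factors` (`s_eff_i`), all named per IP.
#' @export
spike_norm_coefficients <- function(spike, ip_totals, input_totals,
                                    input_sample = "input_1") {
  if (!all(input_sample %in% spike$sample))
    abort("input sample(s) missing from the spike table: ",
          paste(setdiff(input_sample, spike$sample), collapse = ", "))
  if (any(ip_totals <= 0) || any(input_totals <= 0))
    abort("read totals must be positive")
  spike_tot <- c(tapply(spike$count, spike$sample, sum))
  ips <- names(ip_totals)
  if (!all(ips %in% names(spike_tot)))
    abort("spike table lacks IP sample(s): ",
          paste(setdiff(ips, names(spike_tot)), collapse = ", "))
  spike_in <- sum(spike_tot[input_sample])
  if (spike_in == 0)
    abort("zero spike reads in input; normalization coefficient undefined")
  if (any(spike_tot[ips] == 0))
    abort("zero spike reads in IP sample(s): ",
          paste(ips[spike_tot[ips] == 0], collapse = ", "))
  input_share <- spike_in / sum(input_totals)
  E <- (spike_tot[ips] / ip_totals) / input_share
  cc <- E / geomean(E)
  raw <- ip_totals * cc
  s_eff <- raw / geomean(raw)
  structure(list(enrichment = E, coefficient = cc, size_factors = s_eff),
            class = "spike_norm")
}

#' Call differential H3K4me3 regions
#'
#' Runs the negative binomial Wald contrast of [nb_wald_test()] on the IP
#' region counts using either spike-aware effective size factors (from
#' [spike_norm_coefficients()]) or naive median-of-ratios depth
#' normalization, then applies the DMR thresholds: strict, BH-adjusted
#' p below `padj_cutoff` (default 0.05); relaxed, raw p below `p_cutoff`
#' (default 0.05, the screen used for the weak-effect heterozygote).
#' Direction is `"hyper"`/`"hypo"` by the sign of the fold change.
#'
#' @param x A [count_matrix()] of region counts (input samples are dropped
#'   before testing).
#' @param contrast `c(numerator, denominator)` genotype pair.
#' @param spike_norm A `spike_norm` object covering all IP samples of the
#'   contrast; required when `normalization = "spike"`.
#' @param normalization `"spike"` or `"naive"`.
#' @param mode `"strict"`/`"relaxed"`; `NULL` returns the full result table
#'   without thresholding.
#' @param padj_cutoff,p_cutoff DMR thresholds (strict inequalities).
#' @param dispersion_method Passed to [estimate_dispersions()].
#' @return In thresholded modes, the selected rows with a `direction`
#'   column; with `mode = NULL`, the full `de_result` table (plus
#'   `direction`).
#' @export
call_dmrs <- function(x, contrast, spike_norm = NULL,
                      normalization = c("spike", "naive"),
                      mode = c("strict", "relaxed"),
                      padj_cutoff = 0.05, p_cutoff = 0.05,
                      dispersion_method = c("feature", "common")) {
  normalization <- match.arg(normalization)
  ip <- subset_samples(x, ip_samples(x))
  if (normalization == "spike") {
    if (is.null(spike_norm)) abort("`spike_norm` is required for spike ",
                                   "normalization")
    sf <- spike_norm$size_factors
    missing <- setdiff(ip$design$sample, names(sf))
    if (length(missing))
      abort("spike normalization lacks IP sample(s): ",
            paste(missing, collapse = ", "))
    sf <- sf[ip$design$sample]
  } else {
    sf <- size_factors(ip)
  }
  res <- nb_wald_test(ip, contrast, sf = sf,
                      dispersion_method = match.arg(dispersion_method))
  res$direction <- ifelse(res$log2FC > 0, "hyper", "hypo")
  if (is.null(mode)) return(res)
  mode <- match.arg(mode)
  keep <- if (mode == "strict") {
    !is.na(res$padj) & res$padj < padj_cutoff
  } else {
    !is.na(res$pvalue) & res$pvalue < p_cutoff
  }
  out <- res[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "contrast") <- contrast
  out
}
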