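# Peak-to-gene assignment, mRNA x H3K4me3 quadrant integration, and
# Fisher gene-set enrichment.

parse_int_list <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Assign regions to their nearest gene and genomic feature class
#'
#' Each region is assigned to exactly one gene: the one whose TSS is
#' nearest to the region midpoint (ties broken by the lexicographically
#' smaller gene id). The distance is signed and strand-aware (positive
#' downstream of the TSS). The feature class follows the priority
#' promoter > exon > intron > distal: `"promoter"` when the midpoint lies
#' within `promoter_halfwidth` of the TSS (+/- 1 kb by default), else
#' `"exon"` when it falls in an annotated exon of the assigned gene, else
#' `"intron"` within the gene body, else `"distal"`. Regions on
#' chromosomes absent from the annotation get `gene = NA` and class
#' `"distal"`.
#'
#' @param regions Data frame with columns `region`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genes Gene annotation as from [read_gene_annotation()]: `gene`,
#'   `chrom`, `strand`, `tss`, optional `tx_start`/`tx_end` and
#'   `exon_starts`/`exon_ends`.
#' @param promoter_halfwidth Promoter window half-width in bp
#'   (default 1000).
#' @return Data frame with columns `region`, `gene`, `distance` (signed,
#'   strand-aware midpoint-to-TSS), `class`.
#' @export
annotate_peaks <- function(regions, genes, promoter_halfwidth = 1000L) {
  if (!nrow(genes)) abort("gene annotation is empty")
  mid <- (regions$start + regions$end) %/% 2L
  n <- nrow(regions)
  gene <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  cls <- rep("distal", n)
  has_exons <- all(c("exon_starts", "exon_ends") %in% names(genes))
  has_body <- all(c("tx_start", "tx_end") %in% names(genes))

  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    # order candidate genes by TSS, then id, so the tie rule is positional
    gi <- gi[order(genes$tss[gi], genes$gene[gi])]
    tss <- genes$tss[gi]
    for (k in ri) {
      dd <- abs(mid[k] - tss)
      best <- which(dd == min(dd))
      if (length(best) > 1)
        best <- best[order(genes$gene[gi[best]])[1]]
      g <- gi[best]
      gene[k] <- genes$gene[g]
      distance[k] <- if (genes$strand[g] == "+") mid[k] - genes$tss[g]
                     else genes$tss[g] - mid[k]
      if (abs(mid[k] - genes$tss[g]) <= promoter_halfwidth) {
        cls[k] <- "promoter"
      } else if (has_exons &&
                 in_any_interval(mid[k],
                                 parse_int_list(genes$exon_starts[g]),
                                 parse_int_list(genes$exon_ends[g]))) {
        cls[k] <- "exon"
      } else if (has_body && mid[k] >= genes$tx_start[g] &&
                 mid[k] < genes$tx_end[g]) {
        cls[k] <- "intron"
      }
    }
  }
  data.frame(region = regions$region, gene = gene, distance = distance,
             class = cls, stringsAsFactors = FALSE)
}

in_any_interval <- function(pos, starts, ends) {
  length(starts) > 0 && any(pos >= starts & pos < ends)
}

#' Quadrant analysis of paired mRNA and chromatin fold changes
#'
#' Classifies paired fold changes by sign into four quadrants — Q1
#' (`x < 0, y > 0`), Q2 (`x > 0, y > 0`), Q3 (`x < 0, y < 0`), Q4
#' (`x > 0, y < 0`), with `x` the mRNA and `y` the H3K4me3 log2 fold
#' change — and tests the sign structure three ways, each a chi-squared
#' statistic `sum((O - E)^2 / E)`:
#' \itemize{
#'   \item 4-cell goodness of fit against a uniform quarter split (3 df);
#'   \item concordance, Q2+Q3 vs Q1+Q4 against 50/50 (1 df);
#'   \item pairwise 2-cell tests within each x sign (Q2 vs Q4, Q3 vs Q1).
#' }
#' Pairs with an exact zero in either coordinate are excluded from the
#' quadrants and counted separately. Pearson's correlation of the paired
#' fold changes is reported with its two-sided t-test p value. Counts are
#' invariant under positive rescaling of either axis.
#'
#' @param mrna_fc,chip_fc Paired numeric vectors.
#' @param features Optional feature ids carried through to the result.
#' @param min_n Minimum non-zero pairs for the tests (default 4); below it
#'   only counts are returned, with a warning.
#' @return List of class `quadrant_table`: `counts` (named Q1..Q4),
#'   `n_zero`, `n`, `tests` (data frame: test, statistic, df, p.value),
#'   `pearson_r`, `pearson_p`.
#' @export
quadrant_analysis <- function(mrna_fc, chip_fc, features = NULL,
                              min_n = 4L) {
  if (length(mrna_fc) != length(chip_fc))
    abort("`mrna_fc` and `chip_fc` must be paired vectors")
  ok <- !is.na(mrna_fc) & !is.na(chip_fc)
  x <- mrna_fc[ok]; y <- chip_fc[ok]
  zero <- x == 0 | y == 0
  n_zero <- sum(zero)
  x <- x[!zero]; y <- y[!zero]
  counts <- c(Q1 = sum(x < 0 & y > 0), Q2 = sum(x > 0 & y > 0),
              Q3 = sum(x < 0 & y < 0), Q4 = sum(x > 0 & y < 0))
  n <- sum(counts)
  out <- list(counts = counts, n_zero = n_zero, n = n)
  if (n < min_n) {
    warning("fewer than ", min_n, " non-zero pairs; tests skipped")
    out$tests <- data.frame()
    out$pearson_r <- NA_real_; out$pearson_p <- NA_real_
    class(out) <- "quadrant_table"
    return(out)
  }
  gof2 <- function(o) {
    e <- sum(o) / length(o)
    if (e == 0) return(c(NA_real_, NA_real_))
    stat <- sum((o - e)^2 / e)
    c(stat, pchisq(stat, length(o) - 1, lower.tail = FALSE))
  }
  t4 <- gof2(counts)
  tc <- gof2(c(counts["Q2"] + counts["Q3"], counts["Q1"] + counts["Q4"]))
  t24 <- gof2(counts[c("Q2", "Q4")])
  t31 <- gof2(counts[c("Q3", "Q1")])
  out$tests <- data.frame(
    test = c("uniform_4cell", "concordance", "Q2_vs_Q4", "Q3_vs_Q1"),
    statistic = c(t4[1], tc[1], t24[1], t31[1]),
    df = c(3L, 1L, 1L, 1L),
    p.value = c(t4[2], tc[2], t24[2], t31[2]),
    stringsAsFactors = FALSE)
  r <- suppressWarnings(cor(x, y))
  if (is.na(r) || abs(r) >= 1) {
    out$pearson_r <- r
    out$pearson_p <- if (is.na(r)) NA_real_ else 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    out$pearson_r <- r
    out$pearson_p <- 2 * pt(-abs(tstat), n - 2)
  }
  class(out) <- "quadrant_table"
  out
}

#' @export
print.quadrant_table <- function(x, ...) {
  cat("quadrant counts (x = mRNA log2FC, y = H3K4me3 log2FC):\n")
  print(x$counts)
  cat(sprintf("zeros excluded: %d; Pearson r = %.3f (p = %.3g)\n",
              x$n_zero, x$pearson_r, x$pearson_p))
  if (nrow(x$tests)) print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Fisher's exact gene-set enrichment
#'
#' One-sided (enrichment) Fisher test per gene set from the hypergeometric
#' tail, on the 2x2 table of query membership by set membership within the
#' universe. The odds ratio is the classical cross-product `ad / bc`
#' (0 when the overlap is empty, `Inf` when `b` or `c` is 0). P values are
#' BH-adjusted across sets with [bh_adjust()]; `significant` flags
#' `padj < 0.05`.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `universe`.
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#'   Sets are intersected with the universe.
#' @param universe Character vector of all eligible genes (e.g. all tested
#'   features).
#' @return Data frame, one row per set, ordered as supplied: `set`,
#'   `set_size`, `overlap`, `odds_ratio`, `p.value`, `padj`, `significant`,
#'   `overlap_genes` (semicolon-collapsed).
#' @export
fisher_enrichment <- function(query, gene_sets, universe) {
  if (!length(universe)) abort("`universe` is empty")
  if (!length(query)) abort("`query` is empty")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    abort("`query` must be a subset of `universe`")
  N <- length(universe); nq <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    m <- length(set)
    hit <- intersect(query, set)
    a <- length(hit)
    b <- nq - a
    cc <- m - a
    d <- N - a - b - cc
    or <- if (a == 0) 0 else if (b == 0 || cc == 0) Inf
          else (a * d) / (b * cc)
    p <- phyper(a - 1, m, N - m, nq, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = a, odds_ratio = or,
               p.value = p,
               overlap_genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p.value)
  out$significant <- !is.na(out$padj) & out$padj < 0.05
  out[, c("set", "set_size", "overlap", "odds_ratio", "p.value", "padj",
          "significant", "overlap_genes")]
}
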