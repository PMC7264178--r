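# Rescue quantification: fold-change tables across the five contrasts,
# direction cross-classification, paired signed-rank group shift tests,
# regression slopes tested against unity, and threshold-based
# rescue-driver calling.

contrast_keys <- function() c("A_vs_WT", "B_vs_WT", "DM_vs_WT",
                              "DM_vs_A", "DM_vs_B")

#' Assemble the five-contrast fold-change table
#'
#' Joins the per-contrast Wald results (A vs WT, B vs WT, DM vs WT, DM vs A,
#' DM vs B) on a shared feature universe into one table with columns
#' `log2FC_<contrast>`, `pvalue_<contrast>`, `padj_<contrast>`. All five
#' results must come from one shared normalization so that contrast
#' additivity (`log2FC(DM vs A) = log2FC(DM vs WT) - log2FC(A vs WT)`)
#' holds to numerical tolerance. Features missing statistics in any
#' contrast are flagged `complete = FALSE`.
#'
#' @param de_results Named list of `de_result` tables; names must be the
#'   five contrast keys above.
#' @return A `fold_change_table` data frame, one row per feature.
#' @export
build_fold_change_table <- function(de_results) {
  keys <- contrast_keys()
  missing <- setdiff(keys, names(de_results))
  if (length(missing))
    abort("missing contrast(s): ", paste(missing, collapse = ", "))
  feats <- de_results[[keys[1]]]$feature
  for (k in keys[-1]) {
    other <- de_results[[k]]$feature
    if (!setequal(feats, other)) {
      d1 <- setdiff(feats, other); d2 <- setdiff(other, feats)
      abort("feature universes differ across contrasts; e.g. ",
            paste(utils::head(c(d1, d2), 5), collapse = ", "))
    }
  }
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (k in keys) {
    r <- de_results[[k]]
    i <- match(feats, r$feature)
    out[[paste0("log2FC_", k)]] <- r$log2FC[i]
    out[[paste0("pvalue_", k)]] <- r$pvalue[i]
    out[[paste0("padj_", k)]] <- r$padj[i]
  }
  out$complete <- complete.cases(out[, paste0("log2FC_", keys)])
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Cross-classify one mutant's calls by their direction in the other mutant
#'
#' For each differential feature of mutant X, looks up its fold change and
#' p value in the other single mutant Y (vs WT) and assigns: `"opposite"`
#' if the signs disagree and Y's change is nominally significant
#' (`p < nominal_p`), `"same"` if the signs agree and Y is nominally
#' significant, otherwise `"unchanged"`. A fold change of exactly zero in Y
#' is classified `"unchanged"` regardless of its p value.
#'
#' @param features Character vector of feature ids (e.g. a DEG/DMR set of
#'   mutant X); must be present in `fc`.
#' @param fc A [build_fold_change_table()] result.
#' @param mutant The mutant the features belong to, `"A"` or `"B"` (the
#'   classification uses the *other* mutant's contrast).
#' @param nominal_p Nominal significance for "changed in Y" (default 0.05).
#' @return Data frame with columns `feature`, `fc_self`, `fc_other`,
#'   `p_other`, `class`.
#' @export
classify_direction <- function(features, fc, mutant = c("A", "B"),
                               nominal_p = 0.05) {
  mutant <- match.arg(mutant)
  other <- if (mutant == "A") "B" else "A"
  i <- match(features, fc$feature)
  if (anyNA(i)) abort("feature(s) absent from the fold-change table: ",
                      paste(features[is.na(i)], collapse = ", "))
  fc_self <- fc[[paste0("log2FC_", mutant, "_vs_WT")]][i]
  fc_other <- fc[[paste0("log2FC_", other, "_vs_WT")]][i]
  p_other <- fc[[paste0("pvalue_", other, "_vs_WT")]][i]
  changed <- !is.na(p_other) & p_other < nominal_p & !is.na(fc_other) &
    fc_other != 0
  prod_sign <- sign(fc_self) * sign(fc_other)
  cls <- ifelse(changed & prod_sign < 0, "opposite",
                ifelse(changed & prod_sign > 0, "same", "unchanged"))
  data.frame(feature = features, fc_self = fc_self, fc_other = fc_other,
             p_other = p_other, class = cls, stringsAsFactors = FALSE)
}

# Exact signed-rank tail probabilities by convolution over the (doubled,
# hence integer) ranks: distribution of the sum of a random subset of the
# ranks, each included with probability 1/2.
signed_rank_exact_cdf <- function(ranks2) {
  total <- sum(ranks2)
  dist <- numeric(total + 1)
  dist[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1 - r)])
    dist <- (dist + shifted) / 2
  }
  cumsum(dist)
}

#' Wilcoxon signed-rank test on a vector of differences
#'
#' Classic signed-rank treatment: zero differences are dropped, ties get
#' mid-ranks, and `W` is the sum of ranks of the positive differences. For
#' `n <= exact_max_n` the null distribution is computed exactly by
#' convolution over the (possibly tied) ranks; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Two-sided p values double the smaller tail (capped at 1).
#'
#' @param d Numeric vector of paired differences.
#' @param alternative `"two.sided"`, `"greater"` (positive shift), or
#'   `"less"`.
#' @param exact_max_n Largest `n` for the exact distribution (default 25).
#' @return List of class `signed_rank_test`: `statistic` (W), `n` (non-zero
#'   differences), `p.value`, `method` (`"exact"`/`"normal"`), `degenerate`
#'   (`TRUE` when all differences are zero, in which case `W = 0` and
#'   `p = 1`).
#' @examples
#' signed_rank_test(1:5)$p.value  # 2/2^5 = 0.0625
#' @export
signed_rank_test <- function(d, alternative = c("two.sided", "greater",
                                                "less"),
                             exact_max_n = 25L) {
  alternative <- match.arg(alternative)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(structure(list(statistic = 0, n = 0L, p.value = 1,
                          method = "degenerate", degenerate = TRUE),
                     class = "signed_rank_test"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max_n) {
    ranks2 <- as.integer(round(2 * r))
    cdf <- signed_rank_exact_cdf(ranks2)
    w2 <- as.integer(round(2 * W))
    p_le <- cdf[w2 + 1]
    p_ge <- 1 - (if (w2 >= 1) cdf[w2] else 0)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    method <- "exact"
  } else {
    m <- n * (n + 1) / 4
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5
    z_ge <- (W - m - cc) / sqrt(v)
    z_le <- (W - m + cc) / sqrt(v)
    p_ge <- pnorm(z_ge, lower.tail = FALSE)
    p_le <- pnorm(z_le)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    method <- "normal"
  }
  structure(list(statistic = W, n = n, p.value = p, method = method,
                 degenerate = FALSE),
            class = "signed_rank_test")
}

#' Paired signed-rank test of a group fold-change shift
#'
#' Tests whether a feature set's fold changes in the double mutant are
#' shifted relative to the single mutant — the group-level rescue readout.
#' Differences are `fc_dm - fc_single`; a rescued up-regulated set shows a
#' negative shift.
#'
#' @param fc_single,fc_dm Equal-length paired vectors of log2 fold changes
#'   (single mutant vs WT, DM vs WT) for one feature set.
#' @param alternative Sidedness of [signed_rank_test()] (default
#'   two-sided).
#' @param set_id Optional label stored in the result.
#' @return List of class `group_rescue_test`: `set_id`, `n`,
#'   `median_single`, `median_dm`, `statistic` (W), `p.value`, `direction`
#'   of the shift (`"attenuated"` when the DM median is nearer zero,
#'   `"amplified"` otherwise, `"none"` if degenerate), `method`.
#' @export
group_rescue_test <- function(fc_single, fc_dm,
                              alternative = c("two.sided", "greater",
                                              "less"),
                              set_id = NULL) {
  if (length(fc_single) != length(fc_dm))
    abort("`fc_single` and `fc_dm` must be paired vectors of equal length")
  ok <- !is.na(fc_single) & !is.na(fc_dm)
  fc_single <- fc_single[ok]; fc_dm <- fc_dm[ok]
  if (!length(fc_single)) abort("no complete pairs")
  t <- signed_rank_test(fc_dm - fc_single, match.arg(alternative))
  med_s <- median(fc_single); med_d <- median(fc_dm)
  direction <- if (t$degenerate) "none"
               else if (abs(med_d) < abs(med_s)) "attenuated" else "amplified"
  structure(list(set_id = set_id, n = length(fc_single),
                 median_single = med_s, median_dm = med_d,
                 statistic = t$statistic, p.value = t$p.value,
                 direction = direction, method = t$method),
            class = "group_rescue_test")
}

#' @export
print.group_rescue_test <- function(x, ...) {
  cat(sprintf(paste0("group rescue test%s: n = %d, median fc %0.3f -> ",
                     "%0.3f (%s), W = %g, p = %.3g [%s]\n"),
              if (is.null(x$set_id)) "" else paste0(" [", x$set_id, "]"),
              x$n, x$median_single, x$median_dm, x$direction, x$statistic,
              x$p.value, x$method))
  invisible(x)
}

#' Through-origin regression slope with a test against unity
#'
#' Fits the double-mutant fold changes (`y`) against the single-mutant fold
#' changes (`x`) through the origin and tests the null hypothesis that the
#' slope equals 1 (no rescue). A slope significantly below 1 quantifies
#' fold-change shrinkage in the double mutant.
#'
#' Two estimators are available. `"ols_origin"` is ordinary least squares:
#' `slope = sum(xy) / sum(x^2)`, with a t test of `(slope - 1)/SE` on
#' `n - 1` degrees of freedom. `"sma_origin"` is the standardized major
#' axis through the origin: `slope = sign(sum(xy)) * sqrt(sum(y^2) /
#' sum(x^2))`, tested via the correlation between the rotated axes
#' `y - x` and `y + x` (F reference on 1 and `n - 1` df), the classical
#' slope test for axis fits. The slope is equivariant under joint positive
#' rescaling of `x` and `y` for both methods.
#'
#' @param x,y Paired fold-change vectors (single mutant, double mutant).
#' @param method `"ols_origin"` or `"sma_origin"`.
#' @param conf_level Confidence level for the slope CI (default 0.95).
#' @return List of class `slope_test`: `method`, `slope`, `conf_int`,
#'   `statistic`, `df`, `p.value` (H0: slope = 1), `n`.
#' @examples
#' slope_test(c(1, 2, 4), c(0.5, 1, 2))$slope  # 0.5
#' @export
slope_test <- function(x, y, method = c("ols_origin", "sma_origin"),
                       conf_level = 0.95) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("slope test needs at least 3 complete pairs")
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  if (sxx == 0) abort("all x are zero; slope undefined")
  df <- n - 1
  if (method == "ols_origin") {
    slope <- sxy / sxx
    rss <- sum((y - slope * x)^2)
    se <- sqrt(rss / df / sxx)
    if (se == 0) {
      stat <- if (slope == 1) 0 else sign(slope - 1) * Inf
      p <- if (slope == 1) 1 else 0
    } else {
      stat <- (slope - 1) / se
      p <- 2 * pt(-abs(stat), df)
    }
    ci <- slope + c(-1, 1) * qt(1 - (1 - conf_level) / 2, df) * se
  } else {
    slope <- sign(ifelse(sxy == 0, 1, sxy)) * sqrt(syy / sxx)
    # test slope = 1 through the correlation of the rotated axes
    u <- y - x; v <- y + x
    suu <- sum(u^2); svv <- sum(v^2); suv <- sum(u * v)
    if (suu == 0 || svv == 0) {
      stat <- 0; p <- 1
    } else {
      r2 <- suv^2 / (suu * svv)
      if (r2 >= 1) { stat <- Inf; p <- 0 }
      else {
        stat <- r2 * df / (1 - r2)
        p <- pf(stat, 1, df, lower.tail = FALSE)
      }
    }
    r2xy <- sxy^2 / (sxx * syy)
    if (r2xy >= 1) {
      ci <- c(slope, slope)
    } else {
      B <- qf(conf_level, 1, df) * (1 - r2xy) / df
      ci <- abs(slope) * (sqrt(B + 1) + c(-1, 1) * sqrt(B))
      if (slope < 0) ci <- rev(-ci)
    }
  }
  structure(list(method = method, slope = slope, conf_int = ci,
                 statistic = stat, df = df, p.value = p, n = n),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("slope test (%s): slope = %.4f [%.4f, %.4f], p(H0 slope=1) = %.3g, n = %d\n",
              x$method, x$slope, x$conf_int[1], x$conf_int[2], x$p.value,
              x$n))
  invisible(x)
}

#' Call rescue-driving features by explicit fold-change thresholds
#'
#' A feature drives the rescue when it moves strongly between the single
#' mutant and the double mutant while the double mutant sits near wild
#' type: `|log2FC(single vs DM)| > t_single_dm` AND
#' `|log2FC(DM vs WT)| < t_dm_wt`, both strict. Defaults are the RNA screen
#' (2 and 0.7); `domain = "chip_integration"` switches the first threshold
#' to 1, the screen used when integrating with chromatin.
#'
#' @param fc A [build_fold_change_table()] result.
#' @param mutant `"A"` or `"B"` — which single mutant's rescue is being
#'   scored (uses the `DM_vs_A` or `DM_vs_B` contrast).
#' @param domain `"rna"` or `"chip_integration"`; sets default thresholds.
#' @param t_single_dm,t_dm_wt Threshold overrides.
#' @return Data frame with columns `feature`, `fc_single_dm`, `fc_dm_wt`,
#'   `driver` (logical); attribute `thresholds`.
#' @export
call_rescue_drivers <- function(fc, mutant = c("A", "B"),
                                domain = c("rna", "chip_integration"),
                                t_single_dm = NULL, t_dm_wt = NULL) {
  mutant <- match.arg(mutant)
  domain <- match.arg(domain)
  if (is.null(t_single_dm)) t_single_dm <- if (domain == "rna") 2 else 1
  if (is.null(t_dm_wt)) t_dm_wt <- 0.7
  fc_dm_single <- fc[[paste0("log2FC_DM_vs_", mutant)]]
  fc_dm_wt <- fc[["log2FC_DM_vs_WT"]]
  # |log2FC(single vs DM)| = |log2FC(DM vs single)|
  driver <- !is.na(fc_dm_single) & !is.na(fc_dm_wt) &
    abs(fc_dm_single) > t_single_dm & abs(fc_dm_wt) < t_dm_wt
  out <- data.frame(feature = fc$feature,
                    fc_single_dm = -fc_dm_single, fc_dm_wt = fc_dm_wt,
                    driver = driver, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(t_single_dm = t_single_dm, t_dm_wt = t_dm_wt)
  attr(out, "mutant") <- mutant
  attr(out, "domain") <- domain
  out
}

#' Direction-stratified DMR rescue summary
#'
#' Applies the enzymatic-activity focus filter (writer-HET: hypomethylated
#' regions only; eraser-KO: hypermethylated only), stratifies the focused
#' DMRs by their direction class in the other mutant (`"opposite"` /
#' `"same"`), and per class reports fold-change quartiles across the three
#' mutants (A vs WT, B vs WT, DM vs WT) plus a [group_rescue_test()] of DM
#' against the single mutant. Empty classes are reported with `n = 0` and
#' no test.
#'
#' @param dmr_features Character vector of DMR ids of the single mutant.
#' @param fc [build_fold_change_table()] result on the region universe.
#' @param mutant `"A"` (focus on hypo) or `"B"` (focus on hyper).
#' @param classes Optional precomputed [classify_direction()] table for
#'   these features; computed if `NULL`.
#' @param nominal_p Passed to [classify_direction()] when computing classes.
#' @return List of class `dmr_rescue_summary`: `mutant`, `focus`,
#'   `quartiles` (data frame: class x contrast quartiles), `tests` (named
#'   list of `group_rescue_test` results), `n` (per-class counts).
#' @export
dmr_rescue_summary <- function(dmr_features, fc, mutant = c("A", "B"),
                               classes = NULL, nominal_p = 0.05) {
  mutant <- match.arg(mutant)
  focus <- if (mutant == "A") "hypo" else "hyper"
  i <- match(dmr_features, fc$feature)
  if (anyNA(i)) abort("DMR(s) absent from the fold-change table")
  fc_self <- fc[[paste0("log2FC_", mutant, "_vs_WT")]][i]
  keep <- if (focus == "hypo") !is.na(fc_self) & fc_self < 0
          else !is.na(fc_self) & fc_self > 0
  feats <- dmr_features[keep]
  if (!length(feats)) {
    return(structure(list(mutant = mutant, focus = focus,
                          quartiles = data.frame(), tests = list(),
                          n = c(opposite = 0L, same = 0L)),
                     class = "dmr_rescue_summary"))
  }
  if (is.null(classes))
    classes <- classify_direction(feats, fc, mutant, nominal_p)
  cls <- classes$class[match(feats, classes$feature)]
  j <- match(feats, fc$feature)
  contrasts <- c("A_vs_WT", "B_vs_WT", "DM_vs_WT")
  qs <- list(); tests <- list(); ns <- c(opposite = 0L, same = 0L)
  for (cl in c("opposite", "same")) {
    sel <- which(cls == cl)
    ns[cl] <- length(sel)
    if (!length(sel)) next
    for (ct in contrasts) {
      v <- fc[[paste0("log2FC_", ct)]][j[sel]]
      qq <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      qs[[length(qs) + 1]] <- data.frame(class = cl, contrast = ct,
                                         n = length(sel), q25 = qq[1],
                                         median = qq[2], q75 = qq[3],
                                         stringsAsFactors = FALSE)
    }
    tests[[cl]] <- group_rescue_test(
      fc[[paste0("log2FC_", mutant, "_vs_WT")]][j[sel]],
      fc[["log2FC_DM_vs_WT"]][j[sel]],
      set_id = paste0(mutant, "_", cl))
  }
  structure(list(mutant = mutant, focus = focus,
                 quartiles = do.call(rbind, qs), tests = tests, n = ns),
            class = "dmr_rescue_summary")
}
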