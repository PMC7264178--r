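#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features of the ratio
#' of that sample's count to the feature's geometric mean across samples,
#' using only features with strictly positive counts in every sample. This
#' is the classical depth/composition normalization for count matrices.
#' Scaling one sample's column by `k` scales its size factor by exactly `k`.
#'
#' @param x A [count_matrix()] or a plain counts matrix.
#' @return Named positive numeric vector, one size factor per sample.
#' @examples
#' m <- matrix(c(100, 400, 200, 800), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' size_factors(m)  # 0.7071, 1.4142
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  logg <- rowMeans(log(counts))
  ok <- is.finite(logg)
  if (!any(ok))
    abort("no feature has strictly positive counts in all samples; ",
          "filter features or add a pseudocount before normalization")
  ratios <- counts[ok, , drop = FALSE] / exp(logg[ok])
  s <- apply(ratios, 2, median)
  if (any(!is.finite(s) | s <= 0))
    abort("size factor estimation failed (non-positive median ratio)")
  s
}

#' Method-of-moments negative binomial dispersion estimates
#'
#' On size-factor-normalized counts, with per-genotype centering, the pooled
#' within-genotype variance `v_g` and overall mean `m_g` of each feature give
#' the moment estimator `alpha_g = (v_g - xi * m_g) / m_g^2`, floored at
#' `alpha_floor`; `xi = mean(1/s_j)` corrects the Poisson term for the
#' normalization (for equal depths `xi = 1` and the estimator reduces to
#' `(var - mean)/mean^2`). Under Poisson data the estimator concentrates
#' around zero, so most features land on the floor region.
#'
#' `method = "common"` additionally pools information across features: all
#' features share the (floored) mean of the raw per-feature estimates. With
#' thousands of features this pooled value has negligible sampling noise, so
#' Wald statistics computed from it can be referred to the normal
#' distribution; per-feature estimates carry only `n - K` residual degrees
#' of freedom and downstream tests use a t reference instead. The returned
#' vector carries the reference degrees of freedom in `attr(, "df")`.
#'
#' @param x A [count_matrix()] (the genotype column of its design defines the
#'   centering groups) or a plain matrix, in which case `groups` is required.
#' @param sf Size factors from [size_factors()]; computed if `NULL`.
#' @param groups Optional grouping vector overriding the design genotypes.
#' @param alpha_floor Lower bound for the estimates (default `1e-8`).
#' @param method `"feature"` (per-feature estimates) or `"common"` (one
#'   pooled dispersion shared by all features).
#' @return Named numeric vector of dispersions with attributes `df` (degrees
#'   of freedom for downstream Wald references; `Inf` for `"common"`) and
#'   `method`.
#' @examples
#' # mean 100, variance 600 on normalized counts gives alpha = 0.05
#' @export
estimate_dispersions <- function(x, sf = NULL, groups = NULL,
                                 alpha_floor = 1e-8,
                                 method = c("feature", "common")) {
  method <- match.arg(method)
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  if (is.null(groups)) {
    if (!inherits(x, "count_matrix"))
      abort("`groups` is required when `x` is a plain matrix")
    groups <- x$design$genotype
  }
  if (ncol(counts) < 2) abort("dispersion estimation needs at least 2 samples")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  groups <- as.character(groups)
  K <- length(unique(groups))
  df <- ncol(counts) - K
  if (df < 1) abort("dispersion estimation needs replicates within groups")

  m <- rowMeans(norm)
  ss <- 0
  for (g in unique(groups)) {
    cols <- norm[, groups == g, drop = FALSE]
    ss <- ss + rowSums((cols - rowMeans(cols))^2)
  }
  v <- ss / df
  xi <- mean(1 / sf)
  raw <- (v - xi * m) / m^2
  raw[!is.finite(raw)] <- alpha_floor
  alpha <- pmax(alpha_floor, raw)
  if (method == "common") {
    alpha <- rep(max(alpha_floor, mean(raw)), length(raw))
    df <- Inf
  }
  names(alpha) <- rownames(counts)
  structure(alpha, df = df, method = method)
}

# Vectorized per-group NB log-link MLE with offsets log(s_j) and fixed
# per-feature dispersion. Newton iterations on the group log-mean; returns
# the estimate and its Fisher information.
nb_fit_group <- function(y, s, alpha, max_iter = 50L, tol = 1e-10) {
  beta <- log((rowSums(y) + 0.5) / sum(s))
  for (i in seq_len(max_iter)) {
    mu <- exp(beta) %o% s
    w <- 1 + alpha * mu
    info <- rowSums(mu / w)
    step <- rowSums((y - mu) / w) / info
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -5), 5)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(beta) %o% s
  list(beta = beta, info = rowSums(mu / (1 + alpha * mu)))
}

#' Negative binomial Wald test for a two-genotype contrast
#'
#' Fits, per feature, a negative binomial log-link model of the genotype
#' indicator with offsets `log(s_j)` and fixed dispersion, and tests the
#' log2 fold change (numerator vs denominator genotype) with a Wald
#' statistic `log2FC / SE`. No fold-change shrinkage is applied, so the
#' estimates are the plain group-mean contrasts that the downstream rescue
#' slopes consume, and `log2FC(DM vs A) = log2FC(DM vs WT) - log2FC(A vs
#' WT)` holds to numerical tolerance.
#'
#' P values are two-sided from a t reference with the degrees of freedom
#' carried by the dispersion estimates (`Inf`, i.e. normal, for a pooled
#' common dispersion). Features with zero counts in every sample of the
#' contrast are excluded from testing and from the BH ranking; features
#' whose fit does not converge (e.g. one group all zero) are flagged with
#' `NA` statistics rather than failing.
#'
#' @param x A [count_matrix()].
#' @param contrast Character vector `c(numerator, denominator)` of genotype
#'   labels, e.g. `c("B_KO", "WT")` for B vs WT.
#' @param sf Size factors (named, covering the contrast samples); computed
#'   from the full matrix if `NULL`.
#' @param dispersions Per-feature dispersions from [estimate_dispersions()]
#'   (or a bare numeric vector, treated as known with a normal reference);
#'   estimated with `dispersion_method` if `NULL`.
#' @param dispersion_method Passed to [estimate_dispersions()] when
#'   `dispersions` is `NULL`.
#' @return A `de_result` data frame with columns `feature`, `baseMean`,
#'   `log2FC`, `lfcSE`, `stat`, `pvalue`, `padj`, `tested`, and attributes
#'   `contrast` and `df`.
#' @export
nb_wald_test <- function(x, contrast, sf = NULL, dispersions = NULL,
                         dispersion_method = c("feature", "common")) {
  stopifnot(inherits(x, "count_matrix"), length(contrast) == 2)
  geno <- x$design$genotype
  for (g in contrast) {
    if (sum(geno == g & x$design$role != "input") < 2)
      abort("contrast genotype `", g, "` needs at least 2 replicates")
  }
  if (is.null(sf)) sf <- size_factors(x)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(x, sf = sf,
                                        method = match.arg(dispersion_method))
  df <- attr(dispersions, "df")
  if (is.null(df)) df <- Inf
  alpha <- as.numeric(dispersions)

  sel_num <- which(geno == contrast[1] & x$design$role != "input")
  sel_den <- which(geno == contrast[2] & x$design$role != "input")
  y_num <- x$counts[, sel_num, drop = FALSE]
  y_den <- x$counts[, sel_den, drop = FALSE]
  s_num <- sf[x$design$sample[sel_num]]
  s_den <- sf[x$design$sample[sel_den]]

  tested <- rowSums(y_num) + rowSums(y_den) > 0
  converged <- rowSums(y_num) > 0 & rowSums(y_den) > 0

  n <- nrow(x$counts)
  log2fc <- se <- stat <- p <- rep(NA_real_, n)
  ok <- tested & converged
  if (any(ok)) {
    fit_n <- nb_fit_group(y_num[ok, , drop = FALSE], s_num, alpha[ok])
    fit_d <- nb_fit_group(y_den[ok, , drop = FALSE], s_den, alpha[ok])
    log2fc[ok] <- (fit_n$beta - fit_d$beta) / log(2)
    se[ok] <- sqrt(1 / fit_n$info + 1 / fit_d$info) / log(2)
    stat[ok] <- log2fc[ok] / se[ok]
    p[ok] <- 2 * pt(-abs(stat[ok]), df = df)
  }
  norm_all <- sweep(x$counts[, c(sel_num, sel_den), drop = FALSE], 2,
                    c(s_num, s_den), "/")
  res <- data.frame(feature = rownames(x$counts),
                    baseMean = rowMeans(norm_all),
                    log2FC = log2fc, lfcSE = se, stat = stat, pvalue = p,
                    padj = bh_adjust(p), tested = tested,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "contrast") <- contrast
  attr(res, "df") <- df
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Literal step-up implementation: with `p` sorted ascending,
#' `padj_(i) = min_{j >= i} ( p_(j) * n / j )`, capped at 1. `NA`/`NaN`
#' entries propagate and are excluded from the ranking (`n` counts only
#' non-missing values).
#'
#' @param p Numeric vector of p values in `[0, 1]` (NA allowed).
#' @return Numeric vector of adjusted p values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  if (!length(idx)) return(out)
  pp <- p[idx]
  if (any(pp < 0 | pp > 1)) abort("p values must lie in [0, 1]")
  n <- length(pp)
  o <- order(pp, decreasing = TRUE)
  adj <- pmin(1, cummin(pp[o] * n / seq(n, 1)))
  out[idx[o]] <- adj
  out
}

#' Call differentially expressed features at the study thresholds
#'
#' Strict mode selects features with BH-adjusted p below `padj_cutoff`
#' (default 0.1, the DEG screen); relaxed mode selects on the raw Wald p
#' below `p_cutoff` (default 0.005, the screen used for the mildly affected
#' heterozygote). Each call carries `direction = sign(log2FC)`.
#'
#' @param deres A `de_result` from [nb_wald_test()].
#' @param mode `"strict"` or `"relaxed"`.
#' @param padj_cutoff,p_cutoff Thresholds (strict inequalities).
#' @return Data frame of selected rows with an added `direction` column
#'   (`"up"`/`"down"`); attribute `mode` records the rule applied. An empty
#'   set is allowed.
#' @export
call_degs <- function(deres, mode = c("strict", "relaxed"),
                      padj_cutoff = 0.1, p_cutoff = 0.005) {
  mode <- match.arg(mode)
  keep <- if (mode == "strict") {
    !is.na(deres$padj) & deres$padj < padj_cutoff
  } else {
    !is.na(deres$pvalue) & deres$pvalue < p_cutoff
  }
  out <- as.data.frame(deres)[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2FC > 0, "up", "down")
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "contrast") <- attr(deres, "contrast")
  out
}

#' Write a DE/DMR result table as TSV
#'
#' Fixed column order: feature, baseMean, log2FC, lfcSE, stat, pvalue, padj.
#'
#' @param deres A `de_result` data frame.
#' @param path Output path.
#' @param extra Optional data frame of extra columns (e.g. region
#'   coordinates) appended after the fixed columns, matched by `feature`.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(deres, path, extra = NULL) {
  cols <- c("feature", "baseMean", "log2FC", "lfcSE", "stat", "pvalue", "padj")
  out <- as.data.frame(deres)[, cols]
  if (!is.null(extra)) out <- cbind(out, extra[match(out$feature,
                                                     extra$feature),
                                              setdiff(names(extra), "feature"),
                                              drop = FALSE])
  write_tsv(out, path)
}
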