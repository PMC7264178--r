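test_that("size factors follow the median-of-ratios definition", {
  # identical columns are symmetric
  m <- matrix(rep(c(10, 50, 200), 3), ncol = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), c(1, 1, 1))
  # hand-computed 2x2 example
  m2 <- matrix(c(100, 400, 200, 800), nrow = 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(size_factors(m2)), c(sqrt(0.5), sqrt(2)),
               tolerance = 1e-9)
  # scale equivariance: tripling one column triples its factor relative to
  # every other sample (size factors are defined up to a shared constant,
  # which the per-feature geometric means re-anchor)
  set.seed(1)
  m3 <- matrix(rpois(200, 60) + 1, ncol = 4,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  s0 <- size_factors(m3)
  m3b <- m3; m3b[, 2] <- m3[, 2] * 3
  s1 <- size_factors(m3b)
  expect_equal(unname(s1[2] / s1[-2]), unname(3 * s0[2] / s0[-2]),
               tolerance = 1e-12)
  expect_equal(unname(s1[3] / s1[4]), unname(s0[3] / s0[4]),
               tolerance = 1e-12)
  # no all-positive feature -> instructive error
  m4 <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(size_factors(m4), "pseudocount|filter")
})

test_that("dispersion estimation applies the moment formula and the floor", {
  # mean 100, variance 600 -> alpha = 0.05; constructed from centered noise
  dev <- c(-30, 10, 20, -30, 30, 0)
  dev <- dev - mean(dev)
  x <- 100 + dev * sqrt(600 / var(dev))
  m <- matrix(rep(round(x), 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  d <- estimate_dispersions(m, sf = rep(1, 6), groups = rep("WT", 6))
  expect_equal(unname(d[1]), (var(m[1, ]) - mean(m[1, ])) / mean(m[1, ])^2,
               tolerance = 1e-12)
  expect_gt(d[1], 0.04)
  # variance <= mean -> floor
  m2 <- matrix(c(10, 10, 10, 10, 11, 9, 10, 10), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  d2 <- estimate_dispersions(m2, sf = rep(1, 4), groups = rep("WT", 4))
  expect_equal(unname(d2[1]), 1e-8)
  expect_error(estimate_dispersions(m[, 1, drop = FALSE], sf = 1,
                                    groups = "WT"), "2 samples")
})

test_that("dispersion estimates concentrate near zero for Poisson counts", {
  set.seed(5)
  n <- 300
  m <- matrix(rpois(n * 200, 100), nrow = n,
              dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:200)))
  d <- estimate_dispersions(m, sf = rep(1, 200), groups = rep("WT", 200))
  expect_gte(mean(d < 0.01), 0.95)
  expect_gt(mean(d == 1e-8), 0.3)  # the negative half of the noise floors
})

test_that("Wald test recovers a planted four-fold change", {
  # sampling-theory oracle: SE(log2FC) ~= sqrt(2 * (1/800 + 0.01) / 4) / ln2
  # = 0.108, so P(|log2FC - 2| <= 0.2) ~= P(|z| < 1.85) ~= 0.94; the test
  # asserts recovery above 0.9 plus unbiasedness of the mean estimate
  set.seed(99)
  ests <- c()
  hits <- replicate(60, {
    cfg <- sim_config(n_genes = 100, baseline_logmean = log(800),
                      baseline_logsd = 0.3, dispersion = 0.01,
                      frac_B_up = 0.2, frac_B_down = 0, frac_A_up = 0,
                      frac_A_down = 0, frac_opposite_overlap = 0,
                      frac_same_overlap = 0, frac_rescued = 0,
                      effect_logmean = log(2), effect_logsd = 0,
                      seed = sample.int(1e6, 1))
    sim <- simulate_rnaseq(cfg)
    # true depth factors as size factors: this isolates the Wald estimator
    # from the (separately tested) normalization step
    res <- nb_wald_test(sim$counts, c("B_KO", "WT"),
                        sf = sim$truth$library_sizes)
    up <- sim$truth$features$true_log2FC_B == 2
    ests <<- c(ests, res$log2FC[up])
    mean(res$log2FC[up] >= 1.8 & res$log2FC[up] <= 2.2)
  })
  expect_gte(mean(hits), 0.9)
  expect_lt(abs(mean(ests) - 2), 0.02)
})

test_that("identical counts across samples give a null Wald result", {
  m <- matrix(50, nrow = 3, ncol = 8,
              dimnames = list(paste0("g", 1:3),
                              paste0("s", 1:8)))
  cm <- toy_count_matrix(m, rep(c("WT", "B_KO"), each = 4))
  res <- nb_wald_test(cm, c("B_KO", "WT"), sf = setNames(rep(1, 8),
                                                         colnames(m)),
                      dispersions = rep(0.05, 3))
  expect_equal(res$log2FC, rep(0, 3), tolerance = 1e-8)
  expect_true(all(res$pvalue >= 0.99))
})

test_that("log2FC is antisymmetric under contrast reversal", {
  sim <- simulate_rnaseq(sim_config(n_genes = 150, seed = 31))
  sf <- size_factors(sim$counts)
  d <- estimate_dispersions(sim$counts, sf = sf)
  a <- nb_wald_test(sim$counts, c("B_KO", "WT"), sf = sf, dispersions = d)
  b <- nb_wald_test(sim$counts, c("WT", "B_KO"), sf = sf, dispersions = d)
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-7)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-7)
})

test_that("all-zero features are excluded and one-sided zeros flagged", {
  set.seed(8)
  m <- matrix(rpois(5 * 8, 40), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  m[1, ] <- 0                  # untested
  m[2, 1:4] <- 0               # non-convergent one-sided zero
  cm <- toy_count_matrix(m, rep(c("WT", "B_KO"), each = 4))
  res <- nb_wald_test(cm, c("B_KO", "WT"), sf = setNames(rep(1, 8),
                                                         colnames(m)),
                      dispersions = rep(0.05, 5))
  expect_false(res$tested[1])
  expect_true(is.na(res$pvalue[1]))
  expect_true(res$tested[2] && is.na(res$stat[2]))
  expect_true(all(!is.na(res$pvalue[3:5])))
  # BH ranking covers only features with a p value
  expect_equal(res$padj[3:5], bh_adjust(res$pvalue)[3:5])
})

test_that("BH adjustment equals the literal step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    a <- bh_adjust(p)
    expect_equal(a, bh_brute(p))
    expect_true(all(a <= 1))
    expect_true(all(diff(a[order(p)]) >= -1e-12))  # monotone in rank
  }
  # NA propagates and is excluded from ranking
  p <- c(0.01, NA, 0.04)
  a <- bh_adjust(p)
  expect_true(is.na(a[2]))
  expect_equal(a[c(1, 3)], bh_brute(c(0.01, 0.04)))
})

test_that("DEG calling applies the strict and relaxed screens", {
  res <- data.frame(feature = paste0("g", 1:5),
                    baseMean = 100, log2FC = c(1, -2, 0.5, 3, -1),
                    lfcSE = 1, stat = 1,
                    pvalue = c(0.0009, 0.004, 0.02, 0.5, 1),
                    padj = c(0.09, 0.3, 0.11, 0.9, 1),
                    tested = TRUE)
  strict <- call_degs(res, "strict")
  expect_identical(strict$feature, "g1")        # padj 0.09 in, 0.11 out
  relaxed <- call_degs(res, "relaxed")
  expect_identical(relaxed$feature, c("g1", "g2"))  # p<0.005 regardless of padj
  expect_identical(relaxed$direction, c("up", "down"))
  none <- call_degs(transform(res, pvalue = 1, padj = 1), "strict")
  expect_identical(nrow(none), 0L)
})

test_that("size factors and fold changes agree with an established NB pipeline", {
  suppressPackageStartupMessages(library(DESeq2))
  cfg <- sim_config(n_genes = 200, baseline_logmean = log(500),
                    dispersion = 0.02, frac_B_up = 0.2, frac_B_down = 0.1,
                    effect_logmean = log(2), effect_logsd = 0.2, seed = 23,
                    frac_rescued = 0)
  sim <- simulate_rnaseq(cfg)
  keep <- sim$counts$design$genotype %in% c("WT", "B_KO")
  cts <- sim$counts$counts[, keep]
  geno <- factor(sim$counts$design$genotype[keep], levels = c("WT", "B_KO"))
  dds <- DESeqDataSetFromMatrix(round(cts), S4Vectors::DataFrame(geno = geno),
                                ~geno)
  dds <- suppressMessages(DESeq(dds, quiet = TRUE))
  ours_sf <- size_factors(cts)
  expect_equal(unname(ours_sf), unname(sizeFactors(dds)), tolerance = 1e-4)
  ours <- nb_wald_test(sim$counts, c("B_KO", "WT"))
  ref <- results(dds, contrast = c("geno", "B_KO", "WT"))
  ok <- !is.na(ours$log2FC) & !is.na(ref$log2FoldChange)
  expect_gt(cor(ours$log2FC[ok], ref$log2FoldChange[ok]), 0.999)
  expect_lt(median(abs(ours$log2FC[ok] - ref$log2FoldChange[ok])), 0.05)
})
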