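fake_de <- function(features, fc, p = NULL, contrast = c("X", "Y")) {
  p <- if (is.null(p)) runif(length(features)) else p
  r <- data.frame(feature = features, baseMean = 100, log2FC = fc,
                  lfcSE = 0.1, stat = fc / 0.1, pvalue = p,
                  padj = bh_adjust(p), tested = TRUE,
                  stringsAsFactors = FALSE)
  attr(r, "contrast") <- contrast
  class(r) <- c("de_result", "data.frame")
  r
}

fake_fc_table <- function(features, fcA, fcB, fcDM, pA = NULL, pB = NULL,
                          pDM = NULL) {
  build_fold_change_table(list(
    A_vs_WT = fake_de(features, fcA, pA),
    B_vs_WT = fake_de(features, fcB, pB),
    DM_vs_WT = fake_de(features, fcDM, pDM),
    DM_vs_A = fake_de(features, fcDM - fcA),
    DM_vs_B = fake_de(features, fcDM - fcB)))
}

test_that("fold-change table joins five contrasts and checks the universe", {
  set.seed(2)
  fc <- fake_fc_table(paste0("g", 1:4), fcA = c(-1, 0, 2, 1),
                      fcB = c(0.5, 0, -1, 2), fcDM = c(-0.2, 0, 0.5, 3))
  # contrast additivity: fc(DM vs A) = fc(DM vs WT) - fc(A vs WT)
  expect_equal(fc$log2FC_DM_vs_A, fc$log2FC_DM_vs_WT - fc$log2FC_A_vs_WT,
               tolerance = 1e-6)
  expect_equal(fc$log2FC_DM_vs_A[1], 0.8)
  expect_true(all(fc$complete))
  # a missing contrast is named
  bad <- list(A_vs_WT = fake_de("g1", 0))
  expect_error(build_fold_change_table(bad), "B_vs_WT")
  # mismatched universes are reported
  good <- lapply(c("A_vs_WT", "B_vs_WT", "DM_vs_WT", "DM_vs_A", "DM_vs_B"),
                 function(k) fake_de(paste0("g", 1:3), c(0, 1, 2)))
  names(good) <- c("A_vs_WT", "B_vs_WT", "DM_vs_WT", "DM_vs_A", "DM_vs_B")
  good$DM_vs_B <- fake_de(paste0("g", 2:4), c(1, 2, 3))
  expect_error(build_fold_change_table(good), "g1|g4")
})

test_that("direction classification follows the sign-and-significance rule", {
  set.seed(3)
  fc <- fake_fc_table(paste0("g", 1:5),
                      fcA = c(2, 2, 2, 2, 0.5),
                      fcB = c(-1, 1.5, -1, 0, 1),
                      fcDM = c(0, 0, 0, 0, 0),
                      pB = c(0.01, 0.001, 0.5, 0.001, 0.2))
  cl <- classify_direction(paste0("g", 1:5), fc, "A")
  expect_identical(cl$class,
                   c("opposite",   # signs differ, p_B < 0.05
                     "same",       # signs agree, p_B < 0.05
                     "unchanged",  # p_B = 0.5 regardless of sign
                     "unchanged",  # fc exactly 0 despite small p
                     "unchanged")) # p_B = 0.2 above nominal
  # brute-force re-application of the rule on a random toy table
  set.seed(4)
  n <- 20
  fc2 <- fake_fc_table(sprintf("t%02d", 1:n), fcA = rnorm(n),
                       fcB = round(rnorm(n), 1), fcDM = rnorm(n),
                       pB = runif(n))
  cl2 <- classify_direction(fc2$feature, fc2, "A", nominal_p = 0.05)
  brute <- mapply(function(a, b, p) {
    if (is.na(p) || p >= 0.05 || b == 0) "unchanged"
    else if (sign(a) * sign(b) < 0) "opposite" else "same"
  }, fc2$log2FC_A_vs_WT, fc2$log2FC_B_vs_WT, fc2$pvalue_B_vs_WT)
  expect_identical(cl2$class, unname(brute))
})

test_that("exact signed-rank p equals full enumeration", {
  expect_equal(signed_rank_test(1:5)$p.value, 0.0625)  # 2/2^5
  set.seed(6)
  for (i in 1:60) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), sample(0:1, 1))  # rounding provokes ties/zeros
    if (all(d == 0)) next
    got <- signed_rank_test(d)
    expect_equal(got$p.value, signed_rank_enumerate(d),
                 info = paste(d, collapse = ","))
  }
  # agreement with the classical implementation when no ties/zeros
  set.seed(7)
  d <- rnorm(12)
  expect_equal(signed_rank_test(d)$p.value,
               wilcox.test(d, exact = TRUE)$p.value)
  # degenerate all-zero input
  z <- signed_rank_test(rep(0, 4))
  expect_true(z$degenerate)
  expect_equal(z$p.value, 1)
  expect_equal(z$statistic, 0)
  # large-n normal approximation matches the classical implementation
  set.seed(8)
  d2 <- rnorm(80, 0.2)
  expect_equal(signed_rank_test(d2)$p.value,
               wilcox.test(d2, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("group rescue test detects planted attenuation and degenerates cleanly", {
  set.seed(9)
  fc_single <- rlnorm(100, 0, 0.4)           # 100 up-regulated features
  fc_dm <- 0.5 * fc_single + rnorm(100, 0, 0.05)
  g <- group_rescue_test(fc_single, fc_dm)
  expect_lt(g$p.value, 1e-3)
  expect_lt(g$median_dm, g$median_single)
  expect_identical(g$direction, "attenuated")
  # identical vectors -> p = 1
  same <- group_rescue_test(fc_single, fc_single)
  expect_equal(same$p.value, 1)
  expect_identical(same$direction, "none")
  expect_error(group_rescue_test(1:3, 1:4), "equal length")
})

test_that("slope tests match their closed forms", {
  # y = x exactly: slope 1, statistic 0, p 1
  x <- c(0.5, 1, 2, 3)
  for (m in c("ols_origin", "sma_origin")) {
    st <- slope_test(x, x, method = m)
    expect_equal(st$slope, 1)
    expect_equal(st$statistic, 0)
    expect_equal(st$p.value, 1)
  }
  # perfect halving: OLS slope exactly 0.5, p -> 0
  st <- slope_test(c(1, 2, 4), c(0.5, 1, 2))
  expect_equal(st$slope, 0.5)
  expect_equal(st$p.value, 0)
  # SMA closed form sqrt(sum(y^2)/sum(x^2)); the origin point adds nothing
  st2 <- slope_test(c(1, 2, 0), c(1, 4, 0), method = "sma_origin")
  expect_equal(st2$slope, sqrt(17 / 5), tolerance = 1e-9)
  # equivariance under joint positive rescaling
  set.seed(10)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30, 0, 0.1)
  for (m in c("ols_origin", "sma_origin")) {
    a <- slope_test(x, y, method = m)
    b <- slope_test(7.3 * x, 7.3 * y, method = m)
    expect_equal(a$slope, b$slope, tolerance = 1e-12)
    expect_equal(a$p.value, b$p.value, tolerance = 1e-9)
  }
  # CI contains the slope; errors on degenerate input
  expect_true(a$conf_int[1] <= a$slope && a$slope <= a$conf_int[2])
  expect_error(slope_test(c(0, 0, 0), c(1, 2, 3)), "all x are zero")
  expect_error(slope_test(1:2, 1:2), "3 complete pairs")
})

test_that("slope recovery hits planted attenuation for both methods", {
  set.seed(12)
  for (a in c(0.5, 0.9)) {
    ok_ols <- ok_sma <- logical(30)
    for (i in 1:30) {
      x <- sample(c(-1, 1), 300, TRUE) * rlnorm(300, 0, 0.5)
      y <- a * x + rnorm(300, 0, 0.08)
      ok_ols[i] <- abs(slope_test(x, y)$slope - a) <= 0.05
      ok_sma[i] <- abs(slope_test(x, y, method = "sma_origin")$slope - a) <=
        0.05
    }
    expect_gte(mean(ok_ols), 0.9)
    expect_gte(mean(ok_sma), 0.9)
  }
})

test_that("rescue drivers equal the literal threshold filter", {
  set.seed(13)
  n <- 50
  fcDM_A <- rnorm(n, 0, 2)   # log2FC(DM vs A)
  fcDM_WT <- rnorm(n, 0, 1)
  fc <- fake_fc_table(sprintf("d%02d", 1:n), fcA = fcDM_WT - fcDM_A,
                      fcB = rnorm(n), fcDM = fcDM_WT)
  drv <- call_rescue_drivers(fc, "A", domain = "rna")
  brute <- abs(fc$log2FC_DM_vs_A) > 2 & abs(fc$log2FC_DM_vs_WT) < 0.7
  expect_identical(drv$driver, brute)
  # paper-style example: strong move off DM, DM near WT -> driver
  fc2 <- fake_fc_table("x", fcA = -2.2, fcB = 0, fcDM = 0.3)
  expect_true(call_rescue_drivers(fc2, "A")$driver)
  # boundary is strict: exactly 2.0 is not a driver
  fc3 <- fake_fc_table("x", fcA = -1.7, fcB = 0, fcDM = 0.3)
  expect_equal(abs(fc3$log2FC_DM_vs_A), 2)
  expect_false(call_rescue_drivers(fc3, "A")$driver)
  # chip_integration mode lowers the first threshold to 1
  fc4 <- fake_fc_table("x", fcA = -1.4, fcB = 0, fcDM = 0.1)
  expect_false(call_rescue_drivers(fc4, "A", domain = "rna")$driver)
  expect_true(call_rescue_drivers(fc4, "A", domain = "chip_integration")$driver)
})

test_that("DMR rescue summary focuses, stratifies, and reports quartiles", {
  set.seed(14)
  n <- 60
  fcA <- c(-rlnorm(40, 0, 0.3), rlnorm(20, 0, 0.3))   # 40 hypo, 20 hyper
  fcB <- -fcA + rnorm(n, 0, 0.05)                      # opposite regulation
  fcDM <- 0.5 * (fcA + fcB)
  fc <- fake_fc_table(sprintf("r%02d", 1:n), fcA, fcB, fcDM,
                      pB = rep(0.001, n))
  summ <- dmr_rescue_summary(fc$feature, fc, "A")
  # focus filter keeps only hypomethylated features for the writer mutant
  expect_equal(sum(summ$n), 40L)
  expect_true(all(summ$quartiles$class %in% c("opposite", "same")))
  # quartiles equal sort-based percentiles
  opp_rows <- summ$quartiles[summ$quartiles$class == "opposite" &
                               summ$quartiles$contrast == "A_vs_WT", ]
  cls <- classify_direction(fc$feature[fcA < 0], fc, "A")
  vals <- fc$log2FC_A_vs_WT[match(cls$feature[cls$class == "opposite"],
                                  fc$feature)]
  expect_equal(opp_rows$median, unname(quantile(vals, 0.5)))
  expect_equal(opp_rows$q25, unname(quantile(vals, 0.25)))
  # empty focus set exits cleanly
  fc_up <- fake_fc_table(sprintf("u%02d", 1:5), rlnorm(5), rnorm(5),
                         rnorm(5))
  empty <- dmr_rescue_summary(fc_up$feature, fc_up, "A")
  expect_equal(sum(empty$n), 0L)
  expect_length(empty$tests, 0)
})
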