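test_that("cpm matches its definition including the zero case", {
  m <- toy_counts(rbind(c(10, 100), c(0, 0)))
  out <- cpm(m, lib_sizes = c(t1 = 1e6, k1 = 2e6))
  expect_equal(out$t1, c(10, 0))
  expect_equal(out$k1, c(50, 0))
  expect_error(cpm(m, lib_sizes = c(t1 = 0, k1 = 1)), "library size")

  lg <- cpm(m, log2 = TRUE, lib_sizes = c(t1 = 1e6, k1 = 2e6))
  expect_equal(lg$t1[1], log2(10 + 0.5))        # prior 0.5 on a 1e6 library
  expect_equal(lg$k1[2], log2(0 + 0.5 / 2))     # prior scales with library
})

test_that("TMM factors are 1 for identical or purely depth-shifted libraries", {
  m <- toy_counts(cbind(a = c(100, 50, 10, 3), b = c(100, 50, 10, 3)),
                  samples = c("t1", "k1"))
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  m2 <- toy_counts(cbind(c(100, 50, 10, 4), c(200, 100, 20, 8)),
                   samples = c("t1", "k1"))
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
  expect_error(tmm_factors(toy_counts(cbind(c(1, 2), c(0, 0)))), "all-zero")
})

test_that("TMM recovers the analytic factor under partial inflation", {
  # library B: 20% of features 4-fold inflated, rest identical to A.
  # Non-inflated features have M = log2(0.00625/0.01); after trimming the
  # inflated block the factor is 2^M, then geometric-mean normalised.
  counts_a <- rep(100, 100)
  counts_b <- c(rep(400, 20), rep(100, 80))
  m <- toy_counts(cbind(counts_a, counts_b), samples = c("t1", "k1"))
  f <- tmm_factors(m)
  expected_b <- sqrt((100 / 16000) / (100 / 10000))
  expect_equal(unname(f["k1"]), expected_b, tolerance = 0.05)
  expect_equal(unname(f["t1"]), 1 / expected_b, tolerance = 0.05)
  expect_equal(prod(f), 1, tolerance = 1e-12)  # geometric mean 1
})

test_that("bh_adjust reproduces the step-up procedure", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
})

test_that("de_test returns zero log-fold-change for a flat feature", {
  # every feature constant across samples, so libraries are exactly equal
  set.seed(41)
  cnt <- matrix(rep(sample(5:200, 100), 6), 100)
  m <- toy_counts(cnt, samples = c(paste0("t", 1:3), paste0("k", 1:3)))
  res <- de_test(m, toy_groups(m))
  expect_true(all(abs(res$log2_fc) < 1e-8))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$fdr >= res$p_value - 1e-12))
  expect_equal(res$direction, ifelse(res$log2_fc >= 0, "up", "down"))
})

test_that("de_test input contracts are enforced", {
  m <- toy_counts(matrix(1:8, 2), samples = c("t1", "t2", "k1", "k2"))
  g <- toy_groups(m)
  expect_error(de_test(m, setNames(rep("treated", 4), names(g))), "both")
  expect_error(de_test(m, c(g[1], g[3:4])), "without group")
  m3 <- toy_counts(matrix(1:6, 2), samples = c("t1", "k1", "k2"))
  expect_error(de_test(m3, toy_groups(m3)), "two replicates")
})

test_that("nb_exact detects a planted 8-fold change at moderate depth", {
  # 200 planted features act as 200 replicate draws of the detection task
  set.seed(51)
  n_null <- 1800; n_fc <- 200
  mu <- c(rep(20, n_null), rep(20, n_fc))
  cnt <- sapply(1:6, function(j) {
    m <- mu
    if (j <= 3) m[n_null + seq_len(n_fc)] <- m[n_null + seq_len(n_fc)] * 8
    rnbinom(length(m), mu = m, size = 1 / 0.05)
  })
  tbl <- toy_counts(cnt, samples = c(paste0("t", 1:3), paste0("k", 1:3)))
  res <- de_test(tbl, toy_groups(tbl))
  power <- mean(res$p_value[n_null + seq_len(n_fc)] < 0.05)
  expect_gte(power, 0.95)
  # and the fold-change estimate centres near 3 on the log2 scale
  expect_equal(median(res$log2_fc[n_null + seq_len(n_fc)]), 3, tolerance = 0.3)
})

test_that("threshold presets apply strict inequalities", {
  res <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    log2_fc = c(log2(2.5), log2(2), log2(3), -log2(3)),
    p_value = c(0.04, 0.04, 0.2, 0.001),
    fdr = c(0.04, 0.2, 0.06, 0.01),
    mean_cpm = 10, direction = c("up", "up", "up", "down"))
  expect_equal(apply_thresholds(res, circ_de_thresholds())$feature_id,
               c("a", "d"))  # b: FC not > 2; c: p not < 0.05
  expect_equal(apply_thresholds(res, mrna_de_thresholds())$feature_id,
               c("a", "d"))  # c: fdr 0.06 not < 0.05
  expect_error(de_thresholds(min_linear_fc = 1), "> 1")
})

test_that("loosening any threshold never removes a called feature", {
  set.seed(61)
  res <- tibble::tibble(
    feature_id = paste0("f", 1:200),
    log2_fc = rnorm(200, 0, 2),
    p_value = runif(200), fdr = NA, mean_cpm = 10, direction = "up")
  res$fdr <- bh_adjust(res$p_value)
  res$direction <- ifelse(res$log2_fc >= 0, "up", "down")
  tight <- apply_thresholds(res, de_thresholds(max_p = 0.02, max_fdr = 0.1,
                                               min_linear_fc = 2))
  for (loose in list(de_thresholds(max_p = 0.05, max_fdr = 0.1, min_linear_fc = 2),
                     de_thresholds(max_p = 0.02, max_fdr = 0.3, min_linear_fc = 2),
                     de_thresholds(max_p = 0.02, max_fdr = 0.1, min_linear_fc = 1.2),
                     de_thresholds(max_p = NULL, max_fdr = NULL, min_linear_fc = 2))) {
    expect_true(all(tight$feature_id %in%
                      apply_thresholds(res, loose)$feature_id))
  }
})

test_that("nb_exact broadly agrees with edgeR's exact test on a small matrix", {
  skip_if_not_installed("edgeR")
  set.seed(71)
  mu <- rlnorm(400, log(80), 1)
  cnt <- sapply(1:6, function(j) rnbinom(400, mu = mu, size = 8))
  cnt[1:20, 1:3] <- cnt[1:20, 1:3] * 6
  tbl <- toy_counts(cnt, samples = c(paste0("t", 1:3), paste0("k", 1:3)))
  mine <- de_test(tbl, toy_groups(tbl))
  dge <- edgeR::DGEList(counts_to_matrix_for_test(tbl),
                        group = factor(c(1, 1, 1, 2, 2, 2), levels = c(2, 1)))
  dge <- edgeR::calcNormFactors(dge)
  dge <- edgeR::estimateCommonDisp(dge)
  et <- edgeR::exactTest(dge)$table
  # rank agreement: the same features rise to the top of both analyses
  expect_gt(cor(-log10(mine$p_value), -log10(et$PValue), method = "spearman"),
            0.9)
  expect_gt(cor(mine$log2_fc, et$logFC), 0.98)
})
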