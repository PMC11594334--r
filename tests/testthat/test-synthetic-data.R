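test_that("simulation is byte-reproducible from its seed", {
  cfg <- sim_config(seed = 99, n_circ = 40, n_mrna = 80, n_mirna = 12,
                    n_planted_axes = 4, axes_per_circ = 2)
  s1 <- simulate_cerna(cfg)
  s2 <- simulate_cerna(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_cerna(sim_config(seed = 100, n_circ = 40, n_mrna = 80,
                                  n_mirna = 12, n_planted_axes = 4,
                                  axes_per_circ = 2))
  expect_false(identical(s1$circ_counts, s3$circ_counts))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_mirna = 4, n_planted_axes = 40, axes_per_circ = 2),
               "infeasible")
  expect_error(sim_config(planted_fc = 1), "> 1")
  expect_error(sim_config(dispersion = 0), "> 0")
  expect_error(sim_config(frac_de = 1.5), "frac_de")
})

test_that("planted axes are discoverable: sites, rows and expression", {
  sim <- simulate_cerna(sim_config(seed = 7, n_circ = 60, n_mrna = 150,
                                   n_mirna = 15, n_planted_axes = 8,
                                   axes_per_circ = 4))
  ax <- sim$truth$planted_axes
  expect_equal(nrow(ax), 8)
  expect_equal(length(unique(ax$circ_id)), 2)   # hub-module structure
  expect_true(all(ax$mirna_id %in% expressed_mirnas(sim$mirna_counts)))
  expect_true(all(paste(ax$mirna_id, ax$gene_id) %in%
                    paste(sim$target_table$mirna_id, sim$target_table$gene_id)))
  for (k in seq_len(nrow(ax))) {
    cs <- sim$circ_seqs$seq[sim$circ_seqs$id == ax$circ_id[k]]
    ms <- sim$mirna_seqs$seq[sim$mirna_seqs$id == ax$mirna_id[k]]
    sites <- scan_mre(cs, ms)
    expect_true(any(sites$site_type %in% c("8mer", "7mer-m8", "7mer-A1")))
  }
  # truth projects onto the planted pairs
  expect_identical(sim$truth$planted_pairs,
                   ax[, c("circ_id", "gene_id")])
})

test_that("simulated counts match negative-binomial moments", {
  # large replicate number, fixed library factors, no DE: the marginal
  # variance of each background feature must be mu + phi * mu^2
  sim <- simulate_cerna(sim_config(seed = 17, n_per_group = 5000, n_circ = 20,
                                   n_mrna = 2, n_mirna = 2, frac_de = 0,
                                   n_planted_axes = 0, dispersion = 0.15,
                                   libsize_sd = 0, frac_mirna_silent = 0))
  m <- counts_to_matrix_for_test(sim$circ_counts)
  mhat <- rowMeans(m)
  vhat <- apply(m, 1, var)
  expected <- mhat + 0.15 * mhat^2
  expect_true(all(abs(vhat / expected - 1) < 0.15))
})

test_that("a null simulation yields calibrated DE false-positive rates", {
  sim <- simulate_cerna(sim_config(seed = 27, n_circ = 1500, n_mrna = 2,
                                   n_mirna = 2, frac_de = 0,
                                   n_planted_axes = 0))
  de <- de_test(sim$circ_counts, sim$groups)
  expect_gt(mean(de$p_value < 0.05), 0.03)
  expect_lt(mean(de$p_value < 0.05), 0.07)
  called <- apply_thresholds(de, circ_de_thresholds())
  # the fold-change gate removes most false positives left by p < 0.05
  expect_lt(nrow(called), 0.03 * nrow(de))
  expect_lt(nrow(called), 0.5 * sum(de$p_value < 0.05))
})

test_that("planted-pair correlations exceed 0.90 at calibrated frequency", {
  # ~200 planted pairs drawn across independent low-noise simulations
  hits <- 0; total <- 0
  for (s in 1:6) {
    sim <- simulate_cerna(low_noise_config(seed = 300 + s))
    lc <- cpm(sim$circ_counts, log2 = TRUE)
    lm <- cpm(sim$mrna_counts, log2 = TRUE)
    cm <- counts_to_matrix_for_test(lc)
    mm <- counts_to_matrix_for_test(lm)
    ax <- sim$truth$planted_axes
    r <- vapply(seq_len(nrow(ax)), function(k)
      cor(cm[ax$circ_id[k], ], mm[ax$gene_id[k], ]), numeric(1))
    hits <- hits + sum(r > 0.90)
    total <- total + length(r)
  }
  expect_gte(total, 200)
  expect_gte(hits / total, 0.80)
})

test_that("recovery scoring handles exact, empty and diluted predictions", {
  truth_ax <- random_axes(10)
  truth_ax <- dplyr::distinct(truth_ax)
  truth <- structure(list(planted_axes = truth_ax), class = "cerna_truth")
  exact <- score_recovery(truth, truth_ax)
  expect_equal(as.numeric(exact[, c("precision", "recall", "f1")]), c(1, 1, 1))

  none <- score_recovery(truth, truth_ax[0, ])
  expect_equal(as.numeric(none[, c("precision", "recall")]), c(0, 0))
  expect_true(none$empty_prediction)

  n <- nrow(truth_ax)
  half <- truth_ax[seq_len(floor(n / 2)), ]
  decoys <- tibble::tibble(circ_id = paste0("zc", seq_len(nrow(half))),
                           mirna_id = "zu", gene_id = "zg")
  mixed <- score_recovery(truth, dplyr::bind_rows(half, decoys))
  expect_equal(mixed$precision, 0.5)
  expect_equal(mixed$recall, floor(n / 2) / n)
})

test_that("written simulations reload through the pipeline readers", {
  sim <- simulate_cerna(sim_config(seed = 37, n_circ = 30, n_mrna = 40,
                                   n_mirna = 10, n_planted_axes = 3,
                                   axes_per_circ = 3))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_count_matrix(file.path(dir, "circ_counts.tsv"),
                            readr::read_tsv(file.path(dir, "groups.tsv"),
                                            show_col_types = FALSE))
  expect_equal(as.data.frame(back), as.data.frame(sim$circ_counts))
  expect_equal(read_fasta(file.path(dir, "circ_seqs.fa")),
               sim$circ_seqs)
  tt <- read_target_table(file.path(dir, "target_table.tsv"))
  expect_setequal(paste(tt$mirna_id, tt$gene_id),
                  paste(sim$target_table$mirna_id, sim$target_table$gene_id))
  expect_true(file.exists(file.path(dir, "truth", "planted_axes.tsv")))
})
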