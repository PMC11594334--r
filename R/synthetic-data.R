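#' Simulation configuration
#'
#' Parameters of the synthetic ceRNA study generator. The default design
#' mirrors a two-group cell-culture experiment with three treated and three
#' control replicates, negative-binomial counts, and a planted tripartite
#' sponge structure:
#'
#' * counts for feature i, sample j are
#'   `NB(mean = mu_i * l_j * fc_i^[treated] * exp(beta * z_j), size = 1/phi)`
#'   where `l_j` is a log-normal library factor, `fc_i` the planted linear
#'   fold change for DE features, and `z_j` a per-sample latent factor with
#'   standard deviation `latent_sd` scaled by the loading `beta =
#'   latent_loading`.
#' * the planted truth is organised as hub modules, mirroring the hub-
#'   centred topology of real ceRNA networks: each planted circRNA sponges
#'   one miRNA whose targets are the module's `axes_per_circ` genes, giving
#'   `n_planted_axes` axes in total. The circRNA and the genes of a module
#'   share their latent factor and respond to treatment with a common sign
#'   (coordinated regulation); every other DE feature draws an independent
#'   latent factor of the same strength, so all screened features have
#'   comparable marginal variance and modules differ only through sharing.
#'   Non-DE background features are plain negative binomial, which keeps
#'   the common-dispersion estimate (and hence null calibration) clean.
#' * each planted axis (circ, miR, gene) is realised by an 8mer seed site
#'   for the module miRNA embedded at a random circular position of the
#'   circRNA sequence, a (miR, gene) row in the target table, and miRNA
#'   counts that pass the expression rule; all three are asserted after
#'   generation.
#' * decoy (miR, gene) rows are added to the target table at
#'   `decoy_interaction_rate` (fraction of all possible miRNA x gene
#'   combinations); random sequence provides natural decoy seed sites.
#' * the disease-annotation list marks each miRNA with probability
#'   `assoc_baseline`, raised to odds `assoc_enrichment_odds` times baseline
#'   odds for sponged (planted-axis) miRNAs.
#'
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param n_per_group Replicates per group (3, as in a 3-vs-3 design).
#' @param n_circ,n_mrna,n_mirna Feature counts per matrix.
#' @param frac_de Fraction of circRNAs/mRNAs with a planted fold change
#'   (planted-pair members are always DE and count toward this fraction).
#' @param planted_fc Linear fold change of DE features (> 1).
#' @param dispersion NB dispersion phi (variance `mu + phi * mu^2`).
#' @param n_planted_axes Number of planted circ-miR-gene triples.
#' @param axes_per_circ Module size: target genes per planted hub circRNA.
#' @param latent_sd Standard deviation of the latent factor (natural-log scale).
#' @param latent_loading Loading beta multiplying the latent factor.
#' @param decoy_interaction_rate Decoy density of the target table.
#' @param assoc_enrichment_odds Odds ratio for disease annotation of sponged
#'   vs non-sponged miRNAs.
#' @param assoc_baseline Baseline disease-annotation probability.
#' @param libsize_sd Log-normal sd of library-size factors.
#' @param frac_mirna_silent Fraction of miRNAs simulated as unexpressed.
#' @param circ_len_range Length range (nt) of circRNA sequences.
#' @param mirna_len Mature miRNA length (nt).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_per_group = 3L, n_circ = 300L,
                       n_mrna = 1000L, n_mirna = 30L, frac_de = 0.02,
                       planted_fc = 4, dispersion = 0.1,
                       n_planted_axes = 36L, axes_per_circ = 9L,
                       latent_sd = 0.4,
                       latent_loading = 1, decoy_interaction_rate = 0.005,
                       assoc_enrichment_odds = 8, assoc_baseline = 0.2,
                       libsize_sd = 0.2, frac_mirna_silent = 0.25,
                       circ_len_range = c(200L, 400L), mirna_len = 22L) {
  cfg <- list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
              n_circ = as.integer(n_circ), n_mrna = as.integer(n_mrna),
              n_mirna = as.integer(n_mirna), frac_de = frac_de,
              planted_fc = planted_fc, dispersion = dispersion,
              n_planted_axes = as.integer(n_planted_axes),
              axes_per_circ = as.integer(axes_per_circ),
              latent_sd = latent_sd, latent_loading = latent_loading,
              decoy_interaction_rate = decoy_interaction_rate,
              assoc_enrichment_odds = assoc_enrichment_odds,
              assoc_baseline = assoc_baseline, libsize_sd = libsize_sd,
              frac_mirna_silent = frac_mirna_silent,
              circ_len_range = as.integer(circ_len_range),
              mirna_len = as.integer(mirna_len))
  with(cfg, {
    if (n_per_group < 2) stop_spongenet("need at least 2 replicates per group")
    if (planted_fc <= 1) stop_spongenet("`planted_fc` must be > 1")
    if (dispersion <= 0) stop_spongenet("`dispersion` must be > 0")
    if (frac_de < 0 || frac_de > 1) stop_spongenet("`frac_de` must be in [0, 1]")
    if (decoy_interaction_rate < 0 || decoy_interaction_rate > 1) {
      stop_spongenet("`decoy_interaction_rate` must be in [0, 1]")
    }
  })
  n_expressed_mir <- round(cfg$n_mirna * (1 - cfg$frac_mirna_silent))
  n_modules <- ceiling(cfg$n_planted_axes / max(1L, cfg$axes_per_circ))
  if (cfg$n_planted_axes > cfg$n_mrna ||
      n_modules > min(cfg$n_circ, n_expressed_mir)) {
    stop_spongenet("infeasible config: more planted axes than available circRNA/mRNA/expressed-miRNA triples")
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param ... Overrides passed on to [sim_config()].
#' @details `low_noise_config()` is the calibration preset used for
#'   end-to-end recovery checks: dispersion 0.05, fold change 8, latent
#'   standard deviation 0.6.
#' @export
low_noise_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, dispersion = 0.05, planted_fc = 8, latent_sd = 0.6, ...)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# overwrite len characters of a circular string starting at 0-based pos
plant_circular <- function(seq, pos, insert) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  ins <- strsplit(insert, "")[[1]]
  idx <- ((pos + seq_along(ins) - 1) %% L) + 1
  ch[idx] <- ins
  paste(ch, collapse = "")
}

# The 8mer target window for a miRNA, 5'->3' on the target:
# [WC match to position 8][revcomp of seed 2-7][A opposite position 1]
mre_8mer_window <- function(mirna_seq) {
  paste0(chartr("ACGU", "UGCA", substr(mirna_seq, 8, 8)),
         revcomp_rna(substr(mirna_seq, 2, 7)), "A")
}

#' Simulate a complete synthetic ceRNA study
#'
#' Generates every input the pipeline consumes — circRNA/mRNA/miRNA count
#' matrices, circRNA and miRNA sequences, a TargetScan-like target table and
#' a disease-annotation miRNA list — together with the planted ground truth.
#' See [sim_config()] for the generative model. Byte-identical outputs for a
#' given config.
#'
#' @param config A [sim_config()].
#' @return A list of class `cerna_sim`: `circ_counts`, `mrna_counts`,
#'   `mirna_counts` (count tibbles), `groups` (named vector), `circ_seqs`,
#'   `mirna_seqs` (`id`/`seq` tibbles), `target_table`, `assoc_mirnas`,
#'   and `truth` (class `cerna_truth`: `de_circ`, `de_mrna`,
#'   `planted_pairs`, `planted_axes`, `expressed_mirnas`, `config`).
#' @export
simulate_cerna <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_per_group
  samples <- c(paste0("treated_", seq_len(n)), paste0("control_", seq_len(n)))
  groups <- setNames(rep(c("treated", "control"), each = n), samples)
  trt <- groups == "treated"
  K <- cf$n_planted_axes

  circ_ids <- format_circ_id(
    paste0("chr", sample(c(1:22, "X"), cf$n_circ, replace = TRUE)),
    st <- sort(sample(1e4:2e8, cf$n_circ)),
    st + sample(200:50000, cf$n_circ, replace = TRUE))
  gene_ids <- sprintf("GENE%04d", seq_len(cf$n_mrna))
  mir_ids <- sprintf("miR-%d-5p", sample(1000:9999, cf$n_mirna))

  silent_mir <- sample(cf$n_mirna, round(cf$n_mirna * cf$frac_mirna_silent))
  expressed_idx <- setdiff(seq_len(cf$n_mirna), silent_mir)

  # hub-module structure: each planted circRNA sponges one miRNA whose
  # targets are the module's genes; axis k belongs to module mod_of[k]
  n_mod <- ceiling(K / max(1L, cf$axes_per_circ))
  mod_of <- rep(seq_len(n_mod), each = cf$axes_per_circ)[seq_len(K)]
  mod_circ <- sample(cf$n_circ, n_mod)
  planted_gene <- sample(cf$n_mrna, K)
  mod_mir <- sample(expressed_idx, n_mod)
  planted_circ <- mod_circ[mod_of]
  planted_mir <- mod_mir[mod_of]

  # DE assignment: planted members always DE; module members share the sign
  pick_de <- function(n_feat, planted) {
    n_de <- max(length(planted), round(cf$frac_de * n_feat))
    extra <- sample(setdiff(seq_len(n_feat), planted),
                    max(0, n_de - length(planted)))
    c(planted, extra)
  }
  de_circ_idx <- pick_de(cf$n_circ, mod_circ)
  de_gene_idx <- pick_de(cf$n_mrna, planted_gene)
  mod_sign <- sample(c(1, -1), n_mod, replace = TRUE)
  sign_circ <- setNames(rep(0, cf$n_circ), circ_ids)
  sign_gene <- setNames(rep(0, cf$n_mrna), gene_ids)
  sign_circ[de_circ_idx] <- sample(c(1, -1), length(de_circ_idx), replace = TRUE)
  sign_gene[de_gene_idx] <- sample(c(1, -1), length(de_gene_idx), replace = TRUE)
  sign_circ[mod_circ] <- mod_sign
  sign_gene[planted_gene] <- mod_sign[mod_of]

  # baseline means (counts); planted members kept well-expressed so the
  # junction filter / correlation screen see them
  mu_circ <- rlnorm(cf$n_circ, log(50), 1)
  mu_circ[mod_circ] <- rlnorm(n_mod, log(300), 0.3)
  mu_gene <- rlnorm(cf$n_mrna, log(300), 1)
  mu_gene[planted_gene] <- rlnorm(K, log(500), 0.3)
  mu_mir <- rlnorm(cf$n_mirna, log(200), 0.7)
  mu_mir[silent_mir] <- 0.05

  # latent structure of stimulus-responsive (DE) features: a per-module
  # factor z_mj is shared by a planted circRNA and its module genes (their
  # private co-regulation); every other DE feature draws an independent
  # factor of the same strength, so all screened features have comparable
  # marginal variance. Non-DE background features are plain NB.
  z_module <- matrix(rnorm(n_mod * 2 * n, 0, cf$latent_sd), n_mod)
  latent_for <- function(n_feat, de_rows, planted_rows, mod_idx) {
    z <- matrix(0, n_feat, 2 * n)
    z[de_rows, ] <- rnorm(length(de_rows) * 2 * n, 0, cf$latent_sd)
    z[planted_rows, ] <- z_module[mod_idx, , drop = FALSE]
    z
  }
  z_circ <- latent_for(cf$n_circ, de_circ_idx, mod_circ, seq_len(n_mod))
  z_gene <- latent_for(cf$n_mrna, de_gene_idx, planted_gene, mod_of)

  nb_matrix <- function(mu, sign, z, ids) {
    l <- rlnorm(2 * n, 0, cf$libsize_sd)
    fc <- cf$planted_fc^sign
    mean_m <- outer(mu, l) * exp(cf$latent_loading * z)
    mean_m[, trt] <- mean_m[, trt] * fc
    cnt <- matrix(rnbinom(length(mean_m), mu = mean_m, size = 1 / cf$dispersion),
                  nrow = length(mu))
    out <- as_tibble(as.data.frame(cnt))
    names(out) <- samples
    dplyr::bind_cols(tibble(feature_id = ids), out)
  }
  circ_counts <- nb_matrix(mu_circ, sign_circ, z_circ, circ_ids)
  mrna_counts <- nb_matrix(mu_gene, sign_gene, z_gene, gene_ids)
  mirna_counts <- nb_matrix(mu_mir, rep(0, cf$n_mirna),
                            matrix(0, cf$n_mirna, 2 * n), mir_ids)
  attr(circ_counts, "groups") <- groups
  attr(mrna_counts, "groups") <- groups
  attr(mirna_counts, "groups") <- groups

  # sequences: miRNA in RNA alphabet, circRNA in DNA (scanner accepts both)
  mirna_seqs <- tibble(id = mir_ids,
                       seq = vapply(seq_len(cf$n_mirna), function(i)
                         random_seq(cf$mirna_len), character(1)))
  circ_len <- sample(cf$circ_len_range[1]:cf$circ_len_range[2], cf$n_circ,
                     replace = TRUE)
  circ_seq <- vapply(circ_len, function(L)
    random_seq(L, c("A", "C", "G", "T")), character(1))
  for (m in seq_len(n_mod)) {
    i <- mod_circ[m]
    win <- chartr("U", "T", mre_8mer_window(mirna_seqs$seq[mod_mir[m]]))
    pos <- sample(0:(circ_len[i] - 1), 1)
    circ_seq[i] <- plant_circular(circ_seq[i], pos, win)
  }
  circ_seqs <- tibble(id = circ_ids, seq = circ_seq)

  # target table: planted rows + uniform decoys
  planted_rows <- tibble(mirna_id = mir_ids[planted_mir],
                         gene_id = gene_ids[planted_gene])
  n_decoy <- round(cf$decoy_interaction_rate * cf$n_mirna * cf$n_mrna)
  all_combo <- tidyr::expand_grid(mirna_id = mir_ids, gene_id = gene_ids)
  all_combo <- dplyr::anti_join(all_combo, planted_rows,
                                by = c("mirna_id", "gene_id"))
  decoys <- all_combo[sample(nrow(all_combo), min(n_decoy, nrow(all_combo))), ]
  target_table <- bind_rows(planted_rows, decoys)
  target_table <- target_table[sample(nrow(target_table)), ]

  # disease annotation with enriched odds for sponged miRNAs
  p0 <- cf$assoc_baseline
  p1 <- cf$assoc_enrichment_odds * p0 / (1 - p0 + cf$assoc_enrichment_odds * p0)
  p_assoc <- ifelse(seq_len(cf$n_mirna) %in% mod_mir, p1, p0)
  assoc_mirnas <- mir_ids[runif(cf$n_mirna) < p_assoc]

  planted_axes <- tibble(circ_id = circ_ids[planted_circ],
                         mirna_id = mir_ids[planted_mir],
                         gene_id = gene_ids[planted_gene])
  truth <- structure(list(
    de_circ = tibble(feature_id = circ_ids[de_circ_idx],
                     sign = unname(sign_circ[de_circ_idx]),
                     linear_fc = cf$planted_fc^unname(sign_circ[de_circ_idx])),
    de_mrna = tibble(feature_id = gene_ids[de_gene_idx],
                     sign = unname(sign_gene[de_gene_idx]),
                     linear_fc = cf$planted_fc^unname(sign_gene[de_gene_idx])),
    planted_pairs = planted_axes[, c("circ_id", "gene_id")],
    planted_axes = planted_axes,
    expressed_mirnas = mir_ids[expressed_idx],
    config = cf), class = "cerna_truth")

  sim <- structure(list(circ_counts = circ_counts, mrna_counts = mrna_counts,
                        mirna_counts = mirna_counts, groups = groups,
                        circ_seqs = circ_seqs, mirna_seqs = mirna_seqs,
                        target_table = target_table,
                        assoc_mirnas = assoc_mirnas, truth = truth),
                   class = "cerna_sim")
  assert_discoverable(sim)
  sim
}

# every planted axis must be recoverable in principle: its seed site
# survives the scanner and its miRNA passes the expression rule
assert_discoverable <- function(sim) {
  expr_mir <- expressed_mirnas(sim$mirna_counts)
  ax <- sim$truth$planted_axes
  for (k in seq_len(nrow(ax))) {
    if (!ax$mirna_id[k] %in% expr_mir) {
      stop_spongenet(paste0("planted miRNA fails the expression rule: ", ax$mirna_id[k]))
    }
    cs <- sim$circ_seqs$seq[sim$circ_seqs$id == ax$circ_id[k]]
    ms <- sim$mirna_seqs$seq[sim$mirna_seqs$id == ax$mirna_id[k]]
    hits <- circ_mir_interactions(scan_mre(cs, ms, ax$circ_id[k], ax$mirna_id[k]))
    if (nrow(hits) == 0) {
      stop_spongenet(paste0("planted seed site not recoverable for axis ",
                            ax$circ_id[k], " / ", ax$mirna_id[k]))
    }
  }
  invisible(sim)
}

#' Write a simulated study to disk
#'
#' Emits every file in the dialect the pipeline reads (TSV count matrices,
#' FASTA sequences, two-column target table, one-ID-per-line annotation
#' list, a sample-to-group table) plus the ground truth under `truth/`.
#'
#' @param sim A `cerna_sim` from [simulate_cerna()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cerna_sim"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$circ_counts, file.path(dir, "circ_counts.tsv"))
  write_count_matrix(sim$mrna_counts, file.path(dir, "mrna_counts.tsv"))
  write_count_matrix(sim$mirna_counts, file.path(dir, "mirna_counts.tsv"))
  readr::write_tsv(tibble(sample = names(sim$groups), group = unname(sim$groups)),
                   file.path(dir, "groups.tsv"), progress = FALSE)
  write_fasta(sim$circ_seqs, file.path(dir, "circ_seqs.fa"))
  write_fasta(sim$mirna_seqs, file.path(dir, "mirna_seqs.fa"))
  readr::write_tsv(sim$target_table, file.path(dir, "target_table.tsv"),
                   progress = FALSE, col_names = FALSE)
  write_annotation_list(sim$assoc_mirnas, file.path(dir, "assoc_mirnas.txt"))
  tr <- sim$truth
  readr::write_tsv(tr$de_circ, file.path(dir, "truth", "de_circ.tsv"), progress = FALSE)
  readr::write_tsv(tr$de_mrna, file.path(dir, "truth", "de_mrna.tsv"), progress = FALSE)
  readr::write_tsv(tr$planted_pairs, file.path(dir, "truth", "planted_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(tr$planted_axes, file.path(dir, "truth", "planted_axes.tsv"),
                   progress = FALSE)
  write_annotation_list(tr$expressed_mirnas,
                        file.path(dir, "truth", "expressed_mirnas.txt"))
  invisible(dir)
}

#' Score recovery of planted axes
#'
#' Set precision/recall/F1 over exact (circ, miR, gene) triples.
#'
#' @param truth A `cerna_truth` (or a planted-axis tibble).
#' @param predicted_axes Predicted axes: a `cerna_network` or a tibble with
#'   `circ_id`, `mirna_id`, `gene_id`.
#' @return One-row tibble: `precision`, `recall`, `f1`, `n_true`,
#'   `n_predicted`, `n_hit`, `empty_prediction`. An empty prediction reports
#'   precision 0 with the flag set.
#' @export
score_recovery <- function(truth, predicted_axes) {
  true_ax <- if (inherits(truth, "cerna_truth")) truth$planted_axes else as_tibble(truth)
  if (inherits(predicted_axes, "cerna_network")) predicted_axes <- predicted_axes$axes
  pred <- distinct(as_tibble(predicted_axes)[, c("circ_id", "mirna_id", "gene_id")])
  true_key <- do.call(paste, c(true_ax[, c("circ_id", "mirna_id", "gene_id")], sep = "\r"))
  pred_key <- do.call(paste, c(pred, sep = "\r"))
  hit <- sum(pred_key %in% true_key)
  empty <- nrow(pred) == 0
  precision <- if (empty) 0 else hit / nrow(pred)
  recall <- if (nrow(true_ax) == 0) 1 else hit / nrow(true_ax)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1,
         n_true = nrow(true_ax), n_predicted = nrow(pred), n_hit = hit,
         empty_prediction = empty)
}
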