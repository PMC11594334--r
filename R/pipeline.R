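#' Run the ceRNA-network pipeline for one model
#'
#' Orchestrates the full analysis of one exposure model end to end:
#' junction-read filtering of circRNA counts, differential expression of
#' circRNAs (raw `p < 0.05`, fold change `> 2`) and mRNAs (`FDR < 0.05`,
#' fold change `> 1.5`), one-sided Pearson co-expression screening of DE
#' circRNA-mRNA pairs on log2-CPM, seed-site scanning of DE circRNA
#' sequences against expressed miRNAs, target-table filtering, tripartite
#' axis assembly, hub ranking and subnetwork extraction, and (when a
#' disease-associated miRNA list is supplied) the sponged-by-disease Fisher
#' enrichment over the expressed-miRNA universe. Deterministic given its
#' inputs; every table in the result can be written to `out_dir`.
#'
#' @param circ_counts,mrna_counts,mirna_counts Count tibbles sharing the
#'   sample set in `groups`.
#' @param circ_seqs,mirna_seqs Sequence tibbles (`id`, `seq`).
#' @param target_table miRNA-to-gene tibble (`mirna_id`, `gene_id`).
#' @param groups Named sample-to-group vector (defaults to the counts'
#'   `"groups"` attribute).
#' @param assoc_mirnas Optional disease-associated miRNA IDs for the Fisher
#'   enrichment.
#' @param annotation Optional term-to-gene annotation (tibble or named list)
#'   for over-representation analysis of the subnetwork target genes.
#' @param model Label for the run (e.g. `"PD-OS"`).
#' @param min_junction_reads,min_junction_fraction circRNA confidence filter.
#' @param circ_thresholds,mrna_thresholds DE calling regimes.
#' @param de_method Test passed to [de_test()].
#' @param r_min,max_adj_p Co-expression screen cutoffs.
#' @param mirna_min_count,mirna_min_fraction miRNA expression rule.
#' @param min_site_type Weakest seed-site class counted as sponging.
#' @param hub_method,k Hub ranking method and size.
#' @param out_dir Optional directory: all intermediate tables, SIF/GraphML
#'   exports, and a JSON + Markdown report are written there.
#' @return A list of class `cerna_run` with elements `model`, `params`,
#'   `circ_filtered`, `circ_de`, `mrna_de`, `de_circ`, `de_mrna` (called
#'   sets), `pairs`, `sites`, `circ_mir`, `mir_mrna`, `expressed_mirnas`,
#'   `network`, `stats`, `hubs`, `subnetwork`, `sponge_table`, `fisher_p`,
#'   `ora`, and `flags` (degenerate-stage notes).
#' @export
run_cerna_pipeline <- function(circ_counts, mrna_counts, mirna_counts,
                               circ_seqs, mirna_seqs, target_table,
                               groups = NULL, assoc_mirnas = NULL,
                               annotation = NULL, model = "model",
                               min_junction_reads = 2,
                               min_junction_fraction = 0.5,
                               circ_thresholds = circ_de_thresholds(),
                               mrna_thresholds = mrna_de_thresholds(),
                               de_method = "nb_exact",
                               r_min = 0.90, max_adj_p = 0.05,
                               mirna_min_count = 1, mirna_min_fraction = 0.5,
                               min_site_type = "7mer-A1",
                               hub_method = "degree", k = 10,
                               out_dir = NULL) {
  groups <- groups %||% attr(circ_counts, "groups")
  flags <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_spongenet(paste0("pipeline stage '", name, "' failed: ",
                            conditionMessage(e)))
    })
  }

  circ_filtered <- stage("junction_filter",
    filter_by_junction_reads(circ_counts, min_junction_reads, min_junction_fraction))
  circ_de <- stage("circ_de", de_test(circ_filtered, groups, method = de_method))
  mrna_de <- stage("mrna_de", de_test(mrna_counts, groups, method = de_method))
  de_circ <- apply_thresholds(circ_de, circ_thresholds)
  de_mrna <- apply_thresholds(mrna_de, mrna_thresholds)
  if (nrow(de_circ) == 0) flags <- c(flags, "no DE circRNAs")
  if (nrow(de_mrna) == 0) flags <- c(flags, "no DE mRNAs")

  expr_mir <- stage("mirna_expression",
    expressed_mirnas(mirna_counts, mirna_min_count, mirna_min_fraction))

  empty_pairs <- tibble(circ_id = character(), gene_id = character())
  if (nrow(de_circ) > 0 && nrow(de_mrna) > 0) {
    lc <- cpm(circ_filtered, log2 = TRUE)
    lm <- cpm(mrna_counts, log2 = TRUE)
    pairs <- stage("coexpression", coexpressed_pairs(
      lc[lc[[1]] %in% de_circ$feature_id, , drop = FALSE],
      lm[lm[[1]] %in% de_mrna$feature_id, , drop = FALSE],
      r_min = r_min, max_adj_p = max_adj_p))
  } else {
    pairs <- empty_pairs
  }
  if (nrow(pairs) == 0) flags <- c(flags, "no co-expressed pairs")

  scan_circ <- filter(circ_seqs, .data$id %in% unique(pairs$circ_id))
  scan_mir <- filter(mirna_seqs, .data$id %in% expr_mir)
  sites <- if (nrow(scan_circ) > 0 && nrow(scan_mir) > 0) {
    stage("seed_scan", scan_mre_all(scan_circ, scan_mir))
  } else {
    tibble(circ_id = character(), mirna_id = character(),
           site_type = character(), start = integer(), spans_bsj = logical())
  }
  circ_mir <- circ_mir_interactions(sites, min_site_type)
  mir_mrna <- stage("target_filter",
                    mir_mrna_interactions(target_table, de_mrna$feature_id))

  net <- stage("axes", build_axes(pairs, circ_mir, mir_mrna, expr_mir))
  stats <- network_stats(net)
  if (stats$n_axes == 0) flags <- c(flags, "empty ceRNA network")

  hubs <- stage("hubs", suppressWarnings(rank_hubs(net, hub_method, k)))
  subnet <- extract_subnetwork(net, hubs$node)

  sponge_table <- NULL; fisher_p <- NA_real_
  if (!is.null(assoc_mirnas)) {
    sponged <- intersect(unique(net$axes$mirna_id), expr_mir)
    associated <- intersect(unique(assoc_mirnas), expr_mir)
    sponge_table <- build_sponge_table(sponged, associated, expr_mir)
    fisher_p <- fisher_exact_greater(sponge_table)
  }

  ora <- NULL
  if (!is.null(annotation) && nrow(subnet$axes) > 0) {
    ann_genes <- if (is.data.frame(annotation)) unique(annotation$gene_id) else
      unique(unlist(annotation, use.names = FALSE))
    # unannotated genes are dropped from the query, as in standard ORA tools
    query <- intersect(unique(subnet$axes$gene_id), ann_genes)
    if (length(query) > 0) {
      ora <- stage("ora", hypergeom_ora(query, annotation, universe = NULL))
    }
  }

  params <- list(model = model, min_junction_reads = min_junction_reads,
                 min_junction_fraction = min_junction_fraction,
                 circ_thresholds = unclass(circ_thresholds),
                 mrna_thresholds = unclass(mrna_thresholds),
                 de_method = de_method, r_min = r_min, max_adj_p = max_adj_p,
                 mirna_min_count = mirna_min_count,
                 mirna_min_fraction = mirna_min_fraction,
                 min_site_type = min_site_type, hub_method = hub_method, k = k)
  run <- structure(list(model = model, params = params,
                        circ_filtered = circ_filtered,
                        circ_de = circ_de, mrna_de = mrna_de,
                        de_circ = de_circ, de_mrna = de_mrna,
                        pairs = pairs, sites = sites, circ_mir = circ_mir,
                        mir_mrna = mir_mrna, expressed_mirnas = expr_mir,
                        network = net, stats = stats, hubs = hubs,
                        subnetwork = subnet, sponge_table = sponge_table,
                        fisher_p = fisher_p, ora = ora, flags = flags),
                   class = "cerna_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.cerna_run <- function(x, ...) {
  cat("<cerna_run> model:", x$model, "\n")
  cat("  DE circRNAs:", nrow(x$de_circ), " DE mRNAs:", nrow(x$de_mrna),
      " co-expressed pairs:", nrow(x$pairs), "\n")
  s <- x$stats
  cat("  network:", s$n_axes, "axes,", s$n_nodes, "nodes (",
      s$n_circ_mir_edges, "sponge +", s$n_mir_mrna_edges, "target edges )\n")
  if (!is.na(x$fisher_p)) {
    cat("  sponge/disease Fisher p =", format.pval(x$fisher_p, digits = 3), "\n")
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Write the pipeline result bundle
#'
#' Emits every intermediate table as TSV, network exports (SIF, GraphML,
#' edge TSV, axis table), and a reproducibility report (`report.json` with
#' parameters, counts and statistics; `report.md` as a human-readable
#' summary). Every number in the report is recomputable from the written
#' tables.
#'
#' @param run A `cerna_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "cerna_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tbl, name) readr::write_tsv(as_tibble(tbl), file.path(dir, name),
                                            progress = FALSE)
  w(run$circ_de, "circ_de.tsv"); w(run$mrna_de, "mrna_de.tsv")
  w(run$de_circ, "de_circ.tsv"); w(run$de_mrna, "de_mrna.tsv")
  w(run$pairs, "coexpressed_pairs.tsv"); w(run$sites, "mre_sites.tsv")
  w(run$circ_mir, "circ_mir_interactions.tsv")
  w(run$mir_mrna, "mir_mrna_interactions.tsv")
  w(run$network$axes, "axes.tsv")
  w(run$hubs, "hubs.tsv")
  w(run$subnetwork$axes, "subnetwork_axes.tsv")
  write_annotation_list(run$expressed_mirnas, file.path(dir, "expressed_mirnas.txt"))
  export_network(run$network, file.path(dir, "network.sif"), "sif")
  export_network(run$network, file.path(dir, "network.graphml"), "graphml")
  export_network(run$network, file.path(dir, "network_edges.tsv"), "edge_tsv")
  if (!is.null(run$sponge_table)) w(run$sponge_table, "sponge_table.tsv")
  if (!is.null(run$ora)) w(run$ora, "ora.tsv")
  report <- list(model = run$model, params = run$params,
                 n_circ_filtered = nrow(run$circ_filtered),
                 n_de_circ = nrow(run$de_circ), n_de_mrna = nrow(run$de_mrna),
                 n_pairs = nrow(run$pairs),
                 network = as.list(run$stats),
                 n_subnetwork_axes = nrow(run$subnetwork$axes),
                 n_subnetwork_mirnas = length(unique(run$subnetwork$axes$mirna_id)),
                 n_subnetwork_mrnas = length(unique(run$subnetwork$axes$gene_id)),
                 hubs = run$hubs$node,
                 fisher_p = if (is.na(run$fisher_p)) NULL else run$fisher_p,
                 sponge_table = if (is.null(run$sponge_table)) NULL else
                   as.list(run$sponge_table),
                 flags = run$flags)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c(paste0("# ceRNA pipeline report - ", run$model), "",
          paste0("- circRNAs past junction filter: ", nrow(run$circ_filtered)),
          paste0("- DE circRNAs: ", nrow(run$de_circ),
                 "; DE mRNAs: ", nrow(run$de_mrna)),
          paste0("- co-expressed pairs: ", nrow(run$pairs)),
          paste0("- network: ", run$stats$n_axes, " axes, ",
                 run$stats$n_nodes, " nodes, ", run$stats$n_circ_mir_edges,
                 " sponge + ", run$stats$n_mir_mrna_edges, " target edges"),
          paste0("- hub circRNAs (", run$params$hub_method, ", k = ",
                 run$params$k, "): ", paste(run$hubs$node, collapse = ", ")),
          if (!is.na(run$fisher_p))
            paste0("- sponge/disease Fisher p (one-sided): ",
                   signif(run$fisher_p, 4)),
          if (length(run$flags)) paste0("- flags: ",
                                        paste(run$flags, collapse = "; ")))
  readr::write_lines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Compare two model runs
#'
#' Set comparison of the DE circRNA calls of two runs (e.g. the two exposure
#' models of a study): shared and model-specific DE circRNAs, with union
#' semantics for the merged DE set.
#'
#' @param run_a,run_b `cerna_run` objects.
#' @return A list with `shared_de_circ`, `only_a`, `only_b`,
#'   `union_de_circ`, and the corresponding counts in `summary`.
#' @export
compare_runs <- function(run_a, run_b) {
  stopifnot(inherits(run_a, "cerna_run"), inherits(run_b, "cerna_run"))
  a <- run_a$de_circ$feature_id
  b <- run_b$de_circ$feature_id
  list(shared_de_circ = intersect(a, b),
       only_a = setdiff(a, b), only_b = setdiff(b, a),
       union_de_circ = union(a, b),
       summary = tibble(model_a = run_a$model, model_b = run_b$model,
                        n_a = length(a), n_b = length(b),
                        n_shared = length(intersect(a, b)),
                        n_union = length(union(a, b))))
}
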