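#' Assemble circRNA-miRNA-mRNA ceRNA axes
#'
#' An axis (circ, miR, gene) is emitted when the circRNA-gene pair passed the
#' co-expression screen, the circRNA is predicted to sponge the miRNA, the
#' miRNA is predicted to target the gene, and the miRNA is expressed in the
#' samples — i.e. co-expressed pairs whose two members share a common
#' expressed miRNA.
#'
#' @param pairs Co-expression pairs (`circ_id`, `gene_id`), e.g. from
#'   [coexpressed_pairs()].
#' @param circ_mir circRNA-miRNA interactions (`circ_id`, `mirna_id`).
#' @param mir_mrna miRNA-mRNA interactions (`mirna_id`, `gene_id`).
#' @param expressed Character vector of expressed miRNA IDs.
#' @return A `cerna_network` object (see [cerna_network()]).
#' @export
build_axes <- function(pairs, circ_mir, mir_mrna, expressed) {
  need <- function(tbl, cols, what) {
    if (!all(cols %in% names(tbl))) {
      stop_spongenet(paste0("`", what, "` needs columns ", paste(cols, collapse = ", ")))
    }
    distinct(as_tibble(tbl)[, cols, drop = FALSE])
  }
  pairs <- need(pairs, c("circ_id", "gene_id"), "pairs")
  circ_mir <- need(circ_mir, c("circ_id", "mirna_id"), "circ_mir")
  mir_mrna <- need(mir_mrna, c("mirna_id", "gene_id"), "mir_mrna")
  circ_mir <- filter(circ_mir, .data$mirna_id %in% expressed)
  axes <- inner_join(pairs, circ_mir, by = "circ_id", relationship = "many-to-many")
  axes <- inner_join(axes, mir_mrna, by = c("mirna_id", "gene_id"))
  axes <- distinct(axes[, c("circ_id", "mirna_id", "gene_id")])
  cerna_network(axes)
}

#' Tripartite ceRNA network
#'
#' A `cerna_network` wraps an axis table and the node/edge sets derived from
#' it: circRNA-miRNA "sponge" edges and miRNA-mRNA "target" edges. The graph
#' is tripartite by construction — the three node partitions must be
#' disjoint, every node lies on at least one axis, and no circ-mRNA or
#' within-partition edges exist.
#'
#' @param axes Tibble with columns `circ_id`, `mirna_id`, `gene_id`.
#' @return An object of class `cerna_network` with elements `axes`, `nodes`
#'   (`id`, `type`) and `edges` (`from`, `to`, `interaction`).
#' @export
cerna_network <- function(axes) {
  axes <- distinct(as_tibble(axes)[, c("circ_id", "mirna_id", "gene_id")])
  if (nrow(axes) > 0 &&
      (any(!nzchar(axes$circ_id)) || any(!nzchar(axes$mirna_id)) ||
       any(!nzchar(axes$gene_id)) || anyNA(axes))) {
    stop_spongenet("axis table contains empty IDs")
  }
  circ <- sort(unique(axes$circ_id))
  mir <- sort(unique(axes$mirna_id))
  gene <- sort(unique(axes$gene_id))
  overlap <- c(intersect(circ, mir), intersect(circ, gene), intersect(mir, gene))
  if (length(overlap) > 0) {
    stop_spongenet(paste0("node '", overlap[1],
                          "' appears in more than one partition; network must be tripartite"))
  }
  nodes <- tibble(id = c(circ, mir, gene),
                  type = rep(c("circRNA", "miRNA", "mRNA"),
                             c(length(circ), length(mir), length(gene))))
  sponge <- distinct(axes[, c("circ_id", "mirna_id")])
  target <- distinct(axes[, c("mirna_id", "gene_id")])
  edges <- bind_rows(
    tibble(from = sponge$circ_id, to = sponge$mirna_id, interaction = "sponges"),
    tibble(from = target$mirna_id, to = target$gene_id, interaction = "targets")
  )
  structure(list(axes = axes, nodes = nodes, edges = edges),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- network_stats(x)
  cat("<cerna_network> ", s$n_axes, " axes, ", s$n_nodes, " nodes (",
      sum(x$nodes$type == "circRNA"), " circRNA / ",
      sum(x$nodes$type == "miRNA"), " miRNA / ",
      sum(x$nodes$type == "mRNA"), " mRNA), ",
      s$n_circ_mir_edges, " sponge + ", s$n_mir_mrna_edges,
      " target edges\n", sep = "")
  invisible(x)
}

#' Network summary counts
#'
#' @param net A `cerna_network`.
#' @return One-row tibble: `n_axes`, `n_nodes`, `n_circ_mir_edges`,
#'   `n_mir_mrna_edges`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  tibble(n_axes = nrow(net$axes),
         n_nodes = nrow(net$nodes),
         n_circ_mir_edges = sum(net$edges$interaction == "sponges"),
         n_mir_mrna_edges = sum(net$edges$interaction == "targets"))
}

# internal: igraph view with partition-prefixed node names
as_igraph_cerna <- function(net) {
  pref <- c(circRNA = "circ:", miRNA = "miR:", mRNA = "gene:")
  nodes <- mutate(net$nodes, name = paste0(pref[.data$type], .data$id))
  key <- setNames(nodes$name, nodes$id)
  edges <- tibble(from = key[net$edges$from], to = key[net$edges$to],
                  interaction = net$edges$interaction)
  nodes$feature_id <- nodes$id
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = nodes[, c("name", "type", "feature_id")])
}

#' Rank hub circRNAs
#'
#' Scores every circRNA node of the network and returns the top `k`.
#' `degree` counts incident edges; `mcc` is Maximal Clique Centrality — the
#' sum over maximal cliques containing the node of `(clique size - 1)!`,
#' with isolated nodes scoring 0. On a triangle-free graph (every tripartite
#' graph is) maximal cliques are exactly the edges and MCC reduces to
#' degree, which doubles as a cross-method consistency check. Ties break
#' lexicographically by node ID for reproducibility.
#'
#' @param net A `cerna_network`.
#' @param method `"degree"` (default) or `"mcc"`.
#' @param k Number of hubs to return; if larger than the number of circRNA
#'   nodes, all are returned with a warning.
#' @return A tibble of class `cerna_hubs` with `node`, `score`, `rank` for
#'   the top-`k` circRNAs; scores for all circRNA nodes are kept in the
#'   `"scores"` attribute.
#' @export
rank_hubs <- function(net, method = c("degree", "mcc"), k = 10) {
  stopifnot(inherits(net, "cerna_network"))
  method <- match.arg(method)
  if (k < 1) stop_spongenet("`k` must be >= 1")
  circ <- net$nodes$id[net$nodes$type == "circRNA"]
  if (length(circ) == 0) {
    out <- tibble(node = character(), score = numeric(), rank = integer())
    return(structure(out, class = c("cerna_hubs", class(out)),
                     method = method, k = k, scores = out))
  }
  if (method == "degree") {
    deg <- table(c(net$edges$from, net$edges$to))
    score <- as.numeric(deg[circ])
    score[is.na(score)] <- 0
  } else {
    g <- as_igraph_cerna(net)
    cl <- igraph::max_cliques(g, min = 2)
    score <- setNames(numeric(length(circ)), paste0("circ:", circ))
    for (cc in cl) {
      nm <- names(cc)
      contrib <- factorial(length(cc) - 1)
      hit <- intersect(nm, names(score))
      score[hit] <- score[hit] + contrib
    }
    score <- as.numeric(score)
  }
  ord <- order(-score, circ)
  all_scores <- tibble(node = circ[ord], score = score[ord],
                       rank = seq_along(circ))
  if (k > length(circ)) {
    warning("`k` exceeds the number of circRNA nodes; returning all of them")
    k <- length(circ)
  }
  out <- all_scores[seq_len(k), , drop = FALSE]
  structure(out, class = c("cerna_hubs", class(out)),
            method = method, k = k, scores = all_scores)
}

#' Extract the hub-centred subnetwork
#'
#' Keeps every axis whose circRNA is one of the given hubs; miRNA and mRNA
#' nodes not on any retained axis drop out.
#'
#' @param net A `cerna_network`.
#' @param hubs Character vector of circRNA IDs (e.g. `rank_hubs(net)$node`),
#'   all of which must be circRNA nodes of `net`.
#' @return A `cerna_network`.
#' @export
extract_subnetwork <- function(net, hubs) {
  stopifnot(inherits(net, "cerna_network"))
  hubs <- as.character(hubs)
  circ <- net$nodes$id[net$nodes$type == "circRNA"]
  unknown <- setdiff(hubs, circ)
  if (length(unknown) > 0) {
    stop_spongenet(paste0("unknown hub circRNA: '", unknown[1], "'"))
  }
  cerna_network(filter(net$axes, .data$circ_id %in% hubs))
}

#' Export a ceRNA network
#'
#' Writes Cytoscape-readable graph files. Node IDs are prefixed by partition
#' (`circ:`, `miR:`, `gene:`) so that a circRNA and a gene sharing a symbol
#' stay distinct.
#'
#' * `sif` — lines `source<TAB>interaction<TAB>target` with interaction
#'   `sponges` or `targets`;
#' * `graphml` — via igraph, carrying node `type` and optional numeric
#'   attributes (e.g. log2 fold changes) supplied in `node_attrs`;
#' * `edge_tsv` — tidy edge list (`from`, `interaction`, `to`), re-readable
#'   with [read_edge_tsv()].
#'
#' @param net A `cerna_network`.
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"edge_tsv"`.
#' @param node_attrs Optional tibble (`id`, then attribute columns) merged
#'   onto nodes for GraphML export.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "edge_tsv"),
                           node_attrs = NULL) {
  stopifnot(inherits(net, "cerna_network"))
  format <- match.arg(format)
  pref <- c(circRNA = "circ:", miRNA = "miR:", mRNA = "gene:")
  key <- setNames(paste0(pref[net$nodes$type], net$nodes$id), net$nodes$id)
  edges <- tibble(from = unname(key[net$edges$from]),
                  interaction = net$edges$interaction,
                  to = unname(key[net$edges$to]))
  if (format == "sif") {
    readr::write_lines(sprintf("%s\t%s\t%s", edges$from, edges$interaction, edges$to),
                       path)
  } else if (format == "edge_tsv") {
    readr::write_tsv(edges, path, progress = FALSE)
  } else {
    g <- as_igraph_cerna(net)
    if (!is.null(node_attrs)) {
      idx <- match(igraph::V(g)$feature_id, node_attrs[[1]])
      for (col in names(node_attrs)[-1]) {
        g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][idx])
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
read_edge_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, col_types = "ccc")
}
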