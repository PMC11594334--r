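#' One-sided Fisher's exact test (enrichment)
#'
#' Exact upper-tail test on a 2x2 contingency table laid out column-major as
#' `matrix(c(a, b, c, d), nrow = 2)` — i.e. `a` and `b` fill the first
#' column, matching the conventional R call. With the sponge/disease
#' cross-tabulation, `a` counts miRNAs that are both sponged and
#' disease-associated, `b` sponged only, `c` associated only, `d` neither.
#' The p-value is the hypergeometric tail
#' `P(X >= a)` for `X ~ Hypergeom(N = a+b+c+d, K = a+c, n = a+b)`, summed in
#' log-space for numerical stability; it is exact for any table size.
#'
#' @param a,b,c,d Non-negative integer cell counts; alternatively pass a
#'   one-row table from [build_sponge_table()] as `a`.
#' @return The one-sided (greater) p-value.
#' @examples
#' fisher_exact_greater(66, 48, 105, 665)  # < 0.001
#' @export
fisher_exact_greater <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.data.frame(a)) {
    tbl <- a
    a <- tbl$a; b <- tbl$b; c <- tbl$c; d <- tbl$d
  }
  cells <- c(a, b, c, d)
  if (length(cells) != 4 || anyNA(cells) || any(cells < 0) ||
      any(cells != floor(cells))) {
    stop_spongenet("cells a, b, c, d must be non-negative integers")
  }
  N <- a + b + c + d
  if (N < 1) stop_spongenet("grand total must be >= 1")
  hyper_tail_greater(a, K = a + c, n = a + b, N = N)
}

# log-space upper tail of the hypergeometric: P(X >= x0)
hyper_tail_greater <- function(x0, K, n, N) {
  hi <- min(K, n)
  if (x0 <= max(0, K + n - N)) return(1)
  if (x0 > hi) return(0)
  lp <- dhyper(x0:hi, m = K, n = N - K, k = n, log = TRUE)
  min(1, exp(logsumexp(lp)))
}

#' Build the sponged-by-disease contingency table
#'
#' Cross-tabulates the expressed miRNA universe by whether each miRNA is
#' sponged by circRNAs of the network and whether it is disease-associated:
#' `a = |sponged & associated|`, `b = |sponged \ associated|`,
#' `c = |associated \ sponged|`, `d = |universe \ (sponged | associated)|`.
#'
#' @param sponged miRNA IDs sponged in the network (subset of `universe`).
#' @param associated Disease-associated miRNA IDs (subset of `universe`).
#' @param universe All miRNAs expressed in the system.
#' @return One-row tibble with columns `a`, `b`, `c`, `d` plus the margins
#'   `n_sponged`, `n_associated`, `n_universe`.
#' @export
build_sponge_table <- function(sponged, associated, universe) {
  sponged <- unique(as.character(sponged))
  associated <- unique(as.character(associated))
  universe <- unique(as.character(universe))
  if (length(setdiff(sponged, universe)) > 0) {
    stop_spongenet("`sponged` must be a subset of `universe`")
  }
  if (length(setdiff(associated, universe)) > 0) {
    stop_spongenet("`associated` must be a subset of `universe`")
  }
  a <- length(intersect(sponged, associated))
  b <- length(setdiff(sponged, associated))
  c <- length(setdiff(associated, sponged))
  d <- length(universe) - a - b - c
  tibble(a = a, b = b, c = c, d = d,
         n_sponged = a + b, n_associated = a + c, n_universe = a + b + c + d)
}

#' Hypergeometric over-representation analysis
#'
#' One-tailed hypergeometric ORA of a query gene set against a flat
#' term-to-gene annotation: per term with at least one annotated gene in the
#' universe, `p = P(X >= k)` for
#' `X ~ Hypergeom(N = |universe|, K = |term|, n = |query|)` with `k` the
#' query/term overlap; BH adjustment across all tested terms.
#'
#' @param query Gene IDs of interest (must lie in the universe).
#' @param annotation Either a tibble (`term_id`, `gene_id`) or a named list
#'   of gene-ID vectors (e.g. from [read_gmt()]).
#' @param universe Background gene set; defaults to all genes in the
#'   annotation. Annotated genes outside an explicit universe are dropped.
#' @return Tibble sorted by p: `term_id`, `overlap_k`, `term_size_K`,
#'   `query_size_n`, `universe_N`, `p_value`, `fdr`.
#' @export
hypergeom_ora <- function(query, annotation, universe = NULL) {
  if (is.data.frame(annotation)) {
    if (!all(c("term_id", "gene_id") %in% names(annotation))) {
      stop_spongenet("`annotation` needs columns term_id, gene_id")
    }
    ann <- split(annotation$gene_id, annotation$term_id)
  } else {
    ann <- annotation
  }
  ann <- lapply(ann, function(g) unique(as.character(g)))
  if (is.null(universe)) {
    universe <- unique(unlist(ann, use.names = FALSE))
  } else {
    universe <- unique(as.character(universe))
    ann <- lapply(ann, intersect, universe)
  }
  if (length(universe) == 0) stop_spongenet("empty universe")
  query <- unique(as.character(query))
  if (length(setdiff(query, universe)) > 0) {
    stop_spongenet("`query` must be a subset of the universe")
  }
  ann <- ann[lengths(ann) > 0]
  N <- length(universe); n <- length(query)
  res <- purrr::imap_dfr(ann, function(genes, term) {
    K <- length(genes)
    k <- length(intersect(genes, query))
    tibble(term_id = term, overlap_k = k, term_size_K = K,
           query_size_n = n, universe_N = N,
           p_value = hyper_tail_greater(k, K = K, n = n, N = N))
  })
  if (nrow(res) == 0) {
    res$fdr <- numeric(0)
    return(res)
  }
  res$fdr <- bh_adjust(res$p_value)
  arrange(res, .data$p_value, .data$term_id)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `term<TAB>description<TAB>`
#' followed by gene IDs.
#'
#' @param path Path to the GMT file.
#' @return Named list of gene-ID character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_spongenet(paste0("file not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop_spongenet("malformed GMT line (need term, description, >=1 gene)")
  setNames(lapply(parts, function(x) unique(x[-(1:2)])),
           vapply(parts, `[[`, character(1), 1))
}
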