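# Independent oracles used to cross-check the package implementations.
# These deliberately use different code paths (explicit loops, choose(),
# character indexing) from the functions they verify.

# Benjamini-Hochberg step-up, written directly from the definition
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, input order restored.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) ps[j] * m / j, numeric(1))
    q[i] <- min(1, min(cands))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Upper-tail Fisher p by full enumeration of all 2x2 tables with the
# observed margins, probabilities from choose() arithmetic.
oracle_fisher_greater <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c   # column-1 margin (associated)
  n <- a + b   # row-1 margin (sponged)
  lo <- max(0, K + n - N)
  hi <- min(K, n)
  probs <- vapply(lo:hi, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1))
  sum(probs[(lo:hi) >= a])
}

# Naive windowed seed-site scanner over the circular sequence using modular
# character indexing (no circularize(), no substring vectorisation).
oracle_scan <- function(circ_seq, mirna_seq) {
  norm <- function(s) chartr("T", "U", toupper(s))
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  circ <- strsplit(norm(circ_seq), "")[[1]]
  mir <- strsplit(norm(mirna_seq), "")[[1]]
  L <- length(circ)
  seed_rc <- rev(unname(comp[mir[2:7]]))   # w[2..7], 5'->3' on target
  m8 <- unname(comp[mir[8]])
  hits <- list()
  for (s in 0:(L - 1)) {
    w <- circ[((s + 0:7) %% L) + 1]
    if (!all(w[2:7] == seed_rc)) next
    has_m8 <- w[1] == m8
    has_a1 <- w[8] == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    hits[[length(hits) + 1]] <- data.frame(site_type = type, start = s,
                                           spans_bsj = s + 8 > L)
  }
  if (length(hits) == 0) {
    return(data.frame(site_type = character(), start = integer(),
                      spans_bsj = logical()))
  }
  do.call(rbind, hits)
}

# The enumerated toy network instance: pairs {(c1,m1),(c1,m2),(c2,m1)},
# sponge interactions {(c1,u1),(c1,u2),(c2,u1)}, targets {(u1,m1),(u2,m2)},
# all miRNAs expressed. Expected axes: (c1,u1,m1), (c1,u2,m2), (c2,u1,m1).
toy_network_inputs <- function() {
  list(
    pairs = tibble::tibble(circ_id = c("c1", "c1", "c2"),
                           gene_id = c("m1", "m2", "m1")),
    circ_mir = tibble::tibble(circ_id = c("c1", "c1", "c2"),
                              mirna_id = c("u1", "u2", "u1")),
    mir_mrna = tibble::tibble(mirna_id = c("u1", "u2"),
                              gene_id = c("m1", "m2")),
    expressed = c("u1", "u2")
  )
}

# Random tripartite axis table for property tests.
random_axes <- function(n_axes, n_circ = 6, n_mir = 5, n_gene = 8) {
  tibble::tibble(
    circ_id = sample(paste0("c", seq_len(n_circ)), n_axes, replace = TRUE),
    mirna_id = sample(paste0("u", seq_len(n_mir)), n_axes, replace = TRUE),
    gene_id = sample(paste0("g", seq_len(n_gene)), n_axes, replace = TRUE)
  )
}

# Small count fixture: deterministic 2-group matrix.
toy_counts <- function(counts, samples = NULL) {
  n <- ncol(counts)
  if (is.null(samples)) {
    samples <- c(paste0("t", seq_len(n / 2)), paste0("k", seq_len(n / 2)))
  }
  tbl <- tibble::as_tibble(as.data.frame(counts))
  names(tbl) <- samples
  dplyr::bind_cols(tibble::tibble(feature_id = paste0("f", seq_len(nrow(counts)))), tbl)
}

# matrix view of a counts tibble for handing to external packages
counts_to_matrix_for_test <- function(tbl) {
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl[[1]]
  m
}

toy_groups <- function(counts_tbl) {
  s <- names(counts_tbl)[-1]
  stats::setNames(ifelse(startsWith(s, "t"), "treated", "control"), s)
}
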