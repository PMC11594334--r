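#' One-sided Pearson correlation test
#'
#' Tests for positive correlation: `r` is the sample Pearson coefficient and
#' the p-value is the upper tail of `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero variance.
#' @return A one-row tibble with `r` and `p_value`.
#' @examples
#' pearson_one_sided(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
pearson_one_sided <- function(x, y) {
  if (length(x) != length(y)) stop_spongenet("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stop_spongenet("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_spongenet("constant vector: correlation undefined")
  }
  r <- cor(x, y)
  tibble(r = r, p_value = r_to_p_greater(r, n))
}

# upper-tail p for positive correlation from r and n
r_to_p_greater <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  t[r == 1] <- Inf
  t[r == -1] <- -Inf
  pt(t, df = n - 2, lower.tail = FALSE)
}

#' Screen circRNA-mRNA pairs by positive co-expression
#'
#' Every circRNA profile is tested against every mRNA profile across the same
#' ordered samples with the one-sided (positive) Pearson test; p-values are
#' BH-adjusted jointly over all tested combinations, and pairs are retained
#' when `r > r_min` and `adj_p < max_adj_p` (both strict). Expression is
#' expected on a variance-stabilised scale (log2-CPM); correlate DE circRNAs
#' against DE mRNAs of the same model to reproduce the standard screen.
#'
#' @param circ_expr,mrna_expr Expression tibbles (feature_id + one column per
#'   sample) sharing the same ordered sample set.
#' @param r_min Correlation cutoff (default 0.90, strict `>`).
#' @param max_adj_p BH-adjusted p cutoff (default 0.05, strict `<`).
#' @param keep_all Return all tested combinations instead of only the
#'   retained pairs (the retention rule is then in column `retained`).
#' @return Tibble with `circ_id`, `gene_id`, `r`, `p_value`, `adj_p`,
#'   `n_samples` (and `retained` when `keep_all = TRUE`), sorted by `adj_p`.
#' @export
coexpressed_pairs <- function(circ_expr, mrna_expr, r_min = 0.90,
                              max_adj_p = 0.05, keep_all = FALSE) {
  cm <- expr_to_matrix(circ_expr)
  mm <- expr_to_matrix(mrna_expr)
  if (!identical(colnames(cm), colnames(mm))) {
    stop_spongenet("circRNA and mRNA matrices must share the same ordered sample set")
  }
  n <- ncol(cm)
  if (n < 3) stop_spongenet("need at least 3 samples")
  if (nrow(cm) == 0 || nrow(mm) == 0) {
    return(tibble(circ_id = character(), gene_id = character(), r = numeric(),
                  p_value = numeric(), adj_p = numeric(), n_samples = integer()))
  }
  const_c <- apply(cm, 1, stats::sd) == 0
  const_m <- apply(mm, 1, stats::sd) == 0
  if (any(const_c) || any(const_m)) {
    stop_spongenet(paste0("constant expression profile: '",
                          c(rownames(cm)[const_c], rownames(mm)[const_m])[1], "'"))
  }
  r <- cor(t(cm), t(mm))
  out <- tibble(
    circ_id = rep(rownames(cm), times = nrow(mm)),
    gene_id = rep(rownames(mm), each = nrow(cm)),
    r = as.numeric(r),
    p_value = as.numeric(r_to_p_greater(r, n))
  )
  out$adj_p <- bh_adjust(out$p_value)
  out$n_samples <- n
  out$retained <- out$r > r_min & out$adj_p < max_adj_p
  out <- arrange(out, .data$adj_p, .data$p_value, .data$circ_id, .data$gene_id)
  if (!keep_all) {
    out <- filter(out, .data$retained)
    out$retained <- NULL
  }
  out
}
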