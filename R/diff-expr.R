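#' Counts per million
#'
#' CPM normalises each sample by its (effective) library size:
#' `cpm_ij = counts_ij * 1e6 / lib_j`. The log2 variant adds a prior count
#' (0.5 by default, expressed in raw-count units and converted to the CPM
#' scale of each library) before taking logs, so all-zero features map to a
#' finite floor.
#'
#' @param counts Counts tibble (feature_id + sample columns).
#' @param log2 Return `log2(CPM + prior)` instead of CPM.
#' @param prior_count Prior count (raw-count units) for the log transform.
#' @param lib_sizes Optional effective library sizes (named by sample, or in
#'   column order); defaults to column sums.
#' @return A tibble with the same shape as `counts`.
#' @export
cpm <- function(counts, log2 = FALSE, prior_count = 0.5, lib_sizes = NULL) {
  m <- counts_to_matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (!is.null(names(lib_sizes))) lib_sizes <- lib_sizes[colnames(m)]
  if (any(lib_sizes <= 0) || anyNA(lib_sizes)) {
    stop_spongenet("every library size must be > 0")
  }
  out <- sweep(m, 2, lib_sizes / 1e6, "/")
  if (log2) {
    # prior on the CPM scale of each library, as in standard log-CPM practice
    prior_cpm <- prior_count / lib_sizes * 1e6
    out <- base::log2(sweep(out, 2, prior_cpm, "+"))
  }
  res <- as_tibble(as.data.frame(out))
  res <- dplyr::bind_cols(counts[, 1, drop = FALSE], res)
  names(res) <- names(counts)
  res
}

#' Trimmed mean of M-values normalisation factors
#'
#' Estimates per-sample scaling factors compensating for composition bias
#' between libraries: for each sample vs the reference, feature-wise
#' log-ratios (M) and average log-abundances (A) are computed on CPM, the
#' most extreme 30% of M and 5% of A are trimmed, and the factor is the
#' precision-weighted mean of the remaining M values. The reference sample is
#' the library whose upper quartile is closest to the mean upper quartile.
#' Factors are rescaled so their geometric mean is 1; they multiply library
#' sizes to give effective sizes.
#'
#' @param counts Counts tibble, at least two samples.
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @return Named numeric vector of factors (one per sample).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- counts_to_matrix(counts)
  if (ncol(m) < 2) stop_spongenet("TMM needs at least two samples")
  lib <- colSums(m)
  if (any(lib == 0)) stop_spongenet("sample with all-zero counts")
  uq <- apply(m, 2, function(x) quantile(x[x > 0], 0.75) / sum(x))
  ref_j <- which.min(abs(uq - mean(uq)))
  p <- sweep(m, 2, lib, "/")  # proportions
  ref <- p[, ref_j]
  f <- vapply(seq_len(ncol(m)), function(j) {
    obs <- p[, j]
    keep <- obs > 0 & ref > 0
    if (!any(keep)) return(1)
    M <- base::log2(obs[keep] / ref[keep])
    A <- 0.5 * base::log2(obs[keep] * ref[keep])
    # asymptotic delta-method weights (inverse variances of M)
    w <- 1 / ((1 - p[keep, j]) / (lib[j] * p[keep, j]) +
                (1 - ref[keep]) / (lib[ref_j] * ref[keep]))
    lo_m <- quantile(M, trim_m); hi_m <- quantile(M, 1 - trim_m)
    lo_a <- quantile(A, trim_a); hi_a <- quantile(A, 1 - trim_a)
    sel <- M >= lo_m & M <= hi_m & A >= lo_a & A <= hi_a
    if (!any(sel)) return(1)
    2^(sum(w[sel] * M[sel]) / sum(w[sel]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))  # geometric mean 1
  setNames(f, colnames(m))
}

#' Differential-expression thresholds
#'
#' Two preset regimes are used for calling features differentially expressed:
#' circRNAs at raw `p < 0.05` and linear fold change `> 2`, mRNAs at BH
#' `FDR < 0.05` and fold change `> 1.5`. All inequalities are strict.
#'
#' @param max_p Raw p-value cutoff, or `NULL` to skip.
#' @param max_fdr BH-adjusted cutoff, or `NULL` to skip.
#' @param min_linear_fc Linear fold-change cutoff (> 1); applied as
#'   `|log2_fc| > log2(min_linear_fc)`.
#' @return A `de_thresholds` list.
#' @export
de_thresholds <- function(max_p = NULL, max_fdr = NULL, min_linear_fc = 2) {
  if (min_linear_fc <= 1) stop_spongenet("`min_linear_fc` must be > 1")
  structure(list(max_p = max_p, max_fdr = max_fdr, min_linear_fc = min_linear_fc),
            class = "de_thresholds")
}

#' @rdname de_thresholds
#' @export
circ_de_thresholds <- function() de_thresholds(max_p = 0.05, min_linear_fc = 2)

#' @rdname de_thresholds
#' @export
mrna_de_thresholds <- function() de_thresholds(max_fdr = 0.05, min_linear_fc = 1.5)

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_(j>=i) p_(j) * m / j`, clipped at 1
#' and returned in input order. Delegates to [stats::p.adjust()] after
#' validating the input range.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop_spongenet("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential-expression test for count matrices
#'
#' Two test methods over a treated-vs-control design:
#'
#' * `nb_exact` — exact conditional negative-binomial test. Counts are scaled
#'   to a common effective library size (TMM-normalised) and rounded to
#'   pseudo-counts; a single common dispersion is estimated by method of
#'   moments pooled across features; per feature, the treated-group total is
#'   tested against its conditional distribution given the grand total, with
#'   the two-sided p-value summing all outcomes no more probable than the
#'   observed one. Degenerates to the conditional binomial (Poisson) test
#'   when the dispersion estimate is zero.
#' * `welch_logcpm` — two-sample unequal-variance t-test on log2-CPM.
#'
#' @param counts Counts tibble.
#' @param groups Named vector (or two-column data frame) mapping every sample
#'   to `"treated"`/`"control"`; defaults to the `"groups"` attribute set by
#'   [read_count_matrix()]. Both groups need at least two replicates.
#' @param method `"nb_exact"` (default) or `"welch_logcpm"`.
#' @param normalize Apply TMM factors to library sizes.
#' @return A tibble of class `cerna_de` with one row per feature:
#'   `feature_id`, `log2_fc` (treated vs control), `p_value`, `fdr`
#'   (BH over all tested features), `mean_cpm`, `direction` (`"up"`/`"down"`).
#'   The common dispersion estimate is attached as attribute `"dispersion"`.
#' @export
de_test <- function(counts, groups = NULL,
                    method = c("nb_exact", "welch_logcpm"), normalize = TRUE) {
  method <- match.arg(method)
  groups <- check_groups(counts, groups %||% attr(counts, "groups"))
  if (sum(groups == "treated") < 2 || sum(groups == "control") < 2) {
    stop_spongenet("need at least two replicates per group")
  }
  m <- counts_to_matrix(counts)
  lib <- colSums(m)
  if (any(lib == 0)) stop_spongenet("sample with all-zero counts")
  eff <- if (normalize) lib * tmm_factors(counts) else lib
  trt <- groups == "treated"

  cpm_m <- sweep(m, 2, eff / 1e6, "/")
  mean_cpm <- rowMeans(cpm_m)
  prior_cpm <- 0.5 / mean(eff) * 1e6
  log2_fc <- base::log2((rowMeans(cpm_m[, trt, drop = FALSE]) + prior_cpm) /
                          (rowMeans(cpm_m[, !trt, drop = FALSE]) + prior_cpm))

  if (method == "welch_logcpm") {
    lg <- counts_to_matrix(cpm(counts, log2 = TRUE, lib_sizes = eff))
    p <- welch_rows(lg[, trt, drop = FALSE], lg[, !trt, drop = FALSE])
    phi <- NA_real_
  } else {
    # pseudo-counts at a common library size
    L0 <- exp(mean(log(eff)))
    ps <- round(sweep(m, 2, L0 / eff, "*"))
    phi <- common_dispersion_mom(ps, trt)
    p <- nb_exact_rows(ps, trt, phi)
  }
  res <- tibble(
    feature_id = rownames(m),
    log2_fc = as.numeric(log2_fc),
    p_value = pmin(pmax(p, 0), 1),
    fdr = bh_adjust(pmin(pmax(p, 0), 1)),
    mean_cpm = as.numeric(mean_cpm),
    direction = ifelse(log2_fc >= 0, "up", "down")
  )
  structure(res, class = c("cerna_de", class(res)),
            method = method, dispersion = phi)
}

# Method-of-moments common NB dispersion from library-equalised
# pseudo-counts: ratio-of-sums estimator
#   phi = sum_i sum_g (v_ig - m_ig) / sum_i sum_g (m_ig^2 - v_ig / n)
# over within-group sample moments (the v/n term debiases the squared
# mean). Features with an apparent fold change beyond 2 between groups are
# excluded first: under the null essentially nothing is excluded (the
# estimator stays unbiased), while strongly responding features — whose
# condition-driven variability is not the sampling dispersion being
# estimated — cannot inflate the common value.
common_dispersion_mom <- function(ps, trt) {
  mA <- rowMeans(ps[, trt, drop = FALSE])
  mB <- rowMeans(ps[, !trt, drop = FALSE])
  keep <- abs(base::log2((mA + 0.5) / (mB + 0.5))) <= 1
  if (!any(keep)) keep <- rep(TRUE, nrow(ps))
  num <- 0; den <- 0
  for (sel in list(trt, !trt)) {
    x <- ps[keep, sel, drop = FALSE]
    n <- ncol(x)
    mb <- rowMeans(x)
    v <- apply(x, 1, var)
    num <- num + sum(v - mb)
    den <- den + sum(pmax(mb^2 - v / n, mb^2 * 0.1))
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

# Exact conditional NB test per feature: treated total A vs grand total s.
# Under equal means and equalised library sizes, A | s follows the ratio of
# NB convolutions; p sums P(x) over all x with P(x) <= P(a_obs).
nb_exact_rows <- function(ps, trt, phi) {
  nA <- sum(trt); nB <- sum(!trt)
  a_all <- rowSums(ps[, trt, drop = FALSE])
  s_all <- a_all + rowSums(ps[, !trt, drop = FALSE])
  vapply(seq_along(a_all), function(i) {
    s <- s_all[i]; a <- a_all[i]
    if (s == 0) return(1)
    x <- 0:s
    if (phi <= 1e-8) {
      ld <- stats::dbinom(x, s, nA / (nA + nB), log = TRUE)
    } else {
      rA <- nA / phi; rB <- nB / phi
      ld <- dnbinom(x, size = rA, prob = 0.5, log = TRUE) +
        dnbinom(s - x, size = rB, prob = 0.5, log = TRUE)
      ld <- ld - logsumexp(ld)
    }
    min(1, sum(exp(ld[ld <= ld[a + 1] + 1e-10])))
  }, numeric(1))
}

# Row-wise Welch t-test (two-sided) on a log-expression matrix.
welch_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # no variance, no evidence
  p
}

#' Call differentially expressed features
#'
#' Applies a [de_thresholds()] regime to a `cerna_de` result table with
#' strict inequalities: `p_value < max_p` (if set), `fdr < max_fdr` (if set),
#' `|log2_fc| > log2(min_linear_fc)`.
#'
#' @param results A `cerna_de` tibble (features jointly BH-adjusted).
#' @param thresholds A [de_thresholds()] object.
#' @return The subset of `results` passing all cuts (possibly empty).
#' @export
apply_thresholds <- function(results, thresholds) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  keep <- abs(results$log2_fc) > base::log2(thresholds$min_linear_fc)
  if (!is.null(thresholds$max_p)) keep <- keep & results$p_value < thresholds$max_p
  if (!is.null(thresholds$max_fdr)) keep <- keep & results$fdr < thresholds$max_fdr
  results[keep, , drop = FALSE]
}

#' Write a DE result table
#'
#' @param results `cerna_de` tibble.
#' @param path Output TSV path.
#' @export
write_de_results <- function(results, path) {
  readr::write_tsv(as_tibble(results), path, progress = FALSE)
  invisible(path)
}
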