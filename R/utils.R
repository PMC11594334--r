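#' @importFrom rlang abort %||% .data
#' @importFrom dplyr filter mutate select arrange left_join inner_join distinct
#'   group_by summarise ungroup bind_rows rename pull n across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats cor pt p.adjust dhyper dnbinom dbinom rnbinom rlnorm rnorm
#'   runif setNames quantile var sd median
NULL

# Stop with a classed condition so callers can distinguish user errors.
stop_spongenet <- function(msg, class = "spongenet_error", ...) {
  abort(msg, class = c(class, "spongenet_error"), ...)
}

is_count_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x == floor(x))
}

# Coerce a counts table (feature_id + one numeric column per sample) to a
# base matrix with feature rownames. The first column is taken as the ID.
counts_to_matrix <- function(counts) {
  check_counts_tbl(counts)
  expr_to_matrix(counts)
}

# Same coercion for general expression tables (log-CPM may be negative).
expr_to_matrix <- function(tbl) {
  if (!is.data.frame(tbl) || ncol(tbl) < 2) {
    stop_spongenet("expected a data frame with a feature-ID column followed by sample columns")
  }
  if (anyDuplicated(tbl[[1]])) stop_spongenet("duplicate feature IDs")
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop_spongenet("non-numeric or missing expression values")
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tbl[[1]])
  m
}

check_counts_tbl <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    stop_spongenet("`counts` must be a data frame with a feature-ID column followed by one column per sample.")
  }
  ids <- as.character(counts[[1]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop_spongenet(paste0("duplicate feature ID: '", dup, "'"))
  }
  num <- counts[, -1, drop = FALSE]
  ok <- vapply(num, is.numeric, logical(1))
  if (!all(ok)) {
    stop_spongenet(paste0("non-numeric sample column: '", names(num)[!ok][1], "'"))
  }
  if (anyNA(num)) stop_spongenet("counts contain missing values")
  if (any(vapply(num, function(x) any(x < 0), logical(1)))) {
    stop_spongenet("counts contain negative entries")
  }
  invisible(counts)
}

sample_ids <- function(counts) names(counts)[-1]

# Validate a sample -> {treated, control} mapping against a counts table.
check_groups <- function(counts, groups, require_both = TRUE) {
  samples <- sample_ids(counts)
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups[[2]]), as.character(groups[[1]]))
  }
  if (is.null(names(groups)) || anyNA(names(groups))) {
    stop_spongenet("`groups` must be named by sample ID (or be a two-column data frame).")
  }
  missing <- setdiff(names(groups), samples)
  if (length(missing) > 0) {
    stop_spongenet(paste0("sample in group map absent from counts: '", missing[1], "'"))
  }
  absent <- setdiff(samples, names(groups))
  if (length(absent) > 0) {
    stop_spongenet(paste0("sample without group label: '", absent[1], "'"))
  }
  bad <- setdiff(unique(groups), c("treated", "control"))
  if (length(bad) > 0) {
    stop_spongenet(paste0("group labels must be 'treated'/'control', got '", bad[1], "'"))
  }
  if (require_both && length(unique(groups)) < 2) {
    stop_spongenet("both 'treated' and 'control' samples are required")
  }
  groups[samples]
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
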