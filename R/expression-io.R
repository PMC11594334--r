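#' Parse back-spliced-junction circRNA identifiers
#'
#' circRNAs are conventionally identified by the genomic coordinates of their
#' back-spliced junction (BSJ) in the form `"chrom:start|end"`, e.g.
#' `"chr4:73956384|73958017"`. Coordinates are 1-based and inclusive, per the
#' CIRI/CIRIquant convention; strand is not part of the identifier.
#'
#' @param x Character vector of circRNA identifiers.
#' @return A tibble with columns `circ_id`, `chromosome`, `start`, `end`.
#'   `format_circ_id()` is its exact inverse: formatting the parsed fields
#'   reproduces the input string byte-for-byte.
#' @examples
#' parse_circ_id("chr4:73956384|73958017")
#' @export
parse_circ_id <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^([^:|[:space:]]+):([0-9]+)\\|([0-9]+)$", x))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    stop_spongenet(paste0("malformed circRNA ID: '", x[bad][1],
                          "' (expected \"chrom:start|end\")"),
                   class = "spongenet_parse_error")
  }
  chrom <- vapply(m, `[[`, character(1), 2)
  start <- as.numeric(vapply(m, `[[`, character(1), 3))
  end <- as.numeric(vapply(m, `[[`, character(1), 4))
  rev <- start > end
  if (any(rev)) {
    stop_spongenet(paste0("start > end in circRNA ID: '", x[rev][1], "'"),
                   class = "spongenet_parse_error")
  }
  tibble(circ_id = x, chromosome = chrom, start = start, end = end)
}

#' @rdname parse_circ_id
#' @param chromosome,start,end Parsed coordinate fields (vectors or a tibble
#'   as returned by `parse_circ_id()` passed as `chromosome`).
#' @export
format_circ_id <- function(chromosome, start = NULL, end = NULL) {
  if (is.data.frame(chromosome)) {
    start <- chromosome$start
    end <- chromosome$end
    chromosome <- chromosome$chromosome
  }
  sprintf("%s:%s|%s", chromosome, format(start, scientific = FALSE, trim = TRUE),
          format(end, scientific = FALSE, trim = TRUE))
}

#' Read and write count matrices
#'
#' Count tables are TSV with a header row: the first column holds feature IDs,
#' the remaining columns one sample each. Counts must be non-negative
#' integers. gzip-compressed files are accepted by extension.
#'
#' @param path Path to a TSV (optionally `.gz`).
#' @param group_map Optional named character vector (or two-column data frame)
#'   mapping every sample ID to `"treated"` or `"control"`. When supplied it
#'   is validated against the header and attached as the `"groups"` attribute.
#' @return A tibble (feature_id + sample columns).
#' @export
read_count_matrix <- function(path, group_map = NULL) {
  if (!file.exists(path)) stop_spongenet(paste0("file not found: ", path))
  header <- strsplit(readr::read_lines(path, n_max = 1, progress = FALSE), "\t")[[1]]
  if (length(header) < 2) stop_spongenet("count table needs a feature-ID column plus sample columns")
  # first column is the feature ID regardless of its header label
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = paste0("c", strrep("d", length(header) - 1)),
                         name_repair = "minimal")
  if (nrow(readr::problems(tbl)) > 0 || anyNA(tbl)) {
    stop_spongenet("count table has missing or non-numeric entries (ragged rows?)")
  }
  num <- tbl[, -1, drop = FALSE]
  if (any(vapply(num, function(x) any(x < 0 | x != floor(x)), logical(1)))) {
    stop_spongenet("counts must be non-negative integers")
  }
  check_counts_tbl(tbl)
  if (!is.null(group_map)) {
    attr(tbl, "groups") <- check_groups(tbl, group_map)
  }
  tbl
}

#' @rdname read_count_matrix
#' @param counts A counts tibble.
#' @export
write_count_matrix <- function(counts, path) {
  check_counts_tbl(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Junction-read confidence filter
#'
#' Retains a feature when at least `ceiling(min_sample_fraction * n_samples)`
#' samples have `min_reads` or more supporting reads — by default a minimum
#' of two junction reads in at least half of the samples, the standard
#' high-confidence cutoff for BSJ-quantified circRNAs. The same rule, with
#' `min_reads = 1`, serves as the miRNA expression gate.
#'
#' @param counts Counts tibble (feature_id + sample columns).
#' @param min_reads Minimum reads for a sample to support a feature.
#' @param min_sample_fraction Fraction of samples that must reach `min_reads`.
#' @return The filtered counts tibble; sample set and feature order unchanged.
#' @examples
#' m <- tibble::tibble(feature_id = c("a", "b"),
#'                     s1 = c(2, 2), s2 = c(2, 2), s3 = c(2, 0),
#'                     s4 = c(0, 0), s5 = c(0, 0), s6 = c(0, 0))
#' filter_by_junction_reads(m)  # keeps "a" only
#' @export
filter_by_junction_reads <- function(counts, min_reads = 2, min_sample_fraction = 0.5) {
  check_counts_tbl(counts)
  if (nrow(counts) == 0) stop_spongenet("empty count matrix")
  if (min_reads < 0) stop_spongenet("`min_reads` must be >= 0")
  if (min_sample_fraction <= 0 || min_sample_fraction > 1) {
    stop_spongenet("`min_sample_fraction` must be in (0, 1]")
  }
  m <- counts_to_matrix(counts)
  need <- ceiling(min_sample_fraction * ncol(m))
  keep <- rowSums(m >= min_reads) >= need
  out <- counts[keep, , drop = FALSE]
  attr(out, "groups") <- attr(counts, "groups")
  out
}

#' Read a one-ID-per-line annotation list
#'
#' Used for e.g. the disease-associated miRNA list. Blank lines and lines
#' starting with `#` are skipped; duplicates are collapsed.
#'
#' @param path Path to a plain-text file, one identifier per line.
#' @return Character vector of unique IDs.
#' @export
read_annotation_list <- function(path) {
  if (!file.exists(path)) stop_spongenet(paste0("file not found: ", path))
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' @rdname read_annotation_list
#' @param ids Character vector of IDs to write.
#' @export
write_annotation_list <- function(ids, path) {
  readr::write_lines(unique(as.character(ids)), path)
  invisible(path)
}

#' Read a miRNA-to-gene target table
#'
#' A TargetScan-like two-column TSV (`mirna_id`, `gene_id`); a header row is
#' detected by name and otherwise the first row is treated as data.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `mirna_id`, `gene_id` (duplicates collapsed).
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stop_spongenet(paste0("file not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = "cc", col_names = FALSE)
  if (ncol(tbl) < 2) stop_spongenet("target table must have two tab-separated columns")
  names(tbl)[1:2] <- c("mirna_id", "gene_id")
  if (tolower(tbl$mirna_id[1]) %in% c("mirna", "mirna_id", "mir", "mir_id")) {
    tbl <- tbl[-1, , drop = FALSE]
  }
  if (any(!nzchar(tbl$mirna_id)) || any(!nzchar(tbl$gene_id)) || anyNA(tbl)) {
    stop_spongenet("malformed target-table row (empty field)")
  }
  distinct(tbl[, c("mirna_id", "gene_id")])
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings that return sequences as a tidy tibble.
#' `T` and `U` are both accepted; sequences are kept verbatim and normalised
#' only inside the seed-site scanner.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id` (first word of the header) and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_spongenet(paste0("file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  tibble(id = sub("\\s.*$", "", names(ss)), seq = unname(as.character(ss)))
}

#' @rdname read_fasta
#' @param seqs Tibble with `id` and `seq` columns (or a named character vector).
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
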