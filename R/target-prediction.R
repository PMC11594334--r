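# Canonical miRNA seed-site classes, weakest to strongest.
SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

normalize_rna <- function(seq, what = "sequence") {
  s <- toupper(seq)
  s <- chartr("T", "U", s)
  bad <- grepl("[^ACGU]", s)
  if (any(bad)) {
    ch <- sub(".*?([^ACGU]).*", "\\1", s[bad][1])
    stop_spongenet(paste0("invalid character '", ch, "' in ", what,
                          " (expected A/C/G/U/T)"))
  }
  s
}

revcomp_rna <- function(s) {
  vapply(strsplit(chartr("ACGU", "UGCA", s), ""), function(x)
    paste(rev(x), collapse = ""), character(1))
}

#' Circularise a sequence for junction-aware scanning
#'
#' Appends the first `overhang` bases of the sequence to its end so that
#' sites spanning the back-spliced junction (position 0 of the circle) fall
#' inside a linear window. The default overhang of 7 is one less than the
#' longest site length (8), the minimum guaranteeing every junction-spanning
#' site is seen.
#'
#' @param seq A nucleotide string.
#' @param overhang Number of leading bases to append; must be < `nchar(seq)`.
#' @return The extended string.
#' @examples
#' circularize("ACGTACGT", 3)  # "ACGTACGTACG"
#' @export
circularize <- function(seq, overhang = 7) {
  if (length(seq) != 1) stop_spongenet("`seq` must be a single string")
  if (overhang < 0) stop_spongenet("`overhang` must be >= 0")
  if (overhang >= nchar(seq)) {
    stop_spongenet("`overhang` must be smaller than the sequence length")
  }
  paste0(seq, substr(seq, 1, overhang))
}

#' Scan a circRNA sequence for miRNA seed sites
#'
#' Slides an 8-nt window over the circularised sequence and reports
#' canonical seed matches to the miRNA. Writing the window 5'->3' on the
#' target as `w[1..8]`, a site requires `w[2..7]` to equal the reverse
#' complement of miRNA positions 2-7 (the seed). Classification:
#'
#' * `8mer` — seed plus Watson-Crick match of `w[1]` to miRNA position 8
#'   plus `A` at `w[8]` (the base opposite miRNA position 1);
#' * `7mer-m8` — seed plus the position-8 match;
#' * `7mer-A1` — seed plus the `A`;
#' * `6mer` — seed only.
#'
#' Each site gets exactly one type, the strongest applicable. Site starts are
#' 0-based offsets of the 8-nt window on the circular sequence (modulo its
#' length; duplicates introduced by the overhang are removed), and
#' `spans_bsj` flags windows crossing the back-spliced junction.
#'
#' @param circ_seq circRNA sequence (the linear BSJ transcript; treated as
#'   circular). `T`/`U` interchangeable.
#' @param mirna_seq Mature miRNA sequence, length >= 8.
#' @param circ_id,mirna_id Identifiers carried into the output.
#' @return Tibble: `circ_id`, `mirna_id`, `site_type`, `start`, `spans_bsj`.
#' @export
scan_mre <- function(circ_seq, mirna_seq, circ_id = "circ", mirna_id = "mirna") {
  circ <- normalize_rna(circ_seq, "circRNA sequence")
  mir <- normalize_rna(mirna_seq, "miRNA sequence")
  if (nchar(mir) < 8) stop_spongenet("miRNA must be at least 8 nt")
  L <- nchar(circ)
  if (L < 8) stop_spongenet("circRNA sequence must be at least 8 nt")
  ext <- circularize(circ, 7)
  starts <- 0:(L - 1)
  win <- substring(ext, starts + 1, starts + 8)
  seed_rc <- revcomp_rna(substr(mir, 2, 7))        # expected w[2..7]
  m8_base <- chartr("ACGU", "UGCA", substr(mir, 8, 8))  # expected w[1]
  seed_hit <- substr(win, 2, 7) == seed_rc
  if (!any(seed_hit)) {
    return(tibble(circ_id = character(), mirna_id = character(),
                  site_type = character(), start = integer(),
                  spans_bsj = logical()))
  }
  w <- win[seed_hit]
  s <- starts[seed_hit]
  m8 <- substr(w, 1, 1) == m8_base
  a1 <- substr(w, 8, 8) == "A"
  type <- ifelse(m8 & a1, "8mer",
                 ifelse(m8, "7mer-m8", ifelse(a1, "7mer-A1", "6mer")))
  tibble(circ_id = circ_id, mirna_id = mirna_id, site_type = type,
         start = as.integer(s), spans_bsj = s + 8 > L)
}

#' @rdname scan_mre
#' @param circ_seqs,mirna_seqs Sequence tibbles (`id`, `seq`) as returned by
#'   [read_fasta()]; all circRNA x miRNA combinations are scanned.
#' @export
scan_mre_all <- function(circ_seqs, mirna_seqs) {
  grid <- tidyr::expand_grid(ci = seq_len(nrow(circ_seqs)),
                             mi = seq_len(nrow(mirna_seqs)))
  purrr::pmap_dfr(grid, function(ci, mi) {
    scan_mre(circ_seqs$seq[ci], mirna_seqs$seq[mi],
             circ_id = circ_seqs$id[ci], mirna_id = mirna_seqs$id[mi])
  })
}

#' Derive circRNA-miRNA interactions from seed sites
#'
#' A circRNA is taken to sponge a miRNA when it carries at least one seed
#' site of the requested class or stronger (order
#' `8mer > 7mer-m8 > 7mer-A1 > 6mer`). The default, `7mer-A1`, excludes
#' marginal 6mer-only matches.
#'
#' @param sites Site tibble from [scan_mre()] / [scan_mre_all()].
#' @param min_site_type Weakest site class that counts as an interaction.
#' @return Tibble of distinct (`circ_id`, `mirna_id`) pairs.
#' @export
circ_mir_interactions <- function(sites, min_site_type = "7mer-A1") {
  min_site_type <- match.arg(min_site_type, SITE_TYPES)
  rank <- match(sites$site_type, SITE_TYPES)
  if (anyNA(rank)) stop_spongenet("unknown site type in `sites`")
  distinct(sites[rank >= match(min_site_type, SITE_TYPES),
                 c("circ_id", "mirna_id"), drop = FALSE])
}

#' Filter a miRNA-target table to differentially expressed mRNAs
#'
#' @param target_table Tibble (`mirna_id`, `gene_id`), e.g. from
#'   [read_target_table()].
#' @param de_mrna Character vector of DE gene IDs.
#' @return Tibble of distinct (`mirna_id`, `gene_id`) pairs with the gene DE.
#' @export
mir_mrna_interactions <- function(target_table, de_mrna) {
  if (!all(c("mirna_id", "gene_id") %in% names(target_table))) {
    stop_spongenet("`target_table` needs columns mirna_id, gene_id")
  }
  distinct(filter(target_table, .data$gene_id %in% de_mrna)[, c("mirna_id", "gene_id")])
}

#' Expressed miRNAs under the count-based rule
#'
#' Same rule as the junction filter: a miRNA is expressed when at least
#' `ceiling(min_sample_fraction * n)` samples show `min_count` or more reads.
#'
#' @param counts miRNA counts tibble.
#' @param min_count Minimum reads per supporting sample.
#' @param min_sample_fraction Fraction of samples required.
#' @return Character vector of expressed miRNA IDs.
#' @export
expressed_mirnas <- function(counts, min_count = 1, min_sample_fraction = 0.5) {
  kept <- filter_by_junction_reads(counts, min_reads = min_count,
                                   min_sample_fraction = min_sample_fraction)
  as.character(kept[[1]])
}
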