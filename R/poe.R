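#' Classify maternal-like parent-of-origin genes
#'
#' A gene shows a maternal-like parent-of-origin effect when (i) the
#' genetically identical offspring of the two reciprocal crosses differ
#' significantly in expression (q below the threshold) and (ii) the
#' direction of that difference matches the direction in which the maternal
#' strains differ. Maternal-like genes are further split by which maternal
#' strain's level the offspring track more closely — the strain whose
#' cross shows the smaller absolute log-ratio of offspring to
#' maternal-parent FPKM; significant genes with zero parental difference,
#' or exactly balanced tracking, are classed `"unresolved"`.
#'
#' @param crosses Tibble with one row per gene: `gene_id`,
#'   `parent_a`, `parent_b` (parental-strain FPKM), `offspring_ma`,
#'   `offspring_mb` (offspring FPKM of the cross with mother A resp. B),
#'   and `q` (FDR-adjusted significance of the reciprocal difference).
#' @param q_threshold Significance threshold (default 0.05).
#' @return The input with columns `maternal_like` (logical) and
#'   `resembles` (`"A"`, `"B"`, `"unresolved"`, or `NA` when not
#'   maternal-like) appended.
#' @export
maternal_like_genes <- function(crosses, q_threshold = 0.05) {
  need <- c("gene_id", "parent_a", "parent_b", "offspring_ma",
            "offspring_mb", "q")
  if (!all(need %in% names(crosses))) {
    abort(paste0("crosses must have columns: ", paste(need, collapse = ", ")))
  }
  sig <- crosses$q < q_threshold
  d_off <- crosses$offspring_ma - crosses$offspring_mb
  d_par <- crosses$parent_a - crosses$parent_b
  ml <- sig & sign(d_off) == sign(d_par) & d_par != 0 & d_off != 0
  unresolved <- sig & (d_par == 0 | d_off == 0)
  if (any(unresolved)) {
    inform(paste0(sum(unresolved), " significant gene(s) with zero",
                  " parental or offspring difference: unresolved"))
  }
  eps <- 1e-12
  da <- abs(log(pmax(crosses$offspring_ma, eps) /
                  pmax(crosses$parent_a, eps)))
  db <- abs(log(pmax(crosses$offspring_mb, eps) /
                  pmax(crosses$parent_b, eps)))
  resembles <- rep(NA_character_, nrow(crosses))
  resembles[ml] <- dplyr::case_when(da[ml] < db[ml] ~ "A",
                                    db[ml] < da[ml] ~ "B",
                                    TRUE ~ "unresolved")
  resembles[unresolved] <- "unresolved"
  mutate(crosses, maternal_like = ml, resembles = resembles)
}

#' Assign reads to parental haplotypes by exact matching
#'
#' Locus-anchored allele assignment: each read is compared with zero
#' mismatches against the substrings of both parental haplotypes at its
#' position. A read matching exactly one parent is assigned to it; matching
#' both (no covered SNP) is `"ambiguous"`; if either parental substring
#' contains an `N` anywhere under the read, the read is excluded
#' (`"excluded_N"`) even when the other parent matches. Reads matching
#' neither parent are `"ambiguous"` (with error-free reads this cannot
#' occur).
#'
#' @param reads Tibble with `seq` (read sequence, same strand as the
#'   haplotypes) and `pos` (0-based start on the haplotypes).
#' @param haplotype_a,haplotype_b Parental haplotype sequences (single
#'   character strings or `Biostrings::DNAString`), positionally aligned.
#' @return `reads` with an `assignment` column, one of `"A"`, `"B"`,
#'   `"ambiguous"`, `"excluded_N"`.
#' @export
assign_reads <- function(reads, haplotype_a, haplotype_b) {
  ha <- as.character(haplotype_a)
  hb <- as.character(haplotype_b)
  rl <- nchar(reads$seq)
  if (any(reads$pos < 0) || any(reads$pos + rl > nchar(ha)) ||
      any(reads$pos + rl > nchar(hb))) {
    abort("read extends beyond haplotype bounds")
  }
  sub_a <- substring(ha, reads$pos + 1, reads$pos + rl)
  sub_b <- substring(hb, reads$pos + 1, reads$pos + rl)
  has_n <- grepl("N", sub_a, fixed = TRUE) | grepl("N", sub_b, fixed = TRUE)
  match_a <- reads$seq == sub_a
  match_b <- reads$seq == sub_b
  assignment <- dplyr::case_when(
    has_n ~ "excluded_N",
    match_a & !match_b ~ "A",
    match_b & !match_a ~ "B",
    TRUE ~ "ambiguous"
  )
  mutate(reads, assignment = assignment)
}

#' Per-gene allele counts from assigned reads
#'
#' @param assigned Tibble from [assign_reads()] with a `gene_id` column.
#' @return Tibble `gene_id`, `reads_a`, `reads_b`, `excluded_n`,
#'   `ambiguous`.
#' @export
allele_counts <- function(assigned) {
  assigned |>
    group_by(.data$gene_id) |>
    summarise(reads_a = sum(.data$assignment == "A"),
              reads_b = sum(.data$assignment == "B"),
              excluded_n = sum(.data$assignment == "excluded_N"),
              ambiguous = sum(.data$assignment == "ambiguous"),
              .groups = "drop")
}

#' Allelic-ratio tests across genes and reciprocal crosses
#'
#' Genes are filtered to at least `min_reads` allele-specific reads
#' (`reads_a + reads_b`); the per-gene ratio is `reads_a / (reads_a +
#' reads_b)`. Genome-wide allele excess is tested with a two-sided sign
#' (exact binomial) test of per-gene ratios against 0.5. When `cross`
#' labels two reciprocal crosses, the cross-to-cross shift in ratios is
#' additionally tested with the paired signed-rank test
#' ([paired_level_test()]) over genes measured in both.
#'
#' @param counts Tibble `gene_id`, `reads_a`, `reads_b` and optionally
#'   `cross` (two levels for the paired comparison).
#' @param min_reads Minimum allele-specific reads per gene (default 100).
#' @return List with `ratios` (filtered per-gene tibble with `ratio`),
#'   `excess_test` (one-row tibble: `n_above`, `n_below`, `p`), and
#'   `cross_shift` (paired-test tibble or `NULL`).
#' @export
allelic_ratio_test <- function(counts, min_reads = 100) {
  counts <- mutate(counts, total = .data$reads_a + .data$reads_b)
  kept <- filter(counts, .data$total >= min_reads)
  if (!nrow(kept)) {
    abort(paste0("no gene reaches the ", min_reads, "-read floor"))
  }
  kept <- mutate(kept, ratio = .data$reads_a / .data$total)
  n_above <- sum(kept$ratio > 0.5)
  n_below <- sum(kept$ratio < 0.5)
  p <- if (n_above + n_below == 0) 1 else
    binom.test(n_above, n_above + n_below)$p.value
  excess <- tibble(n_above = n_above, n_below = n_below,
                   n_tied = sum(kept$ratio == 0.5), p = p)
  shift <- NULL
  if ("cross" %in% names(kept) && length(unique(kept$cross)) == 2) {
    lv <- sort(unique(kept$cross))
    wide <- kept |>
      select("gene_id", "cross", "ratio") |>
      tidyr::pivot_wider(names_from = "cross", values_from = "ratio") |>
      filter(complete.cases(.data[[lv[1]]], .data[[lv[2]]]))
    if (nrow(wide) >= 2) {
      shift <- paired_level_test(wide[[lv[1]]], wide[[lv[2]]])
      shift$cross_a <- lv[1]
      shift$cross_b <- lv[2]
    }
  }
  list(ratios = kept, excess_test = excess, cross_shift = shift)
}
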