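#' Call a gene actively transcribed
#'
#' A gene is active in a sample when its FPKM is strictly above the
#' threshold *and* at least `min_reads` reads mapped to it. Two conventional
#' FPKM thresholds are in use: 0.1 (permissive, the default) and 1
#' (conservative); both are exposed.
#'
#' @param fpkm Non-negative FPKM value(s).
#' @param mapped_reads Non-negative mapped read count(s).
#' @param fpkm_threshold Strict lower FPKM bound (default 0.1).
#' @param min_reads Minimum mapped reads (default 10).
#' @return Logical vector.
#' @export
#' @examples
#' call_active(0.5, 20)          # TRUE
#' call_active(5, 9)             # FALSE: read floor
#' call_active(0.1, 50)          # FALSE: strictly above
call_active <- function(fpkm, mapped_reads, fpkm_threshold = 0.1,
                        min_reads = 10) {
  if (any(fpkm < 0) || any(mapped_reads < 0)) {
    abort("fpkm and mapped_reads must be non-negative")
  }
  if (fpkm_threshold < 0 || min_reads < 0) abort("thresholds must be >= 0")
  fpkm > fpkm_threshold & mapped_reads >= min_reads
}

#' Add activity calls to an expression table
#'
#' Tibble-in, tibble-out wrapper over [call_active()].
#'
#' @param expression Tibble with `fpkm` and `mapped_reads` columns.
#' @inheritParams call_active
#' @return The input with a logical `active` column appended.
#' @export
annotate_activity <- function(expression, fpkm_threshold = 0.1,
                              min_reads = 10) {
  mutate(expression,
         active = call_active(.data$fpkm, .data$mapped_reads,
                              fpkm_threshold = fpkm_threshold,
                              min_reads = min_reads))
}

#' Signed fold change between two expression levels
#'
#' Returns `+a/b` when `a >= b` and `-b/a` otherwise, so the magnitude is
#' always at least 1 and the sign says which side is higher (positive =
#' higher in the first argument). Zeros are not accepted: genes with a zero
#' level in either condition are excluded upstream rather than patched with
#' a pseudocount.
#'
#' @param fpkm_a,fpkm_b Strictly positive FPKM values (vectorised).
#' @return Signed fold change(s).
#' @export
#' @examples
#' round(fold_change(1.74, 68.09), 1)  # -39.1
fold_change <- function(fpkm_a, fpkm_b) {
  if (any(fpkm_a <= 0 | fpkm_b <= 0)) {
    abort("fold_change requires strictly positive values; filter zeros first")
  }
  ifelse(fpkm_a >= fpkm_b, fpkm_a / fpkm_b, -fpkm_b / fpkm_a)
}

#' Differential-expression summary table
#'
#' Builds the per-gene Early-vs-Late record: mean FPKM in each condition,
#' signed fold change (positive = higher in Early), and BH-adjusted q when
#' per-gene p-values are supplied. Genes with zero FPKM in either condition
#' are excluded from fold-change ranking and their count reported via
#' message.
#'
#' @param expression Tibble `gene_id`, `sample_id`, `fpkm`, `mapped_reads`.
#' @param samples Sample metadata tibble with `sample_id` and `condition`
#'   (`"Early"`/`"Late"`).
#' @param p_values Optional tibble `gene_id`, `p` of externally computed
#'   differential-expression p-values; only BH adjustment and thresholding
#'   are applied here.
#' @return Tibble `gene_id`, `fpkm_early`, `fpkm_late`, `fold_change`, `p`,
#'   `q`, sorted by decreasing |fold change|.
#' @export
de_table <- function(expression, samples, p_values = NULL) {
  cond <- samples[c("sample_id", "condition")]
  wide <- expression |>
    inner_join(cond, by = "sample_id") |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(fpkm = mean(.data$fpkm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "fpkm",
                       names_prefix = "fpkm_") |>
    rename(fpkm_early = "fpkm_Early", fpkm_late = "fpkm_Late")
  zero <- wide$fpkm_early <= 0 | wide$fpkm_late <= 0
  if (any(zero)) {
    inform(paste0(sum(zero),
                  " gene(s) with zero FPKM in a condition excluded from",
                  " fold-change ranking"))
  }
  out <- wide[!zero, , drop = FALSE] |>
    mutate(fold_change = fold_change(.data$fpkm_early, .data$fpkm_late))
  if (!is.null(p_values)) {
    out <- left_join(out, p_values[c("gene_id", "p")], by = "gene_id")
    out$q <- NA_real_
    out$q[!is.na(out$p)] <- bh_adjust(out$p[!is.na(out$p)])
  } else {
    out$p <- NA_real_
    out$q <- NA_real_
  }
  arrange(out, dplyr::desc(abs(.data$fold_change)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: q(i) = min over j with
#' p(j) >= p(i) of m * p(j) / rank(j), capped at 1 and order-preserving.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) ||
      anyNA(p_values)) {
    abort("p-values must be in [0, 1] with no NA")
  }
  p.adjust(p_values, method = "BH")
}

#' X-vs-autosome transcription contrast
#'
#' Tests whether the proportion of transcribed genes differs between the X
#' chromosome and the autosomes with a 2x2 chi-square (active/inactive by
#' X/autosome), by default without continuity correction. Genes on
#' unplaced scaffolds are excluded.
#'
#' @param calls Tibble with `gene_id` and logical `active` (one row per
#'   gene).
#' @param annotation [genome_annotation()] supplying each gene's chromosome
#'   class.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `prop_x`, `prop_autosome`, `n_x`, `n_autosome`,
#'   `chi_square`, `p`.
#' @export
chromosome_activity_contrast <- function(calls, annotation, correct = FALSE) {
  df <- calls |>
    inner_join(annotation$genes[c("gene_id", "chrom")], by = "gene_id") |>
    inner_join(annotation$chromosomes[c("chrom", "chrom_class")],
               by = "chrom") |>
    filter(.data$chrom_class != "unplaced")
  if (!all(c("X", "autosome") %in% df$chrom_class)) {
    abort("need at least one gene in each of the X and autosome classes")
  }
  tab <- table(factor(df$chrom_class, levels = c("X", "autosome")),
               factor(df$active, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate 2x2 table: a margin is empty")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble(
    prop_x = tab["X", "TRUE"] / sum(tab["X", ]),
    prop_autosome = tab["autosome", "TRUE"] / sum(tab["autosome", ]),
    n_x = sum(tab["X", ]), n_autosome = sum(tab["autosome", ]),
    chi_square = unname(ct$statistic), p = ct$p.value
  )
}

#' Paired signed-rank level test
#'
#' Wilcoxon matched-pairs signed-rank test with the tie-corrected normal
#' approximation, exposing the Z statistic. Zero differences are dropped
#' (an error if all are zero); with fewer than 10 informative pairs the
#' normal approximation is unreliable and a warning is issued.
#'
#' @param values_a,values_b Equal-length paired numeric vectors (per gene).
#' @return One-row tibble: `z`, `p`, `n` (informative pairs), `w` (sum of
#'   positive signed ranks).
#' @export
paired_level_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    abort("paired vectors must have equal length")
  }
  d <- values_a - values_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("all paired differences are zero: no signal to test")
  if (n < 10) warn("fewer than 10 informative pairs: normal approximation unreliable")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_plus - mu) / sqrt(sigma2)
  tibble(z = z, p = 2 * pnorm(-abs(z)), n = n, w = w_plus)
}
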