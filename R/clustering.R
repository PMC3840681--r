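#' Ordered activity sequence along the genome
#'
#' Genes are ordered by (chrom, start, end, gene_id); overlapping genes each
#' contribute one label in that order. Genes lacking a call are dropped
#' with a message.
#'
#' @param annotation [genome_annotation()].
#' @param calls Tibble with `gene_id` and logical `active`.
#' @return Tibble `chrom`, `gene_id`, `active` in genomic order.
#' @export
activity_sequence <- function(annotation, calls) {
  seqs <- annotation$genes |>
    left_join(calls[c("gene_id", "active")], by = "gene_id")
  if (anyNA(seqs$active)) {
    inform(paste0(sum(is.na(seqs$active)), " gene(s) without an activity",
                  " call dropped from the ordered sequence"))
    seqs <- filter(seqs, !is.na(.data$active))
  }
  seqs[c("chrom", "gene_id", "active")]
}

count_runs <- function(labels) {
  if (!length(labels)) return(0L)
  1L + sum(labels[-1] != labels[-length(labels)])
}

runs_moments <- function(n1, n2) {
  n <- n1 + n2
  e <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  c(e = e, v = v)
}

#' Wald-Wolfowitz runs test for clustering of expressed genes
#'
#' Tests whether active and inactive genes are randomly interleaved along
#' the genome. Runs (maximal stretches of one label) are counted within each
#' chromosome — chromosome junctions never create artificial switches — and
#' either summed with per-chromosome moments (`mode = "per_chromosome"`,
#' the default) or the genome is treated as one concatenated sequence
#' (`mode = "genome"`). Physical clustering of expressed genes manifests as
#' fewer runs than expected, i.e. `z < 0`.
#'
#' @param sequence Tibble with logical `active` and (for the default mode) a
#'   `chrom` column, in genomic order — see [activity_sequence()]. A bare
#'   logical vector is treated as a single chromosome.
#' @param mode `"per_chromosome"` or `"genome"`.
#' @return Object of class `runs_test` with fields `n_runs`, `n_active`,
#'   `n_inactive`, `expected_runs`, `variance_runs`, `z`, `p` (two-sided,
#'   normal approximation), `mean_active_cluster_size`, and the
#'   per-chromosome breakdown in `$by_chrom`. `z`/`p` are `NA` with an
#'   explanation when only one label is present.
#' @export
runs_test <- function(sequence, mode = c("per_chromosome", "genome")) {
  mode <- match.arg(mode)
  if (is.logical(sequence)) {
    sequence <- tibble(chrom = "seq", active = sequence)
  }
  if (nrow(sequence) < 2) abort("need at least 2 genes for a runs test")
  by_chrom <- sequence |>
    group_by(.data$chrom) |>
    summarise(n_runs = count_runs(.data$active),
              n_active = sum(.data$active),
              n_inactive = sum(!.data$active), .groups = "drop")
  if (mode == "genome") {
    lab <- sequence$active
    by_chrom <- tibble(chrom = "genome", n_runs = count_runs(lab),
                       n_active = sum(lab), n_inactive = sum(!lab))
  }
  mom <- purrr::map2(by_chrom$n_active, by_chrom$n_inactive, function(a, b) {
    if (a == 0 || b == 0) c(e = NA_real_, v = NA_real_) else runs_moments(a, b)
  })
  by_chrom$expected_runs <- purrr::map_dbl(mom, "e")
  by_chrom$variance_runs <- purrr::map_dbl(mom, "v")
  usable <- !is.na(by_chrom$expected_runs)
  n_active <- sum(by_chrom$n_active)
  n_inactive <- sum(by_chrom$n_inactive)
  out <- list(
    n_runs = sum(by_chrom$n_runs),
    n_active = n_active,
    n_inactive = n_inactive,
    mean_active_cluster_size =
      if (n_active > 0) mean_cluster_size(sequence, TRUE) else NA_real_,
    by_chrom = by_chrom,
    mode = mode
  )
  if (!any(usable)) {
    out$expected_runs <- NA_real_
    out$variance_runs <- NA_real_
    out$z <- NA_real_
    out$p <- NA_real_
    out$note <- "only one label present: z/p undefined"
  } else {
    e <- sum(by_chrom$expected_runs[usable])
    v <- sum(by_chrom$variance_runs[usable])
    r <- sum(by_chrom$n_runs[usable])
    out$expected_runs <- e
    out$variance_runs <- v
    out$z <- (r - e) / sqrt(v)
    out$p <- 2 * pnorm(-abs(out$z))
  }
  structure(out, class = "runs_test")
}

#' @export
print.runs_test <- function(x, ...) {
  cat("<runs_test> mode =", x$mode, "\n")
  cat("  runs:", x$n_runs, " expected:", round(x$expected_runs, 2),
      " z:", round(x$z, 3), " p:", signif(x$p, 3), "\n")
  cat("  active:", x$n_active, " inactive:", x$n_inactive,
      " mean active cluster:", round(x$mean_active_cluster_size, 2), "\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' @method tidy runs_test
#' @export
tidy.runs_test <- function(x, ...) {
  x$by_chrom
}

#' @method glance runs_test
#' @export
glance.runs_test <- function(x, ...) {
  tibble(n_runs = x$n_runs, n_active = x$n_active,
         n_inactive = x$n_inactive, expected_runs = x$expected_runs,
         variance_runs = x$variance_runs, z = x$z, p = x$p,
         mean_active_cluster_size = x$mean_active_cluster_size)
}

#' Mean size of maximal same-label clusters
#'
#' Mean length of maximal runs of `target_label` along the ordered sequence,
#' counted within chromosomes.
#'
#' @param sequence Tibble with `active` (and optionally `chrom`) in genomic
#'   order, or a bare logical vector.
#' @param target_label The label whose clusters are measured (default
#'   `TRUE`, i.e. active genes).
#' @return Mean cluster size (real).
#' @export
#' @examples
#' mean_cluster_size(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))  # mean(3, 1) = 2
mean_cluster_size <- function(sequence, target_label = TRUE) {
  if (is.logical(sequence)) sequence <- tibble(chrom = "seq", active = sequence)
  lens <- sequence |>
    group_by(.data$chrom) |>
    summarise(lens = list({
      r <- rle(.data$active)
      r$lengths[r$values == target_label]
    }), .groups = "drop") |>
    pull("lens") |>
    unlist()
  if (!length(lens)) abort("target label absent from sequence")
  mean(lens)
}
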