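#' Read a per-gene expression table
#'
#' Reads a tab-delimited expression table with one row per (gene, sample)
#' cell: columns `gene_id`, `sample_id`, `fpkm`, `mapped_reads`. Cells not
#' present in the file are *absent*, not zero; threshold operations treat
#' absent as not expressed but the count of absent cells is reported.
#'
#' @param path Path to the TSV.
#' @return A tibble with the four columns, attribute `n_absent` giving the
#'   number of (gene, sample) combinations not present in the file.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("expression file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "sample_id", "fpkm", "mapped_reads")
  if (!all(need %in% names(tab))) {
    abort(paste0("expression table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  tab <- tab[need]
  if (!is.numeric(tab$fpkm)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$fpkm))))[1]
    abort(paste0("non-numeric FPKM at row ", bad, " (gene ",
                 tab$gene_id[bad], ", sample ", tab$sample_id[bad], ")"))
  }
  validate_expression(tab)
  n_cells <- length(unique(tab$gene_id)) * length(unique(tab$sample_id))
  n_absent <- n_cells - nrow(tab)
  if (n_absent > 0) {
    inform(paste0(n_absent,
                  " (gene, sample) cell(s) absent from expression table"))
  }
  attr(tab, "n_absent") <- n_absent
  tab
}

#' Validate an expression table
#'
#' @param expression Tibble with `gene_id`, `sample_id`, `fpkm`,
#'   `mapped_reads`.
#' @return The table, invisibly, or an error on negative/non-finite FPKM,
#'   negative reads, or duplicate cells.
#' @export
validate_expression <- function(expression) {
  if (any(!is.finite(expression$fpkm))) abort("FPKM must be finite")
  if (any(expression$fpkm < 0)) abort("FPKM must be non-negative")
  if (any(expression$mapped_reads < 0)) abort("mapped_reads must be >= 0")
  dup <- duplicated(expression[c("gene_id", "sample_id")])
  if (any(dup)) {
    abort(paste0("duplicate (gene, sample) cell: ",
                 expression$gene_id[dup][1], " / ",
                 expression$sample_id[dup][1]))
  }
  invisible(expression)
}

#' Write any result tibble as TSV
#'
#' Tab-delimited, header row, UTF-8, '.' decimal. The write -> read round
#' trip is the identity on values.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a recombination map
#'
#' Fixed, non-overlapping, uniform-width windows with a rate in cM/Mb.
#' Columns: `chrom`, `start`, `end` (0-based half-open), `rate`.
#'
#' @param path Path to a BED-like TSV with a header row.
#' @return Tibble sorted by (chrom, start).
#' @export
read_recombination_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end", "rate")
  if (!all(need %in% names(tab))) {
    abort(paste0("recombination map must have columns: ",
                 paste(need, collapse = ", ")))
  }
  tab <- arrange(tab[need], .data$chrom, .data$start)
  validate_recombination_map(tab)
  tab
}

#' Validate a recombination map
#'
#' Windows must be sorted, non-overlapping within chromosome, of uniform
#' width, with non-negative rates.
#'
#' @param map Tibble of `chrom`, `start`, `end`, `rate`.
#' @return The map, invisibly.
#' @export
validate_recombination_map <- function(map) {
  if (any(map$rate < 0)) abort("recombination rate must be >= 0")
  if (any(map$end <= map$start)) abort("windows must satisfy start < end")
  widths <- unique(map$end - map$start)
  if (length(widths) > 1) abort("recombination map windows must be uniform width")
  ovl <- map |> group_by(.data$chrom) |>
    summarise(bad = any(head(.data$end, -1) > tail(.data$start, -1)),
              .groups = "drop")
  if (any(ovl$bad)) abort("recombination map windows overlap")
  invisible(map)
}

#' Read DSB events from BED3
#'
#' @param path Path to a headerless BED3 file (0-based half-open).
#' @param max_width Maximum permitted event width in bp (default 500).
#' @param annotation Optional [genome_annotation()] used to bound-check
#'   events.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_dsb_events <- function(path, max_width = 500, annotation = NULL) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         show_col_types = FALSE, progress = FALSE,
                         col_types = "cii")
  validate_dsb_events(tab, max_width = max_width, annotation = annotation)
  tab
}

#' Validate DSB events
#'
#' @param events Tibble `chrom`, `start`, `end`.
#' @inheritParams read_dsb_events
#' @return The events, invisibly.
#' @export
validate_dsb_events <- function(events, max_width = 500, annotation = NULL) {
  if (any(events$end <= events$start)) abort("DSB events must have start < end")
  w <- events$end - events$start
  if (any(w > max_width)) {
    abort(paste0(sum(w > max_width), " DSB event(s) wider than ", max_width,
                 " bp"))
  }
  if (!is.null(annotation)) {
    idx <- match(events$chrom, annotation$chromosomes$chrom)
    if (anyNA(idx)) abort("DSB event on unknown chromosome")
    off <- events$start < 0 | events$end > annotation$chromosomes$length[idx]
    if (any(off)) {
      abort(paste0("DSB event(s) outside chromosome bounds at rows ",
                   paste(head(which(off), 5), collapse = ", ")))
    }
  }
  invisible(events)
}

#' Write DSB events as BED3
#'
#' @param events Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(events, path) {
  readr::write_tsv(events[c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Percentage of gross reads that mapped
#'
#' Sequencing-summary arithmetic: `100 * mapped / gross`, at full precision
#' (round at the caller).
#'
#' @param gross_reads Total reads sequenced (> 0).
#' @param mapped_reads Reads mapped (0 <= mapped <= gross). Vectorised.
#' @return Percentage(s) in `[0, 100]`.
#' @export
#' @examples
#' round(percent_mapped(231032550, 179734201), 1)  # 77.8
percent_mapped <- function(gross_reads, mapped_reads) {
  if (any(gross_reads <= 0)) abort("gross_reads must be > 0")
  if (any(mapped_reads < 0 | mapped_reads > gross_reads)) {
    abort("mapped_reads must lie in [0, gross_reads]")
  }
  100 * mapped_reads / gross_reads
}
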