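# small in-code fixtures shared across test files

tiny_annotation <- function() {
  genome_annotation(
    chromosomes = tibble::tibble(
      chrom = c("chrX", "chr2", "chrU"),
      length = c(10000, 20000, 5000),
      chrom_class = c("X", "autosome", "unplaced")),
    genes = tibble::tibble(
      gene_id = c("gX1", "gX2", "g21", "g22", "g23", "gU1"),
      chrom = c("chrX", "chrX", "chr2", "chr2", "chr2", "chrU"),
      start = c(100L, 2000L, 500L, 4000L, 4500L, 100L),
      end = c(1100L, 3500L, 1500L, 5200L, 6000L, 600L),
      strand = c("+", "-", "+", "+", "-", "."),
      transcript_length = c(800L, 1200L, 900L, 1000L, 1100L, 400L)))
}

# chi-square oracle: straight sum of (O - E)^2 / E over a 2x2 table
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# per-base boolean scan oracle for transcribed kb inside one window
kb_scan_oracle <- function(win_start, win_end, gene_starts, gene_ends) {
  covered <- logical(win_end - win_start)
  for (i in seq_along(gene_starts)) {
    lo <- max(gene_starts[i], win_start)
    hi <- min(gene_ends[i], win_end)
    if (lo < hi) covered[(lo - win_start + 1):(hi - win_start)] <- TRUE
  }
  sum(covered) / 1000
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  q[o] <- rev(cummin(rev(sorted)))
  pmin(q, 1)
}
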