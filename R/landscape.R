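#' Tile the genome into adjacent windows
#'
#' Left-closed, non-overlapping windows of `window_size` bp tiling each
#' chromosome; the final partial window is kept and flagged so that
#' rate-per-Mb comparisons can drop it.
#'
#' @param annotation [genome_annotation()].
#' @param window_size Window width in bp (default 100 kb).
#' @return Tibble `chrom`, `start`, `end`, `partial`.
#' @export
bin_genome <- function(annotation, window_size = 1e5) {
  if (window_size <= 0) abort("window_size must be > 0")
  purrr::pmap_dfr(annotation$chromosomes[c("chrom", "length")],
                  function(chrom, length) {
    starts <- seq(0, length - 1, by = window_size)
    ends <- pmin(starts + window_size, length)
    tibble(chrom = chrom, start = starts, end = ends,
           partial = ends - starts < window_size)
  })
}

#' Windowed transcription metrics
#'
#' For each window computes the three transcription-landscape measures:
#'
#' * `n_transcribed` — number of transcribed genes whose midpoint falls in
#'   the window (each gene counts in exactly one window);
#' * `kb_transcribed` — kilobases of the window covered by at least one
#'   transcribed gene's genomic footprint (interval union, clipped to the
#'   window, so overlapping transcripts count once);
#' * `ota` — overall transcriptional activity: log10 of the sum of
#'   FPKM x transcript_length over transcribed genes assigned (by midpoint)
#'   to the window; undefined (`NA`) when the window has no transcribed
#'   gene.
#'
#' @param windows Tibble from [bin_genome()].
#' @param annotation [genome_annotation()].
#' @param gene_expression Tibble with `gene_id`, `fpkm` (one row per gene;
#'   the caller decides which sample/condition the FPKM summarises) and
#'   optionally a logical `active` column. When `active` is absent it is
#'   derived as `fpkm > fpkm_threshold`.
#' @param fpkm_threshold Strict FPKM threshold used when `active` is not
#'   supplied (default 1, the conservative landscape threshold).
#' @return `windows` with `n_transcribed`, `kb_transcribed`, `ota` appended.
#' @export
window_metrics <- function(windows, annotation, gene_expression,
                           fpkm_threshold = 1) {
  genes <- inner_join(annotation$genes, gene_expression, by = "gene_id")
  unknown <- setdiff(genes$chrom, annotation$chromosomes$chrom)
  if (length(unknown)) {
    abort(paste0("gene on unknown chromosome: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!"active" %in% names(genes)) {
    genes$active <- genes$fpkm > fpkm_threshold
  }
  act <- filter(genes, .data$active)

  win_gr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1, windows$end))

  # midpoint assignment for counts and OTA
  n_transcribed <- integer(nrow(windows))
  ota_sum <- numeric(nrow(windows))
  if (nrow(act)) {
    mid <- floor((act$start + act$end) / 2)
    mid_gr <- GenomicRanges::GRanges(act$chrom,
                                     IRanges::IRanges(mid + 1, mid + 1))
    hits <- GenomicRanges::findOverlaps(mid_gr, win_gr)
    tab <- tapply(rep(1L, length(hits)), S4Vectors::subjectHits(hits), sum)
    n_transcribed[as.integer(names(tab))] <- as.integer(tab)
    prod <- act$fpkm * act$transcript_length
    osum <- tapply(prod[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits), sum)
    ota_sum[as.integer(names(osum))] <- osum
  }

  # interval-union footprint clipped to windows
  kb <- numeric(nrow(windows))
  if (nrow(act)) {
    cov_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      act$chrom, IRanges::IRanges(act$start + 1, act$end)))
    hits <- GenomicRanges::findOverlaps(win_gr, cov_gr)
    if (length(hits)) {
      ov <- GenomicRanges::pintersect(
        win_gr[S4Vectors::queryHits(hits)],
        cov_gr[S4Vectors::subjectHits(hits)])
      bp <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
      kb[as.integer(names(bp))] <- bp / 1000
    }
  }

  mutate(windows,
         n_transcribed = n_transcribed,
         kb_transcribed = kb,
         ota = ifelse(ota_sum > 0, log10(ota_sum), NA_real_))
}

join_windows <- function(metrics, recomb_map, include_partial = FALSE) {
  joined <- inner_join(metrics, recomb_map[c("chrom", "start", "end", "rate")],
                       by = c("chrom", "start", "end"))
  if (!include_partial && "partial" %in% names(joined)) {
    joined <- filter(joined, !.data$partial)
  }
  joined
}

#' Correlate window transcription metrics with recombination rate
#'
#' Rank (Spearman, default) or product-moment correlation of each window
#' metric with the window recombination rate, with average-rank tie
#' handling. Metrics and map windows must align exactly on
#' (chrom, start, end); windows without a rate (or with undefined OTA, for
#' the OTA metric) are dropped and counted.
#'
#' @param metrics Output of [window_metrics()].
#' @param recomb_map Recombination map tibble (`chrom`, `start`, `end`,
#'   `rate`).
#' @param metric_cols Metric columns to correlate.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param include_partial Include flagged partial terminal windows
#'   (default `FALSE`).
#' @return Tibble `metric`, `rho`, `p`, `n_windows`, `n_dropped`.
#' @export
correlate_with_recombination <- function(metrics, recomb_map,
                                         metric_cols = c("n_transcribed",
                                                         "kb_transcribed",
                                                         "ota"),
                                         method = c("spearman", "pearson"),
                                         include_partial = FALSE) {
  method <- match.arg(method)
  joined <- join_windows(metrics, recomb_map, include_partial)
  purrr::map_dfr(metric_cols, function(mc) {
    x <- joined[[mc]]
    keep <- !is.na(x) & !is.na(joined$rate)
    if (sum(keep) < 3) {
      abort(paste0("fewer than 3 aligned windows with defined '", mc, "'"))
    }
    ct <- suppressWarnings(
      cor.test(x[keep], joined$rate[keep], method = method, exact = FALSE))
    tibble(metric = mc, rho = unname(ct$estimate), p = ct$p.value,
           n_windows = sum(keep), n_dropped = nrow(metrics) - sum(keep))
  })
}

#' Multiple regression of recombination rate on window metrics
#'
#' Ordinary least squares of rate on `n_transcribed`, `kb_transcribed` and
#' `ota` with intercept, reporting per-coefficient two-sided t-test
#' p-values. Windows with undefined OTA (no transcription) are imputed at
#' the minimum observed OTA minus 1 (flagged in the returned data;
#' disable with `impute_ota = FALSE` to drop them). Set `rank = TRUE` to
#' regress on average ranks of every variable instead of raw values.
#'
#' @inheritParams correlate_with_recombination
#' @param impute_ota Impute undefined OTA as min(OTA) - 1 (default `TRUE`).
#' @param rank Rank-transform all variables first (default `FALSE`).
#' @return Object of class `landscape_fit` wrapping the `lm` fit; use
#'   [tidy()] for the coefficient table and [glance()] for the model
#'   summary.
#' @export
landscape_regression <- function(metrics, recomb_map, impute_ota = TRUE,
                                 rank = FALSE, include_partial = FALSE) {
  joined <- join_windows(metrics, recomb_map, include_partial)
  joined$ota_imputed <- is.na(joined$ota)
  if (impute_ota) {
    if (all(is.na(joined$ota))) abort("all OTA values undefined")
    joined$ota[joined$ota_imputed] <- min(joined$ota, na.rm = TRUE) - 1
  } else {
    joined <- filter(joined, !.data$ota_imputed)
  }
  preds <- c("n_transcribed", "kb_transcribed", "ota")
  if (nrow(joined) < 10) abort("need at least 10 complete windows")
  dat <- joined[c("rate", preds)]
  if (rank) dat[] <- lapply(dat, rank)
  for (pr in preds) {
    if (length(unique(dat[[pr]])) < 2) {
      abort(paste0("constant predictor: ", pr))
    }
  }
  fit <- lm(rate ~ n_transcribed + kb_transcribed + ota, data = dat)
  if (any(is.na(coef(fit)))) {
    abort(paste0("collinear predictor(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  structure(list(fit = fit, data = joined, rank = rank,
                 n_imputed = sum(joined$ota_imputed)),
            class = "landscape_fit")
}

#' @export
print.landscape_fit <- function(x, ...) {
  cat("<landscape_fit> n =", nrow(x$data),
      if (x$rank) "(rank-transformed)" else "(raw OLS)",
      "| OTA imputed in", x$n_imputed, "window(s)\n")
  print(tidy(x))
  invisible(x)
}

#' @method tidy landscape_fit
#' @export
tidy.landscape_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p = s[, 4])
}

#' @method glance landscape_fit
#' @export
glance.landscape_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         sigma = s$sigma, n = nrow(x$data), n_ota_imputed = x$n_imputed)
}

#' Recombination in untranscribed vs transcribed windows
#'
#' Two-sided Mann-Whitney (rank-sum) test comparing recombination rates of
#' windows with no transcribed gene against windows with one or more.
#'
#' @inheritParams correlate_with_recombination
#' @return One-row tibble `u`, `p`, `n_zero`, `n_nonzero`, `median_zero`,
#'   `median_nonzero`.
#' @export
zero_vs_nonzero_transcription <- function(metrics, recomb_map,
                                          include_partial = FALSE) {
  joined <- join_windows(metrics, recomb_map, include_partial)
  zero <- joined$rate[joined$n_transcribed == 0]
  nonzero <- joined$rate[joined$n_transcribed >= 1]
  if (!length(zero) || !length(nonzero)) {
    abort("both window groups (zero and nonzero transcription) must be nonempty")
  }
  wt <- suppressWarnings(wilcox.test(zero, nonzero, exact = FALSE))
  tibble(u = unname(wt$statistic), p = wt$p.value,
         n_zero = length(zero), n_nonzero = length(nonzero),
         median_zero = median(zero), median_nonzero = median(nonzero))
}
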