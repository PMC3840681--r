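#' Default pipeline configuration
#'
#' Thresholds and sizes used across the pipeline stages, overridable by a
#' named list or a YAML file.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list with `seed`, `fpkm_active` (0.1 or 1),
#'   `fpkm_landscape`, `silent_threshold`, `min_reads`, `q_threshold`,
#'   `min_allele_reads`, `window_size`, `n_replicates`, and `sim` (a
#'   [sim_config()], rebuilt with the shared seed).
#' @export
pipeline_config <- function(...) {
  cfg <- list(seed = 1L, fpkm_active = 0.1, fpkm_landscape = 1,
              silent_threshold = 0.001, min_reads = 10, q_threshold = 0.05,
              min_allele_reads = 100, window_size = 1e5,
              n_replicates = 10000, sim = list())
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) && is.character(dots[[1]])) {
    dots <- yaml::read_yaml(dots[[1]])
  }
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  num <- unlist(cfg[c("fpkm_active", "fpkm_landscape", "silent_threshold",
                      "min_reads", "q_threshold", "min_allele_reads",
                      "window_size", "n_replicates")])
  if (any(num <= 0)) abort("all pipeline thresholds must be positive")
  cfg$sim <- do.call(sim_config, c(list(seed = cfg$seed),
                                   cfg$sim[setdiff(names(cfg$sim), "seed")]))
  cfg
}

#' Run the full synthetic pipeline
#'
#' Generates every input with the synthetic-data module, then runs each
#' analysis stage: activity calling and chromosome contrast, runs-test
#' clustering, windowed landscape metrics with recombination correlations
#' and regression, Monte-Carlo DSB enrichment, maternal-like
#' parent-of-origin classification, allele-specific read assignment and
#' ratio tests, and the novel-candidate filter cascade on a simulated
#' candidate set. Outputs are deterministic under a fixed seed. When
#' `out_dir` is given, every stage writes its TSV artifact plus a JSON run
#' manifest (config hash, seed, per-stage row counts).
#'
#' @param config A [pipeline_config()] (or arguments for one, via `...`).
#' @param stages Character vector of stages to run, subset of
#'   `c("expression", "clustering", "landscape", "dsb", "poe", "novel")`;
#'   default all.
#' @param out_dir Optional directory for TSV artifacts and the manifest.
#' @param ... Passed to [pipeline_config()] when `config` is missing.
#' @return Named list of stage results plus `inputs` (the simulated data)
#'   and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(...),
                         stages = c("expression", "clustering", "landscape",
                                    "dsb", "poe", "novel"),
                         out_dir = NULL, ...) {
  stages <- match.arg(stages, several.ok = TRUE)
  sim <- config$sim
  annotation <- simulate_genome(sim)
  expr <- simulate_expression(annotation, sim)
  early_ids <- expr$samples$sample_id[expr$samples$condition == "Early"]
  gene_early <- expr$expression |>
    filter(.data$sample_id %in% early_ids) |>
    group_by(.data$gene_id) |>
    summarise(fpkm = mean(.data$fpkm),
              mapped_reads = sum(.data$mapped_reads), .groups = "drop")
  res <- list(inputs = list(annotation = annotation, expression = expr,
                            gene_early = gene_early))

  calls <- gene_early |>
    mutate(active = call_active(.data$fpkm, .data$mapped_reads,
                                fpkm_threshold = config$fpkm_active,
                                min_reads = config$min_reads))

  if ("expression" %in% stages) {
    res$expression <- list(
      calls = calls,
      contrast = chromosome_activity_contrast(calls, annotation),
      de = de_table(expr$expression, expr$samples))
  }
  if ("clustering" %in% stages) {
    seq_01 <- activity_sequence(annotation, gene_early |>
      mutate(active = .data$fpkm > 0.1))
    seq_1 <- activity_sequence(annotation, gene_early |>
      mutate(active = .data$fpkm > 1))
    res$clustering <- list(runs_fpkm_0.1 = runs_test(seq_01),
                           runs_fpkm_1 = runs_test(seq_1))
  }
  recomb_map <- simulate_recombination_map(annotation, gene_early, sim)
  if ("landscape" %in% stages) {
    windows <- bin_genome(annotation, config$window_size)
    metrics <- window_metrics(windows, annotation, gene_early,
                              fpkm_threshold = config$fpkm_landscape)
    res$landscape <- list(
      metrics = metrics,
      correlations = correlate_with_recombination(metrics, recomb_map),
      regression = landscape_regression(metrics, recomb_map),
      zero_vs_nonzero = zero_vs_nonzero_transcription(metrics, recomb_map))
  }
  if ("dsb" %in% stages) {
    dsbs <- simulate_dsbs(annotation, gene_early, sim)
    res$dsb <- dsb_enrichment(dsbs$events, dsbs$partition,
                              n_replicates = config$n_replicates,
                              seed = config$seed)
    res$inputs$dsbs <- dsbs
  }
  if ("poe" %in% stages) {
    crosses <- simulate_reciprocal_crosses(annotation, sim)
    ml <- maternal_like_genes(crosses, q_threshold = config$q_threshold)
    hap <- simulate_haplotypes_and_reads(sim)
    assigned <- assign_reads(hap$reads, hap$reference_a, hap$reference_b)
    counts <- allele_counts(assigned)
    ratios <- allelic_ratio_test(counts,
                                 min_reads = config$min_allele_reads)
    res$poe <- list(maternal_like = ml, assigned = assigned,
                    allele_counts = counts, ratio_tests = ratios)
    res$inputs$haplotypes <- hap
  }
  if ("novel" %in% stages) {
    novel_in <- simulate_novel_candidates(annotation, sim)
    res$novel <- filter_cascade(novel_in$candidates, novel_in$fpkm)
    res$inputs$novel <- novel_in
  }

  counts <- purrr::imap(res[setdiff(names(res), "inputs")], function(x, nm) {
    if (is.data.frame(x)) nrow(x) else NA_integer_
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("meiotrans")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "sim")]),
    stages = stages,
    n_genes = nrow(annotation$genes),
    stage_rows = counts)
  res$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(annotation$genes, file.path(out_dir, "genes.tsv"))
    write_table(expr$expression, file.path(out_dir, "expression.tsv"))
    write_table(recomb_map, file.path(out_dir, "recombination_map.tsv"))
    if (!is.null(res$expression)) {
      write_table(res$expression$de, file.path(out_dir, "de_table.tsv"))
      write_table(res$expression$contrast,
                  file.path(out_dir, "chromosome_contrast.tsv"))
    }
    if (!is.null(res$clustering)) {
      write_table(bind_rows(
        mutate(glance(res$clustering$runs_fpkm_0.1), fpkm_threshold = 0.1),
        mutate(glance(res$clustering$runs_fpkm_1), fpkm_threshold = 1)),
        file.path(out_dir, "runs_test.tsv"))
    }
    if (!is.null(res$landscape)) {
      write_table(res$landscape$metrics, file.path(out_dir, "windows.tsv"))
      write_table(res$landscape$correlations,
                  file.path(out_dir, "landscape_correlations.tsv"))
      write_table(tidy(res$landscape$regression),
                  file.path(out_dir, "landscape_regression.tsv"))
    }
    if (!is.null(res$dsb)) {
      write_table(res$dsb, file.path(out_dir, "dsb_enrichment.tsv"))
      write_bed3(attr(res$dsb, "events"), file.path(out_dir, "dsbs.bed"))
    }
    if (!is.null(res$poe)) {
      write_table(res$poe$maternal_like,
                  file.path(out_dir, "maternal_like.tsv"))
      write_table(res$poe$allele_counts,
                  file.path(out_dir, "allele_counts.tsv"))
    }
    if (!is.null(res$novel)) {
      write_table(res$novel$counts, file.path(out_dir, "novel_cascade.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Simulate a candidate novel-transcript set
#'
#' Plants candidates in intergenic space with known per-stage pass/fail
#' status so the filter cascade's per-stage counts can be checked against
#' truth.
#'
#' @param annotation [genome_annotation()].
#' @param config A [sim_config()]; its seed stream (offset 6) drives the
#'   sampler.
#' @param n_candidates Number of candidates (default 60).
#' @param n_samples Number of samples with per-candidate FPKM (default 8).
#' @return List with `candidates`, `fpkm`, and `truth` (logical
#'   `pass_stage1..3` per candidate).
#' @export
simulate_novel_candidates <- function(annotation, config, n_candidates = 60,
                                      n_samples = 8) {
  with_sim_seed(config, 6L, {
    chrom <- annotation$chromosomes$chrom[1]
    clen <- annotation$chromosomes$length[1]
    len <- sample(c(150, 500, 1200), n_candidates, replace = TRUE)
    start <- sort(sample.int(clen - max(len), n_candidates))
    n_det <- sample(0:n_samples, n_candidates, replace = TRUE)
    max_fpkm <- stats::runif(n_candidates, 0.1, 5)
    cand <- tibble(
      id = sprintf("nov%03d", seq_len(n_candidates)),
      chrom = chrom, start = start, end = start + len, length = len,
      repetitive_fraction = stats::runif(n_candidates, 0, 1),
      splice_junction_support = stats::runif(n_candidates) < 0.7)
    fpkm <- purrr::map_dfr(seq_len(n_candidates), function(i) {
      f <- numeric(n_samples)
      if (n_det[i] > 0) {
        idx <- sample.int(n_samples, n_det[i])
        f[idx] <- stats::runif(n_det[i], 0.01, 1) * max_fpkm[i]
        f[idx[1]] <- max_fpkm[i]
      }
      tibble(id = cand$id[i], sample_id = paste0("s", seq_len(n_samples)),
             fpkm = f)
    })
    truth <- cand |>
      mutate(n_detected = n_det, max_fpkm = ifelse(n_det > 0, max_fpkm, 0),
             pass_stage1 = .data$n_detected >= 2,
             pass_stage2 = .data$pass_stage1 & .data$max_fpkm > 1,
             pass_stage3 = .data$pass_stage2 & .data$length > 300 &
               .data$repetitive_fraction <= 0.5 &
               .data$splice_junction_support)
    list(candidates = cand, fpkm = fpkm,
         truth = truth[c("id", "pass_stage1", "pass_stage2", "pass_stage3")])
  })
}
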