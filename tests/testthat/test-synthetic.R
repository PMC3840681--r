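test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 3, n_genes = 300,
                    chrom_lengths = c(chrX = 2e6, chr2 = 2e6), n_dsbs = 200,
                    n_reads = 500, hap_length = 2e4)
  a1 <- simulate_genome(cfg)
  a2 <- simulate_genome(cfg)
  expect_identical(a1$genes, a2$genes)
  e1 <- simulate_expression(a1, cfg)
  e2 <- simulate_expression(a1, cfg)
  expect_identical(e1$expression, e2$expression)
  g <- dplyr::select(dplyr::filter(e1$expression, sample_id == "A_Early"),
                     gene_id, fpkm)
  expect_identical(simulate_dsbs(a1, g, cfg)$events,
                   simulate_dsbs(a1, g, cfg)$events)
  expect_identical(simulate_haplotypes_and_reads(cfg)$reads,
                   simulate_haplotypes_and_reads(cfg)$reads)
  expect_identical(simulate_recombination_map(a1, g, cfg),
                   simulate_recombination_map(a1, g, cfg))
})

test_that("simulated genomes satisfy every annotation invariant", {
  cfg <- sim_config(seed = 19, n_genes = 1000,
                    chrom_lengths = c(chrX = 1e7, chr2 = 1e7))
  ann <- simulate_genome(cfg)
  expect_silent(validate_annotation(ann))
  expect_equal(nrow(ann$genes), 1000)
  expect_equal(sum(ann$chromosomes$chrom_class == "X"), 1)
  # non-overlapping within chromosome
  by_chr <- split(ann$genes, ann$genes$chrom)
  for (g in by_chr) {
    g <- dplyr::arrange(g, start)
    expect_true(all(utils::head(g$end, -1) <= utils::tail(g$start, -1)))
  }
  # empty genome
  ann0 <- simulate_genome(sim_config(n_genes = 0))
  expect_equal(nrow(ann0$genes), 0)
  # impossible footprint
  expect_error(simulate_genome(sim_config(
    n_genes = 5000, chrom_lengths = c(chrX = 1e5, chr2 = 1e5),
    gene_length_meanlog = log(5000), gene_length_sdlog = 0.1)),
    "exceeds")
})

test_that("expression design has 8 samples and coherent read counts", {
  cfg <- sim_config(seed = 101, n_genes = 300,
                    chrom_lengths = c(chrX = 2e6, chr2 = 2e6))
  ann <- simulate_genome(cfg)
  sim <- simulate_expression(ann, cfg)
  expect_equal(nrow(sim$samples), 8)
  expect_equal(sort(unique(sim$samples$condition)), c("Early", "Late"))
  expect_equal(sort(unique(sim$samples$genotype)),
               c("A", "AxB", "B", "BxA"))
  expect_true(all(sim$samples$mapped_reads <= sim$samples$gross_reads))
  expect_silent(validate_expression(sim$expression))
  # inactive genes are fully silent
  joined <- dplyr::inner_join(sim$expression, sim$truth, by = "gene_id")
  expect_true(all(joined$fpkm[!joined$active] == 0))
})

test_that("X-activity excess appears when planted and calibrates when absent", {
  cfg <- sim_config(seed = 67, n_genes = 3000,
                    chrom_lengths = c(chrX = 8e6, chr2 = 8e6),
                    p_active_x = 0.75, p_active_autosome = 0.5)
  ann <- simulate_genome(cfg)
  sim <- simulate_expression(ann, cfg)
  calls <- tibble::tibble(gene_id = sim$truth$gene_id,
                          active = sim$truth$active)
  res <- chromosome_activity_contrast(calls, ann)
  expect_gt(res$prop_x, res$prop_autosome)
  expect_lt(res$p, 0.001)
  # equal probabilities: contrast should usually be non-significant
  hits <- vapply(1:40, function(i) {
    cfg0 <- sim_config(seed = 2000 + i, n_genes = 500,
                       chrom_lengths = c(chrX = 2e6, chr2 = 2e6),
                       clustering_strength = 0,
                       p_active_x = 0.5, p_active_autosome = 0.5)
    a <- simulate_genome(cfg0)
    s <- simulate_expression(a, cfg0)
    chromosome_activity_contrast(
      tibble::tibble(gene_id = s$truth$gene_id, active = s$truth$active),
      a)$p < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.15)
})

test_that("flat-effect recombination maps equal base plus trend and clip at zero", {
  cfg <- sim_config(seed = 7, n_genes = 200,
                    chrom_lengths = c(chrX = 2e6, chr2 = 2e6),
                    beta_genes = 0, beta_kb = 0, beta_ota = 0,
                    recomb_noise_sd = 0, bell_amplitude = 0)
  ann <- simulate_genome(cfg)
  g <- dplyr::select(dplyr::filter(
    simulate_expression(ann, cfg)$expression, sample_id == "A_Early"),
    gene_id, fpkm)
  map <- simulate_recombination_map(ann, g, cfg)
  expect_true(all(map$rate == cfg$recomb_base_rate))
  expect_silent(validate_recombination_map(
    map[c("chrom", "start", "end", "rate")]))
  # a deeply negative base clips to zero
  cfg2 <- sim_config(seed = 7, n_genes = 200,
                     chrom_lengths = c(chrX = 2e6, chr2 = 2e6),
                     recomb_base_rate = -100, beta_genes = 0, beta_kb = 0,
                     beta_ota = 0, recomb_noise_sd = 0)
  map2 <- simulate_recombination_map(ann, g, cfg2)
  expect_true(all(map2$rate == 0))
})

test_that("synthetic DSB events respect the 500 bp width cap and bounds", {
  cfg <- sim_config(seed = 31, n_genes = 300,
                    chrom_lengths = c(chrX = 2e6, chr2 = 2e6), n_dsbs = 1000)
  ann <- simulate_genome(cfg)
  g <- dplyr::select(dplyr::filter(
    simulate_expression(ann, cfg)$expression, sample_id == "A_Early"),
    gene_id, fpkm)
  dsbs <- simulate_dsbs(ann, g, cfg)
  expect_equal(nrow(dsbs$events), 1000)
  expect_silent(validate_dsb_events(dsbs$events, annotation = ann))
})

test_that("haplotypes differ only at SNPs and planted allele ratio is respected", {
  cfg <- sim_config(seed = 41, hap_length = 2e4, n_reads = 4000,
                    allele_ratio = 0.7, n_rate = 0)
  hap <- simulate_haplotypes_and_reads(cfg)
  a <- strsplit(hap$reference_a, "")[[1]]
  b <- strsplit(hap$reference_b, "")[[1]]
  diffs <- which(a != b)
  expect_equal(diffs - 1L, hap$snp_positions)
  expect_lt(abs(mean(hap$reads$origin == "A") - 0.7),
            3 * sqrt(0.7 * 0.3 / 4000))
  # reads are exact substrings of their origin haplotype (no N, no errors)
  got <- assign_reads(hap$reads, hap$reference_a, hap$reference_b)
  informative <- got[got$assignment %in% c("A", "B"), ]
  expect_equal(informative$assignment, informative$origin)
})

test_that("sim_config validates probabilities, weights and sizes", {
  expect_error(sim_config(allele_ratio = 1.5), "probabilities")
  expect_error(sim_config(dsb_category_weights = c(intergenic = -1)),
               "weights")
  expect_error(sim_config(chrom_lengths = c(1e6, 2e6)), "named")
  expect_error(sim_config(dsb_width_range = c(100, 900)), "500")
})
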