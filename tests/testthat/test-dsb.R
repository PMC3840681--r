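partition_fixture <- function() {
  # 10 kb genome: one silent gene, three active genes spanning the
  # low/medium/high tertiles, the rest intergenic
  ann <- genome_annotation(
    tibble::tibble(chrom = "c1", length = 10000, chrom_class = "autosome"),
    tibble::tibble(gene_id = c("s", "l", "m", "h"), chrom = "c1",
                   start = c(1000L, 3000L, 5000L, 7000L),
                   end = c(2000L, 4000L, 6000L, 8000L),
                   strand = "+", transcript_length = 1000L))
  expr <- tibble::tibble(gene_id = c("s", "l", "m", "h"),
                         fpkm = c(0.0001, 1, 10, 100))
  build_partition(ann, expr)
}

test_that("partition splits active genes at count tertiles and covers the genome", {
  part <- partition_fixture()
  expect_equal(as.character(part$gene_categories$category[
    match(c("s", "l", "m", "h"), part$gene_categories$gene_id)]),
    c("silent", "low", "medium", "high"))
  expect_equal(sum(part$footprint$bp), 10000)  # exact genome partition
  expect_equal(part$footprint$bp[part$footprint$category == "intergenic"],
               6000)
  expect_equal(part$n_contested_bases, 0)
})

test_that("partition handles no genes, all-silent genes, and 3/3/3 tertiles", {
  chroms <- tibble::tibble(chrom = "c1", length = 5000,
                           chrom_class = "autosome")
  empty <- genome_annotation(chroms, tibble::tibble(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), transcript_length = integer()))
  p0 <- build_partition(empty, tibble::tibble(gene_id = character(),
                                              fpkm = numeric()))
  expect_equal(p0$footprint$fraction[p0$footprint$category == "intergenic"], 1)

  ann <- genome_annotation(chroms, tibble::tibble(
    gene_id = sprintf("g%d", 1:9), chrom = "c1",
    start = seq(0L, 4000L, by = 500L), end = seq(300L, 4300L, by = 500L),
    strand = "+", transcript_length = 100L))
  silent <- build_partition(ann, tibble::tibble(gene_id = sprintf("g%d", 1:9),
                                                fpkm = 0))
  expect_equal(sum(silent$footprint$bp[
    silent$footprint$category %in% c("low", "medium", "high")]), 0)

  part9 <- build_partition(ann, tibble::tibble(gene_id = sprintf("g%d", 1:9),
                                               fpkm = 2^(1:9)))
  tabs <- table(part9$gene_categories$category)
  expect_equal(unname(tabs[c("low", "medium", "high")]), rep(3L, 3),
               ignore_attr = TRUE)
  expect_error(build_partition(ann, tibble::tibble(
    gene_id = sprintf("g%d", 1:9), fpkm = 1), activity_cuts = c(0.6, 0.3)),
    "strictly increasing")
})

test_that("overlapping genes resolve to the higher category", {
  ann <- genome_annotation(
    tibble::tibble(chrom = "c1", length = 4000, chrom_class = "autosome"),
    tibble::tibble(gene_id = c("lo", "hi"), chrom = "c1",
                   start = c(500L, 800L), end = c(1500L, 1200L),
                   strand = "+", transcript_length = 500L))
  part <- build_partition(ann, tibble::tibble(gene_id = c("lo", "hi"),
                                              fpkm = c(1, 1000)),
                          activity_cuts = 0.5)
  seg <- part$segments
  hi_bp <- sum((seg$end - seg$start)[seg$category == "medium"])
  expect_equal(hi_bp, 400)  # the hi gene's span wins its 400 contested bases
  expect_equal(part$n_contested_bases, 400)
  expect_equal(sum(part$footprint$bp), 4000)
})

test_that("event classification uses the midpoint rule", {
  part <- partition_fixture()
  ev <- tibble::tibble(
    chrom = "c1",
    start = c(1400L, 2500L, 1950L, 7400L),
    end = c(1600L, 2700L, 2250L, 7600L))
  # midpoints: 1500 (silent), 2600 (intergenic), 2100 (straddles the silent
  # gene edge but midpoint is outside -> intergenic), 7500 (high)
  cl <- classify_events(ev, part)
  expect_equal(as.character(cl$events$category),
               c("silent", "intergenic", "intergenic", "high"))
  expect_equal(sum(cl$observed$observed), 4)
  expect_error(classify_events(
    tibble::tibble(chrom = "c1", start = 9950L, end = 10100L), part),
    "bounds")
})

test_that("Monte-Carlo null matches the binomial oracle and conserves events", {
  part <- partition_fixture()  # silent footprint = 1000/10000 = 10%
  null <- monte_carlo_null(1000, part, n_replicates = 2000, seed = 9)
  expect_equal(rowSums(null$counts), rep(1000, 2000))  # conservation
  fr <- part$footprint$fraction
  names(fr) <- as.character(part$footprint$category)
  for (cat in names(fr)) {
    se <- sqrt(1000 * fr[cat] * (1 - fr[cat]) / 2000)
    expect_lt(abs(null$expected$expected[null$expected$category == cat] -
                    1000 * fr[cat]), 3 * se + 1e-9)
  }
  # fixed seed reproducibility
  null2 <- monte_carlo_null(1000, part, n_replicates = 2000, seed = 9)
  expect_identical(null$counts, null2$counts)
})

test_that("single-category genome gives expected counts equal to n_events", {
  chroms <- tibble::tibble(chrom = "c1", length = 1000,
                           chrom_class = "autosome")
  ann <- genome_annotation(chroms, tibble::tibble(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), transcript_length = integer()))
  part <- build_partition(ann, tibble::tibble(gene_id = character(),
                                              fpkm = numeric()))
  null <- monte_carlo_null(50, part, n_replicates = 200, seed = 1)
  expect_equal(null$expected$expected[
    null$expected$category == "intergenic"], 50)
})

test_that("empirical p uses the doubled smaller tail with add-one floor", {
  part <- partition_fixture()
  null <- monte_carlo_null(500, part, n_replicates = 1000, seed = 3)
  # observed at the null mean: p near 1
  obs_mean <- tibble::tibble(
    category = null$expected$category,
    observed = as.integer(round(null$expected$expected)))
  res_mean <- enrichment_test(obs_mean, null)
  expect_true(all(res_mean$p_empirical > 0.5))
  expect_true(all(res_mean$relative_presence > 0.8 &
                    res_mean$relative_presence < 1.2))
  # observed far beyond the null maximum: p at the add-one floor x2 tail
  obs_far <- dplyr::mutate(obs_mean,
                           observed = c(500L, 0L, 0L, 0L, 0L))
  res_far <- enrichment_test(obs_far, null)
  expect_equal(res_far$p_empirical[1], 2 / 1001)
  expect_true(all(res_far$p_empirical > 0))  # never zero
  expect_error(enrichment_test(obs_mean,
                               monte_carlo_null(10, part, 50, seed = 1)),
               "100 replicates")
})

test_that("planted 2x weight on transcribed genes is recovered as enrichment", {
  cfg <- sim_config(seed = 13, n_genes = 500,
                    chrom_lengths = c(chrX = 3e6, chr2 = 4e6),
                    n_dsbs = 5000,
                    dsb_category_weights = c(intergenic = 1, silent = 1,
                                             low = 2, medium = 2, high = 2))
  ann <- simulate_genome(cfg)
  sim <- simulate_expression(ann, cfg)
  gene_fpkm <- sim$expression |>
    dplyr::filter(sample_id == "A_Early") |>
    dplyr::select(gene_id, fpkm)
  dsbs <- simulate_dsbs(ann, gene_fpkm, cfg)
  res <- dsb_enrichment(dsbs$events, dsbs$partition, n_replicates = 2000,
                        seed = 13)
  transcribed <- res[res$category %in% c("low", "medium", "high"), ]
  expect_true(all(transcribed$relative_presence > 1))
  expect_true(all(transcribed$p_empirical < 0.05 / 5))
  # truth labels agree with midpoint classification
  cl <- classify_events(dsbs$events, dsbs$partition)
  expect_equal(as.character(cl$events$category), dsbs$events$true_category)
})

test_that("zero-weight categories receive no synthetic events", {
  cfg <- sim_config(seed = 17, n_genes = 200,
                    chrom_lengths = c(chrX = 2e6, chr2 = 2e6), n_dsbs = 500,
                    dsb_category_weights = c(intergenic = 0, silent = 1,
                                             low = 1, medium = 1, high = 1))
  ann <- simulate_genome(cfg)
  sim <- simulate_expression(ann, cfg)
  gene_fpkm <- dplyr::select(dplyr::filter(sim$expression,
                                           sample_id == "A_Early"),
                             gene_id, fpkm)
  dsbs <- simulate_dsbs(ann, gene_fpkm, cfg)
  expect_false(any(dsbs$events$true_category == "intergenic"))
})
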