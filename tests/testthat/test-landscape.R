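test_that("genome binning tiles chromosomes and flags partial windows", {
  ann <- genome_annotation(
    tibble::tibble(chrom = "c1", length = 250000, chrom_class = "autosome"),
    tibble::tibble(gene_id = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   transcript_length = integer()))
  w <- bin_genome(ann, 1e5)
  expect_equal(nrow(w), 3)
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  expect_equal(w$end[3] - w$start[3], 50000)
  expect_equal(sum(w$end - w$start), 250000)  # conservation

  tiny <- bin_genome(tiny_annotation(), 1e6)
  expect_equal(nrow(tiny), 3)  # one partial window per chromosome
  expect_true(all(tiny$partial))
})

test_that("window metrics: midpoint counts, interval-union kb, OTA arithmetic", {
  ann <- genome_annotation(
    tibble::tibble(chrom = "c1", length = 2000, chrom_class = "autosome"),
    tibble::tibble(gene_id = c("a", "b"), chrom = "c1",
                   start = c(100L, 400L), end = c(600L, 900L),
                   strand = "+", transcript_length = c(1000L, 2000L)))
  w <- tibble::tibble(chrom = "c1", start = 0, end = 1000, partial = FALSE)
  expr <- tibble::tibble(gene_id = c("a", "b"), fpkm = c(10, 5))
  m <- window_metrics(w, ann, expr, fpkm_threshold = 1)
  expect_equal(m$n_transcribed, 2)
  # union of [100,600) and [400,900) = 800 bp
  expect_equal(m$kb_transcribed, 0.8)
  # OTA = log10(10*1000 + 5*2000)
  expect_equal(m$ota, log10(20000))

  # window with no transcribed gene: zero counts, undefined OTA
  m0 <- window_metrics(w, ann, dplyr::mutate(expr, fpkm = 0.5))
  expect_equal(m0$n_transcribed, 0)
  expect_equal(m0$kb_transcribed, 0)
  expect_true(is.na(m0$ota))
})

test_that("OTA is order-invariant and increasing in any gene's FPKM", {
  ann <- genome_annotation(
    tibble::tibble(chrom = "c1", length = 10000, chrom_class = "autosome"),
    tibble::tibble(gene_id = sprintf("g%d", 1:5), chrom = "c1",
                   start = seq(0L, 8000L, by = 2000L),
                   end = seq(1000L, 9000L, by = 2000L),
                   strand = "+", transcript_length = 500L))
  w <- tibble::tibble(chrom = "c1", start = 0, end = 10000, partial = FALSE)
  expr <- tibble::tibble(gene_id = sprintf("g%d", 1:5),
                         fpkm = c(3, 8, 2, 9, 4))
  base_ota <- window_metrics(w, ann, expr)$ota
  shuffled <- expr[sample(5), ]
  expect_equal(window_metrics(w, ann, shuffled)$ota, base_ota)
  bumped <- dplyr::mutate(expr, fpkm = fpkm + (gene_id == "g3"))
  expect_gt(window_metrics(w, ann, bumped)$ota, base_ota)
})

test_that("kb_transcribed equals the per-base scan oracle on fuzzed windows", {
  set.seed(71)
  for (i in 1:60) {
    n <- sample(1:12, 1)
    start <- sample.int(9000, n)
    end <- pmin(start + sample.int(3000, n), 10000)
    keep <- end > start
    start <- start[keep]; end <- end[keep]
    if (!length(start)) next
    ann <- genome_annotation(
      tibble::tibble(chrom = "c1", length = 10000, chrom_class = "autosome"),
      tibble::tibble(gene_id = sprintf("g%d", seq_along(start)),
                     chrom = "c1", start = as.integer(start),
                     end = as.integer(end), strand = "+",
                     transcript_length = 100L))
    w <- tibble::tibble(chrom = "c1", start = c(0, 5000), end = c(5000, 10000),
                        partial = FALSE)
    expr <- tibble::tibble(gene_id = sprintf("g%d", seq_along(start)),
                           fpkm = 10)
    m <- window_metrics(w, ann, expr)
    expect_equal(m$kb_transcribed[1],
                 kb_scan_oracle(0, 5000, start, end))
    expect_equal(m$kb_transcribed[2],
                 kb_scan_oracle(5000, 10000, start, end))
    expect_true(all(m$kb_transcribed <= 5))
  }
})

make_metric_fixture <- function(rates, metric) {
  list(
    metrics = tibble::tibble(chrom = "c1",
                             start = seq(0, by = 100, length.out = length(rates)),
                             end = seq(100, by = 100, length.out = length(rates)),
                             partial = FALSE,
                             n_transcribed = metric,
                             kb_transcribed = metric / 10,
                             ota = log10(pmax(metric, 0.1))),
    map = tibble::tibble(chrom = "c1",
                         start = seq(0, by = 100, length.out = length(rates)),
                         end = seq(100, by = 100, length.out = length(rates)),
                         rate = rates))
}

test_that("correlation with recombination recovers perfect monotone relations", {
  fx <- make_metric_fixture(rates = 1:10, metric = 1:10)
  res <- correlate_with_recombination(fx$metrics, fx$map,
                                      metric_cols = "n_transcribed")
  expect_equal(res$rho, 1)
  fx2 <- make_metric_fixture(rates = 10:1, metric = 1:10)
  expect_equal(correlate_with_recombination(fx2$metrics, fx2$map,
                                            metric_cols = "n_transcribed")$rho,
               -1)
})

test_that("spearman matches a rank-then-Pearson oracle with ties", {
  set.seed(81)
  rates <- round(runif(10, 0, 5), 1)
  metric <- sample(0:3, 10, replace = TRUE)
  fx <- make_metric_fixture(rates, metric)
  got <- correlate_with_recombination(fx$metrics, fx$map,
                                      metric_cols = "n_transcribed")
  oracle <- cor(rank(metric), rank(rates))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  expect_error(correlate_with_recombination(fx$metrics[1:2, ], fx$map,
                                            metric_cols = "n_transcribed"),
               "fewer than 3")
})

test_that("landscape regression matches the normal-equations oracle", {
  set.seed(91)
  n <- 24
  X <- cbind(1, n_transcribed = sample(0:8, n, TRUE),
             kb_transcribed = runif(n, 0, 80), ota = runif(n, 2, 7))
  beta <- c(1, 0.5, 0.02, 0.3)
  y <- drop(X %*% beta) + rnorm(n, 0, 0.1)
  metrics <- tibble::tibble(chrom = "c1",
                            start = seq(0, by = 100, length.out = n),
                            end = seq(100, by = 100, length.out = n),
                            partial = FALSE,
                            n_transcribed = X[, 2], kb_transcribed = X[, 3],
                            ota = X[, 4])
  map <- dplyr::mutate(metrics[1:3], rate = y, chrom = "c1")
  fit <- landscape_regression(metrics, map)
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(coef(fit$fit)), unname(drop(oracle)), tolerance = 1e-8)
  expect_equal(glance(fit)$n, n)
})

test_that("regression recovers the generating predictor and flags degenerate input", {
  set.seed(101)
  n <- 200
  ng <- sample(0:10, n, TRUE)
  kb <- runif(n, 0, 100)
  ota <- runif(n, 2, 8)
  metrics <- tibble::tibble(chrom = "c1",
                            start = seq(0, by = 100, length.out = n),
                            end = seq(100, by = 100, length.out = n),
                            partial = FALSE, n_transcribed = ng,
                            kb_transcribed = kb, ota = ota)
  map <- dplyr::mutate(metrics[1:3], rate = 2 + 0.8 * ng + rnorm(n, 0, 0.2))
  fit <- landscape_regression(metrics, map)
  td <- tidy(fit)
  expect_lt(td$p[td$term == "n_transcribed"], 1e-10)
  # pure-noise rate -> slopes indistinguishable from zero
  fit0 <- landscape_regression(metrics, dplyr::mutate(metrics[1:3],
                                                      rate = 3 + rnorm(n)))
  expect_true(all(tidy(fit0)$p[-1] > 0.001))
  expect_error(landscape_regression(
    dplyr::mutate(metrics, n_transcribed = 4), map), "constant predictor")
})

test_that("zero-vs-nonzero transcription contrast behaves at both extremes", {
  set.seed(111)
  n <- 40
  metrics <- tibble::tibble(chrom = "c1",
                            start = seq(0, by = 100, length.out = n),
                            end = seq(100, by = 100, length.out = n),
                            partial = FALSE,
                            n_transcribed = rep(c(0, 3), each = n / 2),
                            kb_transcribed = 0, ota = NA_real_)
  # disjoint rate ranges -> essentially the smallest attainable p
  map <- dplyr::mutate(metrics[1:3],
                       rate = c(runif(n / 2, 0, 1), runif(n / 2, 5, 6)))
  res <- zero_vs_nonzero_transcription(metrics, map)
  expect_lt(res$p, 1e-6)
  expect_equal(res$n_zero, 20)
  # identical distributions -> no signal
  same <- dplyr::mutate(map, rate = rep(runif(n / 2), 2))
  expect_gt(zero_vs_nonzero_transcription(metrics, same)$p, 0.2)
  # empty group
  m1 <- dplyr::mutate(metrics, n_transcribed = 1)
  expect_error(zero_vs_nonzero_transcription(m1, map), "nonempty")
})

test_that("synthetic maps with positive gene effect yield positive recovered rho", {
  cfg <- sim_config(seed = 5, n_genes = 600,
                    chrom_lengths = c(chrX = 4e6, chr2 = 5e6),
                    beta_genes = 0.5, beta_kb = 0, beta_ota = 0,
                    bell_amplitude = 0, recomb_noise_sd = 1)
  ann <- simulate_genome(cfg)
  sim <- simulate_expression(ann, cfg)
  gene_fpkm <- sim$expression |>
    dplyr::filter(grepl("Early", sample_id)) |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(fpkm = mean(fpkm), .groups = "drop")
  map <- simulate_recombination_map(ann, gene_fpkm, cfg)
  metrics <- window_metrics(bin_genome(ann, cfg$window_size), ann, gene_fpkm)
  res <- correlate_with_recombination(metrics, map,
                                      metric_cols = "n_transcribed")
  expect_gt(res$rho, 0)
  expect_lt(res$p, 0.05)
})
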