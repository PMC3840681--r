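#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with validated
#' defaults. The defaults describe a desk-scale Drosophila-like study: a
#' few multi-megabase chromosomes with one X, clustered gene activity with
#' an X excess, lognormal FPKM for active genes, a bell-shaped
#' recombination landscape with a configurable dependence on window
#' transcription, localized DSB events with category weights, reciprocal
#' crosses with a planted maternal-like fraction, and SNP-bearing parental
#' haplotypes read error-free.
#'
#' @param seed Global integer seed; every generator derives its stream from
#'   it, so a fixed seed gives bit-identical output.
#' @param chrom_lengths Named vector of chromosome lengths in bp; names
#'   starting with an X are classed `"X"` (see [infer_chrom_class()]).
#' @param n_genes Total genes to place (allocated across chromosomes by
#'   length).
#' @param gene_length_meanlog,gene_length_sdlog Lognormal parameters of the
#'   genomic gene span in bp.
#' @param clustering_strength Probability in `[0, 1)` that a gene copies
#'   the activity state of its upstream neighbour (two-state Markov chain);
#'   0 gives independent states.
#' @param p_active_x,p_active_autosome Stationary probabilities that an
#'   X-linked / autosomal gene is active.
#' @param fpkm_meanlog,fpkm_sdlog Lognormal parameters of active-gene FPKM.
#' @param sample_sdlog Per-sample lognormal noise (log-SD) around a gene's
#'   base FPKM.
#' @param strain_sdlog Log-SD of the parental strain-A/strain-B expression
#'   difference per gene.
#' @param reads_per_fpkm_kb Expected mapped reads per FPKM per transcript
#'   kilobase (Poisson).
#' @param maternal_effect_fraction Fraction of genes with a planted
#'   maternal-like parent-of-origin effect.
#' @param maternal_effect_size Fractional log-scale shift of offspring
#'   expression from the midparent toward the maternal parent, in `[0, 1]`.
#' @param recomb_base_rate Baseline recombination rate, cM/Mb.
#' @param beta_genes,beta_kb,beta_ota Effect of a window's transcribed gene
#'   count, transcribed kb, and OTA on its rate (cM/Mb per unit).
#' @param bell_amplitude Amplitude (cM/Mb) of the bell-shaped chromosomal
#'   trend peaking mid-arm.
#' @param recomb_noise_sd Gaussian window noise, cM/Mb.
#' @param window_size Landscape window width in bp.
#' @param dsb_category_weights Named relative placement weights for
#'   categories `intergenic`, `silent`, `low`, `medium`, `high`; the
#'   placement probability of a category is proportional to
#'   weight x footprint, so equal weights give uniform placement.
#' @param n_dsbs Number of DSB events.
#' @param dsb_width_range Min/max event width in bp (max 500).
#' @param hap_length Haplotype length in bp.
#' @param n_hap_genes Number of equal-width gene segments tiling the
#'   haplotype (used to aggregate allele counts per gene).
#' @param snp_density SNPs per bp between the parental haplotypes.
#' @param n_rate Probability that a reference-haplotype base is masked `N`.
#' @param read_length Read length in bp.
#' @param n_reads Number of reads sampled from the (error-free) true
#'   haplotypes.
#' @param allele_ratio Fraction of reads originating from parent A.
#' @param n_replicates Replicate libraries per cross for the reciprocal
#'   cross generator.
#' @param replicate_sdlog Lognormal noise (log-SD) between replicate
#'   libraries of the same cross (deep-coverage library CV).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrX = 8e6, chr2 = 10e6,
                                         chr3 = 10e6),
                       n_genes = 2000,
                       gene_length_meanlog = log(3000),
                       gene_length_sdlog = 0.5,
                       clustering_strength = 0.7,
                       p_active_x = 0.604,
                       p_active_autosome = 0.553,
                       fpkm_meanlog = 3,
                       fpkm_sdlog = 1.5,
                       sample_sdlog = 0.15,
                       strain_sdlog = 0.5,
                       reads_per_fpkm_kb = 20,
                       maternal_effect_fraction = 0.1,
                       maternal_effect_size = 0.7,
                       recomb_base_rate = 2,
                       beta_genes = 0.2,
                       beta_kb = 0.05,
                       beta_ota = 0.1,
                       bell_amplitude = 2,
                       recomb_noise_sd = 1,
                       window_size = 1e5,
                       dsb_category_weights = c(intergenic = 0.9,
                                                silent = 1, low = 2,
                                                medium = 1.5, high = 1.2),
                       n_dsbs = 5610,
                       dsb_width_range = c(50, 500),
                       hap_length = 1e5,
                       n_hap_genes = 20,
                       snp_density = 0.005,
                       n_rate = 0.001,
                       read_length = 120,
                       n_reads = 10000,
                       allele_ratio = 0.5,
                       n_replicates = 4,
                       replicate_sdlog = 0.1) {
  cfg <- as.list(environment())
  probs <- c(clustering_strength, p_active_x, p_active_autosome,
             maternal_effect_fraction, maternal_effect_size, snp_density,
             n_rate, allele_ratio)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (any(dsb_category_weights < 0)) abort("DSB weights must be >= 0")
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0)) {
    abort("chrom_lengths must be a named vector of positive lengths")
  }
  if (dsb_width_range[2] > 500) abort("DSB events must be <= 500 bp")
  if (window_size <= 0 || n_genes < 0) abort("invalid size parameter")
  structure(cfg, class = "sim_config")
}

# run code under a seed derived from the config without disturbing the
# caller's RNG state
with_sim_seed <- function(config, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed((as.integer(config$seed) + offset) %% .Machine$integer.max)
  force(code)
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes along the configured chromosomes (allocated
#' proportionally to length) with lognormal genomic spans and exonic
#' transcript lengths drawn as a uniform fraction of the span. The first
#' X-named chromosome carries the X class.
#'
#' @param config A [sim_config()].
#' @return A [genome_annotation()].
#' @export
simulate_genome <- function(config) {
  with_sim_seed(config, 0L, {
    chroms <- tibble(chrom = names(config$chrom_lengths),
                     length = unname(config$chrom_lengths),
                     chrom_class = infer_chrom_class(names(config$chrom_lengths)))
    if (config$n_genes == 0) {
      return(genome_annotation(chroms, tibble(
        gene_id = character(), chrom = character(), start = integer(),
        end = integer(), strand = character(), transcript_length = integer())))
    }
    n_per <- round(config$n_genes * chroms$length / sum(chroms$length))
    n_per[1] <- n_per[1] + config$n_genes - sum(n_per)
    genes <- purrr::pmap_dfr(
      list(chroms$chrom, chroms$length, n_per),
      function(chrom, clen, n) {
        if (n == 0) return(NULL)
        len <- pmax(200, round(rlnorm(n, config$gene_length_meanlog,
                                      config$gene_length_sdlog)))
        free <- clen - sum(len)
        if (free < 0) {
          abort(paste0("requested gene footprint exceeds chromosome ", chrom))
        }
        gaps <- diff(c(0, sort(runif(n, 0, free)), free))[seq_len(n)]
        starts <- cumsum(gaps) + cumsum(c(0, len[-n]))
        tibble(chrom = chrom,
               start = as.integer(round(starts)),
               end = as.integer(round(starts) + len),
               strand = sample(c("+", "-"), n, replace = TRUE),
               transcript_length = pmax(1L, as.integer(round(
                 len * runif(n, 0.5, 0.95)))))
      })
    genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
    genome_annotation(chroms, genes)
  })
}

markov_states <- function(n, persistence, p_active) {
  state <- logical(n)
  state[1] <- runif(1) < p_active
  if (n > 1) {
    copy <- runif(n - 1) < persistence
    fresh <- runif(n - 1) < p_active
    for (i in 2:n) {
      state[i] <- if (copy[i - 1]) state[i - 1] else fresh[i - 1]
    }
  }
  state
}

#' Generate a synthetic expression table
#'
#' Produces the eight-sample design of the emulated study — four genotypes
#' (two parental strains A and B, and the two reciprocal crosses AxB with
#' mother A and BxA with mother B), each in Early and Late condition.
#' Activity states are drawn as a two-state Markov chain along gene order
#' (persistence = `clustering_strength`) with a higher activity probability
#' on the X. Active genes get lognormal base FPKM, a per-gene parental
#' strain difference, per-sample lognormal noise, and Poisson mapped
#' reads. A `maternal_effect_fraction` of genes has offspring expression
#' shifted from the midparent toward the maternal strain by
#' `maternal_effect_size` on the log scale.
#'
#' @param annotation A nonempty [genome_annotation()].
#' @param config A [sim_config()].
#' @return List with `expression` (tibble `gene_id`, `sample_id`, `fpkm`,
#'   `mapped_reads`), `samples` (metadata tibble), and `truth` (tibble
#'   `gene_id`, `active`, `base_fpkm`, `strain_lfc`, `maternal_effect`).
#' @export
simulate_expression <- function(annotation, config) {
  if (!nrow(annotation$genes)) abort("annotation has no genes")
  with_sim_seed(config, 1L, {
    genes <- annotation$genes |>
      left_join(annotation$chromosomes[c("chrom", "chrom_class")],
                by = "chrom")
    # per-chromosome Markov chain over genomic gene order
    active <- unlist(lapply(split(genes$chrom_class, genes$chrom)[
      unique(genes$chrom)], function(cls) {
        p <- if (cls[1] == "X") config$p_active_x else config$p_active_autosome
        markov_states(length(cls), config$clustering_strength, p)
      }), use.names = FALSE)
    n <- nrow(genes)
    base_fpkm <- ifelse(active,
                        rlnorm(n, config$fpkm_meanlog, config$fpkm_sdlog), 0)
    strain_lfc <- rnorm(n, 0, config$strain_sdlog)      # log(A) - log(B)
    maternal_effect <- runif(n) < config$maternal_effect_fraction
    cond_lfc <- rnorm(n, 0, 0.3)                        # Early vs Late shift

    samples <- tibble(
      genotype = rep(c("A", "B", "AxB", "BxA"), each = 2),
      condition = rep(c("Early", "Late"), 4),
      maternal_strain = rep(c(NA, NA, "A", "B"), each = 2)
    ) |>
      mutate(sample_id = paste0(.data$genotype, "_", .data$condition))

    parent_a <- base_fpkm * exp(strain_lfc / 2)
    parent_b <- base_fpkm * exp(-strain_lfc / 2)
    mid <- sqrt(parent_a * parent_b)  # geometric midparent = base_fpkm
    shift <- ifelse(maternal_effect, config$maternal_effect_size, 0)
    off_ma <- mid * (parent_a / pmax(mid, 1e-12))^shift
    off_mb <- mid * (parent_b / pmax(mid, 1e-12))^shift

    level <- list(A = parent_a, B = parent_b, AxB = off_ma, BxA = off_mb)
    expr <- purrr::pmap_dfr(samples, function(genotype, condition,
                                              maternal_strain, sample_id) {
      mu <- level[[genotype]] *
        exp(if (condition == "Early") cond_lfc / 2 else -cond_lfc / 2)
      fpkm <- mu * rlnorm(n, 0, config$sample_sdlog)
      fpkm[!active] <- 0
      reads <- rpois(n, fpkm * genes$transcript_length / 1000 *
                       config$reads_per_fpkm_kb)
      tibble(gene_id = genes$gene_id, sample_id = sample_id,
             fpkm = fpkm, mapped_reads = reads)
    })
    mapped <- expr |> group_by(.data$sample_id) |>
      summarise(mapped_reads = sum(.data$mapped_reads), .groups = "drop")
    samples <- samples |>
      left_join(mapped, by = "sample_id") |>
      mutate(gross_reads = ceiling(.data$mapped_reads /
                                     runif(dplyr::n(), 0.72, 0.86)))
    truth <- tibble(gene_id = genes$gene_id, active = active,
                    base_fpkm = base_fpkm, strain_lfc = strain_lfc,
                    maternal_effect = maternal_effect)
    list(expression = expr,
         samples = samples[c("sample_id", "condition", "genotype",
                             "maternal_strain", "gross_reads",
                             "mapped_reads")],
         truth = truth)
  })
}

#' Generate a synthetic recombination map
#'
#' Window rate = max(0, base + beta_genes * n_transcribed +
#' beta_kb * kb_transcribed + beta_ota * OTA + bell-shaped chromosomal
#' trend + Gaussian noise), computed on the full (non-partial) windows of
#' the annotation at the configured window size. Undefined OTA (windows
#' with no transcription) contributes 0 to the generative model.
#'
#' @param annotation [genome_annotation()].
#' @param gene_expression Tibble `gene_id`, `fpkm` used for the window
#'   metrics (e.g. mean Early FPKM).
#' @param config A [sim_config()].
#' @param fpkm_threshold Activity threshold for the metrics (default 1).
#' @return Recombination-map tibble `chrom`, `start`, `end`, `rate` of
#'   uniform-width windows, with the generating metrics as extra columns
#'   `n_transcribed`, `kb_transcribed`, `ota`.
#' @export
simulate_recombination_map <- function(annotation, gene_expression, config,
                                       fpkm_threshold = 1) {
  with_sim_seed(config, 2L, {
    windows <- bin_genome(annotation, config$window_size) |>
      filter(!.data$partial)
    met <- window_metrics(windows, annotation, gene_expression,
                          fpkm_threshold = fpkm_threshold)
    clen <- setNames(annotation$chromosomes$length,
                     annotation$chromosomes$chrom)
    x <- (met$start + met$end) / 2 / clen[met$chrom]
    bell <- config$bell_amplitude * 4 * x * (1 - x)
    ota0 <- ifelse(is.na(met$ota), 0, met$ota)
    rate <- pmax(0, config$recomb_base_rate +
                   config$beta_genes * met$n_transcribed +
                   config$beta_kb * met$kb_transcribed +
                   config$beta_ota * ota0 +
                   bell +
                   rnorm(nrow(met), 0, config$recomb_noise_sd))
    met |>
      mutate(rate = rate) |>
      select("chrom", "start", "end", "rate", "n_transcribed",
             "kb_transcribed", "ota")
  })
}

#' Generate synthetic DSB events
#'
#' Events are drawn category-first: a transcription category is sampled
#' with probability proportional to weight x footprint (so equal weights
#' give uniform genome-wide placement), then the event midpoint is placed
#' uniformly within that category's footprint and the event width drawn
#' uniformly from `dsb_width_range` (clipped at segment/chromosome
#' boundaries, never above 500 bp).
#'
#' @param annotation [genome_annotation()].
#' @param gene_expression Tibble `gene_id`, `fpkm` for the partition.
#' @param config A [sim_config()].
#' @return List with `events` (tibble `chrom`, `start`, `end`,
#'   `true_category`) and the `partition` used.
#' @export
simulate_dsbs <- function(annotation, gene_expression, config) {
  with_sim_seed(config, 3L, {
    partition <- build_partition(annotation, gene_expression)
    fp <- partition$footprint
    w <- config$dsb_category_weights[as.character(fp$category)]
    if (anyNA(w)) abort("dsb_category_weights must name every category")
    prob <- unname(w) * fp$bp
    if (sum(prob) <= 0) abort("all category placement probabilities are zero")
    cat_draw <- sample(as.character(fp$category), config$n_dsbs,
                       replace = TRUE, prob = prob)
    seg <- partition$segments
    chrom_len <- setNames(annotation$chromosomes$length,
                          annotation$chromosomes$chrom)
    events <- purrr::map_dfr(split(seq_len(config$n_dsbs), cat_draw),
                             function(ii) {
      cat <- cat_draw[ii[1]]
      s <- seg[as.character(seg$category) == cat, , drop = FALSE]
      widths <- s$end - s$start
      pick <- sample.int(nrow(s), length(ii), replace = TRUE, prob = widths)
      mid <- s$start[pick] + floor(runif(length(ii)) * widths[pick])
      ew <- round(runif(length(ii), config$dsb_width_range[1],
                        config$dsb_width_range[2]))
      start <- pmax(0, mid - floor(ew / 2))
      end <- pmin(chrom_len[s$chrom[pick]], mid + ceiling(ew / 2))
      tibble(chrom = s$chrom[pick], start = as.integer(start),
             end = as.integer(end), true_category = cat)
    })
    events <- arrange(events, .data$chrom, .data$start)
    list(events = events, partition = partition)
  })
}

#' Generate parental haplotypes and error-free reads
#'
#' Parent B's true sequence equals parent A's with substitutions at SNP
#' positions (density `snp_density`). The *reference* version of each
#' haplotype additionally has bases masked to `N` at rate `n_rate` —
#' emulating imperfect reference assemblies; reads are sampled error-free
#' from the true (unmasked) haplotypes, from parent A with probability
#' `allele_ratio`. The haplotype is tiled into `n_hap_genes` equal gene
#' segments and each read is labelled with the gene containing its
#' midpoint.
#'
#' @param config A [sim_config()].
#' @return List with `reference_a`/`reference_b` (character; the N-masked
#'   references used for assignment), `reads` (tibble `read_id`, `gene_id`,
#'   `origin`, `pos`, `seq`), `snp_positions` (0-based), and `genes`
#'   (tibble `gene_id`, `start`, `end`).
#' @export
simulate_haplotypes_and_reads <- function(config) {
  with_sim_seed(config, 4L, {
    L <- as.integer(config$hap_length)
    bases <- c("A", "C", "G", "T")
    true_a <- sample(bases, L, replace = TRUE)
    true_b <- true_a
    n_snps <- rbinom(1, L, config$snp_density)
    snp_pos <- sort(sample.int(L, n_snps))        # 1-based here
    true_b[snp_pos] <- vapply(true_a[snp_pos], function(b) {
      sample(setdiff(bases, b), 1)
    }, character(1))
    ref_a <- true_a
    ref_b <- true_b
    na_pos <- which(runif(L) < config$n_rate)
    nb_pos <- which(runif(L) < config$n_rate)
    ref_a[na_pos] <- "N"
    ref_b[nb_pos] <- "N"

    rl <- config$read_length
    if (rl > L) abort("read_length exceeds haplotype length")
    origin <- ifelse(runif(config$n_reads) < config$allele_ratio, "A", "B")
    pos <- sample.int(L - rl + 1, config$n_reads, replace = TRUE) - 1L
    true_a_str <- paste(true_a, collapse = "")
    true_b_str <- paste(true_b, collapse = "")
    seqs <- ifelse(origin == "A",
                   substring(true_a_str, pos + 1, pos + rl),
                   substring(true_b_str, pos + 1, pos + rl))
    gene_w <- L / config$n_hap_genes
    gene_id <- sprintf("hg%03d",
                       pmin(config$n_hap_genes,
                            floor((pos + rl / 2) / gene_w) + 1))
    genes <- tibble(
      gene_id = sprintf("hg%03d", seq_len(config$n_hap_genes)),
      start = as.integer(floor((seq_len(config$n_hap_genes) - 1) * gene_w)),
      end = as.integer(floor(seq_len(config$n_hap_genes) * gene_w)))
    list(reference_a = paste(ref_a, collapse = ""),
         reference_b = paste(ref_b, collapse = ""),
         reads = tibble(read_id = sprintf("r%06d", seq_len(config$n_reads)),
                        gene_id = gene_id, origin = origin, pos = pos,
                        seq = seqs),
         snp_positions = snp_pos - 1L,
         genes = genes)
  })
}

#' Generate a reciprocal-cross expression table with replicates
#'
#' Per-gene parental and offspring FPKM with `n_replicates` replicate
#' libraries per profile, a planted maternal-like effect in a configured
#' fraction of genes, and a per-gene reciprocal-difference p-value from a
#' two-sample t-test on log FPKM of the replicates (BH-adjusted to q).
#' Only active genes (which have positive FPKM) are emitted.
#'
#' @param annotation [genome_annotation()].
#' @param config A [sim_config()].
#' @return Tibble with `gene_id`, `parent_a`, `parent_b`, `offspring_ma`,
#'   `offspring_mb` (replicate-mean FPKM), `p`, `q`, and the truth flag
#'   `true_maternal_effect`.
#' @export
simulate_reciprocal_crosses <- function(annotation, config) {
  sim <- simulate_expression(annotation, config)
  with_sim_seed(config, 5L, {
    truth <- filter(sim$truth, .data$active)
    n <- nrow(truth)
    if (!n) abort("no active genes to simulate crosses for")
    parent_a <- truth$base_fpkm * exp(truth$strain_lfc / 2)
    parent_b <- truth$base_fpkm * exp(-truth$strain_lfc / 2)
    shift <- ifelse(truth$maternal_effect, config$maternal_effect_size, 0)
    mu_ma <- truth$base_fpkm * exp(shift * truth$strain_lfc / 2)
    mu_mb <- truth$base_fpkm * exp(-shift * truth$strain_lfc / 2)
    reps <- function(mu) {
      matrix(mu * rlnorm(n * config$n_replicates, 0, config$replicate_sdlog),
             nrow = n)
    }
    ma <- reps(mu_ma)
    mb <- reps(mu_mb)
    p <- vapply(seq_len(n), function(i) {
      stats::t.test(log(ma[i, ]), log(mb[i, ]))$p.value
    }, numeric(1))
    tibble(gene_id = truth$gene_id,
           parent_a = parent_a, parent_b = parent_b,
           offspring_ma = rowMeans(ma), offspring_mb = rowMeans(mb),
           p = p, q = bh_adjust(p),
           true_maternal_effect = truth$maternal_effect)
  })
}

#' Write haplotypes as FASTA
#'
#' @param haplotypes Named character vector or list of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(haplotypes, path) {
  seqs <- Biostrings::DNAStringSet(unlist(haplotypes))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}
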