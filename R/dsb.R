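#' Partition the genome into transcription categories
#'
#' Genes are classed by expression: silent when FPKM < `silent_threshold`
#' (default 0.001, a conservative "no active transcription" bound), and
#' active genes split into low/medium/high by ranking the target-potential
#' product FPKM x transcript_length at `activity_cuts` (default count
#' tertiles). Bases covered by genes of different categories take the
#' highest category (high > medium > low > silent); everything else is
#' intergenic. Category footprints partition the genome exactly.
#'
#' @param annotation [genome_annotation()].
#' @param gene_expression Tibble `gene_id`, `fpkm` (one row per gene).
#' @param silent_threshold FPKM below which a gene is silent.
#' @param activity_cuts Strictly increasing quantile cut points in (0, 1)
#'   splitting active genes into groups (default `c(1/3, 2/3)`).
#' @return Object of class `category_partition`: list with `segments`
#'   (tibble `chrom`, `start`, `end`, `category`, 0-based half-open,
#'   disjoint, covering the genome), `footprint` (tibble `category`, `bp`,
#'   `fraction`), `gene_categories` (tibble `gene_id`, `category`), and
#'   `n_contested_bases` (bases where overlapping genes disagreed).
#' @export
build_partition <- function(annotation, gene_expression,
                            silent_threshold = 0.001,
                            activity_cuts = c(1 / 3, 2 / 3)) {
  if (length(activity_cuts) &&
      (any(activity_cuts <= 0) || any(activity_cuts >= 1) ||
       is.unsorted(activity_cuts, strictly = TRUE))) {
    abort("activity_cuts must be strictly increasing within (0, 1)")
  }
  cat_levels <- c("intergenic", "silent", "low", "medium", "high")
  genes <- inner_join(annotation$genes, gene_expression, by = "gene_id")
  genes$category <- "silent"
  act <- genes$fpkm >= silent_threshold
  if (any(act)) {
    potential <- genes$fpkm[act] * genes$transcript_length[act]
    grp_names <- c("low", "medium", "high")[seq_len(length(activity_cuts) + 1)]
    # count-based split: rank, then cut at ceiling(q * n)
    rk <- rank(potential, ties.method = "first")
    bounds <- ceiling(activity_cuts * sum(act))
    grp <- findInterval(rk, c(0, bounds) + 0.5) |> pmin(length(grp_names))
    genes$category[act] <- grp_names[grp]
  }

  chrom_gr <- GenomicRanges::GRanges(
    annotation$chromosomes$chrom,
    IRanges::IRanges(1, annotation$chromosomes$length))
  seg <- list()
  remaining <- chrom_gr
  # peel off categories from highest priority down; remainder is intergenic
  for (cat in c("high", "medium", "low", "silent")) {
    g <- genes[genes$category == cat, , drop = FALSE]
    if (nrow(g)) {
      gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        g$chrom, IRanges::IRanges(g$start + 1, g$end)))
      take <- GenomicRanges::intersect(remaining, gr, ignore.strand = TRUE)
      if (length(take)) {
        seg[[cat]] <- tibble(
          chrom = as.character(GenomicRanges::seqnames(take)),
          start = GenomicRanges::start(take) - 1L,
          end = GenomicRanges::end(take),
          category = cat)
      }
      remaining <- GenomicRanges::setdiff(remaining, gr, ignore.strand = TRUE)
    }
  }
  if (length(remaining)) {
    seg[["intergenic"]] <- tibble(
      chrom = as.character(GenomicRanges::seqnames(remaining)),
      start = GenomicRanges::start(remaining) - 1L,
      end = GenomicRanges::end(remaining),
      category = "intergenic")
  }
  segments <- bind_rows(seg) |>
    arrange(.data$chrom, .data$start) |>
    mutate(category = factor(.data$category, levels = cat_levels))

  genome_bp <- sum(annotation$chromosomes$length)
  footprint <- segments |>
    group_by(.data$category) |>
    summarise(bp = sum(.data$end - .data$start), .groups = "drop") |>
    tidyr::complete(category = factor(cat_levels, levels = cat_levels),
                    fill = list(bp = 0)) |>
    mutate(fraction = .data$bp / genome_bp)

  # contested bases: covered by >1 distinct gene category
  gene_grs <- lapply(split(genes, genes$category), function(g) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$start + 1, g$end)))
  })
  contested <- 0
  cats <- names(gene_grs)
  if (length(cats) > 1) {
    for (i in seq_len(length(cats) - 1)) {
      for (j in seq(i + 1, length(cats))) {
        ov <- GenomicRanges::intersect(gene_grs[[i]], gene_grs[[j]],
                                       ignore.strand = TRUE)
        contested <- contested + sum(GenomicRanges::width(ov))
      }
    }
  }

  structure(list(segments = segments, footprint = footprint,
                 gene_categories = genes[c("gene_id", "category")],
                 n_contested_bases = contested,
                 genome_bp = genome_bp,
                 chromosomes = annotation$chromosomes),
            class = "category_partition")
}

#' @export
print.category_partition <- function(x, ...) {
  cat("<category_partition> genome =", x$genome_bp, "bp;",
      x$n_contested_bases, "contested base(s)\n")
  print(x$footprint)
  invisible(x)
}

# sorted segment table with cumulative genome offsets, for fast
# midpoint-to-category lookup
partition_index <- function(partition) {
  chr <- partition$chromosomes
  offset <- c(0, cumsum(chr$length))[seq_len(nrow(chr))]
  names(offset) <- chr$chrom
  seg <- partition$segments
  seg$gstart <- seg$start + offset[seg$chrom]
  seg$gend <- seg$end + offset[seg$chrom]
  seg <- seg[order(seg$gstart), ]
  list(seg = seg, offset = offset, total = sum(chr$length))
}

#' Classify DSB events by transcription category
#'
#' Each event (an interval of at most 500 bp) is reduced to its midpoint
#' and classified by the partition category at that base — the same rule
#' the Monte-Carlo null uses, keeping observed and expected commensurable.
#'
#' @param events Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param partition A [build_partition()] result.
#' @return List with `events` (input plus `category`) and `observed`
#'   (tibble `category`, `observed`).
#' @export
classify_events <- function(events, partition) {
  idx <- partition_index(partition)
  pos <- match(events$chrom, names(idx$offset))
  if (anyNA(pos)) {
    abort(paste0("event on unknown chromosome: ",
                 paste(unique(events$chrom[is.na(pos)]), collapse = ", ")))
  }
  lens <- partition$chromosomes$length[pos]
  bad <- events$start < 0 | events$end > lens
  if (any(bad)) {
    abort(paste0("event(s) out of chromosome bounds at rows ",
                 paste(head(which(bad), 5), collapse = ", ")))
  }
  mid <- floor((events$start + events$end) / 2)
  gpos <- mid + idx$offset[events$chrom]
  cat <- idx$seg$category[findInterval(gpos, idx$seg$gstart)]
  events$category <- cat
  observed <- events |>
    group_by(.data$category) |>
    summarise(observed = n(), .groups = "drop") |>
    tidyr::complete(category = levels(idx$seg$category) |>
                      factor(levels = levels(idx$seg$category)),
                    fill = list(observed = 0L))
  list(events = events, observed = observed)
}

#' Monte-Carlo null for DSB category counts
#'
#' Each replicate places `n_events` midpoints uniformly over the
#' concatenated genome and tallies the partition category at each placed
#' base. The per-category mean over replicates is the expected count; as
#' the replicate number grows it converges to footprint-fraction x
#' `n_events`.
#'
#' @param n_events Number of events per replicate (> 0).
#' @param partition A [build_partition()] result.
#' @param n_replicates Number of replicates (default 10,000).
#' @param seed Integer seed for the placement RNG.
#' @return Object of class `dsb_null`: list with `counts` (replicates x
#'   categories integer matrix), `expected` (tibble `category`, `expected`),
#'   `n_events`, `n_replicates`, `seed`.
#' @export
monte_carlo_null <- function(n_events, partition, n_replicates = 10000,
                             seed = 1L) {
  if (n_events <= 0) abort("n_events must be > 0")
  idx <- partition_index(partition)
  if (idx$total <= 0) abort("zero-length genome")
  cats <- levels(idx$seg$category)
  counts <- matrix(0L, nrow = n_replicates, ncol = length(cats),
                   dimnames = list(NULL, cats))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    chunk <- max(1L, floor(5e6 / n_events))
    done <- 0L
    while (done < n_replicates) {
      k <- min(chunk, n_replicates - done)
      u <- runif(k * n_events, min = 0, max = idx$total)
      cat_i <- as.integer(idx$seg$category[findInterval(u, idx$seg$gstart)])
      m <- matrix(cat_i, nrow = k, byrow = TRUE)
      for (ci in seq_along(cats)) {
        counts[done + seq_len(k), ci] <- rowSums(m == ci)
      }
      done <- done + k
    }
  })
  expected <- tibble(category = factor(cats, levels = cats),
                     expected = unname(colMeans(counts)))
  structure(list(counts = counts, expected = expected, n_events = n_events,
                 n_replicates = n_replicates, seed = seed),
            class = "dsb_null")
}

#' Empirical enrichment test of observed DSB counts against the null
#'
#' Relative presence is observed / expected (undefined and flagged when the
#' expected count is 0 with observed > 0). The empirical p-value is
#' two-sided by doubling the smaller tail with add-one correction:
#' `p = min(1, 2 * (1 + min(#null <= obs, #null >= obs)) / (1 + R))` —
#' never exactly zero.
#'
#' @param observed Tibble `category`, `observed` (e.g. from
#'   [classify_events()]).
#' @param null A [monte_carlo_null()] result with at least 100 replicates.
#' @return Tibble `category`, `observed`, `expected`, `relative_presence`,
#'   `p_empirical`, `n_replicates`, `seed`.
#' @export
enrichment_test <- function(observed, null) {
  if (null$n_replicates < 100) abort("null needs >= 100 replicates")
  cats <- colnames(null$counts)
  obs <- observed$observed[match(cats, as.character(observed$category))]
  obs[is.na(obs)] <- 0L
  exp_ <- null$expected$expected
  rp <- ifelse(exp_ > 0, obs / exp_,
               ifelse(obs > 0, NA_real_, 1))
  if (any(is.na(rp))) {
    warn("relative presence undefined for category with expected = 0 and observed > 0")
  }
  res <- purrr::map_dbl(seq_along(cats), function(i) {
    lower <- sum(null$counts[, i] <= obs[i])
    upper <- sum(null$counts[, i] >= obs[i])
    min(1, 2 * (1 + min(lower, upper)) / (1 + null$n_replicates))
  })
  tibble(category = factor(cats, levels = cats), observed = obs,
         expected = exp_, relative_presence = rp, p_empirical = res,
         n_replicates = null$n_replicates, seed = null$seed)
}

#' DSB enrichment analysis in one call
#'
#' Classifies events against the partition, simulates the random-placement
#' null, and tests each category.
#'
#' @inheritParams classify_events
#' @inheritParams monte_carlo_null
#' @return The [enrichment_test()] tibble, with the classified events in
#'   attribute `"events"`.
#' @export
dsb_enrichment <- function(events, partition, n_replicates = 10000,
                           seed = 1L) {
  cl <- classify_events(events, partition)
  null <- monte_carlo_null(nrow(events), partition,
                           n_replicates = n_replicates, seed = seed)
  out <- enrichment_test(cl$observed, null)
  attr(out, "events") <- cl$events
  out
}
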