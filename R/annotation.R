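#' Genome annotation container
#'
#' Bundles the chromosome table and the gene table that form the coordinate
#' backbone for every downstream stage. All coordinates are 0-based,
#' half-open; format readers convert at the boundary.
#'
#' @param chromosomes Tibble with columns `chrom` (character, unique),
#'   `length` (bp, > 0) and `chrom_class` (one of `"X"`, `"autosome"`,
#'   `"unplaced"`).
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`, `"-"` or `"."`) and
#'   `transcript_length` (summed exonic bp; may exceed the genomic span is
#'   not required but must be positive).
#'
#' @return An object of class `genome_annotation`: a list with elements
#'   `chromosomes` and `genes`, genes sorted by (chrom, start, end, gene_id).
#' @export
#' @examples
#' ann <- genome_annotation(
#'   chromosomes = tibble::tibble(chrom = "chr2L", length = 1e6,
#'                                chrom_class = "autosome"),
#'   genes = tibble::tibble(gene_id = "g1", chrom = "chr2L", start = 100L,
#'                          end = 900L, strand = "+", transcript_length = 600L)
#' )
genome_annotation <- function(chromosomes, genes) {
  chromosomes <- as_tibble(chromosomes)
  genes <- as_tibble(genes)
  need_chr <- c("chrom", "length", "chrom_class")
  need_gen <- c("gene_id", "chrom", "start", "end", "strand",
                "transcript_length")
  if (!all(need_chr %in% names(chromosomes))) {
    abort(paste0("chromosomes must have columns: ",
                 paste(need_chr, collapse = ", ")))
  }
  if (!all(need_gen %in% names(genes))) {
    abort(paste0("genes must have columns: ", paste(need_gen, collapse = ", ")))
  }
  out <- structure(
    list(chromosomes = chromosomes[need_chr],
         genes = arrange(genes[need_gen], .data$chrom, .data$start,
                         .data$end, .data$gene_id)),
    class = "genome_annotation"
  )
  validate_annotation(out)
  out
}

#' Validate a genome annotation
#'
#' Checks the structural invariants: unique chromosome names, positive
#' chromosome lengths, genes with `start < end` lying within their
#' chromosome, positive transcript lengths, and a known chromosome class.
#'
#' @param annotation A [genome_annotation()] object.
#' @return The annotation, invisibly, if valid; otherwise an error.
#' @export
validate_annotation <- function(annotation) {
  chr <- annotation$chromosomes
  gen <- annotation$genes
  if (anyDuplicated(chr$chrom)) abort("duplicate chromosome names")
  if (any(chr$length <= 0)) abort("chromosome lengths must be > 0")
  bad_class <- setdiff(unique(chr$chrom_class), c("X", "autosome", "unplaced"))
  if (length(bad_class)) {
    abort(paste0("unknown chrom_class: ", paste(bad_class, collapse = ", ")))
  }
  if (nrow(gen)) {
    if (any(gen$start >= gen$end)) {
      abort("genes must satisfy start < end (0-based half-open)")
    }
    if (any(gen$transcript_length <= 0)) {
      abort("transcript_length must be > 0")
    }
    if (!all(gen$strand %in% c("+", "-", "."))) {
      abort("strand must be one of '+', '-', '.'")
    }
    idx <- match(gen$chrom, chr$chrom)
    if (anyNA(idx)) {
      abort(paste0("gene chromosome not in annotation: ",
                   paste(unique(gen$chrom[is.na(idx)]), collapse = ", ")))
    }
    off <- gen$start < 0 | gen$end > chr$length[idx]
    if (any(off)) {
      abort(paste0("gene(s) outside chromosome bounds: ",
                   paste(head(gen$gene_id[off], 5), collapse = ", ")))
    }
  }
  invisible(annotation)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", nrow(x$chromosomes), " chromosome(s), ",
      nrow(x$genes), " gene(s)\n", sep = "")
  cat("  classes: ",
      paste(sprintf("%s=%d", names(table(x$chromosomes$chrom_class)),
                    table(x$chromosomes$chrom_class)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read a genome annotation from GFF3 or BED12
#'
#' GFF3 gene/mRNA-bearing files or BED12 transcript files are converted to
#' the internal 0-based half-open convention. For GFF3, records of type
#' `gene` (falling back to `mRNA`/`transcript` when no `gene` records exist)
#' become genes and `transcript_length` is the summed length of their exon
#' children when exons are present, else the genomic span. For BED12 the
#' block sizes are summed.
#'
#' @param path Path to the annotation file.
#' @param format `"GFF3"` or `"BED12"` (also accepts `"BED"`/`"BED6"`; with
#'   no blocks the span is used as transcript length).
#' @param chromosomes Tibble of chromosome `chrom`, `length`, `chrom_class`.
#'   If `NULL`, chromosome lengths are taken from the file's sequence
#'   information when present, else set to the maximum gene end per
#'   chromosome, and every chromosome is classed by [infer_chrom_class()].
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("GFF3", "BED12", "BED", "BED6"),
                            chromosomes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  gr <- tryCatch(
    rtracklayer::import(path,
                        format = if (format == "GFF3") "gff3" else "bed"),
    error = function(e) abort(paste0("failed to parse ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(gr) == 0) {
    warn(paste0("empty annotation file: ", path))
    genes <- tibble(gene_id = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character(),
                    transcript_length = integer())
  } else if (format == "GFF3") {
    genes <- gff_to_genes(gr)
  } else {
    genes <- bed_to_genes(gr)
  }
  if (is.null(chromosomes)) {
    sl <- annotation_seqlengths(gr)
    if (format == "GFF3") {
      sl <- c(sl[!is.na(sl)], gff_sequence_regions(path))
      sl <- sl[!duplicated(names(sl))]
    }
    if (nrow(genes)) {
      span <- genes |> group_by(.data$chrom) |>
        summarise(maxend = max(.data$end), .groups = "drop")
    } else {
      span <- tibble(chrom = character(), maxend = integer())
    }
    chroms <- unique(c(names(sl)[!is.na(sl)], span$chrom))
    len <- ifelse(chroms %in% names(sl) & !is.na(sl[chroms]),
                  unname(sl[chroms]),
                  span$maxend[match(chroms, span$chrom)])
    chromosomes <- tibble(chrom = chroms, length = as.numeric(len),
                          chrom_class = infer_chrom_class(chroms))
  }
  genome_annotation(chromosomes, genes)
}

annotation_seqlengths <- function(gr) {
  tryCatch(GenomeInfoDb::seqlengths(gr), error = function(e) integer())
}

# ##sequence-region pragmas carry chromosome lengths in GFF3 headers
gff_sequence_regions <- function(path) {
  hdr <- grep("^##sequence-region", readLines(path, warn = FALSE),
              value = TRUE)
  if (!length(hdr)) return(integer())
  parts <- strsplit(trimws(hdr), "\\s+")
  setNames(vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
           vapply(parts, function(p) p[2], character(1)))
}

gff_to_genes <- function(gr) {
  type <- as.character(gr$type)
  gene_types <- if (any(type == "gene")) "gene" else
    intersect(c("mRNA", "transcript"), type)
  if (!length(gene_types)) abort("no gene/mRNA/transcript records in GFF3")
  g <- gr[type %in% gene_types]
  ids <- as.character(g$ID %||% g$Name %||% paste0("gene", seq_along(g)))
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  exons <- gr[type == "exon"]
  tl <- GenomicRanges::width(g)  # fallback: genomic span
  if (length(exons) && !is.null(exons$Parent)) {
    par <- as.character(S4Vectors::unstrsplit(exons$Parent, ","))
    exon_sum <- tapply(GenomicRanges::width(exons), par, sum)
    hit <- ids %in% names(exon_sum)
    tl[hit] <- exon_sum[ids[hit]]
  }
  tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,  # GFF 1-based closed -> 0-based
    end = GenomicRanges::end(g),
    strand = chartr("*", ".", as.character(GenomicRanges::strand(g))),
    transcript_length = as.integer(tl)
  )
}

bed_to_genes <- function(gr) {
  tl <- if (!is.null(gr$blocks)) {
    as.integer(sum(GenomicRanges::width(gr$blocks)))
  } else {
    GenomicRanges::width(gr)
  }
  ids <- as.character(gr$name %||% paste0("gene", seq_along(gr)))
  tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # rtracklayer presents 1-based
    end = GenomicRanges::end(gr),
    strand = chartr("*", ".", as.character(GenomicRanges::strand(gr))),
    transcript_length = as.integer(tl)
  )
}

#' Guess chromosome class from its name
#'
#' `X`-named chromosomes are class `"X"`, names containing `U`, `random` or
#' `Het`-style unplaced markers are `"unplaced"`, everything else
#' `"autosome"`.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of classes.
#' @export
infer_chrom_class <- function(chrom) {
  dplyr::case_when(
    grepl("(^|chr)X(Het)?$", chrom) ~ "X",
    grepl("U|random|Un", chrom) ~ "unplaced",
    TRUE ~ "autosome"
  )
}

#' Convert genes to a GRanges
#'
#' Internal 0-based half-open gene intervals become 1-based closed ranges.
#'
#' @param genes Gene tibble (as in a [genome_annotation()]).
#' @param chromosomes Optional chromosome tibble supplying seqlengths.
#' @return A `GRanges`.
#' @export
genes_to_granges <- function(genes, chromosomes = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = chartr(".", "*", genes$strand)
  )
  names(gr) <- genes$gene_id
  if (!is.null(chromosomes)) {
    GenomicRanges::seqlevels(gr) <- chromosomes$chrom
    GenomicRanges::seqlengths(gr) <- chromosomes$length
  }
  gr
}

#' Write genes as BED6
#'
#' @param genes Gene tibble (0-based half-open coordinates, written as-is:
#'   BED shares the internal convention).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(genes, path) {
  readr::write_tsv(
    tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
           name = genes$gene_id, score = 0L, strand = genes$strand),
    path, col_names = FALSE)
  invisible(path)
}
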