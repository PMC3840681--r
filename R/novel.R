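#' Staged filter cascade for candidate novel transcripts
#'
#' Applies, in fixed order, the reproducible filters used to whittle an
#' assembler's list of unannotated transcribed items down to
#' high-confidence candidates:
#'
#' 1. detected in at least `min_samples` samples (detection = FPKM > 0 by
#'    default, or any mapped read with `detected = "reads"`);
#' 2. expressed above `min_fpkm` in at least one sample;
#' 3. length > `min_length` bp *and* repetitive fraction at most
#'    `max_repetitive` *and* (when required) reliable splice-junction
#'    support.
#'
#' The cascade is monotone: each stage filters the previous stage's
#' survivors, so counts never increase. The final manual-inspection step
#' that a curator would apply afterwards is outside its scope.
#'
#' @param candidates Tibble with one row per candidate: `id`, `chrom`,
#'   `start`, `end`, `length` (bp), `repetitive_fraction` in `[0, 1]`,
#'   logical `splice_junction_support`.
#' @param fpkm Long tibble `id`, `sample_id`, `fpkm` of per-sample
#'   expression for the candidates (and, with `detected = "reads"`, a
#'   `mapped_reads` column).
#' @param min_samples Minimum samples with detection at stage 1 (default 2).
#' @param min_fpkm Strict FPKM bound at stage 2 (default 1).
#' @param min_length Strict length bound in bp at stage 3 (default 300).
#' @param max_repetitive Maximum repetitive fraction at stage 3
#'   (default 0.5).
#' @param require_junctions Require splice-junction support at stage 3
#'   (default `TRUE`).
#' @param detected Stage-1 detection rule: `"fpkm"` (FPKM > 0, default) or
#'   `"reads"` (mapped_reads > 0).
#' @return Object of class `novel_cascade`: list with `counts` (tibble
#'   `stage`, `description`, `n_surviving`), `survivors` (list of id
#'   vectors per stage, stage 0 = input), and `final` (the surviving rows
#'   of `candidates`).
#' @export
filter_cascade <- function(candidates, fpkm, min_samples = 2, min_fpkm = 1,
                           min_length = 300, max_repetitive = 0.5,
                           require_junctions = TRUE,
                           detected = c("fpkm", "reads")) {
  detected <- match.arg(detected)
  if (nrow(candidates)) {
    if (any(candidates$repetitive_fraction < 0 |
            candidates$repetitive_fraction > 1)) {
      abort("repetitive_fraction must lie in [0, 1]")
    }
    if (any(candidates$length != candidates$end - candidates$start)) {
      abort("candidate length must equal end - start")
    }
  }
  det_col <- if (detected == "fpkm") "fpkm" else "mapped_reads"
  per_cand <- fpkm |>
    group_by(.data$id) |>
    summarise(n_detected = sum(.data[[det_col]] > 0),
              max_fpkm = max(c(.data$fpkm, 0)), .groups = "drop")
  cand <- left_join(candidates, per_cand, by = "id") |>
    mutate(n_detected = dplyr::coalesce(.data$n_detected, 0L),
           max_fpkm = dplyr::coalesce(.data$max_fpkm, 0))

  s0 <- cand$id
  s1 <- cand$id[cand$n_detected >= min_samples]
  c1 <- cand[cand$id %in% s1, , drop = FALSE]
  s2 <- c1$id[c1$max_fpkm > min_fpkm]
  c2 <- c1[c1$id %in% s2, , drop = FALSE]
  pass3 <- c2$length > min_length &
    c2$repetitive_fraction <= max_repetitive &
    (!require_junctions | c2$splice_junction_support)
  s3 <- c2$id[pass3]
  c3 <- c2[pass3, , drop = FALSE]

  counts <- tibble(
    stage = 0:3,
    description = c("input candidates",
                    paste0("detected in >= ", min_samples, " samples"),
                    paste0("FPKM > ", min_fpkm, " in >= 1 sample"),
                    paste0("length > ", min_length, " bp, repetitive <= ",
                           max_repetitive,
                           if (require_junctions) ", junction support" else "")),
    n_surviving = c(length(s0), length(s1), length(s2), length(s3))
  )
  structure(list(counts = counts,
                 survivors = list(stage0 = s0, stage1 = s1, stage2 = s2,
                                  stage3 = s3),
                 final = c3),
            class = "novel_cascade")
}

#' @export
print.novel_cascade <- function(x, ...) {
  cat("<novel_cascade>\n")
  print(x$counts)
  invisible(x)
}

#' @method tidy novel_cascade
#' @export
tidy.novel_cascade <- function(x, ...) {
  x$counts
}
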