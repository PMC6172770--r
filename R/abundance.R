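# Read-recruitment filtering, breadth-of-coverage detection, and
# length/library-normalized vOTU abundances.

validate_alignments <- function(alignments) {
  needed <- c("read_id", "contig_id", "read_len", "aligned_len",
              "matches", "start", "end")
  missing <- setdiff(needed, names(alignments))
  if (length(missing)) {
    abort(paste0("alignment table lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(
    alignments$matches < 0 |
      alignments$matches > alignments$aligned_len |
      alignments$aligned_len > alignments$read_len |
      alignments$start >= alignments$end
  )
  if (length(bad)) {
    abort(sprintf("malformed alignment record at index %d", bad[1]))
  }
  invisible(alignments)
}

#' Filter read alignments by identity and best hit
#'
#' Retains records whose read identity (`matches / aligned_len`, or over
#' the full read length with `denominator = "read"`) meets
#' `min_read_ani`, then keeps only each read's best-scoring record
#' (most matched bases; ties go to the first record in input order), so
#' multi-mapped reads are counted once.
#'
#' @param alignments Alignment-record tibble (see [map_reads()] /
#'   [read_sam()]).
#' @param min_read_ani Minimum read-to-contig identity (default 0.90).
#' @param denominator Identity denominator: aligned columns (default)
#'   or full read length.
#' @return The filtered alignment tibble, in input order.
#' @export
filter_alignments <- function(alignments, min_read_ani = 0.90,
                              denominator = c("aligned", "read")) {
  denominator <- match.arg(denominator)
  validate_alignments(alignments)
  den <- if (denominator == "aligned") alignments$aligned_len else
    alignments$read_len
  out <- alignments[alignments$matches / den >= min_read_ani, , drop = FALSE]
  out %>%
    mutate(.row = row_number()) %>%
    group_by(.data$read_id) %>%
    slice(which.max(.data$matches)) %>%
    ungroup() %>%
    arrange(.data$.row) %>%
    select(-".row")
}

#' Detect contigs and quantify their abundance in one sample
#'
#' Breadth of coverage is the union of covered intervals divided by the
#' contig length; a contig is detected when breadth reaches
#' `min_breadth`. Abundance is mapped base pairs, normalized by contig
#' length and library size, and scaled to "per Gbp of library"
#' (`x 1e9`); undetected contigs report 0.
#'
#' @param alignments Filtered alignment tibble for one sample (see
#'   [filter_alignments()]).
#' @param contig_lengths Named vector of contig lengths; every aligned
#'   contig must be present, and every named contig gets an output row.
#' @param total_bp Library size in base pairs (> 0).
#' @param min_breadth Detection threshold on breadth (default 0.75).
#' @param scale Scaling constant for the abundance units (default
#'   `1e9`, i.e. per Gbp).
#' @return A tibble with one row per contig: `contig_id`, `length`,
#'   `mapped_bp`, `breadth`, `detected`, `abundance`.
#' @export
detect_and_quantify <- function(alignments, contig_lengths, total_bp,
                                min_breadth = 0.75, scale = 1e9) {
  stopifnot(total_bp > 0)
  validate_alignments(alignments)
  unknown <- setdiff(unique(alignments$contig_id), names(contig_lengths))
  if (length(unknown)) {
    abort(sprintf("contig '%s' absent from the length table", unknown[1]))
  }
  per_contig <- alignments %>%
    group_by(.data$contig_id) %>%
    summarise(
      mapped_bp = sum(.data$aligned_len),
      covered = sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = .data$start + 1L, end = .data$end)
      ))),
      .groups = "drop"
    )
  out <- tibble(
    contig_id = names(contig_lengths),
    length = as.integer(unname(contig_lengths))
  ) %>%
    left_join(per_contig, by = "contig_id") %>%
    mutate(
      mapped_bp = dplyr::coalesce(.data$mapped_bp, 0L),
      covered = dplyr::coalesce(.data$covered, 0L),
      breadth = .data$covered / .data$length,
      detected = .data$breadth >= min_breadth,
      abundance = ifelse(
        .data$detected,
        (.data$mapped_bp / .data$length) / total_bp * scale,
        0
      )
    ) %>%
    select("contig_id", "length", "mapped_bp", "breadth",
           "detected", "abundance")
  out
}

#' Total-sum scaling of an abundance matrix
#'
#' Divides each sample row by its row sum so rows sum to 1. All-zero
#' rows are left unchanged with a warning.
#'
#' @param m Numeric matrix (samples x taxa), values >= 0.
#' @return The row-normalized matrix.
#' @export
total_sum_scale <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) abort("total_sum_scale() requires non-negative values")
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero)) {
    warn(sprintf("%d all-zero sample row(s) left unscaled", sum(zero)))
    rs[zero] <- 1
  }
  sweep(m, 1, rs, "/")
}

#' Summarize per-virome read accounting
#'
#' Derives the standard accounting statistics from per-sample read
#' counts: the percentage of reads assembling per sample (mean and
#' range), pooled vOTU-read fractions (of assembled and of
#' putative-viral reads), and pairwise assembled-read fold ratios.
#'
#' @param counts Tibble with columns `sample`, `total_reads`,
#'   `assembled_reads`, `viral_reads`, `votu_reads` (see
#'   [stordalen_virome_counts()] for the published seven-virome table).
#' @return A `virome_summary` object; see [tidy.virome_summary()],
#'   [glance.virome_summary()] and [fold_ratio()].
#' @export
summarize_viromes <- function(counts) {
  needed <- c("sample", "total_reads", "assembled_reads",
              "viral_reads", "votu_reads")
  missing <- setdiff(needed, names(counts))
  if (length(missing)) {
    abort(paste0("counts lack columns: ", paste(missing, collapse = ", ")))
  }
  ok <- counts$votu_reads <= counts$viral_reads &
    counts$viral_reads <= counts$assembled_reads &
    counts$assembled_reads <= counts$total_reads
  if (!all(ok)) {
    abort(sprintf("count ordering violated for sample '%s'",
                  counts$sample[which(!ok)[1]]))
  }
  per_sample <- counts %>%
    mutate(
      assembled_pct = .data$assembled_reads / .data$total_reads * 100,
      viral_pct_of_assembled = .data$viral_reads / .data$assembled_reads * 100,
      votu_pct_of_assembled = .data$votu_reads / .data$assembled_reads * 100,
      votu_pct_of_viral = .data$votu_reads / .data$viral_reads * 100
    )
  pooled <- list(
    votu_of_assembled = sum(counts$votu_reads) / sum(counts$assembled_reads),
    votu_of_viral = sum(counts$votu_reads) / sum(counts$viral_reads),
    viral_of_assembled = sum(counts$viral_reads) / sum(counts$assembled_reads)
  )
  structure(
    list(per_sample = per_sample, pooled = pooled),
    class = "virome_summary"
  )
}

#' @export
print.virome_summary <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<virome_summary> %d viromes; assembled %% mean %.1f ",
           "(range %.1f-%.1f); pooled vOTU reads: %.1f%% of assembled, ",
           "%.1f%% of viral\n"),
    nrow(x$per_sample), g$mean_assembled_pct, g$min_assembled_pct,
    g$max_assembled_pct, g$votu_pct_of_assembled, g$votu_pct_of_viral
  ))
  invisible(x)
}

#' Tidy a virome summary
#'
#' @param x A `virome_summary` from [summarize_viromes()].
#' @param ... Unused.
#' @return `tidy()` returns the per-sample table with derived
#'   percentages; `glance()` a one-row pooled summary.
#' @method tidy virome_summary
#' @export
tidy.virome_summary <- function(x, ...) x$per_sample

#' @rdname tidy.virome_summary
#' @method glance virome_summary
#' @export
glance.virome_summary <- function(x, ...) {
  tibble(
    n_samples = nrow(x$per_sample),
    mean_assembled_pct = mean(x$per_sample$assembled_pct),
    min_assembled_pct = min(x$per_sample$assembled_pct),
    max_assembled_pct = max(x$per_sample$assembled_pct),
    votu_pct_of_assembled = 100 * x$pooled$votu_of_assembled,
    votu_pct_of_viral = 100 * x$pooled$votu_of_viral
  )
}

#' Assembled-read fold ratio between two viromes
#'
#' @param x A `virome_summary`.
#' @param a,b Sample names; the ratio is `assembled_a / assembled_b`.
#' @return A single number.
#' @export
fold_ratio <- function(x, a, b) {
  stopifnot(inherits(x, "virome_summary"))
  ps <- x$per_sample
  ia <- match(a, ps$sample)
  ib <- match(b, ps$sample)
  if (is.na(ia) || is.na(ib)) abort("unknown sample name")
  ps$assembled_reads[ia] / ps$assembled_reads[ib]
}
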