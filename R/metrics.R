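#' Normalize a count per million mapped reads
#'
#' @param count Non-negative count (fragments or genes).
#' @param mapped_reads Positive number of mapped reads for the sample.
#' @return `1e6 * count / mapped_reads`.
#' @export
normalize_per_million <- function(count, mapped_reads) {
  if (any(!is.finite(mapped_reads)) || any(mapped_reads <= 0))
    stop("mapped_reads must be positive")
  1e6 * count / mapped_reads
}

#' Fragment-length mean and histogram modes
#'
#' Modes are detected on a fixed-bin histogram (default 10 bp bins): a bin is
#' a mode when its count exceeds both neighbours (boundary bins need only
#' exceed their single neighbour). Modes are reported as bin centres in
#' decreasing height order. Fixed binning keeps mode detection deterministic,
#' unlike kernel-density peaks.
#'
#' @param lengths Integer vector of fragment lengths in bp (may be a
#'   `microdna_calls` data.frame, in which case its `length` column is used).
#' @param histogram_bin_bp Bin width in bp (default 10).
#' @return List with `mean` (`NA` when no fragments) and `modes` (numeric bin
#'   centres, possibly empty).
#' @export
length_stats <- function(lengths, histogram_bin_bp = 10L) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  stopifnot(histogram_bin_bp >= 1)
  if (length(lengths) == 0) return(list(mean = NA_real_, modes = numeric(0)))
  m <- mean(lengths)
  b <- histogram_bin_bp
  idx <- lengths %/% b - min(lengths %/% b) + 1L
  counts <- tabulate(idx)
  centers <- (seq_along(counts) - 1 + min(lengths %/% b)) * b + b / 2
  nb <- length(counts)
  if (nb == 1) return(list(mean = m, modes = centers))
  left <- c(-Inf, counts[-nb])
  right <- c(counts[-1], -Inf)
  is_mode <- counts > left & counts > right
  modes <- centers[is_mode]
  h <- counts[is_mode]
  o <- order(-h, modes)
  list(mean = m, modes = modes[o])
}

#' Per-sample microDNA profiles
#'
#' One row per sample: unique fragment (call) count, microDNA-producing gene
#' count, both normalized per million mapped reads, and the mean fragment
#' length. A "microDNA-producing gene" is a gene with at least one assigned
#' call; intergenic calls count toward fragments but not genes.
#'
#' @param calls_by_sample Named list (by `sample_id`) of `microdna_calls`.
#' @param samples Sample metadata (see [read_sample_sheet()]).
#' @param annotations Pooled annotation data.frame with `sample_id` and
#'   `gene_name` (see [annotate_calls()]).
#' @return Data.frame of per-sample profiles joined to the sample metadata.
#' @export
build_sample_profiles <- function(calls_by_sample, samples, annotations) {
  stopifnot(all(names(calls_by_sample) %in% samples$sample_id))
  rows <- lapply(samples$sample_id, function(sid) {
    calls <- calls_by_sample[[sid]]
    nfrag <- if (is.null(calls)) 0L else nrow(calls)
    ann <- annotations[annotations$sample_id == sid & !is.na(annotations$gene_name), ,
                       drop = FALSE]
    ngene <- length(unique(ann$gene_name))
    mr <- samples$mapped_reads[samples$sample_id == sid]
    data.frame(
      sample_id = sid, n_fragments = nfrag, n_genes = ngene,
      fragments_per_million = normalize_per_million(nfrag, mr),
      genes_per_million = normalize_per_million(ngene, mr),
      length_mean = if (nfrag) mean(calls$length) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  merge(samples, do.call(rbind, rows), by = "sample_id", sort = FALSE)
}

#' Compare a per-sample metric across disease stages
#'
#' Per-stage means/medians plus pairwise two-sided Wilcoxon rank-sum
#' (Mann-Whitney) p-values: exact when both groups have at most 10
#' observations and no ties, otherwise the normal approximation with tie
#' correction.
#'
#' @param profiles Data.frame with a `stage` column (e.g. from
#'   [build_sample_profiles()]).
#' @param metric Name of the numeric column to compare.
#' @return List with `summary` (per-stage n/mean/median) and `pairwise`
#'   (stage pair, p-value).
#' @export
stage_comparison <- function(profiles, metric) {
  stopifnot(metric %in% names(profiles))
  x <- profiles[[metric]]
  levels_all <- unique(profiles$stage)
  keep <- !is.na(x)
  x <- x[keep]
  stage <- factor(profiles$stage[keep], levels = levels_all)
  groups <- split(x, stage)
  empty <- lengths(groups) == 0
  if (any(empty)) {
    warning("stage(s) with no samples excluded: ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  if (length(groups) < 2) stop("need at least two stages with samples")
  summ <- data.frame(
    stage = names(groups), n = lengths(groups),
    mean = vapply(groups, mean, 0), median = vapply(groups, stats::median, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  prs <- utils::combn(names(groups), 2)
  pw <- apply(prs, 2, function(pp) {
    rank_sum_p(groups[[pp[1]]], groups[[pp[2]]])
  })
  list(summary = summ,
       pairwise = data.frame(stage1 = prs[1, ], stage2 = prs[2, ], p = pw,
                             stringsAsFactors = FALSE))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact when both groups have `max_exact_n` or fewer observations and the
#' pooled data has no ties; otherwise the normal approximation with tie
#' correction (no continuity correction, matching the large-sample
#' Mann-Whitney convention).
#'
#' @param x,y Numeric samples.
#' @param max_exact_n Largest group size for which the exact distribution is
#'   used (default 10).
#' @return Two-sided p-value.
#' @export
rank_sum_p <- function(x, y, max_exact_n = 10L) {
  if (length(unique(c(x, y))) == 1) return(1)  # degenerate: constant data
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= max_exact_n && length(y) <= max_exact_n && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)$p.value
  )
}
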