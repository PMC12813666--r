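#' Circle-caller configuration
#'
#' @param min_support Minimum junction-read support for a retained call
#'   (default 2; rolling-circle amplified libraries make singleton junctions
#'   unreliable).
#' @param cluster_tolerance_bp Maximum per-endpoint distance (bp) for two
#'   candidates to be single-linkage clustered (default 5).
#' @param min_length,max_length Retained circle length range in bp; the
#'   default 50-2000 reflects the microDNA (<2 kb) size regime.
#' @param merge_strands Merge candidates across strands (default `FALSE`:
#'   calls at identical coordinates on opposite strands stay separate).
#' @return A `caller_config` list.
#' @export
caller_config <- function(min_support = 2L, cluster_tolerance_bp = 5L,
                          min_length = 50L, max_length = 2000L,
                          merge_strands = FALSE) {
  stopifnot(min_support >= 1, cluster_tolerance_bp >= 0,
            min_length > 0, max_length > min_length)
  structure(list(min_support = as.integer(min_support),
                 cluster_tolerance_bp = as.integer(cluster_tolerance_bp),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 merge_strands = isTRUE(merge_strands)),
            class = "caller_config")
}

as_microdna_calls <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand", "support") %in% names(df)))
  df$length <- df$end - df$start
  if (is.null(df$call_id)) df$call_id <- sprintf("mdna_%05d", seq_len(nrow(df)))
  rownames(df) <- NULL
  class(df) <- c("microdna_calls", "data.frame")
  df
}

#' Turn chimeric junctions into circle candidates
#'
#' A junction supports a circular template iff donor and acceptor are on the
#' same chromosome and strand and the acceptor lies upstream of the donor
#' (head-to-tail orientation: the downstream end of the circle joins back to
#' its upstream start). Inter-chromosomal (translocation-like), opposite-
#' strand (inversion-like), and linear-splice-orientation junctions are
#' discarded, with counts recorded in the `filter_stats` attribute. Reads
#' with duplicated `read_id` are collapsed first, so each candidate reflects
#' a distinct junction read.
#'
#' Input positions are 1-based; candidate intervals are 0-based half-open
#' `[acceptor - 1, donor)`, each with support 1.
#'
#' @param junctions A junction data.frame from [read_chimeric_junctions()].
#' @return A `microdna_calls` data.frame of unclustered candidates.
#' @export
junctions_to_candidates <- function(junctions) {
  n0 <- nrow(junctions)
  junctions <- junctions[!duplicated(junctions$read_id), , drop = FALSE]
  n_dup <- n0 - nrow(junctions)
  same_chrom <- junctions$chrom_donor == junctions$chrom_acceptor
  same_strand <- junctions$strand_donor == junctions$strand_acceptor
  circular <- same_chrom & same_strand &
    junctions$pos_acceptor < junctions$pos_donor
  stats <- c(
    n_reads = nrow(junctions),
    n_duplicate_reads = n_dup,
    n_translocation_like = sum(!same_chrom),
    n_inversion_like = sum(same_chrom & !same_strand),
    n_linear_orientation = sum(same_chrom & same_strand & !circular),
    n_circular = sum(circular)
  )
  k <- junctions[circular, , drop = FALSE]
  out <- as_microdna_calls(data.frame(
    chrom = k$chrom_donor,
    start = k$pos_acceptor - 1L,
    end = k$pos_donor,
    strand = k$strand_donor,
    support = rep(1L, nrow(k)),
    stringsAsFactors = FALSE
  ))
  attr(out, "filter_stats") <- stats
  out
}

# support-weighted lower median: smallest x whose cumulative weight reaches
# half the total (ties resolve to the smaller coordinate)
weighted_median_low <- function(x, w) {
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o])
  x[which(cw >= cw[length(cw)] / 2)[1]]
}

# single-linkage components among candidates whose start AND end each differ
# by <= tol; candidates are pre-sorted by start so only a sliding window of
# start-neighbours needs checking
linkage_components <- function(start, end, tol) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && start[j] - start[i] <= tol) {
      if (abs(end[j] - end[i]) <= tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      j <- j + 1L
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Cluster circle candidates and filter calls
#'
#' Single-linkage clustering joins candidates whose start and end positions
#' each differ by at most `cluster_tolerance_bp`; every cluster becomes one
#' call with support-weighted lower-median endpoints (ties resolve to the
#' smaller coordinate) and support equal to the summed member support (the
#' cluster size when members are unit-support candidates; summing keeps the
#' operation idempotent). Calls are then filtered by `min_support` and the
#' `[min_length, max_length]` window and sorted by (chrom, start, end,
#' strand). The result is deterministic and invariant to input order.
#'
#' @param candidates A `microdna_calls` data.frame (typically from
#'   [junctions_to_candidates()]).
#' @param config A [caller_config()].
#' @return A filtered, sorted `microdna_calls` data.frame.
#' @export
cluster_and_filter <- function(candidates, config = caller_config()) {
  if (nrow(candidates) == 0) return(as_microdna_calls(candidates[, c(
    "chrom", "start", "end", "strand", "support")]))
  grp <- if (config$merge_strands) candidates$chrom else
    paste(candidates$chrom, candidates$strand)
  pieces <- lapply(split(seq_len(nrow(candidates)), grp), function(idx) {
    cc <- candidates[idx, , drop = FALSE]
    o <- order(cc$start, cc$end, cc$support)
    cc <- cc[o, , drop = FALSE]
    comp <- linkage_components(cc$start, cc$end, config$cluster_tolerance_bp)
    merged <- lapply(split(seq_len(nrow(cc)), comp), function(m) {
      data.frame(
        chrom = cc$chrom[m[1]],
        start = weighted_median_low(cc$start[m], cc$support[m]),
        end = weighted_median_low(cc$end[m], cc$support[m]),
        strand = if (config$merge_strands && length(unique(cc$strand[m])) > 1)
          "*" else cc$strand[m[1]],
        support = sum(cc$support[m]),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, merged)
  })
  calls <- do.call(rbind, pieces)
  calls$length <- calls$end - calls$start
  keep <- calls$support >= config$min_support &
    calls$length >= config$min_length & calls$length <= config$max_length
  calls <- calls[keep, , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$start, calls$end, calls$strand), ,
                 drop = FALSE]
  calls$call_id <- sprintf("mdna_%05d", seq_len(nrow(calls)))
  as_microdna_calls(calls)
}

#' Call microDNA circles from a junction file's records
#'
#' Convenience wrapper: [junctions_to_candidates()] followed by
#' [cluster_and_filter()]; filter statistics from the candidate step are
#' carried over in the `filter_stats` attribute.
#'
#' @inheritParams junctions_to_candidates
#' @inheritParams cluster_and_filter
#' @return A `microdna_calls` data.frame.
#' @export
call_circles <- function(junctions, config = caller_config()) {
  cand <- junctions_to_candidates(junctions)
  calls <- cluster_and_filter(cand, config)
  attr(calls, "filter_stats") <- c(attr(cand, "filter_stats"),
                                   n_calls = nrow(calls))
  calls
}
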