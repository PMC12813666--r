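#' Presence-matrix container
#'
#' A binary gene x sample detection indicator paired with sample metadata.
#' Columns must match the sample sheet's `sample_id`s (same order).
#'
#' @param detected Integer 0/1 matrix, genes as rows, samples as columns.
#' @param samples Sample metadata data.frame (see [read_sample_sheet()]).
#' @return A `presence_matrix` object.
#' @export
presence_matrix <- function(detected, samples) {
  stopifnot(is.matrix(detected),
            nrow(detected) == 0 || !is.null(rownames(detected)))
  if (is.null(colnames(detected))) colnames(detected) <- samples$sample_id
  stopifnot(identical(colnames(detected), samples$sample_id),
            all(detected %in% c(0L, 1L)))
  storage.mode(detected) <- "integer"
  structure(list(detected = detected, samples = samples),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x$detected), "genes x",
      ncol(x$detected), "samples\n")
  tab <- table(stage = x$samples$stage, tissue = x$samples$tissue)
  print(tab)
  invisible(x)
}

#' Build a presence matrix from pooled call annotations
#'
#' `detected(g, s) = 1` iff sample `s` has at least one call assigned to gene
#' `g`; intergenic calls are excluded, and genes detected in no sample do not
#' appear (observed matrices drop empty genes). Samples with no gene-assigned
#' calls remain as all-zero columns.
#'
#' @param annotations Pooled annotation data.frame with `sample_id` and
#'   `gene_name` columns (see [annotate_calls()]).
#' @param samples Sample metadata.
#' @return A [presence_matrix()].
#' @export
build_presence_matrix <- function(annotations, samples) {
  ann <- annotations[!is.na(annotations$gene_name), , drop = FALSE]
  genes <- sort(unique(ann$gene_name))
  m <- matrix(0L, length(genes), nrow(samples),
              dimnames = list(genes, samples$sample_id))
  if (nrow(ann)) {
    gi <- match(ann$gene_name, genes)
    si <- match(ann$sample_id, samples$sample_id)
    if (anyNA(si)) stop("annotation sample_id missing from sample sheet")
    m[cbind(gi, si)] <- 1L
  }
  presence_matrix(m, samples)
}

#' Subset a presence matrix by stage and/or tissue
#'
#' @param pm A [presence_matrix()].
#' @param stage,tissue Optional stratum filters.
#' @param drop_empty_genes Drop all-zero gene rows after subsetting.
#' @return A [presence_matrix()].
#' @export
pm_subset <- function(pm, stage = NULL, tissue = NULL, drop_empty_genes = FALSE) {
  keep <- rep(TRUE, nrow(pm$samples))
  if (!is.null(stage)) keep <- keep & pm$samples$stage %in% stage
  if (!is.null(tissue)) keep <- keep & pm$samples$tissue %in% tissue
  m <- pm$detected[, keep, drop = FALSE]
  if (drop_empty_genes) m <- m[rowSums(m) > 0, , drop = FALSE]
  presence_matrix(m, pm$samples[keep, , drop = FALSE])
}

#' Per-gene count of distinct detecting patients in a stratum
#'
#' Counts distinct `patient_id`s (not samples) with at least one detection,
#' optionally restricted to a stage/tissue stratum.
#'
#' @param pm A [presence_matrix()].
#' @param stage,tissue Optional stratum filters.
#' @return Named integer vector, one entry per gene.
#' @export
patient_detection_counts <- function(pm, stage = NULL, tissue = NULL) {
  sub <- pm_subset(pm, stage, tissue)
  if (ncol(sub$detected) == 0)
    return(stats::setNames(integer(nrow(sub$detected)), rownames(sub$detected)))
  by_patient <- vapply(split(seq_len(ncol(sub$detected)), sub$samples$patient_id),
                       function(cols) as.integer(
                         rowSums(sub$detected[, cols, drop = FALSE]) > 0),
                       integer(nrow(sub$detected)))
  if (is.null(dim(by_patient))) by_patient <- matrix(by_patient, nrow = 1)
  stats::setNames(as.integer(rowSums(by_patient)), rownames(sub$detected))
}

#' Genes shared by at least k individuals of a stage
#'
#' @param pm A [presence_matrix()].
#' @param stage Disease stage.
#' @param tissue Optional tissue filter.
#' @param k Sharing threshold: minimum number of distinct patients (default 2).
#' @return Character vector of shared gene names (sorted).
#' @export
stage_shared_set <- function(pm, stage, tissue = NULL, k = 2L) {
  sub <- pm_subset(pm, stage, tissue)
  n_pat <- length(unique(sub$samples$patient_id))
  if (n_pat < k) {
    warning("fewer than k = ", k, " patients in stratum (", stage,
            if (!is.null(tissue)) paste0(", ", tissue), "); empty shared set")
    return(character(0))
  }
  cnt <- patient_detection_counts(pm, stage, tissue)
  sort(names(cnt)[cnt >= k])
}

#' Venn partition of three sets
#'
#' Exact set algebra: counts of elements in exactly A, exactly B, exactly C,
#' each pairwise-only intersection, and the triple intersection.
#'
#' @param a,b,c Vectors (treated as sets).
#' @param names Region labels for the three sets.
#' @return Named integer vector of the 7 region counts.
#' @export
venn_partition <- function(a, b, c, names = c("A", "B", "C")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  counts <- c(
    sum(ina & !inb & !inc), sum(!ina & inb & !inc), sum(!ina & !inb & inc),
    sum(ina & inb & !inc), sum(ina & !inb & inc), sum(!ina & inb & inc),
    sum(ina & inb & inc)
  )
  stats::setNames(as.integer(counts), c(
    paste0(names[1], "_only"), paste0(names[2], "_only"), paste0(names[3], "_only"),
    paste(names[1], names[2], sep = "_"), paste(names[1], names[3], sep = "_"),
    paste(names[2], names[3], sep = "_"),
    paste(names[1], names[2], names[3], sep = "_")
  ))
}

#' Parameters of the binomial expected-sharing null
#'
#' Under the null every gene is produced independently in each individual
#' with probability `p`; a gene counts as "shared" in a stage when at least
#' `k` of that stage's `n` individuals produce it. The default `p = 0.05`
#' reflects roughly 2,000 microDNA-producing genes per individual out of a
#' universe of ~40,000 genes; default group sizes are 25 diagnosis, 9
#' relapse, and 18 remission individuals.
#'
#' @param p Per-individual per-gene production probability.
#' @param group_sizes Named integer vector of individuals per stage.
#' @param k Sharing threshold.
#' @param gene_universe Number of genes G.
#' @return A `binomial_null_spec` list.
#' @export
binomial_null_spec <- function(p = 0.05,
                               group_sizes = c(diagnosis = 25L, relapse = 9L,
                                               remission = 18L),
                               k = 2L, gene_universe = 40000L) {
  stopifnot(p > 0, p < 1, all(group_sizes >= 1), k >= 1, gene_universe >= 1,
            !is.null(names(group_sizes)))
  structure(list(p = p, group_sizes = group_sizes, k = as.integer(k),
                 gene_universe = as.integer(gene_universe)),
            class = "binomial_null_spec")
}

#' Probability a gene is shared by >= k of n individuals
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`; for `k = 2` this is
#' `1 - (1-p)^n - n p (1-p)^(n-1)`.
#'
#' @param n Number of individuals (vectorised).
#' @param p Per-individual production probability.
#' @param k Sharing threshold.
#' @return Probability (vector).
#' @export
binomial_sharing_probability <- function(n, p, k = 2L) {
  stopifnot(all(n >= 0), p >= 0, p <= 1, k >= 1)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Expected Venn-region frequencies under the binomial null
#'
#' With per-stage sharing probabilities `q_s` and independence across
#' stages, the probability that a gene lands in e.g. the "stage 1 only"
#' region is `q_1 (1-q_2)(1-q_3)`, and in the triple region
#' `q_1 q_2 q_3`. Expected counts are `G` times the region probability. In
#' `"conditional"` mode frequencies are renormalized over the 7 non-empty
#' regions (the probability a gene is shared somewhere); `"absolute"` leaves
#' them on the gene-universe scale.
#'
#' @param spec A [binomial_null_spec()].
#' @param mode `"conditional"` (default) or `"absolute"`.
#' @return Data.frame with region, probability, frequency, and expected
#'   count; the probability of the "none" outcome is in the `p_none`
#'   attribute.
#' @export
expected_region_frequencies <- function(spec, mode = c("conditional", "absolute")) {
  mode <- match.arg(mode)
  q <- binomial_sharing_probability(spec$group_sizes, spec$p, spec$k)
  nm <- names(spec$group_sizes)
  # region order matches venn_partition(): singles, pairs, triple
  membership <- rbind(
    c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
    c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
    c(TRUE, TRUE, TRUE)
  )
  probs <- apply(membership, 1, function(g) prod(ifelse(g, q, 1 - q)))
  region <- apply(membership, 1, function(g) {
    inn <- nm[g]
    if (length(inn) == 1) paste0(inn, "_only") else paste(inn, collapse = "_")
  })
  p_none <- prod(1 - q)
  freq <- if (mode == "conditional") probs / sum(probs) else
    probs * spec$gene_universe
  out <- data.frame(region = region, probability = probs, frequency = freq,
                    expected_count = probs * spec$gene_universe,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "p_none") <- p_none
  attr(out, "q") <- q
  out
}

#' Pearson chi-squared test of observed vs expected region counts
#'
#' Expected counts are rescaled to the observed total; any region with a
#' rescaled expected count below 1 is merged with the smallest remaining
#' region (reported via `message`). `df = regions - 1` after merging.
#'
#' @param observed,expected Numeric vectors of region counts (same length,
#'   same order).
#' @return List with `statistic`, `df`, `p`, and the (possibly merged)
#'   `observed`/`expected` vectors used.
#' @export
observed_vs_expected_chisq <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), all(expected > 0))
  if (sum(observed) == 0) stop("all-zero observed counts")
  e <- expected * sum(observed) / sum(expected)
  o <- observed
  while (length(e) > 1 && min(e) < 1) {
    i <- which.min(e)
    rest <- setdiff(seq_along(e), i)
    j <- rest[which.min(e[rest])]
    message("merging region ", i, " (expected ", signif(e[i], 3),
            ") into region ", j)
    o[j] <- o[j] + o[i]
    e[j] <- e[j] + e[i]
    o <- o[-i]; e <- e[-i]
  }
  stat <- sum((o - e)^2 / e)
  df <- length(e) - 1
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = o, expected = e)
}

#' Observed Venn-region counts of stage-shared gene sets
#'
#' Computes the per-stage shared sets (genes detected in >= k distinct
#' patients of the stage) and their 7-region Venn partition.
#'
#' @param pm A [presence_matrix()].
#' @param stages Character vector of the three stages (region order).
#' @param tissue Optional tissue filter.
#' @param k Sharing threshold.
#' @return List with `sets` (per-stage shared gene sets) and `regions`
#'   (named 7-region counts).
#' @export
sharing_summary <- function(pm, stages = c("diagnosis", "relapse", "remission"),
                            tissue = NULL, k = 2L) {
  stopifnot(length(stages) == 3)
  sets <- lapply(stages, function(s) stage_shared_set(pm, s, tissue, k))
  names(sets) <- stages
  regions <- venn_partition(sets[[1]], sets[[2]], sets[[3]], names = stages)
  list(sets = sets, regions = regions)
}
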