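#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

calls_granges <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(calls$start + 1L, calls$end))
}

# strand-aware promoter window: promoter_bp upstream of the TSS
promoter_window <- function(genes, promoter_bp) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$tx_start - promoter_bp), genes$tx_end)
  end <- ifelse(plus, genes$tx_start, genes$tx_end + promoter_bp)
  data.frame(chrom = genes$chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

# 0-based half-open intersection of one interval set with a window
intersect_window <- function(starts, ends, w_start, w_end) {
  s <- pmax(starts, w_start)
  e <- pmin(ends, w_end)
  keep <- s < e
  list(start = s[keep], end = e[keep])
}

# per-gene class intervals used by feature classification, one row per
# interval: class in {utr5_promoter, utr3, exon} (intron is the fallback)
feature_interval_table <- function(genes, promoter_bp = 2000L) {
  prom <- promoter_window(genes, promoter_bp)
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    plus <- genes$strand[i] == "+"
    coding <- genes$cds_start[i] < genes$cds_end[i]
    st <- prom$start[i]; en <- prom$end[i]; cls <- "utr5_promoter"
    if (coding) {
      u5 <- if (plus) intersect_window(es, ee, genes$tx_start[i], genes$cds_start[i])
            else intersect_window(es, ee, genes$cds_end[i], genes$tx_end[i])
      u3 <- if (plus) intersect_window(es, ee, genes$cds_end[i], genes$tx_end[i])
            else intersect_window(es, ee, genes$tx_start[i], genes$cds_start[i])
      st <- c(st, u5$start, u3$start)
      en <- c(en, u5$end, u3$end)
      cls <- c(cls, rep("utr5_promoter", length(u5$start)),
               rep("utr3", length(u3$start)))
    }
    st <- c(st, es); en <- c(en, ee)
    cls <- c(cls, rep("exon", length(es)))
    rows[[i]] <- data.frame(gene_name = genes$gene_name[i],
                            chrom = genes$chrom[i], start = st, end = en,
                            class = cls, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Assign each microDNA call to a gene
#'
#' A call is assigned to a gene when it overlaps (by at least 1 bp) the
#' gene's transcript span extended by `promoter_bp` upstream of the
#' strand-aware TSS. When several genes overlap, the gene with the largest
#' overlap wins; exact ties resolve to the lexicographically smallest gene
#' name. Calls overlapping no gene are intergenic (`NA`).
#'
#' @param calls A `microdna_calls` data.frame.
#' @param genes A `gene_models` data.frame.
#' @param promoter_bp Upstream promoter window in bp (default 2000).
#' @return Character vector of gene names (`NA` = intergenic), one per call.
#' @export
assign_gene <- function(calls, genes, promoter_bp = 2000L) {
  if (nrow(calls) == 0) return(character(0))
  ext_start <- ifelse(genes$strand == "+",
                      pmax(0L, genes$tx_start - promoter_bp), genes$tx_start)
  ext_end <- ifelse(genes$strand == "+",
                    genes$tx_end, genes$tx_end + promoter_bp)
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(ext_start + 1L, ext_end))
  hits <- GenomicRanges::findOverlaps(calls_granges(calls), gr_genes)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(calls$end[qi], ext_end[si]) - pmax(calls$start[qi], ext_start[si])
  out <- rep(NA_character_, nrow(calls))
  for (grp in split(seq_along(qi), qi)) {
    cands <- si[grp]
    w <- ov[grp]
    best <- cands[w == max(w)]
    out[qi[grp[1]]] <- min(genes$gene_name[best])
  }
  out
}

#' Classify calls into a single gene-feature category
#'
#' Each gene-assigned call receives exactly one category by the precedence
#' `utr5_promoter > utr3 > exon > intron`: the highest-precedence class whose
#' intervals the call overlaps by at least 1 bp wins; a call within the
#' transcript span touching no exonic or regulatory interval is intronic.
#' The promoter window (strand-aware, `promoter_bp` upstream of the TSS) is
#' pooled with the 5' UTR into one `utr5_promoter` category; UTRs are derived
#' from the CDS versus exon structure. Non-coding genes have all exonic
#' overlap classed as `exon`, with the promoter window still applying.
#' Unassigned calls are `intergenic`.
#'
#' @param calls A `microdna_calls` data.frame.
#' @param genes A `gene_models` data.frame.
#' @param gene_assignment Character vector from [assign_gene()]; computed
#'   when omitted.
#' @param promoter_bp Promoter window in bp (default 2000).
#' @return Character vector of categories, one per call.
#' @export
classify_feature <- function(calls, genes, gene_assignment = NULL,
                             promoter_bp = 2000L) {
  if (is.null(gene_assignment)) gene_assignment <- assign_gene(calls, genes, promoter_bp)
  stopifnot(length(gene_assignment) == nrow(calls))
  out <- ifelse(is.na(gene_assignment), "intergenic", "intron")
  assigned <- which(!is.na(gene_assignment))
  if (!length(assigned)) return(out)
  feats <- feature_interval_table(genes, promoter_bp)
  prio <- c(utr5_promoter = 1L, utr3 = 2L, exon = 3L)
  gr_feat <- GenomicRanges::GRanges(feats$chrom,
                                    IRanges::IRanges(feats$start + 1L, feats$end))
  hits <- GenomicRanges::findOverlaps(calls_granges(calls[assigned, , drop = FALSE]),
                                      gr_feat)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same_gene <- feats$gene_name[si] == gene_assignment[assigned][qi]
  qi <- qi[same_gene]; si <- si[same_gene]
  if (length(qi)) {
    best <- tapply(prio[feats$class[si]], qi, min)
    idx <- assigned[as.integer(names(best))]
    out[idx] <- names(prio)[best]
  }
  out
}

#' Flag call overlap with open-chromatin peak sets
#'
#' Each named peak set (e.g. DNase/ATAC peaks from a lymphoblastoid cell line
#' or from B-ALL samples) is evaluated independently; a flag is `TRUE` iff
#' the call shares at least 1 bp with any peak of the set (half-open
#' intervals, so abutting intervals do not overlap).
#'
#' @param calls A `microdna_calls` data.frame.
#' @param peak_sets Named list of peak data.frames (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. from [read_peaks_bed()].
#' @return Logical matrix, calls x peak sets.
#' @export
overlap_open_chromatin <- function(calls, peak_sets) {
  stopifnot(is.list(peak_sets), !is.null(names(peak_sets)))
  out <- matrix(FALSE, nrow(calls), length(peak_sets),
                dimnames = list(NULL, names(peak_sets)))
  if (nrow(calls) == 0) return(out)
  gr_calls <- calls_granges(calls)
  for (nm in names(peak_sets)) {
    p <- peak_sets[[nm]]
    if (nrow(p) == 0) next
    gr_p <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
    out[, nm] <- IRanges::overlapsAny(gr_calls, gr_p)
  }
  out
}

#' Annotate calls with gene, feature category, and open-chromatin flags
#'
#' @param calls A `microdna_calls` data.frame.
#' @param genes A `gene_models` data.frame.
#' @param peak_sets Optional named list of peak data.frames.
#' @param promoter_bp Promoter window in bp.
#' @param sample_id Optional sample id recycled onto each row (used when
#'   pooling annotations across a cohort).
#' @return Data.frame with `call_id`, `gene_name`, `category`, and one
#'   logical `oc_<set>` column per peak set.
#' @export
annotate_calls <- function(calls, genes, peak_sets = list(),
                           promoter_bp = 2000L, sample_id = NULL) {
  gene <- assign_gene(calls, genes, promoter_bp)
  cat <- classify_feature(calls, genes, gene, promoter_bp)
  ann <- data.frame(call_id = calls$call_id, gene_name = gene,
                    category = cat, stringsAsFactors = FALSE)
  if (length(peak_sets)) {
    oc <- overlap_open_chromatin(calls, peak_sets)
    colnames(oc) <- paste0("oc_", colnames(oc))
    ann <- cbind(ann, as.data.frame(oc))
  }
  if (!is.null(sample_id)) ann <- cbind(sample_id = sample_id, ann,
                                        stringsAsFactors = FALSE)
  ann
}

# round half away from zero (presentation-grade percentages)
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Per-gene annotation summaries
#'
#' For each (gene, tissue) stratum: the number of distinct individuals with
#' at least one call at diagnosis and at relapse, the total fragment count,
#' per-category fragment counts with percentages rounded half away from zero,
#' and open-chromatin counts/percentages per peak set.
#'
#' @param annotations Pooled annotation data.frame (must carry `sample_id`,
#'   `gene_name`, `category`, and any `oc_*` columns).
#' @param samples Sample metadata (see [read_sample_sheet()]).
#' @return Data.frame with one row per gene x tissue.
#' @export
summarize_gene_annotations <- function(annotations, samples) {
  ann <- annotations[!is.na(annotations$gene_name), , drop = FALSE]
  meta_idx <- match(ann$sample_id, samples$sample_id)
  if (anyNA(meta_idx)) stop("annotation sample_id missing from sample sheet")
  ann$tissue <- samples$tissue[meta_idx]
  ann$stage <- samples$stage[meta_idx]
  ann$patient_id <- samples$patient_id[meta_idx]
  cats <- c("exon", "utr5_promoter", "utr3", "intron")
  oc_cols <- grep("^oc_", names(ann), value = TRUE)
  groups <- split(seq_len(nrow(ann)), paste(ann$gene_name, ann$tissue, sep = "\r"))
  rows <- lapply(groups, function(idx) {
    g <- ann[idx, , drop = FALSE]
    n <- nrow(g)
    row <- data.frame(
      gene_name = g$gene_name[1], tissue = g$tissue[1],
      n_individuals_dx = length(unique(g$patient_id[g$stage == "diagnosis"])),
      n_individuals_rel = length(unique(g$patient_id[g$stage == "relapse"])),
      n_microdna = n, stringsAsFactors = FALSE
    )
    for (cc in cats) {
      k <- sum(g$category == cc)
      row[[paste0("n_", cc)]] <- k
      row[[paste0("pct_", cc)]] <- round_half_away(100 * k / n)
    }
    for (oc in oc_cols) {
      k <- sum(g[[oc]])
      row[[paste0("n_", sub("^oc_", "", oc))]] <- k
      row[[paste0("pct_", sub("^oc_", "", oc))]] <- round_half_away(100 * k / n)
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_name, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
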