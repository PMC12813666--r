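# shared fixtures, all built in code

write_junction_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

junction_row <- function(cd, pd, sd, ca, pa, sa, type = 0, read = "r1") {
  paste(cd, pd, sd, ca, pa, sa, type, 0, read, sep = "\t")
}

# a two-gene toy locus on chr1:
#  geneA: + strand, tx [10000, 20000), exons [10000,11000) [14000,15500)
#         [18500,20000), CDS [10300, 19700)
#         -> 5'UTR [10000,10300), 3'UTR [19700,20000), promoter [8000,10000)
#  geneB: - strand, tx [30000, 40000), same exon layout, CDS [30300, 39700)
#         -> promoter [40000,42000), 5'UTR (exonic) [39700,40000)
toy_genes <- function() {
  g <- data.frame(
    gene_name = c("geneA", "geneB"),
    chrom = "chr1",
    strand = c("+", "-"),
    tx_start = c(10000L, 30000L), tx_end = c(20000L, 40000L),
    cds_start = c(10300L, 30300L), cds_end = c(19700L, 39700L),
    stringsAsFactors = FALSE
  )
  g$exon_starts <- list(c(10000L, 14000L, 18500L), c(30000L, 34000L, 38500L))
  g$exon_ends <- list(c(11000L, 15500L, 20000L), c(31000L, 35500L, 40000L))
  class(g) <- c("gene_models", "data.frame")
  g
}

mk_calls <- function(chrom, start, end, strand = "+", support = 2L) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(chrom, n), start = rep_len(start, n),
                   end = rep_len(end, n), strand = rep_len(strand, n),
                   support = rep_len(support, n), stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  df$call_id <- sprintf("c%04d", seq_len(n))
  class(df) <- c("microdna_calls", "data.frame")
  df
}

mk_samples <- function(patient_id, tissue, stage, later_relapse = "unknown",
                       mapped_reads = 1e6) {
  n <- length(patient_id)
  validate_sample_sheet(data.frame(
    sample_id = paste(patient_id, substr(stage, 1, 3), tissue, sep = "_"),
    patient_id = patient_id, tissue = rep_len(tissue, n),
    stage = rep_len(stage, n), mapped_reads = rep_len(mapped_reads, n),
    later_relapse = rep_len(later_relapse, n), stringsAsFactors = FALSE
  ))
}

# presence matrix from a gene x sample 0/1 matrix spec
mk_pm <- function(m, samples) {
  storage.mode(m) <- "integer"
  colnames(m) <- samples$sample_id
  presence_matrix(m, samples)
}

# build an annotation fixture with a prescribed per-category composition,
# spread over diagnosis and relapse plasma samples
category_fixture <- function(n_by_cat, n_dx = 5, n_rel = 5) {
  genes <- toy_genes()
  windows <- list(exon = c(14100L, 14300L), utr5_promoter = c(9000L, 9200L),
                  utr3 = c(19750L, 19900L), intron = c(12000L, 12300L))
  rows <- list()
  for (cat in names(n_by_cat)) {
    k <- n_by_cat[[cat]]
    if (k == 0) next
    w <- windows[[cat]]
    rows[[cat]] <- mk_calls("chr1", rep(w[1], k), rep(w[2], k))
  }
  calls <- do.call(rbind, rows)
  class(calls) <- c("microdna_calls", "data.frame")
  calls$call_id <- sprintf("c%04d", seq_len(nrow(calls)))
  samples <- rbind(
    mk_samples(sprintf("D%02d", seq_len(n_dx)), "plasma", "diagnosis"),
    mk_samples(sprintf("R%02d", seq_len(n_rel)), "plasma", "relapse")
  )
  sample_ids <- rep_len(samples$sample_id, nrow(calls))
  ann <- annotate_calls(calls, genes, sample_id = sample_ids)
  list(ann = ann, samples = samples)
}

# a small BM + plasma cohort sample sheet covering all strata:
# 4 diagnosis patients (2 future relapse), 2 relapse, 2 remission
small_two_tissue_samples <- function() {
  rows <- list()
  for (ti in c("BM", "plasma")) {
    rows[[length(rows) + 1]] <- mk_samples(paste0("P", 1:4), ti, "diagnosis",
                                           c("yes", "yes", "no", "no"))
    rows[[length(rows) + 1]] <- mk_samples(paste0("P", 1:2), ti, "relapse", "yes")
    rows[[length(rows) + 1]] <- mk_samples(paste0("P", 3:4), ti, "remission", "no")
  }
  do.call(rbind, rows)
}
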