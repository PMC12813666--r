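#' Run the full microDNA analysis pipeline on junction files
#'
#' For each sample: parse chimeric junctions, call circles, annotate calls
#' against the gene models and peak sets; then pool annotations into
#' per-sample profiles and per-tissue presence matrices.
#'
#' @param junction_paths Named character vector (names = `sample_id`) of
#'   junction TSV paths.
#' @param genes A `gene_models` data.frame.
#' @param samples Sample metadata (see [read_sample_sheet()]).
#' @param peak_sets Optional named list of peak data.frames.
#' @param config A [caller_config()].
#' @param promoter_bp Promoter window (bp).
#' @param strict Strict junction parsing.
#' @return List with `calls` (per-sample `microdna_calls`), `annotations`
#'   (pooled), `profiles` (per-sample metrics), and `matrices` (per-tissue
#'   [presence_matrix()] objects).
#' @export
run_pipeline <- function(junction_paths, genes, samples, peak_sets = list(),
                         config = caller_config(), promoter_bp = 2000L,
                         strict = FALSE) {
  stopifnot(!is.null(names(junction_paths)),
            all(names(junction_paths) %in% samples$sample_id))
  calls <- list()
  anns <- list()
  for (sid in names(junction_paths)) {
    junc <- read_chimeric_junctions(junction_paths[[sid]], strict = strict)
    calls[[sid]] <- call_circles(junc, config)
    anns[[sid]] <- annotate_calls(calls[[sid]], genes, peak_sets,
                                  promoter_bp, sample_id = sid)
  }
  annotations <- do.call(rbind, anns)
  rownames(annotations) <- NULL
  profiles <- build_sample_profiles(calls, samples, annotations)
  tissues <- unique(samples$tissue)
  matrices <- lapply(tissues, function(ti) {
    keep <- samples$tissue == ti
    sub_ann <- annotations[annotations$sample_id %in% samples$sample_id[keep], ,
                           drop = FALSE]
    build_presence_matrix(sub_ann, samples[keep, , drop = FALSE])
  })
  names(matrices) <- tissues
  list(calls = calls, annotations = annotations, profiles = profiles,
       matrices = matrices)
}

#' Run the pipeline on an emitted simulated cohort directory
#'
#' Convenience wrapper reading the files written by [emit_cohort_files()].
#'
#' @param dir Cohort directory.
#' @param config A [caller_config()].
#' @return As [run_pipeline()], plus the sample sheet under `$samples`.
#' @export
run_pipeline_dir <- function(dir, config = caller_config()) {
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  genes <- read_gene_models(file.path(dir, "genes.refflat.tsv"), "refflat")
  peak_files <- list.files(dir, "^peaks_.*\\.bed$", full.names = TRUE)
  peak_sets <- lapply(peak_files, read_peaks_bed)
  names(peak_sets) <- sub("^peaks_(.*)\\.bed$", "\\1", basename(peak_files))
  jf <- file.path(dir, "junctions", paste0(samples$sample_id, ".junctions.tsv"))
  names(jf) <- samples$sample_id
  res <- run_pipeline(jf, genes, samples, peak_sets, config)
  res$samples <- samples
  res
}
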