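#' Stepwise selection thresholds for the signature panel
#'
#' A candidate gene must produce microDNA in at least `min_dx_bm` diagnosis
#' bone-marrow patients and `min_dx_plasma` diagnosis plasma patients, be
#' detected in at most `remission_max` remission patients in either tissue
#' (0 = absent in all remission samples), and be confirmed in at least
#' `min_rel_bm` relapse BM and `min_rel_plasma` relapse plasma patients.
#'
#' @param min_dx_bm,min_dx_plasma,min_rel_bm,min_rel_plasma Minimum distinct
#'   detecting patients per stratum (defaults 2).
#' @param remission_max Maximum remission patients allowed (default 0).
#' @return A `selection_thresholds` list.
#' @export
selection_thresholds <- function(min_dx_bm = 2L, min_dx_plasma = 2L,
                                 min_rel_bm = 2L, min_rel_plasma = 2L,
                                 remission_max = 0L) {
  stopifnot(min_dx_bm >= 0, min_dx_plasma >= 0, min_rel_bm >= 0,
            min_rel_plasma >= 0, remission_max >= 0)
  structure(list(min_dx_bm = as.integer(min_dx_bm),
                 min_dx_plasma = as.integer(min_dx_plasma),
                 min_rel_bm = as.integer(min_rel_bm),
                 min_rel_plasma = as.integer(min_rel_plasma),
                 remission_max = as.integer(remission_max)),
            class = "selection_thresholds")
}

count_stratum <- function(pm, stage, tissue, genes) {
  have <- any(pm$samples$stage == stage & pm$samples$tissue == tissue)
  if (!have) stop("no samples in stratum: ", stage, " ", tissue)
  cnt <- patient_detection_counts(pm, stage, tissue)
  out <- stats::setNames(integer(length(genes)), genes)
  hit <- intersect(genes, names(cnt))
  out[hit] <- cnt[hit]
  out
}

#' Stepwise derivation of the disease/relapse microDNA gene signature
#'
#' Applies six ordered presence/absence filters over the gene universe of the
#' two tissue matrices: (1) detected in >= `min_dx_bm` diagnosis-BM patients;
#' (2) detected in <= `remission_max` remission-BM patients; (3) detected in
#' >= `min_rel_bm` relapse-BM patients (survivors of steps 1-3 form the
#' BM relapse-specific set, reported separately); (4) detected in >=
#' `min_dx_plasma` diagnosis-plasma patients; (5) detected in <=
#' `remission_max` remission-plasma patients; (6) detected in >=
#' `min_rel_plasma` relapse-plasma patients. All counting is over distinct
#' `patient_id`s. The final set is the intersection of the six monotone
#' filters and therefore independent of their order; the trace records the
#' survivors after each step in the fixed order above.
#'
#' Step (6) can be restricted to a designated subset of relapse-plasma
#' samples via `rel_plasma_samples` (e.g. the deep-sequenced ones), mirroring
#' two-pass confirmation designs in which relapse plasma is re-sequenced at
#' higher depth.
#'
#' @param bm,plasma [presence_matrix()] objects for the two tissues, each
#'   covering all three stages.
#' @param thresholds A [selection_thresholds()].
#' @param rel_plasma_samples Optional character vector of relapse-plasma
#'   `sample_id`s on which step (6) is evaluated.
#' @return A `signature_panel`: `genes` (final sorted panel), `trace`
#'   (per-step survivor counts and gene sets), `bm_relapse_specific`, and the
#'   thresholds used.
#' @export
select_signature <- function(bm, plasma, thresholds = selection_thresholds(),
                             rel_plasma_samples = NULL) {
  stopifnot(inherits(bm, "presence_matrix"), inherits(plasma, "presence_matrix"))
  genes <- as.character(sort(union(rownames(bm$detected),
                                   rownames(plasma$detected))))
  pl6 <- plasma
  if (!is.null(rel_plasma_samples)) {
    keep <- pl6$samples$stage != "relapse" |
      pl6$samples$sample_id %in% rel_plasma_samples
    if (!any(pl6$samples$stage[keep] == "relapse"))
      stop("rel_plasma_samples leaves no relapse-plasma samples")
    pl6 <- presence_matrix(pl6$detected[, keep, drop = FALSE],
                           pl6$samples[keep, , drop = FALSE])
  }
  steps <- list(
    list(name = "dx_bm_min", pass = count_stratum(bm, "diagnosis", "BM", genes) >=
           thresholds$min_dx_bm),
    list(name = "remission_bm_absent",
         pass = count_stratum(bm, "remission", "BM", genes) <=
           thresholds$remission_max),
    list(name = "rel_bm_min", pass = count_stratum(bm, "relapse", "BM", genes) >=
           thresholds$min_rel_bm),
    list(name = "dx_plasma_min",
         pass = count_stratum(plasma, "diagnosis", "plasma", genes) >=
           thresholds$min_dx_plasma),
    list(name = "remission_plasma_absent",
         pass = count_stratum(plasma, "remission", "plasma", genes) <=
           thresholds$remission_max),
    list(name = "rel_plasma_min",
         pass = count_stratum(pl6, "relapse", "plasma", genes) >=
           thresholds$min_rel_plasma)
  )
  surviving <- genes
  trace <- vector("list", length(steps))
  bm_relapse_specific <- NULL
  for (i in seq_along(steps)) {
    surviving <- surviving[steps[[i]]$pass[surviving]]
    trace[[i]] <- data.frame(step = i, filter = steps[[i]]$name,
                             n_genes = length(surviving),
                             stringsAsFactors = FALSE)
    trace[[i]]$genes <- list(surviving)
    if (i == 3) bm_relapse_specific <- surviving
  }
  trace <- do.call(rbind, trace)
  structure(list(genes = surviving, trace = trace,
                 bm_relapse_specific = bm_relapse_specific,
                 thresholds = thresholds),
            class = "signature_panel")
}

#' @export
print.signature_panel <- function(x, ...) {
  cat("signature_panel:", length(x$genes), "gene(s)\n")
  print(x$trace[, c("step", "filter", "n_genes")])
  if (length(x$genes)) cat("genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}
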