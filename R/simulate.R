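#' Synthetic-cohort generator configuration
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: per sample, each background gene produces microDNA independently
#' with probability `background_p` (0.05, i.e. ~2,000 producing genes out of
#' a 40,000-gene universe at paper scale); planted signature genes are
#' produced with `present_prob_disease` at diagnosis and relapse and never in
#' remission. Active genes emit a geometric number of circle fragments (mean
#' `fragments_per_active_gene`); fragment lengths follow a two-component
#' lognormal mixture with modes at ~150 and ~294 bp plus an exponential right
#' tail whose weight is solved numerically at configuration time so the
#' overall mean length hits `length_mean_target` (588 bp by default).
#' Per-fragment detection follows an exponential-saturation depth model,
#' `p = 1 - exp(-depth_lambda * depth_millions * abundance)`: at standard
#' depth relapse-plasma fragments (low-abundance, `relapse_plasma_abundance`)
#' are mostly missed, while deep sequencing restores detection — the cohort
#' defaults mark relapse-plasma samples as deep-sequenced, as a two-pass
#' design would.
#'
#' The default gene universe is a 2,000-gene test scale; set
#' `gene_universe = 40000` for paper-scale cohorts.
#'
#' @param gene_universe Number of genes G.
#' @param background_p Per-sample per-gene production probability.
#' @param n_patients Named counts of patients per stage.
#' @param n_relapse_labeled Number of diagnosis patients labeled as future
#'   relapse (the relapse-stage patients are drawn from these).
#' @param tissues Tissues sampled per patient and stage.
#' @param n_signature Number of planted signature genes.
#' @param present_prob_disease Signature-gene production probability in
#'   diagnosis/relapse samples.
#' @param present_prob_remission Signature-gene production probability in
#'   remission (0: disease-specific by construction).
#' @param fragments_per_active_gene Mean fragment count per active gene
#'   (1 + geometric).
#' @param length_modes,length_sdlog,length_tail_start,length_tail_mean,length_mean_target
#'   Length-mixture parameters (bp): lognormal component modes, their common
#'   log-sd, the tail offset and (untruncated) tail mean, and the target
#'   overall mean the tail weight is solved for.
#' @param min_length,max_length Supported length range (bp).
#' @param support_mean,support_offset Junction-read support per fragment is
#'   `support_offset + Poisson(support_mean - support_offset)`; the default
#'   offset 2 guarantees every emitted fragment survives the default caller
#'   `min_support`.
#' @param depth_lambda Saturation rate per million reads.
#' @param standard_depth,deep_depth Mapped reads for standard and deep runs.
#' @param relapse_plasma_abundance Abundance factor of relapse-plasma
#'   fragments (suppresses standard-depth detection).
#' @param deep_relapse_plasma Sequence relapse plasma at `deep_depth`.
#' @param promoter_bias Probability a fragment is placed in the promoter
#'   window rather than uniformly in the gene body.
#' @param gene_span,gene_gap,genes_per_chrom Toy-genome layout (bp).
#' @param jitter_bp Maximum junction-endpoint jitter when emitting files.
#' @param peak_fractions Named fractions of gene promoters covered by each
#'   emitted open-chromatin peak set.
#' @return A `cohort_sim_config` list (with the solved `length_tail_weight`).
#' @export
cohort_sim_config <- function(gene_universe = 2000L,
                              background_p = 0.05,
                              n_patients = c(diagnosis = 25L, relapse = 9L,
                                             remission = 18L),
                              n_relapse_labeled = 11L,
                              tissues = c("BM", "plasma"),
                              n_signature = 11L,
                              present_prob_disease = 0.9,
                              present_prob_remission = 0,
                              fragments_per_active_gene = 4,
                              length_modes = c(150, 294),
                              length_sdlog = 0.12,
                              length_tail_start = 500,
                              length_tail_mean = 600,
                              length_mean_target = 588,
                              min_length = 60L,
                              max_length = 2000L,
                              support_mean = 3,
                              support_offset = 2L,
                              depth_lambda = 2,
                              standard_depth = 3.5e6,
                              deep_depth = 115e6,
                              relapse_plasma_abundance = 0.05,
                              deep_relapse_plasma = TRUE,
                              promoter_bias = 0.2,
                              gene_span = 10000L,
                              gene_gap = 8000L,
                              genes_per_chrom = 100L,
                              jitter_bp = 2L,
                              peak_fractions = c(LCL = 0.6, BALL = 0.3)) {
  stopifnot(
    gene_universe >= 1, background_p >= 0, background_p < 1,
    all(n_patients >= 1), identical(sort(names(n_patients)),
                                    sort(c("diagnosis", "relapse", "remission"))),
    n_relapse_labeled >= n_patients[["relapse"]],
    n_relapse_labeled <= n_patients[["diagnosis"]],
    n_patients[["remission"]] <= n_patients[["diagnosis"]],
    all(tissues %in% c("BM", "plasma")),
    n_signature >= 0, n_signature < gene_universe,
    present_prob_disease >= 0, present_prob_disease <= 1,
    present_prob_remission >= 0, present_prob_remission <= 1,
    fragments_per_active_gene >= 1,
    length(length_modes) == 2, length_sdlog > 0,
    min_length < length_modes[1], max_length > length_tail_start,
    support_mean >= support_offset, support_offset >= 0,
    depth_lambda > 0, standard_depth > 0, deep_depth >= standard_depth,
    relapse_plasma_abundance > 0, relapse_plasma_abundance <= 1,
    promoter_bias >= 0, promoter_bias <= 1,
    gene_span > max_length, gene_gap > 2000 + max_length + 4L * jitter_bp,
    jitter_bp >= 0
  )
  cfg <- list(
    gene_universe = as.integer(gene_universe), background_p = background_p,
    n_patients = n_patients, n_relapse_labeled = as.integer(n_relapse_labeled),
    tissues = tissues, n_signature = as.integer(n_signature),
    present_prob_disease = present_prob_disease,
    present_prob_remission = present_prob_remission,
    fragments_per_active_gene = fragments_per_active_gene,
    length_modes = length_modes, length_sdlog = length_sdlog,
    length_tail_start = length_tail_start, length_tail_mean = length_tail_mean,
    length_mean_target = length_mean_target,
    min_length = as.integer(min_length), max_length = as.integer(max_length),
    support_mean = support_mean, support_offset = as.integer(support_offset),
    depth_lambda = depth_lambda, standard_depth = standard_depth,
    deep_depth = deep_depth,
    relapse_plasma_abundance = relapse_plasma_abundance,
    deep_relapse_plasma = isTRUE(deep_relapse_plasma),
    promoter_bias = promoter_bias,
    gene_span = as.integer(gene_span), gene_gap = as.integer(gene_gap),
    genes_per_chrom = as.integer(genes_per_chrom),
    jitter_bp = as.integer(jitter_bp), peak_fractions = peak_fractions
  )
  cfg$length_tail_weight <- solve_tail_weight(cfg)
  class(cfg) <- "cohort_sim_config"
  cfg
}

# mean of an exponential(mean m) truncated to [0, L]
truncated_exp_mean <- function(m, L) m - L / (expm1(L / m))

# tail weight w solving (1-w) * mean(modes) + w * mean(tail) = target
solve_tail_weight <- function(cfg) {
  comp_means <- cfg$length_modes * exp(1.5 * cfg$length_sdlog^2)
  mode_mean <- mean(comp_means)
  tail_mean <- cfg$length_tail_start +
    truncated_exp_mean(cfg$length_tail_mean,
                       cfg$max_length - cfg$length_tail_start)
  w <- (cfg$length_mean_target - mode_mean) / (tail_mean - mode_mean)
  if (w < 0 || w >= 1)
    stop("length_mean_target unreachable with these mixture parameters")
  w
}

#' Draw fragment lengths from the bimodal-plus-tail mixture
#'
#' Two equally weighted lognormal components with histogram modes at
#' `length_modes`, plus a truncated-exponential right tail starting at
#' `length_tail_start`, with the tail weight solved so the mixture mean
#' equals `length_mean_target`. Lengths are integers in
#' `[min_length, max_length]` (out-of-range lognormal draws are resampled).
#'
#' @param config A [cohort_sim_config()].
#' @param n Number of lengths to draw.
#' @return Integer vector of lengths (bp).
#' @export
simulate_lengths <- function(config, n) {
  stopifnot(n >= 1)
  w <- config$length_tail_weight
  comp <- sample.int(3L, n, replace = TRUE,
                     prob = c((1 - w) / 2, (1 - w) / 2, w))
  out <- numeric(n)
  meanlog <- log(config$length_modes) + config$length_sdlog^2
  for (k in 1:2) {
    idx <- which(comp == k)
    if (!length(idx)) next
    x <- stats::rlnorm(length(idx), meanlog[k], config$length_sdlog)
    bad <- which(x < config$min_length | x > config$max_length)
    while (length(bad)) {
      x[bad] <- stats::rlnorm(length(bad), meanlog[k], config$length_sdlog)
      bad <- bad[x[bad] < config$min_length | x[bad] > config$max_length]
    }
    out[idx] <- x
  }
  idx <- which(comp == 3L)
  if (length(idx)) {
    L <- config$max_length - config$length_tail_start
    u <- stats::runif(length(idx)) * stats::pexp(L, 1 / config$length_tail_mean)
    out[idx] <- config$length_tail_start +
      stats::qexp(u, 1 / config$length_tail_mean)
  }
  pmin.int(as.integer(round(out)), config$max_length)
}

#' Deterministic toy gene models for simulation
#'
#' Genes are packed along synthetic chromosomes with `gene_span` bp
#' transcripts separated by `gene_gap` bp gaps (wide enough that a promoter
#' window plus a maximal fragment can never reach the next gene, keeping
#' gene assignment unambiguous). Strands alternate; each gene has three
#' exons and a CDS so every feature category is exercised.
#'
#' @param config A [cohort_sim_config()].
#' @return A `gene_models` data.frame of `gene_universe` genes.
#' @export
make_sim_genes <- function(config) {
  G <- config$gene_universe
  span <- config$gene_span
  pitch <- span + config$gene_gap
  idx <- seq_len(G) - 1L
  chrom_i <- idx %/% config$genes_per_chrom + 1L
  pos_i <- idx %% config$genes_per_chrom
  tx_start <- 5000L + pos_i * pitch
  rel <- function(f) as.integer(round(f * span))
  ex_s <- c(0L, rel(0.40), rel(0.85))
  ex_e <- c(rel(0.10), rel(0.55), span)
  g <- data.frame(
    gene_name = sprintf("G%05d", seq_len(G)),
    chrom = paste0("chr", chrom_i),
    strand = ifelse(idx %% 2L == 0L, "+", "-"),
    tx_start = tx_start, tx_end = tx_start + span,
    cds_start = tx_start + rel(0.03), cds_end = tx_start + rel(0.97),
    stringsAsFactors = FALSE
  )
  g$exon_starts <- lapply(tx_start, function(s) s + ex_s)
  g$exon_ends <- lapply(tx_start, function(s) s + ex_e)
  class(g) <- c("gene_models", "data.frame")
  g
}

sim_sample_sheet <- function(config) {
  n_dx <- config$n_patients[["diagnosis"]]
  patients <- sprintf("P%03d", seq_len(n_dx))
  relapse_labeled <- sort(sample(patients, config$n_relapse_labeled))
  rel_patients <- sort(sample(relapse_labeled, config$n_patients[["relapse"]]))
  nonrel <- setdiff(patients, relapse_labeled)
  n_rem <- config$n_patients[["remission"]]
  rem_patients <- if (n_rem <= length(nonrel)) sort(sample(nonrel, n_rem)) else
    sort(c(nonrel, sample(relapse_labeled, n_rem - length(nonrel))))
  stage_patients <- list(diagnosis = patients, relapse = rel_patients,
                         remission = rem_patients)
  rows <- list()
  for (st in names(stage_patients)) {
    for (ti in config$tissues) {
      for (p in stage_patients[[st]]) {
        deep <- config$deep_relapse_plasma && st == "relapse" && ti == "plasma"
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste(p, substr(st, 1, 3), ti, sep = "_"),
          patient_id = p, tissue = ti, stage = st,
          mapped_reads = if (deep) config$deep_depth else config$standard_depth,
          later_relapse = if (p %in% relapse_labeled) "yes" else "no",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  validate_sample_sheet(do.call(rbind, rows))
}

sample_detection_prob <- function(config, samples) {
  abundance <- ifelse(samples$stage == "relapse" & samples$tissue == "plasma",
                      config$relapse_plasma_abundance, 1)
  1 - exp(-config$depth_lambda * samples$mapped_reads / 1e6 * abundance)
}

#' Simulate a synthetic microDNA cohort
#'
#' Draws the per-sample active-gene indicators (background plus planted
#' signature genes), fragment counts, the depth-model detection thinning,
#' and — at `level = "fragments"` — fragment coordinates, lengths, and
#' junction-read supports on the toy genome. The truth manifest records the
#' planted signature genes and, per tissue, both the `active`
#' (production-truth) and `detected` (post-thinning) presence matrices over
#' the full gene universe; the pipeline applied to emitted files reproduces
#' the `detected` matrices.
#'
#' @param config A [cohort_sim_config()].
#' @param seed Integer seed; fixed seed gives byte-identical cohorts.
#' @param level `"fragments"` (full call-level cohort, default) or
#'   `"matrix"` (presence matrices only; much faster for cohort-scale
#'   statistics).
#' @return A `microdna_cohort` list: `config`, `seed`, `samples`, `genes`
#'   (fragment level only), `signature_genes`, and `truth` with `active` and
#'   `detected` matrices per tissue plus `fragments` (fragment level).
#' @export
simulate_cohort <- function(config = cohort_sim_config(), seed = 1L,
                            level = c("fragments", "matrix")) {
  level <- match.arg(level)
  set.seed(seed)
  samples <- sim_sample_sheet(config)
  G <- config$gene_universe
  gene_names <- sprintf("G%05d", seq_len(G))
  signature_genes <- sort(sample(gene_names, config$n_signature))
  sig_idx <- match(signature_genes, gene_names)
  n_s <- nrow(samples)
  p_act <- matrix(config$background_p, G, n_s)
  disease <- samples$stage %in% c("diagnosis", "relapse")
  p_act[sig_idx, disease] <- config$present_prob_disease
  p_act[sig_idx, !disease] <- config$present_prob_remission
  active <- matrix(stats::rbinom(G * n_s, 1L, p_act), G, n_s,
                   dimnames = list(gene_names, samples$sample_id))
  # fragment counts for active genes: 1 + geometric, mean fragments_per_active_gene
  geom_p <- 1 / config$fragments_per_active_gene
  n_frag <- matrix(0L, G, n_s)
  on <- which(active == 1L)
  n_frag[on] <- 1L + stats::rgeom(length(on), geom_p)
  # depth-model thinning, per fragment
  p_det <- sample_detection_prob(config, samples)
  n_det <- matrix(0L, G, n_s)
  n_det[on] <- stats::rbinom(length(on), n_frag[on],
                             rep(p_det, each = G)[on])
  detected <- (n_det > 0L) + 0L
  dimnames(detected) <- dimnames(active)
  split_tissue <- function(m) {
    out <- lapply(config$tissues, function(ti) {
      keep <- samples$tissue == ti
      presence_matrix(m[, keep, drop = FALSE], samples[keep, , drop = FALSE])
    })
    stats::setNames(out, config$tissues)
  }
  truth <- list(active = split_tissue(active), detected = split_tissue(detected),
                n_detected_fragments = n_det)
  cohort <- list(config = config, seed = seed, samples = samples,
                 signature_genes = signature_genes, truth = truth)
  if (level == "fragments") {
    genes <- make_sim_genes(config)
    hits <- which(n_det > 0L, arr.ind = TRUE)
    counts <- n_det[hits]
    gi <- rep(hits[, 1], counts)
    si <- rep(hits[, 2], counts)
    total <- length(gi)
    frag <- data.frame(
      sample_id = samples$sample_id[si],
      gene_name = gene_names[gi],
      stringsAsFactors = FALSE
    )
    len <- simulate_lengths(config, max(total, 1L))[seq_len(total)]
    in_prom <- stats::runif(total) < config$promoter_bias
    gs <- genes$tx_start[gi]; ge <- genes$tx_end[gi]
    plus <- genes$strand[gi] == "+"
    start <- integer(total)
    # promoter placement: overlap the strand-aware 2 kb upstream window
    pw_lo <- ifelse(plus, gs - 2000L, ge)
    pw_hi <- ifelse(plus, gs, ge + 2000L)
    lo <- pmax.int(0L, pw_lo - len + 1L)
    start_prom <- lo + floor(stats::runif(total) * (pw_hi - 1L - lo + 1L))
    start_body <- gs + floor(stats::runif(total) * (ge - len - gs + 1L))
    start <- as.integer(ifelse(in_prom, start_prom, start_body))
    frag$chrom <- genes$chrom[gi]
    frag$start <- start
    frag$end <- start + len
    frag$length <- len
    frag$strand <- genes$strand[gi]
    frag$support <- config$support_offset +
      stats::rpois(total, config$support_mean - config$support_offset)
    frag$in_promoter_draw <- in_prom
    cohort$genes <- genes
    cohort$truth$fragments <- frag
  }
  structure(cohort, class = "microdna_cohort")
}

#' @export
print.microdna_cohort <- function(x, ...) {
  cat("microdna_cohort: G =", x$config$gene_universe, "genes,",
      nrow(x$samples), "samples, seed", x$seed, "\n")
  cat("signature genes:", paste(x$signature_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits per-sample chimeric-junction TSVs (each fragment becomes `support`
#' junction rows with independent endpoint jitter up to `jitter_bp`), the toy
#' refFlat gene models, open-chromatin peak BEDs covering the configured
#' fraction of gene promoters, the sample sheet, truth presence matrices
#' (TSV), and a JSON truth manifest. Writing is deterministic given the
#' cohort (jitter and peak draws are re-seeded from the cohort seed).
#'
#' @param cohort A fragment-level [simulate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths (junction files under `$junctions`).
#' @export
emit_cohort_files <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "microdna_cohort"),
            !is.null(cohort$truth$fragments))
  dir.create(file.path(out_dir, "junctions"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(cohort$seed + 1L)
  cfg <- cohort$config
  frag <- cohort$truth$fragments
  paths <- list()
  paths$genes <- file.path(out_dir, "genes.refflat.tsv")
  write_gene_models_refflat(cohort$genes, paths$genes)
  paths$samples <- file.path(out_dir, "samples.tsv")
  utils::write.table(cohort$samples, paths$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # junction rows: donor = circle end (1-based), acceptor = start + 1
  reads <- frag[rep(seq_len(nrow(frag)), frag$support), , drop = FALSE]
  j <- cfg$jitter_bp
  jit <- function(n) if (j > 0) sample.int(2L * j + 1L, n, replace = TRUE) - j - 1L
    else integer(n)
  n_r <- nrow(reads)
  don <- reads$end + jit(n_r)
  acc <- reads$start + 1L + jit(n_r)
  junc <- data.frame(
    reads$chrom, don, reads$strand, reads$chrom, acc, reads$strand,
    0L, 0L,
    paste0(reads$sample_id, "_r", stats::ave(seq_len(n_r), reads$sample_id,
                                             FUN = seq_along)),
    stringsAsFactors = FALSE
  )
  paths$junctions <- character(0)
  for (sid in cohort$samples$sample_id) {
    f <- file.path(out_dir, "junctions", paste0(sid, ".junctions.tsv"))
    utils::write.table(junc[reads$sample_id == sid, , drop = FALSE], f,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    paths$junctions[sid] <- f
  }
  # open-chromatin peak sets over a fraction of gene promoters
  prom <- promoter_window(cohort$genes, 2000L)
  paths$peaks <- character(0)
  for (nm in names(cfg$peak_fractions)) {
    n_pick <- round(cfg$peak_fractions[[nm]] * nrow(prom))
    pick <- sort(sample.int(nrow(prom), n_pick))
    f <- file.path(out_dir, paste0("peaks_", nm, ".bed"))
    utils::write.table(prom[pick, c("chrom", "start", "end")], f, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths$peaks[nm] <- f
  }
  paths$truth_matrices <- character(0)
  for (ti in cfg$tissues) {
    f <- file.path(out_dir, paste0("truth_detected_", ti, ".tsv"))
    write_matrix_tsv(cohort$truth$detected[[ti]], f)
    paths$truth_matrices[ti] <- f
  }
  manifest <- list(
    seed = cohort$seed,
    gene_universe = cfg$gene_universe,
    signature_genes = cohort$signature_genes,
    n_fragments_per_sample = as.list(table(frag$sample_id)),
    files = list(genes = basename(paths$genes),
                 samples = basename(paths$samples),
                 truth_matrices = as.list(basename(paths$truth_matrices)))
  )
  paths$manifest <- file.path(out_dir, "truth.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
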