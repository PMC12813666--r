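#' Read a chimeric-junction file
#'
#' Parses the tab-separated chimeric-junction dialect emitted by split-read
#' aligners (one junction-supporting read per row). The pinned dialect has at
#' least nine columns: donor chromosome, donor position (1-based), donor
#' strand, acceptor chromosome, acceptor position (1-based), acceptor strand,
#' an integer junction-type code, one ignored repeat-length column, and the
#' read identifier. Extra columns are ignored; header or comment lines
#' beginning with `#` are skipped.
#'
#' Amplified circle libraries are noisy, so parsing is lenient by default:
#' malformed rows (wrong column count, non-integer or non-positive
#' coordinates, unknown strand, empty chromosome) are skipped, counted, and
#' reported in the `n_malformed` attribute with a warning. With
#' `strict = TRUE` the first malformed row is fatal.
#'
#' @param path Path to the junction TSV.
#' @param strict Logical; abort on the first malformed row instead of
#'   skipping it.
#' @return A data.frame with columns `chrom_donor`, `pos_donor`,
#'   `strand_donor`, `chrom_acceptor`, `pos_acceptor`, `strand_acceptor`,
#'   `junction_type`, `read_id`, and an integer attribute `n_malformed`.
#' @export
read_chimeric_junctions <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("junction file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- data.frame(
    chrom_donor = character(0), pos_donor = integer(0),
    strand_donor = character(0), chrom_acceptor = character(0),
    pos_acceptor = integer(0), strand_acceptor = character(0),
    junction_type = integer(0), read_id = character(0),
    stringsAsFactors = FALSE
  )
  n_bad <- 0L
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    ok <- nf >= 9L
    pd <- pa <- jt <- rep(NA_integer_, length(lines))
    get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
    cd <- get(1); sd_ <- get(3); ca <- get(4); sa <- get(6); rid <- get(9)
    suppressWarnings({
      pd <- as.integer(get(2)); pa <- as.integer(get(5)); jt <- as.integer(get(7))
    })
    ok <- ok & !is.na(pd) & !is.na(pa) & pd >= 1L & pa >= 1L &
      sd_ %in% c("+", "-") & sa %in% c("+", "-") &
      nzchar(cd) & nzchar(ca) & !is.na(cd) & !is.na(ca) & !is.na(jt)
    n_bad <- sum(!ok)
    if (n_bad > 0L && strict) {
      stop("malformed junction row ", which(!ok)[1], " in ", path)
    }
    out <- data.frame(
      chrom_donor = cd[ok], pos_donor = pd[ok], strand_donor = sd_[ok],
      chrom_acceptor = ca[ok], pos_acceptor = pa[ok], strand_acceptor = sa[ok],
      junction_type = jt[ok], read_id = rid[ok], stringsAsFactors = FALSE
    )
    if (n_bad > 0L) {
      warning(n_bad, " malformed junction row(s) skipped in ", path)
    }
  }
  attr(out, "n_malformed") <- as.integer(n_bad)
  out
}

#' Read gene models from refFlat or BED12
#'
#' Both dialects are normalised to the same representation: 0-based
#' half-open transcript, CDS, and exon coordinates. A non-coding transcript is
#' encoded by `cds_start == cds_end`.
#'
#' @param path Path to the gene-model file.
#' @param dialect `"refflat"` (11-column refFlat TSV) or `"bed12"`.
#' @return A `gene_models` data.frame with columns `gene_name`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`, and list-columns
#'   `exon_starts` / `exon_ends`.
#' @export
read_gene_models <- function(path, dialect = c("refflat", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("gene-model file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  split_ints <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                   function(v) as.integer(v[nzchar(v)]))
  if (dialect == "refflat") {
    if (ncol(tab) < 11) stop("refFlat requires 11 columns, found ", ncol(tab))
    g <- data.frame(
      gene_name = as.character(tab[[1]]), chrom = as.character(tab[[3]]),
      strand = as.character(tab[[4]]),
      tx_start = as.integer(tab[[5]]), tx_end = as.integer(tab[[6]]),
      cds_start = as.integer(tab[[7]]), cds_end = as.integer(tab[[8]]),
      stringsAsFactors = FALSE
    )
    g$exon_starts <- split_ints(as.character(tab[[10]]))
    g$exon_ends <- split_ints(as.character(tab[[11]]))
    n_exons <- as.integer(tab[[9]])
  } else {
    if (ncol(tab) < 12) stop("BED12 requires 12 columns, found ", ncol(tab))
    g <- data.frame(
      gene_name = as.character(tab[[4]]), chrom = as.character(tab[[1]]),
      strand = as.character(tab[[6]]),
      tx_start = as.integer(tab[[2]]), tx_end = as.integer(tab[[3]]),
      cds_start = as.integer(tab[[7]]), cds_end = as.integer(tab[[8]]),
      stringsAsFactors = FALSE
    )
    sizes <- split_ints(as.character(tab[[11]]))
    offs <- split_ints(as.character(tab[[12]]))
    g$exon_starts <- Map(function(s, o) s + o, g$tx_start, offs)
    g$exon_ends <- Map(`+`, g$exon_starts, sizes)
    n_exons <- as.integer(tab[[10]])
  }
  validate_gene_models(g, n_exons)
  class(g) <- c("gene_models", "data.frame")
  g
}

validate_gene_models <- function(g, n_exons = NULL) {
  for (i in seq_len(nrow(g))) {
    es <- g$exon_starts[[i]]; ee <- g$exon_ends[[i]]
    bad <-
      g$tx_start[i] >= g$tx_end[i] ||
      !(g$strand[i] %in% c("+", "-")) ||
      length(es) != length(ee) || length(es) == 0 ||
      any(es >= ee) ||
      is.unsorted(es, strictly = TRUE) ||
      any(es[-1] < ee[-length(ee)]) ||                      # overlap
      es[1] < g$tx_start[i] || ee[length(ee)] > g$tx_end[i] ||
      (!is.null(n_exons) && n_exons[i] != length(es)) ||
      (g$cds_start[i] != g$cds_end[i] &&
         (g$cds_start[i] < g$tx_start[i] || g$cds_end[i] > g$tx_end[i] ||
            g$cds_start[i] >= g$cds_end[i]))
    if (bad) stop("inconsistent gene model at row ", i, " (", g$gene_name[i], ")")
  }
  invisible(g)
}

#' Write gene models as refFlat
#'
#' @param genes A `gene_models` data.frame.
#' @param path Output path.
#' @export
write_gene_models_refflat <- function(genes, path) {
  join <- function(l) vapply(l, function(v) paste0(paste(v, collapse = ","), ","), "")
  tab <- data.frame(
    genes$gene_name, genes$gene_name, genes$chrom, genes$strand,
    genes$tx_start, genes$tx_end, genes$cds_start, genes$cds_end,
    lengths(genes$exon_starts), join(genes$exon_starts), join(genes$exon_ends),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cohort sample sheet
#'
#' The sheet is a header-labelled TSV with required columns `sample_id`,
#' `patient_id`, `tissue` (`BM` or `plasma`), `stage` (`diagnosis`,
#' `relapse`, or `remission`), and `mapped_reads`; the optional
#' `later_relapse` column (`yes`/`no`/`unknown`) defaults to `"unknown"`.
#'
#' @param path Path to the sample-sheet TSV.
#' @return A validated data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  s <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  validate_sample_sheet(s)
}

#' Validate sample metadata
#'
#' @param s A data.frame of sample metadata.
#' @return The validated (and completed) data.frame, invisibly usable.
#' @export
validate_sample_sheet <- function(s) {
  req <- c("sample_id", "patient_id", "tissue", "stage", "mapped_reads")
  miss <- setdiff(req, names(s))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(s$sample_id))
    stop("duplicated sample_id: ", s$sample_id[duplicated(s$sample_id)][1])
  bad_t <- which(!(s$tissue %in% c("BM", "plasma")))
  if (length(bad_t)) stop("unknown tissue '", s$tissue[bad_t[1]], "' at row ", bad_t[1])
  bad_s <- which(!(s$stage %in% c("diagnosis", "relapse", "remission")))
  if (length(bad_s)) stop("unknown stage '", s$stage[bad_s[1]], "' at row ", bad_s[1])
  if (any(!is.finite(s$mapped_reads)) || any(s$mapped_reads <= 0))
    stop("mapped_reads must be positive")
  if (is.null(s$later_relapse)) {
    s$later_relapse <- "unknown"
  } else {
    bad_r <- which(!(s$later_relapse %in% c("yes", "no", "unknown")))
    if (length(bad_r)) stop("unknown later_relapse '", s$later_relapse[bad_r[1]],
                            "' at row ", bad_r[1])
  }
  key <- paste(s$patient_id, s$tissue, s$stage)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, tissue, stage) stratum: ", key[duplicated(key)][1])
  s
}

#' Write microDNA calls as BED6
#'
#' Coordinates are 0-based half-open; the BED name is the call id and the
#' score the junction-read support. [read_calls_bed()] round-trips the file.
#'
#' @param calls A `microdna_calls` data.frame.
#' @param path Output path.
#' @export
write_calls_bed <- function(calls, path) {
  tab <- data.frame(calls$chrom, calls$start, calls$end, calls$call_id,
                    calls$support, calls$strand, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read microDNA calls from BED6
#'
#' @param path Path to a BED6 file written by [write_calls_bed()].
#' @return A `microdna_calls` data.frame.
#' @export
read_calls_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (ncol(tab) < 6) stop("BED6 requires 6 columns, found ", ncol(tab))
  calls <- data.frame(
    chrom = as.character(tab[[1]]), start = as.integer(tab[[2]]),
    end = as.integer(tab[[3]]), strand = as.character(tab[[6]]),
    support = as.integer(tab[[5]]), call_id = as.character(tab[[4]]),
    stringsAsFactors = FALSE
  )
  calls$length <- calls$end - calls$start
  as_microdna_calls(calls)
}

#' Read an interval BED file (3+ columns)
#'
#' @param path Path to a BED file.
#' @return A data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  data.frame(chrom = as.character(tab[[1]]), start = as.integer(tab[[2]]),
             end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
}

#' Write / read a binary presence matrix as TSV
#'
#' Genes are rows, samples columns, cells 0/1; the first column is `gene`.
#' `write_matrix_tsv` accepts either a plain 0/1 matrix with dimnames or a
#' [presence_matrix()] object (only the indicator part is written; sample
#' metadata travels in the sample sheet).
#'
#' @param m A presence matrix (or `presence_matrix` object).
#' @param path TSV path.
#' @return `read_matrix_tsv` returns the integer indicator matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "presence_matrix")) m <- m$detected
  tab <- data.frame(gene = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  storage.mode(m) <- "integer"
  if (length(m) && !all(m %in% c(0L, 1L))) stop("presence matrix cells must be 0/1")
  m
}
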