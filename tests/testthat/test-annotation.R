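test_that("calls assign to the overlapping gene, promoter window included", {
  genes <- toy_genes()
  # inside an exon of geneA only
  expect_equal(assign_gene(mk_calls("chr1", 14100L, 14400L), genes), "geneA")
  # 1,500 bp upstream of the + strand TSS: inside the 2 kb promoter window
  expect_equal(assign_gene(mk_calls("chr1", 8400L, 8600L), genes), "geneA")
  # just beyond the window
  expect_true(is.na(assign_gene(mk_calls("chr1", 7500L, 7990L), genes)))
  # minus-strand promoter is downstream of tx_end
  expect_equal(assign_gene(mk_calls("chr1", 40500L, 40700L), genes), "geneB")
  # intergenic
  expect_true(is.na(assign_gene(mk_calls("chr1", 25000L, 25400L), genes)))
})

test_that("multi-gene overlap resolves by largest overlap then gene name", {
  g <- toy_genes()
  g$tx_start <- c(1000L, 1120L)
  g$tx_end <- c(1120L, 1400L)
  g$cds_start <- c(1000L, 1120L)
  g$cds_end <- c(1000L, 1120L)  # non-coding, keep invariants simple
  g$exon_starts <- list(1000L, 1120L)
  g$exon_ends <- list(1120L, 1400L)
  # call [1000,1200): 120 bp in geneA's span, 80 bp in geneB's
  expect_equal(assign_gene(mk_calls("chr1", 1000L, 1200L, "+"), g,
                           promoter_bp = 0L), "geneA")
  # exact tie -> lexicographically smallest name
  g2 <- g
  g2$tx_start <- c(1000L, 1000L); g2$tx_end <- c(1200L, 1200L)
  g2$exon_starts <- list(1000L, 1000L); g2$exon_ends <- list(1200L, 1200L)
  g2$gene_name <- c("geneZ", "geneB")
  expect_equal(assign_gene(mk_calls("chr1", 1050L, 1150L, "+"), g2,
                           promoter_bp = 0L), "geneB")
})

test_that("feature categories follow the utr5/promoter > utr3 > exon > intron precedence", {
  genes <- toy_genes()
  cls <- function(s, e) classify_feature(mk_calls("chr1", s, e), genes)
  expect_equal(cls(9000L, 9200L), "utr5_promoter")     # promoter window
  expect_equal(cls(10050L, 10200L), "utr5_promoter")   # 5'UTR exon part
  expect_equal(cls(9800L, 10500L), "utr5_promoter")    # spans promoter AND exon
  expect_equal(cls(19750L, 19900L), "utr3")            # 3'UTR exon part
  expect_equal(cls(14100L, 14400L), "exon")            # CDS exon
  expect_equal(cls(12000L, 12300L), "intron")          # fully intronic
  expect_equal(cls(25000L, 25200L), "intergenic")
  # minus strand: 5'UTR sits at the high-coordinate end
  expect_equal(cls(39750L, 39900L), "utr5_promoter")
  expect_equal(cls(30050L, 30200L), "utr3")
  # non-coding gene: exonic overlap is exon, promoter still applies
  nc <- toy_genes()
  nc$cds_start <- nc$tx_start
  nc$cds_end <- nc$tx_start
  expect_equal(classify_feature(mk_calls("chr1", 10050L, 10200L), nc), "exon")
  expect_equal(classify_feature(mk_calls("chr1", 9000L, 9200L), nc), "utr5_promoter")
})

test_that("open-chromatin overlap uses half-open interval semantics per peak set", {
  peaks <- list(LCL = data.frame(chrom = "chr1", start = 250L, end = 400L),
                BALL = data.frame(chrom = "chr1", start = 200L, end = 300L))
  calls <- mk_calls("chr1", c(100L, 100L), c(300L, 200L))
  oc <- overlap_open_chromatin(calls, peaks)
  expect_true(oc[1, "LCL"])    # [100,300) vs [250,400): shared bases
  expect_false(oc[2, "LCL"])   # [100,200) vs [250,400)
  expect_false(oc[2, "BALL"])  # [100,200) vs [200,300): abutting, no shared base
  expect_true(oc[1, "BALL"])
})

test_that("interval overlap flags equal a brute-force scan on random fixtures", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 40; m <- 15
    calls <- mk_calls(sample(c("chr1", "chr2"), n, TRUE),
                      as.integer(sample(1:5000, n)), 0L)
    calls$end <- calls$start + sample(50:500, n, TRUE)
    calls$length <- calls$end - calls$start
    ps <- sample(1:5000, m)
    peaks <- list(X = data.frame(chrom = sample(c("chr1", "chr2"), m, TRUE),
                                 start = ps, end = ps + sample(20:400, m, TRUE)))
    got <- overlap_open_chromatin(calls, peaks)[, "X"]
    want <- vapply(seq_len(n), function(i) any(
      peaks$X$chrom == calls$chrom[i] &
        pmax(peaks$X$start, calls$start[i]) < pmin(peaks$X$end, calls$end[i])
    ), TRUE)
    expect_equal(unname(got), want)
  }
})

test_that("per-gene summaries reproduce printed count/percentage structure", {
  # an AASS-like plasma gene: 42 fragments split 8 exon / 2 promoter-5'UTR /
  # 1 3'UTR / 31 intron over 5 diagnosis + 5 relapse individuals
  fx <- category_fixture(c(exon = 8, utr5_promoter = 2, utr3 = 1, intron = 31))
  s <- summarize_gene_annotations(fx$ann, fx$samples)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_microdna, 42)
  expect_equal(s$n_individuals_dx, 5)
  expect_equal(s$n_individuals_rel, 5)
  expect_equal(c(s$pct_exon, s$pct_utr5_promoter, s$pct_utr3, s$pct_intron),
               c(19, 5, 2, 74))
  expect_equal(s$n_exon + s$n_utr5_promoter + s$n_utr3 + s$n_intron,
               s$n_microdna)

  # a KBTBD11-like gene: 34 of 39 fragments in the promoter/5'UTR window
  fx2 <- category_fixture(c(exon = 1, utr5_promoter = 34, utr3 = 4, intron = 0))
  s2 <- summarize_gene_annotations(fx2$ann, fx2$samples)
  expect_equal(s2$n_microdna, 39)
  expect_equal(s2$pct_utr5_promoter, 87)
  expect_equal(s2$pct_exon, 3)
  expect_equal(s2$pct_utr3, 10)
})

test_that("open-chromatin summary percentages count overlapping fragments", {
  genes <- toy_genes()
  calls <- mk_calls("chr1", c(rep(14100L, 10), rep(12000L, 10)), 0L)
  calls$end <- calls$start + 200L
  calls$length <- 200L
  # peak covering only the exon window -> 10 of 20 fragments overlap
  peaks <- list(LCL = data.frame(chrom = "chr1", start = 14000L, end = 14500L))
  samples <- mk_samples("P1", "plasma", "diagnosis")
  ann <- annotate_calls(calls, genes, peaks, sample_id = samples$sample_id)
  s <- summarize_gene_annotations(ann, samples)
  expect_equal(s$n_LCL, 10)
  expect_equal(s$pct_LCL, 50)
})

test_that("every annotated call gets exactly one category and counts partition", {
  set.seed(88)
  genes <- toy_genes()
  for (rep in 1:5) {
    n <- 60
    st <- as.integer(sample(7000:41000, n))
    calls <- mk_calls("chr1", st, st + sample(50:1500, n, TRUE))
    samples <- mk_samples(sprintf("P%d", 1:3), "BM", "diagnosis")
    ann <- annotate_calls(calls, genes,
                          sample_id = sample(samples$sample_id, n, TRUE))
    expect_true(all(ann$category %in% c("exon", "utr5_promoter", "utr3",
                                        "intron", "intergenic")))
    expect_identical(is.na(ann$gene_name), ann$category == "intergenic")
    s <- summarize_gene_annotations(ann, samples)
    expect_equal(s$n_exon + s$n_utr5_promoter + s$n_utr3 + s$n_intron,
                 s$n_microdna)
    pct_sum <- s$pct_exon + s$pct_utr5_promoter + s$pct_utr3 + s$pct_intron
    expect_true(all(pct_sum >= 98 & pct_sum <= 102))
  }
})
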