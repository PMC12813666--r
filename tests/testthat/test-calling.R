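test_that("only same-chromosome same-strand head-to-tail junctions yield candidates", {
  f <- write_junction_lines(c(
    junction_row("chr1", 1500, "+", "chr1", 1200, "+", 0, "circ1"),
    junction_row("chr1", 1501, "+", "chr1", 1201, "+", 0, "circ2"),
    junction_row("chr1", 1499, "+", "chr1", 1199, "+", 0, "circ3"),
    junction_row("chr1", 1500, "+", "chr2", 1200, "+", 0, "trans1"),
    junction_row("chr3", 100, "+", "chr2", 900, "+", 0, "trans2"),
    junction_row("chr1", 1500, "+", "chr1", 1200, "-", 0, "inv1")
  ))
  cand <- junctions_to_candidates(read_chimeric_junctions(f))
  expect_equal(nrow(cand), 3)
  st <- attr(cand, "filter_stats")
  expect_equal(unname(st[c("n_translocation_like", "n_inversion_like",
                           "n_circular")]), c(2, 1, 3))

  # circular orientation: acceptor upstream of donor
  one <- junctions_to_candidates(data.frame(
    chrom_donor = "chr1", pos_donor = 1500L, strand_donor = "+",
    chrom_acceptor = "chr1", pos_acceptor = 1200L, strand_acceptor = "+",
    junction_type = 0L, read_id = "a", stringsAsFactors = FALSE))
  expect_equal(one$start, 1199L)
  expect_equal(one$end, 1500L)
  expect_equal(one$length, 301L)
  expect_equal(one$support, 1L)

  # linear splice orientation (donor upstream) is not a circle
  lin <- junctions_to_candidates(data.frame(
    chrom_donor = "chr1", pos_donor = 1200L, strand_donor = "+",
    chrom_acceptor = "chr1", pos_acceptor = 1500L, strand_acceptor = "+",
    junction_type = 0L, read_id = "a", stringsAsFactors = FALSE))
  expect_equal(nrow(lin), 0)
})

test_that("duplicate read ids are collapsed before candidate generation", {
  f <- write_junction_lines(c(
    junction_row("chr1", 1500, "+", "chr1", 1200, "+", 0, "dup"),
    junction_row("chr1", 1500, "+", "chr1", 1200, "+", 0, "dup"),
    junction_row("chr1", 1500, "+", "chr1", 1200, "+", 0, "uniq")
  ))
  cand <- junctions_to_candidates(read_chimeric_junctions(f))
  expect_equal(nrow(cand), 2)
  expect_equal(unname(attr(cand, "filter_stats")["n_duplicate_reads"]), 1)
})

test_that("clustering merges within tolerance to weighted-median endpoints", {
  cand <- mk_calls("chr1", c(1199L, 1199L, 1199L, 1201L),
                   c(1500L, 1500L, 1500L, 1502L), support = 1L)
  out <- cluster_and_filter(cand, caller_config())
  expect_equal(nrow(out), 1)
  expect_equal(out$support, 4L)
  expect_equal(out$start, 1199L)  # weighted lower median, tie -> smaller
  expect_equal(out$end, 1500L)

  # a singleton below min_support drops
  expect_equal(nrow(cluster_and_filter(mk_calls("chr1", 100L, 400L, support = 1L),
                                       caller_config(min_support = 2))), 0)

  # length filter: 2500 bp exceeds the <2 kb regime
  expect_equal(nrow(cluster_and_filter(mk_calls("chr1", 1000L, 3500L, support = 5L),
                                       caller_config())), 0)

  # candidates on opposite strands at identical coordinates stay separate
  two <- rbind(mk_calls("chr1", 100L, 400L, "+", 2L),
               mk_calls("chr1", 100L, 400L, "-", 2L))
  class(two) <- c("microdna_calls", "data.frame")
  expect_equal(nrow(cluster_and_filter(two, caller_config())), 2)
  expect_equal(nrow(cluster_and_filter(two, caller_config(merge_strands = TRUE))), 1)
})

# independent oracle: transitive closure over the pairwise tolerance graph,
# then weighted lower medians computed by direct cumulative sums
brute_cluster <- function(cand, tol) {
  n <- nrow(cand)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- cand$chrom[i] == cand$chrom[j] &&
      cand$strand[i] == cand$strand[j] &&
      abs(cand$start[i] - cand$start[j]) <= tol &&
      abs(cand$end[i] - cand$end[j]) <= tol
  }
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% (reach * 1) > 0)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1
    comp[which(reach[i, ])] <- cid
  }
  wmed <- function(x, w) {
    o <- order(x)
    x[o][which(cumsum(w[o]) >= sum(w) / 2)[1]]
  }
  rows <- lapply(split(seq_len(n), comp), function(m) data.frame(
    chrom = cand$chrom[m[1]],
    start = wmed(cand$start[m], cand$support[m]),
    end = wmed(cand$end[m], cand$support[m]),
    strand = cand$strand[m[1]], support = sum(cand$support[m]),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$end, out$strand), ]
}

random_candidates <- function(n) {
  centers_s <- sample(seq(1000, 5000, by = 40), 6)
  s <- sample(centers_s, n, replace = TRUE) + sample(-4:4, n, replace = TRUE)
  e <- s + sample(c(200L, 205L, 900L), n, replace = TRUE) +
    sample(-4:4, n, replace = TRUE)
  mk_calls(sample(c("chr1", "chr2"), n, replace = TRUE), as.integer(s),
           as.integer(e), sample(c("+", "-"), n, replace = TRUE), 1L)
}

test_that("single-linkage clustering equals brute-force transitive closure", {
  set.seed(202)
  for (rep in 1:10) {
    cand <- random_candidates(sample(5:50, 1))
    cfg <- caller_config(min_support = 1, cluster_tolerance_bp = 5,
                         min_length = 1, max_length = 10000)
    got <- cluster_and_filter(cand, cfg)
    want <- brute_cluster(cand, 5)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$support, want$support)
  }
})

test_that("clustering is idempotent, permutation invariant, and support conserving", {
  set.seed(303)
  cfg <- caller_config()
  cfg_nofilter <- caller_config(min_support = 1, min_length = 1,
                                max_length = 10000)
  for (rep in 1:10) {
    cand <- random_candidates(sample(10:60, 1))
    out <- cluster_and_filter(cand, cfg)
    expect_equal(cluster_and_filter(out, cfg), out)
    shuf <- cand[sample(nrow(cand)), ]
    expect_equal(cluster_and_filter(shuf, cfg), out)
    expect_lte(sum(out$support), nrow(cand))
    # no filtering -> support exactly conserved
    expect_equal(sum(cluster_and_filter(cand, cfg_nofilter)$support), nrow(cand))
  }
})

test_that("jitter beyond the tolerance splits a fragment into unsupported singletons", {
  f <- write_junction_lines(c(
    junction_row("chr1", 1500, "+", "chr1", 1200, "+", 0, "r1"),
    junction_row("chr1", 1512, "+", "chr1", 1212, "+", 0, "r2")
  ))
  calls <- call_circles(read_chimeric_junctions(f), caller_config())
  expect_equal(nrow(calls), 0)
  # within tolerance the same two reads support one call
  f2 <- write_junction_lines(c(
    junction_row("chr1", 1500, "+", "chr1", 1200, "+", 0, "r1"),
    junction_row("chr1", 1504, "+", "chr1", 1204, "+", 0, "r2")
  ))
  expect_equal(call_circles(read_chimeric_junctions(f2), caller_config())$support, 2L)
})
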