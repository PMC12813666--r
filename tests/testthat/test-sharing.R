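test_that("presence matrix is built from gene-assigned calls only", {
  samples <- mk_samples(c("P1", "P2"), "BM", "diagnosis")
  ann <- data.frame(
    sample_id = c("P1_dia_BM", "P1_dia_BM", "P2_dia_BM", "P2_dia_BM"),
    gene_name = c("A", "B", "B", NA),
    stringsAsFactors = FALSE
  )
  pm <- build_presence_matrix(ann, samples)
  expect_equal(rownames(pm$detected), c("A", "B"))
  expect_equal(unname(pm$detected["A", ]), c(1L, 0L))
  expect_equal(unname(pm$detected["B", ]), c(1L, 1L))

  # a sample with only intergenic calls keeps an all-zero column
  ann2 <- data.frame(sample_id = c("P1_dia_BM", "P2_dia_BM"),
                     gene_name = c("A", NA), stringsAsFactors = FALSE)
  pm2 <- build_presence_matrix(ann2, samples)
  expect_equal(rownames(pm2$detected), "A")
  expect_equal(unname(pm2$detected["A", "P2_dia_BM"]), 0L)
})

test_that("stage sharing counts distinct patients, not samples", {
  # P1 detected in two tissues at diagnosis: still one individual
  samples <- rbind(mk_samples(c("P1", "P2"), "BM", "diagnosis"),
                   mk_samples(c("P1", "P2"), "plasma", "diagnosis"))
  m <- matrix(0L, 1, 4, dimnames = list("G1", samples$sample_id))
  m["G1", c("P1_dia_BM", "P1_dia_plasma")] <- 1L
  pm <- mk_pm(m, samples)
  expect_equal(stage_shared_set(pm, "diagnosis", k = 2), character(0))
  m["G1", "P2_dia_BM"] <- 1L
  pm <- mk_pm(m, samples)
  expect_equal(stage_shared_set(pm, "diagnosis", k = 2), "G1")
  # boundary: exactly k patients
  expect_equal(unname(patient_detection_counts(pm, "diagnosis")), 2L)
  # fewer than k patients in stratum -> empty with warning
  expect_warning(
    out <- stage_shared_set(pm_subset(pm, tissue = "BM"), "diagnosis",
                            tissue = "BM", k = 5),
    "fewer than")
  expect_equal(out, character(0))
})

test_that("venn partition performs exact set algebra", {
  expect_equal(unname(venn_partition(c(1, 2), c(2, 3), c())),
               c(1L, 1L, 0L, 1L, 0L, 0L, 0L))
  expect_equal(unname(venn_partition("x", "x", "x")),
               c(0L, 0L, 0L, 0L, 0L, 0L, 1L))
  set.seed(17)
  for (rep in 1:5) {
    u <- sprintf("g%03d", 1:500)
    a <- sample(u, 200); b <- sample(u, 150); c <- sample(u, 100)
    got <- venn_partition(a, b, c)
    want <- integer(7)
    for (g in union(union(a, b), c)) {
      key <- c(g %in% a, g %in% b, g %in% c)
      i <- which(apply(rbind(
        c(T, F, F), c(F, T, F), c(F, F, T),
        c(T, T, F), c(T, F, T), c(F, T, T), c(T, T, T)
      ), 1, identical, key))
      want[i] <- want[i] + 1L
    }
    expect_equal(unname(got), want)
    expect_equal(sum(got), length(union(union(a, b), c)))
    # relabeling genes leaves counts unchanged
    relab <- setNames(sample(u), u)
    expect_equal(unname(venn_partition(relab[a], relab[b], relab[c])), want)
  }
})

test_that("binomial sharing probability matches pmf summation and known values", {
  expect_equal(binomial_sharing_probability(1, 0.05, 2), 0)
  expect_equal(round(binomial_sharing_probability(25, 0.05, 2), 5), 0.35762)
  expect_equal(round(binomial_sharing_probability(9, 0.05, 2), 5), 0.07121)
  # closed form for k = 2
  p <- 0.05; n <- 25
  expect_equal(binomial_sharing_probability(n, p, 2),
               1 - (1 - p)^n - n * p * (1 - p)^(n - 1))
  # monotone in n and in p
  expect_true(all(diff(binomial_sharing_probability(1:60, 0.05, 2)) >= 0))
  expect_true(all(diff(vapply(seq(0.01, 0.5, 0.01), function(pp)
    binomial_sharing_probability(20, pp, 2), 0)) >= 0))
})

test_that("the 7 region probabilities plus the empty region sum to one", {
  set.seed(13)
  for (rep in 1:10) {
    spec <- binomial_null_spec(
      p = runif(1, 0.01, 0.4),
      group_sizes = c(diagnosis = sample(2:40, 1), relapse = sample(2:40, 1),
                      remission = sample(2:40, 1)),
      k = sample(1:3, 1), gene_universe = 1000
    )
    ef <- expected_region_frequencies(spec)
    expect_equal(sum(ef$probability) + attr(ef, "p_none"), 1)
    expect_equal(sum(ef$frequency), 1)  # conditional mode renormalizes
    abs_mode <- expected_region_frequencies(spec, "absolute")
    expect_equal(abs_mode$frequency, ef$probability * spec$gene_universe)
  }
  # symmetric case: q = 0.5 each -> all 8 outcomes at 1/8, conditional 1/7
  spec5 <- binomial_null_spec(p = 0.5, group_sizes = c(diagnosis = 1L,
                                                       relapse = 1L,
                                                       remission = 1L), k = 1)
  ef5 <- expected_region_frequencies(spec5)
  expect_equal(ef5$probability, rep(0.125, 7))
  expect_equal(ef5$frequency, rep(1 / 7, 7))
})

test_that("observed-vs-expected chi-squared handles rescaling and merging", {
  eq <- observed_vs_expected_chisq(c(5, 5, 5, 5, 5, 5, 5), rep(10, 7))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)

  conc <- observed_vs_expected_chisq(c(10, 0, 0, 0, 0, 0, 0), rep(10 / 7, 7))
  expect_equal(conc$statistic, 60)
  expect_equal(conc$df, 6)

  # a region with rescaled expectation below 1 merges into the smallest other
  expect_message(
    merged <- observed_vs_expected_chisq(c(10, 10, 1), c(50, 50, 0.5)),
    "merging")
  expect_equal(merged$df, 1)
  expect_equal(sum(merged$observed), 21)

  expect_error(observed_vs_expected_chisq(c(0, 0), c(1, 1)), "all-zero")
})

test_that("sharing summary regions align with the expected-frequency order", {
  samples <- rbind(mk_samples(paste0("D", 1:3), "BM", "diagnosis"),
                   mk_samples(paste0("R", 1:3), "BM", "relapse"),
                   mk_samples(paste0("E", 1:3), "BM", "remission"))
  m <- matrix(0L, 3, 9, dimnames = list(c("G1", "G2", "G3"), samples$sample_id))
  m["G1", 1:2] <- 1L                  # diagnosis only
  m["G2", c(1, 2, 4, 5)] <- 1L        # diagnosis + relapse
  m["G3", c(1, 2, 4, 5, 7, 8)] <- 1L  # all three
  pm <- mk_pm(m, samples)
  ss <- sharing_summary(pm, k = 2)
  expect_equal(unname(ss$regions),
               c(1L, 0L, 0L, 1L, 0L, 0L, 1L))
  spec <- binomial_null_spec()
  expect_equal(expected_region_frequencies(spec)$region[c(1, 4, 7)],
               c("diagnosis_only", "diagnosis_relapse",
                 "diagnosis_relapse_remission"))
})
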