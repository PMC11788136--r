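# Repertoire statistics against closed forms and brute-force oracles.

test_that("inverse Simpson hits its closed forms and bounds", {
  expect_equal(inverse_simpson(rep(1, 10)), 10)
  expect_equal(inverse_simpson(5), 1)
  expect_equal(inverse_simpson(c(2, 1, 1)), 8 / 3)
  expect_error(inverse_simpson(integer(0)))
  set.seed(31)
  for (i in 1:50) {
    counts <- sample(1:50, sample(1:30, 1), replace = TRUE)
    d <- inverse_simpson(counts)
    expect_gte(d, 1 - 1e-12)
    expect_lte(d, length(counts) + 1e-12)
  }
})

test_that("analytic rarefaction matches exhaustive enumeration at small N", {
  set.seed(32)
  for (i in 1:15) {
    counts <- sample(1:5, sample(2:4, 1), replace = TRUE)
    while (sum(counts) > 12) counts <- counts[-1]
    if (length(counts) < 2) next
    N <- sum(counts)
    for (d in unique(c(1L, sample(1:N, 2, replace = TRUE)))) {
      expect_equal(rarefaction(counts, d), rarefaction_oracle(counts, d),
                   tolerance = 1e-10)
    }
  }
  # closed-form identities
  counts <- c(5, 3, 2)
  expect_equal(rarefaction(counts, 1), 1)
  expect_equal(rarefaction(counts, sum(counts)), 3)
  expect_equal(rarefaction(counts, 4), rarefaction_oracle(counts, 4),
               tolerance = 1e-10)
  expect_error(rarefaction(counts, 11), "depth")
  # monotone in depth
  set.seed(33)
  counts <- sample(1:100, 40, replace = TRUE)
  vals <- rarefaction(counts, seq(1, sum(counts), length.out = 20))
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("top, rare and clonal proportions match direct computation", {
  expect_equal(top_proportion(rep(10, 10), 10), 1)
  expect_equal(top_proportion(c(90, 5, 5), 1), 0.9)
  set.seed(34)
  for (i in 1:30) {
    counts <- sample(1:1000, sample(5:50, 1), replace = TRUE)
    k <- sample(1:15, 1)
    expect_equal(top_proportion(counts, k),
                 sum(sort(counts, decreasing = TRUE)[seq_len(min(k,
                     length(counts)))]) / sum(counts))
    rp <- rare_proportion(counts)
    expect_equal(sum(rp), 1, tolerance = 1e-9)
    # direct binning oracle
    edges <- c(1, 3, 10, 30, 100, 1000)
    direct <- vapply(seq_along(edges), function(b) {
      lo <- if (b == 1) 1 else edges[b - 1] + 1
      sum(counts[counts >= lo & counts <= edges[b]])
    }, numeric(1))
    direct <- c(direct, sum(counts[counts > 1000])) / sum(counts)
    expect_equal(unname(rp), direct, tolerance = 1e-12)
  }
  expect_equal(unname(rare_proportion(c(25, 500))[c(4, 6)]),
               c(25 / 525, 500 / 525))
  expect_equal(unname(rare_proportion(c(1, 1, 1))[1]), 1)
})

test_that("clonal_proportion counts the minimal covering clone set", {
  expect_equal(clonal_proportion(c(50, 30, 20), 0.31), 1L)
  expect_equal(clonal_proportion(rep(10, 10), 0.31), 4L)
  expect_equal(clonal_proportion(c(5, 4, 1), 1.0), 3L)
  set.seed(35)
  for (i in 1:30) {
    counts <- sample(1:500, sample(3:40, 1), replace = TRUE)
    q <- runif(1, 0.05, 1)
    m <- clonal_proportion(counts, q)
    s <- sort(counts, decreasing = TRUE)
    expect_gte(sum(s[seq_len(m)]), q * sum(counts) - 1e-6)
    if (m > 1) expect_lt(sum(s[seq_len(m - 1)]), q * sum(counts))
  }
  # more concentration never needs more clonotypes
  counts <- c(10, 10, 10, 10)
  bumped <- c(25, 10, 10, 10)
  expect_lte(clonal_proportion(bumped, 0.31), clonal_proportion(counts, 0.31))
})

make_sample <- function(aa, counts = rep(1, length(aa)), id = "s") {
  structure(list(sample_id = id,
                 clonotypes = data.frame(
                   cdr3_nt = vapply(aa, function(a)
                     paste(rep("TGT", nchar(a)), collapse = ""), character(1)),
                   cdr3_aa = aa, count = counts,
                   v_gene = "IgHV1-1", d_gene = "", j_gene = "IgHJ1-1",
                   stringsAsFactors = FALSE),
                 total_reads = sum(counts), aligned_reads = sum(counts)),
            class = "repertoire_sample")
}

test_that("overlap is a symmetric set intersection with bounds", {
  a <- make_sample(c("CARW", "CDRW", "CERW"))
  b <- make_sample(c("CDRW", "CERW", "CFRW", "CGRW"))
  expect_equal(overlap(a, b), 2L)
  expect_equal(overlap(b, a), 2L)
  expect_equal(overlap(a, a), 3L)
  disjoint <- make_sample(c("CXXW"))
  expect_equal(overlap(a, disjoint), 0L)
  expect_lte(overlap(a, b), min(nrow(a$clonotypes), nrow(b$clonotypes)))
  set.seed(36)
  keys <- replicate(40, paste(sample(LETTERS, 6), collapse = ""))
  sa <- make_sample(sample(keys, 25))
  sb <- make_sample(sample(keys, 25))
  expect_equal(overlap(sa, sb),
               length(intersect(sa$clonotypes$cdr3_aa, sb$clonotypes$cdr3_aa)))
})

test_that("shared_across returns the full intersection and Venn regions", {
  s1 <- make_sample(c("AAA", "BBB", "CCC"))
  s2 <- make_sample(c("BBB", "CCC", "DDD"))
  s3 <- make_sample(c("CCC", "EEE"))
  res <- shared_across(list(a = s1, b = s2, c = s3))
  expect_equal(res$shared, "CCC")
  expect_equal(unname(res$regions[["a&b&c"]]), 1L)
  expect_equal(sum(res$regions), 5L)  # AAA BBB CCC DDD EEE
  # identical samples share everything
  res2 <- shared_across(list(s1, s1, s1))
  expect_setequal(res2$shared, c("AAA", "BBB", "CCC"))
  # planted common keys across five samples
  set.seed(37)
  common <- replicate(40, paste(sample(letters, 8), collapse = ""))
  samples <- lapply(1:5, function(i)
    make_sample(c(common, replicate(30, paste(sample(LETTERS, 8),
                                              collapse = "")))))
  expect_setequal(shared_across(samples)$shared, common)
})

test_that("length distribution reports the histogram and ultra-long count", {
  s <- make_sample(strrep("C", 25))
  ld <- length_distribution(s)
  expect_equal(ld$histogram, c("25" = 1L))
  s2 <- make_sample(vapply(c(51, 55, 70, 30), strrep, character(1), x = "C"))
  ld2 <- length_distribution(s2, ultra_threshold = 50)
  expect_equal(ld2$ultra_long, 3L)
  expect_equal(ld2$max_length, 70L)
})

test_that("gene usage frequencies sum to one with a D-unassigned class", {
  cl <- data.frame(cdr3_nt = "TGT", cdr3_aa = "C", count = 1,
                   v_gene = c("Va", "Va", "Vb"),
                   d_gene = c("D1", "", ""),
                   j_gene = c("J1", "J1", "J2"), stringsAsFactors = FALSE)
  vu <- gene_usage(cl, "V")
  expect_equal(unname(vu[c("Va", "Vb")]), c(2 / 3, 1 / 3))
  du <- gene_usage(cl, "D")
  expect_equal(unname(du[["(none)"]]), 2 / 3)
  expect_equal(sum(vu), 1)
  expect_equal(sum(du), 1)
})

test_that("sample summary reproduces printed-precision percentages", {
  out <- summarize_sample(total_reads = 8046744, aligned_reads = 1832517,
                          clonotype_count = 44716, unique_clones = 14464)
  expect_equal(out$aligned_pct, 22.77)
  expect_equal(out$unique_over_total_pct, 32.3)
  degenerate <- summarize_sample(total_reads = 100, aligned_reads = 100,
                                 clonotype_count = 50, unique_clones = 50)
  expect_equal(degenerate$aligned_pct, 100)
  expect_equal(degenerate$unique_over_total_pct, 100)
  expect_error(summarize_sample(total_reads = 1, aligned_reads = 0,
                                clonotype_count = 0, unique_clones = 0))
})
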