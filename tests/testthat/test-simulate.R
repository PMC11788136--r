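# The synthetic-data generator: determinism, truth bookkeeping, planted
# composition.

test_that("locus generation is deterministic and honours its settings", {
  spec <- locus_spec(n_v = 6L, n_d = 3L, n_j = 3L, n_c = 2L,
                     pseudogene_fraction = 0, orf_fraction = 0,
                     reversed_v_fraction = 0, seed = 61L)
  a <- generate_locus(spec)
  b <- generate_locus(spec)
  expect_identical(a$genome, b$genome)
  expect_identical(a$genes, b$genes)
  tab <- table(a$genes$segment_type)
  expect_equal(as.integer(tab[c("V", "D", "J", "C")]), c(6L, 3L, 3L, 2L))
  # zero pseudogene fraction: D and V all functional
  expect_true(all(a$genes$functionality[a$genes$segment_type
                                        %in% c("V", "D")] == "F"))
})

test_that("planted defect mix covers the defect codes at the set fractions", {
  loc <- fixture_locus()
  v <- loc$genes[loc$genes$segment_type == "V", ]
  expect_equal(sum(v$functionality == "P"), round(0.4 * nrow(v)))
  planted_codes <- unique(unlist(strsplit(v$defects[v$defects != ""], ",")))
  expect_true(all(c("STOP_CODON", "MISSING_C23", "NO_INIT_CODON") %in%
                    planted_codes))
  # reversed fraction shows up as minus-strand V genes
  expect_gt(sum(v$strand == "-"), 0)
  # P genes always carry a defect, F genes never
  expect_true(all(v$defects[v$functionality == "P"] != ""))
  expect_true(all(v$defects[v$functionality == "F"] == ""))
})

test_that("repertoire simulation is deterministic given the seed", {
  ref <- fixture_reference()
  spec <- repertoire_spec(ref, n_reads = 200L, n_clonotypes = 50L, seed = 62L)
  a <- simulate_repertoire(spec)
  b <- simulate_repertoire(spec)
  expect_identical(a$reads, b$reads)
  expect_identical(a$clonotypes, b$clonotypes)
})

test_that("the noise-free limit reproduces germline junctions exactly", {
  ref <- fixture_reference()
  spec <- repertoire_spec(ref, n_reads = 100L, n_clonotypes = 30L,
                          trim_p = 1 - 1e-9, ins_lambda = 0, d_prob = 0,
                          mutation_rate = 0, seed = 63L)
  sim <- simulate_repertoire(spec)
  expect_true(all(sim$clonotypes$v_del == 0))
  expect_true(all(sim$clonotypes$j_del == 0))
  expect_true(all(sim$clonotypes$n_ins == 0))
  # junction equals the germline anchor-to-anchor concatenation
  for (i in seq_len(nrow(sim$clonotypes))) {
    row <- sim$clonotypes[i, ]
    v <- ref$v[ref$v$name == row$v_gene, ]
    j <- ref$j[ref$j$name == row$j_gene, ]
    germ <- paste0(substr(v$nt_sequence, v$anchor_nt + 1L,
                          nchar(v$nt_sequence)),
                   substr(j$nt_sequence, 1L, j$anchor_nt + 3L))
    expect_equal(row$cdr3_nt, germ)
  }
})

test_that("planted usage bias is realised within binomial error", {
  ref <- fixture_reference()
  v_names <- ref$v$name[ref$v$productive]
  w <- setNames(rep(0.6 / (length(v_names) - 1), length(v_names)), v_names)
  w[v_names[1]] <- 0.4
  spec <- repertoire_spec(ref, n_reads = 4000L, n_clonotypes = 400L,
                          v_usage = w, seed = 64L)
  sim <- simulate_repertoire(spec)
  freq <- sum(sim$read_truth$v_gene == v_names[1]) / nrow(sim$read_truth)
  # clonotype-level sampling inflates the read-level variance; bound via the
  # clonotype draw instead
  cl_freq <- mean(tapply(sim$read_truth$v_gene,
                         sim$read_truth$clonotype_id, `[`, 1) == v_names[1])
  expect_lt(abs(cl_freq - 0.4), 3 * sqrt(0.4 * 0.6 / 400) + 0.05)
  expect_gt(freq, 0.1)
})

test_that("amplicon windowing keeps reads within the gel band", {
  ref <- fixture_reference()
  sim <- simulate_repertoire(repertoire_spec(ref, n_reads = 200L,
                                             n_clonotypes = 50L, seed = 65L))
  lens <- nchar(sim$reads)
  expect_true(all(lens <= 300L))
  # reads shorter than the window floor only when the rearrangement itself is
  expect_gt(mean(lens >= 200L), 0.95)
})

test_that("the ultra-long preset produces productive CDR3s beyond 50 aa", {
  ref <- fixture_reference()
  sim <- simulate_repertoire(repertoire_spec(ref, n_reads = 300L,
                                             n_clonotypes = 60L,
                                             ultralong_fraction = 0.5,
                                             amplicon = c(250L, 350L),
                                             seed = 66L))
  lens <- nchar(sim$clonotypes$cdr3_aa[sim$clonotypes$productive])
  expect_gt(sum(lens > 50), 0)
})
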