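# Candidate detection: V by seed similarity, D by dual 12-RSS geometry,
# J by 5' RSS, C by exon chaining; end-to-end recovery on a planted locus.

tpl <- ig_templates("IGH")

test_that("a verbatim planted seed is recovered with identity 1 on + and -", {
  set.seed(51)
  seed <- tpl$v_seeds[["fam1"]]
  genome <- c(ctg = paste0(igloci:::clean_random_dna(300), seed,
                           igloci:::clean_random_dna(300)))
  cand <- find_v_candidates(genome, tpl$v_seeds["fam1"])
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$identity, 1.0)
  expect_equal(cand$start, 300L)
  expect_equal(cand$end, 300L + nchar(seed))
  expect_equal(cand$strand, "+")
  # minus strand planting yields the reading-sense sequence
  genome2 <- c(ctg = paste0(igloci:::clean_random_dna(300), revcomp(seed),
                            igloci:::clean_random_dna(300)))
  cand2 <- find_v_candidates(genome2, tpl$v_seeds["fam1"])
  expect_equal(cand2$strand, "-")
  expect_equal(cand2$exon_seq, seed)
})

test_that("divergence beyond the identity threshold is not recovered", {
  set.seed(52)
  seed <- tpl$v_seeds[["fam1"]]
  mut10 <- igloci:::mutate_coding(seed, 0.10)
  mut30 <- igloci:::mutate_coding(seed, 0.35)
  expect_gte(igloci:::hamming_identity(seed, mut10), 0.75)
  expect_lt(igloci:::hamming_identity(seed, mut30), 0.75)
  genome <- c(ctg = paste0(igloci:::clean_random_dna(200), mut10,
                           igloci:::clean_random_dna(200), mut30,
                           igloci:::clean_random_dna(200)))
  cand <- find_v_candidates(genome, tpl$v_seeds["fam1"])
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 200L)
})

test_that("D candidates require both 12-RSS flanks and a G-rich core", {
  set.seed(53)
  core <- "GGTATAGGGGGTGGTTC"
  left <- paste0("ACAAAAACC", strrep("T", 12), "CACAGTG")
  right <- paste0("CACAGTG", strrep("T", 12), "ACAAAAACC")
  genome <- c(ctg = paste0(igloci:::clean_random_dna(150), left, core, right,
                           igloci:::clean_random_dna(150)))
  ds <- find_d_candidates(genome)
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$nt_sequence, core)
  expect_equal(ds$start, 150L + nchar(left))
  # A-rich core below the G threshold is not reported
  genome2 <- c(ctg = paste0(igloci:::clean_random_dna(150), left,
                            "AATATAAAATATAATTC", right,
                            igloci:::clean_random_dna(150)))
  expect_equal(nrow(find_d_candidates(genome2)), 0L)
  # a decoy missing its downstream RSS is not reported
  genome3 <- c(ctg = paste0(igloci:::clean_random_dna(150), left, core,
                            igloci:::clean_random_dna(150)))
  expect_equal(nrow(find_d_candidates(genome3)), 0L)
})

test_that("J candidates report motif and donor flags without requiring them", {
  set.seed(54)
  jseq <- tpl$j_nt
  rss <- paste0("ACAAAAACC", strrep("T", 23), "CACAGTG")
  genome <- c(ctg = paste0(igloci:::clean_random_dna(150), rss, jseq, "GT",
                           igloci:::clean_random_dna(150)))
  js <- find_j_candidates(genome, "IGH")
  expect_equal(nrow(js), 1L)
  expect_true(js$motif_ok)
  expect_true(js$donor_ok)
  expect_true(js$rss_ok)
  expect_equal(js$start, 150L + nchar(rss))
  # tryptophan-free J is still detected, motif flag false
  no_w <- igloci:::set_codon(jseq, 8L, "TCG")
  genome2 <- c(ctg = paste0(igloci:::clean_random_dna(150), rss, no_w, "GT",
                            igloci:::clean_random_dna(150)))
  js2 <- find_j_candidates(genome2, "IGH")
  expect_equal(nrow(js2), 1L)
  expect_false(js2$motif_ok)
})

test_that("C exon chains assemble per gene and are not merged across genes", {
  set.seed(55)
  exons <- vapply(1:4, function(k) tpl$c_exons[[k]], character(1))
  intron <- function() paste0("GT", igloci:::clean_random_dna(100), "AG")
  gene4 <- paste0(exons[1], intron(), exons[2], intron(), exons[3], intron(),
                  exons[4])
  gene1 <- exons[1]
  genome <- c(ctg = paste0(igloci:::clean_random_dna(200), gene4,
                           paste(replicate(12, igloci:::clean_random_dna(450)),
                                 collapse = ""),
                           gene1, igloci:::clean_random_dna(200)))
  seeds <- setNames(exons, paste0("Cex", 1:4))
  cc <- find_c_candidates(genome, seeds)
  expect_equal(nrow(cc$genes), 2L)
  expect_equal(cc$genes$n_exons, c(4L, 1L))
  expect_true(all(cc$genes$splice_ok))
})

test_that("annotation recovers a planted locus exactly, including strand", {
  loc <- fixture_locus()
  ann <- fixture_annotation()
  key <- function(d) paste(d$segment_type, d$start, d$end, d$strand,
                           d$functionality, d$defects, d$name)
  expect_setequal(key(ann$genes), key(loc$genes))
  # every planted defect class is recovered (diagonal confusion matrix)
  tr <- loc$genes[order(loc$genes$start), ]
  an <- ann$genes[order(ann$genes$start), ]
  expect_equal(an$functionality, tr$functionality)
  expect_equal(an$defects, tr$defects)
  expect_equal(an$family, tr$family)
  # some minus-strand V genes were planted and recovered
  expect_gt(sum(an$strand == "-"), 0)
})

test_that("planted gene intervals slice back to the planted sequences", {
  loc <- fixture_locus()
  g <- loc$genes[loc$genes$segment_type %in% c("V", "D", "J"), ]
  for (i in seq_len(nrow(g))) {
    s <- substr(loc$genome[[g$contig[i]]], g$start[i] + 1L, g$end[i])
    if (g$strand[i] == "-") s <- revcomp(s)
    expect_equal(s, g$nt_sequence[i])
  }
})

test_that("RSS spacer classes follow the chain/segment table", {
  expect_equal(expected_rss("IGH", "V")$class, 23L)
  expect_equal(expected_rss("IGH", "D")$class, c(12L, 12L))
  expect_equal(expected_rss("IGH", "J")$class, 23L)
  expect_equal(expected_rss("IGK", "V")$class, 12L)
  expect_equal(expected_rss("IGK", "J")$class, 23L)
  expect_equal(expected_rss("IGL", "V")$class, 23L)
  expect_equal(expected_rss("IGL", "J")$class, 12L)
})
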