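# F/ORF/P classification rules, numbering, families and naming.

tpl <- ig_templates("IGH")

test_that("template numbering is the identity with C/W/L/C anchors", {
  nv <- number_v(translate_nt(tpl$v_nt), "IGH")
  expect_equal(nv$status, "ok")
  expect_equal(nv$map, 1:104)
  expect_equal(residue_at(nv, 23), "C")
  expect_equal(residue_at(nv, 41), "W")
  expect_equal(residue_at(nv, 89), "L")
  expect_equal(residue_at(nv, 104), "C")
})

test_that("numbering absorbs CDR indels and tracks substitutions", {
  aa <- tpl$v_aa
  # CDR1 lengthened by 2: FR anchors unchanged
  aa_ins <- paste0(substr(aa, 1, 32), "GG", substr(aa, 33, nchar(aa)))
  nv <- number_v(aa_ins, "IGH")
  expect_equal(residue_at(nv, 23), "C")
  expect_equal(residue_at(nv, 41), "W")
  expect_equal(residue_at(nv, 104), "C")
  expect_equal(nv$map[104], 106L)
  # C104 -> R substitution is visible at position 104
  aa_sub <- paste0(substr(aa, 1, 103), "R", substr(aa, 105, nchar(aa)))
  expect_equal(residue_at(number_v(aa_sub, "IGH"), 104), "R")
  # too-short sequences are unalignable
  expect_equal(number_v(substr(aa, 1, 80), "IGH")$status, "unalignable")
})

intact_candidate <- function(exon = tpl$v_nt) {
  list(exon_seq = exon, chain = "IGH", init_ok = TRUE, donor_ok = TRUE,
       acceptor_ok = TRUE, rss_ok = TRUE)
}

test_that("V classification applies the P > ORF > F precedence", {
  res <- classify_v(intact_candidate())
  expect_equal(res$functionality, "F")
  expect_length(res$defects, 0)

  stopped <- intact_candidate(igloci:::set_codon(tpl$v_nt, 50L, "TGA"))
  res <- classify_v(stopped)
  expect_equal(res$functionality, "P")
  expect_equal(res$defects, "STOP_CODON")

  no_rss <- intact_candidate()
  no_rss$rss_ok <- FALSE
  res <- classify_v(no_rss)
  expect_equal(res$functionality, "ORF")
  expect_equal(res$defects, "NO_RSS")

  # structural defects dominate signal defects
  both <- intact_candidate(igloci:::set_codon(tpl$v_nt, 23L, "CGT"))
  both$rss_ok <- FALSE
  res <- classify_v(both)
  expect_equal(res$functionality, "P")
  expect_true("MISSING_C23" %in% res$defects)

  no_init <- intact_candidate()
  no_init$init_ok <- FALSE
  expect_equal(classify_v(no_init)$defects, "NO_INIT_CODON")

  no_acc <- intact_candidate()
  no_acc$acceptor_ok <- FALSE
  expect_equal(classify_v(no_acc)$functionality, "P")
})

test_that("missing anchor residues are each detected as defects", {
  cases <- list(c(23L, "CGT", "MISSING_C23"), c(41L, "CGG", "MISSING_W41"),
                c(104L, "AGT", "MISSING_C104"))
  for (cs in cases) {
    cand <- intact_candidate(igloci:::set_codon(tpl$v_nt, as.integer(cs[1]),
                                                cs[2]))
    res <- classify_v(cand)
    expect_equal(res$functionality, "P")
    expect_equal(res$defects, cs[3])
  }
  # L89 loss is a warning, not a defect
  l89 <- intact_candidate(igloci:::set_codon(tpl$v_nt, 89L, "GTT"))
  res <- classify_v(l89)
  expect_equal(res$functionality, "F")
  expect_true(res$l89_warning)
})

test_that("J classification follows donor/motif/heptamer rules", {
  f <- classify_j(list(donor_ok = TRUE, motif_ok = TRUE, rss_ok = TRUE))
  expect_equal(f$functionality, "F")
  orf <- classify_j(list(donor_ok = TRUE, motif_ok = FALSE, rss_ok = TRUE))
  expect_equal(orf$functionality, "ORF")
  expect_equal(orf$defects, "NO_WGXG")
  orf2 <- classify_j(list(donor_ok = TRUE, motif_ok = TRUE, rss_ok = FALSE))
  expect_equal(orf2$defects, "NO_J_HEPTAMER")
  p <- classify_j(list(donor_ok = FALSE, motif_ok = TRUE, rss_ok = TRUE))
  expect_equal(p$functionality, "P")
  expect_equal(p$defects, "NO_DONOR_SPLICE")
  # light chains report the FGXG motif code
  orf3 <- classify_j(list(donor_ok = TRUE, motif_ok = FALSE, rss_ok = TRUE),
                     chain = "IGL")
  expect_equal(orf3$defects, "NO_FGXG")
})

test_that("C classification checks spliced stops and junctions", {
  exons <- vapply(1:4, function(k) tpl$c_exons[[k]], character(1))
  expect_equal(classify_c(list(exon_seqs = exons,
                               splice_ok = TRUE))$functionality, "F")
  exons2 <- exons
  exons2[2] <- igloci:::set_codon(exons2[2], 10L, "TAA")
  res <- classify_c(list(exon_seqs = exons2, splice_ok = TRUE))
  expect_equal(res$functionality, "P")
  expect_equal(res$defects, "STOP_CODON")
  res2 <- classify_c(list(exon_seqs = exons, splice_ok = FALSE))
  expect_equal(res2$functionality, "P")
})

test_that("family clustering is single linkage at the identity threshold", {
  a <- tpl$v_seeds[["fam1"]]
  b <- tpl$v_seeds[["fam2"]]
  expect_equal(assign_families(c(a, a)), c("1", "1"))
  # two divergent seeds split at 0.75 (verified by the identity oracle)
  expect_lt(alignment_identity(a, b), 0.75)
  expect_length(unique(assign_families(c(a, b))), 2)
  # chained pairs merge: A-B and B-C above, A-C below threshold
  set.seed(41)
  mk <- function(base, rate, protect) igloci:::mutate_coding(base, rate)
  b1 <- igloci:::mutate_coding(a, 0.13)
  c1 <- igloci:::mutate_coding(b1, 0.13)
  if (alignment_identity(a, b1) >= 0.75 &&
      alignment_identity(b1, c1) >= 0.75 &&
      alignment_identity(a, c1) < 0.75) {
    fams <- assign_families(c(a, b1, c1))
    expect_length(unique(fams), 1)
  }
  # order invariance
  set.seed(42)
  seqs <- c(a, igloci:::mutate_coding(a, 0.05), b,
            igloci:::mutate_coding(b, 0.05))
  f1 <- assign_families(seqs, seeds = tpl$v_seeds)
  perm <- c(3, 1, 4, 2)
  f2 <- assign_families(seqs[perm], seeds = tpl$v_seeds,
                        starts = perm)
  expect_equal(f1[perm], f2)
})

test_that("gene naming encodes family, cluster and 5'-to-3' position", {
  starts <- c(100, 300, 500, 1000, 1100, 1200, 1300, 1400, 1500, 2000,
              2100, 2200)
  genes <- data.frame(
    segment_type = c(rep("V", 3), rep("D", 2), rep("J", 3), "C",
                     "J", "J", "C"),
    start = starts, end = starts + 50,
    family = c("1", "1", "2", rep(NA, 9)),
    stringsAsFactors = FALSE)
  named <- name_genes(genes, "IGH")
  expect_equal(named$name[named$segment_type == "V"],
               c("IgHV1-1", "IgHV1-2", "IgHV2-3"))
  expect_equal(named$name[named$segment_type == "J"],
               c("IgHJ1-1", "IgHJ1-2", "IgHJ1-3", "IgHJ2-1", "IgHJ2-2"))
  expect_equal(named$name[named$segment_type == "D"],
               c("IgHD1-1", "IgHD1-2"))
  expect_equal(named$name[named$segment_type == "C"], c("IgHC1", "IgHC2"))
  # single C gene loses its ordinal, single-cluster J loses the cluster tag
  single <- data.frame(segment_type = c("J", "C"), start = c(1, 100),
                       end = c(50, 200), family = NA,
                       stringsAsFactors = FALSE)
  named2 <- name_genes(single, "IGK")
  expect_equal(named2$name, c("IgkJ1", "IgkC"))
  dup <- data.frame(segment_type = c("V", "V"), start = c(1, 1),
                    end = c(10, 10), family = "1", stringsAsFactors = FALSE)
  expect_error(name_genes(dup, "IGH"), "duplicate")
})

test_that("classification summary totals equal F + P + ORF", {
  counts <- data.frame(segment = c("IgHV", "IglV"), F = c(19L, 31L),
                       P = c(35L, 35L), ORF = c(0L, 5L),
                       stringsAsFactors = FALSE)
  out <- functionality_summary(counts)
  expect_equal(out$Total, c(54L, 71L))
  genes <- data.frame(segment_type = c("V", "V", "J"), chain = "IGH",
                      functionality = c("F", "P", "ORF"),
                      stringsAsFactors = FALSE)
  out2 <- functionality_summary(genes)
  expect_equal(out2$Total[out2$segment == "IgHV"], 2L)
})

test_that("classification is deterministic on identical input", {
  cand <- intact_candidate(igloci:::set_codon(tpl$v_nt, 60L, "TAG"))
  r1 <- classify_v(cand)
  r2 <- classify_v(cand)
  expect_identical(r1, r2)
})
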