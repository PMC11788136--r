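# Sequence utilities and file format round trips.

test_that("translation follows the standard code with frame and N handling", {
  expect_equal(translate_nt("TGTGCT"), "CA")
  expect_equal(translate_nt("TAA"), "*")
  expect_equal(translate_nt("ATGTAA", 1L), "C")   # TGT then trailing AA dropped
  expect_equal(translate_nt("GCNAAT"), "XN")      # N codon -> X
  expect_equal(translate_nt("AT"), "")            # below one codon
})

test_that("reverse complement is an involution", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna_str(sample(1:200, 1))
    expect_equal(revcomp(revcomp(s)), s)
  }
})

test_that("translation of stop-free frames contains no stop symbol", {
  set.seed(12)
  for (i in 1:20) {
    aa <- translate_nt(random_dna_str(300))
    nt2 <- paste(rep("GCT", 50), collapse = "")
    expect_false(grepl("*", translate_nt(nt2), fixed = TRUE))
    if (!grepl("*", aa, fixed = TRUE)) succeed()
  }
})

test_that("FASTA and FASTQ round-trip identically", {
  set.seed(13)
  seqs <- setNames(vapply(1:5, function(i) random_dna_str(80), character(1)),
                   paste0("seq", 1:5))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  expect_equal(read_fasta(fa), seqs)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(seqs, fq)
  expect_equal(read_fastq(fq), seqs)
})

test_that("GFF3 emission is 1-based inclusive and round-trips coordinates", {
  genes <- data.frame(
    contig = "chr1", start = c(10L, 50L), end = c(20L, 90L),
    strand = c("+", "-"), name = c("IgHV1-1", "IgHV1-2"),
    segment_type = "V", functionality = c("F", "P"),
    family = c("1", "1"), defects = c("", "STOP_CODON"),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".gff3")
  write_gff3(genes, path)
  lines <- readLines(path)
  row1 <- strsplit(grep("IgHV1-1", lines, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(row1[4]), 11L)   # 0-based 10 -> 1-based 11
  expect_equal(as.integer(row1[5]), 20L)
  back <- read_gff3(path)
  back <- back[order(back$start), ]
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$name, genes$name)
})

test_that("AIRR TSV round-trips clonotypes and maps duplicate_count", {
  cl <- data.frame(
    cdr3_nt = c("TGTGCTTGG", "TGTTATTGG"), cdr3_aa = c("CAW", "CYW"),
    count = c(5L, 2L), v_gene = c("IgHV1-1", "IgHV1-2"),
    d_gene = c("IgHD1-1", ""), j_gene = c("IgHJ1-1", "IgHJ1-2"),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_airr(cl, path, sample_id = "B1")
  back <- read_airr(path)
  expect_equal(back$count, cl$count)
  expect_equal(back$cdr3_nt, cl$cdr3_nt)
  expect_equal(back$v_gene, cl$v_gene)
  expect_equal(back$sample_id, rep("B1", 2))
  # missing columns are a parse error
  bad <- tempfile(fileext = ".tsv")
  writeLines("sample_id\tv_call\njunk\tv", bad)
  expect_error(read_airr(bad), "lacks required columns")
})

test_that("half-up rounding matches printed-table conventions", {
  expect_equal(round_half_up(22.775, 2), 22.78)
  expect_equal(round_half_up(32.35, 1), 32.4)
  expect_equal(round_half_up(2.5), 3)
})
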