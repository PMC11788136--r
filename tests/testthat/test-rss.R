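# RSS scanning against the heptamer/nonamer consensus and the 12/23 rule.

test_that("an exact consensus signal is found with full match counts", {
  set.seed(21)
  for (cls in c(12L, 23L)) {
    sig <- paste0("CACAGTG", random_dna_str(cls), "ACAAAAACC")
    seq <- paste0("TTCTTCTTAA", sig, "TTCTTCAATT")
    hits <- scan_rss(seq, cls, "V-side")
    exact <- hits[hits$spacer_length == cls, ]
    expect_equal(nrow(exact), 1L)
    expect_equal(exact$heptamer_matches, 7L)
    expect_equal(exact$nonamer_matches, 9L)
    expect_equal(exact$start, 10L)
  }
})

test_that("spacer lengths of class +/- 1 are accepted, +/- 2 rejected", {
  for (s in 20:26) {
    seq <- paste0("TTCTTCTTAA", "CACAGTG", strrep("T", s), "ACAAAAACC",
                  "TTCTTCTTAA")
    hits <- scan_rss(seq, 23L, "V-side")
    hits <- hits[hits$spacer_length == s, ]
    if (s >= 22 && s <= 24) {
      expect_equal(nrow(hits), 1L, info = paste("spacer", s))
    } else {
      expect_equal(nrow(hits), 0L, info = paste("spacer", s))
    }
  }
})

test_that("J-side orientation mirrors the signal arrangement", {
  seq <- paste0("GGCTTCTTCT", "ACAAAAACC", strrep("T", 23), "CACAGTG",
                "TTCTTCTTGG")
  hits <- scan_rss(seq, 23L, "J-side")
  hits <- hits[hits$spacer_length == 23L, ]
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 10L)
  # and nothing in V-side orientation
  expect_equal(nrow(scan_rss(seq, 23L, "V-side")), 0L)
})

test_that("scan_rss equals the exhaustive sliding-window oracle", {
  set.seed(22)
  for (i in 1:40) {
    seq <- random_dna_str(500)
    for (cls in c(12L, 23L)) {
      for (ori in c("V-side", "J-side")) {
        expect_equal(scan_rss(seq, cls, ori),
                     rss_oracle(seq, cls, ori),
                     ignore_attr = TRUE)
      }
    }
  }
  # relaxed thresholds too
  cfg <- rss_config_relaxed()
  for (i in 1:10) {
    seq <- random_dna_str(400)
    expect_equal(scan_rss(seq, 12L, "V-side", cfg),
                 rss_oracle(seq, 12L, "V-side", cfg), ignore_attr = TRUE)
  }
})

test_that("sequences shorter than the minimal window yield no hits", {
  expect_equal(nrow(scan_rss("CACAGTG", 12L, "V-side")), 0L)
})

test_that("best_rss_hit prefers total matches then proximity", {
  hits <- data.frame(start = c(5L, 0L), end = c(44L, 39L),
                     spacer_class = 23L, spacer_length = 23L,
                     heptamer = "CACAGTG", nonamer = "ACAAAAACC",
                     heptamer_matches = c(7L, 7L),
                     nonamer_matches = c(6L, 9L),
                     orientation = "V-side", stringsAsFactors = FALSE)
  expect_equal(best_rss_hit(hits, coding_end = 5L)$start, 0L)
})

test_that("conservation matrix matches a direct tally and closed forms", {
  m <- conservation_matrix(rep("CACAGTG", 10))
  expect_true(all(apply(m$freq, 2, max) == 1))
  expect_equal(m$information, rep(2, 7))
  m2 <- conservation_matrix(c("A", "T"))
  expect_equal(unname(m2$information), 1)
  set.seed(23)
  seqs <- vapply(1:100, function(i) random_dna_str(9), character(1))
  m3 <- conservation_matrix(seqs)
  expect_equal(unname(m3$freq), unname(tally_oracle(seqs)),
               tolerance = 1e-12)
  expect_true(all(abs(colSums(m3$freq) - 1) < 1e-9))
  expect_error(conservation_matrix(c("AA", "A")), "equal length")
})
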