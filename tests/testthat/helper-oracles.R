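# Independent brute-force oracles used to check the package's optimised
# implementations. These deliberately use different code paths (character
# sliding windows, exhaustive enumeration) than the functions they check.

# Exhaustive sliding-window RSS scan: checks every (heptamer, spacer,
# nonamer) placement with plain substring arithmetic.
rss_oracle <- function(seq, spacer_class, orientation, config = rss_config()) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  hep <- strsplit(config$heptamer, "")[[1]]
  non <- strsplit(config$nonamer, "")[[1]]
  spacers <- (spacer_class - 1L):(spacer_class + 1L)
  rows <- list()
  for (i in seq_len(max(0L, n - (7L + min(spacers) + 9L) + 1L))) {
    for (s in spacers) {
      win <- 7L + s + 9L
      if (i + win - 1L > n) next
      if (orientation == "V-side") {
        h <- x[i:(i + 6L)]
        nn <- x[(i + 7L + s):(i + 7L + s + 8L)]
      } else {
        nn <- x[i:(i + 8L)]
        h <- x[(i + 9L + s):(i + 9L + s + 6L)]
      }
      hep_mm <- sum(h != hep)
      non_mm <- sum(nn != non)
      if (hep_mm > config$max_heptamer_mismatch) next
      if (non_mm > config$max_nonamer_mismatch) next
      if (config$require_cac && !all(h[1:3] == c("C", "A", "C"))) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = i - 1L, end = i + win - 1L, spacer_class = spacer_class,
        spacer_length = s, heptamer = paste(h, collapse = ""),
        nonamer = paste(nn, collapse = ""),
        heptamer_matches = 7L - hep_mm, nonamer_matches = 9L - non_mm,
        orientation = orientation, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(igloci:::empty_rss_hits())
  out <- do.call(rbind, rows)
  out[order(out$start, out$spacer_length), , drop = FALSE]
}

# Exhaustive expected richness: mean distinct clonotypes over all
# choose(N, d) subsamples (feasible for N <= 12).
rarefaction_oracle <- function(counts, depth) {
  ids <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(ids), depth)
  mean(apply(subsets, 2, function(ix) length(unique(ids[ix]))))
}

# Direct tally oracle for conservation matrices.
tally_oracle <- function(seqs) {
  chars <- do.call(rbind, strsplit(seqs, ""))
  symbols <- sort(unique(as.vector(chars)))
  sapply(seq_len(ncol(chars)), function(j) {
    sapply(symbols, function(s) mean(chars[, j] == s))
  })
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small shared fixtures built once per test run (cached in an environment
# so the expensive locus build happens a single time).
.fixtures <- new.env()

fixture_locus <- function() {
  if (is.null(.fixtures$locus)) {
    .fixtures$locus <- generate_locus(locus_spec(
      n_v = 12L, n_d = 6L, n_j = 6L, n_c = 4L, n_clusters = 2L,
      pseudogene_fraction = 0.4, orf_fraction = 0.1,
      reversed_v_fraction = 0.25, seed = 303L))
  }
  .fixtures$locus
}

fixture_annotation <- function() {
  if (is.null(.fixtures$annotation)) {
    loc <- fixture_locus()
    .fixtures$annotation <- annotate_locus(loc$genome, loc$v_seeds,
                                           loc$c_seeds, "IGH")
  }
  .fixtures$annotation
}

fixture_reference <- function() {
  if (is.null(.fixtures$reference)) {
    .fixtures$reference <- build_reference(fixture_annotation()$genes, "IGH")
  }
  .fixtures$reference
}
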