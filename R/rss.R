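#' RSS scanning configuration
#'
#' Mismatch tolerances for recombination signal sequence (RSS) detection.
#' The defaults implement the strict rule used for functionality calls:
#' heptamer at most 1 mismatch from CACAGTG with the first three bases (CAC)
#' exact, nonamer at most 3 mismatches from ACAAAAACC. A relaxed
#' configuration (see [rss_config_relaxed()]) is used for candidate
#' discovery so that genes with degraded signals are still found and can be
#' classified as ORF.
#'
#' @param heptamer,nonamer Consensus strings.
#' @param max_heptamer_mismatch,max_nonamer_mismatch Mismatch budgets.
#' @param require_cac Must heptamer positions 1-3 match CAC exactly?
#' @return A list of class "rss_config".
#' @export
rss_config <- function(heptamer = "CACAGTG", nonamer = "ACAAAAACC",
                       max_heptamer_mismatch = 1L, max_nonamer_mismatch = 3L,
                       require_cac = TRUE) {
  structure(list(heptamer = heptamer, nonamer = nonamer,
                 max_heptamer_mismatch = as.integer(max_heptamer_mismatch),
                 max_nonamer_mismatch = as.integer(max_nonamer_mismatch),
                 require_cac = require_cac),
            class = "rss_config")
}

#' Relaxed RSS configuration for candidate discovery
#' @return A list of class "rss_config".
#' @export
rss_config_relaxed <- function() {
  rss_config(max_heptamer_mismatch = 2L, max_nonamer_mismatch = 3L,
             require_cac = FALSE)
}

#' Expected RSS spacer class and side per chain and segment type
#'
#' IGH: V 23 at 3', D 12 on both sides, J 23 at 5'. IGK: V 12 at 3',
#' J 23 at 5'. IGL: V 23 at 3', J 12 at 5'.
#'
#' @param chain One of "IGH", "IGK", "IGL".
#' @param segment_type One of "V", "D", "J".
#' @return List with elements `class` (12 or 23; for D a vector of two) and
#'   `side` ("3prime", "5prime" or "both").
#' @export
expected_rss <- function(chain, segment_type) {
  key <- paste(chain, segment_type)
  table <- list(
    "IGH V" = list(class = 23L, side = "3prime"),
    "IGH D" = list(class = c(12L, 12L), side = "both"),
    "IGH J" = list(class = 23L, side = "5prime"),
    "IGK V" = list(class = 12L, side = "3prime"),
    "IGK J" = list(class = 23L, side = "5prime"),
    "IGL V" = list(class = 23L, side = "3prime"),
    "IGL J" = list(class = 12L, side = "5prime"))
  if (is.null(table[[key]])) stop("no RSS expectation for ", key)
  table[[key]]
}

empty_rss_hits <- function() {
  data.frame(start = integer(0), end = integer(0), spacer_class = integer(0),
             spacer_length = integer(0), heptamer = character(0),
             nonamer = character(0), heptamer_matches = integer(0),
             nonamer_matches = integer(0), orientation = character(0),
             stringsAsFactors = FALSE)
}

match_positions <- function(seq, consensus, max_mismatch) {
  hits <- Biostrings::matchPattern(consensus, Biostrings::DNAString(seq),
                                   max.mismatch = max_mismatch)
  starts <- IRanges::start(hits@ranges)
  # drop partially out-of-bounds matches
  starts[starts >= 1L & starts + nchar(consensus) - 1L <= nchar(seq)]
}

#' Scan a sequence for RSS motifs
#'
#' Finds heptamer-spacer-nonamer signals matching the consensus within the
#' configured mismatch budgets. Spacer lengths of class +/- 1 are accepted
#' (12: 11-13; 23: 22-24). In "V-side" orientation the signal reads
#' heptamer, spacer, nonamer 5' to 3' (as found 3' of a V gene); "J-side"
#' is the mirror arrangement nonamer, spacer, heptamer (as found 5' of a
#' J gene).
#'
#' @param seq DNA sequence (character scalar).
#' @param spacer_class 12 or 23.
#' @param orientation "V-side" or "J-side".
#' @param config An [rss_config()].
#' @return Data frame of hits sorted by position with 0-based half-open
#'   `start`/`end` spanning the full signal, the observed heptamer/nonamer,
#'   match counts, spacer length and orientation. Empty if the sequence is
#'   shorter than the minimal window.
#' @export
scan_rss <- function(seq, spacer_class, orientation = c("V-side", "J-side"),
                     config = rss_config()) {
  orientation <- match.arg(orientation)
  spacer_class <- as.integer(spacer_class)
  stopifnot(spacer_class %in% c(12L, 23L))
  n <- nchar(seq)
  spacers <- (spacer_class - 1L):(spacer_class + 1L)
  min_win <- 7L + min(spacers) + 9L
  if (n < min_win) return(empty_rss_hits())

  hep_starts <- match_positions(seq, config$heptamer,
                                config$max_heptamer_mismatch)
  non_starts <- match_positions(seq, config$nonamer,
                                config$max_nonamer_mismatch)
  if (length(hep_starts) == 0 || length(non_starts) == 0) {
    return(empty_rss_hits())
  }
  non_set <- logical(n)
  non_set[non_starts] <- TRUE

  rows <- list()
  for (h in hep_starts) {
    hep <- substr(seq, h, h + 6L)
    if (config$require_cac && substr(hep, 1L, 3L) != "CAC") next
    hep_mm <- count_mismatch(hep, config$heptamer)
    if (hep_mm > config$max_heptamer_mismatch) next
    for (s in spacers) {
      if (orientation == "V-side") {
        nstart <- h + 7L + s
        if (nstart + 8L > n) next
        if (!non_set[nstart]) next
        sig_start <- h; sig_end <- nstart + 8L
      } else {
        nstart <- h - s - 9L
        if (nstart < 1L) next
        if (!non_set[nstart]) next
        sig_start <- nstart; sig_end <- h + 6L
      }
      non <- substr(seq, nstart, nstart + 8L)
      non_mm <- count_mismatch(non, config$nonamer)
      rows[[length(rows) + 1L]] <- data.frame(
        start = sig_start - 1L, end = sig_end,
        spacer_class = spacer_class, spacer_length = s,
        heptamer = hep, nonamer = non,
        heptamer_matches = 7L - hep_mm, nonamer_matches = 9L - non_mm,
        orientation = orientation, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_rss_hits())
  out <- do.call(rbind, rows)
  out[order(out$start, out$spacer_length), , drop = FALSE]
}

#' Pick the best RSS hit nearest a gene end
#'
#' When several placements abut one gene end, keeps the hit with the highest
#' total matches, ties broken by proximity to the coding end.
#'
#' @param hits Data frame from [scan_rss()].
#' @param coding_end Position (0-based) of the gene end the signal abuts.
#' @return A single-row data frame, or NULL if no hits.
#' @export
best_rss_hit <- function(hits, coding_end = 0L) {
  if (nrow(hits) == 0) return(NULL)
  total <- hits$heptamer_matches + hits$nonamer_matches
  dist <- abs(hits$start - coding_end)
  ord <- order(-total, dist)
  hits[ord[1L], , drop = FALSE]
}

#' Per-position symbol frequencies and information content of an alignment
#'
#' For equal-length sequences, tallies per-position symbol frequencies and
#' computes the information content 2 - H (Shannon entropy in bits) per
#' position, the quantity displayed by sequence-logo tools for nucleotide
#' alphabets.
#'
#' @param seqs Character vector of equal-length sequences.
#' @return List with `freq` (symbols x positions frequency matrix, columns
#'   summing to 1) and `information` (numeric vector of bits per position).
#' @export
conservation_matrix <- function(seqs) {
  stopifnot(length(seqs) > 0)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  L <- lens[1L]
  chars <- do.call(rbind, strsplit(seqs, ""))
  symbols <- sort(unique(as.vector(chars)))
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = symbols))
    as.numeric(tab) / length(seqs)
  }, numeric(length(symbols)))
  freq <- matrix(freq, nrow = length(symbols), ncol = L,
                 dimnames = list(symbols, NULL))
  info <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  list(freq = freq, information = info)
}
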