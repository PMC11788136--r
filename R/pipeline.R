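# Read alignment against the segmented germline reference and CDR3
# extraction. V/J candidates are picked by a k-mer vote prefilter and
# verified by local Smith-Waterman alignment; junction boundaries are then
# attributed by maximal exact extension outward from the CDR3 anchors
# (V first, then J), the same canonical convention the simulator records,
# so junction bookkeeping is well defined in the presence of insertions
# that happen to match the germline continuation.

#' Pipeline configuration
#'
#' @param k K-mer size of the V prefilter.
#' @param stride Read k-mer sampling stride.
#' @param match,mismatch,gap_open,gap_ext Smith-Waterman scoring.
#' @param min_v_score,min_j_score Minimum accepted alignment scores.
#' @param d_min_core Minimum exact D core match (nt) for a D call.
#' @return List of class "pipeline_config".
#' @export
pipeline_config <- function(k = 16L, stride = 4L, match = 2, mismatch = -3,
                            gap_open = 5, gap_ext = 2,
                            min_v_score = 50, min_j_score = 20,
                            d_min_core = 7L) {
  structure(list(k = as.integer(k), stride = as.integer(stride),
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, min_v_score = min_v_score,
                 min_j_score = min_j_score, d_min_core = as.integer(d_min_core)),
            class = "pipeline_config")
}

kmer_set <- function(seq, k, stride = 1L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq(1L, n - k + 1L, by = stride)
  unique(substring(seq, starts, starts + k - 1L))
}

sub_matrix <- function(config) {
  Biostrings::nucleotideSubstitutionMatrix(match = config$match,
                                           mismatch = config$mismatch,
                                           baseOnly = TRUE)
}

# Vote matrix: reads x refs counts of shared k-mers.
vote_matrix <- function(read_kmers_flat, read_id, n_reads, ref_seqs, config) {
  votes <- matrix(0L, nrow = n_reads, ncol = length(ref_seqs))
  for (ri in seq_along(ref_seqs)) {
    rk <- kmer_set(ref_seqs[ri], config$k, 1L)
    hit <- !is.na(match(read_kmers_flat, rk))
    if (any(hit)) {
      tab <- tabulate(read_id[hit], nbins = n_reads)
      votes[, ri] <- votes[, ri] + tab
    }
  }
  votes
}

#' Align reads to a germline reference
#'
#' For each read, both orientations are screened by shared k-mer counts
#' against every V record; the best candidate (and the runner-up when votes
#' are close) is verified by local Smith-Waterman alignment and the
#' higher-scoring assignment kept. The J segment is then aligned on the
#' read region downstream of the V anchor. Rejection reasons (NO_V, NO_J,
#' LOW_SCORE) are data, not errors.
#'
#' @param reads Named character vector of read sequences.
#' @param reference A "germline_reference"; only anchor-bearing productive
#'   records are used for assignment.
#' @param config A [pipeline_config()].
#' @return Data frame with one row per read: read_id, orientation, v_gene,
#'   v_score, read/germline alignment bounds for V and J, j_gene, j_score,
#'   status ("OK" or a rejection reason).
#' @export
align_reads <- function(reads, reference, config = pipeline_config()) {
  v_ref <- reference$v[reference$v$productive & !is.na(reference$v$anchor_nt),
                       , drop = FALSE]
  j_ref <- reference$j[reference$j$productive & !is.na(reference$j$anchor_nt),
                       , drop = FALSE]
  stopifnot(nrow(v_ref) > 0, nrow(j_ref) > 0)
  n <- length(reads)
  out <- data.frame(
    read_id = names(reads), orientation = NA_character_,
    v_gene = NA_character_, v_score = NA_real_,
    v_read_start = NA_integer_, v_read_end = NA_integer_,
    v_germ_start = NA_integer_, v_germ_end = NA_integer_,
    j_gene = NA_character_, j_score = NA_real_,
    j_read_start = NA_integer_, j_read_end = NA_integer_,
    j_germ_start = NA_integer_, j_germ_end = NA_integer_,
    status = "OK", stringsAsFactors = FALSE)
  if (n == 0) return(out)

  fwd <- unname(reads)
  rev <- revcomp(fwd)
  mk_flat <- function(seqs) {
    ks <- lapply(seqs, kmer_set, k = config$k, stride = config$stride)
    list(flat = unlist(ks, use.names = FALSE),
         id = rep(seq_along(seqs), lengths(ks)))
  }
  ff <- mk_flat(fwd)
  rf <- mk_flat(rev)
  vf <- vote_matrix(ff$flat, ff$id, n, v_ref$nt_sequence, config)
  vr <- vote_matrix(rf$flat, rf$id, n, v_ref$nt_sequence, config)
  best_f <- apply(vf, 1, max)
  best_r <- apply(vr, 1, max)
  use_rev <- best_r > best_f
  votes <- vf
  votes[use_rev, ] <- vr[use_rev, , drop = FALSE]
  oriented <- ifelse(use_rev, rev, fwd)
  out$orientation <- ifelse(use_rev, "-", "+")

  top_votes <- apply(votes, 1, max)
  no_v <- top_votes == 0
  out$status[no_v] <- "NO_V"

  cand1 <- max.col(votes, ties.method = "first")
  votes2 <- votes
  votes2[cbind(seq_len(n), cand1)] <- -1L
  cand2 <- max.col(votes2, ties.method = "first")
  need2 <- !no_v & apply(votes2, 1, max) >= (top_votes - 4L) &
    apply(votes2, 1, max) > 0
  smat <- sub_matrix(config)

  sw_group <- function(idx, ref_seq) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(oriented[idx]),
      Biostrings::DNAString(ref_seq), type = "local",
      substitutionMatrix = smat, gapOpening = config$gap_open,
      gapExtension = config$gap_ext)
    list(score = Biostrings::score(aln),
         rs = IRanges::start(Biostrings::pattern(aln)@range),
         re = IRanges::end(Biostrings::pattern(aln)@range),
         gs = IRanges::start(Biostrings::subject(aln)@range),
         ge = IRanges::end(Biostrings::subject(aln)@range))
  }

  v_best_score <- rep(-Inf, n)
  v_best <- rep(NA_integer_, n)
  v_bounds <- matrix(NA_integer_, nrow = n, ncol = 4)
  for (pass in 1:2) {
    cand <- if (pass == 1) cand1 else cand2
    rows <- if (pass == 1) which(!no_v) else which(need2)
    if (length(rows) == 0) next
    for (ri in unique(cand[rows])) {
      idx <- rows[cand[rows] == ri]
      a <- sw_group(idx, v_ref$nt_sequence[ri])
      better <- a$score > v_best_score[idx]
      upd <- idx[better]
      v_best_score[upd] <- a$score[better]
      v_best[upd] <- ri
      v_bounds[upd, ] <- cbind(a$rs, a$re, a$gs, a$ge)[better, , drop = FALSE]
    }
  }
  ok <- !no_v & v_best_score >= config$min_v_score
  out$status[!no_v & !ok] <- "LOW_SCORE"
  out$v_gene[ok] <- v_ref$name[v_best[ok]]
  out$v_score[ok] <- v_best_score[ok]
  out$v_read_start[ok] <- v_bounds[ok, 1]
  out$v_read_end[ok] <- v_bounds[ok, 2]
  out$v_germ_start[ok] <- v_bounds[ok, 3]
  out$v_germ_end[ok] <- v_bounds[ok, 4]

  # J alignment on the read suffix from the V anchor onward
  ok_idx <- which(ok)
  if (length(ok_idx) > 0) {
    anchor_read <- v_bounds[ok_idx, 2] -
      (v_bounds[ok_idx, 4] - (v_ref$anchor_nt[v_best[ok_idx]] + 1L))
    suffix_from <- pmax(1L, anchor_read)
    suffixes <- substring(oriented[ok_idx], suffix_from)
    j_score <- matrix(-Inf, nrow = length(ok_idx), ncol = nrow(j_ref))
    j_info <- vector("list", nrow(j_ref))
    for (ji in seq_len(nrow(j_ref))) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(suffixes),
        Biostrings::DNAString(j_ref$nt_sequence[ji]), type = "local",
        substitutionMatrix = smat, gapOpening = config$gap_open,
        gapExtension = config$gap_ext)
      j_score[, ji] <- Biostrings::score(aln)
      j_info[[ji]] <- list(
        rs = IRanges::start(Biostrings::pattern(aln)@range),
        re = IRanges::end(Biostrings::pattern(aln)@range),
        gs = IRanges::start(Biostrings::subject(aln)@range),
        ge = IRanges::end(Biostrings::subject(aln)@range))
    }
    jb <- max.col(j_score, ties.method = "first")
    js <- j_score[cbind(seq_along(ok_idx), jb)]
    has_j <- js >= config$min_j_score
    rows <- ok_idx[has_j]
    sel <- which(has_j)
    out$j_gene[rows] <- j_ref$name[jb[sel]]
    out$j_score[rows] <- js[sel]
    out$j_read_start[rows] <- vapply(sel, function(s)
      j_info[[jb[s]]]$rs[s], numeric(1)) + suffix_from[sel] - 1L
    out$j_read_end[rows] <- vapply(sel, function(s)
      j_info[[jb[s]]]$re[s], numeric(1)) + suffix_from[sel] - 1L
    out$j_germ_start[rows] <- vapply(sel, function(s)
      j_info[[jb[s]]]$gs[s], numeric(1))
    out$j_germ_end[rows] <- vapply(sel, function(s)
      j_info[[jb[s]]]$ge[s], numeric(1))
    out$status[ok_idx[!has_j]] <- "NO_J"
  }
  out$oriented_seq <- oriented
  out
}

#' Align a single read
#'
#' Convenience wrapper over [align_reads()] for one read.
#' @param read Read sequence (character scalar).
#' @param reference A "germline_reference".
#' @param config A [pipeline_config()].
#' @return One-row data frame as from [align_reads()].
#' @export
align_read <- function(read, reference, config = pipeline_config()) {
  align_reads(c(read1 = read), reference, config)
}

#' Assign a D gene to a junction middle segment
#'
#' The D gene whose longest exact substring shared with the inter-anchor
#' region reaches at least `min_core` bases and is maximal; ties broken by
#' locus order of the D references; empty string if none qualifies.
#'
#' @param junction_nt Inter-anchor (post-V, pre-J) nucleotide segment.
#' @param d_reference Data frame with columns name, nt_sequence (in locus
#'   order), or a "germline_reference".
#' @param min_core Minimum exact match length.
#' @return List with `d_gene` ("" if unassigned) and `match_len`.
#' @export
assign_d <- function(junction_nt, d_reference, min_core = 7L) {
  if (inherits(d_reference, "germline_reference")) d_reference <- d_reference$d
  nm <- nchar(junction_nt)
  best <- list(d_gene = "", match_len = 0L)
  if (is.null(d_reference) || nrow(d_reference) == 0 || nm < min_core) {
    return(best)
  }
  for (i in seq_len(nrow(d_reference))) {
    d <- d_reference$nt_sequence[i]
    cap <- min(nm, nchar(d))
    if (cap < min_core) next
    len <- 0L
    for (L in seq(cap, min_core)) {
      starts <- 1:(nm - L + 1L)
      subs <- substring(junction_nt, starts, starts + L - 1L)
      if (any(vapply(subs, function(s) grepl(s, d, fixed = TRUE),
                     logical(1)))) {
        len <- L
        break
      }
    }
    if (len > best$match_len) {
      best <- list(d_gene = d_reference$name[i], match_len = len)
    }
  }
  best
}

# Maximal exact extension of the V (rightward from its anchor) and J
# (leftward from its anchor toward the germline 5' end) attribution on an
# aligned read. Both extensions start at the CDR3 anchors so the rule is
# identical to the simulator's canonical bookkeeping.
extend_boundaries <- function(read, v_nt, v_anchor_nt, v_read_at_germ1,
                              j_nt, j_anchor_nt, j_anchor_read) {
  Lv <- nchar(v_nt)
  # read position of germline V position p (ungapped mapping)
  v_read_pos <- function(p) v_read_at_germ1 + p - 1L
  p <- v_anchor_nt + 3L                       # last base of the C104 codon
  while (p < Lv) {
    rp <- v_read_pos(p + 1L)
    if (rp > nchar(read)) break
    if (substr(read, rp, rp) != substr(v_nt, p + 1L, p + 1L)) break
    p <- p + 1L
  }
  v_end_germ <- p
  v_end_read <- v_read_pos(p)
  # J: extend leftward from the W/F codon start toward germline position 1
  g <- j_anchor_nt + 1L                       # germ position of the W/F codon
  r <- j_anchor_read
  while (g > 1L && r - 1L > v_end_read &&
         substr(read, r - 1L, r - 1L) == substr(j_nt, g - 1L, g - 1L)) {
    g <- g - 1L
    r <- r - 1L
  }
  list(v_end_germ = v_end_germ, v_end_read = v_end_read,
       j_start_germ = g, j_start_read = r)
}

# Anchor mapping + canonical extension for one read; everything except the
# D call (which is memoised per unique junction in the batch path). Inputs
# are plain scalars/vectors so the 10k-read loop avoids data-frame row
# subsetting.
extract_core <- function(read, status, v_nt, v_anchor, v_read_start,
                         v_germ_start, v_germ_end, j_nt, j_anchor,
                         j_read_start, j_germ_start, j_germ_end) {
  rej <- function(s) list(cdr3_nt = NA_character_, middle = NA_character_,
                          v_del = NA_integer_, j_del = NA_integer_,
                          status = s)
  if (is.na(status) || status != "OK") return(rej(status))
  if (is.na(j_germ_start)) return(rej("NO_J"))
  v_read_at_germ1 <- v_read_start - v_germ_start + 1L
  anchor_read <- v_read_at_germ1 + v_anchor          # C104 codon start
  if (anchor_read < 1L || v_germ_end < v_anchor + 3L ||
      anchor_read + 2L > nchar(read)) {
    return(rej("ANCHOR_LOST"))
  }
  # J anchor position on the read via the (ungapped) alignment mapping
  if (j_germ_start > j_anchor + 1L || j_germ_end < j_anchor + 3L) {
    return(rej("ANCHOR_LOST"))
  }
  j_anchor_read <- j_read_start + (j_anchor + 1L - j_germ_start)
  j_anchor_end <- j_anchor_read + 2L
  if (j_anchor_end > nchar(read) || j_anchor_end <= anchor_read) {
    return(rej("ANCHOR_LOST"))
  }
  ext <- extend_boundaries(read, v_nt, v_anchor, v_read_at_germ1,
                           j_nt, j_anchor, j_anchor_read)
  cdr3_nt <- substr(read, anchor_read, j_anchor_end)
  middle <- if (ext$j_start_read - 1L >= ext$v_end_read + 1L)
    substr(read, ext$v_end_read + 1L, ext$j_start_read - 1L) else ""
  list(cdr3_nt = cdr3_nt, middle = middle,
       v_del = nchar(v_nt) - ext$v_end_germ,
       j_del = ext$j_start_germ - 1L, status = "OK")
}

#' Extract the CDR3 and junction bookkeeping from an aligned read
#'
#' The CDR3 spans the read from the position aligned to the V C104 codon
#' start through the end of the position aligned to the J W/F codon
#' (anchors inclusive). Germline attribution at the junction is canonical
#' maximal extension (V first, then J); v/j_deletions are germline bases
#' missing beyond the attributed ends, and n_insertions is the inter-
#' anchor length minus any assigned D contribution.
#'
#' @param alignment One row of [align_reads()] output (with oriented_seq).
#' @param reference A "germline_reference".
#' @param config A [pipeline_config()].
#' @return List with cdr3_nt, cdr3_aa, v_gene, d_gene, j_gene, v_del,
#'   j_del, n_ins and status ("OK", or ANCHOR_LOST / the alignment's
#'   rejection reason).
#' @export
extract_cdr3 <- function(alignment, reference, config = pipeline_config()) {
  vi <- match(alignment$v_gene, reference$v$name)
  ji <- match(alignment$j_gene, reference$j$name)
  core <- extract_core(
    alignment$oriented_seq, alignment$status,
    reference$v$nt_sequence[vi], reference$v$anchor_nt[vi],
    alignment$v_read_start, alignment$v_germ_start, alignment$v_germ_end,
    reference$j$nt_sequence[ji], reference$j$anchor_nt[ji],
    alignment$j_read_start, alignment$j_germ_start, alignment$j_germ_end)
  if (core$status != "OK") {
    return(list(cdr3_nt = NA_character_, cdr3_aa = NA_character_,
                v_gene = alignment$v_gene, d_gene = "",
                j_gene = alignment$j_gene, v_del = NA_integer_,
                j_del = NA_integer_, n_ins = NA_integer_,
                status = core$status))
  }
  dm <- assign_d(core$middle, reference, config$d_min_core)
  list(cdr3_nt = core$cdr3_nt, cdr3_aa = translate_nt(core$cdr3_nt),
       v_gene = alignment$v_gene, d_gene = dm$d_gene,
       j_gene = alignment$j_gene, v_del = core$v_del, j_del = core$j_del,
       n_ins = nchar(core$middle) - dm$match_len, status = "OK")
}

# Batched extraction: plain-vector loop plus D assignment memoised over
# unique inter-anchor segments.
extract_cdr3_batch <- function(aln, reference, config = pipeline_config()) {
  n <- nrow(aln)
  vi <- match(aln$v_gene, reference$v$name)
  ji <- match(aln$j_gene, reference$j$name)
  v_nt <- reference$v$nt_sequence[vi]
  v_anchor <- reference$v$anchor_nt[vi]
  j_nt <- reference$j$nt_sequence[ji]
  j_anchor <- reference$j$anchor_nt[ji]
  out <- data.frame(cdr3_nt = rep(NA_character_, n), middle = NA_character_,
                    v_gene = aln$v_gene, d_gene = "", j_gene = aln$j_gene,
                    v_del = NA_integer_, j_del = NA_integer_,
                    n_ins = NA_integer_, status = aln$status,
                    stringsAsFactors = FALSE)
  reads <- aln$oriented_seq
  status <- aln$status
  vrs <- aln$v_read_start; vgs <- aln$v_germ_start; vge <- aln$v_germ_end
  jrs <- aln$j_read_start; jgs <- aln$j_germ_start; jge <- aln$j_germ_end
  for (i in seq_len(n)) {
    core <- extract_core(reads[i], status[i], v_nt[i], v_anchor[i], vrs[i],
                         vgs[i], vge[i], j_nt[i], j_anchor[i], jrs[i],
                         jgs[i], jge[i])
    out$status[i] <- core$status
    if (core$status == "OK") {
      out$cdr3_nt[i] <- core$cdr3_nt
      out$middle[i] <- core$middle
      out$v_del[i] <- core$v_del
      out$j_del[i] <- core$j_del
    }
  }
  ok <- which(out$status == "OK")
  if (length(ok) > 0) {
    mids <- unique(out$middle[ok])
    dms <- lapply(mids, assign_d, d_reference = reference,
                  min_core = config$d_min_core)
    d_gene <- vapply(dms, `[[`, character(1), "d_gene")
    d_len <- vapply(dms, `[[`, integer(1), "match_len")
    mi <- match(out$middle[ok], mids)
    out$d_gene[ok] <- d_gene[mi]
    out$n_ins[ok] <- nchar(out$middle[ok]) - d_len[mi]
    out$cdr3_aa <- NA_character_
    out$cdr3_aa[ok] <- translate_nt(out$cdr3_nt[ok])
  } else {
    out$cdr3_aa <- NA_character_
  }
  out$middle <- NULL
  out
}

#' Assemble clonotypes from per-read CDR3 extractions
#'
#' Groups accepted reads by exact (cdr3_nt, v_gene, j_gene); the clonotype
#' count is the number of contributing reads, "unique clones" the number of
#' distinct groups.
#'
#' @param extractions Data frame of per-read extraction rows (status "OK").
#' @param sample_id Sample identifier.
#' @param total_reads Total input reads (for the sample accounting).
#' @return A "repertoire_sample": list with sample_id, clonotypes (data
#'   frame sorted by decreasing count), total_reads, aligned_reads.
#' @export
assemble_clonotypes <- function(extractions, sample_id = "sample",
                                total_reads = nrow(extractions)) {
  ok <- extractions[extractions$status == "OK", , drop = FALSE]
  if (nrow(ok) == 0) {
    clonotypes <- data.frame(cdr3_nt = character(0), cdr3_aa = character(0),
                             count = integer(0), v_gene = character(0),
                             d_gene = character(0), j_gene = character(0),
                             v_del = integer(0), j_del = integer(0),
                             n_ins = integer(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(ok$cdr3_nt, ok$v_gene, ok$j_gene, sep = "|")
    groups <- split(seq_len(nrow(ok)), key)
    clonotypes <- do.call(rbind, lapply(groups, function(idx) {
      r <- ok[idx[1], , drop = FALSE]
      data.frame(cdr3_nt = r$cdr3_nt, cdr3_aa = r$cdr3_aa,
                 count = length(idx), v_gene = r$v_gene, d_gene = r$d_gene,
                 j_gene = r$j_gene, v_del = r$v_del, j_del = r$j_del,
                 n_ins = r$n_ins, stringsAsFactors = FALSE)
    }))
    clonotypes <- clonotypes[order(-clonotypes$count, clonotypes$cdr3_nt), ,
                             drop = FALSE]
    rownames(clonotypes) <- NULL
  }
  structure(list(sample_id = sample_id, clonotypes = clonotypes,
                 total_reads = total_reads, aligned_reads = nrow(ok)),
            class = "repertoire_sample")
}

#' Remove non-productive clonotypes
#'
#' Drops clonotypes whose CDR3 contains a stop codon and clonotypes whose
#' CDR3 length is not a multiple of 3 (out-of-frame junctions). Removal
#' counts are attached as the "removed" attribute.
#'
#' @param sample A "repertoire_sample" or clonotype data frame.
#' @return Same type, filtered; attr(x, "removed") holds the counts
#'   c(stop = ..., frame = ...).
#' @export
filter_productive <- function(sample) {
  is_sample <- inherits(sample, "repertoire_sample")
  cl <- if (is_sample) sample$clonotypes else sample
  frame_bad <- nchar(cl$cdr3_nt) %% 3L != 0L
  stop_bad <- grepl("*", cl$cdr3_aa, fixed = TRUE)
  removed <- c(stop = sum(stop_bad & !frame_bad), frame = sum(frame_bad))
  cl <- cl[!frame_bad & !stop_bad, , drop = FALSE]
  rownames(cl) <- NULL
  if (is_sample) {
    sample$clonotypes <- cl
    attr(sample, "removed") <- removed
    sample
  } else {
    attr(cl, "removed") <- removed
    cl
  }
}

#' Run the repertoire pipeline end to end
#'
#' Aligns reads, extracts CDR3s, assembles clonotypes and removes
#' non-productive ones.
#'
#' @param reads Named character vector of read sequences.
#' @param reference A "germline_reference".
#' @param sample_id Sample identifier.
#' @param config A [pipeline_config()].
#' @param productive_only Drop stop-containing/out-of-frame clonotypes?
#' @return A "repertoire_sample" with an `accounting` attribute tabulating
#'   per-read statuses.
#' @export
run_repertoire <- function(reads, reference, sample_id = "sample",
                           config = pipeline_config(),
                           productive_only = TRUE) {
  aln <- align_reads(reads, reference, config)
  extdf <- extract_cdr3_batch(aln, reference, config)
  sample <- assemble_clonotypes(extdf, sample_id, total_reads = length(reads))
  if (productive_only) sample <- filter_productive(sample)
  attr(sample, "accounting") <- table(extdf$status)
  sample
}
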