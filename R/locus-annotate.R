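# Candidate V/D/J/C gene detection in genomic sequence.
#
# V and C candidates are seeded by similarity to known germline sequences
# (exhaustive ungapped matching with a mismatch budget derived from the
# identity threshold); D and J candidates are found from their RSS geometry.
# Discovery uses a relaxed RSS threshold so that genes with degraded signals
# are still found; the strict threshold is applied at classification time.

#' Annotation configuration
#'
#' All thresholds of the locus annotator. `min_identity` is the seed-match
#' identity threshold; `v_exon_range` the accepted V exon length window
#' around ~290 bp; `leader_len`/`intron_len` the fixed leader/intron
#' geometry used for initiation-codon and splice checks; `j_length` the
#' annotated J gene length; `d_g_fraction`/`d_core_range` the D-gene
#' G-richness rule; `max_rss_gap` how far from the coding end a strict RSS
#' may sit; `max_intron` the largest gap joining C exons into one gene.
#'
#' @param min_identity Seed identity threshold in (0, 1].
#' @param v_exon_range Length window (bp) for V exons.
#' @param leader_len,intron_len Leader exon and intron lengths (bp).
#' @param j_length Annotated J gene length (bp).
#' @param d_g_fraction Minimum G fraction of a D core.
#' @param d_core_range Allowed D core length range (bp).
#' @param max_rss_gap Maximum distance (bp) between coding end and RSS.
#' @param max_intron Maximum intron length when chaining C exons.
#' @param rss_strict,rss_relaxed RSS configurations for classification and
#'   discovery respectively.
#' @return List of class "annotation_config".
#' @export
annotation_config <- function(min_identity = 0.75,
                              v_exon_range = c(240L, 340L),
                              leader_len = 48L, intron_len = 80L,
                              j_length = 48L,
                              d_g_fraction = 0.4, d_core_range = c(5L, 40L),
                              max_rss_gap = 10L, max_intron = 2000L,
                              rss_strict = rss_config(),
                              rss_relaxed = rss_config_relaxed()) {
  structure(list(min_identity = min_identity, v_exon_range = v_exon_range,
                 leader_len = as.integer(leader_len),
                 intron_len = as.integer(intron_len),
                 j_length = as.integer(j_length),
                 d_g_fraction = d_g_fraction, d_core_range = d_core_range,
                 max_rss_gap = as.integer(max_rss_gap),
                 max_intron = as.integer(max_intron),
                 rss_strict = rss_strict, rss_relaxed = rss_relaxed),
            class = "annotation_config")
}

seed_matches <- function(contig_seq, seed, max_mm) {
  hits <- Biostrings::matchPattern(seed, Biostrings::DNAString(contig_seq),
                                   max.mismatch = max_mm)
  starts <- IRanges::start(hits@ranges)
  L <- nchar(seed)
  starts <- starts[starts >= 1L & starts + L - 1L <= nchar(contig_seq)]
  if (length(starts) == 0) return(NULL)
  obs <- substring(contig_seq, starts, starts + L - 1L)
  mm <- vapply(obs, function(o) count_mismatch(o, seed), integer(1),
               USE.NAMES = FALSE)
  keep <- mm <= max_mm
  data.frame(start = starts[keep] - 1L, end = starts[keep] - 1L + L,
             identity = 1 - mm[keep] / L, obs = obs[keep],
             stringsAsFactors = FALSE)
}

#' Find V gene candidates by seed similarity
#'
#' Scans every contig on both strands for ungapped matches to the seed
#' sequences with identity at least `min_identity` (mismatch-budget search;
#' the divergence model is substitution-only). Overlapping candidates on the
#' same strand are merged keeping the higher identity. Each candidate then
#' gets leader/splice flags and a strict 3' RSS check attached.
#'
#' @param genome Named character vector of contig sequences.
#' @param seeds Named character vector of known germline V sequences.
#' @param min_identity Identity threshold in (0, 1].
#' @param chain "IGH", "IGK" or "IGL" (fixes the expected RSS class).
#' @param config An [annotation_config()].
#' @return Data frame of candidates: contig, start, end (0-based half-open),
#'   strand, seed, identity, exon_seq (reading sense) plus the structural
#'   flags init_ok, donor_ok, acceptor_ok, rss_ok.
#' @export
find_v_candidates <- function(genome, seeds, min_identity = 0.75,
                              chain = "IGH", config = annotation_config()) {
  stopifnot(length(seeds) > 0, min_identity > 0, min_identity <= 1)
  rows <- list()
  for (contig in names(genome)) {
    cseq <- genome[[contig]]
    for (sname in names(seeds)) {
      seed <- seeds[[sname]]
      L <- nchar(seed)
      if (L < config$v_exon_range[1] || L > config$v_exon_range[2]) next
      max_mm <- floor((1 - min_identity) * L)
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") seed else revcomp(seed)
        m <- seed_matches(cseq, pat, max_mm)
        if (is.null(m) || nrow(m) == 0) next
        m$contig <- contig
        m$strand <- strand
        m$seed <- sname
        m$exon_seq <- if (strand == "+") m$obs else revcomp(m$obs)
        rows[[length(rows) + 1L]] <- m[, c("contig", "start", "end", "strand",
                                           "seed", "identity", "exon_seq")]
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seed = character(0), identity = numeric(0),
                      exon_seq = character(0), stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$contig, cand$start, -cand$identity), , drop = FALSE]
  # merge candidates sharing >= 1 bp on the same strand: keep best identity
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    j <- i + 1L
    while (j <= nrow(cand) && cand$contig[j] == cand$contig[i] &&
           cand$start[j] < cand$end[i]) {
      if (cand$strand[j] == cand$strand[i]) keep[j] <- FALSE
      j <- j + 1L
    }
  }
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  flags <- lapply(seq_len(nrow(cand)), function(i)
    v_structure_flags(genome, cand[i, ], chain, config))
  cand$init_ok <- vapply(flags, `[[`, logical(1), "init_ok")
  cand$donor_ok <- vapply(flags, `[[`, logical(1), "donor_ok")
  cand$acceptor_ok <- vapply(flags, `[[`, logical(1), "acceptor_ok")
  cand$rss_ok <- vapply(flags, `[[`, logical(1), "rss_ok")
  cand
}

# Reading-sense context of a V candidate: [leader][intron][exon][rss window].
v_structure_flags <- function(genome, cand, chain, config) {
  cseq <- genome[[cand$contig]]
  n <- nchar(cseq)
  up <- config$leader_len + config$intron_len
  down <- 45L
  if (cand$strand == "+") {
    ctx_start <- cand$start - up
    ctx_end <- cand$end + down
    if (ctx_start < 0 || ctx_end > n) {
      return(list(init_ok = FALSE, donor_ok = FALSE, acceptor_ok = FALSE,
                  rss_ok = FALSE))
    }
    ctx <- substr(cseq, ctx_start + 1L, ctx_end)
  } else {
    ctx_start <- cand$start - down
    ctx_end <- cand$end + up
    if (ctx_start < 0 || ctx_end > n) {
      return(list(init_ok = FALSE, donor_ok = FALSE, acceptor_ok = FALSE,
                  rss_ok = FALSE))
    }
    ctx <- revcomp(substr(cseq, ctx_start + 1L, ctx_end))
  }
  exon_at <- up
  init_ok <- substr(ctx, 1L, 3L) == "ATG"
  donor_ok <- substr(ctx, config$leader_len + 1L,
                     config$leader_len + 2L) == "GT"
  acceptor_ok <- substr(ctx, exon_at - 1L, exon_at) == "AG"
  exon_len <- cand$end - cand$start
  window <- substr(ctx, exon_at + exon_len + 1L, nchar(ctx))
  exp <- expected_rss(chain, "V")
  hits <- scan_rss(window, exp$class[1], "V-side", config$rss_strict)
  rss_ok <- nrow(hits) > 0 && min(hits$start) <= config$max_rss_gap
  list(init_ok = init_ok, donor_ok = donor_ok, acceptor_ok = acceptor_ok,
       rss_ok = rss_ok)
}

#' Find D gene candidates from dual 12-RSS geometry
#'
#' D cores sit between a J-side 12-RSS upstream (nonamer-spacer-heptamer)
#' and a V-side 12-RSS downstream (heptamer-spacer-nonamer). A candidate is
#' reported when the enclosed core has G fraction at least `min_g_fraction`
#' and length within `length_range`.
#'
#' @param genome Named character vector of contig sequences.
#' @param config An [annotation_config()].
#' @param min_g_fraction Minimum G fraction of the core.
#' @param length_range Core length range (bp).
#' @return Data frame of D candidates (plus strand) with core interval and
#'   flanking RSS spans.
#' @export
find_d_candidates <- function(genome, config = annotation_config(),
                              min_g_fraction = config$d_g_fraction,
                              length_range = config$d_core_range) {
  stopifnot(length_range[1] >= 5, length_range[2] <= 60)
  rows <- list()
  for (contig in names(genome)) {
    cseq <- genome[[contig]]
    left <- scan_rss(cseq, 12L, "J-side", config$rss_strict)
    right <- scan_rss(cseq, 12L, "V-side", config$rss_strict)
    if (nrow(left) == 0 || nrow(right) == 0) next
    left_ends <- unique(left$end)          # heptamer 3' boundary (0-based end)
    right_starts <- unique(right$start)    # heptamer 5' boundary
    for (le in left_ends) {
      for (rs in right_starts) {
        core_len <- rs - le
        if (core_len < length_range[1] || core_len > length_range[2]) next
        core <- substr(cseq, le + 1L, rs)
        gfrac <- sum(strsplit(core, "")[[1]] == "G") / core_len
        if (gfrac < min_g_fraction) next
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig, start = le, end = rs, strand = "+",
          nt_sequence = core, g_fraction = gfrac,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      nt_sequence = character(0), g_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Find J gene candidates downstream of a correctly oriented 5' RSS
#'
#' Scans (plus strand) for J-side RSS signals of the chain's expected spacer
#' class at a relaxed threshold, and reports the `j_length` bases following
#' the heptamer as the J candidate. The conserved motif (WGXG / FGXG) and
#' the donor splice site are recorded as flags but not required; the strict
#' J-heptamer rule is evaluated for later ORF classification.
#'
#' @param genome Named character vector of contig sequences.
#' @param chain "IGH", "IGK" or "IGL".
#' @param config An [annotation_config()].
#' @return Data frame of J candidates with flags motif_ok, donor_ok, rss_ok.
#' @export
find_j_candidates <- function(genome, chain = "IGH",
                              config = annotation_config()) {
  exp <- expected_rss(chain, "J")
  motif <- j_motif_regex(chain)
  rows <- list()
  for (contig in names(genome)) {
    cseq <- genome[[contig]]
    n <- nchar(cseq)
    hits <- scan_rss(cseq, exp$class[1], "J-side", config$rss_relaxed)
    if (nrow(hits) == 0) next
    hep_ends <- unique(hits$end)
    for (he in hep_ends) {
      j_start <- he
      j_end <- he + config$j_length
      if (j_end + 2L > n) next
      jseq <- substr(cseq, j_start + 1L, j_end)
      aa <- translate_nt(jseq)
      motif_ok <- grepl(motif, aa)
      donor_ok <- substr(cseq, j_end + 1L, j_end + 2L) == "GT"
      win_from <- max(1L, he - 45L)
      strict <- scan_rss(substr(cseq, win_from, he),
                         exp$class[1], "J-side", config$rss_strict)
      # require a strict hit whose heptamer ends at this J boundary
      rss_ok <- nrow(strict) > 0 && any(strict$end == he - win_from + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, start = j_start, end = j_end, strand = "+",
        nt_sequence = jseq, aa_sequence = aa, motif_ok = motif_ok,
        donor_ok = donor_ok, rss_ok = rss_ok, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      nt_sequence = character(0), aa_sequence = character(0),
                      motif_ok = logical(0), donor_ok = logical(0),
                      rss_ok = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Find C gene candidates by exon seeding and intron chaining
#'
#' Matches each C exon seed on the plus strand (mismatch budget from
#' `min_identity`), orders hits by position, and chains consecutive exon
#' hits into one gene. A new gene starts when the exon index does not
#' increase or when the gap to the previous exon exceeds `max_intron`.
#' Intron boundaries are checked for GT..AG dinucleotides (recorded in
#' `splice_ok`, consumed by the F/P call).
#'
#' @param genome Named character vector of contig sequences.
#' @param seeds Named character vector of exon seeds; names must end in the
#'   1-based exon index (e.g. "Cex1".."Cex4").
#' @param min_identity Identity threshold.
#' @param config An [annotation_config()].
#' @return List with `genes` (one row per gene: interval, n_exons,
#'   splice_ok, exon_seqs as a semicolon-joined string) and `exons` (one row
#'   per exon).
#' @export
find_c_candidates <- function(genome, seeds, min_identity = 0.75,
                              config = annotation_config()) {
  stopifnot(length(seeds) > 0)
  exon_idx <- as.integer(sub("^.*?(\\d+)$", "\\1", names(seeds)))
  hits <- list()
  for (contig in names(genome)) {
    cseq <- genome[[contig]]
    for (k in seq_along(seeds)) {
      L <- nchar(seeds[[k]])
      m <- seed_matches(cseq, seeds[[k]], floor((1 - min_identity) * L))
      if (is.null(m) || nrow(m) == 0) next
      m$contig <- contig
      m$exon <- exon_idx[k]
      hits[[length(hits) + 1L]] <- m
    }
  }
  empty <- list(genes = data.frame(contig = character(0), start = integer(0),
                                   end = integer(0), strand = character(0),
                                   n_exons = integer(0), splice_ok = logical(0),
                                   exon_seqs = character(0),
                                   stringsAsFactors = FALSE),
                exons = data.frame())
  if (length(hits) == 0) return(empty)
  h <- do.call(rbind, hits)
  h <- h[order(h$contig, h$start), , drop = FALSE]
  gene_id <- integer(nrow(h))
  gid <- 0L
  prev_exon <- Inf
  prev_end <- -Inf
  prev_contig <- ""
  for (i in seq_len(nrow(h))) {
    new_gene <- h$contig[i] != prev_contig || h$exon[i] <= prev_exon ||
      (h$start[i] - prev_end) > config$max_intron
    if (new_gene) gid <- gid + 1L
    gene_id[i] <- gid
    prev_exon <- h$exon[i]; prev_end <- h$end[i]; prev_contig <- h$contig[i]
  }
  h$gene_id <- gene_id
  genes <- do.call(rbind, lapply(split(h, h$gene_id), function(g) {
    cseq <- genome[[g$contig[1]]]
    splice_ok <- TRUE
    if (nrow(g) > 1) {
      for (k in 1:(nrow(g) - 1)) {
        donor <- substr(cseq, g$end[k] + 1L, g$end[k] + 2L)
        acceptor <- substr(cseq, g$start[k + 1] - 1L, g$start[k + 1])
        if (donor != "GT" || acceptor != "AG") splice_ok <- FALSE
      }
    }
    data.frame(contig = g$contig[1], start = min(g$start), end = max(g$end),
               strand = "+", n_exons = nrow(g), splice_ok = splice_ok,
               exon_seqs = paste(g$obs, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  list(genes = genes[order(genes$contig, genes$start), , drop = FALSE],
       exons = h)
}

#' Annotate a locus end to end
#'
#' Runs V/D/J/C candidate detection, F/ORF/P classification, V family
#' clustering and 5'-to-3' naming, returning one annotated gene table.
#'
#' @param genome Named character vector of contig sequences.
#' @param v_seeds Named character vector of germline V seeds.
#' @param c_seeds Named character vector of C exon seeds (names ending in
#'   the exon index).
#' @param chain "IGH", "IGK" or "IGL".
#' @param config An [annotation_config()].
#' @return List with `genes` (annotated, classified, named gene table) and
#'   `c_exons` (per-exon table for C genes).
#' @export
annotate_locus <- function(genome, v_seeds, c_seeds = NULL, chain = "IGH",
                           config = annotation_config()) {
  vs <- find_v_candidates(genome, v_seeds, config$min_identity, chain, config)
  v_rows <- NULL
  if (nrow(vs) > 0) {
    cls <- lapply(seq_len(nrow(vs)), function(i) {
      cand <- as.list(vs[i, ])
      cand$chain <- chain
      classify_v(cand)
    })
    v_rows <- data.frame(
      contig = vs$contig, start = vs$start, end = vs$end, strand = vs$strand,
      segment_type = "V", chain = chain,
      functionality = vapply(cls, `[[`, character(1), "functionality"),
      defects = vapply(cls, function(x) paste(x$defects, collapse = ","),
                       character(1)),
      nt_sequence = vs$exon_seq, identity = vs$identity,
      stringsAsFactors = FALSE)
    v_rows$family <- assign_families(v_rows$nt_sequence, config$min_identity,
                                     seeds = v_seeds, starts = v_rows$start)
  }

  d_rows <- NULL
  if (chain == "IGH") {
    ds <- find_d_candidates(genome, config)
    if (nrow(ds) > 0) {
      d_rows <- data.frame(
        contig = ds$contig, start = ds$start, end = ds$end, strand = "+",
        segment_type = "D", chain = chain, functionality = "F", defects = "",
        nt_sequence = ds$nt_sequence, identity = NA_real_,
        family = NA_character_, stringsAsFactors = FALSE)
    }
  }

  js <- find_j_candidates(genome, chain, config)
  j_rows <- NULL
  if (nrow(js) > 0) {
    cls <- lapply(seq_len(nrow(js)), function(i)
      classify_j(as.list(js[i, ]), chain))
    j_rows <- data.frame(
      contig = js$contig, start = js$start, end = js$end, strand = "+",
      segment_type = "J", chain = chain,
      functionality = vapply(cls, `[[`, character(1), "functionality"),
      defects = vapply(cls, function(x) paste(x$defects, collapse = ","),
                       character(1)),
      nt_sequence = js$nt_sequence, identity = NA_real_,
      family = NA_character_, stringsAsFactors = FALSE)
  }

  c_rows <- NULL
  c_exons <- NULL
  if (!is.null(c_seeds) && length(c_seeds) > 0) {
    cc <- find_c_candidates(genome, c_seeds, config$min_identity, config)
    if (nrow(cc$genes) > 0) {
      cls <- lapply(seq_len(nrow(cc$genes)), function(i) {
        classify_c(list(exon_seqs = strsplit(cc$genes$exon_seqs[i], ";")[[1]],
                        splice_ok = cc$genes$splice_ok[i]))
      })
      c_rows <- data.frame(
        contig = cc$genes$contig, start = cc$genes$start, end = cc$genes$end,
        strand = "+", segment_type = "C", chain = chain,
        functionality = vapply(cls, `[[`, character(1), "functionality"),
        defects = vapply(cls, function(x) paste(x$defects, collapse = ","),
                         character(1)),
        nt_sequence = gsub(";", "", cc$genes$exon_seqs), identity = NA_real_,
        family = NA_character_, stringsAsFactors = FALSE)
      c_exons <- cc$exons
    }
  }

  genes <- do.call(rbind, Filter(Negate(is.null),
                                 list(v_rows, d_rows, j_rows, c_rows)))
  if (is.null(genes) || nrow(genes) == 0) {
    return(list(genes = genes, c_exons = c_exons))
  }
  genes <- name_genes(genes, chain)
  rownames(genes) <- NULL
  list(genes = genes, c_exons = c_exons)
}
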