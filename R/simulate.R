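# Ground-truthed synthetic data: toy germline loci for the annotation modules
# and simulated V(D)J amplicon repertoires for the pipeline/statistics modules.
#
# Identifiability: intergenic and intronic filler is rejection-sampled to be
# free of relaxed-threshold RSS motifs, and junction windows between assembly
# pieces are re-checked, so the only discovery signals present in a generated
# locus are the planted ones. Without this, random RSS look-alikes would make
# exact-recovery validation ill-posed.

#' Specification of a synthetic germline locus
#'
#' @param chain "IGH", "IGK" or "IGL".
#' @param n_v,n_d,n_j,n_c Segment counts (n_d must be 0 outside IGH).
#' @param n_clusters Number of D-J-C clusters the D/J/C genes split into.
#' @param pseudogene_fraction Fraction of V genes (and J, C) planted as
#'   pseudogenes, cycling through all structural defect codes.
#' @param orf_fraction Fraction planted as ORF (RSS/motif defects).
#' @param reversed_v_fraction Fraction of V genes on the minus strand.
#' @param intergenic_range Intergenic spacer length range (bp).
#' @param within_family_rate Per-base substitution rate of each gene away
#'   from its family seed.
#' @param rss_mutation_rate Per-base substitution rate applied to planted
#'   RSS spacers beyond their random draw (0 keeps consensus heptamer and
#'   nonamer exact for F genes).
#' @param seed RNG seed; same seed gives byte-identical output.
#' @return List of class "locus_spec".
#' @export
locus_spec <- function(chain = "IGH", n_v = 30L, n_d = 10L, n_j = 8L,
                       n_c = 9L, n_clusters = 2L,
                       pseudogene_fraction = 0.4, orf_fraction = 0.1,
                       reversed_v_fraction = 0.2,
                       intergenic_range = c(200L, 400L),
                       within_family_rate = 0.05,
                       rss_mutation_rate = 0, seed = 1L) {
  if (chain != "IGH" && n_d > 0) stop("D genes only exist in IGH")
  stopifnot(n_v >= 0, n_j >= 0, n_c >= 0,
            pseudogene_fraction >= 0, pseudogene_fraction <= 1,
            reversed_v_fraction >= 0, reversed_v_fraction <= 1)
  structure(list(chain = chain, n_v = as.integer(n_v), n_d = as.integer(n_d),
                 n_j = as.integer(n_j), n_c = as.integer(n_c),
                 n_clusters = as.integer(n_clusters),
                 pseudogene_fraction = pseudogene_fraction,
                 orf_fraction = orf_fraction,
                 reversed_v_fraction = reversed_v_fraction,
                 intergenic_range = intergenic_range,
                 within_family_rate = within_family_rate,
                 rss_mutation_rate = rss_mutation_rate,
                 seed = as.integer(seed)),
            class = "locus_spec")
}

set_codon <- function(nt, k, codon) {
  paste0(substr(nt, 1L, 3L * (k - 1L)), codon, substr(nt, 3L * k + 1L,
                                                      nchar(nt)))
}

v_p_codes <- c("STOP_CODON", "MISSING_C23", "MISSING_W41", "MISSING_C104",
               "NO_INIT_CODON", "NO_DONOR_SPLICE", "NO_ACCEPTOR_SPLICE")
j_orf_codes <- c("NO_WGXG", "NO_J_HEPTAMER")

draw_spacer_len <- function(class) {
  class + sample(c(-1L, 0L, 1L), 1L, prob = c(0.15, 0.7, 0.15))
}

rss_v_side <- function(class, heptamer = "CACAGTG", rate = 0) {
  s <- draw_spacer_len(class)
  spacer <- random_dna(s)
  paste0(heptamer, spacer, "ACAAAAACC")
}

rss_j_side <- function(class, heptamer = "CACAGTG", rate = 0) {
  s <- draw_spacer_len(class)
  paste0("ACAAAAACC", random_dna(s), heptamer)
}

# Relaxed J-side discovery hits of a sequence: absolute heptamer end
# positions (0-based, half-open ends).
j_scan_hep_ends <- function(seq, class) {
  hits <- scan_rss(seq, class, "J-side", rss_config_relaxed())
  unique(hits$end)
}

build_v_block <- function(tpl, seed_nt, family, defect, spec, j_class) {
  anchors <- unname(tpl$anchors)
  # orientation is decided once: retries must not flip it, or differential
  # rejection rates would bias the realised reversed fraction
  reversed <- stats::runif(1) < spec$reversed_v_fraction
  for (try in 1:60) {
    exon <- mutate_coding(seed_nt, spec$within_family_rate,
                          protect_aa = anchors)
    if (!rss_clean(exon)) next
    defects <- if (is.na(defect)) character(0) else defect
    if (identical(defect, "STOP_CODON")) {
      k <- sample(setdiff(30:80, anchors), 1L)
      exon <- set_codon(exon, k, "TGA")
    } else if (identical(defect, "MISSING_C23")) {
      exon <- set_codon(exon, 23L, "CGT")
    } else if (identical(defect, "MISSING_W41")) {
      exon <- set_codon(exon, 41L, "CGG")
    } else if (identical(defect, "MISSING_C104")) {
      exon <- set_codon(exon, 104L, "AGT")
    }
    leader_start <- if (identical(defect, "NO_INIT_CODON")) "ACG" else "ATG"
    leader <- paste0(leader_start, clean_random_dna(tpl$leader_len - 3L))
    donor <- if (identical(defect, "NO_DONOR_SPLICE")) "GA" else "GT"
    acceptor <- if (identical(defect, "NO_ACCEPTOR_SPLICE")) "AC" else "AG"
    intron <- paste0(donor, clean_random_dna(tpl$intron_len - 4L), acceptor)
    hep <- if (identical(defect, "NO_RSS")) "CTCAGTG" else "CACAGTG"
    exp <- expected_rss(tpl$chain, "V")
    rss <- rss_v_side(exp$class[1], heptamer = hep)
    block <- paste0(leader, intron, exon, rss)
    final <- if (reversed) revcomp(block) else block
    if (length(j_scan_hep_ends(final, j_class)) > 0) next
    exon_off <- tpl$leader_len + tpl$intron_len
    bl <- nchar(block)
    if (reversed) {
      rel_start <- bl - (exon_off + nchar(exon))
      rel_end <- bl - exon_off
    } else {
      rel_start <- exon_off
      rel_end <- exon_off + nchar(exon)
    }
    functionality <- if (is.na(defect)) "F"
      else if (defect == "NO_RSS") "ORF" else "P"
    return(list(seq = final, rel_start = rel_start, rel_end = rel_end,
                strand = if (reversed) "-" else "+",
                nt_sequence = exon, functionality = functionality,
                defects = paste(defects, collapse = ","), family = family,
                hep_ends = integer(0)))
  }
  stop("could not build a clean V block")
}

build_d_block <- function(core, chain, j_class) {
  for (try in 1:60) {
    left <- rss_j_side(12L)
    right <- rss_v_side(12L)
    block <- paste0(left, core, right)
    if (length(j_scan_hep_ends(block, j_class)) > 0) next
    return(list(seq = block, rel_start = nchar(left),
                rel_end = nchar(left) + nchar(core), strand = "+",
                nt_sequence = core, functionality = "F", defects = "",
                family = NA_character_, hep_ends = integer(0)))
  }
  stop("could not build a clean D block")
}

build_j_block <- function(tpl, functionality, defect, spec, j_class,
                          prev_j = character(0)) {
  motif_aa <- 8:11
  suffix_dist <- function(a, b) {
    av <- strsplit(substr(a, 13L, nchar(a)), "")[[1]]
    bv <- strsplit(substr(b, 13L, nchar(b)), "")[[1]]
    sum(av != bv)
  }
  for (try in 1:200) {
    # J genes diverge faster than V family members here so that every J is
    # identifiable from its trim-surviving 3' region (pairwise distance >= 4)
    jseq <- mutate_coding(tpl$j_nt, 0.15, protect_aa = motif_aa)
    if (length(prev_j) > 0 &&
        any(vapply(prev_j, suffix_dist, integer(1), a = jseq) < 4L)) next
    if (identical(defect, "NO_WGXG")) {
      jseq <- set_codon(jseq, 8L, "TCG")   # W -> S
      if (grepl(tpl$j_motif, translate_nt(jseq))) next
    } else {
      if (!grepl(tpl$j_motif, translate_nt(jseq))) next
    }
    if (!rss_clean(jseq)) next
    hep <- if (identical(defect, "NO_J_HEPTAMER")) "CTCAGTG" else "CACAGTG"
    rss <- rss_j_side(j_class, heptamer = hep)
    donor <- if (identical(defect, "NO_DONOR_SPLICE")) "CA" else "GT"
    block <- paste0(rss, jseq, donor)
    hep_end_rel <- nchar(rss)
    ends <- j_scan_hep_ends(block, j_class)
    if (!setequal(ends, hep_end_rel)) next
    return(list(seq = block, rel_start = nchar(rss),
                rel_end = nchar(rss) + nchar(jseq), strand = "+",
                nt_sequence = jseq, functionality = functionality,
                defects = if (is.na(defect)) "" else defect,
                family = NA_character_, hep_ends = hep_end_rel))
  }
  stop("could not build a clean J block")
}

build_c_block <- function(tpl, n_exons, defect, spec, j_class) {
  for (try in 1:60) {
    exons <- vapply(seq_len(n_exons), function(k) {
      mutate_coding(tpl$c_exons[[k]], spec$within_family_rate)
    }, character(1))
    if (!all(vapply(exons, rss_clean, logical(1)))) next
    if (identical(defect, "STOP_CODON")) {
      tgt <- min(2L, n_exons)
      k <- (nchar(exons[tgt]) %/% 3L) %/% 2L
      exons[tgt] <- set_codon(exons[tgt], k, "TAA")
    }
    introns <- if (n_exons > 1) {
      vapply(seq_len(n_exons - 1L), function(k)
        paste0("GT", clean_random_dna(120L), "AG"), character(1))
    } else character(0)
    if (identical(defect, "NO_ACCEPTOR_SPLICE")) {
      stopifnot(n_exons > 1)
      introns[1] <- paste0("GT", substr(introns[1], 3L,
                                        nchar(introns[1]) - 2L), "AC")
    }
    pieces <- character(0)
    rel <- integer(0)
    pos <- 0L
    exon_bounds <- matrix(0L, nrow = n_exons, ncol = 2L)
    for (k in seq_len(n_exons)) {
      exon_bounds[k, ] <- c(pos, pos + nchar(exons[k]))
      pieces <- c(pieces, exons[k])
      pos <- pos + nchar(exons[k])
      if (k < n_exons) {
        pieces <- c(pieces, introns[k])
        pos <- pos + nchar(introns[k])
      }
    }
    block <- paste(pieces, collapse = "")
    if (length(j_scan_hep_ends(block, j_class)) > 0) next
    functionality <- if (is.na(defect)) "F" else "P"
    return(list(seq = block, rel_start = 0L, rel_end = nchar(block),
                strand = "+", nt_sequence = paste(exons, collapse = ""),
                functionality = functionality,
                defects = if (is.na(defect)) "" else
                  (if (defect == "STOP_CODON") "STOP_CODON"
                   else "NO_ACCEPTOR_SPLICE"),
                family = NA_character_, hep_ends = integer(0),
                exon_bounds = exon_bounds, n_exons = n_exons))
  }
  stop("could not build a clean C block")
}

split_counts <- function(n, k) {
  diff(round(seq(0, n, length.out = k + 1L)))
}

build_locus_once <- function(spec) {
  tpl <- ig_templates(spec$chain)
  j_class <- expected_rss(spec$chain, "J")$class[1]
  contig <- "locus1"

  # plan functionality classes
  n_vp <- round(spec$pseudogene_fraction * spec$n_v)
  n_vorf <- round(spec$orf_fraction * spec$n_v)
  v_defects <- c(rep_len(v_p_codes, n_vp),
                 rep("NO_RSS", n_vorf),
                 rep(NA_character_, spec$n_v - n_vp - n_vorf))
  v_defects <- sample(v_defects)
  v_families <- sample(names(tpl$v_seeds), spec$n_v, replace = TRUE)

  n_jp <- if (spec$n_j > 0) max(0L, round(spec$pseudogene_fraction / 2 *
                                          spec$n_j)) else 0L
  n_jorf <- if (spec$n_j > 0) min(spec$n_j - n_jp,
                                  max(length(j_orf_codes),
                                      round(0.25 * spec$n_j))) else 0L
  j_defects <- c(rep("NO_DONOR_SPLICE", n_jp),
                 rep_len(j_orf_codes, n_jorf),
                 rep(NA_character_, spec$n_j - n_jp - n_jorf))
  j_defects <- sample(j_defects)

  n_cp <- round(0.2 * spec$n_c)
  c_defects <- sample(c(rep_len(c("STOP_CODON", "NO_ACCEPTOR_SPLICE"), n_cp),
                        rep(NA_character_, spec$n_c - n_cp)))
  c_exon_counts <- sample(1:4, spec$n_c, replace = TRUE)
  # splice-defect genes need at least 2 exons
  c_exon_counts[!is.na(c_defects) & c_defects == "NO_ACCEPTOR_SPLICE" &
                  c_exon_counts < 2] <- 2L

  d_cores <- tpl$d_cores[seq_len(spec$n_d)]
  d_split <- split_counts(spec$n_d, spec$n_clusters)
  j_split <- split_counts(spec$n_j, spec$n_clusters)
  c_split <- split_counts(spec$n_c, spec$n_clusters)

  # assembly state
  genome_str <- ""
  cur <- 0L
  planted_heps <- integer(0)
  truth <- list()
  exon_truth <- list()

  junction_ok <- function(piece, piece_heps_rel) {
    # the whole new piece plus the previous tail may contain no relaxed
    # J-side discovery hits beyond the planted ones
    tail_len <- min(cur, 60L)
    prev_tail <- if (tail_len > 0)
      substr(genome_str, cur - tail_len + 1L, cur) else ""
    window <- paste0(prev_tail, piece)
    offset <- cur - nchar(prev_tail)
    ends <- j_scan_hep_ends(window, j_class) + offset
    allowed <- c(planted_heps, piece_heps_rel + cur)
    all(ends %in% allowed)
  }

  append_piece <- function(builder) {
    for (try in 1:40) {
      p <- builder()
      heps <- p$hep_ends %||% integer(0)
      if (!junction_ok(p$seq, heps)) next
      genome_str <<- paste0(genome_str, p$seq)
      if (length(heps) > 0) planted_heps <<- c(planted_heps, heps + cur)
      p$abs_start <- cur
      cur <<- cur + nchar(p$seq)
      return(p)
    }
    stop("could not place piece without spurious junction signals")
  }

  filler_seq <- function() {
    len <- sample(spec$intergenic_range[1]:spec$intergenic_range[2], 1L)
    clean_random_dna(len)
  }

  filler <- function() list(seq = filler_seq(), hep_ends = integer(0))

  # a gene is placed together with its preceding intergenic spacer so a
  # spurious signal straddling either boundary can be resampled away
  with_filler <- function(builder) {
    function() {
      f <- filler_seq()
      b <- builder()
      off <- nchar(f)
      b$seq <- paste0(f, b$seq)
      b$rel_start <- b$rel_start + off
      b$rel_end <- b$rel_end + off
      b$hep_ends <- (b$hep_ends %||% integer(0)) + off
      if (!is.null(b$exon_bounds)) b$exon_bounds <- b$exon_bounds + off
      b
    }
  }

  record_gene <- function(p, segment_type) {
    truth[[length(truth) + 1L]] <<- data.frame(
      contig = contig, start = p$abs_start + p$rel_start,
      end = p$abs_start + p$rel_end, strand = p$strand,
      segment_type = segment_type, chain = spec$chain,
      functionality = p$functionality, defects = p$defects,
      nt_sequence = p$nt_sequence,
      family = if (!is.na(p$family)) sub("^fam", "", p$family)
               else NA_character_,
      stringsAsFactors = FALSE)
    if (segment_type == "C") {
      eb <- p$exon_bounds
      exon_truth[[length(exon_truth) + 1L]] <<- data.frame(
        contig = contig, gene_start = p$abs_start + p$rel_start,
        exon = seq_len(nrow(eb)), start = p$abs_start + eb[, 1],
        end = p$abs_start + eb[, 2], stringsAsFactors = FALSE)
    }
  }

  for (i in seq_len(spec$n_v)) {
    fam <- v_families[i]
    p <- append_piece(with_filler(function()
      build_v_block(tpl, tpl$v_seeds[[fam]], fam, v_defects[i], spec,
                    j_class)))
    record_gene(p, "V")
  }
  di <- 0L; ji <- 0L; ci <- 0L
  j_nts <- character(0)
  for (k in seq_len(spec$n_clusters)) {
    for (m in seq_len(d_split[k])) {
      di <- di + 1L
      core <- d_cores[[di]]
      p <- append_piece(with_filler(function()
        build_d_block(core, spec$chain, j_class)))
      record_gene(p, "D")
    }
    for (m in seq_len(j_split[k])) {
      ji <- ji + 1L
      def <- j_defects[ji]
      fun <- if (is.na(def)) "F" else if (def == "NO_DONOR_SPLICE") "P"
             else "ORF"
      p <- append_piece(with_filler(function()
        build_j_block(tpl, fun, def, spec, j_class, prev_j = j_nts)))
      j_nts <- c(j_nts, p$nt_sequence)
      record_gene(p, "J")
    }
    for (m in seq_len(c_split[k])) {
      ci <- ci + 1L
      def <- c_defects[ci]
      nex <- c_exon_counts[ci]
      p <- append_piece(with_filler(function()
        build_c_block(tpl, nex, def, spec, j_class)))
      record_gene(p, "C")
    }
  }
  append_piece(filler)

  genome_seq <- genome_str
  genes <- do.call(rbind, truth)
  genes <- name_genes(genes, spec$chain)
  rownames(genes) <- NULL
  c_seeds <- vapply(seq_along(tpl$c_exons), function(k) tpl$c_exons[[k]],
                    character(1))
  names(c_seeds) <- paste0("Cex", seq_along(tpl$c_exons))
  list(genome = stats::setNames(genome_seq, contig), genes = genes,
       c_exons = if (length(exon_truth) > 0) do.call(rbind, exon_truth)
                 else NULL,
       v_seeds = tpl$v_seeds, c_seeds = c_seeds, spec = spec,
       planted_hep_ends = sort(planted_heps))
}

verify_locus <- function(locus, config = annotation_config()) {
  spec <- locus$spec
  genome <- locus$genome
  genes <- locus$genes
  j_class <- expected_rss(spec$chain, "J")$class[1]
  # planted J discovery signals and no others
  ends <- j_scan_hep_ends(genome[[1]], j_class)
  j_rows <- genes[genes$segment_type == "J", , drop = FALSE]
  if (!setequal(ends, j_rows$start)) return(FALSE)
  # D detection yields exactly the planted cores
  if (spec$n_d > 0) {
    ds <- find_d_candidates(genome, config)
    d_rows <- genes[genes$segment_type == "D", , drop = FALSE]
    if (nrow(ds) != nrow(d_rows)) return(FALSE)
    if (!all(ds$start == d_rows$start & ds$end == d_rows$end)) return(FALSE)
  }
  # V seeding finds exactly the planted exons
  vs <- seed_match_set(genome[[1]], locus$v_seeds, config$min_identity)
  v_rows <- genes[genes$segment_type == "V", , drop = FALSE]
  key_truth <- paste(v_rows$start, v_rows$end, v_rows$strand)
  key_found <- paste(vs$start, vs$end, vs$strand)
  setequal(key_truth, key_found)
}

seed_match_set <- function(cseq, seeds, min_identity) {
  rows <- list()
  for (sname in names(seeds)) {
    seed <- seeds[[sname]]
    max_mm <- floor((1 - min_identity) * nchar(seed))
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seed else revcomp(seed)
      m <- seed_matches(cseq, pat, max_mm)
      if (is.null(m) || nrow(m) == 0) next
      m$strand <- strand
      rows[[length(rows) + 1L]] <- m[, c("start", "end", "strand")]
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  out <- unique(do.call(rbind, rows))
  out
}

#' Generate a synthetic germline locus with ground truth
#'
#' Plants V (leader + ATG, GT..AG intron, ~330 bp exon, 3' RSS), D (G-rich
#' core with dual 12-RSS), J (5' RSS, conserved motif, 3' donor) and
#' multi-exon C genes in RSS-clean random background, with the requested
#' pseudogene/ORF mixture realised as concrete sequence defects that are
#' recorded in the truth table. Deterministic given `spec$seed`.
#'
#' @param spec A [locus_spec()].
#' @return List with `genome` (named character vector), `genes` (truth
#'   table in the annotated-gene layout, named via [name_genes()]),
#'   `c_exons` (truth exon intervals of C genes), `v_seeds`/`c_seeds` (the
#'   family/exon seed sequences an annotator would use), and `spec`.
#' @export
generate_locus <- function(spec) {
  for (attempt in 0:49) {
    seed <- (spec$seed + 77003L * attempt) %% 2147483647L
    locus <- with_seed(seed, build_locus_once(spec))
    if (verify_locus(locus)) return(locus)
  }
  stop("failed to generate a verifiable locus")
}

#' Specification of a simulated amplicon repertoire
#'
#' @param reference A segmented germline reference from [build_reference()].
#' @param n_reads Number of reads to draw.
#' @param n_clonotypes Number of distinct rearrangements to generate.
#' @param v_usage Optional named weight vector over productive V genes.
#' @param d_prob Probability a rearrangement includes a D segment.
#' @param trim_p Geometric(p) parameter of exonucleolytic trimming at the
#'   V 3' and J 5' ends (and D ends, capped at 2).
#' @param max_v_del,max_j_del Trimming caps keeping the CDR3 anchors intact.
#' @param ins_lambda Total non-templated insertion length is the sum of two
#'   Poisson(ins_lambda/2) draws (V-D and D-J sides).
#' @param mutation_rate Per-base substitution rate applied to each read.
#' @param amplicon Amplicon length window (bp), the gel-excision band.
#' @param abundance_sdlog Log-normal sdlog of clonotype abundance weights.
#' @param ultralong_fraction Fraction of clonotypes built with an extended
#'   D-like core producing ultra-long (> 50 aa) CDR3s.
#' @param seed RNG seed.
#' @return List of class "repertoire_spec".
#' @export
repertoire_spec <- function(reference, n_reads = 10000L, n_clonotypes = 500L,
                            v_usage = NULL, d_prob = 0.8, trim_p = 0.5,
                            max_v_del = 12L, max_j_del = 9L, ins_lambda = 4,
                            mutation_rate = 0, amplicon = c(200L, 300L),
                            abundance_sdlog = 1.2, ultralong_fraction = 0,
                            seed = 1L) {
  stopifnot(amplicon[1] >= 150, amplicon[2] <= 400)
  structure(list(reference = reference, n_reads = as.integer(n_reads),
                 n_clonotypes = as.integer(n_clonotypes), v_usage = v_usage,
                 d_prob = d_prob, trim_p = trim_p,
                 max_v_del = as.integer(max_v_del),
                 max_j_del = as.integer(max_j_del), ins_lambda = ins_lambda,
                 mutation_rate = mutation_rate, amplicon = amplicon,
                 abundance_sdlog = abundance_sdlog,
                 ultralong_fraction = ultralong_fraction,
                 seed = as.integer(seed)),
            class = "repertoire_spec")
}

rgeom_capped <- function(n, p, cap) pmin(stats::rgeom(n, p), cap)

# Longest exact substring of `middle` found in any of `d_seqs` (independent
# of the pipeline's assign_d; used for canonical truth bookkeeping).
truth_d_match <- function(middle, d_seqs, min_core = 7L) {
  best_len <- 0L; best_d <- ""
  nm <- nchar(middle)
  if (nm >= min_core) {
    for (di in seq_along(d_seqs)) {
      d <- d_seqs[[di]]
      nd <- nchar(d)
      cap <- min(nm, nd)
      found <- 0L
      for (L in seq(cap, min_core)) {
        hit <- FALSE
        for (s in 1:(nm - L + 1L)) {
          if (grepl(substr(middle, s, s + L - 1L), d, fixed = TRUE)) {
            hit <- TRUE; break
          }
        }
        if (hit) { found <- L; break }
      }
      if (found > best_len) { best_len <- found; best_d <- names(d_seqs)[di] }
    }
  }
  list(d = best_d, len = best_len)
}

ultralong_core <- function() {
  cods <- c("GGT", "GGA", "GGG", "TAT", "GAT", "AGT", "TGT", "GCT", "ACT")
  n <- sample(40:55, 1L)
  paste(sample(cods, n, replace = TRUE), collapse = "")
}

#' Simulate a V(D)J amplicon repertoire with ground truth
#'
#' Each rearrangement is built as: sampled V trimmed at the 3' end
#' (geometric), non-templated insertions (Poisson), an optionally trimmed D
#' core, more insertions, then a 5'-trimmed J. Junction bookkeeping
#' (v_deletions, j_deletions, n_insertions, D call) is recorded in
#' canonical maximal-attribution form: bases at the junction that happen to
#' match the germline continuation are credited to the germline segment,
#' V first, then J, and the D call is the longest exact substring match,
#' matching the convention of the read-processing pipeline so that truth
#' and recovered tables are comparable base for base. Reads are drawn over
#' clonotypes with log-normal abundance weights, clipped to the amplicon
#' window around the junction, and optionally point-mutated.
#'
#' @param spec A [repertoire_spec()].
#' @return List with `reads` (named character vector), `clonotypes` (truth
#'   table: cdr3_nt, cdr3_aa, count, v_gene, d_gene, j_gene, v_del, j_del,
#'   n_ins, productive), `read_truth` (read id -> clonotype id and V/J) and
#'   `spec`.
#' @export
simulate_repertoire <- function(spec) {
  with_seed(spec$seed, simulate_repertoire_impl(spec))
}

simulate_repertoire_impl <- function(spec) {
  ref <- spec$reference
  v <- ref$v[ref$v$productive & !is.na(ref$v$anchor_nt), , drop = FALSE]
  j <- ref$j[ref$j$productive & !is.na(ref$j$anchor_nt), , drop = FALSE]
  d <- ref$d
  stopifnot(nrow(v) > 0, nrow(j) > 0)
  v_w <- rep(1, nrow(v))
  if (!is.null(spec$v_usage)) {
    v_w <- spec$v_usage[v$name]
    v_w[is.na(v_w)] <- 0
  }
  d_seqs <- stats::setNames(as.list(d$nt_sequence), d$name)

  n <- spec$n_clonotypes
  clono <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      vi <- sample.int(nrow(v), 1L, prob = v_w)
      ji <- sample.int(nrow(j), 1L)
      v_nt <- v$nt_sequence[vi]; Lv <- nchar(v_nt)
      j_nt <- j$nt_sequence[ji]; Lj <- nchar(j_nt)
      v_anchor <- v$anchor_nt[vi]      # 0-based codon start of C104
      j_anchor <- j$anchor_nt[ji]      # 0-based codon start of W/F
      v_del <- rgeom_capped(1L, spec$trim_p, spec$max_v_del)
      j_del <- rgeom_capped(1L, spec$trim_p, spec$max_j_del)
      n1 <- stats::rpois(1L, spec$ins_lambda / 2)
      n2 <- stats::rpois(1L, spec$ins_lambda / 2)
      ul <- stats::runif(1) < spec$ultralong_fraction
      if (ul) {
        d_seq <- ultralong_core()
        d_name_planted <- ""
      } else if (stats::runif(1) < spec$d_prob && length(d_seqs) > 0) {
        di <- sample.int(length(d_seqs), 1L)
        core <- d_seqs[[di]]
        t5 <- rgeom_capped(1L, spec$trim_p, 2L)
        t3 <- rgeom_capped(1L, spec$trim_p, 2L)
        d_seq <- substr(core, 1L + t5, nchar(core) - t3)
        d_name_planted <- names(d_seqs)[di]
      } else {
        d_seq <- ""
        d_name_planted <- ""
      }
      ins1 <- if (n1 > 0) random_dna(n1) else ""
      ins2 <- if (n2 > 0) random_dna(n2) else ""
      v_part <- substr(v_nt, 1L, Lv - v_del)
      j_part <- substr(j_nt, j_del + 1L, Lj)
      if (ul) {
        # keep the junction in frame so ultra-long clones can be productive
        len_mid <- nchar(ins1) + nchar(d_seq) + nchar(ins2)
        cdr3_len <- (nchar(v_part) - v_anchor) + len_mid +
          (j_anchor + 3L - j_del)
        pad <- (3L - (cdr3_len %% 3L)) %% 3L
        if (pad > 0) ins2 <- paste0(ins2, random_dna(pad))
      }
      core_seq <- paste0(v_part, ins1, d_seq, ins2, j_part)
      # canonical maximal attribution: extend V, then J
      vc <- nchar(v_part)
      t <- 0L
      while (vc + t < Lv && vc + t < nchar(core_seq) &&
             substr(core_seq, vc + t + 1L, vc + t + 1L) ==
             substr(v_nt, vc + t + 1L, vc + t + 1L)) t <- t + 1L
      v_end <- vc + t
      can_v_del <- Lv - v_end
      jstart <- nchar(core_seq) - (Lj - j_del) + 1L
      # leftward extension starts at the J anchor (same rule as the pipeline)
      g <- j_anchor + 1L
      r <- jstart + (j_anchor + 1L) - (j_del + 1L)
      while (g > 1L && r - 1L > v_end &&
             substr(core_seq, r - 1L, r - 1L) ==
             substr(j_nt, g - 1L, g - 1L)) {
        g <- g - 1L
        r <- r - 1L
      }
      j_start <- r
      can_j_del <- g - 1L
      middle <- if (j_start - 1L >= v_end + 1L)
        substr(core_seq, v_end + 1L, j_start - 1L) else ""
      dm <- truth_d_match(middle, d_seqs)
      n_ins <- nchar(middle) - dm$len
      # CDR3: C104 codon start through the end of the J W/F codon
      cdr3_start <- v_anchor + 1L
      cdr3_end <- j_start + (j_anchor + 3L - can_j_del) - 1L
      if (v_end < v_anchor + 3L) next      # anchor trimmed away; redraw
      if (cdr3_end > nchar(core_seq)) next
      cdr3_nt <- substr(core_seq, cdr3_start, cdr3_end)
      cdr3_aa <- translate_nt(cdr3_nt)
      productive <- nchar(cdr3_nt) %% 3L == 0L &&
        !grepl("*", cdr3_aa, fixed = TRUE)
      if (ul && !productive) next
      clono[[i]] <- data.frame(
        clonotype_id = i, v_gene = v$name[vi], d_gene = dm$d,
        j_gene = j$name[ji], cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
        v_del = can_v_del, j_del = can_j_del, n_ins = n_ins,
        productive = productive, core_seq = core_seq,
        stringsAsFactors = FALSE)
      break
    }
    if (is.null(clono[[i]])) stop("failed to build clonotype ", i)
  }
  clono <- do.call(rbind, clono)

  w <- stats::rlnorm(n, meanlog = 0, sdlog = spec$abundance_sdlog)
  draw <- sample.int(n, spec$n_reads, replace = TRUE, prob = w)
  counts <- tabulate(draw, nbins = n)

  reads <- character(spec$n_reads)
  for (r in seq_len(spec$n_reads)) {
    cl <- draw[r]
    core_seq <- clono$core_seq[cl]
    target <- sample(spec$amplicon[1]:spec$amplicon[2], 1L)
    start <- max(1L, nchar(core_seq) - target + 1L)
    rd <- substr(core_seq, start, nchar(core_seq))
    if (spec$mutation_rate > 0) {
      nmut <- stats::rbinom(1L, nchar(rd), spec$mutation_rate)
      if (nmut > 0) {
        pos <- sample.int(nchar(rd), nmut)
        vch <- strsplit(rd, "")[[1]]
        for (pp in pos) vch[pp] <- sample(setdiff(c("A", "C", "G", "T"),
                                                  vch[pp]), 1L)
        rd <- paste(vch, collapse = "")
      }
    }
    reads[r] <- rd
  }
  names(reads) <- sprintf("read%06d", seq_len(spec$n_reads))

  drawn <- clono[counts > 0, , drop = FALSE]
  drawn$count <- counts[counts > 0]
  # aggregate identical (cdr3_nt, V, J) rearrangements like the pipeline does
  key <- paste(drawn$cdr3_nt, drawn$v_gene, drawn$j_gene, sep = "|")
  agg <- lapply(split(seq_len(nrow(drawn)), key), function(idx) {
    row <- drawn[idx[1], , drop = FALSE]
    row$count <- sum(drawn$count[idx])
    row
  })
  truth <- do.call(rbind, agg)
  truth <- truth[order(-truth$count, truth$cdr3_nt), , drop = FALSE]
  rownames(truth) <- NULL
  read_truth <- data.frame(read_id = names(reads), clonotype_id = draw,
                           v_gene = clono$v_gene[draw],
                           j_gene = clono$j_gene[draw],
                           stringsAsFactors = FALSE)
  list(reads = reads,
       clonotypes = truth[, c("cdr3_nt", "cdr3_aa", "count", "v_gene",
                              "d_gene", "j_gene", "v_del", "j_del", "n_ins",
                              "productive")],
       read_truth = read_truth, spec = spec)
}
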