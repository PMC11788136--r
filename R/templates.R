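# Built-in synthetic germline templates. These are structurally valid V/D/J/C
# template sequences (anchors, motifs, splice geometry) constructed in code so
# that locus generation and the repertoire simulator need no external
# downloads. They are synthetic stand-ins, not sequences of any real species.

.igloci_env <- new.env(parent = emptyenv())

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# One deterministic codon per amino acid (used to back-translate templates),
# plus a synonymous alternative used to recode away RSS look-alikes.
codon_of <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA", E = "GAA",
  G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA", M = "ATG", F = "TTT",
  P = "CCT", S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")
alt_codon_of <- c(
  A = "GCA", R = "CGA", N = "AAC", D = "GAC", C = "TGC", Q = "CAG", E = "GAG",
  G = "GGA", H = "CAC", I = "ATC", L = "CTT", K = "AAG", M = "ATG", F = "TTC",
  P = "CCA", S = "TCA", T = "ACA", W = "TGG", Y = "TAC", V = "GTA")

back_translate <- function(aa) {
  paste(codon_of[strsplit(aa, "")[[1]]], collapse = "")
}

#' Is a sequence free of relaxed RSS motifs on both strands?
#' @keywords internal
both_strand_clean <- function(seq) {
  rss_clean(seq) && rss_clean(revcomp(seq))
}

# Synonymously recode codons overlapping RSS look-alikes (either strand)
# until the coding sequence is clean on both strands. Deterministic.
repair_coding <- function(nt, protect_aa = integer(0)) {
  aa <- strsplit(translate_nt(nt), "")[[1]]
  cfg <- rss_config_relaxed()
  for (iter in 1:200) {
    hit_span <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") nt else revcomp(nt)
      for (cls in c(12L, 23L)) {
        for (side in c("V-side", "J-side")) {
          h <- scan_rss(s, cls, side, cfg)
          if (nrow(h) > 0) {
            span <- c(h$start[1], h$end[1])
            if (strand == "-") span <- c(nchar(nt) - span[2],
                                         nchar(nt) - span[1])
            hit_span <- span
            break
          }
        }
        if (!is.null(hit_span)) break
      }
      if (!is.null(hit_span)) break
    }
    if (is.null(hit_span)) return(nt)
    codons <- unique(pmin(pmax((hit_span[1]):(hit_span[2] - 1L) %/% 3L + 1L,
                               1L), length(aa)))
    codons <- setdiff(codons, protect_aa)
    codons <- codons[codon_of[aa[codons]] != alt_codon_of[aa[codons]]]
    if (length(codons) == 0) {
      stop("cannot repair coding sequence away from RSS motif")
    }
    # toggle a random recodable codon in the offending span; the random
    # choice avoids deterministic flip cycles
    k <- codons[sample.int(length(codons), 1L)]
    cur <- substr(nt, 3L * k - 2L, 3L * k)
    alt <- if (cur == codon_of[[aa[k]]]) alt_codon_of[[aa[k]]]
           else codon_of[[aa[k]]]
    nt <- set_codon(nt, k, alt)
  }
  stop("coding sequence repair did not converge")
}

stop_codons <- c("TAA", "TAG", "TGA")

has_inframe_stop <- function(nt) {
  n <- nchar(nt) %/% 3L
  cods <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  any(cods %in% stop_codons)
}

#' Is a sequence free of relaxed-threshold RSS motifs?
#' @keywords internal
rss_clean <- function(seq) {
  cfg <- rss_config_relaxed()
  for (cls in c(12L, 23L)) {
    for (side in c("V-side", "J-side")) {
      if (nrow(scan_rss(seq, cls, side, cfg)) > 0) return(FALSE)
    }
  }
  TRUE
}

#' Random DNA with no relaxed RSS motif (rejection sampled)
#' @keywords internal
clean_random_dna <- function(n, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(n)
    if (rss_clean(s)) return(s)
  }
  stop("could not draw RSS-clean random sequence of length ", n)
}

#' Substitute bases in a coding sequence without creating stops
#'
#' Mutates each unprotected position with the given per-base probability,
#' then repairs any codon that became a stop or that fell in a protected
#' codon. Operates in frame 0.
#' @keywords internal
mutate_coding <- function(nt, rate, protect_aa = integer(0)) {
  bases <- c("A", "C", "G", "T")
  v <- strsplit(nt, "")[[1]]
  n_cod <- length(v) %/% 3L
  protect_pos <- unlist(lapply(protect_aa, function(k) (3L * k - 2L):(3L * k)))
  hit <- which(stats::runif(length(v)) < rate)
  hit <- setdiff(hit, protect_pos)
  for (i in hit) {
    v[i] <- sample(setdiff(bases, v[i]), 1L)
  }
  # repair stop codons introduced by mutation
  for (k in seq_len(n_cod)) {
    idx <- (3L * k - 2L):(3L * k)
    while (paste(v[idx], collapse = "") %in% stop_codons) {
      j <- idx[sample.int(3L, 1L)]
      if (j %in% protect_pos) j <- idx[1L]
      v[j] <- sample(setdiff(bases, v[j]), 1L)
    }
  }
  paste(v, collapse = "")
}

# The V template: 110 codons; IMGT-style anchors C23, W41, L89, C104 under
# the identity numbering used by number_v(). Region boundaries follow the
# IMGT convention FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104.
v_template_aa <- function() {
  fr1 <- "QVQLRESGPSLVKPSQTLSLTSCTVG"          # 26 aa, C at 23
  cdr1 <- "GFSLSTSGVGVG"                        # 12 aa
  fr2 <- "IRWVRQAPGKGLEWVSA"                    # 17 aa, W at 41
  cdr2 <- "AISGSGGSTY"                          # 10 aa
  fr3 <- paste0("YADSVKGRFTISRDNSKNTLYLQL",     # 24 aa, L at 89
                "NSLRAEDTAVYFAT",               # 14 aa
                "C")                            # C at 104
  post <- "ARDAGY"                              # germline CDR3 start
  aa <- paste0(fr1, cdr1, fr2, cdr2, fr3, post)
  stopifnot(nchar(aa) == 110L,
            substr(aa, 23, 23) == "C", substr(aa, 41, 41) == "W",
            substr(aa, 89, 89) == "L", substr(aa, 104, 104) == "C")
  aa
}

# IMGT-style region boundaries (aa positions, inclusive) on the template.
v_region_bounds <- function() {
  list(FR1 = c(1L, 26L), CDR1 = c(27L, 38L), FR2 = c(39L, 55L),
       CDR2 = c(56L, 65L), FR3 = c(66L, 104L))
}

v_anchor_positions <- function() c(C23 = 23L, W41 = 41L, L89 = 89L, C104 = 104L)

# J template: 16 codons (48 nt), W/F of the W/F-G-x-G motif at aa position 8
# (nucleotide offset 21, 0-based). Residues are kept non-repetitive so the
# alignment diagonal is unambiguous.
j_template_aa <- function(chain = "IGH") {
  if (chain == "IGH") "EYNFDHMWGQGTKVSV" else "EYNFDHMFGGGTKVSV"
}

j_motif_regex <- function(chain = "IGH") {
  if (chain == "IGH") "WG.G" else "FG.G"
}

make_d_cores <- function(n = 10L) {
  # G-rich cores, pairwise sharing no 7-mer, so D assignment is unambiguous.
  with_seed(197001L, {
    cores <- character(0)
    kmers7 <- function(s) {
      if (nchar(s) < 7L) return(character(0))
      substring(s, 1:(nchar(s) - 6L), 7:nchar(s))
    }
    seen <- character(0)
    while (length(cores) < n) {
      len <- sample(15:17, 1L)
      cand <- paste(sample(c("G", "G", "G", "A", "T", "C"), len,
                           replace = TRUE), collapse = "")
      gfrac <- sum(strsplit(cand, "")[[1]] == "G") / len
      if (gfrac < 0.45 || gfrac > 0.8) next
      if (!rss_clean(cand)) next
      # no relaxed heptamer look-alike: cores sit between planted RSS
      # nonamers, where such a 7-mer would create a spurious signal pair
      hep_hits <- Biostrings::matchPattern("CACAGTG",
                                           Biostrings::DNAString(cand),
                                           max.mismatch = 2)
      if (length(hep_hits) > 0) next
      ks <- kmers7(cand)
      if (any(ks %in% seen)) next
      cores <- c(cores, cand)
      seen <- c(seen, ks)
    }
    cores
  })
}

make_c_exons <- function() {
  # Four stop-free coding exons; genes with fewer exons use a prefix.
  with_seed(197002L, {
    lens <- c(300L, 300L, 300L, 120L)
    lapply(lens, function(L) {
      repeat {
        s <- random_dna(L)
        if (!has_inframe_stop(s) && rss_clean(s)) return(s)
      }
    })
  })
}

#' Built-in synthetic germline templates for a chain
#'
#' Returns the template V amino-acid/nucleotide sequence with anchor and
#' region definitions, V family seed sequences (divergent enough to fall
#' into distinct 75\%-identity families), the J and C templates, D cores,
#' and the leader/intron geometry used by both the locus generator and the
#' annotator.
#'
#' @param chain One of "IGH", "IGK", "IGL".
#' @return List of template components.
#' @export
ig_templates <- function(chain = "IGH") {
  key <- paste0("templates_", chain)
  if (!is.null(.igloci_env[[key]])) return(.igloci_env[[key]])
  v_aa <- v_template_aa()
  anchors <- v_anchor_positions()
  # reversed-orientation V genes are planted as reverse complements, so the
  # template must be free of RSS look-alikes on both strands
  v_nt <- with_seed(197005L,
                    repair_coding(back_translate(v_aa),
                                  protect_aa = unname(anchors)))
  stopifnot(translate_nt(v_nt) == v_aa, both_strand_clean(v_nt))
  tpl <- with_seed(197003L, {
    # Family seeds: family 1 is the template; families 2 and 3 are heavily
    # substituted (~30% nt) away from it and from each other, keeping the
    # anchor codons and avoiding stops and RSS-like motifs.
    seeds <- c(fam1 = v_nt)
    while (length(seeds) < 3L) {
      cand <- mutate_coding(v_nt, 0.30, protect_aa = unname(anchors))
      if (!both_strand_clean(cand)) next
      ids <- vapply(seeds, function(s) hamming_identity(s, cand), numeric(1))
      if (any(ids > 0.72)) next
      seeds <- c(seeds, cand)
    }
    names(seeds) <- paste0("fam", seq_along(seeds))
    j_aa <- j_template_aa(chain)
    j_nt <- back_translate(j_aa)
    stopifnot(rss_clean(j_nt))
    list(seeds = seeds, j_nt = j_nt, j_aa = j_aa)
  })
  out <- list(
    chain = chain,
    v_aa = v_aa,
    v_nt = v_nt,
    v_len = nchar(v_nt),
    anchors = anchors,
    regions = v_region_bounds(),
    v_seeds = tpl$seeds,
    j_nt = tpl$j_nt,
    j_aa = tpl$j_aa,
    j_anchor_aa = 8L,             # W/F of the W/F-G-x-G motif
    j_motif = j_motif_regex(chain),
    d_cores = make_d_cores(10L),
    c_exons = make_c_exons(),
    leader_len = 48L,             # leader exon, starts with ATG
    intron_len = 80L)             # GT ... AG
  .igloci_env[[key]] <- out
  out
}
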