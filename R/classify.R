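# F/ORF/P functionality classification, family clustering and locus naming.
#
# Precedence rule: structural/coding defects (stop codons, missing conserved
# anchors, splice or initiation failures) force P; regulatory-signal defects
# alone (RSS below threshold, missing J motif) yield ORF; otherwise F.

p_defects_v <- c("STOP_CODON", "MISSING_C23", "MISSING_W41", "MISSING_C104",
                 "NO_INIT_CODON", "NO_DONOR_SPLICE", "NO_ACCEPTOR_SPLICE",
                 "UNALIGNABLE")

aa_substitution_matrix <- function() {
  letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 2
  m["X", ] <- 0; m[, "X"] <- 0
  m
}

#' Number a V amino-acid sequence against the built-in chain template
#'
#' Profile alignment of the chain-specific template fixes the FR1/CDR1/FR2/
#' CDR2/FR3 boundaries and the conserved anchor positions 23 (C), 41 (W),
#' 89 (L) and 104 (C). Numbering is transferred from the template through a
#' global alignment; sequences shorter than 90 aa, or that align too poorly,
#' are reported unalignable.
#'
#' @param aa Amino-acid sequence of the V exon (frame 0 translation).
#' @param chain "IGH", "IGK" or "IGL".
#' @return List of class "numbered_v" with elements `aa`, `map` (integer
#'   vector: template position 1..104 -> query position or NA) and `status`
#'   ("ok" or "unalignable").
#' @export
number_v <- function(aa, chain = "IGH") {
  tpl <- ig_templates(chain)
  out <- structure(list(aa = aa, map = rep(NA_integer_, 104L),
                        status = "unalignable"), class = "numbered_v")
  if (nchar(aa) < 90L) return(out)
  tpl_aa <- substr(tpl$v_aa, 1L, 104L)
  # template global, query local: query flanks (e.g. residues past 104)
  # overhang freely instead of distorting the template tail
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(tpl_aa), Biostrings::AAString(aa),
    type = "global-local",
    substitutionMatrix = aa_substitution_matrix(),
    gapOpening = 25, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- rep(NA_integer_, 104L)
  ti <- 0L
  qi <- IRanges::start(Biostrings::subject(aln)@range) - 1L
  for (k in seq_along(p)) {
    if (p[k] != "-") ti <- ti + 1L
    if (s[k] != "-") qi <- qi + 1L
    if (p[k] != "-" && s[k] != "-") map[ti] <- qi
  }
  matched <- sum(p != "-" & s != "-" & p == s)
  if (matched / 104 < 0.3) return(out)
  out$map <- map
  out$status <- "ok"
  out
}

#' Residue of a numbered V sequence at a template position
#'
#' @param numbered A "numbered_v" object from [number_v()].
#' @param pos Template position (1-104).
#' @return Single character, or NA if the position is unaligned.
#' @export
residue_at <- function(numbered, pos) {
  qp <- numbered$map[pos]
  if (is.na(qp)) return(NA_character_)
  substr(numbered$aa, qp, qp)
}

#' Classify a V candidate as F, ORF or P
#'
#' P if the coding region carries a structural defect (in-frame stop codon,
#' missing C23/W41/C104 anchor, missing initiation codon, missing donor or
#' acceptor splice site, unalignable numbering); otherwise ORF if the 3' RSS
#' is absent or below the strict threshold; otherwise F. A missing L89 is a
#' warning only. Candidates whose coding region contains N are kept out of F.
#'
#' @param candidate List/row with logical flags `init_ok`, `donor_ok`,
#'   `acceptor_ok`, `rss_ok` and the exon sequence `exon_seq`.
#' @param numbered A "numbered_v" object for the exon translation.
#' @return List with `functionality` ("F", "ORF" or "P") and `defects`
#'   (character vector of defect codes, empty for F).
#' @export
classify_v <- function(candidate, numbered = NULL) {
  aa <- translate_nt(candidate$exon_seq)
  if (is.null(numbered)) numbered <- number_v(aa, candidate$chain %||% "IGH")
  defects <- character(0)
  if (numbered$status != "ok") {
    return(list(functionality = "P", defects = "UNALIGNABLE"))
  }
  if (grepl("*", aa, fixed = TRUE)) defects <- c(defects, "STOP_CODON")
  if (!identical(residue_at(numbered, 23L), "C"))
    defects <- c(defects, "MISSING_C23")
  if (!identical(residue_at(numbered, 41L), "W"))
    defects <- c(defects, "MISSING_W41")
  if (!identical(residue_at(numbered, 104L), "C"))
    defects <- c(defects, "MISSING_C104")
  if (!isTRUE(candidate$init_ok)) defects <- c(defects, "NO_INIT_CODON")
  if (!isTRUE(candidate$donor_ok)) defects <- c(defects, "NO_DONOR_SPLICE")
  if (!isTRUE(candidate$acceptor_ok)) defects <- c(defects, "NO_ACCEPTOR_SPLICE")
  warn_l89 <- !identical(residue_at(numbered, 89L), "L")
  if (length(defects) > 0) {
    return(list(functionality = "P", defects = defects, l89_warning = warn_l89))
  }
  if (!isTRUE(candidate$rss_ok)) {
    return(list(functionality = "ORF", defects = "NO_RSS",
                l89_warning = warn_l89))
  }
  if (grepl("N", candidate$exon_seq, fixed = TRUE)) {
    return(list(functionality = "ORF", defects = "AMBIGUOUS_BASE",
                l89_warning = warn_l89))
  }
  list(functionality = "F", defects = character(0), l89_warning = warn_l89)
}

#' Classify a J candidate as F, ORF or P
#'
#' P if the donor splice site is absent; otherwise ORF if the conserved
#' motif (WGXG for heavy, FGXG for light chains) is absent or the J-heptamer
#' fails the strict RSS rule; otherwise F.
#'
#' @param candidate List/row with flags `donor_ok`, `motif_ok`, `rss_ok`
#'   (strict J-heptamer present).
#' @param chain "IGH", "IGK" or "IGL".
#' @return List with `functionality` and `defects`.
#' @export
classify_j <- function(candidate, chain = "IGH") {
  if (!isTRUE(candidate$donor_ok)) {
    return(list(functionality = "P", defects = "NO_DONOR_SPLICE"))
  }
  defects <- character(0)
  if (!isTRUE(candidate$motif_ok)) {
    defects <- c(defects, if (chain == "IGH") "NO_WGXG" else "NO_FGXG")
  }
  if (!isTRUE(candidate$rss_ok)) defects <- c(defects, "NO_J_HEPTAMER")
  if (length(defects) > 0) return(list(functionality = "ORF", defects = defects))
  list(functionality = "F", defects = character(0))
}

#' Classify a C candidate as F or P
#'
#' P if the spliced translation contains a stop codon before the final exon
#' (or mid-exon for single-exon genes), or if any intron lacks its GT donor
#' or AG acceptor dinucleotide; otherwise F.
#'
#' @param candidate List with `exon_seqs` (character vector in order) and
#'   `splice_ok` (logical: all GT..AG junctions valid).
#' @return List with `functionality` and `defects`.
#' @export
classify_c <- function(candidate) {
  defects <- character(0)
  exons <- candidate$exon_seqs
  spliced <- paste(exons, collapse = "")
  aa <- translate_nt(spliced)
  stop_pos <- regexpr("*", aa, fixed = TRUE)
  if (stop_pos > 0) {
    # allow a stop only in the last codon of the final exon
    last_codon <- nchar(spliced) %/% 3L
    if (stop_pos < last_codon) defects <- c(defects, "STOP_CODON")
  }
  if (!isTRUE(candidate$splice_ok)) defects <- c(defects, "NO_ACCEPTOR_SPLICE")
  if (length(defects) > 0) return(list(functionality = "P", defects = defects))
  list(functionality = "F", defects = character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster V genes into families by nucleotide identity
#'
#' Single-linkage clustering on pairwise global-alignment identity: two
#' genes share a family iff they are connected by a chain of pairs each at
#' or above the threshold (default 75\%, the IMGT family rule). When a gene
#' matches a named seed at or above the threshold the seed's family label is
#' reused for its cluster; remaining clusters get fresh integer labels in
#' 5'-to-3' order of their first member.
#'
#' @param nt Character vector of V nucleotide sequences (reading sense).
#' @param threshold Identity threshold in (0, 1).
#' @param seeds Optional named character vector of family seed sequences;
#'   names like "fam1" carry the family label after the "fam" prefix.
#' @param starts Optional numeric vector of 5' coordinates used to order
#'   fresh labels; defaults to input order.
#' @return Character vector of family labels, parallel to `nt`.
#' @export
assign_families <- function(nt, threshold = 0.75, seeds = NULL, starts = NULL) {
  n <- length(nt)
  stopifnot(n >= 1)
  if (is.null(starts)) starts <- seq_len(n)
  # single-linkage components over the >= threshold graph
  comp <- seq_len(n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (comp[i] == comp[j]) next
        if (alignment_identity(nt[i], nt[j]) >= threshold) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
  }
  labels <- rep(NA_character_, n)
  seed_label_of <- function(seq) {
    if (is.null(seeds) || length(seeds) == 0) return(NA_character_)
    ids <- vapply(seeds, function(s) alignment_identity(seq, s), numeric(1))
    if (max(ids) >= threshold) {
      sub("^fam", "", names(seeds)[which.max(ids)])
    } else NA_character_
  }
  comps <- unique(comp)
  # order components by 5'-most member for deterministic fresh labels
  comp_min_start <- vapply(comps, function(cc) min(starts[comp == cc]),
                           numeric(1))
  comps <- comps[order(comp_min_start)]
  used <- character(0)
  fresh <- 1L
  for (cc in comps) {
    members <- which(comp == cc)
    lab <- NA_character_
    for (m in members) {
      lab <- seed_label_of(nt[m])
      if (!is.na(lab)) break
    }
    if (is.na(lab) || lab %in% used) {
      while (as.character(fresh) %in% used) fresh <- fresh + 1L
      lab <- as.character(fresh)
    }
    used <- c(used, lab)
    labels[members] <- lab
  }
  labels
}

chain_prefix <- function(chain) {
  switch(chain, IGH = "IgH", IGK = "Igk", IGL = "Igl",
         stop("unknown chain ", chain))
}

#' Name annotated genes by locus position
#'
#' V genes are named <chain>V<family>-<ordinal> with the ordinal running
#' 5' to 3' over all V genes of the locus. D and J genes are named within
#' D-J-C clusters as <chain><seg><cluster>-<ordinal within cluster> when the
#' locus has more than one cluster, else <chain><seg><ordinal>. C genes get
#' a plain 5'-to-3' ordinal (omitted when the locus has a single C gene).
#' Cluster boundaries are inferred by walking D/J/C features in coordinate
#' order: a D or J segment occurring after a C gene opens a new cluster.
#'
#' @param genes Data frame with columns segment_type, start, end and (for V)
#'   family.
#' @param chain "IGH", "IGK" or "IGL".
#' @return The gene table with `name` and `cluster` columns filled,
#'   re-sorted by start coordinate.
#' @export
name_genes <- function(genes, chain = "IGH") {
  if (any(duplicated(genes[, c("start", "end")]))) {
    stop("duplicate gene coordinates")
  }
  pre <- chain_prefix(chain)
  genes <- genes[order(genes$start), , drop = FALSE]
  genes$name <- NA_character_
  genes$cluster <- NA_integer_

  is_v <- genes$segment_type == "V"
  if (any(is_v)) {
    ord <- seq_len(sum(is_v))
    fam <- genes$family[is_v]
    genes$name[is_v] <- paste0(pre, "V", fam, "-", ord)
  }

  djc <- which(genes$segment_type %in% c("D", "J", "C"))
  cluster <- 1L
  seen_c <- FALSE
  for (i in djc) {
    st <- genes$segment_type[i]
    if (st %in% c("D", "J") && seen_c) {
      cluster <- cluster + 1L
      seen_c <- FALSE
    }
    if (st == "C") seen_c <- TRUE
    genes$cluster[i] <- cluster
  }
  n_clusters <- if (length(djc) > 0) max(genes$cluster[djc]) else 0L
  for (st in c("D", "J")) {
    rows <- which(genes$segment_type == st)
    if (length(rows) == 0) next
    for (cl in unique(genes$cluster[rows])) {
      members <- rows[genes$cluster[rows] == cl]
      ords <- seq_along(members)
      genes$name[members] <- if (n_clusters > 1) {
        paste0(pre, st, cl, "-", ords)
      } else {
        paste0(pre, st, ords)
      }
    }
  }
  c_rows <- which(genes$segment_type == "C")
  if (length(c_rows) == 1) {
    genes$name[c_rows] <- paste0(pre, "C")
  } else if (length(c_rows) > 1) {
    genes$name[c_rows] <- paste0(pre, "C", seq_along(c_rows))
  }
  genes
}

#' Functionality summary in the layout of a per-segment count table
#'
#' Given either an annotated gene table (with `segment_type`, `chain` and
#' `functionality` columns) or a data frame of per-class counts (columns
#' `segment`, `F`, `P`, `ORF`), returns counts of F, P and ORF per segment
#' with a Total column equal to F + P + ORF.
#'
#' @param x Gene table or per-class count table.
#' @return Data frame with columns segment, F, P, ORF, Total.
#' @export
functionality_summary <- function(x) {
  if (all(c("F", "P", "ORF") %in% names(x))) {
    out <- x
  } else {
    stopifnot(all(c("segment_type", "functionality") %in% names(x)))
    pre <- if ("chain" %in% names(x)) {
      vapply(x$chain, chain_prefix, character(1))
    } else rep("", nrow(x))
    seg <- paste0(pre, x$segment_type)
    segs <- unique(seg)
    out <- data.frame(segment = segs,
                      F = vapply(segs, function(s)
                        sum(seg == s & x$functionality == "F"), integer(1)),
                      P = vapply(segs, function(s)
                        sum(seg == s & x$functionality == "P"), integer(1)),
                      ORF = vapply(segs, function(s)
                        sum(seg == s & x$functionality == "ORF"), integer(1)),
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  out$Total <- out$F + out$P + out$ORF
  out
}
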