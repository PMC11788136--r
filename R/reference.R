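# Segmented germline reference: FR/CDR boundaries and CDR3 anchor positions,
# the information a junction-extraction aligner needs from each gene.

#' Build a segmented germline reference from an annotated locus
#'
#' Every V gene with a numberable position 104 yields a record carrying its
#' FR1/CDR1/FR2/CDR2/FR3 nucleotide spans and the offset of the conserved
#' C104 codon (the CDR3 5' anchor). Every J gene with a W/F-G-x-G motif
#' yields a record with its FR4 span and the offset of the W/F codon (the
#' CDR3 3' anchor, inclusive). Pseudogenes are included but flagged
#' non-productive; V genes whose numbering lacks position 104 and J genes
#' without the motif are excluded from anchor-bearing records (reason
#' logged in the `excluded` element).
#'
#' @param genes Annotated gene table (from [annotate_locus()] or a locus
#'   truth table) with columns name, segment_type, chain, functionality,
#'   nt_sequence.
#' @param chain "IGH", "IGK" or "IGL".
#' @return List of class "germline_reference" with data frames `v`
#'   (name, nt_sequence, anchor_nt, fr1/cdr1/fr2/cdr2/fr3 spans as
#'   "start-end" strings, productive), `d` (name, nt_sequence), `j`
#'   (name, nt_sequence, anchor_nt, productive) and `excluded`.
#' @export
build_reference <- function(genes, chain = "IGH") {
  tplmotif <- j_motif_regex(chain)
  excluded <- character(0)

  v_rows <- genes[genes$segment_type == "V", , drop = FALSE]
  v_list <- list()
  for (i in seq_len(nrow(v_rows))) {
    nt <- v_rows$nt_sequence[i]
    aa <- translate_nt(nt)
    num <- number_v(aa, chain)
    if (num$status != "ok" || is.na(num$map[104L])) {
      excluded <- c(excluded, paste0(v_rows$name[i],
                                     ": no numberable position 104"))
      next
    }
    span <- function(lo, hi) {
      a <- num$map[lo]; b <- num$map[hi]
      if (is.na(a) || is.na(b)) return(NA_character_)
      paste0((a - 1L) * 3L, "-", b * 3L)   # 0-based half-open nt span
    }
    bounds <- v_region_bounds()
    anchor_nt <- (num$map[104L] - 1L) * 3L
    v_list[[length(v_list) + 1L]] <- data.frame(
      name = v_rows$name[i], nt_sequence = nt, anchor_nt = anchor_nt,
      fr1 = span(bounds$FR1[1], bounds$FR1[2]),
      cdr1 = span(bounds$CDR1[1], bounds$CDR1[2]),
      fr2 = span(bounds$FR2[1], bounds$FR2[2]),
      cdr2 = span(bounds$CDR2[1], bounds$CDR2[2]),
      fr3 = span(bounds$FR3[1], bounds$FR3[2]),
      productive = v_rows$functionality[i] %in% c("F", "ORF"),
      stringsAsFactors = FALSE)
  }
  v <- if (length(v_list) > 0) do.call(rbind, v_list) else
    data.frame(name = character(0), nt_sequence = character(0),
               anchor_nt = integer(0), fr1 = character(0), cdr1 = character(0),
               fr2 = character(0), cdr2 = character(0), fr3 = character(0),
               productive = logical(0), stringsAsFactors = FALSE)

  d_rows <- genes[genes$segment_type == "D", , drop = FALSE]
  d <- data.frame(name = d_rows$name, nt_sequence = d_rows$nt_sequence,
                  stringsAsFactors = FALSE)

  j_rows <- genes[genes$segment_type == "J", , drop = FALSE]
  j_list <- list()
  for (i in seq_len(nrow(j_rows))) {
    nt <- j_rows$nt_sequence[i]
    aa <- translate_nt(nt)
    m <- regexpr(tplmotif, aa)
    anchor_nt <- if (m > 0) (as.integer(m) - 1L) * 3L else NA_integer_
    if (is.na(anchor_nt)) {
      excluded <- c(excluded, paste0(j_rows$name[i], ": no W/F-G-x-G motif"))
    }
    j_list[[length(j_list) + 1L]] <- data.frame(
      name = j_rows$name[i], nt_sequence = nt, anchor_nt = anchor_nt,
      fr4 = if (!is.na(anchor_nt)) paste0(anchor_nt + 3L, "-", nchar(nt))
            else NA_character_,
      productive = j_rows$functionality[i] %in% c("F", "ORF") &&
        !is.na(anchor_nt),
      stringsAsFactors = FALSE)
  }
  j <- if (length(j_list) > 0) do.call(rbind, j_list) else
    data.frame(name = character(0), nt_sequence = character(0),
               anchor_nt = integer(0), fr4 = character(0),
               productive = logical(0), stringsAsFactors = FALSE)
  rownames(v) <- rownames(d) <- rownames(j) <- NULL
  v <- v[order(v$name), , drop = FALSE]
  d <- d[order(d$name), , drop = FALSE]
  j <- j[order(j$name), , drop = FALSE]
  structure(list(v = v, d = d, j = j, chain = chain, excluded = excluded),
            class = "germline_reference")
}

#' Serialize a germline reference to a FASTA + segments TSV pair
#'
#' @param ref A "germline_reference" from [build_reference()].
#' @param prefix Output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.segments.tsv`. Deterministic (records sorted by name).
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(ref, prefix) {
  seqs <- c(stats::setNames(ref$v$nt_sequence, ref$v$name),
            stats::setNames(ref$d$nt_sequence, ref$d$name),
            stats::setNames(ref$j$nt_sequence, ref$j$name))
  fasta <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".segments.tsv")
  write_fasta(seqs, fasta)
  seg <- rbind(
    data.frame(name = ref$v$name, segment_type = "V",
               anchor_nt = ref$v$anchor_nt, productive = ref$v$productive,
               fr1 = ref$v$fr1, cdr1 = ref$v$cdr1, fr2 = ref$v$fr2,
               cdr2 = ref$v$cdr2, fr3 = ref$v$fr3, fr4 = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(name = ref$d$name, segment_type = "D", anchor_nt = NA_integer_,
               productive = TRUE, fr1 = NA, cdr1 = NA, fr2 = NA, cdr2 = NA,
               fr3 = NA, fr4 = NA, stringsAsFactors = FALSE),
    data.frame(name = ref$j$name, segment_type = "J",
               anchor_nt = ref$j$anchor_nt, productive = ref$j$productive,
               fr1 = NA, cdr1 = NA, fr2 = NA, cdr2 = NA, fr3 = NA,
               fr4 = ref$j$fr4, stringsAsFactors = FALSE))
  utils::write.table(seg, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, tsv))
}

#' Read back a reference written by [write_reference()]
#'
#' @param prefix Path prefix used at write time.
#' @param chain Chain label stored on the object.
#' @return A "germline_reference" list.
#' @export
read_reference <- function(prefix, chain = "IGH") {
  seqs <- read_fasta(paste0(prefix, ".fasta"))
  seg <- utils::read.delim(paste0(prefix, ".segments.tsv"),
                           stringsAsFactors = FALSE)
  seg$nt_sequence <- unname(seqs[seg$name])
  v <- seg[seg$segment_type == "V",
           c("name", "nt_sequence", "anchor_nt", "fr1", "cdr1", "fr2",
             "cdr2", "fr3", "productive")]
  d <- seg[seg$segment_type == "D", c("name", "nt_sequence")]
  j <- seg[seg$segment_type == "J",
           c("name", "nt_sequence", "anchor_nt", "fr4", "productive")]
  rownames(v) <- rownames(d) <- rownames(j) <- NULL
  structure(list(v = v, d = d, j = j, chain = chain, excluded = character(0)),
            class = "germline_reference")
}
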