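#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' @param path Path to a FASTQ file (Sanger phred+33).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a FASTQ file with constant qualities
#'
#' @param seqs Named character vector of read sequences.
#' @param path Output path.
#' @param quality_char Single quality character applied to every base.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  quals <- Biostrings::PhredQuality(vapply(nchar(seqs), function(n)
    paste(rep(quality_char, n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

# Gene tables use 0-based half-open coordinates internally; GFF3 is 1-based
# inclusive. Feature types follow the Sequence Ontology-style names
# V_gene_segment / D_gene_segment / J_gene_segment / C_gene_segment / RSS.

#' Write an annotated gene table as GFF3
#'
#' Converts the package's 0-based half-open gene table to 1-based inclusive
#' GFF3 via rtracklayer. Functionality class and defect codes are carried in
#' the attribute column.
#'
#' @param genes Data frame with columns contig, start, end, strand, name,
#'   segment_type and optionally functionality, family, defects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  stopifnot(all(genes$start >= 0), all(genes$end > genes$start))
  type <- ifelse(genes$segment_type == "RSS", "RSS",
                 paste0(genes$segment_type, "_gene_segment"))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- type
  gr$ID <- genes$name
  gr$Name <- genes$name
  if (!is.null(genes$functionality)) gr$functionality <- genes$functionality
  if (!is.null(genes$family)) gr$family <- as.character(genes$family)
  if (!is.null(genes$defects)) gr$defects <- genes$defects
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path Path to a GFF3 file.
#' @return Data frame in the package's 0-based half-open convention.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = if (!is.null(md$Name)) as.character(md$Name) else NA_character_,
    segment_type = sub("_gene_segment$", "", as.character(md$type)),
    stringsAsFactors = FALSE)
  for (col in c("functionality", "family", "defects")) {
    if (!is.null(md[[col]])) df[[col]] <- as.character(md[[col]])
  }
  df
}

airr_columns <- c("sample_id", "v_call", "d_call", "j_call",
                  "junction", "junction_aa", "duplicate_count")

#' Write a clonotype table as AIRR-style TSV
#'
#' Columns: sample_id, v_call, d_call, j_call, junction, junction_aa,
#' duplicate_count. `junction` is the CDR3 nucleotide sequence (anchors
#' included), `duplicate_count` the clonotype read count.
#'
#' @param clonotypes Data frame with columns cdr3_nt, cdr3_aa, count, v_gene,
#'   d_gene, j_gene.
#' @param path Output path.
#' @param sample_id Sample identifier written to every row.
#' @return Invisibly, `path`.
#' @export
write_airr <- function(clonotypes, path, sample_id = "sample") {
  df <- data.frame(
    sample_id = sample_id,
    v_call = clonotypes$v_gene,
    d_call = ifelse(is.na(clonotypes$d_gene) | clonotypes$d_gene == "",
                    "", clonotypes$d_gene),
    j_call = clonotypes$j_gene,
    junction = clonotypes$cdr3_nt,
    junction_aa = clonotypes$cdr3_aa,
    duplicate_count = clonotypes$count,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an AIRR-style clonotype TSV
#'
#' @param path Path to a TSV with the columns written by [write_airr()].
#' @return Data frame with columns sample_id, cdr3_nt, cdr3_aa, count,
#'   v_gene, d_gene, j_gene.
#' @export
read_airr <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(airr_columns, names(df))
  if (length(missing) > 0) {
    stop("AIRR file ", path, " lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  data.frame(
    sample_id = df$sample_id,
    cdr3_nt = df$junction,
    cdr3_aa = df$junction_aa,
    count = as.integer(df$duplicate_count),
    v_gene = df$v_call,
    d_gene = df$d_call,
    j_gene = df$j_call,
    stringsAsFactors = FALSE)
}
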