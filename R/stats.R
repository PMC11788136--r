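# Diversity, clonality, overlap, length, usage and junction statistics.
# Clonality analyses operate on total clone counts; length and gene-usage
# distributions operate on unique clones.

clonotype_table <- function(x) {
  if (inherits(x, "repertoire_sample")) x$clonotypes else x
}

#' Summarize a repertoire sample
#'
#' Computes the sequencing/clonotype accounting of a sample: alignment
#' percentage (2 decimals) and unique/total clone percentage (1 decimal),
#' both rounded half-up as printed in summary tables.
#'
#' @param sample A "repertoire_sample", or NULL if the integer columns are
#'   given directly.
#' @param total_reads,aligned_reads,clonotype_count,unique_clones Integer
#'   overrides (used when summarizing printed tables).
#' @return Data frame row with total_reads, aligned_reads, aligned_pct,
#'   clonotype_count, unique_clones, unique_over_total_pct.
#' @export
summarize_sample <- function(sample = NULL, total_reads = NULL,
                             aligned_reads = NULL, clonotype_count = NULL,
                             unique_clones = NULL) {
  if (!is.null(sample)) {
    cl <- clonotype_table(sample)
    total_reads <- total_reads %||% sample$total_reads
    aligned_reads <- aligned_reads %||% sample$aligned_reads
    clonotype_count <- clonotype_count %||% sum(cl$count)
    unique_clones <- unique_clones %||% nrow(cl)
  }
  if (clonotype_count == 0) stop("no clonotypes to summarize")
  data.frame(
    total_reads = total_reads, aligned_reads = aligned_reads,
    aligned_pct = round_half_up(100 * aligned_reads / total_reads, 2),
    clonotype_count = clonotype_count, unique_clones = unique_clones,
    unique_over_total_pct = round_half_up(100 * unique_clones /
                                            clonotype_count, 1))
}

#' Inverse Simpson diversity index
#'
#' 1 / sum(p_i^2) over clonotype frequencies; 1 for a monoclonal sample and
#' the number of clonotypes for a perfectly even one.
#'
#' @param counts Positive integer vector of clonotype counts.
#' @return Numeric scalar >= 1.
#' @export
inverse_simpson <- function(counts) {
  if (length(counts) == 0) stop("empty count vector")
  p <- counts / sum(counts)
  1 / sum(p^2)
}

#' Analytic rarefaction of clonotype richness
#'
#' Expected number of distinct clonotypes in a uniform random subsample of
#' each depth, via the hypergeometric form
#' E[S(d)] = sum_i (1 - choose(N - c_i, d) / choose(N, d)).
#'
#' @param counts Positive integer clonotype counts (sum N).
#' @param depths Integer subsampling depths, each <= N.
#' @return Numeric vector of expected richness, parallel to `depths`.
#' @export
rarefaction <- function(counts, depths) {
  N <- sum(counts)
  if (any(depths > N)) stop("depth exceeds total count")
  vapply(depths, function(d) {
    term <- ifelse(N - counts >= d,
                   exp(lchoose(N - counts, d) - lchoose(N, d)), 0)
    sum(1 - term)
  }, numeric(1))
}

#' Proportion of reads in the k most abundant clonotypes
#'
#' @param counts Clonotype counts.
#' @param k Number of top clones (k beyond the number of clonotypes gives 1).
#' @return Fraction in [0, 1].
#' @export
top_proportion <- function(counts, k) {
  stopifnot(k >= 1)
  k <- min(k, length(counts))
  sum(sort(counts, decreasing = TRUE)[seq_len(k)]) / sum(counts)
}

#' Proportion of reads per clonotype-abundance class
#'
#' Bins clonotypes by count into classes (1], (1,3], (3,10], ... defined by
#' `bin_edges` plus an open top class, and reports the fraction of reads in
#' each class.
#'
#' @param counts Clonotype counts.
#' @param bin_edges Strictly increasing integer upper edges.
#' @return Named numeric vector of read fractions summing to 1.
#' @export
rare_proportion <- function(counts, bin_edges = c(1, 3, 10, 30, 100, 1000)) {
  stopifnot(all(diff(bin_edges) > 0))
  edges <- c(0, bin_edges, Inf)
  labs <- character(length(edges) - 1)
  for (i in seq_along(labs)) {
    lo <- edges[i] + 1
    hi <- edges[i + 1]
    labs[i] <- if (is.infinite(hi)) paste0("(", edges[i], ", Inf)")
               else if (lo == hi) paste0("[", hi, ", ", hi, "]")
               else paste0("[", lo, ", ", hi, "]")
  }
  cls <- cut(counts, breaks = edges, labels = labs)
  out <- tapply(counts, cls, sum, default = 0) / sum(counts)
  out <- as.numeric(out)
  names(out) <- labs
  out
}

#' Number of top clonotypes occupying a given repertoire fraction
#'
#' The minimal m such that the m largest counts sum to at least q of all
#' reads; a concentration measure (smaller = more clonal).
#'
#' @param counts Clonotype counts.
#' @param q Target fraction in (0, 1].
#' @return Integer m.
#' @export
clonal_proportion <- function(counts, q = 0.31) {
  stopifnot(q > 0, q <= 1)
  s <- sort(counts, decreasing = TRUE)
  cum <- cumsum(s)
  # guard against floating error at q = 1
  which(cum >= q * sum(counts) - 1e-9)[1]
}

clonotype_keys <- function(x, identity = c("cdr3_aa", "cdr3_nt")) {
  identity <- match.arg(identity)
  unique(clonotype_table(x)[[identity]])
}

#' Number of clonotypes shared between two samples
#'
#' @param sample_a,sample_b "repertoire_sample"s or clonotype data frames.
#' @param identity Key: exact CDR3 amino-acid (default) or nucleotide match.
#' @return Integer overlap.
#' @export
overlap <- function(sample_a, sample_b, identity = c("cdr3_aa", "cdr3_nt")) {
  identity <- match.arg(identity)
  length(intersect(clonotype_keys(sample_a, identity),
                   clonotype_keys(sample_b, identity)))
}

#' Clonotype keys shared across all samples, with Venn region sizes
#'
#' @param samples List of two or more samples/clonotype tables.
#' @param identity Key definition as in [overlap()].
#' @return List with `shared` (keys present in every sample) and `regions`
#'   (named integer vector of all Venn region cardinalities; names are
#'   sample-membership patterns like "s1&s3").
#' @export
shared_across <- function(samples, identity = c("cdr3_aa", "cdr3_nt")) {
  identity <- match.arg(identity)
  stopifnot(length(samples) >= 2)
  keysets <- lapply(samples, clonotype_keys, identity = identity)
  nm <- names(samples) %||% paste0("s", seq_along(samples))
  all_keys <- unique(unlist(keysets))
  member <- vapply(keysets, function(ks) all_keys %in% ks,
                   logical(length(all_keys)))
  if (length(all_keys) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row) paste(nm[row], collapse = "&"))
  regions <- table(pattern)
  shared <- all_keys[rowSums(member) == length(samples)]
  list(shared = shared,
       regions = stats::setNames(as.integer(regions), names(regions)))
}

#' CDR3 length distribution over unique clones
#'
#' @param sample Sample or clonotype table (productive clonotypes).
#' @param ultra_threshold Ultra-long cutoff in amino acids.
#' @return List with `histogram` (named integer vector over aa lengths),
#'   `ultra_long` (count of unique clones above the threshold) and
#'   `max_length`.
#' @export
length_distribution <- function(sample, ultra_threshold = 50L) {
  cl <- clonotype_table(sample)
  lens <- nchar(cl$cdr3_aa)
  tab <- table(lens)
  list(histogram = stats::setNames(as.integer(tab), names(tab)),
       ultra_long = sum(lens > ultra_threshold),
       max_length = if (length(lens) > 0) max(lens) else NA_integer_)
}

#' Germline gene usage frequencies over unique clones
#'
#' @param sample Sample or clonotype table.
#' @param segment "V", "D" or "J". Unassigned D calls are reported as the
#'   "(none)" category so frequencies sum to 1.
#' @return Named numeric vector of frequencies.
#' @export
gene_usage <- function(sample, segment = c("V", "D", "J")) {
  segment <- match.arg(segment)
  cl <- clonotype_table(sample)
  col <- switch(segment, V = "v_gene", D = "d_gene", J = "j_gene")
  g <- cl[[col]]
  if (segment == "D") g[is.na(g) | g == ""] <- "(none)"
  tab <- table(g)
  stats::setNames(as.numeric(tab) / nrow(cl), names(tab))
}

#' Junction trimming/insertion profile over unique clones
#'
#' @param sample Sample or clonotype table with v_del, j_del, n_ins columns.
#' @return List of three named integer histograms: v_deletions,
#'   j_deletions, n_insertions.
#' @export
junction_indel_profile <- function(sample) {
  cl <- clonotype_table(sample)
  hist_of <- function(x) {
    tab <- table(x)
    stats::setNames(as.integer(tab), names(tab))
  }
  list(v_deletions = hist_of(cl$v_del),
       j_deletions = hist_of(cl$j_del),
       n_insertions = hist_of(cl$n_ins))
}
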