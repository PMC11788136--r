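---
title: "Methods: immunoglobulin locus annotation and CDR3 repertoire analysis"
author: "igloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immunoglobulin locus annotation and CDR3 repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`igloci` implements two connected analyses for immunoglobulin (Ig) genetics
in a species whose loci are being annotated for the first time:

1. **Germline locus annotation** — detecting V, D, J and C gene segments in
   genomic sequence from their structural hallmarks (similarity to known
   germline genes, recombination signal sequences, splice geometry,
   conserved residues) and classifying each gene as functional (F), open
   reading frame (ORF) or pseudogene (P).
2. **IgH CDR3 repertoire analysis** — building a segmented germline
   reference from the annotation, aligning amplicon reads against it,
   extracting CDR3 junctions with trimming/insertion bookkeeping,
   assembling clonotypes and computing diversity, clonality, overlap,
   length and gene-usage statistics.

Because a 2.6 Gb assembly and millions of spleen reads cannot be reanalysed
at desk scale, the package ships a ground-truthed synthetic-data generator
that emulates the *structure* of such data; all validation is
exact-recovery testing against planted truth.

## The annotation model

### RSS scanning

A recombination signal sequence is modelled as a heptamer
(consensus `CACAGTG`) and nonamer (consensus `ACAAAAACC`) separated by a
poorly conserved spacer of 12 ± 1 or 23 ± 1 bp. `scan_rss()` reports every
placement whose heptamer and nonamer are within configurable mismatch
budgets of the consensus. Two configurations are used:

* **strict** (classification): heptamer ≥ 6/7 with the first three bases
  `CAC` exact, nonamer ≥ 6/9. The `CAC` is the functionally critical
  cleavage motif; nonamer positions are the degenerate ones.
* **relaxed** (discovery): heptamer ≥ 5/7 without the `CAC` requirement,
  nonamer ≥ 6/9, so genes with degraded signals are still *found* and can
  then be classified as ORF rather than silently missed.

The expected spacer class per chain and segment is fixed by the 12/23 rule
as observed in ruminant loci: IGH V 23 (3'), D 12+12, J 23 (5'); IGK V 12,
J 23; IGL V 23, J 12.

### Gene detection

* **V genes** are seeded by similarity to known germline V sequences.
  The search is exhaustive ungapped matching with a mismatch budget of
  `floor((1 - min_identity) * length)` (default `min_identity` 0.75, the
  same threshold as family clustering). We deliberately chose ungapped
  scanning over banded local alignment: it finds *every* copy of a seed
  (local alignment reports only the best), identity is exactly
  `1 - mismatches/length`, and the package's divergence model is
  substitution-only. Gapped divergence between the target and seed species
  is a known limitation for real assemblies.
* **Leader and splice checks** use a fixed geometry: a leader exon of
  `leader_len` (48 bp) beginning with `ATG`, then an intron of `intron_len`
  (80 bp) delimited by `GT`..`AG`, immediately 5' of the V exon. Real
  leaders and introns vary in length; the geometric model (both lengths
  configurable) turns the qualitative requirement of intact donor and
  acceptor splice sites into an exact, auditable check on generated loci.
  A splice-site PWM would be needed for real data.
* **D genes** are intervals between a J-side 12-RSS (upstream) and a
  V-side 12-RSS (downstream), both at the strict threshold, with core
  G fraction ≥ 0.4 and length 5–40 bp; G-richness is the only sequence
  hallmark these short segments offer, so both knobs are exposed.
* **J genes** are the `j_length` (48 bp) downstream of a relaxed J-side
  RSS heptamer. The conserved W-G-x-G (heavy) / F-G-x-G (light) motif and
  the 3' `GT` donor are recorded as flags, not required — their absence
  drives the ORF/P calls. The ~50 bp length is taken to exclude the RSS.
* **C genes** are chains of exon-seed matches; a new gene starts when the
  exon index fails to increase or the gap exceeds `max_intron` (2 kb).
  Intron boundaries are checked for `GT`..`AG`.

### Functionality classification

Classification is a pure function of the candidate with an explicit
precedence: **structural/coding defects force P** (in-frame stop codon,
missing C23 / W41 / C104 anchor, missing initiation codon, missing donor or
acceptor splice site, unalignable numbering); **signal defects alone yield
ORF** (V: RSS below the strict threshold; J: missing W/F-G-x-G motif or
strict J-heptamer failure); otherwise **F**. A missing L89 is recorded as a
warning only (it is typical but not universal). Every defect triggers a
code in the gene's defect list, so pseudogene calls are auditable.

Anchor positions come from `number_v()`, a profile alignment of a built-in
104-residue chain template (identity numbering, anchors C23/W41/L89/C104;
region bounds FR1 1–26, CDR1 27–38, FR2 39–55, CDR2 56–65, FR3 66–104).
The alignment is template-global / query-local with high gap penalties
(open 25, extend 1): query flanks overhang freely, gaps are only opened
when a genuine CDR-length indel pays for them. This approximates IMGT
unique numbering well enough for the four anchor positions the rules
consume; full gap-inserting IMGT numbering is out of scope.

### Families and names

Family assignment is single-linkage clustering on pairwise global-alignment
nucleotide identity at 75% (gaps count as mismatches). Clusters containing
a gene that matches a named seed at ≥ 75% reuse the seed's family label,
so families inherit names by homology to the reference species; other clusters
get fresh integers in 5'-to-3' order. Names encode position: V genes
`<chain>V<family>-<locus ordinal>`; D and J genes are numbered within
D-J-C clusters (`IgHJ1-4`, `IgHJ2-1`, ...) when the locus has more than one
cluster; C genes get a plain ordinal. Cluster boundaries are inferred by
walking D/J/C features 5' to 3': a D or J after a C opens a new cluster.

## The repertoire model

### Reference

Each numberable V gene yields a record with FR/CDR nucleotide spans and the
offset of its C104 codon; each motif-bearing J the offset of its W/F codon.
**CDR3 is defined inclusive of both anchors** — from the conserved
cysteine codon through the W/F codon — and this convention is used
consistently by the reference builder, the simulator and the extractor.
(Under the exclusive convention all lengths shift by 2 aa.) Pseudogenes are
carried but flagged non-productive; only productive, anchor-bearing
records participate in alignment.

### Alignment and junction extraction

V assignment screens both read orientations by shared k-mer counts
(k = 16, stride 4) against every V record, then verifies the best
candidate (and the runner-up when votes are within 4) by local
Smith–Waterman alignment (match +2, mismatch −3, gap open 5, extend 2;
minimum V score 50, J score 20). The k-mer stage is a standard seed-level
prefilter; the reported assignment is always Smith–Waterman-verified, and
a test checks that assignments equal an exhaustive all-pairs alignment
oracle. J alignment runs on the read suffix from the V anchor onward.

Junction boundaries are then attributed by **canonical maximal extension**:
starting at the C104 codon end, the V is extended base by base while the
read continues to match the germline; the J is extended leftward from its
W/F codon the same way (V first, then J). Junction bases that happen to
match a germline continuation are thus always credited to the germline
segment, which makes `v_deletions`, `j_deletions` and `n_insertions`
well-defined observables; the simulator records its truth under the same
convention, so recovered and planted bookkeeping are comparable base for
base. D assignment is the longest exact substring of the inter-anchor
region found in any D record (minimum core 7 nt, ties to locus order);
`n_insertions` is the inter-anchor length minus the assigned D
contribution.

Clonotypes are exact (CDR3 nucleotide, V call, J call) groups. The
productive filter removes clonotypes with a stop codon in the CDR3 and
clonotypes whose CDR3 length is not a multiple of 3 — amino-acid-level
reporting requires in-frame junctions — and logs both counts separately.

### Statistics

Clonality analyses (inverse Simpson, top/rare/clonal proportions,
rarefaction) run on total clone counts; length and gene-usage
distributions run on unique clones. Rarefaction uses the analytic
hypergeometric expectation `E[S(d)] = sum_i (1 - C(N - c_i, d) / C(N, d))`
rather than Monte-Carlo resampling, so results are deterministic; tests
check it against exhaustive enumeration at N ≤ 12. Repertoire overlap
defaults to exact CDR3 amino-acid identity (the most common public-clone
convention; switchable to nucleotide identity). Printed-table percentages
round half-up: 2 decimals for alignment rate, 1 for unique/total. The
ultra-long reporter counts unique clones with CDR3 > 50 aa (configurable).

## The synthetic-data generator

`generate_locus()` plants structurally complete genes — V (ATG leader,
GT..AG intron, 330 bp exon, 3' RSS), D (G-rich core, dual 12-RSS), J
(5' RSS, motif, 3' donor), multi-exon C — in random background, realising
the requested pseudogene/ORF mixture as concrete sequence defects (planted
stop codons, mutated anchors, `ATG`→`ACG`, `GT`→`GA`, `AG`→`AC`,
`CAC`→`CTC` heptamers) that are recorded in the truth table. A configurable
fraction of V genes is reverse-complemented in place, emulating the
reversed transcriptional orientation seen in ruminant λ loci.

Three design choices make exact-recovery validation well-posed:

* **RSS-clean background.** Intergenic and intronic filler is rejection
  sampled to contain no relaxed-threshold RSS motif, each gene-plus-spacer
  piece is re-screened at assembly (junctions included), and the finished
  locus is verified to contain exactly the planted discovery signals.
  Random sequence contains RSS look-alikes roughly every few kilobases, so
  without this the planted truth would not be the unique correct answer.
* **Identifiable gene sets.** D cores are pairwise 7-mer-disjoint and free
  of heptamer look-alikes; J genes diverge at ~15% with an enforced
  pairwise distance ≥ 4 over the trim-surviving 3' region, so every read
  has a unique best germline assignment. Family seeds are ≤ 72% identical
  to each other, comfortably below the 75% family threshold, while
  within-family genes (5% substitution) stay above it.
* **Canonical truth.** Junction bookkeeping is recorded in the same
  maximal-attribution form the pipeline reports (see above).

`simulate_repertoire()` draws clonotypes (V by configurable usage weights;
geometric(p = 0.5) trimming capped so anchors survive; two
Poisson(lambda/2) insertion tracts; an optionally trimmed D with
probability 0.8), assigns log-normal abundances, and emits reads clipped
to the 200–300 bp amplicon window around the junction, mirroring the
gel-excision step of a multiplex-PCR protocol; the default junction model
yields CDR3 lengths centred in the low-to-mid 20s aa. A "bovid ultra-long"
preset splices extended D-like cores (in-frame, stop-depleted) into a
fraction of clonotypes to exercise the > 50 aa reporting path. Mutation is
substitution-only and defaults to 0; the large unalignable-read
fractions seen with real multiplex-PCR libraries (primer artefacts,
genomic background) are deliberately not modelled.

What passing tests therefore show: the operations are internally
consistent and recover planted truth exactly under a substitution-only,
fixed-geometry, signal-clean model. What they do not show: robustness to
indel divergence, non-canonical splice sites, somatic hypermutation,
sequencing-error profiles or primer bias in real data.

## Problem sizes and determinism

The validation suite uses a 12V/6D/6J/4C locus for module tests and the
full 30V/10D/8J/9C two-cluster locus (40% pseudogenes, 10% ORF, 20%
reversed V) with a 10,000-read, 800-clonotype zero-mutation repertoire for
the end-to-end checks; statistics oracles run on 100 seeded random
repertoires and RSS oracle equivalence on 1,000 seeded 1 kb sequences.
These sizes were chosen as the smallest that exercise every code path,
defect code and cluster boundary more than once. Every stochastic step is
seeded; identical seeds give byte-identical FASTA/FASTQ/GFF3/TSV outputs.
Built-in template sequences are synthetic, constructed deterministically
at load time, and are stand-ins rather than sequences of any real species.

## Known limitations

* Ungapped seed search and substitution-only simulation: indel divergence
  between target and reference species is not handled.
* Fixed leader/intron geometry instead of splice-site models.
* IMGT numbering is approximated by one template per chain; allele-level
  naming (`*01`) and clan assignment are out of scope.
* No paired-end merging, UMI handling, quality trimming or
  somatic-hypermutation-aware lineage grouping.
* The λ "family I / IV" Roman-numeral distinction seen in some ruminant
  nomenclature has no stated criterion and is not reproduced; a single
  numbering scheme is used.
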