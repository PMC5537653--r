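---
title: "Protein similarity networks for comparative prophage genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein similarity networks for comparative prophage genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromenet)
```

## Scope and model

`viromenet` compares sets of (pro)phage proteomes by building a
*reciprocated protein similarity network*: nodes are proteins, and an
undirected edge joins two proteins only when **both** directed pairwise
comparisons pass every threshold. Connected components of that graph are
the package's unit of protein grouping; everything downstream —
subgraph-size summaries, annotation transfer, marker congruence — is
computed on this partition.

"Reciprocated" here means *both directed hits pass all thresholds*, not
"reciprocal best hit". Two observations motivate this reading: query
coverage is asymmetric (a short protein can cover a long one poorly while
being fully covered itself), so requiring both directions is a real
filter; and best-hit schemes produce at most one edge per node per
proteome, which cannot yield the dense within-family cliques that
connected-component clustering relies on.

### Alignment engine

The pairwise engine is an exact Smith–Waterman local aligner with affine
gaps, written in C++ for speed. Scoring defaults are the gapped BLASTP
defaults — BLOSUM62 (taken from Biostrings' matrix data), gap existence
11, extension 1, a gap of length L costing 11 + L — with Karlin–Altschul
statistics (lambda = 0.267 nats, K = 0.041) converting raw scores to bit
scores and E-values. Three conventions matter and are fixed here:

* **Identity denominator**: alignment columns *including* gap columns
  (the BLAST `pident` convention).
* **Query coverage**: the aligned query span of the single optimal local
  trace over the query length. BLAST's `qcovs` sums all HSPs; a
  single-trace aligner has exactly one local alignment, so best-trace
  coverage is the honest analogue. This can undercount coverage for
  proteins whose similarity is split across several segments.
* **E-value search space**: pairwise `m * n` by default;
  `db_wide_evalue = TRUE` substitutes the total residue count of the
  protein set for `n`, closer to a database search. Absolute E-values
  still differ from NCBI BLAST, which adds composition-based statistics
  and edge-effect corrections; at the default 1e-5 threshold the passing
  set is dominated by the identity and coverage filters, which are
  E-value-free.

Among co-optimal alignments the trace with the smallest
`(q_start, s_start)`, then the smallest `(q_end, s_end)`, is reported;
the choice is implemented by propagating the minimal origin through the
three dynamic-programming matrices, so results are deterministic. A pair
with no positive-scoring residue match (e.g. disjoint alphabets) reports
raw score 0 with `NA` bounds and zero identity/coverage — such hits can
never become edges.

### Thresholds and summaries

Edge thresholds default to E <= 1e-5, identity >= 50%, coverage >= 50%,
applied with `<=`/`>=` so boundary values pass (the source material for
these cutoffs is silent on boundary semantics; inclusive comparison is
the less surprising choice). Isolated proteins stay in the graph as
one-element clusters, which is why `build_network()` takes the node
universe explicitly rather than inferring it from the hit table.

Printed percentages use round-half-up (66.1, 72.32-style values), not
R's round-half-even, to match how such tables are conventionally
reported; `summarize_components()` renders the subgraph-size
distribution as `"<size>s:<count>n"` tokens and
`parse_size_distribution()` is its exact inverse.

### Annotation transfer and congruence

The transfer rule is *majority label*: a hypothetical protein inherits
the most frequent non-hypothetical product of its component, ties broken
lexicographically for determinism. Any-annotated-neighbour rules
transfer more but are order-dependent and noisy; majority-with-tie-break
is reproducible and conservative. All-hypothetical components transfer
nothing, and existing annotations are never overwritten.

Marker congruence (e.g. terminase large subunit vs major capsid protein)
is quantified by the adjusted Rand index over phages carrying both
markers — a deliberate quantification of what is usually a qualitative
claim. Degenerate cases get a documented convention: fewer than 3 shared
phages returns `NA`; when the pair-counting correction denominator is 0
(both partitions trivial) the index is defined as 0.

The hypothetical-protein label test is case-insensitive equality to
"hypothetical protein" after whitespace collapse. The MTase scan matches
the amino-MTase catalytic tetrapeptide `NPP[YFW]` (motif IV);
C5-cytosine MTases expose no comparable short protein motif and are out
of scope. Replication proximity is measured in gene-order units (ordinal
CDS distance) rather than base pairs, because "adjacent to the
replication module" is a statement about gene neighbourhood, not
distance in nucleotides; replication genes are recognized by a
configurable product-keyword set (default: products containing
"replication").

### Attachment-site detection

Integration of a temperate phage into a tRNA gene leaves the attL/attR
common core as an exact direct repeat — the first N nucleotides of the
prophage region recurring downstream of the region end — while
reconstituting an intact tRNA at one junction. `find_att_repeat()`
searches for the *longest* region prefix (anchored at the region start,
forward strand, exact match) recurring within a downstream window,
breaking positional ties toward the position nearest the region end.
Defaults — `min_len = 10`, `max_prefix = 200`, `window = 1000` — bracket
the empirically observed 17 bp and 57 bp cores with a wide margin while
keeping the background rate of chance exact matches (~4^-10 per
position) negligible. Inverted or mismatched repeats and sliding-anchor
search are out of scope.

## The synthetic-data generator

Downstream stages are validated on data with planted, known structure:

* **Protein families** derive from one random ancestor under a star
  topology: each member mutates every site independently with
  probability `p = 1 - sqrt(identity/100)`, so two members agree at a
  site with probability ~`identity/100` and the expected pairwise
  identity matches the dial. No indels by default — the network rule
  only needs identity/coverage dials, and the no-indel model keeps the
  expectation analytic. Default family identities in the examples are
  60/75/90%, spanning weakly to strongly conserved modules. Planted
  motifs (e.g. `NPPW`) occupy a fixed relative position, are excluded
  from mutation, and thus appear verbatim in every member.
* **Label policy**: proteins without an explicit product are
  "hypothetical protein" with probability 0.70, the typical share of
  hypothetical annotations in (pro)phage proteomes.
* **Hosts** are uniform-composition DNA at 62% GC (prophage regions at
  61%, slightly AT-richer than the host, as observed for rhizobial
  prophages), carrying a prophage whose first L nucleotides are copied
  once into the downstream window, the following base forced to differ
  so the repeat cannot extend by chance; generation re-draws the
  placement (bounded retries) if the prefix accidentally recurs
  elsewhere in the window. The integration-site tRNA is placed so its 3'
  portion coincides with the attL core. CDS features follow a
  configurable module layout, integrase first and MTase genes adjacent
  to the replication gene by default.

What the generator does *not* emulate — realistic codon usage or
composition bias, indels, domain shuffling, phylogenetically structured
(non-star) evolution, split or overlapping genes, degenerate repeats —
bounds what green tests show: they demonstrate that the pipeline
recovers structure of the planted kind exactly, not that it is robust to
every failure mode of real annotations. In particular, real proteomes
produce chimeric components linked by multidomain proteins, which the
star model cannot generate.

## Problem sizes and determinism

The shipped analyses and tests use deliberately scaled problem sizes:
the simulated virome has 10 phages / ~215 proteins (23 families + 120
singletons), family-recovery checks run 20 replicate datasets of ~29
proteins at 75% identity, attachment-site recovery runs 100 replicates
per repeat length on 3 kb regions, and the alignment oracle comparison
uses 200 short reduced-alphabet pairs. These sizes give stable
Monte-Carlo margins (identity calibrated within ±3 points, hypothetical
fraction within ±5, background motif counts tested against the analytic
3/20^4 per-site rate by a Poisson test) while keeping a full run in
minutes on one core.

All randomness flows from explicit seeds (`synth_config(seed = ...)`,
`set.seed()` for ad-hoc generation); identical configurations produce
byte-identical FASTA/GFF3/TSV/JSON outputs, which the test suite asserts
directly.

## Known limitations

* The aligner computes one optimal local trace per pair; fragmented
  similarity (multiple HSPs) undercounts coverage relative to BLAST
  `qcovs`.
* E-values are uncorrected Karlin–Altschul values; do not compare them
  numerically with NCBI BLAST output, only through the (identity- and
  coverage-dominated) edge rule.
* Connected components are the only clustering offered; no community
  detection within large mixed components.
* Attachment-site detection requires exact, forward-strand, prefix-
  anchored repeats; biologically degenerate att cores will be missed or
  truncated at the first mismatch.
* GenBank flat files are not parsed; features enter as GFF3 (or the
  equivalent 9-column TSV), proteins as FASTA with
  `phageID|proteinID product` headers.
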