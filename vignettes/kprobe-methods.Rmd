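---
title: "Reference-free RNA event quantification with k-mer count indexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free RNA event quantification with k-mer count indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kprobe)
library(dplyr)
```

## The model

kprobe treats a collection of RNA-seq samples as a queryable database of
k-mer counts.  Every read of every sample is decomposed into its
overlapping 31-mers; each 31-mer is stored in *canonical* form (the
lexicographic minimum of the k-mer and its reverse complement, so
matching is strand-agnostic), together with one count per sample.  Any
RNA event that leaves a sequence-level signature — a point mutation, an
indel, a fusion junction, an aberrant splice junction, or simply a
transcript — can then be quantified by engineering a short *probe*
sequence containing that signature and looking up the counts of its
k-mers.  No alignment, no annotation and no re-processing of the reads
is needed once the index is built.

The choice k = 31 is the field's standard compromise: long enough that
random 31-mers essentially never collide in a transcriptome-sized
reference, short enough that a single-base event still yields 31
informative k-mers.  k must be odd so that no k-mer equals its own
reverse complement.

### Monotigs

Storing a count vector per k-mer is wasteful: adjacent k-mers along a
transcript almost always share the same counts.  The index therefore
groups k-mers into **monotigs**: maximal non-branching paths of the de
Bruijn graph over the indexed k-mers, split wherever the per-sample
count vector changes.  Each monotig stores one sequence and one count
vector; by construction, reconstructing per-k-mer counts from monotigs
is lossless.  Construction is fully vectorised: successor candidates of
both orientations of every k-mer are canonicalised in one pass,
unambiguous extensions become links, and maximal link chains are walked
out.

An optional *quantized* mode reproduces the behaviour of large
production indexes that trade exactness for space: monotigs become
purely structural unitigs (no count splitting) and each (monotig,
sample) count is binned to a power of two
(`2^floor(log2(mean of present k-mer counts))`).  Only in this mode can
a query run be unreliable, which is where the star marker below comes
from.  The default is lossless so that every downstream number is
exact and oracle-testable.

### Queries, triplets and the presence threshold

A probe of length L yields L − k + 1 query k-mers.  Consecutive query
k-mers that fall in the same monotig are reported, per sample, as one
run `begin-end:count` (1-based inclusive k-mer ordinals); k-mers absent
from the index form explicit `:0` runs, so the runs always tile
`1..L-k+1`.  Explicit zeros matter: the mean over all query k-mers is
the package's TPM-like abundance measure, and omitting absent k-mers
would bias it upward.

In quantized mode, a run whose fraction of present constituent k-mers
is below the presence threshold (`-P`, default 40%) is flagged with a
star: its binned count is not trustworthy.  Starred runs are excluded
from aggregates by default (configurable to count as zero) and never
contribute to the positive-k-mer tally used for calling.  Whether the
threshold should be evaluated against the monotig's full k-mer set or
only the k-mers the query overlaps is an open design point; kprobe uses
the overlapped k-mers, which is the more local and more conservative
reading, and documents rather than asserts it.

### Aggregation

Four per-sample aggregates are available, all computed over the
expansion of each run into `end − begin + 1` copies of its count:
weighted **mean** (TPM-like), weighted **median** (lower of the two
middle elements on even total weight, for determinism), **sum**
(raw-count-like) and **max** (unweighted over run values).  Summed
counts overestimate read counts by a factor read_len − k + 1, because
each read contributes that many k-mer observations;
`estimate_raw_reads()` divides it back out.  A "not measurable" result
(all runs starred, or a fully masked probe) is `NA`, never 0.

## Probe design

**Mutations.**  For each variant the mutant probe is the 30-nt left
flank + ALT + 30-nt right flank, and the wildtype probe the same flanks
around REF.  For SNVs both are 61 nt = 2k − 1 and every k-mer of the
probe covers the variant base, so mutant and wildtype k-mer sets are
disjoint.  For indels, "centered" is ambiguous; kprobe keeps the
(k−1)-nt flanks and lets the probe length follow the allele
(2(k−1) + allele length), which preserves the covering property for any
allele.  Flanks are truncated at contig edges with a warning; probes
that would fall below k are errors.

**Junctions.**  Fusion and neo-splicing probes are 51 nt centered on
the breakpoint — deliberately shorter than 2k − 1 so that all
51 − 31 + 1 = 21 k-mers span the junction, overlapping each side by at
least 5 nt.  An odd length forces an asymmetric split; kprobe fixes it
as 25 nt ending at the left breakpoint and 26 nt starting at the right
one, reverse-complementing minus-strand sides.  Junction coordinates
are accepted in the package's own 1-based inclusive TSV dialect rather
than BED, to avoid silent off-by-one errors against the many
half-open/closed BED producers.  A support filter
(`filter_junctions_min_support()`, default 4 reads) screens junction
catalogues before probe design.

## Masking

Probe k-mers that are not specific to the targeted event produce false
counts, and low-complexity k-mers match everywhere.  Masking deletes
offending k-mers and reassembles the surviving runs into fragments
(each necessarily ≥ k nt):

* **default**: delete k-mers occurring more than once in the genome;
* **max-on-transcriptome**: additionally cap transcriptome occurrences
  at X (X = 100 for wildtype mutation probes, whose sequence is by
  definition present in the references; X = 0 demands absence and is
  used for neojunction probes);
* **chimera**: delete any k-mer present at all in genome or
  transcriptome — appropriate for mutant and fusion probes, whose
  informative k-mers should not exist in any reference;
* **low-complexity**: delete k-mers containing a ≥ 6-nt homopolymer or
  with 3-mer complexity (distinct overlapping 3-mers / (k − 2)) below
  0.55.  The cutoff is taken as an established operating point; poly-A
  scores 1/29 ≈ 0.034 and an ACGT repeat 4/29 ≈ 0.138, both far below
  it.

Reference occurrence counting is canonical (both strands), so a probe
matching the minus strand of the genome still counts as present; the
original masking tools do not state their strand convention, and the
strand-agnostic choice is the safe one for unstranded libraries.  All
rules are applied per-k-mer in one pass and fragments are rebuilt once;
masking is idempotent.  A probe with zero surviving k-mers is *fully
deleted*: it is excluded from calling and from evaluation denominators
and reported separately, mirroring the usual "probes after selection"
accounting.

Fragments are queried separately and merged back per probe as the
pooled k-mer-weighted mean.  Only the mean supports this merge — a
fragmented probe's sum, median or max cannot be reconstructed from
per-fragment aggregates — so masked workflows fix mean aggregation.

## Calling and evaluation

A probe is called present in a sample when at least `min_hits` of its
masked k-mers have non-zero counts (default 3).  One positive k-mer is
enough to be sensitive but admits any single spurious k-mer; requiring
a handful is a large specificity gain at minor recall cost, and 3 is
the conventional default.  Variant allele frequency is
100 · mut/(mut + wt) from the mean counts of the masked mutant and
wildtype probes; when both are 0 the site is unmeasured (`NA`).

`evaluate_calls()` scores calls against a truth set over
(probe, sample) pairs: TP/FP/FN, precision TP/(TP+FP) (NA when nothing
is called — undefined, not zero) and recall TP/(TP+FN), across a grid
of `min_hits` values (1, 3, 5, 10 by default).  Called sets are nested
as `min_hits` grows, so recall is non-increasing in `min_hits` by
construction.

## The synthetic cohort

All validation runs on data generated by the package itself
(`simulate_cohort()`), with mandatory seeds and no hidden randomness.
The standard study is 3 samples over 20 random transcripts of
400–600 nt, 10 SNVs spiked at allele fraction 0.5 (each carried by one
sample, assigned round-robin), 5 fusion transcripts expressed only in
their carrier samples, and error-free 75-nt reads at 100× mean
coverage; an optional 1% uniform substitution error rate exercises the
`min_hits` trade-off.  Reads are drawn per transcript with probability
proportional to abundance × (length − read_len + 1), with uniform
starts; a transcript carrying a variant at fraction f emits
mutant-haplotype reads with probability f.  Transcript count and length
were sized so the whole cohort (≈ 40,000 reads per condition) builds
and queries in seconds on one core while leaving every event dozens of
informative reads.

The generator is deliberately idealised: uniform base composition, no
positional or GC bias, no fragment-length model, no PCR duplicates, no
quality-score structure, substitution-only errors.  Passing tests
therefore demonstrate the correctness of the counting, masking and
calling machinery — not performance on real libraries, where
non-uniform coverage and systematic error patterns degrade precision
and recall in ways the simulator does not emulate.

## Numerical and degenerate-input choices

* Windows containing N (or any non-ACGT IUPAC code) are skipped during
  counting and treated as absent during queries; non-IUPAC characters
  are hard errors naming the offending read.
* The abundance filter (`abundance_min`, default 1) is applied per
  sample *before* monotig construction, matching per-sample
  preprocessing of production pipelines; raising it can only shrink the
  k-mer set.
* Homopolymer k-mers are their own de Bruijn successors; such
  self-loops (and two-node hairpins) are never chained into longer
  monotigs.
* An empty read set yields a valid empty index with a warning; querying
  it returns all-zero runs.
* The `.kqx` index container is a versioned plain-text format (metadata
  block, one tab-separated line per monotig, optional presence lines in
  quantized mode); the k-mer→monotig map is rebuilt at load, and a
  round trip compares equal to the saved object.  Corrupt headers or
  truncated lines fail hard, naming the offending field.

## Worked example

```{r example}
co <- simulate_cohort(n_transcripts = 8, n_snvs = 3, n_fusions = 1,
                      coverage = 50, seed = 11)
idx <- build_index(co$reads, index_config(k = 31))
glance(idx)

g <- setNames(co$transcripts$seq, co$transcripts$transcript_id)
gcounts <- reference_kmer_counts(g, 31)
pp <- design_mutation_probes(co$variants, g, k = 31)
mm <- mask_probes(tibble::tibble(probe_id = pp$variant_id, seq = pp$mutant_seq),
                  gcounts, mode = "chimera", transcriptome_counts = gcounts)
mw <- mask_probes(tibble::tibble(probe_id = pp$variant_id, seq = pp$wildtype_seq),
                  gcounts, mode = "max_on_transcriptome",
                  transcriptome_counts = gcounts, max_on_transcriptome = 100)
calls <- call_mutations(idx, mm, mw, min_hits = 3)
calls

evaluate_calls(calls, co$truth_mutation_pairs)
```

## Limitations

* The index lives in memory; this implementation targets method
  validation and moderate desk-scale collections, not thousand-sample
  compendia (no disk-resident query path, no socket server).
* Lossless monotig splitting fragments heavily when coverage is noisy
  across many samples (count vectors change often), reducing — though
  never invalidating — the compression benefit.
* Quantized mode documents its own binning; it is not bit-compatible
  with any external index format.
* The simulator's error model is substitution-only; indel sequencing
  errors, which break longer k-mer runs, are not emulated.
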