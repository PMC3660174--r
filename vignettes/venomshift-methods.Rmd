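---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(venomshift)
```

`venomshift` analyses a paired newborn/adult venom-gland experiment: long
transcriptome reads for toxin-family expression and isoform inference,
short small-RNA reads for miRNA profiling, and a target scan connecting
the two. This vignette records the models, their assumptions, the
parameters that matter, and the design decisions taken where a choice was
genuinely open.

## Read quality control

Long reads are kept when the arithmetic mean of their per-base Phred
scores strictly exceeds `min_mean_qv` (default 20) — whole-read filtering
in the min-qual-mean convention, with no trimming. Small-RNA reads are
quality-filtered the same way, then the longest 3' suffix matching an
adapter prefix with at least `min_adapter_overlap` exact bases (default 8,
no mismatch tolerance) is removed; reads that were entirely adapter are
the adapter-dimer bucket, and clipped reads outside the 15–40 nt window —
including reads in which no adapter was found at all — fall into the
length-filter bucket. Every input read lands in exactly one of processed /
adapter-only / length-filtered, so the per-stage bookkeeping table always
balances.

The low-complexity masker is a DUST-style triplet statistic: within a
sliding window (64 nt, step 32) the score
`sum(c_t (c_t - 1) / 2) / (n_triplets - 1)` over overlapping 3-mer counts
is compared against a threshold of 2.0, and offending windows become `N`.
It is a stand-in for library-based repeat masking: it flags tandem and
low-complexity sequence only, and knows nothing about interspersed repeat
families.

## Annotation and pileups

Reads are assigned to toxin families by local alignment against every
panel reference: +5/−4 match/mismatch in nucleotide mode, BLOSUM62 over
all six reading-frame translations in translated mode. Alignments at this
stage are ungapped, which keeps the scores on the scale described by the
ungapped Karlin–Altschul statistics used for the e-values: λ is solved
numerically for the scoring scheme under uniform letter frequencies, K is
fixed at 0.1, and the database size is the panel residue count. The
cutoff is `e_value < 1e-3`. These e-values rank hits against a small
curated panel; they are not a substitute for a full database search. Ties
break to the lexicographically smaller reference id, everywhere and by
construction.

Accepted reads are placed on their family reference by semi-global
alignment (read global, reference ends free; +5/−4, affine gaps open 10 /
extend 1) and stacked into a pileup in reference coordinates. Reads whose
alignment identity (matches over aligned columns, indels included) falls
below `min_identity = 0.70` are excluded from the pileup and reported as
the stage's singleton count — the identity floor is not something the
two-stage design fixes, so it is a configurable parameter. Coordinates
are 0-based half-open internally and 1-based inclusive in every report.

## Consensus, variants, and the distinctness model

Per pileup column, the consensus residue is the majority base, reported
only when depth ≥ `min_support` (4 reads); ties break to the
alphabetically first base. A residue is a valid variant when its support
is at least `min_variant_reads`. The default is 3 — the observing read
plus two others; the laxer reading (two reads in total) is exposed as the
same knob set to 2. A position with two or more valid variants is flagged
variable, the signature of co-transcribed alleles or isoforms.

Two aligned sequences are the same gene when their differences are
explainable by sequencing error. With per-base substitution rate `e`
(default 0.015) on each of the two sequences, a column mismatches by
error alone with probability `p_mm = 1 − (1 − e)²`; over the `L` columns
where both sequences are determined, the error-only mismatch count is
Binomial(L, `p_mm`), and the pair is distinct when the observed count `d`
exceeds the `1 − α` quantile (α = 0.01, one-sided, configurable). The
test operates on nucleotide columns by default; amino-acid level
comparison is available by supplying translated sequences. `d` counts
only differences whose residues meet the variant-support rule when that
information is available: `distinctness_test()` accepts per-column
validity masks, and `infer_gene_groups()` derives a per-column, per-base
support matrix from the pileup, so isolated error-attributable
differences do not inflate `d`.

The minimum gene count of a family is the number of connected components
under single linkage of the pairwise same-gene relation. Two numerical
guards matter here:

* Pairs sharing fewer than `min_overlap` comparable columns contribute no
  link. For read-level grouping the default is 150 columns: a short
  overlap gives the binomial test too little power near the detectable
  divergence floor, and under single linkage one under-powered pair can
  chain two true isoform groups together.
* Detectability itself has a floor. At `L` comparable columns the
  threshold is `Q = qbinom(1 − α, L, p_mm)` — about 28 at L = 600 — so
  isoforms must differ at comfortably more positions than `Q` before the
  model can separate them. At `e = 0.015` that means a within-family
  divergence of roughly three times the threshold rate (≳ 0.14
  substitutions per site) for reliable recovery; divergence near
  `Q / L` (≈ 0.05) sits exactly at the decision boundary and recovery
  there is a coin flip by design of the test, not an implementation
  artefact. The synthetic fixture therefore plants isoforms at divergence
  0.15.

Cross-stage comparison translates each gene group's consensus and
clusters the proteins greedily in decreasing length order (ties by id):
a sequence joins the first cluster whose representative it matches at
global identity strictly above 0.8, else founds a new cluster. A cluster
containing members from both stages is shared. After the mandated length
sort with id tie-break, the outcome is permutation-stable.

## Quantification and NOISeq-sim

Family expression is standard RPKM,
`(reads + singletons) / ((total_reads / 1e6) × (length_nt / 1e3))`, where
`total_reads` is the stage's quality-filtered read total and the length
is the family reference ORF length (both interpretations are arguments,
not constants). Percentage shares are per stage and sum to 100 within
rendering precision; reports print two decimals and additionally carry
full-precision values, because published tables of this kind mix
round-half-even with truncation and a reader should be able to tell.

NOISeq-sim handles the no-replicate design. Counts with zeros replaced by
`k = 0.5` are scaled to reads-per-million of their sample depth and
divided by length (kb) when lengths are supplied. Per condition,
`nss = 5` pseudo-replicates are drawn multinomially at `pnr = 0.2` of the
condition depth, jittered uniformly in `[1 − v, 1 + v]` with `v = 0.02`.
The signal per feature is `M = log2(mean_a / mean_b)` and
`D = |mean_a − mean_b|` over the normalised replicate means; the noise
distribution pools `(|M|, D)` from all within-condition replicate pairs
across all features. The differential probability is the fraction of
noise pairs strictly dominated in both coordinates — strict inequalities,
the conservative tie choice — and a feature is called at
`prob > 0.9`. Where the published description of the procedure is silent
(noise pooled across features, uniform jitter), these choices are fixed
here and deterministic under the seed. Below 10 features the noise
distribution is unstable; the fit proceeds with a warning.

## miRNA profiling

Processed reads are clustered greedily in decreasing length, then
multiplicity, then sequence order; a read joins the best-matching
(highest-identity) cluster whose representative it matches at global
identity strictly above 0.98, in the accurate-mode sense, else founds a
cluster. Identity is matches over global-alignment columns. A consequence
worth knowing: for 15–40 nt sequences, one mismatch already drops
identity below 0.98 (39/40 = 0.975), so the default threshold admits only
identical sequences and the cluster consensus equals the representative;
the per-column majority consensus becomes active only at laxer
thresholds. Abundances are counts per million processed reads (the
published scaling states no unit; raw fractions are recoverable from the
counts), and the ≥ 100-read filter selects the reportable clusters, with
the ≥ 1000-copy view available as a report option.

Stage comparison cross-matches the two consensus sets at the same
identity threshold into one-to-one shared pairs (highest identity first)
and stage-unique remainders, then runs NOISeq-sim on the shared clusters'
read counts. Annotation against a user-supplied mature-miRNA FASTA
reports the reference entry with the fewest mismatches over a
full-length-of-the-shorter sliding alignment, bounded at 2 mismatches,
with the species parsed from the reference header.

## Target scanning

The scanner is a position-weighted local alignment of the reversed miRNA
along each 3'-UTR under complementarity scoring: Watson–Crick +5, G:U +1,
mismatch −3, gap open −9, gap extend −4, with pair scores over miRNA
positions 1–11 doubled (`fiveprime_weight = 2`). Non-overlapping local
optima above a reporting floor (40) are enumerated by iterative masking.
The published analysis fixes only the three reporting filters — score
strictly above 100, duplex ΔG strictly below −19 kcal/mol, and at least
2 distinct target transcripts per miRNA — so all other constants live in
`scan_params()`.

The seed requirement demands Watson–Crick pairing at miRNA positions 2–7;
G:U wobbles fail the seed unless explicitly allowed, and position 1 is
never required (the 5'-most nucleotide of an Argonaute-bound guide is
anchored in the protein, not paired), with a flag to enforce it for
sensitivity analyses. 3'-compensatory pairing (positions 13–16/17) is
annotated on hits but does not relax the seed by default, since such
sites are rare.

Duplex free energy is a two-state nearest-neighbour estimate: stacking
terms over consecutive Watson–Crick pairs adjacent on both strands, from
a shipped RNA/RNA 37 °C table (the ten canonical stack values plus their
reverse-complement completions), plus a +4.09 kcal/mol initiation
penalty. Wobble, mismatched, gapped and unpaired positions break stacks
and contribute nothing; terminal-AU penalties and dangling ends are
omitted. This is deliberately not a partition function — it is the
secondary filter the reporting thresholds were designed around, and an
adapter seam allows substituting an external folding engine without
touching the filters.

## The synthetic generator: what it emulates, what it does not

The generator reproduces the statistical structure the analysis assumes:
per-family abundances defaulting to the published newborn/adult
percentage shares (the adult column prints to 99.95 and is renormalised),
within-family isoform mixtures at controlled divergence (an isoform
differs from the family reference at exactly `round(divergence × length)`
positions; with two isoforms per family that is also their pairwise
difference), substitution errors at 1.5 % per base, read lengths around
560 nt, a configurable fraction of low-quality reads, adapter-flanked
miRNA reads with exact per-stage copy numbers plus binomially injected
adapter-dimer reads, and planted 3'-UTR target sites that are exact
reverse complements of their miRNA. Expressed miRNAs are kept comfortably
above the 100-read filter so the designed stage roles are realisable,
with one deliberately low-abundance miRNA per exclusive group to
exercise the filter.

It does not emulate: indels (an optional rate exists conceptually but the
error model is substitution-only, keeping the binomial distinctness model
exact — homopolymer artefacts of pyrosequencing are out of scope),
position-dependent quality, chimeras, flow-space effects, or real adapter
chemistry (the 30-mer/23-mer adapters are fixed arbitrary placeholders,
as the published sequences are not available). Passing tests on this
generator therefore demonstrate correctness of the inference under the
stated error model, not robustness to indel-rich real 454/Ion-Torrent
data.

All generators are pure functions of (parameters, seed); the pipeline
derives per-stage child seeds from one master seed, and a re-run of the
same configuration writes byte-identical reports (the manifest hashes the
content-defining configuration, excluding the output directory).

## Problem sizes

The shipped fixture uses 4 families × 2 isoforms (600 nt ORFs, 150 nt
UTRs), 4,000 long reads and 20,000 small-RNA reads per stage — sizes
chosen so a complete two-stage run finishes in about two minutes on one
CPU while every stage still operates in its intended regime (30–60×
family coverage, clusters on both sides of the abundance filter).
Recovery experiments use 450 nt ORFs, 350 nt reads and 30× per-isoform
coverage over 100 seeded replicates per condition. Pileup-based gene
grouping subsamples to at most `group_max_reads = 400` reads per family
(deterministically, by read id) — pairwise grouping is quadratic in
reads, and 400 reads at these coverages already determine the grouping.

## Known limitations

* The distinctness model assumes independent substitution errors; systematic
  or homopolymer errors violate it and would inflate gene counts.
* Single linkage is deliberately conservative (a "minimum" gene count) but
  is sensitive to chaining near the divergence floor; the `min_overlap`
  guard mitigates, not eliminates, this.
* No de novo assembly: "mapped" read counts stand in for assembled-read
  counts, and the reports say so in their column naming (`mapped_reads`
  with the assembled percentage computed from it).
* The e-value model is ungapped and panel-sized; it ranks candidates, it
  does not calibrate genome-scale searches.
* The energy model omits loop, dangle and terminal corrections; its ΔG
  values are comparable against the −19 kcal/mol filter threshold, not
  against folding-engine outputs.
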