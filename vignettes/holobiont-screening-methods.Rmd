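---
title: "Screening holobiont transcriptome assemblies: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening holobiont transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoscreen)
```

## The problem

RNA extracted from a symbiotic cnidarian — a coral or anemone hosting
intracellular dinoflagellates — is a mixture: host mRNA, symbiont mRNA,
residual rRNA and mitochondrial transcripts, and material from the
associated microbial community. A de novo assembly of such a library
therefore needs screening before it can serve as a reference: which
transcripts are host, which are symbiont, which are organellar or
bacterial? And when several libraries are barcoded, prepared and
sequenced together, material can leak between them, leaving nearly
identical sequences in assemblies from different species.

`holoscreen` implements that screening as a set of small, testable
stages: whole-read filtering, assembly size statistics and completeness
metrics, a taxonomic-origin decision tree, an abundance-ratio
cross-contamination screen, gene-name transfer with reciprocal lookup,
imperfect microsatellite discovery, and taxon-occupancy-filtered
supermatrix construction. A synthetic-data module generates every input
with planted truth, so each stage's behavior is verified end to end
without any external database.

## Read filtering

Reads are removed whole, never trimmed. A pair is dropped when either
mate has **strictly more than 20 positions below Phred 20**, contains an
adapter as an exact substring, or contains a poly-A homopolymer run of
at least `polya_min` bases. The poly-A run length is not a standard
constant; the default is 20 bp and configurable. Whether poly-T runs
(the reverse-complement appearance of an oligo-dT artifact) also count
is flag-selectable and on by default. A read removed for several reasons
is counted once, under the first rule in the fixed order low-quality,
adapter, poly-A, so reports are deterministic and the counts always
partition the input.

## Size statistics and the core set

Homology-based analyses use only contigs of at least 400 bp (inclusive):
shorter contigs rarely produce significant matches and inflate
transcript counts. N50 is the length at which the cumulative length of
core transcripts, taken longest first, first reaches half the total core
length. The tests verify both the mean and N50 against an independent
implementation (largest length L such that contigs of length at least L
hold half the total), including the 399/400 boundary.

## Ortholog Hit Ratio

Completeness is measured per reference ortholog, on a 0–1 scale:

* **OHR~HITS~** — the fraction of the reference protein covered by the
  union of a transcript's local-alignment segments (HSPs), computed
  with interval arithmetic on orientation-normalized subject
  coordinates. Strict: divergent regions that fail to align count
  against the ratio.
* **OHR~ORF~** — the transcript's longest stop-codon-free codon run in
  the search-defined reading frame, in codons, divided by the reference
  protein length, clamped at 1. Inclusive: it credits sequence that is
  present but too divergent to align.

Two deliberate choices: coverage is computed per (transcript, gene) pair
and then maximized per gene — coverage from different transcripts is
never pooled, since the metric describes how complete a *single*
assembled transcript is; and the ORF run requires no start codon,
because assemblies routinely truncate 5' ends and demanding ATG would
bias the ratio downward. Stop codons are TAA/TAG/TGA (standard code);
a codon containing N cannot be confirmed as a stop and is treated as
non-stop. Genes with no match are absent from the summary rather than
scored zero, so medians are over matched genes.

## The origin decision tree

Evidence per transcript is the best (maximum) bit-score against each of
four small databases — host rRNA, a cnidarian mitochondrial genome,
host gene models, symbiont gene models — thresholded at bit-score 45,
plus the taxon class (metazoan/nonmetazoan) of the best hit in a
comprehensive protein database at E-value at or below 1e-5. The class
label arrives as a precomputed column; accession-to-lineage resolution
is out of scope. Rules apply in order, first match wins:

1. any rRNA hit → `rRNA`; 2. any mitochondrial hit → `mtDNA`;
3. symbiont above host (absent = −∞) and class not metazoan →
   `dinoflagellate`;
4. host above symbiont and class metazoan or absent → `metazoan`;
5. the two routes conflict, or host and symbiont tie exactly →
   `other_taxa`;
6. neither host nor symbiont hit: the class label decides;
7. no evidence at all → `no_match`.

The exact host/symbiont tie goes to `other_taxa` because the procedure
routes ambiguity away from both partners. A transcript with only a
symbiont hit but a metazoan best match in the comprehensive database is
treated as a conflict (rule 5); the source procedure does not specify
this corner, and we flag rather than guess. `other_taxa` and `no_match`
are kept separate categories. The implementation is verified against a
hand-written 72-row decision table covering the full evidence space,
and the six categories always partition the assembly.

## The cross-contamination screen

Cross-library hits at bit-score ≥ 100 define a near-identity graph;
connected components are clusters of putatively shared sequence. Per
cluster, each library's value is the maximum abundance among its member
copies, in per-million units so libraries of different depth are
comparable (whether the original procedure used raw or normalized
counts is unstated; normalization is the default and a flag exposes the
choice). With m the highest and s the second-highest library value:

* s = 0 < m: assigned to the top library (infinite ratio);
* m/s ≥ 10 (inclusive): assigned — recipients' copies are removed;
* otherwise every copy is flagged `unknown origin` and removed from all
  libraries. Both-zero clusters are undecidable and flagged.

The ratio comparison uses a relative epsilon of 1e-12, so a planted
ratio of exactly 10 realized through one floating-point division cannot
fall on the wrong side of the inclusive boundary. Components confined
to one library are within-library duplicates, not cross-contamination;
they are logged as singletons and retained. Every input transcript
appears exactly once in the cleaned output or the removal report.

## Name transfer and reciprocal lookup

Gene names transfer from the best protein-database hit at E ≤ 1e-4
whose description is informative; matches whose descriptions contain
"uncharacterized", "unknown", "hypothetical" or "predicted protein"
(case-insensitive substrings; the lexicon is configurable, since the
source list is open-ended) fall through to the next-best informative
hit rather than leaving the transcript unnamed. Bit-score ties break
lexicographically by accession, so results are independent of hit-table
row order. Reciprocal lookup accepts a transcript when its forward
match reaches bit-score 45 and the description of its best informative
reverse hit contains at least one target keyword.

## Microsatellite discovery

The repeat-finding tolerance trio — locus length ≥ 30 bp, ≤ 15%
deviation from a perfect repeat, flanks ≥ 30 bp, motifs 2–5 bp — needs
a concrete definition of "deviation"; the original tooling kept it
internal to its scoring engine. Here deviation is the **edit distance
between the locus and the best-phase perfect tandem array of the motif
(minimum over cyclic rotations and their reverse complements, tiled to
the locus length), divided by locus length**. This is transparent and
independently checkable by dynamic programming, which the tests do for
every emitted locus. Motifs are reported canonically (lexicographic
minimum over rotations and reverse-complement rotations), homopolymers
and homopolymer multiples are excluded, and overlapping calls of one
repeat type collapse to the longest window.

Detection is seed-and-refine. Seeds are maximal positively scoring
segments of the period-*k* self-match profile (base *i* equals base
*i+k*; match +1, mismatch −1.25 — calibrated so an array at the 15%
ceiling still yields one spanning segment while random background, with
~75% mismatches, drifts firmly negative). Candidate motifs are the
frequent k-mers of the segment, ranked by how close their perfect array
is to the segment. The window is then refined in deterministic passes:
growth with jump lookahead (an extension must add fewer edits than half
its length, so isolated interior edits are crossed but random flank is
not absorbed), a junk trim removing mostly-mismatch edges, a shrink
safety net, and a deviation polish that trims any edge whose removal
lowers the deviation — never below the minimum length — so a perfect
array is reported exactly, with deviation 0. All-mismatch pads are
removed even below the minimum length: a 28 bp repeat padded with junk
to 30 bp is not a locus. When greedy refinement strands a genuine locus
just under the minimum length, an exhaustive fallback scores all
admissible windows around the seed and keeps the minimum-deviation one.
The greedy-plus-fallback design is a documented local-optimality
compromise; it is validated by planted-truth recovery rather than by a
global optimality proof.

Redundancy collapse groups loci by canonical motif and collapses
transcripts connected by ≥ 95% identity hits to the longest
representative — an identity-based stand-in for re-assembly, justified
because inputs are already assembled transcripts. Primer targets grow
symmetrically from the locus plus its 30 bp flanks until the window is
150–500 bp at 45–65% GC, and are emitted as Boulder-IO records for a
primer-design run; primer design itself is delegated.

## Ortholog groups and the supermatrix

Tree-based paralogy screening is out of scope; the module implements the
terminal steps on pre-screened, pre-aligned groups: keep the longest
sequence per taxon (ties by lexicographic id), drop members under
100 amino acids — the length filter applies to the ungapped protein,
not the aligned row — then retain groups with taxon occupancy at or
above the chosen threshold (14 of 15 for the conservative matrix, 10
for the relaxed one). Retained groups concatenate in lexicographic
group-id order; taxa missing from a group receive all-gap blocks, and
the partition table uses 1-based inclusive coordinates in the common
`MODEL, name = start-end` convention. The occupancy filter is verified
against brute force and is monotone in the threshold.

## The synthetic-data generator

The generator's defaults describe the study conditions the package
targets: four co-prepared libraries — two aposymbiotic with a small
dinoflagellate fraction, two symbiotic with a large one — transcript
lengths near 1.4 kb (sd 600 bp, floored at 200 bp, echoing observed
core-set size distributions), host transcripts built as UTRs around a
long stop-free ORF so the ORF-based completeness ratio is exercised
meaningfully, symbiont background at distinct GC (0.51 vs 0.39; the
classifier never uses composition — the contrast simply mirrors real
host/symbiont compositional difference), 50 spiked contaminant
clusters cycling fold ratios {2, 5, 10, 20, 100} across both sides of
the decision boundary, and scattered per-database bit-scores planted
above the relevant thresholds. Scores are planted relative to
thresholds, not drawn from an alignment-score statistics model, and
reads carry no sequencing-error model: what passing tests show is that
the decision logic is exact over its evidence space, not that the
thresholds themselves are optimal for any particular real library.

Planted microsatellites are perfect arrays mutated by exactly
`floor(deviation × length)` substitutions, placed with pairwise
distance greater than the motif length and replaced by a uniform draw
from the three other bases. The spacing models scattered point
mutations and keeps the ground truth identifiable: clustered edits can
coherently rewrite adjacent copies into a *different* repeat type, at
which point the planted motif is no longer the true description of the
locus and "recovery" becomes ill-posed. Abundances are log-normal,
scaled to parts per million, with contaminant copies overwritten so the
planted ratio holds exactly (noiseless) or under log-normal noise
(noisy mode); overwriting after scaling leaves library sums within a
few percent of 1e6.

Determinism: every dataset is a pure function of the configuration
seed; the same seed reproduces byte-identical files.

## Problem sizes used in the checks

The shipped verification runs use: 1,380 transcripts (1000 host + 300
symbiont + 20 rRNA + 10 mito + 50 bacterial) for noiseless origin
recovery; 4 libraries with 50 spiked clusters for the contamination
screen; 500 random HSP sets and 200 random transcripts for the
completeness-metric oracles; 100 random length lists for N50; 100
planted microsatellites; 100 random ortholog groups over 15 taxa; and
2,900–220 read pairs for the filter checks. These sizes keep every
property exact (agreement is reported as a percentage of cases, not a
statistical fit) while running in minutes on one CPU.

## Known limitations

* Hit tables are consumed, never produced: no aligner is run, and the
  synthetic tables encode idealized evidence. Real search output adds
  noise the decision tree does not see here.
* The comprehensive-database taxon class is a given label; taxonomy
  resolution errors upstream propagate directly.
* The SSR detector is greedy with an exhaustive local fallback;
  pathological edit arrangements outside the generator's point-mutation
  model (long indel runs, adjacent-copy rewrites) may shift reported
  boundaries or the motif label.
* The contamination screen decides per cluster from abundance ratios
  only; it cannot distinguish true biological sharing (e.g. identical
  symbiont sequences in two symbiotic samples) from library leakage —
  such clusters are conservatively flagged unknown origin.
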