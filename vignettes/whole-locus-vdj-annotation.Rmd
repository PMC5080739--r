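---
title: "Whole-locus alignment and annotation of V(D)J recombination reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-locus alignment and annotation of V(D)J recombination reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjalign)
```

## The problem

Adaptive immune receptors are assembled somatically: one Variable,
optionally one Diversity, and one Joining region are cut out of the germline
locus and joined, with exonucleolytic trimming and non-templated
N-nucleotide insertion at the junctions. 5' RACE repertoire sequencing
captures receptor cDNA without V-segment primers and therefore also captures
transcripts that never completed recombination: J regions transcribed with
their genomic upstream, D–J-only intermediates (consistent with allelic
exclusion), intergenic transcripts, lone constant-region fragments, and
expressed pseudogenes. Aligning such reads against V/D/J segment databases
misplaces them; this package instead aligns every read against the **whole
receptor locus**, so that intergenic and upstream sequence is annotatable
rather than invisible.

A read is **regular** when it carries both a V and a J segment; everything
else is non-regular and is sub-classified by what its J segment is joined
to. The package covers the full path from raw reads to per-read segment
annotations, CDR3 junctions and regularity classes, plus a simulator that
makes the whole pipeline testable without any external data.

## The pipeline and its assumptions

### Alignment (anchor–chain–extend)

Candidate alignments are produced by an internal seed-and-extend aligner:

* **Anchors** are maximal exact matches of length ≥ `min_anchor` (default
  20 nt) on either strand, found with a k-mer index of the locus. No
  uniqueness filter is applied: a read segment matching several V-family
  copies produces one anchor per copy, which is essential for honest
  multi-hit ambiguity downstream. Non-ACGT characters never match.
* **Chaining** joins colinear anchors whose read and reference gaps are both
  ≤ `breaklen` (default 200 nt). Inter-anchor gaps are aligned by global
  affine-gap DP, and chains are scored by their true alignment score, so a
  merge across a gap is reported only when it beats its own sub-chains.
  Chains are extracted best-first until no anchor remains; inversions within
  one alignment are not modelled (they surface as separate alignments).
* **Extension** continues past the chain ends by free-end DP over a window
  of `breaklen` columns beyond the remaining read — `breaklen` is thus both
  the chaining gap bound and the extension reach, mirroring how far an
  aligner should "keep trying" before giving up. When extension changes a
  chain, both the extended and the bare variant are reported and greedy
  selection arbitrates; this keeps, e.g., a short J alignment alive when its
  extension across the J–C intergenic gap would otherwise lose wholesale to
  the constant-region alignment.

Scoring defaults are match +3, mismatch −4, gap open −6, gap extend −2,
with a gap run of length L costing `open + L·extend`; alignments scoring
below `min_report_score` (60, a 20 nt perfect match) are not reported.
Scores and identities are always recomputable from the stored trace, and
identity is matched columns over all alignment columns (gap columns
included). All of these are explicit stand-ins for a classical
genome-aligner parameterisation and are exposed in `align_params()`.

### Greedy optimal set

Initial alignments of one read heavily overlap. The reduction is
deliberately greedy, not globally optimal: repeatedly move the best-scoring
alignment into the set — together with every co-optimal alignment of equal
score **and identical read interval**, the multi-hit exemption — then drop
every remaining alignment whose read-coordinate overlap with a member
exceeds half of the shorter one (strict `> 0.5`). Overlap is measured on
read coordinates only: reference overlap is legitimate for duplicated
segments, read overlap is what marks mutually exclusive explanations.
Ties beyond the score are broken by a fixed total order (score desc, read
start, reference start, strand), making the result independent of input
order. The stricter reading of the co-optimal exemption (identical read
intervals, not merely equal scores) was chosen because equal scores at
different read positions are genuinely competing explanations.

### Annotation-aware filtering

Four rules run in a fixed order (exon consistency → putative-CDR3 →
intergenic → multi-V realignment), each only ever removing alignments:

1. **Exon consistency** — co-optimal hits of one read segment to the same
   exon of several V genes are resolved by any member hitting the partner
   exon of a subset of those genes; the supported subset survives.
2. **Putative CDR3** — a member whose transcript-order neighbours are a V
   second exon (5') and a J (3') sits where the hypervariable junction lies;
   random junction alignments are noise unless the segment is from a D or J
   region or the alignment is long (≥ 60 bp). "Flanked" requires adjacency
   among surviving members, with gaps allowed, because N-additions make
   exact abutment impossible; the rule is mirrored for minus-strand reads.
3. **Intergenic** — alignments whose dominant label is intergenic are
   dropped when short (< 40 bp) **and** inferior (identity < 95%). The
   conjunctive reading is the conservative one (it filters less) and a
   `disjunctive` switch is provided in `filter_params()`.
4. **Multi-V realignment** — if co-optimal alignments still annotate more
   than one V gene, the read is realigned with `relaxed_breaklen` (default
   800 nt), letting chains merge across longer gaps and extensions reach
   further; selection and the filters rerun, and the rebuilt set is adopted
   only if exactly one V gene's alignment now scores strictly higher than
   all competitors ("stands out"). Ties keep the ambiguity, and multiple V
   calls are then reported side by side — never silently reduced to one.

### Overlap trimming

Alignments surviving selection can still overlap by a few bases. For each
consecutive overlapping pair, every cut point in the overlap (inclusive of
both ends) is evaluated: the left alignment is trimmed to end at the cut,
the right one to start there, boundary gap columns are stripped, and scores
are re-derived from the trimmed traces. The chosen cut maximises the total
**bonus score** — alignment score plus one point per aligned base whose
reference position lies in a V, D or J region — which pulls cut points onto
exon boundaries. The bonus deliberately excludes C-region bases ("V/D/J"
taken literally). Ties take the smallest cut. Cut points live on read
positions; a cut falling inside a reference-gap run resolves to the nearest
read position on its left. For three or more mutually overlapping members
the pairs are resolved left-to-right (chained small overlaps are rare and
this keeps the procedure deterministic); joint optimisation over all cut
points is a non-goal. Co-optimal siblings are trimmed identically, using
the first sibling in reference order to choose the cut.

### Segments, classes, CDR3

Each surviving alignment (sibling groups merged) becomes a segment labelled
by the **dominant annotated kind** of its reference interval — the kind
with the largest overlap, ties to the earlier region; a single overlapping
base suffices to count as "from" a kind, and intergenic only labels
segments touching no annotated region at all. This matters for the
signature non-regular pattern: an alignment running 120 nt upstream into a
50 nt J region is a J segment with `extends_upstream` (threshold: reference
start ≥ 10 nt before the region start, configurable), not an intergenic
one. A segment spanning two J regions carries both gene names.

Classification: V and J present → `REGULAR`. Otherwise the J segment's
immediate 5' transcript neighbour decides, in precedence order D → C →
another J (distinct gene) → intergenic segment; a J with no 5' partner is
`J_NO_V` (the upstream-extension class). Reads without a J are
`INTERGENIC_ONLY`, `C_ONLY`, `V_ONLY` (V, optionally with C) or `OTHER`.
The precedence is fixed and documented because a read can match several
descriptions; keying the subclass on the J's 5' partner keeps the classes
mutually exclusive and matches how non-regular RACE reads are described
(J extended upstream / joined to a D, a C, an intergenic segment, or
another J). A trailing C after the J — present in essentially every cDNA —
never reclassifies a read.

CDR3 extraction needs a V segment covering its gene's conserved 2nd-CYS
codon and a same-strand downstream J covering its J-PHE/J-TRP codon; both
anchors are mapped through the alignment traces to read positions. An
anchor falling in a gap column maps to the nearest aligned base toward the
junction and flags the record. The junction is reported anchor-inclusive
(Cys…Phe/Trp) with the anchor-exclusive IMGT-style interval alongside,
since conventions differ on inclusivity; translation is in the Cys frame,
`in_frame` and `has_stop` are recorded, and out-of-frame junctions are
translated up to the last full codon. D-segment calls are emitted but
excluded from accuracy guarantees: D regions are too short (≲ 16 nt) to
anchor reliably.

`compare_annotations()` reproduces the consistency taxonomy used to compare
annotation tools: per common read, `identical` (same V and J sets),
`extra` / `missing` (one side's calls are a proper superset/subset),
`distinct`, and `non_vj` (the second input made no V or J call at all);
reads present in only one input are tallied `unannotated`.

## The simulator: what it emulates and what it does not

`simulate_reference()` builds a scaled-down receptor locus: 9 V genes in 3
families at 97% within-family identity (pairwise; each member diverges from
a family ancestor at half the target divergence), exon1–intron–exon2 V
structure with introns of 250–400 nt, two D regions, a J cluster of six
(one flagged pseudogene, since expressed pseudogenes must still be
detected), one 300 nt C region, and a long (1.2 kb) intergenic stretch
upstream of the first D from which intergenic read material is drawn —
where aberrant intergenic transcripts concentrate in real data. CDR3
anchors are planted as a TGT codon 9 nt before each V exon-2 end and a TTT
codon at J offsets 31–33. The full human TRβ locus is an order of magnitude
larger (67 V, 2 D, 13 J over ~620 kb); the scaled locus preserves the
features that make the problem hard — repetitive V copies, introns wider
than `breaklen`, a dense J cluster — at test-friendly size.

Reads model spliced RACE cDNA: joined V exons (the non-spliced variant is
what the upstream-extension classes produce), junctions with uniform trims
(V end 0–6 nt, D 0–4 nt per side, J start 0–6 nt) and 0–10 uniform random
N-additions, a trimmed J, and constant-region sequence truncated to a
120–350 nt target (truncation only ever shortens the trailing C segment).
The default class mixture emulates the composition reported for 454 RACE
data of human TRβ: ~34% regular, the non-regular remainder dominated by
J-only reads (5' partners: upstream 77%, D 14%, C 5%, intergenic 3%,
another J 1%) and intergenic-only reads. The error model applies
independent per-base substitutions (default 1%) and indels (0.2%), with an
optional 454-like homopolymer length error, off by default. Junction
N-bases are drawn uniformly over ACGT — the simplest defensible choice, as
junction composition is not modelled here.

Per-read truth records the generating class, source genes, segment tilings
of the pre-error read, the exact CDR3 interval and sequence, and error
counts; all output is byte-deterministic under the seed. What the simulator
does **not** emulate: realistic clonotype frequency distributions, somatic
hypermutation (relevant for Ig, where identity thresholds are the only
lever), quality-score structure, and chimeric reads joining the locus to
foreign sequence. Passing tests therefore demonstrate correct mechanics on
locus-derived reads with uniform errors, not robustness to every artefact
of a real sequencing run.

## Numerical and interface choices

* Coordinates are 0-based half-open internally (BED-compatible annotation
  files); all human-readable output is 1-based inclusive.
* Minus-strand alignments store forward-read coordinates; the trace
  describes the reverse-complemented read walked along the reference.
  CDR3 sequences are always reported in mRNA sense.
* The read-length prefilter defaults to 100 nt: primer-trimmed RACE reads
  below that carry too little information to place on a locus.
* Reads are processed independently (no cross-read state), so a dataset may
  be sharded by read and the records concatenated; the test suite asserts
  byte-identical results.
* The reference k-mer index is memoised per locus and anchor length and is
  rebuilt transparently if invalidated by serialisation.
* Degenerate inputs: an empty FASTQ yields empty outputs and a warning;
  an all-N read aligns nowhere; an empty alignment set classifies `OTHER`;
  a member trimmed below one aligned base is dropped with a message.

Problem sizes in the test and acceptance suites — a ~12.5 kb simulated
locus, 500 error-free plus 1000 noisy reads, 300–1000 random cases per
brute-force oracle comparison — were chosen so the whole suite documents
the pipeline's behaviour at desk scale; all thresholds above are the
defaults the checks run with, not tuned values.

## Known limitations

* The greedy optimal set is faithful to its definition and therefore not
  globally optimal; adversarial overlap structures exist where a DP chain
  selection would keep more aligned bases.
* `breaklen` semantics couple chaining and extension; an aligner with
  asymmetric bounds could resolve some multi-V cases this one reports as
  ambiguous (ambiguity is always reported, never guessed away).
* Trimming optimises each overlapping pair separately; with ≥ 3 mutually
  overlapping members the left-to-right order is part of the definition.
* Single locus per run: paired-locus (e.g. TRα+TRβ) references are out of
  scope, as is aligning unannotated segments to a whole genome to chase
  translocations.
* Quality scores are read but unused by the algorithm.
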