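---
title: "Template-guided antibody sequencing from cryoEM models and de novo peptides"
author: "fabseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-guided antibody sequencing from cryoEM models and de novo peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Antibody variable domains are encoded by recombined germline gene segments
(V and J, plus D for heavy chains) carrying somatic hypermutation (SHM,
typically 1-10% of variable-domain residues). Two experimental routes give
direct but error-prone sequence reads of the secreted protein itself:

* **cryoEM model chains.** De novo model building in a cryoEM map of an
  antibody-antigen complex yields fragmented polypeptide chains whose
  per-residue confidence is written into the B-factor column of the mmCIF
  file. Sequencing accuracy is limited by local map quality and the error
  rate usually exceeds SHM levels, so raw model sequences cannot be read off
  as the antibody sequence -- but they are accurate enough to identify the
  germline V gene and often to span CDR3.
* **de novo LC-MS/MS peptides.** Bottom-up proteomics yields short tryptic
  peptides with per-residue local confidence. Peptides are accurate but
  unanchored: in a polyclonal mixture they cannot be attributed to the right
  antibody, isobaric Ile/Leu are indistinguishable, and CDRH3 spans the
  V(D)J junction where no germline template exists.

`fabseq` integrates both: reads are assembled **onto templates** rather than
against each other. A first pass matches reads to germline V/J/C segments
and identifies the top V gene per chain; CDR3 is read out of the consensus
between the conserved anchor residues; a recombined V+CDR3+J template --
optionally flanked by all unrelated germline V segments as decoys -- then
guides a second assembly pass over the peptide reads. The decisive benefit
of the EM-derived template appears in mixtures: peptides from unrelated
background antibodies are absorbed by their own germlines (the decoys)
instead of corrupting the target consensus.

## The procedure

1. **Ingest.** Chains are extracted from mmCIF atomic models, split at
   residue-number gaps (fragments align independently); per-residue
   confidence comes from the representative atom's B-factor (CA first,
   since CA is always present in built backbones). Files whose maximum
   B-factor is <= 1 are rescaled by 100: de novo builders write 0-1
   confidences while the ALC convention is 0-100. Peptide tables supply the
   residue string and space-separated local confidences; modification
   annotations are stripped. Every read gets an ALC (average local
   confidence) score.
2. **Filter.** Reads with ALC below the cutoff or fewer than `min_length`
   residues are dropped (both bounds inclusive). Defaults follow the
   standard run parameters: ALC 80 and length 5 for model chains, ALC 90
   for the guided peptide pass.
3. **Template matching.** Every read is aligned locally (affine-gap
   Smith-Waterman/Gotoh) against every template and assigned
   winner-takes-all to its best template if that score reaches
   `cutoff_score` (8 in pass one, 10 in the guided pass). Constant-domain
   and antigen *sink* templates are first-class templates so non-Fv chains
   do not inflate V-gene scores. A template's aggregate score is the sum of
   raw placement scores (length-normalisation is deliberately not applied;
   the aggregate then reflects both read quality and depth, which is what
   the score-identity correlation exploits).
4. **Consensus.** Each aligned read residue adds its confidence to its
   residue's weight at the mapped template column; the consensus residue is
   the weighted argmax. Insertions form separate columns keyed by
   (preceding column, rank); deletions contribute no weight.
5. **CDR3.** The junction is delimited by the conserved 2nd-Cys on the V
   segment and the J-Trp/Phe. CDR3 counts as covered only when every
   consensus column from anchor to anchor has nonzero read depth; the
   reported sequence lies strictly *between* the anchors.
6. **Recombine and guide.** The top V (through its anchor Cys), the detected
   CDR3 (or an X-run placeholder), and the top J (from its anchor onward)
   are concatenated into the primary template; with decoys enabled, every
   other V segment of the repertoire is appended. The peptide reads are
   re-matched against this template set and the final consensus is built on
   the primary templates only.

## Scoring scheme

BLOSUM62 with gap open -12 and extend -1 per additional gapped position,
over the 20 amino acids plus X. Two deliberate modifications:

* **X is neutral** (scores 0 against everything, including itself). X marks
  unknown residues and the CDR3 placeholder; a placeholder junction should
  attract reads by its flanking context, not by spurious X-residue scores.
* **Equivalence sets** (default {I, L}) are scored as identity: the mutual
  substitution score is raised to the pair's diagonal maximum *and* both
  residues score identically against every third residue (the more
  favourable of the two original scores). The second step is what makes the
  alignment score invariant under I/L swaps -- with raw BLOSUM62 rows, I and
  L differ against e.g. Trp, and a mass-identical swap would change the
  score. I/L equivalence is appropriate for MS-derived reads (identical
  masses); for model chains, side-chain density does distinguish them, so
  the EM scheme disables it (`equivalence_sets = list()`).

The exact modification of Smith-Waterman used by the original tooling is
not published; the scheme here is configurable and recorded in every run
report.

Deterministic tie-breaking: the endpoint with the longer aligned span, then
the smaller template coordinate, is preferred; within the traceback,
diagonal moves are preferred over gaps. Assignment ties between templates
go to the first template in input order. Consensus ties prefer the
template's own residue, then the lexicographically smallest.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff_alc` | 80 (pass one), 90 (guided) | minimum read ALC, 0-100 |
| `min_length` | 5 | minimum read length (residues) |
| `cutoff_score` | 8 (pass one), 10 (guided) | minimum raw alignment score for assignment |
| `gap_open`, `gap_extend` | -12, -1 | affine gap penalties |
| `placeholder_length` | 12 | X-run length for an uncovered CDR3 (a typical CDRH3 length) |
| `use_decoys` | TRUE | append unrelated germline V segments in the guided pass |

The ALC/score cutoffs follow the published run parameters of the workflow
this package reimplements; the score cutoff applies to the raw local
alignment score because no normalisation was specified.

## Two consensus outputs

`consensus_sequence()` returns the read-supported consensus with `.` at
uncovered template columns; all evaluation metrics treat `.` as an error
(`full` identity = matches / truth length). The pipeline additionally
reports a *final candidate sequence* in which uncovered columns inherit the
template residue (`fallback = "template"`): a template-guided assembly
always has a residue hypothesis at every position, and for the germline
framework that hypothesis is wrong only at uncovered SHM positions. The
honest dot-consensus is what the metrics grade; the backfilled sequence is
what a user would order as a synthetic gene, and it is the quantity used in
the mixture comparisons (where strategies differ mainly in whether the
*right* template was chosen).

## The synthetic-data generator

The simulator generates ground-truthed inputs with the statistical
structure of the real data, so every stage is testable without large
external downloads:

* `simulate_antibody()`: uniform V/J draw, uniform random CDR3, per-position
  SHM substitution (default 5%, inside the 1-10% range typical of mature
  antibodies) sparing the two anchor residues.
* `simulate_model_reads()`: fragments with geometric-tailed lengths (mean
  30, minimum 5) placed uniformly to a target coverage (default 5x),
  per-residue substitution errors (default 10%). Confidence is coupled to
  correctness -- correct residues draw from N(90, 6), erroneous ones from
  N(60, 12), clipped to [0, 100] -- so ALC filtering has signal, which is
  the premise of the ALC cutoff.
* `simulate_peptide_reads()`: tryptic digestion (cleave after K/R, not
  before P), missed cleavages merging adjacent fragments (default 0.2 per
  junction), substitution errors (default 4%), and I/L swaps (default 0.5
  per I/L residue) that keep *high* confidence -- MS genuinely cannot see
  them. `simulate_ms_dataset()` pools several digest replicates, as repeated
  LC-MS/MS runs would.
* `simulate_background()`: n unrelated antibodies with pairwise-distinct V
  genes, each contributing a fixed number of peptide reads; n = 5 with
  target-sized contributions reproduces a hard 5:1 background:target
  mixture, n = 1 a diffuse 1:1 background.

What the simulator does **not** model: spectrum-level peptide quality,
PTMs/glycosylation, nucleotide-level SHM hotspots, D-segment structure
(CDR3 is drawn uniformly -- the D segment is too short and hypervariable to
act as a template anyway), multi-copy Fabs in one map, and non-antibody
map content beyond a single antigen sink. Passing synthetic tests therefore
demonstrates the correctness and robustness of the *assembly machinery*
under controlled error models, not the accuracy attainable on any
particular experimental map, which is dominated by local map quality.

A note on the confidence model: because correct-residue confidence is
centred exactly at 90, the guided pass's ALC 90 cutoff passes roughly half
of all error-free peptides. This is intentional left-tail behaviour of the
stated confidence means, and it is why the pipeline pools digest
replicates; the template-backfilled final sequence covers the residual
coverage gaps.

## Bundled germline set

`inst/extdata/germlines_synthetic.fasta` is a **synthetic** human-like
repertoire: 20 V segments (10 heavy, 6 kappa, 4 lambda), 7 J segments,
3 constant-domain sinks and one antigen sink, generated from hand-written
family frameworks by seeded diversification (12-30% substitutions,
conserved anchors preserved). Segment names follow IMGT nomenclature but
the sequences are plausible stand-ins, not IMGT reference alleles; its
baseline pairwise V-gene identity (mean ~0.53 heavy) is in the realistic
range for a germline repertoire. For real analyses, convert an IMGT
reference FASTA to the header dialect
`>segment_id|species|chain_class|segment_type` (one record per allele,
gaps `.` and stops `*` are stripped on load). Anchor annotation flags
segments in which no Cys (V) or Trp/Phe (J) candidate is found; reference
databases occasionally misplace these residues and flagged segments need
manual curation.

## Numerical and design choices

* All indices and spans are 1-based and inclusive.
* V anchor = last Cys of the segment (the 2nd-Cys is the most C-terminal
  Cys in trimmed V genes); J anchor = first Trp/Phe in the `[WF]G.G` motif
  context, else the first Trp/Phe. Full IMGT unique numbering is out of
  scope.
* CDR3 excludes both anchor residues. The convention is applied to truth
  and prediction alike, so length differences are convention-invariant.
* CDR3 coverage requires contiguous depth from anchor to anchor: a
  consensus with holes inside the junction does not define a junction
  sequence.
* Insertion columns enter a spliced consensus only with majority support
  from the reads covering the neighbouring columns, so a single noisy read
  cannot lengthen the consensus.
* Decoy-captured reads are dropped, not subtracted from primary scores.
* Winner-takes-all assignment: each physical read has one origin.
* Confidence-scale auto-detection uses the file-wide maximum B-factor
  (<= 1 means 0-1 scale).
* The length difference reported for CDR3 is signed (predicted - true), so
  its distribution should be symmetric about zero for an unbiased
  estimator.

## Problem sizes in the test suite

The packaged tests and the acceptance script run entirely on synthetic
data at desk scale: 1,000 random string pairs (length <= 6) for the
alignment-vs-enumeration check, 50 seeded consensus fixtures, 20 recovery
replicates at SHM 5% / 5x coverage / 10% read error, 30 CDR3 detection
cases spanning covered and uncovered junctions, and 10 seeded 5:1 mixtures
for the background-tolerance comparison. These sizes give stable medians
and binomial checks with 3-sigma bands while a full run stays in the
minutes range.

## Known limitations

* Template-anchored only: no de Bruijn/overlap assembly, so reads that
  match no template (score below cutoff against every segment) are
  discarded, and truly novel framework regions cannot be recovered.
* Heavy/light pairing is taken from the map (chains co-located in one
  model); peptide data alone cannot pair chains.
* The aggregate score scale depends on read depth; cutoffs tuned for one
  input depth are not directly portable to another.
* The exhaustive alignment oracle is exponential and only usable for the
  short-string checks it exists for.
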