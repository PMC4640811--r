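---
title: "Methods: target-site specificity analysis for site-specific non-LTR retrotransposons"
author: "retrotarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-site specificity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrotarget)
```

## The biological problem

Several lineages of non-LTR retrotransposons that encode a
restriction-like endonuclease (RLE) integrate at a fixed position inside
a multicopy gene. For the families this package models, the target is
the U2 snRNA gene: the endonuclease cuts the bottom strand of the gene
after a fixed nucleotide (position 38 of the gene in the default model),
reverse transcription is primed at the nick, and the junction structure
left behind depends on where the enzyme cuts the top strand:

* top cut **downstream** of the bottom cut by *t* bases — the *t*
  intervening target bases are duplicated on both sides of the element
  (a target site duplication, TSD; reptile-type families leave 20 bp),
* top cut **at** the bottom cut — a blunt junction with no duplication
  (arthropod-type families),
* top cut **upstream** of the bottom cut by *t* bases — the *t* target
  bases between the cuts are lost (oomycete-type families delete the 38
  5'-terminal bases of the gene, so every disrupted gene fragment
  starts at nucleotide 39).

Because all nucleotides required for U2 function are concentrated in the
5' region, a gene is operationally *intact* when its first 50 nt are
present and uninterrupted, and *disrupted* when the locus begins at or
after the insertion site with an element 3' terminus immediately
upstream. Counting intact versus disrupted genes, classifying the
sequences flanking element termini, and measuring TSD/deletion lengths
together characterise a family's target specificity.

The package implements that analysis end to end and validates it by
parameter recovery on a synthetic-genome generator whose insertions
carry known ground truth.

## The synthetic-genome generator

`build_target_arrays()` emits one contig per tandem array: random
background, then genes separated by spacers, then background. Design
choices, fixed once:

* **Target gene**: `example_u2_model()` is a fixed synthetic 190-nt
  stand-in (not a natural U2 sequence) carrying the diagnostic
  post-insertion-site fragment `TCTGTTCTAATCAGTGTGAAA` at positions
  39–59, with `functional_5prime_len = 50` and `insertion_site = 38`.
* **Spacers** (150–400 nt by default) all derive from one ancestral
  random sequence and are then mutated at 30% per site: real intergenic
  sequence between tandem U2 genes is essentially unalignable between
  loci, and this makes spacers mutually diverged while remaining
  non-random in a realistic way.
* **Strand**: each array is emitted on the plus or minus genome strand
  with probability 0.5. Target-primed reverse transcription fixes the
  element's orientation *relative to the gene* (the junction structure
  `target[1..s+t] ⊕ element ⊕ target[s+1..L]` is orientation-coupled),
  so on-target insertions inherit the locus strand; only off-target
  copies get an independent random strand. Randomising at the array
  level therefore exercises both strands of every downstream algorithm
  without breaking the biology.
* **Copies**: each copy may be 5'-truncated (probability 0.5 by
  default, length uniform on `[0, 0.8 × length]` — the non-LTR
  hallmark of incomplete reverse transcription; truncation is 5'-only),
  then mutated at 5% substitutions and 0.1% single-nt indels per site.
* **Off-target copies** are placed at uniform random background
  positions with the family's geometry applied mechanically at the
  arbitrary site. Whether off-target integration really uses the same
  top-strand offset is unresolved in the literature; the generator
  implements the mechanistic model and the analysis reports what it
  sees rather than reconciling the two.
* **Tandem nesting** inserts later copies immediately 5' of the
  resident copy at an occupied locus, producing element-flanked 3'
  junctions.
* **Deletion model**: only the clean between-cuts deletion is
  simulated. Real oomycete loci may alternatively arise by duplication
  followed by recombination or gene conversion; sequence data cannot
  distinguish the two and the generator does not attempt to.

Every edit is recorded in a truth table (`copy_id`, interval, strand,
`tsd_len`, `deletion_len`, truncation, on/off-target, nesting), the
channel used by all recovery tests. Coordinates are 1-based closed in
memory (the R/Bioconductor convention); file output of truth and hit
tables is BED-like 0-based half-open.

What the generator does **not** emulate: sequencing error and assembly
gaps (N-runs can appear in real input and are handled by flagging, but
are not simulated), segmental duplications, gene conversion between
gene copies, nested insertions of one family into another at off-target
sites, and fine-scale substitution biases (mutations are uniform across
sites and bases). Passing recovery tests therefore demonstrates
correctness of the inference machinery under a clean insertion model,
not robustness to assembly artefacts.

## Alignment core

`smith_waterman()` is the exact local-alignment oracle (Biostrings
dynamic programming under a custom scheme; match +1, mismatch −1, gap
of length *L* scores −2 − (*L* − 1); `N` never matches anything,
including `N`). `seed_extend_scan()` makes it scale: exact *k*-mers of
the query (default *k* = 11) are matched genome-wide, seeds are
clustered on diagonals (band 32), and each cluster's window — sized to
hold the full query — is resolved by the exact aligner, so every
reported hit carries a true optimal score for its window and nothing
below `min_score` (default 30) is reported. Overlapping window hits are
collapsed to the best score. The defaults are chosen so a 70-bp 3'
anchor at ≤15% divergence seeds reliably; all are user-tunable.

## Copy detection and the junction harvest

`detect_copies()` scans with each family's full consensus, chains
collinear fragments within a 50-nt gap (kept deliberately tight:
junction precision matters more than chaining distant fragments),
resolves loci hit by several families to the best identity, and
annotates 5' truncation (consensus bases missing from the alignment 5'
end) and 3'-terminus intactness (alignment reaches the final consensus
base). `anchor_3prime_scan()` scans with only the 3'-terminal 70 bp —
the junction-harvest mode that finds termini of heavily 5'-truncated
copies a full-length scan can miss. Flanks containing an N-run of ≥5 nt
are flagged unsequenced; the threshold is our choice of proxy for
"region not sequenced" and is configurable.

## Junction analysis

Flanks are extracted in element sense (60 nt by default) and classified
against the target model and every family consensus: a candidate match
needs ≥75% identity over ≥12 aligned nt, with precedence target gene >
element > other on ties. The permissive default profile deliberately
scores the short degenerate target fragments seen at weakly specific
junctions as target-like; a strict profile (0.85/15) is available.

TSD and deletion inference combines three lines of evidence, in order:

1. **Coordinate evidence.** When both flanks match the target model at
   the junction, the gap between the 5' match end and the 3' match
   start decides: negative gaps are TSDs (the duplicated block maps
   twice), positive gaps are deletions, zero is blunt.
2. **Sequence evidence.** Otherwise the longest common block ending the
   5' flank and starting the 3' flank is a TSD if at least 5 nt
   (`min_seq_tsd`): shorter agreements occur by chance at 1/4 per
   base and are never called. This is the rule that still calls 20-bp
   TSDs at off-target insertions with no target-gene flank at all.
3. **Asymmetric deletion evidence.** A 3' flank matching the target
   model from position *p* > 1, with no junction-abutting target match
   on the 5' side, implies the 5'-terminal *p* − 1 target bases were
   deleted on integration — the upstream flank is then spacer or the
   intact neighbouring gene, exactly the oomycete signature.

### Junction refinement

The single hardest problem in this analysis is that the element
boundary reported by a local aligner is not the integration junction
whenever the sequence near the junction is ambiguous:

* a 5'-truncated copy offers the aligner consensus bases 5' of its
  truncation point, which sometimes pair spuriously with target bases
  (the aligner annexes flank into the element);
* a diverged terminal base drops out of the element alignment and sits
  in the flank, where it can coincidentally match the target model
  continuation (the target annexes element bases);
* a homopolymer shared by target end and element start makes the
  boundary genuinely undefined at ±1.

`call_insertions()` therefore refines both boundaries with a
split-point parse. A window spanning the flank plus up to 40 bases of
the detected element is probed with the target model (the 3' side is
handled by the same code on the reverse-complemented locus). If the
target match reaches the junction, each candidate reassignment of *k*
element-claimed bases is scored as

> target gain(*k*) − element marginal(*k*) − 0.5 *k*

where the element marginal is computed *exactly*, as E(0) − E(*k*) with
E(*k*) the best local score of the consensus against the element head
with *k* bases ceded — re-aligning for every *k* lets the element
re-anchor, so bases annexed through homopolymer shifts carry a
near-zero claim. The 0.5/base margin compensates the systematic
asymmetry that target gains are exact-model matches while element
claims are scored against a diverged copy. Finally, when a few terminal
consensus bases were left unaligned by detection (1–6 nt), they are
treated as the element's diverged terminus and returned to it before
probing; a large unaligned 5' remainder means truncation and is left
alone. The refusal threshold `probe_min_score = 12` keeps chance 12-nt
flank matches from triggering any of this.

On 200 simulated full-length insertions per geometry at 5%
divergence in a ~1-Mb genome (40 five-gene arrays, 1200-nt consensus),
this machinery recovers the exact top-strand offset for 97–99% of calls
across geometries and random family consensi, and the modal TSD length
and modal deletion length are exact. For 5'-truncated copies the 5'
junction is information-theoretically ambiguous whenever the base just
5' of the truncation point equals the corresponding target base
(probability 1/4 per copy), so the geometry-recovery experiments use
full-length insertions; truncation is exercised everywhere else, and
the two statistics anchored on the unambiguous 3' junction (the flank
start coordinate and the census missing-5' length) are reported under
the generator's default 50% truncation.

## Target-gene census

`census_target_genes()` scans the genome with the full target model,
merges overlapping hits, and — critically — clips every locus so it
never overlaps a detected element copy, re-aligning the clipped segment
so model coordinates stay exact. Without clipping, the one or two
element bases that coincidentally extend a gene alignment drag
`missing_5prime` off its true value *systematically*, because all
copies share a consensus terminus. Status rules: *intact* = model
coverage from base 1 through the functional 5' region; *disrupted* =
locus begins past the insertion site **and** an element 3' terminus
lies within `adjacency_gap` (5 nt) on its gene-sense 5' side (5'-end
adjacency is recorded but never counts as disruption); everything else
is *fragment*. Note that a TSD-type insertion splits a gene into a
still-functional 5' piece (intact: positions 1–58 include the whole
functional region) and a disrupted 3' piece, so intact + disrupted can
exceed the locus count for that geometry; for blunt and deletion
geometries under clean settings the counts are conserved exactly.
`bootstrap_target_model()` rebuilds the model from the majority
consensus of the surveyed genome's own intact loci, avoiding
cross-species reference bias.

## Family tools

`cluster_copies()` is single-linkage clustering on pairwise local
identity (link at ≥85% over ≥100 aligned nt); connected components make
the partition order-independent, and copies too short to reach the
overlap floor are flagged singletons. `majority_consensus()` emits the
most frequent non-gap base per column, keeps a column only when at
least half the rows are non-gap, and breaks ties alphabetically (a
fixed, documented rule). `star_align()` aligns each copy to a reference
and projects into common columns with shared insertion blocks.
Distances are plain p-distances on gap-excluded pairwise columns —
deliberately not model-corrected, because the tree
(`neighbor_joining()`, with bootstrap over alignment columns, 100
replicates by default) is a family-clustering aid, not a publishable
phylogeny; maximum-likelihood analysis of protein domains is outside
this package's scope. Negative NJ branch lengths are clamped to zero
and flagged.

## Pipeline and scoring

`run_pipeline()` chains detection (full-consensus scan supplemented by
anchor-only termini), junction calls, 3' and 5' specificity tables,
census, clustering, per-cluster consensus and the NJ tree, and writes
everything to TSV/BED/FASTA/newick with a parameter echo. The 3'
specificity table excludes copies that are 3'-truncated or have
unsequenced 3' flanks from the denominator — the standard exclusion
rule for junction tables. `score_against_truth()` reports detection
sensitivity, geometry accuracy (exact top-offset agreement on matched
on-target, non-nested calls), census accuracy against
`expected_census()`, and the adjusted Rand index between detected and
true family assignments. Identical inputs and seed give byte-identical
outputs.

## Problem sizes and numerical choices

The recovery experiments in the test suite and the acceptance script
use 200 insertions per geometry in ~1 Mb (40 arrays × 5 genes, ~25-kb
contigs), 1200-nt consensus sequences, 5% substitutions and 0.1%
indels — sizes chosen so a full three-geometry recovery analysis runs
in a few minutes on one CPU while keeping per-geometry call counts
large enough for stable modal statistics. Unit tests use smaller
genomes (hundreds of bases to tens of kb) with the same code paths.
Degenerate inputs are handled explicitly: empty flanks and N-rich
flanks are flagged unsequenced rather than classified; a deletion
geometry reaching past the target 5' end is rejected unless spillover
is explicitly allowed; all-gap alignment columns are dropped; local
alignments with no positive-scoring cell return an empty hit with
score 0.

## Known limitations

* Per-copy geometry calls on 5'-truncated copies are irreducibly
  ambiguous at single-base resolution; only modal statistics are
  reliable there.
* Off-target junction geometry is reported as simulated/observed; the
  package takes no position on whether real off-target integration
  shares the on-target cleavage offsets.
* The census inherits the field's operational definition of "intact"
  (functional 5' region present); it does not verify expression or
  function.
* Family clusters are identity-threshold proxies and need not match
  curated family boundaries.
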