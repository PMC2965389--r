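---
title: "Screening bacterial genomes for transcriptional attenuators"
author: "attenuscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening bacterial genomes for transcriptional attenuators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attenuscan)
```

## The screening problem

Transcriptional attenuation controls a bacterial operon by letting the
nascent transcript fold either into a Rho-independent (intrinsic)
terminator — a GC-rich hairpin followed by a U-rich stretch that dissociates
RNA polymerase — or into an alternative structure that permits readthrough.
Riboswitches, T-boxes, leader peptides and protein-responsive leaders all
share this output stage, so a terminator sitting in the 5' leader of a gene,
co-oriented with it, is a broad-spectrum footprint of attenuation that does
not require any knowledge of the sensing structure.

`attenuscan` implements that screen end to end:

1. derive searchable intergenic regions from an annotated genome,
   absorbing short (< 200 nt) hypothetical ORFs, which are often
   unrecognized leader peptides;
2. detect intrinsic terminator motifs on both strands (a trainable profile
   scorer first, a descriptor search as fallback);
3. classify hits as 5' (leader) or 3' terminators and filter 5' hits into
   attenuator candidates by orientation and distance;
4. rank gene families by attenuation propensity with normalized,
   phylogeny-weighted scores and Fisher exact enrichment tests;
5. cluster candidate leader sequences into putative regulons and flag
   mobile (insertion-sequence derived) attenuators.

A synthetic-cohort generator with planted ground truth makes the whole
pipeline testable without downloading genomes.

## Terminator detection

### The descriptor

The descriptor is the canonical intrinsic-terminator motif: a helix of
4–18 bp (Watson–Crick pairs, GU wobble allowed), a loop of 3–10 nt, a
spacer of 0–2 nt and a 12-nt T-rich tail with at least 7 T overall and at
least 3 T among the first 5 positions.  All admissible decompositions of a
sequence are enumerated exhaustively (the unit tests compare the scanner
against an independent brute-force enumerator); hits whose stems share any
position are resolved to the single hit with the lowest folding free
energy, with ties broken leftmost, then longest stem, then shortest
spacer.  An optional mode (`allow_bulge`) admits one single-nucleotide
bulge per stem arm, for the minority of natural terminators with imperfect
helices.

The descriptor alone, with no stability requirement, is extremely
permissive: on iid random sequence at GC 0.5 almost half of all 225-nt
regions contain some weak 4-bp hairpin in front of a chance T-rich window.
Intrinsic-terminator descriptors therefore carry a hairpin stability
threshold, and so does ours: `dg_max` (default −5.0 kcal/mol) rejects
decompositions whose hairpin is weaker.  The default was calibrated once,
before the validation suite was written, so that the descriptor's
false-positive rate on shuffled, UTR-sized sequence matches the 2–3% per
region that published screens of this kind report as their control level
(measured here: ~1.2% of random 115-nt regions, ~5% of T-rich shuffled
leaders).  Real terminator hairpins are far below the threshold: stems of
8 ± 1 bp at GC 0.8 have ΔG ≤ −5.7 kcal/mol in more than 99% of draws.

### The energy model

Hairpin stability is a transparent nearest-neighbor sum: stack free
energies over consecutive base-pair steps, a loop-initiation penalty for
`min(loop, 30)`, a +0.50 kcal/mol penalty when the closing pair is AU or
GU, and +3.8 kcal/mol per single-nucleotide bulge.  The values are the
Turner 2004 RNA parameters (DNA T read as U).  Loop terminal-mismatch and
special-loop bonuses are deliberately omitted: the energy of every
decomposition is then an auditable table sum, which the test suite
verifies against an independent re-summation to 1e-9.  Absolute energies
are therefore slightly less negative than a full folding model would give;
all thresholds and comparisons in the package use this same scale, so the
offset cancels.

### The profile scorer

The primary detector is a position-specific scorer trained on a
structure-annotated alignment of terminators (Stockholm, `#=GC SS_cons`
with matched brackets): ordered base-pair log-odds per stem column and
base log-odds per loop and tail column, with pseudocounts spread according
to the background composition.  Every descriptor-admissible decomposition
is scored (stems aligned to the profile columns outermost-first; columns
beyond the shorter span contribute nothing) and hits above the model's bit
threshold are reported, best score first.  `calibrate_threshold()` picks
the smallest threshold whose hit density on background sequences — for
example dinucleotide shuffles — stays below a target per-kilobase rate,
verifying each candidate threshold with a real filtered scan.

Regions are scanned two-pass: where the profile finds at least one hit on
a strand those hits are used; otherwise the descriptor result is used for
that strand.  With no model supplied the screen is pure descriptor.

## From hits to attenuator candidates

A hit is `five_prime` when it points toward a co-oriented flanking gene
(right gene for a `+` hit, left gene for a `-` hit), `three_prime` when it
instead trails a co-oriented upstream gene, with 5' taking precedence and
failed 5' hits falling back to 3'.  Candidates must satisfy two distance
rules that exclude ordinary 3' terminators of upstream genes and
terminators of independent small-RNA genes:

* `d_down` ≤ 300 nt — nucleotides strictly between the tail 3' end and the
  first codon of the downstream gene;
* `d_down / d_up` ≤ 1 — the hit must sit closer to its downstream gene
  than to the upstream gene.  `d_up` runs from the stem 5' start to the
  nearest boundary of the upstream gene and is floored at 1, so a hit
  overlapping the upstream gene gets a huge ratio and is discarded; a
  region with no upstream gene passes the ratio test automatically.

These anchor points (tail end vs. stem start, nearest boundary) are the
package's choice; the ratio rule itself does not pin them.  The candidate
leader runs from the limit of the upstream gene — or at most 200 nt
5' of the terminator stem, whichever is closer — to the position
immediately 3' of the tail, reported on the candidate strand.  The 200-nt
cap is anchored at the stem start; anchoring it at the tail end would
shift leaders by the ~35 nt of the motif and was rejected to keep the
upstream context, where sensing structures live, inside the window.

The 5'-vs-3' stability comparison (`compare_utr_stats`) reports class
means of ΔG and stem length with two-sided Welch t-tests: regulatory
terminators must permit an alternative readthrough fold and are expected
to be the less stable class.

## False-positive control by dinucleotide shuffling

`dinucleotide_shuffle()` is an exact Eulerian-path (Altschul–Erickson)
shuffle: the output has the input's exact 16-entry dinucleotide count
vector and the same first and last base.  This preserves local composition
— in particular the TT-richness of UTRs — so the control is conservative.
`estimate_false_positive_rate()` applies the scan protocol to `n`
shuffles of each region and reports the fraction of shuffles with at least
one hit, per UTR class, next to the observed rate on the originals.

## Family enrichment

Let `c_s` be the number of candidates upstream of family-`f` genes in
species `s`, and `g_s` the number of family-`f` genes there.  The package
reports three scores: the absolute count (favors big paralog families),
the normalized score `sum_s c_s / g_s`, and the phylogeny-weighted score
in which each `b_s = c_s / g_s` inside a run of `L` consecutive attenuated
species (in the user-supplied species order) is multiplied by
`1 + 0.1 L`.  Consecutive presence is evidence for a single ancestral
element rather than repeated independent gains, so parsimony-consistent
distributions score higher; a singleton species still receives the factor
1.1, so the weighted score is always at least 1.1 times the normalized
score.  The phrasing "+0.1 times the run length" also admits an additive
reading, which is available as `mode = "additive"`; the multiplicative
form is the default because it keeps the weighting scale-free in `b`.

Significance is a one-sided hypergeometric tail (`stats::phyper`), the
one-sided Fisher exact test on the 2×2 table (family genes, all genes,
attenuated family genes, all attenuated genes).  Raw p-values are
reported by default, with an optional Benjamini–Hochberg column; ranking
is by descending score with ties broken by ascending p, then family id.

## Regulon clustering

Candidate leaders are compared all-against-all with local alignment
(Smith–Waterman–Gotoh, match +1, mismatch −2, gap open 2, gap extend 1).
Raw scores convert to bits via the Karlin–Altschul formula with lambda
solved numerically from `sum p_i p_j exp(lambda s_ij) = 1` on the
background composition (~1.33 nats for these scores) and K = 0.621, the
published ungapped value for +1/−2.  The distance between two leaders is
the inverse bit score, capped at 1 for pairs without a positive-scoring
alignment, and complete-linkage clustering is cut at height 0.038 — i.e.
two leaders co-cluster only if they share a local alignment of at least
~26.3 bits, which for leader-sized sequences corresponds to an E-value
near 1e-4.  A pair at exactly the cut height is merged.

Before alignment the distance step hard-masks homopolymer runs of 5 nt or
more (N scores 0 against N and as a mismatch against bases).  This is the
low-complexity filtering that BLAST applies by default, and it is
essential here: every leader ends in a poly-T tail, and without masking
those shared runs alone pull unrelated pairs to ~27 bits, below the cut.
The pure scoring function `local_alignment_score()` is unmasked.

Clusters are classified from the families of their downstream genes —
`a` (one family: orthologous regulation), `c` (at least two families each
appearing twice: a super-cluster/regulon), `b` (anything else) — and
flagged mobile when any downstream product matches an IS keyword
(transposase, insertion sequence, integrase, IS element, prophage).

## The synthetic cohort

`synthetic_spec()` defaults describe the reference validation cohort: 10
species × 300 genes on one linear replicon each, iid background at GC 0.5,
60 families assigned round-robin (≈5 paralogs per family per species),
intergenic gaps of 50–400 nt (gaps hosting planted elements are widened to
whatever their geometry requires), and:

* 200 planted 5' attenuators (stem 8 ± 1 bp at GC 0.8, loop 4, 12-T
  tail), all satisfying the candidate filters by construction, including
  8 in consecutive species for the designated enriched family;
* a 3' terminator (stem 9 ± 1 bp — one base pair longer on average, so
  the 5'-vs-3' stability contrast has a known sign) after every gene;
* 15 labeled filter violators — too far (d_down > 300), wrong ratio
  (planted closer to the upstream gene), or antisense to the downstream
  gene — which the screen must reject for exactly the labeled reason;
* 6 insertion-sequence cassettes: transposase genes sharing one conserved
  leader, giving a mobile-attenuator cluster of known membership.

Planted motifs carry a 5' "C" clamp that cannot pair with the tail, so
chance outward stem extension does not blur the planted coordinates
(inward extension is geometrically impossible at loop 4).  Truth matching
tolerates ±3 nt on the tail end because an alternative spacer choice can
shift a detection by up to two bases.

What the generator does *not* emulate: Markov background (the detector's
null behavior is exercised separately through dinucleotide shuffles of
these same sequences), codon structure, promoters, operon structure,
anti-terminator folds, or sequence divergence within families.  Passing
the planted-recovery tests therefore demonstrates correctness of the
machinery under the stated geometry, not detector performance on real
genomes — where terminator variability (bulged, GC-poor stems) and
Rho-dependent termination put a ceiling on recall that only the real
screen's published control numbers speak to.

Two subtleties of the evaluation are worth making explicit.  First,
precision is measured against *all* planted elements: in a short gap a
planted 3' terminator can sit closer to the downstream gene than to its
own (< 300 nt, co-oriented) and then satisfies every attenuator criterion
— by the method's own definition it is indistinguishable from an
attenuator, so it is not counted as a detector false positive.  Second,
divergently transcribed gene pairs share one gap, their leaders physically
overlap, and each contains the other's palindromic hairpin in reverse
complement; such pairs can legitimately co-cluster (the synthetic analog
of bidirectional terminator elements shared by divergent genes).

## Problem sizes and determinism

The validation suite runs the descriptor-vs-oracle comparison on 500
random 80-mers, the energy and alignment oracles on 100–200 random
instances, exhaustive Fisher enumeration for all margins up to 30, the
full reference cohort for recovery/precision, 20 reseeded 10 × 50-gene
cohorts for enrichment recovery, and 100 shuffles of 50 planted regions
for the false-positive control; together they complete in a few minutes
on one CPU.  Every stochastic step is seeded: cohorts are byte-for-byte
reproducible from `synthetic_spec(seed = )`, and `dinucleotide_shuffle`
takes an explicit seed without disturbing the caller's RNG stream.

## Known limitations

* The profile scorer is a position-specific log-odds model, not a full
  covariance model; it shares the descriptor's admissibility space and
  cannot detect terminators outside it (stems > 18 bp, loops > 10 nt,
  more than one bulge per arm).
* The hairpin energy omits loop-sequence bonuses, so absolute ΔG values
  are comparable within the package but not directly to full folding
  programs.
* Rho-dependent terminators and purely translational attenuators leave no
  intrinsic-terminator footprint and are invisible to this screen.
* The distance filters cannot distinguish an attenuator from the 3'
  terminator of an unannotated small-RNA gene in the leader; family-level
  recurrence (the enrichment score) is the screen's main defense.
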