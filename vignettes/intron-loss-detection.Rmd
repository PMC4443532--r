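---
title: "Detecting and classifying intron loss between orthologous genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying intron loss between orthologous genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronloss)
```

## The problem

Introns are removed from gene structures over evolutionary time, and five
distinct molecular routes can account for one "lost" intron when two
orthologous gene models are compared:

* **Precise intron loss (PIL)** — the intron is deleted exactly, leaving
  both flanking exons intact.
* **Imprecise intron loss (IIL)** — the deletion extends into one or both
  flanking exons (in the extreme, a whole adjacent exon is co-deleted),
  or nucleotides are inserted at the site.
* **De-intronization** — splice-signal mutations convert the intron into
  exonic sequence; nothing is deleted from the genome.
* **De-exonization** — splice-signal mutations convert an internal exon
  into intron interior, fusing it with both flanking introns; the exon
  sequence stays in the genome.
* **Exon deletion** — an internal exon is deleted from the genome and the
  two flanking introns fuse.

PIL leaves the protein untouched; the other four change the mRNA and are
therefore expected to be rarer and under stronger selection. But there is
also a *methodological* asymmetry: an imprecise loss damages the local
alignment around the site, and studies that filter poorly aligned regions
against a diverged reference genome preferentially discard exactly those
cases. `intronloss` implements both the classifier and the bias analysis
that quantifies this asymmetry.

## The pipeline

For each ortholog pair (donor candidate first — the intron-bearing
reference):

1. **Spliced comparison.** Both gene models are reduced to spliced
   sequences — the full transcript when both models have annotated UTRs
   (a loss can sit in a UTR intron), the CDS otherwise — and globally
   aligned with an affine-gap Needleman–Wunsch/Gotoh aligner
   (match +2, mismatch −3, gap open −10, gap extend −1; a run of length
   *L* costs `open + L·extend`). The paper-facing conventions are fixed:
   terminal gaps are scored, and traceback ties resolve
   diagonal > up > left, which makes every alignment reproducible.
2. **Projection and matching.** Each intron boundary is mapped to the
   alignment column reached after consuming its spliced offset in its own
   row (minimal column when gaps abut the site). Placements are matched
   greedily left-to-right within a tolerance `tol` (default 0 — positions
   are homologous only when identical). With `tol > 0` the match also
   requires equal phase for CDS introns; at `tol = 0` the exact column is
   the evidence, and phase is deliberately *not* gated because a
   frame-disrupting imprecise loss legitimately shifts every downstream
   phase.
3. **Classification.** Unmatched donor introns run through a decision
   tree: (i) intron sequence found (70% identity over 70% of its length,
   by local alignment) inside the recipient's spliced transcript near the
   projected site → de-intronization; (ii) found in the recipient genomic
   locus → flagged `UNCLASSIFIED_CONVERSION`; (iii) absent → PIL if no
   exonic gap run touches the site within `adjacency_window` (15 columns
   per side), else IIL with the gap columns split at the projected
   boundary into upstream/downstream indel bp. A missing internal donor
   exon (≥ 80% of its columns gapped) flanked by one matched and one
   unmatched intron is resolved by retention checks: exon retained →
   de-exonization; exon absent with both flanking introns retained →
   exon deletion; exon absent with one intron also absent → IIL with
   `whole_exon_lost_bp` set. Unmatched recipient introns become
   `CANDIDATE_GAIN` records and are not classified further.
4. **Evidence and populations.** Events are `supported` when their splice
   junction has **> 10** RNA-Seq reads *and* the variation site has
   ≥ 5 WGS reads (the strict RNA rule is the worked examples' evidence
   threshold; the WGS floor is our configurable convention — a site with
   nine WGS reads was acceptable evidence, no cutoff was stated).
   The fixation survey counts carriers among called lines; an event is
   `fixed` only when *every* called line (≥ 2) carries it, and missing
   lines never enter the denominator.
5. **Bias analysis.** Whole-gene identities (gap-excluded) against a
   diverged reference are thresholded at their first quartile (type-7
   linear interpolation — the convention is documented because the
   quartile of a genome-wide identity list cannot be re-derived without
   that list), and each event's 45-bp gap-excluded flank identity decides
   detectability. The resulting 2×2 table (PIL/IIL × detected/undetected)
   is tested three ways: Pearson χ², Yates-corrected χ², and a two-sided
   Fisher exact test computed by hypergeometric enumeration. All three
   are reported because "the χ² test" is ambiguous at these cell sizes:
   on the table `[[9,2],[1,5]]` the uncorrected χ² gives p ≈ 0.009 while
   Yates (≈ 0.036) and Fisher (≈ 0.035) agree with a printed p of about
   0.03; with expected counts below 5 the exact test is the one we
   recommend reading.

### Reporting conventions

* A fusion event (de-exonization, exon deletion) is reported under the
  ordinal of the donor intron *following* the exon, a fixed convention
  chosen because sequence divergence can make the matcher pair the fused
  recipient intron with either flank.
* In the whole-exon co-deletion pattern, the lost intron is identified by
  retention: the flanking intron whose sequence is absent from the
  recipient locus is the one that went with the exon.
* `lost_intron_length` and `whole_exon_lost_bp` are read from the donor
  annotation (exact); upstream/downstream indel bp are alignment-derived.
* Events with a CDS net indel ≢ 0 (mod 3) are annotated
  `frame_disrupting = TRUE` but never discarded.
* One transcript per gene is analyzed: the longest CDS, ties broken by
  lexicographic transcript id (a convention; multi-isoform handling is
  out of scope).
* Classification runs once per ortholog pair in the direction given by
  the ortholog table; without an outgroup a "loss" is directional only
  after `polarize()` confirms the intron in the outgroup at the
  homologous position.

## The synthetic-data generator

Real genome-scale inputs are deliberately out of scope, so the generator
builds the study conditions in miniature: one ancestral gene (5–8 exons
of 90–240 bp; GT..AG introns of 60–200 bp, long enough for retention
checks to have signal; GC 0.45; intact ATG..stop ORF), two descendants
produced by independent uniform substitution at `divergence/2` per
lineage (default total divergence 0.05 — comfortably "closely related",
under the 10% that makes whole-gene alignments reliable), and planted
events applied exactly to the recipient copy. Splice dinucleotides and
the start/stop codons are protected from substitution; with
`frame_preserving = TRUE`, planted CDS indels must be 0 mod 3 and any
stop codon created at a deletion junction (or by substitution) is
repaired.

**Identifiability guard.** A planted indel whose boundary bases repeat
(e.g. a deleted block ending in the same base that precedes it) can slide
in any optimal alignment, so the "true" upstream/downstream split would
be unrecoverable *in principle*. The generator therefore adjusts one
ancestral base at each block boundary (ORF-safely) so that no slide is
score-neutral. This is a property of fixture construction — making the
planted truth well-defined — not a tuning of the classifier.

What the generator does *not* emulate: transition/transversion bias, rate
heterogeneity, indel evolution outside the planted events, transposon
insertions, paralogy, and annotation error. Passing the recovery suite
therefore demonstrates that the classifier inverts the generative model
it was given — it bounds algorithmic errors, not the messiness of real
annotations.

With these conditions, planted-event recovery (type and all reported
sizes) is exact on 204 events at divergence 0 and ≥ 95% at divergence
0.05 (fixed seed); the residual losses are one-to-three-bp shifts of the
indel split when a boundary substitution makes a gap slide profitable,
plus occasional retention false calls — both inherent ambiguities of the
data, not implementation defects.

## Worked reconstructions

The two structural worked examples are reconstructed as fixtures: an
intron excised together with its entire 21-bp downstream exon while the
next intron stays intact (classified IIL with
`whole_exon_lost_bp = 21`), and a 204-bp intron excised with 22 bp of
the upstream and 9 bp of the downstream exon (IIL with sizes 204/22/9).
The population reconstruction builds 104 genotype tables over 180 lines
— 101 fully carried, three polymorphic at carrier fractions 97.7%
(172/176 called, four lines missing), 36.1% (65/180) and 97.2% (175/180)
— and recovers 101 fixed events. 97.7% and 97.2% are not multiples of
1/180, so the original denominators must have excluded some lines; the
172/176 and 175/180 reconstructions are our documented choice among the
fractions that round to the printed values.

```{r example}
cfg <- generator_config(
  seed = 2025, divergence = 0, n_exons = c(5L, 5L),
  intron_lengths = c(120L, 204L, 110L, 95L),
  planted = list(planted_event("IIL", intron_index = 2,
                               up_del_bp = 22, down_del_bp = 9)))
bundle <- generate_locus_pair(cfg)
detect_bundle(bundle)
```

## Numerical choices and degenerate inputs

* Minimum intron length 4 bp (shorter exon gaps are annotation errors:
  no room for both splice dinucleotides); retention calls need ≥ 10 bp
  of query and otherwise return `unknown`.
* `alignment_identity` and `flank_identity` both exclude gap columns
  from their denominators; an empty denominator yields 0 (overall) or
  `NA` (flank side with nothing to count).
* `N` bases never match.
* Empty sequences align to all-gap rows; a single-exon gene has an empty
  intron inventory; an event set with no rows summarizes to all-zero
  counts.
* The fixation survey calls a single-called-line event `polymorphic`
  rather than `fixed`: one line is not evidence of fixation.
* Problem sizes used by the test and acceptance suites — 204-event
  cohorts, 180-line surveys, exhaustive alignment-oracle pairs up to
  length 6 and Fisher tables up to N = 30 — were chosen as the smallest
  sizes at which every property is exercised meaningfully.

## Known limitations

* Intron "sliding" studies need `tol > 0`, where phase gating applies
  but frame-disrupting upstream events can then mask downstream matches.
* De-intronization is distinguished from alignment noise by a
  retained-near-site rule (local alignment of the intron against a
  window of the recipient transcript); the boundary between
  de-intronization and recipient-side "exonization" nomenclature is not
  resolved here — recipient-only introns stay `CANDIDATE_GAIN`.
* The bias analysis covers a single 2×2 test; no multiple-testing
  control is included, and reproducing real ortholog searches against a
  diverged genome is out of scope.
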