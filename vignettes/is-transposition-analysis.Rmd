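---
title: "Detecting and characterising IS transpositions into defense loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising IS transpositions into defense loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isbreach)
```

## The problem

Bacterial insertion sequences (ISs) are the smallest autonomous mobile
elements: a transposase gene between short inverted terminal repeats.
When an IS transposes into a new site, most families duplicate a short
stretch of target DNA, leaving identical copies — the target-site
duplication (TSD) — directly flanking the inserted element. The TSD is
the forensic signature of a transposition event: its presence
distinguishes a genuine insertion from an assembly artifact or ancestral
copy, and its length and base composition are family-characteristic
(8–9 bp for IS1, 9 bp for IS10, with rarer aberrant lengths such as 7,
11 or 23 bp).

ISs matter for genome defense because cas genes and other defense
operons are preferred landing sites under selection: a cell whose
CRISPR-Cas machinery is cleaving its own chromosome (or an addicted
plasmid) can survive by letting an IS knock out a *cas* gene. Scanning
replicons for IS copies, verifying them by their TSDs, and mapping them
onto defense annotations is therefore a recurring analysis. `isbreach`
packages that analysis, together with the inverse engineering problem:
recoding a *cas* coding sequence so that it no longer contains the
sequence motifs the dominant IS families prefer to target.

## The detection model

Detection is exact by design. An IS copy is reported only when the
element sequence occurs in the target at 100% identity and 100%
coverage, on either strand (`find_exact_copies()`). This is the
retention rule used for natural-genome scans of recently mobile
elements; it makes the result set fully testable — the contract is the
brute-force all-offsets comparison, and the test suite enforces that
equivalence on randomized instances. There is no alignment heuristic to
tune, and an `N` in a target can never support a hit.

TSD calling (`call_tsd()`) generalises fixed-length direct-repeat
pattern searches (a k-mer, a fixed-length gap the size of the element,
the same k-mer) to a longest-k rule: the caller reports the largest
`k` in `[k_min, k_max]` (defaults 4–25) for which the `k` bases
immediately 5′ of the element equal the `k` bases immediately 3′ of it,
compared exactly on the + strand. Longest-k discovers aberrant
duplication lengths that a fixed-length scan would miss, at a price
made explicit rather than hidden: a random k-mer duplication arises by
chance with probability 4^−k per boundary, so 4 bp calls are
individually unreliable (P ≈ 1/256) while 8–9 bp calls are essentially
certain. Every call carries this `p_random` alongside its
canonical/aberrant status, and a `canonical_only` mode restricts the
search to the element family's characteristic lengths, reproducing a
fixed-length pattern scan exactly.

Two consequences of longest-k are worth knowing. First, it can only
extend an implanted duplication, never shorten it: extension by one
base requires the flanking k-mer to be period-1 repetitive at its ends,
so for k\* ≥ 7 the implanted length is recovered in ≥ 99% of cases (a
property the tests measure over 1,000 seeded trials). Second, when an
8-mer and its 9-mer extension are both duplicated, 9 wins — ties of
this kind are resolved toward the longer, rarer event.

## Annotation and the insertion spectrum

The "insertion point" is defined as the + strand boundary between the
upstream TSD copy and the element start. That single anchor drives all
downstream bookkeeping: the disrupted gene is the annotated feature
with maximal overlap with the element interval (leftmost start on
ties), the position of the insertion within the gene is measured on the
gene's own strand, and the ±10 kb context window (`scan_context()`)
collects the neighborhood's features with whatever defense-system
labels the annotation carries (`system=` attributes in GFF3 — labels
are consumed, never computed; running defense-system HMMs is out of
scope). The insertion-spectrum matrix (`build_spectrum()`) collapses
repeated events at the same (gene, position, duplication length) site
into one column listing the inserting families; a TSD sequence observed
at more than one distinct site is flagged as potentially off-target
rather than silently kept or dropped, a scripted stand-in for what is
usually a manual curation step.

Amplicon prediction (`predict_amplicons()`) encodes the colony-PCR
diagnostic: the base product is the inclusive span between the two
primer 5′ ends, and every insertion inside the span adds
`element_length + k` — the element plus the one extra repeat copy that
transposition creates (e.g. a 4,443 bp cassette grows to 5,220 bp with
a 768 bp element and a 9 bp duplication).

## Motif statistics

TSD sets are summarised per element family and length class: mixing
lengths in one matrix is an error by contract, because motifs are only
comparable within a length class. The position frequency matrix uses
plain frequencies with no pseudocounts — pseudocounts would silently
change correlations between motifs. Pearson comparison flattens the two
4×k matrices to 4k-vectors; this is the simplest reproducible reading
of "PFMs were correlated", it is symmetric, exactly 1 on identical
input, and undefined (an error, not an NA) for a uniform matrix. The
IUPAC consensus reduction uses two thresholds: a single base is written
when its frequency reaches `major` (default 0.75), a two-base code
(R/Y/S/W/K/M) when the top two bases jointly reach `pair` (default
0.9), else N. The thresholds are configuration, not biology: sequence
logos are usually reduced to strings by eye, and these defaults
reproduce the conventional readings of the IS1/IS5/IS10 motif strings
(NRAWWWWN, YTAR, NRCWNWRYN) on data sampled from them. GC comparisons
between TSD groups use the two-sided two-sample t test, Welch form by
default ("unpaired t test" is ambiguous; unequal variances is the safer
reading, and the pooled form is a flag away).

## Recoding coding sequences against IS target sites

`recode_cds()` removes every match to a set of IUPAC target-site motifs
and every exact internal repeat ≥ `min_repeat` (default 10 bp, the
threshold at which homologous recombination between internal
duplications becomes a practical concern), under the constraint that
the encoded protein is unchanged and the start and stop codons are
never touched. Repeat elimination reduces to k-mer bookkeeping: any
repeat of length ≥ m contains a duplicated m-mer, so a sequence with no
duplicated `min_repeat`-window has no offending repeat at all.

The elimination strategy is greedy and deterministic given its seed:
passes run until fixpoint, each pass walking offenses left to right and
trying synonymous substitutions at the overlapping codons — single
codons first, preferring the fewest base changes, then a bounded
exhaustive search over all synonymous combinations at the site's codons
(a site spans at most 4 codons, so at most a few thousand candidates).
A substitution is accepted only when it strictly reduces the global
offense count, which prevents whack-a-mole cycles where destroying one
site creates another. When no combination helps — e.g. a motif pinned
by Met/Trp codons — the site is reported as a residual instead of being
silently retained, and the test suite independently re-verifies such
residuals by exhaustive enumeration. Motif scanning is forward-strand
by default with a both-strands flag (YTAR is its own reverse complement
anyway; NRAWWWWN is not), and reverse-complement repeat copies are
likewise flag-controlled, since the orientation conventions of the
original designs are not documented.

## Spacer–protospacer matching

`match_spacers()` applies the same 100%/100% exactness rule to CRISPR
spacers against candidate replicons, with the PAM expressed in
protospacer-local orientation (IUPAC motif + side), so the type I-E
5′ AAG and a Cas9-style 3′ NGG are both one configuration line. PAM
status is reported alongside each match, never used as a filter —
whether a natural spacer-search pipeline enforced PAM presence is
generally unknowable after the fact, so the two judgments are kept
separate. A PAM window truncated by a sequence end is reported as
failing with an explicit "truncated" note.

## What the synthetic generator emulates — and what it does not

`generate_locus()` builds a random replicon at a stated GC content
carrying non-overlapping CDS-like features (an 8-gene locus with
300–3,000 bp genes mimics a type I-E *cas* operon).
`implant_elements()` then performs textbook transpositions: draw a
duplication length from a stated mixture (the IS1 default world is
P(9 bp) = 0.78, P(8 bp) = 0.22, the proportions observed across
thousands of natural and trapped IS1 events), pick an insertion point
uniformly or by rejection sampling against a site motif, insert the
element (either orientation) and duplicate the target k-mer on both
sides. Truth records are emitted in final coordinates, gene intervals
are stretched through insertions, and the sequence grows by exactly
`element_length + k` per event — a conservation law asserted
throughout the tests.

The generator emulates the statistical structure the analysis relies
on: exact element copies, exact flanking duplications, length mixtures,
motif-biased site choice, both strands. It deliberately does not
emulate sequencing error, partial or nested IS copies, ancestral copies
without TSDs, rearrangements after insertion, or transposition
kinetics. A green implant-and-recover test therefore establishes that
the scanner and caller are correct for clean transposition signatures;
it says nothing about robustness to degraded elements, which the
exactness contract excludes by construction.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; files (GFF3,
  TSV reports) are 1-based inclusive, and every emitted table says so
  in a header comment. BED output is 0-based half-open as BED requires.
* `N` never matches: not in element hits, not in TSD windows, not in
  IUPAC motif subjects. Catalogs reject non-ACGT outright (probes must
  be exact); targets tolerate them as never-matching.
* TSD windows that would run past a sequence end are skipped, not
  errors; flank extraction clips and sets a `truncated` flag.
* PFM column sums are exact to 1e−12 by construction (counts divided
  by n); self-correlation returns exactly 1.
* Circular replicons are off by default; `circular = TRUE` virtually
  extends the target by the longest element length minus one, and
  wrapped duplicate hits are de-duplicated back into `[0, L)`.
* All stochastic components (locus generation, implant draws, recoder
  tie-breaks) consume a single integer seed and are byte-reproducible.

## Known limitations

Approximate matching (degenerate IS copies, mismatched TSDs) is out of
scope by contract. The spectrum's multi-mapping flag marks suspicious
sites but does not adjudicate them. The recoder optimises nothing
beyond offense removal — codon usage, GC windows and RNA structure are
the user's problem. The pipeline consumes defense-system labels; it
does not compute them.
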