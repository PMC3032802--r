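---
title: "Methods: PWM-20 scanning, repeat mapping and chromatin context of p53 sites in Alu repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PWM-20 scanning, repeat mapping and chromatin context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alup53)
```

# The binding-site model

A p53 site is two `RRRCWWGYYY` decamers separated by a spacer of S bp that
the protein loops over; the spacer contributes nothing to recognition and
is excluded from scoring. `p53_pwm()` therefore always models a 20-mer.
Sixteen positions are scored as mononucleotides; positions 5–6 and 15–16 —
the central WW of each `CWWG` core, where dinucleotide identity (AT and
AA:TT favoured, TA/SW/WS depleted) matters beyond single-base composition —
are scored as dinucleotides over the 16 possible dimers.

Two constructive choices define the estimator:

* **Symmetrization.** Every training 20-mer is counted together with its
  reverse complement. Because the DNA-bound p53 tetramer is 2-fold
  symmetric, a site and its reverse complement are the same physical
  object; counting both makes the matrix exactly symmetric, so only one
  strand ever needs to be scanned. `raw_score()` additionally accumulates
  its sum in symmetric column pairs (p, 21−p), which makes the score of a
  sequence and its reverse complement *bit-identical*, not merely equal to
  rounding error.
* **Weight form.** Weights are log2 odds of pseudocounted frequencies
  against a uniform background (1/4 per base, 1/16 per dimer). The percent
  score is an affine rescaling of the raw score between the column-wise
  worst (0) and best (100) sequences, so any monotone weight transform
  yields the same percent scale; log-odds is used as the field's default.
  The pseudocount (default 0.5) is a *background admixture per accumulated
  sequence*: with n accumulated 20-mers, a cell's frequency is
  (count + pc·n/4) / (n·(1 + pc)). This formulation was chosen over an
  absolute additive pseudocount because it makes the matrix invariant under
  duplication of the training multiset — rebuilding from the sites plus
  their reverse complements reproduces the identical matrix — while
  retaining the usual behaviour that a growing pseudocount shrinks all
  weights monotonically toward zero.

Ambiguous bases make a window *unscorable* (`NA`), deliberately distinct
from a bad score: a masked window carries no evidence either way.

The percent cutoff default is 70, the "natural" operating point for
functional response elements on this model family; it is stored in the
fitted object and can be overridden per scan.

# Scanning

`scan_p53()` enumerates every (start, S) pair for S = 0..`s_max` and scores
the concatenated half-sites. Defaults: `s_max = 14` (the range tabulated
per subfamily; up to 20 is supported, matching the widest spacer range used
for spacer-distribution work), cutoff 70. All overlapping hits and all
spacers at the same start are reported — the analysis counts motifs, not
merged loci; whether overlapping predictions should be merged is a
downstream choice the package does not impose. Coordinates are 0-based
half-open internally and in BED output; textual reports are 1-based.

Masking: hard-masked bases (`N`) always kill the windows containing them;
lower-case (soft-masked) bases do so only behind `soft_mask = TRUE`,
because RepeatMasker products differ in which convention they ship.

`peak_z()` quantifies the excess of the prevalent spacers (S = 0, 3, 8, 14)
over the remaining spacer lengths in units of the background's *population*
standard deviation (divide by n, not n−1) — the convention that reproduces
the published worked values (6.22 and 14.58) from their printed means and
RMSDs. The statistic is invariant under shifting all counts by a constant
and scaling by any positive factor.

# Repeat mapping

`parse_repeatmasker_out()` reads the standard `.out` dialect, including the
'C' (minus-strand) rows whose repeat-coordinate triple appears as
`(left) end begin`. Query coordinates are converted to 0-based half-open;
consensus begin/end are normalized so begin ≤ end on both strands.

`assign_sites()` assigns each site to the annotation of maximal genomic
overlap, requiring at least 5 bp (the same threshold used to call a
response element "repeat-associated"); ties go to the left-most annotation.
The site's *midpoint* is projected into consensus coordinates by linear
interpolation between consensus begin and end across the annotated block
(mirrored for minus-strand annotations). RepeatMasker emits no per-base
alignment, so this gapless proportional mapping is approximate — for a
full-length, indel-free annotation it is exact, and for typical Alu
annotations the error is a few bases, small against hotspot windows tens
of bases wide. A start-based position convention was considered and
rejected: the downstream chromatin model phrases accessibility in terms of
the *center* of the site.

Hotspot windows default to A = [1, 45], B = [60, 115], A′ = [125, 175],
centered on the canonical cluster positions 10, 85 and 150. No published
window bounds exist, so the windows are configurable; the defaults are
disjoint, cover each cluster with generous margins, and leave gaps between
boxes unclassified rather than force every position into a box. Groups for
the evolutionary analysis collapse A and A′ into group A (CpG-deamination
born) and keep B as group B (ancestral).

`build_spacer_table()` produces per-subfamily rows with one column per
spacer 0..`s_max` plus a Total row; row motif totals equal row sums by
construction. Note that the packaged published count table carries only
the four prevalent spacer columns (S = 0, 3, 8, 14) of the original, so on
that fixture only column sums — 393,947 motifs, 99,521 at S = 0 — are
checkable, not row-wise completeness. `content_ratio()` reports
100 · (sites with S in a chosen set) / (elements in the subfamily), both
at full precision and rounded to the nearest percent.

# Consensus evolution

`global_align()` is a Gotoh affine-gap global aligner with defaults
match +1, mismatch −1, gap open 5, gap extend 1 (a gap of length k costs
5 + k). The implementation is intentionally in-package rather than
delegated: the analysis needs a *deterministic* traceback (ties resolved
diagonal first, then gap-in-first-sequence, then gap-in-second) so that
substitution and CpG statistics are reproducible to the base; the
test-suite cross-checks its scores against both an exhaustive enumeration
oracle and an independent alignment library. Pre-computed alignments can
be supplied instead by constructing the alignment object directly from
aligned strings.

`divergence_percent()` counts mismatched columns over ungapped columns
only, reporting gap events separately — divergence figures from alignment
tools conflate gaps in tool-specific ways, so the package fixes one
documented convention and treats agreement with tool-reported divergences
as approximate.

`count_cg_to_tg()` counts consensus CG dinucleotides whose aligned RE
dinucleotide is TG (deamination of the methylated C on the given strand)
or CA (the same event on the complementary strand). `scope = "core"`
restricts to the CNNG core columns, located from the RE's own half-site
registration (site positions 4–7 and 14+S..17+S) rather than from the
consensus, because the registration of the functional site is what defines
where the cores sit. Core counts can never exceed full-site counts.

The published group-level values (divergence ≈ 10.5 % for the exemplar
RE-plus-flanks, substitution rates 0.23 vs 0.14 per bp, 16 vs 1 core
CG → TG transitions for groups A and B) require the Repbase Alu subfamily
consensi and the original supplementary alignments, which are user-supplied
inputs; the package computes all of these statistics for any supplied
RE/consensus pair (`re_consensus_report()`), and its tests exercise them on
synthetic alignments with known truth instead.

# Chromatin context

The "right" Alu nucleosome is constrained between two long A-tracts; on
the packaged synthetic consensus these delimit exactly the canonical
147-bp window 134–280, whose center — dyad 207 — is returned directly for
an exact-fit window. For longer windows, `place_nucleosome()` scores every
admissible dyad and returns the argmax (smallest dyad on ties).

`rotational_score()` uses the canonical nucleosomal sequence pattern:
AT-rich dinucleotides (AA, TT, AT, TA; weight +1) favour minor-groove-in
bending, GC-rich ones (GG, CC, GC, CG; weight −1) major-groove-in, all
others 0. Each dinucleotide's weight is multiplied by
−cos(2π·(i + ½ − dyad)/P) and summed over the footprint; with period
P = 10.36 bp/turn an AT dimer centered (n + ½) turns from the dyad
contributes +1. The phase is evaluated at the dinucleotide *midpoint*
(i + ½): with a start-indexed phase the score would change under reverse
complementation of the footprint about the dyad (a dimer starting at
offset d maps to one starting at −d−1), whereas the midpoint convention
makes the score exactly strand-symmetric, as a physically meaningful
score must be. The original numeric weight set behind this approach is
not reproduced here; the ±1 weighting with a cosine kernel is a documented
stand-in whose three constants (period, weights, tolerance) are all
configurable.

`classify_exposure()` labels a site center outside all footprints as
*linker*; inside a footprint, the fractional-turn offset
f = ((center − dyad)/P) mod 1 makes the site *exposed* (minor-groove-in,
accessible to p53) when |f − 0.5| ≤ 0.15 turns, else *occluded*. The
0.15-turn tolerance (≈ ±54° of helical phase) is half the distance to the
fully occluded phase, a neutral split; position 150 against dyad 207 sits
at 57/10.36 = 5.502 turns, i.e. f ≈ 0.498, comfortably exposed, and stays
exposed for any period in [10.2, 10.5] (the deviation of f from 0.5 grows
to ≈ 0.09 turns at the interval edges, still well inside the tolerance).
The convention forces f = 0 (the dyad itself) to be occluded.

The default left nucleosome (footprint −72..74, dyad 1) encodes the
observation that its center lies near the element's 5′ end; it mainly
serves to keep Box A centers out of the linker class.

# The synthetic generator

`build_synthetic_genome()` emulates exactly the statistical structure the
analysis assumes, no more:

* a 290-bp synthetic Alu-like consensus (explicitly *not* a Repbase
  sequence) with CG-rich CNNG arrangements at Box-A/A′-like positions, a
  CG-poor site at a Box-B-like position, an A-tract at 121–133 and a
  3′ A-tail from 281 — so hotspot mapping, CpG statistics and nucleosome
  placement all have designed ground truth;
* per-element independent decay: every base substitutes with probability r
  (default 0.10/bp, a typical Alu-to-consensus divergence), and the C and G
  of each consensus CpG undergo their deamination transition with total
  probability m·r (default m = 8, putting CpG transitions roughly an order
  of magnitude above background). "Total" means the C→T probability at a
  CpG *is* m·r, with the two transversions keeping their background r/3
  each; consequently `estimate_cpg_multiplier()` recovers m as the ratio of
  the CpG transition fraction to the overall non-CpG substitution fraction.
  The model requires m·r + 2r/3 ≤ 1, so high decay rates need m scaled
  down toward 1. Both strands are treated symmetrically, producing the
  CA:TG dimer pattern on the element;
* uniform random background of GC fraction 0.41 (human-genome-like),
  non-overlapping element placement, random strands, RepeatMasker-style
  annotations covering the full element, and a truth table of implanted
  sites. Implants are written into the consensus *before* decay, so
  recovery degrades with r, as it should.

Indels are off (and unimplemented): the site-level analysis is
substitution-centric, and indel-free elements keep the gapless consensus
projection exact, which is what makes end-to-end truth recovery a sharp
test. What the generator does *not* emulate — subfamily phylogeny,
insertion-age structure, regional mutation-rate variation, real Alu
sequence — bounds what the tests show: they validate the machinery
(scoring, enumeration, projection, counting, phase arithmetic), not the
biological claims about real genomes.

# Problem sizes and determinism

The shipped tests and the acceptance script run on deliberately small
instances: 40–60 kb synthetic genomes with 15–50 elements, 200–500 decay
replicates of the 290-bp consensus, 300-bp oracle-equivalence scans.
These sizes give exact combinatorial checks and binomial intervals tight
enough to pin the CpG multiplier, while keeping any single check under a
minute. Every stochastic step is seed-pinned; `build_synthetic_genome()`
is byte-identical for a fixed configuration, and the pipeline summary is
reproducible run to run.

# Known limitations

* The consensus-coordinate projection is proportional, not alignment-based;
  with real (indel-containing) RepeatMasker annotations centers can drift
  by a few bases.
* The original training matrix of the PWM-20 approach is not reproduced
  (its numeric table was never published); the package rebuilds the
  estimator from any supplied training set and fixes only the percent-scale
  behaviour.
* The rotational-positioning weights are a two-class stand-in for the
  original calibrated dinucleotide set; relative scores across distant
  sequences should be interpreted qualitatively.
* Genome-scale absolute counts (millions of sites, per-subfamily census
  numbers) are out of desk-scale reach by design; the packaged published
  count table serves as the fixture for all ratio and conservation
  checks.
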