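---
title: "Methods: MULE discovery, structural annotation, and transposition-assay analytics"
author: "mulescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MULE discovery, structural annotation, and transposition-assay analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`mulescan` re-implements, as a tested pipeline, two connected analyses around
*Mutator*-like transposable elements (MULEs): (i) discovery and structural
characterization of MULE families in a genome assembly, and (ii) the
quantitative readouts of a yeast transposition assay (excision frequencies,
reintegration ratios, excision footprints, reinsertion-site TSD censuses).

The structural model of an autonomous MULE used throughout is:

* long terminal inverted repeats (TIRs, typically > 100 bp) whose outermost
  10 bp form an imperfect palindrome (in the reference family, positions 5
  and 6 unpaired), and which carry an array of subterminal tandem repeats
  (9–15 bp units, short spacers);
* an 8–10 bp target-site duplication (TSD) created at insertion;
* a transposase ORF whose catalytic core is the acidic D..D..E triad.

Nonautonomous derivatives share the termini but have truncated TIRs and
heterogeneous internal sequence, sometimes carrying captured host-gene
fragments (Pack-MULE content).

# Discovery stage

## Translated homology search

`search_dde()` emulates a TBLASTN stage: each scaffold is translated in six
frames and scanned with a full Smith–Waterman local aligner (Gotoh affine
gaps, BLOSUM62; a gap of length $k$ costs $o + k e$ with defaults $o = 10$,
$e = 1$, so a length-1 gap costs 11, matching the common 11/1 calibration).
Each accepted hit is masked and its frame re-scanned, so multiple copies per
frame are recovered. Significance uses the Karlin–Altschul surrogate

$$E = K \, m \, n \, e^{-\lambda S}$$

with fixed gapped-BLOSUM62 constants $\lambda = 0.267$, $K = 0.041$, query
length $m$ and total translated search space $n$. The surrogate is monotone
in the alignment score, which is all the published cutoffs require: the
search stage uses a permissive $10^{-3}$ cutoff and the significance filter
$10^{-15}$. Because the two cutoffs are applied at different stages in the
source analyses without an explicit mapping, both are exposed
(`search_evalue`, `filter_evalue` in `default_config()`); the pipeline
searches permissively and filters strictly.

Unknown residues (`X`, `*`) score $-4$ against everything; `N` bases never
match in any nucleotide alignment. Ties in the traceback are broken
deterministically (diagonal, then up, then left), and the local maximum cell
is the first one in row-major order, so results are bit-reproducible.

## Boundary detection and span refinement

Element ends are found by comparing two family copies with their flanking
DNA (`detect_boundaries()`): the copies share the element but not the
flanks. The windowed-identity profile (20 bp windows at ≥ 80% identity,
both exposed in the call) detects where similarity collapses on each side;
the boundary is then refined with an X-drop walk (+1 match, −3 mismatch,
drop 9) from a known-good interior position, which tolerates the occasional
substitution between close copies while stopping crisply at random flanks.
Ungapped anchored extension is assumed between copies — appropriate for the
nearly identical copies used for boundary calls; indel-diverged copies are
out of scope for this operation.

Because one or two flanking bases can match by chance, similarity-based
boundaries can be off by a base or two. `refine_element_span()` therefore
enumerates small shifts (± 12 bp) of both boundaries and selects the span
whose flanks carry a perfect TSD, preferring longer duplications and then
terminal inverted-repeat agreement. On TSD-bearing elements this pins the
span exactly; elements without a perfect TSD keep the similarity-based span.

## Structural annotation

* **TIR** (`find_tir()`): local alignment of the 5′ prefix against the
  reverse complement of the 3′ suffix (window `min(len/2, 1000)` bp),
  anchored within 5 bp of both termini, reported when ≥ 50 bp at ≥ 80%
  identity (defaults exposed).
* **TSD** (`call_tsd()`): the longest exact duplication with length in
  8–10 bp wins; when both an 8- and a 9-bp duplication exist the longer is
  reported (a 9-bp duplication containing an 8-bp one is a single 9-bp TSD)
  with an ambiguity flag. Imperfect (single-mismatch) candidates are
  reported flagged and are never counted by any census — the analysis
  semantics of "perfect TSD" depend on this.
* **Subterminal repeats** (`find_subterminal_repeats()`): scans unit
  lengths 9–15 bp and all phases, greedily chaining occurrences with 0–6 bp
  spacers and ≤ 1 mismatch per copy. Chains are scored
  `copies × unit_len − 2 × mismatches`; the mismatch penalty is required
  because a unit of length $u{+}1$ that absorbs one spacer base per copy
  would otherwise always outscore the true $u$-periodicity.
* **Terminal palindrome** (`score_terminal_palindrome()`): position $i$
  pairs with $11-i$ iff Watson–Crick complementary; both members of broken
  pairs are reported, `N` counts as unpaired.
* **Coding** (`locate_orf_dde()`): best translated alignment of the DDE
  query over six frames localizes the domain; the longest stop-free stretch
  overlapping it is reported as a single-ORF approximation (multi-exon
  structure is deliberately not inferred), with an `interrupted` flag when a
  stop falls inside the aligned domain.

## Families and phylogeny

Family clustering is single linkage at > 95% global-alignment identity:
connected components of the "shares > 95% identity" graph, matching the
transitive reading of family membership. Whether the 95% applies to
nucleotide elements or translated domains is not fixed by the sources;
both are supported (`type` argument) and nucleotide is the default.

`neighbor_joining()` is a from-scratch Saitou–Nei implementation with a
deterministic tie-break (smallest $(i,j)$ index pair on equal $Q$) and
negative branch lengths clamped to zero; `ape::nj` serves as an independent
oracle in the test suite, never as the implementation. Bootstrap supports
resample alignment columns with replacement and count, per internal
bipartition of the full-data tree, the percentage of replicate trees
containing it. Multiple alignment is center-star progressive (the
highest-sum-of-scores sequence is the center; pairwise alignments are merged
under once-a-gap-always-a-gap): adequate for the closely related domain
sequences whose downstream use is distances and topologies, not
column-level inference.

## Derivatives

`terminal_seed_search()` finds all placements of the 50-bp element terminus
with ≤ 5 mismatches on either strand (exact 12-mer seed dictionary, full
50-mer verification). `pair_ends()` matches 3′-end hits to the most recent
open 5′-end hit within 100 bp – 20 kb, parenthesis-style, which reduces to
nearest pairing for flat arrangements and recovers nested elements (both
emitted, flagged). `verify_and_annotate()` retrieves 100 bp of flanking DNA
and partitions candidates into perfect-TSD-verified and unverified;
Pack-MULE content is called by local nucleotide alignment of the internal
region against host coding sequences at ≥ 70% identity over ≥ 100 bp
(defaults chosen to admit the canonical quantified example — a 276-bp
fragment at 97.5% identity — with wide margin; both exposed).

# Insertion-site statistics

`classify_proximity()` buckets a site as `gene_body`, `within_window`
(distance to the nearest gene edge ≤ window, inclusive, strand-ignored), or
`distal`; windows are 5 kb for genome-scale analyses and 1 kb for the yeast
reinsertion analysis. The randomized null draws sites uniformly over total
genome length (scaffolds weighted by length — the sources say only
"randomly generated", and the uniform choice keeps the analytic expectation
closed-form), classifies each of 1,000 replicates, and reports per-category
means and SDs; `enrichment()` converts observed counts to z-scores. No
multiple-testing correction is applied: a single contrast is performed.
Position-frequency matrices use information content
$IC_j = 2 + \sum_b f_{bj}\log_2 f_{bj}$ against a uniform background.

# Assay analytics

Viable-cell estimates average `colonies × dilution / volume-fraction` over
the plated dilutions; excision frequency is revertants per viable cell, and
the reintegration ratio is the rounded percentage of the two frequencies.

`classify_footprint()` compares a revertant junction with the reconstructed
empty donor site (flank + one TSD copy + flank when the donor carried a
TSD; plain flank + flank otherwise — "precise" without a donor TSD means
exact restoration, since there is no duplication to retain). The
discrepancy is decomposed by longest common prefix/suffix: pure deletions
become `flank_deletion` with per-side accounting across the junction; pure
insertions are tested against all slide-equivalent placements and become
`tir_remnant` when any candidate equals a terminal segment of the element
(≤ 13 bp — longer terminal leftovers are classed `complex`, mirroring the
observed ceiling), otherwise `insertion`; mixtures are `complex`. A
revertant still containing both element termini is an error ("element not
excised"), not a footprint.

Reinsertion analysis trims the element terminus from each transposon-display
read, exact-maps the remaining ≥ 20 bp flank on both strands
(unique/ambiguous/unmapped), resolves the junction pair to a locus, and
calls the TSD with the same longest-match rule; a call longer than the
geometric duplication (a coincidental flanking match) carries an ambiguity
flag, and flanks that disagree with the genome are flagged and excluded
from censuses.

# The synthetic-data module

`generate_genome()` emulates exactly the structure the analysis assumes:
uniform-ACGT background (the sources are silent on composition; uniformity
keeps the nulls analytic); planted full-length copies built from an
`element_template()` whose defaults mirror the reference family (3198 bp,
145-bp TIRs, 9-bp TSD, 10-bp terminal palindrome with positions 5/6
unpaired, nine 12-bp subterminal repeats with 3–4 bp spacers, a 2-exon
transposase); derivatives with per-side TIR truncation drawn uniformly from
50–100% (the sources show "often truncated" without a distribution) and
internal lengths from a configurable range (200–1500 bp by default — the
real internal-length distribution is unpublished, so it is a parameter, not
a guess). Insertions duplicate the 8/9 bp at the insertion point; a
configurable fraction of derivative TSDs is made imperfect by mutating one
base of the right-hand copy. A fraction `genic_insert_frac` (default 0.643)
of planted sites falls inside gene bodies, the rest farther than the window
from any gene — placements whose distances could be altered by later
insertions are avoided by construction, since splicing extra sequence can
only increase distances.

Two fixture-validity constraints matter for closed-loop testing. First,
insertion sites are rejected when a shifted span within ± 12 bp would carry
an equal-or-longer perfect duplication, i.e. when the (flank, TSD, element)
decomposition would be genuinely ambiguous — no annotator could recover
such a span "exactly". Second, reinsertion fixtures resample positions
whose neighborhoods would extend the longest-match TSD call past the
planted length (in uniform sequence this requires a homopolymer run and is
rare). Both are properties of the planted truth, not of the methods under
test. The assay-fixture generator analogously rejects inserted bases that
are literally indistinguishable from a TIR remnant.

The transposase planted in full copies is a fixed synthetic sequence
shipped as a plain-text fixture (`inst/extdata/synthetic_transposase.faa`),
not any natural gene: the discovery stage only requires an ORF whose
conceptual translation carries D..D..E at known offsets. One global integer
seed drives everything; submodules derive their streams by fixed offsets,
so identical seeds give byte-identical output.

What the generator does **not** emulate: realistic base composition or
repeat landscapes, sequencing error, assembly gaps, or genuinely
multi-exon derivative structure. Passing closed-loop tests therefore
demonstrates correctness of the operations under the stated structural
model, not performance on real mosquito assemblies.

# Problem sizes and numerical choices

The test and acceptance workloads use 3–4 scaffolds of 50–60 kb with 4–8
full copies and 10–20 derivatives, 1,000 null replicates, 50 random 8-leaf
trees for the NJ oracle, and brute-force alignment enumeration up to
12-mers — sizes chosen so the full closed loop (simulate → discover →
annotate → verify) exercises every operation at comfortably interactive
cost. Determinism is absolute: all randomness flows through seeds, ties
break by fixed rules, and no floating-point comparison in the pipeline
depends on platform-specific ordering.

Known limitations: boundary detection assumes indel-free alignment between
the two compared copies; the single-ORF approximation under-reports coding
structure for multi-exon transposases (the 2-exon planted gene is located
via its contiguous DDE domain); the E-value surrogate is calibrated for
filtering semantics, not for reproducing BLAST bit-scores; and center-star
alignment is not a general-purpose MSA.
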