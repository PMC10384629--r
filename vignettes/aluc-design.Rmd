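---
title: "Designing artificial luciferase variants from single-sequence alignment"
author: "aluckit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing artificial luciferase variants from single-sequence alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluckit)
```

## The idea

Copepod luciferases are small secreted enzymes built from a flexible
N-terminal region followed by two tandem, highly conserved catalytic
domains. Because all three stretches descend from the same ancestral
repeat, a *single* protein can be split into its three regions and the
regions aligned against each other — a single-sequence alignment (SSA).
Stacked this way, the N-region typically shows a *vacant* span: a run of
alignment columns where both catalytic domains carry residues but the
N-region has none. Filling that vacancy with a peptide block copied from
one of the homologous rows raises the per-column consensus of the
stacked alignment, and nested truncations of the donor block generate an
ordered family of sibling variants whose only difference is how much of
the missing block was restored. `aluckit` implements that design loop —
partition, stack, detect, compensate — together with the downstream
bookkeeping a wet-lab campaign needs: cDNA construct assembly, a
phylogeny of the designed family, emission-spectrum summaries, sequence
properties, and a loop-proximity metric for structural models.

## The alignment core

Pairwise alignment is global Needleman–Wunsch/Gotoh with affine gaps,
implemented in C++ for speed. The conventions are explicit because
scores must be reproducible bit-for-bit:

* substitution matrix BLOSUM62 (any symmetric matrix may be supplied);
* a gap run of length $L$ costs $g_{open} + L\,g_{ext}$ with defaults
  $g_{open} = 10$, $g_{ext} = 0.5$;
* end gaps are penalized (true global alignment);
* traceback ties resolve diagonal > up > left, so the alignment string,
  not just the score, is deterministic.

`partitionRepeats()` chooses the two split positions $(b_1, b_2)$ that
maximize the domain1–domain2 alignment score, constraining the N-region
to 20 residues–45% of the protein and the two domains to within 15% of
each other in length. The score surface is scanned on a step-5 grid and
the eight best cells are refined at step 1. Refining several cells
rather than one matters: when the N-region itself resembles the domains,
the surface has shifted-phase local optima whose basins can trap a
single-point refinement. Explicit boundaries bypass the search entirely.

`stackRegions()` is progressive: the two domains (the highest-homology
pair) are aligned first, the N-region is then aligned against the
column-majority consensus of that pair, and columns where the N-region
carries extra residues become all-gap columns in the domain rows. A
majority profile (not a profile HMM) is enough for three rows and keeps
the construction transparent. `detectVacantRegions()` reports maximal
all-gap runs of a minimum column length (default 5) in one row, with the
anchor residue (last target-row residue before the run) and the donor
strings from the other rows. `consensusScore()` counts the fraction of
columns where the target row matches the column majority, with gaps
excluded from the majority and ties counting as a match when the target
residue is among the most frequent; an all-gap target column never
matches.

## Block design

Donor strings are cut into sub-blocks *after flexible residues*
(G, I, A, V by default) — flexibility at the seams lets an inserted
block adopt the local backbone without strain. Cuts may be given
explicitly (they must fall after a flexible residue) or chosen greedily
toward a 7-residue target fragment length. `deriveBlocks()` returns the
*nested cumulative* blocks — fragment 1, fragments 1–2, fragments 1–2–3
— all anchored immediately after the vacancy's anchor residue, which is
what produces an 8/15/21-residue (or 7/14/22-residue) sibling ladder
from a single donor.

Insertion semantics follow the superscript-coordinate convention: a
block "occupying positions 51…" is inserted between old residues 50 and
51, so its last residue sits at position anchor + length − 1 of the new
sequence. A 21-residue block anchored at 51 therefore ends at residue
71, and a 22-residue block at 72. `generateVariantSeries()` emits one
variant per block, one per substitution, and one per block × substitution
when both are supplied; `buildSiblingVariants()` composes the canonical
3 + 3 + 1 + 3 = 10-variant scheme (two donor ladders, one four-residue
substitution, and the first ladder re-applied on the substituted
template). Every variant is C-terminally tagged with an ER retention
signal (KDEL by default, appended once, idempotently), and every variant
stores its edit list so it can be reverted to the template exactly — the
suite asserts this inverse for all generated variants.

## Constructs

`reverseTranslate()` uses a murine codon-usage table (shipped as TSV,
replaceable) and picks the highest-usage codon per residue; wherever a
forbidden restriction site would appear — including sites spanning codon
boundaries — the fewest possible codons are swapped to next-ranked
synonyms until the sequence is clean, or an error reports that synonymy
is exhausted. Expression inserts are `HindIII — ATG-initiated ORF — stop
— XhoI`. Strain probes fuse partner–reporter–partner (e.g.
FRB–ALuc–FKBP) with the KpnI and BamHI sites kept in frame, which
appends Gly-Thr and Gly-Ser junction dipeptides; this retained-site
convention is declared and configurable, since cloning strategy, not
biology, dictates it. The reporter must be SP-free — secretion peptides
stop sandwiched reporters from working as strain sensors — so an SP
annotation raises an error rather than a warning. PCA probes split a
reporter after residue $k$ (slash notation `1–k / k+1–end`) around a
sensing insert; with no insert and junctions suppressed the assembly
reconstitutes the intact reporter, an identity the tests exercise.
`proposeDissectionSites()` nominates the midpoint of every coil run
flanked by helices on both sides, the hinge regions where split
reporters tolerate dissection.

## Phylogeny, spectra, structure metrics

Distances between designed sequences are `1 − identity` over global
alignment columns (gap columns included by default; an ungapped-columns
mode exists because the denominator convention must be stated, not
assumed). Tree building is Saitou–Nei neighbor joining written in-repo:
Q-criterion, deterministic lexicographic tie-break, negative branch
lengths clamped to zero with a warning. On additive matrices the
algorithm is exact; the tests verify topology and branch lengths to
1e-9 against matrices synthesized from random trees, and cross-check one
tree against the independent `ape::nj`. Trees are `ape::phylo` objects;
the Newick writer quotes labels containing metacharacters.

Spectrum summaries report the peak wavelength (ties toward the blue),
the FWHM from the two outermost half-maximum crossings found by linear
interpolation (one number per spectrum even if multimodal), and the
fraction of trapezoidal spectral mass above a cutoff (600 nm by default
— the tissue-transparency window that makes redshifted reporters useful
in animals). No smoothing is applied unless asked. Fold intensities are
condition mean over reference mean with first-order error propagation.

Structure metrics parse PDB ATOM records (fixed columns, via `bio3d`
with a strict coordinate-column pre-check), and
`sidechainMinDistance()` takes the minimum over heavy side-chain atom
pairs, counting Cβ as side chain and falling back to Cα for glycine.
`classifyLoopProximity()` buckets a distance as close (≤ 6 Å), middle
(6–8.5 Å] or far (> 8.5 Å); the 8.5 Å middle/far boundary is chosen so
that an 8.0 Å contact is middle and an 8.7 Å contact is far, and both
thresholds are arguments. Classification near the boundaries can differ
from a visual call on a full loop — the metric is a single minimal
distance, and users can annotate overrides rather than the package
guessing.

## The synthetic family generator

`familyRecipe()`/`generateSyntheticFamily()` emulate the architecture
the pipeline targets: SP (17 aa) ∥ N-region ∥ domain (90 aa) ∥ domain
copy, about 200 mature residues. The N-region is a *diverged* copy of
the domain (default 30% per-residue substitution) with a planted
vacancy, by default 21 residues deleted after position 50 — so the
ground truth the pipeline must recover is the domain span 51–71. The
divergence default reflects the variable N-region of real copepod
luciferases and is also what makes the recovery problem well-posed: with
an undiverged N-copy the protein is effectively a threefold tandem
repeat and a phase-shifted three-way split can legitimately outscore the
planted one. The second domain copy carries its own substitution rate
(`domain_mut_rate`, 0 by default). Generators are pure functions of
their recipe (the seed is a field, and the caller's RNG stream is
restored afterwards).

What the generator does *not* emulate: real secretion-peptide
composition biases, realistic residue frequencies (draws are uniform
over the 20 residues, which is neutral for BLOSUM scoring), indel
divergence between the domains, and any connection between sequence and
brightness or emission color. Spectra are sums of Gaussians with
optional multiplicative noise. Passing tests therefore demonstrate that
the algorithms recover planted signal under the stated noise model — not
that a designed variant will be bright.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the scale of the study
design: 194-residue templates, 90-residue domains, 20-seed recovery
panels, 50 six-leaf trees for NJ exactness, 1-nm spectral grids. pI is
solved by bisection on pH 0–14 to 1e-4 (the net-charge function is
monotone), and validated against a two-stage grid scan at 1e-5
resolution. Molecular weights use average isotopic residue masses plus
one water, matching the kD convention for reporting luciferase sizes,
and are additive up to a water per peptide bond. The pKa set is a
Bjellqvist-style table shipped as YAML and overridable; published
"theoretical pI" values rarely state their table, so ours is explicit.

Degenerate inputs are rejected loudly: ambiguity codes (B, Z, X, U, O)
at ingest, all-zero spectra, non-increasing wavelength grids, SPs
covering a whole sequence, dissection sites at or beyond the C-terminus,
asymmetric or negative distance matrices. Deletion placement in a
repeat is identifiable only up to equivalent placements when a deleted
block's flanks coincide; recovery checks therefore use the
reconstruction identity (re-inserting the detected donor at the detected
anchor must restore the undeleted region) rather than literal string
equality of one arbitrarily chosen placement.

## Known limitations

* The three-region split assumes exactly two tandem domains; proteins
  with other repeat counts need explicit boundaries.
* The majority-profile stacking can misplace a gap by a column or two
  at high N-region divergence; the vacancy span is still found, but its
  edges inherit alignment uncertainty.
* Reverse translation optimizes codon rank and site avoidance only — no
  GC balancing, no secondary-structure or splice-motif avoidance.
* NJ is the only tree method; no bootstrap support values.
* The structural module measures distances on coordinates you provide;
  it does not build models.
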