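---
title: "The DDxP annotation grammar and the growth-by-insertion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DDxP annotation grammar and the growth-by-insertion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddxpscan)
```

## The model

DDxP proteins are large secreted bacterial proteins whose central region
is an array of repeat modules, each module closing with an Asp–Asp–x–Pro
(DDxP) tetrapeptide. The mechanistic account this package implements is a
DNA-level insertion grammar:

1. A site-specific endonuclease recognises an 18-bp site fitting the
   IUPAC consensus `DTYnnnGAYGAYGKnCCV`. Read in frame, the six codons of
   any conforming site translate to a peptide whose residues 3, 4 and 6
   are Asp, Asp and Pro — i.e. the site itself encodes a DDxP motif
   (typically at the border between the N region and the repeat array;
   the best-characterised target is the dodecamer `GACGACGGCCCG`
   encoding DDGP, corresponding to positions 7–18 of the consensus).
2. The enzyme cuts at the right end of that dodecamer and 6 bp upstream
   of the full site — two cuts 18 bp apart, leaving single-stranded
   overhangs. Repair after insertion of a DNA module duplicates the
   overhang, producing an 18-bp **target site duplication** on each side
   of the insert. This is why every module *ends* with DDxP: the
   downstream TSD copy contributes the module's last six codons.
3. Each TSD copy is itself a functional target, so arrays grow by
   further insertions; head-to-tail clusters arise from tandem
   amplification of a module together with one flanking TSD copy.
   Point mutation then diversifies copies.

Every component of the package is one face of this grammar: the scanner
inverts it (from protein to module array), the TSD detector verifies its
DNA-level footprint, the consensus builder recovers the recognition site
from the footprints, and the simulator runs the grammar forward to make
ground-truth data.

## Segmentation

`segment_modules()` collects the end positions of all terminal-motif hits
as candidate boundaries and keeps the chain of boundaries with the most
inter-boundary gaps inside the module-length window
(`min_module_len = 120`, `max_module_len = 350` aa). These defaults
bracket the observed catalog range (136–309 aa) with margin, so unseen
variants are admitted while 4-aa spurious gaps are not. Design choices
made where the grammar itself is silent:

* **Chain objective.** The chain maximises module *count*, not covered
  length; ties resolve to the leftmost chain. Known DDxP proteins carry a
  single repeat region, so a count-maximal chain is the parsimonious
  reading; a second valid chain outside the chosen one is reported via
  the `extra_module_chain` flag rather than merged (proteins with two
  unlinked clusters exist but are exceptional).
* **The wildcard position.** The terminal motif's third residue is
  unrestricted by default: the catalog shows x ∈ {G, T, V, A, M, K, I},
  broader than the G/T/V seen in Legionella alone. `x_allowed` restricts
  it; `relaxed_terminal` additionally tolerates one mismatch at the
  second position only, admitting the three divergent catalog repeats
  (DSGP, DTGP, DVGP) — off by default because it also admits noise.
* **DGDGD is a warning, not a rule.** A conserved DGDGD motif sits
  11–19 aa upstream of the terminal motif in the known repeats, but its
  strength as a constraint is not quantified, so its absence sets the
  `missing_dgdgd` flag and never changes segmentation.
* **Size classes.** S ≤ 215 aa and L ≥ 243 aa as printed; the 216–242 aa
  gap is reported as `intermediate` and flagged, never silently
  reassigned — the catalog itself contains one 219-aa entry printed S,
  and the disagreement is surfaced by `catalog_stats()` instead of being
  corrected away.
* **Group calls.** Group I requires ≥ 2 RTX nonapeptide hits inside the
  C region. One hit is too weak a signal for a calcium-binding β-roll;
  the threshold is configurable.

Coordinates are 0-based half-open everywhere internally; conversion to
1-based inclusive happens only at the GFF3/report boundary. This keeps
module arithmetic (`length = end - start`, tiling checks) free of
off-by-one cases.

## Typing

The family literature types repeats by ">70% sequence identity" without
stating the alignment or the denominator. The package fixes both
explicitly: global end-to-end alignment with match +1, mismatch 0, linear
gap −1, and identity = matches / alignment length (gaps included). This
makes identity symmetric, bounded by 1, and equal to 1 only for identical
sequences; all scores are configurable. Clustering is single linkage at
*strict* > 0.70 (a pair at exactly the threshold stays separate),
mirroring the ">70%" wording; identical sequences always share a type so
the threshold-1 limit degenerates to unique-sequence classes. Types whose
mean internal divergence exceeds 5% are het (the published dichotomy is
< 5% vs 15–20%; the band in between is flagged `het_marginal` because the
description leaves it open). Trees over type representatives are UPGMA on
1 − identity, which matches the average-linkage, ultrametric style of the
published circular tree; reproducing that tree's exact topology is out of
scope because the underlying repeat sequences are published only in an
appendix not packaged here.

## TSD detection

Detection is anchored at module junctions: for module *i* the 18 bp
closing its CDS interval are compared with the 18 bp closing the previous
segment. This follows the grammar (TSDs exist exactly at junctions); a
genome-wide duplication scan is deliberately out of scope. The two copies
may diverge by up to `max_tsd_mismatches = 4` of 18 positions — published
junction alignments show diverged copies but no count, so the bound is a
package default, chosen low enough that random 18-mers (expected ~13.5
mismatches) never pass, and configurable. The 18-bp frame alignment is
enforced (module boundaries are codon-aligned by construction), and
modules starting < 18 bp into the CDS are skipped with a flag rather than
guessed at. `consensus_from_tsds()` pools all copies and returns the
column-wise minimal IUPAC cover, so every observed copy matches the
derived pattern by construction.

One point in the source account requires an interpretation: the cut is
described as "at the right end of the dodecamer and 6 bp upstream", yet
the duplication is 18 bp. The only geometry consistent with both is that
"6 bp upstream" refers to the *full 18-bp site's* left end (6 bp + the
12-bp dodecamer = 18 bp between cuts), and that is how the simulator
implements it.

## The simulator

`simulate_lineage()` runs the grammar forward from an ancestral "empty"
gene — N region, one planted consensus-conforming target, C region —
mirroring the empty (rep−) homologs that motivate the insertion model.
Parameters, with units and defaults:

| parameter | default | meaning |
|---|---|---|
| `n_insertions` | 2 | module insertion events |
| `amplification_copies` | 3 | tandem copies per inserted module |
| `mutation_rate` | 0 | per-base substitution probability |
| `module_length_range` | 130–310 aa | module length draw |
| `phe_bias` | 0.9 | P(target codon 1 is TTC/TTT) |
| `n_region_len`, `c_region_len` | 200, 300 aa | flank lengths |

No insertion/amplification/mutation rates are published, so these are
user parameters. The module range brackets the catalog's 136–309 aa;
`phe_bias` reflects the reported predominance of TTC/TTT at target
residues 1–3 (hence phenylalanine at the matching protein position);
flank lengths are typical of the family's shorter members. Module bodies
are generated with a DGDGD planted 11–19 aa upstream of the eventual
terminal motif so simulated proteins exercise the DGDGD validator.

Numerical and degenerate-input choices:

* All generation is rejection-sampled so the translated gene contains
  *exactly* the planted DDxP occurrences — no spurious boundaries at
  mutation 0 (bounded at 10,000 draws; exceeding the bound is an error,
  not a silent fallback).
* Target codon 2 (`nnn`) is redrawn when it would be a stop codon: the
  consensus admits stops but a real gene cannot.
* Point substitutions that would create an in-frame stop are redrawn
  among the remaining bases (configurable off), and the terminal stop
  codon is never mutated, so every emitted CDS stays a well-formed gene
  with `protein length = (CDS − 3)/3`.
* A single seeded RNG stream drives every event, so a lineage is
  replayable byte-for-byte from `config$seed`.

## What the simulator does and does not emulate

It emulates the DNA-level mechanism: consensus-conforming targets, exact
18-bp duplication, head-to-tail amplification of module+TSD units, i.i.d.
point substitution. It does **not** emulate homologous-recombination
exchange of modules between genes, selection on repeat number or
composition, indels, codon-usage bias, or the N/C-region subtype
diversity of real proteins (flanks are random sequence). Passing
round-trip tests therefore show that the scanner inverts the grammar
correctly under the stated noise model — not that real proteomes contain
no harder cases (diverged terminal motifs, nested rearrangements,
composition bias mimicking motifs).

A quantitative consequence worth stating: the terminal motif is the only
segmentation signal, and its 12 coding bases contain about 7.3
non-synonymous position-equivalents. Under i.i.d. substitution at rate
*r* per base, each boundary survives with probability ≈ (1 − r)^7.3, so
at *r* = 0.01 roughly 7% of boundaries lose their motif and module counts
change accordingly in multi-module arrays. Recovery under mutation is
therefore strongly array-size-dependent; the relaxed terminal mode
recovers some of it at the cost of specificity.

## Problem sizes used in the test suite

The packaged tests validate the scanner against the simulator at desk
scale: 1,000 single-insertion draws for the TSD-mechanics check, 100
seeded lineage configurations (1–3 insertions × 1–6 copies) for
round-trip recovery at mutation rates 0 and 0.01, oracle equivalence on
sequences ≤ 200 aa, ≤ 12-module clustering problems, and ≤ 6-taxon trees.
These sizes were chosen to exercise every code path with comfortable
statistical resolution while keeping the default suite fast enough to run
on every change.

## Known limitations

* Typing identity is alignment-parameter-dependent; the defaults are a
  declared convention, not a recovered one.
* The scanner reports only the best module chain; genuine multi-cluster
  proteins surface as `extra_module_chain` flags, not as multi-region
  annotations.
* The catalog packages the published metadata only (ids, lengths,
  labels, motifs); the repeat sequences themselves are not included, so
  sequence-level reproduction of the published tree is not possible from
  this package alone.
* CDS inputs are assumed in coding orientation and frame 0 unless a
  `frame_offset` is given; there is no reverse-complement or ORF search.
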