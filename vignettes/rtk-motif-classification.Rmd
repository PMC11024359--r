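---
title: "Motif-based classification of crustacean receptor tyrosine kinases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based classification of crustacean receptor tyrosine kinases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtkclass)
```

## The problem

Receptor tyrosine kinases (RTKs) in crustaceans fall into four classes —
insulin receptors (InsR) and the growth-factor receptors EGFR, FGFR and the
undivided invertebrate PDGFR/VEGFR ortholog (PVR) — which subdivide further
into subtypes (InsR1–3, EGFR1, FGFR1–3, PVR1/2A/2B). Assigning a new
transcriptome contig to a class and subtype normally requires building a
large multi-species alignment and a maximum-likelihood tree. The motifs in
the kinase catalytic domain and, for InsR, near the first fibronectin
type 3 (FN3) domain are diagnostic enough that a scan against a small motif
library can discriminate classes and subtypes without any phylogenetics.
`rtkclass` implements that scan, the supervised discovery procedure that
derives such motifs from a labelled alignment, and a synthetic-sequence
generator so the whole pipeline is testable without a transcriptome
database.

## The motif model

A *degenerate consensus motif* is an ungapped fixed-length pattern: position
$j$ is either a fixed residue (set) or the wildcard `x`. A window of a
subject sequence is scored as

$$\mathrm{score} = \frac{\#\{\text{fixed positions matched}\}}
                        {\#\{\text{fixed positions}\}}$$

Wildcards contribute to neither numerator nor denominator (the tables that
define the motifs use `x` for "any residue"), and an ambiguity character `X`
in the subject never matches a fixed position: sequences with unknown
residues are kept but penalised rather than discarded. *Universal*
positions — residues identical across all subtypes of a class, the bold
residues of the published tables — are tracked per motif; they are the most
reliable signal and drive the confidence tier (below). `scan_motif()`
returns all windows above a threshold sorted by score (descending) then
start (ascending), so output is deterministic.

The shipped library (`load_motif_library()`) contains:

* the InsR catalytic-loop 10-mer `VHRDLAARNC` (all ten positions universal);
* three 20-residue InsR subtype motifs located near the first FN3 domain,
  with universal columns Y2, A3, V6, S20;
* three FGFR catalytic-domain subtype motifs (117–118 residues) bounded by
  `VAVK` and `HRDLA`;
* three PVR catalytic-domain subtype motifs (62 residues) containing the
  `HGDLA`-anchored catalytic loop and ending in `PxKW`;
* a synthetic EGFR catalytic-context string. EGFR1 has no published
  subtype-diagnostic motif (the class is nearly invariant in its catalytic
  domain), so the package ships an artifact-derived 49-mer — clearly marked
  `artifact-derived (synthetic)` in the fixture — carrying the canonical
  `HRDLA` loop and a downstream `DFG`. It is constructed so that its best
  window against `VHRDLAARNC` scores 0.7, below the class threshold, which
  keeps the EGFR and InsR tests disjoint.

Universal columns in the fixture are *derived* as the columns where all
subtype consensus strings of a class agree on a fixed residue — this is
exactly the published definition of the bold markup, and on the InsR FN3
trio the derivation reproduces the printed bold set, which validates the
rule. Two printed length figures for the FGFR and PVR motifs disagree
between the running text and the table captions (113/112 vs 118/117 and 46
vs 62); the discrepancy is resolved by observing that the smaller numbers
are the anchor-to-anchor sub-spans of the full table strings. Motif lengths
are therefore never used as hard constraints; the anchored-region bounds
default to a permissive [100, 125] interior for `VAVK..HRDLA` and [30, 50]
for `HGDLA..PxKW`, both configurable. The single `-` character inside the
FGFR2/FGFR3 table strings is stored verbatim in the fixture (`variant =
"verbatim"`) but stripped in the `scan` variant the classifier uses, since
the scanner is ungapped.

All four classes share three kinase landmarks in fixed N-to-C order: the
glycine-rich loop `GxGxFG`, the catalytic loop `H[GR]DLA` (`HGDLA` in PVR,
`HRDLA` elsewhere) and `DFG` near the activation loop.
`locate_kinase_landmarks()` reports the left-most order-consistent triple,
or each landmark's first match with `ordering_ok = FALSE` when no
consistent triple exists.

## The classifier

`classify()` proceeds in four steps:

1. locate the kinase landmarks;
2. **class call** from four class-marker scores: best window of
   `VHRDLAARNC` (InsR), best FGFR subtype motif, best PVR subtype motif,
   and the EGFR context string. A perfect `VHRDLAARNC` always wins
   regardless of other scores. Otherwise the best score at or above
   `theta_class` (default 0.8) wins among InsR/FGFR/PVR; EGFR is called
   only by elimination — landmarks present and ordered with the canonical
   `HRDLA`, all three other class tests failed, and either the context
   string scores ≥ `theta_class` or a supplied domain architecture matches
   the EGFR signature. Elimination alone would label arbitrary kinases
   EGFR; the conjunction keeps the false-positive rate on random sequences
   below 1%.
3. **subtype call**: the best-scoring subtype motif of the class with score
   ≥ `theta_sub` (default 0.7) and margin over the runner-up ≥ `margin`
   (default 0.02), else `unassigned`. For InsR the subtype motifs are the
   N-terminal FN3 20-mers, so a contig lacking its kinase domain can still
   be assigned a subtype (tier `partial`) — mirroring how a kinase-less
   partial insulin-receptor contig was identified in practice. FGFR/PVR
   subtype motifs are kinase-internal, so kinase-less FGFR/PVR contigs
   degrade to class-level or unknown calls.
4. optional **architecture check** (`architecture_class()`): InsR = 2
   Receptor L + ≥1 furin-like + 2 FN3 (kinase optional); EGFR = 2 Receptor
   L + 1–2 furin-like + 1 GF-IV + kinase; FGFR = 1–3 immunoglobulin-like
   *or* 1 cadherin repeat, + kinase; PVR = 2–5 immunoglobulin-like +
   kinase. A conflict demotes the tier to `ambiguous`; an unambiguous
   architecture can rescue a motif-free sequence at tier
   `architecture_only`.

Confidence tiers: `full` = kinase evidence, ordered landmarks and a subtype
motif with every universal position intact; `partial` = one evidence source
or universal positions broken; `architecture_only`; `ambiguous`.

### Why universal positions gate the tier, not the subtype call

A natural stricter rule would reject any subtype call whose universal
positions are not all matched. The FGFR motifs have ~36 universal columns,
so at a 5% per-position substitution rate the probability that all survive
is about $0.95^{36} \approx 0.16$ — the strict gate would discard most
correct calls on modestly diverged sequences while the score margin still
identifies the subtype unambiguously. The package therefore uses universal
integrity to set the *confidence tier* and the score+margin rule to set the
*label*. Noise-free behaviour is identical under both rules.

### Threshold calibration

`theta_class = 0.8` tolerates two mismatches in the InsR 10-mer while
rejecting the closest cross-class window (the EGFR context scores 0.7
against it by construction). `theta_sub = 0.7` sits far above the largest
cross-subtype score observed deterministically (≈0.64 for InsR FN3 pairs,
≈0.5 for FGFR pairs). The margin default is 0.02: the PVR2A and PVR2B
motifs agree on 37 of PVR2A's 41 fixed columns, so on a PVR2B sequence the
runner-up score is ≥0.90 before any chance matches at wildcard positions; a
0.05 margin would misreject ~1.5% of noise-free PVR2B sequences, while 0.02
fails only when all four free columns coincide by chance
(≈$6\times10^{-6}$ per sequence). The relaxed PVR catalytic-loop anchor
(`relaxed_catloop = TRUE`, admitting `HRDLA` in place of `HGDLA`) exists
for the documented G→R variant in one shrimp VEGFR2; it is off by default
so that PVR evidence is not silently conflated with the other classes.

## Supervised motif discovery

Given an alignment whose rows carry group labels (subtypes from a prior
phylogeny), `column_profiles()` tabulates per-column residue counts overall
and per group; `group_consensus()` emits, per group, the modal residue
where its within-group frequency is ≥ `tau` (default 0.8) and the gap
frequency ≤ `gamma` (default 0.5), else `x`; columns gapped beyond `gamma`
in *every* group are dropped from all consensuses so the strings stay
comparable. `universal_positions()` and `diagnostic_positions()` then
separate columns conserved across all groups from columns fixed within each
group but different between groups — the subtype-diagnostic peptide-binding
residues. `residue_proportions()` produces the per-column frequency table
used for sequence-logo rendering (gap-inclusive by default, gap-excluded by
flag). Ties for the modal residue are broken alphabetically; since a tied
column cannot reach `tau > 0.5`, the tie-break affects only reporting,
never consensus content. The thresholds are not published for the original
discovery tool; `tau = 0.8` is chosen so that the worked reconstruction of
the InsR FN3 motifs from a 20-row-per-group rotation-filled alignment
recovers the printed strings exactly.

## The synthetic generator

`generate_sequence()` assembles: random N-terminal linker (200–400 aa; for
InsR the subtype FN3 20-mer is planted inside it), glycine-rich loop,
spacer (30–80 aa), class/subtype catalytic cassette (InsR: `VHRDLAARNC`;
FGFR/PVR: the full subtype motif, anchors included; EGFR: the synthetic
context string), a `DFG` landmark where the cassette lacks one (the PVR and
EGFR cassettes already contain it), and a tail (30–60 aa). Wildcards and
linkers draw from a uniform background over the 20 residues — the most
stringent choice for false-positive testing, since any compositional bias
would only make random matches rarer. Substitutions replace a residue by a
uniformly drawn different residue at rate `p_fix` on fixed motif positions
and `p_bg` elsewhere; no substitution matrix is claimed. Truncation removes
the N- or C-terminal part, keeping a stated fraction, and the truth record
flags every planted motif the cut destroyed. All randomness flows from the
spec's seed through a deterministic per-record derivation, so identical
specs give byte-identical datasets.

What the generator does *not* emulate: real domain content outside the
planted motifs, indels, compositional bias, assembly artifacts, or isoform
structure. A green recovery test therefore establishes that the classifier
reads its own planted signal correctly at the stated noise levels — not
that it matches phylogenetic annotation on real transcriptomes, where
homologous but unmodelled context could raise cross-class scores.

## Numerical and edge-case choices

* Internal coordinates are 0-based half-open; all files and reports are
  1-based inclusive.
* Scan ties: score descending, then leftmost start.
* A subject shorter than a motif scans to an empty hit list, not an error.
* Nucleotide input and ORF translation are out of scope; protein FASTA
  only. The trailing-`*` partial-sequence header convention is this
  package's own (the source naming convention is not machine-readable).
* Diagnostic positions are reported in alignment coordinates only; mapping
  them onto unaligned sequences would require the unpublished reference
  alignment.
* Isoform collapsing across contigs is out of scope; calls are
  per-sequence.

## Known limitations

Real (non-synthetic) EGFR and InsR catalytic loops are similar
(`xHRDLAARNx`); the class decision separates them by the final cysteine of
`VHRDLAARNC` plus the score comparison, which is validated only on
synthetic data here. The architecture checker consumes externally produced
domain tables and trusts their labels. The discovery stage assumes a
trustworthy input alignment; it does not align.
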