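# rtkclass

Motif-based classification of crustacean receptor tyrosine kinases (RTKs).

Crustacean RTKs fall into four classes — insulin receptors (**InsR**) and the
growth-factor receptors **EGFR**, **FGFR** and **PVR** (the undivided
invertebrate PDGFR/VEGFR ortholog) — subdivided into the subtypes InsR1–3,
EGFR1, FGFR1–3 and PVR1/2A/2B. Assigning a transcriptome contig to a class
and subtype normally means building a multi-species alignment and a
maximum-likelihood tree. Short degenerate consensus motifs make that
unnecessary: all classes share three kinase landmarks (the glycine-rich loop
`GxGxFG`, the catalytic loop `H[G/R]DLA`, and `DFG` near the activation
loop), the InsRs carry an invariant catalytic 10-mer `VHRDLAARNC` and
subtype-diagnostic 20-mers near the first fibronectin type 3 domain, and the
FGFR/PVR subtypes are distinguished by catalytic-domain motifs bounded by
`VAVK..HRDLA` and `HGDLA..PxKW` respectively.

`rtkclass` is for sequence curators and comparative endocrinologists who
need fast, reproducible class/subtype calls (and their evidence) for protein
FASTA sequences with CrusTome-style identifiers. It provides:

* **motif model** — compile degenerate motifs (fixed / wildcard / universal
  positions), scan sequences (`scan_motif`), find anchored catalytic regions
  (`find_anchored_region`) and kinase landmarks
  (`locate_kinase_landmarks`). A window's score is the fraction of *fixed*
  positions matched; wildcards are free; an `X` in the subject never
  matches.
* **motif library** — the published class/subtype motifs shipped as a TSV
  fixture and compiled at load time (`load_motif_library`).
* **discovery** — supervised group-conservation analysis of a labelled
  alignment: per-column profiles, per-group consensus strings
  (`group_consensus`, threshold `tau`), universal and subtype-diagnostic
  positions, and the residue-proportion table behind sequence logos.
* **classifier** — hierarchical class → subtype assignment with evidence
  lists, confidence tiers (`full` / `partial` / `architecture_only` /
  `ambiguous`) and optional domain-architecture consistency checks
  (`classify`, `classify_batch`, `architecture_class`).
* **synthetic data** — a generator that plants the library motifs in random
  background at controlled substitution/truncation rates, with truth
  records, so every stage is testable without a transcriptome database.
* **CLI** — `exec/rtkclass` with subcommands `classify`, `discover`,
  `logo`, `simulate`, `check-arch`; every run writes a manifest JSON.

## Worked example

Simulate two sequences each of a clean InsR3, a noisy FGFR2 (5%
substitutions at fixed motif positions) and an N-terminally truncated PVR1,
then classify:

```r
library(rtkclass)
specs <- list(synthetic_spec("InsR", "InsR3", n = 2, seed = 11),
              synthetic_spec("FGFR", "FGFR2", n = 2, p_fix = 0.05, seed = 12),
              synthetic_spec("PVR",  "PVR1",  n = 2, truncation = "n_terminal",
                             retained = 0.5, seed = 13))
ds <- generate_dataset(specs)
b  <- classify_batch(ds$records)
b$table[, c("seq_id", "class", "subtype", "tier", "best_score")]
#>           seq_id class subtype    tier best_score
#>  synInsR3_11_001  InsR   InsR3    full  1.0000000
#>  synInsR3_11_002  InsR   InsR3    full  1.0000000
#>  synFGFR2_12_001  FGFR   FGFR2 partial  0.9259259
#>  synFGFR2_12_002  FGFR   FGFR2 partial  0.9382716
#>   synPVR1_13_001   PVR    PVR1    full  1.0000000
#>   synPVR1_13_002   PVR    PVR1    full  1.0000000
```

All six labels are recovered. The noisy FGFR2 sequences drop to tier
`partial`: their best subtype-motif windows score ≈0.93 (75/81 and 76/81
fixed positions) and some *universal* positions — the residues identical
across all FGFR subtypes — were hit by substitutions, so the call is
correct but flagged as lower confidence. The truncated PVR1 keeps tier
`full` because its subtype motif is kinase-internal and survived the cut.
Landmarks for the first sequence (0-based half-open coordinates):

```r
b$results[[1]]$landmarks
#> <kinase_landmarks> gly_loop [298,304), catalytic_loop [338,343), dfg [360,363) (ordered)
```

Discovery round-trip: rebuild the InsR subtype 20-mers from a toy labelled
alignment (20 rows per subtype, wildcard columns rotation-filled so no
residue exceeds 25% per column), then ask which columns are universal:

```r
fn3 <- c(InsR1 = "RYAVYVETDTVADADIGARS",
         InsR2 = "RYAVxVKxxSLxSSxxGAQS",
         InsR3 = "xYAxYVxxYYTDxxKxxSRS")
aln  <- generate_grouped_alignment(fn3, n_per_group = 20, seed = 1)
cons <- group_consensus(column_profiles(aln), tau = 0.8)
universal_positions(cons)
#> [1]  2  3  6 20
#> attr(,"residues")
#> [1] "Y" "A" "V" "S"
```

The consensus strings equal the inputs exactly, and the four universally
conserved residues (Y2, A3, V6, S20) are the class-wide signature of the
InsR FN3 motif.

## Domain vocabulary (architecture checks)

`read_domains()` accepts a TSV (`seq_id`, `domain`, `start`, `end`; 1-based
inclusive) with labels `RECEPTOR_L`, `FURIN_LIKE`, `FN3`, `TM`, `TK`,
`IG_LIKE`, `CADHERIN`, `GF_IV` (unknown labels are kept but flagged).
Signatures: InsR = 2×RECEPTOR_L, ≥1 FURIN_LIKE, 2×FN3 (TK optional);
EGFR = 2×RECEPTOR_L, 1–2 FURIN_LIKE, 1×GF_IV, TK; FGFR = 1–3 IG_LIKE or
1×CADHERIN, TK; PVR = 2–5 IG_LIKE, TK.

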