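---
title: "Allele-specific CRISPR targeting: model and design notes"
author: "crisprAllele"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific CRISPR targeting: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprAllele)
```

# The scientific problem

Cancer driver mutations such as KRAS G12S differ from the wild-type allele
by a single nucleotide. A CRISPR nuclease can, in principle, destroy the
mutant allele while sparing the wild type — but only when that single
nucleotide falls where the nuclease is least tolerant of mismatches: inside
the PAM itself, or within the PAM-proximal "seed" region of the
protospacer. `crisprAllele` implements this discrimination model end to
end: per-variant editability calls, whole-catalog scans, deep-sequencing
outcome profiling around the cut site, and treated-vs-control off-target
triage from variant tables.

# The editability model

A single-nucleotide variant (SNV) is called **editable** by a nuclease iff
the *mutant* allele carries at least one complete protospacer+PAM site (on
either strand) such that the SNV lies

* inside the PAM, or
* within the PAM-proximal seed window of the protospacer.

Three consequences of scanning the mutant allele:

1. A variant that *creates* a PAM is editable (the guide exists only on the
   mutant allele).
2. A variant that *destroys* a PAM is not counted — the site no longer
   exists on the allele being targeted.
3. A seed-resident variant is editable because the wild-type protospacer
   carries a seed mismatch against the mutant-matched guide.

`editability()` returns an `EditabilityCall` with all candidate guides,
their `snv_in` zone (`pam`/`seed`/`distal`), the 1-based
`snv_to_pam_distance` (0 inside the PAM, otherwise distance from the
PAM-proximal protospacer end), and a strand category: `S` (only sense
guides qualify), `AS` (only antisense), or `S_plus_AS`.

`strict = TRUE` additionally requires the wild-type allele to carry at
least one recognition-relevant mismatch (`wt_mismatch_count >= 1`),
excluding the corner case where the SNV sits at a degenerate PAM position
(e.g. the N of NGG): the guide matches the mutant perfectly, but the wild
type is recognised equally well, so no discrimination is possible.
`wt_mismatch_count` counts literal protospacer mismatches plus PAM
positions where the wild-type base *violates the PAM consensus* — a
wild-type base that still satisfies a degenerate PAM letter is not a
discriminating position.

# Nuclease parameters

The registry (`inst/extdata/nucleases.tsv`, loaded by
`nucleaseRegistry()`) ships three enzymes:

| name   | PAM    | side   | spacer | seed |
|--------|--------|--------|--------|------|
| SpCas9 | NGG    | 3′     | 20     | 8    |
| SaCas9 | NNGRRT | 3′     | 21     | 8    |
| LbCpf1 | TTTV   | 5′     | 23     | 6    |

The seed lengths are deliberate *lower bounds* from the mismatch-tolerance
literature (SpCas9 and SaCas9 are commonly credited with 8–12 nt
PAM-proximal sensitivity, Cas12a/Cpf1 with ~6 nt). Lower bounds make the
editability call conservative: a variant called editable at seed 8 remains
editable at any longer seed (editability is monotone in seed length — this
is tested). Because the values live in a plain-text registry, a user who
prefers different seeds can edit one file, or set them programmatically
via `seedLength<-`.

IUPAC degenerate matching uses one deliberate rule: an `N` **in the
subject sequence** matches only an `N` in the pattern. Ambiguous genome
bases therefore never silently satisfy a concrete PAM letter, again
keeping calls conservative.

# Coordinates

All internal intervals are **1-based, fully closed**, the native
convention of `IRanges`/`GRanges` and of `substr()`. File I/O follows each
format's own convention (VCF 1-based via `vcfR`, BED 0-based half-open via
`rtracklayer`). Reverse-strand PAM sites are reported in forward-strand
coordinates.

# Amplicon outcome profiling

`ampliconRef()` fixes the geometry around a guide: for a 3′-PAM nuclease
the blunt cut falls 3 bp 5′ of the PAM (between protospacer positions 17
and 18 for SpCas9), and the default quantification window is cut ± 10 bp.
Reads are aligned globally with `alignGlobal()` (Needleman–Wunsch via
`Biostrings::pairwiseAlignment`; match +5, mismatch −4, gap open 10, gap
extend 1 — gap-averse scoring so small indels are represented as single
gaps rather than scattered mismatches). `callEvents()` walks the aligned
columns and emits maximal runs of insertion (`I`), deletion (`D`) and
substitution (`S`); only events overlapping the quantification window
count. Substitution runs require base quality ≥ Q20 when qualities are
provided, which suppresses sequencing-error false positives.
`classifyRead()` labels each read `unmodified`, a single-event label such
as `I1` or `D2` (kind + total bases), or `C` (complex, ≥2 event kinds);
`buildSpectra()` normalises label/length/position distributions over
modified reads and `editingEfficiency()` is the modified fraction.

Alignments scoring below 30% of the perfect-match score are dropped and
reported, not classified.

# Off-target and WES comparison

`enumerateOffTargets()` is an exhaustive PAM-anchored scan: every PAM
occurrence on either strand whose adjacent protospacer has at most
`maxMismatch` (default 4) mismatches to the spacer, optionally with NGG
relaxed to NRG. This is deliberately a complete enumeration, not a
heuristic index — genomes at desk scale make this affordable, and
exhaustiveness is what the oracle equivalence tests certify.

`subtractBackground()` removes control variants from a treated table by
exact `(chrom, pos, ref, alt)` key — order-stable and idempotent.
`intersectOffTargets()` matches surviving variants to candidate sites
within a `slop` window (default 25 bp, generous for indel
position-calling jitter). `annotateReframe()` places each indel in
exon/intron/intergenic space from a BED gene model and calls `reframed =
"yes"` only for exonic indels whose net length is not a multiple of 3;
intronic and in-frame exonic indels are `"no"`, unannotated ones `NA`.

# Synthetic data

The generators in `R/simulate.R` are first-class, tested code — they are
the package's ground-truth machinery:

* `genGenome()` — seeded i.i.d. genome with a GC dial.
* `plantSnvCatalog()` — rejection-samples SNVs until an *exact* number of
  editable and non-editable variants is reached, labelled by
  `bruteLabelEditable()`, a brute-force labeler that shares no code with
  the production scanner (own IUPAC table, own loops). Scanner/labeler
  concordance is itself a test.
* `simAmpliconReads()` — applies a requested outcome spectrum
  (e.g. `c(I1 = 0.6, D2 = 0.2)`, remainder unmodified) at the cut site
  plus uniform base errors, returning reads, constant-Q40 qualities and a
  per-read truth table. Defaults match the validation conditions used
  throughout the tests: n = 2000 reads, 0.1% base error.
* `simVariantTables()` — treated/control tables sharing `nShared`
  background indels, with `nUnique` treatment-only indels placed either
  away from or inside a supplied site set.

One global seed fans out to fixed per-generator offsets, so adding a
generator never perturbs existing fixtures. All generators restore the
caller's RNG state. The generators deliberately do *not* model quality
ramps, indel sequencing errors or population structure.

The shipped demo fixtures (`inst/extdata/demo_*`) are produced by the
`simulate` subcommands of `inst/scripts/crisprallele.R`; see
`inst/scripts/make-demo-data.R` for the exact calls.

# Worked example

```{r kras}
call <- editability(krasG12SContext(), spCas9())
call
rankGuides(call)[, c("protospacer", "pam", "snv_in", "snv_to_pam_distance")]
```

The KRAS G12S variant (c.34G>A) sits 2 bp from a TGG PAM — inside the
SpCas9 seed — with a second qualifying guide at distance 8; both are on
the sense strand, so the strand category is `S`.

```{r catalog}
genome <- genGenome(10000, 0.5, seed = 7, name = "chrDemo")
planted <- plantSnvCatalog(genome, n = 60, fraction = 0.5, seed = 7)
summarizeCatalog(planted$catalog, genome,
                 nucleases = list(SpCas9 = spCas9()))$overall
```

# Validation strategy

Every scanning primitive is checked against an independent brute-force
implementation on hundreds of seeded random instances (PAM discovery,
protospacer enumeration, editability, off-target enumeration); alignment
scores are checked against exhaustive alignment enumeration on short
pairs; the published mouse WES indel table bundled in
`inst/extdata/mouse_wes_indels.tsv` is reproduced row for row by
`classifyIndel()` + `annotateReframe()`; and simulation-recovery tests
confirm the profiler recovers planted spectra within 3 binomial σ and
planted catalog fractions exactly. `scripts/acceptance.R` recomputes the
headline quantities from scratch into a JSON file.

# Limitations

* Editability is a geometric necessary condition; it does not predict
  cutting efficiency, chromatin accessibility, or guide activity scores.
* The seed lengths are configurable lower bounds, not measured per-guide
  tolerances.
* Off-target enumeration is mismatch-only (no DNA/RNA bulges).
* The read simulator's error model is uniform substitution only.
* Problem sizes in examples and tests (10-kb genomes, 2000-read pools)
  are package choices for desk-scale reproducibility, not biological
  claims.
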