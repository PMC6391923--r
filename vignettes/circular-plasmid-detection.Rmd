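---
title: "Methods: circular plasmid detection and typing from plasmidome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular plasmid detection and typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circplasmid)
```

## The detection model

Plasmid-enriched shotgun libraries are assembled into linear scaffolds. A
scaffold that derives from a circular molecule shows two independent
signatures of the underlying circle, and `circplasmid` requires both, plus
a minimum size, before calling a complete circular plasmid:

* **Terminal direct repeat.** When an assembler traverses a circle it
  re-emits the starting sequence, leaving (near-)identical sequence at both
  scaffold ends. `find_end_overlap()` aligns the first against the last
  `search_window_bp` bases (local alignment, forward vs forward only — a
  reverse-orientation end match indicates an inverted repeat, not a
  circle). The alignment score $S$ is converted to a Karlin–Altschul
  E-value $E = K\,m\,n\,e^{-\lambda S}$ with $m, n$ the two window
  lengths.
* **Junction-spanning read pairs.** A sequencing fragment that crosses the
  circular origin maps with one mate near each end of the linearized
  scaffold, mates facing outward in linear coordinates (start-proximal
  mate on the minus strand, end-proximal on plus, under FR paired-end
  chemistry). `count_junction_pairs()` counts pairs whose mates lie wholly
  within opposite terminal windows with that orientation.
* **Size.** Very short circles are dominated by artifacts (small cloning
  vectors, chimeric miniature circles), so scaffolds of 2 kb or less are
  never called.

`call_circular()` takes the strict conjunction of the three criteria and,
when positive, `circularize()` removes the suffix copy of the repeat so
the reported sequence is exactly one monomer of the circle. Detection is
deterministic: there is no randomness anywhere in the decision path.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_scaffold_bp` | 2000 (exclusive) | bp | minimum scaffold length |
| `min_overlap_bp` | 34 (exclusive) | bp | minimum end-overlap alignment length |
| `max_evalue` | 1e-5 | — | maximum E-value of the end overlap |
| `end_window_bp` | 500 (inclusive) | bp | terminal window for junction mates |
| `min_junction_pairs` | 2 (inclusive) | pairs | minimum junction support |
| `search_window_bp` | 1000 | bp | window searched for the terminal repeat |
| `lambda`, `K` | 1.28, 0.46 | — | Karlin–Altschul parameters |
| `match`, `mismatch` | +1, −2 | — | alignment scoring |
| `gap_open`, `gap_extend` | −2, −2 | — | gap penalties (E-value treats the score as ungapped) |
| `require_orientation` | TRUE | — | strict outward-facing junction mates |

The first five encode the published decision rule this package
operationalizes; the remainder are implementation policy, chosen as
standard nucleotide-search defaults. The inequality directions are read
literally from the rule's wording: "greater than 2 kb" and "greater than
34 bp" are strict, "at least two pairs" and "a maximum of 500 bp from the
end" are inclusive. The E-value bound is applied as $E \le 10^{-5}$ —
i.e. at least as significant as the threshold — since an alignment-evidence
rule with a lower bound on E would accept arbitrarily poor alignments.

### Numerical and edge-case choices

* **Windows on short scaffolds** are truncated to $\lfloor L/2 \rfloor$ so
  the two windows never overlap; a scaffold of length 1 yields no overlap
  (absence is a value, not an error).
* **"34-bp homology"** is interpreted as alignment length (columns). An
  alternative reading — matched bases — is obtainable from the reported
  identity; the choice only matters for gapped or imperfect repeats.
* **"A maximum of 500 bp from the end"** is read as the mate interval lying
  wholly inside the terminal window, the strictest unambiguous
  interpretation. A mate whose inner boundary sits exactly 500 bp from the
  end qualifies.
* **Orientation.** The strict mode demands the outward-facing pattern;
  `require_orientation = FALSE` counts any pair with mates in opposite
  windows, since "opposite ends" alone does not fix an orientation.
  Strict is the default because it suppresses chimeric-pair false
  positives.
* **N bases** are accepted in scaffolds and always score as mismatches in
  the overlap alignment (including N vs N), so assembly gaps cannot
  manufacture homology.
* **Ties** among equally scoring end overlaps are resolved deterministically
  by the aligner; repeated runs give identical calls.
* **Degenerate trims** (an overlap spanning the entire scaffold) are
  contract errors rather than empty sequences.
* **Cross-scaffold read pairs** are tallied on parsing and never count as
  junction evidence; the criterion is per-contig.
* Coordinates are 0-based half-open internally; SAM (1-based) and tabular
  (1-based inclusive) inputs are converted once at the boundary.

## Decontamination

Both filters remove whole scaffolds, never masked regions, because the aim
is to purge every trace of chromosomal or spike-in DNA:

* `filter_rrna_scaffolds()` removes a scaffold with any 16S rRNA hit whose
  alignment length exceeds 200 bp. Only length is thresholded; an optional
  identity floor is deliberately not applied by default.
* `filter_control_plasmids()` removes a scaffold with any control-plasmid
  hit above 95% identity (strict) over at least 1,000 bp (inclusive).

The filters consume hit tables; running the underlying sequence searches
(e.g. against SILVA or the control references) is the caller's job. This
keeps the package database-free. `fraction_reads_on_removed()` reports the
read-level proportion on removed scaffolds, counting both mates of each
mapped pair; mapped reads form the denominator, as the proportion is a
property of the mapped library.

## Typing rules

Mobility is decided solely by relaxase and T4SS presence: conjugative =
relaxase and T4SS; mobilizable = relaxase only; nonmobilizable = neither.
T4CP and the oriT/oriV origins are carried in the profile for reporting
but never influence the class — origins are rarely detectable by homology
and T4CP is optional in mobilizable plasmids. MOB family and Inc group are
best-bitscore assignments; MOB ties break by the fixed order
MOBF > MOBP > MOBQ > MOBC > MOBV > MOBB > MOBT and then lexical subject
id, so shuffled hit tables give identical calls. When the two IncA/C
schemes (cgPMLST and PMLST) tie at the top score the combined label
"IncA/C cgPMLST or IncA/C PMLST" is reported. A marker counts as present
only above a configurable bitscore floor (default 50); this floor is
package policy, not part of the published scheme.

## The synthetic community

`generate_community()` emulates the inputs of a deep-sequenced plasmidome
run: circular plasmids are built as random uniform-composition templates,
linearized with an exact terminal repeat (default 100 bp); paired-end
reads are drawn uniformly from the circular template, so junction-spanning
fragments arise at the analytic rate $(i-1)/L$ for insert $i$ and circle
length $L$; chromosomal decoys are linear; 16S decoys carry a planted
fragment length that surfaces in a fabricated hit table; and three
control plasmids (5, 48 and 202 kb, mirroring a spike-in model system of
two *E. coli* strains and one *Desulfovibrio vulgaris*) are generated at
elevated depth (default 40× vs 20×), echoing deliberately spiked controls.

Defaults define the package's reference study conditions: 20 circular
plasmids from 3 to 250 kb including a 202-kb control-scale replicon, 10
linear decoys of 5–30 kb, 4 rRNA decoys with 1,500-bp planted fragments,
2×150 bp reads with a 450 ± 50 bp insert model (within MiSeq v3 paired-end
capability), error-free by default. Insert size and read length are
package policy; no specific values are prescribed by the protocol being
emulated. The insert mean is deliberately larger than twice the read
length: overlapping mates can never satisfy the wholly-within-opposite-
windows junction rule, so a short-insert library would starve criterion
(iii) — a genuine property of the method worth knowing when applying it to
real libraries.

`map_reads_naive()` (exact 31-mer seed on the leading read k-mer, both
strands, ungapped full-length verification, unique-best placement) stands
in for an external short-read mapper so the loop closes without downloads.
It is intentionally naive: reads lying entirely inside a repeat copy map
ambiguously and are dropped, gapped alignment is unsupported, and error
tolerance is a small substitution budget. It is suitable only for
synthetic validation, and the alignment interface is aligner-agnostic
(SAM subset or the internal TSV dialect) precisely so real data can come
from any mapper.

What passing synthetic tests does **not** show: robustness to assembly
errors (misjoins, collapsed repeats), non-uniform coverage from
amplification bias (Phi29 amplification skews real plasmidome libraries
toward small circles), natural sequence composition, chimeric read pairs,
or imperfect terminal repeats from assembler heuristics. The E-value path
for mutated repeats is exercised separately by planting mismatches, but
real repeat-degeneracy statistics are not modeled.

## Shared-plasmid comparison

`shared_plasmids()` matches circularized sequences across two samples
rotation-invariantly (each circle aligned against the doubled partner) and
reports reciprocal best pairs exceeding 99.8% identity and 93.6% query
coverage, both strict. Reciprocal-best was chosen over one-directional
matching to keep the relation symmetric; query coverage is the aligned
query span over the query length.

## Problem sizes in the test suite

The suite validates on communities at the reference conditions above
(≈1.9 Mb of sequence, ≈145,000 read pairs per seed, five seeds) for the
end-to-end recovery check, 100 random planted constructs for the
terminal-repeat oracle equivalence, 10,000-pair runs for simulator
calibration, and a parameter grid on one fixed community for
monotonicity. These sizes were chosen so the whole suite runs in a couple
of minutes on a laptop while keeping every Monte-Carlo check at three
standard errors.

## Known limitations

* Criterion (iii) needs junction fragments to map contiguously across the
  repeat; libraries whose insert exceeds the repeat length by less than a
  read length lose junction evidence (see above).
* Multimeric plasmids (dimers of a smaller circle) pass the criteria as a
  single large circle; resolving multimers is out of scope.
* The detector consumes one alignment record per read pair; split-read
  (supplementary alignment) evidence of circularity is not used.
* Coverage is a pass-through mean depth; no copy-number model is applied.
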