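---
title: "Classifying immunophilin families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying immunophilin families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immfam)
```

# The problem

Immunophilins — FK506-binding proteins (FKBPs) and cyclophilins (CYPs) —
share peptidyl-prolyl cis/trans isomerase (PPIase) activity but form two
structurally unrelated families. Plant genomes carry unusually many of
them, a large fraction targeted to the chloroplast. Classifying a set of
candidate immunophilin proteins means answering, per protein:

1. How many PPIase domains does it carry, and of which family?
2. Which auxiliary domains accompany them (TPR, CaM, RRM, Arg/Lys-rich
   linkers, ...), i.e. is it a single-domain (SD) or multiple-domain (MD)
   member?
3. Where does the mature protein go — cytosol, chloroplast thylakoid
   lumen (soluble or membrane-anchored), ER, or nucleus?
4. How well does it retain the key drug-binding/catalytic residues of the
   human reference proteins?
5. What should it be called — after an ortholog in a reference proteome,
   or after its own mature molecular weight?

`immfam` implements this pipeline with fixed, documented heuristics in
place of the web predictors originally used for such surveys, so every
call is reproducible from the sequence alone.

# Reference anchors

All conservation statistics are anchored on two human proteins shipped as
fixtures: hFKBP12 (108 aa) with 14 key positions
(27, 37, 38, 43, 47, 55, 56, 57, 60, 82, 83, 88, 92, 100; residues
`YFDRFEVIWAYHIF`) and hCypA (165 aa) with 7 key positions
(54, 55, 60, 111, 113, 121, 126; residues `HRFQFWH`). Positions are
1-based in each reference's own numbering. `loadReferences()` validates
the fixtures against these canonical lists and fails hard on tampering.
Both reference proteins are single catalytic domains, which is why they
double as the domain models for scanning.

# Pairwise alignment

The alignment engine is a three-state affine-gap dynamic program
(Needleman–Wunsch / Smith–Waterman with Gotoh states) implemented in C++.
Conventions, all deliberate and tested:

* a gap of length $L$ costs $g_o + L\,g_e$ with defaults $g_o = 10$,
  $g_e = 0.5$ over BLOSUM62;
* global mode penalizes terminal gaps (a true global alignment — the
  simplest contract to state and test);
* traceback ties prefer the diagonal, then a gap in the second sequence,
  then a gap in the first, making every alignment deterministic;
* `X` (also used for masking) scores the minimum of its partner's
  BLOSUM62 row, so unknown or masked residues can never help an
  alignment;
* local alignments have score $\ge 0$, with the empty alignment at 0.

Correctness is established two independent ways: a brute-force oracle
that enumerates every monotone alignment path and scores it directly
(exact for short sequences), and a cross-check against a second,
independently developed affine-gap implementation. The brute-force
comparison runs over every pair up to length 2 on a four-letter
sub-alphabet plus a seeded sample of 300 longer pairs (lengths 3–6);
exhausting all length-≤6 pairs would be tens of millions of pairs, so the
suite samples — the enumeration itself is exact.

Percent identity uses, by default, all aligned columns (including gap
columns) as denominator; percent similarity additionally counts columns
with a positive substitution score. Both conventions are configurable
because published percentages from external tools rarely state theirs.

# Domain scanning

`scanPpiaseDomains()` runs a greedy iterative local-alignment scan: the
better-scoring of the two family references is aligned locally to the
protein; if the normalized score (raw / reference self-score) reaches
`minNormalized` (default 0.3) the hit is accepted and its span is masked
with `X`; repeat up to `maxCopies` (default 4, one more than the largest
architecture observed in the motivating family survey). Masking rather
than splitting preserves coordinates and guarantees non-overlapping hits
and termination. A verbatim reference copy scores exactly 1.0. The
threshold is a configuration value — no equivalence with any external
domain database's cutoff is claimed.

For multi-domain proteins the *representative* domain — the one used for
conservation scoring — is the hit with the highest normalized score (ties:
leftmost), mirroring the practice of scoring the most conserved copy.

The only auxiliary feature detected in-package is the Arg/Lys-rich
region (every `window = 20` subwindow with ≥ 40% R+K, merged, minimum
length 30), because it is defined compositionally. TPR, CCD, CaM, WD40,
RRM, U-box, zinc-finger and TM annotations enter through an optional
tab-separated annotation file; re-implementing profile-based domain
databases is out of scope.

# Targeting signals

The heuristics encode the qualitative rules read off immunophilin
alignments; all numeric defaults below are package choices, documented
and configurable, since the original analyses drew signal boxes by hand.

**Tat (twin-arginine) signal** — an `RR` pair within the first
`nWindow = 80` residues, followed within 25 residues by a hydrophobic
stretch: at least `hMinLen = 8` consecutive residues with mean
Kyte–Doolittle hydropathy ≥ `hMinMean = 1.5`. The stretch is extended
while the trailing 8-residue window stays at the threshold — a windowed
rule rather than a whole-run mean, so one polar residue ends the region
instead of being absorbed. An Ala-Xaa-Ala peptidase motif searched from
10 residues before the stretch's end (alanines are mildly hydrophobic and
often absorbed into it) to `cleaveWindow = 30` residues after marks a
cleaved, soluble lumenal protein; its absence marks a membrane-anchored
one. `RR` means exactly two arginines; a toggle admits KR/RK variants.
Every RR pair in the window is tried in order and the first with a valid
hydrophobic stretch wins.

**ER** — an N-terminal hydrophobic leader (same stretch rule, no RR
requirement, starting within 30 residues) plus a C-terminal tetrapeptide
matching `[A-Z][SD]EL` (covers DSEL/NSEL-type plant variants and classic
KDEL/HDEL).

**NLS** — monopartite: ≥ 4 K/R in any window of 6; bipartite: two basic
doublets separated by 9–12 residues; overlapping detections merge.

**Precedence** (a fixed artifact decision; the source analyses judged
case by case): Tat+cleavage → chloroplast lumen; Tat without cleavage →
thylakoid membrane-anchored; ER leader + retention → ER; NLS alone →
nucleus; nothing → cytosol. Chloroplast stroma cannot be distinguished by
these heuristics and is never emitted; mitochondrial presequences are not
modelled.

# Key-residue conservation and the printed tables

`extractKeyResidues()` aligns a protein (usually its representative
domain) globally to the family reference and reads the protein's residue
in each key position's column ('-' when gapped). Conservation is the
fraction of positions retaining the reference residue exactly — '-' never
counts — rounded half away from zero (so 12/14 → 86), the convention that
reproduces the printed values.

The package ships the two published rice/Arabidopsis key-residue tables
transcribed verbatim in their ditto notation (`"` = reference residue,
`X/Y` = rice/Arabidopsis residues, `-` = absent).
`recomputePaperTables()` re-derives every Conserved and Similarity value
and the per-position bottom row from the residue cells and reports
agreement with the print. A handful of printed values contradict their
own printed residues; the audit *flags* them (showing print and
recomputation side by side) and never forces agreement. Two notation
quirks surfaced during transcription and are handled deliberately:

* the tables occasionally spell a residue out even when it equals the
  reference (ditto would apply); the renderer therefore keeps verbatim
  cell tokens in `printed` mode so round trips are byte-identical;
* the printed bottom row is consistent with counting ditto marks rather
  than residue equality, so several bottom-row cells mismatch an
  equality-based recount; the recount is kept (it is the stated
  definition) and the mismatches are flagged. The bottom-row denominators
  count rows carrying a profile for the respective organism.
* one Arabidopsis-only row prints a non-standard residue letter; the
  table is transcribed verbatim, and table-derived profiles accept any
  uppercase letter, while protein sequences remain restricted to the 20
  standard residues plus X.

The printed Similarity column is treated as identity-mode (equal residues
at the key positions), which reproduces the arithmetically consistent
rows; a matrix-positive mode (counting positive BLOSUM62 pairs too) is
offered as an option.

# Nomenclature

Mature mass = sum of average residue masses + one water, over the
sequence after the predicted cleavage site when a Tat cleavage or ER
leader was detected, else the full sequence (both conventions are
available; mature is the default because names refer to mature
proteins). kDa = mass/1000 rounded half away from zero.

Ortholog assignment applies three gates against a panel of named
references: global identity strictly greater than 50%, same predicted
compartment, same architecture composition string. Among passing
references the highest identity wins (ties: higher similarity, then
lexicographic id). Named candidates inherit the ortholog's suffix;
candidates without an ortholog get their kDa as suffix; flagged
trigger-factor candidates are named `<prefix>TIG`. When several
candidates share a suffix, letters a, b, c, ... are appended in
decreasing similarity to the shared ortholog (molecular-weight groups:
decreasing mean pairwise identity, ties by id). Naming is a pure function
of its inputs — permuting candidates cannot change any name. Letter
sequences extend alphabetically (aa, ab, ...) for synthetic-scale groups;
real families never need more than a few letters.

Callers must pre-select one isoform per gene (the longest); isoform
grouping is out of scope.

# Phylogeny

Family trees are built from full-length sequences: progressive multiple
alignment (pairwise p-distances → average-linkage guide tree →
profile-profile affine-gap merges with sum-of-pairs column scoring; gap
penalties scale with the residue count of the consumed column times the
rows of the gapped profile, approximating the induced sum-of-pairs cost),
then a p-distance matrix over columns gap-free in each pair, then
canonical neighbor joining. NJ is exact on additive matrices — the test
suite verifies 100% topology and branch-length recovery on random trees
of 4–8 taxa — and was chosen because the original trees come from a
NJ-based aligner pipeline. Negative branch estimates are clamped to zero
and flagged. Newick output quotes labels containing metacharacters. No
claim is made of reproducing any published tree topology: that would
require the original 56 sequences and the exact aligner parameters.
Bootstrap support and likelihood methods are out of scope.

The progressive MSA is a heuristic: the suite checks it on structured
triples (two close relatives plus one distant sequence in unfavourable
input order), where the guide tree must match or beat input-order
merging in sum-of-pairs score — not an optimality claim. For very
heterogeneous families the MSA can leave a sequence pair with no shared
gap-free columns; the p-distance matrix then errors by contract, and the
pipeline falls back to distances from individual pairwise alignments for
the tree.

# The synthetic-data generator

`generateFamily()` emulates the observed family structure so that every
stage can be validated against known ground truth without downloads:
mutated PPIase cores (hFKBP12/hCypA, or a named ancestor panel),
independent per-site substitution with separate rates at key (κ) and
non-key (ρ) positions drawn uniformly over the 19 alternatives (no rate
matrix — the simplest null that exercises the scoring), 1–3 domain copies
joined by short neutral linkers, at most one N-terminal signal (Tat with
or without cleavage, or an ER leader + retention motif), an optional
appended NLS cluster and an optional Arg/Lys-rich linker. Spacer and
hydrophobic-run lengths are drawn inside the detector defaults, so
implanted positives are detectable by construction; neutral spacers avoid
R/K, A and hydrophobic residues so they cannot fake signals. All
randomness flows from one seed, and the same seed reproduces records and
truth byte-identically.

What the generator does *not* emulate: indels, site-rate heterogeneity,
compositional bias, real linker sequences. Passing recovery tests
therefore demonstrates internal coherence of detectors and generator
under the stated conditions, not performance on real proteomes.

Default study conditions used by the validation suite and the acceptance
script: n = 200 proteins (500 for the Tat sensitivity/specificity run),
κ = ρ = 0.15 for domain-boundary recovery, 20% divergence from a
6-per-family named panel (itself at 30% divergence from the human cores)
for ortholog recovery, and 50 seeded three-clade runs (clade ancestors at
30% divergence, members at 5%) for monophyly. These sizes keep the full
suite in tens of seconds while leaving the empirical rates stable across
seeds.

One benchmark-design decision deserves its own paragraph: ortholog-name
recovery is measured at the assignment operation, giving `assignOrtholog`
the candidate's true compartment and architecture from the generator
truth. Run end to end instead, recovery is capped near 0.85 — not
because a wrong reference is ever chosen, but because chance basic
clusters (and occasionally chance RR+hydrophobic stretches) in 20%-mutated
cores flip the *detected* compartment and close the location gate. That
failure mode belongs to the signal detectors, whose sensitivity and
specificity are measured separately; conflating the two would make the
ortholog benchmark a second, noisier Tat/NLS test. The end-to-end
compartment accuracy is still computed and reported by `scoreRecovery()`.

# Numerical and degenerate-input choices

* Rounding of all printed percentages and kDa: nearest integer, half away
  from zero.
* Empty local alignments are represented with zero-length spans and score
  0; `percentIdentity`/`percentSimilarity` refuse empty alignments.
* `pDistance` requires at least one gap-free column and errors otherwise;
  guide-tree construction maps that error to distance 1 (maximally
  distant) to stay total.
* Records that fail any stage are reported with a `failed:` status row
  and an entry in `errors` — never dropped; classification of the
  remaining records proceeds.
* A protein with no domain hit gets family `IMM` for naming purposes and
  no conservation result.

# Known limitations

* The heuristics are calibrated for detectability of the generator's
  implants, not tuned against curated signal databases; no equivalence
  with TargetP/PSORT/SignalP calls is claimed.
* Chloroplast stroma vs lumen beyond the Tat rule, and mitochondrial
  targeting, are out of reach.
* The progressive MSA is a heuristic without optimality guarantees.
* Printed full-length identity/similarity percentages from external
  tools are not reproduced — their conventions and inputs are not fully
  specified; only the key-residue statistics are recomputed exactly.

# Session

```{r}
sessionInfo()
```
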