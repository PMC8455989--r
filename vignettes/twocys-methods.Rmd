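---
title: "Methods: annotating and classifying 2-Cys type III metacaspases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and classifying 2-Cys type III metacaspases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twocys)
```

## The biological problem

Metacaspases (MCs) are cysteine proteases structurally homologous to
caspases: a large catalytic **p20** domain carrying a His–Cys catalytic
dyad, and a small **p10** domain. Domain order defines the MC type; in
**type III** MCs, found in secondary-endosymbiosis algae such as
diatoms, the p10 *precedes* the p20. A subset of diatom type III MCs
additionally carries a cysteine pair — homologous to positions C202 and
C259 of the *Phaeodactylum tricornutum* metacaspase PtMCA-IIIc — that
sits close enough in the folded protein to form a reversible,
activity-enhancing disulfide. Proteins carrying this pair are the
**2-Cys** subtype. `twocys` provides the computational pipeline for
finding them in protein sequence collections, placing them on a p20
phylogeny, and quantifying the supporting biochemical readouts
(knockout guide design, redox proteomics, fluorogenic kinetics, qPCR).

## Domain detection

### p20: position-specific scoring

Public domain databases detect the p20 reliably, but a database search
is neither reproducible offline nor testable, so the package scores
candidates against a transparent PSSM built from a seed alignment
(`build_pssm()`). For column $j$ and residue $r$,

$$ f_j(r) = \frac{c_j(r) + \alpha\,b(r)}{n_j + \alpha}, \qquad
   S_j(r) = \log_2 \frac{f_j(r)}{b(r)}, $$

with $c_j$ the residue counts among ungapped rows, $n_j$ their number,
$b$ the background (uniform 0.05 by default), and $\alpha$ the
pseudocount weight (default 1). Columns with ≥ 50% gaps are dropped.
The scan is ungapped and sliding (`scan_pssm()`); `X` scores 0 in any
column so truncated transcripts are penalized, not excluded. The
default acceptance threshold is 60% of the maximum attainable profile
score — scale-free in profile width, so it transfers between seed
alignments without re-tuning. Overlapping hits keep the higher score,
ties leftmost. The His–Cys dyad is verified by reading the residues at
two configured profile columns of each hit (`find_p20()`); for real
data these columns must be set by the user, since the catalytic His of
PtMCA-IIIc has no published residue number.

The shipped seed alignment (`p20_seed_msa()`) is **synthetic** —
scaffold copies mutated at 5% per residue — because no real p20 seed
alignment is distributed with the package; `read_alignment()` imports
a real one.

### p10: three-anchor pattern search

The p10 of diatom MCs evades profile databases, and is instead located
by three short anchors: `Dx[QE]TSAD` at the start, `GGAX[ST]` in the
middle, `QxPQL` at the end. The grammar (uppercase literal, `x`/`X`
wildcard, `[...]` class) is parsed by `parse_pattern()`; a wildcard
matches any residue *including* `X`, because `X` marks unknown
residues in transcriptome-derived proteins and excluding it would
silently drop them. `find_p10()` chains the anchors: for each start
anchor (left to right), the leftmost middle anchor within `gap1`
residues, then the leftmost end anchor within `gap2`. The source
biology states the anchors but not the spacing; the defaults
`gap1 = [0, 40]`, `gap2 = [0, 60]` cover the plausible 70–120-residue
p10 span and are configurable. Leftmost-first tie-breaking makes the
search deterministic and mirrors how a manual left-to-right reading
would resolve ambiguity. The earlier two-anchor "basis" pattern set
(`[QE]TSAD` / `GAX[ST]XXXXXX[IVLA]`) is shipped as a named alternative
(`p10_patterns("basis")`), off by default in favor of the refined set.

## Classification and the 2-Cys call

`classify_mc()` is a total decision table: no p20 → `unclassified`;
p20 only → `MCP` (metacaspase-like protease); p10 entirely before the
best p20 → `type_III`; p20 before p10 → `type_I` if the inter-domain
linker is under 50 residues, else `type_II` (the type I/II distinction
is drawn pictorially in the literature, never numerically; 50 is a
package convention and configurable, and type I prodomain detection is
not attempted); overlapping domains → `unclassified` with a warning.

`call_two_cys()` maps reference positions 202 and 259 onto a query
through a global affine-gap alignment (BLOSUM62, gap open 10, extend
0.5 — conventional protein defaults) and reports `both`,
`first_only`, `second_only`, `none`, or `unmapped` when a reference
position lands on a gap. The call demands exact column homology: a
±1-column tolerance would trade precision for recall, and exactness is
the conservative default for claiming a regulatory pair. Reference
numbering is full-protein 1-based, as the positions are printed
(C202/C259/C264). The shipped `default_reference()` is a synthetic
310-residue type III protein laid out so that its pair falls exactly
at 202/259 and its catalytic Cys at 264; for real analyses a real
reference sequence goes through `reference_spec()`.

`summarize_species()` reproduces the per-species abundance view: MC
count, presence of type III, presence of 2-Cys, and the dataset-level
fraction of species with at least one 2-Cys MC.

## p20 phylogeny

`trim_p20()` cuts the annotated p20 interval from each protein.
`center_star_msa()` provides a built-in alignment (center = record
with maximal summed pairwise score; others aligned to it pairwise;
gaps merged "once a gap, always a gap") so the pipeline runs without
external aligners — imported ClustalW/MAFFT alignments are
first-class via `read_alignment()`. `distance_matrix()` offers the
uncorrected p-distance (default) and the Kimura protein correction
$-\ln(1 - p - 0.2p^2)$; which correction the original ClustalW runs
used is unknown, so both are exposed rather than guessed.

`nj_tree()` implements Saitou–Nei neighbor joining with two fully
specified details: Q-matrix ties break on the lowest taxon-index pair
(determinism), and negative branch-length estimates are clipped to
zero with the deficit moved to the sister edge so the joined pair's
distance is preserved. On additive matrices the algorithm is exact;
the test suite certifies topology and path-length recovery
(|Δ| < 1e-9) on random additive matrices and cross-checks topology
against `ape::nj`.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and maps bipartition frequencies
onto the full-data tree (not a consensus), matching how supports are
conventionally displayed. Defaults honor the study settings: 1,000
replicates, seed 111. Replicate RNG streams are split by counter
(`seed + replicate`) so results do not depend on evaluation order.
`write_newick()` emits branch lengths at fixed six decimals with
integer supports as internal node labels — directly consumable by
iTOL and round-trippable through `ape::read.tree`.

## Guide design

`enumerate_targets()` lists every 20-nt protospacer with an NGG PAM on
either strand; the blunt cut site is 3 bp 5′ of the PAM (standard
SpCas9 biology, stated nowhere in the source and therefore fixed here
as a convention). Candidates containing `N` are excluded;
for off-target *comparison*, `N` counts as a mismatch instead.
`off_target_scan()` implements the published screening rule: exact
match over the 12 PAM-proximal seed nucleotides, an NGG PAM, and at
most three mismatches over the remaining 8 nt — NAG PAMs are not
accepted and the non-seed block is exactly 8 nt. The scan is a
complete within-genome enumeration, which is stricter than the
original BLAST heuristic and subsumes it at gene scale. On-target
scoring by trained models is out of scope; externally computed scores
can be carried as an extra column. `design_excision()` intersects the
deletion interval between two cut sites with the exon model to get
deleted CDS length, flags a frameshift when that length is not a
multiple of 3, and flags catalytic-Cys loss when the codon's genomic
span is fully deleted.

## Quantitation

**Delta oxidation.** OxICAT labels reduced thiols light and originally
oxidized thiols heavy, so %oxidation = heavy/(light + heavy) × 100.
`delta_oxidation()` averages replicate oxidation degrees per cysteine
site and subtracts non-lethal from lethal means; significance is a
two-tailed unpaired Student's t-test with pooled variance (Welch
behind a flag), matching the stated statistical procedure. Raw
p-values are reported by default; Benjamini–Hochberg is optional for
large site tables. Records with zero total intensity are dropped, not
imputed. With zero variance in both groups the t statistic is
undefined; p is then 1 for a zero difference and `NA` otherwise.

**Kinetics.** `fit_calibration()` fits RFU against the six-point AMC
curve (12, 6, 3, 1.5, 0.75, 0 µM) by OLS. `compute_activity()` takes
the initial slope as the maximum windowed OLS slope with the window
start restricted to the first third of the trace, converts RFU/min to
µM/min via the calibration slope, and to specific activity as
rate × well volume (µM·L = µmol) / protein mass (defaults 200 µL and
60 ng per well). The default window is 5 points, appropriate for
traces that plateau. A variance note: the windowed-slope standard
error is $\sigma / \sqrt{\sum (t_i - \bar t)^2}$, so at noise of 2% of
the trace range a 5-point window on a 31-point/30-min trace has ~19%
slope error — no short window can certify 5% rate recovery at that
noise. The package's recovery analyses therefore quantify densely
sampled linear traces (121 points/30 min) with the full-trace window,
whose ~0.6% slope error makes the 5% bound meaningful. For saturating
real traces, choose the window long enough to cover the linear phase
and no longer.

**Relative expression** is the textbook 2^−ΔΔCt, normalizing the
target to a reference gene within sample and to a baseline sample.

## Synthetic data: what it does and does not show

Every generator is a pure function of its spec and seed (per-record
streams split by counter; byte-identical reruns; the caller's RNG
state is restored). Problem sizes used by the test suite and the
acceptance script — 500-protein proteomes, a ~50 kb genome for the
off-target oracle, 10,000 null t-tests, 100-seed kinetics recovery,
1,000 bootstrap replicates — were chosen as the smallest sizes at
which the certified properties are statistically meaningful.

- `synth_proteome()` assembles proteins from a fixed 170-residue p20
  scaffold (a typical caspase-fold large subunit) and a 75-residue p10
  anchor block, at the architecture mix requested; the 2-Cys pair is
  planted at the scaffold columns homologous to reference 202/259.
  The carrier fraction is planted at the *species* level
  (deterministic count = round(fraction × n_species)) so that
  species-level summaries are exact parameter-recovery checks — e.g.
  a 0.62 fraction over 100 species yields exactly 62% in
  `summarize_species()`. Mutations apply outside constrained columns
  (anchors, dyad, pair).
- `synth_genome()` draws background sequence with no GG/CC
  dinucleotide, so the only NGG PAM sites are the planted ones; the
  default geometry plants two guides whose cut sites sit 115 nt
  apart, spanning the catalytic Cys codon (written TGC) and the third
  intron, with a 55-nt exonic deletion (frameshift).
- `synth_ox_table()` draws intensities so that oxidation degree equals
  clip(baseline + group effect + N(0, sd), 0, 100); the default plants
  a +20.9-point shift at a C202-like site over a 35% baseline.
- `synth_kinetics()` produces linear-plus-noise traces and noise-free
  standards on the six-point curve.

What passing these tests shows: the pipeline's algorithms are correct
against independent oracles and recover planted truth under the
modeled noise. What it does not show: performance on real proteomes.
The generators plant detectable truth — they model neither indel
evolution, site-rate variation, domain divergence beyond point
mutations, nor intensity-dependent mass-spectrometry noise. Anchor
patterns are held exact in synthetic p10s, so synthetic recall does
not bound recall on diverged real p10 domains.

## Known limitations

- The p20 scan is ungapped; strongly indel-divergent p20s need an
  externally aligned seed or an external alignment import.
- Maximum-likelihood trees are out of scope; the NJ branch is the
  implemented one.
- Type I prodomains and autocleavage-site prediction are not
  attempted; reference-mapped positions can be reported when
  configured.
- `center_star_msa()` is a guide-tree-free progressive method; for
  publication-grade alignments import MAFFT/ClustalW output.
- The 2-Cys call depends on global alignment quality; for fragmentary
  queries the `unmapped` status should be treated as "no call", not
  absence.
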