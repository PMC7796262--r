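---
title: "Methods: bZIP family characterization with zipperscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bZIP family characterization with zipperscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zipperscan)
```

This vignette documents the models and procedures behind each analysis
stage, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generators do and do not emulate. It states no
empirical result beyond what the package's own tests and the acceptance
script compute.

## The bZIP signature and the heptad register

A bZIP transcription factor couples a basic DNA-binding segment to a
dimerizing leucine zipper. The basic region contains an invariant
asparagine followed seven arbitrary residues later by arginine or lysine;
`find_basic_regions()` reports every overlapping match of `N-x7-R/K`
(1-based positions; the 16-residue context ending at the R/K is attached
to each hit).

The zipper is an alpha-helical coiled coil with a seven-residue repeat.
Positions within a heptad are labelled *a*–*g*; leucine canonically
occupies *d*, and heptads are indexed L0, L1, … counting from the first
leucine in the d position after the basic region. `assign_register()`
implements that convention directly:

* **Anchor.** The first leucine strictly after the R/K takes register
  letter *d* of L0. Plant families retain members whose heptads lack
  d-leucines entirely, so when no leucine exists downstream the first
  aliphatic residue (I, V, M) anchors instead and the annotation carries a
  `weak_anchor` flag; with no candidate at all the annotation simply has
  no heptads — that outcome is data, not an error. Whether an anchor
  could ever legitimately sit *inside* the basic region is left alone: we
  anchor strictly after the R/K and flag, rather than guess.
* **Tiling and termination.** Letters *a*, *b*, *c* occupy the three
  positions before the anchor (never reaching back past the R/K), and
  heptads tile every seven residues. Tiling stops at the first
  helix-disrupting residue, at the sequence end (the final heptad may then
  be partial), or after `max_heptads` (default 10, the upper end of
  reported plant zipper lengths — zippers of three to ten or more heptads
  occur). Heptads after L0 are retained whether or not their d position
  carries leucine.
* **Disruptor set.** Proline is the only residue we treat as a disruptor
  by default. Helix-breaking is a spectrum and identification from
  sequence alone is acknowledged to be difficult; proline is the one
  universally accepted member, so the set is `{P}` and the argument
  `disruptors` accepts any extension (e.g. `c("P", "G")`).
* **Multiple hits.** When a protein has several basic-region matches,
  `annotate_family()` keeps the hit whose downstream region yields the
  most complete heptads, ties going to the left-most. Curated alignments
  sidestep this choice; an automated tool must make it, and "longest
  resulting zipper" is the least surprising rule.

## Dimerization propensity rules

The dimer interface of a parallel coiled coil has two kinds of contact.
The *g*–*e*′ electrostatic pair joins position *g* of heptad *k* to
position *e* of heptad *k*+1 **on the partner helix**; `classify_ge_pair()`
calls a pair attractive when one residue is acidic (D/E) and the other
basic (K/R), repulsive when both share a sign, and incomplete otherwise.
"Charged" means exactly {D, E, K, R}: histidine is treated as uncharged.
The index offset (*k* vs *k*+1) is the cited coiled-coil convention; since
conventions differ across the literature, `homodimer_profile()` exposes it
as `e_offset` with 1 as the documented default.

The *a*–*a*′ core contact uses a deliberately minimal rule table:
homotypic V, I, or R is favorable; N–V favours heterodimers; N–I is
destabilizing; two charged residues are destabilizing; **everything else
is neutral**. The table is the closure of the stated qualitative rules
and nothing more — we do not extrapolate energetics the source rules do
not state.

`position_frequencies()` counts residues per register letter over heptads
L0–L4 by default. That window is the one used for published composition
statistics; whether later heptads belonged in those statistics is
ambiguous in the source material, so the window is a parameter. Truncated
heptads contribute the letters they have; a `complete_only` switch
restricts to complete heptads since the original counting convention is
unstated. `X` residues are excluded from every denominator. Summary
percentages are rounded half-up for reporting (printed tables round half
up, base R rounds half to even — `ratio_from_table()` makes the same
choice for the same reason).

## Nei–Gojobori divergence

The estimator is the counting method: per-codon synonymous site fractions,
pathway-averaged difference counts, and a Jukes–Cantor multiple-hit
correction.

* `ng_sites()` enumerates, at each codon position, the three single-
  nucleotide changes; the synonymous fraction sums to the codon's
  synonymous site count `s`, with `n = 3 - s`. Changes creating a stop
  codon count as nonsynonymous. `S + N = 3 ×` codons, always.
* `ng_pair_counts()` averages synonymous/nonsynonymous step counts over
  every ordering of the differing positions. The original method leaves
  stop-traversing pathways to the implementer: we **skip** them and
  average over the remainder, falling back to all pathways when every
  ordering hits a stop; the choice is switchable (`skip_stop_paths`).
  Pathways are weighted uniformly (no transition/transversion weighting —
  that is the modified method and out of scope).
* `ng_estimate()` computes `S` as the mean of the two sequences' site
  sums over non-gap columns, applies the correction
  `K = -3/4 ln(1 - 4p/3)`, and reports `Ka/Ks` only when both corrections
  are defined and `Ks > 0`; otherwise the estimate carries `jc_saturated`
  or `ks_zero` flags and `classify_selection()` returns `undetermined`.
  The 61×61 single-column tables are computed once and cached.
* `align_codons()` trims a terminal stop codon (annotations differ on
  whether they include it; the decision is recorded here), rejects
  internal stops, translates, aligns the proteins globally with BLOSUM62
  and a linear gap penalty of 8 per residue, and threads codons back under
  the protein alignment. The alignment scores are configuration, not
  science: simulated acceptance data contains no indels, so they do not
  affect the reported numbers.
* `classify_duplication()` calls a pair tandem when both genes share a
  chromosome and either at most `max_intervening = 5` annotated genes lie
  between them or the genomic gap is at most `max_distance = 100` kb.
  These thresholds are pragmatic stand-ins for a full collinearity
  analysis (which is out of scope — pairs are inputs here); both are
  exposed as arguments.

## Gene structure

Intron phase is a coding concept: phase 0 between codons, 1 after the
first base, 2 after the second. `intron_phases()` therefore works on CDS
spans only, ordered 5′→3′ in transcript orientation (reversed for minus
strand), and computes each phase as the cumulative coding length mod 3.
Terminal exons receive a virtual phase 0 at the CDS start and end so that
they get flanking-pair labels like internal exons — that is how
`(0,0)`-style labels for terminal exons arise. A CDS whose total length
is not divisible by 3 is processed with a warning and a `partial` flag
rather than rejected: genome annotations contain partial models and
silent failure would be worse.

## Promoters

`extract_promoter()` returns the 2000 bp (configurable) immediately 5′ of
the TSS in transcript orientation, reverse-complemented for minus-strand
genes and clipped with a warning at chromosome edges. `scan_motifs()`
counts all matches at step 1 (overlaps included — the counting convention
in published CRE grids is unstated, and overlap counting is the
conservative complete choice), adds reverse-complement matches when
`both_strands`, and counts reverse-complement-palindromic patterns on one
strand only so a palindromic site is never double-counted. The bundled
motif table ships the three canonical ACGT-core boxes (A-box `TACGTA`,
C-box `GACGTC`, G-box `CACGTG`) plus common plant elements whose IUPAC
strings are this package's transcription of the public PlantCARE
consensus — explicitly editable configuration rather than ground truth,
because authoritative pattern strings for the remaining named elements
cannot be recovered from survey figures alone.

## Protein properties

Molecular weight is the sum of average-isotope residue masses plus one
water (reported in kDa); average rather than monoisotopic masses match
conventional whole-protein reporting. The isoelectric point solves
`Q(pH) = 0` where `Q` sums Henderson–Hasselbalch fractional charges of
the termini and the K, R, H, D, E, C, Y side chains under the EMBOSS pKa
set (N-terminus 8.6, C-terminus 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8,
R 12.5, Y 10.1). `Q` is strictly decreasing in pH, so bisection on
`[0, 14]` (tolerance 10⁻³ pH units) always converges; for a side-chain-
free peptide the root has the closed form `(pKa_N + pKa_C)/2`, which the
tests use as an oracle alongside a fine grid scan. The pKa table is a
named constant, swappable for other sets.

## Expression summarization

`hcluster()` delegates to `stats::hclust` with Euclidean distance and
complete linkage — the combination whose merge heights are monotone — and
the tests verify it against a brute-force agglomerative oracle.
`de_filter()` applies the inclusive thresholds `log2FC ≥ 1.2` (or
`≤ -1.2`) and `padj ≤ 0.05`; boundaries pass, by the stated convention.
Expression bands name `< 2` low, `4–6` moderate and `6–10` high; the
`2–4` gap between the named bands is mapped to an explicit
`moderate_low` band rather than silently absorbed, and the shared
endpoint at exactly 6.0 is assigned to `moderate` as a configuration
choice (`default_expression_bands()` makes all of this editable).
Missing expression values fail fast by default with an optional row-drop
policy. `build_report()` writes deterministic TSV/JSON stage outputs so
reruns are byte-identical.

## The synthetic-data generators

Every generator takes an explicit seed, isolates its randomness from the
global RNG, and returns machine-readable ground truth sufficient to score
the corresponding analysis stage.

* **Zippers.** `gen_zipper_set()` plants one basic-region motif and one
  zipper per protein. Signature positions draw with the documented
  default probabilities — leucine at *d* 0.65, charged at *g* 0.43, at
  *e* 0.28, the {N, I, V, M} set at *a* 0.30, the composition profile
  reported for plant bZIP families — and all other zipper positions use a
  neutral background alphabet excluding the aliphatics, the charged set,
  N and P. That exclusion is what makes planted frequencies exact and
  recovery tests free of accidental motif hits; it also means the
  generator does **not** emulate the full residue diversity of real
  zippers, only their register structure. Two guarantees keep the planted
  register identifiable: the d-position draws are permuted so a leucine
  (if any) appears at L0 first — preserving the aggregate binomial
  composition exactly — and the flanks exclude residues (N, L, K, R) that
  could fabricate a second motif or capture the anchor. Heptad counts
  can be a range (e.g. `3:10`), sampled per protein.
* **Codon pairs.** `gen_codon_pair()` evolves two lineages from a uniform
  sense-codon ancestor by proposal/acceptance: uniform single-nucleotide
  proposals (Poisson count with mean `n_codons × expected_subs_per_codon`
  per lineage, default intensity 0.15), stop-creating candidates
  rejected, nonsynonymous candidates accepted with probability
  `min(1, ω)` and synonymous with `min(1, 1/ω)`. This is deliberately a
  proposal/acceptance scheme rather than a full rate-matrix simulator:
  the target is estimator parameter recovery with exact realized-event
  ground truth, not phylogenetic realism. Two known, accepted departures
  from the estimator's idealization: rejected stop proposals slightly
  reduce the realized nonsynonymous rate relative to the estimator's site
  definition (stops count as nonsynonymous sites there), and multiple
  hits accumulate at higher intensities — both effects are small at the
  default intensity and are covered by the recovery tolerance.
* **Gene models.** `gen_gene_models()` realizes a chain of internal-exon
  phase pairs as exon lengths of the right residue classes mod 3, embeds
  them in a random chromosome, and emits GFF3 + FASTA text alongside the
  planted profile. UTRs are not emulated (phases are a CDS concept).
* **Promoters.** `gen_promoters()` plants non-overlapping realized motif
  instances into a GC-controlled background and then resamples background
  bases until no listed motif matches anywhere but its planted sites, so
  a scanner recovers the planted counts exactly. Motif sets where one
  listed pattern can match inside another's planted site (ABRE `ACGTG`
  inside a G-box `CACGTG`) are detected and refused rather than silently
  miscounted — real promoter elements genuinely nest, and for nested sets
  only joint counts are meaningful.
* **Expression.** `gen_expression()` adds a block effect of `separation`
  log2 units over a baseline with Gaussian noise — enough structure to
  validate clustering recovery, with no attempt to emulate count noise,
  normalization artefacts, or correlated samples.

Because the generators emulate structure, not biology, passing recovery
tests demonstrates the *algorithms* are correct, not that real genomes
will be as clean: real proteins contain spurious motif-like substrings,
real promoters nest elements, and real expression matrices violate the
independence assumptions. The analysis functions make no assumption the
generators satisfy by construction except where flagged above.

## Problem sizes and tolerances

The test suite and acceptance script use planted families of 200–500
proteins (about 1000 heptads for composition checks, inside a 99%
binomial band), 100-replicate batches of 2000-codon pairs per selection
intensity for dN/dS recovery (15% relative tolerance on the mean),
exhaustive 61×61 sense-codon checks against an independent pathway
enumerator (10⁻¹² tolerance), 100 planted promoters and gene models for
exact recovery, and brute-force clustering oracles up to n = 6 over 100
trials. These sizes give stable statistics at interactive runtimes; all
are parameters, not limits.

One bundled-data caveat: the shipped paralog divergence table prints Ka,
Ks, and Ka/Ks each rounded to two decimals. Recomputing the ratio from
the printed Ka and Ks reproduces the printed ratio for 16 of the 22 rows;
the remaining 6 differ by exactly 0.01 because the original ratios were
evidently computed from unrounded distances before all three columns were
rounded for print. The table is transcribed as printed, and
`ratio_from_table()` documents the half-up rounding convention.
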