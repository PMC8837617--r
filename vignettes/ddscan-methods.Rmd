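---
title: "ddscan: models and methods for sort-seq docking-domain screens"
author: "ddscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ddscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddscan)
```

## The experiment this package models

A sort-seq screen couples each member of a combinatorial protein library to
a bead, assays the activity of every bead in one pot, sorts beads into a
small number of fluorescence gates (here low / medium / high), and
deep-sequences the variants recovered from each gate. The analysis problem
is to go from three files of merged amplicon reads back to biology: which
variants are active, which residues and residue *pairs* drive activity, and
how the active variants are organised in sequence space.

`ddscan` models a six-position randomisation of the MKK1 docking domain
(D-domain), the short motif through which MKK1 binds the docking groove of
ERK2. Positions 6, 9, 11 and 13 are substitutions on the degenerate
reference `MPKKKXTPXQXNXAPDG`; 7a and 8a are optional insertions after
reference residues 7 and 8, written `-` when absent. A genotype is the
six-symbol string over these positions in order, e.g. the wild type
`P--ILP`. With the default 12-residue alphabet the library has
`12^4 * 13 * 2 = 539136` members, so ideal (balanced-library) residue
frequencies are 1/12, 1/13 and 1/2 per position class.

## Variant recovery from reads

Reads are consumed *merged* (single sequence per fragment); merging of
paired ends is a solved upstream problem and out of scope.

1. **Anchoring.** The constant flanks are located by exact match. Reads with
   a missing flank (`no-anchor`), a flank matching twice (`ambiguous`),
   non-ACGTN characters (`bad-char`), or an insert length that is not one of
   51/54/57 nt (`bad-length`) are rejected with the reason recorded —
   nothing is silently dropped.
2. **Translation.** Standard genetic code; a codon containing N or an
   in-frame stop rejects the read.
3. **Alignment.** Because the insertions sit two residues apart in a short,
   highly randomised region, DNA-level alignment is uninformative; proteins
   are aligned to the degenerate reference instead. The scheme scores
   identical residues +5, any residue opposite a randomised `X` +1 (match to
   a randomised position carries less evidence than a constant-region
   match), other substitutions −1, and a gap of $k$ columns
   $3 + 5k$. The optimiser is a Gotoh affine-gap Needleman–Wunsch written
   for this scheme. End gaps are penalised like internal ones because query
   and reference are both complete domains. The wild-type peptide scores
   $13\cdot5 + 4\cdot1 = 69$.
4. **Genotype calling.** Residues aligned to the four `X` columns fill
   positions 6/9/11/13. Insertion columns are assigned by reference
   registry: a run inserted after residue 7 fills 7a, after residue 8 fills
   8a, and a two-residue run fills both in order. Non-X mismatches,
   deletions, out-of-registry insertions and residues outside the design
   are categorised rejections.

### Numerical choices in the aligner

* **Tie-breaking.** The traceback prefers diagonal over gap-in-reference
  over gap-in-query at every cell. Ties never change the score, only the
  reported alignment.
* **Insertion left-normalisation.** When an inserted residue equals the
  query residue matched immediately to its left, the two placements score
  identically; before calling, insertions are slid left through identical
  residues (the same normalisation used for indels in variant callers).
  This makes score-tied placements call deterministically and correctly:
  e.g. a 7a proline next to the constant proline at reference position 8,
  or an 8a alanine next to an alanine at position 9. With this
  normalisation the encode→sequence→extract→align→call round trip recovers
  *every* genotype of an exhaustive reduced design, including all insertion
  edge cases; that property is asserted in the tests.
* **Memoisation.** Alignment is memoised on unique protein sequences, which
  makes the per-read cost of the pure-R dynamic program negligible.
* **Verification.** The aligner is checked against (a) exhaustive
  enumeration of all global alignment paths at short lengths, scoring gap
  runs straight from the cost definition, and (b) an independent
  implementation (`Biostrings::pairwiseAlignment`) configured with an
  identical substitution matrix and the same gap-cost convention.

## Counting, cutoffs and the active set

Counts live in a `GateCountTable` (a `SummarizedExperiment` with genotypes
as rows and the three gates as columns). Per-gate observation cutoffs
default to ≥3 (low), ≥5 (medium) and ≥10 (high) supporting reads; the
looser documented alternative of ≥3 for the medium gate is available by
argument. The active-set filter keeps genotypes with at least 51 high-gate
reads — the prevalence of the wild type in the high gate, i.e. "at least as
active as wild type" — *and*, under the default rule, a gate-normalised
high-gate frequency strictly greater than in each lower gate. The
enrichment clause is deliberately pluggable (`rule = "none"` keeps the
floor only): the literature formulates this ratio in several near-equivalent
ways, and the strict-inequality reads-per-gate-total version used here is a
documented default, not a claim about any one source's exact rule.

Position-wise diversity is the normalised Shannon entropy
$H = -\sum_a p_a \log p_a / \log K$ over the $K$ allowed residues, so 1
means perfectly balanced and 0 fixed; both unweighted (per unique variant)
and read-weighted compositions are supported.

## Enrichment and epistasis statistics

All statistics run over the unweighted unique-variant composition of the
active set by default (read weighting is available for diversity
summaries). With $f^{obs}$ observed and $f^{id}$ ideal frequencies:

* single-position enrichment: $f_a^{obs} / f_a^{id}$;
* joint enrichment: $f_{a,b}^{obs} / (f_a^{id} f_b^{id}$);
* epistatic enrichment: $f_{a,b}^{obs} / (f_a^{obs} f_b^{obs})$, which is 1
  exactly when the two positions are independent. Cells with a zero
  marginal are *undefined* and reported as `NA`, never 0 or ∞, so that
  downstream log-scale displays stay well defined.

The chi-squared statistic tests the observed joint counts against the
independence expectation $n\, f_a^{obs} f_b^{obs}$ — the same null as the
epistatic ratio — with $(K_a-1)(K_b-1)$ degrees of freedom. Residues
unobserved at a position are dropped before testing, so no expected cell is
zero. `stats::chisq.test(correct = FALSE)` supplies the machinery;
Bonferroni correction multiplies by the number of pairs tested (15 for six
positions, including all pairs involving 8a). Family-wise type-I error
under the independence null is verified by 200 null simulations in the
acceptance tests.

Conditional profiles divide residue frequencies in a subset (e.g. variants
carrying Φ = Leu/Ile at both members of an adjacent position pair, or
carrying anything but Φ there) by the frequencies in the full active set,
exposing how a fixed motif re-shapes preferences elsewhere.

## The sequence similarity network

Nodes are active genotypes; edges join pairs at Hamming distance exactly 1,
with an absent insertion treated as an ordinary symbol. The graph is built
by hashing every genotype under six per-position wildcard keys — two
genotypes share a key exactly when they agree everywhere outside one
position — which is exact and avoids the quadratic scan; equality with the
all-pairs edge set is asserted on random 500-node sets.

Partitioning uses Leiden (modularity objective; Louvain as fallback) from
`igraph`. Two numerical choices matter:

* **Seeded restarts.** Community detection finds local optima. A single run
  occasionally returns a slightly lower-modularity partition with
  qualitatively different structure, so `partitionSSN()` runs a few seeded
  restarts (default 5) and keeps the best-modularity labels; the whole
  procedure stays deterministic given its seed.
* **Independent modularity.** The reported Q is recomputed directly from
  the labels and edges ($Q = \sum_c [e_c/m - (d_c/2m)^2]$) and must agree
  with the community-detection output to $10^{-12}$.

Centrality summaries (degree, betweenness, closeness, eigenvector; the
latter two per connected component) support the question of whether the
network has hub variants, and per-cluster content is exported as position
frequency matrices and FASTA (fixed-length genotype records with `-` for an
absent insertion, or variable-length full peptides).

## The synthetic data generator

The generator exists so that the full pipeline — including its statistical
conclusions — can be validated against a known truth. It emulates:

* **Activity.** `FitnessLandscape`: additive per-position residue effects,
  plus a bonus when two Φ residues occupy adjacent randomised positions
  (adjacency chain 6–7a–9–11–13; an absent 7a makes 6 and 9 adjacent), plus
  optional explicit pairwise terms and a `customTerm` hook for higher-order
  structure. The default landscape gives each Φ residue +1 and the motif a
  bonus of 4 (activity units are arbitrary; only their ratio to the gate
  thresholds and noise matters).
* **Sorting.** Each variant contributes `beadsPerVariant` beads (default
  7, the screen's oversampling); each bead receives Gaussian activity noise
  (sd 0.5) and a nominal gate from thresholds (1.5, 3.5), then
  misassignment: a nominally high bead is demoted with probability 0.5
  (the screen's estimated per-bead false-negative rate; demotion goes to
  low or medium equiprobably) and a nominally lower bead is promoted to
  high with probability 0.08. The false-positive default takes the
  screen's reported ~8% figure as the per-bead misassignment rate; under
  the alternative gate-composition reading (8% of *high-gate beads* being
  false) the per-bead rate would be ~0.002, and both are a single argument
  away. With the defaults, roughly 9.7% of library variants are planted
  actives and the called active set is ~16% of variants — the leakage is
  visible, as in a real screen, and the active-set filter's
  sensitivity/specificity against truth is reported rather than assumed.
* **Sequencing.** Poisson reads per bead (mean 30), uniform per-base
  substitution errors (default 0 — error profiles are conventional, not
  calibrated to any instrument), Sanger-encoded FASTQ with constant
  quality, plus a truth table and a config echo. Identical seed and config
  give byte-identical output.
* **The register shift.** `twoRegisterLandscape()` plants *different*
  anchoring motifs depending on the 8a insertion — (6,7a) with the
  insertion, (11,13) without. This mirrors the biological reading of the
  8a insertion as a registry shift that changes which positions reach the
  binding pockets. It matters for validation: under a single shared motif,
  modularity-optimal partitions of the Hamming graph keep anchor classes
  together *across* registers, and no clean 8a split exists to recover;
  with two registers the split is exact, and the packaged experiment
  recovers clusters of pure register membership with modularity ≈ 0.75.

### What the generator does and does not show

Selection in the generator is a hard threshold plus bead-level noise and
categorical misassignment. That reproduces the qualitative signatures of
threshold selection on an epistatic landscape: strong joint enrichment of
Φ,Φ cells, epistatic ratios above 1 at planted adjacent pairs (driven by
the interaction plus uniform false-positive leakage), near-1 ratios at
non-interacting pairs, and collider-induced mild negative epistasis among
individually beneficial residues. It does not model PCR amplification bias,
read-quality-dependent errors, droplet co-occupancy, or expression-level
variation between beads; passing tests therefore validate the *analysis*,
and say nothing about those upstream artefacts in real data.

## Problem sizes

The test suite and acceptance script run everything at desk scale, chosen
so the full battery completes in a few minutes on one CPU: exhaustive
round trips on 648–2560-genotype reduced designs, planted-synergy recovery
on 10,000–20,000-variant simulated screens (~3,100 active variants), 200
null simulations of 1,000 variants for the chi-squared calibration, 500-node
SSN oracles, and an 18,144-genotype two-register experiment (~1,000 active
nodes). All stochastic steps are driven by explicit seeds.

## Known limitations

* The exact 12-residue alphabet of the emulated library is configurable
  because the canonical set is design-specific; all defaults are stated in
  `defaultLibraryDesign()`.
* A lone inserted alanine between reference residues 7 and 9 can be
  genuinely ambiguous between 7a and 8a when its sequence context is
  symmetric; the registry rule plus left-normalisation resolves every case
  that is decidable from sequence, and the exhaustive round-trip test
  documents the behaviour.
* The enrichment clause of the active-set filter and the chi-squared
  pooling of unobserved residues are documented defaults; both are
  parameterised where the field's formulations differ.
* Quality scores are carried but ignored; calling is sequence-only.
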