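---
title: "Methods: disulfide stereochemistry and the QueF census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disulfide stereochemistry and the QueF census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(queftools)
```

This vignette records how the package computes what it computes, which
knobs exist and why their defaults are what they are, what the
synthetic generators do and do not emulate, and where the design was
genuinely open.

## 1. Disulfide stereochemistry

### Model

A disulfide bridge is described by the five torsions spanning it:
χ₁ = N–Cα–Cβ–Sγ and χ₂ = Cα–Cβ–Sγ–Sγ′ on the unprimed half-cystine,
χ₃ = Cβ–Sγ–Sγ′–Cβ′ across the bond, and the primed mirrors χ₂′, χ₁′ on
the second residue. Torsions follow the right-handed (IUPAC) sign
convention and live in (−180°, 180°]; exactly −180° is normalized to
+180° so every torsion has one representation.

Two derived quantities summarize the bridge:

* **Configuration class.** Handedness comes from sign(χ₃) (− → LH,
  + → RH); the shape from how many of χ₂, χ₂′ share χ₃'s sign (both →
  Spiral, exactly one → Hook, neither → Staple); a prefix from the
  (χ₁, χ₁′) signs. Hooks are asymmetric under the residue swap, so
  their mixed prefixes stay ordered (−/+ vs +/−); Spiral and Staple are
  symmetric and collapse both mixed prefixes into −/+. That yields
  2 × (3 + 4 + 3) = 20 classes, and the package's tests enumerate all
  32 sign patterns to confirm exactly 20 distinct names. The
  classification literature anchors one case used throughout:
  (−,−,−,+,−) → −LHHook, the geometry characteristic of regulatory/
  allosteric disulfides. Exotic patterns beyond the anchored and
  rule-forced cases should be cross-checked against the classification
  literature before the names are relied on.

* **Dihedral strain energy**, the five-term cosine potential
  E = 8.37(1+cos 3χ₁) + 8.37(1+cos 3χ₁′) + 4.18(1+cos 3χ₂) +
  4.18(1+cos 3χ₂′) + 14.64(1+cos 2χ₃) + 2.51(1+cos 3χ₃) kJ/mol.
  It is non-negative, bounded by 84.5 kJ/mol (all terms at their
  maxima), 120°-periodic in the four threefold angles, and symmetric
  under the primed/unprimed swap. It estimates stored torsional strain
  only — no bond-stretch, angle-bend or nonbonded terms — which is the
  convention in classifying allosteric disulfides.

### Detection and ordering

Bridges are detected purely from coordinates: every pair of CYS
residues whose Sγ–Sγ′ distance is at most the cutoff is a candidate,
and candidates are accepted greedily by ascending distance with each Sγ
used at most once. The default cutoff of **2.30 Å** covers real S–S
bonds (2.0–2.1 Å) with margin while staying well below the ~3.5 Å of
adjacent free thiols; it is configurable via `geometry_config()`.
SSBOND header records are parsed but only kept as advisory metadata —
detection is always recomputed. Within a pair, the residue with the
lower (chain, residue number) is the unprimed half, so reported angles
are invariant to input order.

### Numerical choices and degenerate inputs

* Torsions are computed with the atan2 cross-product formula, which is
  stable near 0° and 180°; coincident or collinear points raise a
  geometry error rather than returning NaN.
* An angle whose magnitude falls below the ambiguity threshold
  (default **0.5°**) has a crystallographically unreliable sign; the
  best class is still reported but the record is flagged `ambiguous`.
* PDB parsing keeps the highest-occupancy altloc (ties: alphabetically
  first tag) so the dihedral math always sees one conformer; only the
  first MODEL of multi-model files is read (with a warning); HETATM
  cysteines are included so modified residues are not silently missed;
  author numbering is preserved.
* PDB coordinates carry three decimals. Writing and re-reading a
  bridge therefore perturbs torsions by up to ~0.05° and energies by a
  few hundredths of a kJ/mol; tests that route through files use a
  0.05 kJ/mol band for this reason, while in-memory paths are exact to
  better than 1e-6°.

## 2. The coordinate generator

`build_disulfide_coords()` places the eight-atom chain
N→Cα→Cβ→Sγ→Sγ′→Cβ′→Cα′→N′ by sequential internal-to-Cartesian (NeRF)
construction: the first three atoms seed a canonical frame (origin,
x-axis, xy-plane) and each subsequent atom is placed from the previous
three via (bond, bend angle, torsion). The torsions consumed are
exactly χ₁, χ₂, χ₃, χ₂′, χ₁′ in that order, so the generator is an
exact inverse of the analyzer — the package's core oracle. Default
internal geometry is standard cystine stereochemistry (N–Cα 1.46 Å,
Cα–Cβ 1.53 Å, Cβ–Sγ 1.81 Å; N–Cα–Cβ 110.5°, Cα–Cβ–Sγ 114.0°,
Cβ–Sγ–Sγ′ 104.0°; S–S 2.04 Å), all overridable. The tests drive 1000
uniformly random torsion quintuples through build→measure and observe
recovery within 1e-6° (measured ~1e-13°), plus invariance of all
torsions under random rigid motions to 1e-9°.

`write_disulfide_pdb()` emits one chain per bridge with residues
numbered 55 and 99 (mnemonic for the catalytic/backdoor pair), each
bridge rigid-body randomized on a 30 Å grid from a caller seed, so the
same seed yields a byte-identical file. What the generator does *not*
emulate: full protein context (no backbone beyond N, no neighboring
side chains), thermal noise, or alternate conformers — passing tests
show the geometry engine is correct, not that detection thresholds are
tuned for crowded real structures.

## 3. The QueF census

### Procedure

Each sequence is processed independently:

1. **Modularity** by length: below 200 residues → unimodular, 200 and
   above → bimodular. The subfamily descriptions leave length exactly
   200 unassigned; it is classed bimodular here (ties favor the longer
   architecture) so the rule is total.
2. **Landmark transfer.** The query is globally aligned (Needleman–
   Wunsch, affine gaps, BLOSUM62, gap open 10 / extend 0.5) against the
   subfamily reference, and the reference landmarks — catalytic Cys
   (55/194), Asp (62/201), Glu (97/234), motif-Glu (78/94), backdoor
   Cys (99/236), alternative Cys (53, unimodular only) — are read off
   at their alignment columns. A landmark under a gap maps to NA.
   Pairwise alignment replaces a one-shot multiple alignment
   deliberately: it is deterministic, incremental (adding a sequence
   cannot change earlier calls), and testable per sequence.
3. **Family gate.** The sequence is QueF iff the mapped catalytic-Cys
   position holds C, the Asp position D, the Glu position E, and the
   QueF motif E(S/L)K(S/A)hK(L/Y)(Y/F/W) is present covering the
   mapped motif-Glu. Every failed check is named in `failure_reasons`.
   The hydrophobic set for *h* is not fixed by the motif's published
   form; the default {A, V, L, I, M, F, W, Y, C} is configurable. X
   never matches. With several motif hits the leftmost wins (all hits
   are available verbosely).
4. **Backdoor status.** `primary_cys` if the mapped backdoor position
   holds C; otherwise, for unimodular sequences, `alternative_cys` if
   the mapped position-53 holds C; otherwise `none`. The alternative
   check is a sequence-position proxy for the spatial-proximity
   inspection one would do on a 3D homology model — a deliberate
   simplification, since homology modelling is out of this package's
   scope.
5. **Aggregation** with per-subfamily QueF counts as denominators;
   percentages are NA (never 0/0) when a subfamily is empty.

`split_bimodular()` separates the tandem modules for downstream
phylogenetics: the two best non-overlapping local alignments of the
unimodular reference against the query locate the modules, and the
split point is the midpoint between the first span's end and the
second's start (a fixed boundary can be supplied instead). The
concatenation of the two parts always equals the input; on synthetic
bimodular sequences the found boundary lands near the true junction at
140, upstream of the catalytic and backdoor cysteines and downstream
of the motif.

### Synthetic references and the sequence generator

The real subfamily anchor sequences are not shipped; users supply their
own via `reference_spec()` (validated so each landmark actually holds
its expected residue). For offline tests the package carries frozen
*synthetic* references: a random 140-residue core with landmarks
planted at the canonical positions, extended to 160 residues for the
unimodular reference; the bimodular reference concatenates two
independently mutated (35%) copies of the same core — motif planted in
the N-module, catalytic/Asp/Glu/backdoor landmarks in the C-module —
mirroring the tandem-duplication origin of the bimodular subfamily and
giving the module splitter genuine homology signal.

`generate_quef_like()` derives a query from the reference by
substitution-only mutation (default rate 0.2) outside the protected
landmark/motif positions, plus tail trimming/extension to the target
length (unimodular 140–199, bimodular 240–320). Landmark positions
therefore stay at the reference numbering — the generator's ground
truth is exact — while the 20% divergence and length variation still
exercise non-trivial alignment. The background alphabet excludes C and
E so backdoor state and motif presence are fully controlled by the
feature switches. Category counts in `generate_sequence_set()` are
planted exactly via largest-remainder rounding (not Bernoulli draws),
so census recovery is exact rather than statistical: 200 unimodular
sequences at fractions (0.61, 0.22, 0.17) give exactly 122/44/34 and a
census of exactly 61.0% / 83.0% / 100.0%. The default composition
mirrors the conservation pattern observed in the family.

What the sequence generator does not emulate: realistic phylogenetic
correlation, insertions inside domains, compositional bias, or
partial/fragment sequences. Passing census tests therefore demonstrate
that gating, mapping and tallying are correct on sequences whose
homology the aligner can resolve — not that the gate's
sensitivity/specificity tradeoff is calibrated for a real database
snapshot, which depends on the reference sequences and the 2016-era
database state and is outside desk-scale reproduction.

## 4. Problem sizes

The test suite runs 1000 build→measure round trips, 50 rigid-motion
replicates, 200 energy-property draws, and censuses of up to 260
sequences; the full suite completes in well under a minute on one CPU.
The acceptance script routes the five published torsion quintuples
through build→measure→energy in memory.

## 5. Known limitations

* The strain potential ranks torsional strain only; it is not a
  thermodynamic bond-breaking predictor, and no redox potentials are
  estimated.
* Class names outside the anchored −LHHook case and the rule-forced
  neighbours follow the stated sign rules; they have not been validated
  case-by-case against the original taxonomy tables.
* mmCIF input, symmetry expansion and biological assemblies are not
  supported; the PDB dialect is the contract.
* The census maps positions through one pairwise alignment per
  sequence; deep-diverged family members that a profile/MSA approach
  would recover may fail the gate here.
* Which author chains of a deposited structure correspond to which
  published subunit labels is not guessed; per-chain results are keyed
  by chain ID and the mapping is left to the user.
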