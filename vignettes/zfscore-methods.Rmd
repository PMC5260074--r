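---
title: "Scoring zinc finger-DNA specificity with zfscore: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring zinc finger-DNA specificity with zfscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfscore)
```

# The model

zfscore ranks candidate recognition helices for Cys2His2 zinc fingers by
the interfacial hydrogen-bond energy (IHBE) of the threaded protein-DNA
complex. The model rests on three assumptions:

1. **Specificity is carried by hydrogen bonds at the interface.** Only
   hydrogen bonds between an amino-acid atom and a nucleotide atom
   contribute; van der Waals, electrostatic, hydrophobic and
   water-mediated terms are deliberately excluded. Donors and acceptors
   are restricted to N, O and S atoms of side chains and base edges;
   every atom pair containing a carbon is discarded, and main-chain
   protein N/O and DNA sugar-phosphate oxygens are classified but not
   scored unless `includeBackbone = TRUE`.
2. **The backbone is rigid.** Mutating a helix position replaces side-
   chain atoms only; N, CA, C and O coordinates are carried over
   unchanged, and the DNA is not deformed. This makes scoring fast and
   deterministic at the cost of ignoring induced fit (see Limitations).
3. **Binding is either modular or synergistic.** Modular scoring treats
   each finger independently on its own 9-bp target and sums finger
   energies for a 9-bp prediction; synergistic scoring applies one helix
   to all three fingers of a 27-bp repeated-triplet target and scores the
   whole complex at once. The synergistic search applies the *same* helix
   to all fingers, which collapses the 448^3 independent-finger space to
   448 evaluations per target; an independent-per-finger search is out of
   scope.

Each detected bond contributes a 10-12 potential modulated by bond
linearity,

$$\Delta G_{hb} = \epsilon_{ij}\left[3\left(\frac{d'_{ij}}{d_{ij}}\right)^{8} -
4\left(\frac{d'_{ij}}{d_{ij}}\right)^{6}\right]\cos^4\theta,$$

which equals exactly $-\epsilon$ at $d = d'$, $\theta = 0$ and vanishes
at $\theta = 90^\circ$. Signed energies are summed per complex; the
ranking score is the absolute value, and reports carry both because both
conventions are common in the literature.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| $\epsilon$ (N-N, N-O, O-O) | 2.0, 2.8, 4.0 | kcal/mol | class well depths |
| $d'$ (N-N, N-O, O-O) | 3.2, 3.0, 2.8 | Å | class optimum lengths |
| `cutoff` | 3.5 | Å | heavy-atom pair screen (350 pm) |
| `thetaMax` | 90 | degrees | reject anti-aligned donors |
| `sulfurAs` | `"O"` | — | class sulfur maps to |
| `twist`, `rise` | 36, 3.38 | deg, Å | B-DNA step geometry |
| `clashRadius` | 2.5 | Å | rotamer clash counting |
| `approachDistance` | 6.5 | Å | helix placement in the synthetic template |

Notes on the open choices these encode:

* **θ definition.** The scoring formula needs an angle, but hydrogens
  are absent from heavy-atom models. zfscore defines θ as the deviation
  of D–H···A from linearity after *idealized* hydrogen placement:
  sp2 donors with two ring neighbours get a single in-plane H on the
  external bisector; sp2 amines get two in-plane H at ±120° from their
  heavy neighbour; rotationally free donors (hydroxyl, thiol, lysine
  ammonium) are oriented toward the acceptor, θ = 0 — the
  energy-maximizing, permissive convention. Donors whose geometric
  context is missing fall back to θ = 0. `hMode = "strict"` instead
  requires explicit hydrogens and rejects donors without them.
* **θ > 90° is rejected, not scored.** cos⁴ is positive again beyond
  90°, which would reward anti-aligned geometry; such pairs are treated
  as non-bonds.
* **Sulfur.** S atoms are legal donors/acceptors but the parameter table
  has no S row; they borrow the O row by default (`sulfurAs`), a
  provisional mapping — S-mediated bonds are rare at zinc-finger
  interfaces.
* **Both-way pairs.** When both atoms could donate (e.g. Ser OG facing a
  base donor), both directions are evaluated and the more favorable one
  is kept, once.
* **Pool identities.** The restricted consensus pools ship as an
  editable default whose *sizes* define the design space: 7 residues at
  −1, 7 at +3 (8 with glutamate for the synergistic run), 8 at +6, or
  all 20 everywhere. The specific letters are provisional defaults drawn
  from the phage-display positional-preference literature and can be
  replaced from YAML (`poolFromConfig`).
* **Scaffold and numbering.** Non-key helix positions default to the
  S/G/L/T scaffold (the ?SG?LT? pattern of consensus designs). Helix
  position p maps to residue `helix_start + p − 1` for p ≥ 1 and
  `helix_start − 1` for p = −1 (there is no position 0); the shipped map
  uses the Zif-268 template numbering (starts 19/47/75). Finger slots
  are numbered 5'→3' along the primary strand and templates are used
  exactly as printed; the protein-order question (F1–F3 vs sub-site
  order) is deliberately left to the position map.

# The DNA and protein builders

`buildBDNA` generates a straight idealized B-form duplex: base heavy
atoms come from planar ring geometry (regular 6-rings, fused regular
5-rings, standard exocyclic bond lengths), Watson-Crick partners are
placed with the central purine N1 / pyrimidine N3 bond at 2.90 Å (the
flanking donor/acceptor contacts then fall near 3.0 Å), and successive
pairs are related by the twist/rise step. A fixed idealized
sugar-phosphate template hangs off each glycosidic frame, on opposite
sides of the base plane for the two strands so the backbones run
antiparallel. The builder is *not* a crystallographic fiber model:
backbone torsions are not continuous between residues and grooves are
only approximate. Only the base-edge geometry matters for scoring, and
that is what the invariant tests pin down (sequence recovery, pairing
distances, exact twist/rise round-trip, rigid-motion invariance).

`buildPeptide` constructs α-helical backbones at ideal dihedrals
(φ = −57°, ψ = −47°, ω = 180°) and side chains by natural-extension
(NeRF) placement from ideal internal geometry plus rotamer χ angles.
Ring closures (His, Phe/Tyr, Trp, Pro) are approximate to ~0.1–0.3 Å
because rings are built open from ideal bond angles; χ dihedrals,
which the tests check, round-trip to well below 10⁻³ degrees.

`syntheticTemplateComplex` assembles a stand-in template: three
7-residue helices placed with their side chains facing the sub-site
edges at 6.5 Å (CA centroid to base-edge centroid — the range observed
between contacting helix residues and base edges in zinc-finger
complexes), then relaxed by clash-minimizing rotamer re-selection. It is
a geometric scaffold with real residue chemistry, not a docked
structure; scores computed on it demonstrate the machinery and rank
relative candidates, they are not affinity predictions.

# What the fixture generator emulates — and what it does not

`makeFixture` plants hydrogen bonds at exact (class, d, θ) geometry
using real atom identities (Lys NZ, Ser OG, Arg NH1 with its guanidinium
context, guanine O6/N7), so the chemistry table, the pair screen, the
donor/acceptor resolution and the energy formula are all exercised
end-to-end with a closed-form expected total. Decoy sites realize the
three exclusion rules: carbon pairs inside the cutoff, donor/acceptor
pairs beyond it, and donor-donor pairs. Nonzero θ is planted through the
Arg guanidinium (up to 60°, the range its in-plane hydrogens can
realize); O-O bonds can only be planted at θ = 0 because all oxygen
donors are rotatable. `randomFixture` scatters catalogue atoms with a
1.5 Å minimum separation for oracle-equivalence sweeps.

Passing these tests shows the *rules* are implemented exactly; it does
not show that scores predict affinities of real complexes, which depend
on docked geometry, induced fit and the neglected energy terms.

# Numerical choices

* Energies are double precision; `cospi` makes the 90° factor exactly
  zero. Planted-bond totals are required to match closed forms to
  10⁻⁹ kcal/mol; rigid-motion invariance is asserted to 10⁻⁹ after
  random rotations/translations.
* Ranking ties (identical absolute scores) break by more-negative signed
  energy first, then lexicographic helix code — rankings are
  order-independent and byte-reproducible.
* Rotamer ties (equal clash counts) break by higher library frequency,
  then library order. The shipped library is minimal (1–4 common
  rotamers per residue with standard frequencies); a full library can be
  supplied as TSV.
* Degenerate inputs: targets with no qualifying interface pairs score
  exactly 0 and stay in the ranking; empty record sets rank to an empty
  table with a warning; `top_k` larger than a table falls back to the
  full table with a warning.
* Alternate locations in PDB input resolve to the highest-occupancy
  copy; both `DA`-style and legacy one-letter DNA residue names are
  accepted.

# Problem sizes

The test suite runs its heavier property sweeps at 200 random-interface
oracle comparisons and ~110 planted-bond fixtures, and exercises the
full pipeline on small pools (4–8 helices per key); the acceptance
script additionally runs the full approach-1 pool (392 helices per
finger) for one 9-bp address and the full approach-2 pool (448 helices)
for one synergistic target. These sizes were chosen to exercise every
code path at interactive run times; the enumeration functions themselves
cover the complete design spaces (192 targets, 8000 all-20 helices)
directly.

# Limitations

* No docking and no energy minimization: the pipeline scores a supplied
  (or synthetic) template after rigid-backbone threading. Post-placement
  relaxation is known to matter for absolute energies and is explicitly
  out of scope.
* Cross-strand contacts (the overlapping 4-bp sub-site read through
  position +2) are excluded by design; position +2 is held at the
  scaffold value by default.
* The B-DNA model is sequence-independent (no sequence-dependent step
  parameters, groove widths or solvent).
* Zinc coordination is inert: Cys2His2 zinc sites are carried as plain
  atoms, not modelled.
* Scores are rankings, not binding free energies; validation against
  experimental dissociation constants is outside the package.
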