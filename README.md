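# zfscore

Ab-initio ranking of Cys2His2 zinc-finger recognition helices against
double-stranded DNA targets by interfacial hydrogen-bond energy.

## The problem

Cys2His2 zinc fingers are the workhorse DNA-binding modules of designed
transcription factors and genome-editing fusions. Each finger reads one
3-bp sub-site through the residues at positions −1, +2, +3 and +6 of its
recognition α-helix; a three-finger protein such as Zif-268 addresses a
9-bp site. Choosing the helix residues that best bind a given sub-site —
the "recognition code" problem — is what this package computes, without
training on naturally occurring proteins: candidate helices are threaded
onto a fixed-backbone template complex and ranked by a physics-based
score.

## The score

A hydrogen bond between an amino-acid atom *i* and a nucleotide atom *j*
contributes the AMBER99-style 10-12 potential

ΔG(hb) = ε\_ij \[ 3 (d′\_ij / d\_ij)⁸ − 4 (d′\_ij / d\_ij)⁶ \] cos⁴ θ

where d is the donor–acceptor distance, θ the deviation of D–H···A from
linearity, and (ε, d′) depend on the element pair: 2.0 kcal/mol at 3.2 Å
for N–N, 2.8 at 3.0 Å for N–O, 4.0 at 2.8 Å for O–O. Candidate pairs are
screened at 3.5 Å (350 pm) between heavy atoms; pairs containing a carbon
are ignored; only N, O and S side-chain and base-edge atoms may donate or
accept; bonds must join an amino acid to a nucleotide. Per-bond energies
are summed, and the absolute value of the sum — the interfacial
hydrogen-bond energy (IHBE) — is the ranking score. Under *modular*
binding each finger is scored on its own 9-bp target (variable sub-site
inside a fixed `NNN-GTT-TAT` / `TAT-NNN-TAT` / `TAT-GTT-NNN` template)
and finger energies add; under *synergistic* binding one helix is applied
to all three fingers of a 27-bp repeated-triplet target flanked by
`TATGTTTAT`, scored as a single complex.

The surrounding machinery is self-contained: an idealized B-form duplex
builder (36°/3.38 Å per step, written/read as PDB), per-position
amino-acid pools (7×7×8 consensus space, 7×8×8 with glutamate at +3, or
all-20), and fixed-backbone side-chain threading from a rotamer library
with clash-minimizing selection.

## Worked example

```r
library(zfscore)

hbondEnergy(2.8, 0, "O-O")   # energy at the O-O optimum
#> [1] -4

## rank a small candidate set for sub-site GCG at finger 2
pool <- aminoAcidPool(c("R", "Q"), c("E", "H"), c("R", "T"))
tabs <- runModular("GCG", fingers = 2, pool = pool)
rankedRecords(tabs[["GCG/F2"]])
#>   rank   helix short_code triplet finger total_energy    score n_bonds
#> 1    1 QSGELTT        QET     GCG      2    -4.427901 4.427901       2
#> 2    2 QSGHLTT        QHT     GCG      2    -4.427901 4.427901       2
#> 3    3 RSGELTT        RET     GCG      2    -4.427901 4.427901       2
#> 4    4 RSGHLTT        RHT     GCG      2    -4.427901 4.427901       2
#> 5    5 QSGELTR        QER     GCG      2    -1.726250 1.726250       1
#> 6    6 QSGHLTR        QHR     GCG      2    -1.726250 1.726250       1
#> 7    7 RSGELTR        RER     GCG      2    -1.726250 1.726250       1
#> 8    8 RSGHLTR        RHR     GCG      2    -1.726250 1.726250       1
```

Each row is one threaded helix (7-letter code, positions −1, +1..+6);
`total_energy` is the signed bond-energy sum in kcal/mol (negative =
favorable) and `score` its absolute value. The per-bond detail behind a
score is available too:

```r
tc <- syntheticTemplateComplex(makeModularTarget("GCG", 2))
sel <- selectInterfaceResidues(tc$model, tc$positionMap, 2,
                               tc$windows[[2]], dnaChain = "A")
hbonds(scoreComplex(tc$model, helixAtoms = sel$helix, baseAtoms = sel$bases))
#>         donor    acceptor     dist    theta class    energy
#> 1 P:THR52:OG1    A:DG6:N7 2.896215  0.00000   N-O -2.701651
#> 2    A:DG4:N2 P:ASP48:OD2 3.132620 26.56181   N-O -1.726250
```

Here the wild-type finger-2 helix donates a Thr OG1 hydrogen bond to
guanine N7 (2.90 Å, linear) and accepts one from guanine N2 into Asp
OD2, for a total of −4.43 kcal/mol.

A command-line front end with subcommands `targets`, `helices`, `score`,
`rank` and `propensity` ships in `inst/cli/zfscore.R`.

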