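# abforce

Desk-scale analysis of how an antibody recognises a protein antigen, built
around the system most studied in demyelinating autoimmune disease: the
external domain of myelin oligodendrocyte glycoprotein (MOG) bound by an
anti-MOG Fab. The package is for structural bioinformaticians and
biophysicists who want the *computational* half of a combined
simulation/force-spectroscopy study — interface contacts, epitope ranking,
interaction energetics, steered-pulling rupture forces, and AFM-style
adhesion processing — in a form that runs in seconds on a laptop and is
fully testable without downloading structures or trajectories.

## What it computes

**Geometric interface contacts.** A hydrogen bond is counted between a
donor D (with bonded hydrogen H) and an acceptor A when

    d(D, A) < 3.5 Å   and   ∠(H–D–A) < 60°,

a salt bridge when an acidic-residue oxygen and a basic-residue nitrogen
satisfy d(O, N) < 3.2 Å. Both comparisons are strict. Roles come from
versioned residue chemistry tables (ASP/GLU oxygens and the C-terminal OXT
acidic; LYS NZ, ARG NH1/NH2/NE, HIS ND1/NE2 basic). Detection runs
per-frame over a trajectory, giving count series with block averages,
per-CDR attribution of antigen–antibody bonds, and an occupancy-weighted
ranking of antigen *anchor residues*.

**Conformation.** Kabsch (SVD) superposition with proper-rotation
correction, and RMSD time series (Cα or all-atom, in Å and nm) for whole
molecules or annotated sub-regions.

**Energetics.** Gas-phase molecular-mechanics cross energies between the
antigen and antibody selections: Coulomb `332.06 qᵢqⱼ/(εᵣ rᵢⱼ)` and
Lennard-Jones `4ε[(σ/r)¹² − (σ/r)⁶]` with Lorentz–Berthelot combining,
sampled on a stride through a trajectory window (the ΔE_elec / ΔE_vdW
terms of an MM/PBSA-style decomposition; solvation and entropy are out of
scope).

**Steered pulling.** A coarse-grained constant-velocity pulling simulator:
one bead per participating residue, breakable harmonic interface bonds,
fixed anchor beads, and a harmonic spring (k = 2.15 kcal mol⁻¹ Å⁻², v =
0.025 Å ps⁻¹ = 0.00005 Å per 2 fs step) whose anchor advances along the
pulling direction, integrated with overdamped Langevin dynamics at 310 K.
Replicate runs yield rupture-force statistics; the standard comparison is
the full interface versus the contact subset inside a peptide window, and
the *force fraction* 100 × F_subset / F_full.

**Force spectra.** AFM retract-curve adhesion extraction (baseline minus
minimum), SMD rupture extraction with three-phase labelling (maintenance /
detachment / separation), and Tukey-boxplot comparison of force
distributions with containment fractions and rank tests.

**Synthetic data.** Generators for annotated complexes with planted
contacts (recovered exactly at zero noise), trajectories with tunable
per-contact persistence, and AFM curves with planted adhesion — every
stage of the pipeline is exercised end-to-end from a single seed.

## Worked example

```r
library(abforce)

cx <- makeComplex(complexSpec(seed = 1))
cx$structure
#> ComplexStructure with 1001 atoms
#>   antigen       110 residues,   411 atoms
#>   heavy_chain    60 residues,   231 atoms
#>   light_chain    60 residues,   239 atoms
#>   water          40 residues,   120 atoms
#>   chemistry: assigned

ag <- atomSelect(cx$structure, molecule = "antigen")
ab <- atomSelect(cx$structure, molecule = c("heavy_chain", "light_chain"))
head(detectHBonds(cx$structure, ag, ab)[, c("donor_chain", "donor_resno",
                                            "acceptor_resno", "d_DA",
                                            "theta_HDA")], 3)
#>   donor_chain donor_resno acceptor_resno d_DA theta_HDA
#> 1           H          27            108 2.80         0
#> 2           H          28              1 2.84         0
#> 3           H          29            104 2.88         0
```

The 13 planted interface bonds are found at their planted distances with
ideal geometry. The full pipeline ranks anchor residues over a noisy
trajectory, maps them onto encephalitogenic peptide windows, and pulls the
full interface against the 92–106 window subset:

```r
res <- runPipeline(defaultPipelineConfig(seed = 1))
res$objects$ranking
#> AnchorRanking: 13 residues
#>    ASN_108(189) ASN_1(180) ASN_104(171) ASN_33(162) ASN_103(162) ...
res$objects$window_report
#> WindowReport
#>   win_1_22 [1-22]: 2 members
#>   win_35_55 [35-55]: 3 members
#>   win_92_106 [92-106]: 5 members
#>   union: 10 | outside all windows: 3
res$summary$rupture_full$mean      # 1982 pN (± 128 over 20 replicates)
res$summary$rupture_subset$mean    # 1119 pN (± 117)
res$summary$force_fraction$pct     # 56.5
```

The counts read: of the 13 ranked anchor residues, 5 fall in the 92–106
window and 10 in the union of the three encephalitogenic windows; the
window subset carries a bit over half of the full unbinding force in this
synthetic system. For the published mean forces the same arithmetic gives

```r
forceFraction(780, 1042)
#> $pct
#> [1] 74.9
#> $pct_rounded
#> [1] 75
```

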