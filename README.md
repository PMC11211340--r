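# fcbase

Tools for analysing the **base of the IgG Fc region** — the cross-shaped
surface formed by the C-terminal C<sub>H</sub>3 domains of the two heavy
chains — and its interaction with model gold nanoparticles (AuNPs).

The base is an attractive conjugation site for nanoparticle–antibody
constructs because it lies far from the antigen-binding (Fab) and effector
(C<sub>H</sub>2) sites, so a particle bound there leaves antibody function
intact. Its surface follows a general motif: a hydrophobic patch
(positions 351–355, 359 in PDB numbering) surrounded by hydrophilic
residues, several of which are charged at physiological pH.

## What the package computes

* **Base catalogue** — the 19 positions per heavy chain that form the base,
  with Kabat and PDB numbering, the sequence variants observed across IgG
  species/subclasses, and conservation flags (the four conserved positions
  are P354, W418, K440 and S443).
* **Sequence analysis** — progressive global alignment (affine-gap Gotoh,
  BLOSUM62 by default), per-position conservation profiles, residue surface
  classification (hydrophobic / hydrophilic / positive / negative),
  isoelectric point by Henderson–Hasselbalch net-charge bisection, and
  average molecular weight.
* **Structure I/O and geometry** — fixed-column PDB (including multi-model
  trajectories) and XYZ, residue-range extraction, and Kabsch rigid-body
  superposition (SVD solution, proper rotations only).
* **Nanoparticle models** — spherical fcc AuNPs (default 2.5 nm,
  a = 4.078 Å), surface-atom detection by coordination number
  (< 12 neighbours within 1.2 × a/√2), charge assignment (total, e.g.
  −10 e, or per surface atom, e.g. −0.05 e), and placement at a given
  surface-to-surface gap from a protein.
* **Trajectory metrics** — contact residues within a cutoff (default 5 Å)
  of the particle, minimum-separation time series, backbone RMSD

  RMSD(t) = √( Σᵢ |rᵢ(t) − rᵢ(t₀)|² / N )   (after rigid-body superposition),

  per-residue RMSF about the window-average positions

  RMSFₖ = √( ⟨ Σᵢ |rᵢ(t) − ⟨rᵢ⟩|² / Nₖ ⟩_T ),

  and inter-chain Cα distances with mean ± SEM over a trailing window
  (default 20 ns).
* **Synthetic generators** — seed-deterministic toy C<sub>H</sub>3 dimers
  carrying the catalogued base identities, sequence families with
  controlled variability, and adsorption trajectories with planted contact
  sets, used to validate every metric with exact ground truth.

## Worked example

```r
library(fcbase)

map <- load_base_position_map()
nrow(map)                        # 19
map$pdb[map$conserved]           # 354 418 440 443

## conservation over a sequence family drawn from the catalogued variants
fam  <- make_base_family(map, n = 25, seed = 1)
prof <- conservation_profile(align_sequences(fam), map = map,
                             first_resno = 341)
attr(prof, "conserved_count")    # 4
attr(prof, "variable_count")     # 15

## a charged 2.5 nm AuNP
np <- assign_charges(detect_surface_atoms(build_fcc_sphere()), "total", -10)
np
#> aunp_model: 459 Au atoms, 2.50 nm fcc sphere (a = 4.078 A),
#> surface atoms: 234, net charge -10 e

## adsorption trajectory planting the charged-condition contact set
dimer <- make_ch3_dimer()
ref   <- reference_contact_sets("charged")
traj  <- make_adsorption_trajectory(dimer, np, ref[, c("chain", "resno")],
                                    n_frames = 11, seed = 1)
ct <- contact_residues(traj, chains = c("B", "D"), cutoff = 5)
table(ct$chain)                  # B: 13, D: 11
head(ct[, c("chain", "resno", "aa", "class")], 4)
#>   chain resno aa       class
#> 1     B   353  P hydrophobic
#> 2     B   354  P hydrophobic
#> 3     B   355  P hydrophobic
#> 4     B   356  E    negative
```

The contact table lists, per heavy chain, every residue with an atom
within the cutoff of the particle at the final frame, with its surface
class — 13 chain-B and 11 chain-D residues here, matching the planted
charged-condition set.

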