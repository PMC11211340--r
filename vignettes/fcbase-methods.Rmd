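---
title: "Methods: the Fc base, model gold nanoparticles, and trajectory metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Fc base, model gold nanoparticles, and trajectory metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcbase)
```

## The scientific problem

IgG antibodies end, at the C-terminus of their two heavy chains, in a pair
of C~H~3 domains packed into a cross-shaped surface — the *base* of the Fc
region. Because this surface is far from the antigen-binding Fabs and from
the effector-function sites on C~H~2, it is a natural place to attach a
nanoparticle without compromising antibody function. fcbase provides the
analysis layer for studying this surface: a catalogue of its 19 positions
per heavy chain, sequence conservation and surface-character analysis,
model gold nanoparticle (AuNP) construction, and the geometric metrics
used to characterise protein–nanoparticle adsorption trajectories.

## The base catalogue

`load_base_position_map()` ships the 19 base positions with their Kabat
numbers (371–474), PDB-file residue numbers (351–444), and the variants
observed across IgG species and subclasses. Four positions carry a single
variant — P354, W418, K440 and S443 in PDB numbering — and are flagged
conserved; the other 15 vary. The catalogue is a versioned fixture and is
validated on load (monotone numbering, legal amino-acid codes, the
conservation flag consistent with the variant set), with errors naming the
offending row. A general antibody-numbering engine (Kabat/IMGT/Chothia) is
deliberately out of scope: the catalogue supplies the mapping this package
needs, and general numbering is a separate project.

All downstream analyses use PDB-file numbering verbatim; no renumbering is
performed.

## Sequence analysis

**Alignment.** `align_sequences()` performs progressive global alignment:
each sequence is aligned to the growing profile with an affine-gap Gotoh
dynamic program (gap of length $L$ costs `gap_open` $+ L \cdot$
`gap_extend`; defaults 10 and 0.5 with BLOSUM62). Profile columns score
against a residue by the mean substitution score over the column's non-gap
residues, and the guide order is the input order. For near-equal-length
C~H~3 domains the choice of progressive scheme is immaterial to
conservation counts; the dynamic program itself is validated against
exhaustive enumeration of all alignments for short pairs.

**Conservation.** `conservation_profile()` records, per profiled column,
the set of observed residues; gaps are counted separately and never listed
as variants, and a column is conserved when exactly one residue occurs.
Profiling an aligned family built from the catalogued variant sets
recovers 4 conserved / 15 variable positions with the conserved set
{354, 418, 440, 443}.

**Surface classes.** `classify_residue()` partitions the 20 standard
residues: hydrophobic {A, V, L, I, P, M, F, W}, positive {K, R, H},
negative {E, D}, hydrophilic {G, S, C, N, Q, Y, T}; anything else maps to
`unknown`. Two deliberate choices: His counts as positive despite partial
protonation at pH 7 (the convention of the surface-colouring scheme this
reproduces), and both Tyr (Y) and Thr (T) are hydrophilic — colour-scheme
listings of this palette are occasionally ambiguous between the two, but
the hydrophilic assignment of Thr 360 in the contact tables fixes both.

**pI and molecular weight.** `isoelectric_point()` bisects the
Henderson–Hasselbalch net-charge curve on pH (0, 14) to $10^{-3}$ pH
units. The default pKa set (N-term 9.0, C-term 2.0, D 3.65, E 4.25,
C 8.3, Y 10.07, H 6.0, K 10.53, R 12.48) is a conventional table and is
caller-overridable; published pI values computed with other tables (e.g.
web services whose exact pKa sets are unspecified) will differ by a few
tenths of a pH unit, so no such value is asserted. `molecular_weight()`
sums average residue masses plus one water.

## Structure I/O and superposition

PDB reading goes through the bio3d parser behind `read_pdb()` /
`read_trajectory_pdb()` (fixed-column dialect; only blank or `'A'`
alternate locations are kept; `MODEL` blocks become trajectory frames),
with a pre-scan that reports malformed ATOM/HETATM records by line number.
Writing — including multi-model trajectory output — uses an in-package
fixed-column formatter, since the round trip must preserve coordinates to
the PDB's native $10^{-3}$ Å column precision. XYZ (count + comment +
`element x y z`, concatenated blocks for frames) is read and written
directly.

`kabsch_superpose()` computes the optimal proper rotation via SVD of the
cross-covariance matrix with the standard determinant sign correction, so
a reflection is never returned; degenerate (collinear or < 3 point)
inputs are rejected. The backbone atom set for RMSD-style analyses is
fixed to {N, CA, C, O} — the conventional choice where only "backbone
atoms" is specified.

## Nanoparticle models

`build_fcc_sphere()` enumerates the conventional fcc cell (4-atom basis)
over a bounding grid and keeps lattice points within `diameter/2` of the
centre. The gold lattice constant defaults to the standard
crystallographic 4.078 Å (configurable); nearest neighbours then sit at
$a/\sqrt2 \approx 2.88$ Å and interior atoms have coordination 12.

`detect_surface_atoms()` flags atoms with fewer than 12 neighbours within
$1.2 \times a/\sqrt2$. Coordination counting is preferred over convex-hull
membership because the curvature of a small sphere leaves facet-edge atoms
off the hull even though they are chemically surface; hull support points
remain a subset and are used as a test oracle.

`assign_charges()` offers both reported charging conventions: a **total**
charge (default −10 e) spread uniformly over surface atoms, or a
**per-atom** surface charge (e.g. −0.05 e). The two are consistent only
for exactly 200 surface atoms; a 2.5 nm sphere at a = 4.078 Å has
`r sum(detect_surface_atoms(build_fcc_sphere())$surface)` surface atoms,
so total mode is the default for reproducing the net-charge value, and
per-atom mode is available for the stated per-atom convention.

`place_near()` translates the particle along the ray from the protein
centroid through the centroid of a target selection until the minimum
atom–atom distance equals the requested surface-to-surface gap (default
10 Å, the unbiased adsorption starting distance), solved by root finding
to $10^{-6}$ and verified to $10^{-3}$ Å by construction. For near-zero
gaps an exact crossing may not exist (interatomic distances are bounded
below along the sweep); the closest attainable point is then returned.

`ion_pair_count()` implements the closed-form arithmetic
$\mathrm{round}(I \cdot N_A \cdot V_{solv})$ with
$V_{solv} = V_{box} - V_{excl}$ and a caller-supplied excluded volume
(default 0). Published ion counts for specific boxes are not exactly
recoverable without the original excluded-volume convention, so they are
not asserted anywhere.

## Trajectory metrics

Trajectories are frames over a shared atom table with strictly increasing
times (ns). All metrics are validated against brute-force
reimplementations (explicit loops, independent superposition route) at
$10^{-9}$ Å on small systems.

* **Contacts** (`contact_residues()`): a residue is in contact when *any*
  of its atoms (side chains included) is within the cutoff of any particle
  atom at the chosen frame; the default cutoff is 5 Å (the contact-table
  convention; looser discovery bands like 5–7 Å are available via the
  parameter), and the default frame is the last. Contact sets are
  monotone in the cutoff.
* **RMSD** (`rmsd_series()`): per frame, the alignment selection is
  superposed on the reference frame (the first, by default) and the RMSD
  is evaluated over the atom mask — backbone only by default, side chains
  excluded as their orientations add noise without structural signal.
  Per-domain analysis is done by passing one chain's backbone as the
  selection, so inter-domain motion does not inflate the values.
* **RMSF** (`rmsf()`): frames in the window (default: trailing 20 ns) are
  aligned on the chosen fragment, each atom's window-average position is
  computed, and residue $k$ gets
  $\sqrt{\langle \sum_i |r_i(t)-\langle r_i\rangle|^2 / N_k \rangle_T}$.
  Aligning per fragment removes rigid and inter-domain motion, so pure
  isotropic jitter of per-coordinate standard deviation $\sigma$ is
  recovered as $\sigma\sqrt3$ (verified within 5% at 2000 frames for
  $\sigma \in \{0.2, 0.5, 1.0\}$ Å).
* **Pair distances** (`pair_distance_summary()`): per-frame Cα–Cα
  distances between the same residue number on the two heavy chains,
  summarised over the window by mean and SEM $= s/\sqrt{n}$ over frames.
  No autocorrelation correction is applied to the SEM — frames are treated
  as independent, which understates the error for strongly correlated
  sampling; this is a known limitation.

## The synthetic generators, and what they do (not) show

The study-scale inputs — crystal structures and 100 ns explicit-solvent MD
trajectories — are not reproducible at desk scale, so validation uses
generators whose ground truth is exact:

* `make_ch3_dimer()` builds a *geometric stand-in*, not a physical fold:
  chains B and D with residues 341–444, the 19 base positions carrying the
  1IGT (mouse IgG2a) residue identities (the first-listed catalogue
  variant; alanine fillers elsewhere), backbone {N, CA, C, O} plus one
  side-chain pseudo-atom (CB) per residue, and exact two-fold symmetry
  about z. Base CAs lie on an arc facing a fixed focal point below the
  protein, side-chain pseudo-atoms pointing toward it — outward from the
  protein body, as base side chains face a particle approaching from
  below.
* `make_adsorption_trajectory()` moves the particle linearly along the
  approach axis to the focal point, and extends the planted residues'
  pseudo-atoms radially to a contact shell `cutoff − 1.5` Å above the
  particle surface — emulating the observed adaptation of the base surface
  on adsorption. By construction, at the final frame every planted
  residue is within `cutoff − 0.5` Å and every other residue beyond
  `cutoff + 1` Å, so contact recovery is exact rather than statistical;
  the margins are re-verified after jitter and violate with an error.
  Defaults mirror the study conditions: 5 Å cutoff, 51 frames spanning
  0–100 ns, and a small 0.1 Å jitter (large enough to exercise the
  numerics, small enough to not erode the 0.86 Å excluded-residue margin).
* `make_jitter_trajectory()` adds i.i.d. Gaussian displacement (and
  optional rigid drift) to a structure, giving the closed-form RMSF
  ground truth $\sigma\sqrt3$.

Passing these tests shows the *metrics and bookkeeping* are correct —
numbering, identities, classification, distances, superposition, and the
estimator formulas. It does not show anything about force fields,
adsorption energetics, or real side-chain packing: the generators have no
physics, and real trajectories differ in atom density, correlated motion
and side-chain geometry. Conclusions about real systems still require real
structures and trajectories, which the same functions accept via
`read_pdb()` / `read_trajectory_pdb()`.

## Reference contact sets

`reference_contact_sets()` ships the per-chain residue lists reported
within 5 Å of the charged and uncharged AuNP at the end of the 100 ns
1IGT adsorption trajectories (13 residues on chain B in both conditions;
11 and 3 on chain D for charged and uncharged respectively), with their
surface classes. These drive the planted sets of the pipeline's synthetic
runs and the class-agreement checks.

## Numerical choices and problem sizes

Ties in the alignment dynamic program break deterministically
(match > gap-in-profile > gap-in-sequence at equal score). The pI
bisection runs to $10^{-3}$ pH; superposition rotations are orthonormal to
$10^{-8}$. Test problem sizes are chosen for exactness rather than scale:
brute-force metric comparisons use ≤ 100 atoms × ≤ 50 frames,
alignment enumeration uses sequences of length ≤ 6, conservation uses
families of 10–30 sequences, and fluctuation recovery uses 2000 frames of
the 1040-atom dimer — sizes at which every oracle is exhaustive or the
closed form is tight.

## The pipeline

`run_base_analysis()` and `run_conjugate_analysis()` orchestrate the
end-to-end runs from an `fc_run_config()` (YAML round-trippable; defaults
match the study conditions: 5 Å cutoff, trailing 20 ns window, backbone
mask, chains B/D, 2.5 nm AuNP at −10 e total, 10 Å placement gap) and
emit tidy CSV tables plus a JSON manifest recording the package version,
seed and config hash. Outputs are byte-identical across re-runs with the
same config and seed. The package is library-first: these functions, with
`Rscript` one-liners, are the command-line surface.
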