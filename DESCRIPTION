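Package: fcbase
Title: Analysis of the IgG Fc Base and Its Interactions with Model Gold
    Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing the "base" of the IgG Fc region, the
    cross-shaped surface formed by the C-terminal CH3 domains of the two
    heavy chains, and its interaction with model gold nanoparticles.
    Provides a catalogue of the 19 Fc-base positions with Kabat/PDB
    numbering and observed variants, progressive sequence alignment and
    per-position conservation profiling, residue surface classification,
    sequence isoelectric point and molecular weight, fixed-column PDB and
    XYZ structure I/O, Kabsch rigid-body superposition, construction of
    spherical fcc gold nanoparticle models with surface-atom detection and
    charge assignment, and trajectory metrics (contact residues at a
    distance cutoff, minimum-separation time series, backbone RMSD,
    per-residue RMSF, inter-chain C-alpha distances with mean and SEM).
    Synthetic generators produce toy CH3 dimers, sequence families with
    controlled variability, and adsorption trajectories with planted
    contact sets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
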