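#' Assemble a run configuration
#'
#' Bundles the parameters of the end-to-end analyses with defaults matching
#' the study conditions: 5 Angstrom contact cutoff, trailing 20 ns RMSF /
#' pair-distance window, backbone mask N/CA/C/O, heavy chains B and D, a
#' 2.5 nm fcc AuNP (a = 4.078 Angstrom) carrying a total charge of -10 e
#' on its surface atoms, and a 10 Angstrom initial surface-to-surface gap.
#'
#' @param outdir output directory for report files.
#' @param seed integer seed for all synthetic inputs.
#' @param condition `"charged"` or `"uncharged"` nanoparticle condition.
#' @param cutoff contact cutoff (Angstrom).
#' @param window_ns trailing analysis window (ns).
#' @param backbone backbone atom-name mask.
#' @param chains heavy-chain identifiers.
#' @param np_diameter nanoparticle diameter (nm).
#' @param np_lattice_constant fcc lattice constant (Angstrom).
#' @param np_charge_mode `"total"` or `"per_atom"`.
#' @param np_charge charge value in e (total, or per surface atom).
#' @param np_gap initial surface-to-surface placement gap (Angstrom).
#' @param n_frames,frame_spacing synthetic trajectory length and spacing
#'   (ns).
#' @param jitter_sigma synthetic per-coordinate jitter (Angstrom).
#' @param n_family synthetic sequence-family size.
#' @param fasta optional FASTA file of sequences for the base analysis
#'   (default: synthesise a family from the catalogue).
#' @param trajectory optional multi-model PDB trajectory for the conjugate
#'   analysis (default: synthesise an adsorption trajectory).
#' @param pair_resno residue numbers for the inter-chain C-alpha distance
#'   summary.
#' @return a list of class `fc_run_config`.
#' @export
fc_run_config <- function(outdir = tempfile("fcbase_run_"), seed = 1,
                          condition = "charged", cutoff = 5,
                          window_ns = 20, backbone = c("N", "CA", "C", "O"),
                          chains = c("B", "D"), np_diameter = 2.5,
                          np_lattice_constant = 4.078,
                          np_charge_mode = "total", np_charge = -10,
                          np_gap = 10, n_frames = 51, frame_spacing = 2,
                          jitter_sigma = 0.1, n_family = 30, fasta = NULL,
                          trajectory = NULL,
                          pair_resno = c(357, 415, 420, 421, 444)) {
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              condition = condition, cutoff = cutoff,
              window_ns = window_ns, backbone = backbone, chains = chains,
              np_diameter = np_diameter,
              np_lattice_constant = np_lattice_constant,
              np_charge_mode = np_charge_mode, np_charge = np_charge,
              np_gap = np_gap, n_frames = as.integer(n_frames),
              frame_spacing = frame_spacing, jitter_sigma = jitter_sigma,
              n_family = as.integer(n_family), fasta = fasta,
              trajectory = trajectory, pair_resno = pair_resno)
  class(cfg) <- "fc_run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' Round-trips an [fc_run_config()] through a structured config file.
#'
#' @param config an `fc_run_config`.
#' @param path YAML file path.
#' @return `path` invisibly (write) or the `fc_run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, TRUE)]
  do.call(fc_run_config, raw)
}

run_manifest <- function(config, outputs, stage) {
  cfg_path <- file.path(config$outdir, "config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("fcbase")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Run the base-catalogue analysis
#'
#' Emits, under `config$outdir`: the base-position map (`base_map.csv`), a
#' conservation profile of an aligned sequence family over the 19 base
#' positions (`conservation.csv`), the per-chain residue classification of
#' the synthetic dimer (`base_classification.csv`), per-sequence
#' isoelectric points and molecular weights (`sequence_properties.csv`),
#' and a JSON run manifest.  Sequences come from `config$fasta` when
#' given, otherwise a family is synthesised from the catalogue under
#' `config$seed`.
#'
#' @param config an [fc_run_config()].
#' @return invisibly, a list with `map`, `alignment`, `conservation`,
#'   `classification`, `properties`, `manifest`.
#' @export
run_base_analysis <- function(config = fc_run_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  map <- load_base_position_map()
  records <- if (!is.null(config$fasta)) read_fasta(config$fasta)
             else make_base_family(map, n = config$n_family,
                                   seed = config$seed)
  aln <- align_sequences(records)
  prof <- conservation_profile(aln, map = map,
                               first_resno = CH3_FIRST_RESNO)
  dimer <- make_ch3_dimer(map)
  cls <- base_motif_summary(dimer, map, chains = config$chains)
  props <- data.frame(id = records$id,
                      pI = vapply(records$seq, isoelectric_point, 0),
                      mwt = vapply(records$seq, molecular_weight, 0),
                      row.names = NULL)
  files <- c(base_map = "base_map.csv", conservation = "conservation.csv",
             classification = "base_classification.csv",
             properties = "sequence_properties.csv")
  write_base_map_csv(map, file.path(config$outdir, files["base_map"]))
  write.csv(as.data.frame(prof), file.path(config$outdir, files["conservation"]),
            row.names = FALSE, quote = FALSE)
  write.csv(cls, file.path(config$outdir, files["classification"]),
            row.names = FALSE, quote = FALSE)
  write.csv(props, file.path(config$outdir, files["properties"]),
            row.names = FALSE, quote = FALSE)
  manifest <- run_manifest(config, as.list(files), "base_analysis")
  invisible(list(map = map, alignment = aln, conservation = prof,
                 classification = cls, properties = props,
                 manifest = manifest))
}

#' Run the nanoparticle-conjugate analysis
#'
#' Builds the nanoparticle model (surface detection plus charge assignment
#' per the configured mode), obtains an adsorption trajectory (from
#' `config$trajectory` if given, otherwise synthesised with the reference
#' contact set of `config$condition` planted), and emits under
#' `config$outdir`: the end-frame contact table (`contacts.csv`), the
#' per-contact minimum-separation series (`min_separation.csv`), per-chain
#' backbone RMSD (`rmsd.csv`), per-residue RMSF over the trailing window
#' (`rmsf.csv`), the inter-chain C-alpha distance summary
#' (`pair_distances.csv`), the nanoparticle charge table
#' (`nanoparticle.csv`), and a JSON run manifest.
#'
#' @param config an [fc_run_config()].
#' @return invisibly, a list with `np`, `trajectory`, `contacts`,
#'   `min_separation`, `rmsd`, `rmsf`, `pair_distances`, `manifest`.
#' @export
run_conjugate_analysis <- function(config = fc_run_config()) {
  np <- build_fcc_sphere(config$np_diameter, config$np_lattice_constant)
  np <- detect_surface_atoms(np)
  np <- assign_charges(np, mode = config$np_charge_mode,
                       value = config$np_charge)
  if (!is.null(config$trajectory)) {
    traj <- read_trajectory_pdb(config$trajectory)
  } else {
    planted <- reference_contact_sets(config$condition)
    traj <- make_adsorption_trajectory(
      make_ch3_dimer(), np, planted[, c("chain", "resno")],
      n_frames = config$n_frames, frame_spacing = config$frame_spacing,
      gap_start = config$np_gap + 20, cutoff = config$cutoff,
      jitter_sigma = config$jitter_sigma, seed = config$seed)
  }
  if (n_frames(traj) < 1 || !nrow(traj$atoms)) stop("empty trajectory")

  contacts <- contact_residues(traj, chains = config$chains,
                               cutoff = config$cutoff,
                               condition = config$condition)
  npidx <- particle_indices(traj)
  minsep <- do.call(rbind, lapply(seq_len(nrow(contacts)), function(i) {
    s <- min_separation_series(
      traj, list(chain = contacts$chain[i], resno = contacts$resno[i]),
      npidx)
    cbind(chain = contacts$chain[i], resno = contacts$resno[i], s)
  }))
  window <- trailing_window(traj, config$window_ns)
  rmsd_tab <- do.call(rbind, lapply(config$chains, function(ch) {
    r <- rmsd_series(traj, atoms = list(chain = ch, name = config$backbone))
    cbind(chain = ch, r)
  }))
  rmsf_tab <- do.call(rbind, lapply(config$chains, function(ch) {
    rmsf(traj, fragment = list(chain = ch, name = config$backbone),
         window = window)
  }))
  pairs <- pair_distance_summary(traj, config$pair_resno,
                                 chains = config$chains, window = window)

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(contacts = "contacts.csv", min_separation = "min_separation.csv",
             rmsd = "rmsd.csv", rmsf = "rmsf.csv",
             pair_distances = "pair_distances.csv",
             nanoparticle = "nanoparticle.csv")
  write.csv(as.data.frame(contacts), file.path(config$outdir, files["contacts"]),
            row.names = FALSE, quote = FALSE)
  write.csv(minsep, file.path(config$outdir, files["min_separation"]),
            row.names = FALSE, quote = FALSE)
  write.csv(rmsd_tab, file.path(config$outdir, files["rmsd"]),
            row.names = FALSE, quote = FALSE)
  write.csv(rmsf_tab, file.path(config$outdir, files["rmsf"]),
            row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(pairs), file.path(config$outdir, files["pair_distances"]),
            row.names = FALSE, quote = FALSE)
  write_aunp_csv(np, file.path(config$outdir, files["nanoparticle"]))
  manifest <- run_manifest(config, as.list(files), "conjugate_analysis")
  invisible(list(np = np, trajectory = traj, contacts = contacts,
                 min_separation = minsep, rmsd = rmsd_tab, rmsf = rmsf_tab,
                 pair_distances = pairs, manifest = manifest))
}
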