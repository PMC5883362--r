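## Readers and writers binding the sampler and the analysis pipeline:
## PDB structures with sidecar charge tables, multi-model PDB
## trajectories, tab-separated step records, and YAML run configurations.

#' Read a structure from PDB plus a per-atom charge table
#'
#' Coordinates come from the PDB (first model by default); partial charges
#' are joined from a tab-separated sidecar keyed by atom serial, since the
#' PDB format has no charge field.  Atoms on `ligand_chain` form the
#' ligand partition; all others are receptor.
#'
#' @param pdb_path path to a PDB file.
#' @param charge_table_path path to a TSV with columns `serial` and
#'   `charge`, one row per atom.
#' @param ligand_chain chain identifier(s) of the ligand (default "L").
#' @param model model number to read from a multi-model file.
#' @param masses per-atom masses; a single value is recycled.
#' @return a [particle_system()].
#' @export
read_structure <- function(pdb_path, charge_table_path,
                           ligand_chain = "L", model = 1L, masses = 12) {
  if (!file.exists(pdb_path)) stop("PDB file not found: ", pdb_path)
  if (!file.exists(charge_table_path))
    stop("charge table not found: ", charge_table_path)
  pdb <- bio3d::read.pdb(pdb_path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  n <- nrow(atoms)
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  pos <- matrix(xyz, ncol = 3L, byrow = TRUE)

  ch <- utils::read.table(charge_table_path, header = TRUE, sep = "\t")
  if (!all(c("serial", "charge") %in% names(ch)))
    stop("charge table must have columns 'serial' and 'charge'")
  if (nrow(ch) != n)
    stop("atom count mismatch: PDB has ", n, " atoms, charge table has ",
         nrow(ch), " rows")
  jj <- match(atoms$eleno, ch$serial)
  if (anyNA(jj))
    stop("charge table missing serial(s): ",
         paste(atoms$eleno[is.na(jj)], collapse = ", "))
  role <- ifelse(atoms$chain %in% ligand_chain, "ligand", "receptor")
  particle_system(
    positions = pos, masses = masses, role = role,
    charges = ch$charge[jj],
    residue_index = atoms$resno, residue_name = atoms$resid,
    atom_name = atoms$elety
  )
}

#' Write / read a multi-model PDB trajectory
#'
#' Frames are stored as MODEL/ENDMDL records; the round trip is lossless
#' at PDB coordinate precision (1e-3 Angstrom).
#'
#' @param trajectory a `retamd_run` or frames matrix (rows = frames,
#'   bio3d xyz ordering).
#' @param system the matching [particle_system()] providing atom naming.
#' @param path output path.
#' @return `write_trajectory` invisibly returns the path;
#'   `read_trajectory` returns the frames matrix.
#' @export
write_trajectory <- function(trajectory, system, path) {
  frames <- .traj_frames(trajectory)
  if (nrow(frames) == 0L) stop("trajectory has no frames")
  n <- length(system$masses)
  if (ncol(frames) != 3L * n)
    stop("frame width does not match the system's atom count")
  chain <- ifelse(system$role == "receptor", "R", "L")
  bio3d::write.pdb(file = path, xyz = frames,
                   resno = system$residue_index,
                   resid = system$residue_name,
                   eleno = seq_len(n), elety = system$atom_name,
                   chain = chain, o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(as.numeric(xyz), nrow = 1L)
  unclass(xyz)
}

#' Write / read per-step scalar records as TSV
#'
#' The scalar time series of a run (targets, CV values, per-CV receptor
#' distances, smallest ligand-receptor distance, artificial thermal
#' energy, acceptance flag and probability) as tab-separated values with a
#' commented header line.
#'
#' @param run a `retamd_run`, or a records data frame.
#' @param path output path.
#' @return `write_step_records` invisibly returns the path;
#'   `read_step_records` returns the data frame.
#' @export
write_step_records <- function(run, path) {
  records <- if (inherits(run, "retamd_run")) run$records else run
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(records), collapse = "\t")), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_step_records
#' @export
read_step_records <- function(path) {
  header <- sub("^#\\s*", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t")[[1]]
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = cols)
  df$accepted <- as.logical(df$accepted)
  df
}

#' Named parameter presets for the enhanced sampling runs
#'
#' Parameter triples (ratchet strictness c, adaptive-temperature numerator
#' k and offset h) with the matching CV counts for the three peptide
#' regimes: `pt13` (13-mer, 3 CVs, c = 0.02, k = 40, h = 10), `pt7`
#' (7-mer, 2 CVs, c = 0.02, k = 30, h = 10) and `pt3` (3-mer, 1 CV,
#' c = 0.7, k = 30, h = 10).  All values are overridable through
#' [retamd_params()].
#'
#' @param name one of `"pt13"`, `"pt7"`, `"pt3"`.
#' @param ... overrides passed on to [retamd_params()].
#' @return a [retamd_params()] object with attribute `n_cvs` and
#'   `ligand_length`.
#' @export
retamd_preset <- function(name = c("pt13", "pt7", "pt3"), ...) {
  name <- match.arg(name)
  tab <- list(
    pt13 = list(c_ratchet = 0.02, k_adapt = 40, h_adapt = 10,
                n_cvs = 3L, ligand_length = 13L),
    pt7 = list(c_ratchet = 0.02, k_adapt = 30, h_adapt = 10,
               n_cvs = 2L, ligand_length = 7L),
    pt3 = list(c_ratchet = 0.7, k_adapt = 30, h_adapt = 10,
               n_cvs = 1L, ligand_length = 3L)
  )[[name]]
  over <- list(...)
  args <- utils::modifyList(
    list(c_ratchet = tab$c_ratchet, k_adapt = tab$k_adapt,
         h_adapt = tab$h_adapt, gamma = 1, gamma_bar = 8, dt = 0.015), over)
  p <- do.call(retamd_params, args)
  attr(p, "preset") <- name
  attr(p, "n_cvs") <- tab$n_cvs
  attr(p, "ligand_length") <- tab$ligand_length
  p
}

#' Save / load a run configuration
#'
#' A run configuration bundles the system source (toy preset or PDB plus
#' charge table), the simulation parameters, strides and analysis
#' thresholds into one YAML mapping, so an archived config plus its seed
#' reproduces a run bit-identically on the same platform.
#'
#' @param config a named list; `params` entries are flattened in/out of
#'   [retamd_params()].
#' @param path YAML file path.
#' @return `save_run_config` invisibly returns the path;
#'   `load_run_config` returns the config list.
#' @export
save_run_config <- function(config, path) {
  if (inherits(config$params, "retamd_params"))
    config$params <- unclass(config$params)
  config$params <- config$params[!vapply(config$params, is.null, logical(1))]
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  if (!is.null(config$params))
    config$params <- do.call(retamd_params, config$params)
  config
}

#' Default run configuration
#'
#' @param preset toy preset name (see [retamd_preset()]).
#' @param seed master seed.
#' @param n_steps number of integration steps.
#' @return a config list understood by [save_run_config()] and
#'   [retamd_cli()].
#' @export
default_run_config <- function(preset = "pt13", seed = 1L, n_steps = 10000L) {
  params <- retamd_preset(preset, seed = seed, n_steps = n_steps)
  list(
    system = list(source = "toy", preset = preset,
                  n_receptor = 60L,
                  ligand_length = attr(params, "ligand_length")),
    params = params,
    output = list(frame_stride = 100L, record_stride = 10L),
    analysis = list(cutoff = 4.0, charge_threshold = 0.2,
                    hotspot_levels = c(0.5, 0.8)),
    seed = as.integer(seed)
  )
}
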