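#' Build a topology table
#'
#' A topology describes the atoms of one system: atom names, the residue each
#' atom belongs to, and the role of the chain carrying that residue. Protein
#' residues are numbered from 1 upwards; ligand residues are numbered zero or
#' negative (e.g. -4 to 0 for a five-residue peptide ligand), which makes the
#' two chains distinguishable by residue index alone.
#'
#' @param atom character vector of atom names (PDB naming conventions, e.g.
#'   "CA", "CB", "O", "HA", "1HB").
#' @param resid integer vector of residue indices (positive = protein,
#'   <= 0 = ligand).
#' @param chain optional chain role per atom, `"protein"` or `"ligand"`.
#'   Defaults to `"protein"` for `resid >= 1` and `"ligand"` otherwise.
#' @return A `data.frame` of class `"cd_topology"` with columns `atom`,
#'   `resid`, `chain`.
#' @export
cd_topology <- function(atom, resid, chain = NULL) {
  stopifnot(length(atom) == length(resid), length(atom) > 0)
  resid <- as.integer(resid)
  if (is.null(chain)) {
    chain <- ifelse(resid >= 1L, "protein", "ligand")
  }
  chain <- match.arg(chain, c("protein", "ligand"), several.ok = TRUE)
  if (length(chain) == 1L) chain <- rep(chain, length(atom))
  bad <- (chain == "protein" & resid < 1L) | (chain == "ligand" & resid > 0L)
  if (any(bad)) {
    stop("protein residues must have index >= 1 and ligand residues <= 0")
  }
  out <- data.frame(atom = as.character(atom), resid = resid,
                    chain = chain, stringsAsFactors = FALSE)
  class(out) <- c("cd_topology", "data.frame")
  out
}

#' Infer the chemical element of an atom from its PDB-style name
#'
#' Leading digits (as in "1HB2") are stripped and the first remaining letter
#' is taken as the element symbol. This follows the common PDB naming
#' convention for biomolecules, where two-letter elements other than hydrogen
#' essentially never occur in protein/peptide residues.
#'
#' @param name character vector of atom names.
#' @return character vector of single-letter element symbols (upper case).
#' @export
atom_element <- function(name) {
  stripped <- sub("^[0-9]+", "", trimws(name))
  toupper(substr(stripped, 1, 1))
}

#' Is an atom a heavy (non-hydrogen) atom?
#' @param name character vector of atom names.
#' @return logical vector.
#' @export
is_heavy_atom <- function(name) atom_element(name) != "H"

#' Build a trajectory object
#'
#' @param coords numeric array `[n_frames, n_atoms, 3]` of coordinates in nm.
#' @param topology a [cd_topology()] table with one row per atom.
#' @param dt_ns frame interval in ns (e.g. 0.02 for a 20 ps write-out).
#' @param id optional trajectory identifier.
#' @return A list of class `"cd_trajectory"`.
#' @export
cd_trajectory <- function(coords, topology, dt_ns, id = "traj1") {
  stopifnot(inherits(topology, "cd_topology"))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be an [n_frames, n_atoms, 3] array")
  }
  if (dim(coords)[2] != nrow(topology)) {
    stop("coords atom dimension does not match topology")
  }
  if (!all(is.finite(coords))) stop("coords must be finite")
  stopifnot(is.numeric(dt_ns), dt_ns > 0)
  structure(list(coords = coords, topology = topology,
                 dt_ns = dt_ns, id = as.character(id)),
            class = "cd_trajectory")
}

#' Build an ensemble of trajectories sharing one topology
#'
#' @param trajectories list of [cd_trajectory()] objects.
#' @return A list of class `"cd_ensemble"`.
#' @export
cd_ensemble <- function(trajectories) {
  if (length(trajectories) == 0) stop("ensemble must contain >= 1 trajectory")
  stopifnot(all(vapply(trajectories, inherits, logical(1), "cd_trajectory")))
  ref <- trajectories[[1]]$topology
  for (tr in trajectories[-1]) {
    if (!identical(tr$topology$atom, ref$atom) ||
        !identical(tr$topology$resid, ref$resid)) {
      stop("all trajectories in an ensemble must share the same topology")
    }
  }
  nf <- sum(vapply(trajectories, function(tr) dim(tr$coords)[1], integer(1)))
  if (nf == 0) stop("ensemble contains zero frames")
  structure(list(trajectories = trajectories, topology = ref),
            class = "cd_ensemble")
}

#' @export
print.cd_ensemble <- function(x, ...) {
  nf <- vapply(x$trajectories, function(tr) dim(tr$coords)[1], integer(1))
  cat(sprintf("cd_ensemble: %d trajectories, %d atoms, %d residues, %s frames total\n",
              length(x$trajectories), nrow(x$topology),
              length(unique(x$topology$resid)), sum(nf)))
  invisible(x)
}

#' Read a coordinate ensemble from structure/trajectory files
#'
#' Each file becomes one trajectory. Multi-model PDB files are read with
#' `bio3d::read.pdb(multi = TRUE)`; DCD trajectories require a companion
#' topology PDB. Coordinates are converted from Angstrom to nm.
#'
#' @param files character vector of multi-model PDB files (or DCD files when
#'   `topology_file` is given).
#' @param dt_ns frame interval in ns.
#' @param topology_file optional PDB giving the topology for DCD input.
#' @return A [cd_ensemble()].
#' @export
read_structure_ensemble <- function(files, dt_ns, topology_file = NULL) {
  if (length(files) == 0) stop("no input files")
  trajs <- lapply(seq_along(files), function(i) {
    f <- files[[i]]
    if (!file.exists(f)) stop("input file does not exist: ", f)
    if (grepl("\\.dcd$", f, ignore.case = TRUE)) {
      if (is.null(topology_file)) stop("DCD input requires topology_file")
      pdb <- bio3d::read.pdb(topology_file)
      xyz <- bio3d::read.dcd(f, verbose = FALSE)
    } else {
      pdb <- bio3d::read.pdb(f, multi = TRUE)
      xyz <- pdb$xyz
    }
    top <- cd_topology(atom = pdb$atom$elety, resid = pdb$atom$resno)
    nfr <- nrow(xyz)
    nat <- ncol(xyz) / 3L
    coords <- aperm(array(t(xyz) / 10, dim = c(3L, nat, nfr)), c(3L, 2L, 1L))
    cd_trajectory(coords, top, dt_ns,
                  id = sub("\\.[^.]*$", "", basename(f)))
  })
  cd_ensemble(trajs)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are converted from nm to Angstrom. The residue name is a
#' generic "RES"; ligand atoms get chain B, protein atoms chain A.
#'
#' @param trajectory a [cd_trajectory()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure_pdb <- function(trajectory, file) {
  top <- trajectory$topology
  nfr <- dim(trajectory$coords)[1]
  nat <- dim(trajectory$coords)[2]
  xyz <- matrix(0, nfr, 3L * nat)
  for (k in 1:3) xyz[, seq(k, 3L * nat, by = 3L)] <- trajectory$coords[, , k] * 10
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = top$resid,
                   resid = rep("RES", nat),
                   elety = top$atom,
                   chain = ifelse(top$chain == "ligand", "B", "A"))
  invisible(file)
}
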