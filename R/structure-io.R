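#' @title Structures, trajectories and ligand annotations
#' @name structure_io
#' @description
#' The data model every other module consumes: an atom table (the topology),
#' per-frame coordinates in Angstrom, and a user-supplied ligand annotation
#' declaring which ligand atoms can act as hydrogen-bond donors/acceptors,
#' aromatic rings, charged groups and hydrophobes. Multi-model PDB files are
#' read and written through bio3d. No periodic-boundary handling is done:
#' input trajectories are assumed imaged/whole.
NULL

DEFAULT_WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "SPC")

#' Construct a trajectory object
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resseq`, `formal_charge`, `is_ligand`, `is_water`.
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param dt_ns time between frames in nanoseconds.
#' @return Object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, coords, dt_ns = 0.02) {
  need <- c("serial", "name", "element", "resname", "chain", "resseq",
            "formal_charge", "is_ligand", "is_water")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (dim(coords)[1] != nrow(atoms) || dim(coords)[2] != 3L)
    stop("coords must be n_atoms x 3 x n_frames with n_atoms == nrow(atoms)")
  if (dim(coords)[3] < 1L) stop("trajectory needs at least one frame")
  if (!is.numeric(dt_ns) || dt_ns <= 0) stop("dt_ns must be > 0")
  key <- paste(atoms$chain, atoms$resseq, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resseq, name) atom identifiers in topology")
  if (any(!nzchar(atoms$element)))
    stop("every atom needs a non-empty element symbol")
  structure(list(atoms = atoms, coords = coords,
                 n_frames = dim(coords)[3], dt_ns = dt_ns),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d atoms, %d frames, dt = %g ns (%g ns total)\n",
              nrow(x$atoms), x$n_frames, x$dt_ns, x$dt_ns * (x$n_frames - 1)))
  cat(sprintf("  ligand atoms: %d, water atoms: %d, protein atoms: %d\n",
              sum(x$atoms$is_ligand), sum(x$atoms$is_water),
              sum(!x$atoms$is_ligand & !x$atoms$is_water)))
  invisible(x)
}

#' Extract one frame's coordinates
#' @param traj an `md_trajectory`.
#' @param frame 1-based frame index.
#' @return n_atoms x 3 matrix.
#' @export
frame_coords <- function(traj, frame) {
  if (frame < 1 || frame > traj$n_frames)
    stop("frame index ", frame, " out of range 1..", traj$n_frames)
  traj$coords[, , frame, drop = TRUE]
}

#' Subset a trajectory's frames (topology is preserved)
#' @param traj an `md_trajectory`.
#' @param frames 1-based frame indices.
#' @export
slice_frames <- function(traj, frames) {
  if (!length(frames) || any(frames < 1 | frames > traj$n_frames))
    stop("frame indices out of range")
  md_trajectory(traj$atoms, traj$coords[, , frames, drop = FALSE], traj$dt_ns)
}

infer_element <- function(name) {
  ## PDB atom-name convention: strip digits/primes, two-letter elements only
  ## for a small known set; everything else takes its first letter.
  ## CA/NA are ambiguous with protein atom names and resolve to C/N here
  nm <- toupper(gsub("[0-9']", "", trimws(name)))
  two <- c("CL", "BR", "MG", "ZN", "FE", "MN")
  ifelse(nm %in% two, substr(nm, 1, 2), substr(nm, 1, 1))
}

#' Read a multi-model PDB file as a trajectory
#'
#' One frame per MODEL block (a single-model file yields one frame). Atoms
#' whose residue name is in `ligand_resnames` / `water_resnames` are flagged
#' accordingly. Elements missing from the element column are inferred from
#' the atom name with a warning.
#'
#' @param path PDB file.
#' @param ligand_resnames character vector of ligand residue names.
#' @param water_resnames water residue names
#'   (default HOH, WAT, TIP3, SPC).
#' @param dt_ns frame spacing in ns (default 0.02, i.e. 5000 frames per
#'   100 ns).
#' @return An [md_trajectory()].
#' @export
read_multimodel_pdb <- function(path, ligand_resnames = character(),
                                water_resnames = DEFAULT_WATER_RESNAMES,
                                dt_ns = 0.02) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_model_atom_counts(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  missing_el <- is.na(elem) | !nzchar(trimws(elem))
  if (any(missing_el)) {
    warning(sum(missing_el), " atoms lack an element symbol; inferred from atom names")
    elem[missing_el] <- infer_element(at$elety[missing_el])
  }
  charge <- suppressWarnings(as.integer(at$charge))
  charge[is.na(charge)] <- 0L
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = trimws(elem),
    resname = trimws(at$resid), chain = chain, resseq = at$resno,
    formal_charge = charge,
    is_ligand = trimws(at$resid) %in% ligand_resnames,
    is_water = trimws(at$resid) %in% water_resnames,
    stringsAsFactors = FALSE)
  n_at <- nrow(atoms)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_fr <- nrow(xyz)
  coords <- array(0, c(n_at, 3, n_fr))
  for (f in seq_len(n_fr))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  md_trajectory(atoms, coords, dt_ns = dt_ns)
}

## MODEL blocks must share one atom ordering; report the offending model.
check_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) < 2) return(invisible(TRUE))
  model_ends <- which(rec == "ENDMDL")
  counts <- mapply(function(s, e) sum(rec[s:e] %in% c("ATOM  ", "HETATM")),
                   model_starts, model_ends[seq_along(model_starts)])
  if (length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("inconsistent atom count in MODEL %d (%d atoms vs %d in MODEL 1)",
                 bad, counts[bad], counts[1]))
  }
  invisible(TRUE)
}

#' Write a trajectory (or a frame selection) as a multi-model PDB
#'
#' Fixed-width PDB columns, coordinates to three decimals. By default MODEL/
#' ENDMDL records are written even for a single frame.
#'
#' @param traj an [md_trajectory()].
#' @param path output file.
#' @param frame_indices 1-based frames to write (default: all).
#' @param model_records keep MODEL records for a single-frame write.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path, frame_indices = NULL, model_records = TRUE) {
  if (is.null(frame_indices)) frame_indices <- seq_len(traj$n_frames)
  if (!length(frame_indices)) stop("empty frame selection")
  if (any(frame_indices < 1 | frame_indices > traj$n_frames))
    stop("frame index out of range 1..", traj$n_frames)
  at <- traj$atoms
  n_fr <- length(frame_indices)
  xyz <- matrix(0, n_fr, nrow(at) * 3)
  for (i in seq_len(n_fr))
    xyz[i, ] <- as.vector(t(frame_coords(traj, frame_indices[i])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(at$is_ligand | at$is_water, "HETATM", "ATOM"),
                   resno = at$resseq, resid = at$resname, eleno = at$serial,
                   elety = at$name, chain = at$chain, elesy = at$element)
  if (n_fr == 1L) {
    ## bio3d writes a bare single model; add or keep MODEL records as asked
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!(substr(lines, 1, 6) %in% c("MODEL ", "ENDMDL"))]
    if (model_records) {
      last_atom <- max(which(substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")))
      lines <- c("MODEL        1", lines[seq_len(last_atom)], "ENDMDL",
                 lines[-seq_len(last_atom)])
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read and validate a ligand annotation file
#'
#' JSON file declaring the interaction-capable sites of the ligand:
#' \preformatted{
#' {
#'   "ligand_resname": "LIG",
#'   "donors":      [["N1","HN1"], ...],
#'   "acceptors":   [{"atom":"O1","neighbors":["C1"]}, ...],
#'   "rings":       [["C2","C3","C4","C5","C6","C7"], ...],
#'   "cations":     [{"atoms":["N2"],"charge":1}, ...],
#'   "anions":      [{"atoms":["O3"],"charge":-1}, ...],
#'   "hydrophobes": ["C8","C9"]
#' }
#' }
#' Every named atom must exist in the ligand residue of `traj`; unknown
#' names raise a validation error listing all offenders. Empty lists are
#' valid (a ligand without aromatic rings simply has no `rings`).
#'
#' @param path annotation JSON (or a pre-parsed list).
#' @param traj an [md_trajectory()] whose ligand the annotation describes.
#' @return Validated annotation list of class `ligand_annotation`.
#' @export
read_ligand_annotation <- function(path, traj) {
  ann <- if (is.character(path))
    jsonlite::fromJSON(path, simplifyVector = FALSE) else path
  validate_ligand_annotation(ann, traj)
}

validate_ligand_annotation <- function(ann, traj) {
  lig <- traj$atoms[traj$atoms$is_ligand, , drop = FALSE]
  if (!nrow(lig)) stop("trajectory has no ligand atoms to annotate")
  known <- lig$name
  named <- c(
    unlist(ann$donors, use.names = FALSE),
    unlist(lapply(ann$acceptors, function(a) c(a$atom, unlist(a$neighbors))),
           use.names = FALSE),
    unlist(ann$rings, use.names = FALSE),
    unlist(lapply(ann$cations, function(g) unlist(g$atoms)), use.names = FALSE),
    unlist(lapply(ann$anions, function(g) unlist(g$atoms)), use.names = FALSE),
    unlist(ann$hydrophobes, use.names = FALSE))
  bad <- setdiff(unique(named), known)
  if (length(bad))
    stop("ligand annotation names atoms absent from the ligand residue: ",
         paste(bad, collapse = ", "))
  for (r in ann$rings)
    if (length(unlist(r)) < 5)
      stop("aromatic ring must have at least 5 atoms")
  ann$ligand_resname <- ann$ligand_resname %||% lig$resname[1]
  class(ann) <- "ligand_annotation"
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ligand annotation to JSON
#' @param ann a `ligand_annotation` (or compatible list).
#' @param path output file.
#' @export
write_ligand_annotation <- function(ann, path) {
  jsonlite::write_json(unclass(ann), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
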