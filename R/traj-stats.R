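#' @title Superposition, RMSD and RMSF
#' @name traj_stats
#' @description
#' Least-squares (Kabsch) rigid-body superposition and the trajectory
#' statistics built on it: RMSD time series of a selection after alignment
#' on a (possibly different) selection, and per-residue RMSF profiles.
NULL

#' Atom selection helpers
#'
#' @param traj an [md_trajectory()].
#' @return Integer atom indices.
#' @name selections
NULL

#' @rdname selections
#' @export
select_calpha <- function(traj) {
  with(traj$atoms, which(!is_ligand & !is_water & name == "CA"))
}

#' @rdname selections
#' @export
select_ligand_heavy <- function(traj) {
  with(traj$atoms, which(is_ligand & toupper(element) != "H"))
}

#' @rdname selections
#' @export
select_protein_heavy <- function(traj) {
  with(traj$atoms, which(!is_ligand & !is_water & toupper(element) != "H"))
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` (determinant +1, reflections excluded) and
#' translation minimizing the weighted RMSD between `mobile` and
#' `reference`. The aligned coordinates are
#' `sweep(mobile, 2, cm) \%*\% R + rep(cr, each = n)` where `cm`/`cr` are
#' the (weighted) centroids; [apply_transform()] does this for you.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, with
#'   non-degenerate (non-collinear) spread.
#' @param weights optional non-negative per-point weights.
#' @return List with `R` (3 x 3 rotation), `center_mobile`,
#'   `center_reference`, and `rmsd` (Angstrom, after superposition).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference) || ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("mobile and reference must be equal-size n x 3 matrices")
  if (n < 3L) stop("superposition needs at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  C <- t(A * w) %*% B
  sv <- svd(C)
  spread <- svd(t(B * w) %*% B)$d
  if (spread[2] < 1e-10 * max(spread[1], 1e-300))
    stop("degenerate (collinear or coincident) point set: rotation is not unique")
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- A %*% R
  rmsd <- sqrt(sum(w * rowSums((aligned - B)^2)))
  list(R = R, center_mobile = cm, center_reference = cr, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz n x 3 coordinates.
#' @param fit a [kabsch_superpose()] result.
#' @return Transformed n x 3 coordinates.
#' @export
apply_transform <- function(xyz, fit) {
  sweep(sweep(as.matrix(xyz), 2, fit$center_mobile) %*% fit$R,
        2, fit$center_reference, "+")
}

rmsd_plain <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD time series
#'
#' Each frame is rigidly aligned to the reference frame on
#' `alignment_selection` (default: the measured selection itself; for a
#' protein series use the protein C-alpha set for both). RMSD is then
#' measured over `selection` without a second fit -- so with
#' `selection = ligand heavy atoms` and `alignment_selection = protein
#' C-alpha` the series reports the ligand's drift within the pocket
#' (ligand equilibration relative to the protein), not its internal motion.
#'
#' @param traj an [md_trajectory()].
#' @param selection atom indices measured.
#' @param alignment_selection atom indices used for the fit
#'   (default `selection`).
#' @param reference_frame 1-based reference frame (default 1).
#' @return Object of class `rmsd_series`: list with `values` (Angstrom per
#'   frame), `time_ns`, `reference_frame`, `selection`,
#'   `alignment_selection`.
#' @export
rmsd_series <- function(traj, selection, alignment_selection = selection,
                        reference_frame = 1) {
  if (!length(selection) || !length(alignment_selection))
    stop("empty selection")
  ref <- frame_coords(traj, reference_frame)
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    xyz <- frame_coords(traj, f)
    fit <- kabsch_superpose(xyz[alignment_selection, , drop = FALSE],
                            ref[alignment_selection, , drop = FALSE])
    rmsd_plain(apply_transform(xyz[selection, , drop = FALSE], fit),
               ref[selection, , drop = FALSE])
  }, numeric(1))
  structure(list(values = vals,
                 time_ns = (seq_len(traj$n_frames) - 1) * traj$dt_ns,
                 reference_frame = reference_frame, selection = selection,
                 alignment_selection = alignment_selection),
            class = "rmsd_series")
}

#' Per-residue RMSF profile
#'
#' Every frame is aligned to the reference on `alignment_selection`; the
#' fluctuation of each selected atom is then
#' `sqrt(mean over frames of |r - rbar|^2)` about its mean aligned
#' position, reported per residue at the C-alpha atom (default basis).
#' For isotropic per-coordinate Gaussian jitter of width sigma the profile
#' converges to `sigma * sqrt(3)`.
#'
#' @param traj an [md_trajectory()] with at least 2 frames.
#' @param alignment_selection atoms used for the fit
#'   (default: protein C-alpha).
#' @param atom_selection atoms whose RMSF is reported
#'   (default: protein C-alpha).
#' @param reference `"first"` aligns to frame 1; `"mean"` additionally
#'   re-aligns to the mean structure once.
#' @return data.frame `chain, resseq, resname, rmsf` of class
#'   `rmsf_profile`.
#' @export
rmsf_profile <- function(traj, alignment_selection = select_calpha(traj),
                         atom_selection = select_calpha(traj),
                         reference = c("first", "mean")) {
  reference <- match.arg(reference)
  if (traj$n_frames < 2L) stop("RMSF needs at least 2 frames")
  if (!length(alignment_selection) || !length(atom_selection))
    stop("empty selection")
  aligned <- aligned_coords(traj, alignment_selection, atom_selection,
                            frame_coords(traj, 1))
  if (reference == "mean") {
    ## one re-alignment pass against the mean structure on the fit atoms
    mean_ref <- apply(aligned_coords(traj, alignment_selection,
                                     alignment_selection,
                                     frame_coords(traj, 1)), c(1, 2), mean)
    ref2 <- frame_coords(traj, 1)
    ref2[alignment_selection, ] <- mean_ref
    aligned <- aligned_coords(traj, alignment_selection, atom_selection, ref2)
  }
  rbar <- apply(aligned, c(1, 2), mean)
  dev2 <- sweep(aligned, c(1, 2), rbar)^2
  ## dev2 is atoms x 3 x frames; mean over frames of the squared deviation norm
  rmsf <- sqrt(rowMeans(apply(dev2, 3, rowSums)))
  at <- traj$atoms[atom_selection, ]
  out <- data.frame(chain = at$chain, resseq = at$resseq,
                    resname = at$resname, rmsf = rmsf,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rmsf_profile", class(out))
  out
}

## atoms(sel) x 3 x frames array of coordinates after per-frame alignment
aligned_coords <- function(traj, alignment_selection, atom_selection, ref) {
  out <- array(0, c(length(atom_selection), 3, traj$n_frames))
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    fit <- kabsch_superpose(xyz[alignment_selection, , drop = FALSE],
                            ref[alignment_selection, , drop = FALSE])
    out[, , f] <- apply_transform(xyz[atom_selection, , drop = FALSE], fit)
  }
  out
}
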