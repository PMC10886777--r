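#' @title Ligand-pose clustering and representative-frame selection
#' @name clustering
#' @description
#' Clusters trajectory frames by ligand pose and returns the representative
#' complex: the medoid frame of the most populated cluster -- the geometry
#' most often visited during the simulation.
NULL

#' Cluster ligand poses over a strided trajectory
#'
#' Analyzed frames are taken every `stride` frames (a 5000-frame trajectory
#' at stride 10 yields 500 analyzed frames). Every analyzed frame is
#' aligned to the first analyzed frame on the protein C-alpha atoms; the
#' pairwise ligand-heavy-atom RMSD matrix is then clustered by
#' average-linkage hierarchical clustering cut at `cutoff` Angstrom. The
#' representative frame is the medoid of the largest cluster (minimum
#' summed RMSD to its members); all ties break to the lowest frame index.
#'
#' @param traj an [md_trajectory()] containing a ligand and protein
#'   C-alpha atoms.
#' @param stride frame stride (default 10).
#' @param cutoff linkage-height cut in Angstrom (default 2.0).
#' @param method `stats::hclust` linkage (default `"average"`).
#' @return Object of class `cluster_result`: list with
#'   `frames_analyzed` (original 1-based frame indices), `labels`
#'   (cluster id per analyzed frame, relabelled so cluster 1 is largest),
#'   `sizes`, `representative_frame` (original frame index),
#'   `cutoff`, `stride`, and `rmsd` (the analyzed-frame RMSD matrix).
#' @export
cluster_ligand_poses <- function(traj, stride = 10, cutoff = 2.0,
                                 method = "average") {
  if (stride < 1) stop("stride must be >= 1")
  if (stride >= traj$n_frames)
    stop("stride (", stride, ") must be smaller than n_frames (",
         traj$n_frames, ")")
  frames <- seq(1L, traj$n_frames, by = as.integer(stride))
  if (length(frames) < 2L) stop("need at least 2 analyzed frames after stride")
  ca <- select_calpha(traj)
  lig <- select_ligand_heavy(traj)
  if (length(ca) < 3L) stop("protein C-alpha alignment set too small")
  if (!length(lig)) stop("no ligand heavy atoms found")
  ref <- frame_coords(traj, frames[1])
  flat <- matrix(0, length(frames), 3 * length(lig))
  for (i in seq_along(frames)) {
    xyz <- frame_coords(traj, frames[i])
    fit <- kabsch_superpose(xyz[ca, , drop = FALSE], ref[ca, , drop = FALSE])
    flat[i, ] <- as.vector(apply_transform(xyz[lig, , drop = FALSE], fit))
  }
  ## Euclidean distance of flattened aligned coordinates / sqrt(n) == RMSD
  D <- stats::dist(flat) / sqrt(length(lig))
  hc <- stats::hclust(D, method = method)
  raw <- stats::cutree(hc, h = cutoff)
  ## relabel clusters by decreasing size; ties by lowest analyzed frame index
  sizes <- table(raw)
  first_frame <- vapply(names(sizes), function(k) min(which(raw == as.integer(k))),
                        numeric(1))
  ord <- order(-as.integer(sizes), first_frame)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  labels <- relabel[raw]
  Dm <- as.matrix(D)
  members <- which(labels == 1L)
  sums <- if (length(members) == 1L) 0
          else rowSums(Dm[members, members, drop = FALSE])
  rep_local <- members[which.min(sums)]  # which.min already takes the first tie
  structure(list(frames_analyzed = frames, labels = labels,
                 sizes = as.integer(table(labels)),
                 representative_frame = frames[rep_local],
                 cutoff = cutoff, stride = stride, method = method,
                 rmsd = Dm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d analyzed frames (stride %d), %d clusters at %.2f Angstrom\n",
              length(x$frames_analyzed), x$stride, length(x$sizes), x$cutoff))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat(sprintf("  representative frame: %d (medoid of largest cluster)\n",
              x$representative_frame))
  invisible(x)
}

#' Write the representative complex of a clustering result as PDB
#'
#' @param traj the clustered [md_trajectory()].
#' @param result a [cluster_ligand_poses()] result.
#' @param path output PDB path.
#' @export
write_representative <- function(traj, result, path) {
  write_pdb(traj, path, frame_indices = result$representative_frame)
}
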