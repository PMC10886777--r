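#' @title End-to-end analysis pipeline
#' @name pipeline
#' @description
#' Orchestrates the full analysis from one configuration: reactivity
#' descriptors (when an energy table is given), interaction fingerprinting,
#' RMSD/RMSF statistics, pose clustering with representative-frame
#' extraction, and a side-by-side contact-frequency comparison when two
#' trajectories (e.g. two candidate ligands against one target) are given.
#' Every output file is listed with its checksum in a machine-readable
#' manifest, and all thresholds are echoed there so results are
#' self-describing.
NULL

#' Read and validate an analysis configuration
#'
#' YAML or JSON with fields:
#' \preformatted{
#' trajectories:            # one or two entries
#'   - id: ligandA
#'     path: trajA.pdb
#'     annotation: ligA.json
#' ligand_resname: LIG
#' criteria: {hbond_max_HA: 2.5, ...}   # optional overrides
#' stride: 10
#' cluster_cutoff: 2.0
#' dt_ns: 0.02
#' energies: species.csv    # optional
#' energies_from_orbitals: false
#' outdir: results/
#' }
#'
#' @param path config file, or a pre-built list.
#' @return Validated config list of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(cfg$trajectories) || !length(cfg$trajectories))
    stop("config must list at least one trajectory")
  if (length(cfg$trajectories) > 2)
    stop("at most two trajectories (a compound pair) are compared")
  for (tr in cfg$trajectories) {
    if (is.null(tr$id) || is.null(tr$path) || is.null(tr$annotation))
      stop("each trajectory entry needs id, path and annotation")
    for (f in c(tr$path, tr$annotation))
      if (!file.exists(f)) stop("config references missing file: ", f)
  }
  if (!is.null(cfg$energies) && !file.exists(cfg$energies))
    stop("config references missing file: ", cfg$energies)
  cfg$ligand_resname <- cfg$ligand_resname %||% "LIG"
  cfg$stride <- cfg$stride %||% 10
  cfg$cluster_cutoff <- cfg$cluster_cutoff %||% 2.0
  cfg$dt_ns <- cfg$dt_ns %||% 0.02
  cfg$outdir <- cfg$outdir %||% "pocketfp_out"
  cfg$criteria_obj <- do.call(interaction_criteria, cfg$criteria %||% list())
  class(cfg) <- "analysis_config"
  cfg
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' For each configured trajectory: detect all interactions over all
#' frames, write the contact-frequency table, per-(residue, kind)
#' timelines, protein and ligand-in-pocket RMSD series, the C-alpha RMSF
#' profile, the pose clustering assignment and the representative-complex
#' PDB. With an energy table, the descriptor table is written; with two
#' trajectories, a merged contact-frequency comparison. A `manifest.json`
#' records every output with its MD5 checksum plus the criteria and
#' parameters used. Any stage failure aborts with an error naming the
#' stage.
#'
#' @param config path to a config file or an `analysis_config`.
#' @return The manifest, invisibly.
#' @export
run_analysis <- function(config) {
  cfg <- if (inherits(config, "analysis_config")) config
         else read_analysis_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  freq_tables <- list()
  for (tr in cfg$trajectories) {
    id <- tr$id
    traj <- stage(paste0(id, ":read"), read_multimodel_pdb(
      tr$path, ligand_resnames = cfg$ligand_resname, dt_ns = cfg$dt_ns))
    ann <- stage(paste0(id, ":annotation"),
                 read_ligand_annotation(tr$annotation, traj))
    model <- stage(paste0(id, ":model"), build_model(traj, ann))
    events <- stage(paste0(id, ":fingerprint"),
                    detect_trajectory(traj, model, cfg$criteria_obj))
    freq <- aggregate_contacts(events, traj$n_frames)
    freq_tables[[id]] <- freq
    p <- file.path(cfg$outdir, paste0(id, "_contact_frequencies.csv"))
    write_csv_plain(as.data.frame(freq), p); outputs <- c(outputs, p)
    p <- file.path(cfg$outdir, paste0(id, "_events.csv"))
    write_csv_plain(tidy_events(events), p); outputs <- c(outputs, p)
    ## timelines for every observed (residue, kind)
    tl <- stage(paste0(id, ":timeline"), {
      keys <- unique(as.data.frame(freq)[, c("chain", "resseq", "kind")])
      do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
        t <- contact_timeline(events, traj$n_frames, keys$chain[i],
                              keys$resseq[i], keys$kind[i])
        data.frame(chain = keys$chain[i], resseq = keys$resseq[i],
                   kind = keys$kind[i], frame = seq_len(traj$n_frames),
                   count = t$counts, stringsAsFactors = FALSE)
      }))
    })
    if (!is.null(tl)) {
      p <- file.path(cfg$outdir, paste0(id, "_timelines.csv"))
      write_csv_plain(tl, p); outputs <- c(outputs, p)
    }
    ## RMSD / RMSF
    ca <- select_calpha(traj)
    lig <- select_ligand_heavy(traj)
    stats_ok <- length(ca) >= 3 && traj$n_frames >= 2
    if (stats_ok) {
      rp <- stage(paste0(id, ":rmsd"), rmsd_series(traj, ca, ca))
      rl <- stage(paste0(id, ":rmsd"), rmsd_series(traj, lig, ca))
      p <- file.path(cfg$outdir, paste0(id, "_rmsd.csv"))
      write_csv_plain(data.frame(frame = seq_len(traj$n_frames),
                                 time_ns = rp$time_ns,
                                 protein_ca = rp$values,
                                 ligand_in_pocket = rl$values), p)
      outputs <- c(outputs, p)
      rf <- stage(paste0(id, ":rmsf"), rmsf_profile(traj))
      p <- file.path(cfg$outdir, paste0(id, "_rmsf.csv"))
      write_csv_plain(as.data.frame(rf), p); outputs <- c(outputs, p)
    }
    ## clustering + representative complex
    if (traj$n_frames > cfg$stride) {
      cl <- stage(paste0(id, ":cluster"),
                  cluster_ligand_poses(traj, stride = cfg$stride,
                                       cutoff = cfg$cluster_cutoff))
      p <- file.path(cfg$outdir, paste0(id, "_clusters.csv"))
      write_csv_plain(data.frame(frame = cl$frames_analyzed,
                                 cluster = cl$labels), p)
      outputs <- c(outputs, p)
      p <- file.path(cfg$outdir, paste0(id, "_representative.pdb"))
      write_representative(traj, cl, p); outputs <- c(outputs, p)
    }
  }
  ## descriptor table
  if (!is.null(cfg$energies)) {
    sp <- stage("descriptors", read_species_table(
      cfg$energies, from_orbitals = isTRUE(cfg$energies_from_orbitals)))
    p <- file.path(cfg$outdir, "descriptors.csv")
    write_csv_plain(stage("descriptors", descriptor_table(sp)), p)
    outputs <- c(outputs, p)
  }
  ## side-by-side comparison of two ligands
  if (length(freq_tables) == 2L) {
    ids <- names(freq_tables)
    a <- as.data.frame(freq_tables[[1]]); b <- as.data.frame(freq_tables[[2]])
    cmp <- merge(a[, c("chain", "resseq", "resname", "kind", "value")],
                 b[, c("chain", "resseq", "resname", "kind", "value")],
                 by = c("chain", "resseq", "resname", "kind"), all = TRUE,
                 suffixes = paste0("_", ids))
    cmp[is.na(cmp)] <- 0
    cmp <- cmp[order(cmp$chain, cmp$resseq, cmp$kind), ]
    p <- file.path(cfg$outdir, "comparison.csv")
    write_csv_plain(cmp, p); outputs <- c(outputs, p)
  }
  manifest <- list(
    package = "pocketfp",
    parameters = list(ligand_resname = cfg$ligand_resname,
                      stride = cfg$stride,
                      cluster_cutoff = cfg$cluster_cutoff,
                      dt_ns = cfg$dt_ns,
                      criteria = unclass(cfg$criteria_obj)),
    trajectories = lapply(cfg$trajectories, function(tr)
      list(id = tr$id, path = tr$path, annotation = tr$annotation)),
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  mp <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
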