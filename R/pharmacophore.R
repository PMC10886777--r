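#' @title Pharmacophore typing
#' @name pharmacophore
#' @description
#' Assigns interaction-capable roles (hydrogen-bond donor/acceptor, aromatic
#' ring, formally charged group, hydrophobe) to protein residues and waters
#' from built-in templates for the 20 standard amino acids, and merges them
#' with the user's ligand annotation into one pharmacophore model consumed
#' by the interaction detectors.
#'
#' Protein formal charges are fixed by template (LYS +1, ARG +1, ASP -1,
#' GLU -1; termini ignored) and HIS is treated as a neutral pi ring with
#' donor/acceptor nitrogens -- no protonation-state inference is attempted.
#' Donor hydrogens are located geometrically: an element-H atom of the same
#' residue within 1.3 Angstrom of the donor heavy atom in frame 1.
NULL

residue_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "residue_templates.json",
                          package = "pocketfp", mustWork = TRUE)
      tpl <- jsonlite::fromJSON(path, simplifyVector = FALSE)
      tpl[["_comment"]] <- NULL
      cache <<- tpl
    }
    cache
  }
})

MAX_DH_BOND <- 1.3  # Angstrom; H belongs to a donor heavy atom below this

empty_model <- function() {
  list(
    donors = data.frame(d = integer(), h = integer(), owner = character(),
                        chain = character(), resseq = integer(),
                        resname = character(), label = character(),
                        stringsAsFactors = FALSE),
    acceptors = data.frame(a = integer(), owner = character(),
                           chain = character(), resseq = integer(),
                           resname = character(), label = character(),
                           stringsAsFactors = FALSE),
    acceptor_nbrs = list(),
    rings = list(),
    cations = list(),
    anions = list(),
    hydrophobes = data.frame(idx = integer(), owner = character(),
                             chain = character(), resseq = integer(),
                             resname = character(), label = character(),
                             stringsAsFactors = FALSE))
}

merge_models <- function(a, b) {
  a$donors <- rbind(a$donors, b$donors)
  a$acceptors <- rbind(a$acceptors, b$acceptors)
  a$acceptor_nbrs <- c(a$acceptor_nbrs, b$acceptor_nbrs)
  a$rings <- c(a$rings, b$rings)
  a$cations <- c(a$cations, b$cations)
  a$anions <- c(a$anions, b$anions)
  a$hydrophobes <- rbind(a$hydrophobes, b$hydrophobes)
  a
}

## hydrogens (element H) of `resrows` within MAX_DH_BOND of heavy atom `d`
attached_hydrogens <- function(d, resrows, xyz) {
  hs <- resrows[tolower(resrows$element_) == "h" & resrows$row != d, ]
  if (!nrow(hs)) return(integer())
  dd <- sqrt(colSums((t(xyz[hs$row, , drop = FALSE]) - xyz[d, ])^2))
  hs$row[dd < MAX_DH_BOND]
}

residue_rows <- function(atoms) {
  data.frame(row = seq_len(nrow(atoms)), name_ = atoms$name,
             element_ = atoms$element, stringsAsFactors = FALSE)
}

#' Type protein residues from the built-in templates
#'
#' Backbone N (with an amide hydrogen; PRO excluded) becomes a donor and
#' backbone O an acceptor for every residue; side-chain sites follow the
#' template table (see the packaged `residue_templates.json`, which users
#' can extend). Residues with non-template names are skipped with a warning.
#'
#' @param traj an [md_trajectory()].
#' @return Pharmacophore entry set (protein-owned).
#' @export
type_protein <- function(traj) {
  tpl <- residue_templates()
  atoms <- traj$atoms
  xyz <- frame_coords(traj, 1)
  prot <- which(!atoms$is_ligand & !atoms$is_water)
  model <- empty_model()
  if (!length(prot)) return(model)
  key <- paste(atoms$chain[prot], atoms$resseq[prot])
  skipped <- character()
  for (res in split(prot, factor(key, levels = unique(key)))) {
    rn <- atoms$resname[res[1]]
    ch <- atoms$chain[res[1]]
    rs <- atoms$resseq[res[1]]
    if (is.null(tpl[[rn]])) { skipped <- c(skipped, rn); next }
    t <- tpl[[rn]]
    rr <- residue_rows(atoms)[res, ]
    rr$name_ <- atoms$name[res]
    find <- function(nm) rr$row[match(nm, rr$name_)]
    m <- empty_model()
    ## backbone donor/acceptor
    bbN <- find("N")
    if (!is.na(bbN) && rn != "PRO") {
      for (h in attached_hydrogens(bbN, rr, xyz))
        m$donors[nrow(m$donors) + 1L, ] <-
          list(bbN, h, "protein", ch, rs, rn,
               paste0("don:N-", atoms$name[h]))
    }
    bbO <- find("O")
    if (!is.na(bbO)) {
      bbC <- find("C")
      m$acceptors[nrow(m$acceptors) + 1L, ] <-
        list(bbO, "protein", ch, rs, rn, "acc:O")
      m$acceptor_nbrs <- c(m$acceptor_nbrs,
                           list(if (is.na(bbC)) integer() else bbC))
    }
    ## side-chain donors
    for (dn in t$donors %||% list()) {
      d <- find(dn)
      if (is.na(d)) next
      for (h in attached_hydrogens(d, rr, xyz))
        m$donors[nrow(m$donors) + 1L, ] <-
          list(d, h, "protein", ch, rs, rn,
               paste0("don:", dn, "-", atoms$name[h]))
    }
    ## side-chain acceptors
    for (ac in t$acceptors %||% list()) {
      a <- find(ac$atom)
      if (is.na(a)) next
      nb <- stats::na.omit(vapply(unlist(ac$neighbors), find, integer(1)))
      m$acceptors[nrow(m$acceptors) + 1L, ] <-
        list(a, "protein", ch, rs, rn, paste0("acc:", ac$atom))
      m$acceptor_nbrs <- c(m$acceptor_nbrs, list(as.integer(nb)))
    }
    ## rings
    for (rg in t$rings %||% list()) {
      ix <- vapply(unlist(rg), find, integer(1))
      if (anyNA(ix)) next
      m$rings <- c(m$rings, list(list(
        atoms = as.integer(ix), owner = "protein", chain = ch, resseq = rs,
        resname = rn, label = paste0("ring:", paste(unlist(rg), collapse = "")))))
    }
    ## charged groups
    for (g in t$cations %||% list()) {
      ix <- stats::na.omit(vapply(unlist(g$atoms), find, integer(1)))
      if (!length(ix)) next
      m$cations <- c(m$cations, list(list(
        atoms = as.integer(ix), charge = g$charge, owner = "protein",
        chain = ch, resseq = rs, resname = rn,
        label = paste0("cat:", paste(atoms$name[ix], collapse = "+")))))
    }
    for (g in t$anions %||% list()) {
      ix <- stats::na.omit(vapply(unlist(g$atoms), find, integer(1)))
      if (!length(ix)) next
      m$anions <- c(m$anions, list(list(
        atoms = as.integer(ix), charge = g$charge, owner = "protein",
        chain = ch, resseq = rs, resname = rn,
        label = paste0("ani:", paste(atoms$name[ix], collapse = "+")))))
    }
    ## hydrophobes
    for (hp in t$hydrophobes %||% list()) {
      i <- find(hp)
      if (is.na(i)) next
      m$hydrophobes[nrow(m$hydrophobes) + 1L, ] <-
        list(i, "protein", ch, rs, rn, paste0("hyd:", hp))
    }
    model <- merge_models(model, m)
  }
  if (length(skipped))
    warning("skipped non-template residues: ",
            paste(unique(skipped), collapse = ", "))
  model
}

#' Type water molecules
#'
#' Each water oxygen becomes an acceptor (its hydrogens are the bonded
#' neighbors) and each attached hydrogen a donor pair. Waters without
#' hydrogens are excluded from donor duty with a warning (they cannot
#' relay a water bridge).
#'
#' @param traj an [md_trajectory()].
#' @return Pharmacophore entry set (water-owned).
#' @export
type_waters <- function(traj) {
  atoms <- traj$atoms
  xyz <- frame_coords(traj, 1)
  wat <- which(atoms$is_water)
  model <- empty_model()
  if (!length(wat)) return(model)
  key <- paste(atoms$chain[wat], atoms$resseq[wat])
  dry <- 0L
  for (res in split(wat, factor(key, levels = unique(key)))) {
    ch <- atoms$chain[res[1]]; rs <- atoms$resseq[res[1]]
    rn <- atoms$resname[res[1]]
    o <- res[toupper(atoms$element[res]) == "O"]
    if (!length(o)) next
    o <- o[1]
    rr <- residue_rows(atoms)[res, ]
    hs <- attached_hydrogens(o, rr, xyz)
    model$acceptors[nrow(model$acceptors) + 1L, ] <-
      list(o, "water", ch, rs, rn, "acc:O")
    model$acceptor_nbrs <- c(model$acceptor_nbrs, list(as.integer(hs)))
    if (!length(hs)) { dry <- dry + 1L; next }
    for (h in hs)
      model$donors[nrow(model$donors) + 1L, ] <-
        list(o, h, "water", ch, rs, rn, paste0("don:O-", atoms$name[h]))
  }
  if (dry > 0)
    warning(dry, " water(s) without hydrogens excluded from water-bridge donor duty")
  model
}

ligand_model <- function(traj, annotation) {
  atoms <- traj$atoms
  lig <- which(atoms$is_ligand)
  ch <- atoms$chain[lig[1]]; rs <- atoms$resseq[lig[1]]
  rn <- atoms$resname[lig[1]]
  find <- function(nm) lig[match(nm, atoms$name[lig])]
  m <- empty_model()
  for (dp in annotation$donors %||% list()) {
    dp <- unlist(dp)
    m$donors[nrow(m$donors) + 1L, ] <-
      list(find(dp[1]), find(dp[2]), "ligand", ch, rs, rn,
           paste0("don:", dp[1], "-", dp[2]))
  }
  for (ac in annotation$acceptors %||% list()) {
    nb <- vapply(unlist(ac$neighbors), find, integer(1))
    m$acceptors[nrow(m$acceptors) + 1L, ] <-
      list(find(ac$atom), "ligand", ch, rs, rn, paste0("acc:", ac$atom))
    m$acceptor_nbrs <- c(m$acceptor_nbrs, list(as.integer(nb)))
  }
  for (rg in annotation$rings %||% list()) {
    nms <- unlist(rg)
    m$rings <- c(m$rings, list(list(
      atoms = vapply(nms, find, integer(1)), owner = "ligand", chain = ch,
      resseq = rs, resname = rn,
      label = paste0("ring:", paste(nms, collapse = "")))))
  }
  for (g in annotation$cations %||% list()) {
    nms <- unlist(g$atoms)
    m$cations <- c(m$cations, list(list(
      atoms = vapply(nms, find, integer(1)), charge = g$charge,
      owner = "ligand", chain = ch, resseq = rs, resname = rn,
      label = paste0("cat:", paste(nms, collapse = "+")))))
  }
  for (g in annotation$anions %||% list()) {
    nms <- unlist(g$atoms)
    m$anions <- c(m$anions, list(list(
      atoms = vapply(nms, find, integer(1)), charge = g$charge,
      owner = "ligand", chain = ch, resseq = rs, resname = rn,
      label = paste0("ani:", paste(nms, collapse = "+")))))
  }
  for (hp in annotation$hydrophobes %||% list()) {
    m$hydrophobes[nrow(m$hydrophobes) + 1L, ] <-
      list(find(hp), "ligand", ch, rs, rn, paste0("hyd:", hp))
  }
  m
}

#' Build the full pharmacophore model
#'
#' Union of the ligand annotation's sites with template-typed protein and
#' water entries, each tagged with its owner. Ring centroids and normals
#' are not stored -- they are computed per frame on demand by the detectors.
#'
#' @param traj an [md_trajectory()].
#' @param annotation a validated [read_ligand_annotation()] result (or a
#'   compatible list, which will be validated).
#' @return Object of class `pharmacophore_model`.
#' @export
build_model <- function(traj, annotation = NULL) {
  model <- empty_model()
  if (any(traj$atoms$is_ligand)) {
    if (is.null(annotation))
      stop("trajectory has a ligand: a ligand annotation is required")
    if (!inherits(annotation, "ligand_annotation"))
      annotation <- validate_ligand_annotation(annotation, traj)
    model <- merge_models(model, ligand_model(traj, annotation))
  }
  model <- merge_models(model, type_protein(traj))
  model <- merge_models(model, type_waters(traj))
  class(model) <- "pharmacophore_model"
  model
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat("pharmacophore_model:\n")
  cat(sprintf("  donors: %d  acceptors: %d  rings: %d  cations: %d  anions: %d  hydrophobes: %d\n",
              nrow(x$donors), nrow(x$acceptors), length(x$rings),
              length(x$cations), length(x$anions), nrow(x$hydrophobes)))
  for (own in c("ligand", "protein", "water"))
    cat(sprintf("  %s-owned donor/acceptor entries: %d/%d\n", own,
                sum(x$donors$owner == own), sum(x$acceptors$owner == own)))
  invisible(x)
}
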