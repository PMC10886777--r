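# Programmatic fixtures: a 20-residue peptide with full side chains for
# template typing, and randomized mixed-site systems for detector-oracle
# equivalence.

SIDECHAINS <- list(
  ALA = list(heavy = c("CB"), h = list()),
  ARG = list(heavy = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
             h = list(c("HE", "NE"), c("HH11", "NH1"), c("HH12", "NH1"),
                      c("HH21", "NH2"), c("HH22", "NH2"))),
  ASN = list(heavy = c("CB", "CG", "OD1", "ND2"),
             h = list(c("HD21", "ND2"), c("HD22", "ND2"))),
  ASP = list(heavy = c("CB", "CG", "OD1", "OD2"), h = list()),
  CYS = list(heavy = c("CB", "SG"), h = list()),
  GLN = list(heavy = c("CB", "CG", "CD", "OE1", "NE2"),
             h = list(c("HE21", "NE2"), c("HE22", "NE2"))),
  GLU = list(heavy = c("CB", "CG", "CD", "OE1", "OE2"), h = list()),
  GLY = list(heavy = character(), h = list()),
  HIS = list(heavy = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
             h = list(c("HE2", "NE2"))),
  ILE = list(heavy = c("CB", "CG1", "CG2", "CD1"), h = list()),
  LEU = list(heavy = c("CB", "CG", "CD1", "CD2"), h = list()),
  LYS = list(heavy = c("CB", "CG", "CD", "CE", "NZ"),
             h = list(c("HZ1", "NZ"), c("HZ2", "NZ"), c("HZ3", "NZ"))),
  MET = list(heavy = c("CB", "CG", "SD", "CE"), h = list()),
  PHE = list(heavy = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             h = list()),
  PRO = list(heavy = c("CB", "CG", "CD"), h = list()),
  SER = list(heavy = c("CB", "OG"), h = list(c("HG", "OG"))),
  THR = list(heavy = c("CB", "OG1", "CG2"), h = list(c("HG1", "OG1"))),
  TRP = list(heavy = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                       "CZ2", "CZ3", "CH2"),
             h = list(c("HE1", "NE1"))),
  TYR = list(heavy = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
             h = list(c("HH", "OH"))),
  VAL = list(heavy = c("CB", "CG1", "CG2"), h = list()))

elem_of <- function(name) substr(gsub("[0-9]", "", name), 1, 1)

# One residue's atoms on a radius-4 circle at the given center; hydrogens
# 1.0 A outward from their parent heavy atom (tilted so siblings differ).
residue_atoms <- function(resname, resseq, chain, center) {
  sc <- SIDECHAINS[[resname]]
  heavies <- c("N", "CA", "C", "O", sc$heavy)
  n <- length(heavies)
  rows <- list(); xyz <- list()
  pos <- list()
  for (k in seq_len(n)) {
    th <- 2 * pi * (k - 1) / n
    p <- center + 4 * c(cos(th), sin(th), 0)
    pos[[heavies[k]]] <- p
    rows[[length(rows) + 1L]] <- data.frame(
      name = heavies[k], element = elem_of(heavies[k]), resname = resname,
      chain = chain, resseq = resseq, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- p
  }
  hs <- sc$h
  if (resname != "PRO") hs <- c(list(c("H", "N")), hs)
  sib <- integer()
  for (hp in hs) {
    parent <- pos[[hp[2]]]
    radial <- (parent - center); radial[3] <- 0
    radial <- radial / sqrt(sum(radial^2))
    sib[hp[2]] <- (if (is.na(sib[hp[2]])) 0L else sib[hp[2]]) + 1L
    phi <- c(0, 60, -60)[sib[hp[2]]] * pi / 180
    p <- parent + cos(phi) * radial + sin(phi) * c(0, 0, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      name = hp[1], element = "H", resname = resname, chain = chain,
      resseq = resseq, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- p
  }
  list(rows = do.call(rbind, rows), xyz = do.call(rbind, xyz))
}

finish_topology <- function(rows, xyz, ligand_resnames = "LIG") {
  atoms <- rows
  atoms$serial <- seq_len(nrow(atoms))
  atoms$formal_charge <- 0L
  atoms$is_ligand <- atoms$resname %in% ligand_resnames
  atoms$is_water <- atoms$resname %in% c("HOH", "WAT", "TIP3", "SPC")
  md_trajectory(atoms, array(xyz, c(nrow(xyz), 3, 1)), dt_ns = 0.02)
}

# Peptide with one residue of each given type, spaced 12 A apart.
make_test_peptide <- function(resnames = names(SIDECHAINS)) {
  rows <- list(); xyz <- list()
  for (i in seq_along(resnames)) {
    r <- residue_atoms(resnames[i], i, "A", c(0, 0, 12 * i))
    rows[[i]] <- r$rows; xyz[[i]] <- r$xyz
  }
  finish_topology(do.call(rbind, rows), do.call(rbind, xyz))
}

rand_dir <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# A crowded random pocket with every site type, n_frames of jittered
# coordinates around a random base, for oracle-equivalence testing.
random_system <- function(seed, n_res = 12, n_waters = 4, n_frames = 5,
                          jitter = 0.8) {
  set.seed(seed)
  rows <- list(); xyz <- list()
  add <- function(name, element, resname, chain, resseq, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, resname = resname, chain = chain,
      resseq = resseq, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- p
  }
  in_sphere <- function(rmax) rand_dir() * stats::runif(1, 0, rmax)
  ## ligand with every site type
  add("C0", "C", "LIG", "L", 1, c(0, 0, 0))
  nd <- in_sphere(4); add("N1", "N", "LIG", "L", 1, nd)
  add("H1", "H", "LIG", "L", 1, nd + rand_dir())
  c1 <- in_sphere(4); add("C1", "C", "LIG", "L", 1, c1)
  add("O1", "O", "LIG", "L", 1, c1 + 1.3 * rand_dir())
  rc <- in_sphere(3); rv <- rand_dir(); rw <- pocketfp:::perp_vec(rv)
  for (j in 1:6) {
    th <- 2 * pi * (j - 1) / 6
    add(paste0("CR", j), "C", "LIG", "L", 1,
        rc + 1.39 * (cos(th) * rw + sin(th) * cross3(rv, rw)))
  }
  add("NC", "N", "LIG", "L", 1, in_sphere(4))
  add("OA", "O", "LIG", "L", 1, in_sphere(4))
  add("CH1", "C", "LIG", "L", 1, in_sphere(4))
  add("CH2", "C", "LIG", "L", 1, in_sphere(4))
  annotation <- list(
    ligand_resname = "LIG",
    donors = list(c("N1", "H1")),
    acceptors = list(list(atom = "O1", neighbors = list("C1"))),
    rings = list(as.list(paste0("CR", 1:6))),
    cations = list(list(atoms = list("NC"), charge = 1)),
    anions = list(list(atoms = list("OA"), charge = -1)),
    hydrophobes = list("CH1", "CH2"))
  ## residues in a shell around the ligand
  pool <- c("ALA", "SER", "LYS", "ASP", "PHE", "LEU", "GLY", "THR", "HIS",
            "ASN", "ARG", "GLU")
  for (i in seq_len(n_res)) {
    ## first few residues: ring/charge carriers close in, so pi stacking
    ## and salt bridges actually occur at these cutoffs
    rn <- if (i <= 3) c("PHE", "TYR", "LYS")[i] else sample(pool, 1)
    ctr <- rand_dir() * if (i <= 3) stats::runif(1, 2.5, 5.5)
           else stats::runif(1, 3, 8)
    sc <- SIDECHAINS[[rn]]
    heavies <- c("N", "CA", "C", "O", sc$heavy)
    ppos <- list()
    for (k in seq_along(heavies)) {
      p <- ctr + 1.4 * rand_dir()
      ppos[[heavies[k]]] <- p
      add(heavies[k], elem_of(heavies[k]), rn, "A", i + 10L, p)
    }
    hs <- sc$h
    if (rn != "PRO") hs <- c(list(c("H", "N")), hs)
    for (hp in hs)
      add(hp[1], "H", rn, "A", i + 10L, ppos[[hp[2]]] + rand_dir())
  }
  for (i in seq_len(n_waters)) {
    ctr <- rand_dir() * stats::runif(1, 3, 8)
    add("O", "O", "HOH", "W", i + 100L, ctr)
    add("H1", "H", "HOH", "W", i + 100L, ctr + 0.96 * rand_dir())
    add("H2", "H", "HOH", "W", i + 100L, ctr + 0.96 * rand_dir())
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$formal_charge <- 0L
  atoms$is_ligand <- atoms$resname == "LIG"
  atoms$is_water <- atoms$resname == "HOH"
  base <- do.call(rbind, xyz)
  ## frame 1 keeps the clean base geometry (typing reads hydrogens there);
  ## later frames are jittered hard so events straddle every cutoff
  coords <- array(0, c(nrow(base), 3, n_frames))
  coords[, , 1] <- base
  for (f in seq_len(n_frames)[-1])
    coords[, , f] <- base + matrix(stats::rnorm(nrow(base) * 3, 0, jitter),
                                   nrow(base), 3)
  traj <- md_trajectory(atoms, coords, dt_ns = 0.02)
  model <- suppressWarnings(build_model(traj, annotation))
  list(traj = traj, model = model, annotation = annotation)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
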