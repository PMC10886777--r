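#' @title Synthetic binding-pocket trajectories with planted interactions
#' @name synthetic_data
#' @description
#' Seeded generators producing inputs with the statistical structure the
#' analysis assumes: a small binding pocket (ligand, interacting residues,
#' optional waters, inert filler residues) whose planted interactions
#' toggle on/off per frame with stated probabilities under clamped Gaussian
#' positional jitter; a two-state ligand-pose mixture for clustering tests;
#' and species-energy tables with known true IP/EA. The generators produce
#' geometric, not dynamical, truth: there is no force field or thermostat,
#' so they emulate contact statistics and pose mixtures, not physics.
NULL

POCKET_KINDS <- c("hbond", "hbond_acceptor", "hbond_pair", "ionic",
                  "hydrophobic", "pi_pi", "pi_cation", "water_bridge")

## one axis direction slot per planted interaction; 90 degree separation
## keeps the planted geometries from cross-talking
POCKET_DIRECTIONS <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                           c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specify a synthetic binding pocket
#'
#' Each planted interaction occupies its own direction slot around the
#' ligand (at most 6 per pocket) and is realized by a minimal residue
#' (or residue + water) whose contact atoms sit at an "on" geometry
#' satisfying the given criteria with an explicit margin, and are displaced
#' to an "off" geometry violating them. Feasibility is validated at build
#' time by running the detectors on pure on/off frames: the on frame must
#' yield exactly the planted event set and the off frame none.
#'
#' @param interactions list of plants, each
#'   `list(kind =, p =, frames_on = NULL)` with `kind` one of
#'   `r paste(POCKET_KINDS, collapse = ", ")`, per-frame probability
#'   `p` in \[0, 1\], and optional explicit `frames_on` (1-based frame
#'   indices) overriding the Bernoulli draw.
#' @param n_frames frames to generate.
#' @param dt_ns frame spacing, ns.
#' @param jitter_sigma per-coordinate Gaussian jitter (Angstrom), clamped
#'   at 2.5 sigma so on/off classification is preserved.
#' @param n_filler inert glycine residues padding the pocket.
#' @param seed integer seed; identical seeds give bit-identical pockets.
#' @param criteria the [interaction_criteria()] the geometries are
#'   validated against.
#' @return Object of class `pocket_spec`.
#' @export
pocket_spec <- function(interactions, n_frames = 1000, dt_ns = 0.02,
                        jitter_sigma = 0.03, n_filler = 10, seed = 1,
                        criteria = interaction_criteria()) {
  if (!length(interactions)) stop("at least one planted interaction required")
  if (length(interactions) > nrow(POCKET_DIRECTIONS))
    stop("at most ", nrow(POCKET_DIRECTIONS), " planted interactions per pocket")
  for (it in interactions) {
    if (!it$kind %in% POCKET_KINDS)
      stop("unknown interaction kind: ", it$kind)
    p <- it$p %||% NA_real_
    if (is.null(it$frames_on) && (!is.finite(p) || p < 0 || p > 1))
      stop("each plant needs a probability p in [0, 1] or explicit frames_on")
    if (!is.null(it$frames_on) &&
        (any(it$frames_on < 1) || any(it$frames_on > n_frames)))
      stop("frames_on out of range")
  }
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (jitter_sigma < 0 || jitter_sigma > 0.1)
    stop("jitter_sigma must be in [0, 0.1] Angstrom to preserve on/off classification")
  structure(list(interactions = interactions, n_frames = as.integer(n_frames),
                 dt_ns = dt_ns, jitter_sigma = jitter_sigma,
                 n_filler = as.integer(n_filler), seed = as.integer(seed),
                 criteria = criteria),
            class = "pocket_spec")
}

## --- pocket assembly ------------------------------------------------------

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$xyz <- list()
  env
}

add_atom <- function(b, name, element, resname, chain, resseq, pos,
                     is_ligand = FALSE, is_water = FALSE, charge = 0L) {
  i <- length(b$rows) + 1L
  b$rows[[i]] <- data.frame(serial = i, name = name, element = element,
                            resname = resname, chain = chain,
                            resseq = as.integer(resseq),
                            formal_charge = as.integer(charge),
                            is_ligand = is_ligand, is_water = is_water,
                            stringsAsFactors = FALSE)
  b$xyz[[i]] <- pos
  i
}

## Each plant_* returns list(mobile = atom indices toggled off,
## off_offset = displacement, expected = data.frame(kind, n_events))
plant_interaction <- function(b, it, u, resseq, ann) {
  v <- perp_vec(u)
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  k <- it$kind
  id <- resseq - 100L
  A <- function(...) add_atom(b, ...)
  if (k == "hbond") {
    ann$donors <- c(ann$donors, list(c(paste0("ND", id), paste0("HD", id))))
    A(paste0("ND", id), "N", "LIG", "L", 1, 2.0 * u, is_ligand = TRUE)
    A(paste0("HD", id), "H", "LIG", "L", 1, 3.0 * u, is_ligand = TRUE)
    o <- A("O", "O", "ALA", "A", resseq, 4.8 * u)
    c_ <- A("C", "C", "ALA", "A", resseq, 6.1 * u)
    A("CA", "C", "ALA", "A", resseq, 7.6 * u)
    A("N", "N", "ALA", "A", resseq, 9.0 * u)
    A("CB", "C", "ALA", "A", resseq, 7.6 * u + 1.5 * v)
    res <- list(mobile = c(o, c_), off_offset = 2.4 * u,
                expected = data.frame(kind = "hbond", n = 1L))
  } else if (k == "hbond_acceptor") {
    ann$acceptors <- c(ann$acceptors, list(list(atom = paste0("OA", id),
                                                neighbors = list(paste0("CA", id)))))
    A(paste0("CA", id), "C", "LIG", "L", 1, 1.2 * u, is_ligand = TRUE)
    A(paste0("OA", id), "O", "LIG", "L", 1, 2.4 * u, is_ligand = TRUE)
    h <- A("H", "H", "GLY", "A", resseq, 4.2 * u)
    n <- A("N", "N", "GLY", "A", resseq, 5.2 * u)
    A("CA", "C", "GLY", "A", resseq, 6.7 * u)
    A("C", "C", "GLY", "A", resseq, 8.0 * u)
    A("O", "O", "GLY", "A", resseq, 9.0 * u)
    res <- list(mobile = c(h, n), off_offset = 2.4 * u,
                expected = data.frame(kind = "hbond", n = 1L))
  } else if (k == "hbond_pair") {
    o <- A("O", "O", "ALA", "A", resseq, 4.8 * u)
    c_ <- A("C", "C", "ALA", "A", resseq, 6.1 * u)
    A("CA", "C", "ALA", "A", resseq, 7.6 * u)
    A("N", "N", "ALA", "A", resseq, 9.0 * u)
    A("CB", "C", "ALA", "A", resseq, 7.6 * u + 1.5 * v)
    for (s in c(1, 2)) {
      wk <- as.vector(rotation_about(v, c(15, -15)[s]) %*% u)
      dn <- paste0("ND", id, s); hn <- paste0("HD", id, s)
      ann$donors <- c(ann$donors, list(c(dn, hn)))
      A(hn, "H", "LIG", "L", 1, 4.8 * u - 1.8 * wk, is_ligand = TRUE)
      A(dn, "N", "LIG", "L", 1, 4.8 * u - 2.8 * wk, is_ligand = TRUE)
    }
    res <- list(mobile = c(o, c_), off_offset = 2.4 * u,
                expected = data.frame(kind = "hbond", n = 2L))
  } else if (k == "ionic") {
    ann$anions <- c(ann$anions, list(list(atoms = list(paste0("OX", id)),
                                          charge = -1)))
    A(paste0("OX", id), "O", "LIG", "L", 1, 2.0 * u, is_ligand = TRUE,
      charge = -1L)
    nz <- A("NZ", "N", "LYS", "A", resseq, 4.9 * u, charge = 1L)
    A("CE", "C", "LYS", "A", resseq, 6.4 * u)
    A("CD", "C", "LYS", "A", resseq, 7.9 * u)
    A("CG", "C", "LYS", "A", resseq, 9.4 * u)
    A("CB", "C", "LYS", "A", resseq, 10.9 * u)
    A("CA", "C", "LYS", "A", resseq, 12.4 * u)
    A("C", "C", "LYS", "A", resseq, 13.6 * u)
    A("O", "O", "LYS", "A", resseq, 14.6 * u)
    A("N", "N", "LYS", "A", resseq, 12.4 * u + 1.4 * v)
    res <- list(mobile = nz, off_offset = 2.6 * u,
                expected = data.frame(kind = "ionic", n = 1L))
  } else if (k == "hydrophobic") {
    ann$hydrophobes <- c(ann$hydrophobes, list(paste0("CH", id)))
    A(paste0("CH", id), "C", "LIG", "L", 1, 2.0 * u, is_ligand = TRUE)
    cd1 <- A("CD1", "C", "LEU", "A", resseq, 5.2 * u)
    A("CG", "C", "LEU", "A", resseq, 6.8 * u)
    A("CD2", "C", "LEU", "A", resseq, 6.8 * u + 1.5 * v)
    A("CB", "C", "LEU", "A", resseq, 8.3 * u)
    A("CA", "C", "LEU", "A", resseq, 9.8 * u)
    A("C", "C", "LEU", "A", resseq, 11.0 * u)
    A("O", "O", "LEU", "A", resseq, 12.0 * u)
    A("N", "N", "LEU", "A", resseq, 9.8 * u + 1.4 * v)
    res <- list(mobile = cd1, off_offset = 2.4 * u,
                expected = data.frame(kind = "hydrophobic", n = 1L))
  } else if (k %in% c("pi_pi", "pi_cation")) {
    ring_at <- function(center, prefix, resname, resseq, lig) {
      idx <- integer(6)
      for (j in 1:6) {
        th <- 2 * pi * (j - 1) / 6
        idx[j] <- A(paste0(prefix, j), "C", resname,
                    if (lig) "L" else "A", resseq,
                    center + 1.39 * (cos(th) * v + sin(th) * w),
                    is_ligand = lig)
      }
      idx
    }
    if (k == "pi_pi") {
      nms <- paste0("CR", id, 1:6)
      ann$rings <- c(ann$rings, list(as.list(nms)))
      for (j in 1:6) {
        th <- 2 * pi * (j - 1) / 6
        A(nms[j], "C", "LIG", "L", 1,
          3.0 * u + 1.39 * (cos(th) * v + sin(th) * w), is_ligand = TRUE)
      }
      ctr <- 6.8 * u
      ridx <- ring_at(ctr, "", "PHE", resseq, FALSE)
      ## ring_at used generic names; rename to the PHE template names
      ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      for (j in 1:6) b$rows[[ridx[j]]]$name <- ring_names[j]
      A("CB", "C", "PHE", "A", resseq, 8.8 * u)
      A("CA", "C", "PHE", "A", resseq, 10.3 * u)
      A("C", "C", "PHE", "A", resseq, 11.5 * u)
      A("O", "O", "PHE", "A", resseq, 12.5 * u)
      A("N", "N", "PHE", "A", resseq, 10.3 * u + 1.4 * v)
      res <- list(mobile = ridx, off_offset = 2.2 * u,
                  expected = data.frame(kind = c("pi_pi", "hydrophobic"),
                                        n = c(1L, 0L)))
    } else {
      ann$cations <- c(ann$cations, list(list(atoms = list(paste0("NP", id)),
                                              charge = 1)))
      A(paste0("NP", id), "N", "LIG", "L", 1, 2.5 * u, is_ligand = TRUE,
        charge = 1L)
      ctr <- 6.3 * u
      ridx <- ring_at(ctr, "", "PHE", resseq, FALSE)
      ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      for (j in 1:6) b$rows[[ridx[j]]]$name <- ring_names[j]
      A("CB", "C", "PHE", "A", resseq, 8.3 * u)
      A("CA", "C", "PHE", "A", resseq, 9.8 * u)
      A("C", "C", "PHE", "A", resseq, 11.0 * u)
      A("O", "O", "PHE", "A", resseq, 12.0 * u)
      A("N", "N", "PHE", "A", resseq, 9.8 * u + 1.4 * v)
      res <- list(mobile = ridx, off_offset = 2.2 * u,
                  expected = data.frame(kind = "pi_cation", n = 1L))
    }
  } else if (k == "water_bridge") {
    ann$acceptors <- c(ann$acceptors, list(list(atom = paste0("OW", id),
                                                neighbors = list(paste0("CW", id)))))
    A(paste0("CW", id), "C", "LIG", "L", 1, 1.2 * u, is_ligand = TRUE)
    A(paste0("OW", id), "O", "LIG", "L", 1, 2.4 * u, is_ligand = TRUE)
    h1 <- A("H1", "H", "HOH", "W", resseq + 100L, 4.2 * u, is_water = TRUE)
    ow <- A("O", "O", "HOH", "W", resseq + 100L, 5.2 * u, is_water = TRUE)
    h2 <- A("H2", "H", "HOH", "W", resseq + 100L,
            5.2 * u + cos(105 * pi / 180) * u + sin(105 * pi / 180) * v,
            is_water = TRUE)
    A("H", "H", "GLY", "A", resseq, 7.0 * u)
    A("N", "N", "GLY", "A", resseq, 8.0 * u)
    A("CA", "C", "GLY", "A", resseq, 9.5 * u)
    A("C", "C", "GLY", "A", resseq, 10.8 * u)
    A("O", "O", "GLY", "A", resseq, 11.8 * u)
    res <- list(mobile = c(h1, ow, h2), off_offset = 4.0 * v,
                expected = data.frame(kind = "water_bridge", n = 1L))
  }
  res$ann <- ann
  res
}

build_pocket <- function(spec) {
  b <- new_builder()
  ann <- list(ligand_resname = "LIG", donors = list(), acceptors = list(),
              rings = list(), cations = list(), anions = list(),
              hydrophobes = list())
  add_atom(b, "C0", "C", "LIG", "L", 1, c(0, 0, 0), is_ligand = TRUE)
  plants <- list()
  for (i in seq_along(spec$interactions)) {
    it <- spec$interactions[[i]]
    pl <- plant_interaction(b, it, POCKET_DIRECTIONS[i, ], 100L + i, ann)
    ann <- pl$ann
    pl$ann <- NULL
    pl$kind <- it$kind
    pl$resseq <- 100L + i
    plants[[i]] <- pl
  }
  ## inert filler residues on a shell well outside every contact geometry
  if (spec$n_filler > 0) {
    golden <- pi * (3 - sqrt(5))
    for (j in seq_len(spec$n_filler)) {
      z <- 1 - 2 * (j - 0.5) / spec$n_filler
      r <- sqrt(max(0, 1 - z^2))
      th <- golden * (j - 1)
      ctr <- 16 * c(r * cos(th), r * sin(th), z)
      d <- perp_vec(if (sum(ctr^2) > 0) ctr else c(0, 0, 1))
      add_atom(b, "N", "N", "GLY", "B", j, ctr + 1.4 * d)
      add_atom(b, "CA", "C", "GLY", "B", j, ctr)
      add_atom(b, "C", "C", "GLY", "B", j, ctr - 1.4 * d)
      add_atom(b, "O", "O", "GLY", "B", j, ctr - 2.6 * d)
    }
  }
  atoms <- do.call(rbind, b$rows)
  base <- do.call(rbind, b$xyz)
  list(atoms = atoms, base = base, plants = plants, annotation = ann)
}

## Detector-backed feasibility check: the all-on frame must yield exactly
## the planted events, the all-off frame none.
validate_pocket_geometry <- function(pocket, spec) {
  base <- pocket$base
  off <- base
  for (pl in pocket$plants)
    off[pl$mobile, ] <- off[pl$mobile, , drop = FALSE] +
      rep(pl$off_offset, each = length(pl$mobile))
  coords <- array(0, c(nrow(base), 3, 2))
  coords[, , 1] <- base
  coords[, , 2] <- off
  traj <- md_trajectory(pocket$atoms, coords, dt_ns = spec$dt_ns)
  model <- build_model(traj, pocket$annotation)
  ev_on <- detect_frame(traj, model, 1, spec$criteria)
  ev_off <- detect_frame(traj, model, 2, spec$criteria)
  expected <- do.call(rbind, lapply(pocket$plants, function(pl) {
    ex <- pl$expected[pl$expected$n > 0, , drop = FALSE]
    if (!nrow(ex)) return(NULL)
    data.frame(resseq = pl$resseq, kind = ex$kind, n = ex$n,
               stringsAsFactors = FALSE)
  }))
  got <- if (nrow(ev_on))
    stats::aggregate(list(n = ev_on$frame),
                     by = list(resseq = ev_on$resseq, kind = ev_on$kind),
                     FUN = length)
  else data.frame(resseq = integer(), kind = character(), n = integer())
  key <- function(d) sort(paste(d$resseq, d$kind, d$n))
  if (!identical(key(expected), key(got)))
    stop("pocket_spec: infeasible on-geometry (detected events do not match plants): got {",
         paste(key(got), collapse = "; "), "} expected {",
         paste(key(expected), collapse = "; "), "}")
  if (nrow(ev_off))
    stop("pocket_spec: infeasible off-geometry (events persist in the off state)")
  list(traj2 = traj, model = model)
}

#' Generate a pocket trajectory with planted probabilistic interactions
#'
#' Per frame, each planted interaction is independently "on" with its
#' probability (or exactly on its `frames_on` list); the mobile contact
#' atoms sit at the on or off geometry accordingly, and clamped Gaussian
#' jitter is added to every atom. The realized per-frame states are
#' returned as ground truth.
#'
#' @param spec a [pocket_spec()].
#' @return List with `traj` (an [md_trajectory()]), `annotation` (the
#'   matching ligand annotation), `truth` (list: `states` n_frames x
#'   n_plants logical matrix, `table` one row per plant with kind, residue
#'   and realized frequency), and `seed`.
#' @export
gen_pocket_trajectory <- function(spec) {
  stopifnot(inherits(spec, "pocket_spec"))
  pocket <- build_pocket(spec)
  validate_pocket_geometry(pocket, spec)
  n_at <- nrow(pocket$atoms)
  nf <- spec$n_frames
  k <- length(pocket$plants)
  with_seed(spec$seed, {
    states <- matrix(FALSE, nf, k)
    for (i in seq_len(k)) {
      it <- spec$interactions[[i]]
      states[, i] <- if (!is.null(it$frames_on))
        seq_len(nf) %in% it$frames_on
      else stats::runif(nf) < it$p
    }
    coords <- array(0, c(n_at, 3, nf))
    s <- spec$jitter_sigma
    for (f in seq_len(nf)) {
      X <- pocket$base
      for (i in seq_len(k)) {
        if (!states[f, i]) {
          pl <- pocket$plants[[i]]
          X[pl$mobile, ] <- X[pl$mobile, , drop = FALSE] +
            rep(pl$off_offset, each = length(pl$mobile))
        }
      }
      if (s > 0) {
        jit <- matrix(stats::rnorm(n_at * 3, 0, s), n_at, 3)
        jit <- pmin(pmax(jit, -2.5 * s), 2.5 * s)
        X <- X + jit
      }
      coords[, , f] <- X
    }
  })
  traj <- md_trajectory(pocket$atoms, coords, dt_ns = spec$dt_ns)
  annotation <- validate_ligand_annotation(pocket$annotation, traj)
  tab <- do.call(rbind, lapply(seq_len(k), function(i) {
    pl <- pocket$plants[[i]]
    data.frame(plant = i, kind = pl$kind, chain = "A", resseq = pl$resseq,
               events_per_frame_on = sum(pl$expected$n),
               frequency = mean(states[, i]), stringsAsFactors = FALSE)
  }))
  list(traj = traj, annotation = annotation,
       truth = list(states = states, table = tab), seed = spec$seed)
}

#' Generate a two-state ligand-pose trajectory
#'
#' A static ring of backbone residues encloses a rigid 8-atom ligand that
#' alternates between two poses separated by `displacement` Angstrom along
#' x; every atom receives isotropic Gaussian jitter. Used as the test bed
#' for pose clustering.
#'
#' @param weights length-2 state probabilities summing to 1 (majority
#'   state first by convention).
#' @param displacement inter-pose distance, Angstrom.
#' @param jitter per-coordinate Gaussian sigma, Angstrom. A displacement
#'   of at most twice the jitter triggers a state-overlap warning.
#' @param n_frames,dt_ns,seed trajectory bookkeeping.
#' @return List with `traj`, `states` (1/2 per frame) and `seed`.
#' @export
gen_two_state_trajectory <- function(weights = c(0.7, 0.3), displacement = 5,
                                     jitter = 0.3, n_frames = 5000,
                                     dt_ns = 0.02, seed = 1) {
  if (length(weights) != 2L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be two non-negative numbers summing to 1")
  if (displacement <= 2 * jitter)
    warning("displacement <= 2 * jitter: the two states may overlap")
  b <- new_builder()
  ## 20-residue backbone ring, radius 12 Angstrom
  for (j in 1:20) {
    th <- 2 * pi * (j - 1) / 20
    ctr <- 12 * c(cos(th), sin(th), 0)
    d <- unit_vec(c(-sin(th), cos(th), 0))
    add_atom(b, "N", "N", "ALA", "A", j, ctr + 1.4 * d)
    add_atom(b, "CA", "C", "ALA", "A", j, ctr)
    add_atom(b, "C", "C", "ALA", "A", j, ctr - 1.4 * d)
    add_atom(b, "O", "O", "ALA", "A", j, ctr - 2.4 * d + c(0, 0, 1))
  }
  ## rigid 8-atom ligand: 1.2-Angstrom cube vertices
  for (j in 1:8) {
    sgn <- c(ifelse(bitwAnd(j - 1, 1L) > 0, 1, -1),
             ifelse(bitwAnd(j - 1, 2L) > 0, 1, -1),
             ifelse(bitwAnd(j - 1, 4L) > 0, 1, -1))
    add_atom(b, paste0("C", j), "C", "LIG", "L", 1, 1.2 * sgn,
             is_ligand = TRUE)
  }
  atoms <- do.call(rbind, b$rows)
  base <- do.call(rbind, b$xyz)
  lig <- which(atoms$is_ligand)
  n_at <- nrow(atoms)
  with_seed(seed, {
    states <- 1L + (stats::runif(n_frames) < weights[2])
    coords <- array(0, c(n_at, 3, n_frames))
    for (f in seq_len(n_frames)) {
      X <- base
      if (states[f] == 2L) X[lig, 1] <- X[lig, 1] + displacement
      if (jitter > 0)
        X <- X + matrix(stats::rnorm(n_at * 3, 0, jitter), n_at, 3)
      coords[, , f] <- X
    }
  })
  list(traj = md_trajectory(atoms, coords, dt_ns = dt_ns),
       states = states, seed = seed)
}

#' Species energies with known true IP and EA
#'
#' Builds an energy table whose descriptor pipeline output recovers the
#' planted values exactly: `E_cation = E_neutral + true_ip`,
#' `E_anion = E_neutral - true_ea`.
#'
#' @param true_ip,true_ea planted values, eV.
#' @param E_neutral neutral-species energy, eV.
#' @param compound_id label.
#' @return A [species_energy_set()] (unit eV).
#' @export
gen_species_energies <- function(true_ip, true_ea, E_neutral = -11530.10,
                                 compound_id = "synthetic") {
  species_energy_set(compound_id, E_neutral, E_neutral + true_ip,
                     E_neutral - true_ea, unit = "eV")
}
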