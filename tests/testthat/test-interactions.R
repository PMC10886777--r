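# Hand-constructed micro-systems exercising each geometric criterion at
# both sides of its threshold, plus randomized oracle-equivalence checks.

tiny_system <- function(spec, annotation = NULL) {
  rows <- do.call(rbind, lapply(spec, function(a)
    data.frame(name = a$name, element = a$element, resname = a$resname,
               chain = a$chain, resseq = a$resseq,
               stringsAsFactors = FALSE)))
  xyz <- do.call(rbind, lapply(spec, function(a) a$pos))
  rows$serial <- seq_len(nrow(rows))
  rows$formal_charge <- 0L
  rows$is_ligand <- rows$resname == "LIG"
  rows$is_water <- rows$resname == "HOH"
  traj <- md_trajectory(rows, array(xyz, c(nrow(xyz), 3, 1)))
  model <- suppressWarnings(build_model(traj, annotation))
  list(traj = traj, model = model)
}

at <- function(name, element, pos, resname = "LIG", chain = "L", resseq = 1)
  list(name = name, element = element, resname = resname, chain = chain,
       resseq = resseq, pos = pos)

donor_ann <- list(ligand_resname = "LIG", donors = list(c("N1", "H1")),
                  acceptors = list(), rings = list(), cations = list(),
                  anions = list(), hydrophobes = list())

# ligand N1-H1 pointing at an ALA backbone O along +x, H...O = ha
hbond_sys <- function(ha, dha_deg = 180) {
  ## place the donor so that angle(D, H, A) == dha_deg with H...A fixed
  th <- dha_deg * pi / 180
  d_pos <- c(cos(th), sin(th), 0)
  tiny_system(list(
    at("N1", "N", d_pos), at("H1", "H", c(0, 0, 0)),
    at("O", "O", c(ha, 0, 0), "ALA", "A", 10),
    at("C", "C", c(ha + 1.3, 0, 0), "ALA", "A", 10),
    at("CA", "C", c(ha + 2.6, 0, 0), "ALA", "A", 10)), donor_ann)
}

test_that("hydrogen bonds respect the H...A distance threshold", {
  s <- hbond_sys(1.9)
  ev <- detect_hbonds(s$traj, s$model, 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "hbond")
  expect_equal(ev$resname, "ALA")
  expect_equal(ev$dist, 1.9, tolerance = 1e-9)
  expect_equal(ev$ang_dha, 180, tolerance = 1e-6)
  ## ideal angles but 2.6 A fails the 2.5 A cutoff
  expect_equal(nrow(detect_hbonds(hbond_sys(2.6)$traj,
                                  hbond_sys(2.6)$model, 1)), 0L)
})

test_that("hydrogen bonds respect the D-H-A and H-A-X angle minima", {
  ## DHA = 100 deg < 120 deg fails under the conjunctive default
  s <- hbond_sys(1.9, dha_deg = 100)
  expect_equal(nrow(detect_hbonds(s$traj, s$model, 1)), 0L)
  ## but passes under the disjunctive reading (H-A-X = 180 >= 90)
  crit_or <- interaction_criteria(hbond_angle_mode = "or")
  expect_equal(nrow(detect_hbonds(s$traj, s$model, 1, crit_or)), 1L)
  ## the 120 deg threshold is a minimum: just above passes, just below fails
  s2 <- hbond_sys(1.9, dha_deg = 120.001)
  expect_equal(nrow(detect_hbonds(s2$traj, s2$model, 1)), 1L)
  s3 <- hbond_sys(1.9, dha_deg = 119.999)
  expect_equal(nrow(detect_hbonds(s3$traj, s3$model, 1)), 0L)
})

ionic_sys <- function(d, lig_charge = -1, prot_res = "LYS") {
  ann <- list(ligand_resname = "LIG", donors = list(), acceptors = list(),
              rings = list(), cations = list(), anions = list(),
              hydrophobes = list())
  if (lig_charge < 0) ann$anions <- list(list(atoms = list("OX"), charge = -1))
  else ann$cations <- list(list(atoms = list("NX"), charge = 1))
  nm <- if (lig_charge < 0) "OX" else "NX"
  el <- if (lig_charge < 0) "O" else "N"
  tiny_system(list(
    at(nm, el, c(0, 0, 0)),
    at("NZ", "N", c(d, 0, 0), prot_res, "A", 20),
    at("CE", "C", c(d + 1.5, 0, 0), prot_res, "A", 20),
    at("CA", "C", c(d + 4.5, 0, 0), prot_res, "A", 20)), ann)
}

test_that("ionic contacts require opposite charges within 3.4 Angstrom", {
  s <- ionic_sys(3.3)
  ev <- detect_ionic(s$traj, s$model, 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$dist, 3.3, tolerance = 1e-9)
  expect_equal(nrow(detect_ionic(ionic_sys(3.5)$traj,
                                 ionic_sys(3.5)$model, 1)), 0L)
  ## like charges at 2.0 A produce nothing
  s2 <- ionic_sys(2.0, lig_charge = +1)
  expect_equal(nrow(detect_ionic(s2$traj, s2$model, 1)), 0L)
})

hydrophobic_sys <- function(n_pairs = 1, d = 3.5) {
  ats <- list()
  ann_h <- list()
  for (i in seq_len(n_pairs)) {
    ats[[length(ats) + 1L]] <- at(paste0("CL", i), "C", c(0, 2.0 * i, 0))
    ann_h[[i]] <- paste0("CL", i)
  }
  nm <- c("CB", "CG", "CD1", "CD2", "CA")[seq_len(min(n_pairs + 1, 5))]
  for (i in seq_len(n_pairs))
    ats[[length(ats) + 1L]] <- at(nm[i], "C", c(d, 2.0 * i, 0),
                                  "LEU", "A", 30)
  ann <- list(ligand_resname = "LIG", donors = list(), acceptors = list(),
              rings = list(), cations = list(), anions = list(),
              hydrophobes = ann_h)
  tiny_system(ats, ann)
}

test_that("hydrophobic contacts emit at most one event per residue per frame", {
  s <- hydrophobic_sys(1, 3.5)
  ev <- detect_hydrophobic(s$traj, s$model, 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$dist, 3.5, tolerance = 1e-9)
  expect_equal(nrow(detect_hydrophobic(hydrophobic_sys(1, 3.7)$traj,
                                       hydrophobic_sys(1, 3.7)$model, 1)), 0L)
  ## four qualifying atom pairs to one LEU still yield a single event
  s4 <- hydrophobic_sys(4, 3.5)
  ev4 <- detect_hydrophobic(s4$traj, s4$model, 1)
  expect_equal(nrow(ev4), 1L)
})

ring_atoms <- function(prefix, center, resname = "LIG", chain = "L",
                       resseq = 1, names = NULL) {
  out <- list()
  for (j in 1:6) {
    th <- 2 * pi * (j - 1) / 6
    nm <- if (is.null(names)) paste0(prefix, j) else names[j]
    out[[j]] <- at(nm, "C", center + 1.39 * c(cos(th), sin(th), 0),
                   resname, chain, resseq)
  }
  out
}

test_that("pi-pi and pi-cation stacking follow the centroid-distance cutoff", {
  phe_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  mk <- function(dz) {
    ats <- c(ring_atoms("CR", c(0, 0, 0)),
             ring_atoms(NULL, c(0, 0, dz), "PHE", "A", 40, names = phe_names))
    ann <- list(ligand_resname = "LIG", donors = list(), acceptors = list(),
                rings = list(as.list(paste0("CR", 1:6))), cations = list(),
                anions = list(), hydrophobes = list())
    tiny_system(ats, ann)
  }
  s <- mk(3.8)
  ev <- detect_pi(s$traj, s$model, 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "pi_pi")
  expect_equal(ev$dist, 3.8, tolerance = 1e-9)
  expect_equal(nrow(detect_pi(mk(4.6)$traj, mk(4.6)$model, 1)), 0L)
  ## ligand cation over a PHE ring
  mkc <- function(dz) {
    ats <- c(list(at("NX", "N", c(0, 0, dz))),
             ring_atoms(NULL, c(0, 0, 0), "PHE", "A", 40, names = phe_names))
    ann <- list(ligand_resname = "LIG", donors = list(), acceptors = list(),
                rings = list(), cations = list(list(atoms = list("NX"),
                                                    charge = 1)),
                anions = list(), hydrophobes = list())
    tiny_system(ats, ann)
  }
  evc <- detect_pi(mkc(4.4)$traj, mkc(4.4)$model, 1)
  expect_equal(evc$kind, "pi_cation")
  expect_equal(nrow(detect_pi(mkc(4.6)$traj, mkc(4.6)$model, 1)), 0L)
})

water_sys <- function(leg2 = 1.9) {
  ## ligand acceptor O1 <- water H1; water O <- GLY H-N donor
  ann <- list(ligand_resname = "LIG", donors = list(),
              acceptors = list(list(atom = "O1", neighbors = list("C1"))),
              rings = list(), cations = list(), anions = list(),
              hydrophobes = list())
  tiny_system(list(
    at("C1", "C", c(-1.3, 0, 0)), at("O1", "O", c(0, 0, 0)),
    at("H1", "H", c(1.9, 0, 0), "HOH", "W", 90),
    at("O", "O", c(2.9, 0, 0), "HOH", "W", 90),
    at("H2", "H", c(2.9, 0.96, 0), "HOH", "W", 90),
    at("H", "H", c(2.9 + leg2, 0, 0), "GLY", "A", 50),
    at("N", "N", c(3.9 + leg2, 0, 0), "GLY", "A", 50),
    at("CA", "C", c(5.4 + leg2, 0, 0), "GLY", "A", 50)), ann)
}

test_that("water bridges require both relaxed-geometry legs and name the water", {
  s <- water_sys(1.9)
  ev <- detect_water_bridges(s$traj, s$model, 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "water_bridge")
  expect_equal(ev$water, "W 90")
  expect_equal(ev$resname, "GLY")
  ## water-residue leg at 2.9 A fails the 2.8 A water threshold
  s2 <- water_sys(2.9)
  expect_equal(nrow(detect_water_bridges(s2$traj, s2$model, 1)), 0L)
})

test_that("each detector matches its exhaustive brute-force oracle on random frames", {
  cr <- interaction_criteria()
  for (seed in c(101, 202)) {
    sys <- random_system(seed, n_res = 8, n_waters = 3, n_frames = 6)
    for (f in seq_len(sys$traj$n_frames)) {
      expect_identical(ev_keys(detect_hbonds(sys$traj, sys$model, f, cr)),
                       oracle_hbond_keys(sys$traj, sys$model, f, cr))
      expect_identical(ev_keys(detect_ionic(sys$traj, sys$model, f, cr)),
                       oracle_ionic_keys(sys$traj, sys$model, f, cr))
      expect_identical(ev_keys(detect_hydrophobic(sys$traj, sys$model, f, cr)),
                       oracle_hydrophobic_keys(sys$traj, sys$model, f, cr))
      expect_identical(ev_keys(detect_pi(sys$traj, sys$model, f, cr)),
                       oracle_pi_keys(sys$traj, sys$model, f, cr))
      expect_identical(ev_keys(detect_water_bridges(sys$traj, sys$model, f, cr)),
                       oracle_water_keys(sys$traj, sys$model, f, cr))
    }
  }
})

test_that("detect_frame is the ordered union of the five detectors", {
  sys <- random_system(77, n_res = 8, n_waters = 3, n_frames = 2)
  all_ev <- detect_frame(sys$traj, sys$model, 1)
  parts <- c(ev_keys(detect_hbonds(sys$traj, sys$model, 1)),
             ev_keys(detect_ionic(sys$traj, sys$model, 1)),
             ev_keys(detect_hydrophobic(sys$traj, sys$model, 1)),
             ev_keys(detect_pi(sys$traj, sys$model, 1)),
             ev_keys(detect_water_bridges(sys$traj, sys$model, 1)))
  expect_identical(ev_keys(all_ev), sort(parts))
  ## deterministic ordering: re-detection gives the identical table
  expect_identical(all_ev, detect_frame(sys$traj, sys$model, 1))
})

test_that("enlarging any distance cutoff never removes an event", {
  sys <- random_system(55, n_res = 8, n_waters = 3, n_frames = 3)
  base_cr <- interaction_criteria()
  base <- ev_keys(detect_trajectory(sys$traj, sys$model, base_cr))
  for (par in c("hbond_max_HA", "water_max_HA", "ionic_max",
                "hydrophobic_max", "pi_max")) {
    args <- list(); args[[par]] <- base_cr[[par]] + 1.0
    wide <- ev_keys(detect_trajectory(sys$traj, sys$model,
                                      do.call(interaction_criteria, args)))
    expect_true(all(base %in% wide),
                label = paste("monotonicity in", par))
  }
})

test_that("aggregation is the exact count/n_frames identity and conserves events", {
  sys <- random_system(303, n_res = 8, n_waters = 2, n_frames = 10)
  ev <- detect_trajectory(sys$traj, sys$model)
  tab <- aggregate_contacts(ev, sys$traj$n_frames)
  expect_equal(sum(tab$count), nrow(ev))           # conservation
  expect_equal(tab$value * sys$traj$n_frames, tab$count)  # exact identity
  expect_error(aggregate_contacts(ev, 0), "positive")
  ## empty events aggregate to an empty table
  empty <- aggregate_contacts(ev[0, ], 5)
  expect_equal(nrow(empty), 0L)
})

test_that("timelines report per-frame counts and the longest run", {
  sp <- pocket_spec(list(list(kind = "hbond", frames_on = c(2:5, 8))),
                    n_frames = 10, seed = 4)
  g <- gen_pocket_trajectory(sp)
  m <- build_model(g$traj, g$annotation)
  ev <- detect_trajectory(g$traj, m)
  tl <- contact_timeline(ev, 10, "A", 101, "hbond")
  expect_equal(tl$counts, as.integer(c(0, 1, 1, 1, 1, 0, 0, 1, 0, 0)))
  expect_equal(tl$longest_run, 4L)
  ## brute-force run check
  runs <- rle(tl$counts > 0)
  expect_equal(tl$longest_run, max(runs$lengths[runs$values]))
  ## unknown key gives an all-zero series
  tl0 <- contact_timeline(ev, 10, "A", 999, "hbond")
  expect_equal(sum(tl0$counts), 0L)
  expect_equal(tl0$longest_run, 0L)
  ## all-frames contact: constant series, longest run = n_frames
  sp2 <- pocket_spec(list(list(kind = "ionic", p = 1)), n_frames = 6, seed = 4)
  g2 <- gen_pocket_trajectory(sp2)
  ev2 <- detect_trajectory(g2$traj, build_model(g2$traj, g2$annotation))
  tl2 <- contact_timeline(ev2, 6, "A", 101, "ionic")
  expect_equal(tl2$counts, rep(1L, 6))
  expect_equal(tl2$longest_run, 6L)
})

test_that("criteria validation rejects non-physical thresholds", {
  expect_error(interaction_criteria(hbond_max_HA = -1), "positive")
  expect_error(interaction_criteria(hbond_min_DHA = 200), "0, 180")
  expect_error(interaction_criteria(pi_max = 0), "positive")
})
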