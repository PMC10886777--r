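count_entries <- function(model, ch, rs) {
  pick <- function(df) sum(df$chain == ch & df$resseq == rs)
  pickl <- function(lst) sum(vapply(lst, function(e)
    e$chain == ch && e$resseq == rs, logical(1)))
  c(donors = pick(model$donors), acceptors = pick(model$acceptors),
    rings = pickl(model$rings), cations = pickl(model$cations),
    anions = pickl(model$anions), hydrophobes = pick(model$hydrophobes))
}

test_that("a lone LYS gets exactly one cation group at NZ", {
  traj <- make_test_peptide("LYS")
  m <- type_protein(traj)
  expect_length(m$cations, 1L)
  expect_equal(traj$atoms$name[m$cations[[1]]$atoms], "NZ")
  expect_equal(m$cations[[1]]$charge, 1)
  ## 3 NZ-H donors + 1 backbone donor
  expect_equal(nrow(m$donors), 4L)
})

test_that("a lone GLY has backbone donor+acceptor and nothing else", {
  traj <- make_test_peptide("GLY")
  m <- type_protein(traj)
  expect_equal(nrow(m$donors), 1L)
  expect_equal(traj$atoms$name[m$donors$d], "N")
  expect_equal(nrow(m$acceptors), 1L)
  expect_equal(traj$atoms$name[m$acceptors$a], "O")
  expect_equal(traj$atoms$name[m$acceptor_nbrs[[1]]], "C")
  expect_length(m$rings, 0L)
  expect_equal(nrow(m$hydrophobes), 0L)
})

test_that("the full 20-residue peptide reproduces the hand-enumerated template table", {
  expected <- read.csv(test_path("template_counts.csv"))
  traj <- make_test_peptide(expected$resname)
  m <- type_protein(traj)
  for (i in seq_len(nrow(expected))) {
    got <- count_entries(m, "A", i)
    want <- unlist(expected[i, -1])
    expect_equal(got, want, ignore_attr = TRUE,
                 label = paste("entry counts for", expected$resname[i]))
  }
})

test_that("nonstandard residues are skipped with a warning, not an error", {
  traj <- make_test_peptide(c("ALA", "GLY"))
  atoms <- traj$atoms
  atoms$resname[atoms$resseq == 2] <- "XYZ"
  traj2 <- md_trajectory(atoms, traj$coords)
  expect_warning(m <- type_protein(traj2), "XYZ")
  expect_equal(nrow(m$acceptors), 1L)  # only the ALA remains
})

test_that("water typing yields one acceptor and two donors per intact water", {
  rows <- data.frame(name = c("O", "H1", "H2", "O"), element = c("O", "H", "H", "O"),
                     resname = "HOH", chain = "W", resseq = c(1, 1, 1, 2),
                     stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0), c(8, 0, 0))
  rows$serial <- 1:4; rows$formal_charge <- 0L
  rows$is_ligand <- FALSE; rows$is_water <- TRUE
  traj <- md_trajectory(rows, array(xyz, c(4, 3, 1)))
  expect_warning(m <- type_waters(traj), "without hydrogens")
  w1 <- m$donors$resseq == 1
  expect_equal(sum(w1), 2L)           # two O-H donor pairs
  expect_equal(nrow(m$acceptors), 2L) # both oxygens accept
  expect_equal(nrow(m$donors), 2L)    # the dry water donates nothing
  ## n intact waters give 3n typed entries
  expect_equal(sum(w1) + sum(m$acceptors$resseq == 1), 3L)
})

test_that("model building is deterministic and owners partition the entries", {
  sys <- random_system(seed = 19, n_frames = 1)
  m1 <- suppressWarnings(build_model(sys$traj, sys$annotation))
  m2 <- suppressWarnings(build_model(sys$traj, sys$annotation))
  expect_identical(m1, m2)
  idx_by_owner <- function(own) {
    unique(c(m1$donors$d[m1$donors$owner == own],
             m1$acceptors$a[m1$acceptors$owner == own],
             m1$hydrophobes$idx[m1$hydrophobes$owner == own]))
  }
  expect_length(intersect(idx_by_owner("ligand"), idx_by_owner("protein")), 0L)
  expect_length(intersect(idx_by_owner("ligand"), idx_by_owner("water")), 0L)
  ## every donor hydrogen sits on its heavy atom
  x <- frame_coords(sys$traj, 1)
  dh <- sqrt(rowSums((x[m1$donors$d, , drop = FALSE] -
                      x[m1$donors$h, , drop = FALSE])^2))
  expect_true(all(dh < 1.3))
})

test_that("ligand-only systems carry only ligand-tagged entries", {
  sp <- pocket_spec(list(list(kind = "hbond", p = 1)), n_frames = 1, seed = 2)
  g <- gen_pocket_trajectory(sp)
  keep <- g$traj$atoms$is_ligand
  atoms <- g$traj$atoms[keep, ]
  traj <- md_trajectory(atoms, g$traj$coords[keep, , , drop = FALSE])
  m <- build_model(traj, g$annotation)
  expect_true(all(m$donors$owner == "ligand"))
  expect_true(all(m$acceptors$owner == "ligand"))
  expect_equal(nrow(m$hydrophobes[m$hydrophobes$owner != "ligand", ]), 0L)
})

test_that("ring centroids are coordinate means and normals are unit length", {
  traj <- make_test_peptide("PHE")
  m <- type_protein(traj)
  expect_length(m$rings, 1L)
  x <- frame_coords(traj, 1)
  rg <- pocketfp:::ring_centroid_normal(x[m$rings[[1]]$atoms, ])
  expect_equal(rg$centroid, colMeans(x[m$rings[[1]]$atoms, ]))
  expect_equal(sqrt(sum(rg$normal^2)), 1, tolerance = 1e-12)
})

test_that("the pocket generator's model matches its ground-truth site list", {
  sp <- pocket_spec(list(list(kind = "hbond", p = 0.5),
                         list(kind = "ionic", p = 0.5)),
                    n_frames = 3, seed = 5)
  g <- gen_pocket_trajectory(sp)
  m <- build_model(g$traj, g$annotation)
  expect_equal(sum(m$donors$owner == "ligand"), 1L)   # planted donor pair
  expect_length(Filter(function(x) x$owner == "ligand", m$anions), 1L)
  expect_length(Filter(function(x) x$owner == "protein", m$cations), 1L)
})
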