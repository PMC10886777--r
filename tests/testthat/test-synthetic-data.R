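test_that("degenerate plant probabilities give exact frequencies 1 and 0", {
  sp1 <- pocket_spec(list(list(kind = "hbond", p = 1)), n_frames = 100,
                     seed = 1)
  g1 <- gen_pocket_trajectory(sp1)
  expect_true(all(g1$truth$states))
  ev <- detect_trajectory(g1$traj, build_model(g1$traj, g1$annotation))
  tab <- aggregate_contacts(ev, 100)
  expect_equal(tab$value[tab$kind == "hbond"], 1.0)
  sp0 <- pocket_spec(list(list(kind = "ionic", p = 0)), n_frames = 50,
                     seed = 1)
  g0 <- gen_pocket_trajectory(sp0)
  expect_false(any(g0$truth$states))
  ev0 <- detect_trajectory(g0$traj, build_model(g0$traj, g0$annotation))
  expect_equal(nrow(ev0), 0L)
})

test_that("every planted kind is detected exactly when on and never when off", {
  kinds <- c("hbond", "hbond_acceptor", "ionic", "hydrophobic", "pi_pi")
  sp <- pocket_spec(lapply(kinds, function(k) list(kind = k, p = 0.5)),
                    n_frames = 40, seed = 23)
  g <- gen_pocket_trajectory(sp)
  m <- build_model(g$traj, g$annotation)
  ev <- detect_trajectory(g$traj, m)
  for (i in seq_along(kinds)) {
    want_kind <- g$truth$table$kind[i]
    kk <- if (want_kind %in% c("hbond_acceptor", "hbond_pair")) "hbond"
          else want_kind
    got <- sort(ev$frame[ev$resseq == 100 + i & ev$kind == kk])
    expect_identical(got, sort(which(g$truth$states[, i])),
                     label = paste("frames for plant", kinds[i]))
  }
  ## water bridge and pi-cation in a second pocket
  sp2 <- pocket_spec(list(list(kind = "water_bridge", p = 0.5),
                          list(kind = "pi_cation", p = 0.5)),
                     n_frames = 40, seed = 24)
  g2 <- gen_pocket_trajectory(sp2)
  ev2 <- detect_trajectory(g2$traj, build_model(g2$traj, g2$annotation))
  expect_identical(sort(ev2$frame[ev2$kind == "water_bridge"]),
                   sort(which(g2$truth$states[, 1])))
  expect_identical(sort(ev2$frame[ev2$kind == "pi_cation"]),
                   sort(which(g2$truth$states[, 2])))
})

test_that("generation is bit-identical under one seed and differs across seeds", {
  sp <- function(s) pocket_spec(list(list(kind = "hbond", p = 0.4)),
                                n_frames = 30, seed = s)
  a <- gen_pocket_trajectory(sp(5))
  b <- gen_pocket_trajectory(sp(5))
  c <- gen_pocket_trajectory(sp(6))
  expect_identical(a$traj$coords, b$traj$coords)
  expect_identical(a$truth$states, b$truth$states)
  expect_false(identical(a$traj$coords, c$traj$coords))
  ## two-state generator likewise
  x <- gen_two_state_trajectory(n_frames = 50, seed = 9)
  y <- gen_two_state_trajectory(n_frames = 50, seed = 9)
  z <- gen_two_state_trajectory(n_frames = 50, seed = 10)
  expect_identical(x$traj$coords, y$traj$coords)
  expect_false(identical(x$traj$coords, z$traj$coords))
})

test_that("generated pockets round-trip through PDB within format precision", {
  sp <- pocket_spec(list(list(kind = "hbond", p = 0.5),
                         list(kind = "water_bridge", p = 0.5)),
                    n_frames = 4, seed = 12)
  g <- gen_pocket_trajectory(sp)
  f <- tempfile(fileext = ".pdb")
  write_pdb(g$traj, f)
  got <- read_multimodel_pdb(f, ligand_resnames = "LIG")
  expect_equal(got$n_frames, 4L)
  expect_lt(max(abs(got$coords - g$traj$coords)), 1e-3)
  expect_identical(got$atoms$is_ligand, g$traj$atoms$is_ligand)
  expect_identical(got$atoms$is_water, g$traj$atoms$is_water)
})

test_that("two-state fractions land within three binomial deviations", {
  w <- c(0.7, 0.3)
  g <- gen_two_state_trajectory(w, n_frames = 1000, seed = 31)
  frac <- mean(g$states == 2L)
  expect_lt(abs(frac - w[2]), 3 * sqrt(w[2] * w[1] / 1000))
  expect_warning(gen_two_state_trajectory(c(0.5, 0.5), displacement = 0.5,
                                          jitter = 0.3, n_frames = 10,
                                          seed = 1), "overlap")
  expect_error(gen_two_state_trajectory(c(0.7, 0.7), n_frames = 10, seed = 1),
               "summing to 1")
})

test_that("species-energy fixtures recover planted IP/EA exactly", {
  s <- gen_species_energies(7.8, 1.5)
  expect_equal(compute_ip(s), 7.8, tolerance = 1e-12)
  expect_equal(compute_ea(s), 1.5, tolerance = 1e-12)
  s0 <- gen_species_energies(5, 0)
  expect_identical(s0$E_anion, s0$E_neutral)
  set.seed(2)
  for (i in 1:25) {
    ip <- runif(1, 4, 10); ea <- runif(1, 0, ip)
    d <- descriptors_from_species(gen_species_energies(ip, ea))
    expect_equal(d$IP, ip, tolerance = 1e-12)
    expect_equal(d$EA, ea, tolerance = 1e-12)
    expect_equal(d$eta, (ip - ea) / 2, tolerance = 1e-12)
  }
})

test_that("pocket specifications are validated eagerly", {
  expect_error(pocket_spec(list()), "at least one")
  expect_error(pocket_spec(list(list(kind = "magic", p = 0.5))), "unknown")
  expect_error(pocket_spec(list(list(kind = "hbond", p = 1.5))), "p in")
  expect_error(pocket_spec(list(list(kind = "hbond", p = 0.5)),
                           jitter_sigma = 0.5), "jitter_sigma")
  expect_error(pocket_spec(list(list(kind = "hbond", frames_on = 99)),
                           n_frames = 10), "out of range")
  expect_error(pocket_spec(rep(list(list(kind = "hbond", p = 1)), 7)),
               "at most")
})

test_that("generator seeds are recorded in the output metadata", {
  sp <- pocket_spec(list(list(kind = "hbond", p = 1)), n_frames = 2,
                    seed = 77)
  expect_equal(gen_pocket_trajectory(sp)$seed, 77L)
  expect_equal(gen_two_state_trajectory(n_frames = 5, seed = 78)$seed, 78)
})
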