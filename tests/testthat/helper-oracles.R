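# Exhaustive brute-force oracles for the five detectors, written
# independently of the package internals: plain triple loops, law-of-
# cosines angles, no early exits. Events are compared as sorted key sets.

o_dist <- function(x, i, j) sqrt(sum((x[i, ] - x[j, ])^2))

# angle p-q-r via the law of cosines (different route than the package)
o_angle <- function(x, p, q, r) {
  a <- o_dist(x, p, q); b <- o_dist(x, r, q); cc <- o_dist(x, p, r)
  arg <- (a^2 + b^2 - cc^2) / (2 * a * b)
  acos(max(-1, min(1, arg))) * 180 / pi
}

o_hbond_ok <- function(x, d, h, a, nbrs, dmax, min_dha, min_hax, mode) {
  if (!(o_dist(x, h, a) < dmax)) return(FALSE)
  dha <- o_angle(x, d, h, a)
  nbrs <- setdiff(nbrs, c(d, h))
  hax <- NA_real_
  if (length(nbrs)) {
    hax <- Inf
    for (nb in nbrs) hax <- min(hax, o_angle(x, h, a, nb))
  }
  if (mode == "and") dha >= min_dha && (is.na(hax) || hax >= min_hax)
  else dha >= min_dha || (!is.na(hax) && hax >= min_hax)
}

oracle_hbond_keys <- function(traj, model, frame, cr) {
  x <- frame_coords(traj, frame)
  keys <- character()
  for (side in list(c("ligand", "protein"), c("protein", "ligand"))) {
    don <- model$donors[model$donors$owner == side[1], , drop = FALSE]
    am <- model$acceptors$owner == side[2]
    acc <- model$acceptors[am, , drop = FALSE]
    nbrs <- model$acceptor_nbrs[am]
    if (!nrow(don) || !nrow(acc)) next
    for (i in seq_len(nrow(don))) for (j in seq_len(nrow(acc))) {
      if (acc$a[j] == don$d[i]) next
      if (o_hbond_ok(x, don$d[i], don$h[i], acc$a[j], nbrs[[j]],
                     cr$hbond_max_HA, cr$hbond_min_DHA, cr$hbond_min_HAX,
                     cr$hbond_angle_mode)) {
        prot <- if (side[1] == "protein") don[i, ] else acc[j, ]
        lig <- if (side[1] == "ligand") don[i, ] else acc[j, ]
        keys <- c(keys, paste("hbond", prot$chain, prot$resseq, lig$label,
                              prot$label,
                              round(o_dist(x, don$h[i], acc$a[j]), 9)))
      }
    }
  }
  sort(keys)
}

oracle_ionic_keys <- function(traj, model, frame, cr) {
  x <- frame_coords(traj, frame)
  keys <- character()
  gs <- c(model$cations, model$anions)
  for (gl in gs) for (gp in gs) {
    if (gl$owner != "ligand" || gp$owner != "protein") next
    if (gl$charge * gp$charge >= 0) next
    dmin <- Inf
    for (i in gl$atoms) for (j in gp$atoms) dmin <- min(dmin, o_dist(x, i, j))
    if (dmin <= cr$ionic_max)
      keys <- c(keys, paste("ionic", gp$chain, gp$resseq, gl$label, gp$label,
                            round(dmin, 9)))
  }
  sort(keys)
}

oracle_hydrophobic_keys <- function(traj, model, frame, cr) {
  x <- frame_coords(traj, frame)
  lig <- model$hydrophobes[model$hydrophobes$owner == "ligand", , drop = FALSE]
  prot <- model$hydrophobes[model$hydrophobes$owner == "protein", , drop = FALSE]
  keys <- character()
  if (!nrow(lig) || !nrow(prot)) return(keys)
  for (res in unique(paste(prot$chain, prot$resseq))) {
    pr <- prot[paste(prot$chain, prot$resseq) == res, , drop = FALSE]
    hit <- FALSE; dmin <- Inf
    for (i in lig$idx) for (j in pr$idx) {
      d <- o_dist(x, i, j)
      if (d < cr$hydrophobic_max) hit <- TRUE
      dmin <- min(dmin, d)
    }
    if (hit)
      keys <- c(keys, paste("hydrophobic", pr$chain[1], pr$resseq[1],
                            round(dmin, 9)))
  }
  sort(keys)
}

o_center <- function(x, atoms) {
  p <- c(0, 0, 0)
  for (i in atoms) p <- p + x[i, ]
  p / length(atoms)
}

oracle_pi_keys <- function(traj, model, frame, cr) {
  x <- frame_coords(traj, frame)
  keys <- character()
  for (rl in model$rings) for (rp in model$rings) {
    if (rl$owner != "ligand" || rp$owner != "protein") next
    d <- sqrt(sum((o_center(x, rl$atoms) - o_center(x, rp$atoms))^2))
    if (d <= cr$pi_max)
      keys <- c(keys, paste("pi_pi", rp$chain, rp$resseq, rl$label, rp$label,
                            round(d, 9)))
  }
  for (rl in model$rings) for (gc in model$cations) {
    if (rl$owner == "ligand" && gc$owner == "protein" && gc$charge > 0) {
      d <- sqrt(sum((o_center(x, rl$atoms) - o_center(x, gc$atoms))^2))
      if (d <= cr$pi_max)
        keys <- c(keys, paste("pi_cation", gc$chain, gc$resseq, rl$label,
                              gc$label, round(d, 9)))
    }
    if (rl$owner == "protein" && gc$owner == "ligand" && gc$charge > 0) {
      d <- sqrt(sum((o_center(x, rl$atoms) - o_center(x, gc$atoms))^2))
      if (d <= cr$pi_max)
        keys <- c(keys, paste("pi_cation", rl$chain, rl$resseq, gc$label,
                              rl$label, round(d, 9)))
    }
  }
  sort(keys)
}

# (site, water, site) triples composed from two relaxed-geometry legs
oracle_water_keys <- function(traj, model, frame, cr) {
  x <- frame_coords(traj, frame)
  legs <- function(owner_a, owner_b) {
    ## hbonds from owner_a donors to owner_b acceptors under water criteria
    out <- list()
    don <- model$donors[model$donors$owner == owner_a, , drop = FALSE]
    am <- model$acceptors$owner == owner_b
    acc <- model$acceptors[am, , drop = FALSE]
    nbrs <- model$acceptor_nbrs[am]
    if (!nrow(don) || !nrow(acc)) return(out)
    for (i in seq_len(nrow(don))) for (j in seq_len(nrow(acc)))
      if (o_hbond_ok(x, don$d[i], don$h[i], acc$a[j], nbrs[[j]],
                     cr$water_max_HA, cr$water_min_DHA, cr$water_min_HAX,
                     cr$hbond_angle_mode))
        out[[length(out) + 1L]] <- list(don = don[i, ], acc = acc[j, ])
    out
  }
  lig_wat <- c(lapply(legs("ligand", "water"), function(l)
                 list(site = l$don$label, wat = paste(l$acc$chain, l$acc$resseq))),
               lapply(legs("water", "ligand"), function(l)
                 list(site = l$acc$label, wat = paste(l$don$chain, l$don$resseq))))
  wat_prot <- c(lapply(legs("water", "protein"), function(l)
                  list(site = l$acc$label, wat = paste(l$don$chain, l$don$resseq),
                       chain = l$acc$chain, resseq = l$acc$resseq)),
                lapply(legs("protein", "water"), function(l)
                  list(site = l$don$label, wat = paste(l$acc$chain, l$acc$resseq),
                       chain = l$don$chain, resseq = l$don$resseq)))
  keys <- character()
  for (l in lig_wat) for (p in wat_prot)
    if (l$wat == p$wat)
      keys <- c(keys, paste("water_bridge", p$chain, p$resseq, l$site,
                            p$site, l$wat))
  sort(unique(keys))
}

# Matching key construction from the package's event tables.
ev_keys <- function(ev) {
  if (!nrow(ev)) return(character())
  k <- vapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    switch(e$kind,
      hbond = paste("hbond", e$chain, e$resseq, e$lig_site, e$partner_site,
                    round(e$dist, 9)),
      ionic = paste("ionic", e$chain, e$resseq, e$lig_site, e$partner_site,
                    round(e$dist, 9)),
      hydrophobic = paste("hydrophobic", e$chain, e$resseq, round(e$dist, 9)),
      pi_pi = paste("pi_pi", e$chain, e$resseq, e$lig_site, e$partner_site,
                    round(e$dist, 9)),
      pi_cation = paste("pi_cation", e$chain, e$resseq, e$lig_site,
                        e$partner_site, round(e$dist, 9)),
      water_bridge = paste("water_bridge", e$chain, e$resseq, e$lig_site,
                           e$partner_site, e$water))
  }, character(1))
  sort(k)
}
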