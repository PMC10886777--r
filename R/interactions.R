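#' @title Interaction detection and contact-frequency aggregation
#' @name interactions
#' @description
#' Per-frame geometric detection of five protein-ligand interaction classes
#' -- hydrogen bonds, water bridges, ionic (salt) bridges, hydrophobic
#' contacts and pi-pi / pi-cation stacking -- followed by aggregation into
#' per-residue contact-frequency tables (mean qualifying contacts per frame;
#' 1.0 means the contact is present in every frame, values above 1 mean a
#' residue holds several simultaneous contacts of that class) and
#' persistence timelines.
NULL

#' Geometric interaction criteria
#'
#' Distance/angle thresholds for the five detectors. Defaults: hydrogen
#' bonds H...A < 2.5 Angstrom with D-H-A >= 120 deg and (when the acceptor
#' has bonded neighbors X) H-A-X >= 90 deg; water-bridge legs relaxed to
#' H...A < 2.8 Angstrom and D-H-A >= 110 deg; ionic contacts at <= 3.4
#' Angstrom between charged atoms; hydrophobic contacts < 3.6 Angstrom;
#' pi-pi and pi-cation stacking at centroid distance <= 4.5 Angstrom.
#'
#' `hbond_angle_mode` selects how the two angle clauses combine: `"and"`
#' (both minima must hold; default) or `"or"` (either suffices).
#'
#' @param hbond_max_HA,water_max_HA H...A distance cutoffs, Angstrom.
#' @param hbond_min_DHA,water_min_DHA minimum donor-H-acceptor angle, deg.
#' @param hbond_min_HAX,water_min_HAX minimum H-acceptor-neighbor angle, deg.
#' @param ionic_max,hydrophobic_max,pi_max distance cutoffs, Angstrom.
#' @param hbond_angle_mode `"and"` or `"or"`.
#' @return Object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_max_HA = 2.5, hbond_min_DHA = 120,
                                 hbond_min_HAX = 90, water_max_HA = 2.8,
                                 water_min_DHA = 110, water_min_HAX = 90,
                                 ionic_max = 3.4, hydrophobic_max = 3.6,
                                 pi_max = 4.5,
                                 hbond_angle_mode = c("and", "or")) {
  cr <- list(hbond_max_HA = hbond_max_HA, hbond_min_DHA = hbond_min_DHA,
             hbond_min_HAX = hbond_min_HAX, water_max_HA = water_max_HA,
             water_min_DHA = water_min_DHA, water_min_HAX = water_min_HAX,
             ionic_max = ionic_max, hydrophobic_max = hydrophobic_max,
             pi_max = pi_max,
             hbond_angle_mode = match.arg(hbond_angle_mode))
  dists <- unlist(cr[c("hbond_max_HA", "water_max_HA", "ionic_max",
                       "hydrophobic_max", "pi_max")])
  angs <- unlist(cr[c("hbond_min_DHA", "hbond_min_HAX", "water_min_DHA",
                      "water_min_HAX")])
  if (any(!is.finite(dists)) || any(dists <= 0))
    stop("all distance cutoffs must be positive")
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs > 180))
    stop("all angle thresholds must lie in (0, 180]")
  structure(cr, class = "interaction_criteria")
}

EVENT_COLS <- c("frame", "kind", "lig_site", "chain", "resseq", "resname",
                "partner_site", "dist", "ang_dha", "ang_hax", "water",
                ".i1", ".i2")

empty_events <- function() {
  data.frame(frame = integer(), kind = character(), lig_site = character(),
             chain = character(), resseq = integer(), resname = character(),
             partner_site = character(), dist = numeric(),
             ang_dha = numeric(), ang_hax = numeric(), water = character(),
             .i1 = integer(), .i2 = integer(), stringsAsFactors = FALSE)
}

event_row <- function(frame, kind, lig_site, chain, resseq, resname,
                      partner_site, dist, ang_dha = NA_real_,
                      ang_hax = NA_real_, water = NA_character_,
                      i1 = NA_integer_, i2 = NA_integer_) {
  data.frame(frame = frame, kind = kind, lig_site = lig_site, chain = chain,
             resseq = resseq, resname = resname, partner_site = partner_site,
             dist = dist, ang_dha = ang_dha, ang_hax = ang_hax, water = water,
             .i1 = i1, .i2 = i2, stringsAsFactors = FALSE)
}

bind_events <- function(lst) {
  lst <- lst[vapply(lst, function(x) !is.null(x) && nrow(x) > 0, logical(1))]
  if (!length(lst)) return(empty_events())
  do.call(rbind, lst)
}

## All (donor row, acceptor row) pairs satisfying the hydrogen-bond
## geometry. Returns row indices into donors/acceptors plus the measures.
hbond_pairs <- function(donors, acceptors, acceptor_nbrs, xyz,
                        dmax, min_dha, min_hax, mode) {
  out <- list()
  if (!nrow(donors) || !nrow(acceptors)) return(out)
  for (i in seq_len(nrow(donors))) {
    d <- donors$d[i]; h <- donors$h[i]
    for (j in seq_len(nrow(acceptors))) {
      a <- acceptors$a[j]
      if (a == d) next  # a site cannot bond to itself
      dha_dist <- dist3(xyz[h, ], xyz[a, ])
      if (!(dha_dist < dmax)) next
      ang1 <- angle_deg(xyz[d, ], xyz[h, ], xyz[a, ])
      nbrs <- acceptor_nbrs[[j]]
      nbrs <- setdiff(nbrs, c(d, h))
      ang2 <- if (length(nbrs))
        min(vapply(nbrs, function(x)
          angle_deg(xyz[h, ], xyz[a, ], xyz[x, ]), numeric(1)))
      else NA_real_
      ok <- if (mode == "and")
        (ang1 >= min_dha) && (is.na(ang2) || ang2 >= min_hax)
      else
        (ang1 >= min_dha) || (!is.na(ang2) && ang2 >= min_hax)
      if (ok)
        out[[length(out) + 1L]] <- list(di = i, aj = j, dist = dha_dist,
                                        ang_dha = ang1, ang_hax = ang2)
    }
  }
  out
}

owner_rows <- function(df, own) df[df$owner == own, , drop = FALSE]

#' Detect ligand-protein hydrogen bonds in one frame
#'
#' Scans both directions (ligand donor to protein acceptor and protein
#' donor to ligand acceptor). A pair qualifies when H...A is below the
#' cutoff, the D-H-A angle is at least the minimum and -- when the acceptor
#' has bonded neighbors X -- the smallest H-A-X angle is at least its
#' minimum (see [interaction_criteria()] for the `"or"` variant).
#'
#' @param traj an [md_trajectory()].
#' @param model a [build_model()] result.
#' @param frame 1-based frame index.
#' @param criteria an [interaction_criteria()].
#' @return Event data.frame (one row per qualifying site pair).
#' @export
detect_hbonds <- function(traj, model, frame, criteria = interaction_criteria()) {
  xyz <- frame_coords(traj, frame)
  ## hydrogen-bond capable system (acceptors on both sides) but no donor
  ## hydrogens anywhere: the topology was stripped of hydrogens
  no_donors <- !any(model$donors$owner %in% c("ligand", "protein"))
  capable <- any(model$acceptors$owner == "ligand") &&
    any(model$acceptors$owner == "protein")
  if (no_donors && capable && !any(toupper(traj$atoms$element) == "H"))
    stop("no donor hydrogens in the topology: hydrogen-bond detection needs explicit hydrogens")
  scan <- function(don_owner, acc_owner) {
    don <- owner_rows(model$donors, don_owner)
    accs <- model$acceptors$owner == acc_owner
    acc <- model$acceptors[accs, , drop = FALSE]
    nbrs <- model$acceptor_nbrs[accs]
    hits <- hbond_pairs(don, acc, nbrs, xyz, criteria$hbond_max_HA,
                        criteria$hbond_min_DHA, criteria$hbond_min_HAX,
                        criteria$hbond_angle_mode)
    lapply(hits, function(hh) {
      dr <- don[hh$di, ]; ar <- acc[hh$aj, ]
      prot <- if (don_owner == "protein") dr else ar
      lig <- if (don_owner == "ligand") dr else ar
      event_row(frame, "hbond", lig$label, prot$chain, prot$resseq,
                prot$resname, prot$label, hh$dist, hh$ang_dha, hh$ang_hax,
                i1 = min(dr$d, ar$a), i2 = max(dr$d, ar$a))
    })
  }
  ev <- c(scan("ligand", "protein"), scan("protein", "ligand"))
  order_events(bind_events(ev))
}

#' Detect ionic (salt-bridge) contacts in one frame
#'
#' One event per ligand/protein pair of oppositely charged groups whose
#' minimal inter-atom distance over group members is at most `ionic_max`.
#'
#' @inheritParams detect_hbonds
#' @return Event data.frame.
#' @export
detect_ionic <- function(traj, model, frame, criteria = interaction_criteria()) {
  xyz <- frame_coords(traj, frame)
  groups <- c(model$cations, model$anions)
  lig <- Filter(function(g) g$owner == "ligand", groups)
  prot <- Filter(function(g) g$owner == "protein", groups)
  ev <- list()
  for (gl in lig) for (gp in prot) {
    if (sign(gl$charge) * sign(gp$charge) >= 0) next
    dmin <- min_cross_dist(xyz[gl$atoms, , drop = FALSE],
                           xyz[gp$atoms, , drop = FALSE])
    if (dmin <= criteria$ionic_max)
      ev[[length(ev) + 1L]] <- event_row(
        frame, "ionic", gl$label, gp$chain, gp$resseq, gp$resname, gp$label,
        dmin, i1 = min(gl$atoms), i2 = min(gp$atoms))
  }
  order_events(bind_events(ev))
}

#' Detect hydrophobic contacts in one frame
#'
#' At most one event per (ligand, residue) pair per frame, emitted when any
#' ligand-hydrophobe / residue-hydrophobe atom pair is closer than
#' `hydrophobic_max`. The reported geometry is the closest pair.
#'
#' @inheritParams detect_hbonds
#' @return Event data.frame.
#' @export
detect_hydrophobic <- function(traj, model, frame,
                               criteria = interaction_criteria()) {
  xyz <- frame_coords(traj, frame)
  lig <- owner_rows(model$hydrophobes, "ligand")
  prot <- owner_rows(model$hydrophobes, "protein")
  ev <- list()
  if (!nrow(lig) || !nrow(prot)) return(empty_events())
  for (res in split(seq_len(nrow(prot)), paste(prot$chain, prot$resseq))) {
    pi_ <- prot$idx[res]
    d2 <- outer(rowSums(xyz[lig$idx, , drop = FALSE]^2),
                rowSums(xyz[pi_, , drop = FALSE]^2), "+") -
      2 * xyz[lig$idx, , drop = FALSE] %*% t(xyz[pi_, , drop = FALSE])
    dmin <- sqrt(max(0, min(d2)))
    if (dmin < criteria$hydrophobic_max) {
      best <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
      lr <- lig[best[1], ]; pr <- prot[res[best[2]], ]
      ev[[length(ev) + 1L]] <- event_row(
        frame, "hydrophobic", lr$label, pr$chain, pr$resseq, pr$resname,
        pr$label, dmin, i1 = lr$idx, i2 = pr$idx)
    }
  }
  order_events(bind_events(ev))
}

group_center <- function(xyz, atoms) {
  if (length(atoms) == 1L) xyz[atoms, ] else colMeans(xyz[atoms, , drop = FALSE])
}

#' Detect pi-pi and pi-cation stacking in one frame
#'
#' pi-pi: ligand-ring / protein-ring centroid distance at most `pi_max`.
#' pi-cation: ring centroid to charged-group center at most `pi_max`,
#' scanned in both orientations (ligand ring vs protein cation and ligand
#' cation vs protein ring). Centroid distance is the only default filter;
#' no ring-plane angle condition is applied.
#'
#' @inheritParams detect_hbonds
#' @return Event data.frame with kinds `pi_pi` and `pi_cation`.
#' @export
detect_pi <- function(traj, model, frame, criteria = interaction_criteria()) {
  xyz <- frame_coords(traj, frame)
  ligR <- Filter(function(r) r$owner == "ligand", model$rings)
  protR <- Filter(function(r) r$owner == "protein", model$rings)
  ligC <- Filter(function(g) g$owner == "ligand" && g$charge > 0, model$cations)
  protC <- Filter(function(g) g$owner == "protein" && g$charge > 0, model$cations)
  ev <- list()
  for (rl in ligR) for (rp in protR) {
    d <- dist3(group_center(xyz, rl$atoms), group_center(xyz, rp$atoms))
    if (d <= criteria$pi_max)
      ev[[length(ev) + 1L]] <- event_row(
        frame, "pi_pi", rl$label, rp$chain, rp$resseq, rp$resname, rp$label,
        d, i1 = min(rl$atoms), i2 = min(rp$atoms))
  }
  for (rl in ligR) for (gc in protC) {
    d <- dist3(group_center(xyz, rl$atoms), group_center(xyz, gc$atoms))
    if (d <= criteria$pi_max)
      ev[[length(ev) + 1L]] <- event_row(
        frame, "pi_cation", rl$label, gc$chain, gc$resseq, gc$resname,
        gc$label, d, i1 = min(rl$atoms), i2 = min(gc$atoms))
  }
  for (gc in ligC) for (rp in protR) {
    d <- dist3(group_center(xyz, gc$atoms), group_center(xyz, rp$atoms))
    if (d <= criteria$pi_max)
      ev[[length(ev) + 1L]] <- event_row(
        frame, "pi_cation", gc$label, rp$chain, rp$resseq, rp$resname,
        rp$label, d, i1 = min(gc$atoms), i2 = min(rp$atoms))
  }
  order_events(bind_events(ev))
}

#' Detect water-mediated hydrogen-bond bridges in one frame
#'
#' One event per (ligand site, water, protein site) triple in which the
#' ligand-water contact and the water-protein contact each satisfy the
#' relaxed water hydrogen-bond geometry (`water_max_HA`, `water_min_DHA`,
#' `water_min_HAX`); each leg may run in either donor/acceptor direction.
#' The bridging water is recorded on the event.
#'
#' @inheritParams detect_hbonds
#' @return Event data.frame with kind `water_bridge`.
#' @export
detect_water_bridges <- function(traj, model, frame,
                                 criteria = interaction_criteria()) {
  xyz <- frame_coords(traj, frame)
  wat_don <- owner_rows(model$donors, "water")
  wacc <- model$acceptors$owner == "water"
  wat_acc <- model$acceptors[wacc, , drop = FALSE]
  wat_nbrs <- model$acceptor_nbrs[wacc]
  if (!nrow(wat_don) && !nrow(wat_acc)) return(empty_events())

  leg <- function(don, accs_mask) {
    acc <- model$acceptors[accs_mask, , drop = FALSE]
    hbond_pairs(don, acc, model$acceptor_nbrs[accs_mask], xyz,
                criteria$water_max_HA, criteria$water_min_DHA,
                criteria$water_min_HAX, criteria$hbond_angle_mode)
  }
  ## ligand <-> water legs, tagged by water residue
  lw <- list()
  lig_don <- owner_rows(model$donors, "ligand")
  hits <- hbond_pairs(lig_don, wat_acc, wat_nbrs, xyz, criteria$water_max_HA,
                      criteria$water_min_DHA, criteria$water_min_HAX,
                      criteria$hbond_angle_mode)
  for (hh in hits) {
    ar <- wat_acc[hh$aj, ]
    lw[[length(lw) + 1L]] <- list(wat = paste(ar$chain, ar$resseq),
                                  site = lig_don[hh$di, ]$label,
                                  i = lig_don[hh$di, ]$d)
  }
  lacc <- model$acceptors$owner == "ligand"
  hits <- hbond_pairs(wat_don, model$acceptors[lacc, , drop = FALSE],
                      model$acceptor_nbrs[lacc], xyz, criteria$water_max_HA,
                      criteria$water_min_DHA, criteria$water_min_HAX,
                      criteria$hbond_angle_mode)
  for (hh in hits) {
    dr <- wat_don[hh$di, ]
    ar <- model$acceptors[lacc, , drop = FALSE][hh$aj, ]
    lw[[length(lw) + 1L]] <- list(wat = paste(dr$chain, dr$resseq),
                                  site = ar$label, i = ar$a)
  }
  ## water <-> protein legs
  wp <- list()
  pacc <- model$acceptors$owner == "protein"
  hits <- hbond_pairs(wat_don, model$acceptors[pacc, , drop = FALSE],
                      model$acceptor_nbrs[pacc], xyz, criteria$water_max_HA,
                      criteria$water_min_DHA, criteria$water_min_HAX,
                      criteria$hbond_angle_mode)
  for (hh in hits) {
    dr <- wat_don[hh$di, ]
    ar <- model$acceptors[pacc, , drop = FALSE][hh$aj, ]
    wp[[length(wp) + 1L]] <- list(wat = paste(dr$chain, dr$resseq),
                                  chain = ar$chain, resseq = ar$resseq,
                                  resname = ar$resname, site = ar$label,
                                  i = ar$a)
  }
  prot_don <- owner_rows(model$donors, "protein")
  hits <- hbond_pairs(prot_don, wat_acc, wat_nbrs, xyz, criteria$water_max_HA,
                      criteria$water_min_DHA, criteria$water_min_HAX,
                      criteria$hbond_angle_mode)
  for (hh in hits) {
    dr <- prot_don[hh$di, ]
    ar <- wat_acc[hh$aj, ]
    wp[[length(wp) + 1L]] <- list(wat = paste(ar$chain, ar$resseq),
                                  chain = dr$chain, resseq = dr$resseq,
                                  resname = dr$resname, site = dr$label,
                                  i = dr$d)
  }
  ev <- list()
  for (l in lw) for (p in wp) {
    if (l$wat != p$wat) next
    ev[[length(ev) + 1L]] <- event_row(
      frame, "water_bridge", l$site, p$chain, p$resseq, p$resname, p$site,
      NA_real_, water = l$wat, i1 = l$i, i2 = p$i)
  }
  ## distinct (ligand site, water, residue site) triples only; the same
  ## triple can be reached through both water hydrogens
  ev <- bind_events(ev)
  if (nrow(ev))
    ev <- ev[!duplicated(ev[, c("lig_site", "water", "chain", "resseq",
                                "partner_site")]), ]
  order_events(ev)
}

order_events <- function(ev) {
  if (!nrow(ev)) return(ev)
  ev <- ev[order(ev$kind, ev$chain, ev$resseq, ev$.i1, ev$.i2,
                 ev$lig_site, ev$partner_site, ev$water,
                 method = "radix"), ]
  rownames(ev) <- NULL
  ev
}

#' Detect all interaction classes in one frame
#'
#' Union of the five detectors, in a deterministic order
#' (kind, then residue, then ascending atom index).
#'
#' @inheritParams detect_hbonds
#' @return Event data.frame.
#' @export
detect_frame <- function(traj, model, frame, criteria = interaction_criteria()) {
  order_events(bind_events(list(
    detect_hbonds(traj, model, frame, criteria),
    detect_ionic(traj, model, frame, criteria),
    detect_hydrophobic(traj, model, frame, criteria),
    detect_pi(traj, model, frame, criteria),
    detect_water_bridges(traj, model, frame, criteria))))
}

#' Detect interactions over all (or selected) frames
#'
#' @inheritParams detect_hbonds
#' @param frames 1-based frame indices (default: all frames).
#' @return Event data.frame over all scanned frames.
#' @export
detect_trajectory <- function(traj, model, criteria = interaction_criteria(),
                              frames = NULL) {
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  bind_events(lapply(frames, function(f)
    detect_frame(traj, model, f, criteria)))
}

#' Aggregate events into a contact-frequency table
#'
#' For every (residue, interaction kind) the value is the total event count
#' divided by the number of frames: 0.25 means the contact is present a
#' quarter of the simulated time, 1.0 means it is held throughout, and
#' values above 1 mean the residue carries several simultaneous contacts
#' of that kind (e.g. two persistent hydrogen bonds).
#'
#' @param events event data.frame from the detectors.
#' @param n_frames number of frames scanned (must be >= 1).
#' @return data.frame `chain, resseq, resname, kind, count, value` of class
#'   `contact_frequency_table`, with `n_frames` as an attribute.
#' @export
aggregate_contacts <- function(events, n_frames) {
  if (length(n_frames) != 1L || !is.finite(n_frames) || n_frames < 1)
    stop("n_frames must be a positive integer")
  if (!nrow(events)) {
    out <- data.frame(chain = character(), resseq = integer(),
                      resname = character(), kind = character(),
                      count = integer(), value = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(events$chain, events$resseq, events$resname, events$kind,
                 sep = "\r")
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    out <- data.frame(chain = parts[, 1], resseq = as.integer(parts[, 2]),
                      resname = parts[, 3], kind = parts[, 4],
                      count = as.integer(tab),
                      value = as.integer(tab) / n_frames,
                      stringsAsFactors = FALSE)
    out <- out[order(out$chain, out$resseq, out$kind), ]
    rownames(out) <- NULL
  }
  attr(out, "n_frames") <- as.integer(n_frames)
  class(out) <- c("contact_frequency_table", class(out))
  out
}

#' Per-frame presence/count timeline for one contact key
#'
#' @param events event data.frame.
#' @param n_frames total frames scanned.
#' @param chain,resseq residue identity.
#' @param kind optional interaction kind; `NULL` counts all kinds.
#' @return List with `counts` (integer per frame) and `longest_run`
#'   (longest consecutive stretch of frames with at least one contact).
#' @export
contact_timeline <- function(events, n_frames, chain, resseq, kind = NULL) {
  sel <- events$chain == chain & events$resseq == resseq
  if (!is.null(kind)) sel <- sel & events$kind == kind
  counts <- integer(n_frames)
  if (any(sel)) {
    tb <- table(events$frame[sel])
    counts[as.integer(names(tb))] <- as.integer(tb)
  }
  present <- counts > 0
  runs <- rle(present)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(counts = counts, longest_run = longest)
}

#' Strip internal sort columns from an event table
#' @param events event data.frame.
#' @return The same events without the internal ordering columns.
#' @export
tidy_events <- function(events) {
  events[, setdiff(names(events), c(".i1", ".i2")), drop = FALSE]
}
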