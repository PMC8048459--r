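# Synthetic fixtures: toy molecules with analytic Hessians, cross-link-like
# molecules with a known residue partition, and multi-chain helical
# trajectories with planted hydrogen-bond geometry.
#
# Every generator is deterministic given its seed, and the generating truth
# is always returned alongside the data so recovery tests never read truth
# from the data itself.

#' Build a toy molecule with a known harmonic force field
#'
#' The returned Hessian is the analytic MM Hessian of the generating force
#' field at the generating geometry, so it is ground truth for parameter
#' recovery.
#'
#' @param recipe list with \code{names}, \code{elements} (optional),
#'   \code{masses} (optional), \code{coords} (N x 3, nm), \code{bonds}
#'   (data.frame i, j, k_b, b0) and \code{angles} (data.frame i, j, k,
#'   k_theta, theta0).
#' @return list with \code{geometry}, \code{ff} (a \code{harmonic_ff}),
#'   \code{hessian} (kJ mol^-1 nm^-2).
#' @export
make_toy_molecule <- function(recipe) {
  atoms <- atom_table(recipe$names, element = recipe$elements)
  if (!is.null(recipe$masses)) atoms$mass <- recipe$masses
  geom <- molecule_geometry(atoms, recipe$coords)
  n <- nrow(atoms)
  refs <- c(recipe$bonds$i, recipe$bonds$j,
            recipe$angles$i, recipe$angles$j, recipe$angles$k)
  if (length(refs) && any(refs < 1 | refs > n)) {
    stop("recipe references atom outside 1..", n)
  }
  ff <- harmonic_ff(bonds = recipe$bonds, angles = recipe$angles)
  list(geometry = geom, ff = ff, hessian = build_mm_hessian(geom, ff))
}

#' Diatomic recipe at exact equilibrium
#'
#' @param k_b bond force constant (kJ mol^-1 nm^-2).
#' @param b0 bond length (nm).
#' @param element element symbol for both atoms.
#' @param masses optional explicit masses (amu).
#' @return a recipe list for \code{\link{make_toy_molecule}}.
#' @export
recipe_diatomic <- function(k_b = 1000, b0 = 0.1, element = "C", masses = NULL) {
  list(names = c(paste0(element, "1"), paste0(element, "2")),
       elements = c(element, element), masses = masses,
       coords = rbind(c(0, 0, 0), c(b0, 0, 0)),
       bonds = data.frame(i = 1L, j = 2L, k_b = k_b, b0 = b0),
       angles = NULL)
}

#' Bent (water-like) triatomic recipe at exact equilibrium
#'
#' Two bonds plus one angle with the apex at atom 1; the geometry realizes
#' every equilibrium value exactly. Default constants are at the realistic
#' magnitudes HF Hessians of small molecules give (O-H stretch ~4.6e5
#' kJ mol^-1 nm^-2, H-O-H bend ~3e2 kJ mol^-1 rad^-2); soft unrealistic
#' bonds make the Seminario bond projection angle-contaminated.
#'
#' @param k1,k2 bond force constants (kJ mol^-1 nm^-2).
#' @param b1,b2 bond lengths (nm).
#' @param k_theta angle force constant (kJ mol^-1 rad^-2); 0 drops the term.
#' @param theta0 equilibrium angle (degrees).
#' @param elements three element symbols, apex first.
#' @return a recipe list.
#' @export
recipe_water_like <- function(k1 = 462750, k2 = 462750, b1 = 0.096, b2 = 0.096,
                              k_theta = 317, theta0 = 104.5,
                              elements = c("O", "H", "H")) {
  th <- theta0 * pi / 180
  coords <- rbind(c(0, 0, 0),
                  c(b1, 0, 0),
                  c(b2 * cos(th), b2 * sin(th), 0))
  angles <- if (k_theta > 0) {
    data.frame(i = 2L, j = 1L, k = 3L, k_theta = k_theta, theta0 = theta0)
  } else NULL
  list(names = paste0(elements, 1:3), elements = elements,
       coords = coords,
       bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L),
                          k_b = c(k1, k2), b0 = c(b1, b2)),
       angles = angles)
}

#' Five-atom non-planar chain recipe at exact equilibrium
#'
#' Four bonds and three angles with distinct constants at realistic
#' Amber-like magnitudes; the chain is built in 3D so no angle is
#' degenerate.
#'
#' @return a recipe list.
#' @export
recipe_chain5 <- function() {
  b0 <- c(0.10, 0.12, 0.14, 0.11)
  th <- c(109.5, 120.0, 100.0) * pi / 180
  coords <- matrix(0, 5, 3)
  coords[2, ] <- c(b0[1], 0, 0)
  # place each next atom at the required distance and angle, twisting out
  # of plane for a non-degenerate 3D chain
  dihed <- c(0, 60, -70) * pi / 180
  for (a in 3:5) {
    i <- a - 2L; j <- a - 1L
    u <- .unit(coords[j, ] - coords[i, ])
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    p <- .unit(cross3(u, ref))
    q <- cross3(u, p)
    ang <- pi - th[a - 2L]
    dir <- cos(ang) * u + sin(ang) * (cos(dihed[a - 2L]) * p + sin(dihed[a - 2L]) * q)
    coords[a, ] <- coords[j, ] + b0[a - 1L] * dir
  }
  list(names = c("C1", "C2", "C3", "C4", "C5"),
       elements = rep("C", 5),
       coords = coords,
       bonds = data.frame(i = 1:4, j = 2:5,
                          k_b = c(259408, 282001, 251040, 265266), b0 = b0),
       angles = data.frame(i = 1:3, j = 2:4, k = 3:5,
                           k_theta = c(418, 669, 527),
                           theta0 = c(109.5, 120.0, 100.0)))
}

# Lay a named chain of atoms along a jittered 3D path with ~0.15 nm steps.
.chain_coords <- function(n, seed) {
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
  dirs[1, ] <- c(1, 0, 0)
  steps <- t(apply(dirs, 1, function(v) 0.15 * v / sqrt(sum(v^2))))
  apply(steps, 2, cumsum)
}

#' Build a cross-link-shaped fixture with a known residue partition
#'
#' A reduced molecule carrying the atom-naming conventions the default
#' hydrogen-bond donor/acceptor sets use (HD5, HD6, HD10, HD12, HD13, HN;
#' N, ND2, ND4-ND6, OD1-OD5), an explicit bond graph, a declared
#' lysine-side/arginine-side boundary bond, methyl cap atoms, and random
#' zero-sum charges. The three kinds differ in how many carbonyl/hydroxyl
#' oxygens decorate the arginine-derived half, loosely mirroring the
#' 3-deoxyglucosone-, glyoxal-, and methylglyoxal-derived cross-links.
#'
#' @param kind \code{"DOGDIC-like"}, \code{"GODIC-like"} or
#'   \code{"MODIC-like"}.
#' @param seed RNG seed for the geometry jitter and charges.
#' @return list with \code{geometry} (charges populated), \code{bonds}
#'   (explicit bond data.frame), \code{boundary} (list of name pairs),
#'   \code{caps} (cap atom names), \code{truth} (generating partition).
#' @export
make_crosslink_fixture <- function(kind = c("DOGDIC-like", "GODIC-like",
                                            "MODIC-like"),
                                   seed = 42L) {
  kind <- match.arg(kind)
  # lysine-derived half: backbone amide + side chain reaching CE
  side_a <- c("N", "HN", "CA", "CB", "CD", "CE", "ND2", "HD5", "OD1", "HD6")
  # arginine-derived half: imidazolium-like ring with ND4/ND5/ND6
  side_b <- c("CX", "ND4", "HD10", "ND5", "HD12", "ND6", "HD13", "CZ",
              "OD2", "OD3", "OD4", "OD5")
  drop <- switch(kind, "DOGDIC-like" = character(),
                 "GODIC-like" = c("OD4", "OD5"),
                 "MODIC-like" = "OD5")
  side_b <- setdiff(side_b, drop)
  caps <- c("CM1", "CM2")
  nm <- c(side_a, side_b, caps)
  bonds_nm <- rbind(
    c("N", "HN"), c("N", "CA"), c("CA", "CB"), c("CB", "CD"), c("CD", "CE"),
    c("CA", "ND2"), c("ND2", "HD5"), c("CB", "OD1"), c("OD1", "HD6"),
    c("CE", "CX"),                       # the boundary bond
    c("CX", "ND4"), c("ND4", "HD10"), c("ND4", "ND5"), c("ND5", "HD12"),
    c("ND5", "ND6"), c("ND6", "HD13"), c("ND6", "CZ"), c("CZ", "OD2"),
    c("CX", "OD3"),
    if (!"OD4" %in% drop) c("CZ", "OD4"),
    if (!"OD5" %in% drop) c("OD3", "OD5"),
    c("CM1", "N"), c("CM2", "CZ"))
  elem <- element_from_name(nm)
  elem[nm %in% caps] <- "C"
  coords <- .chain_coords(length(nm), seed)
  atoms <- atom_table(nm, element = elem)
  # zero-net charge holds over the central fragment (caps excluded, as in
  # restrained charge fitting with neutral capped groups)
  set.seed(seed + 1L)
  core <- !nm %in% caps
  q <- stats::runif(sum(core), -0.6, 0.6)
  atoms$charge <- 0
  atoms$charge[core] <- q - mean(q)
  geom <- molecule_geometry(atoms, coords)
  bonds <- data.frame(i = match(bonds_nm[, 1], nm), j = match(bonds_nm[, 2], nm))
  list(geometry = geom, bonds = bonds,
       boundary = list(c("CE", "CX")), caps = caps,
       truth = list(kind = kind, side_a = side_a, side_b = side_b,
                    caps = caps))
}

#' Generate a multi-chain helical trajectory with planted hydrogen bonds
#'
#' Three helical chains (labels A, B, C) with backbone atoms N, CA, C, O
#' emulate a triple-helix-like scaffold; a separate bank of donor
#' (O-H) / acceptor (O) probe groups carries planted hydrogen-bond
#' geometry. Per frame, the number of planted bonds is either fixed or
#' drawn from a Binomial count model; planted pairs are projected exactly
#' onto the target distance/angle after noise, unplanted probes are parked
#' beyond the cutoff. Optionally frames alternate between two backbone
#' conformers.
#'
#' @param n_frames number of frames.
#' @param n_res residues per chain (default 10).
#' @param sigma isotropic Gaussian positional noise, nm (default 0.002).
#' @param n_probes number of donor/acceptor probe pairs (default 12).
#' @param planted either a single count (plant that many bonds each frame)
#'   or \code{list(n = , p = )} for a per-frame Binomial draw; must not
#'   exceed \code{n_probes}.
#' @param hb_distance planted donor-acceptor distance, nm (default 0.28).
#' @param two_conformer alternate frames between two backbone conformers.
#' @param box optional 3x3 triclinic cell matrix (NULL = non-periodic).
#' @param rise,twist helix rise (nm) and twist (degrees) per residue.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with \code{traj} (a \code{trajectory}), \code{bonds}
#'   (bond graph for hydrogen resolution), \code{donor_sel} /
#'   \code{acceptor_sel} (probe atom indices), \code{truth} (per-frame
#'   planted counts, conformer labels, generator parameters).
#' @export
make_synthetic_trajectory <- function(n_frames = 100L, n_res = 10L,
                                      sigma = 0.002, n_probes = 12L,
                                      planted = 1L, hb_distance = 0.28,
                                      two_conformer = FALSE, box = NULL,
                                      rise = 0.29, twist = 103, seed = 1L) {
  stopifnot(n_frames >= 1L, n_res >= 2L, sigma >= 0)
  set.seed(seed)

  # --- backbone scaffold: 3 chains, ideal helix ---
  chains <- c("A", "B", "C")
  bb_names <- c("N", "CA", "C", "O")
  bb_elem <- c("N", "C", "C", "O")
  bb_off <- rbind(c(0, 0, 0), c(0.05, 0.02, 0.03),
                  c(0.10, -0.02, 0.05), c(0.12, 0.05, 0.08))
  at <- list(); xyz <- list()
  for (ci in seq_along(chains)) {
    phase <- 2 * pi * (ci - 1) / 3
    for (ri in seq_len(n_res)) {
      ang <- phase + (ri - 1) * twist * pi / 180
      center <- c(0.4 * cos(ang), 0.4 * sin(ang), (ri - 1) * rise)
      for (ai in seq_along(bb_names)) {
        at[[length(at) + 1L]] <- data.frame(
          name = bb_names[ai], element = bb_elem[ai],
          chain = chains[ci], resid = ri, stringsAsFactors = FALSE)
        xyz[[length(xyz) + 1L]] <- center + bb_off[ai, ]
      }
    }
  }
  # --- probe bank: OW-HW donor groups and OA acceptors, well separated ---
  probe_first <- length(at) + 1L
  for (p in seq_len(n_probes)) {
    base <- c(3 + 1.2 * ((p - 1) %% 4), 3 + 1.2 * ((p - 1) %/% 4), 0.5 * p)
    at[[length(at) + 1L]] <- data.frame(name = "OW", element = "O",
                                        chain = "W", resid = p,
                                        stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- base
    at[[length(at) + 1L]] <- data.frame(name = "HW", element = "H",
                                        chain = "W", resid = p,
                                        stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- base + c(0.1, 0, 0)
    at[[length(at) + 1L]] <- data.frame(name = "OA", element = "O",
                                        chain = "V", resid = p,
                                        stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- base + c(0.6, 0, 0)
  }
  atoms <- do.call(rbind, at)
  atoms$index <- seq_len(nrow(atoms))
  atoms$mass <- element_mass(atoms$element)
  atoms$charge <- 0
  base_xyz <- do.call(rbind, xyz)
  n_atoms <- nrow(atoms)

  # bond graph: backbone chain bonds + probe O-H bonds
  bonds <- list()
  for (ci in seq_along(chains)) for (ri in seq_len(n_res)) {
    o <- (ci - 1) * n_res * 4 + (ri - 1) * 4
    bonds[[length(bonds) + 1L]] <- data.frame(i = o + 1, j = o + 2) # N-CA
    bonds[[length(bonds) + 1L]] <- data.frame(i = o + 2, j = o + 3) # CA-C
    bonds[[length(bonds) + 1L]] <- data.frame(i = o + 3, j = o + 4) # C-O
    if (ri > 1) bonds[[length(bonds) + 1L]] <-
        data.frame(i = o - 4 + 3, j = o + 1)                         # C-N
  }
  probe_idx <- function(p) probe_first + 3L * (p - 1L)
  for (p in seq_len(n_probes)) {
    bonds[[length(bonds) + 1L]] <- data.frame(i = probe_idx(p),
                                              j = probe_idx(p) + 1L)
  }
  bonds <- do.call(rbind, bonds)

  # second conformer: bend the top half of every chain
  conf2 <- base_xyz
  top <- base_xyz[, 3] > (n_res / 2) * rise
  rot <- matrix(c(cos(0.4), -sin(0.4), 0, sin(0.4), cos(0.4), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  conf2[top, ] <- base_xyz[top, ] %*% t(rot) + matrix(c(0.3, 0.2, 0),
                                                     sum(top), 3, byrow = TRUE)

  # per-frame planted counts
  planted_counts <- if (is.list(planted)) {
    stats::rbinom(n_frames, planted$n, planted$p)
  } else rep_len(as.integer(planted), n_frames)
  if (max(planted_counts) > n_probes) stop("planted count exceeds n_probes")
  if (sigma > 0.02) {
    warning("noise sigma ", sigma,
            " nm is large relative to the planting tolerance; criteria may",
            " break in a non-negligible fraction of frames")
  }

  conformer <- if (two_conformer) rep_len(c(1L, 2L), n_frames) else
    rep(1L, n_frames)
  coords <- array(0, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    x <- if (conformer[f] == 1L) base_xyz else conf2
    x <- x + matrix(stats::rnorm(n_atoms * 3, sd = sigma), n_atoms, 3)
    for (p in seq_len(n_probes)) {
      ow <- probe_idx(p); hw <- ow + 1L; oa <- ow + 2L
      if (p <= planted_counts[f]) {
        # exact planting: acceptor on the donor->acceptor axis at the
        # target distance, hydrogen on the same axis (D-H-A = 180 deg)
        u <- .unit(x[oa, ] - x[ow, ])
        x[oa, ] <- x[ow, ] + hb_distance * u
        x[hw, ] <- x[ow, ] + 0.1 * u
      } else {
        u <- .unit(x[oa, ] - x[ow, ])
        x[oa, ] <- x[ow, ] + 0.6 * u
      }
    }
    coords[f, , ] <- x
  }
  list(traj = trajectory(coords, atoms, box = box, dt = 20),
       bonds = bonds,
       donor_sel = which(atoms$chain == "W"),
       acceptor_sel = which(atoms$chain == "V"),
       truth = list(planted_per_frame = planted_counts,
                    conformer = conformer,
                    params = list(n_frames = n_frames, n_res = n_res,
                                  sigma = sigma, n_probes = n_probes,
                                  planted = planted,
                                  hb_distance = hb_distance, seed = seed)))
}
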