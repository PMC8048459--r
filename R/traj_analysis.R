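# Trajectory analyses: hydrogen bonds, Shrake-Rupley SASA, Kabsch RMSD,
# all-pairs net-RMSD, backbone PCA, centroid extraction, distribution
# tests.

#' Construct a trajectory
#'
#' @param coords numeric array frames x atoms x 3 (nm).
#' @param atoms atom table; may carry extra columns \code{chain},
#'   \code{resid}, \code{resname}.
#' @param box per-frame 3x3 cell-vector matrices (rows = a, b, c) as a list,
#'   a single 3x3 matrix recycled over frames, or NULL for no periodicity.
#' @param dt time between frames (ps), metadata only.
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(coords, atoms, box = NULL, dt = NA_real_) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L,
            dim(coords)[2] == nrow(atoms), dim(coords)[1] >= 1L)
  if (!is.null(box)) {
    if (is.matrix(box)) box <- rep(list(box), dim(coords)[1])
    stopifnot(length(box) == dim(coords)[1])
    vol <- vapply(box, function(b) det(b), 0)
    if (any(vol <= 0)) stop("box vectors must form a positive-volume cell")
  }
  structure(list(coords = coords, atoms = atoms, box = box, dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$coords)[1], "frames x", dim(x$coords)[2], "atoms",
      if (is.null(x$box)) "(non-periodic)" else "(periodic)", "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Select atoms with a mini-grammar
#'
#' Clauses joined by \code{and}: \code{chain A B}, \code{name N CA C O},
#' \code{element O N}, \code{resid 1 2 3}, \code{all}. Example:
#' \code{"chain A and name N CA C O"}.
#'
#' @param atoms an atom table (with optional chain/resid columns).
#' @param expr selection string.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(atoms, expr) {
  keep <- rep(TRUE, nrow(atoms))
  for (clause in strsplit(expr, "\\s+and\\s+")[[1]]) {
    tok <- strsplit(trimws(clause), "\\s+")[[1]]
    if (!length(tok)) next
    key <- tok[1]; vals <- tok[-1]
    keep <- keep & switch(
      key,
      all = rep(TRUE, nrow(atoms)),
      name = atoms$name %in% vals,
      element = atoms$element %in% vals,
      chain = {
        if (is.null(atoms$chain)) stop("atom table has no chain labels")
        atoms$chain %in% vals
      },
      resid = {
        if (is.null(atoms$resid)) stop("atom table has no residue ids")
        atoms$resid %in% as.integer(vals)
      },
      stop("unknown selection keyword: ", key))
  }
  which(keep)
}

#' Backbone heavy-atom selection (names N, CA, C, O)
#' @param atoms an atom table.
#' @return integer vector of atom indices.
#' @export
backbone_selection <- function(atoms) select_atoms(atoms, "name N CA C O")

#' Drop the equilibration segment of a trajectory
#'
#' @param traj a \code{trajectory}.
#' @param fraction leading fraction of frames to discard (default 0.25,
#'   mirroring a 50 ns burn-in of a 200 ns run).
#' @return a \code{trajectory} with the leading frames removed.
#' @export
discard_equilibration <- function(traj, fraction = 0.25) {
  stopifnot(fraction >= 0, fraction < 1)
  nf <- n_frames(traj)
  drop <- floor(nf * fraction)
  keep <- (drop + 1L):nf
  trajectory(traj$coords[keep, , , drop = FALSE], traj$atoms,
             box = if (is.null(traj$box)) NULL else traj$box[keep],
             dt = traj$dt)
}

# Minimum-image displacement(s) under a triclinic cell. disp: m x 3.
min_image <- function(disp, box = NULL) {
  if (is.null(box)) return(disp)
  frac <- disp %*% solve(box)
  (frac - round(frac)) %*% box
}

# ---------------------------------------------------------------------------
# Hydrogen bonds
# ---------------------------------------------------------------------------

#' Hydrogen-bond criteria
#'
#' Geometric criteria: donor-acceptor heavy-atom distance cutoff and
#' donor-hydrogen-acceptor angle cutoff. \code{distance_mode =
#' "hydrogen_acceptor"} switches the distance criterion to the H..A
#' distance (the alternative reading of a 3 Angstrom cutoff).
#'
#' @param d_max distance cutoff in nm (default 0.3).
#' @param angle_min minimum D-H-A angle in degrees (default 120).
#' @param donors hydrogen atom-name set defining donors (NULL = every
#'   hydrogen bonded to N or O).
#' @param acceptors acceptor atom-name set (NULL = every N or O).
#' @param distance_mode \code{"donor_acceptor"} (default) or
#'   \code{"hydrogen_acceptor"}.
#' @return object of class \code{hbond_criteria}.
#' @export
hbond_criteria <- function(d_max = 0.3, angle_min = 120,
                           donors = NULL, acceptors = NULL,
                           distance_mode = c("donor_acceptor", "hydrogen_acceptor")) {
  stopifnot(d_max > 0, angle_min >= 0, angle_min <= 180)
  structure(list(d_max = d_max, angle_min = angle_min, donors = donors,
                 acceptors = acceptors,
                 distance_mode = match.arg(distance_mode)),
            class = "hbond_criteria")
}

# Resolve (donor_heavy, hydrogen) pairs and acceptor indices from the atom
# table and bond graph.
.hbond_roles <- function(atoms, bonds, criteria) {
  is_h <- atoms$element == "H"
  heavy_ok <- atoms$element %in% c("N", "O")
  # hydrogen -> bonded heavy atom
  hd <- rbind(data.frame(h = bonds$i, x = bonds$j),
              data.frame(h = bonds$j, x = bonds$i))
  hd <- hd[is_h[hd$h] & !is_h[hd$x], , drop = FALSE]
  if (is.null(criteria$donors)) {
    hd <- hd[heavy_ok[hd$x], , drop = FALSE]
  } else {
    sel_h <- which(is_h & atoms$name %in% criteria$donors)
    no_h <- setdiff(which(atoms$name %in% criteria$donors), c(sel_h))
    hd <- hd[hd$h %in% sel_h, , drop = FALSE]
    lost <- setdiff(sel_h, hd$h)
    if (length(lost)) {
      warning("donor hydrogen(s) with no bonded heavy atom skipped: ",
              paste(atoms$name[lost], collapse = ", "))
    }
  }
  acceptors <- if (is.null(criteria$acceptors)) which(heavy_ok & !is_h)
  else which(atoms$name %in% criteria$acceptors)
  list(donors = hd, acceptors = acceptors)
}

#' Detect hydrogen bonds in one frame
#'
#' Returns every (donor, hydrogen, acceptor) triple meeting the distance
#' and angle criteria, with the minimum-image convention applied when a
#' periodic box is given. The donor heavy atom is never its own acceptor.
#'
#' @param coords atoms x 3 coordinate matrix (nm).
#' @param atoms atom table (names, elements).
#' @param bonds bond data.frame (i, j) resolving hydrogens to donors.
#' @param criteria an \code{\link{hbond_criteria}}.
#' @param box optional 3x3 cell matrix.
#' @return data.frame donor, hydrogen, acceptor (atom indices), distance
#'   (nm), angle (degrees).
#' @export
hbonds_frame <- function(coords, atoms, bonds, criteria = hbond_criteria(),
                         box = NULL) {
  roles <- .hbond_roles(atoms, bonds, criteria)
  out <- list()
  acc <- roles$acceptors
  if (!nrow(roles$donors) || !length(acc)) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  }
  for (r in seq_len(nrow(roles$donors))) {
    h <- roles$donors$h[r]; d <- roles$donors$x[r]
    a_ok <- acc[acc != d]
    if (!length(a_ok)) next
    ref_idx <- if (criteria$distance_mode == "donor_acceptor") d else h
    disp <- min_image(coords[a_ok, , drop = FALSE] -
                        matrix(coords[ref_idx, ], length(a_ok), 3, byrow = TRUE),
                      box)
    dist <- sqrt(rowSums(disp^2))
    near <- which(dist <= criteria$d_max)
    for (m in near) {
      a <- a_ok[m]
      v1 <- min_image(matrix(coords[d, ] - coords[h, ], 1), box)[1, ]
      v2 <- min_image(matrix(coords[a, ] - coords[h, ], 1), box)[1, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang >= criteria$angle_min) {
        out[[length(out) + 1L]] <- data.frame(
          donor = d, hydrogen = h, acceptor = a,
          distance = dist[m], angle = ang)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$donor, res$hydrogen, res$acceptor), , drop = FALSE]
}

#' Hydrogen-bond distribution over a trajectory
#'
#' Per-frame bond counts between two atom groups (donor in one group,
#' acceptor in the other, in either direction), per-donor and per-acceptor
#' participation tallies, and summary statistics. Groups default to all
#' atoms.
#'
#' @param traj a \code{trajectory}.
#' @param bonds bond data.frame (i, j).
#' @param criteria an \code{\link{hbond_criteria}}.
#' @param selection_a,selection_b integer atom-index groups; NULL = all.
#' @return object of class \code{hbond_result}: \code{per_frame} counts,
#'   \code{per_donor}/\code{per_acceptor} named tallies, \code{summary}
#'   (median, min, max, mean, sd).
#' @export
hbond_distribution <- function(traj, bonds, criteria = hbond_criteria(),
                               selection_a = NULL, selection_b = NULL) {
  na <- dim(traj$coords)[2]
  if (is.null(selection_a)) selection_a <- seq_len(na)
  if (is.null(selection_b)) selection_b <- seq_len(na)
  if (!length(selection_a) || !length(selection_b)) stop("empty selection")
  counts <- integer(n_frames(traj))
  per_donor <- integer(0); per_acceptor <- integer(0)
  for (f in seq_len(n_frames(traj))) {
    hb <- hbonds_frame(traj$coords[f, , ], traj$atoms, bonds, criteria,
                       box = if (is.null(traj$box)) NULL else traj$box[[f]])
    keep <- (hb$donor %in% selection_a & hb$acceptor %in% selection_b) |
      (hb$donor %in% selection_b & hb$acceptor %in% selection_a)
    hb <- hb[keep, , drop = FALSE]
    counts[f] <- nrow(hb)
    if (nrow(hb)) {
      dn <- table(traj$atoms$name[hb$donor])
      an <- table(traj$atoms$name[hb$acceptor])
      for (nmx in names(dn)) per_donor[nmx] <- sum(per_donor[nmx], dn[[nmx]], na.rm = TRUE)
      for (nmx in names(an)) per_acceptor[nmx] <- sum(per_acceptor[nmx], an[[nmx]], na.rm = TRUE)
    }
  }
  structure(list(per_frame = counts,
                 per_donor = per_donor, per_acceptor = per_acceptor,
                 summary = c(median = stats::median(counts), min = min(counts),
                             max = max(counts), mean = mean(counts),
                             sd = stats::sd(counts))),
            class = "hbond_result")
}

# ---------------------------------------------------------------------------
# SASA (Shrake-Rupley)
# ---------------------------------------------------------------------------

#' Deterministic unit-sphere point lattice (golden spiral)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Each atom's sphere is inflated to (atomic radius + probe radius) and
#' sampled with a deterministic golden-spiral lattice; the per-atom area is
#' the exposed-point fraction times the inflated-sphere area.
#'
#' @param coords atoms x 3 matrix (nm) or a \code{trajectory}.
#' @param elements element symbols (ignored when \code{coords} is a
#'   trajectory); used to look up Bondi radii unless \code{radii} is given.
#' @param probe probe radius in nm (default 0.14, a water probe).
#' @param n_points sphere points per atom (default 960).
#' @param radii optional explicit per-atom radii (nm); overrides the
#'   element lookup. A single value is recycled (the uniform-radius
#'   reading of the method).
#' @return per-atom areas (nm^2) for a matrix input; a frames x atoms
#'   matrix for a trajectory.
#' @export
sasa <- function(coords, elements = NULL, probe = 0.14, n_points = 960,
                 radii = NULL) {
  stopifnot(n_points >= 12, probe >= 0)
  if (inherits(coords, "trajectory")) {
    traj <- coords
    r <- if (is.null(radii)) vdw_radius(traj$atoms$element)
    else rep_len(radii, dim(traj$coords)[2])
    out <- t(vapply(seq_len(n_frames(traj)), function(f)
      .sasa_frame(traj$coords[f, , ], r, probe, n_points),
      numeric(dim(traj$coords)[2])))
    return(out)
  }
  r <- if (is.null(radii)) vdw_radius(elements) else rep_len(radii, nrow(coords))
  .sasa_frame(as.matrix(coords), r, probe, n_points)
}

.sasa_frame <- function(coords, r, probe, n_points) {
  n <- nrow(coords)
  pts <- sphere_points(n_points)
  R <- r + probe
  d2 <- as.matrix(stats::dist(coords))^2
  areas <- numeric(n)
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    p <- pts * R[i] + matrix(coords[i, ], n_points, 3, byrow = TRUE)
    exposed <- rep(TRUE, n_points)
    for (j in neigh) {
      dj <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      exposed <- exposed & dj > R[j]^2
      if (!any(exposed)) break
    }
    areas[i] <- sum(exposed) / n_points * 4 * pi * R[i]^2
  }
  areas
}

# ---------------------------------------------------------------------------
# RMSD / superposition
# ---------------------------------------------------------------------------

#' Kabsch superposition and RMSD
#'
#' Least-squares RMSD after removing centroids and solving for the optimal
#' proper rotation (SVD with determinant correction).
#'
#' @param frame_a,frame_b m x 3 coordinate matrices over the same atoms.
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(frame_a, frame_b) {
  fit <- kabsch_fit(frame_a, frame_b)
  sqrt(mean(rowSums((fit$transformed - frame_b)^2)))
}

#' Kabsch fit returning the rotation
#'
#' Rotates/translates \code{frame_a} onto \code{frame_b}.
#'
#' @param frame_a,frame_b m x 3 coordinate matrices.
#' @return list with \code{rotation} (3x3, det +1), \code{transformed}
#'   (frame_a superposed onto frame_b).
#' @export
kabsch_fit <- function(frame_a, frame_b) {
  frame_a <- as.matrix(frame_a); frame_b <- as.matrix(frame_b)
  if (nrow(frame_a) != nrow(frame_b)) {
    stop("atom-count mismatch: ", nrow(frame_a), " vs ", nrow(frame_b))
  }
  ca <- colMeans(frame_a); cb <- colMeans(frame_b)
  A <- sweep(frame_a, 2, ca); B <- sweep(frame_b, 2, cb)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(rotation = R,
       transformed = sweep(A %*% t(R), 2, cb, "+"))
}

#' All-pairs net-RMSD matrix
#'
#' The full pairwise backbone RMSD matrix across (strided) frames: the
#' "against every previous frame" lower triangle, mirrored.
#'
#' @param traj a \code{trajectory}.
#' @param selection atom indices (default: backbone heavy atoms).
#' @param stride frame stride (default 1).
#' @return object of class \code{rmsd_matrix}: \code{matrix}, \code{frames}
#'   (original frame indices), \code{selection}.
#' @export
net_rmsd_matrix <- function(traj, selection = NULL, stride = 1L) {
  if (is.null(selection)) selection <- backbone_selection(traj$atoms)
  frames <- seq(1L, n_frames(traj), by = stride)
  if (length(frames) < 2L) stop("need at least 2 frames after striding")
  nf <- length(frames)
  M <- matrix(0, nf, nf)
  for (p in seq_len(nf - 1L)) for (q in (p + 1L):nf) {
    M[p, q] <- M[q, p] <- kabsch_rmsd(traj$coords[frames[p], selection, ],
                                      traj$coords[frames[q], selection, ])
  }
  structure(list(matrix = M, frames = frames, selection = selection),
            class = "rmsd_matrix")
}

# ---------------------------------------------------------------------------
# PCA
# ---------------------------------------------------------------------------

#' Principal component analysis of backbone motion
#'
#' Two-pass superposition (fit every frame to frame 1, compute the mean
#' structure, re-fit every frame to the mean), then eigen-decomposition of
#' the 3M x 3M positional covariance.
#'
#' @param traj a \code{trajectory}.
#' @param selection atom indices (default: backbone heavy atoms).
#' @return object of class \code{pca_result}: \code{values} (variances,
#'   non-increasing), \code{vectors} (orthonormal columns),
#'   \code{projections} (frames x components), \code{mean} (3M vector),
#'   \code{total_variance}.
#' @export
pca_backbone <- function(traj, selection = NULL) {
  if (is.null(selection)) selection <- backbone_selection(traj$atoms)
  nf <- n_frames(traj)
  if (nf < 2L) stop("need at least 2 frames for PCA")
  m <- length(selection)
  get <- function(f) traj$coords[f, selection, , drop = TRUE]
  ref <- get(1)
  fitted <- lapply(seq_len(nf), function(f) kabsch_fit(get(f), ref)$transformed)
  mean_str <- Reduce("+", fitted) / nf
  fitted <- lapply(seq_len(nf), function(f) kabsch_fit(get(f), mean_str)$transformed)
  X <- do.call(rbind, lapply(fitted, function(m3) as.vector(t(m3))))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (nf - 1L)
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  structure(list(values = pmax(e$values, 0), vectors = e$vectors,
                 projections = Xc %*% e$vectors,
                 mean = colMeans(X),
                 reference = as.vector(t(mean_str)),
                 total_variance = sum(diag(C))),
            class = "pca_result")
}

# ---------------------------------------------------------------------------
# Centroid structure
# ---------------------------------------------------------------------------

#' Centroid structure by pairwise similarity
#'
#' Transforms the pairwise RMSD matrix into similarity scores
#' \code{s_ij = exp(-beta d_ij / mean(d))} (i != j) and returns the frame
#' maximizing the summed similarity; ties break to the lowest frame index.
#' If every pairwise distance is zero the frames are identical and frame 1
#' is returned.
#'
#' @param traj a \code{trajectory} (or an \code{rmsd_matrix}).
#' @param selection atom indices (ignored for an \code{rmsd_matrix}).
#' @param beta similarity sharpness (default 1).
#' @return list with \code{frame} (index into the strided frame list),
#'   \code{scores} (summed similarity per frame).
#' @export
centroid_structure <- function(traj, selection = NULL, beta = 1) {
  rm <- if (inherits(traj, "rmsd_matrix")) traj
  else net_rmsd_matrix(traj, selection)
  D <- rm$matrix
  off <- D[upper.tri(D)]
  if (all(off < 1e-12)) {
    return(list(frame = rm$frames[1], scores = rep(1, nrow(D)) * (nrow(D) - 1)))
  }
  S <- exp(-beta * D / mean(off))
  diag(S) <- 0
  scores <- rowSums(S)
  best <- which(scores == max(scores))[1]
  list(frame = rm$frames[best], scores = scores)
}

# ---------------------------------------------------------------------------
# Distribution tests
# ---------------------------------------------------------------------------

#' Shapiro-Wilk normality test
#'
#' @param sample numeric vector, n >= 3.
#' @return list of class \code{stat_test_result}: test, statistic, p_value, n.
#' @export
shapiro_wilk <- function(sample) {
  if (length(sample) < 3L) stop("Shapiro-Wilk needs n >= 3, got ", length(sample))
  r <- stats::shapiro.test(sample)
  structure(list(test = "shapiro_wilk", statistic = unname(r$statistic),
                 p_value = r$p.value, n = length(sample)),
            class = "stat_test_result")
}

#' Fligner-Killeen test of variance homogeneity
#'
#' Robust to non-normality; used when Shapiro-Wilk rejects normality, which
#' is the decision rule the comparison reports follow.
#'
#' @param ... two or more numeric vectors (or a single list of them).
#' @return list of class \code{stat_test_result}: test, statistic, p_value, n.
#' @export
fligner_killeen <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2L) stop("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 3L)) stop("each group needs n >= 3")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), ns))
  r <- stats::fligner.test(x, g)
  structure(list(test = "fligner_killeen", statistic = unname(r$statistic),
                 p_value = r$p.value, n = ns),
            class = "stat_test_result")
}

#' Compare two distributions with the normality-gated rule
#'
#' Tests each sample for normality (Shapiro-Wilk); when either rejects at
#' \code{alpha}, the groups are compared with Fligner-Killeen, otherwise
#' with an F test of variances.
#'
#' @param a,b numeric samples.
#' @param alpha normality-rejection level (default 0.001).
#' @return list with \code{normality} (per-group results), \code{comparison}
#'   (a \code{stat_test_result}).
#' @export
compare_distributions <- function(a, b, alpha = 0.001) {
  na <- shapiro_wilk(a); nb <- shapiro_wilk(b)
  non_normal <- na$p_value < alpha || nb$p_value < alpha
  comp <- if (non_normal) fligner_killeen(a, b) else {
    r <- stats::var.test(a, b)
    structure(list(test = "f_test", statistic = unname(r$statistic),
                   p_value = r$p.value, n = c(length(a), length(b))),
              class = "stat_test_result")
  }
  list(normality = list(a = na, b = nb), comparison = comp)
}
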