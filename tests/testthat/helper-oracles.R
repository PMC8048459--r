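# Independent oracles and fixture helpers shared across the suite. These
# deliberately avoid the package's own code paths wherever they act as a
# reference (brute-force loops, finite differences, numeric optimizers).

# Apply a rigid rotation (and optional translation) to a geometry together
# with the Hessian congruence transform H' = (I (x) R) H (I (x) R)^T.
rigid_transform <- function(geom, h, R, shift = c(0, 0, 0)) {
  coords2 <- geom$coords %*% t(R) + matrix(shift, nrow(geom$coords), 3,
                                           byrow = TRUE)
  n <- nrow(geom$coords)
  big <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) {
    idx <- (3 * (a - 1) + 1):(3 * a)
    big[idx, idx] <- R
  }
  H2 <- big %*% h$matrix %*% t(big)
  list(geometry = molecule_geometry(geom$atoms, coords2),
       hessian = cartesian_hessian((H2 + t(H2)) / 2, units = h$units,
                                   n_atoms = n))
}

# A random rotation matrix from a QR decomposition (deterministic per seed).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Brute-force hydrogen-bond detection: naive triple loop over every
# hydrogen, its bonded heavy atom, and every candidate acceptor, with its
# own minimum-image arithmetic.
hbonds_brute <- function(coords, atoms, bonds, d_max = 0.3, angle_min = 120,
                         box = NULL) {
  mi <- function(v) {
    if (is.null(box)) return(v)
    f <- as.vector(v %*% solve(box))
    as.vector((f - round(f)) %*% box)
  }
  hits <- list()
  for (h in which(atoms$element == "H")) {
    partners <- c(bonds$j[bonds$i == h], bonds$i[bonds$j == h])
    partners <- partners[atoms$element[partners] %in% c("N", "O")]
    for (d in partners) {
      for (a in which(atoms$element %in% c("N", "O"))) {
        if (a == d) next
        dv <- mi(coords[a, ] - coords[d, ])
        if (sqrt(sum(dv^2)) > d_max) next
        v1 <- mi(coords[d, ] - coords[h, ])
        v2 <- mi(coords[a, ] - coords[h, ])
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(max(-1, min(1, cosang))) * 180 / pi
        if (ang >= angle_min) {
          hits[[length(hits) + 1L]] <- c(d, h, a)
        }
      }
    }
  }
  if (!length(hits)) return(matrix(integer(), 0, 3))
  m <- do.call(rbind, hits)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Random 200-atom frame with H atoms bonded to their nearest heavy atom.
random_hbond_frame <- function(seed, n = 200, box_len = 1.8) {
  set.seed(seed)
  element <- sample(c("C", "N", "O", "H"), n, replace = TRUE,
                    prob = c(0.35, 0.2, 0.2, 0.25))
  coords <- matrix(runif(n * 3, 0, box_len), n, 3)
  atoms <- data.frame(index = seq_len(n), name = paste0(element, seq_len(n)),
                      element = element, mass = element_mass(element),
                      charge = 0, stringsAsFactors = FALSE)
  heavy <- which(element != "H")
  bonds <- do.call(rbind, lapply(which(element == "H"), function(h) {
    d2 <- rowSums((coords[heavy, , drop = FALSE] -
                     matrix(coords[h, ], length(heavy), 3, byrow = TRUE))^2)
    data.frame(i = h, j = heavy[which.min(d2)])
  }))
  list(coords = coords, atoms = atoms, bonds = bonds,
       box = diag(rep(box_len, 3)))
}

# Brute-force RMSD minimization over rotations parameterized by Euler
# angles (numeric optimizer oracle, independent of the SVD route).
rmsd_optim_oracle <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  rotmat <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) mean(rowSums((A %*% t(rotmat(p)) - B)^2))
  best <- Inf
  for (start in list(c(0, 0, 0), c(1, 1, 1), c(-1, 2, 0.5), c(2, -1, -2))) {
    r <- stats::optim(start, obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 2000))
    best <- min(best, r$value)
  }
  sqrt(best)
}
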