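# Hydrogen bonds -------------------------------------------------------------

planted_frame <- function(d_da = 0.28, angle = 180) {
  # O donor at origin, H on +x, acceptor placed at the requested D-A
  # distance and D-H-A angle (angle applies at the hydrogen)
  atoms <- data.frame(index = 1:3, name = c("OD", "HD", "OA"),
                      element = c("O", "H", "O"),
                      mass = element_mass(c("O", "H", "O")), charge = 0,
                      stringsAsFactors = FALSE)
  h <- c(0.1, 0, 0)
  # position acceptor: for 180 deg it lies on the +x axis beyond H
  th <- (180 - angle) * pi / 180
  dir <- c(cos(th), sin(th), 0)
  # distance from H chosen so the D-A distance is d_da (solve on the axis)
  # for simplicity place A along dir from H and scale to match d_da
  f <- function(s) sqrt(sum((h + s * dir)^2)) - d_da
  s <- stats::uniroot(f, c(1e-4, 1))$root
  coords <- rbind(c(0, 0, 0), h, h + s * dir)
  list(atoms = atoms, coords = coords, bonds = data.frame(i = 1L, j = 2L))
}

test_that("planted geometries pass or fail the criteria as constructed", {
  ok <- planted_frame(0.28, 180)
  hb <- hbonds_frame(ok$coords, ok$atoms, ok$bonds)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$donor, 1L)
  expect_equal(hb$acceptor, 3L)

  far <- planted_frame(0.32, 180)
  expect_equal(nrow(hbonds_frame(far$coords, far$atoms, far$bonds)), 0L)

  bent <- planted_frame(0.28, 100)  # angle below the 120 degree cutoff
  expect_equal(nrow(hbonds_frame(bent$coords, bent$atoms, bent$bonds)), 0L)
})

test_that("minimum-image convention finds bonds across the periodic boundary", {
  atoms <- data.frame(index = 1:3, name = c("OD", "HD", "OA"),
                      element = c("O", "H", "O"),
                      mass = element_mass(c("O", "H", "O")), charge = 0)
  box <- diag(c(1.2, 1.2, 1.2))
  coords <- rbind(c(0.05, 0.5, 0.5),   # donor near the face
                  c(1.15, 0.5, 0.5),   # its hydrogen, wrapped across
                  c(0.97, 0.5, 0.5))   # acceptor: image distance 0.28
  bonds <- data.frame(i = 1L, j = 2L)
  hb <- hbonds_frame(coords, atoms, bonds, box = box)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 0.28, tolerance = 1e-10)
  # without the box the direct distance fails the cutoff
  expect_equal(nrow(hbonds_frame(coords, atoms, bonds)), 0L)
})

test_that("detection equals the brute-force triple loop on random frames", {
  n_nonempty <- 0L
  for (seed in 1:25) {
    fr <- random_hbond_frame(seed)
    got <- hbonds_frame(fr$coords, fr$atoms, fr$bonds, box = fr$box)
    ref <- hbonds_brute(fr$coords, fr$atoms, fr$bonds, box = fr$box)
    got_m <- matrix(as.integer(c(got$donor, got$hydrogen, got$acceptor)),
                    ncol = 3)
    ref_m <- matrix(as.integer(ref), ncol = 3)
    expect_equal(got_m, ref_m, info = paste("seed", seed))
    if (nrow(ref_m)) n_nonempty <- n_nonempty + 1L
  }
  expect_gt(n_nonempty, 10L)  # the fixtures actually exercise detection
})

test_that("hbond distributions conserve counts and recover planted truth", {
  st <- make_synthetic_trajectory(n_frames = 30, planted = 1, sigma = 0.002,
                                  seed = 5)
  hb <- hbond_distribution(st$traj, st$bonds, hbond_criteria(),
                           st$donor_sel, st$acceptor_sel)
  expect_equal(unname(hb$summary[c("median", "min", "max", "mean")]),
               c(1, 1, 1, 1))
  expect_equal(unname(hb$summary["sd"]), 0)
  # conservation: per-frame total = per-donor total = per-acceptor total
  expect_equal(sum(hb$per_frame), sum(hb$per_donor))
  expect_equal(sum(hb$per_frame), sum(hb$per_acceptor))

  alt <- make_synthetic_trajectory(n_frames = 40, planted = c(2L, 4L),
                                   sigma = 0.001, seed = 9)
  hb2 <- hbond_distribution(alt$traj, alt$bonds, hbond_criteria(),
                            alt$donor_sel, alt$acceptor_sel)
  expect_equal(unname(hb2$summary["median"]), 3)
  expect_equal(unname(hb2$summary["mean"]), 3)
  expect_error(hbond_distribution(st$traj, st$bonds, hbond_criteria(),
                                  integer(), st$acceptor_sel),
               "empty selection")
})

test_that("binomially planted bond counts are recovered within 3 SE", {
  st <- make_synthetic_trajectory(n_frames = 2000, n_res = 3,
                                  planted = list(n = 12, p = 0.6),
                                  sigma = 0.001, seed = 17)
  hb <- hbond_distribution(st$traj, st$bonds, hbond_criteria(),
                           st$donor_sel, st$acceptor_sel)
  expect_equal(hb$per_frame, st$truth$planted_per_frame)
  se <- sqrt(12 * 0.6 * 0.4 / 2000)
  expect_lt(abs(mean(hb$per_frame) - 7.2), 3 * se)
})

# SASA ------------------------------------------------------------------------

test_that("an isolated sphere reproduces the closed form within 0.5%", {
  a <- sasa(matrix(0, 1, 3), radii = 0.15, probe = 0.14, n_points = 960)
  expect_lt(abs(a / (4 * pi * 0.29^2) - 1), 0.005)
})

test_that("burial, separation and monotonicity behave geometrically", {
  # small atom fully inside a much larger sphere
  two <- rbind(c(0, 0, 0), c(0.01, 0, 0))
  a <- sasa(two, radii = c(0.05, 0.5), probe = 0.0, n_points = 960)
  expect_equal(a[1], 0)
  # far separated atoms: no occlusion
  far <- rbind(c(0, 0, 0), c(5, 0, 0))
  a2 <- sasa(far, elements = c("O", "N"), probe = 0.14, n_points = 960)
  iso <- vapply(c("O", "N"), function(e)
    sasa(matrix(0, 1, 3), elements = e, probe = 0.14, n_points = 960), 0)
  expect_equal(unname(a2), unname(iso), tolerance = 1e-12)
  # monotone non-increasing as a neighbor approaches
  areas <- vapply(seq(0.8, 0.15, by = -0.05), function(d)
    sasa(rbind(c(0, 0, 0), c(d, 0, 0)), elements = c("C", "C"),
         probe = 0.14, n_points = 960)[1], 0)
  expect_true(all(diff(areas) <= 1e-12))
  expect_error(sasa(matrix(0, 1, 3), elements = "Xx"), "Xx")
})

# RMSD ------------------------------------------------------------------------

test_that("kabsch RMSD is zero on rigid transforms and matches the optimizer", {
  set.seed(101)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(A, A), 0)
  R <- random_rotation(3)
  B <- A %*% t(R) + matrix(c(0.5, -1, 2), 10, 3, byrow = TRUE)
  expect_lt(kabsch_rmsd(A, B), 1e-10)
  det_check <- kabsch_fit(A, B)$rotation
  expect_equal(det(det_check), 1, tolerance = 1e-10)

  # single displaced atom among N = 10: compare with numeric optimization
  C <- A
  C[4, ] <- C[4, ] + c(0.1, 0, 0)
  expect_equal(kabsch_rmsd(A, C), rmsd_optim_oracle(A, C), tolerance = 1e-6)
  expect_error(kabsch_rmsd(A, A[1:5, ]), "mismatch")
})

test_that("RMSD behaves as a pseudo-metric on trajectory frames", {
  st <- make_synthetic_trajectory(n_frames = 6, sigma = 0.01, seed = 23)
  sel <- backbone_selection(st$traj$atoms)
  fr <- lapply(1:6, function(f) st$traj$coords[f, sel, ])
  for (p in 1:5) for (q in (p + 1):6) {
    dpq <- kabsch_rmsd(fr[[p]], fr[[q]])
    expect_equal(dpq, kabsch_rmsd(fr[[q]], fr[[p]]), tolerance = 1e-12)
    for (r in seq_len(6)[-c(p, q)]) {
      expect_lte(dpq, kabsch_rmsd(fr[[p]], fr[[r]]) +
                   kabsch_rmsd(fr[[r]], fr[[q]]) + 1e-12)
    }
  }
})

test_that("net-RMSD matrices are symmetric, consistent, and reveal conformers", {
  ident <- make_synthetic_trajectory(n_frames = 4, sigma = 0, seed = 2)
  M0 <- net_rmsd_matrix(ident$traj)$matrix
  expect_lt(max(M0), 1e-10)

  st <- make_synthetic_trajectory(n_frames = 8, two_conformer = TRUE,
                                  sigma = 0, seed = 4)
  rm <- net_rmsd_matrix(st$traj)
  M <- rm$matrix
  expect_identical(M, t(M))
  expect_equal(diag(M), rep(0, 8))
  # exactly two distinct off-diagonal values: within- and between-conformer
  expect_equal(length(unique(round(M[upper.tri(M)], 8))), 2L)
  # self-consistency against direct kabsch calls
  sel <- rm$selection
  expect_equal(M[2, 5],
               kabsch_rmsd(st$traj$coords[2, sel, ], st$traj$coords[5, sel, ]),
               tolerance = 1e-12)
  one <- trajectory(st$traj$coords[1, , , drop = FALSE], st$traj$atoms)
  expect_error(net_rmsd_matrix(one), "at least 2 frames")
})

# PCA -------------------------------------------------------------------------

test_that("a single planted motion direction captures all PCA variance", {
  st <- make_synthetic_trajectory(n_frames = 2, sigma = 0, seed = 8)
  sel <- backbone_selection(st$traj$atoms)
  base <- st$traj$coords[1, , ]
  m <- length(sel)
  set.seed(31)
  # internal motion direction: project rigid-body translations/rotations
  # out of a random direction so superposition cannot remove any of it
  ctr <- sweep(base[sel, ], 2, colMeans(base[sel, ]))
  rigid <- matrix(0, 3 * m, 6)
  for (a in seq_len(m)) {
    idx <- (3 * (a - 1) + 1):(3 * a)
    rigid[idx, 1:3] <- diag(3)
    r <- ctr[a, ]
    rigid[idx, 4] <- c(0, -r[3], r[2])
    rigid[idx, 5] <- c(r[3], 0, -r[1])
    rigid[idx, 6] <- c(-r[2], r[1], 0)
  }
  Q <- qr.Q(qr(rigid))
  v <- rnorm(3 * m)
  v <- v - Q %*% (t(Q) %*% v)
  v <- v / sqrt(sum(v^2))
  dirv <- matrix(v, m, 3, byrow = TRUE)
  amp <- rnorm(60, sd = 0.01)
  coords <- array(0, c(60, nrow(st$traj$atoms), 3))
  for (f in 1:60) {
    x <- base
    x[sel, ] <- x[sel, ] + amp[f] * dirv
    coords[f, , ] <- x
  }
  tr <- trajectory(coords, st$traj$atoms)
  p <- pca_backbone(tr, sel)
  expect_equal(p$values[1] / sum(p$values), 1, tolerance = 1e-6)
  expect_equal(p$values[1], stats::var(amp), tolerance = 1e-4)
  expect_equal(sum(p$values), p$total_variance, tolerance = 1e-8)
})

test_that("PCA conserves variance and reconstructs centered coordinates", {
  st <- make_synthetic_trajectory(n_frames = 25, sigma = 0.01, seed = 13)
  p <- pca_backbone(st$traj)
  expect_lt(abs(sum(p$values) - p$total_variance) / p$total_variance, 1e-8)
  expect_true(all(diff(p$values) <= 1e-12))
  G <- t(p$vectors) %*% p$vectors
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # projections onto the full eigenbasis reproduce the centered data
  recon <- p$projections %*% t(p$vectors)
  sel <- backbone_selection(st$traj$atoms)
  fitted <- lapply(seq_len(25), function(f) {
    kabsch_fit(st$traj$coords[f, sel, ],
               matrix(p$reference, ncol = 3, byrow = TRUE))$transformed
  })
  X <- do.call(rbind, lapply(fitted, function(m3) as.vector(t(m3))))
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(recon - Xc)), 1e-8)
})

test_that("isotropic noise spreads variance across components", {
  # iid Gaussian displacements: the leading sample eigenvalue exceeds the
  # uniform share 1/(3M) only by the Marchenko-Pastur edge factor
  # (1 + sqrt(d/n))^2 (< 2 for the chosen d = 3M and n), so the ratio must
  # lie in [1/(3M), 2/(3M)] up to superposition losses
  n_fr <- 1200
  st <- make_synthetic_trajectory(n_frames = 2, sigma = 0, seed = 19)
  sel <- backbone_selection(st$traj$atoms)[1:20]
  base <- st$traj$coords[1, , ]
  set.seed(77)
  coords <- array(0, c(n_fr, nrow(st$traj$atoms), 3))
  for (f in seq_len(n_fr)) {
    x <- base
    x[sel, ] <- x[sel, ] + matrix(rnorm(60, sd = 0.01), 20, 3)
    coords[f, , ] <- x
  }
  p <- pca_backbone(trajectory(coords, st$traj$atoms), sel)
  ratio <- p$values[1] / sum(p$values)
  expect_gt(ratio, 1 / 60)
  expect_lt(ratio, 2 / 60)
})

# Centroid --------------------------------------------------------------------

test_that("the centroid frame maximizes summed similarity", {
  # three frames along one direction: the middle frame is nearest to both
  st <- make_synthetic_trajectory(n_frames = 2, sigma = 0, seed = 3)
  sel <- backbone_selection(st$traj$atoms)
  base <- st$traj$coords[1, , ]
  # alternating internal displacement (not a rigid translation)
  dirv <- matrix(0, length(sel), 3)
  dirv[, 1] <- rep_len(c(1, -1), length(sel))
  dirv <- dirv / sqrt(sum(dirv^2))
  coords <- array(0, c(3, nrow(st$traj$atoms), 3))
  for (f in 1:3) {
    x <- base
    x[sel, ] <- x[sel, ] + (f - 2) * 0.1 * dirv
    coords[f, , ] <- x
  }
  tr <- trajectory(coords, st$traj$atoms)
  expect_equal(centroid_structure(tr, sel)$frame, 2L)

  # identical frames: tie broken to frame 1
  ident <- make_synthetic_trajectory(n_frames = 5, sigma = 0, seed = 2)
  expect_equal(centroid_structure(ident$traj)$frame, 1L)
})

test_that("the centroid is invariant to frame reordering up to relabeling", {
  st <- make_synthetic_trajectory(n_frames = 7, sigma = 0.01, seed = 29)
  sel <- backbone_selection(st$traj$atoms)
  cs <- centroid_structure(st$traj, sel)
  perm <- c(4L, 1L, 7L, 3L, 2L, 6L, 5L)
  tr2 <- trajectory(st$traj$coords[perm, , , drop = FALSE], st$traj$atoms)
  cs2 <- centroid_structure(tr2, sel)
  expect_equal(perm[cs2$frame], cs$frame)
})

# Distribution tests ----------------------------------------------------------

test_that("identical groups give a null Fligner-Killeen result", {
  x <- rep(c(1.2, 3.4, 5.6, 2.2, 4.4), 4)
  r <- fligner_killeen(x, x)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
})

test_that("Shapiro-Wilk holds its nominal type-I error rate", {
  # 400 replicates at n = 500: the 5% rejection rate must land within
  # 3 binomial standard errors (0.05 +/- 3 * 0.0109)
  set.seed(42)
  rej <- vapply(1:400, function(i)
    shapiro_wilk(rnorm(500))$p_value < 0.05, logical(1))
  expect_gt(mean(rej), 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("Fligner-Killeen detects a 1-vs-9 variance ratio at n = 200", {
  set.seed(7)
  a <- rnorm(200, sd = 1)
  b <- rnorm(200, sd = 3)
  r <- fligner_killeen(a, b)
  expect_lt(r$p_value, 0.01)
  expect_error(fligner_killeen(a), "two groups")
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
})

test_that("the comparison report follows the normality-gated decision rule", {
  set.seed(11)
  skewed_a <- rexp(300); skewed_b <- rexp(300) * 3
  rep1 <- compare_distributions(skewed_a, skewed_b)
  expect_equal(rep1$comparison$test, "fligner_killeen")
  normal_a <- rnorm(300); normal_b <- rnorm(300)
  rep2 <- compare_distributions(normal_a, normal_b)
  expect_equal(rep2$comparison$test, "f_test")
})

# Selections and trajectory plumbing ------------------------------------------

test_that("the selection grammar and equilibration discard work together", {
  st <- make_synthetic_trajectory(n_frames = 8, sigma = 0, seed = 6)
  at <- st$traj$atoms
  sel <- select_atoms(at, "chain A and name N CA C O")
  expect_true(all(at$chain[sel] == "A"))
  expect_true(all(at$name[sel] %in% c("N", "CA", "C", "O")))
  expect_error(select_atoms(at, "banana A"), "unknown selection keyword")
  trimmed <- discard_equilibration(st$traj, 0.25)
  expect_equal(n_frames(trimmed), 6L)
})

test_that("PDB trajectories round-trip through the text reader", {
  st <- make_synthetic_trajectory(n_frames = 3, sigma = 0.01, seed = 44)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st$traj, path)
  back <- read_pdb(path)
  expect_equal(n_frames(back), 3L)
  expect_equal(back$atoms$name, st$traj$atoms$name)
  expect_equal(back$coords, st$traj$coords, tolerance = 1e-3) # 0.001 A files
  g <- withr::local_tempfile(fileext = ".gro")
  fx <- make_crosslink_fixture("DOGDIC-like")
  write_gro(fx$geometry, g)
  back2 <- read_gro(g)
  expect_equal(back2$coords[1, , ], unname(fx$geometry$coords),
               tolerance = 1e-3)
})
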