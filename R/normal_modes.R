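# MM normal-mode layer: analytic Hessian of the harmonic bonded energy,
# mass-weighted mode spectrum, and spectrum comparison against reference
# (QM) wavenumbers.

#' Construct a harmonic bonded force field
#'
#' @param bonds data.frame with columns i, j, k_b (kJ mol^-1 nm^-2),
#'   b0 (nm); may be empty.
#' @param angles data.frame with columns i, j, k (apex j), k_theta
#'   (kJ mol^-1 rad^-2), theta0 (degrees); may be empty.
#' @return object of class \code{harmonic_ff}.
#' @export
harmonic_ff <- function(bonds = NULL, angles = NULL) {
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          k_b = numeric(), b0 = numeric())
  if (is.null(angles)) angles <- data.frame(i = integer(), j = integer(),
                                            k = integer(), k_theta = numeric(),
                                            theta0 = numeric())
  stopifnot(all(bonds$k_b >= 0), all(angles$k_theta >= 0),
            all(bonds$b0 > 0))
  structure(list(bonds = bonds, angles = angles), class = "harmonic_ff")
}

#' Coerce a parameter set to a harmonic force field
#' @param p a \code{parameter_set} from \code{\link{derive_all}}.
#' @return a \code{\link{harmonic_ff}}.
#' @export
as_harmonic_ff <- function(p) {
  harmonic_ff(bonds = p$bonds[, c("i", "j", "k_b", "b0")],
              angles = p$angles[, c("i", "j", "k", "k_theta", "theta0")])
}

#' Harmonic bonded energy of a configuration
#'
#' \code{sum 1/2 k_b (b - b0)^2 + sum 1/2 k_theta (theta - theta0)^2};
#' used directly and as the target of the finite-difference Hessian oracle.
#'
#' @param coords N x 3 matrix (nm).
#' @param ff a \code{harmonic_ff}.
#' @return energy in kJ/mol.
#' @export
bonded_energy <- function(coords, ff) {
  e <- 0
  for (r in seq_len(nrow(ff$bonds))) {
    b <- ff$bonds[r, ]
    d <- sqrt(sum((coords[b$i, ] - coords[b$j, ])^2))
    e <- e + 0.5 * b$k_b * (d - b$b0)^2
  }
  for (r in seq_len(nrow(ff$angles))) {
    a <- ff$angles[r, ]
    u <- coords[a$i, ] - coords[a$j, ]
    v <- coords[a$k, ] - coords[a$j, ]
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    th <- acos(max(-1, min(1, cosang)))
    e <- e + 0.5 * a$k_theta * (th - a$theta0 * pi / 180)^2
  }
  e
}

# Analytic Hessian of the angle theta(i,j,k) w.r.t. the nine coordinates,
# plus its gradient. Derivatives of f = cos(theta) in terms of the arm
# vectors a = r_i - r_j, c = r_k - r_j, then theta = acos(f):
#   dtheta = -df / sin(theta)
#   d2theta = -d2f/sin - cos/sin^3 * df (x) df
.angle_derivs <- function(coords, i, j, k) {
  a <- coords[i, ] - coords[j, ]
  c_ <- coords[k, ] - coords[j, ]
  A <- sqrt(sum(a^2)); C <- sqrt(sum(c_^2))
  u <- a / A; v <- c_ / C
  f <- sum(u * v)
  f <- max(-1, min(1, f))
  s <- sqrt(max(0, 1 - f^2))
  if (s < 1e-8) stop("collinear angle configuration: second derivative undefined")
  theta <- acos(f)

  I3 <- diag(3)
  # first derivatives of f w.r.t. arm vectors
  fa <- (v - f * u) / A
  fc <- (u - f * v) / C
  # second derivatives of f
  faa <- (-outer(v - f * u, u) - outer(u, v - f * u) - f * (I3 - outer(u, u))) / A^2
  fcc <- (-outer(u - f * v, v) - outer(v, u - f * v) - f * (I3 - outer(v, v))) / C^2
  fac <- (I3 - outer(v, v) - outer(u, u) + f * outer(u, v)) / (A * C)

  # theta derivatives w.r.t. arm vectors
  ga <- -fa / s
  gc <- -fc / s
  Taa <- -faa / s - (f / s^3) * outer(fa, fa)
  Tcc <- -fcc / s - (f / s^3) * outer(fc, fc)
  Tac <- -fac / s - (f / s^3) * outer(fa, fc)

  # chain to atoms: d/dr_i = d/da, d/dr_k = d/dc, d/dr_j = -d/da - d/dc
  g <- list()
  g[[as.character(i)]] <- ga
  g[[as.character(k)]] <- gc
  g[[as.character(j)]] <- -(ga + gc)
  H <- list(
    ii = Taa, kk = Tcc, ik = Tac,
    ij = -(Taa + Tac), kj = -(t(Tac) + Tcc),
    jj = Taa + Tac + t(Tac) + Tcc
  )
  list(theta = theta, grad = g, hess = H)
}

#' Build the MM Hessian from a harmonic force field
#'
#' Analytic second derivatives of the bonded energy at the supplied
#' geometry (not only at equilibrium: the anharmonic geometry-dependent
#' terms \code{k (x - x0) d2x} are included).
#'
#' @param geom a \code{molecule_geometry}.
#' @param ff a \code{harmonic_ff} whose indices refer to \code{geom}.
#' @return a \code{cartesian_hessian} in kJ mol^-1 nm^-2.
#' @export
build_mm_hessian <- function(geom, ff) {
  n <- nrow(geom$atoms)
  stopifnot(all(c(ff$bonds$i, ff$bonds$j, ff$angles$i, ff$angles$j, ff$angles$k)
                %in% seq_len(n)))
  H <- matrix(0, 3 * n, 3 * n)
  add <- function(a, b, blk) {
    ia <- .block_idx(a); ib <- .block_idx(b)
    H[ia, ib] <<- H[ia, ib] + blk
  }
  for (r in seq_len(nrow(ff$bonds))) {
    bd <- ff$bonds[r, ]
    rij <- geom$coords[bd$i, ] - geom$coords[bd$j, ]
    b <- sqrt(sum(rij^2))
    if (b < 1e-9) stop("coincident atoms in bond ", bd$i, "-", bd$j)
    u <- rij / b
    blk <- bd$k_b * outer(u, u) +
      bd$k_b * (b - bd$b0) * (diag(3) - outer(u, u)) / b
    add(bd$i, bd$i, blk); add(bd$j, bd$j, blk)
    add(bd$i, bd$j, -blk); add(bd$j, bd$i, -blk)
  }
  for (r in seq_len(nrow(ff$angles))) {
    an <- ff$angles[r, ]
    d <- .angle_derivs(geom$coords, an$i, an$j, an$k)
    dth <- d$theta - an$theta0 * pi / 180
    kth <- an$k_theta
    atoms <- c(an$i, an$j, an$k)
    for (a in atoms) for (b in atoms) {
      key <- paste0(c("i", "j", "k")[match(c(a, b), atoms)], collapse = "")
      blk2 <- switch(key,
                     ii = d$hess$ii, jj = d$hess$jj, kk = d$hess$kk,
                     ij = d$hess$ij, ji = t(d$hess$ij),
                     ik = d$hess$ik, ki = t(d$hess$ik),
                     jk = t(d$hess$kj), kj = d$hess$kj)
      ga <- d$grad[[as.character(a)]]
      gb <- d$grad[[as.character(b)]]
      add(a, b, kth * outer(ga, gb) + kth * dth * blk2)
    }
  }
  cartesian_hessian(H, units = "kj_per_mol_nm2", n_atoms = n)
}

#' Finite-difference Hessian of the bonded energy
#'
#' Central-difference oracle used to validate \code{\link{build_mm_hessian}}.
#'
#' @param geom a \code{molecule_geometry}.
#' @param ff a \code{harmonic_ff}.
#' @param step displacement step in nm.
#' @return 3N x 3N numeric matrix.
#' @export
fd_hessian <- function(geom, ff, step = 1e-5) {
  x0 <- as.vector(t(geom$coords))
  nd <- length(x0)
  energy_at <- function(x) bonded_energy(matrix(x, ncol = 3, byrow = TRUE), ff)
  H <- matrix(0, nd, nd)
  for (p in seq_len(nd)) for (q in p:nd) {
    xpp <- x0; xpp[p] <- xpp[p] + step; xpp[q] <- xpp[q] + step
    xpm <- x0; xpm[p] <- xpm[p] + step; xpm[q] <- xpm[q] - step
    xmp <- x0; xmp[p] <- xmp[p] - step; xmp[q] <- xmp[q] + step
    xmm <- x0; xmm[p] <- xmm[p] - step; xmm[q] <- xmm[q] - step
    H[p, q] <- (energy_at(xpp) - energy_at(xpm) - energy_at(xmp) + energy_at(xmm)) /
      (4 * step^2)
    H[q, p] <- H[p, q]
  }
  H
}

#' Mass-weighted normal-mode spectrum
#'
#' Diagonalizes \code{F_ij = H_ij / sqrt(m_i m_j)} and converts eigenvalues
#' to signed wavenumbers: \code{sign(lambda) * sqrt(|lambda|) / (2 pi c)}.
#' Negative eigenvalues (imaginary modes) are reported as negative
#' wavenumbers. Translation/rotation are not projected out; near-zero modes
#' are counted post hoc with the \code{zero_tol} threshold.
#'
#' @param geom a \code{molecule_geometry} carrying masses.
#' @param h a \code{cartesian_hessian} in kJ mol^-1 nm^-2.
#' @param zero_tol near-zero wavenumber threshold (cm^-1, default 5).
#' @return object of class \code{mode_spectrum}: \code{wavenumbers}
#'   (ascending, cm^-1), \code{vectors} (orthonormal mass-weighted
#'   displacement columns), \code{n_zero}.
#' @export
mode_spectrum <- function(geom, h, zero_tol = 5) {
  if (h$units != "kj_per_mol_nm2") h <- convert_hessian_units(h, "kj_per_mol_nm2")
  m <- rep(geom$atoms$mass, each = 3L)
  invsq <- 1 / sqrt(m)
  Fm <- h$matrix * outer(invsq, invsq)
  e <- eigen((Fm + t(Fm)) / 2, symmetric = TRUE)
  lam <- rev(e$values)               # ascending
  vec <- e$vectors[, rev(seq_along(lam)), drop = FALSE]
  omega2 <- lam * xlf_constants$kjmol_nm2_amu_to_s2   # s^-2
  wn <- sign(omega2) * sqrt(abs(omega2)) / (2 * pi * xlf_constants$c_cm_s)
  ord <- order(wn)
  structure(list(wavenumbers = wn[ord],
                 vectors = vec[, ord, drop = FALSE],
                 n_zero = sum(abs(wn) < zero_tol),
                 zero_tol = zero_tol),
            class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat("mode_spectrum:", length(x$wavenumbers), "modes,",
      x$n_zero, "near-zero (<", x$zero_tol, "cm^-1 )\n")
  invisible(x)
}

#' Compare an MM mode spectrum with reference wavenumbers
#'
#' Drops the near-zero (translation/rotation) modes from the MM spectrum,
#' aligns the remaining modes to the reference list by ascending rank, and
#' reports per-mode differences plus the RMS over the first \code{n_modes}.
#'
#' @param qm a \code{qm_frequency_set} (zero modes already absent).
#' @param mm a \code{mode_spectrum}.
#' @param n_modes number of leading modes to compare.
#' @return object of class \code{spectrum_comparison}: data.frame
#'   \code{modes} (mode, qm, mm, diff) and scalar \code{rms}.
#' @export
compare_spectra <- function(qm, mm, n_modes) {
  mm_wn <- mm$wavenumbers[abs(mm$wavenumbers) >= mm$zero_tol]
  if (length(mm_wn) < n_modes || length(qm$wavenumbers) < n_modes) {
    stop("insufficient modes: need ", n_modes, ", have mm=", length(mm_wn),
         ", qm=", length(qm$wavenumbers))
  }
  qmv <- qm$wavenumbers[seq_len(n_modes)]
  mmv <- mm_wn[seq_len(n_modes)]
  d <- mmv - qmv
  structure(list(modes = data.frame(mode = seq_len(n_modes), qm = qmv,
                                    mm = mmv, diff = d),
                 rms = sqrt(mean(d^2))),
            class = "spectrum_comparison")
}

#' @export
print.spectrum_comparison <- function(x, ...) {
  cat("spectrum_comparison over", nrow(x$modes), "modes, RMS difference",
      format(x$rms, digits = 4), "cm^-1\n")
  invisible(x)
}
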