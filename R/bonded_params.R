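# Derivation of harmonic bond and angle terms from a Cartesian Hessian by
# the Seminario interatomic-block eigen-projection.
#
# Harmonic convention throughout: V = 1/2 k (x - x0)^2. Force constants in
# kJ mol^-1 nm^-2 (bonds) and kJ mol^-1 rad^-2 (angles); equilibrium values
# in nm and degrees.

.block_idx <- function(a) (3L * (a - 1L) + 1L):(3L * a)

#' Interatomic Hessian sub-block
#'
#' Returns the negated 3x3 off-diagonal block coupling the displacements of
#' atoms \code{a} and \code{b}: \code{-d2E/dr_a dr_b}.
#'
#' @param h a \code{cartesian_hessian}.
#' @param a,b distinct 1-based atom indices.
#' @return 3x3 numeric matrix.
#' @export
interatomic_block <- function(h, a, b) {
  n <- h$n_atoms
  if (a == b) stop("self-block requested (a == b == ", a, "): not an interatomic coupling")
  if (a < 1 || a > n || b < 1 || b > n) {
    stop("atom index out of range 1..", n, ": ", a, ", ", b)
  }
  -h$matrix[.block_idx(a), .block_idx(b), drop = FALSE]
}

# Sum_m lambda_m |u . v_m| over the eigenpairs of a 3x3 block. Blocks from
# exact harmonic Hessians are symmetric; small numerical asymmetry is
# tolerated by discarding negligible imaginary parts.
.eigen_projection <- function(block, u) {
  e <- eigen(block)
  lam <- e$values
  vec <- e$vectors
  if (is.complex(lam)) {
    if (max(abs(Im(lam))) > 0.05 * max(1, max(abs(Re(lam))))) {
      warning("interatomic block has significantly complex eigenvalues; using real parts")
    }
    lam <- Re(lam)
    vec <- Re(vec)
  }
  sum(lam * abs(as.vector(u %*% vec)))
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

#' Derive a harmonic bond term
#'
#' Seminario projection: the force constant is the mean over the (i,j) and
#' (j,i) interatomic blocks of the eigenvalue sum projected on the unit
#' bond vector, \code{sum_m lambda_m |u_ij . v_m|}. Negative eigenvalues
#' contribute through the absolute-value projection, so the result is
#' always non-negative. The equilibrium length is read from the geometry.
#'
#' @param h \code{cartesian_hessian} in kJ mol^-1 nm^-2.
#' @param geom the paired \code{molecule_geometry}.
#' @param pair integer vector (i, j).
#' @return list of class \code{bond_term}: i, j (canonical i < j), k_b
#'   (kJ mol^-1 nm^-2), b0 (nm).
#' @export
derive_bond <- function(h, geom, pair) {
  stopifnot(h$units == "kj_per_mol_nm2")
  pair <- canonical_pair(as.integer(pair))
  i <- pair[1]; j <- pair[2]
  rij <- geom$coords[j, ] - geom$coords[i, ]
  b0 <- sqrt(sum(rij^2))
  if (b0 < 1e-6) stop("atoms ", i, " and ", j, " are coincident (|r| < 1e-6 nm)")
  u <- rij / b0
  k_b <- mean(c(.eigen_projection(interatomic_block(h, i, j), u),
                .eigen_projection(interatomic_block(h, j, i), u)))
  structure(list(i = i, j = j, k_b = k_b, b0 = b0), class = "bond_term")
}

# In-plane unit vectors perpendicular to the two angle arms.
.angle_frame <- function(geom, i, j, k, tol = 1e-4) {
  u_ij <- .unit(geom$coords[i, ] - geom$coords[j, ])
  u_kj <- .unit(geom$coords[k, ] - geom$coords[j, ])
  cosang <- max(-1, min(1, sum(u_ij * u_kj)))
  theta <- acos(cosang)
  if (theta < tol || theta > pi - tol) {
    stop("collinear triplet (", i, ",", j, ",", k,
         "): angle plane undefined")
  }
  n <- .unit(cross3(u_kj, u_ij))
  list(u_ij = u_ij, u_kj = u_kj, u_n = n,
       u_pi = cross3(n, u_ij), u_pk = cross3(u_kj, n),
       r_ij = sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2)),
       r_kj = sqrt(sum((geom$coords[k, ] - geom$coords[j, ])^2)),
       theta = theta)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Derive a harmonic angle term
#'
#' Two realizations of the interatomic-block projection are provided.
#'
#' \code{"arm_block"} (default) reads the bending stiffness from the
#' 1-3 coupling block between the two arm atoms:
#' \code{k_theta = R_ij R_kj |u_Pi . (-block(i,k)) . u_Pk|}, where
#' \code{u_Pi}, \code{u_Pk} are the in-plane unit vectors perpendicular to
#' the two arms. Bond-stretch terms never contribute to the (i,k) block of
#' a bond+angle harmonic Hessian, so this projection recovers a generating
#' angle constant exactly on analytic fixtures.
#'
#' \code{"seminario_reciprocal"} is the classical two-term reciprocal form
#' \code{1/k_theta = 1/(R_ij^2 S_i) + 1/(R_kj^2 S_k)} with \code{S_i} the
#' eigen-projection of the (i,j) block onto \code{u_Pi} (averaging the
#' (a,b) and (b,a) blocks). On an idealized single-angle Hessian this form
#' systematically underestimates (the series sum halves a lone angle
#' spring); it is retained for comparison with the classical method.
#'
#' The equilibrium angle is always read from the geometry.
#'
#' @param h \code{cartesian_hessian} in kJ mol^-1 nm^-2.
#' @param geom the paired \code{molecule_geometry}.
#' @param triplet integer vector (i, j, k) with apex j.
#' @param method \code{"arm_block"} or \code{"seminario_reciprocal"}.
#' @return list of class \code{angle_term}: i, j, k (canonical, apex j),
#'   k_theta (kJ mol^-1 rad^-2), theta0 (degrees).
#' @export
derive_angle <- function(h, geom, triplet,
                         method = c("arm_block", "seminario_reciprocal")) {
  stopifnot(h$units == "kj_per_mol_nm2")
  method <- match.arg(method)
  triplet <- canonical_triplet(as.integer(triplet))
  i <- triplet[1]; j <- triplet[2]; k <- triplet[3]
  if (anyDuplicated(triplet)) stop("angle atoms must be distinct: ",
                                   paste(triplet, collapse = ","))
  fr <- .angle_frame(geom, i, j, k)
  if (method == "arm_block") {
    # bilinear perpendicular projection of the arm-arm block; average the
    # (i,k) and (k,i) blocks (exact transposes, so this symmetrizes)
    b_ik <- interatomic_block(h, i, k)
    q <- (as.numeric(fr$u_pi %*% b_ik %*% fr$u_pk) +
            as.numeric(fr$u_pk %*% t(b_ik) %*% fr$u_pi)) / 2
    k_theta <- fr$r_ij * fr$r_kj * abs(q)
  } else {
    proj <- function(a, b, u) {
      mean(c(.eigen_projection(interatomic_block(h, a, b), u),
             .eigen_projection(interatomic_block(h, b, a), u)))
    }
    s_i <- proj(i, j, fr$u_pi)
    s_k <- proj(k, j, fr$u_pk)
    if (s_i <= 0 || s_k <= 0) {
      warning("non-positive arm projection for angle (",
              paste(triplet, collapse = ","), "); k_theta set to 0")
      k_theta <- 0
    } else {
      k_theta <- 1 / (1 / (fr$r_ij^2 * s_i) + 1 / (fr$r_kj^2 * s_k))
    }
  }
  structure(list(i = i, j = j, k = k, k_theta = k_theta,
                 theta0 = fr$theta * 180 / pi),
            class = "angle_term")
}

#' Derive a full parameter set
#'
#' One bond term per canonical pair and one angle term per canonical
#' triplet, with provenance recorded.
#'
#' @param h \code{cartesian_hessian} in kJ mol^-1 nm^-2 (converted if in
#'   Hartree/Bohr^2).
#' @param geom the paired \code{molecule_geometry}.
#' @param pairs list of integer pairs.
#' @param triplets list of integer triplets.
#' @param method angle realization, see \code{\link{derive_angle}}.
#' @param provenance optional character tag recorded in the result.
#' @return object of class \code{parameter_set} with data.frames
#'   \code{bonds} (i, j, name_i, name_j, k_b, b0) and \code{angles}
#'   (i, j, k, names, k_theta, theta0).
#' @export
derive_all <- function(h, geom, pairs, triplets,
                       method = c("arm_block", "seminario_reciprocal"),
                       provenance = "derive_all") {
  method <- match.arg(method)
  if (h$units != "kj_per_mol_nm2") h <- convert_hessian_units(h, "kj_per_mol_nm2")
  pairs <- lapply(pairs, canonical_pair)
  triplets <- lapply(triplets, canonical_triplet)
  if (anyDuplicated(vapply(pairs, paste, "", collapse = "-"))) {
    stop("duplicate canonical bond pair in request")
  }
  if (anyDuplicated(vapply(triplets, paste, "", collapse = "-"))) {
    stop("duplicate canonical angle triplet in request")
  }
  bonds <- do.call(rbind, lapply(pairs, function(p) {
    bt <- tryCatch(derive_bond(h, geom, p),
                   error = function(e) stop("bond (", paste(p, collapse = ","),
                                            "): ", conditionMessage(e)))
    data.frame(i = bt$i, j = bt$j,
               name_i = geom$atoms$name[bt$i], name_j = geom$atoms$name[bt$j],
               k_b = bt$k_b, b0 = bt$b0, stringsAsFactors = FALSE)
  }))
  angles <- do.call(rbind, lapply(triplets, function(t3) {
    at <- tryCatch(derive_angle(h, geom, t3, method = method),
                   error = function(e) stop("angle (", paste(t3, collapse = ","),
                                            "): ", conditionMessage(e)))
    data.frame(i = at$i, j = at$j, k = at$k,
               name_i = geom$atoms$name[at$i], name_j = geom$atoms$name[at$j],
               name_k = geom$atoms$name[at$k],
               k_theta = at$k_theta, theta0 = at$theta0, stringsAsFactors = FALSE)
  }))
  empty_b <- data.frame(i = integer(), j = integer(), name_i = character(),
                        name_j = character(), k_b = numeric(), b0 = numeric(),
                        stringsAsFactors = FALSE)
  empty_a <- data.frame(i = integer(), j = integer(), k = integer(),
                        name_i = character(), name_j = character(),
                        name_k = character(), k_theta = numeric(),
                        theta0 = numeric(), stringsAsFactors = FALSE)
  structure(list(bonds = if (is.null(bonds)) empty_b else bonds,
                 angles = if (is.null(angles)) empty_a else angles,
                 provenance = provenance),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("parameter_set:", nrow(x$bonds), "bond term(s),",
      nrow(x$angles), "angle term(s) [", x$provenance, "]\n")
  invisible(x)
}
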