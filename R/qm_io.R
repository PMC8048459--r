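# QM input layer: domain containers, the formatted-checkpoint dialect,
# unit normalization, and the bonded-term request files.

#' Construct an atom table
#'
#' @param name character vector of atom names (e.g. \code{"OD1"}).
#' @param element element symbols; guessed from names when \code{NULL}.
#' @param mass atomic masses (amu); looked up by element when \code{NULL}.
#' @param charge partial charges (e); \code{NA} when not yet assigned.
#' @return data.frame with columns index, name, element, mass, charge.
#' @export
atom_table <- function(name, element = NULL, mass = NULL, charge = NA_real_) {
  if (is.null(element)) element <- element_from_name(name)
  if (is.null(mass)) mass <- element_mass(element)
  stopifnot(all(mass > 0))
  if (anyDuplicated(name)) {
    stop("duplicate atom names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  data.frame(index = seq_along(name), name = name, element = element,
             mass = mass, charge = rep_len(charge, length(name)),
             stringsAsFactors = FALSE)
}

#' Construct a molecule geometry
#'
#' Coordinates are stored internally in nm; pass \code{unit} to convert at
#' the boundary.
#'
#' @param atoms atom table (see \code{\link{atom_table}}).
#' @param coords N x 3 numeric matrix of positions.
#' @param unit one of \code{"nm"}, \code{"angstrom"}, \code{"bohr"}.
#' @return object of class \code{molecule_geometry}.
#' @export
molecule_geometry <- function(atoms, coords, unit = c("nm", "angstrom", "bohr")) {
  unit <- match.arg(unit)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3L) {
    stop("coords must be ", nrow(atoms), " x 3, got ",
         nrow(coords), " x ", ncol(coords))
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (nrow(atoms) < 2L) stop("a molecule needs at least 2 atoms")
  scale <- switch(unit, nm = 1,
                  angstrom = xlf_constants$angstrom_to_nm,
                  bohr = xlf_constants$bohr_to_nm)
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords * scale),
            class = "molecule_geometry")
}

#' @export
print.molecule_geometry <- function(x, ...) {
  cat("molecule_geometry:", nrow(x$atoms), "atoms (",
      paste(utils::head(x$atoms$name, 8), collapse = " "),
      if (nrow(x$atoms) > 8) "..." else "", ")\n")
  invisible(x)
}

#' Construct a Cartesian Hessian
#'
#' @param matrix 3N x 3N symmetric matrix of second derivatives.
#' @param units \code{"hartree_per_bohr2"} or \code{"kj_per_mol_nm2"}.
#' @param n_atoms number of atoms the Hessian belongs to.
#' @return object of class \code{cartesian_hessian}.
#' @export
cartesian_hessian <- function(matrix, units = c("kj_per_mol_nm2", "hartree_per_bohr2"),
                              n_atoms = nrow(matrix) / 3L) {
  units <- match.arg(units)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("Hessian must be square")
  if (nrow(matrix) != 3L * n_atoms) {
    stop("Hessian dimension ", nrow(matrix), " does not match 3 x ",
         n_atoms, " atoms")
  }
  rel <- max(abs(matrix - t(matrix))) / max(1, max(abs(matrix)))
  if (rel > 1e-8) stop("Hessian not symmetric (relative asymmetry ", signif(rel, 3), ")")
  structure(list(matrix = (matrix + t(matrix)) / 2, units = units,
                 n_atoms = as.integer(n_atoms)),
            class = "cartesian_hessian")
}

#' Convert Hessian units
#'
#' Supported units: Hartree/Bohr^2 (QM native) and kJ mol^-1 nm^-2
#' (internal). Forth-and-back conversion is an exact inverse scaling.
#'
#' @param h a \code{cartesian_hessian}.
#' @param target target unit tag.
#' @return a \code{cartesian_hessian} in the target units.
#' @export
convert_hessian_units <- function(h, target = c("kj_per_mol_nm2", "hartree_per_bohr2")) {
  target <- match.arg(target)
  if (h$units == target) return(h)
  # Hartree/Bohr^2 -> kJ/mol/nm^2
  s <- xlf_constants$hartree_to_kjmol / xlf_constants$bohr_to_nm^2
  scale <- if (target == "kj_per_mol_nm2") s else 1 / s
  cartesian_hessian(h$matrix * scale, units = target, n_atoms = h$n_atoms)
}

#' Construct a QM frequency set
#'
#' @param wavenumbers numeric vector of vibrational wavenumbers (cm^-1).
#' @return object of class \code{qm_frequency_set} (ascending order enforced).
#' @export
qm_frequency_set <- function(wavenumbers) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.unsorted(wavenumbers)) wavenumbers <- sort(wavenumbers)
  structure(list(wavenumbers = wavenumbers), class = "qm_frequency_set")
}

# ---------------------------------------------------------------------------
# Formatted-checkpoint dialect
#
# Recognized sections: "Number of atoms" (I), "Atomic numbers" (I N=),
# "Current cartesian coordinates" (R N=, Bohr), "Cartesian Force Constants"
# (R N=, lower triangle, Hartree/Bohr^2).
# ---------------------------------------------------------------------------

.read_fchk_block <- function(lines, start, n, numeric = TRUE) {
  vals <- c()
  i <- start + 1L
  while (length(vals) < n && i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- c(vals, tok)
    i <- i + 1L
  }
  if (length(vals) < n) stop("truncated checkpoint block (expected ", n, " values)")
  vals <- vals[seq_len(n)]
  if (numeric) as.numeric(vals) else vals
}

#' Read a formatted-checkpoint file
#'
#' Parses the formatted-checkpoint dialect: atom count, atomic numbers,
#' Cartesian coordinates (Bohr) and the lower-triangular Cartesian force
#' constants (Hartree/Bohr^2). The Hessian is expanded to a full symmetric
#' matrix and coordinates are converted to nm; masses are assigned from the
#' packaged element-mass table.
#'
#' @param path path to the checkpoint file.
#' @return list with elements \code{geometry} (a
#'   \code{\link{molecule_geometry}}) and \code{hessian} (a
#'   \code{\link{cartesian_hessian}} in Hartree/Bohr^2).
#' @export
read_checkpoint <- function(path) {
  lines <- readLines(path)
  find <- function(tag) {
    hit <- grep(tag, lines, fixed = TRUE)
    if (!length(hit)) stop("checkpoint section not found: ", tag)
    hit[1]
  }
  i_n <- find("Number of atoms")
  n_atoms <- as.integer(tail(strsplit(trimws(lines[i_n]), "\\s+")[[1]], 1))
  if (is.na(n_atoms) || n_atoms < 1) stop("unreadable atom count")

  z <- as.integer(.read_fchk_block(lines, find("Atomic numbers"), n_atoms))
  coords_bohr <- matrix(.read_fchk_block(lines, find("Current cartesian coordinates"),
                                         3L * n_atoms),
                        ncol = 3L, byrow = TRUE)

  i_fc <- find("Cartesian Force Constants")
  n_declared <- as.integer(sub(".*N=\\s*", "", lines[i_fc]))
  n_expected <- (3L * n_atoms) * (3L * n_atoms + 1L) / 2L
  if (!is.na(n_declared) && n_declared != n_expected) {
    stop("Hessian block holds ", n_declared, " values but 3N = ", 3L * n_atoms,
         " requires ", n_expected)
  }
  tri <- .read_fchk_block(lines, i_fc, n_expected)

  dim3n <- 3L * n_atoms
  H <- matrix(0, dim3n, dim3n)
  H[upper.tri(H, diag = TRUE)] <- tri     # column-wise upper == row-wise lower
  H <- H + t(H) - diag(diag(H))

  elem <- element_from_number(z)
  nm <- make.unique(paste0(elem, seq_along(elem)), sep = "_")
  atoms <- atom_table(name = nm, element = elem)
  geom <- molecule_geometry(atoms, coords_bohr, unit = "bohr")
  list(geometry = geom,
       hessian = cartesian_hessian(H, units = "hartree_per_bohr2",
                                   n_atoms = n_atoms))
}

#' Write a formatted-checkpoint file
#'
#' Inverse of \code{\link{read_checkpoint}}; used to round-trip synthetic
#' molecules through the parser. Coordinates are written in Bohr and the
#' Hessian as a lower-triangular block in Hartree/Bohr^2.
#'
#' @param geom a \code{molecule_geometry}.
#' @param h a \code{cartesian_hessian} (any units; converted on write).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_checkpoint <- function(geom, h, path) {
  h <- convert_hessian_units(h, "hartree_per_bohr2")
  n <- nrow(geom$atoms)
  z <- .element_numbers[geom$atoms$element]
  coords_bohr <- as.vector(t(geom$coords / xlf_constants$bohr_to_nm))
  tri <- h$matrix[upper.tri(h$matrix, diag = TRUE)]
  fmt <- function(x) {
    rows <- split(x, ceiling(seq_along(x) / 5))
    vapply(rows, function(r) paste(sprintf("% .15E", r), collapse = " "), "")
  }
  out <- c(
    "synthetic checkpoint",
    sprintf("Number of atoms                            I %16d", n),
    sprintf("Atomic numbers                             I   N= %10d", n),
    vapply(split(z, ceiling(seq_along(z) / 6)),
           function(r) paste(sprintf("%12d", r), collapse = ""), ""),
    sprintf("Current cartesian coordinates              R   N= %10d", 3L * n),
    fmt(coords_bohr),
    sprintf("Cartesian Force Constants                  R   N= %10d", length(tri)),
    fmt(tri)
  )
  writeLines(out, path)
  invisible(path)
}

#' Read a plain wavenumber list
#'
#' One or more wavenumbers (cm^-1) per line, \code{#} comments allowed.
#'
#' @param path file path.
#' @return a \code{\link{qm_frequency_set}}.
#' @export
read_frequencies <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[nzchar(trimws(lines))]), "\\s+")))
  if (anyNA(vals)) stop("non-numeric wavenumber entries in ", path)
  qm_frequency_set(vals)
}

# ---------------------------------------------------------------------------
# Pair / triplet request files
# ---------------------------------------------------------------------------

.parse_request_lines <- function(path, geom, arity) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(sub("#.*", "", lines))))
  out <- list()
  for (ln in keep) {
    tok <- strsplit(trimws(sub("#.*", "", lines[ln])), "\\s+")[[1]]
    if (length(tok) != 2L * arity) {
      stop("line ", ln, " of ", path, ": expected ", 2L * arity,
           " fields (names then ids), got ", length(tok))
    }
    nm <- tok[seq_len(arity)]
    id <- suppressWarnings(as.integer(tok[arity + seq_len(arity)]))
    if (anyNA(id)) stop("line ", ln, " of ", path, ": non-integer atom id")
    bad <- id < 1L | id > nrow(geom$atoms)
    if (any(bad)) {
      stop("line ", ln, " of ", path, ": atom id ", paste(id[bad], collapse = ","),
           " outside 1..", nrow(geom$atoms))
    }
    mism <- geom$atoms$name[id] != nm
    if (any(mism)) {
      stop("line ", ln, " of ", path, ": name/id mismatch: ",
           paste0(nm[mism], "!=", geom$atoms$name[id[mism]], collapse = ", "))
    }
    out[[length(out) + 1L]] <- id
  }
  out
}

# Canonical order: bonds (i,j) with i<j; angles keep the apex in the middle
# and put the lexicographically smaller endpoint first.
canonical_pair <- function(p) if (p[1] <= p[2]) p else rev(p)
canonical_triplet <- function(t) if (t[1] <= t[3]) t else rev(t)

#' Read bonded-term request files
#'
#' Reads the atom-pair (bond) and atom-triplet (angle) request files:
#' whitespace-separated \code{name_i name_j id_i id_j} (and the triplet
#' analogue), \code{#} comments. Names are cross-checked against the
#' geometry; (i,j)/(j,i) pairs and (i,j,k)/(k,j,i) triplets are the same
#' term and are deduplicated to canonical order.
#'
#' @param pairs_path path to the bond-pair request file.
#' @param triplets_path path to the angle-triplet request file.
#' @param geom the \code{molecule_geometry} the ids refer to.
#' @return list with \code{pairs} (list of length-2 integer vectors) and
#'   \code{triplets} (list of length-3 integer vectors).
#' @export
read_pair_triplet_requests <- function(pairs_path, triplets_path, geom) {
  pairs <- lapply(.parse_request_lines(pairs_path, geom, 2L), canonical_pair)
  trips <- lapply(.parse_request_lines(triplets_path, geom, 3L), canonical_triplet)
  dedup <- function(xs, what) {
    key <- vapply(xs, paste, "", collapse = "-")
    if (anyDuplicated(key)) {
      warning("duplicate ", what, " request(s) deduplicated: ",
              paste(unique(key[duplicated(key)]), collapse = " "))
    }
    xs[!duplicated(key)]
  }
  list(pairs = dedup(pairs, "pair"), triplets = dedup(trips, "triplet"))
}
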