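# Cross-link topology construction and GROMACS-dialect emission: two
# residue templates joined by special-bond records, with zero-net-charge
# bookkeeping.

#' Construct a residue template
#'
#' @param name residue identifier (e.g. a lysine-derived half).
#' @param atoms data.frame with columns name, type, charge.
#' @param bonds data.frame with columns a, b (atom names within the residue).
#' @return object of class \code{residue_template}.
#' @export
residue_template <- function(name, atoms, bonds = NULL) {
  if (nrow(atoms) == 0L) stop("empty residue '", name, "' refused")
  if (anyDuplicated(atoms$name)) {
    stop("duplicate atom names in residue '", name, "'")
  }
  if (is.null(bonds)) bonds <- data.frame(a = character(), b = character(),
                                          stringsAsFactors = FALSE)
  missing <- setdiff(c(bonds$a, bonds$b), atoms$name)
  if (length(missing)) {
    stop("bond endpoint(s) not in residue '", name, "': ",
         paste(missing, collapse = ", "))
  }
  structure(list(name = name, atoms = atoms, bonds = bonds),
            class = "residue_template")
}

#' Construct a cross-link topology
#'
#' @param residue_a,residue_b the two \code{\link{residue_template}} halves.
#' @param connection_bonds data.frame with columns atom_a, atom_b (one name
#'   from each residue), b0 (nm) and k_b (kJ mol^-1 nm^-2, may be NA).
#' @param parameters optional \code{parameter_set} backing the topology.
#' @return object of class \code{crosslink_topology}.
#' @export
crosslink_topology <- function(residue_a, residue_b, connection_bonds,
                               parameters = NULL) {
  stopifnot(inherits(residue_a, "residue_template"),
            inherits(residue_b, "residue_template"))
  bad_a <- setdiff(connection_bonds$atom_a, residue_a$atoms$name)
  bad_b <- setdiff(connection_bonds$atom_b, residue_b$atoms$name)
  if (length(bad_a) || length(bad_b)) {
    stop("connection bond endpoints must join the two residues; unknown: ",
         paste(c(bad_a, bad_b), collapse = ", "))
  }
  structure(list(residue_a = residue_a, residue_b = residue_b,
                 connection_bonds = connection_bonds, parameters = parameters),
            class = "crosslink_topology")
}

#' Infer a covalent bond graph from interatomic distances
#'
#' Atoms closer than 1.2 times the sum of their covalent radii are bonded.
#'
#' @param geom a \code{molecule_geometry}.
#' @param scale cutoff multiplier (default 1.2).
#' @return data.frame with integer columns i, j (i < j).
#' @export
infer_bonds <- function(geom, scale = 1.2) {
  n <- nrow(geom$atoms)
  r <- covalent_radius(geom$atoms$element)
  d <- as.matrix(stats::dist(geom$coords))
  cut <- outer(r, r, "+") * scale
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2])
}

# Connected components of an undirected graph given as an edge data.frame.
.components <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

#' Split a cross-link into two residue templates
#'
#' Removes the boundary bonds from the molecular bond graph; the two
#' connected components that remain (after excluding capping atoms) become
#' the two residue halves, and each boundary bond becomes an inter-residue
#' connection record.
#'
#' @param geom a \code{molecule_geometry} with charges populated (charges
#'   may be NA; they are carried through).
#' @param boundary list of atom-name pairs straddling the partition.
#' @param bonds optional explicit bond data.frame (i, j); inferred from
#'   covalent radii when NULL.
#' @param caps character vector of capping-atom names excluded from both
#'   residues.
#' @param names two residue names, default \code{c("XL1", "XL2")}.
#' @return list with \code{residue_a}, \code{residue_b}
#'   (\code{residue_template}s) and \code{connections} (data.frame atom_a,
#'   atom_b, b0 from the geometry).
#' @export
split_crosslink <- function(geom, boundary, bonds = NULL, caps = character(),
                            names = c("XL1", "XL2")) {
  atoms <- geom$atoms
  if (is.null(bonds)) bonds <- infer_bonds(geom)
  idx_of <- function(nm) {
    i <- match(nm, atoms$name)
    if (anyNA(i)) stop("unknown atom name(s): ", paste(nm[is.na(i)], collapse = ", "))
    i
  }
  bkey <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  cut_idx <- lapply(boundary, function(p) sort(idx_of(p)))
  for (ci in cut_idx) {
    if (!paste(ci[1], ci[2]) %in% bkey) {
      stop("boundary pair (", atoms$name[ci[1]], ",", atoms$name[ci[2]],
           ") is not an existing bond")
    }
  }
  ckey <- vapply(cut_idx, function(ci) paste(ci[1], ci[2]), "")
  keep <- bonds[!(bkey %in% ckey), , drop = FALSE]

  cap_idx <- if (length(caps)) idx_of(caps) else integer()
  comp <- .components(nrow(atoms), keep)
  core <- setdiff(seq_len(nrow(atoms)), cap_idx)
  core_comps <- unique(comp[core])
  if (length(core_comps) != 2L) {
    memb <- split(atoms$name[core], comp[core])
    stop("boundary removal yields ", length(core_comps),
         " components, expected 2. Memberships: ",
         paste(vapply(memb, paste, "", collapse = ","), collapse = " | "))
  }
  # deterministic labelling: the component holding the lowest atom index is A
  comp_a <- comp[min(core)]
  in_a <- core[comp[core] == comp_a]
  in_b <- core[comp[core] != comp_a]

  make_res <- function(sel, nm) {
    sub <- atoms[sel, , drop = FALSE]
    inb <- keep[keep$i %in% sel & keep$j %in% sel, , drop = FALSE]
    residue_template(nm,
                     atoms = data.frame(name = sub$name, type = sub$element,
                                        charge = sub$charge,
                                        stringsAsFactors = FALSE),
                     bonds = data.frame(a = atoms$name[inb$i],
                                        b = atoms$name[inb$j],
                                        stringsAsFactors = FALSE))
  }
  conn <- do.call(rbind, lapply(cut_idx, function(ci) {
    a <- if (ci[1] %in% in_a) ci[1] else ci[2]
    b <- setdiff(ci, a)
    if (!(a %in% in_a && b %in% in_b)) {
      stop("boundary pair (", atoms$name[ci[1]], ",", atoms$name[ci[2]],
           ") does not straddle the partition")
    }
    data.frame(atom_a = atoms$name[a], atom_b = atoms$name[b],
               b0 = sqrt(sum((geom$coords[a, ] - geom$coords[b, ])^2)),
               stringsAsFactors = FALSE)
  }))
  conn <- conn[order(conn$atom_a, conn$atom_b), , drop = FALSE]
  rownames(conn) <- NULL
  list(residue_a = make_res(in_a, names[1]),
       residue_b = make_res(in_b, names[2]),
       connections = conn)
}

#' Check the zero-net-charge invariant
#'
#' Sums the partial charges of both residue halves and reports pass/fail at
#' \code{|sum| <= tol}. Never mutates charges.
#'
#' @param t a \code{crosslink_topology}.
#' @param tol tolerance in e (default 1e-6).
#' @return list with \code{total_charge}, \code{pass}, \code{tol}.
#' @export
check_net_charge <- function(t, tol = 1e-6) {
  q <- c(t$residue_a$atoms$charge, t$residue_b$atoms$charge)
  nm <- c(t$residue_a$atoms$name, t$residue_b$atoms$name)
  if (anyNA(q)) stop("missing charge on atom(s): ",
                     paste(nm[is.na(q)], collapse = ", "))
  total <- sum(q)
  list(total_charge = total, pass = abs(total) <= tol, tol = tol)
}

.fmt_num <- function(x) sprintf("%.6f", x)

#' Write residue-template entries
#'
#' Emits both halves in the rtp-style residue dialect: \code{[ resname ]},
#' \code{[ atoms ]} (name, type, charge, charge-group; one atom per charge
#' group) and \code{[ bonds ]}. Output is byte-stable for identical input.
#'
#' @param t a \code{crosslink_topology}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_residue_entries <- function(t, path) {
  emit <- function(res) {
    at <- res$atoms
    if (anyNA(at$charge)) stop("residue '", res$name, "' has atoms without charges")
    c(sprintf("[ %s ]", res$name),
      " [ atoms ]",
      sprintf("  %-6s %-6s %10s %4d", at$name, at$type,
              .fmt_num(at$charge), seq_len(nrow(at)) - 1L),
      " [ bonds ]",
      if (nrow(res$bonds)) sprintf("  %-6s %-6s", res$bonds$a, res$bonds$b))
  }
  writeLines(c(emit(t$residue_a), emit(t$residue_b)), path)
  invisible(path)
}

#' Read residue-template entries
#'
#' Parses a file written by \code{\link{write_residue_entries}}.
#'
#' @param path file path.
#' @return list of \code{residue_template} objects.
#' @export
read_residue_entries <- function(path) {
  lines <- readLines(path)
  res_starts <- grep("^\\[ ", lines)
  out <- list()
  for (s in seq_along(res_starts)) {
    from <- res_starts[s]
    to <- if (s < length(res_starts)) res_starts[s + 1] - 1L else length(lines)
    block <- lines[from:to]
    nm <- sub("^\\[ (.*) \\]$", "\\1", block[1])
    sec <- cumsum(grepl("^ \\[", block))
    atom_lines <- block[sec == 1 & !grepl("^ \\[", block)]
    bond_lines <- block[sec == 2 & !grepl("^ \\[", block)]
    at <- do.call(rbind, lapply(strsplit(trimws(atom_lines), "\\s+"), function(x)
      data.frame(name = x[1], type = x[2], charge = as.numeric(x[3]),
                 stringsAsFactors = FALSE)))
    bd <- if (length(bond_lines)) {
      do.call(rbind, lapply(strsplit(trimws(bond_lines), "\\s+"), function(x)
        data.frame(a = x[1], b = x[2], stringsAsFactors = FALSE)))
    } else NULL
    out[[nm]] <- residue_template(nm, at, bd)
  }
  out
}

#' Write special-bond records
#'
#' One line per inter-residue connection bond in the special-bond dialect:
#' \code{resname1 atom1 nbonds1 resname2 atom2 nbonds2 length newres1
#' newres2}, length in nm.
#'
#' @param t a \code{crosslink_topology} with non-empty connection bonds.
#' @param path output path.
#' @param nbonds bookkeeping bond counts written for both atoms (default 1).
#' @return \code{path}, invisibly.
#' @export
write_specbond <- function(t, path, nbonds = c(1L, 1L)) {
  cb <- t$connection_bonds
  if (is.null(cb) || nrow(cb) == 0L) stop("no connection bonds to write")
  if (anyNA(cb$b0)) stop("connection bond without a derived b0")
  cb <- cb[order(cb$atom_a, cb$atom_b), , drop = FALSE]
  writeLines(c(sprintf("%d", nrow(cb)),
               sprintf("%s %s %d %s %s %d %s %s %s",
                       t$residue_a$name, cb$atom_a, nbonds[1],
                       t$residue_b$name, cb$atom_b, nbonds[2],
                       .fmt_num(cb$b0), t$residue_a$name, t$residue_b$name)),
             path)
  invisible(path)
}

#' Read special-bond records
#' @param path file path.
#' @return data.frame res_a, atom_a, res_b, atom_b, b0 (nm).
#' @export
read_specbond <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  do.call(rbind, lapply(rows, function(x)
    data.frame(res_a = x[1], atom_a = x[2], res_b = x[4], atom_b = x[5],
               b0 = as.numeric(x[7]), stringsAsFactors = FALSE)))
}

#' Write bonded parameter tables
#'
#' Emits \code{[ bondtypes ]} (atom names, function type 1, b0 nm, k_b) and
#' \code{[ angletypes ]} (names, type 1, theta0 deg, k_theta) in the
#' harmonic 1/2 k convention.
#'
#' @param p a \code{parameter_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bonded_parameters <- function(p, path) {
  if (nrow(p$bonds) == 0L && nrow(p$angles) == 0L) {
    warning("empty parameter set: writing empty sections")
  }
  b <- p$bonds[order(p$bonds$name_i, p$bonds$name_j), , drop = FALSE]
  a <- p$angles[order(p$angles$name_i, p$angles$name_j, p$angles$name_k), ,
                drop = FALSE]
  writeLines(c(
    "[ bondtypes ]",
    if (nrow(b)) sprintf("  %-6s %-6s 1 %12.10f %14.6f",
                         b$name_i, b$name_j, b$b0, b$k_b),
    "[ angletypes ]",
    if (nrow(a)) sprintf("  %-6s %-6s %-6s 1 %12.8f %14.8f",
                         a$name_i, a$name_j, a$name_k, a$theta0, a$k_theta)
  ), path)
  invisible(path)
}

#' Read bonded parameter tables
#' @param path file path.
#' @return list with data.frames \code{bonds} (name_i, name_j, b0, k_b) and
#'   \code{angles} (name_i, name_j, name_k, theta0, k_theta).
#' @export
read_bonded_parameters <- function(path) {
  lines <- readLines(path)
  sec <- cumsum(grepl("^\\[", lines))
  parse_rows <- function(ls, fn) {
    ls <- ls[nzchar(trimws(ls))]
    if (!length(ls)) return(NULL)
    do.call(rbind, lapply(strsplit(trimws(ls), "\\s+"), fn))
  }
  bonds <- parse_rows(lines[sec == 1 & !grepl("^\\[", lines)], function(x)
    data.frame(name_i = x[1], name_j = x[2], b0 = as.numeric(x[4]),
               k_b = as.numeric(x[5]), stringsAsFactors = FALSE))
  angles <- parse_rows(lines[sec == 2 & !grepl("^\\[", lines)], function(x)
    data.frame(name_i = x[1], name_j = x[2], name_k = x[3],
               theta0 = as.numeric(x[5]), k_theta = as.numeric(x[6]),
               stringsAsFactors = FALSE))
  list(bonds = bonds, angles = angles)
}
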