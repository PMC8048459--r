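# Plain-text structure/trajectory formats: PDB (single- and multi-model)
# and GRO. Coordinates are Angstrom in PDB and nm in GRO; both are nm
# internally.

.pdb_atom_line <- function(serial, name, resname, chain, resid, xyz, element) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resid,
          xyz[1] * 10, xyz[2] * 10, xyz[3] * 10, element)
}

#' Write coordinates as PDB
#'
#' A \code{trajectory} is written as a multi-MODEL file; a
#' \code{molecule_geometry} (or a plain matrix with an atom table) as a
#' single model.
#'
#' @param x a \code{trajectory} or \code{molecule_geometry}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "molecule_geometry")) {
    atoms <- x$atoms
    frames <- list(x$coords)
  } else {
    atoms <- x$atoms
    frames <- lapply(seq_len(n_frames(x)), function(f) x$coords[f, , ])
  }
  chain <- if (is.null(atoms$chain)) rep("A", nrow(atoms)) else atoms$chain
  resid <- if (is.null(atoms$resid)) rep(1L, nrow(atoms)) else atoms$resid
  resname <- if (is.null(atoms$resname)) rep("UNK", nrow(atoms)) else atoms$resname
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (f in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL %8d", f), con)
    writeLines(vapply(seq_len(nrow(atoms)), function(a)
      .pdb_atom_line(a, atoms$name[a], resname[a], substr(chain[a], 1, 1),
                     resid[a], frames[[f]][a, ], atoms$element[a]), ""), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a PDB file as a trajectory
#'
#' Multi-MODEL files become multi-frame trajectories; a single model gives
#' a one-frame trajectory. Fixed-column parsing; coordinates converted from
#' Angstrom to nm.
#'
#' @param path input path.
#' @return a \code{trajectory}.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_id <- cumsum(grepl("^MODEL", lines))
  if (max(model_id) == 0L) model_id <- rep(1L, length(lines))
  atom_lines <- lines[is_atom]
  frames <- model_id[is_atom]
  if (min(frames) == 0L) frames <- frames + 1L
  parse_frame <- function(ls) {
    cbind(as.numeric(substr(ls, 31, 38)),
          as.numeric(substr(ls, 39, 46)),
          as.numeric(substr(ls, 47, 54))) / 10
  }
  first <- atom_lines[frames == frames[1]]
  name <- trimws(substr(first, 13, 16))
  element <- trimws(substr(first, 77, 78))
  element <- ifelse(nzchar(element), element, element_from_name(name))
  atoms <- data.frame(index = seq_along(name), name = name, element = element,
                      mass = element_mass(element), charge = 0,
                      chain = trimws(substr(first, 22, 22)),
                      resid = as.integer(substr(first, 23, 26)),
                      resname = trimws(substr(first, 18, 20)),
                      stringsAsFactors = FALSE)
  fr_ids <- unique(frames)
  coords <- array(0, c(length(fr_ids), nrow(atoms), 3))
  for (fi in seq_along(fr_ids)) {
    ls <- atom_lines[frames == fr_ids[fi]]
    if (length(ls) != nrow(atoms)) {
      stop("model ", fi, " has ", length(ls), " atoms, expected ", nrow(atoms))
    }
    coords[fi, , ] <- parse_frame(ls)
  }
  trajectory(coords, atoms)
}

#' Write a GRO coordinate file (single frame, nm)
#'
#' @param geom a \code{molecule_geometry} (or trajectory; frame 1 is used).
#' @param path output path.
#' @param box box lengths in nm (default 10 10 10).
#' @return \code{path}, invisibly.
#' @export
write_gro <- function(geom, path, box = c(10, 10, 10)) {
  if (inherits(geom, "trajectory")) {
    atoms <- geom$atoms; coords <- geom$coords[1, , ]
  } else {
    atoms <- geom$atoms; coords <- geom$coords
  }
  resid <- if (is.null(atoms$resid)) rep(1L, nrow(atoms)) else atoms$resid
  resname <- if (is.null(atoms$resname)) rep("UNK", nrow(atoms)) else atoms$resname
  writeLines(c(
    "generated by xlinkforge",
    sprintf("%5d", nrow(atoms)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resid, resname, atoms$name,
            seq_len(nrow(atoms)) %% 100000L,
            coords[, 1], coords[, 2], coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])
  ), path)
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' @param path input path.
#' @return a one-frame \code{trajectory} with an orthorhombic box.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  body <- lines[2 + seq_len(n)]
  name <- trimws(substr(body, 11, 15))
  element <- element_from_name(name)
  atoms <- data.frame(index = seq_len(n), name = name, element = element,
                      mass = element_mass(element), charge = 0,
                      resid = as.integer(substr(body, 1, 5)),
                      resname = trimws(substr(body, 6, 10)),
                      chain = "A", stringsAsFactors = FALSE)
  coords <- cbind(as.numeric(substr(body, 21, 28)),
                  as.numeric(substr(body, 29, 36)),
                  as.numeric(substr(body, 37, 44)))
  boxv <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])
  arr <- array(0, c(1L, n, 3L))
  arr[1, , ] <- coords
  trajectory(arr, atoms, box = diag(boxv[1:3]))
}
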