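# Multi-model PDB reading/writing, atom selection, and conversion of model
# series into in-memory trajectories.
#
# A "structure" is a tibble of atoms (one row per atom, ordered as in the
# file) with class "pdb_structure"; a multi-model file yields a list of such
# tibbles. Residue numbers are taken verbatim from the file: for the P2/FABP
# structures this package targets, the conventional FABP numbering differs by
# -1 from mutation-report numbering (the portal gatekeeper is Phe57 here),
# and no renumbering is ever performed.

atom_cols <- c("serial", "name", "element", "resname", "chain", "resid",
               "x", "y", "z", "is_hetero")

new_structure <- function(atoms, model_id = 1L) {
  out <- as_tibble(atoms)[, atom_cols]
  attr(out, "model_id") <- as.integer(model_id)
  class(out) <- c("pdb_structure", class(out))
  out
}

#' Build a structure from an atom table
#'
#' Constructs the atom-table representation used throughout the package from
#' a data frame with one row per atom. Coordinates are in Angstrom.
#'
#' @param atoms Data frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resid`, `x`, `y`, `z`, `is_hetero`.
#' @param model_id Integer model number (1 for single-model structures).
#' @return A tibble of atoms with class `pdb_structure`.
#' @export
as_structure <- function(atoms, model_id = 1L) {
  missing_cols <- setdiff(atom_cols, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("structure has zero atoms")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates in atom table")
  }
  new_structure(atoms, model_id)
}

# Fixed-column PDB fields (1-based, inclusive), per the format spec.
parse_atom_line <- function(line, lineno) {
  if (nchar(line) < 54) {
    abort(sprintf("line %d: ATOM/HETATM record too short (%d chars, need 54)",
                  lineno, nchar(line)))
  }
  serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
  name   <- trimws(substr(line, 13, 16))
  altloc <- substr(line, 17, 17)
  resname <- trimws(substr(line, 18, 20))
  chain   <- substr(line, 22, 22)
  resid   <- suppressWarnings(as.integer(substr(line, 23, 26)))
  icode   <- substr(line, 27, 27)
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (is.na(serial) || is.na(resid) || anyNA(xyz)) {
    abort(sprintf("line %d: cannot parse ATOM/HETATM fields", lineno))
  }
  if (icode != " ") {
    abort(sprintf("line %d: insertion codes are not supported", lineno))
  }
  if (!altloc %in% c(" ", "A")) return(NULL)  # keep altloc blank or "A" only
  element <- if (nchar(line) >= 78) trimws(substr(line, 77, 78)) else ""
  if (element == "") element <- guess_element(name)
  list(serial = serial, name = name, element = element, resname = resname,
       chain = chain, resid = resid, x = xyz[1], y = xyz[2], z = xyz[3])
}

# Element from atom name when columns 77-78 are absent: strip leading digits,
# take first letter (adequate for C/N/O/S/H/P protein and lipid atoms).
guess_element <- function(name) {
  stripped <- sub("^[0-9]+", "", name)
  toupper(substr(stripped, 1, 1))
}

#' Read a (multi-model) PDB file
#'
#' Parses ATOM/HETATM/MODEL/ENDMDL/TER records from standard fixed-column
#' PDB text. Files without MODEL records yield a single structure. Alternate
#' locations other than blank or "A" are dropped so each model has a single
#' deterministic conformer; insertion codes raise an error.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @return A list of `pdb_structure` tibbles, one per model, in file order.
#' @examples
#' barrel <- build_toy_barrel()
#' path <- tempfile(fileext = ".pdb")
#' write_pdb(barrel, path)
#' models <- read_pdb(path)
#' length(models)
#' @export
read_pdb <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) &&
               file.exists(source)) readLines(source) else
    unlist(strsplit(source, "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- list()
  cur_hetero <- logical()
  model_id <- NA_integer_
  n_models_seen <- 0L
  flush_model <- function() {
    if (length(cur) == 0) return(invisible(NULL))
    atoms <- dplyr::bind_rows(lapply(cur, as_tibble))
    atoms$is_hetero <- cur_hetero
    id <- if (is.na(model_id)) length(models) + 1L else model_id
    models[[length(models) + 1L]] <<- new_structure(atoms, id)
    cur <<- list(); cur_hetero <<- logical(); model_id <<- NA_integer_
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      flush_model()
      n_models_seen <- n_models_seen + 1L
      model_id <- suppressWarnings(as.integer(trimws(substr(lines[i], 7, 14))))
      if (is.na(model_id)) model_id <- n_models_seen
    } else if (r == "ENDMDL") {
      flush_model()
    } else if (r %in% c("ATOM  ", "HETATM")) {
      parsed <- parse_atom_line(lines[i], i)
      if (!is.null(parsed)) {
        cur[[length(cur) + 1L]] <- parsed
        cur_hetero[length(cur)] <- (r == "HETATM")
      }
    }
  }
  flush_model()
  if (length(models) == 0) abort("no atoms found in PDB input")
  models
}

#' Write structures as PDB text
#'
#' Serializes one or more structures to standard PDB text with `%8.3f`
#' coordinates. MODEL/ENDMDL blocks are emitted only when more than one
#' structure is given. All structures must share an identical atom topology
#' (chain, resid, atom name, in order).
#'
#' @param structures A `pdb_structure` or list of them (shared topology).
#' @param path Optional file path; if `NULL` the text is returned invisibly.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(structures, path = NULL) {
  if (inherits(structures, "pdb_structure")) structures <- list(structures)
  check_shared_topology(structures)
  multi <- length(structures) > 1
  out <- character()
  for (m in seq_along(structures)) {
    s <- structures[[m]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, format_atom_lines(s))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

format_atom_lines <- function(s) {
  rec <- ifelse(s$is_hetero, "HETATM", "ATOM  ")
  # Atom names: 1-3 char names start in column 14; 4-char names in column 13.
  name_field <- ifelse(nchar(s$name) >= 4,
                       sprintf("%-4s", substr(s$name, 1, 4)),
                       sprintf(" %-3s", s$name))
  sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, s$serial %% 100000L, name_field, s$resname, s$chain, s$resid,
          s$x, s$y, s$z, 1, 0, s$element)
}

topology_key <- function(s) paste(s$chain, s$resid, s$name, sep = "|")

check_shared_topology <- function(structures) {
  ref <- topology_key(structures[[1]])
  for (m in seq_along(structures)[-1]) {
    key <- topology_key(structures[[m]])
    if (length(key) != length(ref) || any(key != ref)) {
      first_bad <- if (length(key) != length(ref)) 1L else which(key != ref)[1]
      abort(sprintf(
        "topology mismatch in model %d (first differing atom index %d)",
        m, first_bad))
    }
  }
  invisible(TRUE)
}

#' Define an atom selection
#'
#' A selection is a reusable filter over an atom table, resolving to a
#' deterministic ordered index list via [atom_indices()]. Residue ranges are
#' inclusive on both ends.
#'
#' @param chain Optional chain id(s) to keep.
#' @param resid Optional residue numbers to keep (any integer vector; use
#'   `55:60` for an inclusive range).
#' @param name Optional atom-name set (e.g. `"CA"` for C-alpha only).
#' @param element Optional element set.
#' @param heavy If `TRUE`, exclude hydrogens.
#' @param hetero Hetero-atom (ligand/solvent) handling: `"exclude"`
#'   (default), `"include"`, or `"only"`.
#' @return An object of class `atom_selection`.
#' @examples
#' sel <- atom_selection(resid = 55:60, name = "CA")
#' @export
atom_selection <- function(chain = NULL, resid = NULL, name = NULL,
                           element = NULL, heavy = TRUE,
                           hetero = c("exclude", "include", "only")) {
  hetero <- match.arg(hetero)
  structure(list(chain = chain, resid = resid, name = name,
                 element = element, heavy = isTRUE(heavy), hetero = hetero),
            class = "atom_selection")
}

#' Resolve a selection to atom indices
#'
#' @param atoms An atom table (`pdb_structure` or trajectory topology).
#' @param selection An [atom_selection()]; `NULL` selects every atom allowed
#'   by the default selection (heavy, non-hetero).
#' @return Integer vector of row indices in atom-table order (possibly empty).
#' @export
atom_indices <- function(atoms, selection = NULL) {
  if (is.null(selection)) selection <- atom_selection()
  stopifnot(inherits(selection, "atom_selection"))
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(selection$chain))  keep <- keep & atoms$chain %in% selection$chain
  if (!is.null(selection$resid))  keep <- keep & atoms$resid %in% selection$resid
  if (!is.null(selection$name))   keep <- keep & atoms$name %in% selection$name
  if (!is.null(selection$element)) keep <- keep & atoms$element %in% selection$element
  if (selection$heavy) keep <- keep & atoms$element != "H"
  keep <- switch(selection$hetero,
                 exclude = keep & !atoms$is_hetero,
                 only    = keep & atoms$is_hetero,
                 include = keep)
  which(keep)
}

#' Filter a structure by a selection
#'
#' @inheritParams atom_indices
#' @return The filtered atom tibble (order preserved).
#' @export
select_atoms <- function(atoms, selection = NULL) {
  atoms[atom_indices(atoms, selection), , drop = FALSE]
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

#' Convert a series of models into a trajectory
#'
#' Stacks the selected atoms of each model into a fixed-topology coordinate
#' array (frames are 0-indexed throughout the package). All models must have
#' an identical selected topology.
#'
#' @param structures List of `pdb_structure` objects, in frame order.
#' @param selection Optional [atom_selection()] applied to every model.
#' @param times Optional strictly increasing frame times (ns).
#' @return A `trajectory` object: `topology` (atom tibble), `coords`
#'   (frames x atoms x 3 array, Angstrom), `times`.
#' @export
models_to_trajectory <- function(structures, selection = NULL, times = NULL) {
  if (inherits(structures, "pdb_structure")) structures <- list(structures)
  if (length(structures) < 1) abort("need at least one model")
  selected <- lapply(structures, select_atoms, selection = selection)
  if (nrow(selected[[1]]) == 0) abort("selection matches no atoms")
  check_shared_topology(selected)
  coords <- array(NA_real_, dim = c(length(selected), nrow(selected[[1]]), 3))
  for (f in seq_along(selected)) coords[f, , ] <- coords_matrix(selected[[f]])
  new_trajectory(selected[[1]], coords, times)
}

new_trajectory <- function(topology, coords, times = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == nrow(topology),
            dim(coords)[3] == 3)
  if (!is.null(times)) {
    stopifnot(length(times) == dim(coords)[1])
    if (any(diff(times) <= 0)) abort("frame times must be strictly increasing")
  }
  structure(list(topology = as_tibble(topology), coords = coords,
                 times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms\n",
              n_frames(x), nrow(x$topology)))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory as a structure
#'
#' @param traj A `trajectory`.
#' @param frame 0-indexed frame number.
#' @return A `pdb_structure` tibble.
#' @export
trajectory_frame <- function(traj, frame = 0) {
  f <- as.integer(frame) + 1L
  if (f < 1 || f > n_frames(traj)) abort("frame index out of range")
  atoms <- traj$topology
  atoms$x <- traj$coords[f, , 1]
  atoms$y <- traj$coords[f, , 2]
  atoms$z <- traj$coords[f, , 3]
  new_structure(atoms, f)
}

#' Convert a trajectory back to a list of structures
#'
#' @param traj A `trajectory`.
#' @return List of `pdb_structure` tibbles, one per frame.
#' @export
trajectory_to_models <- function(traj) {
  lapply(seq_len(n_frames(traj)) - 1L, trajectory_frame, traj = traj)
}
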