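#' Construct a StructureModel
#'
#' A \code{StructureModel} holds the atoms of one conformation: a data frame
#' with columns \code{chain}, \code{resno} (integer), \code{insert}
#' (insertion code, "" if none), \code{resid} (3-letter residue name),
#' \code{elety} (atom name) and coordinates \code{x,y,z} in Angstrom.
#'
#' @param atoms data frame with the columns above.
#' @param model integer model id (default 1).
#' @return object of class \code{StructureModel}.
#' @export
structure_model <- function(atoms, model = 1L) {
  need <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("structure_model(): missing columns: ",
                         paste(miss, collapse = ", "))
  atoms$insert[is.na(atoms$insert)] <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key)) {
    stop("structure_model(): duplicate (chain, residue, atom) records")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("structure_model(): non-finite coordinates")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model = as.integer(model)),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s), model", x$model, "\n")
  invisible(x)
}

#' Coordinates of a StructureModel as a matrix
#' @param model a \code{StructureModel}.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# replace coordinates, keeping atom records
#' @keywords internal
set_coords <- function(model, xyz) {
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

#' Read a structure from a PDB file
#'
#' Reads ATOM records of one model from a (possibly multi-model) PDB file.
#' HETATM records and waters are excluded; for alternate locations the first
#' listed altloc of each atom is kept and occupancies are ignored. Residue
#' numbering and insertion codes are taken verbatim from the file.
#'
#' @param path PDB file path.
#' @param model_index 0-based model index into multi-model files (default 0,
#'   the first MODEL block).
#' @return a \code{StructureModel}.
#' @export
read_structure <- function(path, model_index = 0L) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("read_structure(): cannot parse '",
                                           path, "': ", conditionMessage(e)))
  nmod <- nrow(pdb$xyz)
  if (model_index < 0L || model_index >= nmod) {
    stop("read_structure(): model_index ", model_index,
         " out of range (file has ", nmod, " model(s))")
  }
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (!any(keep)) stop("read_structure(): no protein ATOM records in '", path, "'")
  xyz <- matrix(pdb$xyz[model_index + 1L, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at <- at[keep, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  # first listed altloc per atom wins
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]
  structure_model(at[, c("chain", "resno", "insert", "resid", "elety",
                         "x", "y", "z")],
                  model = model_index + 1L)
}

#' Write a StructureModel (or Trajectory) to a PDB file
#'
#' Fixed-width PDB writer; trajectories are written as multi-model files
#' (MODEL/ENDMDL blocks sharing one topology).
#'
#' @param x a \code{StructureModel} or \code{Trajectory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(x, path) {
  fmt_atom <- function(i, a, xyz) {
    name <- a$elety[i]
    name <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
            i, name, a$resid[i], substr(a$chain[i], 1, 1), a$resno[i],
            ifelse(a$insert[i] == "", " ", a$insert[i]),
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0)
  }
  con <- file(path, "w"); on.exit(close(con))
  if (inherits(x, "Trajectory")) {
    a <- x$atoms
    for (f in seq_len(nframes(x))) {
      writeLines(sprintf("MODEL     %4d", f), con)
      xyz <- matrix(x$xyz[f, ], ncol = 3, byrow = TRUE)
      writeLines(vapply(seq_len(nrow(a)), fmt_atom, "", a = a, xyz = xyz), con)
      writeLines("ENDMDL", con)
    }
  } else {
    a <- x$atoms
    writeLines(vapply(seq_len(nrow(a)), fmt_atom, "", a = a,
                      xyz = coords(x)), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Construct a Trajectory
#'
#' A \code{Trajectory} is an ordered sequence of conformations sharing one
#' topology: the atom records of the first frame plus an
#' \code{nframes x (3 * natoms)} coordinate matrix (rows are frames, columns
#' x1,y1,z1,x2,...).
#'
#' @param models list of \code{StructureModel}s with identical atom ordering,
#'   or a single template model plus \code{xyz}.
#' @param xyz optional coordinate matrix when \code{models} is one template.
#' @return object of class \code{Trajectory}.
#' @export
trajectory <- function(models, xyz = NULL) {
  if (inherits(models, "StructureModel")) {
    stopifnot(!is.null(xyz))
    if (ncol(xyz) != 3L * nrow(models$atoms)) {
      stop("trajectory(): xyz width does not match atom count")
    }
    return(structure(list(atoms = models$atoms, xyz = as.matrix(xyz)),
                     class = "Trajectory"))
  }
  ref <- models[[1]]$atoms
  key0 <- paste(ref$chain, ref$resno, ref$insert, ref$elety)
  xyz <- matrix(NA_real_, length(models), 3L * nrow(ref))
  for (i in seq_along(models)) {
    a <- models[[i]]$atoms
    if (nrow(a) != nrow(ref) ||
        !identical(paste(a$chain, a$resno, a$insert, a$elety), key0)) {
      stop("trajectory(): frame ", i, " does not share the topology of frame 1")
    }
    xyz[i, ] <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  }
  structure(list(atoms = ref, xyz = xyz), class = "Trajectory")
}

#' Number of frames in a Trajectory
#' @param traj a \code{Trajectory}.
#' @export
nframes <- function(traj) nrow(traj$xyz)

#' Extract one frame of a Trajectory as a StructureModel
#' @param traj a \code{Trajectory}.
#' @param i frame index (1-based).
#' @export
frame <- function(traj, i) {
  if (i < 1L || i > nframes(traj)) stop("frame(): index out of range")
  xyz <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
  m <- structure(list(atoms = traj$atoms, model = as.integer(i)),
                 class = "StructureModel")
  set_coords(m, xyz)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", nframes(x), "frames x", nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Read a trajectory
#'
#' Supported inputs: a multi-model PDB used as both topology and coordinates,
#' or a topology PDB plus a DCD coordinate file. Frames are returned in file
#' order; the coordinate atom count must match the topology.
#'
#' @param topology PDB file defining the atom records.
#' @param coords coordinate file (defaults to \code{topology}); multi-model
#'   PDB or \code{.dcd}.
#' @return a \code{Trajectory}.
#' @export
read_trajectory <- function(topology, coords = topology) {
  top <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE)
  keep <- which(top$atom$type == "ATOM")
  model0 <- read_structure(topology, 0L)
  nat <- nrow(model0$atoms)
  if (grepl("\\.dcd$", coords, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(coords, verbose = FALSE)
    if (ncol(xyz) != 3L * nrow(top$atom)) {
      stop("read_trajectory(): atom-count mismatch between topology (",
           nrow(top$atom), ") and DCD (", ncol(xyz) / 3, ")")
    }
    idx <- as.numeric(t(outer(keep - 1L, 1:3, function(a, b) 3L * a + b)))
    xyz <- xyz[, idx, drop = FALSE]
  } else {
    crd <- bio3d::read.pdb(coords, multi = TRUE, verbose = FALSE)
    ckeep <- which(crd$atom$type == "ATOM")
    if (length(ckeep) != length(keep)) {
      stop("read_trajectory(): atom-count mismatch between topology (",
           length(keep), ") and coordinates (", length(ckeep), ")")
    }
    idx <- as.numeric(t(outer(ckeep - 1L, 1:3, function(a, b) 3L * a + b)))
    xyz <- crd$xyz[, idx, drop = FALSE]
  }
  if (any(!is.finite(xyz))) stop("read_trajectory(): truncated frame (non-finite coordinates)")
  # honor the first-altloc filter of read_structure on the topology
  if (nat != length(keep)) {
    at <- top$atom[keep, ]
    at$insert[is.na(at$insert)] <- ""
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    sel <- which(!duplicated(key))
    idx <- as.numeric(t(outer(sel - 1L, 1:3, function(a, b) 3L * a + b)))
    xyz <- xyz[, idx, drop = FALSE]
  }
  trajectory(model0, xyz = xyz)
}
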