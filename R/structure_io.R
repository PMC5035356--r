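#' @useDynLib fluctB, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd cor var setNames
#' @importFrom utils write.table head tail
NULL

# Light pre-scan so malformed fixed-width records are reported with their
# line number before the parser sees them.
validate_pdb_lines <- function(lines, path) {
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0L) stop("no ATOM/HETATM records in ", path)
  for (i in rec) {
    l <- lines[i]
    if (nchar(l) < 54) {
      stop(sprintf("malformed ATOM/HETATM record at line %d of %s (too short)",
                   i, path))
    }
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (any(is.na(xyz)) || any(!is.finite(xyz))) {
      stop(sprintf("malformed coordinates at line %d of %s", i, path))
    }
    if (trimws(substr(l, 13, 16)) == "") {
      stop(sprintf("empty atom name at line %d of %s", i, path))
    }
  }
  invisible(TRUE)
}

structure_from_bio3d <- function(pdb, source_id, altloc_keep) {
  a <- pdb$atom
  alt <- a$alt
  alt[is.na(alt)] <- ""
  keep <- alt %in% altloc_keep
  a <- a[keep, , drop = FALSE]
  b <- a$b
  b[is.na(b)] <- 0
  o <- a$o
  o[is.na(o)] <- 1
  chain <- a$chain
  chain[is.na(chain)] <- ""
  ele <- a$elesy
  ele[is.na(ele)] <- ""
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    resname = trimws(a$resid),
    chain = chain,
    resid = a$resno,
    x = a$x, y = a$y, z = a$z,
    occupancy = o,
    bfactor = b,
    element = trimws(ele),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(atoms$bfactor < 0)) stop("negative B-factor in ", source_id)
  structure(list(atoms = atoms, source_id = source_id,
                 keep = which(keep)),
            class = "md_structure")
}

#' Read a PDB file (first model)
#'
#' Fixed-column parse of ATOM/HETATM records; B-factors come from columns
#' 61-66 and occupancies from 55-60.  Records whose altloc indicator is
#' neither blank nor `'A'` are dropped.  Only the first MODEL of a
#' multi-model file is returned; use [read_multimodel_pdb()] for all frames.
#'
#' @param path PDB file path.
#' @return An object of class `md_structure`: list with `atoms` (a data frame
#'   with columns serial, name, resname, chain, resid, x, y, z, occupancy,
#'   bfactor, element, het) and `source_id`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  structure_from_bio3d(pdb, basename(path), altloc_keep = c("", "A"))
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure '%s': %d atoms (%d HETATM), %d residues\n",
              x$source_id, nrow(x$atoms), sum(x$atoms$het),
              length(unique(paste(x$atoms$chain, x$atoms$resid)))))
  invisible(x)
}

#' Read a multi-model PDB trajectory
#'
#' Every MODEL/ENDMDL block must contain the same atoms in the same order;
#' a mismatch is an error naming the offending model index.  Atom metadata is
#' taken from the first model.
#'
#' @param path multi-model PDB path.
#' @return List with `coords` (frames x atoms x 3 array, A) and `structure`
#'   (an `md_structure` from the first model).
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(m) {
      blk <- lines[bounds[m]:(bounds[m + 1L] - 1L)]
      blk <- blk[seq_len(match(TRUE, grepl("^ENDMDL", blk), nomatch = length(blk)))]
      sum(grepl("^(ATOM  |HETATM)", blk))
    }, integer(1L))
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1L])[1L]
      stop(sprintf("model %d has %d atoms; model 1 has %d", bad, counts[bad],
                   counts[1L]))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  struct <- structure_from_bio3d(pdb, basename(path), altloc_keep = c("", "A"))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_all <- ncol(xyz) / 3L
  nf <- nrow(xyz)
  coords <- aperm(array(t(xyz), dim = c(3L, n_all, nf)), c(3L, 2L, 1L))
  coords <- coords[, struct$keep, , drop = FALSE]
  if (any(!is.finite(coords))) stop("non-finite coordinates in ", path)
  list(coords = coords, structure = struct)
}

format_pdb_name <- function(name, element) {
  # Standard convention: names shorter than 4 chars start in column 14
  ifelse(nchar(name) >= 4L, substr(name, 1, 4),
         sprintf(" %-3s", name))
}

pdb_atom_line <- function(atoms, x, y, z) {
  rectype <- ifelse(atoms$het, "HETATM", "ATOM  ")
  sprintf("%s%5d %s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, atoms$serial %% 100000L,
          format_pdb_name(atoms$name, atoms$element), "",
          substr(atoms$resname, 1, 4), substr(atoms$chain, 1, 1),
          atoms$resid %% 10000L, "",
          x, y, z, atoms$occupancy, atoms$bfactor, atoms$element)
}

#' Write a structure as a single-model PDB file
#'
#' Coordinates are written at 3 decimals and occupancy/B-factor at 2, the
#' fixed-column PDB precision.
#'
#' @param structure an `md_structure`.
#' @param path output path.
#' @param coords optional n x 3 matrix overriding the structure's own
#'   coordinates.
#' @param bfactor optional replacement B-factor vector.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path, coords = NULL, bfactor = NULL) {
  a <- structure$atoms
  if (!is.null(bfactor)) {
    stopifnot(length(bfactor) == nrow(a))
    a$bfactor <- bfactor
  }
  if (is.null(coords)) {
    coords <- cbind(a$x, a$y, a$z)
  }
  stopifnot(nrow(coords) == nrow(a))
  lines <- c(pdb_atom_line(a, coords[, 1], coords[, 2], coords[, 3]), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param frames frames x atoms x 3 array in A.
#' @param structure `md_structure` giving the atom table.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(frames, structure, path) {
  a <- structure$atoms
  stopifnot(length(dim(frames)) == 3L, dim(frames)[2L] == nrow(a))
  out <- vector("list", dim(frames)[1L])
  for (f in seq_len(dim(frames)[1L])) {
    out[[f]] <- c(sprintf("MODEL     %4d", f),
                  pdb_atom_line(a, frames[f, , 1], frames[f, , 2],
                                frames[f, , 3]),
                  "ENDMDL")
  }
  writeLines(c(unlist(out), "END"), path)
  invisible(path)
}

#' Write a trajectory in XYZ format
#'
#' Each frame is a block: atom-count line, a comment line carrying
#' `frame_time_fs=<float>`, then one `element x y z` line per atom with
#' 6-decimal coordinates.
#'
#' @param frames frames x atoms x 3 array, A.
#' @param elements character vector of element symbols, one per atom.
#' @param path output path.
#' @param frame_times_fs numeric vector of frame times; defaults to
#'   `0, 1, 2, ...`.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(frames, elements, path,
                      frame_times_fs = seq_len(dim(frames)[1L]) - 1) {
  n <- dim(frames)[2L]
  stopifnot(length(elements) == n,
            length(frame_times_fs) == dim(frames)[1L])
  out <- vector("list", dim(frames)[1L])
  for (f in seq_len(dim(frames)[1L])) {
    out[[f]] <- c(sprintf("%d", n),
                  sprintf("frame_time_fs=%g", frame_times_fs[f]),
                  sprintf("%-2s %13.6f %13.6f %13.6f", elements,
                          frames[f, , 1], frames[f, , 2], frames[f, , 3]))
  }
  writeLines(unlist(out), path)
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file path (dialect of [write_xyz()]).
#' @return List with `coords` (frames x atoms x 3), `elements`, and
#'   `frame_times_fs`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(); elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("bad atom-count line %d in %s", i, path))
    tm <- regmatches(lines[i + 1L],
                     regexec("frame_time_fs=([-0-9.eE+]+)", lines[i + 1L]))[[1L]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2L]) else NA_real_)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    ele <- vapply(parts, `[[`, character(1L), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3L)))
    if (any(!is.finite(xyz))) stop("non-finite coordinate near line ", i)
    if (is.null(elements)) elements <- ele
    else if (!identical(elements, ele)) stop("atom order changes at line ", i)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  coords <- aperm(simplify2array(frames), c(3L, 1L, 2L))
  list(coords = coords, elements = elements, frame_times_fs = times)
}

#' Define an atom-name selection
#'
#' Built-in labels follow the conventions of backbone/side-chain B-factor
#' work: `"CA"` selects alpha carbons; `"CG"` selects atoms named CG or CG2
#' (note CG1 of Ile/Val is deliberately not included).
#'
#' @param label `"CA"`, `"CG"`, or `"custom"`.
#' @param names character vector of stripped atom names (required for
#'   `"custom"`, ignored otherwise).
#' @return Object of class `atom_selection`.
#' @export
atom_selection <- function(label = c("CA", "CG", "custom"), names = NULL) {
  label <- match.arg(label)
  name_set <- switch(label,
    CA = "CA",
    CG = c("CG", "CG2"),
    custom = {
      if (is.null(names) || length(names) == 0L) {
        stop("custom selection requires a non-empty name set")
      }
      unique(trimws(names))
    })
  structure(list(name_set = name_set, label = label), class = "atom_selection")
}

#' Resolve a selection against a structure
#'
#' @param structure an `md_structure`.
#' @param selection an [atom_selection()], a label string, or a character
#'   vector of atom names.
#' @param include_het include HETATM records (default FALSE).
#' @param min_atoms minimum number of matched atoms; use 3 when the indices
#'   will feed a rigid-body fit.
#' @return Strictly increasing integer vector of atom indices (row numbers of
#'   `structure$atoms`).
#' @export
select_atoms <- function(structure, selection, include_het = FALSE,
                         min_atoms = 1L) {
  if (is.character(selection)) {
    selection <- if (length(selection) == 1L && selection %in% c("CA", "CG")) {
      atom_selection(selection)
    } else {
      atom_selection("custom", names = selection)
    }
  }
  stopifnot(inherits(selection, "atom_selection"))
  a <- structure$atoms
  idx <- which(a$name %in% selection$name_set & (include_het | !a$het))
  if (length(idx) == 0L) {
    stop(sprintf("selection '%s' matches no atoms", selection$label))
  }
  if (length(idx) < min_atoms) {
    stop(sprintf("selection '%s' matches %d atoms; %d required",
                 selection$label, length(idx), min_atoms))
  }
  idx
}

#' Bundle replicate trajectories into an ensemble
#'
#' @param trajectories list of frames x atoms x 3 arrays sharing one atom
#'   count and order.
#' @param atom_table `md_structure` describing the shared atoms.
#' @param seeds integer seed per trajectory.
#' @param save_interval_steps saving cadence in integrator steps.
#' @param nominal_timestep integrator timestep in fs (nominal clock).
#' @return Object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(trajectories, atom_table, seeds,
                                save_interval_steps = 1000L,
                                nominal_timestep = 1.0) {
  stopifnot(length(trajectories) >= 1L,
            length(seeds) == length(trajectories))
  n <- nrow(atom_table$atoms)
  for (k in seq_along(trajectories)) {
    d <- dim(trajectories[[k]])
    if (length(d) != 3L || d[2L] != n || d[3L] != 3L) {
      stop(sprintf("trajectory %d does not match the %d-atom table", k, n))
    }
    if (any(!is.finite(trajectories[[k]]))) {
      stop(sprintf("non-finite frame in trajectory %d", k))
    }
  }
  if (anyDuplicated(seeds)) warning("duplicate seeds in ensemble")
  structure(list(trajectories = trajectories, atom_table = atom_table,
                 seeds = as.integer(seeds),
                 save_interval_steps = as.integer(save_interval_steps),
                 nominal_timestep = nominal_timestep),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$trajectories, function(t) dim(t)[1L], integer(1L))
  cat(sprintf(
    "trajectory_ensemble: %d trajectories x %d atoms, %s frames each\n",
    length(x$trajectories), nrow(x$atom_table$atoms),
    if (length(unique(nf)) == 1L) nf[1L] else paste(range(nf), collapse = "-")))
  cat(sprintf("  save cadence %d steps at dt = %g fs (nominal)\n",
              x$save_interval_steps, x$nominal_timestep))
  invisible(x)
}
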