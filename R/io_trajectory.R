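## Multi-frame trajectory container and its two text carriers: multi-model PDB
## and a simple XYZ dialect whose comment line holds the frame time and whose
## atom-name token encodes "resname.resnum.atom" (optionally
## "chain.resname.resnum.atom") so molecule identity survives the round trip.

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "HSD", "HSE", "HSP")

#' Build a trajectory object
#'
#' A `Trajectory` is a fixed atom roster observed over frames: a
#' `n_frames x n_atoms x 3` coordinate array (Angstrom), an atom table with
#' the molecule id and molecule class of every atom, and the frame spacing in
#' nanoseconds. Frame indices are 0-based in all event bookkeeping.
#'
#' @param coords numeric array `n_frames x n_atoms x 3`.
#' @param atoms data.frame with columns `chain`, `resnum`, `icode`, `resname`,
#'   `atom`, `mol_id`, `mol_class`.
#' @param timestep_ns frame spacing in ns (> 0).
#' @param times optional per-frame times in ns (default `(0:(F-1)) * timestep`).
#' @return an object of class `Trajectory`.
#' @export
trajectory <- function(coords, atoms, timestep_ns, times = NULL) {
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L)
    ltk_stop("ltk_bad_trajectory", "coords must be n_frames x n_atoms x 3")
  if (d[1] < 1L)
    ltk_stop("ltk_bad_trajectory", "trajectory needs >= 1 frame")
  if (!is.numeric(timestep_ns) || timestep_ns <= 0)
    ltk_stop("ltk_bad_timestep", "timestep must be > 0 ns")
  if (nrow(atoms) != d[2])
    ltk_stop("ltk_bad_trajectory", "atom table (%d) != roster size (%d)",
             nrow(atoms), d[2])
  rownames(atoms) <- NULL
  structure(list(coords = coords, atoms = atoms,
                 timestep_ns = as.numeric(timestep_ns),
                 times = times %||% ((seq_len(d[1]) - 1) * timestep_ns)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d frames x %d atoms, dt = %g ns, classes: %s\n",
    n_frames(x), nrow(x$atoms), x$timestep_ns,
    paste(names(table(x$atoms$mol_class)), collapse = ", ")))
  invisible(x)
}

#' Number of frames of a trajectory
#' @param traj a `Trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Default molecule-class assignment rules
#'
#' Maps residue names to molecule classes: standard amino acids to
#' `"protein"`, common water names to `"water"`, and any user-supplied
#' residue-name to class pairs (e.g. `c(TAG = "DHA-TAG", LPC = "PC")`).
#'
#' @param ... named residue-name = class pairs.
#' @param .default fallback class for unknown residue names; if `NA`
#'   (default), unknown names are an error.
#' @return named character vector with attribute `default`.
#' @export
molecule_map <- function(..., .default = NA_character_) {
  extra <- c(...)
  base <- c(stats::setNames(rep("protein", length(AMINO_ACIDS)), AMINO_ACIDS),
            stats::setNames(rep("water", length(WATER_RESNAMES)),
                            WATER_RESNAMES))
  m <- c(extra, base[setdiff(names(base), names(extra))])
  attr(m, "default") <- .default
  m
}

assign_molecules <- function(atoms, map) {
  cls <- unname(map[atoms$resname])
  if (any(is.na(cls))) {
    dflt <- attr(map, "default")
    if (is.na(dflt))
      ltk_stop("ltk_unknown_resname",
               "no molecule class for residue name '%s' and no fallback",
               atoms$resname[is.na(cls)][1])
    cls[is.na(cls)] <- dflt
  }
  atoms$mol_class <- cls
  atoms$mol_id <- ifelse(
    cls == "protein", paste0("protein:", atoms$chain),
    paste0(cls, ":", atoms$chain, ":", atoms$resnum, atoms$icode))
  atoms
}

#' Read a multi-frame trajectory
#'
#' Reads a multi-model PDB (`MODEL`/`ENDMDL` blocks) or the package's XYZ
#' dialect, checked to have an identical atom roster in every frame, and
#' assigns molecule classes from `map`.
#'
#' @param path trajectory file; format from extension (`.xyz` else PDB)
#'   unless `format` is given.
#' @param map a [molecule_map()].
#' @param timestep_ns frame spacing in ns; for XYZ, inferred from the comment
#'   lines (`t= <ns> ns`) when absent.
#' @param format `"pdb"`, `"xyz"` or `NULL` (auto).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, map = molecule_map(), timestep_ns = NULL,
                            format = NULL) {
  if (!file.exists(path))
    ltk_stop("ltk_missing_file", "file not found: %s", path)
  fmt <- format %||%
    (if (tolower(tools::file_ext(path)) == "xyz") "xyz" else "pdb")
  if (fmt == "xyz") read_trajectory_xyz(path, map, timestep_ns)
  else read_trajectory_pdb(path, map, timestep_ns %||% 1)
}

read_trajectory_pdb <- function(path, map, timestep_ns) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  starts <- which(rec == "MODEL ")
  if (!length(starts)) starts <- 1L
  ends <- c(starts[-1] - 1L, length(lines))
  frames <- lapply(seq_along(starts), function(i) {
    parse_pdb_atoms(lines[starts[i]:ends[i]], path)
  })
  frames <- frames[!vapply(frames, is.null, logical(1))]
  if (!length(frames)) ltk_stop("ltk_no_atoms", "no ATOM records in %s", path)
  roster <- frames[[1]][c("chain", "resnum", "icode", "resname", "atom")]
  key0 <- do.call(paste, roster)
  coords <- array(NA_real_, c(length(frames), nrow(roster), 3))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (nrow(f) != nrow(roster) ||
        !identical(do.call(paste, f[names(roster)]), key0))
      ltk_stop("ltk_frame_mismatch",
               "frame %d atom roster differs from frame 1", i)
    coords[i, , ] <- as.matrix(f[c("x", "y", "z")])
  }
  trajectory(coords, assign_molecules(roster, map), timestep_ns)
}

read_trajectory_xyz <- function(path, map, timestep_ns) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; frames <- list(); names_list <- list(); times <- numeric()
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      ltk_stop("ltk_bad_trajectory", "bad atom count line %d in %s", i, path)
    if (i + 1L + nat > length(lines))
      ltk_stop("ltk_frame_mismatch", "truncated frame at line %d in %s", i, path)
    tm <- regmatches(lines[i + 1L],
                     regexec("t\\s*=\\s*([-0-9.eE+]+)", lines[i + 1L]))[[1]]
    times <- c(times, if (length(tm)) as.numeric(tm[2]) else NA_real_)
    body <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(tok) < 4L))
      ltk_stop("ltk_bad_coordinate", "bad XYZ atom line in %s", path)
    nm <- vapply(tok, `[`, character(1), 1L)
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(tok, `[`, 2:4)))), ncol = 3, byrow = TRUE)
    if (any(is.na(xyz)))
      ltk_stop("ltk_bad_coordinate", "unparseable XYZ coordinate in %s", path)
    frames[[length(frames) + 1L]] <- xyz
    names_list[[length(names_list) + 1L]] <- nm
    i <- i + 2L + nat
  }
  if (!length(frames)) ltk_stop("ltk_no_atoms", "no frames in %s", path)
  n0 <- names_list[[1]]
  for (k in seq_along(frames))
    if (!identical(names_list[[k]], n0))
      ltk_stop("ltk_frame_mismatch",
               "frame %d atom roster differs from frame 1", k)
  atoms <- parse_xyz_names(n0)
  coords <- array(NA_real_, c(length(frames), length(n0), 3))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  dt <- timestep_ns %||%
    (if (length(times) > 1 && !any(is.na(times))) diff(times)[1] else 1)
  if (!is.numeric(dt) || is.na(dt) || dt <= 0) dt <- 1
  trajectory(coords, assign_molecules(atoms, map), dt,
             times = if (!any(is.na(times))) times else NULL)
}

## "A.SER.146.OG" or "SER.146.OG" or bare "CA"
parse_xyz_names <- function(nm) {
  parts <- strsplit(nm, ".", fixed = TRUE)
  mk <- function(p, idx) {
    if (length(p) >= 4L)
      c(p[1], p[3], "", p[2], p[4])
    else if (length(p) == 3L)
      c("A", p[2], "", p[1], p[3])
    else c("A", as.character(idx), "", p[1], p[1])
  }
  m <- t(mapply(mk, parts, seq_along(parts)))
  data.frame(chain = m[, 1], resnum = as.integer(m[, 2]), icode = m[, 3],
             resname = m[, 4], atom = m[, 5], stringsAsFactors = FALSE)
}

#' Write a trajectory
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format `"xyz"` (default) or `"pdb"` (multi-model).
#' @param digits coordinate decimals (default 3, PDB precision).
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "pdb"),
                             digits = 3) {
  format <- match.arg(format)
  a <- traj$atoms
  nf <- n_frames(traj)
  con <- file(path, "w"); on.exit(close(con))
  if (format == "xyz") {
    nm <- paste(a$chain, a$resname, a$resnum, a$atom, sep = ".")
    for (f in seq_len(nf)) {
      writeLines(c(sprintf("%d", nrow(a)),
                   sprintf("t= %.6f ns", traj$times[f])), con)
      writeLines(sprintf(paste0("%s %.", digits, "f %.", digits, "f %.",
                                digits, "f"),
                         nm, traj$coords[f, , 1], traj$coords[f, , 2],
                         traj$coords[f, , 3]), con)
    }
  } else {
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL %8d", f), con)
      fa <- a
      fa$x <- traj$coords[f, , 1]; fa$y <- traj$coords[f, , 2]
      fa$z <- traj$coords[f, , 3]
      fa$het <- !(fa$resname %in% AMINO_ACIDS)
      writeLines(vapply(seq_len(nrow(fa)), format_pdb_atom, character(1),
                        a = fa), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

## atom indices of one molecule / of a set of classes
mol_atom_idx <- function(traj, mol_id) {
  idx <- which(traj$atoms$mol_id == mol_id)
  if (!length(idx))
    ltk_stop("ltk_unknown_molecule", "unknown molecule id '%s'", mol_id)
  idx
}

class_atom_idx <- function(traj, cls) {
  idx <- which(traj$atoms$mol_class == cls)
  if (!length(idx))
    ltk_stop("ltk_unknown_class", "no molecules of class '%s'", cls)
  idx
}

## per-frame centroid (F x 3) of a set of atom indices
frame_centroid <- function(traj, idx) {
  out <- matrix(NA_real_, n_frames(traj), 3)
  for (k in 1:3) {
    m <- traj$coords[, idx, k, drop = FALSE]
    dim(m) <- c(n_frames(traj), length(idx))
    out[, k] <- rowMeans(m)
  }
  out
}
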