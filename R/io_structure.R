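## PDB structure reading/writing. Only ATOM/HETATM/MODEL/ENDMDL records are
## interpreted; the residue identity key is (chain, resnum, insertion code)
## in author numbering, never renumbered.

WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "DOD")

#' Create a structure model from an atom table
#'
#' A `StructureModel` holds the atoms of one protein model: chain id, author
#' residue number, insertion code, 3-letter residue name, atom name, Cartesian
#' coordinates in Angstrom, and whether the record was a HETATM.
#'
#' @param atoms data.frame with columns `chain`, `resnum`, `icode`, `resname`,
#'   `atom`, `x`, `y`, `z`, `het`.
#' @param model_id model identifier (integer, default 1).
#' @return an object of class `StructureModel`.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  need <- c("chain", "resnum", "icode", "resname", "atom", "x", "y", "z", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    ltk_stop("ltk_missing_column", "atom table lacks column(s): %s",
             paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    ltk_stop("ltk_bad_coordinate", "non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$atom, sep = "|")
  if (anyDuplicated(key))
    ltk_stop("ltk_duplicate_atom",
             "duplicate (chain, residue, atom) key: %s", key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id)),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel: %d atoms, %d residues, model %d\n",
              nrow(x$atoms), length(unique(residue_keys(x))), x$model_id))
  invisible(x)
}

#' Residue keys of a structure model
#'
#' @param model a `StructureModel`.
#' @return character vector "chain:resnum[icode]:resname", one per atom.
#' @export
residue_keys <- function(model) {
  a <- model$atoms
  paste0(a$chain, ":", a$resnum, a$icode, ":", a$resname)
}

parse_pdb_atoms <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  sel <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[sel]
  if (!length(lines)) return(NULL)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v)))
      ltk_stop("ltk_bad_coordinate",
               "unparseable %s field in %s (e.g. '%s')", what, path,
               trimws(s[is.na(v)][1]))
    v
  }
  data.frame(
    chain   = substr(lines, 22, 22),
    resnum  = as.integer(num(substr(lines, 23, 26), "residue number")),
    icode   = trimws(substr(lines, 27, 27)),
    resname = trimws(substr(lines, 18, 20)),
    atom    = trimws(substr(lines, 13, 16)),
    x       = num(substr(lines, 31, 38), "coordinate"),
    y       = num(substr(lines, 39, 46), "coordinate"),
    z       = num(substr(lines, 47, 54), "coordinate"),
    het     = substr(lines, 1, 6) == "HETATM",
    stringsAsFactors = FALSE)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records of the first model. With
#' `strip_het = TRUE` all HETATM records and water residues are dropped, the
#' usual pre-treatment before docking-box construction.
#'
#' @param path PDB file.
#' @param strip_het drop HETATM and water records (default TRUE).
#' @return a [structure_model()].
#' @export
read_structure <- function(path, strip_het = TRUE) {
  if (!file.exists(path))
    ltk_stop("ltk_missing_file", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  endm <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  atoms <- parse_pdb_atoms(lines, path)
  if (is.null(atoms) || !any(!atoms$het))
    ltk_stop("ltk_no_atoms", "no ATOM records in %s", path)
  if (strip_het)
    atoms <- atoms[!atoms$het & !(atoms$resname %in% WATER_RESNAMES), ,
                   drop = FALSE]
  structure_model(atoms)
}

format_pdb_atom <- function(i, a) {
  sprintf("%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
          if (a$het[i]) "HETATM" else "ATOM", i %% 100000L,
          substr(a$atom[i], 1, 4), substr(a$resname[i], 1, 3),
          a$chain[i], a$resnum[i],
          if (nzchar(a$icode[i])) a$icode[i] else " ",
          a$x[i], a$y[i], a$z[i])
}

#' Write a structure model to a PDB file
#'
#' @param model a `StructureModel`.
#' @param path output file.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  out <- vapply(seq_len(nrow(a)), format_pdb_atom, character(1), a = a)
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Extract coordinates of one residue (optionally one atom) of a model
#'
#' @param model a `StructureModel`.
#' @param key residue key "chain:resnum[icode]:resname" (resname optional).
#' @param atom atom name, or NULL for all atoms of the residue.
#' @return numeric matrix n x 3.
#' @export
residue_coords <- function(model, key, atom = NULL) {
  k <- parse_residue_key(key)
  a <- model$atoms
  sel <- a$chain == k$chain & a$resnum == k$resnum & a$icode == k$icode
  if (!is.na(k$resname)) sel <- sel & a$resname == k$resname
  if (!is.null(atom)) sel <- sel & a$atom == atom
  if (!any(sel))
    ltk_stop("ltk_missing_residue", "no atoms match residue '%s'%s", key,
             if (is.null(atom)) "" else sprintf(" atom '%s'", atom))
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}

## "A:146:SER" / "A:146A:SER" / "A:146" -> chain, resnum, icode, resname
parse_residue_key <- function(key) {
  if (is.list(key)) return(key)
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2)
    ltk_stop("ltk_bad_residue_key", "bad residue key '%s'", key)
  m <- regmatches(parts[2], regexec("^([0-9]+)([A-Za-z]?)$", parts[2]))[[1]]
  if (!length(m))
    ltk_stop("ltk_bad_residue_key", "bad residue number in key '%s'", key)
  list(chain = parts[1], resnum = as.integer(m[2]), icode = m[3],
       resname = if (length(parts) >= 3) parts[3] else NA_character_)
}
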