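## Structure-based triage of docking results for serine hydrolases.
##
## The docking search volume is a cube centred on the geometric centre of the
## catalytic triad (Ser-His-Asp/Glu). Triage is two-stage: a loose prefilter
## (catalytic distance < 8 A, strictly negative affinity) followed by a dual
## cutoff on the focus ligands (affinity <= -5 kcal/mol AND distance <= 4 A,
## both inclusive). The prefilter uses strict inequalities, the main screen
## inclusive ones, matching how each criterion is conventionally printed.

#' Specify a catalytic triad
#'
#' @param ser,his,acid residue keys "chain:resnum:resname" for the
#'   nucleophilic serine, the histidine and the aspartate/glutamate.
#' @param nucleophile name of the nucleophile atom on the serine
#'   (default "OG", the Ser O-gamma).
#' @return an object of class `TriadSpec`.
#' @export
triad_spec <- function(ser, his, acid, nucleophile = "OG") {
  structure(list(ser = ser, his = his, acid = acid,
                 nucleophile = nucleophile),
            class = "TriadSpec")
}

triad_atoms <- function(model, triad) {
  do.call(rbind, lapply(list(triad$ser, triad$his, triad$acid),
                        function(k) residue_coords(model, k)))
}

#' Geometric centre of the catalytic triad
#'
#' Unweighted mean of the coordinates of every atom belonging to the three
#' triad residues; the point the docking box is centred on.
#'
#' @param model a [structure_model()].
#' @param triad a [triad_spec()].
#' @return numeric length-3 point in Angstrom.
#' @export
triad_center <- function(model, triad) {
  ## validates the nucleophile atom exists even though it has weight equal
  ## to the other Ser atoms in the mean
  residue_coords(model, triad$ser, atom = triad$nucleophile)
  colMeans(triad_atoms(model, triad))
}

#' Cubic docking grid box
#'
#' @param center box centre (Angstrom).
#' @param edge edge length in Angstrom; default 22.5, large enough to hold a
#'   triacylglycerol in any pose around a lipase triad.
#' @return an object of class `GridBox`.
#' @export
make_grid_box <- function(center, edge = 22.5) {
  center <- assert_finite_point(center, "box center")
  if (!is.numeric(edge) || length(edge) != 1L || edge <= 0)
    ltk_stop("ltk_bad_box", "box edge must be a positive number")
  structure(list(center = center, edge = as.numeric(edge)), class = "GridBox")
}

#' @export
print.GridBox <- function(x, ...) {
  cat(format_grid_box(x), sep = "\n")
  invisible(x)
}

#' Serialize a grid box as a docking-config stanza
#' @param box a [make_grid_box()].
#' @return character vector of `center_x = ...` / `size_x = ...` lines.
#' @export
format_grid_box <- function(box) {
  c(sprintf("center_%s = %.3f", c("x", "y", "z"), box$center),
    sprintf("size_%s = %.3f", c("x", "y", "z"), rep(box$edge, 3)))
}

#' Does a grid box contain a point?
#' @param box a [make_grid_box()].
#' @param p length-3 point.
#' @export
box_contains <- function(box, p) {
  all(abs(assert_finite_point(p) - box$center) <= box$edge / 2)
}

#' Catalytic distance
#'
#' Euclidean distance between the Ser O-gamma and the substrate acyl carbon,
#' the geometric proxy for nucleophilic-attack competence.
#'
#' @param ser_og,acyl_carbon length-3 points in Angstrom.
#' @return distance in Angstrom.
#' @export
catalytic_distance <- function(ser_og, acyl_carbon) {
  sqrt(sum((assert_finite_point(ser_og, "ser_og") -
              assert_finite_point(acyl_carbon, "acyl_carbon"))^2))
}

#' Loose prefilter of a docking table
#'
#' Keeps structures whose ligand records have catalytic distance strictly
#' below `distance_lt` and affinity strictly below `affinity_lt`. With
#' `scope = "all"` (default) every ligand record of the structure must pass;
#' with `"any"` one passing record suffices.
#'
#' @param table a [docking_table()].
#' @param distance_lt strict distance cutoff in Angstrom (default 8).
#' @param affinity_lt strict affinity cutoff in kcal/mol (default 0,
#'   i.e. "negative affinity").
#' @param scope `"all"` or `"any"` ligand records per structure.
#' @return the subset of `table` for passing structures (possibly empty).
#' @export
prefilter <- function(table, distance_lt = 8, affinity_lt = 0,
                      scope = c("all", "any")) {
  scope <- match.arg(scope)
  if (!nrow(table)) ltk_stop("ltk_empty_table", "empty docking table")
  ok <- table$distance_A < distance_lt & table$affinity_kcal_mol < affinity_lt
  agg <- tapply(ok, table$structure,
                if (scope == "all") all else any)
  keep <- names(agg)[agg]
  out <- table[table$structure %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Screening criteria for the main dual-cutoff screen
#'
#' @param affinity_le inclusive affinity cutoff in kcal/mol (default -5).
#' @param distance_le inclusive distance cutoff in Angstrom (default 4;
#'   4.5 is the documented alternative).
#' @param focus_ligands ligand ids that must all pass (non-empty).
#' @return an object of class `ScreenCriteria`.
#' @export
screen_criteria <- function(affinity_le = -5, distance_le = 4,
                            focus_ligands = c("DHA-TAG", "DUPC")) {
  if (!length(focus_ligands))
    ltk_stop("ltk_bad_criteria", "focus ligand set must be non-empty")
  structure(list(affinity_le = affinity_le, distance_le = distance_le,
                 focus_ligands = as.character(focus_ligands)),
            class = "ScreenCriteria")
}

## best pose per (structure, ligand): lowest affinity, ties -> smallest distance
best_poses <- function(table) {
  o <- order(table$structure, table$ligand, table$affinity_kcal_mol,
             table$distance_A)
  t2 <- table[o, , drop = FALSE]
  t2[!duplicated(paste(t2$structure, t2$ligand, sep = "|")), , drop = FALSE]
}

#' Dual-cutoff screen on focus ligands
#'
#' A structure passes iff for every focus ligand its best pose satisfies
#' affinity <= `affinity_le` AND distance <= `distance_le` (inclusive).
#' Structures lacking a record for a focus ligand fail with a warning.
#'
#' @param table a [docking_table()].
#' @param criteria a [screen_criteria()].
#' @return character vector of passing structure ids, ordered by best (most
#'   negative) affinity over the focus ligands, ties broken lexicographically.
#' @export
screen <- function(table, criteria) {
  stopifnot(inherits(criteria, "ScreenCriteria"))
  bp <- best_poses(table)
  bp <- bp[bp$ligand %in% criteria$focus_ligands, , drop = FALSE]
  ids <- unique(table$structure)
  nlig <- length(criteria$focus_ligands)
  cover <- tapply(bp$ligand, bp$structure,
                  function(l) length(unique(l)) == nlig)
  missing <- setdiff(ids, names(cover)[!is.na(cover) & cover])
  if (length(missing))
    ltk_warn("ltk_missing_focus_ligand",
             "%d structure(s) lack a focus-ligand record and fail (e.g. %s)",
             length(missing), missing[1])
  ok <- bp$affinity_kcal_mol <= criteria$affinity_le &
    bp$distance_A <= criteria$distance_le
  allok <- tapply(ok, bp$structure, all)
  passers <- intersect(names(allok)[allok], names(cover)[cover])
  if (!length(passers)) return(character())
  best <- tapply(bp$affinity_kcal_mol[bp$structure %in% passers],
                 bp$structure[bp$structure %in% passers], min)
  passers[order(best[passers], passers)]
}

#' Group screened structures by organism
#'
#' @param ids structure ids in screen order.
#' @param mapping data.frame with columns `structure`, `organism`; ids absent
#'   from the mapping are grouped under `"unknown"`.
#' @return data.frame (`structure`, `organism`) ordered by organism first
#'   appearance, preserving the screen order within each group.
#' @export
annotate_organisms <- function(ids, mapping) {
  org <- mapping$organism[match(ids, mapping$structure)]
  org[is.na(org)] <- "unknown"
  out <- data.frame(structure = ids, organism = org,
                    stringsAsFactors = FALSE)
  out[order(match(org, unique(org))), , drop = FALSE]
}

#' Full screening report
#'
#' Runs prefilter + screen and assembles a per-structure report with the
#' per-focus-ligand best-pose values and pass flags.
#'
#' @param table a [docking_table()].
#' @param criteria a [screen_criteria()].
#' @param organisms optional organism mapping (see [annotate_organisms()]).
#' @inheritParams prefilter
#' @return list with elements `prefilter_ids`, `screen_ids`, `report`
#'   (data.frame), `n_prefilter`, `n_screen`.
#' @export
screen_report <- function(table, criteria = screen_criteria(),
                          organisms = NULL, distance_lt = 8, affinity_lt = 0,
                          scope = "all") {
  pre <- prefilter(table, distance_lt, affinity_lt, scope)
  pre_ids <- unique(pre$structure)
  hits <- suppressWarnings(screen(pre, criteria))
  bp <- best_poses(pre)
  rows <- lapply(hits, function(s) {
    r <- data.frame(structure = s, stringsAsFactors = FALSE)
    for (l in criteria$focus_ligands) {
      rec <- bp[bp$structure == s & bp$ligand == l, , drop = FALSE]
      r[[paste0("affinity_", l)]] <- rec$affinity_kcal_mol[1]
      r[[paste0("distance_", l)]] <- rec$distance_A[1]
    }
    r$pass <- TRUE
    r
  })
  rep <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (!is.null(organisms) && length(hits)) {
    ann <- annotate_organisms(hits, organisms)
    rep <- merge(rep, ann, by = "structure", sort = FALSE)
    rep <- rep[order(match(rep$organism, unique(ann$organism))), , drop = FALSE]
  }
  list(prefilter_ids = pre_ids, screen_ids = hits, report = rep,
       n_prefilter = length(pre_ids), n_screen = length(hits))
}
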