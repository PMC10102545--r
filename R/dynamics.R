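## Structure-activity descriptors from trajectories: rigid superposition,
## per-residue flexibility (RMSF about the time mean), flexible-region
## calling, channel geometry time series (dihedral / angle / distance on
## C-alpha anchors) and per-residue substrate contact frequencies.

#' Rigidly superpose every frame onto frame 1
#'
#' Least-squares (Kabsch) rotation + translation fitted on the selection and
#' applied to all atoms of the frame. The default selection is the protein
#' backbone (N, CA, C, O atoms of protein-class molecules).
#'
#' @param traj a [trajectory()].
#' @param selection integer atom indices to fit on, or `NULL` for the
#'   protein backbone.
#' @return a new [trajectory()] with transformed coordinates.
#' @export
superpose_frames <- function(traj, selection = NULL) {
  a <- traj$atoms
  selection <- selection %||%
    which(a$mol_class == "protein" & a$atom %in% c("N", "CA", "C", "O"))
  if (!length(selection))
    ltk_stop("ltk_empty_selection", "superposition selection is empty")
  ref <- traj$coords[1, selection, , drop = TRUE]
  dim(ref) <- c(length(selection), 3)
  ref_c <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_c)
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    mob <- traj$coords[f, selection, , drop = TRUE]
    dim(mob) <- c(length(selection), 3)
    mob_c <- colMeans(mob)
    R <- kabsch_rotation(sweep(mob, 2, mob_c), ref0)
    all_f <- traj$coords[f, , , drop = TRUE]
    dim(all_f) <- c(nrow(a), 3)
    out[f, , ] <- sweep(sweep(all_f, 2, mob_c) %*% R, 2, ref_c, `+`)
  }
  trajectory(out, a, traj$timestep_ns, times = traj$times)
}

## optimal rotation mapping centred mob onto centred ref (proper rotation)
kabsch_rotation <- function(mob, ref) {
  s <- svd(crossprod(mob, ref))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Per-residue flexibility profile (RMSF)
#'
#' Root-mean-square fluctuation of each protein residue's representative atom
#' about its time-average position. Superpose the trajectory first
#' ([superpose_frames()]) or rigid-body drift will dominate.
#'
#' @param traj a (superposed) [trajectory()].
#' @param representative atom name per residue (default `"CA"`).
#' @return data.frame of class `FlexibilityProfile`: `chain`, `resnum`,
#'   `icode`, `resname`, `rmsf` (Angstrom), ordered by residue number.
#'   Residues lacking the representative atom are omitted with a warning.
#' @export
flexibility_profile <- function(traj, representative = "CA") {
  a <- traj$atoms
  prot <- a$mol_class == "protein"
  idx <- which(prot & a$atom == representative)
  nres <- length(unique(paste(a$chain, a$resnum, a$icode)[prot]))
  if (length(idx) < nres)
    ltk_warn("ltk_missing_atom",
             "%d residue(s) lack atom '%s'; omitted from profile",
             nres - length(idx), representative)
  if (!length(idx))
    ltk_stop("ltk_empty_selection", "no residues carry atom '%s'",
             representative)
  rmsf <- vapply(idx, function(i) {
    p <- traj$coords[, i, , drop = TRUE]
    dim(p) <- c(n_frames(traj), 3)
    mu <- colMeans(p)
    sqrt(mean(rowSums(sweep(p, 2, mu)^2)))
  }, numeric(1))
  out <- data.frame(chain = a$chain[idx], resnum = a$resnum[idx],
                    icode = a$icode[idx], resname = a$resname[idx],
                    rmsf = rmsf, stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resnum, out$icode), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("FlexibilityProfile", "data.frame")
  out
}

#' Contiguous flexible regions of a profile
#'
#' Maximal runs of consecutive residue numbers whose flexibility is strictly
#' above `cutoff`.
#'
#' @param profile a [flexibility_profile()].
#' @param cutoff Angstrom threshold (default 0.025; treat as data — the
#'   useful scale depends on how rigid the system is).
#' @return data.frame `chain`, `from`, `to` (inclusive residue numbers),
#'   `n_residues`, `max_rmsf`; zero rows if nothing is flexible.
#' @export
flexible_regions <- function(profile, cutoff = 0.025) {
  hot <- profile[profile$rmsf > cutoff, , drop = FALSE]
  if (!nrow(hot))
    return(data.frame(chain = character(), from = integer(),
                      to = integer(), n_residues = integer(),
                      max_rmsf = numeric()))
  out <- do.call(rbind, lapply(split(hot, hot$chain), function(g) {
    g <- g[order(g$resnum), , drop = FALSE]
    brk <- cumsum(c(1L, diff(g$resnum) != 1L))
    do.call(rbind, lapply(split(g, brk), function(run) {
      data.frame(chain = run$chain[1], from = min(run$resnum),
                 to = max(run$resnum), n_residues = nrow(run),
                 max_rmsf = max(run$rmsf), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

anchor_series <- function(traj, keys, atom) {
  lapply(keys, function(key) {
    k <- parse_residue_key(key)
    a <- traj$atoms
    sel <- a$chain == k$chain & a$resnum == k$resnum & a$icode == k$icode &
      a$atom == atom
    if (!is.na(k$resname)) sel <- sel & a$resname == k$resname
    i <- which(sel)
    if (length(i) != 1L)
      ltk_stop("ltk_missing_residue", "anchor '%s' atom '%s': %d matches",
               if (is.character(key)) key else "<key>", atom, length(i))
    p <- traj$coords[, i, , drop = TRUE]
    dim(p) <- c(n_frames(traj), 3)
    p
  })
}

descriptor_series <- function(kind, anchors, values) {
  structure(list(kind = kind, anchors = anchors, values = values),
            class = "DescriptorSeries")
}

#' @export
print.DescriptorSeries <- function(x, ...) {
  cat(sprintf("DescriptorSeries[%s] over %d frames, anchors: %s\n",
              x$kind, length(x$values),
              paste(unlist(x$anchors), collapse = ", ")))
  invisible(x)
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Torsion (dihedral) time series over four residue anchors
#'
#' Signed torsion about the p2–p3 axis, degrees in (-180, 180]. Frames where
#' the torsion is undefined (collinear anchors) carry `NA`.
#'
#' @param traj a [trajectory()].
#' @param anchors four residue keys ("chain:resnum[:resname]").
#' @param atom anchor atom name (default `"CA"`; the channel descriptors are
#'   residue-level, so the C-alpha is the natural anchor).
#' @return a `DescriptorSeries` with `kind = "dihedral"`.
#' @export
dihedral_series <- function(traj, anchors, atom = "CA") {
  if (length(anchors) != 4L)
    ltk_stop("ltk_bad_anchors", "dihedral needs exactly 4 anchors")
  p <- anchor_series(traj, anchors, atom)
  b1 <- p[[2]] - p[[1]]; b2 <- p[[3]] - p[[2]]; b3 <- p[[4]] - p[[3]]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross3(n1, b2n)
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  bad <- rowSums(n1^2) < 1e-18 | rowSums(n2^2) < 1e-18
  ang[bad] <- NA_real_
  ang[!bad & ang <= -180 + 1e-12] <- 180  # convention: (-180, 180]
  descriptor_series("dihedral", anchors, ang)
}

#' Vertex-angle time series over three residue anchors
#'
#' Angle at the middle anchor, degrees in [0, 180]; `NA` where anchors
#' coincide.
#'
#' @inheritParams dihedral_series
#' @param anchors three residue keys, vertex in the middle.
#' @return a `DescriptorSeries` with `kind = "angle"`.
#' @export
angle_series <- function(traj, anchors, atom = "CA") {
  if (length(anchors) != 3L)
    ltk_stop("ltk_bad_anchors", "angle needs exactly 3 anchors")
  p <- anchor_series(traj, anchors, atom)
  u <- p[[1]] - p[[2]]; v <- p[[3]] - p[[2]]
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / (nu * nv)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang[nu < 1e-9 | nv < 1e-9] <- NA_real_
  descriptor_series("angle", anchors, ang)
}

#' Distance time series between two residue anchors
#'
#' @inheritParams dihedral_series
#' @param anchors two residue keys.
#' @return a `DescriptorSeries` with `kind = "distance"` (Angstrom).
#' @export
distance_series <- function(traj, anchors, atom = "CA") {
  if (length(anchors) != 2L)
    ltk_stop("ltk_bad_anchors", "distance needs exactly 2 anchors")
  p <- anchor_series(traj, anchors, atom)
  descriptor_series("distance", anchors, sqrt(rowSums((p[[1]] - p[[2]])^2)))
}

#' Per-residue substrate contact frequencies
#'
#' For each protein residue and substrate class, the number of frames in
#' which any atom of the residue lies strictly within `cutoff` of any atom of
#' any molecule of that class. A residue contributes at most one count per
#' frame per class. Residues whose frequency reaches `highlight` are flagged.
#'
#' @param traj a [trajectory()].
#' @param classes substrate classes (default all non-protein/non-water).
#' @param cutoff contact distance in Angstrom (default 8 — generous, to
#'   capture interactions of bulky, sterically hindered substrates).
#' @param highlight frequency (frame count) at which a residue is flagged as
#'   a strong interactor (default 70).
#' @return data.frame of class `ContactFrequencyMap`: `chain`, `resnum`,
#'   `icode`, `resname`, one frequency column per class, and per-class
#'   logical highlight columns; attribute `n_frames`.
#' @export
contact_frequency <- function(traj, classes = NULL, cutoff = 8,
                              highlight = 70) {
  a <- traj$atoms
  classes <- classes %||%
    setdiff(unique(a$mol_class), c("protein", "water"))
  cls_idx <- lapply(classes, function(cl) class_atom_idx(traj, cl))
  prot <- which(a$mol_class == "protein")
  if (!length(prot)) ltk_stop("ltk_empty_selection", "no protein atoms")
  reskey <- paste(a$chain[prot], a$resnum[prot], a$icode[prot])
  res_first <- !duplicated(reskey)
  res_of_atom <- match(reskey, reskey[res_first])
  nres <- sum(res_first)
  nf <- n_frames(traj)
  counts <- matrix(0L, nres, length(classes))
  cut2 <- cutoff^2
  for (f in seq_len(nf)) {
    P <- traj$coords[f, prot, , drop = TRUE]
    dim(P) <- c(length(prot), 3)
    for (j in seq_along(classes)) {
      S <- traj$coords[f, cls_idx[[j]], , drop = TRUE]
      dim(S) <- c(length(cls_idx[[j]]), 3)
      ## squared all-pairs distances via the expansion |p-s|^2
      d2 <- outer(rowSums(P^2), rowSums(S^2), `+`) - 2 * tcrossprod(P, S)
      hit <- rowSums(d2 < cut2) > 0L
      touched <- unique(res_of_atom[hit])
      counts[touched, j] <- counts[touched, j] + 1L
    }
  }
  out <- data.frame(chain = a$chain[prot][res_first],
                    resnum = a$resnum[prot][res_first],
                    icode = a$icode[prot][res_first],
                    resname = a$resname[prot][res_first],
                    stringsAsFactors = FALSE)
  for (j in seq_along(classes)) {
    out[[paste0("freq_", classes[j])]] <- counts[, j]
    out[[paste0("highlight_", classes[j])]] <- counts[, j] >= highlight
  }
  attr(out, "n_frames") <- nf
  class(out) <- c("ContactFrequencyMap", "data.frame")
  out
}

#' Average contact maps across batches
#'
#' @param maps list of [contact_frequency()] maps over the same residue set.
#' @return data.frame with mean frequency per residue and class.
#' @export
average_contact_maps <- function(maps) {
  if (!length(maps)) ltk_stop("ltk_empty_input", "no contact maps")
  base <- maps[[1]][c("chain", "resnum", "icode", "resname")]
  fcols <- grep("^freq_", names(maps[[1]]), value = TRUE)
  for (cl in fcols) {
    vals <- vapply(maps, function(m) m[[cl]], numeric(nrow(base)))
    base[[sub("^freq_", "mean_freq_", cl)]] <-
      if (is.matrix(vals)) rowMeans(vals) else mean(vals)
  }
  base
}
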