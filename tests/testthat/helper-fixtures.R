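# Fixture builders and independent oracles. Oracles deliberately use
# different formulations than the implementation they check.

toy_model <- function() {
  atoms <- data.frame(
    chain = "A",
    resnum = c(1L, 1L, 2L, 3L),
    icode = "",
    resname = c("SER", "SER", "ASP", "HIS"),
    atom = c("CA", "OG", "CA", "CA"),
    x = c(0, 0, 3, 0), y = c(0, 0, 0, 3), z = c(0, 1, 0, 0),
    het = FALSE, stringsAsFactors = FALSE)
  structure_model(atoms)
}

toy_triad <- function() triad_spec("A:1:SER", "A:3:HIS", "A:2:ASP")

write_toy_pdb <- function(path, with_water = TRUE) {
  lines <- c(
    "ATOM      1  CA  SER A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  OG  SER A   1       0.000   0.000   1.000  1.00  0.00",
    "ATOM      3  CA  ASP A   2       3.000   0.000   0.000  1.00  0.00",
    "ATOM      4  CA  HIS A   3       0.000   3.000   0.000  1.00  0.00")
  if (with_water)
    lines <- c(lines,
      "HETATM    5  O   HOH A 101       9.000   9.000   9.000  1.00  0.00")
  writeLines(c(lines, "END"), path)
  path
}

# trajectory from an explicit list of frame coordinate matrices
traj_from_frames <- function(frames, atoms, timestep_ns = 0.1) {
  coords <- array(NA_real_, c(length(frames), nrow(atoms), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, atoms, timestep_ns)
}

protein_atoms <- function(n = 4, extra = NULL) {
  a <- data.frame(chain = "A", resnum = seq_len(n), icode = "",
                  resname = "ALA", atom = "CA",
                  mol_id = "protein:A", mol_class = "protein",
                  stringsAsFactors = FALSE)
  if (!is.null(extra)) a <- rbind(a, extra)
  a
}

substrate_atoms <- function(classes) {
  data.frame(chain = "S", resnum = seq_along(classes), icode = "",
             resname = ifelse(classes == "PC", "LPC", "TAG"), atom = "C1",
             mol_id = sprintf("%s:S:%d", classes, seq_along(classes)),
             mol_class = classes, stringsAsFactors = FALSE)
}

# independent torsion oracle: angle between half-plane normals with sign
# from the scalar triple product (different construction than atan2 path)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(pmin(1, pmax(-1, cosphi))) * 180 / pi
  # IUPAC sign: negative when n1 x n2 points along b2
  if (sum(pracma_cross(n1, n2) * b2) > 0) phi <- -phi
  phi
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

oracle_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# brute-force double-loop triage oracle over a docking table
oracle_screen <- function(df, aff_le, dist_le, focus) {
  pass <- character(0)
  for (s in unique(df$structure)) {
    ok <- TRUE
    for (l in focus) {
      rows <- df[df$structure == s & df$ligand == l, , drop = FALSE]
      if (!nrow(rows)) { ok <- FALSE; break }
      rows <- rows[order(rows$affinity_kcal_mol, rows$distance_A), ]
      if (!(rows$affinity_kcal_mol[1] <= aff_le &&
            rows$distance_A[1] <= dist_le)) { ok <- FALSE; break }
    }
    if (ok) pass <- c(pass, s)
  }
  pass
}

oracle_prefilter <- function(df, dist_lt = 8, aff_lt = 0) {
  keep <- character(0)
  for (s in unique(df$structure)) {
    rows <- df[df$structure == s, , drop = FALSE]
    if (all(rows$distance_A < dist_lt & rows$affinity_kcal_mol < aff_lt))
      keep <- c(keep, s)
  }
  keep
}

random_rigid_motion <- function(seed) {
  set.seed(seed)
  th <- runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  list(R = Rx %*% Ry %*% Rz, t = runif(3, -20, 20))
}

apply_rigid <- function(traj, motion) {
  out <- traj$coords
  for (f in seq_len(dim(out)[1])) {
    m <- out[f, , , drop = TRUE]
    dim(m) <- c(dim(out)[2], 3)
    out[f, , ] <- sweep(m %*% t(motion$R), 2, motion$t, `+`)
  }
  trajectory(out, traj$atoms, traj$timestep_ns)
}
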