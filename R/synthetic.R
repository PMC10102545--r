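## Synthetic-data generators. These state a small, fully-known world: toy
## C-alpha protein chains, docking tables with planted triage outcomes,
## trajectories with planted per-molecule binding schedules under an
## anhydrous vs micro-water contrast, and FAME tables of known composition.
## Every generator is deterministic given (parameters, seed) and returns its
## ground truth so analysis stages can be checked exactly.

LIGAND_SET <- c("DHA-TAG", "DHA-DAG", "DHA-MAG", "DHA", "C18:2", "C16:0",
                "DPPC", "DUPC")

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old))
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## uniform point in a ball of given radius
runif_ball <- function(n, radius) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  v * radius * stats::runif(n)^(1 / 3)
}

runif_sphere <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a toy C-alpha protein with a catalytic triad
#'
#' Residues lie on a smooth random curve (smoothed random-walk, ~3.8 A
#' C-alpha spacing). Three residues are Ser/Asp/His; the serine carries an
#' additional OG atom. If `triad_positions` is given (3 x 3 matrix, rows =
#' Ser/Asp/His), those C-alpha coordinates are imposed.
#'
#' @param n_residues chain length (>= 3).
#' @param triad_positions optional 3 x 3 coordinate matrix for the triad
#'   C-alphas; rows closer than 0.5 A are rejected.
#' @param triad_at indices of (Ser, Asp, His) along the chain; default
#'   roughly the 1/2, 2/3 and 5/6 points.
#' @param seed RNG seed.
#' @return a [structure_model()] with attribute `"triad"` (a [triad_spec()]).
#' @export
gen_structure <- function(n_residues, triad_positions = NULL,
                          triad_at = NULL, seed = 1L) {
  if (n_residues < 3L)
    ltk_stop("ltk_bad_number", "need >= 3 residues")
  if (!is.null(triad_positions)) {
    triad_positions <- as.matrix(triad_positions)
    if (min(stats::dist(triad_positions)) < 0.5)
      ltk_stop("ltk_triad_collision",
               "triad positions closer than 0.5 A")
  }
  if (is.null(triad_at)) {
    triad_at <- unique(pmax(1L, pmin(n_residues, c(
      ceiling(n_residues / 2), ceiling(2 * n_residues / 3),
      ceiling(5 * n_residues / 6)))))
    spare <- setdiff(seq_len(n_residues), triad_at)
    triad_at <- c(triad_at, spare)[1:3]  # pad for very short chains
  }
  if (length(unique(triad_at)) != 3L)
    ltk_stop("ltk_bad_number", "triad indices must be 3 distinct residues")
  with_seed(seed, {
    steps <- matrix(stats::rnorm(3 * (n_residues + 4)), ncol = 3)
    ## moving-average smoothing gives a slowly-turning curve
    sm <- apply(steps, 2, function(s) stats::filter(s, rep(0.2, 5), sides = 2))
    sm <- sm[!apply(is.na(sm), 1, any), , drop = FALSE][seq_len(n_residues), ]
    sm <- sm / sqrt(rowSums(sm^2)) * 3.8
    ca <- apply(sm, 2, cumsum)
    if (!is.null(triad_positions)) ca[triad_at, ] <- triad_positions
    resname <- sample(c("ALA", "GLY", "LEU", "VAL", "THR"), n_residues,
                      replace = TRUE)
    resname[triad_at] <- c("SER", "ASP", "HIS")
    atoms <- data.frame(chain = "A", resnum = seq_len(n_residues),
                        icode = "", resname = resname, atom = "CA",
                        x = ca[, 1], y = ca[, 2], z = ca[, 3], het = FALSE,
                        stringsAsFactors = FALSE)
    og <- atoms[triad_at[1], ]
    og$atom <- "OG"
    ogdir <- runif_sphere(1)
    og[c("x", "y", "z")] <- og[c("x", "y", "z")] + 1.4 * ogdir
    model <- structure_model(rbind(atoms, og))
    attr(model, "triad") <- triad_spec(
      ser = sprintf("A:%d:SER", triad_at[1]),
      his = sprintf("A:%d:HIS", triad_at[3]),
      acid = sprintf("A:%d:ASP", triad_at[2]))
    model
  })
}

gen_pdb_ids <- function(n) {
  ids <- character(0)
  while (length(ids) < n) {
    cand <- paste0(sample(1:9, n, TRUE),
                   apply(matrix(sample(letters, 3 * n, TRUE), ncol = 3), 1,
                         paste, collapse = ""))
    ids <- unique(c(ids, cand))
  }
  ids[seq_len(n)]
}

#' Generate a docking table with planted triage outcomes
#'
#' Exactly `n_prefilter_pass` structures pass the loose prefilter and exactly
#' `n_screen_pass` of those also pass the dual-cutoff screen; every planted
#' value keeps a margin of at least 0.1 (kcal/mol or Angstrom) from every
#' cutoff, so the outcome is scope- and tie-independent. Failing structures
#' fail on every ligand, so the planted truth holds under both `"all"` and
#' `"any"` prefilter scopes.
#'
#' @param n_structures,n_prefilter_pass,n_screen_pass planted counts with
#'   `n_screen_pass <= n_prefilter_pass <= n_structures`.
#' @param criteria a [screen_criteria()] (defaults: -5 kcal/mol, 4 A,
#'   focus DHA-TAG + DUPC).
#' @param distance_lt,affinity_lt prefilter cutoffs (defaults 8 A, 0).
#' @param ligands ligand panel (default the 8-ligand set: DHA esters, free
#'   fatty acids and the two phosphatidylcholines).
#' @param seed RNG seed.
#' @return list `table` (a [docking_table()] with an `organism` column),
#'   `prefilter_ids`, `screen_ids` (planted ground truth, unordered sets).
#' @export
gen_docking_table <- function(n_structures = 158, n_prefilter_pass = 85,
                              n_screen_pass = 24,
                              criteria = screen_criteria(),
                              distance_lt = 8, affinity_lt = 0,
                              ligands = LIGAND_SET, seed = 1L) {
  if (n_screen_pass > n_prefilter_pass || n_prefilter_pass > n_structures)
    ltk_stop("ltk_bad_number",
             "need n_screen_pass <= n_prefilter_pass <= n_structures")
  m <- 0.1  # planted margin from every cutoff
  with_seed(seed, {
    ids <- gen_pdb_ids(n_structures)
    kind <- rep("fail", n_structures)
    kind[seq_len(n_prefilter_pass)] <- "pre"
    kind[seq_len(n_screen_pass)] <- "hit"
    kind <- sample(kind)  # shuffle so id order carries no signal
    organisms <- sample(c("Thermomyces lanuginosus", "Moesziomyces antarcticus",
                          "Aspergillus oryzae", "Pseudomonas aeruginosa",
                          "Homo sapiens", "Serratia marcescens"),
                        n_structures, TRUE)
    n <- n_structures * length(ligands)
    df <- data.frame(
      structure = rep(ids, each = length(ligands)),
      ligand = rep(ligands, n_structures),
      affinity_kcal_mol = NA_real_, distance_A = NA_real_,
      organism = rep(organisms, each = length(ligands)),
      stringsAsFactors = FALSE)
    focus <- df$ligand %in% criteria$focus_ligands
    k <- rep(kind, each = length(ligands))
    n_all <- length(k)
    ## every draw keeps >= m from every cutoff it could be compared against
    aff_loose <- function(n) stats::runif(n, -6, affinity_lt - m)
    dst_loose <- function(n) stats::runif(n, 0.5, distance_lt - m)
    ## focus-row values that fail the dual screen but pass the prefilter,
    ## with margins from both the screen and prefilter cutoffs
    aff_nonpass <- function(n) stats::runif(n, criteria$affinity_le + m,
                                            affinity_lt - m)
    dst_either <- function(n) ifelse(
      stats::runif(n) < 0.5,
      stats::runif(n, 0.5, criteria$distance_le - m),
      stats::runif(n, criteria$distance_le + m, distance_lt - m))
    ## baseline: everything prefilter-clean
    df$affinity_kcal_mol <- aff_loose(n_all)
    df$distance_A <- dst_loose(n_all)
    ## focus rows of non-hit structures fail the screen via affinity
    sel <- focus & k != "hit"
    df$affinity_kcal_mol[sel] <- aff_nonpass(sum(sel))
    df$distance_A[sel] <- dst_either(sum(sel))
    ## screen hits: focus ligands strictly inside the dual cutoffs
    sel <- focus & k == "hit"
    df$affinity_kcal_mol[sel] <- stats::runif(sum(sel), -9,
                                              criteria$affinity_le - m)
    df$distance_A[sel] <- stats::runif(sum(sel), 0.5,
                                       criteria$distance_le - m)
    ## failing structures: every ligand row violates the prefilter
    sel <- k == "fail"
    by_dist <- stats::runif(sum(sel)) < 0.5
    df$distance_A[sel][by_dist] <-
      stats::runif(sum(by_dist), distance_lt + m, distance_lt + 12)
    df$affinity_kcal_mol[sel][!by_dist] <-
      stats::runif(sum(!by_dist), affinity_lt + m, 3)
    list(table = docking_table(df),
         prefilter_ids = sort(ids[match(unique(df$structure[k != "fail"]),
                                        ids)]),
         screen_ids = sort(unique(df$structure[k == "hit"])))
  })
}

## draw a per-molecule schedule: enters with probability p_enter; if it
## enters, 1-3 disjoint bound intervals at random positions
draw_schedule <- function(n_mol, n_frames, p_enter) {
  lapply(seq_len(n_mol), function(i) {
    if (stats::runif(1) >= p_enter)
      return(matrix(integer(), 0, 2,
                    dimnames = list(NULL, c("start", "end"))))
    n_ev <- 1L + stats::rbinom(1, 2, 0.3)
    len <- pmax(1L, stats::rpois(n_ev, max(2, n_frames / 10)))
    ## lay events left to right with random gaps; clip to the series
    gaps <- stats::rgeom(n_ev, prob = min(0.9, 4 / n_frames)) + 1L
    starts <- cumsum(gaps) + c(0L, cumsum(len))[seq_len(n_ev)]
    ends <- pmin(starts + len, n_frames)
    keep <- starts < n_frames & ends > starts
    ev <- cbind(start = starts[keep], end = ends[keep])
    if (!nrow(ev)) ev <- cbind(start = 0L, end = min(2L, n_frames))
    ev
  })
}

#' Generate a trajectory with a planted binding schedule
#'
#' Substrate molecules are single pseudo-atoms (their own centroids) placed
#' at `bound_distance` (default 5 A) from the triad centre while bound and
#' `unbound_distance` (default 40 A) while unbound, plus uniform-in-ball
#' noise. Because noise is bounded, the planted bound/unbound state never
#' crosses the entry cutoff and analysis must recover the schedule
#' frame-exactly. The protein is held rigid (optionally jittered on selected
#' residues).
#'
#' Presets encode the observed anhydrous vs micro-water contrast: per-batch
#' expected distinct-PC entries of 0.5 vs 2.5 (a 5x design over `n_pc = 20`
#' molecules, entry probabilities 0.025 vs 0.125) with DHA-TAG statistics
#' equal in both (entry probability 0.05 over `n_tag = 200` molecules, ~10
#' expected entries).
#'
#' @param n_frames frames (>= 1).
#' @param timestep_ns frame spacing in ns (default 0.1).
#' @param n_pc,n_tag number of PC / DHA-TAG molecules (defaults 20 / 200).
#' @param schedule named list `mol_id -> events matrix` (0-based half-open
#'   frame intervals) for any subset of molecules; molecules not listed stay
#'   unbound. Overrides `preset`.
#' @param preset `"anhydrous"` or `"micro-water"`; random schedules drawn at
#'   the preset rates. `NULL` (with no schedule) leaves everything unbound.
#' @param noise noise amplitude in Angstrom (uniform in a ball); must keep
#'   bound/unbound states on their side of `cutoff`.
#' @param cutoff entry cutoff the planted states must respect (default 15).
#' @param bound_distance,unbound_distance planted centroid distances.
#' @param protein a [gen_structure()] model (default `gen_structure(30)`
#'   derived from the seed); must carry a `"triad"` attribute.
#' @param jitter_residues residue numbers to jitter; `jitter` amplitude (A).
#' @param jitter jitter amplitude in Angstrom (default 0).
#' @param seed RNG seed.
#' @return list `trajectory`, `schedule` (full named list incl. empty
#'   matrices), `triad`, `preset`.
#' @export
gen_trajectory <- function(n_frames = 240, timestep_ns = 0.1, n_pc = 20,
                           n_tag = 200, schedule = NULL, preset = NULL,
                           noise = 1, cutoff = 15, bound_distance = 5,
                           unbound_distance = 40, protein = NULL,
                           jitter_residues = NULL, jitter = 0, seed = 1L) {
  if (noise >= (cutoff - bound_distance) || noise >= (unbound_distance - cutoff))
    ltk_stop("ltk_bad_noise",
             "noise %.2f crosses the cutoff margins (bound %g, unbound %g, cutoff %g)",
             noise, bound_distance, unbound_distance, cutoff)
  if (!is.null(preset)) preset <- match.arg(preset, c("anhydrous", "micro-water"))
  with_seed(seed, {
    protein <- protein %||% gen_structure(30, seed = sample.int(2^31 - 1, 1))
    triad <- attr(protein, "triad")
    if (is.null(triad))
      ltk_stop("ltk_bad_protein", "protein model lacks a 'triad' attribute")
    tc <- triad_center(protein, triad)
    mol_ids <- c(if (n_pc) sprintf("PC:S:%d", seq_len(n_pc)),
                 if (n_tag) sprintf("DHA-TAG:S:%d", n_pc + seq_len(n_tag)))
    mol_cls <- c(rep("PC", n_pc), rep("DHA-TAG", n_tag))
    full <- stats::setNames(rep(list(
      matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end")))),
      length(mol_ids)), mol_ids)
    if (is.null(schedule) && !is.null(preset)) {
      p_pc <- if (preset == "micro-water") 0.125 else 0.025
      p_tag <- 0.05
      sch <- c(draw_schedule(n_pc, n_frames, p_pc),
               draw_schedule(n_tag, n_frames, p_tag))
      names(sch) <- mol_ids
      schedule <- sch
    }
    if (!is.null(schedule)) {
      bad <- setdiff(names(schedule), mol_ids)
      if (length(bad))
        ltk_stop("ltk_unknown_molecule", "schedule names unknown molecule '%s'",
                 bad[1])
      full[names(schedule)] <- lapply(schedule, function(ev) {
        ev <- as.matrix(ev)
        if (nrow(ev) && (any(ev < 0) || any(ev[, 2] > n_frames) ||
                         any(ev[, 2] <= ev[, 1])))
          ltk_stop("ltk_bad_schedule", "schedule interval out of range")
        colnames(ev) <- c("start", "end")
        ev
      })
    }
    prot_a <- protein$atoms
    n_pa <- nrow(prot_a)
    n_mol <- length(mol_ids)
    coords <- array(NA_real_, c(n_frames, n_pa + n_mol, 3))
    base <- as.matrix(prot_a[c("x", "y", "z")])
    for (f in seq_len(n_frames)) coords[f, seq_len(n_pa), ] <- base
    if (jitter > 0 && length(jitter_residues)) {
      ji <- which(prot_a$resnum %in% jitter_residues)
      for (i in ji)
        coords[, i, ] <- coords[, i, ] + runif_ball(n_frames, jitter)
    }
    ## each molecule keeps one random direction from the triad centre
    dirs <- runif_sphere(n_mol)
    for (jm in seq_len(n_mol)) {
      mask <- events_to_mask(full[[jm]], n_frames)
      r <- ifelse(mask, bound_distance, unbound_distance)
      pos <- matrix(tc, n_frames, 3, byrow = TRUE) + r %o% dirs[jm, ]
      if (noise > 0) pos <- pos + runif_ball(n_frames, noise)
      coords[, n_pa + jm, ] <- pos
    }
    atoms <- rbind(
      cbind(prot_a[c("chain", "resnum", "icode", "resname", "atom")],
            mol_id = "protein:A", mol_class = "protein"),
      data.frame(chain = "S", resnum = seq_len(n_mol), icode = "",
                 resname = ifelse(mol_cls == "PC", "LPC", "TAG"),
                 atom = "C1", mol_id = mol_ids, mol_class = mol_cls,
                 stringsAsFactors = FALSE))
    list(trajectory = trajectory(coords, atoms, timestep_ns),
         schedule = full, triad = triad, preset = preset)
  })
}

#' Generate a FAME table realizing a stated fatty-acid composition
#'
#' @param composition named percentages summing to 100.
#' @param band band id (default `"PC"`).
#' @param seed RNG seed (drives the random positive overall scale).
#' @return a [fame_table()].
#' @export
gen_fame_table <- function(composition, band = "PC", seed = 1L) {
  if (any(composition < 0))
    ltk_stop("ltk_bad_number", "negative composition entry")
  if (abs(sum(composition) - 100) > 1e-6)
    ltk_stop("ltk_bad_number", "composition must sum to 100 (got %g)",
             sum(composition))
  with_seed(seed, {
    scale <- stats::runif(1, 0.2, 5)
    fame_table(data.frame(band = band, fatty_acid = names(composition),
                          amount = unname(composition) / 100 * scale,
                          stringsAsFactors = FALSE))
  })
}
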