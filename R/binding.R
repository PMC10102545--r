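## Binding-event statistics from trajectories.
##
## A substrate molecule counts as "in the active pocket" in a frame when the
## distance between the catalytic-triad geometric centre and the molecule's
## reference point (centroid by default) is strictly below the entry cutoff
## (15 A by default — generous because triacylglycerol substrates are bulky
## and never reach the triad itself). Frames are 0-based and events are
## half-open [start, end) so durations are additive.

#' Per-frame pocket distance of one molecule
#'
#' @param traj a [trajectory()].
#' @param triad a [triad_spec()]; its residues must belong to the protein in
#'   the trajectory.
#' @param mol_id molecule id (see the trajectory's atom table).
#' @param reference `"centroid"` (default) or the name of an atom of the
#'   molecule (e.g. the acyl carbon).
#' @return numeric vector of Angstrom distances, one per frame.
#' @export
pocket_distance_series <- function(traj, triad, mol_id,
                                   reference = "centroid") {
  tc <- triad_center_series(traj, triad)
  idx <- mol_atom_idx(traj, mol_id)
  if (!identical(reference, "centroid")) {
    idx <- idx[traj$atoms$atom[idx] == reference]
    if (!length(idx))
      ltk_stop("ltk_missing_atom", "molecule '%s' has no atom '%s'",
               mol_id, reference)
  }
  p <- frame_centroid(traj, idx)
  sqrt(rowSums((p - tc)^2))
}

## per-frame triad geometric centre (protein may move)
triad_center_series <- function(traj, triad) {
  a <- traj$atoms
  sel <- rep(FALSE, nrow(a))
  for (key in list(triad$ser, triad$his, triad$acid)) {
    k <- parse_residue_key(key)
    s <- a$chain == k$chain & a$resnum == k$resnum & a$icode == k$icode
    if (!is.na(k$resname)) s <- s & a$resname == k$resname
    if (!any(s))
      ltk_stop("ltk_missing_residue",
               "triad residue '%s' absent from trajectory",
               if (is.character(key)) key else paste(unlist(key), collapse = ":"))
    sel <- sel | s
  }
  frame_centroid(traj, which(sel))
}

#' Threshold a distance series into a bound/unbound mask
#'
#' Bound means distance strictly below `cutoff`. With `debounce = k > 0`,
#' interior runs shorter than `k` frames are absorbed into their
#' surroundings — short bound blips are removed first, then short unbound
#' gaps are bridged. Runs touching the window edges are never merged (their
#' true length is unknown).
#'
#' @param series numeric distance series (Angstrom).
#' @param cutoff entry cutoff in Angstrom (default 15).
#' @param debounce minimal run length in frames (default 0 = no smoothing).
#' @return logical vector, `TRUE` = bound.
#' @export
bound_state <- function(series, cutoff = 15, debounce = 0L) {
  if (!is.numeric(cutoff) || cutoff <= 0)
    ltk_stop("ltk_bad_cutoff", "entry cutoff must be > 0")
  mask <- series < cutoff
  if (debounce > 0L) {
    mask <- drop_short_runs(mask, debounce, TRUE)   # kill short bound blips
    mask <- drop_short_runs(mask, debounce, FALSE)  # bridge short gaps
  }
  mask
}

drop_short_runs <- function(mask, k, value) {
  r <- rle(mask)
  short <- r$values == value & r$lengths < k
  ## runs touching the window edges are kept: they may be truncated by the
  ## observation window, so their true length is unknown
  short[c(1L, length(r$values))] <- FALSE
  r$values[short] <- !value
  inverse.rle(r)
}

#' Maximal bound intervals of a mask
#'
#' @param mask logical bound/unbound series.
#' @return integer matrix with columns `start`, `end`: maximal `TRUE` runs as
#'   0-based half-open frame intervals; zero rows if never bound.
#' @export
segment_events <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  sel <- which(r$values)
  cbind(start = starts[sel], end = ends[sel])
}

#' Expand events back into a mask (inverse of [segment_events()])
#' @param events integer matrix `start`,`end` (0-based, half-open).
#' @param n_frames series length.
#' @export
events_to_mask <- function(events, n_frames) {
  mask <- rep(FALSE, n_frames)
  if (is.null(events) || nrow(events) == 0L) return(mask)
  for (i in seq_len(nrow(events)))
    mask[(events[i, 1] + 1L):events[i, 2]] <- TRUE
  mask
}

#' Binding traces for all molecules of the given classes
#'
#' @param traj a [trajectory()].
#' @param triad a [triad_spec()].
#' @param classes substrate classes to trace (default every non-protein,
#'   non-water class in the trajectory).
#' @param cutoff,debounce see [bound_state()].
#' @param reference see [pocket_distance_series()].
#' @return list of `BindingTrace` objects: `mol_id`, `class`, `mask`,
#'   `events` (0-based half-open), `timestep_ns`.
#' @export
binding_traces <- function(traj, triad, classes = NULL, cutoff = 15,
                           debounce = 0L, reference = "centroid") {
  classes <- classes %||%
    setdiff(unique(traj$atoms$mol_class), c("protein", "water"))
  for (cl in classes) class_atom_idx(traj, cl)  # validate
  a <- traj$atoms
  sub <- unique(a[a$mol_class %in% classes, c("mol_id", "mol_class")])
  tc <- triad_center_series(traj, triad)
  lapply(seq_len(nrow(sub)), function(i) {
    idx <- mol_atom_idx(traj, sub$mol_id[i])
    if (!identical(reference, "centroid")) {
      ridx <- idx[a$atom[idx] == reference]
      if (length(ridx)) idx <- ridx
    }
    d <- sqrt(rowSums((frame_centroid(traj, idx) - tc)^2))
    mask <- bound_state(d, cutoff, debounce)
    structure(list(mol_id = sub$mol_id[i], class = sub$mol_class[i],
                   mask = mask, events = segment_events(mask),
                   timestep_ns = traj$timestep_ns),
              class = "BindingTrace")
  })
}

#' Per-batch entry counts and binding times
#'
#' "Entering count" is the number of distinct molecules with at least one
#' binding event; episode counts are reported alongside. Total binding time
#' is the summed bound duration over all molecules of a class.
#'
#' @param traces list of `BindingTrace` (one batch).
#' @param timestep_ns frame spacing in ns (default taken from the traces).
#' @param batch id of the batch (default 1).
#' @return data.frame of class `BatchSummary`: one row per substrate class
#'   with `n_entering`, `n_episodes`, `time_ns`.
#' @export
batch_summary <- function(traces, timestep_ns = NULL, batch = 1L) {
  if (!length(traces)) ltk_stop("ltk_empty_input", "no binding traces")
  nf <- vapply(traces, function(t) length(t$mask), integer(1))
  if (length(unique(nf)) != 1L)
    ltk_stop("ltk_frame_mismatch", "traces have differing frame counts")
  timestep_ns <- timestep_ns %||% traces[[1]]$timestep_ns
  cls <- vapply(traces, `[[`, character(1), "class")
  out <- do.call(rbind, lapply(unique(cls), function(cl) {
    tr <- traces[cls == cl]
    nev <- vapply(tr, function(t) nrow(t$events), integer(1))
    bound <- vapply(tr, function(t) sum(t$mask), integer(1))
    data.frame(batch = batch, class = cl,
               n_entering = sum(nev > 0L),
               n_episodes = sum(nev),
               time_ns = sum(bound) * timestep_ns,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("BatchSummary", "data.frame")
  out
}

#' Assemble a batch summary from already-known per-class values
#'
#' Convenience constructor for worked examples and for aggregating published
#' per-batch tables.
#'
#' @param batch batch id.
#' @param class character vector of substrate classes.
#' @param n_entering,time_ns numeric vectors parallel to `class`.
#' @param n_episodes optional episode counts (default `NA`).
#' @return a `BatchSummary` data.frame.
#' @export
batch_summary_values <- function(batch, class, n_entering, time_ns,
                                 n_episodes = NA_integer_) {
  if (any(n_entering < 0) || any(time_ns < 0))
    ltk_stop("ltk_bad_number", "counts and times must be >= 0")
  if (any(n_entering == 0 & time_ns > 0))
    ltk_stop("ltk_bad_number", "zero entries cannot have positive time")
  out <- data.frame(batch = batch, class = class, n_entering = n_entering,
                    n_episodes = n_episodes, time_ns = time_ns,
                    stringsAsFactors = FALSE)
  class(out) <- c("BatchSummary", "data.frame")
  out
}

#' Cross-batch averages of entry counts and binding times
#'
#' @param summaries list of `BatchSummary` objects (>= 1).
#' @return list with `per_batch` (all rows) and `average` (one row per class
#'   with arithmetic means of `n_entering`, `n_episodes`, `time_ns`).
#' @export
aggregate_batches <- function(summaries) {
  if (!length(summaries)) ltk_stop("ltk_empty_input", "no batch summaries")
  all <- do.call(rbind, lapply(summaries, as.data.frame))
  avg <- do.call(rbind, lapply(split(all, all$class), function(g) {
    data.frame(class = g$class[1],
               n_entering = mean(g$n_entering),
               n_episodes = mean(g$n_episodes),
               time_ns = mean(g$time_ns),
               n_batches = nrow(g),
               stringsAsFactors = FALSE)
  }))
  avg <- avg[order(match(avg$class, all$class)), , drop = FALSE]
  rownames(avg) <- NULL
  list(per_batch = all, average = avg)
}

#' Ternary-complex overlap windows
#'
#' Maximal frame intervals during which at least one molecule of *every*
#' required substrate class is simultaneously bound — the signature of an
#' enzyme–acceptor–donor ternary complex.
#'
#' @param traces list of `BindingTrace`.
#' @param required character vector of required classes
#'   (default `c("PC", "DHA-TAG")`).
#' @return list with `windows` (data.frame `start`, `end`, `duration_frames`,
#'   `duration_ns`, and comma-separated ids of molecules of each class bound
#'   at some point inside the window), `total_frames`, `total_ns`.
#' @export
ternary_overlap <- function(traces, required = c("PC", "DHA-TAG")) {
  cls <- vapply(traces, `[[`, character(1), "class")
  unknown <- setdiff(required, cls)
  if (length(unknown))
    ltk_stop("ltk_unknown_class", "no traces of class '%s'", unknown[1])
  nf <- length(traces[[1]]$mask)
  dt <- traces[[1]]$timestep_ns
  class_mask <- lapply(required, function(cl) {
    Reduce(`|`, lapply(traces[cls == cl], `[[`, "mask"))
  })
  overlap <- Reduce(`&`, class_mask)
  ev <- segment_events(overlap)
  win <- if (nrow(ev)) {
    ids <- lapply(seq_len(nrow(ev)), function(i) {
      fr <- (ev[i, 1] + 1L):ev[i, 2]
      vapply(required, function(cl) {
        tr <- traces[cls == cl]
        inwin <- vapply(tr, function(t) any(t$mask[fr]), logical(1))
        paste(vapply(tr[inwin], `[[`, character(1), "mol_id"),
              collapse = ",")
      }, character(1))
    })
    df <- data.frame(start = unname(ev[, 1]), end = unname(ev[, 2]),
                     duration_frames = unname(ev[, 2] - ev[, 1]),
                     duration_ns = unname(ev[, 2] - ev[, 1]) * dt)
    for (j in seq_along(required))
      df[[paste0("ids_", required[j])]] <-
        vapply(ids, `[`, character(1), j)
    df
  } else data.frame(start = integer(), end = integer(),
                    duration_frames = integer(), duration_ns = numeric())
  list(windows = win, total_frames = sum(overlap),
       total_ns = sum(overlap) * dt)
}
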