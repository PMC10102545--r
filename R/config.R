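## Run configuration: one document holding the triad spec and every cutoff
## the pipeline uses, serializable to YAML or JSON (by file extension) and
## round-tripping losslessly.

#' Default run configuration
#'
#' Defaults follow the conventional values for lipase screening and pocket
#' analysis: 22.5 A docking box edge, -5.0 kcal/mol and 4.0 A dual screen
#' cutoffs (8 A / negative-affinity prefilter), 15 A pocket-entry cutoff,
#' 0.025 A flexibility cutoff, 8 A contact distance with highlight count 70.
#'
#' @param triad list with `ser`, `his`, `acid` residue keys (may be NULL for
#'   subcommands that do not need a structure).
#' @param seed integer seed.
#' @return a list of class `RunConfig`.
#' @export
run_config <- function(triad = NULL, seed = 1L) {
  structure(list(
    triad = triad,
    screening = list(affinity_le = -5, distance_le = 4,
                     prefilter_distance_lt = 8, prefilter_affinity_lt = 0,
                     prefilter_scope = "all",
                     focus_ligands = c("DHA-TAG", "DUPC")),
    grid_edge = 22.5,
    binding = list(cutoff = 15, debounce = 0, timestep_ns = 0.1,
                   classes = c("PC", "DHA-TAG"), reference = "centroid"),
    flexibility = list(cutoff = 0.025, representative = "CA"),
    contact = list(cutoff = 8, highlight = 70),
    seed = as.integer(seed)),
    class = "RunConfig")
}

#' Read a run configuration from YAML or JSON
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a validated `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    ltk_stop("ltk_missing_file", "config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]]))
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    else cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$triad)) cfg$triad <- raw$triad
  validate_run_config(cfg)
}

#' Write a run configuration to YAML or JSON
#' @param cfg a `RunConfig`.
#' @param path output file; format from extension.
#' @export
write_run_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Validate a run configuration
#' @param cfg a `RunConfig`-shaped list.
#' @return the config, invisibly classed, or an error with a named reason.
#' @export
validate_run_config <- function(cfg) {
  must_pos <- list("binding cutoff" = cfg$binding$cutoff,
                   "grid edge" = cfg$grid_edge,
                   "contact cutoff" = cfg$contact$cutoff,
                   "timestep" = cfg$binding$timestep_ns)
  for (nm in names(must_pos))
    if (!is.numeric(must_pos[[nm]]) || must_pos[[nm]] <= 0)
      ltk_stop("ltk_bad_config", "%s must be positive", nm)
  if (!is.null(cfg$triad)) {
    for (role in c("ser", "his", "acid"))
      if (is.null(cfg$triad[[role]]))
        ltk_stop("ltk_bad_config", "triad spec lacks '%s' residue", role)
  }
  if (!length(cfg$screening$focus_ligands))
    ltk_stop("ltk_bad_config", "focus ligand set must be non-empty")
  class(cfg) <- "RunConfig"
  cfg
}
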