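# Trajectory I/O: plain-text XYZ frames with a JSON energy sidecar, and the
# JSON run manifest that allows bit-for-bit reruns.

#' Write a trajectory as XYZ frames with a JSON energy sidecar
#'
#' Standard multi-frame XYZ text (atom count, comment line, then
#' `species x y z` records at fixed precision) plus a JSON sidecar carrying
#' the per-frame energies and run metadata.
#'
#' @param traj a `gbion_trajectory`.
#' @param path output XYZ file.
#' @param sidecar JSON sidecar path (default `<path>.json`); NULL skips it.
#' @param digits coordinate precision (decimal places).
#' @return (invisibly) the XYZ path.
#' @export
write_traj <- function(traj, path, sidecar = paste0(path, ".json"),
                       digits = 6) {
  stopifnot(inherits(traj, "gbion_trajectory"))
  n <- n_particles(traj$system)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in seq_len(traj$n_frames)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d", f), con)
    p <- matrix(traj$frames[, , f], ncol = 3)
    writeLines(sprintf(fmt, traj$system$species, p[, 1], p[, 2], p[, 3]), con)
  }
  if (!is.null(sidecar)) {
    meta <- list(kind = traj$kind, n_frames = traj$n_frames,
                 seed = traj$config$seed,
                 energies = traj$energies)
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an XYZ trajectory (and its JSON sidecar)
#'
#' A truncated final frame is dropped with a warning stating the number of
#' complete frames read.
#'
#' @param path XYZ file.
#' @param sidecar optional JSON sidecar with per-frame energies.
#' @return list with `frames` (array particle x 3 x frame), `species`,
#'   `n_frames`, and `energies` (data.frame or NULL).
#' @export
read_traj <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty trajectory file: ", path)
  frames <- list(); species <- NULL
  i <- 1; truncated <- FALSE
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) { truncated <- TRUE; break }
    if (i + 1 + n > length(lines)) { truncated <- TRUE; break }
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    if (any(vapply(parts, length, integer(1)) < 4)) { truncated <- TRUE; break }
    sp <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(species)) species <- sp
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  if (!length(frames)) stop("no complete frames in: ", path)
  if (truncated)
    warning("truncated trajectory; read ", length(frames),
            " complete frame(s)", call. = FALSE)
  arr <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  energies <- NULL
  if (!is.null(sidecar) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    energies <- as.data.frame(meta$energies)
  }
  list(frames = arr, species = species, n_frames = length(frames),
       energies = energies)
}

#' Write a run manifest
#'
#' The manifest captures everything needed to reproduce a simulation
#' bit-for-bit: the particle records, the pair-class table, the restraint
#' specification and the full configuration (including the seed).
#'
#' @param system a [particle_system()].
#' @param pair_table a [pair_class_table()].
#' @param restraints a [restraint_spec()] or NULL.
#' @param config a [sim_config()].
#' @param path output JSON file.
#' @return (invisibly) the path.
#' @export
write_manifest <- function(system, pair_table, restraints, config, path) {
  man <- list(
    package = "gbion",
    version = as.character(utils::packageVersion("gbion")),
    records = .system_records(system),
    meta = system$meta,
    gamma = pair_table$gamma, eps_in = pair_table$eps_in,
    eps_out = pair_table$eps_out,
    restraints = if (!is.null(restraints)) unclass(restraints),
    config = unclass(config))
  # I(17) significant digits: doubles survive the JSON round trip exactly
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Re-run a simulation from a manifest
#'
#' @param path manifest JSON written by [write_manifest()].
#' @return a `gbion_trajectory`, identical to the original run.
#' @export
run_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  sys <- particle_system(as.data.frame(man$records))
  sys$meta <- man$meta
  tab <- pair_class_table(gamma = matrix(unlist(man$gamma), 3, 3,
                                         dimnames = list(.topo_classes, .topo_classes)),
                          eps_in = matrix(unlist(man$eps_in), 3, 3,
                                          dimnames = list(.topo_classes, .topo_classes)),
                          eps_out = man$eps_out)
  rst <- if (!is.null(man$restraints)) {
    restraint_spec(anchor = if (is.character(man$restraints$anchor))
                     man$restraints$anchor else as.numeric(man$restraints$anchor),
                   r3 = man$restraints$r3, k = man$restraints$k,
                   applies_to = man$restraints$applies_to)
  }
  cfg <- do.call(sim_config, man$config[setdiff(names(man$config), character(0))])
  run_simulation(sys, tab, rst, cfg)
}
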