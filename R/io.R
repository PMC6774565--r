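## Configuration files, fixtures, and plain-text exporters. All units are
## um (length), s (time), nN (force).

config_schema <- function() {
  list(
    dt = "number", t_end = "number", sample_interval = "number",
    seed = "integer", params = "object", network = "object",
    cells = "array", reduction = "object")
}

#' Load and validate a simulation configuration (JSON)
#'
#' Required top-level fields: `dt`, `t_end`, `sample_interval`, `seed`,
#' `network`, `cells`. Optional: `params` (overrides of
#' [default_params()]), `reduction` (`m_c`, `m_e`, `lambda`). Unknown keys
#' are rejected with their field paths. Defaults are filled into the
#' returned object so that save/load round-trips are stable.
#'
#' @param path JSON file path.
#' @return object of class `ecm_config`.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' Validate a configuration list
#' @param cfg named list (parsed JSON).
#' @return validated, defaults-filled `ecm_config`.
#' @export
validate_config <- function(cfg) {
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  required <- c("dt", "t_end", "sample_interval", "seed", "network", "cells")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("missing required config field(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(cfg$dt) || cfg$dt <= 0) stop("dt: must be a positive number")
  if (!is.numeric(cfg$t_end) || cfg$t_end < cfg$dt) stop("t_end: must be >= dt")
  net <- cfg$network
  net_known <- c("domain", "radius", "length", "lx", "ly", "lz",
                 "boundary_tol", "n_fibers", "segments_per_fiber",
                 "crosslink_radius")
  bad <- setdiff(names(net), net_known)
  if (length(bad)) stop("network: unknown field(s): ", paste(bad, collapse = ", "))
  if (is.null(net$domain) || !net$domain %in% c("cylinder", "box"))
    stop("network.domain: must be 'cylinder' or 'box'")
  cells <- cfg$cells
  if (is.data.frame(cells)) cells <- split(cells, seq_len(nrow(cells)))
  cfg$cells <- lapply(cells, function(cl) {
    ctr <- unlist(cl$center %||% cl[["center"]])
    if (length(ctr) != 3 || !is.numeric(ctr))
      stop("cells[].center: must be a numeric 3-vector")
    list(center = as.numeric(ctr))
  })
  if (!is.null(cfg$params)) {
    do.call(default_params, as.list(cfg$params))   # errors on unknown names
  } else cfg$params <- list()
  red <- cfg$reduction %||% list()
  red$m_c <- red$m_c %||% 50
  red$m_e <- red$m_e %||% 50
  red$lambda <- red$lambda %||% 1e-6
  if (red$m_c < 1 || red$m_e < 1)
    stop("reduction.m_c / reduction.m_e: latent dimension must be >= 1")
  cfg$reduction <- red
  cfg$network$n_fibers <- net$n_fibers %||% 110
  cfg$network$segments_per_fiber <- net$segments_per_fiber %||% 4
  cfg$network$crosslink_radius <- net$crosslink_radius %||% 1
  cfg$network$boundary_tol <- net$boundary_tol %||% 3
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "ecm_config")
}

#' Save a configuration to JSON
#' @param cfg an `ecm_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build the simulation world described by a configuration
#'
#' @param cfg an `ecm_config`.
#' @return list with `world` (a `sim_world`), `net`, `cells`, `sim`
#'   (a `sim_config`) and `params`.
#' @export
build_from_config <- function(cfg) {
  params <- do.call(default_params, as.list(cfg$params))
  dom <- if (cfg$network$domain == "cylinder") {
    cylinder_domain(cfg$network$radius %||% 20, cfg$network$length %||% 100,
                    cfg$network$boundary_tol)
  } else {
    box_domain(cfg$network$lx %||% 125, cfg$network$ly %||% 50,
               cfg$network$lz %||% 25, cfg$network$boundary_tol)
  }
  net <- generate_network(dom, n_fibers = cfg$network$n_fibers,
                          segments_per_fiber = cfg$network$segments_per_fiber,
                          crosslink_radius = cfg$network$crosslink_radius,
                          seed = cfg$seed, params = params)
  cells <- lapply(seq_along(cfg$cells), function(k)
    cell_mesh(cfg$cells[[k]]$center, cell_id = k, params = params))
  pol <- withr_seed(cfg$seed + 1000L, {
    lapply(seq_along(cells), function(k)
      polarity_state(unitize(rnorm(3)), params = params))
  })
  world <- sim_world(net, cells, polarity = pol, params = params)
  sim <- sim_config(dt = cfg$dt, t_end = cfg$t_end,
                    sample_interval = cfg$sample_interval, seed = cfg$seed)
  list(world = world, net = net, cells = cells, sim = sim, params = params,
       reduction = cfg$reduction)
}

#' Write a named study fixture
#'
#' Emits the seeded, reduced-scale configuration reproducing a study
#' scenario:
#' \describe{
#'   \item{toy_spring}{scalar hard-spring system (a, b, D, x0).}
#'   \item{tiny_cylinder}{single cell centred in a 40 um x 100 um cylinder.}
#'   \item{two_cell_cylinder}{two cells placed `spacing` um apart (default
#'     30) on the axis of the same cylinder, flat ends clamped.}
#'   \item{plated_box}{half-scale rectangular gel (125 x 50 x 25 um) with a
#'     5-cell cluster near the left edge and one isolated cell near the
#'     right edge.}
#' }
#' Byte-identical output for a fixed seed.
#'
#' @param name fixture name.
#' @param seed integer seed stored in the config.
#' @param dir output directory.
#' @param spacing cell separation (um) for `two_cell_cylinder`.
#' @param t_end simulated time (s).
#' @return path to the written JSON config.
#' @export
make_fixture <- function(name = c("toy_spring", "tiny_cylinder",
                                  "two_cell_cylinder", "plated_box"),
                         seed = 1L, dir = ".", spacing = 30, t_end = 3000) {
  name <- match.arg(name)
  path <- file.path(dir, paste0(name, ".json"))
  if (name == "toy_spring") {
    jsonlite::write_json(list(a = 1, b = 1, D = 1, x0 = 0.1, t_end = 1,
                              dt = 1e-3, seed = seed),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  base <- list(dt = 0.1, t_end = t_end, sample_interval = 1, seed = seed,
               params = list(),
               reduction = list(m_c = 50, m_e = 50, lambda = 1e-6))
  cfg <- switch(
    name,
    tiny_cylinder = c(base, list(
      network = list(domain = "cylinder", radius = 20, length = 100,
                     boundary_tol = 3, n_fibers = 110, segments_per_fiber = 4,
                     crosslink_radius = 1),
      cells = list(list(center = c(50, 0, 0))))),
    two_cell_cylinder = c(base, list(
      network = list(domain = "cylinder", radius = 20, length = 100,
                     boundary_tol = 3, n_fibers = 110, segments_per_fiber = 4,
                     crosslink_radius = 1),
      cells = list(list(center = c(50 - spacing / 2, 0, 0)),
                   list(center = c(50 + spacing / 2, 0, 0))))),
    plated_box = c(base, list(
      network = list(domain = "box", lx = 125, ly = 50, lz = 25,
                     boundary_tol = 3, n_fibers = 110, segments_per_fiber = 4,
                     crosslink_radius = 1),
      cells = c(lapply(1:5, function(i)
        list(center = c(12 + 8 * ((i - 1) %% 3), 15 + 10 * ((i - 1) %/% 3), 12.5))),
        list(list(center = c(112, 25, 12.5)))))))
  cfg <- validate_config(cfg)
  save_config(cfg, path)
  invisible(path)
}

#' Write points + line segments as legacy VTK polydata (ASCII)
#'
#' @param path output `.vtk` file.
#' @param points n x 3 matrix.
#' @param lines optional m x 2 integer matrix of 1-based point index pairs.
#' @param polygons optional m x 3 integer matrix of 1-based triangles.
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(path, points, lines = NULL, polygons = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "ecmsuper export", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(points))), con)
  utils::write.table(format(points, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(lines) && nrow(lines)) {
    writeLines(sprintf("LINES %d %d", nrow(lines), 3 * nrow(lines)), con)
    utils::write.table(cbind(2L, lines - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  if (!is.null(polygons) && nrow(polygons)) {
    writeLines(sprintf("POLYGONS %d %d", nrow(polygons), 4 * nrow(polygons)), con)
    utils::write.table(cbind(3L, polygons - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export trajectory frames to VTK series + bond tables to CSV
#'
#' Writes `ecm_%04d.vtk` (network polyline geometry), `cell<k>_%04d.vtk`
#' (membrane triangulation) and a long-format `bonds.csv`
#' (`time, cell, i, j, n_int`).
#'
#' @param traj an `ecm_trajectory`.
#' @param dir output directory (created).
#' @param every export every this many frames.
#' @return `dir`, invisibly.
#' @export
export_trajectory <- function(traj, dir, every = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frames <- seq(1, length(traj$times), by = every)
  for (fi in seq_along(frames)) {
    t <- frames[fi]
    write_vtk_polydata(file.path(dir, sprintf("ecm_%04d.vtk", fi)),
                       unflatten_coords(traj$xe[t, ]),
                       lines = traj$net$segments)
    for (k in seq_along(traj$cells)) {
      write_vtk_polydata(file.path(dir, sprintf("cell%d_%04d.vtk", k, fi)),
                         unflatten_coords(traj$xc[[k]][t, ]),
                         polygons = traj$cells[[k]]$triangles)
    }
  }
  if (!is.null(traj$bonds)) {
    rows <- list()
    for (t in seq_along(traj$bonds)) {
      for (k in seq_along(traj$bonds[[t]])) {
        b <- traj$bonds[[t]][[k]]
        if (nrow(b))
          rows[[length(rows) + 1L]] <- cbind(time = traj$times[t], cell = k, b)
      }
    }
    if (length(rows))
      utils::write.csv(do.call(rbind, rows), file.path(dir, "bonds.csv"),
                       row.names = FALSE)
  }
  invisible(dir)
}

#' Write a run manifest
#'
#' Records the provenance of a pipeline stage: a stable hash of the
#' configuration, the seeds in play, the package version, the input/output
#' paths and a timestamp, so that every artifact file is traceable and
#' deterministic stages are reproducible from their manifest alone.
#'
#' @param cfg an `ecm_config` (or any serializable list).
#' @param seeds named integer vector of seeds used by the stage.
#' @param inputs,outputs character vectors of file paths.
#' @param path optional JSON file to write.
#' @return the manifest list, invisibly if written to `path`.
#' @export
run_manifest <- function(cfg, seeds = integer(), inputs = character(),
                         outputs = character(), path = NULL) {
  payload <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  hash <- sprintf("%08x", sum(utf8ToInt(as.character(payload)) *
                                (seq_len(nchar(payload)) %% 97 + 1)) %% .Machine$integer.max)
  man <- list(config_hash = hash,
              seeds = as.list(seeds),
              package_version = as.character(utils::packageVersion("ecmsuper")),
              inputs = inputs, outputs = outputs,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(man))
  }
  man
}
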