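#' Load and validate a run configuration
#'
#' YAML configuration with sections `cell` (diameter, nc, n_vertices and
#' assembly overrides), `thermo` (kBT, dt, steps, seed), `experiment`
#' (kind plus kind-specific parameters) and `output` (path, cadence).
#' Missing values are filled from the calibrated defaults; unknown keys
#' are rejected with a message naming the field.
#'
#' @param path YAML file path.
#' @return validated config list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' @rdname load_config
#' @param config a raw config list.
#' @export
validate_config <- function(config) {
  defaults <- list(
    cell = list(diameter = 16, nc = 0.29, n_vertices = 3500,
                assembly = list()),
    thermo = list(kBT = 1, dt = 1e-3, steps = 5e5, seed = 1),
    experiment = list(kind = "aspiration"),
    output = list(path = "out", cadence = 1000)
  )
  known_exp <- c("kind", "pipette_radius", "gap", "depth", "row_spacing",
                 "pressure_gradient", "max_pressure", "rate", "n_levels",
                 "steps_per_level", "hold", "rotations")
  if (!length(config))
    stop("schema violation: empty config (missing section 'experiment')")
  for (sec in names(config)) {
    if (!sec %in% names(defaults))
      stop("schema violation: unknown section '", sec, "'")
    for (key in names(config[[sec]])) {
      ok <- if (sec == "experiment") known_exp else
        c(names(defaults[[sec]]), if (sec == "cell") "assembly")
      if (!key %in% ok)
        stop("schema violation: unknown field '", sec, ".", key, "'")
    }
  }
  if (is.null(config$experiment))
    stop("schema violation: missing section 'experiment'")
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$experiment$kind %in% c("aspiration", "transit"))
    stop("schema violation: experiment.kind must be aspiration or transit")
  akeys <- names(cfg$cell$assembly)
  bad <- setdiff(akeys, names(formals(assembly_config)))
  if (length(bad))
    stop("schema violation: unknown field 'cell.assembly.", bad[1], "'")
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a trajectory frame
#'
#' `xyz`: plain extended-XYZ text (element = type name).  `vtk`: legacy
#' ASCII VTK polydata with mesh connectivity preserved.  `json`: full
#' checkpoint (positions, velocities, types, box) readable with
#' [read_checkpoint()].
#'
#' @param sys a [particle_system()].
#' @param path output file.
#' @param format "xyz", "vtk" or "json".
#' @param meshes optional list of [tri_mesh] objects (with
#'   `vertex_offset` attributes) for VTK connectivity.
#' @param append append to an existing XYZ trajectory.
#' @export
write_trajectory <- function(sys, path, format = c("xyz", "vtk", "json"),
                             meshes = NULL, append = FALSE) {
  format <- match.arg(format)
  if (format == "xyz") {
    con <- file(path, if (append) "a" else "w")
    on.exit(close(con))
    nm <- names(particle_types)[sys$types]
    writeLines(as.character(nrow(sys$positions)), con)
    writeLines(sprintf("box %.8g %.8g %.8g", sys$box[1], sys$box[2],
                       sys$box[3]), con)
    writeLines(sprintf("%s %.8g %.8g %.8g", nm, sys$positions[, 1],
                       sys$positions[, 2], sys$positions[, 3]), con)
  } else if (format == "vtk") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "dpdcell frame", "ASCII",
                 "DATASET POLYDATA"), con)
    writeLines(sprintf("POINTS %d double", nrow(sys$positions)), con)
    writeLines(sprintf("%.8g %.8g %.8g", sys$positions[, 1],
                       sys$positions[, 2], sys$positions[, 3]), con)
    if (!is.null(meshes)) {
      tris <- do.call(rbind, lapply(meshes, function(m) {
        off <- attr(m, "vertex_offset")
        if (is.null(off)) off <- 0L
        m$tris + off
      }))
      writeLines(sprintf("POLYGONS %d %d", nrow(tris), 4 * nrow(tris)), con)
      writeLines(sprintf("3 %d %d %d", tris[, 1] - 1L, tris[, 2] - 1L,
                         tris[, 3] - 1L), con)
    }
  } else {
    jsonlite::write_json(list(positions = sys$positions,
                              velocities = sys$velocities,
                              types = sys$types, box = sys$box,
                              periodic = sys$periodic, mass = sys$mass),
                         path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read an XYZ frame back into positions
#' @param path XYZ file.
#' @return list(positions, types, box) of the first frame.
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  n <- as.integer(ln[1])
  box <- as.numeric(strsplit(ln[2], "\\s+")[[1]][2:4])
  rows <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  types <- particle_types[vapply(rows, `[[`, character(1), 1)]
  list(positions = pos, types = unname(types), box = box)
}

#' @rdname write_trajectory
#' @export
read_checkpoint <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  particle_system(d$positions, d$velocities, d$types, d$box, d$periodic,
                  d$mass)
}
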