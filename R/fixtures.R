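#' Deterministic reduced-scale test fixtures
#'
#' Named presets small enough for desk-scale testing:
#' \describe{
#'   \item{"fluid-box"}{periodic DPD fluid, density 3, a = 10, gamma = 30,
#'     in a 6x6x6 box.}
#'   \item{"membrane-only"}{a 200-vertex, 6 um membrane mesh.}
#'   \item{"mini-cell"}{a 6 um cell with ~320-vertex surface mesh,
#'     nucleus (NC = 0.29) and a reduced cytoskeleton.}
#'   \item{"mini-device"}{one constriction period (gap 5 um, depth 8 um,
#'     row spacing 16 um).}
#'   \item{"network-box"}{a 6x6x6 um periodic cytoskeleton network at the
#'     default densities.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed; the same seed reproduces the same object.
#' @return the fixture object (a [particle_system()], [tri_mesh],
#'   [build_cell()] bundle, [device_geometry()] or [filament_network()]).
#' @export
make_fixture <- function(name, seed = 1L) {
  presets <- c("fluid-box", "membrane-only", "mini-cell", "mini-device",
               "network-box")
  if (!name %in% presets)
    stop("unknown fixture '", name, "'; presets: ",
         paste(presets, collapse = ", "))
  switch(name,
    "fluid-box" = {
      set.seed(seed)
      box <- c(6, 6, 6)
      n <- round(3 * prod(box))
      particle_system(matrix(stats::runif(3 * n), n, 3) %*% diag(box),
                      matrix(stats::rnorm(3 * n), n, 3), rep(1L, n), box)
    },
    "membrane-only" = make_sphere_mesh(200, 6),
    "mini-cell" = build_cell(
      diameter = 6, nc = 0.29, n_vertices = 320,
      config = assembly_config(polymerize_steps = 2000,
                               cl_max_steps = 2e4, link_max_steps = 1e4,
                               window = 2000),
      seed = seed, box = rep(8, 3)),
    "mini-device" = device_geometry(gap = 5, depth = 8, row_spacing = 16,
                                    side = 5),
    "network-box" = assemble_network(
      rep(6, 3),
      assembly_config(polymerize_steps = 2000, cl_max_steps = 3e4,
                      window = 3000),
      seed = seed)
  )
}
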