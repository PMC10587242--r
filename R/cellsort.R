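# Differential-adhesion cell sorting: a two-type aggregate whose cells
# (surfaces) carry area and perimeter constraints, type-dependent edge
# tension and type-pair adhesion, plus a random motile force on vertices.
# Sorting is tracked by the fractional heterotypic boundary length.

#' Parameters of the cell-sorting model
#'
#' Defaults are the standard parameter set of the model: time step 0.00250,
#' merge distance 0.100 (split distance twice that), random force magnitude
#' 8.94, fixed vertex damping 1.00, target area 1.00 with area parameter
#' 50.0, target perimeter `2 sqrt(pi)` (the perimeter of the unit-area
#' circle) with perimeter parameter 1.00, edge tension 10.0 (type 1) and
#' 20.0 (type 2), and adhesion -18.0 / -26.0 / -38.0 for the 1-1 / 1-2 /
#' 2-2 interfaces.
#'
#' @param grid cells per axis of the initial square aggregate,
#'   `c(n_x, n_y)`.
#' @param type_prob probability a cell is assigned type 1 (fair by default).
#' @param seed RNG seed (type assignment, merge selection, random force).
#' @param dt time step.
#' @param merge_distance,split_distance quality thresholds.
#' @param random_force random vertex force magnitude.
#' @param damping fixed vertex drag M.
#' @param target_area,lambda_area area constraint (both types).
#' @param target_perimeter,lambda_perimeter perimeter constraint (both
#'   types).
#' @param lambda_tension edge tension per type, length 2.
#' @param lambda_adhesion adhesion per interface, named `c(a11, a12, a22)`.
#' @param metric_cadence steps between heterotypic-length samples.
#' @return A parameter list of class `cellsort_params`.
#' @export
cellsort_params <- function(grid = c(10L, 10L), type_prob = 0.5, seed = 1L,
                            dt = 0.00250, merge_distance = 0.100,
                            split_distance = 0.200, random_force = 8.94,
                            damping = 1.00, target_area = 1.00,
                            lambda_area = 50.0,
                            target_perimeter = 2 * sqrt(pi),
                            lambda_perimeter = 1.00,
                            lambda_tension = c(10.0, 20.0),
                            lambda_adhesion = c(a11 = -18.0, a12 = -26.0,
                                                a22 = -38.0),
                            metric_cadence = 100L) {
  structure(as.list(environment()), class = "cellsort_params")
}

#' Build the cell-sorting simulation state
#'
#' Initializes a square aggregate of unit-area quadrilateral cells, assigns
#' each cell independently to one of two types with the seeded RNG, binds
#' the type-level actors and adhesion table, and configures the engine
#' (fixed drag, random vertex force, merge/split quality operations). The
#' heterotypic boundary length at time zero is stored on the state as the
#' normalization reference, so the initial fractional length is 1.
#'
#' @param params a [cellsort_params()] list.
#' @return A `vm_state` with `$het0` set.
#' @export
build_cellsort <- function(params = cellsort_params()) {
  p <- params
  side <- sqrt(p$target_area)
  mesh <- square_grid(p$grid[1], p$grid[2], cell_side = side)
  model <- vm_model()
  for (tp in 1:2) {
    bind_actor(model, surface_area_constraint(p$lambda_area, p$target_area),
               surface_type = tp)
    bind_actor(model,
               perimeter_constraint(p$lambda_perimeter, p$target_perimeter),
               surface_type = tp)
    bind_actor(model, edge_tension(p$lambda_tension[tp], p = 1L),
               surface_type = tp)
  }
  set_adhesion(model, 1L, 1L, p$lambda_adhesion[["a11"]])
  set_adhesion(model, 1L, 2L, p$lambda_adhesion[["a12"]])
  set_adhesion(model, 2L, 2L, p$lambda_adhesion[["a22"]])
  margin <- 3 * max(p$grid) * side
  domain <- rbind(min = c(-margin, -margin, -1),
                  max = c(p$grid[1] * side + margin, p$grid[2] * side + margin, 1))
  cfg <- engine_config(dt = p$dt, domain = domain, fixed_drag = p$damping,
                       seed = p$seed,
                       quality = quality_params(
                         merge_distance = p$merge_distance,
                         split_distance = p$split_distance,
                         insert = TRUE),
                       random_force = p$random_force,
                       metric_cadence = p$metric_cadence)
  st <- vm_state(mesh, model, cfg)
  sids <- surface_ids(mesh)
  mesh$s_type[sids] <- ifelse(stats::runif(length(sids)) < p$type_prob, 1L, 2L)
  st$params <- p
  st$het0 <- heterotypic_length(mesh)
  st
}

#' Run the cell-sorting simulation
#'
#' Advances the state and samples the fractional heterotypic boundary
#' length (heterotypic length divided by its time-zero value) at the
#' configured cadence.
#'
#' @param state a state from [build_cellsort()].
#' @param n_steps number of steps.
#' @return Data frame with `step`, `time` and `frac_het`.
#' @export
run_cellsort <- function(state, n_steps) {
  if (is.null(state$het0) || state$het0 <= 0) {
    stop("state has no positive time-zero heterotypic length", call. = FALSE)
  }
  out <- run_steps(state, n_steps, metric = function(st) {
    pos <- st$mesh$pos[vertex_ids(st$mesh), ]
    if (anyNA(pos) || any(!is.finite(pos))) {
      stop("numerical instability: non-finite vertex position at step ",
           st$nstep, "; reduce dt or the split distance", call. = FALSE)
    }
    c(frac_het = fractional_heterotypic_length(st$mesh, state$het0))
  })
  out
}
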