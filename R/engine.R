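# Simulation engine: force accumulation over all bindings, overdamped
# explicit (forward Euler) integration, quality operations, then events,
# every step.

#' Engine configuration
#'
#' @param dt time step (> 0).
#' @param domain axis-aligned bounding box as a 2 x 3 matrix (rows: min,
#'   max); positions are clamped to it (no-flux boundary). Default is a
#'   practically unbounded box.
#' @param fixed_drag fixed vertex damping coefficient M, or `NA` to use the
#'   variable per-vertex drag from object drag densities.
#' @param seed integer RNG seed; all stochastic elements (random forces,
#'   merge-removal choice, event sampling) draw from the seeded stream, so
#'   equal seeds give bit-identical trajectories.
#' @param quality a [quality_params()] list.
#' @param random_force magnitude of the random vertex force (0 disables); a
#'   fresh uniformly random in-plane unit direction is drawn for every
#'   vertex every step.
#' @param metric_cadence steps between metric samples in [run_steps()].
#' @param events list of events, each `list(cadence = k, fn = function(state))`,
#'   called (in order) every `k` steps after quality operations.
#' @param auto_shape_constraints automatically apply the shape-restoring
#'   constraints to every surface: the convex-polygon constraint (and, in
#'   3D, the flat-surface constraint). These keep cycles simple while
#'   quality operations rearrange the topology; both vanish on flat convex
#'   polygons.
#' @param shape_gain restoring gain of the automatic shape constraints.
#'   Both the restoring force and the fold-deepening force of a stiff
#'   quadratic constraint grow linearly with fold depth, so the gain must
#'   exceed the model's stiffest constraint modulus to win that race at any
#'   depth; the default clears the demonstration models' stiffest modulus
#'   (50) while keeping the explicit integration stable
#'   (`gain * dt << 2`).
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(dt, domain = NULL, fixed_drag = 1.0, seed = 1L,
                          quality = quality_params(), random_force = 0,
                          metric_cadence = 100L, events = list(),
                          auto_shape_constraints = TRUE, shape_gain = 100) {
  stopifnot(dt > 0)
  if (is.null(domain)) {
    domain <- rbind(min = rep(-1e9, 3), max = rep(1e9, 3))
  }
  stopifnot(all(domain[2, ] > domain[1, ]))
  structure(list(dt = dt, domain = domain, fixed_drag = fixed_drag,
                 seed = as.integer(seed), quality = quality,
                 random_force = random_force,
                 metric_cadence = as.integer(metric_cadence), events = events,
                 auto_shape_constraints = isTRUE(auto_shape_constraints),
                 shape_gain = shape_gain),
            class = "engine_config")
}

#' Assemble a simulation state
#'
#' Seeds the RNG and bundles mesh, binding model, configuration and optional
#' particle system into a mutable state object.
#'
#' @param mesh a `vm_mesh`.
#' @param model a `vm_model`.
#' @param config an [engine_config()].
#' @param particles optional [particle_system()].
#' @return An environment of class `vm_state`.
#' @export
vm_state <- function(mesh, model, config, particles = NULL) {
  st <- new.env(parent = emptyenv())
  st$mesh <- mesh
  st$model <- model
  st$config <- config
  st$particles <- particles
  st$time <- 0
  st$nstep <- 0L
  st$ops <- list()
  set.seed(config$seed)
  class(st) <- "vm_state"
  st
}

#' @export
print.vm_state <- function(x, ...) {
  cat(sprintf("<vm_state at step %d (t = %g): ", x$nstep, x$time))
  print(x$mesh)
  invisible(x)
}

#' Number of steps in a simulated duration
#'
#' @param duration simulated time span.
#' @param dt time step.
#' @return Integer step count `round(duration / dt)`.
#' @export
steps_for_duration <- function(duration, dt) {
  as.integer(round(duration / dt))
}

#' Random in-plane vertex force
#'
#' Every live vertex receives `magnitude` times an independent uniformly
#' random unit direction in the xy-plane, redrawn on every call.
#'
#' @param mesh a `vm_mesh`.
#' @param magnitude force magnitude (>= 0).
#' @return An `n x 3` force matrix by vertex id.
#' @export
random_vertex_force <- function(mesh, magnitude) {
  F <- matrix(0, nrow = length(mesh$v_alive), ncol = 3L)
  if (magnitude <= 0) return(F)
  vids <- vertex_ids(mesh)
  ang <- stats::runif(length(vids), 0, 2 * pi)
  F[vids, 1] <- magnitude * cos(ang)
  F[vids, 2] <- magnitude * sin(ang)
  F
}

#' Accumulate all forces of the current state
#'
#' Sums actor bindings, the random vertex force and (for hybrid models)
#' particle potentials, including the particle-vertex coupling bonds.
#'
#' @param state a `vm_state`.
#' @return List with `vertex` (`n x 3` by vertex id) and `particle`
#'   (`m x 3` by particle id, or `NULL`).
#' @export
accumulate_forces <- function(state) {
  F <- mesh_forces(state$mesh, state$model)
  if (state$config$auto_shape_constraints && sum(state$mesh$s_alive) > 0) {
    ge <- geom_eval(state$mesh)
    sids <- surface_ids(state$mesh)
    F <- convex_constraint_add(F, state$mesh, ge, sids,
                               state$config$shape_gain)
    if (state$mesh$dim == 3L) {
      F <- flat_constraint_add(F, state$mesh, sids, state$config$shape_gain)
    }
  }
  if (state$config$random_force > 0) {
    F <- F + random_vertex_force(state$mesh, state$config$random_force)
  }
  Fp <- NULL
  if (!is.null(state$particles)) {
    pf <- particle_forces(state$particles, state$mesh)
    Fp <- pf$particle
    if (nrow(pf$vertex) > 0) {
      n <- min(nrow(F), nrow(pf$vertex))
      F[seq_len(n), ] <- F[seq_len(n), , drop = FALSE] +
        pf$vertex[seq_len(n), , drop = FALSE]
    }
  }
  if (state$mesh$dim == 2L) F[, 3] <- 0
  list(vertex = F, particle = Fp)
}

#' Advance positions one step of overdamped dynamics
#'
#' `r <- r + (f / M) * dt` for every vertex (particles analogously with
#' their own damping), with positions clamped to the domain box and the
#' third coordinate pinned to zero in 2D mode.
#'
#' @param state a `vm_state`.
#' @param forces output of [accumulate_forces()].
#' @export
integrate_step <- function(state, forces) {
  mesh <- state$mesh
  cfg <- state$config
  vids <- vertex_ids(mesh)
  if (length(vids) > 0) {
    if (!is.na(cfg$fixed_drag)) {
      if (cfg$fixed_drag <= 0) stop("zero drag", call. = FALSE)
      M <- cfg$fixed_drag
    } else {
      M <- vapply(vids, function(v) vertex_drag(mesh, v), numeric(1))
    }
    p <- mesh$pos[vids, , drop = FALSE] +
      forces$vertex[vids, , drop = FALSE] / M * cfg$dt
    p <- clamp_box(p, cfg$domain)
    if (mesh$dim == 2L) p[, 3] <- 0
    mesh$pos[vids, ] <- p
  }
  ps <- state$particles
  if (!is.null(ps) && !is.null(forces$particle)) {
    pids <- which(ps$alive)
    p <- ps$pos[pids, , drop = FALSE] +
      forces$particle[pids, , drop = FALSE] / ps$damping[pids] * cfg$dt
    ps$pos[pids, ] <- clamp_box(p, cfg$domain)
  }
  invisible(state)
}

clamp_box <- function(p, domain) {
  for (k in 1:3) {
    p[, k] <- pmin(pmax(p[, k], domain[1, k]), domain[2, k])
  }
  p
}

#' Advance the simulation
#'
#' One `step_state()` performs, in order: force accumulation, overdamped
#' integration, quality operations (using the step's forces), then any due
#' events. `run_steps()` iterates and optionally samples a metric function
#' at a fixed cadence.
#'
#' @param state a `vm_state`.
#' @param n_steps number of steps to execute.
#' @param metric optional `function(state) -> named numeric` sampled every
#'   `cadence` steps (including before the first step).
#' @param cadence sampling cadence in steps; defaults to the config value.
#' @return `step_state`: the state, invisibly. `run_steps`: a data.frame of
#'   metric samples (columns `step`, `time`, then the metric values), empty
#'   when no metric is given.
#' @export
step_state <- function(state) {
  f <- accumulate_forces(state)
  integrate_step(state, f)
  log <- quality_step(state$mesh, f$vertex, state$config$quality)
  for (k in seq_along(log)) {
    rec <- log[[k]]
    if (isTRUE(rec$accepted)) {
      rec$step <- state$nstep + 1L
      state$ops[[length(state$ops) + 1L]] <- rec
    } else {
      # persistent candidates (e.g. a rosette whose split stays in
      # compression) would re-log every step; keep refusals as aggregate
      # counts so long runs stay memory-bounded
      key <- paste(rec$kind, rec$reason, sep = ": ")
      if (is.null(state$refusals)) state$refusals <- integer(0)
      state$refusals[key] <- (if (is.na(state$refusals[key])) 0L
                              else state$refusals[key]) + 1L
    }
  }
  state$nstep <- state$nstep + 1L
  state$time <- state$time + state$config$dt
  for (ev in state$config$events) {
    if (state$nstep %% ev$cadence == 0L) ev$fn(state)
  }
  invisible(state)
}

#' @rdname step_state
#' @export
run_steps <- function(state, n_steps, metric = NULL,
                      cadence = state$config$metric_cadence) {
  samples <- list()
  take <- function() {
    if (is.null(metric)) return()
    samples[[length(samples) + 1L]] <<-
      c(step = state$nstep, time = state$time, metric(state))
  }
  take()
  for (k in seq_len(n_steps)) {
    step_state(state)
    if (!is.null(metric) && state$nstep %% cadence == 0L) take()
  }
  if (length(samples) == 0) return(data.frame())
  as.data.frame(do.call(rbind, samples))
}

#' Write the operation log as JSON lines
#'
#' @param state a `vm_state`.
#' @param path output file; one JSON object per operation record.
#' @export
write_ops_log <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in state$ops) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
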