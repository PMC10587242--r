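# Hybrid vertex-particle cell migration: a single polygonal cell (area
# constraint + harmonic edge tension) crawling over a bead-spring fiber
# substrate via integrin particles. Integrins bond to a fiber segment and to
# the two leading-edge vertices; the cytoskeleton bond's constant-magnitude
# separating force pushes the leading edge forward while anchoring into the
# matrix.

#' Parameters of the cell-migration model
#'
#' Defaults follow the standard parameter set of the hybrid model: time
#' step 0.01; 100 integrins placed within 5-25% of the initial cell
#' circumradius from the leading edge (the printed band `[0.0310, 0.155]`
#' for a unit-area hexagon); cytoskeleton bonds destroyed beyond 0.921;
#' fiber segment counts in `[10, 100]`; substrate width 1.00 and period
#' 4.00; dampings 1.00 (vertices and fiber segments) and 0.100 (integrins);
#' cell energy `1.0 (A - 1)^2 + 0.5 sum |e|^2`; fiber bond parameters
#' (tensile 10.0 at 0.0100, bending 1e-4 at pi, inter-fiber Morse 0.00100 /
#' 12.0 / 0.0200), integrin-fiber bond 1.00 at 0.0100, and cytoskeleton
#' parameter -0.0100.
#'
#' @param seed RNG seed.
#' @param n_steps default run length.
#' @param n_integrins fixed integrin count the lifecycle restores.
#' @param placement_band distances from the leading-edge midpoint eligible
#'   for new integrin anchoring.
#' @param max_bond_length cytoskeleton bond destruction threshold.
#' @param dt,forward,substrate_xlim,density,amplitude,width,period substrate
#'   and engine settings; `density` is fibers per unit channel area.
#' @param segment_range fiber segment-count range.
#' @param damping_vertex,damping_fiber,damping_integrin species dampings.
#' @param target_area,lambda_area,lambda_tension cell energy parameters.
#' @param k_tensile,r0_tensile,k_bending,theta0 fiber bond parameters.
#' @param k_inter,a_inter,r0_inter inter-fiber Morse parameters.
#' @param k_integ,r0_integ integrin-fiber bond parameters.
#' @param k_cyto cytoskeleton bond parameter (negative = protrusive).
#' @param lifecycle_cadence steps between integrin lifecycle events.
#' @return Parameter list of class `migration_params`.
#' @export
migration_params <- function(seed = 1L, n_steps = 2000L, dt = 0.01,
                             n_integrins = 100L,
                             placement_band = c(0.0310, 0.155),
                             max_bond_length = 0.921,
                             segment_range = c(10L, 100L),
                             width = 1.00, period = 4.00, amplitude = 0.4,
                             density = 8, substrate_xlim = c(-1, 5),
                             damping_vertex = 1.00, damping_fiber = 1.00,
                             damping_integrin = 0.100,
                             target_area = 1.00, lambda_area = 1.00,
                             lambda_tension = 0.500,
                             k_tensile = 10.0, r0_tensile = 0.0100,
                             k_bending = 1.00e-4, theta0 = pi,
                             k_inter = 0.00100, a_inter = 12.0,
                             r0_inter = 0.0200, cutoff_inter = 3 * 0.0200,
                             k_integ = 1.00, r0_integ = 0.0100,
                             k_cyto = -0.0100,
                             forward = c(1, 0, 0),
                             lifecycle_cadence = 1L) {
  structure(as.list(environment()), class = "migration_params")
}

#' Leading-edge vertices of a cell
#'
#' The two cycle vertices with the greatest projection on the forward
#' direction; ties resolve to the lower vertex ids.
#'
#' @param mesh a `vm_mesh`.
#' @param surface the cell's surface id.
#' @param forward forward (migration) direction.
#' @return Integer vector of the two vertex ids.
#' @export
leading_edge <- function(mesh, surface, forward = c(1, 0, 0)) {
  cyc <- surface_cycle(mesh, surface)
  proj <- as.numeric(mesh$pos[cyc, , drop = FALSE] %*% as_point3(forward))
  cyc[order(-proj, cyc)][1:2]
}

#' Build the cell-migration simulation state
#'
#' Initializes a unit-area hexagonal cell (two rightmost vertices forming a
#' leading edge) at the channel entrance, scatters the fiber substrate
#' between the two sine walls, configures the inter-fiber pair rule and
#' schedules the integrin lifecycle event. Topology is static for this
#' model (no quality operations).
#'
#' @param params a [migration_params()] list.
#' @return A `vm_state` with `$mig` bookkeeping attached.
#' @export
build_migration <- function(params = migration_params()) {
  p <- params
  R <- hexagon_circumradius(p$target_area)
  mesh <- vm_mesh(2L)
  regular_hexagon(mesh, center = c(0, 0), circumradius = R, phase = pi / 6)
  cell <- surface_ids(mesh)[1]
  model <- vm_model()
  bind_actor(model, surface_area_constraint(p$lambda_area, p$target_area),
             surface_type = 1L)
  bind_actor(model, edge_tension(p$lambda_tension, p = 2L), surface_type = 1L)
  domain <- rbind(min = c(p$substrate_xlim[1] - 2, -p$amplitude - p$width - 2, -1),
                  max = c(p$substrate_xlim[2] + 2, p$amplitude + p$width + 2, 1))
  lifecycle <- list(cadence = p$lifecycle_cadence,
                    fn = function(state) integrin_lifecycle_event(state))
  cfg <- engine_config(dt = p$dt, domain = domain,
                       fixed_drag = p$damping_vertex, seed = p$seed,
                       quality = quality_params(enabled = FALSE),
                       events = list(lifecycle))
  ps <- particle_system()
  st <- vm_state(mesh, model, cfg, particles = ps)
  sine_channel_substrate(ps, width = p$width, period = p$period,
                         amplitude = p$amplitude, density = p$density,
                         xlim = p$substrate_xlim,
                         segment_range = p$segment_range,
                         r0 = p$r0_tensile, k_tensile = p$k_tensile,
                         k_bending = p$k_bending, damping = p$damping_fiber)
  set_interfiber_rule(ps, k = p$k_inter, a = p$a_inter, r0 = p$r0_inter,
                      cutoff = p$cutoff_inter, rebuild_every = 25L)
  st$params <- p
  st$mig <- list(cell = cell, circumradius = R, forward = as_point3(p$forward))
  st
}

#' Create one integrin
#'
#' A live fiber segment particle is selected uniformly at random among
#' those whose distance from the current leading-edge midpoint lies within
#' the placement band; the integrin is placed at that particle's in-plane
#' position, bonded to it, and bonded to both current leading-edge
#' vertices. Returns `NA` (creation deferred) when no segment particle is
#' eligible.
#'
#' @param state a migration `vm_state`.
#' @return The new integrin particle id, or `NA`.
#' @export
create_integrin <- function(state) {
  p <- state$params
  ps <- state$particles
  mesh <- state$mesh
  le <- leading_edge(mesh, state$mig$cell, state$mig$forward)
  fids <- which(ps$alive & ps$species == SPECIES_FIBER)
  if (length(fids) == 0) return(NA_integer_)
  # distance from the leading edge = point-to-segment distance, so anchors
  # spread along the whole edge
  a <- mesh$pos[le[1], 1:2]; b <- mesh$pos[le[2], 1:2]
  ab <- b - a
  tt <- ((ps$pos[fids, 1] - a[1]) * ab[1] + (ps$pos[fids, 2] - a[2]) * ab[2]) /
    max(sum(ab^2), DEGENERATE_TOL)
  tt <- pmin(pmax(tt, 0), 1)
  d <- sqrt((a[1] + tt * ab[1] - ps$pos[fids, 1])^2 +
              (a[2] + tt * ab[2] - ps$pos[fids, 2])^2)
  elig <- fids[d >= p$placement_band[1] & d <= p$placement_band[2]]
  # the integrin sits on the cell above its anchor, so the anchor must lie
  # under the cell polygon
  if (length(elig) > 0) {
    cyc <- surface_cycle(mesh, state$mig$cell)
    elig <- elig[points_in_polygon(ps$pos[elig, 1], ps$pos[elig, 2],
                                   mesh$pos[cyc, 1], mesh$pos[cyc, 2],
                                   tol = 1e-9)]
  }
  if (length(elig) == 0) return(NA_integer_)
  anchor <- elig[sample.int(length(elig), 1L)]
  id <- add_particle(ps, c(ps$pos[anchor, 1], ps$pos[anchor, 2], 0),
                     SPECIES_INTEGRIN, p$damping_integrin)
  ps$integ$i <- c(ps$integ$i, id)
  ps$integ$j <- c(ps$integ$j, anchor)
  ps$integ$k <- c(ps$integ$k, p$k_integ)
  ps$integ$r0 <- c(ps$integ$r0, p$r0_integ)
  ps$integ$alive <- c(ps$integ$alive, TRUE)
  for (v in le) {
    ps$cyto$i <- c(ps$cyto$i, id)
    ps$cyto$v <- c(ps$cyto$v, v)
    ps$cyto$k <- c(ps$cyto$k, p$k_cyto)
    ps$cyto$alive <- c(ps$cyto$alive, TRUE)
  }
  id
}

#' Integrin lifecycle event
#'
#' Runs each event tick: (1) cytoskeleton bonds longer than the maximum
#' bond length are destroyed; (2) integrins outside the cell polygon
#' (points exactly on the boundary are retained) or with both cytoskeleton
#' bonds destroyed are removed along with their fiber bond; (3) new
#' integrins are created until the configured count is restored, deferring
#' when no fiber segment is eligible.
#'
#' @param state a migration `vm_state`.
#' @return The state, invisibly.
#' @export
integrin_lifecycle_event <- function(state) {
  p <- state$params
  ps <- state$particles
  mesh <- state$mesh
  cb <- ps$cyto
  live <- which(cb$alive)
  if (length(live) > 0) {
    r <- row_norms(mesh$pos[cb$v[live], , drop = FALSE] -
                     ps$pos[cb$i[live], , drop = FALSE])
    ps$cyto$alive[live[r > p$max_bond_length]] <- FALSE
  }
  cyc <- surface_cycle(mesh, state$mig$cell)
  px <- mesh$pos[cyc, 1]; py <- mesh$pos[cyc, 2]
  ints <- which(ps$alive & ps$species == SPECIES_INTEGRIN)
  if (length(ints) > 0) {
    nbonds <- tabulate(ps$cyto$i[ps$cyto$alive], nbins = length(ps$alive))[ints]
    inside <- points_in_polygon(ps$pos[ints, 1], ps$pos[ints, 2], px, py,
                                tol = 1e-9)
    gone <- ints[!inside | nbonds == 0L]
    if (length(gone) > 0) {
      free_particle(ps, gone)
      ps$integ$alive[ps$integ$i %in% gone] <- FALSE
      ps$cyto$alive[ps$cyto$i %in% gone] <- FALSE
    }
  }
  compact_bonds(ps)
  deficit <- p$n_integrins - sum(ps$alive & ps$species == SPECIES_INTEGRIN)
  while (deficit > 0) {
    if (is.na(create_integrin(state))) break
    deficit <- deficit - 1L
  }
  invisible(state)
}

#' Run the cell-migration simulation
#'
#' Builds the state, advances it, and reports the cell-centroid trajectory
#' together with the net displacement of every fiber segment particle.
#'
#' @param params a [migration_params()] list.
#' @param trajectory_cadence steps between trajectory samples.
#' @return List with `trajectory` (data frame: step, time, x, y),
#'   `fibers` (data frame: particle, fiber, initial x/y, net displacement,
#'   distance to the cell path) and the final `state`.
#' @export
run_migration <- function(params = migration_params(),
                          trajectory_cadence = 20L) {
  st <- build_migration(params)
  ps <- st$particles
  fids <- which(ps$alive & ps$species == SPECIES_FIBER)
  init_pos <- ps$pos[fids, 1:2, drop = FALSE]
  traj <- run_steps(st, params$n_steps, metric = function(state) {
    cen <- surface_centroid(state$mesh, state$mig$cell)
    c(x = cen[1], y = cen[2])
  }, cadence = trajectory_cadence)
  dxy <- ps$pos[fids, 1:2, drop = FALSE] - init_pos
  disp <- row_norms(cbind(dxy, 0))
  # shape-change displacement: remove each fiber's rigid translation, so
  # bulk drift from inter-fiber adhesion does not mask cell-induced
  # deformation of the fibers
  fib <- ps$cluster[fids]
  drift <- rowsum(dxy, group = fib, reorder = FALSE) /
    as.integer(table(fib)[as.character(unique(fib))])
  deform <- row_norms(cbind(dxy - drift[match(fib, unique(fib)), , drop = FALSE], 0))
  # distance of each particle's initial position to the sampled cell path
  path <- as.matrix(traj[, c("x", "y")])
  d2path <- vapply(seq_along(fids), function(k) {
    min(sqrt((path[, 1] - init_pos[k, 1])^2 + (path[, 2] - init_pos[k, 2])^2))
  }, numeric(1))
  fibers <- data.frame(particle = fids, fiber = ps$cluster[fids],
                       x0 = init_pos[, 1], y0 = init_pos[, 2],
                       displacement = disp, deformation = deform,
                       path_distance = d2path)
  list(trajectory = traj, fibers = fibers, state = st)
}

#' Cell-induced fiber displacement via a matched control run
#'
#' Runs the migration model twice with the same seed: once as configured and
#' once with zero integrins. The substrate realizations are identical and
#' the fiber dynamics share no other stochastic input, so the per-particle
#' difference between final positions isolates exactly the displacement
#' caused by the migrating cell (fibers the cell never touched differ by
#' zero), separating it from the substrate's own relaxation.
#'
#' @param params a [migration_params()] list.
#' @return List with `active` (the full [run_migration()] result) and
#'   `fibers`: the active run's fiber table plus an `induced` column, the
#'   norm of the position difference against the matched control.
#' @export
migration_fiber_response <- function(params = migration_params()) {
  res <- run_migration(params)
  ctl_params <- params
  ctl_params$n_integrins <- 0L
  ctl <- run_migration(ctl_params)
  fid <- res$fibers$particle
  stopifnot(identical(fid, ctl$fibers$particle))
  d <- res$state$particles$pos[fid, 1:2, drop = FALSE] -
    ctl$state$particles$pos[fid, 1:2, drop = FALSE]
  fibers <- res$fibers
  fibers$induced <- sqrt(rowSums(d^2))
  list(active = res, fibers = fibers)
}
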