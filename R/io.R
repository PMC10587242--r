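# File interfaces: Wavefront OBJ polygon import/export, versioned JSON
# state snapshots, and YAML/JSON model configuration.

#' Import a polygon-soup mesh from a Wavefront OBJ file
#'
#' Reads `v` and `f` records (1-based indices; texture/normal slots in
#' `f` entries of the form `a/b/c` are ignored and normals are recomputed
#' from the cycles). One surface is created per face; vertices shared by
#' index become shared mesh vertices, so shared edges follow from shared
#' indices.
#'
#' @param path OBJ file path.
#' @param dim mesh dimensionality (3 by default; use 2 for planar z = 0
#'   polygons).
#' @return A `vm_mesh` of surfaces. Malformed records raise an error citing
#'   the line number.
#' @export
import_obj <- function(path, dim = 3L) {
  lines <- readLines(path, warn = FALSE)
  mesh <- vm_mesh(as.integer(dim))
  vmap <- integer(0)
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] %in% c("", "#")) next
    if (tok[1] == "v") {
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (length(tok) < 4 || anyNA(xyz)) {
        stop("malformed OBJ vertex record at line ", ln, call. = FALSE)
      }
      vmap <- c(vmap, add_vertex(mesh, xyz))
    } else if (tok[1] == "f") {
      idx <- suppressWarnings(as.integer(sub("/.*$", "", tok[-1])))
      if (length(idx) < 3 || anyNA(idx) || any(idx < 1) ||
          any(idx > length(vmap))) {
        stop("malformed OBJ face record at line ", ln, call. = FALSE)
      }
      add_surface(mesh, vmap[idx])
    }
    # other record types (vn, vt, o, g, s, usemtl, ...) are ignored
  }
  mesh
}

#' Export mesh surfaces to a Wavefront OBJ file
#'
#' @param mesh a `vm_mesh`.
#' @param path output path.
#' @export
export_obj <- function(mesh, path) {
  vids <- vertex_ids(mesh)
  remap <- integer(length(mesh$v_alive))
  remap[vids] <- seq_along(vids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$pos[vids, 1], mesh$pos[vids, 2], mesh$pos[vids, 3]),
             con)
  for (s in surface_ids(mesh)) {
    writeLines(paste("f", paste(remap[mesh$s_cycle[[s]]], collapse = " ")), con)
  }
  invisible(path)
}

SNAPSHOT_FORMAT <- 1L

#' Save and load simulation state snapshots (JSON)
#'
#' The snapshot holds the full mesh (positions, cycles, types, bodies with
#' orientation flags), the particle system, simulated time/step and the RNG
#' state, so a loaded run continues identically. The binding model travels
#' with the snapshot as its plain parameter lists.
#'
#' @param state a `vm_state`.
#' @param path snapshot file path.
#' @return `save_state`: the path; `load_state`: a reconstructed `vm_state`.
#' @export
save_state <- function(state, path) {
  mesh <- state$mesh
  snap <- list(
    format = SNAPSHOT_FORMAT,
    dim = mesh$dim,
    time = state$time,
    nstep = state$nstep,
    rng = .Random.seed,
    vertices = list(ids = vertex_ids(mesh),
                    pos = mesh$pos[vertex_ids(mesh), , drop = FALSE]),
    surfaces = lapply(surface_ids(mesh), function(s) {
      list(id = s, type = mesh$s_type[s], cycle = mesh$s_cycle[[s]])
    }),
    bodies = lapply(body_ids(mesh), function(b) {
      list(id = b, type = mesh$b_type[b], surfaces = mesh$b_surfs[[b]],
           alpha = mesh$b_alpha[[b]], drag = mesh$b_drag[b])
    }),
    model = serialize_model(state$model),
    config = state$config[c("dt", "fixed_drag", "seed", "random_force",
                            "metric_cadence", "auto_shape_constraints",
                            "shape_gain")],
    domain = state$config$domain,
    quality = unclass(state$config$quality),
    particles = if (!is.null(state$particles)) {
      ps <- state$particles
      ids <- which(ps$alive)
      list(ids = ids, pos = ps$pos[ids, , drop = FALSE],
           species = ps$species[ids], damping = ps$damping[ids],
           cluster = ps$cluster[ids], tensile = ps$tensile,
           bending = ps$bending, integ = ps$integ, cyto = ps$cyto,
           pair_rule = ps$pair_rule, nl_every = ps$nl_every)
    }
  )
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA,
                       null = "null", always_decimal = FALSE)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  snap <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  if (!identical(as.integer(snap$format), SNAPSHOT_FORMAT)) {
    stop("unsupported snapshot format: ", snap$format, call. = FALSE)
  }
  mesh <- vm_mesh(as.integer(snap$dim))
  vids <- snap$vertices$ids
  pos <- matrix(unlist(snap$vertices$pos), ncol = 3)
  # restore with original ids (pad dead slots)
  nmax <- max(vids)
  mesh$pos <- matrix(0, nrow = nmax, ncol = 3)
  mesh$pos[vids, ] <- pos
  mesh$v_alive <- seq_len(nmax) %in% vids
  mesh$v_surfs <- rep(list(integer(0)), nmax)
  surfs <- snap$surfaces
  smax <- if (length(surfs)) max(vapply(surfs, function(s) s$id, numeric(1))) else 0L
  mesh$s_alive <- logical(smax)
  mesh$s_cycle <- rep(list(integer(0)), smax)
  mesh$s_type <- integer(smax)
  mesh$s_bodies <- rep(list(integer(0)), smax)
  for (s in surfs) {
    id <- as.integer(s$id)
    mesh$s_alive[id] <- TRUE
    mesh$s_cycle[[id]] <- as.integer(s$cycle)
    mesh$s_type[id] <- as.integer(s$type)
    for (v in as.integer(s$cycle)) mesh$v_surfs[[v]] <- c(mesh$v_surfs[[v]], id)
  }
  bodies <- snap$bodies
  bmax <- if (length(bodies)) max(vapply(bodies, function(b) b$id, numeric(1))) else 0L
  mesh$b_alive <- logical(bmax)
  mesh$b_surfs <- rep(list(integer(0)), bmax)
  mesh$b_alpha <- rep(list(numeric(0)), bmax)
  mesh$b_type <- integer(bmax)
  mesh$b_drag <- rep(NA_real_, bmax)
  for (b in bodies) {
    id <- as.integer(b$id)
    mesh$b_alive[id] <- TRUE
    mesh$b_surfs[[id]] <- as.integer(b$surfaces)
    mesh$b_alpha[[id]] <- as.numeric(b$alpha)
    mesh$b_type[id] <- as.integer(b$type)
    mesh$b_drag[id] <- if (is.null(b$drag)) NA_real_ else as.numeric(b$drag)
    for (s in as.integer(b$surfaces)) {
      mesh$s_bodies[[s]] <- c(mesh$s_bodies[[s]], id)
    }
  }
  bump_topo(mesh)
  validate_mesh(mesh)
  model <- deserialize_model(snap$model)
  cfg <- engine_config(dt = snap$config$dt,
                       domain = matrix(unlist(snap$domain), nrow = 2),
                       fixed_drag = if (is.null(snap$config$fixed_drag))
                         NA_real_ else snap$config$fixed_drag,
                       seed = snap$config$seed,
                       quality = do.call(quality_params,
                                         snap$quality[names(snap$quality) %in%
                                                        names(formals(quality_params))]),
                       random_force = snap$config$random_force,
                       metric_cadence = snap$config$metric_cadence,
                       auto_shape_constraints =
                         snap$config$auto_shape_constraints %||% TRUE,
                       shape_gain = snap$config$shape_gain %||% 1.0)
  ps <- NULL
  if (!is.null(snap$particles) && length(snap$particles) > 0) {
    sp <- snap$particles
    ps <- particle_system()
    nmaxp <- max(sp$ids)
    ps$pos <- matrix(0, nrow = nmaxp, ncol = 3)
    ps$pos[sp$ids, ] <- matrix(unlist(sp$pos), ncol = 3)
    ps$alive <- seq_len(nmaxp) %in% sp$ids
    ps$species <- ps$damping <- rep(NA, nmaxp)
    ps$cluster <- rep(NA_integer_, nmaxp)
    ps$species[sp$ids] <- sp$species
    ps$damping[sp$ids] <- sp$damping
    ps$cluster[sp$ids] <- sp$cluster
    as_list <- function(x) lapply(x, function(col) unlist(col) %||% vector(mode(col), 0))
    ps$tensile <- lapply(sp$tensile, as.vector)
    ps$bending <- lapply(sp$bending, as.vector)
    ps$integ <- lapply(sp$integ, as.vector)
    ps$integ$alive <- as.logical(ps$integ$alive)
    ps$cyto <- lapply(sp$cyto, as.vector)
    ps$cyto$alive <- as.logical(ps$cyto$alive)
    ps$pair_rule <- sp$pair_rule
    ps$nl_every <- sp$nl_every
  }
  st <- vm_state(mesh, model, cfg, particles = ps)
  st$time <- snap$time
  st$nstep <- as.integer(snap$nstep)
  rng <- as.integer(unlist(snap$rng))
  assign(".Random.seed", rng, envir = globalenv())
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

serialize_model <- function(model) {
  ser_actors <- function(lst) {
    lapply(lst, function(acts) lapply(acts, unclass))
  }
  list(surface_type_actors = ser_actors(model$surface_type_actors),
       body_type_actors = ser_actors(model$body_type_actors),
       surface_actors = ser_actors(model$surface_actors),
       body_actors = ser_actors(model$body_actors),
       adh2d = model$adh2d, adh3d = model$adh3d)
}

deserialize_model <- function(ser) {
  model <- vm_model()
  de_actor <- function(a) {
    a$tau <- if (!is.null(a$tau)) as.numeric(unlist(a$tau))
    a$force <- if (!is.null(a$force)) as.numeric(unlist(a$force))
    a[vapply(a, is.null, logical(1))] <- NULL
    structure(a, class = "vm_actor")
  }
  de_actors <- function(lst) {
    lapply(lst, function(acts) lapply(acts, de_actor))
  }
  model$surface_type_actors <- de_actors(ser$surface_type_actors)
  model$body_type_actors <- de_actors(ser$body_type_actors)
  model$surface_actors <- de_actors(ser$surface_actors)
  model$body_actors <- de_actors(ser$body_actors)
  to_mat <- function(m) {
    if (is.null(m) || length(m) == 0) return(matrix(numeric(0), 0, 0))
    as.matrix(m)
  }
  model$adh2d <- to_mat(ser$adh2d)
  model$adh3d <- to_mat(ser$adh3d)
  model
}

#' Read a binding model from a YAML or JSON configuration file
#'
#' The configuration lists surface/body types with their actors and
#' adhesion parameters, keyed by the conventional symbols, e.g.
#' \preformatted{
#' surface_types:
#'   - id: 1
#'     area_constraint:      {lambda: 50.0, target: 1.0}
#'     perimeter_constraint: {lambda: 1.0, target: 3.5449077}
#'     edge_tension:         {lambda: 10.0, p: 1}
#' adhesion:
#'   - {types: [1, 1], lambda: -18.0}
#' }
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A `vm_model`.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  model <- vm_model()
  mk <- list(
    area_constraint = function(p) surface_area_constraint(p$lambda, p$target),
    perimeter_constraint = function(p) perimeter_constraint(p$lambda, p$target),
    edge_tension = function(p) edge_tension(p$lambda, p$p %||% 1L),
    surface_traction = function(p) surface_traction(unlist(p$tau)),
    normal_stress = function(p) normal_stress(p$magnitude),
    flat_surface_constraint = function(p) flat_surface_constraint(p$strength %||% 1),
    convex_polygon_constraint = function(p) convex_polygon_constraint(p$strength %||% 1),
    volume_constraint = function(p) body_volume_constraint(p$lambda, p$target),
    body_area_constraint = function(p) body_area_constraint(p$lambda, p$target),
    body_force = function(p) body_force(unlist(p$force)))
  for (tp in cfg$surface_types %||% list()) {
    for (nm in setdiff(names(tp), "id")) {
      if (is.null(mk[[nm]])) stop("unknown actor kind in config: ", nm)
      bind_actor(model, mk[[nm]](tp[[nm]]), surface_type = tp$id)
    }
  }
  for (tp in cfg$body_types %||% list()) {
    for (nm in setdiff(names(tp), "id")) {
      if (is.null(mk[[nm]])) stop("unknown actor kind in config: ", nm)
      bind_actor(model, mk[[nm]](tp[[nm]]), body_type = tp$id)
    }
  }
  for (ad in cfg$adhesion %||% list()) {
    set_adhesion(model, ad$types[[1]], ad$types[[2]], ad$lambda,
                 class = ad$class %||% "surface")
  }
  model
}
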