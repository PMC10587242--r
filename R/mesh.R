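#' Create an empty vertex-model mesh
#'
#' A mesh is the single source of topological truth for a vertex-model
#' simulation. It stores three kinds of objects with stable integer ids:
#' vertices (points carrying the dynamics), surfaces (ordered cycles of three
#' or more vertices forming polygons with straight edges) and bodies
#' (unordered sets of four or more surfaces enclosing a volume). References
#' are kept in both directions: each vertex knows the surfaces it defines and
#' each surface knows the bodies it defines.
#'
#' Coordinates are always 3-vectors. In 2D mode (`dim = 2`) the third
#' coordinate is constrained to zero and the engine zeroes any out-of-plane
#' force component; the cross-product based geometry (normals, areas) is
#' shared between the two modes.
#'
#' The returned object is an environment: mesh-modifying functions update it
#' in place, which is what a simulation engine with dynamic topology needs.
#' Ids of destroyed objects are never reused within a run so that operation
#' priorities keyed on ids are reproducible.
#'
#' @param dim 2 or 3; 2D meshes hold only surfaces, 3D meshes also bodies.
#' @return An object of class `vm_mesh`.
#' @export
vm_mesh <- function(dim = 2L) {
  stopifnot(dim %in% c(2L, 3L))
  m <- new.env(parent = emptyenv())
  m$dim <- as.integer(dim)
  m$pos <- matrix(numeric(0), ncol = 3L)
  m$v_alive <- logical(0)
  m$v_surfs <- list()
  m$s_alive <- logical(0)
  m$s_cycle <- list()
  m$s_type <- integer(0)
  m$s_bodies <- list()       # integer body ids per surface (0-2 of them)
  m$b_alive <- logical(0)
  m$b_surfs <- list()
  m$b_alpha <- list()        # orientation flags, parallel to b_surfs
  m$b_type <- integer(0)
  m$b_drag <- numeric(0)     # drag density rho(B); NA when unset
  m$topo_version <- 0L
  m$cache <- NULL
  class(m) <- "vm_mesh"
  m
}

#' @export
print.vm_mesh <- function(x, ...) {
  cat(sprintf("<vm_mesh %dD: %d vertices, %d surfaces, %d bodies>\n",
              x$dim, sum(x$v_alive), sum(x$s_alive), sum(x$b_alive)))
  invisible(x)
}

bump_topo <- function(mesh) {
  mesh$topo_version <- mesh$topo_version + 1L
  mesh$cache <- NULL
  invisible(mesh)
}

#' Live object ids
#'
#' @param mesh a `vm_mesh`.
#' @return Integer vector of ids of live vertices, surfaces or bodies.
#' @export
vertex_ids <- function(mesh) which(mesh$v_alive)

#' @rdname vertex_ids
#' @export
surface_ids <- function(mesh) which(mesh$s_alive)

#' @rdname vertex_ids
#' @export
body_ids <- function(mesh) which(mesh$b_alive)

check_vertex <- function(mesh, id) {
  if (length(id) != 1L || id < 1L || id > length(mesh$v_alive) ||
      !mesh$v_alive[id]) {
    stop("unknown vertex id: ", id, call. = FALSE)
  }
  invisible(id)
}

check_surface <- function(mesh, id) {
  if (length(id) != 1L || id < 1L || id > length(mesh$s_alive) ||
      !mesh$s_alive[id]) {
    stop("unknown surface id: ", id, call. = FALSE)
  }
  invisible(id)
}

check_body <- function(mesh, id) {
  if (length(id) != 1L || id < 1L || id > length(mesh$b_alive) ||
      !mesh$b_alive[id]) {
    stop("unknown body id: ", id, call. = FALSE)
  }
  invisible(id)
}

#' Add a vertex to a mesh
#'
#' @param mesh a `vm_mesh`.
#' @param position numeric position; a 2-vector is padded with z = 0.
#' @return The new vertex id (invisibly the mesh is updated in place).
#' @export
add_vertex <- function(mesh, position) {
  p <- as_point3(position)
  if (mesh$dim == 2L && abs(p[3]) > DEGENERATE_TOL) {
    stop("2D meshes require z = 0 vertex positions", call. = FALSE)
  }
  mesh$pos <- rbind(mesh$pos, p, deparse.level = 0)
  id <- nrow(mesh$pos)
  mesh$v_alive[id] <- TRUE
  mesh$v_surfs[[id]] <- integer(0)
  bump_topo(mesh)
  id
}

#' Vertex position(s)
#'
#' @param mesh a `vm_mesh`.
#' @param id vertex id(s).
#' @return A 3-vector for a single id, or an n x 3 matrix.
#' @export
vertex_position <- function(mesh, id) {
  if (length(id) == 1L) {
    check_vertex(mesh, id)
    return(mesh$pos[id, ])
  }
  mesh$pos[id, , drop = FALSE]
}

#' Set a vertex position
#' @inheritParams vertex_position
#' @param position new position (2- or 3-vector).
#' @export
set_vertex_position <- function(mesh, id, position) {
  check_vertex(mesh, id)
  mesh$pos[id, ] <- as_point3(position)
  invisible(mesh)
}

#' Add a surface (polygon) to a mesh
#'
#' The cycle lists vertex ids in order; by convention generators emit
#' counter-clockwise cycles whose normal points along +z in 2D. A surface may
#' later be claimed by at most two bodies.
#'
#' @param mesh a `vm_mesh`.
#' @param cycle integer vector of >= 3 distinct vertex ids, in cycle order.
#' @param type surface type id (positive integer tag).
#' @return The new surface id.
#' @export
add_surface <- function(mesh, cycle, type = 1L) {
  cycle <- as.integer(cycle)
  if (length(cycle) < 3L) stop("surface cycle needs >= 3 vertices", call. = FALSE)
  if (anyDuplicated(cycle)) stop("surface cycle repeats a vertex", call. = FALSE)
  for (v in cycle) check_vertex(mesh, v)
  id <- length(mesh$s_alive) + 1L
  mesh$s_alive[id] <- TRUE
  mesh$s_cycle[[id]] <- cycle
  mesh$s_type[id] <- as.integer(type)
  mesh$s_bodies[[id]] <- integer(0)
  for (v in cycle) mesh$v_surfs[[v]] <- c(mesh$v_surfs[[v]], id)
  bump_topo(mesh)
  id
}

#' Surface accessors
#'
#' @param mesh a `vm_mesh`.
#' @param id surface id.
#' @return `surface_cycle`: integer vector of vertex ids; `surface_type`: the
#'   type tag; `surface_bodies`: ids of bodies the surface defines (0-2).
#' @export
surface_cycle <- function(mesh, id) {
  check_surface(mesh, id)
  mesh$s_cycle[[id]]
}

#' @rdname surface_cycle
#' @export
surface_type <- function(mesh, id) {
  check_surface(mesh, id)
  mesh$s_type[id]
}

#' @rdname surface_cycle
#' @export
surface_bodies <- function(mesh, id) {
  check_surface(mesh, id)
  mesh$s_bodies[[id]]
}

#' Surfaces defined by a vertex
#' @param mesh a `vm_mesh`.
#' @param id vertex id.
#' @return Integer vector of surface ids whose cycles contain the vertex.
#' @export
vertex_surfaces <- function(mesh, id) {
  check_vertex(mesh, id)
  mesh$v_surfs[[id]]
}

#' Vertices connected to a vertex by an edge
#'
#' Edges are implicit: two adjacent vertices in any surface cycle are
#' connected. The result is deduplicated.
#'
#' @param mesh a `vm_mesh`.
#' @param id vertex id.
#' @return Integer vector of connected vertex ids (sorted).
#' @export
connected_vertices <- function(mesh, id) {
  check_vertex(mesh, id)
  out <- integer(0)
  for (s in mesh$v_surfs[[id]]) {
    cyc <- mesh$s_cycle[[s]]
    k <- match(id, cyc)
    n <- length(cyc)
    out <- c(out, cyc[if (k == 1L) n else k - 1L], cyc[if (k == n) 1L else k + 1L])
  }
  sort(unique(out))
}

#' Do two surfaces share at least one vertex?
#' @param mesh a `vm_mesh`.
#' @param a,b surface ids.
#' @export
surfaces_connected <- function(mesh, a, b) {
  check_surface(mesh, a); check_surface(mesh, b)
  length(intersect(mesh$s_cycle[[a]], mesh$s_cycle[[b]])) > 0L
}

#' Add a body (closed set of surfaces) to a mesh
#'
#' Orientation flags relating each surface's own normal to the outward
#' direction are computed at construction by testing the sign of the
#' surface's divergence-theorem volume contribution about the body centroid,
#' and stored with the body.
#'
#' @param mesh a `vm_mesh`.
#' @param surfaces integer vector of >= 4 surface ids enclosing a volume.
#' @param type body type id.
#' @param drag_density optional drag density rho(B) >= 0 for variable-drag
#'   dynamics; `NA` (default) means the engine must run in fixed-drag mode.
#' @return The new body id.
#' @export
add_body <- function(mesh, surfaces, type = 1L, drag_density = NA_real_) {
  surfaces <- as.integer(surfaces)
  if (length(surfaces) < 4L) stop("body needs >= 4 surfaces", call. = FALSE)
  if (anyDuplicated(surfaces)) stop("body repeats a surface", call. = FALSE)
  if (mesh$dim != 3L) stop("bodies require a 3D mesh", call. = FALSE)
  for (s in surfaces) {
    check_surface(mesh, s)
    if (length(mesh$s_bodies[[s]]) >= 2L) {
      stop("surface ", s, " already defines two bodies", call. = FALSE)
    }
  }
  id <- length(mesh$b_alive) + 1L
  alpha <- body_orientation_flags(mesh, surfaces)
  mesh$b_alive[id] <- TRUE
  mesh$b_surfs[[id]] <- surfaces
  mesh$b_alpha[[id]] <- alpha
  mesh$b_type[id] <- as.integer(type)
  mesh$b_drag[id] <- drag_density
  for (s in surfaces) mesh$s_bodies[[s]] <- c(mesh$s_bodies[[s]], id)
  bump_topo(mesh)
  vol <- body_volume(mesh, id)
  if (!is.finite(vol) || vol <= 0) {
    stop("body volume is not positive after orientation correction",
         call. = FALSE)
  }
  id
}

# Orientation flag alpha(B, S) per surface: +1 when the surface normal faces
# outward from the body. Determined from the sign of the surface's
# divergence-theorem volume contribution measured about the body centroid.
body_orientation_flags <- function(mesh, surfaces) {
  cents <- t(vapply(surfaces, function(s) surface_centroid(mesh, s), numeric(3)))
  areas <- vapply(surfaces, function(s) surface_area(mesh, s), numeric(1))
  if (sum(areas) <= 0) stop("degenerate body: zero total area", call. = FALSE)
  bc <- colSums(cents * areas) / sum(areas)
  vapply(surfaces, function(s) {
    v <- surface_volume_about(mesh, s, origin = bc)
    if (v >= 0) 1 else -1
  }, numeric(1))
}

#' Body accessors
#' @param mesh a `vm_mesh`.
#' @param id body id.
#' @return `body_surfaces`: surface ids; `body_type`: type tag;
#'   `body_drag_density`: rho(B) or NA.
#' @export
body_surfaces <- function(mesh, id) {
  check_body(mesh, id)
  mesh$b_surfs[[id]]
}

#' @rdname body_surfaces
#' @export
body_type <- function(mesh, id) {
  check_body(mesh, id)
  mesh$b_type[id]
}

#' @rdname body_surfaces
#' @export
body_drag_density <- function(mesh, id) {
  check_body(mesh, id)
  mesh$b_drag[id]
}

#' Vertices of a body
#'
#' The deduplicated union of cycle vertices over the body's surfaces.
#'
#' @param mesh a `vm_mesh`.
#' @param id body id.
#' @return Sorted integer vector of vertex ids.
#' @export
body_vertices <- function(mesh, id) {
  check_body(mesh, id)
  sort(unique(unlist(mesh$s_cycle[mesh$b_surfs[[id]]])))
}

# ---- destruction (internal; used by topology operations) -------------------

drop_surface <- function(mesh, id) {
  for (v in mesh$s_cycle[[id]]) {
    mesh$v_surfs[[v]] <- setdiff(mesh$v_surfs[[v]], id)
  }
  for (b in mesh$s_bodies[[id]]) {
    k <- match(id, mesh$b_surfs[[b]])
    mesh$b_surfs[[b]] <- mesh$b_surfs[[b]][-k]
    mesh$b_alpha[[b]] <- mesh$b_alpha[[b]][-k]
  }
  mesh$s_alive[id] <- FALSE
  mesh$s_cycle[[id]] <- integer(0)
  mesh$s_bodies[[id]] <- integer(0)
  bump_topo(mesh)
}

drop_vertex <- function(mesh, id) {
  if (length(mesh$v_surfs[[id]]) > 0L) {
    stop("cannot drop vertex ", id, ": still defines surfaces", call. = FALSE)
  }
  mesh$v_alive[id] <- FALSE
  bump_topo(mesh)
}

drop_body <- function(mesh, id) {
  for (s in mesh$b_surfs[[id]]) {
    mesh$s_bodies[[s]] <- setdiff(mesh$s_bodies[[s]], id)
  }
  mesh$b_alive[id] <- FALSE
  mesh$b_surfs[[id]] <- integer(0)
  mesh$b_alpha[[id]] <- numeric(0)
  bump_topo(mesh)
}

# Destroy vertices that no longer define any surface.
drop_orphan_vertices <- function(mesh, candidates) {
  for (v in candidates) {
    if (mesh$v_alive[v] && length(mesh$v_surfs[[v]]) == 0L) drop_vertex(mesh, v)
  }
  invisible(mesh)
}

#' Validate mesh integrity
#'
#' Checks referential integrity in both directions, cycle lengths, body
#' sizes, duplicate-free cycles and finite positions. Used by tests and by
#' topology operations, which must each leave the mesh in a valid state.
#'
#' @param mesh a `vm_mesh`.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_mesh <- function(mesh) {
  for (v in vertex_ids(mesh)) {
    if (!all(is.finite(mesh$pos[v, ]))) stop("vertex ", v, ": non-finite position")
    for (s in mesh$v_surfs[[v]]) {
      if (!mesh$s_alive[s]) stop("vertex ", v, " references dead surface ", s)
      if (sum(mesh$s_cycle[[s]] == v) != 1L) {
        stop("vertex ", v, " not exactly once in cycle of surface ", s)
      }
    }
  }
  for (s in surface_ids(mesh)) {
    cyc <- mesh$s_cycle[[s]]
    if (length(cyc) < 3L) stop("surface ", s, ": cycle shorter than 3")
    if (anyDuplicated(cyc)) stop("surface ", s, ": repeated vertex in cycle")
    for (v in cyc) {
      if (!mesh$v_alive[v]) stop("surface ", s, " references dead vertex ", v)
      if (!(s %in% mesh$v_surfs[[v]])) {
        stop("surface ", s, " missing from vertex ", v, " back-reference")
      }
    }
    bs <- mesh$s_bodies[[s]]
    if (length(bs) > 2L) stop("surface ", s, " defines more than two bodies")
    for (b in bs) {
      if (!mesh$b_alive[b]) stop("surface ", s, " references dead body ", b)
      if (!(s %in% mesh$b_surfs[[b]])) {
        stop("surface ", s, " missing from body ", b, " back-reference")
      }
    }
  }
  for (b in body_ids(mesh)) {
    if (length(mesh$b_surfs[[b]]) < 4L) stop("body ", b, ": fewer than 4 surfaces")
    for (s in mesh$b_surfs[[b]]) {
      if (!mesh$s_alive[s]) stop("body ", b, " references dead surface ", s)
      if (!(b %in% mesh$s_bodies[[s]])) {
        stop("body ", b, " missing from surface ", s, " back-reference")
      }
    }
  }
  invisible(TRUE)
}
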