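# Geometric measures on mesh objects. Every surface is treated through its
# fan triangulation: each pair of adjacent cycle vertices forms a triangle
# with the surface centroid, so every cycle vertex defines two triangles.

#' Surface centroid
#'
#' The arithmetic mean of the positions of the vertices in the cycle. All
#' fan triangles of the surface share this point.
#'
#' @param mesh a `vm_mesh`.
#' @param id surface id.
#' @return A 3-vector.
#' @export
surface_centroid <- function(mesh, id) {
  check_surface(mesh, id)
  colMeans(mesh$pos[mesh$s_cycle[[id]], , drop = FALSE])
}

#' Triangle normal from two vertex positions and the surface centroid
#'
#' The cross product of the positions relative to the centroid,
#' `(a - C) x (b - C)`. Not normalized: its norm is twice the triangle
#' area. Degenerate (collinear) input gives the zero vector.
#'
#' @param a,b positions of the two cycle vertices (3-vectors).
#' @param centroid the surface centroid (3-vector).
#' @return A 3-vector.
#' @export
triangle_normal <- function(a, b, centroid) {
  cross3(as_point3(a) - as_point3(centroid), as_point3(b) - as_point3(centroid))
}

#' Triangle area
#'
#' Half the norm of the (unnormalized) triangle normal.
#'
#' @inheritParams triangle_normal
#' @return Scalar area >= 0.
#' @export
triangle_area <- function(a, b, centroid) {
  0.5 * vec_norm(triangle_normal(a, b, centroid))
}

# Unnormalized fan-triangle normals of a surface: one row per cycle vertex,
# for the triangle (vertex, next-vertex, centroid).
surface_tri_normals <- function(mesh, id) {
  cyc <- mesh$s_cycle[[id]]
  p <- mesh$pos[cyc, , drop = FALSE]
  cen <- colMeans(p)
  a <- sweep(p, 2L, cen)
  b <- a[c(2:nrow(a), 1L), , drop = FALSE]
  row_cross(a, b)
}

#' Surface normal
#'
#' The normalized sum of fan-triangle normals. For a planar polygon whose
#' cycle runs counter-clockwise when viewed from the normal direction this is
#' the plane normal.
#'
#' @param mesh a `vm_mesh`.
#' @param id surface id.
#' @return Unit 3-vector.
#' @export
surface_normal <- function(mesh, id) {
  check_surface(mesh, id)
  s <- colSums(surface_tri_normals(mesh, id))
  n <- vec_norm(s)
  if (n < DEGENERATE_TOL) {
    stop("degenerate surface ", id, ": all triangles have zero area",
         call. = FALSE)
  }
  s / n
}

#' Surface area
#'
#' The sum of fan-triangle areas about the centroid.
#'
#' @param mesh a `vm_mesh`.
#' @param id surface id.
#' @return Scalar area >= 0.
#' @export
surface_area <- function(mesh, id) {
  check_surface(mesh, id)
  0.5 * sum(row_norms(surface_tri_normals(mesh, id)))
}

#' Surface perimeter
#'
#' The sum of straight-edge lengths around the cycle.
#'
#' @param mesh a `vm_mesh`.
#' @param id surface id.
#' @return Scalar length.
#' @export
surface_perimeter <- function(mesh, id) {
  check_surface(mesh, id)
  p <- mesh$pos[mesh$s_cycle[[id]], , drop = FALSE]
  sum(row_norms(p[c(2:nrow(p), 1L), , drop = FALSE] - p))
}

#' Vertex area contribution and vertex area
#'
#' Each cycle vertex contributes half the area of each of the two fan
#' triangles it defines, so contributions over a cycle partition the surface
#' area. `vertex_area` sums contributions over all surfaces the vertex
#' defines.
#'
#' @param mesh a `vm_mesh`.
#' @param vertex vertex id.
#' @param surface surface id (vertex must be in its cycle).
#' @return Scalar area.
#' @export
vertex_area_contribution <- function(mesh, vertex, surface) {
  check_vertex(mesh, vertex)
  check_surface(mesh, surface)
  cyc <- mesh$s_cycle[[surface]]
  k <- match(vertex, cyc)
  if (is.na(k)) {
    stop("vertex ", vertex, " is not in the cycle of surface ", surface,
         call. = FALSE)
  }
  areas <- 0.5 * row_norms(surface_tri_normals(mesh, surface))
  n <- length(cyc)
  0.5 * (areas[k] + areas[if (k == 1L) n else k - 1L])
}

#' @rdname vertex_area_contribution
#' @export
vertex_area <- function(mesh, vertex) {
  check_vertex(mesh, vertex)
  sum(vapply(mesh$v_surfs[[vertex]],
             function(s) vertex_area_contribution(mesh, vertex, s),
             numeric(1)))
}

# Divergence-theorem volume contribution of one surface about an origin:
# sum over fan triangles of (1/6) C . eta, with positions shifted by -origin.
surface_volume_about <- function(mesh, id, origin = c(0, 0, 0)) {
  cyc <- mesh$s_cycle[[id]]
  p <- sweep(mesh$pos[cyc, , drop = FALSE], 2L, origin)
  cen <- colMeans(p)
  a <- sweep(p, 2L, cen)
  b <- a[c(2:nrow(a), 1L), , drop = FALSE]
  eta <- row_cross(a, b)
  sum(eta %*% cen) / 6
}

#' Body surface area and centroid
#'
#' The body area is the sum of its surfaces' areas; the centroid is the
#' area-weighted mean of the surface centroids.
#'
#' @param mesh a `vm_mesh`.
#' @param id body id.
#' @return `body_area`: scalar; `body_centroid`: 3-vector.
#' @export
body_area <- function(mesh, id) {
  check_body(mesh, id)
  sum(vapply(mesh$b_surfs[[id]], function(s) surface_area(mesh, s), numeric(1)))
}

#' @rdname body_area
#' @export
body_centroid <- function(mesh, id) {
  check_body(mesh, id)
  ss <- mesh$b_surfs[[id]]
  areas <- vapply(ss, function(s) surface_area(mesh, s), numeric(1))
  tot <- sum(areas)
  if (tot <= 0) stop("degenerate body ", id, ": zero total area", call. = FALSE)
  cents <- t(vapply(ss, function(s) surface_centroid(mesh, s), numeric(3)))
  colSums(cents * areas) / tot
}

#' Body volume (divergence theorem)
#'
#' Signed fan-triangle volume contributions are summed over the body's
#' surfaces with the stored orientation flags, so that all surface normals
#' are treated as outward-facing. Positive for a valid body.
#'
#' @param mesh a `vm_mesh`.
#' @param id body id.
#' @return Scalar volume > 0.
#' @export
body_volume <- function(mesh, id) {
  check_body(mesh, id)
  ss <- mesh$b_surfs[[id]]
  al <- mesh$b_alpha[[id]]
  sum(vapply(seq_along(ss), function(k) {
    al[k] * surface_volume_about(mesh, ss[k])
  }, numeric(1)))
}

#' Vertex volume contribution and vertex volume
#'
#' A vertex's volume contribution to a body is the body volume times the
#' vertex's share of the body surface area (its summed area contributions
#' over the body's surfaces divided by the body area). `vertex_volume` sums
#' contributions over every body whose vertex set contains the vertex.
#'
#' @param mesh a `vm_mesh`.
#' @param vertex vertex id.
#' @param body body id.
#' @return Scalar volume.
#' @export
vertex_volume_contribution <- function(mesh, vertex, body) {
  check_vertex(mesh, vertex)
  check_body(mesh, body)
  ss <- mesh$b_surfs[[body]]
  mine <- intersect(mesh$v_surfs[[vertex]], ss)
  if (length(mine) == 0L) {
    stop("vertex ", vertex, " is not part of body ", body, call. = FALSE)
  }
  a <- sum(vapply(mine, function(s) vertex_area_contribution(mesh, vertex, s),
                  numeric(1)))
  body_volume(mesh, body) / body_area(mesh, body) * a
}

#' @rdname vertex_volume_contribution
#' @export
vertex_volume <- function(mesh, vertex) {
  check_vertex(mesh, vertex)
  bodies <- unique(unlist(mesh$s_bodies[mesh$v_surfs[[vertex]]]))
  if (length(bodies) == 0L) return(0)
  sum(vapply(bodies, function(b) vertex_volume_contribution(mesh, vertex, b),
             numeric(1)))
}

#' Vertex drag
#'
#' In fixed-drag mode every vertex has the constant drag `fixed`. In
#' variable-drag mode the drag is the sum over bodies (2D: surfaces) the
#' vertex defines of the object's drag density times the vertex's volume
#' (2D: area) contribution to it.
#'
#' @param mesh a `vm_mesh`.
#' @param vertex vertex id.
#' @param fixed fixed damping coefficient M, or `NA` for variable drag.
#' @return Scalar drag > 0.
#' @export
vertex_drag <- function(mesh, vertex, fixed = NA_real_) {
  check_vertex(mesh, vertex)
  if (!is.na(fixed)) return(fixed)
  if (mesh$dim == 3L) {
    bodies <- unique(unlist(mesh$s_bodies[mesh$v_surfs[[vertex]]]))
    if (length(bodies) == 0L) stop("vertex ", vertex, " has no drag source")
    rho <- mesh$b_drag[bodies]
    if (anyNA(rho)) stop("body without drag density in variable-drag mode")
    m <- sum(rho * vapply(bodies, function(b) {
      vertex_volume_contribution(mesh, vertex, b)
    }, numeric(1)))
  } else {
    ss <- mesh$v_surfs[[vertex]]
    if (length(ss) == 0L) stop("vertex ", vertex, " has no drag source")
    rho <- mesh$s_drag[ss]
    if (is.null(rho) || anyNA(rho)) {
      stop("surface without drag density in variable-drag mode")
    }
    m <- sum(rho * vapply(ss, function(s) {
      vertex_area_contribution(mesh, vertex, s)
    }, numeric(1)))
  }
  if (m <= 0) stop("vertex ", vertex, ": zero drag", call. = FALSE)
  m
}

#' Set surface drag densities for 2D variable-drag dynamics
#'
#' @param mesh a `vm_mesh`.
#' @param ids surface ids.
#' @param rho drag density values (recycled).
#' @export
set_surface_drag <- function(mesh, ids, rho) {
  if (is.null(mesh$s_drag)) mesh$s_drag <- rep(NA_real_, length(mesh$s_alive))
  length(mesh$s_drag) <- length(mesh$s_alive)
  mesh$s_drag[ids] <- rho
  invisible(mesh)
}
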