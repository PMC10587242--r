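# Shared fixtures and oracles, all built in code.

# Random star-shaped polygon around the origin (2D mesh, one surface).
random_polygon_mesh <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # radii close to 1 keep the polygon star-shaped about its centroid, so
  # the fan triangulation does not fold (the methodology targets convex
  # polygons)
  ang <- 2 * pi * (seq_len(n) - 1) / n +
    stats::runif(n, -0.25, 0.25) * 2 * pi / n
  r <- stats::runif(n, 0.9, 1.1)
  m <- vm_mesh(2L)
  ids <- vapply(seq_len(n), function(k) {
    add_vertex(m, c(r[k] * cos(ang[k]), r[k] * sin(ang[k]), 0))
  }, integer(1))
  add_surface(m, ids)
  m
}

# Shoelace area of a planar polygon given as an n x 2 matrix (CCW positive).
shoelace_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  0.5 * abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]))
}

# Axis-aligned box as a closed 6-face body.
box_mesh <- function(lx = 1, ly = 1, lz = 1, origin = c(0, 0, 0)) {
  m <- vm_mesh(3L)
  v <- array(0L, c(2, 2, 2))
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    v[i + 1, j + 1, k + 1] <- add_vertex(m, origin + c(i * lx, j * ly, k * lz))
  }
  f <- c(
    add_surface(m, c(v[1,1,1], v[2,1,1], v[2,2,1], v[1,2,1])),   # z = 0
    add_surface(m, c(v[1,1,2], v[2,1,2], v[2,2,2], v[1,2,2])),   # z = lz
    add_surface(m, c(v[1,1,1], v[2,1,1], v[2,1,2], v[1,1,2])),   # y = 0
    add_surface(m, c(v[1,2,1], v[2,2,1], v[2,2,2], v[1,2,2])),   # y = ly
    add_surface(m, c(v[1,1,1], v[1,2,1], v[1,2,2], v[1,1,2])),   # x = 0
    add_surface(m, c(v[2,1,1], v[2,2,1], v[2,2,2], v[2,1,2])))   # x = lx
  body <- add_body(m, f)
  list(mesh = m, body = body, faces = f, corners = v)
}

# Two unit cubes sharing one face (x in [0,1] and [1,2]).
two_cube_mesh <- function(type1 = 1L, type2 = 2L) {
  m <- vm_mesh(3L)
  v <- array(0L, c(3, 2, 2))
  for (i in 0:2) for (j in 0:1) for (k in 0:1) {
    v[i + 1, j + 1, k + 1] <- add_vertex(m, c(i, j, k))
  }
  quad <- function(a, b, cc, d) add_surface(m, c(a, b, cc, d))
  shared <- quad(v[2,1,1], v[2,2,1], v[2,2,2], v[2,1,2])          # x = 1
  f1 <- c(quad(v[1,1,1], v[2,1,1], v[2,2,1], v[1,2,1]),
          quad(v[1,1,2], v[2,1,2], v[2,2,2], v[1,2,2]),
          quad(v[1,1,1], v[2,1,1], v[2,1,2], v[1,1,2]),
          quad(v[1,2,1], v[2,2,1], v[2,2,2], v[1,2,2]),
          quad(v[1,1,1], v[1,2,1], v[1,2,2], v[1,1,2]),
          shared)
  f2 <- c(quad(v[2,1,1], v[3,1,1], v[3,2,1], v[2,2,1]),
          quad(v[2,1,2], v[3,1,2], v[3,2,2], v[2,2,2]),
          quad(v[2,1,1], v[3,1,1], v[3,1,2], v[2,1,2]),
          quad(v[2,2,1], v[3,2,1], v[3,2,2], v[2,2,2]),
          shared,
          quad(v[3,1,1], v[3,2,1], v[3,2,2], v[3,1,2]))
  b1 <- add_body(m, f1, type = type1)
  b2 <- add_body(m, f2, type = type2)
  list(mesh = m, b1 = b1, b2 = b2, shared = shared)
}

# Regular tetrahedron with edge length 1 as a closed body.
tetrahedron_mesh <- function() {
  m <- vm_mesh(3L)
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
             c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  ids <- vapply(1:4, function(k) add_vertex(m, p[k, ]), integer(1))
  f <- c(add_surface(m, ids[c(1, 2, 3)]),
         add_surface(m, ids[c(1, 2, 4)]),
         add_surface(m, ids[c(2, 3, 4)]),
         add_surface(m, ids[c(1, 3, 4)]))
  body <- add_body(m, f)
  list(mesh = m, body = body)
}

# Tetrahedral-decomposition volume oracle: fan every face about its own
# centroid and sum |det| / 6 of tetrahedra to the body centroid. Valid for
# bodies star-shaped about the centroid; independent of the signed
# divergence-theorem path.
tet_decomposition_volume <- function(mesh, body) {
  bc <- body_centroid(mesh, body)
  tot <- 0
  for (s in body_surfaces(mesh, body)) {
    cyc <- surface_cycle(mesh, s)
    p <- vertex_position(mesh, cyc)
    cen <- colMeans(p)
    n <- nrow(p)
    for (k in seq_len(n)) {
      a <- p[k, ] - bc
      b <- p[if (k == n) 1L else k + 1L, ] - bc
      cc <- cen - bc
      tot <- tot + abs(det(rbind(a, b, cc))) / 6
    }
  }
  tot
}

# Proper random rotation matrix (det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid_motion <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  vids <- vertex_ids(mesh)
  mesh$pos[vids, ] <- mesh$pos[vids, , drop = FALSE] %*% t(R) +
    matrix(t, length(vids), 3, byrow = TRUE)
  bump_topo(mesh)
  mesh
}

# Central finite-difference check of an actor's analytic force against its
# energy; returns the max relative error over all vertices and coordinates.
fd_force_error <- function(mesh, actor, id, h = 1e-6) {
  Fa <- actor_forces(mesh, actor, id)
  dims <- if (mesh$dim == 2L) 1:2 else 1:3
  maxrel <- 0
  for (v in vertex_ids(mesh)) {
    for (k in dims) {
      p0 <- mesh$pos[v, k]
      mesh$pos[v, k] <- p0 + h
      ep <- actor_energy(mesh, actor, id)
      mesh$pos[v, k] <- p0 - h
      em <- actor_energy(mesh, actor, id)
      mesh$pos[v, k] <- p0
      fd <- -(ep - em) / (2 * h)
      maxrel <- max(maxrel, abs(fd - Fa[v, k]) /
                      max(abs(fd), abs(Fa[v, k]), 1e-3))
    }
  }
  maxrel
}

# Same check against the full binding-model energy.
fd_model_force_error <- function(mesh, model, h = 1e-6) {
  Fa <- mesh_forces(mesh, model)
  dims <- if (mesh$dim == 2L) 1:2 else 1:3
  maxrel <- 0
  for (v in vertex_ids(mesh)) {
    for (k in dims) {
      p0 <- mesh$pos[v, k]
      mesh$pos[v, k] <- p0 + h
      ep <- mesh_energy(mesh, model)
      mesh$pos[v, k] <- p0 - h
      em <- mesh_energy(mesh, model)
      mesh$pos[v, k] <- p0
      fd <- -(ep - em) / (2 * h)
      maxrel <- max(maxrel, abs(fd - Fa[v, k]) /
                      max(abs(fd), abs(Fa[v, k]), 1e-3))
    }
  }
  maxrel
}

# Jitter vertex positions in-plane (2D) or in space (3D).
jitter_mesh <- function(mesh, sd = 0.05) {
  vids <- vertex_ids(mesh)
  k <- if (mesh$dim == 2L) 1:2 else 1:3
  mesh$pos[vids, k] <- mesh$pos[vids, k, drop = FALSE] +
    matrix(stats::rnorm(length(vids) * length(k), 0, sd), ncol = length(k))
  bump_topo(mesh)
  mesh
}
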