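test_that("surface centroid is the cycle mean and translates with the mesh", {
  m <- vm_mesh(2L)
  ids <- vapply(list(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), function(p) {
    add_vertex(m, c(p, 0))
  }, integer(1))
  s <- add_surface(m, ids)
  expect_equal(surface_centroid(m, s), c(0.5, 0.5, 0))

  m2 <- vm_mesh(2L)
  ids2 <- vapply(list(c(0, 0), c(2, 0), c(2, 1), c(0, 3)), function(p) {
    add_vertex(m2, c(p, 0))
  }, integer(1))
  s2 <- add_surface(m2, ids2)
  expect_equal(surface_centroid(m2, s2), c(1, 1, 0))
  # translation equivariance
  m2$pos[vertex_ids(m2), 1] <- m2$pos[vertex_ids(m2), 1] + 3.5
  m2$pos[vertex_ids(m2), 2] <- m2$pos[vertex_ids(m2), 2] - 1.25
  expect_equal(surface_centroid(m2, s2), c(4.5, -0.25, 0))
  expect_error(surface_centroid(m2, 99L), "unknown surface")
})

test_that("triangle normal is the unnormalized cross product", {
  expect_equal(triangle_normal(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)),
               c(0, 0, 1))
  # antisymmetry and degenerate collinear input
  expect_equal(triangle_normal(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)),
               c(0, 0, -1))
  expect_equal(triangle_normal(c(1, 1, 1), c(2, 2, 2), c(0, 0, 0)),
               c(0, 0, 0))
  # norm is twice the triangle area
  expect_equal(triangle_area(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)), 0.5)
})

test_that("surface normal is unit, follows cycle orientation, flips on reversal", {
  m <- vm_mesh(2L)
  ids <- vapply(list(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), function(p) {
    add_vertex(m, c(p, 0))
  }, integer(1))
  s <- add_surface(m, ids)
  expect_equal(surface_normal(m, s), c(0, 0, 1))
  s2 <- add_surface(m, rev(ids))
  expect_equal(surface_normal(m, s2), c(0, 0, -1))

  # mildly non-planar quad: unit norm, positive dot with every triangle normal
  m3 <- vm_mesh(3L)
  ids3 <- vapply(list(c(0, 0, 0), c(1, 0, 0.1), c(1, 1, 0), c(0, 1, -0.07)),
                 function(p) add_vertex(m3, p), integer(1))
  s3 <- add_surface(m3, ids3)
  nrm <- surface_normal(m3, s3)
  expect_equal(sum(nrm^2), 1)
  cen <- surface_centroid(m3, s3)
  p <- vertex_position(m3, surface_cycle(m3, s3))
  for (k in 1:4) {
    tn <- triangle_normal(p[k, ], p[if (k == 4) 1 else k + 1, ], cen)
    expect_gt(sum(tn * nrm), 0)
  }
})

test_that("fan-triangulation area matches closed forms and the shoelace oracle", {
  m <- vm_mesh(2L)
  regular_hexagon(m, circumradius = 1)
  expect_equal(surface_area(m, 1), 3 * sqrt(3) / 2, tolerance = 1e-12)
  # unit-area hexagon and its circumradius closed form
  R1 <- hexagon_circumradius(1)
  expect_equal(R1, 0.6204032394013997, tolerance = 1e-12)
  m1 <- vm_mesh(2L)
  regular_hexagon(m1, circumradius = R1)
  expect_equal(surface_area(m1, 1), 1, tolerance = 1e-12)
  expect_equal(surface_perimeter(m1, 1), 6 * R1, tolerance = 1e-12)

  for (seed in 1:8) {
    mp <- random_polygon_mesh(5 + seed %% 4, seed = seed)
    p <- vertex_position(mp, surface_cycle(mp, 1))
    expect_equal(surface_area(mp, 1), shoelace_area(p[, 1:2]),
                 tolerance = 1e-9)
    # reversed cycle preserves area and perimeter, flips normal
    mr <- vm_mesh(2L)
    idr <- vapply(rev(seq_len(nrow(p))), function(k) add_vertex(mr, p[k, ]),
                  integer(1))
    add_surface(mr, idr)
    expect_equal(surface_area(mr, 1), surface_area(mp, 1), tolerance = 1e-12)
    expect_equal(surface_perimeter(mr, 1), surface_perimeter(mp, 1),
                 tolerance = 1e-12)
    expect_equal(surface_normal(mr, 1), -surface_normal(mp, 1),
                 tolerance = 1e-12)
  }
})

test_that("perimeter sums straight edge lengths, zero-length edges count zero", {
  m <- square_grid(1, 1)
  expect_equal(surface_perimeter(m, 1), 4)
  # degenerate pair of coincident vertices
  m2 <- vm_mesh(2L)
  ids <- vapply(list(c(0, 0), c(1, 0), c(1, 0), c(0, 1)), function(p) {
    add_vertex(m2, c(p, 0))
  }, integer(1))
  add_surface(m2, ids)
  expect_equal(surface_perimeter(m2, 1), 1 + sqrt(2) + 1)
})

test_that("vertex area contributions partition the surface area", {
  m <- square_grid(1, 1)
  for (v in surface_cycle(m, 1)) {
    expect_equal(vertex_area_contribution(m, v, 1), 0.25)
  }
  expect_error(vertex_area_contribution(m, 1, 2), "unknown surface")

  for (seed in 1:6) {
    mp <- random_polygon_mesh(6, seed = 100 + seed)
    cyc <- surface_cycle(mp, 1)
    contribs <- vapply(cyc, function(v) vertex_area_contribution(mp, v, 1),
                       numeric(1))
    expect_equal(sum(contribs), surface_area(mp, 1), tolerance = 1e-12)
    # per-vertex value equals half the area of its two fan triangles
    cen <- surface_centroid(mp, 1)
    p <- vertex_position(mp, cyc)
    n <- nrow(p)
    for (k in seq_len(n)) {
      t1 <- triangle_area(p[k, ], p[if (k == n) 1 else k + 1, ], cen)
      t2 <- triangle_area(p[if (k == 1) n else k - 1, ], p[k, ], cen)
      expect_equal(vertex_area_contribution(mp, cyc[k], 1), 0.5 * (t1 + t2),
                   tolerance = 1e-12)
    }
  }
  # vertex_area sums over all defining surfaces
  mg <- square_grid(2, 2)
  center <- which(apply(mg$pos, 1, function(p) all(p[1:2] == c(1, 1))))
  expect_equal(vertex_area(mg, center), 4 * 0.25)
})

test_that("body area, centroid and volume match closed forms", {
  bx <- box_mesh(1, 2, 3)
  expect_equal(body_area(bx$mesh, bx$body), 22)
  expect_equal(body_centroid(bx$mesh, bx$body), c(0.5, 1, 1.5))
  expect_equal(body_volume(bx$mesh, bx$body), 6, tolerance = 1e-12)

  cb <- box_mesh()
  expect_equal(body_area(cb$mesh, cb$body), 6)
  expect_equal(body_volume(cb$mesh, cb$body), 1, tolerance = 1e-12)

  tt <- tetrahedron_mesh()
  expect_equal(body_volume(tt$mesh, tt$body), 1 / (6 * sqrt(2)),
               tolerance = 1e-9)

  # volume is invariant to rigid translation (divergence-theorem property)
  for (off in list(c(10, 0, 0), c(-3, 7, 2), c(0.1, -0.2, 100))) {
    bx2 <- box_mesh(1, 2, 3)
    apply_rigid_motion(bx2$mesh, t = off)
    expect_equal(body_volume(bx2$mesh, bx2$body), 6, tolerance = 1e-9)
  }
})

test_that("vertex volume contributions conserve the body volume", {
  cb <- box_mesh()
  for (v in body_vertices(cb$mesh, cb$body)) {
    expect_equal(vertex_volume_contribution(cb$mesh, v, cb$body), 1 / 8,
                 tolerance = 1e-12)
  }
  bx <- box_mesh(2, 1, 0.5)
  vs <- body_vertices(bx$mesh, bx$body)
  contribs <- vapply(vs, function(v) {
    vertex_volume_contribution(bx$mesh, v, bx$body)
  }, numeric(1))
  expect_equal(sum(contribs), body_volume(bx$mesh, bx$body),
               tolerance = 1e-12)
  # proportional to per-vertex area shares
  shares <- vapply(vs, function(v) {
    sum(vapply(intersect(vertex_surfaces(bx$mesh, v),
                         body_surfaces(bx$mesh, bx$body)),
               function(s) vertex_area_contribution(bx$mesh, v, s),
               numeric(1)))
  }, numeric(1))
  expect_equal(contribs / sum(contribs), shares / sum(shares),
               tolerance = 1e-12)
  expect_error(vertex_volume_contribution(cb$mesh, 1, 99), "unknown body")
})

test_that("vertex drag follows drag densities and conserves rho * V", {
  cb <- box_mesh()
  # fixed-drag mode
  expect_equal(vertex_drag(cb$mesh, 1, fixed = 1.0), 1.0)
  # variable drag via the body drag density
  m <- vm_mesh(3L)
  bx <- box_mesh()
  bx$mesh$b_drag[bx$body] <- 2.5
  drags <- vapply(body_vertices(bx$mesh, bx$body), function(v) {
    vertex_drag(bx$mesh, v)
  }, numeric(1))
  expect_equal(drags, rep(2.5 / 8, 8), tolerance = 1e-12)
  expect_equal(sum(drags), 2.5 * body_volume(bx$mesh, bx$body),
               tolerance = 1e-12)
  # 2D analogue with surface drag densities
  m2 <- square_grid(1, 1)
  set_surface_drag(m2, 1, 3)
  expect_equal(vertex_drag(m2, 1), 3 * 0.25, tolerance = 1e-12)
})

test_that("body vertex sets deduplicate shared vertices", {
  cb <- box_mesh()
  expect_length(body_vertices(cb$mesh, cb$body), 8)
  tc <- two_cube_mesh()
  expect_length(body_vertices(tc$mesh, tc$b1), 8)
  shared_vs <- surface_cycle(tc$mesh, tc$shared)
  expect_true(all(shared_vs %in% body_vertices(tc$mesh, tc$b1)))
  expect_true(all(shared_vs %in% body_vertices(tc$mesh, tc$b2)))
  # pentagonal prism: 10 vertices over 7 surfaces
  ang <- pi / 2 + (0:4) * 2 * pi / 5
  pent <- cbind(cos(ang), sin(ang))
  pr <- extruded_prism(pent, 1)
  expect_length(body_surfaces(pr$mesh, pr$body), 7)
  expect_length(body_vertices(pr$mesh, pr$body), 10)
})

test_that("all measures are rigid-motion invariant/equivariant", {
  set.seed(11)
  for (rep in 1:5) {
    mp <- random_polygon_mesh(7, seed = 200 + rep)
    a0 <- surface_area(mp, 1)
    p0 <- surface_perimeter(mp, 1)
    c0 <- surface_centroid(mp, 1)
    n0 <- surface_normal(mp, 1)
    R <- random_rotation()
    tv <- stats::rnorm(3)
    # rotations move 2D polygons out of plane; re-declare as 3D
    mp$dim <- 3L
    apply_rigid_motion(mp, R, tv)
    expect_equal(surface_area(mp, 1), a0, tolerance = 1e-10)
    expect_equal(surface_perimeter(mp, 1), p0, tolerance = 1e-10)
    expect_equal(surface_centroid(mp, 1), as.numeric(R %*% c0 + tv),
                 tolerance = 1e-10)
    expect_equal(surface_normal(mp, 1), as.numeric(R %*% n0),
                 tolerance = 1e-8)
  }
  bx <- box_mesh(1.3, 0.7, 2.1)
  v0 <- body_volume(bx$mesh, bx$body)
  a0 <- body_area(bx$mesh, bx$body)
  c0 <- body_centroid(bx$mesh, bx$body)
  R <- random_rotation(); tv <- c(3, -2, 0.5)
  apply_rigid_motion(bx$mesh, R, tv)
  expect_equal(body_volume(bx$mesh, bx$body), v0, tolerance = 1e-10)
  expect_equal(body_area(bx$mesh, bx$body), a0, tolerance = 1e-10)
  expect_equal(body_centroid(bx$mesh, bx$body), as.numeric(R %*% c0 + tv),
               tolerance = 1e-10)
})

test_that("mesh validation catches broken invariants", {
  m <- square_grid(2, 1)
  expect_true(validate_mesh(m))
  expect_error(add_surface(m, c(1, 2)), ">= 3")
  expect_error(add_surface(m, c(1, 2, 2)), "repeat")
  # a surface can define at most two bodies
  tc <- two_cube_mesh()
  expect_error(add_body(tc$mesh, c(tc$shared, 2, 3, 4)),
               "already defines two bodies")
})
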