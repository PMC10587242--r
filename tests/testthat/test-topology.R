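test_that("vertex merge collapses an edge and respects the cycle-length rule", {
  # pentagon with two close vertices -> square cycle
  m <- vm_mesh(2L)
  ids <- vapply(list(c(0, 0), c(1, 0), c(1.02, 0.02), c(1, 1), c(0, 1)),
                function(p) add_vertex(m, c(p, 0)), integer(1))
  add_surface(m, ids)
  vertex_merge(m, ids[2], ids[3])
  expect_true(validate_mesh(m))
  expect_length(surface_cycle(m, 1), 4)
  expect_false(m$v_alive[ids[3]])
  # survivor keeps its own position
  expect_equal(vertex_position(m, ids[2]), c(1, 0, 0))

  # refused on a triangle
  m2 <- vm_mesh(2L)
  tri <- vapply(list(c(0, 0), c(1, 0), c(0.5, 1)),
                function(p) add_vertex(m2, c(p, 0)), integer(1))
  add_surface(m2, tri)
  expect_error(vertex_merge(m2, tri[1], tri[2]), "fewer than 4")
  # refused when not connected
  m3 <- square_grid(2, 2)
  expect_error(vertex_merge(m3, 1, 9), "not connected")
})

test_that("merging a tri-junction vertex updates all three cycles without duplicates", {
  # three quads around a central shared edge pair
  m <- square_grid(2, 2)
  center <- which(apply(m$pos, 1, function(p) all(p[1:2] == c(1, 1))))
  right <- which(apply(m$pos, 1, function(p) all(p[1:2] == c(2, 1))))
  n_surf_before <- lengths(m$s_cycle[surface_ids(m)])
  vertex_merge(m, center, right)
  expect_true(validate_mesh(m))
  for (s in vertex_surfaces(m, center)) {
    expect_equal(sum(surface_cycle(m, s) == center), 1)
  }
  expect_length(vertex_surfaces(m, center), 4)
})

test_that("split criterion accepts tension and rejects compression and zero force", {
  m <- square_grid(2, 2)
  vc <- which(apply(m$pos, 1, function(p) all(p[1:2] == c(1, 1))))
  vl <- which(apply(m$pos, 1, function(p) all(p[1:2] == c(0, 1))))
  vr <- which(apply(m$pos, 1, function(p) all(p[1:2] == c(2, 1))))
  F <- matrix(0, nrow = length(m$v_alive), ncol = 3)
  # outward pulls along x (asymmetric so the total relative force is nonzero)
  F[vl, ] <- c(-10, 1, 0)
  F[vr, ] <- c(8, 0.5, 0)
  pr <- propose_vertex_split(m, vc, F, 0.2)
  expect_true(pr$accept)
  # inward pushes -> compression -> rejected
  F2 <- matrix(0, nrow = length(m$v_alive), ncol = 3)
  F2[vl, ] <- c(10, 1, 0)
  F2[vr, ] <- c(-8, 0.5, 0)
  pr2 <- propose_vertex_split(m, vc, F2, 0.2)
  expect_false(pr2$accept)
  # all forces zero -> no cut plane -> rejected
  pr3 <- propose_vertex_split(m, vc, 0 * F, 0.2)
  expect_false(pr3$accept)
  expect_match(pr3$reason, "zero")
  # fewer than 4 connected vertices -> not a candidate
  pr4 <- propose_vertex_split(m, 1, F, 0.2)
  expect_false(pr4$accept)
})

test_that("an accepted split turns a 4-junction into two 3-junctions", {
  m <- square_grid(2, 2)
  vc <- which(apply(m$pos, 1, function(p) all(p[1:2] == c(1, 1))))
  vl <- which(apply(m$pos, 1, function(p) all(p[1:2] == c(0, 1))))
  vr <- which(apply(m$pos, 1, function(p) all(p[1:2] == c(2, 1))))
  F <- matrix(0, nrow = length(m$v_alive), ncol = 3)
  F[vl, ] <- c(-10, 1, 0)
  F[vr, ] <- c(8, 0.5, 0)
  pr <- propose_vertex_split(m, vc, F, 0.2)
  u <- apply_vertex_split(m, pr)
  expect_true(validate_mesh(m))
  expect_length(connected_vertices(m, vc), 3)
  expect_length(connected_vertices(m, u), 3)
  expect_true(u %in% connected_vertices(m, vc))
  expect_equal(vec_norm(vertex_position(m, u) - vertex_position(m, vc)), 0.2,
               tolerance = 1e-12)
  # exactly two cells gained the new edge (cycles of length 5)
  expect_equal(sort(lengths(m$s_cycle[surface_ids(m)])), c(4, 4, 5, 5))
})

test_that("T1 round trip (merge then split) exchanges one neighbor pair", {
  # honeycomb: interior edges join two degree-3 vertices, so the merged
  # junction has degree 4 (the canonical T1 configuration)
  m <- hex_sheet(1, circumradius = 1)
  shares_edge <- function(a, b) nrow(shared_edges(m, a, b)) > 0
  # find an interior edge: both endpoints define three cells
  deg3 <- which(vapply(seq_along(m$v_alive), function(v) {
    m$v_alive[v] && length(m$v_surfs[[v]]) == 3L
  }, logical(1)))
  edge <- NULL
  for (v1 in deg3) {
    for (v2 in intersect(connected_vertices(m, v1), deg3)) {
      if (length(intersect(vertex_surfaces(m, v1),
                           vertex_surfaces(m, v2))) == 2L) {
        edge <- c(v1, v2); break
      }
    }
    if (!is.null(edge)) break
  }
  AB <- intersect(vertex_surfaces(m, edge[1]), vertex_surfaces(m, edge[2]))
  C <- setdiff(vertex_surfaces(m, edge[1]), AB)
  D <- setdiff(vertex_surfaces(m, edge[2]), AB)
  expect_true(shares_edge(AB[1], AB[2]))
  expect_false(shares_edge(C, D))
  set.seed(12)
  vertex_merge(m, edge[1], edge[2])
  expect_true(validate_mesh(m))
  expect_false(shares_edge(AB[1], AB[2]))
  vj <- if (m$v_alive[edge[1]]) edge[1] else edge[2]
  expect_length(connected_vertices(m, vj), 4)
  # pull the A-side and B-side connected vertices apart (tension across the
  # A-B axis), with slight asymmetry so the relative force is nonzero
  conn <- connected_vertices(m, vj)
  axis <- surface_centroid(m, AB[1]) - surface_centroid(m, AB[2])
  axis <- axis / vec_norm(axis)
  F <- matrix(0, nrow = length(m$v_alive), ncol = 3)
  for (w in conn) {
    d <- vertex_position(m, w) - vertex_position(m, vj)
    side <- sign(sum(d * axis))
    F[w, ] <- side * axis * ifelse(side > 0, 5.5, 5)
  }
  pr <- propose_vertex_split(m, vj, F, 0.2)
  expect_true(pr$accept)
  u <- apply_vertex_split(m, pr)
  expect_true(validate_mesh(m))
  # neighbor exchange: the endpoint cells now share the new edge, the old
  # pair stays apart
  expect_true(shares_edge(C, D))
  expect_false(shares_edge(AB[1], AB[2]))
  expect_true(all(sort(c(vj, u)) == sort(shared_edges(m, C, D)[1, ])))
})

test_that("a split can disconnect two surfaces sharing only one vertex", {
  # two quads sharing a single vertex, plus enough connectivity for a split
  m <- vm_mesh(2L)
  a <- vapply(list(c(-1, 0), c(0, -1), c(1, 0), c(0, 1)),
              function(p) add_vertex(m, c(p, 0)), integer(1))
  sq1 <- add_surface(m, a)
  b <- vapply(list(c(2, -1), c(3, 0), c(2, 1)),
              function(p) add_vertex(m, c(p, 0)), integer(1))
  sq2 <- add_surface(m, c(a[3], b))
  expect_true(surfaces_connected(m, sq1, sq2))
  F <- matrix(0, nrow = length(m$v_alive), ncol = 3)
  F[a[2], ] <- c(-4, -0.5, 0); F[a[4], ] <- c(-4.5, 0.5, 0)
  F[b[1], ] <- c(4, -0.4, 0); F[b[3], ] <- c(3.6, 0.3, 0)
  pr <- propose_vertex_split(m, a[3], F, 0.2)
  expect_true(pr$accept)
  apply_vertex_split(m, pr)
  expect_true(validate_mesh(m))
  expect_false(surfaces_connected(m, sq1, sq2))
})

test_that("surface demote (T2) replaces a small surface by its centroid vertex", {
  m <- vm_mesh(2L)
  a <- add_vertex(m, c(0, 0, 0)); b <- add_vertex(m, c(1, 0, 0))
  cc <- add_vertex(m, c(0.5, 0.866, 0))
  A <- add_vertex(m, c(-0.5, -0.87, 0)); B <- add_vertex(m, c(1.5, -0.87, 0))
  C <- add_vertex(m, c(0.5, 1.87, 0))
  tri <- add_surface(m, c(a, b, cc))
  q1 <- add_surface(m, c(A, B, b, a))
  q2 <- add_surface(m, c(B, C, cc, b))
  q3 <- add_surface(m, c(C, A, a, cc))
  cen <- surface_centroid(m, tri)
  res <- surface_demote(m, tri)
  expect_true(validate_mesh(m))
  expect_equal(res$removed_surfaces, tri)
  expect_equal(vertex_position(m, res$vertex), cen)
  # each neighbor quad lost one vertex of the pair it shared
  expect_equal(lengths(m$s_cycle[surface_ids(m)]), c(3, 3, 3))
  expect_length(vertex_surfaces(m, res$vertex), 3)
  # old triangle vertices are gone
  expect_false(any(m$v_alive[c(a, b, cc)]))
})

test_that("surface demote is refused inside a four-surface body", {
  tt <- tetrahedron_mesh()
  expect_error(surface_demote(tt$mesh, body_surfaces(tt$mesh, tt$body)[1]),
               "four surfaces")
})

test_that("surface demote cascades remove neighbors left with <3 vertices", {
  # demote a sliver triangle: a quad neighbor survives (loses one vertex),
  # a triangle neighbor sharing an edge collapses to a 2-cycle and is removed
  m <- vm_mesh(2L)
  a <- add_vertex(m, c(0, 0, 0)); b <- add_vertex(m, c(1, 0, 0))
  cc <- add_vertex(m, c(0.5, 0.1, 0))
  d <- add_vertex(m, c(0, -1, 0)); e <- add_vertex(m, c(1, -1, 0))
  dl <- add_vertex(m, c(-1, 0.5, 0))
  tri <- add_surface(m, c(a, b, cc))
  nb <- add_surface(m, c(b, a, d, e))    # quad sharing edge a-b
  nb2 <- add_surface(m, c(a, cc, dl))    # triangle sharing edge a-cc
  res <- surface_demote(m, tri)
  expect_true(validate_mesh(m))
  expect_true(nb2 %in% res$removed_surfaces)
  expect_true(m$s_alive[nb])
  expect_length(surface_cycle(m, nb), 3)
})

test_that("body demote collapses bodies and demotes boundary faces", {
  # isolated cube -> a single vertex at its centroid
  cb <- box_mesh()
  cen <- body_centroid(cb$mesh, cb$body)
  nv <- body_demote(cb$mesh, cb$body)
  expect_true(validate_mesh(cb$mesh))
  expect_equal(sum(cb$mesh$v_alive), 1)
  expect_equal(sum(cb$mesh$s_alive), 0)
  expect_equal(sum(cb$mesh$b_alive), 0)
  expect_equal(vertex_position(cb$mesh, nv), cen)

  # cube in a row: neighbor survives with its shared face demoted
  tc <- two_cube_mesh()
  nv2 <- body_demote(tc$mesh, tc$b1)
  expect_true(validate_mesh(tc$mesh))
  expect_false(tc$mesh$b_alive[tc$b1])
  expect_true(tc$mesh$b_alive[tc$b2])
  expect_false(tc$mesh$s_alive[tc$shared])
  expect_length(body_surfaces(tc$mesh, tc$b2), 5)
  expect_true(nv2 %in% body_vertices(tc$mesh, tc$b2))
  expect_gt(body_volume(tc$mesh, tc$b2), 0)
})

test_that("body demote cascade absorbs bodies invalidated by the removal", {
  # a tetrahedron glued to a cube face cannot survive removal of the cube:
  # demoting its shared face would leave it under four surfaces
  cb <- box_mesh()
  m <- cb$mesh
  top <- cb$faces[2]                      # z = 1 face
  apex <- add_vertex(m, c(0.5, 0.5, 1.8))
  cyc <- surface_cycle(m, top)
  side <- vapply(seq_along(cyc), function(k) {
    k2 <- if (k == length(cyc)) 1L else k + 1L
    add_surface(m, c(cyc[k], cyc[k2], apex))
  }, integer(1))
  pyr <- add_body(m, c(top, side))        # 5-surface pyramid on the cube
  nv <- body_demote(m, cb$body)
  expect_true(validate_mesh(m))
  # the pyramid loses the shared face and its sides collapse with it
  expect_false(m$b_alive[pyr])
  expect_equal(sum(m$b_alive), 0)
})

test_that("vertex insert (T3) connects colliding surfaces and refuses connected pairs", {
  m <- vm_mesh(2L)
  s1v <- vapply(list(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                function(p) add_vertex(m, c(p, 0)), integer(1))
  sq1 <- add_surface(m, s1v)
  s2v <- vapply(list(c(0.95, 0.4), c(1.9, 0.2), c(2, 1)),
                function(p) add_vertex(m, c(p, 0)), integer(1))
  sq2 <- add_surface(m, s2v)
  pen <- find_penetrations(m, 0.1)
  expect_equal(nrow(pen), 1)
  expect_equal(unname(pen[1, "vertex"]), s2v[1])
  expect_equal(unname(pen[1, "surface"]), sq1)
  vertex_insert(m, pen[1, "vertex"], pen[1, "surface"],
                c(pen[1, "ea"], pen[1, "eb"]))
  expect_true(validate_mesh(m))
  expect_length(surface_cycle(m, sq1), 5)
  expect_true(surfaces_connected(m, sq1, sq2))
  # now connected: further insert refused
  expect_error(vertex_insert(m, s2v[2], sq1, c(s1v[1], s1v[2])),
               "already connected")
})

test_that("manual surface split halves a square and refuses adjacent cuts", {
  m <- square_grid(1, 1)
  cyc <- surface_cycle(m, 1)
  out <- split_surface(m, 1, list(list(edge = c(cyc[1], cyc[2]), t = 0.5),
                                  list(edge = c(cyc[3], cyc[4]), t = 0.5)))
  expect_true(validate_mesh(m))
  areas <- vapply(out, function(s) surface_area(m, s), numeric(1))
  expect_equal(areas, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(areas), 1, tolerance = 1e-9)
  # hexagon cut across opposite vertices -> two quads, areas conserved
  m2 <- vm_mesh(2L)
  regular_hexagon(m2, circumradius = 1)
  cyc2 <- surface_cycle(m2, 1)
  a0 <- surface_area(m2, 1)
  out2 <- split_surface(m2, 1, list(list(vertex = cyc2[1]),
                                    list(vertex = cyc2[4])))
  expect_equal(lengths(m2$s_cycle[out2]), c(4, 4))
  expect_equal(sum(vapply(out2, function(s) surface_area(m2, s), numeric(1))),
               a0, tolerance = 1e-9)
  # adjacent cut positions refused
  m3 <- square_grid(1, 1)
  cyc3 <- surface_cycle(m3, 1)
  expect_error(split_surface(m3, 1, list(list(vertex = cyc3[1]),
                                         list(vertex = cyc3[2]))),
               "adjacent")
})

test_that("quality step honors priorities, affect-once and the global disable", {
  # two merge candidates sharing a vertex: only the lower-owner one applies
  m <- vm_mesh(2L)
  ids <- vapply(list(c(0, 0), c(0.05, 0), c(0.1, 0), c(1, 0), c(1, 1), c(0, 1)),
                function(p) add_vertex(m, c(p, 0)), integer(1))
  add_surface(m, ids)
  F <- matrix(0, nrow = length(m$v_alive), ncol = 3)
  set.seed(1)
  log <- quality_step(m, F, quality_params(merge_distance = 0.08, split = FALSE,
                                           demote = FALSE, insert = FALSE))
  acc <- Filter(function(r) isTRUE(r$accepted), log)
  expect_equal(length(acc), 1)
  expect_equal(acc[[1]]$owner, 1)
  expect_true(validate_mesh(m))

  # global disable freezes topology
  m2 <- square_grid(2, 2)
  cyc0 <- m2$s_cycle[surface_ids(m2)]
  log2 <- quality_step(m2, matrix(0, length(m2$v_alive), 3),
                       quality_params(enabled = FALSE))
  expect_length(log2, 0)
  expect_identical(m2$s_cycle[surface_ids(m2)], cyc0)
})

test_that("randomized quality stress runs always leave a valid mesh", {
  set.seed(77)
  for (rep in 1:3) {
    m <- square_grid(3, 3)
    jitter_mesh(m, 0.1)
    params <- quality_params(merge_distance = 0.25, split_distance = 0.5)
    for (step in 1:25) {
      F <- matrix(stats::rnorm(3 * length(m$v_alive), 0, 4), ncol = 3)
      F[, 3] <- 0
      quality_step(m, F, params)
      expect_true(validate_mesh(m))
    }
    # all cycles >= 3, no duplicate vertices (validate_mesh covers both)
    expect_true(all(lengths(m$s_cycle[surface_ids(m)]) >= 3))
  }
})

test_that("operation logs are reproducible under a fixed seed", {
  run_once <- function() {
    set.seed(99)
    m <- square_grid(3, 3)
    jitter_mesh(m, 0.1)
    params <- quality_params(merge_distance = 0.3, split_distance = 0.6)
    log <- list()
    for (step in 1:10) {
      F <- matrix(stats::rnorm(3 * length(m$v_alive), 0, 4), ncol = 3)
      log <- c(log, quality_step(m, F, params))
    }
    log
  }
  expect_identical(run_once(), run_once())
})
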