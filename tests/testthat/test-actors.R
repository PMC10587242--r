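test_that("constraint energies vanish at their targets and forces are restoring", {
  m <- square_grid(1, 1)
  expect_equal(actor_energy(m, surface_area_constraint(50, 1), 1), 0)
  expect_equal(actor_forces(m, surface_area_constraint(50, 1), 1),
               matrix(0, 4, 3))
  expect_equal(actor_energy(m, perimeter_constraint(1, 4), 1), 0)
  expect_equal(max(abs(actor_forces(m, perimeter_constraint(1, 4), 1))), 0)
  # p = 2 edge tension of the unit square: 0.5 * 4 * 1^2
  expect_equal(actor_energy(m, edge_tension(0.5, 2), 1), 2.0)
  cb <- box_mesh()
  expect_equal(actor_energy(cb$mesh, body_volume_constraint(10, 1), cb$body), 0)
  expect_equal(max(abs(actor_forces(cb$mesh, body_volume_constraint(10, 1),
                                    cb$body))), 0)
})

test_that("every energy-based actor matches its finite-difference gradient", {
  set.seed(31)
  # >= 20 random configurations across the surface actors
  for (rep in 1:8) {
    m <- random_polygon_mesh(5 + rep %% 3, seed = 300 + rep)
    expect_lt(fd_force_error(m, surface_area_constraint(50, 1), 1), 1e-4)
    expect_lt(fd_force_error(m, perimeter_constraint(1, 2 * sqrt(pi)), 1), 1e-4)
    expect_lt(fd_force_error(m, edge_tension(10, 1), 1), 1e-4)
    expect_lt(fd_force_error(m, edge_tension(0.5, 2), 1), 1e-4)
  }
  # body actors on jittered boxes
  for (rep in 1:4) {
    bx <- box_mesh(1 + 0.3 * rep, 0.8, 1.1)
    jitter_mesh(bx$mesh, sd = 0.03)
    expect_lt(fd_force_error(bx$mesh, body_volume_constraint(10, 1), bx$body),
              1e-4)
    expect_lt(fd_force_error(bx$mesh, body_area_constraint(5, 5), bx$body),
              1e-4)
  }
})

test_that("2D adhesion counts shared edges once and matches its gradient", {
  m <- square_grid(2, 1)
  m$s_type[1:2] <- c(1L, 2L)
  md <- vm_model()
  set_adhesion(md, 1, 2, -18)
  # two unit squares sharing one unit edge
  expect_equal(mesh_energy(m, md), -18)
  expect_equal(adhesion_energy(m, 1, 2, -18), -18)
  # disconnected pair contributes zero
  m2 <- vm_mesh(2L)
  a <- vapply(list(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
              function(p) add_vertex(m2, c(p, 0)), integer(1))
  b <- vapply(list(c(5, 0), c(6, 0), c(6, 1), c(5, 1)),
              function(p) add_vertex(m2, c(p, 0)), integer(1))
  s1 <- add_surface(m2, a); s2 <- add_surface(m2, b)
  expect_equal(adhesion_energy(m2, s1, s2, -18), 0)
  expect_equal(max(abs(adhesion_forces(m2, s1, s2, -18))), 0)
  # FD agreement on a jittered two-cell mesh
  set.seed(32)
  for (rep in 1:4) {
    mj <- square_grid(2, 1)
    mj$s_type[1:2] <- c(1L, 2L)
    jitter_mesh(mj, 0.05)
    mdj <- vm_model()
    set_adhesion(mdj, 1, 2, -26)
    expect_lt(fd_model_force_error(mj, mdj), 1e-4)
  }
})

test_that("3D adhesion acts on shared surfaces with the right sign", {
  tc <- two_cube_mesh()
  md <- vm_model()
  set_adhesion(md, 1, 2, 0.7, class = "body")
  expect_equal(mesh_energy(tc$mesh, md), 0.7)   # shared face area 1
  set.seed(33)
  jitter_mesh(tc$mesh, 0.02)
  expect_lt(fd_model_force_error(tc$mesh, md), 1e-4)
  # positive lambda (monotonically increasing energy in area) compresses the
  # shared surface: relaxation shrinks its area
  tc2 <- two_cube_mesh()
  md2 <- vm_model()
  set_adhesion(md2, 1, 2, 0.7, class = "body")
  st <- vm_state(tc2$mesh, md2,
                 engine_config(dt = 0.01, seed = 1,
                               quality = quality_params(enabled = FALSE),
                               auto_shape_constraints = FALSE))
  a0 <- surface_area(tc2$mesh, tc2$shared)
  run_steps(st, 50)
  expect_lt(surface_area(tc2$mesh, tc2$shared), a0)
})

test_that("traction and body forces conserve the total applied force", {
  m <- square_grid(1, 1)
  tau <- c(0, 0, 1)
  m$dim <- 3L   # allow out-of-plane traction
  F <- actor_forces(m, surface_traction(tau), 1)
  expect_equal(colSums(F), surface_area(m, 1) * tau)
  expect_equal(F[1, ], 0.25 * tau)   # symmetric square: equal shares
  # irregular polygon: shares proportional to vertex area contributions
  mp <- random_polygon_mesh(6, seed = 44)
  mp$dim <- 3L
  Fp <- actor_forces(mp, surface_traction(c(0.3, -0.2, 0.5)), 1)
  cyc <- surface_cycle(mp, 1)
  shares <- vapply(cyc, function(v) vertex_area_contribution(mp, v, 1),
                   numeric(1))
  expect_equal(Fp[cyc, ], outer(shares, c(0.3, -0.2, 0.5)), tolerance = 1e-12)

  bx <- box_mesh()
  fb <- c(1, -2, 0.5)
  Fb <- actor_forces(bx$mesh, body_force(fb), bx$body)
  expect_equal(colSums(Fb), fb, tolerance = 1e-12)
  expect_equal(Fb[1, ], fb / 8, tolerance = 1e-12)   # cube symmetry
})

test_that("normal stress distributes magnitude * normal as a traction", {
  m <- square_grid(1, 1)
  m$dim <- 3L
  F <- actor_forces(m, normal_stress(2), 1)
  expect_equal(colSums(F), c(0, 0, 2 * surface_area(m, 1)))
  expect_equal(max(abs(actor_forces(m, normal_stress(0), 1))), 0)
  # reversed cycle flips the total force
  m2 <- vm_mesh(3L)
  ids <- vapply(list(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                function(p) add_vertex(m2, c(p, 0)), integer(1))
  add_surface(m2, rev(ids))
  F2 <- actor_forces(m2, normal_stress(2), 1)
  expect_equal(colSums(F2), c(0, 0, -2))
})

test_that("shape constraints restore flatness and convexity and vanish otherwise", {
  # planar convex polygon: both zero
  m <- vm_mesh(3L)
  ids <- vapply(list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                function(p) add_vertex(m, p), integer(1))
  add_surface(m, ids)
  expect_equal(max(abs(actor_forces(m, flat_surface_constraint(), 1))), 0)
  expect_equal(max(abs(actor_forces(m, convex_polygon_constraint(), 1))), 0)
  # lift one vertex: flat-constraint force antiparallel to the lift
  m$pos[ids[2], 3] <- 0.2
  bump_topo(m)
  Ff <- actor_forces(m, flat_surface_constraint(), 1)
  expect_lt(Ff[ids[2], 3], 0)
  # dart-shaped quad: reflex vertex pulled toward its neighbors' chord,
  # forces only on the reflex vertex and its cycle neighbors
  m2 <- vm_mesh(2L)
  dart <- vapply(list(c(0, 0), c(2, 0), c(1, 0.4), c(1, 2)),
                 function(p) add_vertex(m2, c(p, 0)), integer(1))
  add_surface(m2, dart)
  Fc <- actor_forces(m2, convex_polygon_constraint(), 1)
  expect_gt(abs(sum(Fc[dart[3], ])), 0)
  expect_equal(Fc[dart[1], ], c(0, 0, 0))
  expect_gt(Fc[dart[3], 2], 0)    # pushed up toward the chord
})

test_that("bindings are additive and type-level equals per-object", {
  m <- square_grid(2, 2)
  set.seed(35)
  jitter_mesh(m, 0.08)
  actor <- surface_area_constraint(50, 1)
  md1 <- vm_model()
  bind_actor(md1, actor, surface_type = 1L)
  md2 <- vm_model()
  for (s in surface_ids(m)) bind_actor(md2, actor, surface = s)
  expect_equal(mesh_forces(m, md1), mesh_forces(m, md2), tolerance = 1e-12)
  # two identical bindings double the force
  md3 <- vm_model()
  bind_actor(md3, actor, surface_type = 1L)
  bind_actor(md3, actor, surface_type = 1L)
  f1 <- mesh_forces(m, md1)
  expect_equal(mesh_forces(m, md3),
               f1 + mesh_forces(m, md1), tolerance = 1e-12)
  # mixed bindings sum: area + perimeter == each alone summed
  md4 <- vm_model()
  bind_actor(md4, perimeter_constraint(1, 2 * sqrt(pi)), surface_type = 1L)
  md5 <- vm_model()
  bind_actor(md5, actor, surface_type = 1L)
  bind_actor(md5, perimeter_constraint(1, 2 * sqrt(pi)), surface_type = 1L)
  expect_equal(mesh_forces(m, md5), f1 + mesh_forces(m, md4),
               tolerance = 1e-12)
})

test_that("energy-gradient convention: quadratic well gives -k r force", {
  # an isolated cell with only the area constraint relaxes back to target
  m <- square_grid(1, 1)
  md <- vm_model()
  bind_actor(md, surface_area_constraint(50, 1), surface_type = 1L)
  vids <- vertex_ids(m)
  m$pos[vids, 1:2] <- m$pos[vids, 1:2] * 1.1   # area 1.21
  bump_topo(m)
  st <- vm_state(m, md, engine_config(dt = 0.0025, seed = 1,
                                      quality = quality_params(enabled = FALSE)))
  run_steps(st, 2000)
  expect_equal(surface_area(m, 1), 1, tolerance = 1e-3)
  # an isolated cell with only the perimeter constraint relaxes toward L_o
  m2 <- square_grid(1, 1)
  md2 <- vm_model()
  bind_actor(md2, perimeter_constraint(1, 2 * sqrt(pi)), surface_type = 1L)
  st2 <- vm_state(m2, md2, engine_config(dt = 0.005, seed = 1,
                                         quality = quality_params(enabled = FALSE)))
  run_steps(st2, 4000)
  expect_equal(surface_perimeter(m2, 1), 2 * sqrt(pi), tolerance = 1e-3)
})
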