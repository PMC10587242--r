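# Vectorized evaluation of actor forces and energies over the whole mesh.
#
# The topology-dependent index structure (flattened cycles, edge table) is
# cached on the mesh and rebuilt only when topology changes; the
# position-dependent quantities are recomputed every evaluation.

# Topology index: one fan triangle per cycle slot.
geom_index <- function(mesh) {
  cache <- mesh$cache
  if (!is.null(cache) && cache$version == mesh$topo_version) return(cache)
  sids <- surface_ids(mesh)
  slen <- lengths(mesh$s_cycle[sids])
  grp <- rep(seq_along(sids), slen)       # triangle -> surface position
  va <- unlist(mesh$s_cycle[sids], use.names = FALSE)
  if (is.null(va)) va <- integer(0)
  # next vertex within each cycle
  vb <- integer(length(va))
  if (length(va) > 0) {
    off <- cumsum(c(0L, slen[-length(slen)]))
    for (k in seq_along(sids)) {
      idx <- off[k] + seq_len(slen[k])
      vb[idx] <- va[c(idx[-1L], idx[1L])]
    }
  }
  # undirected edge table; an edge shared by two surfaces appears twice
  nmax <- length(mesh$v_alive) + 1L
  ekey <- pmin(va, vb) * nmax + pmax(va, vb)
  ord <- order(ekey)
  shared_first <- shared_second <- integer(0)
  if (length(ekey) > 1) {
    dup <- ekey[ord][-1L] == ekey[ord][-length(ekey)]
    shared_first <- ord[c(dup, FALSE)]
    shared_second <- ord[c(FALSE, dup)]
  }
  # unique undirected edges (first occurrence) and vertex degrees
  und <- if (length(ekey) > 0) ord[!duplicated(ekey[ord])] else integer(0)
  degree <- tabulate(c(va[und], vb[und]), nbins = length(mesh$v_alive))
  # next cycle slot of each slot (wrapping within each surface)
  nxt_slot <- integer(length(va))
  if (length(va) > 0) {
    ends <- cumsum(slen)
    starts <- ends - slen + 1L
    nxt_slot <- seq_along(va) + 1L
    nxt_slot[ends] <- starts
  }
  cache <- list(version = mesh$topo_version, sids = sids, nS = length(sids),
                slen = slen, grp = grp, va = va, vb = vb,
                shared_first = shared_first, shared_second = shared_second,
                und = und, degree = degree, nxt_slot = nxt_slot)
  mesh$cache <- cache
  cache
}

# Position-dependent geometry for all live surfaces.
geom_eval <- function(mesh, gi = geom_index(mesh)) {
  pa <- mesh$pos[gi$va, , drop = FALSE]
  pb <- mesh$pos[gi$vb, , drop = FALSE]
  cent <- rowsum(pa, group = gi$grp, reorder = FALSE) / gi$slen
  centT <- cent[gi$grp, , drop = FALSE]
  u <- pa - centT
  v <- pb - centT
  eta <- row_cross(u, v)
  two_a <- row_norms(eta)
  tri_area <- 0.5 * two_a
  area <- as.numeric(rowsum(tri_area, group = gi$grp, reorder = FALSE))
  edge <- pb - pa
  elen <- row_norms(edge)
  perim <- as.numeric(rowsum(elen, group = gi$grp, reorder = FALSE))
  list(gi = gi, pa = pa, pb = pb, cent = cent, centT = centT, u = u, v = v,
       eta = eta, two_a = two_a, tri_area = tri_area, area = area,
       edge = edge, elen = elen, perim = perim)
}

# Scatter-add rows of `vals` into F at (possibly repeated) row indices.
acc_rows <- function(F, idx, vals) {
  s <- rowsum(vals, group = idx, reorder = FALSE)
  ridx <- as.integer(rownames(s))
  F[ridx, ] <- F[ridx, , drop = FALSE] + s
  F
}

# d(surface area)/dr contributions with a per-surface coefficient `coef`
# (full-length nS vector; zero entries are skipped implicitly). Adds
# coef_S * dA_S/dr to F.
area_gradient_add <- function(F, ge, coef) {
  gi <- ge$gi
  if (all(coef == 0)) return(F)
  n <- ge$two_a
  n[n < DEGENERATE_TOL] <- Inf
  hat <- ge$eta / n
  P <- row_cross(ge$v, hat)            # d|eta|/da (holding C)
  Q <- row_cross(hat, ge$u)            # d|eta|/db (holding C)
  R <- rowsum(P + Q, group = gi$grp, reorder = FALSE)
  cT <- coef[gi$grp]
  F <- acc_rows(F, gi$va, 0.5 * cT * (P - R[gi$grp, , drop = FALSE] / gi$slen[gi$grp]))
  F <- acc_rows(F, gi$vb, 0.5 * cT * Q)
  F
}

# d(perimeter)/dr with per-surface coefficient: adds coef_S * dL_S/dr.
perimeter_gradient_add <- function(F, ge, coef) {
  gi <- ge$gi
  if (all(coef == 0)) return(F)
  n <- ge$elen
  n[n < DEGENERATE_TOL] <- Inf
  ehat <- ge$edge / n
  cT <- coef[gi$grp]
  F <- acc_rows(F, gi$va, -cT * ehat)
  F <- acc_rows(F, gi$vb, cT * ehat)
  F
}

# d(sum edge^2)/dr with per-surface coefficient.
edge_sq_gradient_add <- function(F, ge, coef) {
  gi <- ge$gi
  if (all(coef == 0)) return(F)
  cT <- coef[gi$grp]
  F <- acc_rows(F, gi$va, -2 * cT * ge$edge)
  F <- acc_rows(F, gi$vb, 2 * cT * ge$edge)
  F
}

# Distribute per-surface traction vectors tau (nS x 3) over cycle vertices
# in proportion to vertex area contributions: each triangle passes half its
# area to each of its two cycle vertices.
traction_add <- function(F, ge, tau) {
  gi <- ge$gi
  if (all(tau == 0)) return(F)
  w <- 0.5 * ge$tri_area
  tT <- tau[gi$grp, , drop = FALSE]
  F <- acc_rows(F, gi$va, w * tT)
  F <- acc_rows(F, gi$vb, w * tT)
  F
}

# d(volume contribution)/dr of each surface with per-surface coefficient
# (already including the orientation flag alpha). V^S about the origin is
# (1/6) sum_T C . (a x b); see body_volume().
volume_gradient_add <- function(F, ge, coef) {
  gi <- ge$gi
  if (all(coef == 0)) return(F)
  axb <- row_cross(ge$pa, ge$pb)
  Q <- rowsum(axb, group = gi$grp, reorder = FALSE)
  cT <- coef[gi$grp]
  F <- acc_rows(F, gi$va, cT / 6 * (row_cross(ge$pb, ge$centT) +
                                      Q[gi$grp, , drop = FALSE] / gi$slen[gi$grp]))
  F <- acc_rows(F, gi$vb, cT / 6 * row_cross(ge$centT, ge$pa))
  F
}

# Per-surface coefficient vector (length nS) from a term's id set.
coef_for <- function(ge, ids, values) {
  out <- numeric(ge$gi$nS)
  out[match(ids, ge$gi$sids)] <- values
  out
}

# Map body ids to per-surface coefficient * alpha for volume terms.
body_volume_coef <- function(mesh, ge, bids, values) {
  out <- numeric(ge$gi$nS)
  for (k in seq_along(bids)) {
    b <- bids[k]
    pos <- match(mesh$b_surfs[[b]], ge$gi$sids)
    out[pos] <- out[pos] + values[k] * mesh$b_alpha[[b]]
  }
  out
}

body_area_coef <- function(mesh, ge, bids, values) {
  out <- numeric(ge$gi$nS)
  for (k in seq_along(bids)) {
    pos <- match(mesh$b_surfs[[bids[k]]], ge$gi$sids)
    out[pos] <- out[pos] + values[k]
  }
  out
}

# Current per-body volume/area from a geometry evaluation.
body_measures <- function(mesh, ge, bids) {
  vol <- area <- numeric(length(bids))
  for (k in seq_along(bids)) {
    b <- bids[k]
    pos <- match(mesh$b_surfs[[b]], ge$gi$sids)
    area[k] <- sum(ge$area[pos])
    vol[k] <- sum(mesh$b_alpha[[b]] * vapply(mesh$b_surfs[[b]], function(s) {
      surface_volume_about(mesh, s)
    }, numeric(1)))
  }
  list(volume = vol, area = area)
}

# ---- shape constraints (explicit restoring forces) -------------------------

# Least-squares plane restoring force toward planarity.
flat_constraint_add <- function(F, mesh, ids, strength) {
  for (s in ids) {
    cyc <- mesh$s_cycle[[s]]
    p <- mesh$pos[cyc, , drop = FALSE]
    cen <- colMeans(p)
    q <- sweep(p, 2L, cen)
    sv <- svd(q, nu = 0, nv = 3)
    nrm <- sv$v[, 3]
    d <- as.numeric(q %*% nrm)
    if (max(abs(d)) < DEGENERATE_TOL) next
    F[cyc, ] <- F[cyc, , drop = FALSE] - strength * outer(d, nrm)
  }
  F
}

# Push reflex vertices toward the chord joining their cycle neighbors;
# reaction split between the neighbors. Vectorized over the fan structure:
# the vertex at cycle slot k (vb[k]) sits between edges k and nxt_slot[k],
# and is reflex when the turn opposes the surface normal.
convex_constraint_add <- function(F, mesh, ge, ids, strength) {
  gi <- ge$gi
  spos <- match(ids, gi$sids)
  nsum <- rowsum(ge$eta, group = gi$grp, reorder = FALSE)
  nn <- row_norms(nsum)
  nn[nn < DEGENERATE_TOL] <- Inf
  nhat <- nsum / nn
  sel <- which(gi$grp %in% spos)
  if (length(sel) == 0) return(F)
  nx <- gi$nxt_slot[sel]
  turn <- rowSums(row_cross(ge$edge[sel, , drop = FALSE],
                            ge$edge[nx, , drop = FALSE]) *
                    nhat[gi$grp[sel], , drop = FALSE])
  reflex <- sel[turn < -DEGENERATE_TOL]
  if (length(reflex) == 0) return(F)
  w <- gi$vb[reflex]                       # reflex vertex
  vprev <- gi$va[reflex]
  vnext <- gi$vb[gi$nxt_slot[reflex]]
  a <- mesh$pos[vprev, , drop = FALSE]
  b <- mesh$pos[vnext, , drop = FALSE]
  x <- mesh$pos[w, , drop = FALSE]
  ab <- b - a
  tt <- rowSums((x - a) * ab) / pmax(rowSums(ab * ab), DEGENERATE_TOL)
  tt <- pmin(pmax(tt, 0), 1)
  f <- strength * (a + tt * ab - x)
  F <- acc_rows(F, w, f)
  F <- acc_rows(F, vprev, -f / 2)
  F <- acc_rows(F, vnext, -f / 2)
  F
}

# ---- full-model evaluation -------------------------------------------------

#' Accumulate actor forces on all vertices
#'
#' Sums the forces of every binding in the model (object-level and
#' type-level) plus pairwise adhesion, evaluated at the current vertex
#' positions. All actors act simultaneously.
#'
#' @param mesh a `vm_mesh`.
#' @param model a `vm_model`.
#' @return An `n x 3` matrix of forces indexed by vertex id (dead vertex
#'   rows are zero).
#' @export
mesh_forces <- function(mesh, model) {
  F <- matrix(0, nrow = length(mesh$v_alive), ncol = 3L)
  if (sum(mesh$s_alive) == 0L) return(F)
  gi <- geom_index(mesh)
  gm <- fan_measures(mesh$pos, gi$va, gi$vb, gi$grp, gi$nS)
  terms <- resolve_terms(mesh, model)
  # fuse all per-surface scalar constraint terms into one compiled gradient
  # pass (coefficients are additive across bindings); other actor kinds fall
  # through to the general path below
  gA <- gL <- gE2 <- numeric(gi$nS)
  other <- list()
  for (tm in terms) {
    a <- tm$actor
    pos <- match(tm$ids, gi$sids)
    switch(a$kind,
      area_constraint = {
        gA[pos] <- gA[pos] - 2 * a$lambda * (gm$area[pos] - a$target)
      },
      perimeter_constraint = {
        gL[pos] <- gL[pos] - 2 * a$lambda * (gm$perim[pos] - a$target)
      },
      edge_tension = {
        if (a$p == 1L) gL[pos] <- gL[pos] - a$lambda
        else gE2[pos] <- gE2[pos] - a$lambda
      },
      other[[length(other) + 1L]] <- tm)
  }
  F <- F + surface_constraint_forces(mesh$pos, gi$va, gi$vb, gi$grp, gi$slen,
                                     gA, gL, gE2, nrow(F))
  if (length(other) > 0 || nrow(model$adh3d) > 0) {
    F <- mesh_forces_general(mesh, model, F, other)
  }
  F <- adhesion2d_forces_add(F, mesh, model, gi)
  if (mesh$dim == 2L) F[, 3] <- 0
  F
}

# General per-term path for the non-fused actor kinds (tractions, normal
# stress, shape constraints, body actors) and 3D adhesion.
mesh_forces_general <- function(mesh, model, F, terms) {
  ge <- geom_eval(mesh)
  gi <- ge$gi
  for (tm in terms) {
    a <- tm$actor
    ids <- tm$ids
    switch(a$kind,
      surface_traction = {
        tau <- matrix(0, gi$nS, 3L)
        tau[match(ids, gi$sids), ] <- matrix(a$tau, length(ids), 3L, byrow = TRUE)
        F <- traction_add(F, ge, tau)
      },
      normal_stress = {
        tau <- matrix(0, gi$nS, 3L)
        pos <- match(ids, gi$sids)
        nsum <- rowsum(ge$eta, group = gi$grp, reorder = FALSE)
        nn <- row_norms(nsum)
        if (any(nn[pos] < DEGENERATE_TOL)) {
          stop("normal stress on degenerate surface", call. = FALSE)
        }
        tau[pos, ] <- a$magnitude * nsum[pos, , drop = FALSE] / nn[pos]
        F <- traction_add(F, ge, tau)
      },
      flat_constraint = {
        F <- flat_constraint_add(F, mesh, ids, a$strength)
      },
      convex_constraint = {
        F <- convex_constraint_add(F, mesh, ge, ids, a$strength)
      },
      volume_constraint = {
        bm <- body_measures(mesh, ge, ids)
        g <- -2 * a$lambda * (bm$volume - a$target)
        F <- volume_gradient_add(F, ge, body_volume_coef(mesh, ge, ids, g))
      },
      body_area_constraint = {
        bm <- body_measures(mesh, ge, ids)
        g <- -2 * a$lambda * (bm$area - a$target)
        F <- area_gradient_add(F, ge, body_area_coef(mesh, ge, ids, g))
      },
      body_force = {
        for (b in ids) {
          vs <- body_vertices(mesh, b)
          share <- vapply(vs, function(v) {
            vertex_volume_contribution(mesh, v, b)
          }, numeric(1))
          share <- share / body_volume(mesh, b)
          F[vs, ] <- F[vs, , drop = FALSE] + outer(share, a$force)
        }
      },
      stop("unknown actor kind: ", a$kind)
    )
  }
  # shared-surface (3D) adhesion: linear in shared-surface area
  if (nrow(model$adh3d) > 0) {
    coef <- numeric(gi$nS)
    for (k in seq_along(gi$sids)) {
      bs <- mesh$s_bodies[[gi$sids[k]]]
      if (length(bs) == 2L) {
        coef[k] <- coef[k] - adhesion_lambda(model, mesh$b_type[bs[1]],
                                             mesh$b_type[bs[2]], "body")
      }
    }
    F <- area_gradient_add(F, ge, coef)
  }
  F
}

# Shared-edge (2D) adhesion forces, computed directly on the edge table.
adhesion2d_forces_add <- function(F, mesh, model, gi) {
  if (nrow(model$adh2d) == 0 || length(gi$shared_first) == 0) return(F)
  i1 <- gi$shared_first
  i2 <- gi$shared_second
  t1 <- mesh$s_type[gi$sids[gi$grp[i1]]]
  t2 <- mesh$s_type[gi$sids[gi$grp[i2]]]
  k <- nrow(model$adh2d)
  lam <- numeric(length(i1))
  ok <- t1 <= k & t2 <= k
  lam[ok] <- model$adh2d[cbind(t1[ok], t2[ok])]
  nz <- which(lam != 0)
  if (length(nz) > 0) {
    va <- gi$va[i1[nz]]; vb <- gi$vb[i1[nz]]
    e <- mesh$pos[vb, , drop = FALSE] - mesh$pos[va, , drop = FALSE]
    n <- row_norms(e)
    n[n < DEGENERATE_TOL] <- Inf
    ehat <- e / n
    F <- acc_rows(F, va, lam[nz] * ehat)
    F <- acc_rows(F, vb, -lam[nz] * ehat)
  }
  F
}

#' Total effective energy of all energy-based bindings
#'
#' Sums the energies of area/perimeter/volume constraints, edge tension and
#' adhesion. Non-energy actors (tractions, normal stress, body forces, shape
#' constraints) contribute nothing.
#'
#' @param mesh a `vm_mesh`.
#' @param model a `vm_model`.
#' @return Scalar energy.
#' @export
mesh_energy <- function(mesh, model) {
  if (sum(mesh$s_alive) == 0L) return(0)
  ge <- geom_eval(mesh)
  gi <- ge$gi
  H <- 0
  for (tm in resolve_terms(mesh, model)) {
    a <- tm$actor
    ids <- tm$ids
    pos <- match(ids, gi$sids)
    H <- H + switch(a$kind,
      area_constraint = sum(a$lambda * (ge$area[pos] - a$target)^2),
      perimeter_constraint = sum(a$lambda * (ge$perim[pos] - a$target)^2),
      edge_tension = {
        if (a$p == 1L) {
          sum(a$lambda * ge$perim[pos])
        } else {
          el2 <- rowsum(ge$elen^2, group = gi$grp, reorder = FALSE)
          sum(a$lambda * el2[pos])
        }
      },
      volume_constraint = {
        bm <- body_measures(mesh, ge, ids)
        sum(a$lambda * (bm$volume - a$target)^2)
      },
      body_area_constraint = {
        bm <- body_measures(mesh, ge, ids)
        sum(a$lambda * (bm$area - a$target)^2)
      },
      0)
  }
  # adhesion, counted once per shared edge / shared surface
  if (nrow(model$adh2d) > 0 && length(gi$shared_first) > 0) {
    i1 <- gi$shared_first
    t1 <- mesh$s_type[gi$sids[gi$grp[i1]]]
    t2 <- mesh$s_type[gi$sids[gi$grp[gi$shared_second]]]
    k <- nrow(model$adh2d)
    lam <- numeric(length(i1))
    ok <- t1 <= k & t2 <= k
    lam[ok] <- model$adh2d[cbind(t1[ok], t2[ok])]
    H <- H + sum(lam * ge$elen[i1])
  }
  if (nrow(model$adh3d) > 0) {
    for (k in seq_along(gi$sids)) {
      bs <- mesh$s_bodies[[gi$sids[k]]]
      if (length(bs) == 2L) {
        H <- H + adhesion_lambda(model, mesh$b_type[bs[1]],
                                 mesh$b_type[bs[2]], "body") * ge$area[k]
      }
    }
  }
  H
}

#' Pairwise adhesion energy and forces between two connected surfaces
#'
#' The shared-interface energy `lambda * C(a, b)` where `C` is the total
#' length of edges shared by the two cycles, counted once per edge, with the
#' implied forces on the shared vertices. Disconnected surfaces contribute
#' zero.
#'
#' @param mesh a `vm_mesh`.
#' @param a,b surface ids.
#' @param lambda adhesion parameter for this pair.
#' @return `adhesion_energy`: scalar; `adhesion_forces`: `n x 3` force
#'   matrix.
#' @export
adhesion_energy <- function(mesh, a, b, lambda) {
  lambda * shared_edge_length(mesh, a, b)
}

#' @rdname adhesion_energy
#' @export
adhesion_forces <- function(mesh, a, b, lambda) {
  F <- matrix(0, nrow = length(mesh$v_alive), ncol = 3L)
  se <- shared_edges(mesh, a, b)
  if (nrow(se) == 0) return(F)
  e <- mesh$pos[se[, 2], , drop = FALSE] - mesh$pos[se[, 1], , drop = FALSE]
  n <- row_norms(e)
  n[n < DEGENERATE_TOL] <- Inf
  ehat <- e / n
  F <- acc_rows(F, se[, 1], lambda * ehat)
  F <- acc_rows(F, se[, 2], -lambda * ehat)
  F
}

# Undirected edges (2-column matrix of vertex ids) present in both cycles.
shared_edges <- function(mesh, a, b) {
  ea <- cycle_edges(mesh$s_cycle[[a]])
  eb <- cycle_edges(mesh$s_cycle[[b]])
  nmax <- length(mesh$v_alive) + 1L
  ka <- pmin(ea[, 1], ea[, 2]) * nmax + pmax(ea[, 1], ea[, 2])
  kb <- pmin(eb[, 1], eb[, 2]) * nmax + pmax(eb[, 1], eb[, 2])
  ea[ka %in% kb, , drop = FALSE]
}

shared_edge_length <- function(mesh, a, b) {
  se <- shared_edges(mesh, a, b)
  if (nrow(se) == 0) return(0)
  sum(row_norms(mesh$pos[se[, 2], , drop = FALSE] -
                  mesh$pos[se[, 1], , drop = FALSE]))
}

cycle_edges <- function(cyc) {
  cbind(cyc, cyc[c(seq_along(cyc)[-1L], 1L)])
}

#' Evaluate a single actor on one object
#'
#' Convenience entry points used for verification: the energy and the full
#' vertex-force field of one actor applied to one surface or body, evaluated
#' independently of any binding model.
#'
#' @param mesh a `vm_mesh`.
#' @param actor a `vm_actor`.
#' @param id surface or body id matching the actor's class.
#' @return `actor_energy`: scalar (zero for non-energy actors);
#'   `actor_forces`: `n x 3` matrix of forces by vertex id.
#' @export
actor_energy <- function(mesh, actor, id) {
  md <- vm_model()
  if (actor$class == "surface") bind_actor(md, actor, surface = id)
  else bind_actor(md, actor, body = id)
  mesh_energy(mesh, md)
}

#' @rdname actor_energy
#' @export
actor_forces <- function(mesh, actor, id) {
  md <- vm_model()
  if (actor$class == "surface") bind_actor(md, actor, surface = id)
  else bind_actor(md, actor, body = id)
  mesh_forces(mesh, md)
}
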