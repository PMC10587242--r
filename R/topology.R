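# Dynamic-topology "quality operations": local transformations that keep the
# mesh well conditioned as vertices move. Every operation leaves the mesh in
# a valid state (cycles >= 3, bodies >= 4 surfaces, referential integrity),
# so no cleanup pass exists.

#' Quality-operation parameters
#'
#' Thresholds and switches for the automatic topology operations. The split
#' distance must exceed the merge distance so a fresh split is not
#' immediately re-merged; the conventional choice (and the default) is twice
#' the merge distance. The demote thresholds default to the merge distance
#' squared (surface area) and cubed (body volume).
#'
#' @param merge_distance distance below which two connected vertices merge.
#' @param split_distance separation given to the two vertices of a split.
#' @param surface_demote_area area below which a surface demotes to a vertex
#'   (T2).
#' @param body_demote_volume volume below which a body demotes to a vertex.
#' @param edge_penetration_tolerance maximum distance from the penetrated
#'   edge for a vertex-insert (T3) candidate.
#' @param enabled master switch; `FALSE` freezes the topology entirely.
#' @param merge,split,demote,insert per-operation switches.
#' @return A list of class `quality_params`.
#' @export
quality_params <- function(merge_distance = 0.1,
                           split_distance = 2 * merge_distance,
                           surface_demote_area = merge_distance^2,
                           body_demote_volume = merge_distance^3,
                           edge_penetration_tolerance = merge_distance,
                           enabled = TRUE, merge = TRUE, split = TRUE,
                           demote = TRUE, insert = TRUE) {
  stopifnot(merge_distance >= 0, split_distance > merge_distance,
            surface_demote_area >= 0, body_demote_volume >= 0,
            edge_penetration_tolerance >= 0)
  structure(list(merge_distance = merge_distance,
                 split_distance = split_distance,
                 surface_demote_area = surface_demote_area,
                 body_demote_volume = body_demote_volume,
                 edge_penetration_tolerance = edge_penetration_tolerance,
                 enabled = enabled, merge = merge, split = split,
                 demote = demote, insert = insert),
            class = "quality_params")
}

# Can these two vertices merge? Returns NULL if yes, else a reason string.
merge_refusal <- function(mesh, keep, remove) {
  if (!(remove %in% connected_vertices(mesh, keep))) {
    return("vertices are not connected")
  }
  ss <- union(mesh$v_surfs[[keep]], mesh$v_surfs[[remove]])
  if (any(lengths(mesh$s_cycle[ss]) < 4L)) {
    return("a defining surface has a cycle of fewer than 4 vertices")
  }
  NULL
}

#' Merge two connected vertices (edge collapse)
#'
#' The removed vertex is replaced by the kept vertex in every cycle it
#' appeared in (with duplicates collapsed); the kept vertex retains its own
#' position. Restricted to vertices all of whose defining surfaces have
#' cycles of four or more vertices, since the shared cycles lose a vertex.
#'
#' @param mesh a `vm_mesh`.
#' @param keep,remove connected vertex ids; `remove` is destroyed.
#' @return The kept vertex id, invisibly. Errors if the preconditions fail.
#' @export
vertex_merge <- function(mesh, keep, remove) {
  check_vertex(mesh, keep); check_vertex(mesh, remove)
  reason <- merge_refusal(mesh, keep, remove)
  if (!is.null(reason)) stop("vertex merge refused: ", reason, call. = FALSE)
  for (s in mesh$v_surfs[[remove]]) {
    cyc <- mesh$s_cycle[[s]]
    cyc[cyc == remove] <- keep
    w <- which(cyc == keep)
    if (length(w) > 1L) cyc <- cyc[-w[-1L]]
    mesh$s_cycle[[s]] <- cyc
    if (!(s %in% mesh$v_surfs[[keep]])) {
      mesh$v_surfs[[keep]] <- c(mesh$v_surfs[[keep]], s)
    }
  }
  mesh$v_surfs[[remove]] <- integer(0)
  drop_vertex(mesh, remove)
  invisible(keep)
}

#' Propose a vertex split (tension criterion)
#'
#' Evaluates whether splitting `vertex` into two vertices would create an
#' edge under tension, from the current per-vertex forces: (1) the total
#' force on the connected vertices relative to the candidate's force defines
#' a cut plane through the candidate, normal along that total relative
#' force; (2) connected vertices are partitioned by cut-plane side (a vertex
#' within 1e-12 of the plane goes to the positive side); (3) in the
#' candidate topology each split vertex is assumed to carry half the
#' candidate's force, and the total relative force on its own connected
#' vertices (excluding the other split vertex) must point away from the cut
#' plane on both sides for acceptance.
#'
#' @param mesh a `vm_mesh`.
#' @param vertex candidate vertex id with >= 4 connected vertices.
#' @param forces `n x 3` matrix of current forces by vertex id.
#' @param split_distance separation of the two split vertices.
#' @return A list with `accept` (logical), `reason`, and for workable
#'   geometry the `normal`, the connected-vertex partition (`side_pos`,
#'   `side_neg`) and `split_distance`; pass to [apply_vertex_split()].
#' @export
propose_vertex_split <- function(mesh, vertex, forces, split_distance) {
  check_vertex(mesh, vertex)
  conn <- connected_vertices(mesh, vertex)
  if (length(conn) < 4L) {
    return(list(accept = FALSE, reason = "fewer than 4 connected vertices",
                vertex = vertex))
  }
  fv <- forces[vertex, ]
  frel <- colSums(forces[conn, , drop = FALSE]) - length(conn) * fv
  nf <- vec_norm(frel)
  if (nf < DEGENERATE_TOL) {
    return(list(accept = FALSE, reason = "zero total relative force",
                vertex = vertex))
  }
  nhat <- frel / nf
  sgn <- as.numeric(sweep(mesh$pos[conn, , drop = FALSE], 2L,
                          mesh$pos[vertex, ]) %*% nhat)
  pos_side <- sgn >= -DEGENERATE_TOL
  side_pos <- conn[pos_side]
  side_neg <- conn[!pos_side]
  fhalf <- fv / 2
  tot_pos <- if (length(side_pos)) {
    colSums(forces[side_pos, , drop = FALSE]) - length(side_pos) * fhalf
  } else c(0, 0, 0)
  tot_neg <- if (length(side_neg)) {
    colSums(forces[side_neg, , drop = FALSE]) - length(side_neg) * fhalf
  } else c(0, 0, 0)
  accept <- sum(tot_pos * nhat) > 0 && sum(tot_neg * -nhat) > 0
  list(accept = accept,
       reason = if (accept) "new edge in tension" else "new edge in compression",
       vertex = vertex, normal = nhat, side_pos = side_pos,
       side_neg = side_neg, split_distance = split_distance)
}

#' Apply an accepted vertex split
#'
#' The candidate vertex keeps the negative cut-plane side and is displaced
#' by half the split distance against the plane normal; a new vertex on the
#' positive side is displaced the other way. Surfaces whose neighbors of the
#' candidate fall on both sides receive both split vertices (gaining the new
#' edge); surfaces entirely on one side keep that side's vertex only, which
#' can disconnect two surfaces that shared only the candidate vertex.
#'
#' @param mesh a `vm_mesh`.
#' @param proposal an accepted proposal from [propose_vertex_split()].
#' @return The new vertex id.
#' @export
apply_vertex_split <- function(mesh, proposal) {
  if (!isTRUE(proposal$accept)) stop("proposal was not accepted", call. = FALSE)
  v <- proposal$vertex
  check_vertex(mesh, v)
  nhat <- proposal$normal
  d <- proposal$split_distance / 2
  r0 <- mesh$pos[v, ]
  if (mesh$dim == 2L) {
    nhat[3] <- 0
    nn <- vec_norm(nhat)
    if (nn < DEGENERATE_TOL) stop("in-plane split normal degenerate", call. = FALSE)
    nhat <- nhat / nn
  }
  u <- add_vertex(mesh, r0 + d * nhat)      # positive side
  mesh$pos[v, ] <- r0 - d * nhat            # candidate keeps negative side
  side_of <- function(w) if (w %in% proposal$side_pos) u else v
  for (s in mesh$v_surfs[[v]]) {
    cyc <- mesh$s_cycle[[s]]
    k <- match(v, cyc)
    n <- length(cyc)
    p <- cyc[if (k == 1L) n else k - 1L]
    nx <- cyc[if (k == n) 1L else k + 1L]
    sp <- side_of(p); sn <- side_of(nx)
    repl <- if (sp == sn) sp else c(sp, sn)
    cyc <- append(cyc[-k], repl, after = if (k == 1L) n - 1L else k - 1L)
    mesh$s_cycle[[s]] <- cyc
    if (u %in% cyc && !(s %in% mesh$v_surfs[[u]])) {
      mesh$v_surfs[[u]] <- c(mesh$v_surfs[[u]], s)
    }
    if (!(v %in% cyc)) {
      mesh$v_surfs[[v]] <- setdiff(mesh$v_surfs[[v]], s)
    }
  }
  bump_topo(mesh)
  u
}

# Would demoting this surface be refused? NULL if allowed.
surface_demote_refusal <- function(mesh, s) {
  for (b in mesh$s_bodies[[s]]) {
    if (length(mesh$b_surfs[[b]]) <= 4L) {
      return("surface defines a body set of four surfaces")
    }
  }
  NULL
}

#' Demote a surface to a vertex (T2)
#'
#' Creates a new vertex at the surface centroid and replaces the surface
#' with it: every connected surface has the demoted surface's vertices
#' replaced by the new vertex (inserted once per cycle); connected surfaces
#' left with fewer than three vertices are removed as well. Refused for
#' surfaces that belong to a body of exactly four surfaces, since bodies are
#' never removed by this operation.
#'
#' @param mesh a `vm_mesh`.
#' @param s surface id to demote.
#' @param target_vertex optional existing vertex to demote onto (used by
#'   [body_demote()]); default creates one at the surface centroid.
#' @param check if `FALSE`, skip the body-of-four refusal (internal use).
#' @return List with `vertex` (the replacement vertex id) and
#'   `removed_surfaces` (ids removed, including `s`).
#' @export
surface_demote <- function(mesh, s, target_vertex = NULL, check = TRUE) {
  check_surface(mesh, s)
  if (check) {
    reason <- surface_demote_refusal(mesh, s)
    if (!is.null(reason)) stop("surface demote refused: ", reason, call. = FALSE)
  }
  old_vs <- mesh$s_cycle[[s]]
  nv <- if (is.null(target_vertex)) {
    add_vertex(mesh, surface_centroid(mesh, s))
  } else {
    check_vertex(mesh, target_vertex)
  }
  neighbors <- setdiff(unique(unlist(mesh$v_surfs[old_vs])), s)
  removed <- s
  drop_surface(mesh, s)
  touched <- old_vs
  for (t in neighbors) {
    cyc <- mesh$s_cycle[[t]]
    cyc[cyc %in% old_vs] <- nv
    w <- which(cyc == nv)
    if (length(w) > 1L) cyc <- cyc[-w[-1L]]
    if (length(cyc) < 3L) {
      touched <- union(touched, mesh$s_cycle[[t]])
      drop_surface(mesh, t)
      removed <- c(removed, t)
      next
    }
    for (v in setdiff(mesh$s_cycle[[t]], cyc)) {
      mesh$v_surfs[[v]] <- setdiff(mesh$v_surfs[[v]], t)
    }
    mesh$s_cycle[[t]] <- cyc
    if (!(t %in% mesh$v_surfs[[nv]])) {
      mesh$v_surfs[[nv]] <- c(mesh$v_surfs[[nv]], t)
    }
  }
  bump_topo(mesh)
  drop_orphan_vertices(mesh, setdiff(touched, nv))
  list(vertex = nv, removed_surfaces = removed)
}

# Deep copy of a mesh (used to simulate demote cascades without mutating).
mesh_clone <- function(mesh) {
  m <- new.env(parent = emptyenv())
  for (nm in ls(mesh)) m[[nm]] <- mesh[[nm]]
  class(m) <- "vm_mesh"
  m
}

#' Demote a body to a vertex
#'
#' Determines the full set of bodies removed by the operation by a
#' fixed-point cascade: starting from the demoted body, surfaces of the
#' current removed set are (virtually) surface-demoted; any body invalidated
#' by those removals joins the set, and the cascade repeats until stable.
#' The removed bodies and the surfaces defining only removed bodies are then
#' destroyed, a new vertex is created at the demoted body's centroid, and
#' every surface bordering a removed and a surviving body is surface-demoted
#' onto that vertex.
#'
#' @param mesh a `vm_mesh`.
#' @param b body id to demote.
#' @return The replacement vertex id.
#' @export
body_demote <- function(mesh, b) {
  check_body(mesh, b)
  centroid <- body_centroid(mesh, b)
  removed_bodies <- b
  repeat {
    cur_surfs <- unique(unlist(mesh$b_surfs[removed_bodies]))
    sim <- mesh_clone(mesh)
    dead <- integer(0)
    for (s in cur_surfs) {
      if (!sim$s_alive[s]) { dead <- union(dead, s); next }
      res <- surface_demote(sim, s, check = FALSE)
      dead <- union(dead, res$removed_surfaces)
    }
    invalidated <- setdiff(body_ids(mesh), removed_bodies)
    invalidated <- invalidated[vapply(invalidated, function(bb) {
      sum(!(mesh$b_surfs[[bb]] %in% dead)) < 4L
    }, logical(1))]
    if (length(invalidated) == 0L) break
    removed_bodies <- c(removed_bodies, invalidated)
  }
  all_surfs <- unique(unlist(mesh$b_surfs[removed_bodies]))
  boundary <- all_surfs[vapply(all_surfs, function(s) {
    any(!(mesh$s_bodies[[s]] %in% removed_bodies))
  }, logical(1))]
  interior <- setdiff(all_surfs, boundary)
  for (bb in removed_bodies) drop_body(mesh, bb)
  nv <- add_vertex(mesh, centroid)
  touched <- integer(0)
  for (s in interior) {
    touched <- union(touched, mesh$s_cycle[[s]])
    drop_surface(mesh, s)
  }
  drop_orphan_vertices(mesh, touched)
  for (s in boundary) {
    if (mesh$s_alive[s]) surface_demote(mesh, s, target_vertex = nv, check = FALSE)
  }
  nv
}

#' Insert a vertex into the cycle of an unconnected surface (T3)
#'
#' Handles the collision of two unconnected surfaces: the penetrating vertex
#' is inserted into the penetrated surface's cycle between the two vertices
#' of the penetrated edge, connecting the two surfaces.
#'
#' @param mesh a `vm_mesh`.
#' @param vertex penetrating vertex id (member of some other surface).
#' @param surface penetrated surface id, currently unconnected to every
#'   surface of `vertex`.
#' @param edge the penetrated edge as the two adjacent cycle vertex ids.
#' @return The surface id, invisibly.
#' @export
vertex_insert <- function(mesh, vertex, surface, edge) {
  check_vertex(mesh, vertex); check_surface(mesh, surface)
  for (s in mesh$v_surfs[[vertex]]) {
    if (surfaces_connected(mesh, s, surface)) {
      stop("vertex insert refused: surfaces already connected", call. = FALSE)
    }
  }
  cyc <- mesh$s_cycle[[surface]]
  n <- length(cyc)
  k <- match(edge[1], cyc)
  if (is.na(k) || cyc[if (k == n) 1L else k + 1L] != edge[2]) {
    k2 <- match(edge[2], cyc)
    if (!is.na(k2) && cyc[if (k2 == n) 1L else k2 + 1L] == edge[1]) {
      k <- k2
    } else {
      stop("edge is not an edge of the penetrated surface", call. = FALSE)
    }
  }
  mesh$s_cycle[[surface]] <- append(cyc, vertex, after = k)
  mesh$v_surfs[[vertex]] <- c(mesh$v_surfs[[vertex]], surface)
  bump_topo(mesh)
  invisible(surface)
}

#' Split a surface in two (manual division)
#'
#' Cuts a surface along a chord between two non-adjacent cycle positions;
#' each position is either an existing cycle vertex or a point on an edge
#' (which creates a vertex shared with the edge's other surface, if any).
#' The two parts share the new edge and inherit the parent's type.
#'
#' @param mesh a `vm_mesh`.
#' @param s surface id (must not define bodies).
#' @param at list of two cut positions; each either `list(vertex = id)` or
#'   `list(edge = c(a, b), t = fraction)` with `t` in (0, 1) along the edge.
#' @return Integer vector of the two new surface ids.
#' @export
split_surface <- function(mesh, s, at) {
  check_surface(mesh, s)
  if (length(mesh$s_bodies[[s]]) > 0L) {
    stop("cannot split a surface that defines a body", call. = FALSE)
  }
  stopifnot(length(at) == 2L)
  cut_vertex <- integer(2)
  for (k in 1:2) {
    spec <- at[[k]]
    if (!is.null(spec$vertex)) {
      cut_vertex[k] <- spec$vertex
      if (!(spec$vertex %in% mesh$s_cycle[[s]])) {
        stop("cut vertex is not in the surface cycle", call. = FALSE)
      }
    } else {
      a <- spec$edge[1]; b <- spec$edge[2]
      t <- if (is.null(spec$t)) 0.5 else spec$t
      nv <- add_vertex(mesh, (1 - t) * mesh$pos[a, ] + t * mesh$pos[b, ])
      # insert into every surface that has this edge (keeps the mesh conforming)
      for (t2 in intersect(mesh$v_surfs[[a]], mesh$v_surfs[[b]])) {
        cyc <- mesh$s_cycle[[t2]]
        n <- length(cyc)
        i <- match(a, cyc)
        j <- match(b, cyc)
        adj <- (i %% n) + 1L == j || (j %% n) + 1L == i
        if (!adj) next
        after <- if ((i %% n) + 1L == j) i else j
        mesh$s_cycle[[t2]] <- append(cyc, nv, after = after)
        mesh$v_surfs[[nv]] <- c(mesh$v_surfs[[nv]], t2)
      }
      cut_vertex[k] <- nv
    }
  }
  cyc <- mesh$s_cycle[[s]]
  i <- match(cut_vertex[1], cyc)
  j <- match(cut_vertex[2], cyc)
  n <- length(cyc)
  if (is.na(i) || is.na(j) || i == j) stop("invalid cut positions", call. = FALSE)
  if ((i %% n) + 1L == j || (j %% n) + 1L == i) {
    stop("surface split refused: cut positions are adjacent", call. = FALSE)
  }
  if (i < j) {
    cyc1 <- cyc[i:j]
    cyc2 <- cyc[c(j:n, 1:i)]
  } else {
    cyc1 <- cyc[c(i:n, 1:j)]
    cyc2 <- cyc[j:i]
  }
  type <- mesh$s_type[s]
  drop_surface(mesh, s)
  c(add_surface(mesh, cyc1, type = type), add_surface(mesh, cyc2, type = type))
}

# ---- per-step scheduling ---------------------------------------------------

# Affected-object sets per operation kind (conservative).
affected_of_merge <- function(mesh, keep, remove) {
  ss <- union(mesh$v_surfs[[keep]], mesh$v_surfs[[remove]])
  list(v = unique(c(keep, remove, connected_vertices(mesh, remove))),
       s = ss, b = unique(unlist(mesh$s_bodies[ss])))
}

affected_of_split <- function(mesh, v) {
  ss <- mesh$v_surfs[[v]]
  list(v = unique(c(v, connected_vertices(mesh, v))),
       s = ss, b = unique(unlist(mesh$s_bodies[ss])))
}

affected_of_surface_demote <- function(mesh, s) {
  vs <- mesh$s_cycle[[s]]
  ss <- unique(c(s, unlist(mesh$v_surfs[vs])))
  list(v = unique(c(vs, unlist(mesh$s_cycle[ss]))),
       s = ss, b = unique(unlist(mesh$s_bodies[ss])))
}

affected_of_insert <- function(mesh, vertex, surface, edge) {
  list(v = c(vertex, edge), s = c(surface, mesh$v_surfs[[vertex]]),
       b = unique(unlist(mesh$s_bodies[[surface]])))
}

affected_of_body_demote <- function(mesh, b) {
  ss <- mesh$b_surfs[[b]]
  vs <- unique(unlist(mesh$s_cycle[ss]))
  ss2 <- unique(c(ss, unlist(mesh$v_surfs[vs])))
  list(v = unique(c(vs, unlist(mesh$s_cycle[ss2]))), s = ss2,
       b = unique(c(b, unlist(mesh$s_bodies[ss2]))))
}

#' Run one round of quality operations
#'
#' Enumerates candidate operations level by level (vertices, then surfaces,
#' then bodies), evaluates them in increasing owner-id order (lower id =
#' higher priority), and applies each candidate only if none of its affected
#' objects was already affected this step, so the connectivity of each mesh
#' object changes at most once per step. Ownership follows the operation
#' kind: merge is owned by the lesser-id vertex, split by the splitting
#' vertex, demotes by the removed surface/body, insert by the penetrated
#' surface.
#'
#' @param mesh a `vm_mesh`.
#' @param forces `n x 3` per-vertex force matrix from the current step
#'   (required by the split criterion).
#' @param params a [quality_params()] list.
#' @return A list of operation log records (kind, owner, accepted, reason,
#'   ids involved).
#' @export
quality_step <- function(mesh, forces, params) {
  log <- list()
  if (!isTRUE(params$enabled)) return(log)
  nv0 <- length(mesh$v_alive); ns0 <- length(mesh$s_alive)
  nb0 <- length(mesh$b_alive)
  aff <- new.env(parent = emptyenv())
  aff$v <- logical(nv0 + 64L); aff$s <- logical(ns0 + 64L)
  aff$b <- logical(nb0 + 16L)
  is_free <- function(a) {
    !any(aff$v[a$v], na.rm = TRUE) && !any(aff$s[a$s], na.rm = TRUE) &&
      !any(aff$b[a$b], na.rm = TRUE)
  }
  mark <- function(a) {
    grow <- function(x, n) { if (length(x) < n) x[n] <- FALSE; x }
    aff$v <- grow(aff$v, max(a$v, 0)); aff$v[a$v] <- TRUE
    aff$s <- grow(aff$s, max(c(a$s, 0))); aff$s[a$s] <- TRUE
    aff$b <- grow(aff$b, max(c(a$b, 0))); aff$b[a$b] <- TRUE
  }
  note <- function(...) log[[length(log) + 1L]] <<- list(...)

  # --- level 1: vertex operations ---------------------------------------
  cands <- list()
  gi <- geom_index(mesh)
  if (isTRUE(params$merge) && length(gi$und) > 0) {
    elen_und <- row_norms(mesh$pos[gi$vb[gi$und], , drop = FALSE] -
                            mesh$pos[gi$va[gi$und], , drop = FALSE])
    short <- gi$und[elen_und < params$merge_distance]
    for (k in short) {
      a <- gi$va[k]; b <- gi$vb[k]
      cands[[length(cands) + 1L]] <- list(kind = "merge", owner = min(a, b),
                                          pair = c(a, b))
    }
  }
  if (isTRUE(params$split)) {
    for (v in which(gi$degree >= 4L)) {
      cands[[length(cands) + 1L]] <- list(kind = "split", owner = v, vertex = v)
    }
  }
  if (length(cands) > 0) {
    ord <- order(vapply(cands, `[[`, numeric(1), "owner"),
                 vapply(cands, function(c) match(c$kind, c("merge", "split")),
                        numeric(1)))
    for (cd in cands[ord]) {
      if (cd$kind == "merge") {
        a <- cd$pair[1]; b <- cd$pair[2]
        if (!mesh$v_alive[a] || !mesh$v_alive[b]) next
        reason <- merge_refusal(mesh, a, b)
        if (!is.null(reason)) {
          note(kind = "merge", owner = cd$owner, accepted = FALSE,
               reason = reason, ids = cd$pair)
          next
        }
        af <- affected_of_merge(mesh, a, b)
        if (!is_free(af)) next
        # one vertex is randomly selected for removal
        remove <- if (stats::runif(1) < 0.5) a else b
        keep <- if (remove == a) b else a
        vertex_merge(mesh, keep, remove)
        mark(af)
        note(kind = "merge", owner = cd$owner, accepted = TRUE,
             reason = "edge shorter than merge distance",
             ids = c(keep = keep, removed = remove))
      } else {
        v <- cd$vertex
        if (!mesh$v_alive[v]) next
        if (nrow(forces) < length(mesh$v_alive)) {
          # vertices created earlier this step carry zero force
          forces <- rbind(forces, matrix(0, length(mesh$v_alive) - nrow(forces), 3L))
        }
        prop <- propose_vertex_split(mesh, v, forces, params$split_distance)
        if (!isTRUE(prop$accept)) {
          if (!identical(prop$reason, "fewer than 4 connected vertices")) {
            note(kind = "split", owner = v, accepted = FALSE,
                 reason = prop$reason, ids = v)
          }
          next
        }
        af <- affected_of_split(mesh, v)
        if (!is_free(af)) next
        u <- apply_vertex_split(mesh, prop)
        af$v <- c(af$v, u)
        mark(af)
        note(kind = "split", owner = v, accepted = TRUE,
             reason = prop$reason, ids = c(kept = v, new = u))
      }
    }
  }

  # --- level 2: surface operations ---------------------------------------
  cands <- list()
  if (isTRUE(params$demote)) {
    gi <- geom_index(mesh)   # refresh: level 1 may have changed topology
    gm <- fan_measures(mesh$pos, gi$va, gi$vb, gi$grp, gi$nS)
    for (s in gi$sids[gm$area < params$surface_demote_area]) {
      cands[[length(cands) + 1L]] <- list(kind = "surface_demote",
                                          owner = s, surface = s)
    }
  }
  if (isTRUE(params$insert) && mesh$dim == 2L && sum(mesh$b_alive) == 0L) {
    pen <- find_penetrations(mesh, params$edge_penetration_tolerance)
    for (k in seq_len(nrow(pen))) {
      cands[[length(cands) + 1L]] <-
        list(kind = "insert", owner = pen[k, "surface"],
             vertex = pen[k, "vertex"], surface = pen[k, "surface"],
             edge = c(pen[k, "ea"], pen[k, "eb"]))
    }
  }
  if (length(cands) > 0) {
    ord <- order(vapply(cands, `[[`, numeric(1), "owner"))
    for (cd in cands[ord]) {
      if (cd$kind == "surface_demote") {
        s <- cd$surface
        if (!mesh$s_alive[s]) next
        reason <- surface_demote_refusal(mesh, s)
        if (!is.null(reason)) {
          note(kind = "surface_demote", owner = s, accepted = FALSE,
               reason = reason, ids = s)
          next
        }
        af <- affected_of_surface_demote(mesh, s)
        if (!is_free(af)) next
        res <- surface_demote(mesh, s)
        af$v <- c(af$v, res$vertex)
        mark(af)
        note(kind = "surface_demote", owner = s, accepted = TRUE,
             reason = "area below threshold",
             ids = c(vertex = res$vertex, removed = res$removed_surfaces))
      } else {
        if (!mesh$v_alive[cd$vertex] || !mesh$s_alive[cd$surface]) next
        connected <- any(vapply(mesh$v_surfs[[cd$vertex]], function(ss) {
          surfaces_connected(mesh, ss, cd$surface)
        }, logical(1)))
        if (connected) next
        if (!all(cd$edge %in% mesh$s_cycle[[cd$surface]])) next
        af <- affected_of_insert(mesh, cd$vertex, cd$surface, cd$edge)
        if (!is_free(af)) next
        vertex_insert(mesh, cd$vertex, cd$surface, cd$edge)
        mark(af)
        note(kind = "insert", owner = cd$surface, accepted = TRUE,
             reason = "vertex penetrated edge",
             ids = c(vertex = cd$vertex, surface = cd$surface))
      }
    }
  }

  # --- level 3: body operations ------------------------------------------
  if (isTRUE(params$demote) && sum(mesh$b_alive) > 0L) {
    cands <- list()
    for (b in body_ids(mesh)) {
      if (body_volume(mesh, b) < params$body_demote_volume) {
        cands[[length(cands) + 1L]] <- list(owner = b)
      }
    }
    if (length(cands) > 0) {
      ord <- order(vapply(cands, `[[`, numeric(1), "owner"))
      for (cd in cands[ord]) {
        b <- cd$owner
        if (!mesh$b_alive[b]) next
        af <- affected_of_body_demote(mesh, b)
        if (!is_free(af)) next
        nv <- body_demote(mesh, b)
        af$v <- c(af$v, nv)
        mark(af)
        note(kind = "body_demote", owner = b, accepted = TRUE,
             reason = "volume below threshold", ids = c(vertex = nv, body = b))
      }
    }
  }
  log
}

# T3 candidate detection (2D): vertices of one surface inside an unconnected
# surface's polygon and within tolerance of its nearest edge. A vectorized
# bounding-box prefilter against the "near set" of each surface (vertices of
# any surface sharing a vertex with it) keeps the common no-collision step
# cheap.
find_penetrations <- function(mesh, tol) {
  out <- matrix(integer(0), ncol = 4,
                dimnames = list(NULL, c("vertex", "surface", "ea", "eb")))
  sids <- surface_ids(mesh)
  if (length(sids) < 2L) return(out)
  vids <- vertex_ids(mesh)
  vx <- mesh$pos[vids, 1]; vy <- mesh$pos[vids, 2]
  gi <- geom_index(mesh)
  # near mask: vertex v is "near" surface s when it belongs to any surface
  # sharing a vertex with s (cached per topology; incidence-matrix product)
  nc <- mesh$near_cache
  if (is.null(nc) || nc$version != mesh$topo_version) {
    A <- matrix(0, nrow = length(mesh$v_alive), ncol = gi$nS)
    A[cbind(gi$va, gi$grp)] <- 1
    near <- (A %*% (crossprod(A) > 0)) > 0
    nc <- list(version = mesh$topo_version, near = near)
    mesh$near_cache <- nc
  }
  hits <- penetration_candidates(mesh$pos, vids, gi$va, gi$grp, gi$nS,
                                 nc$near, tol)
  if (nrow(hits) == 0) return(out)
  for (h in seq_len(nrow(hits))) {
    v <- vids[hits[h, 1]]
    s <- sids[hits[h, 2]]
    cyc <- mesh$s_cycle[[s]]
    {
      k <- hits[h, 1]
      if (length(mesh$v_surfs[[v]]) == 0L) next
      px <- mesh$pos[cyc, 1]; py <- mesh$pos[cyc, 2]
      if (!point_in_polygon(vx[k], vy[k], px, py)) next
      # nearest edge
      nn <- length(cyc)
      jx <- c(2:nn, 1L)
      dx <- px[jx] - px; dy <- py[jx] - py
      len2 <- pmax(dx^2 + dy^2, DEGENERATE_TOL)
      t <- pmin(pmax(((vx[k] - px) * dx + (vy[k] - py) * dy) / len2, 0), 1)
      d2 <- (px + t * dx - vx[k])^2 + (py + t * dy - vy[k])^2
      j <- which.min(d2)
      if (sqrt(d2[j]) <= tol) {
        out <- rbind(out, c(v, s, cyc[j], cyc[jx[j]]))
      }
    }
  }
  out
}

# Ray-casting point-in-polygon (inside or on the boundary).
point_in_polygon <- function(x, y, px, py, tol = 1e-12) {
  points_in_polygon(x, y, px, py, tol)[1]
}

# Vectorized over query points.
points_in_polygon <- function(xs, ys, px, py, tol = 1e-12) {
  n <- length(px)
  j <- c(2:n, 1L)
  dx <- px[j] - px; dy <- py[j] - py
  len2 <- pmax(dx^2 + dy^2, tol)
  m <- length(xs)
  inside <- logical(m)
  on_edge <- rep(FALSE, m)
  crossings <- integer(m)
  for (k in seq_len(n)) {
    # boundary proximity to edge k
    t <- pmin(pmax(((xs - px[k]) * dx[k] + (ys - py[k]) * dy[k]) / len2[k], 0), 1)
    d2 <- (px[k] + t * dx[k] - xs)^2 + (py[k] + t * dy[k] - ys)^2
    on_edge <- on_edge | d2 <= tol^2
    a <- py[k]; b <- py[j[k]]
    str <- (a > ys) != (b > ys)
    if (any(str)) {
      xint <- px[k] + (ys - a) / (b - a) * (px[j[k]] - px[k])
      crossings <- crossings + (str & xs < xint)
    }
  }
  (crossings %% 2L == 1L) | on_edge
}
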