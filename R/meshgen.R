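# Primitive mesh generators and tissue-level metrics. All generators emit
# counter-clockwise cycles (normal along +z in the plane) and pass full mesh
# validation; seeded generators are deterministic.

#' Square grid of quadrilateral cells
#'
#' `(n_x + 1) * (n_y + 1)` vertices and `n_x * n_y` quadrilateral surfaces
#' with shared edges between neighbors.
#'
#' @param n_x,n_y number of cells per axis (>= 1).
#' @param cell_side cell edge length.
#' @param origin lower-left corner.
#' @param type surface type for every cell.
#' @return A 2D `vm_mesh`.
#' @export
square_grid <- function(n_x, n_y, cell_side = 1, origin = c(0, 0), type = 1L) {
  stopifnot(n_x >= 1, n_y >= 1, cell_side > 0)
  mesh <- vm_mesh(2L)
  vid <- matrix(0L, n_x + 1L, n_y + 1L)
  for (j in 0:n_y) {
    for (i in 0:n_x) {
      vid[i + 1L, j + 1L] <- add_vertex(mesh, c(origin[1] + i * cell_side,
                                                origin[2] + j * cell_side, 0))
    }
  }
  for (j in seq_len(n_y)) {
    for (i in seq_len(n_x)) {
      add_surface(mesh, c(vid[i, j], vid[i + 1L, j],
                          vid[i + 1L, j + 1L], vid[i, j + 1L]), type = type)
    }
  }
  mesh
}

#' Circumradius of a regular hexagon of given area
#'
#' Inverts `A = (3 sqrt(3) / 2) R^2`.
#'
#' @param area hexagon area.
#' @return The circumradius.
#' @export
hexagon_circumradius <- function(area) {
  sqrt(2 * area / (3 * sqrt(3)))
}

#' Single regular hexagon surface
#'
#' @param mesh a 2D `vm_mesh` to add into (default: a fresh one).
#' @param center hexagon center.
#' @param circumradius distance from center to each corner.
#' @param phase angular offset of the first corner in radians. The default
#'   `pi / 6` gives a flat right edge (two rightmost corners at +-30 deg).
#' @param type surface type.
#' @return The mesh (with the surface added).
#' @export
regular_hexagon <- function(mesh = vm_mesh(2L), center = c(0, 0),
                            circumradius = 1, phase = pi / 6, type = 1L) {
  ang <- phase + (0:5) * pi / 3
  ids <- vapply(ang, function(a) {
    add_vertex(mesh, c(center[1] + circumradius * cos(a),
                       center[2] + circumradius * sin(a), 0))
  }, integer(1))
  add_surface(mesh, ids, type = type)
  mesh
}

#' Hexagonal sheet
#'
#' Regular hexagonal cells in `n_rings` rings around a central cell
#' (`n_rings = 0` is a single hexagon); shared corners are deduplicated so
#' interior vertices define three cells.
#'
#' @param n_rings number of rings (>= 0).
#' @param circumradius corner distance of each hexagon.
#' @param type surface type for every cell.
#' @return A 2D `vm_mesh` with `3 n (n + 1) + 1` cells for `n = n_rings`.
#' @export
hex_sheet <- function(n_rings, circumradius = 1, type = 1L) {
  stopifnot(n_rings >= 0)
  mesh <- vm_mesh(2L)
  r <- circumradius
  centers <- list()
  for (q in -n_rings:n_rings) {
    for (s in max(-n_rings, -q - n_rings):min(n_rings, -q + n_rings)) {
      # axial hex coordinates -> cartesian (pointy-top spacing)
      centers[[length(centers) + 1L]] <-
        c(sqrt(3) * r * (q + s / 2), 1.5 * r * s)
    }
  }
  seen <- new.env(parent = emptyenv())
  corner_id <- function(p) {
    key <- paste(round(p[1] / (1e-9 * r)), round(p[2] / (1e-9 * r)))
    id <- seen[[key]]
    if (is.null(id)) {
      id <- add_vertex(mesh, c(p, 0))
      seen[[key]] <- id
    }
    id
  }
  for (cen in centers) {
    ang <- pi / 6 + (0:5) * pi / 3
    ids <- vapply(ang, function(a) {
      corner_id(c(cen[1] + r * cos(a), cen[2] + r * sin(a)))
    }, integer(1))
    add_surface(mesh, ids, type = type)
  }
  mesh
}

#' Extrude a planar convex polygon into a prism body
#'
#' Builds two polygonal caps and one quadrilateral per side, then assembles
#' the body (orientation flags are determined automatically); the volume
#' equals the polygon area times the height.
#'
#' @param polygon `n x 2` (or `n x 3` with constant z) matrix of corner
#'   coordinates in cycle order.
#' @param height extrusion height along +z.
#' @param type body type.
#' @param drag_density optional body drag density.
#' @return List with the 3D `vm_mesh` and the `body` id.
#' @export
extruded_prism <- function(polygon, height, type = 1L,
                           drag_density = NA_real_) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) == 2L) polygon <- cbind(polygon, 0)
  if (diff(range(polygon[, 3])) > 1e-9) {
    stop("polygon must be planar (constant z)", call. = FALSE)
  }
  n <- nrow(polygon)
  mesh <- vm_mesh(3L)
  lo <- vapply(seq_len(n), function(k) add_vertex(mesh, polygon[k, ]), integer(1))
  hi <- vapply(seq_len(n), function(k) {
    add_vertex(mesh, polygon[k, ] + c(0, 0, height))
  }, integer(1))
  bottom <- add_surface(mesh, rev(lo))
  top <- add_surface(mesh, hi)
  sides <- vapply(seq_len(n), function(k) {
    k2 <- if (k == n) 1L else k + 1L
    add_surface(mesh, c(lo[k], lo[k2], hi[k2], hi[k]))
  }, integer(1))
  body <- add_body(mesh, c(bottom, top, sides), type = type,
                   drag_density = drag_density)
  list(mesh = mesh, body = body)
}

#' Heterotypic boundary length
#'
#' The total length of edges shared by surfaces of different types, each
#' shared edge counted once. `fractional_heterotypic_length` normalizes by a
#' reference measurement (conventionally the value at time zero).
#'
#' @param mesh a `vm_mesh`.
#' @param reference positive reference length.
#' @return Scalar length (raw or fractional).
#' @export
heterotypic_length <- function(mesh) {
  gi <- geom_index(mesh)
  if (length(gi$shared_first) == 0) return(0)
  i1 <- gi$shared_first
  t1 <- mesh$s_type[gi$sids[gi$grp[i1]]]
  t2 <- mesh$s_type[gi$sids[gi$grp[gi$shared_second]]]
  het <- which(t1 != t2)
  if (length(het) == 0) return(0)
  sum(row_norms(mesh$pos[gi$vb[i1[het]], , drop = FALSE] -
                  mesh$pos[gi$va[i1[het]], , drop = FALSE]))
}

#' @rdname heterotypic_length
#' @export
fractional_heterotypic_length <- function(mesh, reference) {
  if (!is.numeric(reference) || reference <= 0) {
    stop("reference heterotypic length must be positive", call. = FALSE)
  }
  heterotypic_length(mesh) / reference
}

#' Random fiber substrate between two sine waves
#'
#' Scatters straight fibers of random length and orientation inside a
#' sinusoidal channel: points (x, y) with
#' `|y - amplitude * sin(2 pi x / period)| <= width / 2`. A candidate fiber
#' is kept only if every segment particle falls inside the channel (and the
#' x-range), so the constraint holds by construction.
#'
#' @param ps a `particle_system` to fill.
#' @param width channel width.
#' @param period sine period.
#' @param amplitude sine amplitude.
#' @param density target fiber count per unit channel area (x-extent times
#'   width).
#' @param xlim x-extent of the substrate, e.g. `c(0, period)`.
#' @param segment_range integer range of segment counts per fiber.
#' @param r0 segment spacing (tensile rest length).
#' @param k_tensile,k_bending,damping fiber bond parameters.
#' @param max_tries rejection-sampling attempts per fiber.
#' @return The particle system, invisibly; fibers added in place.
#' @export
sine_channel_substrate <- function(ps, width = 1, period = 4, amplitude = 1,
                                   density = 8, xlim = c(0, period),
                                   segment_range = c(10L, 100L), r0 = 0.01,
                                   k_tensile = 10, k_bending = 1e-4,
                                   damping = 1, max_tries = 200L) {
  stopifnot(width > 0, period > 0, density >= 0)
  n_fibers <- round(density * diff(xlim) * width)
  inside <- function(x, y) {
    abs(y - amplitude * sin(2 * pi * x / period)) <= width / 2 &
      x >= xlim[1] & x <= xlim[2]
  }
  for (f in seq_len(n_fibers)) {
    nseg <- sample(segment_range[1]:segment_range[2], 1L)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      theta <- stats::runif(1, 0, 2 * pi)
      midx <- stats::runif(1, xlim[1], xlim[2])
      midy <- amplitude * sin(2 * pi * midx / period) +
        stats::runif(1, -width / 2, width / 2)
      dir <- c(cos(theta), sin(theta))
      off <- (seq_len(nseg) - (nseg + 1) / 2) * r0
      xs <- midx + off * dir[1]
      ys <- midy + off * dir[2]
      if (all(inside(xs, ys))) {
        build_fiber(ps, c(xs[1], ys[1], 0), c(dir, 0), nseg,
                    k_tensile = k_tensile, r0_tensile = r0,
                    k_bending = k_bending, damping = damping)
        placed <- TRUE
        break
      }
    }
  }
  invisible(ps)
}
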