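# Bead-spring particle subsystem for hybrid vertex-particle models:
# extracellular-matrix fibers as clusters of bonded segment particles, and
# integrin particles linking fibers to cell vertices.

SPECIES_FIBER <- 1L
SPECIES_INTEGRIN <- 2L

#' Create an empty particle system
#'
#' Particles carry a position, a species (fiber segment or integrin), a
#' damping coefficient and, for fiber segments, a cluster (fiber) id.
#' Interactions are bonded (tensile, bending, integrin-fiber,
#' integrin-vertex) or pairwise (an inter-fiber Morse-form adhesion between
#' segment particles of different fibers).
#'
#' @return An environment of class `particle_system`.
#' @export
particle_system <- function() {
  ps <- new.env(parent = emptyenv())
  ps$pos <- matrix(numeric(0), ncol = 3L)
  ps$alive <- logical(0)
  ps$species <- integer(0)
  ps$damping <- numeric(0)
  ps$cluster <- integer(0)           # fiber id; NA for integrins
  ps$tensile <- list(i = integer(0), j = integer(0), k = numeric(0),
                     r0 = numeric(0))
  ps$bending <- list(i = integer(0), j = integer(0), k = integer(0),
                     kb = numeric(0), th0 = numeric(0))
  ps$integ <- list(i = integer(0), j = integer(0), k = numeric(0),
                   r0 = numeric(0), alive = logical(0))  # i integrin, j fiber
  ps$cyto <- list(i = integer(0), v = integer(0), k = numeric(0),
                  alive = logical(0))                    # i integrin, v vertex
  ps$pair_rule <- NULL
  ps$nl <- NULL
  ps$nl_age <- 0L
  ps$nl_every <- 10L
  class(ps) <- "particle_system"
  ps
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("<particle_system: %d fiber segments, %d integrins, %d fibers>\n",
              sum(x$alive & x$species == SPECIES_FIBER),
              sum(x$alive & x$species == SPECIES_INTEGRIN),
              length(unique(x$cluster[x$alive & !is.na(x$cluster)]))))
  invisible(x)
}

add_particle <- function(ps, position, species, damping, cluster = NA_integer_) {
  # reuse rows of destroyed particles to keep the store compact under the
  # integrin creation/destruction churn
  if (!is.null(ps$free) && length(ps$free) > 0) {
    id <- ps$free[length(ps$free)]
    ps$free <- ps$free[-length(ps$free)]
    ps$pos[id, ] <- as_point3(position)
  } else {
    ps$pos <- rbind(ps$pos, as_point3(position), deparse.level = 0)
    id <- nrow(ps$pos)
  }
  ps$alive[id] <- TRUE
  ps$species[id] <- species
  ps$damping[id] <- damping
  ps$cluster[id] <- cluster
  # the neighbor list tracks fiber segment particles only
  if (species == SPECIES_FIBER) ps$nl <- NULL
  id
}

# Mark a particle dead and make its row reusable.
free_particle <- function(ps, ids) {
  ps$alive[ids] <- FALSE
  ps$free <- c(ps$free, ids)
  invisible(ps)
}

# Drop dead bond rows (bond rows carry no stable identity).
compact_bonds <- function(ps) {
  keep <- ps$integ$alive
  if (!all(keep)) ps$integ <- lapply(ps$integ, `[`, keep)
  keep <- ps$cyto$alive
  if (!all(keep)) ps$cyto <- lapply(ps$cyto, `[`, keep)
  invisible(ps)
}

#' Bond and pair potentials
#'
#' The interaction energies of the fiber/integrin subsystem, as functions of
#' separation `r` (or bend angle `theta`):
#' \describe{
#'   \item{`potential_tensile`}{`k * (r - r0)^2`, harmonic stretch between
#'     adjacent segment particles of one fiber.}
#'   \item{`potential_bending`}{`k * (theta - theta0)^2` on the angle at
#'     each interior segment particle; `theta0 = pi` makes straight fibers
#'     stress-free.}
#'   \item{`potential_interfiber`}{Morse form
#'     `k * (1 - exp(-a * (r - r0)))^2` between segment particles of
#'     different fibers (adhesion without friction); tends to `k` at large
#'     separation.}
#'   \item{`potential_integrin`}{`k * (r - r0)^2` between an integrin and
#'     its fiber segment particle.}
#'   \item{`potential_cytoskeleton`}{`k * r` between an integrin and a cell
#'     vertex; negative `k` gives a constant-magnitude protrusive force
#'     `|k|` pushing the pair apart.}
#' }
#' Each returns a list with `energy` and `dU_dr` (or `dU_dtheta`); the force
#' on each endpoint is `-dU_dr` along the separation axis, equal and
#' opposite.
#'
#' @param r separation (>= 0).
#' @param theta bend angle in (0, pi].
#' @param k,r0,a,theta0 potential parameters.
#' @name particle_potentials
NULL

#' @rdname particle_potentials
#' @export
potential_tensile <- function(r, k, r0) {
  list(energy = k * (r - r0)^2, dU_dr = 2 * k * (r - r0))
}

#' @rdname particle_potentials
#' @export
potential_bending <- function(theta, k, theta0) {
  list(energy = k * (theta - theta0)^2, dU_dtheta = 2 * k * (theta - theta0))
}

#' @rdname particle_potentials
#' @export
potential_interfiber <- function(r, k, a, r0) {
  ex <- exp(-a * (r - r0))
  list(energy = k * (1 - ex)^2, dU_dr = 2 * k * a * ex * (1 - ex))
}

#' @rdname particle_potentials
#' @export
potential_integrin <- function(r, k, r0) {
  list(energy = k * (r - r0)^2, dU_dr = 2 * k * (r - r0))
}

#' @rdname particle_potentials
#' @export
potential_cytoskeleton <- function(r, k) {
  list(energy = k * r, dU_dr = rep(k, length(r)))
}

#' Build a straight fiber
#'
#' Places `n_segments` fiber segment particles along a line at the tensile
#' rest spacing, with tensile bonds between neighbors and bending bonds on
#' consecutive triples; a fresh straight fiber carries zero energy.
#'
#' @param ps a `particle_system`.
#' @param start 3-vector (or 2-vector) position of the first particle.
#' @param direction direction of the fiber axis (normalized internally).
#' @param n_segments number of particles (>= 2).
#' @param k_tensile,r0_tensile,k_bending,theta0 bond parameters.
#' @param damping per-particle damping coefficient.
#' @return The fiber (cluster) id.
#' @export
build_fiber <- function(ps, start, direction, n_segments,
                        k_tensile = 10, r0_tensile = 0.01,
                        k_bending = 1e-4, theta0 = pi, damping = 1) {
  if (n_segments < 2L) stop("a fiber needs at least 2 segments", call. = FALSE)
  dir <- as_point3(direction)
  dir <- dir / vec_norm(dir)
  fid <- if (length(ps$cluster) == 0 || all(is.na(ps$cluster))) 1L else
    max(ps$cluster, na.rm = TRUE) + 1L
  ids <- integer(n_segments)
  for (k in seq_len(n_segments)) {
    ids[k] <- add_particle(ps, as_point3(start) + (k - 1) * r0_tensile * dir,
                           SPECIES_FIBER, damping, cluster = fid)
  }
  ps$tensile$i <- c(ps$tensile$i, ids[-n_segments])
  ps$tensile$j <- c(ps$tensile$j, ids[-1L])
  ps$tensile$k <- c(ps$tensile$k, rep(k_tensile, n_segments - 1L))
  ps$tensile$r0 <- c(ps$tensile$r0, rep(r0_tensile, n_segments - 1L))
  if (n_segments >= 3L) {
    ps$bending$i <- c(ps$bending$i, ids[1:(n_segments - 2L)])
    ps$bending$j <- c(ps$bending$j, ids[2:(n_segments - 1L)])
    ps$bending$k <- c(ps$bending$k, ids[3:n_segments])
    ps$bending$kb <- c(ps$bending$kb, rep(k_bending, n_segments - 2L))
    ps$bending$th0 <- c(ps$bending$th0, rep(theta0, n_segments - 2L))
  }
  fid
}

#' Configure the inter-fiber pairwise rule
#'
#' Applies the Morse-form adhesion between fiber segment particles of
#' different fibers. Same-fiber pairs are excluded. The interaction width is
#' `1 / a`; the default cutoff of three widths beyond the rest length keeps
#' more than 95% of the well depth while truncating forces below 5% of
#' their peak.
#'
#' @param ps a `particle_system`.
#' @param k,a,r0 Morse parameters (magnitude, width, target length).
#' @param cutoff interaction cutoff; default `r0 + 3 / a`.
#' @param rebuild_every neighbor-list rebuild cadence in force evaluations.
#' @export
set_interfiber_rule <- function(ps, k, a, r0, cutoff = r0 + 3 / a,
                                rebuild_every = 10L) {
  ps$pair_rule <- list(k = k, a = a, r0 = r0, cutoff = cutoff)
  ps$nl_every <- as.integer(rebuild_every)
  ps$nl <- NULL
  invisible(ps)
}

# Uniform-grid neighbor list over fiber segment particles; pairs from
# different clusters within cutoff (+ skin).
build_neighbor_list <- function(ps, cutoff, skin = 0.25 * cutoff) {
  ids <- which(ps$alive & ps$species == SPECIES_FIBER)
  if (length(ids) < 2L) return(cbind(i = integer(0), j = integer(0)))
  grid_neighbor_pairs(ps$pos, ids, ps$cluster[ids], cutoff + skin)
}

# ---- force/energy evaluation ----------------------------------------------

# Gradient of the bend angle at triple (p1, p2, p3): angle between
# u = p1 - p2 and v = p3 - p2.
angle_and_grads <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  lu <- row_norms(u); lv <- row_norms(v)
  bad <- lu < DEGENERATE_TOL | lv < DEGENERATE_TOL
  lu[bad] <- 1; lv[bad] <- 1
  uh <- u / lu; vh <- v / lv
  ct <- pmin(pmax(rowSums(uh * vh), -1), 1)
  th <- acos(ct)
  st <- sqrt(pmax(1 - ct^2, 0))
  ok <- !bad & st > 1e-8
  inv <- ifelse(ok, 1 / st, 0)
  g1 <- -(vh - ct * uh) / lu * inv
  g3 <- -(uh - ct * vh) / lv * inv
  g2 <- -(g1 + g3)
  list(theta = th, g1 = g1, g2 = g2, g3 = g3, ok = ok)
}

#' Particle-system forces
#'
#' Evaluates all bonded and pairwise potentials. All internal forces are
#' equal and opposite, so the total momentum injected is zero; the
#' cytoskeleton bonds also act on mesh vertices, returned separately.
#'
#' @param ps a `particle_system`.
#' @param mesh the mesh holding the vertices referenced by cytoskeleton
#'   bonds (may be `NULL` when there are none).
#' @return List with `particle` (`m x 3` forces by particle id) and
#'   `vertex` (`n x 3` forces by vertex id).
#' @export
particle_forces <- function(ps, mesh = NULL) {
  Fp <- matrix(0, nrow = length(ps$alive), ncol = 3L)
  nv <- if (is.null(mesh)) 0L else length(mesh$v_alive)
  Fv <- matrix(0, nrow = nv, ncol = 3L)

  add_pair_forces <- function(i, j, dU_dr) {
    d <- ps$pos[j, , drop = FALSE] - ps$pos[i, , drop = FALSE]
    r <- row_norms(d)
    r[r < DEGENERATE_TOL] <- Inf
    f <- -dU_dr / r * d           # force on j
    Fp <<- acc_rows(Fp, j, f)
    Fp <<- acc_rows(Fp, i, -f)
    invisible(NULL)
  }

  tb <- ps$tensile
  if (length(tb$i) > 0) {
    d <- ps$pos[tb$j, , drop = FALSE] - ps$pos[tb$i, , drop = FALSE]
    r <- row_norms(d)
    add_pair_forces(tb$i, tb$j, potential_tensile(r, tb$k, tb$r0)$dU_dr)
  }
  bb <- ps$bending
  if (length(bb$i) > 0) {
    ag <- angle_and_grads(ps$pos[bb$i, , drop = FALSE],
                          ps$pos[bb$j, , drop = FALSE],
                          ps$pos[bb$k, , drop = FALSE])
    dU <- potential_bending(ag$theta, bb$kb, bb$th0)$dU_dtheta * ag$ok
    Fp <- acc_rows(Fp, bb$i, -dU * ag$g1)
    Fp <- acc_rows(Fp, bb$j, -dU * ag$g2)
    Fp <- acc_rows(Fp, bb$k, -dU * ag$g3)
  }
  if (!is.null(ps$pair_rule)) {
    pr <- ps$pair_rule
    if (is.null(ps$nl) || ps$nl_age >= ps$nl_every) {
      ps$nl <- build_neighbor_list(ps, pr$cutoff)
      ps$nl_age <- 0L
    }
    ps$nl_age <- ps$nl_age + 1L
    nl <- ps$nl
    if (nrow(nl) > 0) {
      Fp <- Fp + morse_pair_forces(ps$pos, nl[, 1], nl[, 2], pr$k, pr$a,
                                   pr$r0, pr$cutoff, nrow(Fp))
    }
  }
  ib <- ps$integ
  live_ib <- which(ib$alive)
  if (length(live_ib) > 0) {
    i <- ib$i[live_ib]; j <- ib$j[live_ib]
    d <- ps$pos[j, , drop = FALSE] - ps$pos[i, , drop = FALSE]
    r <- row_norms(d)
    add_pair_forces(i, j, potential_integrin(r, ib$k[live_ib], ib$r0[live_ib])$dU_dr)
  }
  cb <- ps$cyto
  live_cb <- which(cb$alive)
  if (length(live_cb) > 0 && !is.null(mesh)) {
    i <- cb$i[live_cb]; v <- cb$v[live_cb]
    d <- mesh$pos[v, , drop = FALSE] - ps$pos[i, , drop = FALSE]
    r <- row_norms(d)
    ok <- r >= DEGENERATE_TOL
    rr <- ifelse(ok, r, Inf)
    f <- -cb$k[live_cb] / rr * d    # force on the vertex
    Fv <- acc_rows(Fv, v, f)
    Fp <- acc_rows(Fp, i, -f)
  }
  list(particle = Fp, vertex = Fv)
}

#' Total particle-system potential energy
#'
#' @inheritParams particle_forces
#' @return Scalar energy (bonded plus in-cutoff pairwise terms).
#' @export
particle_energy <- function(ps, mesh = NULL) {
  H <- 0
  tb <- ps$tensile
  if (length(tb$i) > 0) {
    r <- row_norms(ps$pos[tb$j, , drop = FALSE] - ps$pos[tb$i, , drop = FALSE])
    H <- H + sum(potential_tensile(r, tb$k, tb$r0)$energy)
  }
  bb <- ps$bending
  if (length(bb$i) > 0) {
    ag <- angle_and_grads(ps$pos[bb$i, , drop = FALSE],
                          ps$pos[bb$j, , drop = FALSE],
                          ps$pos[bb$k, , drop = FALSE])
    H <- H + sum(potential_bending(ag$theta, bb$kb, bb$th0)$energy[ag$ok])
  }
  if (!is.null(ps$pair_rule)) {
    pr <- ps$pair_rule
    nl <- build_neighbor_list(ps, pr$cutoff, skin = 0)
    if (nrow(nl) > 0) {
      r <- row_norms(ps$pos[nl[, 2], , drop = FALSE] -
                       ps$pos[nl[, 1], , drop = FALSE])
      H <- H + sum(potential_interfiber(r[r <= pr$cutoff], pr$k, pr$a, pr$r0)$energy)
    }
  }
  ib <- ps$integ
  live_ib <- which(ib$alive)
  if (length(live_ib) > 0) {
    r <- row_norms(ps$pos[ib$j[live_ib], , drop = FALSE] -
                     ps$pos[ib$i[live_ib], , drop = FALSE])
    H <- H + sum(potential_integrin(r, ib$k[live_ib], ib$r0[live_ib])$energy)
  }
  cb <- ps$cyto
  live_cb <- which(cb$alive)
  if (length(live_cb) > 0 && !is.null(mesh)) {
    r <- row_norms(mesh$pos[cb$v[live_cb], , drop = FALSE] -
                     ps$pos[cb$i[live_cb], , drop = FALSE])
    H <- H + sum(potential_cytoskeleton(r, cb$k[live_cb])$energy)
  }
  H
}

#' Export the fiber substrate as a data frame
#'
#' @param ps a `particle_system`.
#' @return Data frame with `particle`, `fiber`, `x`, `y` for live fiber
#'   segment particles.
#' @export
fiber_table <- function(ps) {
  ids <- which(ps$alive & ps$species == SPECIES_FIBER)
  data.frame(particle = ids, fiber = ps$cluster[ids],
             x = ps$pos[ids, 1], y = ps$pos[ids, 2])
}
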