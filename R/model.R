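# Actors: parameterized force/energy models that resolve to forces on
# vertices. Actors bind to individual mesh objects or to object types;
# bindings are additive, so the force on a vertex is the sum over all
# bindings that match any object the vertex defines.

new_actor <- function(kind, class, ...) {
  structure(list(kind = kind, class = class, ...), class = "vm_actor")
}

#' @export
print.vm_actor <- function(x, ...) {
  ps <- setdiff(names(x), c("kind", "class"))
  cat(sprintf("<actor %s on %s: %s>\n", x$kind, x$class,
              paste(sprintf("%s=%s", ps,
                            vapply(x[ps], function(v) paste(signif(unlist(v), 4),
                                                            collapse = ","),
                                   character(1))), collapse = ", ")))
  invisible(x)
}

#' Surface actors
#'
#' Constructors for the built-in surface-bound actors:
#' \describe{
#'   \item{`surface_area_constraint`}{quadratic energy
#'     `lambda * (A - target)^2` pressing the surface area toward `target`.}
#'   \item{`perimeter_constraint`}{quadratic energy
#'     `lambda * (L - target)^2` on the cycle perimeter.}
#'   \item{`edge_tension`}{energy `lambda * sum(edge length^p)` over the
#'     cycle edges, with exponent `p` of 1 (contractile line tension) or
#'     2 (harmonic).}
#'   \item{`surface_traction`}{a uniform traction vector distributed over
#'     cycle vertices in proportion to their area contributions, so the
#'     total applied force is `A * tau`.}
#'   \item{`normal_stress`}{a traction of `magnitude` along the surface
#'     unit normal.}
#'   \item{`flat_surface_constraint`}{restoring force pulling each cycle
#'     vertex toward the least-squares plane of the cycle; zero for planar
#'     polygons.}
#'   \item{`convex_polygon_constraint`}{restoring force pulling reflex
#'     vertices toward the chord joining their cycle neighbors (with the
#'     reaction split between the neighbors); zero for convex polygons.}
#' }
#'
#' @param lambda non-negative model parameter (energy scale).
#' @param target target area (`surface_area_constraint`) or perimeter
#'   (`perimeter_constraint`).
#' @param p edge-length exponent, 1 or 2.
#' @param tau traction vector (3-vector; 2-vectors are padded).
#' @param magnitude signed normal-stress magnitude; positive pushes along
#'   the surface normal.
#' @param strength restoring-force gain for the shape constraints.
#' @return A `vm_actor` object to pass to [bind_actor()].
#' @name surface_actors
NULL

#' @rdname surface_actors
#' @export
surface_area_constraint <- function(lambda, target) {
  stopifnot(lambda >= 0)
  new_actor("area_constraint", "surface", lambda = lambda, target = target)
}

#' @rdname surface_actors
#' @export
perimeter_constraint <- function(lambda, target) {
  stopifnot(lambda >= 0)
  new_actor("perimeter_constraint", "surface", lambda = lambda, target = target)
}

#' @rdname surface_actors
#' @export
edge_tension <- function(lambda, p = 1L) {
  stopifnot(p %in% c(1L, 2L))
  new_actor("edge_tension", "surface", lambda = lambda, p = as.integer(p))
}

#' @rdname surface_actors
#' @export
surface_traction <- function(tau) {
  new_actor("surface_traction", "surface", tau = as_point3(tau))
}

#' @rdname surface_actors
#' @export
normal_stress <- function(magnitude) {
  new_actor("normal_stress", "surface", magnitude = magnitude)
}

#' @rdname surface_actors
#' @export
flat_surface_constraint <- function(strength = 1) {
  stopifnot(strength >= 0)
  new_actor("flat_constraint", "surface", strength = strength)
}

#' @rdname surface_actors
#' @export
convex_polygon_constraint <- function(strength = 1) {
  stopifnot(strength >= 0)
  new_actor("convex_constraint", "surface", strength = strength)
}

#' Body actors
#'
#' Constructors for the built-in body-bound actors: a quadratic volume
#' constraint `lambda * (V - target)^2`, a quadratic constraint on the body
#' surface area, and a uniform body force distributed over the body's
#' vertices in proportion to their volume contributions (total applied force
#' equals `force`).
#'
#' @param lambda non-negative model parameter.
#' @param target target volume or body surface area.
#' @param force force vector acting uniformly on the body.
#' @return A `vm_actor`.
#' @name body_actors
NULL

#' @rdname body_actors
#' @export
body_volume_constraint <- function(lambda, target) {
  stopifnot(lambda >= 0)
  new_actor("volume_constraint", "body", lambda = lambda, target = target)
}

#' @rdname body_actors
#' @export
body_area_constraint <- function(lambda, target) {
  stopifnot(lambda >= 0)
  new_actor("body_area_constraint", "body", lambda = lambda, target = target)
}

#' @rdname body_actors
#' @export
body_force <- function(force) {
  new_actor("body_force", "body", force = as_point3(force))
}

#' Create an empty binding model
#'
#' A model collects actor bindings (to objects and to types) and pairwise
#' adhesion parameters. Types are positive integer tags shared with the mesh
#' objects' `type` fields.
#'
#' @return An object of class `vm_model` (environment, updated in place).
#' @export
vm_model <- function() {
  md <- new.env(parent = emptyenv())
  md$surface_type_actors <- list()   # [[type]] -> list of actors
  md$body_type_actors <- list()
  md$surface_actors <- list()        # [[surface id]] -> list of actors
  md$body_actors <- list()
  md$adh2d <- matrix(numeric(0), 0, 0)  # lambda^adh by surface-type pair
  md$adh3d <- matrix(numeric(0), 0, 0)  # lambda^adh by body-type pair
  md$version <- 0L
  class(md) <- "vm_model"
  md
}

#' @export
print.vm_model <- function(x, ...) {
  nb <- length(unlist(x$surface_type_actors, recursive = FALSE)) +
    length(unlist(x$body_type_actors, recursive = FALSE)) +
    length(unlist(x$surface_actors, recursive = FALSE)) +
    length(unlist(x$body_actors, recursive = FALSE))
  cat(sprintf("<vm_model: %d actor bindings, %d surface-type adhesion pairs>\n",
              nb, sum(x$adh2d != 0) %/% 2 + sum(diag(x$adh2d) != 0)))
  invisible(x)
}

#' Bind an actor to a mesh object or an object type
#'
#' Binding is additive: successive bindings to the same object or type sum
#' their forces. A type-level binding applies the actor to every object of
#' that type.
#'
#' @param model a `vm_model`.
#' @param actor a `vm_actor`.
#' @param surface,body,surface_type,body_type exactly one of these chooses
#'   the binding target (object id or type id).
#' @export
bind_actor <- function(model, actor, surface = NULL, body = NULL,
                       surface_type = NULL, body_type = NULL) {
  stopifnot(inherits(model, "vm_model"), inherits(actor, "vm_actor"))
  tgt <- c(!is.null(surface), !is.null(body), !is.null(surface_type),
           !is.null(body_type))
  if (sum(tgt) != 1L) stop("specify exactly one binding target", call. = FALSE)
  add_to <- function(field, key) {
    lst <- model[[field]]
    if (length(lst) < key || is.null(lst[key][[1]])) lst[key] <- list(list())
    lst[[key]] <- c(lst[[key]], list(actor))
    model[[field]] <- lst
  }
  if (!is.null(surface)) {
    stopifnot(actor$class == "surface"); add_to("surface_actors", surface)
  } else if (!is.null(surface_type)) {
    stopifnot(actor$class == "surface"); add_to("surface_type_actors", surface_type)
  } else if (!is.null(body)) {
    stopifnot(actor$class == "body"); add_to("body_actors", body)
  } else {
    stopifnot(actor$class == "body"); add_to("body_type_actors", body_type)
  }
  model$version <- model$version + 1L
  invisible(model)
}

#' Set an adhesion parameter for an unordered type pair
#'
#' Adhesion acts along shared edges of connected surfaces (2D) or on shared
#' surfaces of connected bodies (3D), with energy `lambda` times the shared
#' length/area. Negative `lambda` makes shared interface energetically
#' favorable (tensile interface force); unlisted pairs default to zero.
#'
#' @param model a `vm_model`.
#' @param type_a,type_b type tags (surface types for `class = "surface"`,
#'   body types for `class = "body"`).
#' @param lambda adhesion parameter.
#' @param class `"surface"` (2D, shared-edge length) or `"body"` (3D,
#'   shared-surface area).
#' @export
set_adhesion <- function(model, type_a, type_b, lambda, class = "surface") {
  stopifnot(inherits(model, "vm_model"))
  field <- if (class == "surface") "adh2d" else "adh3d"
  m <- model[[field]]
  k <- max(type_a, type_b, nrow(m))
  if (nrow(m) < k) {
    m2 <- matrix(0, k, k)
    if (nrow(m) > 0) m2[seq_len(nrow(m)), seq_len(nrow(m))] <- m
    m <- m2
  }
  m[type_a, type_b] <- lambda
  m[type_b, type_a] <- lambda
  model[[field]] <- m
  model$version <- model$version + 1L
  invisible(model)
}

adhesion_lambda <- function(model, type_a, type_b, class = "surface") {
  m <- if (class == "surface") model$adh2d else model$adh3d
  if (nrow(m) < max(type_a, type_b)) return(0)
  m[type_a, type_b]
}

# Flatten the binding model against the current mesh into evaluation terms,
# each term = one actor applied to a concrete set of object ids.
resolve_terms <- function(mesh, model) {
  terms <- list()
  push <- function(actor, ids) {
    if (length(ids) > 0) terms[[length(terms) + 1L]] <<- list(actor = actor, ids = ids)
  }
  sids <- surface_ids(mesh)
  for (tp in seq_along(model$surface_type_actors)) {
    acts <- model$surface_type_actors[[tp]]
    if (length(acts) == 0) next
    ids <- sids[mesh$s_type[sids] == tp]
    for (a in acts) push(a, ids)
  }
  for (sid in seq_along(model$surface_actors)) {
    acts <- model$surface_actors[sid][[1]]
    if (is.null(acts) || !mesh$s_alive[sid]) next
    for (a in acts) push(a, sid)
  }
  bids <- body_ids(mesh)
  for (tp in seq_along(model$body_type_actors)) {
    acts <- model$body_type_actors[[tp]]
    if (length(acts) == 0) next
    ids <- bids[mesh$b_type[bids] == tp]
    for (a in acts) push(a, ids)
  }
  for (bid in seq_along(model$body_actors)) {
    acts <- model$body_actors[bid][[1]]
    if (is.null(acts) || !mesh$b_alive[bid]) next
    for (a in acts) push(a, bid)
  }
  terms
}
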