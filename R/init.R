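#' Initial vesicle: regular polygon
#'
#' Places the ring as a regular `n_beads`-gon centered at the origin with
#' every edge (including the closure edge) exactly `l0`; the circumradius
#' is `l0 / (2 sin(pi / n_beads))`.
#'
#' @param n_beads number of ring beads (>= 3).
#' @param l0 edge length.
#' @return An `n_beads x 2` coordinate matrix.
#' @export
init_vesicle <- function(n_beads, l0) {
  stopifnot(n_beads >= 3)
  r <- l0 / (2 * sin(pi / n_beads))
  phi <- 2 * pi * (seq_len(n_beads) - 1) / n_beads
  cbind(r * cos(phi), r * sin(phi))
}

#' Initial polymer placement
#'
#' Places the linear chain entirely outside the vesicle with all bonds at
#' `l0`, nearest vesicle approach at least `lj_rm`, and no bead pair (on
#' any chain) closer than `0.9 * morse_rmin`.
#'
#' `straight-tangent` mode (the default) lays a straight segment tangent
#' to the vesicle circle at contact distance `lj_rm`, centered on the
#' tangent point, with a per-replica random rotation about the vesicle
#' center; adsorption then nucleates immediately at the contact point.
#' `random-walk` mode grows a self-avoiding walk outward from a random
#' point outside the vesicle, retrying on constraint violations up to a
#' cap.
#'
#' @param n_beads number of polymer beads (>= 2).
#' @param l0 bond length.
#' @param vesicle_xy the already-placed ring coordinates.
#' @param rng an [mc_rng()] stream (source of the rotation / walk).
#' @param mode `"straight-tangent"` or `"random-walk"`.
#' @param params a [model_params()] object (contact distances).
#' @param max_retry retry cap for `random-walk` mode.
#' @return An `n_beads x 2` coordinate matrix.
#' @export
init_polymer <- function(n_beads, l0, vesicle_xy, rng,
                         mode = c("straight-tangent", "random-walk"),
                         params = model_params(), max_retry = 200L) {
  mode <- match.arg(mode)
  stopifnot(n_beads >= 2)
  center <- colMeans(vesicle_xy)
  rad <- max(sqrt(rowSums(sweep(vesicle_xy, 2, center)^2)))
  contact <- params$lj_rm

  if (mode == "straight-tangent") {
    phi <- rng_uniform(rng, 1, 0, 2 * pi)
    u <- c(cos(phi), sin(phi))            # outward normal
    w <- c(-sin(phi), cos(phi))           # tangent direction
    t0 <- (seq_len(n_beads) - (n_beads + 1) / 2) * l0
    xy <- t(center + (rad + contact) * u + outer(w, t0))
    return(xy)
  }

  min_pair <- 0.9 * params$morse_rmin
  for (try in seq_len(max_retry)) {
    phi <- rng_uniform(rng, 1, 0, 2 * pi)
    start <- center + (rad + contact + 0.5) * c(cos(phi), sin(phi))
    dir <- rng_uniform(rng, 1, 0, 2 * pi)
    xy <- matrix(NA_real_, n_beads, 2)
    xy[1, ] <- start
    ok <- TRUE
    for (i in 2:n_beads) {
      placed <- FALSE
      for (att in 1:20) {
        dir_i <- dir + rng_uniform(rng, 1, -0.6, 0.6)
        cand <- xy[i - 1, ] + l0 * c(cos(dir_i), sin(dir_i))
        d_ves <- sqrt(min(rowSums(sweep(vesicle_xy, 2, cand)^2)))
        d_self <- if (i > 2)
          sqrt(min(rowSums(sweep(xy[1:(i - 2), , drop = FALSE], 2, cand)^2)))
          else Inf
        if (d_ves >= contact && d_self >= min_pair) {
          xy[i, ] <- cand; dir <- dir_i; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xy)
  }
  stop("random-walk polymer placement failed after ", max_retry, " retries")
}

#' Default initial conformation
#'
#' Regular-polygon vesicle at the origin plus a polymer placed by
#' [init_polymer()].
#'
#' @param params a [model_params()] object.
#' @param rng an [mc_rng()] stream.
#' @param mode polymer placement mode.
#' @return A [conformation()].
#' @export
init_conformation <- function(params, rng, mode = "straight-tangent") {
  ves <- init_vesicle(params$n_bonds + 1L, params$l0)
  pol <- init_polymer(params$n_bonds + 1L, params$l0, ves, rng,
                      mode = mode, params = params)
  conformation(ves, pol)
}
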