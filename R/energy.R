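#' Full energy of a conformation, broken down by term
#'
#' Computes every term of the two-chain Hamiltonian by direct summation:
#' FENE over every bond of both chains (the vesicle ring has `N + 1` bonds
#' including the closure bond), Morse over all intra-chain non-bonded
#' pairs (the ring closure pair counts as bonded), bending over the
#' polymer's interior vertices only (the vesicle is soft), Lennard-Jones
#' over all vesicle-polymer bead pairs within the cutoff, and (only when
#' the `morse_inter` option is on) the Morse excluded volume between the
#' chains as well.
#'
#' This is a plain vectorized R implementation, deliberately independent
#' of the compiled incremental bookkeeping used by the sampling engine;
#' the two are held together by consistency tests.
#'
#' @param conf a [conformation()].
#' @param params a [model_params()] object.
#' @return An object of class `energy_breakdown`: a list with fields
#'   `fene_vesicle`, `fene_polymer`, `morse_vesicle`, `morse_polymer`,
#'   `bend_polymer`, `lj_inter`, `morse_inter` and their sum `total`. If any bond lies
#'   outside `(l_min, l_max)` the affected FENE term and the total are
#'   `+Inf`.
#' @examples
#' p <- model_params(kappa = 10, eps_vp = 2)
#' cf <- conformation(init_vesicle(61, 0.7),
#'                    init_polymer(61, 0.7, init_vesicle(61, 0.7), mc_rng(1)))
#' total_energy(cf, p)
#' @export
total_energy <- function(conf, params) {
  v <- conf$vesicle_xy
  p <- conf$polymer_xy

  fene_v <- sum(fene_energy(bond_lengths(v, closed = TRUE), params))
  fene_p <- sum(fene_energy(bond_lengths(p, closed = FALSE), params))

  morse_v <- morse_intra(v, params, closed = TRUE)
  morse_p <- morse_intra(p, params, closed = FALSE)

  bend_p <- 0
  np <- nrow(p)
  if (np >= 3 && params$kappa > 0) {
    thetas <- vapply(2:(np - 1), function(i)
      vertex_angle(p[i - 1, ], p[i, ], p[i + 1, ]), 0)
    bend_p <- sum(bending_energy(thetas, params))
  } else if (np >= 3) {
    bend_p <- 0
  }

  dx <- outer(v[, 1], p[, 1], "-")
  dy <- outer(v[, 2], p[, 2], "-")
  r <- sqrt(dx^2 + dy^2)
  lj <- sum(lj_energy(r, params))
  morse_i <- 0
  if (params$morse_inter) {
    rc <- r[r <= params$morse_cutoff]
    if (length(rc)) morse_i <- sum(morse_energy(rc, params))
  }

  out <- list(fene_vesicle = fene_v, fene_polymer = fene_p,
              morse_vesicle = morse_v, morse_polymer = morse_p,
              bend_polymer = bend_p, lj_inter = lj, morse_inter = morse_i,
              total = fene_v + fene_p + morse_v + morse_p + bend_p + lj +
                morse_i)
  class(out) <- "energy_breakdown"
  out
}

# Morse sum over non-bonded same-chain pairs; for a ring the closure pair
# (1, n) is bonded and excluded
morse_intra <- function(xy, params, closed) {
  n <- nrow(xy)
  if (n < 3) return(0)
  d <- as.matrix(stats::dist(xy))
  keep <- upper.tri(d) & abs(row(d) - col(d)) > 1
  if (closed) keep[1, n] <- FALSE
  r <- d[keep]
  r <- r[r <= params$morse_cutoff]
  if (length(r) == 0) return(0)
  sum(morse_energy(r, params))
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy breakdown (kBT):\n")
  for (k in names(x)) cat(sprintf("  %-14s %12.6f\n", k, x[[k]]))
  invisible(x)
}

#' Incremental energy change of a single-bead displacement
#'
#' Returns `U(conf with bead moved) - U(conf)` computed from only the
#' terms that touch the moved bead: its (at most two) bonds, the (at most
#' three) bending vertices involving it, its Morse partners on the same
#' chain and its Lennard-Jones partners on the other chain. Returns
#' `+Inf` when any touched bond would leave `(l_min, l_max)`. This is the
#' O(N)-per-move bookkeeping that makes Metropolis sampling affordable;
#' it uses the same compiled kernel as the engine.
#'
#' @param conf a [conformation()].
#' @param chain `"vesicle"` or `"polymer"`.
#' @param bead 1-based bead index within the chain.
#' @param new_xy numeric length-2, the proposed position.
#' @param params a [model_params()] object.
#' @return Numeric scalar energy difference (possibly `+Inf`).
#' @export
local_energy_delta <- function(conf, chain, bead, new_xy, params) {
  chain <- match.arg(chain, c("vesicle", "polymer"))
  n <- if (chain == "vesicle") nrow(conf$vesicle_xy) else nrow(conf$polymer_xy)
  bead <- as.integer(bead)
  if (is.na(bead) || bead < 1L || bead > n) stop("invalid bead index")
  cpp_local_delta(conf$vesicle_xy, conf$polymer_xy, params,
                  if (chain == "vesicle") 0L else 1L, bead - 1L,
                  new_xy[1], new_xy[2])
}
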