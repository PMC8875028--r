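#' FENE bond potential
#'
#' Finitely extendable nonlinear elastic bond energy
#' `U(l) = -(k r0^2 / 2) log(1 - ((l - l0)/r0)^2)` for bond lengths inside
#' the open interval `(l_min, l_max)`; outside that interval the bond is
#' unphysical and the energy is `+Inf` (the Metropolis reject sentinel).
#' The divergence at both bounds, combined with the Morse excluded volume,
#' prevents chain crossing.
#'
#' @param l bond length(s), strictly positive.
#' @param params a [model_params()] object.
#' @return Energy value(s), same length as `l`.
#' @examples
#' p <- model_params()
#' fene_energy(0.7, p)   # zero at the equilibrium length
#' fene_energy(1.0, p)   # +Inf at the maximum extension
#' @export
fene_energy <- function(l, params = model_params()) {
  if (any(l <= 0)) stop("bond length must be positive")
  out <- rep(Inf, length(l))
  ok <- l > params$l_min & l < params$l_max
  x <- (l[ok] - params$l0) / params$r0
  out[ok] <- -0.5 * params$fene_k * params$r0^2 * log(1 - x^2)
  out
}

#' Morse pair potential (intra-chain excluded volume)
#'
#' `U(r) = eps (exp(-2 alpha (r - rmin)) - 2 exp(-alpha (r - rmin)))`,
#' truncated unshifted at `morse_cutoff`. With the default `alpha = 24`
#' the potential is negligible beyond `r = 1`, which is where it is cut.
#' Applied between all non-bonded bead pairs of the same chain.
#'
#' @param r distance(s), strictly positive.
#' @param params a [model_params()] object.
#' @return Energy value(s).
#' @examples
#' morse_energy(0.8, model_params())   # -eps at the minimum
#' @export
morse_energy <- function(r, params = model_params()) {
  if (any(r <= 0)) stop("distance must be positive")
  e <- exp(-params$morse_alpha * (r - params$morse_rmin))
  out <- params$morse_eps * e * (e - 2)
  out[r > params$morse_cutoff] <- 0
  out
}

#' Bending potential of the semiflexible polymer
#'
#' `U(theta) = kappa (1 + cos theta)` where `theta` is the interior angle
#' at a vertex: a straight chain (`theta = pi`) costs nothing, a full fold
#' (`theta = 0`) costs `2 kappa`. Applied at the polymer's interior
#' vertices only; the vesicle is soft and carries no bending energy.
#'
#' @param theta interior vertex angle(s) in `[0, pi]`.
#' @param params a [model_params()] object (supplies `kappa`).
#' @return Energy value(s).
#' @export
bending_energy <- function(theta, params = model_params()) {
  if (any(theta < -1e-12 | theta > pi + 1e-12))
    stop("theta must lie in [0, pi]")
  params$kappa * (1 + cos(theta))
}

#' Vesicle-polymer Lennard-Jones attraction
#'
#' `U(r) = eps_vp ((rm/r)^12 - 2 (rm/r)^6)`, truncated unshifted at
#' `lj_cutoff`. The minimum value is exactly `-eps_vp` at `r = lj_rm`, so
#' `eps_vp` is literally the adsorption strength; the `r^-12` core also
#' supplies the inter-chain excluded volume.
#'
#' @param r distance(s), strictly positive.
#' @param params a [model_params()] object.
#' @return Energy value(s).
#' @examples
#' p <- model_params(eps_vp = 2)
#' lj_energy(0.8, p)   # -2: well depth equals eps_vp
#' @export
lj_energy <- function(r, params = model_params()) {
  if (any(r <= 0)) stop("distance must be positive")
  u3 <- (params$lj_rm / r)^6
  out <- params$eps_vp * u3 * (u3 - 2)
  out[r > params$lj_cutoff] <- 0
  out
}

#' Interior angle at a chain vertex
#'
#' Returns the angle at `p_mid` between the rays `p_mid -> p_prev` and
#' `p_mid -> p_next`, in `[0, pi]`. A straight chain returns `pi`; the
#' bending energy [bending_energy()] is therefore zero for straight
#' segments.
#'
#' @param p_prev,p_mid,p_next numeric length-2 points.
#' @return Angle in radians.
#' @export
vertex_angle <- function(p_prev, p_mid, p_next) {
  u <- p_prev - p_mid
  v <- p_next - p_mid
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("coincident points have no defined angle")
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}
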