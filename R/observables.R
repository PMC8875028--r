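#' Instantaneous vesicle-polymer adsorption energy
#'
#' Sum of the Lennard-Jones pair energy over all vesicle-polymer bead
#' pairs within the cutoff; identical to the `lj_inter` field of
#' [total_energy()]. Its ensemble average over equilibrated samples is
#' the adsorption energy `<U_VL>`.
#'
#' @param conf a [conformation()].
#' @param params a [model_params()] object.
#' @return Numeric scalar energy.
#' @export
attraction_energy <- function(conf, params) {
  v <- conf$vesicle_xy; p <- conf$polymer_xy
  r <- sqrt(outer(v[, 1], p[, 1], "-")^2 + outer(v[, 2], p[, 2], "-")^2)
  sum(lj_energy(r, params))
}

#' Polymer end-to-end distance
#'
#' Euclidean distance between the first and last beads of the linear
#' chain. Near-maximal (`N l0`) for rod-like conformations, small when
#' the polymer wraps the vesicle.
#'
#' @param x a [conformation()] or a polymer coordinate matrix.
#' @return Numeric scalar length.
#' @export
end_to_end <- function(x) {
  xy <- if (inherits(x, "conformation")) x$polymer_xy else as.matrix(x)
  if (nrow(xy) < 2) stop("need at least two beads")
  sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
}

#' Tangent-tangent correlation of the vesicle ring
#'
#' `C(s) = (1/L) sum_k t_k . t_(k+s mod L)` over the `L = N + 1` bond
#' (tangent) vectors of the closed ring, with periodic indexing. With
#' `normalized = TRUE` (the default) tangents are unit vectors and
#' `C(0) = 1`; with raw bond vectors the exact ring-closure identity
#' `sum_s C(s) = 0` holds for every configuration. The shape of `C(s)`
#' diagnoses the vesicle morphology: a circle gives `cos(2 pi s / L)`,
#' an n-fold folded vesicle shows n troughs.
#'
#' @param vesicle_xy ring coordinate matrix (or a [conformation()]).
#' @param normalized use unit tangent vectors.
#' @return Numeric vector `C(s)` for `s = 0, ..., L - 1`.
#' @export
tangent_correlation <- function(vesicle_xy, normalized = TRUE) {
  xy <- if (inherits(vesicle_xy, "conformation")) vesicle_xy$vesicle_xy
        else as.matrix(vesicle_xy)
  L <- nrow(xy)
  t_vec <- xy[c(2:L, 1), , drop = FALSE] - xy
  if (normalized) {
    len <- sqrt(rowSums(t_vec^2))
    if (any(len == 0)) stop("ring has a zero-length bond")
    t_vec <- t_vec / len
  }
  # C(s) via the Gram matrix of tangents, averaged along circulant diagonals
  g <- tcrossprod(t_vec)
  s_idx <- (col(g) - row(g)) %% L
  as.numeric(tapply(g, s_idx, mean))[seq_len(L)]
}

#' Gyration-tensor shape descriptors
#'
#' Eigen-decomposes the 2D gyration tensor of a point set. The
#' asphericity `A = ((lambda1 - lambda2) / (lambda1 + lambda2))^2` is 0
#' for an isotropic (circular) cloud and 1 for collinear points.
#'
#' @param xy coordinate matrix with at least 3 rows.
#' @return A list: `asphericity`, `eigenvalues` (decreasing), `axes`
#'   (columns are the principal directions).
#' @export
gyration_shape <- function(xy) {
  xy <- if (inherits(xy, "conformation")) xy$vesicle_xy else as.matrix(xy)
  if (nrow(xy) < 3) stop("need at least three points")
  centered <- sweep(xy, 2, colMeans(xy))
  s <- crossprod(centered) / nrow(xy)
  if (sum(diag(s)) == 0) stop("all points coincide")
  e <- eigen(s, symmetric = TRUE)
  lam <- e$values
  list(asphericity = ((lam[1] - lam[2]) / (lam[1] + lam[2]))^2,
       eigenvalues = lam, axes = e$vectors)
}

#' Count the troughs of a ring correlation curve
#'
#' Counts local minima of the periodically extended, moving-average
#' smoothed correlation curve, keeping only minima below zero and
#' enforcing a minimum circular separation of `L / 10` samples (when two
#' candidate minima are closer, the deeper one wins; exact ties go to the
#' leftmost index). The trough count equals the fold number of the
#' vesicle: 1 for a circle, 2 for a double vesicle, 3 for a triple.
#'
#' @param C correlation values `C(s)`, `s = 0, ..., L - 1`, length >= 8.
#' @param window moving-average smoothing window (odd).
#' @param min_sep minimum circular index separation between counted
#'   troughs; defaults to `L / 10`.
#' @return Integer trough count.
#' @export
count_troughs <- function(C, window = 5L, min_sep = NULL) {
  L <- length(C)
  if (L < 8) stop("correlation curve too short")
  if (is.null(min_sep)) min_sep <- L / 10
  half <- (window - 1L) %/% 2L
  ext <- C[((seq_len(L + 2L * half) - 1L - half) %% L) + 1L]
  sm <- stats::filter(ext, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm[(half + 1L):(half + L)])

  prv <- sm[((seq_len(L) - 2L) %% L) + 1L]
  nxt <- sm[(seq_len(L) %% L) + 1L]
  cand <- which(sm < prv & sm <= nxt & sm < 0)   # leftmost of a flat minimum
  if (length(cand) == 0) return(0L)

  ord <- cand[order(sm[cand], cand)]             # deepest first, ties leftmost
  kept <- integer(0)
  for (i in ord) {
    dsep <- pmin(abs(i - kept), L - abs(i - kept))
    if (length(kept) == 0 || all(dsep >= min_sep)) kept <- c(kept, i)
  }
  length(kept)
}

#' Classify the vesicle morphology
#'
#' Heuristic rule-based labelling of the folded vesicle shapes from the
#' ensemble-averaged descriptors. Rules are applied in order:
#'
#' 1. `rod-partial` when the polymer is near-fully extended
#'    (`r_ee > rod_ree_frac * N * l0`) with weak contact
#'    (`|u_vl| < rod_uvl_frac * (N + 1) * eps_vp`): only part of the
#'    vesicle adsorbs onto a rigid rod.
#' 2. By trough count of `C(s)`: 3 or more is `triple`; 2 is `double`
#'    unless the ring is strongly elongated (asphericity above
#'    `asph_elong`), which routes to the cigar family; 1 is `circular`
#'    or, when moderately elongated (above `asph_oval`), `oval`; 0 is
#'    `random`.
#' 3. Within the cigar family, the symmetry of `C` about `s = L/2`
#'    decides: a symmetric curve is a `cigar`; an asymmetric curve with
#'    one trough much deeper than the other is a `racquet`; otherwise
#'    `bent-cigar`.
#'
#' All thresholds are configuration values, and the raw descriptors are
#' reported alongside labels elsewhere so results can be re-thresholded
#' without re-running.
#'
#' @param C ensemble-mean normalized correlation curve.
#' @param asphericity ensemble-mean vesicle asphericity.
#' @param r_ee_polymer ensemble-mean polymer end-to-end distance.
#' @param u_vl ensemble-mean adsorption energy.
#' @param params a [model_params()] object.
#' @param thresholds a [classify_thresholds()] list.
#' @return A single label string.
#' @export
classify_shape <- function(C, asphericity, r_ee_polymer, u_vl, params,
                           thresholds = classify_thresholds()) {
  th <- thresholds
  n <- params$n_bonds
  if (params$eps_vp > 0 &&
      r_ee_polymer > th$rod_ree_frac * n * params$l0 &&
      abs(u_vl) < th$rod_uvl_frac * (n + 1) * params$eps_vp)
    return("rod-partial")

  folds <- count_troughs(C)
  if (folds >= 3) return("triple")
  if (folds == 2) {
    if (asphericity < th$asph_elong) return("double")
    L <- length(C)
    mirrored <- C[c(1L, L:2L)]                    # C(L - s), s = 0..L-1
    asym <- max(abs(C - mirrored))
    sm_min <- troughs_depths(C)
    if (length(sm_min) >= 2) {
      ratio <- min(sm_min) / max(sm_min)          # both negative: deeper/shallower
      if (ratio > th$racquet_depth_ratio) return("racquet")
    }
    if (asym > th$asym_bent) return("bent-cigar")
    return("cigar")
  }
  if (folds == 1) {
    if (asphericity >= th$asph_oval) return("oval")
    return("circular")
  }
  "random"
}

# depths (smoothed values) of the counted troughs; helper for classify_shape
troughs_depths <- function(C, window = 5L) {
  L <- length(C)
  half <- (window - 1L) %/% 2L
  ext <- C[((seq_len(L + 2L * half) - 1L - half) %% L) + 1L]
  sm <- stats::filter(ext, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm[(half + 1L):(half + L)])
  prv <- sm[((seq_len(L) - 2L) %% L) + 1L]
  nxt <- sm[(seq_len(L) %% L) + 1L]
  sm[sm < prv & sm <= nxt & sm < 0]
}

#' Thresholds for [classify_shape()]
#'
#' @param rod_ree_frac fraction of the contour length `N l0` above which
#'   the polymer counts as near-fully extended.
#' @param rod_uvl_frac fraction of the maximal contact energy
#'   `(N + 1) eps_vp` below which adsorption counts as weak.
#' @param asph_elong asphericity above which a two-trough ring is
#'   elongated (cigar family) rather than a double vesicle.
#' @param asph_oval asphericity above which a one-trough ring is oval
#'   rather than circular.
#' @param asym_bent maximum `|C(s) - C(L - s)|` above which a cigar
#'   counts as bent.
#' @param racquet_depth_ratio trough depth ratio (deeper / shallower,
#'   both negative) above which the shape is racquet-like.
#' @return A named list of thresholds.
#' @export
classify_thresholds <- function(rod_ree_frac = 0.8, rod_uvl_frac = 0.25,
                                asph_elong = 0.5, asph_oval = 0.1,
                                asym_bent = 0.2, racquet_depth_ratio = 2) {
  list(rod_ree_frac = rod_ree_frac, rod_uvl_frac = rod_uvl_frac,
       asph_elong = asph_elong, asph_oval = asph_oval,
       asym_bent = asym_bent, racquet_depth_ratio = racquet_depth_ratio)
}

#' Quadrature oracle: mean vertex-angle cosine of a free chain
#'
#' For an isolated chain whose vertices feel only the bending penalty
#' `kappa (1 + cos theta)`, the interior angle of a 2D chain with free
#' hinges has density proportional to `exp(-kappa (1 + cos theta) / kBT)`
#' on `[0, pi]` (the 2D angular measure is flat). This returns
#' `<cos theta>` by adaptive quadrature; it is the independent check for
#' the sampled bending statistics. For large `kappa` it approaches
#' `-1 + kBT / (2 kappa)`.
#'
#' @param kappa bending stiffness.
#' @param kBT thermal energy.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
wlc_angle_oracle <- function(kappa, kBT = 1) {
  stopifnot(kappa >= 0)
  w <- function(th) exp(-kappa * (1 + cos(th)) / kBT)
  num <- stats::integrate(function(th) cos(th) * w(th), 0, pi,
                          rel.tol = 1e-10, abs.tol = 1e-12)$value
  den <- stats::integrate(w, 0, pi, rel.tol = 1e-10, abs.tol = 1e-12)$value
  num / den
}

#' Quadrature oracle: equilibrium FENE bond-length density
#'
#' For a single FENE bond between two beads free in the plane, the bond
#' length has density `p(l) proportional to l exp(-U_FENE(l) / kBT)` on
#' `(l_min, l_max)` (the factor `l` is the 2D radial measure). Returns
#' the normalized density tabulated on a fine grid together with
#' interpolating `pdf` and `cdf` functions; the `cdf` drives the
#' Kolmogorov-Smirnov check of the sampling engine's detailed balance.
#'
#' @param params a [model_params()] object.
#' @param n_grid number of grid points.
#' @return A list: `l` (grid), `density`, `pdf`, `cdf` (vectorized
#'   functions), `norm` (the raw normalization integral).
#' @export
fene_bond_oracle <- function(params, n_grid = 4096L) {
  f <- function(l) l * exp(-fene_energy(l, params) / params$kBT)
  norm <- stats::integrate(f, params$l_min, params$l_max,
                           rel.tol = 1e-12, abs.tol = 1e-300)$value
  l <- seq(params$l_min, params$l_max, length.out = n_grid)
  dens <- f(l) / norm
  cum <- c(0, cumsum((dens[-1] + dens[-n_grid]) / 2 * diff(l)))
  cum <- cum / cum[n_grid]
  pdf_fun <- stats::approxfun(l, dens, yleft = 0, yright = 0)
  cdf_fun <- stats::approxfun(l, cum, yleft = 0, yright = 1)
  list(l = l, density = dens, pdf = pdf_fun, cdf = cdf_fun, norm = norm)
}
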