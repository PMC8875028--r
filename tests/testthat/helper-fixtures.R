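# Shared fixtures: small systems, independently generated configurations,
# and a brute-force energy oracle written with explicit loops and inline
# formulas (no calls into the package's energy code).

small_params <- function(n_bonds = 8L, kappa = 0, eps_vp = 0, ...) {
  model_params(n_bonds = n_bonds, kappa = kappa, eps_vp = eps_vp, ...)
}

# a valid two-chain configuration: polygon vesicle + jittered arc polymer,
# re-jittered until every bond is safely inside (l_min, l_max)
random_valid_conformation <- function(params, seed) {
  set.seed(seed)
  n <- params$n_bonds + 1L
  for (attempt in 1:50) {
    ves <- init_vesicle(n, params$l0)
    ves <- ves + matrix(runif(2 * n, -0.05, 0.05), n, 2)
    rad <- params$l0 / (2 * sin(pi / n))
    rw <- rad + params$lj_rm + runif(1, 0, 0.3)
    dth <- 2 * asin(params$l0 / (2 * rw))
    th <- runif(1, 0, 2 * pi) + dth * seq_len(n)
    pol <- cbind(rw * cos(th), rw * sin(th))
    pol <- pol + matrix(runif(2 * n, -0.05, 0.05), n, 2)
    cf <- conformation(ves, pol)
    if (is_valid_conformation(cf, params)) return(cf)
  }
  stop("could not build a valid random conformation")
}

# direct transcription of the model: double loops, no cutoff shortcuts
# beyond the truncations that define the potentials themselves
brute_force_energy <- function(conf, params) {
  v <- conf$vesicle_xy; p <- conf$polymer_xy
  nv <- nrow(v); np <- nrow(p)
  fene <- function(l) {
    if (l <= params$l_min || l >= params$l_max) return(Inf)
    -0.5 * params$fene_k * params$r0^2 * log(1 - ((l - params$l0) / params$r0)^2)
  }
  morse <- function(r) {
    if (r > params$morse_cutoff) return(0)
    e <- exp(-params$morse_alpha * (r - params$morse_rmin))
    params$morse_eps * e * (e - 2)
  }
  lj <- function(r) {
    if (r > params$lj_cutoff) return(0)
    u <- (params$lj_rm / r)^6
    params$eps_vp * u * (u - 2)
  }
  dst <- function(a, b) sqrt(sum((a - b)^2))

  fene_v <- 0
  for (i in seq_len(nv)) fene_v <- fene_v + fene(dst(v[i, ], v[i %% nv + 1, ]))
  fene_p <- 0
  for (i in seq_len(np - 1)) fene_p <- fene_p + fene(dst(p[i, ], p[i + 1, ]))

  morse_v <- 0
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    if (j <= i) next
    if (j - i == 1 || (i == 1 && j == nv)) next
    morse_v <- morse_v + morse(dst(v[i, ], v[j, ]))
  }
  morse_p <- 0
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (j <= i + 1) next
    morse_p <- morse_p + morse(dst(p[i, ], p[j, ]))
  }

  bend_p <- 0
  if (np >= 3 && params$kappa > 0) {
    for (i in 2:(np - 1)) {
      a <- p[i - 1, ] - p[i, ]; b <- p[i + 1, ] - p[i, ]
      ct <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
      bend_p <- bend_p + params$kappa * (1 + ct)
    }
  }

  lj_i <- 0; morse_i <- 0
  for (i in seq_len(nv)) for (j in seq_len(np)) {
    r <- dst(v[i, ], p[j, ])
    lj_i <- lj_i + lj(r)
    if (params$morse_inter) morse_i <- morse_i + morse(r)
  }

  list(fene_vesicle = fene_v, fene_polymer = fene_p,
       morse_vesicle = morse_v, morse_polymer = morse_p,
       bend_polymer = bend_p, lj_inter = lj_i, morse_inter = morse_i,
       total = fene_v + fene_p + morse_v + morse_p + bend_p + lj_i + morse_i)
}

# apply a single-bead move to a conformation
move_bead <- function(conf, chain, bead, new_xy) {
  if (chain == "vesicle") conf$vesicle_xy[bead, ] <- new_xy
  else conf$polymer_xy[bead, ] <- new_xy
  conf
}
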