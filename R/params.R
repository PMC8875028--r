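#' Model parameters for the vesicle-polymer system
#'
#' Collects every physical constant of the two-chain bead-spring model:
#' FENE bond spring, Morse intra-chain excluded volume, polymer bending
#' stiffness, vesicle-polymer Lennard-Jones attraction, thermal energy and
#' the Metropolis displacement half-width. Lengths are in units of the
#' maximum bond extension `l_max`, energies in units of `kBT`.
#'
#' The defaults are the reference parameter set of the model: chain length
#' `N = 60` (so each chain has `N + 1 = 61` beads), FENE spring constant
#' `k = 20`, equilibrium bond length `l0 = 0.7` on the allowed open interval
#' `(0.4, 1)`, Morse range parameter `alpha = 24` with minimum at
#' `r_min = 0.8` and depth `eps = 1`, thermal energy `kBT = 1`, and trial
#' displacements drawn uniformly from `(-0.25, 0.25)` per coordinate.
#' The bending stiffness `kappa` (polymer only; the vesicle is soft) and
#' the adsorption strength `eps_vp` are the two control parameters of the
#' shape diagram and have no privileged default.
#'
#' The Lennard-Jones well is parameterized by its minimum position `lj_rm`
#' and depth `eps_vp`: `U(r) = eps_vp * ((rm/r)^12 - 2 (rm/r)^6)`, so the
#' depth is exactly `eps_vp` at `r = lj_rm = 0.8`, the same contact
#' distance as the Morse minimum. Both non-bonded potentials are truncated
#' unshifted: Morse at 1.0 (beyond which it is negligible at `alpha = 24`)
#' and LJ at `2.5 * lj_rm = 2`.
#'
#' @param n_bonds polymer bond count `N`; both chains have `N + 1` beads.
#' @param fene_k FENE spring constant (energy / length^2).
#' @param l0 equilibrium bond length.
#' @param l_min,l_max open interval of allowed bond lengths.
#' @param morse_alpha Morse range parameter (1 / length).
#' @param morse_rmin position of the Morse minimum.
#' @param morse_eps Morse well depth.
#' @param morse_cutoff truncation radius of the Morse potential.
#' @param kappa bending stiffness of the polymer (energy); `kappa = 0` is a
#'   fully flexible chain, large `kappa` a rigid rod.
#' @param eps_vp vesicle-polymer attraction strength (LJ well depth).
#' @param lj_rm position of the LJ minimum.
#' @param lj_cutoff truncation radius of the LJ potential.
#' @param morse_inter also apply the Morse excluded-volume potential
#'   between the chains (off by default: the vesicle-polymer interaction
#'   is the Lennard-Jones term alone, whose repulsive core supplies the
#'   inter-chain excluded volume). Provided as a model option because
#'   with identical monomers an excluded volume among all non-bonded
#'   pairs is the natural alternative reading.
#' @param kBT thermal energy (the unit of energy).
#' @param max_disp half-width of the uniform single-bead displacement.
#'
#' @return An object of class `model_params`: a named list with the fields
#'   above plus the derived `r0 = l_max - l0`.
#' @examples
#' p <- model_params(kappa = 10, eps_vp = 2)
#' p$r0
#' @export
model_params <- function(n_bonds = 60L,
                         fene_k = 20,
                         l0 = 0.7,
                         l_min = 0.4,
                         l_max = 1.0,
                         morse_alpha = 24,
                         morse_rmin = 0.8,
                         morse_eps = 1,
                         morse_cutoff = 1.0,
                         kappa = 0,
                         eps_vp = 0,
                         lj_rm = 0.8,
                         lj_cutoff = 2.0,
                         morse_inter = FALSE,
                         kBT = 1,
                         max_disp = 0.25) {
  p <- list(n_bonds = as.integer(n_bonds), fene_k = fene_k, l0 = l0,
            l_min = l_min, l_max = l_max, r0 = l_max - l0,
            morse_alpha = morse_alpha, morse_rmin = morse_rmin,
            morse_eps = morse_eps, morse_cutoff = morse_cutoff,
            kappa = kappa, eps_vp = eps_vp, lj_rm = lj_rm,
            lj_cutoff = lj_cutoff, morse_inter = as.logical(morse_inter),
            kBT = kBT, max_disp = max_disp)
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(
    "n_bonds must be >= 2" = p$n_bonds >= 2,
    "need l_min < l0 < l_max" = p$l_min < p$l0 && p$l0 < p$l_max,
    "r0 must equal l_max - l0" = identical(p$r0, p$l_max - p$l0),
    "fene_k must be positive" = p$fene_k > 0,
    "morse_alpha must be positive" = p$morse_alpha > 0,
    "morse_eps must be non-negative" = p$morse_eps >= 0,
    "eps_vp must be non-negative" = p$eps_vp >= 0,
    "kappa must be non-negative" = p$kappa >= 0,
    "kBT must be positive" = p$kBT > 0,
    "max_disp must be non-negative" = p$max_disp >= 0,
    "morse_cutoff must be >= morse_rmin" = p$morse_cutoff >= p$morse_rmin,
    "lj_cutoff must be >= lj_rm" = p$lj_cutoff >= p$lj_rm,
    "morse_inter must be TRUE or FALSE" =
      is.logical(p$morse_inter) && !is.na(p$morse_inter)
  )
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Vesicle-polymer model parameters (reduced units)\n")
  cat(sprintf("  chains: N = %d bonds, %d beads each\n", x$n_bonds, x$n_bonds + 1L))
  cat(sprintf("  FENE: k = %g, l0 = %g on (%g, %g)\n", x$fene_k, x$l0, x$l_min, x$l_max))
  cat(sprintf("  Morse: alpha = %g, rmin = %g, eps = %g, cutoff = %g\n",
              x$morse_alpha, x$morse_rmin, x$morse_eps, x$morse_cutoff))
  cat(sprintf("  bending: kappa = %g (polymer only)\n", x$kappa))
  cat(sprintf("  LJ: eps_vp = %g, rm = %g, cutoff = %g\n", x$eps_vp, x$lj_rm, x$lj_cutoff))
  cat(sprintf("  inter-chain Morse: %s\n", if (x$morse_inter) "on" else "off"))
  cat(sprintf("  kBT = %g, max_disp = %g\n", x$kBT, x$max_disp))
  invisible(x)
}

# fields allowed in a flat key-value parameter file (r0 is derived but
# accepted for round-trip fidelity; it must agree with l_max - l0)
.param_keys <- c("n_bonds", "fene_k", "l0", "l_min", "l_max", "r0",
                 "morse_alpha", "morse_rmin", "morse_eps", "morse_cutoff",
                 "kappa", "eps_vp", "lj_rm", "lj_cutoff", "morse_inter",
                 "kBT", "max_disp")

#' Read model parameters from a flat key-value file
#'
#' The file format is one `key = value` pair per line; `#` starts a
#' comment. Keys must be valid `model_params` field names; an unknown key
#' is an error. Missing keys take their defaults.
#'
#' @param path file to read.
#' @return A `model_params` object.
#' @seealso [write_params()]
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(model_params())
  parts <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", lines))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(parts, `[`, "", 2L)
  vals <- as.numeric(vapply(parts, `[`, "", 3L))
  unknown <- setdiff(keys, .param_keys)
  if (length(unknown)) stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicate parameter key(s) in config")
  args <- as.list(vals)
  names(args) <- keys
  r0_given <- args$r0
  args$r0 <- NULL
  p <- do.call(model_params, args)
  if (!is.null(r0_given) && abs(r0_given - p$r0) > 1e-12)
    stop("config r0 inconsistent with l_max - l0")
  p
}

#' Write model parameters to a flat key-value file
#'
#' @param params a `model_params` object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @seealso [read_params()]
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  lines <- vapply(.param_keys, function(k)
    sprintf("%s = %.17g", k, as.numeric(params[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' Monte Carlo schedule
#'
#' Defines the length and measurement layout of a run: total Monte Carlo
#' steps (MCS; one MCS is one attempted displacement per bead, i.e.
#' `2(N+1)` trials), the equilibration span that is discarded, the
#' measurement interval, the number of measurements, the replica count and
#' the base seed from which per-replica streams are derived.
#'
#' The reference protocol is `3e8` total MCS with 100 measurements every
#' `1e6` MCS and 100 replicas, i.e. `2e8` MCS of equilibration followed by
#' a `1e8`-MCS measurement window (a 2:1 equilibration:measurement split).
#' [scale_schedule()] shrinks that protocol while preserving the split.
#'
#' @param total_mcs total MCS per replica.
#' @param equil_mcs MCS discarded before the first measurement.
#' @param measure_every interval between measurements, in MCS.
#' @param n_measurements number of measurements per replica.
#' @param n_runs number of independent replicas.
#' @param base_seed integer seed; replica `i` uses the derived stream
#'   [derive_seed()]`(base_seed, i)`.
#' @return An object of class `mc_schedule`.
#' @examples
#' schedule()                      # the reference protocol
#' scale_schedule(factor = 1e-3)   # same layout, 1000x shorter
#' @export
schedule <- function(total_mcs = 3e8,
                     equil_mcs = 2e8,
                     measure_every = 1e6,
                     n_measurements = 100L,
                     n_runs = 100L,
                     base_seed = 1L) {
  s <- list(total_mcs = total_mcs, equil_mcs = equil_mcs,
            measure_every = measure_every,
            n_measurements = as.integer(n_measurements),
            n_runs = as.integer(n_runs),
            base_seed = as.integer(base_seed))
  stopifnot(
    "schedule spans must be positive" =
      total_mcs > 0 && measure_every > 0 && s$n_measurements > 0,
    "equil_mcs must be non-negative" = equil_mcs >= 0,
    "n_runs must be >= 1" = s$n_runs >= 1,
    "measurements must fit inside total_mcs" =
      equil_mcs + s$n_measurements * measure_every <= total_mcs
  )
  class(s) <- "mc_schedule"
  s
}

#' Scale the reference schedule down
#'
#' Shrinks the reference protocol by `factor` while preserving its 2:1
#' equilibration:measurement split and the number of measurements.
#'
#' @param factor multiplier applied to the MCS spans (0 < factor <= 1).
#' @param n_measurements measurements per replica.
#' @param n_runs replica count.
#' @param base_seed base seed.
#' @return An `mc_schedule`.
#' @export
scale_schedule <- function(factor, n_measurements = 100L, n_runs = 10L,
                           base_seed = 1L) {
  stopifnot(factor > 0, factor <= 1)
  total <- ceiling(3e8 * factor)
  equil <- ceiling(2e8 * factor)
  every <- max(1, floor((total - equil) / n_measurements))
  schedule(total_mcs = equil + every * n_measurements, equil_mcs = equil,
           measure_every = every, n_measurements = n_measurements,
           n_runs = n_runs, base_seed = base_seed)
}

#' @export
print.mc_schedule <- function(x, ...) {
  cat(sprintf(
    "MC schedule: %g total MCS (%g equilibration), %d measurements every %g MCS, %d replicas, base seed %d\n",
    x$total_mcs, x$equil_mcs, x$n_measurements, x$measure_every, x$n_runs,
    x$base_seed))
  invisible(x)
}

#' Derive a replica seed from a base seed
#'
#' Runs the pair (base seed, replica index) through a splitmix64 mixing
#' function and reduces the result modulo 2^31, so that replicas get
#' well-separated deterministic streams.
#'
#' @param base_seed integer base seed.
#' @param index replica index (1-based).
#' @return A numeric scalar in `[0, 2^31)`.
#' @export
derive_seed <- function(base_seed, index) {
  cpp_derive_seed(as.numeric(base_seed), as.numeric(index))
}
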