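#' Deterministic random stream
#'
#' Creates a self-contained xoshiro256++ random stream, independent of
#' R's global RNG. Runs and replicas driven by these streams are
#' bit-reproducible given their seed, and the stream state can be
#' serialized into checkpoints via [rng_state()].
#'
#' @param seed non-negative integer seed, or `NULL` when restoring.
#' @param state an 8-word state vector from [rng_state()], overriding
#'   `seed`.
#' @return An object of class `mc_rng` (external pointer).
#' @export
mc_rng <- function(seed = 1L, state = NULL) {
  ptr <- if (!is.null(state)) cpp_rng_restore(as.numeric(state))
         else cpp_rng_new(as.numeric(seed))
  class(ptr) <- "mc_rng"
  ptr
}

#' @rdname mc_rng
#' @param rng an `mc_rng` stream.
#' @export
rng_state <- function(rng) cpp_rng_state(rng)

#' @rdname mc_rng
#' @param n number of variates.
#' @param lo,hi interval bounds.
#' @export
rng_uniform <- function(rng, n = 1L, lo = 0, hi = 1) {
  cpp_runif(rng, as.integer(n), lo, hi)
}

#' Draw a trial move
#'
#' Chooses a bead uniformly among all beads of both chains and draws a
#' displacement `(dx, dy)` uniform on `(-max_disp, max_disp)^2`. The
#' proposal is symmetric, so the plain Metropolis ratio applies.
#'
#' @param conf a [conformation()].
#' @param params a [model_params()] object.
#' @param rng an [mc_rng()] stream.
#' @return A list with `chain` (`"vesicle"`/`"polymer"`), 1-based `bead`,
#'   and displacements `dx`, `dy`.
#' @export
draw_move <- function(conf, params, rng) {
  m <- cpp_draw_move(rng, nrow(conf$vesicle_xy),
                     nrow(conf$polymer_xy), params$max_disp)
  list(chain = if (m[1] == 0) "vesicle" else "polymer",
       bead = as.integer(m[2]) + 1L, dx = m[3], dy = m[4])
}

#' Metropolis acceptance rule
#'
#' Accepts a move with probability `min(exp(-delta_u / kBT), 1)`:
#' downhill moves (`delta_u <= 0`) always accept, an infinite energy
#' difference (broken bond sentinel) always rejects.
#'
#' @param delta_u energy difference of the trial move (may be `+Inf`).
#' @param rng an [mc_rng()] stream.
#' @param kBT thermal energy.
#' @return Logical scalar.
#' @export
metropolis_accept <- function(delta_u, rng, kBT = 1) {
  cpp_metropolis(rng, delta_u, kBT)
}

#' Advance the system by whole Monte Carlo steps
#'
#' One Monte Carlo step (MCS) is `2(N + 1)` attempted single-bead
#' displacements (one per bead on average); rejected trials still count.
#' Runs entirely in compiled code.
#'
#' @param conf a [conformation()].
#' @param params a [model_params()] object.
#' @param rng an [mc_rng()] stream (advanced in place).
#' @param n_mcs number of MCS to perform.
#' @return A list: updated `conformation`, `accepted` and `trials`
#'   counts, and `delta_sum`, the sum of accepted energy differences
#'   (useful for verifying running-energy bookkeeping).
#' @export
run_mcs <- function(conf, params, rng, n_mcs = 1) {
  out <- cpp_run_mcs(conf$vesicle_xy, conf$polymer_xy, params,
                     rng, n_mcs)
  list(conformation = conformation(out$vesicle_xy, out$polymer_xy),
       accepted = out$accepted, trials = out$trials,
       delta_sum = out$delta_sum)
}

#' Run one replica: equilibrate, then measure on a schedule
#'
#' Performs `equil_mcs` MCS without measuring, then records one
#' measurement every `measure_every` MCS until `n_measurements` samples
#' are collected. Each measurement records the instantaneous
#' vesicle-polymer LJ energy `u_vl`, the polymer end-to-end distance
#' `r_ee`, the vesicle gyration asphericity, the mean cosine of the
#' polymer's interior vertex angles, and (optionally per sample) the
#' normalized ring tangent-tangent correlation. The run is fully
#' deterministic given `(seed, schedule, params, initial)`.
#'
#' A running total energy is maintained from accepted move deltas and
#' resynchronized against a full recompute every `resync_every` MCS; the
#' largest correction observed is reported as `max_energy_drift`.
#'
#' @param initial a valid [conformation()].
#' @param params a [model_params()] object.
#' @param sched an [schedule()] object (its `n_runs` is ignored here).
#' @param seed stream seed for this run (default: the schedule's
#'   `base_seed`).
#' @param store_corr keep the per-measurement correlation matrix
#'   (`n_measurements x (N+1)`) in the result; the mean curve is always
#'   kept.
#' @param normalized_corr use unit tangent vectors in the correlation.
#' @param resync_every MCS between running-energy resynchronizations.
#' @return An object of class `run_result`: `seed`, `records` (data frame
#'   with columns `mcs`, `u_vl`, `r_ee`, `asphericity`, `mean_cos`,
#'   `shape_label`), `tt_corr` (matrix or `NULL`), `tt_corr_mean`,
#'   `final_conformation`, `acceptance_rate`, `max_energy_drift`.
#' @export
run_mc <- function(initial, params, sched, seed = sched$base_seed,
                   store_corr = TRUE, normalized_corr = TRUE,
                   resync_every = 1e4) {
  stopifnot(inherits(initial, "conformation"),
            inherits(params, "model_params"),
            inherits(sched, "mc_schedule"))
  if (!is_valid_conformation(initial, params))
    stop("initial conformation has a bond outside (l_min, l_max)")
  rng <- mc_rng(seed)
  out <- cpp_run(initial$vesicle_xy, initial$polymer_xy, params,
                 rng, sched$equil_mcs, sched$measure_every,
                 sched$n_measurements, store_corr, normalized_corr,
                 resync_every)
  rec <- as.data.frame(out$records)
  if (store_corr) {
    rec$shape_label <- vapply(seq_len(nrow(rec)), function(i)
      classify_shape(out$tt_corr[i, ], rec$asphericity[i], rec$r_ee[i],
                     rec$u_vl[i], params), "")
  } else {
    rec$shape_label <- NA_character_
  }
  structure(list(
    seed = seed,
    records = rec,
    tt_corr = out$tt_corr,
    tt_corr_mean = out$tt_corr_mean,
    final_conformation = conformation(out$vesicle_xy, out$polymer_xy),
    acceptance_rate = out$accepted / out$trials,
    max_energy_drift = out$max_energy_drift), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "MC run (seed %s): %d measurements, acceptance %.3f, <u_vl> = %.3f, <r_ee> = %.3f\n",
    format(x$seed), nrow(x$records), x$acceptance_rate,
    mean(x$records$u_vl), mean(x$records$r_ee)))
  invisible(x)
}

#' Run independent replicas and pool their measurements
#'
#' Launches `n_runs` independent runs with distinct derived seeds
#' ([derive_seed()]) and distinct initial conformations (the polymer
#' placement is randomized per replica), then aggregates: pooled means of
#' each observable with standard errors computed over replica means, and
#' the replica-averaged tangent-tangent correlation curve with per-lag
#' standard errors.
#'
#' @param params a [model_params()] object.
#' @param sched an [schedule()] object; `n_runs` and `base_seed` are
#'   taken from it.
#' @param init_fn optional function `(replica_index, rng) -> conformation`
#'   supplying initial states; the default places the regular-polygon
#'   vesicle at the origin and a straight polymer tangent to it at a
#'   per-replica random rotation.
#' @param init_mode polymer initialization mode for the default
#'   `init_fn`; see [init_polymer()].
#' @param store_corr keep per-measurement correlation matrices per run.
#' @param progress print one line per completed replica.
#' @return An object of class `replica_result`: `records` (pooled data
#'   frame with `run`, `seed` prepended), `summary` (one-row data frame
#'   of means and standard errors), `tt_corr` (data frame `s`, `C_mean`,
#'   `C_stderr`), `runs` (per-replica summaries), `params`, `schedule`.
#' @export
run_replicas <- function(params, sched, init_fn = NULL,
                         init_mode = "straight-tangent",
                         store_corr = FALSE, progress = FALSE) {
  n_runs <- sched$n_runs
  if (is.null(init_fn)) {
    init_fn <- function(i, rng) {
      ves <- init_vesicle(params$n_bonds + 1L, params$l0)
      pol <- init_polymer(params$n_bonds + 1L, params$l0, ves, rng,
                          mode = init_mode, params = params)
      conformation(ves, pol)
    }
  }
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    seed_i <- derive_seed(sched$base_seed, i)
    init_rng <- mc_rng(derive_seed(seed_i, 0))
    conf0 <- init_fn(i, init_rng)
    runs[[i]] <- run_mc(conf0, params, sched, seed = seed_i,
                        store_corr = store_corr)
    if (progress)
      message(sprintf("replica %d/%d: <u_vl> = %.3f, <r_ee> = %.3f",
                      i, n_runs, mean(runs[[i]]$records$u_vl),
                      mean(runs[[i]]$records$r_ee)))
  }

  rec <- do.call(rbind, lapply(seq_len(n_runs), function(i)
    cbind(run = i, seed = runs[[i]]$seed, runs[[i]]$records)))

  rep_mean <- function(field) vapply(runs, function(r) mean(r$records[[field]]), 0)
  se <- function(m) if (n_runs > 1) stats::sd(m) / sqrt(n_runs) else NA_real_
  u <- rep_mean("u_vl"); re <- rep_mean("r_ee"); asph <- rep_mean("asphericity")
  cosm <- rep_mean("mean_cos")

  corr_mat <- do.call(rbind, lapply(runs, function(r) r$tt_corr_mean))
  c_mean <- colMeans(corr_mat)
  c_se <- if (n_runs > 1) apply(corr_mat, 2, stats::sd) / sqrt(n_runs)
          else rep(NA_real_, ncol(corr_mat))

  summary <- data.frame(
    n_runs = n_runs, n_samples = nrow(rec),
    u_vl_mean = mean(u), u_vl_se = se(u),
    r_ee_mean = mean(re), r_ee_se = se(re),
    asphericity_mean = mean(asph), asphericity_se = se(asph),
    mean_cos_mean = mean(cosm), mean_cos_se = se(cosm),
    acceptance_rate = mean(vapply(runs, function(r) r$acceptance_rate, 0)))
  summary$trough_count <- count_troughs(c_mean)
  summary$shape_label <- classify_shape(c_mean, summary$asphericity_mean,
                                        summary$r_ee_mean, summary$u_vl_mean,
                                        params)

  structure(list(
    records = rec, summary = summary,
    tt_corr = data.frame(s = seq_along(c_mean) - 1L, C_mean = c_mean,
                         C_stderr = c_se),
    runs = runs, params = params, schedule = sched),
    class = "replica_result")
}

#' @export
print.replica_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("Replica ensemble: %d runs x %d samples\n",
           "  <u_vl> = %.3f (se %.3f)   <r_ee> = %.3f (se %.3f)\n",
           "  asphericity = %.3f, troughs = %d, shape = %s\n"),
    s$n_runs, s$n_samples / s$n_runs, s$u_vl_mean, s$u_vl_se,
    s$r_ee_mean, s$r_ee_se, s$asphericity_mean, s$trough_count,
    s$shape_label))
  invisible(x)
}
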