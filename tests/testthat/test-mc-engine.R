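# Metropolis dynamics, move generation, determinism and bookkeeping.

test_that("draw_move picks beads uniformly with bounded displacements", {
  p <- small_params()                 # 9 + 9 beads
  cf <- random_valid_conformation(p, seed = 1)
  rng <- mc_rng(123)
  n <- 5e4
  nb <- nrow(cf$vesicle_xy) + nrow(cf$polymer_xy)
  idx <- integer(n); dx <- numeric(n)
  for (i in seq_len(n)) {
    m <- draw_move(cf, p, rng)
    idx[i] <- m$bead + if (m$chain == "polymer") nrow(cf$vesicle_xy) else 0L
    dx[i] <- m$dx
  }
  counts <- tabulate(idx, nbins = nb)
  sd_bin <- sqrt(n * (1 / nb) * (1 - 1 / nb))
  expect_true(all(abs(counts - n / nb) < 4 * sd_bin))
  expect_true(all(abs(dx) < p$max_disp))
  # uniform displacement: mean 0 within 4 sigma, sd ~ max_disp/sqrt(3)
  expect_lt(abs(mean(dx)), 4 * p$max_disp / sqrt(3 * n))
  expect_equal(sd(dx), p$max_disp / sqrt(3), tolerance = 0.05)
})

test_that("Metropolis rule: downhill always, +Inf never, uphill at exp(-dU)", {
  rng <- mc_rng(7)
  expect_true(all(vapply(1:200, function(i) metropolis_accept(-3, rng), NA)))
  expect_false(any(vapply(1:200, function(i) metropolis_accept(Inf, rng), NA)))
  n <- 1e5
  acc <- vapply(seq_len(n), function(i) metropolis_accept(2, rng, kBT = 1), NA)
  prob <- exp(-2)
  expect_lt(abs(mean(acc) - prob), 4 * sqrt(prob * (1 - prob) / n))
})

test_that("one MCS is 2(N+1) trials; zero displacement always accepts", {
  p <- small_params(kappa = 4, eps_vp = 1)
  cf <- random_valid_conformation(p, seed = 2)
  out <- run_mcs(cf, p, mc_rng(5), n_mcs = 10)
  ntot <- nrow(cf$vesicle_xy) + nrow(cf$polymer_xy)
  expect_equal(out$trials, 10 * ntot)
  expect_true(out$accepted >= 0 && out$accepted <= out$trials)

  p0 <- small_params(max_disp = 0)
  out0 <- run_mcs(cf, p0, mc_rng(5), n_mcs = 5)
  expect_equal(out0$accepted, out0$trials)      # identity moves, dU = 0
  expect_equal(out0$conformation$vesicle_xy, cf$vesicle_xy)
})

test_that("running energy from accepted deltas tracks a full recompute", {
  p <- model_params(kappa = 10, eps_vp = 2)
  cf <- init_conformation(p, mc_rng(9))
  e0 <- total_energy(cf, p)$total
  out <- run_mcs(cf, p, mc_rng(17), n_mcs = 1000)
  e1 <- total_energy(out$conformation, p)$total
  expect_lt(abs(e0 + out$delta_sum - e1), 1e-6)
})

test_that("the engine matches a step-by-step replay through the public API", {
  # same seed drives cpp_run_mcs and the draw/delta/accept primitives; the
  # optimized kernel (caches + neighbour lists) must reproduce the naive
  # path move for move
  p <- model_params(n_bonds = 20L, kappa = 30, eps_vp = 3)
  cf <- init_conformation(p, mc_rng(21))
  eng <- run_mcs(cf, p, mc_rng(77), n_mcs = 8)
  cur <- cf
  rng <- mc_rng(77)
  for (s in seq_len(8 * 2 * (p$n_bonds + 1))) {
    mv <- draw_move(cur, p, rng)
    xy <- if (mv$chain == "vesicle") cur$vesicle_xy[mv$bead, ]
          else cur$polymer_xy[mv$bead, ]
    nw <- xy + c(mv$dx, mv$dy)
    d <- local_energy_delta(cur, mv$chain, mv$bead, nw, p)
    if (metropolis_accept(d, rng, p$kBT)) cur <- move_bead(cur, mv$chain, mv$bead, nw)
  }
  expect_identical(cur$vesicle_xy, eng$conformation$vesicle_xy)
  expect_identical(cur$polymer_xy, eng$conformation$polymer_xy)
})

test_that("runs are bit-reproducible by seed and differ across seeds", {
  p <- model_params(n_bonds = 20L, kappa = 10, eps_vp = 2)
  sched <- schedule(total_mcs = 600, equil_mcs = 400, measure_every = 10,
                    n_measurements = 20, n_runs = 1, base_seed = 42)
  cf <- init_conformation(p, mc_rng(1))
  r1 <- run_mc(cf, p, sched)
  r2 <- run_mc(cf, p, sched)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$final_conformation, r2$final_conformation)
  r3 <- run_mc(cf, p, sched, seed = 43)
  expect_false(identical(r1$records$u_vl, r3$records$u_vl))
})

test_that("measurement schedule is honoured", {
  p <- model_params(n_bonds = 10L, kappa = 5, eps_vp = 1)
  sched <- schedule(total_mcs = 450, equil_mcs = 200, measure_every = 25,
                    n_measurements = 10, n_runs = 1, base_seed = 1)
  r <- run_mc(init_conformation(p, mc_rng(2)), p, sched)
  expect_equal(nrow(r$records), 10)
  expect_equal(r$records$mcs, seq(225, 450, by = 25))
  expect_true(all(c("u_vl", "r_ee", "asphericity", "shape_label")
                  %in% names(r$records)))
})

test_that("the vesicle ring never opens during sampling", {
  p <- model_params(n_bonds = 20L, kappa = 10, eps_vp = 8)
  cf <- init_conformation(p, mc_rng(4))
  out <- run_mcs(cf, p, mc_rng(8), n_mcs = 2000)
  expect_true(is_valid_conformation(out$conformation, p))
  expect_equal(nrow(out$conformation$vesicle_xy), 21)
})

test_that("schedule invariants are enforced and scaling preserves the split", {
  expect_error(schedule(total_mcs = 100, equil_mcs = 90, measure_every = 10,
                        n_measurements = 5), "fit inside")
  expect_error(schedule(n_runs = 0), "n_runs")
  s <- scale_schedule(1e-4, n_runs = 7)
  expect_equal(s$equil_mcs / (s$total_mcs - s$equil_mcs), 2, tolerance = 0.01)
  expect_equal(s$n_runs, 7L)
  expect_true(s$equil_mcs + s$n_measurements * s$measure_every <= s$total_mcs)
})

test_that("replica seeds are distinct and derived deterministically", {
  seeds <- vapply(1:100, function(i) derive_seed(1, i), 0)
  expect_equal(length(unique(seeds)), 100)
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_identical(seeds, vapply(1:100, function(i) derive_seed(1, i), 0))
  expect_false(derive_seed(1, 1) == derive_seed(2, 1))
})

test_that("replica pooling has the right shape and degenerate limit", {
  p <- model_params(n_bonds = 10L, kappa = 5, eps_vp = 0)
  sched <- schedule(total_mcs = 150, equil_mcs = 100, measure_every = 10,
                    n_measurements = 5, n_runs = 3, base_seed = 9)
  r <- run_replicas(p, sched)
  expect_equal(nrow(r$records), 3 * 5)
  expect_equal(length(unique(r$records$seed)), 3)
  # eps_vp = 0: no interaction, u_vl identically zero with zero spread
  expect_equal(r$summary$u_vl_mean, 0)
  expect_equal(r$summary$u_vl_se, 0)
  expect_equal(nrow(r$tt_corr), 11)
  expect_equal(r$tt_corr$C_mean[1], 1, tolerance = 1e-12)
})

test_that("replica standard errors shrink roughly as 1/sqrt(n_runs)", {
  p <- model_params(n_bonds = 16L, kappa = 0, eps_vp = 0)
  se_at <- function(nr, seed) {
    sched <- schedule(total_mcs = 1500, equil_mcs = 1000, measure_every = 25,
                      n_measurements = 20, n_runs = nr, base_seed = seed)
    run_replicas(p, sched)$summary$r_ee_se
  }
  # average the SE estimates over a few base seeds to tame their own noise
  r4 <- mean(vapply(1:4, function(s) se_at(4L, s), 0))
  r16 <- mean(vapply(1:4, function(s) se_at(16L, s), 0))
  expect_gt(r4 / r16, 1.25)     # ideal ratio 2
  expect_lt(r4 / r16, 3.2)
})

test_that("acceptance rate falls with adsorption strength when adsorbed", {
  rate_at <- function(eps) {
    p <- model_params(kappa = 10, eps_vp = eps)
    cf <- init_conformation(p, mc_rng(31))
    warm <- run_mcs(cf, p, mc_rng(32), 15000)      # reach the adsorbed state
    out <- run_mcs(warm$conformation, p, mc_rng(33), 5000)
    out$accepted / out$trials
  }
  r <- vapply(c(2, 8), rate_at, 0)
  expect_true(all(r > 0))
  expect_lt(r[2], r[1])
})
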