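# System construction, file formats, sweep driver and CLI.

test_that("regular-polygon vesicle has exact edges and circumradius", {
  xy <- init_vesicle(61, 0.7)
  expect_equal(max(sqrt(rowSums(xy^2))), 0.7 / (2 * sin(pi / 61)),
               tolerance = 1e-12)
  expect_equal(0.7 / (2 * sin(pi / 61)), 6.798, tolerance = 1e-3)
  b <- bond_lengths(xy, closed = TRUE)
  expect_equal(length(b), 61)
  expect_true(all(abs(b - 0.7) < 1e-12))
})

test_that("straight-tangent polymer placement honours its constraints", {
  p <- model_params()
  ves <- init_vesicle(61, 0.7)
  pol <- init_polymer(61, 0.7, ves, mc_rng(3), mode = "straight-tangent",
                      params = p)
  expect_equal(end_to_end(pol), 42, tolerance = 1e-9)
  expect_true(all(abs(bond_lengths(pol) - 0.7) < 1e-12))
  cross <- as.matrix(dist(rbind(ves, pol)))[1:61, 62:122]
  expect_gte(min(cross), p$lj_rm - 1e-9)
  pol2 <- init_polymer(61, 0.7, ves, mc_rng(4), mode = "straight-tangent",
                       params = p)
  expect_false(isTRUE(all.equal(pol, pol2)))   # per-seed rotation differs
})

test_that("random-walk polymer placement is self-avoiding and outside", {
  p <- model_params()
  ves <- init_vesicle(31, 0.7)
  pol <- init_polymer(31, 0.7, ves, mc_rng(11), mode = "random-walk",
                      params = p)
  expect_true(all(abs(bond_lengths(pol) - 0.7) < 1e-12))
  d_self <- as.matrix(dist(pol))
  nonadj <- abs(row(d_self) - col(d_self)) > 1
  expect_gte(min(d_self[nonadj]), 0.9 * p$morse_rmin - 1e-9)
  cross <- as.matrix(dist(rbind(ves, pol)))[1:31, 32:62]
  expect_gte(min(cross), p$lj_rm - 1e-9)
})

test_that("XYZ frames round-trip with vesicle lines first", {
  p <- model_params(n_bonds = 10L)
  cf <- init_conformation(p, mc_rng(6))
  path <- tempfile(fileext = ".xyz")
  write_trajectory_frame(cf, 1000, path)
  write_trajectory_frame(cf, 2000, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2 * (22 + 2))
  expect_equal(lines[1], "22")
  expect_equal(lines[2], "mcs=1000")
  tags <- substr(lines[3:24], 1, 1)
  expect_equal(tags, c(rep("V", 11), rep("P", 11)))
  frames <- read_trajectory(path)
  expect_equal(length(frames), 2)
  expect_equal(frames[[2]]$mcs, 2000)
  expect_equal(frames[[1]]$conformation$vesicle_xy, cf$vesicle_xy,
               tolerance = 1e-9)
  expect_equal(frames[[1]]$conformation$polymer_xy, cf$polymer_xy,
               tolerance = 1e-9)
})

test_that("checkpoints resume bit-exactly", {
  p <- model_params(n_bonds = 12L, kappa = 20, eps_vp = 4)
  cf <- init_conformation(p, mc_rng(13))

  # uninterrupted reference: 30 MCS in one go
  rng_a <- mc_rng(99)
  ref <- run_mcs(cf, p, rng_a, 30)

  # interrupted: 15 MCS, checkpoint to disk, restore, 15 more
  rng_b <- mc_rng(99)
  half <- run_mcs(cf, p, rng_b, 15)
  path <- tempfile(fileext = ".chk")
  write_checkpoint(half$conformation, p, rng_b, path)
  st <- read_checkpoint(path)
  expect_identical(st$conformation$vesicle_xy, half$conformation$vesicle_xy)
  expect_identical(st$conformation$polymer_xy, half$conformation$polymer_xy)
  for (f in names(p)) expect_identical(st$params[[f]], p[[f]])
  resumed <- run_mcs(st$conformation, st$params, st$rng, 15)
  expect_identical(resumed$conformation$vesicle_xy, ref$conformation$vesicle_xy)
  expect_identical(resumed$conformation$polymer_xy, ref$conformation$polymer_xy)
})

test_that("sweep writes one directory per state point plus a summary", {
  p <- model_params(n_bonds = 8L)
  sched <- schedule(total_mcs = 150, equil_mcs = 100, measure_every = 10,
                    n_measurements = 5, n_runs = 2, base_seed = 3)
  out <- tempfile("sweep")
  plan <- sweep_plan(kappa_grid = c(0, 5), eps_grid = c(0, 1),
                     sched = sched, output_dir = out)
  summary <- run_sweep(plan, params_base = p)
  expect_equal(nrow(summary), 4)
  expect_true(all(summary$completed))
  expect_true(all(summary$u_vl_mean[summary$eps_vp == 0] == 0))
  d <- file.path(out, "k5_e1")
  expect_true(dir.exists(d))
  for (f in c("measurements.tsv", "correlation.tsv", "params.cfg",
              "manifest.json"))
    expect_true(file.exists(file.path(d, f)), info = f)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_true(man$completed)
  expect_equal(man$kappa, 5)

  # refuses to clobber, reruns byte-identically when forced
  expect_error(run_sweep(plan, params_base = p), "exists")
  s1 <- readLines(file.path(out, "summary.tsv"))
  run_sweep(plan, params_base = p, overwrite = TRUE)
  expect_identical(readLines(file.path(out, "summary.tsv")), s1)
})

test_that("the CLI runs, errors usefully, and is deterministic", {
  out1 <- tempfile("cli")
  args <- c("run", "--kappa", "5", "--eps-vp", "1", "--n-bonds", "8",
            "--total-mcs", "150", "--equil-mcs", "100",
            "--measure-every", "10", "--n-measurements", "5",
            "--runs", "2", "--seed", "7", "--out", out1,
            "--log-level", "quiet")
  expect_equal(run_cli(args), 0L)
  for (f in c("measurements.tsv", "correlation.tsv", "summary.tsv",
              "params.cfg", "manifest.json"))
    expect_true(file.exists(file.path(out1, f)), info = f)

  out2 <- tempfile("cli")
  args2 <- args; args2[which(args2 == out1)] <- out2
  expect_equal(run_cli(args2), 0L)
  expect_identical(readLines(file.path(out2, "measurements.tsv")),
                   readLines(file.path(out1, "measurements.tsv")))

  expect_equal(suppressMessages(run_cli(c("run", "--eps-vp", "2"))), 1L)
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(run_cli(character(0))), 1L)
  expect_equal(suppressMessages(run_cli(c("run", "--bogus", "1"))), 1L)

  # config file feeds the CLI; flags override it
  cfg <- tempfile(fileext = ".cfg")
  write_params(model_params(n_bonds = 8L, kappa = 3, eps_vp = 1), cfg)
  out3 <- tempfile("cli")
  expect_equal(run_cli(c("run", "--config", cfg, "--eps-vp", "0",
                         "--total-mcs", "150", "--equil-mcs", "100",
                         "--measure-every", "10", "--n-measurements", "5",
                         "--runs", "1", "--seed", "1", "--out", out3,
                         "--log-level", "quiet")), 0L)
  resolved <- read_params(file.path(out3, "params.cfg"))
  expect_equal(resolved$kappa, 3)      # from config
  expect_equal(resolved$eps_vp, 0)     # overridden by flag
})

test_that("plot subcommand renders a correlation curve from a run dir", {
  out <- tempfile("cli")
  expect_equal(run_cli(c("run", "--kappa", "5", "--eps-vp", "1",
                         "--n-bonds", "8", "--total-mcs", "150",
                         "--equil-mcs", "100", "--measure-every", "10",
                         "--n-measurements", "5", "--runs", "1",
                         "--seed", "2", "--out", out,
                         "--log-level", "quiet")), 0L)
  pdf_path <- tempfile(fileext = ".pdf")
  expect_equal(run_cli(c("plot", "--in", out, "--out", pdf_path)), 0L)
  expect_true(file.size(pdf_path) > 1000)
})

test_that("analyze recomputes observables from an XYZ trajectory", {
  p <- model_params(n_bonds = 10L, kappa = 5, eps_vp = 1)
  cf <- init_conformation(p, mc_rng(3))
  traj <- tempfile(fileext = ".xyz")
  write_trajectory_frame(cf, 100, traj)
  out2 <- run_mcs(cf, p, mc_rng(4), 50)
  write_trajectory_frame(out2$conformation, 150, traj)

  cfg <- tempfile(fileext = ".cfg")
  write_params(p, cfg)
  tab_path <- tempfile(fileext = ".tsv")
  expect_equal(run_cli(c("analyze", "--in", traj, "--config", cfg,
                         "--out", tab_path)), 0L)
  tab <- read.delim(tab_path)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mcs, c(100, 150))
  expect_equal(tab$u_vl[1], attraction_energy(cf, p), tolerance = 1e-6)
  expect_equal(tab$r_ee[2], end_to_end(out2$conformation), tolerance = 1e-6)
})

test_that("scaling the schedule changes errors but not means", {
  # stationary small system: an isolated flexible ring + chain
  p <- model_params(n_bonds = 12L, kappa = 5, eps_vp = 1)
  run_at <- function(total, runs, seed) {
    sched <- schedule(total_mcs = total, equil_mcs = round(2 / 3 * total),
                      measure_every = max(1, round(total / 3 / 40)),
                      n_measurements = 40, n_runs = runs, base_seed = seed)
    run_replicas(p, sched)$summary
  }
  long <- run_at(12000, 6, 1)
  short <- run_at(4000, 6, 2)
  pooled <- sqrt(long$r_ee_se^2 + short$r_ee_se^2)
  expect_lt(abs(long$r_ee_mean - short$r_ee_mean), 3 * pooled)
  pooled_u <- sqrt(long$u_vl_se^2 + short$u_vl_se^2)
  expect_lt(abs(long$u_vl_mean - short$u_vl_mean), max(3 * pooled_u, 0.5))
})
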