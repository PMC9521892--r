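test_that("migration mixes retained, immigrant, and wild-type fractions", {
  spec <- migration_spec()
  pop1 <- c(1, 0); pop2 <- c(0, 1); wt <- c(0, 1)
  out <- apply_migration(pop1, pop2, wt, spec)
  expect_equal(out$pop1, c(0.99, 0.01))
  expect_equal(out$pop2, c(0.005, 0.995))   # wild-type fraction 0.995
  none <- apply_migration(pop1, pop2, wt, migration_spec(0, 0, 0))
  expect_equal(none$pop1, pop1)
  expect_equal(none$pop2, pop2)
  # symmetric states are a fixed point
  sym <- apply_migration(wt, wt, wt, spec)
  expect_equal(sym$pop1, wt)
  expect_equal(sym$pop2, wt)
})

test_that("the release scenario seeds generation one as specified", {
  cfg <- sim_preset("direct_dcd")
  cfg$generations <- 3L
  traj <- run_simulation(cfg)
  f1 <- traj$allele[traj$allele$generation == 1 & traj$allele$population == 1, ]
  # 25% of males homozygous for all three elements = 12.5% overall per locus
  for (l in c("A", "B", "C")) {
    expect_equal(f1$frequency[f1$locus == l & f1$class == "D"], 0.125)
  }
  f2 <- traj$allele[traj$allele$generation == 1 & traj$allele$population == 2, ]
  expect_equal(f2$frequency[f2$locus == "A" & f2$class == "T"], 1)
  # self-perpetuating preset releases 100x fewer carriers
  spd <- sim_preset("spd")
  expect_equal(spd$release$fraction, 0.0025)
  # release zero: wild-type steady state forever
  none <- config_modify(sim_preset("spd"), "release.fraction", 0)
  none$generations <- 10L
  t0 <- run_simulation(none)
  expect_true(all(class_trajectory(t0, class = "T") == 1))
})

test_that("released individuals pass through selection before mating", {
  cfg <- sim_preset("direct_dcd")
  cfg$populations <- 1L
  cfg$generations <- 2L
  traj <- run_simulation(cfg)
  # generation-2 zygotes: the paternal drive-gamete share reflects the 0.81
  # fitness of the released triple homozygotes; mothers are all wild-type
  w_rel <- 0.9 * 0.95 * 0.95
  expected_share <- 0.25 * w_rel / (0.25 * w_rel + 0.75)
  f <- class_trajectory(traj, locus = "A", class = "D")
  expect_equal(f[2], expected_share / 2, tolerance = 1e-12)
})

test_that("a neutral design with no release is a Mendelian equilibrium", {
  design <- drive_design(locus_spec("A", "E", cuttable = TRUE), name = "inertE")
  cfg <- sim_config(design, repair = repair_params(),
                    fitness = fitness_params(),
                    release = release_spec(0.3), populations = 1L,
                    generations = 12L)
  traj <- run_simulation(cfg)
  f <- class_trajectory(traj, class = "D")
  # no machinery, no fitness: allele frequency constant from generation 2 on
  expect_equal(diff(f[-1]), rep(0, 10), tolerance = 1e-12)
})

test_that("ideal homing follows the closed-form recursion q' = 1 - (1 - q)^2", {
  cfg <- sim_config(drive_preset("spd"),
                    repair = repair_params(kappa = 1, alpha = 1),
                    fitness = fitness_params(),
                    release = release_spec(0.2, sex = "both"),
                    populations = 1L, generations = 15L)
  q <- class_trajectory(run_simulation(cfg))
  pred <- q[1:2]
  for (t in 3:15) pred[t] <- 1 - (1 - pred[t - 1])^2
  expect_equal(q, pred, tolerance = 1e-14)
})

test_that("runs are deterministic and zygote vectors stay normalised", {
  cfg <- sim_preset("indirect_dcd")
  cfg$generations <- 20L
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$allele, t2$allele)
  for (p in 1:2) {
    expect_equal(rowSums(t1$zygote[[p]]), rep(1, 20), tolerance = 1e-9)
  }
})

test_that("containment weakens monotonically as migration into population two grows", {
  maxes <- vapply(0.5^(8:1), function(m) {
    cfg <- config_modify(sim_preset("direct_dcd"), "migration.m21", m)
    cfg$generations <- 60L
    summarize_trajectory(run_simulation(cfg))$max_drive[2]
  }, numeric(1))
  expect_true(all(diff(maxes) > 0))
})

test_that("an all-lethal state space aborts with a collapse diagnostic", {
  design <- drive_preset("spd")
  fp <- fitness_params(dominant = list(A = c(`N^A` = 0, T = 0, R1 = 0, R2 = 0)))
  cfg <- sim_config(design, fitness = fp, release = release_spec(0.5),
                    populations = 1L, generations = 3L)
  expect_error(run_simulation(cfg), "collapse")
})

test_that("the individual-based oracle agrees with the recursion within sampling noise", {
  set.seed(20260920)
  n_ind <- 2e4  # per sex
  mc <- mc_spd(n_ind = n_ind, generations = 10, release = 0.25)
  cfg <- sim_config(drive_preset("spd"), release = release_spec(0.25),
                    populations = 1L, generations = 10L)
  det <- class_trajectory(run_simulation(cfg))
  se <- sqrt(det * (1 - det) / (2 * 2 * n_ind))
  # allow sqrt(t) accumulation of independent per-generation sampling errors
  expect_true(all(abs(mc - det) <= 3 * pmax(se, 1e-8) * sqrt(seq_along(det))))
})
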