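test_that("an isolated supra-threshold unit turns on once and stays up", {
  # no recurrence: a single E unit with drive above threshold
  spec <- network_spec(N_E = 1L, N_I = 1L, Q = 1L, m_X = 0.05,
                       J_EX_factor = 50)    # J_EX * m_X > theta
  w <- derive_weights(spec)
  wm <- build_matrix(spec, seed = 1)
  wm$J@x <- numeric(length(wm$J@x))          # silence any recurrence
  expect_gt(spec$J_EX * spec$m_X, spec$theta_E)
  cfg <- simulation_config(duration = 200, init_p = 0, discard_ms = 0)
  sim <- simulate_network(wm, cfg, seed = 2)
  spk <- spike_times(sim)
  expect_equal(nrow(spk[spk$unit_id == 0, ]), 1)   # exactly one 0->1 event
  expect_equal(sim$flips$state[sim$flips$unit == 1], 1L)
})

test_that("event logs are bit-identical for identical seeds", {
  spec <- small_spec()
  wm <- build_matrix(spec, seed = 3)
  cfg <- simulation_config(duration = 300, record_updates = TRUE)
  s1 <- simulate_network(wm, cfg, seed = 4)
  s2 <- simulate_network(wm, cfg, seed = 4)
  expect_identical(s1$updates, s2$updates)
  expect_identical(s1$flips, s2$flips)
  s3 <- simulate_network(wm, cfg, seed = 5)
  expect_false(identical(s1$flips, s3$flips))
  # spike count per unit cannot exceed update count per unit
  upd <- table(factor(s1$updates$unit, levels = 1:500))
  spk <- table(factor(s1$flips$unit[s1$flips$state == 1], levels = 1:500))
  expect_true(all(spk <= upd))
})

test_that("inter-update intervals are exponential with mean tau per population", {
  spec <- small_spec()
  wm <- build_matrix(spec, seed = 6)
  cfg <- simulation_config(duration = 3000, record_updates = TRUE)
  sim <- simulate_network(wm, cfg, seed = 7)
  u <- sim$updates
  iv_E <- unlist(lapply(sample(1:400, 50), function(j)
    diff(u$t[u$unit == j])), use.names = FALSE)
  iv_I <- unlist(lapply(sample(401:500, 30), function(j)
    diff(u$t[u$unit == j])), use.names = FALSE)
  expect_equal(mean(iv_E), spec$tau_E, tolerance = 0.05)
  expect_equal(mean(iv_I), spec$tau_I, tolerance = 0.05)
  ks <- suppressWarnings(stats::ks.test(iv_E, "pexp", 1 / spec$tau_E))
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster rate series reproduce hand-computable cases", {
  spec <- small_spec(clustering_mode = "E_weights", J_Eplus = 1)
  wm <- build_matrix(spec, seed = 8)
  sim <- simulate_network(wm, simulation_config(duration = 400), seed = 9)
  cr <- cluster_rates(sim, bin_ms = 10)
  expect_equal(dim(cr$rates), c(40, 20))
  expect_true(all(cr$rates >= 0 & cr$rates <= 1))
  # size-weighted cluster average equals the whole-population rate per bin
  memb_all <- c(rep(1L, 400), rep(NA_integer_, 100))
  pop <- cluster_rates(sim, memb_all, bin_ms = 10)
  expect_equal(drop(cr$rates %*% (cr$group_sizes / sum(cr$group_sizes))),
               pop$rates[, 1], tolerance = 1e-12)
  expect_error(cluster_rates(sim, rep(NA_integer_, 500)), "assigned")

  # synthetic flip streams: all units up throughout
  sim_up <- sim
  sim_up$flips <- sim$flips[0, ]
  sim_up$sigma0 <- rep(1L, 500)
  cr_up <- cluster_rates(sim_up, bin_ms = 20)
  expect_true(all(cr_up$rates == 1))
  # one cluster up, rest down
  sim_one <- sim_up
  sim_one$sigma0 <- c(rep(1L, 20), rep(0L, 480))
  cr_one <- cluster_rates(sim_one, bin_ms = 20)
  expect_true(all(cr_one$rates[, 1] == 1))
  expect_true(all(cr_one$rates[, -1] == 0))
})

test_that("the rate-variance statistic matches closed-form series", {
  spec <- small_spec()
  wm <- build_matrix(spec, seed = 10)
  sim <- simulate_network(wm, simulation_config(duration = 400), seed = 11)
  # constant rates: zero variance
  sim_c <- sim
  sim_c$flips <- sim$flips[0, ]
  sim_c$sigma0 <- rep(c(1L, 0L), c(250, 250))
  memb <- c(rep(1L, 400), rep(NA_integer_, 100))
  expect_equal(sigma2_m(cluster_rates(sim_c, memb, bin_ms = 10)), 0)
  # a cluster alternating all-up/all-down each bin has variance ~ 1/4
  n_bins <- 40
  t_flip <- seq(10, 400, by = 10) - 1e-6
  units <- rep(1:400, times = n_bins)
  st <- rep(rep(c(0L, 1L), length.out = n_bins), each = 400)
  sim_a <- sim
  sim_a$sigma0 <- c(rep(1L, 400), rep(0L, 100))
  sim_a$flips <- data.frame(t = rep(t_flip, each = 400), unit = units,
                            state = st)
  v <- sigma2_m(cluster_rates(sim_a, memb, bin_ms = 10), discard_ms = 0)
  expect_equal(v, var(rep(c(0, 1), length.out = n_bins)), tolerance = 1e-12)
  expect_error(sigma2_m(cluster_rates(sim, memb, bin_ms = 10),
                        discard_ms = 500), "discard")
})

test_that("winnerless switching raises sigma2_m well above the unclustered baseline", {
  spec <- default_spec()
  cfg <- simulation_config(duration = 1000, n_trials = 2,
                           n_realizations = 2, seed = 0)
  vs <- variance_sweep(spec, "E_weights", grid = c(1, 2.2), config = cfg)
  expect_equal(nrow(vs), 2)
  expect_gt(vs$mean_sigma2_m[2], 5 * vs$mean_sigma2_m[1])
  # single-value grid gives a single-row table
  vs1 <- variance_sweep(spec, "E_weights", grid = 1,
                        config = simulation_config(duration = 300,
                                                   n_trials = 1,
                                                   n_realizations = 1))
  expect_equal(nrow(vs1), 1)
})

test_that("inhibitory clusters track their excitatory partners in the winnerless regime", {
  spec <- default_spec(clustering_mode = "EI_weights", J_Eplus = 4,
                      R_J = 0.75)
  wm <- build_matrix(spec, seed = 12)
  sim <- simulate_network(wm, simulation_config(duration = 2000), seed = 13)
  crE <- cluster_rates(sim)
  membI <- c(rep(NA_integer_, spec$N_E), sim$assignment_I)
  crI <- cluster_rates(sim, membI)
  keep <- crE$t > 100
  cors <- vapply(1:20, function(q)
    cor(crE$rates[keep, q], crI$rates[keep, q]), numeric(1))
  expect_gt(median(cors), 0.5)
  expect_true(all(cors > 0))
})
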