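test_that("initial velocities are Maxwell-Boltzmann with zero COM momentum", {
  m <- rep(12, 500)
  expect_equal(init_velocities(m, 0, seed = 1), matrix(0, 500, 3))
  v <- init_velocities(m, 300, seed = 3)
  expect_equal(kinetic_temperature(v, m), 300, tolerance = 0.1)
  expect_equal(colSums(v * m), c(0, 0, 0), tolerance = 1e-10)
  expect_identical(v, init_velocities(m, 300, seed = 3))
  expect_error(init_velocities(m, -5), "non-negative")
})

test_that("NVE oscillator matches the closed-form period to 0.1%", {
  theory <- 2 * pi * sqrt(12 / (1 * md_units$energy_to_internal))
  expect_equal(oscillator_period(k = 1, mass = 12, timestep = 0.5), theory,
               tolerance = 1e-3)
})

test_that("an atom at the tether minimum with zero velocity stays put", {
  sys <- harmonic_tether_system(matrix(1:3, 1, 3), k = 2)
  cfg <- sim_config(timestep = 1, n_steps = 100, save_interval_steps = 10,
                    ensemble = nve(), seed = 1)
  res <- integrate_system(sys, cfg, velocities = matrix(0, 1, 3))
  expect_equal(max(abs(sweep(matrix(res$frames, ncol = 3), 2, 1:3))), 0)
})

test_that("NVE energy drift over 1e5 steps is below 1e-4 of mean potential", {
  sys <- elastic_network_system(grid_reference(10), k = 1, cutoff = 8,
                                masses = 12)
  v0 <- init_velocities(sys$masses, 100, seed = 5)
  cfg <- sim_config(timestep = 1, n_steps = 1e5, save_interval_steps = 1000,
                    ensemble = nve(), seed = 5)
  res <- integrate_system(sys, cfg, velocities = v0)
  drift <- abs(diff(range(res$log$total)))
  expect_lt(drift, 1e-4 * mean(res$log$potential))
})

test_that("mass scaling x c with velocities / sqrt(c) reproduces the dt / sqrt(c) run", {
  ref <- grid_reference(10)
  sys_s <- elastic_network_system(ref, k = 1, cutoff = 8, masses = 12)
  sys_h <- elastic_network_system(ref, k = 1, cutoff = 8, masses = 1200)
  v0 <- init_velocities(rep(12, 10), 300, seed = 7)
  cfg_s <- sim_config(timestep = 0.1, n_steps = 1e4, save_interval_steps = 1000,
                      ensemble = nve(), seed = 1)
  cfg_h <- sim_config(timestep = 1.0, n_steps = 1e4, save_interval_steps = 1000,
                      ensemble = nve(), seed = 1)
  tr_s <- integrate_system(sys_s, cfg_s, velocities = v0)
  tr_h <- integrate_system(sys_h, cfg_h, velocities = v0 / 10)
  expect_lt(max(abs(tr_s$frames - tr_h$frames)), 1e-8)
})

test_that("Berendsen thermostat converges mean kinetic T to the target", {
  sys <- harmonic_tether_system(scatter_reference(50), k = 1, masses = 12)
  cfg <- sim_config(timestep = 1, n_steps = 1e5, save_interval_steps = 10,
                    ensemble = berendsen(300, tau = 100), seed = 9)
  res <- integrate_system(sys, cfg,
                          velocities = init_velocities(sys$masses, 150,
                                                       seed = 9))
  after <- res$log$kinetic_T[res$log$time_fs > 10 * 100]
  expect_equal(mean(after), 300, tolerance = 0.02)
})

test_that("heating ramp reaches the target at the configured rate", {
  sys <- harmonic_tether_system(scatter_reference(50), k = 1, masses = 12)
  # 10 K/ps to 300 K: the target is reached at 30 ps
  cfg <- sim_config(timestep = 1, n_steps = 35000, save_interval_steps = 100,
                    ensemble = berendsen(300, tau = 100),
                    heat_ramp = list(rate = 10, target = 300), seed = 2)
  res <- integrate_system(sys, cfg,
                          velocities = init_velocities(sys$masses, 5,
                                                       seed = 2))
  mid <- res$log$kinetic_T[res$log$time_fs >= 14000 & res$log$time_fs <= 16000]
  expect_equal(mean(mid), 150, tolerance = 0.1)  # ~rate * t mid-ramp
  late <- res$log$kinetic_T[res$log$time_fs > 30000 + 100]
  expect_equal(mean(late), 300, tolerance = 0.05)
})

test_that("Langevin sampling of a tether reproduces <|dr|^2> = 3 kB T / k", {
  k <- 2; T0 <- 300
  sys <- harmonic_tether_system(scatter_reference(10), k = k, masses = 12)
  cfg <- sim_config(timestep = 1, n_steps = 2e5, save_interval_steps = 100,
                    ensemble = langevin(T0, gamma = 0.02), seed = 13)
  res <- integrate_system(sys, cfg)
  ref <- sys$potential$ref
  msd <- mean(apply(res$frames, 1L, function(fr) {
    mean(rowSums((matrix(fr, ncol = 3) - ref)^2))
  }))
  expect_equal(msd, 3 * md_units$kB * T0 / k, tolerance = 0.1)
})

test_that("run_ensemble is seed-deterministic with a shared atom table", {
  sys <- harmonic_tether_system(scatter_reference(5), k = 1)
  cfg <- sim_config(timestep = 1, n_steps = 2000, save_interval_steps = 500,
                    ensemble = langevin(100, gamma = 0.01), seed = 1)
  expect_warning(e_dup <- run_ensemble(sys, cfg, seeds = c(4, 4)), "duplicate")
  expect_identical(e_dup$trajectories[[1]], e_dup$trajectories[[2]])
  e <- run_ensemble(sys, cfg, seeds = 1:4)
  expect_equal(length(e$trajectories), 4L)
  expect_false(identical(e$trajectories[[1]], e$trajectories[[2]]))
  e2 <- run_ensemble(sys, cfg, seeds = 1:4)
  expect_identical(e$trajectories, e2$trajectories)
})

test_that("analytic tether B matches the closed form and scales linearly in T", {
  sys <- harmonic_tether_system(matrix(0, 1, 3), k = 1)
  T1 <- 0.1 / md_units$kB  # kB T / k = 0.1 A^2 per axis
  expect_equal(enm_analytic_bfactors(sys, T1), 8 * pi^2 * 0.1,
               tolerance = 1e-12)
  sysE <- elastic_network_system(grid_reference(30), k = 1, cutoff = 8)
  expect_equal(enm_analytic_bfactors(sysE, 200),
               2 * enm_analytic_bfactors(sysE, 100), tolerance = 1e-9)
  expect_lt(max(abs(enm_analytic_bfactors(sysE, 1e-6))), 1e-5)
})

test_that("disconnected elastic networks are rejected by the analytic oracle", {
  ref <- rbind(grid_reference(8), grid_reference(8) + 100)
  sys <- elastic_network_system(ref, k = 1, cutoff = 8)
  expect_error(enm_analytic_bfactors(sys, 300), "disconnected")
})
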