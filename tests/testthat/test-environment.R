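test_that("observations apply the Weber-Fechner transform exactly", {
  o <- observation(c(0L, 3L, 17L))
  expect_identical(o$measurements, log(c(0, 3, 17) + 1))
  expect_identical(o$mean_measurement, mean(o$measurements))
  expect_error(observation(c(-1, 2)))
  expect_error(observation(c(1.5, 2)))
})

test_that("sensor counts are Poisson with the expected mean and variance", {
  set.seed(31)
  field <- field_params(C0 = 160)
  cell <- cell_params(radius = 2)
  st <- cell_state(c(40, 0), heading = pi / 3)
  em <- expected_counts(field, cell, st)
  n <- 2e4
  draws <- matrix(0L, n, cell$n_sensors)
  for (i in seq_len(n))
    draws[i, ] <- sample_observation(field, cell, st)$counts
  for (k in seq_len(cell$n_sensors)) {
    se_mean <- sqrt(em[k] / n)
    expect_lt(abs(mean(draws[, k]) - em[k]), 4 * se_mean)
    # var(s^2) for Poisson ~ (lambda + 2 lambda^2)/n
    se_var <- sqrt((em[k] + 2 * em[k]^2) / n)
    expect_lt(abs(stats::var(draws[, k]) - em[k]), 4 * se_var)
  }
  # no-signal limit: zero mean gives zero counts surely
  far <- cell_state(c(1e6, 0))
  expect_identical(sample_observation(field, cell, far)$counts,
                   rep(0L, cell$n_sensors))
})

test_that("heading dynamics follow the Euler-Maruyama update", {
  cell0 <- cell_params(rot_diffusion = 0)
  st <- cell_state(c(0, 0), heading = 1)
  # D_R = 0, zero action: straight line, displacement n*v*dt exact
  s <- st
  for (i in 1:25) s <- step_cell(s, 0, cell0, dt = 0.1)
  expect_equal(s$heading, 1)
  expect_equal(s$position, 25 * 5 * 0.1 * c(cos(1), sin(1)))
  expect_equal(s$time, 2.5)
  # constant turn rate integrates exactly
  s <- st
  for (i in 1:30) s <- step_cell(s, 0.3, cell0, dt = 0.1)
  expect_equal(s$heading, chemonav:::wrap_angle(1 + 0.3 * 3))
  # noise variance 2*D_R*dt
  set.seed(99)
  cell <- cell_params(rot_diffusion = 0.025)
  dth <- replicate(1e4, {
    s2 <- step_cell(st, 0, cell, dt = 0.1)
    chemonav:::wrap_pi(s2$heading - st$heading)
  })
  expect_lt(abs(stats::var(dth) / (2 * 0.025 * 0.1) - 1), 0.05)
  expect_error(step_cell(st, NaN, cell, 0.1), "non-finite")
})

test_that("episode resets sample the documented initial distributions", {
  config <- episode_config(d0_range = c(100, 500), delta = 10,
                           t_max = 100, dt = 0.1, conc_range = c(16, 160))
  field <- field_params()
  set.seed(5)
  r1 <- reset_episode(config, field)
  set.seed(5)
  r2 <- reset_episode(config, field)
  expect_identical(r1, r2)
  set.seed(6)
  n <- 1e4
  d0 <- numeric(n); c0 <- numeric(n); th <- numeric(n)
  for (i in seq_len(n)) {
    r <- reset_episode(config, field)
    d0[i] <- sqrt(sum(r$state$position^2))
    c0[i] <- r$field$C0
    th[i] <- r$state$heading
  }
  expect_gt(suppressWarnings(
    stats::ks.test(d0, "punif", 100, 500)$p.value), 0.01)
  expect_true(all(c0 >= 16 & c0 <= 160))
  expect_gt(suppressWarnings(
    stats::ks.test(th, "punif", 0, 2 * pi)$p.value), 0.01)
})

test_that("the terminal reward matches its closed form and bounds", {
  config <- episode_config(d0_range = c(50, 400), delta = 10,
                           t_max = 2000, dt = 0.1)
  # timeout at the initial distance: exactly -1
  expect_identical(compute_reward(2000, 200, 200, config), -1)
  # instant (one-step) arrival approaches 1
  expect_equal(compute_reward(0.1, 10, 200, config), (2000 - 0.1) / 2000)
  # timeout halfway out
  expect_identical(compute_reward(2000, (200 + 10) / 2, 200, config), -0.5)
  expect_error(compute_reward(100, 5, 8, config), "d_init")
  # grid: bounded in [-1, 1], and exactly one term active per outcome
  tau <- seq(0.1, 2000, length.out = 80)
  d <- seq(10, 400, length.out = 81)
  grid <- expand.grid(tau = tau, d = d)
  r <- compute_reward(grid$tau, grid$d, 200, config)
  expect_true(all(r >= -1 & r <= 1))
  reached <- grid$d <= 10
  expect_true(all(r[reached] == (2000 - grid$tau[reached]) / 2000))
  expect_true(all(r[!reached] ==
                    pmax(-1, (10 - grid$d[!reached]) / (200 - 10))))
})

test_that("episodes terminate by arrival or horizon with correct timing", {
  env <- tiny_env(d0 = c(40, 40.0001), t_max = 30, dt = 0.1,
                  rot_diffusion = 0)
  res <- run_episode(oracle_policy(), env$config, env$field, env$cell,
                     deterministic = TRUE, seed = 3)
  expect_true(res$reached)
  expect_lte(abs(res$tau - (40 - 10) / 5), 0.1 + 1e-12)
  expect_equal(res$reward, (30 - res$tau) / 30)
  # a policy aiming exactly away from the source never arrives
  res2 <- run_episode(oracle_policy(offset = pi), env$config, env$field,
                      env$cell, deterministic = TRUE, seed = 3)
  expect_false(res2$reached)
  expect_equal(res2$tau, 30)
  expect_equal(res2$reward, -1)  # it ends far beyond d0
})

test_that("episode batches are deterministic under a fixed seed", {
  env <- tiny_env()
  pol <- random_tiny_policy("combined")
  b1 <- run_episodes(pol, env$config, env$field, env$cell, n = 8, seed = 17)
  b2 <- run_episodes(pol, env$config, env$field, env$cell, n = 8, seed = 17)
  expect_identical(b1, b2)
  r1 <- run_episode(pol, env$config, env$field, env$cell, record = TRUE,
                    seed = 21)
  r2 <- run_episode(pol, env$config, env$field, env$cell, record = TRUE,
                    seed = 21)
  expect_identical(r1, r2)
})

test_that("recorded trajectories carry consistent step-level data", {
  env <- tiny_env(rot_diffusion = 0)
  pol <- random_tiny_policy("combined")
  res <- run_episode(pol, env$config, env$field, env$cell, record = TRUE,
                     deterministic = TRUE, seed = 2)
  tr <- res$trajectory
  n <- length(tr$t)
  expect_identical(tr$m, log(tr$M + 1))
  expect_equal(tr$t, (seq_len(n) - 1) * env$config$dt)
  expect_equal(tr$prev_action, c(0, tr$action[-n]))
  expect_equal(dim(tr$h_pre), c(n, pol$spec$hidden_size))
  expect_equal(tr$h_pre[1, ], rep(0, pol$spec$hidden_size))
  # with D_R = 0 the recorded states replay under the recorded actions
  s <- cell_state(tr$x[1, ], tr$theta[1])
  for (k in seq_len(n - 1)) {
    s <- step_cell(s, tr$action[k], env$cell, env$config$dt)
    expect_equal(s$position, tr$x[k + 1, ])
  }
})
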