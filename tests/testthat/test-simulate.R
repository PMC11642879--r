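test_that("toggle-switch simulation is seeded and settles at fixed points", {
  r1 <- simulate_toggle_switch(n_cells = 100, seed = 5)
  r2 <- simulate_toggle_switch(n_cells = 100, seed = 5)
  expect_identical(r1$states, r2$states)
  r3 <- simulate_toggle_switch(n_cells = 100, seed = 6)
  expect_false(identical(r1$states, r3$states))
  expect_true(all(r1$states >= 0))
  expect_identical(dim(r1$states), dim(r1$velocities))
  ## a committed attractor located by deterministic integration is a root of
  ## the drift (root-finding oracle: damped fixed-point iteration)
  p <- toggle_switch_params(sigma = 0)
  st <- c(50, 1)
  for (it in 1:4000) {
    dr <- graphvelo:::.toggle_drift(st[1], st[2], p)
    st <- pmax(st + 0.05 * as.numeric(dr), 0)
  }
  drift_at_fp <- graphvelo:::.toggle_drift(st[1], st[2], p)
  expect_lt(max(abs(drift_at_fp)), 1e-8)
  ## noiseless simulation from long durations concentrates near attractors
  det <- simulate_toggle_switch(toggle_switch_params(sigma = 0, t_max = 40),
                                n_cells = 50, seed = 7)
  late <- det$states[det$times > 30, , drop = FALSE]
  sp <- sqrt(rowSums(graphvelo:::.toggle_drift(late[, 1], late[, 2], p)^2))
  expect_lt(median(sp), 1e-3)
})

test_that("sphere lifting produces tangent velocities of the right scale", {
  ## the pole of the sphere has z = r
  res0 <- structure(list(states = cbind(x = 0, y = 0),
                         velocities = cbind(x = 1, y = 1),
                         velocities_true = cbind(x = 1, y = 1),
                         times = 0, labels = "a", normals = NULL),
                    class = "simulation_result")
  sp0 <- embed_on_sphere(res0, sphere_embed_config(r = 70))
  expect_equal(unname(sp0$states[1, 3]), 70)
  ## interior points: x.v -> 0 as dt -> 0 (sphere tangency identity)
  res <- simulate_toggle_switch(n_cells = 300, seed = 8)
  sp_small <- embed_on_sphere(res, sphere_embed_config(dt = 1e-6))
  radial <- abs(rowSums(sp_small$states * sp_small$velocities)) /
    (70 * pmax(sqrt(rowSums(sp_small$velocities^2)), 1e-12))
  expect_lt(median(radial), 1e-4)
  ## ground-truth tangency at a small finite step
  sp_m <- embed_on_sphere(res, sphere_embed_config(dt = 1e-3))
  rad_m <- abs(rowSums(sp_m$states * sp_m$velocities)) /
    (70 * pmax(sqrt(rowSums(sp_m$velocities^2)), 1e-12))
  expect_lt(median(rad_m), 0.02)
  ## finite-difference vertical velocity approaches the analytic derivative
  ## with an O(dt) error (measured empirically at dt = 1 and dt = 0.5)
  err_at <- function(dt) {
    sp <- embed_on_sphere(res, sphere_embed_config(dt = dt))
    z <- sp$states[, 3]
    ok <- z > 5
    analytic <- -(sp$states[ok, 1] * sp$velocities[ok, 1] +
                    sp$states[ok, 2] * sp$velocities[ok, 2]) / z[ok]
    median(abs(sp$velocities[ok, 3] - analytic))
  }
  e1 <- err_at(1); e05 <- err_at(0.5)
  expect_lt(e05, e1)
  expect_lt(e1, 0.5)   # small relative to typical speeds of a few units
})

test_that("noise injection respects its mode, level and seed", {
  sp <- sphere_fixture(n_cells = 200, seed = 9)
  ## zero level leaves the field untouched
  expect_equal(add_noise(sp, "gaussian", 0, seed = 1)$velocities,
               sp$velocities_true)
  ## orthogonal noise lies along the radial direction only
  no <- add_noise(sp, "orthogonal", 1.5, seed = 2)
  diff <- no$velocities - no$velocities_true
  ## build two tangent basis vectors per cell and check orthogonality
  for (i in c(1, 50, 200)) {
    nrm <- sp$normals[i, ]
    t1 <- c(-nrm[2], nrm[1], 0)
    if (sqrt(sum(t1^2)) < 1e-8) t1 <- c(1, 0, 0)
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2],
            nrm[3] * t1[1] - nrm[1] * t1[3],
            nrm[1] * t1[2] - nrm[2] * t1[1])
    expect_lt(abs(sum(diff[i, ] * t1)), 1e-10)
    expect_lt(abs(sum(diff[i, ] * t2)), 1e-10)
  }
  ## gaussian level is calibrated (Monte-Carlo check at n = 2000)
  big <- sphere_fixture(n_cells = 2000, seed = 10)
  ng <- add_noise(big, "gaussian", 2, seed = 3)
  sds <- apply(ng$velocities - ng$velocities_true, 2, sd)
  expect_true(all(abs(sds - 2) < 0.1))
  ## orthogonal mode without a normal field fails loudly
  flat <- simulate_toggle_switch(n_cells = 20, seed = 1)
  expect_error(add_noise(flat, "orthogonal", 1), "normal")
  ## seeding contract
  expect_identical(add_noise(sp, "orthogonal", 1, seed = 4)$velocities,
                   add_noise(sp, "orthogonal", 1, seed = 4)$velocities)
})

test_that("variable-degradation kinetics start at steady state and stiffen", {
  traj <- simulate_variable_degradation()
  expect_equal(traj$du[1], 0, tolerance = 1e-10)
  expect_equal(traj$ds[1], 0, tolerance = 1e-10)
  ## gamma(t) = gamma0 + k_gamma * m(t) grows monotonically to its plateau
  expect_true(all(diff(traj$gamma_t) >= -1e-10))
  expect_lt(max(traj$gamma_t), 1 + 3 * (1 / 0.5) + 1e-6)
  ## the failure mode of constant-rate estimators: a sizeable stretch of the
  ## trajectory has positive naive velocity (beta u - gamma0 s > 0) while
  ## the true ds/dt is negative
  p <- traj$params
  naive <- p$beta * traj$u - p$gamma0 * traj$s
  frac <- mean(traj$ds < 0 & naive > 0)
  expect_gt(frac, 0.2)
  ## guard on parameters that would drive transcription negative
  expect_error(degradation_params(k_alpha = 6), "alpha0")
})

test_that("transcription bursts jump between the two linear asymptotes", {
  b <- simulate_transcription_burst(alpha = 5, beta = 1, gamma = 1,
                                    t_burst = 8, fold = 3, t_max = 20)
  i_pre <- max(which(b$times < b$t_burst))
  ## pre-burst asymptote alpha/beta, post-burst fold*alpha/beta (within 1%)
  expect_lt(abs(b$u[i_pre] - 5) / 5, 0.01)
  expect_lt(abs(b$u[length(b$u)] - 15) / 15, 0.01)
  ## du/dt immediately after the burst from steady state is 2*alpha
  i_post <- min(which(b$times >= b$t_burst))
  du_burst <- b$fold * 5 - 1 * b$u[i_post]
  expect_lt(abs(du_burst - 2 * 5) / 10, 0.02)
  expect_error(simulate_transcription_burst(t_burst = 30, t_max = 20),
               "t_burst")
})

test_that("kinetics trajectories package into valid one-gene populations", {
  traj <- simulate_variable_degradation(degradation_params(n_steps = 50))
  pop <- kinetics_population(traj)
  expect_s3_class(validate_population(pop), "cell_population")
  expect_identical(dim(pop$X), c(50L, 1L))
  expect_equal(unname(pop$layers$velocity[, 1]), traj$ds)
  expect_equal(pop$obs$pseudotime, traj$times)
})
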