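test_that("realization seeding is deterministic and distinct", {
  expect_equal(realization_seed(1L, 1L), realization_seed(1L, 1L))
  s <- vapply(1:20, function(r) realization_seed(42L, r), 0)
  expect_equal(length(unique(s)), 20L)
  expect_true(all(s >= 0 & s < 2147483647))
  ch <- fixture_chain("ATATATAT", clamp_len = 2)
  p <- fixture_params(A_p = 0)
  cfg <- sim_config(dt = 0.5, n_steps = 2000, preheat_steps = 0,
                    n_realizations = 1, sample_stride = 10, seed = 7L)
  t1 <- run_realization(ch, p, cfg, 1L)
  t2 <- run_realization(ch, p, cfg, 1L)
  expect_identical(t1$Y, t2$Y)
  t3 <- run_realization(ch, p, cfg, 2L)
  expect_false(identical(t1$Y, t3$Y))
  expect_false(identical(t1$seed_used, t3$seed_used))
})

test_that("zero-temperature damped dynamics relaxes to the closed chain", {
  ch <- fixture_chain("ATGCATGC", clamp_len = 1)
  p <- fixture_params(G_bar = 0, A_p = 0)
  res <- langevin_run(ch, p, dt = 0.5, n_steps = 4e4, sample_stride = 4e4,
                      y0 = rep(0.8, ch$N), v0 = rep(0, ch$N),
                      temperature = 0, with_particle = FALSE)
  expect_lt(max(abs(res$y_final)), 1e-3)
  expect_lt(max(abs(res$v_final)), 1e-3)
})

test_that("conservative limit conserves energy at high order in dt", {
  ch <- fixture_chain("ATGAT")
  p <- fixture_params(A_p = 0)
  set.seed(3)
  y0 <- runif(ch$N, 0.1, 0.6)
  v0 <- rnorm(ch$N, sd = 0.005)
  drift <- vapply(c(0.5, 0.25, 0.125), function(dt) {
    res <- langevin_run(ch, p, dt = dt, n_steps = round(2000 / dt),
                        sample_stride = round(2000 / dt) / 10,
                        y0 = y0, v0 = v0, gamma = 0, temperature = 0,
                        with_particle = FALSE, record_energy = TRUE)
    max(abs(res$energy - res$energy[1]))
  }, 0)
  # absolute sanity bound: drift at the coarsest step is a negligible
  # fraction of the ~0.05 eV energy scale
  expect_lt(drift[1], 1e-5)
  # at least 4th-order convergence of the energy error
  expect_gt(drift[1] / drift[2], 14)
  expect_gt(drift[2] / drift[3], 14)
})

test_that("clamped boundary sites stay exactly closed", {
  ch <- fixture_chain("ATAT", clamp_len = 3)
  p <- fixture_params()
  cfg <- sim_config(dt = 0.5, n_steps = 5000, preheat_steps = 500,
                    n_realizations = 1, sample_stride = 25, seed = 2L)
  tr <- run_realization(ch, p, cfg, 1L)
  expect_equal(max(abs(tr$Y[, !ch$mask])), 0)
  expect_true(all(abs(tr$Y[, ch$mask]) > 0))
})

test_that("kinetic temperature satisfies equipartition with the bath", {
  ch <- fixture_chain(strrep("AT", 20), clamp_len = 2)
  p <- fixture_params(A_p = 0)
  cfg <- sim_config(dt = 0.5, n_steps = 1.2e5, preheat_steps = 1e4,
                    n_realizations = 1, sample_stride = 10, seed = 11L)
  tr <- run_realization(ch, p, cfg, 1L)
  expect_lt(abs(kinetic_temperature(tr, ch, p) - 290) / 290, 0.05)
})

test_that("A-T tracts breathe more than G-C tracts", {
  p <- fixture_params(A_p = 0)
  cfg <- sim_config(dt = 0.5, n_steps = 6e4, preheat_steps = 5e3,
                    n_realizations = 2, sample_stride = 20, seed = 5L)
  at <- run_ensemble(fixture_chain(strrep("A", 30), clamp_len = 3), p, cfg)
  gc <- run_ensemble(fixture_chain(strrep("G", 30), clamp_len = 3), p, cfg)
  # site-level 95% CI separation between the two homogeneous tracts
  tt <- stats::t.test(at$profile$mean_opening, gc$profile$mean_opening,
                      alternative = "greater")
  expect_lt(tt$p.value, 0.05)
  expect_gt(mean(at$profile$mean_opening), mean(gc$profile$mean_opening))
  expect_gt(mean(at$profile$mean_opening), 0)
})

test_that("the stochastic integrator agrees with an Euler-Maruyama oracle", {
  ch <- fixture_chain(strrep("AT", 8), clamp_len = 2)
  p <- fixture_params(A_p = 0)
  mean_open <- function(method, dt, seed) {
    set.seed(seed)
    res <- langevin_run(ch, p, dt = dt, n_steps = round(3e4 / dt),
                        sample_stride = 5, y0 = numeric(ch$N),
                        v0 = rnorm(ch$N, sd = sqrt(kBT(p) / p$mass)),
                        with_particle = FALSE, method = method)
    mean(res$Y[-(1:200), ch$mask])
  }
  a <- mean(vapply(1:4, function(s) mean_open("srk4", 0.5, s), 0))
  b <- mean(vapply(1:4, function(s) mean_open("euler", 0.05, s), 0))
  expect_lt(abs(a - b), 0.08)
})

test_that("opening profile and particle histogram match hand counts", {
  ch <- fixture_chain("ACGT")
  Y <- rbind(c(0, 1, 2, 3), c(4, 3, 2, 1), c(2, 2, 2, 2))
  tr <- fixture_trajectory(Y, x = c(0, 3.6, 2.0))
  pr <- opening_profile(list(tr), ch)
  expect_equal(pr$mean_opening, c(2, 2, 2, 2))
  # sites: round(0) -> 1, round(3.6) = 4 wraps to 1, round(2) -> 3
  expect_equal(pr$particle_fraction, c(2, 0, 1, 0) / 3)
  expect_equal(particle_site(c(-0.4, 0.6, 3.49), 4), c(1L, 2L, 4L))

  # clamped sites are excluded and the histogram renormalized over the rest
  ch2 <- fixture_chain("AC", clamp_len = 1)
  tr2 <- fixture_trajectory(matrix(0, 2, 4), x = c(1, 1))
  pr2 <- opening_profile(list(tr2), ch2)
  expect_equal(nrow(pr2), 2L)
  expect_equal(sum(pr2$particle_fraction), 1)
})
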