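test_that("on-site potential has Morse limits and barrier peak", {
  p <- fixture_params(G_bar = 0)
  expect_equal(onsite_potential(0, "AT", p), 0)
  expect_equal(onsite_potential(1e3, "AT", p), p$D_AT, tolerance = 1e-12)
  expect_equal(onsite_potential(1e3, "GC", p), p$D_GC, tolerance = 1e-12)

  pb <- fixture_params()  # barrier on
  morse_at_peak <- onsite_potential(pb$b_pos, "AT", fixture_params(G_bar = 0))
  expect_equal(onsite_potential(pb$b_pos, "AT", pb),
               morse_at_peak + pb$G_bar)

  # G-C on-site potential dominates A-T for open states
  y <- seq(0, 6, by = 0.05)
  expect_true(all(onsite_potential(y, "GC", p) >=
                    onsite_potential(y, "AT", p) - 1e-12))
})

test_that("stacking potential has the two elastic-constant regimes", {
  p <- fixture_params()
  expect_equal(stacking_potential(0.7, 0.7, p), 0)
  # y_n + y_prev = 0: effective constant k*(1+rho)
  d <- 0.3
  expect_equal(stacking_potential(d / 2, -d / 2, p),
               0.5 * p$k_stack * (1 + p$rho) * d^2)
  # large openings: constant drops to k
  expect_equal(stacking_potential(50 + d, 50, p),
               0.5 * p$k_stack * d^2, tolerance = 1e-10)
})

test_that("particle potential is a saturating bounded attraction", {
  p <- fixture_params()
  y <- rep(0, 21)
  expect_equal(particle_potential(10, y, p), 0)
  # saturated single open site under the particle -> -A_p
  y[11] <- 1e4
  expect_equal(particle_potential(10, y, p), -p$A_p, tolerance = 1e-9)
  # symmetric about an isolated open site
  expect_equal(particle_potential(10 + 1.3, y, p),
               particle_potential(10 - 1.3, y, p))
  # bounded: between -A_p * sum(g) and 0
  set.seed(1)
  yr <- abs(rnorm(21))
  g <- exp(-((10.4 - (0:20))^2) / (2 * p$sigma_p^2))
  v <- particle_potential(10.4, yr, p)
  expect_lte(v, 0)
  expect_gte(v, -p$A_p * sum(g))
})

test_that("well-sum truncation at 6 sigma is numerically negligible", {
  p <- fixture_params(sigma_p = 2)
  y <- rep(3, 101)
  v_trunc <- particle_potential(50, y, p)
  g <- exp(-((50 - (0:100))^2) / (2 * p$sigma_p^2))
  v_full <- -p$A_p * sum(tanh(3 / p$y_sat) * g)
  expect_lt(abs(v_trunc - v_full), 1e-6 * p$A_p)
})

test_that("total energy decomposes and validates lengths", {
  p <- fixture_params()
  ch <- fixture_chain("ATGC")
  # closed chain has zero energy only without the solvent barrier (whose
  # Gaussian tail contributes ~G_bar*exp(-b_pos^2/(2*b_w^2)) per site at y=0)
  p_nb <- fixture_params(G_bar = 0)
  expect_equal(total_energy(rep(0, 4), 0, ch, p_nb,
                            with_particle = FALSE)$total, 0)
  expect_equal(total_energy(rep(0, 4), 0, ch, p, with_particle = FALSE)$total,
               4 * p$G_bar * exp(-p$b_pos^2 / (2 * p$b_w^2)))
  # N = 2 toy: term-by-term hand evaluation
  ch2 <- fixture_chain("AG")
  y <- c(0.4, -0.1); x <- 0.7
  e <- total_energy(y, x, ch2, p)
  hand <- onsite_potential(y[1], "AT", p) + onsite_potential(y[2], "GC", p) +
    stacking_potential(y[2], y[1], p) + particle_potential(x, y, p)
  expect_equal(e$total, hand, tolerance = 1e-12)
  # decoupling when A_p = 0
  p0 <- fixture_params(A_p = 1e-12)
  p0$A_p <- 0
  e0 <- total_energy(y, x, ch2, p0)
  expect_equal(e0$particle, 0)
  expect_error(total_energy(rep(0, 3), 0, ch2, p), "match")
})

test_that("forces equal minus the gradient of the energy (FD property)", {
  p <- fixture_params()
  s <- synth_promoter(25, 0.5, seed = 42)
  ch <- encode_chain(s, clamp_len = 2)
  h <- 1e-6
  for (rep in 1:5) {
    set.seed(rep)
    # keep openings away from the (intentional) derivative kink at y = 0
    y <- abs(rnorm(ch$N, 0.6, 0.5)) + 0.05
    x <- runif(1, 0, ch$N)
    f <- chain_forces(y, x, ch, p)
    fd <- vapply(seq_len(ch$N), function(i) {
      yp <- y; yp[i] <- y[i] + h
      ym <- y; ym[i] <- y[i] - h
      -(total_energy(yp, x, ch, p)$total -
          total_energy(ym, x, ch, p)$total) / (2 * h)
    }, 0)
    expect_equal(f$fy, fd, tolerance = 1e-6)
    fxd <- -(total_energy(y, x + h, ch, p)$total -
               total_energy(y, x - h, ch, p)$total) / (2 * h)
    # absolute bound: the particle force can be arbitrarily small far from
    # wells, where a relative tolerance is meaningless
    expect_lt(abs(f$fx - fxd), 1e-7)
  }
  # closed chain without barrier or particle is the global minimum
  p0 <- fixture_params(G_bar = 0)
  f0 <- chain_forces(rep(0, ch$N), 0, ch, p0, with_particle = FALSE)
  expect_equal(f0$fy, rep(0, ch$N))
})

test_that("particle back-reaction on the chain has the analytic form", {
  p <- fixture_params()
  ch <- fixture_chain("AAAAA")
  y <- c(0.2, 0.5, 1.0, 0.5, 0.2)
  x <- 2.3
  n0 <- 3  # site index (1-based), well center at x = 2
  f_with <- chain_forces(y, x, ch, p)$fy[n0]
  f_wo <- chain_forces(y, x, ch, p, with_particle = FALSE)$fy[n0]
  tt <- tanh(y[n0] / p$y_sat)
  expected <- p$A_p * (1 - tt^2) / p$y_sat *
    exp(-(x - (n0 - 1))^2 / (2 * p$sigma_p^2))
  expect_equal(f_with - f_wo, expected, tolerance = 1e-12)
})

test_that("parameter validation enforces the physical constraints", {
  expect_error(model_params(D_AT = 0.08), "D_GC > D_AT")
  expect_error(model_params(D_AT = -1), "D_GC > D_AT")
  expect_error(model_params(G_bar = -0.1), "G_bar")
  expect_error(model_params(y_sat = 0), "y_sat")
  expect_error(model_params(temperature = -5), "temperature")
  p <- model_params(temperature = 300)
  expect_equal(kBT(p), 300 * p$kB)
  expect_equal(kBT(p, 150), 150 * p$kB)
})
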