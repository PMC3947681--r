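test_that("probability condition: psi(1, t) = 1 for every valid model", {
  withr::with_seed(20, {
    models <- c(list(fixture_pure_death(4, 1.3),
                     fixture_birth_death(3, 0.6, 1.1),
                     fixture_transfer(),
                     as_linear_model(cascade_spec(c(1, 2), c(0.3, 0.2), 3))),
                lapply(1:4, function(i) fixture_random_linear(2, 3, seed = i)))
    for (m in models) {
      maxrate <- max(sum(rates_at(m, m$initial_pops)), 0.1)
      for (t in c(0.3, 2) / maxrate) {
        expect_lt(abs(solve_w(m, rep(1, m$n_events), t)$psi - 1), 1e-9)
      }
    }
  })
})

test_that("pure-death w solution matches the binomial closed form", {
  pd <- fixture_pure_death(M = 2, rate = 0.9)
  for (z in c(0, 0.5, -0.3 + 0.4i, 1i)) {
    for (t in c(0.2, 1, 3)) {
      sol <- solve_w(pd, z, t)
      expect_lt(abs(sol$psi - pure_death_psi(2, 0.9, t, z)), 1e-8)
      # inner bracket: w = exp(-rt) + z (1 - exp(-rt))
      expect_lt(abs(sol$w[1] - (exp(-0.9 * t) + z * (1 - exp(-0.9 * t)))),
                1e-8)
    }
  }
  # t = 0 initial condition
  s0 <- solve_w(pd, 0.3, 0)
  expect_equal(unname(s0$w), 1 + 0i)
  expect_equal(s0$psi, 1 + 0i)
})

test_that("the w route and the flow/exponent route agree", {
  withr::with_seed(31, {
    models <- c(list(fixture_birth_death(2, 0.8, 1.2), fixture_transfer()),
                lapply(1:10, function(i) {
                  n <- sample(1:3, 1)
                  fixture_random_linear(n, n + sample(0:2, 1),
                                        seed = 300 + i)
                }))
    for (m in models) {
      z <- exp(2i * pi * runif(m$n_events))    # unit circle
      maxrate <- max(sum(rates_at(m, m$initial_pops)), 0.1)
      t <- runif(1, 0.1, 1.5) / maxrate
      psi_w <- solve_w(m, z, t)$psi
      psi_f <- solve_f_via_phi1(m, z, t)$psi
      expect_lt(abs(psi_w - psi_f), 1e-7)
    }
    # z = 1 gives Phi1 = 1 exactly up to integration error
    bd <- fixture_birth_death(2, 0.8, 1.2)
    expect_lt(abs(solve_f_via_phi1(bd, c(1, 1), 0.7)$psi - 1), 1e-9)
  })
})

test_that("transform inversion reproduces the binomial death-count law", {
  pd <- fixture_pure_death(M = 2, rate = 1)
  d <- event_count_distribution(pd, log(2), truncation = 2)
  expect_equal(d$probability, c(0.25, 0.5, 0.25), tolerance = 1e-8)

  # t = 0: point mass at the origin
  d0 <- event_count_distribution(pd, 0, truncation = 2)
  expect_equal(d0$probability, c(1, 0, 0))

  # M = 10, rt = ln 2: Binomial(10, 1/2)
  pd10 <- fixture_pure_death(M = 10, rate = 1)
  d10 <- event_count_distribution(pd10, log(2), truncation = 10)
  expect_lt(max(abs(d10$probability - dbinom(0:10, 10, 0.5))), 1e-8)
})

test_that("transform inversion agrees with master-equation integration", {
  m <- fixture_transfer()
  K <- c(8, 8, 8)
  d1 <- event_count_distribution(m, 0.5, truncation = K)
  d2 <- master_equation_integrate(m, 0.5, truncation = K)
  expect_lt(tv_dist(d1, d2), 1e-6)

  cc <- as_linear_model(cascade_spec(c(1, 2), cohort_size = 3))
  d3 <- event_count_distribution(cc, 0.8, truncation = c(3, 3))
  d4 <- master_equation_integrate(cc, 0.8, truncation = c(3, 3))
  expect_lt(tv_dist(d3, d4), 1e-6)
})

test_that("projection to population space conserves mass and matches the binomial", {
  pd <- fixture_pure_death(M = 4, rate = 1)
  d <- event_count_distribution(pd, log(2), truncation = 4)
  p <- project_to_populations(d)
  # survivors = M - deaths ~ Binomial(4, 1/2) reversed = same symmetric law
  expect_equal(p$probability, dbinom(4:0, 4, 0.5), tolerance = 1e-8)
  expect_lt(abs(sum(p$probability) + attr(p, "discarded_mass") -
                  attr(d, "mass_captured")), 1e-10)

  # birth-death marginal matches coefficient extraction from the closed form
  bd <- fixture_birth_death(2, 0.5, 1)
  db <- event_count_distribution(bd, 0.6, truncation = c(12, 12))
  pb <- project_to_populations(db)
  # extract population pmf from the population-space pgf by 1-d inversion
  Kx <- 24
  th <- exp(2i * pi * (0:Kx) / (Kx + 1))
  vals <- vapply(th, function(y) birth_death_psi(2, 0.5, 1, 0.6, y),
                 complex(1))
  pmf <- Re(fft(vals)) / (Kx + 1)
  for (i in seq_len(nrow(pb))) {
    expect_lt(abs(pb$probability[i] - pmf[pb$X[i] + 1]), 1e-6)
  }
})

test_that("structural-zero monomials are conserved along the flow", {
  bd <- fixture_birth_death(1, 0.7, 1.3)
  res <- check_constants_of_motion(bd, c(0.8 + 0.3i, 0.2 - 0.5i), 2)
  expect_equal(nrow(res), 1)
  expect_lt(res$max_residual, 1e-8)

  # projected constant: z from population arguments gives C = 1
  y <- 0.6 + 0.2i
  zp <- event_args_from_pop(bd, y)
  expect_equal(prod(zp^structural_zeroes(bd)[, 1]), 1 + 0i)

  # full-rank square incidence: no structural zeroes, empty result
  cc <- as_linear_model(cascade_spec(c(1, 2), cohort_size = 1))
  expect_equal(nrow(check_constants_of_motion(cc, c(0.5, 0.5), 1)), 0)

  # mortality cascade: all residuals small
  mc <- as_linear_model(cascade_spec(c(1, 2), c(0.4, 0.6), 2))
  resm <- check_constants_of_motion(mc, random_z(4) * 0.5 + 0.5, 1)
  expect_equal(nrow(resm), 2)
  expect_true(all(resm$max_residual <= 1e-8))
})

test_that("moments match distribution-law oracles", {
  pd <- fixture_pure_death(M = 10, rate = 1)
  t <- log(2)
  mo <- moments(pd, t, order = 2)
  expect_equal(unname(mo$mean), 10 * (1 - exp(-t)), tolerance = 1e-4)
  expect_equal(unname(mo$cov[1, 1]), 10 * 0.5 * 0.5, tolerance = 1e-3)

  # birth-death: mean population follows the Malthusian ODE
  bd <- fixture_birth_death(3, 0.7, 1.3)
  mb <- moments(bd, 0.8)
  expect_equal(3 + unname(mb$mean[1] - mb$mean[2]), 3 * exp(-0.6 * 0.8),
               tolerance = 1e-4)

  # t = 0: all moments vanish
  m0 <- moments(bd, 0, order = 2)
  expect_equal(unname(m0$mean), c(0, 0))
  expect_equal(unname(m0$cov), matrix(0, 2, 2), tolerance = 1e-8)
})

test_that("projection wrapper matches the birth-death closed form", {
  bd <- fixture_birth_death(3, 0.7, 1.3)
  for (y in c(0.4 + 0.1i, 0.9, -0.2 + 0.6i)) {
    expect_lt(abs(population_psi(bd, y, 0.8) -
                    birth_death_psi(3, 0.7, 1.3, 0.8, y)), 1e-8)
  }
})

test_that("transform arguments far outside the disk are rejected", {
  pd <- fixture_pure_death(2, 1)
  expect_error(solve_w(pd, 2, 1), "1.5")
})
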