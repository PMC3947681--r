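test_that("every closed form satisfies the probability condition at z = 1", {
  withr::with_seed(41, {
    for (i in 1:20) {
      E <- sample(1:5, 1)
      rr <- runif(E, 0.3, 3)
      qq <- runif(E, 0.1, 1)
      t <- runif(1, 0.1, 2)
      ones <- rep(1 + 0i, E)
      expect_lt(abs(pure_death_psi(sample(1:10, 1), rr[1], t, 1) - 1), 1e-12)
      expect_lt(abs(birth_death_psi(3, rr[1], qq[1], t, 1) - 1), 1e-12)
      expect_lt(abs(cascade_W0_distinct(rr, t, ones) - 1), 1e-9)
      expect_lt(abs(cascade_W0_equal(E, rr[1], t, ones) - 1), 1e-12)
      expect_lt(abs(cascade_mortality_W0_distinct(
        cascade_spec(rr, qq), t, ones, ones) - 1), 1e-9)
      expect_lt(abs(cascade_mortality_W0_equal(E, rr[1], qq[1], t,
                                               ones, ones) - 1), 1e-12)
    }
  })
})

test_that("closed forms agree with the characteristics solver", {
  withr::with_seed(42, {
    # pure death at a grid of (z, t)
    pd <- fixture_pure_death(3, 1.1)
    for (i in 1:10) {
      z <- random_z(1); t <- runif(1, 0.05, 2)
      expect_lt(abs(pure_death_psi(3, 1.1, t, z) - solve_w(pd, z, t)$psi),
                1e-8)
    }
    # birth-death in population space
    bd <- fixture_birth_death(2, 0.6, 1.4)
    for (i in 1:10) {
      y <- random_z(1); t <- runif(1, 0.05, 1.5)
      expect_lt(abs(birth_death_psi(2, 0.6, 1.4, t, y) -
                      population_psi(bd, y, t)), 1e-8)
    }
    # cascade, distinct rates
    rr <- c(1.0, 1.7, 0.6)
    cc <- as_linear_model(cascade_spec(rr, cohort_size = 2))
    for (i in 1:10) {
      z <- random_z(3); t <- runif(1, 0.05, 1.5)
      expect_lt(abs(cascade_W0_distinct(rr, t, z)^2 - solve_w(cc, z, t)$psi),
                1e-8)
    }
    # cascade, equal rates
    ce <- as_linear_model(cascade_spec(rep(1.3, 3), cohort_size = 2))
    for (i in 1:10) {
      z <- random_z(3); t <- runif(1, 0.05, 1.5)
      expect_lt(abs(cascade_W0_equal(3, 1.3, t, z)^2 - solve_w(ce, z, t)$psi),
                1e-8)
    }
    # mortality cascade, distinct exit rates: event order (death, mat) pairs
    spec <- cascade_spec(c(1.0, 1.7, 0.6), c(0.3, 0.8, 0.2), 2)
    cm <- as_linear_model(spec)
    for (i in 1:10) {
      z <- random_z(3); y <- random_z(3); t <- runif(1, 0.05, 1.5)
      zy <- as.vector(rbind(z, y))       # interleave to event order
      expect_lt(abs(cascade_mortality_W0_distinct(spec, t, z, y)^2 -
                      solve_w(cm, zy, t)$psi), 1e-8)
    }
    # mortality cascade, equal rates
    spec_e <- cascade_spec(rep(1.2, 3), rep(0.4, 3), 2)
    cme <- as_linear_model(spec_e)
    for (i in 1:10) {
      z <- random_z(3); y <- random_z(3); t <- runif(1, 0.05, 1.5)
      zy <- as.vector(rbind(z, y))
      expect_lt(abs(cascade_mortality_W0_equal(3, 1.2, 0.4, t, z, y)^2 -
                      solve_w(cme, zy, t)$psi), 1e-8)
    }
  })
})

test_that("partial-fraction cascade forms match the integral recursion", {
  withr::with_seed(43, {
    rr <- c(0.9, 2.1, 0.5, 1.4)
    qq <- c(0.2, 0.7, 0.35, 0.15)
    for (i in 1:5) {
      z <- random_z(4); y <- random_z(4); t <- runif(1, 0.1, 2)
      spec0 <- cascade_spec(rr)
      expect_lt(abs(cascade_W0_distinct(rr, t, z) -
                      cascade_W0_ode(spec0, t, z)), 1e-8)
      expect_lt(abs(cascade_W0_equal(4, 1.1, t, z) -
                      cascade_W0_ode(cascade_spec(rep(1.1, 4)), t, z)), 1e-8)
      specm <- cascade_spec(rr, qq)
      expect_lt(abs(cascade_mortality_W0_distinct(specm, t, z, y) -
                      cascade_W0_ode(specm, t, z, y)), 1e-8)
      expect_lt(abs(cascade_mortality_W0_equal(4, 1.1, 0.3, t, z, y) -
                      cascade_W0_ode(cascade_spec(rep(1.1, 4), rep(0.3, 4)),
                                     t, z, y)), 1e-8)
    }
  })
})

test_that("degenerate limits: distinct-rate forms converge to the equal-rate forms", {
  z <- c(0.3 + 0.2i, 0.7, 0.4 - 0.1i)
  t <- 0.9
  target <- cascade_W0_equal(3, 1.5, t, z)
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    rr <- 1.5 * (1 + (0:2) * eps)
    abs(cascade_W0_distinct(rr, t, z) - target)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))       # monotone decrease
  expect_lt(errs[3], 1e-3)
  # near-ties are refused and routed to the recursion
  expect_error(cascade_W0_distinct(1.5 * (1 + (0:2) * 1e-8), t, z),
               "degenerate")
  expect_lt(abs(cascade_W0(cascade_spec(1.5 * (1 + (0:2) * 1e-8)), t, z) -
                  target), 1e-6)
  # birth_death equal-rate branch is the analytic limit
  expect_lt(abs(birth_death_psi(2, 1, 1, 0.7, 0.4) -
                  birth_death_psi(2, 1, 1 + 1e-7, 0.7, 0.4)), 1e-6)
})

test_that("q = 0 mortality cascade reduces to the plain cascade", {
  z <- c(0.5, 0.2 + 0.3i)
  y <- c(0.8, 0.6 - 0.2i)
  t <- 1.2
  # with q = 0 the death arguments z are inert; maturation args must match
  expect_lt(abs(cascade_mortality_W0_equal(2, 1.4, 0, t, z, y) -
                  cascade_W0_equal(2, 1.4, t, y)), 1e-12)
})

test_that("single-stage mortality cascade matches the competing-risks law", {
  r <- 1.3; q <- 0.6; t <- 0.8; R <- r + q
  z <- 0.4 + 0.2i; y <- 0.7 - 0.1i
  expected <- r * y / R * (1 - exp(-R * t)) + exp(-R * t) +
    q * z / R * (1 - exp(-R * t))
  expect_lt(abs(cascade_mortality_W0_equal(1, r, q, t, z, y) - expected),
            1e-12)
  expect_lt(abs(cascade_mortality_W0_distinct(cascade_spec(r, q), t, z, y) -
                  expected), 1e-12)
})

test_that("exit-time distribution matches Erlang/hypoexponential oracles", {
  # equal rates: Erlang CDF
  cdf <- exit_time_cdf(cascade_spec(rep(1, 3)))
  expect_equal(cdf(3), pgamma(3, 3), tolerance = 1e-12)
  # E = 2 distinct: hand-computed hypoexponential value
  cdf2 <- exit_time_cdf(cascade_spec(c(1, 2)))
  expect_equal(cdf2(1), 1 - 2 * exp(-1) + exp(-2), tolerance = 1e-10)
  # general distinct rates vs phase-type matrix-exponential oracle
  rr <- c(0.7, 1.9, 1.1, 2.8)
  cdf4 <- exit_time_cdf(cascade_spec(rr))
  for (t in c(0.3, 1, 2.5)) {
    expect_equal(cdf4(t), hypoexp_cdf_expm(rr, t), tolerance = 1e-8)
  }
  # coefficient of prod z in the equal-rate form is the Erlang CDF:
  # extract by binary inversion over all z in {1,-1}^E
  for (E in c(1, 2, 5)) {
    for (rt in c(0.5, 1, 3)) {
      grid <- as.matrix(expand.grid(rep(list(c(1, -1)), E)))
      vals <- apply(grid, 1, function(z) cascade_W0_equal(E, 1, rt, z))
      coef <- Re(sum(vals * apply(grid, 1, prod))) / 2^E
      expect_lt(abs(coef - pgamma(rt, E)), 1e-10)
    }
  }
  # defective exit law under mortality: t -> Inf mass
  rr <- c(1, 2, 1.5); qq <- c(0.3, 0.5, 0.2)
  cdfm <- exit_time_cdf(cascade_spec(rr, qq))
  expect_lt(abs(cdfm(200) - prod(rr / (rr + qq))), 1e-8)
  # SSA exit fraction within 3 sigma
  spec <- cascade_spec(c(1.5, 1.5), cohort_size = 1)
  model <- as_linear_model(spec)
  n_runs <- 400
  exits <- withr::with_seed(7, {
    sum(vapply(seq_len(n_runs), function(i) {
      tr <- ssa_simulate(model, 1.2)
      tr[[nrow(tr), "mat1"]] == 1
    }, logical(1)))
  })
  p <- exit_time_cdf(spec)(1.2)
  expect_lt(abs(exits / n_runs - p), 3 * sqrt(p * (1 - p) / n_runs))
})

test_that("stage occupancies match the mortality-cascade coefficients", {
  lambda <- c(1.0, 1.7, 0.6, 2.3)
  mu <- c(0.3, 0.8, 0.2, 0.5)
  occ0 <- stage_occupancy(lambda, mu, 0)
  expect_equal(occ0$probability, c(1, 0, 0, 0), tolerance = 1e-12)
  t <- 0.7
  occ <- stage_occupancy(lambda, mu, t)
  expect_equal(occ$probability[1], exp(-t * (lambda[1] + mu[1])),
               tolerance = 1e-12)
  # coefficient extraction from the 4-stage mortality cascade W0:
  # occupancy of stage i = coefficient of y_0..y_{i-1} (no z, no later y)
  spec <- cascade_spec(lambda, mu)
  grid <- as.matrix(expand.grid(rep(list(c(1, -1)), 8)))
  zg <- grid[, 1:4]; yg <- grid[, 5:8]
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    cascade_mortality_W0_distinct(spec, t, zg[i, ], yg[i, ])
  }, complex(1))
  coef_of <- function(y_expo) {
    mono <- apply(yg, 1, function(y) prod(y^y_expo))
    Re(sum(vals * mono)) / 2^8
  }
  for (s in 0:3) {
    expo <- c(rep(1, s), rep(0, 4 - s))
    expect_lt(abs(occ$probability[s + 1] - coef_of(expo)), 1e-8)
  }
})

test_that("transform inversion recovers binomial and negative-binomial laws", {
  # pure death <-> binomial
  pd <- fixture_pure_death(6, 0.8)
  t <- 0.9; p <- 1 - exp(-0.8 * t)
  d <- event_count_distribution(pd, t, truncation = 6)
  expect_lt(max(abs(d$probability - dbinom(0:6, 6, p))), 1e-9)
  # pure birth <-> negative binomial (births counted from X0 individuals)
  pb <- linear_model(matrix(1L, 1, 1), matrix(0.7, 1, 1), 3)
  tb <- 0.6
  db <- event_count_distribution(pb, tb, truncation = 40)
  pr <- exp(-0.7 * tb)                   # success probability per individual
  expect_lt(max(abs(db$probability - dnbinom(0:40, size = 3, prob = pr))),
            1e-9)
})
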