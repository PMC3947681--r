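test_that("first-order Picard iterate is the linear multinomial factor", {
  bd <- fixture_birth_death(3, 0.7, 1.3)
  w1 <- picard_iterate(bd, 1, k = 1)
  # 1 + h (r1 (z1 - 1) + r2 (z2 - 1))
  expect_equal(w1$terms[["0,0"]][1:2], c(1, -2))
  expect_equal(w1$terms[["1,0"]][2], 0.7)
  expect_equal(w1$terms[["0,1"]][2], 1.3)
  expect_equal(length(w1$terms), 3)
})

test_that("second-order Picard iterate matches an independent expansion term by term", {
  withr::with_seed(50, {
    for (rep in 1:3) {
      m <- fixture_random_linear(2, 3, seed = 500 + rep)
      r <- m$rate_coeffs
      Fm <- r %*% m$incidence
      for (k in 1:2) {
        w2 <- picard_iterate(m, 2, k = k)
        rk <- r[, k]
        E <- 3
        # assemble the second-order coefficients independently:
        # w = 1 + h sum r (z-1) + h^2/2 (sum r (z-1))^2
        #       + h^2/2 sum_b r_b z_b sum_g F[g,b] (z_g - 1)
        co <- list()
        add <- function(expo, tord, val) {
          key <- paste(expo, collapse = ",")
          v <- co[[key]] %||% numeric(3)
          v[tord + 1] <- v[tord + 1] + val
          co[[key]] <<- v
        }
        add(c(0, 0, 0), 0, 1)
        for (b in 1:E) {
          e <- integer(E); e[b] <- 1
          add(e, 1, rk[b]); add(integer(E), 1, -rk[b])
          for (g in 1:E) {
            eg <- integer(E); eg[g] <- 1
            # (h^2/2) r_b r_g (z_b - 1)(z_g - 1)
            add(e + eg, 2, rk[b] * rk[g] / 2)
            add(e, 2, -rk[b] * rk[g] / 2)
            add(eg, 2, -rk[b] * rk[g] / 2)
            add(integer(E), 2, rk[b] * rk[g] / 2)
            # (h^2/2) r_b z_b F[g, b] (z_g - 1)
            add(e + eg, 2, rk[b] * Fm[g, b] / 2)
            add(e, 2, -rk[b] * Fm[g, b] / 2)
          }
        }
        co <- Filter(function(v) any(v != 0), co)
        expect_setequal(names(w2$terms), names(co))
        for (key in names(co)) {
          expect_equal(w2$terms[[key]], co[[key]], tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("Picard iterates are one-individual generating functions", {
  withr::with_seed(51, {
    models <- list(fixture_birth_death(1, 0.9, 1.1), fixture_transfer(),
                   fixture_random_linear(2, 3, seed = 52))
    for (m in models) {
      for (n in 1:4) {
        w <- picard_iterate(m, n)
        for (k in seq_along(w)) {
          # z-degree bounded by n, and leading time order >= z-degree
          for (key in names(w[[k]]$terms)) {
            expo <- as.integer(strsplit(key, ",")[[1]])
            p <- sum(expo)
            expect_lte(p, n)
            co <- w[[k]]$terms[[key]]
            if (p > 0) expect_true(all(co[seq_len(min(p, length(co)))] == 0))
          }
          # normalisation at z = 1: coefficient cancellation, exact up
          # to floating roundoff on the double-precision rate draws
          ones <- rep(1, m$n_events)
          for (t in c(0.13, 0.71)) {
            expect_lt(Mod(tp_eval(w[[k]], ones, t) - 1), 1e-12)
          }
          # coefficients nonnegative for small h
          h <- 0.01 / max(rates_at(m, m$initial_pops) /
                            max(m$initial_pops, 1))
          expect_true(all(tp_coeffs_at(w[[k]], h) > -1e-15))
        }
      }
    }
  })
})

test_that("successive Picard differences shrink like h^n", {
  bd <- fixture_birth_death(2, 0.7, 1.3)
  hs <- 2^-(4:9)
  for (n in 2:4) {
    wa <- picard_iterate(bd, n)
    wb <- picard_iterate(bd, n - 1)
    dmax <- vapply(hs, function(h) {
      m <- 0
      for (k in seq_along(wa)) {
        ka <- tp_coeffs_at(wa[[k]], h)
        kb <- tp_coeffs_at(wb[[k]], h)
        keys <- union(names(ka), names(kb))
        av <- setNames(numeric(length(keys)), keys)
        av[names(ka)] <- ka
        bv <- setNames(numeric(length(keys)), keys)
        bv[names(kb)] <- kb
        m <- max(m, max(abs(av - bv)))
      }
      m
    }, numeric(1))
    slope <- unname(coef(lm(log(dmax) ~ log(hs)))[2])
    expect_lt(abs(slope - n), 0.2)
  }
})

test_that("step probabilities sum to one exactly and match their closed forms", {
  withr::with_seed(53, {
    for (i in 1:50) {
      np <- sample(1:3, 1)
      m <- fixture_random_linear(np, np + sample(0:2, 1), seed = 600 + i)
      k <- sample(np, 1)
      sp <- second_order_step(m, k, h = 0.9 * min(1, m_hmax <- {
        s <- sum(m$rate_coeffs[, k]); if (s > 0) 0.05 / s else 0.05
      }))
      total <- sp$p_none + sum(sp$p_one) + sum(sp$p_two)
      expect_lt(abs(total - 1), 1e-14)
      # conditional decomposition reconstructs the two-event block
      recon <- outer(sp$p_one_bar, rep(1, m$n_events)) * sp$p_cond
      expect_lt(max(abs(recon - sp$p_two)), sp$h^3 * 10)
    }
  })
  # pure death: an individual cannot die twice
  pd <- fixture_pure_death(1, 1.7)
  expect_identical(unname(second_order_step(pd, 1, 0.05)$p_two[1, 1]), 0)
  # pure birth: p_two = h^2 r^2 (F = +r)
  pb <- linear_model(matrix(1L, 1, 1), matrix(1.7, 1, 1), 1)
  expect_equal(unname(second_order_step(pb, 1, 0.05)$p_two[1, 1]),
               0.05^2 * 1.7^2, tolerance = 1e-14)
  # oversized steps are refused with the admissible maximum
  expect_error(second_order_step(pd, 1, 5), "admissible")
})

test_that("one-step total-variation errors decay at the scheme's order", {
  pd <- fixture_pure_death(10, 1)
  bd <- fixture_birth_death(3, 0.7, 1.3)
  expect_lt(abs(order_of_accuracy(pd, "poisson", truncation = 6)$slope - 2),
            0.2)
  expect_lt(abs(order_of_accuracy(bd, "poisson", truncation = 6)$slope - 2),
            0.2)
  expect_lt(abs(order_of_accuracy(bd, "mn1", truncation = 6)$slope - 2), 0.2)
  expect_lt(abs(order_of_accuracy(pd, "mn2", truncation = 6)$slope - 3), 0.2)
  expect_lt(abs(order_of_accuracy(bd, "mn2", truncation = 6)$slope - 3), 0.2)
})

test_that("Poisson approximation error bound on the pure-death mean", {
  M <- 10; r <- 1
  pd <- fixture_pure_death(M, r)
  for (t in c(0.05, 0.1, 0.2)) {
    # Poisson mean M r t vs exact M (1 - e^{-rt}): Taylor bound M (rt)^2 / 2
    expect_lte(abs(M * r * t - M * (1 - exp(-r * t))), M * (r * t)^2 / 2)
    # and the pgf at z = 1 stays normalised
    expect_equal(Mod(poisson_psi(pd, t, 1)), 1, tolerance = 1e-14)
  }
})
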