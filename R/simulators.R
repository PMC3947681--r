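# Stochastic simulation and brute-force integration oracles: the exact
# (Gillespie/Kendall) algorithm, truncated master-equation integration on
# the event-count lattice, and the fixed-step multinomial simulator built
# on the order-1/order-2 per-individual step probabilities.

#' Exact stochastic simulation (Gillespie algorithm)
#'
#' Exponential waiting times with total rate `sum_alpha R_alpha(X)`; the
#' next event is chosen with probability proportional to its rate.
#' Cumulative event counts and populations are recorded at every jump.
#'
#' @param model a validated [linear_model()].
#' @param t_end time horizon.
#' @param seed optional integer seed (fixed seed gives bit-identical
#'   trajectories).
#' @param max_events guard against population explosions (default 1e6).
#' @return A tibble of class `trajectory_sample` with columns `time`,
#'   one cumulative count column per event, one column per population;
#'   attributes `seed`, `scheme = "ssa"`.
#' @examples
#' ssa_simulate(fixture_pure_death(M = 5, rate = 1), t_end = 1, seed = 1)
#' @export
ssa_simulate <- function(model, t_end, seed = NULL, max_events = 1e6) {
  run <- function() {
    delta <- model$incidence
    rates <- model$rate_coeffs
    X <- model$initial_pops
    E <- model$n_events
    n <- numeric(E)
    t <- 0
    cap <- 256L
    times <- numeric(cap); counts <- matrix(0, cap, E)
    pops <- matrix(0, cap, model$n_pops)
    rec <- 1L
    times[1] <- 0; counts[1, ] <- n; pops[1, ] <- X
    repeat {
      R <- as.vector(rates %*% X)
      total <- sum(R)
      if (total <= 0) break
      t <- t + rexp(1, total)
      if (t > t_end) break
      a <- sample.int(E, 1, prob = R)
      n[a] <- n[a] + 1
      X <- X + delta[, a]
      rec <- rec + 1L
      if (rec > cap) {
        cap <- cap * 2L
        times <- c(times, numeric(cap / 2))
        counts <- rbind(counts, matrix(0, cap / 2, E))
        pops <- rbind(pops, matrix(0, cap / 2, model$n_pops))
      }
      times[rec] <- t; counts[rec, ] <- n; pops[rec, ] <- X
      if (sum(n) >= max_events) {
        stop("event cap reached (", max_events,
             "): population explosion suspected")
      }
    }
    idx <- seq_len(rec)
    out <- tibble::as_tibble(cbind(
      data.frame(time = times[idx]),
      setNames(as.data.frame(counts[idx, , drop = FALSE]), model$event_names),
      setNames(as.data.frame(pops[idx, , drop = FALSE]), model$pop_names)))
    structure(out, class = c("trajectory_sample", class(out)),
              seed = seed, scheme = "ssa", t_end = t_end,
              event_names = model$event_names, pop_names = model$pop_names)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Truncated master-equation integration (brute-force oracle)
#'
#' Integrates the Kolmogorov forward equation for `P(n_1, ..., n_E, t)`
#' directly on the truncated event-count lattice `0..K_alpha` per event:
#' `dP(n)/dt = sum_alpha P(n - e_alpha) R_alpha(n - e_alpha) - P(n) sum_alpha R_alpha(n)`
#' with `R(n) = R0 + F n` clamped at zero (states with negative implied
#' populations carry no mass).  Probability flowing past the truncation
#' boundary is discarded; the leaked mass is reported.
#'
#' @param model a validated [linear_model()].
#' @param t_end time horizon.
#' @param truncation per-event count bound `K` (scalar or length `E`);
#'   lattice size `prod(K + 1)` is capped at 1e5.
#' @param rtol,atol integration tolerances.
#' @return An `event_dist` tibble (same shape as
#'   [event_count_distribution()]), attribute `mass_captured`.
#' @export
master_equation_integrate <- function(model, t_end, truncation,
                                      rtol = 1e-10, atol = 1e-12) {
  E <- model$n_events
  K <- truncation
  if (length(K) == 1) K <- rep(K, E)
  stopifnot(length(K) == E)
  Kp1 <- K + 1
  S <- prod(Kp1)
  if (S > 1e5) stop("truncated lattice has ", S, " > 1e5 states")
  der <- derive_matrices(model)
  counts <- as.matrix(do.call(expand.grid,
                              c(lapply(Kp1, function(n) 0:(n - 1)),
                                KEEP.OUT.ATTRS = FALSE)))
  # per-event rate over the lattice, clamped at 0 outside the feasible cone
  Rarr <- lapply(seq_len(E), function(a) {
    pmax(as.vector(der$R0[a] + counts %*% der$F[a, ]), 0)
  })
  # target index of n + e_alpha (NA when out of lattice): linear indices
  strides <- c(1, cumprod(Kp1[-E]))
  lin <- as.vector(counts %*% strides) + 1
  shift_idx <- lapply(seq_len(E), function(a) {
    tgt <- lin + strides[a]
    tgt[counts[, a] + 1 >= Kp1[a]] <- NA
    tgt
  })
  rhs <- function(t, P, parms) {
    dP <- numeric(S)
    for (a in seq_len(E)) {
      flux <- P * Rarr[[a]]
      dP <- dP - flux
      tgt <- shift_idx[[a]]
      ok <- !is.na(tgt)
      dP[tgt[ok]] <- dP[tgt[ok]] + flux[ok]
    }
    list(dP)
  }
  P0 <- numeric(S); P0[1] <- 1
  if (t_end == 0) {
    P <- P0
  } else {
    out <- deSolve::ode(y = P0, times = c(0, t_end), func = rhs,
                        parms = NULL, method = "adams",
                        rtol = rtol, atol = atol)
    P <- pmax(out[nrow(out), -1], 0)
  }
  leaked <- 1 - sum(P)
  if (leaked > 1e-4) {
    warning("mass leaked past truncation: ", signif(leaked, 3),
            "; increase `truncation`")
  }
  tb <- tibble::as_tibble(as.data.frame(counts))
  names(tb) <- model$event_names
  tb$probability <- as.vector(P)
  structure(tb, class = c("event_dist", class(tb)),
            truncation = K, mass_captured = sum(P), t = t_end,
            model = model)
}

#' Fixed-step multinomial simulation
#'
#' The consistent short-time simulation scheme: per step of length `h`
#' and per population `k`, each of the `X_k` individuals independently
#' draws `no event' or a first event `beta` (one multinomial with `X_k`
#' trials over `Pbar_k(h, I, beta)`); at order 2 each first event then
#' draws a second event from the conditional probabilities
#' `P_k(h, alpha | beta)` (no-second-event takes the remaining mass).
#' Populations are updated at step end.  Per-individual factors multiply
#' into the cohort generating function, which is what guarantees the
#' scheme never produces negative populations for valid models.
#'
#' @param model a validated [linear_model()].
#' @param t_end horizon; the last step is shortened to land on it.
#' @param h step size (must keep all step probabilities nonnegative).
#' @param order 1 or 2.
#' @param seed optional integer seed.
#' @param record `"steps"` (default) records every step; `"end"` records
#'   only the initial and final states (faster for ensembles).
#' @return A `trajectory_sample` tibble (columns `time`, event counts,
#'   populations).
#' @export
multinomial_step_simulate <- function(model, t_end, h, order = 2,
                                      seed = NULL, record = c("steps", "end")) {
  stopifnot(order %in% c(1, 2), h > 0, t_end >= 0)
  record <- match.arg(record)
  N <- model$n_pops; E <- model$n_events
  delta <- model$incidence
  r <- model$rate_coeffs
  steps_t <- seq(h, t_end, by = h)
  if (length(steps_t) == 0 || steps_t[length(steps_t)] < t_end) {
    steps_t <- c(steps_t, t_end)
  }
  # per-population step probabilities for the regular step size; a
  # shortened final step gets its own set
  step_probs <- function(hh) {
    lapply(seq_len(N), function(k) {
      if (order == 2) {
        sp <- second_order_step(model, k, hh)
        ncond <- 1 - rowSums(sp$p_cond)
        if (any(ncond < 0)) {
          if (min(ncond) < -1e-6) {
            message("conditional no-second-event mass renormalised by ",
                    signif(-min(ncond), 3))
          }
          sp$p_cond <- sp$p_cond / rowSums(sp$p_cond)
          ncond <- pmax(ncond, 0)
        }
        # p_none + sum(p_one_bar) = 1 algebraically
        list(first = c(none = sp$p_none, sp$p_one_bar),
             cond = cbind(sp$p_cond, none = ncond))
      } else {
        S <- sum(r[, k])
        if (1 - S * hh < 0) stop("h too large for order-1 step (negative no-event probability)")
        list(first = c(none = 1 - S * hh, r[, k] * hh), cond = NULL)
      }
    })
  }
  run <- function() {
    sp_regular <- step_probs(h)
    X <- model$initial_pops
    n <- numeric(E)
    rec_times <- 0; rec_counts <- list(n); rec_pops <- list(X)
    t_prev <- 0
    for (tt in steps_t) {
      hh <- tt - t_prev
      sp <- if (abs(hh - h) < 1e-12) sp_regular else step_probs(hh)
      dn <- numeric(E)
      for (k in seq_len(N)) {
        Xk <- X[k]
        if (Xk <= 0) next
        pk <- sp[[k]]
        first <- as.vector(rmultinom(1, Xk, pk$first))
        nb <- first[-1]                  # first-event counts per beta
        if (any(nb > 0)) {
          dn <- dn + nb
          if (order == 2) {
            for (b in which(nb > 0)) {
              second <- as.vector(rmultinom(1, nb[b], pk$cond[b, ]))
              dn <- dn + second[-(E + 1)]
            }
          }
        }
      }
      n <- n + dn
      X <- X + as.vector(delta %*% dn)
      if (any(X < -1e-9)) stop("negative population produced; reduce h")
      t_prev <- tt
      if (record == "steps") {
        rec_times <- c(rec_times, tt)
        rec_counts[[length(rec_counts) + 1]] <- n
        rec_pops[[length(rec_pops) + 1]] <- X
      }
    }
    if (record == "end") {
      rec_times <- c(0, t_end)
      rec_counts <- list(numeric(E), n)
      rec_pops <- list(model$initial_pops, X)
    }
    out <- tibble::as_tibble(cbind(
      data.frame(time = rec_times),
      setNames(as.data.frame(do.call(rbind, rec_counts)), model$event_names),
      setNames(as.data.frame(do.call(rbind, rec_pops)), model$pop_names)))
    structure(out, class = c("trajectory_sample", class(out)),
              seed = seed, scheme = paste0("mn", order), h = h, t_end = t_end,
              event_names = model$event_names, pop_names = model$pop_names)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Ensemble of terminal event counts
#'
#' Repeats a simulator and tabulates the empirical event-count
#' distribution at the horizon, with per-event means and standard errors.
#'
#' @param model a validated [linear_model()].
#' @param t_end horizon.
#' @param n_runs number of independent runs.
#' @param scheme `"ssa"`, `"mn1"` or `"mn2"`.
#' @param h step size for the multinomial schemes.
#' @param seed optional integer seed for the whole ensemble.
#' @return A list of class `ensemble_summary`: `distribution` (tibble of
#'   counts + `probability`), `means` (tibble event/mean/se), `n_runs`,
#'   `scheme`.
#' @export
simulate_ensemble <- function(model, t_end, n_runs = 1000,
                              scheme = c("ssa", "mn1", "mn2"), h = NULL,
                              seed = NULL) {
  scheme <- match.arg(scheme)
  E <- model$n_events
  run_one <- function() {
    tr <- if (scheme == "ssa") ssa_simulate(model, t_end)
          else multinomial_step_simulate(model, t_end, h,
                                         order = as.integer(substr(scheme, 3, 3)),
                                         record = "end")
    as.numeric(tr[nrow(tr), 1 + seq_len(E)])
  }
  sim <- function() {
    counts <- matrix(0, n_runs, E)
    for (i in seq_len(n_runs)) counts[i, ] <- run_one()
    counts
  }
  counts <- if (!is.null(seed)) withr::with_seed(seed, sim()) else sim()
  colnames(counts) <- model$event_names
  tb <- tibble::as_tibble(as.data.frame(counts))
  dist <- dplyr::summarise(
    dplyr::group_by(tb, dplyr::across(dplyr::everything())),
    n = dplyr::n(), .groups = "drop")
  dist$probability <- dist$n / n_runs
  dist$n <- NULL
  means <- tibble::tibble(
    event = model$event_names,
    mean = colMeans(counts),
    se = apply(counts, 2, stats::sd) / sqrt(n_runs))
  structure(list(distribution = dist, means = means, n_runs = n_runs,
                 scheme = scheme, t_end = t_end),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary>", x$n_runs, "runs, scheme", x$scheme,
      ", t_end", x$t_end, "\n")
  print(x$means)
  invisible(x)
}

#' Compare an empirical ensemble with an exact distribution
#'
#' Total-variation distance between the empirical terminal event-count
#' distribution and an exact `event_dist`, with per-cell z-scores
#' (binomial standard errors).  Cells are flagged when they deviate
#' beyond the `flag_sigma`-sigma level: by z-score when the expected
#' cell count `n p` is at least 5, and by the equivalent two-sided
#' Poisson tail test for rarer cells (where the normal approximation
#' would misfire).
#'
#' @param ensemble a [simulate_ensemble()] result.
#' @param exact an `event_dist` at the same horizon.
#' @param flag_sigma flag threshold in standard errors (default 4).
#' @return A list of class `ensemble_comparison`: `tv`, `cells` (tibble
#'   with counts, `p_exact`, `p_emp`, `z`, `flagged`), `n_flagged`.
#' @export
compare_to_exact <- function(ensemble, exact, flag_sigma = 4) {
  ev <- setdiff(names(exact), "probability")
  emp <- ensemble$distribution
  joined <- dplyr::full_join(
    dplyr::rename(exact, p_exact = "probability"),
    dplyr::rename(emp, p_emp = "probability"), by = ev)
  joined$p_exact[is.na(joined$p_exact)] <- 0
  joined$p_emp[is.na(joined$p_emp)] <- 0
  n <- ensemble$n_runs
  se <- sqrt(pmax(joined$p_exact * (1 - joined$p_exact), 1e-300) / n)
  joined$z <- (joined$p_emp - joined$p_exact) / se
  lam <- n * joined$p_exact
  obs <- round(n * joined$p_emp)
  tail_p <- stats::pnorm(-flag_sigma)    # one-sided mass at flag_sigma
  flagged <- ifelse(
    lam >= 5,
    abs(joined$z) > flag_sigma,
    stats::ppois(obs - 1, lam, lower.tail = FALSE) < tail_p |
      stats::ppois(obs, lam) < tail_p)
  joined$flagged <- flagged
  tv <- sum(abs(joined$p_emp - joined$p_exact)) / 2
  structure(list(tv = tv, cells = tibble::as_tibble(joined),
                 n_flagged = sum(flagged)),
            class = "ensemble_comparison")
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat("<ensemble_comparison> TV =", signif(x$tv, 4),
      ";", x$n_flagged, "cell(s) flagged\n")
  invisible(x)
}
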