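# Closed-form generating functions: pure death, linear birth-death, and
# developmental cascades with and without per-stage mortality, plus the
# stage-occupancy formulas used in the drug-delivery example.
#
# The partial-fraction (distinct-rate) forms blow up as rates collide;
# evaluation is routed to the equal-rate forms on exact ties and refused
# (with a pointer to the ODE recursion route) on near ties.  Stage
# indexing is 0-based in the field's notation; vectors here are 1-based
# R vectors with element i holding stage i-1.

degeneracy_gap <- 1e-6

check_distinct <- function(x, what) {
  if (length(x) < 2) return(invisible(TRUE))
  s <- sort(x)
  gaps <- diff(s) / pmax(abs(s[-1]), 1e-300)
  if (any(gaps <= degeneracy_gap)) {
    stop("near-degenerate ", what,
         " (relative gap <= 1e-6): use the equal-rate form for exact ties ",
         "or `cascade_W0_ode()` for near ties", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pure-death generating function
#'
#' `Psi(z, t) = (exp(-r t) + z (1 - exp(-r t)))^M`: the death count of a
#' cohort of `M` independent individuals is binomial with per-individual
#' death probability `1 - exp(-r t)`.
#'
#' @param M cohort size (nonnegative integer).
#' @param r per-capita death rate (1/time).
#' @param t elapsed time.
#' @param z transform argument (complex scalar or vector).
#' @return Complex value(s) of `Psi`.
#' @examples
#' pure_death_psi(2, 1, log(2), 0)  # P(no deaths) = 1/4
#' @export
pure_death_psi <- function(M, r, t, z) {
  stopifnot(M >= 0, M == round(M), r >= 0, t >= 0)
  (exp(-r * t) + z * (1 - exp(-r * t)))^M
}

#' Birth-death generating function in population space
#'
#' For per-capita birth rate `r1` and death rate `r2`,
#' `Psi_pop(y, t) = (((r2 - r1 y) W - r2 (1 - y)) / ((r2 - r1 y) W - r1 (1 - y)))^X0`
#' with `W = exp((r2 - r1) t)`.  The equal-rate case is the analytic
#' limit `((y + r t (1 - y)) / (1 + r t (1 - y)))^X0`, used for exact and
#' near ties (relative gap below 1e-9, where the generic form loses
#' precision to cancellation).
#'
#' @param X0 initial population (positive integer).
#' @param r1,r2 birth and death rates (1/time).
#' @param t elapsed time.
#' @param y population transform argument (complex scalar or vector).
#' @return Complex value(s) of the population generating function.
#' @export
birth_death_psi <- function(X0, r1, r2, t, y) {
  stopifnot(X0 >= 1, r1 >= 0, r2 >= 0, t >= 0)
  gap <- abs(r2 - r1) / max(r1, r2, 1e-300)
  if (gap < 1e-9) {
    r <- (r1 + r2) / 2
    return(((y + r * t * (1 - y)) / (1 + r * t * (1 - y)))^X0)
  }
  W <- exp((r2 - r1) * t)
  (((r2 - r1 * y) * W - r2 * (1 - y)) /
     ((r2 - r1 * y) * W - r1 * (1 - y)))^X0
}

#' Cascade generating factor, distinct maturation rates
#'
#' The per-individual generating factor `W0(z, t)` of a mortality-free
#' developmental cascade with pairwise-distinct stage rates, evaluated
#' from its partial-fraction form: the all-stages-completed term carries
#' the hypoexponential CDF, the partial-progress terms carry the
#' per-stage phase probabilities.  The cohort generating function is
#' `W0^M`.
#'
#' @param spec a [cascade_spec()] without mortality (or a rate vector).
#' @param t elapsed time.
#' @param z complex vector, one argument per maturation event.
#' @return Complex scalar `W0`.
#' @seealso [cascade_W0_equal()] for equal rates, [cascade_W0_ode()] for
#'   the recursion route used on near-degenerate rates.
#' @export
cascade_W0_distinct <- function(spec, t, z) {
  rr <- if (inherits(spec, "cascade_spec")) {
    if (!is.null(spec$death_rates)) stop("use cascade_mortality_W0_distinct for cascades with mortality")
    spec$maturation_rates
  } else spec
  E <- length(rr)
  stopifnot(length(z) == E, t >= 0)
  check_distinct(rr, "maturation rates")
  term1 <- prod(z) * (1 - sum(vapply(seq_len(E), function(k) {
    exp(-rr[k] * t) * prod(rr[-k] / (rr[-k] - rr[k]))
  }, numeric(1))))
  term2 <- 0
  for (k in seq_len(E)) {
    i <- E - k + 1                       # stage E-k, 1-based
    pref <- prod(z[seq_len(i)]) / (z[i] * rr[i])
    inner <- sum(vapply(seq_len(i), function(m) {
      l <- setdiff(seq_len(i), m)
      rr[m] * exp(-rr[m] * t) * prod(rr[l] / (rr[l] - rr[m]))
    }, numeric(1)))
    term2 <- term2 + pref * inner
  }
  term1 + term2
}

#' Cascade generating factor, equal maturation rates
#'
#' Equal-rate (Erlang) form of [cascade_W0_distinct()]: the completed
#' term carries the regularized lower incomplete gamma `P(E, r t)`
#' (Erlang CDF) and the stage-`j` terms carry Poisson weights
#' `dpois(j, r t)`.
#'
#' @param E number of stages.
#' @param r common maturation rate (1/time).
#' @param t elapsed time.
#' @param z complex vector of length `E`.
#' @return Complex scalar `W0`.
#' @export
cascade_W0_equal <- function(E, r, t, z) {
  stopifnot(E >= 1, r >= 0, t >= 0, length(z) == E)
  term1 <- prod(z) * pgamma(r * t, E)
  term2 <- sum(vapply(seq_len(E), function(k) {
    j <- E - k                           # completed stages
    pref <- if (j >= 1) prod(z[seq_len(j)]) else 1 + 0i
    pref * dpois(j, r * t)
  }, complex(1)))
  term1 + term2
}

#' Mortality-cascade generating factor, distinct stage exit rates
#'
#' Per-individual generating factor `W0(z, y, t)` for a cascade where
#' maturation (argument `y`, rate `r`) competes with death (argument `z`,
#' rate `q`) at every stage, evaluated from its partial-fraction form.
#' Requires the stage exit rates `q + r` to be pairwise distinct; the
#' bracketed stage factors are `r[E-k] y[E-k]` and `q[E-k] z[E-k]`, a
#' reading verified against the integral recursion (see the unit tests
#' and [cascade_W0_ode()]).
#'
#' @param spec a [cascade_spec()] with mortality, or a list with
#'   `maturation_rates` and `death_rates`.
#' @param t elapsed time.
#' @param z,y complex vectors of length `E` (death and maturation
#'   arguments).
#' @return Complex scalar `W0`; the cohort generating function is `W0^M`.
#' @export
cascade_mortality_W0_distinct <- function(spec, t, z, y) {
  rr <- spec$maturation_rates; qq <- spec$death_rates
  if (is.null(qq)) stop("`spec` has no death rates")
  E <- length(rr)
  stopifnot(length(z) == E, length(y) == E, t >= 0)
  R <- qq + rr
  check_distinct(R, "stage exit rates (q + r)")
  t1 <- prod(rr * y / R) - sum(vapply(seq_len(E), function(m) {
    k <- setdiff(seq_len(E), m)
    rr[m] * y[m] * exp(-R[m] * t) / R[m] * prod(rr[k] * y[k] / (R[k] - R[m]))
  }, complex(1)))
  t2 <- 0
  for (k in seq_len(E)) {
    i <- E - k + 1                       # stage E-k, 1-based
    qz <- qq[i] * z[i]; ry <- rr[i] * y[i]
    idx <- seq_len(i)
    a <- prod(rr[idx] * y[idx] / R[idx]) * qz
    b <- sum(vapply(idx, function(m) {
      j <- setdiff(idx, m)
      (1 - qz / R[m]) * rr[m] * y[m] * exp(-R[m] * t) *
        prod(rr[j] * y[j] / (R[j] - R[m]))
    }, complex(1)))
    t2 <- t2 + (a + b) / ry
  }
  t1 + t2
}

#' Mortality-cascade generating factor, equal rates
#'
#' All stages share maturation rate `r` and death rate `q`.  The gamma
#' integrals `int_0^t exp(-(q+r) x) x^k dx` are evaluated via the
#' regularized incomplete gamma function.
#'
#' @param E number of stages.
#' @param r,q common maturation and death rates (1/time).
#' @param t elapsed time.
#' @param z,y complex vectors of length `E`.
#' @return Complex scalar `W0`.
#' @export
cascade_mortality_W0_equal <- function(E, r, q, t, z, y) {
  stopifnot(E >= 1, r >= 0, q >= 0, t >= 0, length(z) == E, length(y) == E)
  R <- q + r
  intk <- function(k) {                  # int_0^t e^{-R x} x^k dx
    if (R == 0) return(t^(k + 1) / (k + 1))
    gamma(k + 1) / R^(k + 1) * pgamma(R * t, k + 1)
  }
  t1 <- prod(r * y) / factorial(E - 1) * intk(E - 1)
  t2 <- sum(vapply(0:(E - 1), function(k) {
    pref <- prod((r * y)[seq_len(k + 1)]) / ((r * y[k + 1]) * factorial(k))
    pref * (t^k * exp(-R * t) + q * z[k + 1] * intk(k))
  }, complex(1)))
  t1 + t2
}

#' Cascade generating factor by direct integration of the recursion
#'
#' Integrates the linear ODE system for the stage factors
#' (`dW_j/dt = -(q_j + r_j) W_j + q_j z_j + r_j y_j W_{j+1}`, `W_E = 1`,
#' `W(0) = 1`; mortality-free cascades have `q = 0` terms absent).  Valid
#' for any rates, including degenerate ones; serves as the reference for
#' the partial-fraction forms.
#'
#' @param spec a [cascade_spec()] (with or without mortality).
#' @param t elapsed time.
#' @param z complex vector of length `E` (maturation arguments for
#'   mortality-free cascades, death arguments otherwise).
#' @param y complex vector of maturation arguments (mortality only).
#' @return Complex scalar `W0`.
#' @export
cascade_W0_ode <- function(spec, t, z, y = NULL) {
  rr <- spec$maturation_rates
  qq <- spec$death_rates
  E <- length(rr)
  if (t == 0) return(1 + 0i)
  if (is.null(qq)) {
    zz <- as.complex(z)
    rhs <- function(tt, W, p) {
      Wnext <- c(W[-1], 1 + 0i)
      list(-rr * W + rr * zz * Wnext)
    }
  } else {
    stopifnot(!is.null(y))
    zz <- as.complex(z); yy <- as.complex(y)
    rhs <- function(tt, W, p) {
      Wnext <- c(W[-1], 1 + 0i)
      list(-(qq + rr) * W + qq * zz + rr * yy * Wnext)
    }
  }
  out <- deSolve::zvode(y = rep(1 + 0i, E), times = c(0, t), func = rhs,
                        parms = NULL, rtol = 1e-11, atol = 1e-13, mf = 10, maxsteps = 1e5)
  out[nrow(out), 2]
}

#' Cascade generating factor with automatic routing
#'
#' Dispatches to the equal-rate closed form on exact rate ties, the
#' partial-fraction form on well-separated rates, and the ODE recursion
#' on near ties.
#'
#' @inheritParams cascade_W0_ode
#' @return Complex scalar `W0`.
#' @export
cascade_W0 <- function(spec, t, z, y = NULL) {
  rr <- spec$maturation_rates
  qq <- spec$death_rates
  E <- length(rr)
  if (is.null(qq)) {
    if (E == 1 || all(rr == rr[1])) return(cascade_W0_equal(E, rr[1], t, z))
    ok <- tryCatch({ check_distinct(rr, "rates"); TRUE },
                   error = function(e) FALSE)
    if (ok) cascade_W0_distinct(rr, t, z) else cascade_W0_ode(spec, t, z)
  } else {
    if (E == 1 || (all(rr == rr[1]) && all(qq == qq[1]))) {
      return(cascade_mortality_W0_equal(E, rr[1], qq[1], t, z, y))
    }
    ok <- tryCatch({ check_distinct(qq + rr, "rates"); TRUE },
                   error = function(e) FALSE)
    if (ok) cascade_mortality_W0_distinct(spec, t, z, y)
    else cascade_W0_ode(spec, t, z, y)
  }
}

#' Stage-occupancy probabilities (drug-delivery cascade)
#'
#' For a four-stage cascade with stage passage rates `lambda` and
#' dissolution (death) rates `mu`, the probability that a particle
#' ingested at `t = 0` is still undissolved in stage `i` at time `t`:
#' `p_0(t) = exp(-t R_0)` and, for `i = 1..3`,
#' `p_i(t) = P(i-1) * sum_{m=0}^{i} exp(-t R_m) / Q(i, m)` with
#' `P(s) = prod_{m<=s} lambda_m`,
#' `Q(s, m) = prod_{k != m, k <= s} (lambda_k - lambda_m + mu_k - mu_m)`,
#' `R_m = lambda_m + mu_m`.  Stage exit rates must be pairwise distinct.
#'
#' @param lambda,mu length-4 vectors of passage and dissolution rates
#'   (1/time), stages 0..3.
#' @param t time point(s).
#' @return A tibble with columns `t`, `stage` (0..3), `probability`.
#' @export
stage_occupancy <- function(lambda, mu, t) {
  stopifnot(length(lambda) == 4, length(mu) == 4)
  R <- lambda + mu
  check_distinct(R, "stage exit rates (lambda + mu)")
  P <- function(s) prod(lambda[seq_len(s + 1)])
  Q <- function(s, m) {
    k <- setdiff(0:s, m)
    prod(lambda[k + 1] - lambda[m + 1] + mu[k + 1] - mu[m + 1])
  }
  purrr::map_dfr(t, function(tt) {
    p <- numeric(4)
    p[1] <- exp(-tt * R[1])
    for (i in 1:3) {
      p[i + 1] <- P(i - 1) * sum(vapply(0:i, function(m) {
        exp(-tt * R[m + 1]) / Q(i, m)
      }, numeric(1)))
    }
    tibble::tibble(t = tt, stage = 0:3, probability = p)
  })
}

#' Exit-time distribution of a cascade
#'
#' Probability that a single individual has completed all `E` stages by
#' time `t`.  Equal rates give the Erlang CDF `P(E, r t)`; distinct rates
#' give the hypoexponential CDF; with mortality the distribution is
#' defective, with total mass `prod r / (q + r)` as `t -> Inf`, each
#' factor the per-stage competing-risk probability of maturing before
#' dying.
#'
#' @param spec a [cascade_spec()].
#' @return A function of `t` (vectorized) returning probabilities.
#' @examples
#' cdf <- exit_time_cdf(cascade_spec(rep(1, 3)))
#' cdf(3)  # Erlang(3, 1) CDF at t = 3
#' @export
exit_time_cdf <- function(spec) {
  rr <- spec$maturation_rates
  qq <- spec$death_rates
  E <- length(rr)
  if (is.null(qq)) {
    if (E == 1 || all(rr == rr[1])) {
      r <- rr[1]
      return(function(t) pgamma(r * t, E))
    }
    check_distinct(rr, "maturation rates")
    return(function(t) {
      vapply(t, function(tt) {
        1 - sum(vapply(seq_len(E), function(k) {
          exp(-rr[k] * tt) * prod(rr[-k] / (rr[-k] - rr[k]))
        }, numeric(1)))
      }, numeric(1))
    })
  }
  R <- qq + rr
  thin <- prod(rr / R)
  if (E == 1 || (all(rr == rr[1]) && all(qq == qq[1]))) {
    return(function(t) thin * pgamma(R[1] * t, E))
  }
  check_distinct(R, "stage exit rates (q + r)")
  function(t) {
    vapply(t, function(tt) {
      Re(prod(rr / R) - sum(vapply(seq_len(E), function(m) {
        k <- setdiff(seq_len(E), m)
        rr[m] * exp(-R[m] * tt) / R[m] * prod(rr[k] / (R[k] - R[m]))
      }, numeric(1))))
    }, numeric(1))
  }
}
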