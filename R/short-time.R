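# Short-time approximation schemes: the Poisson approximation (events as
# independent Poisson counts at their initial rates) and the order-n
# multinomial schemes built from truncated Picard iterations of the
# population-coordinate characteristic ODE.

#' Poisson approximation of the generating function
#'
#' `Psi(z, t) ~ exp(t * sum_beta R0[beta] (z_beta - 1))`: each event
#' count is an independent Poisson variable with its initial rate frozen.
#' One-step error is `o(t)` (total-variation error of one step decays
#' quadratically in the step size); structural zeroes are respected, but
#' positive invariance of populations is not.
#'
#' @param model a validated [linear_model()].
#' @param t elapsed time.
#' @param z complex vector of length `E` (or scalar, recycled).
#' @return Complex scalar.
#' @export
poisson_psi <- function(model, t, z) {
  z <- as.complex(z)
  if (length(z) == 1) z <- rep(z, model$n_events)
  R0 <- as.vector(model$rate_coeffs %*% model$initial_pops)
  exp(t * sum(R0 * (z - 1)))
}

#' Truncated Picard iterate of the per-individual generating factor
#'
#' Builds the order-`n` Picard iterate `w_k^{(n)}(z, t)` of the
#' population-coordinate characteristic ODE, with the Maclaurin
#' truncation of order `n - 1` in time applied inside the integral at
#' step `n`.  The result is, exactly, a polynomial of degree `n` in `z`
#' whose coefficient of total `z`-degree `p` has leading time order
#' `t^p`, evaluates to 1 at `z = 1`, and has nonnegative coefficients for
#' small `t` -- a genuine one-individual generating function, which is
#' what makes the multinomial simulation scheme consistent.
#'
#' @param model a validated [linear_model()] (constant rates).
#' @param order iteration order `n >= 0`; orders above 6 are refused
#'   (combinatorial growth).
#' @param k optional population index: return only `w_k`.
#' @return A list of `tpoly` objects (one per population), or a single
#'   `tpoly` when `k` is given.
#' @examples
#' pd <- fixture_pure_death(M = 1, rate = 1)
#' picard_iterate(pd, order = 2, k = 1)
#' @export
picard_iterate <- function(model, order, k = NULL) {
  stopifnot(order >= 0)
  if (order > 6) stop("orders above 6 are not supported (combinatorial blow-up)")
  N <- model$n_pops; E <- model$n_events
  tcap <- max(order, 1)
  delta <- model$incidence
  r <- model$rate_coeffs
  w <- replicate(N, tp_const(E, tcap), simplify = FALSE)
  if (order >= 1) {
    for (it in seq_len(order)) {
      m <- it - 1                        # truncation order inside integral
      wnew <- vector("list", N)
      # event factors z_beta * prod_j w_j^{delta[j, beta]} shared across k
      ev <- vector("list", E)
      for (b in seq_len(E)) {
        p <- tp_const(E, tcap)
        for (j in seq_len(N)) {
          d <- delta[j, b]
          if (d != 0) p <- tp_mul(p, tp_pow_int(w[[j]], d))
        }
        zmono <- tp_zero(E, tcap)
        e <- integer(E); e[b] <- 1L
        co <- numeric(tcap + 1); co[1] <- 1
        zmono$terms[[tp_key(e)]] <- co
        ev[[b]] <- tp_mul(zmono, p)      # z_beta * prod w^delta
      }
      one <- tp_const(E, tcap)
      for (kk in seq_len(N)) {
        acc <- tp_zero(E, tcap)
        for (b in seq_len(E)) {
          if (r[b, kk] == 0) next
          term <- tp_add(ev[[b]], tp_scale(one, -1))
          acc <- tp_add(acc, tp_scale(term, r[b, kk]))
        }
        integrand <- tp_trunc_t(tp_mul(w[[kk]], acc), m)
        wnew[[kk]] <- tp_add(one, tp_integrate_t(integrand))
      }
      w <- wnew
    }
  }
  names(w) <- model$pop_names
  if (!is.null(k)) w[[k]] else w
}

# approximate psi from Picard iterates: prod_k w_k^{X_k(0)} at (z, t)
picard_psi <- function(model, w_list, z, t) {
  X0 <- model$initial_pops
  psi <- 1 + 0i
  for (k in seq_along(w_list)) {
    if (X0[k] > 0) psi <- psi * tp_eval(w_list[[k]], z, t)^X0[k]
  }
  psi
}

#' One-step event probabilities of the order-2 multinomial scheme
#'
#' For one individual of population `k` over a step of length `h`, the
#' second-order per-individual generating factor assigns:
#' no event `P(h, 0) = 1 - h S + h^2/2 S^2` with `S = sum_beta r[beta, k]`;
#' exactly one `beta` event
#' `P(h, I, beta) = r[beta, k] (h - h^2 S - h^2/2 sum_alpha F[alpha, beta])`;
#' a `beta` event followed by an `alpha` event
#' `P(h, II, beta, alpha) = h^2/2 r[beta, k] (r[alpha, k] + F[alpha, beta])`.
#' These sum to one algebraically.  The simulation decomposition uses
#' `Pbar(h, I, beta) = r[beta, k] (h - h^2/2 S)` (a first event, possibly
#' followed by a second) and the conditional second-event probabilities
#' `P(alpha | beta) = (h/2)(r[alpha, k] + F[alpha, beta]) / (1 - (h/2) S)`.
#'
#' @param model a validated [linear_model()].
#' @param k population index.
#' @param h step size; must keep all probabilities nonnegative (see the
#'   returned `h_max`).
#' @return A list of class `step_probabilities`: `p_none`, `p_one` (E),
#'   `p_two` (E x E, first event in rows), `p_one_bar`, `p_cond`, `h`,
#'   `k`, `h_max`.
#' @examples
#' pd <- fixture_pure_death(M = 1, rate = 1)
#' second_order_step(pd, 1, h = 0.01)$p_two  # 0: no double deaths
#' @export
second_order_step <- function(model, k, h) {
  stopifnot(h > 0)
  E <- model$n_events
  r <- model$rate_coeffs[, k]
  Fm <- model$rate_coeffs %*% model$incidence   # F[alpha, beta]
  S <- sum(r)
  colF <- colSums(Fm)                           # sum_alpha F[alpha, beta]
  probs_at <- function(hh) {
    p_none <- 1 - hh * S + hh^2 / 2 * S^2
    p_one <- r * (hh - hh^2 * S - hh^2 / 2 * colF)
    p_two <- (hh^2 / 2) * outer(r, rep(1, E)) *
      (outer(rep(1, E), r) + t(Fm))             # [beta, alpha]
    list(p_none = p_none, p_one = p_one, p_two = p_two)
  }
  h_max <- step_h_max(probs_at, S)
  p <- probs_at(h)
  if (min(p$p_none, p$p_one, p$p_two) < 0) {
    stop("step size h = ", h, " gives negative probabilities; ",
         "maximum admissible h is ", signif(h_max, 6))
  }
  p_one_bar <- r * (h - h^2 / 2 * S)
  p_cond <- (h / 2) * (outer(rep(1, E), r) + t(Fm)) / (1 - (h / 2) * S)
  dimnames(p_cond) <- dimnames(p$p_two) <-
    list(first = model$event_names, second = model$event_names)
  structure(list(p_none = p$p_none,
                 p_one = setNames(p$p_one, model$event_names),
                 p_two = p$p_two,
                 p_one_bar = setNames(p_one_bar, model$event_names),
                 p_cond = p_cond,
                 h = h, k = k, h_max = h_max),
            class = "step_probabilities")
}

# largest h keeping all second-order step probabilities nonnegative;
# bisection on the minimum entry (decreasing in h near 0)
step_h_max <- function(probs_at, S) {
  if (S == 0) return(Inf)
  minp <- function(hh) { p <- probs_at(hh); min(p$p_none, p$p_one, p$p_two) }
  hi <- 1 / S
  if (minp(hi) >= 0) {
    while (minp(hi * 2) >= 0 && hi < 1e6 / S) hi <- hi * 2
    if (hi >= 1e6 / S) return(Inf)
  }
  lo <- 0
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (minp(mid) >= 0) lo <- mid else hi <- mid
  }
  lo
}

#' @export
print.step_probabilities <- function(x, ...) {
  cat("<step_probabilities> population", x$k, " h =", x$h,
      " (h_max =", signif(x$h_max, 4), ")\n")
  cat("P(no event) =", x$p_none, "\n")
  cat("P(one event):", signif(x$p_one, 6), "\n")
  cat("total two-event probability:", signif(sum(x$p_two), 6), "\n")
  invisible(x)
}

# --- approximate one-step distributions --------------------------------

# event-count distribution of an approximation scheme over one step,
# by transform inversion of the scheme's generating function
approx_event_distribution <- function(model, t, scheme = c("poisson", "mn1", "mn2"),
                                      truncation) {
  scheme <- match.arg(scheme)
  K <- truncation
  if (length(K) == 1) K <- rep(K, model$n_events)
  psi_fun <- switch(scheme,
    poisson = function(Z) apply(Z, 1, function(z) poisson_psi(model, t, z)),
    mn1 = {
      w <- picard_iterate(model, 1)
      function(Z) apply(Z, 1, function(z) picard_psi(model, w, z, t))
    },
    mn2 = {
      w <- picard_iterate(model, 2)
      function(Z) apply(Z, 1, function(z) picard_psi(model, w, z, t))
    })
  invert_psi_grid(model, t, K, psi_fun = psi_fun)
}

#' Empirical order of accuracy of a one-step scheme
#'
#' Measures the total-variation distance between a scheme's one-step
#' event-count distribution and the exact distribution over a list of
#' step sizes, and fits the log-log slope.  Expected slopes: Poisson 2,
#' order-1 multinomial 2, order-2 multinomial 3 (one-step error one order
#' above the global error).
#'
#' @param model a validated [linear_model()].
#' @param scheme `"poisson"`, `"mn1"` or `"mn2"`.
#' @param h_list geometric sequence of step sizes; the default spans
#'   2^-6..2^-11, small enough that the leading error term dominates
#'   (larger steps visibly mix in the next order and bias the slope
#'   low).
#' @param truncation count bound for the comparison lattice (scalar or
#'   per-event).
#' @return A list of class `order_test`: `slope`, `table` (tibble with
#'   `h`, `tv_error`), `scheme`.
#' @export
order_of_accuracy <- function(model, scheme = c("poisson", "mn1", "mn2"),
                              h_list = 2^-(6:11), truncation = 8) {
  scheme <- match.arg(scheme)
  tv <- vapply(h_list, function(h) {
    # reference solved extra tight: the smallest mn2 errors (~1e-10)
    # must stay above the reference noise floor
    exact <- event_count_distribution(model, h, truncation = truncation,
                                      rtol = 1e-12, atol = 1e-14)
    appr <- approx_event_distribution(model, h, scheme, truncation)
    sum(abs(exact$probability - appr$probability)) / 2
  }, numeric(1))
  keep <- tv > 1e-14                    # below this, roundoff dominates
  slope <- if (sum(keep) >= 2) {
    unname(coef(lm(log(tv[keep]) ~ log(h_list[keep])))[2])
  } else NA_real_
  structure(list(slope = slope,
                 table = tibble::tibble(h = h_list, tv_error = tv),
                 scheme = scheme),
            class = "order_test")
}

#' @export
print.order_test <- function(x, ...) {
  cat("<order_test> scheme:", x$scheme, " slope:", signif(x$slope, 4), "\n")
  print(x$table)
  invisible(x)
}
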