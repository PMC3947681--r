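# Characteristic-ODE solutions of the event-space generating function.
#
# The generating function Psi(z, t) = sum_n P(n, t) prod z^n of the
# event-count distribution satisfies a first-order linear PDE whose
# characteristics are a small autonomous ODE system.  Two equivalent
# routes are implemented:
#   * population coordinates: per-individual factors w_k with
#     Psi = prod_k w_k^{X_k(0)}; structural zeroes are automatically
#     respected.  This is the primary route.
#   * the flow/exponent route: integrate the characteristic flow from the
#     transform point and accumulate exp(int sum R0 (x - 1)); kept as an
#     internal cross-check.
# Constant rate coefficients are assumed throughout, so the time origin
# is taken at 0 without loss of generality.

default_rtol <- 1e-10
default_atol <- 1e-12

# Solve the w-ODE for a whole G x E matrix of transform points in one
# stacked complex ODE call; returns list(W = G x N complex, psi = G).
solve_w_grid <- function(model, Z, t, rtol = default_rtol,
                         atol = default_atol, times = NULL) {
  N <- model$n_pops; E <- model$n_events
  G <- nrow(Z)
  delta <- model$incidence
  r <- model$rate_coeffs
  rs <- colSums(r)                       # sum_beta r_beta^k
  rhs <- function(tt, y, p) {
    W <- matrix(y, G, N)
    P <- matrix(1 + 0i, G, E)
    for (b in seq_len(E)) {
      for (j in seq_len(N)) {
        d <- delta[j, b]
        if (d == 1) P[, b] <- P[, b] * W[, j]
        else if (d == -1) P[, b] <- P[, b] / W[, j]
        else if (d != 0) P[, b] <- P[, b] * W[, j]^d
      }
    }
    dW <- W * ((Z * P) %*% r - matrix(rs, G, N, byrow = TRUE))
    list(as.vector(dW))
  }
  tt <- if (is.null(times)) c(0, t) else times
  if (t == 0) {
    W <- matrix(1 + 0i, G, N)
    return(list(W = W, psi = rep(1 + 0i, G), steps = 0L, times = NULL))
  }
  out <- deSolve::zvode(y = rep(1 + 0i, G * N), times = tt, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol, mf = 10, maxsteps = 1e5)
  W <- matrix(out[nrow(out), -1], G, N)
  psi <- as.vector(W2psi(W, model$initial_pops))
  list(W = W, psi = psi, steps = attr(out, "istate")[15],
       times = if (!is.null(times)) out)
}

W2psi <- function(W, X0) {
  psi <- rep(1 + 0i, nrow(W))
  for (k in seq_along(X0)) if (X0[k] > 0) psi <- psi * W[, k]^X0[k]
  psi
}

check_z <- function(z, E) {
  z <- as.complex(z)
  if (length(z) == 1) z <- rep(z, E)
  if (length(z) != E) stop("`z` must have length ", E)
  if (any(abs(z) > 1.5)) {
    stop("|z| > 1.5: characteristic ODE may blow up; transform arguments should lie on or inside the unit circle")
  }
  z
}

#' Generating-function solution in population coordinates
#'
#' Integrates the per-individual factors
#' `dw_k/dt = w_k * sum_beta r[beta, k] (z_beta * prod_j w_j^delta[j, beta] - 1)`,
#' `w_k(0) = 1`, and assembles `Psi(z, t) = prod_k w_k^{X_k(0)}` together
#' with the event-coordinate factors `f_beta = prod_j w_j^delta[j, beta]`.
#' This route incorporates structural zeroes automatically.
#'
#' @param model a validated [linear_model()] (constant rates).
#' @param z complex vector of length `E` (or scalar, recycled): transform
#'   argument per event; `|z| <= 1.5` required, the unit polydisk is the
#'   meaningful domain.
#' @param t elapsed time, `>= 0`.
#' @param rtol,atol ODE tolerances (defaults 1e-10 / 1e-12, chosen so the
#'   transform-inversion error is dominated by truncation, not
#'   integration).
#' @param check reject `|z| > 1.5`?  Projection points derived from
#'   population arguments may legitimately leave the disk; the wrapper
#'   [population_psi()] disables the guard.
#' @return A `pgf_solution`: list with `w` (length `N` complex), `f`
#'   (length `E`), `psi` (complex scalar), `z`, `t`, `stats`.
#' @examples
#' pd <- fixture_pure_death(M = 2, rate = 1)
#' solve_w(pd, z = 0, t = log(2))$psi  # P(no deaths by t) = 0.25
#' @seealso [solve_f_via_phi1()], [event_count_distribution()]
#' @export
solve_w <- function(model, z, t, rtol = default_rtol, atol = default_atol,
                    check = TRUE) {
  stopifnot(t >= 0)
  z <- if (check) check_z(z, model$n_events) else as.complex(z)
  res <- solve_w_grid(model, matrix(z, 1), t, rtol, atol)
  w <- setNames(as.vector(res$W), model$pop_names)
  f <- vapply(seq_len(model$n_events), function(b) {
    prod(w^model$incidence[, b])
  }, complex(1))
  structure(list(w = w, f = setNames(f, model$event_names),
                 psi = res$psi[1], z = z, t = t,
                 stats = list(steps = res$steps, rtol = rtol, atol = atol,
                              route = "w")),
            class = "pgf_solution")
}

#' @export
print.pgf_solution <- function(x, ...) {
  cat("<pgf_solution> route:", x$stats$route, " t =", x$t, "\n")
  cat("psi =", format(x$psi, digits = 10), "\n")
  invisible(x)
}

#' Generating-function solution via the characteristic flow
#'
#' The variation-of-constants route: integrates the characteristic flow
#' `dx_beta/dtau = (sum_alpha F[alpha, beta] (x_alpha - 1)) x_beta` from
#' `x(0) = z` together with the exponent integral
#' `int_0^t sum_alpha R0[alpha] (x_alpha(tau) - 1) dtau`, and returns
#' `psi = exp(integral)` (natural initial condition, so the homogeneous
#' factor is 1).  Agrees with [solve_w()] on valid models; kept as an
#' independent route for cross-checking.
#'
#' @inheritParams solve_w
#' @return A `pgf_solution` with `psi` and the terminal flow point in `f`
#'   slot `NULL`; `w` is `NULL` for this route.
#' @export
solve_f_via_phi1 <- function(model, z, t, rtol = default_rtol,
                             atol = default_atol) {
  stopifnot(t >= 0)
  z <- check_z(z, model$n_events)
  E <- model$n_events
  der <- derive_matrices(model)
  Fm <- der$F; R0 <- der$R0
  rhs <- function(tt, y, p) {
    x <- y[seq_len(E)]
    dx <- as.vector((x - 1) %*% Fm) * x
    dI <- sum(R0 * (x - 1))
    list(c(dx, dI))
  }
  if (t == 0) {
    psi <- 1 + 0i
    xT <- z
    steps <- 0L
  } else {
    out <- deSolve::zvode(y = c(z, 0 + 0i), times = c(0, t), func = rhs,
                          parms = NULL, rtol = rtol, atol = atol, mf = 10, maxsteps = 1e5)
    xT <- out[nrow(out), 1 + seq_len(E)]
    psi <- exp(out[nrow(out), E + 2])
    steps <- attr(out, "istate")[15]
  }
  structure(list(w = NULL, f = NULL, psi = psi, z = z, t = t,
                 flow_endpoint = setNames(xT, model$event_names),
                 stats = list(steps = steps, rtol = rtol, atol = atol,
                              route = "phi1")),
            class = "pgf_solution")
}

# Flow/exponent route evaluated on a whole grid of transform points in
# one stacked complex ODE call (one flow + one exponent per point).
phi1_psi_grid <- function(model, Z, t, rtol = default_rtol,
                          atol = default_atol) {
  E <- model$n_events
  G <- nrow(Z)
  der <- derive_matrices(model)
  Fm <- der$F; R0 <- der$R0
  if (t == 0) return(rep(1 + 0i, G))
  rhs <- function(tt, y, p) {
    X <- matrix(y[seq_len(G * E)], G, E)
    dX <- ((X - 1) %*% Fm) * X
    dI <- (X - 1) %*% R0
    list(c(as.vector(dX), as.vector(dI)))
  }
  out <- deSolve::zvode(y = c(as.vector(Z), rep(0 + 0i, G)),
                        times = c(0, t), func = rhs, parms = NULL,
                        rtol = rtol, atol = atol, mf = 10, maxsteps = 1e5)
  exp(out[nrow(out), 1 + G * E + seq_len(G)])
}

# Default per-event truncation bound: mean + spread guard, then doubled
# by the caller until the captured mass is close enough to 1.
default_truncation <- function(model, t) {
  mu <- tryCatch(moments(model, t, order = 1)$mean,
                 error = function(e) rep(1, model$n_events))
  pmax(ceiling(mu + 8 * sqrt(mu + 1) + 4), 3)
}

#' Event-count distribution by transform inversion
#'
#' Evaluates `Psi` on the tensor grid of roots of unity
#' `z_alpha = exp(2 pi i k / (K_alpha + 1))` (one stacked ODE solve) and
#' applies the inverse discrete Fourier transform, yielding the exact
#' probabilities `P(n_1, ..., n_E, t)` up to lattice truncation (counts
#' beyond `K_alpha` alias back; the captured-mass attribute reports the
#' truncation quality).
#'
#' @param model a validated [linear_model()].
#' @param t elapsed time.
#' @param truncation per-event count bound `K` (scalar or length `E`);
#'   `NULL` chooses bounds from the mean counts and doubles them until the
#'   tail mass is below `tail_tol`.
#' @param tail_tol acceptable unaccounted tail mass (default 1e-6); a
#'   larger tail triggers a warning, not an error.
#' @param rtol,atol ODE tolerances.
#' @return A tibble of class `event_dist` with one count column per event
#'   and a `probability` column, plus attributes `truncation`,
#'   `mass_captured`, `t`, and `model`.
#' @examples
#' pd <- fixture_pure_death(M = 2, rate = 1)
#' event_count_distribution(pd, t = log(2), truncation = 2)
#' @export
event_count_distribution <- function(model, t, truncation = NULL,
                                     tail_tol = 1e-6,
                                     rtol = default_rtol,
                                     atol = default_atol) {
  E <- model$n_events
  auto <- is.null(truncation)
  K <- if (auto) default_truncation(model, t) else truncation
  if (length(K) == 1) K <- rep(K, E)
  stopifnot(length(K) == E, all(K >= 0))
  repeat {
    if (prod(K + 1) > 1e6) stop("truncation lattice exceeds 10^6 points")
    dist <- invert_psi_grid(model, t, K, rtol, atol)
    tail <- 1 - attr(dist, "mass_captured")
    if (!auto || tail <= tail_tol) break
    K <- K * 2 + 1
  }
  if (1 - attr(dist, "mass_captured") > tail_tol) {
    warning("tail mass ", signif(1 - attr(dist, "mass_captured"), 3),
            " exceeds tail_tol; increase `truncation`")
  }
  dist
}

invert_psi_grid <- function(model, t, K, rtol = default_rtol,
                            atol = default_atol, psi_fun = NULL) {
  E <- model$n_events
  Kp1 <- K + 1
  roots <- lapply(Kp1, function(n) exp(2i * pi * (seq_len(n) - 1) / n))
  grid <- as.matrix(expand.grid(roots, KEEP.OUT.ATTRS = FALSE))
  psi <- if (is.null(psi_fun)) solve_w_grid(model, grid, t, rtol, atol)$psi
         else psi_fun(grid)
  arr <- array(psi, dim = Kp1)
  probs <- Re(fft(arr)) / prod(Kp1)
  neg <- probs < 0
  if (any(probs < -1e-8)) {
    warning("negative probabilities down to ", signif(min(probs), 3),
            " clipped to zero (truncation/roundoff)")
  }
  probs[neg] <- 0
  counts <- do.call(expand.grid, c(lapply(Kp1, function(n) 0:(n - 1)),
                                   KEEP.OUT.ATTRS = FALSE))
  names(counts) <- model$event_names
  out <- tibble::as_tibble(counts)
  out$probability <- as.vector(probs)
  structure(out, class = c("event_dist", class(out)),
            truncation = K, mass_captured = sum(probs), t = t,
            model = model)
}

#' Project an event-count distribution to population space
#'
#' Bins event-count probabilities by the resulting population vector
#' `X(0) + delta %*% n`.  Any mass on negative populations (which should
#' vanish for valid models, up to truncation noise) is discarded and
#' reported in the `discarded_mass` attribute.
#'
#' @param dist an `event_dist` from [event_count_distribution()] or
#'   [master_equation_integrate()].
#' @param model the model; defaults to the one stored in `dist`.
#' @return A tibble of class `pop_dist` with one column per population and
#'   a `probability` column; attributes `discarded_mass`, `t`.
#' @examples
#' pd <- fixture_pure_death(M = 2, rate = 1)
#' d <- event_count_distribution(pd, t = log(2), truncation = 2)
#' project_to_populations(d)  # survivors ~ Binomial(2, 1/2)
#' @export
project_to_populations <- function(dist, model = attr(dist, "model")) {
  stopifnot(inherits(dist, "event_dist"))
  n <- as.matrix(dist[model$event_names])
  X <- matrix(rep(model$initial_pops, each = nrow(n)), nrow(n)) +
    n %*% t(model$incidence)
  colnames(X) <- model$pop_names
  ok <- rowSums(X < 0) == 0
  discarded <- sum(dist$probability[!ok])
  tb <- tibble::as_tibble(as.data.frame(X[ok, , drop = FALSE]))
  tb$probability <- dist$probability[ok]
  out <- dplyr::summarise(
    dplyr::group_by(tb, dplyr::across(dplyr::all_of(model$pop_names))),
    probability = sum(.data$probability), .groups = "drop")
  structure(out, class = c("pop_dist", class(out)),
            discarded_mass = discarded, t = attr(dist, "t"))
}

#' Constants of motion along the characteristic flow
#'
#' Each structural zero `v` makes `prod_alpha x_alpha^{v_alpha}` invariant
#' along the characteristic ODE flow.  This check integrates the flow from
#' a transform point and reports, for each kernel basis vector, the
#' maximum deviation of the monomial from its initial value over a set of
#' checkpoints.  Under the default tolerances the residuals are below
#' 1e-8; the projected constant equals 1 when `z` is derived from
#' population arguments.
#'
#' @param model a validated [linear_model()].
#' @param z transform point (complex, nonzero entries).
#' @param t time horizon.
#' @param n_checkpoints number of interior checkpoints.
#' @return A tibble with one row per structural zero: `vector` (label),
#'   `initial_value`, `max_residual`.  Zero rows when the model has no
#'   structural zeroes.
#' @export
check_constants_of_motion <- function(model, z, t, n_checkpoints = 20) {
  basis <- structural_zeroes(model)
  if (ncol(basis) == 0) {
    return(tibble::tibble(vector = character(), initial_value = complex(),
                          max_residual = numeric()))
  }
  z <- check_z(z, model$n_events)
  if (any(z == 0)) stop("`z` entries must be nonzero for monomial invariants")
  E <- model$n_events
  Fm <- derive_matrices(model)$F
  rhs <- function(tt, y, p) {
    x <- y
    list(as.vector((x - 1) %*% Fm) * x)
  }
  times <- seq(0, t, length.out = n_checkpoints + 2)
  out <- deSolve::zvode(y = z, times = times, func = rhs, parms = NULL,
                        rtol = default_rtol, atol = default_atol, mf = 10, maxsteps = 1e5)
  X <- out[, -1, drop = FALSE]
  purrr::map_dfr(seq_len(ncol(basis)), function(i) {
    v <- basis[, i]
    mono <- apply(X, 1, function(x) prod(x^v))
    tibble::tibble(
      vector = paste0("(", paste(v, collapse = ","), ")"),
      initial_value = mono[1],
      max_residual = max(abs(mono - mono[1])))
  })
}

#' Mean and covariance of event counts
#'
#' Derivatives of `Psi` at `z = 1`: means by a complex-step derivative
#' (no subtractive cancellation), second factorial moments by central
#' finite differences with step `1e-5` on the real axis.  `Psi` is
#' analytic in `z`, so the step can be chosen to balance the truncation
#' error against the amplified ODE integration error; the defaults
#' (complex step 1e-4, central step 1e-3, ODE tolerances 1e-12/1e-14
#' for these solves) give means to ~1e-5 and variances to ~1e-4
#' relative.
#'
#' @param model a validated [linear_model()].
#' @param t elapsed time.
#' @param order 1 (means only) or 2 (means and covariance matrix).
#' @param step finite-difference step for second derivatives.
#' @return A list of class `event_moments`: `mean` (named vector), `cov`
#'   (matrix or `NULL`), `t`.
#' @examples
#' pd <- fixture_pure_death(M = 10, rate = 1)
#' moments(pd, t = log(2))$mean  # 5 expected deaths
#' @export
moments <- function(model, t, order = 1, step = 1e-3) {
  stopifnot(order %in% c(1, 2))
  E <- model$n_events
  hs <- 1e-4
  mrtol <- 1e-12; matol <- 1e-14
  ones <- rep(1 + 0i, E)
  # means: complex step, all directions in one stacked solve
  Zm <- matrix(rep(ones, each = E), E, E)
  diag(Zm) <- 1 + 1i * hs
  mean_psi <- solve_w_grid(model, Zm, t, mrtol, matol)$psi
  mu <- Im(mean_psi) / hs
  mu <- pmax(mu, 0)
  names(mu) <- model$event_names
  covm <- NULL
  if (order == 2) {
    # second factorial moments d2 psi / dz_a dz_b at z = 1
    pts <- list(); idx <- list()
    for (a in seq_len(E)) for (b in seq_len(a)) {
      if (a == b) {
        for (s in c(-1, 0, 1)) {
          zp <- ones; zp[a] <- zp[a] + s * step
          pts[[length(pts) + 1]] <- zp
        }
      } else {
        for (sa in c(-1, 1)) for (sb in c(-1, 1)) {
          zp <- ones; zp[a] <- zp[a] + sa * step; zp[b] <- zp[b] + sb * step
          pts[[length(pts) + 1]] <- zp
        }
      }
      idx[[length(idx) + 1]] <- c(a, b)
    }
    psis <- solve_w_grid(model, do.call(rbind, pts), t, mrtol, matol)$psi
    covm <- matrix(0, E, E, dimnames = list(model$event_names,
                                            model$event_names))
    pos <- 1
    for (ab in idx) {
      a <- ab[1]; b <- ab[2]
      if (a == b) {
        d2 <- Re(psis[pos] - 2 * psis[pos + 1] + psis[pos + 2]) / step^2
        pos <- pos + 3
        covm[a, a] <- d2 + mu[a] - mu[a]^2  # Var = E[n(n-1)] + mu - mu^2
      } else {
        d2 <- Re(psis[pos + 3] - psis[pos + 2] - psis[pos + 1] + psis[pos]) /
          (4 * step^2)
        pos <- pos + 4
        covm[a, b] <- covm[b, a] <- d2 - mu[a] * mu[b]
      }
    }
  }
  structure(list(mean = mu, cov = covm, t = t), class = "event_moments")
}

#' @export
print.event_moments <- function(x, ...) {
  cat("<event_moments> t =", x$t, "\nmean counts:\n")
  print(signif(x$mean, 6))
  if (!is.null(x$cov)) { cat("covariance:\n"); print(signif(x$cov, 6)) }
  invisible(x)
}

#' Population-space transform arguments
#'
#' Maps population arguments `y` to the event arguments
#' `z_alpha = prod_k y_k^delta[k, alpha]` of the projection lemma, so that
#' `Psi_pop(y) = prod_k y_k^{X_k(0)} * Psi(z(y))`.
#'
#' @param model a [linear_model()].
#' @param y complex vector of length `N` (nonzero entries).
#' @return Complex vector of length `E`.
#' @export
event_args_from_pop <- function(model, y) {
  stopifnot(length(y) == model$n_pops, all(y != 0))
  vapply(seq_len(model$n_events),
         function(a) prod(y^model$incidence[, a]), complex(1))
}

#' Population-space generating function
#'
#' Convenience wrapper: `Psi_pop(y, t) = prod y^X0 * Psi(z(y), t)` via
#' [solve_w()] and [event_args_from_pop()].
#'
#' @inheritParams event_args_from_pop
#' @param t elapsed time.
#' @return Complex scalar.
#' @export
population_psi <- function(model, y, t) {
  z <- event_args_from_pop(model, y)
  prod(y^model$initial_pops) * solve_w(model, z, t, check = FALSE)$psi
}
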