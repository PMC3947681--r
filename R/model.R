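#' Define a linear-rate population model in event space
#'
#' A linear population model is the triple (X, delta, r): a vector of
#' `N` nonnegative integer populations, an `N x E` integer *incidence
#' matrix* `delta` whose entry `delta[j, alpha]` is the change of
#' population `j` when event `alpha` fires, and an `E x N` matrix of
#' nonnegative *rate coefficients* `r` (units 1/time) so that event
#' `alpha` occurs with probability rate `R_alpha = sum_k r[alpha, k] X_k`.
#' The process state is the lattice of cumulative event counts; the
#' populations are recovered by `X(t) = X(0) + delta %*% n`.
#'
#' For population numbers to stay nonnegative the model must satisfy two
#' structural rules: every incidence entry is `>= -1`, and an event that
#' decrements population `i` may only have rate proportional to that same
#' population (`r[alpha, k] = 0` for `k != i`).  Linearly independent
#' increments additionally require `delta` to have full row rank.  Use
#' [validate_model()] to check these.
#'
#' @param incidence integer matrix, `N` rows (populations) by `E` columns
#'   (events).
#' @param rate_coeffs numeric matrix, `E` rows by `N` columns, entries
#'   `>= 0`, units 1/time.
#' @param initial_pops length-`N` vector of nonnegative integers.
#' @param pop_names,event_names optional character labels; defaults
#'   `X1..XN` and `e1..eE`.
#' @param validate if `TRUE` (default), [validate_model()] is run and an
#'   invalid model is rejected with an error.
#' @return An object of class `linpop_model`.
#' @examples
#' # pure death: one population, one event removing one individual
#' m <- linear_model(matrix(-1, 1, 1), matrix(1, 1, 1), initial_pops = 10)
#' m
#' @seealso [validate_model()], [derive_matrices()], [structural_zeroes()]
#' @export
linear_model <- function(incidence, rate_coeffs, initial_pops,
                         pop_names = NULL, event_names = NULL,
                         validate = TRUE) {
  incidence <- as.matrix(incidence)
  rate_coeffs <- as.matrix(rate_coeffs)
  n_pops <- nrow(incidence)
  n_events <- ncol(incidence)
  if (!all(dim(rate_coeffs) == c(n_events, n_pops))) {
    stop("`rate_coeffs` must be ", n_events, " x ", n_pops,
         " (events x populations); got ", nrow(rate_coeffs), " x ",
         ncol(rate_coeffs), call. = FALSE)
  }
  if (length(initial_pops) != n_pops) {
    stop("`initial_pops` must have length ", n_pops, call. = FALSE)
  }
  if (is.null(pop_names)) pop_names <- paste0("X", seq_len(n_pops))
  if (is.null(event_names)) event_names <- paste0("e", seq_len(n_events))
  stopifnot(length(pop_names) == n_pops, length(event_names) == n_events)
  dimnames(incidence) <- list(pop_names, event_names)
  dimnames(rate_coeffs) <- list(event_names, pop_names)
  model <- structure(
    list(n_pops = n_pops, n_events = n_events,
         incidence = incidence, rate_coeffs = rate_coeffs,
         initial_pops = setNames(as.numeric(initial_pops), pop_names),
         pop_names = pop_names, event_names = event_names),
    class = "linpop_model")
  if (validate) {
    rep <- validate_model(model)
    if (!rep$passed) {
      stop("invalid model:\n  ",
           paste(rep$violations$message, collapse = "\n  "), call. = FALSE)
    }
  }
  model
}

#' @export
print.linpop_model <- function(x, ...) {
  cat("<linpop_model> ", x$n_pops, " population(s), ", x$n_events,
      " event(s)\n", sep = "")
  cat("incidence (populations x events):\n")
  print(x$incidence)
  cat("rate coefficients (events x populations):\n")
  print(x$rate_coeffs)
  cat("initial populations:", paste(x$pop_names, "=", x$initial_pops,
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Validate the structural rules of a linear population model
#'
#' Checks every invariant required for the event-space description to be a
#' well-posed, positively invariant Markov jump process with linear rates:
#' integer incidence entries `>= -1`; each decrementing event's rate
#' proportional only to the decremented population; nonnegative rate
#' coefficients; nonnegative integer initial populations; and full row
#' rank of the incidence matrix (linearly independent increments),
#' computed in exact integer arithmetic.
#'
#' @param model a [linear_model()] (possibly built with `validate = FALSE`).
#' @return A `validation_report`: list with `passed` (logical) and
#'   `violations`, a tibble with columns `rule` and `message`.
#' @examples
#' m <- linear_model(matrix(-1, 1, 1), matrix(1, 1, 1), 5)
#' validate_model(m)$passed
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(rule, message) {
    v[[length(v) + 1]] <<- tibble::tibble(rule = rule, message = message)
  }
  d <- model$incidence
  r <- model$rate_coeffs

  if (any(d != round(d))) {
    add("incidence-integer", "incidence entries must be integers")
  }
  if (any(d < -1)) {
    bad <- which(d < -1, arr.ind = TRUE)[1, ]
    add("incidence-min",
        sprintf("incidence < -1 at population %d, event %d (linear rates only allow single-individual removals)",
                bad[1], bad[2]))
  }
  if (any(r < 0)) {
    bad <- which(r < 0, arr.ind = TRUE)[1, ]
    add("rate-nonneg",
        sprintf("negative rate coefficient at event %d, population %d",
                bad[1], bad[2]))
  }
  # decrement coupling rule: delta[i, a] == -1 forces R_a = r[a, i] X_i
  for (a in seq_len(model$n_events)) {
    dec <- which(d[, a] == -1)
    for (i in dec) {
      if (any(r[a, -i] != 0)) {
        add("decrement-coupling",
            sprintf("event %d decrements population %d but its rate depends on other populations (positive invariance would fail)",
                    a, i))
      }
    }
  }
  if (any(model$initial_pops < 0) ||
      any(model$initial_pops != round(model$initial_pops))) {
    add("initial-pops", "initial populations must be nonnegative integers")
  }
  if (all(d == round(d)) && int_rank(d) < model$n_pops) {
    add("lii-rank",
        sprintf("incidence matrix has rank %d < %d populations: increments are linearly dependent",
                int_rank(d), model$n_pops))
  }
  violations <- if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(rule = character(), message = character())
  structure(list(passed = nrow(violations) == 0, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$passed) cat("model valid: all structural rules satisfied\n")
  else {
    cat("model INVALID:\n")
    for (m in x$violations$message) cat(" -", m, "\n")
  }
  invisible(x)
}

#' Event rates at a given population state
#'
#' `R_alpha = sum_k r[alpha, k] X_k` for every event.
#'
#' @param model a [linear_model()].
#' @param X length-`N` vector of nonnegative population values.
#' @return Named length-`E` numeric vector of rates (1/time).
#' @examples
#' m <- linear_model(matrix(-1, 1, 1), matrix(0.5, 1, 1), 10)
#' rates_at(m, 10)  # 5 deaths per unit time
#' @export
rates_at <- function(model, X) {
  if (length(X) != model$n_pops) stop("`X` must have length ", model$n_pops)
  if (any(X < 0)) stop("populations must be nonnegative")
  setNames(as.vector(model$rate_coeffs %*% X), model$event_names)
}

#' Apply accumulated event counts to a population vector
#'
#' The bookkeeping identity `X' = X + delta %*% n`.  Negative results are
#' permitted here (they indicate counts unreachable by the process and are
#' flagged by the simulators and the projection step, not by this helper).
#'
#' @param model a [linear_model()].
#' @param X length-`N` population vector.
#' @param counts length-`E` vector of nonnegative event counts.
#' @return Named length-`N` vector.
#' @export
apply_events <- function(model, X, counts) {
  if (any(counts < 0)) stop("event counts must be nonnegative")
  setNames(as.vector(X + model$incidence %*% counts), model$pop_names)
}

#' Derived matrices of a linear model
#'
#' Computes the event-space drift matrix `F[alpha, beta] =
#' sum_k r[alpha, k] delta[k, beta]`, the initial rates `R0[alpha] =
#' sum_k r[alpha, k] X_k(0)` (so that `R = R0 + F %*% n` along the
#' process), the exact integer kernel basis of the incidence matrix
#' (structural zeroes), and, when the linear system `F m = R0` is
#' consistent, a minimal-norm solution `m` (see [find_m_vector()]).
#'
#' @param model a validated [linear_model()].
#' @return A list of class `derived_matrices` with elements `F`, `R0`,
#'   `m_vector` (or `NULL`), `structural_zero_basis` (matrix, one kernel
#'   vector per column).
#' @examples
#' bd <- fixture_birth_death(X0 = 3, birth = 1, death = 2)
#' derive_matrices(bd)$F
#' @export
derive_matrices <- function(model) {
  Fm <- model$rate_coeffs %*% model$incidence
  dimnames(Fm) <- list(model$event_names, model$event_names)
  R0 <- setNames(as.vector(model$rate_coeffs %*% model$initial_pops),
                 model$event_names)
  structure(
    list(F = Fm, R0 = R0,
         m_vector = find_m_vector_impl(Fm, R0),
         structural_zero_basis = structural_zeroes(model)),
    class = "derived_matrices")
}

#' @export
print.derived_matrices <- function(x, ...) {
  cat("<derived_matrices>\nF (events x events):\n"); print(x$F)
  cat("R0:", x$R0, "\n")
  if (is.null(x$m_vector)) cat("m vector: none (F m = R0 inconsistent)\n")
  else cat("m vector:", signif(x$m_vector, 6), "\n")
  nz <- ncol(x$structural_zero_basis)
  cat("structural zeroes:", nz, "\n")
  invisible(x)
}

#' Structural zeroes of the incidence matrix
#'
#' A *structural zero* is a nonzero integer vector `v` with
#' `delta %*% v = 0`: a combination of events that leaves every population
#' unchanged.  Each one yields a constant of motion
#' `prod_alpha x_alpha^(v_alpha)` of the characteristic ODEs and collapses
#' under projection to population space.  Under linearly independent
#' increments there are exactly `E - N` of them.  The basis is computed in
#' exact integer arithmetic.
#'
#' @param model a [linear_model()].
#' @return An `E x (E - rank)` integer matrix, one basis vector per column
#'   (zero columns when the kernel is trivial).
#' @examples
#' bd <- fixture_birth_death(X0 = 1, birth = 1, death = 2)
#' structural_zeroes(bd)  # single vector (1, 1): one birth + one death
#' @export
structural_zeroes <- function(model) {
  b <- int_kernel(model$incidence)
  rownames(b) <- model$event_names
  b
}

find_m_vector_impl <- function(Fm, R0, tol = 1e-12) {
  sv <- svd(Fm)
  pos <- sv$d > max(sv$d[1], 1) * 1e-13
  if (!any(pos)) {
    if (sqrt(sum(R0^2)) <= tol * (1 + sqrt(sum(R0^2)))) return(R0 * 0)
    return(NULL)
  }
  m <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% R0) / sv$d[pos])
  m <- as.vector(m)
  if (sqrt(sum((Fm %*% m - R0)^2)) > tol * (1 + sqrt(sum(R0^2)))) return(NULL)
  setNames(m, names(R0))
}

#' Mimic the initial condition on the rates: solve F m = R0
#'
#' When consistent, returns the minimal-norm real solution of
#' `F %*% m = R0`; the generating function is unchanged if any combination
#' of structural zeroes is added to `m`, so non-uniqueness is harmless.
#' The population-coordinate solver does not need `m` at all; it is kept
#' as a diagnostic.  Real (non-integer) solutions are accepted.
#'
#' @param derived a [derive_matrices()] result, or a `linpop_model`.
#' @return Length-`E` vector, or `NULL` with a message when `F m = R0` has
#'   no solution.
#' @examples
#' pd <- fixture_pure_death(M = 4, rate = 1)
#' find_m_vector(derive_matrices(pd))  # -4: minus the initial cohort
#' @export
find_m_vector <- function(derived) {
  if (inherits(derived, "linpop_model")) derived <- derive_matrices(derived)
  m <- find_m_vector_impl(derived$F, derived$R0)
  if (is.null(m)) message("F m = R0 is inconsistent: no m vector exists")
  m
}
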