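# broom-style tidiers for the package's result objects.

#' Tidy a generating-function solution
#'
#' One row per population with the per-individual factor `w_k` (and one
#' row per event with `f_beta` when available), split into real and
#' imaginary parts.
#'
#' @param x a `pgf_solution`.
#' @param ... unused.
#' @return A tibble with columns `coordinate`, `name`, `re`, `im`, `mod`.
#' @method tidy pgf_solution
#' @export
tidy.pgf_solution <- function(x, ...) {
  rows <- list()
  if (!is.null(x$w)) {
    rows$w <- tibble::tibble(coordinate = "w", name = names(x$w),
                             re = Re(x$w), im = Im(x$w), mod = Mod(x$w))
  }
  if (!is.null(x$f)) {
    rows$f <- tibble::tibble(coordinate = "f", name = names(x$f),
                             re = Re(x$f), im = Im(x$f), mod = Mod(x$f))
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.pgf_solution
#' @return For `glance()`: a one-row tibble with `psi_re`, `psi_im`,
#'   `psi_mod`, `t`, `route`, `ode_steps`.
#' @method glance pgf_solution
#' @export
glance.pgf_solution <- function(x, ...) {
  tibble::tibble(psi_re = Re(x$psi), psi_im = Im(x$psi),
                 psi_mod = Mod(x$psi), t = x$t,
                 route = x$stats$route,
                 ode_steps = as.integer(x$stats$steps))
}

#' Tidy one-step probabilities
#'
#' Long format: the no-event probability, each single-event probability,
#' and each ordered two-event probability of the order-2 scheme.
#'
#' @param x a `step_probabilities` object.
#' @param ... unused.
#' @return A tibble with columns `outcome`, `first`, `second`,
#'   `probability`.
#' @method tidy step_probabilities
#' @export
tidy.step_probabilities <- function(x, ...) {
  ev <- names(x$p_one)
  two <- expand.grid(first = ev, second = ev, stringsAsFactors = FALSE)
  dplyr::bind_rows(
    tibble::tibble(outcome = "none", first = NA_character_,
                   second = NA_character_, probability = x$p_none),
    tibble::tibble(outcome = "one", first = ev, second = NA_character_,
                   probability = as.vector(x$p_one)),
    tibble::tibble(outcome = "two", first = two$first, second = two$second,
                   probability = as.vector(x$p_two)))
}

#' Tidy event-count moments
#'
#' @param x an `event_moments` object.
#' @param ... unused.
#' @return A tibble with columns `event`, `mean` and, at order 2,
#'   `variance`.
#' @method tidy event_moments
#' @export
tidy.event_moments <- function(x, ...) {
  out <- tibble::tibble(event = names(x$mean), mean = as.vector(x$mean))
  if (!is.null(x$cov)) out$variance <- diag(x$cov)
  out
}

#' Tidy a validation report
#'
#' @param x a `validation_report`.
#' @param ... unused.
#' @return The violations tibble (zero rows when the model is valid).
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$violations

#' Glance at an event-count distribution
#'
#' @param x an `event_dist` tibble.
#' @param ... unused.
#' @return A one-row tibble: `mass_captured`, `tail_mass`, `n_cells`, `t`.
#' @method glance event_dist
#' @export
glance.event_dist <- function(x, ...) {
  tibble::tibble(mass_captured = attr(x, "mass_captured"),
                 tail_mass = 1 - attr(x, "mass_captured"),
                 n_cells = nrow(x), t = attr(x, "t"))
}

#' Glance at a simulation ensemble
#'
#' @param x an `ensemble_summary`.
#' @param ... unused.
#' @return A one-row tibble: `n_runs`, `scheme`, `t_end`, `n_cells`.
#' @method glance ensemble_summary
#' @export
glance.ensemble_summary <- function(x, ...) {
  tibble::tibble(n_runs = x$n_runs, scheme = x$scheme, t_end = x$t_end,
                 n_cells = nrow(x$distribution))
}
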