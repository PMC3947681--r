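# Fixture model families: the worked examples (pure death, birth-death,
# developmental cascades) plus random valid linear models for
# property-style testing.  All builders return validated `linpop_model`s.

#' Pure death process
#'
#' One population of `M` individuals, one event removing one individual at
#' per-capita rate `rate`.  The number of deaths by time `t` is
#' `Binomial(M, 1 - exp(-rate * t))`.
#'
#' @param M initial cohort size.
#' @param rate per-capita death rate (1/time).
#' @return A `linpop_model`.
#' @export
fixture_pure_death <- function(M = 10, rate = 1) {
  linear_model(matrix(-1L, 1, 1), matrix(rate, 1, 1), M,
               pop_names = "X", event_names = "death")
}

#' Linear birth-death process
#'
#' One population, two events: birth (`+1`, rate `birth * X`) and death
#' (`-1`, rate `death * X`).  Events outnumber populations by one, so
#' there is a single structural zero `(1, 1)`: one birth plus one death
#' leaves the population unchanged.
#'
#' @param X0 initial population.
#' @param birth,death per-capita rates (1/time).
#' @return A `linpop_model`.
#' @export
fixture_birth_death <- function(X0 = 1, birth = 1, death = 1) {
  linear_model(matrix(c(1L, -1L), 1, 2),
               matrix(c(birth, death), 2, 1), X0,
               pop_names = "X", event_names = c("birth", "death"))
}

#' Specification of a developmental cascade
#'
#' A cohort of `cohort_size` individuals starts in stage 0 and matures
#' through `n_stages` sequential stages; stage `j` is left at per-capita
#' rate `maturation_rates[j + 1]`, optionally competing with a per-stage
#' death at rate `death_rates[j + 1]`.  Completion of the final stage is
#' exit (pupation/emergence); the absorbing post-cascade stage carries no
#' events and is not modelled as a population.  With equal maturation
#' rates and no mortality the exit time is Erlang-distributed; with
#' distinct rates it is hypoexponential; with mortality the exit-time
#' distribution is defective with total mass `prod r / (q + r)`.
#'
#' @param maturation_rates length-`E` positive vector (1/time).
#' @param death_rates optional length-`E` nonnegative vector; `NULL` means
#'   no mortality.
#' @param cohort_size number of independent individuals starting in stage 0.
#' @return An object of class `cascade_spec`.
#' @export
cascade_spec <- function(maturation_rates, death_rates = NULL,
                         cohort_size = 1) {
  E <- length(maturation_rates)
  stopifnot(E >= 1, all(maturation_rates >= 0), cohort_size >= 1)
  if (!is.null(death_rates)) {
    stopifnot(length(death_rates) == E, all(death_rates >= 0))
  }
  structure(list(n_stages = E,
                 maturation_rates = as.numeric(maturation_rates),
                 death_rates = if (!is.null(death_rates)) as.numeric(death_rates),
                 cohort_size = cohort_size),
            class = "cascade_spec")
}

#' @export
print.cascade_spec <- function(x, ...) {
  cat("<cascade_spec> ", x$n_stages, " stage(s), cohort ", x$cohort_size,
      if (is.null(x$death_rates)) ", no mortality" else ", with mortality",
      "\n", sep = "")
  cat("maturation rates:", x$maturation_rates, "\n")
  if (!is.null(x$death_rates)) cat("death rates:", x$death_rates, "\n")
  invisible(x)
}

#' Build the event-space model of a developmental cascade
#'
#' Without mortality: `E` populations (stages `0 .. E-1`) and `E`
#' maturation events with bidiagonal incidence (`-1` on the diagonal,
#' `+1` on the subdiagonal; the final event only removes, its count is the
#' number of completed individuals).  With mortality: events are ordered
#' in per-stage pairs (death 0, maturation 0, death 1, ...), giving `2E`
#' events over `E` populations and hence `E` structural zeroes.
#'
#' @param spec a [cascade_spec()].
#' @return A `linpop_model`.
#' @export
as_linear_model <- function(spec) {
  stopifnot(inherits(spec, "cascade_spec"))
  E <- spec$n_stages
  r <- spec$maturation_rates
  stage_names <- paste0("S", seq_len(E) - 1)
  if (is.null(spec$death_rates)) {
    delta <- matrix(0L, E, E)
    rates <- matrix(0, E, E)
    for (a in seq_len(E)) {
      delta[a, a] <- -1L
      if (a < E) delta[a + 1, a] <- 1L
      rates[a, a] <- r[a]
    }
    ev <- paste0("mat", seq_len(E) - 1)
  } else {
    q <- spec$death_rates
    delta <- matrix(0L, E, 2 * E)
    rates <- matrix(0, 2 * E, E)
    for (a in seq_len(E)) {
      delta[a, 2 * a - 1] <- -1L           # death of stage a-1
      delta[a, 2 * a] <- -1L               # maturation out of stage a-1
      if (a < E) delta[a + 1, 2 * a] <- 1L
      rates[2 * a - 1, a] <- q[a]
      rates[2 * a, a] <- r[a]
    }
    ev <- as.vector(rbind(paste0("death", seq_len(E) - 1),
                          paste0("mat", seq_len(E) - 1)))
  }
  X0 <- c(spec$cohort_size, rep(0, E - 1))
  linear_model(delta, rates, X0, pop_names = stage_names, event_names = ev)
}

#' Random valid linear model
#'
#' Draws a model that passes [validate_model()] by construction: each
#' event is a removal (`-1` on one population, rate proportional to it),
#' a transfer (`-1`/`+1` pair), or a single-birth production event
#' (`+1`, rate coefficient on a random population), redrawing until the
#' incidence matrix has full row rank.  Used for property-style tests.
#' Production is capped at one individual per event so the drawn models
#' stay in the regime where the characteristic flow is well-conditioned
#' over the tested horizons.
#'
#' @param n_pops,n_events dimensions; `n_events >= n_pops` is required,
#'   since the incidence matrix cannot otherwise reach full row rank.
#' @param rate_range range for uniform rate-coefficient draws (1/time).
#' @param seed optional integer seed (drawn models are deterministic
#'   given the seed).
#' @return A `linpop_model`.
#' @export
fixture_random_linear <- function(n_pops = 2, n_events = 3,
                                  rate_range = c(0.2, 1.5), seed = NULL) {
  if (n_events < n_pops) {
    stop("full-rank incidence needs n_events >= n_pops")
  }
  draw <- function() {
    delta <- matrix(0L, n_pops, n_events)
    rates <- matrix(0, n_events, n_pops)
    for (a in seq_len(n_events)) {
      kind <- sample(c("removal", "transfer", "production"), 1)
      if (kind == "transfer" && n_pops < 2) kind <- "removal"
      i <- sample.int(n_pops, 1)
      rate <- runif(1, rate_range[1], rate_range[2])
      if (kind == "removal") {
        delta[i, a] <- -1L
        rates[a, i] <- rate
      } else if (kind == "transfer") {
        j <- sample(setdiff(seq_len(n_pops), i), 1)
        delta[i, a] <- -1L
        delta[j, a] <- 1L
        rates[a, i] <- rate
      } else {
        delta[i, a] <- 1L
        k <- sample.int(n_pops, 1)
        rates[a, k] <- rate
      }
    }
    list(delta = delta, rates = rates)
  }
  run <- function() {
    repeat {
      d <- draw()
      if (int_rank(d$delta) == n_pops) {
        X0 <- sample(0:5, n_pops, replace = TRUE)
        if (all(rates_at_raw(d$rates, X0) == 0)) next  # inert model
        return(linear_model(d$delta, d$rates, X0))
      }
    }
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

rates_at_raw <- function(rates, X) as.vector(rates %*% X)

#' Generate a fixture model by family name
#'
#' Thin dispatcher over the family builders, mirroring the worked-example
#' families: `"pure-death"`, `"birth-death"`, `"cascade"`,
#' `"cascade-mortality"`, `"random-linear"`.
#'
#' @param family family name.
#' @param ... passed to the family builder.
#' @param seed optional seed (only `"random-linear"` draws random numbers).
#' @return A `linpop_model`.
#' @examples
#' generate_fixture("cascade", maturation_rates = c(1, 2, 3), cohort_size = 5)
#' @export
generate_fixture <- function(family = c("random-linear", "pure-death",
                                        "birth-death", "cascade",
                                        "cascade-mortality"),
                             ..., seed = NULL) {
  family <- match.arg(family)
  switch(family,
    "pure-death" = fixture_pure_death(...),
    "birth-death" = fixture_birth_death(...),
    "cascade" = as_linear_model(cascade_spec(...)),
    "cascade-mortality" = {
      args <- list(...)
      if (is.null(args$death_rates)) stop("cascade-mortality needs `death_rates`")
      as_linear_model(do.call(cascade_spec, args))
    },
    "random-linear" = fixture_random_linear(..., seed = seed))
}
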