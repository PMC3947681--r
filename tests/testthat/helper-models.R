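# Shared fixtures and small oracles used across test files.

# total-variation distance between two event_dist tibbles on the same
# lattice (aligned by count columns)
tv_dist <- function(a, b) {
  ev <- setdiff(names(a), "probability")
  j <- dplyr::full_join(dplyr::rename(a, pa = "probability"),
                        dplyr::rename(b, pb = "probability"), by = ev)
  j$pa[is.na(j$pa)] <- 0
  j$pb[is.na(j$pb)] <- 0
  sum(abs(j$pa - j$pb)) / 2
}

# small random transform point on/inside the unit circle
random_z <- function(E, radius = 1) {
  radius * sqrt(runif(E)) * exp(2i * pi * runif(E))
}

# hypoexponential CDF oracle via phase-type matrix exponential
# (independent of the closed forms under test)
hypoexp_cdf_expm <- function(rates, t) {
  E <- length(rates)
  Tm <- diag(-rates, E, E)
  if (E > 1) for (i in seq_len(E - 1)) Tm[i, i + 1] <- rates[i]
  one <- rep(1, E)
  vapply(t, function(tt) {
    1 - sum(as.matrix(Matrix::expm(Tm * tt))[1, ] %*% one)
  }, numeric(1))
}

# two-population transfer model with an extra production event: small
# model with no structural zeroes used in several tests
fixture_transfer <- function() {
  # events: transfer 1->2 (rate 1.2 X1), removal of 2 (rate 0.8 X2),
  # production of 1 at rate 0.5 X2
  linear_model(
    incidence = matrix(c(-1, 1,
                         0, -1,
                         1, 0), 2, 3),
    rate_coeffs = matrix(c(1.2, 0,
                           0, 0.8,
                           0, 0.5), 3, 2, byrow = TRUE),
    initial_pops = c(3, 2))
}
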