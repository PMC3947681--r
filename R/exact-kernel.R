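# Exact (fraction-free) linear algebra on small integer matrices.
#
# Structural statements about the incidence matrix (its rank, its kernel)
# must not depend on floating-point thresholds: a conservation law either
# holds exactly or it does not.  All elimination steps below are
# fraction-free (Bareiss), so every intermediate value is an integer;
# doubles represent these integers exactly for the matrix sizes handled
# here (entries in {-1, 0, 1, ...}, dimensions of order 10).

int_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

int_gcd_vec <- function(v) {
  g <- 0
  for (x in v) g <- int_gcd(g, x)
  g
}

# Fraction-free row echelon form.  Returns the echelon matrix (integer
# entries), the pivot column of each nonzero row, and the rank.
int_echelon <- function(A) {
  A <- matrix(as.numeric(A), nrow(A), ncol(A))
  m <- nrow(A); n <- ncol(A)
  pivots <- integer(0)
  row <- 1L
  prev_pivot <- 1
  for (col in seq_len(n)) {
    if (row > m) break
    sel <- which(A[row:m, col] != 0)
    if (length(sel) == 0) next
    sel <- sel[1] + row - 1L
    if (sel != row) A[c(row, sel), ] <- A[c(sel, row), ]
    piv <- A[row, col]
    if (row < m) {
      for (i in (row + 1L):m) {
        if (A[i, col] != 0 || TRUE) {
          # Bareiss step: exact division by previous pivot
          A[i, ] <- (piv * A[i, ] - A[i, col] * A[row, ]) / prev_pivot
        }
      }
    }
    prev_pivot <- piv
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(echelon = A, pivots = pivots, rank = length(pivots))
}

# Exact rank of an integer matrix.
int_rank <- function(A) int_echelon(A)$rank

# Exact integer basis of the right kernel {v : A v = 0}.  Each basis
# vector is scaled to coprime integer entries and re-verified by exact
# multiplication.  Returns a (possibly zero-column) matrix with one basis
# vector per column.
int_kernel <- function(A) {
  n <- ncol(A)
  ech <- int_echelon(A)
  U <- ech$echelon
  pivots <- ech$pivots
  free <- setdiff(seq_len(n), pivots)
  basis <- matrix(0, n, length(free))
  if (length(free) == 0) return(basis)
  r <- ech$rank
  for (fi in seq_along(free)) {
    f <- free[fi]
    # rational back-substitution kept integral: v carries a running
    # denominator that is a product of pivots
    v <- numeric(n)
    v[f] <- 1
    den <- 1
    if (r > 0) {
      for (i in r:1) {
        p <- pivots[i]
        s <- sum(U[i, ] * v) - U[i, p] * v[p]
        # v[p] = -s / U[i,p]; clear the denominator instead of dividing
        piv <- U[i, p]
        g <- int_gcd(abs(s), abs(piv))
        if (g == 0) { v[p] <- 0; next }
        mult <- abs(piv) / g
        if (mult != 1) { v <- v * mult; den <- den * mult; s <- s * mult }
        v[p] <- -s / piv
      }
    }
    g <- int_gcd_vec(v)
    if (g > 0) v <- v / g
    stopifnot(max(abs(A %*% v)) == 0)  # exact integer verification
    basis[, fi] <- v
  }
  basis
}
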