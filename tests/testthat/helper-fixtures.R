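# Canonical worked-example parameter set: strong refuge (m = 0.4) with a
# unique, globally attractive interior equilibrium near (1.4521, 11.485).
example_params <- function() {
  lg_params(r1 = 11, b1 = 5, a1 = 4, k1 = 6.5,
            r2 = 8, a2 = 2, k2 = 2, m = 0.4)
}

# Bistable reference: two interior equilibria (existence Case 2).
two_equilibria_params <- function() {
  lg_params(r1 = 1, b1 = 0.1, a1 = 1, k1 = 0.01,
            r2 = 1, a2 = 10, k2 = 2, m = 0)
}

# No interior equilibrium (Case 3): predation pressure too strong, no
# real roots. B < 0, m below threshold, Delta < 0.
no_equilibrium_params <- function() {
  # a1 r2 k2 = 40 > a2 r1 k1 = 5 (m below threshold); B = 2 - 10 + 2.5
  # = -5.5; Delta = 30.25 - 4*5*(4 - 5/2)... computed < 0 in the test.
  lg_params(r1 = 1, b1 = 0.5, a1 = 2, k1 = 0.5,
            r2 = 1, a2 = 10, k2 = 20, m = 0)
}

# Log-uniform random parameter draw (optionally validated-only).
rand_params <- function(m_max = 0.95) {
  repeat {
    v <- exp(stats::runif(7, log(0.05), log(20)))
    p <- try(lg_params(r1 = v[1], b1 = v[2], a1 = v[3], k1 = v[4],
                       r2 = v[5], a2 = v[6], k2 = v[7],
                       m = stats::runif(1, 0, m_max)), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

# Draw n random parameter sets satisfying the attractivity condition C3.
rand_c3_params <- function(n) {
  out <- list()
  while (length(out) < n) {
    p <- rand_params()
    if (lg_conditions(p)$c3$holds) out[[length(out) + 1L]] <- p
  }
  out
}

# Independent root oracle: intersect the prey nullcline with the predator
# nullcline by sign-change bisection in x, never touching the quadratic.
nullcline_roots_bisect <- function(p, tol = 1e-12) {
  om <- 1 - p$m
  g <- function(x) {
    y <- p$r2 * (om * x + p$k2) / p$a2
    p$r1 - p$b1 * x - p$a1 * om * y / (om * x + p$k1)
  }
  hi <- p$r1 / p$b1 * 2
  grid <- seq(1e-9, hi, length.out = 4001)
  gv <- vapply(grid, g, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (gv[i] == 0) roots <- c(roots, grid[i])
    if (gv[i] * gv[i + 1] < 0) {
      lo <- grid[i]; up <- grid[i + 1]
      while (up - lo > tol * max(1, up)) {
        mid <- (lo + up) / 2
        if (g(lo) * g(mid) <= 0) up <- mid else lo <- mid
      }
      roots <- c(roots, (lo + up) / 2)
    }
  }
  sort(roots)
}
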