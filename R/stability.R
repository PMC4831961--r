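#' Linearized stability of an equilibrium
#'
#' Computes the eigenvalues of the analytic Jacobian at the equilibrium
#' and classifies it as `stable` (both real parts negative), `unstable`
#' (at least one positive real part) or `nonhyperbolic` (a real part
#' within tolerance of zero). For positive equilibria the sufficient
#' polynomial criterion
#' \deqn{2 b_1 (1-m) x^2 - \left(r_1(1-m) - r_2(1-m) - b_1 k_1\right)x
#'   + k_1 r_2 > 0}
#' is also evaluated at the equilibrium and recorded as a diagnostic: a
#' positive value is sufficient for stability of `E3_1` / `E3_plus`, but
#' the criterion is one-sided, so the eigenvalue computation is the
#' authoritative verdict and any disagreement on a hyperbolic point is
#' reported, never used to override the eigenvalues.
#'
#' @param p an [lg_params()] object.
#' @param e an `lg_equilibrium` (from [lg_boundary_equilibria()] or
#'   [lg_positive_equilibria()]).
#' @param tol hyperbolicity tolerance: a real part with
#'   `|Re| <= tol * (1 + |lambda|)` counts as zero.
#' @return An object of class `lg_stability`: list with `label`,
#'   `eigenvalues` (complex pair), `poly_value` (the polynomial value,
#'   `NA` for boundary equilibria), and `poly_agrees` (`NA` when the
#'   criterion is silent, i.e. polynomial non-positive or point
#'   nonhyperbolic).
#' @export
lg_stability <- function(p, e, tol = 1e-9) {
  p <- as_params(p)
  if (!inherits(e, "lg_equilibrium"))
    stop("'e' must be an lg_equilibrium object", call. = FALSE)
  J <- if (p$k2 == 0 && e$x == 0 && e$y == 0)
    # Holling-Tanner origin: predator equation singular; prey linearization
    # still r1, predator growth rate bounded by r2 -- report the formal
    # diagonal linearization
    matrix(c(p$r1, 0, 0, p$r2), 2, 2)
  else
    lg_jacobian(p, c(e$x, e$y))
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  re <- Re(ev)
  zeroish <- abs(re) <= tol * (1 + Mod(ev))
  label <- if (any(zeroish)) "nonhyperbolic"
           else if (all(re < 0)) "stable"
           else "unstable"

  poly <- NA_real_
  agrees <- NA
  if (startsWith(e$kind, "E3")) {
    om <- 1 - p$m
    poly <- 2 * p$b1 * om * e$x^2 -
      (p$r1 * om - p$r2 * om - p$b1 * p$k1) * e$x + p$k1 * p$r2
    if (poly > 0 && label != "nonhyperbolic" &&
        e$kind %in% c("E3_1", "E3_plus"))
      agrees <- label == "stable"
  }
  structure(list(label = label, eigenvalues = ev,
                 poly_value = poly, poly_agrees = agrees),
            class = "lg_stability")
}

#' @export
print.lg_stability <- function(x, ...) {
  cat(sprintf("%s (eigenvalues %s, %s)",
              x$label, format(x$eigenvalues[1], digits = 4),
              format(x$eigenvalues[2], digits = 4)))
  if (!is.na(x$poly_value))
    cat(sprintf("; polynomial criterion value %.6g", x$poly_value))
  cat("\n")
  invisible(x)
}

#' Random-parameter consistency scan of the stability criteria
#'
#' Samples random parameter sets that admit positive equilibria and
#' cross-checks the two stability routes on each:
#' (a) the smaller interior equilibrium `E3_minus`, when it exists, must
#' be eigenvalue-unstable; (b) whenever the sufficient polynomial
#' criterion is positive at `E3_1` or `E3_plus` and the point is
#' hyperbolic, the eigenvalue verdict must be `stable`. Counterexample
#' configurations, if any, are returned verbatim for inspection.
#'
#' Sampling draws coefficients log-uniformly and the refuge fraction
#' uniformly; half the draws are multiplicative jitters around a
#' reference two-equilibrium configuration so that `E3_minus` is
#' exercised, since generic draws land there rarely.
#'
#' @param n_samples number of parameter sets with at least one positive
#'   equilibrium to examine.
#' @param seed integer seed for reproducibility.
#' @param include optional list of `lg_params` objects forced into the
#'   scan in addition to the random draws.
#' @return An object of class `lg_scan`: list with `n_examined`,
#'   `n_with_two`, and `counterexamples` (list of
#'   `list(params, equilibrium, verdict, check)`, empty when consistent).
#' @export
lg_stability_scan <- function(n_samples, seed = 0L, include = NULL) {
  if (n_samples < 0) stop("n_samples must be >= 0", call. = FALSE)
  set.seed(seed)
  examined <- 0L
  n_two <- 0L
  counterexamples <- list()
  pool <- include
  check_one <- function(p) {
    eqs <- lg_positive_equilibria(p)
    if (!length(eqs)) return(FALSE)
    if (length(eqs) == 2L) n_two <<- n_two + 1L
    for (e in eqs) {
      v <- lg_stability(p, e)
      bad_minus <- e$kind == "E3_minus" && v$label == "stable"
      bad_poly <- isFALSE(v$poly_agrees)
      if (bad_minus || bad_poly)
        counterexamples[[length(counterexamples) + 1L]] <<-
          list(params = p, equilibrium = e, verdict = v,
               check = if (bad_minus) "E3_minus stable" else
                 "polynomial positive but not eigenvalue-stable")
    }
    TRUE
  }
  for (p in pool) check_one(as_params(p))
  guard <- 0L
  while (examined < n_samples && guard < 1000L * max(1L, n_samples)) {
    guard <- guard + 1L
    p <- sample_params(case2_bias = guard %% 2L == 0L)
    if (is.null(p)) next
    if (check_one(p)) examined <- examined + 1L
  }
  structure(list(n_examined = examined, n_with_two = n_two,
                 counterexamples = counterexamples),
            class = "lg_scan")
}

#' @export
print.lg_scan <- function(x, ...) {
  cat(sprintf(
    "Stability consistency scan: %d parameter sets (%d with two interior equilibria), %d counterexample(s)\n",
    x$n_examined, x$n_with_two, length(x$counterexamples)))
  invisible(x)
}

# Reference configuration with two interior equilibria: small k1, strong
# predator conversion pressure (a2 r1 > a1 r2 + a2 b1 k1) while the
# refuge threshold stays above m.
case2_reference <- function() {
  lg_params(r1 = 1, b1 = 0.1, a1 = 1, k1 = 0.01,
            r2 = 1, a2 = 10, k2 = 2, m = 0)
}

# Draw one random parameter set; returns NULL if the draw is invalid.
sample_params <- function(case2_bias = FALSE) {
  p <- try(silent = TRUE, {
    if (case2_bias) {
      ref <- case2_reference()
      jit <- function(v) v * exp(stats::runif(1, -0.3, 0.3))
      lg_params(r1 = jit(ref$r1), b1 = jit(ref$b1), a1 = jit(ref$a1),
                k1 = jit(ref$k1), r2 = jit(ref$r2), a2 = jit(ref$a2),
                k2 = jit(ref$k2), m = stats::runif(1, 0, 0.5))
    } else {
      lu <- function() exp(stats::runif(1, log(0.05), log(20)))
      lg_params(r1 = lu(), b1 = lu(), a1 = lu(), k1 = lu(),
                r2 = lu(), a2 = lu(), k2 = lu(),
                m = stats::runif(1, 0, 0.95))
    }
  })
  if (inherits(p, "try-error")) NULL else p
}
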