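#' Discriminant algebra for positive equilibria
#'
#' Positive equilibria are intersections of the prey nullcline with the
#' predator nullcline \eqn{y = r_2((1-m)x + k_2)/a_2}; eliminating
#' \eqn{y} gives the quadratic
#' \deqn{a_2 b_1 (1-m)\, x^2 + B x + \left[(1-m)a_1 r_2 k_2 -
#'   a_2 r_1 k_1\right] = 0}
#' with
#' \deqn{B = a_1 r_2 (1-m)^2 - a_2 r_1 (1-m) + a_2 b_1 k_1, \qquad
#'  \Delta = B^2 - 4(1-m) a_2 b_1\left[(1-m)a_1 r_2 k_2 - a_2 r_1 k_1\right].}
#' The refuge threshold \eqn{1 - a_2 r_1 k_1 / (a_1 r_2 k_2)} separates the
#' existence regimes; `D` is the constant term of the auxiliary quadratic
#' used in the uniqueness argument of the attractivity theory (its
#' negativity under the attractivity condition rules out two distinct
#' limit points).
#'
#' @param p an [lg_params()] object.
#' @return An object of class `lg_discriminants`: list with fields `B`,
#'   `Delta`, `D`, and `m_threshold` (`-Inf` when `k2 = 0`, where the
#'   threshold formula diverges to minus infinity).
#' @examples
#' p <- lg_params(11, 5, 4, 6.5, 8, 2, 2, m = 0.4)
#' lg_discriminants(p)   # B = 63.32, Delta = 6519.8224
#' @export
lg_discriminants <- function(p) {
  p <- as_params(p)
  om <- 1 - p$m
  B <- p$a1 * p$r2 * om^2 - p$a2 * p$r1 * om + p$a2 * p$b1 * p$k1
  cterm <- om * p$a1 * p$r2 * p$k2 - p$a2 * p$r1 * p$k1
  Delta <- B^2 - 4 * om * p$a2 * p$b1 * cterm
  D <- p$a2 * (p$a1 * om^2 * p$r1 * p$r2 +
                 p$a1 * om * p$b1 * p$r2 * p$k2 -
                 p$a2 * p$b1 * p$r1 * p$k1) +
    p$a1 * p$r2 * om * (p$a1 * p$r2 * om^2 - p$a2 * p$b1 * p$k1)
  m_threshold <- if (p$k2 == 0) -Inf else
    1 - p$a2 * p$r1 * p$k1 / (p$a1 * p$r2 * p$k2)
  structure(list(B = B, Delta = Delta, D = D, m_threshold = m_threshold),
            class = "lg_discriminants")
}

#' @export
print.lg_discriminants <- function(x, ...) {
  cat("Positive-equilibrium discriminants\n")
  cat(sprintf("  B = %g   Delta = %g   D = %g\n", x$B, x$Delta, x$D))
  cat(sprintf("  refuge threshold 1 - a2*r1*k1/(a1*r2*k2) = %g\n",
              x$m_threshold))
  invisible(x)
}

new_equilibrium <- function(x, y, kind, degenerate = FALSE) {
  structure(list(x = x, y = y, kind = kind, degenerate = degenerate,
                 stability = NULL),
            class = "lg_equilibrium")
}

#' @export
print.lg_equilibrium <- function(x, ...) {
  cat(sprintf("%s = (%.6g, %.6g)%s", x$kind, x$x, x$y,
              if (x$degenerate) "  [degenerate]" else ""))
  if (!is.null(x$stability)) cat("  --", x$stability$label)
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.lg_equilibrium <- function(x, ...) {
  data.frame(kind = x$kind, x = x$x, y = x$y, degenerate = x$degenerate,
             stability = if (is.null(x$stability)) NA_character_
                         else x$stability$label,
             stringsAsFactors = FALSE)
}

#' Boundary equilibria
#'
#' The system always has the extinction state `E0 = (0, 0)`, the
#' predator-free state `E1 = (r1/b1, 0)` (prey at carrying capacity), and
#' the prey-free state `E2 = (0, r2*k2/a2)` (predator living on alternate
#' food only). With `k2 = 0` the prey-free state collapses onto the
#' origin; it is still returned, labelled `E2` and flagged degenerate.
#'
#' @param p an [lg_params()] object.
#' @return List of three `lg_equilibrium` objects (`E0`, `E1`, `E2`).
#' @export
lg_boundary_equilibria <- function(p) {
  p <- as_params(p)
  list(
    new_equilibrium(0, 0, "E0"),
    new_equilibrium(p$r1 / p$b1, 0, "E1"),
    new_equilibrium(0, p$r2 * p$k2 / p$a2, "E2", degenerate = p$k2 == 0)
  )
}

#' Existence classification of positive equilibria
#'
#' Classifies the parameter set into the mutually exclusive existence
#' regimes for interior equilibria, in terms of the refuge fraction `m`
#' versus the threshold \eqn{1 - a_2 r_1 k_1/(a_1 r_2 k_2)}, the sign of
#' `B` and the sign of the discriminant \eqn{\Delta}:
#'
#' * `CASE1_i`: `m` above the threshold - one positive equilibrium `E3_1`;
#' * `CASE1_ii`: `m` at the threshold and `B < 0` - one (`E3_1`);
#' * `CASE1_iii`: `m` below the threshold, `B < 0`, `Delta = 0` - one
#'   (double root, `E3_1`);
#' * `CASE2`: `m` below the threshold, `B < 0`, `Delta > 0` - two
#'   (`E3_minus < E3_plus`);
#' * `CASE3`: none of the above - no positive equilibrium.
#'
#' Equalities (`m` at the threshold, `Delta = 0`) are algebraic
#' knife-edges; they are detected with an absolute tolerance scaled by the
#' magnitude of the compared quantities. With `k2 = 0` the threshold is
#' `-Inf`, so any admissible `m` falls in `CASE1_i`.
#'
#' The configuration `B >= 0` with `m` below the threshold and
#' `Delta > 0` is not covered by the case list; it is classified `CASE3`
#' and flagged in the returned object (`flag` field) so callers can see
#' the literal rule was applied.
#'
#' @param p an [lg_params()] object.
#' @param tol relative tolerance for the equality comparisons
#'   (default `1e-12`, scaled by magnitude).
#' @return An object of class `lg_case`: list with `case_label`,
#'   `n_positive`, the `lg_discriminants` used, and an optional `flag`.
#' @export
lg_classify_case <- function(p, tol = 1e-12) {
  p <- as_params(p)
  d <- lg_discriminants(p)
  scale_m <- max(1, abs(d$m_threshold))
  # with k2 = 0 the threshold is -Inf and m > threshold always
  m_eq  <- is.finite(d$m_threshold) &&
    abs(p$m - d$m_threshold) <= tol * scale_m
  m_gt  <- !m_eq && p$m > d$m_threshold
  B_neg <- d$B < 0
  scale_D <- max(1, d$B^2, abs(d$Delta))
  Delta_zero <- abs(d$Delta) <= tol * scale_D
  Delta_pos  <- !Delta_zero && d$Delta > 0

  flag <- NULL
  if (m_gt) {
    label <- "CASE1_i";  n <- 1L
  } else if (m_eq && B_neg) {
    label <- "CASE1_ii"; n <- 1L
  } else if (!m_gt && !m_eq && B_neg && Delta_zero) {
    label <- "CASE1_iii"; n <- 1L
  } else if (!m_gt && !m_eq && B_neg && Delta_pos) {
    label <- "CASE2"; n <- 2L
  } else {
    label <- "CASE3"; n <- 0L
    if (!m_gt && !B_neg && Delta_pos)
      flag <- "B >= 0 with m below threshold and Delta > 0: not covered by the case list; classified as no positive equilibrium by the literal rule"
  }
  structure(list(case_label = label, n_positive = n,
                 discriminants = d, flag = flag),
            class = "lg_case")
}

#' @export
print.lg_case <- function(x, ...) {
  cat(sprintf("Existence case %s: %d positive equilibri%s\n",
              x$case_label, x$n_positive,
              if (x$n_positive == 1L) "um" else "a"))
  if (!is.null(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

#' Positive (interior) equilibria
#'
#' Solves the equilibrium quadratic for the prey coordinate with the
#' numerically stable root formula (larger-magnitude root from
#' \eqn{q = -(B + \mathrm{sign}(B)\sqrt\Delta)/2}, companion root via the
#' product of roots, avoiding catastrophic cancellation), keeps roots with
#' `x > 0`, and pairs each with the predator nullcline value
#' \eqn{y = r_2((1-m)x + k_2)/a_2}. Labels follow the existence
#' classification: `E3_1` for the unique-equilibrium cases, `E3_minus` /
#' `E3_plus` (in increasing `x`) when two coexist.
#'
#' @param p an [lg_params()] object.
#' @param tol roots with `x <=` `tol` (scaled by the prey carrying
#'   capacity) are treated as boundary collisions and excluded.
#' @return List of `lg_equilibrium` objects; empty in the no-equilibrium
#'   case. The list length always matches `lg_classify_case(p)$n_positive`.
#' @examples
#' p <- lg_params(11, 5, 4, 6.5, 8, 2, 2, m = 0.4)
#' lg_positive_equilibria(p)   # x* ~ 1.4521, y* ~ 11.485
#' @export
lg_positive_equilibria <- function(p, tol = 1e-12) {
  p <- as_params(p)
  cls <- lg_classify_case(p)
  if (cls$n_positive == 0L) return(list())
  d <- cls$discriminants
  om <- 1 - p$m
  a <- p$a2 * p$b1 * om
  cc <- om * p$a1 * p$r2 * p$k2 - p$a2 * p$r1 * p$k1
  Delta <- max(d$Delta, 0)  # CASE1_iii: tolerance-zero discriminant
  sq <- sqrt(Delta)
  if (d$B >= 0) {
    q <- -(d$B + sq) / 2
  } else {
    q <- -(d$B - sq) / 2
  }
  roots <- if (q == 0) c(0, 0) else c(q / a, cc / q)
  pos_tol <- tol * max(1, p$r1 / p$b1)
  roots <- sort(roots[roots > pos_tol])
  nullcline_y <- function(x) p$r2 * (om * x + p$k2) / p$a2
  if (cls$n_positive == 1L) {
    xs <- roots[length(roots)]   # the (-B + sqrt(Delta)) root
    return(list(new_equilibrium(xs, nullcline_y(xs), "E3_1")))
  }
  if (length(roots) != 2L)
    stop("internal inconsistency: classification predicts two positive ",
         "equilibria but ", length(roots), " positive root(s) found",
         call. = FALSE)
  list(new_equilibrium(roots[1], nullcline_y(roots[1]), "E3_minus"),
       new_equilibrium(roots[2], nullcline_y(roots[2]), "E3_plus"))
}

#' All equilibria with stability verdicts
#'
#' Convenience wrapper assembling boundary and positive equilibria with
#' their linearized stability verdicts, the discriminant data and the
#' existence classification; this is the object serialized by the
#' `equilibria` command-line subcommand.
#'
#' @param p an [lg_params()] object.
#' @return A list with components `parameters`, `discriminants`, `case`,
#'   and `equilibria` (list of `lg_equilibrium`, each with a `stability`
#'   field filled in).
#' @export
lg_equilibria_report <- function(p) {
  p <- as_params(p)
  eqs <- c(lg_boundary_equilibria(p), lg_positive_equilibria(p))
  eqs <- lapply(eqs, function(e) {
    e$stability <- lg_stability(p, e)
    e
  })
  list(parameters = p,
       discriminants = lg_discriminants(p),
       case = lg_classify_case(p),
       equilibria = eqs)
}
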