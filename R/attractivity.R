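#' Global-attractivity and permanence conditions
#'
#' Evaluates the four sufficient conditions appearing in the
#' global-attractivity theory as signed margins (condition holds iff the
#' margin is strictly positive):
#'
#' * `C1`: \eqn{a_2 b_1 r_1 k_1 - a_1 r_1 r_2 - a_1 b_1 r_2 k_2 > 0} -
#'   the refuge-free (`m = 0`) attractivity condition;
#' * `C2`: \eqn{2 a_2 b_1 M + (a_2 b_1 k_1 - a_2 r_1 - a_1 r_2) > 0}, with
#'   \eqn{L = (r_1 r_2 + b_1 r_2 k_2)/(a_2 b_1)} and
#'   \eqn{M = (r_1 k_1 - a_1 L)/(b_1 k_1)} - the second condition of the
#'   older refuge-free theorem. It belongs to the `m = 0` theory and is
#'   evaluated with those definitions regardless of `m`; the iterative
#'   certificate shows it is superfluous, so it is computed for reporting
#'   and comparison only and never gates anything;
#' * `C3`: \eqn{a_2 b_1 r_1 k_1 - a_1(1-m)^2 r_1 r_2 -
#'   a_1(1-m) b_1 r_2 k_2 > 0} - the refuge-aware attractivity condition;
#'   at `m = 0` its margin equals the `C1` margin exactly;
#' * `C4`: \eqn{a_2 b_1 r_1 k_1 - a_1(1-m)^2 r_1 r_2 > 0} - the
#'   Holling-Tanner (`k2 = 0`) specialization, where it coincides with
#'   `C3`; it is flagged as not meaningful when `k2 > 0`.
#'
#' @param p an [lg_params()] object.
#' @return An object of class `lg_conditions`: list with components `c1`,
#'   `c2`, `c3`, `c4` (each `list(holds, margin)` plus a `note` where one
#'   applies), and the auxiliary constants `L` and `M`.
#' @examples
#' p <- lg_params(11, 5, 4, 6.5, 8, 2, 2, m = 0.4)
#' lg_conditions(p)$c3$margin   # 396.28: C3 holds
#' @export
lg_conditions <- function(p) {
  p <- as_params(p)
  om <- 1 - p$m
  base <- p$a2 * p$b1 * p$r1 * p$k1
  c1m <- base - p$a1 * p$r1 * p$r2 - p$a1 * p$b1 * p$r2 * p$k2
  L <- (p$r1 * p$r2 + p$b1 * p$r2 * p$k2) / (p$a2 * p$b1)
  M <- (p$r1 * p$k1 - p$a1 * L) / (p$b1 * p$k1)
  c2m <- 2 * p$a2 * p$b1 * M + (p$a2 * p$b1 * p$k1 - p$a2 * p$r1 -
                                  p$a1 * p$r2)
  c3m <- base - p$a1 * om^2 * p$r1 * p$r2 - p$a1 * om * p$b1 * p$r2 * p$k2
  c4m <- base - p$a1 * om^2 * p$r1 * p$r2
  cond <- function(margin, note = NULL) {
    out <- list(holds = margin > 0, margin = margin)
    if (!is.null(note)) out$note <- note
    out
  }
  structure(list(
    c1 = cond(c1m),
    c2 = cond(c2m, note = paste("belongs to the m = 0 theory (uses its M",
                                "and L); reported for comparison only,",
                                "never gates a certificate")),
    c3 = cond(c3m),
    c4 = cond(c4m, note = if (p$k2 > 0)
      "only meaningful in Holling-Tanner mode (k2 = 0)" else NULL),
    L = L, M = M), class = "lg_conditions")
}

#' @export
print.lg_conditions <- function(x, ...) {
  fmt <- function(nm, c) cat(sprintf("  %s: %-5s margin = %.6g%s\n", nm,
                                     c$holds, c$margin,
                                     if (!is.null(c$note)) " *" else ""))
  cat("Attractivity/permanence conditions (holds iff margin > 0)\n")
  fmt("C1", x$c1); fmt("C2", x$c2); fmt("C3", x$c3); fmt("C4", x$c4)
  cat(sprintf("  L = %.6g, M = %.6g  (* see $note)\n", x$L, x$M))
  invisible(x)
}

#' Comparison-argument slack for the bounding sequences
#'
#' The iterative certificate needs a slack \eqn{\varepsilon > 0} small
#' enough that the strict inequality
#' \deqn{\frac{a_2 b_1 r_1 k_1 - a_1(1-m)^2 r_1 r_2 -
#'   a_1(1-m) b_1 r_2 k_2}{a_2 b_1 k_1} - \left(
#'   \frac{a_1(1-m)^2 r_2}{a_2 k_1} + \frac{a_1(1-m)}{k_1}\right)
#'   \varepsilon > 0}
#' survives, and additionally small enough that the first-round lower
#' bounds \eqn{m_1^{(1)}, m_2^{(1)}} stay strictly positive (these are
#' further linear constraints on \eqn{\varepsilon} that the slack
#' inequality alone does not imply). The returned value is half the
#' minimum of the three critical values, so every required inequality is
#' strict with a factor-two margin.
#'
#' @param p an [lg_params()] object; condition `C3` must hold.
#' @return A single positive number, with attribute `"critical"` holding
#'   the three critical values (named `slack`, `m1_positive`,
#'   `m2_positive`).
#' @export
lg_epsilon <- function(p) {
  p <- as_params(p)
  cond <- lg_conditions(p)
  if (!cond$c3$holds)
    stop("condition C3 fails (margin ", format(cond$c3$margin),
         "); the attractivity certificate requires C3", call. = FALSE)
  om <- 1 - p$m
  # critical epsilon of the slack inequality
  slack0 <- cond$c3$margin / (p$a2 * p$b1 * p$k1)
  slope <- p$a1 * om^2 * p$r2 / (p$a2 * p$k1) + p$a1 * om / p$k1
  e_slack <- slack0 / slope
  # m1^(1)(eps) = m1_0 - beta1 * eps, linear in eps
  m1_0 <- cond$c3$margin / (p$a2 * p$b1^2 * p$k1)
  beta1 <- p$a1 * om * (om * p$r2 / p$a2 + 1) / (p$k1 * p$b1) + 1
  e_m1 <- m1_0 / beta1
  # m2^(1)(eps) = r2((1-m) m1^(1)(eps) + k2)/a2 - eps
  m2_0 <- p$r2 * (om * m1_0 + p$k2) / p$a2
  beta2 <- p$r2 * om * beta1 / p$a2 + 1
  e_m2 <- m2_0 / beta2
  crit <- c(slack = e_slack, m1_positive = e_m1, m2_positive = e_m2)
  structure(0.5 * min(crit), critical = crit)
}

# Value of the slack inequality left-hand side at a given epsilon.
slack_inequality <- function(p, epsilon) {
  om <- 1 - p$m
  cond <- lg_conditions(p)
  cond$c3$margin / (p$a2 * p$b1 * p$k1) -
    (p$a1 * om^2 * p$r2 / (p$a2 * p$k1) + p$a1 * om / p$k1) * epsilon
}

#' Monotone iterative bounding sequences
#'
#' Constructs the four sequences of ultimate bounds that certify global
#' attractivity of the positive equilibrium when condition `C3` holds:
#' prey upper `M1`, predator upper `M2`, prey lower `m1`, predator lower
#' `m2`. The first round is seeded from the logistic comparison bounds
#' \deqn{M_1^{(1)} = r_1/b_1 + \varepsilon, \quad
#'   M_2^{(1)} = r_2((1-m)M_1^{(1)} + k_2)/a_2 + \varepsilon, \quad
#'   m_1^{(1)} = (r_1 - a_1(1-m)M_2^{(1)}/k_1)/b_1 - \varepsilon, \quad
#'   m_2^{(1)} = r_2((1-m)m_1^{(1)} + k_2)/a_2 - \varepsilon,}
#' and subsequent rounds apply the recurrences
#' \deqn{M_1^{(n)} = \frac{r_1 - \frac{a_1(1-m) m_2^{(n-1)}}
#'   {(1-m)M_1^{(n-1)} + k_1}}{b_1} + \frac{\varepsilon}{n}, \qquad
#'   M_2^{(n)} = \frac{r_2\left((1-m)M_1^{(n)} + k_2\right)}{a_2} +
#'   \frac{\varepsilon}{n},}
#' \deqn{m_1^{(n)} = \frac{r_1 - \frac{a_1(1-m) M_2^{(n)}}
#'   {(1-m)m_1^{(n-1)} + k_1}}{b_1} - \frac{\varepsilon}{n}, \qquad
#'   m_2^{(n)} = \frac{r_2\left((1-m)m_1^{(n)} + k_2\right)}{a_2} -
#'   \frac{\varepsilon}{n},}
#' kept exactly in this form (including the vanishing
#' \eqn{\varepsilon/n} terms), so the recorded iterates are genuine
#' ultimate bounds: the upper sequences are non-increasing, the lower
#' ones non-decreasing, and every positive solution is eventually
#' squeezed between them.
#'
#' Because the \eqn{\varepsilon/n} offsets decay only like \eqn{1/n}, the
#' raw iterates approach their limits at rate \eqn{O(\varepsilon/n)}. The
#' limits themselves - the quantities the attractivity theorem is about -
#' satisfy the same recurrences with the vanishing offset removed, so
#' they are computed by iterating the offset-free map, which converges
#' geometrically; the squeezed limit equals the unique positive
#' equilibrium. Both views are returned: the raw sequences (the
#' certificate) and the `limits` (their common limit).
#'
#' @param p an [lg_params()] object; `C3` must hold.
#' @param n_max maximum number of rounds (default 10000).
#' @param tol convergence tolerance on the change of the bracket widths
#'   (default `1e-10`).
#' @param epsilon comparison slack; default [lg_epsilon()] of `p`. An
#'   over-large value that drives a lower bound non-positive is an error
#'   (it would invalidate the certificate), never silently repaired.
#' @return An object of class `lg_bounds`: list with `epsilon`,
#'   `sequences` (data frame `n, M1, M2, m1, m2` of the raw iterates),
#'   `limits` (named vector `x_lower, x_upper, y_lower, y_upper`),
#'   `converged`, and `n_iterations` (rounds used by the limit
#'   iteration).
#' @examples
#' p <- lg_params(11, 5, 4, 6.5, 8, 2, 2, m = 0.4)
#' b <- lg_iterate_bounds(p)
#' b$limits   # all four within tol of (x*, y*) = (1.4521, 11.485)
#' @export
lg_iterate_bounds <- function(p, n_max = 10000L, tol = 1e-10,
                              epsilon = NULL) {
  p <- as_params(p)
  if (is.null(epsilon)) epsilon <- as.numeric(lg_epsilon(p))
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  cond <- lg_conditions(p)
  if (!cond$c3$holds)
    stop("condition C3 fails; the bounding sequences require C3",
         call. = FALSE)
  om <- 1 - p$m

  step <- function(M1p, m1p, m2p, eps_n) {
    M1 <- (p$r1 - p$a1 * om * m2p / (om * M1p + p$k1)) / p$b1 + eps_n
    M2 <- p$r2 * (om * M1 + p$k2) / p$a2 + eps_n
    m1 <- (p$r1 - p$a1 * om * M2 / (om * m1p + p$k1)) / p$b1 - eps_n
    m2 <- p$r2 * (om * m1 + p$k2) / p$a2 - eps_n
    c(M1, M2, m1, m2)
  }
  seed <- function(eps) {
    M1 <- p$r1 / p$b1 + eps
    M2 <- p$r2 * (om * M1 + p$k2) / p$a2 + eps
    m1 <- (p$r1 - p$a1 * om * M2 / p$k1) / p$b1 - eps
    m2 <- p$r2 * (om * m1 + p$k2) / p$a2 - eps
    c(M1, M2, m1, m2)
  }

  # offset-free iteration: the limit of the epsilon-sequences
  lim <- seed(0)
  n_lim <- 1L
  converged <- FALSE
  width <- c(lim[1] - lim[3], lim[2] - lim[4])
  while (n_lim < n_max) {
    n_lim <- n_lim + 1L
    lim <- step(lim[1], lim[3], lim[4], 0)
    w <- c(lim[1] - lim[3], lim[2] - lim[4])
    if (max(abs(w - width)) < tol) { converged <- TRUE; break }
    width <- w
  }

  # raw epsilon-sequences, recorded for the same number of rounds
  n_seq <- n_lim
  M1 <- M2 <- m1 <- m2 <- numeric(n_seq)
  s <- seed(epsilon)
  M1[1] <- s[1]; M2[1] <- s[2]; m1[1] <- s[3]; m2[1] <- s[4]
  check_pos <- function(n, v1, v2) {
    if (v1 <= 0 || v2 <= 0)
      stop("lower-bound sequence became non-positive at round ", n,
           " (m1 = ", format(v1), ", m2 = ", format(v2), "): epsilon too ",
           "large or C3 marginal; the certificate is invalid as ",
           "constructed", call. = FALSE)
  }
  check_pos(1L, m1[1], m2[1])
  if (n_seq > 1L) for (n in 2:n_seq) {
    s <- step(M1[n - 1], m1[n - 1], m2[n - 1], epsilon / n)
    M1[n] <- s[1]; M2[n] <- s[2]; m1[n] <- s[3]; m2[n] <- s[4]
    check_pos(n, m1[n], m2[n])
  }

  structure(list(
    epsilon = epsilon,
    sequences = data.frame(n = seq_len(n_seq), M1 = M1, M2 = M2,
                           m1 = m1, m2 = m2),
    limits = c(x_lower = lim[3], x_upper = lim[1],
               y_lower = lim[4], y_upper = lim[2]),
    converged = converged,
    n_iterations = n_lim), class = "lg_bounds")
}

#' @export
print.lg_bounds <- function(x, ...) {
  cat(sprintf(
    "Iterative bounding sequences: %d rounds, epsilon = %.6g, %s\n",
    x$n_iterations, x$epsilon,
    if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  prey limit     [%.8g, %.8g]\n",
              x$limits["x_lower"], x$limits["x_upper"]))
  cat(sprintf("  predator limit [%.8g, %.8g]\n",
              x$limits["y_lower"], x$limits["y_upper"]))
  invisible(x)
}

#' Permanence box from the first-round comparison bounds
#'
#' Under condition `C3` the system is permanent: every positive solution
#' eventually enters and stays in the box given by the first-round
#' comparison bounds with the slack removed,
#' \deqn{\bar x = r_1/b_1, \quad \bar y = r_2((1-m)\bar x + k_2)/a_2,
#'   \quad \underline{x} = (r_1 - a_1(1-m)\bar y / k_1)/b_1, \quad
#'   \underline{y} = r_2((1-m)\underline{x} + k_2)/a_2,}
#' all strictly positive when `C3` holds.
#'
#' @param p an [lg_params()] object; `C3` must hold.
#' @return Named numeric vector `c(x_lower, x_upper, y_lower, y_upper)`.
#' @export
lg_permanence_bounds <- function(p) {
  p <- as_params(p)
  cond <- lg_conditions(p)
  if (!cond$c3$holds)
    stop("condition C3 fails (margin ", format(cond$c3$margin),
         "); permanence is only certified under C3", call. = FALSE)
  om <- 1 - p$m
  x_up <- p$r1 / p$b1
  y_up <- p$r2 * (om * x_up + p$k2) / p$a2
  x_lo <- (p$r1 - p$a1 * om * y_up / p$k1) / p$b1
  y_lo <- p$r2 * (om * x_lo + p$k2) / p$a2
  c(x_lower = x_lo, x_upper = x_up, y_lower = y_lo, y_upper = y_up)
}

#' Global-attractivity certificate
#'
#' End-to-end certificate for a parameter set: checks the conditions,
#' selects the slack, runs the bounding sequences, and compares their
#' limit with the positive equilibrium from the quadratic. Parameter sets
#' with two interior equilibria are refused - the iterative argument
#' only covers the unique-equilibrium regime, and bistability makes a
#' global certificate impossible.
#'
#' @param p an [lg_params()] object.
#' @param n_max,tol passed to [lg_iterate_bounds()].
#' @return An object of class `lg_certificate`: list with `conditions`,
#'   `epsilon`, `bounds` (the `lg_bounds` object), `equilibrium` (the
#'   unique positive equilibrium with stability verdict), and
#'   `agreement_gap` (max absolute difference between the four sequence
#'   limits and the equilibrium coordinates).
#' @export
lg_certify <- function(p, n_max = 10000L, tol = 1e-10) {
  p <- as_params(p)
  cls <- lg_classify_case(p)
  if (cls$case_label == "CASE2")
    stop("two positive equilibria (", cls$case_label, "): the iterative ",
         "certificate only covers the unique-equilibrium regime and is ",
         "not extrapolated to bistable configurations", call. = FALSE)
  cond <- lg_conditions(p)
  if (!cond$c3$holds)
    stop("condition C3 fails (margin ", format(cond$c3$margin),
         "); no attractivity certificate", call. = FALSE)
  bounds <- lg_iterate_bounds(p, n_max = n_max, tol = tol)
  eqs <- lg_positive_equilibria(p)
  if (length(eqs) != 1L)
    stop("internal inconsistency: C3 holds but ", length(eqs),
         " positive equilibria found", call. = FALSE)
  eq <- eqs[[1]]
  eq$stability <- lg_stability(p, eq)
  gap <- max(abs(bounds$limits[c("x_lower", "x_upper")] - eq$x),
             abs(bounds$limits[c("y_lower", "y_upper")] - eq$y))
  structure(list(parameters = p, conditions = cond,
                 epsilon = bounds$epsilon, bounds = bounds,
                 equilibrium = eq, agreement_gap = gap),
            class = "lg_certificate")
}

#' @export
print.lg_certificate <- function(x, ...) {
  cat("Global-attractivity certificate\n")
  cat(sprintf("  C3 margin %.6g (holds), epsilon = %.6g\n",
              x$conditions$c3$margin, x$epsilon))
  cat(sprintf("  positive equilibrium (%.6g, %.6g), %s\n",
              x$equilibrium$x, x$equilibrium$y,
              x$equilibrium$stability$label))
  cat(sprintf("  bound limits agree with the equilibrium to %.3g\n",
              x$agreement_gap))
  invisible(x)
}
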