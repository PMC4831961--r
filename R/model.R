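#' Vector field of the refuge-modified Leslie-Gower system
#'
#' Evaluates the right-hand side
#' \deqn{\dot x = \left(r_1 - b_1 x - \frac{a_1(1-m)y}{(1-m)x + k_1}\right)x,
#'   \qquad
#'   \dot y = \left(r_2 - \frac{a_2 y}{(1-m)x + k_2}\right)y}
#' at a single state.
#'
#' @param p an [lg_params()] object.
#' @param state numeric vector `c(x, y)` of non-negative densities.
#' @return Named numeric vector `c(dx, dy)`.
#' @details With `k2 = 0` (Holling-Tanner mode) the predator equation has
#'   denominator `(1-m)x`, which vanishes at `x = 0`; evaluating there with
#'   `y > 0` is a domain error. A state with `y = 0` is always fine (the
#'   predator equation is identically zero on the prey axis).
#' @export
lg_vector_field <- function(p, state) {
  p <- as_params(p)
  s <- check_state(p, state)
  x <- s[1]; y <- s[2]
  c(dx = unname(prey_rhs(p, x, y)), dy = unname(pred_rhs(p, x, y)))
}

# Unchecked right-hand sides, shared with the integrator.
prey_rhs <- function(p, x, y) {
  (p$r1 - p$b1 * x - p$a1 * (1 - p$m) * y / ((1 - p$m) * x + p$k1)) * x
}
pred_rhs <- function(p, x, y) {
  if (y == 0) return(0)
  (p$r2 - p$a2 * y / ((1 - p$m) * x + p$k2)) * y
}

check_state <- function(p, state) {
  if (!is.numeric(state) || length(state) != 2L || !all(is.finite(state)))
    stop("state must be a finite numeric vector c(x, y)", call. = FALSE)
  if (any(state < 0))
    stop("state densities must be non-negative (got x = ", state[1],
         ", y = ", state[2], ")", call. = FALSE)
  if (p$k2 == 0 && state[1] == 0 && state[2] > 0)
    stop("with k2 = 0 the predator equation is singular at x = 0; ",
         "x > 0 is required wherever y > 0", call. = FALSE)
  as.numeric(state)
}

#' Jacobian matrix of the vector field
#'
#' Analytic partial derivatives of the system right-hand side, used for
#' linearized stability and to accelerate the stiff integrator.
#'
#' @inheritParams lg_vector_field
#' @return A 2x2 numeric matrix, rows = equations (prey, predator),
#'   columns = states (x, y).
#' @export
lg_jacobian <- function(p, state) {
  p <- as_params(p)
  s <- check_state(p, state)
  jac_unchecked(p, s[1], s[2])
}

jac_unchecked <- function(p, x, y) {
  om <- 1 - p$m
  d1 <- om * x + p$k1
  d2 <- om * x + p$k2
  j11 <- p$r1 - 2 * p$b1 * x - p$a1 * om * p$k1 * y / d1^2
  j12 <- -p$a1 * om * x / d1
  if (y == 0) {
    # predator equation vanishes identically on y = 0; its linearization
    # is (0, r2 - a2*y/d2) evaluated at y = 0
    j21 <- 0
    j22 <- p$r2
  } else {
    j21 <- p$a2 * om * y^2 / d2^2
    j22 <- p$r2 - 2 * p$a2 * y / d2
  }
  matrix(c(j11, j21, j12, j22), 2L, 2L,
         dimnames = list(c("prey", "predator"), c("x", "y")))
}
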