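#' Integrate a trajectory of the system
#'
#' Adaptive-step numerical integration of the model from a positive
#' initial condition, with the analytic Jacobian supplied to the solver.
#' Defaults (`rtol = 1e-9`, `atol = 1e-12`) keep integrator noise well
#' below the model-level tolerances used in the equilibrium-convergence
#' checks; `t_end = 50` comfortably passes the transient for systems with
#' rates of order ten, and is overridable.
#'
#' The model is only meaningful on the non-negative quadrant. Interior
#' trajectories stay positive analytically, so a solver value below
#' `-1e-9` aborts with an error (integrator failure, never clipped
#' silently); harmless round-off undershoot in `(-1e-9, 0)` is clipped to
#' zero and flagged via the `clipped` attribute.
#'
#' @param p an [lg_params()] object.
#' @param initial numeric `c(x, y)`, both strictly positive (positive
#'   solutions are the object of the attractivity theory).
#' @param t_end final time (> 0).
#' @param n_grid number of output sample times (uniform on `[0, t_end]`);
#'   the adaptive solver's accuracy does not depend on this grid.
#' @param rtol,atol relative/absolute integrator tolerances.
#' @param method a [deSolve::ode()] method name (default `"lsoda"`).
#' @return An object of class `lg_trajectory`: data frame with columns
#'   `time`, `x`, `y`; attributes `params`, `initial`, `clipped`.
#' @examples
#' p <- lg_params(11, 5, 4, 6.5, 8, 2, 2, m = 0.4)
#' tr <- lg_integrate(p, c(3, 12), t_end = 50)
#' tail(tr, 1)   # near the equilibrium (1.4521, 11.485)
#' @export
lg_integrate <- function(p, initial, t_end = 50, n_grid = 1001L,
                         rtol = 1e-9, atol = 1e-12, method = "lsoda") {
  p <- as_params(p)
  if (!is.numeric(initial) || length(initial) != 2L ||
      !all(is.finite(initial)) || any(initial <= 0))
    stop("initial condition must be c(x, y) with both strictly positive",
         call. = FALSE)
  if (!is.numeric(t_end) || t_end <= 0)
    stop("t_end must be positive", call. = FALSE)
  times <- seq(0, t_end, length.out = max(2L, as.integer(n_grid)))
  rhs <- function(t, state, parms) {
    list(c(prey_rhs(p, state[1], state[2]),
           pred_rhs(p, state[1], state[2])))
  }
  jac <- function(t, state, parms) jac_unchecked(p, state[1], state[2])
  sol <- deSolve::ode(y = c(x = initial[1], y = initial[2]), times = times,
                      func = rhs, parms = NULL, jacfunc = jac,
                      jactype = "fullusr", method = method,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed near t = ", max(sol[, "time"]), call. = FALSE)
  out <- as.data.frame(sol)
  names(out) <- c("time", "x", "y")
  low <- min(out$x, out$y)
  if (low < -1e-9)
    stop("trajectory left the non-negative quadrant (minimum ",
         format(low), " at t = ",
         format(out$time[which.min(pmin(out$x, out$y))]),
         "); the model is only meaningful for non-negative densities",
         call. = FALSE)
  clipped <- low < 0
  out$x <- pmax(out$x, 0)
  out$y <- pmax(out$y, 0)
  structure(out, params = p, initial = initial, clipped = clipped,
            class = c("lg_trajectory", "data.frame"))
}

#' @export
print.lg_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Trajectory: t in [%g, %g] (%d samples) from (%g, %g), m = %g\n",
    min(x$time), max(x$time), nrow(x),
    attr(x, "initial")[1], attr(x, "initial")[2], p$m))
  cat(sprintf("  final state (%.6g, %.6g)%s\n",
              x$x[nrow(x)], x$y[nrow(x)],
              if (isTRUE(attr(x, "clipped"))) "  [round-off clipped]"
              else ""))
  invisible(x)
}

#' Refuge-fraction sweep
#'
#' Re-analyzes the system over a grid of refuge fractions, holding every
#' other coefficient fixed: existence classification, attractivity margin
#' `C3`, the positive equilibria and their stability. Increasing the
#' refuge shrinks the predation-pressure terms \eqn{a_1(1-m)^2 r_1 r_2}
#' and \eqn{a_1(1-m) b_1 r_2 k_2}, so the `C3` margin is non-decreasing
#' in `m`: more refuge makes coexistence easier to certify.
#'
#' @param p an [lg_params()] object whose `m` is ignored.
#' @param m_grid numeric vector of refuge fractions in `[0, 1)`.
#' @return A data frame, one row per grid point, with columns `m`,
#'   `case_label`, `n_positive`, `c3_margin`, `c3_holds`, `x_star`,
#'   `y_star`, `stability` (of `E3_1`/`E3_plus`; `NA` when no positive
#'   equilibrium exists).
#' @export
lg_sweep_refuge <- function(p, m_grid) {
  p <- as_params(p)
  cols <- function(m, case_label, n_positive, c3_margin, c3_holds,
                   x_star, y_star, stability)
    data.frame(m = m, case_label = case_label, n_positive = n_positive,
               c3_margin = c3_margin, c3_holds = c3_holds,
               x_star = x_star, y_star = y_star, stability = stability,
               stringsAsFactors = FALSE)
  if (!length(m_grid)) return(cols(numeric(0), character(0), integer(0),
                                   numeric(0), logical(0), numeric(0),
                                   numeric(0), character(0)))
  rows <- lapply(m_grid, function(m) {
    pm <- lg_params(p$r1, p$b1, p$a1, p$k1, p$r2, p$a2, p$k2, m = m,
                    holling_tanner = p$holling_tanner)
    cls <- lg_classify_case(pm)
    cond <- lg_conditions(pm)
    eqs <- lg_positive_equilibria(pm)
    top <- if (length(eqs)) eqs[[length(eqs)]] else NULL
    cols(m, cls$case_label, cls$n_positive, cond$c3$margin,
         cond$c3$holds,
         if (is.null(top)) NA_real_ else top$x,
         if (is.null(top)) NA_real_ else top$y,
         if (is.null(top)) NA_character_
         else lg_stability(pm, top)$label)
  })
  do.call(rbind, rows)
}
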