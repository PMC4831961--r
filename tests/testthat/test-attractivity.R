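test_that("condition margins match direct evaluation on the example", {
  p <- example_params()
  cond <- lg_conditions(p)
  # refuge-aware condition, written out from the printed coefficients:
  # a2 b1 r1 k1 - a1 (1-m)^2 r1 r2 - a1 (1-m) b1 r2 k2
  expect_equal(cond$c3$margin,
               2 * 5 * 11 * 6.5 - 4 * 0.36 * 11 * 8 - 4 * 0.6 * 5 * 8 * 2,
               tolerance = 1e-12)
  expect_true(cond$c3$holds)
  expect_equal(cond$c1$margin, 2 * 5 * 11 * 6.5 - 4 * 11 * 8 -
                 4 * 5 * 8 * 2, tolerance = 1e-12)
  expect_equal(cond$L, (11 * 8 + 5 * 8 * 2) / (2 * 5), tolerance = 1e-12)
  expect_equal(cond$M, (11 * 6.5 - 4 * cond$L) / (5 * 6.5),
               tolerance = 1e-12)
  expect_equal(cond$c2$margin,
               2 * 2 * 5 * cond$M + (2 * 5 * 6.5 - 2 * 11 - 4 * 8),
               tolerance = 1e-12)
  expect_equal(cond$c4$margin, 2 * 5 * 11 * 6.5 - 4 * 0.36 * 11 * 8,
               tolerance = 1e-12)
})

test_that("without refuge the two attractivity margins coincide", {
  set.seed(404)
  for (rep in 1:25) {
    p <- rand_params()
    p0 <- lg_params(p$r1, p$b1, p$a1, p$k1, p$r2, p$a2, p$k2, m = 0)
    cond <- lg_conditions(p0)
    expect_equal(cond$c3$margin, cond$c1$margin, tolerance = 1e-12)
  }
})

test_that("slack selection keeps every required inequality strict", {
  p <- example_params()
  eps <- lg_epsilon(p)
  expect_gt(as.numeric(eps), 0)
  crit <- attr(eps, "critical")
  expect_equal(as.numeric(eps), 0.5 * min(crit))
  om <- 1 - p$m
  cond <- lg_conditions(p)
  slack <- function(e) cond$c3$margin / (p$a2 * p$b1 * p$k1) -
    (p$a1 * om^2 * p$r2 / (p$a2 * p$k1) + p$a1 * om / p$k1) * e
  expect_gt(slack(eps), 0)
  # the slack inequality hits zero exactly at its own critical value
  expect_equal(slack(crit[["slack"]]), 0, tolerance = 1e-12)
  # first-round lower bounds hit zero exactly at theirs
  m1_first <- function(e) {
    M1 <- p$r1 / p$b1 + e
    M2 <- p$r2 * (om * M1 + p$k2) / p$a2 + e
    (p$r1 - p$a1 * om * M2 / p$k1) / p$b1 - e
  }
  expect_equal(m1_first(crit[["m1_positive"]]), 0, tolerance = 1e-10)
  expect_gt(m1_first(as.numeric(eps)), 0)
  # refusal without the attractivity condition
  expect_error(lg_epsilon(no_equilibrium_params()), "C3")
})

test_that("slack scales linearly to zero with a vanishing margin", {
  # shrink the C3 margin toward 0+ by raising predation pressure a1
  p <- example_params()
  margin_zero_a1 <- 2 * 5 * 11 * 6.5 / (0.36 * 11 * 8 + 0.6 * 5 * 8 * 2)
  eps <- vapply(c(0.9, 0.99, 0.999), function(f) {
    q <- lg_params(11, 5, f * margin_zero_a1, 6.5, 8, 2, 2, m = 0.4)
    as.numeric(lg_epsilon(q))
  }, numeric(1))
  expect_true(all(diff(eps) < 0))
  expect_lt(eps[3] / eps[1], 0.02)
})

test_that("bounding sequences are monotone and squeeze the equilibrium", {
  p <- example_params()
  b <- lg_iterate_bounds(p, n_max = 200)
  expect_true(b$converged)
  s <- b$sequences
  expect_true(all(diff(s$M1) <= 0))
  expect_true(all(diff(s$M2) <= 0))
  expect_true(all(diff(s$m1) >= 0))
  expect_true(all(diff(s$m2) >= 0))
  expect_true(all(s$m1 > 0 & s$m2 > 0))
  expect_true(all(s$m1 <= s$M1 & s$m2 <= s$M2))
  e <- lg_positive_equilibria(p)[[1]]
  # every raw iterate brackets the equilibrium strictly
  expect_true(all(s$m1 < e$x & e$x < s$M1))
  expect_true(all(s$m2 < e$y & e$y < s$M2))
  # and the sequence limits are the equilibrium
  expect_lt(max(abs(b$limits[c("x_lower", "x_upper")] - e$x)), 1e-6)
  expect_lt(max(abs(b$limits[c("y_lower", "y_upper")] - e$y)), 1e-6)
})

test_that("sequence limits equal the equilibrium on random draws", {
  set.seed(505)
  for (p in rand_c3_params(30)) {
    b <- lg_iterate_bounds(p)
    expect_true(b$converged)
    s <- b$sequences
    expect_true(all(diff(s$M1) <= 0) && all(diff(s$M2) <= 0))
    expect_true(all(diff(s$m1) >= 0) && all(diff(s$m2) >= 0))
    expect_true(all(s$m1 > 0 & s$m2 > 0))
    eqs <- lg_positive_equilibria(p)
    expect_length(eqs, 1L)   # the condition forces the one-root case
    e <- eqs[[1]]
    expect_lt(max(abs(b$limits - c(e$x, e$x, e$y, e$y))), 1e-6)
  }
})

test_that("an oversized slack is surfaced as an error, never masked", {
  p <- example_params()
  crit <- attr(lg_epsilon(p), "critical")
  expect_error(lg_iterate_bounds(p, epsilon = 1.5 * crit[["m1_positive"]]),
               "non-positive")
  expect_error(lg_iterate_bounds(p, epsilon = 0), "positive")
})

test_that("permanence box is positive and strictly contains the equilibrium", {
  p <- example_params()
  box <- lg_permanence_bounds(p)
  expect_equal(unname(box["x_upper"]), 11 / 5)
  expect_true(all(box > 0))
  e <- lg_positive_equilibria(p)[[1]]
  expect_true(box["x_lower"] < e$x && e$x < box["x_upper"])
  expect_true(box["y_lower"] < e$y && e$y < box["y_upper"])
  expect_error(lg_permanence_bounds(no_equilibrium_params()), "C3")
})

test_that("a near-total refuge releases the prey to its carrying capacity", {
  p <- example_params()
  q <- lg_params(p$r1, p$b1, p$a1, p$k1, p$r2, p$a2, p$k2, m = 0.999)
  expect_true(lg_conditions(q)$c3$holds)
  box <- lg_permanence_bounds(q)
  expect_equal(unname(box["x_lower"]), p$r1 / p$b1, tolerance = 1e-2)
})

test_that("certificate converges without the second historical condition", {
  # randomized search for a refuge-free configuration where the first
  # condition holds but the second fails; its certificate must still
  # converge, showing the second condition is redundant
  set.seed(606)
  witness <- NULL
  for (i in 1:20000) {
    v <- exp(stats::runif(7, log(0.05), log(20)))
    p <- try(lg_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7], m = 0),
             silent = TRUE)
    if (inherits(p, "try-error")) next
    cond <- lg_conditions(p)
    if (cond$c1$holds && !cond$c2$holds) { witness <- p; break }
  }
  expect_false(is.null(witness))
  cond <- lg_conditions(witness)
  expect_true(cond$c1$holds)
  expect_false(cond$c2$holds)
  cert <- lg_certify(witness)
  expect_true(cert$bounds$converged)
  expect_lt(cert$agreement_gap, 1e-6)
})

test_that("no-alternate-food certificate converges under its condition", {
  ht <- lg_params(2, 1, 1, 1, 1, 1, k2 = 0, m = 0.2, holling_tanner = TRUE)
  cond <- lg_conditions(ht)
  expect_true(cond$c4$holds)
  # with k2 = 0 the refuge-aware margin coincides with the k2-free one
  expect_equal(cond$c3$margin, cond$c4$margin)
  cert <- lg_certify(ht)
  expect_true(cert$bounds$converged)
  expect_lt(cert$agreement_gap, 1e-6)
})

test_that("certificate refuses the bistable regime", {
  expect_error(lg_certify(two_equilibria_params()),
               "two positive equilibria")
})
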