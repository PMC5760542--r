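# toy systems with known equilibria exercise the solver machinery
test_that("multi-start root finding recovers known equilibria", {
  # logistic: dx/dt = x(1-x) has exactly {0, 1}
  rhs <- function(x) x * (1 - x)
  eq <- find_steady_states(rhs, cbind(lower = -0.5, upper = 2),
                           n_starts = 25, seed = 7, nonneg = FALSE)
  vals <- sort(vapply(eq$state, `[[`, numeric(1), 1))
  expect_equal(vals, c(0, 1), tolerance = 1e-8)
  expect_true(all(eq$residual < 1e-9))
  # determinism given the seed
  eq2 <- find_steady_states(rhs, cbind(lower = -0.5, upper = 2),
                            n_starts = 25, seed = 7, nonneg = FALSE)
  expect_identical(eq$state, eq2$state)
  # a field with no zeros in the box returns an empty list, not an error
  none <- find_steady_states(function(x) x * 0 + 1, cbind(lower = 0, upper = 1),
                             n_starts = 5, seed = 1, nonneg = FALSE)
  expect_equal(nrow(none), 0)
})

test_that("jacobian stability classifies textbook cases", {
  s1 <- jacobian_stability(function(x) -x, 0)
  expect_true(s1$stable)
  expect_equal(Re(s1$eigenvalues[[1]]), -1, tolerance = 1e-6)
  s2 <- jacobian_stability(function(x) x * (1 - x), 0)
  expect_false(s2$stable)
  s3 <- jacobian_stability(function(x) x * (1 - x), 1)
  expect_true(s3$stable)
  expect_error(jacobian_stability(function(x) x * (1 - x), 0.5),
               "not an equilibrium")
})

test_that("continuation reproduces the saddle-node of a fold normal form", {
  # dx/dt = p - x^2: branch x = +/- sqrt(p), fold at p = 0
  rhs <- function(x, p) p - x[[1]]^2
  br <- continue_branch(rhs, c(1, -0.5), start_state = 1,
                        h0 = 5e-3, h_max = 2e-2)
  bf <- attr(br, "bifurcations")
  expect_true(nrow(bf) >= 1)
  expect_equal(bf$param[[1]], 0, tolerance = 1e-3)
  # upper branch stable, lower branch unstable
  upper <- vapply(br$state, `[[`, numeric(1), 1) > 0.1
  expect_true(all(br$stable[upper]))
  expect_true(all(!br$stable[vapply(br$state, `[[`, numeric(1), 1) < -0.1]))
  # the fold is a parameter extremum along the branch
  expect_lte(abs(min(br$param) - bf$param[[1]]), 2e-3)
})

test_that("continuation detects a Hopf bifurcation in the normal form", {
  # dx = p*x - y - x(x^2+y^2); dy = x + p*y - y(x^2+y^2): HB at p = 0
  rhs <- function(s, p) {
    r2 <- s[[1]]^2 + s[[2]]^2
    c(p * s[[1]] - s[[2]] - s[[1]] * r2,
      s[[1]] + p * s[[2]] - s[[2]] * r2)
  }
  br <- continue_branch(rhs, c(-1, 1), start_state = c(0, 0),
                        h0 = 5e-3, h_max = 2e-2)
  bf <- attr(br, "bifurcations")
  hb <- bf[bf$type == "HB", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$param[[1]], 0, tolerance = 0.02)
  expect_true(all(br$stable[br$param < -0.05]))
  expect_true(all(!br$stable[br$param > 0.05]))
})

test_that("continuation agrees with the multi-start oracle on a bistable system", {
  # dx/dt = p + x^2/(1+x^2)*2 - x : S-shaped curve in p with two folds
  rhs <- function(x, p) p + 2 * x[[1]]^2 / (1 + x[[1]]^2) - x[[1]]
  br <- continue_branch(rhs, c(-0.3, 1.2), start_state = 0 - 0.3 / 1,
                        h0 = 5e-3, h_max = 2e-2, tol = 1e-11)
  bf <- attr(br, "bifurcations")
  expect_equal(sum(bf$type == "SN"), 2)
  # oracle-vs-continuation cross-validation at parameter values inside
  # the bistable window
  for (pv in c(0.05, 0.1)) {
    eq <- find_steady_states(function(x) rhs(x, pv),
                             cbind(lower = -1, upper = 3),
                             n_starts = 30, seed = 3, nonneg = FALSE)
    xs <- sort(vapply(eq$state, `[[`, numeric(1), 1))
    # every oracle equilibrium is met by the polished branch equilibrium
    for (x0 in xs) {
      bx <- branch_equilibrium_at(br, rhs, pv, near = x0)
      expect_false(is.null(bx))
      expect_lt(abs(bx[[1]] - x0), 1e-6)
    }
  }
})
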