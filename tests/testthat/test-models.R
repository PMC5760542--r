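test_that("compiled subsystem right-hand side matches the R reference", {
  p <- unlist(default_parameters("meiosis"))
  set.seed(11)
  for (i in 1:25) {
    y <- stats::runif(8, 0, 3)
    tor2 <- sample(c(0, 0.5, 1), 1); pka <- sample(c(0, 0.75, 1, 1.2), 1)
    r_deriv <- meioswitch:::meiosis_core(y, p, tor2, pka, TRUE)$deriv
    # one microscopic Euler step through the compiled solver path
    sched <- nutrient_schedule(0, tor2, pka, TRUE)
    out <- deSolve::lsoda(y, c(0, 1e-6), func = "derivs_meiosis",
                          dllname = "meioswitch", initfunc = "init_meiosis",
                          parms = c(p, tor2, pka, 1, 0),
                          rtol = 1e-10, atol = 1e-12)
    c_deriv <- (as.numeric(out[2, -1]) - y) / 1e-6
    expect_equal(c_deriv, r_deriv, tolerance = 1e-4)
  }
})

test_that("compiled integrated right-hand side matches the R reference", {
  p <- unlist(default_parameters("integrated"))
  pars <- default_parameters("integrated")
  set.seed(12)
  for (i in 1:25) {
    y <- c(stats::runif(8, 0, 2), stats::runif(8, 0.01, 1.5),
           stats::runif(1, 0.5, 3), stats::runif(2, 0, 1))
    tor2 <- sample(c(0, 1), 1); pka <- sample(c(0.75, 1), 1)
    sched <- nutrient_schedule(0, tor2, pka, TRUE)
    r_deriv <- integrated_rhs(0, y, pars, sched)
    out <- deSolve::lsoda(y, c(0, 1e-6), func = "derivs_integrated",
                          dllname = "meioswitch", initfunc = "init_integrated",
                          parms = c(p, tor2, pka, 1),
                          rtol = 1e-10, atol = 1e-12)
    c_deriv <- (as.numeric(out[2, -1]) - y) / 1e-6
    expect_equal(c_deriv, r_deriv, tolerance = 1e-4)
  }
})

test_that("the nutrient-rich resting state is a genuine equilibrium", {
  p <- default_parameters()
  rs <- meiosis_rich_state(p)
  expect_lt(max(abs(meiosis_rhs(0, rs, p, rich_schedule()))), 1e-8)
  # resting state: Pat1 active, active Mei2 low relative to committed levels
  ref <- starved_reference(p)
  expect_gt(1 - rs[["cpx"]], 0.9 * p[["pat1_t"]])
  expect_lt(rs[["mei2a"]], 0.25 * ref[["mei2_active"]])
})

test_that("trajectories stay nonnegative and conserve Pat1", {
  p <- default_parameters()
  schedules <- list(rich_schedule(), starvation_schedule(0),
                    starvation_schedule(50))
  for (s in schedules) {
    tr <- simulate_meiosis(p, s, t_end = 400, dt = 1)
    states <- as.matrix(tr[, meiosis_state_names()])
    expect_gte(min(states), -1e-8)
    # conservation: free Pat1 derived as pat1_t - cpx, complex bounded
    expect_lte(max(tr$cpx), p[["pat1_t"]] + 1e-6)
    expect_equal(tr$pat1_free + tr$cpx, rep(p[["pat1_t"]], nrow(tr)),
                 tolerance = 1e-6)
  }
})

test_that("increasing PKA never increases total Ste11 at rich steady state", {
  pars <- default_parameters()
  rs <- meiosis_rich_state(pars)
  ste11 <- vapply(c(0.85, 0.95, 1, 1.1, 1.2), function(pka) {
    # relax onto the resting attractor at this PKA level, then polish
    tr <- simulate_meiosis(pars, nutrient_schedule(0, 1, pka, TRUE),
                           t_end = 1500, dt = 50, init = rs)
    y <- as.numeric(tr[nrow(tr), meiosis_state_names()])
    p <- unlist(pars)
    f <- function(x) meioswitch:::meiosis_core(pmax(x, 0), p, 1, pka, TRUE)$deriv
    sol <- meioswitch:::newton_solve(f, y, tol = 1e-11)
    sum(pmax(sol$x[1:2], 0))
  }, numeric(1))
  expect_true(all(diff(ste11) <= 1e-4 * max(ste11)))
})

test_that("PheS feedback loops act redundantly on Ste11 accumulation", {
  p0 <- unlist(default_parameters())
  base <- simulate_meiosis(default_parameters(), starvation_schedule(0),
                           t_end = 300, dt = 1)
  # removing the PheS->import arm alone
  p1 <- p0; p1[["b_imphe"]] <- 0
  tr1 <- simulate_meiosis(new_parameter_set(p1, "meiosis"),
                          starvation_schedule(0), t_end = 300, dt = 1,
                          init = meiosis_rich_state(default_parameters()))
  # removing the PheS->Pat1 arm alone (PheS no longer inhibits Pat1)
  p2 <- p0; p2[["j_iphe"]] <- 1e6
  tr2 <- simulate_meiosis(new_parameter_set(p2, "meiosis"),
                          starvation_schedule(0), t_end = 300, dt = 1,
                          init = meiosis_rich_state(default_parameters()))
  n0 <- base$ste11n[[1]]
  for (tr in list(base, tr1, tr2)) {
    expect_gt(max(tr$ste11n), 5 * n0)  # accumulation in every variant
  }
})

test_that("integrated model sustains a division cycle under rich conditions", {
  p <- default_parameters("integrated")
  y0 <- integrated_rich_state(p)
  period <- attr(y0, "period")
  expect_gt(period, 100); expect_lt(period, 250)
  tr <- simulate_integrated(p, rich_schedule(), t_end = ceiling(3.2 * period),
                            dt = 1, init = y0)
  dv <- division_times(tr)
  expect_gte(length(dv), 3)
  # inter-division times equal the period within integration tolerance
  expect_lt(max(abs(diff(dv) - period)), 0.05 * period)
  # mass halves exactly at division and is continuous elsewhere
  expect_true(all(tr$mass > 0))
  # event detector re-derives the recorded division times
  redetect <- detect_division_events(tr)
  expect_equal(length(redetect), length(dv))
  expect_lt(max(abs(redetect - dv)), 1.5)
})

test_that("Ste11 is periodic and peaks when Cdk1 is low in the rich cycle", {
  p <- default_parameters("integrated")
  tr <- simulate_integrated(p, rich_schedule(), t_end = 340, dt = 1)
  # periodic accumulation: clear amplitude over the cycle
  expect_gt(max(tr$ste11_t) / min(tr$ste11_t), 1.5)
  # the Ste11 peak falls in a low-Cdk1 phase ...
  expect_lt(tr$mpf[[which.max(tr$ste11_t)]], stats::median(tr$mpf))
  # ... and Ste11 is depressed while Cdk1 is mitotically high
  expect_lt(max(tr$ste11_t[tr$mpf > 0.3]), 0.95 * max(tr$ste11_t))
})

test_that("removing the Cdk1 coupling elevates Ste11 without activating Mei2", {
  p0 <- default_parameters("integrated")
  gp <- apply_genotype(p0, "ste11_T82A")
  y0 <- integrated_rich_state(p0)
  wt <- simulate_integrated(p0, rich_schedule(), t_end = 340, dt = 1, init = y0)
  mut <- simulate_integrated(gp$params, rich_schedule(), t_end = 340, dt = 1,
                             init = y0)
  expect_gt(min(mut$ste11_t[mut$time > 100]),
            min(wt$ste11_t[wt$time > 100]))
  ref <- starved_reference(default_parameters("meiosis"))
  expect_lt(max(mut$mei2_active), 0.5 * ref[["mei2_active"]])
})

test_that("uncoupled cell-cycle block is unaffected by the meiosis layer", {
  # zero every coupling and compare against a pure cell-cycle integration
  p <- unlist(default_parameters("integrated"))
  p[["c_cdkste11"]] <- 0; p[["c_pherum1"]] <- 0
  pars <- new_parameter_set(p, "integrated")
  y0 <- integrated_rich_state(default_parameters("integrated"))
  tr <- simulate_integrated(pars, rich_schedule(), t_end = 400, dt = 1,
                            init = y0)
  # same run with the meiosis block frozen at zero (no Ste11/Mei2/PheS)
  y0z <- y0; y0z[1:8] <- 0
  pz <- p
  pz[["ks_ste11r"]] <- 0; pz[["ks_ste11a"]] <- 0; pz[["ks_ste11_0"]] <- 0
  pz[["ks_mei2"]] <- 0; pz[["k_sphe"]] <- 0
  trz <- simulate_integrated(new_parameter_set(pz, "integrated"),
                             rich_schedule(), t_end = 400, dt = 1, init = y0z)
  dv <- division_times(tr); dvz <- division_times(trz)
  expect_equal(length(dv), length(dvz))
  # oscillation period unchanged to < 1%
  expect_lt(max(abs(diff(dv) - diff(dvz))) / mean(diff(dv)), 0.01)
  cc <- c("cdc13t", "rum1t", "mass", "mpf")
  expect_lt(max(abs(as.matrix(tr[cc]) - as.matrix(trz[cc]))), 1e-4)
})

test_that("division times are reproducible under tolerance refinement", {
  p <- default_parameters("integrated")
  y0 <- integrated_rich_state(p)
  a <- simulate_integrated(p, starvation_schedule(150), t_end = 450, dt = 1,
                           init = y0)
  b <- simulate_integrated(p, starvation_schedule(150), t_end = 450, dt = 1,
                           init = y0, rtol = 1e-9, atol = 1e-11)
  da <- division_times(a); db <- division_times(b)
  expect_equal(length(da), length(db))
  expect_lt(max(abs(da - db)), 0.5)
})
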