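pars <- default_parameters()

test_that("wild-type starvation upregulates the cascade in strict order", {
  ref <- starved_reference(pars)
  tr <- simulate_meiosis(pars, starvation_schedule(0), t_end = 600, dt = 1)
  ord <- sequential_order_check(tr, ref)
  expect_equal(ord$observable, c("phes", "mat1pm", "mei3_t", "mei2_active"))
  expect_true(all(is.finite(ord$crossing_time)))
  expect_true(all(diff(ord$crossing_time) > 0))
})

test_that("mei3-null mates but never activates Mei2 (intermediate Pat1)", {
  ref <- starved_reference(pars)
  gp <- apply_genotype(pars, "mei3D")
  tr <- simulate_meiosis(gp$params, starvation_schedule(0), t_end = 600,
                         dt = 1, init = meiosis_rich_state(pars))
  ord <- sequential_order_check(tr, ref)
  expect_true(all(is.finite(ord$crossing_time[1:2])))   # PheS, Mat1-Pm rise
  expect_equal(unname(ord$crossing_time[3:4]), c(Inf, Inf)) # Mei3, Mei2 never
  # free Pat1 settles at an intermediate activity: neither full nor off
  tail_act <- tr$pat1_activity[tr$time > 400]
  expect_true(all(tail_act > 0.05 * pars[["pat1_t"]]))
  expect_true(all(tail_act < 0.8 * pars[["pat1_t"]]))
  expect_lt(max(tr$mei2_active), 0.5 * ref[["mei2_active"]])
})

test_that("complete Pat1 loss activates Mei2 without Mei3 in rich medium", {
  ref <- starved_reference(pars)
  gp <- apply_genotype(pars, "pat1_114_34C_h90")
  tr <- simulate_meiosis(gp$params, rich_schedule(), t_end = 600, dt = 1,
                         init = meiosis_rich_state(pars))
  ord <- sequential_order_check(tr, ref)
  expect_lt(ord$crossing_time[[4]], Inf)       # active Mei2 rises
  expect_equal(ord$crossing_time[[3]], Inf)    # without any Mei3
})

test_that("partial Pat1 loss activates Mei2 in a Mei3-dependent way", {
  ref <- starved_reference(pars)
  init <- meiosis_rich_state(pars)
  gp <- apply_genotype(pars, "pat1_114_30C")
  tr <- simulate_meiosis(gp$params, rich_schedule(), t_end = 900, dt = 1,
                         init = init)
  expect_gt(tr$mei2_active[[nrow(tr)]], 0.5 * ref[["mei2_active"]])
  # the same strain without Mei3 synthesis cannot activate Mei2
  p2 <- unlist(gp$params); p2[["k_smei3"]] <- 0
  tr0 <- simulate_meiosis(new_parameter_set(p2, "meiosis"), rich_schedule(),
                          t_end = 900, dt = 1, init = init)
  expect_lt(tr0$mei2_active[[nrow(tr0)]], 0.5 * ref[["mei2_active"]])
})

test_that("return to growth flips from reversible to irreversible", {
  r135 <- run_return_to_growth(135, pars, horizon = 650)
  r150 <- run_return_to_growth(150, pars, horizon = 650)
  expect_equal(r135$verdict, "reversible")
  expect_equal(r150$verdict, "irreversible")
  expect_gt(r135$final_pat1_free, r150$final_pat1_free)
  expect_error(run_return_to_growth(700, pars, horizon = 650), "horizon")
})

test_that("commitment window lies inside the bracket and narrows with k_smei3", {
  win <- commitment_window(pars, resolution = 2)
  expect_false(win$degenerate)
  expect_gte(win$t_reversible_max, 135)
  expect_lte(win$t_irreversible_min, 150)
  # mei3-null never commits: degenerate outcome, not an error
  gp <- apply_genotype(pars, "mei3D")
  win0 <- commitment_window(gp$params, resolution = 5)
  expect_true(win0$degenerate)
  expect_equal(win0$verdict, "reversible")
  # doubling Mei3 synthesis moves the flip strictly earlier
  p2 <- unlist(pars); p2[["k_smei3"]] <- 2 * p2[["k_smei3"]]
  win2 <- commitment_window(new_parameter_set(p2, "meiosis"),
                            resolution = 2, t_min = 60, t_max = 150)
  expect_false(win2$degenerate)
  expect_lt(win2$t_irreversible_min, win$t_irreversible_min)
})

test_that("PheS is needed to enter but not to maintain commitment", {
  # commit fully under starvation, then disable PheS synthesis: Pat1 must
  # not re-activate
  tr <- simulate_meiosis(pars, starvation_schedule(0), t_end = 300, dt = 1)
  y <- as.numeric(tr[nrow(tr), meiosis_state_names()])
  p2 <- unlist(pars); p2[["k_sphe"]] <- 0
  tr2 <- simulate_meiosis(new_parameter_set(p2, "meiosis"),
                          starvation_schedule(0), t_end = 400, dt = 1, init = y)
  expect_lt(tr2$pat1_free[[nrow(tr2)]], 0.1 * pars[["pat1_t"]])
  ref <- starved_reference(pars)
  expect_gt(tr2$mei2_active[[nrow(tr2)]], 0.5 * ref[["mei2_active"]])
})

test_that("either PKA or Tor2 inactivation suffices, PheS-dependently", {
  ref <- starved_reference(pars)
  init <- meiosis_rich_state(pars)
  for (ov in list(c(tor2 = 0, pka = 1), c(tor2 = 1, pka = 0))) {
    sched <- nutrient_schedule(0, ov[["tor2"]], ov[["pka"]], TRUE)
    tr <- simulate_meiosis(pars, sched, t_end = 700, dt = 1, init = init)
    expect_gt(tr$mei2_active[[nrow(tr)]], 0.5 * ref[["mei2_active"]])
    # with PheS disabled, the same shift cannot activate Mei2
    p2 <- unlist(pars); p2[["k_sphe"]] <- 0
    tr0 <- simulate_meiosis(new_parameter_set(p2, "meiosis"), sched,
                            t_end = 700, dt = 1, init = init)
    expect_lt(tr0$mei2_active[[nrow(tr0)]], 0.5 * ref[["mei2_active"]])
  }
})

test_that("PKA loss drives stronger Ste11 accumulation than Tor2 loss", {
  ref <- starved_reference(pars)
  init <- meiosis_rich_state(pars)
  thr <- 0.5 * ref[["mei2_active"]]
  tr_pka <- simulate_meiosis(pars, nutrient_schedule(0, 1, 0, TRUE),
                             t_end = 700, dt = 1, init = init)
  tr_tor <- simulate_meiosis(pars, nutrient_schedule(0, 0, 1, TRUE),
                             t_end = 700, dt = 1, init = init)
  # both single-input losses activate Mei2 ...
  t_pka <- meioswitch:::first_crossing(tr_pka$time, tr_pka$mei2_active, thr)
  t_tor <- meioswitch:::first_crossing(tr_tor$time, tr_tor$mei2_active, thr)
  expect_lt(t_pka, Inf); expect_lt(t_tor, Inf)
  # ... and Ste11 accumulates higher without PKA (full Rst2 derepression)
  expect_gt(max(tr_pka$ste11_t), 1.3 * max(tr_tor$ste11_t))
})

test_that("protocol registry runs by name and rejects unknown names", {
  expect_error(run_protocol("fig99"), "unknown protocol")
  tr <- run_protocol("fig2b")
  expect_s3_class(tr, "msw_trajectory")
  rv <- run_protocol("fig4a")
  expect_equal(rv$verdict, "reversible")
})
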