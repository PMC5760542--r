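test_that("hill activation has the closed form, bounds and monotonicity", {
  # half-saturation symmetry for any Hill coefficient
  for (h in c(1, 2, 4, 8)) {
    expect_equal(hill_activation(0.3, k = 0.3, h = h), 0.5)
  }
  expect_equal(hill_activation(0, k = 0.3, h = 2), 0)
  # direct closed-form evaluation and saturation toward 1
  expect_equal(hill_activation(1, k = 0.3, h = 4),
               1 / (0.3^4 + 1), tolerance = 1e-12)
  expect_lt(abs(hill_activation(1e4, k = 0.3, h = 4) - 1), 1e-10)
  x <- seq(0, 5, by = 0.1)
  expect_true(all(diff(hill_activation(x, 0.4, 3)) > 0))
  expect_true(all(hill_activation(x, 0.4, 3) <= 1))
  expect_error(hill_activation(1, k = 0, h = 2), "must be > 0")
  expect_error(hill_activation(1, k = 1, h = 0.5), ">= 1")
  expect_error(hill_activation(-1, k = 1, h = 2), ">= 0")
})

test_that("Michaelis-Menten flux saturates and respects its domain", {
  expect_equal(mm_flux(0, 1, 2, 0.5), 0)
  # half-maximal at substrate = Km
  expect_equal(mm_flux(0.5, 1.5, 2, 0.5), 2 * 1.5 / 2)
  # within 1% of Vmax at substrate = 99 Km (algebraic bound 99/100)
  expect_equal(mm_flux(99 * 0.2, 2, 1, 0.2), 2 * 99 / 100)
  s <- seq(0, 10, by = 0.25)
  expect_true(all(diff(mm_flux(s, 1, 1, 0.3)) > 0))
  expect_true(all(mm_flux(s, 1, 1, 0.3) <= 1))
  expect_error(mm_flux(1, 1, 1, 0), "must be > 0")
  expect_error(mm_flux(-1, 1, 1, 1), ">= 0")
})

test_that("Goldbeter-Koshland fraction matches the steady-state equation", {
  # the GK fraction G solves va*(1-G)/(Ja+1-G) = vi*G/(Ji+G)
  cases <- expand.grid(va = c(0.2, 1, 2), vi = c(0.5, 1.5), J = c(0.01, 0.1))
  for (i in seq_len(nrow(cases))) {
    va <- cases$va[i]; vi <- cases$vi[i]; J <- cases$J[i]
    G <- goldbeter_koshland(va, vi, J, J)
    expect_lt(abs(va * (1 - G) / (J + 1 - G) - vi * G / (J + G)), 1e-8)
    expect_gte(G, 0); expect_lte(G, 1)
  }
})

test_that("Pat1 partition conserves mass and responds to both inhibitors", {
  p <- default_parameters()
  out <- pat1_partition(1, 0, 0, p)
  expect_equal(out$free, 1)
  expect_equal(out$activity, 1)
  out2 <- pat1_partition(1, 0.6, 0, p)
  expect_equal(out2$free + out2$complexed, 1)
  # stoichiometric excess of complexed Mei3 drives free Pat1 to zero
  expect_equal(pat1_partition(1, 1, 0, p)$free, 0)
  # activity decreases monotonically in PheS at fixed sequestration
  act <- vapply(c(0, 0.5, 1, 2, 5), function(ph)
    pat1_partition(1, 0.3, ph, p)$activity, numeric(1))
  expect_true(all(diff(act) < 0))
  expect_error(pat1_partition(1, -0.1, 0, p), ">= 0")
})
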