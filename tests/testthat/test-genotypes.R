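pars <- default_parameters()

test_that("genotype overrides apply without touching the original", {
  gp <- apply_genotype(pars, "mei3D")
  expect_equal(gp$params[["k_smei3"]], 0)
  expect_gt(pars[["k_smei3"]], 0)  # original unchanged
  # wild type is the identity
  wt <- apply_genotype(pars, "wild_type")
  expect_identical(unlist(wt$params), unlist(pars))
  # temperature-sensitive alleles combine parameter and input overrides
  gp2 <- apply_genotype(pars, "pat1_114_34C")
  expect_equal(gp2$params[["pat1_t"]], 0.001)
  expect_equal(gp2$params[["k_smei3"]], 0)  # heterothallic: no partner
  gp3 <- apply_genotype(pars, "tor2_51")
  expect_equal(gp3$inputs$tor2, 0)
  expect_error(apply_genotype(pars, "not_a_strain"), "unregistered")
  # a registry row with an unknown parameter target names the offender
  bad <- genotype_registry()[1, ]
  bad$overrides <- "no_such_rate=1"
  expect_error(apply_genotype(pars, bad), "no_such_rate")
})

test_that("heterothallic strains run without pheromone signalling", {
  sched <- genotype_schedule("mei2_SATA")
  expect_false(any(sched$phes_enabled))
  sched2 <- genotype_schedule("cyr1D_M_factor")  # exogenous pheromone added
  expect_true(all(sched2$phes_enabled))
})

test_that("classification is a pure function of evidence and thresholds", {
  ref <- starved_reference(pars)
  tr <- simulate_meiosis(pars, starvation_schedule(0), t_end = 600, dt = 1)
  a <- classify_phenotype(tr, ref)
  b <- classify_phenotype(tr, ref)
  expect_identical(a, b)
  expect_equal(a$mating, "+"); expect_equal(a$meiosis, "+")
  expect_error(classify_phenotype(tr[, 1:3], ref), "lacks required")
})

test_that("the full registry screen reproduces every expected call", {
  sc <- run_screen(params = pars)
  expect_equal(attr(sc, "concordance"), 1)
  expect_length(attr(sc, "unmapped"), 0)
})

test_that("screen handles empty and unmapped strain lists gracefully", {
  sc0 <- run_screen(character(0), params = pars)
  expect_true(is.na(attr(sc0, "concordance")))
  sc1 <- run_screen(c("wild_type", "nonexistent_strain"), params = pars)
  expect_equal(attr(sc1, "unmapped"), "nonexistent_strain")
  expect_equal(nrow(sc1), 1)
})

test_that("epistasis relations hold across the registry", {
  sc <- run_screen(c("pat1_114_34C", "mei2D_pat1_114_34C",
                     "byr2_DN", "byr2_DN_mei3D",
                     "tor2_51_cgs1D", "tor2_51_pka1D"), params = pars)
  calls <- stats::setNames(paste0(sc$mating, sc$meiosis), sc$strain)
  # mei2 deletion suppresses pat1-driven meiosis
  expect_equal(unname(calls["pat1_114_34C"]), "-+")
  expect_equal(unname(calls["mei2D_pat1_114_34C"]), "--")
  # constitutive Byr2 meiosis is Mei3-independent
  expect_equal(unname(calls["byr2_DN"]), "-+")
  expect_equal(unname(calls["byr2_DN_mei3D"]), "-+")
  # PKA hyperactivation blocks the tor2-ts rescue; PKA loss does not
  expect_equal(unname(calls["tor2_51_cgs1D"]), "--")
  expect_equal(unname(calls["tor2_51_pka1D"]), "++")
})

test_that("calls are robust to +/- 10 point threshold shifts", {
  for (mf in c(0.4, 0.6)) {
    sc <- run_screen(params = pars, mating_frac = mf, meiosis_frac = mf)
    flagged <- sc$strain[!sc$match & sc$scored & !is.na(sc$expected_mating)]
    expect_lte(length(flagged), 2)
  }
})

test_that("registry CSV fixture matches the built-in registry", {
  f <- system.file("extdata", "table1_registry.csv", package = "meioswitch")
  expect_true(nzchar(f))
  csv <- utils::read.csv(f, stringsAsFactors = FALSE)
  reg <- as.data.frame(genotype_registry())
  expect_equal(csv$strain, reg$strain)
  expect_equal(csv$overrides, reg$overrides)
  expect_equal(csv$expected_mating[csv$scored == "TRUE" | csv$scored == TRUE],
               reg$expected_mating[reg$scored])
})
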