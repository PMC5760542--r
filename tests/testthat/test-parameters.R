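test_that("default parameter sets validate and reject corrupted sets", {
  p <- default_parameters("meiosis")
  expect_s3_class(p, "msw_params")
  expect_true(all(unlist(p) >= 0))
  expect_gte(p[["hs"]], 1)
  expect_gt(p[["pat1_t"]], 0)
  pi <- default_parameters("integrated")
  expect_true(all(names(p) %in% names(pi)))

  v <- unlist(p)
  expect_error(new_parameter_set(v[-1], "meiosis"), "missing: k_imste11")
  v2 <- c(v, bogus = 1)
  expect_error(new_parameter_set(v2, "meiosis"), "unknown: bogus")
  v3 <- v; v3[["k_sphe"]] <- -1
  expect_error(new_parameter_set(v3, "meiosis"), ">= 0")
})

test_that("XPPAUT .ode parameter files parse, normalise names and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".ode")
  writeLines(c(
    "# comment line",
    "par KIMSTE11=0.11, kexste11=0.9",
    "p k_sphe=0.2",
    "x' = -x  # equations are ignored",
    "done"
  ), tmp)
  vals <- meioswitch:::parse_ode_parameters(tmp)
  expect_equal(unname(vals[["KIMSTE11"]]), 0.11)
  nm <- meioswitch:::normalize_param_names(names(vals), "meiosis")
  expect_true(all(c("k_imste11", "k_exste11", "k_sphe") %in% nm))

  # an incomplete file reports the missing names
  expect_error(load_parameters(tmp, "meiosis"), "missing")

  # full round-trip: write then reload equals the original exactly
  p <- default_parameters("meiosis")
  f <- withr::local_tempfile(fileext = ".ode")
  write_parameters(p, f)
  p2 <- load_parameters(f, "meiosis")
  expect_identical(unlist(p2), unlist(p))

  bad <- withr::local_tempfile(fileext = ".ode")
  writeLines("par k_imste11=abc", bad)
  expect_error(load_parameters(bad, "meiosis"), "line 1")
  empty <- withr::local_tempfile(fileext = ".ode")
  writeLines("# nothing here", empty)
  expect_error(load_parameters(empty, "meiosis"), "no 'par' lines")
})

test_that("bundled .ode fixtures reproduce the default calibration", {
  for (model in c("meiosis", "integrated")) {
    f <- system.file("extdata", paste0(model, ".ode"), package = "meioswitch")
    expect_true(nzchar(f))
    expect_identical(unlist(load_parameters(f, model)),
                     unlist(default_parameters(model)))
  }
})

test_that("parameter manifest covers every state and parameter", {
  mf <- parameter_manifest("integrated")
  expect_setequal(mf$name[mf$kind == "state"], integrated_state_names())
  expect_setequal(mf$name[mf$kind == "parameter"],
                  names(unlist(default_parameters("integrated"))))
})

test_that("yaml and json parameter sources are accepted", {
  p <- unlist(default_parameters("meiosis"))
  fy <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(as.list(p), fy)
  expect_equal(unlist(load_parameters(fy, "meiosis")), p, tolerance = 1e-4)
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as.list(p), fj, auto_unbox = TRUE, digits = NA)
  expect_equal(unlist(load_parameters(fj, "meiosis")), p, tolerance = 1e-12)
})
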