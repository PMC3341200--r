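test_that("default parameter sets carry the published constants", {
  p <- default_parameters("methods")
  expect_length(core_parameter_names(), 30)
  expect_named(p, c(core_parameter_names(), "RSK1_total"))
  expect_identical(p[["k_Mdiss"]], 1)
  expect_identical(p[["k_Mp73ass"]], 0.03)
  expect_identical(p[["gamma_STAT3"]], 0.002)
  expect_identical(p[["gamma_PIAS3"]], 0.008)
  expect_identical(p[["p_STAT3"]], 0.211)
  expect_identical(p[["RSK1_total"]], 500)
  expect_identical(p[["ERKp_baseline"]], 10)
  expect_identical(p[["JAKp_baseline"]], 10)

  # the two printed readings of the PIAS3 production rate
  expect_identical(default_parameters("methods")[["p_PIAS3"]], 1.262)
  expect_identical(default_parameters("table1")[["p_PIAS3"]], 0.262)
  expect_error(default_parameters("bogus"))
})

test_that("complex degradation is 20% of the mean constituent rate", {
  expect_equal(complex_degradation_rate(0.0012, 0.008), 0.00092)
  expect_equal(complex_degradation_rate(0, 0), 0)
  g <- 0.0123
  expect_equal(complex_degradation_rate(g, g), g / 5)
  expect_error(complex_degradation_rate(-1, 0.1))
})

test_that("parameter overrides validate names and suggest corrections", {
  p <- default_parameters()
  q <- override_parameters(p, list(p_MITF = 7, k_Mp409_plus = 0))
  expect_identical(q[["p_MITF"]], 7)
  expect_identical(q[["k_Mp409_plus"]], 0)
  expect_error(override_parameters(p, list(p_PIAS = 1)), "p_PIAS3")
  expect_error(simulate_model(replace(p, "k_u", -1), duration = 1), "negative")
})

test_that("the bundled parameter files reproduce the defaults per dialect", {
  for (dial in c("methods", "table1")) {
    f <- system.file("extdata", paste0("parameters_", dial, ".json"),
                     package = "pias3net")
    expect_true(nzchar(f))
    q <- read_parameters(f)
    p <- default_parameters(dial)
    expect_equal(as.numeric(q), as.numeric(p[names(q)]))
  }
})

test_that("parameter files round-trip through JSON and YAML", {
  p <- default_parameters()
  for (ext in c("json", "yaml")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_parameters(p, f)
    q <- read_parameters(f)
    expect_equal(as.numeric(q), as.numeric(p[names(q)]))
  }
})
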