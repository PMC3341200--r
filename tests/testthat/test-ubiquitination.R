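test_that("ubiquitination terms vanish as required at the boundaries", {
  p <- default_parameters()
  s <- random_state()
  s[["R"]] <- 0
  u <- ubiquitination_terms(s, p, erkp = 10)
  expect_equal(u$term_ii, 0)
  expect_equal(u$term_iii, 0)
  expect_equal(u$dR, 10 * p[["k_u"]])
  expect_gte(u$dR, 0)

  s[["R"]] <- 1
  u1 <- ubiquitination_terms(s, p, erkp = 10)
  expect_equal(u1$term_i, 0)
})

test_that("the singularity-free depletion form matches the literal ratio form", {
  p <- default_parameters()
  set.seed(7)
  for (i in 1:200) {
    s <- random_state(scale = stats::runif(1, 1, 500))
    s[["R"]] <- stats::runif(1, 1e-6, 1 - 1e-6)
    erkp <- stats::runif(1, 0, 1200)
    # literal form needs a positive dilution denominator
    den <- s[["MITFp73"]] + s[["MITFpp"]] +
      p[["p_MITF"]] - s[["MITFp409"]] * p[["gamma_MITFp409"]]
    if (den <= 0) next
    A <- (s[["MITFp73"]] + s[["MITFpp"]]) / den
    if (A > 1) next  # clamped regime, covered below
    expect_lt(abs(ubiquitination_terms(s, p, erkp)$dR -
                    oracle_dR_literal(s, p, erkp)), 1e-10)
  }
})

test_that("the dilution ratio is clamped into [0, 1] and guards its denominator", {
  p <- default_parameters()
  s <- random_state()
  # degradation outflow exceeding production: denominator would go negative
  s[["MITFp73"]] <- 0; s[["MITFpp"]] <- 0
  s[["MITFp409"]] <- 10 * p[["p_MITF"]] / p[["gamma_MITFp409"]]
  u <- ubiquitination_terms(s, p, erkp = 10)
  expect_equal(u$A, 1)
  expect_equal(u$term_iii, 0)
  expect_error(ubiquitination_terms(replace(s, "R", 1.5), p, 10), "\\[0, 1\\]")
})

test_that("R stays within [0, 1] under sustained strong activation", {
  p <- default_parameters()
  tr <- simulate_model(p, initial = steady_state(p), duration = 600,
                       erkp = 1200, jakp = 250, times = seq(0, 600, 5))
  expect_true(all(tr$R >= 0 & tr$R <= 1))
  expect_gt(max(tr$R), 0.9)  # heavy tagging under strong ERK input
})
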