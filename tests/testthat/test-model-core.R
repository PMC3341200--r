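test_that("at an empty state with zero inputs only production terms remain", {
  p <- default_parameters()
  s <- stats::setNames(numeric(15), state_names())
  d <- model_rhs(0, s, p, erkp = 0, jakp = 0)
  expect_equal(d[["MITF"]], p[["p_MITF"]])
  expect_equal(d[["PIAS3"]], p[["p_PIAS3"]])
  expect_equal(d[["STAT3"]], p[["p_STAT3"]])
  others <- setdiff(state_names(), c("MITF", "PIAS3", "STAT3"))
  expect_equal(unname(d[others]), rep(0, length(others)))
})

test_that("the RHS matches the stoichiometry-matrix oracle on random states", {
  p <- default_parameters()
  set.seed(101)
  for (i in 1:100) {
    s <- random_state(scale = stats::runif(1, 1, 1000))
    erkp <- stats::runif(1, 0, 1200)
    jakp <- stats::runif(1, 0, 1000)
    d <- model_rhs(0, s, p, erkp, jakp)[oracle_species]
    d_oracle <- oracle_rhs_species(s, p, erkp, jakp)
    expect_lt(max(abs(d - d_oracle) / pmax(abs(d_oracle), 1e-8)), 1e-9)
  }
})

test_that("the compiled and reference integrators agree", {
  p <- default_parameters()
  ss <- steady_state(p)
  tc <- simulate_model(p, initial = ss, duration = 60, erkp = 1000,
                       jakp = 1000, times = 0:60)
  tr <- simulate_model(p, initial = ss, duration = 60, erkp = 1000,
                       jakp = 1000, times = 0:60, engine = "r")
  mc <- as.matrix(as.data.frame(tc)[state_names()])
  mr <- as.matrix(as.data.frame(tr)[state_names()])
  expect_lt(max(abs(mc - mr) / pmax(abs(mr), 1e-6)), 1e-5)
})

test_that("the RSK1 pool is conserved along trajectories", {
  p <- default_parameters()
  tr <- simulate_model(p, initial = steady_state(p), duration = 120,
                       erkp = 1000, jakp = 10, times = seq(0, 120, 0.5))
  tot <- tr$RSK1 + tr$RSK1p
  expect_equal(tot, rep(tot[1], length(tot)), tolerance = 1e-12)
  # and the derivative cancels exactly, at any state
  s <- random_state()
  d <- model_rhs(0, s, p, 123, 45)
  expect_identical(d[["RSK1"]] + d[["RSK1p"]], 0)
})

test_that("with production, degradation and ubiquitination off, totals are conserved", {
  p <- default_parameters()
  p[c("p_MITF", "p_PIAS3", "p_STAT3",
      "gamma_MITF", "gamma_MITFp73", "gamma_MITFp409",
      "gamma_PIAS3", "gamma_STAT3", "k_u")] <- 0
  s0 <- steady_state(default_parameters())
  tr <- simulate_model(p, initial = s0, duration = 1000, erkp = 100,
                       jakp = 100, times = seq(0, 1000, 100))
  df <- as.data.frame(tr)
  mitf <- rowSums(df[c("MITF", "MITFp73", "MITFp409", "MITFpp", "PIAS3_MITF",
                       "PIAS3_MITFp73", "PIAS3_MITFp409", "PIAS3_MITFpp")])
  pias <- rowSums(df[c("PIAS3", "PIAS3_MITF", "PIAS3_MITFp73",
                       "PIAS3_MITFp409", "PIAS3_MITFpp", "PIAS3_STAT3p")])
  stat <- rowSums(df[c("STAT3", "STAT3p", "PIAS3_STAT3p")])
  for (tot in list(mitf, pias, stat)) {
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
})

test_that("pure binding relaxes to the ratio of association to dissociation", {
  p <- default_parameters()
  p[c("k_Mp73E_plus", "k_Mp73_minus", "k_Mp73a_plus", "k_Mp409_plus",
      "k_Mp409_minus", "k_Sp_plus", "k_Sp_minus", "k_Rp_plus", "k_Rp_minus",
      "p_MITF", "p_PIAS3", "p_STAT3",
      "gamma_MITF", "gamma_MITFp73", "gamma_MITFp409", "gamma_PIAS3",
      "gamma_STAT3", "k_u")] <- 0
  s0 <- empty_state(p)
  s0[c("MITF", "MITFp73", "MITFp409", "MITFpp", "STAT3p")] <- 50
  s0[["PIAS3"]] <- 200
  tr <- simulate_model(p, initial = s0, duration = 2e5, times = c(0, 2e5),
                       atol = 1e-10, rtol = 1e-10)
  s <- final_state(tr)
  pairs <- list(c("MITF", "PIAS3_MITF", "k_Mass", "k_Mdiss"),
                c("MITFp73", "PIAS3_MITFp73", "k_Mp73ass", "k_Mp73diss"),
                c("MITFp409", "PIAS3_MITFp409", "k_Mp409ass", "k_Mp409diss"),
                c("MITFpp", "PIAS3_MITFpp", "k_Mppass", "k_Mppdiss"),
                c("STAT3p", "PIAS3_STAT3p", "k_Spass", "k_Spdiss"))
  pd <- default_parameters()
  for (pr in pairs) {
    K_obs <- s[[pr[2]]] / (s[[pr[1]]] * s[["PIAS3"]])
    K_exp <- pd[[pr[3]]] / pd[[pr[4]]]
    expect_equal(K_obs, K_exp, tolerance = 1e-3)
  }
})

test_that("the isolated RSK1 cycle matches its closed-form resting fraction", {
  p <- default_parameters()
  ss <- steady_state(p)
  frac <- ss[["RSK1p"]] / (ss[["RSK1"]] + ss[["RSK1p"]])
  expect_equal(frac, 0.004 / 0.044, tolerance = 1e-6)
})

test_that("simulation is deterministic and anchored at the initial state", {
  p <- default_parameters()
  s0 <- steady_state(p)
  t1 <- simulate_model(p, initial = s0, duration = 50, erkp = 500, times = 0:50)
  t2 <- simulate_model(p, initial = s0, duration = 50, erkp = 500, times = 0:50)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(as.numeric(as.data.frame(t1)[1, state_names()]),
               as.numeric(s0[state_names()]))
  expect_true(all(diff(t1$time_min) > 0))
})

test_that("steady states satisfy the residual criterion and degenerate cases", {
  p <- default_parameters()
  ss <- steady_state(p)
  d <- model_rhs(0, ss, p)
  expect_lt(max(abs(d) / pmax(abs(ss), 1e-3 * max(abs(ss)))), 1e-6)
  # no phosphorylation source: the STAT3p arm empties
  q <- override_parameters(p, list(k_Sp_plus = 0))
  ssq <- steady_state(q)
  expect_equal(ssq[["STAT3p"]], 0, tolerance = 1e-6)
  expect_equal(ssq[["PIAS3_STAT3p"]], 0, tolerance = 1e-6)
})

test_that("resting totals of the three proteins are within one order of magnitude", {
  ss <- steady_state(default_parameters())
  mitf <- sum(ss[c("MITF", "MITFp73", "MITFp409", "MITFpp", "PIAS3_MITF",
                   "PIAS3_MITFp73", "PIAS3_MITFp409", "PIAS3_MITFpp")])
  pias <- sum(ss[c("PIAS3", "PIAS3_MITF", "PIAS3_MITFp73", "PIAS3_MITFp409",
                   "PIAS3_MITFpp", "PIAS3_STAT3p")])
  stat <- sum(ss[c("STAT3", "STAT3p", "PIAS3_STAT3p")])
  expect_gt(min(mitf, pias, stat), 0)
  expect_lt(max(mitf, pias, stat) / min(mitf, pias, stat), 10)
})

test_that("input schedules validate their breakpoints", {
  expect_error(input_schedule(c(5, 10), c(10, 10), c(10, 10)), "start at time 0")
  expect_error(input_schedule(c(0, 0), c(10, 10), c(10, 10)), "increasing")
  expect_error(input_schedule(0, -1, 10), "non-negative")
  sch <- input_schedule(c(0, 2880), erkp = c(10, 1000), jakp = c(10, 1000))
  tr <- simulate_model(default_parameters(), initial = steady_state(default_parameters()),
                       duration = 2890, schedule = sch, times = c(0, 2880, 2885, 2890))
  expect_equal(tr$ERKp, c(10, 10, 1000, 1000))
})
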