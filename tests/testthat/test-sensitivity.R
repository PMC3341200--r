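test_that("parameter sampling is log-uniform within the factor range and reproducible", {
  d <- default_parameters()
  sp <- sample_parameters(d, n = 10000, seed = 11)
  m <- sp$matrix
  expect_equal(dim(m), c(10000, 30))
  base <- as.numeric(d[core_parameter_names()])
  lo <- sweep(m, 2, 0.5 * base, `/`)
  hi <- sweep(m, 2, 2 * base, `/`)
  expect_true(all(lo >= 1 - 1e-12) && all(hi <= 1 + 1e-12))
  # log-symmetry: per-parameter median near the default
  med <- apply(m, 2, stats::median)
  expect_true(all(abs(log(med / base)) < 0.05))
  # determinism
  sp2 <- sample_parameters(d, n = 10000, seed = 11)
  expect_identical(sp$matrix, sp2$matrix)
  expect_false(identical(sample_parameters(d, n = 100, seed = 12)$matrix,
                         sample_parameters(d, n = 100, seed = 13)$matrix))
})

test_that("the binned statistic matches its exact combinatorial value", {
  set.seed(5)
  n <- 10000
  x <- stats::runif(n)
  # outcomes split exactly at the parameter median: 50 empty bins and 50
  # full bins around f = 1/2, so s = 100 * 0.5 = 50 exactly
  y <- x > stats::median(x)
  expect_identical(sensitivity_measure(x, y, n_bins = 100), 50)
  # degenerate outcome columns carry no signal
  expect_identical(sensitivity_measure(x, rep(TRUE, n), n_bins = 100), 0)
  # rank-based: invariant under strictly monotone transforms
  expect_identical(sensitivity_measure(exp(3 * x), y, n_bins = 100), 50)
  expect_error(sensitivity_measure(x[1:9999], y[1:9999]), "divisible")
})

test_that("the statistic is bounded by n_bins * max(f, 1 - f)", {
  set.seed(6)
  for (i in 1:20) {
    n <- 2000
    x <- stats::rnorm(n)
    y <- stats::runif(n) < plogis(2 * x)
    s <- sensitivity_measure(x, y, n_bins = 100)
    f <- mean(y)
    expect_gte(s, 0)
    expect_lte(s, 100 * max(f, 1 - f) + 1e-12)
  }
})

test_that("permutation filtering separates a real effect from null noise", {
  set.seed(9)
  n <- 2000
  # two parameters: one determines the outcome, one is pure noise
  m <- cbind(a = stats::runif(n), b = stats::runif(n))
  outcomes <- cbind(`1` = m[, "a"] > stats::median(m[, "a"]))
  sp <- structure(list(matrix = m,
                       defaults = stats::setNames(c(1, 1), c("a", "b")),
                       seed = 9, factor_range = c(0.5, 2)),
                  class = "pias3net_sample")
  sens <- sensitivity_analysis(sp, outcomes, n_bins = 100,
                               n_permutations = 500, seed = 99)
  expect_true(all(sens$threshold >= 0))
  expect_equal(sens$s[1, "a"], 50)
  expect_gt(sens$filtered[1, "a"], 0)           # survives the null
  expect_identical(sens$filtered[1, "b"], 0)    # noise is filtered out
  expect_identical(insensitive_parameters(sens), "b")
  expect_equal(sens$normalized[1, "a"], 1)
  # determinism of the permutation stream
  sens2 <- sensitivity_analysis(sp, outcomes, n_bins = 100,
                                n_permutations = 500, seed = 99)
  expect_identical(sens$threshold, sens2$threshold)
})

test_that("normalization maps rows to [0, 1], keeps order, and preserves zeros", {
  s <- rbind(a = c(0, 2, 8), b = c(0, 0, 0))
  ns <- normalize_sensitivity(s)
  expect_equal(ns["a", ], c(0, 0.25, 1))
  expect_equal(ns["b", ], c(0, 0, 0))
  expect_identical(order(ns["a", ]), order(s["a", ]))
  expect_identical(insensitive_parameters(rbind(z = c(0, 0, 0))),
                   colnames(rbind(z = c(0, 0, 0))))
})

test_that("a one-row outcome matrix at the defaults equals the default batch", {
  d <- default_parameters()
  sp <- sample_parameters(d, n = 1, seed = 1)
  sp$matrix[1, ] <- as.numeric(d[core_parameter_names()])
  om <- outcome_matrix(sp)
  ref <- run_all_experiments(d)
  expect_equal(om$outcomes[1, ], ref$passes)
  expect_true(all(om$success_rate >= 0 & om$success_rate <= 1))
})
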