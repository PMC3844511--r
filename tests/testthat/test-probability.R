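test_that("normalizer matches hand-evaluated values and rejects bad input", {
  expect_equal(risk_normalizer(risk_params(0.5, 1, 1)), 1.0)
  expect_equal(risk_normalizer(risk_params(0.5, 1, 2)), 1.25)
  expect_equal(risk_normalizer(risk_params(0.2, 2, 4)), 1.44)
  expect_error(risk_params(0, 1, 1), "strictly between")
  expect_error(risk_params(1.2, 1, 1), "strictly between")
  expect_error(risk_params(0.5, -1, 1), "nonnegative")
  expect_error(risk_params(0.5, 1, Inf), "finite")
})

test_that("triad probabilities reduce to HWE x Mendel at the null", {
  pr <- triad_probabilities(risk_params(0.5, 1, 1))
  expect_equal(unname(pr),
               c(0.0625, 0.125, 0.125, 0.125, 0.0625, 0.125, 0.0625,
                 0.125, 0.125, 0.0625))
  # at the null, monads are plain HWE genotype frequencies
  p <- 0.37
  expect_equal(unname(monad_probabilities(risk_params(p, 1, 1))),
               c(p^2, 2 * p * (1 - p), (1 - p)^2))
})

test_that("hand-evaluated cells under association", {
  expect_equal(unname(triad_probabilities(risk_params(0.5, 1, 2))[1]), 0.1)
  expect_equal(unname(dyad_probabilities(risk_params(0.5, 1, 2))["m3"]), 0.2)
  expect_equal(unname(dyad_probabilities(risk_params(0.5, 1, 1))),
               c(0.125, 0.125, 0.125, 0.25, 0.125, 0.125, 0.125))
  expect_equal(unname(monad_probabilities(risk_params(0.5, 1, 2))),
               c(0.4, 0.4, 0.2))
})

test_that("probability vectors are normalized across the parameter space", {
  set.seed(11)
  for (i in 1:100) {
    params <- risk_params(runif(1, 0.001, 0.999),
                          runif(1, 0, 100), runif(1, 0, 100))
    expect_equal(sum(triad_probabilities(params)), 1, tolerance = 1e-12)
    expect_equal(sum(dyad_probabilities(params)), 1, tolerance = 1e-12)
    expect_equal(sum(monad_probabilities(params)), 1, tolerance = 1e-12)
  }
  # psi = 0 boundaries stay normalized
  for (params in list(risk_params(0.3, 0, 0), risk_params(0.3, 1, 0))) {
    expect_equal(sum(triad_probabilities(params)), 1, tolerance = 1e-12)
  }
})

test_that("simplified and complex dyad columns agree to machine precision", {
  set.seed(12)
  for (i in 1:100) {
    params <- random_params()
    expect_equal(dyad_probabilities(params, "simplified"),
                 dyad_probabilities(params, "complex"), tolerance = 1e-12)
  }
})

test_that("marginalizing triad cells over the unobserved parent gives the dyad cells", {
  # For an observed parent G and child C, sum P(MT, C | D) over the other
  # parent's genotype, halving cells of heterogeneous mating types (the
  # observed parent is a specific one of the two).
  set.seed(13)
  for (i in 1:25) {
    params <- random_params()
    tp <- triad_probabilities(params)
    expected <- c(
      m1 = tp[["n1"]] + tp[["n2"]] / 2,             # G=AA, C=AA
      m2 = tp[["n3"]] / 2 + tp[["n4"]] / 2,         # G=AA, C=Aa
      m3 = tp[["n2"]] / 2 + tp[["n5"]],             # G=Aa, C=AA
      m4 = tp[["n3"]] / 2 + tp[["n6"]] + tp[["n8"]] / 2,
      m5 = tp[["n7"]] + tp[["n9"]] / 2,             # G=Aa, C=aa
      m6 = tp[["n4"]] / 2 + tp[["n8"]] / 2,         # G=aa, C=Aa
      m7 = tp[["n9"]] / 2 + tp[["n10"]]             # G=aa, C=aa
    )
    expect_equal(unname(dyad_probabilities(params)), unname(expected),
                 tolerance = 1e-12)
  }
})

test_that("unordered Schaid-Sommer form exceeds the ordered dyad cell by p^3 q psi2 / R", {
  expect_equal(schaid_sommer_unordered(risk_params(0.5, 1, 1)), 0.1875)
  expect_equal(schaid_sommer_unordered(risk_params(0.5, 1, 2)), 0.3)
  set.seed(14)
  for (i in 1:25) {
    params <- random_params()
    p <- params$p; q <- 1 - p
    diff <- schaid_sommer_unordered(params) -
      dyad_probabilities(params)[["m3"]]
    expect_equal(diff, p^3 * q * params$psi2 / risk_normalizer(params),
                 tolerance = 1e-14)
  }
})
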