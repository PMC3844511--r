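test_that("cell-sum and printed-expansion forms of the log-likelihoods agree", {
  set.seed(21)
  for (i in 1:50) {
    params <- random_params()
    nn <- rpois(10, 3); mm <- rpois(7, 3); ss <- rpois(3, 3)
    expect_equal(loglik_triads(triad_counts(nn), params),
                 oracle_loglik_triads(nn, params$p, params$psi1, params$psi2),
                 tolerance = 1e-10)
    expect_equal(loglik_dyads(dyad_counts(mm), params),
                 oracle_loglik_dyads(mm, params$p, params$psi1, params$psi2),
                 tolerance = 1e-10)
    expect_equal(loglik_monads(monad_counts(ss), params),
                 oracle_loglik_monads(ss, params$p, params$psi1, params$psi2),
                 tolerance = 1e-10)
  }
})

test_that("hand-evaluated log-likelihood values", {
  # single triad in the AA x aa cell: 2 p^2 q^2 psi1 / R
  # with (p, psi1, psi2) = (0.5, 2, 1): R = 1.5, so log(1/6)
  nn <- integer(10); nn[4] <- 1L
  expect_equal(loglik_triads(triad_counts(nn), risk_params(0.5, 2, 1)),
               log(2 * 0.0625 * 2 / 1.5))
  # single dyad in the Aa/Aa cell at the null: log(1/4)
  mm <- integer(7); mm[4] <- 1L
  expect_equal(loglik_dyads(dyad_counts(mm), risk_params(0.5, 1, 1)),
               log(0.25))
  # monads (s2, s1, s0) = (1, 2, 1) at the null: -6 log 2
  expect_equal(loglik_monads(monad_counts(c(1, 2, 1)), risk_params(0.5)),
               -6 * log(2))
})

test_that("empty counts give zero log-likelihood and components add up", {
  params <- risk_params(0.3, 2, 3)
  empty <- family_dataset()
  expect_identical(loglik_combined(empty, params), 0)
  set.seed(22)
  d <- random_dataset()
  expect_equal(loglik_combined(d, params),
               loglik_triads(d$triads, params) +
                 loglik_dyads(d$dyads, params) +
                 loglik_monads(d$monads, params),
               tolerance = 1e-12)
  only_triads <- family_dataset(triads = d$triads)
  expect_equal(loglik_combined(only_triads, params),
               loglik_triads(d$triads, params))
})

test_that("positive count on a zero-probability cell yields -Inf, not an error", {
  nn <- integer(10); nn[1] <- 3L  # AA x AA cell needs psi2 > 0
  expect_identical(loglik_triads(triad_counts(nn), risk_params(0.5, 1, 0)),
                   -Inf)
  # but a zero count on that cell contributes 0
  nn2 <- integer(10); nn2[10] <- 2L
  expect_true(is.finite(loglik_triads(triad_counts(nn2),
                                      risk_params(0.5, 1, 0))))
})

test_that("count constructors reject invalid cells", {
  expect_error(triad_counts(c(1, 2, 3)), "10 cell counts")
  expect_error(triad_counts(c(-1, rep(0, 9))), "nonnegative")
  expect_error(monad_counts(c(0.5, 0, 0)), "integers")
})

test_that("sufficient statistics match direct coefficient pooling", {
  set.seed(23)
  d <- random_dataset()
  S <- suff_stats(d)
  nn <- as.numeric(d$triads); mm <- as.numeric(d$dyads)
  ss <- as.numeric(d$monads)
  expect_equal(S[["Kp"]],
               sum(nn * c(4, 3, 3, 2, 2, 2, 2, 1, 1, 0)) +
                 sum(mm * c(3, 2, 2, 1, 1, 1, 0)) + 2 * ss[1] + ss[2])
  expect_equal(S[["K1"]],
               sum(nn * c(0, 0, 1, 1, 0, 1, 0, 1, 0, 0)) +
                 sum(mm * c(0, 1, 0, 1, 0, 1, 0)) + ss[2])
  expect_equal(S[["N"]], sum(nn) + sum(mm) + sum(ss))
  # Kp + Kq pools 4 alleles per triad, 3 per dyad (except the Aa/Aa cell
  # m4, whose simplified probability p q psi1 has total allele power 2)
  # and 2 per monad
  expect_equal(S[["Kp"]] + S[["Kq"]],
               4 * sum(nn) + 3 * sum(mm) - mm[4] + 2 * sum(ss))
})
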