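test_that("null MLE has the closed form Kp / (Kp + Kq)", {
  d <- family_dataset(triads = null_triads())
  fit <- mle_null(d)
  expect_equal(fit$p, 0.5)
  expect_equal(fit$psi1, 1)
  expect_equal(fit$psi2, 1)
  # monomorphic data cannot be tested
  expect_error(mle_null(family_dataset(monads = c(4, 0, 0))), "degenerate")
  expect_error(mle_null(family_dataset(monads = c(0, 0, 7))), "degenerate")
})

test_that("closed-form null MLE equals the 1-D numeric maximizer", {
  set.seed(31)
  for (i in 1:10) {
    d <- random_dataset(n = rpois(1, 40) + 5, m = rpois(1, 15),
                        s = rpois(1, 10),
                        params = random_params())
    fit <- mle_null(d)
    opt <- optimize(function(p) loglik_combined(d, risk_params(p, 1, 1)),
                    interval = c(1e-6, 1 - 1e-6), maximum = TRUE,
                    tol = 1e-10)
    # golden-section locates the maximum to ~sqrt(eps); the likelihood
    # value is comparable far more tightly than the location
    expect_equal(fit$p, opt$maximum, tolerance = 1e-6)
    expect_gte(fit$loglik, opt$objective - 1e-10)
    expect_equal(fit$loglik, opt$objective, tolerance = 1e-8)
  }
})

test_that("data at exact null proportions give the null as constrained MLE", {
  d <- family_dataset(triads = null_triads())
  null_ll <- mle_null(d)$loglik
  for (model in c("Unr", "Dom", "Rec", "Mult", "Add")) {
    fit <- mle_alternative(d, model)
    expect_equal(fit$p, 0.5, tolerance = 1e-5)
    expect_equal(fit$psi1, 1, tolerance = 1e-4)
    expect_equal(fit$psi2, 1, tolerance = 1e-4)
    expect_equal(fit$loglik, null_ll, tolerance = 1e-9)
  }
})

test_that("constraints are satisfied exactly and likelihoods nest", {
  set.seed(32)
  for (i in 1:8) {
    d <- random_dataset(n = 50, m = 18, s = 12, params = random_params())
    null_ll <- mle_null(d)$loglik
    fits <- lapply(setNames(nm = c("Unr", "Dom", "Rec", "Mult", "Add")),
                   function(mod) mle_alternative(d, mod))
    expect_identical(fits$Dom$psi2, fits$Dom$psi1)
    expect_identical(fits$Mult$psi2, fits$Mult$psi1^2)
    expect_identical(fits$Add$psi2, 2 * fits$Add$psi1 - 1)
    expect_identical(fits$Rec$psi1, 1)
    expect_gte(fits$Add$psi1, 0.5)
    for (mod in c("Dom", "Rec", "Mult", "Add")) {
      expect_gte(fits$Unr$loglik, fits[[mod]]$loglik - 1e-9)
      expect_gte(fits[[mod]]$loglik, null_ll - 1e-9)
    }
  }
})

test_that("constrained MLEs match a coarse-to-fine grid oracle", {
  set.seed(33)
  d <- random_dataset(n = 30, m = 10, s = 8,
                      params = risk_params(0.35, 1.6, 2.4))
  for (model in c("Unr", "Dom", "Rec", "Mult", "Add")) {
    fit <- mle_alternative(d, model)
    grid <- oracle_grid_mle(d, model)
    # the optimizer must do at least as well as the grid's best point ...
    expect_gte(fit$loglik, grid$loglik - 1e-6)
    # ... and cannot be far above it (the grid brackets the optimum)
    expect_lt(fit$loglik - grid$loglik, 0.05)
  }
})

test_that("free parameters are recovered at large sample size", {
  # single large-sample check under the multiplicative model
  set.seed(34)
  truth <- risk_params(0.3, 1.8, 3.24)
  d <- family_dataset(triads = drop(rmultinom(1, 50000,
                                              triad_probabilities(truth))))
  fit <- mle_alternative(d, "Mult")
  expect_lt(abs(fit$p - 0.3), 0.02)
  expect_lt(abs(fit$psi1 - 1.8), 0.02)

  # bias of the free parameters vanishes: average estimates over 20
  # replicate datasets per correctly specified model
  gen <- list(Unr = risk_params(0.5, 1.2, 1.5),
              Dom = risk_params(0.5, 1.5, 1.5),
              Rec = risk_params(0.5, 1, 1.45),
              Mult = risk_params(0.3, 1.8, 3.24),
              Add = risk_params(0.5, 1.5, 2))
  for (model in names(gen)) {
    truth <- gen[[model]]
    counts <- rmultinom(20, 50000, triad_probabilities(truth))
    est <- vapply(seq_len(20), function(j) {
      f <- mle_alternative(family_dataset(triads = counts[, j]), model)
      c(f$p, f$psi1, f$psi2)
    }, numeric(3))
    avg <- rowMeans(est)
    expect_lt(abs(avg[1] - truth$p), 0.02)
    expect_lt(abs(avg[2] - truth$psi1), 0.02)
    expect_lt(abs(avg[3] - truth$psi2), 0.02)
  }
})

test_that("boundary estimates are flagged instead of failing", {
  # no AA children at all: the recessive psi2 MLE sits on the zero boundary
  d <- family_dataset(triads = c(0, 0, 4, 5, 0, 8, 3, 6, 5, 2))
  fit <- mle_alternative(d, "Rec")
  expect_true(fit$boundary)
  expect_lt(fit$psi2, 1e-8)
  expect_true(is.finite(fit$loglik))
})
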