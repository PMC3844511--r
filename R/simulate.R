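#' Simulation study configuration
#'
#' Bundles the generating parameters and sample sizes of a Monte-Carlo
#' study: each replicate dataset draws the triad cells from
#' `Multinomial(n, triad_probabilities(params))`, the dyad cells from
#' `Multinomial(m, dyad_probabilities(params))` and the monad cells from
#' `Multinomial(s, monad_probabilities(params))`, mutually independently.
#'
#' @param p,psi1,psi2 generating values (see [risk_params()]); the null
#'   hypothesis is `psi1 = psi2 = 1`.
#' @param n,m,s numbers of triad, dyad and monad families per replicate
#'   (nonnegative, not all zero).
#' @param replicates number of replicate datasets.
#' @param seed integer seed for the Mersenne-Twister stream, or `NULL` to
#'   use the current RNG state.
#' @param alpha nominal significance levels.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(p = 0.5, n = 100, m = 25, s = 50, replicates = 1000, seed = 1)
#' @export
sim_config <- function(p, psi1 = 1, psi2 = 1, n = 0, m = 0, s = 0,
                       replicates = 10000, seed = NULL,
                       alpha = c(0.05, 0.01)) {
  params <- risk_params(p, psi1, psi2)
  for (nm in c("n", "m", "s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop("`", nm, "` must be a single nonnegative integer", call. = FALSE)
  }
  if (n + m + s == 0)
    stop("at least one of n, m, s must be positive", call. = FALSE)
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1)
    stop("`replicates` must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha > 1))
    stop("`alpha` levels must lie in (0, 1]", call. = FALSE)
  structure(list(params = params, n = as.integer(n), m = as.integer(m),
                 s = as.integer(s), replicates = as.integer(replicates),
                 seed = if (!is.null(seed)) as.integer(seed),
                 alpha = alpha),
            class = "sim_config")
}

.rmultinom_or_zero <- function(reps, size, prob) {
  if (size > 0) rmultinom(reps, size, prob)
  else matrix(0L, nrow = length(prob), ncol = reps)
}

#' Simulate one family dataset from a study configuration
#'
#' @param config a [sim_config()].
#' @return A [family_dataset()] whose component totals are exactly
#'   `config$n`, `config$m`, `config$s`.
#' @examples
#' simulate_dataset(sim_config(p = 0.5, n = 100, seed = 1))
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  family_dataset(
    triads = drop(.rmultinom_or_zero(1L, config$n,
                                     triad_probabilities(config$params))),
    dyads = drop(.rmultinom_or_zero(1L, config$m,
                                    dyad_probabilities(config$params))),
    monads = drop(.rmultinom_or_zero(1L, config$s,
                                     monad_probabilities(config$params))))
}

## vectorized moment starts / constrained parameter maps for batch fitting

.moment_theta_mat <- function(model, mom) {
  cl <- function(x) pmin(pmax(x, -.V_BOUND + 5), .V_BOUND - 5)
  switch(model,
    Unr = cbind(cl(log(mom[, 1L])), cl(log(mom[, 2L]))),
    Dom = cbind(cl(log((mom[, 1L] + mom[, 2L]) / 2))),
    Rec = cbind(cl(log(mom[, 2L]))),
    Mult = cbind(cl((log(mom[, 1L]) + 0.5 * log(mom[, 2L])) / 2)),
    Add = cbind(cl(log(pmax(mom[, 1L] - 0.5, 1e-6))))
  )
}

.theta_to_psi_mat <- function(model, V) {
  switch(model,
    Unr = cbind(exp(V[, 1L]), exp(V[, 2L])),
    Dom = { s <- exp(V[, 1L]); cbind(s, s) },
    Rec = cbind(1, exp(V[, 1L])),
    Mult = { s <- exp(V[, 1L]); cbind(s, s^2) },
    Add = { s <- 0.5 + exp(V[, 1L]); cbind(s, 2 * s - 1) }
  )
}

# Constrained maximized log-likelihood (constants-free scale) for every row
# of a sufficient-statistic matrix.  First pass starts each fit at the null;
# rows where the model-constrained moment start attains a higher likelihood
# than the fitted optimum are refit from that start.
.fit_batch <- function(STu, model) {
  nu <- nrow(STu)
  ll <- rep(NA_real_, nu)
  conv <- logical(nu)
  bound <- logical(nu)
  phat <- .null_phat(STu)
  u0 <- pmin(pmax(qlogis(phat), -.U_BOUND + 1), .U_BOUND - 1)
  th_null <- .theta_null(model)
  for (i in seq_len(nu)) {
    f <- .fit_stats(STu[i, ], model, rbind(c(u0[i], th_null)))
    ll[i] <- f$ll_stats
    conv[i] <- f$converged
    bound[i] <- f$boundary
  }
  mom <- .moment_psi(STu, phat)
  Vm <- .moment_theta_mat(model, mom)
  psim <- .theta_to_psi_mat(model, Vm)
  llm <- .ll_stats(STu, phat, psim[, 1L], psim[, 2L])
  redo <- which(llm > ll + 1e-8)
  for (i in redo) {
    f <- .fit_stats(STu[i, ], model, rbind(c(u0[i], Vm[i, ])))
    if (f$ll_stats > ll[i]) {
      ll[i] <- f$ll_stats
      conv[i] <- f$converged
      bound[i] <- f$boundary
    }
  }
  list(ll = ll, converged = conv, boundary = bound)
}

.TDT_B_W <- c(0, 1, 0, 0, 2, 1, 0, 1, 0, 0)
.TDT_C_W <- c(0, 0, 1, 0, 0, 1, 2, 0, 1, 0)
.DYAD_B1_W <- c(0, 1, 0, 0, 1, 0, 0)
.DYAD_C1_W <- c(0, 0, 1, 0, 0, 1, 0)

.STATISTICS <- c(.MODELS, "TDT", "zcom")

#' Run a type-I-error or power study
#'
#' Simulates `config$replicates` datasets, evaluates each requested
#' statistic on every replicate and reports the proportion rejecting at
#' each nominal level.  LRT statistics are compared to the upper chi-square
#' quantile (2 df for Unr, 1 df otherwise), the TDT to chi-square with 1 df
#' and `z_com` to the two-sided standard-normal critical value.
#'
#' Replicates on which a statistic is undefined (degenerate data for the
#' LRTs, `b + c = 0` for the TDT, `V_com = 0` for `z_com`) or on which the
#' optimizer fails are counted as failures and excluded from both the
#' numerator and denominator of the rejection proportion, never silently
#' dropped; the failure count is reported per statistic.
#'
#' Identical (config, seed) pairs reproduce identical results: all
#' replicate counts are drawn from one seeded Mersenne-Twister stream in a
#' deterministic order.  Internally the likelihood is maximized on the
#' sufficient statistics of each replicate, with identical replicates
#' deduplicated, so studies with `1e5` replicates run in minutes.
#'
#' @param config a [sim_config()].
#' @param statistics character vector drawn from
#'   `c("Unr", "Dom", "Rec", "Mult", "Add", "TDT", "zcom")`.
#' @param on_failure `"warn"` (default) or `"error"`: escalation when a
#'   statistic fails on more than 1% of replicates.
#' @return A data frame of class `triad_study`, one row per
#'   statistic x alpha, with columns `statistic`, `alpha`, `replicates`,
#'   `n_failed`, `n_used`, `n_reject`, `proportion` and `mc_se`
#'   (`sqrt(r (1 - r) / n_used)`).  The configuration is attached as
#'   attribute `"config"`.
#' @examples
#' cfg <- sim_config(p = 0.5, n = 100, m = 25, s = 50,
#'                   replicates = 200, seed = 1)
#' run_study(cfg, statistics = c("Dom", "TDT"))
#' @export
run_study <- function(config, statistics = .STATISTICS,
                      on_failure = c("warn", "error")) {
  stopifnot(inherits(config, "sim_config"))
  on_failure <- match.arg(on_failure)
  statistics <- unique(vapply(statistics, function(s) {
    i <- match(tolower(s), tolower(.STATISTICS))
    if (is.na(i)) stop("unknown statistic '", s, "'", call. = FALSE)
    .STATISTICS[i]
  }, character(1L), USE.NAMES = FALSE))
  reps <- config$replicates
  if (!is.null(config$seed)) set.seed(config$seed)
  Tn <- .rmultinom_or_zero(reps, config$n, triad_probabilities(config$params))
  Tm <- .rmultinom_or_zero(reps, config$m, dyad_probabilities(config$params))
  Ts <- .rmultinom_or_zero(reps, config$s, monad_probabilities(config$params))

  lrt_models <- intersect(statistics, .MODELS)
  stat_vals <- list()
  if (length(lrt_models)) {
    ST <- cbind(t(Tn) %*% .TRIAD_COEF + t(Tm) %*% .DYAD_COEF +
                  t(Ts) %*% .MONAD_COEF,
                N = config$n + config$m + config$s)
    ok <- ST[, 1L] > 0 & ST[, 2L] > 0
    idx <- which(ok)
    key <- paste(ST[idx, 1L], ST[idx, 2L], ST[idx, 3L], ST[idx, 4L])
    first <- !duplicated(key)
    STu <- ST[idx[first], , drop = FALSE]
    map <- match(key, key[first])
    phat_u <- .null_phat(STu)
    ll0_u <- .ll_stats(STu, phat_u, 1, 1)
    for (model in lrt_models) {
      fb <- .fit_batch(STu, model)
      stat_u <- 2 * (fb$ll - ll0_u)
      stat_u[stat_u < 0 & stat_u > -1e-8] <- 0
      stat_u[stat_u < 0 | !is.finite(stat_u)] <- NA_real_
      # an estimate on an admissibility boundary (e.g. psi2 -> 0 with no
      # AA children observed) is a diverged risk-parameter update: counted
      # as a non-converged replicate, per the failure-exclusion policy
      stat_u[fb$boundary] <- NA_real_
      stat <- rep(NA_real_, reps)
      stat[idx] <- stat_u[map]
      stat_vals[[model]] <- stat
    }
  }
  if ("TDT" %in% statistics) {
    b <- drop(.TDT_B_W %*% Tn)
    cc <- drop(.TDT_C_W %*% Tn)
    stat <- (b - cc)^2 / (b + cc)
    stat[b + cc == 0] <- NA_real_
    stat_vals[["TDT"]] <- stat
  }
  if ("zcom" %in% statistics) {
    b <- drop(.TDT_B_W %*% Tn)
    cc <- drop(.TDT_C_W %*% Tn)
    b1 <- drop(.DYAD_B1_W %*% Tm)
    c1 <- drop(.DYAD_C1_W %*% Tm)
    V <- (b + cc) / 4 + (b1 + c1) / 4
    z <- ((b + b1) - ((b + cc) / 2 + (b1 + c1) / 2)) / sqrt(V)
    z[V == 0] <- NA_real_
    stat_vals[["zcom"]] <- z
  }

  rows <- list()
  for (statname in statistics) {
    x <- stat_vals[[statname]]
    n_failed <- sum(is.na(x))
    n_used <- reps - n_failed
    if (n_failed > 0.01 * reps) {
      msg <- sprintf("statistic %s failed on %d of %d replicates",
                     statname, n_failed, reps)
      if (on_failure == "error") stop(msg, call. = FALSE) else warning(msg)
    }
    for (a in config$alpha) {
      crit <- switch(statname,
        Unr = qchisq(1 - a, 2L),
        TDT = qchisq(1 - a, 1L),
        zcom = qnorm(1 - a / 2),
        qchisq(1 - a, 1L))
      rej <- if (statname == "zcom") abs(x) >= crit else x >= crit
      n_reject <- sum(rej, na.rm = TRUE)
      r <- n_reject / n_used
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = statname, alpha = a, replicates = reps,
        n_failed = n_failed, n_used = n_used, n_reject = n_reject,
        proportion = r, mc_se = sqrt(r * (1 - r) / n_used),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("triad_study", "data.frame")
  out
}

#' @export
print.triad_study <- function(x, ...) {
  cfg <- attr(x, "config")
  if (!is.null(cfg))
    cat(sprintf(
      "Simulation study: p = %g, psi1 = %g, psi2 = %g, n = %d, m = %d, s = %d, %d replicates\n",
      cfg$params$p, cfg$params$psi1, cfg$params$psi2, cfg$n, cfg$m, cfg$s,
      cfg$replicates))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write study results to TSV or JSON
#'
#' @param study a [run_study()] result.
#' @param path output file path.
#' @param format `"tsv"` (tidy, one row per statistic x alpha) or `"json"`
#'   (results plus the generating configuration).
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(study, "triad_study"))
  if (format == "tsv") {
    write.table(as.data.frame(study), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    cfg <- attr(study, "config")
    jsonlite::write_json(
      list(config = list(p = cfg$params$p, psi1 = cfg$params$psi1,
                         psi2 = cfg$params$psi2, n = cfg$n, m = cfg$m,
                         s = cfg$s, replicates = cfg$replicates,
                         seed = cfg$seed, alpha = cfg$alpha),
           results = as.data.frame(study)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
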