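#' Constrained relative-risk model specifications
#'
#' The five alternative hypotheses tested against the null
#' `psi1 = psi2 = 1`:
#' * `Unr` - unrestricted, `psi1 >= 0`, `psi2 >= 0` free (2 df);
#' * `Dom` - dominant, `psi2 = psi1` (1 df);
#' * `Rec` - recessive, `psi1 = 1`, `psi2` free (1 df);
#' * `Mult` - multiplicative, `psi2 = psi1^2` (1 df);
#' * `Add` - additive, `psi2 = 2 psi1 - 1` (1 df; admissibility
#'   `psi2 >= 0` induces `psi1 >= 1/2`).
#'
#' @param name model name (case-insensitive): one of `"Unr"`, `"Dom"`,
#'   `"Rec"`, `"Mult"`, `"Add"`.
#' @return An object of class `model_spec` with elements `name`, `df` and
#'   `constraint` (a function mapping the free risk parameter(s) to
#'   `c(psi1, psi2)`).
#' @examples
#' model_spec("mult")$constraint(1.8)  # c(1.8, 3.24)
#' @export
model_spec <- function(name) {
  nm <- .match_model(name)
  constraint <- switch(nm,
    Unr = function(psi1, psi2) c(psi1 = psi1, psi2 = psi2),
    Dom = function(psi1) c(psi1 = psi1, psi2 = psi1),
    Rec = function(psi2) c(psi1 = 1, psi2 = psi2),
    Mult = function(psi1) c(psi1 = psi1, psi2 = psi1^2),
    Add = function(psi1) c(psi1 = psi1, psi2 = 2 * psi1 - 1)
  )
  structure(list(name = nm, df = if (nm == "Unr") 2L else 1L,
                 constraint = constraint),
            class = "model_spec")
}

.MODELS <- c("Unr", "Dom", "Rec", "Mult", "Add")

.match_model <- function(name) {
  if (inherits(name, "model_spec")) return(name$name)
  if (!is.character(name) || length(name) != 1L)
    stop("`model` must be a single model name or a `model_spec`", call. = FALSE)
  i <- match(tolower(name), tolower(.MODELS))
  if (is.na(i))
    stop("unknown model '", name, "'; choose one of ",
         paste(.MODELS, collapse = ", "), call. = FALSE)
  .MODELS[i]
}

## ---- internal fitting machinery on sufficient statistics ----------------
##
## theta[1] = logit(p); theta[-1] parameterizes the free risk parameter(s):
##   Unr : psi1 = exp(v1), psi2 = exp(v2)
##   Dom : psi1 = psi2 = exp(v)
##   Rec : psi1 = 1, psi2 = exp(v)
##   Mult: psi1 = exp(v), psi2 = exp(2v)
##   Add : psi1 = 1/2 + exp(t), psi2 = 2 exp(t)   (so psi2 = 2 psi1 - 1 >= 0)
## The transforms enforce every admissibility bound without explicit
## constraints; the psi = 0 boundaries are reached as v -> -Inf and are
## clamped at the box bound .V_BOUND (relative likelihood error O(exp(-25))).

.V_BOUND <- 25
.U_BOUND <- 35

.theta_to_psi <- function(model, theta) {
  v <- theta[-1L]
  # psi2 is recomputed from psi1 so each constraint holds bit-exactly
  switch(model,
    Unr = c(exp(v[1L]), exp(v[2L])),
    Dom = { s <- exp(v); c(s, s) },
    Rec = c(1, exp(v)),
    Mult = { s <- exp(v); c(s, s^2) },
    Add = { s <- 0.5 + exp(v); c(s, 2 * s - 1) }
  )
}

.theta_null <- function(model) {
  switch(model, Unr = c(0, 0), Add = log(0.5), 0)
}

.npar <- function(model) if (model == "Unr") 3L else 2L

# constants-free log-likelihood at explicit parameter values (vectorized)
.ll_stats <- function(S, p, psi1, psi2) {
  q <- 1 - p
  R <- p^2 * psi2 + 2 * p * q * psi1 + q^2
  S[, 1L] * log(p) + S[, 2L] * log(q) +
    ifelse(S[, 3L] > 0, S[, 3L] * log(psi1), 0) +
    ifelse(S[, 4L] > 0, S[, 4L] * log(psi2), 0) -
    S[, 5L] * log(R)
}

.negloglik <- function(theta, S, model) {
  p <- plogis(theta[1L]); q <- 1 - p
  ps <- .theta_to_psi(model, theta)
  R <- p^2 * ps[2L] + 2 * p * q * ps[1L] + q^2
  -(S[1L] * log(p) + S[2L] * log(q) +
      S[3L] * log(ps[1L]) + S[4L] * log(ps[2L]) - S[5L] * log(R))
}

.neggrad <- function(theta, S, model) {
  p <- plogis(theta[1L]); q <- 1 - p
  ps <- .theta_to_psi(model, theta)
  s1 <- ps[1L]; s2 <- ps[2L]
  R <- p^2 * s2 + 2 * p * q * s1 + q^2
  Rp <- 2 * p * s2 + 2 * (q - p) * s1 - 2 * q
  du <- S[1L] * q - S[2L] * p - S[5L] * p * q * Rp / R
  gv <- switch(model,
    Unr = c(S[3L] - S[5L] * 2 * p * q * s1 / R,
            S[4L] - S[5L] * p^2 * s2 / R),
    Dom = S[3L] + S[4L] - S[5L] * (p^2 + 2 * p * q) * s1 / R,
    Rec = S[4L] - S[5L] * p^2 * s2 / R,
    Mult = S[3L] + 2 * S[4L] - S[5L] * (2 * p^2 * s2 + 2 * p * q * s1) / R,
    Add = {
      e <- s2 / 2  # exp(t)
      S[3L] * e / s1 + S[4L] - S[5L] * (2 * p^2 + 2 * p * q) * e / R
    }
  )
  -c(du, gv)
}

.null_phat <- function(S) {
  S <- rbind(S)
  unname(S[, 1L] / (S[, 1L] + S[, 2L]))
}

# moment starting values for the risk parameters: the affected-child
# genotype marginal is (p^2 psi2, 2pq psi1, q^2)/R for every family type,
# so child genotype ratios against the aa class estimate psi1 and psi2
# directly (counts smoothed by 1/2 to keep the start finite).
.moment_psi <- function(S, p0) {
  S <- rbind(S)
  q0 <- 1 - p0
  K0 <- S[, 5L] - S[, 3L] - S[, 4L]
  psi1 <- (S[, 3L] + 0.5) * q0 / (2 * p0 * (K0 + 0.5))
  psi2 <- (S[, 4L] + 0.5) * q0^2 / (p0^2 * (K0 + 0.5))
  cbind(psi1 = psi1, psi2 = psi2)
}

.moment_theta <- function(model, psi1, psi2) {
  clamp <- function(x) pmin(pmax(x, -.V_BOUND + 5), .V_BOUND - 5)
  switch(model,
    Unr = c(clamp(log(psi1)), clamp(log(psi2))),
    Dom = clamp(log((psi1 + psi2) / 2)),
    Rec = clamp(log(psi2)),
    Mult = clamp((log(psi1) + 0.5 * log(psi2)) / 2),
    Add = clamp(log(pmax(psi1 - 0.5, 1e-6)))
  )
}

# safeguarded maximization from one or more starts; returns the best fit
.fit_stats <- function(S, model, starts) {
  np <- .npar(model)
  lower <- c(-.U_BOUND, rep(-.V_BOUND, np - 1L))
  upper <- -lower
  best <- NULL
  conv <- FALSE
  iters <- 0L
  for (k in seq_len(nrow(starts))) {
    th0 <- pmin(pmax(starts[k, ], lower), upper)
    f <- tryCatch(
      nlminb(th0, .negloglik, .neggrad, S = S, model = model,
             lower = lower, upper = upper,
             control = list(iter.max = 200, eval.max = 400)),
      error = function(e) NULL)
    if (is.null(f)) next
    iters <- iters + f$iterations
    if (is.null(best) || f$objective < best$objective) {
      best <- f
      conv <- f$convergence == 0
    }
  }
  if (is.null(best))
    stop("optimizer failed from every starting point", call. = FALSE)
  theta <- unname(best$par)
  # a free log-risk drifting far below zero means the likelihood is flat
  # towards the psi = 0 (psi1 = 1/2 for Add) admissibility boundary: snap to
  # the box bound (likelihood change O(exp(-.V_BOUND))) and flag it
  low <- theta[-1L] <= -10
  if (any(low)) {
    snapped <- theta
    snapped[-1L][low] <- -.V_BOUND
    obj <- .negloglik(snapped, S, model)
    if (obj <= best$objective) {
      theta <- snapped
      best$objective <- obj
    }
  }
  psi <- unname(.theta_to_psi(model, theta))
  at_bound <- any(abs(theta[-1L]) >= .V_BOUND - 1e-4) ||
    abs(theta[1L]) >= .U_BOUND - 1e-4
  list(theta = theta, p = unname(plogis(theta[1L])), psi1 = psi[1L],
       psi2 = psi[2L], ll_stats = -unname(best$objective), converged = conv,
       iterations = iters, boundary = at_bound)
}

# coarse-to-fine grid start used as a last-resort restart
.grid_start <- function(S, model) {
  us <- qlogis(seq(0.02, 0.98, length.out = 17))
  vs <- seq(-4, 4, length.out = 17)
  if (model == "Unr") {
    g <- as.matrix(expand.grid(us, vs, vs))
  } else {
    g <- as.matrix(expand.grid(us, vs))
  }
  obj <- apply(g, 1L, .negloglik, S = S, model = model)
  g[which.min(obj), ]
}

.check_degenerate <- function(S) {
  if (S[[1L]] == 0 || S[[2L]] == 0)
    stop("degenerate data: all observed alleles are of one type, so the ",
         "allele frequency estimate lies on the boundary and the tests are ",
         "undefined", call. = FALSE)
  invisible(S)
}

.new_fit <- function(model, df, p, psi1, psi2, loglik, converged, iterations,
                     boundary) {
  structure(list(model = model, df = df, p = p, psi1 = psi1, psi2 = psi2,
                 loglik = loglik, converged = converged,
                 iterations = as.integer(iterations), boundary = boundary),
            class = "triad_fit")
}

#' @export
print.triad_fit <- function(x, ...) {
  cat(sprintf("%s fit: p = %.4f, psi1 = %.4f, psi2 = %.4f, logL = %.4f\n",
              x$model, x$p, x$psi1, x$psi2, x$loglik))
  if (!x$converged) cat("  (optimizer did not report convergence)\n")
  if (x$boundary) cat("  (estimate on the parameter boundary)\n")
  invisible(x)
}

#' Maximum-likelihood estimation under the null hypothesis
#'
#' Under `H0: psi1 = psi2 = 1` the normalizer is `R = 1` and the combined
#' log-likelihood is linear in `log p` and `log q`, so the allele-frequency
#' MLE has the closed form `Kp / (Kp + Kq)` where `Kp` and `Kq` are the
#' pooled coefficients returned by [suff_stats()] (the numbers of A and a
#' alleles counted by the likelihood).
#'
#' @param data a [family_dataset()].
#' @return A `triad_fit` object with `psi1 = psi2 = 1`.
#' @examples
#' d <- family_dataset(triads = c(1, 2, 2, 2, 1, 2, 1, 2, 2, 1))
#' mle_null(d)$p  # 0.5
#' @export
mle_null <- function(data) {
  stopifnot(inherits(data, "family_dataset"))
  S <- suff_stats(data)
  .check_degenerate(S)
  phat <- .null_phat(S)
  .new_fit("Null", 0L, phat, 1, 1,
           loglik = loglik_combined(data, risk_params(phat, 1, 1)),
           converged = TRUE, iterations = 0L, boundary = FALSE)
}

#' Constrained maximum-likelihood estimation under an alternative model
#'
#' Maximizes the combined log-likelihood over `(p, psi1, psi2)` subject to
#' the chosen model's constraint (see [model_spec()]).  Optimization runs on
#' the transformed scale `(logit p, log psi ...)` with analytic gradients
#' from three deterministic starts (null parameters; moment estimates from
#' the affected-child genotype ratios; an overdispersed start), plus a
#' coarse grid restart if the attained likelihood falls below the null
#' likelihood.  The constraint is satisfied exactly by construction
#' (`psi2` is recomputed from `psi1` for Dom/Mult/Add).
#'
#' @param data a [family_dataset()].
#' @param model a model name or [model_spec()].
#' @return A `triad_fit` object; `boundary` is `TRUE` when an estimate hit
#'   an admissibility bound (for example `psi2 = 0` under Rec).
#' @examples
#' d <- family_dataset(triads = c(1, 2, 2, 2, 1, 2, 1, 2, 2, 1))
#' mle_alternative(d, "Dom")  # data at exact null proportions: MLE at null
#' @export
mle_alternative <- function(data, model) {
  stopifnot(inherits(data, "family_dataset"))
  model <- .match_model(model)
  S <- suff_stats(data)
  .check_degenerate(S)
  phat <- .null_phat(S)
  u0 <- pmin(pmax(qlogis(phat), -.U_BOUND + 1), .U_BOUND - 1)
  mom <- .moment_psi(S, phat)
  starts <- rbind(
    c(u0, .theta_null(model)),
    c(u0, .moment_theta(model, mom[1L, "psi1"], mom[1L, "psi2"])),
    c(u0, .theta_null(model) + log(3))
  )
  fit <- .fit_stats(S, model, starts)
  ll0 <- .ll_stats(rbind(S), phat, 1, 1)
  if (fit$ll_stats < ll0 - 1e-9) {
    fit2 <- .fit_stats(S, model, rbind(.grid_start(S, model)))
    if (fit2$ll_stats > fit$ll_stats) fit <- fit2
    if (fit$ll_stats < ll0 - 1e-9) {
      cond <- structure(
        class = c("triadlrt_nonconvergence", "error", "condition"),
        list(message = sprintf(
          "constrained optimization for model %s did not reach the null likelihood (best logL deficit %.3g)",
          model, ll0 - fit$ll_stats),
          call = NULL, best = fit))
      stop(cond)
    }
  }
  params <- risk_params(fit$p, fit$psi1, fit$psi2)
  .new_fit(model, model_spec(model)$df, fit$p, fit$psi1, fit$psi2,
           loglik = loglik_combined(data, params),
           converged = fit$converged, iterations = fit$iterations,
           boundary = fit$boundary)
}
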