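# Triad counts at exact null proportions (p = 0.5, psi1 = psi2 = 1):
# 16 families distributed as 16 * triad_probabilities(risk_params(0.5)).
null_triads <- function() triad_counts(c(1, 2, 2, 2, 1, 2, 1, 2, 2, 1))

random_params <- function() {
  risk_params(runif(1, 0.05, 0.95), runif(1, 0, 5), runif(1, 0, 5))
}

random_dataset <- function(n = 60, m = 20, s = 15,
                           params = risk_params(0.4, 1.5, 2)) {
  family_dataset(
    triads = drop(rmultinom(1, n, triad_probabilities(params))),
    dyads = drop(rmultinom(1, m, dyad_probabilities(params))),
    monads = drop(rmultinom(1, s, monad_probabilities(params))))
}

# Expand a family_dataset back into per-family records, randomizing which
# parent carries which genotype (triads) and which parent is observed
# (dyads): tabulation must be invariant to both.
synthesize_records <- function(d) {
  tcells <- triad_cells()
  dcells <- dyad_cells()
  rows <- list()
  add <- function(father, mother, child) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family_id = sprintf("F%03d", length(rows) + 1L),
      father = father, mother = mother, child = child,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(10)) {
    pair <- strsplit(tcells$mating_type[i], "x", fixed = TRUE)[[1L]]
    for (k in seq_len(d$triads[[i]])) {
      ord <- sample(2L)
      add(pair[ord[1L]], pair[ord[2L]], tcells$child[i])
    }
  }
  for (i in seq_len(7)) {
    for (k in seq_len(d$dyads[[i]])) {
      if (sample(2L, 1L) == 1L) add(dcells$parent[i], NA, dcells$child[i])
      else add(NA, dcells$parent[i], dcells$child[i])
    }
  }
  for (i in seq_len(3)) {
    for (k in seq_len(d$monads[[i]]))
      add(NA, NA, names(d$monads)[i])
  }
  do.call(rbind, rows)
}

# Independent log-likelihood oracle: the printed coefficient expansions of
# the triad/dyad/monad log-likelihoods plus the parameter-free per-cell
# Mendelian constants (log 2 terms) that the expansions drop.
oracle_loglik_triads <- function(nn, p, psi1, psi2) {
  q <- 1 - p
  R <- p^2 * psi2 + 2 * p * q * psi1 + q^2
  const <- log(c(1, 2, 2, 2, 1, 2, 1, 2, 2, 1))
  sum(nn * c(4, 3, 3, 2, 2, 2, 2, 1, 1, 0)) * log(p) +
    sum(nn * c(0, 1, 1, 2, 2, 2, 2, 3, 3, 4)) * log(q) +
    sum(nn * c(0, 0, 1, 1, 0, 1, 0, 1, 0, 0)) * log(psi1) +
    sum(nn * c(1, 1, 0, 0, 1, 0, 0, 0, 0, 0)) * log(psi2) -
    sum(nn) * log(R) + sum(nn * const)
}

oracle_loglik_dyads <- function(mm, p, psi1, psi2) {
  q <- 1 - p
  R <- p^2 * psi2 + 2 * p * q * psi1 + q^2
  sum(mm * c(3, 2, 2, 1, 1, 1, 0)) * log(p) +
    sum(mm * c(0, 1, 1, 1, 2, 2, 3)) * log(q) +
    sum(mm * c(0, 1, 0, 1, 0, 1, 0)) * log(psi1) +
    sum(mm * c(1, 0, 1, 0, 0, 0, 0)) * log(psi2) -
    sum(mm) * log(R)
}

oracle_loglik_monads <- function(ss, p, psi1, psi2) {
  # ss in (AA, Aa, aa) order, i.e. (s2, s1, s0)
  q <- 1 - p
  R <- p^2 * psi2 + 2 * p * q * psi1 + q^2
  const <- log(c(1, 2, 1))
  (2 * ss[1] + ss[2]) * log(p) + (ss[2] + 2 * ss[3]) * log(q) +
    ss[2] * log(psi1) + ss[1] * log(psi2) - sum(ss) * log(R) +
    sum(ss * const)
}

# Coarse-to-fine grid maximization of the combined log-likelihood under a
# model constraint; independent of the package's optimizer.
oracle_grid_mle <- function(data, model, levels = 3) {
  constraint <- model_spec(model)$constraint
  lo_p <- 0.02; hi_p <- 0.98
  lo_v <- -2.5; hi_v <- 2.5
  npar2 <- if (model == "Unr") 2 else 1
  best <- NULL
  for (lev in seq_len(levels)) {
    ps <- seq(lo_p, hi_p, length.out = 15)
    vs <- seq(lo_v, hi_v, length.out = 15)
    grid <- if (npar2 == 2) expand.grid(p = ps, v1 = vs, v2 = vs)
            else expand.grid(p = ps, v1 = vs)
    ll <- apply(grid, 1, function(g) {
      psi <- if (npar2 == 2) constraint(exp(g[2]), exp(g[3]))
             else if (model == "Add") constraint(0.5 + exp(g[2]))
             else constraint(exp(g[2]))
      loglik_combined(data, risk_params(g[1], psi[1], psi[2]))
    })
    k <- which.max(ll)
    best <- list(par = unlist(grid[k, ]), loglik = ll[k])
    dp <- (hi_p - lo_p) / 14; dv <- (hi_v - lo_v) / 14
    lo_p <- max(0.001, best$par[1] - dp); hi_p <- min(0.999, best$par[1] + dp)
    lo_v <- best$par[2] - dv; hi_v <- best$par[2] + dv
    if (npar2 == 2) {
      lo_v <- min(best$par[2], best$par[3]) - dv
      hi_v <- max(best$par[2], best$par[3]) + dv
    }
  }
  best
}
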