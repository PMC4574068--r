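# Diversification likelihoods on branching times.
#
# All models share one additive-constant convention (crown-conditioned, no
# (N-1)! term): the pure-birth log-likelihood is
#   lnL = (N-2) ln lambda - lambda * G,   G = 2 t_2 + sum_{i>=3} t_i,
# and every other model reduces to it bit-identically on its nested
# boundary (BD at a = 0; DDX at x = 0; DDL as K -> Inf; multi-rate Yule
# with equal rates). AIC = 2 * df - 2 lnL throughout, so cross-model AIC
# differences are meaningful.

as_branching_times <- function(x) {
  bt <- if (inherits(x, "phylo")) branching_times(x) else sort(as.numeric(x), decreasing = TRUE)
  if (length(bt) < 1 || any(bt <= 0) || any(!is.finite(bt))) {
    abort("branching times must be positive and finite")
  }
  bt
}

# total lineage-time ("exposure") G = 2 t_2 + sum_{i>=3} t_i
bt_exposure <- function(bt) bt[1] + sum(bt)

# duration with k lineages, k = 2..N (last interval ends at the present)
bt_durations <- function(bt) bt - c(bt[-1], 0)

#' Pure-birth (Yule) likelihood and closed-form MLE
#'
#' `pb_loglik()` evaluates the crown-conditioned pure-birth log-likelihood
#' on a branching-time vector; `pb_mle()` returns the closed-form maximum
#' `lambda_hat = (N - 2) / G` with `G` the total lineage-time.
#'
#' @param bt Branching times (descending numeric vector) or a dated `phylo`.
#' @param lambda Speciation rate, > 0.
#' @param permissive Return `-Inf` instead of erroring for `lambda <= 0`.
#' @return `pb_loglik()`: scalar log-likelihood. `pb_mle()`: list with
#'   `lambda`, `loglik`, `df`, `aic`.
#' @examples
#' pb_loglik(c(2, 1), lambda = 0.2)  # ln 0.2 - 1
#' pb_mle(c(2, 1))$lambda            # 0.2
#' @export
pb_loglik <- function(bt, lambda, permissive = FALSE) {
  bt <- as_branching_times(bt)
  if (lambda <= 0) {
    if (permissive) return(-Inf)
    abort("`lambda` must be > 0")
  }
  n <- length(bt) + 1L
  (n - 2) * log(lambda) - lambda * bt_exposure(bt)
}

#' @rdname pb_loglik
#' @export
pb_mle <- function(bt) {
  bt <- as_branching_times(bt)
  n <- length(bt) + 1L
  G <- bt_exposure(bt)
  lambda <- (n - 2) / G
  ll <- if (n == 2) 0 else pb_loglik(bt, lambda)
  list(lambda = lambda, loglik = ll, df = 1L, aic = 2 - 2 * ll)
}

#' Birth-death likelihood (reconstructed process)
#'
#' Log-likelihood of the constant-rate birth-death reconstructed process,
#' conditioned on the crown age and survival, parameterised by the net
#' diversification rate `r = lambda - mu` and the extinction fraction
#' `a = mu / lambda` in `[0, 1)`. At `a = 0` it reproduces [pb_loglik()]
#' exactly.
#'
#' @inheritParams pb_loglik
#' @param r Net diversification rate, > 0.
#' @param a Extinction fraction `mu / lambda`, in `[0, 1)`.
#' @export
bd_loglik <- function(bt, r, a) {
  bt <- as_branching_times(bt)
  if (r <= 0) abort("`r` must be > 0")
  if (a < 0 || a >= 1) abort("`a` must lie in [0, 1)")
  n <- length(bt) + 1L
  rt <- r * bt
  # log(e^{rt} - a) computed as rt + log1p(-a e^{-rt}) for stability
  (n - 2) * log(r) + n * log1p(-a) + r * sum(bt[-1]) -
    2 * sum(rt + log1p(-a * exp(-rt)))
}

#' Diversity-dependent likelihoods
#'
#' Per-lineage speciation declines with the standing lineage count `k`:
#' linearly, `lambda_k = lambda0 (1 - k / K)` (DDL, with ceiling `K`), or as
#' a power law, `lambda_k = lambda0 k^-x` (DDX). The shared constant makes
#' `ddx_loglik(bt, l, x = 0)` and the `K -> Inf` limit of `ddl_loglik()`
#' identical to `pb_loglik(bt, l)`.
#'
#' @inheritParams pb_loglik
#' @param lambda0 Baseline speciation rate, > 0.
#' @param K Linear-model ceiling (species); every `lambda_k`, `k = 2..N`,
#'   must stay positive.
#' @param x Exponential-model exponent (any real).
#' @export
ddl_loglik <- function(bt, lambda0, K) {
  dd_loglik(bt, lambda0, rate_fun = function(k) lambda0 * (1 - k / K))
}

#' @rdname ddl_loglik
#' @export
ddx_loglik <- function(bt, lambda0, x) {
  dd_loglik(bt, lambda0, rate_fun = function(k) lambda0 * k^(-x))
}

dd_loglik <- function(bt, lambda0, rate_fun) {
  bt <- as_branching_times(bt)
  if (lambda0 <= 0) abort("`lambda0` must be > 0")
  n <- length(bt) + 1L
  k <- 2:n
  lam <- rate_fun(k)
  if (any(lam <= 0)) abort("per-lineage rate must stay positive over k = 2..N")
  tau <- bt_durations(bt)
  sum(log(lam[-length(lam)])) - sum(k * lam * tau)
}

#' Multi-rate Yule likelihood
#'
#' Piecewise pure-birth likelihood with `length(rates)` regimes separated by
#' `shift_ages` (descending, strictly inside `(0, crown age)`). Events and
#' lineage-time accrue with the rate in force at their age; an event lying
#' exactly on a shift belongs to the older regime.
#'
#' @inheritParams pb_loglik
#' @param rates Per-regime speciation rates, oldest first, each >= 0
#'   (a zero rate is the boundary fit of an event-free regime).
#' @param shift_ages Ages of the rate shifts (Myr), descending.
#' @export
yule_multirate_loglik <- function(bt, rates, shift_ages) {
  bt <- as_branching_times(bt)
  if (length(rates) != length(shift_ages) + 1L) {
    abort("need one more rate than shift ages")
  }
  if (length(shift_ages) && any(diff(shift_ages) >= 0)) {
    abort("shift ages must be strictly decreasing")
  }
  if (length(shift_ages) && (max(shift_ages) >= bt[1] || min(shift_ages) <= 0)) {
    abort("shift ages must lie strictly inside (0, crown age)")
  }
  if (any(rates < 0)) abort("rates must be >= 0")
  stats <- regime_stats(bt, shift_ages)
  ll <- 0
  for (j in seq_along(rates)) {
    if (stats$events[j] > 0) {
      if (rates[j] <= 0) return(-Inf)
      ll <- ll + stats$events[j] * log(rates[j])
    }
    ll <- ll - rates[j] * stats$exposure[j]
  }
  ll
}

# events (t_3..t_N) and lineage-time per age regime delimited by shift ages;
# regime boundaries are [s_j, s_{j-1}) with the event at the boundary going
# to the older regime
regime_stats <- function(bt, shift_ages) {
  n <- length(bt) + 1L
  bounds <- c(Inf, shift_ages, -Inf)
  events <- integer(length(shift_ages) + 1L)
  expo <- numeric(length(shift_ages) + 1L)
  ev <- bt[-1]
  starts <- bt                 # interval with k lineages: [ends_k, starts_k]
  ends <- c(bt[-1], 0)
  k <- 2:n
  for (j in seq_along(events)) {
    hi <- bounds[j]; lo <- bounds[j + 1L]
    events[j] <- sum(ev >= lo & ev < hi)
    expo[j] <- sum(k * pmax(0, pmin(starts, hi) - pmax(ends, lo)))
  }
  list(events = events, exposure = expo)
}

# ---- per-model ML fits -----------------------------------------------------
# Internal fits return plain lists (assembled into one tibble at the end);
# objectives work from precomputed sufficient statistics for speed.

fit_pb <- function(bt) {
  m <- pb_mle(bt)
  div_fit_row("PB", r1 = m$lambda, loglik = m$loglik, df = 1L)
}

fit_bd <- function(bt) {
  n <- length(bt) + 1L
  s3 <- sum(bt[-1])
  lam0 <- pb_mle(bt)$lambda
  obj <- function(p) {
    r <- exp(p[1]); a <- p[2]
    rt <- r * bt
    -((n - 2) * p[1] + n * log1p(-a) + r * s3 - 2 * sum(rt + log1p(-a * exp(-rt))))
  }
  starts <- list(c(log(lam0), 0), c(log(lam0), 0.3), c(log(lam0), 0.7),
                 c(log(lam0 / 2), 0.5), c(log(lam0 * 2), 0.2))
  best <- optimize_multistart(obj, starts,
                              lower = c(log(1e-8), 0), upper = c(log(1e3), 1 - 1e-9))
  div_fit_row("BD", r1 = exp(best$par[1]), a = best$par[2],
              loglik = -best$objective, df = 2L, converged = best$converged)
}

fit_ddx <- function(bt) {
  n <- length(bt) + 1L
  k <- 2:n
  lk <- log(k)
  ktau <- k * bt_durations(bt)
  lam0 <- pb_mle(bt)$lambda
  obj <- function(p) {
    lam <- exp(p[1] - p[2] * lk)                  # lambda0 * k^-x
    -(sum(p[1] - p[2] * lk[-length(lk)]) - sum(ktau * lam))
  }
  starts <- list(c(log(lam0), 0), c(log(lam0), 0.5), c(log(lam0), -0.5),
                 c(log(lam0 * 3), 1), c(log(lam0 / 3), -1))
  best <- optimize_multistart(obj, starts,
                              lower = c(log(1e-8), -10), upper = c(log(1e3), 10))
  div_fit_row("DDX", r1 = exp(best$par[1]), x = best$par[2],
              loglik = -best$objective, df = 2L, converged = best$converged)
}

fit_ddl <- function(bt) {
  n <- length(bt) + 1L
  k <- 2:n
  ktau <- k * bt_durations(bt)
  lam0 <- pb_mle(bt)$lambda
  # K parameterised as N + exp(theta) so every lambda_k stays positive
  obj <- function(p) {
    K <- n + exp(p[2])
    lam <- exp(p[1]) * (1 - k / K)
    -(sum(log(lam[-length(lam)])) - sum(ktau * lam))
  }
  starts <- list(c(log(lam0), log(n)), c(log(lam0), log(0.2 * n)),
                 c(log(lam0), log(10 * n)), c(log(2 * lam0), log(0.05 * n)),
                 c(log(lam0), log(1e6)))
  best <- optimize_multistart(obj, starts,
                              lower = c(log(1e-8), log(1e-6)), upper = c(log(1e3), log(1e9)))
  div_fit_row("DDL", r1 = exp(best$par[1]), k = n + exp(best$par[2]),
              loglik = -best$objective, df = 2L, converged = best$converged)
}

# multi-rate Yule: the likelihood is piecewise-constant in the shifts
# between events, so shifts are searched over the observed branching times
# and the per-regime rate MLEs are closed-form (events / exposure); the
# whole search is vectorised with the cumulative event count and
# lineage-time "above age s" evaluated at every candidate
fit_yule_multirate <- function(bt, n_rates) {
  n <- length(bt) + 1L
  cand <- sort(unique(bt[-1]), decreasing = TRUE)   # interior candidates
  cand <- cand[cand < bt[1] & cand > 0]
  if (!length(cand)) return(NULL)
  ev <- bt[-1]
  starts <- bt; ends <- c(bt[-1], 0); k <- 2:n
  n_above <- vapply(cand, function(s) sum(ev >= s), numeric(1))
  # lineage-time above age s: sum_k k * max(0, starts_k - max(ends_k, s))
  nk <- length(k); nc <- length(cand)
  lo <- pmax(matrix(ends, nk, nc), matrix(cand, nk, nc, byrow = TRUE))
  contrib <- matrix(starts, nk, nc) - lo
  contrib[contrib < 0] <- 0
  A <- colSums(k * contrib)
  G <- bt_exposure(bt)
  xlogy <- function(m, g) ifelse(m > 0, m * log(m / g), 0)
  if (n_rates == 2L) {
    ll <- xlogy(n_above, A) + xlogy((n - 2) - n_above, G - A) - (n - 2)
    i <- which.max(ll)
    n1 <- n_above[i]; n2 <- (n - 2) - n1
    div_fit_row("Y2R", r1 = n1 / A[i], r2 = if (G - A[i] > 0) n2 / (G - A[i]) else 0,
                st1 = cand[i], loglik = ll[i], df = 3L)
  } else {
    if (length(cand) < 2) return(NULL)
    m <- length(cand)
    # pair (i, j), i < j in descending candidates, so s1 = cand[i] > s2 = cand[j]
    n1 <- outer(n_above, rep(1, m)); n12 <- outer(rep(1, m), n_above)
    G1 <- outer(A, rep(1, m)); G12 <- outer(rep(1, m), A)
    ll <- xlogy(n1, G1) + xlogy(n12 - n1, G12 - G1) +
      xlogy((n - 2) - n12, G - G12) - (n - 2)
    ll[!upper.tri(ll)] <- -Inf
    idx <- arrayInd(which.max(ll), dim(ll))
    i <- idx[1]; j <- idx[2]
    e1 <- n_above[i]; e2 <- n_above[j] - n_above[i]; e3 <- (n - 2) - n_above[j]
    g1 <- A[i]; g2 <- A[j] - A[i]; g3 <- G - A[j]
    rate <- function(e, g) if (g > 0) e / g else 0
    div_fit_row("Y3R", r1 = rate(e1, g1), r2 = rate(e2, g2), r3 = rate(e3, g3),
                st1 = cand[i], st2 = cand[j],
                loglik = max(ll), df = 5L)
  }
}

div_fit_row <- function(model, r1 = NA, r2 = NA, r3 = NA, st1 = NA, st2 = NA,
                        a = NA, x = NA, k = NA, loglik, df, converged = TRUE) {
  list(
    model = model, r1 = as.numeric(r1), r2 = as.numeric(r2), r3 = as.numeric(r3),
    st1 = as.numeric(st1), st2 = as.numeric(st2), a = as.numeric(a),
    x = as.numeric(x), k = as.numeric(k), loglik = loglik, df = as.integer(df),
    aic = 2 * df - 2 * loglik, converged = converged
  )
}

optimize_multistart <- function(obj, starts, lower, upper, tol = 1e-8) {
  safe <- function(p) {
    v <- tryCatch(obj(p), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      nlminb(s, safe, lower = lower, upper = upper,
             control = list(rel.tol = tol, abs.tol = 0)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      best$converged <- fit$convergence == 0
    }
  }
  if (is.null(best)) abort("diversification optimizer failed from every start")
  best
}

#' Fit the six-model diversification suite
#'
#' Maximum-likelihood fits of the two rate-constant models (PB, BD) and four
#' rate-variable models (DDX, DDL, two- and three-rate Yule) on one set of
#' branching times, with shared likelihood constant so the AIC column is
#' comparable across models. Deterministic given the input (fixed start
#' grid, exhaustive shift search).
#'
#' @inheritParams pb_loglik
#' @return A tibble of class `div_fits`, one row per model, with columns
#'   `model`, `r1`, `r2`, `r3`, `st1`, `st2`, `a`, `x`, `k`, `loglik`, `df`,
#'   `aic`, `delta_aic` (AIC minus the best AIC) and `converged`.
#' @examples
#' fit_diversification(sim_yule(n = 20, lambda = 0.5, seed = 1))
#' @export
fit_diversification <- function(bt) {
  rows <- div_fit_rows(bt)
  out <- tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  })))
  out$delta_aic <- out$aic - min(out$aic)
  class(out) <- c("div_fits", class(out))
  out
}

div_fit_rows <- function(bt) {
  bt <- as_branching_times(bt)
  if (length(bt) + 1L < 4L) abort("need at least 4 tips")
  rows <- list(fit_pb(bt), fit_bd(bt), fit_ddx(bt), fit_ddl(bt),
               fit_yule_multirate(bt, 2L), fit_yule_multirate(bt, 3L))
  rows[!vapply(rows, is.null, logical(1))]
}

# fast path for the simulated null: only the six AICs, no table assembly
div_aics <- function(bt) {
  rows <- div_fit_rows(bt)
  setNames(vapply(rows, `[[`, numeric(1), "aic"),
           vapply(rows, `[[`, character(1), "model"))
}

daicrc_statistic_aics <- function(aics) {
  rc <- aics[names(aics) %in% c("PB", "BD")]
  min(rc) - min(aics[setdiff(names(aics), c("PB", "BD"))])
}

#' @export
glance.div_fits <- function(x, ...) {
  best <- x$model[which.min(x$aic)]
  tibble::tibble(
    best_model = best,
    daic_rc = daicrc_statistic(x),
    n_models = nrow(x),
    all_converged = all(x$converged)
  )
}

# AIC(best rate-constant) - AIC(best rate-variable)
daicrc_statistic <- function(fits) {
  rc <- fits$aic[fits$model %in% c("PB", "BD")]
  rv <- fits$aic[!(fits$model %in% c("PB", "BD"))]
  min(rc) - min(rv)
}

#' Simulation-based test of rate-constancy (delta-AIC_RC)
#'
#' Compares the AIC of the best rate-constant model with that of the best
#' rate-variable model; the observed statistic is referred to a null
#' distribution obtained by simulating pure-birth trees of the same size at
#' the pure-birth MLE rate and refitting all six models on each.
#'
#' @inheritParams pb_loglik
#' @param reps Number of null simulations (study scale: 1000).
#' @param seed Integer seed for the null simulations.
#' @return List of class `daicrc` with `statistic` (observed delta-AIC_RC),
#'   `null` (numeric vector, length `reps`), `p_value`
#'   (`Pr(null >= observed)`), `lambda_null` and `fits` (the observed
#'   six-model table).
#' @export
daicrc_test <- function(bt, reps = 1000, seed = NULL) {
  bt <- as_branching_times(bt)
  if (reps < 1) abort("`reps` must be >= 1")
  fits <- fit_diversification(bt)
  obs <- daicrc_statistic(fits)
  n <- length(bt) + 1L
  lam <- pb_mle(bt)$lambda
  null <- with_seed(seed, vapply(seq_len(reps), function(i) {
    daicrc_statistic_aics(div_aics(yule_branching_times_sim(n, lam)))
  }, numeric(1)))
  out <- list(statistic = obs, null = null, p_value = mean(null >= obs),
              lambda_null = lam, reps = reps, fits = fits)
  class(out) <- "daicrc"
  out
}

#' @export
print.daicrc <- function(x, ...) {
  cat(sprintf(
    "delta-AIC_RC test: statistic = %.3f, p = %.4g (null reps = %d, lambda = %.3g)\n",
    x$statistic, x$p_value, x$reps, x$lambda_null
  ))
  invisible(x)
}

#' @export
tidy.daicrc <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 reps = x$reps, lambda_null = x$lambda_null)
}

#' @export
autoplot.daicrc <- function(object, ...) {
  df <- tibble::tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick") +
    ggplot2::labs(x = "null delta-AIC_RC", y = "count") +
    ggplot2::theme_minimal()
}
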