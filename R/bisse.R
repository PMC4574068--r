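# Binary State Speciation and Extinction (BiSSE): likelihood by adaptive
# ODE integration (compiled core), the thirteen-model constraint suite
# fitted by ML across a tree sample, AIC/LRT comparison, credible-interval
# summaries, and likelihood-based marginal ancestral states.

bisse_par_names <- c("lambdaO", "lambdaS", "muO", "muS", "qOS", "qSO")

bisse_tip_d <- function(phy, tips, sampling_f) {
  states <- resolve_tip_states(phy, tips)
  ntip <- ape::Ntip(phy)
  d <- matrix(0, ntip, 2)
  d[, 1] <- ifelse(is.na(states) | states == 0L, sampling_f[1], 0)
  d[, 2] <- ifelse(is.na(states) | states == 1L, sampling_f[2], 0)
  d
}

#' BiSSE log-likelihood
#'
#' Joint likelihood of a dated tree and binary tip states under the binary
#' state speciation and extinction model, computed by integrating the
#' coupled extinction/data ODEs along every branch (adaptive Runge-Kutta,
#' compiled) and combining daughters at nodes. State 0 is "O"
#' (outcrossing/ancestral), state 1 is "S" (selfing/derived).
#'
#' @param phy A dated `phylo`.
#' @param tips Tip states (tibble `species`/`state` or named vector;
#'   `NA` = missing, contributing both states).
#' @param pars Named vector `lambdaO`, `lambdaS`, `muO`, `muS`, `qOS`,
#'   `qSO` (all >= 0, /Myr).
#' @param root `"observed"` (weights proportional to the root D values,
#'   default), `"flat"`, or `"given"` with `root_p`.
#' @param root_p Numeric root-state weights when `root = "given"`.
#' @param condition_surv Condition the likelihood on survival of the two
#'   crown lineages (divide by `sum_i w_i lambda_i (1 - E_i)^2`). Default
#'   `TRUE`.
#' @param sampling_f Per-state sampling fractions (default complete
#'   sampling, `c(1, 1)`).
#' @param rtol,atol ODE integration tolerances. The absolute tolerance
#'   default is effectively zero: with per-branch renormalisation the
#'   integration is controlled in relative terms, which keeps likelihoods
#'   accurate even where a branch's data likelihood decays by hundreds of
#'   orders of magnitude (high transition-rate regions of the parameter
#'   space would otherwise surface spurious likelihood modes at the
#'   absolute-error floor).
#' @return Scalar log-likelihood.
#' @examples
#' phy <- parse_newick("(A:1,B:1);")
#' tips <- tibble::tibble(species = c("A", "B"), state = c(0L, 0L))
#' pars <- c(lambdaO = 0.5, lambdaS = 0.5, muO = 0, muS = 0, qOS = 0, qSO = 0)
#' bisse_loglik(phy, tips, pars, condition_surv = FALSE)  # log(0.5) - 1
#' @export
bisse_loglik <- function(phy, tips, pars, root = c("observed", "flat", "given"),
                         root_p = c(0.5, 0.5), condition_surv = TRUE,
                         sampling_f = c(1, 1), rtol = 1e-8, atol = 1e-200) {
  root <- match.arg(root)
  validate_tree(phy)
  pars <- validate_bisse_pars(pars)
  tip_d <- bisse_tip_d(phy, tips, sampling_f)
  po <- ape::reorder.phylo(phy, "postorder")
  bisse_loglik_cpp(po$edge, po$edge.length, ape::Ntip(phy), tip_d,
                   unname(pars), sampling_f,
                   match(root, c("observed", "flat", "given")) - 1L,
                   root_p / sum(root_p), condition_surv, rtol, atol)
}

# ---- constraints -----------------------------------------------------------

#' BiSSE model constraints
#'
#' A constraint is a set of equality ties between the six rates plus a set
#' of rates fixed to zero. Free-parameter count = 6 - #ties - #zeros (zeros
#' applied to untied parameters). `bisse_model_set()` returns the thirteen
#' canonical models: the full model, three equality ties, six single
#' zero-fixes and three multi-zero "dead end" models.
#'
#' @param ties List of character pairs to tie, e.g.
#'   `list(c("lambdaO", "lambdaS"))`.
#' @param zeros Character vector of parameters fixed at zero.
#' @param name Optional model label.
#' @return A `bisse_constraint` (list with `ties`, `zeros`, `df`, `name`).
#' @export
bisse_constraint <- function(ties = list(), zeros = character(), name = NULL) {
  for (tie in ties) {
    if (!all(tie %in% bisse_par_names)) abort("unknown parameter in tie")
  }
  if (!all(zeros %in% bisse_par_names)) abort("unknown parameter in zeros")
  tied_members <- unlist(ties)
  df <- 6L - length(ties) - length(setdiff(zeros, tied_members))
  if (is.null(name)) {
    bits <- c(
      vapply(ties, function(tie) paste(tie, collapse = "="), character(1)),
      if (length(zeros)) paste0(zeros, "=0")
    )
    name <- if (length(bits)) paste(bits, collapse = ",") else "full"
  }
  structure(list(ties = ties, zeros = zeros, df = df, name = name),
            class = "bisse_constraint")
}

#' @rdname bisse_constraint
#' @export
bisse_model_set <- function() {
  short <- function(...) bisse_constraint(...)
  list(
    full = short(),
    short(ties = list(c("lambdaO", "lambdaS")), name = "lambdaO=lambdaS"),
    short(ties = list(c("muO", "muS")), name = "muO=muS"),
    short(ties = list(c("qOS", "qSO")), name = "qOS=qSO"),
    short(zeros = "lambdaO", name = "lambdaO=0"),
    short(zeros = "lambdaS", name = "lambdaS=0"),
    short(zeros = "muO", name = "muO=0"),
    short(zeros = "muS", name = "muS=0"),
    short(zeros = "qOS", name = "qOS=0"),
    short(zeros = "qSO", name = "qSO=0"),
    short(zeros = c("lambdaS", "muO"), name = "lambdaS=0,muO=0"),
    short(zeros = c("lambdaS", "muO", "qSO"), name = "lambdaS=0,muO=0,qSO=0"),
    short(zeros = c("lambdaS", "muO", "muS", "qSO"),
          name = "lambdaS=0,muO=0,muS=0,qSO=0")
  )
}

# map free parameters (log scale) to the full six-vector under a constraint
constraint_expand <- function(constraint) {
  groups <- as.list(bisse_par_names)
  names(groups) <- bisse_par_names
  for (tie in constraint$ties) {
    lead <- tie[1]
    groups[[lead]] <- unique(c(groups[[lead]], tie[-1]))
    for (other in tie[-1]) groups[[other]] <- NULL
  }
  zero_set <- constraint$zeros
  free_leads <- names(groups)[!vapply(names(groups), function(g) {
    all(groups[[g]] %in% zero_set) || g %in% zero_set
  }, logical(1))]
  list(groups = groups, free = free_leads, zeros = zero_set)
}

constraint_pars <- function(map, theta) {
  pars <- setNames(numeric(6), bisse_par_names)
  for (i in seq_along(map$free)) {
    lead <- map$free[i]
    pars[map$groups[[lead]]] <- exp(theta[i])
  }
  pars[map$zeros] <- 0
  pars
}

# ---- single-tree ML fit ----------------------------------------------------

# heuristic starting point: state-independent BD fit replicated to both
# states, transitions started at a tenth of the speciation rate
bisse_start_pars <- function(phy) {
  bt <- branching_times(phy)
  bd <- fit_bd(bt)
  r <- max(bd$r1, 1e-3); a <- ifelse(is.na(bd$a), 0, min(bd$a, 0.95))
  lam <- r / (1 - a); mu <- max(lam * a, 1e-4)
  c(lambdaO = lam, lambdaS = lam, muO = mu, muS = mu,
    qOS = 0.1 * lam, qSO = 0.1 * lam)
}

bisse_fit_tree <- function(phy, tips, constraint, start_pars = NULL,
                           extra_starts = list(),
                           root = "observed", condition_surv = TRUE,
                           sampling_f = c(1, 1), rtol = 1e-8, atol = 1e-200) {
  map <- constraint_expand(constraint)
  if (is.null(start_pars)) start_pars <- bisse_start_pars(phy)
  tip_d <- bisse_tip_d(phy, tips, sampling_f)
  po <- ape::reorder.phylo(phy, "postorder")
  ntip <- ape::Ntip(phy)
  rmode <- match(root, c("observed", "flat", "given")) - 1L
  obj <- function(theta) {
    pars <- constraint_pars(map, theta)
    -bisse_loglik_cpp(po$edge, po$edge.length, ntip, tip_d, unname(pars),
                      sampling_f, rmode, c(0.5, 0.5), condition_surv,
                      rtol, atol)
  }
  to_theta <- function(p) unname(log(pmax(p[map$free], 1e-6)))
  theta0 <- to_theta(start_pars)
  jitters <- list(rep(0, length(theta0)), rep(log(3), length(theta0)),
                  rep(-log(3), length(theta0)))
  starts <- c(lapply(jitters, function(j) theta0 + j),
              lapply(extra_starts, to_theta))
  best <- optimize_multistart(obj, starts,
                              lower = rep(-20, length(theta0)),
                              upper = rep(5, length(theta0)))
  pars <- constraint_pars(map, best$par)
  list(pars = pars, loglik = -best$objective, df = constraint$df,
       aic = 2 * constraint$df + 2 * best$objective,
       converged = best$converged)
}

# fit a set of models to one tree with start chaining: every constrained
# model also starts from the full-model optimum projected onto its
# constraint, and the full model is refit from any constrained optimum
# that beats it (the surfaces are multimodal; chaining keeps the fitted
# suite consistent with the nesting inequalities)
bisse_suite_tree <- function(phy, tips, models, root = "observed",
                             condition_surv = TRUE, sampling_f = c(1, 1),
                             rtol = 1e-8, atol = 1e-200) {
  start0 <- bisse_start_pars(phy)
  fit_args <- list(phy = phy, tips = tips, start_pars = start0, root = root,
                   condition_surv = condition_surv, sampling_f = sampling_f,
                   rtol = rtol, atol = atol)
  full_i <- which(vapply(models, function(m) m$name == "full", logical(1)))
  fits <- vector("list", length(models))
  full_fit <- NULL
  if (length(full_i)) {
    full_fit <- do.call(bisse_fit_tree, c(fit_args, list(constraint = models[[full_i]])))
    fits[[full_i]] <- full_fit
  }
  for (i in seq_along(models)) {
    if (length(full_i) && i == full_i) next
    extra <- if (!is.null(full_fit)) list(pmax(full_fit$pars, 1e-6)) else list()
    fits[[i]] <- do.call(bisse_fit_tree,
                         c(fit_args, list(constraint = models[[i]],
                                          extra_starts = extra)))
  }
  if (!is.null(full_fit)) {
    best_con <- which.max(vapply(seq_along(fits), function(i) {
      if (i == full_i) -Inf else fits[[i]]$loglik
    }, numeric(1)))
    if (fits[[best_con]]$loglik > full_fit$loglik + 1e-6) {
      refit <- do.call(bisse_fit_tree, c(fit_args, list(
        constraint = models[[full_i]],
        extra_starts = list(pmax(fits[[best_con]]$pars, 1e-6))
      )))
      if (refit$loglik > full_fit$loglik) fits[[full_i]] <- refit
    }
  }
  fits
}

#' Fit a BiSSE model by ML across a tree sample
#'
#' Fits one (possibly constrained) BiSSE model to each tree of a sample by
#' bounded quasi-Newton optimization on log rates, starting from a
#' state-independent birth-death heuristic (with deterministic jittered
#' restarts), then summarises parameters, log-likelihoods and AIC as
#' medians and 95% ranges across trees. AIC is computed per tree and then
#' summarised, so the median AIC column is the median of per-tree AICs.
#'
#' @param trees A dated `phylo` or list of them.
#' @param tips Tip states shared by all trees.
#' @param constraint A [bisse_constraint()]; default the full model.
#' @inheritParams bisse_loglik
#' @return Object of class `bisse_fit`: list with `per_tree` (tibble of
#'   per-tree estimates), `summary` (tibble of medians and 2.5/97.5%
#'   quantiles per parameter), `constraint`, `n_failed`.
#' @export
bisse_fit <- function(trees, tips, constraint = bisse_constraint(),
                      root = c("observed", "flat", "given"),
                      condition_surv = TRUE, sampling_f = c(1, 1),
                      rtol = 1e-8, atol = 1e-200) {
  root <- match.arg(root)
  if (inherits(trees, "phylo")) trees <- list(trees)
  rows <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    fit <- tryCatch(
      bisse_fit_tree(trees[[i]], tips, constraint, root = root,
                     condition_surv = condition_surv,
                     sampling_f = sampling_f, rtol = rtol, atol = atol),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rows[[i]] <- c(tree = i, fit$pars, loglik = fit$loglik,
                   aic = fit$aic, converged = as.numeric(fit$converged))
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) abort("BiSSE optimization failed on every tree")
  per_tree <- tibble::as_tibble(do.call(rbind, rows[ok]))
  qs <- function(v) quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
  cols <- c(bisse_par_names, "loglik", "aic")
  summ <- purrr::map_dfr(cols, function(cn) {
    q <- qs(per_tree[[cn]])
    tibble::tibble(term = cn, q2.5 = q[1], median = q[2], q97.5 = q[3])
  })
  out <- list(per_tree = per_tree, summary = summ, constraint = constraint,
              df = constraint$df, n_failed = sum(!ok))
  class(out) <- "bisse_fit"
  out
}

#' @export
print.bisse_fit <- function(x, ...) {
  med <- setNames(x$summary$median, x$summary$term)
  cat(sprintf("BiSSE model '%s' (df = %d) over %d trees (%d failed)\n",
              x$constraint$name, x$df, nrow(x$per_tree), x$n_failed))
  cat(sprintf("  median lnL = %.3f, median AIC = %.3f\n",
              med[["loglik"]], med[["aic"]]))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.bisse_fit <- function(x, ...) {
  dplyr::filter(x$summary, .data$term %in% bisse_par_names) |>
    dplyr::transmute(term = .data$term, estimate = .data$median,
                     conf.low = .data$q2.5, conf.high = .data$q97.5)
}

#' @export
glance.bisse_fit <- function(x, ...) {
  med <- setNames(x$summary$median, x$summary$term)
  tibble::tibble(model = x$constraint$name, df = x$df,
                 loglik = med[["loglik"]], aic = med[["aic"]],
                 n_trees = nrow(x$per_tree), n_failed = x$n_failed)
}

#' Likelihood-ratio test of nested BiSSE models
#'
#' `statistic = 2 (lnL_full - lnL_constrained)`, referred to the upper tail
#' of a chi-squared distribution with `df` equal to the difference in free
#' parameters.
#'
#' @param loglik_full,loglik_constrained Log-likelihoods of the nesting and
#'   nested model (the former must not be smaller beyond `tol`).
#' @param df_diff Difference in free parameters, >= 1.
#' @param tol Numerical slack on the nesting inequality.
#' @return Tibble with `statistic`, `df` and `p_value`.
#' @export
lrt <- function(loglik_full, loglik_constrained, df_diff, tol = 1e-6) {
  if (df_diff < 1) abort("`df_diff` must be >= 1")
  stat <- 2 * (loglik_full - loglik_constrained)
  if (stat < -tol) {
    abort("constrained log-likelihood exceeds the full model's: optimization failure")
  }
  stat <- max(stat, 0)
  tibble::tibble(statistic = stat, df = as.integer(df_diff),
                 p_value = pchisq(stat, df_diff, lower.tail = FALSE))
}

#' Fit the thirteen-model BiSSE suite
#'
#' Fits the full model, the three equality-tie models, the six single
#' zero-fix models and the three multi-zero "dead end" models to every tree
#' of the sample, ranks them by median AIC, and reports for each
#' constrained model the percentage of trees on which the likelihood-ratio
#' test against the (per-tree) full model rejects at `P < 0.05`.
#'
#' @inheritParams bisse_fit
#' @return Object of class `bisse_suite`: list with `table` (ranked tibble:
#'   `model`, `df`, median rates, `loglik`, `aic`, `delta_aic`,
#'   `pct_reject`) and `fits` (named list of `bisse_fit`).
#' @export
bisse_model_suite <- function(trees, tips, root = c("observed", "flat", "given"),
                              condition_surv = TRUE, sampling_f = c(1, 1),
                              rtol = 1e-8, atol = 1e-200) {
  root <- match.arg(root)
  if (inherits(trees, "phylo")) trees <- list(trees)
  models <- bisse_model_set()
  names(models) <- vapply(models, `[[`, character(1), "name")
  per_tree_fits <- lapply(seq_along(trees), function(i) {
    tryCatch(
      bisse_suite_tree(trees[[i]], tips, models, root = root,
                       condition_surv = condition_surv,
                       sampling_f = sampling_f, rtol = rtol, atol = atol),
      error = function(e) NULL
    )
  })
  ok_trees <- which(!vapply(per_tree_fits, is.null, logical(1)))
  if (!length(ok_trees)) abort("BiSSE optimization failed on every tree")
  fits <- lapply(seq_along(models), function(mi) {
    rows <- lapply(ok_trees, function(ti) {
      f <- per_tree_fits[[ti]][[mi]]
      c(tree = ti, f$pars, loglik = f$loglik, aic = f$aic,
        converged = as.numeric(f$converged))
    })
    per_tree <- tibble::as_tibble(do.call(rbind, rows))
    qs <- function(v) quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    summ <- purrr::map_dfr(c(bisse_par_names, "loglik", "aic"), function(cn) {
      q <- qs(per_tree[[cn]])
      tibble::tibble(term = cn, q2.5 = q[1], median = q[2], q97.5 = q[3])
    })
    structure(list(per_tree = per_tree, summary = summ,
                   constraint = models[[mi]], df = models[[mi]]$df,
                   n_failed = length(trees) - length(ok_trees)),
              class = "bisse_fit")
  })
  names(fits) <- names(models)
  full <- fits[["full"]]
  rows <- purrr::map_dfr(fits, function(f) {
    med <- setNames(f$summary$median, f$summary$term)
    pct <- NA_real_
    if (f$constraint$name != "full") {
      # per-tree pairing of full and constrained lnL
      joined <- dplyr::inner_join(
        full$per_tree[, c("tree", "loglik")],
        f$per_tree[, c("tree", "loglik")],
        by = "tree", suffix = c("_full", "_con")
      )
      dd <- 6L - f$df
      stat <- pmax(2 * (joined$loglik_full - joined$loglik_con), 0)
      pct <- 100 * mean(pchisq(stat, dd, lower.tail = FALSE) < 0.05)
    }
    tibble::tibble(
      model = f$constraint$name, df = f$df,
      lambdaO = med[["lambdaO"]], lambdaS = med[["lambdaS"]],
      muO = med[["muO"]], muS = med[["muS"]],
      qOS = med[["qOS"]], qSO = med[["qSO"]],
      loglik = med[["loglik"]], aic = med[["aic"]], pct_reject = pct
    )
  })
  rows <- dplyr::arrange(rows, .data$aic)
  rows$delta_aic <- rows$aic - rows$aic[1]
  out <- list(table = rows, fits = fits)
  class(out) <- "bisse_suite"
  out
}

#' @export
print.bisse_suite <- function(x, ...) {
  cat("BiSSE model suite (ranked by median AIC):\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.bisse_suite <- function(x, ...) x$table

#' @export
autoplot.bisse_suite <- function(object, ...) {
  df <- object$table
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_aic, y = .data$model)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "delta AIC (median, vs best)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Marginal ancestral states under BiSSE
#'
#' For every internal node (and, for imputation, every missing tip) the
#' node is constrained to each state in turn, the likelihood recomputed,
#' and the two constrained likelihoods normalised.
#'
#' @inheritParams bisse_loglik
#' @return Tibble of class `asr_states` with `node`, `bipartition`, `p0`,
#'   `p1` (missing tips keyed by their tip label).
#' @export
bisse_asr_marginal <- function(phy, tips, pars,
                               root = c("observed", "flat", "given"),
                               root_p = c(0.5, 0.5), condition_surv = TRUE,
                               sampling_f = c(1, 1), rtol = 1e-8, atol = 1e-200) {
  root <- match.arg(root)
  validate_tree(phy)
  pars <- validate_bisse_pars(pars)
  states <- resolve_tip_states(phy, tips)
  tip_d <- bisse_tip_d(phy, tips, sampling_f)
  po <- ape::reorder.phylo(phy, "postorder")
  ntip <- ape::Ntip(phy)
  rmode <- match(root, c("observed", "flat", "given")) - 1L
  ll_forced <- function(node, state) {
    bisse_loglik_cpp(po$edge, po$edge.length, ntip, tip_d, unname(pars),
                     sampling_f, rmode, root_p / sum(root_p), condition_surv,
                     rtol, atol, node, state)
  }
  marg <- function(node) {
    l0 <- ll_forced(node, 0L); l1 <- ll_forced(node, 1L)
    m <- max(l0, l1)
    w <- exp(c(l0, l1) - m)
    w / sum(w)
  }
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  bi <- bipartition_index(phy)
  pm <- t(vapply(nodes, marg, numeric(2)))
  res <- tibble::tibble(
    node = nodes, bipartition = bi$bipartition[match(nodes, bi$node)],
    p0 = pm[, 1], p1 = pm[, 2]
  )
  miss <- which(is.na(states))
  if (length(miss)) {
    mm <- t(vapply(miss, marg, numeric(2)))
    res <- dplyr::bind_rows(res, tibble::tibble(
      node = miss, bipartition = phy$tip.label[miss],
      p0 = mm[, 1], p1 = mm[, 2]
    ))
  }
  class(res) <- c("asr_states", class(res))
  res
}

#' Per-parameter distributions across per-tree fits
#'
#' Frequency summaries (2.5/50/97.5 percentiles) of each full-model
#' parameter across the per-tree ML estimates, plus an overlap indicator
#' between the outcrossing and selfing distribution of each rate class
#' (speciation, extinction, transition, net diversification).
#'
#' @param fit A `bisse_fit` with at least `min_fits` per-tree rows.
#' @param min_fits Minimum number of per-tree fits required.
#' @return List of class `bisse_param_dist`: `percentiles` (tibble) and
#'   `overlap` (tibble: `rate_class`, `overlap` logical).
#' @export
bisse_param_distributions <- function(fit, min_fits = 20) {
  pt <- fit$per_tree
  if (nrow(pt) < min_fits) {
    abort(sprintf("need at least %d per-tree fits (have %d)", min_fits, nrow(pt)))
  }
  pt$rO <- pt$lambdaO - pt$muO
  pt$rS <- pt$lambdaS - pt$muS
  terms <- c(bisse_par_names, "rO", "rS")
  perc <- purrr::map_dfr(terms, function(cn) {
    q <- quantile(pt[[cn]], c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(term = cn, q2.5 = q[1], median = q[2], q97.5 = q[3])
  })
  ov <- function(a, b) {
    qa <- quantile(pt[[a]], c(0.025, 0.975), names = FALSE)
    qb <- quantile(pt[[b]], c(0.025, 0.975), names = FALSE)
    qa[1] <= qb[2] && qb[1] <= qa[2]
  }
  overlap <- tibble::tibble(
    rate_class = c("speciation", "extinction", "transition", "net_diversification"),
    overlap = c(ov("lambdaO", "lambdaS"), ov("muO", "muS"),
                ov("qOS", "qSO"), ov("rO", "rS"))
  )
  structure(list(percentiles = perc, overlap = overlap),
            class = "bisse_param_dist")
}

#' @export
print.bisse_param_dist <- function(x, ...) {
  print(x$percentiles); print(x$overlap)
  invisible(x)
}

#' @export
autoplot.bisse_param_dist <- function(object, ...) {
  df <- object$percentiles
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$q2.5, xmax = .data$q97.5)) +
    ggplot2::labs(x = "rate (/Myr), median and 95% interval", y = NULL) +
    ggplot2::theme_minimal()
}
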