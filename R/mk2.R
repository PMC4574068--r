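# Two-state continuous-time Markov (Mk2) machinery: closed-form transition
# probabilities, Felsenstein pruning, ML fitting, MCMC over a posterior tree
# sample (BayesTraits-style), and marginal ancestral-state reconstruction.

#' Mk2 transition probabilities
#'
#' Closed-form 2x2 transition-probability matrix of the two-state chain with
#' forward rate `q01` and backward rate `q10` over time `t`: with
#' `s = q01 + q10`, `P(0->0) = (q10 + q01 e^{-st}) / s` and analogously for
#' the other entries; `s = 0` gives the identity.
#'
#' @param q01,q10 Transition rates, >= 0.
#' @param t Elapsed time, >= 0.
#' @return 2x2 matrix with rows = starting state (0, 1), rows summing to 1.
#' @export
mk2_transition_prob <- function(q01, q10, t) {
  if (t < 0) abort("`t` must be >= 0")
  if (q01 < 0 || q10 < 0) abort("rates must be >= 0")
  s <- q01 + q10
  if (s == 0) return(diag(2))
  e <- exp(-s * t)
  matrix(c(
    (q10 + q01 * e) / s, (q01 - q01 * e) / s,
    (q10 - q10 * e) / s, (q01 + q10 * e) / s
  ), nrow = 2, byrow = TRUE)
}

# tip-state inputs: named 0/1/NA vector or tibble(species, state).
# every tree tip must be present; NA = missing (partial likelihood (1,1))
resolve_tip_states <- function(phy, tips) {
  if (is.data.frame(tips)) {
    if (!all(c("species", "state") %in% names(tips))) {
      abort("tip-state table needs columns `species` and `state`")
    }
    v <- setNames(tips$state, tips$species)
  } else {
    v <- tips
  }
  missing_tips <- setdiff(phy$tip.label, names(v))
  if (length(missing_tips)) {
    abort(paste("tips absent from the state table:",
                paste(missing_tips, collapse = ", ")))
  }
  v <- v[phy$tip.label]
  bad <- !is.na(v) & !(v %in% c(0, 1))
  if (any(bad)) abort("tip states must be 0, 1 or NA")
  as.integer(v)
}

mk2_root_prior <- function(root_prior, q01, q10) {
  if (is.numeric(root_prior)) {
    if (length(root_prior) != 2 || abs(sum(root_prior) - 1) > 1e-9) {
      abort("a numeric root prior must be two probabilities summing to 1")
    }
    return(root_prior)
  }
  switch(root_prior,
    equal = c(0.5, 0.5),
    stationary = {
      s <- q01 + q10
      if (s == 0) c(0.5, 0.5) else c(q10, q01) / s
    },
    abort("root prior must be 'equal', 'stationary' or two probabilities")
  )
}

# precomputed pruning skeleton for one tree (postorder edge sweep)
mk2_prep <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  list(parent = po$edge[, 1], child = po$edge[, 2], len = po$edge.length,
       ntip = ape::Ntip(phy), nn = ape::Ntip(phy) + phy$Nnode,
       root = ape::Ntip(phy) + 1L, postorder = po)
}

# partial likelihoods at every node (rows: nodes, cols: states), postorder;
# underflow-safe via per-node rescaling with exact log accumulation
mk2_partials_prep <- function(prep, states, q01, q10) {
  L <- matrix(1, prep$nn, 2)
  obs <- which(!is.na(states))
  L[obs, 1] <- as.numeric(states[obs] == 0L)
  L[obs, 2] <- as.numeric(states[obs] == 1L)
  s <- q01 + q10
  if (s > 0) {
    e <- exp(-s * prep$len)
    P00 <- (q10 + q01 * e) / s; P01 <- 1 - P00
    P11 <- (q01 + q10 * e) / s; P10 <- 1 - P11
  } else {
    P00 <- P11 <- rep(1, length(prep$len))
    P01 <- P10 <- rep(0, length(prep$len))
  }
  logscale <- 0
  ntip <- prep$ntip
  for (i in seq_along(prep$len)) {
    p <- prep$parent[i]; ch <- prep$child[i]
    l0 <- L[ch, 1]; l1 <- L[ch, 2]
    up0 <- P00[i] * l0 + P01[i] * l1
    up1 <- P10[i] * l0 + P11[i] * l1
    n0 <- L[p, 1] * up0; n1 <- L[p, 2] * up1
    if (ch > ntip) {
      m <- n0 + n1
      if (m > 0 && m < 1e-12) {
        n0 <- n0 / m; n1 <- n1 / m; logscale <- logscale + log(m)
      }
    }
    L[p, 1] <- n0; L[p, 2] <- n1
  }
  list(L = L, logscale = logscale, P = cbind(P00, P01, P10, P11))
}

mk2_partials <- function(phy, states, q01, q10) {
  prep <- mk2_prep(phy)
  out <- mk2_partials_prep(prep, states, q01, q10)
  out$postorder <- prep$postorder
  out
}

#' Mk2 pruning log-likelihood
#'
#' Exact Felsenstein-pruning likelihood of a binary character on a dated
#' tree. Missing tips contribute the uninformative partial likelihood
#' `(1, 1)`; the root is combined under the chosen prior.
#'
#' @param phy A dated `phylo`.
#' @param tips Tip states: a tibble with columns `species`, `state`
#'   (0/1/`NA`), or a named vector.
#' @param q01,q10 Transition rates, >= 0.
#' @param root_prior `"equal"` (default), `"stationary"`, or a numeric
#'   vector of two probabilities.
#' @return Scalar log-likelihood.
#' @export
mk2_loglik <- function(phy, tips, q01, q10, root_prior = "equal") {
  validate_tree(phy)
  states <- resolve_tip_states(phy, tips)
  pr <- mk2_root_prior(root_prior, q01, q10)
  parts <- mk2_partials(phy, states, q01, q10)
  root <- ape::Ntip(phy) + 1L
  log(sum(pr * parts$L[root, ])) + parts$logscale
}

#' Maximum-likelihood Mk2 fit
#'
#' Bounded quasi-Newton optimization of `(q01, q10)` on the log scale from
#' a fixed multi-start grid (deterministic). Monomorphic data drive the
#' unused rate to its lower boundary, with a warning.
#'
#' @inheritParams mk2_loglik
#' @return List of class `mk2_fit`: `q01`, `q10`, `loglik`, `df`, `aic`,
#'   `converged`, `boundary`.
#' @export
mk2_fit_ml <- function(phy, tips, root_prior = "equal") {
  validate_tree(phy)
  states <- resolve_tip_states(phy, tips)
  obs <- states[!is.na(states)]
  if (!length(obs)) abort("all tips missing: nothing to fit")
  mono <- length(unique(obs)) == 1L
  scale0 <- 1 / max(crown_age(phy), .Machine$double.eps)
  prep <- mk2_prep(phy)
  obj <- function(p) {
    q <- exp(p)
    pr <- mk2_root_prior(root_prior, q[1], q[2])
    parts <- mk2_partials_prep(prep, states, q[1], q[2])
    -(log(sum(pr * parts$L[prep$root, ])) + parts$logscale)
  }
  g <- log(scale0 * c(0.2, 1, 5))
  starts <- list(c(g[2], g[2]), c(g[1], g[3]), c(g[3], g[1]),
                 c(g[1], g[1]), c(g[3], g[3]))
  best <- optimize_multistart(obj, starts, lower = c(-18, -18), upper = c(8, 8))
  q <- exp(best$par)
  if (mono) warn("all observed tips share one state: boundary fit")
  out <- list(
    q01 = q[1], q10 = q[2], loglik = -best$objective, df = 2L,
    aic = 4 + 2 * best$objective, converged = best$converged,
    boundary = mono || any(best$par <= -18 + 1e-6)
  )
  class(out) <- "mk2_fit"
  out
}

#' @export
print.mk2_fit <- function(x, ...) {
  cat(sprintf("Mk2 ML fit: q01 = %.4g, q10 = %.4g, lnL = %.4f (AIC %.2f)\n",
              x$q01, x$q10, x$loglik, x$aic))
  invisible(x)
}

#' @export
tidy.mk2_fit <- function(x, ...) {
  tibble::tibble(term = c("q01", "q10"), estimate = c(x$q01, x$q10))
}

#' @export
glance.mk2_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, df = x$df, aic = x$aic,
                 converged = x$converged, boundary = x$boundary)
}

#' Bayesian MCMC for Mk2 rates over a tree sample
#'
#' Metropolis-Hastings sampler over `(q01, q10)` with uniform sliding-window
#' proposals, integrating over phylogenetic uncertainty by drawing a tree
#' uniformly from `trees` at every generation. Each rate carries an
#' exponential prior whose mean is itself a sampled hyper-parameter with a
#' uniform prior on `prior_mean_range` (the hierarchical form of the
#' BayesTraits-style hyperprior); the hyper-mean is updated by its own
#' sliding-window move each generation.
#'
#' @param trees A list of dated `phylo` objects (>= 1) sharing the tip set.
#' @param tips Tip states (see [mk2_loglik()]).
#' @param generations Total MCMC generations.
#' @param burnin Generations discarded as burn-in (must be < `generations`).
#' @param ratedev Half-width of the uniform proposal window, in rate units
#'   (the analogue of BayesTraits' `ratedev` tuning parameter).
#' @param prior_mean_range Range of the uniform hyperprior on the
#'   exponential prior mean.
#' @param thin Keep every `thin`-th generation.
#' @param seed Integer seed; a seeded rerun reproduces the chain exactly.
#' @inheritParams mk2_loglik
#' @return List of class `mk2_mcmc`: `samples` (tibble with `generation`,
#'   `tree_index`, `q01`, `q10`, `prior_mean`, `loglik`), `burnin`,
#'   `acceptance_rate`, `settings`.
#' @export
mk2_mcmc <- function(trees, tips, generations = 10000, burnin = 1000,
                     ratedev = 3, prior_mean_range = c(0, 30), thin = 10,
                     root_prior = "equal", seed = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) abort("need at least one tree")
  if (burnin >= generations) abort("`burnin` must be smaller than `generations`")
  states_list <- lapply(trees, resolve_tip_states, tips = tips)
  preps <- lapply(trees, mk2_prep)
  loglik_on <- function(i, q) {
    pr <- mk2_root_prior(root_prior, q[1], q[2])
    parts <- mk2_partials_prep(preps[[i]], states_list[[i]], q[1], q[2])
    log(sum(pr * parts$L[preps[[i]]$root, ])) + parts$logscale
  }
  with_seed(seed, {
    m <- runif(1, prior_mean_range[1], prior_mean_range[2])
    q <- rexp(2, 1 / max(m, 1e-8))
    i <- sample.int(length(trees), 1)
    ll <- loglik_on(i, q)
    lprior <- function(q, m) sum(dexp(q, 1 / max(m, 1e-12), log = TRUE))
    lp <- ll + lprior(q, m)
    keep <- seq(thin, generations, by = thin)
    out <- matrix(NA_real_, length(keep), 6)
    accepted <- 0L; proposed <- 0L; ki <- 1L
    for (gen in seq_len(generations)) {
      i <- sample.int(length(trees), 1)
      ll <- loglik_on(i, q)
      lp <- ll + lprior(q, m)
      # rate move: slide one of the two rates
      j <- if (gen %% 2L == 1L) 1L else 2L
      qp <- q
      qp[j] <- q[j] + runif(1, -ratedev, ratedev)
      proposed <- proposed + 1L
      if (qp[j] >= 0) {
        llp <- loglik_on(i, qp)
        lpp <- llp + lprior(qp, m)
        if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
          q <- qp; ll <- llp; lp <- lpp; accepted <- accepted + 1L
        }
      }
      # hyper-mean move (uniform prior: acceptance on the exponential terms)
      mp <- m + runif(1, -1, 1) * diff(prior_mean_range) / 10
      if (mp > prior_mean_range[1] && mp <= prior_mean_range[2]) {
        if (log(runif(1)) < lprior(q, mp) - lprior(q, m)) m <- mp
      }
      if (ki <= length(keep) && gen == keep[ki]) {
        out[ki, ] <- c(gen, i, q[1], q[2], m, ll)
        ki <- ki + 1L
      }
    }
    samples <- tibble::tibble(
      generation = as.integer(out[, 1]), tree_index = as.integer(out[, 2]),
      q01 = out[, 3], q10 = out[, 4], prior_mean = out[, 5], loglik = out[, 6]
    )
    res <- list(
      samples = samples, burnin = burnin,
      acceptance_rate = accepted / proposed,
      settings = list(generations = generations, burnin = burnin,
                      ratedev = ratedev, prior_mean_range = prior_mean_range,
                      thin = thin, root_prior = root_prior, seed = seed)
    )
    class(res) <- "mk2_mcmc"
    res
  })
}

#' @export
print.mk2_mcmc <- function(x, ...) {
  s <- posterior_samples(x)
  cat(sprintf(
    "Mk2 MCMC: %d kept samples (post burn-in), acceptance %.2f\n  q01 median %.4g, q10 median %.4g\n",
    nrow(s), x$acceptance_rate, median(s$q01), median(s$q10)
  ))
  invisible(x)
}

#' Post-burn-in samples of an Mk2 MCMC run
#' @param x An `mk2_mcmc` object.
#' @return Tibble of retained samples with `generation > burnin`.
#' @export
posterior_samples <- function(x) {
  dplyr::filter(x$samples, .data$generation > x$burnin)
}

#' @export
tidy.mk2_mcmc <- function(x, ...) {
  s <- posterior_samples(x)
  purrr::map_dfr(c("q01", "q10"), function(p) {
    v <- s[[p]]
    tibble::tibble(term = p, estimate = median(v),
                   conf.low = quantile(v, 0.05), conf.high = quantile(v, 0.95))
  })
}

#' @export
glance.mk2_mcmc <- function(x, ...) {
  tibble::tibble(n_samples = nrow(posterior_samples(x)),
                 acceptance_rate = x$acceptance_rate,
                 generations = x$settings$generations, burnin = x$burnin)
}

#' Marginal ancestral states under Mk2
#'
#' Per-node marginal probability of each state from the standard up-down
#' (inside-outside) pass at fixed rates. Missing tips additionally get
#' marginal state probabilities (their pendant "outside" likelihood), so
#' downstream transition counting can impute them.
#'
#' @inheritParams mk2_loglik
#' @return Tibble of class `asr_states`: `node` (ape number), `bipartition`
#'   (tip-set key; for imputed missing tips, the tip name), `p0`, `p1`.
#' @export
mk2_asr_marginal <- function(phy, tips, q01, q10, root_prior = "equal") {
  validate_tree(phy)
  states <- resolve_tip_states(phy, tips)
  pr <- mk2_root_prior(root_prior, q01, q10)
  parts <- mk2_partials(phy, states, q01, q10)
  L <- parts$L
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  nn <- ntip + phy$Nnode
  po <- parts$postorder
  # outside pass (preorder = reverse postorder edge sweep)
  out <- matrix(NA_real_, nn, 2)
  out[root, ] <- pr
  children <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    P <- mk2_transition_prob(q01, q10, po$edge.length[e])
    sibs <- setdiff(children[[as.character(p)]], e)
    sib_term <- rep(1, 2)
    for (se in sibs) {
      Ps <- mk2_transition_prob(q01, q10, po$edge.length[se])
      sib_term <- sib_term * as.numeric(Ps %*% L[po$edge[se, 2], ])
    }
    out[ch, ] <- as.numeric(t(P) %*% (out[p, ] * sib_term))
  }
  nodes <- (ntip + 1L):nn
  marg <- L[nodes, , drop = FALSE] * out[nodes, , drop = FALSE]
  marg <- marg / rowSums(marg)
  bi <- bipartition_index(phy)
  res <- tibble::tibble(
    node = nodes,
    bipartition = bi$bipartition[match(nodes, bi$node)],
    p0 = marg[, 1], p1 = marg[, 2]
  )
  # marginal imputation for missing tips
  miss <- which(is.na(states))
  if (length(miss)) {
    mt <- L[miss, , drop = FALSE] * out[miss, , drop = FALSE]
    mt <- mt / rowSums(mt)
    res <- dplyr::bind_rows(res, tibble::tibble(
      node = miss, bipartition = phy$tip.label[miss],
      p0 = mt[, 1], p1 = mt[, 2]
    ))
  }
  class(res) <- c("asr_states", class(res))
  res
}

#' Average ancestral states over a posterior tree sample
#'
#' Matches nodes across trees by bipartition and averages the per-tree
#' marginal probabilities onto the nodes of a reference tree. By default a
#' reference node is averaged over the trees whose topology contains it
#' (`absent = "skip"`), with the support count reported;
#' `absent = "zero"` divides by the full sample size instead, so the
#' reported probabilities sum to the node's support fraction.
#'
#' @param asr_list List of `asr_states` tibbles, one per tree.
#' @param reference A `phylo` whose internal nodes define the output rows.
#' @param absent `"skip"` or `"zero"` (see above).
#' @return Tibble of class `asr_states` with `node`, `bipartition`, `p0`,
#'   `p1`, `support` (number of contributing trees) and `unsupported`
#'   (no tree contained the bipartition).
#' @export
asr_average <- function(asr_list, reference, absent = c("skip", "zero")) {
  absent <- match.arg(absent)
  bi <- bipartition_index(reference)
  all_asr <- dplyr::bind_rows(asr_list)
  n_trees <- length(asr_list)
  agg <- all_asr |>
    dplyr::filter(.data$bipartition %in% bi$bipartition) |>
    dplyr::group_by(.data$bipartition) |>
    dplyr::summarise(sum0 = sum(.data$p0), sum1 = sum(.data$p1),
                     support = dplyr::n(), .groups = "drop")
  res <- dplyr::left_join(bi, agg, by = "bipartition")
  res$support[is.na(res$support)] <- 0L
  denom <- if (absent == "skip") res$support else n_trees
  res$p0 <- res$sum0 / denom
  res$p1 <- res$sum1 / denom
  res$unsupported <- res$support == 0L
  res <- dplyr::select(res, "node", "bipartition", "p0", "p1", "support",
                       "unsupported")
  class(res) <- c("asr_states", class(res))
  res
}

#' @export
autoplot.asr_states <- function(object, ...) {
  df <- dplyr::arrange(object, .data$node)
  df$node_f <- factor(df$node, levels = df$node)
  long <- tidyr::pivot_longer(df, c("p0", "p1"), names_to = "state",
                              values_to = "probability")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$node_f, y = .data$probability,
                                     fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "node", y = "marginal probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
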