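two_tip_pars <- c(lambdaO = 0.5, lambdaS = 0.5, muO = 0, muS = 0,
                  qOS = 0, qSO = 0)

test_that("the two-tip closed forms are reproduced", {
  phy <- parse_newick("(A:1,B:1);")
  tips <- tibble::tibble(species = c("A", "B"), state = c(0L, 0L))
  expect_equal(bisse_loglik(phy, tips, two_tip_pars, condition_surv = FALSE),
               log(0.5) - 1, tolerance = 1e-7)
  expect_equal(bisse_loglik(phy, tips, two_tip_pars, condition_surv = TRUE),
               -1, tolerance = 1e-7)
})

test_that("the adaptive integrator agrees with a fixed-step RK4 oracle", {
  set.seed(10)
  for (i in 1:4) {
    phy <- sim_yule(n = 6, lambda = 1)
    st <- sample(c(0L, 1L), 6, replace = TRUE)
    if (i == 3) st[2] <- NA
    names(st) <- phy$tip.label
    p6 <- stats::runif(6, 0.05, 1)
    p6[3:4] <- p6[3:4] * 0.3
    names(p6) <- names(two_tip_pars)
    h <- if (i <= 2) 1e-4 else 1e-3
    a <- bisse_loglik(phy, st, p6, condition_surv = TRUE)
    b <- rk4_bisse_loglik(phy, unname(st[phy$tip.label]), unname(p6),
                          h = h, cond = TRUE)
    expect_lt(abs(a - b), 1e-6)
  }
})

test_that("with no extinction and no transitions BiSSE reduces to pure birth", {
  # survival conditioning removes the extra crown-speciation factor, so the
  # difference to the branching-time likelihood is constant in lambda
  phy <- sim_yule(n = 10, lambda = 0.8, seed = 17)
  tips <- tibble::tibble(species = phy$tip.label, state = 0L)
  bt <- branching_times(phy)
  diffs <- vapply(c(0.2, 0.5, 0.9, 1.5), function(lam) {
    pars <- c(lambdaO = lam, lambdaS = lam, muO = 0, muS = 0, qOS = 0, qSO = 0)
    (bisse_loglik(phy, tips, pars, root = "flat", condition_surv = TRUE) -
       log(0.5)) - pb_loglik(bt, lam)
  }, numeric(1))
  expect_lt(max(diffs) - min(diffs), 1e-5)
})

test_that("the likelihood is invariant under relabelling states and swapping rates", {
  phy <- sim_yule(n = 12, lambda = 0.7, seed = 19)
  st <- random_tip_states(phy, p1 = 0.4)
  pars <- c(lambdaO = 0.6, lambdaS = 0.3, muO = 0.1, muS = 0.2,
            qOS = 0.25, qSO = 0.05)
  swapped_pars <- pars[c("lambdaS", "lambdaO", "muS", "muO", "qSO", "qOS")]
  names(swapped_pars) <- names(pars)
  swapped_tips <- st
  swapped_tips$state <- 1L - swapped_tips$state
  expect_equal(bisse_loglik(phy, st, pars),
               bisse_loglik(phy, swapped_tips, swapped_pars), tolerance = 1e-7)
  # missing tips contribute both states
  miss <- st; miss$state[1] <- NA
  expect_true(is.finite(bisse_loglik(phy, miss, pars)))
  expect_error(bisse_loglik(phy, st[-1, ], pars), "absent")
})

test_that("likelihood-ratio tests reproduce the printed-median arithmetic", {
  med <- clade_c_bisse_medians()
  full_ll <- med$log_likelihood[med$model == "full"]
  eq_lam <- med$log_likelihood[med$model == "lambdaO=lambdaS"]
  no_qos <- med$log_likelihood[med$model == "qOS=0"]
  l1 <- lrt(full_ll, eq_lam, 1)
  expect_equal(l1$statistic, 6.42, tolerance = 1e-9)
  expect_lt(l1$p_value, 0.05)
  expect_equal(l1$p_value, 0.0113, tolerance = 0.01)
  l2 <- lrt(full_ll, no_qos, 1)
  expect_equal(l2$statistic, 16.58, tolerance = 1e-9)
  expect_lt(l2$p_value, 1e-4)
  l0 <- lrt(-5, -5, 2)
  expect_equal(l0$statistic, 0)
  expect_equal(l0$p_value, 1)
  expect_error(lrt(-10, -5, 1), "failure")
})

test_that("the thirteen canonical constraints carry the right dimensions", {
  models <- bisse_model_set()
  expect_length(models, 13)
  dfs <- vapply(models, `[[`, integer(1), "df")
  expect_equal(sort(unname(dfs)), c(2L, 3L, 4L, rep(5L, 9), 6L))
  expect_equal(dfs[["full"]], 6L)
  nm <- vapply(models, `[[`, character(1), "name")
  expect_equal(unname(nm[dfs == 2L]), "lambdaS=0,muO=0,muS=0,qSO=0")
})

test_that("zero-fixed parameters never move and fits summarise sanely", {
  cc <- sim_clade_c_like(seed = 4, n_trees = 2)
  dead_end <- bisse_constraint(zeros = c("lambdaS", "muO", "muS", "qSO"))
  fit <- bisse_fit(cc$trees, cc$tip_states, dead_end)
  expect_true(all(fit$per_tree$lambdaS == 0))
  expect_true(all(fit$per_tree$muO == 0))
  expect_true(all(fit$per_tree$muS == 0))
  expect_true(all(fit$per_tree$qSO == 0))
  expect_equal(fit$df, 2L)
  expect_true(all(fit$per_tree$aic == 4 - 2 * fit$per_tree$loglik))
  td <- tidy(fit)
  expect_setequal(td$term, names(two_tip_pars))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("the model suite ranks by median AIC and honours per-tree nesting", {
  cc <- sim_clade_c_like(seed = 5, n_trees = 2)
  suite <- bisse_model_suite(cc$trees, cc$tip_states)
  tab <- suite$table
  expect_equal(nrow(tab), 13)
  expect_true(!is.unsorted(tab$aic))
  expect_equal(tab$delta_aic[1], 0)
  expect_true(all(tab$pct_reject[!is.na(tab$pct_reject)] >= 0 &
                    tab$pct_reject[!is.na(tab$pct_reject)] <= 100))
  full_ll <- suite$fits[["full"]]$per_tree$loglik
  for (nm in names(suite$fits)) {
    if (nm == "full") next
    expect_true(all(suite$fits[[nm]]$per_tree$loglik <= full_ll + 1e-4))
  }
})

test_that("a state-symmetric fit recovers birth-death rates", {
  con <- bisse_constraint(
    ties = list(c("lambdaO", "lambdaS"), c("muO", "muS"), c("qOS", "qSO")),
    name = "state-independent"
  )
  set.seed(11)
  est <- replicate(40, {
    phy <- sim_bd(120, 0.6, 0.3)
    st <- tibble::tibble(species = phy$tip.label,
                         state = sample(c(0L, 1L), 120, replace = TRUE))
    f <- selfsse:::bisse_fit_tree(phy, st, con)
    c(f$pars[["lambdaO"]], f$pars[["muO"]])
  })
  expect_lt(abs(stats::median(est[1, ]) - 0.6) / 0.6, 0.25)
  expect_lt(abs(stats::median(est[2, ]) - 0.3) / 0.3, 0.25)
})

test_that("marginal ancestral states normalise, match Mk2 in the neutral limit, and favour the ancestral state on the fixture", {
  set.seed(21)
  for (i in 1:3) {
    phy <- sim_yule(n = 6, lambda = 1)
    st <- sample(c(0L, 1L), 6, replace = TRUE)
    if (length(unique(st)) == 1) st[1] <- 1L - st[1]
    names(st) <- phy$tip.label
    q <- stats::runif(2, 0.1, 0.6)
    pars <- c(lambdaO = 0.5, lambdaS = 0.5, muO = 0, muS = 0,
              qOS = q[1], qSO = q[2])
    ab <- bisse_asr_marginal(phy, st, pars, root = "given",
                             root_p = c(0.5, 0.5), condition_surv = FALSE)
    am <- mk2_asr_marginal(phy, st, q[1], q[2])
    j <- dplyr::inner_join(ab, am, by = "bipartition", suffix = c("_b", "_m"))
    expect_lt(max(abs(j$p1_b - j$p1_m)), 0.05)
    expect_true(all(abs(ab$p0 + ab$p1 - 1) < 1e-9))
  }

  cc <- sim_clade_c_like(seed = 7, n_trees = 3)
  best <- c(lambdaO = 0.68, lambdaS = 0, muO = 0, muS = 0, qOS = 0.21, qSO = 0)
  for (tr in cc$trees) {
    a <- bisse_asr_marginal(tr, cc$tip_states, best)
    internal <- a[a$node > ape::Ntip(tr), ]
    expect_true(all(internal$p0 >= 0.5))
  }
})

test_that("parameter distributions summarise per-tree fits with overlap flags", {
  cc <- sim_clade_c_like(seed = 9, n_trees = 20)
  fit <- bisse_fit(cc$trees, cc$tip_states, bisse_constraint())
  dist <- bisse_param_distributions(fit)
  p <- dist$percentiles
  expect_true(all(p$q2.5 <= p$median & p$median <= p$q97.5))
  # speciation simulated at lambdaO = 0.68 vs lambdaS = 0: no overlap
  expect_false(dist$overlap$overlap[dist$overlap$rate_class == "speciation"])
  expect_error(bisse_param_distributions(fit, min_fits = 50), "at least")

  # identical distributions must overlap
  fake <- fit
  fake$per_tree$lambdaS <- fake$per_tree$lambdaO
  expect_true(bisse_param_distributions(fake)$overlap$overlap[1])
})
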