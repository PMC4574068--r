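test_that("transition probabilities match the closed form and the matrix exponential", {
  # q01 = q10 = 1 and exp(-2t) = 0.5 gives P(0->0) = 0.75
  t_half <- log(2) / 2
  P <- mk2_transition_prob(1, 1, t_half)
  expect_equal(P[1, 1], 0.75, tolerance = 1e-12)
  expect_equal(mk2_transition_prob(0.3, 0.8, 0), diag(2))
  expect_equal(mk2_transition_prob(0, 0, 5), diag(2))
  expect_error(mk2_transition_prob(1, 1, -1), ">= 0")

  set.seed(3)
  for (i in 1:15) {
    q <- stats::runif(2, 0, 3); t <- stats::runif(1, 0, 10)
    Q <- matrix(c(-q[1], q[1], q[2], -q[2]), 2, byrow = TRUE)
    expect_lt(max(abs(mk2_transition_prob(q[1], q[2], t) -
                        as.matrix(Matrix::expm(Q * t)))), 1e-10)
  }
})

test_that("pruning likelihood equals exhaustive enumeration on small trees", {
  set.seed(5)
  for (i in 1:10) {
    phy <- sim_yule(n = sample(4:6, 1), lambda = 1)
    st <- sim_mk2(phy, 0.4, 0.7)$tip_states$state
    if (i %% 2 == 0) st[1] <- NA  # exercise the missing-tip path
    names(st) <- phy$tip.label
    q <- stats::runif(2, 0.05, 2)
    expect_lt(abs(mk2_loglik(phy, st, q[1], q[2]) -
                    enum_mk2_loglik(phy, unname(st[phy$tip.label]), q[1], q[2])),
              1e-10)
  }
})

test_that("likelihood limits and symmetries hold", {
  phy <- sim_yule(n = 8, lambda = 1, seed = 4)
  all_na <- setNames(rep(NA_integer_, 8), phy$tip.label)
  expect_equal(mk2_loglik(phy, all_na, 0.4, 0.2), 0)

  st <- sim_mk2(phy, 0.5, 0.3, seed = 6)$tip_states
  swapped <- st
  swapped$state <- 1L - swapped$state
  expect_equal(mk2_loglik(phy, st, 0.5, 0.3),
               mk2_loglik(phy, swapped, 0.3, 0.5), tolerance = 1e-12)

  # tips absent from the table are a data error, not silently missing
  expect_error(mk2_loglik(phy, st[-1, ], 0.5, 0.3), "absent")
})

test_that("ML fit recovers simulated rates and flags boundary data", {
  big <- sim_yule(n = 200, lambda = 0.5, seed = 10)
  # cross-check the likelihood surface against an independent implementation
  st <- sim_mk2(big, 0.3, 0.1, seed = 11)$tip_states
  ours <- mk2_fit_ml(big, st)
  fm <- phytools::fitMk(big, setNames(as.factor(st$state), st$species),
                        model = "ARD", pi = c(0.5, 0.5))
  expect_equal(ours$loglik, as.numeric(stats::logLik(fm)), tolerance = 1e-3)

  set.seed(12)
  est <- replicate(11, {
    s <- sim_mk2(big, 0.3, 0.1)$tip_states
    f <- mk2_fit_ml(big, s)
    c(f$q01, f$q10)
  })
  expect_lt(abs(stats::median(est[1, ]) - 0.3) / 0.3, 0.25)
  expect_lt(abs(stats::median(est[2, ]) - 0.1) / 0.1, 0.25)

  mono <- tibble::tibble(species = big$tip.label, state = 0L)
  expect_warning(f0 <- mk2_fit_ml(big, mono), "one state")
  expect_lt(f0$q01, 1e-6)

  # invariance to tip relabelling that preserves the states
  phy <- sim_yule(n = 12, lambda = 1, seed = 13)
  st <- sim_mk2(phy, 0.4, 0.2, seed = 14)$tip_states
  perm <- sample(nrow(st))
  expect_equal(mk2_fit_ml(phy, st)$loglik,
               mk2_fit_ml(phy, st[perm, ])$loglik, tolerance = 1e-8)
})

test_that("a prior-only chain reproduces the hierarchical exponential prior", {
  trees <- lapply(1:3, function(i) sim_yule(n = 10, lambda = 1, seed = i))
  no_data <- tibble::tibble(species = trees[[1]]$tip.label, state = NA_integer_)
  ch <- mk2_mcmc(trees, no_data, generations = 60000, burnin = 5000,
                 ratedev = 12, thin = 20, seed = 3)
  s <- posterior_samples(ch)
  set.seed(99)
  m <- stats::runif(5e4, 0, 30)
  direct <- stats::rexp(5e4, 1 / m)
  probs <- seq(0.1, 0.9, by = 0.1)
  qc <- stats::quantile(s$q01, probs)
  qd <- stats::quantile(direct, probs)
  # deciles agree within MCMC error (chain draws are autocorrelated)
  expect_lt(max(abs(qc - qd) / (1 + qd)), 0.25)
})

test_that("the sampler is seeded-reproducible with sane acceptance on the fixture", {
  cc <- sim_clade_c_like(seed = 8, n_trees = 5)
  ch1 <- mk2_mcmc(cc$trees, cc$tip_states, generations = 4000, burnin = 500,
                  thin = 5, seed = 21)
  ch2 <- mk2_mcmc(cc$trees, cc$tip_states, generations = 4000, burnin = 500,
                  thin = 5, seed = 21)
  expect_identical(ch1$samples, ch2$samples)
  expect_gt(ch1$acceptance_rate, 0.1)
  expect_lt(ch1$acceptance_rate, 0.6)
  expect_error(mk2_mcmc(cc$trees, cc$tip_states, generations = 100, burnin = 100),
               "smaller")
})

test_that("posterior intervals are calibrated for truths drawn from the prior", {
  # Cook-Gelman-Rubin-style self-consistency: when the generating rates are
  # drawn from the sampler's own hierarchical prior, nominal 90% credible
  # intervals must cover them at close to the nominal rate
  phy <- sim_clade_c_like(seed = 8, n_trees = 1)$trees[[1]]
  set.seed(31)
  cover <- replicate(8, {
    m <- stats::runif(1, 0, 30)
    q <- stats::rexp(2, 1 / m)
    st <- sim_mk2(phy, q[1], q[2])$tip_states
    ch <- mk2_mcmc(list(phy), st, generations = 20000, burnin = 4000,
                   ratedev = 3, thin = 10)
    s <- posterior_samples(ch)
    c(stats::quantile(s$q01, 0.05) <= q[1] && stats::quantile(s$q01, 0.95) >= q[1],
      stats::quantile(s$q10, 0.05) <= q[2] && stats::quantile(s$q10, 0.95) >= q[2])
  })
  expect_gte(mean(cover[1, ]), 0.625)
  expect_gte(mean(cover[2, ]), 0.625)
})

test_that("marginal ancestral states match enumeration and behave at limits", {
  phy <- sim_yule(n = 5, lambda = 1, seed = 9)
  st <- c(0L, 1L, 1L, 0L, 1L)
  names(st) <- phy$tip.label
  for (q in list(c(0.4, 0.9), c(0.05, 0.02))) {
    a <- mk2_asr_marginal(phy, st, q[1], q[2])
    expect_true(all(abs(a$p0 + a$p1 - 1) < 1e-9))
    for (nd in a$node[a$node > ape::Ntip(phy)]) {
      expect_lt(abs(a$p1[a$node == nd] -
                      enum_mk2_marginal(phy, unname(st[phy$tip.label]),
                                        q[1], q[2], nd)[2]), 1e-9)
    }
  }
  # a cherry of two derived tips under tiny rates is confidently derived
  cherry <- parse_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  stc <- c(A = 1L, B = 1L, C = 0L, D = 0L)
  ac <- mk2_asr_marginal(cherry, stc, 0.005, 0.005)
  nd <- bipartition_lookup(bipartition_index(cherry), c("A", "B"))
  expect_gt(ac$p1[ac$node == nd], 0.99)
  # missing tips get imputation rows keyed by their label
  stm <- stc; stm["D"] <- NA
  am <- mk2_asr_marginal(cherry, stm, 0.1, 0.1)
  expect_true("D" %in% am$bipartition)
})

test_that("averaging ancestral states across trees follows the support rules", {
  phy <- sim_yule(n = 8, lambda = 1, seed = 40)
  st <- sim_mk2(phy, 0.3, 0.2, seed = 41)$tip_states
  a1 <- mk2_asr_marginal(phy, st, 0.3, 0.2)
  same <- asr_average(list(a1, a1, a1), phy)
  j <- dplyr::inner_join(same, a1, by = "bipartition", suffix = c("_avg", "_one"))
  expect_equal(j$p1_avg, j$p1_one, tolerance = 1e-12)
  expect_true(all(same$support == 3L))

  # a bipartition present in half the trees: skip-averaging keeps its mean,
  # zero-averaging scales it to the support fraction
  other <- phy
  # swap two tip labels to break some bipartitions in half the sample
  other$tip.label[1:2] <- other$tip.label[2:1]
  a2 <- mk2_asr_marginal(other, st, 0.3, 0.2)
  avg_skip <- asr_average(list(a1, a2), phy, absent = "skip")
  avg_zero <- asr_average(list(a1, a2), phy, absent = "zero")
  half <- avg_skip$support == 1L
  expect_true(any(half))
  expect_equal(avg_zero$p1[half] + avg_zero$p0[half],
               rep(0.5, sum(half)), tolerance = 1e-12)
  expect_equal(avg_skip$p1[half] + avg_skip$p0[half],
               rep(1, sum(half)), tolerance = 1e-12)
})

test_that("averaged reconstructions recover the true simulated node states", {
  cc <- sim_clade_c_like(seed = 6, n_trees = 20)
  p_true <- unlist(lapply(1:3, function(k) {
    truth <- sim_mk2(cc$base_tree, 0.15, 0.05, seed = 60 + k)
    per_tree <- lapply(cc$trees, function(tr) {
      mk2_asr_marginal(tr, truth$tip_states, 0.15, 0.05)
    })
    avg <- asr_average(per_tree, cc$base_tree)
    true_states <- truth$node_states[as.character(avg$node)]
    ifelse(true_states == 1L, avg$p1, avg$p0)
  }))
  expect_gte(mean(p_true >= 0.5), 0.8)
})
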