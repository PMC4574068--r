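# Independent oracles used across test files. These deliberately avoid the
# package's own computational paths: the Mk2 oracle enumerates internal
# state assignments, the BiSSE oracle is a fixed-step classical RK4
# integrator written in plain R.

enum_mk2_loglik <- function(phy, states, q01, q10, prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(phy)
  combos <- expand.grid(rep(list(0:1), phy$Nnode))
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    asg <- c(states, as.integer(combos[r, ]))
    p <- prior[asg[ntip + 1] + 1]
    for (e in seq_len(nrow(phy$edge))) {
      a <- asg[phy$edge[e, 1]]; b <- asg[phy$edge[e, 2]]
      if (is.na(b)) next  # missing tip: marginalised out (P rows sum to 1)
      p <- p * mk2_transition_prob(q01, q10, phy$edge.length[e])[a + 1, b + 1]
    }
    tot <- tot + p
  }
  log(tot)
}

enum_mk2_marginal <- function(phy, states, q01, q10, node, prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(phy)
  combos <- expand.grid(rep(list(0:1), phy$Nnode))
  tot <- c(0, 0)
  for (r in seq_len(nrow(combos))) {
    asg <- c(states, as.integer(combos[r, ]))
    p <- prior[asg[ntip + 1] + 1]
    for (e in seq_len(nrow(phy$edge))) {
      a <- asg[phy$edge[e, 1]]; b <- asg[phy$edge[e, 2]]
      if (is.na(b)) next
      p <- p * mk2_transition_prob(q01, q10, phy$edge.length[e])[a + 1, b + 1]
    }
    s <- asg[node]
    tot[s + 1] <- tot[s + 1] + p
  }
  tot / sum(tot)
}

# fixed-step fourth-order Runge-Kutta BiSSE likelihood (pars in the order
# lambdaO, lambdaS, muO, muS, qOS, qSO; states aligned with tip order)
rk4_bisse_loglik <- function(phy, states, pars, h = 1e-4, cond = TRUE,
                             root = "observed") {
  deriv <- function(y, p) {
    E0 <- y[1]; E1 <- y[2]; D0 <- y[3]; D1 <- y[4]
    c(p[3] - (p[1] + p[3] + p[5]) * E0 + p[1] * E0^2 + p[5] * E1,
      p[4] - (p[2] + p[4] + p[6]) * E1 + p[2] * E1^2 + p[6] * E0,
      -(p[1] + p[3] + p[5]) * D0 + p[5] * D1 + 2 * p[1] * E0 * D0,
      -(p[2] + p[4] + p[6]) * D1 + p[6] * D0 + 2 * p[2] * E1 * D1)
  }
  integ <- function(y, len, p) {
    nst <- max(1L, ceiling(len / h)); hh <- len / nst
    for (i in seq_len(nst)) {
      k1 <- deriv(y, p); k2 <- deriv(y + hh / 2 * k1, p)
      k3 <- deriv(y + hh / 2 * k2, p); k4 <- deriv(y + hh * k3, p)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  po <- ape::reorder.phylo(phy, "postorder")
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  Y <- matrix(0, nn, 4); seen <- integer(nn)
  for (i in seq_len(ntip)) {
    if (is.na(states[i])) Y[i, 3:4] <- 1
    else Y[i, 3:4] <- c(as.numeric(states[i] == 0), as.numeric(states[i] == 1))
  }
  for (e in seq_len(nrow(po$edge))) {
    p_ <- po$edge[e, 1]; ch <- po$edge[e, 2]
    y <- integ(Y[ch, ], po$edge.length[e], pars)
    if (!seen[p_]) { Y[p_, ] <- y; seen[p_] <- 1 }
    else {
      Y[p_, 3] <- pars[1] * Y[p_, 3] * y[3]
      Y[p_, 4] <- pars[2] * Y[p_, 4] * y[4]
    }
  }
  root_i <- ntip + 1
  d <- Y[root_i, 3:4]; ee <- Y[root_i, 1:2]
  w <- if (root == "observed") d / sum(d) else c(0.5, 0.5)
  l <- sum(w * d)
  if (cond) l <- l / sum(w * pars[1:2] * (1 - ee)^2)
  log(l)
}

random_tip_states <- function(phy, p1 = 0.5, n_missing = 0) {
  n <- ape::Ntip(phy)
  st <- stats::rbinom(n, 1, p1)
  if (n_missing > 0) st[sample.int(n, n_missing)] <- NA
  tibble::tibble(species = phy$tip.label, state = as.integer(st))
}
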