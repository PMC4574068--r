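# Forward simulators. All are crown-conditioned Gillespie processes: the
# simulation starts from the two crown lineages, waiting times are
# exponential in the total event rate, and (by default) once the survivor
# count first reaches n the interval to the present is drawn as the waiting
# time to the next, unobserved event. Extinct lineages are pruned so the
# returned tree is the reconstructed tree.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One crown-conditioned realisation of the binary-state birth-death process.
# Returns NULL on whole-clade extinction (caller retries), otherwise a list
# with the reconstructed phylo, tip/node states and bookkeeping.
#
# Size conditioning: "first_passage" stops when the survivor count first
# reaches n and draws the final segment as the waiting time to the next
# (unobserved) event — exact for pure birth, where the count is monotone.
# "gsa" is the general sampling approach required once extinction can make
# the count revisit n: the simulation runs on until the count either dies
# out or safely exceeds n, every time interval during which exactly n
# lineages were alive is recorded, a "present" is drawn from those
# intervals with probability proportional to their length, and the tree is
# reconstructed as of that present (first-passage stopping would cluster
# events against the stopping boundary and bias extinction estimates
# upward).
sim_sse_once <- function(n = NULL, t_max = NULL, lambda, mu, q, root_state,
                         method = c("first_passage", "gsa")) {
  method <- match.arg(method)
  cap <- 8L * (if (is.null(n)) 64L else n) + 64L
  kind <- integer(cap)            # 0 tip, 1 node
  birth <- numeric(cap); tend <- numeric(cap)
  state <- integer(cap); bstate <- integer(cap)
  c1 <- integer(cap); c2 <- integer(cap)
  alive <- logical(cap)
  nelem <- 0L
  flip_elem <- integer(0); flip_time <- numeric(0)  # state-change history
  new_elem <- function(tb, st) {
    nelem <<- nelem + 1L
    if (nelem > length(kind)) {   # grow
      grow <- function(x) c(x, x)
      kind <<- grow(kind); birth <<- grow(birth); tend <<- grow(tend)
      state <<- grow(state); bstate <<- grow(bstate)
      c1 <<- grow(c1); c2 <<- grow(c2); alive <<- grow(alive)
    }
    kind[nelem] <<- 0L; birth[nelem] <<- tb; state[nelem] <<- st
    bstate[nelem] <<- st
    alive[nelem] <<- TRUE
    nelem
  }
  root <- new_elem(0, root_state)
  a <- new_elem(0, root_state); b <- new_elem(0, root_state)
  kind[root] <- 1L; tend[root] <- 0; c1[root] <- a; c2[root] <- b
  alive[root] <- FALSE
  act <- c(a, b)

  t <- 0
  present <- NA_real_
  size_cap <- if (!is.null(n)) max(3L * n, n + 30L) else NA_integer_
  niv_start <- numeric(0); niv_end <- numeric(0)  # intervals with exactly n alive
  open_start <- if (!is.null(n) && length(act) == n) 0 else NA_real_
  repeat {
    st_act <- state[act]
    per <- lambda[st_act + 1L] + mu[st_act + 1L] + q[st_act + 1L]
    R <- sum(per)
    if (method == "first_passage" && !is.null(n) && length(act) == n) {
      present <- t + if (R > 0) rexp(1, R) else 0
      break
    }
    if (method == "gsa" && !is.null(n) && length(act) >= size_cap) break
    if (R <= 0) {
      if (!is.null(t_max)) { present <- t_max; break }
      if (method == "gsa" && !is.na(open_start)) {
        # frozen forever at n (all rates zero): close a unit-length window
        niv_start <- c(niv_start, open_start); niv_end <- c(niv_end, t + 1)
        t <- t + 1
        break
      }
      return(NULL)  # frozen below target size: cannot reach n
    }
    dt <- rexp(1, R)
    if (!is.null(t_max) && t + dt >= t_max) { present <- t_max; break }
    t <- t + dt
    i <- sample.int(length(act), 1L, prob = per)
    id <- act[i]; s <- state[id]
    k_before <- length(act)
    u <- runif(1) * (lambda[s + 1L] + mu[s + 1L] + q[s + 1L])
    if (u < lambda[s + 1L]) {            # speciation
      kind[id] <- 1L; tend[id] <- t; alive[id] <- FALSE
      a <- new_elem(t, s); b <- new_elem(t, s)
      c1[id] <- a; c2[id] <- b
      act <- c(act[-i], a, b)
    } else if (u < lambda[s + 1L] + mu[s + 1L]) {  # extinction
      tend[id] <- t; alive[id] <- FALSE
      act <- act[-i]
      if (length(act) == 0L && method != "gsa") return(NULL)
    } else {                              # state flip
      state[id] <- 1L - s
      flip_elem <- c(flip_elem, id); flip_time <- c(flip_time, t)
    }
    if (method == "gsa" && !is.null(n)) {
      k_after <- length(act)
      if (k_before == n && k_after != n) {
        niv_start <- c(niv_start, open_start); niv_end <- c(niv_end, t)
        open_start <- NA_real_
      } else if (k_before != n && k_after == n) {
        open_start <- t
      }
      if (k_after == 0L) break
    }
  }

  n_time <- 0
  if (method == "gsa" && !is.null(n)) {
    if (!length(niv_start)) return(NULL)   # never observed at size n
    lens <- niv_end - niv_start
    n_time <- sum(lens)
    u <- runif(1, 0, n_time)
    j <- findInterval(u, cumsum(c(0, lens)), rightmost.closed = TRUE)
    present <- niv_start[j] + (u - cumsum(c(0, lens))[j])
  }
  # close lineages still alive at the end of the simulated span
  if (length(act)) tend[act] <- max(t, present, na.rm = TRUE) + 1e-9

  # state of a lineage at a given moment: birth state plus the parity of
  # its recorded flips up to that time
  state_at <- function(id, when) {
    if (!length(flip_elem)) return(bstate[id])
    k <- sum(flip_elem == id & flip_time <= when)
    if (k %% 2L == 0L) bstate[id] else 1L - bstate[id]
  }

  # reconstruct the tree as of `present`: lineages alive then become tips
  # (truncated at the present), extinct lineages are pruned, and a node
  # with one surviving side collapses, its branch length accruing to the
  # surviving child's pending length
  node_ages_out <- numeric(0)
  tip_state_out <- integer(0)
  rec <- function(id) {
    is_node_before <- kind[id] == 1L && tend[id] < present
    if (!is_node_before) {
      # a lineage segment at the present: alive iff it ends after it
      if (tend[id] <= present) return(NULL)
      tip_state_out[length(tip_state_out) + 1L] <<- state_at(id, present)
      return(list(str = sprintf("@%d", length(tip_state_out)),
                  len = present - birth[id], n = 1L))
    }
    len <- tend[id] - birth[id]
    l <- rec(c1[id]); r <- rec(c2[id])
    if (is.null(l) && is.null(r)) return(NULL)
    if (is.null(l)) { r$len <- r$len + len; return(r) }
    if (is.null(r)) { l$len <- l$len + len; return(l) }
    node_ages_out <<- c(node_ages_out, present - tend[id])
    list(
      str = sprintf("(%s:%.12g,%s:%.12g)s%d", l$str, l$len, r$str, r$len,
                    state[id]),
      len = len, n = l$n + r$n
    )
  }
  res <- rec(root)
  if (is.null(res) || res$n < 2L) return(NULL)
  # stable tip labels in emission order
  str <- res$str
  for (k in seq_along(tip_state_out)) {
    str <- sub(sprintf("@%d:", k), sprintf("t%d:", k), str, fixed = TRUE)
  }
  phy <- ape::read.tree(text = paste0(str, ";"))
  tip_states <- setNames(tip_state_out,
                         sprintf("t%d", seq_along(tip_state_out)))[phy$tip.label]
  nodest <- as.integer(sub("^s", "", phy$node.label))
  phy$node.label <- NULL
  list(
    phy = phy,
    tip_states = tip_states,
    node_states = setNames(nodest, ape::Ntip(phy) + seq_len(phy$Nnode)),
    event_ages = sort(node_ages_out, decreasing = TRUE),
    present = present,
    n_time = n_time
  )
}

# Conditioned simulation with rejection. Under "gsa" a realisation must be
# drawn with probability proportional to its total time spent at size n
# (realisations that merely pass through n quickly carry less of the
# conditional law); this is done by importance resampling within batches of
# `weight_batch` successful realisations.
sim_sse_conditioned <- function(n, t_max, lambda, mu, q, root_state,
                                max_retries = 10000L,
                                method = "first_passage",
                                weight_batch = 16L) {
  retries <- 0L
  draw <- function() {
    repeat {
      res <- sim_sse_once(n = n, t_max = t_max, lambda = lambda, mu = mu,
                          q = q, root_state = root_state, method = method)
      ok <- !is.null(res) && (is.null(n) || ape::Ntip(res$phy) == n)
      if (ok) return(res)
      retries <<- retries + 1L
      if (retries > max_retries) {
        abort(sprintf(
          "simulation failed to meet the stopping condition after %d retries",
          max_retries))
      }
    }
  }
  if (method == "gsa" && !is.null(n)) {
    batch <- replicate(weight_batch, draw(), simplify = FALSE)
    w <- vapply(batch, `[[`, numeric(1), "n_time")
    res <- batch[[sample.int(weight_batch, 1L, prob = w)]]
  } else {
    res <- draw()
  }
  res$retries <- retries
  res
}

#' Simulate a Yule (pure-birth) tree
#'
#' Crown-conditioned constant-rate pure-birth simulation. While `k` lineages
#' exist the waiting time to the next speciation is Exponential(k * lambda);
#' after the n-th lineage arises the interval to the present is drawn as the
#' waiting time to the next (unobserved) event, Exponential(n * lambda)
#' (`final_segment = "exponential"`), or set to zero
#' (`final_segment = "at_birth"`).
#'
#' @param n Number of tips (>= 2). Exactly one of `n`, `t_max` must be given.
#' @param lambda Speciation rate (events / lineage / Myr), > 0.
#' @param seed Optional integer seed; fixed seed gives byte-identical output.
#' @param t_max Simulate for a fixed time span instead of to a fixed size.
#' @param final_segment Convention for the interval between the last
#'   recorded speciation and the present (size-stopped simulations only).
#' @return A dated ultrametric `phylo`. Attribute `event_ages` records the
#'   simulator's own branching-event ages (backward from the present).
#' @examples
#' phy <- sim_yule(n = 10, lambda = 0.5, seed = 1)
#' branching_times(phy)
#' @export
sim_yule <- function(n = NULL, lambda, seed = NULL, t_max = NULL,
                     final_segment = c("exponential", "at_birth")) {
  final_segment <- match.arg(final_segment)
  if (is.null(n) == is.null(t_max)) abort("give exactly one of `n`, `t_max`")
  if (!is.null(n) && n < 2) abort("`n` must be >= 2")
  if (lambda <= 0) abort("`lambda` must be > 0")
  with_seed(seed, {
    res <- sim_sse_conditioned(n, t_max, lambda = c(lambda, lambda),
                               mu = c(0, 0), q = c(0, 0), root_state = 0L)
    phy <- res$phy
    if (!is.null(n) && final_segment == "at_birth") {
      # trim the final exponential segment back to the n-th birth
      last <- min(res$event_ages)   # age of the youngest speciation
      tip_edges <- phy$edge[, 2] <= ape::Ntip(phy)
      phy$edge.length[tip_edges] <- pmax(phy$edge.length[tip_edges] - last, 0)
      res$event_ages <- res$event_ages - last
    }
    attr(phy, "event_ages") <- res$event_ages
    attr(phy, "retries") <- res$retries
    phy
  })
}

#' Simulate a constant-rate birth-death tree
#'
#' Forward Gillespie simulation conditioned on `n` surviving tips: the
#' process runs until it dies out or safely exceeds `n`, the "present" is
#' drawn among all time intervals during which exactly `n` lineages were
#' alive (the general sampling approach), and realisations that never reach
#' `n` are rejected and retried. Extinct lineages are pruned, so the
#' returned tree is the reconstructed tree of the lineages alive at the
#' sampled present.
#'
#' @inheritParams sim_yule
#' @param mu Extinction rate, with `lambda > mu >= 0`.
#' @param max_retries Rejection-sampling cap.
#' @return A dated `phylo`; attribute `retries` counts rejected attempts.
#' @export
sim_bd <- function(n, lambda, mu, seed = NULL, max_retries = 10000L) {
  if (n < 2) abort("`n` must be >= 2")
  if (mu < 0 || lambda <= mu) abort("need `lambda > mu >= 0`")
  with_seed(seed, {
    res <- sim_sse_conditioned(n, NULL, lambda = c(lambda, lambda),
                               mu = c(mu, mu), q = c(0, 0), root_state = 0L,
                               max_retries = max_retries, method = "gsa")
    phy <- res$phy
    attr(phy, "event_ages") <- res$event_ages
    attr(phy, "retries") <- res$retries
    phy
  })
}

#' Simulate a tree and binary character under the BiSSE process
#'
#' Per-lineage Gillespie simulation with state-dependent speciation
#' (`lambda`), extinction (`mu`) and state-flip (`q`) events, conditioned on
#' `n` surviving tips by rejection. True states are recorded at every
#' surviving node so that parameter- and ancestral-state-recovery can be
#' scored against the truth.
#'
#' @param pars Named numeric vector with entries `lambdaO`, `lambdaS`,
#'   `muO`, `muS`, `qOS`, `qSO` (state 0 = "O" outcrossing, 1 = "S" selfing).
#' @param n Number of surviving tips to condition on.
#' @param root_state `0`, `1`, `"equal"` (Bernoulli(0.5)) or `"stationary"`
#'   (Bernoulli at the transition process' stationary frequency).
#' @inheritParams sim_bd
#' @return A list with `phy` (dated `phylo`), `tip_states` (tibble:
#'   `species`, `state`), `node_states` (integer vector named by ape node
#'   number), `event_ages` and `retries`.
#' @export
sim_bisse <- function(pars, n, seed = NULL, root_state = 0L, max_retries = 10000L) {
  pars <- validate_bisse_pars(pars)
  if (all(pars == 0)) abort("all six rates are zero")
  with_seed(seed, {
    rs <- root_state
    if (identical(rs, "equal")) rs <- sample(0:1, 1)
    if (identical(rs, "stationary")) {
      s <- pars[["qOS"]] + pars[["qSO"]]
      p1 <- if (s > 0) pars[["qOS"]] / s else 0.5
      rs <- stats::rbinom(1, 1, p1)
    }
    res <- sim_sse_conditioned(
      n, NULL,
      lambda = c(pars[["lambdaO"]], pars[["lambdaS"]]),
      mu = c(pars[["muO"]], pars[["muS"]]),
      q = c(pars[["qOS"]], pars[["qSO"]]),
      root_state = as.integer(rs), max_retries = max_retries, method = "gsa"
    )
    list(
      phy = res$phy,
      tip_states = tibble::tibble(species = res$phy$tip.label,
                                  state = as.integer(res$tip_states)),
      node_states = res$node_states,
      event_ages = res$event_ages,
      retries = res$retries
    )
  })
}

validate_bisse_pars <- function(pars) {
  nm <- c("lambdaO", "lambdaS", "muO", "muS", "qOS", "qSO")
  if (is.null(names(pars))) names(pars) <- nm[seq_along(pars)]
  if (!all(nm %in% names(pars))) {
    abort(paste("`pars` must carry", paste(nm, collapse = ", ")))
  }
  pars <- pars[nm]
  if (any(!is.finite(pars)) || any(pars < 0)) abort("all six rates must be finite and >= 0")
  pars
}

#' Simulate a binary character on a fixed tree (Mk2)
#'
#' Evolves a two-state continuous-time Markov chain with forward rate `q01`
#' and backward rate `q10` down every branch of a dated tree, returning both
#' tip states and the true internal-node states.
#'
#' @param phy A dated `phylo`.
#' @param q01,q10 Transition rates (/Myr), >= 0.
#' @param root_prior `"equal"`, `"stationary"`, or a fixed state (0/1).
#' @inheritParams sim_yule
#' @return List with `tip_states` (tibble `species`, `state`) and
#'   `node_states` (integer vector named by ape node number).
#' @export
sim_mk2 <- function(phy, q01, q10, root_prior = "equal", seed = NULL) {
  validate_tree(phy)
  if (q01 < 0 || q10 < 0) abort("rates must be >= 0")
  with_seed(seed, {
    ntip <- ape::Ntip(phy)
    root <- ntip + 1L
    states <- integer(ntip + phy$Nnode)
    states[root] <- if (identical(root_prior, "equal")) {
      sample(0:1, 1)
    } else if (identical(root_prior, "stationary")) {
      s <- q01 + q10
      stats::rbinom(1, 1, if (s > 0) q01 / s else 0.5)
    } else as.integer(root_prior)
    q <- c(q01, q10)  # away-rate from state 0, 1
    ord <- ape::reorder.phylo(phy, "cladewise")  # parents before children
    for (e in seq_len(nrow(ord$edge))) {
      p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
      len <- ord$edge.length[e]
      s <- states[p]; remaining <- len
      repeat {
        rate <- q[s + 1L]
        if (rate <= 0) break
        w <- rexp(1, rate)
        if (w >= remaining) break
        remaining <- remaining - w
        s <- 1L - s
      }
      states[ch] <- s
    }
    list(
      tip_states = tibble::tibble(species = phy$tip.label,
                                  state = states[seq_len(ntip)]),
      node_states = setNames(states[(ntip + 1L):(ntip + phy$Nnode)],
                             (ntip + 1L):(ntip + phy$Nnode))
    )
  })
}

# fast path used by the delta-AIC null: Yule branching times without
# building a phylo (law identical to sim_yule's size-stopped convention)
yule_branching_times_sim <- function(n, lambda) {
  w <- rexp(n - 1L, lambda * (2:n))
  present <- sum(w)
  ages <- present - cumsum(c(0, w[-(n - 1L)]))
  sort(ages, decreasing = TRUE)
}

#' Synthetic clade-C-like study dataset
#'
#' Emulates the study conditions: a posterior-like sample of dated 30-tip
#' trees sharing one true topology (branch lengths jittered log-normally,
#' crown age jittered around 5.3 Myr) and one tip-state table with 8
#' selfing (state 1) species and 2 species coded missing. The base tree and
#' true character history are simulated under the irreversible two-parameter
#' BiSSE regime (`lambdaO = 0.68`, `qOS = 0.21`, all other rates 0),
#' re-drawn until exactly 8 of the 30 tips are selfing; the 2 missing
#' entries are drawn from the outcrossing tips so the observed composition
#' is 20 / 8 / 2.
#'
#' @param seed Integer seed.
#' @param n_trees Number of jittered trees in the sample (study scale: 1000).
#' @param crown_age_myr Median crown age of the sample.
#' @param crown_log_sd Log-scale SD of the crown-age jitter (0.29 reproduces
#'   a 95% interval of roughly 2.7-8.5 Myr around 5.3).
#' @param node_log_sd Log-scale SD of the per-node age jitter
#'   (rank-preserving, so every tree keeps the shared topology and stays
#'   ultrametric).
#' @return List with `trees` (list of `phylo`), `tip_states` (tibble
#'   `species`, `state` with `NA` = missing), `base_tree`, and `truth`
#'   (the fully observed simulated states).
#' @export
sim_clade_c_like <- function(seed = 1, n_trees = 1000,
                             crown_age_myr = 5.3, crown_log_sd = 0.29,
                             node_log_sd = 0.1) {
  pars <- c(lambdaO = 0.68, lambdaS = 0, muO = 0, muS = 0, qOS = 0.21, qSO = 0)
  with_seed(seed, {
    base <- NULL
    for (i in 1:2000) {
      cand <- sim_bisse(pars, n = 30)
      if (sum(cand$tip_states$state == 1L) == 8L) { base <- cand; break }
    }
    if (is.null(base)) abort("failed to draw a 30-tip history with 8 derived tips")
    phy <- base$phy
    phy$edge.length <- phy$edge.length * (crown_age_myr / crown_age(phy))
    tips <- base$tip_states
    missing_idx <- sample(which(tips$state == 0L), 2L)
    observed <- tips
    observed$state[missing_idx] <- NA_integer_
    trees <- lapply(seq_len(n_trees), function(i) {
      jitter_node_ages(phy, crown_age_myr, crown_log_sd, node_log_sd)
    })
    list(
      trees = trees,
      tip_states = observed,
      base_tree = phy,
      truth = list(tip_states = tips, node_states = base$node_states)
    )
  })
}

# multiplicative, rank-preserving jitter of internal-node ages;
# output is ultrametric with the same topology
jitter_node_ages <- function(phy, crown_age_myr, crown_log_sd, node_log_sd) {
  ntip <- ape::Ntip(phy)
  ages <- node_ages(phy)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  a <- ages[nodes]
  prop <- a * exp(rnorm(length(a), 0, node_log_sd))
  # reassign jittered values in rank order so ancestor > descendant survives
  new_a <- numeric(length(a))
  new_a[order(a, decreasing = TRUE)] <- sort(prop, decreasing = TRUE)
  new_a <- new_a * (crown_age_myr * exp(rnorm(1, 0, crown_log_sd)) / max(new_a))
  full <- c(rep(0, ntip), new_a)
  out <- phy
  out$edge.length <- full[phy$edge[, 1]] - full[phy$edge[, 2]]
  out
}
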