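# Mating-type coding, Bayes-factor monophyly statistics, transition
# counting, and the end-to-end study workflow.

#' Code mating types as a binary character ("any instance" rule)
#'
#' A species is scored as derived (state 1, "selfing") if the derived
#' condition occurs in any sampled individual: `Dimorphic` and `Trimorphic`
#' species map to 1, `Outcrossing` (fixed ancestral state) to 0, and
#' `Unknown` to missing (`NA`).
#'
#' @param table A data frame with columns `species` and `mating_type`
#'   (values in `Outcrossing`, `Dimorphic`, `Trimorphic`, `Unknown`).
#' @return Tibble with `species` and `state` (integer 0/1/`NA`).
#' @examples
#' code_any_instance(clade_c_mating_types()) |> dplyr::count(state)
#' @export
code_any_instance <- function(table) {
  if (!all(c("species", "mating_type") %in% names(table))) {
    abort("`table` needs columns `species` and `mating_type`")
  }
  if (!nrow(table)) abort("`table` is empty")
  if (anyDuplicated(table$species)) abort("duplicate species names")
  allowed <- c("Outcrossing", "Dimorphic", "Trimorphic", "Unknown")
  bad <- setdiff(unique(table$mating_type), allowed)
  if (length(bad)) {
    abort(paste("unrecognized mating-type categories:", paste(bad, collapse = ", ")))
  }
  tibble::tibble(
    species = table$species,
    state = dplyr::case_when(
      table$mating_type == "Outcrossing" ~ 0L,
      table$mating_type %in% c("Dimorphic", "Trimorphic") ~ 1L,
      TRUE ~ NA_integer_
    )
  )
}

#' Bayes-factor statistic for a monophyly constraint
#'
#' Evidence against a topology-constrained model from marginal log tree
#' likelihoods. The default `rule = "difference"` computes
#' `lnL_unconstrained - lnL_constrained`, the arithmetic that reproduces
#' the published statistic column; `rule = "twice"` applies the literal
#' `2 x` reading. Evidence bands: `<= 2` none, `(2, 6]` positive,
#' `(6, 10]` strong, `> 10` very strong.
#'
#' @param loglik_unconstrained,loglik_constrained Marginal log likelihoods
#'   (finite).
#' @param rule `"difference"` (default) or `"twice"`.
#' @return Tibble with `statistic` and `evidence`.
#' @examples
#' bf_statistic(-15887.6, -16371.7)  # 484.1, very strong
#' @export
bf_statistic <- function(loglik_unconstrained, loglik_constrained,
                         rule = c("difference", "twice")) {
  rule <- match.arg(rule)
  if (!is.finite(loglik_unconstrained) || !is.finite(loglik_constrained)) {
    abort("marginal log likelihoods must be finite")
  }
  stat <- loglik_unconstrained - loglik_constrained
  if (rule == "twice") stat <- 2 * stat
  if (stat < 0) warn("constrained model has the higher marginal likelihood")
  evidence <- if (stat <= 2) "none" else if (stat <= 6) "positive" else
    if (stat <= 10) "strong" else "very strong"
  tibble::tibble(statistic = stat, evidence = evidence)
}

#' Count character transitions implied by an ancestral reconstruction
#'
#' Assigns every node and tip its modal state (probability > 0.5; exact
#' ties resolve to the ancestral state 0 and are flagged) and counts
#' parent-to-child edges whose modal states differ, split by direction.
#' Missing tips take their reconstruction-imputed modal state
#' (`missing = "impute"`, requires tip rows in `asr`); `missing = "strict"`
#' excludes their pendant edges instead.
#'
#' @param asr An `asr_states` tibble for `phy` (internal nodes, plus tip
#'   rows for missing tips when imputing).
#' @param tips Tip states used in the reconstruction.
#' @param phy The tree the reconstruction lives on.
#' @param missing `"impute"` or `"strict"`.
#' @return Tibble with `gains` (0 to 1), `losses` (1 to 0), `n_tied_nodes`.
#' @export
count_transitions <- function(asr, tips, phy, missing = c("impute", "strict")) {
  missing <- match.arg(missing)
  states <- resolve_tip_states(phy, tips)
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  modal <- rep(NA_integer_, nn)
  modal[seq_len(ntip)] <- states
  node_rows <- asr[asr$node > ntip, ]
  if (!all((ntip + 1L):nn %in% node_rows$node)) {
    abort("`asr` must cover every internal node")
  }
  ties <- 0L
  for (i in seq_len(nrow(asr))) {
    nd <- asr$node[i]
    p1 <- asr$p1[i]
    if (!is.na(modal[nd]) && nd <= ntip) next  # observed tip wins
    if (p1 == 0.5) { modal[nd] <- 0L; ties <- ties + 1L }
    else modal[nd] <- as.integer(p1 > 0.5)
  }
  if (ties > 0) warn(sprintf("%d node(s) at probability exactly 0.5: tie rule (ancestral state) applied", ties))
  drop_tip <- rep(FALSE, nn)
  if (missing == "strict") drop_tip[which(is.na(states))] <- TRUE
  gains <- 0L; losses <- 0L
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    if (ch <= ntip && drop_tip[ch]) next
    sp <- modal[p]; sc <- modal[ch]
    if (is.na(sp) || is.na(sc)) {
      if (missing == "strict") next
      abort("modal state unavailable for an edge endpoint; provide imputed tip rows in `asr`")
    }
    if (sp == 0L && sc == 1L) gains <- gains + 1L
    if (sp == 1L && sc == 0L) losses <- losses + 1L
  }
  tibble::tibble(gains = gains, losses = losses, n_tied_nodes = ties)
}

#' Run the full study workflow
#'
#' Orchestrates the complete analysis on a tree sample plus tip-state
#' table: any-instance coding (if raw mating types are given),
#' lineage-through-time data, the six-model diversification table and
#' delta-AIC_RC test on a reference chronogram, the thirteen-model BiSSE
#' suite, Mk2 ML fit and MCMC, marginal ancestral states under both Mk2 and
#' the best BiSSE model (averaged over the sample onto the reference tree),
#' transition counts, and Bayes-factor statistics from supplied marginal
#' likelihoods. Results are returned as a list of tibbles and, if
#' `out_dir` is given, written as TSV files plus a JSON manifest.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `trees` (list of `phylo`, or a NEXUS/newick file path), `tip_states`
#'   (tibble/TSV path with `species` + `state`, or `mating_types` with raw
#'   categories), `seed` (integer), and optional `reference_tree`,
#'   `daicrc_reps` (0 skips the test), `n_bisse_trees`, `n_mk2_trees`,
#'   `mcmc` (list passed to [mk2_mcmc()]; `NULL` skips), `marginal_likelihoods`
#'   (tibble with `constraint`, `marginal_log_likelihood`).
#' @param out_dir Optional output directory for TSV artifacts + manifest.
#' @return List of class `study_result` with elements `coding`, `ltt`,
#'   `diversification`, `daicrc`, `bisse_suite`, `bisse_asr`, `mk2_fit`,
#'   `mk2_mcmc`, `mk2_asr`, `transitions`, `bayes_factors`, `manifest`.
#' @export
run_study <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("study stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  trees <- stage("load-trees", {
    tr <- config$trees
    if (is.character(tr)) {
      tr <- if (grepl("\\.nex$", tr, ignore.case = TRUE)) {
        parse_nexus_trees(file = tr)
      } else {
        lapply(readLines(tr), parse_newick)
      }
    }
    if (inherits(tr, "phylo")) tr <- list(tr)
    tr
  })
  reference <- config$reference_tree %||% trees[[1]]
  coding <- stage("coding", {
    if (!is.null(config$mating_types)) {
      mt <- config$mating_types
      if (is.character(mt)) mt <- tibble::as_tibble(read.delim(mt))
      code_any_instance(mt)
    } else {
      ts <- config$tip_states
      if (is.character(ts)) ts <- tibble::as_tibble(read.delim(ts))
      tibble::as_tibble(ts)
    }
  })
  ltt <- stage("ltt", ltt_curve(reference))
  div <- stage("diversification", fit_diversification(reference))
  reps <- config$daicrc_reps %||% 200
  daicrc <- if (reps > 0) {
    stage("daicrc", daicrc_test(reference, reps = reps, seed = seed))
  } else NULL
  nb <- min(config$n_bisse_trees %||% length(trees), length(trees))
  suite <- stage("bisse-suite", bisse_model_suite(trees[seq_len(nb)], coding))
  best_name <- suite$table$model[1]
  best_fit <- suite$fits[[best_name]]
  best_pars <- setNames(
    vapply(bisse_par_names, function(p) {
      s <- best_fit$summary
      s$median[s$term == p]
    }, numeric(1)), bisse_par_names)
  bisse_asr <- stage("bisse-asr", {
    per_tree <- lapply(trees[seq_len(nb)], function(tr) {
      bisse_asr_marginal(tr, coding, best_pars)
    })
    asr_average(per_tree, reference)
  })
  mk2fit <- stage("mk2-fit", mk2_fit_ml(reference, coding))
  mcmc_cfg <- config$mcmc
  mk2mcmc <- if (!is.null(mcmc_cfg)) {
    nm <- min(config$n_mk2_trees %||% length(trees), length(trees))
    stage("mk2-mcmc", do.call(mk2_mcmc, c(
      list(trees = trees[seq_len(nm)], tips = coding, seed = seed), mcmc_cfg
    )))
  } else NULL
  mk2_asr <- stage("mk2-asr", {
    nm <- min(config$n_mk2_trees %||% length(trees), length(trees))
    per_tree <- lapply(trees[seq_len(nm)], function(tr) {
      mk2_asr_marginal(tr, coding, mk2fit$q01, mk2fit$q10)
    })
    asr_average(per_tree, reference)
  })
  transitions <- stage("transitions", {
    # impute missing tips from the BiSSE reconstruction on the reference tree
    ref_asr <- bisse_asr_marginal(reference, coding, best_pars)
    count_transitions(ref_asr, coding, reference)
  })
  bf <- if (!is.null(config$marginal_likelihoods)) {
    stage("bayes-factors", {
      ml <- config$marginal_likelihoods
      if (is.character(ml)) ml <- tibble::as_tibble(read.delim(ml))
      base <- ml$marginal_log_likelihood[ml$constraint == "none"]
      if (!length(base)) abort("need an unconstrained ('none') marginal likelihood")
      rows <- ml[ml$constraint != "none", ]
      dplyr::bind_cols(
        tibble::tibble(constraint = rows$constraint),
        purrr::map_dfr(rows$marginal_log_likelihood,
                       function(l) bf_statistic(base, l))
      )
    })
  } else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("selfsse")),
    seed = seed,
    n_trees = length(trees),
    n_bisse_trees = nb,
    daicrc_reps = reps,
    daicrc_skipped = reps == 0,
    mcmc_skipped = is.null(mcmc_cfg),
    best_bisse_model = best_name,
    timestamp = NA  # fixed field kept NA so identical configs give identical bytes
  )
  out <- list(
    coding = coding, ltt = ltt, diversification = div, daicrc = daicrc,
    bisse_suite = suite, bisse_asr = bisse_asr, mk2_fit = mk2fit,
    mk2_mcmc = mk2mcmc, mk2_asr = mk2_asr, transitions = transitions,
    bayes_factors = bf, manifest = manifest
  )
  class(out) <- "study_result"
  if (!is.null(out_dir)) write_study_result(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_study_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(as.data.frame(df), file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(res$coding, "coding")
  wr(res$ltt, "ltt")
  wr(res$diversification, "diversification")
  if (!is.null(res$daicrc)) wr(tidy(res$daicrc), "daicrc")
  wr(res$bisse_suite$table, "bisse_models")
  wr(res$bisse_asr, "bisse_asr")
  wr(glance(res$mk2_fit), "mk2_fit")
  if (!is.null(res$mk2_mcmc)) wr(posterior_samples(res$mk2_mcmc), "mk2_posterior")
  wr(res$mk2_asr, "mk2_asr")
  wr(res$transitions, "transitions")
  wr(res$bayes_factors, "bayes_factors")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study workflow result\n")
  cat(sprintf("  coding: %d species (%d derived, %d missing)\n",
              nrow(x$coding), sum(x$coding$state == 1L, na.rm = TRUE),
              sum(is.na(x$coding$state))))
  cat(sprintf("  best diversification model: %s\n",
              x$diversification$model[which.min(x$diversification$aic)]))
  if (!is.null(x$daicrc)) {
    cat(sprintf("  delta-AIC_RC = %.3f (p = %.3f)\n",
                x$daicrc$statistic, x$daicrc$p_value))
  }
  cat(sprintf("  best BiSSE model: %s\n", x$manifest$best_bisse_model))
  cat(sprintf("  transitions to selfing: %d (losses: %d)\n",
              x$transitions$gains, x$transitions$losses))
  invisible(x)
}
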