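#' Parse trees from newick or NEXUS text
#'
#' Thin wrappers around ape's parsers that validate the result against the
#' package's expectations for dated trees. `parse_newick()` reads a single
#' newick string; `parse_nexus_trees()` reads every tree of a NEXUS TREES
#' block (TRANSLATE tables are resolved, square-bracket comments ignored).
#'
#' @param text A newick string (for `parse_newick`) or the full text of a
#'   NEXUS file (for `parse_nexus_trees`). Alternatively `file` may name a
#'   file to read.
#' @param file Optional path read instead of `text`.
#' @return `parse_newick()`: a `phylo`; `parse_nexus_trees()`: a list of
#'   `phylo` objects (possibly empty) in file order.
#' @examples
#' phy <- parse_newick("((A:1,B:1):1,C:2);")
#' crown_age(phy)
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file), collapse = "")
  check_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("newick parse error: ", conditionMessage(e)))
  )
  if (is.null(phy)) abort("newick parse error: unreadable tree string")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  phy
}

# cheap structural pre-check so malformed input errors carry a character offset
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("newick parse error: unmatched ')' at character offset %d", i))
      }
    }
  }
  if (depth != 0L) {
    abort(sprintf(
      "newick parse error: %d unclosed '(' by character offset %d",
      depth, length(chars)
    ))
  }
  invisible(TRUE)
}

#' @rdname parse_newick
#' @export
parse_nexus_trees <- function(text = NULL, file = NULL) {
  if (is.null(file)) {
    file <- tempfile(fileext = ".nex")
    on.exit(unlink(file))
    writeLines(text, file)
    text_lines <- text
  } else {
    text_lines <- readLines(file)
  }
  body <- paste(text_lines, collapse = "\n")
  if (!grepl("begin\\s+trees", body, ignore.case = TRUE)) {
    abort("NEXUS format error: no TREES block found")
  }
  if (!grepl("\\btree\\b[^;]*=", body, ignore.case = TRUE)) {
    return(list())
  }
  trees <- ape::read.nexus(file)
  if (inherits(trees, "phylo")) return(list(trees))
  # [[ decompresses shared tip labels that read.nexus stores at sample level
  lapply(seq_along(trees), function(i) trees[[i]])
}

#' Write trees
#'
#' `write_newick()` serialises one tree (or several, one per line);
#' `write_nexus_trees()` writes a NEXUS TREES block with a TRANSLATE table.
#'
#' @param phy A `phylo` or list of `phylo`.
#' @param file Optional output path; if `NULL` the newick string(s) are
#'   returned invisibly-visible as a character vector.
#' @return `write_newick()`: character vector of newick strings (invisibly if
#'   written to a file).
#' @export
write_newick <- function(phy, file = NULL) {
  if (inherits(phy, "phylo")) phy <- list(phy)
  out <- vapply(phy, function(p) ape::write.tree(p, digits = 14), character(1))
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' @rdname write_newick
#' @export
write_nexus_trees <- function(phy, file) {
  if (inherits(phy, "phylo")) phy <- list(phy)
  class(phy) <- "multiPhylo"
  ape::write.nexus(phy, file = file, translate = TRUE)
  invisible(file)
}

#' Node ages and crown age of a dated tree
#'
#' Ages are measured backward from the present in the tree's time unit
#' (Myr throughout the package); tips of an ultrametric tree sit at age 0.
#'
#' @param phy A rooted `phylo` with branch lengths.
#' @return `node_ages()`: numeric vector over all nodes (tips first, then
#'   internal nodes, in ape's numbering); `crown_age()`: the root age.
#' @export
node_ages <- function(phy) {
  depths <- ape::node.depth.edgelength(phy)
  max(depths) - depths
}

#' @rdname node_ages
#' @export
crown_age <- function(phy) {
  node_ages(phy)[ape::Ntip(phy) + 1L]
}

#' Validate a dated (ultrametric) tree
#'
#' Checks the structural invariants required by the likelihood machinery:
#' a single root, at least two children per internal node, finite
#' non-negative branch lengths, unique non-empty tip labels, and (relative
#' to crown age) ultrametricity of the tips.
#'
#' @param phy A `phylo`.
#' @param ultrametric Require tips at age 0 (within `tol` * crown age).
#' @param tol Relative ultrametricity tolerance. Trees beyond it are
#'   rejected, never silently re-scaled.
#' @return `phy`, invisibly, if valid; otherwise an error.
#' @export
validate_tree <- function(phy, ultrametric = TRUE, tol = 1e-6) {
  if (!inherits(phy, "phylo")) abort("`phy` must be a `phylo` object")
  if (is.null(phy$edge.length)) abort("tree has no branch lengths")
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0)) {
    abort("branch lengths must be finite and >= 0")
  }
  labs <- phy$tip.label
  if (anyDuplicated(labs)) abort("duplicate tip names")
  if (any(!nzchar(labs))) abort("empty tip names")
  tab <- tabulate(phy$edge[, 1], nbins = ape::Ntip(phy) + phy$Nnode)
  internal <- (ape::Ntip(phy) + 1L):(ape::Ntip(phy) + phy$Nnode)
  if (ape::Ntip(phy) >= 2 && any(tab[internal] < 2L)) {
    abort("internal nodes must have >= 2 children")
  }
  if (ultrametric && ape::Ntip(phy) >= 2) {
    ages <- node_ages(phy)
    tip_ages <- ages[seq_len(ape::Ntip(phy))]
    ca <- ages[ape::Ntip(phy) + 1L]
    if (ca <= 0) abort("crown age must be positive for a dated tree")
    if (max(abs(tip_ages)) > tol * ca) {
      abort(sprintf(
        "tree is not ultrametric: max tip age %.3g exceeds %.1g * crown age",
        max(abs(tip_ages)), tol
      ))
    }
  }
  invisible(phy)
}

#' Branching times of a dated tree
#'
#' The ages (backward from the present) of the internal nodes of the
#' reconstructed tree, sorted non-increasing, so the first entry is the
#' crown age. These are the sufficient statistics for all the
#' trait-independent diversification likelihoods.
#'
#' @param phy A dated ultrametric `phylo` with `N >= 2` tips.
#' @return Numeric vector of length `N - 1`, non-increasing.
#' @examples
#' branching_times(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
branching_times <- function(phy) {
  validate_tree(phy)
  if (ape::Ntip(phy) < 2) abort("branching times need at least 2 tips")
  bt <- sort(unname(ape::branching.times(phy)), decreasing = TRUE)
  if (any(bt <= 0)) abort("branching times must be strictly positive")
  bt
}

#' Lineage-through-time curve
#'
#' One row per distinct branching-event age, with the lineage count `k`
#' holding from that age until the next event. Simultaneous events (ages
#' within `tol`) are merged so `k` jumps by their multiplicity; the final
#' count equals the number of tips.
#'
#' @param phy A dated tree, or a numeric vector of branching times.
#' @param tol Absolute age tolerance for merging simultaneous events.
#' @return A tibble with columns `age` (descending), `lineages` and
#'   `log_lineages`, of class `ltt_curve`.
#' @export
ltt_curve <- function(phy, tol = 1e-12) {
  bt <- if (is.numeric(phy)) sort(phy, decreasing = TRUE) else branching_times(phy)
  n <- length(bt) + 1L
  groups <- cumsum(c(TRUE, diff(bt) < -tol))
  age <- tapply(bt, groups, max)
  mult <- tapply(bt, groups, length)
  k <- 1L + cumsum(as.integer(mult))
  out <- tibble::tibble(
    age = as.numeric(age),
    lineages = as.integer(k),
    log_lineages = log(k)
  )
  stopifnot(out$lineages[nrow(out)] == n)
  class(out) <- c("ltt_curve", class(out))
  out
}

#' @export
autoplot.ltt_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = -.data$age, y = .data$lineages)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time before present (Myr, negative scale)",
      y = "lineages (log scale)"
    ) +
    ggplot2::theme_minimal()
}

# ---- bipartitions ----------------------------------------------------------

#' Bipartition keys and index
#'
#' A bipartition is identified by the sorted set of tip names on its
#' descendant side; `bipartition_key()` canonicalises a tip-name vector and
#' `bipartition_index()` maps every internal node of a tree to its key.
#' These keys are how per-node quantities (ancestral-state probabilities)
#' are matched across trees of a posterior sample.
#'
#' @param tips Character vector of tip names.
#' @param phy A `phylo` with unique tip names.
#' @param include_root Include the root node's (trivial) bipartition.
#' @return `bipartition_key()`: a single string. `bipartition_index()`: a
#'   tibble with columns `node` (ape node number) and `bipartition`.
#' @export
bipartition_key <- function(tips) paste(sort(tips), collapse = "|")

#' @rdname bipartition_key
#' @export
bipartition_index <- function(phy, include_root = TRUE) {
  if (anyDuplicated(phy$tip.label)) abort("duplicate tip names")
  ntip <- ape::Ntip(phy)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  if (!include_root) nodes <- setdiff(nodes, ntip + 1L)
  desc <- node_tip_sets(phy)
  tibble::tibble(
    node = nodes,
    bipartition = vapply(nodes, function(nd) bipartition_key(desc[[nd]]), character(1))
  )
}

# tip-label sets below every node (list indexed by node number)
node_tip_sets <- function(phy) {
  ntip <- ape::Ntip(phy)
  phy <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Look up a bipartition in a tree
#'
#' @param index A tibble from [bipartition_index()].
#' @param tips Tip names of the queried descendant set.
#' @return The ape node number, or `NA_integer_` if the bipartition is
#'   absent from the tree.
#' @export
bipartition_lookup <- function(index, tips) {
  key <- bipartition_key(tips)
  hit <- match(key, index$bipartition)
  if (is.na(hit)) NA_integer_ else index$node[hit]
}
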