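BIG <- 1e9

# Sankoff-style small parsimony with unit costs on an unrooted tree
# (multifurcations allowed). Unknown tips are wildcards: every state has
# cost 0, so they never force a change.
sankoff_tables <- function(tree, tip_states, states) {
  n <- length(tree$tip.label)
  k <- length(states)
  up <- matrix(0, n + tree$Nnode, k)
  for (i in seq_len(n)) {
    st <- tip_states[tree$tip.label[i]]
    if (!is.na(st)) up[i, ] <- ifelse(states == st, 0, BIG)
  }
  post <- ape::reorder.phylo(tree, "postorder")
  children <- split(post$edge[, 2], post$edge[, 1])
  # a child edge contributes, for a parent in state s, the minimum over
  # child states of up[child] plus 1 when the state changes on the edge
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    contrib <- vapply(seq_len(k), function(s) {
      min(up[ch, s], min(up[ch, ]) + 1)
    }, numeric(1))
    up[p, ] <- up[p, ] + contrib
  }
  list(up = up, post = post, children = children, k = k, n = n)
}

#' Minimum state changes on a fixed tree (small parsimony)
#'
#' Counts the minimum number of discrete character-state changes needed to
#' explain the tip states on the tree (Fitch/Sankoff small parsimony with
#' unit costs, evaluated on the unrooted tree so the result is invariant to
#' rerooting). Tips with `NA` state are wildcards: they are compatible with
#' every state and never force a change. Branches are reported separately
#' as mandatory (a change lies on the branch in every most-parsimonious
#' reconstruction) or possible (a change lies there in at least one).
#'
#' @param tree An `ape::phylo` (or Newick string).
#' @param tip_states Named character vector (or factor) of tip states; `NA`
#'   or missing tips are wildcards.
#' @return Object of class `parsimony_fit`: `min_changes`,
#'   `change_branches` (tibble of mandatory-change branches described by
#'   the smaller tip side), `possible_branches` (branches carrying a change
#'   in some but not all reconstructions), `states`, `tree`, `tip_states`.
#' @export
fitch_min_changes <- function(tree, tip_states) {
  if (is.character(tree) && length(tree) == 1) tree <- read_newick(text = tree)
  if (is.null(tree$edge) || length(tree$tip.label) == 0) {
    abort("empty tree")
  }
  tip_states <- unlist_states(tip_states)
  known <- tip_states[!is.na(tip_states)]
  if (!length(known)) abort("at least one tip must have a known state")
  extra <- setdiff(names(tip_states), tree$tip.label)
  if (length(extra)) {
    abort(sprintf("state given for tip(s) not in tree: %s",
                  paste(extra, collapse = ", ")))
  }
  tree <- if (length(tree$tip.label) > 2) ape::unroot(tree) else tree
  states <- sort(unique(known))
  tip_states <- tip_states[tree$tip.label]
  names(tip_states) <- tree$tip.label
  tabs <- sankoff_tables(tree, tip_states, states)
  up <- tabs$up
  k <- tabs$k
  n <- tabs$n
  root <- n + 1L
  min_changes <- min(up[root, ])

  # second pass: dn[v, s] = min changes outside the subtree of v given v's
  # parent takes state s (edge (parent, v) excluded)
  pre <- ape::reorder.phylo(tree, "cladewise")
  parent_of <- integer(n + tree$Nnode)
  parent_of[pre$edge[, 2]] <- pre$edge[, 1]
  dn <- matrix(NA_real_, n + tree$Nnode, k)
  dn[root, ] <- 0
  edge_contrib <- function(child, s) min(up[child, s], min(up[child, ]) + 1)
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]; v <- pre$edge[e, 2]
    sibs <- setdiff(tabs$children[[as.character(p)]], v)
    # A[s]: best cost of everything outside subtree(v), parent at state s
    A <- vapply(seq_len(k), function(s) {
      base <- if (p == root) 0 else min(dn[p, s], min(dn[p, ]) + 1)
      base + sum(vapply(sibs, function(w) edge_contrib(w, s), numeric(1)))
    }, numeric(1))
    dn[v, ] <- A
  }

  # per-edge diagnostics: can the edge be change-free / change-bearing in
  # an optimal reconstruction?
  edges <- pre$edge
  no_change <- change <- numeric(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; v <- edges[e, 2]
    tot_same <- min(vapply(seq_len(k), function(s) dn[v, s] + up[v, s],
                           numeric(1)))
    tot_diff <- if (k == 1) Inf else min(vapply(seq_len(k), function(s) {
      dn[v, s] + min(up[v, -s]) + 1
    }, numeric(1)))
    no_change[e] <- tot_same
    change[e] <- tot_diff
  }
  desc <- tip_sets(tree)
  side_label <- vapply(edges[, 2], function(v) {
    side <- desc[[v]]
    if (length(side) > n / 2) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = ",")
  }, character(1))
  branch_tbl <- tibble(
    parent = edges[, 1], node = edges[, 2], tip_side = side_label,
    mandatory = no_change > min_changes & change <= min_changes,
    possible = change <= min_changes & no_change <= min_changes
  )
  structure(list(
    min_changes = as.integer(min_changes),
    change_branches = branch_tbl %>% filter(.data$mandatory) %>%
      select("parent", "node", "tip_side"),
    possible_branches = branch_tbl %>% filter(.data$possible) %>%
      select("parent", "node", "tip_side"),
    states = states, tree = tree, tip_states = tip_states
  ), class = "parsimony_fit")
}

unlist_states <- function(x) {
  x <- setNames(as.character(x), names(x))
  if (is.null(names(x))) abort("tip states must be named by tip label")
  x
}

#' @export
print.parsimony_fit <- function(x, ...) {
  cat(sprintf("<parsimony_fit> %d change(s), states: %s\n", x$min_changes,
              paste(x$states, collapse = ", ")))
  if (nrow(x$change_branches)) {
    cat("mandatory change on branch(es):\n")
    for (s in x$change_branches$tip_side) cat("  {", s, "}\n")
  }
  invisible(x)
}

#' Count distinct sex-chromosome identities
#'
#' @param tip_states Named character vector of per-species identity labels
#'   (`NA` = unknown).
#' @return Number of distinct non-missing identities (0 with a warning when
#'   everything is unknown).
#' @export
count_identities <- function(tip_states) {
  known <- unique(stats::na.omit(unlist_states(tip_states)))
  if (!length(known)) {
    warn("all identities unknown")
    return(0L)
  }
  length(known)
}

#' Minimum number of heterogamety shifts on a tree
#'
#' [fitch_min_changes()] restricted to the two-state XY/ZW character.
#'
#' @param tree An `ape::phylo` or Newick string.
#' @param heterogamety Named character vector of `"XY"`/`"ZW"` per tip
#'   (`NA` = unknown).
#' @return A `parsimony_fit`; its `min_changes` is the minimum shift count.
#' @export
heterogamety_shifts <- function(tree, heterogamety) {
  st <- unlist_states(heterogamety)
  bad <- setdiff(unique(stats::na.omit(st)), c("XY", "ZW"))
  if (length(bad)) {
    abort(sprintf("heterogamety states must be XY/ZW, got: %s",
                  paste(bad, collapse = ", ")))
  }
  fitch_min_changes(tree, st)
}

#' Worked example: sex-chromosome identities of nine torrent frog species
#'
#' The bundled example places the nine *Amolops* species on their published
#' two-clade phylogeny (branch lengths in millions of years, eastern and
#' western clades splitting about 31 My ago). Eight western-clade species
#' carry sex-linked markers homologous to chromosome 5; the single
#' eastern-clade species (*A. wuyiensis*) carries them on a different,
#' non-homologous chromosome. All nine are male-heterogametic.
#'
#' @return List with `tree` (`phylo`), `identities`, and `heterogamety`
#'   (named character vectors per tip).
#' @export
#' @examples
#' ex <- amolops_example()
#' fitch_min_changes(ex$tree, ex$identities)$min_changes  # 1 turnover
#' count_identities(ex$identities)                        # 2 identities
amolops_example <- function() {
  tree <- read_newick(text = paste0(
    "(A_wuyiensis:31,((A_chunganensis:18,(A_jinjiangensis:12,",
    "A_tuberodepressus:12):6):4,((A_lifanensis:14,A_loloensis:14):5,",
    "(A_mantzorum:15,(A_xinduqiao:8,A_sp:8):7):4):3):9);"
  ))
  species <- tree$tip.label
  identities <- setNames(
    if_else(species == "A_wuyiensis", "other", "chr5-homologous"), species
  )
  heterogamety <- setNames(rep("XY", length(species)), species)
  list(tree = tree, identities = identities, heterogamety = heterogamety)
}
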