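#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` the transition and
#' `Q` the transversion proportion over compared sites. Sites where either
#' sequence has a gap or ambiguity character are excluded pairwise.
#'
#' @param a,b Equal-length DNA strings.
#' @return Non-negative distance (0 iff the sequences are identical on the
#'   compared sites). Errors when the log arguments are non-positive
#'   (saturation) or no comparable sites remain.
#' @export
#' @examples
#' k2p_distance("AAAA", "AAAG")  # one transition in four sites
k2p_distance <- function(a, b) {
  m <- aln_matrix(c(x = a, y = b))
  ok <- m[1, ] %in% DNA_BASES & m[2, ] %in% DNA_BASES
  if (!any(ok)) abort("no comparable sites")
  diff <- ok & m[1, ] != m[2, ]
  ts <- diff & is_transition(m[1, ], m[2, ])
  k2p_from_props(sum(ts) / sum(ok), sum(diff & !ts) / sum(ok))
}

k2p_from_props <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0)) {
    abort("K2P distance undefined: sequences saturated")
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

# pairwise site classification matrices for an alignment: for every
# unordered taxon pair a row of indicators per site (comparable / transition
# / transversion), enabling distance computation under arbitrary bootstrap
# column weights by a single matrix product
pair_site_stats <- function(seqs) {
  m <- aln_matrix(seqs)
  n <- nrow(m)
  L <- ncol(m)
  valid <- matrix(m %in% DNA_BASES, n, L)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  ok <- ts <- tv <- matrix(0, np, L)
  for (p in seq_len(np)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    okp <- valid[i, ] & valid[j, ]
    diffp <- okp & m[i, ] != m[j, ]
    tsp <- diffp & is_transition(m[i, ], m[j, ])
    ok[p, ] <- okp
    ts[p, ] <- tsp
    tv[p, ] <- diffp & !tsp
  }
  list(pairs = pairs, ok = ok, ts = ts, tv = tv, labels = rownames(m),
       n_sites = L)
}

dist_from_stats <- function(st, weights) {
  nok <- as.vector(st$ok %*% weights)
  if (any(nok == 0)) abort("no comparable sites for some pair")
  P <- as.vector(st$ts %*% weights) / nok
  Q <- as.vector(st$tv %*% weights) / nok
  d <- k2p_from_props(P, Q)
  n <- length(st$labels)
  D <- matrix(0, n, n, dimnames = list(st$labels, st$labels))
  D[t(st$pairs)] <- d
  D[t(st$pairs[2:1, , drop = FALSE])] <- d
  D
}

#' Kimura two-parameter distance matrix
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
k2p_distance_matrix <- function(seqs) {
  dist_from_stats(pair_site_stats(seqs), rep(1, nchar(seqs[[1]])))
}

#' Neighbor-joining tree (Saitou--Nei agglomeration)
#'
#' Standard neighbor joining with a deterministic tie-break (among equal Q
#' values the pair whose lexicographically smallest member labels sort
#' first is joined). Negative branch lengths are clamped to zero with the
#' deficit moved to the sister edge, so path lengths between joined
#' neighbors are preserved. Internal edges of exactly zero length are
#' collapsed, so an all-zero matrix yields a star tree.
#'
#' @param D Symmetric numeric matrix with zero diagonal and row/col names.
#' @return An unrooted `ape::phylo`.
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) abort("distance matrix not symmetric")
  labels <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 2) abort("need at least two taxa")
  if (n == 2) {
    tr <- read_newick(text = sprintf("(%s:%f,%s:%f);", labels[1], D[1, 2] / 2,
                                     labels[2], D[1, 2] / 2))
    return(tr)
  }
  # cluster bookkeeping: ape tip ids 1..n, internal ids assigned after
  active <- seq_len(n)
  node_id <- seq_len(n)            # phylo node id per active cluster
  rep_label <- labels              # lexicographic representative per cluster
  W <- unname(D)
  next_node <- 2L * n - 2L         # internal ids count down; root ends n+1
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  id_of <- function(k) node_id[k]
  while (length(active) > 3) {
    m <- length(active)
    r <- rowSums(W)
    Qm <- (m - 2) * W - outer(r, r, `+`)
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # among Q ties prefer the closest pair, then lexicographic label order
    dv <- W[cand]
    cand <- cand[dv - min(dv) <= 1e-12 * max(1, abs(min(dv))), ,
                 drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(rep_label[ij[1]], rep_label[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- W[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    u <- next_node
    next_node <- next_node - 1L
    edges <- rbind(edges, c(u, node_id[i]), c(u, node_id[j]))
    lens <- c(lens, bi, bj)
    newd <- (W[i, ] + W[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    W <- rbind(cbind(W[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    node_id <- c(node_id[keep], u)
    rep_label <- c(rep_label[keep], min(rep_label[c(i, j)]))
    active <- seq_len(nrow(W))
  }
  # join the last three clusters at a central node
  root <- n + 1L
  stopifnot(next_node == root)
  d12 <- W[1, 2]; d13 <- W[1, 3]; d23 <- W[2, 3]
  b <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2,
         (d13 + d23 - d12) / 2)
  b <- pmax(b, 0)
  edges <- rbind(edges, cbind(root, node_id[1:3]))
  lens <- c(lens, b)
  tr <- structure(list(edge = edges, edge.length = lens,
                       tip.label = labels, Nnode = n - 2L),
                  class = "phylo", order = NULL)
  # distances between merged clusters can drift slightly negative through
  # the reduction formula; floor the resulting edges at zero
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr <- ape::reorder.phylo(tr, "cladewise")
  ape::di2multi(tr, tol = 1e-12)
}

# canonical bipartition keys of all internal (non-trivial) splits of a tree;
# the side not containing the alphabetically first taxon is the key
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  if (n < 4 || is.null(tree$edge) || tree$Nnode < 2) return(character(0))
  desc <- tip_sets(tree)
  keys <- character(0)
  for (node in (n + 2):(n + tree$Nnode)) {
    side <- desc[[node]]
    if (length(side) <= 1 || length(side) >= n - 1) next
    keys <- c(keys, split_key(side, tree$tip.label, anchor))
  }
  unique(keys)
}

split_key <- function(side, all_tips, anchor = sort(all_tips)[1]) {
  if (anchor %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "|")
}

# tip label sets below every node (index = node id)
tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Bootstrap supports for the splits of a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree for each
#' replicate, and reports for every internal bipartition of the
#' point-estimate tree the percentage of replicate trees containing it.
#' Deterministic given the seed and invariant to taxon input order
#' (bipartitions are canonically encoded).
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (or NULL to use the current RNG stream).
#' @param tree_builder Function mapping a named sequence vector to a
#'   `phylo`; the default builds a neighbor-joining tree on K2P distances.
#' @return List with `tree` (point estimate, supports written into
#'   `node.label`), `supports` (named numeric vector, percent, keyed by
#'   canonical split), `n_replicates`, `n_failed` (replicates dropped
#'   because a distance was undefined), and `zero_information` (TRUE when
#'   the alignment has no variable site).
#' @export
bootstrap_supports <- function(seqs, n_replicates = 100, seed = NULL,
                               tree_builder = NULL) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  seqs <- seqs[order(names(seqs))]
  L <- nchar(seqs[[1]])
  fast <- is.null(tree_builder)
  st <- if (fast) pair_site_stats(seqs) else NULL
  builder <- tree_builder %||% function(s) nj_tree(k2p_distance_matrix(s))
  point_tree <- if (fast) nj_tree(dist_from_stats(st, rep(1, L))) else
    builder(seqs)
  point_splits <- tree_splits(point_tree)
  counts <- setNames(numeric(length(point_splits)), point_splits)
  n_failed <- 0L
  with_seed_if(seed, {
    for (b in seq_len(n_replicates)) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      rep_tree <- tryCatch({
        if (fast) {
          nj_tree(dist_from_stats(st, w))
        } else {
          idx <- rep(seq_len(L), w)
          builder(vapply(strsplit(seqs, "", fixed = TRUE), function(s) {
            paste(s[idx], collapse = "")
          }, character(1)))
        }
      }, error = function(e) NULL)
      if (is.null(rep_tree)) {
        n_failed <- n_failed + 1L
        next
      }
      found <- tree_splits(rep_tree)
      hit <- point_splits %in% found
      counts[hit] <- counts[hit] + 1
    }
  })
  n_eff <- n_replicates - n_failed
  supports <- if (n_eff > 0) 100 * counts / n_eff else counts * NA_real_
  tree <- annotate_supports(point_tree, supports)
  var_sites <- apply(aln_matrix(seqs), 2, function(col) {
    length(unique(col[col %in% DNA_BASES])) > 1
  })
  list(tree = tree, supports = supports, n_replicates = n_replicates,
       n_failed = n_failed, zero_information = !any(var_sites))
}

annotate_supports <- function(tree, supports) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  desc <- tip_sets(tree)
  labs <- character(tree$Nnode)
  for (node in (n + 1):(n + tree$Nnode)) {
    if (node == n + 1) next
    side <- desc[[node]]
    if (length(side) <= 1 || length(side) >= n - 1) next
    key <- split_key(side, tree$tip.label, anchor)
    if (key %in% names(supports)) {
      labs[node - n] <- format(supports[[key]], digits = 3)
    }
  }
  tree$node.label <- labs
  tree
}

#' Classify a gene-tree topology as gametolog- or species-clustered
#'
#' On the unrooted tree, the genealogy is `gametolog_clustered` when the
#' Y-class tips, spanning at least two species, form one side of a
#' bipartition supported at or above the threshold (the signature of an
#' ancestral, non-recombining sex-determining region). It is
#' `species_clustered` when every species' tip set is monophyletic at or
#' above the threshold and at least one species contributes both X and Y
#' tips (the signature of ongoing X--Y recombination outside the ancestral
#' region). Anything else — including sub-threshold support — is
#' `unresolved`. Trivial splits (single tips or their complements) count as
#' supported at 100. Unphased tips can satisfy species clustering but never
#' gametolog clustering.
#'
#' @param tree An `ape::phylo` whose tips appear in `labels`.
#' @param labels Tibble with columns `label`, `species_id`, `allele_class`
#'   (`"X"`, `"Y"`, or `"unphased"`).
#' @param supports Named numeric vector of split supports (percent), as
#'   returned by [bootstrap_supports()]; `NULL` treats every split present
#'   in the tree as fully supported.
#' @param support_threshold Minimum percent support (default 50).
#' @return Object of class `topology_class` with fields `classification`,
#'   `gametolog_clustered`, `species_clustered`, `y_clade_support`,
#'   `species_supports`, `support_threshold`.
#' @export
classify_topology <- function(tree, labels, supports = NULL,
                              support_threshold = 50) {
  tips <- tree$tip.label
  labels <- labels %>% filter(.data$label %in% tips)
  if (!setequal(labels$label, tips)) {
    abort("labels must cover every tree tip")
  }
  if (n_distinct(labels$species_id) < 2) {
    abort("need tips from at least two species")
  }
  n <- length(tips)
  anchor <- sort(tips)[1]
  present <- tree_splits(tree)
  support_of <- function(side) {
    len <- length(side)
    if (len == 0 || len == n) return(NA_real_)
    if (len == 1 || len == n - 1) return(100)
    key <- split_key(side, tips, anchor)
    if (!key %in% present) return(NA_real_)
    if (is.null(supports)) return(100)
    if (key %in% names(supports)) supports[[key]] else NA_real_
  }
  y_tips <- labels$label[labels$allele_class == "Y"]
  y_species <- unique(labels$species_id[labels$allele_class == "Y"])
  y_support <- if (length(y_species) >= 2) support_of(y_tips) else NA_real_
  gametolog <- !is.na(y_support) && y_support >= support_threshold
  by_species <- split(labels$label, labels$species_id)
  sp_support <- vapply(by_species, support_of, numeric(1))
  has_both <- vapply(split(labels$allele_class, labels$species_id),
                     function(a) all(c("X", "Y") %in% a), logical(1))
  species_cl <- all(!is.na(sp_support) & sp_support >= support_threshold) &&
    any(has_both)
  if (gametolog && species_cl) {
    abort("internal error: topology satisfies both clustering patterns")
  }
  classification <- if (gametolog) "gametolog_clustered" else
    if (species_cl) "species_clustered" else "unresolved"
  structure(list(classification = classification,
                 gametolog_clustered = gametolog,
                 species_clustered = species_cl,
                 y_clade_support = y_support,
                 species_supports = sp_support,
                 support_threshold = support_threshold),
            class = "topology_class")
}

#' @export
print.topology_class <- function(x, ...) {
  cat(sprintf("<topology_class> %s (threshold %g%%)\n", x$classification,
              x$support_threshold))
  invisible(x)
}

#' Build (and classify) a gene tree from allele sequences
#'
#' Computes K2P distances, builds the neighbor-joining tree, bootstraps the
#' supports, and classifies the topology with [classify_topology()].
#' Externally estimated trees (e.g. maximum-likelihood trees computed with
#' another program) are accepted via `method = "external"` with `tree`
#' carrying percent supports as internal-node labels; unlabeled internal
#' nodes are taken at face value (treated as fully supported).
#'
#' @param alleles Tibble with columns `label`, `species_id`,
#'   `allele_class`, `sequence` (equal-length), e.g. from
#'   [simulate_gene_history()] or [retrieve_homologs()].
#' @param n_bootstrap Bootstrap replicates (default 100).
#' @param seed Integer seed for the bootstrap.
#' @param support_threshold Percent support required by the classifier.
#' @param method `"NJ"` (default) or `"external"`.
#' @param tree External `phylo` when `method = "external"`.
#' @return Object of class `gene_tree_result`: `tree`, `supports`,
#'   `classification`, `detail` (the `topology_class`), `method`,
#'   `support_threshold`, `labels`, `n_bootstrap`.
#' @export
build_gene_tree <- function(alleles, n_bootstrap = 100, seed = NULL,
                            support_threshold = 50,
                            method = c("NJ", "external"), tree = NULL) {
  method <- match.arg(method)
  if (anyDuplicated(alleles$label)) abort("allele labels must be unique")
  labels <- alleles %>% select("label", "species_id", "allele_class")
  if (method == "NJ") {
    seqs <- setNames(alleles$sequence, alleles$label)
    bs <- bootstrap_supports(seqs, n_replicates = n_bootstrap, seed = seed)
    tree <- bs$tree
    supports <- bs$supports
  } else {
    if (is.null(tree)) abort("method = 'external' needs a tree")
    supports <- external_supports(tree)
  }
  detail <- classify_topology(tree, labels, supports = supports,
                              support_threshold = support_threshold)
  structure(list(tree = tree, supports = supports,
                 classification = detail$classification, detail = detail,
                 method = method, support_threshold = support_threshold,
                 labels = labels, n_bootstrap = n_bootstrap),
            class = "gene_tree_result")
}

external_supports <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  desc <- tip_sets(tree)
  out <- numeric(0)
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  for (node in (n + 1):(n + tree$Nnode)) {
    side <- desc[[node]]
    if (length(side) <= 1 || length(side) >= n - 1) next
    key <- split_key(side, tree$tip.label, anchor)
    lab <- tree$node.label[node - n]
    val <- suppressWarnings(as.numeric(lab))
    out[key] <- if (is.na(val)) 100 else val
  }
  out
}

#' @export
print.gene_tree_result <- function(x, ...) {
  cat(sprintf("<gene_tree_result> %s tree, %d tips, %s\n", x$method,
              length(x$tree$tip.label), x$classification))
  invisible(x)
}

#' Retrieve cross-species homologs of a sex-linked locus
#'
#' Reconstructs the two haplotypes of every individual at the focal locus
#' (consensus with the called alleles substituted); in focal-species males
#' the haplotype carrying the validated sex-specific allele is labelled Y
#' and its partner X, focal females are X/X, and all other-species
#' haplotypes are `unphased` (X/Y is only assignable where sex linkage is
#' demonstrated). Homologous loci in the other species are found with the
#' built-in global matcher ([match_sequences()]), keeping each species'
#' best hit at `E <= evalue_cutoff`; species without a qualifying homolog
#' are omitted (recorded in the `omitted_species` attribute).
#'
#' @param locus_id Focal locus id.
#' @param focal_species Species id of the focal catalog.
#' @param catalogs Named list of [locus_catalog()]s (must include
#'   `focal_species`).
#' @param registry Sex registry covering all catalog samples.
#' @param sex_specific_allele,column The validated sex-specific allele and
#'   its 0-based column (from the screens); when absent, focal male
#'   haplotypes stay unphased.
#' @param evalue_cutoff Homology threshold (default 1e-20).
#' @param min_identity Minimum percent identity for the global matcher.
#' @param phasing Optional tibble (`species_id`, `locus_id`,
#'   `sex_specific_allele`, `column`) phasing X/Y in non-focal species where
#'   the homologous locus is itself a confirmed sex-linked marker (the
#'   trans-species case); other species stay `unphased`.
#' @return Allele tibble (`species_id`, `sample_id`, `sex`, `allele_class`,
#'   `label`, `sequence`, `locus_id`) usable with [build_gene_tree()].
#' @export
retrieve_homologs <- function(locus_id, focal_species, catalogs, registry,
                              sex_specific_allele = NULL, column = NULL,
                              evalue_cutoff = 1e-20, min_identity = 70,
                              phasing = NULL) {
  if (!focal_species %in% names(catalogs)) {
    abort("focal_species must name an element of catalogs")
  }
  focal <- catalogs[[focal_species]]
  cons <- setNames(focal$consensus$consensus, focal$consensus$locus_id)
  if (!locus_id %in% names(cons)) abort("locus not in focal catalog")
  rows <- list(haplotypes_at_locus(focal, locus_id, focal_species, registry,
                                   sex_specific_allele, column))
  omitted <- character(0)
  for (sp in setdiff(names(catalogs), focal_species)) {
    other <- catalogs[[sp]]
    other_cons <- setNames(other$consensus$consensus,
                           other$consensus$locus_id)
    same_len <- other_cons[nchar(other_cons) == nchar(cons[[locus_id]])]
    hits <- if (length(same_len)) {
      match_sequences(cons[locus_id], same_len, mode = "global",
                      min_identity = min_identity)
    } else {
      empty_hits()
    }
    hits <- hits %>% filter(.data$e_value <= evalue_cutoff)
    if (!nrow(hits)) {
      omitted <- c(omitted, sp)
      next
    }
    hom_id <- hits$subject_id[1]
    ph <- if (is.null(phasing)) NULL else {
      phasing %>% filter(.data$species_id == sp, .data$locus_id == hom_id)
    }
    rows[[length(rows) + 1L]] <- haplotypes_at_locus(
      other, hom_id, sp, registry,
      sex_specific_allele = if (!is.null(ph) && nrow(ph))
        ph$sex_specific_allele[1] else NULL,
      column = if (!is.null(ph) && nrow(ph)) ph$column[1] else NULL
    )
  }
  out <- bind_rows(rows)
  attr(out, "omitted_species") <- omitted
  out
}

haplotypes_at_locus <- function(catalog, locus_id, species_id, registry,
                                sex_specific_allele, column) {
  reg <- registry %>% filter(.data$sample_id %in% catalog$samples)
  cons <- catalog$consensus$consensus[catalog$consensus$locus_id == locus_id]
  gts <- catalog$snps %>%
    filter(.data$locus_id == !!locus_id, !is.na(.data$allele1))
  pres <- catalog$presence %>%
    filter(.data$locus_id == !!locus_id, .data$present)
  out <- list()
  for (sid in intersect(pres$sample_id, reg$sample_id)) {
    gt <- gts %>% filter(.data$sample_id == sid)
    h <- c(cons, cons)
    for (j in seq_len(nrow(gt))) {
      h[1] <- substitute_base(h[1], gt$column[j], gt$allele1[j])
      h[2] <- substitute_base(h[2], gt$column[j], gt$allele2[j])
    }
    sex <- as.character(reg$sex[reg$sample_id == sid])
    classes <- c("unphased", "unphased")
    if (!is.null(sex_specific_allele) && !is.null(column)) {
      at_col <- gt %>% filter(.data$column == !!column)
      if (nrow(at_col) == 1 && sex == "male" &&
          at_col$allele1 != at_col$allele2) {
        classes <- if (at_col$allele1 == sex_specific_allele) c("Y", "X")
                   else if (at_col$allele2 == sex_specific_allele) c("X", "Y")
                   else c("unphased", "unphased")
      } else if (sex == "female") {
        classes <- c("X", "X")
      }
    }
    out[[length(out) + 1L]] <- tibble(
      species_id = species_id, sample_id = sid, sex = sex,
      allele_class = classes,
      label = sprintf("%s|h%d|%s", sid, 1:2, classes),
      sequence = h, locus_id = locus_id
    )
  }
  bind_rows(out)
}

#' Build per-locus and concatenated multilocus gene trees
#'
#' Runs [build_gene_tree()] on each locus and, when at least two loci share
#' a common set of labels, on the concatenation of the per-locus alignments
#' over that shared set. With a single locus the concatenated analysis
#' equals the single-locus analysis exactly.
#'
#' @param allele_tables List of allele tibbles (one per locus).
#' @inheritParams build_gene_tree
#' @return List with `per_locus` (list of `gene_tree_result`) and
#'   `concatenated` (a `gene_tree_result`, or `NULL` when no label is
#'   shared across all loci, with a warning).
#' @export
build_multilocus_trees <- function(allele_tables, n_bootstrap = 100,
                                   seed = NULL, support_threshold = 50) {
  stopifnot(length(allele_tables) >= 1)
  per_locus <- purrr::imap(allele_tables, function(tab, i) {
    build_gene_tree(tab, n_bootstrap = n_bootstrap,
                    seed = if (is.null(seed)) NULL else seed + as.integer(i),
                    support_threshold = support_threshold)
  })
  shared <- Reduce(intersect, purrr::map(allele_tables, "label"))
  if (length(shared) < 3) {
    warn("fewer than three labels shared across loci; per-locus results only")
    return(list(per_locus = per_locus, concatenated = NULL))
  }
  concat <- allele_tables[[1]] %>%
    filter(.data$label %in% shared) %>%
    select("label", "species_id", "allele_class")
  concat$sequence <- purrr::map_chr(concat$label, function(lb) {
    paste(purrr::map_chr(allele_tables, function(tab) {
      tab$sequence[tab$label == lb]
    }), collapse = "")
  })
  concat$locus_id <- paste(
    purrr::map_chr(allele_tables, ~ .x$locus_id[1]), collapse = "+"
  )
  conc_res <- build_gene_tree(concat, n_bootstrap = n_bootstrap,
                              seed = seed,
                              support_threshold = support_threshold)
  list(per_locus = per_locus, concatenated = conc_res)
}
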