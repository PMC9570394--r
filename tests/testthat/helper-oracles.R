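# Independent oracles, written deliberately as naive loops so they share no
# code path with the package implementations they check.

# --- brute-force evaluation of the three screening predicates --------------

brute_force_screen <- function(catalog, registry, thresholds) {
  reg <- registry[registry$sample_id %in% catalog$samples, ]
  males <- reg$sample_id[reg$sex == "male"]
  females <- reg$sample_id[reg$sex == "female"]
  out <- list()
  sites <- unique(catalog$snps[, c("locus_id", "column")])
  for (r in seq_len(nrow(sites))) {
    lid <- sites$locus_id[r]; col <- sites$column[r]
    rows <- catalog$snps[catalog$snps$locus_id == lid &
                           catalog$snps$column == col, ]
    gt <- function(sid) {
      x <- rows[rows$sample_id == sid, ]
      if (nrow(x) == 0 || is.na(x$allele1)) NULL else c(x$allele1, x$allele2)
    }
    for (sys in c("XY", "ZW")) {
      het_sex <- if (sys == "XY") males else females
      hom_sex <- if (sys == "XY") females else males
      n_het <- n_hom <- g_het <- g_hom <- 0
      copies_het <- copies_hom <- character(0)
      for (s in het_sex) {
        g <- gt(s)
        if (is.null(g)) next
        g_het <- g_het + 1
        if (g[1] != g[2]) n_het <- n_het + 1
        copies_het <- c(copies_het, g)
      }
      for (s in hom_sex) {
        g <- gt(s)
        if (is.null(g)) next
        g_hom <- g_hom + 1
        if (g[1] == g[2]) n_hom <- n_hom + 1
        copies_hom <- c(copies_hom, g)
      }
      if (g_het < thresholds$min_genotyped_per_sex ||
          g_hom < thresholds$min_genotyped_per_sex) next
      het_ok <- (n_het / g_het >= thresholds$min_frac_het_heterogametic) &&
        (n_hom / g_hom >= thresholds$min_frac_hom_homogametic)
      if (het_ok) {
        out[[length(out) + 1]] <- data.frame(
          locus_id = lid, column = col, strategy = "heterozygosity",
          system = sys)
        limited <- setdiff(unique(copies_het), unique(copies_hom))
        if (length(limited) > 0) {
          out[[length(out) + 1]] <- data.frame(
            locus_id = lid, column = col, strategy = "allele_frequency",
            system = sys)
        }
      }
    }
  }
  # sex-limited whole-locus rule
  loci <- unique(catalog$presence$locus_id)
  for (lid in loci) {
    pr <- catalog$presence[catalog$presence$locus_id == lid, ]
    present_in <- function(sid) {
      any(pr$sample_id == sid & pr$present)
    }
    for (sys in c("XY", "ZW")) {
      het_sex <- if (sys == "XY") males else females
      hom_sex <- if (sys == "XY") females else males
      n_p_het <- sum(vapply(het_sex, present_in, logical(1)))
      n_p_hom <- sum(vapply(hom_sex, present_in, logical(1)))
      if (length(het_sex) < thresholds$min_genotyped_per_sex ||
          length(hom_sex) < thresholds$min_genotyped_per_sex) next
      if (n_p_hom <= thresholds$max_present_homogametic &&
          n_p_het / length(het_sex) >=
            thresholds$min_frac_present_heterogametic) {
        out[[length(out) + 1]] <- data.frame(
          locus_id = lid, column = NA_integer_, strategy = "sex_limited",
          system = sys)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(locus_id = character(0), column = integer(0),
                      strategy = character(0), system = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$locus_id, res$column, res$strategy, res$system), ]
}

screen_key <- function(df) {
  sort(paste(df$locus_id, ifelse(is.na(df$column), "tag", df$column),
             df$strategy, df$system))
}

# --- random small catalogs for property tests ------------------------------

random_small_catalog <- function(n_loci = 8, n_males = 4, n_females = 4,
                                 locus_length = 30, p_missing = 0.15) {
  samples <- c(sprintf("m%02d", seq_len(n_males)),
               sprintf("f%02d", seq_len(n_females)))
  registry <- tibble::tibble(
    sample_id = samples,
    species_id = "spX",
    sex = factor(rep(c("male", "female"), c(n_males, n_females)),
                 levels = c("male", "female"))
  )
  cons <- tibble::tibble(
    locus_id = sprintf("L%03d", seq_len(n_loci)),
    consensus = vapply(seq_len(n_loci), function(i) {
      paste(sample(c("A", "C", "G", "T"), locus_length, TRUE), collapse = "")
    }, character(1))
  )
  snps <- list()
  presence <- list()
  for (i in seq_len(n_loci)) {
    col <- sample.int(locus_length, 1) - 1L
    ref <- substr(cons$consensus[i], col + 1, col + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    present <- stats::runif(length(samples)) > p_missing
    a1 <- ifelse(stats::runif(length(samples)) < 0.4, alt, ref)
    a2 <- ifelse(stats::runif(length(samples)) < 0.4, alt, ref)
    a1[!present] <- NA; a2[!present] <- NA
    miss <- stats::runif(length(samples)) < p_missing
    a1[miss] <- NA; a2[miss] <- NA
    snps[[i]] <- tibble::tibble(locus_id = cons$locus_id[i], column = col,
                                sample_id = samples, allele1 = a1,
                                allele2 = a2)
    presence[[i]] <- tibble::tibble(locus_id = cons$locus_id[i],
                                    sample_id = samples, present = present,
                                    depth = ifelse(present, 10L, 0L))
  }
  list(
    catalog = locus_catalog(cons, dplyr::bind_rows(snps),
                            dplyr::bind_rows(presence), samples),
    registry = registry
  )
}

# a tiny single-site catalog built from explicit per-sample genotypes
# (genotype strings like "T/A"; NA = missing)
site_catalog <- function(male_gts, female_gts, consensus = NULL,
                         column = 10L) {
  samples <- c(sprintf("m%02d", seq_along(male_gts)),
               sprintf("f%02d", seq_along(female_gts)))
  gts <- c(male_gts, female_gts)
  if (is.null(consensus)) {
    # realistic tag length so built-in E-values can clear stringent cutoffs
    consensus <- paste(rep("A", 150), collapse = "")
    substr(consensus, column + 1, column + 1) <- "T"
  }
  registry <- tibble::tibble(
    sample_id = samples, species_id = "spX",
    sex = factor(rep(c("male", "female"),
                     c(length(male_gts), length(female_gts))),
                 levels = c("male", "female"))
  )
  a1 <- substr(gts, 1, 1); a2 <- substr(gts, 3, 3)
  a1[is.na(gts)] <- NA; a2[is.na(gts)] <- NA
  catalog <- locus_catalog(
    consensus = tibble::tibble(locus_id = "L1", consensus = consensus),
    snps = tibble::tibble(locus_id = "L1", column = column,
                          sample_id = samples, allele1 = a1, allele2 = a2),
    presence = tibble::tibble(locus_id = "L1", sample_id = samples,
                              present = !is.na(gts),
                              depth = ifelse(is.na(gts), 0L, 10L)),
    samples = samples
  )
  list(catalog = catalog, registry = registry)
}

# --- least-squares topology selection (brute force over all unrooted
# --- topologies of 4 or 5 taxa) --------------------------------------------

all_quartet_topologies <- function(taxa) {
  stopifnot(length(taxa) == 4)
  t <- taxa
  c(sprintf("((%s:1,%s:1):1,(%s:1,%s:1):1);", t[1], t[2], t[3], t[4]),
    sprintf("((%s:1,%s:1):1,(%s:1,%s:1):1);", t[1], t[3], t[2], t[4]),
    sprintf("((%s:1,%s:1):1,(%s:1,%s:1):1);", t[1], t[4], t[2], t[3]))
}

all_unrooted_topologies <- function(taxa) {
  if (length(taxa) == 4) return(all_quartet_topologies(taxa))
  stopifnot(length(taxa) == 5)
  out <- list()
  for (base in all_quartet_topologies(taxa[1:4])) {
    tr <- ape::unroot(ape::read.tree(text = base))
    for (e in seq_len(nrow(tr$edge))) {
      t5 <- ape::bind.tree(
        tr, ape::read.tree(text = sprintf("(%s:1);", taxa[5])),
        where = tr$edge[e, 2], position = 0.5
      )
      out[[length(out) + 1]] <- ape::write.tree(ape::unroot(t5))
    }
  }
  unique(unlist(out))
}

# ordinary least-squares fit of branch lengths for a fixed topology
ls_rss <- function(tree, D) {
  taxa <- tree$tip.label
  pairs <- utils::combn(length(taxa), 2)
  npair <- ncol(pairs)
  nedge <- nrow(tree$edge)
  X <- matrix(0, npair, nedge)
  y <- numeric(npair)
  for (p in seq_len(npair)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    path_nodes <- ape::nodepath(tree, i, j)
    for (e in seq_len(nedge)) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      hit <- FALSE
      for (q in seq_len(length(path_nodes) - 1)) {
        if ((path_nodes[q] == a && path_nodes[q + 1] == b) ||
            (path_nodes[q] == b && path_nodes[q + 1] == a)) hit <- TRUE
      }
      X[p, e] <- as.numeric(hit)
    }
    y[p] <- D[taxa[i], taxa[j]]
  }
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

best_ls_topology <- function(D) {
  taxa <- rownames(D)
  newicks <- all_unrooted_topologies(taxa)
  rss <- vapply(newicks, function(nw) {
    ls_rss(ape::unroot(ape::read.tree(text = nw)), D)
  }, numeric(1))
  ape::unroot(ape::read.tree(text = newicks[which.min(rss)]))
}

random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.2, 1))
  list(tree = ape::unroot(tr), D = stats::cophenetic(tr))
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# --- exhaustive small-parsimony oracle -------------------------------------

brute_force_parsimony <- function(tree, tip_states) {
  tree <- if (length(tree$tip.label) > 2) ape::unroot(tree) else tree
  states <- sort(unique(stats::na.omit(unname(tip_states))))
  n <- length(tree$tip.label)
  n_int <- tree$Nnode
  grid <- expand.grid(rep(list(states), n_int), stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign_state <- function(node) {
      if (node <= n) {
        st <- tip_states[tree$tip.label[node]]
        if (is.na(st)) NA else st
      } else {
        grid[g, node - n]
      }
    }
    changes <- 0
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign_state(tree$edge[e, 1])
      b <- assign_state(tree$edge[e, 2])
      if (is.na(b)) next  # wildcard tip matches its parent for free
      if (is.na(a)) { ok <- FALSE; break }
      if (a != b) changes <- changes + 1
    }
    if (ok) best <- min(best, changes)
  }
  best
}
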