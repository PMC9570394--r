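test_that("K2P distance matches its closed form and the ape oracle", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  # one transition in 100 sites: P = 0.01, Q = 0
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 99), "G")
  expect_equal(k2p_distance(a, b), -0.5 * log(0.98), tolerance = 1e-12)
  expect_equal(round(k2p_distance(a, b), 5), 0.0101)
  # P = Q = 0.25 is still inside the domain
  s1 <- paste(rep(c("A", "A", "A", "A"), 25), collapse = "")
  s2 <- paste(rep(c("G", "C", "A", "A"), 25), collapse = "")
  expect_equal(k2p_distance(s1, s2),
               -0.5 * log(1 - 0.5 - 0.25) - 0.25 * log(1 - 0.5),
               tolerance = 1e-12)
  # P = 0.4, Q = 0.2 saturates the transition term
  s3 <- paste(rep(c("G", "G", "C", "A", "A"), 20), collapse = "")
  s4 <- paste(rep(c("A", "A", "A", "A", "A"), 20), collapse = "")
  expect_error(k2p_distance(s3, s4), "saturated")
  # ambiguity codes are excluded pairwise
  expect_equal(k2p_distance("ANGT", "AAGT"), 0)

  withr::with_seed(5, {
    for (i in 1:10) {
      x <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
      y <- x
      idx <- sample(200, 20)
      subs <- vapply(strsplit(y, "")[[1]][idx], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      for (k in seq_along(idx)) substr(y, idx[k], idx[k]) <- subs[k]
      mine <- k2p_distance(x, y)
      expect_equal(mine, k2p_distance(y, x))
      bin <- ape::as.DNAbin(strsplit(tolower(c(a = x, b = y)), ""))
      expect_equal(mine,
                   as.numeric(ape::dist.dna(bin, model = "K80")),
                   tolerance = 1e-10)
    }
  })
})

test_that("neighbor joining handles the degenerate base cases", {
  D <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), c("a", "b"))
  expect_equal(unname(tr$edge.length), c(1.5, 1.5))

  Z <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  star <- nj_tree(Z)
  expect_equal(star$Nnode, 1)           # all internal edges collapsed
  expect_true(all(star$edge.length == 0))

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(bad), "symmetric")
})

test_that("neighbor joining recovers additive trees (least-squares oracle)", {
  withr::with_seed(17, {
    for (n in c(4, 4, 4, 5, 5, 5)) {
      gen <- random_additive_matrix(n)
      mine <- nj_tree(gen$D)
      expect_true(same_topology(mine, gen$tree))
      # brute-force least squares over all unrooted topologies agrees
      best <- best_ls_topology(gen$D)
      expect_true(same_topology(mine, best))
    }
    for (n in 6:8) {
      gen <- random_additive_matrix(n)
      expect_true(same_topology(nj_tree(gen$D), gen$tree))
      # independent oracle: ape's NJ on the same matrix
      expect_true(same_topology(nj_tree(gen$D), ape::nj(gen$D)))
    }
  })
})

test_that("bootstrap supports are deterministic and order-invariant", {
  withr::with_seed(23, {
    block <- function(ch, n) paste(rep(ch, n), collapse = "")
    # two clearly separated two-taxon clusters, 30 diagnostic transversion
    # columns out of 100 (well inside the K2P domain)
    seqs <- c(a1 = paste0(block("A", 70), block("C", 30)),
              a2 = paste0("G", block("A", 69), block("C", 30)),
              b1 = paste0(block("A", 70), block("G", 30)),
              b2 = paste0("T", block("A", 69), block("G", 30)))
    bs <- bootstrap_supports(seqs, n_replicates = 100, seed = 1)
    expect_equal(length(bs$supports), 1)
    expect_equal(unname(bs$supports), 100)
    bs2 <- bootstrap_supports(seqs, n_replicates = 100, seed = 1)
    expect_identical(bs$supports, bs2$supports)
    # taxon input order does not matter
    bs3 <- bootstrap_supports(seqs[c(3, 1, 4, 2)], n_replicates = 100,
                              seed = 1)
    expect_identical(bs$supports, bs3$supports)
    # identical sequences: supports reported, flagged zero-information
    same <- setNames(rep(block("A", 60), 4), paste0("t", 1:4))
    bz <- bootstrap_supports(same, n_replicates = 10, seed = 2)
    expect_true(bz$zero_information)
    expect_error(bootstrap_supports(seqs, n_replicates = 0), "replicates")
  })
})

test_that("topology classification separates the two gene-history scenarios", {
  lab <- function(labels, species, cls) {
    tibble::tibble(label = labels, species_id = species,
                   allele_class = cls)
  }
  gam_tree <- read_newick(text =
    "((Xa:0.1,Xb:0.1):1,(Ya:0.1,Yb:0.1):1);")
  labels <- lab(c("Xa", "Xb", "Ya", "Yb"), c("a", "b", "a", "b"),
                c("X", "X", "Y", "Y"))
  cl <- classify_topology(gam_tree, labels)
  expect_equal(cl$classification, "gametolog_clustered")

  sp_tree <- read_newick(text =
    "((Xa:0.1,Ya:0.1):1,(Xb:0.1,Yb:0.1):1);")
  cl2 <- classify_topology(sp_tree, labels)
  expect_equal(cl2$classification, "species_clustered")

  star <- read_newick(text = "(Xa:1,Xb:1,Ya:1,Yb:1);")
  expect_equal(classify_topology(star, labels)$classification, "unresolved")

  # sub-threshold support downgrades to unresolved
  key <- paste(sort(c("Ya", "Yb")), collapse = "|")
  weak <- setNames(40, key)
  expect_equal(classify_topology(gam_tree, labels,
                                 supports = weak)$classification,
               "unresolved")

  one_sp <- lab(c("Xa", "Ya"), c("a", "a"), c("X", "Y"))
  expect_error(classify_topology(read_newick(text = "(Xa:1,Ya:1);"),
                                 one_sp), "two species")

  # unphased tips can satisfy species clustering but never gametolog
  unph <- lab(c("Xa", "Ya", "u1", "u2"), c("a", "a", "b", "b"),
              c("X", "Y", "unphased", "unphased"))
  cl3 <- classify_topology(read_newick(text =
    "((Xa:0.1,Ya:0.1):1,(u1:0.1,u2:0.1):1);"), unph)
  expect_equal(cl3$classification, "species_clustered")
})

test_that("homolog retrieval phases focal haplotypes and drops weak matches", {
  sim <- simulate_catalog(sim_config(
    species = c("a", "b", "c"), n_males = 4, n_females = 4,
    n_autosomal_loci = 5, n_xy_snp_loci = 2, n_y_limited_loci = 0,
    n_ancestral_sdr_loci = 1, sdr_shared_species = c("a", "b"),
    species_tree = "(a:1,(b:0.2,c:0.2):0.8);",
    genotyping_error_rate = 0, locus_dropout_rate = 0, seed = 31
  ))
  truth <- dplyr::filter(sim$truth, species_id == "a",
                         class == "ancestral_sdr")
  al <- retrieve_homologs(truth$locus_id, "a", sim$catalogs, sim$registry,
                          sex_specific_allele = truth$sex_specific_allele,
                          column = truth$snp_column)
  focal <- dplyr::filter(al, species_id == "a")
  reg <- sim$registry
  males <- reg$sample_id[reg$sex == "male"]
  # every focal male contributes one X and one Y haplotype
  per_male <- dplyr::filter(focal, sample_id %in% males) |>
    dplyr::count(sample_id, allele_class)
  expect_true(all(c("X", "Y") %in% per_male$allele_class))
  expect_true(all(per_male$n == 1))
  # the Y haplotype carries the sex-specific allele at the column
  ys <- dplyr::filter(focal, allele_class == "Y")
  expect_true(all(substr(ys$sequence, truth$snp_column + 1,
                         truth$snp_column + 1) == truth$sex_specific_allele))
  # focal females are X/X
  expect_true(all(dplyr::filter(focal, !sample_id %in% males)$allele_class
                  == "X"))
  # homologous species included as unphased; unrelated loci cannot qualify
  expect_true("b" %in% al$species_id)
  expect_true(all(dplyr::filter(al, species_id == "b")$allele_class ==
                    "unphased"))
})

test_that("single- and multi-locus tree building agree for one locus", {
  tree <- "(a:1,(b:0.6,c:0.6):0.4);"
  al <- simulate_gene_history("ongoing_recombination", c("a", "b", "c"),
                              tree, seed = 41)
  single <- build_gene_tree(al, n_bootstrap = 50, seed = 99)
  multi <- build_multilocus_trees(list(al), n_bootstrap = 50, seed = 99)
  expect_equal(multi$concatenated$classification, single$classification)
  expect_equal(ape::write.tree(multi$concatenated$tree),
               ape::write.tree(single$tree))
  expect_length(multi$per_locus, 1)

  al5 <- lapply(1:5, function(i) {
    simulate_gene_history("ongoing_recombination", c("a", "b", "c"), tree,
                          seed = 50 + i)
  })
  res5 <- build_multilocus_trees(al5, n_bootstrap = 50, seed = 7)
  expect_equal(res5$concatenated$classification, "species_clustered")
})

test_that("external trees carry their own supports through classification", {
  ext <- read_newick(text = "((Xa:0.1,Xb:0.1)95:1,(Ya:0.1,Yb:0.1)88:1);")
  labels <- tibble::tibble(label = c("Xa", "Xb", "Ya", "Yb"),
                           species_id = c("a", "b", "a", "b"),
                           allele_class = c("X", "X", "Y", "Y"))
  al <- dplyr::mutate(labels, sequence = NA_character_)
  res <- build_gene_tree(al, method = "external", tree = ext)
  expect_equal(res$classification, "gametolog_clustered")
  expect_equal(res$method, "external")
})
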