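DEFAULT_SPECIES_TREE <- paste0(
  "(species_1:1,((species_2:0.55,(species_3:0.35,species_4:0.35):0.2):0.25,",
  "((species_5:0.45,species_6:0.45):0.2,(species_7:0.5,",
  "(species_8:0.3,species_9:0.3):0.2):0.15):0.15):0.2);"
)

#' Configuration for the synthetic catalog generator
#'
#' Defaults emulate the sampling design the analysis assumes: nine species on
#' a two-clade ultrametric phylogeny, ten males and ten females per species
#' (reduced-representation studies of this kind sample roughly ten
#' individuals per sex), 150 bp tags, and a few dozen planted sex-linked loci
#' against a larger autosomal background. Noise knobs (`genotyping_error_rate`,
#' `locus_dropout_rate`) are free parameters of the generator, not estimates
#' of any particular data set.
#'
#' @param species Character vector of species ids.
#' @param n_males,n_females Individuals per sex per species (recycled).
#' @param n_autosomal_loci,n_xy_snp_loci,n_y_limited_loci,n_ancestral_sdr_loci
#'   Locus counts per species. `xy_snp` loci carry one SNP heterozygous in
#'   every heterogametic-sex individual and homozygous in the other sex;
#'   `y_limited` loci are present only in the heterogametic sex;
#'   `ancestral_sdr` loci are shared (homologous) across
#'   `sdr_shared_species`, with X/Y haplotypes split before those species
#'   diverged.
#' @param system Per-species heterogamety, `"XY"` or `"ZW"` (recycled). ZW
#'   simulation is the exact sex-mirror of XY.
#' @param genotyping_error_rate Probability that a called genotype is
#'   replaced by one of the other two genotype classes at that site.
#' @param locus_dropout_rate Probability that a locus is not recovered in an
#'   individual (presence `FALSE`, genotypes missing).
#' @param locus_length Tag length in bases.
#' @param minor_allele_freq Allele frequency used for autosomal SNPs.
#' @param mutation_rate Substitutions per site per branch-length unit, used
#'   for the ancestral-SDR gene histories.
#' @param ts_tv Transition/transversion ratio of the substitution process.
#' @param species_tree Newick string or `ape::phylo` with branch lengths.
#' @param sdr_shared_species Species sharing the ancestral sex-determining
#'   region (subset of `species`).
#' @param n_chromosomes Number of reference chromosomes.
#' @param sex_chromosome Per-species true sex chromosome name (recycled).
#' @param mean_depth Mean read depth of recovered loci.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(species = paste0("species_", 1:9),
                       n_males = 10, n_females = 10,
                       n_autosomal_loci = 200, n_xy_snp_loci = 40,
                       n_y_limited_loci = 15, n_ancestral_sdr_loci = 0,
                       system = "XY",
                       genotyping_error_rate = 0.01,
                       locus_dropout_rate = 0.05,
                       locus_length = 150, minor_allele_freq = 0.2,
                       mutation_rate = 0.15, ts_tv = 2,
                       species_tree = DEFAULT_SPECIES_TREE,
                       sdr_shared_species = character(0),
                       n_chromosomes = 6, sex_chromosome = "chr5",
                       mean_depth = 20, seed = 1) {
  if (is.character(species_tree)) {
    species_tree <- read_newick(text = species_tree)
  }
  cfg <- list(
    species = species,
    n_males = as.integer(rep_len(n_males, length(species))),
    n_females = as.integer(rep_len(n_females, length(species))),
    n_autosomal_loci = n_autosomal_loci, n_xy_snp_loci = n_xy_snp_loci,
    n_y_limited_loci = n_y_limited_loci,
    n_ancestral_sdr_loci = n_ancestral_sdr_loci,
    system = rep_len(system, length(species)),
    genotyping_error_rate = genotyping_error_rate,
    locus_dropout_rate = locus_dropout_rate,
    locus_length = locus_length, minor_allele_freq = minor_allele_freq,
    mutation_rate = mutation_rate, ts_tv = ts_tv,
    species_tree = species_tree,
    sdr_shared_species = sdr_shared_species,
    n_chromosomes = n_chromosomes,
    sex_chromosome = rep_len(sex_chromosome, length(species)),
    mean_depth = mean_depth, seed = as.integer(seed)
  )
  for (r in c("genotyping_error_rate", "locus_dropout_rate",
              "minor_allele_freq")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) abort(sprintf("%s must be in [0,1]", r))
  }
  if (any(cfg$n_males < 1) || any(cfg$n_females < 1)) {
    abort("every species needs at least one individual of each sex")
  }
  if (!all(cfg$system %in% c("XY", "ZW"))) abort("system must be XY or ZW")
  if (!all(species %in% species_tree$tip.label)) {
    abort("all species must be tips of the species tree")
  }
  if (!all(cfg$sdr_shared_species %in% species)) {
    abort("sdr_shared_species must be a subset of species")
  }
  if (length(cfg$sdr_shared_species) == 1) {
    abort("sdr_shared_species needs 0 or >= 2 species")
  }
  chroms <- paste0("chr", seq_len(n_chromosomes))
  if (!all(cfg$sex_chromosome %in% chroms)) {
    abort("sex_chromosome must be one of the generated chromosome names")
  }
  structure(cfg, class = "sim_config")
}

# one Kimura-2-parameter evolution step: Poisson(rate * L * len) substitutions,
# transitions with probability kappa / (kappa + 2)
evolve_seq <- function(seq, branch_len, rate, ts_tv) {
  L <- nchar(seq)
  n_mut <- rpois(1, rate * L * branch_len)
  if (n_mut == 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  sites <- sample.int(L, n_mut, replace = TRUE)
  for (pos in sites) {
    base <- s[pos]
    if (runif(1) < ts_tv / (ts_tv + 2)) {
      s[pos] <- switch(base, A = "G", G = "A", C = "T", T = "C")
    } else {
      s[pos] <- sample(setdiff(
        if (base %in% PURINES) PYRIMIDINES else PURINES, character(0)
      ), 1)
    }
  }
  paste(s, collapse = "")
}

# evolve a root sequence down a (rooted) phylo; returns named tip sequences
evolve_along_tree <- function(tree, root_seq, rate, ts_tv) {
  n_tip <- length(tree$tip.label)
  seqs <- character(n_tip + tree$Nnode)
  seqs[n_tip + 1L] <- root_seq
  ord <- reorder(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[i, 1]
    child <- ord$edge[i, 2]
    seqs[child] <- evolve_seq(seqs[parent], ord$edge.length[i], rate, ts_tv)
  }
  setNames(seqs[seq_len(n_tip)], tree$tip.label)
}

tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Simulate aligned X/Y allele sequences under the two gene-history scenarios
#'
#' `"ancestral_suppression"`: the X and Y lineages split on the branch
#' ancestral to all selected species (stem length `xy_stem`) and then evolve
#' independently down the species tree — the Y never recombines, so the true
#' genealogy clusters by gametolog. `"ongoing_recombination"`: Y alleles are
#' homogenized with the within-species X pool, so every haplotype of a
#' species descends from that species' tip sequence and the true genealogy
#' clusters by species; within-species variation comes from a short
#' terminal branch of length `within_species_branch`.
#'
#' @param scenario `"ancestral_suppression"` or `"ongoing_recombination"`.
#' @param species Character vector (>= 2) of tree tips to simulate.
#' @param tree Newick string or `ape::phylo` with branch lengths.
#' @param mutation_rate Substitutions per site per branch unit (>= 0; a
#'   negative rate is an error, rate 0 yields identical sequences).
#' @param seed Integer seed.
#' @param locus_length Tag length.
#' @param ts_tv Transition/transversion ratio.
#' @param n_males,n_females Individuals per sex per species.
#' @param xy_stem Branch length separating the X and Y roots under
#'   `ancestral_suppression`; default twice the tree height.
#' @param within_species_branch Branch length of within-species haplotype
#'   divergence.
#' @param locus_id Label recorded on every row.
#' @return Tibble with columns `species_id`, `sample_id`, `sex`,
#'   `allele_class` (`"X"`/`"Y"`), `label`, `sequence`, `locus_id`. Labels
#'   encode species, sex, individual, and allele (e.g.
#'   `species_1|M01|Y`).
#' @export
simulate_gene_history <- function(scenario = c("ancestral_suppression",
                                               "ongoing_recombination"),
                                  species, tree,
                                  mutation_rate = 0.15, seed = 1,
                                  locus_length = 150, ts_tv = 2,
                                  n_males = 1, n_females = 1,
                                  xy_stem = NULL,
                                  within_species_branch = 0.02,
                                  locus_id = "locus") {
  scenario <- match.arg(scenario)
  if (mutation_rate < 0) abort("mutation_rate must be non-negative")
  if (is.character(tree)) tree <- read_newick(text = tree)
  if (length(species) < 2) abort("need at least two species")
  if (!all(species %in% tree$tip.label)) {
    abort("species must all be tips of the tree")
  }
  tree <- ape::keep.tip(tree, species)
  xy_stem <- xy_stem %||% (2 * tree_height(tree))
  with_seed_if(seed, {
    anc <- random_dna(1, locus_length)
    if (scenario == "ancestral_suppression") {
      x_root <- evolve_seq(anc, xy_stem / 2, mutation_rate, ts_tv)
      y_root <- evolve_seq(anc, xy_stem / 2, mutation_rate, ts_tv)
      x_tip <- evolve_along_tree(tree, x_root, mutation_rate, ts_tv)
      y_tip <- evolve_along_tree(tree, y_root, mutation_rate, ts_tv)
    } else {
      x_tip <- evolve_along_tree(tree, anc, mutation_rate, ts_tv)
      y_tip <- x_tip  # Y pool homogenized with X within each species
    }
    rows <- list()
    for (sp in species) {
      for (i in seq_len(n_males)) {
        sid <- sprintf("%s_M%02d", sp, i)
        for (allele in c("X", "Y")) {
          src <- if (allele == "X") x_tip[[sp]] else y_tip[[sp]]
          rows[[length(rows) + 1L]] <- tibble(
            species_id = sp, sample_id = sid, sex = "male",
            allele_class = allele,
            label = sprintf("%s|M%02d|%s", sp, i, allele),
            sequence = evolve_seq(src, within_species_branch,
                                  mutation_rate, ts_tv),
            locus_id = locus_id
          )
        }
      }
      for (i in seq_len(n_females)) {
        sid <- sprintf("%s_F%02d", sp, i)
        for (copy in 1:2) {
          rows[[length(rows) + 1L]] <- tibble(
            species_id = sp, sample_id = sid, sex = "female",
            allele_class = "X",
            label = sprintf("%s|F%02d|X%d", sp, i, copy),
            sequence = evolve_seq(x_tip[[sp]], within_species_branch,
                                  mutation_rate, ts_tv),
            locus_id = locus_id
          )
        }
      }
    }
    bind_rows(rows)
  })
}

#' Simulate multi-species locus catalogs with known ground truth
#'
#' Generates, for every species in the configuration, a [locus_catalog()]
#' containing autosomal background loci (SNPs at a configurable minor-allele
#' frequency, sex-independent), perfectly sex-linked SNP loci (before noise
#' injection every heterogametic-sex individual is heterozygous for a
#' sex-limited allele and every homogametic-sex individual homozygous),
#' sex-limited tags (present only in the heterogametic sex), and optional
#' ancestral-SDR loci shared across species. A reference genome is built
#' with every locus consensus embedded at a recorded position on its true
#' chromosome. ZW species are the exact sex-mirror of XY species.
#'
#' @param config A [sim_config()].
#' @return List with elements `catalogs` (named list of [locus_catalog()]),
#'   `registry` (tibble), `truth` (tibble: `species_id`, `locus_id`, `class`,
#'   `sex_linked`, `chromosome`, `position`, `sex_specific_allele`,
#'   `snp_column`), `reference` ([reference_genome()]), `unified_map`
#'   (tibble: `species_id`, `locus_id`, `unified_id`), `species_tree`, and
#'   the `config`.
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, simulate_catalog_impl(config))
}

simulate_catalog_impl <- function(cfg) {
  L <- cfg$locus_length
  n_sp <- length(cfg$species)

  registry <- purrr::map_dfr(seq_len(n_sp), function(i) {
    sp <- cfg$species[i]
    tibble(
      sample_id = c(sprintf("%s_M%02d", sp, seq_len(cfg$n_males[i])),
                    sprintf("%s_F%02d", sp, seq_len(cfg$n_females[i]))),
      species_id = sp,
      sex = factor(rep(c("male", "female"),
                       c(cfg$n_males[i], cfg$n_females[i])),
                   levels = c("male", "female"))
    )
  })

  # ancestral-SDR gene histories (shared, homologous loci)
  sdr <- list()
  if (cfg$n_ancestral_sdr_loci > 0 && length(cfg$sdr_shared_species) >= 2) {
    sub_tree <- ape::keep.tip(cfg$species_tree, cfg$sdr_shared_species)
    stem <- 2 * tree_height(sub_tree)
    for (k in seq_len(cfg$n_ancestral_sdr_loci)) {
      anc <- random_dna(1, L)
      x_root <- evolve_seq(anc, stem / 2, cfg$mutation_rate, cfg$ts_tv)
      y_root <- evolve_seq(anc, stem / 2, cfg$mutation_rate, cfg$ts_tv)
      sdr[[k]] <- list(
        locus_id = sprintf("sdr_%03d", k),
        x_tip = evolve_along_tree(sub_tree, x_root, cfg$mutation_rate,
                                  cfg$ts_tv),
        y_tip = evolve_along_tree(sub_tree, y_root, cfg$mutation_rate,
                                  cfg$ts_tv)
      )
    }
  }

  # per-species locus plans
  plans <- list()
  for (i in seq_len(n_sp)) {
    sp <- cfg$species[i]
    sysi <- cfg$system[i]
    sexchr <- cfg$sex_chromosome[i]
    autos <- setdiff(paste0("chr", seq_len(cfg$n_chromosomes)), sexchr)
    snp_class <- if (sysi == "XY") "xy_snp" else "zw_snp"
    lim_class <- if (sysi == "XY") "y_limited" else "w_limited"
    plan <- tibble(
      locus_id = c(
        sprintf("%s_aut_%04d", sp, seq_len(cfg$n_autosomal_loci)),
        sprintf("%s_sexsnp_%03d", sp, seq_len(cfg$n_xy_snp_loci)),
        sprintf("%s_lim_%03d", sp, seq_len(cfg$n_y_limited_loci))
      ),
      class = rep(c("autosomal", snp_class, lim_class),
                  c(cfg$n_autosomal_loci, cfg$n_xy_snp_loci,
                    cfg$n_y_limited_loci)),
      species_id = sp
    )
    plan$chromosome <- if_else(
      plan$class == "autosomal",
      sample(autos, nrow(plan), replace = TRUE),
      sexchr
    )
    plan$consensus <- random_dna(nrow(plan), L)
    if (length(sdr) && sp %in% cfg$sdr_shared_species) {
      plan <- bind_rows(plan, tibble(
        locus_id = vapply(sdr, `[[`, character(1), "locus_id"),
        class = "ancestral_sdr", species_id = sp, chromosome = sexchr,
        consensus = vapply(sdr, function(s) s$x_tip[[sp]], character(1))
      ))
    }
    plans[[sp]] <- plan
  }
  all_plan <- bind_rows(plans)

  # reference genome: embed every locus consensus in its true chromosome
  slot <- L + 100L
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  ref_seqs <- character(0)
  all_plan$position <- NA_integer_
  for (ch in chrom_names) {
    idx <- which(all_plan$chromosome == ch)
    n_slots <- length(idx) + 5L
    order_slots <- sample.int(n_slots, length(idx))
    pieces <- random_dna(n_slots, slot)
    pos <- integer(length(idx))
    for (j in seq_along(idx)) {
      sl <- order_slots[j]
      pieces[sl] <- paste0(
        substr(pieces[sl], 1, 50), all_plan$consensus[idx[j]],
        substr(pieces[sl], 51 + L, slot)
      )
      pos[j] <- (sl - 1L) * slot + 51L
    }
    all_plan$position[idx] <- pos
    ref_seqs[ch] <- paste(pieces, collapse = "")
  }
  reference <- reference_genome(sequences = ref_seqs,
                                chromosomes = chrom_names)

  catalogs <- list()
  truth_rows <- list()
  for (i in seq_len(n_sp)) {
    sp <- cfg$species[i]
    plan <- all_plan %>% filter(.data$species_id == sp)
    reg <- registry %>% filter(.data$species_id == sp)
    het_sex <- if (cfg$system[i] == "XY") "male" else "female"
    built <- build_species_catalog(plan, reg, het_sex, cfg, sdr, sp)
    catalogs[[sp]] <- built$catalog
    truth_rows[[sp]] <- built$truth
  }
  truth <- bind_rows(truth_rows)
  unified_map <- truth %>%
    select("species_id", "locus_id") %>%
    mutate(unified_id = .data$locus_id)

  list(catalogs = catalogs, registry = registry, truth = truth,
       reference = reference, unified_map = unified_map,
       species_tree = cfg$species_tree, config = cfg)
}

build_species_catalog <- function(plan, reg, het_sex, cfg, sdr, sp) {
  samples <- reg$sample_id
  het_samples <- reg$sample_id[reg$sex == het_sex]
  hom_samples <- setdiff(samples, het_samples)
  L <- cfg$locus_length
  other_bases <- function(b) setdiff(DNA_BASES, b)

  snp_rows <- list()
  truth <- plan %>%
    mutate(sex_linked = .data$class != "autosomal",
           sex_specific_allele = NA_character_,
           snp_column = NA_integer_)

  for (r in seq_len(nrow(plan))) {
    cls <- plan$class[r]
    lid <- plan$locus_id[r]
    cons <- plan$consensus[r]
    if (cls == "autosomal") {
      col0 <- sample.int(L, 1) - 1L
      ref <- substr(cons, col0 + 1, col0 + 1)
      alt <- sample(other_bases(ref), 1)
      a1 <- if_else(rbinom(length(samples), 1, cfg$minor_allele_freq) == 1,
                    alt, ref)
      a2 <- if_else(rbinom(length(samples), 1, cfg$minor_allele_freq) == 1,
                    alt, ref)
      snp_rows[[length(snp_rows) + 1L]] <- tibble(
        locus_id = lid, column = col0, sample_id = samples,
        allele1 = a1, allele2 = a2
      )
      truth$snp_column[truth$locus_id == lid] <- col0
    } else if (cls %in% c("xy_snp", "zw_snp")) {
      col0 <- sample.int(L, 1) - 1L
      x_allele <- substr(cons, col0 + 1, col0 + 1)
      y_allele <- sample(other_bases(x_allele), 1)
      snp_rows[[length(snp_rows) + 1L]] <- tibble(
        locus_id = lid, column = col0, sample_id = samples,
        allele1 = x_allele,
        allele2 = if_else(samples %in% het_samples, y_allele, x_allele)
      )
      sel <- truth$locus_id == lid
      truth$sex_specific_allele[sel] <- y_allele
      truth$snp_column[sel] <- col0
    } else if (cls == "ancestral_sdr") {
      entry <- sdr[[which(vapply(sdr, `[[`, character(1), "locus_id") == lid)]]
      x_seq <- strsplit(entry$x_tip[[sp]], "", fixed = TRUE)[[1]]
      y_seq <- strsplit(entry$y_tip[[sp]], "", fixed = TRUE)[[1]]
      cols0 <- which(x_seq != y_seq) - 1L
      for (col0 in cols0) {
        snp_rows[[length(snp_rows) + 1L]] <- tibble(
          locus_id = lid, column = col0, sample_id = samples,
          allele1 = x_seq[col0 + 1],
          allele2 = if_else(samples %in% het_samples, y_seq[col0 + 1],
                            x_seq[col0 + 1])
        )
      }
      sel <- truth$locus_id == lid
      if (length(cols0)) {
        truth$sex_specific_allele[sel] <- y_seq[cols0[1] + 1]
        truth$snp_column[sel] <- cols0[1]
      }
    }
    # y_limited / w_limited loci carry no SNPs
  }
  snps <- bind_rows(snp_rows)

  # presence: sex-limited loci absent in the homogametic sex; dropout on top
  presence <- tidyr::expand_grid(locus_id = plan$locus_id,
                                 sample_id = samples) %>%
    left_join(plan %>% select("locus_id", "class"), by = "locus_id") %>%
    mutate(
      limited = .data$class %in% c("y_limited", "w_limited"),
      present = !(.data$limited & .data$sample_id %in% hom_samples),
      present = .data$present &
        (runif(dplyr::n()) >= cfg$locus_dropout_rate)
    )

  # genotyping error: replace a called genotype with one of the other two
  # genotype classes at that site
  if (nrow(snps) && cfg$genotyping_error_rate > 0) {
    hit <- runif(nrow(snps)) < cfg$genotyping_error_rate
    if (any(hit)) {
      site_alleles <- snps %>%
        group_by(.data$locus_id, .data$column) %>%
        summarise(ref = .data$allele1[1],
                  alt = {
                    alls <- setdiff(unique(c(.data$allele1, .data$allele2)),
                                    .data$allele1[1])
                    if (length(alls)) alls[1] else
                      sample(setdiff(DNA_BASES, .data$allele1[1]), 1)
                  }, .groups = "drop")
      snps <- snps %>% left_join(site_alleles, by = c("locus_id", "column"))
      for (j in which(hit)) {
        ref <- snps$ref[j]; alt <- snps$alt[j]
        classes <- list(c(ref, ref), c(ref, alt), c(alt, alt))
        cur <- paste(sort(c(snps$allele1[j], snps$allele2[j])), collapse = "")
        keys <- vapply(classes, function(g) paste(sort(g), collapse = ""),
                       character(1))
        pick <- sample(which(keys != cur), 1)
        snps$allele1[j] <- classes[[pick]][1]
        snps$allele2[j] <- classes[[pick]][2]
      }
      snps <- snps %>% select(-"ref", -"alt")
    }
  }

  # dropped loci lose their genotype calls
  absent <- presence %>% filter(!.data$present)
  snps <- snps %>%
    left_join(absent %>% select("locus_id", "sample_id") %>%
                mutate(gone = TRUE),
              by = c("locus_id", "sample_id")) %>%
    mutate(allele1 = if_else(is.na(.data$gone), .data$allele1, NA_character_),
           allele2 = if_else(is.na(.data$gone), .data$allele2,
                             NA_character_)) %>%
    select(-"gone")

  presence <- presence %>%
    mutate(depth = if_else(.data$present,
                           rpois(dplyr::n(), cfg$mean_depth - 1) + 1L, 0L)) %>%
    select("locus_id", "sample_id", "present", "depth")

  catalog <- locus_catalog(
    consensus = plan %>% select("locus_id", "consensus"),
    snps = snps, presence = presence, samples = samples
  )
  list(catalog = catalog,
       truth = truth %>% select("species_id", "locus_id", "class",
                                "sex_linked", "chromosome", "position",
                                "sex_specific_allele", "snp_column"))
}

#' Emit per-sex read pools from a catalog
#'
#' Every recovered locus of every sample emits error-free, full-length
#' copies of that sample's two haplotypes (built from the consensus with the
#' called alleles substituted at each SNP column; a missing call falls back
#' to the consensus base). Haplotypes of sex-limited loci therefore never
#' appear in the homogametic-sex pool. The operation is deterministic —
#' reads are exact haplotype copies, so no randomness is involved.
#'
#' @param catalog A [locus_catalog()].
#' @param registry Sex registry tibble covering the catalog samples.
#' @param coverage Copies emitted per haplotype (>= 1).
#' @return List with named character vectors `male` and `female`.
#' @export
simulate_reads <- function(catalog, registry, coverage = 1) {
  stopifnot(coverage >= 1)
  reg <- registry_for_catalog(registry, catalog)
  cons <- setNames(catalog$consensus$consensus, catalog$consensus$locus_id)
  called <- catalog$snps %>% filter(!is.na(.data$allele1))
  snps_by_key <- split(called, paste(called$locus_id, called$sample_id))
  pres <- catalog$presence %>% filter(.data$present)
  out <- list(male = character(0), female = character(0))
  reads <- vector("list", nrow(pres))
  for (i in seq_len(nrow(pres))) {
    lid <- pres$locus_id[i]; sid <- pres$sample_id[i]
    h1 <- h2 <- cons[[lid]]
    gt <- snps_by_key[[paste(lid, sid)]]
    if (!is.null(gt)) {
      for (j in seq_len(nrow(gt))) {
        h1 <- substitute_base(h1, gt$column[j], gt$allele1[j])
        h2 <- substitute_base(h2, gt$column[j], gt$allele2[j])
      }
    }
    copies <- rep(c(h1, h2), each = coverage)
    names(copies) <- sprintf("%s|%s|h%d|c%d", sid, lid,
                             rep(1:2, each = coverage),
                             rep(seq_len(coverage), 2))
    reads[[i]] <- copies
  }
  sex_of <- setNames(as.character(reg$sex), reg$sample_id)
  all_reads <- unlist(reads)
  read_sex <- sex_of[pres$sample_id[rep(seq_len(nrow(pres)),
                                        each = 2 * coverage)]]
  list(male = all_reads[read_sex == "male"],
       female = all_reads[read_sex == "female"])
}
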