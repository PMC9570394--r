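PIPELINE_FIELDS <- c("simulation", "inputs", "thresholds", "rules",
                     "n_bootstrap", "support_threshold", "alpha",
                     "coverage", "max_tree_loci", "seed")

#' Configuration for the end-to-end pipeline
#'
#' The pipeline runs either on synthetic data (`simulation` holds arguments
#' for [sim_config()]) or on files (`inputs` holds paths: `registry`, a
#' named `catalogs` list of per-species `genotypes`/`presence`/`fasta`
#' paths, `species_tree`, and optionally per-species `male_pool` /
#' `female_pool` FASTAs and a `reference` FASTA). Exactly one of the two
#' must be supplied. Unknown fields are rejected.
#'
#' @param simulation Named list of [sim_config()] arguments (or NULL).
#' @param inputs Named list of input paths (or NULL).
#' @param thresholds A [screen_thresholds()].
#' @param rules An [assignment_rules()].
#' @param n_bootstrap,support_threshold Gene-tree settings.
#' @param alpha Significance level for the system call.
#' @param coverage Read-pool coverage for in-silico validation.
#' @param max_tree_loci Maximum number of shared loci sent to the gene-tree
#'   stage.
#' @param seed Master seed; every stage derives its randomness from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            thresholds = screen_thresholds(),
                            rules = assignment_rules(),
                            n_bootstrap = 100, support_threshold = 50,
                            alpha = 0.05, coverage = 1, max_tree_loci = 3,
                            seed = 1) {
  cfg <- list(simulation = simulation, inputs = inputs,
              thresholds = thresholds, rules = rules,
              n_bootstrap = n_bootstrap,
              support_threshold = support_threshold, alpha = alpha,
              coverage = coverage, max_tree_loci = max_tree_loci,
              seed = as.integer(seed))
  if (is.null(cfg$simulation) && is.null(cfg$inputs)) {
    abort("pipeline_config: one of 'simulation' or 'inputs' is required")
  }
  if (!is.null(cfg$inputs)) {
    for (req in c("registry", "catalogs", "species_tree")) {
      if (is.null(cfg$inputs[[req]])) {
        abort(sprintf("pipeline_config: inputs field '%s' is required", req))
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown top-level keys are rejected; threshold and rule blocks are
#' passed to [screen_thresholds()] and [assignment_rules()].
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), PIPELINE_FIELDS)
  if (length(unknown)) {
    abort(sprintf("unknown pipeline config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$thresholds)) {
    raw$thresholds <- do.call(screen_thresholds, raw$thresholds)
  }
  if (!is.null(raw$rules)) raw$rules <- do.call(assignment_rules, raw$rules)
  do.call(pipeline_config, raw)
}

#' Run the full inference pipeline
#'
#' Executes simulate (or load) -> screen -> validate -> map -> trees ->
#' turnover, writing per-stage TSV/FASTA/Newick outputs plus a
#' machine-readable `summary.json` into `out_dir`. Every output file opens
#' with a comment line declaring the configuration hash and seed that
#' produced it; the run is idempotent given the seed. Any stage failure
#' halts with a stage-tagged error.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; stage subfolders inside).
#' @return Invisibly, the summary list (class `sexlink_run`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- rlang::hash(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dir <- function(s) {
    d <- file.path(out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  stamp <- sprintf("# sexlinkr run config=%s seed=%d", hash, config$seed)
  write_stage_tsv <- function(x, stage, name) {
    path <- file.path(stage_dir(stage), name)
    writeLines(stamp, path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", stage, conditionMessage(e)))
    })
  }

  # -- simulate / load ------------------------------------------------
  data <- in_stage("simulate", pipeline_data(config))
  write_stage_tsv(data$registry, "simulate", "registry.tsv")
  if (!is.null(data$truth)) {
    write_stage_tsv(data$truth, "simulate", "truth.tsv")
  }

  # -- screen ---------------------------------------------------------
  candidates <- in_stage("screen", {
    purrr::imap_dfr(data$catalogs, function(cat, sp) {
      combine_candidates(primary = screen_all(cat, data$registry,
                                              config$thresholds)) %>%
        mutate(species_id = sp)
    })
  })
  write_stage_tsv(candidates, "screen", "candidates.tsv")

  # -- validate -------------------------------------------------------
  validated <- in_stage("validate", {
    purrr::imap_dfr(data$catalogs, function(cat, sp) {
      cand <- candidates %>% filter(.data$species_id == sp)
      if (!nrow(cand)) return(cand %>% mutate(status = character(0)))
      pools <- data$pools[[sp]]
      if (is.null(pools)) {
        pools <- simulate_reads(cat, data$registry,
                                coverage = config$coverage)
      }
      verify_markers(cand, pools$male, pools$female, catalog = cat)
    })
  })
  confirmed <- validated %>% filter(.data$status == "confirmed")
  write_stage_tsv(validated, "validate", "validated.tsv")
  systems <- in_stage("validate",
                      call_system(confirmed, alpha = config$alpha))
  write_stage_tsv(systems, "validate", "systems.tsv")
  shared <- NULL
  if (!is.null(data$unified_map)) {
    shared <- in_stage("validate",
                       find_trans_species_markers(confirmed,
                                                  data$unified_map))
    write_stage_tsv(shared, "validate", "shared_markers.tsv")
  }

  # -- map ------------------------------------------------------------
  assignments <- concentration <- NULL
  identities <- setNames(rep(NA_character_, length(data$catalogs)),
                         names(data$catalogs))
  if (!is.null(data$reference) && !is.null(data$reference$sequences)) {
    assignments <- in_stage("map", {
      loci <- confirmed %>%
        distinct(.data$species_id, .data$locus_id, .data$consensus)
      if (!nrow(loci)) {
        tibble(marker_id = character(), status = character(),
               chromosome = character(), position = double(),
               species_id = character())
      } else {
        queries <- setNames(loci$consensus,
                            paste(loci$species_id, loci$locus_id, sep = "@"))
        hits <- match_sequences(queries, data$reference$sequences,
                                mode = "exact")
        assign_direct(hits, config$rules, markers = names(queries)) %>%
          tidyr::separate_wider_delim("marker_id", "@",
                                      names = c("species_id", "locus_id"),
                                      cols_remove = FALSE)
      }
    })
    write_stage_tsv(assignments, "map", "assignments.tsv")
    concentration <- in_stage("map",
                              concentration_test(assignments,
                                                 data$reference,
                                                 alpha = config$alpha))
    write_stage_tsv(concentration$table, "map", "concentration.tsv")
    modal <- assignments %>%
      filter(.data$status == "assigned") %>%
      count(.data$species_id, .data$chromosome) %>%
      group_by(.data$species_id) %>%
      slice_min(order_by = dplyr::desc(.data$n), n = 1,
                with_ties = FALSE) %>%
      ungroup()
    identities[modal$species_id] <- modal$chromosome
  }

  # -- trees ----------------------------------------------------------
  tree_results <- list()
  if (!is.null(shared) && nrow(shared)) {
    tree_results <- in_stage("trees", {
      take <- head(seq_len(nrow(shared)), config$max_tree_loci)
      purrr::map(take, function(i) {
        sp_set <- strsplit(shared$species[i], ",")[[1]]
        focal <- sp_set[1]
        uid <- shared$unified_id[i]
        lid <- data$unified_map %>%
          filter(.data$species_id == focal, .data$unified_id == uid) %>%
          pull("locus_id") %>% first()
        info <- confirmed %>%
          filter(.data$species_id == focal, .data$locus_id == lid,
                 !is.na(.data$sex_specific_allele)) %>%
          slice(1)
        phasing <- confirmed %>%
          filter(!is.na(.data$sex_specific_allele)) %>%
          distinct(.data$species_id, .data$locus_id,
                   .keep_all = TRUE) %>%
          select("species_id", "locus_id", "sex_specific_allele", "column")
        alleles <- retrieve_homologs(
          lid, focal, data$catalogs, data$registry,
          sex_specific_allele = if (nrow(info)) info$sex_specific_allele
                                else NULL,
          column = if (nrow(info)) info$column else NULL,
          phasing = phasing
        )
        build_gene_tree(alleles, n_bootstrap = config$n_bootstrap,
                        seed = config$seed + i,
                        support_threshold = config$support_threshold)
      }) %>% setNames(shared$unified_id[take])
    })
    tree_tbl <- purrr::imap_dfr(tree_results, function(res, uid) {
      tibble(unified_id = uid, classification = res$classification,
             n_tips = length(res$tree$tip.label))
    })
    write_stage_tsv(tree_tbl, "trees", "classifications.tsv")
    tre_path <- file.path(stage_dir("trees"), "gene_trees.nwk")
    writeLines(c(stamp, vapply(tree_results, function(r) {
      ape::write.tree(r$tree)
    }, character(1))), tre_path)
  }

  # -- turnover -------------------------------------------------------
  turn <- in_stage("turnover", {
    tr <- ape::keep.tip(data$species_tree,
                        intersect(data$species_tree$tip.label,
                                  names(identities)))
    het <- setNames(if_else(systems$call %in% c("XY", "ZW"), systems$call,
                            NA_character_), systems$species_id)
    het <- het[intersect(tr$tip.label, names(het))]
    fit <- if (any(!is.na(identities[tr$tip.label]))) {
      fitch_min_changes(tr, identities[tr$tip.label])
    } else {
      NULL
    }
    shifts <- if (any(!is.na(het))) heterogamety_shifts(tr, het) else NULL
    list(fit = fit, shifts = shifts,
         n_identities = count_identities(identities))
  })
  turn_tbl <- tibble(
    quantity = c("turnover_events", "distinct_identities",
                 "heterogamety_shifts"),
    value = c(if (is.null(turn$fit)) NA_integer_ else turn$fit$min_changes,
              turn$n_identities,
              if (is.null(turn$shifts)) NA_integer_ else
                turn$shifts$min_changes)
  )
  write_stage_tsv(turn_tbl, "turnover", "turnover.tsv")

  summary <- list(
    config_hash = hash, seed = config$seed,
    n_species = length(data$catalogs),
    n_candidates = nrow(candidates),
    n_confirmed = nrow(confirmed),
    confirmed_per_species = as.list(table(confirmed$species_id)),
    system_calls = setNames(as.list(systems$call), systems$species_id),
    n_shared_markers = if (is.null(shared)) NA_integer_ else nrow(shared),
    identities = as.list(identities),
    tree_classifications = purrr::map_chr(tree_results, "classification"),
    turnover_events = turn_tbl$value[1],
    distinct_identities = turn_tbl$value[2],
    heterogamety_shifts = turn_tbl$value[3]
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(summary, class = "sexlink_run"))
}

# materialize catalogs/registry/reference either from the simulator or
# from input files
pipeline_data <- function(config) {
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_args$seed <- sim_args$seed %||% config$seed
    sim <- simulate_catalog(do.call(sim_config, sim_args))
    return(list(catalogs = sim$catalogs, registry = sim$registry,
                truth = sim$truth, reference = sim$reference,
                unified_map = sim$unified_map,
                species_tree = sim$species_tree, pools = list()))
  }
  inp <- config$inputs
  registry <- read_registry(inp$registry)
  catalogs <- purrr::imap(inp$catalogs, function(paths, sp) {
    read_catalog(paths$genotypes, paths$presence, paths$fasta)
  })
  reference <- NULL
  if (!is.null(inp$reference)) {
    reference <- reference_genome(sequences = read_fasta(inp$reference))
  }
  pools <- purrr::imap(inp$catalogs, function(paths, sp) {
    if (is.null(paths$male_pool) || is.null(paths$female_pool)) return(NULL)
    list(male = read_fasta(paths$male_pool),
         female = read_fasta(paths$female_pool))
  })
  unified_map <- NULL
  if (!is.null(inp$unified_map)) {
    unified_map <- readr::read_tsv(inp$unified_map, col_types =
      readr::cols(.default = readr::col_character()), progress = FALSE)
  }
  list(catalogs = catalogs, registry = registry, truth = NULL,
       reference = reference, unified_map = unified_map,
       species_tree = read_newick(inp$species_tree), pools = pools)
}

#' @export
print.sexlink_run <- function(x, ...) {
  cat(sprintf(
    "<sexlink_run> %d species, %d confirmed markers, %s turnover(s)\n",
    x$n_species, x$n_confirmed, x$turnover_events))
  invisible(x)
}
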