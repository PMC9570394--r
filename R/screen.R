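#' Thresholds for the sex-linkage screens
#'
#' Defaults reproduce the published filtering rules: a SNP site is a
#' candidate when it is heterozygous in at least one-third of the
#' heterogametic-sex samples and homozygous in at least one-third of the
#' homogametic-sex samples; a sex-limited tag must be completely absent in
#' the homogametic sex and present in at least half of the heterogametic
#' sex. All fraction boundaries are inclusive.
#'
#' @param min_frac_het_heterogametic Minimum fraction of genotyped
#'   heterogametic-sex individuals that are heterozygous (default 1/3).
#' @param min_frac_hom_homogametic Minimum fraction of genotyped
#'   homogametic-sex individuals that are homozygous (default 1/3).
#' @param min_frac_present_heterogametic Minimum fraction of
#'   heterogametic-sex individuals in which a sex-limited locus is present
#'   (default 1/2).
#' @param max_present_homogametic Maximum number of homogametic-sex
#'   individuals allowed to carry a sex-limited locus (default 0).
#' @param min_genotyped_per_sex Sites with fewer genotyped individuals of
#'   either sex are skipped (default 3). Fractions are computed over
#'   genotyped (non-missing) individuals.
#' @param strict_homogametic_het When `TRUE`, the heterozygosity screen
#'   additionally requires zero heterozygous individuals of the homogametic
#'   sex (off by default; the published rule imposes no such cap).
#' @param allele_freq_diff_cutoff Optional alternative predicate for the
#'   allele-frequency screen: instead of requiring an allele strictly absent
#'   from the homogametic sex, require a between-sex allele-frequency
#'   difference of at least this value.
#' @return List of class `screen_thresholds`.
#' @export
screen_thresholds <- function(min_frac_het_heterogametic = 1 / 3,
                              min_frac_hom_homogametic = 1 / 3,
                              min_frac_present_heterogametic = 1 / 2,
                              max_present_homogametic = 0L,
                              min_genotyped_per_sex = 3L,
                              strict_homogametic_het = FALSE,
                              allele_freq_diff_cutoff = NULL) {
  th <- list(
    min_frac_het_heterogametic = min_frac_het_heterogametic,
    min_frac_hom_homogametic = min_frac_hom_homogametic,
    min_frac_present_heterogametic = min_frac_present_heterogametic,
    max_present_homogametic = as.integer(max_present_homogametic),
    min_genotyped_per_sex = as.integer(min_genotyped_per_sex),
    strict_homogametic_het = strict_homogametic_het,
    allele_freq_diff_cutoff = allele_freq_diff_cutoff
  )
  fr <- c(th$min_frac_het_heterogametic, th$min_frac_hom_homogametic,
          th$min_frac_present_heterogametic)
  if (any(fr <= 0 | fr > 1)) abort("threshold fractions must be in (0, 1]")
  if (th$max_present_homogametic < 0) {
    abort("max_present_homogametic must be >= 0")
  }
  structure(th, class = "screen_thresholds")
}

# per-site, per-sex genotype class counts over genotyped individuals
site_sex_counts <- function(catalog, registry) {
  reg <- registry_for_catalog(registry, catalog)
  catalog$snps %>%
    dplyr::inner_join(reg %>% select("sample_id", "sex"), by = "sample_id") %>%
    filter(!is.na(.data$allele1)) %>%
    mutate(het = .data$allele1 != .data$allele2) %>%
    group_by(.data$locus_id, .data$column, .data$sex) %>%
    summarise(n_genotyped = dplyr::n(), n_het = sum(.data$het),
              n_hom = sum(!.data$het), .groups = "drop") %>%
    tidyr::pivot_wider(
      names_from = "sex",
      values_from = c("n_genotyped", "n_het", "n_hom"),
      values_fill = 0L
    ) %>%
    ensure_count_cols()
}

ensure_count_cols <- function(tab) {
  for (cn in c("n_genotyped_male", "n_genotyped_female", "n_het_male",
               "n_het_female", "n_hom_male", "n_hom_female")) {
    if (!cn %in% names(tab)) tab[[cn]] <- 0L
  }
  tab
}

# per-site, per-allele copy counts by sex
site_allele_counts <- function(catalog, registry) {
  reg <- registry_for_catalog(registry, catalog)
  catalog$snps %>%
    dplyr::inner_join(reg %>% select("sample_id", "sex"), by = "sample_id") %>%
    filter(!is.na(.data$allele1)) %>%
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") %>%
    count(.data$locus_id, .data$column, .data$sex, .data$allele,
          name = "copies") %>%
    tidyr::pivot_wider(names_from = "sex", values_from = "copies",
                       names_prefix = "copies_", values_fill = 0L)
}

candidate_skeleton <- function(counts, catalog, system, strategy) {
  counts %>%
    mutate(system = system, strategy = strategy,
           marker_id = sprintf("%s:%s:%s",
                               .data$locus_id,
                               if_else(is.na(.data$column), "tag",
                                       as.character(.data$column)),
                               system)) %>%
    left_join(catalog$consensus, by = "locus_id")
}

het_condition <- function(counts, system, th) {
  het_sex <- if (system == "XY") "male" else "female"
  hom_sex <- if (system == "XY") "female" else "male"
  ngh <- counts[[paste0("n_genotyped_", het_sex)]]
  ngo <- counts[[paste0("n_genotyped_", hom_sex)]]
  ok <- ngh >= th$min_genotyped_per_sex & ngo >= th$min_genotyped_per_sex
  pass <- ok &
    counts[[paste0("n_het_", het_sex)]] / ngh >=
      th$min_frac_het_heterogametic &
    counts[[paste0("n_hom_", hom_sex)]] / ngo >= th$min_frac_hom_homogametic
  if (isTRUE(th$strict_homogametic_het)) {
    pass <- pass & counts[[paste0("n_het_", hom_sex)]] == 0L
  }
  pass
}

#' Screen SNP sites for sex-linked heterozygosity patterns
#'
#' Flags a site as an XY-consistent candidate when the fraction of
#' heterozygous genotyped males and the fraction of homozygous genotyped
#' females both reach their thresholds, and as a ZW-consistent candidate
#' under the sex-swapped rule. A site passing both mirrored predicates
#' yields one row per system; downstream validation and the system call
#' resolve which expectation survives. Sites with fewer than
#' `min_genotyped_per_sex` genotyped individuals of either sex are skipped
#' (counted in the `n_skipped` attribute), never errored.
#'
#' @param catalog A [locus_catalog()].
#' @param registry Sex registry tibble (must cover the catalog samples with
#'   at least one individual of each sex).
#' @param thresholds A [screen_thresholds()].
#' @return Tibble of candidate markers with columns `marker_id`, `locus_id`,
#'   `column`, `strategy`, `system`, `sex_specific_allele`, the per-sex
#'   support counts, and the locus `consensus`.
#' @export
screen_heterozygosity <- function(catalog, registry,
                                  thresholds = screen_thresholds()) {
  counts <- site_sex_counts(catalog, registry)
  out <- list()
  for (system in c("XY", "ZW")) {
    pass <- het_condition(counts, system, thresholds)
    out[[system]] <- candidate_skeleton(counts[pass, , drop = FALSE],
                                        catalog, system, "heterozygosity") %>%
      mutate(sex_specific_allele = NA_character_)
  }
  skipped <- sum(counts$n_genotyped_male < thresholds$min_genotyped_per_sex |
                   counts$n_genotyped_female < thresholds$min_genotyped_per_sex)
  finalize_candidates(bind_rows(out), n_skipped = skipped)
}

#' Screen SNP sites for sex-limited alleles (allele-frequency strategy)
#'
#' The stricter companion of [screen_heterozygosity()]: besides the
#' heterozygosity conditions, an XY-consistent candidate must carry an
#' allele with zero copies among genotyped females and at least one copy
#' among genotyped males (the putative Y allele, recorded as
#' `sex_specific_allele`); ZW-consistent candidates mirror the sexes. When
#' `thresholds$allele_freq_diff_cutoff` is set, the zero-tolerance rule is
#' replaced by a between-sex allele-frequency difference of at least that
#' value.
#'
#' @inheritParams screen_heterozygosity
#' @return Candidate tibble as in [screen_heterozygosity()].
#' @export
screen_allele_frequency <- function(catalog, registry,
                                    thresholds = screen_thresholds()) {
  counts <- site_sex_counts(catalog, registry)
  alleles <- site_allele_counts(catalog, registry)
  for (cn in c("copies_male", "copies_female")) {
    if (!cn %in% names(alleles)) alleles[[cn]] <- 0L
  }
  out <- list()
  for (system in c("XY", "ZW")) {
    het_col <- if (system == "XY") "copies_male" else "copies_female"
    hom_col <- if (system == "XY") "copies_female" else "copies_male"
    if (is.null(thresholds$allele_freq_diff_cutoff)) {
      qual <- alleles %>%
        filter(.data[[hom_col]] == 0L, .data[[het_col]] > 0L)
    } else {
      qual <- alleles %>%
        group_by(.data$locus_id, .data$column) %>%
        mutate(freq_het = .data[[het_col]] / sum(.data[[het_col]]),
               freq_hom = .data[[hom_col]] / sum(.data[[hom_col]])) %>%
        ungroup() %>%
        filter(.data$freq_het - .data$freq_hom >=
                 thresholds$allele_freq_diff_cutoff)
    }
    qual <- qual %>%
      group_by(.data$locus_id, .data$column) %>%
      arrange(dplyr::desc(.data[[het_col]]), .data$allele) %>%
      slice(1) %>%
      ungroup() %>%
      select("locus_id", "column", sex_specific_allele = "allele")
    pass <- counts %>%
      filter(het_condition(counts, system, thresholds)) %>%
      dplyr::inner_join(qual, by = c("locus_id", "column"))
    out[[system]] <- candidate_skeleton(pass, catalog, system,
                                        "allele_frequency")
  }
  finalize_candidates(bind_rows(out))
}

#' Screen whole loci for sex-limited presence
#'
#' Flags a locus as XY-consistent (putative Y-limited tag) when it is
#' present in at most `max_present_homogametic` females (default: completely
#' absent) and present in at least half of the males; ZW-consistent under
#' the mirrored rule. Presence fractions are computed over all registry
#' individuals of the sex, since locus absence is itself the signal.
#'
#' @inheritParams screen_heterozygosity
#' @return Candidate tibble; `column` is `NA` for these whole-locus markers.
#' @export
screen_sex_limited <- function(catalog, registry,
                               thresholds = screen_thresholds()) {
  reg <- registry_for_catalog(registry, catalog)
  n_sex <- c(male = sum(reg$sex == "male"), female = sum(reg$sex == "female"))
  pres <- catalog$presence %>%
    dplyr::inner_join(reg %>% select("sample_id", "sex"), by = "sample_id") %>%
    group_by(.data$locus_id, .data$sex) %>%
    summarise(n_present = sum(.data$present), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "sex", values_from = "n_present",
                       names_prefix = "n_present_", values_fill = 0L)
  for (cn in c("n_present_male", "n_present_female")) {
    if (!cn %in% names(pres)) pres[[cn]] <- 0L
  }
  out <- list()
  for (system in c("XY", "ZW")) {
    het_sex <- if (system == "XY") "male" else "female"
    hom_sex <- if (system == "XY") "female" else "male"
    pass <- pres %>%
      filter(
        .data[[paste0("n_present_", hom_sex)]] <=
          thresholds$max_present_homogametic,
        .data[[paste0("n_present_", het_sex)]] / n_sex[[het_sex]] >=
          thresholds$min_frac_present_heterogametic
      ) %>%
      mutate(column = NA_integer_,
             n_male = n_sex[["male"]], n_female = n_sex[["female"]])
    out[[system]] <- candidate_skeleton(pass, catalog, system, "sex_limited") %>%
      mutate(sex_specific_allele = NA_character_)
  }
  finalize_candidates(bind_rows(out))
}

CANDIDATE_COLS <- c("marker_id", "locus_id", "column", "strategy", "system",
                    "sex_specific_allele", "n_genotyped_male",
                    "n_genotyped_female", "n_het_male", "n_het_female",
                    "n_hom_male", "n_hom_female", "n_present_male",
                    "n_present_female", "consensus")

finalize_candidates <- function(cand, n_skipped = 0L) {
  for (cn in CANDIDATE_COLS) {
    if (!cn %in% names(cand)) {
      cand[[cn]] <- if (cn %in% c("marker_id", "locus_id", "strategy",
                                  "system", "sex_specific_allele",
                                  "consensus")) NA_character_ else NA_integer_
    }
  }
  out <- cand %>%
    select(all_of(CANDIDATE_COLS)) %>%
    arrange(.data$locus_id, .data$column, .data$system)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Run all three screens on one catalog
#'
#' Convenience wrapper running [screen_heterozygosity()],
#' [screen_allele_frequency()], and [screen_sex_limited()] and binding the
#' candidate rows.
#'
#' @inheritParams screen_heterozygosity
#' @return Combined candidate tibble.
#' @export
screen_all <- function(catalog, registry,
                       thresholds = screen_thresholds()) {
  bind_rows(
    screen_heterozygosity(catalog, registry, thresholds),
    screen_allele_frequency(catalog, registry, thresholds),
    screen_sex_limited(catalog, registry, thresholds)
  )
}

#' Combine and deduplicate candidate sets from several datasets
#'
#' Candidates found in multiple assembly parameterizations (or by multiple
#' strategies) of the same species collapse on identical locus consensus
#' sequence, SNP column, sex-specific allele, and system; strategy tags and
#' dataset provenance are concatenated. Identical sites flagged under
#' conflicting systems are both retained with `system_conflict = TRUE` for
#' the validation stage to resolve.
#'
#' @param ... Candidate tibbles, ideally named (names become dataset tags).
#' @return Deduplicated candidate tibble with `strategies`, `datasets`, and
#'   `system_conflict` columns.
#' @export
combine_candidates <- function(...) {
  sets <- rlang::dots_list(..., .named = TRUE)
  tagged <- purrr::imap(sets, function(x, nm) mutate(x, dataset = nm))
  all <- bind_rows(tagged) %>%
    mutate(.col_key = if_else(is.na(.data$column), -1L, .data$column)) %>%
    # a strategy that records no sex-specific allele (e.g. heterozygosity)
    # merges with one that does, provided the recorded alleles agree
    group_by(.data$consensus, .data$.col_key, .data$system) %>%
    mutate(.allele_key = {
      a <- unique(stats::na.omit(.data$sex_specific_allele))
      if (length(a) <= 1) rep(c(a, ".")[1], dplyr::n())
      else dplyr::coalesce(.data$sex_specific_allele, ".")
    }) %>%
    ungroup()
  collapsed <- all %>%
    group_by(.data$consensus, .data$.col_key, .data$.allele_key,
             .data$system) %>%
    arrange(.data$dataset, .data$strategy) %>%
    summarise(
      marker_id = first(.data$marker_id),
      locus_id = first(.data$locus_id),
      column = first(.data$column),
      sex_specific_allele =
        c(as.character(stats::na.omit(.data$sex_specific_allele)),
          NA_character_)[1],
      strategies = paste(sort(unique(.data$strategy)), collapse = ","),
      datasets = paste(sort(unique(.data$dataset)), collapse = ","),
      across(dplyr::starts_with("n_"), ~ max(.x, na.rm = FALSE)),
      .groups = "drop"
    )
  collapsed %>%
    group_by(.data$consensus, .data$.col_key) %>%
    mutate(system_conflict = n_distinct(.data$system) > 1) %>%
    ungroup() %>%
    select(-".col_key", -".allele_key") %>%
    dplyr::relocate("marker_id", "locus_id", "column", "system",
                    "sex_specific_allele", "strategies", "datasets",
                    "system_conflict") %>%
    arrange(.data$locus_id, .data$column, .data$system)
}
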