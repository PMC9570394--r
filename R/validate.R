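count_occurrences <- function(pattern, pool, strand_aware = TRUE) {
  if (!length(pool)) return(0L)
  hits <- stringr::str_detect(pool, stringr::fixed(pattern))
  if (strand_aware) {
    hits <- hits | stringr::str_detect(pool, stringr::fixed(revcomp(pattern)))
  }
  sum(hits)
}

# index a read pool for alignment-style SNP verification: equal-length
# reads as a character matrix (other read lengths cannot align end-to-end
# with the built-in matcher and are ignored)
pool_index <- function(pool, L) {
  total_len <- sum(nchar(pool))
  keep <- pool[nchar(pool) == L]
  mat <- if (length(keep)) {
    do.call(rbind, strsplit(toupper(unname(keep)), "", fixed = TRUE))
  } else {
    matrix(character(0), 0, L)
  }
  list(mat = mat, total_len = total_len, L = L)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# for every pool read aligning to the locus consensus at E <= cutoff
# (ungapped, either strand), the read's base at the given 0-based column;
# NA for non-aligning reads
aligned_bases_at <- function(idx, consensus, column0, evalue_cutoff) {
  if (!nrow(idx$mat)) return(character(0))
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  cons_rc <- strsplit(revcomp(consensus), "", fixed = TRUE)[[1]]
  L <- idx$L
  qualifies <- function(mism) {
    bits <- 2 * (L - mism) - 3 * mism
    approx_evalue(idx$total_len, L, bits) <= evalue_cutoff
  }
  mism_f <- rowSums(idx$mat != matrix(cons, nrow(idx$mat), L, byrow = TRUE))
  mism_r <- rowSums(idx$mat != matrix(cons_rc, nrow(idx$mat), L,
                                      byrow = TRUE))
  base <- rep(NA_character_, nrow(idx$mat))
  fwd <- qualifies(mism_f)
  base[fwd] <- idx$mat[fwd, column0 + 1]
  # reads matching the minus strand: their base at the mirrored position,
  # complemented, is the plus-strand allele
  rev <- !fwd & qualifies(mism_r)
  base[rev] <- unname(COMPLEMENT[idx$mat[rev, L - column0]])
  base
}

#' Verify a candidate sex-linked SNP against sex-partitioned read pools
#'
#' Opposite-sex in-silico verification: a candidate is `confirmed` when (a)
#' the homogametic-sex pool contains no alignment at `E <= evalue_cutoff`
#' covering the SNP column with the sex-specific allele, and (b) at least
#' `min_het_occurrences` sequences of the heterogametic-sex pool do carry
#' it. With the built-in matcher, "carrying the allele" means the
#' full-length locus haplotype bearing the sex-specific allele occurs
#' exactly (either strand) in a pool sequence. Externally computed hit
#' tables (queries keyed by `marker_id`, one table per pool) may be supplied
#' instead, in which case any qualifying alignment covering the variable
#' base counts; the E-value cutoff applies to the supplied E-values
#' verbatim.
#'
#' Candidates without a recorded sex-specific allele (heterozygosity-only
#' markers) are verified on the presence of a second allele: if two or more
#' allele haplotypes of the site occur in the homogametic pool the marker is
#' rejected, otherwise an allele occurring only in the heterogametic pool
#' confirms it.
#'
#' @param marker One-row candidate tibble (as produced by the screens or
#'   [combine_candidates()]); SNP candidates need `consensus`, `column`,
#'   `system`, and ideally `sex_specific_allele`.
#' @param male_pool,female_pool Named character vectors of sequences (e.g.
#'   from [simulate_reads()] or read from FASTA).
#' @param evalue_cutoff E-value threshold for qualifying alignments.
#' @param hits_male,hits_female Optional hit tibbles from an external search
#'   of marker haplotypes against each pool.
#' @param min_het_occurrences Minimum supporting occurrences in the
#'   heterogametic pool (default 1).
#' @param alleles For allele-less markers, the site's alleles; derived from
#'   the marker's genotype support columns when absent, or supplied here.
#' @return One-row tibble: `marker_id`, `status` (`confirmed`,
#'   `rejected_homogametic_evidence`, `rejected_heterogametic_inconsistent`,
#'   `insufficient_data`), `n_het_occurrences`, `n_hom_occurrences`.
#' @export
verify_snp_marker <- function(marker, male_pool, female_pool,
                              evalue_cutoff = 1e-20,
                              hits_male = NULL, hits_female = NULL,
                              min_het_occurrences = 1, alleles = NULL) {
  stopifnot(nrow(marker) == 1)
  het_pool <- if (marker$system == "XY") male_pool else female_pool
  hom_pool <- if (marker$system == "XY") female_pool else male_pool
  hits_het <- if (marker$system == "XY") hits_male else hits_female
  hits_hom <- if (marker$system == "XY") hits_female else hits_male

  if (!is.null(hits_het) || !is.null(hits_hom)) {
    return(verify_snp_from_hits(marker, hits_het, hits_hom, evalue_cutoff,
                                min_het_occurrences))
  }
  L <- nchar(marker$consensus)
  idx_het <- pool_index(het_pool, L)
  idx_hom <- pool_index(hom_pool, L)
  verify_snp_indexed(marker, idx_het, idx_hom, evalue_cutoff,
                     min_het_occurrences, alleles)
}

verify_snp_indexed <- function(marker, idx_het, idx_hom, evalue_cutoff,
                               min_het_occurrences, alleles) {
  het_bases <- aligned_bases_at(idx_het, marker$consensus, marker$column,
                                evalue_cutoff)
  hom_bases <- aligned_bases_at(idx_hom, marker$consensus, marker$column,
                                evalue_cutoff)
  if (is.na(marker$sex_specific_allele %||% NA_character_)) {
    return(verify_snp_het_only(marker, het_bases, hom_bases,
                               min_het_occurrences, alleles))
  }
  n_hom <- sum(hom_bases == marker$sex_specific_allele, na.rm = TRUE)
  n_het <- sum(het_bases == marker$sex_specific_allele, na.rm = TRUE)
  status <- if (n_hom > 0) {
    "rejected_homogametic_evidence"
  } else if (n_het >= min_het_occurrences) {
    "confirmed"
  } else if (any(!is.na(het_bases)) || any(!is.na(hom_bases))) {
    "rejected_heterogametic_inconsistent"
  } else {
    "insufficient_data"
  }
  tibble(marker_id = marker$marker_id, status = status,
         n_het_occurrences = n_het, n_hom_occurrences = n_hom)
}

verify_snp_from_hits <- function(marker, hits_het, hits_hom, evalue_cutoff,
                                 min_het_occurrences) {
  covering <- function(hits) {
    if (is.null(hits) || !nrow(hits)) return(0L)
    hits %>%
      filter(.data$query_id == marker$marker_id,
             .data$e_value <= evalue_cutoff,
             .data$q_start <= marker$column + 1,
             .data$q_end >= marker$column + 1) %>%
      nrow()
  }
  n_hom <- covering(hits_hom)
  n_het <- covering(hits_het)
  status <- if (n_hom > 0) {
    "rejected_homogametic_evidence"
  } else if (n_het >= min_het_occurrences) {
    "confirmed"
  } else {
    "insufficient_data"
  }
  tibble(marker_id = marker$marker_id, status = status,
         n_het_occurrences = n_het, n_hom_occurrences = n_hom)
}

verify_snp_het_only <- function(marker, het_bases, hom_bases,
                                min_het_occurrences, alleles) {
  if (is.null(alleles)) {
    abort("marker has no sex_specific_allele; supply the site alleles")
  }
  in_hom <- vapply(alleles, function(a) sum(hom_bases == a, na.rm = TRUE),
                   integer(1))
  in_het <- vapply(alleles, function(a) sum(het_bases == a, na.rm = TRUE),
                   integer(1))
  status <- if (sum(in_hom > 0) >= 2) {
    # the homogametic sex carries a second allele at the variable base
    "rejected_homogametic_evidence"
  } else if (any(in_het >= min_het_occurrences & in_hom == 0)) {
    "confirmed"
  } else if (sum(in_het) + sum(in_hom) > 0) {
    "rejected_heterogametic_inconsistent"
  } else {
    "insufficient_data"
  }
  tibble(marker_id = marker$marker_id, status = status,
         n_het_occurrences = sum(in_het), n_hom_occurrences = sum(in_hom))
}

#' Verify a sex-limited tag against sex-partitioned read pools
#'
#' The candidate is `confirmed` when its locus consensus occurs as an exact
#' full-length substring of zero homogametic-pool sequences and of at least
#' one heterogametic-pool sequence. By default the check is strand-aware (a
#' reverse-complement occurrence counts); `strand_aware = FALSE` restores
#' literal forward-strand matching.
#'
#' @inheritParams verify_snp_marker
#' @param strand_aware Count reverse-complement occurrences (default TRUE).
#' @return One-row status tibble as in [verify_snp_marker()].
#' @export
verify_sex_limited_marker <- function(marker, male_pool, female_pool,
                                      strand_aware = TRUE,
                                      min_het_occurrences = 1) {
  stopifnot(nrow(marker) == 1)
  het_pool <- if (marker$system == "XY") male_pool else female_pool
  hom_pool <- if (marker$system == "XY") female_pool else male_pool
  if (!length(het_pool) && !length(hom_pool)) {
    return(tibble(marker_id = marker$marker_id, status = "insufficient_data",
                  n_het_occurrences = 0L, n_hom_occurrences = 0L))
  }
  n_hom <- count_occurrences(marker$consensus, hom_pool, strand_aware)
  n_het <- count_occurrences(marker$consensus, het_pool, strand_aware)
  status <- if (n_hom > 0) {
    "rejected_homogametic_evidence"
  } else if (n_het >= min_het_occurrences) {
    "confirmed"
  } else {
    "insufficient_data"
  }
  tibble(marker_id = marker$marker_id, status = status,
         n_het_occurrences = n_het, n_hom_occurrences = n_hom)
}

#' Verify a whole candidate table
#'
#' Dispatches every candidate row to [verify_snp_marker()] or
#' [verify_sex_limited_marker()] and returns the candidates with their
#' validation status attached.
#'
#' @param candidates Candidate tibble (screen or [combine_candidates()]
#'   output; rows with `NA` `column` are treated as sex-limited tags).
#' @inheritParams verify_snp_marker
#' @inheritParams verify_sex_limited_marker
#' @param catalog Optional [locus_catalog()] used to derive site alleles for
#'   heterozygosity-only markers.
#' @return `candidates` plus `status`, `n_het_occurrences`,
#'   `n_hom_occurrences`.
#' @export
verify_markers <- function(candidates, male_pool, female_pool,
                           evalue_cutoff = 1e-20, strand_aware = TRUE,
                           hits_male = NULL, hits_female = NULL,
                           min_het_occurrences = 1, catalog = NULL) {
  site_alleles <- NULL
  if (!is.null(catalog)) {
    site_alleles <- catalog$snps %>%
      filter(!is.na(.data$allele1)) %>%
      tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") %>%
      distinct(.data$locus_id, .data$column, .data$allele)
  }
  idx_cache <- new.env(parent = emptyenv())
  get_idx <- function(which_pool, pool, L) {
    key <- paste(which_pool, L)
    if (is.null(idx_cache[[key]])) idx_cache[[key]] <- pool_index(pool, L)
    idx_cache[[key]]
  }
  res <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    m <- candidates[i, ]
    if (is.na(m$column)) {
      verify_sex_limited_marker(m, male_pool, female_pool,
                                strand_aware = strand_aware,
                                min_het_occurrences = min_het_occurrences)
    } else if (!is.null(hits_male) || !is.null(hits_female)) {
      verify_snp_marker(m, male_pool, female_pool,
                        evalue_cutoff = evalue_cutoff,
                        hits_male = hits_male, hits_female = hits_female,
                        min_het_occurrences = min_het_occurrences)
    } else {
      alleles <- NULL
      if (is.na(m$sex_specific_allele) && !is.null(site_alleles)) {
        alleles <- site_alleles %>%
          filter(.data$locus_id == m$locus_id, .data$column == m$column) %>%
          pull("allele")
      }
      L <- nchar(m$consensus)
      idx_m <- get_idx("male", male_pool, L)
      idx_f <- get_idx("female", female_pool, L)
      verify_snp_indexed(m,
                         idx_het = if (m$system == "XY") idx_m else idx_f,
                         idx_hom = if (m$system == "XY") idx_f else idx_m,
                         evalue_cutoff = evalue_cutoff,
                         min_het_occurrences = min_het_occurrences,
                         alleles = alleles)
    }
  })
  dplyr::bind_cols(candidates, res %>% select(-"marker_id"))
}

#' Call the heterogametic system per species
#'
#' Counts confirmed XY-consistent and ZW-consistent markers per species and
#' tests the counts against the random expectation (an exact two-sided
#' binomial test of the XY count against p = 0.5) — the null under which
#' XY- and ZW-patterned false positives are equally likely. The majority
#' system is called when p < `alpha`; the excluded minority markers are
#' reported in `n_excluded`, not silently dropped.
#'
#' @param confirmed Tibble of confirmed markers with columns `species_id`
#'   and `system` (`"XY"`/`"ZW"`).
#' @param alpha Significance level (default 0.05).
#' @param species Optional character vector of all species to report;
#'   species without any confirmed marker then appear with zero counts and
#'   an `undetermined` call (p-value absent).
#' @return Tibble with one row per species: `species_id`, `n_confirmed_xy`,
#'   `n_confirmed_zw`, `p_value`, `call` (`XY`, `ZW`, or `undetermined`),
#'   `n_excluded`.
#' @export
call_system <- function(confirmed, alpha = 0.05, species = NULL) {
  counts <- confirmed %>%
    group_by(.data$species_id) %>%
    summarise(n_confirmed_xy = sum(.data$system == "XY"),
              n_confirmed_zw = sum(.data$system == "ZW"),
              .groups = "drop")
  if (!is.null(species)) {
    counts <- tibble(species_id = species) %>%
      left_join(counts, by = "species_id") %>%
      mutate(across(dplyr::starts_with("n_confirmed"),
                    ~ dplyr::coalesce(.x, 0L)))
  }
  counts %>%
    mutate(
      p_value = purrr::map2_dbl(
        .data$n_confirmed_xy, .data$n_confirmed_zw,
        function(x, z) {
          if (x + z == 0) return(NA_real_)
          binom.test(x, x + z, p = 0.5, alternative = "two.sided")$p.value
        }
      ),
      call = case_when(
        is.na(.data$p_value) | .data$p_value >= alpha ~ "undetermined",
        .data$n_confirmed_xy > .data$n_confirmed_zw ~ "XY",
        .data$n_confirmed_zw > .data$n_confirmed_xy ~ "ZW",
        TRUE ~ "undetermined"
      ),
      n_excluded = if_else(
        .data$call == "XY", .data$n_confirmed_zw,
        if_else(.data$call == "ZW", .data$n_confirmed_xy, 0L)
      )
    )
}

#' Find sex-linked markers shared across species
#'
#' Maps each species' confirmed markers to unified locus ids and reports,
#' for every unified locus, the set of species in which it is confirmed.
#'
#' @param confirmed Tibble with columns `species_id`, `locus_id` (confirmed
#'   markers per species).
#' @param unified_map Tibble mapping species-level loci to unified ids:
#'   columns `species_id`, `locus_id`, `unified_id`.
#' @param shared_only Keep only loci confirmed in at least two species
#'   (default TRUE).
#' @return Tibble `unified_id`, `n_species`, `species` (comma-joined,
#'   sorted); the attribute `max_sharing_set` holds the species set of the
#'   most widely shared locus.
#' @export
find_trans_species_markers <- function(confirmed, unified_map,
                                       shared_only = TRUE) {
  missing_sp <- setdiff(unique(confirmed$species_id),
                        unique(unified_map$species_id))
  if (length(missing_sp)) {
    abort(sprintf("species absent from unified catalog: %s",
                  paste(missing_sp, collapse = ", ")))
  }
  shared <- confirmed %>%
    distinct(.data$species_id, .data$locus_id) %>%
    dplyr::inner_join(unified_map, by = c("species_id", "locus_id")) %>%
    group_by(.data$unified_id) %>%
    summarise(n_species = n_distinct(.data$species_id),
              species = paste(sort(unique(.data$species_id)),
                              collapse = ","),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$n_species), .data$unified_id)
  if (shared_only) {
    report <- shared %>% filter(.data$n_species >= 2)
  } else {
    report <- shared
  }
  attr(report, "max_sharing_set") <-
    if (nrow(shared)) strsplit(shared$species[1], ",")[[1]] else character(0)
  report
}
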