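#' Rules for assigning markers to reference chromosomes
#'
#' Defaults follow the published mapping procedure: hits qualify at
#' `E <= 1e-20`, a best hit wins only when it is at least five orders of
#' magnitude below the next-best qualifying hit (or is the only qualifying
#' hit), and indirect mapping extends bridge-assembly hits by 2 kb of
#' scaffold sequence on each side.
#'
#' @param evalue_cutoff Maximum qualifying E-value (default 1e-20).
#' @param best_hit_gap_orders Minimum log10 gap between the best and
#'   next-best qualifying E-values (default 5; must be >= 0).
#' @param flank_length Bases of scaffold extracted on each side of a bridge
#'   hit (default 2000).
#' @return List of class `assignment_rules`.
#' @export
assignment_rules <- function(evalue_cutoff = 1e-20, best_hit_gap_orders = 5,
                             flank_length = 2000) {
  if (best_hit_gap_orders < 0) abort("best_hit_gap_orders must be >= 0")
  structure(list(evalue_cutoff = evalue_cutoff,
                 best_hit_gap_orders = best_hit_gap_orders,
                 flank_length = as.integer(flank_length)),
            class = "assignment_rules")
}

# log10 of an E-value with a finite floor, so order-of-magnitude gaps stay
# finite even when a search tool reports E = 0
log10_evalue <- function(e) log10(pmax(e, 1e-308))

#' Assign markers to chromosomes by the direct method
#'
#' Per query, hits at `E <= evalue_cutoff` qualify; the query is assigned to
#' the best qualifying hit's subject iff it is the only qualifying hit or
#' the next-best qualifying E-value is at least `best_hit_gap_orders`
#' orders of magnitude larger. Ties and sub-gap runners-up yield
#' `ambiguous_gap`; queries whose hits all fail the cutoff yield
#' `fails_evalue`; queries without hits yield `no_hit`. Output is invariant
#' to hit-row order (hits are sorted internally and ties broken
#' deterministically).
#'
#' @param hits Hit tibble ([read_hits()] / [match_sequences()] shape).
#' @param rules An [assignment_rules()].
#' @param markers Optional character vector of all marker ids, so markers
#'   with no hit rows still receive a `no_hit` record.
#' @param apply_gap Apply the best-hit-gap rule (default TRUE).
#' @return Tibble with one row per marker: `marker_id`, `status`
#'   (`assigned`, `no_hit`, `fails_evalue`, `ambiguous_gap`), `chromosome`,
#'   `position` (1-based subject start of the best hit), `best_evalue`,
#'   `next_evalue`, `gap_orders`, `method = "direct"`.
#' @export
assign_direct <- function(hits, rules = assignment_rules(), markers = NULL,
                          apply_gap = TRUE) {
  sorted <- hits %>%
    arrange(.data$query_id, .data$e_value, dplyr::desc(.data$bit_score),
            .data$subject_id, .data$s_start)
  per_query <- sorted %>%
    group_by(marker_id = .data$query_id) %>%
    summarise(
      n_hits = dplyr::n(),
      n_qualifying = sum(.data$e_value <= rules$evalue_cutoff),
      chromosome = .data$subject_id[1],
      position = .data$s_start[1],
      best_evalue = .data$e_value[1],
      next_evalue = if (dplyr::n() >= 2) .data$e_value[2] else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(
      gap_orders = if_else(is.na(.data$next_evalue), Inf,
                           log10_evalue(.data$next_evalue) -
                             log10_evalue(.data$best_evalue)),
      status = case_when(
        .data$n_qualifying == 0 ~ "fails_evalue",
        .data$n_qualifying == 1 ~ "assigned",
        !apply_gap ~ "assigned",
        .data$gap_orders >= rules$best_hit_gap_orders ~ "assigned",
        TRUE ~ "ambiguous_gap"
      ),
      chromosome = if_else(.data$status == "assigned", .data$chromosome,
                           NA_character_),
      position = if_else(.data$status == "assigned", .data$position,
                         NA_real_),
      method = "direct"
    ) %>%
    select("marker_id", "status", "chromosome", "position", "best_evalue",
           "next_evalue", "gap_orders", "method")
  if (!is.null(markers)) {
    missing <- setdiff(markers, per_query$marker_id)
    if (length(missing)) {
      per_query <- bind_rows(per_query, tibble(
        marker_id = missing, status = "no_hit", chromosome = NA_character_,
        position = NA_real_, best_evalue = NA_real_, next_evalue = NA_real_,
        gap_orders = NA_real_, method = "direct"
      ))
    }
  }
  per_query %>% arrange(.data$marker_id)
}

#' Extract flanking sequence around hits
#'
#' For each hit, returns the subject (plus-strand) sequence from
#' `flank_length` bases before the hit to `flank_length` bases after it,
#' clipped at the scaffold ends with the clipping recorded.
#'
#' @param hits Hit tibble (normalized ascending subject coordinates).
#' @param scaffolds Named character vector of scaffold sequences.
#' @param flank_length Bases on each side (default 2000).
#' @return Tibble `fragment_id` (query id), `subject_id`, `start`, `end`
#'   (1-based inclusive extracted interval), `clipped_left`,
#'   `clipped_right`, `sequence`.
#' @export
extract_flanks <- function(hits, scaffolds, flank_length = 2000) {
  missing <- setdiff(unique(hits$subject_id), names(scaffolds))
  if (length(missing)) {
    abort(sprintf("subject(s) absent from scaffold set: %s",
                  paste(missing, collapse = ", ")))
  }
  hits %>%
    mutate(
      scaffold_len = unname(nchar(scaffolds[.data$subject_id])),
      start = pmax(1, .data$s_start - flank_length),
      end = pmin(.data$scaffold_len, .data$s_end + flank_length),
      clipped_left = .data$start == 1 & .data$s_start - flank_length < 1,
      clipped_right = .data$end == .data$scaffold_len &
        .data$s_end + flank_length > .data$scaffold_len,
      sequence = unname(substr(scaffolds[.data$subject_id], .data$start,
                               .data$end))
    ) %>%
    select(fragment_id = "query_id", "subject_id", "start", "end",
           "clipped_left", "clipped_right", "sequence")
}

#' Assign markers by the two-step indirect method
#'
#' Markers are first placed on a bridge assembly (step 1: E-value rule; the
#' gap rule is optional there and off by default), their bridge hits are
#' extended by `flank_length` on each side, and the extended fragments are
#' aligned to the target genome (step 2: E-value and gap rules). A marker
#' inherits the chromosome of its extended fragment. `target_hits` must be
#' keyed by marker id (the fragment produced from each marker carries the
#' marker's id).
#'
#' @param bridge_hits Hit tibble of markers against the bridge assembly.
#' @param bridge_scaffolds Named character vector of bridge scaffold
#'   sequences (used to record flank clipping; may be `NULL` if the
#'   fragments were produced elsewhere).
#' @param target_hits Hit tibble of extended fragments against the target
#'   genome, queries keyed by marker id.
#' @param rules An [assignment_rules()].
#' @param markers Optional marker id vector for complete `no_hit` records.
#' @param gap_at_bridge Apply the best-hit-gap rule at step 1 too
#'   (default FALSE).
#' @return Assignment tibble as in [assign_direct()] with
#'   `method = "indirect"` and a `stage` column saying where unassigned
#'   markers failed (`"bridge"` or `"target"`).
#' @export
assign_indirect <- function(bridge_hits, bridge_scaffolds, target_hits,
                            rules = assignment_rules(), markers = NULL,
                            gap_at_bridge = FALSE) {
  step1 <- assign_direct(bridge_hits, rules, markers = markers,
                         apply_gap = gap_at_bridge)
  bridged <- step1 %>% filter(.data$status == "assigned")
  step2 <- assign_direct(
    target_hits %>% filter(.data$query_id %in% bridged$marker_id),
    rules, markers = bridged$marker_id, apply_gap = TRUE
  )
  failed1 <- step1 %>%
    filter(.data$status != "assigned") %>%
    mutate(stage = "bridge")
  step2 %>%
    mutate(stage = "target") %>%
    left_join(bridged %>% select("marker_id", bridge_subject = "chromosome"),
              by = "marker_id") %>%
    bind_rows(failed1) %>%
    mutate(method = "indirect") %>%
    arrange(.data$marker_id)
}

#' Test whether assigned markers concentrate on particular chromosomes
#'
#' For each chromosome, a one-sided exact binomial test of the number of
#' assigned markers against the proportional expectation (chromosome length
#' over total chromosome length), Holm-adjusted across chromosomes. The
#' published analyses assert (non-)concentration without naming a test;
#' this binomial/Holm procedure is this package's operationalization.
#'
#' @param assignments Assignment tibble ([assign_direct()] /
#'   [assign_indirect()] output).
#' @param genome A [reference_genome()] (only its `chromosomes` enter the
#'   test) or a named vector of chromosome lengths.
#' @param alpha Significance level recorded on the report (default 0.05).
#' @return Object of class `concentration_report`: a list with `table`
#'   (per-chromosome counts, expected fractions, raw and adjusted p),
#'   `n_assigned`, `n_markers`, `fraction_unassigned`, `alpha`, and
#'   `tested` (FALSE when nothing was assigned, in which case the test is
#'   skipped).
#' @export
concentration_test <- function(assignments, genome, alpha = 0.05) {
  if (inherits(genome, "reference_genome")) {
    lengths <- genome$lengths[genome$chromosomes]
  } else {
    lengths <- genome
  }
  assigned <- assignments %>%
    filter(.data$status == "assigned", .data$chromosome %in% names(lengths))
  n_assigned <- nrow(assigned)
  n_markers <- nrow(assignments)
  counts <- tibble(chromosome = names(lengths),
                   length = as.numeric(lengths)) %>%
    left_join(assigned %>% count(.data$chromosome, name = "n_assigned"),
              by = "chromosome") %>%
    mutate(n_assigned = dplyr::coalesce(.data$n_assigned, 0L),
           expected_frac = .data$length / sum(.data$length))
  n_tot <- n_assigned
  if (n_assigned > 0) {
    counts <- counts %>%
      mutate(
        p_value = purrr::map2_dbl(.data$n_assigned, .data$expected_frac,
          ~ binom.test(.x, n_tot, .y, alternative = "greater")$p.value),
        p_adjusted = p.adjust(.data$p_value, method = "holm")
      )
  } else {
    counts <- counts %>%
      mutate(p_value = NA_real_, p_adjusted = NA_real_)
  }
  structure(list(
    table = counts, n_assigned = n_assigned, n_markers = n_markers,
    fraction_unassigned =
      if (n_markers) 1 - n_assigned / n_markers else NA_real_,
    alpha = alpha, tested = n_assigned > 0
  ), class = "concentration_report")
}

#' @export
print.concentration_report <- function(x, ...) {
  cat(sprintf(
    "<concentration_report> %d/%d markers assigned (%.1f%% unassigned)\n",
    x$n_assigned, x$n_markers, 100 * x$fraction_unassigned))
  if (x$tested) {
    sig <- x$table %>% filter(.data$p_adjusted < x$alpha)
    if (nrow(sig)) {
      cat("concentrated on:",
          paste(sprintf("%s (adj p = %.3g)", sig$chromosome, sig$p_adjusted),
                collapse = ", "), "\n")
    } else {
      cat(sprintf("no chromosome significant at alpha = %g\n", x$alpha))
    }
  } else {
    cat("test skipped: no assigned markers\n")
  }
  invisible(x)
}

#' Label markers hitting sex-determination candidate genes
#'
#' Joins a hit table of markers against candidate-gene sequences (e.g.
#' AMH, AR, CYP17, CYP19A1, DMRT1, FOXL2, SOX3, SF1) and labels each marker
#' with its best qualifying gene hit.
#'
#' @param hits Hit tibble of markers vs. gene sequences.
#' @param evalue_cutoff Maximum qualifying E-value (default 1e-20).
#' @param min_identity Minimum percent identity (default 77).
#' @param markers Optional marker id vector; markers without a qualifying
#'   hit then appear with `gene = NA`.
#' @return Tibble `marker_id`, `gene`, `percent_identity`, `e_value`,
#'   `s_start`, `s_end` (subject coordinates of the hit on the gene).
#' @export
annotate_candidate_genes <- function(hits, evalue_cutoff = 1e-20,
                                     min_identity = 77, markers = NULL) {
  best <- hits %>%
    filter(.data$e_value <= evalue_cutoff,
           .data$percent_identity >= min_identity) %>%
    arrange(.data$query_id, .data$e_value, dplyr::desc(.data$bit_score)) %>%
    group_by(.data$query_id) %>%
    slice(1) %>%
    ungroup() %>%
    select(marker_id = "query_id", gene = "subject_id",
           "percent_identity", "e_value", "s_start", "s_end")
  if (!is.null(markers)) {
    best <- tibble(marker_id = markers) %>%
      left_join(best, by = "marker_id")
  }
  best
}
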