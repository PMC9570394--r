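#' Construct a locus catalog
#'
#' A locus catalog holds, for one species (or one unified assembly), the
#' consensus sequence of every locus, the per-individual diploid genotypes at
#' every SNP site, and the per-individual presence/absence (with read depth)
#' of every locus. It is the in-memory form of the tag-based genotype tables
#' produced by reduced-representation assemblers.
#'
#' @param consensus Tibble with columns `locus_id`, `consensus` (DNA string).
#' @param snps Long tibble with columns `locus_id`, `column` (0-based offset
#'   into the consensus), `sample_id`, `allele1`, `allele2`. A missing
#'   genotype is a row with both alleles `NA`.
#' @param presence Tibble with columns `locus_id`, `sample_id`, `present`
#'   (logical), `depth` (non-negative integer; 0 when absent).
#' @param samples Ordered character vector of sample ids.
#' @return An object of class `locus_catalog`.
#' @export
locus_catalog <- function(consensus, snps, presence, samples) {
  consensus <- as_tibble(consensus)
  snps <- as_tibble(snps)
  presence <- as_tibble(presence)
  if (anyDuplicated(consensus$locus_id)) {
    dup <- consensus$locus_id[duplicated(consensus$locus_id)][1]
    abort(sprintf("duplicate locus id '%s' in catalog", dup))
  }
  bad_sample <- setdiff(
    unique(c(snps$sample_id, presence$sample_id)), samples
  )
  if (length(bad_sample)) {
    abort(sprintf(
      "genotype/presence tables reference unknown sample(s): %s",
      paste(bad_sample, collapse = ", ")
    ))
  }
  bad_locus <- setdiff(unique(c(snps$locus_id, presence$locus_id)),
                       consensus$locus_id)
  if (length(bad_locus)) {
    abort(sprintf(
      "tables reference locus id(s) absent from consensus set: %s",
      paste(bad_locus, collapse = ", ")
    ))
  }
  lens <- setNames(nchar(consensus$consensus), consensus$locus_id)
  if (nrow(snps) && any(snps$column >= lens[snps$locus_id] | snps$column < 0)) {
    abort("SNP column offsets must lie within the locus consensus")
  }
  # presence FALSE implies all genotypes at that sample are missing
  if (nrow(snps)) {
    absent <- presence %>% filter(!.data$present)
    viol <- snps %>%
      filter(!is.na(.data$allele1)) %>%
      semi_join(absent, by = c("locus_id", "sample_id"))
    if (nrow(viol)) {
      abort(sprintf(
        "called genotype at locus '%s' for sample '%s' absent from that individual",
        viol$locus_id[1], viol$sample_id[1]
      ))
    }
  }
  structure(
    list(consensus = consensus, snps = snps, presence = presence,
         samples = samples),
    class = "locus_catalog"
  )
}

#' @export
print.locus_catalog <- function(x, ...) {
  cat(sprintf(
    "<locus_catalog> %d loci, %d samples, %d SNP sites\n",
    nrow(x$consensus), length(x$samples),
    nrow(distinct(x$snps, .data$locus_id, .data$column))
  ))
  invisible(x)
}

MISSING_GENOTYPE <- "./."

#' Read a locus catalog from genotype, presence, and consensus files
#'
#' The genotype table is tab-separated with columns `locus_id`, `column`
#' (0-based SNP offset), then one column per sample holding diploid genotype
#' calls written `A/T`; `./.` (or any cell with characters outside A/C/G/T)
#' is treated as missing. The presence table is tab-separated with
#' `locus_id` followed by one integer read-depth column per sample; depth 0
#' means the locus was not recovered in that individual. Consensus sequences
#' come from a FASTA file keyed by locus id.
#'
#' @param genotype_path,presence_path,fasta_path File paths.
#' @param samples Optional character vector of expected sample ids; any
#'   sample column not in this list is a hard error.
#' @return A [locus_catalog()].
#' @export
read_catalog <- function(genotype_path, presence_path, fasta_path,
                         samples = NULL) {
  cons_seqs <- read_fasta(fasta_path)
  gt <- readr::read_tsv(genotype_path, col_types = readr::cols(
    locus_id = readr::col_character(), column = readr::col_integer(),
    .default = readr::col_character()
  ), progress = FALSE)
  pres <- readr::read_tsv(presence_path, col_types = readr::cols(
    locus_id = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE)
  gt_samples <- setdiff(names(gt), c("locus_id", "column"))
  pres_samples <- setdiff(names(pres), "locus_id")
  if (!identical(sort(gt_samples), sort(pres_samples))) {
    abort("genotype and presence tables declare different sample sets")
  }
  if (!is.null(samples)) {
    unknown <- setdiff(gt_samples, samples)
    if (length(unknown)) {
      abort(sprintf("unknown sample(s) in tables: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  if (anyDuplicated(pres$locus_id)) {
    abort(sprintf("duplicate locus id '%s' in presence table",
                  pres$locus_id[duplicated(pres$locus_id)][1]))
  }
  key <- paste(gt$locus_id, gt$column)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate SNP site row '%s' in genotype table",
                  key[duplicated(key)][1]))
  }
  snps <- gt %>%
    tidyr::pivot_longer(all_of(gt_samples), names_to = "sample_id",
                        values_to = "genotype") %>%
    mutate(
      genotype = toupper(.data$genotype),
      valid = stringr::str_detect(.data$genotype, "^[ACGT]/[ACGT]$"),
      allele1 = if_else(.data$valid,
                        stringr::str_sub(.data$genotype, 1, 1),
                        NA_character_),
      allele2 = if_else(.data$valid,
                        stringr::str_sub(.data$genotype, 3, 3),
                        NA_character_)
    ) %>%
    select("locus_id", "column", "sample_id", "allele1", "allele2")
  presence <- pres %>%
    tidyr::pivot_longer(all_of(pres_samples), names_to = "sample_id",
                        values_to = "depth") %>%
    mutate(present = .data$depth > 0L) %>%
    select("locus_id", "sample_id", "present", "depth")
  consensus <- tibble(locus_id = names(cons_seqs),
                      consensus = unname(cons_seqs))
  locus_catalog(consensus, snps, presence, samples %||% gt_samples)
}

#' Write a locus catalog back to its three on-disk files
#'
#' Inverse of [read_catalog()]; `write_catalog()` followed by
#' `read_catalog()` round-trips the tables byte-identically.
#'
#' @param catalog A [locus_catalog()].
#' @inheritParams read_catalog
#' @return Invisibly, `catalog`.
#' @export
write_catalog <- function(catalog, genotype_path, presence_path, fasta_path) {
  stopifnot(inherits(catalog, "locus_catalog"))
  gt <- catalog$snps %>%
    mutate(genotype = if_else(is.na(.data$allele1), MISSING_GENOTYPE,
                              paste0(.data$allele1, "/", .data$allele2))) %>%
    select("locus_id", "column", "sample_id", "genotype") %>%
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = "genotype") %>%
    arrange(.data$locus_id, .data$column)
  # keep the declared sample order even if pivot reordered nothing
  gt <- gt[, c("locus_id", "column",
               intersect(catalog$samples, names(gt)))]
  pres <- catalog$presence %>%
    select("locus_id", "sample_id", "depth") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "depth") %>%
    arrange(.data$locus_id)
  pres <- pres[, c("locus_id", intersect(catalog$samples, names(pres)))]
  readr::write_tsv(gt, genotype_path, progress = FALSE)
  readr::write_tsv(pres, presence_path, progress = FALSE)
  write_fasta(setNames(catalog$consensus$consensus,
                       catalog$consensus$locus_id), fasta_path)
  invisible(catalog)
}

#' Read a sample-to-sex registry
#'
#' @param path Tab-separated file with header columns `sample_id`,
#'   `species_id`, `sex`.
#' @param sex_codes Named character vector mapping the normalized sexes to
#'   their input codes (default `c(male = "M", female = "F")`); matching is
#'   case-insensitive.
#' @return Tibble with columns `sample_id`, `species_id`, `sex` (factor with
#'   levels `male`, `female`).
#' @export
read_registry <- function(path, sex_codes = c(male = "M", female = "F")) {
  reg <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!all(c("sample_id", "species_id", "sex") %in% names(reg))) {
    abort("registry needs columns sample_id, species_id, sex")
  }
  if (nrow(reg) == 0) abort("registry file is empty")
  if (anyDuplicated(reg$sample_id)) {
    abort(sprintf("duplicate sample id '%s' in registry",
                  reg$sample_id[duplicated(reg$sample_id)][1]))
  }
  decode <- setNames(names(sex_codes), toupper(sex_codes))
  sex <- decode[toupper(reg$sex)]
  if (anyNA(sex)) {
    bad <- which(is.na(sex))[1]
    abort(sprintf("unknown sex code '%s' in registry line %d",
                  reg$sex[bad], bad + 1L))
  }
  tibble(sample_id = reg$sample_id, species_id = reg$species_id,
         sex = factor(unname(sex), levels = c("male", "female")))
}

# registry rows applying to one catalog, with the >=1 of each sex guard
registry_for_catalog <- function(registry, catalog) {
  reg <- registry %>% filter(.data$sample_id %in% catalog$samples)
  if (nrow(reg) == 0) abort("no registry entries match the catalog samples")
  tab <- table(reg$sex)
  if (any(tab == 0)) {
    abort("catalog must include at least one male and one female sample")
  }
  reg
}

HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end",
                 "e_value", "bit_score")

#' Read a 12-column tabular sequence-search hit file
#'
#' Standard headerless tabular search output (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score). Minus-strand hits (subject start
#' greater than subject end) are normalized at parse time to ascending
#' subject coordinates plus a `strand` flag.
#'
#' @param path File path.
#' @return Tibble with the 12 standard columns (1-based inclusive
#'   coordinates) plus `strand` (`"+"`/`"-"`).
#' @export
read_hits <- function(path) {
  raw <- suppressWarnings(readr::read_tsv(path, col_names = HIT_COLUMNS,
    col_types = readr::cols(
      query_id = readr::col_character(),
      subject_id = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(sprintf("malformed hit row at line %d of %s", probs$row[1], path))
  }
  bad <- which(is.na(raw$e_value) | raw$e_value < 0)
  if (length(bad)) {
    abort(sprintf("invalid E-value at line %d of %s", bad[1], path))
  }
  normalize_hits(raw)
}

normalize_hits <- function(hits) {
  hits %>%
    mutate(
      strand = if_else(.data$s_start <= .data$s_end, "+", "-"),
      s_lo = pmin(.data$s_start, .data$s_end),
      s_hi = pmax(.data$s_start, .data$s_end),
      s_start = .data$s_lo, s_end = .data$s_hi
    ) %>%
    select(-"s_lo", -"s_hi")
}

#' Write hits in the 12-column tabular format
#'
#' Minus-strand rows are emitted with descending subject coordinates, undoing
#' the normalization applied by [read_hits()].
#'
#' @param hits Hit tibble as returned by [read_hits()] or
#'   [match_sequences()].
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  out <- hits %>%
    mutate(
      tmp_lo = .data$s_start, tmp_hi = .data$s_end,
      s_start = if_else(.data$strand == "-", .data$tmp_hi, .data$tmp_lo),
      s_end = if_else(.data$strand == "-", .data$tmp_lo, .data$tmp_hi)
    ) %>%
    select(all_of(HIT_COLUMNS))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(hits)
}

#' Read / write FASTA as a named character vector
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80L
  )
  invisible(seqs)
}

#' Read / write Newick trees
#'
#' Thin wrappers over ape keeping internal-node support labels intact; the
#' writer emits bootstrap supports as internal-node labels.
#'
#' @param path File path, or for `read_newick` a literal Newick string via
#'   `text`.
#' @param text Optional Newick string.
#' @return `read_newick()` returns an `ape::phylo`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) abort("could not parse Newick input")
  tr
}

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(tree)
}

#' Construct a reference genome object
#'
#' @param sequences Named character vector of scaffold/chromosome sequences
#'   (may be `NULL` when only lengths are known).
#' @param lengths Named integer vector of sequence lengths; derived from
#'   `sequences` when omitted.
#' @param chromosomes Character vector naming which sequences are assembled
#'   chromosomes (defaults to all).
#' @return Object of class `reference_genome`.
#' @export
reference_genome <- function(sequences = NULL, lengths = NULL,
                             chromosomes = NULL) {
  if (is.null(lengths)) {
    if (is.null(sequences)) abort("supply sequences or lengths")
    lengths <- setNames(nchar(sequences), names(sequences))
  }
  if (!is.null(sequences)) {
    if (!setequal(names(sequences), names(lengths)) ||
        any(nchar(sequences)[names(lengths)] != lengths)) {
      abort("lengths inconsistent with sequences")
    }
  }
  chromosomes <- chromosomes %||% names(lengths)
  if (!all(chromosomes %in% names(lengths))) {
    abort("chromosome names must be a subset of sequence names")
  }
  structure(list(sequences = sequences,
                 lengths = setNames(as.integer(lengths), names(lengths)),
                 chromosomes = chromosomes),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %d sequences (%d chromosomes), %.2f Mb\n",
              length(x$lengths), length(x$chromosomes),
              sum(as.numeric(x$lengths)) / 1e6))
  invisible(x)
}
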