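snp_marker_fixture <- function() {
  fx <- site_catalog(rep("T/A", 10), rep("T/T", 10))
  cand <- screen_allele_frequency(fx$catalog, fx$registry) |>
    dplyr::filter(system == "XY")
  x_hap <- cand$consensus                 # T at the variable base
  y_hap <- cand$consensus
  substr(y_hap, 11, 11) <- "A"            # sex-specific allele at column 10
  list(marker = cand, x_hap = x_hap, y_hap = y_hap)
}

test_that("opposite-sex verification applies the variable-base rule", {
  fx <- snp_marker_fixture()
  # Y haplotype in five male reads, absent from females -> confirmed
  res <- verify_snp_marker(fx$marker,
                           male_pool = setNames(rep(fx$y_hap, 5),
                                                paste0("m", 1:5)),
                           female_pool = setNames(rep(fx$x_hap, 5),
                                                  paste0("f", 1:5)))
  expect_equal(res$status, "confirmed")
  expect_equal(res$n_het_occurrences, 5L)

  # one Y-allele copy planted in a female read -> rejected
  res <- verify_snp_marker(fx$marker,
                           male_pool = setNames(rep(fx$y_hap, 5),
                                                paste0("m", 1:5)),
                           female_pool = setNames(c(fx$y_hap, fx$x_hap),
                                                  c("f1", "f2")))
  expect_equal(res$status, "rejected_homogametic_evidence")

  # nothing aligns in either pool -> insufficient data
  res <- verify_snp_marker(fx$marker,
                           male_pool = c(r = strrep("G", 150)),
                           female_pool = c(r = strrep("G", 150)))
  expect_equal(res$status, "insufficient_data")
})

test_that("verification accepts externally computed hit tables", {
  fx <- snp_marker_fixture()
  hit_row <- function(q, e, qs = 1, qe = 30) {
    tibble::tibble(query_id = q, subject_id = "db", percent_identity = 100,
                   alignment_length = 30, mismatches = 0, gap_opens = 0,
                   q_start = qs, q_end = qe, s_start = 1, s_end = 30,
                   e_value = e, bit_score = 60, strand = "+")
  }
  m <- fx$marker
  # qualifying female alignment covering the SNP column -> rejected
  res <- verify_snp_marker(m, character(0), character(0),
                           hits_male = hit_row(m$marker_id, 1e-30),
                           hits_female = hit_row(m$marker_id, 1e-30))
  expect_equal(res$status, "rejected_homogametic_evidence")
  # female alignment above the E-value cutoff does not count
  res <- verify_snp_marker(m, character(0), character(0),
                           hits_male = hit_row(m$marker_id, 1e-30),
                           hits_female = hit_row(m$marker_id, 1e-10))
  expect_equal(res$status, "confirmed")
  # female alignment not covering the variable base does not count
  res <- verify_snp_marker(m, character(0), character(0),
                           hits_male = hit_row(m$marker_id, 1e-30),
                           hits_female = hit_row(m$marker_id, 1e-30,
                                                 qs = 15, qe = 30))
  expect_equal(res$status, "confirmed")
})

test_that("sex-limited verification is an exact, strand-aware grep", {
  marker <- tibble::tibble(marker_id = "L9:tag:XY", locus_id = "L9",
                           column = NA_integer_, system = "XY",
                           consensus = "ACGTACGTACGTTGCA")
  flank <- function(s) paste0("GG", s, "TT")
  # consensus verbatim inside a female read -> rejected
  res <- verify_sex_limited_marker(marker,
                                   male_pool = c(m = flank(marker$consensus)),
                                   female_pool = c(f = flank(marker$consensus)))
  expect_equal(res$status, "rejected_homogametic_evidence")
  # male pool only -> confirmed
  res <- verify_sex_limited_marker(marker,
                                   male_pool = c(m = flank(marker$consensus)),
                                   female_pool = c(f = strrep("A", 30)))
  expect_equal(res$status, "confirmed")
  # reverse complement in a female read: rejected when strand-aware,
  # invisible to the literal grep mode
  rc_pool <- c(f = flank(revcomp(marker$consensus)))
  res <- verify_sex_limited_marker(marker,
                                   male_pool = c(m = flank(marker$consensus)),
                                   female_pool = rc_pool)
  expect_equal(res$status, "rejected_homogametic_evidence")
  res <- verify_sex_limited_marker(marker,
                                   male_pool = c(m = flank(marker$consensus)),
                                   female_pool = rc_pool,
                                   strand_aware = FALSE)
  expect_equal(res$status, "confirmed")
  # empty pools
  res <- verify_sex_limited_marker(marker, character(0), character(0))
  expect_equal(res$status, "insufficient_data")
})

test_that("confirmation is monotone in homogametic evidence", {
  fx <- snp_marker_fixture()
  female_pool <- setNames(rep(fx$x_hap, 6), paste0("f", 1:6))
  male_pool <- setNames(rep(fx$y_hap, 4), paste0("m", 1:4))
  full <- verify_snp_marker(fx$marker, male_pool, female_pool)
  expect_equal(full$status, "confirmed")
  for (k in c(4, 2, 0)) {
    sub <- verify_snp_marker(fx$marker, male_pool, female_pool[seq_len(k)])
    expect_equal(sub$status, "confirmed")
  }
})

test_that("the system call is an exact two-sided binomial test", {
  conf <- tibble::tibble(
    species_id = rep("s1", 42),
    system = rep(c("XY", "ZW"), c(40, 2))
  )
  res <- call_system(conf)
  # oracle: two-sided exact binomial tail sum for 40 of 42 at p = 1/2
  p_oracle <- sum(dbinom(c(0:2, 40:42), 42, 0.5))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$call, "XY")
  expect_equal(res$n_excluded, 2L)

  tie <- call_system(tibble::tibble(species_id = "s",
                                    system = rep(c("XY", "ZW"), 5)))
  expect_equal(tie$call, "undetermined")

  # a species with no confirmed marker of either kind
  zero <- call_system(tibble::tibble(species_id = character(0),
                                     system = character(0)),
                      species = "s")
  expect_equal(zero$call, "undetermined")
  expect_true(is.na(zero$p_value))
})

test_that("trans-species sharing reports the right sharing sets", {
  unified <- tibble::tibble(
    species_id = rep(c("a", "b", "c"), each = 3),
    locus_id = c("a1", "a2", "shared", "b1", "b2", "shared",
                 "c1", "c2", "c3"),
    unified_id = c("u1", "u2", "U", "u3", "u4", "U", "u5", "u6", "u7")
  )
  conf <- tibble::tibble(species_id = c("a", "b", "c"),
                         locus_id = c("shared", "shared", "c1"))
  rep1 <- find_trans_species_markers(conf, unified)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$unified_id, "U")
  expect_equal(rep1$n_species, 2L)
  expect_equal(rep1$species, "a,b")
  expect_equal(attr(rep1, "max_sharing_set"), c("a", "b"))

  # no sharing -> empty report
  conf2 <- tibble::tibble(species_id = c("a", "b"),
                          locus_id = c("a1", "b1"))
  expect_equal(nrow(find_trans_species_markers(conf2, unified)), 0)

  # a species missing from the unified catalog is an error
  conf3 <- tibble::tibble(species_id = "zz", locus_id = "x")
  expect_error(find_trans_species_markers(conf3, unified), "zz")
})

test_that("verify_markers confirms planted loci and rejects chance patterns", {
  sim <- simulate_catalog(sim_config(
    species = c("a", "b"), n_males = 8, n_females = 8,
    n_autosomal_loci = 60, n_xy_snp_loci = 15, n_y_limited_loci = 5,
    species_tree = "(a:1,b:1);", genotyping_error_rate = 0,
    locus_dropout_rate = 0, seed = 21
  ))
  cat_a <- sim$catalogs$a
  cand <- screen_all(cat_a, sim$registry)
  pools <- simulate_reads(cat_a, sim$registry)
  ver <- verify_markers(cand, pools$male, pools$female, catalog = cat_a)
  truth <- dplyr::filter(sim$truth, species_id == "a", sex_linked)
  confirmed_loci <- unique(ver$locus_id[ver$status == "confirmed" &
                                          ver$system == "XY"])
  expect_true(all(truth$locus_id %in% confirmed_loci))
  # every autosomal XY-flagged SNP whose minor allele shows up in a female
  # read is rejected
  aut <- dplyr::filter(ver, system == "XY",
                       !locus_id %in% truth$locus_id,
                       strategy %in% c("heterozygosity", "allele_frequency"))
  expect_true(all(aut$status != "confirmed" | aut$n_hom_occurrences == 0))
})
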