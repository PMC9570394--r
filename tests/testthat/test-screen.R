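test_that("the textbook T/A pattern is flagged as an XY candidate", {
  fx <- site_catalog(rep("T/A", 10), rep("T/T", 10))
  cand <- screen_heterozygosity(fx$catalog, fx$registry)
  xy <- dplyr::filter(cand, system == "XY")
  expect_equal(nrow(xy), 1)
  expect_equal(xy$n_het_male, 10L)
  expect_equal(xy$n_hom_female, 10L)
  af <- dplyr::filter(screen_allele_frequency(fx$catalog, fx$registry),
                      system == "XY")
  expect_equal(af$sex_specific_allele, "A")
})

test_that("uninformative sites are not flagged", {
  hom <- site_catalog(rep("T/T", 10), rep("T/T", 10))
  expect_equal(nrow(screen_heterozygosity(hom$catalog, hom$registry)), 0)
  expect_equal(nrow(screen_allele_frequency(hom$catalog, hom$registry)), 0)
})

test_that("the one-third boundaries are inclusive", {
  fx <- site_catalog(c(rep("T/A", 4), rep("T/T", 8)),
                     c(rep("T/T", 4), rep("T/A", 8)))
  cand <- screen_heterozygosity(fx$catalog, fx$registry)
  expect_true("XY" %in% cand$system)   # 4/12 het males, 4/12 hom females
  # 3/12 falls below one third
  fx2 <- site_catalog(c(rep("T/A", 3), rep("T/T", 9)),
                      c(rep("T/T", 4), rep("T/A", 8)))
  expect_false("XY" %in%
                 screen_heterozygosity(fx2$catalog, fx2$registry)$system)
})

test_that("allele-frequency screen requires strict sex limitation of an allele", {
  # A allele het in 6/10 males, absent in all females
  fx <- site_catalog(c(rep("T/A", 6), rep("T/T", 4)), rep("T/T", 10))
  af <- dplyr::filter(screen_allele_frequency(fx$catalog, fx$registry),
                      system == "XY")
  expect_equal(af$sex_specific_allele, "A")
  # one stray A copy in a female disqualifies strategy (i) ...
  fx2 <- site_catalog(c(rep("T/A", 6), rep("T/T", 4)),
                      c("T/A", rep("T/T", 9)))
  expect_equal(nrow(dplyr::filter(
    screen_allele_frequency(fx2$catalog, fx2$registry), system == "XY")), 0)
  # ... but the heterozygosity screen still flags the site
  expect_true("XY" %in%
                screen_heterozygosity(fx2$catalog, fx2$registry)$system)
})

test_that("sex-limited screen enforces complete absence and half presence", {
  lim_catalog <- function(n_pres_m, n_pres_f) {
    fx <- site_catalog(rep("T/T", 10), rep("T/T", 10))
    pres <- fx$catalog$presence
    pres$present <- c(rep(TRUE, n_pres_m), rep(FALSE, 10 - n_pres_m),
                      rep(TRUE, n_pres_f), rep(FALSE, 10 - n_pres_f))
    pres$depth <- ifelse(pres$present, 10L, 0L)
    snps <- fx$catalog$snps
    snps$allele1[!pres$present] <- NA
    snps$allele2[!pres$present] <- NA
    fx$catalog <- locus_catalog(fx$catalog$consensus, snps, pres,
                                fx$catalog$samples)
    fx
  }
  fx <- lim_catalog(6, 0)
  expect_true("XY" %in%
                screen_sex_limited(fx$catalog, fx$registry)$system)
  fx <- lim_catalog(5, 1)
  expect_false("XY" %in%
                 screen_sex_limited(fx$catalog, fx$registry)$system)
  fx <- lim_catalog(5, 0)   # boundary: exactly half of the males
  expect_true("XY" %in%
                screen_sex_limited(fx$catalog, fx$registry)$system)
})

test_that("combining candidate sets deduplicates and tracks provenance", {
  fx <- site_catalog(rep("T/A", 10), rep("T/T", 10))
  het <- screen_heterozygosity(fx$catalog, fx$registry)
  af <- screen_allele_frequency(fx$catalog, fx$registry)
  comb <- combine_candidates(het = het, af = af)
  xy <- dplyr::filter(comb, system == "XY")
  expect_equal(nrow(xy), 1)
  expect_equal(xy$strategies, "allele_frequency,heterozygosity")
  expect_equal(xy$sex_specific_allele, "A")

  # identical consensus from two assembly runs collapses
  again <- combine_candidates(run1 = het, run2 = het)
  expect_equal(nrow(dplyr::filter(again, system == "XY")), 1)
  expect_equal(dplyr::filter(again, system == "XY")$datasets, "run1,run2")

  # disjoint sets concatenate
  fx2 <- site_catalog(rep("C/G", 10), rep("C/C", 10),
                      consensus = strrep("C", 30))
  het2 <- screen_heterozygosity(fx2$catalog, fx2$registry) |>
    dplyr::mutate(locus_id = "L2", marker_id = sub("L1", "L2", marker_id))
  both <- combine_candidates(a = het, b = het2)
  expect_equal(nrow(both), nrow(het) + nrow(het2))
})

test_that("screens match the brute-force predicate evaluation", {
  th <- screen_thresholds()
  withr::with_seed(202, {
    for (i in 1:25) {
      fx <- random_small_catalog()
      got <- screen_all(fx$catalog, fx$registry, th)
      want <- brute_force_screen(fx$catalog, fx$registry, th)
      expect_identical(screen_key(got), screen_key(want))
    }
  })
})

test_that("swapping sex labels mirrors every call between systems", {
  withr::with_seed(303, {
    for (i in 1:10) {
      fx <- random_small_catalog()
      swapped <- fx$registry
      swapped$sex <- factor(ifelse(swapped$sex == "male", "female", "male"),
                            levels = c("male", "female"))
      a <- screen_all(fx$catalog, fx$registry)
      b <- screen_all(fx$catalog, swapped)
      flip <- function(df) {
        k <- df
        k$system <- ifelse(k$system == "XY", "ZW", "XY")
        k$marker_id <- NULL
        dplyr::arrange(
          dplyr::select(k, locus_id, column, strategy, system,
                        sex_specific_allele),
          locus_id, column, strategy, system)
      }
      keep <- function(df) dplyr::arrange(
        dplyr::select(df, locus_id, column, strategy, system,
                      sex_specific_allele),
        locus_id, column, strategy, system)
      expect_identical(as.data.frame(keep(b)), as.data.frame(flip(a)))
    }
  })
})

test_that("raising the heterozygosity threshold never adds candidates", {
  withr::with_seed(404, {
    for (i in 1:10) {
      fx <- random_small_catalog()
      lo <- screen_heterozygosity(fx$catalog, fx$registry,
                                  screen_thresholds(
                                    min_frac_het_heterogametic = 1 / 3))
      hi <- screen_heterozygosity(fx$catalog, fx$registry,
                                  screen_thresholds(
                                    min_frac_het_heterogametic = 2 / 3))
      expect_true(all(screen_key(hi) %in% screen_key(lo)))
    }
  })
})

test_that("screens refuse a registry without both sexes", {
  fx <- site_catalog(rep("T/A", 4), rep("T/T", 4))
  males_only <- dplyr::filter(fx$registry, sex == "male")
  expect_error(screen_heterozygosity(fx$catalog, males_only),
               "at least one male and one female")
})
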