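hit <- function(q, s, e, s_start = 1000, s_end = 1150, bit = 200) {
  tibble::tibble(query_id = q, subject_id = s, percent_identity = 99,
                 alignment_length = 150, mismatches = 1, gap_opens = 0,
                 q_start = 1, q_end = 150, s_start = s_start, s_end = s_end,
                 e_value = e, bit_score = bit, strand = "+")
}

test_that("direct assignment applies the E-value and best-hit-gap rules", {
  rules <- assignment_rules()
  hits <- dplyr::bind_rows(
    hit("m1", "chr1", 1e-30), hit("m1", "chr2", 1e-24),   # gap 6 -> assigned
    hit("m2", "chr1", 1e-30), hit("m2", "chr2", 1e-27),   # gap 3 -> ambiguous
    hit("m3", "chr3", 1e-19)                              # fails cutoff
  )
  res <- assign_direct(hits, rules, markers = c("m1", "m2", "m3", "m4"))
  res <- res[match(c("m1", "m2", "m3", "m4"), res$marker_id), ]
  expect_equal(res$status, c("assigned", "ambiguous_gap", "fails_evalue",
                             "no_hit"))
  expect_equal(res$chromosome[1], "chr1")
  expect_equal(res$position[1], 1000)
  expect_equal(res$gap_orders[1], 6, tolerance = 1e-9)
  # single qualifying hit needs no gap
  one <- assign_direct(hit("m5", "chr4", 1e-25), rules)
  expect_equal(one$status, "assigned")
  # E = 0 is floored, keeping the gap finite
  zero <- assign_direct(dplyr::bind_rows(hit("m6", "chr1", 0),
                                         hit("m6", "chr2", 1e-300)), rules)
  expect_equal(zero$status, "assigned")
  expect_true(is.finite(zero$gap_orders))
})

test_that("assignment is invariant to hit-row order", {
  hits <- dplyr::bind_rows(
    hit("a", "chr1", 1e-40), hit("a", "chr2", 1e-33),
    hit("b", "chr2", 1e-25), hit("b", "chr3", 1e-22),
    hit("c", "chr1", 1e-50)
  )
  base <- assign_direct(hits, assignment_rules())
  withr::with_seed(1, {
    for (i in 1:5) {
      shuf <- hits[sample(nrow(hits)), ]
      expect_identical(assign_direct(shuf, assignment_rules()), base)
    }
  })
})

test_that("flank extraction clips at scaffold ends", {
  scaff <- setNames(paste(rep("ACGTT", 4000), collapse = ""), "sc1")  # 20 kb
  mid <- hit("m", "sc1", 1e-40, s_start = 5001, s_end = 5150)
  fl <- extract_flanks(mid, scaff, 2000)
  expect_equal(fl$start, 3001)
  expect_equal(fl$end, 7150)
  expect_equal(nchar(fl$sequence), 4150)
  expect_false(fl$clipped_left || fl$clipped_right)
  expect_equal(fl$sequence, unname(substr(scaff, 3001, 7150)))

  left <- extract_flanks(hit("m", "sc1", 1e-40, s_start = 501, s_end = 650),
                         scaff, 2000)
  expect_equal(left$start, 1)
  expect_equal(left$end, 2650)
  expect_true(left$clipped_left)

  ident <- extract_flanks(mid, scaff, 0)
  expect_equal(c(ident$start, ident$end), c(5001, 5150))

  expect_error(extract_flanks(hit("m", "nope", 1e-40), scaff), "nope")
})

test_that("indirect assignment chains bridge and target steps", {
  withr::with_seed(77, {
    marker <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    # bridge scaffold embeds the marker; target chromosome embeds the
    # whole scaffold
    scaffold <- paste0(paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                             collapse = ""),
                       marker,
                       paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                             collapse = ""))
    chr5 <- paste0(paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                         collapse = ""), scaffold,
                   paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                         collapse = ""))
    decoys <- setNames(vapply(1:3, function(i) {
      paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
    }, character(1)), paste0("chr", 1:3))
  })
  genome <- c(decoys, chr5 = chr5)
  bridge_hits <- match_sequences(c(mk1 = marker), c(sc1 = scaffold))
  frag <- extract_flanks(bridge_hits, c(sc1 = scaffold), 2000)
  target_hits <- match_sequences(setNames(frag$sequence, frag$fragment_id),
                                 genome)
  res <- assign_indirect(bridge_hits, c(sc1 = scaffold), target_hits)
  expect_equal(res$status, "assigned")
  expect_equal(res$chromosome, "chr5")
  expect_equal(res$method, "indirect")

  # bridge hit but unmappable extension -> no_hit at the target stage
  res2 <- assign_indirect(bridge_hits, c(sc1 = scaffold),
                          target_hits[0, ])
  expect_equal(res2$status, "no_hit")
  expect_equal(res2$stage, "target")

  # flank clipped at the scaffold end still assigns when step 2 passes
  short_scaffold <- substr(scaffold, 2600, 3300)  # marker near the end
  b2 <- match_sequences(c(mk1 = marker), c(sc2 = short_scaffold))
  f2 <- extract_flanks(b2, c(sc2 = short_scaffold), 2000)
  expect_true(f2$clipped_left || f2$clipped_right)
  t2 <- match_sequences(setNames(f2$sequence, f2$fragment_id), genome)
  r2 <- assign_indirect(b2, c(sc2 = short_scaffold), t2)
  expect_equal(r2$status, "assigned")
  expect_equal(r2$chromosome, "chr5")
})

test_that("a second identical embedding makes a marker ambiguous", {
  withr::with_seed(11, {
    marker <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
    genome <- c(chr1 = paste0(pad(500), marker, pad(500)),
                chr2 = paste0(pad(800), marker, pad(200)))
  })
  hits <- match_sequences(c(mk = marker), genome)
  res <- assign_direct(hits, assignment_rules())
  expect_equal(res$status, "ambiguous_gap")
  single <- assign_direct(match_sequences(c(mk = marker), genome["chr1"]),
                          assignment_rules())
  expect_equal(single$status, "assigned")
})

test_that("the concentration test flags a loaded chromosome and not scatter", {
  lengths <- c(chr1 = 1e6, chr2 = 2e6, chr3 = 3e6, chr4 = 4e6)
  conc <- function(chroms) {
    concentration_test(
      tibble::tibble(marker_id = paste0("m", seq_along(chroms)),
                     status = "assigned", chromosome = chroms,
                     position = 1, best_evalue = 1e-40,
                     next_evalue = NA, gap_orders = Inf, method = "direct"),
      lengths
    )
  }
  # all 50 markers on a chromosome holding 10% of the genome
  loaded <- conc(rep("chr1", 50))
  p1 <- dplyr::filter(tidy(loaded), chromosome == "chr1")$p_adjusted
  expect_lt(p1, 1e-20)
  # oracle: one-sided binomial tail (upper bound via Holm factor 4)
  expect_lt(p1, 4 * (0.1 ^ 50) * 2)

  # markers proportional to length: nothing significant
  prop <- conc(rep(c("chr1", "chr2", "chr3", "chr4"), c(5, 10, 15, 20)))
  expect_equal(glance(prop)$n_significant, 0L)

  # a single marker can never reach significance on a chromosome with
  # expected fraction above alpha
  single <- conc("chr4")
  t <- tidy(single)
  expect_true(all(t$p_adjusted[t$expected_frac > 0.05] > 0.05))

  # zero assigned markers: test skipped
  empty <- concentration_test(
    tibble::tibble(marker_id = "m", status = "no_hit",
                   chromosome = NA_character_, position = NA_real_,
                   best_evalue = NA_real_, next_evalue = NA_real_,
                   gap_orders = NA_real_, method = "direct"),
    lengths
  )
  expect_false(empty$tested)
  expect_equal(empty$fraction_unassigned, 1)
})

test_that("candidate-gene annotation applies identity and E-value cutoffs", {
  gene_hit <- function(q, s, ident, e) {
    tibble::tibble(query_id = q, subject_id = s, percent_identity = ident,
                   alignment_length = 120, mismatches = 5, gap_opens = 0,
                   q_start = 1, q_end = 120, s_start = 501, s_end = 620,
                   e_value = e, bit_score = 180, strand = "+")
  }
  hits <- dplyr::bind_rows(
    gene_hit("mA", "CYP19A1", 85, 1e-40),
    gene_hit("mB", "AR", 90, 1e-10),       # fails E-value
    gene_hit("mC", "DMRT1", 60, 1e-40)     # fails identity
  )
  ann <- annotate_candidate_genes(hits, markers = c("mA", "mB", "mC"))
  expect_equal(ann$gene, c("CYP19A1", NA, NA))
  expect_equal(ann$s_start[1], 501)
  expect_equal(ann$s_end[1], 620)
})
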