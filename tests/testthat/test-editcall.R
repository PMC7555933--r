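test_that("mismatch_profile does exact per-position bookkeeping", {
  ref <- tiny_reference()
  # 100 exact reads of mir-A
  tab <- tibble::tibble(sample_id = "s1", sequence = ref$sequence[1],
                        count = 100L)
  prof <- mismatch_profile(assign_sample(tab, ref), ref, "mir-A")
  expect_equal(nrow(prof), 21)
  expect_true(all(prof$coverage == 100))
  for (b in c("A", "C", "G", "T")) {
    expect_equal(prof[[b]], ifelse(prof$ref_base == b, 100, 0))
  }

  # 30 of 100 reads carry G at an A position (position 5 of mir-A)
  mut <- ref$sequence[1]
  substr(mut, 5, 5) <- "G"
  tab2 <- tibble::tibble(sample_id = "s1",
                         sequence = c(ref$sequence[1], mut),
                         count = c(70L, 30L))
  prof2 <- mismatch_profile(assign_sample(tab2, ref), ref, "mir-A")
  expect_equal(prof2$A[5], 70)
  expect_equal(prof2$G[5], 30)
  expect_equal(prof2$coverage[5], 100)

  # short reads leave tail positions uncovered
  trunc <- substr(ref$sequence[1], 1, 19)
  prof3 <- mismatch_profile(
    assign_sample(tibble::tibble(sample_id = "s1", sequence = trunc,
                                 count = 10L), ref),
    ref, "mir-A"
  )
  expect_equal(prof3$coverage[19], 10)
  expect_equal(prof3$coverage[20], 0)
  expect_equal(prof3$coverage[21], 0)

  expect_error(mismatch_profile(assign_sample(tab, ref), ref, "nope"),
               "unknown miRNA")
})

test_that("call_editing_sites applies both thresholds and sets flags", {
  ref <- tiny_reference()
  tab <- tibble::tibble(sample_id = "s1", sequence = ref$sequence[1],
                        count = 1000L)
  prof <- mismatch_profile(assign_sample(tab, ref), ref, "mir-A")
  expect_equal(nrow(call_editing_sites(prof, error_rate = 0)), 0)

  # A->G at position 5 (A in mir-A), plus a C->T at position 11 (C)
  m1 <- ref$sequence[1]; substr(m1, 5, 5) <- "G"
  m2 <- ref$sequence[1]; substr(m2, 11, 11) <- "T"
  tab2 <- tibble::tibble(
    sample_id = "s1",
    sequence = c(ref$sequence[1], m1, m2),
    count = c(700L, 200L, 100L)
  )
  prof2 <- mismatch_profile(assign_sample(tab2, ref), ref, "mir-A")
  calls <- call_editing_sites(prof2, error_rate = 0.001)
  expect_equal(nrow(calls), 2)
  a2g <- calls[calls$position == 5, ]
  expect_true(a2g$is_a_to_g)
  expect_true(a2g$in_seed)
  expect_equal(a2g$fraction, 0.2)
  c2t <- calls[calls$position == 11, ]
  expect_false(c2t$is_a_to_g)
  expect_false(c2t$in_seed)

  # raising min_edited_reads never adds a call (monotone)
  for (thr in c(5, 50, 150, 250)) {
    expect_lte(nrow(call_editing_sites(prof2, 0.001, min_edited_reads = thr)),
               nrow(call_editing_sites(prof2, 0.001,
                                       min_edited_reads = max(thr - 50, 1))))
  }

  # sub-threshold fraction: 2 in 1000 at error 0.001 fails 3 x error rule
  m3 <- ref$sequence[1]; substr(m3, 8, 8) <- "G"
  tab3 <- tibble::tibble(sample_id = "s1",
                         sequence = c(ref$sequence[1], m3),
                         count = c(998L, 2L))
  prof3 <- mismatch_profile(assign_sample(tab3, ref), ref, "mir-A")
  expect_equal(nrow(call_editing_sites(prof3, error_rate = 0.001)), 0)

  expect_error(call_editing_sites(prof2, error_rate = 0.2), "0.05")
})

test_that("seed classification is exactly positions 2-7", {
  ref <- mirna_reference(tibble::tibble(
    mirna_id = "all-a", sequence = strrep("A", 20)
  ))
  base <- strrep("A", 20)
  variants <- vapply(1:9, function(p) {
    s <- base; substr(s, p, p) <- "G"; s
  }, character(1))
  tab <- tibble::tibble(sample_id = "s1",
                        sequence = c(base, variants),
                        count = c(1000L, rep(100L, 9)))
  prof <- mismatch_profile(assign_sample(tab, ref, max_mm = 1), ref, "all-a")
  calls <- call_editing_sites(prof, error_rate = 0.001)
  expect_setequal(calls$position, 1:9)
  expect_equal(calls$in_seed[order(calls$position)],
               c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("pipeline recovers a planted editing fraction", {
  ref <- tiny_reference()
  d <- two_group_design()
  t <- gen_truth(ref, d, n_edited = 1, edited_fraction = 0.3,
                 error_rate = 0.001, seed = 81)
  site <- dplyr::distinct(t$editing_sites, mirna_id, position)
  asn <- simulate_and_assign(t, ref, d, "M03_r1", depth = 3e4)
  prof <- mismatch_profile(asn, ref, site$mirna_id)
  calls <- call_editing_sites(prof, error_rate = 0.001)
  a2g <- calls[calls$is_a_to_g, ]
  expect_equal(nrow(a2g), 1)
  expect_equal(a2g$position, site$position)
  expect_lt(abs(a2g$fraction - 0.3), 0.03)
})

test_that("summarize_edited applies the strict >3000 filter and shares sum to 100", {
  ref <- tiny_reference()
  # calls on mir-A and mir-B; abundances straddle the cut-off
  mutA <- ref$sequence[1]; substr(mutA, 5, 5) <- "G"
  mutB <- ref$sequence[2]; substr(mutB, 8, 8) <- "G"  # pos 8 of mir-B is A
  tab <- tibble::tibble(
    sample_id = "s1",
    sequence = c(ref$sequence[1], mutA, ref$sequence[2], mutB),
    count = c(2400L, 600L, 3200L, 800L)
  )
  asn <- assign_sample(tab, ref)
  calls <- dplyr::bind_rows(
    call_editing_sites(mismatch_profile(asn, ref, "mir-A"), 0.001),
    call_editing_sites(mismatch_profile(asn, ref, "mir-B"), 0.001)
  )
  # normalized means: mir-A 2999.5, mir-B 3000.5, mir-C 0
  norm <- tibble::tibble(mirna_id = c("mir-A", "mir-B", "mir-C"),
                         s1 = c(2999, 3000, 0), s2 = c(3000, 3001, 0))
  sm <- summarize_edited(asn, calls, norm, "s1")
  expect_equal(sm$mirna_id, "mir-B")
  expect_equal(sm$edited_read_count, 800)
  expect_equal(sm$total_reads, 4000)
  expect_equal(sm$percent_of_mirna_reads, 20)
  expect_equal(sm$doughnut_share, 100)

  # lowering the cut-off brings mir-A in; shares sum to 100 within 1e-6
  sm2 <- summarize_edited(asn, calls, norm, "s1", min_avg_reads = 100)
  expect_setequal(sm2$mirna_id, c("mir-A", "mir-B"))
  expect_lt(abs(sum(sm2$doughnut_share) - 100), 1e-6)
  expect_equal(attr(sm2, "top6"), c("mir-B", "mir-A"))

  expect_error(summarize_edited(asn, calls, norm, character(0)), "non-empty")
})

test_that("edited reads are counted only at called sites", {
  ref <- tiny_reference()
  mutA <- ref$sequence[1]; substr(mutA, 5, 5) <- "G"
  stray <- ref$sequence[1]; substr(stray, 14, 14) <- "A"  # T->A, 1 read
  tab <- tibble::tibble(
    sample_id = "s1",
    sequence = c(ref$sequence[1], mutA, stray),
    count = c(8000L, 2000L, 1L)
  )
  asn <- assign_sample(tab, ref)
  calls <- call_editing_sites(mismatch_profile(asn, ref, "mir-A"), 0.001)
  expect_equal(calls$position, 5)  # the stray single read is not a site
  norm <- tibble::tibble(mirna_id = "mir-A", s1 = 10001, s2 = 10001)
  sm <- summarize_edited(asn, calls, norm, "s1")
  # the stray read is not edited: it carries no alt base of a called site
  expect_equal(sm$edited_read_count, 2000)
})
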