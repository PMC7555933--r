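test_that("gen_reference honors count, length and determinism contracts", {
  r1 <- gen_reference(1, c(22, 22), seed = 7)
  expect_equal(nrow(r1), 1)
  expect_equal(nchar(r1$sequence), 22)

  a <- gen_reference(20, c(17, 24), seed = 1)
  b <- gen_reference(20, c(17, 24), seed = 1)
  expect_identical(a, b)

  c2 <- gen_reference(20, c(17, 24), seed = 2)
  expect_false(setequal(a$sequence, c2$sequence))

  # equal-length sequences keep pairwise Hamming distance >= 5
  for (L in unique(nchar(a$sequence))) {
    same <- a$sequence[nchar(a$sequence) == L]
    if (length(same) < 2) next
    for (i in seq_len(length(same) - 1)) {
      for (j in seq(i + 1, length(same))) {
        d <- sum(strsplit(same[i], "")[[1]] != strsplit(same[j], "")[[1]])
        expect_gte(d, 5)
      }
    }
  }
})

test_that("infeasible reference requests fail instead of looping", {
  # at Hamming distance 17 over 17 nt, at most 4 sequences can coexist
  expect_error(gen_reference(300, c(17, 17), seed = 1, min_hamming = 17),
               "infeasible")
})

test_that("reference loader converts U to T and validates lengths", {
  r <- mirna_reference(data.frame(mirna_id = "m", sequence = "ugagauguaagcacuguagcu"))
  expect_equal(r$sequence, "TGAGATGTAAGCACTGTAGCT")
  expect_error(
    mirna_reference(data.frame(mirna_id = "m", sequence = "ACGT")),
    "17-24"
  )
  expect_error(
    mirna_reference(data.frame(mirna_id = c("m", "m"),
                               sequence = c(strrep("A", 20), strrep("C", 20)))),
    "duplicate"
  )
})

test_that("gen_truth plants sites at A positions and honors requested counts", {
  ref <- tiny_reference()
  d <- two_group_design()

  t0 <- gen_truth(ref, d, n_edited = 0, seed = 1)
  expect_equal(nrow(t0$editing_sites), 0)

  t1 <- gen_truth(ref, d, n_edited = 1, edited_fraction = 0.3, seed = 1)
  sites <- dplyr::distinct(t1$editing_sites, mirna_id, position)
  expect_equal(nrow(sites), 1)
  s <- ref$sequence[ref$mirna_id == sites$mirna_id]
  expect_equal(substr(s, sites$position, sites$position), "A")
  expect_true(all(t1$editing_sites$edited_fraction == 0.3))

  t5 <- gen_truth(gen_reference(10, c(20, 22), seed = 3), d,
                  n_de = 5, log2fc = 2, seed = 2)
  expect_equal(length(unique(t5$effects$mirna_id)), 5)
  expect_true(all(t5$effects$log2fc == 2))

  no_a <- mirna_reference(tibble::tibble(
    mirna_id = "gc", sequence = strrep("CG", 10)
  ))
  expect_error(gen_truth(no_a, d, n_edited = 1, seed = 1), "adenosine|A ")
})

test_that("simulated reads reflect the planted truth exactly when noise-free", {
  ref <- tiny_reference()
  d <- two_group_design()

  # no editing, no error: every insert equals a reference sequence
  t0 <- gen_truth(ref, d, error_rate = 0, seed = 4)
  reads <- simulate_sample_reads(t0, ref, d, "M03_r1", depth = 500)
  expect_true(all(nchar(reads$sequence) == 50))
  hits <- vapply(ref$sequence, function(s) startsWith(reads$sequence, s),
                 logical(nrow(reads)))
  expect_true(all(rowSums(hits) >= 1))

  # fraction 1.0: every read of that miRNA carries G at the planted site
  t1 <- gen_truth(ref, d, n_edited = 1, edited_fraction = 1, error_rate = 0,
                  seed = 4)
  site <- dplyr::distinct(t1$editing_sites, mirna_id, position)
  reads1 <- simulate_sample_reads(t1, ref, d, "M03_r1", depth = 2000)
  ref_seq <- ref$sequence[ref$mirna_id == site$mirna_id]
  edited_seq <- ref_seq
  substr(edited_seq, site$position, site$position) <- "G"
  ins <- substr(reads1$sequence, 1, nchar(ref_seq))
  of_mirna <- ins == ref_seq | ins == edited_seq
  expect_gt(sum(of_mirna), 0)
  expect_true(all(ins[of_mirna] == edited_seq))
})

test_that("empirical edited fraction converges to the planted fraction", {
  ref <- tiny_reference()
  d <- two_group_design()
  t <- gen_truth(ref, d, n_edited = 1, edited_fraction = 0.3, error_rate = 0,
                 seed = 11)
  site <- dplyr::distinct(t$editing_sites, mirna_id, position)
  reads <- simulate_sample_reads(t, ref, d, "M03_r1", depth = 3e4)
  ref_seq <- ref$sequence[ref$mirna_id == site$mirna_id]
  edited_seq <- ref_seq
  substr(edited_seq, site$position, site$position) <- "G"
  ins <- substr(reads$sequence, 1, nchar(ref_seq))
  of_mirna <- ins == ref_seq | ins == edited_seq
  n <- sum(of_mirna)
  frac <- mean(ins[of_mirna] == edited_seq)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("group abundance ratios converge to 2^log2FC across replicate seeds", {
  ref <- gen_reference(8, c(20, 22), seed = 9)
  d <- two_group_design()
  t <- gen_truth(ref, d, n_de = 3, log2fc = 1.5, dispersion = 25, seed = 9)
  de_ids <- unique(t$effects$mirna_id)

  n_rep <- 20
  ratios <- matrix(NA_real_, n_rep, length(de_ids))
  for (r in seq_len(n_rep)) {
    cm <- simulate_count_matrix(t, d, depth = 5e4, seed = 1000 + r)
    young <- rowMeans(cm[d$sample_id[d$age_months == 3]])
    old <- rowMeans(cm[d$sample_id[d$age_months == 30]])
    idx <- match(de_ids, cm$mirna_id)
    # compare planted-effect miRNAs on their relative (composition) scale:
    # scale out the compositional shift using the non-DE miRNAs
    null_idx <- setdiff(seq_len(nrow(cm)), idx)
    scale_fac <- mean(old[null_idx] / young[null_idx])
    ratios[r, ] <- (old[idx] / young[idx]) / scale_fac
  }
  mean_ratio <- colMeans(ratios)
  se <- apply(ratios, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(mean_ratio - 2^1.5) <= 3 * se + 0.05 * 2^1.5))
})

test_that("simulation is deterministic and per-sample seeds are stable", {
  ref <- tiny_reference()
  d <- two_group_design()
  t <- gen_truth(ref, d, n_edited = 1, seed = 21)
  r1 <- simulate_sample_reads(t, ref, d, "M30_r2", depth = 1000)
  r2 <- simulate_sample_reads(t, ref, d, "M30_r2", depth = 1000)
  expect_identical(r1, r2)
  expect_error(simulate_sample_reads(t, ref, d, "nope", depth = 10),
               "unknown sample_id")

  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(r1, f1)
  write_reads_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_reads_fastq(f1, sample_id = "M30_r2")
  expect_equal(back$sequence, r1$sequence)
  expect_equal(back$quality, r1$quality)
})
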