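# rno-miR-143-3p mature sequence (DNA alphabet)
MIR143 <- "TGAGATGAAGCACTGTAGCTC"

flank <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

test_that("locate_insert finds exact inserts in either orientation", {
  clone <- paste0(flank(120, 1), MIR143, flank(150, 2))
  aln <- locate_insert(clone, MIR143)
  expect_true(aln$found)
  expect_equal(aln$orientation, "forward")
  expect_equal(aln$offset, 121)
  expect_equal(aln$identity, 1)
  expect_equal(nrow(call_clone_substitutions(aln)), 0)

  rc_clone <- paste0(flank(80, 3), revcomp(MIR143), flank(100, 4))
  aln_rc <- locate_insert(rc_clone, MIR143)
  expect_true(aln_rc$found)
  expect_equal(aln_rc$orientation, "reverse-complement")
  expect_equal(nrow(call_clone_substitutions(aln_rc)), 0)

  # random clone: no window reaches 80% identity
  rand <- flank(500, 5)
  expect_false(locate_insert(rand, MIR143)$found)
})

test_that("reverse-complement inserts report reference-strand calls", {
  # plant A->G at position 5 (an A in the seed region of miR-143)
  edited <- MIR143
  substr(edited, 5, 5) <- "G"
  clone <- paste0(flank(60, 6), revcomp(edited), flank(90, 7))
  aln <- locate_insert(clone, MIR143)
  expect_equal(aln$orientation, "reverse-complement")
  calls <- call_clone_substitutions(aln)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 5L)
  expect_equal(calls$ref_base, "A")
  expect_equal(calls$observed_base, "G")  # appears as C on the clone strand
  expect_true(calls$is_a_to_g)
  expect_true(calls$in_seed)
})

test_that("mixed substitutions get correct flags", {
  # A->G at position 8 (non-seed A) and C->A at position 19
  edited <- MIR143
  substr(edited, 8, 8) <- "G"
  substr(edited, 19, 19) <- "A"
  clone <- paste0(flank(50, 8), edited, flank(60, 9))
  calls <- call_clone_substitutions(locate_insert(clone, MIR143))
  expect_equal(calls$position, c(8L, 19L))
  expect_equal(calls$is_a_to_g, c(TRUE, FALSE))
  expect_equal(calls$in_seed, c(FALSE, FALSE))
})

test_that("strand round-trip returns the identical call", {
  edited <- MIR143
  substr(edited, 10, 10) <- "G"
  fwd_clone <- paste0(flank(70, 10), edited, flank(70, 11))
  rc_clone <- revcomp(fwd_clone)
  c1 <- call_clone_substitutions(locate_insert(fwd_clone, MIR143))
  c2 <- call_clone_substitutions(locate_insert(rc_clone, MIR143))
  expect_identical(c1, c2)
})

test_that("planted positions are recovered over random orientations (property)", {
  withr::with_seed(131, {
    for (i in 1:40) {
      a_pos <- which(strsplit(MIR143, "")[[1]] == "A")
      p <- a_pos[sample.int(length(a_pos), 1)]
      edited <- MIR143
      substr(edited, p, p) <- "G"
      ins <- if (runif(1) < 0.5) edited else revcomp(edited)
      nl <- sample(30:200, 1)
      nr <- sample(30:200, 1)
      clone <- paste0(
        paste(sample(c("A", "C", "G", "T"), nl, TRUE), collapse = ""),
        ins,
        paste(sample(c("A", "C", "G", "T"), nr, TRUE), collapse = "")
      )
      calls <- call_clone_substitutions(locate_insert(clone, MIR143))
      expect_equal(calls$position, p)
      expect_equal(calls$observed_base, "G")
    }
  })
})

test_that("locate_insert agrees with the brute-force scan on random clones", {
  withr::with_seed(132, {
    for (i in 1:200) {
      # half the clones carry a (possibly mutated) insert, half are noise
      has_insert <- i %% 2 == 0
      body <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
      if (has_insert) {
        ins <- MIR143
        n_mut <- sample(0:3, 1)
        if (n_mut) {
          at <- sample(nchar(ins), n_mut)
          for (a in at) substr(ins, a, a) <- sample(c("A", "C", "G", "T"), 1)
        }
        if (runif(1) < 0.5) ins <- revcomp(ins)
        off <- sample.int(nchar(body) - nchar(ins), 1)
        body <- paste0(substr(body, 1, off), ins,
                       substr(body, off + nchar(ins) + 1, nchar(body)))
      }
      got <- locate_insert(body, MIR143)
      want <- oracle_locate(body, MIR143)
      expect_equal(got$found, want$found)
      if (want$found) {
        expect_equal(got$identity, want$identity)
        expect_equal(got$orientation, want$orientation)
        expect_equal(got$offset, want$offset)
      }
    }
  })
})

test_that("clone batches are called and summarized with conserved counts", {
  clones <- gen_clones(MIR143, n_animals = 2, colonies_per_animal = 3,
                       sexes = c("M", "F"), ages_months = c(3, 30),
                       edit_prob = 0.4, seed = 133)
  truth <- attr(clones, "truth")
  calls <- call_clones(clones, MIR143)
  expect_length(attr(calls, "not_found"), 0)

  # every planted edit recovered at its reference position, nothing else
  expect_equal(nrow(calls), nrow(truth))
  merged <- dplyr::inner_join(calls, truth, by = "clone_id")
  expect_equal(merged$position.x, merged$position.y)
  expect_true(all(merged$is_a_to_g))

  sm <- summarize_clone_editing(calls, clones)
  expect_equal(sum(sm$clones_sequenced), nrow(clones))
  expect_equal(sum(sm$seed_calls + sm$nonseed_calls), nrow(calls))
  expect_equal(sum(sm$clones_with_a_to_g),
               length(unique(truth$clone_id)))

  # no calls anywhere -> all-zero counts
  clean <- gen_clones(MIR143, n_animals = 1, colonies_per_animal = 3,
                      sexes = "M", ages_months = 3, edit_prob = 0,
                      seed = 134)
  sm0 <- summarize_clone_editing(call_clones(clean, MIR143), clean)
  expect_equal(sm0$total_calls, 0L)
  expect_equal(sm0$clones_with_a_to_g, 0L)

  # planted clone-edit probability is recovered binomially
  big <- gen_clones(MIR143, n_animals = 5, colonies_per_animal = 5,
                    sexes = c("M", "F"), ages_months = c(3, 30),
                    edit_prob = 0.3, seed = 135)
  big_calls <- call_clones(big, MIR143)
  frac <- length(unique(big_calls$clone_id[big_calls$is_a_to_g])) / nrow(big)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(big)))

  few <- gen_clones(MIR143, n_animals = 1, colonies_per_animal = 2,
                    sexes = "M", ages_months = 3, edit_prob = 0, seed = 136)
  expect_warning(summarize_clone_editing(call_clones(few, MIR143), few),
                 "fewer than 3")
})
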