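#' Construct and validate a mature-miRNA reference
#'
#' A reference is a tibble with columns `mirna_id` and `sequence`. Sequences
#' are DNA (any U is converted to T on load), 17-24 nt long — the length
#' range of mature miRNAs — and ids must be unique. All editing calls are
#' reported in 1-based coordinates of these sequences.
#'
#' @param x A data frame with columns `mirna_id` and `sequence`.
#' @return A validated tibble of class `mirna_reference`.
#' @export
#' @examples
#' mirna_reference(data.frame(mirna_id = "mir-1", sequence = "UGGAAUGUAAAGAAGUAUGUAU"))
mirna_reference <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("mirna_id", "sequence") %in% names(x)))
  x$mirna_id <- as.character(x$mirna_id)
  x$sequence <- normalise_seq(as.character(x$sequence))
  if (anyDuplicated(x$mirna_id)) abort("duplicate mirna_id in reference")
  if (any(!nzchar(x$sequence))) abort("empty sequence in reference")
  assert_dna(x$sequence, what = "reference sequence")
  len <- nchar(x$sequence)
  if (any(len < 17 | len > 24)) {
    abort("reference sequences must be 17-24 nt (mature miRNA length range)")
  }
  class(x) <- c("mirna_reference", class(x))
  x
}

#' Generate a random mature-miRNA reference
#'
#' Draws `n_mirnas` random DNA sequences with lengths uniform in
#' `length_range`. Equal-length sequences are kept at pairwise Hamming
#' distance of at least `min_hamming` so that mismatch-tolerant mapping
#' is unambiguous by construction.
#'
#' @param n_mirnas Number of miRNAs to generate.
#' @param length_range Integer pair within \[17, 24\].
#' @param seed Integer seed; output is deterministic given the seed.
#' @param min_hamming Minimum pairwise Hamming distance between
#'   equal-length sequences (default 5).
#' @return A `mirna_reference` tibble.
#' @export
#' @examples
#' gen_reference(5, c(20, 22), seed = 1)
gen_reference <- function(n_mirnas, length_range = c(17, 24), seed,
                          min_hamming = 5) {
  stopifnot(n_mirnas >= 1, length(length_range) == 2)
  length_range <- as.integer(length_range)
  if (length_range[1] > length_range[2] ||
      length_range[1] < 17 || length_range[2] > 24) {
    abort("length_range must be an ordered pair within [17, 24]")
  }
  withr::with_seed(seed, {
    seqs <- character(0)
    lens <- integer(0)
    attempts <- 0L
    max_attempts <- 1000L * n_mirnas
    while (length(seqs) < n_mirnas) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(sprintf(
          "could not place %d sequences at Hamming distance >= %d; request is infeasible",
          n_mirnas, min_hamming
        ))
      }
      lens_avail <- seq(length_range[1], length_range[2])
      L <- lens_avail[sample.int(length(lens_avail), 1)]
      cand <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
      same_len <- seqs[lens == L]
      ok <- TRUE
      if (length(same_len)) {
        cch <- strsplit(cand, "")[[1]]
        for (s in same_len) {
          if (sum(cch != strsplit(s, "")[[1]]) < min_hamming) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok && !cand %in% seqs) {
        seqs <- c(seqs, cand)
        lens <- c(lens, L)
      }
    }
    mirna_reference(tibble(
      mirna_id = sprintf("mir-sim-%03d", seq_len(n_mirnas)),
      sequence = seqs
    ))
  })
}

#' Read / write a reference as FASTA
#'
#' @param path File path.
#' @param reference A `mirna_reference`.
#' @return `read_reference_fasta()` returns a `mirna_reference`;
#'   `write_reference_fasta()` returns `path` invisibly.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  mirna_reference(tibble(
    mirna_id = sub("\\s.*$", "", names(ss)),
    sequence = as.character(ss)
  ))
}

#' @rdname read_reference_fasta
#' @export
write_reference_fasta <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(setNames(reference$sequence, reference$mirna_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
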