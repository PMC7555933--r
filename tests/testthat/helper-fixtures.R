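# Shared in-code fixtures for the suite.

# tiny fixed reference: hand-written sequences, lengths 20-22
tiny_reference <- function() {
  mirna_reference(tibble::tibble(
    mirna_id = c("mir-A", "mir-B", "mir-C"),
    sequence = c(
      "TGAGATGAAGCACTGTAGCTC",   # 21 nt
      "CCCTGAGACCCTTTAACCTGTG",  # 22 nt
      "TACAGTACTGTGATAACTGA"     # 20 nt
    )
  ))
}

two_group_design <- function(replicates = 2) {
  gen_design(sexes = "M", ages_months = c(3, 30), replicates = replicates)
}

# end-to-end helper: simulate one sample, clean, collapse, assign
simulate_and_assign <- function(truth, reference, design, sample_id,
                                depth, seed = NULL, max_mm = 2) {
  reads <- simulate_sample_reads(truth, reference, design, sample_id,
                                 depth = depth, seed = seed)
  cleaned <- clean_reads(reads, truth$adapter)
  assign_sample(collapse_reads(cleaned), reference, max_mm = max_mm)
}

# independent brute-force median-of-ratios oracle, written directly from
# the normalization definition with plain loops
oracle_norm_factors <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  mk <- m[keep, , drop = FALSE]
  gm <- numeric(nrow(mk))
  for (i in seq_len(nrow(mk))) gm[i] <- prod(mk[i, ])^(1 / ncol(mk))
  out <- numeric(ncol(mk))
  for (j in seq_len(ncol(mk))) {
    ratios <- numeric(nrow(mk))
    for (i in seq_len(nrow(mk))) ratios[i] <- mk[i, j] / gm[i]
    out[j] <- median(ratios)
  }
  out
}

# brute-force 5'-anchored aligner used as the mapping oracle
oracle_align <- function(sequence, reference, max_mm = 2, slack = 2) {
  best_mm <- Inf
  best_ids <- character(0)
  for (i in seq_len(nrow(reference))) {
    rs <- reference$sequence[i]
    if (abs(nchar(sequence) - nchar(rs)) > slack) next
    L <- min(nchar(sequence), nchar(rs))
    mm <- sum(strsplit(substr(sequence, 1, L), "")[[1]] !=
                strsplit(substr(rs, 1, L), "")[[1]])
    if (mm < best_mm) {
      best_mm <- mm
      best_ids <- reference$mirna_id[i]
    } else if (mm == best_mm) {
      best_ids <- c(best_ids, reference$mirna_id[i])
    }
  }
  if (!is.finite(best_mm) || best_mm > max_mm) {
    list(status = "unassigned", mirna_id = NA_character_)
  } else if (length(best_ids) > 1) {
    list(status = "ambiguous", mirna_id = NA_character_)
  } else {
    list(status = "assigned", mirna_id = best_ids, n_mismatch = best_mm)
  }
}

# brute-force all-offsets identity scan for the Sanger locator oracle
oracle_locate <- function(clone, ref, min_identity = 0.8) {
  L <- nchar(ref)
  best <- list(identity = -1, orientation = NA, offset = NA)
  for (orient in c("forward", "reverse-complement")) {
    pat <- if (orient == "forward") ref else revcomp(ref)
    pc <- strsplit(pat, "")[[1]]
    for (off in seq_len(nchar(clone) - L + 1)) {
      wc <- strsplit(substr(clone, off, off + L - 1), "")[[1]]
      id <- sum(wc == pc) / L
      # strict > keeps the first (forward, leftmost) window on ties,
      # matching the documented tie preference
      if (id > best$identity) {
        best <- list(identity = id, orientation = orient, offset = off)
      }
    }
  }
  best$found <- best$identity >= min_identity
  best
}
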