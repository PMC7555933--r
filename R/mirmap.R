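#' Align one read sequence to a mature-miRNA reference
#'
#' Alignment is 5'-anchored: a read is compared to each reference sequence
#' from position 1 over `min(len(read), len(ref))` bases, and a reference
#' is a candidate only when the length difference is at most
#' `max_3prime_slack` (absorbing 3' isomiR length variation). The
#' assignment is the unique candidate with the fewest mismatches, provided
#' that number is at most `max_mm`; a tie between distinct miRNAs yields
#' `ambiguous`, and no candidate within `max_mm` yields `unassigned`.
#' N bases never match and count as mismatches.
#'
#' @param sequence A single read sequence (17-24 nt, over ACGTN).
#' @param reference A [mirna_reference()].
#' @param max_mm Maximum mismatches tolerated (default 2: one edited site
#'   plus one sequencing error).
#' @param max_3prime_slack Maximum read/reference length difference.
#' @return A one-row tibble: `sequence`, `mirna_id` (NA unless assigned),
#'   `status` (assigned/ambiguous/unassigned), `n_mismatch`, and
#'   `mismatches` — a list column of tibbles `position` (1-based in the
#'   reference), `ref_base`, `read_base`.
#' @export
align_read <- function(sequence, reference, max_mm = 2, max_3prime_slack = 2) {
  stopifnot(length(sequence) == 1)
  align_engine(sequence, reference, max_mm, max_3prime_slack)
}

#' @keywords internal
align_engine <- function(seqs, reference, max_mm, max_3prime_slack) {
  stopifnot(inherits(reference, "mirna_reference"))
  seqs <- toupper(seqs)
  assert_dna(seqs, allow_n = TRUE, what = "read sequence")
  lens <- nchar(seqs)
  if (any(lens < 17 | lens > 24)) {
    abort("read sequences must be 17-24 nt; run clean_reads() first")
  }
  ref_len <- nchar(reference$sequence)
  ref_chars <- strsplit(reference$sequence, "")

  n <- length(seqs)
  mirna_id <- rep(NA_character_, n)
  status <- rep("unassigned", n)
  n_mismatch <- rep(NA_integer_, n)
  mismatches <- vector("list", n)

  for (Lr in unique(lens)) {
    rows <- which(lens == Lr)
    k <- length(rows)
    mat <- matrix(unlist(strsplit(seqs[rows], ""), use.names = FALSE),
                  nrow = k, byrow = TRUE)
    cand <- which(abs(ref_len - Lr) <= max_3prime_slack)
    if (!length(cand)) next
    mm <- matrix(NA_integer_, nrow = k, ncol = length(cand))
    for (j in seq_along(cand)) {
      Lc <- min(Lr, ref_len[cand[j]])
      rc <- ref_chars[[cand[j]]][seq_len(Lc)]
      mm[, j] <- as.integer(
        rowSums(mat[, seq_len(Lc), drop = FALSE] !=
                  matrix(rc, nrow = k, ncol = Lc, byrow = TRUE))
      )
    }
    best <- do.call(pmin, as.data.frame(mm))
    n_best <- rowSums(mm == best)
    ok <- best <= max_mm
    amb <- ok & n_best > 1
    asn <- ok & n_best == 1
    status[rows[amb]] <- "ambiguous"
    n_mismatch[rows[amb]] <- best[amb]
    if (any(asn)) {
      which_ref <- cand[apply(mm[asn, , drop = FALSE], 1, which.min)]
      arows <- rows[asn]
      status[arows] <- "assigned"
      n_mismatch[arows] <- best[asn]
      mirna_id[arows] <- reference$mirna_id[which_ref]
      for (i in seq_along(arows)) {
        r <- which_ref[i]
        Lc <- min(Lr, ref_len[r])
        rc <- ref_chars[[r]][seq_len(Lc)]
        rd <- mat[which(asn)[i], seq_len(Lc)]
        d <- which(rd != rc)
        mismatches[[arows[i]]] <- tibble(
          position = d, ref_base = rc[d], read_base = rd[d]
        )
      }
    }
  }
  empty <- tibble(position = integer(), ref_base = character(),
                  read_base = character())
  mismatches[vapply(mismatches, is.null, logical(1))] <- list(empty)
  tibble(
    sequence = seqs, mirna_id = mirna_id, status = status,
    n_mismatch = n_mismatch, mismatches = mismatches, read_len = lens
  )
}

#' Assign a unique-read table to miRNAs
#'
#' Runs [align_read()] over every unique sequence of a collapsed sample
#' table, weighting the assignment summary by read counts.
#'
#' @param table Unique-read tibble from [collapse_reads()]
#'   (`sequence`, `count`, optional `sample_id`).
#' @param reference A [mirna_reference()].
#' @inheritParams align_read
#' @return The table with alignment columns appended, plus an
#'   `"assignment_summary"` attribute: read totals by status
#'   (`assigned + ambiguous + unassigned = total`).
#' @export
assign_sample <- function(table, reference, max_mm = 2, max_3prime_slack = 2) {
  table <- as_tibble(table)
  aln <- align_engine(table$sequence, reference, max_mm, max_3prime_slack)
  out <- dplyr::bind_cols(
    table[setdiff(names(table), names(aln))],
    aln
  )
  attr(out, "assignment_summary") <- out |>
    group_by(.data$status) |>
    summarise(reads = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "status", values_from = "reads") |>
    (\(x) {
      for (col in c("assigned", "ambiguous", "unassigned")) {
        if (!col %in% names(x)) x[[col]] <- 0L
      }
      x$total <- x$assigned + x$ambiguous + x$unassigned
      x[c("assigned", "ambiguous", "unassigned", "total")]
    })()
  out
}

#' Build the miRNA-by-sample count matrix
#'
#' Entry (m, s) is the total count of sequences assigned to miRNA m in
#' sample s. Ambiguous and unassigned reads are excluded and reported in
#' the `"unassigned_summary"` attribute.
#'
#' @param assignments One assignment tibble per sample (a list or a single
#'   row-bound tibble with a `sample_id` column), as returned by
#'   [assign_sample()].
#' @param design Sample design tibble; every sample in `assignments` must
#'   appear in it.
#' @param reference Optional [mirna_reference()]; when given, all its
#'   miRNAs appear as rows (zero-filled).
#' @return A wide count tibble: `mirna_id` plus one column per design
#'   sample.
#' @export
build_count_matrix <- function(assignments, design, reference = NULL) {
  if (is.data.frame(assignments)) assignments <- list(assignments)
  asn <- bind_rows(assignments)
  design <- validate_design(design)
  if (!"sample_id" %in% names(asn)) abort("assignments need a sample_id column")
  extra <- setdiff(unique(asn$sample_id), design$sample_id)
  if (length(extra)) {
    abort(paste("samples absent from design:", paste(extra, collapse = ", ")))
  }
  mirnas <- if (!is.null(reference)) reference$mirna_id else
    sort(unique(asn$mirna_id[asn$status == "assigned"]))

  wide <- asn |>
    filter(.data$status == "assigned") |>
    group_by(.data$sample_id, .data$mirna_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
  out <- tibble(mirna_id = mirnas) |>
    left_join(wide, by = "mirna_id")
  for (s in design$sample_id) {
    if (!s %in% names(out)) out[[s]] <- 0L
    out[[s]][is.na(out[[s]])] <- 0L
  }
  out <- out[c("mirna_id", design$sample_id)]

  attr(out, "unassigned_summary") <- asn |>
    group_by(.data$sample_id, .data$status) |>
    summarise(reads = sum(.data$count), .groups = "drop")
  out
}
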