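#' Per-position base profile of reads assigned to one miRNA
#'
#' Every assigned read contributes its observed base at each reference
#' position it covers (the reference base wherever no mismatch was
#' recorded). Positions beyond a short read's 3' end are uncovered, so
#' coverage can drop toward the reference 3' end.
#'
#' @param assignments Assignment tibble from [assign_sample()] (one or
#'   several samples row-bound; only `status == "assigned"` rows for
#'   `mirna_id` are used).
#' @param reference A [mirna_reference()].
#' @param mirna_id The miRNA to profile.
#' @return A tibble with one row per reference position: `mirna_id`,
#'   `position`, `ref_base`, base counts `A`, `C`, `G`, `T`, and
#'   `coverage` (their sum).
#' @export
mismatch_profile <- function(assignments, reference, mirna_id) {
  stopifnot(inherits(reference, "mirna_reference"))
  i <- match(mirna_id, reference$mirna_id)
  if (is.na(i)) abort(sprintf("unknown miRNA '%s'", mirna_id))
  ref_seq <- reference$sequence[i]
  L <- nchar(ref_seq)
  ref_chars <- strsplit(ref_seq, "")[[1]]

  asn <- assignments |>
    filter(.data$status == "assigned", .data$mirna_id == !!mirna_id)

  counts <- matrix(0, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  if (nrow(asn)) {
    cov_len <- pmin(asn$read_len, L)
    # coverage at position p = reads whose compared length reaches p
    cum <- vapply(seq_len(L), function(p) sum(asn$count[cov_len >= p]),
                  numeric(1))
    for (p in seq_len(L)) counts[ref_chars[p], p] <- cum[p]
    for (r in seq_len(nrow(asn))) {
      mm <- asn$mismatches[[r]]
      if (!nrow(mm)) next
      for (j in seq_len(nrow(mm))) {
        p <- mm$position[j]
        b <- mm$read_base[j]
        counts[ref_chars[p], p] <- counts[ref_chars[p], p] - asn$count[r]
        if (b %in% DNA_BASES) counts[b, p] <- counts[b, p] + asn$count[r]
        # N observations are removed from coverage rather than counted
      }
    }
  }
  tibble(
    mirna_id = mirna_id,
    position = seq_len(L),
    ref_base = ref_chars,
    A = counts["A", ], C = counts["C", ], G = counts["G", ], T = counts["T", ],
    coverage = colSums(counts)
  )
}

#' Call editing sites from a mismatch profile
#'
#' A site is called for an alternative base when its fraction of the
#' position's coverage exceeds `min_fraction_factor * error_rate` (a
#' signal-above-noise rule tied to the sequencing error model) and it is
#' supported by at least `min_edited_reads` reads. All alternative bases
#' are reported; `is_a_to_g` flags the ADAR-consistent A-to-G subset and
#' `in_seed` flags positions 2-7, the target-recognition seed.
#'
#' @param profile Tibble from [mismatch_profile()].
#' @param error_rate Per-base sequencing error rate in \[0, 0.05\].
#' @param min_fraction_factor Fraction threshold multiplier (default 3).
#' @param min_edited_reads Minimum supporting reads (default 5).
#' @return A tibble of calls: `mirna_id`, `position`, `ref_base`,
#'   `alt_base`, `edited_reads`, `total_reads`, `fraction`, `is_a_to_g`,
#'   `in_seed`; zero rows when nothing passes.
#' @export
call_editing_sites <- function(profile, error_rate,
                               min_fraction_factor = 3, min_edited_reads = 5) {
  if (error_rate < 0 || error_rate > 0.05) {
    abort("error_rate must lie in [0, 0.05]")
  }
  long <- profile |>
    tidyr::pivot_longer(dplyr::all_of(DNA_BASES), names_to = "alt_base",
                        values_to = "edited_reads") |>
    filter(.data$alt_base != .data$ref_base, .data$edited_reads > 0,
           .data$coverage > 0) |>
    mutate(
      total_reads = .data$coverage,
      fraction = .data$edited_reads / .data$total_reads
    ) |>
    filter(
      .data$fraction > min_fraction_factor * error_rate,
      .data$edited_reads >= min_edited_reads
    ) |>
    mutate(
      is_a_to_g = .data$ref_base == "A" & .data$alt_base == "G",
      in_seed = in_seed_region(.data$position)
    ) |>
    select("mirna_id", "position", "ref_base", "alt_base", "edited_reads",
           "total_reads", "fraction", "is_a_to_g", "in_seed") |>
    arrange(.data$position, .data$alt_base)
  long
}

#' Summarize edited miRNAs for a group of samples
#'
#' Reproduces the doughnut-chart bookkeeping: among miRNAs whose mean
#' normalized count across the whole dataset is strictly greater than
#' `min_avg_reads` (default 3000) and which carry at least one called
#' site, a read is "edited" when it bears the alternative base of a
#' called site. Reads of the group's samples are pooled.
#'
#' @param assignments Row-bound assignment tibbles for all samples.
#' @param calls Editing calls from [call_editing_sites()] (all miRNAs
#'   row-bound).
#' @param norm_counts Normalized wide count tibble (see
#'   [normalize_counts()]); the `> min_avg_reads` filter uses its mean
#'   over all sample columns.
#' @param group_samples Character vector of sample ids forming the group.
#' @param min_avg_reads Strict lower bound on the dataset-wide mean
#'   normalized count (default 3000).
#' @return A tibble of class `edited_summary`: `mirna_id`,
#'   `edited_read_count`, `total_reads`, `percent_of_mirna_reads`
#'   (100 x edited/total within the miRNA) and `doughnut_share`
#'   (100 x edited / sum of edited over retained miRNAs), sorted by
#'   descending `edited_read_count`; attribute `"top6"` holds the top six
#'   miRNA ids (ties broken by id).
#' @export
summarize_edited <- function(assignments, calls, norm_counts, group_samples,
                             min_avg_reads = 3000) {
  if (!length(group_samples)) abort("group_samples must be non-empty")
  missing <- setdiff(group_samples, names(norm_counts))
  if (length(missing)) {
    abort(paste("samples absent from norm_counts:", paste(missing, collapse = ", ")))
  }
  sample_cols <- setdiff(names(norm_counts), "mirna_id")
  dataset_mean <- rowMeans(as.matrix(norm_counts[sample_cols]))
  abundant <- norm_counts$mirna_id[dataset_mean > min_avg_reads]
  retained <- intersect(abundant, unique(calls$mirna_id))

  grp <- assignments |>
    filter(.data$sample_id %in% group_samples, .data$status == "assigned",
           .data$mirna_id %in% retained)

  per_mirna <- lapply(retained, function(m) {
    sub <- grp |> filter(.data$mirna_id == m)
    sites <- calls |> filter(.data$mirna_id == m)
    edited <- 0
    if (nrow(sub)) {
      is_edited <- vapply(sub$mismatches, function(mm) {
        nrow(mm) > 0 && any(paste(mm$position, mm$read_base) %in%
                              paste(sites$position, sites$alt_base))
      }, logical(1))
      edited <- sum(sub$count[is_edited])
    }
    tibble(mirna_id = m, edited_read_count = edited,
           total_reads = sum(sub$count))
  }) |> bind_rows()

  if (!nrow(per_mirna)) {
    out <- tibble(mirna_id = character(), edited_read_count = numeric(),
                  total_reads = numeric(), percent_of_mirna_reads = numeric(),
                  doughnut_share = numeric())
    attr(out, "top6") <- character(0)
    class(out) <- c("edited_summary", class(out))
    return(out)
  }

  total_edited <- sum(per_mirna$edited_read_count)
  out <- per_mirna |>
    mutate(
      percent_of_mirna_reads = ifelse(
        .data$total_reads > 0, 100 * .data$edited_read_count / .data$total_reads, 0
      ),
      doughnut_share = if (total_edited > 0)
        100 * .data$edited_read_count / total_edited else 0
    ) |>
    arrange(desc(.data$edited_read_count), .data$mirna_id)
  attr(out, "top6") <- head(out$mirna_id, 6)
  attr(out, "group_samples") <- group_samples
  class(out) <- c("edited_summary", class(out))
  out
}
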