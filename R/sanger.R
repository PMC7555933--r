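#' Locate a mature-miRNA insert within a clone sequence
#'
#' Ungapped sliding-window scan of the reference (and its reverse
#' complement) across the clone; the best window by identity wins and is
#' reported only when identity reaches `min_identity`. On an exact
#' orientation tie the forward orientation is preferred. Clones with
#' apparent indels inside the insert fall below `min_identity` and are
#' excluded rather than gap-aligned, because editing calls through a gap
#' would be meaningless.
#'
#' @param clone_seq Clone sequence (vector + insert, DNA).
#' @param ref_seq Mature miRNA reference sequence (>= 17 nt).
#' @param min_identity Minimum window identity (default 0.8).
#' @return A list: `found`, `orientation` (`"forward"` or
#'   `"reverse-complement"`), `offset` (1-based clone position of the
#'   window start), `identity`, `clone_window`, and `ref_seq`.
#' @export
locate_insert <- function(clone_seq, ref_seq, min_identity = 0.8) {
  clone_seq <- normalise_seq(clone_seq)
  ref_seq <- normalise_seq(ref_seq)
  assert_dna(clone_seq, allow_n = TRUE, what = "clone sequence")
  assert_dna(ref_seq, what = "reference sequence")
  L <- nchar(ref_seq)
  if (L < 17) abort("reference must be at least 17 nt")
  if (nchar(clone_seq) < L) {
    return(list(found = FALSE, orientation = NA_character_,
                offset = NA_integer_, identity = 0,
                clone_window = NA_character_, ref_seq = ref_seq))
  }
  fwd <- scan_identity(clone_seq, ref_seq)
  rev <- scan_identity(clone_seq, revcomp(ref_seq))
  # forward preferred on ties
  use_fwd <- fwd$best >= rev$best
  best <- if (use_fwd) fwd else rev
  identity <- best$best / L
  if (identity < min_identity) {
    return(list(found = FALSE, orientation = NA_character_,
                offset = NA_integer_, identity = identity,
                clone_window = NA_character_, ref_seq = ref_seq))
  }
  list(
    found = TRUE,
    orientation = if (use_fwd) "forward" else "reverse-complement",
    offset = best$offset,
    identity = identity,
    clone_window = substr(clone_seq, best$offset, best$offset + L - 1),
    ref_seq = ref_seq
  )
}

# best ungapped window match of `pattern` in `subject`:
# O(len(pattern)) vectorised passes over all offsets
scan_identity <- function(subject, pattern) {
  sc <- strsplit(subject, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  L <- length(pc)
  n_off <- length(sc) - L + 1
  matches <- integer(n_off)
  for (i in seq_len(L)) {
    matches <- matches + (sc[i:(i + n_off - 1)] == pc[i])
  }
  best <- which.max(matches)
  list(offset = best, best = matches[best])
}

#' Call substitutions in a located clone insert
#'
#' Every aligned mismatch is reported in 1-based reference coordinates
#' using reference-strand bases: for reverse-complement inserts the
#' observed clone base is complemented back before reporting, so an
#' A-to-I edit that appears as C on the clone strand is reported as
#' observed G. `is_a_to_g` flags ADAR-consistent changes and `in_seed`
#' flags positions 2-7.
#'
#' @param alignment Result of [locate_insert()] with `found = TRUE`.
#' @return A tibble of calls: `position`, `ref_base`, `observed_base`,
#'   `is_a_to_g`, `in_seed` (zero rows for an exact insert).
#' @export
call_clone_substitutions <- function(alignment) {
  if (!isTRUE(alignment$found)) abort("insert was not located in this clone")
  ref <- strsplit(alignment$ref_seq, "")[[1]]
  L <- length(ref)
  win <- strsplit(alignment$clone_window, "")[[1]]
  if (alignment$orientation == "forward") {
    pos <- which(win != ref)
    obs <- win[pos]
  } else {
    rc <- strsplit(revcomp(alignment$ref_seq), "")[[1]]
    mism <- which(win != rc)
    pos <- L - mism + 1
    obs <- complement_base(win[mism])
    o <- order(pos)
    pos <- pos[o]
    obs <- obs[o]
  }
  tibble(
    position = as.integer(pos),
    ref_base = ref[pos],
    observed_base = obs,
    is_a_to_g = ref[pos] == "A" & obs == "G",
    in_seed = in_seed_region(pos)
  )
}

#' Call substitutions across a set of clones
#'
#' Convenience wrapper: locates the insert in every clone and returns all
#' substitution calls with clone provenance, plus the list of clones in
#' which no insert was found.
#'
#' @param clones Clone tibble (`clone_id`, `animal_id`, `sex`,
#'   `age_months`, `colony_id`, `sequence`), e.g. from [gen_clones()].
#' @param ref_seq Mature miRNA reference sequence.
#' @param min_identity Passed to [locate_insert()].
#' @return A tibble of calls with provenance columns; attributes
#'   `"not_found"` (clone ids without a locatable insert) and
#'   `"located"` (per-clone orientation/identity tibble).
#' @export
call_clones <- function(clones, ref_seq, min_identity = 0.8) {
  calls <- vector("list", nrow(clones))
  located <- vector("list", nrow(clones))
  for (i in seq_len(nrow(clones))) {
    aln <- locate_insert(clones$sequence[i], ref_seq, min_identity)
    located[[i]] <- tibble(
      clone_id = clones$clone_id[i], found = aln$found,
      orientation = aln$orientation, identity = aln$identity
    )
    if (!aln$found) next
    cc <- call_clone_substitutions(aln)
    if (nrow(cc)) {
      calls[[i]] <- dplyr::bind_cols(
        clones[i, c("clone_id", "animal_id", "sex", "age_months", "colony_id")][
          rep(1, nrow(cc)), ],
        cc
      )
    }
  }
  out <- bind_rows(calls)
  if (!nrow(out)) {
    out <- tibble(
      clone_id = character(), animal_id = character(), sex = character(),
      age_months = integer(), colony_id = integer(), position = integer(),
      ref_base = character(), observed_base = character(),
      is_a_to_g = logical(), in_seed = logical()
    )
  }
  located <- bind_rows(located)
  attr(out, "not_found") <- located$clone_id[!located$found]
  attr(out, "located") <- located
  out
}

#' Summarize clone editing by sex and age group
#'
#' @param calls Substitution calls from [call_clones()].
#' @param clones The clone tibble the calls came from.
#' @param min_colonies Expected colonies per animal (default 3); animals
#'   below this are flagged (warned about, not dropped).
#' @return A tibble per (sex, age): `clones_sequenced`,
#'   `clones_with_a_to_g`, `seed_calls`, `nonseed_calls`, `total_calls`,
#'   `a_to_g_calls`; attributes `"per_position"` (per-position call
#'   recurrence across colonies, the substrate for a concordance filter)
#'   and `"low_colony_animals"`.
#' @export
summarize_clone_editing <- function(calls, clones, min_colonies = 3) {
  if (!nrow(clones)) abort("no clones supplied")
  colonies <- clones |>
    count(.data$sex, .data$age_months, .data$animal_id, name = "n_colonies")
  low <- colonies |> filter(.data$n_colonies < min_colonies)
  if (nrow(low)) {
    warn(sprintf("%d animal(s) have fewer than %d colonies", nrow(low),
                 min_colonies))
  }
  a2g_clones <- calls |>
    filter(.data$is_a_to_g) |>
    distinct(.data$clone_id)
  by_group <- clones |>
    group_by(.data$sex, .data$age_months) |>
    summarise(
      clones_sequenced = dplyr::n(),
      clones_with_a_to_g = sum(.data$clone_id %in% a2g_clones$clone_id),
      .groups = "drop"
    )
  call_counts <- calls |>
    group_by(.data$sex, .data$age_months) |>
    summarise(
      seed_calls = sum(.data$in_seed),
      nonseed_calls = sum(!.data$in_seed),
      total_calls = dplyr::n(),
      a_to_g_calls = sum(.data$is_a_to_g),
      .groups = "drop"
    )
  out <- by_group |>
    left_join(call_counts, by = c("sex", "age_months")) |>
    mutate(across(
      c("seed_calls", "nonseed_calls", "total_calls", "a_to_g_calls"),
      ~ ifelse(is.na(.x), 0L, .x)
    ))
  attr(out, "per_position") <- calls |>
    count(.data$sex, .data$age_months, .data$position, .data$ref_base,
          .data$observed_base, name = "n_colonies_with_call")
  attr(out, "low_colony_animals") <- low
  out
}
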