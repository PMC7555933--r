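#' Generate a simulation truth table
#'
#' Plants the ground truth that downstream stages are asked to recover:
#' per-miRNA baseline abundances (negative-binomial means), per-group
#' log2 fold-change effects for a chosen set of differentially expressed
#' miRNAs, and per-site A-to-G editing fractions at adenosine positions of
#' chosen miRNAs. Editing is A-to-G only — inosine produced by ADAR
#' deamination is read as guanosine by the sequencer.
#'
#' @param reference A [mirna_reference()].
#' @param design A design tibble from [gen_design()].
#' @param n_de Number of differentially expressed miRNAs.
#' @param log2fc Log2 fold change applied to DE miRNAs in the affected
#'   groups (scalar or length `n_de`).
#' @param affected_groups Groups receiving the effect; default all groups
#'   whose age is above the youngest age in the design (the youngest age
#'   group is the control, as in longitudinal aging comparisons).
#' @param n_edited Number of miRNAs given one planted editing site each.
#' @param edited_fraction Editing fraction(s) in `edited_groups`; scalar or
#'   length `n_edited`, each in \[0, 1\].
#' @param edited_groups Groups in which planted sites are edited; default
#'   all groups.
#' @param baseline_mean Either `NULL` (baselines drawn log-uniform over
#'   `baseline_range`) or a numeric vector of per-miRNA means.
#' @param baseline_range Range for log-uniform baseline draws.
#' @param dispersion Negative-binomial size parameter (larger = less
#'   overdispersed; 25 gives a count CV of about 0.2 at high mean).
#' @param error_rate Per-base sequencing error rate in \[0, 0.05\].
#' @param adapter 3' adapter appended to every simulated read.
#' @param read_length Raw read length (Illumina small-RNA runs: 50 nt).
#' @param seed Master seed; per-sample seeds are derived with
#'   [derive_seed()].
#' @return A `simulation_truth` list with tibbles `mirnas`
#'   (`mirna_id`, `baseline_mean`, `dispersion`), `effects`
#'   (`mirna_id`, `group`, `log2fc`) and `editing_sites`
#'   (`mirna_id`, `position`, `group`, `edited_fraction`), plus the
#'   generator settings.
#' @export
gen_truth <- function(reference, design,
                      n_de = 0, log2fc = 2, affected_groups = NULL,
                      n_edited = 0, edited_fraction = 0.3, edited_groups = NULL,
                      baseline_mean = NULL, baseline_range = c(500, 5000),
                      dispersion = 25, error_rate = 0.001,
                      adapter = DEFAULT_ADAPTER, read_length = 50,
                      seed) {
  stopifnot(inherits(reference, "mirna_reference"))
  design <- validate_design(design)
  n <- nrow(reference)
  if (n_de > n) abort("n_de exceeds the number of miRNAs")
  if (n_edited > n) abort("n_edited exceeds the number of miRNAs")
  if (any(edited_fraction < 0 | edited_fraction > 1)) {
    abort("edited_fraction must lie in [0, 1]")
  }
  if (error_rate < 0 || error_rate > 0.05) {
    abort("error_rate must lie in [0, 0.05]")
  }
  groups <- unique(design$group)
  affected_groups <- affected_groups %||%
    unique(design$group[design$age_months > min(design$age_months)])
  edited_groups <- edited_groups %||% groups
  if (!all(affected_groups %in% groups)) abort("unknown affected_groups")
  if (!all(edited_groups %in% groups)) abort("unknown edited_groups")

  withr::with_seed(seed, {
    if (is.null(baseline_mean)) {
      baseline_mean <- exp(runif(n, log(baseline_range[1]), log(baseline_range[2])))
    }
    stopifnot(length(baseline_mean) == n, all(baseline_mean > 0))
    mirnas <- tibble(
      mirna_id = reference$mirna_id,
      baseline_mean = baseline_mean,
      dispersion = dispersion
    )

    effects <- tibble(mirna_id = character(), group = character(), log2fc = numeric())
    if (n_de > 0) {
      de_ids <- sample(reference$mirna_id, n_de)
      effects <- tidyr::expand_grid(
        mirna_id = de_ids, group = affected_groups
      ) |>
        left_join(tibble(mirna_id = de_ids, log2fc = rep_len(log2fc, n_de)),
                  by = "mirna_id")
    }

    editing_sites <- tibble(
      mirna_id = character(), position = integer(),
      group = character(), edited_fraction = numeric()
    )
    if (n_edited > 0) {
      has_a <- grepl("A", reference$sequence, fixed = TRUE)
      if (sum(has_a) < n_edited) {
        abort("not enough miRNAs containing an A to place the requested editing sites")
      }
      # only miRNAs with at least one adenosine can carry an A->G site
      edit_ids <- sample(reference$mirna_id[has_a], n_edited)
      pos <- vapply(edit_ids, function(id) {
        s <- reference$sequence[reference$mirna_id == id]
        a_pos <- which(strsplit(s, "")[[1]] == "A")
        if (length(a_pos) == 1) a_pos else sample(a_pos, 1)
      }, integer(1), USE.NAMES = FALSE)
      editing_sites <- tidyr::expand_grid(
        i = seq_len(n_edited), group = edited_groups
      ) |>
        mutate(
          mirna_id = edit_ids[.data$i],
          position = pos[.data$i],
          edited_fraction = rep_len(edited_fraction, n_edited)[.data$i]
        ) |>
        select("mirna_id", "position", "group", "edited_fraction")
    }

    structure(
      list(
        mirnas = mirnas,
        effects = effects,
        editing_sites = editing_sites,
        error_rate = error_rate,
        adapter = normalise_seq(adapter),
        read_length = as.integer(read_length),
        master_seed = as.integer(seed)
      ),
      class = "simulation_truth"
    )
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth>\n")
  cat("  miRNAs:       ", nrow(x$mirnas), "\n")
  cat("  DE effects:   ", length(unique(x$effects$mirna_id)), "miRNAs\n")
  cat("  edited sites: ", length(unique(paste(x$editing_sites$mirna_id,
                                              x$editing_sites$position))), "\n")
  cat("  error rate:   ", x$error_rate, "; read length:", x$read_length, "\n")
  invisible(x)
}

#' Write the truth tables to TSV
#'
#' Writes one row per (site, group) with the planted fraction, and one row
#' per (miRNA, group) effect with its log2 fold change.
#'
#' @param truth A `simulation_truth`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  sites <- truth$editing_sites |> mutate(kind = "editing_site", log2fc = NA_real_)
  eff <- truth$effects |>
    mutate(kind = "abundance_effect", position = NA_integer_,
           edited_fraction = NA_real_)
  readr::write_tsv(
    bind_rows(sites, eff) |>
      select("kind", "mirna_id", "position", "group", "edited_fraction", "log2fc"),
    path
  )
  invisible(path)
}
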