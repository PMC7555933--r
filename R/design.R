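#' Build a sex-by-age sample design
#'
#' The study design crossed with replication: sexes M/F and ages 3, 6, 15,
#' 25 and 30 months, `replicates` animals per cell. The `group` column
#' (`"<sex>-<age>"`) labels each sex-age cell and is the unit of editing
#' summaries, DE comparisons and simulation effects.
#'
#' @param sexes Character vector, subset of `c("M", "F")`.
#' @param ages_months Integer vector, subset of `c(3, 6, 15, 25, 30)`.
#' @param replicates Samples per sex-age group.
#' @return A tibble with columns `sample_id`, `sex`, `age_months`,
#'   `replicate`, `group`.
#' @export
#' @examples
#' gen_design(replicates = 4)
gen_design <- function(sexes = c("M", "F"),
                       ages_months = c(3, 6, 15, 25, 30),
                       replicates = 4) {
  stopifnot(all(sexes %in% c("M", "F")),
            all(ages_months %in% c(3, 6, 15, 25, 30)),
            replicates >= 1)
  d <- tidyr::expand_grid(
    sex = sexes,
    age_months = as.integer(ages_months),
    replicate = seq_len(replicates)
  )
  d |>
    mutate(
      sample_id = sprintf("%s%02d_r%d", .data$sex, .data$age_months, .data$replicate),
      group = sprintf("%s-%d", .data$sex, .data$age_months)
    ) |>
    select("sample_id", "sex", "age_months", "replicate", "group") |>
    validate_design()
}

#' @keywords internal
validate_design <- function(design) {
  design <- as_tibble(design)
  need <- c("sample_id", "sex", "age_months", "replicate")
  if (!all(need %in% names(design))) {
    abort(paste("design needs columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) abort("duplicate sample_id in design")
  if (!all(design$sex %in% c("M", "F"))) abort("sex must be M or F")
  if (!"group" %in% names(design)) {
    design$group <- sprintf("%s-%d", design$sex, design$age_months)
  }
  design
}

#' Read a sample design from TSV
#'
#' Expects columns `sample_id`, `sex`, `age_months`, `replicate`.
#'
#' @param path TSV file path.
#' @return A design tibble (see [gen_design()]).
#' @export
read_design_tsv <- function(path) {
  validate_design(readr::read_tsv(path, show_col_types = FALSE))
}
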