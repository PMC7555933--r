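#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a DE result
#'
#' @param x A `miredit_de` from [de_test()].
#' @param ... Unused.
#' @return The per-miRNA result tibble (already tidy).
#' @exportS3Method generics::tidy
tidy.miredit_de <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-row summary of a DE result
#'
#' @param x A `miredit_de`.
#' @param ... Unused.
#' @return A tibble: miRNAs tested and counts per significance tier.
#' @exportS3Method generics::glance
glance.miredit_de <- function(x, ...) {
  tb <- table(x$tier)
  tibble(
    n_mirnas = nrow(x),
    n_red = unname(tb["red"]), n_orange = unname(tb["orange"]),
    n_blue = unname(tb["blue"]), n_ns = unname(tb["ns"])
  )
}

#' Tidy pairwise Tukey comparisons
#'
#' @param x A `miredit_anova` from [anova_delta_ct()].
#' @param ... Unused.
#' @return The pairwise comparison tibble.
#' @exportS3Method generics::tidy
tidy.miredit_anova <- function(x, ...) x$tukey

#' One-row ANOVA summary
#'
#' @param x A `miredit_anova`.
#' @param ... Unused.
#' @return A tibble with the F statistic, degrees of freedom and p-value.
#' @exportS3Method generics::glance
glance.miredit_anova <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, df1 = x$df[1], df2 = x$df[2],
         p_value = x$p_value)
}

#' Tidy a fold-change result
#'
#' @param x A `miredit_fold` from [pfaffl_fold()].
#' @param ... Unused.
#' @return The per-sample tibble (delta-Ct, delta-delta-Ct, fold).
#' @exportS3Method generics::tidy
tidy.miredit_fold <- function(x, ...) attr(x, "per_sample")
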