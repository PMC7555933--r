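#' Pfaffl / delta-delta-Ct relative quantification
#'
#' Per sample, `delta_ct = ct_target - ct_reference` (reference = the
#' housekeeping gene, e.g. 18S); `ddct = delta_ct - mean(delta_ct)` of the
#' control group; the fold change is `E^(-ddct)` with amplification
#' efficiency E defaulting to 2, which reduces to the classical
#' `2^-ddct`. When per-gene efficiencies for both the target and the
#' reference are supplied, the efficiency-corrected dual-E Pfaffl ratio
#' `E_t^(dCt_t) / E_ref^(dCt_ref)` (dCt = control mean - sample) is also
#' emitted.
#'
#' @param ct Ct tibble with columns `sample_id`, `group`, `ct_target`,
#'   `ct_reference`, optional `target` (gene label; computed per gene when
#'   present) and optional `efficiency_target`, `efficiency_reference`
#'   (each in \[1.6, 2.2\]).
#' @param control_group Label of the control group (e.g. the youngest age
#'   group of each sex); must be non-empty.
#' @param efficiency Amplification efficiency used when the table carries
#'   no per-gene efficiencies (default 2).
#' @return A per-group tibble of class `miredit_fold`: `target`, `group`,
#'   `n`, `mean_delta_ct`, `mean_ddct`, `fold` (with
#'   `fold = E^(-mean_ddct)`, so the control group's fold is exactly 1);
#'   attribute `"per_sample"` holds sample-level `delta_ct`, `ddct` and
#'   `fold`.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = paste0("s", 1:4), group = c("ctl", "ctl", "old", "old"),
#'   ct_target = c(20, 20, 19, 19), ct_reference = c(15, 15, 15, 15)
#' )
#' pfaffl_fold(ct, "ctl") # the old group is one cycle earlier: fold 2
pfaffl_fold <- function(ct, control_group, efficiency = 2) {
  ct <- as_tibble(ct)
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) {
    abort(paste("ct needs columns:", paste(need, collapse = ", ")))
  }
  if (!"target" %in% names(ct)) ct$target <- "target"
  if (!any(ct$group == control_group)) {
    abort(sprintf("control group '%s' is empty", control_group))
  }
  bad <- !is.finite(ct$ct_reference)
  if (any(bad)) {
    warn(sprintf("excluding %d sample(s) with missing reference Ct", sum(bad)))
    ct <- ct[!bad, , drop = FALSE]
  }
  if (any(ct$ct_target <= 0 | ct$ct_target >= 45, na.rm = TRUE) ||
      any(ct$ct_reference <= 0 | ct$ct_reference >= 45)) {
    abort("Ct values must lie in (0, 45)")
  }
  has_eff <- all(c("efficiency_target", "efficiency_reference") %in% names(ct))

  per_sample <- ct |>
    group_by(.data$target) |>
    mutate(
      delta_ct = .data$ct_target - .data$ct_reference,
      ddct = .data$delta_ct - mean(.data$delta_ct[.data$group == control_group]),
      e_target = if (has_eff) .data$efficiency_target else efficiency,
      fold = .data$e_target^(-.data$ddct)
    )
  if (has_eff) {
    per_sample <- per_sample |>
      mutate(
        d_target = mean(.data$ct_target[.data$group == control_group]) - .data$ct_target,
        d_reference = mean(.data$ct_reference[.data$group == control_group]) - .data$ct_reference,
        fold_pfaffl = .data$efficiency_target^.data$d_target /
          .data$efficiency_reference^.data$d_reference
      ) |>
      select(-"d_target", -"d_reference")
  }
  per_sample <- per_sample |> ungroup() |> select(-"e_target")

  groups <- per_sample |>
    group_by(.data$target, .data$group) |>
    summarise(
      n = dplyr::n(),
      mean_delta_ct = mean(.data$delta_ct),
      mean_ddct = mean(.data$ddct),
      .groups = "drop"
    ) |>
    mutate(fold = (if (has_eff) {
      per_sample$efficiency_target[match(paste(.data$target), paste(per_sample$target))]
    } else efficiency)^(-.data$mean_ddct))
  attr(groups, "per_sample") <- per_sample
  attr(groups, "control_group") <- control_group
  class(groups) <- c("miredit_fold", class(groups))
  groups
}

#' One-way ANOVA with Tukey HSD on delta-Ct values
#'
#' Testing is done at the delta-Ct level (not on fold changes) to avoid
#' the bias introduced by averaging exponentially transformed data.
#' Singleton groups are excluded from the pairwise comparisons with a
#' warning.
#'
#' @param data Tibble with the response and grouping columns.
#' @param value Name of the delta-Ct column (default `"delta_ct"`).
#' @param group Name of the group column (default `"group"`).
#' @return An object of class `miredit_anova`: list with `f_statistic`,
#'   `p_value`, `df`, the `aov` fit, and `tukey`, a tibble of pairwise
#'   comparisons (`comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_delta_ct <- function(data, value = "delta_ct", group = "group") {
  data <- as_tibble(data)
  y <- data[[value]]
  g <- as.character(data[[group]])
  if (is.null(y) || is.null(g)) abort("value/group columns not found")
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 groups")
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons)) {
    warn(paste("singleton group(s) excluded from pairwise tests:",
               paste(singletons, collapse = ", ")))
  }
  keep <- !(g %in% singletons)
  d <- data.frame(y = y[keep], g = factor(g[keep]))
  fit <- aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  f <- an$`F value`[1]
  p <- an$`Pr(>F)`[1]
  if (var(d$y) == 0) f <- NaN  # identical constants: F is 0/0, not evidence
  if (!is.finite(f)) {
    # all groups identical constants: 0/0 F statistic; no evidence either way
    f <- 0
    p <- 1
    tukey <- tibble(comparison = character(), diff = numeric(),
                    lwr = numeric(), upr = numeric(), p_adj = numeric())
  } else {
    tk <- TukeyHSD(fit)$g
    tukey <- tibble(
      comparison = rownames(tk),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = tk[, "p adj"]
    )
  }
  structure(
    list(f_statistic = f, p_value = p,
         df = unname(an$Df), fit = fit, tukey = tukey),
    class = "miredit_anova"
  )
}

#' @export
print.miredit_anova <- function(x, ...) {
  cat("One-way ANOVA on delta-Ct\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  cat(sprintf("  %d pairwise Tukey comparisons\n", nrow(x$tukey)))
  invisible(x)
}

#' Flag array fold changes as increase / decrease / unchanged
#'
#' Fold changes strictly greater than `upper` are flagged `increase`,
#' strictly below `lower` are `decrease`, anything else (boundaries
#' included) is `unchanged`.
#'
#' @param fold Positive numeric vector of fold changes.
#' @param upper,lower Cut-offs (defaults 3.0 and 0.3).
#' @return A factor with levels `increase`, `decrease`, `unchanged`.
#' @export
#' @examples
#' classify_array_folds(c(3.0, 3.1, 0.3, 0.29, 1))
classify_array_folds <- function(fold, upper = 3.0, lower = 0.3) {
  if (any(!is.finite(fold) | fold <= 0)) abort("fold changes must be positive")
  factor(
    dplyr::case_when(
      fold > upper ~ "increase",
      fold < lower ~ "decrease",
      TRUE ~ "unchanged"
    ),
    levels = c("increase", "decrease", "unchanged")
  )
}
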