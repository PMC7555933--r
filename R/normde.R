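#' Median-of-ratios normalization factors
#'
#' For sample j the factor is the median, over miRNAs, of the ratio of the
#' sample's count to the miRNA's geometric mean count across all samples.
#' Rows containing any zero are excluded from factor estimation (their
#' geometric mean is degenerate) but are still normalized afterwards.
#'
#' @param counts Wide count tibble: `mirna_id` plus one numeric column per
#'   sample; at least two samples.
#' @return A tibble `sample_id`, `norm_factor` (all positive).
#' @export
#' @examples
#' m <- tibble::tibble(mirna_id = c("a", "b"), s1 = c(4, 1), s2 = c(16, 4))
#' norm_factors(m) # factors 0.5 and 2
norm_factors <- function(counts) {
  counts <- as_tibble(counts)
  samples <- setdiff(names(counts), "mirna_id")
  if (length(samples) < 2) abort("need at least 2 samples to normalize")
  m <- as.matrix(counts[samples])
  if (any(m < 0)) abort("negative counts")
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) {
    abort("no miRNA has nonzero counts in every sample; cannot estimate factors")
  }
  mk <- m[keep, , drop = FALSE]
  geomean <- exp(rowMeans(log(mk)))
  factors <- apply(mk / geomean, 2, median)
  tibble(sample_id = samples, norm_factor = unname(factors))
}

#' Normalize a count matrix
#'
#' Divides each sample's counts by its normalization factor.
#'
#' @param counts Wide count tibble (see [norm_factors()]).
#' @param factors Tibble `sample_id`, `norm_factor`; must cover every
#'   sample column.
#' @return The normalized (real-valued) wide tibble.
#' @export
normalize_counts <- function(counts, factors) {
  counts <- as_tibble(counts)
  samples <- setdiff(names(counts), "mirna_id")
  missing <- setdiff(samples, factors$sample_id)
  if (length(missing)) {
    abort(paste("no normalization factor for:", paste(missing, collapse = ", ")))
  }
  if (any(factors$norm_factor <= 0)) abort("factors must be positive")
  out <- counts
  for (s in samples) {
    out[[s]] <- counts[[s]] / factors$norm_factor[match(s, factors$sample_id)]
  }
  out
}

#' Two-group differential expression with tiered p-values
#'
#' Per miRNA, a two-sample t-test (Welch by default) on
#' `log2(normalized + pseudocount)`, two-tailed, with no multiple-testing
#' correction of the tiers; raw p-values fall into the display tiers
#' red (p <= 0.01), orange (p <= 0.05), blue (p <= 0.1) or ns. A
#' Benjamini-Hochberg adjusted column is emitted alongside for reference.
#'
#' @param norm_counts Normalized wide count tibble.
#' @param group_a,group_b Character vectors of sample ids (each >= 2).
#' @param pseudocount Added before the log2 transform (default 1).
#' @param log_transform Test on the log2 scale (default) or on the
#'   normalized count scale.
#' @param welch Welch (unequal-variance) t-test, the default; `FALSE`
#'   pools variances.
#' @return A tibble of class `miredit_de`: `mirna_id`, `mean_a`, `mean_b`
#'   (normalized-scale group means), `log2fc`
#'   (`log2((mean_b + pseudocount) / (mean_a + pseudocount))`),
#'   `statistic`, `p_value`, `p_adj`, `tier`, `direction`.
#' @export
de_test <- function(norm_counts, group_a, group_b, pseudocount = 1,
                    log_transform = TRUE, welch = TRUE) {
  norm_counts <- as_tibble(norm_counts)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples")
  }
  missing <- setdiff(c(group_a, group_b), names(norm_counts))
  if (length(missing)) {
    abort(paste("samples absent from norm_counts:", paste(missing, collapse = ", ")))
  }
  ma <- as.matrix(norm_counts[group_a])
  mb <- as.matrix(norm_counts[group_b])
  ta <- if (log_transform) log2(ma + pseudocount) else ma
  tb <- if (log_transform) log2(mb + pseudocount) else mb

  res <- lapply(seq_len(nrow(norm_counts)), function(i) {
    xa <- ta[i, ]
    xb <- tb[i, ]
    if (var(xa) == 0 && var(xb) == 0) {
      # degenerate: no within-group variance; equal means give the null
      if (mean(xa) == mean(xb)) {
        c(statistic = 0, p_value = 1)
      } else {
        c(statistic = sign(mean(xb) - mean(xa)) * Inf, p_value = 0)
      }
    } else {
      tt <- t.test(xb, xa, var.equal = !welch)
      c(statistic = unname(tt$statistic), p_value = tt$p.value)
    }
  })
  res <- do.call(rbind, res)

  out <- tibble(
    mirna_id = norm_counts$mirna_id,
    mean_a = rowMeans(ma),
    mean_b = rowMeans(mb),
    log2fc = log2((rowMeans(mb) + pseudocount) / (rowMeans(ma) + pseudocount)),
    statistic = unname(res[, "statistic"]),
    p_value = unname(res[, "p_value"]),
    p_adj = unname(p.adjust(res[, "p_value"], method = "BH")),
    tier = de_tier(unname(res[, "p_value"])),
    direction = if_else(log2fc >= 0, "up", "down")
  )
  attr(out, "groups") <- list(a = group_a, b = group_b)
  class(out) <- c("miredit_de", class(out))
  out
}

# display tiers used in the heatmap figures
de_tier <- function(p) {
  factor(
    dplyr::case_when(
      p <= 0.01 ~ "red",
      p <= 0.05 ~ "orange",
      p <= 0.1 ~ "blue",
      TRUE ~ "ns"
    ),
    levels = c("red", "orange", "blue", "ns")
  )
}

#' @importFrom stats var
NULL
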