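#' Build and validate a pipeline configuration
#'
#' The configuration is a plain key tree (storable as YAML) with four
#' sections: `simulate` (generator settings) or `input` (paths to an
#' existing reference FASTA, FASTQ directory and design TSV), `design`
#' (sexes, ages, replicates; simulate mode only), and `params` (every
#' tunable of the cleaning, mapping, calling, normalization and DE
#' stages). Unknown keys are rejected so that typos cannot silently fall
#' back to defaults.
#'
#' @param seed Master seed for all randomness.
#' @param output_dir Directory for all outputs (created if absent).
#' @param simulate Named list of generator settings (see Details).
#' @param input Named list: `reference_fasta`, `fastq_dir`, `design_tsv`.
#' @param design Named list: `sexes`, `ages_months`, `replicates`.
#' @param params Named list of stage parameters.
#' @details
#' Recognised `simulate` keys: `n_mirnas`, `length_range`, `depth`,
#' `n_de`, `log2fc`, `n_edited`, `edited_fraction`, `error_rate`,
#' `dispersion`, `adapter`, `read_length`, `baseline_range`.
#' Recognised `params` keys: `min_len`, `max_len`, `max_fraction_n`,
#' `min_mean_quality`, `max_mm`, `max_3prime_slack`,
#' `min_fraction_factor`, `min_edited_reads`, `min_avg_reads`,
#' `pseudocount`, `p_tiers`, `fold_upper`, `fold_lower`.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, output_dir, simulate = NULL, input = NULL,
                            design = NULL, params = list()) {
  check_keys(simulate, c("n_mirnas", "length_range", "depth", "n_de", "log2fc",
                         "n_edited", "edited_fraction", "error_rate",
                         "dispersion", "adapter", "read_length",
                         "baseline_range"), "simulate")
  check_keys(input, c("reference_fasta", "fastq_dir", "design_tsv"), "input")
  check_keys(design, c("sexes", "ages_months", "replicates"), "design")
  check_keys(params, c("min_len", "max_len", "max_fraction_n",
                       "min_mean_quality", "max_mm", "max_3prime_slack",
                       "min_fraction_factor", "min_edited_reads",
                       "min_avg_reads", "pseudocount", "p_tiers",
                       "fold_upper", "fold_lower"), "params")
  if (is.null(simulate) && is.null(input)) {
    abort("config needs a 'simulate' or an 'input' section")
  }
  if (!is.null(input)) {
    for (key in c("reference_fasta", "fastq_dir", "design_tsv")) {
      if (is.null(input[[key]])) abort(sprintf("input$%s is required", key))
      if (!file.exists(input[[key]])) {
        abort(sprintf("input$%s does not exist: %s", key, input[[key]]))
      }
    }
  }
  defaults <- list(
    min_len = 17, max_len = 24, max_fraction_n = 0, min_mean_quality = 20,
    max_mm = 2, max_3prime_slack = 2, min_fraction_factor = 3,
    min_edited_reads = 5, min_avg_reads = 3000, pseudocount = 1,
    p_tiers = c(0.01, 0.05, 0.1), fold_upper = 3.0, fold_lower = 0.3
  )
  params <- utils::modifyList(defaults, params)
  stopifnot(params$min_len <= params$max_len, params$max_mm >= 0,
            params$min_avg_reads >= 0, params$pseudocount >= 0,
            all(diff(unlist(params$p_tiers)) > 0))
  structure(
    list(seed = as.integer(seed), output_dir = output_dir,
         simulate = simulate, input = input, design = design, params = params),
    class = "pipeline_config"
  )
}

check_keys <- function(x, allowed, section) {
  if (is.null(x)) return(invisible(NULL))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown %s key(s): %s", section,
                  paste(unknown, collapse = ", ")))
  }
  invisible(NULL)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys `seed`, `output_dir` and the
#'   sections of [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  check_keys(y, c("seed", "output_dir", "simulate", "input", "design",
                  "params"), "top-level")
  pipeline_config(
    seed = y$seed, output_dir = y$output_dir, simulate = y$simulate,
    input = y$input, design = y$design, params = y$params %||% list()
  )
}

#' Run the full editing-analysis pipeline
#'
#' Executes simulation (or FASTQ loading), cleaning, collapsing, mapping,
#' count-matrix construction, median-of-ratios normalization, tiered DE
#' comparisons (each older age vs the youngest within sex; male vs female
#' at each age), per-group editing calls and edited summaries, writing
#' every intermediate as TSV under `config$output_dir`. Re-running with
#' the same config and seed reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return A run report list: file paths, per-stage read-conservation
#'   counts, and the in-memory result tables.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- list()

  if (!is.null(config$simulate)) {
    s <- config$simulate
    say("stage simulate: %d miRNAs, seed %d", s$n_mirnas, config$seed)
    reference <- gen_reference(s$n_mirnas,
                               s$length_range %||% c(17, 24), config$seed)
    dsn <- config$design %||% list()
    design <- gen_design(
      sexes = dsn$sexes %||% c("M", "F"),
      ages_months = dsn$ages_months %||% c(3, 6, 15, 25, 30),
      replicates = dsn$replicates %||% 4
    )
    truth <- gen_truth(
      reference, design,
      n_de = s$n_de %||% 0, log2fc = s$log2fc %||% 2,
      n_edited = s$n_edited %||% 0,
      edited_fraction = s$edited_fraction %||% 0.3,
      baseline_range = s$baseline_range %||% c(500, 5000),
      dispersion = s$dispersion %||% 25,
      error_rate = s$error_rate %||% 0.001,
      adapter = s$adapter %||% DEFAULT_ADAPTER,
      read_length = s$read_length %||% 50,
      seed = config$seed
    )
    paths$reference <- file.path(out_dir, "reference.fasta")
    write_reference_fasta(reference, paths$reference)
    paths$design <- file.path(out_dir, "design.tsv")
    readr::write_tsv(design, paths$design)
    paths$truth <- file.path(out_dir, "truth.tsv")
    write_truth_tsv(truth, paths$truth)
    adapter <- truth$adapter
    read_sets <- lapply(design$sample_id, function(sid) {
      simulate_sample_reads(truth, reference, design, sid,
                            depth = s$depth %||% 1e5)
    })
    names(read_sets) <- design$sample_id
    fastq_dir <- file.path(out_dir, "fastq")
    dir.create(fastq_dir, showWarnings = FALSE)
    for (sid in design$sample_id) {
      write_reads_fastq(read_sets[[sid]],
                        file.path(fastq_dir, paste0(sid, ".fastq")))
    }
    paths$fastq_dir <- fastq_dir
  } else {
    reference <- read_reference_fasta(config$input$reference_fasta)
    design <- read_design_tsv(config$input$design_tsv)
    adapter <- config$simulate$adapter %||% DEFAULT_ADAPTER
    read_sets <- lapply(design$sample_id, function(sid) {
      fq <- file.path(config$input$fastq_dir, paste0(sid, ".fastq"))
      if (!file.exists(fq)) abort(sprintf("missing FASTQ for sample %s: %s", sid, fq))
      read_reads_fastq(fq, sample_id = sid)
    })
    names(read_sets) <- design$sample_id
  }

  say("stage clean/map: %d samples", nrow(design))
  clean_stats <- list()
  assignments <- list()
  for (sid in design$sample_id) {
    cleaned <- clean_reads(read_sets[[sid]], adapter,
                           min_len = p$min_len, max_len = p$max_len,
                           max_fraction_n = p$max_fraction_n,
                           min_mean_quality = p$min_mean_quality)
    cs <- attr(cleaned, "clean_stats")
    asn <- assign_sample(collapse_reads(cleaned), reference,
                         max_mm = p$max_mm,
                         max_3prime_slack = p$max_3prime_slack)
    as_sum <- attr(asn, "assignment_summary")
    clean_stats[[sid]] <- dplyr::bind_cols(tibble(sample_id = sid), cs, as_sum)
    assignments[[sid]] <- asn
    say("  %s: %d reads -> %d cleaned -> %d assigned / %d ambiguous / %d unassigned",
        sid, cs$input, cs$passed, as_sum$assigned, as_sum$ambiguous,
        as_sum$unassigned)
  }
  clean_stats <- bind_rows(clean_stats)
  paths$clean_stats <- file.path(out_dir, "clean_stats.tsv")
  readr::write_tsv(clean_stats, paths$clean_stats)

  asn_all <- bind_rows(assignments)
  paths$assignments <- file.path(out_dir, "assignments.tsv")
  readr::write_tsv(
    asn_all |>
      mutate(mismatch_string = vapply(.data$mismatches, function(mm) {
        # 1-based reference coordinates, "pos:ref>alt" per mismatch
        paste(sprintf("%d:%s>%s", mm$position, mm$ref_base, mm$read_base),
              collapse = ";")
      }, character(1))) |>
      select(-"mismatches"),
    paths$assignments
  )

  counts <- build_count_matrix(asn_all, design, reference)
  paths$counts <- file.path(out_dir, "counts.tsv")
  readr::write_tsv(counts, paths$counts)

  say("stage normalize")
  factors <- norm_factors(counts)
  norm <- normalize_counts(counts, factors)
  paths$norm_factors <- file.path(out_dir, "norm_factors.tsv")
  readr::write_tsv(factors, paths$norm_factors)
  paths$norm_counts <- file.path(out_dir, "norm_counts.tsv")
  readr::write_tsv(norm, paths$norm_counts)

  say("stage differential expression")
  comparisons <- de_comparisons(design)
  de_results <- list()
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    de_results[[nm]] <- de_test(norm, cmp$a, cmp$b,
                                pseudocount = p$pseudocount)
    paths[[paste0("de_", nm)]] <- file.path(out_dir, sprintf("de_%s.tsv", nm))
    readr::write_tsv(de_results[[nm]], paths[[paste0("de_", nm)]])
  }
  if (length(de_results)) {
    heat <- de_signed_logp(de_results)
    paths$de_heatmap <- file.path(out_dir, "de_signed_log10p.tsv")
    readr::write_tsv(heat, paths$de_heatmap)
  }

  say("stage editing calls")
  err <- if (!is.null(config$simulate)) {
    config$simulate$error_rate %||% 0.001
  } else 0.001
  groups <- unique(design$group)
  all_calls <- list()
  summaries <- list()
  for (g in groups) {
    gsamples <- design$sample_id[design$group == g]
    gasn <- asn_all |> filter(.data$sample_id %in% gsamples)
    calls_g <- lapply(reference$mirna_id, function(m) {
      call_editing_sites(
        mismatch_profile(gasn, reference, m), error_rate = err,
        min_fraction_factor = p$min_fraction_factor,
        min_edited_reads = p$min_edited_reads
      )
    }) |> bind_rows()
    all_calls[[g]] <- calls_g |> mutate(group = g, .before = 1)
    if (nrow(calls_g)) {
      sm <- summarize_edited(gasn, calls_g, norm, gsamples,
                             min_avg_reads = p$min_avg_reads)
      summaries[[g]] <- sm |> mutate(group = g, .before = 1)
    }
  }
  all_calls <- bind_rows(all_calls)
  paths$editing_calls <- file.path(out_dir, "editing_calls.tsv")
  readr::write_tsv(all_calls, paths$editing_calls)
  summaries <- bind_rows(summaries)
  paths$edited_summary <- file.path(out_dir, "edited_summary.tsv")
  readr::write_tsv(summaries, paths$edited_summary)

  manifest <- list(
    seed = config$seed,
    params = config$params,
    simulate = config$simulate,
    design = config$design,
    n_samples = nrow(design),
    n_mirnas = nrow(reference)
  )
  paths$manifest <- file.path(out_dir, "run_manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)
  say("done: %d output files in %s", length(paths), out_dir)

  list(
    paths = paths, reference = reference, design = design,
    clean_stats = clean_stats, counts = counts, norm_factors = factors,
    norm_counts = norm, de = de_results, editing_calls = all_calls,
    edited_summary = summaries
  )
}

# the study's comparisons: each older age vs the youngest age within sex,
# and male vs female at each age (only groups with >= 2 samples)
de_comparisons <- function(design) {
  out <- list()
  ages <- sort(unique(design$age_months))
  for (sex in unique(design$sex)) {
    base <- design$sample_id[design$sex == sex & design$age_months == ages[1]]
    for (a in ages[-1]) {
      grp <- design$sample_id[design$sex == sex & design$age_months == a]
      if (length(base) >= 2 && length(grp) >= 2) {
        out[[sprintf("%s%d_vs_%s%d", sex, a, sex, ages[1])]] <-
          list(a = base, b = grp)
      }
    }
  }
  if (all(c("M", "F") %in% design$sex)) {
    for (a in ages) {
      ma <- design$sample_id[design$sex == "M" & design$age_months == a]
      fa <- design$sample_id[design$sex == "F" & design$age_months == a]
      if (length(ma) >= 2 && length(fa) >= 2) {
        out[[sprintf("M%d_vs_F%d", a, a)]] <- list(a = fa, b = ma)
      }
    }
  }
  out
}

# heatmap-ready matrix: signed -log10 p per (miRNA, comparison)
de_signed_logp <- function(de_results) {
  cols <- lapply(names(de_results), function(nm) {
    d <- de_results[[nm]]
    tibble(
      mirna_id = d$mirna_id,
      comparison = nm,
      signed_log10p = sign(d$log2fc) * -log10(pmax(d$p_value, 1e-300))
    )
  })
  bind_rows(cols) |>
    tidyr::pivot_wider(names_from = "comparison", values_from = "signed_log10p")
}
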