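#' Simulate small-RNA reads for one sample
#'
#' Per-miRNA read counts are drawn negative-binomially with mean
#' proportional to `baseline_mean * 2^log2fc(group)` and scaled so the
#' expected total equals `depth`. Each read is the mature sequence with
#' per-site Bernoulli(edited fraction) A-to-G substitutions, then uniform
#' per-base sequencing errors over the insert, followed by the 3' adapter,
#' truncated or padded (with A) to the raw read length (50 nt).
#'
#' @param truth A `simulation_truth` from [gen_truth()].
#' @param reference The [mirna_reference()] used to build the truth.
#' @param design The sample design tibble.
#' @param sample_id Sample to simulate (must exist in `design`).
#' @param depth Expected total read count for the sample.
#' @param seed Optional integer seed; defaults to
#'   `derive_seed(truth$master_seed, index)` where `index` is the sample's
#'   row in the design, so samples are independently reproducible.
#' @return A read-set tibble: `sample_id`, `read_id`, `sequence`,
#'   `quality` (Phred+33, constant Q40 — no quality model is simulated).
#' @export
simulate_sample_reads <- function(truth, reference, design, sample_id,
                                  depth = 1e5, seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"), depth >= 1)
  design <- validate_design(design)
  idx <- match(sample_id, design$sample_id)
  if (is.na(idx)) abort(sprintf("unknown sample_id '%s'", sample_id))
  group <- design$group[idx]
  seed <- seed %||% derive_seed(truth$master_seed, idx)

  withr::with_seed(seed, {
    counts <- draw_group_counts(truth, group, depth)
    pieces <- vector("list", nrow(reference))
    for (i in seq_len(nrow(reference))) {
      k <- counts[i]
      if (k == 0) next
      pieces[[i]] <- simulate_mirna_reads(
        reference$sequence[i], k,
        sites = dplyr::filter(
          truth$editing_sites,
          .data$mirna_id == reference$mirna_id[i], .data$group == !!group
        ),
        error_rate = truth$error_rate,
        adapter = truth$adapter,
        read_length = truth$read_length
      )
    }
    seqs <- unlist(pieces, use.names = FALSE) %||% character(0)
    if (length(seqs)) seqs <- seqs[sample.int(length(seqs))]
    tibble(
      sample_id = sample_id,
      read_id = sprintf("%s_read%07d", sample_id, seq_along(seqs)),
      sequence = seqs,
      quality = strrep("I", truth$read_length)
    )
  })
}

# NB count draw shared by the read and count-matrix simulators: relative
# weights baseline * 2^effect, scaled so the expected sample total = depth.
draw_group_counts <- function(truth, group, depth) {
  eff <- truth$effects |> filter(.data$group == !!group)
  lfc <- eff$log2fc[match(truth$mirnas$mirna_id, eff$mirna_id)]
  lfc[is.na(lfc)] <- 0
  w <- truth$mirnas$baseline_mean * 2^lfc
  mu <- depth * w / sum(w)
  rnbinom(length(mu), mu = mu, size = truth$mirnas$dispersion)
}

# Vectorised read construction for one miRNA: k copies of the mature
# sequence as a k x L character matrix, site edits, then uniform errors.
simulate_mirna_reads <- function(mature, k, sites, error_rate, adapter,
                                 read_length) {
  chars <- strsplit(mature, "")[[1]]
  L <- length(chars)
  m <- matrix(rep(chars, each = k), nrow = k, ncol = L)
  if (nrow(sites)) {
    for (j in seq_len(nrow(sites))) {
      p <- sites$position[j]
      hit <- runif(k) < sites$edited_fraction[j]
      m[hit, p] <- "G"
    }
  }
  if (error_rate > 0) {
    err <- which(matrix(runif(k * L) < error_rate, k, L))
    if (length(err)) {
      cur <- m[err]
      # uniform substitution to one of the three other bases
      pick <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1),
                     character(1), USE.NAMES = FALSE)
      m[err] <- pick
    }
  }
  inserts <- do.call(paste0, lapply(seq_len(L), function(j) m[, j]))
  tail_fill <- substr(strrep(paste0(adapter, strrep("A", read_length)), 2),
                      1, read_length)
  full <- paste0(inserts, substr(tail_fill, 1, read_length - L))
  substr(full, 1, read_length)
}

#' Simulate a miRNA-by-sample count matrix directly
#'
#' Skips read-level simulation and draws the per-sample negative-binomial
#' counts only — the substrate for normalization and differential
#' expression when editing is not of interest.
#'
#' @inheritParams simulate_sample_reads
#' @param depth Expected total count per sample.
#' @return A wide count tibble: `mirna_id` plus one integer column per
#'   sample.
#' @export
simulate_count_matrix <- function(truth, design, depth = 1e5, seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  design <- validate_design(design)
  seed <- seed %||% truth$master_seed
  cols <- withr::with_seed(seed, {
    lapply(seq_len(nrow(design)), function(i) {
      draw_group_counts(truth, design$group[i], depth)
    })
  })
  out <- tibble(mirna_id = truth$mirnas$mirna_id)
  for (i in seq_len(nrow(design))) out[[design$sample_id[i]]] <- cols[[i]]
  out
}

#' Read / write read sets as FASTQ (Phred+33)
#'
#' @param reads A read-set tibble (`read_id`, `sequence`, `quality`).
#' @param path FASTQ file path.
#' @param sample_id Sample label attached on read-in.
#' @return `write_reads_fastq()` returns `path` invisibly;
#'   `read_reads_fastq()` returns a read-set tibble.
#' @export
write_reads_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qs <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qs)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path, sample_id = NULL) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    sample_id = sample_id %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path)),
    read_id = names(ss),
    sequence = unname(as.character(ss)),
    quality = unname(as.character(S4Vectors::mcols(ss)$qualities))
  )
}

#' Simulate Sanger-sequenced clones of a mature miRNA
#'
#' Each clone is a cloning-vector context with the mature sequence (or its
#' reverse complement) inserted at a random offset. With probability
#' `edit_prob` a clone carries one A-to-G edit at a random adenosine of the
#' mature sequence (emitted on the clone strand, i.e. complemented when the
#' insert is reverse-complement).
#'
#' @param ref_seq Mature miRNA sequence (DNA, 17-24 nt).
#' @param n_animals Animals per sex-age group.
#' @param colonies_per_animal Sequenced colonies per animal (study
#'   protocol: three or more).
#' @param sexes,ages_months Group structure.
#' @param edit_prob Per-clone probability of carrying one planted edit.
#' @param vector_length_range Range of total clone lengths.
#' @param seed Integer seed.
#' @return A tibble `clone_id`, `animal_id`, `sex`, `age_months`,
#'   `colony_id`, `sequence`, with attribute `"truth"`: a tibble of planted
#'   edits (`clone_id`, `position`, `orientation`).
#' @export
gen_clones <- function(ref_seq, n_animals = 2, colonies_per_animal = 3,
                       sexes = c("M", "F"), ages_months = c(3, 6, 15, 25, 30),
                       edit_prob = 0.3, vector_length_range = c(300, 600),
                       seed) {
  ref_seq <- normalise_seq(ref_seq)
  assert_dna(ref_seq, what = "ref_seq")
  L <- nchar(ref_seq)
  a_pos <- which(strsplit(ref_seq, "")[[1]] == "A")
  if (edit_prob > 0 && !length(a_pos)) abort("ref_seq has no adenosine to edit")
  withr::with_seed(seed, {
    meta <- tidyr::expand_grid(
      sex = sexes, age_months = as.integer(ages_months),
      animal = seq_len(n_animals), colony_id = seq_len(colonies_per_animal)
    ) |>
      mutate(
        animal_id = sprintf("%s%02d_a%d", .data$sex, .data$age_months, .data$animal),
        clone_id = sprintf("%s_c%d", .data$animal_id, .data$colony_id)
      )
    n <- nrow(meta)
    truth <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      lens_avail <- seq(vector_length_range[1], vector_length_range[2])
      total <- lens_avail[sample.int(length(lens_avail), 1)]
      offset <- sample.int(total - L - 1, 1)
      insert <- ref_seq
      pos <- NA_integer_
      if (runif(1) < edit_prob) {
        pos <- if (length(a_pos) == 1) a_pos else sample(a_pos, 1)
        substr(insert, pos, pos) <- "G"
      }
      orientation <- if (runif(1) < 0.5) "forward" else "reverse-complement"
      if (orientation == "reverse-complement") insert <- revcomp(insert)
      vec <- paste(sample(DNA_BASES, total, replace = TRUE), collapse = "")
      seqs[i] <- paste0(
        substr(vec, 1, offset), insert,
        substr(vec, offset + L + 1, total)
      )
      if (!is.na(pos)) {
        truth[[i]] <- tibble(clone_id = meta$clone_id[i], position = pos,
                             orientation = orientation)
      }
    }
    out <- meta |>
      mutate(sequence = seqs) |>
      select("clone_id", "animal_id", "sex", "age_months", "colony_id", "sequence")
    attr(out, "truth") <- bind_rows(truth)
    out
  })
}
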