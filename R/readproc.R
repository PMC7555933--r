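#' Clean raw small-RNA reads
#'
#' Applies the standard pre-mapping filters: locate and cut the 3' adapter,
#' keep inserts in the mature-miRNA length window, and drop reads with too
#' many N bases or low mean quality. The adapter is located by an exact
#' match of its first 8 nt at the leftmost position; everything from that
#' position onward is removed. Reads in which the adapter cannot be located
#' are dropped, because the insert boundary is then unknown.
#'
#' @param reads Read-set tibble (`sequence`, optional `quality`,
#'   optional `sample_id`).
#' @param adapter 3' adapter sequence (non-empty).
#' @param min_len,max_len Insert length window; default 17-24 nt, the
#'   mature-miRNA range.
#' @param max_fraction_n Maximum tolerated fraction of N in the insert
#'   (default 0: any N drops the read).
#' @param min_mean_quality Minimum mean Phred score over the insert
#'   (Phred+33 encoding); ignored when `reads` has no `quality` column.
#' @return The surviving reads with `sequence`/`quality` trimmed to the
#'   insert, plus a `"clean_stats"` attribute counting reads dropped at
#'   each filter.
#' @export
clean_reads <- function(reads, adapter, min_len = 17, max_len = 24,
                        max_fraction_n = 0, min_mean_quality = 20) {
  reads <- as_tibble(reads)
  adapter <- normalise_seq(adapter)
  if (!nzchar(adapter)) abort("adapter must be a non-empty DNA string")
  if (min_len > max_len) abort("min_len must be <= max_len")
  seed <- substr(adapter, 1, 8)

  n_in <- nrow(reads)
  pos <- regexpr(seed, reads$sequence, fixed = TRUE)
  has_adapter <- pos > 0
  insert_len <- ifelse(has_adapter, as.integer(pos) - 1L, NA_integer_)

  ok_len <- has_adapter & insert_len >= min_len & insert_len <= max_len
  insert <- substr(reads$sequence, 1, ifelse(is.na(insert_len), 0, insert_len))

  n_count <- stringr::str_count(insert, "N")
  ok_n <- ok_len & (n_count <= max_fraction_n * insert_len)

  if ("quality" %in% names(reads)) {
    qual <- substr(reads$quality, 1, ifelse(is.na(insert_len), 0, insert_len))
    mean_q <- vapply(qual, function(q) {
      if (!nzchar(q)) return(0)
      mean(utf8ToInt(q) - 33L)
    }, numeric(1), USE.NAMES = FALSE)
    ok_q <- ok_n & mean_q >= min_mean_quality
  } else {
    qual <- NULL
    ok_q <- ok_n
  }

  out <- reads[which(ok_q), , drop = FALSE]
  out$sequence <- insert[which(ok_q)]
  if (!is.null(qual)) out$quality <- qual[which(ok_q)]

  attr(out, "clean_stats") <- tibble(
    input = n_in,
    no_adapter = sum(!has_adapter),
    bad_length = sum(has_adapter & !ok_len),
    bad_n = sum(ok_len & !ok_n),
    bad_quality = sum(ok_n & !ok_q),
    passed = nrow(out)
  )
  out
}

#' Collapse cleaned reads into a unique-sequence count table
#'
#' @param reads Cleaned read-set tibble.
#' @return A tibble `sample_id` (if present), `sequence`, `count`, sorted
#'   by descending count then sequence; counts sum to the number of input
#'   reads.
#' @export
#' @examples
#' collapse_reads(tibble::tibble(sequence = c("ACGT", "ACGT", "TTTT")))
collapse_reads <- function(reads) {
  reads <- as_tibble(reads)
  if (!nrow(reads)) {
    out <- tibble(sequence = character(), count = integer())
    if ("sample_id" %in% names(reads)) {
      out <- tibble(sample_id = character(), sequence = character(),
                    count = integer())
    }
    return(out)
  }
  keys <- intersect(c("sample_id", "sequence"), names(reads))
  reads |>
    count(across(dplyr::all_of(keys)), name = "count") |>
    arrange(desc(.data$count), .data$sequence)
}
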