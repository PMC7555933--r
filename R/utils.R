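#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows across n count rename pull desc distinct if_else
#' @importFrom stats median rnbinom runif rnorm aov TukeyHSD p.adjust t.test
#'   pt ptukey setNames complete.cases
#' @importFrom utils head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Illumina-style small-RNA 3' adapter prefix used as the simulator default.
DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAA"

#' @keywords internal
assert_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T%s}: e.g. '%s'",
      what, if (allow_n) ",N" else "", x[which(bad)[1]]
    ))
  }
  invisible(x)
}

# U -> T on load; uppercase normalisation.
normalise_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet {A,C,G,T,N}.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("AACGT")
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Derive a per-sample random seed from a master seed
#'
#' Samples are simulated independently; each gets a deterministic seed
#' derived from the master seed and its (1-based) index so that any one
#' sample can be regenerated without re-running the others.
#'
#' @param master_seed Integer master seed.
#' @param index Positive integer sample index.
#' @return An integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 2147483647 * 7919 +
                as.numeric(index) * 104729) %% 2147483647)
}

# positions 2-7 of the mature sequence form the seed region
in_seed_region <- function(position) position >= 2 & position <= 7
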