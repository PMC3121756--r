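#' @importFrom stats runif rbinom rmultinom setNames fisher.test qbinom
#' @importFrom utils write.table read.delim packageVersion download.file
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers can distinguish saturation from bad input
hz_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "haplozein_error")))
}

hz_assert <- function(cond, msg, class = "haplozein_input_error") {
  if (!isTRUE(cond)) hz_stop(msg, class)
}

#' Run code with a temporarily fixed RNG state
#'
#' Sets the seed, runs `expr`, then restores the caller's RNG state, so
#' seeded simulator calls never disturb the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  hz_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-stage seed derivation from one master seed, kept < 2^31
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

DNA_ALPHABET <- c("A", "C", "G", "T", "N",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

check_dna <- function(seq, what = "sequence") {
  hz_assert(is.character(seq) && length(seq) == 1 && nzchar(seq),
            sprintf("%s must be a non-empty string", what))
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  hz_assert(length(bad) == 0,
            sprintf("%s contains non-IUPAC characters: %s", what,
                    paste(bad, collapse = ", ")))
  seq
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
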