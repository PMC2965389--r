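# Internal helpers shared across modules.

#' @noRd
normalize_sequence <- function(x) {
  x <- toupper(x)
  chartr("U", "T", x)
}

#' Reverse complement of a DNA character string
#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Run code under a fixed RNG state without disturbing the caller's stream.
#' @noRd
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Random iid DNA at a given GC content, as one string.
#' @noRd
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' @noRd
empty_hits <- function() {
  data.frame(
    replicon_id = character(0), strand = character(0),
    stem5_start = integer(0), stem5_end = integer(0),
    loop_start = integer(0), loop_end = integer(0),
    stem3_start = integer(0), stem3_end = integer(0),
    spacer_len = integer(0), tail_start = integer(0), tail_end = integer(0),
    stem_len = integer(0), n_bulge = integer(0), delta_g = numeric(0),
    score = numeric(0), method = character(0), utr_class = character(0),
    stringsAsFactors = FALSE)
}
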