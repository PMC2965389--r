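# Dinucleotide-preserving shuffles and false-positive controls.
#
# The shuffle is the Eulerian-path (Altschul-Erickson) construction: a
# sequence is a walk on the 4-vertex multigraph whose edges are its
# dinucleotides; any other Eulerian walk with the same start and end vertex
# spells a sequence with exactly the same dinucleotide counts.  Detector
# false-positive rates estimated on such shuffles control for local
# composition (e.g. T-richness of UTRs), not just mononucleotide content.

#' Dinucleotide-preserving sequence shuffle
#'
#' Produces a random sequence with exactly the same 16-entry dinucleotide
#' count vector, and the same first and last nucleotide, as the input.
#' Deterministic for a given `seed`; the caller's RNG stream is not
#' disturbed.
#'
#' @param seq Character string (length >= 2) over A/C/G/T.
#' @param seed Integer seed.
#' @return The shuffled sequence.
#' @examples
#' dinucleotide_shuffle("ACGTACGT", seed = 1)
#' @export
dinucleotide_shuffle <- function(seq, seed) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 2)
  ch <- strsplit(normalize_sequence(seq), "", fixed = TRUE)[[1]]
  with_local_seed(seed, shuffle_euler(ch))
}

#' @noRd
shuffle_euler <- function(ch) {
  n <- length(ch)
  verts <- unique(ch)
  if (length(verts) == 1L) return(paste(ch, collapse = ""))
  # out-edge target lists per vertex, in input order
  edges <- split(ch[-1], factor(ch[-n], levels = verts))
  last_v <- ch[n]
  first_v <- ch[1]
  # choose a random "last edge" per non-final vertex until they form an
  # arborescence directed toward the final vertex
  repeat {
    last_edge <- vapply(verts, function(v) {
      e <- edges[[v]]
      if (v == last_v || !length(e)) NA_character_
      else e[sample.int(length(e), 1L)]
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last_v || is.na(last_edge[[v]])) next
      seen <- character(0)
      cur <- v
      while (cur != last_v) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute the remaining edges; append the chosen last edge
  for (v in verts) {
    e <- edges[[v]]
    if (!length(e)) next
    if (!is.na(last_edge[[v]])) {
      i <- match(last_edge[[v]], e)
      e <- e[-i]
    }
    e <- if (length(e) > 1) e[sample.int(length(e))] else e
    if (!is.na(last_edge[[v]])) e <- c(e, last_edge[[v]])
    edges[[v]] <- e
  }
  # walk
  out <- character(n)
  out[1] <- first_v
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- first_v
  for (i in 2:n) {
    nxt <- edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Estimate detector false-positive rates by dinucleotide shuffling
#'
#' Each input sequence is shuffled `n_shuffles` times; the false-positive
#' rate is the fraction of shuffles yielding at least one terminator hit,
#' averaged over sequences (optionally split by UTR class).  The observed
#' rate is the same statistic on the original sequences.  Sequences are
#' scanned in the given (sense) orientation with the same two-pass protocol
#' as the screen.
#'
#' @param seqs Character vector of region/UTR sequences.
#' @param model A [train_profile()] model or `NULL` (descriptor only).
#' @param params A [descriptor_params()] object.
#' @param n_shuffles Shuffles per sequence (default 100; must be >= 1).
#' @param seed Integer seed; shuffle s of sequence i uses seed
#'   `seed + (i - 1) * n_shuffles + s`.
#' @param region_class Optional character vector (`"five_prime"` /
#'   `"three_prime"`) splitting the per-class rates.
#' @param energy An [default_energy_model()] object.
#' @return A list of class `shuffle_report`: `n_shuffles`, `fp_rate`,
#'   `fp_rate_5utr`, `fp_rate_3utr`, `observed_rate`, `seed`.
#' @export
estimate_false_positive_rate <- function(seqs, model = NULL,
                                         params = descriptor_params(),
                                         n_shuffles = 100L, seed = 1L,
                                         region_class = NULL,
                                         energy = default_energy_model()) {
  stopifnot(length(seqs) >= 1)
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  scan1 <- function(s) {
    h <- if (!is.null(model)) {
      hh <- scan_profile(s, model, params, energy)
      if (nrow(hh)) hh else scan_descriptor(s, params, energy)
    } else scan_descriptor(s, params, energy)
    nrow(h) > 0
  }
  observed <- vapply(seqs, scan1, logical(1))
  fp_frac <- vapply(seq_along(seqs), function(i) {
    mean(vapply(seq_len(n_shuffles), function(s) {
      scan1(dinucleotide_shuffle(seqs[i],
                                 seed + (i - 1L) * n_shuffles + s))
    }, logical(1)))
  }, numeric(1))
  by_class <- function(cls) {
    if (is.null(region_class)) return(NA_real_)
    i <- region_class == cls
    if (!any(i)) NA_real_ else mean(fp_frac[i])
  }
  structure(list(n_shuffles = as.integer(n_shuffles),
                 fp_rate = mean(fp_frac),
                 fp_rate_5utr = by_class("five_prime"),
                 fp_rate_3utr = by_class("three_prime"),
                 observed_rate = mean(observed), seed = seed),
            class = "shuffle_report")
}

#' @export
print.shuffle_report <- function(x, ...) {
  cat(sprintf(paste0("shuffle_report: %d shuffles/sequence; fp_rate = %.3f",
                     " (5'UTR %.3f, 3'UTR %.3f); observed = %.3f\n"),
              x$n_shuffles, x$fp_rate, x$fp_rate_5utr, x$fp_rate_3utr,
              x$observed_rate))
  invisible(x)
}
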