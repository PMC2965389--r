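# Trainable profile scorer for intrinsic terminators.
#
# The scorer is trained on a structure-annotated alignment of terminators
# (Stockholm, #=GC SS_cons) and assigns each descriptor-admissible
# decomposition a log-odds score in bits: per-column base-pair log-odds over
# the stem, base log-odds over loop and tail columns.  Hit stems shorter or
# longer than the profile's stem span are aligned outermost-first and the
# stem contribution is rescaled to the profile span.  The score threshold is
# calibrated on background (shuffled) sequence for a target false-positive
# density.

#' Read a Stockholm alignment with a consensus structure line
#'
#' A minimal single-block or interleaved Stockholm reader that keeps the
#' `#=GC SS_cons` annotation (base pairs marked with matched `<>` or `()`
#' brackets), which sequence-only alignment readers drop.
#'
#' @param path Path to a Stockholm file.
#' @return A list with `seqs` (named character vector, aligned, gaps `-`/`.`)
#'   and `ss_cons` (character string).
#' @export
read_stockholm <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  seqs <- character(0)
  ss <- ""
  for (ln in lines) {
    if (grepl("^#=GC\\s+SS_cons\\s+", ln)) {
      ss <- paste0(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
    } else if (grepl("^[^#/\\s]\\S*\\s+\\S+$", ln, perl = TRUE)) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) == 2) {
        nm <- parts[1]
        seqs[nm] <- paste0(if (nm %in% names(seqs)) seqs[[nm]] else "",
                           parts[2])
      }
    }
  }
  if (!length(seqs)) stop("no sequences found in Stockholm file ", path)
  if (!nzchar(ss)) stop("no #=GC SS_cons line found in ", path)
  list(seqs = seqs, ss_cons = ss)
}

# Pair the bracketed columns of an SS_cons string; returns a 2-column matrix
# (open, close), outermost pair first.
#' @noRd
parse_ss_cons <- function(ss) {
  ch <- strsplit(ss, "", fixed = TRUE)[[1]]
  open <- ch %in% c("<", "(")
  close <- ch %in% c(">", ")")
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    if (open[i]) stack <- c(stack, i)
    else if (close[i]) {
      if (!length(stack)) stop("unbalanced structure annotation at column ", i)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop("unbalanced structure annotation: ", length(stack),
         " unclosed bracket(s)")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Train a terminator profile from a structure-annotated alignment
#'
#' Builds per-column frequency tables with pseudocounts: for each stem column
#' pair, ordered base-pair frequencies over the 16 dinucleotide pairs; for
#' each unpaired loop and tail column, base frequencies.  Log-odds are taken
#' against `background` (per-base; pair background is the product of the two
#' base frequencies).  Alignment rows with a gap in a column are excluded
#' from that column's counts.
#'
#' @param alignment A list as returned by [read_stockholm()] (elements
#'   `seqs`, `ss_cons`), or a path to a Stockholm file.
#' @param pseudocount Total pseudocount weight added to each column (spread
#'   according to the background distribution).
#' @param background Base frequencies for A, C, G, T (default uniform).
#' @param score_threshold Score threshold in bits used by [scan_profile()];
#'   set it directly or calibrate later with [calibrate_threshold()].
#' @return An object of class `terminator_profile` with elements
#'   `stem_logodds` (list of 4x4 matrices, outermost stem pair first),
#'   `loop_logodds`, `tail_logodds` (lists of per-base vectors),
#'   `background`, `pseudocount`, `score_threshold` and `trained_n`.
#' @export
train_profile <- function(alignment, pseudocount = 1.0,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25),
                          score_threshold = 0) {
  if (is.character(alignment) && length(alignment) == 1L)
    alignment <- read_stockholm(alignment)
  seqs <- toupper(chartr("U", "T", alignment$seqs))
  n <- length(seqs)
  if (n < 10) stop("need at least 10 aligned sequences to train a profile")
  w <- unique(nchar(seqs))
  if (length(w) != 1 || w != nchar(alignment$ss_cons))
    stop("aligned sequences and SS_cons must all have the same length")
  pairs <- parse_ss_cons(alignment$ss_cons)
  if (!nrow(pairs)) stop("structure annotation contains no base pairs")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  pc <- pseudocount
  bg <- background / sum(background)

  pair_logodds <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    xi <- mat[, i]; xj <- mat[, j]
    ok <- xi %in% bases & xj %in% bases
    tab <- table(factor(xi[ok], bases), factor(xj[ok], bases))
    bg_pair <- outer(bg, bg)
    freq <- (tab + pc * bg_pair) / (sum(ok) + pc)
    log2(unclass(freq) / bg_pair)
  })
  unpaired_logodds <- function(cols) {
    lapply(cols, function(i) {
      xi <- mat[, i]
      ok <- xi %in% bases
      cnt <- table(factor(xi[ok], bases))
      freq <- (cnt + pc * bg) / (sum(ok) + pc)
      log2(as.numeric(freq) / bg) |> setNames(bases)
    })
  }
  loop_lo <- max(pairs[, 1]) + 1L
  loop_hi <- min(pairs[, 2]) - 1L
  loop_cols <- if (loop_lo <= loop_hi) setdiff(seq(loop_lo, loop_hi),
                                               c(pairs)) else integer(0)
  tail_cols <- setdiff(seq_len(w), seq_len(max(pairs[, 2])))
  structure(list(stem_logodds = pair_logodds,
                 loop_logodds = unpaired_logodds(loop_cols),
                 tail_logodds = unpaired_logodds(tail_cols),
                 background = bg, pseudocount = pc,
                 score_threshold = score_threshold, trained_n = n),
            class = "terminator_profile")
}

#' @export
print.terminator_profile <- function(x, ...) {
  cat(sprintf(paste0("terminator_profile: %d stem pairs, %d loop + %d tail",
                     " columns, trained on %d sequences, threshold %.2f",
                     " bits\n"),
              length(x$stem_logodds), length(x$loop_logodds),
              length(x$tail_logodds), x$trained_n, x$score_threshold))
  invisible(x)
}

# Score one decomposition (row of the cpp decomposition table) against the
# profile.  Stem pairs are aligned outermost-first and rescaled to the
# profile's stem span; likewise loop and tail columns.
#' @noRd
score_decomposition <- function(ch, d_row, model) {
  L <- d_row$stem_len
  S <- length(model$stem_logodds)
  # paired positions; bulges (n_bulge > 0) are skipped by reconstructing the
  # pairing the same way the scanner laid it out is unnecessary here: profile
  # mode runs with allow_bulge = FALSE.  Hit stems are aligned to the
  # profile columns outermost-first; columns beyond the shorter of the two
  # spans contribute nothing.
  s5 <- seq(d_row$stem5_start, d_row$stem5_end)
  s3 <- seq(d_row$stem3_start, d_row$stem3_end)
  m <- min(L, S)
  stem_sc <- 0
  for (k in seq_len(m)) {
    x <- ch[s5[k]]; y <- ch[s3[L - k + 1]]
    stem_sc <- stem_sc + model$stem_logodds[[k]][x, y]
  }
  loop_pos <- seq(d_row$stem5_end + 1L, d_row$stem3_start - 1L)
  Lm <- length(model$loop_logodds)
  m2 <- min(length(loop_pos), Lm)
  loop_sc <- 0
  if (m2 > 0)
    for (k in seq_len(m2))
      loop_sc <- loop_sc + model$loop_logodds[[k]][ch[loop_pos[k]]]
  tail_pos <- seq(d_row$tail_start, length.out = 12L)
  Tm <- length(model$tail_logodds)
  m3 <- min(length(tail_pos), Tm)
  tail_sc <- 0
  if (m3 > 0)
    for (k in seq_len(m3))
      tail_sc <- tail_sc + model$tail_logodds[[k]][ch[tail_pos[k]]]
  unname(stem_sc + loop_sc + tail_sc)
}

#' Scan a sequence with a trained terminator profile
#'
#' Scores every descriptor-admissible decomposition of `seq` with the profile
#' log-odds and returns hits scoring at least the model's `score_threshold`,
#' resolved so that hits sharing stem positions collapse to the single hit
#' with the highest score (ties: lowest folding energy, then leftmost).
#'
#' @inheritParams scan_descriptor
#' @param model A [train_profile()] model.
#' @param energy An [default_energy_model()] object (used for the folding
#'   energies reported with each hit and the descriptor's stability cutoff).
#' @return A hits data frame as in [scan_descriptor()], with `score` in bits
#'   and `method = "profile"`.
#' @export
scan_profile <- function(seq, model, params = descriptor_params(),
                         energy = default_energy_model()) {
  stopifnot(inherits(model, "terminator_profile"))
  seq <- normalize_sequence(seq)
  p <- params
  p$allow_bulge <- FALSE  # profile columns assume an unbulged stem
  d <- descriptor_decompositions(seq, p, energy)
  if (!nrow(d)) return(empty_hits())
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  d$score <- vapply(seq_len(nrow(d)), function(i)
    score_decomposition(ch, d[i, , drop = FALSE], model), numeric(1))
  d <- d[d$score >= model$score_threshold, , drop = FALSE]
  if (!nrow(d)) return(empty_hits())
  ord <- order(-round(d$score, 9), round(d$delta_g, 9), d$stem5_start,
               d$spacer_len)
  d <- resolve_overlaps(d, ord)
  decomps_to_hits(d, params$tail_len, method = "profile", score = d$score)
}

#' Calibrate the profile score threshold on background sequence
#'
#' Scans a set of background (e.g. dinucleotide-shuffled) sequences with the
#' profile at an open threshold and returns the smallest threshold whose
#' false-positive density does not exceed `target_fp_per_kb`.  The mapping is
#' monotone: a more permissive target gives a lower-or-equal threshold.
#'
#' @param model A [train_profile()] model.
#' @param negatives Character vector of background sequences.
#' @param target_fp_per_kb Tolerated hits per kilobase of background.
#' @param params,energy Scan settings, as in [scan_profile()].
#' @return The threshold in bits.  If no observed score satisfies the target,
#'   the maximum observed score plus one is returned with a warning.
#' @export
calibrate_threshold <- function(model, negatives, target_fp_per_kb,
                                params = descriptor_params(),
                                energy = default_energy_model()) {
  stopifnot(length(negatives) >= 1)
  if (is.infinite(target_fp_per_kb) && target_fp_per_kb > 0)
    return(-Inf)
  open <- model
  open$score_threshold <- -Inf
  scores <- unlist(lapply(negatives, function(s) {
    h <- scan_profile(s, open, params, energy)
    h$score
  }))
  total_kb <- sum(nchar(negatives)) / 1000
  if (!length(scores)) return(-Inf)
  if (target_fp_per_kb < 0) {
    warning("no threshold can reach a negative false-positive density; ",
            "returning max observed score + 1")
    return(max(scores) + 1)
  }
  density_at <- function(t) {
    # filtering before overlap resolution can unmask lower hits, so verify
    # each candidate threshold with a real filtered scan
    mt <- model
    mt$score_threshold <- t
    sum(vapply(negatives, function(s)
      nrow(scan_profile(s, mt, params, energy)), integer(1))) / total_kb
  }
  for (t in sort(unique(scores))) {
    if (sum(scores >= t) / total_kb <= target_fp_per_kb &&
        density_at(t) <= target_fp_per_kb)
      return(t)
  }
  max(scores) + 1  # above every observed score: density 0
}
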