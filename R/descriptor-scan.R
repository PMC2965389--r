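# Descriptor-based intrinsic terminator detection.
#
# The descriptor is the classic intrinsic-terminator motif: a 4-18 bp helix
# (Watson-Crick plus optional GU wobble), a 3-10 nt loop, a 0-2 nt spacer and
# a 12-nt T-rich tail (>= 7 T overall, >= 3 T in the first 5 positions).  A
# hairpin stability cutoff (dg_max) rejects weak, chance hairpins; its default
# is calibrated so that the false-positive rate on shuffled UTR-sized sequence
# matches the 2-3% control level expected of intrinsic-terminator screens.

#' Descriptor parameters for intrinsic terminator search
#'
#' @param stem_min,stem_max Stem length bounds in base pairs.
#' @param spacer_min,spacer_max Spacer (between stem 3' arm and tail) bounds.
#' @param tail_len Tail window length in nt.
#' @param loop_min,loop_max Hairpin loop length bounds in nt.
#' @param tail_min_t Minimum number of T in the tail window.
#' @param tail_head_min_t Minimum number of T in the first 5 tail positions.
#' @param allow_gu Allow GU wobble pairs in the stem.
#' @param allow_bulge Allow one single-nucleotide bulge per stem arm.
#' @param dg_max Maximal (least negative) hairpin free energy in kcal/mol; a
#'   decomposition whose hairpin is weaker than this is not reported.
#' @return A list of class `descriptor_params`.
#' @export
descriptor_params <- function(stem_min = 4L, stem_max = 18L,
                              spacer_min = 0L, spacer_max = 2L,
                              tail_len = 12L, loop_min = 3L, loop_max = 10L,
                              tail_min_t = 7L, tail_head_min_t = 3L,
                              allow_gu = TRUE, allow_bulge = FALSE,
                              dg_max = -5.0) {
  p <- list(stem_min = as.integer(stem_min), stem_max = as.integer(stem_max),
            spacer_min = as.integer(spacer_min),
            spacer_max = as.integer(spacer_max),
            tail_len = as.integer(tail_len),
            loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
            tail_min_t = as.integer(tail_min_t),
            tail_head_min_t = as.integer(tail_head_min_t),
            allow_gu = isTRUE(allow_gu), allow_bulge = isTRUE(allow_bulge),
            dg_max = as.numeric(dg_max))
  stopifnot(p$stem_min <= p$stem_max, p$spacer_min <= p$spacer_max,
            p$tail_min_t <= p$tail_len, p$loop_min <= p$loop_max,
            p$stem_min >= 1)
  class(p) <- "descriptor_params"
  p
}

# All admissible decompositions of a sequence (scan orientation, local
# 1-based coordinates), before overlap resolution.
#' @noRd
descriptor_decompositions <- function(seq, params, model) {
  seq <- normalize_sequence(seq)
  cpp_scan_decomps(seq, params$stem_min, params$stem_max,
                   params$loop_min, params$loop_max,
                   params$spacer_min, params$spacer_max,
                   params$tail_len, params$tail_min_t, params$tail_head_min_t,
                   params$allow_gu, params$allow_bulge,
                   model$stack_dg, unname(model$hairpin_loop_dg),
                   model$terminal_au_penalty, model$bulge_dg, params$dg_max)
}

# Overlap resolution: hits whose stems share any position collapse to one.
# `ord` is the preference order (best first); ties must already be broken.
#' @noRd
resolve_overlaps <- function(d, ord) {
  if (nrow(d) <= 1) return(d)
  d <- d[ord, , drop = FALSE]
  keep <- logical(nrow(d))
  kept_s5 <- kept_e5 <- kept_s3 <- kept_e3 <- integer(0)
  for (i in seq_len(nrow(d))) {
    s5 <- d$stem5_start[i]; e5 <- d$stem5_end[i]
    s3 <- d$stem3_start[i]; e3 <- d$stem3_end[i]
    clash <- any(pmax(kept_s5, s5) <= pmin(kept_e5, e5)) ||
             any(pmax(kept_s3, s5) <= pmin(kept_e3, e5)) ||
             any(pmax(kept_s5, s3) <= pmin(kept_e5, e3)) ||
             any(pmax(kept_s3, s3) <= pmin(kept_e3, e3))
    if (!clash) {
      keep[i] <- TRUE
      kept_s5 <- c(kept_s5, s5); kept_e5 <- c(kept_e5, e5)
      kept_s3 <- c(kept_s3, s3); kept_e3 <- c(kept_e3, e3)
    }
  }
  d[keep, , drop = FALSE]
}

#' @noRd
decomps_to_hits <- function(d, tail_len, method = "descriptor",
                            score = NA_real_) {
  if (!nrow(d)) return(empty_hits())
  data.frame(
    replicon_id = NA_character_, strand = NA_character_,
    stem5_start = d$stem5_start, stem5_end = d$stem5_end,
    loop_start = d$stem5_end + 1L, loop_end = d$stem3_start - 1L,
    stem3_start = d$stem3_start, stem3_end = d$stem3_end,
    spacer_len = d$spacer_len, tail_start = d$tail_start,
    tail_end = d$tail_start + tail_len - 1L,
    stem_len = d$stem_len, n_bulge = d$n_bulge, delta_g = d$delta_g,
    score = if (length(score) == 1) rep(score, nrow(d)) else score,
    method = method, utr_class = "unassigned",
    stringsAsFactors = FALSE)
}

#' Scan a sequence for intrinsic terminator motifs (descriptor mode)
#'
#' Enumerates every decomposition of `seq` into stem-loop-stem-spacer-tail
#' satisfying `params` (including the hairpin stability cutoff), then resolves
#' hits whose stems share any sequence position to the single hit with the
#' lowest folding free energy (ties: leftmost stem start, then longest stem,
#' then shortest spacer).  Coordinates are 1-based on `seq` in scan
#' orientation; to scan the reverse strand, pass the reverse complement (or
#' use [scan_region()], which handles both strands and coordinate mapping).
#'
#' @param seq A character string over A/C/G/T (lowercase and U accepted).
#' @param params A [descriptor_params()] object.
#' @param model An [default_energy_model()] object.
#' @return A data frame of terminator hits with stem/loop/tail intervals,
#'   `spacer_len`, `stem_len`, `delta_g` (kcal/mol), `method = "descriptor"`
#'   and `score = NA`.  A sequence too short for the minimal motif yields
#'   zero rows.
#' @examples
#' seq <- paste0("AA", "GCCGGGCC", "GAAA", "GGCCCGGC", strrep("T", 12), "AA")
#' scan_descriptor(seq)
#' @export
scan_descriptor <- function(seq, params = descriptor_params(),
                            model = default_energy_model()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  d <- descriptor_decompositions(seq, params, model)
  if (!nrow(d)) return(empty_hits())
  # rounding keeps the preference order stable against float summation noise
  ord <- order(round(d$delta_g, 9), d$stem5_start, -d$stem_len, d$spacer_len)
  d <- resolve_overlaps(d, ord)
  decomps_to_hits(d, params$tail_len, method = "descriptor")
}
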