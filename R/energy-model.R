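# Nearest-neighbor hairpin free-energy model.
#
# Values are the Turner 2004 RNA folding parameters (Mathews DH, Turner DH
# and coworkers; as tabulated in the ViennaRNA distribution): Watson-Crick
# and GU-wobble stack free energies at 37C, hairpin loop initiation for loop
# sizes 3-30, and the 0.50 kcal/mol terminal AU/GU helix-end penalty.
# The model scores the terminator hairpin only (stacks + loop initiation +
# terminal penalty, plus a flat single-nucleotide bulge penalty); loop
# terminal-mismatch and special-loop bonuses are intentionally omitted so the
# energy of a decomposition is a transparent table sum.

.pair_levels <- c("CG", "GC", "GT", "TG", "AT", "TA")

.turner_stack <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30),
  nrow = 6, byrow = TRUE, dimnames = list(.pair_levels, .pair_levels))

.turner_hairpin <- setNames(
  c(5.40, 5.60, 5.70, 5.40, 6.00, 5.50, 6.40, 6.50, 6.60, 6.70, 6.80,
    6.90, 6.90, 7.00, 7.10, 7.10, 7.20, 7.20, 7.30, 7.30, 7.40, 7.40,
    7.50, 7.50, 7.50, 7.60, 7.60, 7.70),
  as.character(3:30))

#' Nearest-neighbor energy model for terminator hairpins
#'
#' Returns the energy model used to score hairpin stability: stack free
#' energies over the six canonical pair types (`CG`, `GC`, `GT`, `TG`, `AT`,
#' `TA`; DNA `T` stands for RNA `U`), hairpin loop initiation penalties for
#' loop sizes 3-30 (longer loops reuse the size-30 value), a terminal AU/GU
#' closing-pair penalty and a single-nucleotide bulge penalty.  All values are
#' kcal/mol at 37C (Turner 2004 parameter set).
#'
#' @return An object of class `energy_model`: a list with elements
#'   `stack_dg` (6x6 matrix, rows = outer pair, columns = inner pair read
#'   3'->5'), `hairpin_loop_dg` (named vector, sizes 3-30),
#'   `terminal_au_penalty` and `bulge_dg`.
#' @examples
#' m <- default_energy_model()
#' m$stack_dg["GC", "CG"]  # 5'-GG-3' / 3'-CC-5'
#' @export
default_energy_model <- function() {
  structure(list(stack_dg = .turner_stack,
                 hairpin_loop_dg = .turner_hairpin,
                 terminal_au_penalty = 0.50,
                 bulge_dg = 3.80),
            class = "energy_model")
}

#' Hairpin folding free energy from the nearest-neighbor tables
#'
#' Computes the free energy of a hairpin formed by two stem arms closing a
#' loop: the sum of stack free energies over consecutive base-pair steps, the
#' loop initiation penalty for `min(loop_len, 30)`, and the terminal penalty
#' when the outermost (closing) pair is AU, UA, GU or UG.  Position k of
#' `stem5_seq` pairs with position `length - k + 1` of `stem3_seq`.
#'
#' @param stem5_seq 5' stem arm, 5'->3' (character string over ACGT).
#' @param stem3_seq 3' stem arm, 5'->3'; must be the same length.
#' @param loop_len Loop length in nucleotides (>= 3).
#' @param model An [default_energy_model()] object.
#' @param allow_gu Accept GU wobble pairs in the stem (default `TRUE`).
#' @return Free energy in kcal/mol (negative = more stable).
#' @examples
#' hairpin_delta_g("GGGG", "CCCC", 4)   # three G-C stacks + loop(4)
#' @export
hairpin_delta_g <- function(stem5_seq, stem3_seq, loop_len,
                            model = default_energy_model(), allow_gu = TRUE) {
  stopifnot(is.character(stem5_seq), is.character(stem3_seq),
            length(stem5_seq) == 1L, length(stem3_seq) == 1L)
  s5 <- strsplit(normalize_sequence(stem5_seq), "", fixed = TRUE)[[1]]
  s3 <- strsplit(normalize_sequence(stem3_seq), "", fixed = TRUE)[[1]]
  L <- length(s5)
  if (L != length(s3) || L < 1)
    stop("stem arms must be non-empty and of equal length")
  if (loop_len < 3) stop("loop_len must be >= 3")
  pairs <- paste0(s5, rev(s3))            # outermost -> innermost
  valid <- c("CG", "GC", "AT", "TA", if (allow_gu) c("GT", "TG"))
  bad <- which(!pairs %in% valid)
  if (length(bad))
    stop(sprintf("stem position %d does not pair (%s against %s)",
                 bad[1], s5[bad[1]], rev(s3)[bad[1]]))
  dg <- unname(model$hairpin_loop_dg[as.character(min(loop_len, 30))])
  if (L > 1) {
    inner_rev <- paste0(substr(pairs[-1], 2, 2), substr(pairs[-1], 1, 1))
    dg <- dg + sum(model$stack_dg[cbind(pairs[-L], inner_rev)])
  }
  if (pairs[1] %in% c("AT", "TA", "GT", "TG"))
    dg <- dg + model$terminal_au_penalty
  dg
}
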