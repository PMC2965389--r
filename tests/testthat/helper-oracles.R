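# Independent oracles, written separately from the production code paths:
# a brute-force decomposition enumerator for the descriptor, a by-hand
# energy summation, an exhaustive hypergeometric tail, a cubic-time local
# alignment DP, and an exhaustive Eulerian-shuffle enumerator.

oracle_pair_ok <- function(x, y, allow_gu = TRUE) {
  ok <- paste0(x, y) %in% c("AT", "TA", "GC", "CG")
  if (allow_gu) ok | paste0(x, y) %in% c("GT", "TG") else ok
}

# Energy of a stem given as character vectors, by direct named-table lookup.
oracle_hairpin_dg <- function(s5, s3, loop_len, model = default_energy_model()) {
  L <- length(s5)
  pr <- character(L)
  for (k in seq_len(L)) pr[k] <- paste0(s5[k], s3[L - k + 1])
  dg <- model$hairpin_loop_dg[[as.character(min(loop_len, 30))]]
  if (L >= 2)
    for (k in seq_len(L - 1)) {
      inner <- pr[k + 1]
      dg <- dg + model$stack_dg[pr[k],
                                paste0(substr(inner, 2, 2),
                                       substr(inner, 1, 1))]
    }
  if (pr[1] %in% c("AT", "TA", "GT", "TG")) dg <- dg + model$terminal_au_penalty
  unname(dg)
}

# Exhaustive enumeration of every admissible decomposition of a sequence,
# then the pinned overlap resolution (lowest dG; ties leftmost, longest
# stem, smallest spacer), implemented with its own bookkeeping.
oracle_scan_descriptor <- function(seq, params = descriptor_params(),
                                   model = default_energy_model()) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  p <- params
  rows <- list()
  for (s in seq_len(n)) {
    for (L in p$stem_min:p$stem_max) {
      for (ll in p$loop_min:p$loop_max) {
        s3 <- s + L + ll
        tail0 <- s3 + L
        if (tail0 + p$spacer_min + p$tail_len - 1 > n) next
        pair_all <- TRUE
        for (k in seq_len(L)) {
          if (!oracle_pair_ok(ch[s + k - 1], ch[s3 + L - k], p$allow_gu)) {
            pair_all <- FALSE
            break
          }
        }
        if (!pair_all) next
        dg <- oracle_hairpin_dg(ch[s:(s + L - 1)], ch[s3:(s3 + L - 1)], ll,
                                model)
        if (dg > p$dg_max) next
        for (sp in p$spacer_min:p$spacer_max) {
          ts <- tail0 + sp
          te <- ts + p$tail_len - 1
          if (te > n) next
          tw <- ch[ts:te]
          if (sum(tw == "T") < p$tail_min_t) next
          if (sum(tw[1:5] == "T") < p$tail_head_min_t) next
          rows[[length(rows) + 1L]] <- data.frame(
            stem5_start = s, stem5_end = s + L - 1L, loop_len = ll,
            stem3_start = s3, stem3_end = s3 + L - 1L, spacer_len = sp,
            tail_start = ts, stem_len = L, delta_g = dg)
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  d <- do.call(rbind, rows)
  d <- d[order(round(d$delta_g, 9), d$stem5_start, -d$stem_len,
               d$spacer_len), , drop = FALSE]
  taken <- integer(0)
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    stem_pos <- c(seq(d$stem5_start[i], d$stem5_end[i]),
                  seq(d$stem3_start[i], d$stem3_end[i]))
    if (!any(stem_pos %in% taken)) {
      keep[i] <- TRUE
      taken <- c(taken, stem_pos)
    }
  }
  d <- d[keep, , drop = FALSE]
  d[order(d$stem5_start, d$stem3_start), , drop = FALSE]
}

# Exact one-sided hypergeometric tail by direct enumeration of the support.
oracle_fisher <- function(n_genes_family, n_genes_total, n_hit_family,
                          n_hit_total) {
  ks <- seq(n_hit_family, min(n_genes_family, n_hit_total))
  if (!length(ks)) return(0)
  sum(choose(n_genes_family, ks) *
        choose(n_genes_total - n_genes_family, n_hit_total - ks)) /
    choose(n_genes_total, n_hit_total)
}

# Smith-Waterman-Gotoh raw local score, simple O(nm) three-matrix DP.
oracle_sw_raw <- function(a, b, match = 1, mismatch = -2, gap_open = 2,
                          gap_extend = 1) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  M <- Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(0,
                     M[i - 1, j - 1] + s,
                     Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# All sequences with the same dinucleotide counts and terminal bases as
# `seq`, by exhaustive permutation of the interior (tiny inputs only).
oracle_euler_set <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  dc <- function(x) {
    d <- paste0(x[-length(x)], x[-1])
    table(factor(d, levels = as.vector(outer(c("A", "C", "G", "T"),
                                             c("A", "C", "G", "T"),
                                             paste0))))
  }
  ref <- dc(ch)
  mids <- ch[-c(1, n)]
  perms <- unique(combinat_perms(mids))
  out <- character(0)
  for (i in seq_len(nrow(perms))) {
    cand <- c(ch[1], perms[i, ], ch[n])
    if (all(dc(cand) == ref)) out <- c(out, paste(cand, collapse = ""))
  }
  unique(out)
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- combinat_perms(v[-i])
    out <- rbind(out, cbind(v[i], rest, deparse.level = 0))
  }
  out
}

dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  d <- paste0(ch[-length(ch)], ch[-1])
  table(factor(d, levels = as.vector(outer(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T"), paste0))))
}
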