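# From terminator hits to attenuator candidates.
#
# A hit is a candidate attenuator when it sits in the 5' leader of a gene in
# the same orientation (five_prime class), no further than 300 nt from the
# start codon, and closer to its downstream gene than to the upstream gene
# (distance ratio <= 1) -- the latter guards against canonical 3' terminators
# of the upstream gene and terminators of independent small RNAs.

# Transcript-orientation anchors from forward-coordinate hit intervals.
#' @noRd
hit_anchors <- function(hits) {
  plus <- hits$strand == "+"
  list(tail3p = ifelse(plus, hits$tail_end, hits$tail_start),
       stem5p = ifelse(plus, hits$stem5_start, hits$stem5_end))
}

#' Classify terminator hits as 5' or 3' relative to flanking genes
#'
#' A hit is `five_prime` when it points toward (is co-oriented with) the gene
#' it is transcribed toward: the right flanking gene for a "+" hit, the left
#' flanking gene for a "-" hit.  It is `three_prime` when it instead trails a
#' co-oriented upstream gene.  A hit eligible for both is classified
#' `five_prime` (3' is assigned later if the 5' filters fail); a hit with no
#' co-oriented flanking gene is `unassigned`.
#'
#' @param hits Hits data frame (from [scan_annotation()]), with `left_gene_id`
#'   and `right_gene_id` columns.
#' @param ann The `genome_annotation`.
#' @return `hits` with `utr_class` set and logical columns `five_eligible`,
#'   `three_eligible` added.
#' @export
classify_hits <- function(hits, ann) {
  if (!nrow(hits)) {
    hits$five_eligible <- logical(0)
    hits$three_eligible <- logical(0)
    return(hits)
  }
  gstrand <- setNames(ann$genes$strand, ann$genes$gene_id)
  ls <- gstrand[hits$left_gene_id]
  rs <- gstrand[hits$right_gene_id]
  plus <- hits$strand == "+"
  hits$five_eligible <- (plus & !is.na(rs) & rs == "+") |
    (!plus & !is.na(ls) & ls == "-")
  hits$three_eligible <- (plus & !is.na(ls) & ls == "+") |
    (!plus & !is.na(rs) & rs == "-")
  hits$utr_class <- ifelse(hits$five_eligible, "five_prime",
                           ifelse(hits$three_eligible, "three_prime",
                                  "unassigned"))
  hits
}

# Distances of five_prime hits to their flanking genes, in transcript
# orientation; handles wrap-around regions by modular arithmetic.
#' @noRd
candidate_distances <- function(hits, ann) {
  gstart <- setNames(ann$genes$start, ann$genes$gene_id)
  gend <- setNames(ann$genes$end, ann$genes$gene_id)
  rlen <- setNames(Biostrings::width(ann$replicons), names(ann$replicons))
  an <- hit_anchors(hits)
  plus <- hits$strand == "+"
  down_id <- ifelse(plus, hits$right_gene_id, hits$left_gene_id)
  up_id <- ifelse(plus, hits$left_gene_id, hits$right_gene_id)
  d_down <- ifelse(plus, gstart[down_id] - an$tail3p - 1L,
                   an$tail3p - gend[down_id] - 1L)
  d_up_raw <- ifelse(plus, an$stem5p - gend[up_id] - 1L,
                     gstart[up_id] - an$stem5p - 1L)
  wrap <- if ("region_wrap" %in% names(hits)) hits$region_wrap else FALSE
  rl <- rlen[hits$replicon_id]
  d_down <- ifelse(wrap, (d_down %% rl + rl) %% rl, d_down)
  d_up_raw <- ifelse(wrap, (d_up_raw %% rl + rl) %% rl, d_up_raw)
  d_up <- pmax(1L, d_up_raw)
  list(downstream_gene_id = down_id, upstream_gene_id = up_id,
       d_down = as.integer(d_down), d_up = as.integer(d_up))
}

#' Apply the attenuator orientation/distance filters
#'
#' Keeps `five_prime` hits whose tail ends at most `max_dist` nucleotides
#' before the downstream gene's first codon and whose distance ratio
#' d_down / d_up is at most 1 (the ratio test passes automatically when no
#' upstream gene flanks the region).  d_down counts the nucleotides strictly
#' between the tail 3' end and the first codon base; d_up counts from the
#' stem 5' start to the nearest boundary of the upstream gene, floored at 1.
#'
#' @param hits Classified hits (see [classify_hits()]).
#' @param ann The `genome_annotation`.
#' @param max_dist Maximal distance to the downstream start codon (nt).
#' @return A candidates data frame (one row per retained hit) with
#'   `downstream_gene_id`, `upstream_gene_id`, `d_down`, `d_up`, `ratio` and
#'   all hit columns.  The rejected `five_prime` hits are attached as
#'   `attr(, "rejected")` with a `reason` column (`"distance"` or
#'   `"ratio"`).
#' @export
apply_attenuator_filters <- function(hits, ann, max_dist = 300L) {
  h5 <- hits[hits$utr_class == "five_prime", , drop = FALSE]
  if (!nrow(h5)) {
    out <- cbind(h5, data.frame(downstream_gene_id = character(0),
                                upstream_gene_id = character(0),
                                d_down = integer(0), d_up = integer(0),
                                ratio = numeric(0)))
    rej <- out
    rej$reason <- character(0)
    attr(out, "rejected") <- rej
    return(out)
  }
  dd <- candidate_distances(h5, ann)
  h5$downstream_gene_id <- dd$downstream_gene_id
  h5$upstream_gene_id <- dd$upstream_gene_id
  h5$d_down <- dd$d_down
  h5$d_up <- dd$d_up
  h5$ratio <- ifelse(is.na(h5$upstream_gene_id), 0, h5$d_down / h5$d_up)
  fail_dist <- h5$d_down > max_dist | h5$d_down < 0
  fail_ratio <- !fail_dist & h5$ratio > 1
  keep <- !fail_dist & !fail_ratio
  rejected <- h5[!keep, , drop = FALSE]
  rejected$reason <- if (nrow(rejected))
    ifelse(fail_dist[!keep], "distance", "ratio") else character(0)
  out <- h5[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

# Characters of a replicon interval walked in transcript orientation with
# circular wrap; start0 is the transcript-5' forward coordinate.
#' @noRd
modular_subseq <- function(rep_seq, from, to, strand, rlen) {
  if (strand == "+") {
    len <- (to - from) %% rlen + 1L
    pos <- ((from - 1L + seq_len(len) - 1L) %% rlen) + 1L
  } else {
    len <- (from - to) %% rlen + 1L
    pos <- ((from - 1L - (seq_len(len) - 1L)) %% rlen) + 1L
  }
  s <- paste(strsplit(as.character(rep_seq), "", fixed = TRUE)[[1]][pos],
             collapse = "")
  if (strand == "-") chartr("ACGTN", "TGCAN", s) else s
}

#' Extract the candidate leader sequence
#'
#' The leader runs from the limit of the upstream gene -- or at most `cap`
#' nucleotides 5' of the terminator stem -- to the position immediately 3' of
#' the terminator tail, reported 5'->3' on the candidate strand.
#'
#' @param cand One or more rows of [apply_attenuator_filters()] output.
#' @param ann The `genome_annotation`.
#' @param cap Maximal number of nucleotides upstream of the stem 5' start.
#' @return `cand` with `leader_start`, `leader_end` (forward coordinates of
#'   the leader interval) and `leader_seq` columns filled.
#' @export
extract_candidate_sequence <- function(cand, ann, cap = 200L) {
  if (!nrow(cand)) {
    cand$leader_start <- integer(0)
    cand$leader_end <- integer(0)
    cand$leader_seq <- character(0)
    return(cand)
  }
  gstart <- setNames(ann$genes$start, ann$genes$gene_id)
  gend <- setNames(ann$genes$end, ann$genes$gene_id)
  rlen_tab <- setNames(Biostrings::width(ann$replicons), names(ann$replicons))
  an <- hit_anchors(cand)
  ls <- le <- integer(nrow(cand))
  seqs <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rlen <- rlen_tab[[cand$replicon_id[i]]]
    rep_seq <- ann$replicons[[cand$replicon_id[i]]]
    up <- cand$upstream_gene_id[i]
    wrap <- "region_wrap" %in% names(cand) && isTRUE(cand$region_wrap[i])
    if (cand$strand[i] == "+") {
      from <- an$stem5p[i] - cap
      if (!is.na(up)) from <- max(from, gend[[up]] + 1L)
      if (!wrap) from <- max(from, 1L)
      to <- an$tail3p[i]
    } else {
      from <- an$stem5p[i] + cap
      if (!is.na(up)) from <- min(from, gstart[[up]] - 1L)
      if (!wrap) from <- min(from, rlen)
      to <- an$tail3p[i]
    }
    if (wrap || from < 1L || from > rlen) {
      seqs[i] <- modular_subseq(rep_seq, from, to, cand$strand[i], rlen)
      from <- ((from - 1L) %% rlen) + 1L
    } else if (cand$strand[i] == "+") {
      seqs[i] <- as.character(Biostrings::subseq(rep_seq, from, to))
    } else {
      seqs[i] <- revcomp(as.character(Biostrings::subseq(rep_seq, to, from)))
    }
    ls[i] <- min(from, to)
    le[i] <- max(from, to)
  }
  cand$leader_start <- ls
  cand$leader_end <- le
  cand$leader_seq <- seqs
  cand
}

#' Compare stability and stem length between 5' and 3' terminators
#'
#' Reports per-class means of folding free energy and stem length, with
#' two-sided Welch t-test p-values for each comparison.
#'
#' @param hits5,hits3 Hit data frames (need `delta_g` and `stem_len`).
#' @return A list of class `utr_stats_report`: `n5`, `n3`, `mean_dg5`,
#'   `mean_dg3`, `mean_stem5`, `mean_stem3`, `p_dg`, `p_stem` (p-values `NA`
#'   when either class has fewer than 2 hits).
#' @export
compare_utr_stats <- function(hits5, hits3) {
  stopifnot(nrow(hits5) >= 1, nrow(hits3) >= 1)
  welch <- function(a, b) {
    if (length(a) < 2 || length(b) < 2 || (stats::sd(a) == 0 &&
                                           stats::sd(b) == 0))
      return(NA_real_)
    stats::t.test(a, b)$p.value
  }
  structure(list(
    n5 = nrow(hits5), n3 = nrow(hits3),
    mean_dg5 = mean(hits5$delta_g), mean_dg3 = mean(hits3$delta_g),
    mean_stem5 = mean(hits5$stem_len), mean_stem3 = mean(hits3$stem_len),
    p_dg = welch(hits5$delta_g, hits3$delta_g),
    p_stem = welch(hits5$stem_len, hits3$stem_len)),
    class = "utr_stats_report")
}

#' @export
print.utr_stats_report <- function(x, ...) {
  cat(sprintf("5' terminators: n = %d, mean dG = %.2f kcal/mol, mean stem = %.2f bp\n",
              x$n5, x$mean_dg5, x$mean_stem5))
  cat(sprintf("3' terminators: n = %d, mean dG = %.2f kcal/mol, mean stem = %.2f bp\n",
              x$n3, x$mean_dg3, x$mean_stem3))
  cat(sprintf("Welch p (dG) = %.3g, Welch p (stem) = %.3g\n",
              x$p_dg, x$p_stem))
  invisible(x)
}

#' Run the full attenuator screen on one genome
#'
#' Regions are derived, both strands scanned (profile-first, descriptor
#' fallback), hits classified, the attenuator filters applied, and leader
#' sequences extracted.  Hits whose 5' filters fail but that trail a
#' co-oriented upstream gene are reclassified as 3' terminators.
#'
#' @inheritParams scan_annotation
#' @param max_dist Distance filter for candidates (nt).
#' @param cap Leader length cap (nt upstream of the stem).
#' @return A list of class `attenuator_screen`: `regions`, `hits` (with final
#'   `utr_class`), `candidates` (filtered, with leaders), `rejected` (failed
#'   five_prime hits with reasons).
#' @export
screen_attenuators <- function(ann, model = NULL,
                               params = descriptor_params(),
                               energy = default_energy_model(),
                               max_dist = 300L, cap = 200L,
                               short_orf_max = 200L) {
  regions <- extract_search_regions(ann, short_orf_max)
  hits <- scan_annotation(ann, model, params, energy, regions = regions)
  if (nrow(hits))
    hits$region_wrap <- regions$wrap[match(hits$region_id, regions$region_id)]
  hits <- classify_hits(hits, ann)
  cands <- apply_attenuator_filters(hits, ann, max_dist = max_dist)
  rejected <- attr(cands, "rejected")
  cands <- extract_candidate_sequence(cands, ann, cap = cap)
  if (nrow(cands))
    cands$candidate_id <- sprintf("%s|%s|%d|%s", ann$species_id,
                                  cands$downstream_gene_id, cands$tail_start,
                                  cands$strand)
  else cands$candidate_id <- character(0)
  cands$species_id <- if (nrow(cands)) ann$species_id else character(0)
  # final classes on the hit table: failed 5' hits fall back to 3' if eligible
  if (nrow(hits)) {
    is_cand <- with(hits, paste(region_id, strand, tail_start)) %in%
      with(cands, paste(region_id, strand, tail_start))
    demote <- hits$utr_class == "five_prime" & !is_cand
    hits$utr_class[demote] <- ifelse(hits$three_eligible[demote],
                                     "three_prime", "unassigned")
  }
  structure(list(regions = regions, hits = hits, candidates = cands,
                 rejected = rejected),
            class = "attenuator_screen")
}

#' @export
print.attenuator_screen <- function(x, ...) {
  cat(sprintf(paste0("attenuator_screen: %d regions, %d hits ",
                     "(%d five_prime, %d three_prime), %d candidates\n"),
              nrow(x$regions), nrow(x$hits),
              sum(x$hits$utr_class == "five_prime"),
              sum(x$hits$utr_class == "three_prime"), nrow(x$candidates)))
  invisible(x)
}

#' Screen every species of a cohort
#'
#' @param cohort An `attenuator_cohort` (see [generate_cohort()]) or a named
#'   list of `genome_annotation` objects.
#' @inheritParams screen_attenuators
#' @return A list of class `cohort_screen`: `screens` (per species),
#'   `candidates` (combined, with `species_id`), `hits` (combined).
#' @export
screen_cohort <- function(cohort, model = NULL, params = descriptor_params(),
                          energy = default_energy_model(), max_dist = 300L,
                          cap = 200L) {
  anns <- if (inherits(cohort, "attenuator_cohort")) cohort$annotations
          else cohort
  screens <- lapply(anns, screen_attenuators, model = model, params = params,
                    energy = energy, max_dist = max_dist, cap = cap)
  cands <- do.call(rbind, lapply(screens, `[[`, "candidates"))
  hits <- do.call(rbind, lapply(names(screens), function(sp) {
    h <- screens[[sp]]$hits
    if (nrow(h)) h$species_id <- sp else h$species_id <- character(0)
    h
  }))
  rownames(cands) <- rownames(hits) <- NULL
  structure(list(screens = screens, candidates = cands, hits = hits),
            class = "cohort_screen")
}
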