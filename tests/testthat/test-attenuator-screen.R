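# Hit classification, attenuator filters, leader extraction, UTR stats.

# Minimal annotation with two genes around one gap; hit rows are built by
# hand so the classification and distance rules can be checked exactly.
toy_ann <- function(strand_left = "+", strand_right = "+", W = 400L) {
  genes <- data.frame(gene_id = c("gL", "gR"), replicon_id = "c",
                      start = c(1L, 100L + W + 1L),
                      end = c(100L, 100L + W + 300L),
                      strand = c(strand_left, strand_right), product = "p")
  set.seed(1)
  genome_annotation("sp", c(c = rand_dna(100L + W + 300L)), genes)
}

mk_hit <- function(strand, stem5_start, tail_end, stem_len = 8L) {
  span <- 2L * stem_len + 4L
  h <- data.frame(replicon_id = "c", strand = strand,
                  stem5_start = stem5_start,
                  stem5_end = stem5_start + stem_len - 1L,
                  loop_start = stem5_start + stem_len,
                  loop_end = stem5_start + stem_len + 3L,
                  stem3_start = stem5_start + stem_len + 4L,
                  stem3_end = stem5_start + span - 1L,
                  spacer_len = 0L, tail_start = tail_end - 11L,
                  tail_end = tail_end, stem_len = stem_len, n_bulge = 0L,
                  delta_g = -12, score = NA_real_, method = "descriptor",
                  utr_class = "unassigned",
                  region_id = "c:101-500", left_gene_id = "gL",
                  right_gene_id = "gR", stringsAsFactors = FALSE)
  h
}

test_that("orientation classification follows the flanking-gene rule", {
  ann <- toy_ann("+", "+")
  h <- classify_hits(mk_hit("+", 300L, 340L), ann)
  expect_equal(h$utr_class, "five_prime")   # co-oriented downstream gene
  expect_true(h$three_eligible)             # also trails a + gene

  ann2 <- toy_ann("+", "-")
  h2 <- classify_hits(mk_hit("+", 300L, 340L), ann2)
  expect_equal(h2$utr_class, "three_prime")

  h3 <- mk_hit("+", 300L, 340L)
  h3$right_gene_id <- NA_character_
  h3$left_gene_id <- NA_character_
  expect_equal(classify_hits(h3, ann)$utr_class, "unassigned")

  # minus-strand hit points toward the left gene
  ann4 <- toy_ann("-", "+")
  h4 <- classify_hits(mk_hit("-", 150L, 130L), ann4)
  expect_equal(h4$utr_class, "five_prime")
})

test_that("distance and ratio filters keep and discard per the rules", {
  ann <- toy_ann("+", "+", W = 2000L)  # gene gR starts at 2101
  run1 <- function(tail_end, stem5_start) {
    h <- classify_hits(mk_hit("+", stem5_start, tail_end), ann)
    apply_attenuator_filters(h, ann)
  }
  # d_down = 100, d_up = 400 -> kept, ratio 0.25
  k <- run1(2000L, 501L)
  expect_equal(nrow(k), 1L)
  expect_equal(k$d_down, 100L)
  expect_equal(k$d_up, 400L)
  expect_equal(k$ratio, 0.25)
  # d_down = 350 -> discarded for distance
  r <- run1(1750L, 501L)
  expect_equal(nrow(r), 0L)
  expect_equal(attr(r, "rejected")$reason, "distance")
  # d_down = 100 with d_up = 50 -> discarded for ratio
  r2 <- run1(2000L, 151L)
  expect_equal(attr(r2, "rejected")$reason, "ratio")
  # no upstream gene: ratio passes automatically
  h <- classify_hits(mk_hit("+", 2000L, 2060L), ann)
  h$left_gene_id <- NA_character_
  expect_equal(nrow(apply_attenuator_filters(h, ann)), 1L)
})

test_that("tightening max_dist only shrinks the candidate set", {
  scr <- small_cohort_screen()$screen
  h <- do.call(rbind, lapply(scr$screens, `[[`, "hits"))
  anns <- small_cohort_screen()$cohort$annotations
  sizes <- vapply(c(300L, 200L, 100L, 50L), function(md) {
    sum(vapply(names(anns), function(sp) {
      hh <- scr$screens[[sp]]$hits
      nrow(apply_attenuator_filters(hh, anns[[sp]], max_dist = md))
    }, integer(1)))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("leader extraction obeys the upstream limit and the 200-nt cap", {
  ann <- toy_ann("+", "+", W = 2000L)
  mk_cand <- function(stem5_start, tail_end) {
    h <- classify_hits(mk_hit("+", stem5_start, tail_end), ann)
    extract_candidate_sequence(apply_attenuator_filters(h, ann), ann)
  }
  # upstream gene 150 nt before the stem: leader starts at the gene limit
  cand <- mk_cand(251L, 2080L)
  expect_equal(cand$leader_start, 101L)
  # upstream gene far away: leader starts exactly 200 nt 5' of the stem
  cand2 <- mk_cand(1901L, 2080L)
  expect_equal(cand2$leader_start, 1901L - 200L)
  expect_equal(cand2$leader_end, 2080L)
  expect_equal(nchar(cand2$leader_seq), 2080L - (1901L - 200L) + 1L)
  seqchr <- as.character(ann$replicons[["c"]])
  expect_equal(cand2$leader_seq, substr(seqchr, 1701L, 2080L))
})

test_that("minus-strand leaders are reverse complements of the interval", {
  ann <- toy_ann("-", "+", W = 2000L)
  # tail forward interval [189, 200], stem5 (transcript 5') at 210..217
  h <- classify_hits(mk_hit("-", 210L, 200L), ann)
  cand <- apply_attenuator_filters(h, ann)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$d_down, 88L)
  cand <- extract_candidate_sequence(cand, ann)
  seqchr <- as.character(ann$replicons[["c"]])
  fwd <- substr(seqchr, cand$leader_start, cand$leader_end)
  expect_equal(cand$leader_seq,
               chartr("ACGTN", "TGCAN",
                      paste(rev(strsplit(fwd, "")[[1]]), collapse = "")))
  expect_equal(cand$leader_start, 189L)         # ends at the tail 3' end
  expect_equal(cand$leader_end, 217L + 200L)    # capped 200 nt past the stem
})

test_that("compare_utr_stats reports means and Welch p-values", {
  h5 <- data.frame(delta_g = c(-10, -12), stem_len = c(7, 7))
  h3 <- data.frame(delta_g = c(-20, -22), stem_len = c(9, 9))
  st <- compare_utr_stats(h5, h3)
  expect_equal(st$mean_dg5, -11)
  expect_equal(st$mean_dg3, -21)
  st_same <- compare_utr_stats(
    data.frame(delta_g = rnorm(20, -15), stem_len = rnorm(20, 8)),
    data.frame(delta_g = rnorm(20, -15, 1e-12), stem_len = 8))
  expect_true(is.na(st_same$p_stem) || st_same$p_stem > 0)
  ident <- data.frame(delta_g = c(-10, -11, -12), stem_len = c(7, 8, 9))
  expect_gt(compare_utr_stats(ident, ident)$p_dg, 0.99)
  # n < 2 in a class: p-values reported as NA
  st1 <- compare_utr_stats(h5[1, ], h3)
  expect_true(is.na(st1$p_dg))
})

test_that("planted 5'-vs-3' stem contrast is recovered at n = 150", {
  spec <- synthetic_spec(n_species = 5, genes_per_species = 60,
                         n_families = 40, n_plant_5p = 150,
                         stem_len_5p = c(7, 1), stem_len_3p = c(9, 1),
                         n_is_elements = 0,
                         n_violators = c(distance = 0, ratio = 0,
                                         strand = 0),
                         seed = 8)
  coh <- generate_cohort(spec)
  scr <- screen_cohort(coh)
  h <- scr$hits
  h5 <- h[h$utr_class == "five_prime", ]
  h3 <- h[h$utr_class == "three_prime", ]
  expect_gte(nrow(h5), 150 * 0.9)
  expect_gte(nrow(h3), 150)
  st <- compare_utr_stats(h5, h3)
  expect_lt(st$mean_stem5, st$mean_stem3)
  expect_gt(st$mean_dg5, st$mean_dg3)  # 5' less stable (less negative)
  expect_lt(st$p_stem, 0.01)
  expect_lt(st$p_dg, 0.01)
})
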