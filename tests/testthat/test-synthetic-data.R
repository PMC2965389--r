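# The synthetic cohort generator and its ground truth.

test_that("plant_terminator writes a detectable motif with exact truth", {
  set.seed(70)
  base <- rand_dna(200)
  pl <- plant_terminator(base, pos = 80, stem_len = 8, stem_gc = 0.9)
  h <- scan_descriptor(pl$seq)
  tr <- pl$truth
  expect_true(any(h$stem5_start == tr$stem5_start &
                    h$tail_start == tr$tail_start))
  expect_equal(tr$delta_g,
               hairpin_delta_g(substr(pl$seq, tr$stem5_start, tr$stem5_end),
                               substr(pl$seq, tr$stem3_start, tr$stem3_end),
                               tr$loop_end - tr$loop_start + 1))
})

test_that("plants below the descriptor minimum or overlapping are refused", {
  base <- strrep("A", 200)
  expect_error(plant_terminator(base, 10, stem_len = 3), "4-18")
  expect_error(plant_terminator(base, 190, stem_len = 8), "room")
  pl <- plant_terminator(base, 50, stem_len = 8)
  expect_error(plant_terminator(pl$seq, 55, stem_len = 8,
                                occupied = list(pl$interval)), "overlap")
})

test_that("cohorts are byte-for-byte reproducible from the seed", {
  spec <- synthetic_spec(n_species = 2, genes_per_species = 40,
                         n_families = 8, n_plant_5p = 10,
                         n_is_elements = 1,
                         n_violators = c(distance = 1, ratio = 1,
                                         strand = 1), seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(lapply(c1$annotations, function(a)
    as.character(a$replicons)), lapply(c2$annotations, function(a)
      as.character(a$replicons)))
  expect_identical(c1$truth, c2$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("truth bookkeeping matches the requested plan", {
  spec <- synthetic_spec(n_species = 3, genes_per_species = 50,
                         n_families = 10, n_plant_5p = 20,
                         n_is_elements = 2,
                         n_violators = c(distance = 2, ratio = 2,
                                         strand = 2), seed = 5)
  coh <- generate_cohort(spec)
  tr <- coh$truth
  expect_equal(sum(tr$class == "5p" & tr$violation == "none"), 20L)
  expect_equal(sum(tr$class == "IS"), 2L)
  expect_equal(sum(tr$violation == "distance"), 2L)
  expect_equal(sum(tr$violation == "ratio"), 2L)
  expect_equal(sum(tr$violation == "strand"), 2L)
  expect_equal(sum(tr$class == "3p"), 3L * 50L)  # one per gene
  # planted coordinates address the emitted sequence correctly: the tail
  # window of every plant is T-rich on its strand
  for (i in sample(nrow(tr), 30)) {
    s <- as.character(
      coh$annotations[[tr$species_id[i]]]$replicons[[tr$replicon_id[i]]])
    w <- substr(s, tr$tail_start[i], tr$tail_end[i])
    if (tr$strand[i] == "-")
      w <- chartr("ACGT", "TGCA", w)  # reverse unneeded for counting T/A
    expect_gte(sum(strsplit(w, "")[[1]] == "T"), 7)
  }
})

test_that("written cohorts round-trip through read_genome", {
  coh <- generate_cohort(synthetic_spec(
    n_species = 1, genes_per_species = 30, n_families = 6, n_plant_5p = 5,
    n_is_elements = 1, n_violators = c(distance = 0, ratio = 0, strand = 0),
    seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  ann <- read_genome(file.path(dir, "sp01.fasta"),
                     file.path(dir, "sp01.gff3"), species_id = "sp01")
  orig <- coh$annotations[["sp01"]]
  expect_equal(as.character(ann$replicons), as.character(orig$replicons))
  expect_equal(ann$genes$gene_id, orig$genes$gene_id)
  expect_equal(ann$genes$start, orig$genes$start)
  expect_equal(ann$genes$end, orig$genes$end)
  expect_equal(ann$genes$strand, orig$genes$strand)
  fm <- read_family_map(file.path(dir, "family_map.tsv"))
  expect_equal(nrow(fm), 30L)
})

test_that("background composition matches the binomial expectation", {
  coh <- generate_cohort(synthetic_spec(
    n_species = 1, genes_per_species = 120, n_families = 10,
    n_plant_5p = 0, n_is_elements = 0, plant_3p_all = FALSE,
    n_violators = c(distance = 0, ratio = 0, strand = 0),
    background_gc = 0.5, seed = 44))
  s <- as.character(coh$annotations[[1]]$replicons[[1]])
  n <- nchar(s)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  # within 3 sd of Binomial(n, 0.5)
  expect_lt(abs(gc - n * 0.5), 3 * sqrt(n * 0.25))
})

test_that("positive plants pass the filters; violators fail as labeled", {
  fix <- small_cohort_screen()
  coh <- fix$cohort
  scr <- fix$screen
  tr <- coh$truth
  ev <- evaluate_detection(scr$candidates, tr)
  expect_equal(ev$sensitivity, 1)

  tailc <- ifelse(scr$candidates$strand == "+", scr$candidates$tail_end,
                  scr$candidates$tail_start)
  keyc <- paste(scr$candidates$species_id, scr$candidates$strand)
  near_candidate <- function(row) {
    any(keyc == paste(row$species_id, row$strand) &
          abs(tailc - ifelse(row$strand == "+", row$tail_end,
                             row$tail_start)) <= 3)
  }
  rejected <- do.call(rbind, lapply(names(scr$screens), function(sp) {
    r <- scr$screens[[sp]]$rejected
    r$species_id <- if (nrow(r)) sp else character(0)
    r
  }))
  for (i in which(tr$violation != "none")) {
    row <- tr[i, , drop = FALSE]
    expect_false(near_candidate(row))  # excluded from candidates
    if (row$violation %in% c("distance", "ratio")) {
      # present among rejected five_prime hits with the labeled reason
      rtail <- ifelse(rejected$strand == "+", rejected$tail_end,
                      rejected$tail_start)
      j <- which(rejected$species_id == row$species_id &
                   rejected$strand == row$strand &
                   abs(rtail - ifelse(row$strand == "+", row$tail_end,
                                      row$tail_start)) <= 3)
      expect_true(length(j) >= 1, info = paste("violator row", i))
      expect_true(row$violation %in% rejected$reason[j])
    } else {
      # strand violators are never classified five_prime toward the gene
      h <- scr$screens[[row$species_id]]$hits
      htail <- ifelse(h$strand == "+", h$tail_end, h$tail_start)
      j <- which(h$strand == row$strand &
                   abs(htail - ifelse(row$strand == "+", row$tail_end,
                                      row$tail_start)) <= 3)
      if (length(j)) expect_true(all(h$utr_class[j] != "five_prime"))
    }
  }
})
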