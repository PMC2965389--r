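# Genome parsing and search-region derivation.

test_that("read_genome parses FASTA + GFF3 and flags hypothetical products", {
  paths <- write_toy_genome()
  ann <- read_genome(paths$fasta, paths$gff)
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann$genes), 2L)
  expect_equal(ann$genes$gene_id, c("g1", "g2"))
  expect_equal(ann$genes$length, c(300L, 400L))
  expect_false(ann$genes$hypothetical[1])
  expect_true(ann$genes$hypothetical[2])
  expect_equal(sort(ann$genes$start), c(1L, 501L))
})

test_that("CDS rows yield hypothetical-flagged records with correct length", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  gff <- file.path(dir, "g.gff3")
  set.seed(5)
  writeLines(c(">r1", rand_dna(600)), fa)
  writeLines(c("##gff-version 3",
               "r1\tx\tCDS\t101\t400\t.\t-\t0\tID=c1;product=hypothetical protein"),
             gff)
  ann <- read_genome(fa, gff)
  g <- ann$genes
  expect_equal(g$strand, "-")
  expect_true(g$hypothetical)
  expect_equal(g$length, 300L)
})

test_that("genes extending past their replicon are rejected by name", {
  reps <- c(chr1 = rand_dna(500))
  genes <- data.frame(gene_id = "gX", replicon_id = "chr1", start = 400L,
                      end = 600L, strand = "+", product = "p")
  expect_error(genome_annotation("sp", reps, genes), "gX")
  genes2 <- data.frame(gene_id = "gY", replicon_id = "nope", start = 1L,
                       end = 10L, strand = "+", product = "p")
  expect_error(genome_annotation("sp", reps, genes2), "gY")
})

test_that("the minimal TSV annotation dialect round-trips", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "t.fasta")
  tsv <- file.path(dir, "t.tsv")
  set.seed(6)
  writeLines(c(">c1", rand_dna(800)), fa)
  write.table(data.frame(gene_id = c("a", "b"), replicon = "c1",
                         start = c(10L, 500L), end = c(200L, 700L),
                         strand = c("+", "-"),
                         product = c("enzyme", "hypothetical protein")),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_annotation_tsv(fa, tsv)
  expect_equal(ann$genes$gene_id, c("a", "b"))
  expect_equal(ann$genes$hypothetical, c(FALSE, TRUE))
})

test_that("gap extraction follows the absorption rules", {
  reps <- c(chr = rand_dna(1000))
  mk <- function(genes) genome_annotation("sp", reps, genes)
  base <- function(...) data.frame(..., replicon_id = "chr",
                                   stringsAsFactors = FALSE)
  # plain gap between two genes
  ann <- mk(base(gene_id = c("g1", "g2"), start = c(1L, 501L),
                 end = c(300L, 900L), strand = "+", product = "p"))
  r <- extract_search_regions(ann)
  mid <- r[!is.na(r$left_gene_id) & !is.na(r$right_gene_id), ]
  expect_equal(c(mid$lo, mid$hi), c(301L, 500L))
  expect_equal(c(mid$left_gene_id, mid$right_gene_id), c("g1", "g2"))

  # short hypothetical ORF absorbed into the surrounding gap
  ann2 <- mk(base(gene_id = c("g1", "sORF", "g2"),
                  start = c(1L, 350L, 601L), end = c(300L, 499L, 900L),
                  strand = "+",
                  product = c("p", "hypothetical protein", "p")))
  r2 <- extract_search_regions(ann2)
  mid2 <- r2[!is.na(r2$left_gene_id) & !is.na(r2$right_gene_id), ]
  expect_equal(c(mid2$lo, mid2$hi), c(301L, 600L))
  expect_equal(mid2$absorbed_orf_ids, "sORF")

  # 250-nt hypothetical ORF is NOT absorbed (threshold is < 200)
  ann3 <- mk(base(gene_id = c("g1", "orf", "g2"),
                  start = c(1L, 350L, 701L), end = c(300L, 599L, 900L),
                  strand = "+",
                  product = c("p", "hypothetical protein", "p")))
  r3 <- extract_search_regions(ann3)
  mid3 <- r3[!is.na(r3$left_gene_id) & !is.na(r3$right_gene_id), ]
  expect_equal(nrow(mid3), 2L)
  expect_equal(mid3$lo, c(301L, 600L))
  expect_equal(mid3$hi, c(349L, 700L))
})

test_that("regions and non-absorbed genes tile linear replicons exactly", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    starts <- sort(sample(seq(1, 1800, by = 10), n))
    lens <- sample(30:120, n, replace = TRUE)
    ends <- pmin(starts + lens, 2000L)
    keep <- c(TRUE, starts[-1] > head(ends, -1))  # drop overlapping genes
    genes <- data.frame(gene_id = paste0("g", seq_len(sum(keep))),
                        replicon_id = "c", start = starts[keep],
                        end = ends[keep], strand = "+", product = "p")
    ann <- genome_annotation("sp", c(c = rand_dna(2000)), genes)
    r <- extract_search_regions(ann)
    covered <- sort(c(unlist(Map(seq, r$lo, r$hi)),
                      unlist(Map(seq, genes$start, genes$end))))
    expect_equal(covered, 1:2000)          # full tiling, no overlap
    expect_identical(r, extract_search_regions(ann))  # deterministic
  }
})

test_that("circular replicons emit one wrap-around region", {
  genes <- data.frame(gene_id = c("g1", "g2"), replicon_id = "c",
                      start = c(201L, 601L), end = c(400L, 800L),
                      strand = "+", product = "p")
  ann <- genome_annotation("sp", c(c = rand_dna(1000)), genes,
                           topology = "circular")
  r <- extract_search_regions(ann)
  wrapr <- r[r$wrap, ]
  expect_equal(nrow(wrapr), 1L)
  expect_equal(c(wrapr$lo, wrapr$hi), c(801L, 1200L))  # wraps to 200
  expect_equal(c(wrapr$left_gene_id, wrapr$right_gene_id), c("g2", "g1"))
  expect_equal(sum(r$hi - r$lo + 1) + sum(genes$end - genes$start + 1), 1000)
})

test_that("every absorbed ORF is short and hypothetical, on random layouts", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 12
    starts <- seq(1, by = 300, length.out = n)  # non-overlapping layout
    lens <- sample(c(40, 100, 150, 250), n, replace = TRUE)
    hyp <- sample(c(TRUE, FALSE), n, replace = TRUE)
    genes <- data.frame(gene_id = paste0("g", 1:n), replicon_id = "c",
                        start = starts, end = starts + lens - 1,
                        strand = "+",
                        product = ifelse(hyp, "hypothetical protein",
                                         "real enzyme"))
    ann <- genome_annotation("sp", c(c = rand_dna(3700)), genes)
    r <- extract_search_regions(ann)
    absorbed <- unlist(strsplit(r$absorbed_orf_ids[r$absorbed_orf_ids != ""],
                                ","))
    g <- ann$genes
    expect_true(all(g$hypothetical[match(absorbed, g$gene_id)]))
    expect_true(all(g$length[match(absorbed, g$gene_id)] < 200))
    # and conversely no short hypothetical ORF interrupts a region
    should_absorb <- g$gene_id[g$hypothetical & g$length < 200]
    expect_true(all(should_absorb %in% absorbed))
  }
})
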