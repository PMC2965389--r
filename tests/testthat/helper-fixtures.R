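# Shared fixtures: random sequences, in-memory training alignments, toy
# genomes on disk, and a cached default cohort for the heavier end-to-end
# checks.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A canonical planted terminator: clamp C + stem + GAAA loop + revcomp stem
# + 12 T, with optional flanks.  Clamp prevents chance stem extension.
planted_terminator <- function(stem = "GCCGGGCC", loop = "GAAA",
                               flank5 = "", flank3 = "") {
  paste0(flank5, "C", stem, loop,
         chartr("ACGT", "TGCA", paste(rev(strsplit(stem, "")[[1]]),
                                      collapse = "")),
         strrep("T", 12), flank3)
}

# Ungapped structure-annotated alignment of n independent planted
# terminators (stem L, loop 4, 12-T tails), as read_stockholm() would
# return it.
make_training_alignment <- function(n = 60, stem_len = 8, tail_t = 12,
                                    stem_gc = 0.8) {
  seqs <- vapply(seq_len(n), function(i) {
    s5 <- sample(c("G", "C", "A", "T"), stem_len, replace = TRUE,
                 prob = c(stem_gc / 2, stem_gc / 2,
                          (1 - stem_gc) / 2, (1 - stem_gc) / 2))
    s3 <- rev(chartr("ACGT", "TGCA", s5))
    paste(c(s5, sample(c("A", "C", "G", "T"), 4, replace = TRUE), s3,
            rep("T", tail_t), sample(c("A", "C", "G"), 12 - tail_t,
                                     replace = TRUE)),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("term", seq_len(n))
  list(seqs = seqs,
       ss_cons = paste0(strrep("<", stem_len), "....",
                        strrep(">", stem_len), strrep(".", 12)))
}

# Two-gene toy genome written as FASTA + GFF3; returns the paths.
write_toy_genome <- function(dir = local({d <- tempfile("toygenome")
                                          dir.create(d); d}),
                             len = 1000,
                             genes = data.frame(
                               gene_id = c("g1", "g2"),
                               start = c(1L, 501L), end = c(300L, 900L),
                               strand = c("+", "+"),
                               product = c("ABC transporter",
                                           "hypothetical protein"))) {
  fa <- file.path(dir, "toy.fasta")
  gff <- file.path(dir, "toy.gff3")
  set.seed(99)
  writeLines(c(">chr1", rand_dna(len, 0.5)), fa)
  attrs <- sprintf("ID=%s;product=%s", genes$gene_id, genes$product)
  writeLines(c("##gff-version 3",
               sprintf("chr1\ttoy\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       genes$start, genes$end, genes$strand, attrs)),
             gff)
  list(fasta = fa, gff = gff)
}

# Cached small cohort shared by several end-to-end tests (one generation +
# screen, reused read-only).
.fixture_cache <- new.env(parent = emptyenv())

small_cohort_screen <- function() {
  if (is.null(.fixture_cache$small)) {
    spec <- synthetic_spec(n_species = 3, genes_per_species = 80,
                           n_families = 16, n_plant_5p = 30,
                           n_is_elements = 3,
                           n_violators = c(distance = 3, ratio = 3,
                                           strand = 3),
                           seed = 11)
    coh <- generate_cohort(spec)
    .fixture_cache$small <- list(cohort = coh, screen = screen_cohort(coh))
  }
  .fixture_cache$small
}
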